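test_that("grayscale ball erosion matches a brute-force minimum-filter oracle", {
  set.seed(8)
  v <- array(runif(10 * 11 * 12) * 100, c(10, 11, 12))
  vol <- pa_volume(v, c(1, 1, 1))
  for (radius in c(1, 1.5, 2)) {
    er <- erode_sphere(vol, radius)
    offs <- expand.grid(z = -2:2, y = -2:2, x = -2:2)
    offs <- offs[offs$z^2 + offs$y^2 + offs$x^2 <= radius^2, ]
    bf <- array(Inf, dim(v))
    for (k in seq_len(nrow(offs)))
      for (z in 1:10) for (y in 1:11) for (x in 1:12) {
        zz <- z + offs$z[k]; yy <- y + offs$y[k]; xx <- x + offs$x[k]
        if (zz >= 1 && zz <= 10 && yy >= 1 && yy <= 11 && xx >= 1 && xx <= 12)
          bf[z, y, x] <- min(bf[z, y, x], v[zz, yy, xx])
      }
    expect_equal(unclass(er), bf, ignore_attr = TRUE)
  }
})

test_that("erosion identities: constant volumes, point sources, tiny radii", {
  const <- pa_volume(array(5, c(6, 6, 6)), c(1, 1, 1))
  expect_equal(unclass(erode_sphere(const, 3)), unclass(const),
               ignore_attr = TRUE)
  pt <- array(0, c(7, 7, 7)); pt[4, 4, 4] <- 100
  er <- erode_sphere(pa_volume(pt, c(1, 1, 1)), 1)
  expect_true(all(er == 0))
  v <- pa_volume(array(runif(4^3), c(4, 4, 4)), c(1, 1, 1))
  expect_identical(unclass(erode_sphere(v, 0)), unclass(v))
  expect_warning(out <- erode_sphere(v, 0.2), "identity")
  expect_equal(unclass(out), unclass(v), ignore_attr = TRUE)
})

test_that("eroding a 10 um cylinder by 4 um leaves approximately a 6 um cylinder", {
  d <- c(31, 31, 40)
  cyl10 <- make_cylinder(d, 10, axis = 3)
  er <- erode_sphere(pa_volume(cyl10, c(1, 1, 1)), 4)
  mid <- 10:30  # away from the open ends
  area_eroded <- sum(unclass(er)[, , mid] > 50) / length(mid)
  area_analytic <- sum(make_cylinder(d, 6, axis = 3)[, , 15] > 50)
  expect_lt(abs(area_eroded / area_analytic - 1), 0.15)
})

test_that("erosion is monotone in radius, so MID rises and IR falls", {
  set.seed(9)
  v <- pa_volume(array(runif(12^3) * 50, c(12, 12, 12)), c(1, 1, 1))
  e1 <- erode_sphere(v, 1); e2 <- erode_sphere(v, 2); e3 <- erode_sphere(v, 3)
  expect_true(all(unclass(e2) <= unclass(e1) + 1e-12))
  expect_true(all(unclass(e3) <= unclass(e2) + 1e-12))
  m <- vapply(list(e1, e2, e3), function(e) erosion_metrics(v, e), numeric(2))
  expect_true(all(diff(m["mid", ]) >= -1e-12))
  expect_true(all(diff(m["ir", ]) <= 1e-12))
})

test_that("erosion metrics follow their definitions", {
  v <- pa_volume(array(10, c(2, 2, 2)), c(1, 1, 1))
  expect_equal(erosion_metrics(v, v), c(mid = 0, ir = 1))
  z <- pa_volume(array(0, c(2, 2, 2)), c(1, 1, 1))
  expect_equal(erosion_metrics(v, z), c(mid = 10, ir = 0))
  half <- pa_volume(array(5, c(2, 2, 2)), c(1, 1, 1))
  expect_equal(erosion_metrics(v, half), c(mid = 5, ir = 0.5))
  expect_error(erosion_metrics(z, z), "all-zero")
})

test_that("sweep normalization anchors the curves and interpolates the crossing", {
  set.seed(10)
  ph <- generate_phantom(phantom_spec(shape = c(32, 48, 48), stage = "normal",
                                      seed = 15, attenuation = 0,
                                      noise_sd = 0))
  sw <- sweep_erosion_radius(ph$intensity, radii = c(1, 2, 3, 4))
  expect_equal(sw$mid_norm[1], 0)
  expect_equal(sw$ir_norm[1], 1)
  expect_true(all(diff(sw$mid_raw) >= -1e-12))
  expect_true(all(diff(sw$ir_raw) <= 1e-12))
  expect_gte(sw$optimal_radius, 1)
  expect_lte(sw$optimal_radius, 4)
  expect_error(sweep_erosion_radius(ph$intensity, radii = c(1, 2)),
               "at least 3")
})

test_that("adaptive threshold: constant volumes give empty masks at zero offset", {
  # strict inequality: nothing exceeds its own local mean
  const <- pa_volume(array(4, c(8, 8, 8)), c(1, 1, 1))
  expect_equal(sum(segment_adaptive(const, 25, 0)), 0)
  expect_equal(sum(segment_adaptive(const, 25, -0.1)), 0)
})

test_that("adaptive threshold recovers a bright tube on dark background", {
  set.seed(11)
  d <- c(31, 31, 40)
  a <- make_cylinder(d, 10, axis = 3, value = 100)
  truth <- a > 50
  noisy <- pmax(a + rnorm(length(a), 0, 5), 0); dim(noisy) <- d
  m <- segment_adaptive(pa_volume(noisy, c(1, 1, 1)), 25, 0)
  dice <- 2 * sum(m & truth) / (sum(m) + sum(truth))
  expect_gte(dice, 0.9)
})

test_that("pure local-mean threshold is invariant under additive intensity shifts", {
  set.seed(12)
  a <- array(runif(10^3) * 20, c(10, 10, 10))
  a[4:6, 4:6, ] <- a[4:6, 4:6, ] + 100
  v1 <- pa_volume(a, c(1, 1, 1))
  v2 <- pa_volume(a + 37, c(1, 1, 1))
  m1 <- segment_adaptive(v1, 8, 0, min_intensity = 0)
  m2 <- segment_adaptive(v2, 8, 0, min_intensity = 0)
  expect_same_mask(m1, m2)
})

test_that("median-volume component filter removes sub-median components", {
  d <- c(12, 12, 30)
  m <- array(FALSE, d)
  m[2, 2, 2] <- TRUE                       # size 1
  m[6, 6, 10:11] <- TRUE                   # size 2
  m[9:11, 4:11, 20:24] <- TRUE             # size 120
  out <- filter_small_components(pa_mask(m, c(1, 1, 1)))
  expect_false(out[2, 2, 2])
  expect_true(all(out[6, 6, 10:11]))
  expect_true(all(out[9:11, 4:11, 20:24]))
  # single component always survives
  single <- array(FALSE, c(4, 4, 4)); single[2, 2, 2:3] <- TRUE
  expect_same_mask(filter_small_components(pa_mask(single, c(1, 1, 1))),
                   single)
  # empty mask passes through
  empty <- pa_mask(array(FALSE, c(4, 4, 4)), c(1, 1, 1))
  expect_equal(sum(filter_small_components(empty)), 0)
})

test_that("component filter agrees with a label-and-sort oracle on random masks", {
  set.seed(13)
  for (rep in 1:3) {
    m <- array(runif(18^3) < 0.04, c(18, 18, 18))
    mask <- pa_mask(m, c(1, 1, 1))
    out <- filter_small_components(mask)
    lab <- label_components(mask)
    sizes <- tabulate(lab)
    keep_ids <- which(sizes >= median(sizes))
    expected <- array(lab %in% keep_ids & m, dim(m))
    expect_same_mask(out, expected)
  }
})

test_that("connected-component labelling matches a flood-fill oracle", {
  set.seed(14)
  m <- array(runif(10^3) < 0.15, c(10, 10, 10))
  lab <- label_components(pa_mask(m, c(1, 1, 1)), 26L)
  # R-side BFS flood fill
  oracle <- array(0L, dim(m))
  nxt <- 0L
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  for (i in which(m)) {
    if (oracle[i] > 0L) next
    nxt <- nxt + 1L
    queue <- i
    oracle[i] <- nxt
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      co <- arrayInd(cur, dim(m))
      nb <- sweep(offs, 2, as.integer(co), "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= 10 & nb[, 2] >= 1 & nb[, 2] <= 10 &
        nb[, 3] >= 1 & nb[, 3] <= 10
      nb <- nb[ok, , drop = FALSE]
      lin <- nb[, 1] + 10L * (nb[, 2] - 1L) + 100L * (nb[, 3] - 1L)
      hit <- lin[m[lin] & oracle[lin] == 0L]
      oracle[hit] <- nxt
      queue <- c(queue, hit)
    }
  }
  # same partition (labels may be permuted)
  expect_equal(max(lab), nxt)
  for (id in seq_len(nxt))
    expect_equal(length(unique(lab[oracle == id])), 1L)
})
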