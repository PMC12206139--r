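test_that("vessel instances follow 26-connectivity", {
  d <- c(10, 20, 20)
  two <- (make_cylinder(d, 2, axis = 1, centre = c(5, 5)) +
            make_cylinder(d, 2, axis = 1, centre = c(15, 15))) > 0
  inst <- vessel_instances(pa_mask(two, c(1, 1, 1), role = "vessel"))
  expect_equal(length(inst$ids), 2L)
  touching <- array(FALSE, c(4, 4, 4))
  touching[1:2, 1, 1] <- TRUE; touching[3, 1, 1] <- TRUE  # face-sharing
  inst2 <- vessel_instances(pa_mask(touching, c(1, 1, 1), role = "vessel"))
  expect_equal(length(inst2$ids), 1L)
  none <- vessel_instances(pa_mask(array(FALSE, c(4, 4, 4)), c(1, 1, 1),
                                   role = "vessel"))
  expect_length(none$ids, 0)
})

test_that("Z_max is the deepest occupied slice", {
  m <- array(FALSE, c(10, 4, 4))
  m[3:7, 2, 2] <- TRUE
  expect_equal(vessel_zmax(m), 7L)
  single <- array(FALSE, c(5, 4, 4)); single[1, 1, 1] <- TRUE
  expect_equal(vessel_zmax(single), 1L)
  set.seed(21)
  r <- array(runif(8^3) < 0.2, c(8, 8, 8))
  r[8, 1, 1] <- TRUE
  # exhaustive scan oracle
  zs <- integer(0)
  for (z in 1:8) if (any(r[z, , ])) zs <- c(zs, z)
  expect_equal(vessel_zmax(r), max(zs))
  expect_error(vessel_zmax(array(FALSE, c(3, 3, 3))), "empty")
})

test_that("the upper-sinusoid mask clears the deepest vessel layer and below", {
  s <- array(FALSE, c(10, 3, 3))
  s[c(2, 5, 9), 2, 2] <- TRUE
  out <- sinusoid_upper_mask(pa_mask(s, c(1, 1, 1), role = "sinusoid"), 5L)
  expect_true(out[2, 2, 2])
  expect_false(out[5, 2, 2])
  expect_false(out[9, 2, 2])
  # z_max = 1 clears everything
  all1 <- sinusoid_upper_mask(pa_mask(s, c(1, 1, 1)), 1L)
  expect_equal(sum(all1), 0)
  # z_max = slice count keeps everything except the last slice
  top <- sinusoid_upper_mask(pa_mask(s, c(1, 1, 1)), 10L)
  expect_equal(sum(top), sum(s[1:9, , ]))
})

test_that("a full canopy gives coverage 1, no sinusoids give 0", {
  d <- c(6, 8, 8)
  vessel <- array(FALSE, d); vessel[4, , ] <- TRUE   # flat plate at z = 4
  sin <- array(FALSE, d); sin[3, , ] <- TRUE          # canopy one slice above
  su <- sinusoid_upper_mask(pa_mask(sin, c(1, 1, 1)), 4L)
  expect_equal(coverage_rate(vessel, su), 1)
  su0 <- sinusoid_upper_mask(pa_mask(array(FALSE, d), c(1, 1, 1)), 4L)
  expect_equal(coverage_rate(vessel, su0), 0)
})

test_that("cumulative-presence coverage equals the per-column brute force", {
  set.seed(22)
  for (rep in 1:10) {
    vm <- array(runif(12^3) < 0.1, c(12, 12, 12))
    sm <- array(runif(12^3) < 0.15, c(12, 12, 12))
    if (!any(vm)) next
    inst <- vessel_instances(pa_mask(vm, c(1, 1, 1), role = "vessel"))
    for (id in inst$ids) {
      m <- inst$labels == id
      su <- sinusoid_upper_mask(pa_mask(sm, c(1, 1, 1)), vessel_zmax(m))
      r <- coverage_rate(m, su)
      cov <- 0; tot <- 0
      for (z in 1:12) for (y in 1:12) for (x in 1:12) if (m[z, y, x]) {
        tot <- tot + 1
        if (z > 1 && any(su[1:(z - 1), y, x])) cov <- cov + 1
      }
      expect_equal(r, cov / tot)
      expect_gte(r, 0); expect_lte(r, 1)
    }
  }
})

test_that("adding sinusoid voxels never decreases a coverage rate", {
  set.seed(23)
  vm <- array(runif(10^3) < 0.15, c(10, 10, 10))
  vm[1, , ] <- FALSE
  sm <- array(runif(10^3) < 0.1, c(10, 10, 10))
  rep <- coverage_report(pa_mask(vm, c(1, 1, 1), role = "vessel"),
                         pa_mask(sm, c(1, 1, 1), role = "sinusoid"))
  grow <- sm | array(runif(10^3) < 0.2, c(10, 10, 10))
  rep2 <- coverage_report(pa_mask(vm, c(1, 1, 1), role = "vessel"),
                          pa_mask(grow, c(1, 1, 1), role = "sinusoid"))
  expect_true(all(rep2$per_vessel$rate >= rep$per_vessel$rate - 1e-12))
})

test_that("HC/LC classification is strict at the threshold", {
  cls <- classify_coverage(c(0.9, 0.4))
  expect_identical(cls$class, c("HC", "LC"))
  expect_identical(classify_coverage(0.5)$class, "LC")   # tie goes to LC
  expect_identical(classify_coverage(0.5000001)$class, "HC")
  p <- classify_coverage(c(0.9, 0.4, 0.6))
  expect_equal(p$hc_fraction + p$lc_fraction, 1)
  # permuting vessels permutes labels only
  r <- c(0.2, 0.8, 0.55)
  expect_identical(classify_coverage(r)$class[c(3, 1, 2)],
                   classify_coverage(r[c(3, 1, 2)])$class)
})

test_that("coverage reports summarise per-vessel rates and classes", {
  ph <- tiny_phantom()
  rep <- coverage_report(ph$vessel_truth, ph$sinusoid_truth)
  expect_equal(rep$summary$n_vessels, nrow(rep$per_vessel))
  expect_true(all(rep$per_vessel$rate >= 0 & rep$per_vessel$rate <= 1))
  expect_equal(rep$summary$hc_fraction + rep$summary$lc_fraction, 1)
  expect_identical(rep$per_vessel$class,
                   ifelse(rep$per_vessel$rate > 0.5, "HC", "LC"))
  # truth phantom vessels grow from the base under a sinusoid mesh, so a
  # substantial fraction of their voxels sits below canopy columns
  expect_gt(rep$summary$mean_rate, 0.15)
  # and removing the canopy drives every rate to zero
  none <- coverage_report(ph$vessel_truth,
                          pa_mask(array(FALSE, dim(ph$sinusoid_truth)),
                                  spacing(ph$sinusoid_truth),
                                  role = "sinusoid"))
  expect_true(all(none$per_vessel$rate == 0))
})
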