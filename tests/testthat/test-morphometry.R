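test_that("thinning reduces a straight tube to a single centerline path", {
  d <- c(11, 11, 106)
  tube <- array(FALSE, d)
  for (x in 4:103) tube[, , x] <- make_cylinder(c(11, 11, 1), 3)[, , 1] > 0
  sk <- skeletonize(pa_mask(tube, c(1, 1, 1)))
  g <- build_graph(sk)
  expect_equal(length(g$branches), 1L)
  expect_true(abs(nrow(g$coords) - 100) <= 3)
  expect_true(all(g$degree <= 2))
  expect_equal(sum(g$degree == 1), 2L)
  # topology preservation: one component in, one out
  expect_equal(max(label_components(sk)), 1L)
})

test_that("thinning a solid ball leaves only a few central voxels", {
  ball <- array(FALSE, c(15, 15, 15))
  for (z in 1:15) for (y in 1:15) for (x in 1:15)
    if ((z - 8)^2 + (y - 8)^2 + (x - 8)^2 <= 36) ball[z, y, x] <- TRUE
  sk <- skeletonize(pa_mask(ball, c(1, 1, 1)))
  expect_lte(sum(sk), 10)
})

test_that("disjoint structures keep disjoint skeletons", {
  d <- c(24, 24, 40)
  two <- make_cylinder(d, 3, axis = 3, centre = c(6, 6)) +
    make_cylinder(d, 3, axis = 3, centre = c(18, 18))
  sk <- skeletonize(pa_mask(two > 0, c(1, 1, 1)))
  expect_equal(max(label_components(sk)), 2L)
  empty <- skeletonize(pa_mask(array(FALSE, c(4, 4, 4)), c(1, 1, 1)))
  expect_equal(sum(empty), 0)
})

test_that("graph building labels nodes and branches on canonical shapes", {
  # straight 11-voxel path: 2 endpoints, 1 branch of physical length 10
  m <- make_path_mask(c(5, 5, 15), 3, 3, 3:13)
  g <- build_graph(pa_mask(m, c(1, 1, 1)))
  expect_equal(length(g$node_ids), 2L)
  expect_equal(length(g$branches), 1L)
  expect_equal(g$branch_info$path_length_um, 10)
  expect_equal(g$branch_info$tortuosity, 1)
  # Y: three 10-voxel arms meeting at one voxel
  yd <- c(25, 25, 5)
  ym <- array(FALSE, yd)
  ym[12, 12, 3] <- TRUE
  ym[13:22, 12, 3] <- TRUE           # down
  ym[cbind(11:2, 11:2, 3)] <- TRUE   # diagonal up-left
  ym[cbind(11:2, 13:22, 3)] <- TRUE  # diagonal up-right
  gy <- build_graph(pa_mask(ym, c(1, 1, 1)))
  expect_equal(sum(gy$degree[gy$node_ids] >= 3), 1L)
  expect_equal(sum(gy$degree[gy$node_ids] == 1), 3L)
  expect_equal(length(gy$branches), 3L)
})

test_that("branch decomposition covers every skeleton voxel exactly once", {
  ph <- tiny_phantom()
  g <- build_graph(skeletonize(ph$sinusoid_truth))
  n <- nrow(g$coords)
  interior <- unlist(lapply(g$branches, function(b) b[-c(1, length(b))]))
  expect_false(any(duplicated(interior)))
  covered <- sort(unique(c(unlist(g$branches), g$node_ids)))
  expect_identical(covered, seq_len(n))
  # branch endpoints are nodes; path length >= Euclidean end-to-end distance
  bi <- g$branch_info
  ends_are_nodes <- vapply(g$branches, function(b)
    all(c(b[1], b[length(b)]) %in% g$node_ids) || b[1] == b[length(b)],
    logical(1))
  expect_true(all(ends_are_nodes))
  expect_true(all(bi$path_length_um >= bi$euclidean_um - 1e-9))
  expect_true(all(bi$tortuosity > 0 & bi$tortuosity <= 1 + 1e-9, na.rm = TRUE))
})

test_that("cylinder-model metrics recover an analytic cylinder", {
  d <- c(15, 15, 106)
  tube <- array(FALSE, d)
  for (x in 4:103) tube[, , x] <- make_cylinder(c(15, 15, 1), 3)[, , 1] > 0
  mask <- pa_mask(tube, c(1, 1, 1), role = "sinusoid")
  m <- sinusoid_metrics(mask)
  expect_gte(m$radius_um, 2.5); expect_lte(m$radius_um, 3.5)
  expect_gte(m$length_um, 95); expect_lte(m$length_um, 105)
  expect_equal(m$tortuosity, 1, tolerance = 1e-6)
})

test_that("semicircular branches approach the 2/pi straightness limit", {
  R <- 40
  th <- seq(0, pi, length.out = 4000)
  pts <- unique(cbind(round(10 + R * sin(th)), round(50 + R * cos(th)), 5))
  arc <- array(FALSE, c(60, 100, 9)); arc[pts] <- TRUE
  g <- build_graph(skeletonize(pa_mask(arc, c(1, 1, 1))))
  main <- g$branch_info[which.max(g$branch_info$path_length_um), ]
  expect_equal(main$tortuosity, 2 / pi, tolerance = 0.05)
})

test_that("reported radius scales linearly with voxel spacing", {
  ph <- tiny_phantom()
  m1 <- sinusoid_metrics(ph$sinusoid_truth)
  mask2 <- pa_mask(unclass(ph$sinusoid_truth), spacing = c(2, 2, 2),
                   role = "sinusoid")
  m2 <- sinusoid_metrics(mask2)
  expect_equal(m2$radius_um, 2 * m1$radius_um, tolerance = 1e-9)
})

test_that("sinusoid density follows D = V_S / (V - V_L)", {
  expect_equal(sinusoid_density(10, 20, 120), 0.1)
  expect_equal(sinusoid_density(0, 20, 120), 0)
  expect_true(is.na(sinusoid_density(5, 120, 120)))
  ph <- tiny_phantom()
  r <- ph$realized
  expect_equal(r$density,
               r$sinusoid_voxels / (r$total_voxels - r$vessel_voxels))
})

test_that("vessel-count ratios normalise to the maximum and permute with input", {
  expect_equal(vessel_count_ratio(c(3, 6, 2)), c(0.5, 1, 2 / 6))
  expect_equal(vessel_count_ratio(5), 1)
  x <- c(4, 9, 1, 9)
  p <- c(3, 1, 4, 2)
  expect_equal(vessel_count_ratio(x)[p], vessel_count_ratio(x[p]))
  expect_error(vessel_count_ratio(c(0, 0)), "positive")
})

test_that("relative changes use the larger value as denominator, averaged per subject", {
  ref <- separation_reference()
  early <- ref[ref$stage == "early", ]
  uns <- early[!early$separated, ]; sep <- early[early$separated, ]
  dens <- relative_change_table(uns$density, sep$density)
  expect_equal(dens$mean_pct, 46.48, tolerance = 0.005)
  expect_identical(dens$direction, "decrease")
  tort <- relative_change_table(uns$tortuosity, sep$tortuosity)
  expect_equal(tort$mean_pct, 12.38, tolerance = 0.005)
  rad <- relative_change_table(uns$radius_um, sep$radius_um)
  expect_identical(rad$direction, "increase")
  same <- relative_change_table(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$mean_pct, 0)
  expect_error(relative_change_table(c(1, -1), c(1, 1)), "positive")
  expect_true(all(dens$per_subject_pct >= 0 & dens$per_subject_pct <= 100))
})
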