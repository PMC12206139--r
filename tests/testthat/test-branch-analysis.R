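# branch classes on hand-constructed skeletons with known topology

y_graph <- function() {
  ym <- array(FALSE, c(25, 25, 5))
  ym[12, 12, 3] <- TRUE
  ym[13:22, 12, 3] <- TRUE
  ym[cbind(11:2, 11:2, 3)] <- TRUE
  ym[cbind(11:2, 13:22, 3)] <- TRUE
  build_graph(pa_mask(ym, c(1, 1, 1)))
}

h_graph <- function() {
  # two junctions joined by one bar, four diagonal arms (diagonal arms avoid
  # spurious 26-adjacency between arm and bar voxels): 4 dead-ends + 1 crossing
  hm <- array(FALSE, c(30, 15, 5))
  hm[12, 8, 3] <- TRUE; hm[18, 8, 3] <- TRUE        # the two junctions
  hm[cbind(11:5, 7:1, 3)] <- TRUE                   # arms of junction 1
  hm[cbind(11:5, 9:15, 3)] <- TRUE
  hm[cbind(19:25, 7:1, 3)] <- TRUE                  # arms of junction 2
  hm[cbind(19:25, 9:15, 3)] <- TRUE
  hm[13:17, 8, 3] <- TRUE                           # connecting bar
  build_graph(pa_mask(hm, c(1, 1, 1)))
}

test_that("a Y-shaped skeleton has only dead-end branches", {
  cls <- classify_branches(y_graph())
  expect_true(all(cls$branches$class == "dead_end"))
  expect_equal(unname(cls$fractions["dead_end"]), 1)
})

test_that("an H-shaped skeleton has four dead-ends and one crossing", {
  g <- h_graph()
  cls <- classify_branches(g)
  expect_equal(sum(cls$branches$class == "dead_end"), 4L)
  expect_equal(sum(cls$branches$class == "crossing"), 1L)
  expect_equal(sum(cls$branches$class == "complex"), 0L)
  expect_equal(unname(cls$fractions), c(0.8, 0.2, 0), tolerance = 1e-12)
})

test_that("classification matches brute-force rule application on a junction chain", {
  # ladder with 3 rungs: two rails interrupted by junctions, rungs between
  d <- c(40, 15, 5)
  m <- array(FALSE, d)
  m[5:35, 3, 3] <- TRUE     # left rail
  m[5:35, 11, 3] <- TRUE    # right rail
  for (z in c(10, 20, 30)) m[z, 4:10, 3] <- TRUE  # rungs
  g <- build_graph(pa_mask(m, c(1, 1, 1)))
  cls <- classify_branches(g)
  # independent application of the declared rule from the graph's branch info
  bi <- g$branch_info
  jj <- which(bi$deg1 >= 3 & bi$deg2 >= 3)
  ends <- lapply(g$branches[jj], function(b) unique(c(b[1], b[length(b)])))
  tab <- table(unlist(ends))
  expected <- ifelse(bi$deg1 == 1 | bi$deg2 == 1, "dead_end", "crossing")
  for (i in seq_along(jj)) {
    sharers <- sum(tab[as.character(ends[[i]])] - 1L)
    expected[jj[i]] <- if (sharers >= 2) "complex" else "crossing"
  }
  expect_identical(cls$branches$class, expected)
  # a 3-rung ladder's inner rail segments each touch >= 2 other junction-junction
  # branches, so complex branches must exist
  expect_gt(sum(cls$branches$class == "complex"), 0)
  expect_equal(sum(cls$fractions), 1, tolerance = 1e-9)
})

test_that("every branch gets exactly one label and fractions sum to one", {
  ph <- tiny_phantom()
  g <- build_graph(skeletonize(ph$sinusoid_truth))
  cls <- classify_branches(g)
  expect_equal(nrow(cls$branches), nrow(g$branch_info))
  expect_true(all(cls$branches$class %in% c("dead_end", "crossing", "complex")))
  expect_equal(sum(cls$fractions), 1, tolerance = 1e-9)
  expect_equal(branch_fractions(cls), cls$fractions)
})

test_that("box counting is exact on lines, cubes and single voxels", {
  line <- cbind(rep(1, 256), rep(1, 256), 1:256)
  fd_line <- box_count_fd(line)
  expect_gte(fd_line$fd, 0.9); expect_lte(fd_line$fd, 1.1)
  cube <- as.matrix(expand.grid(1:64, 1:64, 1:64))
  fd_cube <- box_count_fd(cube)
  expect_gte(fd_cube$fd, 2.8); expect_lte(fd_cube$fd, 3.05)
  expect_equal(box_count_fd(matrix(c(5, 5, 5), 1))$fd, 0)
})

test_that("box counts are monotone, anchored and translation invariant", {
  set.seed(20)
  vox <- unique(cbind(sample(1:64, 300, TRUE), sample(1:64, 300, TRUE),
                      sample(1:64, 300, TRUE)))
  r <- box_count_fd(vox)
  expect_true(all(diff(r$counts) <= 0))
  expect_equal(r$counts[1], nrow(vox))  # N(1) = voxel count
  shifted <- box_count_fd(vox + 32L)
  expect_equal(r$counts, shifted$counts)
  expect_equal(r$fd, shifted$fd)
})

test_that("per-class fractal dimensions isolate each class's voxel set", {
  cls <- classify_branches(y_graph())
  fds <- fd_by_class(cls, sizes = c(1, 2, 4, 8))
  whole <- box_count_fd(y_graph()$coords, sizes = c(1, 2, 4, 8))$fd
  expect_equal(unname(fds["dead_end"]), whole)
  expect_true(is.na(fds["crossing"]))
  expect_true(is.na(fds["complex"]))
})

test_that("denser voxel classes have larger fractal dimension", {
  # synthetic classification: a space-filling trunk set vs one sparse line
  grid_lines <- do.call(rbind, lapply(seq(1, 61, by = 4), function(y)
    do.call(rbind, lapply(seq(1, 61, by = 4), function(z)
      cbind(z, y, 1:64)))))
  one_line <- cbind(1, 1, 1:64)
  fake <- structure(list(class_voxels = list(dead_end = one_line,
                                             crossing = NULL,
                                             complex = grid_lines)),
                    class = "branch_classification")
  fds <- fd_by_class(fake)
  expect_gt(fds["complex"], fds["dead_end"])
  # a union of parallel lines stays close to dimension 1 at small scales
  few <- do.call(rbind, lapply(c(1, 30, 60), function(y) cbind(y, 1, 1:64)))
  fd_few <- box_count_fd(few, sizes = c(1, 2, 4, 8))$fd
  expect_gte(fd_few, 0.9); expect_lte(fd_few, 1.3)
})
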