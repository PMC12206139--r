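#' Classify skeleton branches as dead-end, crossing, or complex
#'
#' The classification is purely topological and applied globally across the
#' whole 3D skeleton:
#' * **dead_end** — the branch has at least one endpoint of degree 1
#'   (a terminal path, often indicating obstructed flow);
#' * among branches joining two junctions (both endpoint degrees >= 3):
#'   **complex** if the branch shares a junction with at least two other
#'   junction-junction branches (it participates in a multi-segment trunk
#'   that conducts flow), **crossing** otherwise (an isolated connector
#'   between two junctions).
#'
#' @param graph a `skeleton_graph` from [build_graph()].
#' @return An object of class `branch_classification`: data frame `branches`
#'   (id, class, n_voxels, path_length_um), `fractions` (named vector over
#'   the three classes, summing to 1), and `class_voxels` (per-class matrix
#'   of skeleton voxel coordinates).
#' @export
classify_branches <- function(graph) {
  bi <- graph$branch_info
  if (nrow(bi) == 0L) stop("graph has no branches to classify")
  jj <- bi$deg1 >= 3L & bi$deg2 >= 3L
  dead <- bi$deg1 == 1L | bi$deg2 == 1L
  cls <- rep("crossing", nrow(bi))
  cls[dead] <- "dead_end"
  # count, for each junction-junction branch, how many OTHER junction-junction
  # branches share one of its junction nodes
  if (any(jj)) {
    jj_idx <- which(jj)
    ends <- lapply(graph$branches[jj_idx], function(b) unique(c(b[1], b[length(b)])))
    node_tab <- table(unlist(ends))
    for (i in seq_along(jj_idx)) {
      sharers <- sum(node_tab[as.character(ends[[i]])] - 1L)
      cls[jj_idx[i]] <- if (sharers >= 2L) "complex" else "crossing"
    }
  }
  cls[!dead & !jj & !(bi$deg1 >= 3L | bi$deg2 >= 3L)] <- "crossing"  # pure cycles
  branches <- data.frame(id = bi$id, class = cls, n_voxels = bi$n_voxels,
                         path_length_um = bi$path_length_um)
  counts <- c(dead_end = sum(cls == "dead_end"),
              crossing = sum(cls == "crossing"),
              complex = sum(cls == "complex"))
  fractions <- counts / sum(counts)
  class_voxels <- lapply(c("dead_end", "crossing", "complex"), function(cl) {
    rows <- unique(unlist(graph$branches[cls == cl]))
    graph$coords[rows, , drop = FALSE]
  })
  names(class_voxels) <- c("dead_end", "crossing", "complex")
  structure(list(branches = branches, fractions = fractions,
                 class_voxels = class_voxels, dim = graph$dim),
            class = "branch_classification")
}

#' @export
print.branch_classification <- function(x, ...) {
  cat("<branch_classification>", nrow(x$branches), "branches:",
      paste(sprintf("%s %.1f%%", names(x$fractions), 100 * x$fractions),
            collapse = ", "), "\n")
  invisible(x)
}

#' Branch-class fractions
#' @param classification a `branch_classification`.
#' @return Named numeric vector of count-based class proportions (sum 1).
#' @export
branch_fractions <- function(classification) classification$fractions

#' Box-counting fractal dimension of a voxel set
#'
#' The voxel set is covered by an origin-anchored partition into cubes of
#' side `L` voxels and the number of occupied cubes `N(L)` is counted for
#' each size. The fractal dimension is the least-squares slope of
#' `log N(L)` versus `log(1/L)`. Sizes at which the count has saturated
#' (`N = 1`, one covering box) or not yet left the voxel resolution
#' (`N = ` voxel count) are excluded from the fit; a set occupying a single
#' box at every size has dimension 0.
#'
#' @param voxels an `n x 3` matrix of voxel indices, or a logical 3D array /
#'   `pa_mask`.
#' @param sizes box side lengths in voxels (>= 2 values; default dyadic
#'   `c(1, 2, 4, 8, 16, 32)`).
#' @return A list of class `fd_result`: `sizes`, `counts`, `fd`,
#'   `r_squared`, `n_voxels`.
#' @export
box_count_fd <- function(voxels, sizes = c(1, 2, 4, 8, 16, 32)) {
  if (inherits(voxels, "pa_mask") ||
      (is.array(voxels) && length(dim(voxels)) == 3L))
    voxels <- which(array(as.logical(voxels), dim(voxels)), arr.ind = TRUE)
  voxels <- as.matrix(voxels)
  if (nrow(voxels) == 0L) stop("empty voxel set")
  sizes <- sort(unique(as.integer(sizes)))
  if (length(sizes) < 2L) stop("need at least two box sizes")
  v0 <- sweep(voxels, 2, apply(voxels, 2, min))  # 0-based, translation invariant
  counts <- vapply(sizes, function(L) {
    b <- v0 %/% L
    M <- max(b) + 2
    length(unique(b[, 1] + M * (b[, 2] + M * b[, 3])))
  }, numeric(1))
  nvox <- nrow(voxels)
  loglog_slope <- function(x, y) {
    # closed-form least squares; avoids lm's perfect-fit warnings
    lx <- log(x); ly <- log(y)
    sl <- sum((lx - mean(lx)) * (ly - mean(ly))) / sum((lx - mean(lx))^2)
    res <- ly - mean(ly) - sl * (lx - mean(lx))
    tot <- sum((ly - mean(ly))^2)
    c(slope = sl, r2 = if (tot > 0) 1 - sum(res^2) / tot else NA_real_)
  }
  keep <- counts > 1 & counts < nvox
  fd <- 0; r2 <- NA_real_
  if (sum(keep) >= 2L) {
    fit <- loglog_slope(sizes[keep], counts[keep])
    fd <- -fit[["slope"]]; r2 <- fit[["r2"]]
  } else if (length(unique(counts)) >= 2L) {
    fit <- loglog_slope(sizes, counts)
    fd <- -fit[["slope"]]; r2 <- fit[["r2"]]
  }
  structure(list(sizes = sizes, counts = counts, fd = fd, r_squared = r2,
                 n_voxels = nvox), class = "fd_result")
}

#' @export
print.fd_result <- function(x, ...) {
  cat(sprintf("<fd_result> FD = %.3f (R^2 = %.3f) over box sizes %s; %d voxels\n",
              x$fd, x$r_squared, paste(x$sizes, collapse = ","), x$n_voxels))
  invisible(x)
}

#' Box-counting fractal dimension per branch class
#'
#' Applies [box_count_fd()] independently to each class's skeleton voxel
#' set; empty classes yield `NA`.
#'
#' @param classification a `branch_classification`.
#' @param sizes box sizes, see [box_count_fd()].
#' @return Named numeric vector of per-class fractal dimensions.
#' @export
fd_by_class <- function(classification, sizes = c(1, 2, 4, 8, 16, 32)) {
  vapply(classification$class_voxels, function(v) {
    if (is.null(v) || nrow(v) == 0L) return(NA_real_)
    box_count_fd(v, sizes)$fd
  }, numeric(1))
}
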