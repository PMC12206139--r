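#' Skeletonize a binary mask by 3D thinning
#'
#' Topology-preserving curve thinning: simple points (whose removal changes
#' neither the number of 26-connected foreground components nor the
#' 6-connected background topology) are deleted sequentially from the six
#' face directions in turn until the mask is stable, while curve endpoints
#' are preserved. Elongated structures reduce to one-voxel-wide 26-connected
#' centerline paths with the same number of components as the input.
#'
#' @param mask a `pa_mask`.
#' @return A `pa_mask` holding the skeleton (same spacing/role).
#' @export
skeletonize <- function(mask) {
  out <- cpp_thin3d(as.vector(mask), dim(mask))
  pa_mask(array(out, dim(mask)), spacing(mask), attr(mask, "role"))
}

# 26-neighbourhood offsets as a 26 x 3 integer matrix (z, y, x)
neighbour_offsets_26 <- function() {
  g <- expand.grid(z = -1:1, y = -1:1, x = -1:1)
  as.matrix(g[!(g$z == 0 & g$y == 0 & g$x == 0), ])
}

#' Build a centerline graph from a skeleton
#'
#' Skeleton voxels of 26-neighbour degree other than 2 become graph nodes
#' (degree 1: endpoints; degree >= 3: junctions); maximal degree-2 chains
#' between nodes become branches, each carrying its ordered voxel path and
#' physical path length (sum of inter-voxel centre distances, anisotropy
#' aware). Pure cycles without any node are traced as closed branches.
#'
#' @param skeleton a `pa_mask` holding a skeleton (e.g. from [skeletonize()]).
#' @return An object of class `skeleton_graph`: list with `coords` (n x 3
#'   voxel indices), `degree`, `node_ids`, `branches` (list of integer
#'   vectors of voxel row indices), `branch_info` (data frame with id,
#'   endpoint degrees, voxel count, path length in um, end-to-end Euclidean
#'   distance in um, tortuosity), `spacing`, `dim`.
#' @export
build_graph <- function(skeleton) {
  d <- dim(skeleton); sp <- spacing(skeleton)
  coords <- which(array(as.logical(skeleton), d), arr.ind = TRUE)
  colnames(coords) <- c("z", "y", "x")
  n <- nrow(coords)
  empty <- list(coords = coords, degree = integer(0), node_ids = integer(0),
                branches = list(),
                branch_info = data.frame(id = integer(0), deg1 = integer(0),
                                         deg2 = integer(0), n_voxels = integer(0),
                                         path_length_um = numeric(0),
                                         euclidean_um = numeric(0),
                                         tortuosity = numeric(0)),
                spacing = sp, dim = d)
  class(empty) <- "skeleton_graph"
  if (n == 0L) return(empty)
  lin <- (coords[, 1] - 1L) + d[1] * ((coords[, 2] - 1L) + d[2] * (coords[, 3] - 1L))
  id_of <- integer(prod(d))
  id_of[lin + 1L] <- seq_len(n)
  offs <- neighbour_offsets_26()
  # vectorised adjacency: for each offset, voxels whose shifted position is
  # inside the grid and also on the skeleton
  from <- integer(0); to <- integer(0)
  for (k in seq_len(nrow(offs))) {
    zz <- coords[, 1] + offs[k, 1]; yy <- coords[, 2] + offs[k, 2]
    xx <- coords[, 3] + offs[k, 3]
    ok <- zz >= 1L & zz <= d[1] & yy >= 1L & yy <= d[2] & xx >= 1L & xx <= d[3]
    if (!any(ok)) next
    lin2 <- (zz[ok] - 1L) + d[1] * ((yy[ok] - 1L) + d[2] * (xx[ok] - 1L))
    nb <- id_of[lin2 + 1L]
    hit <- nb > 0L
    from <- c(from, which(ok)[hit]); to <- c(to, nb[hit])
  }
  deg <- tabulate(from, nbins = n)
  adj <- vector("list", n)
  if (length(from)) {
    o <- order(from)
    adj_split <- split(to[o], from[o])
    adj[as.integer(names(adj_split))] <- adj_split
  }
  node_ids <- which(deg != 2L)
  step_len <- function(a, b)
    sqrt(sum(((coords[a, ] - coords[b, ]) * sp)^2))
  edge_key <- function(a, b) paste0(min(a, b), "_", max(a, b))
  used <- new.env(hash = TRUE, parent = emptyenv())
  branches <- list()
  trace_from <- function(u, v) {
    path <- c(u, v)
    prev <- u; cur <- v
    while (deg[cur] == 2L) {
      nb <- adj[[cur]]
      nxt <- if (nb[1] == prev) nb[2] else nb[1]
      path <- c(path, nxt)
      prev <- cur; cur <- nxt
      if (cur == u) break  # safety for cycles re-entering the start
    }
    path
  }
  for (u in node_ids) {
    for (v in adj[[u]]) {
      k <- edge_key(u, v)
      if (!is.null(used[[k]])) next
      path <- trace_from(u, v)
      m <- length(path)
      used[[edge_key(path[1], path[2])]] <- TRUE
      used[[edge_key(path[m - 1], path[m])]] <- TRUE
      branches[[length(branches) + 1L]] <- path
    }
  }
  # pure cycles: components made only of degree-2 voxels
  in_branch <- logical(n)
  for (b in branches) in_branch[b] <- TRUE
  in_branch[node_ids] <- TRUE
  left <- which(!in_branch & deg > 0L)
  while (length(left)) {
    u <- left[1]
    nb <- adj[[u]]
    path <- trace_from(u, nb[1])
    branches[[length(branches) + 1L]] <- path
    in_branch[path] <- TRUE
    left <- which(!in_branch & deg > 0L)
  }
  info <- data.frame(id = seq_along(branches))
  info$deg1 <- vapply(branches, function(b) deg[b[1]], integer(1))
  info$deg2 <- vapply(branches, function(b) deg[b[length(b)]], integer(1))
  info$n_voxels <- vapply(branches, length, integer(1))
  plen <- vapply(branches, function(b) {
    if (length(b) < 2L) return(0)
    sum(vapply(seq_len(length(b) - 1L),
               function(i) step_len(b[i], b[i + 1L]), numeric(1)))
  }, numeric(1))
  info$path_length_um <- plen
  info$euclidean_um <- vapply(branches, function(b)
    step_len(b[1], b[length(b)]), numeric(1))
  info$tortuosity <- ifelse(plen > 0, info$euclidean_um / plen, NA_real_)
  out <- list(coords = coords, degree = deg, node_ids = node_ids,
              branches = branches, branch_info = info, spacing = sp, dim = d)
  class(out) <- "skeleton_graph"
  out
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat(sprintf("<skeleton_graph> %d voxels, %d nodes (%d endpoints, %d junctions), %d branches\n",
              nrow(x$coords), length(x$node_ids),
              sum(x$degree[x$node_ids] == 1L),
              sum(x$degree[x$node_ids] >= 3L), length(x$branches)))
  invisible(x)
}

#' Skeleton-based morphometry of a sinusoid mask
#'
#' Headline metrics in the cylinder model of the microvasculature:
#' * `length_um`: skeleton voxel count times the mean in-plane spacing;
#' * `volume_um3`: foreground voxel count times the voxel volume;
#' * `radius_um`: `sqrt(volume / (pi * length))` (cylinder model);
#' * `tortuosity`: per-branch end-to-end Euclidean distance over path
#'   length (a straightness index in `(0, 1]`), averaged over branches
#'   weighted by branch path length.
#'
#' @param mask the sinusoid `pa_mask`.
#' @param graph the `skeleton_graph` built from `mask`'s skeleton; computed
#'   on the fly when `NULL`.
#' @return A one-row data frame with columns `length_um`, `volume_um3`,
#'   `radius_um`, `tortuosity`, `n_skeleton_voxels`, `n_branches`.
#' @export
sinusoid_metrics <- function(mask, graph = NULL) {
  if (is.null(graph)) graph <- build_graph(skeletonize(mask))
  sp <- spacing(mask)
  nsk <- nrow(graph$coords)
  len <- nsk * mean(sp[2:3])
  vol <- sum(mask) * prod(sp)
  radius <- if (len > 0) sqrt(vol / (pi * len)) else NA_real_
  bi <- graph$branch_info
  w <- bi$path_length_um
  tort <- if (nrow(bi) && sum(w) > 0)
    sum(bi$tortuosity * w, na.rm = TRUE) / sum(w[!is.na(bi$tortuosity)])
  else NA_real_
  data.frame(length_um = len, volume_um3 = vol, radius_um = radius,
             tortuosity = tort, n_skeleton_voxels = nsk,
             n_branches = nrow(bi))
}

#' Sinusoid distribution density
#'
#' `D = V_S / (V - V_L)`: the sinusoid volume relative to the non-vascular
#' tissue volume, so that changes in the vessel compartment do not bleed
#' into the density estimate.
#'
#' @param v_s sinusoid volume (um^3 or voxels, consistently).
#' @param v_l vessel volume.
#' @param v total volume.
#' @return The density `D`; `NA` when `v <= v_l`.
#' @export
sinusoid_density <- function(v_s, v_l, v) {
  stopifnot(v_s >= 0, v_l >= 0)
  if (v <= v_l) return(NA_real_)
  v_s / (v - v_l)
}

#' Normalised vessel-count ratios
#'
#' Divides each dataset's vessel component count by the maximum count across
#' the compared datasets, so the densest dataset scores 1.
#'
#' @param counts non-negative vessel counts, at least one positive.
#' @return Ratios in `[0, 1]` with the maximum attaining 1.
#' @export
vessel_count_ratio <- function(counts) {
  counts <- as.numeric(counts)
  if (any(counts < 0) || !any(counts > 0))
    stop("counts must be non-negative with at least one positive value")
  counts / max(counts)
}

#' Paired relative-change statistics across subjects
#'
#' For each subject with paired measurements `(a, b)` the relative change is
#' `|a - b| / max(a, b) * 100` percent — the larger of the two values is the
#' denominator, so the change is symmetric in the pair and bounded by 100%.
#' Per-subject changes are then averaged; the direction flag is the majority
#' sign of `b - a`.
#'
#' @param a,b positive paired measurement vectors (same length; one entry
#'   per subject). `a` is the first condition, `b` the second.
#' @return A list of class `stage_comparison`: `per_subject_pct`,
#'   `mean_pct`, `sd_pct`, `direction` (`"increase"`, `"decrease"` or
#'   `"none"`), `n`.
#' @export
relative_change_table <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b) || length(a) < 1L)
    stop("need at least one paired subject")
  if (any(a <= 0) || any(b <= 0))
    stop("relative changes are defined for positive values only")
  pct <- abs(a - b) / pmax(a, b) * 100
  s <- sign(b - a)
  direction <- if (sum(s) > 0) "increase" else if (sum(s) < 0) "decrease" else "none"
  structure(list(per_subject_pct = pct, mean_pct = mean(pct),
                 sd_pct = if (length(pct) > 1L) stats::sd(pct) else 0,
                 direction = direction, n = length(pct)),
            class = "stage_comparison")
}

#' @export
print.stage_comparison <- function(x, ...) {
  cat(sprintf("<stage_comparison> n = %d subjects: %.2f%% +/- %.2f%% (%s)\n",
              x$n, x$mean_pct, x$sd_pct, x$direction))
  invisible(x)
}
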