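#' Specification for a synthetic liver-microvasculature phantom
#'
#' The phantom emulates the geometry seen in liver photoacoustic
#' microangiography: a few large wall-bearing vessels (smooth tubes,
#' 20-30 um diameter) rising from the deepest slices and branching upward
#' into a dense mesh of narrow sinusoid tubes (3-5 um diameter) grown as
#' persistent random walks with branching and loop closure. The intensity
#' volume is the soft-rasterised union of both compartments, attenuated
#' exponentially with physical depth and corrupted with additive Gaussian
#' noise, clipped at zero. Stage presets scale the sinusoid target density
#' and walk continuity to mimic progressive sinusoid rarefaction:
#' `normal` 0.091, `early` 0.056, `mid` 0.020, `late` 0.012.
#'
#' @param shape volume shape `(nz, ny, nx)` in voxels (default
#'   `c(150, 256, 256)`).
#' @param spacing voxel spacing `(dz, dy, dx)` in micrometres (default 1 um
#'   isotropic).
#' @param stage one of `"normal"`, `"early"`, `"mid"`, `"late"`; presets for
#'   `target_density` and `continuity`.
#' @param n_vessels number of vessel trunks (default 3).
#' @param vessel_radius vessel radius range in um (default `c(10, 15)`).
#' @param sinusoid_radius sinusoid radius range in um (default
#'   `c(1.5, 2.5)`, i.e. 3-5 um diameters).
#' @param target_density target sinusoid density `V_S / (V - V_L)`;
#'   `NULL` takes the stage preset.
#' @param continuity walk-continuation level in `(0, 1]`; lower values
#'   fragment the mesh; `NULL` takes the stage preset.
#' @param persistence directional persistence of the sinusoid random walks
#'   in `(0, 1)`; higher values give straighter tubes (default 0.75).
#'   Walks additionally carry a per-walk circular-arc curvature so tubes
#'   bend at scales larger than their radius.
#' @param attenuation depth attenuation coefficient in mm^-1 (default 2).
#' @param noise_sd additive Gaussian noise standard deviation as a fraction
#'   of the intensity scale (default 0.1).
#' @param intensity_scale peak intensity in amplitude units (default 255).
#' @param seed integer random seed (default 1).
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(150, 256, 256), spacing = c(1, 1, 1),
                         stage = c("normal", "early", "mid", "late"),
                         n_vessels = 3, vessel_radius = c(10, 15),
                         sinusoid_radius = c(1.5, 2.5),
                         target_density = NULL, continuity = NULL,
                         persistence = 0.75,
                         attenuation = 2, noise_sd = 0.1,
                         intensity_scale = 255, seed = 1) {
  stage <- match.arg(stage)
  presets <- list(normal = list(density = 0.091, continuity = 1.0),
                  early  = list(density = 0.056, continuity = 0.85),
                  mid    = list(density = 0.020, continuity = 0.6),
                  late   = list(density = 0.012, continuity = 0.4))
  if (is.null(target_density)) target_density <- presets[[stage]]$density
  if (is.null(continuity)) continuity <- presets[[stage]]$continuity
  stopifnot(length(shape) == 3L, all(shape >= 8),
            all(vessel_radius > 0), all(sinusoid_radius > 0),
            max(sinusoid_radius) < min(vessel_radius),
            target_density > 0, target_density < 1,
            continuity > 0, continuity <= 1,
            persistence > 0, persistence < 1,
            attenuation >= 0, noise_sd >= 0, intensity_scale > 0)
  structure(list(shape = as.integer(shape), spacing = check_spacing(spacing),
                 stage = stage, n_vessels = as.integer(n_vessels),
                 vessel_radius = vessel_radius,
                 sinusoid_radius = sinusoid_radius,
                 target_density = target_density, continuity = continuity,
                 persistence = persistence,
                 attenuation = attenuation, noise_sd = noise_sd,
                 intensity_scale = intensity_scale, seed = as.integer(seed)),
            class = "phantom_spec")
}

unit_vec <- function(v) v / sqrt(sum(v^2))

# quadratic Bezier sampled at physical step `ds` (um)
bezier3 <- function(p0, p1, p2, ds) {
  approx_len <- sqrt(sum((p1 - p0)^2)) + sqrt(sum((p2 - p1)^2))
  n <- max(8L, ceiling(approx_len / ds))
  t <- seq(0, 1, length.out = n)
  out <- outer((1 - t)^2, p0) + outer(2 * t * (1 - t), p1) + outer(t^2, p2)
  out
}

# rotate vector v around unit axis a by angle theta (Rodrigues)
rotate_about <- function(v, a, theta) {
  v * cos(theta) + c(a[2] * v[3] - a[3] * v[2],
                     a[3] * v[1] - a[1] * v[3],
                     a[1] * v[2] - a[2] * v[1]) * sin(theta) +
    a * sum(a * v) * (1 - cos(theta))
}

# curved random walk: the direction turns with a per-walk circular-arc
# curvature (radius `r_curv` um, random rotation axis) plus directional
# noise controlled by `persistence`; reflected into [margin, L - margin].
# Arc-scale curvature (amplitude larger than the tube radius) is what gives
# the centerline branches their sub-unit straightness after skeletonization.
curved_walk <- function(start, dir, n, ds, persistence, r_curv, L, margin) {
  pts <- matrix(0, n, 3)
  p <- start; d <- unit_vec(dir)
  axis <- unit_vec(stats::rnorm(3))
  theta <- ds / r_curv
  for (i in seq_len(n)) {
    d <- rotate_about(d, axis, theta)
    d <- unit_vec(d * persistence + stats::rnorm(3, sd = 1 - persistence + 0.05))
    p <- p + d * ds
    for (ax in 1:3) {
      if (p[ax] < margin[ax]) { p[ax] <- 2 * margin[ax] - p[ax]; d[ax] <- -d[ax] }
      if (p[ax] > L[ax] - margin[ax]) {
        p[ax] <- 2 * (L[ax] - margin[ax]) - p[ax]; d[ax] <- -d[ax]
      }
    }
    pts[i, ] <- p
  }
  pts
}

#' Generate a synthetic vascular phantom with ground truth
#'
#' Deterministic for a fixed seed. Returns the degraded intensity volume
#' together with voxel-level ground-truth masks (vessel and sinusoid,
#' disjoint — vessel wins at overlaps), the generative centerline polylines,
#' and the realized parameters (including realized sinusoid density).
#'
#' @param spec a [phantom_spec()].
#' @return A list of class `phantom`: `intensity` (`pa_volume`),
#'   `vessel_truth`, `sinusoid_truth` (`pa_mask`s), `centerlines` (list with
#'   `vessels` and `sinusoids`, each a list of n x 3 physical-coordinate
#'   polylines in um), `realized` (list with realized density, voxel counts,
#'   vessel count).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(spec$seed)

  d <- spec$shape; sp <- spec$spacing
  L <- d * sp  # physical extents (z, y, x) in um
  ds <- min(sp) * 0.75

  ## ---- vessel trunks: smooth tubes rising from the base -------------------
  nv <- spec$n_vessels
  # lateral anchor points on a jittered grid so trunks never touch
  gside <- ceiling(sqrt(nv))
  cells <- expand.grid(gy = seq_len(gside), gx = seq_len(gside))
  cells <- cells[sample(nrow(cells), nv), , drop = FALSE]
  vessel_lines <- list()
  vessel_radii <- numeric(nv)
  vessel_tips <- list()
  cell_half <- c(L[2], L[3]) / (2 * gside)
  for (i in seq_len(nv)) {
    r <- stats::runif(1, spec$vessel_radius[1], spec$vessel_radius[2])
    vessel_radii[i] <- r
    cy <- (cells$gy[i] - 0.5) / gside * L[2]
    cx <- (cells$gx[i] - 0.5) / gside * L[3]
    # lateral excursions stay inside the trunk's grid cell, with a margin
    # larger than the erosion/dilation radius, so instances never merge
    max_off <- pmax(0, cell_half - r - 6)
    jit <- function(s) stats::runif(1, -s, s)
    p0 <- c(L[1] * 0.98, cy + jit(0.3 * max_off[1]), cx + jit(0.3 * max_off[2]))
    p2 <- c(L[1] * stats::runif(1, 0.45, 0.6),
            cy + jit(max_off[1]), cx + jit(max_off[2]))
    p1 <- (p0 + p2) / 2 + c(0, jit(0.6 * max_off[1]), jit(0.6 * max_off[2]))
    pts <- bezier3(p0, p1, p2, ds)
    vessel_lines[[i]] <- pts
    vessel_tips[[i]] <- pts[nrow(pts), ]
  }
  vfield <- numeric(prod(d)); dim(vfield) <- d
  for (i in seq_len(nv)) {
    pts <- vessel_lines[[i]]
    vfield <- cpp_stamp_tubes(vfield, d, sp, pts,
                              rep(vessel_radii[i], nrow(pts)))
    dim(vfield) <- d
  }
  vessel_mask <- vfield >= 0.5
  v_l <- sum(vessel_mask)
  v_total <- prod(d)

  ## ---- sinusoid mesh: persistent random walks with branching/loops --------
  target_vs <- spec$target_density * (v_total - v_l)
  sin_lines <- list()
  # physical sampling of already-laid centerline points for branching seeds
  all_pts <- do.call(rbind, lapply(vessel_tips, rbind))
  # keep sinusoid tubes clear of the grid border (tube radius + the default
  # erosion radius), so border shells cannot masquerade as thick structures
  margin <- c(6, 6, 6)
  zlim_hi <- L[1] * 0.8  # sinusoids live above the vessel tips
  sfield <- numeric(prod(d)); dim(sfield) <- d
  v_s <- 0
  max_walks <- 200000L
  w <- 0L
  # walks are rasterised in batches and the realised (voxel-counted) sinusoid
  # volume drives the stopping rule, so overlap between walks cannot bias the
  # realised density away from the target
  batch <- list(); batch_r <- numeric(0)
  flush_batch <- function() {
    if (!length(batch)) return(invisible())
    pts <- do.call(rbind, batch)
    rads <- rep(batch_r, vapply(batch, nrow, integer(1)))
    sfield <<- cpp_stamp_tubes(sfield, d, sp, pts, rads)
    dim(sfield) <<- d
    v_s <<- sum(sfield >= 0.5 & !vessel_mask)
    batch <<- list(); batch_r <<- numeric(0)
  }
  batch_walks <- 12L
  while (v_s < target_vs && w < max_walks) {
    # finer batches near the target keep the realised density close to it
    if (v_s > 0.75 * target_vs) batch_walks <- 3L
    w <- w + 1L
    r <- stats::runif(1, spec$sinusoid_radius[1], spec$sinusoid_radius[2])
    if (nrow(all_pts) > 0 && stats::runif(1) < 0.7) {
      start <- all_pts[sample(nrow(all_pts), 1L), ]
    } else {
      start <- c(stats::runif(1, margin[1], zlim_hi),
                 stats::runif(1, margin[2], L[2] - margin[2]),
                 stats::runif(1, margin[3], L[3] - margin[3]))
    }
    dir0 <- stats::rnorm(3)
    dir0[1] <- dir0[1] - 0.8  # upward (shallower) bias
    steps <- round(stats::runif(1, 25, 70) * spec$continuity / ds)
    pts <- curved_walk(start, dir0, max(8L, steps), ds, spec$persistence,
                       stats::runif(1, 7, 25), c(zlim_hi, L[2], L[3]), margin)
    # fragmentation: drop a middle chunk of low-continuity walks
    if (stats::runif(1) > spec$continuity && nrow(pts) > 16L) {
      cut0 <- sample(4:(nrow(pts) - 12L), 1L)
      pts <- pts[-(cut0:(cut0 + 7L)), , drop = FALSE]
    }
    # loop closure towards an existing sinusoid point
    if (nrow(all_pts) > 10 && stats::runif(1) < 0.35) {
      tail_pt <- pts[nrow(pts), ]
      idx <- sample(nrow(all_pts), min(200L, nrow(all_pts)))
      cand <- all_pts[idx, , drop = FALSE]
      dd <- sqrt(rowSums((cand - matrix(tail_pt, nrow(cand), 3,
                                        byrow = TRUE))^2))
      j <- which.min(dd)
      if (dd[j] < 20) {
        tgt <- cand[j, ]
        nstep <- max(2L, ceiling(dd[j] / ds))
        t <- seq(0, 1, length.out = nstep)
        closing <- outer(1 - t, tail_pt) + outer(t, tgt)
        pts <- rbind(pts, closing)
      }
    }
    sin_lines[[length(sin_lines) + 1L]] <- pts
    batch[[length(batch) + 1L]] <- pts
    batch_r <- c(batch_r, r)
    if (length(batch) >= batch_walks) flush_batch()
    keep <- seq(1, nrow(pts), by = 4)
    all_pts <- rbind(all_pts, pts[keep, , drop = FALSE])
  }
  flush_batch()
  sinusoid_mask <- sfield >= 0.5 & !vessel_mask
  v_s <- sum(sinusoid_mask)

  ## ---- degradation --------------------------------------------------------
  intensity <- pmax(vfield, sfield) * spec$intensity_scale
  if (spec$attenuation > 0) {
    depth_mm <- (seq_len(d[1]) - 1) * sp[1] / 1000
    att <- exp(-spec$attenuation * depth_mm)
    intensity <- intensity * att[slice.index(intensity, 1)]
  }
  if (spec$noise_sd > 0)
    intensity <- intensity +
      stats::rnorm(length(intensity), 0, spec$noise_sd * spec$intensity_scale)
  intensity <- pmax(intensity, 0)
  dim(intensity) <- d

  realized <- list(
    sinusoid_voxels = v_s, vessel_voxels = v_l, total_voxels = v_total,
    density = sinusoid_density(v_s, v_l, v_total),
    vessel_count = spec$n_vessels, n_walks = length(sin_lines))
  structure(list(
    intensity = pa_volume(intensity, sp,
                          provenance = sprintf("phantom stage=%s seed=%d",
                                               spec$stage, spec$seed)),
    vessel_truth = pa_mask(vessel_mask, sp, role = "vessel"),
    sinusoid_truth = pa_mask(sinusoid_mask, sp, role = "sinusoid"),
    centerlines = list(vessels = vessel_lines, sinusoids = sin_lines),
    spec = spec, realized = realized), class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom stage=%s seed=%d> %s voxels; realized density %.4f; %d vessels, %d sinusoid walks\n",
              x$spec$stage, x$spec$seed,
              paste(x$spec$shape, collapse = "x"),
              x$realized$density, x$realized$vessel_count,
              x$realized$n_walks))
  invisible(x)
}

#' Dice and cross-label errors of a separation result against ground truth
#'
#' `Dice = 2 |A intersect B| / (|A| + |B|)` per compartment, plus the
#' fraction of true vessel voxels labelled sinusoid and vice versa.
#'
#' @param vessel_result,sinusoid_result the separated `pa_mask`s.
#' @param vessel_truth,sinusoid_truth the ground-truth `pa_mask`s.
#' @return A list: `vessel_dice`, `sinusoid_dice`,
#'   `vessel_as_sinusoid` (fraction of true vessel voxels in the sinusoid
#'   result), `sinusoid_as_vessel`.
#' @export
evaluate_separation <- function(vessel_result, sinusoid_result,
                                vessel_truth, sinusoid_truth) {
  stopifnot_same_grid(vessel_result, vessel_truth)
  stopifnot_same_grid(sinusoid_result, sinusoid_truth)
  if (!any(vessel_truth) && !any(sinusoid_truth)) stop("empty ground truth")
  dice <- function(a, b) {
    s <- sum(a) + sum(b)
    if (s == 0) return(NA_real_)
    2 * sum(a & b) / s
  }
  list(vessel_dice = dice(vessel_result, vessel_truth),
       sinusoid_dice = dice(sinusoid_result, sinusoid_truth),
       vessel_as_sinusoid = if (any(vessel_truth))
         sum(sinusoid_result & vessel_truth) / sum(vessel_truth) else NA_real_,
       sinusoid_as_vessel = if (any(sinusoid_truth))
         sum(vessel_result & sinusoid_truth) / sum(sinusoid_truth) else NA_real_)
}
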