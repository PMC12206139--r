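#' Label individual vessel instances
#'
#' 26-connected component labelling of the vessel mask; each component is
#' treated as one vessel instance for coverage analysis.
#'
#' @param vessels the vessel `pa_mask`.
#' @return A list: `labels` (integer 3D array, 0 = background) and `ids`
#'   (sorted instance ids; empty for an empty mask).
#' @export
vessel_instances <- function(vessels) {
  labels <- label_components(vessels, 26L)
  n <- max(labels)
  list(labels = labels, ids = if (n > 0) seq_len(n) else integer(0))
}

#' Deepest slice index of a vessel instance
#'
#' The largest Z index containing any voxel of the instance — the deepest
#' layer with vascular signal.
#'
#' @param instance a logical 3D array (or `pa_mask`) for one vessel.
#' @return Integer slice index (1-based).
#' @export
vessel_zmax <- function(instance) {
  zs <- which(apply(array(as.logical(instance), dim(instance)), 1, any))
  if (length(zs) == 0L) stop("empty vessel instance")
  max(zs)
}

#' Restrict a sinusoid mask to slices above a vessel's deepest layer
#'
#' Clears the deepest vessel layer and everything below it (`z >= z_max`),
#' keeping only sinusoid signal strictly above the vessel bottom, so that
#' sinusoids underneath a vessel do not count towards its coverage.
#'
#' @param sinusoids the sinusoid `pa_mask`.
#' @param z_max slice index from [vessel_zmax()].
#' @return A `pa_mask` with slices `z >= z_max` cleared.
#' @export
sinusoid_upper_mask <- function(sinusoids, z_max) {
  nz <- dim(sinusoids)[1]
  stopifnot(z_max >= 1L, z_max <= nz)
  out <- array(as.logical(sinusoids), dim(sinusoids))
  out[seq(z_max, nz), , ] <- FALSE
  pa_mask(out, spacing(sinusoids), attr(sinusoids, "role"))
}

#' Columnar coverage rate of a vessel instance
#'
#' A vessel voxel at `(x, y, z)` counts as covered when the restricted
#' sinusoid mask contains at least one voxel in the same `(x, y)` column
#' strictly above it (`z' < z`). The coverage rate is the covered fraction
#' of the instance's voxels. Implemented with a top-down cumulative
#' presence map, which equals the per-column brute-force enumeration.
#'
#' @param instance logical 3D array (or `pa_mask`) of one vessel instance.
#' @param s_upper the restricted sinusoid mask from [sinusoid_upper_mask()].
#' @return Coverage rate in `[0, 1]`.
#' @export
coverage_rate <- function(instance, s_upper) {
  stopifnot(identical(dim(instance), dim(s_upper)))
  inst <- array(as.logical(instance), dim(instance))
  if (!any(inst)) stop("empty vessel instance")
  s <- array(as.logical(s_upper), dim(s_upper))
  cum <- apply(s, c(2, 3), cumsum)            # presence up to and including z
  nz <- dim(s)[1]
  above <- array(FALSE, dim(s))
  if (nz > 1L) above[2:nz, , ] <- cum[seq_len(nz - 1L), , ] > 0
  sum(inst & above) / sum(inst)
}

#' Per-vessel sinusoidal coverage report
#'
#' For every vessel instance: voxel count, deepest slice `z_max`, covered
#' voxel count, coverage rate `R_i`, and the high/low-coverage class
#' (`HC` iff `R_i > threshold`, strict). The summary gives the mean rate
#' and the HC/LC fractions.
#'
#' @param vessels the vessel `pa_mask`.
#' @param sinusoids the sinusoid `pa_mask` on the same grid.
#' @param threshold HC/LC threshold on the coverage rate (default 0.5;
#'   a rate exactly at the threshold is LC).
#' @return An object of class `coverage_report`: data frame `per_vessel`
#'   (id, n_voxels, z_max, covered, rate, class) and list `summary`
#'   (mean_rate, hc_fraction, lc_fraction, n_vessels).
#' @export
coverage_report <- function(vessels, sinusoids, threshold = 0.5) {
  stopifnot_same_grid(vessels, sinusoids)
  inst <- vessel_instances(vessels)
  if (length(inst$ids) == 0L) {
    return(structure(list(per_vessel = data.frame(id = integer(0),
                                                  n_voxels = integer(0),
                                                  z_max = integer(0),
                                                  covered = integer(0),
                                                  rate = numeric(0),
                                                  class = character(0)),
                          summary = list(mean_rate = NA_real_,
                                         hc_fraction = NA_real_,
                                         lc_fraction = NA_real_,
                                         n_vessels = 0L)),
                     class = "coverage_report"))
  }
  rows <- lapply(inst$ids, function(i) {
    m <- inst$labels == i
    zmax <- vessel_zmax(m)
    su <- sinusoid_upper_mask(sinusoids, zmax)
    r <- coverage_rate(m, su)
    data.frame(id = i, n_voxels = sum(m), z_max = zmax,
               covered = as.integer(round(r * sum(m))), rate = r,
               class = if (r > threshold) "HC" else "LC")
  })
  per_vessel <- do.call(rbind, rows)
  structure(list(per_vessel = per_vessel,
                 summary = list(mean_rate = mean(per_vessel$rate),
                                hc_fraction = mean(per_vessel$class == "HC"),
                                lc_fraction = mean(per_vessel$class == "LC"),
                                n_vessels = nrow(per_vessel))),
            class = "coverage_report")
}

#' @export
print.coverage_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<coverage_report> %d vessels, mean rate %.3f, HC %.0f%% / LC %.0f%%\n",
              s$n_vessels, s$mean_rate, 100 * s$hc_fraction,
              100 * s$lc_fraction))
  invisible(x)
}

#' Classify coverage rates into high/low-coverage groups
#'
#' @param rates numeric coverage rates in `[0, 1]`.
#' @param threshold HC iff rate strictly exceeds this (default 0.5).
#' @return A list: `class` (character vector of `"HC"`/`"LC"`),
#'   `hc_fraction`, `lc_fraction`.
#' @export
classify_coverage <- function(rates, threshold = 0.5) {
  cls <- ifelse(rates > threshold, "HC", "LC")
  list(class = cls, hc_fraction = mean(cls == "HC"),
       lc_fraction = mean(cls == "LC"))
}
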