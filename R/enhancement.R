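#' Per-slice percentile profile of an intensity volume
#'
#' For every Z-slice, the 1st percentile (`i1`) and 99th percentile (`i99`)
#' of the intensity distribution are extracted; their difference is the
#' slice's dynamic range. The slice with the largest range is selected as the
#' reference layer for histogram matching (ties resolved to the shallowest
#' slice). Percentiles use linear interpolation between order statistics
#' (type 7 quantiles).
#'
#' @param volume a `pa_volume`.
#' @return A list of class `percentile_profile` with `i1`, `i99`, `range`
#'   (numeric per-slice vectors) and `reference_index`.
#' @export
percentile_profile <- function(volume) {
  nz <- dim(volume)[1]
  i1 <- numeric(nz); i99 <- numeric(nz)
  for (z in seq_len(nz)) {
    q <- stats::quantile(volume[z, , ], probs = c(0.01, 0.99), names = FALSE,
                         type = 7)
    i1[z] <- q[1]; i99[z] <- q[2]
  }
  rng <- i99 - i1
  structure(list(i1 = i1, i99 = i99, range = rng,
                 reference_index = which.max(rng)),
            class = "percentile_profile")
}

#' @export
print.percentile_profile <- function(x, ...) {
  cat(sprintf("<percentile_profile> %d slices, reference slice %d (range %.4g)\n",
              length(x$i1), x$reference_index, x$range[x$reference_index]))
  invisible(x)
}

# Monotone quantile mapping of `values` onto the empirical distribution of
# `ref`. With bins = NULL the map interpolates the full empirical quantile
# function (knots at every order statistic), which makes matching a slice of
# the same size an exact multiset transfer; an integer `bins` coarsens the
# map to that many quantile knots.
quantile_map <- function(values, ref, bins = NULL) {
  n <- length(values)
  sref <- sort(ref)
  if (length(unique(values)) == 1L) return(values)  # degenerate slice: pass through
  p <- (rank(values, ties.method = "average") - 1) / (n - 1)
  if (!is.null(bins) && bins < length(sref)) {
    knots <- seq(0, 1, length.out = bins)
    sref <- stats::quantile(sref, probs = knots, names = FALSE, type = 7)
    stats::approx(knots, sref, xout = p, rule = 2)$y
  } else {
    pk <- seq(0, 1, length.out = length(sref))
    stats::approx(pk, sref, xout = p, rule = 2, ties = "ordered")$y
  }
}

#' Histogram-match all slices to the reference slice
#'
#' Compensates depth-dependent signal loss: each non-reference slice's
#' empirical intensity distribution is mapped onto the reference slice's
#' distribution by a monotone quantile map, aligning the dynamic range of
#' deep (attenuated) slices with the best slice. The reference slice itself
#' is left unchanged, as are constant (degenerate) slices.
#'
#' @param volume a `pa_volume`.
#' @param profile the [percentile_profile()] computed from `volume`; computed
#'   on the fly when `NULL`.
#' @param bins optional number of quantile knots for the mapping look-up
#'   table; `NULL` (default) uses the full empirical quantile function.
#' @return A `pa_volume` of the same shape and spacing.
#' @export
match_to_reference <- function(volume, profile = NULL, bins = NULL) {
  if (is.null(profile)) profile <- percentile_profile(volume)
  k <- profile$reference_index
  if (profile$range[k] <= 0) {
    warning("reference slice has zero dynamic range; volume returned unchanged")
    return(volume)
  }
  ref <- as.vector(volume[k, , ])
  out <- unclass(volume)
  nz <- dim(volume)[1]
  for (z in seq_len(nz)) {
    if (z == k) next
    out[z, , ] <- quantile_map(as.vector(volume[z, , ]), ref, bins = bins)
  }
  pa_volume(out, spacing(volume), provenance = attr(volume, "provenance"))
}

#' Per-slice signal-to-noise ratio profile
#'
#' For each slice, `SNR = 20 * log10(mean(foreground) / sd(background))` in
#' decibels, where the foreground is given by `foreground` (typically the
#' combined vessel + sinusoid mask) and the background is its complement.
#' Slices without foreground voxels yield `NA`; zero background variance
#' yields `Inf`.
#'
#' @param volume a `pa_volume`.
#' @param foreground a `pa_mask` on the same grid.
#' @return Numeric vector of per-slice SNR values (dB).
#' @export
snr_profile <- function(volume, foreground) {
  stopifnot_same_grid(volume, foreground)
  nz <- dim(volume)[1]
  vapply(seq_len(nz), function(z) {
    sl <- volume[z, , ]; fg <- foreground[z, , ]
    if (!any(fg)) return(NA_real_)
    s <- mean(sl[fg])
    bg <- sl[!fg]
    if (length(bg) < 2L) return(Inf)
    sdev <- stats::sd(bg)
    if (sdev == 0) return(Inf)
    20 * log10(s / sdev)
  }, numeric(1))
}
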