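#' Subtract the vessel compartment from an enhanced volume
#'
#' Pixel-wise subtraction of the vessel mask, scaled to the volume's
#' intensity maximum, from the enhanced image. Vessel voxels therefore go
#' non-positive while non-vessel voxels keep their intensity, yielding a
#' signed difference volume whose positive part is the sinusoid signal.
#'
#' @param enhanced a `pa_volume` (the enhanced image).
#' @param vessels the vessel `pa_mask` on the same grid.
#' @return A plain 3D numeric array of class `pa_difference` (signed values)
#'   with the grid's spacing attached.
#' @export
subtract_vessels <- function(enhanced, vessels) {
  stopifnot_same_grid(enhanced, vessels)
  peak <- max(enhanced)
  diff <- unclass(enhanced) - peak * vessels
  structure(diff, spacing = spacing(enhanced), class = "pa_difference")
}

#' @export
print.pa_difference <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<pa_difference> %d x %d x %d voxels, %.1f%% negative\n",
              d[1], d[2], d[3], 100 * mean(x < 0)))
  invisible(x)
}

#' Clip negative values of a difference volume to zero
#'
#' Retains only the positive residual associated with sinusoid structures.
#'
#' @param diff a `pa_difference` (or any numeric 3D array with a spacing
#'   attribute).
#' @return A `pa_volume`.
#' @export
clip_negative <- function(diff) {
  out <- pmax(unclass(diff), 0)
  pa_volume(array(out, dim(diff)), attr(diff, "spacing"),
            provenance = "clipped difference")
}

gaussian_kernel <- function(sigma, order = 0L) {
  # sampled Gaussian (or its exact derivatives) truncated at 4 sigma
  r <- max(1L, ceiling(4 * sigma))
  x <- seq(-r, r)
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  if (order == 0L) return(g)
  if (order == 1L) return(-x / sigma^2 * g)
  (x^2 - sigma^2) / sigma^4 * g
}

smooth_gaussian <- function(arr, sigma_vox) {
  d <- dim(arr)
  out <- as.vector(arr)
  for (ax in 1:3) {
    if (sigma_vox[ax] <= 0) next
    out <- cpp_conv_axis(out, d, gaussian_kernel(sigma_vox[ax]), ax - 1L)
  }
  array(out, d)
}

# Gaussian-derivative Hessian components at physical scale `sigma_um`.
# Derivative orders per axis (z, y, x); returned in physical units (per um^2)
# and gamma-normalised by sigma^2 so responses are comparable across scales.
hessian_component <- function(arr, d, sp, sigma_um, orders) {
  out <- as.vector(arr)
  for (ax in 1:3) {
    sig <- sigma_um / sp[ax]
    k <- gaussian_kernel(sig, orders[ax]) / sp[ax]^orders[ax]
    out <- cpp_conv_axis(out, d, k, ax - 1L)
  }
  out * sigma_um^2
}

#' Multi-scale Hessian tubularness enhancement
#'
#' Frangi-type vesselness: at each scale the volume is convolved with
#' Gaussian-derivative kernels to obtain the Hessian, whose eigenvalues
#' (sorted by magnitude, `|l1| <= |l2| <= |l3|`) are combined into a
#' bright-tube response
#' `V = (1 - exp(-Ra^2 / 2 alpha^2)) * exp(-Rb^2 / 2 beta^2) * (1 - exp(-S^2 / 2 c^2))`
#' with `Ra = |l2|/|l3|` (plate vs line), `Rb = |l1|/sqrt(|l2 l3|)` (blob),
#' and `S` the Frobenius norm (noise floor; `c` = half the maximal `S` at
#' that scale). Voxels with `l2 > 0` or `l3 > 0` (dark structures) respond 0.
#' The per-voxel maximum over scales is returned.
#'
#' @param volume a `pa_volume`.
#' @param scales Gaussian scales in micrometres, matched to the radii of the
#'   tubes to enhance; default `c(0.5, 1, 1.5, 2, 2.5)` um spans sinusoid
#'   radii.
#' @param alpha,beta Frangi sensitivity parameters (default 0.5 each).
#' @return A non-negative `pa_volume` of tubularness responses in `[0, 1]`.
#' @export
tubular_enhance <- function(volume, scales = c(0.5, 1, 1.5, 2, 2.5),
                            alpha = 0.5, beta = 0.5) {
  stopifnot(all(scales > 0))
  d <- dim(volume); sp <- spacing(volume)
  arr <- unclass(volume)
  best <- numeric(prod(d))
  for (s in scales) {
    hzz <- hessian_component(arr, d, sp, s, c(2, 0, 0))
    hyy <- hessian_component(arr, d, sp, s, c(0, 2, 0))
    hxx <- hessian_component(arr, d, sp, s, c(0, 0, 2))
    hzy <- hessian_component(arr, d, sp, s, c(1, 1, 0))
    hzx <- hessian_component(arr, d, sp, s, c(1, 0, 1))
    hyx <- hessian_component(arr, d, sp, s, c(0, 1, 1))
    ev <- cpp_sym_eigs(hzz, hyy, hxx, hzy, hzx, hyx)
    l1 <- ev$l1; l2 <- ev$l2; l3 <- ev$l3
    S2 <- l1^2 + l2^2 + l3^2
    cpar <- sqrt(max(S2)) / 2
    if (cpar == 0) next
    ra2 <- (l2 / l3)^2
    rb2 <- l1^2 / abs(l2 * l3)
    v <- (1 - exp(-ra2 / (2 * alpha^2))) *
      exp(-rb2 / (2 * beta^2)) *
      (1 - exp(-S2 / (2 * cpar^2)))
    v[l2 > 0 | l3 > 0 | !is.finite(v)] <- 0
    best <- pmax(best, v)
  }
  pa_volume(array(best, d), sp, provenance = "tubularness")
}

#' Segment sinusoids from the tubular-enhanced volume
#'
#' Adaptive local-mean thresholding of the tubularness response, restricted
#' to voxels with appreciable response (`min_response` as a fraction of the
#' response maximum, to keep the local-mean rule from firing on near-zero
#' background), followed by hard removal of vessel voxels: the returned
#' sinusoid mask is disjoint from the vessel mask by construction.
#'
#' @param enhanced_tubular the tubularness `pa_volume`.
#' @param vessels the final vessel `pa_mask`.
#' @param window,offset see [segment_adaptive()].
#' @param min_response response floor as a fraction of the maximum response
#'   (default 0.05).
#' @return A sinusoid `pa_mask`, disjoint from `vessels`.
#' @export
segment_sinusoids <- function(enhanced_tubular, vessels, window = 25,
                              offset = 0, min_response = 0.05) {
  stopifnot_same_grid(enhanced_tubular, vessels)
  m <- segment_adaptive(enhanced_tubular, window, offset, role = "sinusoid")
  keep <- unclass(m) & unclass(enhanced_tubular) > min_response * max(enhanced_tubular)
  keep <- keep & !unclass(vessels)
  pa_mask(keep, spacing(enhanced_tubular), role = "sinusoid")
}
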