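#' GLCM texture features of a 2D image
#'
#' Gray-level co-occurrence statistics on a maximum-amplitude-projection
#' image: the image is quantised to `levels` gray levels over its own
#' min-max range, co-occurrences are accumulated for each pixel offset,
#' symmetrised, pooled over offsets and normalised to a probability matrix
#' `P`. Features:
#' * contrast: `sum P(i,j) (i-j)^2`
#' * entropy: `-sum P log2 P` (with `0 log 0 = 0`)
#' * homogeneity: `sum P / (1 + |i-j|)`
#'
#' A constant image yields `(contrast, entropy, homogeneity) = (0, 0, 1)`.
#'
#' @param image numeric 2D matrix.
#' @param levels number of gray levels (>= 2; default 64).
#' @param offsets list of integer pixel displacements `c(dr, dc)`; default
#'   the four distance-1 directions.
#' @return A list of class `texture_features`: `contrast`, `entropy`,
#'   `homogeneity`, plus the pooled matrix `p`.
#' @export
glcm_features <- function(image, levels = 64L,
                          offsets = list(c(0L, 1L), c(1L, 0L),
                                         c(1L, 1L), c(1L, -1L))) {
  stopifnot(is.matrix(image), levels >= 2L)
  rng <- range(image)
  if (diff(rng) == 0) {
    q <- matrix(1L, nrow(image), ncol(image))
  } else {
    q <- pmin(as.integer(floor((image - rng[1]) / diff(rng) * levels)) + 1L,
              as.integer(levels))
    dim(q) <- dim(image)
  }
  counts <- matrix(0, levels, levels)
  nr <- nrow(q); nc <- ncol(q)
  for (off in offsets) {
    dr <- off[1]; dc <- off[2]
    r1 <- max(1L, 1L - dr):min(nr, nr - dr)
    c1 <- max(1L, 1L - dc):min(nc, nc - dc)
    a <- q[r1, c1, drop = FALSE]
    b <- q[r1 + dr, c1 + dc, drop = FALSE]
    idx <- cbind(as.vector(a), as.vector(b))
    tab <- tabulate((idx[, 1] - 1L) * levels + idx[, 2], nbins = levels^2)
    co <- matrix(tab, levels, levels, byrow = TRUE)
    counts <- counts + co + t(co)  # symmetric
  }
  p <- counts / sum(counts)
  i <- row(p); j <- col(p)
  contrast <- sum(p * (i - j)^2)
  nz <- p > 0
  entropy <- -sum(p[nz] * log2(p[nz]))
  homogeneity <- sum(p / (1 + abs(i - j)))
  structure(list(contrast = contrast, entropy = entropy,
                 homogeneity = homogeneity, p = p),
            class = "texture_features")
}

#' @export
print.texture_features <- function(x, ...) {
  cat(sprintf("<texture_features> contrast %.4g, entropy %.4g, homogeneity %.4g\n",
              x$contrast, x$entropy, x$homogeneity))
  invisible(x)
}

#' Composite image-quality scores from GLCM features
#'
#' Each image's raw score rewards contrast and entropy and penalises
#' homogeneity: `raw = norm(contrast) + norm(entropy) + (1 - norm(homogeneity))`
#' with min-max normalisation of each feature across the compared set
#' (features with zero range contribute 0). Raw scores are then divided by
#' their maximum, so the best image in every compared set scores exactly 1.
#'
#' @param features a list of `texture_features` (>= 1 image).
#' @return Numeric vector of composite scores in `[0, 1]` with max 1.
#' @export
composite_score <- function(features) {
  if (inherits(features, "texture_features")) features <- list(features)
  n <- length(features)
  if (n == 0L) stop("no features given")
  if (n == 1L) return(1)
  get <- function(f) vapply(features, `[[`, numeric(1), f)
  norm01 <- function(x) {
    r <- range(x)
    if (diff(r) == 0) return(rep(0, length(x)))
    (x - r[1]) / diff(r)
  }
  raw <- norm01(get("contrast")) + norm01(get("entropy")) +
    (1 - norm01(get("homogeneity")))
  if (max(raw) == 0) return(rep(1, n))
  raw / max(raw)
}
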