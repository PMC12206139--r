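#' Construct an intensity volume
#'
#' An intensity volume is a 3D array of non-negative photoacoustic amplitudes
#' together with its physical voxel spacing. The axis order is fixed as
#' `(z, y, x)`: the first index runs along depth, with index 1 the shallowest
#' slice and the last index the deepest. All physical quantities downstream
#' (lengths, volumes, radii) are derived from the spacing, never from raw
#' voxel counts.
#'
#' @param data numeric 3D array of non-negative intensities (arbitrary
#'   amplitude units).
#' @param spacing numeric length-3 vector `(dz, dy, dx)` of voxel spacing in
#'   micrometres; all components must be positive.
#' @param provenance free-text tag describing where the volume came from.
#' @return An object of class `pa_volume`: the array with `spacing` and
#'   `provenance` attributes.
#' @export
pa_volume <- function(data, spacing, provenance = "unknown") {
  data <- as_volume_array(data)
  spacing <- check_spacing(spacing)
  if (dim(data)[1] < 2L)
    stop("an intensity volume needs at least 2 slices along Z")
  if (anyNA(data) || min(data) < 0)
    stop("intensities must be non-negative and finite")
  structure(data, spacing = spacing, provenance = as.character(provenance)[1],
            class = "pa_volume")
}

#' Construct a binary mask volume
#'
#' A binary volume shares the grid and spacing of its parent intensity volume
#' and carries a `role` tag saying which compartment it masks.
#'
#' @param data logical (or coercible) 3D array.
#' @param spacing voxel spacing `(dz, dy, dx)` in micrometres.
#' @param role one of `"vessel"`, `"sinusoid"`, `"other"`.
#' @return An object of class `pa_mask`.
#' @export
pa_mask <- function(data, spacing, role = c("other", "vessel", "sinusoid")) {
  role <- match.arg(role)
  d <- dim(data)
  if (is.null(d) || length(d) != 3L) stop("mask data must be a 3D array")
  data <- array(as.logical(data), dim = d)
  if (anyNA(data)) stop("mask may not contain NA")
  structure(data, spacing = check_spacing(spacing), role = role,
            class = "pa_mask")
}

as_volume_array <- function(data) {
  d <- dim(data)
  if (is.null(d) || length(d) != 3L) stop("volume data must be a 3D array")
  storage.mode(data) <- "double"
  data
}

check_spacing <- function(spacing) {
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || anyNA(spacing) || any(spacing <= 0))
    stop("spacing must be three positive numbers (dz, dy, dx) in micrometres")
  spacing
}

#' @export
print.pa_volume <- function(x, ...) {
  d <- dim(x); s <- attr(x, "spacing")
  cat(sprintf("<pa_volume> %d x %d x %d voxels (z, y, x), spacing %.3g x %.3g x %.3g um\n",
              d[1], d[2], d[3], s[1], s[2], s[3]))
  cat(sprintf("  intensity range [%.4g, %.4g], provenance: %s\n",
              min(x), max(x), attr(x, "provenance")))
  invisible(x)
}

#' @export
print.pa_mask <- function(x, ...) {
  d <- dim(x); s <- attr(x, "spacing")
  cat(sprintf("<pa_mask role=%s> %d x %d x %d voxels, %d foreground (%.2f%%)\n",
              attr(x, "role"), d[1], d[2], d[3], sum(x),
              100 * mean(x)))
  invisible(x)
}

#' Voxel spacing of a volume or mask
#' @param x a `pa_volume` or `pa_mask`.
#' @return Numeric `(dz, dy, dx)` in micrometres.
#' @export
spacing <- function(x) attr(x, "spacing")

stopifnot_same_grid <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("volumes/masks must share the same grid (dim mismatch)")
  sa <- attr(a, "spacing"); sb <- attr(b, "spacing")
  if (!is.null(sa) && !is.null(sb) && max(abs(sa - sb)) > 1e-9)
    stop("volumes/masks must share the same voxel spacing")
  invisible(TRUE)
}

sidecar_path <- function(path) paste0(path, ".json")

#' Write a volume as a multi-page grayscale TIFF
#'
#' One Z-slice per page, 32-bit float samples. Intensities are stored scaled
#' into `[0, 1]`; the scale factor and the voxel spacing are written to a JSON
#' sidecar (`<path>.json`) so that [read_volume()] restores the original
#' values (up to 32-bit float precision) and grid metadata.
#'
#' @param volume a `pa_volume` or `pa_mask`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  d <- dim(volume)
  if (is.null(d) || length(d) != 3L) stop("need a 3D volume")
  dat <- if (inherits(volume, "pa_mask")) array(as.double(volume), d) else
    as_volume_array(volume)
  scale <- max(dat)
  if (scale <= 0) scale <- 1
  pages <- lapply(seq_len(d[1]), function(z) dat[z, , , drop = TRUE] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  meta <- list(spacing = attr(volume, "spacing"), scale = scale,
               kind = if (inherits(volume, "pa_mask")) "mask" else "intensity",
               role = attr(volume, "role"))
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multi-page grayscale TIFF as an intensity volume
#'
#' Pages become Z-slices in order (page 1 = shallowest). Values are restored
#' on the scale recorded in the JSON sidecar when one is present; without a
#' sidecar the values are taken as read, without any rescaling.
#'
#' @param path path to a multi-page grayscale TIFF.
#' @param spacing voxel spacing `(dz, dy, dx)` in micrometres; overridden by a
#'   sidecar if `NULL`.
#' @return A `pa_volume`.
#' @export
read_volume <- function(path, spacing = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 2L) stop("need at least 2 pages (Z-slices), got ",
                               length(pages))
  for (p in pages) {
    if (length(dim(p)) != 2L)
      stop("only single-channel grayscale pages are supported")
  }
  scale <- 1
  meta <- NULL
  if (file.exists(sidecar_path(path))) {
    meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
    if (!is.null(meta$scale)) scale <- meta$scale
    if (is.null(spacing) && !is.null(meta$spacing)) spacing <- meta$spacing
  }
  if (is.null(spacing)) stop("spacing must be given when no sidecar exists")
  d2 <- dim(pages[[1]])
  arr <- array(0, dim = c(length(pages), d2[1], d2[2]))
  for (z in seq_along(pages)) arr[z, , ] <- pages[[z]] * scale
  arr[arr < 0 & arr > -1e-6] <- 0  # guard against float round-off
  pa_volume(arr, spacing, provenance = path)
}

#' Write a tabular metric report
#'
#' CSV by default; a `.json` extension selects JSON. Floats are written at
#' full precision. Missing values (the undefined-metric marker) are written
#' as `NA` in CSV and `null` in JSON and survive a round trip through
#' [read_report()].
#'
#' @param records a non-empty data frame.
#' @param path output path; extension chooses the format.
#' @return `path`, invisibly.
#' @export
write_report <- function(records, path) {
  records <- as.data.frame(records)
  if (nrow(records) == 0L || ncol(records) == 0L)
    stop("refusing to write an empty report")
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(records, path, dataframe = "rows", digits = NA,
                         na = "null", auto_unbox = FALSE)
  } else {
    utils::write.csv(records, path, row.names = FALSE, na = "NA")
  }
  invisible(path)
}

#' Read a report written by [write_report()]
#' @param path CSV or JSON report path.
#' @return A data frame.
#' @export
read_report <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json")
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  else
    utils::read.csv(path)
}
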