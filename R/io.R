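#' Construct a D-OCT time-series stack
#'
#' Canonical container for a repeated-B-scan acquisition: a 3D numeric array
#' with time as the leading axis, `(time, depth z, lateral x)`, plus
#' acquisition metadata. All downstream operations assume this layout.
#'
#' @param values 3D numeric array `(n_frames, n_axial, n_lateral)`, finite.
#' @param meta An [acquisition_meta()] object; `meta$n_frames`, `meta$n_axial`
#'   and `meta$n_lateral` must match `dim(values)`.
#' @return An object of class `doct_stack` (the array, with `meta` attribute).
#' @export
doct_stack <- function(values, meta) {
  stopifnot(inherits(meta, "doct_meta"))
  if (!is.array(values) || length(dim(values)) != 3)
    stop("values must be a 3D array (time, z, x)")
  d <- dim(values)
  if (d[1] != meta$n_frames)
    stop(sprintf("time axis length %d does not match meta$n_frames = %d",
                 d[1], meta$n_frames))
  if (d[2] != meta$n_axial || d[3] != meta$n_lateral)
    stop(sprintf(
      "frame shape (%d, %d) does not match meta (n_axial = %d, n_lateral = %d)",
      d[2], d[3], meta$n_axial, meta$n_lateral))
  if (!all(is.finite(values)))
    stop("values must be finite")
  structure(values, meta = meta, class = c("doct_stack", "array"))
}

#' Metadata of a stack
#' @param stack A `doct_stack`.
#' @return The attached [acquisition_meta()] object.
#' @export
stack_meta <- function(stack) attr(stack, "meta")

#' @export
print.doct_stack <- function(x, ...) {
  d <- dim(x)
  m <- stack_meta(x)
  cat(sprintf("D-OCT time-series stack: %d frames of %d (z) x %d (x) px @ %g Hz\n",
              d[1], d[2], d[3], m$frame_rate))
  cat(sprintf("  intensity range [%.4g, %.4g]\n", min(x), max(x)))
  invisible(x)
}

.sidecar_path <- function(path) paste0(path, ".json")

# Samples are stored on a 24-bit grid of the data range (the precision of a
# float32 mantissa). Quantizing ourselves, and snapping back on read, keeps
# round trips exact regardless of the TIFF writer's internal code mapping.
.QUANTUM <- 2^24 - 1

.quantize01 <- function(x) round(x * .QUANTUM) / .QUANTUM

.snap_read <- function(x, lo, hi, integer_data = FALSE) {
  span <- hi - lo
  if (span <= 0) span <- 1
  v <- .quantize01(x) * span + lo
  if (integer_data) v <- round(v)
  v
}

#' Write a time-series stack to a multi-page TIFF
#'
#' Each frame becomes one grayscale page after an affine rescale to `[0, 1]`
#' on a 24-bit quantization grid (single-precision mantissa resolution); the
#' scale (data min/max) and the acquisition metadata are recorded in a JSON
#' sidecar (`<path>.json`) so [read_stack()] restores the original values.
#' Integer-valued data round-trips bitwise; floating data to within
#' `6e-8` of its range, and bitwise from the second pass on.
#'
#' @param stack A [doct_stack()].
#' @param path Output TIFF file path.
#' @param compression TIFF compression, default "none".
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, compression = "none") {
  stopifnot(inherits(stack, "doct_stack"))
  m <- stack_meta(stack)
  lo <- min(stack); hi <- max(stack)
  scale <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(dim(stack)[1]),
                  function(t) .quantize01((stack[t, , ] - lo) / scale))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L,
                  compression = compression, reduce = FALSE)
  sidecar <- list(scale_min = lo, scale_max = hi,
                  integer_data = all(stack == round(stack)),
                  meta = unclass(m))
  jsonlite::write_json(sidecar, .sidecar_path(path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a time-series stack from a multi-page TIFF
#'
#' Reads a grayscale multi-page TIFF into the canonical `(time, z, x)` layout.
#' If a JSON sidecar written by [write_stack()] sits next to the file, its
#' intensity scale and metadata are applied; an explicit `meta` argument
#' overrides the sidecar and is validated against the file geometry.
#'
#' @param path Multi-page TIFF path.
#' @param meta Optional [acquisition_meta()]; required when no sidecar exists.
#' @param crop_axial Optional length-2 integer vector `c(first, last)`
#'   (1-based, inclusive) selecting a depth window of each page, e.g. to crop
#'   1024-pixel A-scans to a 660-pixel region of interest.
#' @return A [doct_stack()].
#' @export
read_stack <- function(path, meta = NULL, crop_axial = NULL) {
  if (!file.exists(path))
    stop(sprintf("stack file not found: %s", path))
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (is.matrix(pages)) pages <- list(pages)
  scale_min <- 0; scale_max <- 1; integer_data <- FALSE; snap <- FALSE
  sp <- .sidecar_path(path)
  if (file.exists(sp)) {
    sc <- jsonlite::read_json(sp, simplifyVector = TRUE)
    scale_min <- sc$scale_min
    scale_max <- sc$scale_max
    integer_data <- isTRUE(sc$integer_data)
    snap <- TRUE
    if (is.null(meta)) meta <- do.call(acquisition_meta, as.list(sc$meta))
  }
  if (is.null(meta))
    stop("no metadata: supply `meta` or provide a JSON sidecar")
  if (!is.null(crop_axial)) {
    stopifnot(length(crop_axial) == 2, crop_axial[1] >= 1)
    pages <- lapply(pages, function(p) p[crop_axial[1]:crop_axial[2], , drop = FALSE])
    meta$n_axial <- as.integer(diff(crop_axial) + 1L)
  }
  if (length(pages) != meta$n_frames)
    stop(sprintf("page count mismatch: expected %d frames, found %d",
                 meta$n_frames, length(pages)))
  d1 <- dim(pages[[1]])
  if (d1[1] != meta$n_axial || d1[2] != meta$n_lateral)
    stop(sprintf(
      "page shape mismatch: expected (%d, %d), found (%d, %d)",
      meta$n_axial, meta$n_lateral, d1[1], d1[2]))
  arr <- array(0, c(length(pages), d1[1], d1[2]))
  for (t in seq_along(pages)) {
    p <- pages[[t]]
    arr[t, , ] <- if (snap) .snap_read(p, scale_min, scale_max, integer_data)
                  else p
  }
  doct_stack(arr, meta)
}

#' Write a volumetric (4D) dataset as per-y stacks with a manifest
#'
#' One repeated-B-scan time stack is written per y position, with a
#' `manifest.yaml` listing the files in y order together with the shared
#' acquisition metadata, mirroring how a volumetric D-OCT acquisition is
#' collected (one time series per y at fixed spacing).
#'
#' @param stacks List of [doct_stack()] objects ordered along y.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_volume <- function(stacks, dir) {
  stopifnot(length(stacks) >= 1)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("y%04d.tif", seq_along(stacks) - 1L)
  for (i in seq_along(stacks))
    write_stack(stacks[[i]], file.path(dir, files[i]))
  m <- stack_meta(stacks[[1]])
  yaml::write_yaml(list(files = files, y_spacing = m$y_spacing,
                        meta = unclass(m)),
                   file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Read a volumetric dataset written by [write_volume()]
#'
#' @param dir Directory containing `manifest.yaml` and per-y TIFF stacks.
#' @return List of [doct_stack()] objects ordered along y, with attribute
#'   `y_spacing` (micrometres).
#' @export
read_volume <- function(dir) {
  mf <- file.path(dir, "manifest.yaml")
  if (!file.exists(mf)) stop(sprintf("manifest not found: %s", mf))
  man <- yaml::read_yaml(mf)
  stacks <- lapply(man$files, function(f) read_stack(file.path(dir, f)))
  attr(stacks, "y_spacing") <- man$y_spacing
  stacks
}

#' Write a 2D map (e.g. fmean) as a 32-bit TIFF with scale sidecar
#' @param map Numeric matrix.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path) {
  stopifnot(is.matrix(map))
  lo <- min(map); hi <- max(map)
  scale <- if (hi > lo) hi - lo else 1
  tiff::writeTIFF(.quantize01((map - lo) / scale), path,
                  bits.per.sample = 32L, compression = "none", reduce = FALSE)
  jsonlite::write_json(list(scale_min = lo, scale_max = hi,
                            integer_data = all(map == round(map))),
                       .sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a 2D map written by [write_map()]
#' @param path TIFF path.
#' @return Numeric matrix.
#' @export
read_map <- function(path) {
  if (!file.exists(path)) stop(sprintf("map file not found: %s", path))
  m <- tiff::readTIFF(path)
  sp <- .sidecar_path(path)
  if (file.exists(sp)) {
    sc <- jsonlite::read_json(sp, simplifyVector = TRUE)
    m <- .snap_read(m, sc$scale_min, sc$scale_max, isTRUE(sc$integer_data))
  }
  m
}

#' Write a binary mask as an 8-bit PNG (0/255)
#' @param mask Logical or 0/1 matrix.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask != 0), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Read a binary mask PNG
#' @param path PNG path.
#' @return Logical matrix.
#' @export
read_mask <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  m > 0.5
}

#' Write an RGB raster as an 8-bit PNG
#' @param rgb Array `(rows, cols, 3)` with values in `[0, 1]`.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_rgb <- function(rgb, path) {
  stopifnot(length(dim(rgb)) == 3, dim(rgb)[3] == 3)
  png::writePNG(pmin(pmax(rgb, 0), 1), path)
  invisible(path)
}
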