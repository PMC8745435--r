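# Domain containers and file I/O for multispectral lesion image sets.
#
# An acquisition consists of three co-registered single-band rasters taken
# under narrow-band LED illumination: G (525 nm), R (660 nm) and IR
# (940 nm). Intensities live on a nominal 8-bit 0-255 scale but are stored
# as doubles so that synthetic data and intermediate maps keep full
# precision. Registration is assumed done upstream; all channels and the
# lesion mask share one pixel grid.

MSI_CHANNELS <- c("G", "R", "IR")

#' Construct a multispectral image set
#'
#' @param channels named list with matrices `G`, `R`, `IR` (identical
#'   dimensions, finite, nonnegative).
#' @param lesion_id,acquisition_id identifiers carried through the pipeline.
#' @param pixel_size_mm physical pixel pitch; the default 0.04 mm/px derives
#'   from a 2 x 2 cm field of view imaged at 500 x 500 px.
#' @return object of class `msi_image_set`.
#' @export
msi_image_set <- function(channels, lesion_id = "lesion", acquisition_id = "acq1",
                          pixel_size_mm = 0.04) {
  missing <- setdiff(MSI_CHANNELS, names(channels))
  if (length(missing) > 0L) {
    stop("incomplete image set: missing channel(s) ", paste(missing, collapse = ", "))
  }
  channels <- channels[MSI_CHANNELS]
  dims <- lapply(channels, dim)
  if (!all(vapply(channels, is.matrix, logical(1L)))) {
    stop("channels must be matrices")
  }
  if (!all(vapply(dims, identical, logical(1L), dims[[1L]]))) {
    stop("channel dimension mismatch")
  }
  for (ch in MSI_CHANNELS) {
    v <- channels[[ch]]
    if (anyNA(v) || any(!is.finite(v)) || any(v < 0)) {
      stop("channel ", ch, " contains non-finite or negative intensities")
    }
  }
  stopifnot(is.numeric(pixel_size_mm), length(pixel_size_mm) == 1L, pixel_size_mm > 0)
  structure(
    list(
      lesion_id = as.character(lesion_id),
      acquisition_id = as.character(acquisition_id),
      channels = lapply(channels, function(m) {storage.mode(m) <- "double"; m}),
      pixel_size_mm = pixel_size_mm
    ),
    class = "msi_image_set"
  )
}

#' @export
print.msi_image_set <- function(x, ...) {
  d <- dim(x$channels$G)
  cat(sprintf("<msi_image_set> %s / %s: %d x %d px (%.3f mm/px), channels G/R/IR\n",
              x$lesion_id, x$acquisition_id, d[1L], d[2L], x$pixel_size_mm))
  invisible(x)
}

#' @export
dim.msi_image_set <- function(x) dim(x$channels$G)

#' Construct a lesion region of interest
#'
#' Either a binary mask, a polygon outline, or both. When only a polygon is
#' given it is rasterised (pixel centre in polygon, even-odd rule) onto
#' `shape`; when both are given the rasterisation must reproduce the mask.
#'
#' @param mask binary matrix (nonzero = lesion) or NULL.
#' @param polygon data frame with columns `x` (column coordinate) and `y`
#'   (row coordinate), or NULL.
#' @param shape target raster dimensions, required when `mask` is NULL.
#' @return object of class `lesion_roi` with elements `mask` and `polygon`.
#' @export
lesion_roi <- function(mask = NULL, polygon = NULL, shape = NULL) {
  if (!is.null(polygon)) {
    stopifnot(is.data.frame(polygon), all(c("x", "y") %in% names(polygon)),
              nrow(polygon) >= 3L)
  }
  if (is.null(mask)) {
    if (is.null(polygon)) stop("provide a mask or a polygon")
    if (is.null(shape)) stop("shape is required to rasterise a polygon ROI")
    mask <- rasterize_polygon(polygon, shape)
  } else {
    stopifnot(is.matrix(mask))
    mask <- (mask != 0) + 0L
    if (!is.null(polygon)) {
      if (!identical(rasterize_polygon(polygon, dim(mask)), mask)) {
        stop("polygon rasterisation does not match the supplied mask")
      }
    }
  }
  if (sum(mask) < 1L) stop("empty ROI")
  structure(list(mask = mask, polygon = polygon), class = "lesion_roi")
}

#' @export
print.lesion_roi <- function(x, ...) {
  cat(sprintf("<lesion_roi> %d x %d px, area %d px%s\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask),
              if (is.null(x$polygon)) "" else sprintf(", polygon (%d vertices)", nrow(x$polygon))))
  invisible(x)
}

# --- raster file I/O -------------------------------------------------------

#' Read a single-band grayscale raster
#'
#' TIFF or PNG by file extension. Multi-band (RGB/RGBA) files are rejected:
#' channel semantics of colour files are ambiguous for narrow-band imagery.
#' Values are rescaled from the decoder's [0, 1] range to `scale`.
#'
#' @param path file path.
#' @param scale full-scale intensity, default 255 (8-bit).
#' @return numeric matrix.
#' @export
read_gray <- function(path, scale = 255) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("unsupported raster format: .", ext)
  )
  if (length(dim(img)) == 3L) {
    stop("multi-band image rejected (expected single-band grayscale): ", path)
  }
  img * scale
}

#' Read a multispectral image set from channel files
#'
#' @param channel_paths named character vector/list with entries `G`, `R`,
#'   `IR` pointing to single-band TIFF/PNG files.
#' @param lesion_id,acquisition_id,pixel_size_mm metadata, see
#'   [msi_image_set()].
#' @param scale full-scale intensity (default 255).
#' @return `msi_image_set`.
#' @export
read_image_set <- function(channel_paths, lesion_id = "lesion",
                           acquisition_id = "acq1", pixel_size_mm = 0.04,
                           scale = 255) {
  missing <- setdiff(MSI_CHANNELS, names(channel_paths))
  if (length(missing) > 0L) {
    stop("incomplete image set: missing channel(s) ", paste(missing, collapse = ", "))
  }
  channels <- lapply(MSI_CHANNELS, function(ch) read_gray(channel_paths[[ch]], scale = scale))
  names(channels) <- MSI_CHANNELS
  msi_image_set(channels, lesion_id = lesion_id, acquisition_id = acquisition_id,
                pixel_size_mm = pixel_size_mm)
}

#' Write a multispectral image set as one TIFF per channel
#'
#' Intensities are divided by `scale`, clamped to [0, 1] and written at the
#' requested bit depth; with integer-valued 8-bit data the write/read round
#' trip is pixel-identical.
#'
#' @param image_set an `msi_image_set`.
#' @param paths named character vector (G, R, IR) of output paths.
#' @param scale,bits encoding parameters (defaults 255 / 8-bit).
#' @return invisibly, the paths.
#' @export
write_image_set <- function(image_set, paths, scale = 255, bits = 8L) {
  stopifnot(inherits(image_set, "msi_image_set"),
            all(MSI_CHANNELS %in% names(paths)))
  for (ch in MSI_CHANNELS) {
    v <- pmin(pmax(image_set$channels[[ch]] / scale, 0), 1)
    tiff::writeTIFF(v, paths[[ch]], bits.per.sample = as.integer(bits))
  }
  invisible(paths)
}

#' Read a lesion mask
#'
#' Any nonzero pixel is foreground.
#'
#' @param mask_path PNG/TIFF path.
#' @param reference_shape expected c(nrow, ncol); checked when given.
#' @return `lesion_roi`.
#' @export
read_roi <- function(mask_path, reference_shape = NULL) {
  m <- read_gray(mask_path, scale = 1)
  if (!is.null(reference_shape) && !identical(dim(m), as.integer(reference_shape))) {
    stop("mask dimensions ", paste(dim(m), collapse = "x"),
         " do not match reference shape ", paste(reference_shape, collapse = "x"))
  }
  lesion_roi(mask = m)
}

#' Write a lesion mask as PNG (foreground = white)
#' @param roi a `lesion_roi`.
#' @param path output path.
#' @export
write_roi <- function(roi, path) {
  stopifnot(inherits(roi, "lesion_roi"))
  png::writePNG(roi$mask + 0, path)
  invisible(path)
}

# --- manifests and feature tables ------------------------------------------

MANIFEST_REQUIRED <- c("lesion_id", "acquisition_id", "g_path", "r_path",
                       "ir_path", "mask_path")

#' Read a cohort manifest (CSV or JSON)
#'
#' A manifest has one row per acquisition with columns `lesion_id`,
#' `acquisition_id`, `g_path`, `r_path`, `ir_path`, `mask_path` and
#' optionally `skin_mask_path`, `truth_label`, `breslow_mm`. Relative paths
#' are resolved against the manifest's directory. (lesion_id,
#' acquisition_id) pairs must be unique and referenced files must exist.
#'
#' @param path manifest file.
#' @param check_files verify referenced files exist (default TRUE).
#' @return data frame.
#' @export
read_manifest <- function(path, check_files = TRUE) {
  ext <- tolower(tools::file_ext(path))
  man <- switch(ext,
    csv = utils::read.csv(path, stringsAsFactors = FALSE),
    json = as.data.frame(jsonlite::fromJSON(path), stringsAsFactors = FALSE),
    stop("unsupported manifest format: .", ext)
  )
  missing <- setdiff(MANIFEST_REQUIRED, names(man))
  if (length(missing) > 0L) {
    stop("manifest lacks required column(s): ", paste(missing, collapse = ", "))
  }
  key <- paste(man$lesion_id, man$acquisition_id)
  if (anyDuplicated(key)) stop("duplicate (lesion_id, acquisition_id) in manifest")
  base <- dirname(normalizePath(path))
  path_cols <- intersect(c("g_path", "r_path", "ir_path", "mask_path", "skin_mask_path"),
                         names(man))
  for (col in path_cols) {
    rel <- !is.na(man[[col]]) & nzchar(man[[col]]) & !grepl("^(/|[A-Za-z]:)", man[[col]])
    man[[col]][rel] <- file.path(base, man[[col]][rel])
    if (check_files) {
      bad <- !is.na(man[[col]]) & nzchar(man[[col]]) & !file.exists(man[[col]])
      if (any(bad)) stop("manifest references missing file(s): ",
                         paste(utils::head(man[[col]][bad], 3L), collapse = ", "))
    }
  }
  man
}

#' Write a feature/prediction table to CSV
#'
#' Column order is fixed to the order of the first record; numeric values
#' are written at full precision (15 significant digits), so the
#' write/read round trip is lossless well beyond 1e-9.
#'
#' @param rows data frame, one row per (lesion, acquisition).
#' @param path output CSV.
#' @export
write_feature_table <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature/prediction table written by [write_feature_table()]
#' @param path CSV path.
#' @export
read_feature_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
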