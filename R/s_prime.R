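# Parameter s': the melanoma/nevus spectral score.
#
# s' = log10( I_G * I_R_skin^2 / (I_G_skin * I_R^2) )
#
# where I_G, I_R are lesion intensities in the green and red channels and
# I_G_skin, I_R_skin the mean intensities of the surrounding skin. Melanin
# attenuates R strongly in melanomas, so the score rises with lesion
# darkness in R relative to skin; lesions are scored by the maximum of the
# per-pixel map over the ROI and called melanoma at >= 0.511 A.U.

#' Construct a skin reference
#'
#' @param I_G_skin,I_R_skin mean surrounding-skin intensities (> 0).
#' @param n_pixels number of pixels the means were taken over.
#' @param region description of the region (annulus parameters or "mask").
#' @param min_pixels minimum acceptable `n_pixels` (default 100).
#' @return object of class `skin_reference`.
#' @export
skin_reference <- function(I_G_skin, I_R_skin, n_pixels, region = NULL,
                           min_pixels = 100L) {
  stopifnot(is.finite(I_G_skin), is.finite(I_R_skin))
  if (I_G_skin <= 0 || I_R_skin <= 0) stop("skin reference intensities must be > 0")
  if (n_pixels < min_pixels) {
    stop("insufficient skin reference: ", n_pixels, " px < ", min_pixels)
  }
  structure(list(I_G_skin = I_G_skin, I_R_skin = I_R_skin,
                 n_pixels = as.integer(n_pixels), region = region),
            class = "skin_reference")
}

#' @export
print.skin_reference <- function(x, ...) {
  cat(sprintf("<skin_reference> I_G_skin %.2f, I_R_skin %.2f (%d px)\n",
              x$I_G_skin, x$I_R_skin, x$n_pixels))
  invisible(x)
}

#' Estimate the surrounding-skin reference intensities
#'
#' By default the skin region is an annulus around the lesion: pixels whose
#' Euclidean distance to the ROI lies in (inner_margin, inner_margin +
#' width], clipped to the image bounds, lesion pixels excluded. An explicit
#' skin mask overrides the annulus. The G and R means over that region form
#' the reference.
#'
#' @param image_set an [msi_image_set()].
#' @param roi the lesion [lesion_roi()].
#' @param inner_margin_px,width_px annulus geometry in pixels (defaults
#'   10 and 20).
#' @param skin_mask optional explicit binary matrix of skin pixels.
#' @param min_pixels minimum region size (default 100).
#' @return `skin_reference`.
#' @export
estimate_skin_reference <- function(image_set, roi, inner_margin_px = 10,
                                    width_px = 20, skin_mask = NULL,
                                    min_pixels = 100L) {
  stopifnot(inherits(image_set, "msi_image_set"), inherits(roi, "lesion_roi"))
  if (!identical(dim(image_set), dim(roi$mask))) stop("channel dimension mismatch")
  if (is.null(skin_mask)) {
    # distance of every background pixel to the lesion
    d <- as.matrix(EBImage::distmap(1L - roi$mask))
    sel <- roi$mask == 0L & d > inner_margin_px & d <= inner_margin_px + width_px
    region <- list(type = "annulus", inner_margin_px = inner_margin_px,
                   width_px = width_px)
  } else {
    stopifnot(is.matrix(skin_mask), identical(dim(skin_mask), dim(roi$mask)))
    sel <- skin_mask != 0 & roi$mask == 0L
    region <- list(type = "mask")
  }
  n <- sum(sel)
  if (n < min_pixels) stop("insufficient skin reference: ", n, " px < ", min_pixels)
  skin_reference(
    I_G_skin = mean(image_set$channels$G[sel]),
    I_R_skin = mean(image_set$channels$R[sel]),
    n_pixels = n, region = region, min_pixels = min_pixels
  )
}

#' Parameter s' from intensity quadruples
#'
#' `log10(I_G * I_R_skin^2 / (I_G_skin * I_R^2))`, vectorised over the
#' lesion intensities. All intensities below `floor` are clamped up to it
#' before taking ratios, which bounds the score for saturated-dark pixels
#' (default floor 1 on the 0-255 scale).
#'
#' @param I_G,I_R lesion intensities (scalars or vectors).
#' @param I_G_skin,I_R_skin skin reference intensities (scalars).
#' @param floor clamping floor (default 1).
#' @return s' values (A.U.).
#' @export
s_prime_value <- function(I_G, I_G_skin, I_R, I_R_skin, floor = 1) {
  vals <- list(I_G = I_G, I_G_skin = I_G_skin, I_R = I_R, I_R_skin = I_R_skin)
  for (nm in names(vals)) {
    if (anyNA(vals[[nm]])) stop("NaN/NA intensity in ", nm)
  }
  I_G <- pmax(I_G, floor)
  I_R <- pmax(I_R, floor)
  I_G_skin <- pmax(I_G_skin, floor)
  I_R_skin <- pmax(I_R_skin, floor)
  log10((I_G * I_R_skin^2) / (I_G_skin * I_R^2))
}

#' Per-pixel s' map and lesion-level score
#'
#' Evaluates [s_prime_value()] at every ROI pixel against scalar skin
#' references; outside the ROI the map is NA. The lesion-level statistic is
#' the maximum of the map over the ROI (the default), or its 99th
#' percentile as a robust alternative.
#'
#' @param image_set an [msi_image_set()].
#' @param roi lesion [lesion_roi()].
#' @param skin a [skin_reference()]; estimated with default annulus
#'   parameters when NULL.
#' @param statistic `"max"` (default) or `"p99"`.
#' @param floor clamping floor passed to [s_prime_value()].
#' @return object of class `s_prime_result` with `map`, `lesion_s_prime`,
#'   `skin_ref`, `statistic`.
#' @export
s_prime_map <- function(image_set, roi, skin = NULL,
                        statistic = c("max", "p99"), floor = 1) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(image_set, "msi_image_set"), inherits(roi, "lesion_roi"))
  if (!identical(dim(image_set), dim(roi$mask))) stop("channel dimension mismatch")
  if (is.null(skin)) skin <- estimate_skin_reference(image_set, roi)
  stopifnot(inherits(skin, "skin_reference"))
  sel <- roi$mask != 0L
  map <- matrix(NA_real_, nrow(roi$mask), ncol(roi$mask))
  map[sel] <- s_prime_value(image_set$channels$G[sel], skin$I_G_skin,
                            image_set$channels$R[sel], skin$I_R_skin,
                            floor = floor)
  lesion <- switch(statistic,
    max = max(map[sel]),
    p99 = stats::quantile(map[sel], 0.99, names = FALSE, type = 7)
  )
  structure(list(map = map, lesion_s_prime = lesion, skin_ref = skin,
                 statistic = statistic),
            class = "s_prime_result")
}

#' @export
print.s_prime_result <- function(x, ...) {
  cat(sprintf("<s_prime_result> lesion s' = %.4f (%s over %d ROI px)\n",
              x$lesion_s_prime, x$statistic, sum(!is.na(x$map))))
  invisible(x)
}

#' Melanoma / nevus call from the lesion-level s'
#'
#' Melanoma iff s' >= threshold; the tie goes to melanoma, favouring
#' sensitivity in a cancer rule-out step.
#'
#' @param lesion_s_prime scalar (or vector) of lesion-level scores.
#' @param threshold decision threshold, default 0.511 A.U.
#' @return character: "melanoma" or "nevus".
#' @export
melanoma_vs_nevus <- function(lesion_s_prime, threshold = 0.511) {
  if (anyNA(lesion_s_prime) || any(!is.finite(lesion_s_prime))) {
    stop("lesion_s_prime must be finite")
  }
  ifelse(lesion_s_prime >= threshold, "melanoma", "nevus")
}

#' Render an s' map as a diverging red-blue image
#'
#' Values are clamped to `limits` (default c(-1.5, 1.5)) and mapped on a
#' continuous diverging scale: deep blue at the low end (nevus-like),
#' white at zero, rufous red at the high end (melanoma-like). Pixels
#' outside the ROI are transparent.
#'
#' @param result an `s_prime_result`.
#' @param limits clamping range for the colour scale.
#' @return H x W x 4 RGBA array in [0, 1].
#' @export
render_s_prime_map <- function(result, limits = c(-1.5, 1.5)) {
  stopifnot(inherits(result, "s_prime_result"), limits[1L] < limits[2L])
  ramp <- grDevices::colorRamp(c("#16317D", "#FFFFFF", "#A81C07"), space = "Lab")
  map <- result$map
  out <- array(0, dim = c(nrow(map), ncol(map), 4L))
  sel <- !is.na(map)
  v <- (pmin(pmax(map[sel], limits[1L]), limits[2L]) - limits[1L]) /
    (limits[2L] - limits[1L])
  cols <- ramp(v) / 255
  for (k in 1:3) {
    plane <- out[, , k]
    plane[sel] <- cols[, k]
    out[, , k] <- plane
  }
  alpha <- out[, , 4L]
  alpha[sel] <- 1
  out[, , 4L] <- alpha
  out
}

#' Write an s' result to disk
#'
#' The float map goes to a tab-separated text file at 17 significant
#' digits (an exact double round trip; NA outside the ROI), and the colour
#' rendering to PNG.
#'
#' @param result an `s_prime_result`.
#' @param map_path TSV output path (NULL to skip).
#' @param png_path PNG output path (NULL to skip).
#' @param limits passed to [render_s_prime_map()].
#' @export
write_s_prime_map <- function(result, map_path = NULL, png_path = NULL,
                              limits = c(-1.5, 1.5)) {
  stopifnot(inherits(result, "s_prime_result"))
  if (!is.null(map_path)) {
    m <- format(result$map, digits = 17, trim = TRUE, scientific = TRUE)
    m[is.na(result$map)] <- "NA"
    utils::write.table(m, map_path, sep = "\t", row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  }
  if (!is.null(png_path)) {
    png::writePNG(render_s_prime_map(result, limits), png_path)
  }
  invisible(result)
}

#' Read an s' map written by [write_s_prime_map()]
#' @param map_path TSV path.
#' @return numeric matrix with NA outside the ROI.
#' @export
read_s_prime_map <- function(map_path) {
  m <- as.matrix(utils::read.table(map_path, sep = "\t", header = FALSE))
  dimnames(m) <- NULL
  storage.mode(m) <- "double"
  m
}
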