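# Intensity and shape morphometry of lesion ROIs, following the ImageJ
# particle-analysis definitions:
#
#   circularity = 4 * pi * area / perimeter^2
#   solidity    = area / convex area
#   roundness   = 4 * area / (pi * major_axis^2)
#
# with the major axis taken from the ellipse sharing the region's
# second-order central moments. For polygon-defined ROIs all quantities are
# exact polygon geometry; for raster masks the boundary is traced as a
# polygon (see boundary_polygon) and moments are computed from pixel centres
# with the 1/12 unit-square correction.

#' Mean gray value of a channel over an ROI
#'
#' Integrated density divided by area: the sum of pixel intensities inside
#' the ROI divided by the ROI pixel count.
#'
#' @param channel numeric matrix.
#' @param roi a [lesion_roi()] (its mask is used as given; no hole filling).
#' @return scalar intensity.
#' @export
mean_gray_value <- function(channel, roi) {
  stopifnot(inherits(roi, "lesion_roi"), is.matrix(channel))
  if (!identical(dim(channel), dim(roi$mask))) {
    stop("channel dimension mismatch")
  }
  sel <- roi$mask != 0L
  if (!any(sel)) stop("empty ROI")
  sum(channel[sel]) / sum(sel)
}

#' Core geometry of an ROI
#'
#' Dispatches between exact polygon geometry (when the ROI carries a
#' polygon) and traced-mask geometry. For masks: holes are filled
#' (`EBImage::fillHull`) so shape and intensity refer to one filled region;
#' the mask must be a single 4-connected component unless
#' `largest_component = TRUE`, which keeps the biggest one.
#'
#' @param roi a `lesion_roi`.
#' @param perimeter_method `"boundary_polygon"` (default; smoothed traced
#'   boundary, accurate on curved outlines) or `"pixel_edge"` (raw crack
#'   length; exact for axis-aligned shapes, overestimates curves).
#' @param fill_holes fill interior holes before measuring (default TRUE).
#' @param largest_component if TRUE, measure only the largest connected
#'   component instead of erroring on disconnected masks.
#' @return list with `area`, `perimeter`, `convex_area`, `major_axis`,
#'   `mask` (the possibly filled/reduced mask actually measured) and
#'   `exact` (TRUE for polygon geometry).
#' @keywords internal
roi_geometry <- function(roi, perimeter_method = c("boundary_polygon", "pixel_edge"),
                         fill_holes = TRUE, largest_component = FALSE) {
  stopifnot(inherits(roi, "lesion_roi"))
  perimeter_method <- match.arg(perimeter_method)

  if (!is.null(roi$polygon)) {
    p <- roi$polygon
    mom <- polygon_moments(p$x, p$y)
    axes <- equivalent_ellipse_axes(mom$sxx, mom$syy, mom$sxy)
    return(list(
      area = mom$area,
      perimeter = polygon_perimeter(p$x, p$y),
      convex_area = convex_hull_area(p$x, p$y),
      major_axis = axes[["major"]],
      mask = roi$mask,
      exact = TRUE
    ))
  }

  mask <- roi$mask
  lab <- EBImage::bwlabel(mask)
  ncomp <- max(lab)
  if (ncomp > 1L) {
    if (!largest_component) {
      stop("disconnected mask: ", ncomp,
           " components (set largest_component = TRUE to keep the biggest)")
    }
    sizes <- tabulate(lab[lab > 0L], nbins = ncomp)
    mask <- (lab == which.max(sizes)) + 0L
  }
  if (fill_holes) {
    mask <- as.matrix(EBImage::fillHull(mask))
    storage.mode(mask) <- "integer"
  }
  bp <- boundary_polygon(mask)
  area <- sum(mask)
  if (abs(bp$area_px - area) > 0.5) {
    # the traced circuit did not capture every pixel: should be impossible
    # after component selection + hole filling
    stop("boundary trace inconsistent with mask area")
  }
  # pixel-centre covariance with the unit-square (1/12) term, so degenerate
  # one-pixel-wide regions still have a finite equivalent ellipse
  idx <- which(mask != 0L, arr.ind = TRUE)
  n <- nrow(idx)
  cx <- mean(idx[, "col"]); cy <- mean(idx[, "row"])
  sxx <- sum((idx[, "col"] - cx)^2) / n + 1 / 12
  syy <- sum((idx[, "row"] - cy)^2) / n + 1 / 12
  sxy <- sum((idx[, "col"] - cx) * (idx[, "row"] - cy)) / n
  axes <- equivalent_ellipse_axes(sxx, syy, sxy)

  perim <- switch(perimeter_method,
    boundary_polygon = bp$perimeter_smooth,
    pixel_edge = bp$perimeter_crack
  )
  list(
    area = area,
    perimeter = perim,
    # hull on the mid-crack boundary vertices, which straddle the true
    # outline (the outer pixel corners would inflate the hull by a
    # half-pixel band and bias convex solidity ~1.5% low); floored at the
    # pixel area so area <= convex_area always holds
    convex_area = max(area, convex_hull_area(bp$midcrack$x, bp$midcrack$y)),
    major_axis = axes[["major"]],
    mask = mask,
    exact = FALSE
  )
}

#' Circularity of an ROI
#'
#' `4 * pi * area / perimeter^2`, clamped at 1 (rasterisation can push a
#' near-circular region marginally above the disk bound).
#'
#' @inheritParams roi_geometry
#' @export
circularity <- function(roi, perimeter_method = "boundary_polygon",
                        fill_holes = TRUE, largest_component = FALSE) {
  g <- roi_geometry(roi, perimeter_method, fill_holes, largest_component)
  min(1, 4 * pi * g$area / g$perimeter^2)
}

#' Solidity of an ROI
#'
#' Area over convex-hull area; 1 for convex regions.
#'
#' @inheritParams roi_geometry
#' @export
solidity <- function(roi, perimeter_method = "boundary_polygon",
                     fill_holes = TRUE, largest_component = FALSE) {
  g <- roi_geometry(roi, perimeter_method, fill_holes, largest_component)
  min(1, g$area / g$convex_area)
}

#' Roundness of an ROI
#'
#' `4 * area / (pi * major_axis^2)` with the major axis of the
#' moment-equivalent ellipse; 1 for a disk, `b/a` for an ellipse with
#' semi-axes a > b.
#'
#' @inheritParams roi_geometry
#' @export
roundness <- function(roi, perimeter_method = "boundary_polygon",
                      fill_holes = TRUE, largest_component = FALSE) {
  g <- roi_geometry(roi, perimeter_method, fill_holes, largest_component)
  min(1, 4 * g$area / (pi * g$major_axis^2))
}

#' Extract the full feature vector of one acquisition
#'
#' One ROI drives all three channels (the analysed area is identical in G,
#' R and IR). Intensity means are taken over the same (hole-filled) mask
#' used for the shape descriptors.
#'
#' @param image_set an [msi_image_set()].
#' @param roi a [lesion_roi()].
#' @inheritParams roi_geometry
#' @return object of class `msi_features`: mean_G/mean_R/mean_IR, area_px,
#'   area_mm2, perimeter_px, convex_area_px, major_axis_px, circularity,
#'   solidity, roundness.
#' @export
extract_features <- function(image_set, roi,
                             perimeter_method = "boundary_polygon",
                             fill_holes = TRUE, largest_component = FALSE) {
  stopifnot(inherits(image_set, "msi_image_set"))
  if (!identical(dim(image_set), dim(roi$mask))) {
    stop("channel dimension mismatch")
  }
  g <- roi_geometry(roi, perimeter_method, fill_holes, largest_component)
  measured <- lesion_roi(mask = g$mask)
  f <- list(
    mean_G = mean_gray_value(image_set$channels$G, measured),
    mean_R = mean_gray_value(image_set$channels$R, measured),
    mean_IR = mean_gray_value(image_set$channels$IR, measured),
    area_px = g$area,
    area_mm2 = g$area * image_set$pixel_size_mm^2,
    perimeter_px = g$perimeter,
    convex_area_px = g$convex_area,
    major_axis_px = g$major_axis,
    circularity = min(1, 4 * pi * g$area / g$perimeter^2),
    solidity = min(1, g$area / g$convex_area),
    roundness = min(1, 4 * g$area / (pi * g$major_axis^2))
  )
  structure(f, class = "msi_features")
}

#' @export
as.data.frame.msi_features <- function(x, ...) {
  as.data.frame(unclass(x), stringsAsFactors = FALSE)
}

#' @export
print.msi_features <- function(x, ...) {
  cat(sprintf(paste0("<msi_features> area %.1f px (%.2f mm2)\n",
                     "  mean gray  G %.2f  R %.2f  IR %.2f\n",
                     "  circularity %.4f  solidity %.4f  roundness %.4f\n"),
              x$area_px, x$area_mm2, x$mean_G, x$mean_R, x$mean_IR,
              x$circularity, x$solidity, x$roundness))
  invisible(x)
}
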