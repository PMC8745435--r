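# Seeded generator of synthetic multispectral lesion cohorts.
#
# Each record emulates one acquisition: a uniform skin background with
# additive Gaussian pixel noise, and an embedded pigmented lesion whose
# outline is a star-like polygon r(theta) = R * (1 + sum_k a_k sin(k theta
# + phi_k)) and whose per-channel intensity is the skin mean times a
# class-drawn attenuation factor, blended into the background over a short
# transition strictly inside the mask. Class-conditional attenuation and
# boundary-irregularity ranges are calibrated so that the four classes
# straddle the published decision thresholds (they are statistical knobs,
# not a physical melanin model): nevi score below the s' threshold; thin
# melanomas are irregular and G-bright; intermediate melanomas can take
# either circularity branch (dark in G on the irregular route, IR-bright on
# the circular route); thick melanomas are circular and IR-dark.

#' Generator configuration
#'
#' Defaults define the reference study conditions used by the package's
#' validation: 500 x 500 px images of a 2 x 2 cm field (0.04 mm/px), skin
#' means G 120 / R 140 / IR 180 A.U., Gaussian pixel noise sd 3, and the
#' class parameter ranges below. `overlap` in [0, 1] linearly widens every
#' class's attenuation and irregularity range toward the pooled
#' across-class range; at 1 all classes draw from identical ranges and the
#' pipeline's class signal vanishes.
#'
#' @param image_size c(nrow, ncol) in pixels.
#' @param pixel_size_mm pixel pitch.
#' @param skin_mean named intensities (G, R, IR).
#' @param noise_sd Gaussian pixel noise standard deviation (A.U.).
#' @param blend_px boundary transition width inside the lesion (px).
#' @param class_params per-class lists with `radius` (px range),
#'   `irregularity` (total boundary-amplitude range), `harmonics`
#'   (wavenumbers), `atten` (named list of per-channel attenuation ranges),
#'   `breslow_mm` (range of true thickness; NA for nevus).
#' @param overlap class-overlap widening knob in [0, 1].
#' @param center_jitter_px max uniform displacement of the lesion centre.
#' @param n_vertices polygon sampling density.
#' @param fiducials stamp four dark corner markers (0.125 cm^2 squares) to
#'   exercise skin-annulus logic (default FALSE).
#' @return object of class `generator_config`.
#' @export
generator_config <- function(image_size = c(500L, 500L),
                             pixel_size_mm = 0.04,
                             skin_mean = c(G = 120, R = 140, IR = 180),
                             noise_sd = 3,
                             blend_px = 2,
                             class_params = default_class_params(),
                             overlap = 0,
                             center_jitter_px = 25,
                             n_vertices = 180L,
                             fiducials = FALSE) {
  stopifnot(length(image_size) == 2L, all(image_size >= 64L),
            all(skin_mean > 0), noise_sd >= 0, blend_px >= 0,
            overlap >= 0, overlap <= 1,
            all(breslow_classes() %in% names(class_params)))
  for (cls in names(class_params)) {
    at <- class_params[[cls]]$atten
    stopifnot(all(vapply(at, function(r) all(r > 0) && all(r <= 1), logical(1L))),
              all(class_params[[cls]]$irregularity >= 0))
  }
  cfg <- list(image_size = as.integer(image_size), pixel_size_mm = pixel_size_mm,
              skin_mean = skin_mean, noise_sd = noise_sd, blend_px = blend_px,
              class_params = class_params, overlap = overlap,
              center_jitter_px = center_jitter_px,
              n_vertices = as.integer(n_vertices), fiducials = fiducials)
  structure(cfg, class = "generator_config")
}

#' Default class-conditional generator parameters
#'
#' Attenuation ranges (fraction of the skin mean remaining inside the
#' lesion) and boundary irregularity per class; see the methods vignette
#' for the calibration rationale.
#'
#' @return named list (nevus, breslow_le_1mm, breslow_1_2mm, breslow_gt_2mm).
#' @export
default_class_params <- function() {
  list(
    nevus = list(
      radius = c(40, 70), irregularity = c(0.02, 0.08), harmonics = 2:5,
      atten = list(G = c(0.28, 0.40), R = c(0.75, 0.90), IR = c(0.80, 0.95)),
      breslow_mm = c(NA_real_, NA_real_)
    ),
    breslow_le_1mm = list(
      radius = c(50, 85), irregularity = c(0.55, 0.75), harmonics = 3:7,
      atten = list(G = c(0.10, 0.25), R = c(0.08, 0.16), IR = c(0.70, 0.90)),
      breslow_mm = c(0.2, 1.0)
    ),
    breslow_1_2mm = list(
      radius = c(70, 95), irregularity = c(0.05, 0.55), harmonics = 3:7,
      atten = list(G = c(0.012, 0.040), R = c(0.03, 0.06), IR = c(0.65, 0.85)),
      breslow_mm = c(1.0, 2.0)
    ),
    breslow_gt_2mm = list(
      radius = c(60, 95), irregularity = c(0.01, 0.04), harmonics = 2:5,
      atten = list(G = c(0.05, 0.12), R = c(0.04, 0.10), IR = c(0.25, 0.45)),
      breslow_mm = c(2.0, 6.0)
    )
  )
}

# widen one class's ranges toward the pooled range across classes
widen_params <- function(class_params, overlap) {
  if (overlap <= 0) return(class_params)
  pool_range <- function(get) {
    vals <- unlist(lapply(class_params, get))
    range(vals, na.rm = TRUE)
  }
  pools <- list(
    irregularity = pool_range(function(p) p$irregularity),
    G = pool_range(function(p) p$atten$G),
    R = pool_range(function(p) p$atten$R),
    IR = pool_range(function(p) p$atten$IR)
  )
  mix <- function(r, pool) (1 - overlap) * r + overlap * pool
  for (cls in names(class_params)) {
    p <- class_params[[cls]]
    p$irregularity <- mix(p$irregularity, pools$irregularity)
    for (ch in names(p$atten)) p$atten[[ch]] <- mix(p$atten[[ch]], pools[[ch]])
    class_params[[cls]] <- p
  }
  class_params
}

#' Draw a star-like lesion outline and rasterise it
#'
#' r(theta) = R * (1 + sum_k a_k sin(k theta + phi_k)) with the total
#' amplitude sum drawn from `params$irregularity` and split randomly over
#' `params$harmonics`; radii are clamped at 0.15 R so the outline stays
#' star-shaped and connected. Larger irregularity lowers the expected
#' circularity and solidity. Uses R's global RNG (seed at the caller).
#'
#' @param params one entry of `class_params` (needs `radius`,
#'   `irregularity`, `harmonics`).
#' @param image_size target raster c(nrow, ncol).
#' @param center lesion centre c(row, col); image centre when NULL.
#' @param n_vertices polygon sampling density (default 180).
#' @return a [lesion_roi()] with polygon and mask; drawn parameters are in
#'   `attr(, "gen_params")`.
#' @export
generate_lesion_shape <- function(params, image_size = c(500L, 500L),
                                  center = NULL, n_vertices = 180L) {
  stopifnot(all(params$radius > 0))
  R <- stats::runif(1L, params$radius[1L], params$radius[2L])
  amp <- stats::runif(1L, params$irregularity[1L], params$irregularity[2L])
  k <- params$harmonics
  w <- stats::runif(length(k))
  w <- w / sum(w) * amp
  phi <- stats::runif(length(k), 0, 2 * pi)
  if (is.null(center)) center <- (image_size + 1) / 2
  theta <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  r <- R * (1 + colSums(w * sin(outer(k, theta) + phi)))
  r <- pmax(r, 0.15 * R)
  polygon <- data.frame(x = center[2L] + r * cos(theta),
                        y = center[1L] + r * sin(theta))
  if (min(polygon$x) < 1 || min(polygon$y) < 1 ||
      max(polygon$x) > image_size[2L] || max(polygon$y) > image_size[1L]) {
    stop("lesion outline exceeds image bounds; reduce radius or jitter")
  }
  roi <- lesion_roi(polygon = polygon, shape = image_size)
  attr(roi, "gen_params") <- list(radius = R, irregularity = amp,
                                  harmonics = k, amplitudes = w, phases = phi,
                                  center = center)
  roi
}

#' Render one synthetic acquisition for a class label
#'
#' Outside the lesion each channel is skin mean + noise; inside it is the
#' skin mean times the class-drawn attenuation, blended from the skin value
#' at the mask boundary to the full lesion value `blend_px` inside, plus
#' noise; everything clipped to [0, 255]. With `noise_sd = 0` and no
#' clipping the interior equals skin_mean * attenuation exactly beyond the
#' blend ring.
#'
#' @param class_label one of [breslow_classes()].
#' @param shape a [lesion_roi()] (typically [generate_lesion_shape()]).
#' @param config a [generator_config()].
#' @param lesion_id,acquisition_id identifiers.
#' @return object of class `synthetic_record`: `image_set`, `roi`, `label`,
#'   `params` (true attenuations, irregularity, radius, breslow_mm).
#' @export
generate_image_set <- function(class_label, shape, config = generator_config(),
                               lesion_id = class_label, acquisition_id = "acq1") {
  stopifnot(inherits(config, "generator_config"),
            class_label %in% breslow_classes(), inherits(shape, "lesion_roi"))
  params <- widen_params(config$class_params, config$overlap)[[class_label]]
  atten <- vapply(c("G", "R", "IR"), function(ch)
    stats::runif(1L, params$atten[[ch]][1L], params$atten[[ch]][2L]), double(1L))
  breslow_mm <- if (anyNA(params$breslow_mm)) NA_real_ else
    stats::runif(1L, params$breslow_mm[1L], params$breslow_mm[2L])

  mask <- shape$mask
  nr <- nrow(mask); nc <- ncol(mask)
  # blend weight: ramps from the skin value at the mask edge to the full
  # lesion value blend_px inside (distance measured to the nearest
  # background pixel, so edge pixels at d = 1 sit mid-ramp)
  if (config$blend_px > 0) {
    d <- as.matrix(EBImage::distmap(mask))
    w <- pmin(1, pmax(0, d / config$blend_px))
  } else {
    w <- (mask != 0L) + 0
  }
  channels <- list()
  for (ch in c("G", "R", "IR")) {
    sk <- config$skin_mean[[ch]]
    base <- matrix(sk, nr, nc)
    base <- base * (1 - w) + (sk * atten[[ch]]) * w
    if (config$fiducials) {
      # 0.125 cm^2 = 12.5 mm^2 markers, clamped for small test rasters
      side <- min(round(sqrt(12.5) / config$pixel_size_mm),
                  floor(min(nr, nc) / 5))
      m <- 10L
      base[m:(m + side), m:(m + side)] <- 5
      base[m:(m + side), (nc - m - side):(nc - m)] <- 5
      base[(nr - m - side):(nr - m), m:(m + side)] <- 5
      base[(nr - m - side):(nr - m), (nc - m - side):(nc - m)] <- 5
    }
    if (config$noise_sd > 0) {
      base <- base + matrix(stats::rnorm(nr * nc, 0, config$noise_sd), nr, nc)
    }
    channels[[ch]] <- pmin(pmax(base, 0), 255)
  }
  image_set <- msi_image_set(channels, lesion_id = lesion_id,
                             acquisition_id = acquisition_id,
                             pixel_size_mm = config$pixel_size_mm)
  gen <- attr(shape, "gen_params")
  structure(
    list(image_set = image_set, roi = shape, label = class_label,
         params = list(attenuation = atten, irregularity = gen$irregularity,
                       radius = gen$radius, breslow_mm = breslow_mm)),
    class = "synthetic_record"
  )
}

#' @export
print.synthetic_record <- function(x, ...) {
  cat(sprintf("<synthetic_record> %s (%s), atten G %.3f R %.3f IR %.3f, irregularity %.3f\n",
              x$image_set$lesion_id, x$label, x$params$attenuation[["G"]],
              x$params$attenuation[["R"]], x$params$attenuation[["IR"]],
              x$params$irregularity))
  invisible(x)
}

#' Generate a labelled synthetic cohort
#'
#' Draws `n_per_class` records for each of the four classes under `config`,
#' fully reproducibly from `seed`. With `out_dir` the cohort is also
#' written to disk in the formats the I/O layer consumes: per-channel 8-bit
#' TIFFs (intensities rounded to integers), mask PNGs and a `manifest.csv`
#' with truth labels and the true generating parameters.
#'
#' @param n_per_class records per class (scalar, or named vector over
#'   [breslow_classes()]).
#' @param config a [generator_config()].
#' @param seed integer seed (the global RNG state is restored on exit).
#' @param out_dir output directory, or NULL for an in-memory cohort.
#' @return list of class `synthetic_cohort`: `records` (list of
#'   `synthetic_record`), `manifest` (data frame), `config`, `seed`.
#' @export
generate_cohort <- function(n_per_class, config = generator_config(),
                            seed = 1L, out_dir = NULL) {
  stopifnot(inherits(config, "generator_config"))
  classes <- breslow_classes()
  if (length(n_per_class) == 1L) {
    n_per_class <- stats::setNames(rep(n_per_class, 4L), classes)
  }
  stopifnot(all(classes %in% names(n_per_class)))

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)

  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  records <- list()
  rows <- list()
  jmax <- config$center_jitter_px
  for (cls in classes) {
    for (i in seq_len(n_per_class[[cls]])) {
      lesion_id <- sprintf("%s_%03d", cls, i)
      center <- (config$image_size + 1) / 2 +
        stats::runif(2L, -jmax, jmax)
      shape <- generate_lesion_shape(config$class_params[[cls]],
                                     image_size = config$image_size,
                                     center = center,
                                     n_vertices = config$n_vertices)
      rec <- generate_image_set(cls, shape, config, lesion_id = lesion_id)
      records[[lesion_id]] <- rec
      row <- data.frame(
        lesion_id = lesion_id, acquisition_id = "acq1", truth_label = cls,
        breslow_mm = rec$params$breslow_mm,
        atten_G = rec$params$attenuation[["G"]],
        atten_R = rec$params$attenuation[["R"]],
        atten_IR = rec$params$attenuation[["IR"]],
        irregularity = rec$params$irregularity,
        radius_px = rec$params$radius,
        stringsAsFactors = FALSE
      )
      if (!is.null(out_dir)) {
        paths <- c(G = file.path(out_dir, paste0(lesion_id, "_g.tif")),
                   R = file.path(out_dir, paste0(lesion_id, "_r.tif")),
                   IR = file.path(out_dir, paste0(lesion_id, "_ir.tif")))
        quantised <- rec$image_set
        quantised$channels <- lapply(quantised$channels, round)
        write_image_set(quantised, paths)
        mask_path <- file.path(out_dir, paste0(lesion_id, "_mask.png"))
        write_roi(rec$roi, mask_path)
        row$g_path <- basename(paths[["G"]])
        row$r_path <- basename(paths[["R"]])
        row$ir_path <- basename(paths[["IR"]])
        row$mask_path <- basename(mask_path)
      }
      rows[[lesion_id]] <- row
    }
  }
  manifest <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (!is.null(out_dir)) {
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
  }
  structure(list(records = records, manifest = manifest, config = config,
                 seed = seed),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d records (seed %s):\n",
              length(x$records), format(x$seed)))
  print(table(x$manifest$truth_label))
  invisible(x)
}
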