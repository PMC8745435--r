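# End-to-end pipeline: features -> s' -> classification -> evaluation.

#' Pipeline run configuration
#'
#' Bundles every tunable of the pipeline; defaults are the published
#' calibration. Serialises losslessly to JSON via [write_run_config()].
#'
#' @param thresholds a [classifier_thresholds()].
#' @param annulus_inner_px,annulus_width_px skin-annulus geometry.
#' @param min_skin_pixels minimum skin-reference size.
#' @param s_prime_statistic `"max"` or `"p99"` lesion-level statistic.
#' @param clamp_floor intensity clamping floor for s'.
#' @param perimeter_method see [roi_geometry()].
#' @param aggregation lesion-level aggregation policy.
#' @param seed seed for seeded sub-steps (bootstrap CIs).
#' @return object of class `run_config`.
#' @export
run_config <- function(thresholds = classifier_thresholds(),
                       annulus_inner_px = 10, annulus_width_px = 20,
                       min_skin_pixels = 100L,
                       s_prime_statistic = c("max", "p99"),
                       clamp_floor = 1,
                       perimeter_method = c("boundary_polygon", "pixel_edge"),
                       aggregation = c("worst_case", "majority"),
                       seed = 1L) {
  structure(list(
    thresholds = thresholds,
    annulus_inner_px = annulus_inner_px,
    annulus_width_px = annulus_width_px,
    min_skin_pixels = as.integer(min_skin_pixels),
    s_prime_statistic = match.arg(s_prime_statistic),
    clamp_floor = clamp_floor,
    perimeter_method = match.arg(perimeter_method),
    aggregation = match.arg(aggregation),
    seed = as.integer(seed)
  ), class = "run_config")
}

#' Write a run configuration to JSON
#' @param config a [run_config()].
#' @param path output path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  x <- unclass(config)
  x$thresholds <- unclass(x$thresholds)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a run configuration written by [write_run_config()]
#' @param path JSON path.
#' @return `run_config`.
#' @export
read_run_config <- function(path) {
  x <- jsonlite::fromJSON(path)
  run_config(
    thresholds = do.call(classifier_thresholds, as.list(x$thresholds)),
    annulus_inner_px = x$annulus_inner_px,
    annulus_width_px = x$annulus_width_px,
    min_skin_pixels = x$min_skin_pixels,
    s_prime_statistic = x$s_prime_statistic,
    clamp_floor = x$clamp_floor,
    perimeter_method = x$perimeter_method,
    aggregation = x$aggregation,
    seed = x$seed
  )
}

# normalise pipeline input to a list of (image_set, roi, ids, truth) items
pipeline_items <- function(x) {
  if (inherits(x, "synthetic_cohort")) x <- x$records
  if (is.list(x) && length(x) > 0L && all(vapply(x, inherits, logical(1L), "synthetic_record"))) {
    return(lapply(x, function(rec) list(
      image_set = rec$image_set, roi = rec$roi,
      lesion_id = rec$image_set$lesion_id,
      acquisition_id = rec$image_set$acquisition_id,
      truth_label = rec$label, breslow_mm = rec$params$breslow_mm
    )))
  }
  if (is.data.frame(x)) {
    return(lapply(seq_len(nrow(x)), function(i) {
      row <- x[i, ]
      image_set <- read_image_set(
        c(G = row$g_path, R = row$r_path, IR = row$ir_path),
        lesion_id = row$lesion_id, acquisition_id = row$acquisition_id
      )
      roi <- read_roi(row$mask_path, dim(image_set))
      skin <- if (!is.null(row$skin_mask_path) && !is.na(row$skin_mask_path) &&
                  nzchar(row$skin_mask_path)) {
        read_gray(row$skin_mask_path, scale = 1)
      } else NULL
      list(image_set = image_set, roi = roi, skin_mask = skin,
           lesion_id = row$lesion_id, acquisition_id = row$acquisition_id,
           truth_label = if ("truth_label" %in% names(row)) row$truth_label else NA,
           breslow_mm = if ("breslow_mm" %in% names(row)) row$breslow_mm else NA)
    }))
  }
  stop("unsupported pipeline input; pass a synthetic cohort, a list of ",
       "synthetic records, or a manifest data frame")
}

#' Per-acquisition feature and score table
#'
#' Runs feature extraction and the s' computation over a cohort (synthetic
#' cohort / record list, or a manifest data frame referencing files).
#'
#' @param x cohort input.
#' @param config a [run_config()].
#' @return data frame with ids, truth columns (if present), the full
#'   feature vector and `s_prime_max`.
#' @export
pipeline_features <- function(x, config = run_config()) {
  items <- pipeline_items(x)
  rows <- lapply(items, function(it) {
    feats <- extract_features(it$image_set, it$roi,
                              perimeter_method = config$perimeter_method)
    skin <- estimate_skin_reference(
      it$image_set, it$roi,
      inner_margin_px = config$annulus_inner_px,
      width_px = config$annulus_width_px,
      skin_mask = it$skin_mask,
      min_pixels = config$min_skin_pixels
    )
    sp <- s_prime_map(it$image_set, it$roi, skin,
                      statistic = config$s_prime_statistic,
                      floor = config$clamp_floor)
    cbind(
      data.frame(lesion_id = it$lesion_id, acquisition_id = it$acquisition_id,
                 truth_label = if (is.null(it$truth_label)) NA else it$truth_label,
                 breslow_mm = if (is.null(it$breslow_mm)) NA_real_ else it$breslow_mm,
                 stringsAsFactors = FALSE),
      as.data.frame(feats),
      data.frame(s_prime_max = sp$lesion_s_prime,
                 skin_G = skin$I_G_skin, skin_R = skin$I_R_skin)
    )
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Classify a feature table
#'
#' Applies the decision tree to every acquisition row and aggregates to one
#' prediction per lesion.
#'
#' @param features data frame from [pipeline_features()].
#' @param config a [run_config()].
#' @return list: `acquisitions` (features + `label` + `decision_trace`),
#'   `lesions` (one aggregated row per lesion).
#' @export
classify_features <- function(features, config = run_config()) {
  preds <- lapply(seq_len(nrow(features)), function(i) {
    classify_acquisition(features[i, ], features$s_prime_max[i],
                         config$thresholds)
  })
  features$label <- vapply(preds, function(p) p$label, character(1L))
  features$decision_trace <- vapply(preds, format_decision_trace, character(1L))

  lesions <- lapply(split(seq_len(nrow(features)), features$lesion_id), function(idx) {
    agg <- aggregate_lesion(preds[idx], policy = config$aggregation)
    data.frame(
      lesion_id = features$lesion_id[idx[1L]],
      truth_label = features$truth_label[idx[1L]],
      breslow_mm = features$breslow_mm[idx[1L]],
      n_acquisitions = length(idx),
      label = agg$label,
      stringsAsFactors = FALSE
    )
  })
  lesions <- do.call(rbind, c(lesions, list(make.row.names = FALSE)))
  lesions <- lesions[order(match(lesions$lesion_id, features$lesion_id)), ,
                     drop = FALSE]
  rownames(lesions) <- NULL
  list(acquisitions = features, lesions = lesions)
}

#' Run the full pipeline
#'
#' features -> s' -> decision tree -> per-lesion aggregation, plus an
#' evaluation report when truth labels are available: confusion matrix,
#' per-class and overall sensitivity/specificity, Cohen's kappa, the
#' melanoma-vs-nevus ROC AUC on s' (when both nevi and melanomas are
#' present) and the Pearson correlation of mean IR with Breslow thickness
#' (when thickness is available). All stage parameters are echoed in the
#' report.
#'
#' @param x cohort input (see [pipeline_features()]).
#' @param config a [run_config()].
#' @return list of class `msi_pipeline_result`: `acquisitions`, `lesions`,
#'   `report`, `config`.
#' @export
run_pipeline <- function(x, config = run_config()) {
  features <- pipeline_features(x, config)
  cls <- classify_features(features, config)
  report <- list(parameters = unclass(config))
  truth_known <- !all(is.na(cls$lesions$truth_label))
  if (truth_known) {
    lt <- cls$lesions
    report$metrics <- metric_report(lt$truth_label, lt$label,
                                    classes = breslow_classes())
    is_mel <- lt$truth_label != "nevus"
    if (any(is_mel) && any(!is_mel)) {
      acq <- cls$acquisitions
      report$nevus_exclusion_roc <- roc_auc(
        acq$s_prime_max,
        ifelse(acq$truth_label == "nevus", "nevus", "melanoma"),
        positive = "melanoma", seed = config$seed
      )
    }
    ok <- is.finite(lt$breslow_mm)
    if (sum(ok) >= 3L) {
      report$pearson_ir_breslow <- tryCatch(
        pearson_correlation(cls$acquisitions$mean_IR[
          match(lt$lesion_id[ok], cls$acquisitions$lesion_id)],
          lt$breslow_mm[ok]),
        error = function(e) NULL
      )
    }
  }
  structure(list(acquisitions = cls$acquisitions, lesions = cls$lesions,
                 report = report, config = config),
            class = "msi_pipeline_result")
}

#' @export
print.msi_pipeline_result <- function(x, ...) {
  cat(sprintf("<msi_pipeline_result> %d acquisitions, %d lesions\n",
              nrow(x$acquisitions), nrow(x$lesions)))
  if (!is.null(x$report$metrics)) {
    m <- x$report$metrics
    if (!is.null(m$kappa)) {
      cat(sprintf("  accuracy %.3f | kappa %.3f (95%% CI %.3f-%.3f)\n",
                  m$accuracy, m$kappa$kappa, m$kappa$ci[1L], m$kappa$ci[2L]))
    } else {
      cat(sprintf("  accuracy %.3f\n", m$accuracy))
    }
    if (!is.null(x$report$nevus_exclusion_roc)) {
      cat(sprintf("  melanoma-vs-nevus AUC on s': %.3f\n",
                  x$report$nevus_exclusion_roc$auc))
    }
  }
  invisible(x)
}
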