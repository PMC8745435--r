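# The three-step Breslow-thickness decision tree.
#
# Step 1: lesion-level s' < 0.511  -> nevus (stop).
# Step 2: circularity <= 0.727     -> LOW branch, otherwise HIGH branch.
# Step 3 (LOW):  mean_G  > 8.0     -> Breslow <= 1 mm, else 1-2 mm.
# Step 3 (HIGH): mean_IR < 107.9   -> Breslow  > 2 mm, else 1-2 mm.
#
# Thin melanomas tend to be irregular (low circularity) and bright in G
# (little melanin); thick/nodular melanomas are more circular and dark in
# the depth-probing IR channel. Tie-breaks follow the comparative wording
# of the rules: strict ">" is required for <= 1 mm, strict "<" for > 2 mm,
# circularity exactly at threshold takes the LOW branch, and s' exactly at
# threshold is called melanoma (sensitivity-favouring).
#
# The four thresholds are calibration constants tied to the original
# device's intensity scale and to this package's feature conventions
# (boundary-polygon perimeter); on other data they are starting points,
# not universal constants.

#' Ordered Breslow class labels
#'
#' Severity order: nevus < breslow_le_1mm < breslow_1_2mm < breslow_gt_2mm.
#' @return character vector of the four labels.
#' @export
breslow_classes <- function() {
  c("nevus", "breslow_le_1mm", "breslow_1_2mm", "breslow_gt_2mm")
}

#' Decision-tree thresholds
#'
#' Defaults are the published calibration: s' 0.511, circularity 0.727,
#' G 8.0, IR 107.9 (all A.U. on the 0-255 intensity scale).
#'
#' @param s_prime,circularity,mean_g,mean_ir threshold values.
#' @return object of class `classifier_thresholds`.
#' @export
classifier_thresholds <- function(s_prime = 0.511, circularity = 0.727,
                                  mean_g = 8.0, mean_ir = 107.9) {
  vals <- c(s_prime = s_prime, circularity = circularity,
            mean_g = mean_g, mean_ir = mean_ir)
  if (!all(is.finite(vals))) stop("thresholds must be finite")
  if (circularity <= 0 || circularity >= 1) {
    stop("circularity threshold must lie in (0, 1)")
  }
  structure(as.list(vals), class = "classifier_thresholds")
}

#' @export
print.classifier_thresholds <- function(x, ...) {
  cat(sprintf("<classifier_thresholds> s' %.3f | circularity %.3f | G %.1f | IR %.1f\n",
              x$s_prime, x$circularity, x$mean_g, x$mean_ir))
  invisible(x)
}

#' Classify one acquisition
#'
#' @param features an [extract_features()] result, or any list/one-row data
#'   frame with `circularity`, `mean_G` and `mean_IR`.
#' @param lesion_s_prime lesion-level s' (the ROI maximum of the map).
#' @param thresholds a [classifier_thresholds()].
#' @return object of class `breslow_prediction`: `label` (one of
#'   [breslow_classes()]) and `trace`, a data frame recording each decision
#'   step (feature, value, threshold, branch taken).
#' @export
classify_acquisition <- function(features, lesion_s_prime,
                                 thresholds = classifier_thresholds()) {
  stopifnot(inherits(thresholds, "classifier_thresholds"))
  if (is.data.frame(features)) features <- as.list(features[1L, ])
  needed <- c("circularity", "mean_G", "mean_IR")
  for (nm in c("lesion_s_prime", needed)) {
    v <- if (nm == "lesion_s_prime") lesion_s_prime else features[[nm]]
    if (is.null(v) || length(v) != 1L || !is.finite(v)) {
      stop("invalid feature: ", nm)
    }
  }

  trace <- data.frame(step = integer(), feature = character(),
                      value = double(), threshold = double(),
                      branch = character(), stringsAsFactors = FALSE)
  add <- function(step, feature, value, threshold, branch) {
    rbind(trace, data.frame(step = step, feature = feature, value = value,
                            threshold = threshold, branch = branch,
                            stringsAsFactors = FALSE))
  }

  if (lesion_s_prime < thresholds$s_prime) {
    trace <- add(1L, "s_prime", lesion_s_prime, thresholds$s_prime, "nevus")
    label <- "nevus"
  } else {
    trace <- add(1L, "s_prime", lesion_s_prime, thresholds$s_prime, "melanoma")
    low <- features$circularity <= thresholds$circularity
    trace <- add(2L, "circularity", features$circularity,
                 thresholds$circularity, if (low) "low" else "high")
    if (low) {
      le1 <- features$mean_G > thresholds$mean_g
      trace <- add(3L, "mean_G", features$mean_G, thresholds$mean_g,
                   if (le1) "breslow_le_1mm" else "breslow_1_2mm")
      label <- if (le1) "breslow_le_1mm" else "breslow_1_2mm"
    } else {
      gt2 <- features$mean_IR < thresholds$mean_ir
      trace <- add(3L, "mean_IR", features$mean_IR, thresholds$mean_ir,
                   if (gt2) "breslow_gt_2mm" else "breslow_1_2mm")
      label <- if (gt2) "breslow_gt_2mm" else "breslow_1_2mm"
    }
  }
  structure(list(label = label, trace = trace), class = "breslow_prediction")
}

#' @export
print.breslow_prediction <- function(x, ...) {
  cat(sprintf("<breslow_prediction> %s\n", x$label))
  for (i in seq_len(nrow(x$trace))) {
    tr <- x$trace[i, ]
    cat(sprintf("  step %d: %s = %.4g vs %.4g -> %s\n",
                tr$step, tr$feature, tr$value, tr$threshold, tr$branch))
  }
  invisible(x)
}

#' Compact one-line rendering of a decision trace
#' @param prediction a `breslow_prediction`.
#' @return character scalar, steps separated by "; ".
#' @export
format_decision_trace <- function(prediction) {
  stopifnot(inherits(prediction, "breslow_prediction"))
  tr <- prediction$trace
  paste(sprintf("%s=%.4g|%.4g->%s", tr$feature, tr$value, tr$threshold, tr$branch),
        collapse = "; ")
}

#' Aggregate several acquisition-level predictions of one lesion
#'
#' Policies: `"worst_case"` (default) returns the thickest class observed;
#' `"majority"` returns the modal class, breaking ties toward the thicker
#' one. Both policies are monotone: adding a thicker prediction never
#' yields a thinner aggregate.
#'
#' @param predictions nonempty list of `breslow_prediction` objects.
#' @param policy aggregation rule.
#' @return `breslow_prediction` whose trace records the policy and votes.
#' @export
aggregate_lesion <- function(predictions, policy = c("worst_case", "majority")) {
  policy <- match.arg(policy)
  if (length(predictions) == 0L) stop("no predictions to aggregate")
  stopifnot(all(vapply(predictions, inherits, logical(1L), "breslow_prediction")))
  labels <- vapply(predictions, function(p) p$label, character(1L))
  sev <- match(labels, breslow_classes())
  label <- switch(policy,
    worst_case = breslow_classes()[max(sev)],
    majority = {
      tab <- table(factor(labels, levels = breslow_classes()))
      winners <- names(tab)[tab == max(tab)]
      winners[which.max(match(winners, breslow_classes()))]
    }
  )
  trace <- data.frame(
    step = 0L, feature = paste0("aggregate_", policy),
    value = length(predictions), threshold = NA_real_,
    branch = paste0(label, " [votes: ", paste(labels, collapse = ","), "]"),
    stringsAsFactors = FALSE
  )
  structure(list(label = label, trace = trace), class = "breslow_prediction")
}

#' Exhaustive decision table over feature grids
#'
#' Evaluates the decision tree at every combination of the supplied feature
#' values; a debugging/verification surface for the tree and its
#' tie-breaks.
#'
#' @param thresholds a [classifier_thresholds()].
#' @param s_prime,circularity,mean_G,mean_IR numeric grids.
#' @return data frame with one row per combination plus a `label` column.
#' @export
decision_table <- function(thresholds = classifier_thresholds(),
                           s_prime, circularity, mean_G, mean_IR) {
  grid <- expand.grid(s_prime = s_prime, circularity = circularity,
                      mean_G = mean_G, mean_IR = mean_IR,
                      KEEP.OUT.ATTRS = FALSE)
  grid$label <- vapply(seq_len(nrow(grid)), function(i) {
    classify_acquisition(
      list(circularity = grid$circularity[i], mean_G = grid$mean_G[i],
           mean_IR = grid$mean_IR[i]),
      grid$s_prime[i], thresholds
    )$label
  }, character(1L))
  grid
}
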