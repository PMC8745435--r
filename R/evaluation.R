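# Diagnostic performance statistics: confusion matrices, one-vs-rest
# sensitivity/specificity, Cohen's kappa with a large-sample CI, ROC/AUC
# with a seeded stratified bootstrap CI, and Pearson correlation.

#' Confusion matrix
#'
#' Rows are truth, columns are prediction, in the order of `classes`.
#'
#' @param truth,predicted equal-length label vectors.
#' @param classes ordered class labels; defaults to the sorted union.
#' @return integer k x k matrix of class `confusion_matrix`.
#' @export
confusion_matrix <- function(truth, predicted, classes = NULL) {
  if (length(truth) == 0L) stop("empty label vectors")
  if (length(truth) != length(predicted)) stop("length mismatch")
  if (is.null(classes)) classes <- sort(unique(c(truth, predicted)))
  unknown <- setdiff(unique(c(truth, predicted)), classes)
  if (length(unknown) > 0L) {
    stop("unknown label(s): ", paste(unknown, collapse = ", "))
  }
  cm <- table(truth = factor(truth, levels = classes),
              predicted = factor(predicted, levels = classes))
  cm <- unclass(cm)
  storage.mode(cm) <- "integer"
  structure(cm, class = c("confusion_matrix", "matrix"))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> rows = truth, cols = predicted\n")
  print(unclass(x))
  invisible(x)
}

#' One-vs-rest sensitivity and specificity
#'
#' For class c: sensitivity = TP/(TP+FN), specificity = TN/(TN+FP). The
#' overall summaries come in both flavours — macro (unweighted mean over
#' classes with defined values) and micro (pooled counts; micro sensitivity
#' equals overall accuracy for single-label classification). Classes absent
#' from truth (or with no negatives) get NA, never 0.
#'
#' @param cm a [confusion_matrix()].
#' @return list: `per_class` data frame (class, sensitivity, specificity),
#'   `macro` and `micro` named vectors, `accuracy`.
#' @export
sens_spec <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  n <- sum(cm)
  classes <- rownames(cm)
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  tn <- n - tp - fn - fp
  sens <- ifelse(tp + fn > 0, tp / (tp + fn), NA_real_)
  spec <- ifelse(tn + fp > 0, tn / (tn + fp), NA_real_)
  list(
    per_class = data.frame(class = classes, sensitivity = as.numeric(sens),
                           specificity = as.numeric(spec),
                           stringsAsFactors = FALSE, row.names = NULL),
    macro = c(sensitivity = mean(sens, na.rm = TRUE),
              specificity = mean(spec, na.rm = TRUE)),
    micro = c(sensitivity = sum(tp) / sum(tp + fn),
              specificity = sum(tn) / sum(tn + fp)),
    accuracy = sum(tp) / n
  )
}

#' Cohen's kappa with large-sample confidence interval
#'
#' Unweighted kappa = (p_o - p_e) / (1 - p_e); the standard error uses the
#' Fleiss-Cohen-Everitt large-sample formula and the CI is
#' kappa +/- 1.96 * SE, clipped to [-1, 1].
#'
#' @param cm a [confusion_matrix()].
#' @param conf_level confidence level (default 0.95).
#' @return list: `kappa`, `se`, `ci` (length-2), `p_o`, `p_e`, `n`.
#' @export
cohens_kappa <- function(cm, conf_level = 0.95) {
  stopifnot(inherits(cm, "confusion_matrix"))
  n <- sum(cm)
  if (n < 2L) stop("need at least 2 observations")
  p <- unclass(cm) / n
  pr <- rowSums(p)
  pc <- colSums(p)
  p_o <- sum(diag(p))
  p_e <- sum(pr * pc)
  if (1 - p_e < .Machine$double.eps^0.5) {
    stop("degenerate matrix: chance agreement is 1, kappa undefined")
  }
  kappa <- (p_o - p_e) / (1 - p_e)
  # Fleiss, Cohen & Everitt large-sample variance of unweighted kappa
  a <- sum(diag(p) * (1 - (pr + pc) * (1 - kappa))^2)
  off <- p
  diag(off) <- 0
  b <- (1 - kappa)^2 *
    sum(off * outer(seq_along(pr), seq_along(pc),
                    function(i, j) (pc[i] + pr[j])^2))
  cc <- (kappa - p_e * (1 - kappa))^2
  var_k <- (a + b - cc) / (n * (1 - p_e)^2)
  se <- sqrt(max(var_k, 0))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- c(max(-1, kappa - z * se), min(1, kappa + z * se))
  list(kappa = kappa, se = se, ci = ci, p_o = p_o, p_e = p_e, n = n)
}

#' ROC curve and AUC with a seeded stratified bootstrap CI
#'
#' The ROC steps through every distinct score threshold (higher score =
#' more positive); the AUC is the trapezoidal area, which equals the
#' Mann-Whitney pair statistic with ties counted 1/2. The CI is a
#' percentile bootstrap, resampling positives and negatives separately.
#'
#' @param scores numeric scores.
#' @param labels class labels (any two values).
#' @param positive which label is the positive class (default: the larger
#'   of the two sorted unique labels... explicitly passing it is wiser).
#' @param n_boot bootstrap resamples (default 2000; 0 disables the CI).
#' @param conf_level confidence level (default 0.95).
#' @param seed integer seed for the bootstrap; the RNG state is restored
#'   afterwards.
#' @return list: `roc` data frame (threshold, tpr, fpr), `auc`, `ci`,
#'   `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels, positive = NULL, n_boot = 2000L,
                    conf_level = 0.95, seed = 1L) {
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  lv <- sort(unique(as.character(labels)))
  if (is.null(positive)) positive <- lv[length(lv)]
  pos <- as.character(labels) == positive
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L) stop("both classes must be present")

  # step curve over distinct thresholds, descending
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  p <- pos[ord]
  dist <- c(diff(s) != 0, TRUE)  # last index of each tied block
  tp <- cumsum(p)[dist]
  fpn <- cumsum(!p)[dist]
  roc <- data.frame(
    threshold = c(Inf, s[dist]),
    tpr = c(0, tp / n_pos),
    fpr = c(0, fpn / n_neg)
  )
  auc_trap <- function(tpr, fpr) sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  auc <- auc_trap(roc$tpr, roc$fpr)

  ci <- NULL
  if (n_boot > 0L) {
    xs <- scores[pos]
    ys <- scores[!pos]
    # rank formula (equals the trapezoid AUC; cheap enough to bootstrap)
    auc_rank <- function(xp, xn) {
      r <- rank(c(xp, xn))
      (sum(r[seq_along(xp)]) - length(xp) * (length(xp) + 1) / 2) /
        (length(xp) * length(xn))
    }
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
    }, add = TRUE)
    set.seed(seed)
    boots <- vapply(seq_len(n_boot), function(i) {
      auc_rank(sample(xs, n_pos, replace = TRUE),
               sample(ys, n_neg, replace = TRUE))
    }, double(1L))
    alpha <- (1 - conf_level) / 2
    ci <- unname(stats::quantile(boots, c(alpha, 1 - alpha), type = 7))
  }
  list(roc = roc, auc = auc, ci = ci, n_pos = n_pos, n_neg = n_neg,
       positive = positive)
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' Thin wrapper over [stats::cor.test()] exposing r, the CI and the
#' two-sided p value; errors on constant input rather than returning NA.
#'
#' @param x,y numeric vectors, length >= 3.
#' @param conf_level confidence level.
#' @return list: `r`, `ci`, `p`, `n`.
#' @export
pearson_correlation <- function(x, y, conf_level = 0.95) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for constant input")
  }
  ct <- stats::cor.test(x, y, method = "pearson", conf.level = conf_level)
  list(r = unname(ct$estimate), ci = as.numeric(ct$conf.int),
       p = ct$p.value, n = length(x))
}

#' Full metric report for a labelled prediction set
#'
#' @param truth,predicted label vectors.
#' @param classes ordered labels (default [breslow_classes()] intersected
#'   with the observed labels).
#' @return list: `confusion`, `sens_spec`, `kappa`, `accuracy`, `n`.
#' @export
metric_report <- function(truth, predicted, classes = NULL) {
  if (is.null(classes)) {
    observed <- unique(c(truth, predicted))
    classes <- intersect(breslow_classes(), observed)
    if (length(classes) < length(observed)) classes <- sort(observed)
  }
  cm <- confusion_matrix(truth, predicted, classes)
  ss <- sens_spec(cm)
  kappa <- tryCatch(cohens_kappa(cm), error = function(e) NULL)
  list(confusion = cm, sens_spec = ss, kappa = kappa,
       accuracy = ss$accuracy, n = sum(cm))
}
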