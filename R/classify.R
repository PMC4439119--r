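#' Linear discriminant classification of a marker combination
#'
#' Fits Fisher's linear discriminant (via [MASS::lda()]) on the supplied
#' marker values and reports the resubstitution confusion matrix, per-group
#' and overall accuracy, and the per-marker ROC AUC. Priors default to the
#' observed group proportions. A leave-one-out mode is available; note that
#' resubstitution rates are optimistic by construction.
#'
#' @param features numeric matrix, samples in rows, one column per marker
#'   (no missing values)
#' @param groups factor of `control`/`case` per sample
#' @param priors `"proportional"` (default) or `"equal"`
#' @param mode `"resubstitution"` (default) or `"loo"`
#' @return object of class `lda_report`: `confusion` matrix (rows truth),
#'   `accuracy` per group and overall in percent, `auc` per marker, and the
#'   fitted `MASS::lda` object.
#' @export
lda_classify <- function(features, groups,
                         priors = c("proportional", "equal"),
                         mode = c("resubstitution", "loo")) {
  features <- as.matrix(features)
  priors <- match.arg(priors)
  mode <- match.arg(mode)
  if (anyNA(features))
    stop("features contain missing values; substitute them first")
  groups <- factor(groups, levels = c("control", "case"))
  n <- nrow(features)
  if (length(groups) != n) stop("one group label per sample required")
  if (any(table(groups) < 2)) stop("need >= 2 samples per group")
  if (is.null(colnames(features)))
    colnames(features) <- sprintf("m%d", seq_len(ncol(features)))
  ## pooled within-group covariance must be invertible for the discriminant
  ctr <- features
  for (lev in levels(groups))
    ctr[groups == lev, ] <- scale(features[groups == lev, , drop = FALSE],
                                  scale = FALSE)
  S <- crossprod(ctr) / (n - 2)
  if (ncol(S) > 1 && rcond(S) < 1e-10 || any(diag(S) == 0))
    stop("singular pooled covariance; use fewer or less collinear markers")
  pr <- if (priors == "proportional") as.vector(prop.table(table(groups)))
        else c(0.5, 0.5)
  ok <- tryCatch({
    fit <- MASS::lda(features, grouping = groups, prior = pr,
                     CV = (mode == "loo"))
    TRUE
  }, error = function(e) {
    stop("discriminant fit failed (", conditionMessage(e),
         "); likely singular pooled covariance - use fewer or less collinear markers")
  })
  pred <- if (mode == "loo") fit$class
          else stats::predict(fit, features)$class
  conf <- table(truth = groups, predicted = pred)
  per_group <- 100 * diag(conf) / rowSums(conf)
  overall <- 100 * sum(diag(conf)) / n
  auc <- vapply(colnames(features), function(nm)
    roc_auc(features[, nm], groups)$auc, numeric(1))
  structure(list(confusion = conf,
                 accuracy = c(per_group, overall = overall),
                 auc = auc, priors = pr, mode = mode, fit = fit,
                 markers = colnames(features)),
            class = "lda_report")
}

#' @export
print.lda_report <- function(x, ...) {
  cat(sprintf("lda_report (%s): markers %s\n", x$mode,
              paste(x$markers, collapse = ", ")))
  print(x$confusion)
  cat(sprintf("  accuracy: control %.1f%%, case %.1f%%, overall %.1f%%\n",
              x$accuracy[["control"]], x$accuracy[["case"]],
              x$accuracy[["overall"]]))
  cat("  per-marker AUC:",
      paste(sprintf("%s = %.2f", names(x$auc), x$auc), collapse = ", "), "\n")
  invisible(x)
}

#' ROC curve and AUC for a single marker
#'
#' AUC by the concordance (rank-sum) formulation: the fraction of
#' control/case pairs the marker orders correctly, tied pairs counting 0.5.
#' The orientation (whether high values point to the case group) is chosen
#' so that AUC >= 0.5 and reported.
#'
#' @param scores numeric marker values
#' @param groups factor of `control`/`case` per sample
#' @return object of class `roc_result`: `auc`, `orientation` (`+1` when
#'   high scores indicate case), `curve` (FPR/TPR coordinates at every
#'   threshold), and a `degenerate` flag when all scores are tied.
#' @export
roc_auc <- function(scores, groups) {
  groups <- factor(groups, levels = c("control", "case"))
  keep <- !is.na(scores)
  scores <- scores[keep]; groups <- groups[keep]
  n1 <- sum(groups == "control"); n2 <- sum(groups == "case")
  if (n1 < 1 || n2 < 1) stop("need >= 1 sample per group")
  r <- rank(scores)
  ## U statistic of the case group; AUC = U / (n1 n2), ties give 0.5 per pair
  u <- sum(r[groups == "case"]) - n2 * (n2 + 1) / 2
  auc <- u / (n1 * n2)
  orientation <- if (auc >= 0.5) 1L else -1L
  if (orientation < 0) auc <- 1 - auc
  degenerate <- length(unique(scores)) == 1L
  s <- orientation * scores
  thr <- c(-Inf, sort(unique(s)))
  curve <- t(vapply(thr, function(th) {
    pos <- s > th
    c(fpr = sum(pos & groups == "control") / n1,
      tpr = sum(pos & groups == "case") / n2)
  }, numeric(2)))
  structure(list(auc = auc, orientation = orientation,
                 curve = as.data.frame(curve), degenerate = degenerate,
                 n = c(control = n1, case = n2)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result: AUC = %.4f (orientation %+d%s)\n", x$auc,
              x$orientation,
              if (x$degenerate) ", degenerate: all scores tied" else ""))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  plot(x$curve$fpr, x$curve$tpr, type = "s", xlim = 0:1, ylim = 0:1,
       xlab = "false positive rate", ylab = "true positive rate",
       main = sprintf("ROC (AUC = %.2f)", x$auc), ...)
  abline(0, 1, lty = 2, col = "grey")
  invisible(x)
}
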