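#' Detection census and FOC set stratification
#'
#' Counts, per assay, in how many samples of each group it is detected
#' (frequency of occurrence, FOC: Cq present and at or below the cutoff),
#' and stratifies the panel into the abundant set A, the less-abundant set
#' B, excluded assays (detected somewhere but FOC below `min_foc` in at
#' least one group) and assays never detected at all.
#'
#' Set A membership requires FOC of at least `ceiling(set_a_frac * n)` in
#' each group. The default fractions 19/28 and 17/22 reproduce the absolute
#' thresholds 19 (control) and 17 (case) at group sizes 28/22 and scale to
#' other cohorts.
#'
#' @param cohort a [join_metadata()] cohort
#' @param min_foc minimum detected samples per group to keep an assay
#'   (default 3)
#' @param set_a_frac length-2 numeric, fraction of the (control, case) group
#'   that must detect an assay for set A membership
#' @return object of class `marker_census`: data.frame `table` with per-assay
#'   `foc_control`, `foc_case`, `detected_anywhere`, `set` (factor
#'   A/B/excluded/undetected), plus the panel-level `summary` counts
#'   (detected, undetected, percent of panel as the floored percentage).
#' @export
detection_census <- function(cohort, min_foc = 3,
                             set_a_frac = c(19 / 28, 17 / 22)) {
  stopifnot(inherits(cohort, "cq_cohort"))
  g <- .groups(cohort)
  if (any(table(g) == 0L)) stop("empty group")
  det <- is_detected(cohort$cq)
  foc_c <- rowSums(det[, g == "control", drop = FALSE])
  foc_a <- rowSums(det[, g == "case", drop = FALSE])
  n_c <- sum(g == "control"); n_a <- sum(g == "case")
  thr <- c(ceiling(set_a_frac[1] * n_c), ceiling(set_a_frac[2] * n_a))
  anywhere <- foc_c + foc_a > 0
  pass <- foc_c >= min_foc & foc_a >= min_foc
  set <- rep("undetected", nrow(det))
  set[anywhere & !pass] <- "excluded"
  set[pass] <- ifelse(foc_c[pass] >= thr[1] & foc_a[pass] >= thr[2], "A", "B")
  tab <- data.frame(assay = rownames(det), foc_control = foc_c,
                    foc_case = foc_a, detected_anywhere = anywhere,
                    set = factor(set, levels = c("A", "B", "excluded",
                                                 "undetected")),
                    row.names = NULL, stringsAsFactors = FALSE)
  n_det <- sum(anywhere)
  structure(list(
    table = tab,
    thresholds = c(min_foc = min_foc, set_a_control = thr[1],
                   set_a_case = thr[2]),
    summary = c(panel = nrow(det), detected = n_det,
                undetected = nrow(det) - n_det,
                percent_detected = floor(100 * n_det / nrow(det)),
                set_a = sum(set == "A"), set_b = sum(set == "B"),
                excluded = sum(set == "excluded"))),
    class = "marker_census")
}

#' @export
print.marker_census <- function(x, ...) {
  s <- x$summary
  cat(sprintf("marker_census: %d of %d assays detected (at least %d%% of the panel)\n",
              s[["detected"]], s[["panel"]], s[["percent_detected"]]))
  cat(sprintf("  set A (abundant, FOC >= %d/%d): %d\n",
              x$thresholds[["set_a_control"]], x$thresholds[["set_a_case"]],
              s[["set_a"]]))
  cat(sprintf("  set B (less abundant, FOC >= %d each group): %d\n",
              x$thresholds[["min_foc"]], s[["set_b"]]))
  cat(sprintf("  excluded (FOC < %d in a group): %d; never detected: %d\n",
              x$thresholds[["min_foc"]], s[["excluded"]], s[["undetected"]]))
  invisible(x)
}

#' Census summary arithmetic from plain counts
#'
#' Panel-level bookkeeping used in reports: floored percent detected and
#' evaluated-marker totals when protein markers ride along with the
#' FOC-passing miRNAs.
#'
#' @param n_detected,panel detected-assay count and panel size
#' @return floored integer percentage of the panel detected.
#' @export
percent_detected <- function(n_detected, panel) {
  if (panel <= 0) stop("panel size must be positive")
  floor(100 * n_detected / panel)
}
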