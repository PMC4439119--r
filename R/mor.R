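#' Measure of Relevance for a two-group comparison
#'
#' Rank-scale standardized mean difference: both groups are pooled, midranks
#' assigned, and the absolute difference of the group mean ranks is divided
#' by the population standard deviation of the pooled ranks. The statistic
#' is nonnegative, symmetric in group order, invariant under strictly
#' monotone transformations of the values, and reads on the familiar
#' standardized-effect scale (the default critical value 0.57 marks a
#' medium-to-large effect).
#'
#' @param x,y numeric vectors of the two groups' values (at least 2
#'   non-missing each)
#' @return the MoR value (single nonnegative number; 0 when all pooled
#'   values are tied).
#' @export
mor_value <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2)
    stop("need >= 2 non-missing values per group")
  r <- rank(c(x, y))            # midranks for ties
  rx <- r[seq_along(x)]; ry <- r[-seq_along(x)]
  s <- sqrt(mean((r - mean(r))^2))   # population SD of pooled ranks
  if (s == 0) return(0)
  abs(mean(rx) - mean(ry)) / s
}

## MoR for every row of a variables x samples matrix, NA-tolerant;
## returns NA for rows with < 2 detected values in either group
.mor_rows <- function(mat, ctrl, case) {
  vapply(seq_len(nrow(mat)), function(i) {
    x <- mat[i, ctrl]; y <- mat[i, case]
    if (sum(!is.na(x)) < 2 || sum(!is.na(y)) < 2) return(NA_real_)
    mor_value(x, y)
  }, numeric(1))
}

#' Explorative MoR screen (information chain)
#'
#' Computes the Measure of Relevance for every variable, sorts the values in
#' ascending order (the information chain) and declares every variable whose
#' MoR exceeds the critical value `d` *informative*. Ties are broken by
#' variable name so the chain is deterministic.
#'
#' @param data numeric matrix, variables in rows, samples in columns (NA
#'   allowed; a variable needs >= 2 detected values per group)
#' @param groups factor of `control`/`case` per sample
#' @param d critical MoR value (default 0.57, a medium-to-large effect)
#' @param statistic two-sample statistic to use in place of [mor_value()]
#'   (same signature); the screen contract only assumes nonnegativity
#' @return object of class `mor_screen`: data.frame `table` ascending along
#'   the chain with `mor`, `chain_position`, `informative`, per-group n
#'   used; `d`; count of informative variables.
#' @export
mor_screen <- function(data, groups, d = 0.57, statistic = mor_value) {
  if (!is.matrix(data)) data <- as.matrix(data)
  if (is.null(rownames(data)))
    rownames(data) <- sprintf("v%03d", seq_len(nrow(data)))
  groups <- as.factor(groups)
  if (length(groups) != ncol(data)) stop("one group label per sample required")
  if (!is.numeric(d) || d <= 0) stop("critical value d must be > 0")
  ctrl <- groups == "control"; case <- groups == "case"
  mor <- if (identical(statistic, mor_value)) .mor_rows(data, ctrl, case)
  else vapply(seq_len(nrow(data)), function(i)
    statistic(data[i, ctrl], data[i, case]), numeric(1))
  tab <- data.frame(variable = rownames(data), mor = mor,
                    n_control = rowSums(!is.na(data[, ctrl, drop = FALSE])),
                    n_case = rowSums(!is.na(data[, case, drop = FALSE])),
                    stringsAsFactors = FALSE)
  ord <- order(tab$mor, tab$variable, na.last = FALSE)
  tab <- tab[ord, , drop = FALSE]
  tab$chain_position <- seq_len(nrow(tab))
  tab$informative <- !is.na(tab$mor) & tab$mor > d
  rownames(tab) <- NULL
  structure(list(table = tab, d = d,
                 n_informative = sum(tab$informative)),
            class = "mor_screen")
}

#' @export
print.mor_screen <- function(x, ...) {
  cat(sprintf("mor_screen: %d variables, critical value d = %g\n",
              nrow(x$table), x$d))
  cat(sprintf("  informative: %d\n", x$n_informative))
  if (x$n_informative) {
    inf <- x$table[x$table$informative, c("variable", "mor")]
    inf <- inf[order(-inf$mor), ]
    cat(paste(sprintf("    %-18s MoR = %.3f", inf$variable, inf$mor),
              collapse = "\n"), "\n")
  }
  invisible(x)
}

#' @export
summary.mor_screen <- function(object, ...) {
  cat(sprintf("Information chain over %d variables (d = %g)\n",
              nrow(object$table), object$d))
  print(utils::tail(object$table, 12), row.names = FALSE)
  invisible(object$table)
}

#' @export
plot.mor_screen <- function(x, ...) {
  tab <- x$table
  plot(tab$chain_position, tab$mor, pch = 16,
       col = ifelse(tab$informative, "firebrick", "grey40"),
       xlab = "information chain position (ascending MoR)",
       ylab = "Measure of Relevance", ...)
  abline(h = x$d, col = "red")
  invisible(x)
}

#' Subsampling reliability analysis of the MoR screen
#'
#' Repeats the MoR screen on `B` random subsamples (drawn without
#' replacement, `m` samples per group) at the fixed critical value `d`. The
#' relative frequency RF of a variable is the fraction of repeats in which
#' it came out informative; variables with RF at or above `rf_threshold`
#' are *reliable*. Each repeat's subsample is drawn from an RNG stream keyed
#' on `(seed, repeat index)`, so repeats are independent and the whole
#' analysis reproduces exactly under the seed.
#'
#' With `substitution = "none"` a variable enters a repeat only through its
#' detected values and is counted non-informative in repeats where either
#' subsampled group retains fewer than 2 of them; `"group_mean"` first
#' imputes missing cells with the full-cohort group mean.
#'
#' @inheritParams mor_screen
#' @param B number of subsample repeats (default 800)
#' @param m per-group subsample size (default 15; must not exceed either
#'   group)
#' @param rf_threshold reliability cutoff on RF (default 0.8, inclusive)
#' @param substitution `"none"` or `"group_mean"`
#' @param seed integer seed for the subsample streams
#' @return object of class `mor_reliability`: data.frame `table` with
#'   per-variable `rf`, `n_informative`, `n_evaluable`, `reliable`;
#'   the parameters; the full-data [mor_screen()] under `full_screen`.
#' @export
mor_reliability <- function(data, groups, B = 800, m = 15, d = 0.57,
                            rf_threshold = 0.8,
                            substitution = c("none", "group_mean"),
                            seed = 1L) {
  if (!is.matrix(data)) data <- as.matrix(data)
  if (is.null(rownames(data)))
    rownames(data) <- sprintf("v%03d", seq_len(nrow(data)))
  substitution <- match.arg(substitution)
  groups <- as.factor(groups)
  if (length(groups) != ncol(data)) stop("one group label per sample required")
  if (B <= 0) stop("B must be positive")
  idx_c <- which(groups == "control"); idx_a <- which(groups == "case")
  if (m > length(idx_c) || m > length(idx_a))
    stop(sprintf("m = %d exceeds a group size (%d control, %d case)",
                 m, length(idx_c), length(idx_a)))
  work <- data
  if (substitution == "group_mean") {
    em <- substitute_missing(expr_matrix(data), groups)
    work <- em$values
  }
  n_inf <- n_eval <- stats::setNames(integer(nrow(work)), rownames(work))
  seed <- as.integer(seed)
  for (b in seq_len(B)) {
    ## counter-based stream: repeat b is reproducible in isolation
    set.seed((seed * 10007L + b) %% .Machine$integer.max)
    sc <- sample(idx_c, m); sa <- sample(idx_a, m)
    sub <- work[, c(sc, sa), drop = FALSE]
    ctrl <- rep(c(TRUE, FALSE), each = m)
    mor <- .mor_rows(sub, ctrl, !ctrl)
    ok <- !is.na(mor)
    n_eval[ok] <- n_eval[ok] + 1L
    n_inf[ok & mor > d] <- n_inf[ok & mor > d] + 1L
  }
  rf <- n_inf / B
  tab <- data.frame(variable = rownames(work), rf = rf,
                    n_informative = n_inf, n_evaluable = n_eval,
                    reliable = rf >= rf_threshold,
                    row.names = NULL, stringsAsFactors = FALSE)
  tab <- tab[order(-tab$rf, tab$variable), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(table = tab, B = B, m = m, d = d,
                 rf_threshold = rf_threshold, substitution = substitution,
                 seed = seed,
                 full_screen = mor_screen(data, groups, d = d)),
            class = "mor_reliability")
}

#' @export
print.mor_reliability <- function(x, ...) {
  cat(sprintf(
    "mor_reliability: B = %d subsamples of %d per group (d = %g, substitution = %s)\n",
    x$B, x$m, x$d, x$substitution))
  rel <- x$table[x$table$reliable, , drop = FALSE]
  cat(sprintf("  reliable (RF >= %g): %d\n", x$rf_threshold, nrow(rel)))
  if (nrow(rel))
    cat(paste(sprintf("    %-18s RF = %.3f", rel$variable, rel$rf),
              collapse = "\n"), "\n")
  invisible(x)
}

#' @export
plot.mor_reliability <- function(x, ...) {
  tab <- x$table[order(x$table$rf), ]
  plot(seq_len(nrow(tab)), tab$rf, pch = 16, ylim = c(0, 1),
       col = ifelse(tab$reliable, "firebrick", "grey40"),
       xlab = "variables (ascending RF)", ylab = "relative frequency informative",
       ...)
  abline(h = x$rf_threshold, col = "red")
  invisible(x)
}

#' Assemble the marker table for a screening stage
#'
#' Pulls the delta-Cq rows of one census stratum and optionally appends the
#' CSF protein markers (tau, p-tau, amyloid-beta 1-42) from the metadata on
#' their native pg/ml scale — the MoR screen is rank-based, so the scale
#' mix is immaterial.
#'
#' @param cohort a [join_metadata()] cohort
#' @param expr an [expr_matrix()] over the same samples
#' @param census a [detection_census()]
#' @param sets which census strata to include (default `"A"`)
#' @param proteins append protein markers (default `TRUE`)
#' @return numeric matrix, variables x samples.
#' @export
marker_table <- function(cohort, expr, census, sets = "A", proteins = TRUE) {
  stopifnot(inherits(cohort, "cq_cohort"), inherits(expr, "expr_matrix"),
            inherits(census, "marker_census"))
  keep <- census$table$assay[census$table$set %in% sets]
  mat <- expr$values[keep, , drop = FALSE]
  if (proteins) {
    pr <- intersect(c("tau", "p_tau", "abeta42"), names(cohort$meta))
    if (length(pr)) {
      pm <- t(as.matrix(cohort$meta[, pr, drop = FALSE]))
      colnames(pm) <- colnames(mat)
      mat <- rbind(mat, pm)
    }
  }
  mat
}
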