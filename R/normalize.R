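#' Rank candidate reference assays by expression stability
#'
#' Scores every assay detected in all samples by a stability value that
#' combines the estimated between-group bias with the average within-group
#' variance of its Cq values (a two-way bias/variance decomposition in the
#' NormFinder tradition): `stability = sqrt(bias^2 + mean within-group
#' variance)`. Lower is more stable; a candidate that is constant across the
#' cohort scores exactly 0. Ties are broken by assay id.
#'
#' @param cohort a [join_metadata()] cohort
#' @param n_refs how many top-ranked candidates to flag for the normalizer
#'   set (default 6)
#' @return data.frame of all candidates, ascending by `stability`, with
#'   `bias` (cycles), `within_var` (cycles squared) and `selected` flag.
#' @export
select_references <- function(cohort, n_refs = 6) {
  stopifnot(inherits(cohort, "cq_cohort"))
  det <- is_detected(cohort$cq)
  cand <- rownames(det)[rowSums(det) == ncol(det)]
  if (!length(cand))
    stop("no assay is detected in every sample; supply a reference list manually")
  g <- .groups(cohort)
  v <- cohort$cq$values[cand, , drop = FALSE]
  m_c <- rowMeans(v[, g == "control", drop = FALSE])
  m_a <- rowMeans(v[, g == "case", drop = FALSE])
  var_c <- apply(v[, g == "control", drop = FALSE], 1, stats::var)
  var_a <- apply(v[, g == "case", drop = FALSE], 1, stats::var)
  bias <- abs(m_a - m_c)
  stab <- sqrt(bias^2 + (var_c + var_a) / 2)
  out <- data.frame(assay = cand, stability = stab, bias = bias,
                    within_var = (var_c + var_a) / 2,
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(out$stability, out$assay), , drop = FALSE]
  rownames(out) <- NULL
  out$selected <- seq_len(nrow(out)) <= min(n_refs, nrow(out))
  out
}

#' Expression matrix on the delta-Cq scale
#'
#' @param values numeric matrix of delta-Cq values (assays x samples), NA
#'   where undetected
#' @param references character vector of normalizer assay ids
#' @param scale one of `"delta_cq"`, `"rel_linear"` (`2^-dCq`) or
#'   `"rel_log2"` (`-dCq`)
#' @return object of class `expr_matrix`
#' @export
expr_matrix <- function(values, references = character(),
                        scale = c("delta_cq", "rel_linear", "rel_log2")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  structure(list(values = values, references = references, scale = scale),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix (%s): %d assays x %d samples, %d missing cells\n",
              x$scale, nrow(x$values), ncol(x$values), sum(is.na(x$values))))
  if (length(x$references))
    cat("  normalizers:", paste(x$references, collapse = ", "), "\n")
  invisible(x)
}

#' Normalize Cq values against a reference-assay set
#'
#' Subtracts, per sample, the arithmetic mean Cq of the reference assays
#' from every assay's Cq, yielding delta-Cq values. Missing wells stay
#' missing.
#'
#' @param cq a [cq_matrix()]
#' @param references character vector of reference assay ids present in `cq`
#' @param mode `"strict"` (default) errors when any reference is undetected
#'   in any sample; `"lenient"` averages the detected references per sample
#'   and warns.
#' @return an [expr_matrix()] on the `delta_cq` scale.
#' @export
normalize_cq <- function(cq, references, mode = c("strict", "lenient")) {
  stopifnot(inherits(cq, "cq_matrix"))
  mode <- match.arg(mode)
  if (!length(references)) stop("need at least one reference assay")
  miss <- setdiff(references, rownames(cq$values))
  if (length(miss)) stop("reference assay(s) not on the panel: ",
                         paste(miss, collapse = ", "))
  det <- is_detected(cq)[references, , drop = FALSE]
  rv <- cq$values[references, , drop = FALSE]
  rv[!det] <- NA_real_
  if (any(!det)) {
    bad <- colnames(rv)[colSums(!det) > 0]
    if (mode == "strict")
      stop("reference assay undetected in sample(s): ",
           paste(bad, collapse = ", "), " (use mode = \"lenient\")")
    if (any(colSums(det) == 0))
      stop("no reference detected at all in sample(s): ",
           paste(colnames(rv)[colSums(det) == 0], collapse = ", "))
    warning("averaging only detected references in sample(s): ",
            paste(bad, collapse = ", "))
  }
  ref_mean <- colMeans(rv, na.rm = TRUE)
  d <- sweep(cq$values, 2, ref_mean, "-")
  expr_matrix(d, references = references, scale = "delta_cq")
}

#' Convert an expression matrix between presentation scales
#'
#' `rel_linear` is `2^(-dCq)` (relative expression), `rel_log2` its log2,
#' i.e. `-dCq`.
#'
#' @param expr an [expr_matrix()]
#' @param scale target scale
#' @return an [expr_matrix()] on the requested scale.
#' @export
expr_rescale <- function(expr, scale = c("delta_cq", "rel_linear", "rel_log2")) {
  stopifnot(inherits(expr, "expr_matrix"))
  scale <- match.arg(scale)
  d <- switch(expr$scale,
              delta_cq = expr$values,
              rel_log2 = -expr$values,
              rel_linear = -log2(expr$values))
  v <- switch(scale,
              delta_cq = d,
              rel_log2 = -d,
              rel_linear = 2^(-d))
  expr_matrix(v, references = expr$references, scale = scale)
}

#' Replace missing expression values by the group mean
#'
#' Each missing cell is filled with the mean of the detected delta-Cq values
#' of the same assay within the sample's own group, leaving group means
#' unchanged.
#'
#' @param expr an [expr_matrix()] on the delta-Cq scale
#' @param groups factor of `control`/`case` per sample
#' @return the imputed [expr_matrix()]; the number of substitutions is
#'   attached as attribute `n_substituted`.
#' @export
substitute_missing <- function(expr, groups) {
  stopifnot(inherits(expr, "expr_matrix"))
  v <- expr$values
  groups <- as.factor(groups)
  if (length(groups) != ncol(v)) stop("one group label per sample required")
  n_sub <- 0L
  for (lev in levels(groups)) {
    sel <- groups == lev
    sub <- v[, sel, drop = FALSE]
    miss <- is.na(sub)
    if (!any(miss)) next
    gm <- rowMeans(sub, na.rm = TRUE)
    bad <- rowSums(!miss) == 0 & rowSums(miss) > 0
    if (any(bad))
      stop("no detected value to substitute from in group '", lev,
           "' for assay(s): ",
           paste(rownames(v)[bad], collapse = ", "))
    sub[miss] <- gm[row(sub)[miss]]
    v[, sel] <- sub
    n_sub <- n_sub + sum(miss)
  }
  out <- expr_matrix(v, references = expr$references, scale = expr$scale)
  attr(out, "n_substituted") <- n_sub
  out
}
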