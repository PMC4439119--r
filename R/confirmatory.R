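## residual cross-product matrix of Y on design X (QR, base R)
.resid_crossprod <- function(Y, X) {
  fit <- stats::lm.fit(X, Y)
  R <- as.matrix(fit$residuals)
  crossprod(R)
}

## Rao's F approximation for Wilks' lambda with p responses, h hypothesis
## df and df_e error df; exact for min(p, h) <= 2 (so always exact for the
## single-df group contrast)
.wilks_f <- function(lambda, p, h, df_e) {
  t_ <- df_e - (p - h + 1) / 2
  denom <- p^2 + h^2 - 5
  s <- if (denom > 0) sqrt((p^2 * h^2 - 4) / denom) else 1
  df1 <- p * h
  df2 <- t_ * s - (p * h) / 2 + 1
  ls <- lambda^(1 / s)
  f <- (1 - ls) / ls * df2 / df1
  c(f = f, df1 = df1, df2 = df2,
    p = stats::pf(f, df1, df2, lower.tail = FALSE))
}

#' Multivariate analysis of covariance for a marker family
#'
#' Fits the multivariate linear model `responses ~ group + covariates` and
#' tests the group effect by Wilks' lambda, `det(E) / det(E + H)`, with `E`
#' and `H` the residual and hypothesis cross-product matrices. The group
#' contrast is a single degree of freedom, so the F transform
#' `F = ((1 - L)/L) * (n - q - p + 1)/p` on `(p, n - q - p + 1)` degrees of
#' freedom is exact (`q` = number of model terms including the intercept).
#' Per-response univariate F tests on `(1, n - q)` df follow, with
#' Bonferroni-adjusted decisions at family level `alpha`. The covariates
#' are tested jointly by the same lambda machinery (Rao's F).
#'
#' Covariate coding: sex enters as a 0/1 indicator, age centered, group as a
#' single 0/1 contrast.
#'
#' @param responses numeric matrix, samples in rows, one column per marker
#'   (no missing values; impute upstream with [substitute_missing()])
#' @param groups factor of `control`/`case` per sample
#' @param covariates data.frame of per-sample covariates (default columns
#'   `age` and `sex`); `NULL` for a MANOVA without covariates
#' @param alpha family-wise significance level (default 0.05)
#' @param family_size Bonferroni family size; defaults to the number of
#'   responses
#' @return object of class `mancova`.
#' @export
mancova <- function(responses, groups, covariates = NULL, alpha = 0.05,
                    family_size = NULL) {
  responses <- as.matrix(responses)
  if (anyNA(responses))
    stop("responses contain missing values; substitute them first")
  n <- nrow(responses); p <- ncol(responses)
  if (is.null(colnames(responses)))
    colnames(responses) <- sprintf("y%d", seq_len(p))
  groups <- as.factor(groups)
  if (length(groups) != n) stop("one group label per sample required")
  g <- as.integer(groups == "case")

  Xc <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    for (nm in names(covariates)) {
      v <- covariates[[nm]]
      if (is.character(v) || is.factor(v)) {
        v <- as.factor(v)
        if (nlevels(v) != 2) stop("factor covariate '", nm, "' must have 2 levels")
        v <- as.integer(v) - 1L            # 0/1 indicator
      } else {
        v <- v - mean(v)                   # centered metric covariate
      }
      Xc <- cbind(Xc, stats::setNames(data.frame(v), nm))
      Xc <- as.matrix(Xc)
    }
  }
  X_full <- cbind(Xc, group = g)
  q <- ncol(X_full)
  if (n <= q + p - 1)
    stop(sprintf("design too small: need n > q + p - 1 (n = %d, q = %d, p = %d)",
                 n, q, p))

  E <- .resid_crossprod(responses, X_full)
  E_nogroup <- .resid_crossprod(responses, Xc)
  H <- E_nogroup - E
  dE <- det(E); dEH <- det(E + H)
  if (dE <= 0 || dEH <= 0 || rcond(E) < 1e-10)
    stop("singular residual cross-product; use fewer or less collinear responses")
  lambda <- dE / dEH
  df_e <- n - q
  mv <- c(f = (1 - lambda) / lambda * (df_e - p + 1) / p,
          df1 = p, df2 = df_e - p + 1)
  mv <- c(mv, p = stats::pf(mv[["f"]], mv[["df1"]], mv[["df2"]],
                            lower.tail = FALSE))

  ## univariate group tests, (1, n - q) df
  rss_full <- diag(E); rss_red <- diag(E_nogroup)
  f_uni <- (rss_red - rss_full) / (rss_full / df_e)
  p_uni <- stats::pf(f_uni, 1, df_e, lower.tail = FALSE)
  adj <- bonferroni(p_uni, m = if (is.null(family_size)) p else family_size,
                    alpha = alpha)
  uni <- data.frame(response = colnames(responses), f = f_uni, df1 = 1,
                    df2 = df_e, p = p_uni, p_adj = adj$p_adj,
                    significant = adj$reject,
                    row.names = NULL, stringsAsFactors = FALSE)

  ## joint covariate test (adjusted for group), when covariates present
  cov_test <- NULL
  if (!is.null(covariates) && ncol(Xc) > 1) {
    X_nocov <- cbind(X_full[, "(Intercept)", drop = FALSE],
                     group = g)
    E_nocov <- .resid_crossprod(responses, X_nocov)
    H_cov <- E_nocov - E
    lam_cov <- det(E) / det(E + H_cov)
    cov_test <- c(lambda = lam_cov,
                  .wilks_f(lam_cov, p, ncol(Xc) - 1, df_e))
  }

  structure(list(lambda = lambda, mv = mv, univariate = uni,
                 covariate_test = cov_test, alpha = alpha,
                 family_size = if (is.null(family_size)) p else family_size,
                 n = n, p = p, q = q, E = E, H = H),
            class = "mancova")
}

#' @export
print.mancova <- function(x, ...) {
  cat(sprintf("MANCOVA: %d samples, %d responses, %d model terms\n",
              x$n, x$p, x$q))
  cat(sprintf("  group effect: Wilks lambda = %.4f, F(%d, %d) = %.2f, p = %.3g\n",
              x$lambda, x$mv[["df1"]], x$mv[["df2"]], x$mv[["f"]],
              x$mv[["p"]]))
  if (!is.null(x$covariate_test))
    cat(sprintf("  covariates:   Wilks lambda = %.4f, F(%g, %g) = %.2f, p = %.3g\n",
                x$covariate_test[["lambda"]], x$covariate_test[["df1"]],
                x$covariate_test[["df2"]], x$covariate_test[["f"]],
                x$covariate_test[["p"]]))
  cat(sprintf("  univariate tests on (1, %d) df, Bonferroni family m = %d:\n",
              x$mv[["df2"]] + x$p - 1, x$family_size))
  u <- x$univariate
  cat(paste(sprintf("    %-18s F = %6.2f  p = %.4f  adj = %.4f%s",
                    u$response, u$f, u$p, u$p_adj,
                    ifelse(u$significant, " *", "")), collapse = "\n"), "\n")
  invisible(x)
}

#' @export
summary.mancova <- function(object, ...) {
  print(object)
  invisible(object$univariate)
}

#' Bonferroni correction
#'
#' @param p_values raw p-values
#' @param m family size (defaults to `length(p_values)`)
#' @param alpha family-wise level
#' @return list with `reject` (p < alpha/m), `p_adj` (`min(1, m * p)`) and
#'   the per-test `threshold`.
#' @export
bonferroni <- function(p_values, m = length(p_values), alpha = 0.05) {
  if (m < 1) stop("family size m must be >= 1")
  list(reject = p_values < alpha / m,
       p_adj = pmin(1, m * p_values),
       threshold = alpha / m)
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' Two-sided p from `t = r sqrt(n-2)/sqrt(1-r^2)`; CI endpoints
#' `tanh(atanh(r) +/- z/sqrt(n-3))`. An optional Cq inclusion cutoff drops
#' pairs whose raw Cq exceeds it before correlating (used when a marker's
#' faint wells should not enter a correlation analysis).
#'
#' @param x,y paired numeric vectors
#' @param ci_level confidence level (default 0.95)
#' @param cq optional raw Cq values parallel to `x`
#' @param cq_cutoff optional inclusion cutoff applied to `cq`
#' @return object of class `cor_result` with `r`, `n`, `p`, `ci`, `r2`
#'   (fraction) and `r2_percent` (integer-rounded percent of variance
#'   explained).
#' @export
pearson_cor <- function(x, y, ci_level = 0.95, cq = NULL, cq_cutoff = NULL) {
  keep <- !is.na(x) & !is.na(y)
  if (!is.null(cq_cutoff)) {
    if (is.null(cq)) stop("cq values required to apply a Cq inclusion cutoff")
    keep <- keep & !is.na(cq) & cq <= cq_cutoff
  }
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4) stop("need >= 4 paired observations (have ", n, ")")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  r <- stats::cor(x, y)
  tstat <- r * sqrt(n - 2) / sqrt(1 - r^2)
  p <- 2 * stats::pt(-abs(tstat), n - 2)
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  ci <- tanh(atanh(r) + c(-1, 1) * z / sqrt(n - 3))
  structure(list(r = r, n = n, p = p, ci = ci, ci_level = ci_level,
                 r2 = r^2, r2_percent = round(100 * r^2),
                 cq_cutoff = cq_cutoff),
            class = "cor_result")
}

#' @export
print.cor_result <- function(x, ...) {
  cat(sprintf("r = %.4f (n = %d), %g%% CI [%.4f, %.4f], p = %.4g\n",
              x$r, x$n, 100 * x$ci_level, x$ci[1], x$ci[2], x$p))
  cat(sprintf("  r^2 = %.4f (%d%% of variance explained)\n", x$r2,
              x$r2_percent))
  invisible(x)
}

#' Two-sample t-test from group summary statistics
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 per-group mean, SD and size
#' @param var_equal pooled variance (default) or Welch
#' @return list with `t`, `df`, `p`.
#' @export
t_test_summary <- function(mean1, sd1, n1, mean2, sd2, n2, var_equal = TRUE) {
  if (n1 < 2 || n2 < 2) stop("need >= 2 observations per group")
  if (var_equal) {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  tstat <- (mean1 - mean2) / se
  list(t = tstat, df = df, p = 2 * stats::pt(-abs(tstat), df))
}

#' Group comparisons of the demographic table
#'
#' Two-sided t-tests (pooled variance by default, Welch by flag) for every
#' numeric metadata column and a Pearson chi-squared test (no continuity
#' correction) for the sex split.
#'
#' @param meta a [cohort_metadata()]
#' @param var_equal pooled (default) vs Welch t
#' @return data.frame with one row per variable: group means/SDs, statistic,
#'   p-value.
#' @export
demographics_tests <- function(meta, var_equal = TRUE) {
  if (!inherits(meta, "cohort_metadata")) meta <- cohort_metadata(meta)
  g <- meta$group
  if (any(table(g) < 2)) stop("need >= 2 samples per group for the t-tests")
  num_cols <- setdiff(names(meta)[vapply(meta, is.numeric, logical(1))],
                      "sample_id")
  rows <- lapply(num_cols, function(nm) {
    x <- meta[[nm]][g == "control"]; y <- meta[[nm]][g == "case"]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    tt <- t_test_summary(mean(x), stats::sd(x), length(x),
                         mean(y), stats::sd(y), length(y),
                         var_equal = var_equal)
    data.frame(variable = nm, test = "t",
               control = sprintf("%.1f +/- %.1f", mean(x), stats::sd(x)),
               case = sprintf("%.1f +/- %.1f", mean(y), stats::sd(y)),
               statistic = tt$t, p = tt$p, stringsAsFactors = FALSE)
  })
  sex_tab <- table(meta$sex, g)
  chi <- suppressWarnings(stats::chisq.test(sex_tab, correct = FALSE))
  rows <- c(rows, list(data.frame(
    variable = "sex", test = "chisq",
    control = paste(sex_tab[, "control"], collapse = "/"),
    case = paste(sex_tab[, "case"], collapse = "/"),
    statistic = unname(chi$statistic), p = chi$p.value,
    stringsAsFactors = FALSE)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
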