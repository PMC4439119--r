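#' Fold changes and volcano summary from delta-Cq values
#'
#' Relative quantification by the delta-delta-Cq method: per assay,
#' `ddCq = mean dCq(case) - mean dCq(control)` over detected values and
#' `FC = 2^(-ddCq)` (case relative to control; FC below 1 means
#' down-regulated). Significance is a two-sided two-sample t-test on the
#' delta-Cq values (pooled variance by default).
#'
#' @param expr an [expr_matrix()] on the delta-Cq scale
#' @param groups factor of `control`/`case` per sample
#' @param threshold fold-change call threshold (default 1.5): `up` when
#'   `FC >= threshold`, `down` when `FC <= 1/threshold`, else `flat`
#' @param var_equal pooled-variance t-test (default `TRUE`); `FALSE` for
#'   Welch
#' @return object of class `fold_change_table`: data.frame with `log2_fc`
#'   (`-ddCq`), `fc`, `p`, `call`, per-group n used; `summary` holds the
#'   volcano counts.
#' @export
fold_changes <- function(expr, groups, threshold = 1.5, var_equal = TRUE) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (threshold < 1) stop("threshold must be >= 1")
  groups <- as.factor(groups)
  v <- expr$values
  if (length(groups) != ncol(v)) stop("one group label per sample required")
  ctrl <- groups == "control"; case <- groups == "case"
  res <- lapply(seq_len(nrow(v)), function(i) {
    x <- v[i, ctrl]; y <- v[i, case]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 1 || length(y) < 1)
      return(data.frame(ddcq = NA_real_, p = NA_real_,
                        n_control = length(x), n_case = length(y)))
    ddcq <- mean(y) - mean(x)
    p <- if (length(x) < 2 || length(y) < 2) NA_real_
    else if (stats::var(x) == 0 && stats::var(y) == 0) {
      if (mean(x) == mean(y)) 1 else 0
    } else {
      stats::t.test(x, y, var.equal = var_equal)$p.value
    }
    data.frame(ddcq = ddcq, p = p, n_control = length(x), n_case = length(y))
  })
  res <- do.call(rbind, res)
  fc <- 2^(-res$ddcq)
  call <- rep("flat", nrow(res))
  call[!is.na(fc) & fc >= threshold] <- "up"
  call[!is.na(fc) & fc <= 1 / threshold] <- "down"
  tab <- data.frame(assay = rownames(v), log2_fc = -res$ddcq, fc = fc,
                    p = res$p, call = factor(call, c("down", "flat", "up")),
                    n_control = res$n_control, n_case = res$n_case,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(table = tab, threshold = threshold,
                 summary = c(up = sum(call == "up"),
                             down = sum(call == "down"),
                             flat = sum(call == "flat"))),
            class = "fold_change_table")
}

#' @export
print.fold_change_table <- function(x, ...) {
  s <- x$summary
  cat(sprintf("fold_change_table: %d assays at FC threshold %g\n",
              nrow(x$table), x$threshold))
  cat(sprintf("  up-regulated: %d, down-regulated: %d, flat: %d\n",
              s[["up"]], s[["down"]], s[["flat"]]))
  invisible(x)
}

#' Volcano-plot coordinates
#'
#' @param x a [fold_changes()] table
#' @param ... unused
#' @return data.frame of `log2_fc` vs `-log10(p)` with the regulation call.
#' @export
volcano_coords <- function(x, ...) {
  stopifnot(inherits(x, "fold_change_table"))
  data.frame(assay = x$table$assay, log2_fc = x$table$log2_fc,
             neg_log10_p = -log10(x$table$p), call = x$table$call,
             stringsAsFactors = FALSE)
}

#' @export
plot.fold_change_table <- function(x, ...) {
  co <- volcano_coords(x)
  col <- c(down = "steelblue", flat = "grey60", up = "firebrick")[as.character(co$call)]
  plot(co$log2_fc, co$neg_log10_p, col = col, pch = 16,
       xlab = "log2 fold change (case vs control)",
       ylab = "-log10 p", main = "Volcano", ...)
  abline(v = c(-1, 1) * log2(x$threshold), lty = 2)
  abline(h = -log10(0.05), lty = 3)
  invisible(x)
}
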