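#' Pipeline run configuration
#'
#' Collects every tunable of the end-to-end analysis with the panel's
#' conventional defaults: Cq cutoff 34, minimum FOC 3, set-A thresholds
#' 19/28 and 17/22, fold-change threshold 1.5, critical MoR value 0.57,
#' 800 subsamples of 15 per group, RF threshold 0.8, alpha 0.05. The full
#' configuration is serialized into the run report so a run can be
#' reproduced from the report alone.
#'
#' @param cq_path,meta_path input table paths (ignored when `sim` data are
#'   passed to [run_pipeline()] directly)
#' @param out_dir where stage TSVs and the report are written; `NULL`
#'   disables file output
#' @param cutoff Cq positivity threshold (cycles)
#' @param min_foc minimum per-group FOC
#' @param set_a_frac set-A FOC fractions (control, case)
#' @param references explicit normalizer assay ids, or `NULL` to select
#'   `n_refs` by stability
#' @param n_refs normalizer count when selecting by stability
#' @param fc_threshold fold-change call threshold
#' @param d critical MoR value
#' @param B,m,rf_threshold,substitution reliability parameters
#' @param alpha family-wise level for the confirmatory stage
#' @param classify_markers marker ids for the discriminant stage; `NULL`
#'   uses the reliable + informative markers (at most 5, best RF/MoR first)
#' @param correlate optional data.frame (`marker`, `protein`, optional
#'   `group`, `cq_cutoff`) of correlation analyses to run
#' @param seed master seed for every random stage
#' @return a `run_config` list.
#' @export
run_config <- function(cq_path = NULL, meta_path = NULL, out_dir = NULL,
                       cutoff = 34, min_foc = 3,
                       set_a_frac = c(19 / 28, 17 / 22),
                       references = NULL, n_refs = 6, fc_threshold = 1.5,
                       d = 0.57, B = 800, m = 15, rf_threshold = 0.8,
                       substitution = "group_mean", alpha = 0.05,
                       classify_markers = NULL, correlate = NULL,
                       seed = 1L) {
  structure(list(cq_path = cq_path, meta_path = meta_path, out_dir = out_dir,
                 cutoff = cutoff, min_foc = min_foc, set_a_frac = set_a_frac,
                 references = references, n_refs = n_refs,
                 fc_threshold = fc_threshold, d = d, B = B, m = m,
                 rf_threshold = rf_threshold, substitution = substitution,
                 alpha = alpha, classify_markers = classify_markers,
                 correlate = correlate, seed = as.integer(seed)),
            class = "run_config")
}

.write_stage <- function(df, out_dir, name) {
  if (is.null(out_dir)) return(invisible(NULL))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  utils::write.table(df, file.path(out_dir, paste0(name, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full screening pipeline
#'
#' Stage order: detection census, reference selection, normalization, fold
#' changes, MoR screen of the less-abundant stratum (set B), subsampling
#' reliability of the abundant stratum (set A plus protein markers),
#' group-mean substitution, confirmatory MANCOVA per marker family,
#' discriminant classification, and any configured correlation analyses.
#' When no marker comes out informative or reliable the confirmatory and
#' classification stages are skipped with a notice in the report.
#'
#' @param config a [run_config()]
#' @param cohort optionally, an in-memory [join_metadata()] cohort (takes
#'   precedence over the configured input paths)
#' @return object of class `run_report`: per-stage results, per-stage log
#'   counts, and the serialized configuration.
#' @export
run_pipeline <- function(config, cohort = NULL) {
  stopifnot(inherits(config, "run_config"))
  log <- list()
  if (is.null(cohort)) {
    if (is.null(config$cq_path) || is.null(config$meta_path))
      stop("no cohort given and no input paths configured")
    if (!file.exists(config$cq_path)) stop("missing input: ", config$cq_path)
    if (!file.exists(config$meta_path)) stop("missing input: ", config$meta_path)
    cq <- read_cq_table(config$cq_path, cutoff = config$cutoff)
    meta <- read_metadata(config$meta_path)
    cohort <- join_metadata(cq, meta)
  }
  g <- .groups(cohort)
  log$samples <- as.list(table(g))
  log$wells <- length(cohort$cq$values)
  log$missing_wells <- sum(is.na(cohort$cq$values))

  ## census
  census <- detection_census(cohort, min_foc = config$min_foc,
                             set_a_frac = config$set_a_frac)
  .write_stage(census$table, config$out_dir, "census")
  log$census <- as.list(census$summary)

  ## references + normalization
  refs <- config$references
  ref_table <- NULL
  if (is.null(refs)) {
    ref_table <- select_references(cohort, n_refs = config$n_refs)
    refs <- ref_table$assay[ref_table$selected]
    .write_stage(ref_table, config$out_dir, "references")
  }
  expr <- normalize_cq(cohort$cq, refs, mode = "lenient")
  log$references <- refs

  ## fold changes over the FOC-passing strata
  keep <- census$table$assay[census$table$set %in% c("A", "B")]
  expr_kept <- expr_matrix(expr$values[keep, , drop = FALSE],
                           references = refs)
  fc <- fold_changes(expr_kept, g, threshold = config$fc_threshold)
  .write_stage(fc$table, config$out_dir, "fold_changes")
  log$volcano <- as.list(fc$summary)

  ## MoR screen on set B (single application)
  set_b <- marker_table(cohort, expr, census, sets = "B", proteins = FALSE)
  screen_b <- if (nrow(set_b) >= 1)
    mor_screen(set_b, g, d = config$d) else NULL
  if (!is.null(screen_b)) .write_stage(screen_b$table, config$out_dir, "screen_set_b")

  ## reliability on set A + proteins
  set_a <- marker_table(cohort, expr, census, sets = "A", proteins = TRUE)
  m_eff <- min(config$m, min(table(g)))
  rel_a <- if (nrow(set_a) >= 1)
    mor_reliability(set_a, g, B = config$B, m = m_eff, d = config$d,
                    rf_threshold = config$rf_threshold,
                    substitution = config$substitution,
                    seed = config$seed) else NULL
  if (!is.null(rel_a)) .write_stage(rel_a$table, config$out_dir, "reliability_set_a")

  reliable <- if (!is.null(rel_a))
    rel_a$table$variable[rel_a$table$reliable] else character()
  informative <- if (!is.null(screen_b))
    screen_b$table$variable[screen_b$table$informative] else character()
  log$screen <- list(set_a_markers = nrow(set_a), set_b_markers = nrow(set_b),
                     reliable = reliable, informative = informative)

  ## substitution + confirmatory MANCOVA per family
  proteins <- intersect(c("tau", "p_tau", "abeta42"), names(cohort$meta))
  confirm <- list()
  expr_sub <- NULL
  families <- list(reliable_set_a = reliable, informative_set_b = informative)
  if (!length(unlist(families))) {
    confirm <- list(notice = "no informative or reliable markers; confirmatory stage skipped")
  } else {
    all_mat <- rbind(marker_table(cohort, expr, census, sets = c("A", "B"),
                                  proteins = TRUE))
    em <- expr_matrix(all_mat)
    expr_sub <- substitute_missing(em, g)
    log$substitutions <- attr(expr_sub, "n_substituted")
    covs <- cohort$meta[, c("age", "sex")]
    for (fam in names(families)) {
      mk <- families[[fam]]
      if (!length(mk)) next
      Y <- t(expr_sub$values[mk, , drop = FALSE])
      confirm[[fam]] <- tryCatch(
        mancova(Y, g, covariates = covs, alpha = config$alpha),
        error = function(e) paste("mancova failed:", conditionMessage(e)))
      if (inherits(confirm[[fam]], "mancova"))
        .write_stage(confirm[[fam]]$univariate, config$out_dir,
                     paste0("mancova_", fam))
    }
  }

  ## classification
  classification <- NULL
  cls_markers <- config$classify_markers
  if (is.null(cls_markers)) {
    ## strongest screened miRNA markers (proteins excluded by default)
    cand <- c(setdiff(reliable, proteins), setdiff(informative, proteins))
    cls_markers <- utils::head(unique(cand), 3)
  }
  if (length(cls_markers) >= 1 && !is.null(expr_sub) &&
      all(cls_markers %in% rownames(expr_sub$values))) {
    X <- t(expr_sub$values[cls_markers, , drop = FALSE])
    classification <- tryCatch(lda_classify(X, g),
                               error = function(e) conditionMessage(e))
    if (inherits(classification, "lda_report")) {
      .write_stage(data.frame(marker = names(classification$auc),
                              auc = classification$auc),
                   config$out_dir, "classification_auc")
    }
  }

  ## correlations
  correlations <- NULL
  if (!is.null(config$correlate) && nrow(config$correlate) && !is.null(expr_sub)) {
    correlations <- lapply(seq_len(nrow(config$correlate)), function(k) {
      cc <- config$correlate[k, ]
      sel <- if (!is.null(cc$group) && !is.na(cc$group) && cc$group != "all")
        g == cc$group else rep(TRUE, length(g))
      xv <- -expr_sub$values[cc$marker, sel]   # expression = -dCq
      yv <- cohort$meta[[cc$protein]][sel]
      cqv <- cohort$cq$values[cc$marker, sel]
      cut <- if (!is.null(cc$cq_cutoff) && !is.na(cc$cq_cutoff)) cc$cq_cutoff else NULL
      res <- tryCatch(pearson_cor(xv, yv, ci_level = 0.98, cq = cqv,
                                  cq_cutoff = cut),
                      error = function(e) conditionMessage(e))
      list(marker = cc$marker, protein = cc$protein, result = res)
    })
  }

  report <- structure(list(config = unclass(config), log = log,
                           census = census, references = ref_table,
                           fold_changes = fc, screen_set_b = screen_b,
                           reliability_set_a = rel_a, confirmatory = confirm,
                           classification = classification,
                           correlations = correlations),
                      class = "run_report")
  if (!is.null(config$out_dir)) {
    ser <- list(config = unclass(config), log = log)
    ser$config$correlate <- NULL
    jsonlite::write_json(ser, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report\n==========\n")
  s <- x$census$summary
  cat(sprintf("census: %d/%d assays detected (at least %d%%); set A %d, set B %d\n",
              s[["detected"]], s[["panel"]], s[["percent_detected"]],
              s[["set_a"]], s[["set_b"]]))
  cat("normalizers:", paste(x$log$references, collapse = ", "), "\n")
  v <- x$fold_changes$summary
  cat(sprintf("volcano: %d up / %d down at FC >= %g\n", v[["up"]],
              v[["down"]], x$fold_changes$threshold))
  cat(sprintf("screen: %d reliable (set A), %d informative (set B)\n",
              length(x$log$screen$reliable), length(x$log$screen$informative)))
  if (!is.null(x$confirmatory$notice)) cat(x$confirmatory$notice, "\n")
  for (fam in intersect(names(x$confirmatory),
                        c("reliable_set_a", "informative_set_b")))
    if (inherits(x$confirmatory[[fam]], "mancova")) {
      mv <- x$confirmatory[[fam]]$mv
      cat(sprintf("mancova [%s]: F(%d, %d) = %.2f, p = %.3g\n", fam,
                  mv[["df1"]], mv[["df2"]], mv[["f"]], mv[["p"]]))
    }
  if (inherits(x$classification, "lda_report"))
    cat(sprintf("classification (%s): overall %.1f%%\n",
                paste(x$classification$markers, collapse = " + "),
                x$classification$accuracy[["overall"]]))
  invisible(x)
}
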