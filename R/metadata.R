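#' Cohort metadata table
#'
#' Validates a per-sample metadata table: diagnostic group, sex, age and —
#' optionally — the classical CSF protein biomarkers (total tau, p-tau,
#' amyloid-beta 1-42, all in pg/ml).
#'
#' @param df data.frame with columns `sample_id`, `group` (levels `control`
#'   and `case`), `sex` (`f`/`m`), `age` (years); optional numeric columns
#'   `tau`, `p_tau`, `abeta42` (pg/ml) and any further per-sample measures.
#' @return the validated data.frame, classed `cohort_metadata`.
#' @export
cohort_metadata <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "sex", "age")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("metadata lacks column(s): ", paste(miss, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample id(s) in metadata: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  df$group <- factor(as.character(df$group), levels = c("control", "case"))
  if (anyNA(df$group)) stop("group must be 'control' or 'case'")
  tab <- table(df$group)
  if (any(tab < 2L))
    stop("both group levels need >= 2 samples; got ",
         paste(sprintf("%s=%d", names(tab), tab), collapse = ", "))
  df$sex <- factor(tolower(as.character(df$sex)), levels = c("f", "m"))
  if (anyNA(df$sex)) stop("sex must be 'f' or 'm'")
  if (!is.numeric(df$age)) stop("age must be numeric (years)")
  for (p in c("tau", "p_tau", "abeta42"))
    if (p %in% names(df) && !is.numeric(df[[p]]))
      stop(p, " must be numeric (pg/ml)")
  class(df) <- c("cohort_metadata", "data.frame")
  df
}

#' Read a cohort metadata table from delimited text
#'
#' @inheritParams read_cq_table
#' @return a [cohort_metadata()] data.frame.
#' @export
read_metadata <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(sep)) sep <- .sniff_sep(path)
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          quote = "\"", comment.char = "", fileEncoding = "UTF-8")
  cohort_metadata(df)
}

#' Join a Cq matrix with its cohort metadata
#'
#' Aligns the two tables on sample id. Every sample carrying Cq data must be
#' covered by the metadata; metadata rows without a Cq column are dropped
#' with a warning (a sample that was consented but never assayed).
#'
#' @param cq a [cq_matrix()]
#' @param meta a [cohort_metadata()] (or coercible data.frame)
#' @return an object of class `cq_cohort`: list with the aligned `cq`,
#'   `meta` (same sample order) and the per-group sizes `n`.
#' @export
join_metadata <- function(cq, meta) {
  stopifnot(inherits(cq, "cq_matrix"))
  if (!inherits(meta, "cohort_metadata")) meta <- cohort_metadata(meta)
  samples <- colnames(cq$values)
  unmatched <- setdiff(samples, meta$sample_id)
  if (length(unmatched))
    stop("sample(s) missing from metadata: ", paste(unmatched, collapse = ", "))
  if (!length(intersect(samples, meta$sample_id)))
    stop("no samples shared between Cq matrix and metadata")
  extra <- setdiff(meta$sample_id, samples)
  if (length(extra))
    warning("dropping ", length(extra), " metadata sample(s) without Cq data: ",
            paste(extra, collapse = ", "))
  meta <- meta[match(samples, meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  n <- table(meta$group)
  structure(list(cq = cq, meta = meta,
                 n = c(control = unname(n[["control"]]),
                       case = unname(n[["case"]]))),
            class = "cq_cohort")
}

#' @export
print.cq_cohort <- function(x, ...) {
  cat(sprintf("cq_cohort: %d assays, %d control / %d case samples\n",
              nrow(x$cq$values), x$n[["control"]], x$n[["case"]]))
  invisible(x)
}

## group factor of a cohort, in sample order
.groups <- function(cohort) cohort$meta$group
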