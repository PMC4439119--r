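#' Cq matrix: per-assay, per-sample quantification cycles
#'
#' Container for a wide RT-qPCR panel: rows are miRNA assays, columns are
#' samples, cells are quantification cycles (Cq). A missing cell means the
#' well gave no signal ("not detected"). An assay is *detected* in a sample
#' when its Cq is present and does not exceed the positivity cutoff.
#'
#' @param values numeric matrix, assays in rows, samples in columns; `NA`
#'   marks undetected wells. Must carry unique row and column names.
#' @param cutoff Cq positivity threshold in cycles (default 34): a well with
#'   Cq above it is recorded but not counted as detected.
#' @param pool optional per-assay pool label (`"A"`, `"B"`, `"C"`, `"D"`),
#'   recycled `NA` when the panel layout is unknown.
#' @return An object of class `cq_matrix`.
#' @export
cq_matrix <- function(values, cutoff = 34, pool = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (assays x samples)")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have assay row names and sample column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate assay ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (any(values <= 0, na.rm = TRUE))
    stop("Cq values must be positive")
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0)
    stop("`cutoff` must be a single positive number of cycles")
  if (is.null(pool)) pool <- rep(NA_character_, nrow(values))
  pool <- as.character(pool)
  if (length(pool) != nrow(values))
    stop("`pool` must have one label per assay")
  bad <- !is.na(pool) & !pool %in% c("A", "B", "C", "D")
  if (any(bad))
    stop("pool labels must be A/B/C/D; offending: ",
         paste(unique(pool[bad]), collapse = ", "))
  structure(
    list(values = values, cutoff = cutoff,
         pool = stats::setNames(pool, rownames(values))),
    class = "cq_matrix")
}

#' @export
print.cq_matrix <- function(x, ...) {
  v <- x$values
  cat(sprintf("cq_matrix: %d assays x %d samples (cutoff Cq <= %g)\n",
              nrow(v), ncol(v), x$cutoff))
  cat(sprintf("  missing wells: %d (%.1f%%)\n", sum(is.na(v)),
              100 * mean(is.na(v))))
  cat(sprintf("  detected wells: %d (%.1f%%)\n", sum(is_detected(x)),
              100 * mean(is_detected(x))))
  invisible(x)
}

#' @export
dim.cq_matrix <- function(x) dim(x$values)

#' Detection indicator matrix
#'
#' @param cq a [cq_matrix()]
#' @return logical matrix, `TRUE` where the well is present and at or below
#'   the positivity cutoff.
#' @export
is_detected <- function(cq) {
  stopifnot(inherits(cq, "cq_matrix"))
  d <- !is.na(cq$values) & cq$values <= cq$cutoff
  d[is.na(d)] <- FALSE
  d
}

## tokens accepted (case-insensitively) as "well gave no signal"
.missing_tokens <- c("", "nd", "na", "n/a")

.sniff_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

#' Read a Cq table from delimited text
#'
#' Expects a header row; the first column holds assay ids, an optional
#' second column named `pool` holds the assay-pool label, and every
#' remaining column is one sample. Blank, `ND`, `NA` or `N/A` cells
#' (case-insensitive) mean the well was not detected.
#'
#' @param path file path to a CSV or TSV table (UTF-8).
#' @param cutoff Cq positivity threshold in cycles.
#' @param sep field delimiter; `NULL` (default) sniffs tab vs comma from the
#'   header line.
#' @return a [cq_matrix()]; the number of missing wells is attached as
#'   attribute `n_missing`.
#' @export
read_cq_table <- function(path, cutoff = 34, sep = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(sep)) sep <- .sniff_sep(path)
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "", fileEncoding = "UTF-8")
  if (ncol(raw) < 2L) stop("Cq table needs an assay-id column plus samples")
  assay_ids <- raw[[1L]]
  hdr <- names(raw)                 # before subsetting: `[.data.frame`
  body <- raw[, -1L, drop = FALSE]  # deduplicates names silently
  hdr <- hdr[-1L]
  pool <- NULL
  if (tolower(hdr[1L]) == "pool") {
    pool <- toupper(trimws(body[[1L]]))
    pool[pool %in% toupper(.missing_tokens)] <- NA_character_
    body <- body[, -1L, drop = FALSE]
    hdr <- hdr[-1L]
  }
  sample_ids <- hdr
  if (anyDuplicated(sample_ids))
    stop("duplicate sample column(s): ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyDuplicated(assay_ids))
    stop("duplicate assay id(s): ",
         paste(unique(assay_ids[duplicated(assay_ids)]), collapse = ", "))
  vals <- matrix(NA_real_, nrow(raw), length(sample_ids),
                 dimnames = list(assay_ids, sample_ids))
  for (j in seq_along(sample_ids)) {
    cell <- trimws(body[[j]])
    miss <- tolower(cell) %in% .missing_tokens | is.na(cell)
    num <- suppressWarnings(as.numeric(cell))
    bad <- !miss & is.na(num)
    if (any(bad))
      stop(sprintf("non-numeric Cq value '%s' at assay '%s', sample '%s'",
                   cell[which(bad)[1L]], assay_ids[which(bad)[1L]],
                   sample_ids[j]))
    vals[!miss, j] <- num[!miss]
  }
  out <- cq_matrix(vals, cutoff = cutoff, pool = pool)
  attr(out, "n_missing") <- sum(is.na(vals))
  out
}

#' Write a Cq table as delimited text
#'
#' Inverse of [read_cq_table()]: missing wells are written as `ND`, the pool
#' column is emitted when any pool label is known.
#'
#' @param cq a [cq_matrix()]
#' @param path output file path
#' @param sep field delimiter (default tab)
#' @return `path`, invisibly.
#' @export
write_cq_table <- function(cq, path, sep = "\t") {
  stopifnot(inherits(cq, "cq_matrix"))
  v <- cq$values
  chr <- matrix(as.character(v), nrow(v), ncol(v), dimnames = dimnames(v))
  chr[is.na(v)] <- "ND"
  df <- data.frame(assay = rownames(v), stringsAsFactors = FALSE,
                   check.names = FALSE)
  if (any(!is.na(cq$pool))) df$pool <- unname(cq$pool)
  df <- cbind(df, as.data.frame(chr, stringsAsFactors = FALSE,
                                check.names = FALSE))
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
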