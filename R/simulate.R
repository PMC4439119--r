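#' Configuration for the synthetic CSF qPCR cohort generator
#'
#' Defaults emulate the case/control study design the pipeline assumes:
#' 28 disease controls vs 22 cases profiled on a 1178-assay miRNA panel with
#' a Cq-34 positivity cutoff, abundance-driven dropout (low-abundance wells
#' fail more often), a handful of stable high-abundance reference assays,
#' planted group effects on a chosen marker subset, an older case group,
#' sex stratification, and CSF protein markers (tau, p-tau, amyloid-beta
#' 1-42) drawn per group with the demographics of such a memory-clinic
#' cohort.
#'
#' @param n_control,n_case group sizes.
#' @param n_assays panel size (unique assays).
#' @param n_reference number of designated stable reference assays: high
#'   abundance (mean Cq ~ 22), low variance, zero group effect.
#' @param planted data.frame with columns `assay` (id or 1-based index into
#'   the panel) and `effect` (delta-delta-Cq in cycles, case minus control;
#'   negative = up-regulated in cases). `NULL` plants the default marker
#'   subset: 12 assays at |ddCq| 0.8-2 in both directions on well-detected
#'   assays.
#' @param baseline_mean,baseline_sd distribution of per-assay mean Cq across
#'   the panel (cycles); the default N(36.9, 2.6) sits mostly above the
#'   cutoff, so only about a third of the panel is ever detected and a few
#'   percent reach the abundant stratum — the detection regime of CSF
#'   miRNA content.
#' @param assay_sd within-assay biological + technical SD of Cq (cycles).
#' @param cutoff Cq positivity threshold (cycles).
#' @param dropout `"abundance"` (default): a well is lost with probability
#'   `plogis((true Cq - cutoff)/dropout_scale)`; `"mar"`: lost i.i.d. with
#'   probability `dropout_prob` regardless of abundance; `"none"`.
#' @param dropout_scale logistic scale (cycles) of the abundance model.
#' @param dropout_prob flat loss probability for the `"mar"` model.
#' @param age_mean,age_sd length-2 vectors (control, case) in years.
#' @param sex_stratified when `TRUE` sexes are allocated deterministically
#'   at the configured per-group female fractions rather than sampled.
#' @param sex_f_frac length-2 female fraction (control, case).
#' @param protein_mean,protein_sd 3 x 2 matrices (rows tau, p_tau, abeta42;
#'   columns control, case) in pg/ml; draws are truncated at 1 pg/ml.
#' @param cor_hooks optional data.frame (`assay`, `protein`, `r`, optional
#'   `group`) coupling a marker's expression to a protein level through a
#'   shared latent Gaussian factor so their Pearson correlation targets `r`
#'   (within `group`, default `"case"`; `"all"` couples both groups).
#' @param seed integer; the same seed yields a bit-identical cohort.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_control = 28, n_case = 22, n_assays = 1178,
                       n_reference = 6, planted = NULL,
                       baseline_mean = 36.9, baseline_sd = 2.6,
                       assay_sd = 1.1, cutoff = 34,
                       dropout = c("abundance", "mar", "none"),
                       dropout_scale = 1.5, dropout_prob = 0,
                       age_mean = c(61.0, 72.1), age_sd = c(12.7, 8.5),
                       sex_stratified = TRUE,
                       sex_f_frac = c(14 / 28, 13 / 22),
                       protein_mean = NULL, protein_sd = NULL,
                       cor_hooks = NULL, seed = 1L) {
  dropout <- match.arg(dropout)
  if (n_control < 2 || n_case < 2) stop("need >= 2 samples per group")
  if (n_assays < 1) stop("need a positive panel size")
  if (n_reference < 0 || n_reference > n_assays)
    stop("n_reference must lie in [0, n_assays]")
  if (dropout_prob < 0 || dropout_prob > 1)
    stop("dropout_prob must be a probability")
  if (is.null(protein_mean))
    protein_mean <- matrix(c(308.9, 708.5, 52.6, 92.0, 719.9, 446.7),
                           nrow = 3, byrow = TRUE,
                           dimnames = list(c("tau", "p_tau", "abeta42"),
                                           c("control", "case")))
  if (is.null(protein_sd))
    protein_sd <- matrix(c(227.7, 282.9, 28.5, 93.3, 406.7, 164.1),
                         nrow = 3, byrow = TRUE,
                         dimnames = list(c("tau", "p_tau", "abeta42"),
                                         c("control", "case")))
  structure(list(n_control = n_control, n_case = n_case, n_assays = n_assays,
                 n_reference = n_reference, planted = planted,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 assay_sd = assay_sd, cutoff = cutoff, dropout = dropout,
                 dropout_scale = dropout_scale, dropout_prob = dropout_prob,
                 age_mean = age_mean, age_sd = age_sd,
                 sex_stratified = sex_stratified, sex_f_frac = sex_f_frac,
                 protein_mean = protein_mean, protein_sd = protein_sd,
                 cor_hooks = cor_hooks, seed = as.integer(seed)),
            class = "sim_config")
}

.assay_names <- function(n) sprintf("mir-%04d", seq_len(n))

## default planted marker subset: 12 well-detected assays, both directions
.default_planted <- function(assay_ids, mu) {
  eff <- c(-2, -1.5, -1.2, -1, -0.9, -0.8, 0.8, 0.9, 1, 1.2, 1.5, 2)
  eff <- utils::head(eff, length(assay_ids))   # small panels plant fewer
  ## pick the most abundant non-reference assays so the markers are in the
  ## high-FOC stratum the reliability analysis targets
  ord <- order(mu)
  pick <- assay_ids[ord[seq_along(eff)]]
  data.frame(assay = pick, effect = eff, stringsAsFactors = FALSE)
}

#' Simulate a case/control Cq cohort
#'
#' Draws per-assay mean Cq across the panel, adds the planted group effects,
#' per-well Gaussian noise on the Cq scale, applies the configured dropout
#' model, and generates matched metadata (age, stratified sex, CSF protein
#' markers). Reference assays are given mean Cq 22 and one third of the
#' panel SD so they are detected everywhere and stable between groups.
#'
#' @param config a [sim_config()]
#' @return list with `cq` (a [cq_matrix()]), `meta` (a
#'   [cohort_metadata()]), `cohort` (the joined [join_metadata()] object)
#'   and `truth`: data.frame per assay with the planted effect, reference
#'   designation, true mean Cq and realized per-group FOC.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  nc <- config$n_control; na <- config$n_case; n <- nc + na
  p <- config$n_assays
  assays <- .assay_names(p)
  samples <- c(sprintf("ctrl_%02d", seq_len(nc)), sprintf("case_%02d", seq_len(na)))
  group <- factor(rep(c("control", "case"), c(nc, na)),
                  levels = c("control", "case"))

  mu <- stats::rnorm(p, config$baseline_mean, config$baseline_sd)
  mu <- pmax(mu, 10)
  sd_a <- rep(config$assay_sd, p)
  is_ref <- rep(FALSE, p)
  if (config$n_reference > 0) {
    ref_idx <- seq_len(config$n_reference)
    mu[ref_idx] <- stats::rnorm(config$n_reference, 22, 0.5)
    sd_a[ref_idx] <- config$assay_sd / 3
    is_ref[ref_idx] <- TRUE
  }

  planted <- config$planted
  if (is.null(planted)) planted <- .default_planted(assays[!is_ref], mu[!is_ref])
  effect <- stats::setNames(rep(0, p), assays)
  if (nrow(planted)) {
    pid <- planted$assay
    if (is.numeric(pid)) pid <- assays[pid]
    bad <- setdiff(pid, assays)
    if (length(bad))
      stop("planted assay id(s) outside panel: ", paste(bad, collapse = ", "))
    if (any(is_ref[match(pid, assays)]))
      stop("cannot plant an effect on a designated reference assay")
    effect[pid] <- planted$effect
  }

  true_mean <- matrix(mu, p, n) + outer(effect, as.integer(group == "case"))
  vals <- true_mean + matrix(stats::rnorm(p * n, 0, rep(sd_a, n)), p, n)
  dimnames(vals) <- list(assays, samples)

  lost <- switch(config$dropout,
    none = matrix(FALSE, p, n),
    mar = matrix(stats::runif(p * n) < config$dropout_prob, p, n),
    abundance = matrix(stats::runif(p * n) <
                         stats::plogis((vals - config$cutoff) / config$dropout_scale),
                       p, n))
  vals[lost] <- NA_real_

  ## metadata
  age <- c(stats::rnorm(nc, config$age_mean[1], config$age_sd[1]),
           stats::rnorm(na, config$age_mean[2], config$age_sd[2]))
  age <- pmax(age, 30)
  sex <- if (config$sex_stratified) {
    nf <- c(round(config$sex_f_frac[1] * nc), round(config$sex_f_frac[2] * na))
    c(rep(c("f", "m"), c(nf[1], nc - nf[1])), rep(c("f", "m"), c(nf[2], na - nf[2])))
  } else {
    ifelse(stats::runif(n) < config$sex_f_frac[ifelse(group == "case", 2, 1)], "f", "m")
  }
  prot <- sapply(rownames(config$protein_mean), function(pn) {
    m <- config$protein_mean[pn, ]; s <- config$protein_sd[pn, ]
    pmax(c(stats::rnorm(nc, m[["control"]], s[["control"]]),
           stats::rnorm(na, m[["case"]], s[["case"]])), 1)
  })
  meta <- data.frame(sample_id = samples, group = as.character(group),
                     sex = sex, age = age, prot, stringsAsFactors = FALSE)

  ## correlation hooks: rebuild the protein from a shared latent factor so
  ## cor(expression, protein) targets r within the hooked group
  if (!is.null(config$cor_hooks) && nrow(config$cor_hooks)) {
    for (k in seq_len(nrow(config$cor_hooks))) {
      hk <- config$cor_hooks[k, ]
      if (!hk$assay %in% assays) stop("cor hook assay outside panel: ", hk$assay)
      if (!hk$protein %in% rownames(config$protein_mean))
        stop("cor hook protein unknown: ", hk$protein)
      gsel <- if (!is.null(hk$group) && identical(hk$group, "all")) rep(TRUE, n)
              else group == (if (is.null(hk$group)) "case" else hk$group)
      z <- vals[hk$assay, gsel]
      if (anyNA(z)) z[is.na(z)] <- mean(z, na.rm = TRUE)
      ## expression scale is -Cq: low Cq = high abundance
      z <- -scale(z)[, 1]
      gcol <- ifelse(group[gsel] == "case", "case", "control")
      m <- config$protein_mean[hk$protein, gcol]
      s <- config$protein_sd[hk$protein, gcol]
      e <- stats::rnorm(sum(gsel))
      meta[[hk$protein]][gsel] <-
        pmax(m + s * (hk$r * z + sqrt(1 - hk$r^2) * e), 1)
    }
  }

  cq <- cq_matrix(vals, cutoff = config$cutoff,
                  pool = rep(c("A", "B", "C", "D"), length.out = p))
  meta <- cohort_metadata(meta)
  cohort <- join_metadata(cq, meta)
  det <- is_detected(cq)
  truth <- data.frame(assay = assays, effect = unname(effect),
                      is_reference = is_ref, true_mean_cq = mu,
                      foc_control = rowSums(det[, group == "control", drop = FALSE]),
                      foc_case = rowSums(det[, group == "case", drop = FALSE]),
                      stringsAsFactors = FALSE)
  list(cq = cq, meta = meta, cohort = cohort, truth = truth, config = config)
}

#' Remove wells from a Cq matrix under a dropout model
#'
#' @param cq a [cq_matrix()]
#' @param prob flat per-well loss probability (missing-at-random), or `NULL`
#'   to use the abundance model.
#' @param scale logistic scale (cycles) for the abundance-driven model
#'   `plogis((Cq - cutoff)/scale)`; used when `prob` is `NULL`.
#' @param seed integer RNG seed.
#' @return the thinned [cq_matrix()]; the number of wells removed is
#'   attached as attribute `n_removed`.
#' @export
inject_dropout <- function(cq, prob = NULL, scale = 1.5, seed = 1L) {
  stopifnot(inherits(cq, "cq_matrix"))
  set.seed(as.integer(seed))
  v <- cq$values
  pmat <- if (!is.null(prob)) {
    if (prob < 0 || prob > 1) stop("prob must be in [0, 1]")
    matrix(prob, nrow(v), ncol(v))
  } else {
    stats::plogis((v - cq$cutoff) / scale)
  }
  lost <- !is.na(v) & matrix(stats::runif(length(v)), nrow(v)) < pmat
  v[lost] <- NA_real_
  out <- cq_matrix(v, cutoff = cq$cutoff, pool = cq$pool)
  attr(out, "n_removed") <- sum(lost, na.rm = TRUE)
  out
}

#' Write the generator truth table
#'
#' @param sim result of [simulate_cohort()]
#' @param path output TSV path
#' @return `path`, invisibly
#' @export
write_truth_table <- function(sim, path) {
  utils::write.table(sim$truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
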