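# shared fixture builders; everything generated in code, no data files

# tiny hand-sized cohort: 4 assays x 6 samples (3 control / 3 case)
tiny_cohort <- function(cutoff = 34) {
  vals <- matrix(c(
    20, 21, 19, 20, 21, 20,     # stable reference-like
    25, 26, 25, 28, 29, 28,     # shifted in cases
    33, 35, 32, NA, 36, 33,     # straddles cutoff, one missing well
    NA, NA, NA, NA, NA, 30),    # nearly absent
    nrow = 4, byrow = TRUE,
    dimnames = list(paste0("as", 1:4),
                    c("c1", "c2", "c3", "a1", "a2", "a3")))
  cq <- cq_matrix(vals, cutoff = cutoff)
  meta <- cohort_metadata(data.frame(
    sample_id = colnames(vals),
    group = rep(c("control", "case"), each = 3),
    sex = c("f", "m", "f", "m", "f", "m"),
    age = c(60, 62, 58, 71, 73, 70),
    tau = c(300, 310, 305, 700, 710, 705),
    p_tau = c(50, 52, 51, 90, 92, 91),
    abeta42 = c(720, 715, 718, 450, 445, 448)))
  join_metadata(cq, meta)
}

# moderately sized null cohort for property tests
null_cohort <- function(seed, n_assays = 40, dropout = "none") {
  simulate_cohort(sim_config(
    n_assays = n_assays, n_reference = 4, dropout = dropout,
    planted = data.frame(assay = character(0), effect = numeric(0)),
    seed = seed))
}

# write a small Cq csv and return the path
write_tiny_csv <- function(dir = tempdir()) {
  path <- file.path(dir, "tiny_cq.csv")
  writeLines(c("assay,s1,s2",
               "mirA,20.5,21.5",
               "mirB,33.0,ND",
               "mirC,28.1,29.9"), path)
  path
}
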