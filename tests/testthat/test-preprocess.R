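test_that("detection census: FOC counts, set thresholds, panel summary", {
  cohort <- tiny_cohort()
  cen <- detection_census(cohort, set_a_frac = c(19 / 28, 17 / 22))
  tab <- cen$table
  # as1, as2 detected everywhere; as3 has missing and over-cutoff wells
  expect_equal(tab$foc_control, c(3, 3, 2, 0))
  expect_equal(tab$foc_case, c(3, 3, 1, 1))
  # thresholds scale: ceiling(19/28 * 3) = 3, ceiling(17/22 * 3) = 3
  expect_equal(as.character(tab$set), c("A", "A", "excluded", "excluded"))
  expect_equal(unname(cen$summary[c("detected", "undetected")]), c(4, 0))

  # at the study's group sizes the absolute thresholds are 19 and 17
  sim <- simulate_cohort(sim_config(seed = 2, n_assays = 200))
  cen2 <- detection_census(sim$cohort)
  expect_equal(unname(cen2$thresholds[c("set_a_control", "set_a_case")]),
               c(19, 17))
  t2 <- cen2$table
  in_a <- t2$set == "A"
  expect_true(all(t2$foc_control[in_a] >= 19 & t2$foc_case[in_a] >= 17))
  in_b <- t2$set == "B"
  expect_true(all(t2$foc_control[in_b] >= 3 & t2$foc_case[in_b] >= 3))
  expect_true(all(!(t2$foc_control[in_b] >= 19 & t2$foc_case[in_b] >= 17)))
  # an assay detected in 2 controls / 10 cases is excluded
  expect_true(all(t2$set[t2$foc_control < 3 & t2$detected_anywhere] == "excluded"))

  # census partition covers the whole panel
  expect_equal(sum(table(t2$set)), nrow(t2))
  expect_equal(unname(cen2$summary[["detected"]] + cen2$summary[["undetected"]]),
               nrow(t2))

  # panel-level percent uses the floored percentage
  expect_equal(percent_detected(441, 1178), 37)
})

test_that("census is invariant to sample order", {
  sim <- simulate_cohort(sim_config(seed = 4, n_assays = 80))
  cen <- detection_census(sim$cohort)
  set.seed(1)
  perm <- sample(ncol(sim$cq$values))
  cq_p <- cq_matrix(sim$cq$values[, perm], cutoff = sim$cq$cutoff,
                    pool = sim$cq$pool)
  cohort_p <- join_metadata(cq_p, sim$meta)
  cen_p <- detection_census(cohort_p)
  expect_equal(cen_p$table, cen$table)
})

test_that("reference stability ranking: constant wins, biased loses, ties by id", {
  vals <- rbind(
    const  = rep(20, 6),
    biased = c(20, 20, 20, 23, 23, 23),   # planted group shift
    noisy  = c(19, 21, 20, 19, 21, 20))
  colnames(vals) <- c("c1", "c2", "c3", "a1", "a2", "a3")
  meta <- cohort_metadata(data.frame(
    sample_id = colnames(vals), group = rep(c("control", "case"), each = 3),
    sex = rep(c("f", "m"), 3), age = 60:65))
  cohort <- join_metadata(cq_matrix(vals), meta)
  refs <- select_references(cohort, n_refs = 2)
  expect_equal(refs$assay[1], "const")
  expect_equal(refs$stability[1], 0)
  # oracle: direct bias/variance decomposition of the two contenders
  stab <- function(v) {
    b <- abs(mean(v[4:6]) - mean(v[1:3]))
    sqrt(b^2 + (var(v[1:3]) + var(v[4:6])) / 2)
  }
  expect_lt(stab(vals["noisy", ]), stab(vals["biased", ]))
  expect_equal(refs$assay[2], "noisy")
  expect_equal(refs$stability, unname(sort(apply(vals, 1, stab))))

  # exact tie broken by assay id order
  tie <- rbind(zz = c(1, 2, 1, 2, 1, 2), aa = c(1, 2, 1, 2, 1, 2)) + 20
  colnames(tie) <- colnames(vals)
  cohort_tie <- join_metadata(cq_matrix(tie), meta)
  expect_equal(select_references(cohort_tie, 1)$assay, c("aa", "zz"))

  # no fully detected assay -> advisory error
  gap <- vals; gap[, 1] <- NA
  expect_error(select_references(join_metadata(cq_matrix(gap), meta)),
               "manual")
})

test_that("normalization: reference-mean subtraction, invariances, modes", {
  # hand oracle: references {20, 22}, target 25 -> dCq = 25 - 21 = 4
  vals <- rbind(ref1 = c(20, 30), ref2 = c(22, 32), tgt = c(25, 31))
  colnames(vals) <- c("s1", "s2")
  cq <- cq_matrix(vals)
  ex <- normalize_cq(cq, c("ref1", "ref2"))
  expect_equal(ex$values["tgt", "s1"], 4)
  expect_equal(ex$values["tgt", "s2"], 0)   # equals the reference mean
  # dCq = 0 means relative expression 1
  expect_equal(expr_rescale(ex, "rel_linear")$values["tgt", "s2"], 1)

  # per-sample additive shift leaves dCq unchanged
  shift <- sweep(vals, 2, c(1.7, -2.4), "+")
  ex_shift <- normalize_cq(cq_matrix(shift), c("ref1", "ref2"))
  expect_equal(ex_shift$values, ex$values)

  # missing wells stay missing
  vals2 <- vals; vals2["tgt", "s2"] <- NA
  ex2 <- normalize_cq(cq_matrix(vals2), c("ref1", "ref2"))
  expect_true(is.na(ex2$values["tgt", "s2"]))
  expect_equal(ex2$values["tgt", "s1"], 4)

  # undetected reference: strict errors naming the sample, lenient warns
  vals3 <- vals; vals3["ref2", "s2"] <- NA
  expect_error(normalize_cq(cq_matrix(vals3), c("ref1", "ref2")), "s2")
  expect_warning(ex3 <- normalize_cq(cq_matrix(vals3), c("ref1", "ref2"),
                                     mode = "lenient"), "s2")
  expect_equal(ex3$values["tgt", "s2"], 31 - 30)
})

test_that("expression scale conversions are self-consistent", {
  sim <- null_cohort(seed = 6, n_assays = 20)
  refs <- select_references(sim$cohort, n_refs = 4)
  ex <- normalize_cq(sim$cq, refs$assay[refs$selected], mode = "lenient")
  lin <- expr_rescale(ex, "rel_linear")
  lg2 <- expr_rescale(ex, "rel_log2")
  expect_true(all(lin$values > 0, na.rm = TRUE))
  expect_equal(lg2$values, -ex$values)
  expect_equal(log2(lin$values), lg2$values, tolerance = 1e-12)
  expect_equal(expr_rescale(lin, "delta_cq")$values, ex$values,
               tolerance = 1e-12)
})

test_that("fold changes follow the 2^(-ddCq) model with boundary calls", {
  mk <- function(ctrl, case) {
    m <- matrix(c(ctrl, case), nrow = 1,
                dimnames = list("m1", sprintf("s%d", seq_along(c(ctrl, case)))))
    expr_matrix(m)
  }
  g <- factor(rep(c("control", "case"), each = 3), c("control", "case"))

  # ddCq = 0 -> FC 1, flat
  fc0 <- fold_changes(mk(c(1, 2, 3), c(3, 2, 1)), g)
  expect_equal(fc0$table$fc, 1)
  expect_equal(as.character(fc0$table$call), "flat")

  # ddCq = -1 -> FC 2, up
  fc1 <- fold_changes(mk(c(4, 4, 4), c(3, 3, 3)), g)
  expect_equal(fc1$table$fc, 2)
  expect_equal(as.character(fc1$table$call), "up")
  expect_equal(fc1$table$log2_fc, 1)

  # closed-form boundary: means 4.0 vs 3.415 -> FC = 2^0.585 = 1.50004, up
  fcb <- fold_changes(mk(c(4, 4, 4), c(3.415, 3.415, 3.415)), g,
                      threshold = 1.5)
  expect_equal(fcb$table$fc, 2^0.585)
  expect_gte(fcb$table$fc, 1.5)
  expect_equal(as.character(fcb$table$call), "up")

  # zero variance, equal means -> p = 1 flat
  fcz <- fold_changes(mk(c(2, 2, 2), c(2, 2, 2)), g)
  expect_equal(fcz$table$p, 1)
  expect_equal(as.character(fcz$table$call), "flat")

  # pooled t matches stats::t.test(var.equal = TRUE)
  set.seed(11)
  x <- rnorm(3); y <- rnorm(3) + 1
  fct <- fold_changes(mk(x, y), g)
  expect_equal(fct$table$p, t.test(x, y, var.equal = TRUE)$p.value)
  fcw <- fold_changes(mk(x, y), g, var_equal = FALSE)
  expect_equal(fcw$table$p, t.test(x, y)$p.value)
})

test_that("volcano counts equal brute-force counts over the table", {
  sim <- simulate_cohort(sim_config(seed = 9, n_assays = 150))
  cen <- detection_census(sim$cohort)
  refs <- select_references(sim$cohort)
  ex <- normalize_cq(sim$cq, refs$assay[refs$selected], mode = "lenient")
  keep <- cen$table$assay[cen$table$set %in% c("A", "B")]
  fc <- fold_changes(expr_matrix(ex$values[keep, , drop = FALSE]),
                     sim$meta$group)
  expect_equal(unname(fc$summary[["up"]]),
               sum(fc$table$fc >= 1.5, na.rm = TRUE))
  expect_equal(unname(fc$summary[["down"]]),
               sum(fc$table$fc <= 1 / 1.5, na.rm = TRUE))
  expect_equal(sum(fc$summary), nrow(fc$table))
  co <- volcano_coords(fc)
  expect_equal(nrow(co), nrow(fc$table))
})

test_that("group-mean substitution fills gaps without moving group means", {
  vals <- rbind(m1 = c(1, 3, NA, 5, NA, 7),
                m2 = c(2, 2, 2, 4, 4, 4))
  colnames(vals) <- sprintf("s%d", 1:6)
  g <- factor(rep(c("control", "case"), each = 3), c("control", "case"))
  ex <- expr_matrix(vals)
  sub <- substitute_missing(ex, g)
  expect_equal(sub$values["m1", "s3"], 2)      # mean of {1, 3}
  expect_equal(sub$values["m1", "s5"], 6)      # mean of {5, 7}
  expect_equal(attr(sub, "n_substituted"), 2L)
  # group means unchanged
  expect_equal(rowMeans(sub$values[, 1:3]), rowMeans(vals[, 1:3], na.rm = TRUE))
  expect_equal(rowMeans(sub$values[, 4:6]), rowMeans(vals[, 4:6], na.rm = TRUE))
  # identity on complete data
  expect_identical(substitute_missing(expr_matrix(vals[2, , drop = FALSE]),
                                      g)$values,
                   vals[2, , drop = FALSE])
  # a group with no detected value errors naming the assay
  bad <- vals; bad["m1", 1:3] <- NA
  expect_error(substitute_missing(expr_matrix(bad), g), "m1")
})
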