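mk_termini <- function(ratios, category = "MTS", mito = TRUE, protein = NULL) {
  n <- length(ratios)
  if (is.null(protein)) protein <- sprintf("P%03d", seq_len(n))
  tbl <- tibble::tibble(
    protein = protein, start = seq_len(n),
    category = rep(category, length.out = n),
    is_mitochondrial = rep(mito, length.out = n),
    nterm_mod = "dimethyl", total_spectral_count = 1L, peptide_count = 1L,
    ambiguity_flag = FALSE)
  k <- length(ratios[[1]])
  for (r in seq_len(k)) {
    tbl[[paste0("ratio_hl_rep", r)]] <- vapply(ratios, `[`, numeric(1), r)
  }
  tbl
}

test_that("normalization centers each replicate on its expected-mito median", {
  t1 <- mk_termini(list(c(0.4, 0), c(0.6, 0), c(0.8, 0), c(1.5, 0)),
                   category = c("MTS", "MTS", "MTS", "unexpected"))
  out <- normalize_ratios(t1)
  expect_equal(attr(out, "normalization_offsets")[["ratio_hl_rep1"]], 0.6)
  expect_equal(out$ratio_hl_rep1, c(-0.2, 0, 0.2, 0.9))
  # reference median already 0: identity
  t2 <- mk_termini(list(c(-0.3, 0), c(0, 0), c(0.3, 0)))
  expect_equal(normalize_ratios(t2)$ratio_hl_rep1, c(-0.3, 0, 0.3))
  # a single reference terminus defines the offset
  t3 <- mk_termini(list(c(1.0, 0), c(2.5, 0)), category = c("MTS", "unexpected"))
  expect_equal(normalize_ratios(t3)$ratio_hl_rep1, c(0, 1.5))
  # no reference in a replicate is an error naming it
  t4 <- mk_termini(list(c(0.5, NA)), category = "MTS")
  expect_error(normalize_ratios(t4), "replicate 2")
  t5 <- mk_termini(list(c(0.5, 0.5)), category = "unexpected")
  expect_error(normalize_ratios(t5), "reference")
})

test_that("normalizing twice equals normalizing once", {
  set.seed(8)
  ratios <- lapply(1:50, function(i) rnorm(3, 0.4))
  t1 <- mk_termini(ratios, category = sample(c("MTS", "P1_2", "unexpected"), 50,
                                             replace = TRUE))
  once <- normalize_ratios(t1)
  twice <- normalize_ratios(once)
  ratio_cols <- grep("^ratio", names(twice))
  expect_equal(twice[ratio_cols], once[ratio_cols], ignore_attr = TRUE)
})

test_that("replicate aggregation enforces the 2-of-3 rule", {
  t1 <- mk_termini(list(c(0.5, 0.7, NA), c(0.5, NA, NA), c(1, 2, 3)))
  out <- aggregate_replicates(t1, min_reps = 2)
  expect_equal(out$mean_norm_log2, c(0.6, NA, 2))
  expect_equal(out$n_quantified, c(2L, 1L, 3L))
  expect_equal(out$diff_call, c(NA, "not_quantified", NA))
})

test_that("class comparison reports delta median and exact Mann-Whitney p", {
  cmp <- compare_class_distributions(expected = c(0, 0, 0),
                                     unexpected = c(1, 1, 1))
  expect_equal(cmp$delta_median, 1)
  expect_equal(cmp$p_two_sided, 0.1)
  cmp2 <- compare_class_distributions(c(0, 1), c(2, 3))
  expect_equal(cmp2$p_two_sided, 1 / 3)
  cmp3 <- compare_class_distributions(c(1, 2, 3), c(1, 2, 3))
  expect_equal(cmp3$delta_median, 0)
  expect_equal(cmp3$p_two_sided, 1)
  expect_error(compare_class_distributions(numeric(0), 1:3), "non-empty")
  td <- tidy(cmp)
  expect_equal(td$delta_median, 1)
  expect_named(glance(cmp2), names(td))
})

test_that("IQR cutoff derivation uses type-7 quartiles", {
  b <- derive_cutoff(c(-0.4, -0.2, 0, 0.2, 0.4))
  expect_equal(b$lower, -0.8)
  expect_equal(b$upper, 0.8)
  expect_warning(derive_cutoff(rep(0, 10)), "degenerate")
  expect_error(derive_cutoff(c(0, 1, 2)), "at least 4")

  set.seed(12)
  v <- rnorm(120, 0, 0.3)
  b2 <- derive_cutoff(v, k = 1.5)
  q <- quantile(v, c(0.25, 0.75), type = 7, names = FALSE)  # direct oracle
  expect_equal(b2$lower, q[1] - 1.5 * (q[2] - q[1]))
  expect_equal(b2$upper, q[2] + 1.5 * (q[2] - q[1]))
  expect_equal(b2$reference_n, 120L)
})

test_that("cutoff magnitude on an unchanged-protein style reference is near 0.9", {
  # reference resembling termini of abundance-unchanged proteins
  set.seed(77)
  for (i in 1:5) {
    b <- derive_cutoff(rnorm(100, 0, 0.3))
    expect_gte(abs(b$lower), 0.5); expect_lte(abs(b$lower), 1.3)
    expect_gte(abs(b$upper), 0.5); expect_lte(abs(b$upper), 1.3)
  }
})

test_that("differential calls use strict inequalities at the bounds", {
  t1 <- mk_termini(list(c(1.2, 1.2, 1.2), c(0.9, 0.9, 0.9), c(-1, -1, -1),
                        c(0, 0, 0), c(NA, NA, 0.2)))
  agg <- aggregate_replicates(t1)
  out <- call_differential_termini(agg, fixed_cutoff(0.9))
  expect_equal(out$diff_call,
               c("accumulating", "unchanged", "depleted", "unchanged",
                 "not_quantified"))
})

test_that("planted shifts are recovered at the derived cutoff", {
  set.seed(19)
  null_vals <- rnorm(200, 0, 0.3)
  shifted <- rnorm(20, 2, 0.3)
  t1 <- mk_termini(as.list(c(null_vals, shifted)), category = "unexpected",
                   mito = FALSE)
  t1$ratio_hl_rep1 <- c(null_vals, shifted)
  agg <- aggregate_replicates(t1, min_reps = 1)
  bounds <- derive_cutoff(agg$mean_norm_log2[seq_len(200)])
  out <- call_differential_termini(agg, bounds)
  expect_gte(sum(out$diff_call[201:220] == "accumulating"), 19)
  expect_lte(mean(out$diff_call[1:200] != "unchanged"), 0.05)
})

test_that("terminus-protein correlations behave per class", {
  t1 <- mk_termini(list(c(1, 1, 1), c(2, 2, 2), c(3, 3, 3)),
                   protein = c("A", "B", "C"))
  agg <- aggregate_replicates(t1)
  lfq <- tibble::tibble(accession = c("A", "B", "C"), log2_ratio = c(1, 2, 3))
  out <- correlate_with_protein_abundance(agg, lfq)
  expect_equal(out$pearson_r[out$class == "expected"], 1.0)
  expect_false(out$computable[out$class == "unexpected"])

  lfq_rev <- tibble::tibble(accession = c("A", "B", "C"), log2_ratio = c(3, 2, 1))
  out2 <- correlate_with_protein_abundance(agg, lfq_rev)
  expect_equal(out2$pearson_r[out2$class == "expected"], -1.0)

  # termini tracking protein effects with modest noise correlate strongly
  set.seed(23)
  prot_effect <- rnorm(120, 0, 0.4)
  t2 <- mk_termini(as.list(prot_effect + rnorm(120, 0, 0.2)))
  t2$ratio_hl_rep1 <- prot_effect + rnorm(120, 0, 0.2)
  agg2 <- aggregate_replicates(t2, min_reps = 1)
  lfq2 <- tibble::tibble(accession = t2$protein, log2_ratio = prot_effect)
  r <- correlate_with_protein_abundance(agg2, lfq2)
  r_exp <- r$pearson_r[r$class == "expected"]
  expect_gte(r_exp, 0.7); expect_lte(r_exp, 0.95)
})

test_that("the planted global neo-terminus shift is recovered across seeds", {
  deltas <- vapply(1:20, function(s) {
    p <- generate_preset("tails-default", seed = 100 + s)
    run <- run_tails(p$db, p$evidence, p$protein_lfq)
    run$comparison$delta_median
  }, numeric(1))
  expect_lt(abs(mean(deltas) - 0.32), 0.05)
})
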