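test_that("window extraction dedupes unique cleavage sites", {
  db <- example_protein_db()
  t1 <- tibble::tibble(protein = c("PROT1", "PROT1", "PROT1"),
                       start = c(21L, 21L, 1L))
  w <- extract_cleavage_windows(t1, db)
  expect_equal(nrow(w), 2)
  expect_equal(w$window[w$cleavage_before == 21], "VRAGK|WTEYF")
  expect_equal(w$window[w$cleavage_before == 1], "-----|MLSRR")
  w2 <- extract_cleavage_windows(t1, db, dedupe = FALSE)
  expect_equal(nrow(w2), 3)
})

test_that("reference frequencies count residues over the in-scope proteome", {
  db1 <- protein_db(tibble::tibble(accession = "A", sequence = "AAAA",
                                   is_mitochondrial = FALSE))
  f <- reference_frequencies(db1, "all_proteins")
  expect_equal(f$frequency[f$residue == "A"], 1.0)
  expect_error(reference_frequencies(db1, "mitochondrial_only"), "no proteins")

  db2 <- protein_db(tibble::tibble(accession = c("A", "B"),
                                   sequence = c("AACC", "CCAA"),
                                   is_mitochondrial = c(TRUE, FALSE)))
  f2 <- reference_frequencies(db2, "all_proteins")
  expect_equal(sort(f2$frequency), c(0.5, 0.5))

  p <- generate_preset("tails-default", seed = 3)
  f3 <- reference_frequencies(p$db, "mitochondrial_only")
  seqs <- p$db$proteins$sequence[p$db$proteins$is_mitochondrial]
  counts <- table(strsplit(paste(seqs, collapse = ""), "")[[1]])  # direct count
  expect_equal(setNames(f3$frequency, f3$residue),
               counts[f3$residue] / sum(counts), ignore_attr = TRUE)
  expect_equal(sum(f3$frequency), 1)
})

test_that("positional enrichment matches the binomial oracle", {
  w <- rep("AAAAR|WTEYF", 10)
  ref <- tibble::tibble(residue = c("R", "A", "W", "T", "E", "Y", "F"),
                        frequency = c(0.05, 0.4, 0.11, 0.11, 0.11, 0.11, 0.11))
  pe <- position_enrichment(w, ref, n_left = 5)
  r_at_p1 <- pe[pe$position_label == "P1" & pe$residue == "R", ]
  expect_equal(r_at_p1$percent_difference, 95)
  expect_equal(r_at_p1$p_value, binom_oracle(10, 10, 0.05), tolerance = 1e-12)
  expect_lt(r_at_p1$p_value, 1e-12)
  expect_true(r_at_p1$significant)

  # observed equal to reference: zero effect, not significant
  w2 <- c(rep("AAAAA|AAAAA", 4), rep("CAAAA|AAAAA", 1),
          rep("AAAAA|CAAAA", 0))
  ref2 <- tibble::tibble(residue = c("A", "C"), frequency = c(0.8, 0.2))
  pe2 <- position_enrichment(w2, ref2, n_left = 5)
  cell <- pe2[pe2$position_label == "P5" & pe2$residue == "C", ]
  expect_equal(cell$observed_freq, 0.2)
  expect_equal(cell$percent_difference, 0)
  expect_false(cell$significant)

  # random cells agree with the oracle
  set.seed(6)
  aas <- c("A", "C", "D", "R")
  w3 <- replicate(15, paste0(paste(sample(aas, 5, TRUE), collapse = ""), "|",
                             paste(sample(aas, 5, TRUE), collapse = "")))
  ref3 <- tibble::tibble(residue = aas, frequency = rep(0.25, 4))
  pe3 <- position_enrichment(w3, ref3, n_left = 5)
  for (i in sample(nrow(pe3), 20)) {
    expect_equal(pe3$p_value[i],
                 binom_oracle(pe3$n_obs[i], pe3$n_total[i],
                              pe3$reference_freq[i]),
                 tolerance = 1e-12)
  }
})

test_that("type-I error of enrichment cells is controlled under the null", {
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  ref <- tibble::tibble(residue = aas, frequency = rep(0.05, 20))
  fracs <- vapply(1:20, function(s) {
    set.seed(400 + s)
    w <- replicate(500, paste0(paste(sample(aas, 5, TRUE), collapse = ""), "|",
                               paste(sample(aas, 5, TRUE), collapse = "")))
    pe <- position_enrichment(w, ref, n_left = 5, alpha = 0.05)
    mean(pe$significant)
  }, numeric(1))
  expect_lte(mean(fracs), 0.07)
})

test_that("P-position subsetting follows Schechter-Berger labels and partitions", {
  db <- example_protein_db()
  w <- extract_cleavage_windows(tibble::tibble(protein = "PROT1", start = 21L), db)
  # "VRAGK|WTEYF": P1 = K, P2 = G, P1' = W
  expect_equal(nrow(subset_by_residue(w, "P1", "K")), 1)
  expect_equal(nrow(subset_by_residue(w, "P2", "G")), 1)
  expect_equal(nrow(subset_by_residue(w, "P2", "K")), 0)
  expect_equal(nrow(subset_by_residue(w, "P1'", "W")), 1)
  expect_error(subset_by_residue(w, "P9", "K"), "outside the window")
  expect_error(subset_by_residue(w, "Q1", "K"), "invalid position label")

  # partition: sizes over all residues sum to the non-padded window count
  t2 <- tibble::tibble(protein = "PROT1", start = c(1L, 3L, 11L, 21L, 28L))
  w2 <- extract_cleavage_windows(t2, db)
  at_p3 <- substring(sub("|", "", w2$window, fixed = TRUE), 3, 3)
  sizes <- vapply(unique(at_p3[at_p3 != "-"]), function(res) {
    nrow(subset_by_residue(w2, "P3", res))
  }, numeric(1))
  expect_equal(sum(sizes), sum(at_p3 != "-"))
})

test_that("N-terminal residue profiles split by N-end-rule class", {
  db <- protein_db(tibble::tibble(
    accession = c("A1", "A2", "D1", "D2"),
    sequence = c("MAAAAAAA", "MAAAAAAA", "MDDDDDDD", "MDDDDDDD"),
    is_mitochondrial = FALSE))
  all_a <- tibble::tibble(protein = c("A1", "A2"), start = c(2L, 2L),
                          category = "unexpected")
  pr <- nterm_residue_profile(all_a, db)
  expect_equal(pr$fraction, 1.0)
  expect_equal(pr$residue, "A")
  expect_equal(pr$nend_class, "stabilizing")

  half <- tibble::tibble(protein = c("A1", "D1"), start = c(2L, 2L),
                         category = "unexpected")
  pr2 <- nterm_residue_profile(half, db)
  expect_equal(sort(pr2$fraction), c(0.5, 0.5))
  expect_setequal(pr2$nend_class, c("stabilizing", "secondary_destabilizing"))

  # generator draws expected mature starts from stabilizing residues only
  cfg <- synthetic_config(seed = 5,
                          mature_start_probs = c(S = 0.3, A = 0.25, T = 0.15,
                                                 G = 0.2, M = 0.1))
  dbb <- generate_protein_db(cfg)
  mts <- tibble::tibble(protein = dbb$truth$accession[dbb$truth$is_mitochondrial],
                        start = dbb$truth$mature_start[dbb$truth$is_mitochondrial],
                        category = "MTS")
  pr3 <- nterm_residue_profile(mts, dbb$db)
  stab <- sum(pr3$fraction[pr3$nend_class == "stabilizing"])
  expect_equal(stab, 1.0)
})
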