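test_that("evidence TSV reading preserves per-replicate ratios and missingness", {
  d <- withr::local_tempdir()
  path <- file.path(d, "ev.tsv")
  tbl <- make_evidence(
    peptide = c("SDEKLVR", "WTEYFDNAR", "MLSRR"),
    protein = "PROT1",
    lys_mods = c("dimethyl_light", "", ""),
    ratios = list(c(0.5, 0.7, NA), c(1.1, NA, 0.9), c(NA, NA, NA)),
    counts = list(c(3, 2, 0), c(1, 1, 1), c(2, 0, 0)))
  readr::write_tsv(tbl, path, na = "")
  ev <- read_evidence_table(path, n_reps = 3)
  expect_equal(nrow(ev), 3)
  expect_equal(ev$ratio_hl_rep1, c(0.5, 1.1, NA))
  expect_equal(ev$ratio_hl_rep2, c(0.7, NA, NA))
  expect_true(all(is.na(ev[3, c("ratio_hl_rep1", "ratio_hl_rep2", "ratio_hl_rep3")])))
  expect_equal(ev$cterm_residue, c("R", "R", "R"))
  expect_error(read_evidence_table(path, n_reps = 2), "expects 2")
})

test_that("unknown modification tokens are rejected by row", {
  ev <- make_evidence("QSTLVR", "PROT1", nterm_mod = "phospho")
  expect_error(labeling_qc(ev), "unknown modification 'phospho'")
  ev2 <- make_evidence("AKLVR", "PROT1", lys_mods = "trimethyl")
  expect_error(labeling_qc(ev2), "unknown modification 'trimethyl'")
})

test_that("labeling QC computes fractions against their thresholds", {
  # 10 Lys observed, 9 dimethylated -> 0.9, below the >0.98 bar
  ev <- make_evidence(
    peptide = rep("AKLVR", 10), protein = "P",
    lys_mods = c(rep("dimethyl_light", 5), rep("dimethyl_heavy", 4), "unmodified"))
  qc <- labeling_qc(ev)
  expect_equal(qc$frac_lys_dimethylated, 0.9)
  expect_false(qc$pass_lys_labeling)
  expect_equal(qc$n_lys, 10)

  # fully labeled, no dimethyl-Lys cleavage: both checks pass
  qc2 <- labeling_qc(make_evidence(rep("AKLVR", 4), "P", lys_mods = "dimethyl_light"))
  expect_equal(qc2$frac_lys_dimethylated, 1.0)
  expect_equal(qc2$frac_cleaved_after_dimethyl_lys, 0.0)
  expect_true(qc2$pass_lys_labeling && qc2$pass_cleavage)

  # 5 of 100 peptides cleaved after dimethyl-Lys -> 0.05, below the <0.06 bar
  ev3 <- make_evidence(rep("AGLVR", 100), "P",
                       after_dimethyl_lys = c(rep(TRUE, 5), rep(FALSE, 95)))
  qc3 <- labeling_qc(ev3)
  expect_equal(qc3$frac_cleaved_after_dimethyl_lys, 0.05)
  expect_true(qc3$pass_cleavage)

  # row order cannot matter
  set.seed(1)
  perm <- sample(nrow(ev3))
  expect_equal(labeling_qc(ev3[perm, ]), qc3)
  expect_error(labeling_qc(ev3[0, ]), "empty")
})

test_that("Lys-only protein ratio recalculation filters then takes the median", {
  ev <- make_evidence(c("AKLR", "AGLR"), "P1",
                      lys_mods = c("dimethyl_light", ""),
                      ratios = list(c(2, NA, NA), c(1, NA, NA)))
  out <- recalc_protein_ratios_lys_only(ev)
  expect_equal(out$log2_ratio, 2.0)  # the Lys-less peptide is excluded
  expect_equal(out$n_peptides_used, 1L)

  ev2 <- make_evidence(c("AGLR", "TGGR"), "P1",
                       ratios = list(c(2, NA, NA), c(1, NA, NA)))
  out2 <- recalc_protein_ratios_lys_only(ev2)
  expect_true(is.na(out2$log2_ratio))
  expect_false(out2$quantified)

  ev3 <- make_evidence(c("AKLR", "TKGR", "PKSR"), "P1",
                       lys_mods = "dimethyl_light",
                       ratios = list(c(1, NA, NA), c(3, NA, NA), c(2, NA, NA)))
  expect_equal(recalc_protein_ratios_lys_only(ev3)$log2_ratio, 2.0)
})

test_that("recalculated ratios equal a brute-force filter-then-median oracle", {
  set.seed(42)
  for (trial in 1:10) {
    n <- 30
    peps <- replicate(n, paste(sample(c("A", "K", "G", "L", "R"), 8,
                                      replace = TRUE), collapse = ""))
    prots <- sample(c("P1", "P2", "P3"), n, replace = TRUE)
    ratios <- lapply(seq_len(n), function(i) {
      r <- rnorm(3)
      r[runif(3) < 0.4] <- NA
      r
    })
    ev <- make_evidence(peps, prots,
                        lys_mods = vapply(peps, function(p) {
                          paste(rep("dimethyl_light",
                                    sum(strsplit(p, "")[[1]] == "K")),
                                collapse = ";")
                        }, character(1)),
                        ratios = ratios)
    out <- recalc_protein_ratios_lys_only(ev)
    for (p in unique(prots)) {
      idx <- which(prots == p)
      vals <- c()
      for (i in idx) {
        if (!grepl("K", peps[i])) next
        r <- ratios[[i]]
        if (all(is.na(r))) next
        vals <- c(vals, mean(r, na.rm = TRUE))
      }
      expected <- if (length(vals) == 0) NA_real_ else median(vals)
      expect_equal(out$log2_ratio[out$protein == p], expected)
    }
  }
})
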