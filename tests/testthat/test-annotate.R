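test_that("ArgC-consistency filters reject with the documented reasons", {
  db <- example_protein_db()
  ev <- make_evidence(
    peptide = c("QSTLVR", "SDEKLVK", "PDNAR", "PDNAR", "SDEKLVR", "WTEYFDNARG"),
    protein = "PROT1",
    nterm_mod = c("pyroglu_Q", "dimethyl", "dimethyl", "free", "dimethyl",
                  "dimethyl"))
  out <- filter_evidence(ev, db = db)
  expect_equal(nrow(out$kept) + nrow(out$rejected), nrow(ev))
  expect_equal(out$rejected$reject_reason[out$rejected$nterm_mod == "pyroglu_Q"],
               "pyroglu")
  expect_equal(out$rejected$reject_reason[out$rejected$peptide == "SDEKLVK"],
               "no_cterm_arg")
  # dimethyl on N-terminal Pro is nonsense; the same peptide with a free
  # N terminus passes
  expect_equal(out$rejected$reject_reason[out$rejected$peptide == "PDNAR" &
                                            out$rejected$nterm_mod == "dimethyl"],
               "pro_dimethyl")
  expect_true("PDNAR" %in% out$kept$peptide)
  # "WTEYFDNARG" ends at the protein C terminus: exempt from the Arg rule
  expect_true("WTEYFDNARG" %in% out$kept$peptide)
  strict <- filter_evidence(ev, db = db, allow_protein_cterm = FALSE)
  expect_true("WTEYFDNARG" %in% strict$rejected$peptide)
})

test_that("peptides map to first occurrence and classify by position", {
  db <- example_protein_db()
  ev <- make_evidence(c("SDEKLVR", "MLSRR", "WTEYFDNAR"), "PROT1")
  m <- map_and_classify(ev, db)
  expect_equal(m$start, c(11L, 1L, 21L))
  expect_equal(m$category, c("MTS", "P1_2", "unexpected"))
  expect_true(all(m$is_mitochondrial))
  expect_false(any(m$ambiguity_flag))

  # Met1-removed N terminus at position 2 is a database terminus
  m2 <- map_and_classify(make_evidence("LSRR", "PROT1"), db)
  expect_equal(m2$category, "P1_2")

  expect_error(map_and_classify(make_evidence("WWWWW", "PROT1"), db),
               "not a substring")

  # repeated substring: first occurrence wins, ambiguity flagged
  db2 <- protein_db(tibble::tibble(accession = "REP",
                                   sequence = "MAGLVRAGLVRAGLVR",
                                   is_mitochondrial = FALSE))
  m3 <- map_and_classify(make_evidence("AGLVR", "REP"), db2)
  expect_equal(m3$start, 2L)
  expect_true(m3$ambiguity_flag)
})

test_that("collapse merges peptides sharing (protein, start)", {
  db <- example_protein_db()
  ev <- make_evidence(
    peptide = c("SDEKLVR", "SDEKLVRAGKWTEYFDNAR", "MLSRR", "MLSRR"),
    protein = "PROT1",
    nterm_mod = c("dimethyl", "dimethyl", "acetyl", "dimethyl"),
    counts = list(c(3, 1, 0), c(2, 0, 0), c(1, 1, 1), c(4, 0, 0)))
  m <- map_and_classify(ev, db)
  u <- collapse_to_unique(m)
  expect_equal(nrow(u), 2)
  t11 <- u[u$start == 11, ]
  expect_equal(t11$total_spectral_count, 6L)
  expect_equal(t11$peptide_count, 2L)
  t1 <- u[u$start == 1, ]  # acetylated + dimethylated collapse to one record
  expect_equal(t1$peptide_count, 2L)
  expect_equal(t1$total_spectral_count, 7L)
  # the modification key option keeps them separate
  expect_equal(nrow(collapse_to_unique(m, include_mod_in_key = TRUE)), 3)
})

test_that("unique-terminus counting matches a distinct-key oracle at scale", {
  set.seed(7)
  # 1058 fragments spread over exactly 963 distinct (protein, start) keys
  keys <- tibble::tibble(
    protein = sprintf("P%03d", sample(1:214, 963, replace = TRUE)),
    start = 1:963)
  picks <- c(seq_len(963), sample(963, 1058 - 963, replace = TRUE))
  frags <- keys[picks, ]
  frags$category <- "unexpected"
  frags$is_mitochondrial <- TRUE
  frags$nterm_mod <- "dimethyl"
  frags$ambiguity_flag <- FALSE
  frags$ratio_hl_rep1 <- rnorm(nrow(frags))
  frags$spectral_count_rep1 <- rpois(nrow(frags), 3)
  u <- collapse_to_unique(frags)
  expect_equal(nrow(u), nrow(dplyr::distinct(frags[, c("protein", "start")])))
  expect_equal(nrow(u), 963)
  expect_equal(sum(u$peptide_count), 1058)
})

test_that("filter/classify/collapse are invariant under row permutation", {
  db <- example_protein_db()
  ev <- make_evidence(
    peptide = c("SDEKLVR", "SDEKLVRAGKWTEYFDNAR", "MLSRR", "QSTLVR", "AFSTASDEKLVR"),
    protein = "PROT1",
    nterm_mod = c("dimethyl", "dimethyl", "acetyl", "pyroglu_Q", "dimethyl"),
    counts = list(c(3, 1, 0), c(2, 0, 0), c(1, 1, 1), c(1, 0, 0), c(2, 2, 0)))
  pipeline <- function(e) {
    collapse_to_unique(map_and_classify(filter_evidence(e, db = db)$kept, db))
  }
  base <- pipeline(ev)
  set.seed(3)
  for (i in 1:5) expect_equal(pipeline(ev[sample(nrow(ev)), ]), base)
})

test_that("terminus categories agree with re-derived expected positions", {
  p <- generate_preset("tails-default", seed = 11)
  filt <- filter_evidence(p$evidence, db = p$db)
  u <- collapse_to_unique(map_and_classify(filt$kept, p$db, window = 5))
  exp_tbl <- expected_start_positions(p$db, window = 5)
  lookup <- setNames(exp_tbl$category, paste(exp_tbl$accession, exp_tbl$position))
  redo <- unname(lookup[paste(u$protein, u$start)])
  redo[is.na(redo)] <- "unexpected"
  expect_equal(u$category, redo)
})

test_that("ragging clusters follow the gap and prevalence rules", {
  t1 <- tibble::tibble(protein = "P1", start = c(11L, 12L, 13L, 21L),
                       total_spectral_count = c(5L, 2L, 1L, 7L))
  cl <- detect_ragging(t1, gap_max = 2)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$member_positions[[1]], c(11L, 12L, 13L))
  expect_equal(cl$most_prevalent_position, 11L)

  t2 <- tibble::tibble(protein = "P1", start = c(11L, 14L),
                       total_spectral_count = c(1L, 1L))
  expect_equal(nrow(detect_ragging(t2, gap_max = 2)), 0)

  t3 <- tibble::tibble(protein = "P1", start = c(11L, 12L),
                       total_spectral_count = c(2L, 2L))
  expect_equal(detect_ragging(t3)$most_prevalent_position, 11L)  # tie -> smaller
})
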