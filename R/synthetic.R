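# Synthetic-data generator with recorded ground truth. Emulates the
# statistical structure the analysis assumes: MTS maturation with the
# twin-Arg motif (Arg at P2, or at P3 after ICP55-style single-residue
# trimming with Phe/Tyr/Leu preference), ragged termini, a global log2
# shift of neo-termini between genotypes, strongly accumulating substrate
# termini and wt-specific (Arg-at-P1) depleted cleavages, log-normal ratio
# noise with spectral-count-dependent missingness, and a NEG/WT/TRAP LFQ
# matrix with intensity-dependent (MNAR) missing values.
#
# Draw order is fixed and documented per generator; each generator seeds
# its own stream (db: seed, TAILS: seed + 1, trap: seed + 2) so the three
# outputs are individually reproducible from one config.

.AA20 <- names(.RESIDUE_COMP)

#' Configuration for the synthetic-data generator
#'
#' All defaults define the simulated study conditions; every field can be
#' overridden by name. Probabilities are checked to lie in \[0, 1\].
#'
#' @param seed Integer seed; identical seeds give byte-identical outputs.
#' @param ... Named overrides of the defaults listed below.
#'
#' @return Object of class `synthetic_config` (a validated list).
#' @export
synthetic_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = as.integer(seed),
    # protein database
    n_proteins = 300,
    frac_mitochondrial = 0.7,
    protein_length_range = c(250L, 600L),
    mts_length_mean = 35, mts_length_sd = 10, mts_length_range = c(15, 80),
    mts_motif_probs = c(R_at_P2 = 0.6, R_at_P3 = 0.3, none = 0.1),
    icp55_trim_prob = 0.8,
    icp55_residues = c("F", "Y", "L"),
    mature_start_probs = c(S = 0.3, A = 0.25, T = 0.15, G = 0.1, M = 0.1),
    predicted_feature_prob = 0.2,
    # terminome
    window = 5,
    p1_terminus_prob = 0.3,
    met_removed_prob = 0.2,
    ragging_trim_prob = 0.35,
    neo_termini_rate = 3,
    protein_effect_sd = 0.15,
    expected_scatter_sd = 0.25,
    neo_scatter_sd = 0.25,
    global_shift_delta = 0.32,
    n_substrates = 10,
    substrate_accumulation = c(mean = 2.0, sd = 0.3),
    termini_per_substrate = 2,
    n_wt_cleaved = 10,
    wt_specific_cleavage = c(mean = -2.0, sd = 0.3),
    p1_arg_prob = 0.7,
    substrate_lfq_shift = 0.5,
    # measurement model
    n_reps = 3,
    ratio_noise_sd = 0.3,
    lambda_expected = 6, lambda_neo = 2, lambda_substrate = 3,
    missing_base = 0.5, missing_decay = 0.25, missing_max = 0.8,
    acetyl_prob = 0.1,
    lys_unlabeled_prob = 0.01,
    after_dimethyl_lys_prob = 0.03,
    missed_cleavage_prob = 0.15,
    reject_pyroglu_prob = 0.02,
    reject_lysend_prob = 0.03,
    lfq_noise_sd = 0.1,
    # trapping screen
    trap = list(n_null = 185, n_substrates = 10, substrate_shift = 3.0,
                n_interactors = 5, interactor_shift = 2.5,
                baseline_mean = 25, baseline_sd = 2, replicate_sd = 0.25,
                mnar_quantile = 0.15, mnar_prob = 0.8,
                frac_mitochondrial = 0.8)
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) {
    abort(paste0("unknown config field(s): ", paste(unknown, collapse = ", ")))
  }
  for (nm in names(dots)) {
    if (nm == "trap") {
      cfg$trap[names(dots$trap)] <- dots$trap
    } else cfg[[nm]] <- dots[[nm]]
  }
  probs <- c(cfg$frac_mitochondrial, cfg$mts_motif_probs, cfg$icp55_trim_prob,
             cfg$p1_terminus_prob, cfg$ragging_trim_prob, cfg$p1_arg_prob,
             cfg$missing_base, cfg$missing_max, cfg$acetyl_prob,
             cfg$trap$mnar_prob)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  if (abs(sum(cfg$mts_motif_probs) - 1) > 1e-8) {
    abort("mts_motif_probs must sum to 1")
  }
  structure(cfg, class = "synthetic_config")
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      x <- rnorm(1, mean, sd)
      if (x >= lo && x <= hi) break
    }
    out[i] <- x
  }
  out
}

sample_start_residue <- function(cfg) {
  p <- cfg$mature_start_probs
  other <- setdiff(.AA20, names(p))
  pool <- c(names(p), other)
  w <- c(p, rep((1 - sum(p)) / length(other), length(other)))
  sample(pool, 1, prob = w)
}

#' Generate a synthetic protein database
#'
#' Sequences are i.i.d. from a uniform background over the 20 standard
#' residues, except for planted signals at mitochondrial maturation sites:
#' the mature-start residue is drawn from a stabilizing-biased table
#' (S/A/T/G/M-rich), and Arg is planted at P2 or P3 relative to the mature
#' start per `mts_motif_probs` (twin-Arg motif); R-at-P3 proteins receive a
#' Phe/Tyr/Leu P1 residue with probability `icp55_trim_prob` (the residue
#' an ICP55-style aminopeptidase would have removed).
#'
#' Draw order per protein: length, MTS length, sequence, start residue,
#' motif class, ICP55 residue, evidence label.
#'
#' @param config A [synthetic_config()].
#' @param dir Optional output directory; writes `proteins.fasta` and
#'   `features.tsv`.
#'
#' @return List with `db` (a `protein_db`) and `truth` (tibble: `accession`,
#'   `is_mitochondrial`, `mature_start`, `motif`).
#' @export
generate_protein_db <- function(config, dir = NULL) {
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n_proteins
  n_mito <- round(n * cfg$frac_mitochondrial)
  acc <- sprintf("SYN%04d", seq_len(n))
  is_mito <- c(rep(TRUE, n_mito), rep(FALSE, n - n_mito))
  rows <- vector("list", n)
  feats <- vector("list", n)
  for (i in seq_len(n)) {
    len <- sample(seq(cfg$protein_length_range[1], cfg$protein_length_range[2]), 1)
    seq_chars <- sample(.AA20, len, replace = TRUE)
    seq_chars[1] <- "M"
    mature_start <- 1L
    motif <- NA_character_
    if (is_mito[i]) {
      mts_len <- round(rtrunc_norm(1, cfg$mts_length_mean, cfg$mts_length_sd,
                                   cfg$mts_length_range[1], cfg$mts_length_range[2]))
      mature_start <- as.integer(mts_len + 1)
      seq_chars[mature_start] <- sample_start_residue(cfg)
      motif <- sample(names(cfg$mts_motif_probs), 1, prob = cfg$mts_motif_probs)
      if (motif == "R_at_P2") {
        seq_chars[mature_start - 2] <- "R"
      } else if (motif == "R_at_P3") {
        seq_chars[mature_start - 3] <- "R"
        if (runif(1) < cfg$icp55_trim_prob) {
          seq_chars[mature_start - 1] <- sample(cfg$icp55_residues, 1)
        }
      }
      feats[[i]] <- tibble(
        accession = acc[i], feature_type = "MTS",
        start = 1L, end = mature_start - 1L,
        evidence = if (runif(1) < cfg$predicted_feature_prob) "predicted" else "annotated")
    }
    rows[[i]] <- tibble(accession = acc[i],
                        sequence = paste(seq_chars, collapse = ""),
                        is_mitochondrial = is_mito[i],
                        mature_start = mature_start,
                        motif = motif)
  }
  truth <- dplyr::bind_rows(rows)
  db <- protein_db(truth[, c("accession", "sequence", "is_mitochondrial")],
                   dplyr::bind_rows(feats))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_protein_db(db, file.path(dir, "proteins.fasta"),
                     file.path(dir, "features.tsv"))
  }
  list(db = db,
       truth = truth[, c("accession", "is_mitochondrial", "mature_start", "motif")])
}

# peptide from `start` to the next Arg at least min_len residues in; falls
# back to the protein C terminus when no Arg follows.
argC_peptide <- function(seq_chars, start, min_len = 4) {
  len <- length(seq_chars)
  rpos <- which(seq_chars == "R")
  rpos <- rpos[rpos >= start + min_len - 1]
  end <- if (length(rpos) > 0) rpos[1] else len
  paste(seq_chars[start:end], collapse = "")
}

miss_prob <- function(sc, cfg) {
  ifelse(sc == 0, 1, pmin(cfg$missing_max, cfg$missing_base * exp(-cfg$missing_decay * sc)))
}

#' Generate a synthetic TAILS experiment
#'
#' Plants termini on a synthetic protein database and simulates the duplex
#' dimethyl quantification: expected termini at maturation sites (with
#' ragging ladders), neo-termini at deep internal positions carrying a
#' global log2 shift (`global_shift_delta`), strongly accumulating
#' substrate termini, and depleted wt-specific cleavages with Arg planted
#' at P1. Observed per-replicate ratios are truth plus normal noise with
#' spectral-count-dependent missingness; a protein-level LFQ ratio table
#' with truth-derived significance flags accompanies the evidence.
#'
#' Draw order: substrate/wt-cleaved protein selection, then per protein:
#' abundance effect, expected termini (+ ragging), neo termini, substrate
#' termini, then per evidence row: modification, Lys labels, spectral
#' counts, ratio noise, missingness, then LFQ noise, then planted reject
#' rows.
#'
#' @param config A [synthetic_config()].
#' @param db_bundle Output of [generate_protein_db()] (same config).
#' @param dir Optional output directory; writes `evidence.tsv`,
#'   `protein_lfq.tsv`, `ground_truth.tsv`.
#'
#' @return List with `evidence`, `protein_lfq` and `ground_truth` tibbles.
#'   Ground truth has one row per evidence row (`row_id`).
#' @export
generate_tails_experiment <- function(config, db_bundle, dir = NULL) {
  cfg <- config
  db <- db_bundle$db
  truth <- db_bundle$truth
  set.seed(cfg$seed + 1L)
  n <- nrow(truth)
  mito_idx <- which(truth$is_mitochondrial)
  sub_idx <- sample(mito_idx, min(cfg$n_substrates, length(mito_idx)))
  wt_pool <- setdiff(mito_idx, sub_idx)
  wt_idx <- sample(wt_pool, min(cfg$n_wt_cleaved, length(wt_pool)))

  seq_list <- strsplit(db$proteins$sequence, "", fixed = TRUE)
  ev_rows <- vector("list", n)
  gt_rows <- vector("list", n)
  lfq_effect <- numeric(n)

  for (i in seq_len(n)) {
    sc <- seq_list[[i]]
    len <- length(sc)
    ms <- truth$mature_start[i]
    effect <- rnorm(1, 0, cfg$protein_effect_sd)
    role <- if (i %in% sub_idx) "accumulating" else if (i %in% wt_idx) "wt_cleaved" else "none"
    lfq_effect[i] <- effect +
      if (role == "accumulating") cfg$substrate_lfq_shift else
        if (role == "wt_cleaved") -cfg$substrate_lfq_shift else 0

    starts <- integer(0); cats <- character(0); truths <- numeric(0)
    tiers <- character(0); flags <- character(0)
    add <- function(s, cat, tr, tier, flag) {
      starts <<- c(starts, s); cats <<- c(cats, cat); truths <<- c(truths, tr)
      tiers <<- c(tiers, tier); flags <<- c(flags, flag)
    }
    # expected termini
    if (truth$is_mitochondrial[i] && ms > 1) {
      add(ms, "MTS", effect + rnorm(1, 0, cfg$expected_scatter_sd), "expected", "none")
      pos <- ms
      while (runif(1) < cfg$ragging_trim_prob && pos + 1 < len) {
        pos <- pos + 1L
        # a ladder can trim past the expected-position window, where the
        # terminus is by definition no longer an expected MTS terminus
        add(pos, if (pos - ms <= cfg$window) "MTS" else "unexpected",
            effect + rnorm(1, 0, cfg$expected_scatter_sd), "expected", "none")
      }
    }
    if (runif(1) < cfg$p1_terminus_prob) {
      s <- if (runif(1) < cfg$met_removed_prob) 2L else 1L
      add(s, "P1_2", effect + rnorm(1, 0, cfg$expected_scatter_sd), "expected", "none")
    }
    # deep-internal region: farther than `window` from any expected site
    deep_lo <- ms + cfg$window + 2L
    deep_hi <- len - 25L
    deep <- if (deep_hi >= deep_lo) seq.int(deep_lo, deep_hi) else integer(0)
    n_neo <- rpois(1, cfg$neo_termini_rate)
    if (n_neo > 0 && length(deep) > 0) {
      pos <- sample(deep, min(n_neo, length(deep)))
      for (p in pos) {
        add(p, "unexpected",
            effect + cfg$global_shift_delta + rnorm(1, 0, cfg$neo_scatter_sd),
            "neo", "none")
      }
    }
    if (role == "accumulating" && length(deep) > 0) {
      pos <- sample(setdiff(deep, starts), min(cfg$termini_per_substrate, length(deep)))
      for (p in pos) {
        add(p, "unexpected",
            effect + rnorm(1, cfg$substrate_accumulation["mean"],
                           cfg$substrate_accumulation["sd"]),
            "substrate", "accumulating")
      }
    }
    if (role == "wt_cleaved" && length(deep) > 0) {
      after_r <- intersect(deep, which(sc == "R") + 1L)
      for (k in seq_len(cfg$termini_per_substrate)) {
        cand <- setdiff(if (runif(1) < cfg$p1_arg_prob && length(after_r) > 0) {
          after_r
        } else deep, starts)
        if (length(cand) == 0) next
        p <- cand[sample.int(length(cand), 1)]
        add(p, "unexpected",
            effect + rnorm(1, cfg$wt_specific_cleavage["mean"],
                           cfg$wt_specific_cleavage["sd"]),
            "substrate", "wt_cleaved")
      }
    }
    if (length(starts) == 0) next
    # evidence rows per terminus (+ occasional missed-cleavage variant)
    pep_rows <- vector("list", length(starts))
    for (t in seq_along(starts)) {
      pep <- argC_peptide(sc, starts[t])
      peps <- pep
      if (runif(1) < cfg$missed_cleavage_prob) {
        ext_start <- starts[t] + nchar(pep)
        if (ext_start <= len) {
          peps <- c(peps, paste0(pep, argC_peptide(sc, ext_start, min_len = 1)))
        }
      }
      lambda <- switch(tiers[t], expected = cfg$lambda_expected,
                       neo = cfg$lambda_neo, cfg$lambda_substrate)
      sub_rows <- vector("list", length(peps))
      for (j in seq_along(peps)) {
        p <- peps[j]
        nterm <- if (tiers[t] == "expected" && runif(1) < cfg$acetyl_prob) {
          "acetyl"
        } else "dimethyl"
        if (substring(p, 1, 1) == "P" && nterm == "dimethyl") nterm <- "free"
        n_k <- sum(strsplit(p, "", fixed = TRUE)[[1]] == "K")
        lys <- if (n_k > 0) {
          paste(ifelse(runif(n_k) < cfg$lys_unlabeled_prob, "unmodified",
                       sample(c("dimethyl_light", "dimethyl_heavy"), n_k,
                              replace = TRUE)),
                collapse = ";")
        } else ""
        counts <- rpois(cfg$n_reps, lambda)
        if (all(counts == 0)) counts[1] <- 1L
        ratios <- truths[t] + rnorm(cfg$n_reps, 0, cfg$ratio_noise_sd)
        ratios[runif(cfg$n_reps) < miss_prob(counts, cfg)] <- NA_real_
        row <- tibble(peptide = p, protein = truth$accession[i],
                      nterm_mod = nterm, lys_mods = lys,
                      after_dimethyl_lys = runif(1) < cfg$after_dimethyl_lys_prob)
        for (r in seq_len(cfg$n_reps)) {
          row[[paste0("ratio_hl_rep", r)]] <- ratios[r]
          row[[paste0("spectral_count_rep", r)]] <- counts[r]
        }
        sub_rows[[j]] <- row
      }
      pep_rows[[t]] <- dplyr::bind_rows(sub_rows)
    }
    n_pep <- vapply(pep_rows, nrow, integer(1))
    ev_rows[[i]] <- dplyr::bind_rows(pep_rows)
    gt_rows[[i]] <- tibble(protein = truth$accession[i],
                           start = rep(starts, n_pep),
                           true_category = rep(cats, n_pep),
                           true_log2 = rep(truths, n_pep),
                           substrate_flag = rep(flags, n_pep),
                           planted_reject = NA_character_)
  }
  evidence <- dplyr::bind_rows(ev_rows)
  ground_truth <- dplyr::bind_rows(gt_rows)

  # protein LFQ table (truth-derived significance flags)
  protein_lfq <- tibble(
    accession = truth$accession,
    log2_ratio = lfq_effect + rnorm(n, 0, cfg$lfq_noise_sd),
    significant_flag = seq_len(n) %in% c(sub_idx, wt_idx))

  # planted reject rows: pyroglutamate peptides and Lys-ended peptides
  n_rej_py <- round(cfg$reject_pyroglu_prob * nrow(evidence))
  n_rej_k <- round(cfg$reject_lysend_prob * nrow(evidence))
  rej <- vector("list", n_rej_py + n_rej_k)
  for (j in seq_len(n_rej_py + n_rej_k)) {
    i <- sample(n, 1)
    sc <- seq_list[[i]]
    len <- length(sc)
    s <- sample(seq.int(3L, len - 30L), 1)
    pep <- argC_peptide(sc, s)
    kind <- if (j <= n_rej_py) "pyroglu" else "no_cterm_arg"
    if (kind == "no_cterm_arg") {
      kpos <- which(strsplit(pep, "", fixed = TRUE)[[1]] == "K")
      kpos <- kpos[kpos >= 4 & kpos < nchar(pep)]
      pep <- if (length(kpos) > 0) substring(pep, 1, kpos[1]) else
        substring(pep, 1, nchar(pep) - 1)  # drop the C-terminal Arg
    }
    nterm <- if (kind == "pyroglu") {
      sample(c("pyroglu_E", "pyroglu_Q"), 1)
    } else "dimethyl"
    n_k <- sum(strsplit(pep, "", fixed = TRUE)[[1]] == "K")
    row <- tibble(peptide = pep, protein = truth$accession[i],
                  nterm_mod = nterm,
                  lys_mods = if (n_k > 0) {
                    paste(rep("dimethyl_light", n_k), collapse = ";")
                  } else "",
                  after_dimethyl_lys = FALSE)
    counts <- rpois(cfg$n_reps, 1) + 1L
    ratios <- rnorm(cfg$n_reps, 0, cfg$ratio_noise_sd)
    for (r in seq_len(cfg$n_reps)) {
      row[[paste0("ratio_hl_rep", r)]] <- ratios[r]
      row[[paste0("spectral_count_rep", r)]] <- counts[r]
    }
    rej[[j]] <- list(row = row,
                     gt = tibble(protein = truth$accession[i], start = s,
                                 true_category = NA_character_,
                                 true_log2 = NA_real_,
                                 substrate_flag = "none",
                                 planted_reject = kind))
  }
  if (length(rej) > 0) {
    evidence <- dplyr::bind_rows(evidence, dplyr::bind_rows(purrr::map(rej, "row")))
    ground_truth <- dplyr::bind_rows(ground_truth,
                                     dplyr::bind_rows(purrr::map(rej, "gt")))
  }
  evidence$row_id <- seq_len(nrow(evidence))
  ground_truth$row_id <- seq_len(nrow(ground_truth))
  evidence <- dplyr::relocate(evidence, "row_id")
  ground_truth <- dplyr::relocate(ground_truth, "row_id")

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(evidence, file.path(dir, "evidence.tsv"))
    readr::write_tsv(protein_lfq, file.path(dir, "protein_lfq.tsv"))
    readr::write_tsv(ground_truth, file.path(dir, "ground_truth.tsv"))
  }
  list(evidence = evidence, protein_lfq = protein_lfq,
       ground_truth = ground_truth)
}

#' Generate a synthetic substrate-trapping LFQ matrix
#'
#' Baseline log2 intensities are drawn per protein from
#' `Normal(baseline_mean, baseline_sd)`; spiked substrates are shifted up
#' in TRAP only, interactors in both WT and TRAP. Values below the
#' `mnar_quantile` quantile of the full matrix are set missing with
#' probability `mnar_prob` (intensity-dependent missingness).
#'
#' Draw order: baselines, replicate noise (protein-major), MNAR mask.
#'
#' @param config A [synthetic_config()] (fields under `trap`).
#' @param dir Optional output directory; writes `trap_proteingroups.tsv`
#'   and `trap_ground_truth.tsv`.
#'
#' @return List with `trap` (intensity tibble) and `truth`
#'   (`accession`, `class` in null/substrate/interactor).
#' @export
generate_trap_experiment <- function(config, dir = NULL) {
  cfg <- config$trap
  n_reps <- config$n_reps
  set.seed(config$seed + 2L)
  n <- cfg$n_null + cfg$n_substrates + cfg$n_interactors
  cls <- c(rep("substrate", cfg$n_substrates),
           rep("interactor", cfg$n_interactors),
           rep("null", cfg$n_null))
  acc <- sprintf("TRAP%04d", seq_len(n))
  is_mito <- cls != "null" | runif(n) < cfg$frac_mitochondrial
  baseline <- rnorm(n, cfg$baseline_mean, cfg$baseline_sd)
  shift <- cbind(NEG = rep(0, n),
                 WT = ifelse(cls == "interactor", cfg$interactor_shift, 0),
                 TRAP = ifelse(cls == "substrate", cfg$substrate_shift,
                               ifelse(cls == "interactor", cfg$interactor_shift, 0)))
  m <- matrix(NA_real_, n, 3 * n_reps,
              dimnames = list(NULL, trap_intensity_cols(n_reps)))
  for (i in seq_len(n)) {
    for (ci in seq_along(.TRAP_CONDITIONS)) {
      cols <- paste0(.TRAP_CONDITIONS[ci], "_", seq_len(n_reps))
      m[i, cols] <- baseline[i] + shift[i, ci] + rnorm(n_reps, 0, cfg$replicate_sd)
    }
  }
  thr <- quantile(m, cfg$mnar_quantile, type = 7)
  drop <- m < thr & matrix(runif(length(m)), nrow(m)) < cfg$mnar_prob
  # a protein with no observed intensity at all would not appear in the
  # report table; keep its strongest measurement
  fully <- rowSums(!drop) == 0
  if (any(fully)) {
    keep_col <- max.col(m[fully, , drop = FALSE])
    drop[cbind(which(fully), keep_col)] <- FALSE
  }
  m[drop] <- NA_real_
  trap <- dplyr::bind_cols(tibble(accession = acc, is_mitochondrial = is_mito),
                           as_tibble(m))
  truth <- tibble(accession = acc, class = cls)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(trap, file.path(dir, "trap_proteingroups.tsv"))
    readr::write_tsv(truth, file.path(dir, "trap_ground_truth.tsv"))
  }
  list(trap = trap, truth = truth)
}

#' Generate a named preset dataset
#'
#' Convenience wrapper bundling the generator calls:
#' \describe{
#'   \item{`tails-default`}{protein database + TAILS experiment with all
#'     planted effects at their default sizes.}
#'   \item{`tails-null`}{as above with the global shift and all substrate
#'     termini removed.}
#'   \item{`trap-default`}{trapping matrix with 10 spiked substrates and 5
#'     interactors.}
#'   \item{`trap-null`}{trapping matrix with no planted effects.}
#' }
#'
#' @param preset Preset name.
#' @param seed Integer seed.
#' @param dir Optional output directory for the emitted files.
#'
#' @return The corresponding generator bundle (see
#'   [generate_tails_experiment()] / [generate_trap_experiment()]); TAILS
#'   presets also carry `db` and `truth`.
#' @export
generate_preset <- function(preset = c("tails-default", "tails-null",
                                       "trap-default", "trap-null"),
                            seed = 1, dir = NULL) {
  preset <- match.arg(preset)
  if (preset %in% c("tails-default", "tails-null")) {
    cfg <- if (preset == "tails-null") {
      synthetic_config(seed = seed, global_shift_delta = 0,
                       n_substrates = 0, n_wt_cleaved = 0)
    } else synthetic_config(seed = seed)
    dbb <- generate_protein_db(cfg, dir = dir)
    out <- generate_tails_experiment(cfg, dbb, dir = dir)
    c(dbb, out, list(config = cfg))
  } else {
    cfg <- if (preset == "trap-null") {
      synthetic_config(seed = seed, trap = list(n_substrates = 0, n_interactors = 0))
    } else synthetic_config(seed = seed)
    c(generate_trap_experiment(cfg, dir = dir), list(config = cfg))
  }
}
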