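# End-to-end orchestration of the two workflows. Inputs may be in-memory
# objects or file paths; when an output directory is given, every result
# table is written as TSV alongside a summary JSON and the effective
# configuration as YAML, so a run is reproducible from its archived config.

tails_effective_config <- function(window, min_reps, cutoff_k,
                                   fixed_cutoff_magnitude, logo_alpha,
                                   gap_max, n_left, n_right) {
  list(window = window, min_reps = min_reps, cutoff_k = cutoff_k,
       fixed_cutoff_magnitude = fixed_cutoff_magnitude,
       logo_alpha = logo_alpha, gap_max = gap_max,
       logo_n_left = n_left, logo_n_right = n_right)
}

#' Run the full TAILS terminome workflow
#'
#' Executes filter, map/classify, collapse, normalize, aggregate,
#' expected-vs-unexpected comparison, cutoff derivation, differential
#' calling, cleavage-logo enrichment, ragging detection and protein-level
#' correlation in order.
#'
#' The cutoff reference set comprises quantified termini mapping to
#' proteins whose `significant_flag` in `protein_lfq` is `FALSE`; passing
#' `fixed_cutoff_magnitude` overrides it with fixed symmetric bounds.
#'
#' @param db A `protein_db`, or a list of `fasta` and `features` paths.
#' @param evidence Evidence tibble or TSV path.
#' @param protein_lfq Protein LFQ tibble (columns `accession`,
#'   `log2_ratio`, `significant_flag`) or TSV path.
#' @param window Expected-position tolerance (default 5).
#' @param min_reps Minimum quantified replicates (default 2).
#' @param cutoff_k IQR multiplier for the derived cutoff (default 1.5).
#' @param fixed_cutoff_magnitude If non-`NULL`, use fixed symmetric bounds
#'   of this half-width instead of deriving them.
#' @param logo_alpha Significance level for positional enrichment.
#' @param gap_max Ragging gap tolerance.
#' @param n_left,n_right Cleavage-window widths.
#' @param out_dir Optional output directory.
#'
#' @return Object of class `tails_run`: a list with `qc`, `rejected`,
#'   `termini`, `quantified`, `comparison`, `cutoff`, `call_summary`,
#'   `category_counts`, `ragging`, `correlation`, `logo_expected_mts`,
#'   `logo_depleted_neo`, `config`.
#' @export
run_tails <- function(db, evidence, protein_lfq, window = 5, min_reps = 2,
                      cutoff_k = 1.5, fixed_cutoff_magnitude = NULL,
                      logo_alpha = 0.05, gap_max = 2, n_left = 5, n_right = 5,
                      out_dir = NULL) {
  if (!inherits(db, "protein_db")) {
    db <- load_protein_db(db$fasta, db$features)
  }
  if (is.character(evidence)) evidence <- read_evidence_table(evidence)
  if (is.character(protein_lfq)) {
    protein_lfq <- readr::read_tsv(protein_lfq, show_col_types = FALSE,
                                   progress = FALSE)
  }
  qc <- labeling_qc(evidence)
  filt <- filter_evidence(evidence, db = db)
  mapped <- map_and_classify(filt$kept, db, window = window)
  termini <- collapse_to_unique(mapped)
  normed <- normalize_ratios(termini)
  quantified <- aggregate_replicates(normed, min_reps = min_reps)

  is_unexp <- quantified$category == "unexpected"
  comparison <- compare_class_distributions(
    expected = quantified$mean_norm_log2[!is_unexp],
    unexpected = quantified$mean_norm_log2[is_unexp])

  cutoff <- if (!is.null(fixed_cutoff_magnitude)) {
    fixed_cutoff(fixed_cutoff_magnitude)
  } else {
    unchanged_prot <- protein_lfq$accession[!protein_lfq$significant_flag]
    ref <- quantified$mean_norm_log2[quantified$protein %in% unchanged_prot]
    derive_cutoff(ref, k = cutoff_k)
  }
  quantified <- call_differential_termini(quantified, cutoff)

  ref_freq <- reference_frequencies(db, "mitochondrial_only")
  mts_termini <- dplyr::filter(quantified, .data$category == "MTS")
  logo_mts <- if (nrow(mts_termini) > 0) {
    position_enrichment(
      extract_cleavage_windows(mts_termini, db, n_left, n_right),
      ref_freq, alpha = logo_alpha)
  } else NULL
  depleted_neo <- dplyr::filter(quantified, .data$category == "unexpected",
                                .data$diff_call == "depleted")
  logo_depleted <- if (nrow(depleted_neo) > 0) {
    position_enrichment(
      extract_cleavage_windows(depleted_neo, db, n_left, n_right),
      ref_freq, alpha = logo_alpha)
  } else NULL

  out <- structure(
    list(qc = qc,
         rejected = filt$rejected,
         termini = termini,
         quantified = quantified,
         comparison = comparison,
         cutoff = cutoff,
         call_summary = call_summary(quantified),
         category_counts = category_counts(termini),
         ragging = detect_ragging(termini, gap_max = gap_max),
         correlation = correlate_with_protein_abundance(quantified, protein_lfq),
         logo_expected_mts = logo_mts,
         logo_depleted_neo = logo_depleted,
         config = tails_effective_config(window, min_reps, cutoff_k,
                                         fixed_cutoff_magnitude, logo_alpha,
                                         gap_max, n_left, n_right)),
    class = "tails_run")
  if (!is.null(out_dir)) write_tails_run(out, out_dir)
  out
}

#' @export
print.tails_run <- function(x, ...) {
  cat("<tails_run> ", nrow(x$termini), " unique termini; ",
      sum(x$quantified$diff_call != "not_quantified"), " quantified\n", sep = "")
  print(x$comparison)
  print(x$cutoff)
  invisible(x)
}

#' @rdname run_tails
#' @param x A `tails_run` object.
#' @param ... Unused.
#' @export
glance.tails_run <- function(x, ...) {
  cs <- x$call_summary
  get_n <- function(cls, call) {
    v <- cs[[call]][cs$class == cls]
    if (length(v) == 0) 0L else as.integer(v)
  }
  tibble(
    n_unique_termini = nrow(x$termini),
    n_quantified = sum(x$quantified$diff_call != "not_quantified"),
    delta_median = x$comparison$delta_median,
    mw_p = x$comparison$p_two_sided,
    cutoff_lower = x$cutoff$lower,
    cutoff_upper = x$cutoff$upper,
    n_expected_accumulating = get_n("expected", "accumulating"),
    n_unexpected_accumulating = get_n("unexpected", "accumulating"),
    n_expected_depleted = get_n("expected", "depleted"),
    n_unexpected_depleted = get_n("unexpected", "depleted")
  )
}

run_summary_list <- function(x) {
  list(
    qc = as.list(x$qc),
    n_rejected = nrow(x$rejected),
    n_unique_termini = nrow(x$termini),
    n_quantified = sum(x$quantified$diff_call != "not_quantified"),
    category_counts = as.list(setNames(x$category_counts$n,
                                       x$category_counts$category)),
    comparison = unclass(tidy(x$comparison)),
    cutoff = list(lower = x$cutoff$lower, upper = x$cutoff$upper,
                  method = x$cutoff$method, reference_n = x$cutoff$reference_n),
    call_table = x$call_summary,
    correlation = x$correlation,
    n_ragging_clusters = nrow(x$ragging)
  )
}

write_tails_run <- function(x, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(x$quantified, file.path(out_dir, "termini_quantified.tsv"))
  readr::write_tsv(x$rejected, file.path(out_dir, "peptides_rejected.tsv"))
  readr::write_tsv(x$call_summary, file.path(out_dir, "call_summary.tsv"))
  readr::write_tsv(x$category_counts, file.path(out_dir, "category_counts.tsv"))
  readr::write_tsv(x$correlation, file.path(out_dir, "correlation.tsv"))
  rag <- x$ragging |>
    dplyr::mutate(member_positions = purrr::map_chr(.data$member_positions,
                                                    paste, collapse = ";"),
                  prevalence_counts = purrr::map_chr(.data$prevalence_counts,
                                                     paste, collapse = ";"))
  readr::write_tsv(rag, file.path(out_dir, "ragging_clusters.tsv"))
  if (!is.null(x$logo_expected_mts)) {
    readr::write_tsv(as_tibble(x$logo_expected_mts),
                     file.path(out_dir, "logo_expected_mts.tsv"))
  }
  if (!is.null(x$logo_depleted_neo)) {
    readr::write_tsv(as_tibble(x$logo_depleted_neo),
                     file.path(out_dir, "logo_depleted_neo.tsv"))
  }
  jsonlite::write_json(run_summary_list(x), file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  yaml::write_yaml(x$config, file.path(out_dir, "config.yaml"))
  invisible(x)
}

#' Run the substrate-trapping workflow
#'
#' Imputation, per-protein ANOVA + BH, Tukey post-hoc tests and hit
#' classification (see [trap_analysis()]), with optional result-file
#' output: hit table, presence/absence table, Fig-5D-style scatter data,
#' summary JSON and effective config YAML.
#'
#' @inheritParams trap_analysis
#' @param out_dir Optional output directory.
#' @return A `trap_fit` object.
#' @export
run_trap <- function(trap, width = 0.3, downshift = 1.8, seed = 1,
                     q_thresh = 0.05, p_thresh = 0.05, n_reps = 3,
                     out_dir = NULL) {
  fit <- trap_analysis(trap, width = width, downshift = downshift, seed = seed,
                       q_thresh = q_thresh, p_thresh = p_thresh, n_reps = n_reps)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(fit$hits, file.path(out_dir, "trap_hits.tsv"))
    readr::write_tsv(fit$presence_absence,
                     file.path(out_dir, "presence_absence.tsv"))
    readr::write_tsv(fit$scatter, file.path(out_dir, "trap_scatter.tsv"))
    jsonlite::write_json(as.list(glance(fit)), file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    yaml::write_yaml(fit$params, file.path(out_dir, "config.yaml"))
  }
  fit
}
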