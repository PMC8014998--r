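# Substrate-trapping screen statistics: MNAR-aware imputation of missing
# label-free intensities, per-protein one-way ANOVA with BH correction,
# Tukey HSD post-hoc tests, and three-way hit classification against the
# negative control (NEG), active protease (WT) and trapping mutant (TRAP).

.TRAP_CONDITIONS <- c("NEG", "WT", "TRAP")

trap_intensity_cols <- function(n_reps = 3) {
  unlist(lapply(.TRAP_CONDITIONS, function(cd) paste0(cd, "_", seq_len(n_reps))))
}

validate_trap_table <- function(trap, n_reps = 3) {
  trap <- as_tibble(trap)
  cols <- trap_intensity_cols(n_reps)
  missing_cols <- setdiff(c("accession", cols), names(trap))
  if (length(missing_cols) > 0) {
    abort(paste0("trap table lacks column(s): ",
                 paste(missing_cols, collapse = ", "),
                 " (expected accession, is_mitochondrial, ",
                 "NEG_1..", n_reps, ", WT_1..", n_reps, ", TRAP_1..", n_reps, ")"))
  }
  if (!"is_mitochondrial" %in% names(trap)) trap$is_mitochondrial <- NA
  for (cl in cols) trap[[cl]] <- as.numeric(trap[[cl]])
  trap
}

#' Read a proteinGroups-style trapping intensity table
#'
#' Tab-separated table with columns `accession`, `is_mitochondrial` and
#' log2 LFQ intensities `NEG_1..3`, `WT_1..3`, `TRAP_1..3` (empty cells are
#' missing values).
#'
#' @param path Path to the TSV.
#' @param n_reps Replicates per condition (default 3).
#' @return Validated tibble.
#' @export
read_trap_table <- function(path, n_reps = 3) {
  if (!file.exists(path)) abort(paste0("trap table not found: ", path))
  validate_trap_table(
    readr::read_tsv(path, show_col_types = FALSE, na = c("", "NA", "NaN"),
                    progress = FALSE),
    n_reps = n_reps)
}

#' Impute missing intensities from a downshifted normal
#'
#' Missing label-free intensities are predominantly low-abundance censoring
#' (missing not at random), so missing cells are drawn per column from a
#' normal distribution shifted below the observed distribution:
#' `Normal(mean - downshift * sd, (width * sd)^2)` of the column's observed
#' values (Perseus-style defaults).
#'
#' @param trap Trap intensity tibble (see [read_trap_table()]).
#' @param width Imputation width as a fraction of the column sd
#'   (default 0.3).
#' @param downshift Downshift in column sd units (default 1.8).
#' @param seed Integer seed; the same seed reproduces the imputation
#'   exactly.
#' @param n_reps Replicates per condition.
#'
#' @return List with `data` (imputed tibble) and `mask` (logical tibble
#'   marking imputed cells).
#' @export
impute_missing <- function(trap, width = 0.3, downshift = 1.8, seed = 1,
                           n_reps = 3) {
  trap <- validate_trap_table(trap, n_reps)
  cols <- trap_intensity_cols(n_reps)
  mask <- trap[, cols]
  set.seed(seed)
  for (cl in cols) {
    v <- trap[[cl]]
    obs <- v[!is.na(v)]
    if (length(obs) == 0) abort(paste0("column ", cl, " is fully missing"))
    if (length(obs) < 2) abort(paste0("column ", cl, " has fewer than 2 observed values"))
    miss <- is.na(v)
    mask[[cl]] <- miss
    if (any(miss)) {
      v[miss] <- rnorm(sum(miss),
                       mean = mean(obs) - downshift * sd(obs),
                       sd = width * sd(obs))
      trap[[cl]] <- v
    }
  }
  list(data = trap, mask = mask)
}

trap_groups <- function(row_values, n_reps = 3) {
  split(row_values, rep(.TRAP_CONDITIONS, each = n_reps))[.TRAP_CONDITIONS]
}

#' Per-protein one-way ANOVA with BH correction
#'
#' Tests each protein for differential abundance across the NEG, WT and
#' TRAP conditions by one-way ANOVA on (imputed) log2 intensities;
#' q-values are Benjamini-Hochberg adjusted across all tested proteins. A
#' protein with zero variance within and between groups receives p = 1 by
#' convention.
#'
#' @param imputed Imputed trap tibble (the `data` element of
#'   [impute_missing()]).
#' @param n_reps Replicates per condition.
#'
#' @return Tibble with `accession`, `f`, `p`, `q`.
#' @export
trap_anova <- function(imputed, n_reps = 3) {
  imputed <- validate_trap_table(imputed, n_reps)
  cols <- trap_intensity_cols(n_reps)
  m <- as.matrix(imputed[, cols])
  stats_list <- apply(m, 1, function(row) {
    fit <- oneway_anova_stats(trap_groups(row, n_reps))
    c(f = fit$f, p = fit$p)
  })
  out <- tibble(accession = imputed$accession,
                f = stats_list["f", ], p = stats_list["p", ])
  out$q <- p.adjust(out$p, method = "BH")
  out
}

#' Tukey HSD post-hoc tests per protein
#'
#' Pairwise studentized-range tests for the three condition contrasts
#' (`TRAP-WT`, `TRAP-NEG`, `WT-NEG`) using the pooled within-group mean
#' square of the same one-way fit.
#'
#' @param imputed Imputed trap tibble.
#' @param accessions Optional subset (typically ANOVA-significant proteins);
#'   default all.
#' @param n_reps Replicates per condition.
#'
#' @return Tibble with `accession`, `tukey_p_trap_wt`, `tukey_p_trap_neg`,
#'   `tukey_p_wt_neg`.
#' @export
tukey_posthoc <- function(imputed, accessions = NULL, n_reps = 3) {
  imputed <- validate_trap_table(imputed, n_reps)
  if (!is.null(accessions)) {
    imputed <- imputed[imputed$accession %in% accessions, , drop = FALSE]
  }
  cols <- trap_intensity_cols(n_reps)
  m <- as.matrix(imputed[, cols])
  ps <- apply(m, 1, function(row) {
    fit <- oneway_anova_stats(trap_groups(row, n_reps))
    p <- tukey_pair_p(fit)
    c(trap_wt = unname(p["TRAP-WT"]), trap_neg = unname(p["TRAP-NEG"]),
      wt_neg = unname(p["WT-NEG"]))
  })
  tibble(accession = imputed$accession,
         tukey_p_trap_wt = ps["trap_wt", ],
         tukey_p_trap_neg = ps["trap_neg", ],
         tukey_p_wt_neg = ps["wt_neg", ])
}

condition_means <- function(tbl, n_reps = 3, observed_only_from = NULL) {
  out <- list()
  for (cd in .TRAP_CONDITIONS) {
    cols <- paste0(cd, "_", seq_len(n_reps))
    m <- as.matrix(tbl[, cols])
    if (!is.null(observed_only_from)) {
      m[as.matrix(observed_only_from[, cols])] <- NA
    }
    out[[cd]] <- rowMeans(m, na.rm = TRUE)
  }
  out
}

#' Classify trapping-screen hits
#'
#' Three-way classification of each protein from its ANOVA q-value, Tukey
#' pair p-values and condition mean directions:
#' \describe{
#'   \item{high_confidence}{`q < q_thresh`, TRAP vs WT significant, and
#'     TRAP mean above WT mean — substrate retained by the trapping mutant
#'     but degraded by the active protease.}
#'   \item{putative}{otherwise `q < q_thresh`, TRAP vs NEG significant and
#'     TRAP above NEG — enriched over background but not discriminated from
#'     the active protease.}
#'   \item{wt_interactor}{otherwise `q < q_thresh`, WT vs NEG significant
#'     and WT above NEG — binds the active protease.}
#'   \item{not_significant}{everything else.}
#' }
#'
#' @param anova_tbl Output of [trap_anova()].
#' @param tukey_tbl Output of [tukey_posthoc()] covering the same proteins.
#' @param means Named list of condition mean vectors (`NEG`, `WT`, `TRAP`)
#'   aligned with `anova_tbl` rows.
#' @param q_thresh,p_thresh Significance thresholds (default 0.05).
#'
#' @return Tibble `accession`, `hit_class`.
#' @export
classify_trap_hits <- function(anova_tbl, tukey_tbl, means,
                               q_thresh = 0.05, p_thresh = 0.05) {
  d <- dplyr::left_join(anova_tbl, tukey_tbl, by = "accession")
  sig <- d$q < q_thresh
  hc <- sig & d$tukey_p_trap_wt < p_thresh & means$TRAP > means$WT
  put <- sig & !hc & d$tukey_p_trap_neg < p_thresh & means$TRAP > means$NEG
  wti <- sig & !hc & !put & d$tukey_p_wt_neg < p_thresh & means$WT > means$NEG
  tibble(
    accession = d$accession,
    hit_class = dplyr::case_when(hc ~ "high_confidence",
                                 put ~ "putative",
                                 wti ~ "wt_interactor",
                                 TRUE ~ "not_significant")
  )
}

#' Presence/absence companion table
#'
#' Proteins consistently detected in one condition but never in another can
#' be missed by imputation + ANOVA; they are reported separately.
#'
#' @param trap Raw (unimputed) trap tibble.
#' @param min_present Minimum observed replicates to count a condition as
#'   present (default 2).
#' @param n_reps Replicates per condition.
#'
#' @return Tibble `accession`, `condition_present`, `n_present`,
#'   `conditions_absent` for qualifying proteins.
#' @export
presence_absence_table <- function(trap, min_present = 2, n_reps = 3) {
  trap <- validate_trap_table(trap, n_reps)
  det <- sapply(.TRAP_CONDITIONS, function(cd) {
    rowSums(!is.na(as.matrix(trap[, paste0(cd, "_", seq_len(n_reps))])))
  })
  rows <- purrr::map_dfr(seq_len(nrow(trap)), function(i) {
    present <- .TRAP_CONDITIONS[det[i, ] >= min_present]
    absent <- .TRAP_CONDITIONS[det[i, ] == 0]
    if (length(present) == 0 || length(absent) == 0) return(NULL)
    tibble(accession = trap$accession[i],
           condition_present = paste(present, collapse = ";"),
           n_present = max(det[i, ]),
           conditions_absent = paste(absent, collapse = ";"))
  })
  if (nrow(rows) == 0) {
    tibble(accession = character(), condition_present = character(),
           n_present = integer(), conditions_absent = character())
  } else rows
}

#' Full substrate-trapping analysis
#'
#' Runs the complete trapping workflow: downshifted-normal imputation,
#' per-protein ANOVA with BH correction, Tukey post-hoc tests, hit
#' classification, presence/absence screening, and assembly of scatter
#' data (log2 TRAP/NEG vs log2 WT/NEG on observed values).
#'
#' @param trap Raw trap tibble or path to a trap TSV.
#' @param width,downshift,seed Imputation parameters (see
#'   [impute_missing()]).
#' @param q_thresh,p_thresh Classification thresholds.
#' @param n_reps Replicates per condition.
#'
#' @return Object of class `trap_fit` with elements `hits` (per-protein
#'   statistics and classes), `presence_absence`, `scatter`, `mask`,
#'   `params`. Supports [tidy()], [glance()] and [autoplot()].
#' @export
trap_analysis <- function(trap, width = 0.3, downshift = 1.8, seed = 1,
                          q_thresh = 0.05, p_thresh = 0.05, n_reps = 3) {
  if (is.character(trap)) trap <- read_trap_table(trap, n_reps)
  trap <- validate_trap_table(trap, n_reps)
  imp <- impute_missing(trap, width = width, downshift = downshift,
                        seed = seed, n_reps = n_reps)
  anova_tbl <- trap_anova(imp$data, n_reps)
  tukey_tbl <- tukey_posthoc(imp$data, n_reps = n_reps)
  means_imp <- condition_means(imp$data, n_reps)
  means_obs <- condition_means(imp$data, n_reps, observed_only_from = imp$mask)
  classes <- classify_trap_hits(anova_tbl, tukey_tbl, means_imp,
                                q_thresh = q_thresh, p_thresh = p_thresh)
  det <- sapply(.TRAP_CONDITIONS, function(cd) {
    rowSums(!is.na(as.matrix(trap[, paste0(cd, "_", seq_len(n_reps))])))
  })
  hits <- anova_tbl |>
    dplyr::left_join(tukey_tbl, by = "accession") |>
    dplyr::left_join(classes, by = "accession") |>
    dplyr::mutate(
      is_mitochondrial = trap$is_mitochondrial,
      n_detected_neg = det[, "NEG"], n_detected_wt = det[, "WT"],
      n_detected_trap = det[, "TRAP"],
      # headline enrichments on observed values only; imputed cells are used
      # in the test but excluded here to avoid imputation-inflated folds
      log2_trap_wt = means_obs$TRAP - means_obs$WT,
      log2_trap_neg = means_obs$TRAP - means_obs$NEG,
      log2_wt_neg = means_obs$WT - means_obs$NEG,
      log2_trap_wt_imputed = means_imp$TRAP - means_imp$WT,
      log2_trap_neg_imputed = means_imp$TRAP - means_imp$NEG,
      log2_wt_neg_imputed = means_imp$WT - means_imp$NEG)
  scatter <- tibble(accession = hits$accession,
                    log2_trap_neg = hits$log2_trap_neg,
                    log2_wt_neg = hits$log2_wt_neg,
                    hit_class = hits$hit_class)
  structure(
    list(hits = hits,
         presence_absence = presence_absence_table(trap, n_reps = n_reps),
         scatter = scatter,
         mask = imp$mask,
         params = list(width = width, downshift = downshift, seed = seed,
                       q_thresh = q_thresh, p_thresh = p_thresh,
                       n_reps = n_reps)),
    class = "trap_fit"
  )
}

#' @export
print.trap_fit <- function(x, ...) {
  tab <- table(x$hits$hit_class)
  cat("<trap_fit> ", nrow(x$hits), " proteins; ",
      sum(x$hits$q < x$params$q_thresh), " ANOVA-significant (q < ",
      x$params$q_thresh, ")\n", sep = "")
  for (cl in c("high_confidence", "putative", "wt_interactor")) {
    cat("  ", cl, ": ", if (cl %in% names(tab)) tab[[cl]] else 0L, "\n", sep = "")
  }
  invisible(x)
}

#' @rdname trap_analysis
#' @param x A `trap_fit` object.
#' @param ... Unused.
#' @export
tidy.trap_fit <- function(x, ...) x$hits

#' @rdname trap_analysis
#' @export
glance.trap_fit <- function(x, ...) {
  tab <- table(factor(x$hits$hit_class,
                      levels = c("high_confidence", "putative",
                                 "wt_interactor", "not_significant")))
  tibble(n_proteins = nrow(x$hits),
         n_significant = sum(x$hits$q < x$params$q_thresh),
         n_high_confidence = as.integer(tab[["high_confidence"]]),
         n_putative = as.integer(tab[["putative"]]),
         n_wt_interactor = as.integer(tab[["wt_interactor"]]),
         n_presence_absence = nrow(x$presence_absence))
}

#' @rdname trap_analysis
#' @param object A `trap_fit` object.
#' @export
autoplot.trap_fit <- function(object, ...) {
  d <- object$scatter
  ggplot2::ggplot(d, ggplot2::aes(x = .data$log2_wt_neg,
                                  y = .data$log2_trap_neg,
                                  colour = .data$hit_class)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(
      high_confidence = "#d73027", putative = "#fc8d59",
      wt_interactor = "#4575b4", not_significant = "grey70")) +
    ggplot2::labs(x = "log2(WT / NEG)", y = "log2(TRAP / NEG)",
                  colour = "hit class") +
    ggplot2::theme_minimal()
}
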