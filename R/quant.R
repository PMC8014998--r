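# Quantitative terminome analysis: per-replicate normalization against
# expected mitochondrial termini, replicate aggregation, expected-vs-
# unexpected distribution comparison, IQR-based cutoff derivation,
# differential calling, and correlation with protein-level abundance.

#' Normalize per-replicate terminus ratios
#'
#' Centers each replicate's log2 heavy/light ratios on the median ratio of
#' the reference termini: expected-category termini (`P1_2`/`SP`/`MTS`/`PP`)
#' of mitochondrial proteins quantified in that replicate. After
#' normalization the reference median is exactly 0 in every replicate, so
#' the operation is idempotent.
#'
#' @param termini Terminus tibble with `ratio_hl_rep*` columns (see
#'   [collapse_to_unique()]).
#'
#' @return The input tibble with normalized ratio columns; per-replicate
#'   offsets are attached as attribute `"normalization_offsets"`.
#' @export
normalize_ratios <- function(termini) {
  rc <- ratio_cols(termini)
  if (length(rc) == 0) abort("no ratio_hl_rep* columns to normalize")
  is_ref <- termini$category != "unexpected" & termini$is_mitochondrial
  offsets <- numeric(length(rc))
  names(offsets) <- rc
  for (i in seq_along(rc)) {
    v <- termini[[rc[i]]]
    ref <- v[is_ref & !is.na(v)]
    if (length(ref) == 0) {
      abort(paste0("no expected mitochondrial reference termini quantified in ",
                   "replicate ", i, " (column ", rc[i], ")"))
    }
    offsets[i] <- median(ref)
    termini[[rc[i]]] <- v - offsets[i]
  }
  attr(termini, "normalization_offsets") <- offsets
  termini
}

#' Aggregate replicate ratios per terminus
#'
#' Averages the available normalized log2 ratios of each terminus. Termini
#' quantified in fewer than `min_reps` replicates are carried along but
#' marked `not_quantified` and receive no mean.
#'
#' @param termini Terminus tibble with (normalized) `ratio_hl_rep*` columns.
#' @param min_reps Minimum replicates with a quantified ratio (default 2).
#'
#' @return The tibble with added `mean_norm_log2`, `n_quantified` and a
#'   `diff_call` column (`"not_quantified"` or `NA`, to be set by
#'   [call_differential_termini()]).
#' @export
aggregate_replicates <- function(termini, min_reps = 2) {
  rc <- ratio_cols(termini)
  m <- as.matrix(termini[, rc, drop = FALSE])
  n_q <- rowSums(!is.na(m))
  mean_v <- rowMeans(m, na.rm = TRUE)
  mean_v[n_q < min_reps] <- NA_real_
  dplyr::mutate(termini,
                mean_norm_log2 = mean_v,
                n_quantified = as.integer(n_q),
                diff_call = ifelse(n_q < min_reps, "not_quantified", NA_character_))
}

#' Compare expected vs unexpected ratio distributions
#'
#' Tests whether the abundance-change distribution of unexpected
#' (protease-generated neo) N termini differs from that of expected
#' (maturation-derived) termini, by two-sided Mann-Whitney U test on the
#' aggregated normalized log2 ratios, and reports the difference of medians
#' (unexpected minus expected).
#'
#' @param expected,unexpected Numeric vectors of mean normalized log2
#'   ratios.
#'
#' @return Object of class `class_comparison` with [tidy()] and [glance()]
#'   methods.
#' @export
compare_class_distributions <- function(expected, unexpected) {
  expected <- expected[!is.na(expected)]
  unexpected <- unexpected[!is.na(unexpected)]
  if (length(expected) == 0 || length(unexpected) == 0) {
    abort("both groups must be non-empty")
  }
  mw <- mann_whitney_u(unexpected, expected)
  structure(
    list(n_expected = length(expected),
         n_unexpected = length(unexpected),
         median_expected = median(expected),
         median_unexpected = median(unexpected),
         delta_median = median(unexpected) - median(expected),
         mw_u = mw$u,
         p_two_sided = mw$p,
         method = mw$method),
    class = "class_comparison"
  )
}

#' @export
print.class_comparison <- function(x, ...) {
  cat("Expected vs unexpected N-terminus abundance comparison\n")
  cat(sprintf("  n = %d expected, %d unexpected\n", x$n_expected, x$n_unexpected))
  cat(sprintf("  medians: expected %.3f, unexpected %.3f (delta = %.3f)\n",
              x$median_expected, x$median_unexpected, x$delta_median))
  cat(sprintf("  Mann-Whitney U = %.1f, two-sided p = %.3g (%s)\n",
              x$mw_u, x$p_two_sided, x$method))
  invisible(x)
}

#' @rdname compare_class_distributions
#' @param x A `class_comparison` object.
#' @param ... Unused.
#' @export
tidy.class_comparison <- function(x, ...) {
  tibble(n_expected = x$n_expected, n_unexpected = x$n_unexpected,
         median_expected = x$median_expected,
         median_unexpected = x$median_unexpected,
         delta_median = x$delta_median, statistic = x$mw_u,
         p.value = x$p_two_sided, method = x$method)
}

#' @rdname compare_class_distributions
#' @export
glance.class_comparison <- function(x, ...) tidy(x)

#' Derive boxplot-style cutoff bounds from a reference distribution
#'
#' Tukey-fence cutoff for strong abundance changes: bounds at
#' `Q1 - k * IQR` and `Q3 + k * IQR` of a reference set of normalized log2
#' ratios, typically termini mapping to proteins whose overall abundance is
#' unchanged. Quartiles use linear interpolation (quantile type 7).
#'
#' @param reference_values Numeric vector (at least 4 non-missing values).
#' @param k IQR multiplier (default 1.5).
#'
#' @return Object of class `cutoff_bounds`: `lower`, `upper`, `k`, `method`,
#'   `reference_n`.
#' @seealso [fixed_cutoff()] for the fixed fallback.
#' @export
derive_cutoff <- function(reference_values, k = 1.5) {
  v <- reference_values[!is.na(reference_values)]
  if (length(v) < 4) abort("need at least 4 reference values to derive a cutoff")
  q <- quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  out <- structure(
    list(lower = q[1] - k * iqr, upper = q[2] + k * iqr, k = k,
         method = "quantile type 7 (linear interpolation)",
         reference_n = length(v)),
    class = "cutoff_bounds"
  )
  if (out$lower == out$upper) warn("degenerate cutoff: lower == upper")
  out
}

#' Fixed symmetric cutoff bounds
#'
#' Fixed fallback cutoff (default the conventional +/-0.9 on the log2
#' scale) for use when no reference set is available.
#'
#' @param magnitude Half-width of the symmetric bounds (default 0.9).
#' @return A `cutoff_bounds` object.
#' @export
fixed_cutoff <- function(magnitude = 0.9) {
  structure(list(lower = -magnitude, upper = magnitude, k = NA_real_,
                 method = "fixed", reference_n = 0L),
            class = "cutoff_bounds")
}

#' @export
print.cutoff_bounds <- function(x, ...) {
  cat(sprintf("<cutoff_bounds> lower %.3f, upper %.3f (%s, n = %d)\n",
              x$lower, x$upper, x$method, x$reference_n))
  invisible(x)
}

#' Call differential termini against cutoff bounds
#'
#' Classifies each quantified terminus as `accumulating`
#' (`mean_norm_log2 > upper`), `depleted` (`< lower`) or `unchanged`
#' (strict inequalities; a value exactly on a bound is unchanged). Termini
#' marked `not_quantified` are left unchanged.
#'
#' @param termini Output of [aggregate_replicates()].
#' @param bounds A `cutoff_bounds` object.
#'
#' @return The tibble with `diff_call` filled in.
#' @seealso [call_summary()] for the 2x3 class-by-call table.
#' @export
call_differential_termini <- function(termini, bounds) {
  stopifnot(inherits(bounds, "cutoff_bounds"))
  quantified <- is.na(termini$diff_call)
  v <- termini$mean_norm_log2
  call <- dplyr::case_when(
    !quantified ~ termini$diff_call,
    v > bounds$upper ~ "accumulating",
    v < bounds$lower ~ "depleted",
    TRUE ~ "unchanged"
  )
  dplyr::mutate(termini, diff_call = call)
}

#' Summarize differential calls by terminus class
#'
#' @param termini Output of [call_differential_termini()].
#' @return Tibble with one row per class (`expected`/`unexpected`) and
#'   columns `accumulating`, `depleted`, `unchanged`.
#' @export
call_summary <- function(termini) {
  termini |>
    dplyr::filter(.data$diff_call != "not_quantified") |>
    dplyr::mutate(
      class = ifelse(.data$category == "unexpected", "unexpected", "expected"),
      diff_call = factor(.data$diff_call,
                         levels = c("accumulating", "depleted", "unchanged"))) |>
    dplyr::count(.data$class, .data$diff_call, .drop = FALSE) |>
    tidyr::pivot_wider(names_from = "diff_call", values_from = "n",
                       values_fill = 0L)
}

#' Correlate terminus ratios with protein-level abundance
#'
#' Joins quantified termini to a protein-level LFQ ratio table and computes
#' the Pearson correlation between terminus and protein log2 ratios,
#' separately for expected and unexpected termini. Maturation-derived
#' termini are expected to track their protein's abundance; protease-
#' generated neo-termini need not.
#'
#' @param termini Output of [aggregate_replicates()] (quantified rows used).
#' @param protein_lfq Tibble with columns `accession` (or `protein`) and
#'   `log2_ratio`.
#'
#' @return Tibble per class: `class`, `n_pairs`, `n_unmatched`, `pearson_r`,
#'   `p_value`, `computable` (`FALSE` with fewer than 3 matched pairs).
#' @export
correlate_with_protein_abundance <- function(termini, protein_lfq) {
  protein_lfq <- as_tibble(protein_lfq)
  if ("protein" %in% names(protein_lfq) && !"accession" %in% names(protein_lfq)) {
    protein_lfq <- dplyr::rename(protein_lfq, accession = "protein")
  }
  if (!all(c("accession", "log2_ratio") %in% names(protein_lfq))) {
    abort("protein_lfq must have columns accession (or protein) and log2_ratio")
  }
  d <- termini |>
    dplyr::filter(!is.na(.data$mean_norm_log2)) |>
    dplyr::mutate(class = ifelse(.data$category == "unexpected",
                                 "unexpected", "expected")) |>
    dplyr::left_join(protein_lfq[, c("accession", "log2_ratio")],
                     by = c(protein = "accession"))
  purrr::map_dfr(c("expected", "unexpected"), function(cl) {
    g <- d[d$class == cl, ]
    matched <- g[!is.na(g$log2_ratio), ]
    if (nrow(matched) >= 3 && sd(matched$mean_norm_log2) > 0 &&
        sd(matched$log2_ratio) > 0) {
      ct <- cor.test(matched$mean_norm_log2, matched$log2_ratio)
      tibble(class = cl, n_pairs = nrow(matched),
             n_unmatched = nrow(g) - nrow(matched),
             pearson_r = unname(ct$estimate), p_value = ct$p.value,
             computable = TRUE)
    } else {
      tibble(class = cl, n_pairs = nrow(matched),
             n_unmatched = nrow(g) - nrow(matched),
             pearson_r = NA_real_, p_value = NA_real_, computable = FALSE)
    }
  })
}
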