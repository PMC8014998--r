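# Terminome annotation: ArgC-consistency filtering of N-terminal peptide
# evidence, mapping onto protein models, five-way positional classification
# (P1_2 / SP / MTS / PP / unexpected), collapse to unique termini, and
# ragging detection.

#' Filter N-terminal peptide evidence
#'
#' Applies the TAILS exclusion rules: pyroglutamate-modified peptides (can
#' arise during sample preparation after digest), peptides without a
#' C-terminal Arg (inconsistent with ArgC-specific digestion), and peptides
#' reporting a nonsense dimethyl modification on an N-terminal Pro
#' (secondary amine; dimethylation is not chemically plausible). A peptide
#' ending at its protein's C terminus is exempt from the Arg rule when
#' `allow_protein_cterm` is `TRUE`, since no digestion site exists there.
#'
#' @param evidence Evidence tibble.
#' @param db Optional `protein_db` used to recognize protein C-terminal
#'   peptides; without it a logical `at_protein_cterm` column is honored if
#'   present.
#' @param allow_protein_cterm Keep Arg-less peptides that end at the protein
#'   C terminus (default `TRUE`).
#'
#' @return List with tibbles `kept` and `rejected`; `rejected` carries a
#'   `reject_reason` column (`"pyroglu"`, `"no_cterm_arg"`,
#'   `"pro_dimethyl"`). Together the two partitions reproduce the input.
#' @export
filter_evidence <- function(evidence, db = NULL, allow_protein_cterm = TRUE) {
  evidence <- validate_evidence(evidence)
  at_cterm <- if (!is.null(db)) {
    seqs <- protein_sequence(db, evidence$protein)
    mapply(function(s, p) endsWith(s, p), seqs, evidence$peptide,
           USE.NAMES = FALSE)
  } else if ("at_protein_cterm" %in% names(evidence)) {
    evidence$at_protein_cterm %in% TRUE
  } else {
    rep(FALSE, nrow(evidence))
  }
  reason <- dplyr::case_when(
    evidence$nterm_mod %in% c("pyroglu_E", "pyroglu_Q") ~ "pyroglu",
    evidence$cterm_residue != "R" & !(allow_protein_cterm & at_cterm) ~ "no_cterm_arg",
    startsWith(evidence$peptide, "P") & evidence$nterm_mod == "dimethyl" ~ "pro_dimethyl",
    TRUE ~ NA_character_
  )
  list(
    kept = evidence[is.na(reason), , drop = FALSE],
    rejected = dplyr::mutate(evidence[!is.na(reason), , drop = FALSE],
                             reject_reason = reason[!is.na(reason)])
  )
}

#' Map peptides to protein positions and classify the termini
#'
#' Locates each peptide at its first occurrence in the stated protein's
#' sequence (1-based start) and classifies the resulting N terminus against
#' [expected_start_positions()]: positions 1/2 (`P1_2`, including
#' Met1-removed starts at 2), signal peptide (`SP`), mitochondrial targeting
#' signal (`MTS`) or propeptide (`PP`) maturation sites within `window`
#' residues of the annotated mature start, and `unexpected` otherwise.
#' Peptides occurring more than once in their protein are mapped to the
#' first occurrence with `ambiguity_flag = TRUE`.
#'
#' @param evidence Filtered evidence tibble (see [filter_evidence()]).
#' @param db A `protein_db`.
#' @param window Tolerance around annotated mature starts (default 5).
#'
#' @return The evidence tibble with added columns `start`, `category`,
#'   `is_mitochondrial`, `ambiguity_flag`.
#' @export
map_and_classify <- function(evidence, db, window = 5) {
  evidence <- validate_evidence(evidence)
  seqs <- protein_sequence(db, evidence$protein)
  pos <- vapply(seq_len(nrow(evidence)), function(i) {
    regexpr(evidence$peptide[i], seqs[i], fixed = TRUE)[1]
  }, integer(1))
  if (any(pos < 1)) {
    i <- which(pos < 1)[1]
    abort(paste0("peptide '", evidence$peptide[i],
                 "' is not a substring of protein ", evidence$protein[i],
                 " (stale protein database?)"))
  }
  n_occ <- vapply(seq_len(nrow(evidence)), function(i) {
    length(gregexpr(evidence$peptide[i], seqs[i], fixed = TRUE)[[1]])
  }, integer(1))
  exp_tbl <- expected_start_positions(db, unique(evidence$protein), window = window)
  key <- paste(exp_tbl$accession, exp_tbl$position)
  cat_lookup <- setNames(exp_tbl$category, key)
  category <- unname(cat_lookup[paste(evidence$protein, pos)])
  category[is.na(category)] <- "unexpected"
  mito <- db$proteins$is_mitochondrial[match(evidence$protein, db$proteins$accession)]
  dplyr::mutate(evidence,
                start = as.integer(pos),
                category = category,
                is_mitochondrial = mito,
                ambiguity_flag = n_occ > 1)
}

modal_value <- function(x) {
  tab <- sort(table(x), decreasing = TRUE)
  names(tab)[1]
}

#' Collapse mapped peptides to unique N termini
#'
#' Peptides sharing a `(protein, start)` key — differing only in their C
#' terminus (missed cleavages), Lys label state or N-terminal modification —
#' are collapsed into one terminus record. Spectral counts are summed over
#' members and replicates, per-replicate ratios combined by median, and the
#' record's `nterm_mod` is the modally observed modification. Setting
#' `include_mod_in_key = TRUE` keeps differently modified termini (e.g.
#' in-vivo acetylated vs dimethylated) separate.
#'
#' @param mapped Output of [map_and_classify()].
#' @param include_mod_in_key Include `nterm_mod` in the uniqueness key
#'   (default `FALSE`).
#'
#' @return Terminus tibble: `protein`, `start`, `category`,
#'   `is_mitochondrial`, `nterm_mod`, per-replicate `ratio_hl_rep*`,
#'   `total_spectral_count`, `peptide_count`, `ambiguity_flag`.
#' @export
collapse_to_unique <- function(mapped, include_mod_in_key = FALSE) {
  rc <- ratio_cols(mapped)
  cc <- count_cols(mapped)
  keys <- c("protein", "start", if (include_mod_in_key) "nterm_mod")
  med_or_na <- function(x) if (all(is.na(x))) NA_real_ else median(x, na.rm = TRUE)
  mapped |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      category = .data$category[1],
      is_mitochondrial = .data$is_mitochondrial[1],
      nterm_mod = modal_value(.data$nterm_mod),
      dplyr::across(dplyr::all_of(rc), med_or_na),
      total_spectral_count = sum(dplyr::pick(dplyr::all_of(cc))),
      peptide_count = dplyr::n(),
      ambiguity_flag = any(.data$ambiguity_flag),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$protein, .data$start)
}

#' Detect N-terminal ragging clusters
#'
#' Ragging — ladders of termini at successive positions of one protein —
#' indicates progressive aminopeptidase trimming. Within each protein,
#' maximal runs of two or more termini whose successive position gaps are at
#' most `gap_max` form one cluster; the cluster's most prevalent terminus is
#' the member with the highest total spectral count (ties resolved to the
#' smallest position).
#'
#' @param termini Terminus tibble (see [collapse_to_unique()]).
#' @param gap_max Maximum gap between successive member positions
#'   (default 2).
#'
#' @return Tibble with one row per cluster: `protein`, `cluster_id`,
#'   `member_positions` and `prevalence_counts` (list columns),
#'   `most_prevalent_position`, `n_members`.
#' @export
detect_ragging <- function(termini, gap_max = 2) {
  termini |>
    dplyr::arrange(.data$protein, .data$start) |>
    dplyr::group_by(protein = .data$protein) |>
    dplyr::group_modify(function(d, g) {
      run <- cumsum(c(TRUE, diff(d$start) > gap_max))
      keep <- split(seq_len(nrow(d)), run)
      keep <- keep[lengths(keep) >= 2]
      if (length(keep) == 0) {
        return(tibble(cluster_id = integer(), member_positions = list(),
                      prevalence_counts = list(),
                      most_prevalent_position = integer(), n_members = integer()))
      }
      purrr::imap_dfr(unname(keep), function(idx, j) {
        counts <- d$total_spectral_count[idx]
        best <- idx[which.max(counts)]  # which.max takes the first maximum
        tibble(cluster_id = as.integer(j),
               member_positions = list(d$start[idx]),
               prevalence_counts = list(counts),
               most_prevalent_position = d$start[best],
               n_members = length(idx))
      })
    }) |>
    dplyr::ungroup()
}

#' Category counts of unique termini
#'
#' Summary of unique termini per positional category, overall and split by
#' mitochondrial localization.
#'
#' @param termini Terminus tibble.
#' @return Tibble with `category`, `n`, `n_mitochondrial`.
#' @export
category_counts <- function(termini) {
  termini |>
    dplyr::mutate(category = factor(.data$category, levels = .CATEGORY_LEVELS)) |>
    dplyr::group_by(category = .data$category, .drop = FALSE) |>
    dplyr::summarise(n = dplyr::n(),
                     n_mitochondrial = sum(.data$is_mitochondrial),
                     .groups = "drop") |>
    dplyr::mutate(category = as.character(.data$category))
}
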