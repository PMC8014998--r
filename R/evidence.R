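# Peptide-evidence I/O and preTAILS QC. The internal evidence dialect is a
# wide tibble, one row per modification-specific peptide:
#   peptide, protein, nterm_mod, lys_mods, after_dimethyl_lys,
#   ratio_hl_rep1..K (log2 heavy/light, NA = missing),
#   spectral_count_rep1..K.
# lys_mods is a ";"-joined token list, one token per Lys residue.

.NTERM_MODS <- c("dimethyl", "acetyl", "pyroglu_E", "pyroglu_Q", "free")
.LYS_MODS <- c("dimethyl_light", "dimethyl_heavy", "unmodified")

ratio_cols <- function(evidence) {
  grep("^ratio_hl_rep", names(evidence), value = TRUE)
}

count_cols <- function(evidence) {
  grep("^spectral_count_rep", names(evidence), value = TRUE)
}

validate_evidence <- function(evidence, n_reps = NULL) {
  evidence <- as_tibble(evidence)
  req <- c("peptide", "protein", "nterm_mod", "lys_mods")
  missing_cols <- setdiff(req, names(evidence))
  if (length(missing_cols) > 0) {
    abort(paste0("evidence table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  rc <- ratio_cols(evidence)
  cc <- count_cols(evidence)
  if (length(rc) == 0 || length(rc) != length(cc)) {
    abort("evidence table needs matching ratio_hl_rep* and spectral_count_rep* columns")
  }
  if (!is.null(n_reps) && length(rc) != n_reps) {
    abort(paste0("evidence table has ", length(rc),
                 " replicate ratio columns; experiment design expects ", n_reps))
  }
  bad_mod <- !(evidence$nterm_mod %in% .NTERM_MODS)
  if (any(bad_mod)) {
    i <- which(bad_mod)[1]
    abort(paste0("row ", i, ": unknown modification '", evidence$nterm_mod[i], "'"))
  }
  lys_tokens <- strsplit(ifelse(is.na(evidence$lys_mods), "", evidence$lys_mods), ";",
                         fixed = TRUE)
  bad_lys <- purrr::map_lgl(lys_tokens, ~ any(!(.x %in% .LYS_MODS) & nzchar(.x)))
  if (any(bad_lys)) {
    i <- which(bad_lys)[1]
    tok <- setdiff(lys_tokens[[i]], .LYS_MODS)[1]
    abort(paste0("row ", i, ": unknown modification '", tok, "'"))
  }
  if (!"after_dimethyl_lys" %in% names(evidence)) {
    evidence$after_dimethyl_lys <- FALSE
  }
  evidence$after_dimethyl_lys <- as.logical(evidence$after_dimethyl_lys) %in% TRUE
  for (cl in rc) {
    v <- evidence[[cl]]
    if (is.character(v)) v <- suppressWarnings(as.numeric(ifelse(v == "NaN", NA, v)))
    if (any(is.infinite(v), na.rm = TRUE)) {
      abort(paste0("non-finite ratio in column ", cl))
    }
    evidence[[cl]] <- as.numeric(v)
  }
  for (cl in cc) {
    v <- as.integer(evidence[[cl]])
    v[is.na(v)] <- 0L
    if (any(v < 0)) abort(paste0("negative spectral count in column ", cl))
    evidence[[cl]] <- v
  }
  evidence$cterm_residue <- substring(evidence$peptide,
                                      nchar(evidence$peptide),
                                      nchar(evidence$peptide))
  evidence
}

#' Read a peptide-evidence table
#'
#' Reads the package's tab-separated evidence dialect (column contract in
#' the package README): one row per modification-specific peptide with
#' per-replicate log2 heavy/light ratios (`ratio_hl_rep1..K`; empty cells or
#' `"NaN"` are missing values, never zero) and spectral counts
#' (`spectral_count_rep1..K`). Native MaxQuant
#' `modificationSpecificPeptides.txt` exports can be converted first with
#' [read_maxquant_evidence()].
#'
#' @param path Path to the TSV.
#' @param n_reps Expected number of replicates; an inconsistent table is an
#'   error. `NULL` (default) accepts whatever the header defines.
#'
#' @return Evidence tibble with validated modification tokens and a derived
#'   `cterm_residue` column.
#' @export
read_evidence_table <- function(path, n_reps = NULL) {
  if (!file.exists(path)) abort(paste0("evidence table not found: ", path))
  tbl <- readr::read_tsv(path, show_col_types = FALSE, na = c("", "NA", "NaN"),
                         progress = FALSE)
  validate_evidence(tbl, n_reps = n_reps)
}

#' Convert a MaxQuant modification-specific peptide export
#'
#' Thin converter from native MaxQuant `modificationSpecificPeptides.txt`
#' column names to the internal evidence dialect. The peptide sequence,
#' leading razor protein, per-experiment H/L ratios and MS/MS counts are
#' mapped directly; the N-terminal modification is derived from the
#' `Modifications` summary string and per-Lys label states from the dimethyl
#' Lys modification counts. Columns the converter cannot derive are filled
#' conservatively (`after_dimethyl_lys = FALSE`).
#'
#' @param path Path to `modificationSpecificPeptides.txt`.
#' @param experiments Character vector of MaxQuant experiment names, in
#'   replicate order (builds column names `Ratio H/L normalized <exp>` and
#'   `MS/MS count <exp>`).
#'
#' @return Evidence tibble in the internal dialect.
#' @export
read_maxquant_evidence <- function(path, experiments) {
  if (!file.exists(path)) abort(paste0("evidence table not found: ", path))
  raw <- readr::read_tsv(path, show_col_types = FALSE, na = c("", "NA", "NaN"),
                         progress = FALSE)
  need <- c("Sequence", "Proteins", "Modifications")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("not a modificationSpecificPeptides export; lacks: ",
                 paste(missing_cols, collapse = ", ")))
  }
  mods <- raw$Modifications
  nterm <- dplyr::case_when(
    stringr::str_detect(mods, stringr::fixed("Gln->pyro-Glu")) ~ "pyroglu_Q",
    stringr::str_detect(mods, stringr::fixed("Glu->pyro-Glu")) ~ "pyroglu_E",
    stringr::str_detect(mods, stringr::regex("Acetyl \\(Protein N-term\\)")) ~ "acetyl",
    stringr::str_detect(mods, stringr::regex("Dimethyl \\((Protein )?N-term\\)")) ~ "dimethyl",
    TRUE ~ "free"
  )
  n_lys <- stringr::str_count(raw$Sequence, "K")
  n_heavy <- stringr::str_count(mods, stringr::regex("Dimethyl:2H\\(6\\)13C\\(2\\) \\(K\\)"))
  n_light <- stringr::str_count(mods, stringr::regex("(?<!\\)13C\\(2\\) )Dimethyl \\(K\\)"))
  lys_mods <- purrr::pmap_chr(list(n_lys, n_light, n_heavy), function(k, l, h) {
    toks <- c(rep("dimethyl_light", min(l, k)),
              rep("dimethyl_heavy", min(h, max(0, k - l))))
    toks <- c(toks, rep("unmodified", max(0, k - length(toks))))
    paste(toks, collapse = ";")
  })
  out <- tibble(
    peptide = raw$Sequence,
    protein = sub(";.*$", "", raw$Proteins),
    nterm_mod = nterm,
    lys_mods = lys_mods,
    after_dimethyl_lys = FALSE
  )
  for (i in seq_along(experiments)) {
    rcol <- paste0("Ratio H/L normalized ", experiments[i])
    if (!rcol %in% names(raw)) rcol <- paste0("Ratio H/L ", experiments[i])
    ccol <- paste0("MS/MS count ", experiments[i])
    if (!rcol %in% names(raw) || !ccol %in% names(raw)) {
      abort(paste0("no ratio/count columns for experiment '", experiments[i], "'"))
    }
    out[[paste0("ratio_hl_rep", i)]] <- log2(as.numeric(raw[[rcol]]))
    out[[paste0("spectral_count_rep", i)]] <- as.integer(raw[[ccol]])
  }
  validate_evidence(out, n_reps = length(experiments))
}

#' Labeling-efficiency quality control
#'
#' Computes the two preTAILS labeling checks: the fraction of observed Lys
#' residues carrying a dimethyl label (light or heavy), and the fraction of
#' peptides flagged as cleaved after a dimethylated Lys (dimethylated Lys
#' should resist tryptic cleavage). Pass thresholds are >0.98 labeled Lys
#' and <0.06 cleavage after labeled Lys.
#'
#' @param evidence Evidence tibble (see [read_evidence_table()]).
#' @param lys_threshold,cleavage_threshold Pass thresholds.
#'
#' @return One-row tibble: `frac_lys_dimethylated`,
#'   `frac_cleaved_after_dimethyl_lys`, `n_peptides`, `n_lys`,
#'   `pass_lys_labeling`, `pass_cleavage`.
#' @export
labeling_qc <- function(evidence, lys_threshold = 0.98, cleavage_threshold = 0.06) {
  if (nrow(evidence) == 0) abort("empty evidence table")
  evidence <- validate_evidence(evidence)
  toks <- unlist(strsplit(ifelse(is.na(evidence$lys_mods), "", evidence$lys_mods),
                          ";", fixed = TRUE))
  toks <- toks[nzchar(toks)]
  n_lys <- length(toks)
  frac_lys <- if (n_lys == 0) NA_real_ else {
    mean(toks %in% c("dimethyl_light", "dimethyl_heavy"))
  }
  frac_cleaved <- mean(evidence$after_dimethyl_lys)
  tibble(
    frac_lys_dimethylated = frac_lys,
    frac_cleaved_after_dimethyl_lys = frac_cleaved,
    n_peptides = nrow(evidence),
    n_lys = n_lys,
    pass_lys_labeling = !is.na(frac_lys) && frac_lys > lys_threshold,
    pass_cleavage = frac_cleaved < cleavage_threshold
  )
}

#' Recompute protein ratios from Lys-containing peptides
#'
#' preTAILS protein-level quantification: in a duplex dimethyl experiment
#' only Lys-containing peptides carry the isotope label on every molecule,
#' so protein log2 heavy/light ratios are recomputed as the median over
#' quantified Lys-containing peptides. Peptides without Lys or without any
#' quantified replicate ratio are excluded; proteins with no qualifying
#' peptide are reported as unquantified (`NA`), never as zero.
#'
#' @param evidence Evidence tibble.
#'
#' @return Tibble with one row per protein: `protein`, `log2_ratio`,
#'   `n_peptides_used`, `quantified`.
#' @export
recalc_protein_ratios_lys_only <- function(evidence) {
  evidence <- validate_evidence(evidence)
  rc <- ratio_cols(evidence)
  per_pep <- rowMeans(as.matrix(evidence[, rc, drop = FALSE]), na.rm = TRUE)
  per_pep[is.nan(per_pep)] <- NA_real_
  evidence$.pep_ratio <- per_pep
  evidence$.qualifies <- grepl("K", evidence$peptide, fixed = TRUE) &
    !is.na(per_pep)
  evidence |>
    dplyr::group_by(protein = .data$protein) |>
    dplyr::summarise(
      log2_ratio = if (any(.data$.qualifies)) {
        median(.data$.pep_ratio[.data$.qualifies])
      } else NA_real_,
      n_peptides_used = sum(.data$.qualifies),
      .groups = "drop"
    ) |>
    dplyr::mutate(quantified = !is.na(.data$log2_ratio))
}
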