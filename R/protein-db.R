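# Protein model: sequences plus positional maturation features (SP/MTS/PP).
# All coordinates are 1-based inclusive; a feature spanning start..end means
# the mature protein begins at end + 1. A cleavage "before position p" sits
# between residues p-1 (P1) and p (P1').

.FEATURE_TYPES <- c("SP", "MTS", "PP")
.CATEGORY_LEVELS <- c("P1_2", "SP", "MTS", "PP", "unexpected")
.AA_ALPHABET <- c(names(.RESIDUE_COMP), "X")

#' Construct a protein database from tibbles
#'
#' @param proteins Tibble with columns `accession`, `sequence` and
#'   `is_mitochondrial`.
#' @param features Tibble with columns `accession`, `feature_type`
#'   (`"SP"`, `"MTS"` or `"PP"`), `start`, `end` (1-based inclusive; the
#'   mature chain starts at `end + 1`) and `evidence` (`"annotated"` or
#'   `"predicted"`). May have zero rows.
#'
#' @return An object of class `protein_db`: a list with validated
#'   `proteins` and `features` tibbles.
#' @export
protein_db <- function(proteins, features = NULL) {
  proteins <- as_tibble(proteins)
  if (is.null(features)) {
    features <- tibble(accession = character(), feature_type = character(),
                       start = integer(), end = integer(), evidence = character())
  }
  features <- as_tibble(features)

  req <- c("accession", "sequence", "is_mitochondrial")
  if (!all(req %in% names(proteins))) {
    abort(paste0("proteins table must have columns: ", paste(req, collapse = ", ")))
  }
  if (anyDuplicated(proteins$accession)) {
    dup <- unique(proteins$accession[duplicated(proteins$accession)])
    abort(paste0("duplicate accession: ", paste(dup, collapse = ", ")))
  }
  if (any(!nzchar(proteins$sequence))) abort("empty sequence")
  bad_seq <- !grepl(paste0("^[", paste(.AA_ALPHABET, collapse = ""), "]+$"),
                    proteins$sequence)
  if (any(bad_seq)) {
    abort(paste0("sequence for ", proteins$accession[bad_seq][1],
                 " contains characters outside the amino-acid alphabet ",
                 "(20 standard residues + X, uppercase)"))
  }
  proteins$length <- nchar(proteins$sequence)
  proteins$is_mitochondrial <- as.logical(proteins$is_mitochondrial)

  freq <- c("accession", "feature_type", "start", "end", "evidence")
  if (!all(freq %in% names(features))) {
    abort(paste0("features table must have columns: ", paste(freq, collapse = ", ")))
  }
  if (nrow(features) > 0) {
    unknown <- !(features$accession %in% proteins$accession)
    if (any(unknown)) {
      i <- which(unknown)[1]
      abort(paste0("feature row ", i, " references unknown accession '",
                   features$accession[i], "'"))
    }
    bad_type <- !(features$feature_type %in% .FEATURE_TYPES)
    if (any(bad_type)) {
      i <- which(bad_type)[1]
      abort(paste0("feature row ", i, ": unknown feature_type '",
                   features$feature_type[i], "'"))
    }
    bad_ev <- !(features$evidence %in% c("annotated", "predicted"))
    if (any(bad_ev)) {
      i <- which(bad_ev)[1]
      abort(paste0("feature row ", i, ": unknown evidence '", features$evidence[i], "'"))
    }
    features$start <- as.integer(features$start)
    features$end <- as.integer(features$end)
    len <- proteins$length[match(features$accession, proteins$accession)]
    bad_coord <- features$start > features$end | features$start < 1 | features$end > len
    if (any(bad_coord)) {
      i <- which(bad_coord)[1]
      abort(paste0("feature row ", i, " (", features$accession[i],
                   " ", features$feature_type[i], " ", features$start[i], "-",
                   features$end[i], "): coordinate out of range"))
    }
    multi <- features |>
      dplyr::filter(.data$feature_type %in% c("SP", "MTS")) |>
      dplyr::count(.data$accession, .data$feature_type) |>
      dplyr::filter(.data$n > 1)
    if (nrow(multi) > 0) {
      abort(paste0("more than one ", multi$feature_type[1], " feature for ",
                   multi$accession[1]))
    }
  }
  structure(
    list(proteins = proteins[, c("accession", "sequence", "length", "is_mitochondrial")],
         features = features[, freq]),
    class = "protein_db"
  )
}

#' @export
print.protein_db <- function(x, ...) {
  cat("<protein_db> ", nrow(x$proteins), " proteins (",
      sum(x$proteins$is_mitochondrial), " mitochondrial), ",
      nrow(x$features), " features\n", sep = "")
  invisible(x)
}

#' Load a protein database from FASTA + feature table
#'
#' Reads protein sequences from FASTA (accession = first word of the header)
#' and positional maturation features from a tab-separated table with columns
#' `accession`, `feature_type`, `start`, `end`, `evidence`,
#' `is_mitochondrial`. A protein is flagged mitochondrial when any of its
#' feature rows carries a true flag.
#'
#' @param fasta_path Path to a protein FASTA file.
#' @param features_path Path to the feature TSV. A header-only file yields a
#'   database without features (every protein's expected termini are then
#'   positions 1 and 2 only).
#'
#' @return A [protein_db()].
#' @export
load_protein_db <- function(fasta_path, features_path) {
  if (!file.exists(fasta_path)) abort(paste0("FASTA not found: ", fasta_path))
  if (!file.exists(features_path)) {
    abort(paste0("feature table not found: ", features_path))
  }
  aa <- Biostrings::readAAStringSet(fasta_path)
  acc <- sub("\\s.*$", "", names(aa))
  feat <- readr::read_tsv(features_path, show_col_types = FALSE,
                          col_types = readr::cols(
                            accession = "c", feature_type = "c",
                            start = "i", end = "i", evidence = "c",
                            is_mitochondrial = "l"))
  mito_by_acc <- feat |>
    dplyr::group_by(.data$accession) |>
    dplyr::summarise(is_mitochondrial = any(.data$is_mitochondrial), .groups = "drop")
  proteins <- tibble(accession = acc, sequence = as.character(aa)) |>
    dplyr::left_join(mito_by_acc, by = "accession") |>
    dplyr::mutate(is_mitochondrial = dplyr::coalesce(.data$is_mitochondrial, FALSE))
  protein_db(proteins, feat[, c("accession", "feature_type", "start", "end", "evidence")])
}

#' Write a protein database back to FASTA + feature TSV
#'
#' Inverse of [load_protein_db()]; reloading the written files reproduces an
#' identical database.
#'
#' @param db A `protein_db`.
#' @param fasta_path,features_path Output paths.
#' @return Invisibly, `db`.
#' @export
write_protein_db <- function(db, fasta_path, features_path) {
  aa <- Biostrings::AAStringSet(setNames(db$proteins$sequence, db$proteins$accession))
  Biostrings::writeXStringSet(aa, fasta_path)
  mito <- db$proteins$is_mitochondrial[match(db$features$accession, db$proteins$accession)]
  out <- dplyr::mutate(db$features, is_mitochondrial = mito)
  readr::write_tsv(out, features_path)
  invisible(db)
}

protein_sequence <- function(db, accession) {
  i <- match(accession, db$proteins$accession)
  if (anyNA(i)) {
    abort(paste0("unknown accession: ",
                 paste(accession[is.na(i)], collapse = ", ")))
  }
  db$proteins$sequence[i]
}

#' Expected N-terminus positions for annotated proteins
#'
#' Positions 1 and 2 of every protein model are expected termini (initiator
#' Met retention or removal). For each SP/MTS/PP maturation feature, every
#' position within `window` residues of the mature-protein start
#' (`feature end + 1`) is expected with the feature's category, capturing
#' ragged processing around the annotated site. When categories collide the
#' precedence is `P1_2 > SP > MTS > PP`.
#'
#' @param db A `protein_db`.
#' @param accessions Optional character vector restricting the result.
#' @param window Non-negative integer tolerance around each mature start
#'   (default 5).
#'
#' @return Tibble with columns `accession`, `position`, `category`.
#' @export
expected_start_positions <- function(db, accessions = NULL, window = 5) {
  stopifnot(window >= 0)
  prot <- db$proteins
  if (!is.null(accessions)) {
    protein_sequence(db, accessions)  # validates
    prot <- prot[prot$accession %in% accessions, ]
  }
  p12 <- tibble(
    accession = rep(prot$accession, each = 2),
    position = rep(1:2, nrow(prot)),
    category = "P1_2"
  )
  p12 <- p12[p12$position <= rep(prot$length, each = 2), ]

  feat <- db$features[db$features$accession %in% prot$accession, ]
  if (nrow(feat) > 0) {
    len <- prot$length[match(feat$accession, prot$accession)]
    mature <- feat$end + 1L
    spans <- purrr::pmap(
      list(feat$accession, mature, len, feat$feature_type),
      function(acc, m, l, type) {
        lo <- max(1L, m - as.integer(window))
        hi <- min(l, m + as.integer(window))
        if (lo > hi) return(NULL)
        tibble(accession = acc, position = seq.int(lo, hi), category = type)
      })
    feat_tbl <- dplyr::bind_rows(spans)
  } else {
    feat_tbl <- NULL
  }
  out <- dplyr::bind_rows(p12, feat_tbl) |>
    dplyr::mutate(category = factor(.data$category, levels = .CATEGORY_LEVELS)) |>
    dplyr::group_by(.data$accession, .data$position) |>
    dplyr::summarise(category = .data$category[which.min(as.integer(.data$category))],
                     .groups = "drop") |>
    dplyr::arrange(.data$accession, .data$position)
  out$category <- as.character(out$category)
  out
}

#' Extract the cleavage window around an observed N terminus
#'
#' For a terminus observed at `cleavage_before = p` the scissile bond lies
#' between residues `p - 1` (P1) and `p` (P1'). The window string lists
#' `n_left` residues P_n..P1, a `"|"` marking the cleavage site, then
#' `n_right` residues P1'..P_n'. Positions outside the protein are padded
#' with `"-"`.
#'
#' @param db A `protein_db`.
#' @param accession Protein accession.
#' @param cleavage_before 1-based position of the observed peptide start.
#' @param n_left,n_right Number of residues on each side (default 5).
#'
#' @return Character window of `n_left + n_right + 1` characters (including
#'   the `"|"` separator).
#' @examples
#' db <- example_protein_db()
#' get_window(db, "PROT1", 21)  # "VRAGK|WTEYF"
#' @export
get_window <- function(db, accession, cleavage_before, n_left = 5, n_right = 5) {
  seqs <- protein_sequence(db, accession)
  len <- nchar(seqs)
  p <- as.integer(cleavage_before)
  if (any(p < 1 | p > len)) {
    abort(paste0("cleavage_before out of range [1, protein length]"))
  }
  one <- function(s, l, p1) {
    idx_l <- seq.int(p1 - n_left, p1 - 1)
    idx_r <- seq.int(p1, p1 + n_right - 1)
    res <- function(idx) {
      ch <- rep("-", length(idx))
      ok <- idx >= 1 & idx <= l
      if (any(ok)) ch[ok] <- substring(s, idx[ok], idx[ok])
      paste(ch, collapse = "")
    }
    paste0(res(idx_l), "|", res(idx_r))
  }
  mapply(one, seqs, len, p, USE.NAMES = FALSE)
}

#' Small worked-example protein database
#'
#' One 30-residue mitochondrial protein (`PROT1`) with an annotated MTS over
#' residues 1-10, so the mature chain starts at position 11. Used throughout
#' the documentation and tests.
#'
#' @return A `protein_db` with a single record.
#' @export
example_protein_db <- function() {
  protein_db(
    tibble(accession = "PROT1",
           sequence = "MLSRRAFSTASDEKLVRAGKWTEYFDNARG",
           is_mitochondrial = TRUE),
    tibble(accession = "PROT1", feature_type = "MTS",
           start = 1L, end = 10L, evidence = "annotated")
  )
}
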