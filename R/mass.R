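# Elemental and residue mass tables. Monoisotopic values are IUPAC/CODATA
# atomic masses of the principal isotope; average values are standard atomic
# weights. "13C" and "D" are first-class elements so that isotope-coded
# modifications (heavy dimethyl) can be expressed as net compositions.

.ATOMIC_MONO <- c(
  C   = 12.0,
  `13C` = 13.0033548378,
  H   = 1.0078250319,
  D   = 2.0141017780,
  N   = 14.0030740052,
  O   = 15.9949146221,
  S   = 31.97207069
)

.ATOMIC_AVG <- c(
  C   = 12.0107,
  `13C` = 13.0034,
  H   = 1.00794,
  D   = 2.0141,
  N   = 14.0067,
  O   = 15.9994,
  S   = 32.065
)

# Residue (= amino acid minus water) elemental compositions, C/H/N/O/S.
.RESIDUE_COMP <- list(
  G = c(C = 2, H = 3, N = 1, O = 1, S = 0),
  A = c(C = 3, H = 5, N = 1, O = 1, S = 0),
  S = c(C = 3, H = 5, N = 1, O = 2, S = 0),
  P = c(C = 5, H = 7, N = 1, O = 1, S = 0),
  V = c(C = 5, H = 9, N = 1, O = 1, S = 0),
  T = c(C = 4, H = 7, N = 1, O = 2, S = 0),
  C = c(C = 3, H = 5, N = 1, O = 1, S = 1),
  L = c(C = 6, H = 11, N = 1, O = 1, S = 0),
  I = c(C = 6, H = 11, N = 1, O = 1, S = 0),
  N = c(C = 4, H = 6, N = 2, O = 2, S = 0),
  D = c(C = 4, H = 5, N = 1, O = 3, S = 0),
  Q = c(C = 5, H = 8, N = 2, O = 2, S = 0),
  K = c(C = 6, H = 12, N = 2, O = 1, S = 0),
  E = c(C = 5, H = 7, N = 1, O = 3, S = 0),
  M = c(C = 5, H = 9, N = 1, O = 1, S = 1),
  H = c(C = 6, H = 7, N = 3, O = 1, S = 0),
  F = c(C = 9, H = 9, N = 1, O = 1, S = 0),
  R = c(C = 6, H = 12, N = 4, O = 1, S = 0),
  Y = c(C = 9, H = 9, N = 1, O = 2, S = 0),
  W = c(C = 11, H = 10, N = 2, O = 1, S = 0)
)

.WATER_COMP <- c(H = 2, O = 1)

#' Monoisotopic delta mass of a modification from its net composition
#'
#' Computes the signed monoisotopic mass change of a chemical modification
#' from its net elemental composition. Heavy isotopes are expressed as the
#' distinct elements `"13C"` and `"D"`, and negative counts encode atoms
#' removed, so isotope-coded labels such as heavy formaldehyde dimethylation
#' (net `(13C)2 D6 H-2`) are representable directly.
#'
#' @param net_composition Named numeric vector mapping elements (among
#'   `C`, `13C`, `H`, `D`, `N`, `O`, `S`) to signed atom counts.
#'
#' @return Signed delta mass in Dalton (monoisotopic).
#'
#' @examples
#' mod_delta_mass(c(C = 2, H = 4))            # light dimethyl, +28.0313
#' mod_delta_mass(c(`13C` = 2, D = 6, H = -2)) # heavy dimethyl, +36.07567
#' mod_delta_mass(c(C = 2, H = 2, O = 1))     # acetyl, +42.010565
#' @export
mod_delta_mass <- function(net_composition) {
  if (length(net_composition) == 0) return(0.0)
  els <- names(net_composition)
  if (is.null(els) || any(!nzchar(els))) {
    abort("`net_composition` must be a named vector of element counts.")
  }
  unknown <- setdiff(els, names(.ATOMIC_MONO))
  if (length(unknown) > 0) {
    abort(paste0("unknown element(s): ", paste(unknown, collapse = ", ")))
  }
  sum(.ATOMIC_MONO[els] * as.numeric(net_composition))
}

#' Built-in modification definitions
#'
#' The five modifications considered in duplex-dimethyl TAILS searches:
#' light and heavy dimethylation, N-terminal acetylation, and pyroglutamate
#' formation from Glu or Gln. Delta masses are computed from the net
#' elemental compositions at call time.
#'
#' @return A tibble with columns `name`, `net_composition` (list column of
#'   named counts) and `delta_monoisotopic` (Da).
#' @examples
#' modification_definitions()
#' @export
modification_definitions <- function() {
  comps <- list(
    dimethyl_light = c(C = 2, H = 4),
    dimethyl_heavy = c(`13C` = 2, D = 6, H = -2),
    acetyl         = c(C = 2, H = 2, O = 1),
    pyroglu_E      = c(H = -2, O = -1),
    pyroglu_Q      = c(N = -1, H = -3)
  )
  tibble(
    name = names(comps),
    net_composition = unname(comps),
    delta_monoisotopic = unname(purrr::map_dbl(comps, mod_delta_mass))
  )
}

residue_mass <- function(residue, scale = c("monoisotopic", "average")) {
  scale <- match.arg(scale)
  tab <- if (scale == "monoisotopic") .ATOMIC_MONO else .ATOMIC_AVG
  comp <- .RESIDUE_COMP[[residue]]
  if (is.null(comp)) abort(paste0("unknown residue: ", residue))
  sum(tab[names(comp)] * comp)
}

water_mass <- function(scale = c("monoisotopic", "average")) {
  scale <- match.arg(scale)
  tab <- if (scale == "monoisotopic") .ATOMIC_MONO else .ATOMIC_AVG
  sum(tab[names(.WATER_COMP)] * .WATER_COMP)
}

#' Predicted mass of a truncated proteoform
#'
#' Mass of the protein chain from a given start position to the C terminus,
#' i.e. the intact proteoform that would result from proteolytic removal of
#' residues 1..start-1. The chain is computed unmodified; retained
#' N-terminal modifications can be added via [mod_delta_mass()].
#'
#' @param db A `protein_db` (see [load_protein_db()]).
#' @param accession Protein accession in `db`.
#' @param start 1-based first residue of the proteoform.
#' @param scale `"average"` (default; intact-protein kDa-scale reporting) or
#'   `"monoisotopic"`.
#'
#' @return Mass in Dalton.
#' @examples
#' db <- example_protein_db()
#' proteoform_mass(db, "PROT1", start = 11)
#' @export
proteoform_mass <- function(db, accession, start, scale = c("average", "monoisotopic")) {
  scale <- match.arg(scale)
  seqs <- protein_sequence(db, accession)
  len <- nchar(seqs)
  if (start < 1 || start > len) {
    abort(paste0("start ", start, " out of range [1, ", len, "] for ", accession))
  }
  chain <- substr(seqs, start, len)
  residues <- strsplit(chain, "", fixed = TRUE)[[1]]
  known <- residues %in% names(.RESIDUE_COMP)
  if (!all(known)) {
    abort(paste0("sequence contains residues without a defined mass: ",
                 paste(unique(residues[!known]), collapse = ", ")))
  }
  sum(vapply(residues, residue_mass, numeric(1), scale = scale)) + water_mass(scale)
}
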