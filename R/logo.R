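# Cleavage-site specificity profiling: P-position window extraction,
# iceLogo-style positional enrichment of residues against a reference
# frequency model, residue-at-position subsetting, and N-terminal residue /
# N-end-rule profiling.

#' Extract cleavage windows for a set of termini
#'
#' One Schechter-Berger window (P_n..P1 | P1'..P_n') per unique cleavage
#' site, via [get_window()].
#'
#' @param termini Terminus tibble with `protein` and `start` columns.
#' @param db A `protein_db`.
#' @param n_left,n_right Residues on each side of the cleavage site
#'   (default 5).
#' @param dedupe Keep one window per unique `(protein, start)` site
#'   (default `TRUE`).
#'
#' @return Tibble with `protein`, `cleavage_before`, `window`; `n_left` and
#'   `n_right` attached as attributes.
#' @export
extract_cleavage_windows <- function(termini, db, n_left = 5, n_right = 5,
                                     dedupe = TRUE) {
  d <- tibble(protein = termini$protein, cleavage_before = termini$start)
  if (dedupe) d <- dplyr::distinct(d)
  d$window <- get_window(db, d$protein, d$cleavage_before,
                         n_left = n_left, n_right = n_right)
  attr(d, "n_left") <- n_left
  attr(d, "n_right") <- n_right
  d
}

#' Residue background frequencies of a proteome
#'
#' Overall amino-acid frequencies of the in-scope protein sequences, used
#' as the reference model for positional enrichment. For analyses of
#' mitochondrial processing the mitochondrial subproteome is the
#' appropriate background.
#'
#' @param db A `protein_db`.
#' @param scope `"mitochondrial_only"` (default) or `"all_proteins"`.
#'
#' @return Tibble with `residue` and `frequency` (sums to 1).
#' @export
reference_frequencies <- function(db, scope = c("mitochondrial_only", "all_proteins")) {
  scope <- match.arg(scope)
  seqs <- db$proteins$sequence
  if (scope == "mitochondrial_only") seqs <- seqs[db$proteins$is_mitochondrial]
  if (length(seqs) == 0) abort(paste0("no proteins in scope '", scope, "'"))
  counts <- table(unlist(strsplit(seqs, "", fixed = TRUE)))
  tibble(residue = names(counts),
         frequency = as.numeric(counts) / sum(counts))
}

position_labels <- function(n_left, n_right) {
  c(paste0("P", rev(seq_len(n_left))), paste0("P", seq_len(n_right), "'"))
}

strip_window <- function(w) sub("|", "", w, fixed = TRUE)

ref_vector <- function(reference) {
  if (is.data.frame(reference)) {
    setNames(reference$frequency, reference$residue)
  } else reference
}

#' Positional residue enrichment of cleavage windows
#'
#' iceLogo-style enrichment: for each window position and residue, the
#' observed frequency is compared with the reference frequency by a
#' two-sided exact binomial test (smaller tail doubled), and the effect is
#' reported as the percent difference `100 * (observed - reference)`.
#' Padding characters (`"-"`) are excluded from the position's trial count.
#' No correction across cells is applied by default (matching iceLogo
#' convention); `bh = TRUE` applies Benjamini-Hochberg across all cells.
#'
#' @param windows Output of [extract_cleavage_windows()], or a character
#'   vector of window strings.
#' @param reference Output of [reference_frequencies()] (or a named
#'   frequency vector).
#' @param alpha Significance level (default 0.05).
#' @param bh Apply BH correction across (position, residue) cells.
#' @param n_left Left window width; taken from the `windows` attribute when
#'   available.
#'
#' @return Tibble of class `position_enrichment` with columns
#'   `position_index`, `position_label`, `residue`, `n_obs`, `n_total`,
#'   `observed_freq`, `reference_freq`, `percent_difference`, `p_value`,
#'   `significant`.
#' @export
position_enrichment <- function(windows, reference, alpha = 0.05, bh = FALSE,
                                n_left = NULL) {
  w <- if (is.data.frame(windows)) windows$window else windows
  if (length(w) == 0) abort("need at least one window")
  if (is.null(n_left)) n_left <- attr(windows, "n_left")
  stripped <- strip_window(w)
  width <- nchar(stripped[1])
  if (is.null(n_left)) n_left <- width %/% 2
  ref <- ref_vector(reference)
  residues <- sort(unique(c(names(ref), unlist(strsplit(stripped, "", fixed = TRUE)))))
  residues <- setdiff(residues, "-")
  mat <- do.call(rbind, strsplit(stripped, "", fixed = TRUE))
  labels <- position_labels(n_left, width - n_left)
  out <- purrr::map_dfr(seq_len(width), function(j) {
    col <- mat[, j]
    col <- col[col != "-"]
    n_total <- length(col)
    purrr::map_dfr(residues, function(res) {
      k <- sum(col == res)
      p0 <- unname(ref[res])
      if (is.na(p0)) p0 <- 0
      tibble(
        position_index = j,
        position_label = labels[j],
        residue = res,
        n_obs = k,
        n_total = n_total,
        observed_freq = if (n_total > 0) k / n_total else NA_real_,
        reference_freq = p0,
        percent_difference = if (n_total > 0) 100 * (k / n_total - p0) else NA_real_,
        p_value = if (n_total > 0 && p0 > 0 && p0 < 1) {
          binom_twosided_p(k, n_total, p0)
        } else NA_real_
      )
    })
  })
  padj <- if (bh) p.adjust(out$p_value, method = "BH") else out$p_value
  out$significant <- !is.na(padj) & padj < alpha
  attr(out, "n_windows") <- length(w)
  attr(out, "alpha") <- alpha
  class(out) <- c("position_enrichment", class(out))
  out
}

parse_position_label <- function(label, n_left, n_right) {
  m <- regmatches(label, regexec("^P([0-9]+)('?)$", label))[[1]]
  if (length(m) == 0) abort(paste0("invalid position label: ", label))
  k <- as.integer(m[2])
  primed <- m[3] == "'"
  if (k < 1 || (!primed && k > n_left) || (primed && k > n_right)) {
    abort(paste0("position label ", label, " outside the window"))
  }
  if (primed) n_left + k else n_left - k + 1
}

#' Subset cleavage windows by the residue at a P position
#'
#' @param windows Output of [extract_cleavage_windows()].
#' @param position_label Position such as `"P1"`, `"P2"` or `"P1'"` (P1 is
#'   the residue immediately N-terminal to the cleavage site, P1' the first
#'   residue of the observed peptide).
#' @param residue Single residue character to match.
#'
#' @return The subset of `windows` whose residue at that position equals
#'   `residue`, with attributes preserved.
#' @export
subset_by_residue <- function(windows, position_label, residue) {
  w <- windows$window
  n_left <- attr(windows, "n_left")
  n_right <- attr(windows, "n_right")
  stripped <- strip_window(w)
  if (is.null(n_left)) n_left <- nchar(stripped[1]) %/% 2
  if (is.null(n_right)) n_right <- nchar(stripped[1]) - n_left
  idx <- parse_position_label(position_label, n_left, n_right)
  out <- windows[substring(stripped, idx, idx) == residue, , drop = FALSE]
  attr(out, "n_left") <- n_left
  attr(out, "n_right") <- n_right
  out
}

#' Bacterial N-end-rule residue classes
#'
#' Static classification of the 20 standard residues under the bacterial
#' N-end rule: primary destabilizing residues (direct degron function),
#' secondary destabilizing residues (destabilizing after enzymatic
#' conjugation), and stabilizing residues.
#'
#' @return Tibble with `residue` and `nend_class`.
#' @export
nend_rule_classes <- function() {
  tibble(
    residue = c("A", "C", "G", "H", "I", "M", "P", "S", "T", "V",
                "F", "K", "L", "R", "W", "Y",
                "D", "E", "N", "Q"),
    nend_class = c(rep("stabilizing", 10),
                   rep("destabilizing", 6),
                   rep("secondary_destabilizing", 4))
  )
}

#' N-terminal residue profile with N-end-rule classes
#'
#' Fraction of each amino acid at the observed N-terminal position (P1')
#' per terminus class, annotated with bacterial N-end-rule stability
#' classes. Maturation-derived termini are dominated by stabilizing
#' residues; protease-generated neo-termini expose destabilizing residues
#' more often.
#'
#' @param termini Terminus tibble with `protein`, `start`, `category`.
#' @param db A `protein_db`.
#' @param group `"class"` (expected vs unexpected, default) or
#'   `"category"` (all five categories).
#'
#' @return Tibble with `group`, `residue`, `n`, `fraction`, `nend_class`;
#'   fractions sum to 1 within each group.
#' @export
nterm_residue_profile <- function(termini, db, group = c("class", "category")) {
  group <- match.arg(group)
  if (nrow(termini) == 0) abort("empty terminus table")
  seqs <- protein_sequence(db, termini$protein)
  res <- substring(seqs, termini$start, termini$start)
  g <- if (group == "class") {
    ifelse(termini$category == "unexpected", "unexpected", "expected")
  } else termini$category
  tibble(group = g, residue = res) |>
    dplyr::count(.data$group, .data$residue) |>
    dplyr::group_by(.data$group) |>
    dplyr::mutate(fraction = .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::left_join(nend_rule_classes(), by = "residue") |>
    dplyr::mutate(nend_class = dplyr::coalesce(.data$nend_class, "other"))
}

#' Logo-style plot of positional enrichment
#'
#' Letter plot of significantly enriched or depleted residues per window
#' position; letter height is the percent difference vs the reference
#' frequency (iceLogo convention).
#'
#' @param object A `position_enrichment` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.position_enrichment <- function(object, ...) {
  d <- dplyr::filter(as_tibble(object), .data$significant)
  d$position_label <- factor(d$position_label,
                             levels = unique(object$position_label))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$position_label,
                                  y = .data$percent_difference,
                                  label = .data$residue)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3, colour = "grey50") +
    ggplot2::geom_text(ggplot2::aes(colour = .data$percent_difference > 0),
                       size = 4, fontface = "bold",
                       position = ggplot2::position_stack(vjust = 0.5)) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#1b7837", `FALSE` = "#762a83"),
                                 guide = "none") +
    ggplot2::labs(x = "window position", y = "% difference vs reference",
                  title = paste0("Positional enrichment (n = ",
                                 attr(object, "n_windows"), " windows)")) +
    ggplot2::theme_minimal()
}
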