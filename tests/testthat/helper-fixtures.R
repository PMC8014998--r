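# Shared fixtures, all built in code.

# evidence tibble builder: one row per peptide, 3 replicates by default
make_evidence <- function(peptide, protein, nterm_mod = "dimethyl",
                          lys_mods = "", after_dimethyl_lys = FALSE,
                          ratios = list(c(NA, NA, NA)), counts = list(c(1, 0, 0))) {
  n <- length(peptide)
  rec <- function(x, n) if (length(x) < n) rep(x, length.out = n) else x
  nterm_mod <- rec(nterm_mod, n); lys_mods <- rec(lys_mods, n)
  after_dimethyl_lys <- rec(after_dimethyl_lys, n)
  ratios <- rec(ratios, n); counts <- rec(counts, n)
  tbl <- tibble::tibble(peptide = peptide, protein = protein,
                        nterm_mod = nterm_mod, lys_mods = lys_mods,
                        after_dimethyl_lys = after_dimethyl_lys)
  k <- length(ratios[[1]])
  for (r in seq_len(k)) {
    tbl[[paste0("ratio_hl_rep", r)]] <- vapply(ratios, `[`, numeric(1), r)
    tbl[[paste0("spectral_count_rep", r)]] <- vapply(counts, function(x) {
      as.integer(x[r])
    }, integer(1))
  }
  tbl
}

# independent Mann-Whitney oracle: enumerate every assignment of the pooled
# values to group 1, computing U by direct pairwise comparison
mw_permutation_oracle <- function(x, y) {
  u_stat <- function(a, b) {
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  pooled <- c(x, y)
  n1 <- length(x)
  mu <- n1 * length(y) / 2
  u_obs <- u_stat(x, y)
  sets <- utils::combn(length(pooled), n1)
  u_all <- apply(sets, 2, function(ix) u_stat(pooled[ix], pooled[-ix]))
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# independent BH step-up oracle
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  out <- numeric(n)
  out[o] <- pmin(q, 1)
  out
}

# independent two-sided binomial oracle by direct tail summation
binom_oracle <- function(k, n, p0) {
  lo <- sum(dbinom(0:k, n, p0))
  hi <- sum(dbinom(k:n, n, p0))
  min(1, 2 * min(lo, hi))
}

# small trap matrix builder: values list of length-9 numeric (NEG/WT/TRAP x 3)
make_trap <- function(values, accession = NULL, is_mitochondrial = TRUE) {
  n <- length(values)
  if (is.null(accession)) accession <- sprintf("P%02d", seq_len(n))
  m <- do.call(rbind, values)
  colnames(m) <- c("NEG_1", "NEG_2", "NEG_3", "WT_1", "WT_2", "WT_3",
                   "TRAP_1", "TRAP_2", "TRAP_3")
  dplyr::bind_cols(
    tibble::tibble(accession = accession,
                   is_mitochondrial = rep(is_mitochondrial, length.out = n)),
    tibble::as_tibble(m))
}
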