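---
title: "Methods: quantitative N-terminomics and substrate-trapping statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative N-terminomics and substrate-trapping statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(terminomics)
```

This vignette is the package's own account of the models and procedures it
implements, the parameters that matter, the design decisions taken where
the design was genuinely open, and what the synthetic-data tests do and do
not demonstrate about real data.

## 1. The data model

The unit of analysis is a protein **N terminus**: a `(protein, start)`
pair supported by one or more identified N-terminal peptides. Inputs are

* a protein database (FASTA + feature table with SP/MTS/PP maturation
  features, 1-based inclusive coordinates; the mature chain starts at
  `end + 1`),
* a peptide-evidence table in a documented wide dialect (one row per
  modification-specific peptide, per-replicate log2 heavy/light ratios and
  spectral counts; `read_maxquant_evidence()` converts native
  modification-specific peptide exports),
* a protein-level LFQ ratio table, and, for the trapping screen, a
  proteinGroups-style log2 intensity matrix over NEG/WT/TRAP × 3.

All user-facing functions take and return tibbles so the workflow
composes with the pipe; `run_tails()` and `run_trap()` chain the stages
and archive every result table, a summary JSON and the effective
configuration next to the outputs. These two orchestrators, together with
`generate_preset()`, are the package's command surface; no shell
executable is shipped because the intended users drive analyses from R.

## 2. Filtering and positional classification

ArgC-consistency filtering removes peptide identifications that cannot be
genuine N-terminal peptides of the labeling chemistry: pyroglutamate
peptides (formed during preparation), peptides without a C-terminal Arg
(except at a protein C terminus, where no cleavage site exists — the
exemption is on by default), and dimethyl reported on an N-terminal Pro
(a secondary amine, chemically implausible). Rejections carry reason
codes and the kept/rejected partition always reproduces the input.

A kept peptide is located at its **first** occurrence in its stated
protein; additional occurrences set an ambiguity flag rather than being
resolved, since the upstream search assigns the protein and full
many-to-many remapping is out of scope. Classification against
`expected_start_positions()` uses the precedence
`P1_2 > SP > MTS > PP > unexpected`. The ±`window` tolerance (default 5
residues) around each annotated mature start is symmetric and inclusive;
sidedness is not specified by convention and ragged processing occurs in
both directions. Position 2 counts as a database terminus (initiator-Met
removal). Annotated and predicted features are treated equally; the
evidence label is carried for downstream filtering but nothing in the
pipeline down-weights predictions.

Uniqueness is `(protein, start)`: peptides differing only in C terminus,
Lys label state or N-terminal modification collapse into one terminus,
spectral counts summed, per-replicate ratios combined by median, the
modification recorded as the modal one. The key is configurable
(`include_mod_in_key`) for analyses that must keep in-vivo acetylation
separate. Ragging clusters are maximal runs of termini with successive
gaps ≤ `gap_max` (default 2 — local ladders; sequential trimming has no
natural upper gap, so this is a tunable locality choice), and the most
prevalent member is the highest total spectral count with ties going to
the smallest position.

## 3. Quantification

* **Normalization** subtracts, per replicate, the median ratio of
  expected-category termini of mitochondrial proteins — the compartment
  enriched by the experiment and expected to be mostly unchanged. The
  reference is whatever the data provide, not a fixed count. The
  operation is idempotent, and a replicate without any reference terminus
  is a hard error rather than a silent skip.
* **Aggregation** keeps termini quantified in ≥ 2 of 3 replicates
  (`min_reps`) and averages the available normalized values. The mean
  (not median) of ≤ 3 log-ratios matches how duplex ratio aggregation
  behaves after log transform.
* **Class comparison** uses a Mann–Whitney *U* test, two-sided. The null
  is computed by exhaustive enumeration of group labelings over pooled
  midranks when `min(n) ≤ 8` and `n1 + n2 ≤ 20` — exact even under ties,
  which textbook implementations refuse — and otherwise by the normal
  approximation with tie and continuity correction. The enumeration bound
  keeps the combination count below ~10^5^; beyond it the approximation
  error is negligible.
* **Cutoff.** Tukey fences `Q1 − k·IQR` / `Q3 + k·IQR` (k = 1.5) of a
  reference set of termini mapping to proteins whose LFQ
  `significant_flag` is false. Quartiles use linear interpolation
  (quantile type 7, recorded in the `method` field); boxplot quartile
  conventions differ across tools and the choice is deliberately pinned
  and reported. A degenerate reference (zero IQR) warns. A fixed
  symmetric cutoff (`fixed_cutoff(0.9)`, the conventional ±0.9) is
  available when no reference exists. Calls use strict inequalities: a
  terminus exactly on a fence is `unchanged`, a deterministic tie rule.
* **Correlation** with protein-level ratios is Pearson's r per class
  (expected vs unexpected), requiring ≥ 3 matched pairs; termini of
  unmatched proteins are counted and reported, not dropped silently.

No multiple-testing correction is applied across termini: differential
termini are called by effect-size cutoff, not per-terminus tests.

## 4. Cleavage-motif enrichment

Windows are P5..P1 | P1′..P5′ by default (configurable); out-of-sequence
positions are padded with `-` and excluded from the position's trial
count. The reference model is the residue frequency of the in-scope
proteome, mitochondrial-only by default for mitochondrial analyses —
whether published logo figures used sampled reference sets or whole-
proteome frequencies is generally not reconstructible, so the reference
is explicit and configurable. Significance per (position, residue) cell
is a two-sided exact binomial test, doubling the smaller tail: a
deterministic, oracle-testable replacement for sampled-reference t-tests
used by iceLogo-style tools. Following that convention no correction is
applied across cells; a Benjamini–Hochberg option exists and is off by
default. Effects are percent differences, `100·(observed − reference)`,
the letter heights of `autoplot()`.

N-terminal residue profiles classify P1′ residues by the bacterial
N-end rule from a static table: primary destabilizing F/K/L/R/W/Y,
secondary destabilizing D/E/N/Q, stabilizing otherwise.

## 5. Trapping-screen statistics

Missing label-free intensities are treated as missing-not-at-random and
imputed per column from `Normal(mean − 1.8·sd, (0.3·sd)²)` of the
observed values — the de-facto standard downshifted-normal parameters,
exposed in the configuration. Imputation happens once, before testing,
under a recorded seed; rerunning with the seed reproduces every cell.

Each protein is tested by one-way ANOVA across the three conditions.
The per-protein F statistic is computed from group sums of squares
directly, which pins the degenerate conventions (no variance anywhere →
p = 1; perfect separation with zero residual variance → p = 0) that
formula-interface fits return as `NaN`; tests verify agreement with
`anova(lm(...))` on non-degenerate data. Benjamini–Hochberg q-values are
computed over all tested proteins and thresholded at 0.05; Tukey HSD
p-values for the three pairs reuse the same pooled within-group mean
square via the studentized-range distribution.

Hit classes follow a fixed precedence: `high_confidence` requires q and
TRAP–WT significance with TRAP above WT (retained by the trap, degraded
by the active enzyme); `putative` requires TRAP–NEG enrichment only;
`wt_interactor` requires WT–NEG. Reported log2 enrichments are computed
on observed values only — imputed cells contribute to the test but not to
the fold change, avoiding imputation-inflated enrichments; the
imputed-value enrichments are also emitted for comparison. Proteins
consistently detected in one condition and never in another can be missed
by imputation + ANOVA entirely and are listed in a companion
presence/absence table.

## 6. The synthetic-data generator

The generator plants exactly the structure the analysis assumes, with one
ground-truth row per evidence row.

Defaults defining the simulated study: 300 proteins (70% mitochondrial),
uniform residue background (which keeps the binomial enrichment oracles
exact; an empirical frequency table can be substituted), MTS lengths from
a truncated Normal(35, 10) on [15, 80], mature-start residues biased to
stabilizing S/A/T/G/M, twin-Arg motif probabilities 0.6 (P2) / 0.3 (P3) /
0.1 (none) with a 0.8-probability Phe/Tyr/Leu residue at P1 of R-at-P3
sites (the residue an ICP55-style aminopeptidase removed), ragging trim
probability 0.35 per step, Poisson(3) neo-termini per protein carrying a
+0.32 global log2 shift, 10 substrate proteins with two accumulating
termini each (Normal(+2.0, 0.3)) and 10 wt-cleaved proteins with two
depleted termini each (Normal(−2.0, 0.3), Arg planted at P1 with
probability 0.7), ratio noise sd 0.3 per replicate, spectral-count-
dependent missingness `min(0.8, 0.5·e^(−0.25·count))` (1 when the count
is 0), and a 200-protein trap matrix (185 null / 10 substrates at +3 / 5
interactors at +2.5) with baseline Normal(25, 2) and 80% dropout below
the 0.15 intensity quantile.

Parameters not pinned by the simulated design were chosen once as
field-typical values and documented here: protein lengths uniform on
250–600 aa; per-protein abundance effects Normal(0, 0.15) with LFQ
measurement noise sd 0.1; biological scatter of individual termini around
their protein's effect sd 0.25; substrate proteins shifted ±0.5 at the
protein level; spectral-count rates 6 / 2 / 3 (expected / neo /
substrate); trap replicate noise sd 0.25. The trap noise value deserves a
note: with 3 replicates per condition the ANOVA noncentrality for a +3
spike is `3·6/σ²`, and σ must be ≲ 0.3 for near-certain recovery at a
BH-adjusted threshold — i.e. the planted-recovery property the generator
is required to satisfy constrains this "free" parameter, and 0.25 is both
consistent with that constraint and typical of technical replicates in
affinity-enrichment LFQ.

Draw order is fixed (database: lengths → MTS → sequence → motif;
experiment: substrate selection → per-protein effects and termini →
per-row modifications, counts, noise, missingness → LFQ noise → planted
reject rows) under one seeded stream per generator (`seed`, `seed + 1`,
`seed + 2`), so identical seeds give byte-identical files and partial
regeneration is impossible rather than subtly wrong.

What the generator does **not** emulate: correlated noise across
replicates, charge-state/retention artifacts, shared peptides between
homologous proteins, non-uniform residue composition, contaminants, or
compression of extreme ratios. Passing recovery tests therefore shows the
statistics behave as designed under their own assumptions — not that the
pipeline is robust to every artifact of real LC-MS data.

## 7. Problem sizes and determinism in the test suite

The suite exercises the full workflows at the default 300-protein /
3-replicate scale (≈1100–1600 evidence rows), recovery claims use fixed
seeds chosen in advance, seed-averaged properties use 20 seeds, and all
statistical primitives are compared against independent oracles
(exhaustive permutation for Mann–Whitney, step-up recursion for BH,
`TukeyHSD`/studentized range for the post-hoc tests, direct tail
summation for binomial p-values, `anova(lm(...))` for F tests).
End-to-end determinism is asserted byte-for-byte on regenerated inputs
and rewritten result bundles.

## 8. Known limitations

* Isoform handling is first-match by the stated accession; alternative
  splicing or translation-initiation discovery is out of scope.
* The Lys-only protein-ratio recalculation treats requantified ratios
  like any other quantified ratio.
* The exact Mann–Whitney branch is limited to `n1 + n2 ≤ 20`.
* Proteoform masses are computed for unmodified chains; retained
  N-terminal modifications are added explicitly via `mod_delta_mass()`,
  since published figure masses are ambiguous about modification state.
* The trapping ANOVA assumes homoscedastic groups after imputation;
  severely censored proteins are better judged from the
  presence/absence table.
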