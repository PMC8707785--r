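---
title: "Methods: statistics of the cytosig immunostimulation pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: statistics of the cytosig immunostimulation pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytosig)
```

This vignette documents the statistical model behind `cytosig`, the
choices made where the design was genuinely open, and what the synthetic
validation does and does not demonstrate about real plates.

## Data model and censoring

The unit of data is one well-level reading: donor × treatment condition ×
cytokine × replicate, in pg/mL, with an explicit censor flag. Flags are
never inferred from sentinel values; a reading is either `none`, `BDL`
(below the lower limit of quantification) or `ADL` (above the upper
limit). The substitution policy is deliberately crude and auditable:
`ADL` becomes the cytokine's ULOQ and `BDL` becomes zero. Zero is an
aggressive lower substitute (LLOQ/2 is a common alternative), but it
interacts cleanly with the rank tests used everywhere downstream: all
`BDL` wells of a cytokine tie at the bottom of the ranking, which is
exactly the information content they carry. Assay limits are
user-supplied configuration, since kits differ and vendors do not always
publish them.

Stimulus doses are normalized to pg/mL internally (µg → 10⁶ pg,
ng → 10³ pg); the display string is kept as metadata. Cytokine readings
must already be pg/mL — no standard-curve back-calculation is performed.

## Normalization

Each cytokine's readings are divided by that cytokine's sample standard
deviation (n − 1) taken over *every* collected value — all donors, all
conditions, controls included, before replicate averaging. This is a
positive per-cytokine rescaling, so it cannot change any rank-based
statistic; its purpose is presentational and for the global analyses
(heatmaps, Euclidean clustering) where a high-abundance analyte would
otherwise dominate. The invariance is not left as a claim: the test suite
asserts bit-identical significance-grid p-values on raw versus normalized
tables, and unit SD (±10⁻¹²) for every unflagged cytokine. Zero-variance
cytokines are flagged and passed through unscaled rather than dropped.

Computing the SD before replicate averaging is one of two defensible
readings of "across all collected values"; since the choice provably
cannot alter any test result, it was fixed once and not revisited.

## Rank tests

All comparisons use Wilcoxon tests. The implementation is hand-authored
because the pipeline needs exact p-values *in the presence of ties* —
censoring at zero guarantees ties — and the stock implementation falls
back to an approximation there.

* **Unpaired** (rank-sum): pooled mid-ranks; the null distribution of the
  rank sum is computed exactly, conditional on the observed tie pattern,
  by a generating-function count over *doubled* mid-ranks (doubling makes
  every rank integral, so all arithmetic is exact integer counting in
  doubles, far below 2⁵³).
* **Paired** (signed-rank): zero differences are dropped and counted;
  mid-ranks of |d|; exact enumeration over the 2ⁿ sign assignments, again
  via the doubled-rank generating function.
* Two-sided p is `min(1, 2·min(P≤, P≥))`, matching the convention of
  `stats::wilcox.test`, whose tie-free exact p-values the suite
  cross-checks against.
* Beyond the exact cutoff (both groups ≤ 12, or ≤ 24 non-zero pairs) the
  normal approximation with tie correction and continuity correction is
  used, matching the corrected reference implementation. The study
  geometry (10 donors) always takes the exact path; pooled-dose
  modulation tests (40 pairs) take the corrected approximation.

An independent brute-force oracle (full `combn`/sign enumeration, no
shared code) must agree *bit-exactly* on all sample pairs up to total
n = 10, ties included; this is enforced in the tests and re-measured by
`scripts/acceptance.R`.

## Significance grid and the elevation gate

Every (stimulus, dose, co-exposure, cytokine) cell is tested against the
negative control. Two conventions coexist in this assay family and both
are supported:

* **paired** — each donor's treated value against that donor's own NC
  (signed-rank). This is the default for signature selection; it removes
  the large stable donor effects.
* **unpaired** — treated values against the NC values pooled across
  donors (rank-sum). This is the default for the top-3/induction-matrix
  path, whose convention also uses inclusive `p ≤ α` rather than strict
  `p < α`.

The two grids are configurable independently because the source
conventions genuinely differ between the two procedures, and no single
test can serve both. A cell is *significant* only if the p-value clears α
**and** the treated median exceeds the reference median. The elevation
gate means suppression never counts as induction, and under the null it
roughly halves the two-sided level — the observed null call rate near
0.024 at α = 0.05 (measured over 200 synthetic null studies) is the
expected behaviour, not a bug.

No multiple-testing correction is applied by default: the selection rules
consume raw p-values and thresholds by construction. Callers who want FDR
control can apply `p.adjust` to the grid's `p` column themselves.

## Selection rules

**Signature cytokine.** Doses are scanned ascending; at the first dose
with ≥ 1 significant cell the minimum-p cytokine wins. Ties in p are real
(exact p-values are discrete: with 10 donors the floor is 2/1024), so the
tie-break is a fixed panel order, making every call deterministic.
**Top-k** is the same scan demanding ≥ k significant cytokines; if the
design is exhausted the significant set at the top dose is returned and
flagged `short` rather than erroring — stimuli with essentially no
cytokine response are an expected outcome, not a failure.
`select_top_k(k = 1)` coincides with the signature rule under identical
mode and strictness, and adding a lower all-null dose can never change a
call (both properties are tested).

**Modulation.** Matched (donor, dose) arms with and without drug
co-exposure are compared per (stimulus, cytokine), pooled over the
stimulus's doses by default (per-dose available); direction is the median
difference. Pooling was chosen as the default because the co-exposure
effect in this assay family is reported as a condition-level phenomenon,
and pooling gives 4× the pairs.

## Panel construction

The induction matrix (stimuli × cytokines, TRUE where selected) feeds an
*exact* set-cover search: cardinalities 1, 2, … are enumerated
exhaustively and the first admitting a cover is returned with **all**
covers of that size, in deterministic lexicographic panel order. With 16
cytokines the search is trivial (≤ 2¹⁶ subsets), and exactness matters:
claims of the form "two three-cytokine panels exist" are about minimum
covers, which a greedy heuristic cannot certify. A brute-force
all-subsets oracle confirms the search on random matrices in the suite.

The package ships `iirmi_reference_matrix()`, the top-3 induction matrix
of ten well-characterized IIRMIs on the 16-plex panel, as a built-in
combinatorial example; on it the minimum panel size is 3, and the
four-cytokine panel {MCP-1, MIP-1α, IL-8, IL-6} covers all ten stimuli.

## Clustering

The response matrix is the donor-averaged normalized value per condition
× cytokine, with missing cells imputed as 0 (the post-censoring floor)
and flagged. Clustering is agglomerative on Euclidean distances with
complete or Ward linkage. Both are offered because the assay literature
uses both names for this analysis; complete linkage is the default as the
more operational description of the dendrograms being emulated. Ward uses
the squared-distance (ward.D2) convention so heights remain on the
distance scale. The implementation delegates to `stats::hclust`; its
merge sequences are verified against a naive O(n³) Lance–Williams
agglomeration oracle (via cophenetic matrices, which determine the tree)
on random instances for both linkages. Tie handling on exactly equal
merge heights follows `hclust`; ties are measure-zero for continuous
data. Pearson-correlation clustering uses dissimilarity 1 − r and
excludes zero-variance items with a flag. Dendrograms export to Newick
with merge heights as branch lengths (`ape`).

## The synthetic generator

`generate_study()` emulates the study layout: NC and PC controls, ten
stimuli × four doses, optional drug co-exposure arms, duplicates, and
log-normal measurement structure:

log value = baseline(c) + donor(i, c) + emax·dʰ/(dʰ + EC50ʰ)
[+ co-exposure shift] + biological noise + replicate noise,

censored at the assay limits after exponentiation. Defaults, chosen once:

| parameter | default | rationale |
|---|---|---|
| donors | 10 | the emulated study size |
| replicates | 2 | duplicate wells |
| baselines | 50–1000 pg/mL (geometric spread) | typical unstimulated PBMC supernatant range; keeps NC wells mostly above a 5 pg/mL LLOQ |
| donor SD (log) | 0.8 | strong stable inter-donor heterogeneity ("high responders"); cancels in the paired design |
| biological SD (log) | 0.1 | within-donor, between-condition noise on one plate is mostly technical |
| replicate CV | 0.15 | realistic duplicate agreement, comfortably inside the %CV < 25 gate |
| LLOQ / ULOQ | 5 / 50 000 pg/mL | representative multiplex kit span |
| Emax (log) | 3 | planted effect size; ≈ 20-fold induction at saturation |
| EC50 | geometric mid-dose | centres the curve on the tested range |
| Hill | 0.5 | shallow population-aggregate slope of a heterogeneous PBMC mix |
| PC effect (log) | 4 | uniform strong induction; drives some PC wells into ADL, as real positive controls do |
| co-exposure | −2 on each planted signature, +2 on PGE-2 | the suppression/enhancement pattern the assay is used to detect |

Effect sizes have no empirical calibration target (none is published for
this assay); they were chosen for testability — large enough that the
pipeline *should* recover them, so that failures indict the code, not the
noise. Under these conditions, measured over 100 independent seeds by the
acceptance script, the planted signature is recovered in ≥ 95% of
(seed, stimulus) calls and planted co-exposure directions are called
correctly in ≥ 95% of cases; over 200 null seeds the significant-call
rate stays in [0.02, 0.09].

What the generator does **not** emulate: plate/batch effects, spatial
well effects, cross-cytokine correlation beyond shared donor offsets,
non-monotone dose–response (e.g. high-dose exhaustion — expressible via a
negative co-exposure-style term but not planted by default), standard
curve back-calculation error, and cohort-specific handling losses. A
green synthetic suite therefore demonstrates correctness of the
*statistics*, not robustness to every artefact of real plates.

## Problem sizes used in validation

The shipped tests and the acceptance script use: exact-test oracle
enumeration up to total n = 10; 50 random tables for normalization
invariance (25 in the script); 100 seeds for signature recovery; 200
seeds for the null rate; 50 random matrices (≤ 8 × 6) per linkage for the
clustering oracle; 100 seeds for modulation directions. These sizes give
Monte-Carlo standard errors well below the margins being asserted while
keeping a full run in minutes on one CPU.

## Known limitations

* The BDL → 0 substitution discards sub-LLOQ ordering information; a
  censored-likelihood model would use it, at the price of parametric
  assumptions the rank pipeline avoids.
* The signature rule is greedy in dose: a cytokine overwhelmingly
  significant at dose 2 loses to a marginal winner at dose 1. This is
  faithful to the procedure being implemented, but users should read the
  full grid, not only the calls.
* Exact p-values with 10 donors are bounded below by 2/1024 (paired), so
  "lowest p" ties are common; the panel-order tie-break is deterministic
  but arbitrary.
* With strict `p < α` and unpaired 3 vs 3 samples the minimum two-sided
  exact p is 0.1: very small pilot studies cannot produce calls at
  α = 0.05, by arithmetic rather than by software choice.
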