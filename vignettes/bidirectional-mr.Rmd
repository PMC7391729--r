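---
title: "Bidirectional two-sample Mendelian randomization with bimr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bidirectional two-sample Mendelian randomization with bimr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bimr)
```

## The problem

Mendelian randomization (MR) uses genetic variants as instrumental
variables to test whether a modifiable exposure causally affects an
outcome. A valid instrument must (1) associate with the exposure
(relevance), (2) share no common cause with the outcome (independence),
and (3) affect the outcome only through the exposure (exclusion). In the
two-sample design, the SNP–exposure and SNP–outcome associations come from
summary statistics of two non-overlapping GWAS, which is the only workable
design when the exposure (for example a serum metabolite) and the outcome
(for example estimated glomerular filtration rate, eGFR, in
mL/min/1.73 m²) were never measured in the same large cohort. Running the
analysis in both directions — metabolite → kidney function and kidney
function → metabolite — distinguishes cause from consequence: a real
causal signal should appear in one direction and not re-appear as its own
mirror image in the other.

`bimr` implements this pipeline end to end: instrument selection, allele
harmonization, estimation, sensitivity diagnostics, family-wise
correction, and a ground-truth synthetic generator used to validate every
stage offline.

## Instrument selection

Instruments are SNPs with exposure association `p < 5e-8` (genome-wide
significance), pruned to mutual linkage-disequilibrium independence at
`R² < 0.2`. Pruning is greedy: candidates are ranked by ascending p-value
(ties broken lexicographically by rsid — the ranking source is silent on
ties, and determinism matters more than the particular rule) and a
candidate is kept iff its known R² with every already-kept SNP is below
the threshold. Pairs absent from the LD table are treated as independent
by default; `unknown_ld = "dependent"` gives the conservative behaviour.

Instrument strength is summarised per SNP by `F = (beta/se)²`, the
squared z-score, which approximates the single-instrument first-stage F.
The R²-based alternative is deliberately not implemented because
effect-allele frequency and sample size are optional columns in several
published metabolite GWAS.

One caveat worth knowing: greedy pruning at a *tighter* R² threshold is
guaranteed to return a subset of the looser run only when the LD table is
block-coherent (one R² level within a block, as reference panels
produce). For arbitrary intransitive pairwise tables a pruned SNP can
admit a later candidate, and the nesting can break. The property tests
assert nesting on block LD only.

## Harmonization

Outcome effects are re-expressed per copy of the exposure's effect
allele. Identical allele pairs are kept (same orientation) or
sign-flipped (swapped orientation); pairs that match only after
complementing both outcome alleles are strand-flipped first. Palindromic
SNPs (A/T, G/C) cannot be strand-resolved from allele labels; the default
policy `infer_by_eaf` aligns by the minor-allele side when both
effect-allele frequencies lie outside `0.5 ± 0.08` and drops the SNP as
ambiguous otherwise. The window (0.08) mirrors common two-sample MR
practice; both policy and window are configurable, and every dropped
instrument is logged with its reason rather than silently discarded.
Matching is rsid-keyed, which is how the relevant summary statistics are
published; positional matching is out of scope.

Effect sizes are never rescaled across studies. Metabolite GWAS are
typically on unitless, differently transformed scales, so estimates are
comparable in sign and significance but not in magnitude — the results
table should be read accordingly.

## Estimators

With ratio estimates `r_i = by_i / bx_i` and first-order weights
`w_i = bx_i² / sy_i²`:

* **Wald ratio** (single instrument): `by/bx`, first-order SE `sy/|bx|`,
  or the second-order delta-method SE
  `sqrt(sy²/bx² + by²·sx²/bx⁴)` on request.
* **IVW**: `Σ w_i r_i / Σ w_i`, algebraically the weighted regression of
  `by` on `bx` through the origin; fixed-effect SE `1/sqrt(Σ w_i)` is the
  headline mode, and multiplicative random effects inflate it by
  `sqrt(max(1, Q/(n−1)))`. A single pair reduces *bitwise* to the Wald
  ratio. Second-order weights are not implemented (first-order is the
  standard default of the tooling this mirrors).
* **MR-Egger**: weighted least squares of `by` on `bx` with intercept
  (weights `1/sy²`) after orienting all `bx ≥ 0`; the intercept estimates
  average directional pleiotropy, the slope is the adjusted causal
  effect. P-values use a t reference on `n − 2` df — with 3–22
  instruments the difference from the normal is material. Requires ≥ 3
  instruments, otherwise the analysis is reported "NA".
* **Weighted median**: the ratio at which cumulative normalized weight
  crosses one half (interpolated); consistent when valid instruments
  carry ≥ 50% of weight. SE from a seeded parametric bootstrap
  (default 5,000 draws).
* **Cochran's Q**: `Σ w_i (r_i − θ̂)²` on `n − 1` df against the pooled
  estimate, the heterogeneity alarm bell.
* **MR-PRESSO**: for each SNP the leave-one-out IVW estimate and the
  weighted squared residual; the observed global residual sum of squares
  is compared to `n_sim` parametric simulations
  (`bx* ~ N(bx, sx)`, `by* ~ N(θ̂₋ᵢ·bx, sy)`), with add-one empirical
  p-values, per-SNP Bonferroni-corrected outlier flags, and an
  outlier-corrected IVW estimate that equals `ivw()` on the non-flagged
  subset exactly. `n_sim < 100` is rejected (the empirical p would be too
  coarse); the default is 1,000 and the seed is mandatory. A distortion
  diagnostic (corrected-vs-full difference against random subsets of the
  same size) is computed but informational only.

Every estimate is reported with the same convention: 95% interval
`estimate ± 1.959964·se` and two-sided normal p (t for Egger). Results
files render estimates to 4 significant digits and p-values as `6.26E-04`
style scientific notation.

## Family-wise correction and orchestration

`run_analysis()` executes select → harmonize → estimate for one spec. The
main estimate is the Wald ratio iff exactly one instrument survives and
IVW otherwise; Egger, median and Q attach at ≥ 3 instruments, MR-PRESSO
at ≥ 4; zero surviving instruments produce a "not analyzable" row rather
than an error. `bonferroni_threshold(n_forward, n_reverse, alpha)` is
`alpha/(n_forward + n_reverse)`; the per-direction counts are *declared*
analysis units, deliberately decoupled from the number of dataset pairs
run, because a trait measured in several studies may still count once in
the family. Significance is a strict inequality against the threshold
(the boundary case is not significant); that choice is documented rather
than derivable, since bold-face conventions in published tables rarely
state it.

`run_sensitivity_suite()` repeats an analysis under stricter pruning
(`R² < 0.001`), tightened significance (`p < 1e-10`, `p < 1e-20`),
keep-lists (replication- or annotation-based selections) and drop-lists
(cross-trait or pleiotropy exclusions, fed by `cross_trait_overlap()`).
Annotation sources are accepted only as plain rsid lists — no database
queries.

## The synthetic generator

`simulate_two_sample()` draws from the structural model

    X = Σ γ_j G_j + c_x U + e_x
    Y = θ X + Σ α_j G_j + c_y U + e_y

with SNP dosages `G_j ~ Binomial(2, maf_j)`, a shared standard-normal
confounder `U`, and noise scaled so X and Y have unit variance in
expectation. Two independent samples are drawn (separate seed streams for
the exposure and outcome samples), and per-SNP *marginal* simple
regressions — the GWAS convention — produce beta, SE, p and EAF, so all
reported columns and the realized-LD table are mutually coherent. An
`asymptotic` mode draws effect estimates directly from their sampling
distributions (`se = 1/sqrt(n·2·maf·(1−maf))` for unit-variance traits)
for large-replicate property tests at a fraction of the cost; its LD is
empty and its SNPs independent.

Choices worth calling out:

* **Directional pleiotropy is oriented.** Direct effects `α_j` are drawn
  `N(pleio_mean, pleio_sd)` *relative to the exposure-increasing allele*.
  On arbitrary allele coding a non-zero mean cancels under Egger's
  `bx ≥ 0` orientation and "directional" pleiotropy would be undetectable
  by construction. Balanced pleiotropy (`pleio_mean = 0`) is unaffected.
* **Outliers are sized for detectability**: `outlier_mult` (default 8)
  times the SNP's expected outcome SE, i.e. about 8 residual SDs on the
  ratio scale.
* **Harmonization is exercised by default**: a configurable fraction of
  outcome rows is reported with swapped allele orientation (25%), on the
  opposite strand (15%), and with palindromic allele pairs (10%) —
  roughly the mix a real cross-study merge presents.
* **LD blocks** use a latent-Gaussian haplotype model; the realized
  genotype R² is attenuated relative to the latent correlation, and it is
  the realized value that goes into the LD table.

`make_fixture_registry()` bundles a deterministic stand-in for the
multi-study setting: a complex kidney-function-like trait with 79
independent genome-wide-significant SNPs (75 primaries + 4 tags at
R² = 0.1) at n = 133,413, and four metabolite-like traits with 1, 2, 5
and 22 instruments at n = 1,960–7,824, instrument z-scores drawn in
[8, 15] and [6, 11.6] respectively (per-instrument F in the tens to
hundreds), one instrument shared between two metabolites, and a
reverse-only causal structure (kidney trait → metabolite, θ = −0.2; no
forward effects). Planted instruments are guaranteed genome-wide
significant by redrawing the rare borderline draw — a mild, seeded
truncation. These sample sizes, instrument counts and scales are the
regimes of the real multi-study setting this package targets; they are
fixed, not tuned.

What a green test on this world does *not* establish: realistic genome
LD, winner's curse in instrument discovery, sample overlap between the
two GWAS (the generator is strictly two-sample), transformation
heterogeneity between laboratories, or anything about effect
*magnitudes* on real scales.

## Numerical and degenerate-input choices

* `se ≤ 0`, `pvalue ∉ (0, 1]`, non-ACGT or indel alleles are validation
  errors (strict mode, the default) or logged drops (lenient mode).
* `bx = 0` is a domain error for the Wald ratio and a logged exclusion
  for IVW.
* Empirical p-values use the add-one rule, so they are bounded below by
  `1/(n_sim+1)` and never zero.
* Simulated p-values are floored at `1e-320` to stay inside (0, 1] in
  double precision.
* Fewer than 3 instruments renders sensitivity estimators "NA"; fewer
  than 4 disables MR-PRESSO; both mirror how such tables are reported.
* All stochastic steps (median bootstrap, MR-PRESSO, generator) take
  explicit seeds and restore the caller's RNG state; two runs with the
  same inputs produce byte-identical result files.

## Known limitations

Correlated-instrument (generalized) IVW, mode-based estimators,
multivariable MR and proxy-SNP search are out of scope. LD enters only as
a precomputed table; the package never computes LD from genotype panels.
Harmonization cannot rescue allele pairs that are inconsistent after
strand and orientation resolution — such SNPs are dropped and logged, not
guessed.
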