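---
title: "Methods: bidirectional two-sample MR for gut microbiota and pancreatitis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bidirectional two-sample MR for gut microbiota and pancreatitis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrbiome)
```

## The question and the design

Observational associations between gut-microbiome composition and
pancreatitis are vulnerable to confounding (diet, alcohol, medication)
and to reverse causation (disease changing the flora). Two-sample
Mendelian randomization (MR) sidesteps both by using germline variants
as instruments: SNPs associated with the abundance of a bacterial taxon
(exposure GWAS, a MiBioGen-style consortium panel of 196 analyzable
taxa across five ranks) are looked up in an independent case-control
GWAS of a pancreatitis phenotype (FinnGen-style: acute, chronic,
alcohol-induced acute, alcohol-induced chronic), and the per-SNP effect
ratios are combined into a causal log-odds estimate. Running the same
machinery with disease as the exposure and taxa as outcomes probes
reverse causation; `run_bidirectional()` orchestrates both directions.

The MR estimate is valid under the three instrumental-variable
assumptions: relevance (instrument associated with the exposure),
exchangeability (no confounder of instrument and outcome) and exclusion
restriction (no effect on the outcome except through the exposure).
Every component of this package is either an enforcement of one of
these assumptions (instrument screening, the confounder blacklist) or a
diagnostic for their failure (Egger intercept, Q, MR-PRESSO,
leave-one-out).

## Instrument selection

For each exposure the filter cascade is, in a fixed logged order:

1. **p-value screen**, strict `p < 1e-5` (the inclusive threshold used
   for microbiome GWAS, where genome-wide-significant hits are rare);
2. **LD clumping**, greedy by ascending p with lexicographic rsid
   tie-break, removing SNPs within 10,000 kb of a retained index SNP
   with `r² ≥ 0.001`. SNP pairs absent from the LD panel count as
   `r² = 0`: panels are sparse and dropping unmatched SNPs would
   silently discard instruments. The deterministic tie-break makes the
   output invariant to input row order.
3. **confounder blacklist**, a static rsid list standing in for an
   interactive phenome scan;
4. **weak-instrument filter**, per-SNP `F = β²/SE²` with `F < 10`
   excluded. Per-SNP variance explained is
   `R² = β²/(β² + n·SE²)` (algebraically equal to the
   `2f(1−f)` form), and the aggregate instrument strength is the
   standard `F = (R²/(1−R²))·(n−k−1)/k`. An alternative printed form of
   the aggregate F circulating in the applied literature,
   `(n−k−1)²/(1−R²)`, squares the degrees-of-freedom term and omits k;
   it is not a valid strength estimator and is exposed only behind
   `literal_form = TRUE` so audits can reproduce numbers computed with
   it.

The order (screen → clump → blacklist → F) follows standard practice:
clumping must see the full significant set, and the last two filters
commute.

## Harmonization

Exposure and outcome effects must refer to the same effect allele.
For each instrument: same allele pair and orientation is kept;
swapped orientation negates the outcome beta and mirrors its EAF;
non-palindromic pairs that match only after strand complementation
(A↔T, C↔G) are reconciled the same way; anything else is removed as a
mismatch. Palindromic SNPs (A/T, C/G) are removed unconditionally —
no allele-frequency rescue window — because strand orientation is
genuinely unidentifiable from summary data and the upstream screens
leave enough instruments. Instruments missing from the outcome study
are dropped (no proxy lookup). Every removal is audited with exactly
one reason; harmonization is idempotent and exactly inverts the
simulator's allele scrambling on non-palindromic SNPs.

## Estimators

With aligned per-SNP effects `(β_X,j, σ_X,j, β_Y,j, σ_Y,j)` the ratio
estimates are `θ_j = β_Y,j/β_X,j` with first-order standard errors
`σ_Y,j/|β_X,j|` (first-order weights throughout; no NOME correction).

- **Wald ratio** (single instrument): `θ = β_Y/β_X`, normal inference.
- **IVW** (primary): precision-weighted mean of the `θ_j`, identical to
  the WLS slope of `β_Y` on `β_X` through the origin with weights
  `1/σ_Y²`. The SE uses multiplicative random effects: the fixed-effect
  SE inflated by `max(1, sqrt(Q/(J−1)))`. This matches the common
  toolchain default and is conservative under heterogeneity;
  `model = "fe"` disables it.
- **MR-Egger**: weighted regression *with* intercept after orienting
  all `β_X,j ≥ 0` (the intercept — the average directional pleiotropic
  effect — is only interpretable relative to the exposure-raising
  allele). Slope inference uses t(J−2) with residual inflation bounded
  below by 1. The intercept test deliberately does **not** apply the
  lower bound: with it, the test's null rejection rate collapses to
  ≈ 0.02; without it the weighted-lm t-test is exactly calibrated
  under the no-pleiotropy null. This split (bounded slope, plain
  intercept) also mirrors the convention of the widely used MR
  toolchains.
- **Weighted median**: order the `θ_j`, interpolate at cumulative
  weight 0.5 (midpoint convention); consistent while ≥ 50% of weight is
  valid. SE by parametric bootstrap (`θ*_j ~ N(θ_j, se_j)`, default
  5,000 draws, fixed seed).
- **Weighted mode**: mode of the inverse-variance-weighted Gaussian
  kernel density of the `θ_j`. The bandwidth is `bandwidth_factor`
  times the median absolute pairwise deviation of the ratios — a
  robust scale that ignores a minority of dispersed invalid
  instruments. The density maximum of a Gaussian mixture lies in the
  convex hull of its means, so a 2048-point grid over the ratio range
  brackets it and a local `optimize()` refines it; bootstrap draws use
  a 512-point grid without refinement. As the bandwidth grows the
  estimate tends to the weighted mean (verified numerically).
- **MR-PRESSO**: observed residual sum of squares against leave-one-out
  IVW predictions, compared with its parametric simulation distribution
  (default 1,000 draws); per-SNP outlier p-values from the simulated
  residual contributions, Bonferroni-adjusted across instruments.
  While the global test rejects at 0.05 and adjusted outlier p-values
  below 0.05 remain, the SNP with the smallest outlier p is removed —
  strictly one at a time, iterating to exhaustion (the removal depth is
  not capped). With a finite simulation count several SNPs can tie at
  simulated p = 0; ties are broken by the largest observed residual
  contribution, which removes the most aberrant SNP first. A
  distortion test compares the pre/post-removal IVW difference with
  the differences from removing equally many random SNPs (1,000
  permutations).

Estimator dispatch follows the instrument count: 1 → Wald ratio,
2 → IVW, ≥ 3 adds Egger/median/mode, ≥ 4 adds PRESSO; IVW is the
primary analysis everywhere. All estimators sort instruments by rsid
internally, so every stochastic procedure is invariant to input order
given its seed.

## Sensitivity diagnostics

Cochran's Q uses fixed-effect weights even though the headline IVW is
random-effects — the chi-square null for Q requires them — and the same
Q feeds the IVW inflation factor (single source of truth).
Leave-one-out refits the random-effects IVW omitting each SNP in turn
(matching the headline estimator; the alternative of FE per omission
changes nothing qualitatively) and flags stability when every omission
preserves the sign and nominal significance of the full estimate.

## Multiplicity and tiers

The Bonferroni divisor is the number of *analyzable* (non-unknown)
taxa at the corresponding taxonomic level — phylum 9, class 16,
order 20, family 32, genus 119 from the packaged registry; unknown
groups never enter the analysis, so they do not count as tests. The
worked class-level example (raw p 0.0005 × 16 = 0.008) pins this
convention down. In the reverse direction the divisor comes from the
microbial *outcome's* level, mirroring the forward rule. BH-FDR is
applied within each (disease, level, method) family. Tiers:
`significant` if Bonferroni-adjusted p < 0.05, `suggestive` if only the
raw p < 0.05, `null` otherwise. The reverse-direction instrument
threshold defaults to the same 1e-5 (config-overridable).

## The synthetic-data generator

Because the consortium data cannot be redistributed, every stage is
exercised on summary-level simulations. For SNP j with effect-allele
frequency `f_j`:

- `se_X,j = 1/sqrt(2 f_j (1−f_j) n_X)` with `n_X = 18,340`;
- `se_Y,j = 1/sqrt(2 f_j (1−f_j) n_eff)`,
  `n_eff = 4/(1/n_cases + 1/n_controls)` (the standard effective-size
  approximation for log-odds statistics), defaulting to the acute-
  pancreatitis cohort (3,022 cases / 195,144 controls);
- `β_X,j ~ N(γ_j, se_X,j²)`, `β_Y,j ~ N(θγ_j + α_j + ω_j, se_Y,j²)`.

True effects `γ_j` have magnitudes uniform on 0.08–0.15 (random sign),
chosen once so that simulated exposure associations clear the p < 1e-5
screen with per-SNP F around 50–180 — i.e. the strong-instrument regime
the real pipeline enforces. MAFs are uniform on 0.05–0.5; the default
instrument count is 15, inside the representative 5–25 range for taxon
GWAS. Pleiotropy `α_j` is mean-zero (balanced) or mean `μ` carried by
`sign(γ_j)` (directional): directional pleiotropy is defined relative
to the exposure-raising allele, because with arbitrary allele coding a
fixed-sign direct effect is re-randomized by Egger's orientation step
and would be indistinguishable from balanced pleiotropy. Outliers
(`round(outlier_frac · J)` SNPs, drawn without replacement) receive
direct effects of `outlier_scale` (default 10) times the median
`|θγ|`, with random or fixed sign; the fixed-sign variant doubles as a
directional invalid-instrument scenario. Simulation is purely at the
summary level — no individual genotypes — which keeps every test
sub-second and is exactly the information two-sample MR consumes.

What the generator does *not* emulate: real LD structure (blocks are
exchangeable with constant within-block r²), allele-frequency
differences between cohorts, sample overlap, winner's curse from
discovery in the same data, and non-normal effect-size distributions.
Passing tests therefore demonstrate the correctness and calibration of
the statistical machinery under its stated assumptions, not robustness
to those additional features of real consortium data.

## Numerical choices and degenerate inputs

- Ties everywhere (clump index choice, sort order) break
  lexicographically by rsid for reproducibility; PRESSO outlier-removal
  ties break by observed residual magnitude as described above.
- CI multiplier is the exact normal 97.5% quantile except Egger, which
  uses t(J−2).
- `β_X = 0` makes the Wald ratio an error; zero heterogeneity gives
  inflation factor exactly 1; an all-identical-ratio set gives Q = 0
  and p = 1; an empty instrument set yields a first-class skip record,
  not an error.
- Missing EAF or n is tolerated at read time and fails fast (with an
  audit entry) only in operations that need them (R², aggregate F).
- Duplicated rsids are dropped entirely (all copies): a duplicated
  identifier is ambiguous and no tie-break is defensible.
- EAF consistency between exposure and outcome after harmonization is
  not enforced (informational only): summary panels often differ in
  ancestry composition.

## Problem sizes in the test-suite

The packaged suites run calibration at 1,000 null replicates (type-I
error of IVW, Egger intercept, Q, PRESSO global), recovery at 500
replicates per causal-effect value, contamination and outlier-recovery
studies at 200 replicates, and PRESSO with 300–500 simulation draws
inside replicate loops — sizes chosen to put Monte-Carlo error well
below the decision margins while keeping the whole suite around a
minute of CPU.

## Known limitations

- First-order ratio weights carry finite-sample regression-dilution
  attenuation of order `1/F` per instrument (about 1–1.5% of θ at the
  generator's default strength). Mean recovery of large effects is
  dominated by this attenuation rather than by Monte-Carlo noise: at
  θ = −0.5 the mean IVW estimate is ≈ −0.493. Applications that need
  unbiased point estimates under weaker instruments should treat the
  IVW sign and interval, not its third decimal, as the deliverable.
- MR-PRESSO's outlier test inherits the discreteness of its simulated
  null; with few draws, outlier p-values saturate at 0.
- The weighted-mode bandwidth rule is a pragmatic robust-scale choice;
  no bandwidth selector is optimal for all contamination patterns.
- The blacklist is static; it cannot discover new confounder
  associations the way a live phenome scan would.
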