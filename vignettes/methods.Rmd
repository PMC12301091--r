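---
title: "Methods: matched-SNP PheWAS enrichment, two-sample MR, and colocalization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: matched-SNP PheWAS enrichment, two-sample MR, and colocalization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`phemr` implements the statistical chain used to link one disease's GWAS
risk loci to the rest of the phenome: (i) covariate-matched control-SNP
selection and Fisher-exact trait enrichment, (ii) phenome-wide and
bidirectional two-sample Mendelian randomization (MR), and (iii) Bayesian
colocalization of regional summary statistics. This vignette documents the
models, the tunable parameters and their defaults, the numerical choices,
and what the synthetic-data generators do and do not emulate.

## Risk-locus selection and matched controls

Independent risk loci are obtained by greedy LD pruning
(`ld_prune()`): SNPs are visited in order of ascending p-value (ties
broken by SNP id) and retained unless correlated at `r² ≥ r2_max` with an
already-retained SNP. The disease-locus default is genome-wide
significance `p < 5e-8` with a stringent `r² < 0.001`; secondary exposures
use `p ≤ 1e-5` (inclusive) with `r² < 0.1` and a minor-allele-frequency
floor of 0.01. Pruning is purely r²-based over the supplied LD matrix; no
physical clumping window is applied, because the matrix already encodes
locality.

Control SNPs (`match_controls()`) emulate the SNPsnap matching procedure:
for each risk SNP, candidates must fall inside four covariate windows —
minor-allele frequency within ±5%, gene density, distance to nearest gene
and LD-buddy count (other SNPs at `r² ≥ 0.50`) within ±50% — and be
unlinked (`r² < 0.1`) to every risk SNP and every control already chosen.
Windows are *relative* (±5% of the risk SNP's MAF, not ±0.05); an
absolute-window mode is available because the published convention is
ambiguous. A zero nearest-gene distance degenerates the relative window to
a point, so it falls back to an absolute ±10 kb window. Controls are
*sampled* uniformly from the eligible pool with a seeded generator rather
than taken nearest-neighbour: sampling yields a proper null ensemble for
the enrichment test, whereas nearest-neighbour matching would
systematically understate covariate variability. When a pool is smaller
than `k` the function either errors with the pool size or, in relax mode,
doubles all tolerances stepwise (up to three doublings) and flags the
affected controls.

## PheWAS enrichment

For each trait, associations are counted at a strict nominal threshold
(`p < 0.01`; a p-value exactly at the threshold does not count, and
missing p-values never count). Traits with zero associated risk SNPs are
excluded from testing *and* from the multiple-testing family; the family
size is reported so the alternative (all-traits) family can be
reconstructed. Each remaining trait contributes a 2×2 table
(associated / not) × (risk set / control set) tested with a two-sided
Fisher exact test by the point-probability rule — the convention of
mainstream statistics libraries, with a relative tie tolerance of 1e-7 —
followed by Benjamini–Hochberg adjustment. The implementation sums
hypergeometric point probabilities via `stats::dhyper`; the test suite
checks it against an independent binomial-coefficient enumeration and
against `stats::fisher.test`.

## Two-sample MR estimators

For instrument *j*, let `βx_j, σx_j` be its exposure association and
`βy_j, σy_j` its outcome association after allele harmonization. All
estimators use first-order ("IVW") weights `w_j = βx_j²/σy_j²` and
two-sided normal inference with `CI = θ ± 1.96·se`; the Wald ratio SE uses
the first-order delta method only (`σy/|βx|`), ignoring exposure-side
noise, which is accurate for strong instruments.

* **IVW**: `θ = Σ w_j (βy_j/βx_j) / Σ w_j`. Heterogeneity is Cochran's
  `Q = Σ w_j (βy_j/βx_j − θ)²` on `J−1` df. The *multiplicative random
  effects* model — the primary analysis — inflates the fixed-effect SE by
  `max(1, sqrt(Q/(J−1)))`.
* **MR-Egger**: weighted least squares of `βy` on `βx` with a free
  intercept after orienting every instrument to `βx ≥ 0`; the intercept
  estimates directional pleiotropy and its normal test is the pleiotropy
  diagnostic; residual `Q` has `J−2` df and scales both SEs under the
  random-effects model.
* **Weighted median**: ratio estimates sorted ascending with normalized
  weights; the estimate interpolates linearly between the ratios whose
  cumulative midpoint weights bracket 0.5. Consistent while valid
  instruments retain a majority of weight. Note that duplicating every
  instrument re-knots this interpolant, so the estimate is only
  gap-stable, not exactly invariant, under duplication.
* **Weighted mode**: the argmax of a weighted normal-kernel density over
  the ratios, bandwidth `φ·0.9·min(sd, IQR/1.34)·J^(−1/5)` with `φ = 1`,
  evaluated on a 512-point grid spanning the ratios ±3 bandwidths; if all
  ratios coincide the common ratio is returned exactly.

Weighted-median and weighted-mode SEs come from a parametric bootstrap
(default 1000 draws, seeded): `βx, βy` are redrawn from normal
distributions with their reported SEs and the point estimate recomputed.
Bootstraps below 100 draws warn; `n_boot = 0` skips the SE.

`mr_phewas()` fixes one instrument set and screens every phenome trait
with IVW-RE, skipping traits with fewer than two overlapping instruments,
then applies BH-FDR across analysed traits. `bidirectional_mr()` runs the
four-estimator panel in both directions with direction-specific instrument
thresholds, since each exposure GWAS carries its own selection rules.

## Allele harmonization

Outcome records are aligned to the exposure's effect allele: swapped
alleles flip the outcome beta sign and complement the effect-allele
frequency; alleles matching after complementing both are treated as strand
flips. Palindromic SNPs (A/T, C/G) are dropped by default — the
conservative convention, since strand cannot be resolved from alleles —
or, under the `keep` policy, oriented by effect-allele frequency and
dropped only when either frequency lies within `eaf_tol = 0.08` of 0.5.
Pairs with irreconcilable alleles are excluded and counted. Missing EAF is
tolerated except where an operation needs it (the MAF filter, palindrome
orientation). Positions are 1-based GRCh37; the build matters only for the
MHC window constant.

## Colocalization

For each SNP the Wakefield approximate Bayes factor compares `H1: β ~
N(0, W)` against `H0: β = 0` given the estimate and its variance `V`:
`log ABF = ½(log(1−r) + r·z²)` with `r = W/(V+W)`, `z = β/se`. The prior
effect scale `sqrt(W)` defaults to 0.15 for quantitative traits (eQTL
effects) and 0.2 for binary traits (log-odds) — the conventional choices.
Under the one-causal-variant-per-trait assumption the five hypotheses are
scored as H0: 1, H1: `p1·S1`, H2: `p2·S2`, H3: `p1·p2·(S1·S2 − S12)`,
H4: `p12·S12`, where `S1, S2, S12` are sums of `exp(lABF)` terms, and
normalised. Priors default to `p1 = p2 = p12 = 1e-4` — the values this
analysis chain ships with; note the broader convention for `p12` is 1e-5,
and the prior is overridable.

Numerically everything is evaluated in log space with log-sum-exp. The H3
term is the sum over *ordered pairs of distinct SNPs*; for regions up to
1000 SNPs it is computed exactly as an off-diagonal log-sum-exp rather
than by the subtraction `S1·S2 − S12`, which suffers catastrophic
cancellation when one SNP dominates both traits. For larger regions the
subtraction is used and a non-positive difference is clamped to zero with
a message. A single-SNP region yields `PPH3 = 0` exactly. Regions are cut
to a cis window of ±1000 kb around the gene and the extended MHC
(chr6:26–34 Mb, GRCh37) is excluded, because its long-range LD breaks the
single-causal-variant assumption. Instrument strength is summarised by
`F = (β/se)²` per signal with the conventional `F ≥ 10` flag. The
`p < 5e-8` eQTL significance rule applies to instrument-based MR of
expression, not to coloc inputs: colocalization uses the full region.

## Synthetic-data generators

All generators are pure functions of their parameters and a seed; each
draws from a substream derived from the root seed and a generator label,
so adding one generator never perturbs another's draws.

* **SNP universe** (`simulate_snp_universe()`): MAF ~ U(0.01, 0.5), gene
  density ~ Poisson(8), nearest-gene distance ~ Exp(mean 20 kb),
  LD buddies ~ negative binomial (mean 30, size 5); LD is block-diagonal
  with blocks of 5 at within-block `r² = 0.3`. Matching feasibility is
  guaranteed by construction: each risk SNP receives clones of its
  covariates (jittered inside the windows) in otherwise-unused LD blocks.
  Two deliberate deviations from pure sampling make the guarantee exact
  rather than probabilistic: risk SNPs occupy disjoint log-spaced MAF
  slots, so no risk SNP's ±5% window overlaps another's and a clone can
  never be consumed by the wrong risk SNP; and the block-mates of clones
  are given multi-megabase nearest-gene distances so they can never be
  selected as controls and thereby place a selected control in LD with a
  clone.
* **Phenome** (`simulate_phenome()`): exchangeable null — every SNP-trait
  pair is "associated" with probability `base_rate = 0.01`
  (p ~ U(0, 0.01), else U(0.01, 1)); planted traits use rate `q1` on risk
  SNPs and `q0` elsewhere. The published design point is 2514 traits over
  35 risk + 140 control SNPs with a planted trait at `q1 = 0.45`,
  `q0 = 0.05`, mirroring the strongest observed enrichment (16/35 vs
  8/140).
* **Two-sample GWAS** (`simulate_two_sample_gwas()`): true effects
  `b_j ~ |N(0, 0.05²)|` rejection-sampled to be detectable at the exposure
  sample size — instruments are coded to the exposure-increasing allele,
  the convention under which directional pleiotropy has a common sign.
  SEs follow `1/sqrt(2·maf·(1−maf)·n)` (standardised-trait approximation;
  binary-trait effects are simulated directly on the log-odds scale, with
  no liability model — adequate for estimator testing). The outcome truth
  is `θ·b_j + α_j` with pleiotropy `α_j ~ N(mean, sd²)` plus optional
  heterogeneity noise. A fraction `prop_invalid` of instruments receives
  an extra pleiotropic offset; the invalid instruments are the *weakest*
  fraction (smallest `b_j`), which is both plausible — pleiotropy tends to
  dominate weak instruments — and keeps the valid set holding the
  majority of IVW weight, the regime where the weighted median's breakdown
  property applies (at exactly half the *weight* invalid, the estimator is
  at its theoretical breakdown point and no method of this family
  recovers θ). Allele swaps and strand flips are planted in ~30%/~20% of
  outcome rows to exercise harmonization.
* **Coloc regions** (`simulate_coloc_region()`): AR(1) LD
  `Σ_ij = ρ^|i−j|`, per-trait z-vectors `~ MVN(Σλ, Σ)` with `λ` carrying
  the causal z-score at the scenario's causal index; H3 places the two
  causal variants far enough apart that `r² < 0.01`.

What the generators do *not* emulate: realistic genome-wide LD (block
structure only), winner's-curse selection of published loci, sample
overlap between exposure and outcome GWAS, case-control ascertainment, or
trait correlation across the phenome. Passing tests therefore demonstrate
correctness of the estimators and decision rules under their stated
assumptions, not robustness to those real-data complications.

## Verification design and problem sizes

The test suite verifies each primitive against an independent oracle:
Fisher p-values against binomial-coefficient enumeration (1000 random
tables, N ≤ 60, 1e-10 relative), BH against the literal step-up
definition (1000 vectors), colocalization against enumeration over the
causal-configuration space (500 regions of ≤ 6 SNPs, 1e-10 relative on
non-negligible components), and fixed-effect IVW against the
origin-constrained weighted-least-squares normal equations. Calibration
and recovery use seeded simulations at the study's design sizes: IVW-RE
bias and 95% CI coverage at θ = 0.3 with J = 200 instruments and GWAS
sample sizes of 200,000 per side over 1000 replicates (biobank-scale
samples; with much smaller GWAS the first-order weights are known to
undercover for instruments near the detection threshold); Egger intercept
recovery of planted directional pleiotropy 0.1 over 200 replicates;
weighted-median robustness at 50% invalid instruments over 200
replicates; null calibration of the phenome-wide screen (500 traits) and
of enrichment (500 exchangeable phenome replicates); and coloc scenario
calibration (200 shared- and 200 distinct-causal-variant regions at
n = 10,000, causal z ≈ 8, ρ = 0.9, 50 SNPs) against the PPH4 > 80%
decision rule. The end-to-end check runs the 35-risk-SNP, k = 4 design
(175 SNPs) against a 2514-trait phenome and requires the planted trait to
rank first and pass FDR < 0.05.

## Known limitations

* LD matrices are inputs (or simulated); the package computes no LD from
  genotype panels and performs no physical-window clumping.
* No MR-PRESSO outlier removal, Steiger filtering, or multivariable MR;
  no SuSiE-style multi-causal colocalization.
* The weighted-median/mode bootstrap treats instruments as independent.
* Fisher enrichment treats SNPs as exchangeable units; residual LD between
  risk and control SNPs below the independence threshold is ignored.
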