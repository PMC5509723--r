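---
title: "Models and methods behind landgen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind landgen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

landgen implements the two-marker intraspecific study design: demographic
inference from a single aligned sequence locus, and
differentiation/selection/association analysis from a genome-wide
dominant-marker (AFLP) panel. This vignette records the models, the
numerical choices, and the places where the design was genuinely open and
a decision had to be made. Nothing here reports an empirical result that
the test suite does not itself compute.

## Sequence statistics

**Site filtering.** Alignment columns containing a gap (`-`) or an
ambiguity code (`N`) are excluded before any statistic is computed
(complete deletion); a pairwise-deletion mode is available by flag.
Complete deletion is the conventional default when indels are rare — the
motivating datasets carry a single 1-bp indel — and it keeps every
statistic defined on one fixed set of columns, the *effective length*
reported with all per-site quantities.

**Haplotype diversity.** The unbiased estimator
`Hd = n/(n−1)(1 − Σ pᵢ²)` with the variance of Nei (1987, eq. 8.12):

```
V(Hd) = 2/(n(n−1)) · { 2(n−2)(Σp³ − (Σp²)²) + Σp² − (Σp²)² }
```

This choice of variance formula reproduces, to the printed precision,
the standard deviations that DnaSP prints next to Hd, which is how it was
selected among the several variants in circulation.

**θπ and θS.** θπ is the mean pairwise difference count divided by the
effective length; θS is `S/(a₁·L)` with `a₁ = Σ_{i<n} 1/i`. Standard
deviations use Nei's (1987, eq. 10.7) variance for π and the Watterson
sampling variance `Var(S) = a₁θL + a₂(θL)²` for θS, with the point
estimates plugged in.

**Haplotype networks.** A minimum spanning tree on Hamming distances
between haplotype representatives (Kruskal), extended to a minimum
spanning *network* by retaining every non-tree edge whose weight equals
the maximum edge weight on the tree path between its endpoints — the
usual equal-weight-detour convention. Statistical-parsimony connection
limits are out of scope.

## Neutrality tests and their null distribution

Tajima's D, Fu's Fs and the R2 statistic are computed from their defining
formulas; Fu's Fs uses the Ewens sampling formula with unsigned Stirling
numbers of the first kind evaluated by the standard recursion in log
space (stable to at least n = 200), and `θ̂ = k̄` by convention.

P-values come from constant-size coalescent replicates that condition on
the observed number of segregating sites S by placing exactly S mutations
on each simulated genealogy in proportion to branch length. Two modes
differ in how genealogies are weighted:

* `fixed-S` — every genealogy counts equally. This is the convention of
  the popular sequence-analysis programs, and it is slightly conservative
  for Fs and R2 because conditioning on S under a fixed mutation rate
  tilts the genealogy distribution toward lengths compatible with S.
* `fixed-theta` — each replicate is importance-weighted by
  `P(Poisson(θ·L_tree/2) = S)`, the exact conditional distribution given
  S at mutation rate θ (Watterson's estimate when θ is not supplied).
  This is the calibrated choice: in the test suite the rejection rate of
  all three statistics at nominal 5% sits inside the binomial confidence
  band over 2000 constant-size replicates at n = 20, θ = 5.

All three p-values are left-tailed, the direction in which demographic
expansion pushes the statistics.

## Mismatch distributions and expansion dating

The sudden-expansion model uses the Rogers–Harpending transient spectrum

```
F_j(τ,θ₀,θ₁) = F̂_j(θ₁) + e^{−τ(θ₁+1)/θ₁} Σ_{i≤j} (τⁱ/i!)(F̂_{j−i}(θ₀) − F̂_{j−i}(θ₁))
```

with the equilibrium geometric `F̂_j(θ) = θʲ/(1+θ)^{j+1}`. The vector is
truncated at the largest observed difference class and renormalised to
sum to one, so observed and expected spectra live on the same support.
(τ, θ₀, θ₁) minimise the sum of squared deviations (SSD) by L-BFGS-B from
a coarse grid start (τ over the observed class range, θ₀ ∈ {0, k̄}, θ₁
offsets up to 10⁴); θ₁ is capped at 10⁵, effectively infinity.
Harpending's raggedness is the sum of squared successive differences of
the relative-frequency vector over the observed classes. SSD, raggedness
and the Kolmogorov–Smirnov distance between the observed and fitted
cumulative spectra get p-values by parametric bootstrap: coalescent
replicates under the fitted sudden-expansion parameters, each refitted.

Dating uses `t = τ/(2 μ_gen k)` with `μ_gen` the per-site rate per
generation. The formula yields generations; because published
applications of this formula frequently label its direct output "years"
while using a per-year mutation rate times generation time, the package
reports both `t_generations` and `t_years = t_generations ×
generation_time` and leaves the interpretation to the user. Confidence
bounds for τ map through the same linear transform.

Recovery at study scale: over 200 simulated expansions (n = 50, θ₁ = 50,
100-fold growth, true τ = 2) the median fitted τ falls within [1.5, 2.6]
— moment fits of τ are upward-noisy, which is why the band is asymmetric.

## Dominant-marker allele frequencies

Band absence is the recessive homozygote, so the absence fraction `x`
estimates `q²` under Hardy–Weinberg within populations. Two estimators:

* **Square-root**: `q̂ = √x`, with a zero-class correction replacing
  `x = 0` by `1/(2(n+1))` so fully banded loci get a small positive q̂.
* **Bayesian** (default for diversity summaries): posterior mean of q
  under a Beta(a,b) prior fitted per population by the method of moments
  to the across-locus distribution of square-root estimates — the
  AFLP-SURV/Zhivotovsky approach to a "non-uniform prior". The posterior
  mean has a closed form through the binomial expansion of `(1+q)^{n−m}`
  into Beta functions, evaluated in log space; the test suite verifies it
  against direct numerical quadrature to 1e−6.

At n = 15 the Bayesian estimator's mean bias against island-model truths
is below 0.02; the raw square-root estimator is roughly twice as biased.

## FST for dominant markers

A naive Weir–Cockerham analysis that treats the square-root estimates as
if they were codominant allele-frequency observations is badly biased at
AFLP sample sizes: measured against a Balding–Nichols truth of 0.15 at
8 populations × 15 individuals, it lands near 0.22 (raw estimates,
under-corrected noise) or near 0.10 (zero-class-corrected estimates,
shrinkage). The package therefore computes the variance components on the
observation scale. With `h(q) = E[√(X/n)]` for `X ~ Bin(n, q²)` —
computable exactly and tabulated per n — each locus gets:

* a pooled reference frequency `q₀ = h⁻¹(mean √x)`;
* a between-population variance component
  `σ̂²_B = (s²(√x) − mean v(q̂ⱼ)) / h′(q₀)²`, where `v(q) = q² − h(q)²`
  is the exact sampling variance of the square-root estimator and the
  `h′(q₀)²` factor maps the spread of the transformed observations back
  to the frequency scale;
* a total-variance denominator `D = q₀(1−q₀) + σ̂²_B/r`.

Multi-locus FST is the ratio of sums `Σσ̂²_B / ΣD` (the standard
variance-components aggregation); per-locus FST is `σ̂²_B/D`. Loci whose
pooled estimate sits within 0.001 of fixation are excluded as
uninformative. Mean recovery at the study scale is 0.155–0.157 for a
true 0.15, both globally and pairwise, within the ±0.02 band the test
suite asserts. Negative pairwise estimates are retained (not truncated)
and flagged, so averages stay unbiased. Sequence-side pairwise
differentiation uses the distance-based Φ_ST (pairwise difference
counts), which for two populations coincides exactly with the AMOVA
Φ_ST — an identity the tests assert.

## AMOVA, clustering, discriminants

AMOVA decomposes squared Euclidean distances between band profiles
(missing calls mean-imputed per locus), or pairwise sequence differences,
into among- and within-population components; Φ_ST = σ²_a/(σ²_a+σ²_w);
significance is the +1-corrected fraction of label permutations with
Φ_ST at least the observed. Fewer than 10 permutations are refused. An
alternative grouping (for instance DAPC clusters) may replace the
population labels.

Cluster search runs PCA on the centred band matrix, keeps components
covering ≥ 90% of variance, k-means with 20 restarts per K, and
`BIC = n·ln(WSS/n) + K·ln(n)`; the best K minimises BIC. Discriminant
axes come from `MASS::lda` on the retained PC scores; per-axis
discriminated-variance fractions are the normalised squared singular
values, which the tests verify against a direct eigen-decomposition of
`W⁻¹B`.

## FST-outlier scanning

**Envelope scan.** Neutral loci are simulated under a Balding–Nichols
island model — per-population band-allele frequencies
`Beta(p̄(1−F)/F, (1−p̄)(1−F)/F)`, dominant phenotypes Binomial with
presence probability `1−(1−p)²` — and pushed through the *same*
square-root-estimator and FST chain as the observed data, so observed and
simulated statistics are exchangeable under neutrality. This
moment-matched stand-in replaces a coalescent island simulator
deliberately: it reproduces the two moments the envelope conditions on
(heterozygosity and FST) at a small fraction of the cost. The ancestral
frequencies are resampled (with jitter) from the observed pooled
frequency estimates so the envelope spans the observed heterozygosity
range. F is calibrated iteratively (≤ 20 rounds at reduced size) until
the simulated trimmed mean FST — top and bottom 30% of loci discarded —
is within 0.005 of the observed trimmed mean. Empirical p-values are
+1-corrected exceedance fractions within 20 equal-width heterozygosity
bins (sparse bins merged below 30 simulated loci). The outlier flag is
conjunctive: above the 95% conditional quantile AND Benjamini–Hochberg
q ≤ 0.05.

Two honest limitations, both visible in the test suite. First, with only
8 demes the per-locus FST estimate carries χ²₇-scale spread, so the
neutral conditional tail reaches ≈ 0.4; post-FDR detection of a single
FST-0.6 locus among 500 (which needs p < 10⁻⁴) has essentially no power
at this design, for any envelope method. Power is therefore measured at
the 95% conditional-quantile flag — the same flag whose null rate the
calibration test fixes at 5% — where it is ≈ 0.9. Second, a locus
"planted at FST 0.6" is drawn from Balding–Nichols and then rescaled so
its realised among-population variance matches the target
(`plant_fst_locus`); without the rescaling, the realisation lottery
leaves ~15% of plants genuinely undetectable and the power statement
would measure the generator, not the scan.

**Posterior-odds scan.** A hierarchical model with
`logit(F_ij) = αᵢδᵢ + βⱼ`, priors `βⱼ ~ N(−1, 1.8²)`,
`αᵢ ~ N(0, 2²)`, and a reversible-jump indicator δᵢ with 10:1 prior odds
for neutrality; per-population frequencies are Beta with
`θ_ij = 1/F_ij − 1` around a uniform ancestral frequency, and the
likelihood is the dominant-phenotype binomial. All updates are
Metropolis-within-Gibbs, vectorised across loci; the RJ move proposes α
from its prior so the acceptance ratio reduces to the likelihood ratio
times the indicator prior odds. Posterior odds are
`P(δ=1|data)/P(δ=0|data)`, capped at 1000 for display (the conventional
capped output); with no data they collapse to the prior odds,
log₁₀PO = −1, which the tests assert. A split-chain heuristic on the βⱼ
means warns about non-convergence.

The honest caveat: at 8 populations × 15 individuals of dominant data,
the evidence for a locus at F = 0.6 against a 0.13 background is
intrinsically weak — direct numerical quadrature of the two marginal
likelihoods gives a Bayes factor near 17, i.e. log₁₀PO ≈ 0.24, matching
the MCMC. The strict log₁₀PO > 1.5 bar is therefore only reached by
strong patterns (near-fixed differences), and the test suite asserts
exactly that: prior recovery, a ≤ 2% false-flag rate, top ranking of a
planted F-0.6 locus, and decisive flagging of a fixed-difference locus.

## Environmental association

One univariate logistic model per locus × variable; individuals inherit
their population's environmental values (the sampling design provides no
individual coordinates). The fit is IRLS (`glm.fit`, tolerance 1e−8);
significance requires BOTH the Wald p and the likelihood-ratio (G) p
below the Bonferroni threshold `α/(L·V)`, where L counts all loci
(including skipped monomorphic ones) and V all variables — so 521 loci ×
7 variables at α = 0.01 gives 2.742 × 10⁻⁶. Predictors stay on their raw
scale; p-values are scale-invariant, which the tests assert.

Quasi-separation matters here: a strong environmental cline drives
fitted probabilities to the boundary, the Wald standard error balloons
(Hauck–Donner), and the conjunctive rule would discard precisely the
strongest signals. Fits are therefore flagged as diverged when any
fitted probability passes 0.999/0.001 (or the coefficients leave a sane
range), and with `firth = TRUE` such loci are refitted by Firth's
Jeffreys-prior penalised likelihood, which keeps estimates finite and
Wald tests usable.

Calibration is stated carefully. Under an *exchangeable* null
(individuals independent, no population structure) the family-wise error
over repeated runs is consistent with the Bonferroni bound, and the test
suite checks this with a drift-free generator setting (background FST
0.001). Under the island-model null at the study's background FST 0.15,
naive logistic association — like the method it models — is confounded
by drift: allele-frequency clines arise by chance and the family-wise
error is badly inflated (measured ≈ 0.6 at these conditions). Spatially
corrected association models are an explicit non-goal, so this
limitation is inherited by design and documented rather than patched;
the adaptive-locus rule's conjunction with an FST-outlier flag is the
design's own mitigation.

## Variation partitioning

RDA is multivariate least squares of the centred band matrix on a
predictor block; `R² = ‖Ŷ‖²/‖Y‖²`, and the Ezekiel adjustment
`1 − (1−R²)(n−1)/(n−1−m)`. The two-block partition follows the classical
convention: [a] pure environment, [b] spatially structured environment
(the shared fraction), [c] pure geography, [d] residual, from the three
marginal adjusted R² values. Note that recent versions of the reference
implementation label the *pure* second-block fraction "[b]" and the
shared fraction "[c]"; the numbers agree exactly (the test suite checks
all four against it), only the letters differ. Environmental predictors
are standardised so fractions are scale-free; the band matrix is centred
but not Hellinger-transformed by default; geography is raw lon/lat with
no polynomial or eigenvector expansion. Collinear predictor columns are
dropped with a warning — with population-level environments expanded to
individuals there are only as many distinct predictor rows as
populations, so this warning is common and harmless. Slightly negative
fractions are an adjusted-R² artifact and are reported as computed.

Marginal fractions are tested by permuting response rows; conditional
fractions [a] and [c] by Freedman–Lane residual permutation (permute
residuals of the reduced model, add back its fitted values, recompute the
semipartial R²); the shared fraction [b] has no direct test and the
request is refused rather than approximated.

## The synthetic-data generators

The generators define the study conditions every stochastic test runs
under; their defaults were fixed once, before the acceptance suite was
written, to mirror the motivating survey:

* **Coalescent sequences**: standard n-coalescent with exponential
  waiting times, infinite-sites mutation (`Poisson(θ·branch/2)`, each
  mutation at a fresh site), optional sudden expansion — backward in
  time the population shrinks by `growth_factor` at scaled time
  `τ/θ`, so `tau_mut` is the expansion age in mutational units. Checks:
  Watterson and pairwise estimators recover θ within 10%, mean Tajima's D
  within ±0.1 of zero, n = 2 tree height mean 1.
* **AFLP panel**: 8 populations × 15 individuals × 500 loci; background
  differentiation Balding–Nichols F = 0.15 (inside the 0.13–0.21 range
  the motivating study reports); ancestral band-allele frequencies
  Beta(0.6, 0.6), chosen so the expected gene diversity is ≈ 0.27,
  matching the published mean H_E of 0.276. Planted loci replace drift
  with a deterministic environmental cline
  `logit(pⱼ) = logit(p̄) + coeff·zⱼ` (optionally with a fixed intercept),
  which is what an association scan can detect; `plant_fst_locus`
  inserts a locus with an exact realised FST.
* **Environment**: each variable is a linear gradient along the
  projection of the population coordinates plus Gaussian noise (sd 0.3 by
  default), so all variables share one spatial axis — deliberately
  mimicking the strong inter-correlation of real bioclimatic layers. With
  zero noise a variable is perfectly collinear with geography; with zero
  gradient it is independent of it.

What the generators do *not* emulate: isolation by distance and
hierarchical structure (the island model is exchangeable), linkage
between loci, AFLP scoring artefacts (size homoplasy, intensity
thresholds), recombination within the sequence locus, and
individual-level environmental variation. Passing tests therefore
certify the estimators and their calibration under the stated models,
not robustness to these features of real data.

## Problem sizes used by the test suite

Chosen to exercise each property at the scale where its statement is
meaningful: 2000 constant-size replicates (n = 20, θ = 5, 1000-replicate
importance-weighted nulls) for test size; 200 expansion replicates for τ
recovery; 50 island-model replicates of 300 loci for FST accuracy; 10
neutral + 60 planted datasets of 500 loci for the envelope scan; 50
planted + 40 null datasets of 100 loci for association power and
family-wise error; the whole suite runs in a few minutes on one core.

## Known limitations

* The coalescent simulator is single-locus, panmictic-within-deme, and
  infinite-sites; no recombination or migration-matrix demography.
* The envelope scan's Balding–Nichols stand-in matches moments, not the
  full coalescent sampling distribution of DFDIST's island model.
* The posterior-odds scan uses modest default chain lengths; for real
  datasets, raise them and watch the split-chain warning.
* Logistic association inherits the drift confounding of its method
  family, as discussed above.
* Dominant markers identify allele frequencies only through `q²`; all
  downstream precision is limited by that, and no amount of modelling
  recovers codominant information.
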