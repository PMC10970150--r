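---
title: "Methods: chloroplast-DNA phylogeography with plastidpop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chloroplast-DNA phylogeography with plastidpop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastidpop)
```

plastidpop implements the analysis chain a plant phylogeographer applies to
a range-wide survey of a uniparentally inherited, non-recombining marker:
haploid sequences from many populations, one or two plastid fragments,
moderate sample sizes per population. This vignette documents the models
and estimator conventions, the choices made where the methodological
literature leaves room, and what the built-in simulator can and cannot
stand in for.

## Haplotypes and diversity

Sites containing a gap or an ambiguity in *any* sequence are removed before
anything else (complete deletion), so the haplotype partition, diversity
statistics and difference counts all describe the same fully resolved
sites. IUPAC ambiguity codes other than N are recoded to N on input: the
package is meant for curated Sanger-quality alignments in which residual
ambiguities carry no information worth modelling. Two sequences share a
haplotype iff they are identical at every retained site; labels H1, H2, ...
are assigned by descending overall abundance with ties broken by first
occurrence, so labelling is deterministic and stable across record order.

Haplotype diversity is the plain probability-of-difference form
$h = 1 - \sum_i p_i^2$ with no $n/(n-1)$ correction. The choice is
deliberate and matters at small $n$: for $n = 3$ with composition (2, 1)
the uncorrected value is 0.4444 while the corrected one would be 0.6667,
and the uncorrected form is what per-population survey tables of this kind
report. Nucleotide diversity per site is the mean proportion of differing
sites over all unordered pairs, again uncorrected, so that for exactly two
sequences differing at $d$ of $L$ sites $\pi = d/L$. For "mean ± SD"
summaries across populations the sample SD ($n-1$ denominator) is the
default, with the population-SD convention available by argument. The
pooled `Total` row of a diversity table is computed on the pooled sample,
not by averaging rows; both conventions exist in the literature, and
pooling is the one that reduces to the single-population definition when
there is only one population.

## Differentiation

Gst uses the Pons & Petit unbiased components: per-population
$h_k = \frac{n_k}{n_k-1}(1 - \sum_i p_{ki}^2)$ weighted equally across
populations, and a total diversity
$h_T = 1 - \sum_i \bar p_i^2 + h_S/(\tilde n K)$ with $\tilde n$ the
harmonic mean sample size. Nst is the same construction with haplotype
identity/non-identity replaced by the pairwise difference count between
haplotype sequences; when all pairwise distances are equal the distance
factors out and Nst equals Gst exactly (this algebraic identity is a unit
test). The phylogeographic test permutes haplotype identities over the
distance matrix, which breaks any association between haplotype relatedness
and geography while holding all frequencies fixed; the one-sided p-value
uses the (extreme + 1)/(permutations + 1) convention, as do all permutation
tests in the package. Populations with fewer than two samples are dropped
from these estimators because their unbiased within-population term is
undefined.

AMOVA is single-level (among/within populations). Raw pairwise difference
counts are treated as squared Euclidean distances — the "number of
different alleles" convention — and variance components come from the mean
squares with the unequal-sample-size coefficient
$n_0 = (N - \sum_k n_k^2/N)/(K-1)$. On a balanced two-deme design with
these distances, $\Phi_{st}$ equals Hudson's $1 - H_w/H_b$ exactly; the
test suite asserts the identity to $10^{-6}$. Negative $\Phi_{st}$ or Fst
estimates are reported as computed in all tables — they are legitimate
sampling outcomes — but are clamped to zero before the isolation-by-distance
transform, which requires $F_{st} < 1$ and benefits from non-negativity.
Hierarchical (region/population) designs are out of scope.

## Isolation by distance and elevation

Great-circle distances use the haversine formula with Earth radius
6371 km on the coordinates as given. Survey tables of this kind print
coordinates like "24.59" that could be either decimal degrees or
degrees.minutes; the package ingests them as printed decimal numbers and
makes no conversion — for the regression on log distance the distinction
perturbs distances by far less than the biological noise, and none of the
bundled checks depend on it. The regression is ordinary least squares of
$F_{st}/(1-F_{st})$ on $\ln(\text{km})$ over unordered population pairs.
Pairs with $F_{st} \ge 1$ or zero distance are excluded and counted.
Because the $P(P-1)/2$ pairs are not independent, the parametric slope
t-test is reported side by side with a Mantel permutation test on the
transformed matrices, and readers should prefer the latter for inference.
Diversity-elevation association is the plain Pearson correlation with the
two-sided t-test on $n-2$ degrees of freedom.

## Neutrality tests and the mismatch distribution

Tajima's D uses the 1989 constants and is undefined (NA) when there are no
segregating sites; report writers render monomorphic populations as
"0 (1)", the convention of the survey tables this output mirrors. Fu's Fs
is computed from the Ewens sampling distribution of the number of
haplotypes: $S' = P(K \ge k_{obs}\,|\,\theta = \hat k)$ with unsigned
Stirling numbers of the first kind evaluated in log space, and
$F_s = \ln(S'/(1-S'))$. Significance for both statistics comes from
coalescent simulation of constant-size panmictic samples conditioned on
$\hat\theta = \hat k$ (the mean pairwise difference); the primary p-value
is the lower tail — the expansion direction — with a two-sided option
exposed.

The mismatch distribution is fitted to the two-epoch sudden-expansion
model ($\theta_0 = 2N_1\mu$, $\theta_1 = 2N_2\mu$, expansion at mutational
time $\tau = 2ut$). The expected spectrum is computed exactly for the
two-epoch pair coalescent: the stationary geometric term
$\theta^i/(1+\theta)^{i+1}$ weighted by the regularised incomplete gamma
probability of coalescing in the current epoch, plus
$e^{-\tau/\theta_1}$ times the Poisson($\tau$) mutation layer convolved
with the pre-expansion geometric. At $\tau = 0$ it reduces to the
stationary spectrum; as $\theta_1 \to \infty$ it approaches the classic
sudden-expansion wave peaked near $\tau$. Fitting minimises
$SSD = \sum_i (obs_i - exp_i)^2$ — plain least squares, since the
goodness-of-fit test is defined through SSD itself — by a coarse grid
search refined with bounded quasi-Newton and Nelder-Mead passes, with
bounds $\theta_0 \in [0, 100]$, $\theta_1 \in [\theta_0, 10^4]$,
$\tau \in [0, 100]$. If refinement fails the best grid point is returned
with a warning flag. Boundary fits ($\tau \to 0$ with residual
polymorphism) are possible and reported as computed.

Harpending's raggedness is the sum of squared successive spectrum
differences with the spectrum padded by a zero class at *both* ends, so a
point mass at zero scores 2 and a uniform spectrum over $0..d$ scores
$2/(d+1)^2$. The more common right-padded-only form scores 1 on the point
mass; the symmetric padding was chosen so that the index treats the two
boundaries of the support identically. SSD and raggedness significance use
a parametric bootstrap: samples of the original size are simulated under
the fitted model, refitted, and $p = P(\text{bootstrap} \ge \text{observed})$.

## The island-model estimator

For a maternally inherited marker, Wright's drift-migration-mutation
equilibrium gives $F_{st} = 1/(1 + 2N_e(m_s + \mu))$ with haploid $N_e$ and
seed migration rate $m_s$. Chloroplast and mitochondrial markers in an
angiosperm share $N_e$ and $m_s$; assuming the mitochondrial mutation rate
is negligible, the two equilibria combine into
$\mu_{cp}/m_s = (1/F_{st}^{cp} - 1)/(1/F_{st}^{mt} - 1) - 1$. The identity
$\texttt{mu\_over\_ms}(\texttt{equilibrium\_fst}(N_e, m_s, \mu),\,
\texttt{equilibrium\_fst}(N_e, m_s, 0)) = \mu/m_s$ holds algebraically and
is tested over a parameter grid. Evaluating the estimator at differentiation
coefficients printed to four decimals propagates a rounding error of about
0.002 on a ratio near 10, so results are reported to four decimals with a
documented tolerance of 0.01 rather than more precision than the inputs
support. $N_e$ and $m_s$ are not separately identifiable from two Fst
values, and the package does not pretend otherwise.

## The synthetic-data generator

The structured-coalescent simulator generates haploid, non-recombining
two-locus samples under a finite island model. Defaults emulate the
sampling design of the kind of survey the pipeline targets: 29 populations
with 3–30 samples each (447 total), aligned lengths 564 and 500, the first
locus mutating five-fold faster (a rapidly evolving spacer against a slower
one), haploid deme size $N_e = 1000$, base migration rate
$5 \times 10^{-4}$ per generation, and a west–east migration gradient
(1.5× down to 0.5×) that raises western within-deme diversity. Mutations
are placed on branches as a Poisson process and assigned uniform positions
on a finite sequence (infinite sites on finite length): repeat hits are
possible but rare at these rates, and every statistic used downstream is a
difference count, for which this model is adequate and fast.

One modelling convention deserves emphasis: a migrating lineage chooses its
destination uniformly over *all* demes, its own included. Under this
migrant-pool convention the expected excess of between- over within-deme
coalescence time is $d/(2m)$ and Hudson's Fst has expectation
$1/(1 + 2N_e m)$ for *any* number of demes — including two — so the
simulator's calibration check against the island-model formula is exact
rather than holding only in the many-deme limit. (With
destination-uniform-over-other-demes the two-deme expectation would be
$1/(1 + 4N_e m)$.) The calibration experiment in the test suite runs 200
replicates of a two-deme model at $N_e = 500$, $m_s = 9 \times 10^{-3}$,
and sets the per-locus mutation rate to $m_s/10$: Hudson's Fst is a ratio
of coalescence times in which $\mu$ cancels, so the experiment keeps the
$\mu$ term of the target formula small against Monte-Carlo error while
still producing enough polymorphism to measure.

Sizes used by the test suite — a few hundred coalescent replicates for
calibrations, 50 replicates for the $\tau$-recovery study, 1000 coalescent
draws for neutrality p-values, 100 bootstrap replicates for mismatch tests,
100–1000 permutations elsewhere — were chosen as the smallest that leave
the Monte-Carlo error comfortably below the tolerances being asserted.

What the generator does *not* emulate: spatially explicit landscapes,
recombination (appropriate for plastid data), selection, sequencing error,
alignment artefacts, and indel polymorphism (simulated alignments are
gap-free). Passing tests therefore certify the statistical machinery and
its calibration under the island model, not robustness to the messiness of
real chromatogram-derived alignments; the cleaning step exists for real
data but is exercised mainly by targeted unit tests.

## Degenerate inputs and numerical conventions

Monomorphic data: D and Fs are NA (rendered "0 (1)"), mismatch spectra are
a point mass at zero, and AMOVA with an all-zero distance matrix reports
zero variance with a warning. Global monomorphism makes Gst/Nst undefined
(NA with a warning). Permutation p-values can never be zero by
construction. All stochastic entry points take a seed; the pipeline derives
per-stage child seeds from its master seed, so reruns are byte-identical
and any single report row can be reproduced by calling the underlying
module function with the recorded stage seed. Reports are written both
rounded to four decimals (the table convention of the field) and at full
precision.

## Known limitations

- Fu's Fs relies on the Ewens distribution, which assumes the
  infinite-alleles model; for loci with substantial homoplasy the statistic
  is approximate (as it is in the standard tools).
- The IBD slope t-test ignores pair non-independence; the Mantel p-value
  is the defensible one.
- The bootstrap refits in the mismatch test inherit the grid bounds, so
  extremely large true $\theta_1$ (beyond $10^4$) saturates.
- The AMOVA is single-level; regional hierarchies are out of scope.
- The island-model estimator assumes equilibrium and equal demography
  across markers; violations bias the ratio in either direction.
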