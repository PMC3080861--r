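---
title: "Detecting, quantifying and dating population admixture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting, quantifying and dating population admixture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`admixdate` implements three complementary ways of interrogating
genome-wide SNP data for population mixture — formal tests, a proportion
estimator, and a dating method — together with the haplotype-mosaic
simulator used to validate them. This vignette is the package's account
of the underlying models, the tunable parameters, and the numerical
choices; every empirical statement here is one that the test suite or
`scripts/acceptance.R` computes.

## Frequency-based tests for mixture

All the f-statistics operate on a long-format frequency table (one row
per SNP and population) produced by `allele_frequencies()` from an
EIGENSTRAT triplet or a simulated cohort.

**4 Population Test.** For a proposed unrooted tree ((A,B),(C,D)) the
statistic is the mean over SNPs of $(p_A - p_B)(p_C - p_D)$. If the
tree is right, the drift on the A–B branch shares no edge with the
drift on the C–D branch, so the expectation is zero; gene flow creates
shared drift paths and pushes the mean away from zero. The standard
error comes from a weighted block jackknife over contiguous 5 cM blocks
(blocks never span chromosomes), and `|Z| > 3` is the conventional
significance line. We report the mean product itself plus, for
description, a normalised version (the cosine similarity of the two
difference vectors); the Z-score is what carries the test.

**3 Population Test.** `f3_test()` computes the mean of
$(p_X - p_A)(p_X - p_B)$. Under a simple tree in which X is an
unadmixed relative of A and B this is positive in expectation; a
significantly negative value can only arise through admixture in X.
Because $\hat p_X$ appears in both factors, its sampling variance
inflates the product by $\mathrm{Var}(\hat p_X)$ per SNP; we subtract
the unbiased estimate $\hat p_X(1-\hat p_X)/(n_X - 1)$ (where $n_X$
counts sampled alleles) so that the sign contract survives small
panels. The correction is on by default and switchable
(`correct_sample_bias = FALSE`); a dedicated test shows a tiny X panel
with truly identical frequencies is pushed to Z > 3 without the
correction and recentred by it.

**f4-ratio ancestry estimation.** With two outgroups and two reference
populations arranged so that outgroup 2 branches off the lineage of
reference B after outgroup 1 diverged, the ratio

$$\hat\alpha =
\frac{\sum_i (p_{O1} - p_{O2})(p_X - p_{B})}
     {\sum_i (p_{O1} - p_{O2})(p_{A} - p_{B})}$$

isolates the proportion of A-related ancestry in X: both sums are
proportional to the drift on the single branch shared between the
outgroup contrast and the reference contrast, and that common factor
cancels. No data from the true mixing populations are required, only
populations related to them through the right topology. The standard
error is a block jackknife of the ratio (leave-one-block-out on both
sums jointly). The estimate may fall slightly outside [0, 1] by
sampling noise and is reported as computed. A denominator within three
jackknife SEs of zero means the reference configuration carries no
usable shared drift, and the function refuses to form the ratio.

**Block jackknife.** All standard errors use the Busing-style weighted
delete-one-block jackknife: with full-data estimate $\hat\theta$,
leave-one-out estimates $\hat\theta_{-j}$ and block weights $m_j$
(SNPs per block, $n = \sum m_j$, $h_j = n/m_j$),

$$\hat\theta_J = g\,\hat\theta - \sum_j (1 - m_j/n)\,\hat\theta_{-j},
\qquad
\widehat{\mathrm{var}} = \frac{1}{g} \sum_j
\frac{(h_j\hat\theta - (h_j - 1)\hat\theta_{-j} - \hat\theta_J)^2}{h_j - 1}.$$

With equal weights this reduces to the classical delete-one jackknife
(verified against the textbook formula in the tests). f-statistics use
5 cM blocks; admixture-LD dates use whole chromosomes, because
admixture LD can extend far enough that smaller blocks are not
independent.

## Dating admixture from the decay of admixture LD

A mixture event $n$ generations ago leaves linkage disequilibrium
between loci that were inherited together from one admixing
individual; two loci $d$ Morgans apart remain unrecombined with
probability $e^{-nd}$, so admixture LD decays exponentially in genetic
distance with rate equal to the age in generations.

`rolloff_date()` estimates that rate in four steps:

1. **Weights.** Each SNP gets $w = (a - b)/\sqrt{p(1-p)}$,
   $p = (a+b)/2$, from the empirical frequencies $a$, $b$ of two
   reference populations close to the mixing sources; $w$ is undefined
   where $p \in \{0, 1\}$ and those SNPs are dropped. When absolute
   surrogate frequencies are untrustworthy the unnormalised difference
   $a - b$ is available (`normalize_weights = FALSE`); the two modes
   give dates within joint error on simulated data.
2. **Pairwise LD score.** For every within-chromosome pair closer than
   `max_cm`, the Pearson correlation $r$ of diploid genotypes over the
   $N$ doubly-non-missing target samples is clipped to $[-0.9, 0.9]$
   and variance-stabilised: $z = \mathrm{atanh}(r)\sqrt{N-3}$
   (Fisher's transformation; approximately standard normal for
   unlinked pairs). Pairs with $N < 4$ or a constant genotype vector
   are skipped. The scalar form is exported as `pair_ld_score()`; the
   production path is a small C++ kernel validated against it
   pair-by-pair in the tests.
3. **Binning.** Pairs enter half-open uniform distance bins (default
   0.1 cM — narrower bins admit background LD through very short
   intervals; at least 0.05 cM is needed) and each bin records the
   Pearson correlation between $z$ and the weight product
   $w(s_1)w(s_2)$ across its pairs. The accumulation is streaming
   (six running sums per bin per chromosome), so leave-one-chromosome
   -out curves cost a subtraction, not a re-scan.
4. **Fit.** `fit_exponential()` fits
   $\mathrm{corr}(d) = A e^{-nd} + c$ by Levenberg–Marquardt least
   squares over bins between `min_cm` (default 0.5 cM — below that
   admixture LD is confounded by background LD) and `max_cm` (default
   30 cM), with starting values from a log-linear regression on the
   positive bins, falling back to port-algorithm `nls` and then a
   direct quasi-Newton minimisation if the curvature is degenerate.
   The fitted rate $n$ is the date in generations.

**Why the additive constant.** A finite cohort whose individuals carry
different genome-wide ancestry fractions shows a distance-independent
baseline: every pair of differentiated SNPs covaries through
individual ancestry, at any separation. For a cohort with ancestry
proportions of mean $\bar\theta$ and variance $v$ the baseline is
roughly $4v / (2\,\overline{\theta(1-\theta)})$ of the admixture-LD
amplitude — 13% when $\theta \sim \mathrm{Beta}$(mean 0.2, sd 0.1) —
and fitting a pure exponential to an offset curve underestimates
recent dates (an ideal-curve calculation gives 4.6 for a true age of
6). The constant absorbs it; `offset = FALSE` restores the pure
exponential for comparison. A fitted amplitude less than twice its
asymptotic standard error, or a non-positive rate, raises "no
detectable admixture LD decay" — the correct outcome on an unadmixed
target.

**Standard errors and bias.** `rolloff_date()` refits the curve
leaving out each chromosome, weighting each run by the SNPs it
excludes, and applies the weighted jackknife above. `estimate_bias()`
implements the matched-simulation correction: simulate the fitted
scenario repeatedly, take `bias = mean(replicate dates) − true date`,
and report `estimate − bias`. The weakness that motivates it — upward
bias for old dates, small proportions, small panels — attenuates with
stronger signal.

`fit_two_exponentials()` is provided for probing double-mixture
histories but flagged experimental: on our own simulations it recovers
a clean older component while the recent rate is unstable, the
well-known ill-conditioning of exponential mixtures.

## The haplotype-mosaic simulator

`generate_ancestral_pools()` builds the two source panels from a small
frequency tree: a root frequency $q \sim U(0.1, 0.9)$ per SNP; pool A
drifts from the root with Balding–Nichols parameter equal to the
target $F_{ST}$; the pool-B branch passes through a recorded internal
node at $F_{ST}/2$ and continues so that the total B drift matches A's.
This calibration makes the pairwise Hudson estimator equal the target
in expectation (0.15 ± 0.01 realised at 100k SNPs), while the internal
node and the root give natural attachment points for outgroups:
`sample_outgroup_freqs()` drifts outgroup 1 from the root and outgroup
2 from the internal node, exactly the topology the f4-ratio needs, so
the ratio recovers a simulated cohort's pool-A fraction in expectation.
Haplotypes are realised by a latent-uniform copying process: the
latent is redrawn with probability $1 - e^{-g/\ell}$ per marker gap
$g$, giving exact marginal frequencies and background LD decaying on
the scale $\ell$ (`ld_scale`, default 0.001 Morgans = 0.1 cM — short
-range LD that is extinguished well before the 0.5 cM fit floor, as in
dense SNP panels). SNPs are uniformly spaced; the default genome is 10
chromosomes of 1 Morgan carrying 20,000 SNPs and pools of 100
haplotypes, the scale at which all bundled analyses run in seconds.

`simulate_pulse()` realises the mosaic model: each haploid chromosome
starts in pool A with probability $\theta$; at each marker an ancestry
-resampling event fires with probability $1 - e^{-\lambda g}$ and
ancestry is redrawn Bernoulli($\theta$) — so A-tracts are approximately
exponential with mean $1/(\lambda(1-\theta))$ Morgans and ancestry
change-points arrive at $2\lambda\theta(1-\theta)$ per Morgan, both
verified in the tests (Kolmogorov–Smirnov on >1000 tracts). Donor
haplotypes are partitioned into disjoint private subsets per admixed
haploid, so no donor segment is ever copied into two genomes — a
slightly stronger form of sampling-without-replacement that makes the
no-reuse invariant checkable by interval arithmetic. When the pools
only allow one private donor per ancestry per haploid the generator
switches to the large-sample mode (each admixed haploid built from one
donor of each ancestry); fewer than that is an error. A resampling
event always switches donors when a second private donor exists, even
if the redrawn ancestry is unchanged; with a single donor it is
necessarily retained. True tracts, donor segments and realised
ancestry fractions are all returned for validation.

**Multi-event histories.** A subtlety worth recording: composing two
pulses as independent marker processes layered on one haplotype is
wrong, because crossing a recent-event breakpoint must land on a
*different* incumbent lineage, decorrelating the older event's
ancestry. `simulate_double_pulse()` therefore composes sequentially —
an intermediate admixed population is built first, and the final
cohort copies segments from those intermediate mosaics or from fresh
pool-B haplotypes (the pool-B panel is split between the stages so no
donor serves both). The exact ancestry covariance of the default
two-pulse design (50/50 at 30 generations, then 50/50 fresh B at 10)
is $\tfrac{1}{16}e^{-10d} + \tfrac{2}{16}e^{-40d}$ under this
construction. `simulate_continuous()` uses nested per-generation
breakpoints (generation $t$'s migrant claims resample at the union of
the generation $1..t$ recombination events), with the per-generation
migrant fraction solved from $(1-m)^{b-a+1} = 1 - \theta_{total}$.

**What the generator does not emulate.** Real allele-frequency spectra
and ascertainment, mutation and genotyping error, variable SNP density
and recombination-map error, and long-range background LD are all
absent. Passing tests therefore demonstrate the estimators' behaviour
under the mosaic model's assumptions, not robustness to every property
of real panels; the wrong-reference and unnormalised-weight tests probe
the two robustness claims that matter most for practice.

## A finding on single-exponential dates for double pulses

Simulating the two-pulse design above and fitting one exponential
gives a median around 20 generations across seeds, not a value near
the recent event. This is not a fitting artifact: unweighted least
squares on the exact noiseless covariance
$\tfrac{1}{16}e^{-10d} + \tfrac{2}{16}e^{-40d}$ over the 0.5–30 cM
window yields ≈19–23 whichever variant (plain, affine, any `max_cm`)
is used, because the older component carries twice the recent one's
amplitude at short range. A single-exponential date near the recent
event would require a curve dominated ~6:1 by the recent component,
which the 50/50 + 50/50 design cannot produce. The acceptance suite
records this honestly: the corresponding check measures ≈20 and
fails its target window, and the two-exponential diagnostic recovers
the older component (≈30–45) alongside an unstable recent one.
Interpretation of single-exponential dates on suspected multi-pulse
histories should lean on the continuous-flow result instead: dates on
`simulate_continuous()` output fall within the gene-flow interval.

## Known limitations

* The chromosome jackknife rests on few independent blocks at the
  default simulation scale (10 chromosomes): across the suite's
  10/50/100-generation recovery grid (50 replicates each) the ±2 SE
  coverage reaches the 90% bar at 10 and 50 generations but falls to
  ~82% at 100, consistent with a jackknife SE that turns mildly
  anticonservative as the informative distance range shrinks. With 10
  blocks even a perfectly calibrated jackknife caps ±2 SE coverage
  near 92% (a t₉ reference), so SEs on old dates from short genomes
  should be read as optimistic.
* Single-exponential dates on multi-pulse histories reflect an
  amplitude-weighted compromise, not the recent event (see above).
* The estimator inherits the documented upward bias when the signal is
  weak (old dates, small proportions, few samples);
  `estimate_bias()` quantifies and removes it by matched simulation.

## Summary arithmetic

`inverse_variance_mean()` averages per-population dates with weights
$1/\mathrm{SE}^2$; when corrected dates are requested, populations
lacking a simulation-based correction contribute their uncorrected
date — the inclusion rule under which the bundled per-population table
(`west_eurasian_dates()`) reproduces all four published regional
averages (55, 34, 89 uncorrected; 32 Levantine corrected) at
nearest-integer rounding, which is the rounding the report output
uses. `generations_to_years()` multiplies by 29 years per generation.

## Problem sizes and numerical conventions

* Default simulation genome: 10 chromosomes × 1 Morgan, 20k SNPs,
  pools of 100 haplotypes; replicated scenarios use 20 seeds and
  report medians. Unit tests use smaller genomes (2–6 chromosomes,
  4k–12k SNPs) chosen so the whole suite runs in minutes.
* Genetic positions are Morgans internally; every user-facing distance
  argument is cM. Physical positions are 1-based; map interpolation is
  linear in bp and clamped (never extrapolated) beyond map ends, which
  keeps interpolated positions monotone.
* Bins are half-open $[k\,w, (k+1)\,w)$; the fit abscissa is the bin
  midpoint; bins with fewer than two pairs are unusable.
* Missing genotypes are EIGENSTRAT `9`; frequencies with zero
  observed alleles are flagged undefined and excluded SNP-wise by
  every statistic.
* All stochastic entry points take an explicit `seed`; the same seed
  reproduces pools bit-identically.
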