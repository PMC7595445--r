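---
title: "Detecting chromosomal inversions with PCA: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting chromosomal inversions with PCA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(invertype)
```

## The model

A polymorphic paracentric inversion segregates in a population as a
biallelic "super-locus": each haplotype carries either the standard or
the inverted orientation, and recombination between orientations is
suppressed inside the inverted interval. Orientation-private variants
accumulate there, so a diploid sample's genotypes at inside-interval
SNPs are informative about its karyotype — homozygous standard
(std/std), heterozygous (std/inv), or homozygous inverted (inv/inv).

`invertype` works entirely from the n_samples × n_SNPs matrix of
unphased genotype categories. Each SNP is expanded to three one-hot
indicator columns (hom-ref / het / hom-alt); a missing call becomes an
all-zero block. After column mean-centering, a missing block contributes
no direction of its own, which is why the encoding needs no imputation.
Only centering is applied — the indicators already share a 0/1 scale,
and variance-scaling would inflate near-monomorphic SNPs (which are
retained: no MAF filter is applied at import).

Three analyses hang off the PCA of that matrix:

* **Scatter plots / clustering.** Samples cluster in PC space by
  karyotype — but equally by species or geography. Clustering alone
  cannot distinguish the two causes; this is the central interpretive
  hazard the association tests resolve.
* **PC–SNP association.** Per SNP, a multinomial logistic model of the
  genotype category on the sample's coordinate along one PC, compared to
  the intercept-only model by a likelihood-ratio test,
  df = G − 1 for G observed categories. An inversion captured by a PC
  produces a contiguous plateau of tiny p-values spanning the inverted
  interval (the Manhattan-plot "step"); structure produces diffuse
  association along the whole arm.
* **Cluster–SNP association.** Per SNP, the direction is reversed: a
  multinomial model predicts the cluster label from the SNP's one-hot
  genotype features, df = (K − 1) · F. This validates a chosen
  clustering: the step appears only if the clusters encode the
  inversion.

## The likelihood-ratio kernel

Both tests share one fitter: Newton–Raphson maximization of the
multinomial logistic log-likelihood with a small ridge penalty
(λ = 1e-3) on slope coefficients only. The penalty exists because
inversion-diagnostic SNPs separate the classes *perfectly*, where the
unpenalized MLE diverges; with the ridge the statistic stays finite and
the test remains usable exactly where the signal is strongest.
Intercepts are never penalized and start at the log class frequencies,
so class base rates are fit exactly. The LRT compares penalized
log-likelihoods of the nested models under the same λ; the null
(intercept-only) optimum has the closed form Σ n_g log(n_g/n). p-values
are floored at 1e-300 so −log10 p stays finite in plots.

Two calibration-driven choices deserve a note:

* **Identifiable feature blocks.** A full 3-column one-hot block is
  collinear with the intercept; counting all three columns in the
  degrees of freedom would misstate the chi-square reference. The
  cluster test therefore drops the most frequent category as reference
  and counts only the remaining non-constant features (F = G − 1 in the
  common case).
* **Balancing by downsampling.** Cluster sizes can be very unequal, and
  the fit is balanced before testing by resampling the training set.
  Downsampling every class (without replacement, seeded per track) to
  the smallest class size keeps the balanced set a set of independent
  observations. The alternative — oversampling minority classes with
  replacement — duplicates observations, and the duplicated information
  breaks the chi-square reference badly: in a 90/10 two-cluster null
  simulation the measured type-I error at α = 0.05 was 0.70 with
  oversampling versus 0.056 with downsampling. Downsampling discards
  data, but a calibrated conservative test beats an anticonservative
  one for a scan whose output is read as a spatial pattern.

The fitter is compiled (RcppArmadillo) because a chromosome-arm scan
calls it once per SNP; the test suite checks it per-SNP against a
brute-force BFGS maximization of the exact penalized likelihood.

Two caveats on the chi-square reference itself, verified in the test
suite and worth knowing when reading Manhattan plots:

* With an *independent* predictor the null p-values are uniform (the
  package tests this by KS at α = 0.01). But PC coordinates are fitted
  from the very genotypes being tested, so every SNP's in-sample
  association with a leading PC is slightly inflated even on pure-noise
  data — the top eigenvector partially overfits each SNP. The inflation
  is uniform along the arm, which is precisely why region calling uses
  an inside/outside *contrast* rather than an absolute significance
  count.
* The LRT's chi-square approximation degrades for very sparse genotype
  cells (hom-alt expected counts near zero at MAF ≈ 0.05) and small
  balanced class sizes, in the usual Bartlett O(1/n) direction. At the
  scales used here (≥ ~35 samples per class) the null passes KS at
  α = 0.01.

## Region calling

The "step" is quantified with three exposed knobs: a −log10 p threshold
(default `max(8, log10(n_tested/0.05))`, i.e. at least 8 or a
Bonferroni-style cutoff for the SNP count), a window width (default
500 kb), and a minimum per-window fraction of above-threshold SNPs
(default 0.2). Windows tile the arm; qualifying windows joined across
single-window gaps form runs; the run with most qualifying windows is
the candidate. Two guards keep structure from being called as an
inversion: the run must leave SNPs outside its span (an arm-wide plateau
is structure, not a step), and the above-threshold fraction inside must
be at least twice that outside. Region bounds are the first and last
above-threshold SNP positions in the run — so calls are resolved to SNP
positions, about one window at the edges in practice. The defaults were
chosen so that a 23 Mb signal on a 50 Mb arm (the geometry of the 2La
inversion on *Anopheles* 2L) is called robustly; all three are flags on
the command line.

Detection across predictors is a disjunction: the inversion counts as
detected if *any* PC track (1–4 by default) or the cluster track shows
the step. No specific PC is required, since which PC captures an
inversion depends on what else structures the sample.

## Genotyping and its score

K-means (10 restarts, best inertia) on PCs 1–2 infers karyotype groups;
the inertia curve over k = 1..6 is summarized by the same elbow rule
used for explained variances: the point with maximal perpendicular
distance to the chord joining the curve's first and last points, ties
toward the smaller index, with an explicit `ambiguous` flag for exactly
linear curves (index 1 in that case). The elbow rule replaces eyeballing
the scree plot with a deterministic criterion; the CLI still prints the
full curve so a user can override `k`.

Cluster IDs are arbitrary, so agreement with known karyotypes is scored
through a classifier: a multinomial model predicts karyotype from
one-hot cluster IDs, and the balanced accuracy (unweighted mean
per-karyotype recall) of its in-sample predictions is reported. Fitting
and evaluating on the same samples is deliberate — the score asks "how
well do these clusters encode karyotype?", not "how well would they
generalize?" — and the construction makes the score invariant to
cluster-ID permutations. With a single cluster and two karyotype
classes the score is 0.5 by construction; with one karyotype class it
is undefined and raises an error rather than returning 1.

Per-PC score signs are fixed by making each component's
largest-magnitude loading positive, so coordinates are bit-reproducible
across runs and sample orderings (up to ties at machine precision).

## The synthetic generator

`simulate_dataset()` draws, per sample, the number of inverted
haplotypes from Binomial(2, q) — Hardy–Weinberg karyotype proportions —
then generates genotypes SNP by SNP:

* inside the inversion interval: orientation-specific allele
  frequencies, p_std from the background range and
  p_inv = clip(p_std ± d); a sample's genotype is one Bernoulli draw
  per haplotype, encoding suppressed recombination directly;
* outside: one background frequency, shifted per population by a
  Balding–Nichols Beta draw with drift F when two populations are
  simulated (F = 0 collapses to panmixia);
* missing calls masked independently at a fixed rate.

Defaults are the positive single-population regime used in validation:
100 samples, 5,000 SNPs on a 50 Mb arm, inversion at 20–43 Mb, q = 0.4,
d = 0.6, MAF range 0.05–0.5, no missingness. The negative-control
regime used in the acceptance tests is two populations at F = 0.1 with
no inversion and 2,000 SNPs; the confounded regime restricts population
2 to a subset of karyotypes (`pop2_karyotypes`), which reproduces the
clusters-mix-species-and-karyotype behavior seen in real two-species
samples. These sizes keep the full validation suite within minutes on
one CPU while leaving every per-window SNP count high enough for the
region-calling statistics to be meaningful.

What the generator deliberately omits: linkage-disequilibrium decay
(SNPs are conditionally independent given karyotype — the detection
signal is orientation-private frequency divergence, and independence
keeps small-sample oracles tractable), coalescent genealogies,
recombination maps, mutation models, and multiple overlapping
inversions per arm. Passing tests therefore demonstrate correctness of
the machinery under the stated generative model, not performance on
real data with LD structure; mutually exclusive overlapping inversions
(a documented failure mode of this family of methods) are out of scope.

## Numerical and interface choices

* PCA is computed from the eigendecomposition of the centered sample
  Gram matrix — exact, deterministic, O(n² · features) with sparse
  feature matrices, no randomized solver, hence no solver seed.
* Zero-variance input (identical samples) yields all-zero scores and
  zero explained-variance ratios rather than NaNs; components beyond
  the data rank have zero scores.
* k-means uses 10 seeded restarts per k, keeping the best inertia;
  labels are canonicalized (descending cluster size, ties by smallest
  member index) so outputs snapshot cleanly. Degenerate inputs with
  fewer distinct points than k fall back to one cluster per distinct
  point, split deterministically.
* Genotypes containing `.` are missing; `0/1` and `1/0` (phased or
  not) are the same heterozygote. Missing samples are dropped per SNP
  only. Coordinates are 1-based VCF positions throughout.
* All numeric artifacts are TSV files round-trippable by package
  readers; plots (PNG) are side effects only. Reruns with identical
  seeds produce byte-identical TSVs, and the suite asserts this.
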