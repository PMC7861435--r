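---
title: "Generating and auditing artificial genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generating and auditing artificial genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplogen)
```

## The problem

Phased SNP data — matrices whose rows are haplotypes and whose columns are
biallelic sites coded 0 (reference) / 1 (alternative) — are often locked away
for privacy reasons. Generative models offer a way out: train a model on a
private cohort, release *artificial genomes* (AGs) sampled from it, and let
downstream analyses run on the artificial set. For that to be defensible two
questions must be answered quantitatively: do the AGs reproduce the
statistical structure of the cohort (fidelity), and are they far enough from
the actual training haplotypes that individuals cannot be re-identified
(privacy)? `haplogen` implements both halves: two neural generative models
(a fully-connected GAN and a restricted Boltzmann machine) plus two
deliberately naive baselines, and a complete fidelity/privacy audit.

## The generative models

### GAN

The generator maps a latent Gaussian vector $z \in \mathbb{R}^{600}$ through
two LeakyReLU hidden layers of sizes $\mathrm{round}(L/1.2)$ and
$\mathrm{round}(L/1.1)$ (for $L$ SNPs) to a tanh output of length $L$; the
discriminator mirrors it with hidden sizes $\mathrm{round}(L/2)$ and
$\mathrm{round}(L/3)$ and a sigmoid output. Both use LeakyReLU slope 0.01,
an L2 penalty of $10^{-4}$ on hidden weights, Adam with binary cross-entropy,
learning rates $8\times10^{-4}$ (discriminator) and $10^{-4}$ (combined
model), and minibatches of 32. Per batch the discriminator takes one step on
real data — labels smoothed uniformly into $[0.9, 1]$, which regularises
without breaking cross-entropy semantics — and one step on generated data
(labels 0), then the generator takes one step through the frozen
discriminator. Sampled outputs are rounded to 0/1.

Numerical choices worth stating:

* **Rounding of layer widths** is half-away-from-zero, so an 805-SNP panel
  gives generator widths 671/732 and discriminator widths 403/268
  (banker's rounding would give 402 for the third width; the difference is
  one unit and documented in `gan_layer_sizes()`).
* **The tanh/data domain**: the default keeps the data as 0/1 and thresholds
  generated values at 0.5; `rescale = TRUE` instead maps data to $[-1, 1]$
  and thresholds at 0. Both are coherent pairings of the tanh output with
  binary data; the flag is recorded in the fitted model and the choice
  matters little in our experiments.
* **Update schedule**: one discriminator round (real step + fake step) per
  generator step. The balance between the two networks is delicate at small
  training sizes — see *Training length*, below.
* **Early stopping**: every 200 epochs (configurable) the nearest-neighbour
  adversarial accuracy between a fresh artificial sample and a held-out
  quarter of the data is recorded. The probe rarely defines a crisp stopping
  point on its own, so by default training runs to `epochs` and the trace is
  kept for inspection; `stop_at_aats = TRUE` stops once the probe sits
  within a tolerance of 0.5 twice in a row.

### RBM

The restricted Boltzmann machine couples $L$ Bernoulli visible units to
$N_h$ hidden units by the energy
$E(v, h) = -v^\top W h - a^\top v - b^\top h$ (for continuous hidden units an
extra $\|h\|^2/2$ term), with $P(v, h) \propto e^{-E(v,h)}$. We state the
sign convention explicitly because the compact form "$\sum W v h$ + bias
terms" is ambiguous; with our convention a large positive $W_{ij} v_i h_j$
raises probability, and nothing observable depends on the choice. Hidden
units are either binary ("sigmoid") or rectified continuous ("relu", the
better-performing variant): conditioned on $v$, a relu unit is a
unit-variance Gaussian centred at its pre-activation and truncated to
$[0, \infty)$; the truncation variance is fixed at 1.

Training maximises the likelihood by persistent contrastive divergence
(PCD-k): positive statistics from the minibatch (with the
conditional-mean, Rao-Blackwellised hidden activation), negative statistics
from 100 persistent Gibbs chains advanced $k = 10$ alternating sweeps per
update, learning rate in $[10^{-4}, 10^{-3}]$, batch size 32. Weights start
at $\mathcal{N}(0, 0.01^2)$, biases at zero.

Because the model is an explicit energy model, it admits an *exact* oracle
at small sizes: `exact_loglik_gradient()` and `rbm_exact_marginal()`
enumerate all visible states (hidden layer marginalised analytically — a
closed form exists for both hidden types) and the test suite requires the
stochastic PCD gradient and the Gibbs sampler to agree with the enumeration.

Sampling artificial genomes runs parallel Gibbs chains for `n_gibbs` sweeps
(default 100, a compromise between mixing and runtime; exposed and logged).
Chains start from random noise, from training rows, or from an independent
*sampling set*. Training-set initialisation inherits the model's
memorisation of training points: on a deliberately overfit model the test
suite shows the sampling-set start yields a visibly higher (less overfit)
adversarial accuracy, which is the practical reason the scheme exists.

### Baselines

The per-site Bernoulli model draws each site independently at its training
frequency; the Markov model draws sites left to right from the observed
conditional distribution given the previous $\min(p-1, w)$ alleles (window
$w$, typically 5 or 10). Both preserve marginal frequencies; neither
preserves population structure (Bernoulli) or long-range structure (Markov).
At generation time an unseen Markov context backs off one allele at a time
until a context observed in training is found (marginal frequency as last
resort): raw empirical frequencies with no pseudocounts, so totality has to
come from backoff rather than smoothing.

## The audit

For a (real, artificial) pair `evaluate_pair()` computes: per-site
allele-frequency correlation; the $r^2$ LD matrix, the correlation between
real and artificial $r^2$ values, and 50-bin LD-decay curves after removing
sites fixed in either dataset; three-point connected correlations
$c_{ijk} = f_{ijk} - f_{ij}f_k - f_{ik}f_j - f_{jk}f_i + 2f_if_jf_k$ for
triplets at fixed separations and at random (allele combination (1,1,1) by
default; all eight available); pairwise Hamming-distance distributions
within and between sets with their 1-D Wasserstein distance and the count of
verbatim copies; a joint PCA with the entropic-regularised 2-D Wasserstein
distance between the PC1/PC2 clouds (squared-Euclidean cost,
regularisation 0.001, log-domain Sinkhorn with epsilon-annealing); a
fixed-site report; and the privacy statistics.

The privacy statistics follow the nearest-neighbour adversarial accuracy:
with $d_{TS}(i)$ the Hamming distance of real haplotype $i$ to its nearest
artificial neighbour, $d_{TT}(i)$ to its nearest other real haplotype (and
symmetrically $d_{ST}, d_{SS}$),

$$AA_{truth} = \tfrac1n \sum_i \mathbf{1}(d_{TS}(i) > d_{TT}(i)), \quad
  AA_{syn} = \tfrac1n \sum_i \mathbf{1}(d_{ST}(i) > d_{SS}(i)), \quad
  AA_{TS} = \tfrac12 (AA_{truth} + AA_{syn}),$$

$$\mathrm{PrivacyLoss} = AA_{TS}^{test} - AA_{TS}^{train}.$$

0.5 is the indistinguishable optimum; below 0.5 is overfitting (a privacy
risk), above is underfitting. Ties contribute zero (the indicators are
strict, exactly as defined), self-distances are excluded, and the Hamming
metric is the package default because "pairwise difference" counts on binary
haplotypes are Hamming distances; the metric is exposed should another be
wanted.

One caveat matters for short panels: Hamming distances are integers, so on
a 100-SNP panel the nearest within-set and cross-set distances *tie* for
roughly 15–18% of points whatever the allele-frequency law, and because a
tie contributes 0 to the strict indicator, the null value of $AA_{TS}$ for
two samples from the same distribution is not 0.5 but
$\approx 0.5 - P(\text{tie})/2 \approx 0.40\text{–}0.42$. The bias shrinks
as the panel grows (ties are rare at thousands of SNPs) and cancels in the
privacy loss for artificial sets equally distant from both real sets,
because both terms of the difference carry it. When comparing $AA_{TS}$
against the 0.5 reference on small panels, compare against a same-sized
same-panel null (e.g. a held-out split) rather than against 0.5 itself. Both one-sided scores are always reported alongside the average,
since a balanced 0.5 can hide $AA_{truth} = 0$, $AA_{syn} = 1$ — the
signature of artificial points parked at the centres of small clusters of
real ones. `spike_in_sensitivity()` measures how sharply the scores react
when $k$ training rows are copied verbatim into the artificial set.

## Synthetic data: what it emulates and what it does not

Real training cohorts cannot ship with a package, so `simulate_structured()`
provides known-truth data: per site an ancestral frequency from
$U(0.05, 0.95)$ (optionally with a rare-allele spike, Beta(0.2, 2), off by
default), per population a Balding–Nichols Beta draw with mean $p$ and
variance $F \cdot p(1-p)$ — so the `differentiation` parameter is the
model's $F_{ST}$, and the realised Hudson estimator matches it in the test
suite — then independent allele draws. `simulate_mosaic()` layers linkage
disequilibrium on top by a Li–Stephens-style copying walk over founder
haplotypes (per-SNP switch probability, per-site mutation flip), giving LD
that decays with SNP distance.

The defaults (2 populations × 250 haplotypes, 100 SNPs, differentiation
0.2) are the desk-scale study conditions used by the end-to-end tests: big
enough that a joint PCA separates the populations cleanly, small enough
that GAN plus RBM training runs in minutes on one CPU. What the generator
does *not* emulate: realistic site-frequency spectra, recombination maps,
selection, phasing errors, or the SNP-ascertainment quirks of real panels.
A model that passes the audit on this synthetic data has demonstrated it
can learn multi-modal structure and marginal frequencies — not that it
will capture every property of a particular biobank.

## Training length and stability at desk scale

A GAN "epoch" here is one adversarial round on a single randomly drawn
minibatch of 32 (the loop structure that makes a 200-epoch probe cadence
meaningful), so epoch counts are update counts. An RBM epoch is a full
pass over the training minibatches.

Adversarial training at this scale is run-to-run unstable: the
discriminator can tell binary real rows from continuous tanh outputs
easily, and the generator tends to concentrate on one population mode,
drifting between modes across training rather than converging. Two
mitigations are part of the recipe, both using only held-out data:
`keep_best` snapshots the networks at every probe and returns the one
whose adversarial accuracy is closest to 0.5, and `run_benchmark()` trains
`gan_restarts` independent GANs and keeps the run with the best probe —
the probe ranks runs in close agreement with their joint-PCA Wasserstein
quality, which is what makes the selection legitimate model selection
rather than peeking. Even so, partial mode collapse is the GAN's
characteristic failure at a few hundred training haplotypes: its
frequency fidelity is high, but its embedding-level match can trail the
structure-free Bernoulli baseline, whereas the RBM (which fits an explicit
likelihood) reproduces the population structure reliably. The benchmark
defaults (`gan_epochs = 3000` with 3 restarts, `rbm_epochs = 250`, 100
hidden units) keep the full four-generator benchmark in the ten-minute
range on one CPU; the README shows the numbers the code actually prints.

## Degenerate inputs and edge policies

* Fixed sites: excluded from LD-decay curves (fixed in *either* dataset),
  reported by `fixed_site_report()`, and a zero-variance frequency vector
  makes the frequency correlation `NA` with a warning rather than an error.
* Unequal real/artificial sizes: the adversarial accuracy is defined for
  equal sizes; unequal inputs are computed with a warning.
* Unphased VCF genotypes: an error in strict mode, accepted with
  `strict = FALSE`; multiallelic sites are skipped with a logged count (or
  error in strict mode).
* Genotype layout: haplotype pairs interleave site-major
  (site $t$ → columns $2t-1, 2t$); the order is arbitrary but fixed,
  documented, and exactly inverted by `from_genotype_layout()`.
* Sinkhorn non-convergence (pathological regularisation/cost ratios) is an
  error carrying the residual marginal error, never a silent wrong number.

## Limitations

The models operate on SNP panels of at most a few thousand sites on one
CPU — chromosome-scale generation requires chunking, which the package does
not do. The GAN can drop rare alleles (fixed-site counts in the audit make
this visible); the RBM tends toward memorisation when over-trained, which
is precisely what the privacy metrics are there to catch. Neither model is
conditioned on labels; population-conditional generation is out of scope.
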