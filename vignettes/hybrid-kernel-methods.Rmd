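---
title: "Hybrid-kernel genomic prediction: models, algorithms and design choices"
author: "hybridGP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid-kernel genomic prediction: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridGP)
```

## The prediction problem

Plant-breeding programs select among hundreds of candidate lines using
phenotypes observed on only part of the candidate set, in only some of the
target environments. Genomic prediction fills the gaps with a mixed model in
which the genetic merit of the lines is a random vector whose covariance is a
relationship kernel built from pedigree records or molecular markers.
`hybridGP` implements a family of such models whose distinguishing feature is
a pair of *hybrid* kernels, C and P, constructed from the matrix product of a
Gaussian marker kernel K and a pedigree kernel A. The hybrid kernels are
intended to capture genetic signal expressed jointly by realized
(marker-based) and expected (pedigree-based) relationships and not available
to either source alone.

## Relationship kernels

Four base constructions are provided, each an $n \times n$ symmetric matrix
over the genotypes:

* **A** — the additive (numerator) relationship matrix, computed from a
  pedigree by the standard tabular recursion
  ($A_{ii} = 1 + \tfrac12 A_{p_1 p_2}$,
  $A_{ij} = \tfrac12 (A_{j p_1} + A_{j p_2})$, missing parents contributing
  zero). A precomputed matrix (for example a coefficient-of-parentage matrix)
  can be supplied directly instead.
* **G** — the linear genomic (GBLUP) matrix $G = XX'/p$, where $X$ is the
  marker matrix with each column centred and scaled to sample standard
  deviation one ($n-1$ denominator) and $p$ is the number of retained
  markers. Zero-variance markers carry no information and are dropped (with a
  warning) before scaling.
* **K** — the Gaussian kernel
  $K_{ij} = \exp(-d_{ij}^2 / (s \cdot \mathrm{med}))$ with $d_{ij}^2$ the
  squared Euclidean distance between marker rows and $\mathrm{med}$ the
  median of the *off-diagonal* squared distances. The median's index set is
  not forced by the formula itself; we take the strictly-upper-triangular
  entries because the $n$ structural zeros on the diagonal would otherwise
  shrink the bandwidth as $n$ grows. The optional scale $s$ (default 1)
  generalizes the bandwidth without changing the default behaviour.
* **C and P** — from the ordinary matrix product $KA$ (which is not symmetric
  and therefore not itself a kernel): the strictly-upper (C) or
  strictly-lower (P) triangular part is added to its transpose, the diagonal
  of $KA$ is restored, and the matrix is divided by the mean of that
  diagonal, so `mean(diag(C)) == 1`. "Strictly" triangular matters: the
  diagonal is handled separately, and including it in the triangle would
  double it. The two constructions satisfy the exact identity
  $\overline{\mathrm{diag}}(KA) \cdot (C + P) = KA + (KA)'$, and with $A = I$
  both collapse onto $K$; the test suite verifies both properties on random
  matrices.

### Positive semi-definiteness and repair

C and P are symmetric by construction but not PSD in general; on simulated
data their smallest eigenvalues are substantially negative (on the order of
$-10$ at $n = 300$), i.e. the indefiniteness is structural, not a
floating-point artifact. `validateKernel()` reports the spectrum and offers
two repairs, both followed by a rescaling that preserves the mean diagonal:

* `eigen_clip` (the model-fitting default) reconstructs the matrix with
  negative eigenvalues set to zero — the nearest PSD matrix in Frobenius
  norm, which preserves the kernel's relational structure;
* `jitter` adds $(|\lambda_{\min}| + tol) I$. With mild indefiniteness the
  two are interchangeable, but with strongly indefinite hybrid kernels the
  jitter constant rivals the signal and the mean-diagonal rescaling then
  shrinks the whole kernel toward a scaled identity, which empirically
  destroys variance-component recovery. This is why clipping, which is also
  the PSD square root used by the phenotype simulator, is the default.

## Single-environment models

Model S5 is $y = 1\mu + g_A + g_K + g_C + g_P + \varepsilon$ with
$g_k \sim N(0, \sigma_k^2 K_k)$ independent across kernels and
$\varepsilon \sim N(0, \sigma_\varepsilon^2 I)$; S1--S4 use the subsets
\{A\}, \{G\}, \{K\} and \{A, K\}. Fitting is by Gibbs sampling:

* Each kernel is eigendecomposed once, $K_k = Q \Lambda Q'$, with eigenvalues
  below $10^{-10}$ truncated and their coordinates pinned at zero. Effects
  are updated in the rotated basis, where the full conditionals are
  independent scalars, so an iteration costs $O(n^2)$ per kernel.
* Variance components get scaled-inverse-chi-square priors with 5 degrees of
  freedom. Scales are set so the prior mode of each genetic variance is
  $R^2_{\mathrm{prior}} \mathrm{var}(y) / K$ ($K$ = number of kernels) and
  the residual prior mode is $(1 - R^2_{\mathrm{prior}})\mathrm{var}(y)$,
  with $R^2_{\mathrm{prior}} = 0.5$ — the convention of the standard Bayesian
  genomic-prediction software this sampler mirrors. The intercept has a flat
  prior.
* Phenotypes are **not** re-standardized internally (a flag is available);
  the expectation is that the input is already an adjusted mean or BLUE,
  standardized upstream if desired.
* Missing phenotypes are treated as unknowns and sampled from their
  predictive distribution each iteration (data augmentation). For a linear
  model this yields the same posterior means as post-hoc prediction and gives
  masked-genotype predictions with no extra machinery.
* Reported effect vectors are Rao-Blackwellized posterior means (averages of
  full-conditional means rather than of draws): same expectation, smaller
  Monte Carlo error. Predictions satisfy
  $\hat y = \hat\mu + \sum_k \hat g_k$ exactly.
* Default chain settings are 50,000 iterations, 5,000 burn-in, thinning 5.
  Effective sample size and a split-chain scale-reduction diagnostic are
  reported for every variance component but not enforced.

With the variance components held fixed the sampler's posterior mean equals
the closed-form mixed-model (BLUP) solution; a deterministic mode replaces
every draw by its conditional mean and converges to that solve exactly, which
the test suite uses as an oracle.

## Multi-environment models

With $m$ environments the models M1--M5 add genotype-by-environment
structure. Two data regimes get two formulations:

* **Balanced** (every genotype in every environment): environments are
  treated as traits. Kernel $k$ contributes effects with covariance
  $U_k \otimes K_k$, where $U_k$ is an unstructured $m \times m$ covariance
  with an inverse-Wishart full conditional, and residual rows have
  unstructured covariance $R$. Priors are inverse-Wishart with
  $\mathrm{df} = m + 2$ and scale
  $R^2_{\mathrm{prior}}\,\mathrm{diag}(\mathrm{var}(y_j))
  (\mathrm{df} - m - 1)/K$ (prior mean equals the scale at this df),
  mirroring the single-environment partition.
* **Unbalanced**: each kernel contributes a single variance on the
  record-level Hadamard covariance
  $(Z_1 K_k Z_1') \circ (Z_2 E Z_2')$, with a homogeneous residual. For
  complete incidence and $E = U$ this equals the Kronecker covariance up to
  the record permutation — an identity the tests verify exactly. The
  environment covariance $E$ is not something the data regime hands us; by
  default it is estimated as the matrix of pairwise phenotype correlations
  over shared genotypes, shrunk halfway toward compound symmetry and clipped
  to PSD (`estimateE(shrink = 0.5)`), and can be overridden from a file. In
  cross-validation it is re-estimated from the unmasked records of each
  replicate.

Records are ordered by (environment, genotype) throughout; all incidence
matrices and Kronecker comparisons use this convention. A record present with
a missing value is a *masked cell* (imputed by data augmentation, balance
preserved); an absent record is a structural hole (unbalanced data). Masked
cells in the balanced sampler are drawn from their conditional normal given
the observed cells of the same genotype through $R$.

## Cross-validation machinery

Two schemes reproduce the evaluation designs used for this model family:

* repeated k-fold over genotypes — 5-fold with 4 repeats and 2-fold with 10
  repeats, each giving 20 training/testing combinations; remainders are
  spread one per fold so sizes differ by at most one;
* environment masking — a random 20% (or 5%) of one environment's records
  stay observed, the rest of that environment is predicted with all other
  environments known, with 10 random samples per scenario.

Fold assignments depend only on the scheme and its seed, never on the model,
so comparisons are paired. Metrics are the Pearson correlation and the
predictive mean squared error, computed per fold and then averaged (not
pooled). The summary reports AVG (the mean of per-fold correlations, raw —
no Fisher-z transform), SE (their standard deviation divided by the square
root of the fold count, the conventional reading of the
$\pm 1.96\,\mathrm{SE}$ intervals used with these designs), and percent
differences against a baseline model. Fit seeds are derived deterministically
from the scheme seed, so an experiment re-run with the same configuration is
bit-identical.

## The synthetic-data generator

The generator emulates the structure of elite yield trial (EYT) wheat
datasets: a few hundred related lines, a few thousand biallelic SNPs, 4--6
environments with partially overlapping genotype sets. Its components:

* a random-mating pedigree (founders plus a configurable number of
  generations);
* gene-dropped markers — founders drawn Binomial(2, freq) with per-marker
  frequencies uniform on a configurable range, descendants inheriting one
  allele per parent with probability dosage/2, markers independent;
* phenotypes drawn from the S5/M5 generative models via PSD matrix square
  roots (eigendecomposition, negative eigenvalues clipped at zero), with all
  true effect vectors returned.

The default preset uses $n = 600$, $p = 2000$, $m = 5$, genetic variance
components $(A, K, C, P) = (0.2, 0.45, 0.35, 0.27)$ and residual $0.22$ —
values in the range reported for standardized grain-yield BLUEs in elite
wheat trials, documented as inspired-by rather than equal-to any particular
dataset. Desk-scale checks use $n = 200$--$300$ with founders scaled
proportionally ($n/10$) and reduced chains (6,000 iterations, 1,000 burn-in,
thinning 5); these sizes are the package's own choice of a configuration
small enough to iterate on while large enough for the directional results to
be stable.

What the generator does *not* emulate: linkage disequilibrium (markers are
independent given the pedigree), selection, genotyping error, and
environment-specific marker effects. One consequence deserves emphasis:
gene-dropping markers down a pedigree makes K track A closely, so A, K and
the derived C and P are strongly collinear — more so than is typical of real
elite panels, where genotyped relationships deviate more from recorded
pedigrees. Passing tests on these data therefore demonstrate correctness of
the machinery, not the field performance of any model.

## Calibration findings and known limitations

The test suite and acceptance script compute, among other things, a
parameter-recovery experiment: fit each model on data simulated from its own
generative law and ask whether every true variance component lies within 2
posterior standard deviations of its posterior mean. For the single-kernel
GBLUP model this holds in essentially all replicates. For the four-kernel
hybrid model it holds in only roughly half the replicates at $n = 300$: the
simulated signal corresponds to a heritability near 0.85 while the default
prior partitions variance 50/50, and because the four kernels are collinear
and all have positive eigenvalue floors, the likelihood at this sample size
only weakly separates the genetic floor from the residual, so the prior
systematically pulls the residual up and the Gaussian-kernel variance down.
A control experiment with the prior proportion matched to the simulated
signal recovers every component in every replicate, confirming that the
sampler itself is calibrated (its fixed-variance posterior means also match
the closed-form BLUP solve to machine-level accuracy). The practical
reading: with several collinear kernels, individual variance components are
weakly identified and their posteriors are prior-sensitive; predictions and
variance *totals* are much better behaved than the component split.

Other limitations: the effect-vector correlation report inherits the same
collinearity (estimated effect vectors for C and A correlate strongly on
generator data even when the true effects are independent, because the
kernels themselves are similar); inverse-Wishart priors on $U_k$ are the
simplest unstructured choice and no factor-analytic or structured
alternatives are provided; and the Hadamard mode uses a single homogeneous
residual variance, the natural reading of the record-level formulation,
while per-environment residuals are available only through the balanced
mode.

## Numerical choices, in one place

* Eigenvalue truncation for sampling bases: $10^{-10}$; coordinates of
  truncated components are fixed at zero.
* Kernel symmetry is enforced to $10^{-10}$ at construction and checked to
  $10^{-8}$ before fitting; accumulated floating-point asymmetry is averaged
  out ($\tfrac12(M + M')$) where products are formed.
* PSD repair preserves the mean diagonal; the model-fitting default is
  `eigen_clip` (see above), `jitter` is available, tolerance $10^{-8}$.
* Variance-component Monte Carlo errors use batch means (30 batches);
  effective sample size is derived from the same quantity.
* Scheme seeds, fit seeds and generator seeds are all derived from a single
  user seed by a fixed integer recurrence, keeping every derived seed below
  $2^{31}$.
* Delimited output uses 17 significant digits, so kernel files round-trip
  bit-stably.
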