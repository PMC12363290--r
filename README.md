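# hybridGP

Bayesian multi-kernel genomic prediction for plant breeding, built around a
pair of **hybrid relationship kernels** derived from the matrix product of a
Gaussian marker kernel and a pedigree kernel.

## The problem and the models

Breeding programs predict the genetic merit of candidate lines from
phenotypes observed on related, partially overlapping sets of lines, often
across several environments. The standard tools are mixed models whose
random genetic effects carry a relationship kernel:

* the pedigree (numerator) matrix **A**, expected relatedness from recorded
  ancestry;
* the linear genomic matrix **G = XX'/p** on standardized markers (GBLUP);
* the Gaussian kernel **K**, `K_ij = exp(-d_ij² / median(d_ij²))` on squared
  Euclidean marker distances, which also captures non-additive signal.

`hybridGP` adds the hybrid kernels **C** and **P**: the matrix product
**KA** is split into its strictly upper and strictly lower triangular parts,
each is symmetrized by adding its transpose, the diagonal of **KA** is
restored, and the result is scaled by its mean diagonal. The pair satisfies
`mean(diag(KA)) · (C + P) = KA + (KA)'` exactly. C and P capture joint
marker-pedigree structure not available to A or K alone.

The model sequence is

```
S1: y = 1μ + g_A + ε                      g_k ~ N(0, σ²_k K_k)
S2: y = 1μ + g_G + ε                      ε   ~ N(0, σ²_ε I)
S3: y = 1μ + g_K + ε
S4: y = 1μ + g_A + g_K + ε
S5: y = 1μ + g_A + g_K + g_C + g_P + ε    (the hybrid model)
```

with multi-environment counterparts M1–M5 in which each kernel's effects
carry an unstructured environment covariance, `U_k ⊗ K_k` for balanced data
or the record-level Hadamard covariance `(Z₁K_kZ₁') ∘ (Z₂EZ₂')` for
unbalanced data. Everything is fitted by Gibbs sampling with
scaled-inverse-chi-square (single-environment) or inverse-Wishart
(multi-environment) variance priors; masked phenotypes are imputed by data
augmentation, which is also how held-out genotypes are predicted.

The package includes the full evaluation machinery used for this model
family (repeated k-fold and environment-masking cross-validation, Pearson /
PMSE summaries with AVG ± 1.96·SE intervals and percent differences against
a baseline) and a synthetic-data generator that simulates pedigrees,
gene-dropped markers and phenotypes from the S/M generative models with
known variance components.

## Worked example

Simulate an elite-yield-trial-like dataset, fit the hybrid model S5, and
compare S5 against the GBLUP baseline S2 in a paired five-fold
cross-validation:

```r
library(hybridGP)

cfg <- simConfig(nGenotypes = 300, nMarkers = 2000, nFounders = 30,
                 generations = 3, mEnvironments = 1)
sim <- simulateDataset(cfg, seed = 11)

y  <- sim$single$y
al <- alignKernels(sim$kernels[c("A", "K", "C", "P")], phenotypes = y)
fit <- fitSingleEnv(al$phenotypes, al$kernels,
                    nIter = 6000, burnIn = 1000, thin = 5, seed = 11)
fit
#> SingleEnvFit: 300 genotypes (300 observed), kernels: A, K, C, P
#>   intercept: -0.4678 (sd 0.6156)
#>  component   mean      sd     mcse    ess  rhat
#>          A 0.2241 0.09993 0.011608  74.12 1.025
#>          K 0.2692 0.14355 0.017971  63.81 1.018
#>          C 0.4079 0.20154 0.021022  91.91 1.030
#>          P 0.1398 0.08629 0.009328  85.58 1.034
#>   residual 0.3943 0.07717 0.005354 207.71 1.001

scheme <- makeKfoldScheme(length(y), k = 5, repeats = 1, seed = 11)
res <- runExperiment(y, sim$kernels,
                     list(S2 = "G", S5 = c("A", "K", "C", "P")),
                     scheme, nIter = 3000, burnIn = 500, thin = 5)
print(summarizeCV(res, baseline = "S2"), digits = 3)
#>   model nFolds   AVG     SE lower95 upper95 pmseMean pmseSd pctDiff
#> 1    S2      5 0.429 0.0529   0.325   0.533    0.771  0.216     0.0
#> 2    S5      5 0.493 0.0593   0.377   0.610    0.715  0.194    14.9
```

The fit shows each kernel's posterior variance component (here the data were
generated with nonzero C and P signal, and the fit assigns them substantial
variance) with Monte Carlo diagnostics. The CV table reports the mean
per-fold Pearson correlation (AVG), its standard error, the 95% interval,
PMSE, and the percent difference of each model against the baseline: S5
predicts held-out genotypes about 15% better than GBLUP on these data, with
a correspondingly lower PMSE.

A command-line interface over the same functions lives in
`inst/scripts/hybridgp.R`, with subcommands `simulate`, `kernels`, `fit` and
`cv` driven by a YAML configuration; every run writes a manifest (config,
seed, input hashes) sufficient to reproduce it bit-exactly.

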