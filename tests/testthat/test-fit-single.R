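test_that("conditional-mean mode reproduces the closed-form BLUP solve", {
  sim <- smallDataset(n = 80, seed = 12, kinds = c("A", "K"))
  y <- sim$single$y
  al <- alignKernels(sim$kernels[c("A", "K")], phenotypes = y)
  vc <- c(A = 0.3, K = 0.4, residual = 0.3)
  # collinear kernels make the coordinate updates contract slowly; give the
  # deterministic pass enough sweeps to converge
  fit <- fitSingleEnv(al$phenotypes, al$kernels, nIter = 1600, burnIn = 1500,
                      thin = 1, seed = 1, fixedVarcomp = vc,
                      deterministic = TRUE)
  mats <- lapply(al$kernels, function(k) {
    kernelMatrix(validateKernel(k, repair = "eigen_clip"))
  })
  oracle <- blupOracle(as.numeric(al$phenotypes), mats,
                       sigma2 = c(0.3, 0.4), sigma2e = 0.3)
  eff <- geneticEffects(fit)
  expect_lt(max(abs(eff[, "A"] - oracle$g[[1]])), 1e-8)
  expect_lt(max(abs(eff[, "K"] - oracle$g[[2]])), 1e-8)
  expect_equal(unname(fit@muPosterior[["mean"]]), oracle$mu,
               tolerance = 1e-8)
})

test_that("stochastic sampler with fixed variances matches BLUP within MCMC error", {
  sim <- smallDataset(n = 80, seed = 13, kinds = "G",
                      varianceComponents = c(G = 0.6), residual = 0.4)
  y <- sim$single$y
  G <- sim$kernels$G
  vc <- c(G = 0.6, residual = 0.4)
  fit <- fitSingleEnv(y, list(G = G), nIter = 3000, burnIn = 500, thin = 1,
                      seed = 2, fixedVarcomp = vc)
  oracle <- blupOracle(as.numeric(y), list(kernelMatrix(G)),
                       sigma2 = 0.6, sigma2e = 0.4)
  relErr <- sqrt(sum((geneticEffects(fit)[, 1] - oracle$g[[1]])^2)) /
    sqrt(sum(oracle$g[[1]]^2))
  expect_lt(relErr, 0.005)
})

test_that("chains are bit-reproducible under a fixed seed", {
  sim <- smallDataset(n = 60, seed = 14)
  y <- sim$single$y
  y[1:10] <- NA  # include data augmentation in the reproducibility check
  al <- alignKernels(sim$kernels[c("A", "K")], phenotypes = y)
  f1 <- fitSingleEnv(y[al$ids], al$kernels, nIter = 800, burnIn = 200,
                     seed = 42)
  f2 <- fitSingleEnv(y[al$ids], al$kernels, nIter = 800, burnIn = 200,
                     seed = 42)
  expect_identical(f1@samples$varcomp, f2@samples$varcomp)
  expect_identical(f1@yhat, f2@yhat)
  f3 <- fitSingleEnv(y[al$ids], al$kernels, nIter = 800, burnIn = 200,
                     seed = 43)
  expect_false(identical(f1@yhat, f3@yhat))
})

test_that("posterior means are invariant to simultaneous genotype permutation", {
  sim <- smallDataset(n = 60, seed = 15)
  y <- sim$single$y
  al <- alignKernels(sim$kernels[c("A", "K")], phenotypes = y)
  fit <- fitSingleEnv(y[al$ids], al$kernels, nIter = 4000, burnIn = 1000,
                      seed = 7)
  set.seed(99)
  perm <- sample(length(al$ids))
  kPerm <- lapply(al$kernels, function(k) {
    RelationshipKernel(kernelMatrix(k)[perm, perm], ids = al$ids[perm],
                       kind = kernelKind(k))
  })
  fitP <- fitSingleEnv(y[al$ids[perm]], kPerm, nIter = 4000, burnIn = 1000,
                       seed = 8)
  # same genotypes, same data: predictions agree within MCMC noise
  expect_equal(unname(fittedValues(fitP)[al$ids]),
               unname(fittedValues(fit)[al$ids]), tolerance = 0.05)
  vc1 <- varianceComponents(fit)
  vc2 <- varianceComponents(fitP)
  expect_equal(vc1$mean, vc2$mean, tolerance = 0.15)
})

test_that("masked phenotypes are predicted and the yhat decomposition holds", {
  sim <- smallDataset(n = 80, seed = 16)
  y <- sim$single$y
  al <- alignKernels(sim$kernels[c("A", "K")], phenotypes = y)
  yMask <- y[al$ids]
  masked <- al$ids[1:20]
  yMask[masked] <- NA
  fit <- fitSingleEnv(yMask, al$kernels, nIter = 2000, burnIn = 500,
                      seed = 3)
  # decomposition: yhat = muHat + sum of effect means, everywhere
  recon <- fit@muPosterior[["mean"]] + rowSums(geneticEffects(fit))
  expect_equal(unname(fit@yhat), unname(recon), tolerance = 1e-10)
  # prediction accessors
  expect_equal(predictSingleEnv(fit, masked),
               fittedValues(fit)[masked])
  expect_length(predictSingleEnv(fit), length(al$ids))
  expect_error(predictSingleEnv(fit, "no-such-id"), "unknown")
  # masked predictions correlate with the held-out truth
  expect_gt(cor(predictSingleEnv(fit, masked), y[masked]), 0.2)
})

test_that("a single identity kernel partitions the sample variance sanely", {
  set.seed(21)
  n <- 500
  ids <- sprintf("g%03d", 1:n)
  I <- RelationshipKernel(diag(n), ids = ids, kind = "custom")
  y <- setNames(rnorm(n, 5, 1), ids)
  fit <- fitSingleEnv(y, list(I = I), nIter = 3000, burnIn = 500, seed = 5)
  vc <- varianceComponents(fit)
  total <- sum(vc$mean)
  expect_lt(abs(total - var(y)) / var(y), 0.10)
})

test_that("constant phenotypes collapse to the prior without failing", {
  n <- 30
  ids <- sprintf("g%02d", 1:n)
  I <- RelationshipKernel(diag(n), ids = ids)
  y <- setNames(rep(2, n), ids)
  fit <- fitSingleEnv(y, list(I = I), nIter = 600, burnIn = 100, seed = 1)
  expect_lt(max(abs(fittedValues(fit) - 2)), 0.05)
  expect_true(all(varianceComponents(fit)$mean > 0))
})

test_that("effect-vector correlation report is well-formed", {
  sim <- smallDataset(n = 60, seed = 17)
  y <- sim$single$y
  al <- alignKernels(sim$kernels[c("A", "K", "C", "P")], phenotypes = y)
  fit <- fitSingleEnv(y[al$ids], al$kernels, nIter = 1500, burnIn = 500,
                      seed = 9)
  R <- effectVectorCorrelations(fit)
  expect_equal(diag(R), setNames(rep(1, 4), c("A", "K", "C", "P")))
  expect_equal(R, t(R))
  expect_true(all(abs(R) <= 1 + 1e-12))

  # a single-kernel fit has no pairwise report
  fit1 <- fitSingleEnv(y[al$ids], al$kernels["A"], nIter = 400,
                       burnIn = 100, seed = 1)
  expect_error(effectVectorCorrelations(fit1), "2 kernels")

  # duplicated kernel: value reported with an identifiability caveat
  fitDup <- fitSingleEnv(y[al$ids],
                         list(A = al$kernels$A, A2 = al$kernels$A),
                         nIter = 400, burnIn = 100, seed = 1)
  fitDup@kernelNames <- c("A", "A")
  expect_message(effectVectorCorrelations(fitDup), "identifiable")
})
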