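test_that("balance detection reports incidence and overlap correctly", {
  gid <- rep(sprintf("g%02d", 1:10), times = 3)
  env <- rep(c("E1", "E2", "E3"), each = 10)
  phen <- phenotypeTable(gid, env, rnorm(30))
  bal <- detectBalance(phen)
  expect_true(bal$balanced)
  expect_equal(unname(bal$envCounts), rep(10L, 3))
  expect_equal(unname(diag(bal$overlap)), unname(bal$envCounts))

  # one missing cell flips the verdict
  bal2 <- detectBalance(phen[-1, ])
  expect_false(bal2$balanced)
  expect_equal(unname(bal2$envCounts), c(9L, 10L, 10L))

  expect_error(detectBalance(phen[phen$env == "E1", ]), "2 environments")
})

test_that("Hadamard covariance equals the Kronecker form on balanced data", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(2:5, 1)
    m <- sample(2:3, 1)
    K <- randPsdKernel(n, seed = 300 + seed)
    U <- crossprod(matrix(rnorm(m * m), m)) / m
    envs <- sprintf("E%d", seq_len(m))
    dimnames(U) <- list(envs, envs)
    # records sorted by (environment, genotype): identity permutation
    phen <- phenotypeTable(rep(genotypeIds(K), times = m),
                           rep(envs, each = n), rnorm(n * m))
    H <- buildHadamardCovariance(K, phen, U)
    expect_equal(H, U %x% kernelMatrix(K), tolerance = 1e-12,
                 ignore_attr = TRUE)

    # shuffled record order: equal up to the record permutation
    perm <- sample(n * m)
    Hp <- buildHadamardCovariance(K, phen[perm, ], U)
    expect_equal(Hp, H[perm, perm], tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("Hadamard covariance limiting cases: shared effect and block diagonal", {
  K <- randPsdKernel(4, seed = 50)
  envs <- c("E1", "E2")
  phen <- phenotypeTable(rep(genotypeIds(K), 2), rep(envs, each = 4),
                         rnorm(8))
  ones <- matrix(1, 2, 2, dimnames = list(envs, envs))
  H1 <- buildHadamardCovariance(K, phen, ones)
  Z1K <- kernelMatrix(K)[rep(1:4, 2), rep(1:4, 2)]
  expect_equal(H1, Z1K, tolerance = 1e-12, ignore_attr = TRUE)

  HI <- buildHadamardCovariance(K, phen, diag(2))
  expect_equal(HI[1:4, 5:8], matrix(0, 4, 4), ignore_attr = TRUE)

  badE <- matrix(1, 2, 2, dimnames = list(c("E1", "EX"), c("E1", "EX")))
  expect_error(buildHadamardCovariance(K, phen, badE), "absent from E")
})

test_that("estimateE recovers limiting cases", {
  ids <- sprintf("g%03d", 1:40)
  v <- rnorm(40)
  # identical phenotypes in two environments: correlation 1
  phen <- phenotypeTable(rep(ids, 2), rep(c("E1", "E2"), each = 40),
                         c(v, v))
  E0 <- estimateE(phen, shrink = 0)
  expect_equal(E0["E1", "E2"], 1, tolerance = 1e-12)

  # independent phenotypes, large overlap: off-diagonal near 0
  set.seed(31)
  ids2 <- sprintf("g%04d", 1:1000)
  phen2 <- phenotypeTable(rep(ids2, 2), rep(c("E1", "E2"), each = 1000),
                          rnorm(2000))
  E2 <- estimateE(phen2, shrink = 0)
  expect_lt(abs(E2["E1", "E2"]), 0.1)

  # shrink = 1 gives the exact compound-symmetry matrix
  E3 <- estimateE(phen2, shrink = 1)
  rbar <- E2["E1", "E2"]
  expect_equal(unname(E3), (1 - rbar) * diag(2) + rbar, tolerance = 1e-12)

  # insufficient overlap falls back to the mean off-diagonal with a warning
  phen3 <- rbind(phen2,
                 phenotypeTable(c("x1", "x2"), c("E3", "E3"), rnorm(2)))
  expect_warning(E4 <- estimateE(phen3, shrink = 0), "insufficient overlap")
  expect_equal(dim(E4), c(3L, 3L))
})

test_that("balanced multi-trait fit recovers known U and R diagonals", {
  cfg <- simConfig(nGenotypes = 200, nMarkers = 800, nFounders = 20,
                   generations = 3, mEnvironments = 3,
                   varianceComponents = c(G = 0.6), residual = 0.4,
                   envCor = 0.5)
  sim <- simulateDataset(cfg, seed = 9)
  fit <- fitMultiEnv(sim$multi$phenotypes, sim$kernels["G"],
                     mode = "balanced_kron", nIter = 4000, burnIn = 1000,
                     thin = 5, seed = 10)
  expect_s4_class(fit, "MultiEnvFit")
  expect_equal(fit@mode, "balanced_kron")
  vc <- varianceComponents(fit)
  truth <- c(diag(sim$multi$UList$G), diag(sim$multi$R))
  z <- abs(vc$mean - truth) / vc$sd
  expect_true(all(z <= 2))
  # posterior-mean U and R stay symmetric
  expect_equal(fit@envCovPosterior$G, t(fit@envCovPosterior$G))
  expect_equal(fit@envCovPosterior$R, t(fit@envCovPosterior$R))
  # off-diagonal genetic covariance is detected (truth 0.3)
  expect_gt(mean(fit@envCovPosterior$G[upper.tri(diag(3))]), 0.1)
})

test_that("forcing balanced mode on unbalanced data errors; auto falls back", {
  sim <- smallDataset(n = 60, seed = 23, m = 2)
  phen <- sim$multi$phenotypes[-1, ]
  expect_error(fitMultiEnv(phen, sim$kernels[c("A", "K")],
                           mode = "balanced_kron", nIter = 200,
                           burnIn = 100),
               "complete")
  fit <- suppressMessages(
    fitMultiEnv(phen, sim$kernels[c("A", "K")], mode = "auto", nIter = 400,
                burnIn = 100, seed = 2)
  )
  expect_equal(fit@mode, "unbalanced_hadamard")
})

test_that("m = 1 Hadamard fit reproduces the single-environment fit", {
  sim <- smallDataset(n = 100, seed = 24)
  y <- sim$single$y
  al <- alignKernels(sim$kernels[c("A", "K")], phenotypes = y)
  fitS <- fitSingleEnv(y[al$ids], al$kernels, nIter = 4000, burnIn = 1000,
                       thin = 5, seed = 7)
  phen <- phenotypeTable(al$ids, "E1", as.numeric(y[al$ids]))
  fitM <- fitMultiEnv(phen, al$kernels, mode = "unbalanced_hadamard",
                      E = matrix(1, 1, 1, dimnames = list("E1", "E1")),
                      nIter = 4000, burnIn = 1000, thin = 5, seed = 8)
  vS <- varianceComponents(fitS)
  vM <- varianceComponents(fitM)
  z <- abs(vS$mean - vM$mean) / sqrt(vS$mcse^2 + vM$mcse^2)
  expect_true(all(z <= 3))
})

test_that("masked target-environment cells receive informed predictions", {
  cfg <- simConfig(nGenotypes = 120, nMarkers = 400, nFounders = 12,
                   generations = 2, mEnvironments = 3,
                   varianceComponents = c(G = 0.6), residual = 0.2,
                   envCor = 0.8)
  sim <- simulateDataset(cfg, seed = 33)
  phen <- sim$multi$phenotypes
  truth <- phen[phen$env == "E2", ]
  masked <- truth$gid[1:90]
  phen$value[phen$env == "E2" & phen$gid %in% masked] <- NA
  fit <- fitMultiEnv(phen, sim$kernels["G"], mode = "balanced_kron",
                     nIter = 2000, burnIn = 500, seed = 3)
  pred <- predictMultiEnv(fit, gid = masked, env = "E2")
  obs <- truth$value[match(pred$gid, truth$gid)]
  expect_gt(cor(pred$yhat, obs), 0.4)
  expect_false(any(pred$observed))
})

test_that("predicting most of an environment works better when more is known", {
  cfg <- simConfig(nGenotypes = 150, nMarkers = 500, nFounders = 15,
                   generations = 2, mEnvironments = 3, envCor = 0.5)
  sim <- simulateDataset(cfg, seed = 41)
  phen <- sim$multi$phenotypes
  models <- list(M5 = c("A", "K", "C", "P"))
  res80 <- runExperiment(phen, sim$kernels, models,
                         makeEnvMaskScheme(phen, "E1", 0.20, 5, seed = 61),
                         nIter = 1200, burnIn = 400, thin = 4)
  res95 <- runExperiment(phen, sim$kernels, models,
                         makeEnvMaskScheme(phen, "E1", 0.05, 5, seed = 61),
                         nIter = 1200, burnIn = 400, thin = 4)
  expect_gt(mean(res80$records$pearson), mean(res95$records$pearson))
})
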