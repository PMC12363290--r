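test_that("G = XX'/p matches hand computation and an accumulation oracle", {
  # column [-1, 0, 1] has mean 0 and sample sd 1: valid standardized input
  X <- matrix(c(-1, 0, 1), ncol = 1)
  G <- computeG(MarkerMatrix(X, standardized = TRUE))
  expect_equal(unname(kernelMatrix(G)),
               rbind(c(1, 0, -1), c(0, 0, 0), c(-1, 0, 1)),
               tolerance = 1e-12)
  # two anticorrelated genotypes: sample-sd scaling at n = 2 gives +/- 0.5
  std <- standardizeMarkers(MarkerMatrix(matrix(c(1, -1, 2, 0), 2)))
  expect_equal(unname(kernelMatrix(computeG(std))),
               matrix(c(0.5, -0.5, -0.5, 0.5), 2), tolerance = 1e-12)

  # column-by-column accumulation oracle on a larger matrix
  set.seed(11)
  Xr <- matrix(rbinom(300, 2, 0.5), 15, 20)
  stdr <- suppressWarnings(standardizeMarkers(MarkerMatrix(Xr)))
  Gr <- kernelMatrix(computeG(stdr))
  V <- markerValues(stdr)
  acc <- matrix(0, nrow(V), nrow(V))
  for (j in seq_len(ncol(V))) acc <- acc + tcrossprod(V[, j])
  expect_equal(Gr, acc / ncol(V), tolerance = 1e-10, ignore_attr = TRUE)

  # identical genotype rows share row/col entries; Gram matrix is PSD
  X2 <- rbind(Xr, Xr[3, ])
  std2 <- suppressWarnings(standardizeMarkers(MarkerMatrix(X2)))
  G2 <- kernelMatrix(computeG(std2))
  n2 <- nrow(G2)
  expect_equal(G2[3, n2], G2[3, 3], tolerance = 1e-12)
  expect_equal(G2[n2, n2], G2[3, 3], tolerance = 1e-12)
  expect_gte(min(eigen(G2, symmetric = TRUE, only.values = TRUE)$values),
             -1e-8)

  expect_error(computeG(MarkerMatrix(Xr)), "standardized")
})

test_that("Gaussian kernel reproduces the hand-derived 3-genotype fixture", {
  X <- rbind(c(0, 0), c(1, 0), c(1, 1))
  K <- gaussianKernel(MarkerMatrix(X))
  # off-diagonal d^2 = {1, 2, 1}, median 1
  expect_equal(K@bandwidthInfo, 1)
  Km <- kernelMatrix(K)
  expect_equal(unname(Km),
               rbind(c(1, exp(-1), exp(-2)),
                     c(exp(-1), 1, exp(-1)),
                     c(exp(-2), exp(-1), 1)),
               tolerance = 1e-15)
  expect_identical(diag(Km), c(g1 = 1, g2 = 1, g3 = 1))

  # bandwidth scale widens the kernel
  K2 <- gaussianKernel(MarkerMatrix(X), bandwidthScale = 2)
  expect_equal(kernelMatrix(K2)[1, 2], exp(-0.5), tolerance = 1e-15)
})

test_that("Gaussian kernel handles duplicates, permutations and degeneracy", {
  set.seed(4)
  X <- matrix(rbinom(120, 2, 0.5), 12, 10)
  X[7, ] <- X[2, ]
  K <- kernelMatrix(gaussianKernel(MarkerMatrix(X)))
  expect_equal(K[2, 7], 1)          # zero distance
  expect_identical(diag(K), setNames(rep(1, 12), rownames(K)))

  # permutation invariance: permuting rows permutes K identically
  perm <- sample(12)
  Kp <- kernelMatrix(gaussianKernel(MarkerMatrix(X[perm, , drop = FALSE],
                                                 ids = paste0("g", perm))))
  expect_equal(unname(Kp), unname(K[perm, perm]), tolerance = 1e-12)

  # all-identical genotypes: median distance 0 is degenerate
  expect_error(gaussianKernel(MarkerMatrix(X[c(1, 1, 1), ])), "degenerate")
})

test_that("pedigree A matches hand-derived cases and the coancestry oracle", {
  # two founders: identity
  ped0 <- pedigreeTable(c("a", "b"), c(NA, NA), c(NA, NA))
  expect_equal(unname(kernelMatrix(pedigreeToA(ped0))), diag(2))

  # full sibs of unrelated founders: relationship 0.5, unit diagonals
  ped1 <- pedigreeTable(c("f1", "f2", "s1", "s2"),
                        c(NA, NA, "f1", "f1"), c(NA, NA, "f2", "f2"))
  A1 <- kernelMatrix(pedigreeToA(ped1))
  expect_equal(A1["s1", "s2"], 0.5)
  expect_equal(diag(A1), c(f1 = 1, f2 = 1, s1 = 1, s2 = 1))

  # selfed founder: offspring diagonal 1 + 0.5 * A_pp = 1.5
  ped2 <- pedigreeTable(c("f", "x"), c(NA, "f"), c(NA, "f"))
  expect_equal(kernelMatrix(pedigreeToA(ped2))["x", "x"], 1.5)

  # random pedigrees up to 6 individuals against the path-counting oracle
  for (seed in 1:25) {
    set.seed(seed)
    n <- sample(3:6, 1L)
    id <- paste0("i", seq_len(n))
    p1 <- p2 <- rep(NA_character_, n)
    for (i in 3:n) {
      if (runif(1) < 0.7) {
        pr <- sample(seq_len(i - 1L), 2L, replace = TRUE)
        p1[i] <- id[pr[1L]]; p2[i] <- id[pr[2L]]
      }
    }
    ped <- pedigreeTable(id, p1, p2)
    expect_equal(kernelMatrix(pedigreeToA(ped)), coancestryOracleA(ped),
                 tolerance = 1e-12)
  }
})

test_that("pedigree construction sorts, adds implicit founders, rejects cycles", {
  # offspring listed before parents gets sorted
  ped <- pedigreeTable(c("kid", "f1", "f2"), c("f1", NA, NA),
                       c("f2", NA, NA))
  expect_equal(pedigreeRecords(ped)$id[3], "kid")
  # a parent never listed as an individual becomes a founder
  ped2 <- pedigreeTable("kid", "mum", "dad")
  expect_setequal(genotypeIds(ped2), c("mum", "dad", "kid"))
  expect_error(pedigreeTable(c("a", "b"), c("b", "a"), c(NA, NA)), "cyclic")
})

test_that("KA product matches hand computation and is generally asymmetric", {
  K <- RelationshipKernel(rbind(c(1, 0.5), c(0.5, 1)), ids = c("a", "b"),
                          kind = "K")
  A <- RelationshipKernel(rbind(c(1, 0.25), c(0.25, 1)), ids = c("a", "b"),
                          kind = "A")
  KA <- computeKA(K, A)
  expect_equal(unname(KA), rbind(c(1.125, 0.75), c(0.75, 1.125)),
               tolerance = 1e-12)

  # identity pedigree leaves K unchanged
  I2 <- RelationshipKernel(diag(2), ids = c("a", "b"), kind = "A")
  expect_equal(computeKA(K, I2), kernelMatrix(K), tolerance = 1e-15)

  # generic symmetric pair: product is asymmetric
  K3 <- randPsdKernel(3, seed = 5)
  A3 <- randPsdKernel(3, seed = 6)
  A3@ids <- K3@ids
  dimnames(A3@matrix) <- dimnames(K3@matrix)
  KA3 <- computeKA(K3, A3)
  expect_gt(max(abs(KA3 - t(KA3))), 1e-6)

  # mismatched ids are rejected
  B <- RelationshipKernel(diag(2), ids = c("x", "y"), kind = "A")
  expect_error(computeKA(K, B), "id order")
})

test_that("C and P reproduce the worked 2x2 example and scaling metadata", {
  KA <- rbind(c(1.125, 0.75), c(0.75, 1.125))
  rownames(KA) <- colnames(KA) <- c("a", "b")
  C <- buildC(KA)
  P <- buildP(KA)
  expect_equal(unname(kernelMatrix(C)),
               rbind(c(1, 2 / 3), c(2 / 3, 1)), tolerance = 1e-12)
  # symmetric KA makes the two constructions coincide
  expect_equal(kernelMatrix(P), kernelMatrix(C), tolerance = 1e-15)
  expect_equal(C@scalingInfo, 1.125)
  expect_equal(kernelKind(C), "C")
  expect_equal(kernelKind(P), "P")

  # KA already symmetric with unit diagonal is returned unchanged
  KAsym <- rbind(c(1, 0.4), c(0.4, 1))
  dimnames(KAsym) <- list(c("a", "b"), c("a", "b"))
  expect_equal(kernelMatrix(buildC(KAsym)), KAsym, tolerance = 1e-12)

  expect_error(buildC(-diag(3)), "degenerate")
})

test_that("kernel algebra identities hold on random PSD pairs", {
  for (seed in 1:100) {
    n <- 3L + (seed %% 18L)
    K <- randPsdKernel(n, seed = 1000L + seed)
    A <- randPsdKernel(n, seed = 2000L + seed)
    A@ids <- K@ids
    dimnames(A@matrix) <- dimnames(K@matrix)
    KA <- computeKA(K, A)
    C <- kernelMatrix(buildC(KA))
    P <- kernelMatrix(buildP(KA))
    md <- mean(diag(KA))
    # scaling identity: meanDiag(KA) * (C + P) == KA + KA'
    expect_lt(max(abs(md * (C + P) - (KA + t(KA)))), 1e-10)
    # mean diagonal of both hybrids is forced to 1
    expect_equal(mean(diag(C)), 1, tolerance = 1e-12)
    expect_equal(mean(diag(P)), 1, tolerance = 1e-12)
    # lower triangle of KA equals the transpose of the upper triangle of AK
    AK <- kernelMatrix(A) %*% kernelMatrix(K)
    low <- KA; low[!lower.tri(low)] <- 0
    upAK <- AK; upAK[!upper.tri(upAK)] <- 0
    expect_lt(max(abs(low - t(upAK))), 1e-10)
  }
})

test_that("A = I collapses both hybrid kernels onto K", {
  X <- matrix(rbinom(80, 2, 0.5), 8, 10)
  set.seed(2)
  K <- gaussianKernel(MarkerMatrix(X))
  I8 <- RelationshipKernel(diag(8), ids = genotypeIds(K), kind = "A")
  KA <- computeKA(K, I8)
  expect_equal(kernelMatrix(buildC(KA)), kernelMatrix(K), tolerance = 1e-12)
  expect_equal(kernelMatrix(buildP(KA)), kernelMatrix(K), tolerance = 1e-12)
})

test_that("validateKernel reports eigenvalues and repairs indefiniteness", {
  I3 <- RelationshipKernel(diag(3))
  v <- validateKernel(I3)
  expect_equal(attr(v, "validity")$minEigenvalue, 1, tolerance = 1e-12)
  expect_false(attr(v, "validity")$repaired)

  M <- RelationshipKernel(rbind(c(1, 2), c(2, 1)))
  vM <- validateKernel(M)
  expect_equal(attr(vM, "validity")$minEigenvalue, -1, tolerance = 1e-12)
  expect_false(attr(vM, "validity")$psd)

  for (policy in c("jitter", "eigen_clip")) {
    rep <- validateKernel(M, repair = policy)
    info <- attr(rep, "validity")
    expect_true(info$repaired)
    expect_gte(info$minEigenvalue, -1e-8)
    # repair preserves the mean diagonal
    expect_equal(mean(diag(kernelMatrix(rep))), 1, tolerance = 1e-10)
  }

  asym <- new("RelationshipKernel", ids = c("a", "b"),
              matrix = rbind(c(1, 0.5), c(0.5 + 5e-11, 1)), kind = "custom",
              bandwidthInfo = NA_real_, scalingInfo = NA_real_,
              minEigenvalue = NA_real_)
  expect_silent(validateKernel(asym))
})

test_that("alignKernels restricts to the common id set in one shared order", {
  K5 <- randPsdKernel(5, seed = 77)
  ids <- genotypeIds(K5)
  # same kernel with permuted storage order
  perm <- c(3L, 1L, 5L, 2L, 4L)
  Kperm <- RelationshipKernel(kernelMatrix(K5)[perm, perm], ids = ids[perm])
  al <- alignKernels(list(a = K5, b = Kperm))
  expect_identical(genotypeIds(al$kernels$a), genotypeIds(al$kernels$b))
  expect_equal(kernelMatrix(al$kernels$a), kernelMatrix(al$kernels$b),
               tolerance = 1e-15)

  # phenotypes restrict the kernel to 3 ids; extra records dropped with a note
  y <- setNames(rnorm(3), ids[c(2, 4, 5)])
  al2 <- alignKernels(list(K5), phenotypes = y)
  expect_equal(length(al2$ids), 3L)
  expect_equal(dim(kernelMatrix(al2$kernels[[1]])), c(3L, 3L))

  K2 <- RelationshipKernel(diag(2), ids = c("zz1", "zz2"))
  expect_error(alignKernels(list(K5, K2)), "empty")
})
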