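# Independent oracles and fixture builders used across the test suite.

# Random symmetric PSD matrix with diagonal rescaled to mean 1.
randPsdKernel <- function(n, seed, kind = "custom") {
  set.seed(seed)
  B <- matrix(rnorm(n * (n + 2L)), n)
  M <- tcrossprod(B) / (n + 2L)
  M <- M / mean(diag(M))
  RelationshipKernel(M, ids = sprintf("g%02d", seq_len(n)), kind = kind)
}

# Recursive path-counting coancestry oracle: f(i, j) is the kinship
# coefficient; the numerator relationship is A = 2 f with A_ii = 1 + F_i.
# Independent of the tabular recursion used by pedigreeToA.
coancestryOracleA <- function(pedigree) {
  rec <- pedigreeRecords(pedigree)
  n <- nrow(rec)
  idx <- seq_len(n)
  names(idx) <- rec$id
  p1 <- ifelse(is.na(rec$parent1), 0L, idx[rec$parent1])
  p2 <- ifelse(is.na(rec$parent2), 0L, idx[rec$parent2])
  memo <- new.env(hash = TRUE)
  f <- function(i, j) {
    if (i == 0L || j == 0L) return(0)
    if (i > j) { tmp <- i; i <- j; j <- tmp }
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- if (i == j) {
      0.5 * (1 + f(p1[i], p2[i]))
    } else {
      # j is the later individual: recurse through j's parents
      0.5 * (f(i, p1[j]) + f(i, p2[j]))
    }
    memo[[key]] <- val
    val
  }
  A <- matrix(0, n, n, dimnames = list(rec$id, rec$id))
  for (i in seq_len(n)) for (j in seq_len(i)) {
    A[i, j] <- A[j, i] <- 2 * f(i, j)
  }
  A
}

# Closed-form mixed-model (BLUP) solution with a flat-prior intercept:
# GLS intercept, then gHat_k = sigma2_k K_k V^{-1} (y - 1 muHat).
blupOracle <- function(y, kernelMats, sigma2, sigma2e) {
  n <- length(y)
  V <- sigma2e * diag(n)
  for (k in seq_along(kernelMats)) V <- V + sigma2[k] * kernelMats[[k]]
  Vi <- solve(V)
  one <- rep(1, n)
  muHat <- as.numeric((t(one) %*% Vi %*% y) / (t(one) %*% Vi %*% one))
  g <- lapply(seq_along(kernelMats), function(k) {
    as.numeric(sigma2[k] * kernelMats[[k]] %*% Vi %*% (y - muHat))
  })
  list(mu = muHat, g = g)
}

# Small aligned dataset (kernels + phenotypes) for sampler tests.
smallDataset <- function(n = 100L, seed = 1L, kinds = c("A", "K"),
                         varianceComponents = c(A = 0.3, K = 0.4),
                         residual = 0.3, m = 1L) {
  cfg <- simConfig(nGenotypes = n, nMarkers = 400L,
                   nFounders = max(4L, n %/% 10L), generations = 2L,
                   varianceComponents = varianceComponents,
                   residual = residual, mEnvironments = m)
  simulateDataset(cfg, seed = seed)
}
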