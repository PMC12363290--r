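# Internal numerical helpers shared across modules.

# Column sample standard deviations (n - 1 denominator), without apply().
.colSds <- function(x) {
  n <- nrow(x)
  cm <- colMeans(x)
  sqrt((colSums(x^2) - n * cm^2) / (n - 1))
}

# Draw from a scaled-inverse-chi-square(df, scale): df * scale / chisq(df).
.rScaledInvChisq <- function(df, scale) {
  df * scale / stats::rchisq(1L, df)
}

# Draw from an inverse-Wishart(df, S): if W ~ Wishart(df, S^{-1}), W^{-1}.
.rInvWishart <- function(df, S) {
  W <- stats::rWishart(1L, df, solve(S))[, , 1L]
  solve((W + t(W)) / 2)
}

# Symmetrize (guards accumulated floating-point asymmetry).
.symm <- function(M) (M + t(M)) / 2

# Eigendecomposition of a kernel, keeping components with eigenvalue > tol.
# Returns vectors Q (n x q) and values lambda (length q).
.kernelEigen <- function(M, tol = 1e-10) {
  e <- eigen(.symm(M), symmetric = TRUE)
  keep <- e$values > tol
  list(Q = e$vectors[, keep, drop = FALSE], lambda = e$values[keep])
}

# Symmetric PSD square root via eigendecomposition; negative eigenvalues
# clipped at zero.
.psdSqrt <- function(M) {
  e <- eigen(.symm(M), symmetric = TRUE)
  vals <- pmax(e$values, 0)
  e$vectors %*% (sqrt(vals) * t(e$vectors))
}

# Batch-means Monte Carlo standard error of the mean of a chain.
.batchMcse <- function(x, nBatch = 30L) {
  n <- length(x)
  nBatch <- max(2L, min(nBatch, n %/% 2L))
  if (nBatch < 2L || n < 4L) return(stats::sd(x) / sqrt(max(n, 1L)))
  size <- n %/% nBatch
  used <- size * nBatch
  bm <- colMeans(matrix(x[seq_len(used)], nrow = size))
  stats::sd(bm) / sqrt(nBatch)
}

# Effective sample size from the batch-means MCSE.
.effectiveSize <- function(x) {
  v <- stats::var(x)
  if (!is.finite(v) || v == 0) return(length(x))
  mcse <- .batchMcse(x)
  if (mcse == 0) return(length(x))
  min(length(x), v / mcse^2)
}

# Split-chain potential scale reduction (two halves of a single chain).
.splitRhat <- function(x) {
  n <- length(x) %/% 2L
  if (n < 2L) return(NA_real_)
  halves <- cbind(x[seq_len(n)], x[n + seq_len(n)])
  m <- 2L
  W <- mean(apply(halves, 2L, stats::var))
  B <- n * stats::var(colMeans(halves))
  if (W == 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# Strict triangular parts (diagonal excluded).
.strictUpper <- function(M) {
  out <- M
  out[!upper.tri(M)] <- 0
  out
}

.strictLower <- function(M) {
  out <- M
  out[!lower.tri(M)] <- 0
  out
}

# Derive a substream seed below 2^31 from a base seed and a stream index.
.streamSeed <- function(seed, stream) {
  (as.numeric(seed) * 1000003 + as.numeric(stream) * 7919) %% 2147483647
}
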