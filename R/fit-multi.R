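#' Construct a long-format phenotype table
#'
#' Phenotypes are handled in long format: one record per (genotype,
#' environment) combination with an adjusted-mean (BLUE) value. A record with
#' \code{NA} value is a structurally present but masked cell (used by the
#' cross-validation machinery); a combination with no record at all is an
#' unbalanced hole.
#'
#' @param gid genotype ids (character), or a data.frame with columns
#'   \code{gid}, \code{env}, \code{value} as the only argument.
#' @param env environment ids (character).
#' @param value numeric phenotype values (\code{NA} = masked).
#' @return data.frame with character \code{gid}, \code{env} and numeric
#'   \code{value}; duplicated (gid, env) combinations are an error.
#' @export
phenotypeTable <- function(gid, env = NULL, value = NULL) {
  if (is.data.frame(gid)) {
    df <- gid
    if (!all(c("gid", "env", "value") %in% names(df))) {
      stop("phenotype data.frame must have columns gid, env, value")
    }
    gid <- df$gid; env <- df$env; value <- df$value
  }
  out <- data.frame(gid = as.character(gid), env = as.character(env),
                    value = as.numeric(value), stringsAsFactors = FALSE)
  if (anyDuplicated(out[, c("gid", "env")])) {
    stop("duplicated (gid, env) combinations in phenotype table")
  }
  out
}

#' Detect whether a phenotype table is balanced across environments
#'
#' A table is balanced when every genotype has a record in every environment
#' (masked \code{NA} values still count as present records: balance is about
#' the incidence structure, not about missingness introduced by prediction
#' scenarios). The summary reports per-environment record counts and the
#' genotype-overlap matrix between environment pairs.
#'
#' @param phenotypes a phenotype table (see \code{\link{phenotypeTable}}).
#' @return List with \code{balanced} (logical), \code{envCounts} (named
#'   integer), \code{overlap} (m x m matrix of shared-genotype counts, whose
#'   diagonal is the per-environment counts) and \code{nGenotypes}.
#' @export
detectBalance <- function(phenotypes) {
  phenotypes <- phenotypeTable(phenotypes)
  envs <- unique(phenotypes$env)
  m <- length(envs)
  if (m < 2L) stop("need at least 2 environments (use fitSingleEnv otherwise)")
  gids <- unique(phenotypes$gid)
  inc <- table(factor(phenotypes$gid, levels = gids),
               factor(phenotypes$env, levels = envs)) > 0L
  overlap <- crossprod(inc)
  storage.mode(overlap) <- "integer"
  list(balanced = all(inc),
       envCounts = stats::setNames(as.integer(diag(overlap)), envs),
       overlap = unclass(overlap),
       nGenotypes = length(gids))
}

#' Hadamard-form covariance for unbalanced multi-environment records
#'
#' Builds the N x N covariance \code{(Z1 K Z1') o (Z2 E Z2')} over phenotype
#' records, where Z1 and Z2 are the incidence matrices relating records to
#' genotypes and environments, K is a relationship kernel and E an m x m
#' environment covariance; \code{o} is the Hadamard (elementwise) product.
#' Entrywise this is \code{K[gid_i, gid_j] * E[env_i, env_j]}. For complete
#' balanced incidence with records sorted by (environment, genotype) and
#' \code{E = U}, the result equals the Kronecker covariance \code{U \%x\% K}.
#'
#' @param kernel a \linkS4class{RelationshipKernel} covering every genotype
#'   in the table.
#' @param phenotypes a phenotype table defining the records (order is
#'   preserved).
#' @param E m x m environment covariance matrix with environment-id dimnames.
#' @return N x N numeric covariance matrix over the records.
#' @export
buildHadamardCovariance <- function(kernel, phenotypes, E) {
  stopifnot(is(kernel, "RelationshipKernel"))
  phenotypes <- phenotypeTable(phenotypes)
  E <- as.matrix(E)
  envs <- unique(phenotypes$env)
  if (is.null(rownames(E))) {
    if (nrow(E) != length(envs)) stop("E dimension does not match environments")
    dimnames(E) <- list(envs, envs)
  }
  if (!all(envs %in% rownames(E))) {
    stop("environment id(s) absent from E")
  }
  gIdx <- match(phenotypes$gid, genotypeIds(kernel))
  if (anyNA(gIdx)) stop("genotype id(s) absent from kernel")
  eIdx <- match(phenotypes$env, rownames(E))
  kernelMatrix(kernel)[gIdx, gIdx] * E[eIdx, eIdx]
}

#' Estimate the environment covariance matrix from phenotypes
#'
#' Pairwise Pearson correlations of phenotypes over the genotypes shared by
#' each environment pair, shrunk toward compound symmetry:
#' \code{E = (1 - shrink) * Ehat + shrink * (rbar J + (1 - rbar) I)}, where
#' \code{rbar} is the mean off-diagonal of the raw estimate. Pairs with fewer
#' than 3 shared genotypes get the mean off-diagonal value (with a warning).
#' The result is eigen-clipped to PSD if needed.
#'
#' @param phenotypes a phenotype table spanning at least 2 environments.
#' @param shrink shrinkage weight in [0, 1]; \code{1} returns the exact
#'   compound-symmetry matrix.
#' @return m x m PSD matrix with unit diagonal and environment-id dimnames.
#' @export
estimateE <- function(phenotypes, shrink = 0.5) {
  stopifnot(shrink >= 0, shrink <= 1)
  phenotypes <- phenotypeTable(phenotypes)
  envs <- unique(phenotypes$env)
  m <- length(envs)
  if (m < 2L) stop("need at least 2 environments")
  gids <- unique(phenotypes$gid)
  wide <- matrix(NA_real_, length(gids), m, dimnames = list(gids, envs))
  wide[cbind(match(phenotypes$gid, gids), match(phenotypes$env, envs))] <-
    phenotypes$value
  Ehat <- diag(m)
  dimnames(Ehat) <- list(envs, envs)
  shortPairs <- 0L
  for (i in seq_len(m - 1L)) {
    for (j in seq((i + 1L), m)) {
      ok <- stats::complete.cases(wide[, c(i, j)])
      if (sum(ok) >= 3L) {
        r <- stats::cor(wide[ok, i], wide[ok, j])
        if (is.na(r)) r <- NA_real_
        Ehat[i, j] <- Ehat[j, i] <- r
      } else {
        shortPairs <- shortPairs + 1L
        Ehat[i, j] <- Ehat[j, i] <- NA_real_
      }
    }
  }
  off <- Ehat[upper.tri(Ehat)]
  rbar <- mean(off, na.rm = TRUE)
  if (!is.finite(rbar)) rbar <- 0
  if (anyNA(off)) {
    warning(sprintf("%d environment pair(s) with insufficient overlap; using mean off-diagonal", shortPairs))
    Ehat[is.na(Ehat)] <- rbar
  }
  cs <- matrix(rbar, m, m)
  diag(cs) <- 1
  E <- (1 - shrink) * Ehat + shrink * cs
  ev <- eigen(.symm(E), symmetric = TRUE)
  if (min(ev$values) < 0) {
    E <- ev$vectors %*% (pmax(ev$values, 0) * t(ev$vectors))
    E <- .symm(E)
  }
  dimnames(E) <- list(envs, envs)
  E
}

#' Fit a Bayesian multi-environment multi-kernel mixed model
#'
#' Fits the genotype-by-environment model sequence M1-M5. With balanced data
#' (every genotype recorded in every environment) the model treats
#' environments as traits: each kernel k contributes effects with covariance
#' \code{U_k \%x\% K_k}, where \code{U_k} is an unstructured m x m
#' environment covariance updated from its inverse-Wishart full conditional,
#' and the residual rows have unstructured covariance \code{R}. With
#' unbalanced data each kernel contributes a single variance
#' \code{sigma2_k} on the Hadamard covariance
#' \code{(Z1 K_k Z1') o (Z2 E Z2')} over records, with a homogeneous
#' residual; the environment covariance \code{E} defaults to
#' \code{\link{estimateE}} on the observed records (shrink 0.5) and can be
#' overridden. Masked cells (records with \code{NA} value) are imputed by
#' data augmentation in both modes, giving predictions for them.
#'
#' Inverse-Wishart priors use df = m + 2 and scale
#' \code{priorR2 * diag(var(y_j)) * (df - m - 1) / K} for each kernel (prior
#' mean equals the scale at this df), mirroring the single-environment prior
#' partition; the unbalanced mode uses the same scaled-inverse-chi-square
#' priors as \code{\link{fitSingleEnv}}.
#'
#' @param phenotypes a phenotype table (see \code{\link{phenotypeTable}});
#'   records are sorted internally by (environment, genotype).
#' @param kernels named list of \linkS4class{RelationshipKernel}s covering
#'   the genotypes of the table.
#' @param mode \code{"auto"} (balanced Kronecker iff the incidence is
#'   complete), \code{"balanced_kron"} or \code{"unbalanced_hadamard"}.
#' @param E optional m x m environment covariance for the Hadamard mode.
#' @param nIter,burnIn,thin,seed MCMC settings as in
#'   \code{\link{fitSingleEnv}}.
#' @param priorDf,priorR2 prior settings (scalar-variance components).
#' @param repair kernel PSD repair policy.
#' @param keepSamples keep thinned chains.
#' @return A \linkS4class{MultiEnvFit}.
#' @export
fitMultiEnv <- function(phenotypes, kernels,
                        mode = c("auto", "balanced_kron",
                                 "unbalanced_hadamard"),
                        E = NULL, nIter = 50000L, burnIn = 5000L, thin = 5L,
                        seed = NULL, priorDf = 5, priorR2 = 0.5,
                        repair = c("eigen_clip", "jitter", "none"),
                        keepSamples = TRUE) {
  mode <- match.arg(mode)
  repair <- match.arg(repair)
  phenotypes <- phenotypeTable(phenotypes)
  envs <- sort(unique(phenotypes$env))
  m <- length(envs)
  # single-environment data is allowed only in Hadamard mode (reduction check)
  if (m >= 2L) {
    bal <- detectBalance(phenotypes)
    if (mode == "auto") {
      mode <- if (bal$balanced) "balanced_kron" else "unbalanced_hadamard"
    } else if (mode == "balanced_kron" && !bal$balanced) {
      stop("balanced_kron mode requires complete genotype x environment incidence")
    }
  } else {
    if (mode == "balanced_kron") {
      stop("balanced_kron mode needs at least 2 environments")
    }
    mode <- "unbalanced_hadamard"
  }
  ord <- order(phenotypes$env, phenotypes$gid)
  phenotypes <- phenotypes[ord, , drop = FALSE]
  rownames(phenotypes) <- NULL
  if (is.null(names(kernels))) {
    names(kernels) <- vapply(kernels, kernelKind, character(1L))
  }
  usedIds <- unique(phenotypes$gid)
  aligned <- alignKernels(kernels, ids = usedIds)
  if (!all(usedIds %in% aligned$ids)) {
    stop("phenotype genotype id(s) absent from kernels")
  }
  kernels <- aligned$kernels
  if (repair != "none") {
    kernels <- lapply(kernels, validateKernel, repair = repair)
  }
  if (mode == "balanced_kron") {
    .fitMultiBalanced(phenotypes, kernels, envs, nIter, burnIn, thin, seed,
                      priorR2, keepSamples)
  } else {
    if (is.null(E)) {
      obsTab <- phenotypes[!is.na(phenotypes$value), , drop = FALSE]
      E <- if (m >= 2L) {
        message("fitMultiEnv: environment covariance E estimated from observed records (shrink = 0.5)")
        estimateE(obsTab, shrink = 0.5)
      } else {
        matrix(1, 1L, 1L, dimnames = list(envs, envs))
      }
    }
    .fitMultiHadamard(phenotypes, kernels, envs, E, nIter, burnIn, thin,
                      seed, priorDf, priorR2, keepSamples)
  }
}

# Balanced multi-trait sampler: environments as traits, U_k %x% K_k genetic
# covariances, unstructured residual R.
.fitMultiBalanced <- function(phenotypes, kernels, envs, nIter, burnIn, thin,
                              seed, priorR2, keepSamples) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  m <- length(envs)
  ids <- sort(unique(phenotypes$gid))
  n <- length(ids)
  K <- length(kernels)
  kn <- names(kernels)
  # records sorted (env, gid) => matrix fill is column-major by environment
  Y <- matrix(phenotypes$value, n, m,
              dimnames = list(ids, envs))
  stopifnot(identical(phenotypes$gid, rep(ids, m)))
  obsM <- !is.na(Y)
  colVar <- apply(Y, 2L, stats::var, na.rm = TRUE)
  colVar[!is.finite(colVar) | colVar == 0] <- 1e-6

  # kernel rows must follow Y's (sorted) genotype order, not the kernels' own
  decomp <- lapply(kernels, function(k) {
    .kernelEigen(kernelMatrix(k)[ids, ids])
  })
  df0 <- m + 2
  S0 <- lapply(seq_len(K), function(k) {
    diag(priorR2 * colVar * (df0 - m - 1) / K, m)
  })
  S0r <- diag((1 - priorR2) * colVar * (df0 - m - 1), m)
  U <- S0
  R <- S0r
  mu <- colMeans(Y, na.rm = TRUE)
  Ycur <- Y
  Ycur[!obsM] <- rep(mu, each = n)[!obsM]
  Glist <- rep(list(matrix(0, n, m)), K)
  Eta <- matrix(0, n, m)

  # group genotypes by missingness pattern once (pattern over environments)
  missRows <- which(rowSums(!obsM) > 0L)
  patterns <- list()
  if (length(missRows)) {
    key <- apply(!obsM[missRows, , drop = FALSE], 1L, paste, collapse = "")
    patterns <- split(missRows, key)
  }

  nSaved <- (nIter - burnIn) %/% thin
  if (nSaved < 1L) stop("no retained samples; check nIter/burnIn/thin")
  effSum <- rep(list(matrix(0, n, m)), K)
  muChain <- matrix(NA_real_, nSaved, m, dimnames = list(NULL, envs))
  Usum <- rep(list(matrix(0, m, m)), K)
  Rsum <- matrix(0, m, m)
  diagChain <- matrix(NA_real_, nSaved, (K + 1L) * m)
  colnames(diagChain) <- c(t(outer(c(kn, "residual"), envs, paste, sep = ":")))
  save <- 0L

  for (it in seq_len(nIter)) {
    store <- it > burnIn && (it - burnIn) %% thin == 0L
    if (store) save <- save + 1L
    L <- t(chol(.symm(R)))
    Linv <- forwardsolve(L, diag(m))
    for (k in seq_len(K)) {
      Q <- decomp[[k]]$Q
      lam <- decomp[[k]]$lambda
      q <- length(lam)
      W <- Ycur - rep(mu, each = n) - Eta + Glist[[k]]
      Wt <- crossprod(Q, W)                        # q x m
      B <- .symm(Linv %*% U[[k]] %*% t(Linv))
      eb <- eigen(B, symmetric = TRUE)
      d <- pmax(eb$values, 0)
      Tm <- L %*% eb$vectors                       # T = L V
      Tinv <- t(eb$vectors) %*% Linv
      Ws <- Wt %*% t(Tinv)                         # rotated observations
      ld <- outer(lam, d)
      v <- ld / (1 + ld)
      Mz <- v * Ws
      Z <- Mz + sqrt(v) * matrix(stats::rnorm(q * m), q, m)
      Gt <- Z %*% t(Tm)
      Gnew <- Q %*% Gt
      Eta <- Eta - Glist[[k]] + Gnew
      Glist[[k]] <- Gnew
      if (store) effSum[[k]] <- effSum[[k]] + Q %*% (Mz %*% t(Tm))
      Sg <- crossprod(Gt, Gt / lam)
      U[[k]] <- .rInvWishart(df0 + q, .symm(S0[[k]] + Sg))
    }
    W0 <- Ycur - Eta
    muMean <- colMeans(W0)
    mu <- muMean + as.numeric(t(chol(.symm(R))) %*% stats::rnorm(m)) / sqrt(n)
    Eres <- Ycur - rep(mu, each = n) - Eta
    R <- .rInvWishart(df0 + n, .symm(S0r + crossprod(Eres)))
    if (length(patterns)) {
      M <- rep(mu, each = n) + Eta
      for (rows in patterns) {
        missEnv <- !obsM[rows[1L], ]
        Roo <- R[!missEnv, !missEnv, drop = FALSE]
        Rmo <- R[missEnv, !missEnv, drop = FALSE]
        Rmm <- R[missEnv, missEnv, drop = FALSE]
        if (any(!missEnv)) {
          A <- Rmo %*% solve(Roo)
          condCov <- .symm(Rmm - A %*% t(Rmo))
          resid <- Ycur[rows, !missEnv, drop = FALSE] -
            M[rows, !missEnv, drop = FALSE]
          condMean <- M[rows, missEnv, drop = FALSE] + resid %*% t(A)
        } else {
          condCov <- Rmm
          condMean <- M[rows, missEnv, drop = FALSE]
        }
        Lc <- t(chol(condCov + 1e-12 * diag(nrow(condCov))))
        noise <- matrix(stats::rnorm(length(rows) * nrow(Lc)),
                        length(rows)) %*% t(Lc)
        Ycur[rows, missEnv] <- condMean + noise
      }
    }
    if (store) {
      muChain[save, ] <- mu
      for (k in seq_len(K)) Usum[[k]] <- Usum[[k]] + U[[k]]
      Rsum <- Rsum + R
      diagChain[save, ] <- c(vapply(U, diag, numeric(m)), diag(R))
    }
  }

  effMean <- lapply(effSum, function(s) s / nSaved)
  Umean <- lapply(Usum, function(s) s / nSaved)
  names(Umean) <- kn
  Rmean <- Rsum / nSaved
  dimnames(Rmean) <- list(envs, envs)
  for (k in seq_len(K)) dimnames(Umean[[k]]) <- list(envs, envs)

  muPost <- data.frame(env = envs, mean = colMeans(muChain),
                       sd = apply(muChain, 2L, stats::sd),
                       stringsAsFactors = FALSE, row.names = NULL)
  vcPost <- data.frame(
    component = colnames(diagChain),
    mean = colMeans(diagChain),
    sd = apply(diagChain, 2L, stats::sd),
    mcse = apply(diagChain, 2L, .batchMcse),
    row.names = NULL, stringsAsFactors = FALSE
  )
  # flatten effects/yhat back to record order (env, gid)
  effRec <- vapply(effMean, function(Ek) as.numeric(Ek), numeric(n * m))
  colnames(effRec) <- kn
  muRec <- rep(muPost$mean, each = n)
  yhat <- muRec + rowSums(effRec)
  out <- phenotypes
  out$observed <- !is.na(out$value)
  new("MultiEnvFit",
      phenotypes = out, kernelNames = kn, mode = "balanced_kron",
      muPosterior = muPost,
      envCovPosterior = c(Umean, list(R = Rmean)),
      varcompPosterior = vcPost,
      effectsPosterior = effRec,
      yhat = as.numeric(yhat),
      samples = if (keepSamples) {
        list(mu = muChain, diag = diagChain)
      } else list(),
      mcmc = c(nIter = nIter, burnIn = burnIn, thin = thin,
               seed = if (is.null(seed)) NA_real_ else seed,
               nSaved = nSaved))
}

# Unbalanced Hadamard sampler: scalar variance per kernel on record-level
# covariances, per-environment intercepts, homogeneous residual.
.fitMultiHadamard <- function(phenotypes, kernels, envs, E, nIter, burnIn,
                              thin, seed, priorDf, priorR2, keepSamples) {
  m <- length(envs)
  E <- as.matrix(E)
  if (is.null(rownames(E))) dimnames(E) <- list(envs, envs)
  if (!all(envs %in% rownames(E))) stop("environment id(s) absent from E")
  N <- nrow(phenotypes)
  K <- length(kernels)
  kn <- names(kernels)
  omegaDecomp <- lapply(kernels, function(k) {
    .kernelEigen(buildHadamardCovariance(k, phenotypes, E))
  })
  envIdx <- match(phenotypes$env, envs)
  y <- phenotypes$value
  obs <- !is.na(y)
  if (sum(obs) < 2L) stop("need at least 2 observed phenotypes")

  if (!is.null(seed)) set.seed(as.integer(seed))
  vy <- stats::var(y[obs])
  if (!is.finite(vy) || vy == 0) vy <- 1e-6
  s0g <- priorR2 * vy / K * (priorDf + 2) / priorDf
  s0e <- (1 - priorR2) * vy * (priorDf + 2) / priorDf
  sigma2 <- rep(priorDf * s0g / (priorDf + 2), K)
  sigma2e <- priorDf * s0e / (priorDf + 2)
  mu <- tapply(y[obs], phenotypes$env[obs], mean)[envs]
  mu[is.na(mu)] <- mean(y[obs])
  yCur <- y
  yCur[!obs] <- mu[envIdx[!obs]]
  gList <- rep(list(numeric(N)), K)
  eta <- numeric(N)
  nEnv <- tabulate(envIdx, m)

  nSaved <- (nIter - burnIn) %/% thin
  if (nSaved < 1L) stop("no retained samples; check nIter/burnIn/thin")
  effSum <- matrix(0, N, K)
  muChain <- matrix(NA_real_, nSaved, m, dimnames = list(NULL, envs))
  vcChain <- matrix(NA_real_, nSaved, K + 1L,
                    dimnames = list(NULL, c(kn, "residual")))
  save <- 0L
  nMiss <- sum(!obs)

  for (it in seq_len(nIter)) {
    store <- it > burnIn && (it - burnIn) %% thin == 0L
    if (store) save <- save + 1L
    muRec <- mu[envIdx]
    for (k in seq_len(K)) {
      Q <- omegaDecomp[[k]]$Q
      lam <- omegaDecomp[[k]]$lambda
      q <- length(lam)
      e <- yCur - muRec - eta + gList[[k]]
      ytil <- crossprod(Q, e)
      slam <- sigma2[k] * lam
      v <- sigma2e * slam / (slam + sigma2e)
      mcond <- v * ytil / sigma2e
      u <- mcond + sqrt(v) * stats::rnorm(q)
      gNew <- as.numeric(Q %*% u)
      eta <- eta - gList[[k]] + gNew
      gList[[k]] <- gNew
      if (store) effSum[, k] <- effSum[, k] + as.numeric(Q %*% mcond)
      ss <- sum(u^2 / lam)
      sigma2[k] <- (priorDf * s0g + ss) / stats::rchisq(1L, priorDf + q)
    }
    r <- yCur - eta
    rMean <- tapply(r, envIdx, mean)
    mu <- stats::rnorm(m, rMean, sqrt(sigma2e / nEnv))
    names(mu) <- envs
    eps <- yCur - mu[envIdx] - eta
    sigma2e <- (priorDf * s0e + sum(eps^2)) / stats::rchisq(1L, priorDf + N)
    if (nMiss > 0L) {
      yCur[!obs] <- mu[envIdx[!obs]] + eta[!obs] +
        stats::rnorm(nMiss, 0, sqrt(sigma2e))
    }
    if (store) {
      muChain[save, ] <- mu
      vcChain[save, ] <- c(sigma2, sigma2e)
    }
  }

  effects <- effSum / nSaved
  colnames(effects) <- kn
  muPost <- data.frame(env = envs, mean = colMeans(muChain),
                       sd = apply(muChain, 2L, stats::sd),
                       stringsAsFactors = FALSE, row.names = NULL)
  vcPost <- data.frame(
    component = colnames(vcChain),
    mean = colMeans(vcChain),
    sd = apply(vcChain, 2L, stats::sd),
    mcse = apply(vcChain, 2L, .batchMcse),
    ess = apply(vcChain, 2L, .effectiveSize),
    rhat = apply(vcChain, 2L, .splitRhat),
    row.names = NULL, stringsAsFactors = FALSE
  )
  out <- phenotypes
  out$observed <- obs
  yhat <- muPost$mean[match(phenotypes$env, envs)] + rowSums(effects)
  new("MultiEnvFit",
      phenotypes = out, kernelNames = kn, mode = "unbalanced_hadamard",
      muPosterior = muPost,
      envCovPosterior = list(E = E),
      varcompPosterior = vcPost,
      effectsPosterior = effects,
      yhat = as.numeric(yhat),
      samples = if (keepSamples) {
        list(mu = muChain, varcomp = vcChain)
      } else list(),
      mcmc = c(nIter = nIter, burnIn = burnIn, thin = thin,
               seed = if (is.null(seed)) NA_real_ else seed,
               nSaved = nSaved))
}

#' Predictions from a multi-environment fit
#'
#' @param fit a \linkS4class{MultiEnvFit}.
#' @param gid,env optional vectors selecting records; default all records.
#' @return data.frame of records with a \code{yhat} column.
#' @export
predictMultiEnv <- function(fit, gid = NULL, env = NULL) {
  stopifnot(is(fit, "MultiEnvFit"))
  out <- fit@phenotypes
  out$yhat <- fit@yhat
  if (!is.null(gid)) out <- out[out$gid %in% gid, , drop = FALSE]
  if (!is.null(env)) out <- out[out$env %in% env, , drop = FALSE]
  out
}
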