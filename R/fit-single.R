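#' Fit a Bayesian single-environment multi-kernel mixed model
#'
#' Fits the model \code{y = 1*mu + sum_k g_k + eps} by Gibbs sampling, where
#' each genetic effect vector follows \code{g_k ~ N(0, sigma2_k K_k)} for a
#' relationship kernel \code{K_k} and \code{eps ~ N(0, sigma2_e I)}. The model
#' sequence S1-S5 corresponds to kernel sets \{A\}, \{G\}, \{K\}, \{A, K\}
#' and \{A, K, C, P\} (see \code{\link{singleEnvKernelSets}}).
#'
#' Each kernel is eigendecomposed once (\code{K_k = Q L Q'}, eigenvalues
#' below 1e-10 truncated with the corresponding coordinates fixed at zero)
#' and effects are sampled in the rotated basis, where the full conditionals
#' are diagonal; one iteration costs O(n^2) per kernel. Variance components
#' get scaled-inverse-chi-square priors with \code{priorDf} degrees of
#' freedom and scales set so the prior mode of each genetic variance is
#' \code{priorR2 * var(y) / K} and the residual prior mode is
#' \code{(1 - priorR2) * var(y)}; the intercept has a flat prior. Missing
#' phenotypes are treated as unknowns and imputed from their predictive
#' distribution each iteration (data augmentation), which yields predictions
#' for masked genotypes as a by-product.
#'
#' Posterior means of the effect vectors are Rao-Blackwellized: the average
#' of the per-iteration full-conditional means rather than of the draws. The
#' two estimators share the same expectation; the former has smaller Monte
#' Carlo error. \code{yhat} is the intercept mean plus the summed effect
#' means, so the additive decomposition holds exactly for every genotype.
#'
#' @param y numeric phenotype vector named by genotype id (or unnamed, in
#'   kernel order); \code{NA} marks masked/unobserved entries.
#' @param kernels named list of \linkS4class{RelationshipKernel}s aligned to
#'   \code{y} (same ids, same order; see \code{\link{alignKernels}}).
#' @param nIter,burnIn,thin MCMC settings; defaults 50000, 5000, 5.
#' @param seed integer seed for reproducible chains (optional).
#' @param priorDf prior degrees of freedom for every variance component.
#' @param priorR2 prior proportion of variance attributed to genetics,
#'   in (0, 1).
#' @param fixedVarcomp optional named numeric of variance components (one
#'   entry per kernel plus \code{"residual"}); when supplied they are held
#'   fixed and not resampled.
#' @param deterministic logical; with \code{fixedVarcomp}, replace every
#'   draw by its full-conditional mean (no noise). The chain then converges
#'   to the joint conditional mean, i.e. the closed-form mixed-model (BLUP)
#'   solution. Intended for verification.
#' @param standardizeY center and scale \code{y} internally (posterior
#'   summaries are returned on the standardized scale); default \code{FALSE}.
#' @param repair PSD repair policy applied to each kernel before fitting
#'   (see \code{\link{validateKernel}}); default \code{"eigen_clip"}, the
#'   nearest-PSD projection, which preserves kernel structure even when the
#'   hybrid kernels are strongly indefinite.
#' @param keepSamples keep thinned chains of the intercept and variance
#'   components in the result.
#' @return A \linkS4class{SingleEnvFit}.
#' @examples
#' set.seed(1)
#' K <- RelationshipKernel(diag(50) * 0.2 + 0.8 * tcrossprod(rnorm(50)) / 50)
#' y <- stats::setNames(rnorm(50), genotypeIds(K))
#' fit <- fitSingleEnv(y, list(K = K), nIter = 600, burnIn = 100, seed = 1)
#' @export
fitSingleEnv <- function(y, kernels, nIter = 50000L, burnIn = 5000L,
                         thin = 5L, seed = NULL, priorDf = 5,
                         priorR2 = 0.5, fixedVarcomp = NULL,
                         deterministic = FALSE, standardizeY = FALSE,
                         repair = c("eigen_clip", "jitter", "none"),
                         keepSamples = TRUE) {
  repair <- match.arg(repair)
  stopifnot(is.list(kernels), length(kernels) >= 1L,
            burnIn < nIter, thin >= 1L, priorDf > 0,
            priorR2 > 0, priorR2 < 1)
  if (deterministic && is.null(fixedVarcomp)) {
    stop("deterministic mode requires fixedVarcomp")
  }
  ids <- genotypeIds(kernels[[1L]])
  n <- length(ids)
  if (is.null(names(y))) {
    if (length(y) != n) stop("unnamed y must match kernel dimension")
    names(y) <- ids
  }
  if (!all(ids %in% names(y)) || length(y) != n) {
    stop("y and kernels are mis-aligned; use alignKernels()")
  }
  y <- y[ids]
  for (k in kernels) {
    if (!identical(genotypeIds(k), ids)) {
      stop("all kernels must share one id order; use alignKernels()")
    }
  }
  if (is.null(names(kernels))) {
    names(kernels) <- vapply(kernels, kernelKind, character(1L))
  }
  obs <- !is.na(y)
  if (sum(obs) < 2L) stop("need at least 2 observed phenotypes")

  yFit <- as.numeric(y)
  scaleInfo <- NULL
  if (standardizeY) {
    ctr <- mean(yFit[obs]); scl <- stats::sd(yFit[obs])
    if (scl == 0) stop("cannot standardize a constant phenotype vector")
    yFit <- (yFit - ctr) / scl
    scaleInfo <- c(center = ctr, scale = scl)
  }

  decomp <- .prepareDecomp(kernels, repair)
  sampler <- .gibbsSingle(
    y = yFit, obs = obs, decomp = decomp, nIter = as.integer(nIter),
    burnIn = as.integer(burnIn), thin = as.integer(thin), seed = seed,
    priorDf = priorDf, priorR2 = priorR2, fixedVarcomp = fixedVarcomp,
    deterministic = deterministic, keepSamples = keepSamples
  )

  vc <- sampler$varcompSummary
  new("SingleEnvFit",
      ids = ids,
      kernelNames = names(kernels),
      muPosterior = c(mean = sampler$muMean, sd = sampler$muSd),
      varcompPosterior = vc,
      effectsPosterior = sampler$effects,
      yhat = sampler$muMean + rowSums(sampler$effects),
      observed = obs,
      samples = sampler$samples,
      mcmc = c(nIter = nIter, burnIn = burnIn, thin = thin,
               seed = if (is.null(seed)) NA_real_ else seed,
               nSaved = sampler$nSaved))
}

# Validate/repair kernels and eigendecompose each once.
.prepareDecomp <- function(kernels, repair) {
  lapply(kernels, function(k) {
    if (repair != "none") k <- validateKernel(k, repair = repair)
    rep <- attr(k, "validity")
    if (!is.null(rep) && !rep$psd) stop("kernel remains non-PSD after repair")
    .kernelEigen(kernelMatrix(k))
  })
}

# Core Gibbs sampler on prepared eigendecompositions. Internal; reused by the
# cross-validation driver with precomputed decompositions.
.gibbsSingle <- function(y, obs, decomp, nIter, burnIn, thin, seed,
                         priorDf, priorR2, fixedVarcomp, deterministic,
                         keepSamples) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- length(y)
  K <- length(decomp)
  kn <- names(decomp)
  vy <- stats::var(y[obs])
  if (!is.finite(vy) || vy == 0) vy <- 1e-6  # constant y: fall back to prior
  s0g <- priorR2 * vy / K * (priorDf + 2) / priorDf
  s0e <- (1 - priorR2) * vy * (priorDf + 2) / priorDf

  fixed <- !is.null(fixedVarcomp)
  if (fixed) {
    need <- c(kn, "residual")
    if (!all(need %in% names(fixedVarcomp))) {
      stop("fixedVarcomp must name every kernel plus 'residual'")
    }
    sigma2 <- as.numeric(fixedVarcomp[kn])
    sigma2e <- as.numeric(fixedVarcomp[["residual"]])
  } else {
    sigma2 <- rep(priorDf * s0g / (priorDf + 2), K)
    sigma2e <- priorDf * s0e / (priorDf + 2)
  }

  yCur <- y
  mu <- mean(y[obs])
  yCur[!obs] <- mu
  gList <- vector("list", K)
  for (k in seq_len(K)) gList[[k]] <- numeric(n)
  eta <- numeric(n)

  nSaved <- (nIter - burnIn) %/% thin
  if (nSaved < 1L) stop("no retained samples; check nIter/burnIn/thin")
  effSum <- matrix(0, n, K)
  muChain <- numeric(nSaved)
  vcChain <- matrix(NA_real_, nSaved, K + 1L,
                    dimnames = list(NULL, c(kn, "residual")))
  save <- 0L
  nMiss <- sum(!obs)

  for (it in seq_len(nIter)) {
    store <- it > burnIn && (it - burnIn) %% thin == 0L
    if (store) save <- save + 1L
    for (k in seq_len(K)) {
      Q <- decomp[[k]]$Q
      lam <- decomp[[k]]$lambda
      q <- length(lam)
      e <- yCur - mu - eta + gList[[k]]
      ytil <- crossprod(Q, e)
      slam <- sigma2[k] * lam
      v <- sigma2e * slam / (slam + sigma2e)
      m <- v * ytil / sigma2e
      u <- if (deterministic) m else m + sqrt(v) * stats::rnorm(q)
      gNew <- as.numeric(Q %*% u)
      eta <- eta - gList[[k]] + gNew
      gList[[k]] <- gNew
      if (store) effSum[, k] <- effSum[, k] + as.numeric(Q %*% m)
      if (!fixed) {
        ss <- sum(u^2 / lam)
        sigma2[k] <- (priorDf * s0g + ss) / stats::rchisq(1L, priorDf + q)
      }
    }
    r <- yCur - eta
    mu <- if (deterministic) mean(r) else
      stats::rnorm(1L, mean(r), sqrt(sigma2e / n))
    if (!fixed) {
      eps <- yCur - mu - eta
      sigma2e <- (priorDf * s0e + sum(eps^2)) /
        stats::rchisq(1L, priorDf + n)
    }
    if (nMiss > 0L) {
      pm <- mu + eta[!obs]
      yCur[!obs] <- if (deterministic) pm else
        pm + stats::rnorm(nMiss, 0, sqrt(sigma2e))
    }
    if (store) {
      muChain[save] <- mu
      vcChain[save, ] <- c(sigma2, sigma2e)
    }
  }

  effects <- effSum / nSaved
  colnames(effects) <- kn
  vcSummary <- data.frame(
    component = c(kn, "residual"),
    mean = colMeans(vcChain),
    sd = apply(vcChain, 2L, stats::sd),
    mcse = apply(vcChain, 2L, .batchMcse),
    ess = apply(vcChain, 2L, .effectiveSize),
    rhat = apply(vcChain, 2L, .splitRhat),
    row.names = NULL, stringsAsFactors = FALSE
  )
  list(
    muMean = mean(muChain), muSd = stats::sd(muChain),
    varcompSummary = vcSummary, effects = effects, nSaved = nSaved,
    samples = if (keepSamples) list(mu = muChain, varcomp = vcChain) else list()
  )
}

#' Predict phenotypes for selected genotypes
#'
#' Returns the posterior-mean prediction \code{yhat} (intercept plus summed
#' genetic effects) for the requested genotypes, whether they were observed
#' during fitting or masked (in which case the value is the model's
#' prediction for the held-out genotype).
#'
#' @param fit a \linkS4class{SingleEnvFit}.
#' @param targetIds genotype ids to predict; default all.
#' @return Named numeric vector of predictions.
#' @export
predictSingleEnv <- function(fit, targetIds = NULL) {
  stopifnot(is(fit, "SingleEnvFit"))
  yhat <- stats::setNames(fit@yhat, fit@ids)
  if (is.null(targetIds)) return(yhat)
  missing <- setdiff(targetIds, fit@ids)
  if (length(missing)) {
    stop(sprintf("unknown genotype id(s): %s",
                 paste(utils::head(missing, 5L), collapse = ", ")))
  }
  yhat[targetIds]
}

#' Correlations among posterior-mean effect vectors
#'
#' Pairwise Pearson correlations among the posterior-mean genetic effect
#' vectors of a multi-kernel fit (e.g. g_A, g_K, g_C, g_P of model S5). Low
#' off-diagonal correlations indicate that the kernels capture complementary,
#' non-duplicated genetic signal. A constant effect vector has no defined
#' correlation and yields \code{NA} entries (with a warning). Entering the
#' same kernel twice makes the two effects non-identifiable; the computed
#' value is reported as-is with a caveat message.
#'
#' @param fit a \linkS4class{SingleEnvFit} with at least two kernels.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
effectVectorCorrelations <- function(fit) {
  stopifnot(is(fit, "SingleEnvFit"))
  E <- fit@effectsPosterior
  if (ncol(E) < 2L) stop("need a fit with at least 2 kernels")
  if (anyDuplicated(fit@kernelNames)) {
    message("duplicated kernel names: effect split is not identifiable; ",
            "reporting computed correlations as-is")
  }
  sds <- .colSds(E)
  const <- sds < .Machine$double.eps^0.5
  if (any(const)) {
    warning(sprintf("constant effect vector(s): %s; correlations set to NA",
                    paste(colnames(E)[const], collapse = ", ")))
  }
  R <- suppressWarnings(stats::cor(E))
  R[const, ] <- NA_real_
  R[, const] <- NA_real_
  diag(R) <- 1
  R
}

#' Kernel sets of the single-environment model sequence
#'
#' @return Named list mapping model ids S1-S5 to their kernel kinds:
#'   S1 = \{A\}, S2 = \{G\}, S3 = \{K\}, S4 = \{A, K\},
#'   S5 = \{A, K, C, P\}.
#' @export
singleEnvKernelSets <- function() {
  list(S1 = "A", S2 = "G", S3 = "K", S4 = c("A", "K"),
       S5 = c("A", "K", "C", "P"))
}

#' Kernel sets of the multi-environment model sequence
#'
#' @return Named list mapping model ids M1-M5 to their kernel kinds
#'   (same sets as S1-S5).
#' @export
multiEnvKernelSets <- function() {
  stats::setNames(singleEnvKernelSets(), c("M1", "M2", "M3", "M4", "M5"))
}
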