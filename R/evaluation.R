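#' Repeated k-fold cross-validation scheme
#'
#' Per replicate, a random partition of \code{n} observations into \code{k}
#' near-equal folds (sizes differ by at most one; remainder observations are
#' distributed one per fold). The two designs used for single-environment
#' evaluation are k = 5 with 4 repeats and k = 2 with 10 repeats, each
#' yielding 20 training/testing combinations. Fold assignments depend only on
#' (n, k, repeats, seed), never on the model, so model comparisons on the
#' same scheme are paired.
#'
#' @param n number of observations.
#' @param k number of folds (2 <= k <= n).
#' @param repeats number of independent replicates.
#' @param seed integer seed.
#' @return List of class settings: \code{kind = "kfold"}, \code{n}, \code{k},
#'   \code{repeats}, \code{seed} and \code{folds}, a list of length
#'   \code{repeats} of integer fold-assignment vectors (values 1..k).
#' @export
makeKfoldScheme <- function(n, k, repeats, seed) {
  stopifnot(k >= 2L, repeats >= 1L)
  if (k > n) stop("k must not exceed n")
  set.seed(as.integer(seed))
  folds <- lapply(seq_len(repeats), function(r) {
    sizes <- rep(n %/% k, k)
    extra <- n %% k
    if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    sample(rep.int(seq_len(k), sizes))
  })
  list(kind = "kfold", n = n, k = as.integer(k),
       repeats = as.integer(repeats), seed = as.integer(seed),
       folds = folds)
}

#' Environment-masking prediction scheme
#'
#' Per replicate, a random subset of the target environment's records of size
#' \code{round(knownFraction * n_env)} is kept observed and the rest are
#' masked, while every other environment stays fully observed. The two
#' scenarios used for multi-environment evaluation keep 20% (predict 80%) or
#' 5% (predict 95%) of the target environment, with 10 random samples each.
#'
#' @param phenotypes a phenotype table.
#' @param targetEnv environment id to mask.
#' @param knownFraction fraction of the target environment kept observed,
#'   in (0, 1).
#' @param repeats number of random samples.
#' @param seed integer seed.
#' @return List: \code{kind = "env_mask"}, \code{targetEnv},
#'   \code{knownFraction}, \code{repeats}, \code{seed} and \code{maskedIds},
#'   a list per replicate of the genotype ids masked in the target
#'   environment.
#' @export
makeEnvMaskScheme <- function(phenotypes, targetEnv, knownFraction, repeats,
                              seed) {
  stopifnot(knownFraction > 0, knownFraction < 1, repeats >= 1L)
  phenotypes <- phenotypeTable(phenotypes)
  if (!targetEnv %in% phenotypes$env) {
    stop(sprintf("unknown environment '%s'", targetEnv))
  }
  envIds <- phenotypes$gid[phenotypes$env == targetEnv]
  nEnv <- length(envIds)
  nKnown <- round(knownFraction * nEnv)
  if (nKnown < 1L) stop("knownFraction leaves no observed records")
  set.seed(as.integer(seed))
  maskedIds <- lapply(seq_len(repeats), function(r) {
    known <- sample(envIds, nKnown)
    setdiff(envIds, known)
  })
  list(kind = "env_mask", targetEnv = targetEnv,
       knownFraction = knownFraction, repeats = as.integer(repeats),
       seed = as.integer(seed), nEnv = nEnv, nKnown = nKnown,
       maskedIds = maskedIds)
}

#' Pearson correlation between predictions and observations
#'
#' Sample Pearson correlation, the primary predictive-ability metric. A
#' constant input leaves the correlation undefined; \code{NA} is returned.
#'
#' @param pred,obs equal-length numeric vectors.
#' @return Correlation in [-1, 1], or \code{NA} if undefined.
#' @export
pearsonCor <- function(pred, obs) {
  stopifnot(length(pred) == length(obs))
  if (length(pred) < 3L) return(NA_real_)
  if (stats::sd(pred) == 0 || stats::sd(obs) == 0) return(NA_real_)
  stats::cor(pred, obs)
}

#' Predictive mean squared error
#'
#' Average of the squared prediction errors on a test set. Lower is better;
#' a higher predictive correlation is expected to pair with a lower PMSE.
#'
#' @param pred,obs equal-length numeric vectors.
#' @return Mean of \code{(pred - obs)^2}.
#' @export
pmse <- function(pred, obs) {
  stopifnot(length(pred) == length(obs))
  mean((pred - obs)^2)
}

#' Run a paired cross-validation experiment
#'
#' Evaluates a set of models under one scheme with identical fold/mask
#' assignments for every model (paired design). For a k-fold scheme the data
#' are a named single-environment phenotype vector plus kernels: per
#' replicate and fold, the test phenotypes are masked, the model is fitted
#' with the masked entries treated as unknowns, and Pearson correlation and
#' PMSE are recorded on the test set. For an environment-masking scheme the
#' data are a phenotype table: the masked cells of the target environment are
#' predicted with all other environments observed.
#'
#' Per-model kernel eigendecompositions are computed once and reused across
#' folds and replicates. Fit seeds are derived deterministically from the
#' scheme seed, so the whole experiment is bit-reproducible.
#'
#' @param data for \code{kfold}: named numeric phenotype vector; for
#'   \code{env_mask}: a phenotype table.
#' @param kernels named list of \linkS4class{RelationshipKernel}s (names are
#'   kernel kinds, e.g. \code{A}, \code{G}, \code{K}, \code{C}, \code{P}).
#' @param models named list mapping model ids to kernel-name subsets, e.g.
#'   \code{list(S2 = "G", S5 = c("A", "K", "C", "P"))}; see
#'   \code{\link{singleEnvKernelSets}}.
#' @param scheme a scheme from \code{\link{makeKfoldScheme}} or
#'   \code{\link{makeEnvMaskScheme}}.
#' @param nIter,burnIn,thin MCMC settings per fit.
#' @param priorDf,priorR2 prior settings.
#' @param mode multi-environment mode (env_mask schemes only).
#' @return List of class-free results: \code{records}, a data.frame with one
#'   row per (model, replicate, fold), columns \code{model},
#'   \code{replicate}, \code{fold}, \code{pearson}, \code{pmse},
#'   \code{nTest}; and \code{testIds}, the per-(replicate, fold) test sets
#'   (shared across models).
#' @export
runExperiment <- function(data, kernels, models, scheme,
                          nIter = 50000L, burnIn = 5000L, thin = 5L,
                          priorDf = 5, priorR2 = 0.5,
                          mode = c("auto", "balanced_kron",
                                   "unbalanced_hadamard")) {
  mode <- match.arg(mode)
  stopifnot(is.list(models), length(models) >= 1L,
            !is.null(names(models)))
  if (identical(scheme$kind, "kfold")) {
    .runKfoldExperiment(data, kernels, models, scheme, nIter, burnIn, thin,
                        priorDf, priorR2)
  } else if (identical(scheme$kind, "env_mask")) {
    .runEnvMaskExperiment(data, kernels, models, scheme, nIter, burnIn,
                          thin, priorDf, priorR2, mode)
  } else {
    stop("unknown scheme kind")
  }
}

.runKfoldExperiment <- function(y, kernels, models, scheme, nIter, burnIn,
                                thin, priorDf, priorR2) {
  aligned <- alignKernels(kernels, phenotypes = y)
  kernels <- aligned$kernels
  y <- aligned$phenotypes
  ids <- aligned$ids
  n <- length(ids)
  if (scheme$n != n) {
    stop(sprintf("scheme built for n = %d but data have n = %d",
                 scheme$n, n))
  }
  for (mk in models) {
    if (!all(mk %in% names(kernels))) {
      stop("model references kernels not supplied")
    }
  }
  decomps <- lapply(models, function(mk) {
    .prepareDecomp(kernels[mk], "eigen_clip")
  })
  rec <- list()
  testIds <- list()
  counter <- 0L
  for (r in seq_len(scheme$repeats)) {
    assign <- scheme$folds[[r]]
    for (f in seq_len(scheme$k)) {
      test <- which(assign == f)
      testIds[[sprintf("rep%d_fold%d", r, f)]] <- ids[test]
      yMask <- as.numeric(y)
      yMask[test] <- NA_real_
      obs <- !is.na(yMask)
      for (mId in names(models)) {
        counter <- counter + 1L
        fitSeed <- .streamSeed(scheme$seed, counter)
        s <- .gibbsSingle(
          y = yMask, obs = obs, decomp = decomps[[mId]],
          nIter = as.integer(nIter), burnIn = as.integer(burnIn),
          thin = as.integer(thin), seed = fitSeed,
          priorDf = priorDf, priorR2 = priorR2, fixedVarcomp = NULL,
          deterministic = FALSE, keepSamples = FALSE
        )
        yhat <- s$muMean + rowSums(s$effects)
        rec[[length(rec) + 1L]] <- data.frame(
          model = mId, replicate = r, fold = f,
          pearson = pearsonCor(yhat[test], as.numeric(y)[test]),
          pmse = pmse(yhat[test], as.numeric(y)[test]),
          nTest = length(test), stringsAsFactors = FALSE
        )
      }
    }
  }
  list(records = do.call(rbind, rec), testIds = testIds, scheme = scheme)
}

.runEnvMaskExperiment <- function(phenotypes, kernels, models, scheme,
                                  nIter, burnIn, thin, priorDf, priorR2,
                                  mode) {
  phenotypes <- phenotypeTable(phenotypes)
  rec <- list()
  testIds <- list()
  counter <- 0L
  for (r in seq_len(scheme$repeats)) {
    masked <- scheme$maskedIds[[r]]
    testIds[[sprintf("rep%d", r)]] <- masked
    pMask <- phenotypes
    inMask <- pMask$env == scheme$targetEnv & pMask$gid %in% masked
    truth <- phenotypes[inMask, , drop = FALSE]
    pMask$value[inMask] <- NA_real_
    for (mId in names(models)) {
      counter <- counter + 1L
      fitSeed <- .streamSeed(scheme$seed, counter)
      fit <- fitMultiEnv(pMask, kernels[models[[mId]]], mode = mode,
                         nIter = nIter, burnIn = burnIn, thin = thin,
                         seed = fitSeed, priorDf = priorDf,
                         priorR2 = priorR2, keepSamples = FALSE)
      pred <- predictMultiEnv(fit, gid = truth$gid, env = scheme$targetEnv)
      pred <- pred$yhat[match(truth$gid, pred$gid)]
      rec[[length(rec) + 1L]] <- data.frame(
        model = mId, env = scheme$targetEnv, replicate = r, fold = 1L,
        pearson = pearsonCor(pred, truth$value),
        pmse = pmse(pred, truth$value),
        nTest = nrow(truth), stringsAsFactors = FALSE
      )
    }
  }
  list(records = do.call(rbind, rec), testIds = testIds, scheme = scheme)
}

#' Aggregate cross-validation records
#'
#' Summarizes per-fold records into the reported quantities: AVG (mean of
#' per-fold Pearson correlations, raw, not Fisher-z transformed), SE (their
#' standard deviation divided by the square root of the fold count), the
#' 95% interval AVG +/- 1.96 SE, PMSE mean and sd, and, when a baseline
#' model is given, the percent difference
#' \code{100 * (AVG_model - AVG_baseline) / AVG_baseline}.
#'
#' @param results output of \code{\link{runExperiment}} (or its
#'   \code{records} data.frame).
#' @param baseline optional model id to compare against (e.g. \code{"S2"}).
#' @return data.frame with one row per model (and environment, if present).
#' @export
summarizeCV <- function(results, baseline = NULL) {
  records <- if (is.data.frame(results)) results else results$records
  hasEnv <- "env" %in% names(records)
  keyCols <- if (hasEnv) c("model", "env") else "model"
  keys <- unique(records[, keyCols, drop = FALSE])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- rep(TRUE, nrow(records))
    for (kc in keyCols) sel <- sel & records[[kc]] == keys[[kc]][i]
    sub <- records[sel, , drop = FALSE]
    if (nrow(sub) < 2L) {
      warning("fewer than 2 replicate records in a cell; SE unreliable")
    }
    avg <- mean(sub$pearson, na.rm = TRUE)
    se <- stats::sd(sub$pearson, na.rm = TRUE) / sqrt(sum(!is.na(sub$pearson)))
    cbind(keys[i, , drop = FALSE],
          data.frame(nFolds = nrow(sub), AVG = avg, SE = se,
                     lower95 = avg - 1.96 * se, upper95 = avg + 1.96 * se,
                     pmseMean = mean(sub$pmse, na.rm = TRUE),
                     pmseSd = stats::sd(sub$pmse, na.rm = TRUE)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(baseline)) {
    if (!baseline %in% out$model) stop("baseline model absent from records")
    if (hasEnv) {
      base <- out[out$model == baseline, c("env", "AVG")]
      out$pctDiff <- 100 * (out$AVG - base$AVG[match(out$env, base$env)]) /
        base$AVG[match(out$env, base$env)]
    } else {
      baseAvg <- out$AVG[out$model == baseline]
      out$pctDiff <- 100 * (out$AVG - baseAvg) / baseAvg
    }
  }
  out
}
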