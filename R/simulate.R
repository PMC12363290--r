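#' Simulation configuration
#'
#' Parameters of the synthetic-data generator. The defaults emulate an elite
#' yield trial (EYT) style wheat dataset: a few hundred related lines
#' genotyped at a few thousand SNP markers, evaluated in several
#' environments, with phenotypes generated from the multi-kernel models so
#' that every variance component is known. Default variance components
#' (A = 0.2, K = 0.45, C = 0.35, P = 0.27, residual = 0.22) sit in the range
#' typically estimated for standardized grain-yield BLUEs in such trials.
#'
#' @param nGenotypes total number of genotypes (founders + descendants).
#' @param nMarkers number of biallelic markers.
#' @param alleleFreqRange range from which per-marker allele frequencies are
#'   drawn uniformly.
#' @param nFounders number of unrelated founders in the simulated pedigree.
#' @param generations number of random-mating generations after the
#'   founders; 0 gives founders only (A = I).
#' @param varianceComponents named numeric of genetic variances, one per
#'   kernel kind to simulate from.
#' @param residual residual variance (single-environment models).
#' @param mEnvironments number of environments (multi-environment models).
#' @param envCor genetic correlation between environments used to build the
#'   default U matrices (compound symmetry).
#' @param residualEnvCor residual correlation between environments.
#' @param seed default seed for generation.
#' @return A list of class-free configuration values.
#' @export
simConfig <- function(nGenotypes = 600L, nMarkers = 2000L,
                      alleleFreqRange = c(0.1, 0.9), nFounders = 60L,
                      generations = 3L,
                      varianceComponents = c(A = 0.2, K = 0.45,
                                             C = 0.35, P = 0.27),
                      residual = 0.22, mEnvironments = 5L, envCor = 0.5,
                      residualEnvCor = 0, seed = 1L) {
  stopifnot(nGenotypes >= 2L, nMarkers >= 1L,
            length(alleleFreqRange) == 2L,
            all(alleleFreqRange > 0), all(alleleFreqRange < 1),
            alleleFreqRange[1L] <= alleleFreqRange[2L],
            nFounders >= 2L, generations >= 0L,
            all(varianceComponents >= 0), residual >= 0,
            mEnvironments >= 1L)
  list(nGenotypes = as.integer(nGenotypes),
       nMarkers = as.integer(nMarkers),
       alleleFreqRange = as.numeric(alleleFreqRange),
       nFounders = as.integer(nFounders),
       generations = as.integer(generations),
       varianceComponents = varianceComponents,
       residual = residual,
       mEnvironments = as.integer(mEnvironments),
       envCor = envCor, residualEnvCor = residualEnvCor,
       seed = as.integer(seed))
}

#' Simulate a random-mating pedigree
#'
#' Founders are unrelated; each subsequent generation is produced by random
#' mating of pairs drawn from the previous generation. The resulting
#' numerator relationship matrix (via \code{\link{pedigreeToA}}) is PSD with
#' unit founder diagonals.
#'
#' @param config a \code{\link{simConfig}}.
#' @param seed seed override (defaults to \code{config$seed}).
#' @return A \linkS4class{PedigreeTable} with \code{config$nGenotypes}
#'   individuals.
#' @export
simulatePedigree <- function(config = simConfig(), seed = config$seed) {
  set.seed(as.integer(seed))
  nF <- config$nFounders
  gens <- config$generations
  total <- config$nGenotypes
  if (gens == 0L) {
    ids <- sprintf("F%03d", seq_len(total))
    return(pedigreeTable(ids, rep(NA_character_, total),
                         rep(NA_character_, total)))
  }
  nOff <- total - nF
  perGen <- rep(nOff %/% gens, gens)
  extra <- nOff %% gens
  if (extra > 0L) perGen[seq_len(extra)] <- perGen[seq_len(extra)] + 1L
  id <- sprintf("F%03d", seq_len(nF))
  p1 <- rep(NA_character_, nF)
  p2 <- rep(NA_character_, nF)
  prev <- id
  for (g in seq_len(gens)) {
    kids <- sprintf("G%d_%03d", g, seq_len(perGen[g]))
    mates <- vapply(seq_len(perGen[g]), function(i) {
      sample(prev, 2L, replace = length(prev) < 2L)
    }, character(2L))
    id <- c(id, kids)
    p1 <- c(p1, mates[1L, ])
    p2 <- c(p2, mates[2L, ])
    prev <- kids
  }
  pedigreeTable(id, p1, p2)
}

#' Simulate a marker matrix
#'
#' Biallelic dosages in \{0, 1, 2\}. With a pedigree, founder genotypes are
#' drawn marker-wise as Binomial(2, freq) and descendants inherit one allele
#' per parent by gene dropping (each parent transmits an allele with
#' probability dosage/2, markers independent — no linkage). Without a
#' pedigree, all genotypes are drawn independently.
#'
#' @param config a \code{\link{simConfig}}.
#' @param pedigree optional \linkS4class{PedigreeTable} to gene-drop down.
#' @param seed seed override.
#' @return A \linkS4class{MarkerMatrix} of raw dosages.
#' @export
simulateMarkers <- function(config = simConfig(), pedigree = NULL,
                            seed = config$seed) {
  set.seed(as.integer(seed))
  p <- config$nMarkers
  fr <- config$alleleFreqRange
  freq <- if (fr[1L] == fr[2L]) rep(fr[1L], p) else stats::runif(p, fr[1L], fr[2L])
  if (is.null(pedigree)) {
    n <- config$nGenotypes
    X <- matrix(stats::rbinom(n * p, 2L, rep(freq, each = n)), n, p)
    ids <- sprintf("F%03d", seq_len(n))
  } else {
    rec <- pedigreeRecords(pedigree)
    n <- nrow(rec)
    ids <- rec$id
    idx <- seq_len(n)
    names(idx) <- ids
    X <- matrix(0L, n, p)
    for (i in seq_len(n)) {
      a <- rec$parent1[i]
      b <- rec$parent2[i]
      if (is.na(a) && is.na(b)) {
        X[i, ] <- stats::rbinom(p, 2L, freq)
      } else {
        da <- if (is.na(a)) stats::rbinom(p, 1L, freq) else
          stats::rbinom(p, 1L, X[idx[a], ] / 2)
        db <- if (is.na(b)) stats::rbinom(p, 1L, freq) else
          stats::rbinom(p, 1L, X[idx[b], ] / 2)
        X[i, ] <- da + db
      }
    }
  }
  colnames(X) <- sprintf("m%05d", seq_len(p))
  MarkerMatrix(X, ids = ids)
}

#' Simulate single-environment phenotypes from kernel models
#'
#' Draws one genetic effect vector per kernel, \code{g_k ~ N(0, sigma2_k
#' K_k)} via a PSD matrix square root (eigendecomposition with negative
#' eigenvalues clipped at zero), adds iid residuals \code{N(0, residual)},
#' and returns \code{y = mu + sum_k g_k + eps} along with every true
#' component, so downstream fits can be checked against the truth.
#'
#' @param kernels named list of \linkS4class{RelationshipKernel}s.
#' @param varianceComponents named numeric, one (nonnegative) variance per
#'   kernel in \code{kernels}.
#' @param residual residual variance.
#' @param mu intercept (default 0).
#' @param seed integer seed.
#' @return List with \code{y} (named numeric), \code{effects} (n x K matrix
#'   of true effect vectors), \code{mu}, \code{varianceComponents},
#'   \code{residual}.
#' @export
simulatePhenotypesSingle <- function(kernels, varianceComponents, residual,
                                     mu = 0, seed = 1L) {
  stopifnot(is.list(kernels), all(varianceComponents >= 0), residual >= 0)
  if (is.null(names(kernels))) {
    names(kernels) <- vapply(kernels, kernelKind, character(1L))
  }
  stopifnot(all(names(kernels) %in% names(varianceComponents)))
  set.seed(as.integer(seed))
  ids <- genotypeIds(kernels[[1L]])
  n <- length(ids)
  effects <- matrix(0, n, length(kernels),
                    dimnames = list(ids, names(kernels)))
  for (k in names(kernels)) {
    if (!identical(genotypeIds(kernels[[k]]), ids)) {
      stop("kernels must share one id order; use alignKernels()")
    }
    s2 <- varianceComponents[[k]]
    if (s2 > 0) {
      S <- .psdSqrt(kernelMatrix(kernels[[k]]))
      effects[, k] <- sqrt(s2) * as.numeric(S %*% stats::rnorm(n))
    }
  }
  eps <- stats::rnorm(n, 0, sqrt(residual))
  y <- stats::setNames(mu + rowSums(effects) + eps, ids)
  list(y = y, effects = effects, mu = mu,
       varianceComponents = varianceComponents, residual = residual)
}

#' Simulate multi-environment phenotypes with genotype-by-environment
#' structure
#'
#' Draws, for each kernel k, an n x m effect matrix with covariance
#' \code{U_k \%x\% K_k} (via \code{G_k = K_k^{1/2} Z U_k^{1/2}'} with iid
#' normal Z), residual rows with covariance \code{R}, builds per-environment
#' phenotypes \code{y_ij = mu_j + sum_k G_k[i, j] + e_ij}, and subsets to the
#' requested incidence pattern (creating unbalanced data when cells are
#' dropped).
#'
#' @param kernels named list of \linkS4class{RelationshipKernel}s.
#' @param UList named list of m x m PSD genetic environment covariances, one
#'   per kernel.
#' @param R m x m PSD residual covariance.
#' @param mu per-environment intercepts (length m; default 0).
#' @param incidence optional n x m logical matrix of cells to keep (default
#'   complete); or a fraction in (0, 1) interpreted as the proportion of
#'   cells to drop at random.
#' @param envNames environment ids (default E1..Em).
#' @param seed integer seed.
#' @return List with \code{phenotypes} (a phenotype table),
#'   \code{effects} (per-kernel true n x m matrices), \code{mu}, \code{UList},
#'   \code{R}.
#' @export
simulatePhenotypesMulti <- function(kernels, UList, R, mu = NULL,
                                    incidence = NULL, envNames = NULL,
                                    seed = 1L) {
  stopifnot(is.list(kernels), is.list(UList))
  if (is.null(names(kernels))) {
    names(kernels) <- vapply(kernels, kernelKind, character(1L))
  }
  stopifnot(all(names(kernels) %in% names(UList)))
  R <- as.matrix(R)
  m <- nrow(R)
  if (is.null(envNames)) envNames <- sprintf("E%d", seq_len(m))
  if (is.null(mu)) mu <- rep(0, m)
  stopifnot(length(mu) == m)
  set.seed(as.integer(seed))
  ids <- genotypeIds(kernels[[1L]])
  n <- length(ids)
  effects <- list()
  total <- matrix(0, n, m)
  for (k in names(kernels)) {
    Uk <- as.matrix(UList[[k]])
    stopifnot(nrow(Uk) == m)
    Sk <- .psdSqrt(kernelMatrix(kernels[[k]]))
    Su <- .psdSqrt(Uk)
    Gk <- Sk %*% matrix(stats::rnorm(n * m), n, m) %*% t(Su)
    dimnames(Gk) <- list(ids, envNames)
    effects[[k]] <- Gk
    total <- total + Gk
  }
  Sr <- .psdSqrt(R)
  Eps <- matrix(stats::rnorm(n * m), n, m) %*% t(Sr)
  Y <- sweep(total + Eps, 2L, mu, "+")
  dimnames(Y) <- list(ids, envNames)
  keep <- matrix(TRUE, n, m)
  if (!is.null(incidence)) {
    if (is.matrix(incidence)) {
      stopifnot(dim(incidence) == c(n, m))
      keep <- incidence
    } else {
      stopifnot(incidence > 0, incidence < 1)
      keep <- matrix(stats::runif(n * m) >= incidence, n, m)
    }
  }
  rows <- which(keep, arr.ind = TRUE)
  phen <- phenotypeTable(ids[rows[, 1L]], envNames[rows[, 2L]],
                         Y[keep])
  list(phenotypes = phen, effects = effects, mu = mu, UList = UList, R = R)
}

#' Simulate a complete elite-yield-trial-like dataset
#'
#' One call producing everything the models consume: a pedigree, gene-dropped
#' markers, the full kernel set (A from the pedigree; G and K from the
#' markers; C and P from the K x A product), single-environment phenotypes
#' from the configured variance components, and (when
#' \code{config$mEnvironments > 1}) multi-environment phenotypes with
#' compound-symmetry U matrices \code{U_k = sigma2_k * ((1 - envCor) I +
#' envCor J)} and residual \code{R = residual * ((1 - residualEnvCor) I +
#' residualEnvCor J)}.
#'
#' Only kernels named in \code{config$varianceComponents} contribute signal;
#' all five kernels are always returned for fitting.
#'
#' @param config a \code{\link{simConfig}}.
#' @param seed seed override.
#' @return List with \code{pedigree}, \code{markers} (standardized),
#'   \code{kernels} (named list A, G, K, C, P), \code{single} (output of
#'   \code{\link{simulatePhenotypesSingle}}), and \code{multi} (output of
#'   \code{\link{simulatePhenotypesMulti}}, or NULL when m = 1).
#' @export
simulateDataset <- function(config = simConfig(), seed = config$seed) {
  ped <- simulatePedigree(config, seed = .streamSeed(seed, 1L))
  markers <- simulateMarkers(config, pedigree = ped,
                             seed = .streamSeed(seed, 2L))
  markersStd <- suppressWarnings(standardizeMarkers(markers))
  A <- pedigreeToA(ped)
  G <- computeG(markersStd)
  K <- gaussianKernel(markersStd)
  KA <- computeKA(K, A)
  kernels <- list(A = A, G = G, K = K, C = buildC(KA), P = buildP(KA))
  vc <- config$varianceComponents
  simKernels <- kernels[names(kernels) %in% names(vc)]
  single <- simulatePhenotypesSingle(
    simKernels, vc, config$residual, seed = .streamSeed(seed, 3L))
  multi <- NULL
  m <- config$mEnvironments
  if (m > 1L) {
    cs <- function(rho) (1 - rho) * diag(m) + rho * matrix(1, m, m)
    UList <- lapply(vc[names(simKernels)], function(s2) s2 * cs(config$envCor))
    R <- config$residual * cs(config$residualEnvCor)
    multi <- simulatePhenotypesMulti(
      simKernels, UList, R, seed = .streamSeed(seed, 4L))
  }
  list(pedigree = ped, markers = markersStd, kernels = kernels,
       single = single, multi = multi, config = config)
}
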