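#' @include AllGenerics.R
NULL

#' MarkerMatrix: genotype-by-marker dosage matrix
#'
#' Container for a numeric genotype-by-marker matrix with ordered genotype
#' identifiers. Dosages may be on any numeric scale (0/1/2 biallelic coding is
#' typical); \code{\link{standardizeMarkers}} centres and scales columns prior
#' to kernel construction and records any zero-variance markers it removed.
#'
#' @slot ids character, ordered genotype identifiers (unique, one per row).
#' @slot values numeric matrix, genotypes in rows, markers in columns.
#' @slot standardized logical flag; when \code{TRUE} every column has mean 0
#'   and sample standard deviation 1 (n - 1 denominator).
#' @slot droppedMarkers character, identifiers of zero-variance columns
#'   removed during standardization.
#'
#' @seealso \code{\link{standardizeMarkers}}, \code{\link{computeG}},
#'   \code{\link{gaussianKernel}}
#' @export
setClass("MarkerMatrix",
  representation(
    ids = "character",
    values = "matrix",
    standardized = "logical",
    droppedMarkers = "character"
  ),
  prototype(standardized = FALSE, droppedMarkers = character(0))
)

setValidity("MarkerMatrix", function(object) {
  msg <- character(0)
  v <- object@values
  if (!is.numeric(v)) {
    msg <- c(msg, "marker values must be numeric")
  }
  if (nrow(v) != length(object@ids)) {
    msg <- c(msg, "number of ids must equal number of rows")
  }
  if (anyDuplicated(object@ids)) {
    msg <- c(msg, "genotype ids must be unique")
  }
  if (length(object@standardized) != 1L) {
    msg <- c(msg, "'standardized' must be a single logical")
  }
  if (isTRUE(object@standardized) && ncol(v) > 0L && nrow(v) >= 2L) {
    cm <- colMeans(v)
    csd <- .colSds(v)
    if (max(abs(cm)) >= 1e-8 || max(abs(csd - 1)) >= 1e-8) {
      msg <- c(msg, "standardized marker columns must have mean 0 and sample sd 1")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a MarkerMatrix
#'
#' @param values numeric matrix of dosages, genotypes in rows.
#' @param ids genotype identifiers; defaults to \code{rownames(values)}.
#' @param standardized logical, whether columns are already standardized.
#' @param droppedMarkers identifiers of removed zero-variance markers.
#' @return A \linkS4class{MarkerMatrix}.
#' @examples
#' X <- matrix(c(0, 1, 2, 2, 1, 0), nrow = 3,
#'             dimnames = list(c("g1", "g2", "g3"), c("m1", "m2")))
#' MarkerMatrix(X)
#' @export
MarkerMatrix <- function(values, ids = rownames(values),
                         standardized = FALSE,
                         droppedMarkers = character(0)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(ids)) {
    ids <- paste0("g", seq_len(nrow(values)))
  }
  if (anyNA(values)) {
    stop("marker matrix contains missing values; impute upstream")
  }
  rownames(values) <- ids
  new("MarkerMatrix", ids = as.character(ids), values = values,
      standardized = standardized,
      droppedMarkers = as.character(droppedMarkers))
}

#' RelationshipKernel: labelled symmetric relationship matrix
#'
#' An n-by-n symmetric relationship (covariance) matrix over a set of
#' genotypes, tagged with its construction kind: pedigree-based \code{A},
#' linear genomic \code{G}, Gaussian \code{K}, the hybrid kernels \code{C} and
#' \code{P} built from the K x A matrix product, or \code{custom}. Provenance
#' metadata records the Gaussian bandwidth (median squared distance) for
#' \code{K} and the mean-diagonal divisor for \code{C}/\code{P}.
#'
#' @slot ids character, ordered genotype identifiers.
#' @slot matrix numeric n x n symmetric matrix.
#' @slot kind character, one of \code{A}, \code{G}, \code{K}, \code{C},
#'   \code{P}, \code{custom}.
#' @slot bandwidthInfo numeric; for \code{kind = "K"} the median squared
#'   Euclidean distance used as bandwidth (times any scale factor).
#' @slot scalingInfo numeric; for \code{C}/\code{P} the mean diagonal of KA
#'   used as divisor.
#' @slot minEigenvalue numeric; smallest eigenvalue, cached by
#'   \code{\link{validateKernel}} (NA until validated).
#'
#' @seealso \code{\link{computeG}}, \code{\link{gaussianKernel}},
#'   \code{\link{pedigreeToA}}, \code{\link{buildC}}, \code{\link{buildP}},
#'   \code{\link{validateKernel}}
#' @export
setClass("RelationshipKernel",
  representation(
    ids = "character",
    matrix = "matrix",
    kind = "character",
    bandwidthInfo = "numeric",
    scalingInfo = "numeric",
    minEigenvalue = "numeric"
  ),
  prototype(kind = "custom", bandwidthInfo = NA_real_,
            scalingInfo = NA_real_, minEigenvalue = NA_real_)
)

setValidity("RelationshipKernel", function(object) {
  msg <- character(0)
  m <- object@matrix
  n <- length(object@ids)
  if (nrow(m) != n || ncol(m) != n) {
    msg <- c(msg, "matrix must be square with dimension equal to number of ids")
  }
  if (anyDuplicated(object@ids)) {
    msg <- c(msg, "genotype ids must be unique")
  }
  if (!(object@kind %in% c("A", "G", "K", "C", "P", "custom"))) {
    msg <- c(msg, "kind must be one of A, G, K, C, P, custom")
  }
  if (nrow(m) == ncol(m) && nrow(m) > 0L) {
    if (max(abs(m - t(m))) > 1e-10) {
      msg <- c(msg, "matrix must be symmetric to within 1e-10")
    }
    if (object@kind == "K") {
      if (any(diag(m) != 1)) {
        msg <- c(msg, "Gaussian kernel diagonal must be exactly 1")
      }
      off <- m[upper.tri(m)]
      if (length(off) && (any(off <= 0) || any(off > 1))) {
        msg <- c(msg, "Gaussian kernel off-diagonal entries must lie in (0, 1]")
      }
    }
    if (object@kind %in% c("C", "P")) {
      if (abs(mean(diag(m)) - 1) > 1e-10) {
        msg <- c(msg, "C/P kernels must have mean diagonal 1 (within 1e-10)")
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a RelationshipKernel
#'
#' @param matrix symmetric numeric matrix.
#' @param ids genotype identifiers; defaults to \code{rownames(matrix)}.
#' @param kind kernel kind (see \linkS4class{RelationshipKernel}).
#' @param bandwidthInfo,scalingInfo,minEigenvalue provenance metadata.
#' @return A \linkS4class{RelationshipKernel}.
#' @export
RelationshipKernel <- function(matrix, ids = rownames(matrix),
                               kind = "custom", bandwidthInfo = NA_real_,
                               scalingInfo = NA_real_,
                               minEigenvalue = NA_real_) {
  matrix <- as.matrix(matrix)
  storage.mode(matrix) <- "double"
  if (is.null(ids)) {
    ids <- paste0("g", seq_len(nrow(matrix)))
  }
  dimnames(matrix) <- list(ids, ids)
  new("RelationshipKernel", ids = as.character(ids), matrix = matrix,
      kind = kind, bandwidthInfo = bandwidthInfo, scalingInfo = scalingInfo,
      minEigenvalue = minEigenvalue)
}

#' PedigreeTable: ordered pedigree records
#'
#' Three-column pedigree (individual, parent1, parent2) with unknown parents
#' coded \code{NA}. Records must be ancestor-sorted: every known parent
#' appears before its offspring. \code{\link{pedigreeTable}} topologically
#' sorts its input when possible and fails on cycles.
#'
#' @slot records data.frame with character columns \code{id}, \code{parent1},
#'   \code{parent2}.
#' @seealso \code{\link{pedigreeToA}}, \code{\link{simulatePedigree}}
#' @export
setClass("PedigreeTable", representation(records = "data.frame"))

setValidity("PedigreeTable", function(object) {
  rec <- object@records
  msg <- character(0)
  if (!all(c("id", "parent1", "parent2") %in% names(rec))) {
    return("records must have columns id, parent1, parent2")
  }
  if (anyDuplicated(rec$id)) {
    msg <- c(msg, "individual ids must be unique")
  }
  pos <- seq_len(nrow(rec))
  names(pos) <- rec$id
  for (pcol in c("parent1", "parent2")) {
    p <- rec[[pcol]]
    known <- !is.na(p)
    if (any(known & !(p %in% rec$id))) {
      msg <- c(msg, sprintf("unknown %s id(s)", pcol))
    } else if (any(known & pos[p] >= pos)) {
      msg <- c(msg, "every parent must precede its offspring (sort with pedigreeTable)")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PedigreeTable
#'
#' Accepts records in any order and topologically sorts them so parents
#' precede offspring; individuals that appear only as parents are added as
#' founders. Cyclic pedigrees (an individual its own ancestor) are an error.
#'
#' @param id,parent1,parent2 character vectors (or a 3-column data.frame as
#'   the first argument). Use \code{NA} or \code{""} for unknown parents.
#' @return A \linkS4class{PedigreeTable}.
#' @examples
#' pedigreeTable(c("f1", "f2", "x"), c(NA, NA, "f1"), c(NA, NA, "f2"))
#' @export
pedigreeTable <- function(id, parent1 = NULL, parent2 = NULL) {
  if (is.data.frame(id)) {
    df <- id
    stopifnot(ncol(df) >= 3L)
    id <- df[[1L]]; parent1 <- df[[2L]]; parent2 <- df[[3L]]
  }
  id <- as.character(id)
  clean <- function(p) {
    p <- as.character(p)
    p[!nzchar(p) | is.na(p) | p %in% c("NA", "0", ".")] <- NA_character_
    p
  }
  parent1 <- clean(parent1)
  parent2 <- clean(parent2)
  implicit <- setdiff(c(parent1, parent2), c(id, NA_character_))
  if (length(implicit)) {
    id <- c(implicit, id)
    parent1 <- c(rep(NA_character_, length(implicit)), parent1)
    parent2 <- c(rep(NA_character_, length(implicit)), parent2)
  }
  ord <- .topoSortPedigree(id, parent1, parent2)
  rec <- data.frame(id = id[ord], parent1 = parent1[ord],
                    parent2 = parent2[ord], stringsAsFactors = FALSE)
  new("PedigreeTable", records = rec)
}

# Kahn topological sort; errors on cycles.
.topoSortPedigree <- function(id, parent1, parent2) {
  n <- length(id)
  idx <- seq_len(n)
  names(idx) <- id
  parents <- cbind(ifelse(is.na(parent1), NA_integer_, idx[parent1]),
                   ifelse(is.na(parent2), NA_integer_, idx[parent2]))
  indeg <- rowSums(!is.na(parents))
  children <- vector("list", n)
  for (i in idx) {
    for (p in parents[i, ]) {
      if (!is.na(p)) children[[p]] <- c(children[[p]], i)
    }
  }
  queue <- idx[indeg == 0L]
  out <- integer(0)
  while (length(queue)) {
    i <- queue[[1L]]; queue <- queue[-1L]
    out <- c(out, i)
    for (ch in children[[i]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(out) != n) {
    stop("cyclic pedigree: an individual is its own ancestor")
  }
  out
}

#' SingleEnvFit: posterior summaries of a single-environment model
#'
#' Result of \code{\link{fitSingleEnv}}. Posterior means of genetic effects
#' are Rao-Blackwellized (averages of per-iteration full-conditional means),
#' and \code{yhat} equals the posterior-mean intercept plus the sum of the
#' effect means for every genotype, so the additive decomposition holds
#' exactly.
#'
#' @slot ids genotype identifiers, in fitting order.
#' @slot kernelNames names of the kernels in the model, in order.
#' @slot muPosterior named numeric: posterior \code{mean} and \code{sd} of
#'   the intercept.
#' @slot varcompPosterior data.frame with columns \code{component},
#'   \code{mean}, \code{sd}, \code{mcse} (one row per kernel plus
#'   \code{residual}).
#' @slot effectsPosterior numeric n x K matrix of posterior-mean effect
#'   vectors, one column per kernel.
#' @slot yhat numeric n vector of posterior-mean predictions.
#' @slot observed logical n vector; \code{FALSE} for masked phenotypes.
#' @slot samples list of thinned chains (\code{mu}, \code{varcomp} matrix).
#' @slot mcmc named numeric: \code{nIter}, \code{burnIn}, \code{thin},
#'   \code{seed}, \code{nSaved}.
#' @export
setClass("SingleEnvFit",
  representation(
    ids = "character",
    kernelNames = "character",
    muPosterior = "numeric",
    varcompPosterior = "data.frame",
    effectsPosterior = "matrix",
    yhat = "numeric",
    observed = "logical",
    samples = "list",
    mcmc = "numeric"
  )
)

setValidity("SingleEnvFit", function(object) {
  n <- length(object@ids)
  if (length(object@yhat) != n) return("yhat length must equal number of ids")
  if (nrow(object@effectsPosterior) != n) {
    return("effectsPosterior must have one row per genotype")
  }
  recon <- object@muPosterior[["mean"]] + rowSums(object@effectsPosterior)
  if (max(abs(recon - object@yhat)) > 1e-8) {
    return("yhat must equal intercept mean plus summed effect means")
  }
  TRUE
})

#' MultiEnvFit: posterior summaries of a multi-environment model
#'
#' Result of \code{\link{fitMultiEnv}}. In balanced (Kronecker) mode the
#' per-kernel genetic covariances are unstructured m x m matrices \code{U_k}
#' and the residual covariance \code{R} is m x m; in unbalanced (Hadamard)
#' mode each kernel carries a single variance and the residual is a scalar.
#'
#' @slot phenotypes data.frame of the fitted records (gid, env, value,
#'   observed flag) in fitting order.
#' @slot kernelNames names of the kernels in the model.
#' @slot mode \code{"balanced_kron"} or \code{"unbalanced_hadamard"}.
#' @slot muPosterior data.frame of per-environment intercept means and sds.
#' @slot envCovPosterior list; balanced mode: per-kernel posterior-mean
#'   \code{U_k} matrices plus \code{R}; unbalanced mode: empty.
#' @slot varcompPosterior data.frame of scalar variance components
#'   (unbalanced mode; balanced mode reports diagonal summaries).
#' @slot effectsPosterior numeric N x K matrix of posterior-mean effects per
#'   phenotype record.
#' @slot yhat numeric N vector of posterior-mean predictions per record.
#' @slot samples list of thinned chains.
#' @slot mcmc named numeric MCMC settings.
#' @export
setClass("MultiEnvFit",
  representation(
    phenotypes = "data.frame",
    kernelNames = "character",
    mode = "character",
    muPosterior = "data.frame",
    envCovPosterior = "list",
    varcompPosterior = "data.frame",
    effectsPosterior = "matrix",
    yhat = "numeric",
    samples = "list",
    mcmc = "numeric"
  )
)

## ---- accessors ----

#' @rdname genotypeIds
#' @export
setMethod("genotypeIds", "MarkerMatrix", function(x) x@ids)

#' @rdname genotypeIds
#' @export
setMethod("genotypeIds", "RelationshipKernel", function(x) x@ids)

#' @rdname genotypeIds
#' @export
setMethod("genotypeIds", "PedigreeTable", function(x) x@records$id)

#' @rdname kernelMatrix
#' @export
setMethod("kernelMatrix", "RelationshipKernel", function(x) x@matrix)

#' @rdname kernelKind
#' @export
setMethod("kernelKind", "RelationshipKernel", function(x) x@kind)

#' Marker dosage values
#'
#' @param x a \linkS4class{MarkerMatrix}.
#' @return The numeric genotype-by-marker matrix.
#' @export
markerValues <- function(x) {
  stopifnot(is(x, "MarkerMatrix"))
  x@values
}

#' Is a MarkerMatrix standardized?
#'
#' @param x a \linkS4class{MarkerMatrix}.
#' @return Logical flag.
#' @export
isStandardized <- function(x) {
  stopifnot(is(x, "MarkerMatrix"))
  x@standardized
}

#' Pedigree records
#'
#' @param x a \linkS4class{PedigreeTable}.
#' @return data.frame with columns id, parent1, parent2 (ancestor-sorted).
#' @export
pedigreeRecords <- function(x) {
  stopifnot(is(x, "PedigreeTable"))
  x@records
}

#' @rdname varianceComponents
#' @export
setMethod("varianceComponents", "SingleEnvFit", function(object) {
  object@varcompPosterior
})

#' @rdname varianceComponents
#' @export
setMethod("varianceComponents", "MultiEnvFit", function(object) {
  object@varcompPosterior
})

#' @rdname geneticEffects
#' @export
setMethod("geneticEffects", "SingleEnvFit", function(object) {
  object@effectsPosterior
})

#' @rdname geneticEffects
#' @export
setMethod("geneticEffects", "MultiEnvFit", function(object) {
  object@effectsPosterior
})

#' @rdname fittedValues
#' @export
setMethod("fittedValues", "SingleEnvFit", function(object) {
  stats::setNames(object@yhat, object@ids)
})

#' @rdname fittedValues
#' @export
setMethod("fittedValues", "MultiEnvFit", function(object) object@yhat)

## ---- show methods ----

setMethod("show", "MarkerMatrix", function(object) {
  cat(sprintf("MarkerMatrix: %d genotypes x %d markers (%s)\n",
              nrow(object@values), ncol(object@values),
              if (object@standardized) "standardized" else "raw"))
  if (length(object@droppedMarkers)) {
    cat(sprintf("  %d zero-variance marker(s) dropped\n",
                length(object@droppedMarkers)))
  }
})

setMethod("show", "RelationshipKernel", function(object) {
  cat(sprintf("RelationshipKernel '%s': %d x %d\n", object@kind,
              nrow(object@matrix), ncol(object@matrix)))
  if (!is.na(object@bandwidthInfo)) {
    cat(sprintf("  bandwidth (median d^2): %.6g\n", object@bandwidthInfo))
  }
  if (!is.na(object@scalingInfo)) {
    cat(sprintf("  mean-diagonal divisor: %.6g\n", object@scalingInfo))
  }
  if (!is.na(object@minEigenvalue)) {
    cat(sprintf("  min eigenvalue: %.3g\n", object@minEigenvalue))
  }
})

setMethod("show", "PedigreeTable", function(object) {
  rec <- object@records
  founders <- sum(is.na(rec$parent1) & is.na(rec$parent2))
  cat(sprintf("PedigreeTable: %d individuals (%d founders)\n",
              nrow(rec), founders))
})

setMethod("show", "SingleEnvFit", function(object) {
  cat(sprintf("SingleEnvFit: %d genotypes (%d observed), kernels: %s\n",
              length(object@ids), sum(object@observed),
              paste(object@kernelNames, collapse = ", ")))
  cat(sprintf("  intercept: %.4f (sd %.4f)\n",
              object@muPosterior[["mean"]], object@muPosterior[["sd"]]))
  print(object@varcompPosterior, row.names = FALSE, digits = 4)
})

setMethod("show", "MultiEnvFit", function(object) {
  cat(sprintf("MultiEnvFit (%s): %d records, %d environments, kernels: %s\n",
              object@mode, nrow(object@phenotypes),
              length(unique(object@phenotypes$env)),
              paste(object@kernelNames, collapse = ", ")))
  print(object@varcompPosterior, row.names = FALSE, digits = 4)
})
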