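#' Linear genomic relationship matrix G = XX'/p
#'
#' The GBLUP relationship matrix computed from a standardized marker matrix:
#' \code{G = X X' / p}, where p is the number of retained markers. As a scaled
#' Gram matrix it is symmetric and positive semi-definite by construction.
#'
#' @param markers a standardized \linkS4class{MarkerMatrix} (see
#'   \code{\link{standardizeMarkers}}).
#' @return A \linkS4class{RelationshipKernel} of kind \code{"G"}.
#' @examples
#' X <- matrix(c(0, 1, 2, 2, 0, 1), nrow = 3)
#' G <- computeG(standardizeMarkers(MarkerMatrix(X)))
#' @export
computeG <- function(markers) {
  stopifnot(is(markers, "MarkerMatrix"))
  if (!isTRUE(markers@standardized)) {
    stop("computeG requires standardized markers; call standardizeMarkers()")
  }
  p <- ncol(markers@values)
  if (p < 1L) stop("no markers retained")
  G <- .symm(tcrossprod(markers@values) / p)
  RelationshipKernel(G, ids = markers@ids, kind = "G")
}

#' Gaussian kernel with median-heuristic bandwidth
#'
#' The Gaussian (RBF) relationship kernel
#' \code{K_ij = exp(-d_ij^2 / (s * med))}, where \code{d_ij^2} is the squared
#' Euclidean distance between marker rows, \code{med} is the median of the
#' strictly-upper-triangular (off-diagonal) squared distances, and \code{s}
#' is an optional bandwidth scale (default 1). The median is taken over
#' off-diagonal entries only: the n structural zeros on the diagonal carry no
#' information and would shrink the bandwidth as n grows. The diagonal of the
#' result is exactly 1.
#'
#' @param markers a \linkS4class{MarkerMatrix} (standardization optional; the
#'   median heuristic adapts to the marker scale).
#' @param bandwidthScale positive multiplier \code{s} of the median bandwidth.
#' @return A \linkS4class{RelationshipKernel} of kind \code{"K"}, with the
#'   bandwidth (\code{s * med}) recorded in \code{bandwidthInfo}.
#' @examples
#' X <- matrix(c(0, 1, 1, 0, 0, 1), nrow = 3)  # rows (0,0), (1,0), (1,1)
#' K <- gaussianKernel(MarkerMatrix(X))
#' kernelMatrix(K)[1, 2]  # exp(-1)
#' @export
gaussianKernel <- function(markers, bandwidthScale = 1) {
  stopifnot(is(markers, "MarkerMatrix"), bandwidthScale > 0)
  D2 <- squaredDistanceMatrix(markers)
  off <- D2[upper.tri(D2)]
  med <- stats::median(off)
  if (!any(off > 0) || med <= 0) {
    stop("degenerate input: median off-diagonal squared distance is zero")
  }
  h <- bandwidthScale * med
  K <- exp(-D2 / h)
  diag(K) <- 1
  RelationshipKernel(K, ids = markers@ids, kind = "K", bandwidthInfo = h)
}

#' Numerator relationship matrix from a pedigree
#'
#' Computes the additive (numerator) relationship matrix A by the standard
#' tabular recursion over an ancestor-sorted pedigree:
#' \code{A_ii = 1 + 0.5 * A_{p1, p2}} and
#' \code{A_ij = 0.5 * (A_{j, p1} + A_{j, p2})} for j earlier than i, with
#' missing parents contributing zero. Founders have unit diagonal; inbred
#' individuals exceed it.
#'
#' When a precomputed relationship matrix (e.g. a coefficient-of-parentage
#' matrix) is available it can be supplied directly via
#' \code{\link{RelationshipKernel}} with \code{kind = "A"} instead.
#'
#' @param pedigree a \linkS4class{PedigreeTable}.
#' @return A \linkS4class{RelationshipKernel} of kind \code{"A"}.
#' @examples
#' ped <- pedigreeTable(c("f1", "f2", "s1", "s2"),
#'                      c(NA, NA, "f1", "f1"), c(NA, NA, "f2", "f2"))
#' kernelMatrix(pedigreeToA(ped))["s1", "s2"]  # full sibs: 0.5
#' @export
pedigreeToA <- function(pedigree) {
  stopifnot(is(pedigree, "PedigreeTable"))
  rec <- pedigree@records
  n <- nrow(rec)
  idx <- seq_len(n)
  names(idx) <- rec$id
  p1 <- ifelse(is.na(rec$parent1), 0L, idx[rec$parent1])
  p2 <- ifelse(is.na(rec$parent2), 0L, idx[rec$parent2])
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    a <- p1[i]; b <- p2[i]
    A[i, i] <- 1 + if (a > 0L && b > 0L) 0.5 * A[a, b] else 0
    if (i > 1L) {
      j <- seq_len(i - 1L)
      va <- if (a > 0L) A[j, a] else 0
      vb <- if (b > 0L) A[j, b] else 0
      aij <- 0.5 * (va + vb)
      A[i, j] <- aij
      A[j, i] <- aij
    }
  }
  RelationshipKernel(A, ids = rec$id, kind = "A")
}

#' Matrix product of the Gaussian and pedigree kernels
#'
#' The ordinary (dot) matrix product \code{K \%*\% A}. Although both factors
#' are symmetric, their product generally is not, so KA is not itself a valid
#' covariance kernel; it is the raw material from which the symmetric hybrid
#' kernels C and P are built (\code{\link{buildC}}, \code{\link{buildP}}).
#'
#' @param K,A \linkS4class{RelationshipKernel}s sharing an identical id
#'   order (align with \code{\link{alignKernels}} first).
#' @return A plain n x n numeric matrix with id dimnames.
#' @export
computeKA <- function(K, A) {
  stopifnot(is(K, "RelationshipKernel"), is(A, "RelationshipKernel"))
  if (!identical(K@ids, A@ids)) {
    stop("K and A must share an identical id order; use alignKernels()")
  }
  KA <- K@matrix %*% A@matrix
  dimnames(KA) <- list(K@ids, K@ids)
  KA
}

# Shared construction for the two hybrid kernels: symmetrize one strict
# triangle of KA, restore KA's diagonal, scale by the mean diagonal.
.buildHybrid <- function(KA, kind) {
  KA <- as.matrix(KA)
  if (nrow(KA) != ncol(KA)) stop("KA must be square")
  meanDiag <- mean(diag(KA))
  if (meanDiag <= 0) stop("degenerate input: mean diagonal of KA is not positive")
  tri <- if (kind == "C") .strictUpper(KA) else .strictLower(KA)
  M <- tri + t(tri)
  diag(M) <- diag(KA)
  M <- M / meanDiag
  ids <- rownames(KA)
  RelationshipKernel(M, ids = ids, kind = kind, scalingInfo = meanDiag)
}

#' Hybrid kernel C from the upper triangle of KA
#'
#' Builds the symmetric hybrid kernel C from the matrix product KA: the
#' strictly-upper-triangular part of KA is summed with its transpose, the
#' diagonal is replaced with the original diagonal of KA, and all entries are
#' divided by the mean of that diagonal (so \code{mean(diag(C)) == 1}). The
#' divisor is recorded in \code{scalingInfo}.
#'
#' @param KA square numeric matrix, the output of \code{\link{computeKA}}.
#' @return A \linkS4class{RelationshipKernel} of kind \code{"C"}.
#' @seealso \code{\link{buildP}}, \code{\link{computeKA}}
#' @export
buildC <- function(KA) .buildHybrid(KA, "C")

#' Hybrid kernel P from the lower triangle of KA
#'
#' As \code{\link{buildC}} with the strictly-lower-triangular part of KA in
#' place of the upper. For symmetric K and A the lower triangle of KA equals
#' the transpose of the upper triangle of AK, so C and P capture the two
#' distinct orientations of the same product. The pair satisfies the exact
#' identity \code{mean(diag(KA)) * (C + P) == KA + t(KA)}.
#'
#' @param KA square numeric matrix, the output of \code{\link{computeKA}}.
#' @return A \linkS4class{RelationshipKernel} of kind \code{"P"}.
#' @export
buildP <- function(KA) .buildHybrid(KA, "P")

#' Validate (and optionally repair) a relationship kernel
#'
#' Checks symmetry and positive semi-definiteness of a kernel and optionally
#' enforces PSD. \code{repair = "jitter"} adds \code{(|lambda_min| + tol) * I}
#' when the smallest eigenvalue is below \code{-tol};
#' \code{repair = "eigen_clip"} reconstructs the matrix with negative
#' eigenvalues set to zero. Either repair is followed by a rescaling that
#' preserves the mean diagonal of the input. The hybrid kernels C and P are
#' not PSD by construction and are the usual candidates for repair before
#' model fitting.
#'
#' @param kernel a \linkS4class{RelationshipKernel} (symmetric to within
#'   1e-8).
#' @param repair \code{"none"}, \code{"jitter"} or \code{"eigen_clip"}.
#' @param tol nonnegative tolerance on the smallest eigenvalue.
#' @return The (possibly repaired) kernel, with \code{minEigenvalue} cached
#'   and a \code{"validity"} attribute holding the report: a list with
#'   \code{minEigenvalue}, \code{symmetryDeviation}, \code{psd},
#'   \code{repaired} and \code{repair}.
#' @export
validateKernel <- function(kernel, repair = c("none", "jitter", "eigen_clip"),
                           tol = 1e-8) {
  stopifnot(is(kernel, "RelationshipKernel"), tol >= 0)
  repair <- match.arg(repair)
  M <- kernel@matrix
  symDev <- if (nrow(M)) max(abs(M - t(M))) else 0
  if (symDev > 1e-8) stop("kernel is asymmetric beyond 1e-8")
  e <- eigen(.symm(M), symmetric = TRUE, only.values = (repair != "eigen_clip"))
  lmin <- min(e$values)
  repaired <- FALSE
  if (lmin < -tol && repair != "none") {
    meanDiag <- mean(diag(M))
    if (repair == "jitter") {
      M <- M + (abs(lmin) + tol) * diag(nrow(M))
    } else {
      vals <- pmax(e$values, 0)
      M <- e$vectors %*% (vals * t(e$vectors))
      M <- .symm(M)
    }
    newDiag <- mean(diag(M))
    if (newDiag > 0 && meanDiag > 0) M <- M * (meanDiag / newDiag)
    dimnames(M) <- list(kernel@ids, kernel@ids)
    lminNew <- min(eigen(M, symmetric = TRUE, only.values = TRUE)$values)
    repaired <- TRUE
  } else {
    lminNew <- lmin
  }
  out <- kernel
  out@matrix <- M
  out@minEigenvalue <- lminNew
  validObject(out)
  attr(out, "validity") <- list(
    minEigenvalue = lminNew,
    minEigenvalueBefore = lmin,
    symmetryDeviation = symDev,
    psd = lminNew >= -tol,
    repaired = repaired,
    repair = repair
  )
  out
}

#' Align kernels (and phenotypes) to a common genotype set
#'
#' Restricts and reorders a list of kernels to the genotypes common to all of
#' them (and, if given, to the phenotypes), in a single shared order.
#' Phenotype rows whose genotype is absent from any kernel are dropped, with
#' the count reported via a message.
#'
#' @param kernels named list of \linkS4class{RelationshipKernel}s.
#' @param phenotypes optional phenotype data: either a numeric vector named
#'   by genotype id (single environment) or a long-format data.frame with
#'   columns \code{gid}, \code{env}, \code{value}.
#' @param ids optional explicit id subset to align to.
#' @return A list with elements \code{kernels} (aligned list),
#'   \code{phenotypes} (aligned, or NULL) and \code{ids} (the common order).
#' @export
alignKernels <- function(kernels, phenotypes = NULL, ids = NULL) {
  stopifnot(is.list(kernels), length(kernels) >= 1L)
  common <- Reduce(intersect, lapply(kernels, genotypeIds))
  if (!is.null(ids)) common <- intersect(common, ids)
  phenoIds <- NULL
  if (!is.null(phenotypes)) {
    phenoIds <- if (is.data.frame(phenotypes)) {
      unique(as.character(phenotypes$gid))
    } else {
      names(phenotypes)
    }
    if (is.null(phenoIds)) {
      stop("single-environment phenotypes must be named by genotype id")
    }
  }
  keep <- if (is.null(phenoIds)) common else intersect(common, phenoIds)
  # preserve the first kernel's order for determinism
  keep <- genotypeIds(kernels[[1L]])[genotypeIds(kernels[[1L]]) %in% keep]
  if (!length(keep)) stop("empty genotype intersection across inputs")
  alignedK <- lapply(kernels, function(k) {
    m <- k@matrix[keep, keep, drop = FALSE]
    out <- k
    out@ids <- keep
    out@matrix <- m
    out@minEigenvalue <- NA_real_
    out
  })
  alignedP <- NULL
  if (!is.null(phenotypes)) {
    if (is.data.frame(phenotypes)) {
      inKeep <- as.character(phenotypes$gid) %in% keep
      dropped <- sum(!inKeep)
      if (dropped > 0L) {
        message(sprintf("alignKernels: dropped %d phenotype record(s) without kernel entries", dropped))
      }
      alignedP <- phenotypes[inKeep, , drop = FALSE]
    } else {
      inKeep <- names(phenotypes) %in% keep
      dropped <- sum(!inKeep)
      if (dropped > 0L) {
        message(sprintf("alignKernels: dropped %d phenotype record(s) without kernel entries", dropped))
      }
      alignedP <- phenotypes[keep[keep %in% names(phenotypes)]]
    }
  }
  list(kernels = alignedK, phenotypes = alignedP, ids = keep)
}
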