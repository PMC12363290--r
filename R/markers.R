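#' Standardize a marker matrix
#'
#' Centres every marker column to mean zero and scales it to sample standard
#' deviation one (n - 1 denominator), the form expected by
#' \code{\link{computeG}}. Zero-variance markers carry no relationship
#' information and cannot be scaled; they are dropped (with a warning) or
#' raised as an error according to \code{zeroVariancePolicy}, and the
#' identifiers of dropped columns are recorded on the result.
#'
#' Standardization is idempotent: applying it to an already-standardized
#' matrix returns the same values (up to floating-point noise).
#'
#' @param markers a \linkS4class{MarkerMatrix} (raw dosages or already
#'   standardized).
#' @param zeroVariancePolicy \code{"drop"} (default) or \code{"error"}.
#' @return A standardized \linkS4class{MarkerMatrix}.
#' @examples
#' X <- matrix(c(0, 1, 2), ncol = 1, dimnames = list(NULL, "m1"))
#' markerValues(standardizeMarkers(MarkerMatrix(X)))  # -1, 0, 1
#' @export
standardizeMarkers <- function(markers,
                               zeroVariancePolicy = c("drop", "error")) {
  stopifnot(is(markers, "MarkerMatrix"))
  zeroVariancePolicy <- match.arg(zeroVariancePolicy)
  X <- markers@values
  if (nrow(X) < 2L) stop("standardization needs at least 2 genotypes")
  if (anyNA(X)) stop("marker matrix contains missing values; impute upstream")
  sds <- .colSds(X)
  zero <- sds < .Machine$double.eps^0.5
  droppedNew <- colnames(X)[zero]
  if (is.null(droppedNew)) droppedNew <- as.character(which(zero))
  if (any(zero)) {
    if (zeroVariancePolicy == "error") {
      stop(sprintf("%d zero-variance marker column(s); use policy 'drop'",
                   sum(zero)))
    }
    warning(sprintf("dropping %d zero-variance marker column(s)", sum(zero)))
    X <- X[, !zero, drop = FALSE]
    sds <- sds[!zero]
  }
  X <- scale(X, center = TRUE, scale = sds)
  attr(X, "scaled:center") <- NULL
  attr(X, "scaled:scale") <- NULL
  MarkerMatrix(X, ids = markers@ids, standardized = TRUE,
               droppedMarkers = c(markers@droppedMarkers, droppedNew))
}

#' Pairwise squared Euclidean distance matrix
#'
#' Entry (i, j) is the squared Euclidean distance between the marker rows of
#' genotypes i and j; the diagonal is exactly zero. Used as the input to the
#' Gaussian kernel.
#'
#' @param markers a \linkS4class{MarkerMatrix}.
#' @return Symmetric n x n numeric matrix with zero diagonal.
#' @export
squaredDistanceMatrix <- function(markers) {
  stopifnot(is(markers, "MarkerMatrix"))
  X <- markers@values
  if (nrow(X) < 2L) stop("need at least 2 genotypes")
  sq <- rowSums(X^2)
  D2 <- outer(sq, sq, "+") - 2 * tcrossprod(X)
  D2 <- .symm(D2)
  D2[D2 < 0] <- 0
  diag(D2) <- 0
  dimnames(D2) <- list(markers@ids, markers@ids)
  D2
}
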