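# Delimited-text readers/writers. Comma is the default dialect; tabs are
# auto-detected on read. Genotype and environment ids are opaque strings.

.detectSep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first, fixed = TRUE)) "\t" else ","
}

#' Read a marker matrix from delimited text
#'
#' Expected layout: header row of marker ids, first column genotype ids,
#' numeric dosage values. A marker-by-genotype layout (numeric-HapMap style)
#' is accepted via \code{transpose = TRUE}.
#'
#' @param path file path (comma- or tab-delimited; auto-detected).
#' @param transpose read markers as rows and genotypes as columns.
#' @return A \linkS4class{MarkerMatrix} of raw dosages.
#' @export
readMarkers <- function(path, transpose = FALSE) {
  sep <- .detectSep(path)
  dt <- data.table::fread(path, sep = sep, header = TRUE,
                          data.table = FALSE, colClasses = list(character = 1L))
  ids <- as.character(dt[[1L]])
  X <- as.matrix(dt[, -1L, drop = FALSE])
  storage.mode(X) <- "double"
  rownames(X) <- ids
  if (transpose) X <- t(X)
  MarkerMatrix(X)
}

#' Write a marker matrix to delimited text
#'
#' @param markers a \linkS4class{MarkerMatrix}.
#' @param path output path.
#' @param sep field separator.
#' @export
writeMarkers <- function(markers, path, sep = ",") {
  stopifnot(is(markers, "MarkerMatrix"))
  X <- markerValues(markers)
  df <- data.frame(gid = genotypeIds(markers),
                   format(X, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  data.table::fwrite(df, path, sep = sep, quote = FALSE)
  invisible(path)
}

#' Read a pedigree from 3-column delimited text
#'
#' Columns: individual id, parent1, parent2; empty fields, \code{NA} or
#' \code{0} mean unknown. Records are topologically sorted on read.
#'
#' @param path file path.
#' @return A \linkS4class{PedigreeTable}.
#' @export
readPedigree <- function(path) {
  sep <- .detectSep(path)
  dt <- data.table::fread(path, sep = sep, header = TRUE,
                          data.table = FALSE, colClasses = "character",
                          na.strings = c("", "NA"))
  pedigreeTable(dt)
}

#' Write a pedigree to delimited text
#'
#' @param pedigree a \linkS4class{PedigreeTable}.
#' @param path output path.
#' @param sep field separator.
#' @export
writePedigree <- function(pedigree, path, sep = ",") {
  stopifnot(is(pedigree, "PedigreeTable"))
  data.table::fwrite(pedigreeRecords(pedigree), path, sep = sep,
                     quote = FALSE)
  invisible(path)
}

#' Read a relationship kernel from a square delimited matrix
#'
#' Layout: id header row, id first column, numeric entries. Values written by
#' \code{\link{writeKernel}} round-trip bit-stably (17 significant digits).
#'
#' @param path file path.
#' @param kind kernel kind to tag the result with.
#' @return A \linkS4class{RelationshipKernel}.
#' @export
readKernel <- function(path, kind = "custom") {
  sep <- .detectSep(path)
  dt <- data.table::fread(path, sep = sep, header = TRUE,
                          data.table = FALSE, colClasses = list(character = 1L))
  ids <- as.character(dt[[1L]])
  M <- as.matrix(dt[, -1L, drop = FALSE])
  storage.mode(M) <- "double"
  if (!identical(colnames(M), ids)) {
    stop("kernel file header ids do not match first-column ids")
  }
  M <- .symm(M)  # guard against last-digit asymmetry from text round-trips
  RelationshipKernel(M, ids = ids, kind = kind)
}

#' Write a relationship kernel as a square delimited matrix
#'
#' @param kernel a \linkS4class{RelationshipKernel}.
#' @param path output path.
#' @param sep field separator.
#' @export
writeKernel <- function(kernel, path, sep = ",") {
  stopifnot(is(kernel, "RelationshipKernel"))
  M <- kernelMatrix(kernel)
  ids <- genotypeIds(kernel)
  lines <- c(paste(c("id", ids), collapse = sep),
             vapply(seq_along(ids), function(i) {
               paste(c(ids[i], sprintf("%.17g", M[i, ])), collapse = sep)
             }, character(1L)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a long-format phenotype table
#'
#' Columns \code{gid}, \code{env}, \code{value}; missing cells are simply
#' absent rows.
#'
#' @param path file path.
#' @return A phenotype table (see \code{\link{phenotypeTable}}).
#' @export
readPhenotypes <- function(path) {
  sep <- .detectSep(path)
  dt <- data.table::fread(path, sep = sep, header = TRUE,
                          data.table = FALSE,
                          colClasses = list(character = 1:2))
  if (!all(c("gid", "env", "value") %in% names(dt))) {
    stop("phenotype file must have columns gid, env, value")
  }
  phenotypeTable(dt)
}

#' Write a long-format phenotype table
#'
#' @param phenotypes a phenotype table.
#' @param path output path.
#' @param sep field separator.
#' @export
writePhenotypes <- function(phenotypes, path, sep = ",") {
  phenotypes <- phenotypeTable(phenotypes)
  out <- phenotypes
  out$value <- sprintf("%.17g", out$value)
  data.table::fwrite(out, path, sep = sep, quote = FALSE)
  invisible(path)
}

#' Serialize posterior summaries of a fit to JSON
#'
#' Writes the intercept(s), variance-component summaries, environment
#' covariance matrices (multi-environment balanced fits), effect vectors and
#' predictions as structured JSON.
#'
#' @param fit a \linkS4class{SingleEnvFit} or \linkS4class{MultiEnvFit}.
#' @param path output path.
#' @export
writeFitSummary <- function(fit, path) {
  if (is(fit, "SingleEnvFit")) {
    obj <- list(
      type = "single_env",
      kernels = fit@kernelNames,
      mu = as.list(fit@muPosterior),
      varianceComponents = fit@varcompPosterior,
      effects = as.data.frame(cbind(gid = fit@ids,
                                    as.data.frame(fit@effectsPosterior))),
      yhat = data.frame(gid = fit@ids, yhat = fit@yhat,
                        observed = fit@observed),
      mcmc = as.list(fit@mcmc)
    )
  } else if (is(fit, "MultiEnvFit")) {
    obj <- list(
      type = "multi_env",
      mode = fit@mode,
      kernels = fit@kernelNames,
      mu = fit@muPosterior,
      varianceComponents = fit@varcompPosterior,
      envCovariances = lapply(fit@envCovPosterior, function(M) {
        as.data.frame(as.matrix(M))
      }),
      yhat = cbind(fit@phenotypes, yhat = fit@yhat),
      mcmc = as.list(fit@mcmc)
    )
  } else {
    stop("unsupported fit object")
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}
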