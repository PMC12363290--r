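# Configuration-driven entry points binding the modules into reproducible
# runs, plus the command-line front end used by inst/scripts/hybridgp.R.

#' Read a run configuration
#'
#' Loads a YAML configuration describing one run: input paths (\code{markers},
#' \code{pedigree} or \code{kernel_A}, \code{phenotypes}, optional \code{E}),
#' a kernel recipe (\code{kernels: recipe/bandwidthScale/repair}), a model id
#' (S1-S5 or M1-M5), MCMC settings (\code{mcmc: iterations/burnin/thin}),
#' prior settings (\code{prior: df/R2}), a CV scheme (\code{scheme}), an
#' output directory and a seed. Command-line overrides (a named list) replace
#' top-level keys.
#'
#' @param path YAML file path.
#' @param overrides named list of top-level overrides.
#' @return The configuration as a named list.
#' @export
readRunConfig <- function(path, overrides = list()) {
  config <- yaml::read_yaml(path)
  for (nm in names(overrides)) config[[nm]] <- overrides[[nm]]
  if (is.null(config$seed)) config$seed <- 1L
  config
}

# Resolve kernel inputs from a config into a named kernel list.
.buildKernelsFromConfig <- function(config) {
  recipe <- config$kernels$recipe
  if (is.null(recipe)) recipe <- c("A", "G", "K", "C", "P")
  recipe <- unique(toupper(recipe))
  bw <- config$kernels$bandwidthScale
  if (is.null(bw)) bw <- 1
  out <- list()
  markersStd <- NULL
  if (!is.null(config$markers)) {
    markers <- readMarkers(config$markers)
    markersStd <- suppressWarnings(standardizeMarkers(markers))
    nd <- length(markersStd@droppedMarkers)
    if (nd > 0L) message(sprintf("dropped %d zero-variance marker(s)", nd))
  }
  if ("A" %in% recipe || any(c("C", "P") %in% recipe)) {
    if (!is.null(config$kernel_A)) {
      out$A <- readKernel(config$kernel_A, kind = "A")
    } else if (!is.null(config$pedigree)) {
      out$A <- pedigreeToA(readPedigree(config$pedigree))
    } else if (any(c("A", "C", "P") %in% recipe)) {
      stop("recipe needs A (or C/P) but neither kernel_A nor pedigree is configured")
    }
  }
  needK <- any(c("K", "C", "P") %in% recipe)
  if ("G" %in% recipe || needK) {
    if (is.null(markersStd)) stop("recipe needs markers but none configured")
    if ("G" %in% recipe) out$G <- computeG(markersStd)
    if (needK) out$K <- gaussianKernel(markersStd, bandwidthScale = bw)
  }
  if (any(c("C", "P") %in% recipe)) {
    aligned <- alignKernels(out[c("K", "A")])
    KA <- computeKA(aligned$kernels$K, aligned$kernels$A)
    if ("C" %in% recipe) out$C <- buildC(KA)
    if ("P" %in% recipe) out$P <- buildP(KA)
  }
  out[intersect(c("A", "G", "K", "C", "P"), recipe)]
}

.writeManifest <- function(config, outDir, extra = list()) {
  inputs <- config[intersect(names(config),
                             c("markers", "pedigree", "kernel_A",
                               "phenotypes", "E"))]
  hashes <- lapply(inputs, function(p) {
    if (is.character(p) && file.exists(p)) unname(tools::md5sum(p)) else NA
  })
  manifest <- c(list(
    package = "hybridGP",
    version = as.character(utils::packageVersion("hybridGP")),
    seed = config$seed,
    config = config,
    inputHashes = hashes
  ), extra)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Build and write relationship kernels from configured inputs
#'
#' Writes each requested kernel as a square delimited matrix plus a validity
#' report (dimension, minimum eigenvalue, repair applied, Gaussian bandwidth,
#' mean diagonal of KA).
#'
#' @param config a run configuration (see \code{\link{readRunConfig}}).
#' @return Invisibly, the named list of written kernels.
#' @export
cliKernels <- function(config) {
  outDir <- config$output %||% "."
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  repairPolicy <- config$kernels$repair %||% "eigen_clip"
  kernels <- .buildKernelsFromConfig(config)
  report <- lapply(names(kernels), function(nm) {
    k <- validateKernel(kernels[[nm]], repair = repairPolicy)
    rep <- attr(k, "validity")
    writeKernel(k, file.path(outDir, sprintf("kernel_%s.csv", nm)))
    list(kind = nm, n = length(genotypeIds(k)),
         minEigenvalue = rep$minEigenvalue,
         repaired = rep$repaired,
         bandwidth = k@bandwidthInfo,
         kaMeanDiagonal = k@scalingInfo)
  })
  jsonlite::write_json(report, file.path(outDir, "kernel_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  .writeManifest(config, outDir)
  invisible(kernels)
}

# Model id -> kernel subset, with single/multi consistency checks.
.resolveModel <- function(modelId, phenotypes) {
  single <- singleEnvKernelSets()
  multi <- multiEnvKernelSets()
  isMulti <- length(unique(phenotypes$env)) > 1L
  if (modelId %in% names(single)) {
    if (isMulti) {
      stop(sprintf("model %s is single-environment but data span multiple environments; use %s",
                   modelId, sub("S", "M", modelId)))
    }
    single[[modelId]]
  } else if (modelId %in% names(multi)) {
    if (!isMulti) {
      stop(sprintf("model %s is multi-environment but data have one environment; use %s",
                   modelId, sub("M", "S", modelId)))
    }
    multi[[modelId]]
  } else {
    stop(sprintf("unknown model id '%s'", modelId))
  }
}

#' Fit a configured model and write its artifacts
#'
#' Runs the requested S- or M-model on the configured phenotypes and kernels
#' and writes posterior summaries, predictions and a reproducibility
#' manifest (config, seed, input hashes, package version) to the output
#' directory.
#'
#' @param config a run configuration.
#' @return Invisibly, the fit object.
#' @export
cliFit <- function(config) {
  outDir <- config$output %||% "."
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  phen <- readPhenotypes(config$phenotypes)
  kernels <- .buildKernelsFromConfig(config)
  modelId <- config$model %||% "S5"
  kinds <- .resolveModel(modelId, phen)
  mcmc <- config$mcmc %||% list()
  nIter <- mcmc$iterations %||% 50000L
  burnIn <- mcmc$burnin %||% 5000L
  thin <- mcmc$thin %||% 5L
  prior <- config$prior %||% list()
  priorDf <- prior$df %||% 5
  priorR2 <- prior$R2 %||% 0.5
  isMulti <- length(unique(phen$env)) > 1L
  if (isMulti) {
    E <- if (!is.null(config$E)) as.matrix(readKernel(config$E)@matrix) else NULL
    fit <- fitMultiEnv(phen, kernels[kinds], E = E, nIter = nIter,
                       burnIn = burnIn, thin = thin, seed = config$seed,
                       priorDf = priorDf, priorR2 = priorR2)
  } else {
    y <- stats::setNames(phen$value, phen$gid)
    aligned <- alignKernels(kernels[kinds], phenotypes = y)
    fit <- fitSingleEnv(aligned$phenotypes, aligned$kernels, nIter = nIter,
                        burnIn = burnIn, thin = thin, seed = config$seed,
                        priorDf = priorDf, priorR2 = priorR2)
  }
  writeFitSummary(fit, file.path(outDir, sprintf("fit_%s.json", modelId)))
  .writeManifest(config, outDir, extra = list(model = modelId))
  invisible(fit)
}

#' Run a configured cross-validation experiment and write its tables
#'
#' Evaluates the configured model list under the configured scheme with
#' paired fold assignments, writing per-fold records
#' (\code{cv_records.csv}), the aggregate table (\code{cv_summary.csv}, with
#' a percent-difference column when a baseline model is configured) and a
#' manifest.
#'
#' @param config a run configuration with \code{models} (vector of model
#'   ids), \code{scheme} (kind, k/repeats or targetEnv/knownFraction) and
#'   optionally \code{baseline}.
#' @return Invisibly, the experiment result list.
#' @export
cliCv <- function(config) {
  outDir <- config$output %||% "."
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  phen <- readPhenotypes(config$phenotypes)
  kernels <- .buildKernelsFromConfig(config)
  modelIds <- unlist(config$models %||% list("S2", "S5"))
  sc <- config$scheme %||% list(kind = "kfold", k = 5, repeats = 4)
  mcmc <- config$mcmc %||% list()
  nIter <- mcmc$iterations %||% 50000L
  burnIn <- mcmc$burnin %||% 5000L
  thin <- mcmc$thin %||% 5L
  isMulti <- length(unique(phen$env)) > 1L
  models <- lapply(modelIds, .resolveModel, phenotypes = phen)
  names(models) <- modelIds
  if (isMulti) {
    scheme <- makeEnvMaskScheme(phen, sc$targetEnv,
                                sc$knownFraction %||% 0.2,
                                sc$repeats %||% 10L, config$seed)
    result <- runExperiment(phen, kernels, models, scheme, nIter = nIter,
                            burnIn = burnIn, thin = thin)
  } else {
    y <- stats::setNames(phen$value, phen$gid)
    aligned <- alignKernels(kernels, phenotypes = y)
    scheme <- makeKfoldScheme(length(aligned$ids), sc$k %||% 5L,
                              sc$repeats %||% 4L, config$seed)
    result <- runExperiment(aligned$phenotypes, aligned$kernels, models,
                            scheme, nIter = nIter, burnIn = burnIn,
                            thin = thin)
  }
  summary <- summarizeCV(result, baseline = config$baseline)
  data.table::fwrite(result$records, file.path(outDir, "cv_records.csv"))
  data.table::fwrite(summary, file.path(outDir, "cv_summary.csv"))
  .writeManifest(config, outDir,
                 extra = list(models = modelIds,
                              scheme = sc))
  invisible(result)
}

#' Simulate a configured synthetic dataset and write its files
#'
#' Generates a complete dataset with \code{\link{simulateDataset}} and writes
#' markers, pedigree, kernels and phenotypes in the formats the readers
#' consume.
#'
#' @param config a run configuration whose \code{simulate} block holds
#'   \code{\link{simConfig}} arguments.
#' @return Invisibly, the simulated dataset list.
#' @export
cliSimulate <- function(config) {
  outDir <- config$output %||% "."
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  args <- config$simulate %||% list()
  args$varianceComponents <- if (!is.null(args$varianceComponents)) {
    unlist(args$varianceComponents)
  } else NULL
  args <- args[!vapply(args, is.null, logical(1L))]
  sim <- simulateDataset(do.call(simConfig, args), seed = config$seed)
  writeMarkers(sim$markers, file.path(outDir, "markers.csv"))
  writePedigree(sim$pedigree, file.path(outDir, "pedigree.csv"))
  for (nm in names(sim$kernels)) {
    writeKernel(sim$kernels[[nm]], file.path(outDir,
                                             sprintf("kernel_%s.csv", nm)))
  }
  singleTab <- phenotypeTable(names(sim$single$y), "E1",
                              as.numeric(sim$single$y))
  writePhenotypes(singleTab, file.path(outDir, "phenotypes_single.csv"))
  if (!is.null(sim$multi)) {
    writePhenotypes(sim$multi$phenotypes,
                    file.path(outDir, "phenotypes_multi.csv"))
  }
  .writeManifest(config, outDir)
  invisible(sim)
}

#' Command-line front end
#'
#' Dispatches the subcommands \code{kernels}, \code{fit}, \code{cv} and
#' \code{simulate} on a YAML configuration, as used by the
#' \code{inst/scripts/hybridgp.R} entry point. Returns exit status 0 on
#' success, 1 on user error (bad arguments, unreadable inputs), 2 on
#' internal error.
#'
#' @param args character vector of command-line arguments (first element the
#'   subcommand).
#' @return Integer exit status, invisibly.
#' @export
hybridgpMain <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: hybridgp.R <kernels|fit|cv|simulate> --config <file> [--seed N] [--output DIR] [--model ID]"
  if (length(args) < 1L || !args[1L] %in% c("kernels", "fit", "cv", "simulate")) {
    message(usage)
    return(invisible(1L))
  }
  sub <- args[1L]
  parser <- optparse::OptionParser(option_list = list(
    optparse::make_option("--config", type = "character", default = NULL),
    optparse::make_option("--seed", type = "integer", default = NULL),
    optparse::make_option("--output", type = "character", default = NULL),
    optparse::make_option("--model", type = "character", default = NULL)
  ))
  opts <- tryCatch(
    optparse::parse_args(parser, args = args[-1L]),
    error = function(e) NULL
  )
  if (is.null(opts) || is.null(opts$config)) {
    message(usage)
    return(invisible(1L))
  }
  if (!file.exists(opts$config)) {
    message(sprintf("config file not found: %s", opts$config))
    return(invisible(1L))
  }
  overrides <- opts[intersect(names(opts), c("seed", "output", "model"))]
  overrides <- overrides[!vapply(overrides, is.null, logical(1L))]
  status <- tryCatch({
    config <- readRunConfig(opts$config, overrides)
    switch(sub,
           kernels = cliKernels(config),
           fit = cliFit(config),
           cv = cliCv(config),
           simulate = cliSimulate(config))
    0L
  }, error = function(e) {
    message(sprintf("error: %s", conditionMessage(e)))
    2L
  })
  invisible(status)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
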