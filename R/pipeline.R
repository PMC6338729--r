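#' Validate a pipeline configuration
#'
#' Fills in stage defaults and checks every stage parameter against its
#' module's preconditions before anything runs: fold counts at least 2,
#' FDR target and significance level in (0, 1), positive grids,
#' candidate weights in [0, 1], a mandatory seed (no silent
#' nondeterminism) and an output directory.
#'
#' @param config named list (or path to a YAML file) with entries
#'   `seed`, `outputDir`, and optional stage blocks `synthetic`,
#'   `profiles`/`markers` (paths), `classify`, `qsep`, `transfer`,
#'   `enrich`.
#' @return the completed configuration list.
#' @export
validatePipelineConfig <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML path")
  if (is.null(config$seed)) stop("config must set a seed")
  config$seed <- as.integer(config$seed)
  if (is.null(config$outputDir)) stop("config must set outputDir")
  defaults <- list(
    classify = list(q = 0.05, rounds = 100, folds = 5,
                    sigmaGrid = 10^seq(-3, 2), costGrid = 2^seq(-4, 4),
                    sigma = NULL, cost = NULL),
    qsep = list(orientation = "row"),
    transfer = list(candidates = c(0, 0.5, 1), iterations = 100,
                    folds = 5, kPrimary = 5, kAuxiliary = 5,
                    budget = 10000),
    enrich = list(nNull = 10000, alpha = 0.01, minSize = 5))
  for (stage in names(defaults)) {
    block <- if (is.null(config[[stage]])) list() else config[[stage]]
    config[[stage]] <- utils::modifyList(defaults[[stage]], block)
  }
  cl <- config$classify
  if (cl$folds < 2) stop("classify: folds must be at least 2")
  if (cl$rounds < 1) stop("classify: rounds must be at least 1")
  if (cl$q <= 0 || cl$q > 1) stop("classify: q must lie in (0, 1]")
  if (any(cl$sigmaGrid <= 0) || any(cl$costGrid <= 0))
    stop("classify: sigma and cost grids must be positive")
  tr <- config$transfer
  if (tr$folds < 2) stop("transfer: folds must be at least 2")
  if (any(tr$candidates < 0 | tr$candidates > 1))
    stop("transfer: candidate weights must lie in [0, 1]")
  if (tr$kPrimary < 1 || tr$kAuxiliary < 1)
    stop("transfer: neighbour counts must be at least 1")
  en <- config$enrich
  if (en$alpha <= 0 || en$alpha >= 1)
    stop("enrich: alpha must lie in (0, 1)")
  if (en$nNull < 1000) stop("enrich: nNull must be at least 1000")
  if (!config$qsep$orientation %in% c("row", "column"))
    stop("qsep: orientation must be 'row' or 'column'")
  config
}

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full organelle-mapping pipeline
#'
#' Executes the configured stages in order — load or generate profiles,
#' filter to complete profiles, principal component projection, QSep
#' resolution assessment, SVM classification with FDR thresholding,
#' optional transfer-learning integration with an auxiliary map, and
#' optional bias-corrected enrichment of the unclassified proteome —
#' writing each stage's tables plus a run manifest (parameters, seed,
#' output checksums, package version) into `outputDir`.  Rerunning an
#' identical configuration reproduces identical outputs.
#'
#' @param config configuration list or YAML path; see
#'   [validatePipelineConfig()].
#' @param quiet suppress progress messages.
#' @return invisibly, a list with the stage results and the manifest.
#' @export
runPipeline <- function(config, quiet = FALSE) {
  config <- validatePipelineConfig(config)
  note <- function(...) if (!quiet) message(...)
  dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  # --- input stage ---------------------------------------------------------
  auxiliary <- NULL
  if (!is.null(config$profiles)) {
    dataset <- stage("load", readProfileTable(config$profiles,
                                              channelInfo = config$channelInfo))
    markers <- stage("load", readMarkerAnnotation(config$markers))
    dataset <- setMarkers(dataset, markers)
  } else {
    spec <- stage("generate", do.call(syntheticSpec,
                                      if (is.null(config$synthetic)) list()
                                      else config$synthetic))
    gen <- stage("generate", generateDataset(spec, seed = config$seed))
    dataset <- gen$dataset
    markers <- gen$markers
    if (!is.null(config$syntheticAuxiliary)) {
      specAux <- stage("generate",
                       do.call(syntheticSpec, config$syntheticAuxiliary))
      pair <- stage("generate",
                    generatePairedMaps(spec, specAux, seed = config$seed))
      dataset <- pair$primary$dataset
      auxiliary <- pair$auxiliary$dataset
      markers <- pair$markers
    }
  }
  note("input: ", nrow(dataset), " proteins x ", ncol(dataset), " channels")
  dataset <- stage("filter", suppressMessages(filterCompleteProfiles(dataset)))
  # --- PCA -----------------------------------------------------------------
  pca <- stage("pca", pcaProject(dataset))
  outputs <- c(outputs, writePcaScores(pca, file.path(config$outputDir,
                                                      "pca_scores.tsv")))
  # --- QSep ----------------------------------------------------------------
  qres <- stage("qsep", qsep(dataset, markers,
                             orientation = config$qsep$orientation))
  outputs <- c(outputs,
               .writeTsv(data.frame(class = rownames(qsepRaw(qres)),
                                    qsepRaw(qres), check.names = FALSE),
                         file.path(config$outputDir, "qsep_raw.tsv")),
               .writeTsv(data.frame(class = rownames(qsepNormalised(qres)),
                                    qsepNormalised(qres), check.names = FALSE),
                         file.path(config$outputDir, "qsep_normalised.tsv")))
  # --- classification ------------------------------------------------------
  cl <- config$classify
  tune <- NULL
  if (is.null(cl$sigma) || is.null(cl$cost)) {
    tune <- stage("tune", tuneSvm(dataset, markers,
                                  sigmaGrid = cl$sigmaGrid,
                                  costGrid = cl$costGrid,
                                  rounds = cl$rounds, folds = cl$folds,
                                  seed = config$seed))
    cl$sigma <- tune@selected[["sigma"]]
    cl$cost <- tune@selected[["cost"]]
    outputs <- c(outputs,
                 .writeTsv(data.frame(round = seq_along(tune@f1),
                                      macroF1 = tune@f1, tune@best),
                           file.path(config$outputDir, "tuning.tsv")))
    note("tuned: sigma = ", cl$sigma, ", cost = ", cl$cost)
  }
  result <- stage("classify", trainAndScore(dataset, markers,
                                            sigma = cl$sigma,
                                            cost = cl$cost))
  if (!is.null(config$reference)) {
    ref <- config$reference
    if (is.character(ref) && length(ref) == 1 && file.exists(ref)) {
      tab <- utils::read.table(ref, sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE)
      ref <- stats::setNames(tab[[2]], tab[[1]])
    }
    result <- stage("fdr",
                    withCallingHandlers(
                      applyFdrThreshold(result, ref, q = cl$q),
                      warning = function(w) {
                        note("fdr: ", conditionMessage(w))
                        invokeRestart("muffleWarning")
                      }))
  }
  assignTab <- data.frame(accession = rownames(scoreMatrix(result)),
                          assigned = assignedClass(result),
                          score = result@score,
                          label = finalLabel(result), row.names = NULL)
  outputs <- c(outputs, .writeTsv(assignTab,
                                  file.path(config$outputDir,
                                            "assignments.tsv")))
  # --- transfer learning ---------------------------------------------------
  theta <- NULL
  if (!is.null(auxiliary)) {
    tr <- config$transfer
    theta <- stage("transfer",
                   optimizeTheta(dataset, auxiliary, markers,
                                 candidates = tr$candidates,
                                 iterations = tr$iterations,
                                 folds = tr$folds, kPrimary = tr$kPrimary,
                                 kAuxiliary = tr$kAuxiliary,
                                 seed = config$seed, budget = tr$budget))
    outputs <- c(outputs,
                 .writeTsv(data.frame(class = theta@classes,
                                      medianTheta = medianTheta(theta)),
                           file.path(config$outputDir, "theta.tsv")))
  }
  # --- enrichment ----------------------------------------------------------
  enrich <- NULL
  if (!is.null(config$categories)) {
    en <- config$enrich
    fi <- featureInfo(dataset)
    if (is.null(fi$abundance))
      stop("pipeline stage 'enrich' failed: no abundance annotation",
           call. = FALSE)
    unclassified <- rownames(dataset)[finalLabel(result) == "unknown"]
    universe <- rownames(dataset)
    pwf <- stage("enrich", fitPwf(stats::setNames(universe %in% unclassified,
                                                  universe),
                                  stats::setNames(fi$abundance, universe)))
    cats <- config$categories
    if (is.character(cats) && length(cats) == 1 && file.exists(cats)) {
      tab <- utils::read.table(cats, sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE)
      cats <- split(tab[[2]], tab[[1]])
    }
    enrich <- stage("enrich",
                    enrichmentTest(cats, unclassified, universe, pwf = pwf,
                                   nNull = en$nNull, seed = config$seed,
                                   alpha = en$alpha, minSize = en$minSize))
    outputs <- c(outputs, .writeTsv(enrich,
                                    file.path(config$outputDir,
                                              "enrichment.tsv")))
  }
  # --- manifest ------------------------------------------------------------
  manifest <- list(
    package = "spatprot",
    version = as.character(utils::packageVersion("spatprot")),
    seed = config$seed,
    parameters = list(classify = config$classify, qsep = config$qsep,
                      transfer = config$transfer, enrich = config$enrich),
    outputs = lapply(stats::setNames(outputs, basename(outputs)),
                     function(f) unname(tools::md5sum(f))))
  manifestPath <- file.path(config$outputDir, "manifest.json")
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  note("wrote ", length(outputs) + 1, " files to ", config$outputDir)
  invisible(list(dataset = dataset, markers = markers, pca = pca,
                 qsep = qres, tune = tune, classification = result,
                 theta = theta, enrichment = enrich,
                 manifest = manifest))
}
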