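#' ProfileSet: protein fraction profiles with channel and feature metadata
#'
#' A `ProfileSet` holds a proteins-by-channels matrix of nonnegative
#' relative reporter abundances from a correlation-profiling spatial
#' proteomics experiment (one column per TMT channel, possibly
#' concatenated over replicates).  It extends
#' [SummarizedExperiment::SummarizedExperiment] with a single `"profile"`
#' assay; per-channel metadata (`replicate`, `fraction`) live in
#' `colData` and per-protein metadata (`markerClass`, optionally
#' `groundTruth` and `abundance`) in `rowData`.
#'
#' Invariants enforced by the validity method: unique accessions
#' (rownames), all quantitation values nonnegative (missing values are
#' allowed until [filterCompleteProfiles()] is applied), and channel
#' metadata aligned with the matrix columns.
#'
#' @slot .Data inherited `SummarizedExperiment` representation.
#' @aliases ProfileSet-class
#' @exportClass ProfileSet
setClass("ProfileSet", contains = "SummarizedExperiment")

setValidity("ProfileSet", function(object) {
  m <- SummarizedExperiment::assay(object, "profile")
  msg <- character()
  if (is.null(rownames(m)))
    msg <- c(msg, "profile matrix must have accession rownames")
  else if (anyDuplicated(rownames(m)))
    msg <- c(msg, paste("duplicated accessions:",
                        paste(unique(rownames(m)[duplicated(rownames(m))]),
                              collapse = ", ")))
  if (any(m < 0, na.rm = TRUE))
    msg <- c(msg, "profile values must be nonnegative")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("replicate", "fraction") %in% colnames(cd)))
    msg <- c(msg, "channel metadata must contain 'replicate' and 'fraction'")
  if (!("markerClass" %in% colnames(SummarizedExperiment::rowData(object))))
    msg <- c(msg, "feature metadata must contain 'markerClass'")
  if (length(msg)) msg else TRUE
})

#' Construct a ProfileSet
#'
#' @param profiles numeric matrix of nonnegative relative abundances with
#'   accession rownames (proteins) and channel colnames.
#' @param channelInfo `data.frame` with one row per channel and at least
#'   columns `replicate` and `fraction`.  Defaults to a single replicate
#'   with fractions numbered along the columns.
#' @param featureInfo `data.frame` with one row per protein; a
#'   `markerClass` column is added (all `"unknown"`) when absent.
#'
#' @return a [ProfileSet-class] object.
#' @examples
#' m <- matrix(runif(20), 4, 5,
#'             dimnames = list(paste0("P", 1:4), paste0("F", 1:5)))
#' ps <- ProfileSet(m)
#' profileMatrix(ps)
#' @export
ProfileSet <- function(profiles, channelInfo = NULL, featureInfo = NULL) {
  profiles <- as.matrix(profiles)
  if (!is.numeric(profiles)) stop("profiles must be a numeric matrix")
  if (is.null(rownames(profiles)))
    stop("profiles must have accession rownames")
  dup <- unique(rownames(profiles)[duplicated(rownames(profiles))])
  if (length(dup))
    stop("duplicated accessions: ", paste(dup, collapse = ", "))
  if (is.null(colnames(profiles)))
    colnames(profiles) <- sprintf("C%02d", seq_len(ncol(profiles)))
  if (is.null(channelInfo)) {
    channelInfo <- data.frame(replicate = rep(1L, ncol(profiles)),
                              fraction = seq_len(ncol(profiles)))
  }
  channelInfo <- as.data.frame(channelInfo)
  if (nrow(channelInfo) != ncol(profiles))
    stop("channelInfo must have one row per channel (",
         ncol(profiles), " channels, ", nrow(channelInfo), " rows)")
  if (!all(c("replicate", "fraction") %in% colnames(channelInfo)))
    stop("channelInfo must contain 'replicate' and 'fraction' columns")
  rownames(channelInfo) <- colnames(profiles)
  if (is.null(featureInfo))
    featureInfo <- data.frame(row.names = rownames(profiles))
  featureInfo <- as.data.frame(featureInfo)
  if (nrow(featureInfo) != nrow(profiles))
    stop("featureInfo must have one row per protein")
  rownames(featureInfo) <- rownames(profiles)
  if (!("markerClass" %in% colnames(featureInfo)))
    featureInfo$markerClass <- "unknown"
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(profile = profiles),
    rowData = S4Vectors::DataFrame(featureInfo, check.names = FALSE),
    colData = S4Vectors::DataFrame(channelInfo, check.names = FALSE))
  new("ProfileSet", se)
}

#' @describeIn ProfileSet the proteins-by-channels profile matrix
#' @param object a `ProfileSet`
#' @export
setMethod("profileMatrix", "ProfileSet", function(object)
  SummarizedExperiment::assay(object, "profile"))

#' @describeIn ProfileSet per-channel metadata as a `data.frame`
#' @export
setMethod("channelInfo", "ProfileSet", function(object)
  as.data.frame(SummarizedExperiment::colData(object)))

#' @describeIn ProfileSet per-protein metadata as a `data.frame`
#' @export
setMethod("featureInfo", "ProfileSet", function(object)
  as.data.frame(SummarizedExperiment::rowData(object)))

#' @describeIn ProfileSet named vector of curated marker labels
#'   (proteins whose `markerClass` is not `"unknown"`)
#' @export
setMethod("markerLabels", "ProfileSet", function(object) {
  mc <- SummarizedExperiment::rowData(object)$markerClass
  keep <- !is.na(mc) & mc != "unknown"
  stats::setNames(as.character(mc[keep]), rownames(object)[keep])
})

setMethod("show", "ProfileSet", function(object) {
  m <- profileMatrix(object)
  cd <- channelInfo(object)
  nm <- sum(SummarizedExperiment::rowData(object)$markerClass != "unknown")
  cat("ProfileSet:", nrow(m), "proteins x", ncol(m), "channels",
      sprintf("(%d replicate%s)\n", length(unique(cd$replicate)),
              ifelse(length(unique(cd$replicate)) == 1, "", "s")))
  cat("  markers:", nm, "| missing cells:", sum(is.na(m)), "\n")
})

#' MarkerAnnotation: curated protein-to-organelle assignments
#'
#' Maps protein accessions to subcellular marker classes.  Marker
#' proteins are the labelled training data of the localisation
#' classifiers; each has curated, unambiguous residence in one class.
#'
#' @slot labels named character vector, accession -> class.
#' @slot classes ordered character vector of class names.
#' @aliases MarkerAnnotation-class
#' @exportClass MarkerAnnotation
setClass("MarkerAnnotation",
         representation(labels = "character", classes = "character"))

setValidity("MarkerAnnotation", function(object) {
  msg <- character()
  if (length(object@labels) && is.null(names(object@labels)))
    msg <- c(msg, "labels must be named by accession")
  if (anyDuplicated(names(object@labels)))
    msg <- c(msg, "duplicated marker accessions")
  if (anyDuplicated(object@classes))
    msg <- c(msg, "duplicated class names")
  bad <- setdiff(unique(object@labels), object@classes)
  if (length(bad))
    msg <- c(msg, paste("marker class not in class list:",
                        paste(bad, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct a MarkerAnnotation
#'
#' @param labels named character vector mapping accession to class name.
#' @param classes ordered class list; defaults to the sorted unique
#'   labels.
#' @return a [MarkerAnnotation-class] object.
#' @export
MarkerAnnotation <- function(labels, classes = NULL) {
  labels <- unlist(labels)
  if (is.null(classes)) classes <- sort(unique(as.character(labels)))
  new("MarkerAnnotation", labels = stats::setNames(as.character(labels),
                                                   names(labels)),
      classes = as.character(classes))
}

#' @describeIn MarkerAnnotation accession -> class vector
#' @param object a `MarkerAnnotation`
#' @export
setMethod("markerLabels", "MarkerAnnotation", function(object) object@labels)

#' @describeIn MarkerAnnotation the ordered class list
#' @export
setMethod("markerClasses", "MarkerAnnotation", function(object) object@classes)

setMethod("show", "MarkerAnnotation", function(object) {
  cat("MarkerAnnotation:", length(object@labels), "markers in",
      length(object@classes), "classes\n")
  print(table(factor(object@labels, levels = object@classes)))
})

#' PcaResult: principal component projection of a ProfileSet
#'
#' @slot scores proteins x components score matrix.
#' @slot loadings channels x components loading matrix.
#' @slot varianceFraction fraction of total profile variance captured by
#'   each component (non-increasing; sums to 1 when all components are
#'   kept).
#' @slot center channel means removed before the projection.
#' @aliases PcaResult-class
#' @exportClass PcaResult
setClass("PcaResult",
         representation(scores = "matrix", loadings = "matrix",
                        varianceFraction = "numeric", center = "numeric"))

setMethod("show", "PcaResult", function(object) {
  cat("PcaResult:", nrow(object@scores), "proteins,",
      ncol(object@scores), "components\n")
  vf <- round(100 * object@varianceFraction, 1)
  cat("  % variance:", paste(vf, collapse = ", "), "\n")
})

#' ClassificationResult: per-protein localisation scores and labels
#'
#' Holds the output of marker-trained classification: a per-protein,
#' per-class score matrix (rows sum to 1), the top-scoring class, and a
#' final label which is either that class or `"unknown"` after
#' score-ordered FDR thresholding.
#'
#' @slot scores proteins x classes score matrix (simplex rows).
#' @slot assigned top-scoring class per protein.
#' @slot score the top score per protein.
#' @slot label final label: the assigned class, or `"unknown"` once a
#'   protein falls below its class score threshold.
#' @slot thresholds per-class score thresholds used (NA before
#'   thresholding or for unthresholded classes).
#' @slot isMarker logical; curated markers retain their label.
#' @slot params classifier parameters (e.g. sigma, cost, k, theta).
#' @aliases ClassificationResult-class
#' @exportClass ClassificationResult
setClass("ClassificationResult",
         representation(scores = "matrix", assigned = "character",
                        score = "numeric", label = "character",
                        thresholds = "numeric", isMarker = "logical",
                        params = "list"))

setValidity("ClassificationResult", function(object) {
  msg <- character()
  n <- nrow(object@scores)
  if (length(object@assigned) != n || length(object@score) != n ||
      length(object@label) != n || length(object@isMarker) != n)
    msg <- c(msg, "per-protein slots must match the score matrix rows")
  th <- object@thresholds
  lab <- object@label
  ok <- lab == "unknown" | object@isMarker |
    is.na(th[match(object@assigned, names(th))]) |
    object@score >= th[match(object@assigned, names(th))] - 1e-12
  if (!all(ok))
    msg <- c(msg, "labelled proteins must score at or above their class threshold")
  if (length(msg)) msg else TRUE
})

#' @describeIn ClassificationResult the proteins x classes score matrix
#' @param object a `ClassificationResult`
#' @export
setMethod("scoreMatrix", "ClassificationResult", function(object) object@scores)

#' @describeIn ClassificationResult top-scoring class per protein
#' @export
setMethod("assignedClass", "ClassificationResult", function(object)
  stats::setNames(object@assigned, rownames(object@scores)))

#' @describeIn ClassificationResult final (post-FDR) label per protein
#' @export
setMethod("finalLabel", "ClassificationResult", function(object)
  stats::setNames(object@label, rownames(object@scores)))

#' @describeIn ClassificationResult per-class score thresholds
#' @export
setMethod("classThresholds", "ClassificationResult", function(object)
  object@thresholds)

setMethod("show", "ClassificationResult", function(object) {
  cat("ClassificationResult:", nrow(object@scores), "proteins,",
      ncol(object@scores), "classes\n")
  cat("  markers:", sum(object@isMarker),
      "| classified:", sum(object@label != "unknown" & !object@isMarker),
      "| unknown:", sum(object@label == "unknown"), "\n")
  if (!all(is.na(object@thresholds)))
    cat("  thresholded at q =",
        if (!is.null(object@params$q)) object@params$q else "?", "\n")
})

#' TuneResult: cross-validated hyperparameter search summary
#'
#' @slot f1 outer macro-F1 per round (best grid point of that round).
#' @slot best data.frame of the selected grid point per round.
#' @slot gridF1 mean inner macro-F1 per grid point (averaged over rounds).
#' @slot selected the modal best grid point over rounds.
#' @aliases TuneResult-class
#' @exportClass TuneResult
setClass("TuneResult",
         representation(f1 = "numeric", best = "data.frame",
                        gridF1 = "data.frame", selected = "numeric"))

setMethod("show", "TuneResult", function(object) {
  cat("TuneResult over", length(object@f1), "rounds\n")
  cat("  macro F1: median", round(stats::median(object@f1), 4),
      " IQR", paste(round(stats::quantile(object@f1, c(.25, .75)), 4),
                    collapse = "-"), "\n")
  cat("  selected:", paste(names(object@selected), "=",
                           signif(object@selected, 4), collapse = ", "), "\n")
})

#' QSepResult: marker-cluster resolution distances
#'
#' Raw entry (i, j) is the mean Euclidean distance over all cross pairs
#' between marker clusters i and j (mean over unordered distinct pairs
#' within a cluster on the diagonal).  The normalised matrix divides
#' each entry by the reference within-cluster distance, so its diagonal
#' is exactly 1 and off-diagonal values say how many within-cluster
#' spreads separate two clusters; larger is better resolved.
#'
#' @slot raw,normalised C x C distance matrices.
#' @slot classes class order of the matrix rows/columns.
#' @slot orientation `"row"` or `"column"` reference convention.
#' @aliases QSepResult-class
#' @exportClass QSepResult
setClass("QSepResult",
         representation(raw = "matrix", normalised = "matrix",
                        classes = "character", orientation = "character"))

#' @describeIn QSepResult raw mean-distance matrix
#' @param object a `QSepResult`
#' @export
setMethod("qsepRaw", "QSepResult", function(object) object@raw)

#' @describeIn QSepResult normalised distance matrix
#' @export
setMethod("qsepNormalised", "QSepResult", function(object) object@normalised)

setMethod("show", "QSepResult", function(object) {
  s <- summarizeQSep(object@normalised)
  cat("QSepResult over", length(object@classes), "marker classes",
      sprintf("(%s-wise reference)\n", object@orientation))
  cat("  off-diagonal normalised distances: median",
      round(s$median, 3), " IQR", round(s$iqr, 3), "\n")
})

#' ThetaProfile: per-class transfer-learning weights
#'
#' The weight vector theta (one entry per organelle class, each in
#' [0, 1]) controls how much of the primary versus the auxiliary map is
#' used when classifying to that class: 1 means primary only, 0
#' auxiliary only, 0.5 an equal blend.
#'
#' @slot candidates the candidate weight set searched.
#' @slot bestWeights iterations x classes matrix of per-iteration best
#'   weight vectors.
#' @slot f1 macro-F1 of the best vector per iteration.
#' @slot medianWeights per-class interpolating median of the best
#'   weights.
#' @slot classes class names.
#' @slot k nearest-neighbour counts used (primary, auxiliary).
#' @aliases ThetaProfile-class
#' @exportClass ThetaProfile
setClass("ThetaProfile",
         representation(candidates = "numeric", bestWeights = "matrix",
                        f1 = "numeric", medianWeights = "numeric",
                        classes = "character", k = "integer"))

#' @describeIn ThetaProfile per-iteration best weight vectors
#' @param object a `ThetaProfile`
#' @export
setMethod("thetaWeights", "ThetaProfile", function(object) object@bestWeights)

#' @describeIn ThetaProfile per-class median weight vector
#' @export
setMethod("medianTheta", "ThetaProfile", function(object) object@medianWeights)

setMethod("show", "ThetaProfile", function(object) {
  cat("ThetaProfile:", nrow(object@bestWeights), "iterations,",
      length(object@classes), "classes, k =",
      paste(object@k, collapse = "/"), "\n")
  print(round(object@medianWeights, 3))
})

#' Pwf: probability weight function for selection-bias correction
#'
#' Estimated probability that a protein is selected (e.g. remains
#' unclassified) as a monotone function of log abundance, fitted by
#' weighted isotonic regression.  Used to draw abundance-matched null
#' sets in the category over-representation test.
#'
#' @slot weights per-protein fitted selection probability, named by
#'   accession.
#' @slot xKnots,yKnots the monotone step function over log abundance.
#' @slot direction `"increasing"` or `"decreasing"` in abundance.
#' @slot rate overall selection rate (equals the mean fitted weight).
#' @aliases Pwf-class
#' @exportClass Pwf
setClass("Pwf",
         representation(weights = "numeric", xKnots = "numeric",
                        yKnots = "numeric", direction = "character",
                        rate = "numeric"))

setMethod("show", "Pwf", function(object) {
  cat("Pwf over", length(object@weights), "proteins (",
      object@direction, "in abundance )\n")
  cat("  selection rate:", round(object@rate, 4),
      "| weight range:", paste(round(range(object@weights), 4),
                               collapse = " - "), "\n")
})
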