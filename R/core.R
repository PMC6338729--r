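#' Read a protein (or PSM) quantitation table
#'
#' Parses a delimited table of reporter quantitation values into a
#' [ProfileSet-class].  Missing cells (empty or `NA`) are preserved as
#' missing, never as zero; the full-reporter-series filter
#' ([filterCompleteProfiles()]) decides their fate later.
#'
#' @param path file path.
#' @param sep field delimiter (default tab).
#' @param idColumn name or index of the accession column (default first
#'   column).
#' @param channelColumns names (or indices) of the quantitation columns;
#'   default: every column except the accession column.
#' @param channelInfo optional per-channel `data.frame` (columns
#'   `replicate`, `fraction`) or path to a TSV with columns
#'   `channel`, `replicate`, `fraction`.
#'
#' @return a [ProfileSet-class].
#' @export
readProfileTable <- function(path, sep = "\t", idColumn = 1L,
                             channelColumns = NULL, channelInfo = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""), colClasses = "character",
                           comment.char = "")
  if (is.numeric(idColumn)) idColumn <- colnames(tab)[idColumn]
  if (!idColumn %in% colnames(tab))
    stop("ID column not found: ", idColumn)
  if (is.null(channelColumns)) {
    channelColumns <- setdiff(colnames(tab), idColumn)
  } else if (is.numeric(channelColumns)) {
    channelColumns <- colnames(tab)[channelColumns]
  }
  missingCols <- setdiff(channelColumns, colnames(tab))
  if (length(missingCols))
    stop("channel columns not found: ", paste(missingCols, collapse = ", "))
  acc <- tab[[idColumn]]
  dup <- unique(acc[duplicated(acc)])
  if (length(dup))
    stop("duplicated accessions: ", paste(dup, collapse = ", "))
  m <- matrix(NA_real_, nrow(tab), length(channelColumns),
              dimnames = list(acc, channelColumns))
  for (j in seq_along(channelColumns)) {
    v <- tab[[channelColumns[j]]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(num))
    if (length(bad))
      stop(sprintf("non-numeric value '%s' in row %d, column '%s'",
                   v[bad[1]], bad[1], channelColumns[j]))
    m[, j] <- num
  }
  if (is.character(channelInfo) && length(channelInfo) == 1)
    channelInfo <- readChannelInfo(channelInfo)
  ProfileSet(m, channelInfo = channelInfo)
}

#' Read per-channel metadata (channel, replicate, fraction)
#' @param path TSV with columns `channel`, `replicate`, `fraction`.
#' @return `data.frame` keyed by channel name.
#' @export
readChannelInfo <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("channel", "replicate", "fraction")
  if (!all(need %in% colnames(tab)))
    stop("channel metadata needs columns: ", paste(need, collapse = ", "))
  rownames(tab) <- tab$channel
  tab[, c("replicate", "fraction"), drop = FALSE]
}

#' Read a two-column marker file (accession, class)
#' @param path TSV with columns `accession` and `class` (a header is
#'   expected).
#' @param classes optional ordered class list.
#' @return a [MarkerAnnotation-class].
#' @export
readMarkerAnnotation <- function(path, classes = NULL) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("marker file must have two columns")
  MarkerAnnotation(stats::setNames(tab[[2]], tab[[1]]), classes = classes)
}

#' Write a ProfileSet as a delimited table
#' @param object a `ProfileSet`.
#' @param path output path.
#' @param sep delimiter.
#' @export
writeProfileTable <- function(object, path, sep = "\t") {
  m <- profileMatrix(object)
  df <- data.frame(accession = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Sum-normalise rows to relative abundances
#'
#' Divides every row by its total so each profile becomes a vector of
#' relative reporter abundances summing to one (applied to each PSM
#' before protein-group aggregation, mirroring standard TMT reporter
#' processing).  Idempotent.  Missing cells are ignored in the sum and
#' preserved.
#'
#' @param object numeric matrix or `ProfileSet`.
#' @return object of the same kind with rows summing to 1.
#' @examples
#' sumNormalizeRows(matrix(c(1, 3), 1, 2,
#'                         dimnames = list("P1", c("a", "b"))))
#' @export
setMethod("sumNormalizeRows", "matrix", function(object) {
  rs <- rowSums(object, na.rm = TRUE)
  bad <- which(rs <= 0 | !is.finite(rs))
  if (length(bad)) {
    id <- if (!is.null(rownames(object))) rownames(object)[bad] else bad
    stop("rows with non-positive total: ", paste(id, collapse = ", "))
  }
  object / rs
})

#' @rdname sumNormalizeRows-matrix-method
#' @export
setMethod("sumNormalizeRows", "ProfileSet", function(object) {
  m <- sumNormalizeRows(profileMatrix(object))
  SummarizedExperiment::assay(object, "profile") <- m
  object
})

#' Aggregate PSM rows into protein groups by channel-wise medians
#'
#' Each protein group's quantitation value per channel is the median of
#' the sum-normalised PSM values belonging to that group.  No
#' renormalisation is applied after aggregation (optionally re-enable
#' per replicate block with `renormalize = TRUE`).
#'
#' @param psm numeric matrix of sum-normalised PSM profiles.
#' @param groups per-row protein group label.
#' @param channelInfo optional channel metadata passed to the result.
#' @param renormalize if `TRUE`, re-apply sum-normalisation per
#'   replicate block after aggregation (off by default).
#' @return a [ProfileSet-class] with one row per group, in order of
#'   first appearance.
#' @export
aggregateProteinGroups <- function(psm, groups, channelInfo = NULL,
                                   renormalize = FALSE) {
  psm <- as.matrix(psm)
  groups <- as.character(groups)
  if (!length(groups)) stop("groups must be non-empty")
  if (length(groups) != nrow(psm))
    stop("one group label per PSM row required")
  ug <- unique(groups)
  out <- matrix(NA_real_, length(ug), ncol(psm),
                dimnames = list(ug, colnames(psm)))
  idx <- split(seq_along(groups), factor(groups, levels = ug))
  for (g in seq_along(ug)) {
    sub <- psm[idx[[g]], , drop = FALSE]
    out[g, ] <- apply(sub, 2, stats::median, na.rm = TRUE)
  }
  out[is.nan(out)] <- NA_real_
  ps <- ProfileSet(out, channelInfo = channelInfo)
  if (renormalize) ps <- normalizePerReplicate(ps)
  ps
}

#' Sum-normalise each replicate block of a ProfileSet
#'
#' Renormalises every row within each replicate's channel block so the
#' block sums to 1.
#' @param object a `ProfileSet`.
#' @return a `ProfileSet`.
#' @export
normalizePerReplicate <- function(object) {
  m <- profileMatrix(object)
  rep <- channelInfo(object)$replicate
  for (r in unique(rep)) {
    cols <- which(rep == r)
    m[, cols] <- sumNormalizeRows(m[, cols, drop = FALSE])
  }
  SummarizedExperiment::assay(object, "profile") <- m
  object
}

#' Keep only proteins with a full reporter ion series
#'
#' Removes every row containing at least one missing quantitation value
#' in any channel of any replicate; row order is otherwise preserved.
#'
#' @param object a `ProfileSet`.
#' @return the filtered `ProfileSet`; the number of removed rows is
#'   reported via `message()` and a warning is raised if nothing
#'   survives.
#' @export
filterCompleteProfiles <- function(object) {
  m <- profileMatrix(object)
  keep <- rowSums(is.na(m)) == 0
  message(sum(!keep), " of ", nrow(m),
          " proteins removed (incomplete reporter series)")
  if (!any(keep))
    warning("no complete profiles remain")
  object[keep, ]
}

#' Drop named channels (e.g. low-intensity TMT channels)
#'
#' Removes channels flagged by the user, such as reporter channels with
#' extremely low ion intensity.  Detection of such channels is left to
#' the analyst; only an explicit list is honoured.
#'
#' @param object a `ProfileSet`.
#' @param channels channel names or indices to remove.
#' @return the reduced `ProfileSet`.
#' @export
dropChannels <- function(object, channels) {
  if (!length(channels)) return(object)
  nm <- colnames(object)
  if (is.numeric(channels)) {
    bad <- channels[channels < 1 | channels > length(nm)]
    if (length(bad)) stop("unknown channel index: ",
                          paste(bad, collapse = ", "))
    channels <- nm[channels]
  }
  bad <- setdiff(channels, nm)
  if (length(bad)) stop("unknown channel: ", paste(bad, collapse = ", "))
  keep <- setdiff(nm, channels)
  if (!length(keep)) stop("cannot drop all channels")
  object[, keep]
}

#' Remove contaminant proteins by accession
#'
#' Drops rows whose accession appears in a user-supplied contaminant
#' list (e.g. a cRAP accession file); the list is supplied by the user
#' because contaminant databases are version-dependent.
#'
#' @param object a `ProfileSet`.
#' @param contaminants character vector of accessions.
#' @return the reduced `ProfileSet`.
#' @export
removeContaminants <- function(object, contaminants) {
  keep <- !(rownames(object) %in% contaminants)
  object[keep, ]
}

#' Concatenate replicate ProfileSets over shared proteins
#'
#' Restricts all replicates to the intersection of their accessions and
#' concatenates channels; the replicate id of every channel records its
#' dataset of origin.  Feature metadata are merged and curated marker
#' labels must agree across replicates.  Accessions are joined as exact
#' strings: protein isoforms (distinct accessions) remain distinct
#' features.
#'
#' @param datasets list of complete (no missing values) `ProfileSet`s.
#' @return the concatenated `ProfileSet`.
#' @export
concatenateReplicates <- function(datasets) {
  if (inherits(datasets, "ProfileSet")) datasets <- list(datasets)
  if (!length(datasets)) stop("no datasets supplied")
  if (length(datasets) == 1L) return(datasets[[1]])
  for (d in datasets)
    if (anyNA(profileMatrix(d)))
      stop("replicates must be complete before concatenation")
  shared <- Reduce(intersect, lapply(datasets, rownames))
  if (!length(shared)) stop("empty accession intersection across replicates")
  mats <- vector("list", length(datasets))
  cinfos <- vector("list", length(datasets))
  finfo <- NULL
  for (i in seq_along(datasets)) {
    d <- datasets[[i]][shared, ]
    mats[[i]] <- profileMatrix(d)
    ci <- channelInfo(d)
    ci$replicate <- i
    rownames(ci) <- colnames(mats[[i]]) <-
      paste0("R", i, ".", colnames(mats[[i]]))
    cinfos[[i]] <- ci
    fi <- featureInfo(d)
    if (is.null(finfo)) {
      finfo <- fi
    } else {
      conflict <- finfo$markerClass != fi$markerClass &
        finfo$markerClass != "unknown" & fi$markerClass != "unknown"
      if (any(conflict))
        stop("conflicting marker labels for: ",
             paste(shared[conflict], collapse = ", "))
      take <- finfo$markerClass == "unknown" & fi$markerClass != "unknown"
      finfo$markerClass[take] <- fi$markerClass[take]
      for (cn in setdiff(colnames(fi), colnames(finfo)))
        finfo[[cn]] <- fi[[cn]]
    }
  }
  common <- Reduce(intersect, lapply(cinfos, colnames))
  ProfileSet(do.call(cbind, mats),
             channelInfo = do.call(rbind, lapply(cinfos, function(x)
               x[, common, drop = FALSE])),
             featureInfo = finfo)
}

#' Attach marker annotation to a ProfileSet
#'
#' Writes curated marker classes into the feature metadata
#' (`markerClass`); proteins without a marker label become `"unknown"`.
#' Markers absent from the dataset are ignored.
#'
#' @param object a `ProfileSet`.
#' @param markers a `MarkerAnnotation`.
#' @return the annotated `ProfileSet`.
#' @export
setMarkers <- function(object, markers) {
  lab <- markerLabels(markers)
  mc <- rep("unknown", nrow(object))
  hit <- match(rownames(object), names(lab))
  mc[!is.na(hit)] <- lab[hit[!is.na(hit)]]
  SummarizedExperiment::rowData(object)$markerClass <- mc
  object
}

#' Merge fine marker classes into coarser ones
#'
#' Relabels marker classes according to a fine-to-coarse merge map, e.g.
#' merging nucleus and chromatin into nucleus/chromatin and the two
#' ribosomal subunits into a single ribosome class turns a 12-class
#' annotation into the 10-class annotation used for differential
#' centrifugation maps.
#'
#' @param markers a `MarkerAnnotation`.
#' @param mergeMap named character vector, fine class -> coarse class.
#' @return the merged `MarkerAnnotation`.
#' @examples
#' m <- MarkerAnnotation(c(P1 = "nucleus", P2 = "chromatin"))
#' mergeMarkerClasses(m, c(nucleus = "nucleus/chromatin",
#'                         chromatin = "nucleus/chromatin"))
#' @export
mergeMarkerClasses <- function(markers, mergeMap) {
  if (!length(mergeMap)) return(markers)
  bad <- setdiff(names(mergeMap), markers@classes)
  if (length(bad))
    stop("merge map references unknown class: ", paste(bad, collapse = ", "))
  lab <- markerLabels(markers)
  hit <- match(lab, names(mergeMap))
  lab[!is.na(hit)] <- mergeMap[hit[!is.na(hit)]]
  cls <- markers@classes
  cls[cls %in% names(mergeMap)] <- mergeMap[cls[cls %in% names(mergeMap)]]
  cls <- cls[!duplicated(cls)]
  MarkerAnnotation(lab, classes = cls)
}

#' Principal component projection of profiles
#'
#' Mean-centred (never variance-scaled: profiles already share a common
#' ratio scale) singular value decomposition of the profile matrix.
#' The sign of each component is fixed so that its largest-magnitude
#' loading is positive, making projections reproducible across runs.
#'
#' @param object a complete `ProfileSet`.
#' @param nComponents number of components to keep (default: all).
#' @return a [PcaResult-class].
#' @export
pcaProject <- function(object, nComponents = NULL) {
  m <- profileMatrix(object)
  if (anyNA(m)) stop("dataset must be complete (no missing values)")
  maxComp <- min(dim(m))
  if (is.null(nComponents)) nComponents <- maxComp
  if (nComponents < 1) stop("nComponents must be at least 1")
  if (nComponents > maxComp)
    stop("nComponents exceeds min(proteins, channels) = ", maxComp)
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  totVar <- sum(pc$sdev^2)
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  scores <- sweep(pc$x, 2, flip, "*")[, seq_len(nComponents), drop = FALSE]
  loadings <- sweep(pc$rotation, 2, flip, "*")[, seq_len(nComponents),
                                               drop = FALSE]
  new("PcaResult", scores = scores, loadings = loadings,
      varianceFraction = (pc$sdev^2 / totVar)[seq_len(nComponents)],
      center = pc$center)
}

#' Write PCA scores with variance fractions in a header comment
#' @param pca a `PcaResult`.
#' @param path output TSV path.
#' @export
writePcaScores <- function(pca, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# variance fraction: ",
                    paste(signif(pca@varianceFraction, 6), collapse = "\t")),
             con)
  df <- data.frame(accession = rownames(pca@scores), pca@scores,
                   check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Cross-map agreement of localisation assignments
#'
#' Builds the contingency table between the final labels of two
#' classification results over the proteins classified in both, after
#' mapping the second result's class vocabulary onto the first's (e.g.
#' chromatin -> nucleus/chromatin when comparing a 12-class map to a
#' 10-class map).  Agreement is the percentage of proteins assigned to
#' matching classes, reported both with and without curated markers.
#'
#' @param resultA,resultB `ClassificationResult`s sharing proteins.
#' @param classMap named character vector mapping B's classes onto A's
#'   (identity for unmapped classes).
#' @return list with `table` (A classes x mapped B classes), `n`,
#'   `agreement` (percent, markers included), `nNonMarker` and
#'   `agreementNonMarker` (markers excluded; `NA` if no non-marker
#'   proteins are shared).
#' @export
agreementMatrix <- function(resultA, resultB, classMap = NULL) {
  accA <- rownames(scoreMatrix(resultA))
  accB <- rownames(scoreMatrix(resultB))
  labA <- finalLabel(resultA)
  labB <- finalLabel(resultB)
  shared <- intersect(accA[labA != "unknown"], accB[labB != "unknown"])
  if (!length(shared)) stop("no proteins classified in both results")
  a <- labA[shared]
  b <- labB[shared]
  if (!is.null(classMap)) {
    hit <- match(b, names(classMap))
    b[!is.na(hit)] <- classMap[hit[!is.na(hit)]]
  }
  lev <- union(unique(a), unique(b))
  tab <- table(factor(a, levels = lev), factor(b, levels = lev),
               dnn = c("A", "B"))
  agree <- 100 * mean(a == b)
  isM <- resultA@isMarker[match(shared, accA)] |
    resultB@isMarker[match(shared, accB)]
  nm <- shared[!isM]
  list(table = tab, n = length(shared), agreement = agree,
       nNonMarker = length(nm),
       agreementNonMarker = if (length(nm))
         100 * mean(a[!isM] == b[!isM]) else NA_real_)
}
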