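#' Raw mean-distance matrix between marker clusters
#'
#' Entry (i, j), i != j, is the mean Euclidean distance over all cross
#' pairs of markers in classes i and j; the diagonal entry (i, i) is
#' the mean over unordered distinct pairs within class i (self
#' distances excluded — including them would deflate the within-cluster
#' reference).  Markers absent from the dataset are dropped from their
#' cluster with a message.
#'
#' @param dataset a complete `ProfileSet`.
#' @param markers a `MarkerAnnotation`; every class must retain at
#'   least 2 markers present in the dataset.
#' @return symmetric nonnegative C x C matrix.
#' @export
clusterDistanceMatrix <- function(dataset, markers) {
  lab <- markerLabels(markers)
  present <- intersect(names(lab), rownames(dataset))
  dropped <- length(lab) - length(present)
  if (dropped > 0)
    message(dropped, " marker(s) absent from the dataset were dropped")
  labels <- as.character(lab[present])
  classes <- markerClasses(markers)
  classes <- classes[classes %in% labels]
  cnt <- table(factor(labels, levels = classes))
  bad <- names(cnt)[cnt < 2]
  if (length(bad) || length(setdiff(markerClasses(markers), classes)))
    stop("marker class with fewer than 2 markers present: ",
         paste(union(bad, setdiff(markerClasses(markers), classes)),
               collapse = ", "))
  X <- profileMatrix(dataset)[present, , drop = FALSE]
  if (anyNA(X)) stop("dataset must be complete (no missing values)")
  D <- as.matrix(stats::dist(X))
  out <- matrix(0, length(classes), length(classes),
                dimnames = list(classes, classes))
  idx <- split(seq_along(labels), factor(labels, levels = classes))
  for (i in seq_along(classes)) {
    di <- D[idx[[i]], idx[[i]], drop = FALSE]
    out[i, i] <- mean(di[upper.tri(di)])
    if (i < length(classes)) {
      for (j in seq(i + 1, length(classes))) {
        out[i, j] <- out[j, i] <- mean(D[idx[[i]], idx[[j]]])
      }
    }
  }
  out
}

#' Normalise a QSep distance matrix by its within-cluster reference
#'
#' Divides each entry by the reference within-cluster average distance.
#' The convention here is row-wise: entry (i, j) is divided by the
#' within distance of row class i, giving an asymmetric matrix whose
#' diagonal is exactly 1 (`orientation = "column"` uses the column
#' class instead).  Ratios are invariant to a global rescaling of all
#' profiles.
#'
#' @param raw raw matrix from [clusterDistanceMatrix()].
#' @param orientation `"row"` (default) or `"column"` reference.
#' @return the normalised matrix.
#' @export
normalizeQSep <- function(raw, orientation = c("row", "column")) {
  orientation <- match.arg(orientation)
  d <- diag(raw)
  if (any(d <= 0))
    stop("degenerate cluster(s) with zero within-cluster distance: ",
         paste(rownames(raw)[d <= 0], collapse = ", "))
  sweep(raw, if (orientation == "row") 1 else 2, d, "/")
}

#' Summarise a normalised QSep matrix
#'
#' @param normalised normalised matrix (or a `QSepResult`).
#' @return list with `perClassMin` (each class's smallest normalised
#'   distance to any other class — the resolution bottleneck), and the
#'   pooled off-diagonal `median`, `iqr` and `quartiles`.
#' @export
summarizeQSep <- function(normalised) {
  if (is(normalised, "QSepResult")) normalised <- qsepNormalised(normalised)
  if (nrow(normalised) < 2) stop("at least two classes required")
  off <- normalised
  diag(off) <- NA
  perClassMin <- apply(off, 1, min, na.rm = TRUE)
  vals <- off[!is.na(off)]
  q <- stats::quantile(vals, c(0.25, 0.5, 0.75))
  list(perClassMin = perClassMin, median = unname(q[2]),
       iqr = unname(q[3] - q[1]), quartiles = q)
}

#' Experiment-wide resolution assessment (QSep)
#'
#' Quantifies how well an experiment separates its subcellular niches
#' by comparing average Euclidean distances within and between marker
#' clusters, each between-cluster distance expressed in units of the
#' reference within-cluster spread.
#'
#' @inheritParams clusterDistanceMatrix
#' @param orientation reference convention for [normalizeQSep()].
#' @return a [QSepResult-class].
#' @export
qsep <- function(dataset, markers, orientation = c("row", "column")) {
  orientation <- match.arg(orientation)
  raw <- clusterDistanceMatrix(dataset, markers)
  new("QSepResult", raw = raw,
      normalised = normalizeQSep(raw, orientation),
      classes = rownames(raw), orientation = orientation)
}
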