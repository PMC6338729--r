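# Matrix-level k-NN class scores: fraction of the k nearest labelled
# rows (Euclidean distance) belonging to each class.  Neighbour ties at
# rank k are broken by ascending accession so results are deterministic.
.knnScoresMatrix <- function(Xmark, labels, Xq, k, classes) {
  n <- nrow(Xmark)
  if (k < 1) stop("k must be at least 1")
  if (k > n) stop("k exceeds the number of markers (", n, ")")
  acc <- rownames(Xmark)
  out <- matrix(0, nrow(Xq), length(classes),
                dimnames = list(rownames(Xq), classes))
  # squared Euclidean distances, queries x markers
  d2 <- outer(rowSums(Xq^2), rowSums(Xmark^2), "+") - 2 * Xq %*% t(Xmark)
  for (r in seq_len(nrow(Xq))) {
    nb <- order(d2[r, ], acc)[seq_len(k)]
    tab <- table(factor(labels[nb], levels = classes))
    out[r, ] <- as.numeric(tab) / k
  }
  out
}

#' k-nearest-neighbour class scores
#'
#' For each query protein, the score of class c is the fraction of its
#' k nearest marker neighbours (Euclidean distance over the full
#' concatenated-replicate profile) labelled c; scores sum to 1.
#'
#' @param dataset a complete `ProfileSet`.
#' @param markers a `MarkerAnnotation` (markers must be present in the
#'   dataset).
#' @param query accessions to score; default all non-marker proteins.
#' @param k number of neighbours.
#' @return query x classes score matrix (rows on the simplex).
#' @export
knnClassScores <- function(dataset, markers, query = NULL, k = 5) {
  mm <- .markerMatrix(dataset, markers)
  X <- profileMatrix(dataset)
  if (is.null(query)) query <- setdiff(rownames(X), names(mm$labels))
  missing <- setdiff(query, rownames(X))
  if (length(missing))
    stop("query accessions absent from dataset: ",
         paste(utils::head(missing, 5), collapse = ", "))
  .knnScoresMatrix(mm$X, mm$labels, X[query, , drop = FALSE], k, mm$classes)
}

#' Combine primary and auxiliary class scores with per-class weights
#'
#' The combined score for class c is
#' `theta_c * primary_c + (1 - theta_c) * auxiliary_c`; theta = 1 uses
#' the primary map only, 0 the auxiliary only.  The prediction is the
#' arg-max class with a deterministic lexicographic tie-break.  With a
#' uniform theta the combined rows remain on the simplex; per-class
#' weights generally do not renormalise.
#'
#' @param primary,auxiliary score matrices with identical rows and
#'   class columns.
#' @param theta scalar or per-class weight vector in [0, 1] (aligned
#'   with the columns; names are checked when present).
#' @return list with `scores` and `prediction`.
#' @export
combineScores <- function(primary, auxiliary, theta) {
  if (!identical(dim(primary), dim(auxiliary)) ||
      !identical(colnames(primary), colnames(auxiliary)))
    stop("primary and auxiliary scores must share classes and proteins")
  nc <- ncol(primary)
  if (length(theta) == 1) theta <- rep(theta, nc)
  if (length(theta) != nc) stop("one theta weight per class required")
  if (!is.null(names(theta))) {
    if (!setequal(names(theta), colnames(primary)))
      stop("theta names do not match the class columns")
    theta <- theta[colnames(primary)]
  }
  if (any(theta < 0 | theta > 1)) stop("theta weights must lie in [0, 1]")
  comb <- sweep(primary, 2, theta, "*") +
    sweep(auxiliary, 2, 1 - theta, "*")
  list(scores = comb, prediction = stats::setNames(.argmaxLex(comb),
                                                   rownames(comb)))
}

#' Cross-validated choice of the number of nearest neighbours
#'
#' Macro F1 of k-NN marker classification per candidate k over
#' `rounds` stratified test/train partitions; returns the modal best k
#' (ties towards smaller k).
#'
#' @param dataset a complete `ProfileSet`.
#' @param markers a `MarkerAnnotation`.
#' @param kGrid candidate neighbour counts.
#' @param rounds,folds cross-validation layout (default 100 x 5).
#' @param seed integer; round r uses `seed + r`.
#' @return list with `bestK`, per-round winners `best` and the
#'   rounds x k macro-F1 matrix `f1`.
#' @export
tuneK <- function(dataset, markers, kGrid = c(3, 5, 7, 9, 11, 15),
                  rounds = 100, folds = 5, seed = 1) {
  if (!length(kGrid)) stop("empty k grid")
  mm <- .markerMatrix(dataset, markers)
  .checkMarkerClasses(mm$labels, folds)
  labels <- mm$labels
  f1 <- matrix(0, rounds, length(kGrid),
               dimnames = list(NULL, paste0("k", kGrid)))
  bestPerRound <- integer(rounds)
  for (r in seq_len(rounds)) {
    set.seed(seed + r)
    fold <- .stratifiedFolds(labels, folds)
    testIdx <- which(fold == 1L)
    trainIdx <- which(fold != 1L)
    for (g in seq_along(kGrid)) {
      sc <- .knnScoresMatrix(mm$X[trainIdx, , drop = FALSE],
                             labels[trainIdx],
                             mm$X[testIdx, , drop = FALSE],
                             kGrid[g], mm$classes)
      f1[r, g] <- macroF1(labels[testIdx], .argmaxLex(sc), mm$classes)
    }
    bestPerRound[r] <- kGrid[which.max(f1[r, ])]  # ties: smallest k first
  }
  tab <- table(bestPerRound)
  bestK <- as.integer(names(tab)[which.max(tab)])
  list(bestK = bestK, best = bestPerRound, f1 = f1)
}

# Order candidate theta vectors by preference: higher total weight
# first (prefer the primary map on ties), then lexicographically larger.
.thetaPreference <- function(thetaMat) {
  args <- c(list(rowSums(thetaMat)),
            lapply(seq_len(ncol(thetaMat)), function(j) thetaMat[, j]))
  do.call(order, c(args, list(decreasing = TRUE)))
}

# Macro F1 of every theta row given per-fold score matrices; vectorised
# over the candidate grid.
.evalThetaGrid <- function(thetaMat, P, A, truth, classes) {
  vapply(seq_len(nrow(thetaMat)), function(t) {
    comb <- sweep(P, 2, thetaMat[t, ], "*") +
      sweep(A, 2, 1 - thetaMat[t, ], "*")
    macroF1(truth, .argmaxLex(comb), classes)
  }, numeric(1))
}

#' Optimise per-class transfer-learning weights
#'
#' For each iteration, the markers shared between the primary and the
#' auxiliary map are split into stratified test/train partitions;
#' held-out markers receive k-NN class scores from both maps and every
#' candidate weight vector is assessed by the macro F1 of the combined
#' prediction.  The best vector per iteration is recorded (ties resolve
#' towards larger weights, preferring the higher-resolution primary
#' map) and the per-class interpolating median over iterations is the
#' headline weight vector, so medians such as 0.75 can arise from the
#' candidate set {0, 0.5, 1}.
#'
#' The exhaustive search covers `length(candidates)^nClasses`
#' combinations when that count is within `budget`; otherwise a
#' coordinate-ascent sweep (classes visited in random order, at most 5
#' sweeps) is used.
#'
#' @param primary,auxiliary complete `ProfileSet`s sharing marker
#'   accessions.
#' @param markers a `MarkerAnnotation`.
#' @param candidates candidate weight set (default {0, 0.5, 1}).
#' @param iterations iterations (default 100).
#' @param folds stratified folds per iteration (default 5).
#' @param kPrimary,kAuxiliary neighbour counts (default 5 and 5).
#' @param seed integer; iteration i uses `seed + i`.
#' @param budget maximal exhaustive grid size (default 10000).
#' @param mode `"auto"`, `"exhaustive"` or `"coordinate"`.
#' @return a [ThetaProfile-class].
#' @export
optimizeTheta <- function(primary, auxiliary, markers,
                          candidates = c(0, 0.5, 1), iterations = 100,
                          folds = 5, kPrimary = 5, kAuxiliary = 5, seed = 1,
                          budget = 10000,
                          mode = c("auto", "exhaustive", "coordinate")) {
  mode <- match.arg(mode)
  if (!length(candidates)) stop("empty candidate set")
  if (any(candidates < 0 | candidates > 1))
    stop("candidate weights must lie in [0, 1]")
  candidates <- sort(unique(candidates))
  lab <- markerLabels(markers)
  shared <- intersect(intersect(names(lab), rownames(primary)),
                      rownames(auxiliary))
  if (!length(shared)) stop("no shared marker proteins between the maps")
  labels <- stats::setNames(as.character(lab[shared]), shared)
  classes <- markerClasses(markers)
  classes <- classes[classes %in% labels]
  .checkMarkerClasses(labels, folds)
  Xp <- profileMatrix(primary)[shared, , drop = FALSE]
  Xa <- profileMatrix(auxiliary)[shared, , drop = FALSE]
  nCls <- length(classes)
  nComb <- length(candidates)^nCls
  exhaustive <- switch(mode, exhaustive = TRUE, coordinate = FALSE,
                       auto = nComb <= budget)
  if (exhaustive && nComb > budget)
    stop("exhaustive grid of ", nComb, " combinations exceeds budget ",
         budget)
  grid <- NULL
  if (exhaustive) {
    grid <- as.matrix(expand.grid(rep(list(candidates), nCls)))
    colnames(grid) <- classes
    grid <- grid[.thetaPreference(grid), , drop = FALSE]
  }
  bestW <- matrix(NA_real_, iterations, nCls,
                  dimnames = list(NULL, classes))
  bestF1 <- numeric(iterations)
  for (i in seq_len(iterations)) {
    set.seed(seed + i)
    fold <- .stratifiedFolds(labels, folds)
    testIdx <- which(fold == 1L)
    trainIdx <- which(fold != 1L)
    P <- .knnScoresMatrix(Xp[trainIdx, , drop = FALSE], labels[trainIdx],
                          Xp[testIdx, , drop = FALSE], kPrimary, classes)
    A <- .knnScoresMatrix(Xa[trainIdx, , drop = FALSE], labels[trainIdx],
                          Xa[testIdx, , drop = FALSE], kAuxiliary, classes)
    truth <- labels[testIdx]
    if (exhaustive) {
      f1 <- .evalThetaGrid(grid, P, A, truth, classes)
      pick <- which.max(f1)  # grid is preference-ordered: first max wins
      bestW[i, ] <- grid[pick, ]
      bestF1[i] <- f1[pick]
    } else {
      theta <- rep(1, nCls)
      f1cur <- .evalThetaGrid(matrix(theta, 1), P, A, truth, classes)
      for (sweepIdx in seq_len(5)) {
        changed <- FALSE
        for (cl in sample.int(nCls)) {
          cand <- matrix(rep(theta, each = length(candidates)),
                         length(candidates))
          cand[, cl] <- candidates
          cand <- cand[.thetaPreference(cand), , drop = FALSE]
          f1c <- .evalThetaGrid(cand, P, A, truth, classes)
          pick <- which.max(f1c)
          if (f1c[pick] > f1cur ||
              (f1c[pick] == f1cur && cand[pick, cl] > theta[cl])) {
            if (!identical(cand[pick, ], theta)) changed <- TRUE
            theta <- cand[pick, ]
            f1cur <- f1c[pick]
          }
        }
        if (!changed) break
      }
      bestW[i, ] <- theta
      bestF1[i] <- f1cur
    }
  }
  med <- apply(bestW, 2, stats::median)
  new("ThetaProfile", candidates = candidates, bestWeights = bestW,
      f1 = bestF1, medianWeights = med, classes = classes,
      k = as.integer(c(kPrimary, kAuxiliary)))
}

#' Classify proteins by theta-weighted map integration
#'
#' Scores every query protein from both maps by k-NN against the shared
#' markers and combines the two score vectors with the per-class theta
#' weights.  Proteins present in only one map are scored from that map
#' alone and flagged.
#'
#' @param primary,auxiliary complete `ProfileSet`s.
#' @param markers a `MarkerAnnotation`.
#' @param theta per-class weights (e.g. [medianTheta()] of an
#'   [optimizeTheta()] run), or a scalar.
#' @param kPrimary,kAuxiliary neighbour counts.
#' @param query accessions to classify; default: all non-marker
#'   proteins found in either map.
#' @return a [ClassificationResult-class]; the `params` carry `theta`
#'   and a per-protein `source` flag ("both", "primary-only",
#'   "auxiliary-only").
#' @export
transferClassify <- function(primary, auxiliary, markers, theta,
                             kPrimary = 5, kAuxiliary = 5, query = NULL) {
  lab <- markerLabels(markers)
  if (is.null(query))
    query <- setdiff(union(rownames(primary), rownames(auxiliary)),
                     names(lab))
  inP <- query %in% rownames(primary)
  inA <- query %in% rownames(auxiliary)
  if (any(!inP & !inA))
    stop("query accessions absent from both maps")
  classes <- markerClasses(markers)
  if (length(theta) == 1) theta <- rep(theta, length(classes))
  if (is.null(names(theta))) names(theta) <- classes
  qBoth <- query[inP & inA]
  scores <- matrix(NA_real_, length(query), length(classes),
                   dimnames = list(query, classes))
  source <- ifelse(inP & inA, "both",
                   ifelse(inP, "primary-only", "auxiliary-only"))
  if (length(qBoth)) {
    P <- knnClassScores(primary, markers, qBoth, kPrimary)
    A <- knnClassScores(auxiliary, markers, qBoth, kAuxiliary)
    scores[qBoth, ] <- combineScores(P, A, theta[classes])$scores
  }
  qP <- query[inP & !inA]
  if (length(qP))
    scores[qP, ] <- knnClassScores(primary, markers, qP, kPrimary)
  qA <- query[!inP & inA]
  if (length(qA))
    scores[qA, ] <- knnClassScores(auxiliary, markers, qA, kAuxiliary)
  assigned <- .argmaxLex(scores)
  topScore <- scores[cbind(seq_along(query), match(assigned, classes))]
  new("ClassificationResult", scores = scores, assigned = assigned,
      score = topScore, label = assigned,
      thresholds = stats::setNames(rep(NA_real_, length(classes)), classes),
      isMarker = rep(FALSE, length(query)),
      params = list(method = "knntl", theta = theta,
                    k = c(kPrimary, kAuxiliary),
                    source = stats::setNames(source, query)))
}
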