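#' Macro-averaged F1 score
#'
#' Per-class F1 is the harmonic mean of precision and recall,
#' 2PR/(P+R), with 0 substituted when undefined (a class never
#' predicted and never present contributes 0); macro F1 is the
#' unweighted mean over classes.
#'
#' @param truth,predicted equal-length label vectors.
#' @param classes class list defining the average (default: classes
#'   present in `truth`).
#' @return value in [0, 1].
#' @examples
#' macroF1(c("A", "A", "B", "B"), c("A", "B", "B", "B"))  # 0.7333...
#' @export
macroF1 <- function(truth, predicted, classes = NULL) {
  if (!length(truth)) stop("empty label vectors")
  if (length(truth) != length(predicted))
    stop("label vectors must have equal length")
  if (is.null(classes)) classes <- sort(unique(as.character(truth)))
  f1 <- vapply(classes, function(cl) {
    tp <- sum(truth == cl & predicted == cl)
    fp <- sum(truth != cl & predicted == cl)
    fn <- sum(truth == cl & predicted != cl)
    if (2 * tp + fp + fn == 0) return(0)
    2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  mean(f1)
}

# --- internal SVM machinery -------------------------------------------------
# One-vs-one C-SVC with radial kernel K(x, y) = exp(-sigma ||x - y||^2)
# (the printed sigma of the organelle-classification protocol; NOT the
# libsvm gamma = 1/(2s^2) convention).  Probabilities: Platt-calibrated
# pairwise decisions coupled by the Wu-Lin (2004) fixed point.

.plattFit <- function(dec, ypos) {
  n1 <- sum(ypos); n0 <- sum(!ypos)
  tpos <- (n1 + 1) / (n1 + 2)
  tneg <- 1 / (n0 + 2)
  t <- ifelse(ypos, tpos, tneg)
  # cross-entropy of p = 1/(1+exp(z)) against Platt's soft targets t;
  # log(1 + e^z) computed stably as max(z, 0) + log1p(exp(-|z|))
  nll <- function(par) {
    z <- par[1] * dec + par[2]
    lse <- pmax(z, 0) + log1p(exp(-abs(z)))   # log(1 + e^z)
    sum(t * lse + (1 - t) * (lse - z))
  }
  init <- c(A = -1, B = log((n0 + 1) / (n1 + 1)))
  fit <- stats::optim(init, nll, method = "BFGS",
                      control = list(maxit = 200, reltol = 1e-10))
  fit$par
}

.plattProb <- function(par, dec) {
  z <- par[1] * dec + par[2]
  1 / (1 + exp(pmin(pmax(z, -700), 700)))
}

# Train all one-vs-one machines on rows `trainIdx` of precomputed
# kernel K (full marker kernel), labels aligned with K's rows.
.ovoTrain <- function(K, labels, classes, trainIdx, cost, platt = FALSE) {
  models <- list()
  for (i in seq_len(length(classes) - 1)) {
    for (j in seq(i + 1, length(classes))) {
      ia <- trainIdx[labels[trainIdx] == classes[i]]
      ib <- trainIdx[labels[trainIdx] == classes[j]]
      idx <- c(ia, ib)
      y <- c(rep(1L, length(ia)), rep(-1L, length(ib)))
      fit <- cpp_smo_train(K[idx, idx, drop = FALSE], y, cost)
      mdl <- list(i = i, j = j, idx = idx, ay = fit$alpha * y, b = fit$b)
      if (platt) {
        dec <- drop(K[idx, idx, drop = FALSE] %*% mdl$ay) + mdl$b
        mdl$platt <- .plattFit(dec, y == 1L)
      }
      models[[length(models) + 1]] <- mdl
    }
  }
  models
}

# Decision values for query rows of a (query x training) kernel slice.
.ovoDecision <- function(models, Kq) {
  vapply(models, function(m)
    drop(Kq[, m$idx, drop = FALSE] %*% m$ay) + m$b,
    numeric(nrow(Kq)))
}

# Vote-based prediction (used inside cross-validated tuning).
.ovoPredictVote <- function(models, Kq, classes) {
  dec <- .ovoDecision(models, Kq)
  if (is.null(dim(dec))) dec <- matrix(dec, nrow = nrow(Kq))
  votes <- matrix(0L, nrow(Kq), length(classes))
  margin <- matrix(0, nrow(Kq), length(classes))
  for (c in seq_along(models)) {
    m <- models[[c]]
    win <- dec[, c] > 0
    votes[win, m$i] <- votes[win, m$i] + 1L
    votes[!win, m$j] <- votes[!win, m$j] + 1L
    margin[, m$i] <- margin[, m$i] + dec[, c]
    margin[, m$j] <- margin[, m$j] - dec[, c]
  }
  out <- integer(nrow(Kq))
  for (r in seq_len(nrow(Kq))) {
    cand <- which(votes[r, ] == max(votes[r, ]))
    if (length(cand) > 1) cand <- cand[which.max(margin[r, cand])]
    out[r] <- cand[1]
  }
  classes[out]
}

# Coupled class probabilities for query rows.
.ovoPredictProb <- function(models, Kq, classes) {
  dec <- .ovoDecision(models, Kq)
  if (is.null(dim(dec))) dec <- matrix(dec, nrow = nrow(Kq))
  rpair <- vapply(seq_along(models), function(c)
    .plattProb(models[[c]]$platt, dec[, c]), numeric(nrow(Kq)))
  if (is.null(dim(rpair))) rpair <- matrix(rpair, nrow = nrow(Kq))
  iIdx <- vapply(models, function(m) m$i, integer(1)) - 1L
  jIdx <- vapply(models, function(m) m$j, integer(1)) - 1L
  P <- cpp_couple_probs(rpair, iIdx, jIdx, length(classes))
  colnames(P) <- classes
  rownames(P) <- rownames(Kq)
  P
}

# Stratified fold assignment: every class distributed over k folds with
# at least one member per fold (class size >= k is checked upstream).
.stratifiedFolds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

.checkMarkerClasses <- function(labels, folds) {
  tab <- table(labels)
  small <- names(tab)[tab < folds]
  if (length(small))
    stop("marker class smaller than the number of folds: ",
         paste(small, collapse = ", "))
  if (length(tab) < 2) stop("at least two marker classes required")
}

.markerMatrix <- function(dataset, markers) {
  lab <- markerLabels(markers)
  present <- intersect(names(lab), rownames(dataset))
  bad <- setdiff(unique(lab), markerClasses(markers))
  if (length(bad))
    stop("unknown class in markers: ", paste(bad, collapse = ", "))
  if (!length(present)) stop("no marker accessions present in the dataset")
  X <- profileMatrix(dataset)[present, , drop = FALSE]
  if (anyNA(X)) stop("dataset must be complete (no missing values)")
  list(X = X, labels = stats::setNames(as.character(lab[present]), present),
       classes = markerClasses(markers))
}

#' Nested cross-validated SVM hyperparameter search
#'
#' For each round, the markers are split into stratified test/train
#' partitions; an inner cross-validation on the training partition
#' selects the radial-kernel width `sigma` and soft-margin `cost` by
#' macro F1 over a grid, the selected machine is retrained on the whole
#' training partition and assessed on the held-out markers.  The
#' selected parameters are the modal per-round winners.  Defaults
#' follow the organelle-classification protocol: 100 rounds of
#' fivefold cross-validation, sigma in 10^(-3..2), cost in 2^(-4..4)
#' (a grid spanning the optima reported for both fractionation
#' chemistries, sigma 0.01 with cost 8 or 16).
#'
#' @param dataset a complete `ProfileSet`.
#' @param markers a `MarkerAnnotation` with at least `folds` members
#'   per class.
#' @param sigmaGrid,costGrid positive parameter grids.
#' @param rounds outer rounds (default 100).
#' @param folds folds for both the outer partition and the inner
#'   search (default 5).
#' @param seed integer; round r uses `seed + r`, so results are
#'   reproducible and invariant to marker row order.
#' @return a [TuneResult-class].
#' @export
tuneSvm <- function(dataset, markers, sigmaGrid = 10^seq(-3, 2),
                    costGrid = 2^seq(-4, 4), rounds = 100, folds = 5,
                    seed = 1) {
  stopifnot(length(sigmaGrid) > 0, length(costGrid) > 0,
            all(sigmaGrid > 0), all(costGrid > 0), folds >= 2, rounds >= 1)
  mm <- .markerMatrix(dataset, markers)
  ord <- order(names(mm$labels))  # invariance to marker row order
  X <- mm$X[ord, , drop = FALSE]
  labels <- mm$labels[ord]
  classes <- mm$classes
  .checkMarkerClasses(labels, folds)
  D2 <- as.matrix(stats::dist(X))^2
  Ks <- lapply(sigmaGrid, function(s) exp(-s * D2))
  grid <- expand.grid(sigma = sigmaGrid, cost = costGrid)
  gridSum <- numeric(nrow(grid))
  outerF1 <- numeric(rounds)
  best <- data.frame(sigma = numeric(rounds), cost = numeric(rounds))
  n <- length(labels)
  for (r in seq_len(rounds)) {
    set.seed(seed + r)
    outerFold <- .stratifiedFolds(labels, folds)
    testIdx <- which(outerFold == 1L)
    trainIdx <- which(outerFold != 1L)
    innerFold <- .stratifiedFolds(labels[trainIdx], folds)
    gf1 <- matrix(0, nrow(grid), folds)
    for (f in seq_len(folds)) {
      inTrain <- trainIdx[innerFold != f]
      inTest <- trainIdx[innerFold == f]
      for (g in seq_len(nrow(grid))) {
        K <- Ks[[match(grid$sigma[g], sigmaGrid)]]
        models <- .ovoTrain(K, labels, classes, inTrain, grid$cost[g])
        pred <- .ovoPredictVote(models, K[inTest, , drop = FALSE], classes)
        gf1[g, f] <- macroF1(labels[inTest], pred, classes)
      }
    }
    gmean <- rowMeans(gf1)
    gbest <- which.max(gmean)   # ties: first = smallest sigma, then cost
    gridSum <- gridSum + gmean
    best$sigma[r] <- grid$sigma[gbest]
    best$cost[r] <- grid$cost[gbest]
    K <- Ks[[match(grid$sigma[gbest], sigmaGrid)]]
    models <- .ovoTrain(K, labels, classes, trainIdx, grid$cost[gbest])
    pred <- .ovoPredictVote(models, K[testIdx, , drop = FALSE], classes)
    outerF1[r] <- macroF1(labels[testIdx], pred, classes)
  }
  key <- paste(best$sigma, best$cost)
  modal <- names(sort(table(key), decreasing = TRUE))[1]
  sel <- best[match(modal, key), ]
  new("TuneResult", f1 = outerF1, best = best,
      gridF1 = data.frame(grid, meanF1 = gridSum / rounds),
      selected = c(sigma = sel$sigma, cost = sel$cost))
}

#' Train on all markers and score every unlabelled protein
#'
#' Trains the one-vs-one radial-kernel SVM on the full curated marker
#' set at the tuned `(sigma, cost)` and assigns every non-marker
#' protein per-class scores (Platt-calibrated pairwise probabilities
#' coupled into a simplex vector) plus the top-scoring class.  Curated
#' markers retain their label with a one-hot score row.
#'
#' @param dataset a complete `ProfileSet`.
#' @param markers a `MarkerAnnotation`.
#' @param sigma radial kernel width in K(x,y) = exp(-sigma ||x-y||^2).
#' @param cost soft-margin penalty.
#' @return a [ClassificationResult-class] (pre-threshold: `label` equals
#'   the assigned class everywhere).
#' @export
trainAndScore <- function(dataset, markers, sigma, cost) {
  mm <- .markerMatrix(dataset, markers)
  X <- profileMatrix(dataset)
  mIdx <- match(names(mm$labels), rownames(X))
  K <- cpp_rbf_kernel(mm$X, mm$X, sigma)
  models <- .ovoTrain(K, mm$labels, mm$classes, seq_along(mm$labels), cost,
                      platt = TRUE)
  qIdx <- setdiff(seq_len(nrow(X)), mIdx)
  scores <- matrix(0, nrow(X), length(mm$classes),
                   dimnames = list(rownames(X), mm$classes))
  if (length(qIdx)) {
    Kq <- cpp_rbf_kernel(X[qIdx, , drop = FALSE], mm$X, sigma)
    rownames(Kq) <- rownames(X)[qIdx]
    scores[qIdx, ] <- .ovoPredictProb(models, Kq, mm$classes)
  }
  scores[cbind(mIdx, match(mm$labels, mm$classes))] <- 1
  assigned <- .argmaxLex(scores)
  topScore <- scores[cbind(seq_len(nrow(scores)),
                           match(assigned, colnames(scores)))]
  isMarker <- seq_len(nrow(X)) %in% mIdx
  assigned[isMarker] <- mm$labels[match(rownames(X)[isMarker],
                                        names(mm$labels))]
  new("ClassificationResult", scores = scores, assigned = assigned,
      score = topScore, label = assigned,
      thresholds = stats::setNames(rep(NA_real_, length(mm$classes)),
                                   mm$classes),
      isMarker = isMarker,
      params = list(sigma = sigma, cost = cost, method = "svm"))
}

# argmax with deterministic lexicographic tie-break on column names
.argmaxLex <- function(scores) {
  cn <- colnames(scores)
  apply(scores, 1, function(x) {
    cand <- cn[x == max(x)]
    sort(cand)[1]
  })
}

#' Score-ordered FDR thresholding of classifier assignments
#'
#' Per class, the non-marker proteins assigned to that class and
#' covered by an external reference (curated localisation annotation,
#' or ground truth for synthetic data) are ordered by descending score;
#' the class threshold is the smallest score whose accepted prefix
#' keeps the fraction of reference disagreements at or below `q`,
#' maximising the accepted set.  Score ties share the fate of the
#' boundary decision.  Every protein assigned to the class — with or
#' without reference annotation — scoring below the threshold is
#' demoted to `"unknown"`; thresholding never changes an assigned
#' class.
#'
#' @param result a pre-threshold `ClassificationResult`.
#' @param reference named character vector, accession -> reference
#'   class (proteins absent from it are unreferenced).
#' @param q target false discovery rate in (0, 1] (default 0.05).
#' @return the thresholded `ClassificationResult`; classes with no
#'   referenced assignment are left unthresholded with a warning.
#' @export
applyFdrThreshold <- function(result, reference, q = 0.05) {
  stopifnot(q > 0, q <= 1)
  scores <- scoreMatrix(result)
  acc <- rownames(scores)
  assigned <- result@assigned
  label <- result@label
  thresholds <- stats::setNames(rep(NA_real_, ncol(scores)),
                                colnames(scores))
  for (cl in colnames(scores)) {
    candIdx <- which(assigned == cl & !result@isMarker)
    if (!length(candIdx)) next
    refIdx <- candIdx[acc[candIdx] %in% names(reference)]
    if (!length(refIdx)) {
      warning("class '", cl, "' has no referenced assignments; ",
              "left unthresholded")
      next
    }
    sc <- result@score[refIdx]
    agree <- reference[acc[refIdx]] == cl
    o <- order(sc, decreasing = TRUE)
    sc <- sc[o]; agree <- agree[o]
    # walk over distinct score cut points; tied scores enter together
    uniq <- unique(sc)
    cumN <- cumsum(table(factor(sc, levels = uniq)))
    cumBad <- cumsum(!agree)
    nAt <- as.integer(cumN)
    fdrAt <- cumBad[nAt] / nAt
    ok <- which(fdrAt <= q)
    if (!length(ok)) {
      thresholds[cl] <- Inf
    } else {
      thresholds[cl] <- uniq[max(ok)]
    }
    demote <- candIdx[result@score[candIdx] < thresholds[cl]]
    label[demote] <- "unknown"
  }
  initialize(result, label = label, thresholds = thresholds,
             params = c(result@params, list(q = q)))
}
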