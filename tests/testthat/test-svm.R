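test_that("macro F1 matches hand-enumerated confusion matrices", {
  expect_equal(macroF1(c("A", "A", "B"), c("A", "A", "B")), 1)
  # F1(A) = 2/3, F1(B) = 0.8 -> macro 0.7333...
  expect_equal(macroF1(c("A", "A", "B", "B"), c("A", "B", "B", "B")),
               (2 / 3 + 0.8) / 2, tolerance = 1e-12)
  # balanced two classes, everything predicted A: F1(A) = 2/3, F1(B) = 0
  expect_equal(macroF1(c("A", "A", "B", "B"), rep("A", 4)), 1 / 3,
               tolerance = 1e-12)
  expect_error(macroF1(character(0), character(0)), "empty")
  expect_error(macroF1("A", c("A", "B")), "equal length")
})

test_that("macro F1 agrees with a brute-force oracle on random labels", {
  set.seed(7)
  classes <- c("A", "B", "C", "D")
  for (i in 1:1000) {
    n <- sample(3:30, 1)
    truth <- sample(classes, n, replace = TRUE)
    pred <- sample(classes, n, replace = TRUE)
    expect_equal(macroF1(truth, pred, classes),
                 bruteMacroF1(truth, pred, classes), tolerance = 1e-12)
  }
})

test_that("the SMO solver reproduces reference SVC decision values", {
  # fixture solved independently with scikit-learn SVC (rbf kernel,
  # gamma = sigma convention, tol 1e-6); decision values frozen below
  X <- matrix(c(0, 0, .2, .1, .1, .4, .4, .3, .3, 0, .9, .8,
                1, 1, 1.2, .9, .9, 1.3, 1.3, 1.2, 1.1, 1, .5, .6),
              ncol = 2, byrow = TRUE)
  y <- c(rep(-1L, 6), rep(1L, 6))
  Tq <- matrix(c(0, .2, 1, .9, .6, .6, .25, .2, 1.4, 1.1),
               ncol = 2, byrow = TRUE)
  oracle <- list(
    list(C = 2.0, sigma = 0.5,
         dec = c(-1.2211285988, 0.8055697743, -0.1467586647,
                 -1.0536917763, 1.2530597073)),
    list(C = 0.5, sigma = 2.0,
         dec = c(-1.0402370289, 0.8984558242, -0.1037695719,
                 -1.0425339165, 0.9185188990)))
  for (o in oracle) {
    K <- spatprot:::cpp_rbf_kernel(X, X, o$sigma)
    fit <- spatprot:::cpp_smo_train(K, y, o$C, tol = 1e-6)
    expect_true(fit$converged)
    dec <- drop(spatprot:::cpp_rbf_kernel(Tq, X, o$sigma) %*%
                  (fit$alpha * y)) + fit$b
    expect_equal(dec, o$dec, tolerance = 1e-4)
    expect_true(all(fit$alpha >= -1e-12 & fit$alpha <= o$C + 1e-12))
    expect_equal(sum(fit$alpha * y), 0, tolerance = 1e-10)
  }
})

test_that("the SMO solver agrees with a quadprog dual solve", {
  skip_if_not_installed("quadprog")
  set.seed(21)
  X <- matrix(rnorm(40), 20, 2)
  X[11:20, ] <- X[11:20, ] + 1.2
  y <- c(rep(-1, 10), rep(1, 10))
  sigma <- 1; C <- 4
  K <- spatprot:::cpp_rbf_kernel(X, X, sigma)
  fit <- spatprot:::cpp_smo_train(K, as.integer(y), C, tol = 1e-8)
  # dual QP: min 1/2 a'Qa - e'a, y'a = 0, 0 <= a <= C (small ridge for PD)
  Q <- (y %*% t(y)) * K + diag(1e-8, 20)
  A <- cbind(y, diag(20), -diag(20))
  b0 <- c(0, rep(0, 20), rep(-C, 20))
  qp <- quadprog::solve.QP(Q, rep(1, 20), A, b0, meq = 1)
  Tq <- matrix(rnorm(20), 10, 2)
  Kt <- spatprot:::cpp_rbf_kernel(Tq, X, sigma)
  decSmo <- drop(Kt %*% (fit$alpha * y)) + fit$b
  # intercept for the QP solution from its free support vectors
  free <- which(qp$solution > 1e-6 & qp$solution < C - 1e-6)
  bQp <- mean(y[free] - (K %*% (qp$solution * y))[free])
  decQp <- drop(Kt %*% (qp$solution * y)) + bQp
  expect_equal(decSmo, decQp, tolerance = 1e-4)
})

test_that("scoring assigns zero-noise unknowns to their generating class", {
  spec <- tinySpec(noiseSd = 0, nMultilocal = 0, nUnrelated = 0)
  gen <- generateDataset(spec, seed = 3)
  res <- trainAndScore(gen$dataset, gen$markers, sigma = 1, cost = 8)
  fi <- featureInfo(gen$dataset)
  unk <- rownames(fi)[fi$role == "unknown"]
  expect_identical(unname(assignedClass(res)[unk]),
                   fi[unk, "groundTruth"])
  # per-protein scores form a probability simplex
  expect_equal(rowSums(scoreMatrix(res)[unk, ]), rep(1, length(unk)),
               ignore_attr = TRUE, tolerance = 1e-9)
  expect_true(all(scoreMatrix(res) >= 0 & scoreMatrix(res) <= 1 + 1e-12))
  # markers retain their curated label
  mk <- markerLabels(gen$markers)
  expect_identical(unname(finalLabel(res)[names(mk)]), unname(mk))
})

test_that("a planted duplicate of a marker profile gets that marker's class", {
  spec <- tinySpec()
  gen <- generateDataset(spec, seed = 9)
  m <- profileMatrix(gen$dataset)
  mk <- markerLabels(gen$markers)
  dupOf <- names(mk)[1]
  m <- rbind(m, DUPLICATE = m[dupOf, ])
  ds <- ProfileSet(m)
  res <- trainAndScore(ds, gen$markers, sigma = 1, cost = 8)
  expect_identical(unname(assignedClass(res)["DUPLICATE"]),
                   unname(mk[dupOf]))
})

test_that("nested CV tuning is reproducible, stratified and validated", {
  spec <- tinySpec(noiseSd = 0, nMultilocal = 0, nUnrelated = 0,
                   unknownsPerClass = 0)
  gen <- generateDataset(spec, seed = 1)
  grid <- list(sigmaGrid = c(0.1, 1), costGrid = c(1, 8))
  t1 <- tuneSvm(gen$dataset, gen$markers, sigmaGrid = grid$sigmaGrid,
                costGrid = grid$costGrid, rounds = 3, folds = 5, seed = 1)
  # zero noise: perfect separability forces perfect CV macro F1
  expect_equal(t1@f1, rep(1, 3))
  expect_true(all(t1@gridF1$meanF1 >= 0 & t1@gridF1$meanF1 <= 1))
  # invariant to marker row order given a fixed seed
  shuffled <- MarkerAnnotation(sample(markerLabels(gen$markers)),
                               classes = markerClasses(gen$markers))
  t2 <- tuneSvm(gen$dataset, shuffled, sigmaGrid = grid$sigmaGrid,
                costGrid = grid$costGrid, rounds = 3, folds = 5, seed = 1)
  expect_identical(t1@selected, t2@selected)
  expect_equal(t1@f1, t2@f1)
  # single-class marker sets and too-small classes are rejected
  oneClass <- MarkerAnnotation(setNames(rep("cytosol", 12),
                                        names(markerLabels(gen$markers))[1:12]))
  expect_error(tuneSvm(gen$dataset, oneClass, rounds = 1),
               "two marker classes")
  tiny <- MarkerAnnotation(markerLabels(gen$markers)[c(1:10, 11:13)],
                           classes = markerClasses(gen$markers))
  expect_error(tuneSvm(gen$dataset, tiny, rounds = 1, folds = 5),
               "smaller than the number of folds")
})

test_that("the FDR walk accepts the largest prefix within the target", {
  # 20 assignments with descending scores; references disagree at ranks
  # 5 and 15; q = 0.05 keeps only the top 4 (FDR at rank 5 is 0.2)
  acc <- sprintf("P%02d", 1:20)
  scores <- seq(1, 0.05, length.out = 20)
  sc <- cbind(X = scores, Y = 1 - scores)
  rownames(sc) <- acc
  res <- new("ClassificationResult", scores = sc,
             assigned = rep("X", 20), score = scores,
             label = rep("X", 20),
             thresholds = c(X = NA_real_, Y = NA_real_),
             isMarker = rep(FALSE, 20), params = list())
  ref <- setNames(rep("X", 20), acc)
  ref[c(5, 15)] <- "Y"
  out <- applyFdrThreshold(res, ref, q = 0.05)
  expect_identical(sum(finalLabel(out) != "unknown"), 4L)
  expect_identical(unname(finalLabel(out)[1:4]), rep("X", 4))
  expect_equal(unname(classThresholds(out)["X"]), scores[4])
  # brute-force cut oracle agrees
  expect_equal(unname(classThresholds(out)["X"]),
               bruteFdrCut(scores, ref[acc] == "X", 0.05))
  # q = 1 retains everything; all-agree keeps all with threshold = min score
  expect_identical(sum(finalLabel(applyFdrThreshold(res, ref, q = 1)) !=
                         "unknown"), 20L)
  allAgree <- applyFdrThreshold(res, setNames(rep("X", 20), acc), q = 0.05)
  expect_identical(sum(finalLabel(allAgree) != "unknown"), 20L)
  expect_equal(unname(classThresholds(allAgree)["X"]), min(scores))
  # a class with no referenced assignment warns and is left alone
  expect_warning(applyFdrThreshold(res, c(QQ = "X"), q = 0.05),
                 "no referenced assignments")
})

test_that("score ties share the boundary fate and the walk matches brute force", {
  set.seed(13)
  for (i in 1:25) {
    n <- sample(8:40, 1)
    scores <- round(runif(n), 2)  # rounding forces ties
    agree <- runif(n) < 0.8
    acc <- sprintf("T%02d", seq_len(n))
    sc <- cbind(X = scores, Y = 1 - scores)
    rownames(sc) <- acc
    res <- new("ClassificationResult", scores = sc,
               assigned = rep("X", n), score = scores,
               label = rep("X", n),
               thresholds = c(X = NA_real_, Y = NA_real_),
               isMarker = rep(FALSE, n), params = list())
    ref <- setNames(ifelse(agree, "X", "Y"), acc)
    q <- sample(c(0.05, 0.1, 0.25), 1)
    out <- applyFdrThreshold(res, ref, q = q)
    expect_equal(unname(classThresholds(out)["X"]),
                 bruteFdrCut(scores, agree, q))
    # tied proteins never straddle the cut
    th <- classThresholds(out)["X"]
    kept <- finalLabel(out) != "unknown"
    if (any(kept) && any(!kept))
      expect_lt(max(scores[!kept]), min(scores[kept]))
  }
})

test_that("classified sets shrink monotonically as q decreases", {
  spec <- tinySpec()
  gen <- generateDataset(spec, seed = 17)
  res <- trainAndScore(gen$dataset, gen$markers, sigma = 1, cost = 8)
  fi <- featureInfo(gen$dataset)
  truth <- setNames(fi$groundTruth, rownames(fi))
  ref <- truth[fi$role != "marker"]
  prevKept <- Inf
  for (q in c(0.5, 0.2, 0.1, 0.05, 0.01)) {
    out <- suppressWarnings(applyFdrThreshold(res, ref, q = q))
    kept <- sum(finalLabel(out) != "unknown" & !out@isMarker)
    expect_lte(kept, prevKept)
    # thresholding demotes but never relabels
    still <- finalLabel(out) != "unknown"
    expect_identical(finalLabel(out)[still], assignedClass(res)[still])
    prevKept <- kept
  }
})
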