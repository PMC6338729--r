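test_that("k-NN class scores follow the neighbour-fraction definition", {
  m <- rbind(M1 = c(0, 0), M2 = c(0, 1), M3 = c(4, 0), M4 = c(4, 1),
             Q1 = c(0.1, 0.1), Q2 = c(2, 0))
  colnames(m) <- c("F1", "F2")
  ds <- ProfileSet(m)
  mk <- MarkerAnnotation(c(M1 = "A", M2 = "A", M3 = "B", M4 = "B"))
  # k = 1: indicator of the nearest marker's class
  s1 <- knnClassScores(ds, mk, k = 1)
  expect_equal(s1["Q1", ], c(A = 1, B = 0))
  # k = 2 with one A and one B neighbour -> (0.5, 0.5)
  s2 <- knnClassScores(ds, mk, query = "Q2", k = 2)
  expect_equal(s2["Q2", ], c(A = 0.5, B = 0.5))
  # rows always sum to 1
  set.seed(31)
  spec <- tinySpec()
  gen <- generateDataset(spec, seed = 31)
  sc <- knnClassScores(gen$dataset, gen$markers, k = 5)
  expect_equal(rowSums(sc), rep(1, nrow(sc)), ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_error(knnClassScores(ds, mk, k = 0), "at least 1")
  expect_error(knnClassScores(ds, mk, k = 9), "exceeds")
  expect_error(knnClassScores(ds, mk, query = "NOPE", k = 1), "absent")
})

test_that("score combination is the theta-weighted blend with lexicographic ties", {
  P <- matrix(c(0.8, 0.2, 0.6, 0.4), 2, 2, byrow = TRUE,
              dimnames = list(c("q1", "q2"), c("alpha", "beta")))
  A <- matrix(c(0.2, 0.8, 0.1, 0.9), 2, 2, byrow = TRUE,
              dimnames = list(c("q1", "q2"), c("alpha", "beta")))
  # all-primary and all-auxiliary extremes are bitwise passthroughs
  expect_identical(combineScores(P, A, 1)$scores, P)
  expect_identical(combineScores(P, A, 0)$scores, A)
  # the printed blend: (0.5, 0.5) with the tie broken lexicographically
  cb <- combineScores(P[1, , drop = FALSE], A[1, , drop = FALSE], 0.5)
  expect_equal(unname(cb$scores[1, ]), c(0.5, 0.5))
  expect_identical(unname(cb$prediction), "alpha")
  # uniform theta keeps rows on the simplex
  set.seed(5)
  P2 <- matrix(rexp(30), 10, 3); P2 <- P2 / rowSums(P2)
  A2 <- matrix(rexp(30), 10, 3); A2 <- A2 / rowSums(A2)
  colnames(P2) <- colnames(A2) <- c("a", "b", "c")
  rownames(P2) <- rownames(A2) <- paste0("p", 1:10)
  for (th in c(0, 0.3, 0.5, 1))
    expect_equal(rowSums(combineScores(P2, A2, th)$scores), rep(1, 10),
                 ignore_attr = TRUE, tolerance = 1e-12)
  # per-class weights respect the named alignment
  cb2 <- combineScores(P2, A2, c(a = 1, b = 0, c = 0.5))
  expect_equal(cb2$scores[, "a"], P2[, "a"])
  expect_equal(cb2$scores[, "b"], A2[, "b"])
  expect_error(combineScores(P2, A2[, c(2, 1, 3)], 0.5), "share classes")
  expect_error(combineScores(P2, A2, c(2, 0, 0)), "\\[0, 1\\]")
})

test_that("neighbour-count tuning returns the modal cross-validated best k", {
  spec <- tinySpec(noiseSd = 0, nMultilocal = 0, nUnrelated = 0,
                   unknownsPerClass = 0)
  gen <- generateDataset(spec, seed = 6)
  # degenerate grid passes straight through
  expect_identical(tuneK(gen$dataset, gen$markers, kGrid = 5, rounds = 2,
                         seed = 1)$bestK, 5L)
  # zero noise: perfect F1 at every k; modal best is the smallest by tie-break
  tk <- tuneK(gen$dataset, gen$markers, kGrid = c(3, 5, 7), rounds = 4,
              seed = 1)
  expect_true(all(tk$f1 == 1))
  expect_identical(tk$bestK, 3L)
  expect_error(tuneK(gen$dataset, gen$markers, kGrid = integer(0)),
               "empty")
})

test_that("theta optimisation prefers the primary map when maps tie", {
  spec <- tinySpec(nMultilocal = 0, nUnrelated = 0, unknownsPerClass = 0)
  gen <- generateDataset(spec, seed = 10)
  th <- optimizeTheta(gen$dataset, gen$dataset, gen$markers,
                      iterations = 3, folds = 5, seed = 1)
  # auxiliary identical to primary: every weight vector ties; the
  # prefer-primary rule returns all ones
  expect_true(all(thetaWeights(th) == 1))
  expect_equal(unname(medianTheta(th)), rep(1, 4))
  expect_error(optimizeTheta(gen$dataset, gen$dataset, gen$markers,
                             candidates = numeric(0)), "empty candidate")
  other <- generateDataset(tinySpec(), seed = 11)
  emptyMk <- MarkerAnnotation(c(NOPE = "cytosol"))
  expect_error(optimizeTheta(gen$dataset, gen$dataset, emptyMk),
               "no shared marker")
})

test_that("exhaustive and coordinate searches agree on a zero-noise fixture", {
  sp <- pairedSpecs(noiseSd = 0, overlapInPrimary = list())
  pair <- generatePairedMaps(sp$primary, sp$auxiliary, seed = 2)
  args <- list(pair$primary$dataset, pair$auxiliary$dataset, pair$markers,
               iterations = 2, folds = 5, seed = 3)
  ex <- do.call(optimizeTheta, c(args, mode = "exhaustive"))
  co <- do.call(optimizeTheta, c(args, mode = "coordinate"))
  expect_identical(thetaWeights(ex), thetaWeights(co))
  expect_equal(ex@f1, co@f1)
})

test_that("an all-ones theta pipeline is bitwise identical to primary-only k-NN", {
  sp <- pairedSpecs()
  pair <- generatePairedMaps(sp$primary, sp$auxiliary, seed = 19)
  res <- transferClassify(pair$primary$dataset, pair$auxiliary$dataset,
                          pair$markers, theta = 1, kPrimary = 5,
                          kAuxiliary = 5)
  primOnly <- knnClassScores(pair$primary$dataset, pair$markers, k = 5)
  q <- rownames(scoreMatrix(res))
  expect_identical(scoreMatrix(res)[q, ], primOnly[q, ])
  expect_identical(unname(assignedClass(res)),
                   unname(spatprot:::.argmaxLex(primOnly[q, ])))
})

test_that("proteins missing from one map are scored from the other and flagged", {
  sp <- pairedSpecs()
  pair <- generatePairedMaps(sp$primary, sp$auxiliary, seed = 23)
  prim <- pair$primary$dataset
  aux <- pair$auxiliary$dataset
  fi <- featureInfo(prim)
  drop1 <- rownames(fi)[fi$role == "unknown"][1:5]   # absent from auxiliary
  aux2 <- aux[setdiff(rownames(aux), drop1), ]
  res <- transferClassify(prim, aux2, pair$markers, theta = 0.5)
  src <- res@params$source
  expect_identical(unname(src[drop1]), rep("primary-only", 5))
  primOnly <- knnClassScores(prim, pair$markers, drop1, 5)
  expect_equal(scoreMatrix(res)[drop1, ], primOnly)
})
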