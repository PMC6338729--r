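test_that("profile tables round-trip through disk, preserving missing cells", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("accession\tC1\tC2\tC3\tC4\tC5\tC6\tC7\tC8\tC9\tC10",
               paste0("P1\t", paste(1:10, collapse = "\t")),
               paste0("P2\t", paste(c("NA", 2:10), collapse = "\t")),
               paste0("P3\t", paste(seq(0.1, 1, 0.1), collapse = "\t"))), f)
  ps <- readProfileTable(f)
  expect_s4_class(ps, "ProfileSet")
  expect_identical(dim(ps), c(3L, 10L))
  expect_identical(sum(is.na(profileMatrix(ps))), 1L)
  expect_true(is.na(profileMatrix(ps)["P2", "C1"]))

  f2 <- tempfile(fileext = ".tsv")
  writeProfileTable(ps, f2)
  ps2 <- readProfileTable(f2)
  expect_equal(profileMatrix(ps2), profileMatrix(ps))
})

test_that("malformed tables are rejected with informative errors", {
  f <- tempfile()
  writeLines(c("accession\tC1\tC2", "P1\t1\t2", "P1\t3\t4"), f)
  expect_error(readProfileTable(f), "duplicated accessions.*P1")
  writeLines(c("accession\tC1\tC2", "P1\t1\toops"), f)
  expect_error(readProfileTable(f), "row 1.*C2")
  expect_error(readProfileTable(tempfile()), "not found")
  expect_error(ProfileSet(matrix(1, 1, 1)), "rownames")
  expect_error(ProfileSet(matrix(-1, 1, 1, dimnames = list("P1", "C1"))),
               "nonnegative")
})

test_that("sum normalisation matches hand examples and is idempotent", {
  expect_equal(unname(sumNormalizeRows(matrix(c(1, 3), 1))),
               matrix(c(0.25, 0.75), 1))
  expect_equal(unname(sumNormalizeRows(matrix(rep(2, 10), 1))),
               matrix(rep(0.1, 10), 1))
  expect_equal(unname(sumNormalizeRows(matrix(c(0, 1, 1), 1))),
               matrix(c(0, 0.5, 0.5), 1))
  set.seed(1)
  m <- matrix(rexp(60), 10, 6)
  n1 <- sumNormalizeRows(m)
  expect_equal(rowSums(n1), rep(1, 10), tolerance = 1e-12)
  expect_equal(sumNormalizeRows(n1), n1, tolerance = 1e-14)
  m[3, ] <- 0
  expect_error(sumNormalizeRows(m), "non-positive total.*3")
})

test_that("protein-group aggregation takes channel-wise medians", {
  psm <- matrix(c(0.2, 0.8,
                  0.4, 0.6,
                  0.5, 0.5), 3, 2, byrow = TRUE)
  agg <- aggregateProteinGroups(psm, c("G1", "G1", "G2"))
  expect_equal(unname(profileMatrix(agg)["G1", ]), c(0.3, 0.7))
  expect_equal(unname(profileMatrix(agg)["G2", ]), c(0.5, 0.5))
  # single-PSM group passes through; odd count takes the middle value
  psm3 <- matrix(c(0.1, 0.9, 0.2, 0.8, 0.6, 0.4), 3, 2, byrow = TRUE)
  agg3 <- aggregateProteinGroups(psm3, rep("G", 3))
  expect_equal(unname(profileMatrix(agg3)[1, ]), c(0.2, 0.8))
  expect_error(aggregateProteinGroups(psm, character(0)), "non-empty")
})

test_that("full-reporter-series filter removes exactly the incomplete rows", {
  m <- matrix(runif(50), 10, 5,
              dimnames = list(sprintf("P%02d", 1:10), NULL))
  m[c(2, 7), 3] <- NA
  ps <- toy <- ProfileSet(m)
  expect_message(out <- filterCompleteProfiles(ps), "2 of 10")
  expect_identical(nrow(out), 8L)
  expect_identical(rownames(out), setdiff(rownames(m), c("P02", "P07")))
  # brute-force property over random missingness patterns
  set.seed(42)
  for (i in 1:20) {
    mm <- matrix(runif(40), 8, 5, dimnames = list(sprintf("Q%d", 1:8), NULL))
    mm[sample(length(mm), sample(0:10, 1))] <- NA
    expected <- sum(apply(mm, 1, function(r) all(!is.na(r))))
    suppressMessages(suppressWarnings(
      expect_identical(nrow(filterCompleteProfiles(ProfileSet(mm))),
                       as.integer(expected))))
  }
  m[] <- NA
  m[1, 1] <- 1  # keep validity: some value present, every row incomplete
  expect_warning(suppressMessages(filterCompleteProfiles(ProfileSet(m))),
                 "no complete profiles")
})

test_that("channel dropping and contaminant removal behave per contract", {
  m <- matrix(runif(60 * 3), 3, 60,
              dimnames = list(paste0("P", 1:3), paste0("C", 1:60)))
  ps <- ProfileSet(m)
  expect_identical(ncol(dropChannels(ps, c("C5", "C17", "C60"))), 57L)
  expect_identical(dropChannels(ps, character(0)), ps)
  expect_error(dropChannels(ps, "C99"), "unknown channel")
  expect_error(dropChannels(ps, paste0("C", 1:60)), "all channels")
  expect_identical(nrow(removeContaminants(ps, c("P1", "P3", "XX"))), 1L)
  expect_equal(profileMatrix(removeContaminants(ps, character(0))),
               profileMatrix(ps))
  expect_equal(profileMatrix(removeContaminants(ps, "ZZZ")),
               profileMatrix(ps))
})

test_that("replicate concatenation intersects accessions and keeps labels", {
  mk <- function(acc, seed) {
    set.seed(seed)
    ProfileSet(matrix(runif(length(acc) * 4), length(acc), 4,
                      dimnames = list(acc, paste0("F", 1:4))))
  }
  a <- mk(c("P1", "P2", "P3", "P4"), 1)
  b <- mk(c("P2", "P3", "P4", "P5"), 2)
  c3 <- mk(c("P3", "P4", "P2"), 3)
  out <- concatenateReplicates(list(a, b, c3))
  expect_identical(sort(rownames(out)), c("P2", "P3", "P4"))
  expect_identical(ncol(out), 12L)
  expect_identical(unique(channelInfo(out)$replicate), c(1L, 2L, 3L))
  # order-insensitive up to channel ordering metadata
  out2 <- concatenateReplicates(list(c3, a, b))
  expect_equal(sort(rownames(out2)), sort(rownames(out)))
  expect_equal(rowSums(profileMatrix(out2)),
               rowSums(profileMatrix(out)[rownames(out2), ]))
  expect_identical(concatenateReplicates(list(a)), a)
  expect_error(concatenateReplicates(list(a, mk(c("X1", "X2"), 4))),
               "empty accession intersection")
  # conflicting marker labels error
  a2 <- setMarkers(a, MarkerAnnotation(c(P2 = "cytosol")))
  b2 <- setMarkers(b, MarkerAnnotation(c(P2 = "ER")))
  expect_error(concatenateReplicates(list(a2, b2)), "conflicting marker")
})

test_that("marker class merging implements the 12-to-10 class scheme", {
  cls12 <- c("cytosol", "proteasome", "nucleus", "chromatin",
             "ribosome 40S", "ribosome 60S", "peroxisome", "mitochondrion",
             "lysosome", "Golgi", "PM", "ER")
  lab <- setNames(rep(cls12, each = 2), sprintf("P%02d", 1:24))
  mk <- MarkerAnnotation(lab, classes = cls12)
  merged <- mergeMarkerClasses(mk, c(
    "nucleus" = "nucleus/chromatin", "chromatin" = "nucleus/chromatin",
    "ribosome 40S" = "ribosome", "ribosome 60S" = "ribosome"))
  expect_length(markerClasses(merged), 10)
  expect_identical(unname(markerLabels(merged)[c("P05", "P07", "P09")]),
                   c("nucleus/chromatin", "nucleus/chromatin", "ribosome"))
  expect_identical(sum(markerLabels(merged) == "ribosome"), 4L)
  expect_identical(mergeMarkerClasses(mk, c()), mk)
  allone <- mergeMarkerClasses(mk, setNames(rep("cell", 12), cls12))
  expect_identical(markerClasses(allone), "cell")
  expect_error(mergeMarkerClasses(mk, c(nonexistent = "x")), "unknown class")
})

test_that("PCA projection is variance-faithful with a fixed sign convention", {
  # points on a line: first component carries all variance
  t <- seq(0, 1, length.out = 10)
  lm <- cbind(F1 = t / 3 + 0.1, F2 = 2 * t / 3 + 0.1)
  rownames(lm) <- paste0("P", 1:10)
  line <- ProfileSet(lm)
  pc <- pcaProject(line)
  expect_equal(pc@varianceFraction[1], 1, tolerance = 1e-12)
  # full-rank data: fractions non-increasing, sum to 1, scores orthogonal
  set.seed(3)
  ps <- ProfileSet(matrix(runif(80), 16, 5,
                          dimnames = list(sprintf("P%02d", 1:16), NULL)))
  pc <- pcaProject(ps)
  expect_equal(sum(pc@varianceFraction), 1, tolerance = 1e-12)
  expect_true(all(diff(pc@varianceFraction) <= 1e-12))
  g <- crossprod(pc@scores)
  expect_equal(g[upper.tri(g)], rep(0, sum(upper.tri(g))), tolerance = 1e-8)
  # reconstruction from all components returns the centred input
  centred <- scale(profileMatrix(ps), center = TRUE, scale = FALSE)
  rec <- pc@scores %*% t(pc@loadings)
  expect_equal(unname(rec), unname(centred), tolerance = 1e-10,
               ignore_attr = TRUE)
  # total variance preserved
  expect_equal(sum(pc@scores^2), sum(centred^2), tolerance = 1e-10)
  # deterministic sign: the largest-magnitude loading per component is positive
  for (j in seq_len(ncol(pc@loadings)))
    expect_gt(pc@loadings[which.max(abs(pc@loadings[, j])), j], 0)
  expect_error(pcaProject(ps, 0), "at least 1")
  expect_error(pcaProject(ps, 99), "exceeds")
})

test_that("agreement analysis counts matching assignments over shared proteins", {
  mkRes <- function(lab, markers = rep(FALSE, length(lab))) {
    sc <- matrix(0, length(lab), 2,
                 dimnames = list(names(lab), c("A", "B")))
    sc[cbind(seq_along(lab), ifelse(lab == "unknown", 1,
                                    match(lab, c("A", "B"))))] <- 1
    new("ClassificationResult", scores = sc, assigned = unname(lab),
        score = rep(1, length(lab)), label = unname(lab),
        thresholds = c(A = NA_real_, B = NA_real_), isMarker = markers,
        params = list())
  }
  acc <- paste0("P", 1:10)
  labA <- setNames(rep(c("A", "B"), 5), acc)
  same <- agreementMatrix(mkRes(labA), mkRes(labA))
  expect_equal(same$agreement, 100)
  expect_true(all(same$table[upper.tri(same$table)] == 0))
  flip <- setNames(ifelse(labA == "A", "B", "A"), acc)
  expect_equal(agreementMatrix(mkRes(labA), mkRes(flip))$agreement, 0)
  one <- labA; one["P10"] <- "A"  # single discordant protein
  expect_equal(agreementMatrix(mkRes(labA), mkRes(one))$agreement, 90)
  # class-vocabulary mapping and marker exclusion
  labB <- setNames(rep(c("A", "Bfine"), 5), acc)
  scB <- matrix(0, 10, 2, dimnames = list(acc, c("A", "Bfine")))
  scB[cbind(1:10, match(labB, c("A", "Bfine")))] <- 1
  resB <- new("ClassificationResult", scores = scB, assigned = unname(labB),
              score = rep(1, 10), label = unname(labB),
              thresholds = c(A = NA_real_, Bfine = NA_real_),
              isMarker = rep(FALSE, 10), params = list())
  mapped <- agreementMatrix(mkRes(labA), resB, classMap = c(Bfine = "B"))
  expect_equal(mapped$agreement, 100)
  withMk <- agreementMatrix(mkRes(labA, markers = c(TRUE, rep(FALSE, 9))),
                            mkRes(one))
  expect_equal(withMk$nNonMarker, 9L)
  expect_equal(withMk$agreementNonMarker, 100 * 8 / 9)
  unkA <- labA; unkA[] <- "unknown"
  expect_error(agreementMatrix(mkRes(unkA), mkRes(labA)), "no proteins")
})
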