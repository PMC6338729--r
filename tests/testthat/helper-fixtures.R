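# Shared fixtures and independent oracles used across the suite.

# small, fast synthetic worlds ------------------------------------------------
tinySpec <- function(...) {
  args <- utils::modifyList(
    list(nClasses = 4, nChannels = 8, nReplicates = 2,
         markersPerClass = 10, unknownsPerClass = 15,
         nMultilocal = 8, nUnrelated = 6),
    list(...))
  do.call(syntheticSpec, args)
}

pairedSpecs <- function(overlapInPrimary = list(c("cytosol", "proteasome")),
                        ...) {
  mk <- function(ov) {
    args <- utils::modifyList(
      list(nClasses = 6, nChannels = 10, nReplicates = 2,
           markersPerClass = 15, unknownsPerClass = 20, nMultilocal = 10,
           nUnrelated = 10, overlapPairs = ov),
      list(...))
    do.call(syntheticSpec, args)
  }
  list(primary = mk(overlapInPrimary), auxiliary = mk(list()))
}

# a tiny ProfileSet built by hand
toyProfileSet <- function(m = NULL) {
  if (is.null(m))
    m <- matrix(c(1, 3, 0, 2, 2, 2, 5, 0, 5), 3, 3, byrow = TRUE,
                dimnames = list(c("P1", "P2", "P3"), c("F1", "F2", "F3")))
  ProfileSet(m)
}

# independent oracles ---------------------------------------------------------

# brute-force macro F1 straight from the confusion-matrix definition
bruteMacroF1 <- function(truth, pred, classes) {
  f1s <- numeric(length(classes))
  for (i in seq_along(classes)) {
    cl <- classes[i]
    tp <- 0; fp <- 0; fn <- 0
    for (t in seq_along(truth)) {
      if (truth[t] == cl && pred[t] == cl) tp <- tp + 1
      if (truth[t] != cl && pred[t] == cl) fp <- fp + 1
      if (truth[t] == cl && pred[t] != cl) fn <- fn + 1
    }
    prec <- if (tp + fp > 0) tp / (tp + fp) else NA
    rec <- if (tp + fn > 0) tp / (tp + fn) else NA
    f1s[i] <- if (is.na(prec) || is.na(rec) || prec + rec == 0) 0
              else 2 * prec * rec / (prec + rec)
  }
  mean(f1s)
}

# exhaustive double-loop QSep oracle
bruteQSep <- function(X, labels, classes) {
  C <- length(classes)
  raw <- matrix(0, C, C, dimnames = list(classes, classes))
  for (i in seq_len(C)) {
    for (j in seq_len(C)) {
      pi <- which(labels == classes[i])
      pj <- which(labels == classes[j])
      tot <- 0; n <- 0
      if (i == j) {
        for (a in pi) for (b in pi) {
          if (a < b) {
            tot <- tot + sqrt(sum((X[a, ] - X[b, ])^2)); n <- n + 1
          }
        }
      } else {
        for (a in pi) for (b in pj) {
          tot <- tot + sqrt(sum((X[a, ] - X[b, ])^2)); n <- n + 1
        }
      }
      raw[i, j] <- tot / n
    }
  }
  norm <- raw
  for (i in seq_len(C)) norm[i, ] <- raw[i, ] / raw[i, i]
  list(raw = raw, normalised = norm)
}

# step-up BH adjustment from the definition (p * m / rank, running min
# from the largest rank, capped at 1)
bruteBH <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  for (i in seq(m - 1, 1, length.out = max(m - 1, 0)))
    adj[i] <- min(adj[i], adj[i + 1])
  pmin(adj, 1)[order(o)]
}

# brute-force FDR walk: scan every cut rank, keep the largest prefix
# whose disagreement fraction stays at or below q (ties share fate)
bruteFdrCut <- function(scores, agree, q) {
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; a <- agree[o]
  bestN <- 0
  for (n in seq_along(s)) {
    if (n < length(s) && s[n + 1] == s[n]) next  # tied block not complete
    if (mean(!a[seq_len(n)]) <= q) bestN <- n
  }
  if (bestN == 0) Inf else s[bestN]
}
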