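# Weighted pool-adjacent-violators: non-decreasing least-squares fit.
.pava <- function(y, w) {
  n <- length(y)
  val <- y; wt <- w; len <- rep(1L, n)
  m <- 0L
  for (i in seq_len(n)) {
    m <- m + 1L
    val[m] <- y[i]; wt[m] <- w[i]; len[m] <- 1L
    while (m > 1L && val[m - 1L] > val[m]) {
      tw <- wt[m - 1L] + wt[m]
      val[m - 1L] <- (wt[m - 1L] * val[m - 1L] + wt[m] * val[m]) / tw
      wt[m - 1L] <- tw
      len[m - 1L] <- len[m - 1L] + len[m]
      m <- m - 1L
    }
  }
  rep(val[seq_len(m)], len[seq_len(m)])
}

#' Fit a probability weight function (selection probability vs abundance)
#'
#' Estimates P(selected | abundance) as a monotone function of log
#' abundance by weighted isotonic regression (pool-adjacent-violators
#' on tie-aggregated log abundance); the monotonicity direction follows
#' the sign of the rank correlation between selection and abundance.
#' Because abundant proteins are more likely to be detected and
#' classified, a category test that ignores this bias misreads
#' abundance structure as biology; the fitted weights let the null
#' draws match the selection's abundance profile.  Proteins lacking an
#' abundance value are excluded from the fit.
#'
#' @param selected logical (or 0/1) selection flags, named by accession.
#' @param abundance protein abundance values aligned with `selected`
#'   (the convention is the maximum abundance recorded across
#'   replicates); NA to exclude a protein.
#' @return a [Pwf-class]; the mean fitted weight equals the overall
#'   selection rate to within 1e-6.
#' @export
fitPwf <- function(selected, abundance) {
  if (is.null(names(selected)) && !is.null(names(abundance)))
    names(selected) <- names(abundance)
  selected <- as.logical(selected)
  keep <- !is.na(abundance) & !is.na(selected)
  if (sum(keep) < 50)
    stop("at least 50 proteins with abundance required (", sum(keep),
         " available)")
  sel <- selected[keep]
  ab <- abundance[keep]
  if (all(sel) || !any(sel))
    stop("degenerate selection: all or none selected")
  x <- log(ab)
  rho <- stats::cor(x, as.numeric(sel), method = "spearman")
  direction <- if (!is.na(rho) && rho < 0) "decreasing" else "increasing"
  xs <- if (direction == "decreasing") -x else x
  o <- order(xs)
  ux <- unique(xs[o])
  grp <- match(xs, ux)
  wts <- as.numeric(table(factor(grp, levels = seq_along(ux))))
  ymean <- as.numeric(tapply(as.numeric(sel), grp, mean))
  fit <- .pava(ymean, wts)
  fit <- pmin(pmax(fit, 0), 1)
  weights <- fit[grp]
  acc <- names(abundance)[keep]
  if (is.null(acc)) acc <- as.character(which(keep))
  new("Pwf", weights = stats::setNames(weights, acc),
      xKnots = if (direction == "decreasing") rev(-ux) else ux,
      yKnots = if (direction == "decreasing") rev(fit) else fit,
      direction = direction, rate = mean(sel))
}

#' Evaluate a fitted probability weight function at new abundances
#' @param pwf a `Pwf`.
#' @param abundance abundance values.
#' @return fitted selection probabilities (constant interpolation).
#' @export
predictPwf <- function(pwf, abundance) {
  x <- log(abundance)
  f <- stats::approxfun(pwf@xKnots, pwf@yKnots, method = "constant",
                        rule = 2, ties = "ordered")
  f(x)
}

#' Selection-bias-corrected category over-representation test
#'
#' Tests whether a category overlaps the selected set more than
#' expected when null sets of the same size are drawn without
#' replacement with inclusion probability proportional to the
#' probability-weight-function weights (so the null inherits the
#' selection's abundance bias).  The empirical p-value is
#' `(1 + #{null overlap >= observed}) / (1 + nNull)` and is therefore
#' never 0.
#'
#' @param category accessions in the category (non-empty, within the
#'   universe).
#' @param selected accessions in the selected set.
#' @param universe all accessions.
#' @param pwf a [Pwf-class], or `NULL` for uniform weights.
#' @param nNull number of null draws (>= 1000).
#' @param seed integer seed.
#' @return list with `observed`, `expected` (mean null overlap), `p`
#'   and `size`.
#' @export
categoryTest <- function(category, selected, universe, pwf = NULL,
                         nNull = 10000, seed = 1) {
  if (!length(category)) stop("empty category")
  if (nNull < 1000) stop("nNull must be at least 1000")
  res <- enrichmentTest(list(category = category), selected, universe,
                        pwf = pwf, nNull = nNull, seed = seed)
  list(observed = res$observed[1], expected = res$expected[1],
       p = res$p[1], size = res$size[1])
}

#' Batch over-representation analysis with a shared null
#'
#' Draws `nNull` abundance-weighted null selections once and scores
#' every category against them (the standard sampling strategy of
#' bias-corrected over-representation analysis), then adjusts p-values
#' by Benjamini-Hochberg and flags significance.
#'
#' @param categories named list of accession vectors.
#' @param selected,universe accession vectors.
#' @param pwf a [Pwf-class] whose weights cover the universe, or `NULL`
#'   for uniform weights (the hypergeometric null in the sampling
#'   limit).
#' @param nNull null draws (default 10000).
#' @param seed integer seed.
#' @param alpha,minSize significance thresholds passed to
#'   [filterSignificant()] (defaults 0.01 and 5).
#' @param method `"sampling"` (weighted null, default) or
#'   `"hypergeometric"` (exact unweighted tail, ignoring the pwf) —
#'   the uncorrected reference test.
#' @return `data.frame` with one row per category: size, observed and
#'   expected overlap, `p`, `padj`, `significant`.
#' @export
enrichmentTest <- function(categories, selected, universe, pwf = NULL,
                           nNull = 10000, seed = 1, alpha = 0.01,
                           minSize = 5,
                           method = c("sampling", "hypergeometric")) {
  method <- match.arg(method)
  if (!length(categories)) stop("no categories supplied")
  if (is.null(names(categories)))
    names(categories) <- paste0("category", seq_along(categories))
  universe <- unique(universe)
  bad <- setdiff(selected, universe)
  if (length(bad)) stop("selected proteins outside the universe")
  for (nm in names(categories)) {
    if (!length(categories[[nm]])) stop("empty category: ", nm)
    if (length(setdiff(categories[[nm]], universe)))
      stop("category '", nm, "' contains proteins outside the universe")
  }
  selFlag <- universe %in% selected
  nSel <- sum(selFlag)
  size <- vapply(categories, length, integer(1))
  observed <- vapply(categories, function(cc) sum(cc %in% selected),
                     integer(1))
  if (method == "hypergeometric") {
    expected <- size * nSel / length(universe)
    p <- stats::phyper(observed - 1, size, length(universe) - size, nSel,
                       lower.tail = FALSE)
  } else {
    w <- rep(1, length(universe))
    if (!is.null(pwf)) {
      w <- pwf@weights[universe]
      if (anyNA(w))
        stop("pwf weights missing for ", sum(is.na(w)),
             " universe protein(s)")
      w <- pmax(w, 1e-12)
    }
    members <- lapply(categories, function(cc)
      match(cc, universe) - 1L)
    set.seed(seed)
    ov <- cpp_null_overlaps(w, nSel, as.integer(nNull), members)
    expected <- colMeans(ov)
    p <- vapply(seq_along(categories), function(c)
      (1 + sum(ov[, c] >= observed[c])) / (1 + nNull), numeric(1))
  }
  out <- data.frame(category = names(categories), size = size,
                    observed = observed, expected = unname(expected),
                    p = unname(p), row.names = NULL,
                    stringsAsFactors = FALSE)
  out$padj <- adjustBH(out$p)
  filterSignificant(out, alpha = alpha, minSize = minSize)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p p-values in (0, 1].
#' @return adjusted p-values (monotone, never below the raw values).
#' @examples adjustBH(c(0.01, 0.02, 0.03))  # all 0.03
#' @export
adjustBH <- function(p) stats::p.adjust(p, method = "BH")

#' Flag significantly over-represented categories
#'
#' A category is significant when its adjusted p-value is strictly
#' below `alpha` AND it contains at least `minSize` proteins.
#'
#' @param results `data.frame` with `padj` and `size` columns.
#' @param alpha adjusted-p threshold (default 0.01, strict inequality).
#' @param minSize minimal category size (default 5).
#' @return `results` with a `significant` logical column.
#' @export
filterSignificant <- function(results, alpha = 0.01, minSize = 5) {
  results$significant <- results$padj < alpha & results$size >= minSize
  results
}

#' Detection-bias diagnostic: abundance vs detection
#'
#' Reports the rank correlation between protein abundance and the
#' probability of detection plus a binned detection-rate table, to
#' confirm (or refute) that abundant proteins are more likely to be
#' detected before applying the bias-corrected test.
#'
#' @param detected logical detection flags.
#' @param abundance abundance values (NA excluded).
#' @param bins number of abundance bins (default 10).
#' @return list with `correlation` (Spearman; `NA` with a `note` when
#'   detection is constant), and `table` of per-bin detection rates.
#' @export
detectionBiasCheck <- function(detected, abundance, bins = 10) {
  keep <- !is.na(abundance) & !is.na(detected)
  det <- as.logical(detected[keep])
  ab <- abundance[keep]
  note <- NULL
  if (all(det) || !any(det)) {
    rho <- NA_real_
    note <- "detection is constant; correlation undefined"
  } else {
    rho <- stats::cor(log(ab), as.numeric(det), method = "spearman")
  }
  br <- unique(stats::quantile(ab, seq(0, 1, length.out = bins + 1)))
  bin <- cut(ab, br, include.lowest = TRUE)
  tab <- data.frame(bin = levels(bin),
                    n = as.integer(table(bin)),
                    detectionRate = as.numeric(tapply(det, bin, mean)))
  list(correlation = rho, table = tab, note = note)
}
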