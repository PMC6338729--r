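#' Specification of a synthetic organelle-profiling dataset
#'
#' Describes the stated world a generated dataset emulates: a set of
#' organelle classes with distinct fraction-enrichment templates (each
#' class peaks in different differential-pelleting fractions), curated
#' markers per class, unannotated single-location proteins,
#' multilocalising proteins whose profiles are convex mixtures of two
#' class templates, unrelated proteins with no class structure, and a
#' log-normal protein abundance model.
#'
#' Defaults describe a desk-scale map: 10 organelle classes over
#' 10 channels x 3 replicates, 30 markers and 200 unknowns per class,
#' 300 multilocalising and 200 unrelated proteins, with additive
#' Gaussian profile noise (sd 0.05 per channel before clipping and
#' per-replicate renormalisation).  The default peak width (0.55
#' channels) is the widest at which 10 classes spread over 10 fractions
#' still satisfy the pairwise cosine-similarity bound of 0.5.
#'
#' @param nClasses number of organelle classes.
#' @param nChannels TMT channels per replicate.
#' @param nReplicates replicates (channel blocks).
#' @param markersPerClass curated markers per class.
#' @param unknownsPerClass unannotated single-location proteins per class.
#' @param nMultilocal multilocalising proteins (template mixtures).
#' @param nUnrelated proteins with no class structure.
#' @param noiseSd additive Gaussian noise sd per channel.
#' @param noiseModel `"gaussian"` (additive, clipped, renormalised) or
#'   `"dirichlet"` (profiles drawn from a Dirichlet centred on the
#'   template).
#' @param dirichletConc Dirichlet concentration when
#'   `noiseModel = "dirichlet"`.
#' @param alphaRange range of the mixing coefficient for
#'   multilocalising proteins.
#' @param abundanceMeanlog,abundanceSdlog log-normal abundance model.
#' @param maxSimilarity maximal allowed pairwise cosine similarity
#'   between class templates (except requested overlapping pairs).
#' @param overlapPairs list of length-2 class-name vectors that should
#'   overlap (near-identical templates), as unresolved niches do in a
#'   lower-resolution map.
#' @param overlapSimilarity target cosine similarity for overlapping
#'   pairs.  The default `NA` derives the target from the noise model:
#'   the two templates are pushed together until their separation is
#'   half the expected within-cluster spread, so the pair is genuinely
#'   unresolved at the dataset's noise level (never below 0.95).
#' @param templateWidth width (in channels) of each class's
#'   fraction-enrichment peak.
#' @param classNames class names; defaults to common organelle names.
#' @return a `SyntheticSpec` (validated list).
#' @export
syntheticSpec <- function(nClasses = 10, nChannels = 10, nReplicates = 3,
                          markersPerClass = 30, unknownsPerClass = 200,
                          nMultilocal = 300, nUnrelated = 200,
                          noiseSd = 0.05, noiseModel = c("gaussian", "dirichlet"),
                          dirichletConc = 100,
                          alphaRange = c(0.3, 0.7),
                          abundanceMeanlog = log(1000), abundanceSdlog = 1.5,
                          maxSimilarity = 0.5, overlapPairs = list(),
                          overlapSimilarity = NA, templateWidth = 0.55,
                          classNames = NULL) {
  noiseModel <- match.arg(noiseModel)
  if (is.null(classNames)) {
    pool <- c("cytosol", "proteasome", "nucleus/chromatin", "ribosome",
              "mitochondrion", "peroxisome", "lysosome", "ER", "Golgi",
              "PM", "nucleus", "chromatin")
    classNames <- if (nClasses <= length(pool)) pool[seq_len(nClasses)]
                  else sprintf("class%02d", seq_len(nClasses))
  }
  if (length(classNames) != nClasses) stop("need one name per class")
  stopifnot(nClasses >= 1, nChannels >= 1, nReplicates >= 1,
            markersPerClass >= 0, unknownsPerClass >= 0,
            nMultilocal >= 0, nUnrelated >= 0, noiseSd >= 0,
            all(alphaRange >= 0), all(alphaRange <= 1),
            maxSimilarity > 0,
            is.na(overlapSimilarity) ||
              (overlapSimilarity > 0 && overlapSimilarity <= 1))
  for (p in overlapPairs) {
    if (length(p) != 2 || !all(p %in% classNames))
      stop("overlapPairs must be pairs of class names")
  }
  structure(list(nClasses = nClasses, nChannels = nChannels,
                 nReplicates = nReplicates, markersPerClass = markersPerClass,
                 unknownsPerClass = unknownsPerClass,
                 nMultilocal = nMultilocal, nUnrelated = nUnrelated,
                 noiseSd = noiseSd, noiseModel = noiseModel,
                 dirichletConc = dirichletConc, alphaRange = alphaRange,
                 abundanceMeanlog = abundanceMeanlog,
                 abundanceSdlog = abundanceSdlog,
                 maxSimilarity = maxSimilarity, overlapPairs = overlapPairs,
                 overlapSimilarity = overlapSimilarity,
                 templateWidth = templateWidth, classNames = classNames),
            class = "SyntheticSpec")
}

.cosine <- function(a, b) sum(a * b) / sqrt(sum(a * a) * sum(b * b))

#' Fraction-enrichment templates for the synthetic classes
#'
#' One simplex vector (nonnegative, summing to 1) per class over one
#' replicate's channels, each peaking at a distinct fraction index
#' (mimicking differential-pelleting enrichment).  Pairwise cosine
#' similarity stays below `spec$maxSimilarity`, except for requested
#' overlapping pairs which are pushed to `spec$overlapSimilarity`.
#'
#' @param spec a `SyntheticSpec`.
#' @return `nClasses x nChannels` matrix with class rownames.
#' @export
makeClassTemplates <- function(spec) {
  k <- spec$nClasses
  nc <- spec$nChannels
  centers <- seq(1, nc, length.out = k)
  idx <- seq_len(nc)
  tpl <- matrix(0, k, nc, dimnames = list(spec$classNames, NULL))
  for (ci in seq_len(k)) {
    v <- exp(-(idx - centers[ci])^2 / (2 * spec$templateWidth^2))
    tpl[ci, ] <- v / sum(v)
  }
  for (p in spec$overlapPairs) {
    a <- tpl[p[1], ]
    b0 <- tpl[p[2], ]
    target <- spec$overlapSimilarity
    if (is.na(target)) {
      # make the pair genuinely unresolved: total template separation
      # across all replicate blocks equal to one per-channel noise sd,
      # i.e. a pair Bayes error of Phi(-1/2) ~ 31% under the isotropic
      # noise model - "overlapping distributions", not merely nearby
      dTarget <- spec$noiseSd / sqrt(spec$nReplicates)
      target <- max(0.95, 1 - dTarget^2 / (2 * sum(a * a)))
    }
    f <- function(beta) {
      .cosine((1 - beta) * b0 + beta * a, a) - target
    }
    if (f(0) >= 0) next  # already overlapping
    beta <- stats::uniroot(f, c(0, 1), tol = 1e-10)$root
    v <- (1 - beta) * b0 + beta * a
    tpl[p[2], ] <- v / sum(v)
  }
  ov <- vapply(spec$overlapPairs, paste, collapse = "\r", character(1))
  for (i in seq_len(k - 1)) {
    for (j in seq((i + 1), k)) {
      pr <- c(paste(spec$classNames[c(i, j)], collapse = "\r"),
              paste(spec$classNames[c(j, i)], collapse = "\r"))
      if (any(pr %in% ov)) next
      if (.cosine(tpl[i, ], tpl[j, ]) > spec$maxSimilarity)
        stop("infeasible template separation: classes '",
             spec$classNames[i], "' and '", spec$classNames[j],
             "' exceed cosine similarity ", spec$maxSimilarity)
    }
  }
  tpl
}

# Roster of synthetic proteins: accession, role, ground truth, mixing
# parameters and abundance.  Shared between paired maps.
.makeRoster <- function(spec) {
  cls <- spec$classNames
  acc <- character(0)
  role <- character(0)
  truth <- character(0)
  marker <- character(0)
  mix1 <- character(0); mix2 <- character(0); alpha <- numeric(0)
  for (ci in seq_along(cls)) {
    if (spec$markersPerClass > 0) {
      a <- sprintf("MRK-%02d-%03d", ci, seq_len(spec$markersPerClass))
      acc <- c(acc, a); role <- c(role, rep("marker", length(a)))
      truth <- c(truth, rep(cls[ci], length(a)))
      marker <- c(marker, rep(cls[ci], length(a)))
      mix1 <- c(mix1, rep(NA, length(a))); mix2 <- c(mix2, rep(NA, length(a)))
      alpha <- c(alpha, rep(NA, length(a)))
    }
    if (spec$unknownsPerClass > 0) {
      a <- sprintf("UNK-%02d-%03d", ci, seq_len(spec$unknownsPerClass))
      acc <- c(acc, a); role <- c(role, rep("unknown", length(a)))
      truth <- c(truth, rep(cls[ci], length(a)))
      marker <- c(marker, rep("unknown", length(a)))
      mix1 <- c(mix1, rep(NA, length(a))); mix2 <- c(mix2, rep(NA, length(a)))
      alpha <- c(alpha, rep(NA, length(a)))
    }
  }
  if (spec$nMultilocal > 0) {
    a <- sprintf("MIX-%04d", seq_len(spec$nMultilocal))
    pairIdx <- t(vapply(seq_len(spec$nMultilocal), function(i)
      sample.int(spec$nClasses, 2), integer(2)))
    al <- stats::runif(spec$nMultilocal, spec$alphaRange[1],
                       spec$alphaRange[2])
    acc <- c(acc, a); role <- c(role, rep("multilocal", length(a)))
    truth <- c(truth, sprintf("mixed(%s,%s,%.4f)", cls[pairIdx[, 1]],
                              cls[pairIdx[, 2]], al))
    marker <- c(marker, rep("unknown", length(a)))
    mix1 <- c(mix1, cls[pairIdx[, 1]]); mix2 <- c(mix2, cls[pairIdx[, 2]])
    alpha <- c(alpha, al)
  }
  if (spec$nUnrelated > 0) {
    a <- sprintf("NON-%04d", seq_len(spec$nUnrelated))
    acc <- c(acc, a); role <- c(role, rep("unrelated", length(a)))
    truth <- c(truth, rep("none", length(a)))
    marker <- c(marker, rep("unknown", length(a)))
    mix1 <- c(mix1, rep(NA, length(a))); mix2 <- c(mix2, rep(NA, length(a)))
    alpha <- c(alpha, rep(NA, length(a)))
  }
  abun <- stats::rlnorm(length(acc), spec$abundanceMeanlog,
                        spec$abundanceSdlog)
  data.frame(accession = acc, role = role, groundTruth = truth,
             markerClass = marker, mixClass1 = mix1, mixClass2 = mix2,
             mixAlpha = alpha, abundance = abun,
             stringsAsFactors = FALSE)
}

# Profiles for a roster given one map's templates; noise drawn from the
# current RNG state.
.makeProfiles <- function(spec, roster, templates) {
  n <- nrow(roster)
  nc <- spec$nChannels
  nb <- spec$nReplicates
  m <- matrix(0, n, nc * nb)
  mean_profile <- matrix(0, n, nc)
  known <- roster$role %in% c("marker", "unknown")
  mean_profile[known, ] <- templates[roster$groundTruth[known], , drop = FALSE]
  multi <- roster$role == "multilocal"
  if (any(multi)) {
    mean_profile[multi, ] <-
      roster$mixAlpha[multi] * templates[roster$mixClass1[multi], ,
                                         drop = FALSE] +
      (1 - roster$mixAlpha[multi]) * templates[roster$mixClass2[multi], ,
                                               drop = FALSE]
  }
  unrel <- which(roster$role == "unrelated")
  for (b in seq_len(nb)) {
    cols <- (b - 1) * nc + seq_len(nc)
    block <- mean_profile
    if (length(unrel)) {
      # flat Dirichlet: no organelle structure, independent per block
      g <- matrix(stats::rexp(length(unrel) * nc), length(unrel), nc)
      block[unrel, ] <- g / rowSums(g)
    }
    if (spec$noiseModel == "gaussian") {
      if (spec$noiseSd > 0)
        block <- block + matrix(stats::rnorm(n * nc, 0, spec$noiseSd), n, nc)
      block[block < 0] <- 0
      rs <- rowSums(block)
      rs[rs == 0] <- 1
      block <- block / rs
    } else {
      g <- matrix(stats::rgamma(n * nc,
                                shape = block * spec$dirichletConc + 1e-8),
                  n, nc)
      block <- g / rowSums(g)
    }
    m[, cols] <- block
  }
  dimnames(m) <- list(roster$accession,
                      paste0("R", rep(seq_len(nb), each = nc),
                             "F", sprintf("%02d", rep(seq_len(nc), nb))))
  m
}

.channelInfoFor <- function(spec) {
  data.frame(replicate = rep(seq_len(spec$nReplicates), each = spec$nChannels),
             fraction = rep(seq_len(spec$nChannels), spec$nReplicates))
}

#' Generate a synthetic organelle map with known ground truth
#'
#' Draws a [ProfileSet-class] according to a [syntheticSpec()]: each
#' single-location protein's profile is its class template plus noise,
#' multilocalising proteins are alpha-mixtures of two templates (their
#' ground truth records `mixed(c1,c2,alpha)` and they never enter the
#' marker set), unrelated proteins carry no class structure.  Profiles
#' are clipped at zero and renormalised per replicate block, so every
#' generated dataset is a valid complete `ProfileSet`.  Bit-identical
#' for equal seeds.
#'
#' @param spec a `SyntheticSpec`.
#' @param seed integer seed.
#' @return list with `dataset` (annotated `ProfileSet`), `markers`
#'   (`MarkerAnnotation`) and `templates`.
#' @export
generateDataset <- function(spec, seed = 1) {
  set.seed(seed)
  templates <- makeClassTemplates(spec)
  roster <- .makeRoster(spec)
  m <- .makeProfiles(spec, roster, templates)
  fi <- roster[, c("role", "groundTruth", "markerClass", "mixClass1",
                   "mixClass2", "mixAlpha", "abundance")]
  rownames(fi) <- roster$accession
  ds <- ProfileSet(m, channelInfo = .channelInfoFor(spec), featureInfo = fi)
  mk <- roster$role == "marker"
  markers <- MarkerAnnotation(stats::setNames(roster$markerClass[mk],
                                              roster$accession[mk]),
                              classes = spec$classNames)
  list(dataset = ds, markers = markers, templates = templates)
}

#' Generate paired primary/auxiliary maps over the same proteins
#'
#' Two maps of one shared protein roster (same ground truth,
#' multilocalisation mixtures and abundances) whose class separability
#' is controlled independently: designated class pairs can overlap in
#' exactly one map, emulating two fractionation chemistries that
#' resolve different niches (e.g. cytosol and proteasome overlapping in
#' a density-gradient map but separating under differential pelleting).
#'
#' @param specPrimary,specAuxiliary `SyntheticSpec`s sharing the class
#'   set and protein roster counts (they may differ in overlap pairs,
#'   noise and channel layout).
#' @param seed integer seed (roster uses `seed`, map noise `seed + 1`
#'   and `seed + 2`).
#' @return list with `primary` and `auxiliary` (as [generateDataset()]
#'   outputs) and the shared `markers`.
#' @export
generatePairedMaps <- function(specPrimary, specAuxiliary, seed = 1) {
  if (!identical(specPrimary$classNames, specAuxiliary$classNames))
    stop("class sets of the two specs differ")
  rosterFields <- c("markersPerClass", "unknownsPerClass", "nMultilocal",
                    "nUnrelated", "alphaRange", "abundanceMeanlog",
                    "abundanceSdlog")
  if (!identical(specPrimary[rosterFields], specAuxiliary[rosterFields]))
    stop("protein rosters of the two specs differ")
  set.seed(seed)
  roster <- .makeRoster(specPrimary)
  build <- function(spec, s) {
    set.seed(s)
    templates <- makeClassTemplates(spec)
    m <- .makeProfiles(spec, roster, templates)
    fi <- roster[, c("role", "groundTruth", "markerClass", "mixClass1",
                     "mixClass2", "mixAlpha", "abundance")]
    rownames(fi) <- roster$accession
    list(dataset = ProfileSet(m, channelInfo = .channelInfoFor(spec),
                              featureInfo = fi),
         templates = templates)
  }
  primary <- build(specPrimary, seed + 1)
  auxiliary <- build(specAuxiliary, seed + 2)
  mk <- roster$role == "marker"
  markers <- MarkerAnnotation(stats::setNames(roster$markerClass[mk],
                                              roster$accession[mk]),
                              classes = specPrimary$classNames)
  list(primary = primary, auxiliary = auxiliary, markers = markers)
}

#' Write a generated dataset as profile/marker/ground-truth TSV files
#'
#' @param generated output of [generateDataset()].
#' @param dir output directory (created if needed).
#' @return invisibly, the three file paths.
#' @export
writeSyntheticDataset <- function(generated, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pf <- file.path(dir, "profiles.tsv")
  mf <- file.path(dir, "markers.tsv")
  gf <- file.path(dir, "ground_truth.tsv")
  writeProfileTable(generated$dataset, pf)
  lab <- markerLabels(generated$markers)
  utils::write.table(data.frame(accession = names(lab), class = lab),
                     mf, sep = "\t", quote = FALSE, row.names = FALSE)
  fi <- featureInfo(generated$dataset)
  utils::write.table(data.frame(accession = rownames(fi),
                                role = fi$role,
                                groundTruth = fi$groundTruth,
                                abundance = fi$abundance),
                     gf, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(profiles = pf, markers = mf, groundTruth = gf))
}
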