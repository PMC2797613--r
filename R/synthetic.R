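# Feature scales used by the generator: plausible zebra-finch syllable
# means, with per-feature CVs for the non-singing condition and UD-singing
# CV multipliers matching the relative increase reported for adult-tutored
# juveniles at 75 days.
.FEATURE_MEANS <- c(duration = 0.12, amplitude = 70, pitch = 800, fm = 30,
                    wiener_entropy = -2.0, mean_frequency = 3500,
                    pitch_goodness = 150)
.FEATURE_CVS_NS <- c(duration = 0.064, amplitude = 0.034, pitch = 0.074,
                     fm = 0.118, wiener_entropy = 0.085,
                     mean_frequency = 0.064, pitch_goodness = 0.101)
.FEATURE_CV_MULT_UD <- c(duration = 0.97, amplitude = 1.26, pitch = 1.14,
                         fm = 1.06, wiener_entropy = 1.15,
                         mean_frequency = 1.02, pitch_goodness = 1.22)
.POSITIVE_FEATURES <- c("duration", "pitch", "mean_frequency")

#' Mixture Markov chain over a syllable cycle
#'
#' One-parameter family of song-syntax models spanning the full entropy
#' range: with mixing weight `epsilon`, syllable `i` transitions to its
#' cycle successor with probability `(1 - epsilon) + epsilon/n` and to each
#' other syllable (including itself) with probability `epsilon/n`.
#' `epsilon = 0` is a deterministic cycle (fixed syllable order, entropy
#' 0); `epsilon = 1` is the uniform chain (entropy 1 after normalization).
#'
#' @param nSyllables repertoire size n >= 2.
#' @param epsilon mixing weight in \[0, 1\].
#' @return a [TransitionModel-class] with integer labels `"1" ... "n"` and
#'   no end-of-motif outcome.
#' @seealso [chainEntropy()] for the closed-form row entropy.
#' @export
makeTransitionMatrix <- function(nSyllables, epsilon) {
  if (nSyllables < 2L) stop("need at least 2 syllables")
  stopifnot(epsilon >= 0, epsilon <= 1)
  n <- as.integer(nSyllables)
  labels <- as.character(seq_len(n))
  p <- matrix(epsilon / n, n, n, dimnames = list(labels, labels))
  succ <- c(seq_len(n)[-1L], 1L)
  p[cbind(seq_len(n), succ)] <- (1 - epsilon) + epsilon / n
  new("TransitionModel", alphabet = labels, endIncluded = FALSE, prob = p)
}

#' Closed-form normalized row entropy of the mixture chain
#'
#' Every row of the [makeTransitionMatrix()] chain has entropy
#' `H = -(p1 log2 p1 + (n-1) q log2 q)` with `q = epsilon/n` and
#' `p1 = 1 - epsilon + q`; normalized by the string-mode ceiling `log2(n)`
#' this gives the exact motif entropy an infinitely long string from the
#' chain would yield. Used as the analytic ground truth in estimator
#' consistency checks.
#'
#' @param epsilon mixing weight in \[0, 1\].
#' @param nSyllables repertoire size n >= 2.
#' @param base logarithm base (cancels in the normalization).
#' @return normalized row entropy in \[0, 1\].
#' @export
chainEntropy <- function(epsilon, nSyllables, base = 2) {
  stopifnot(epsilon >= 0, epsilon <= 1, nSyllables >= 2)
  n <- nSyllables
  q <- epsilon / n
  p1 <- 1 - epsilon + q
  plogp <- function(p) ifelse(p > 0, p * log(p, base = base), 0)
  H <- -(plogp(p1) + (n - 1) * plogp(q))
  H / log(n, base = base)
}

.walk_chain <- function(model, length, start = NULL) {
  p <- model@prob
  labels <- rownames(p)
  idx <- integer(length)
  idx[1L] <- if (is.null(start)) sample.int(nrow(p), 1L) else match(start, labels)
  for (t in seq_len(length - 1L))
    idx[t + 1L] <- sample.int(ncol(p), 1L, prob = p[idx[t], ])
  labels[idx]
}

#' Sample a set of motifs from a transition model
#'
#' Walks the chain to produce `nMotifs` motifs, each started at the first
#' syllable of the alphabet (the natural motif onset of the cycle family).
#' Motif length is either fixed (`motifLength`, default the repertoire
#' size, one pass of the cycle) or geometric: with `endProb` set, the motif
#' terminates after each syllable with that probability (length capped at
#' `maxLength`).
#'
#' @param model a [TransitionModel-class].
#' @param nMotifs number of motifs (default 20, one recording bout).
#' @param motifLength fixed motif length (ignored when `endProb` is given).
#' @param endProb per-syllable termination probability, or NULL.
#' @param seed optional integer seed.
#' @param birdId,condition,ageDays metadata for the result.
#' @param maxLength cap on geometric motif length (default 100).
#' @return a [MotifSet-class]; deterministic given `seed`.
#' @export
sampleMotifs <- function(model, nMotifs = 20L, motifLength = NULL,
                         endProb = NULL, seed = NULL,
                         birdId = NA_character_, condition = NA_character_,
                         ageDays = NA_character_, maxLength = 100L) {
  stopifnot(is(model, "TransitionModel"), nMotifs >= 1L)
  if (is.null(motifLength)) motifLength <- nrow(model@prob)
  start <- rownames(model@prob)[1L]
  ms <- .with_seed(seed, lapply(seq_len(nMotifs), function(i) {
    if (is.null(endProb)) {
      .walk_chain(model, motifLength, start = start)
    } else {
      len <- min(1L + stats::rgeom(1L, endProb), maxLength)
      .walk_chain(model, len, start = start)
    }
  }))
  motifSet(ms, birdId = birdId, condition = condition, ageDays = ageDays)
}

#' Sample a long syllable string from a transition model
#'
#' A single chain walk of the requested length with no end-of-motif
#' markers, emulating the first ~300 automatically segmented syllables of
#' a recording session.
#'
#' @param model a [TransitionModel-class].
#' @param length number of syllables (default 300).
#' @param seed optional integer seed.
#' @param birdId,condition,ageDays metadata for the result.
#' @return a [SyllableString-class]; deterministic given `seed`.
#' @export
sampleSyllableString <- function(model, length = 300L, seed = NULL,
                                 birdId = NA_character_,
                                 condition = NA_character_,
                                 ageDays = NA_character_) {
  stopifnot(is(model, "TransitionModel"), length >= 2L)
  syms <- .with_seed(seed,
                     .walk_chain(model, length, start = rownames(model@prob)[1L]))
  syllableString(syms, birdId = birdId, condition = condition,
                 ageDays = ageDays, nominalLength = length)
}

#' Sample per-rendition acoustic features with known CV
#'
#' Draws `n` independent renditions of one syllable: each feature is
#' Gaussian with the given mean and SD = CV x |mean|. Features that are
#' physically positive (duration, pitch, mean frequency) are redrawn if a
#' draw falls at or below zero (negligible at realistic CVs).
#'
#' @param bird,syllable,condition labels written into the table.
#' @param means named per-feature means (defaults: plausible zebra-finch
#'   syllable values).
#' @param cv per-feature CVs, a named vector or a single number recycled
#'   over features; must be nonnegative.
#' @param n renditions (default 25).
#' @param seed optional integer seed.
#' @return a data.frame in the [readFeatureTable()] layout.
#' @export
sampleFeatureRenditions <- function(bird, syllable, condition,
                                    means = .FEATURE_MEANS,
                                    cv = .FEATURE_CVS_NS, n = 25L,
                                    seed = NULL) {
  stopifnot(n >= 2L)
  if (length(cv) == 1L) cv <- stats::setNames(rep(cv, length(.FEATURES)), .FEATURES)
  if (any(cv < 0)) stop("cv must be nonnegative")
  missing <- setdiff(.FEATURES, names(means))
  if (length(missing)) stop("means missing for: ", paste(missing, collapse = ", "))
  draws <- .with_seed(seed, {
    out <- lapply(.FEATURES, function(f) {
      sdev <- cv[[f]] * abs(means[[f]])
      v <- stats::rnorm(n, means[[f]], sdev)
      if (f %in% .POSITIVE_FEATURES) {
        bad <- which(v <= 0)
        while (length(bad)) {
          v[bad] <- stats::rnorm(length(bad), means[[f]], sdev)
          bad <- which(v <= 0)
        }
      }
      v
    })
    names(out) <- .FEATURES
    out
  })
  data.frame(bird = bird, syllable = as.character(syllable),
             condition = condition, rendition = seq_len(n),
             as.data.frame(draws))
}

#' Generate a paired two-condition synthetic song dataset
#'
#' Emulates the paired study design: each of `nBirds` birds is recorded
#' under a non-singing (`NS-UD`) and an undirected-singing (`UD-UD`)
#' condition, with singing practice making song syntax more variable
#' (higher chain mixing weight `epsUD > epsNS`) and acoustic features more
#' variable (UD CV multipliers > 1 for most features). Bird-level
#' heterogeneity enters through a Gaussian perturbation (SD
#' `betweenBirdSD`, clipped to \[0, 1\]) of each bird's condition epsilons.
#' For every bird and condition the generator produces a 20-motif
#' [MotifSet-class], a length-`stringLength` [SyllableString-class], and a
#' feature table of `nFeatureSyllables` syllables x 25 renditions; the
#' ground-truth per-bird epsilons and closed-form entropies are returned
#' for recovery tests.
#'
#' @param nBirds number of birds (default 11, the 75-day cohort size).
#' @param nSyllables repertoire size (default 5).
#' @param epsNS,epsUD condition-level chain mixing weights (defaults 0.2
#'   and 0.4).
#' @param betweenBirdSD SD of the bird-level epsilon perturbation
#'   (default 0.05); inflate to emulate the high between-bird variability
#'   of younger birds.
#' @param stringLength syllable-string length (default 300).
#' @param nMotifs motifs per bird and condition (default 20).
#' @param nFeatureSyllables syllables with feature renditions per bird
#'   (default 3).
#' @param cvNS per-feature NS-UD CVs; `cvMultiplierUD` scales them for the
#'   UD-UD condition.
#' @param seed optional integer seed; the whole dataset is a pure function
#'   of it.
#' @param dir optional output directory; when given, all motif files,
#'   string files and feature CSVs plus a `ground_truth.json` are written
#'   there in the package's text formats.
#' @param ageDays age label (default `"75"`).
#' @return (invisibly when `dir` is set) a list with `birds` (per-bird list
#'   of per-condition `motifs`, `string`, `features`), `groundTruth`
#'   (data.frame of bird, condition, epsilon, entropy), and `params`.
#' @export
makePairedDataset <- function(nBirds = 11L, nSyllables = 5L, epsNS = 0.2,
                              epsUD = 0.4, betweenBirdSD = 0.05,
                              stringLength = 300L, nMotifs = 20L,
                              nFeatureSyllables = 3L, cvNS = .FEATURE_CVS_NS,
                              cvMultiplierUD = .FEATURE_CV_MULT_UD,
                              seed = NULL, dir = NULL, ageDays = "75") {
  stopifnot(nBirds >= 2L, epsNS >= 0, epsNS <= 1, epsUD >= 0, epsUD <= 1)
  gen <- function() {
    conds <- c("NS-UD", "UD-UD")
    condEps <- c("NS-UD" = epsNS, "UD-UD" = epsUD)
    birds <- list()
    gt <- list()
    for (b in seq_len(nBirds)) {
      birdId <- sprintf("bird%02d", b)
      per <- list()
      for (cond in conds) {
        # independent bird-level perturbation per condition: inflating the
        # SD reproduces the high within-condition variability of younger birds
        eps <- min(max(condEps[[cond]] + stats::rnorm(1L, 0, betweenBirdSD), 0), 1)
        model <- makeTransitionMatrix(nSyllables, eps)
        cvs <- if (cond == "UD-UD") cvNS * cvMultiplierUD[names(cvNS)] else cvNS
        feats <- if (nFeatureSyllables >= 1L) {
          do.call(rbind, lapply(seq_len(nFeatureSyllables), function(s) {
            sampleFeatureRenditions(birdId, as.character(s), cond, cv = cvs)
          }))
        } else NULL
        per[[cond]] <- list(
          epsilon = eps,
          motifs = sampleMotifs(model, nMotifs = nMotifs, birdId = birdId,
                                condition = cond, ageDays = ageDays),
          string = sampleSyllableString(model, length = stringLength,
                                        birdId = birdId, condition = cond,
                                        ageDays = ageDays),
          features = feats
        )
        gt[[length(gt) + 1L]] <- data.frame(
          bird = birdId, condition = cond, epsilon = eps,
          entropy = chainEntropy(eps, nSyllables))
      }
      birds[[birdId]] <- per
    }
    list(birds = birds, groundTruth = do.call(rbind, gt),
         params = list(nBirds = nBirds, nSyllables = nSyllables,
                       epsNS = epsNS, epsUD = epsUD,
                       betweenBirdSD = betweenBirdSD,
                       stringLength = stringLength, nMotifs = nMotifs,
                       seed = if (is.null(seed)) NA_integer_ else as.integer(seed)))
  }
  ds <- .with_seed(seed, gen())
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (birdId in names(ds$birds)) {
      for (cond in names(ds$birds[[birdId]])) {
        x <- ds$birds[[birdId]][[cond]]
        stem <- file.path(dir, paste0(birdId, "_", cond))
        writeMotifFile(x$motifs, paste0(stem, "_motifs.txt"))
        writeSyllableString(x$string, paste0(stem, "_string.txt"))
        writeFeatureTable(x$features, paste0(stem, "_features.csv"))
      }
    }
    jsonlite::write_json(
      list(params = ds$params, ground_truth = ds$groundTruth),
      file.path(dir, "ground_truth.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
    return(invisible(ds))
  }
  ds
}
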