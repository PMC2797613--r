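#' Per-syllable acoustic feature summaries
#'
#' For each (bird, syllable, condition) cell and each acoustic feature,
#' computes the mean, sample standard deviation (n - 1 denominator),
#' standard error of the mean `SD / sqrt(n)`, and coefficient of variation
#' `CV = SD / |mean|` across renditions (conventionally 25 consecutive
#' renditions per syllable). The magnitude of the mean is used so that
#' features on a negative scale (Wiener entropy) report a positive CV; a
#' zero mean leaves the CV undefined (`NA` with a warning).
#'
#' @param table a data.frame in the [readFeatureTable()] layout.
#' @param features feature columns to summarize (default: the seven
#'   standard acoustic features).
#' @return a long data.frame with one row per (bird, syllable, condition,
#'   feature): columns `bird`, `syllable`, `condition`, `feature`, `n`,
#'   `mean`, `sd`, `se`, `cv`.
#' @examples
#' tab <- sampleFeatureRenditions(bird = "b01", syllable = "1",
#'                                condition = "NS-UD", seed = 1)
#' head(featureSummary(tab))
#' @export
featureSummary <- function(table, features = .FEATURES) {
  validateFeatureTable(table)
  key <- interaction(table$bird, table$syllable, table$condition, drop = TRUE)
  ns <- tabulate(key)
  if (any(ns < 2L))
    stop("every (bird, syllable, condition) cell needs >= 2 renditions")
  pieces <- lapply(split(seq_len(nrow(table)), key), function(idx) {
    sub <- table[idx, , drop = FALSE]
    n <- nrow(sub)
    do.call(rbind, lapply(features, function(f) {
      v <- sub[[f]]
      m <- mean(v)
      s <- stats::sd(v)
      cv <- if (m == 0) NA_real_ else s / abs(m)
      data.frame(bird = sub$bird[1], syllable = as.character(sub$syllable[1]),
                 condition = sub$condition[1], feature = f, n = n,
                 mean = m, sd = s, se = s / sqrt(n), cv = cv)
    }))
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  if (anyNA(out$cv))
    warning("CV undefined (zero mean) for some (syllable, feature) cells")
  out
}

#' Aggregate CV (or any summary column) across syllables or birds
#'
#' Group-level aggregation of per-syllable summaries, per condition and
#' feature. `level = "per_syllable"` averages over all syllables ignoring
#' which bird sang them (appropriate when a permutation ANOVA shows the
#' syllable, not the bird, is the independent unit, as for CV scores);
#' `level = "per_bird_then_group"` first averages each bird's syllables,
#' then averages the per-bird means (appropriate when the bird is the
#' independent unit, as for similarity/accuracy scores).
#'
#' @param summaries a data.frame from [featureSummary()].
#' @param level `"per_syllable"` or `"per_bird_then_group"`.
#' @param measure summary column to aggregate (default `"cv"`).
#' @return a data.frame with one row per (condition, feature): `mean`, `se`
#'   (over the independent units), and `n` (number of units).
#' @export
aggregateCV <- function(summaries,
                        level = c("per_syllable", "per_bird_then_group"),
                        measure = "cv") {
  level <- match.arg(level)
  stopifnot(nrow(summaries) > 0, measure %in% names(summaries))
  grp <- split(summaries, list(summaries$condition, summaries$feature),
               drop = TRUE)
  out <- do.call(rbind, lapply(grp, function(sub) {
    units <- if (level == "per_syllable") {
      v <- sub[[measure]]
      # one value per syllable (bird x syllable), as sub already is
      v
    } else {
      vapply(split(sub[[measure]], sub$bird), mean, 0, na.rm = TRUE)
    }
    units <- units[!is.na(units)]
    data.frame(condition = sub$condition[1], feature = sub$feature[1],
               level = level, mean = mean(units),
               se = stats::sd(units) / sqrt(length(units)),
               n = length(units))
  }))
  rownames(out) <- NULL
  out
}

#' Summarize an all-vs-all score batch
#'
#' Mean and standard error of the off-diagonal scores of an m x m
#' similarity (and, when present, accuracy) batch: the diagonal
#' self-comparisons are excluded, leaving exactly `m^2 - m` scores (380 for
#' 20 motifs, 870 for 30 clips).
#'
#' @param x a [ScoreMatrix-class], or a plain square numeric matrix of
#'   similarity scores.
#' @return a data.frame with one row per score type (`similarity`, and
#'   `accuracy` if present): `mean`, `se`, `n_scores`.
#' @examples
#' m <- matrix(85, 20, 20)
#' aggregateScores(m)  # n_scores = 380
#' @export
aggregateScores <- function(x) {
  if (is.matrix(x)) x <- scoreBatch(x)
  stopifnot(is(x, "ScoreMatrix"))
  m <- nrow(x@similarity)
  if (m < 2L) stop("need at least 2 items for pairwise scores")
  off <- !diag(m)
  one <- function(mat, what) {
    v <- mat[off]
    data.frame(score = what, mean = mean(v),
               se = stats::sd(v) / sqrt(length(v)), n_scores = length(v))
  }
  out <- one(x@similarity, "similarity")
  if (length(x@accuracy)) out <- rbind(out, one(x@accuracy, "accuracy"))
  rownames(out) <- NULL
  out
}

#' Syllable identity score
#'
#' `similarity * accuracy / 100`, both on the 0-100 scale. Identity is
#' computed per syllable before any averaging across syllables or birds.
#'
#' @param similarity,accuracy numeric vectors in \[0, 100\].
#' @return identity scores in \[0, 100\].
#' @export
identityScore <- function(similarity, accuracy) {
  if (any(similarity < 0 | similarity > 100) ||
      any(accuracy < 0 | accuracy > 100))
    stop("similarity and accuracy must lie in [0, 100]")
  similarity * accuracy / 100
}

#' Construct a FeatureTrajectory
#'
#' @param pitch,fm,wienerEntropy,pitchGoodness equal-length numeric frame
#'   series.
#' @param framePeriodMs frame period in milliseconds (default 9).
#' @return a [FeatureTrajectory-class].
#' @export
featureTrajectory <- function(pitch, fm, wienerEntropy, pitchGoodness,
                              framePeriodMs = 9) {
  v <- cbind(pitch = pitch, fm = fm, wiener_entropy = wienerEntropy,
             pitch_goodness = pitchGoodness)
  new("FeatureTrajectory", framePeriodMs = framePeriodMs, values = v)
}

#' Per-feature robust scale for trajectory comparison
#'
#' Median absolute deviation of each feature, pooled over the frames of all
#' supplied trajectories; used to put the four features on a common scale
#' before Euclidean distances are taken. Features with zero MAD fall back
#' to 1 so that constant features do not blow up distances.
#'
#' @param ... [FeatureTrajectory-class] objects (or one list of them).
#' @return named numeric vector of four positive scale factors.
#' @export
trajectoryScale <- function(...) {
  trajs <- list(...)
  if (length(trajs) == 1L && is.list(trajs[[1]]) && !is(trajs[[1]], "FeatureTrajectory"))
    trajs <- trajs[[1]]
  pooled <- do.call(rbind, lapply(trajs, function(t) t@values))
  sc <- apply(pooled, 2, stats::mad)
  sc[sc == 0 | !is.finite(sc)] <- 1
  sc
}

#' Simplified feature-trajectory similarity and accuracy
#'
#' A deliberately simplified analogue of spectral song-comparison scoring:
#' the four features of each frame are divided by per-feature robust scales,
#' the Euclidean distance `d` between two scaled frames is mapped to a local
#' score `100 * exp(-d / tau)` (so zero distance scores 100 and a mean
#' scaled distance of 1 scores 50 with the default `tau = 1/log(2)`), and
#'
#' * **accuracy** is the mean local score over frame-by-frame aligned
#'   frames (the short, 9 ms granularity);
#' * **similarity** is the mean over consecutive `windowMs` windows of `a`
#'   of the window score, where in `"symmetric"` mode each window of `a` is
#'   compared with the co-located window of `b`, and in `"asymmetric"` mode
#'   each window of `a` is compared with **every** same-length window of
#'   `b` and the best match is kept (comparison of the most similar song
#'   elements independent of their position).
#'
#' Identical trajectories score 100 for both measures in both modes.
#'
#' @param a,b [FeatureTrajectory-class] objects on the same frame grid.
#' @param mode `"asymmetric"` or `"symmetric"`.
#' @param scale per-feature positive scale factors; defaults to
#'   [trajectoryScale()] of the two inputs.
#' @param tau distance constant of the score map (default `1/log(2)`).
#' @param windowMs similarity window length in milliseconds (default 70).
#' @return named numeric `c(similarity = , accuracy = )`, both in \[0, 100\].
#' @export
trajectorySimilarity <- function(a, b, mode = c("asymmetric", "symmetric"),
                                 scale = NULL, tau = 1 / log(2),
                                 windowMs = 70) {
  mode <- match.arg(mode)
  stopifnot(is(a, "FeatureTrajectory"), is(b, "FeatureTrajectory"))
  if (nrow(a@values) < 1L || nrow(b@values) < 1L)
    stop("zero-length trajectory")
  if (is.null(scale)) scale <- trajectoryScale(a, b)
  if (any(scale <= 0)) stop("scale factors must be positive")
  va <- sweep(a@values, 2, scale, "/")
  vb <- sweep(b@values, 2, scale, "/")
  na <- nrow(va); nb <- nrow(vb)

  frame_score <- function(i, j) {
    d <- sqrt(sum((va[i, ] - vb[j, ])^2))
    100 * exp(-d / tau)
  }
  # accuracy: frame-by-frame over the aligned overlap
  nAligned <- min(na, nb)
  accuracy <- mean(vapply(seq_len(nAligned),
                          function(t) frame_score(t, t), 0))

  wf <- max(1L, as.integer(round(windowMs / a@framePeriodMs)))
  starts <- seq.int(1L, na, by = wf)
  win_score <- function(ia, ib, len) {
    mean(vapply(seq_len(len) - 1L,
                function(k) frame_score(ia + k, ib + k), 0))
  }
  scores <- vapply(starts, function(st) {
    len <- min(wf, na - st + 1L)          # last window may be truncated
    if (mode == "symmetric") {
      len2 <- min(len, nb - st + 1L)
      if (len2 < 1L) return(NA_real_)
      win_score(st, st, len2)
    } else {
      offs <- seq_len(max(1L, nb - len + 1L))
      max(vapply(offs, function(ib) {
        len2 <- min(len, nb - ib + 1L)
        win_score(st, ib, len2)
      }, 0))
    }
  }, 0)
  scores <- scores[!is.na(scores)]
  if (!length(scores)) stop("trajectories do not overlap at the window scale")
  c(similarity = mean(scores), accuracy = accuracy)
}

#' Minimal sample count for a stable mean score
#'
#' Empirical stabilization procedure for choosing how many song samples to
#' compare: evaluate the mean similarity and accuracy over the first
#' `start` items, then `start + step`, and so on, and return the smallest
#' count `n` from which the means no longer change -- i.e. the next
#' `consecutive` increments each move every mean by less than `tol` score
#' units. If the means never settle before the items run out, all items are
#' used and a warning is issued.
#'
#' @param items list (or vector) of song samples.
#' @param scoreFn function taking a subset of `items` and returning a named
#'   numeric vector of mean scores (e.g. `c(similarity = , accuracy = )`).
#' @param start first sample count tried (default 10).
#' @param step increment (default 5).
#' @param tol stability tolerance in score units on the 0-100 scale
#'   (default 0.5).
#' @param consecutive how many consecutive stable increments are required
#'   (default 2).
#' @return a list with `n` (the chosen count), `stabilized` (logical), and
#'   `trace` (data.frame of the mean scores at each count).
#' @export
stabilizeSampleCount <- function(items, scoreFn, start = 10L, step = 5L,
                                 tol = 0.5, consecutive = 2L) {
  nItems <- length(items)
  if (nItems < start) stop("need at least ", start, " items")
  ns <- seq.int(start, nItems, by = step)
  means <- t(vapply(ns, function(n) scoreFn(items[seq_len(n)]),
                    scoreFn(items[seq_len(start)]) * 0))
  trace <- data.frame(n = ns, means, check.names = FALSE)
  if (length(ns) >= 2L) {
    diffs <- abs(means[-1L, , drop = FALSE] - means[-length(ns), , drop = FALSE])
    stableStep <- apply(diffs < tol, 1L, all)  # step k: ns[k] -> ns[k+1]
    for (k in seq_len(length(ns) - consecutive)) {
      if (all(stableStep[k:(k + consecutive - 1L)]))
        return(list(n = ns[k], stabilized = TRUE, trace = trace))
    }
  }
  warning("mean scores did not stabilize; using all ", nItems, " items")
  list(n = nItems, stabilized = FALSE, trace = trace)
}
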