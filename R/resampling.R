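# Run expr with a locally seeded RNG, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(list = ".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Lightweight sign-flip p-value used by both the user-facing test and the
# power simulation (avoids building S4 objects in inner loops).
.signflip_p <- function(differences, nIter) {
  n <- length(differences)
  signs <- matrix(sample(c(-1, 1), n * nIter, replace = TRUE), nIter, n)
  nullMs <- as.vector(signs %*% differences) / n
  M <- mean(differences)
  # The sign-flip null is symmetric about zero by construction, so the
  # reflection point is the distribution mean 0 (not the sampled mean,
  # whose jitter would make counting the atom at -M a coin flip and stop
  # the p-value converging to the exact 2^n enumeration). Inclusive
  # counting, with a small tolerance for floating-point ties at +/-M.
  tol <- 1e-9 * max(1, abs(M))
  p <- mean(abs(nullMs) >= abs(M) - tol)
  list(M = M, nullMs = nullMs, nullMean = mean(nullMs), p = p)
}

#' Sign-flip paired bootstrap test
#'
#' Two-tailed resampling test on paired conditional differences. The test
#' statistic is `M`, the group mean of the per-bird differences
#' (UD-UD minus NS-UD). Each of `nIter` iterations multiplies the
#' difference vector elementwise by independent random +1/-1 draws --
#' randomizing the direction of each bird's conditional difference -- and
#' records the mean, building the null distribution of `M`. The p-value is
#' the fraction of null means at or beyond the critical values (the
#' observed `M` and its reflection across the null-distribution mean),
#' counted inclusively.
#'
#' @param differences numeric vector of paired differences, one per bird
#'   (length >= 2).
#' @param nIter number of sign-flip iterations (default 10000).
#' @param seed optional integer seed; when supplied the caller's RNG state
#'   is left untouched.
#' @param alpha significance level recorded with the result (default 0.05).
#' @return a [BootstrapTest-class]. When every difference is zero the null
#'   distribution is a point mass; `p = 1` is returned with a warning.
#' @examples
#' d <- c(0.9, 1.6, 0.1, 1.2, 0.8, 1.4, 0.3, 1.1, 0.7, 1.0, 0.5)
#' pairedSignflipBootstrap(d, seed = 1)
#' @export
pairedSignflipBootstrap <- function(differences, nIter = 10000L, seed = NULL,
                                    alpha = 0.05) {
  stopifnot(length(differences) >= 2L, nIter >= 1L)
  if (all(differences == 0)) {
    warning("all differences are zero: degenerate null distribution, p = 1")
    return(new("BootstrapTest", statistic = 0, nullMean = 0,
               nullStats = rep(0, nIter), pValue = 1, nIter = as.integer(nIter),
               seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
               alpha = alpha, method = "sign-flip paired bootstrap"))
  }
  res <- .with_seed(seed, .signflip_p(differences, nIter))
  new("BootstrapTest", statistic = res$M, nullMean = res$nullMean,
      nullStats = res$nullMs, pValue = res$p, nIter = as.integer(nIter),
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
      alpha = alpha, method = "sign-flip paired bootstrap")
}

# Absolute-deviation ANOVA ratio: between-group over within-group
# variability, as sums of absolute distances from the grand/group means.
.absdev_stat <- function(values, groups, weighted) {
  gm <- mean(values)
  means <- vapply(split(values, groups), mean, 0)
  ng <- tabulate(groups)
  between <- if (weighted) sum(ng * abs(means - gm)) else sum(abs(means - gm))
  within <- sum(abs(values - means[as.integer(groups)]))
  if (within == 0) {
    if (between == 0) 0 else Inf
  } else between / within
}

#' Permutation one-way ANOVA on absolute deviations
#'
#' Resampling analogue of a one-way ANOVA used to decide the independent
#' unit (bird vs syllable) of an analysis. The statistic is the ratio of
#' between-group over within-group variability, computed not as sums of
#' squares but as sums of absolute distances from the grand and group
#' means:
#' `[sum_g n_g |mean_g - grand mean|] / [sum_g sum_i |x_gi - mean_g|]`
#' (set `weighted = FALSE` for unweighted between-group sums). The null
#' distribution is generated by permuting the group labels `nIter` times;
#' the p-value is the fraction of null statistics at or above the observed
#' one (inclusive). If the observed within-group variability is zero the
#' statistic is infinite and the p-value is the fraction of null statistics
#' that are also infinite.
#'
#' @param values numeric response vector.
#' @param groups group labels (coerced to factor), k >= 2 groups, every
#'   group non-empty, total n >= k + 1.
#' @param nIter number of label permutations (default 10000).
#' @param seed optional integer seed.
#' @param weighted weight between-group terms by group size (default TRUE).
#' @param alpha significance level recorded with the result.
#' @return a [BootstrapTest-class] (upper-tailed p).
#' @export
bootstrapOnewayAnova <- function(values, groups, nIter = 10000L, seed = NULL,
                                 weighted = TRUE, alpha = 0.05) {
  groups <- factor(groups)
  k <- nlevels(groups)
  stopifnot(k >= 2L, all(tabulate(groups) >= 1L),
            length(values) >= k + 1L, nIter >= 1L)
  obs <- .absdev_stat(values, groups, weighted)
  nullStats <- .with_seed(seed, vapply(seq_len(nIter), function(i) {
    .absdev_stat(values, sample(groups), weighted)
  }, 0))
  p <- mean(nullStats >= obs)
  new("BootstrapTest", statistic = obs, nullMean = mean(nullStats[is.finite(nullStats)]),
      nullStats = nullStats, pValue = p, nIter = as.integer(nIter),
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
      alpha = alpha, method = "permutation one-way ANOVA on absolute deviations")
}

#' Wilcoxon signed-rank cross-check
#'
#' Standard two-tailed Wilcoxon signed-rank test on the paired differences,
#' used to cross-flag significance calls of the sign-flip bootstrap at the
#' same alpha. Delegates to [stats::wilcox.test()]. All-zero differences
#' leave the test undefined; `NA` is returned with a warning.
#'
#' @param differences numeric vector of paired differences (length >= 2).
#' @return two-tailed p-value, or `NA` when undefined.
#' @export
wilcoxonCrosscheck <- function(differences) {
  stopifnot(length(differences) >= 2L)
  if (all(differences == 0)) {
    warning("all differences are zero: signed-rank test undefined")
    return(NA_real_)
  }
  suppressWarnings(
    stats::wilcox.test(differences, mu = 0, alternative = "two.sided")$p.value
  )
}

#' Monte-Carlo power analysis for the sign-flip test
#'
#' Estimates the power to detect a conditional effect at a prospective
#' sample size. For each of `nOuter` replicates, `nProspective` differences
#' are drawn from the observed difference vector (nonparametric: resampled
#' with replacement; parametric: Gaussian with the observed mean and SD)
#' and the sign-flip paired bootstrap is run with `nInner` iterations;
#' power is the fraction of replicates with `p < alpha`. Power reflects the
#' within-group variability, the between-condition difference, and the
#' number of birds.
#'
#' @param differences observed paired differences (length >= 2).
#' @param nProspective prospective number of birds (>= 2).
#' @param alpha significance level (default 0.05).
#' @param nOuter number of simulated datasets (default 1000).
#' @param nInner sign-flip iterations per simulated dataset (default 2000).
#' @param method `"nonparametric"` (default) or `"parametric"`.
#' @param seed optional integer seed.
#' @return a list with `power`, `nProspective`, `alpha`, `nOuter`,
#'   `nInner`, `method`, `seed`.
#' @export
powerSimulation <- function(differences, nProspective, alpha = 0.05,
                            nOuter = 1000L, nInner = 2000L,
                            method = c("nonparametric", "parametric"),
                            seed = NULL) {
  method <- match.arg(method)
  stopifnot(length(differences) >= 2L, nProspective >= 2L,
            nOuter >= 1L, nInner >= 1L, alpha > 0, alpha < 1)
  mu <- mean(differences); sdev <- stats::sd(differences)
  hits <- .with_seed(seed, vapply(seq_len(nOuter), function(i) {
    d <- if (method == "nonparametric") {
      sample(differences, nProspective, replace = TRUE)
    } else {
      stats::rnorm(nProspective, mu, sdev)
    }
    if (all(d == 0)) return(FALSE)
    .signflip_p(d, nInner)$p < alpha
  }, NA))
  list(power = mean(hits), nProspective = as.integer(nProspective),
       alpha = alpha, nOuter = as.integer(nOuter), nInner = as.integer(nInner),
       method = method, seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}
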