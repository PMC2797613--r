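# Independent oracles used to freeze expected values. These deliberately
# avoid the package's own code paths: plain loops and enumerations only.

# Term-by-term Shannon entropy in bits.
oracle_entropy <- function(p) {
  h <- 0
  for (pi in p) if (pi > 0) h <- h - pi * log2(pi)
  h
}

# Single-pass transition tally over one symbol sequence (no END).
oracle_tally <- function(symbols) {
  counts <- list()
  for (t in seq_len(length(symbols) - 1)) {
    key <- paste(symbols[t], symbols[t + 1], sep = "->")
    counts[[key]] <- (counts[[key]] %||% 0) + 1
  }
  unlist(counts)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# Exhaustive sign-flip test: enumerate all 2^n sign vectors; two-tailed p
# with inclusive counting at the observed |M - null mean| (null mean is 0
# by symmetry of the enumeration).
oracle_signflip_exact <- function(d) {
  n <- length(d)
  stopifnot(n <= 16)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  nullMs <- as.vector(signs %*% d) / n
  # the enumeration mean is exactly 0; inclusive two-tailed counting
  M <- mean(d)
  mean(abs(nullMs) >= abs(M) - 1e-9 * max(1, abs(M)))
}

# Exhaustive label-permutation ANOVA p over all distinct orderings of the
# label vector (positions of group A among n slots); inclusive upper tail.
oracle_anova_exact <- function(values, groups) {
  groups <- factor(groups)
  stat <- function(g) {
    gm <- mean(values)
    means <- tapply(values, g, mean)
    ng <- table(g)
    between <- sum(ng * abs(means - gm))
    within <- sum(abs(values - means[as.character(g)]))
    if (within == 0) { if (between == 0) 0 else Inf } else between / within
  }
  obs <- stat(groups)
  n <- length(values)
  stopifnot(n <= 8)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  stats <- vapply(perms(as.character(groups)), function(g) stat(factor(g)), 0)
  mean(stats >= obs)
}

# Exact two-tailed signed-rank p for all-distinct, all-nonzero differences
# by enumerating all 2^n sign assignments of the ranked magnitudes.
oracle_signed_rank_exact <- function(d) {
  n <- length(d)
  stopifnot(n <= 12, all(d != 0), !anyDuplicated(abs(d)))
  r <- rank(abs(d))
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Vnull <- as.vector(signs %*% r)
  V <- sum(r[d > 0])
  EV <- n * (n + 1) / 4
  mean(abs(Vnull - EV) >= abs(V - EV))
}

# Closed-form normalized entropy of the cycle/uniform mixture chain,
# written independently of the package's version.
oracle_chain_entropy <- function(eps, n) {
  p <- rep(eps / n, n)
  p[1] <- p[1] + (1 - eps)
  oracle_entropy(p) / log2(n)
}

make_paths <- function(...) {
  f <- tempfile(...)
  f
}

write_lines_tmp <- function(lines) {
  f <- tempfile(fileext = ".txt")
  writeLines(lines, f)
  f
}
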