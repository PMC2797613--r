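.tally_sequences <- function(seqs, includeEnd) {
  alphabet <- sort(unique(unlist(seqs)))
  outcomes <- if (includeEnd) c(alphabet, .END) else alphabet
  counts <- matrix(0, nrow = length(alphabet), ncol = length(outcomes),
                   dimnames = list(alphabet, outcomes))
  for (s in seqs) {
    len <- length(s)
    if (len >= 2L) {
      from <- s[-len]
      to <- s[-1L]
      tab <- table(factor(from, levels = alphabet),
                   factor(to, levels = outcomes))
      counts <- counts + unclass(tab)
    }
    if (includeEnd) counts[s[len], .END] <- counts[s[len], .END] + 1
  }
  fTotal <- rowSums(counts)
  new("TransitionCounts", alphabet = alphabet, endIncluded = includeEnd,
      counts = counts, fTotal = fTotal, frequency = fTotal)
}

#' @describeIn countTransitions motif-based tallying: every within-motif
#'   adjacent pair contributes one transition, and with `includeEnd = TRUE`
#'   (the default, matching motif-based analysis) the last syllable of each
#'   motif contributes one transition to the end-of-motif outcome.
#' @export
setMethod("countTransitions", "MotifSet", function(x, includeEnd = TRUE) {
  lens <- lengths(x@motifs)
  if (!includeEnd && all(lens < 2L))
    stop("no transitions: all motifs have a single syllable and END is excluded")
  .tally_sequences(x@motifs, includeEnd = includeEnd)
})

#' @describeIn countTransitions string-based tallying: adjacent pairs along
#'   the single string; the final symbol contributes no transition. String
#'   data carry no motif boundaries, so `includeEnd = TRUE` is an error.
#' @export
setMethod("countTransitions", "SyllableString", function(x, includeEnd = FALSE) {
  if (isTRUE(includeEnd))
    stop("end-of-motif transitions are undefined for a syllable string")
  .tally_sequences(list(x@symbols), includeEnd = FALSE)
})

#' Convert transition counts to probabilities
#'
#' Each transition probability is the count of the (leading, outcome) pair
#' divided by the total outgoing count of the leading syllable:
#' `p(A -> B) = F(A -> B) / sum_i F(A -> i)`. Syllables with no observed
#' outgoing transition (possible only in string mode, for a symbol whose
#' sole occurrence is the final position) have an undefined distribution and
#' are dropped from the model with a warning.
#'
#' @param counts a [TransitionCounts-class].
#' @return a [TransitionModel-class] whose rows each sum to 1.
#' @examples
#' ms <- motifSet(list(c("1", "2", "1", "2")))
#' probMatrix(transitionProbabilities(countTransitions(ms)))
#' @export
transitionProbabilities <- function(counts) {
  stopifnot(is(counts, "TransitionCounts"))
  keep <- counts@fTotal >= 1
  if (!any(keep)) stop("no syllable has an outgoing transition")
  if (!all(keep))
    warning("dropping syllable(s) with no outgoing transitions: ",
            paste(counts@alphabet[!keep], collapse = ", "))
  p <- counts@counts[keep, , drop = FALSE] / counts@fTotal[keep]
  new("TransitionModel", alphabet = counts@alphabet,
      endIncluded = counts@endIncluded, prob = p)
}

.entropy_of_p <- function(p, base = 2) {
  p <- p[p > 0]  # 0 * log(0) := 0
  -sum(p * log(p, base = base))
}

#' Transition entropy of one syllable
#'
#' Shannon entropy of the syllable's outgoing transition distribution,
#' `H = -sum_i p_i log(p_i)` with `0 log 0 := 0`, in bits for the default
#' base 2. A deterministic outcome gives `H = 0`; a uniform distribution
#' over `n` outcomes gives `log2(n)`.
#'
#' @param model a [TransitionModel-class].
#' @param symbol a leading syllable present in the model.
#' @param base logarithm base (default 2, i.e. bits).
#' @return nonnegative entropy.
#' @export
syllableEntropy <- function(model, symbol, base = 2) {
  stopifnot(is(model, "TransitionModel"))
  symbol <- as.character(symbol)
  if (!symbol %in% rownames(model@prob))
    stop("unknown leading syllable '", symbol, "'")
  .entropy_of_p(model@prob[symbol, ], base = base)
}

#' Maximum possible transition entropy
#'
#' Entropy of the uniform distribution over `nOutcomes` possible outcomes:
#' `log2(nOutcomes)` (0 when there is a single outcome). This is the
#' normalization ceiling: a syllable equally likely to transition to every
#' outcome attains it.
#'
#' @param nOutcomes integer >= 1, the number of possible outcomes (unique
#'   syllables, plus one for the end-of-motif outcome when it is tallied).
#' @param base logarithm base (default 2).
#' @return maximum entropy in the chosen base.
#' @export
maxEntropy <- function(nOutcomes, base = 2) {
  if (length(nOutcomes) != 1L || is.na(nOutcomes) || nOutcomes < 1)
    stop("nOutcomes must be a single integer >= 1")
  log(nOutcomes, base = base)
}

#' Normalize a syllable entropy to the repertoire maximum
#'
#' `H / Hmax`, defined as 0 when `Hmax = 0` (single-outcome repertoire).
#' Values are clamped to \[0, 1\] only against floating-point overshoot of at
#' most 1e-12; an `H` genuinely exceeding `Hmax` (beyond 1e-9) indicates
#' inconsistent inputs and is an error.
#'
#' @param H raw entropy (>= 0).
#' @param Hmax maximum possible entropy in the same base (>= 0).
#' @return normalized entropy in \[0, 1\].
#' @export
normalizedEntropy <- function(H, Hmax) {
  stopifnot(H >= 0, Hmax >= 0)
  if (any(H > Hmax + 1e-9))
    stop("H exceeds Hmax: inconsistent entropy inputs")
  len <- max(length(H), length(Hmax))
  H <- rep_len(H, len)
  Hmax <- rep_len(Hmax, len)
  out <- ifelse(Hmax == 0, 0, H / Hmax)
  pmin(pmax(out, 0), 1)
}

#' Motif entropy, stereotypy, and per-syllable entropy table
#'
#' Computes per-syllable normalized transition entropies and averages them
#' into the motif entropy. With `weighting = "standard"` the average is
#' unweighted, so every syllable contributes equally. With
#' `weighting = "weighted"` each syllable's normalized entropy is first
#' multiplied by `w_s = F_s / F_max`, its frequency as a leading syllable
#' relative to the most frequent syllable, damping the influence of rarely
#' sung syllables, and the weighted values are averaged. Stereotypy is
#' `1 - motif entropy` (exactly), and `stereotypyScaled` is 100 times that
#' for comparison with similarity/accuracy scores.
#'
#' The normalization ceiling is `log2(n)` over the possible outcomes: the
#' `nUnique` syllables of the repertoire, plus one for the end-of-motif
#' outcome when END transitions were tallied (`legacyHmax = TRUE` drops the
#' END outcome from the ceiling for sensitivity analysis).
#'
#' @param model a [TransitionModel-class].
#' @param counts the matching [TransitionCounts-class] (source of the
#'   frequency weights).
#' @param weighting `"standard"` or `"weighted"`.
#' @param mode label recorded in the result (`"motif_based"` or
#'   `"string_based"`).
#' @param legacyHmax if TRUE, use `log2(nUnique)` as the ceiling even when
#'   END transitions are included.
#' @param base logarithm base for the raw entropies (default 2; normalized
#'   and motif entropy are base-invariant).
#' @return a [SequenceVariability-class].
#' @examples
#' ms <- motifSet(rep(list(c("1", "2", "3", "4", "5")), 20))
#' cnt <- countTransitions(ms, includeEnd = TRUE)
#' sv <- motifEntropy(transitionProbabilities(cnt), cnt)
#' stereotypy(sv)  # 1: fixed syllable order
#' @export
motifEntropy <- function(model, counts,
                         weighting = c("standard", "weighted"),
                         mode = c("motif_based", "string_based"),
                         legacyHmax = FALSE, base = 2) {
  stopifnot(is(model, "TransitionModel"), is(counts, "TransitionCounts"))
  weighting <- match.arg(weighting)
  mode <- match.arg(mode)
  syms <- rownames(model@prob)
  if (length(syms) == 0L) stop("empty transition model")
  nUnique <- length(model@alphabet)
  nOutcomes <- nUnique + as.integer(model@endIncluded && !legacyHmax)
  Hmax <- maxEntropy(nOutcomes, base = base)
  H <- vapply(syms, function(s) syllableEntropy(model, s, base = base), 0)
  Hnorm <- normalizedEntropy(H, Hmax)
  freq <- counts@frequency[syms]
  w <- freq / max(freq)
  contrib <- if (weighting == "weighted") w * Hnorm else Hnorm
  me <- mean(contrib)
  new("SequenceVariability",
      perSyllable = data.frame(symbol = syms, frequency = unname(freq),
                               weight = unname(w), entropy = unname(H),
                               maxEntropy = Hmax, normEntropy = unname(Hnorm),
                               row.names = NULL),
      motifEntropy = me, stereotypy = 1 - me, stereotypyScaled = 100 * (1 - me),
      nUnique = nUnique, mode = mode, weighting = weighting)
}

#' One-call sequence variability scoring
#'
#' Convenience wrapper running [countTransitions()],
#' [transitionProbabilities()] and [motifEntropy()] on a [MotifSet-class]
#' (motif-based mode, END transitions included by default) or a
#' [SyllableString-class] (string-based mode, END excluded).
#'
#' @param x a [MotifSet-class] or [SyllableString-class].
#' @param weighting `"standard"` or `"weighted"`.
#' @param includeEnd used for motif sets only (default TRUE).
#' @param legacyHmax,base passed to [motifEntropy()].
#' @return a [SequenceVariability-class].
#' @export
sequenceVariability <- function(x, weighting = c("standard", "weighted"),
                                includeEnd = TRUE, legacyHmax = FALSE,
                                base = 2) {
  weighting <- match.arg(weighting)
  if (is(x, "MotifSet")) {
    cnt <- countTransitions(x, includeEnd = includeEnd)
    mode <- "motif_based"
  } else if (is(x, "SyllableString")) {
    cnt <- countTransitions(x, includeEnd = FALSE)
    mode <- "string_based"
  } else stop("x must be a MotifSet or SyllableString")
  motifEntropy(transitionProbabilities(cnt), cnt, weighting = weighting,
               mode = mode, legacyHmax = legacyHmax, base = base)
}

#' Percent change between paired conditions
#'
#' `100 * (ud - ns) / ns`: the relative change of a measure from the
#' non-singing (NS-UD) to the singing (UD-UD) condition. Negative for
#' stereotypy when song is less stereotyped after undirected singing.
#'
#' @param ns value in the NS-UD (reference) condition; must be nonzero.
#' @param ud value in the UD-UD condition.
#' @return percent change (vectorized).
#' @export
percentChange <- function(ns, ud) {
  if (any(ns == 0)) stop("percent change undefined for a zero reference value")
  100 * (ud - ns) / ns
}
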