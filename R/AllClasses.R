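#' @import methods
NULL

.END <- "END"

#' MotifSet: labeled song motifs for one bird/condition
#'
#' Container for an ordered collection of motifs, each an ordered vector of
#' syllable labels, recorded for one bird under one behavioral condition
#' (typically `"NS-UD"` after two hours of non-singing or `"UD-UD"` after two
#' hours of undirected singing) at a given age.
#'
#' @slot birdId single character bird identifier.
#' @slot condition single character condition label.
#' @slot ageDays single character; days post-hatch (e.g. `"75"`) or `"adult"`.
#' @slot motifs list of character vectors of syllable labels; every motif is
#'   non-empty. Letter labels read from disk are mapped to integer labels
#'   (`A` -> `"1"`, `B` -> `"2"`, ...).
#'
#' @seealso [readMotifFile()], [countTransitions()], [sampleMotifs()]
#' @export
setClass("MotifSet",
  representation(
    birdId = "character",
    condition = "character",
    ageDays = "character",
    motifs = "list"
  ),
  prototype(birdId = NA_character_, condition = NA_character_,
            ageDays = NA_character_, motifs = list())
)

setValidity("MotifSet", function(object) {
  msg <- character()
  if (length(object@birdId) != 1L) msg <- c(msg, "birdId must be length 1")
  if (length(object@condition) != 1L) msg <- c(msg, "condition must be length 1")
  if (length(object@motifs) < 1L) msg <- c(msg, "at least one motif required")
  ok <- vapply(object@motifs, function(m) {
    is.character(m) && length(m) >= 1L && all(nzchar(m)) && !anyNA(m)
  }, logical(1))
  if (!all(ok)) msg <- c(msg, "every motif must be a non-empty character vector")
  if (any(unlist(object@motifs) == .END))
    msg <- c(msg, sprintf("syllable label '%s' is reserved", .END))
  if (length(msg)) msg else TRUE
})

#' SyllableString: one long labeled syllable sequence
#'
#' A single continuous sequence of syllable labels (no motif boundaries),
#' as used for string-based sequence analysis of the first ~300 syllables
#' sung after the behavioral manipulation.
#'
#' @slot birdId,condition,ageDays single character metadata, as in
#'   [MotifSet-class].
#' @slot symbols character vector of syllable labels, length >= 2.
#' @slot nominalLength integer target length (300 by convention); a
#'   mismatch between `length(symbols)` and `nominalLength` is allowed
#'   (readers warn about it) so that birds who sang fewer syllables can
#'   still be analyzed.
#'
#' @seealso [readSyllableString()], [sampleSyllableString()]
#' @export
setClass("SyllableString",
  representation(
    birdId = "character",
    condition = "character",
    ageDays = "character",
    symbols = "character",
    nominalLength = "integer"
  ),
  prototype(birdId = NA_character_, condition = NA_character_,
            ageDays = NA_character_, symbols = character(),
            nominalLength = 300L)
)

setValidity("SyllableString", function(object) {
  msg <- character()
  if (length(object@symbols) < 2L)
    msg <- c(msg, "a syllable string needs at least 2 symbols")
  if (anyNA(object@symbols) || !all(nzchar(object@symbols)))
    msg <- c(msg, "symbols must be non-empty and non-missing")
  if (any(object@symbols == .END))
    msg <- c(msg, sprintf("label '%s' is reserved; strings carry no motif boundaries", .END))
  if (length(object@nominalLength) != 1L || object@nominalLength < 2L)
    msg <- c(msg, "nominalLength must be a single integer >= 2")
  if (length(msg)) msg else TRUE
})

#' TransitionCounts: observed first-order transition tallies
#'
#' Raw counts of how often each leading syllable is followed by each outcome
#' (another syllable, or the end of a motif when `endIncluded`). Rows of
#' `counts` index leading syllables; columns index outcomes. `fTotal` is the
#' total outgoing count per leading syllable and `frequency` the number of
#' occurrences of each syllable as a leading syllable (i.e. with an outgoing
#' transition) -- the frequency used for entropy weighting.
#'
#' @slot alphabet character vector of syllable labels (never the END marker).
#' @slot endIncluded logical; TRUE when end-of-motif transitions were tallied.
#' @slot counts numeric matrix, rows = alphabet, columns = alphabet plus
#'   `"END"` when `endIncluded`.
#' @slot fTotal named numeric, row sums of `counts`.
#' @slot frequency named numeric, leading-occurrence counts (equals `fTotal`).
#'
#' @seealso [countTransitions()], [transitionProbabilities()]
#' @export
setClass("TransitionCounts",
  representation(
    alphabet = "character",
    endIncluded = "logical",
    counts = "matrix",
    fTotal = "numeric",
    frequency = "numeric"
  )
)

setValidity("TransitionCounts", function(object) {
  msg <- character()
  a <- object@alphabet
  want_cols <- if (object@endIncluded) c(a, .END) else a
  if (!identical(rownames(object@counts), a))
    msg <- c(msg, "count matrix rows must equal the alphabet")
  if (!identical(colnames(object@counts), want_cols))
    msg <- c(msg, "count matrix columns must equal the alphabet (plus END when included)")
  if (.END %in% a) msg <- c(msg, "END may not be a leading symbol")
  if (any(object@counts < 0)) msg <- c(msg, "counts must be nonnegative")
  if (!isTRUE(all.equal(unname(rowSums(object@counts)), unname(object@fTotal))))
    msg <- c(msg, "fTotal must equal the row sums of counts")
  if (any(object@frequency < 0)) msg <- c(msg, "frequency must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' TransitionModel: first-order transition probabilities
#'
#' Row-stochastic transition probability estimates, one row per leading
#' syllable with at least one observed outgoing transition. Each row sums to
#' one within 1e-9.
#'
#' @slot alphabet character syllable labels (outcome columns may add `"END"`).
#' @slot endIncluded logical.
#' @slot prob numeric matrix of transition probabilities.
#'
#' @seealso [transitionProbabilities()], [syllableEntropy()], [makeTransitionMatrix()]
#' @export
setClass("TransitionModel",
  representation(
    alphabet = "character",
    endIncluded = "logical",
    prob = "matrix"
  )
)

setValidity("TransitionModel", function(object) {
  msg <- character()
  p <- object@prob
  if (any(p < 0) || any(p > 1)) msg <- c(msg, "probabilities must lie in [0, 1]")
  if (nrow(p) < 1L) msg <- c(msg, "model must have at least one leading symbol")
  if (any(abs(rowSums(p) - 1) > 1e-9))
    msg <- c(msg, "each outgoing distribution must sum to 1 within 1e-9")
  if (.END %in% rownames(p)) msg <- c(msg, "END may not be a leading symbol")
  if (length(msg)) msg else TRUE
})

#' SequenceVariability: entropy and stereotypy summary of a song sample
#'
#' Result of motif-entropy scoring: per-syllable raw transition entropy `H`
#' (in bits by default), the maximum possible entropy `Hmax`, normalized
#' entropy `H/Hmax`, and frequency weights; plus the motif-level entropy
#' (mean of normalized, optionally weighted, syllable entropies), sequence
#' stereotypy `1 - entropy`, and the x100 scaled stereotypy used for
#' comparison with similarity/accuracy scores.
#'
#' @slot perSyllable data.frame with columns `symbol`, `frequency`, `weight`,
#'   `entropy`, `maxEntropy`, `normEntropy`.
#' @slot motifEntropy numeric in \[0, 1\].
#' @slot stereotypy numeric, exactly `1 - motifEntropy`.
#' @slot stereotypyScaled numeric, `100 * stereotypy`.
#' @slot nUnique integer repertoire size (END excluded).
#' @slot mode `"motif_based"` or `"string_based"`.
#' @slot weighting `"standard"` or `"weighted"`.
#'
#' @seealso [motifEntropy()], [sequenceVariability()]
#' @export
setClass("SequenceVariability",
  representation(
    perSyllable = "data.frame",
    motifEntropy = "numeric",
    stereotypy = "numeric",
    stereotypyScaled = "numeric",
    nUnique = "integer",
    mode = "character",
    weighting = "character"
  )
)

setValidity("SequenceVariability", function(object) {
  msg <- character()
  if (object@motifEntropy < 0 || object@motifEntropy > 1)
    msg <- c(msg, "motif entropy must lie in [0, 1]")
  if (!identical(object@stereotypy, 1 - object@motifEntropy))
    msg <- c(msg, "stereotypy must equal 1 - motifEntropy exactly")
  ne <- object@perSyllable$normEntropy
  if (length(ne) && (any(ne < 0) || any(ne > 1)))
    msg <- c(msg, "normalized syllable entropies must lie in [0, 1]")
  if (!object@mode %in% c("motif_based", "string_based"))
    msg <- c(msg, "mode must be 'motif_based' or 'string_based'")
  if (!object@weighting %in% c("standard", "weighted"))
    msg <- c(msg, "weighting must be 'standard' or 'weighted'")
  if (length(msg)) msg else TRUE
})

#' BootstrapTest: result of a resampling test
#'
#' Holds the observed statistic, a summary of the resampled null
#' distribution, the two-tailed (or upper-tail, for the ANOVA) p-value, and
#' the bookkeeping needed to reproduce the run.
#'
#' @slot statistic observed test statistic (mean paired difference `M`, or
#'   the absolute-deviation ratio for the one-way ANOVA).
#' @slot nullMean mean of the null distribution.
#' @slot nullStats the resampled null statistics.
#' @slot pValue p-value in \[0, 1\], inclusive counting at the critical values.
#' @slot nIter number of resampling iterations.
#' @slot seed integer seed used (NA when the caller managed the RNG).
#' @slot alpha significance threshold recorded with the test.
#' @slot method short description of the procedure.
#'
#' @seealso [pairedSignflipBootstrap()], [bootstrapOnewayAnova()]
#' @export
setClass("BootstrapTest",
  representation(
    statistic = "numeric",
    nullMean = "numeric",
    nullStats = "numeric",
    pValue = "numeric",
    nIter = "integer",
    seed = "integer",
    alpha = "numeric",
    method = "character"
  )
)

setValidity("BootstrapTest", function(object) {
  msg <- character()
  if (is.na(object@pValue) || object@pValue < 0 || object@pValue > 1)
    msg <- c(msg, "p-value must lie in [0, 1]")
  if (object@nIter < 1L) msg <- c(msg, "nIter must be >= 1")
  if (length(msg)) msg else TRUE
})

#' ScoreMatrix: all-vs-all similarity/accuracy score batch
#'
#' Square matrix of pairwise similarity scores (0-100 scale) among `m` song
#' items (motifs, one-second clips, or syllable renditions), with an optional
#' parallel accuracy matrix. The diagonal holds self-comparisons, which all
#' summaries exclude.
#'
#' @slot unit `"motif"`, `"clip"`, or `"syllable"`.
#' @slot mode `"asymmetric"` (time-course window search) or `"symmetric"`
#'   (frame-by-frame).
#' @slot similarity m x m numeric matrix in \[0, 100\].
#' @slot accuracy m x m numeric matrix in \[0, 100\], or a 0 x 0 matrix when
#'   only similarity was scored.
#'
#' @seealso [aggregateScores()], [scoreBatch()]
#' @export
setClass("ScoreMatrix",
  representation(
    unit = "character",
    mode = "character",
    similarity = "matrix",
    accuracy = "matrix"
  ),
  prototype(unit = "motif", mode = "asymmetric",
            accuracy = matrix(numeric(), 0, 0))
)

setValidity("ScoreMatrix", function(object) {
  msg <- character()
  s <- object@similarity
  if (nrow(s) != ncol(s)) msg <- c(msg, "similarity matrix must be square")
  if (length(s) && (any(s < 0) || any(s > 100)))
    msg <- c(msg, "scores must lie in [0, 100]")
  a <- object@accuracy
  if (length(a)) {
    if (!all(dim(a) == dim(s))) msg <- c(msg, "accuracy must match similarity dims")
    if (any(a < 0) || any(a > 100)) msg <- c(msg, "scores must lie in [0, 100]")
  }
  if (!object@unit %in% c("motif", "clip", "syllable"))
    msg <- c(msg, "unit must be motif, clip, or syllable")
  if (!object@mode %in% c("asymmetric", "symmetric"))
    msg <- c(msg, "mode must be asymmetric or symmetric")
  if (length(msg)) msg else TRUE
})

#' FeatureTrajectory: frame-wise acoustic feature time series
#'
#' Time series of the four spectral features used for trajectory similarity
#' scoring (pitch, frequency modulation, Wiener entropy, pitch goodness),
#' sampled on a fixed frame grid.
#'
#' @slot framePeriodMs frame period in milliseconds (9 ms by default, the
#'   local-comparison granularity).
#' @slot values numeric matrix, one row per frame, columns `pitch`, `fm`,
#'   `wiener_entropy`, `pitch_goodness`.
#'
#' @seealso [featureTrajectory()], [trajectorySimilarity()]
#' @export
setClass("FeatureTrajectory",
  representation(framePeriodMs = "numeric", values = "matrix")
)

setValidity("FeatureTrajectory", function(object) {
  msg <- character()
  if (nrow(object@values) < 1L) msg <- c(msg, "trajectory must have >= 1 frame")
  if (!identical(colnames(object@values),
                 c("pitch", "fm", "wiener_entropy", "pitch_goodness")))
    msg <- c(msg, "columns must be pitch, fm, wiener_entropy, pitch_goodness")
  if (length(object@framePeriodMs) != 1L || object@framePeriodMs <= 0)
    msg <- c(msg, "framePeriodMs must be a single positive number")
  if (length(msg)) msg else TRUE
})
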