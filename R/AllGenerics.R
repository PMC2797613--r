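#' Accessors for songvar classes
#'
#' Small accessor generics: `motifs()` returns the list of motifs of a
#' [MotifSet-class]; `symbols()` the label vector of a
#' [SyllableString-class]; `alphabet()` the syllable repertoire of a counts
#' or model object; `probMatrix()` the row-stochastic transition matrix;
#' `countsMatrix()` the raw tally matrix; `leadingFrequency()` the
#' per-syllable leading-occurrence counts; `stereotypy()` /
#' `motifEntropyScore()` the scalar summaries of a
#' [SequenceVariability-class]; `pValue()` and `testStatistic()` the results
#' of a [BootstrapTest-class].
#'
#' @param x an object of the documented class.
#' @return The slot value described above.
#' @name accessors
#' @aliases motifs symbols alphabet probMatrix countsMatrix leadingFrequency
#'   stereotypy motifEntropyScore pValue testStatistic
NULL

#' @rdname accessors
#' @export
setGeneric("motifs", function(x) standardGeneric("motifs"))
#' @rdname accessors
#' @export
setGeneric("symbols", function(x) standardGeneric("symbols"))
#' @rdname accessors
#' @export
setGeneric("alphabet", function(x) standardGeneric("alphabet"))
#' @rdname accessors
#' @export
setGeneric("probMatrix", function(x) standardGeneric("probMatrix"))
#' @rdname accessors
#' @export
setGeneric("countsMatrix", function(x) standardGeneric("countsMatrix"))
#' @rdname accessors
#' @export
setGeneric("leadingFrequency", function(x) standardGeneric("leadingFrequency"))
#' @rdname accessors
#' @export
setGeneric("stereotypy", function(x) standardGeneric("stereotypy"))
#' @rdname accessors
#' @export
setGeneric("motifEntropyScore", function(x) standardGeneric("motifEntropyScore"))
#' @rdname accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))
#' @rdname accessors
#' @export
setGeneric("testStatistic", function(x) standardGeneric("testStatistic"))

#' Tally first-order syllable transitions
#'
#' @param x a [MotifSet-class] or [SyllableString-class].
#' @param includeEnd logical; tally a transition from the last syllable of
#'   each motif to the end-of-motif outcome. Defaults to `TRUE` for motif
#'   sets. Strings carry no motif boundaries, so requesting `includeEnd`
#'   for a [SyllableString-class] is an error.
#' @return a [TransitionCounts-class].
#' @seealso [transitionProbabilities()], [sequenceVariability()]
#' @export
setGeneric("countTransitions",
           function(x, includeEnd = TRUE) standardGeneric("countTransitions"))

#' @rdname accessors
setMethod("motifs", "MotifSet", function(x) x@motifs)
#' @rdname accessors
setMethod("symbols", "SyllableString", function(x) x@symbols)
#' @rdname accessors
setMethod("alphabet", "TransitionCounts", function(x) x@alphabet)
#' @rdname accessors
setMethod("alphabet", "TransitionModel", function(x) x@alphabet)
#' @rdname accessors
setMethod("alphabet", "MotifSet",
          function(x) sort(unique(unlist(x@motifs))))
#' @rdname accessors
setMethod("alphabet", "SyllableString", function(x) sort(unique(x@symbols)))
#' @rdname accessors
setMethod("probMatrix", "TransitionModel", function(x) x@prob)
#' @rdname accessors
setMethod("countsMatrix", "TransitionCounts", function(x) x@counts)
#' @rdname accessors
setMethod("leadingFrequency", "TransitionCounts", function(x) x@frequency)
#' @rdname accessors
setMethod("stereotypy", "SequenceVariability", function(x) x@stereotypy)
#' @rdname accessors
setMethod("motifEntropyScore", "SequenceVariability", function(x) x@motifEntropy)
#' @rdname accessors
setMethod("pValue", "BootstrapTest", function(x) x@pValue)
#' @rdname accessors
setMethod("testStatistic", "BootstrapTest", function(x) x@statistic)

setMethod("show", "MotifSet", function(object) {
  cat(sprintf("MotifSet: bird %s, condition %s, age %s\n",
              object@birdId, object@condition, object@ageDays))
  cat(sprintf("  %d motifs, repertoire of %d syllables\n",
              length(object@motifs), length(alphabet(object))))
  preview <- vapply(utils::head(object@motifs, 3), paste, "", collapse = " ")
  cat(sprintf("  %s%s\n", paste(preview, collapse = " | "),
              if (length(object@motifs) > 3) " | ..." else ""))
})

setMethod("show", "SyllableString", function(object) {
  cat(sprintf("SyllableString: bird %s, condition %s, age %s\n",
              object@birdId, object@condition, object@ageDays))
  cat(sprintf("  %d symbols (nominal %d), repertoire of %d\n",
              length(object@symbols), object@nominalLength,
              length(alphabet(object))))
})

setMethod("show", "TransitionCounts", function(object) {
  cat(sprintf("TransitionCounts: %d leading syllables, END %s\n",
              length(object@alphabet),
              if (object@endIncluded) "included" else "excluded"))
  print(object@counts)
})

setMethod("show", "TransitionModel", function(object) {
  cat(sprintf("TransitionModel: %d leading syllables, END %s\n",
              nrow(object@prob),
              if (object@endIncluded) "included" else "excluded"))
  print(round(object@prob, 3))
})

setMethod("show", "SequenceVariability", function(object) {
  cat(sprintf("SequenceVariability (%s, %s weighting)\n",
              object@mode, object@weighting))
  cat(sprintf("  motif entropy %.4f | stereotypy %.4f (scaled %.2f)\n",
              object@motifEntropy, object@stereotypy, object@stereotypyScaled))
  cat(sprintf("  %d unique syllables\n", object@nUnique))
})

setMethod("show", "BootstrapTest", function(object) {
  cat(sprintf("BootstrapTest: %s\n", object@method))
  cat(sprintf("  statistic = %.6g, null mean = %.3g, p = %.4g (%d iterations)\n",
              object@statistic, object@nullMean, object@pValue, object@nIter))
  if (!is.na(object@seed)) cat(sprintf("  seed = %d\n", object@seed))
})

setMethod("show", "ScoreMatrix", function(object) {
  m <- nrow(object@similarity)
  cat(sprintf("ScoreMatrix: %d %ss, %s mode, %d off-diagonal scores\n",
              m, object@unit, object@mode, m * m - m))
})

setMethod("show", "FeatureTrajectory", function(object) {
  cat(sprintf("FeatureTrajectory: %d frames at %.1f ms\n",
              nrow(object@values), object@framePeriodMs))
})
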