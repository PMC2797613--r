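#' Construct a MotifSet
#'
#' @param motifs list of character (or coercible) vectors of syllable labels.
#' @param birdId,condition,ageDays metadata strings.
#' @return a [MotifSet-class].
#' @examples
#' motifSet(list(c("1", "2", "3"), c("1", "2")), birdId = "b01")
#' @export
motifSet <- function(motifs, birdId = NA_character_, condition = NA_character_,
                     ageDays = NA_character_) {
  motifs <- lapply(motifs, function(m) as.character(m))
  new("MotifSet", birdId = as.character(birdId),
      condition = as.character(condition), ageDays = as.character(ageDays),
      motifs = motifs)
}

#' Construct a SyllableString
#'
#' @param symbols character (or coercible) vector of syllable labels.
#' @param birdId,condition,ageDays metadata strings.
#' @param nominalLength target length of the sample (default 300).
#' @return a [SyllableString-class].
#' @export
syllableString <- function(symbols, birdId = NA_character_,
                           condition = NA_character_, ageDays = NA_character_,
                           nominalLength = 300L) {
  new("SyllableString", birdId = as.character(birdId),
      condition = as.character(condition), ageDays = as.character(ageDays),
      symbols = as.character(symbols),
      nominalLength = as.integer(nominalLength))
}

# Map one label token set to canonical integer labels. Letter motifs follow
# the A = 1, B = 2, ... convention; integer tokens pass through.
.parse_label_line <- function(line) {
  line <- trimws(line)
  if (grepl("\\s", line)) {
    tokens <- strsplit(line, "\\s+")[[1]]
  } else {
    tokens <- strsplit(line, "")[[1]]
    if (all(grepl("^[0-9]$", tokens)) && length(tokens) > 1L) {
      # contiguous single digits, e.g. "1123": one label per digit
    } else if (all(grepl("^[A-Za-z]$", tokens))) {
      # contiguous letters handled below
    } else {
      tokens <- line  # a single multi-character token
    }
  }
  if (all(grepl("^[A-Za-z]$", tokens))) {
    list(labels = as.character(match(toupper(tokens), LETTERS)),
         alphabet = "letter")
  } else if (all(grepl("^[0-9]+$", tokens))) {
    list(labels = as.character(as.integer(tokens)), alphabet = "integer")
  } else {
    stop("cannot parse motif line '", line,
         "': use contiguous letters or whitespace-separated integers")
  }
}

#' Read a plain-text motif file
#'
#' One motif per line; within a line, labels are either contiguous letters
#' (`"AAB"`, mapped via A = 1, B = 2, ...) or whitespace-separated integers
#' (`"1 1 2"`), allowing repertoires beyond 26 syllables. Blank lines are
#' ignored. Mixing the two label alphabets within one file is an error.
#'
#' @param path path to the text file.
#' @param birdId,condition,ageDays metadata attached to the result.
#' @return a [MotifSet-class] with one motif per non-blank line, in file
#'   order.
#' @examples
#' tf <- tempfile()
#' writeLines(c("AAB", "AB"), tf)
#' motifs(readMotifFile(tf))
#' @export
readMotifFile <- function(path, birdId = NA_character_,
                          condition = NA_character_, ageDays = NA_character_) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no motifs in '", path, "'")
  parsed <- lapply(lines, .parse_label_line)
  alph <- unique(vapply(parsed, `[[`, "", "alphabet"))
  if (length(alph) > 1L)
    stop("mixed label alphabets (letters and integers) in '", path, "'")
  motifSet(lapply(parsed, `[[`, "labels"), birdId = birdId,
           condition = condition, ageDays = ageDays)
}

#' Write a MotifSet to a plain-text motif file
#'
#' Inverse of [readMotifFile()]; labels are written as whitespace-separated
#' integers, one motif per line, so the round trip is lossless.
#'
#' @param x a [MotifSet-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeMotifFile <- function(x, path) {
  stopifnot(is(x, "MotifSet"))
  writeLines(vapply(x@motifs, paste, "", collapse = " "), path)
  invisible(path)
}

#' Read a syllable-string file
#'
#' Reads a single long sequence of syllable labels (whitespace- or
#' newline-separated integers, or a contiguous letter string) with no motif
#' boundary markers, as used for string-based sequence analysis.
#'
#' @inheritParams readMotifFile
#' @param nominalLength expected number of syllables (default 300); a
#'   different observed length triggers a warning, not an error.
#' @return a [SyllableString-class].
#' @export
readSyllableString <- function(path, birdId = NA_character_,
                               condition = NA_character_,
                               ageDays = NA_character_, nominalLength = 300L) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  text <- paste(trimws(lines[nzchar(trimws(lines))]), collapse = " ")
  if (!nzchar(text)) stop("no symbols in '", path, "'")
  labels <- .parse_label_line(text)$labels
  if (length(labels) < 2L) stop("a syllable string needs at least 2 symbols")
  if (length(labels) != nominalLength)
    warning(sprintf("'%s' has %d symbols (expected %d)", path,
                    length(labels), nominalLength))
  syllableString(labels, birdId = birdId, condition = condition,
                 ageDays = ageDays, nominalLength = nominalLength)
}

#' Write a SyllableString to disk
#'
#' @param x a [SyllableString-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSyllableString <- function(x, path) {
  stopifnot(is(x, "SyllableString"))
  writeLines(paste(x@symbols, collapse = " "), path)
  invisible(path)
}

.FEATURES <- c("duration", "amplitude", "pitch", "fm", "wiener_entropy",
               "mean_frequency", "pitch_goodness")
.FEATURE_KEYS <- c("bird", "syllable", "condition", "rendition")

#' Read a per-rendition acoustic feature table
#'
#' Comma-separated, header row required. Required columns: `bird`,
#' `syllable`, `condition`, `rendition`, plus the seven acoustic features
#' `duration` (s), `amplitude` (dB), `pitch` (Hz), `fm`, `wiener_entropy`,
#' `mean_frequency` (Hz), `pitch_goodness`. Extra columns are preserved
#' untouched.
#'
#' @param path path to the CSV file.
#' @return a data.frame of typed renditions (one row per rendition of one
#'   syllable in one condition).
#' @export
readFeatureTable <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c(.FEATURE_KEYS, .FEATURES), names(df))
  if (length(missing))
    stop("feature table '", path, "' is missing required column(s): ",
         paste(missing, collapse = ", "))
  if (nrow(df) == 0L) stop("feature table '", path, "' has no rows")
  validateFeatureTable(df)
  df
}

#' Validate a feature-rendition table
#'
#' Checks the invariants of the per-rendition format: required columns
#' present, positive durations, and unique rendition indices within each
#' (bird, syllable, condition) cell.
#'
#' @param df a data.frame in the [readFeatureTable()] layout.
#' @return `df`, invisibly, if valid; otherwise an error is thrown.
#' @export
validateFeatureTable <- function(df) {
  missing <- setdiff(c(.FEATURE_KEYS, .FEATURES), names(df))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  if (any(df$duration <= 0)) stop("durations must be positive")
  key <- interaction(df$bird, df$syllable, df$condition, drop = TRUE)
  dup <- vapply(split(df$rendition, key), anyDuplicated, 0L)
  if (any(dup > 0))
    stop("rendition indices must be unique within (bird, syllable, condition)")
  invisible(df)
}

#' Write a feature-rendition table
#'
#' @param df a data.frame in the [readFeatureTable()] layout.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeFeatureTable <- function(df, path) {
  validateFeatureTable(df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Construct a ScoreMatrix
#'
#' @param similarity m x m numeric matrix of similarity scores in \[0, 100\].
#' @param accuracy optional matching matrix of accuracy scores.
#' @param unit `"motif"`, `"clip"`, or `"syllable"`.
#' @param mode `"asymmetric"` or `"symmetric"`.
#' @return a [ScoreMatrix-class].
#' @export
scoreBatch <- function(similarity, accuracy = NULL, unit = "motif",
                       mode = "asymmetric") {
  similarity <- as.matrix(similarity)
  if (is.null(accuracy)) accuracy <- matrix(numeric(), 0, 0)
  new("ScoreMatrix", unit = unit, mode = mode,
      similarity = similarity, accuracy = as.matrix(accuracy))
}

#' Read / write score batches as long-format CSV
#'
#' The on-disk layout is long format with columns `item_i`, `item_j`,
#' `similarity` and (optionally) `accuracy`, covering all ordered pairs
#' including the self-comparisons on the diagonal.
#'
#' @param path CSV path.
#' @param unit,mode stored in the resulting object (see [ScoreMatrix-class]).
#' @return `readScoreMatrix()` returns a [ScoreMatrix-class];
#'   `writeScoreMatrix()` returns `path` invisibly.
#' @export
readScoreMatrix <- function(path, unit = "motif", mode = "asymmetric") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("item_i", "item_j", "similarity")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("score file '", path, "' is missing column(s): ",
         paste(missing, collapse = ", "))
  m <- max(df$item_i, df$item_j)
  sim <- matrix(NA_real_, m, m)
  sim[cbind(df$item_i, df$item_j)] <- df$similarity
  if (anyNA(sim)) stop("score file '", path, "' does not cover all m x m pairs")
  acc <- NULL
  if ("accuracy" %in% names(df)) {
    acc <- matrix(NA_real_, m, m)
    acc[cbind(df$item_i, df$item_j)] <- df$accuracy
  }
  scoreBatch(sim, acc, unit = unit, mode = mode)
}

#' @rdname readScoreMatrix
#' @param x a [ScoreMatrix-class].
#' @export
writeScoreMatrix <- function(x, path) {
  stopifnot(is(x, "ScoreMatrix"))
  m <- nrow(x@similarity)
  idx <- expand.grid(item_i = seq_len(m), item_j = seq_len(m))
  df <- data.frame(idx, similarity = x@similarity[as.matrix(idx)])
  if (length(x@accuracy)) df$accuracy <- x@accuracy[as.matrix(idx)]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
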