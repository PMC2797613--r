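#' Assemble and validate a pipeline run configuration
#'
#' @param includeEndTransitions tally end-of-motif transitions in
#'   motif-based sequence analysis (default TRUE).
#' @param entropyLogBase logarithm base for raw entropies (default 2;
#'   normalized scores are base-invariant).
#' @param nBootstrap resampling iterations for every test (default 10000).
#' @param alpha significance level in (0, 1) (default 0.05).
#' @param seed integer master seed; every stochastic stage derives its seed
#'   from it.
#' @param weighting `"standard"` or `"weighted"` syllable-entropy
#'   averaging.
#' @param legacyHmax drop the END outcome from the normalization ceiling
#'   (sensitivity analysis; default FALSE).
#' @return a validated named list of class `songvarConfig`.
#' @export
runConfig <- function(includeEndTransitions = TRUE, entropyLogBase = 2,
                      nBootstrap = 10000L, alpha = 0.05, seed = 1L,
                      weighting = c("standard", "weighted"),
                      legacyHmax = FALSE) {
  weighting <- match.arg(weighting)
  stopifnot(nBootstrap >= 1L, alpha > 0, alpha < 1, entropyLogBase > 1,
            is.finite(seed))
  structure(list(includeEndTransitions = isTRUE(includeEndTransitions),
                 entropyLogBase = entropyLogBase,
                 nBootstrap = as.integer(nBootstrap), alpha = alpha,
                 seed = as.integer(seed), weighting = weighting,
                 legacyHmax = isTRUE(legacyHmax)),
            class = "songvarConfig")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Keys mirror the arguments of [runConfig()] (snake_case accepted);
#' missing keys take the defaults.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a `songvarConfig` list.
#' @export
readRunConfig <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required to read YAML configs")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  canon <- function(x) gsub("_(\\w)", "\\U\\1", x, perl = TRUE)
  names(raw) <- canon(names(raw))
  known <- names(formals(runConfig))
  do.call(runConfig, raw[intersect(names(raw), known)])
}

#' Discover the inputs of a dataset directory
#'
#' Scans a directory laid out as written by [makePairedDataset()] --
#' `<bird>_<condition>_motifs.txt`, `<bird>_<condition>_string.txt`,
#' `<bird>_<condition>_features.csv` -- and returns one row per
#' (bird, condition) with the file paths found (NA when absent).
#'
#' @param dir dataset directory.
#' @return a data.frame with columns `bird`, `condition`, `motif_file`,
#'   `string_file`, `feature_file`.
#' @export
collectInputs <- function(dir) {
  stopifnot(dir.exists(dir))
  files <- list.files(dir, pattern = "_(motifs|string)\\.txt$|_features\\.csv$")
  if (!length(files)) stop("no recognizable input files in '", dir, "'")
  meta <- regmatches(files, regexec("^(.+)_([^_]+)_(motifs|string|features)\\.", files))
  df <- do.call(rbind, lapply(seq_along(meta), function(i) {
    m <- meta[[i]]
    if (length(m) != 4L) return(NULL)
    data.frame(bird = m[2], condition = m[3], kind = m[4],
               path = file.path(dir, files[i]))
  }))
  cells <- unique(df[c("bird", "condition")])
  pick <- function(b, cond, kind) {
    hit <- df$path[df$bird == b & df$condition == cond & df$kind == kind]
    if (length(hit)) hit[1] else NA_character_
  }
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    b <- cells$bird[i]; cond <- cells$condition[i]
    data.frame(bird = b, condition = cond,
               motif_file = pick(b, cond, "motifs"),
               string_file = pick(b, cond, "string"),
               feature_file = pick(b, cond, "features"))
  }))
  out[order(out$bird, out$condition), , drop = FALSE]
}

.config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(unclass(config), tf, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tf))
}

.sv_row <- function(sv, bird, condition, age) {
  data.frame(bird = bird, condition = condition, age = age, mode = sv@mode,
             weighting = sv@weighting, motif_entropy = sv@motifEntropy,
             stereotypy = sv@stereotypy,
             stereotypy_scaled = sv@stereotypyScaled)
}

#' Run the full song-variability pipeline
#'
#' End-to-end analysis of a paired two-condition dataset: per-bird sequence
#' variability (motif-based and/or string-based, per the files available),
#' per-bird percent change from the NS-UD to the UD-UD condition,
#' sign-flip paired bootstrap tests (with Wilcoxon signed-rank
#' cross-checks) on the conditional differences of motif entropy and
#' stereotypy, acoustic-feature summaries with per-syllable CV aggregation
#' and per-feature CV tests. All tables are written as CSV to `outDir`
#' together with a log recording the config hash, master seed and
#' per-stage record counts; the whole run is a pure function of
#' (inputs, config).
#'
#' @param inputs a data.frame as from [collectInputs()], or a dataset
#'   directory path.
#' @param config a `songvarConfig` from [runConfig()].
#' @param outDir output directory (created if needed).
#' @return invisibly, a list of the result tables: `sequenceScores`,
#'   `perSyllableEntropy`, `percentChanges`, `sequenceTests`,
#'   `featureSummary`, `cvGroupMeans`, `featureTests`.
#' @export
runPipeline <- function(inputs, config = runConfig(), outDir) {
  if (is.character(inputs) && length(inputs) == 1L)
    inputs <- collectInputs(inputs)
  stopifnot(is.data.frame(inputs), all(c("bird", "condition") %in% names(inputs)),
            inherits(config, "songvarConfig"))
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  log <- c(sprintf("songvar pipeline run"),
           sprintf("config_hash: %s", .config_hash(config)),
           sprintf("seed: %d", config$seed),
           sprintf("input_cells: %d", nrow(inputs)))

  seqScores <- list(); perSyl <- list(); featSum <- list()
  for (i in seq_len(nrow(inputs))) {
    b <- inputs$bird[i]; cond <- inputs$condition[i]
    ctx <- sprintf("bird %s, condition %s", b, cond)
    if (!is.na(inputs$motif_file[i])) {
      ms <- tryCatch(readMotifFile(inputs$motif_file[i], birdId = b,
                                   condition = cond),
                     error = function(e) stop("reading '", inputs$motif_file[i],
                                              "' (", ctx, "): ",
                                              conditionMessage(e)))
      sv <- sequenceVariability(ms, weighting = config$weighting,
                                includeEnd = config$includeEndTransitions,
                                legacyHmax = config$legacyHmax,
                                base = config$entropyLogBase)
      seqScores[[length(seqScores) + 1L]] <- .sv_row(sv, b, cond, ms@ageDays)
      perSyl[[length(perSyl) + 1L]] <-
        data.frame(bird = b, condition = cond, mode = sv@mode, sv@perSyllable)
    }
    if (!is.na(inputs$string_file[i])) {
      ss <- tryCatch(suppressWarnings(
        readSyllableString(inputs$string_file[i], birdId = b, condition = cond)),
        error = function(e) stop("reading '", inputs$string_file[i], "' (", ctx,
                                 "): ", conditionMessage(e)))
      sv <- sequenceVariability(ss, weighting = config$weighting,
                                base = config$entropyLogBase)
      seqScores[[length(seqScores) + 1L]] <- .sv_row(sv, b, cond, ss@ageDays)
      perSyl[[length(perSyl) + 1L]] <-
        data.frame(bird = b, condition = cond, mode = sv@mode, sv@perSyllable)
    }
    if (!is.na(inputs$feature_file[i])) {
      tab <- tryCatch(readFeatureTable(inputs$feature_file[i]),
                      error = function(e) stop("reading '",
                                               inputs$feature_file[i], "' (",
                                               ctx, "): ", conditionMessage(e)))
      featSum[[length(featSum) + 1L]] <- featureSummary(tab)
    }
  }
  seqScores <- do.call(rbind, seqScores)
  perSyl <- do.call(rbind, perSyl)
  log <- c(log, sprintf("sequence_score_rows: %d",
                        if (is.null(seqScores)) 0L else nrow(seqScores)))

  # per-bird percent change and paired tests, per mode and measure
  pct <- list(); tests <- list(); testSeed <- config$seed
  if (!is.null(seqScores)) {
    for (mode in unique(seqScores$mode)) {
      sub <- seqScores[seqScores$mode == mode, ]
      wide <- merge(sub[sub$condition == "NS-UD", ],
                    sub[sub$condition == "UD-UD", ],
                    by = c("bird", "mode"), suffixes = c("_ns", "_ud"))
      if (!nrow(wide)) next
      for (measure in c("motif_entropy", "stereotypy")) {
        ns <- wide[[paste0(measure, "_ns")]]
        ud <- wide[[paste0(measure, "_ud")]]
        ok <- ns != 0
        pct[[length(pct) + 1L]] <- data.frame(
          bird = wide$bird[ok], mode = mode, measure = measure,
          ns_value = ns[ok], ud_value = ud[ok],
          percent_change = percentChange(ns[ok], ud[ok]))
        if (nrow(wide) >= 2L) {
          testSeed <- testSeed + 1L
          d <- ud - ns
          bt <- suppressWarnings(
            pairedSignflipBootstrap(d, nIter = config$nBootstrap,
                                    seed = testSeed, alpha = config$alpha))
          tests[[length(tests) + 1L]] <- data.frame(
            mode = mode, measure = measure, n_birds = nrow(wide),
            M = bt@statistic, p_value = bt@pValue,
            p_wilcoxon = suppressWarnings(wilcoxonCrosscheck(d)),
            n_iter = bt@nIter, seed = testSeed)
        }
      }
    }
  }
  pct <- do.call(rbind, pct); tests <- do.call(rbind, tests)

  featSum <- do.call(rbind, featSum)
  cvMeans <- NULL; featTests <- NULL
  if (!is.null(featSum)) {
    cvMeans <- aggregateCV(featSum, level = "per_syllable")
    ft <- list()
    wide <- merge(featSum[featSum$condition == "NS-UD", ],
                  featSum[featSum$condition == "UD-UD", ],
                  by = c("bird", "syllable", "feature"),
                  suffixes = c("_ns", "_ud"))
    for (f in unique(wide$feature)) {
      sub <- wide[wide$feature == f, ]
      d <- sub$cv_ud - sub$cv_ns
      d <- d[!is.na(d)]
      if (length(d) >= 2L) {
        testSeed <- testSeed + 1L
        bt <- suppressWarnings(
          pairedSignflipBootstrap(d, nIter = config$nBootstrap,
                                  seed = testSeed, alpha = config$alpha))
        ft[[length(ft) + 1L]] <- data.frame(
          feature = f, n_syllables = length(d), M = bt@statistic,
          p_value = bt@pValue, n_iter = bt@nIter, seed = testSeed)
      }
    }
    featTests <- do.call(rbind, ft)
  }
  log <- c(log,
           sprintf("feature_summary_rows: %d",
                   if (is.null(featSum)) 0L else nrow(featSum)),
           sprintf("sequence_tests: %d", if (is.null(tests)) 0L else nrow(tests)),
           sprintf("feature_tests: %d",
                   if (is.null(featTests)) 0L else nrow(featTests)))

  res <- list(sequenceScores = seqScores, perSyllableEntropy = perSyl,
              percentChanges = pct, sequenceTests = tests,
              featureSummary = featSum, cvGroupMeans = cvMeans,
              featureTests = featTests)
  outNames <- c(sequenceScores = "sequence_scores.csv",
                perSyllableEntropy = "per_syllable_entropy.csv",
                percentChanges = "percent_changes.csv",
                sequenceTests = "sequence_tests.csv",
                featureSummary = "feature_summary.csv",
                cvGroupMeans = "cv_group_means.csv",
                featureTests = "feature_tests.csv")
  for (nm in names(outNames)) {
    if (!is.null(res[[nm]]))
      utils::write.csv(res[[nm]], file.path(outDir, outNames[[nm]]),
                       row.names = FALSE)
  }
  writeLines(log, file.path(outDir, "songvar_run.log"))
  invisible(res)
}
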