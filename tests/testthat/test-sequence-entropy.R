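test_that("transition tallies match hand counts in both modes", {
  ms <- motifSet(list(c("A", "B", "A", "B")))
  cnt <- countTransitions(ms, includeEnd = TRUE)
  cm <- countsMatrix(cnt)
  expect_equal(cm["A", "B"], 2)
  expect_equal(cm["B", "A"], 1)
  expect_equal(cm["B", "END"], 1)
  expect_equal(sum(cm), 4)  # every position has an outgoing transition
  expect_equal(unname(leadingFrequency(cnt)), c(2, 2))

  ss <- syllableString(c("A", "B", "A", "B"))
  cs <- countsMatrix(countTransitions(ss))
  expect_equal(cs["A", "B"], 2)
  expect_equal(cs["B", "A"], 1)
  expect_equal(sum(cs), 3)  # the final symbol contributes no transition
  expect_error(countTransitions(ss, includeEnd = TRUE), "undefined")
})

test_that("tallies over a long sampled string match an independent recount", {
  model <- makeTransitionMatrix(4, 0.6)
  ss <- sampleSyllableString(model, length = 10000, seed = 21)
  cnt <- countsMatrix(countTransitions(ss))
  ref <- oracle_tally(symbols(ss))
  for (key in names(ref)) {
    ft <- strsplit(key, "->", fixed = TRUE)[[1]]
    expect_equal(cnt[ft[1], ft[2]], unname(ref[key]))
  }
  expect_equal(sum(cnt), sum(ref))
})

test_that("transition probabilities are count ratios with stochastic rows", {
  # a leading syllable followed equally often by each of 5 outcomes
  ms <- motifSet(lapply(c("B", "C", "D", "E", "A"), function(o) c("A", o)))
  cnt <- countTransitions(ms, includeEnd = FALSE)
  p <- probMatrix(suppressWarnings(transitionProbabilities(cnt)))
  expect_equal(unname(p["A", c("A", "B", "C", "D", "E")]), rep(0.2, 5))

  ms2 <- motifSet(list(c("A", "B"), c("A", "B")))
  p2 <- probMatrix(suppressWarnings(
    transitionProbabilities(countTransitions(ms2, includeEnd = FALSE))))
  expect_equal(p2["A", "B"], 1)

  model <- makeTransitionMatrix(8, 0.5)
  ss <- sampleSyllableString(model, length = 2000, seed = 8)
  cnt3 <- countTransitions(ss)
  p3 <- probMatrix(transitionProbabilities(cnt3))
  cm <- countsMatrix(cnt3)
  for (s in rownames(p3))
    expect_equal(p3[s, ], cm[s, ] / sum(cm[s, ]), tolerance = 1e-12)
  expect_true(all(abs(rowSums(p3) - 1) < 1e-9))
})

test_that("string-mode symbols without outgoing transitions are dropped with a warning", {
  ss <- syllableString(c("1", "2", "1", "3"))  # 3 occurs only at the end
  cnt <- countTransitions(ss)
  expect_warning(model <- transitionProbabilities(cnt), "3")
  expect_false("3" %in% rownames(probMatrix(model)))
  expect_true("3" %in% alphabet(model))
})

test_that("syllable entropy follows the Shannon formula with 0 log 0 = 0", {
  ms <- motifSet(list(c("A", "B"), c("A", "B")))
  model <- suppressWarnings(
    transitionProbabilities(countTransitions(ms, includeEnd = FALSE)))
  expect_equal(syllableEntropy(model, "A"), 0)

  ms5 <- motifSet(lapply(c("A", "B", "C", "D", "E"), function(o) c("A", o)))
  m5 <- suppressWarnings(
    transitionProbabilities(countTransitions(ms5, includeEnd = FALSE)))
  expect_equal(syllableEntropy(m5, "A"), log2(5), tolerance = 1e-12)

  # p = (0.5, 0.25, 0.25): frozen from the term-by-term oracle
  ms3 <- motifSet(list(c("A", "A"), c("A", "A"), c("A", "B"), c("A", "C")))
  m3 <- suppressWarnings(
    transitionProbabilities(countTransitions(ms3, includeEnd = FALSE)))
  expect_equal(oracle_entropy(c(0.5, 0.25, 0.25)), 1.5)
  expect_equal(syllableEntropy(m3, "A"), 1.5, tolerance = 1e-12)

  expect_error(syllableEntropy(m3, "Z"), "unknown")
})

test_that("maximum entropy is log2(n) and matches explicit uniform distributions", {
  expect_equal(maxEntropy(5), log2(5))
  expect_equal(maxEntropy(1), 0)
  expect_error(maxEntropy(0))
  for (n in 2:64)
    expect_equal(maxEntropy(n), oracle_entropy(rep(1 / n, n)), tolerance = 1e-9)
})

test_that("normalized entropy divides by the ceiling and guards its domain", {
  expect_equal(normalizedEntropy(log2(5), log2(5)), 1)
  expect_equal(normalizedEntropy(0, log2(5)), 0)
  expect_equal(normalizedEntropy(0, 0), 0)
  expect_equal(normalizedEntropy(1.5, log2(5)), 1.5 / log2(5), tolerance = 1e-12)
  expect_error(normalizedEntropy(2, 1), "exceeds")
  # overshoot within 1e-12 is clamped, not an error
  expect_lte(normalizedEntropy(log2(5) + 1e-13, log2(5)), 1)
})

test_that("fixed sequences give motif entropy 0 and stereotypy 1, with END counted", {
  ms <- motifSet(rep(list(c("A", "B", "C", "D", "E")), 20))
  sv <- sequenceVariability(ms, includeEnd = TRUE)
  expect_identical(motifEntropyScore(sv), 0)
  expect_identical(stereotypy(sv), 1)
  expect_identical(sv@stereotypyScaled, 100)
  expect_equal(sv@nUnique, 5L)
  # deterministic cycles of any length are fixed in both modes
  for (len in c(2, 3, 7)) {
    cyc <- as.character(seq_len(len))
    expect_equal(motifEntropyScore(sequenceVariability(
      motifSet(rep(list(cyc), 5)), includeEnd = TRUE)), 0)
    expect_equal(motifEntropyScore(sequenceVariability(
      syllableString(rep(cyc, 30)))), 0)
  }
})

test_that("weighted and standard motif entropy agree exactly at equal frequencies", {
  ms <- motifSet(list(c("A", "B", "A", "C"), c("B", "C", "B", "A"),
                      c("C", "A", "C", "B")))
  cnt <- countTransitions(ms, includeEnd = TRUE)
  expect_true(length(unique(leadingFrequency(cnt))) == 1)
  model <- transitionProbabilities(cnt)
  expect_identical(motifEntropyScore(motifEntropy(model, cnt, "standard")),
                   motifEntropyScore(motifEntropy(model, cnt, "weighted")))
})

test_that("a rare high-entropy syllable is damped by weighting, matching a hand oracle", {
  # 1 -> 1 (x8) and 1 -> 2; 2 -> 3; 3 alternates to 1/2 only once each
  syms <- c(rep("1", 9), "2", "3", "1", "3", "2", "1", "1")
  ss <- syllableString(syms)
  cnt <- countTransitions(ss)
  model <- transitionProbabilities(cnt)
  stdv <- motifEntropy(model, cnt, "standard", mode = "string_based")
  wtv <- motifEntropy(model, cnt, "weighted", mode = "string_based")
  # direct formula evaluation from the tallied counts
  cm <- countsMatrix(cnt)
  freq <- rowSums(cm)
  hn <- apply(cm, 1, function(r) oracle_entropy(r / sum(r))) / log2(3)
  w <- freq / max(freq)
  expect_equal(motifEntropyScore(stdv), mean(hn), tolerance = 1e-12)
  expect_equal(motifEntropyScore(wtv), mean(w * hn), tolerance = 1e-12)
  expect_lt(motifEntropyScore(wtv), motifEntropyScore(stdv))
})

test_that("END enters the motif-mode normalization ceiling unless legacyHmax", {
  ms <- motifSet(list(c("A", "B"), c("A", "A", "B")))
  sv <- sequenceVariability(ms, includeEnd = TRUE)
  expect_equal(unique(sv@perSyllable$maxEntropy), log2(3))  # A, B, END
  svl <- sequenceVariability(ms, includeEnd = TRUE, legacyHmax = TRUE)
  expect_equal(unique(svl@perSyllable$maxEntropy), log2(2))
})

test_that("entropy outputs are invariant to syllable relabeling", {
  model <- makeTransitionMatrix(5, 0.45)
  ss <- sampleSyllableString(model, length = 1000, seed = 33)
  sv1 <- sequenceVariability(ss, weighting = "weighted")
  relabel <- c("1" = "Q", "2" = "K", "3" = "Z", "4" = "M", "5" = "B")
  ss2 <- syllableString(unname(relabel[symbols(ss)]))
  sv2 <- sequenceVariability(ss2, weighting = "weighted")
  expect_equal(motifEntropyScore(sv1), motifEntropyScore(sv2), tolerance = 1e-12)
  expect_equal(sort(sv1@perSyllable$normEntropy), sort(sv2@perSyllable$normEntropy),
               tolerance = 1e-12)
})

test_that("uniform-chain strings approach normalized entropy 1", {
  model <- makeTransitionMatrix(5, 1)
  ests <- vapply(1:20, function(s) {
    ss <- sampleSyllableString(model, length = 3000, seed = 100 + s)
    motifEntropyScore(sequenceVariability(ss))
  }, 0)
  expect_true(all(abs(ests - 1) < 0.05))
})

test_that("percent change is 100 (UD - NS) / NS with matching sign", {
  expect_equal(percentChange(80, 80), 0)
  expect_equal(percentChange(100, 90), -10)
  expect_error(percentChange(0, 5), "zero")
  set.seed(9)
  ns <- runif(50, 0.1, 2); ud <- runif(50, 0.1, 2)
  expect_equal(sign(percentChange(ns, ud)), sign(ud - ns))
})
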