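make_tab <- function(values, bird = "b1", syllable = "1", cond = "NS-UD") {
  n <- length(values)
  data.frame(bird = bird, syllable = syllable, condition = cond,
             rendition = seq_len(n), duration = values, amplitude = values,
             pitch = values, fm = values, wiener_entropy = -values,
             mean_frequency = values, pitch_goodness = values)
}

test_that("feature summaries compute mean, SD (n-1), SE, and CV", {
  tab <- make_tab(rep(10, 25))
  fs <- featureSummary(tab)
  expect_equal(unique(fs$cv), 0)
  expect_equal(unique(fs$n), 25)

  fs2 <- featureSummary(make_tab(c(9, 10, 11)))
  expect_equal(unique(fs2$cv), 0.1)            # SD = 1 (n-1 denominator), mean 10
  expect_equal(unique(fs2$se), 1 / sqrt(3))
  # Wiener entropy has a negative mean; its CV still reports the magnitude
  expect_equal(fs2$mean[fs2$feature == "wiener_entropy"], -10)
  expect_equal(fs2$cv[fs2$feature == "wiener_entropy"], 0.1)

  expect_error(featureSummary(make_tab(c(10, 10))[1, , drop = FALSE]), ">= 2")
})

test_that("CV of Gaussian renditions recovers sigma/mu and is scale invariant", {
  mu <- 800; sigma <- 0.074 * 800
  cvs <- vapply(1:200, function(s) {
    set.seed(400 + s)
    featureSummary(make_tab(rnorm(25, mu, sigma)))$cv[1]
  }, 0)
  # CV of 25 Gaussian draws: SE approx cv/sqrt(2 n)
  se <- 0.074 / sqrt(50) / sqrt(200)
  expect_lt(abs(mean(cvs) - 0.074), 3 * se + 0.074 * 0.02)

  tab <- make_tab(rnorm(25, 10, 1))
  tab2 <- tab
  num <- c("duration", "amplitude", "pitch", "fm", "wiener_entropy",
           "mean_frequency", "pitch_goodness")
  tab2[num] <- tab2[num] * 7
  expect_equal(featureSummary(tab)$cv, featureSummary(tab2)$cv,
               tolerance = 1e-12)
})

test_that("zero-mean features yield NA CV with a warning", {
  tab <- make_tab(c(-1, 0, 1))
  tab$duration <- c(0.1, 0.2, 0.3)   # durations must stay positive
  expect_warning(fs <- featureSummary(tab), "undefined")
  expect_true(anyNA(fs$cv))
  expect_false(is.na(fs$cv[fs$feature == "duration"]))
})

test_that("CV aggregation by bird or by syllable matches hand calculations", {
  fs <- rbind(
    data.frame(bird = "b1", syllable = c("1", "2"), condition = "NS-UD",
               feature = "pitch", n = 25, mean = 1, sd = 1, se = 1,
               cv = c(0.1, 0.1)),
    data.frame(bird = "b2", syllable = c("1", "2", "3", "4"),
               condition = "NS-UD", feature = "pitch", n = 25, mean = 1,
               sd = 1, se = 1, cv = rep(0.2, 4)))
  perBird <- aggregateCV(fs, level = "per_bird_then_group")
  perSyl <- aggregateCV(fs, level = "per_syllable")
  expect_equal(perBird$mean, 0.15)
  expect_equal(perSyl$mean, mean(c(0.1, 0.1, 0.2, 0.2, 0.2, 0.2)))
  expect_equal(perBird$n, 2)
  expect_equal(perSyl$n, 6)

  # one syllable per bird: the two levels coincide
  one <- fs[fs$syllable == "1", ]
  expect_equal(aggregateCV(one, level = "per_bird_then_group")$mean,
               aggregateCV(one, level = "per_syllable")$mean)
  expect_error(aggregateCV(fs, level = "nope"))
})

test_that("score batches summarize off-diagonal scores only", {
  expect_equal(aggregateScores(matrix(50, 20, 20))$n_scores, 380)
  expect_equal(aggregateScores(matrix(50, 30, 30))$n_scores, 870)
  const <- matrix(85, 20, 20); diag(const) <- 100
  agg <- aggregateScores(const)
  expect_equal(agg$mean, 85)     # the 100s on the diagonal are excluded
  expect_equal(agg$se, 0)
  expect_error(aggregateScores(matrix(1, 1, 1)), "at least 2")

  sb <- scoreBatch(const, const, unit = "clip")
  both <- aggregateScores(sb)
  expect_equal(both$score, c("similarity", "accuracy"))
  expect_equal(both$n_scores, c(380, 380))
})

test_that("identity is similarity x accuracy / 100, computed before averaging", {
  expect_equal(identityScore(100, 100), 100)
  expect_equal(identityScore(50, 50), 25)
  expect_error(identityScore(120, 50), "0, 100")
  set.seed(31)
  sim <- runif(30, 60, 100); acc <- runif(30, 60, 100)
  perSyllable <- mean(identityScore(sim, acc))
  ofMeans <- identityScore(mean(sim), mean(acc))
  expect_equal(perSyllable, mean(sim * acc / 100))   # direct oracle
  expect_false(isTRUE(all.equal(perSyllable, ofMeans)))
  expect_true(all(identityScore(sim, acc) <= 100))
  expect_identical(identityScore(0, 70), 0)
  expect_identical(identityScore(70, 0), 0)
})

rand_traj <- function(n, seed, jitter = 0) {
  set.seed(seed)
  base <- cbind(pitch = 800 + 100 * sin(seq_len(n) / 3),
                fm = 30 + 5 * cos(seq_len(n) / 5),
                wiener_entropy = -2 + 0.3 * sin(seq_len(n) / 7),
                pitch_goodness = 150 + 20 * cos(seq_len(n) / 4))
  base <- base + matrix(rnorm(n * 4, 0, jitter), n, 4) *
    rep(c(100, 5, 0.3, 20), each = n)
  featureTrajectory(base[, 1], base[, 2], base[, 3], base[, 4])
}

test_that("identical trajectories score 100; noise degrades both scores", {
  a <- rand_traj(40, 1)
  same <- trajectorySimilarity(a, a, mode = "asymmetric")
  expect_equal(unname(same), c(100, 100))
  same2 <- trajectorySimilarity(a, a, mode = "symmetric")
  expect_equal(unname(same2), c(100, 100))

  sc <- trajectoryScale(a)
  noise_levels <- c(0.05, 0.2, 0.5, 1)
  avg <- sapply(noise_levels, function(nl) {
    rowMeans(vapply(1:20, function(s) {
      b <- rand_traj(40, 1, jitter = 0)
      set.seed(1000 + s)
      vals <- b@values + matrix(rnorm(40 * 4), 40, 4) *
        rep(nl * c(100, 5, 0.3, 20), each = 40)
      b2 <- featureTrajectory(vals[, 1], vals[, 2], vals[, 3], vals[, 4])
      trajectorySimilarity(a, b2, mode = "symmetric", scale = sc)
    }, c(similarity = 0, accuracy = 0)))
  })
  expect_true(all(diff(avg["similarity", ]) < 0))
  expect_true(all(diff(avg["accuracy", ]) < 0))
})

test_that("asymmetric window search beats symmetric alignment for shifted copies", {
  a <- rand_traj(60, 2)
  shift <- 12
  v <- a@values[c((shift + 1):60, 1:shift), ]
  b <- featureTrajectory(v[, 1], v[, 2], v[, 3], v[, 4])
  sc <- trajectoryScale(a, b)
  asym <- trajectorySimilarity(a, b, mode = "asymmetric", scale = sc)
  sym <- trajectorySimilarity(a, b, mode = "symmetric", scale = sc)
  expect_gt(asym["similarity"], sym["similarity"])
})

test_that("symmetric trajectory similarity is symmetric in its arguments", {
  a <- rand_traj(45, 3)
  b <- rand_traj(45, 4)
  sc <- trajectoryScale(a, b)
  s1 <- trajectorySimilarity(a, b, mode = "symmetric", scale = sc)
  s2 <- trajectorySimilarity(b, a, mode = "symmetric", scale = sc)
  expect_lt(abs(s1["similarity"] - s2["similarity"]), 1e-9)
  expect_lt(abs(s1["accuracy"] - s2["accuracy"]), 1e-9)
})

test_that("sample-count stabilization returns the settling point", {
  # identical scores settle immediately
  items <- rep(list(1), 30)
  scoreFn <- function(x) c(similarity = 80, accuracy = 80)
  res <- stabilizeSampleCount(items, scoreFn)
  expect_equal(res$n, 10)
  expect_true(res$stabilized)

  # cumulative means settle only from n = 30 on: the 25 -> 30 step still
  # moves the mean by 0.6, the later steps by < 0.15
  vals <- rep(c(84, 78, 76, 76, 76, 78.3, 78.5, 78.58, 78.62),
              times = c(10, rep(5, 8)))
  items2 <- as.list(vals)
  meanFn <- function(x) {
    v <- unlist(x)
    c(similarity = mean(v), accuracy = mean(v))
  }
  res2 <- stabilizeSampleCount(items2, meanFn, tol = 0.5)
  expect_true(res2$stabilized)
  expect_equal(res2$n, 30)

  # a low-variance set: the chosen n moves by at most one step across shuffles
  set.seed(45)
  vals3 <- rnorm(60, 80, 0.3)
  ns <- vapply(1:20, function(s) {
    set.seed(500 + s)
    stabilizeSampleCount(as.list(sample(vals3)), meanFn)$n
  }, 0)
  expect_lte(diff(range(ns)), 5)

  # wildly varying scores never settle: all items used, with a warning
  diverge <- as.list(seq(0, 100, length.out = 40))
  expect_warning(res3 <- stabilizeSampleCount(diverge, meanFn), "did not stabilize")
  expect_equal(res3$n, 40)
  expect_false(res3$stabilized)
})
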