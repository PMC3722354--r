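test_that("RT trimming drops only responses beyond two SDs, in one pass", {
  r <- trim_and_mean_rt(c(500, 510, 490, 505, 495))
  expect_equal(r$mean, 500)
  expect_equal(r$n_excluded, 0L)
  # hand-checked: mean 750, SD ~612, |2000 - 750| > 2 SD, others kept
  r2 <- trim_and_mean_rt(c(500, 510, 490, 505, 495, 2000))
  expect_equal(r2$mean, 500)
  expect_equal(r2$n_excluded, 1L)
  r3 <- trim_and_mean_rt(rep(800, 4))
  expect_equal(r3$mean, 800)
  expect_equal(r3$n_excluded, 0L)
  expect_true(is.na(trim_and_mean_rt(c(700, NA))$mean))
})

test_that("word-length-effect slope matches the normal-equations oracle", {
  expect_equal(word_length_effect(c(500, 550, 600, 650), 3:6), 50)
  expect_equal(word_length_effect(rep(520, 4), 3:6), 0)
  set.seed(12)
  for (i in 1:5) {
    y <- 400 + 60 * (3:6) + stats::rnorm(4, 0, 30)
    X <- cbind(1, 3:6)
    beta <- solve(t(X) %*% X, t(X) %*% y)  # independent normal equations
    expect_equal(word_length_effect(y, 3:6), beta[2], tolerance = 1e-10)
  }
  # invariance: additive shifts leave the slope, scaling scales it
  y <- c(510, 620, 640, 800)
  expect_equal(word_length_effect(y + 123, 3:6),
               word_length_effect(y, 3:6), tolerance = 1e-10)
  expect_equal(word_length_effect(3 * y, 3:6),
               3 * word_length_effect(y, 3:6), tolerance = 1e-10)
  expect_error(word_length_effect(500, 3), "2 length bins")
})

test_that("accuracy scoring uses the 1 / 0 / 0.5 scheme and excludes voice-key failures", {
  expect_equal(score_accuracy(c("correct", "correct", "self_corrected",
                                "error")), 62.5)
  expect_equal(score_accuracy(rep("correct", 7)), 100)
  expect_equal(score_accuracy(c("correct", "voicekey_fail")), 100)
  expect_equal(score_accuracy(c("omitted", "error")), 0)
  # permutation invariance
  set.seed(13)
  oc <- sample(c("correct", "error", "self_corrected", "omitted",
                 "voicekey_fail"), 40, TRUE)
  expect_equal(score_accuracy(oc), score_accuracy(sample(oc)))
  expect_error(score_accuracy("voicekey_fail"), "no valid")
})

test_that("text reading speed and inclusion thresholds are computed as stated", {
  expect_equal(text_wpm(90, 30), 180)
  expect_equal(text_wpm(87, 60), 87)
  expect_equal(text_wpm(94, 88.5), 60 * 94 / 88.5)
  expect_error(text_wpm(90, 0))
  expect_equal(inclusion_threshold(495.3, 84.3), 663.9)
  expect_equal(inclusion_threshold(0, 1), 2)
  expect_equal(inclusion_threshold(1.1, 9.4), 19.9)
})

test_that("n-gram decomposition keeps order and duplicates", {
  expect_equal(ngram_decompose("house", 2), c("ho", "ou", "us", "se"))
  expect_equal(ngram_decompose("house", 3), c("hou", "ous", "use"))
  expect_equal(ngram_decompose("at", 2), "at")
  expect_equal(ngram_decompose("aaa", 2), c("aa", "aa"))
  expect_equal(ngram_decompose("at", 3), character(0))
})

test_that("n-gram frequency index counts all reference occurrences", {
  expect_equal(ngram_frequency_index("cat", c("cap", "can"), 2), 1.0)
  expect_equal(ngram_frequency_index("cat", c("dog", "pig"), 2), 0)
  # linearity: duplicating the reference doubles the index
  ref <- c("mast", "mist", "most")
  i1 <- ngram_frequency_index("mast", ref, 2)
  i2 <- ngram_frequency_index("mast", c(ref, ref), 2)
  expect_equal(i2, 2 * i1)
  # within-list index excludes the word's own entry
  i3 <- ngram_frequency_index("mast", ref, 2, exclude_index = 1)
  expect_equal(i3, ngram_frequency_index("mast", ref[-1], 2))
  # brute-force oracle over random lists: all (word n-gram, reference
  # n-gram) equality pairs divided by the word's n-gram count
  set.seed(14)
  letters5 <- c("a", "e", "s", "t", "r", "n", "o")
  for (rep in 1:5) {
    n <- sample(2:3, 1)
    words <- replicate(30, paste(sample(letters5, sample(3:6, 1), TRUE),
                                 collapse = ""))
    w <- words[1]; ref <- words[-1]
    wg <- ngram_decompose(w, n)
    rg <- unlist(lapply(ref, ngram_decompose, n = n))
    brute <- sum(outer(wg, rg, "==")) / length(wg)
    expect_equal(ngram_frequency_index(w, ref, n), brute)
  }
  expect_error(ngram_frequency_index("cat", character(0), 2), "empty")
})

test_that("partial correlation residualizes on the covariate", {
  set.seed(15)
  c0 <- stats::rnorm(200)
  # y identical to the covariate: correlation of residuals is null
  x <- stats::rnorm(200)
  expect_lt(abs(partial_correlation(x, c0, c0)), 1e-10)
  # constant covariate: plain Pearson correlation
  y <- x + stats::rnorm(200)
  expect_equal(partial_correlation(x, y, rep(2, 200)), stats::cor(x, y))
  # known partial correlation 0.5 at n = 500, recovered within 0.1
  n <- 500
  z <- stats::rnorm(n)
  S <- matrix(c(1, 0.5, 0.5, 1), 2)
  uv <- matrix(stats::rnorm(2 * n), n) %*% chol(S)
  x2 <- 2 * z + uv[, 1]
  y2 <- -z + uv[, 2]
  expect_lt(abs(partial_correlation(x2, y2, z) - 0.5), 0.1)
  expect_error(partial_correlation(rep(1, 10), c0[1:10], c0[1:10]),
               "zero-variance")
})

test_that("difficulty ladder moves one level per outcome and saturates", {
  expect_equal(ladder_transition("easy", TRUE)$level, "medium")
  expect_equal(ladder_transition("medium", TRUE)$level, "hard")
  expect_equal(ladder_transition("hard", TRUE)$level, "hard")
  expect_equal(ladder_transition("medium", FALSE)$level, "easy")
  expect_equal(ladder_transition("hard", FALSE)$level, "medium")
  expect_equal(ladder_transition("easy", FALSE)$level, "easy")
  expect_equal(ladder_transition("easy", TRUE)$reward_pence, 1L)
  expect_equal(ladder_transition("easy", FALSE)$reward_pence, 0L)
})

test_that("shared-letter counts use multiset intersection", {
  expect_equal(shared_letters("food", "hate"), 0)
  expect_equal(shared_letters("food", "fill"), 1)
  expect_equal(shared_letters("food", "foot"), 3)
  expect_equal(shared_letters("aab", "aba"), 3)
})

test_that("reading measures summarize a hand-built trial table correctly", {
  trials <- data.frame(
    subject = "S1", timepoint = "t1", list = "trained",
    word = c("cat", "sun", "dogs", "mild", "tall", "horse", "point",
             "brains", "crowds"),
    length = c(3, 3, 4, 4, 4, 5, 5, 6, 6),
    rt_ms = c(600, 640, 700, 720, 740, 800, 820, 900, 940),
    outcome = c("correct", "correct", "correct", "voicekey_fail",
                "correct", "self_corrected", "correct", "correct",
                "correct"))
  m <- reading_measures(trials)
  get <- function(ms) m$value[m$measure == ms]
  expect_equal(get("mean_rt_len3"), 620)
  expect_equal(get("mean_rt_len4"), 720)  # voice-key trial has no RT
  expect_equal(get("mean_rt_len5"), 810)
  expect_equal(get("wle"),
               word_length_effect(c(620, 720, 810, 920), 3:6))
  expect_equal(get("accuracy"), 100 * (1 + 1 + 1 + 1 + 0.5 + 1 + 1 + 1) / 8)
})
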