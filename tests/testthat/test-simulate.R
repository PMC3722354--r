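test_that("generators are pure functions of config and seed", {
  w1 <- generate_word_lists(n_words = 40, seed = 3)
  w2 <- generate_word_lists(n_words = 40, seed = 3)
  expect_identical(w1, w2)
  t1 <- generate_reading_trials(n_subjects = 2, word_lists = w1, seed = 5)
  t2 <- generate_reading_trials(n_subjects = 2, word_lists = w1, seed = 5)
  expect_identical(t1, t2)
  l1 <- generate_training_log(seed = 7)
  l2 <- generate_training_log(seed = 7)
  expect_identical(l1, l2)
})

test_that("word lists are disjoint, length-matched, with controllable overlap", {
  wl <- generate_word_lists(n_words = 40, seed = 2)
  expect_length(wl$list_a, 40)
  expect_length(intersect(wl$list_a, wl$list_b), 0)
  expect_equal(table(nchar(wl$list_a)), table(nchar(wl$list_b)))
  # zero-overlap mode: between-list bigram index is 0 for every word
  wl0 <- generate_word_lists(n_words = 40, overlap = "none", seed = 2)
  idx <- vapply(wl0$list_a, ngram_frequency_index, 0,
                reference = wl0$list_b, n = 2)
  expect_true(all(idx == 0))
  expect_equal(wl0$between_list_bigram_index, 0)
  # natural mode shares letter combinations
  expect_gt(wl$between_list_bigram_index, 0)
})

test_that("generated trial tables pass the behaviour module validation", {
  tr <- generate_reading_trials(n_subjects = 2, seed = 6,
                                word_lists = generate_word_lists(40,
                                                                 seed = 6))
  expect_true(all(tr$length == nchar(tr$word)))
  expect_true(all(tr$list %in% c("trained", "untrained")))
  expect_true(all(tr$timepoint %in% c("t1", "t2", "t3", "t4")))
  expect_true(all(is.na(tr$rt_ms[tr$outcome %in% c("omitted",
                                                   "voicekey_fail")])))
  expect_equal(nrow(tr), 2 * 4 * 128)
  # balanced over length x list within each timepoint
  expect_true(all(table(tr$length, tr$list, tr$timepoint) == 2 * 16))
  m <- reading_measures(tr)
  expect_true(all(c("wle", "accuracy", "mean_rt") %in% m$measure))
})

test_that("a null training effect produces no systematic condition difference", {
  wl <- generate_word_lists(40, seed = 8)
  deltas <- vapply(1:20, function(r) {
    tr <- generate_reading_trials(n_subjects = 2, training_effect = 0,
                                  length_interaction = 0,
                                  word_lists = wl, seed = 800 + r)
    training_effect_pct(reading_measures(tr))
  }, 0)
  se <- stats::sd(deltas) / sqrt(length(deltas))
  expect_lt(abs(mean(deltas)), 2 * se + 0.5)
})

test_that("the configured training effect is recovered by the analyzer", {
  wl <- generate_word_lists(80, seed = 9)
  eff <- vapply(1:10, function(r) {
    tr <- generate_reading_trials(n_subjects = 9, training_effect = 0.115,
                                  word_lists = wl, seed = 900 + r)
    training_effect_pct(reading_measures(tr))
  }, 0)
  expect_lt(abs(mean(eff) - 11.5), 2)
})

test_that("a positive length interaction shrinks the trained word-length effect", {
  wl <- generate_word_lists(80, seed = 10)
  tr <- generate_reading_trials(n_subjects = 4, training_effect = 0.115,
                                length_interaction = 0.03,
                                noise_sigma = 0.01, word_lists = wl,
                                seed = 11)
  m <- reading_measures(tr)
  w <- m[m$measure == "wle" & m$timepoint == "t3", ]
  wle_tr <- mean(w$value[w$list == "trained"])
  wle_un <- mean(w$value[w$list == "untrained"])
  expect_lt(wle_tr, wle_un)
})

test_that("training-log ladder dynamics match their Markov chain", {
  # perfect accuracy: every word reaches and stays at hard (each word is
  # probed on a 'different' trial only about every other block)
  l1 <- generate_training_log(n_words = 8, p_correct = 1, n_blocks = 20,
                              seed = 1)
  last <- l1[l1$block == 20, ]
  expect_true(all(last$level_before == "hard"))
  # zero accuracy: every word stays easy
  l0 <- generate_training_log(n_words = 8, p_correct = 0, n_blocks = 10,
                              seed = 1)
  expect_true(all(l0$level_after == "easy"))
  # pence accounting: one pence per correct answer
  expect_equal(max(l1$pence_total), sum(l1$correct))
  # chance accuracy: level occupancy on 'different' trials approaches the
  # stationary distribution of the 3-state birth-death chain (uniform for
  # p = 0.5)
  lh <- generate_training_log(n_words = 6, p_correct = 0.5,
                              n_blocks = 400, seed = 12)
  diff_trials <- lh[lh$type == "different" & lh$block > 50, ]
  occ <- table(diff_trials$level_before) / nrow(diff_trials)
  expect_true(all(abs(occ[c("easy", "medium", "hard")] - 1 / 3) < 0.05))
})

test_that("synthetic MEG groups honour their signal-to-noise contract", {
  fix <- desk_fixture(n_sensors = 8)
  par <- set_gains(dcm_params(fix$net), c("L_OCC->L_vOT" = 1.5))
  # near-infinite SNR: the robust average equals the noiseless projection
  grp <- generate_meg_group(par, fix$fwd_pattern, fix$lf, n_subjects = 1,
                            n_trials = 8, snr = 1e9,
                            window_ms = c(-100, 250),
                            subject_jitter_sd = 0, seed = 13)
  ep <- grp$subjects[[1]]
  ev <- suppressWarnings(robust_average(ep, "trained"))
  act <- simulate_sources(par, fix$fwd_pattern, "modulated",
                          duration_ms = 250)
  clean <- project_to_sensors(act, fix$lf, noise_sd = 0)
  post <- ep$times_ms >= 0
  expect_lt(max(abs(ev$data[, post] - clean$data)),
            1e-6 * max(abs(clean$data)))
  # epochs carry conditions, catch trials and the full window
  expect_equal(sort(unique(ep$conditions)),
               c("catch", "trained", "untrained"))
  expect_equal(min(ep$times_ms), -100, tolerance = 1e-9)
  # unit gains: the two condition means are statistically identical
  par1 <- dcm_params(fix$net)
  grp1 <- generate_meg_group(par1, fix$fwd_pattern, fix$lf,
                             n_subjects = 1, n_trials = 30, snr = 5,
                             window_ms = c(-100, 250),
                             subject_jitter_sd = 0, seed = 14)
  ep1 <- grp1$subjects[[1]]
  d_tr <- apply(ep1$data[ep1$conditions == "trained", , ], c(2, 3), mean)
  d_un <- apply(ep1$data[ep1$conditions == "untrained", , ], c(2, 3),
                mean)
  noise_evk <- grp1$truth$noise_sd[1] / sqrt(30)
  expect_lt(max(abs(d_tr - d_un)), 6 * noise_evk)
  # empirical noise SD matches the configured SNR
  resid <- ep1$data[1, , ] - ep1$data[2, , ]
  expect_equal(stats::sd(resid) / sqrt(2), grp1$truth$noise_sd[1],
               tolerance = 0.02)
  # determinism
  grp2 <- generate_meg_group(par1, fix$fwd_pattern, fix$lf,
                             n_subjects = 1, n_trials = 30, snr = 5,
                             window_ms = c(-100, 250),
                             subject_jitter_sd = 0, seed = 14)
  expect_identical(grp1$subjects[[1]]$data, grp2$subjects[[1]]$data)
})
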