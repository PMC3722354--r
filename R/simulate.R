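#' Generate a pair of word lists with controlled orthographic overlap
#'
#' Builds two disjoint lists of pronounceable consonant-vowel strings with
#' identical length distributions (lengths 3-6, equal counts per length by
#' default, 500 words per list as in a full training stimulus set).  In
#' `"natural"` mode both lists draw on the same alphabet, so bigrams and
#' trigrams recur within and between lists; in `"none"` mode the lists use
#' disjoint alphabets, so the between-list n-gram frequency index is 0 for
#' every word.
#'
#' @param n_words words per list.
#' @param lengths letter lengths used (equal counts per length).
#' @param overlap `"natural"` or `"none"`.
#' @param seed RNG seed (generation is a pure function of config + seed).
#' @return list with `list_a`, `list_b` (character vectors) and
#'   `between_list_bigram_index` (achieved mean index of list A words
#'   against list B).
#' @export
generate_word_lists <- function(n_words = 500, lengths = 3:6,
                                overlap = c("natural", "none"), seed = 1) {
  overlap <- match.arg(overlap)
  stopifnot(n_words %% length(lengths) == 0)
  set.seed(seed)
  cons <- c("b", "c", "d", "f", "g", "h", "j", "k",
            "l", "m", "n", "p", "r", "s", "t", "v")
  vows <- c("a", "e", "i", "o", "u", "y")
  alph <- if (overlap == "none")
    list(a = list(c = cons[1:8], v = vows[1:3]),
         b = list(c = cons[9:16], v = vows[4:6]))
  else list(a = list(c = cons, v = vows), b = list(c = cons, v = vows))
  make_word <- function(L, ab) {
    paste(vapply(seq_len(L), function(i)
      sample(if (i %% 2 == 1) ab$c else ab$v, 1), ""), collapse = "")
  }
  n_per <- n_words / length(lengths)
  gen_list <- function(ab, taboo = character(0)) {
    words <- character(0)
    for (L in lengths) {
      got <- character(0)
      while (length(got) < n_per) {
        w <- make_word(L, ab)
        if (!(w %in% got) && !(w %in% taboo)) got <- c(got, w)
      }
      words <- c(words, got)
    }
    words
  }
  list_a <- gen_list(alph$a)
  list_b <- gen_list(alph$b, taboo = list_a)
  bl <- mean(vapply(list_a, ngram_frequency_index, 0,
                    reference = list_b, n = 2))
  list(list_a = list_a, list_b = list_b, between_list_bigram_index = bl)
}

#' Generate behavioural reading-trial tables with a known training effect
#'
#' Emulates a four-timepoint (t1, t2 pre-training; t3, t4 post-training)
#' single-word reading study: each timepoint has `n_trials` trials balanced
#' over letter length (3-6) and list (trained/untrained).  RTs are
#' lognormal around a per-subject base plus a per-letter slope; at t3 the
#' trained list carries a multiplicative RT reduction of `training_effect`
#' with a per-letter interaction (training helps longer words more),
#' attenuated by `t4_retention` at follow-up.  The interaction is centred
#' on the mean length so the configured effect equals the average
#' reduction collapsed over lengths.  Outcomes are sampled from
#' `outcome_rates`; omitted and voice-key-failure trials have no RT.
#'
#' @param n_subjects number of simulated patients.
#' @param base_rt_ms group-level median base RT for 3-letter words, ms.
#' @param base_rt_sdlog between-subject lognormal SD of the base RT.
#' @param wle_slope_ms mean RT increase per additional letter, ms.
#' @param training_effect proportional RT reduction for trained words at
#'   t3 (0.115 = 11.5%).
#' @param length_interaction extra proportional reduction per letter above
#'   the mean length.
#' @param t4_retention fraction of the training effect retained at t4.
#' @param noise_sigma lognormal trial-to-trial noise SD (log scale).
#' @param outcome_rates named probabilities over trial outcomes.
#' @param n_trials trials per timepoint (balanced over 4 lengths x 2
#'   lists).
#' @param word_lists optional result of [generate_word_lists()]; generated
#'   (natural overlap) when NULL.
#' @param seed RNG seed.
#' @return data frame with columns `subject`, `word`, `length`, `list`,
#'   `timepoint`, `rt_ms`, `outcome`.
#' @export
generate_reading_trials <- function(n_subjects = 9, base_rt_ms = 1300,
                                    base_rt_sdlog = 0.25,
                                    wle_slope_ms = 100,
                                    training_effect = 0.115,
                                    length_interaction = 0.02,
                                    t4_retention = 0.5,
                                    noise_sigma = 0.2,
                                    outcome_rates = c(correct = 0.90,
                                                      error = 0.03,
                                                      self_corrected = 0.02,
                                                      omitted = 0.018,
                                                      voicekey_fail = 0.032),
                                    n_trials = 128,
                                    word_lists = NULL, seed = 1) {
  stopifnot(training_effect >= 0, training_effect < 1,
            abs(sum(outcome_rates) - 1) < 1e-8, all(outcome_rates >= 0),
            n_trials %% 8 == 0)
  set.seed(seed)
  if (is.null(word_lists))
    word_lists <- generate_word_lists(seed = seed)
  lengths <- 3:6
  mean_len <- mean(lengths)
  n_cell <- n_trials / 8
  rows <- list()
  for (s in seq_len(n_subjects)) {
    base_s <- base_rt_ms * exp(stats::rnorm(1, 0, base_rt_sdlog))
    slope_s <- wle_slope_ms * exp(stats::rnorm(1, 0, 0.2))
    for (tp in c("t1", "t2", "t3", "t4")) {
      for (L in lengths) for (lst in c("trained", "untrained")) {
        pool <- if (lst == "trained") word_lists$list_a else
          word_lists$list_b
        pool <- pool[nchar(pool) == L]
        words <- sample(pool, n_cell, replace = n_cell > length(pool))
        mu <- base_s + slope_s * (L - 3)
        if (lst == "trained") {
          red <- training_effect + length_interaction * (L - mean_len)
          if (tp == "t3") mu <- mu * (1 - red)
          if (tp == "t4") mu <- mu * (1 - t4_retention * red)
        }
        rt <- mu * exp(stats::rnorm(n_cell, 0, noise_sigma) -
                         noise_sigma^2 / 2)
        outc <- sample(names(outcome_rates), n_cell, replace = TRUE,
                       prob = outcome_rates)
        rt[outc %in% c("omitted", "voicekey_fail")] <- NA
        rows[[length(rows) + 1L]] <- data.frame(
          subject = sprintf("S%02d", s), word = words, length = L,
          list = lst, timepoint = tp, rt_ms = rt, outcome = outc,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate an adaptive same/different training session
#'
#' Alternates training blocks (15 audiovisual word pairs, passive) with
#' testing blocks in which each trained word is probed once; half the
#' probes are 'match' trials and half 'different' trials.  'Different'
#' trials drive the easy/medium/hard difficulty ladder one step per
#' outcome; every correct test response earns one pence.
#'
#' @param n_words words per training block (each probed once per test
#'   block).
#' @param p_correct probability of a correct test response: a scalar, or a
#'   named vector over levels (`easy`, `medium`, `hard`).
#' @param n_blocks number of training+testing cycles.
#' @param seed RNG seed.
#' @return data frame log: `block`, `word`, `type` (match/different),
#'   `level_before`, `correct`, `level_after`, `pence_total`.
#' @export
generate_training_log <- function(n_words = 15, p_correct = 0.8,
                                  n_blocks = 10, seed = 1) {
  if (length(p_correct) == 1)
    p_correct <- c(easy = p_correct, medium = p_correct, hard = p_correct)
  stopifnot(all(p_correct >= 0), all(p_correct <= 1),
            all(c("easy", "medium", "hard") %in% names(p_correct)))
  set.seed(seed)
  words <- sprintf("w%02d", seq_len(n_words))
  level <- stats::setNames(rep("easy", n_words), words)
  pence <- 0L
  rows <- list()
  for (b in seq_len(n_blocks)) {
    probe_type <- sample(rep(c("match", "different"),
                             length.out = n_words))
    for (i in seq_len(n_words)) {
      w <- words[i]
      lv <- level[[w]]
      ok <- stats::runif(1) < p_correct[[lv]]
      lv_after <- lv
      if (probe_type[i] == "different") {
        tr <- ladder_transition(lv, ok)
        lv_after <- tr$level
        level[[w]] <- lv_after
      }
      pence <- pence + as.integer(ok)
      rows[[length(rows) + 1L]] <- data.frame(
        block = b, word = w, type = probe_type[i], level_before = lv,
        correct = ok, level_after = lv_after, pence_total = pence,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Head-sphere source locations for a network
#'
#' Maps the network's MNI prior coordinates into the spherical head model
#' by uniform scaling (MNI coordinates sit slightly outside a 90 mm
#' sphere).
#'
#' @param network a `network_spec`.
#' @param scale shrink factor applied to the MNI mm coordinates.
#' @return matrix (sources x 3), mm, rownames = node ids.
#' @export
source_locations_mm <- function(network, scale = 0.8) {
  m <- as.matrix(network[, c("x", "y", "z")]) * scale
  rownames(m) <- network$id
  m
}

# deterministic tangential unit orientation at a location (radial dipoles
# are silent in the spherical model, so sources are given tangential
# moments)
tangential_orientation <- function(loc) {
  r <- loc / sqrt(sum(loc^2))
  up <- if (abs(r[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  o <- c(r[2] * up[3] - r[3] * up[2],
         r[3] * up[1] - r[1] * up[3],
         r[1] * up[2] - r[2] * up[1])
  o / sqrt(sum(o^2))
}

#' Default lead field for a network in the spherical model
#'
#' Places one fixed tangentially-oriented dipole per source at the scaled
#' prior locations.
#'
#' @param network a `network_spec`.
#' @param sensors a `sensor_array`.
#' @param scale location shrink factor (see [source_locations_mm()]).
#' @return a `leadfield`.
#' @export
network_leadfield <- function(network, sensors, scale = 0.8) {
  locs <- source_locations_mm(network, scale)
  oris <- t(apply(locs, 1, tangential_orientation))
  leadfield_matrix(locs, oris, sensors)
}

#' Generate a synthetic MEG group from a known generative model
#'
#' For each subject: the extrinsic strengths are jittered lognormally
#' (between-subject heterogeneity; the condition gains are shared across
#' subjects, matching a random-effects group analysis), both conditions
#' are simulated from the source model, projected to the sensors, and
#' i.i.d. Gaussian sensor noise is added at the configured SNR
#' (`noise_sd = rms(poststimulus clean signal) / snr`).  Trials cover the
#' full peristimulus window (resting zeros before stimulus onset); catch
#' trials (noise only, as from unmodelled stimuli) are labelled for
#' exclusion.  The returned ground-truth record is sufficient to score
#' recovery without re-simulation.
#'
#' @param params true `dcm_params` (including gains set via [set_gains()]).
#' @param pattern the true `modulation_pattern`.
#' @param leadfield a `leadfield` for the network (see
#'   [network_leadfield()]).
#' @param n_subjects,n_trials subjects and trials per condition.
#' @param snr amplitude signal-to-noise ratio of single trials.
#' @param window_ms peristimulus epoch window, ms.
#' @param subject_jitter_sd lognormal SD of the per-subject extrinsic
#'   strength jitter.
#' @param n_catch catch trials per subject (labelled `catch`).
#' @param dt sample interval, s.
#' @param seed RNG seed.
#' @return list with `subjects` (list of `epoch_set`) and `truth` (params,
#'   pattern, per-subject strength factors, noise SD, seed).
#' @export
generate_meg_group <- function(params, pattern, leadfield,
                               n_subjects = 8, n_trials = 50, snr = 10,
                               window_ms = c(-100, 1000),
                               subject_jitter_sd = 0.1, n_catch = 10,
                               dt = 1 / 480, seed = 1) {
  stopifnot(snr > 0, window_ms[1] <= 0)
  set.seed(seed)
  n_pre <- round(-window_ms[1] / 1000 / dt)
  subjects <- vector("list", n_subjects)
  jitters <- vector("list", n_subjects)
  noise_sds <- numeric(n_subjects)
  for (s in seq_len(n_subjects)) {
    par_s <- params
    jit <- exp(stats::rnorm(nrow(par_s$connections), 0, subject_jitter_sd))
    par_s$connections$A <- par_s$connections$A * jit
    jitters[[s]] <- stats::setNames(jit, par_s$connections$id)
    clean <- list()
    for (cond in c("baseline", "modulated")) {
      act <- simulate_sources(par_s, pattern, cond,
                              duration_ms = window_ms[2], dt = dt)
      ev <- project_to_sensors(act, leadfield, noise_sd = 0)
      clean[[cond]] <- cbind(matrix(0, nrow(ev$data), n_pre), ev$data)
    }
    times_ms <- (seq_len(ncol(clean$baseline)) - n_pre - 1) * dt * 1000
    noise_sd <- sqrt(mean(c(clean$baseline[, -(1:n_pre)]^2,
                            clean$modulated[, -(1:n_pre)]^2))) / snr
    noise_sds[s] <- noise_sd
    n_sens <- nrow(clean$baseline); n_samp <- ncol(clean$baseline)
    n_tot <- 2 * n_trials + n_catch
    arr <- array(0, c(n_tot, n_sens, n_samp))
    conds <- c(rep("untrained", n_trials), rep("trained", n_trials),
               rep("catch", n_catch))
    for (tr in seq_len(n_tot)) {
      base <- switch(conds[tr], untrained = clean$baseline,
                     trained = clean$modulated,
                     catch = matrix(0, n_sens, n_samp))
      arr[tr, , ] <- base + matrix(stats::rnorm(n_sens * n_samp, 0,
                                                noise_sd), n_sens)
    }
    subjects[[s]] <- new_epoch_set(arr, times_ms, conds, dt = dt,
                                   provenance = "synthetic; catch trials to exclude")
  }
  list(subjects = subjects,
       truth = list(params = params, pattern = pattern,
                    strength_jitter = jitters, noise_sd = noise_sds,
                    snr = snr, n_trials = n_trials, seed = seed))
}
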