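#' Trimmed mean reaction time
#'
#' Single-pass outlier trimming used for naming latencies: the mean and
#' sample SD are computed once, responses more than two SDs from the mean
#' are excluded (reducing the positive skew typical of reading RTs), and
#' the mean of the survivors is returned.
#'
#' @param rt_ms numeric vector of reaction times, ms (NAs dropped).
#' @param n_sd exclusion threshold in SD units.
#' @return list with `mean` (NA if fewer than 2 valid RTs), `n_excluded`,
#'   `n_used`.
#' @export
trim_and_mean_rt <- function(rt_ms, n_sd = 2) {
  rt <- rt_ms[!is.na(rt_ms)]
  if (length(rt) < 2)
    return(list(mean = NA_real_, n_excluded = 0L, n_used = length(rt)))
  m <- mean(rt); s <- stats::sd(rt)
  keep <- abs(rt - m) <= n_sd * s
  list(mean = mean(rt[keep]), n_excluded = sum(!keep), n_used = sum(keep))
}

#' Word-length-effect slope
#'
#' Average increase in naming latency per additional letter: the
#' ordinary-least-squares slope of the per-length mean RTs on letter
#' length.  For equally spaced lengths this equals the mean successive
#' difference.
#'
#' @param mean_rt mean RT per length bin, ms.
#' @param lengths letter lengths of the bins.
#' @return slope, ms per letter.
#' @export
word_length_effect <- function(mean_rt, lengths = seq_along(mean_rt) + 2) {
  ok <- !is.na(mean_rt)
  if (sum(ok) < 2) stop("word length effect needs >= 2 length bins")
  stats::coef(stats::lm(mean_rt[ok] ~ lengths[ok]))[[2]]
}

#' Reading accuracy score
#'
#' Correct trials score 1, errors and omissions 0, self-corrections and
#' verbal false starts 0.5; voice-key failures are excluded from the
#' denominator.  Returns 100 x the mean score.
#'
#' @param outcomes character vector with values among `correct`, `error`,
#'   `omitted`, `self_corrected`, `voicekey_fail`.
#' @return accuracy, percent.
#' @export
score_accuracy <- function(outcomes) {
  scores <- c(correct = 1, error = 0, omitted = 0, self_corrected = 0.5)
  valid <- outcomes[outcomes != "voicekey_fail"]
  if (!length(valid)) stop("no valid (non voice-key-failure) trials")
  bad <- setdiff(valid, names(scores))
  if (length(bad)) stop("unknown outcome(s): ", paste(bad, collapse = ", "))
  100 * mean(scores[valid])
}

#' Text reading speed
#'
#' @param n_words words in the text.
#' @param duration_s reading time, s.
#' @return words per minute.
#' @export
text_wpm <- function(n_words, duration_s) {
  stopifnot(duration_s > 0)
  60 * n_words / duration_s
}

#' Impairment inclusion threshold
#'
#' Two control-group standard deviations above the control mean; scores
#' beyond this are classed as impaired.
#'
#' @param control_mean,control_sd control-group statistics.
#' @return threshold (same units as the mean).
#' @export
inclusion_threshold <- function(control_mean, control_sd) {
  stopifnot(control_sd >= 0)
  control_mean + 2 * control_sd
}

#' Decompose a word into letter n-grams
#'
#' All contiguous substrings of length n, in order, duplicates kept
#' ("house" has four bigrams ho, ou, us, se and three trigrams hou, ous,
#' use).
#'
#' @param word a string.
#' @param n n-gram length (2 = bigrams, 3 = trigrams).
#' @return character vector of `nchar(word) - n + 1` n-grams (empty when
#'   the word is shorter than n).
#' @export
ngram_decompose <- function(word, n) {
  L <- nchar(word)
  if (L < n) return(character(0))
  vapply(seq_len(L - n + 1), function(i) substr(word, i, i + n - 1), "")
}

#' n-gram frequency index of a word against a reference list
#'
#' Counts, for each of the word's n-grams, every occurrence in every word
#' of the reference list (token counting, so a reference word can
#' contribute more than once), sums the counts and divides by the number of
#' n-grams in the word -- a length-independent measure of sub-lexical
#' orthographic overlap.  For a within-list index, pass `exclude_index` so
#' the word's own list entry is not counted against itself.
#'
#' @param word a string.
#' @param reference character vector of reference words.
#' @param n n-gram length.
#' @param exclude_index optional index into `reference` to drop (the word
#'   itself, for within-list indices).
#' @return the index (>= 0).
#' @export
ngram_frequency_index <- function(word, reference, n, exclude_index = NULL) {
  if (!is.null(exclude_index)) reference <- reference[-exclude_index]
  if (!length(reference)) stop("empty reference list")
  grams <- ngram_decompose(word, n)
  if (!length(grams)) stop("word '", word, "' is shorter than n = ", n)
  ref_grams <- unlist(lapply(reference, ngram_decompose, n = n))
  sum(vapply(grams, function(g) sum(ref_grams == g), 0)) / length(grams)
}

#' Partial correlation controlling for one covariate
#'
#' Pearson correlation of the residuals of x and y after least-squares
#' regression on the covariate.  A constant covariate leaves the plain
#' Pearson correlation.
#'
#' @param x,y,covariate numeric vectors of equal length (>= 4).
#' @return partial correlation coefficient.
#' @export
partial_correlation <- function(x, y, covariate) {
  stopifnot(length(x) == length(y), length(x) == length(covariate),
            length(x) >= 4)
  res_on <- function(v, c) {
    vc <- stats::var(c)
    b <- if (vc > 0) stats::cov(v, c) / vc else 0
    v - mean(v) - b * (c - mean(c))
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero-variance input; partial correlation undefined")
  rx <- res_on(x, covariate); ry <- res_on(y, covariate)
  # a variable collinear with the covariate leaves a null residual: no
  # residual association remains
  if (stats::sd(rx) < 1e-12 * stats::sd(x) ||
      stats::sd(ry) < 1e-12 * stats::sd(y)) return(0)
  stats::cor(rx, ry)
}

#' Adaptive training-ladder transition
#'
#' Word-pair difficulty moves one level per outcome on a 'different' test
#' trial: a correct response moves easy -> medium -> hard (hard stays
#' hard), an incorrect response moves hard -> medium -> easy (easy stays
#' easy).  Every correct test response earns one pence.
#'
#' @param level current level: `"easy"`, `"medium"` or `"hard"`.
#' @param correct logical.
#' @return list with `level` (new level) and `reward_pence` (0 or 1).
#' @export
ladder_transition <- function(level, correct) {
  lv <- c(easy = 1, medium = 2, hard = 3)
  stopifnot(level %in% names(lv))
  new <- max(1, min(3, lv[[level]] + if (correct) 1 else -1))
  list(level = names(lv)[new], reward_pence = as.integer(correct))
}

#' Shared letters between two words
#'
#' Multiset intersection of the letters of two words, used to describe the
#' difficulty of same/different word pairs (easy pairs share almost no
#' letters, hard pairs share several).
#'
#' @param word1,word2 strings.
#' @return number of shared letters (counting multiplicity).
#' @export
shared_letters <- function(word1, word2) {
  a <- table(strsplit(word1, "")[[1]])
  b <- table(strsplit(word2, "")[[1]])
  common <- intersect(names(a), names(b))
  sum(pmin(a[common], b[common]))
}

#' Per-subject reading measures from a trial table
#'
#' For each subject x timepoint x list cell: single-pass trimmed mean RT
#' per length bin, the grand mean over length bins, the word-length-effect
#' slope and the accuracy score.  Voice-key failures and trials without an
#' RT contribute to no RT statistic; accuracy uses all valid trials.
#'
#' @param trials data frame with columns `subject`, `word`, `length`,
#'   `list`, `timepoint`, `rt_ms`, `outcome`.
#' @return tidy data frame: subject, timepoint, list, measure, value.
#' @export
reading_measures <- function(trials) {
  req <- c("subject", "word", "length", "list", "timepoint", "rt_ms",
           "outcome")
  stopifnot(all(req %in% names(trials)))
  stopifnot(all(trials$length == nchar(trials$word)))
  out <- list()
  for (cell in split(trials, trials[c("subject", "timepoint", "list")],
                     drop = TRUE)) {
    rts <- cell$rt_ms
    rts[cell$outcome %in% c("voicekey_fail", "omitted")] <- NA
    lens <- sort(unique(cell$length))
    trims <- lapply(lens, function(L) trim_and_mean_rt(rts[cell$length == L]))
    per_len <- vapply(trims, `[[`, 0, "mean")
    n_exc <- sum(vapply(trims, `[[`, 0L, "n_excluded"))
    wle <- if (sum(!is.na(per_len)) >= 2)
      word_length_effect(per_len, lens) else NA_real_
    base <- cell[1, c("subject", "timepoint", "list")]
    add <- function(measure, value)
      cbind(base, data.frame(measure = measure, value = value))
    out[[length(out) + 1L]] <- rbind(
      do.call(rbind, lapply(seq_along(lens), function(i)
        add(sprintf("mean_rt_len%d", lens[i]), per_len[i]))),
      add("mean_rt", mean(per_len, na.rm = TRUE)),
      add("wle", wle),
      add("accuracy", score_accuracy(cell$outcome)),
      add("n_rt_excluded", n_exc))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Training effect on reading speed
#'
#' Relative RT reduction for trained versus untrained words at a timepoint:
#' `100 * (untrained - trained) / untrained`, computed from the per-subject
#' grand-mean RTs and averaged over subjects.
#'
#' @param measures output of [reading_measures()].
#' @param timepoint timepoint label (default `"t3"`, immediately after
#'   training).
#' @return percent RT reduction (positive = trained words read faster).
#' @export
training_effect_pct <- function(measures, timepoint = "t3") {
  m <- measures[measures$measure == "mean_rt" &
                  measures$timepoint == timepoint, ]
  wide <- merge(m[m$list == "trained", c("subject", "value")],
                m[m$list == "untrained", c("subject", "value")],
                by = "subject", suffixes = c("_tr", "_un"))
  mean(100 * (wide$value_un - wide$value_tr) / wide$value_un)
}
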