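#' Random-effects Bayesian model selection
#'
#' Variational estimation of population model frequencies from a
#' subjects x models matrix of log model evidences (free energies): a
#' Dirichlet posterior over frequencies is fitted by the standard
#' fixed-point scheme, and model exceedance probabilities (the probability
#' that each model is the most frequent in the population) are computed by
#' Monte-Carlo sampling of the fitted Dirichlet.
#'
#' @param evidence subjects x models matrix of free energies, nats.
#' @param seed RNG seed for the exceedance sampling.
#' @param n_samples Dirichlet samples for exceedance probabilities.
#' @param alpha0 symmetric Dirichlet prior count (default 1).
#' @param max_iter,tol fixed-point iteration controls.
#' @return list with `alpha` (Dirichlet counts), `expected_freq`,
#'   `exceedance`, `assignment` (subjects x models posterior model
#'   probabilities) and `seed`.
#' @export
rfx_bms <- function(evidence, seed = 1, n_samples = 10000, alpha0 = 1,
                    max_iter = 200, tol = 1e-8) {
  evidence <- rbind(evidence)
  if (!all(is.finite(evidence))) stop("non-finite model evidence")
  n <- nrow(evidence); K <- ncol(evidence)
  if (K == 1)
    return(list(alpha = alpha0 + n, expected_freq = 1, exceedance = 1,
                assignment = matrix(1, n, 1), seed = seed))
  alpha <- rep(alpha0, K)
  g <- matrix(0, n, K)
  for (it in seq_len(max_iter)) {
    lw <- sweep(evidence, 2, digamma(alpha) - digamma(sum(alpha)), "+")
    lw <- lw - apply(lw, 1, max)
    g <- exp(lw) / rowSums(exp(lw))
    alpha_new <- alpha0 + colSums(g)
    if (max(abs(alpha_new - alpha)) < tol) { alpha <- alpha_new; break }
    alpha <- alpha_new
  }
  set.seed(seed)
  draws <- matrix(stats::rgamma(n_samples * K, shape = rep(alpha,
                                                           each = n_samples)),
                  n_samples, K)
  xp <- tabulate(max.col(draws), nbins = K) / n_samples
  list(alpha = alpha, expected_freq = alpha / sum(alpha), exceedance = xp,
       assignment = g, seed = seed)
}

# per-(subject, model) posterior draw machinery shared by bma_gains
draw_connection_gains <- function(posterior, n_draws, connections) {
  k <- length(posterior$mean)
  L <- tryCatch(chol(posterior$cov + diag(1e-12, k)),
                error = function(e) diag(sqrt(pmax(diag(posterior$cov), 0)),
                                         k))
  z <- matrix(stats::rnorm(n_draws * k), n_draws, k)
  th <- sweep(z %*% L, 2, posterior$mean, "+")
  colnames(th) <- posterior$theta_names
  gains <- matrix(1, n_draws, length(connections),
                  dimnames = list(NULL, connections))
  pat <- posterior$pattern
  for (cid in connections) {
    nm_self <- paste0("bself:", sub("->.*", "", cid))
    if (endsWith(cid, paste0("->", sub("->.*", "", cid))) &&
        nm_self %in% colnames(th)) {
      gains[, cid] <- exp(th[, nm_self])
      next
    }
    if (is.null(pat)) next
    gidx <- pattern_group_of(pat, data.frame(
      source = sub("->.*", "", cid), target = sub(".*->", "", cid)))
    if (!is.na(gidx) && pat$bits[gidx] == 1L) {
      nm <- paste0("b:", pat$groups[[gidx]]$id)
      if (nm %in% colnames(th)) gains[, cid] <- exp(th[, nm])
    }
  }
  gains
}

#' Bayesian model averaging of connection gains
#'
#' Pools condition-modulation gains over subjects and models by repeated
#' sampling: on each draw, a model is sampled per subject from that
#' subject's posterior model probabilities (the random-effects assignment
#' from [rfx_bms()]), a parameter vector is drawn from the selected model's
#' Gaussian posterior, and the implied per-connection gains are pooled
#' across subjects.  Connections that carry no modulation in the sampled
#' model contribute deterministic gain 1.
#'
#' @param posteriors list over subjects of lists over models of
#'   `dcm_posterior` objects.
#' @param assignment subjects x models posterior model probabilities.
#' @param connections character vector of connection ids to report (default:
#'   every connection appearing in any group of the first model, plus
#'   self-connections).
#' @param n_samples number of pooled draws (default 10000).
#' @param seed RNG seed.
#' @return A `bma_result`: data frame `gains` (connection, mean, sd),
#'   `n_samples`, `seed`.
#' @export
bma_gains <- function(posteriors, assignment, connections = NULL,
                      n_samples = 10000, seed = 1) {
  n_sub <- length(posteriors)
  K <- length(posteriors[[1]])
  assignment <- rbind(assignment)
  stopifnot(nrow(assignment) == n_sub, ncol(assignment) == K)
  for (s in seq_len(n_sub)) for (k in seq_len(K))
    if (is.null(posteriors[[s]][[k]]))
      stop(sprintf("missing posterior for subject %d, model %d", s, k))
  if (is.null(connections)) {
    p1 <- posteriors[[1]][[1]]
    ids <- unlist(lapply(p1$pattern$groups, function(g)
      connection_id(g$members$source, g$members$target)))
    selfs <- connection_id(p1$params0$self$node, p1$params0$self$node)
    connections <- unique(c(ids, selfs))
  }
  set.seed(seed)
  pooled <- vector("list", n_sub)
  for (s in seq_len(n_sub)) {
    counts <- stats::rmultinom(1, n_samples, assignment[s, ])[, 1]
    rows <- vector("list", K)
    for (k in which(counts > 0))
      rows[[k]] <- draw_connection_gains(posteriors[[s]][[k]], counts[k],
                                         connections)
    pooled[[s]] <- do.call(rbind, rows[counts > 0])
  }
  all_draws <- do.call(rbind, pooled)
  gains <- data.frame(connection = connections,
                      mean = colMeans(all_draws),
                      sd = apply(all_draws, 2, stats::sd),
                      stringsAsFactors = FALSE)
  rownames(gains) <- NULL
  structure(list(gains = gains, n_samples = n_samples, seed = seed),
            class = "bma_result")
}

#' @export
print.bma_result <- function(x, ...) {
  cat(sprintf("<bma_result> %d connection(s), %d pooled draws\n",
              nrow(x$gains), x$n_samples))
  print(transform(x$gains, mean = round(mean, 3), sd = round(sd, 3)),
        row.names = FALSE)
  invisible(x)
}

#' Sampling-based proportion test on a connection gain
#'
#' Draws `n_samples` (default 10 000) Gaussian samples with the pooled mean
#' and SD of a connection's gain and reports the larger of the fractions
#' above and below 1.  If that exceedance probability passes the threshold
#' (default 0.9), the connection is judged significantly stronger in the
#' modulated condition (gain > 1) or in the baseline condition (gain < 1).
#' The probability converts to a Bayes factor as P / (1 - P).
#'
#' @param mean_gain,sd_gain pooled gain mean and SD (vectorized).
#' @param n_samples Gaussian samples per connection.
#' @param threshold significance threshold on the exceedance probability.
#' @param seed RNG seed.
#' @return A data frame (class `proportion_test_result`) with columns
#'   `mean`, `sd`, `p_exceed`, `direction`, `significant`, `bayes_factor`,
#'   plus attributes `n_samples`, `threshold`, `seed`.
#' @export
proportion_test <- function(mean_gain, sd_gain, n_samples = 10000,
                            threshold = 0.9, seed = 1) {
  stopifnot(all(sd_gain >= 0), length(mean_gain) == length(sd_gain))
  set.seed(seed)
  m <- length(mean_gain)
  p_gt <- numeric(m)
  for (i in seq_len(m)) {
    s <- if (sd_gain[i] > 0)
      stats::rnorm(n_samples, mean_gain[i], sd_gain[i])
    else rep(mean_gain[i], n_samples)
    p_gt[i] <- mean(s > 1)
  }
  p_lt <- 1 - p_gt
  p_ex <- pmax(p_gt, p_lt)
  res <- data.frame(
    mean = mean_gain, sd = sd_gain, p_exceed = p_ex,
    direction = ifelse(p_gt >= p_lt, "stronger_trained",
                       "stronger_untrained"),
    significant = p_ex > threshold,
    bayes_factor = ifelse(p_ex < 1, p_ex / (1 - p_ex), Inf),
    stringsAsFactors = FALSE)
  attr(res, "n_samples") <- n_samples
  attr(res, "threshold") <- threshold
  attr(res, "seed") <- seed
  class(res) <- c("proportion_test_result", "data.frame")
  res
}

#' Posterior probability to Bayes factor
#'
#' @param p posterior probability in [0, 1).
#' @return `p / (1 - p)`; `p = 1` returns +Inf with a warning.
#' @export
bayes_factor <- function(p) {
  stopifnot(all(p >= 0), all(p <= 1))
  out <- ifelse(p < 1, p / (1 - p), Inf)
  if (any(p == 1)) warning("posterior probability 1: Bayes factor is +Inf")
  out
}
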