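test_that("predicted responses are the simulator-projection composition", {
  fix <- desk_fixture()
  par <- set_gains(dcm_params(fix$net), c("L_OCC->L_vOT" = 1.5))
  pr <- predict_response(par, fix$fwd_pattern, fix$lf, c(1, 200))
  # manual composition, bit-identical
  for (cond in c("baseline", "modulated")) {
    act <- simulate_sources(par, fix$fwd_pattern, cond, duration_ms = 200)
    ev <- project_to_sensors(act, fix$lf, noise_sd = 0)
    sel <- act$times_ms >= 1 & act$times_ms <= 200
    expect_identical(pr[[cond]], ev$data[, sel])
  }
  # all B = 1: identical condition predictions
  pr0 <- predict_response(dcm_params(fix$net), fix$fwd_pattern, fix$lf)
  expect_identical(pr0$baseline, pr0$modulated)
  # zero lead field: zero predictions
  lf0 <- fix$lf; lf0$gain[] <- 0
  prz <- predict_response(par, fix$fwd_pattern, lf0)
  expect_true(all(prz$baseline == 0) && all(prz$modulated == 0))
})

test_that("Gaussian KL matches an independent closed-form evaluation", {
  set.seed(8)
  p <- 4
  A <- matrix(stats::rnorm(p * p), p); S1 <- crossprod(A) + diag(p)
  B <- matrix(stats::rnorm(p * p), p); S0 <- crossprod(B) + diag(p)
  m1 <- stats::rnorm(p); m0 <- stats::rnorm(p)
  # oracle written out independently via eigendecompositions
  e0 <- eigen(S0, symmetric = TRUE)
  S0inv <- e0$vectors %*% diag(1 / e0$values) %*% t(e0$vectors)
  kl_oracle <- 0.5 * (sum(diag(S0inv %*% S1)) +
                        t(m1 - m0) %*% S0inv %*% (m1 - m0) - p +
                        sum(log(e0$values)) -
                        sum(log(eigen(S1, symmetric = TRUE)$values)))
  expect_equal(gaussian_kl(m1, S1, m0, S0), as.numeric(kl_oracle),
               tolerance = 1e-8)
  expect_equal(gaussian_kl(m1, S1, m1, S1), 0, tolerance = 1e-10)
})

test_that("noiseless data from the prior means are recovered at the prior", {
  fix <- desk_fixture()
  pair <- desk_evoked_pair(fix, gain = 1)  # generative parameters = priors
  post <- invert(pair$untrained, pair$trained, fix$fwd_pattern, fix$lf,
                 dcm_params(fix$net))
  expect_lt(max(abs(post$mean)), 0.01)
  expect_true(all(diff(post$f_trajectory) >= -1e-9))
  expect_true(is.finite(post$free_energy))
  # covariance is symmetric positive definite
  expect_equal(post$cov, t(post$cov))
  expect_gt(min(eigen(post$cov, symmetric = TRUE)$values), 0)
})

test_that("a known modulatory gain is recovered from noiseless data", {
  fix <- desk_fixture()
  pair <- desk_evoked_pair(fix, gain = 1.5)
  post <- invert(pair$untrained, pair$trained, fix$fwd_pattern, fix$lf,
                 dcm_params(fix$net))
  expect_equal(exp(post$mean[["b:L_OCC->L_vOT"]]), 1.5, tolerance = 0.02)
  expect_true(post$converged)
})

test_that("gain recovery battery: noisy datasets, generating vs null model", {
  # 20 seeded datasets, one modulated connection (B = 1.5), noise at a
  # tenth of the evoked signal amplitude
  fix <- desk_fixture()
  log_err <- numeric(20)
  gains <- numeric(20)
  f_gen_wins <- logical(20)
  null_pattern <- model_pattern(fix$space, 1)
  par0 <- dcm_params(fix$net)
  for (r in 1:20) {
    pair <- desk_evoked_pair(fix, gain = 1.5,
                             noise_sd = 0, seed = r)
    ns <- sqrt(mean(pair$clean$baseline^2)) / 10
    pair <- desk_evoked_pair(fix, gain = 1.5, noise_sd = ns, seed = r)
    post <- invert(pair$untrained, pair$trained, fix$fwd_pattern, fix$lf,
                   par0)
    post0 <- invert(pair$untrained, pair$trained, null_pattern, fix$lf,
                    par0)
    gains[r] <- exp(post$mean[["b:L_OCC->L_vOT"]])
    log_err[r] <- abs(post$mean[["b:L_OCC->L_vOT"]] - log(1.5))
    f_gen_wins[r] <- post$free_energy > post0$free_energy
  }
  expect_lt(stats::median(log_err), 0.15)
  expect_gte(sum(gains >= 1.2 & gains <= 1.8), 16)  # >= 80%
  expect_gte(sum(f_gen_wins), 18)
})

test_that("posterior uncertainty shrinks as the data get cleaner", {
  fix <- desk_fixture()
  base <- desk_evoked_pair(fix, gain = 1.5)
  amp <- sqrt(mean(base$clean$baseline^2))
  tr <- vapply(c(0.2, 0.05), function(ns) {
    pair <- desk_evoked_pair(fix, gain = 1.5, noise_sd = ns * amp,
                             seed = 21)
    post <- invert(pair$untrained, pair$trained, fix$fwd_pattern, fix$lf,
                   dcm_params(fix$net))
    sum(diag(post$cov))
  }, 0)
  expect_lt(tr[2], tr[1])
})

test_that("free energy penalizes superfluous modulation parameters", {
  fix <- desk_fixture()
  pair <- desk_evoked_pair(fix, gain = 1.5,
                           noise_sd = 2e-7, seed = 31)
  full <- model_pattern(fix$space, nrow(fix$space$patterns))
  par0 <- dcm_params(fix$net)
  post_gen <- invert(pair$untrained, pair$trained, fix$fwd_pattern,
                     fix$lf, par0)
  post_full <- invert(pair$untrained, pair$trained, full, fix$lf, par0)
  expect_gt(post_gen$free_energy, post_full$free_energy)
})

test_that("stored posteriors support free-energy recomputation and PSD checks", {
  fix <- desk_fixture()
  pair <- desk_evoked_pair(fix, gain = 1.5)
  post <- invert(pair$untrained, pair$trained, fix$fwd_pattern, fix$lf,
                 dcm_params(fix$net))
  f <- free_energy(post, pair$untrained, pair$trained, fix$lf)
  expect_true(is.finite(f))
  # a posterior equal to the prior has zero complexity: F is pure accuracy
  p <- length(post$mean)
  pv <- lexidcm:::prior_variances(post$theta_names, post$priors)
  post_prior <- post
  post_prior$mean[] <- 0
  post_prior$cov <- diag(pv, p)
  pr <- predict_response(dcm_params(fix$net), fix$fwd_pattern, fix$lf,
                         post$fit_window_ms, post$dt)
  rss <- c(sum((pair$untrained$data / post$scale -
                  pr$baseline / post$scale)^2),
           sum((pair$trained$data / post$scale -
                  pr$modulated / post$scale)^2))
  nvec <- c(length(pr$baseline), length(pr$modulated))
  lam <- as.numeric(post$lambda)
  acc <- sum(0.5 * nvec * lam - 0.5 * exp(lam) * rss -
               0.5 * nvec * log(2 * pi))
  expect_equal(free_energy(post_prior, pair$untrained, pair$trained,
                           fix$lf), acc, tolerance = 1e-6)
  # non-PSD covariance is rejected
  post_bad <- post
  post_bad$cov <- diag(c(-1, rep(1, p - 1)))
  expect_error(free_energy(post_bad, pair$untrained, pair$trained,
                           fix$lf), "positive semi-definite")
})
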