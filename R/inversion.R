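#' Prior specification for model inversion
#'
#' All estimated parameters are log-scaling factors (so positivity of the
#' underlying strengths and gains is structural) with independent Gaussian
#' priors of mean 0 (scaling 1).
#'
#' @param v_log_a prior variance of extrinsic-strength log-scalings.
#' @param v_log_b prior variance of modulatory-gain log-scalings.
#' @param v_log_amp prior variance of the input-amplitude log-scaling.
#' @return An object of class `prior_spec`.
#' @export
dcm_priors <- function(v_log_a = 1 / 16, v_log_b = 1 / 16,
                       v_log_amp = 1 / 16) {
  stopifnot(v_log_a > 0, v_log_b > 0, v_log_amp > 0)
  structure(list(v_log_a = v_log_a, v_log_b = v_log_b,
                 v_log_amp = v_log_amp),
            class = "prior_spec")
}

# estimated-parameter layout for a given model: extrinsic log-scalings per
# connection, one log-gain per switched-on group, one log-gain per
# ungrouped self-connection (expressed in every model), input log-amplitude
theta_layout <- function(params, pattern) {
  nm <- paste0("a:", params$connections$id)
  if (!is.null(pattern)) {
    on <- which(pattern$bits == 1L)
    if (length(on))
      nm <- c(nm, paste0("b:", vapply(pattern$groups[on], `[[`, "", "id")))
    sgrp <- pattern_group_of(pattern,
                             data.frame(source = params$self$node,
                                        target = params$self$node))
    free_self <- params$self$node[is.na(sgrp)]
  } else {
    free_self <- params$self$node
  }
  nm <- c(nm, if (length(free_self)) paste0("bself:", free_self), "amp")
  nm
}

prior_variances <- function(theta_names, priors) {
  v <- numeric(length(theta_names))
  v[startsWith(theta_names, "a:")] <- priors$v_log_a
  v[startsWith(theta_names, "b")] <- priors$v_log_b
  v[theta_names == "amp"] <- priors$v_log_amp
  stats::setNames(v, theta_names)
}

# apply a named theta vector to a baseline parameter set
apply_theta <- function(params, pattern, theta) {
  for (nm in names(theta)) {
    val <- exp(theta[[nm]])
    if (startsWith(nm, "a:")) {
      id <- substring(nm, 3)
      i <- match(id, params$connections$id)
      params$connections$A[i] <- params$connections$A[i] * val
    } else if (startsWith(nm, "b:")) {
      gid <- substring(nm, 3)
      g <- Filter(function(x) x$id == gid, pattern$groups)[[1]]
      mids <- connection_id(g$members$source, g$members$target)
      ci <- match(mids, params$connections$id)
      params$connections$B[ci[!is.na(ci)]] <- val
      self_nodes <- g$members$source[g$members$source == g$members$target]
      si <- match(self_nodes, params$self$node)
      params$self$B[si[!is.na(si)]] <- val
    } else if (startsWith(nm, "bself:")) {
      node <- substring(nm, 7)
      params$self$B[match(node, params$self$node)] <- val
    } else if (nm == "amp") {
      params$input_amplitude <- params$input_amplitude * val
    }
  }
  params
}

#' Predicted two-condition sensor responses
#'
#' Deterministic composition of the source simulator (both conditions) and
#' the noiseless sensor projection, restricted to the fit window.
#'
#' @param params a `dcm_params`.
#' @param pattern a `modulation_pattern` (or NULL).
#' @param leadfield a `leadfield` over the network's sources.
#' @param window_ms fit window, ms (default 1-200).
#' @param dt integration step, s.
#' @return list with `baseline` and `modulated` (sensors x time matrices)
#'   and `times_ms`.
#' @export
predict_response <- function(params, pattern, leadfield,
                             window_ms = c(1, 200), dt = 1 / 480) {
  sel <- NULL
  out <- list()
  for (cond in c("baseline", "modulated")) {
    act <- simulate_sources(params, pattern, cond,
                            duration_ms = window_ms[2], dt = dt)
    if (is.null(sel)) {
      sel <- which(act$times_ms >= window_ms[1] - 1e-9 &
                   act$times_ms <= window_ms[2] + 1e-9)
      out$times_ms <- act$times_ms[sel]
    }
    ev <- project_to_sensors(act, leadfield, noise_sd = 0)
    out[[cond]] <- ev$data[, sel, drop = FALSE]
  }
  out
}

as_fit_matrix <- function(data, window_ms, dt) {
  if (inherits(data, "evoked")) {
    sel <- which(data$times_ms >= window_ms[1] - 1e-9 &
                 data$times_ms <= window_ms[2] + 1e-9)
    list(y = data$data[, sel, drop = FALSE], times = data$times_ms[sel])
  } else stop("data must be 'evoked' objects")
}

#' Kullback-Leibler divergence between two Gaussians
#'
#' KL(N(m1, S1) || N(m0, S0)), in nats.
#' @param m1,S1 mean and covariance of the first Gaussian.
#' @param m0,S0 mean and covariance of the second Gaussian.
#' @return scalar, nats.
#' @export
gaussian_kl <- function(m1, S1, m0, S0) {
  p <- length(m1)
  S0i <- solve(S0)
  d <- m1 - m0
  0.5 * (sum(diag(S0i %*% S1)) + sum(d * (S0i %*% d)) - p +
           determinant(S0)$modulus - determinant(S1)$modulus)[1]
}

#' Invert a DCM against a two-condition evoked pair
#'
#' Variational Laplace: Gauss-Newton/EM ascent on the free energy
#' F = accuracy - complexity under independent Gaussian priors on the
#' log-scaling parameters, with Levenberg-Marquardt step damping and one
#' noise log-precision hyperparameter per condition (point-estimated each
#' iteration).  Accepted iterations never decrease F; rejected steps are
#' rolled back with increased damping.  Deterministic given the data (no
#' randomness is consumed; `seed` is recorded for provenance).
#'
#' @param data_baseline,data_modulated `evoked` objects covering the fit
#'   window (e.g. untrained / trained conditions).
#' @param pattern a `modulation_pattern` defining which groups carry
#'   condition modulation in this model.
#' @param leadfield a `leadfield` over the network's sources.
#' @param params0 baseline `dcm_params` (prior means of the generative
#'   parameters).
#' @param priors a `prior_spec`.
#' @param window_ms fit window, ms.
#' @param dt integration step, s.
#' @param max_iter maximum iterations.
#' @param tol convergence: change in F below `tol` for 3 consecutive
#'   iterations.
#' @param seed recorded in the output.
#' @return A `dcm_posterior`: `mean`, `cov`, `free_energy`, `lambda` (noise
#'   log-precisions), `model_index`, `n_iterations`, `converged`,
#'   `f_trajectory`, plus the model context needed to recompute F.
#' @export
invert <- function(data_baseline, data_modulated, pattern, leadfield,
                   params0, priors = dcm_priors(), window_ms = c(1, 200),
                   dt = 1 / 480, max_iter = 64, tol = 0.01, seed = 0) {
  db <- as_fit_matrix(data_baseline, window_ms, dt)
  dm <- as_fit_matrix(data_modulated, window_ms, dt)
  stopifnot(all(is.finite(db$y)), all(is.finite(dm$y)))
  scale <- stats::sd(c(db$y, dm$y))
  if (scale == 0) scale <- 1
  y <- list(baseline = db$y / scale, modulated = dm$y / scale)
  nvec <- vapply(y, length, 0)

  th_names <- theta_layout(params0, pattern)
  p <- length(th_names)
  pv <- prior_variances(th_names, priors)
  Pi0 <- diag(1 / pv, p)
  mu0 <- stats::setNames(numeric(p), th_names)

  gfun <- function(theta) {
    par <- apply_theta(params0, pattern, stats::setNames(theta, th_names))
    pr <- tryCatch(predict_response(par, pattern, leadfield, window_ms, dt),
                   error = function(e) NULL)
    if (is.null(pr)) return(NULL)
    lapply(pr[c("baseline", "modulated")], function(m) m / scale)
  }

  resid_of <- function(g) list(baseline = y$baseline - g$baseline,
                               modulated = y$modulated - g$modulated)
  rss_of <- function(e) vapply(e, function(m) sum(m^2), 0)

  mu <- mu0
  g <- gfun(mu)
  if (is.null(g))
    stop("prediction failed at the prior mean; parameter regime unstable")
  e <- resid_of(g); rss <- rss_of(e)
  # cap the noise log-precision: on unit-scaled data a precision of e^16
  # already means essentially noiseless; uncapped precisions from
  # zero-residual fits destroy the conditioning of the curvature
  lam_cap <- 16
  lambda <- pmin(pmax(log(nvec / pmax(rss, 1e-12)), -lam_cap), lam_cap)

  jac <- function(mu, g0) {
    h <- 1e-3
    J <- list(baseline = matrix(0, nvec[1], p),
              modulated = matrix(0, nvec[2], p))
    for (j in seq_len(p)) {
      gj <- gfun(mu + (seq_len(p) == j) * h)
      if (is.null(gj)) return(NULL)
      J$baseline[, j] <- (as.numeric(gj$baseline) -
                            as.numeric(g0$baseline)) / h
      J$modulated[, j] <- (as.numeric(gj$modulated) -
                             as.numeric(g0$modulated)) / h
    }
    J
  }

  fe <- function(rss, trc, lambda, mu, Sigma) {
    acc <- sum(0.5 * nvec * lambda - 0.5 * exp(lambda) * (rss + trc) -
                 0.5 * nvec * log(2 * pi))
    acc - gaussian_kl(mu, Sigma, mu0, diag(pv, p))
  }

  nu <- 1
  F_cur <- -Inf
  f_traj <- numeric(0)
  small_steps <- 0L
  converged <- FALSE
  n_iter <- 0L
  Sigma <- diag(pv, p)

  for (it in seq_len(max_iter)) {
    n_iter <- it
    J <- jac(mu, g)
    if (is.null(J)) { nu <- nu * 8; next }
    H_lik <- exp(lambda[1]) * crossprod(J$baseline) +
             exp(lambda[2]) * crossprod(J$modulated)
    grad <- exp(lambda[1]) * crossprod(J$baseline, as.numeric(e$baseline)) +
            exp(lambda[2]) * crossprod(J$modulated, as.numeric(e$modulated)) -
            Pi0 %*% (mu - mu0)
    improved <- FALSE
    for (try in 1:5) {
      H <- H_lik + Pi0
      step <- tryCatch(solve(H + nu * diag(diag(H)), grad),
                       error = function(err)
                         solve(H + (nu + 1e-6) * diag(mean(diag(H)), p),
                               grad))
      mu_new <- mu + as.numeric(step)
      names(mu_new) <- th_names
      g_new <- gfun(mu_new)
      if (!is.null(g_new)) {
        e_new <- resid_of(g_new); rss_new <- rss_of(e_new)
        Sig_new <- tryCatch(solve(H_lik + Pi0), error = function(err) NULL)
        if (!is.null(Sig_new)) {
          Sig_new <- (Sig_new + t(Sig_new)) / 2
          evals <- eigen(Sig_new, symmetric = TRUE, only.values = TRUE)$values
          if (min(evals) <= 0)
            Sig_new <- Sig_new +
              diag(abs(min(evals)) + 1e-12 * max(evals), p)
          trc <- c(sum((J$baseline %*% Sig_new) * J$baseline),
                   sum((J$modulated %*% Sig_new) * J$modulated))
          lam_new <- pmin(pmax(log(nvec / pmax(rss_new + trc, 1e-12)),
                               -lam_cap), lam_cap)
          F_new <- fe(rss_new, trc, lam_new, mu_new, Sig_new)
          if (is.finite(F_new) && F_new > F_cur) {
            dF <- F_new - F_cur
            mu <- mu_new; g <- g_new; e <- e_new; rss <- rss_new
            lambda <- lam_new; Sigma <- Sig_new; F_cur <- F_new
            f_traj <- c(f_traj, F_cur)
            nu <- max(nu / 2, 1e-8)
            improved <- TRUE
            small_steps <- if (is.finite(dF) && dF < tol)
              small_steps + 1L else 0L
            break
          }
        }
      }
      nu <- nu * 8
    }
    if (!improved) small_steps <- small_steps + 1L
    if (small_steps >= 3L && it >= 3L) { converged <- TRUE; break }
  }

  structure(list(mean = mu, cov = Sigma, free_energy = F_cur,
                 lambda = stats::setNames(lambda,
                                          c("baseline", "modulated")),
                 fit_window_ms = window_ms,
                 model_index = if (!is.null(pattern)) pattern$index else NA,
                 n_iterations = n_iter, converged = converged,
                 f_trajectory = f_traj, theta_names = th_names,
                 pattern = pattern, params0 = params0,
                 priors = priors, scale = scale, dt = dt, seed = seed),
            class = "dcm_posterior")
}

#' @export
print.dcm_posterior <- function(x, ...) {
  cat(sprintf("<dcm_posterior> model %s: F = %.2f, %d iteration(s)%s\n",
              x$model_index, x$free_energy, x$n_iterations,
              if (x$converged) ", converged" else " (not converged)"))
  print(round(x$mean, 3))
  invisible(x)
}

#' Recompute the variational free energy of a stored posterior
#'
#' Accuracy (expected log-likelihood under the estimated Gaussian noise
#' precision) minus complexity (KL divergence of the posterior from the
#' prior), re-evaluated from the stored posterior mean against the data.
#'
#' @param posterior a `dcm_posterior`.
#' @param data_baseline,data_modulated the `evoked` pair it was fitted to.
#' @param leadfield the `leadfield` used.
#' @return scalar free energy, nats.
#' @export
free_energy <- function(posterior, data_baseline, data_modulated,
                        leadfield) {
  ev <- eigen(posterior$cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev)))
    stop("posterior covariance is not positive semi-definite")
  db <- as_fit_matrix(data_baseline, posterior$fit_window_ms, posterior$dt)
  dm <- as_fit_matrix(data_modulated, posterior$fit_window_ms, posterior$dt)
  y <- list(baseline = db$y / posterior$scale,
            modulated = dm$y / posterior$scale)
  par <- apply_theta(posterior$params0, posterior$pattern, posterior$mean)
  pr <- predict_response(par, posterior$pattern, leadfield,
                         posterior$fit_window_ms, posterior$dt)
  rss <- c(sum((y$baseline - pr$baseline / posterior$scale)^2),
           sum((y$modulated - pr$modulated / posterior$scale)^2))
  nvec <- vapply(y, length, 0)
  pv <- prior_variances(posterior$theta_names, posterior$priors)
  lam <- as.numeric(posterior$lambda)
  acc <- sum(0.5 * nvec * lam - 0.5 * exp(lam) * rss -
               0.5 * nvec * log(2 * pi))
  acc - gaussian_kl(posterior$mean, posterior$cov,
                    stats::setNames(numeric(length(pv)), names(pv)),
                    diag(pv, length(pv)))
}
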