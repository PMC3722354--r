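#' Population firing-rate sigmoid
#'
#' Converts mean membrane depolarization to population firing rate.
#' Monotone increasing and bounded in (0, 2 e0); at `v = v0` the rate is
#' exactly `e0`.  Inside the coupled dynamics the sigmoid is centred
#' (`s(v) - s(0)`) so that the all-zero resting state is a fixed point.
#'
#' @param v membrane potential, mV (vectorized).
#' @param e0 half-maximum firing rate, 1/s.
#' @param v0 threshold potential, mV.
#' @param r sigmoid slope, 1/mV.
#' @return firing rate, 1/s.
#' @export
sigmoid_rate <- function(v, e0 = 2.5, v0 = 6, r = 0.56) {
  stopifnot(all(is.finite(v)))
  2 * e0 / (1 + exp(-r * (v - v0)))
}

#' Exogenous input drive
#'
#' Gaussian bump modelling the stimulus-driven subcortical volley delivered
#' to the input nodes, peaking at `onset_ms` (default 60 ms peristimulus).
#'
#' @param t_ms peristimulus time, ms (vectorized).
#' @param onset_ms peak latency, ms.
#' @param width_ms Gaussian SD, ms.
#' @param amplitude peak drive (firing-rate units).
#' @return input drive at `t_ms`.
#' @export
exogenous_input <- function(t_ms, onset_ms = 60, width_ms = 16,
                            amplitude = 1) {
  stopifnot(width_ms > 0)
  amplitude * exp(-(t_ms - onset_ms)^2 / (2 * width_ms^2))
}

#' Construct a generative parameter set for a source network
#'
#' Bundles extrinsic connection strengths, condition-specific modulatory
#' gains, intrinsic synaptic constants and input timing for the coupled
#' three-population (pyramidal, spiny stellate, inhibitory interneuron)
#' neural mass model.  Extrinsic connections cover all admissible
#' (forward/backward/lateral) directed pairs of the network; each carries a
#' baseline strength `A` (laminar-typed default) and a modulatory gain `B`
#' (1 = no condition difference).  Self-connections carry a gain on the
#' intrinsic pyramidal-to-stellate loop.
#'
#' @param network a `network_spec`.
#' @param a_forward,a_backward,a_lateral default extrinsic strengths per
#'   connection class (dimensionless scalings of inter-source firing input).
#' @param H_e,H_i excitatory/inhibitory synaptic gains, mV.
#' @param tau_e_ms,tau_i_ms synaptic time constants, ms.
#' @param e0,v0,r sigmoid parameters (see [sigmoid_rate()]).
#' @param gamma intrinsic coupling gains (pyramidal->stellate,
#'   stellate->pyramidal, pyramidal->inhibitory, inhibitory->pyramidal).
#' @param delay_ms uniform inter-source conduction delay, ms.
#' @param input_onset_ms,input_width_ms,input_amplitude exogenous input
#'   bump (see [exogenous_input()]).
#' @param input_nodes node ids receiving the exogenous input; defaults to
#'   all level-1 (occipital) nodes.
#' @return An object of class `dcm_params`.
#' @export
dcm_params <- function(network,
                       a_forward = 32, a_backward = 16, a_lateral = 4,
                       H_e = 3.25, H_i = 22,
                       tau_e_ms = 10, tau_i_ms = 20,
                       e0 = 2.5, v0 = 6, r = 0.56,
                       gamma = c(135, 108, 33.75, 33.75),
                       delay_ms = 16,
                       input_onset_ms = 60, input_width_ms = 16,
                       input_amplitude = 150,
                       input_nodes = NULL) {
  stopifnot(H_e > 0, H_i > 0, tau_e_ms > 0, tau_i_ms > 0,
            a_forward >= 0, a_backward >= 0, a_lateral >= 0)
  conns <- enumerate_connections(network)
  conns <- conns[conns$klass %in% c("forward", "backward", "lateral"), ]
  conns$A <- c(forward = a_forward, backward = a_backward,
               lateral = a_lateral)[conns$klass]
  conns$B <- 1
  rownames(conns) <- NULL
  selfs <- data.frame(node = network$id, A = 1, B = 1,
                      stringsAsFactors = FALSE)
  C <- stats::setNames(as.numeric(network$level == min(network$level)),
                       network$id)
  if (!is.null(input_nodes)) {
    stopifnot(all(input_nodes %in% network$id))
    C[] <- 0; C[input_nodes] <- 1
  }
  structure(list(network = network, connections = conns, self = selfs,
                 C = C, H_e = H_e, H_i = H_i,
                 tau_e_ms = tau_e_ms, tau_i_ms = tau_i_ms,
                 e0 = e0, v0 = v0, r = r, gamma = gamma,
                 delay_ms = delay_ms,
                 input_onset_ms = input_onset_ms,
                 input_width_ms = input_width_ms,
                 input_amplitude = input_amplitude),
            class = "dcm_params")
}

#' @export
print.dcm_params <- function(x, ...) {
  cat(sprintf("<dcm_params> %d sources, %d extrinsic connections\n",
              nrow(x$network), nrow(x$connections)))
  cat(sprintf("  input at %s (onset %g ms), delay %g ms\n",
              paste(names(x$C)[x$C != 0], collapse = ", "),
              x$input_onset_ms, x$delay_ms))
  invisible(x)
}

#' Set modulatory gains on connections
#'
#' @param params a `dcm_params`.
#' @param gains named numeric vector: names are connection ids
#'   (`"SRC->TGT"`; a self-connection is `"NODE->NODE"`), values the gain B.
#' @return updated `dcm_params`.
#' @export
set_gains <- function(params, gains) {
  stopifnot(all(gains > 0))
  for (id in names(gains)) {
    i <- match(id, params$connections$id)
    if (!is.na(i)) { params$connections$B[i] <- gains[[id]]; next }
    node <- sub("->.*", "", id)
    j <- match(node, params$self$node)
    if (id == connection_id(node, node) && !is.na(j)) {
      params$self$B[j] <- gains[[id]]
    } else stop("unknown connection id: ", id)
  }
  params
}

#' Condition-specific effective connection strengths
#'
#' In the baseline condition every extrinsic strength is the intrinsic `A`.
#' In the modulated condition, connections belonging to a switched-on group
#' of `pattern` have strength `A * B`; connections in switched-off groups
#' keep `A`.  Self-connections that are not members of any group are
#' treated as modulated in every model (their gain is always expressed);
#' self-connections inside a group follow the group's switch.
#'
#' @param params a `dcm_params`.
#' @param pattern a `modulation_pattern`, or NULL (no group is on).
#' @param condition `"baseline"` or `"modulated"`.
#' @return list with `connections` (data frame incl. `strength`) and
#'   `selfgain` (named vector of intrinsic gain multipliers).
#' @export
effective_connectivity <- function(params, pattern = NULL,
                                   condition = c("baseline", "modulated")) {
  condition <- match.arg(condition)
  if (any(params$connections$B <= 0) || any(params$self$B <= 0))
    stop("modulatory gains B must be > 0")
  conns <- params$connections
  selfg <- stats::setNames(params$self$A, params$self$node)
  if (condition == "modulated") {
    on_conn <- rep(FALSE, nrow(conns))
    self_grouped <- rep(FALSE, nrow(params$self))
    self_on <- rep(FALSE, nrow(params$self))
    if (!is.null(pattern)) {
      grp <- pattern_group_of(pattern, conns)
      on_conn <- !is.na(grp) & pattern$bits[ifelse(is.na(grp), 1L, grp)] == 1L
      sgrp <- pattern_group_of(pattern,
                               data.frame(source = params$self$node,
                                          target = params$self$node))
      self_grouped <- !is.na(sgrp)
      self_on <- self_grouped & pattern$bits[ifelse(is.na(sgrp), 1L, sgrp)] == 1L
    }
    conns$strength <- conns$A * ifelse(on_conn, conns$B, 1)
    express <- !self_grouped | self_on   # ungrouped selves always expressed
    selfg <- stats::setNames(params$self$A * ifelse(express, params$self$B, 1),
                             params$self$node)
  } else {
    conns$strength <- conns$A
  }
  list(connections = conns, selfgain = selfg)
}

#' Simulate source-level evoked activity
#'
#' Deterministic fixed-step (RK4) integration of the coupled multi-source
#' neural mass model from the resting state, under the condition-specific
#' effective connectivity.  Forward afferents drive the spiny stellate
#' population, backward afferents the pyramidal and inhibitory populations,
#' lateral afferents all three; inter-source coupling is delayed by
#' `delay_ms`, intra-source coupling is undelayed.  The output is the
#' pyramidal-population depolarization per source.
#'
#' @param params a `dcm_params`.
#' @param pattern a `modulation_pattern` or NULL.
#' @param condition `"baseline"` or `"modulated"`.
#' @param duration_ms simulated peristimulus span, ms (from 0).
#' @param dt integration step, s (must be <= 2.5 ms).
#' @param guard instability guard on |state| (mV); divergence is an error.
#' @return A `source_activity`: list with `values` (time x source matrix,
#'   mV), `times_ms`, `dt`, `condition`.
#' @export
simulate_sources <- function(params, pattern = NULL,
                             condition = c("baseline", "modulated"),
                             duration_ms = 300, dt = 1 / 480,
                             guard = 1e3) {
  condition <- match.arg(condition)
  stopifnot(dt <= 2.5e-3, duration_ms > 0)
  eff <- effective_connectivity(params, pattern, condition)
  net <- params$network
  n <- nrow(net)
  AF <- AB <- AL <- matrix(0, n, n, dimnames = list(net$id, net$id))
  for (i in seq_len(nrow(eff$connections))) {
    cn <- eff$connections[i, ]
    M <- switch(cn$klass, forward = "AF", backward = "AB", lateral = "AL")
    if (M == "AF") AF[cn$target, cn$source] <- cn$strength
    if (M == "AB") AB[cn$target, cn$source] <- cn$strength
    if (M == "AL") AL[cn$target, cn$source] <- cn$strength
  }
  nsteps <- as.integer(round(duration_ms / 1000 / dt))
  vals <- simulate_jr_cpp(n, AF, AB, AL,
                          as.numeric(eff$selfgain[net$id]),
                          as.numeric(params$C[net$id]),
                          params$H_e, params$H_i,
                          params$tau_e_ms / 1000, params$tau_i_ms / 1000,
                          params$e0, params$v0, params$r, params$gamma,
                          params$delay_ms / 1000,
                          params$input_onset_ms / 1000,
                          params$input_width_ms / 1000,
                          params$input_amplitude,
                          dt, nsteps, guard)
  colnames(vals) <- net$id
  structure(list(values = vals, times_ms = (0:nsteps) * dt * 1000,
                 dt = dt, condition = condition),
            class = "source_activity")
}

#' @export
print.source_activity <- function(x, ...) {
  cat(sprintf("<source_activity> %d samples x %d sources, %s condition, dt = %.3g ms\n",
              nrow(x$values), ncol(x$values), x$condition, x$dt * 1000))
  invisible(x)
}
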