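# Shared fixture builders for the test suite.  Everything is generated in
# code; nothing is read from disk.

# a 2 x 2 network: two hemispheres, two levels
four_node_network <- function() {
  build_network(labels = c("OCC", "vOT"),
                levels = c(OCC = 1L, vOT = 2L),
                locations = rbind(OCC = c(15, -95, 2),
                                  vOT = c(44, -58, -15)))
}

# desk-scale inversion fixture: 2-source network, 8-model switch space,
# small sensor array
desk_fixture <- function(n_sensors = 16) {
  net <- desk_network()
  groups <- independent_groups(net, include_self = "pooled")
  space <- enumerate_model_space(groups)
  sensors <- make_sensor_array(n_sensors)
  lf <- network_leadfield(net, sensors)
  # model 2 switches the forward group only (little-endian bit order)
  list(net = net, groups = groups, space = space, sensors = sensors,
       lf = lf, fwd_pattern = model_pattern(space, 2))
}

# noiseless two-condition evoked pair generated from a known forward gain
desk_evoked_pair <- function(fix, gain = 1.5, noise_sd = 0, seed = 1) {
  ptrue <- set_gains(dcm_params(fix$net),
                     stats::setNames(gain, "L_OCC->L_vOT"))
  pr <- predict_response(ptrue, fix$fwd_pattern, fix$lf, c(1, 200))
  set.seed(seed)
  noisy <- function(m) m + matrix(stats::rnorm(length(m), 0, noise_sd),
                                  nrow(m))
  list(untrained = new_evoked(noisy(pr$baseline), pr$times_ms, "untrained"),
       trained = new_evoked(noisy(pr$modulated), pr$times_ms, "trained"),
       clean = pr)
}

# minimal hand-constructed posterior for group-inference tests: fixed gain
# on the forward group of the desk space
fake_posterior <- function(fix, log_gain, sd_log = 1e-6,
                           pattern = fix$fwd_pattern) {
  nm <- c("a:L_OCC->L_vOT", "a:L_vOT->L_OCC",
          if (any(pattern$bits == 1L))
            paste0("b:", vapply(pattern$groups[pattern$bits == 1L],
                                `[[`, "", "id")),
          "amp")
  mu <- stats::setNames(rep(0, length(nm)), nm)
  if ("b:L_OCC->L_vOT" %in% nm) mu[["b:L_OCC->L_vOT"]] <- log_gain
  structure(list(mean = mu, cov = diag(sd_log^2, length(nm)),
                 theta_names = nm, pattern = pattern,
                 params0 = dcm_params(fix$net), free_energy = 0,
                 model_index = pattern$index),
            class = "dcm_posterior")
}
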