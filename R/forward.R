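#' Construct a spherical MEG sensor array
#'
#' Sensors are placed on a spherical cap above the head-model sphere with
#' radial orientations (axial-gradiometer geometry approximated as oriented
#' magnetometers).  Positions use a Fibonacci lattice so any count is
#' roughly uniform.
#'
#' @param n_sensors number of channels (275 matches a whole-head axial
#'   gradiometer array; small counts are used for fast synthetic studies).
#' @param array_radius_m distance of sensors from the sphere centre, m.
#' @param head_radius_m radius of the conductor sphere, m.
#' @param cap_fraction fraction of the upper sphere covered (1 = full upper
#'   hemisphere plus a band below the equator).
#' @return An object of class `sensor_array`: `positions` (n x 3, m), unit
#'   `orientations` (n x 3), `sphere_center`, `sphere_radius`.
#' @export
make_sensor_array <- function(n_sensors = 275, array_radius_m = 0.12,
                              head_radius_m = 0.09, cap_fraction = 1.2) {
  stopifnot(n_sensors >= 1, array_radius_m > head_radius_m)
  i <- seq_len(n_sensors) - 0.5
  # z from just below the equator up to the pole
  z <- 1 - cap_fraction * i / n_sensors
  phi <- pi * (1 + sqrt(5)) * i
  rho <- sqrt(pmax(0, 1 - z^2))
  pos <- cbind(rho * cos(phi), rho * sin(phi), z) * array_radius_m
  ori <- pos / sqrt(rowSums(pos^2))
  structure(list(positions = pos, orientations = ori,
                 sphere_center = c(0, 0, 0),
                 sphere_radius = head_radius_m,
                 n_sensors = n_sensors),
            class = "sensor_array")
}

#' @export
print.sensor_array <- function(x, ...) {
  cat(sprintf("<sensor_array> %d sensors at %.0f mm, sphere radius %.0f mm\n",
              x$n_sensors, 1000 * sqrt(sum(x$positions[1, ]^2)),
              1000 * x$sphere_radius))
  invisible(x)
}

#' Read/write sensor geometry as CSV
#'
#' Columns: id, x, y, z (m), ox, oy, oz.
#' @param sensors a `sensor_array`.
#' @param path file path.
#' @return `path` / a `sensor_array`.
#' @export
write_sensor_csv <- function(sensors, path) {
  df <- data.frame(id = seq_len(sensors$n_sensors),
                   x = sensors$positions[, 1], y = sensors$positions[, 2],
                   z = sensors$positions[, 3],
                   ox = sensors$orientations[, 1],
                   oy = sensors$orientations[, 2],
                   oz = sensors$orientations[, 3])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sensor_csv
#' @param head_radius_m conductor sphere radius, m.
#' @export
read_sensor_csv <- function(path, head_radius_m = 0.09) {
  df <- utils::read.csv(path)
  structure(list(positions = as.matrix(df[, c("x", "y", "z")]),
                 orientations = as.matrix(df[, c("ox", "oy", "oz")]),
                 sphere_center = c(0, 0, 0),
                 sphere_radius = head_radius_m,
                 n_sensors = nrow(df)),
            class = "sensor_array")
}

# Sarvas closed-form magnetic field of a current dipole in a homogeneous
# conducting sphere, evaluated at points outside the sphere.  location_m and
# q are in the sphere-centred frame; returns the n x 3 field (T) for a unit
# moment magnitude times |q|.
sarvas_field <- function(location_m, q, sensors) {
  r0 <- location_m - sensors$sphere_center
  pos <- sweep(sensors$positions, 2, sensors$sphere_center)
  mu0_4pi <- 1e-7
  n <- nrow(pos)
  Qxr0 <- c(q[2] * r0[3] - q[3] * r0[2],
            q[3] * r0[1] - q[1] * r0[3],
            q[1] * r0[2] - q[2] * r0[1])
  B <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    r <- pos[i, ]
    a <- r - r0
    na <- sqrt(sum(a * a)); nr <- sqrt(sum(r * r))
    adotr <- sum(a * r)
    F <- na * (nr * na + nr^2 - sum(r0 * r))
    gF <- (na^2 / nr + adotr / na + 2 * na + 2 * nr) * r -
          (na + 2 * nr + adotr / na) * r0
    B[i, ] <- mu0_4pi / F^2 * (F * Qxr0 - sum(Qxr0 * r) * gF)
  }
  B
}

#' Lead field of a current dipole in a spherical conductor
#'
#' Analytic (Sarvas) magnetic forward solution: the field at each sensor,
#' projected on the sensor orientation, per unit dipole moment along
#' `orientation`.  Radial dipoles are magnetically silent in this model.
#'
#' @param location_mm dipole location, mm (sphere-centred frame).
#' @param orientation moment direction (3-vector, need not be unit; the
#'   gain is per unit moment, so the direction is normalized internally).
#' @param sensors a `sensor_array`.
#' @return numeric vector, one gain per sensor.
#' @export
dipole_leadfield <- function(location_mm, orientation, sensors) {
  loc <- location_mm / 1000
  rad <- sqrt(sum((loc - sensors$sphere_center)^2))
  if (rad >= sensors$sphere_radius)
    stop(sprintf("dipole at radius %.1f mm is not inside the %.1f mm sphere",
                 rad * 1000, sensors$sphere_radius * 1000))
  q <- orientation / sqrt(sum(orientation^2))
  B <- sarvas_field(loc, q, sensors)
  rowSums(B * sensors$orientations)
}

#' Lead-field matrix for a set of oriented sources
#'
#' @param locations_mm k x 3 matrix of source locations, mm.
#' @param orientations k x 3 matrix of moment directions.
#' @param sensors a `sensor_array`.
#' @return A `leadfield`: list with `gain` (sources x sensors),
#'   `source_locations_mm`, `source_orientations`.
#' @export
leadfield_matrix <- function(locations_mm, orientations, sensors) {
  locations_mm <- rbind(locations_mm)
  orientations <- rbind(orientations)
  k <- nrow(locations_mm)
  gain <- t(vapply(seq_len(k), function(i)
    dipole_leadfield(locations_mm[i, ], orientations[i, ], sensors),
    numeric(sensors$n_sensors)))
  structure(list(gain = gain, source_locations_mm = locations_mm,
                 source_orientations = orientations, sensors = sensors),
            class = "leadfield")
}

#' Project source activity to the sensor array
#'
#' Sensor data are `gain' x activity` plus i.i.d. Gaussian sensor noise.
#' With `n_trials = 1` and `noise_sd = 0` the projection is deterministic.
#'
#' @param activity a `source_activity` (its column order must match the
#'   lead-field source order).
#' @param leadfield a `leadfield`.
#' @param noise_sd sensor noise SD (same units as the projected signal).
#' @param n_trials number of noisy trials to emit.
#' @param seed RNG seed for the noise.
#' @param condition condition label carried on the output.
#' @return If `n_trials == 1`, an `evoked` (sensors x time); otherwise an
#'   `epoch_set` (trials x sensors x time).
#' @export
project_to_sensors <- function(activity, leadfield, noise_sd = 0,
                               n_trials = 1, seed = NULL,
                               condition = activity$condition) {
  if (nrow(leadfield$gain) != ncol(activity$values))
    stop("lead field has ", nrow(leadfield$gain), " sources but activity has ",
         ncol(activity$values))
  clean <- t(leadfield$gain) %*% t(activity$values)  # sensors x time
  if (!is.null(seed)) set.seed(seed)
  if (n_trials == 1) {
    data <- clean
    if (noise_sd > 0)
      data <- data + matrix(stats::rnorm(length(clean), 0, noise_sd),
                            nrow(clean))
    return(new_evoked(data, activity$times_ms, condition))
  }
  arr <- array(0, c(n_trials, nrow(clean), ncol(clean)))
  for (tr in seq_len(n_trials))
    arr[tr, , ] <- clean +
      matrix(stats::rnorm(length(clean), 0, noise_sd), nrow(clean))
  new_epoch_set(arr, activity$times_ms, rep(condition, n_trials),
                dt = activity$dt)
}

# free-space current-dipole field (Biot-Savart of the primary current);
# its radial component equals the conducting-sphere field's radial
# component, which makes it an independent oracle for the Sarvas solution
free_dipole_field <- function(location_m, q, points_m) {
  mu0_4pi <- 1e-7
  t(apply(points_m, 1, function(r) {
    a <- r - location_m
    na <- sqrt(sum(a * a))
    mu0_4pi * c(q[2] * a[3] - q[3] * a[2],
                q[3] * a[1] - q[1] * a[3],
                q[1] * a[2] - q[2] * a[1]) / na^3
  }))
}

#' Fit equivalent current dipoles to a sensor snapshot
#'
#' Maximum-a-posteriori simplification of variational Bayesian dipole
#' fitting: penalized least squares over dipole locations (moments solved
#' linearly at each candidate location), with a Gaussian penalty on the
#' distance from the prior locations, restarted from jittered starting
#' points (location jitter SD 6 mm, 100 restarts by default) and keeping
#' the best penalized fit.  Deterministic given `seed`.
#'
#' @param snapshot sensor vector at one latency.
#' @param sensors a `sensor_array`.
#' @param prior_mean_mm k x 3 matrix of prior dipole locations, mm.
#' @param location_jitter_sd jitter SD for restart starting points, mm.
#' @param prior_sd_mm Gaussian prior SD on location, mm.
#' @param n_restarts number of restarts.
#' @param seed RNG seed.
#' @param separation_warn_mm warn if two fitted dipoles end up closer than
#'   this (default 20 mm).
#' @return A `dipole_fit`: `locations_mm` (k x 3), `moments` (k x 3),
#'   `residual_variance` in [0, 1], `n_restarts`, `prior`, `seed`.
#' @export
fit_ecd <- function(snapshot, sensors, prior_mean_mm,
                    location_jitter_sd = 6, prior_sd_mm = 20,
                    n_restarts = 100, seed = 1,
                    separation_warn_mm = 20) {
  prior_mean_mm <- rbind(prior_mean_mm)
  k <- nrow(prior_mean_mm)
  stopifnot(k >= 1, length(snapshot) == sensors$n_sensors)
  rad <- sqrt(rowSums(sweep(prior_mean_mm / 1000, 2,
                            sensors$sphere_center)^2))
  stopifnot(all(rad < sensors$sphere_radius))
  ss_y <- sum(snapshot^2)
  if (ss_y == 0) {
    # penalty-only optimum: locations at the prior means, zero moments
    return(structure(list(locations_mm = prior_mean_mm,
                          moments = matrix(0, k, 3),
                          residual_variance = 0, n_restarts = n_restarts,
                          prior = list(mean_mm = prior_mean_mm,
                                       sd_mm = prior_sd_mm,
                                       jitter_sd_mm = location_jitter_sd),
                          seed = seed),
                     class = "dipole_fit"))
  }
  w <- mean(snapshot^2)
  rmax <- 0.95 * sensors$sphere_radius * 1000

  gain_at <- function(locs_mm) {
    G <- matrix(0, sensors$n_sensors, 3 * k)
    for (j in seq_len(k)) {
      loc <- locs_mm[j, ] / 1000
      B <- sarvas_field(loc, c(1, 0, 0), sensors); G[, 3 * j - 2] <-
        rowSums(B * sensors$orientations)
      B <- sarvas_field(loc, c(0, 1, 0), sensors); G[, 3 * j - 1] <-
        rowSums(B * sensors$orientations)
      B <- sarvas_field(loc, c(0, 0, 1), sensors); G[, 3 * j] <-
        rowSums(B * sensors$orientations)
    }
    G
  }
  objective <- function(par) {
    locs <- matrix(par, k, 3, byrow = TRUE)
    rr <- sqrt(rowSums(locs^2))
    if (any(rr >= rmax)) return(1e12 * (1 + max(rr) / rmax))
    G <- gain_at(locs)
    fit <- stats::lm.fit(G, snapshot)
    rss <- sum(fit$residuals^2)
    pen <- sum((locs - prior_mean_mm)^2) / prior_sd_mm^2
    rss + w * pen
  }

  set.seed(seed)
  best <- NULL
  n_ok <- 0
  for (rs in seq_len(n_restarts)) {
    start <- prior_mean_mm +
      matrix(stats::rnorm(3 * k, 0, location_jitter_sd), k, 3)
    opt <- tryCatch(
      stats::optim(as.numeric(t(start)), objective, method = "Nelder-Mead",
                   control = list(maxit = 400, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$value) || opt$value >= 1e12) next
    n_ok <- n_ok + 1
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (n_ok == 0)
    stop("all ", n_restarts, " dipole-fit restarts diverged ",
         "(k = ", k, ", |y| = ", signif(sqrt(ss_y), 3), ")")
  locs <- matrix(best$par, k, 3, byrow = TRUE)
  G <- gain_at(locs)
  fit <- stats::lm.fit(G, snapshot)
  moments <- matrix(fit$coefficients, k, 3, byrow = TRUE)
  moments[!is.finite(moments)] <- 0
  rv <- if (ss_y > 0) max(0, min(1, sum(fit$residuals^2) / ss_y)) else 0
  if (k > 1) {
    d <- as.matrix(stats::dist(locs))
    diag(d) <- Inf
    if (min(d) < separation_warn_mm)
      warning(sprintf("fitted dipoles separated by %.1f mm (< %.0f mm)",
                      min(d), separation_warn_mm))
  }
  structure(list(locations_mm = locs, moments = moments,
                 residual_variance = rv, n_restarts = n_restarts,
                 prior = list(mean_mm = prior_mean_mm, sd_mm = prior_sd_mm,
                              jitter_sd_mm = location_jitter_sd),
                 seed = seed),
            class = "dipole_fit")
}

#' @export
print.dipole_fit <- function(x, ...) {
  cat(sprintf("<dipole_fit> %d dipole(s), residual variance %.3f\n",
              nrow(x$locations_mm), x$residual_variance))
  invisible(x)
}
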