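test_that("band-pass keeps the passband and rejects DC and high frequencies", {
  srate <- 480
  t <- (0:(10 * srate - 1)) / srate
  mid <- seq(2 * srate, 8 * srate)  # avoid filtfilt edge transients
  x10 <- sin(2 * pi * 10 * t)
  y10 <- bandpass(x10, srate)
  expect_lt(abs(max(abs(y10[mid])) / max(abs(x10)) - 1), 0.05)
  ydc <- bandpass(rep(1, length(t)), srate)
  expect_lt(max(abs(ydc[mid])), 0.05)
  x60 <- sin(2 * pi * 60 * t)
  y60 <- bandpass(x60, srate)
  expect_lt(20 * log10(max(abs(y60[mid])) / max(abs(x60))), -20)
  expect_error(bandpass(rep(0, 5), srate), "too short")
  expect_error(bandpass(x10, srate = 50), "srate")
})

test_that("epoching subtracts the prestimulus mean and cuts the right samples", {
  srate <- 480
  set.seed(2)
  cont <- matrix(stats::rnorm(3 * 2000), 3)
  ep <- epoch_and_baseline(cont, event_samples = c(300, 900), srate = srate)
  pre <- ep$times_ms < 0
  for (tr in 1:2) for (s in 1:3)
    expect_equal(mean(ep$data[tr, s, pre]), 0, tolerance = 1e-12)
  # index arithmetic at 480 Hz: -100..1000 ms spans 529 samples
  expect_equal(dim(ep$data)[3], 529)
  expect_equal(ep$times_ms[1], -48 / 480 * 1000)
  expect_equal(ep$times_ms[529], 480 / 480 * 1000)
  # sample values: epoch of a ramp equals the cut segment minus its
  # prestimulus mean
  ramp <- matrix(seq_len(2000), 1)
  epr <- epoch_and_baseline(ramp, 600, srate = srate)
  seg <- ramp[1, (600 - 48):(600 + 480)]
  expect_equal(epr$data[1, 1, ], seg - mean(seg[1:48]))
  # constant signal gives an all-zero epoch
  epc <- epoch_and_baseline(matrix(7, 1, 2000), 600, srate = srate)
  expect_true(all(epc$data == 0))
  # events at the record edge are dropped and logged
  epd <- epoch_and_baseline(cont, c(10, 900), srate = srate)
  expect_equal(dim(epd$data)[1], 1)
  expect_match(epd$provenance, "dropped 1")
})

test_that("baseline correction is idempotent", {
  set.seed(3)
  cont <- matrix(stats::rnorm(2 * 3000), 2)
  ep1 <- epoch_and_baseline(cont, c(500, 1500), srate = 480)
  # re-baseline the epoched data by epoching an identity reconstruction
  pre <- ep1$times_ms < 0
  again <- ep1$data
  for (tr in 1:2) for (s in 1:2)
    again[tr, s, ] <- again[tr, s, ] - mean(again[tr, s, pre])
  expect_equal(again, ep1$data)
})

test_that("robust averaging reproduces clean means and resists artifacts", {
  srate <- 480
  times <- seq(-100, 300, by = 1000 / srate)
  np <- length(times)
  wave <- sin(2 * pi * 5 * times / 1000)

  # identical trials: exact waveform, weights all 1
  arr <- array(rep(wave, each = 10 * 2), c(10, 2, np))
  ep <- new_epoch_set(arr, times, rep("a", 10))
  ev <- robust_average(ep, "a")
  expect_equal(ev$data[1, ], wave)
  expect_true(all(ev$weights == 1))

  # 50 clean Gaussian trials: close to the arithmetic mean
  set.seed(4)
  noise_sd <- 0.5
  arr <- array(0, c(50, 2, np))
  for (tr in 1:50) arr[tr, , ] <-
    rbind(wave, wave) + matrix(stats::rnorm(2 * np, 0, noise_sd), 2)
  ep <- new_epoch_set(arr, times, rep("a", 50))
  ev <- suppressWarnings(robust_average(ep, "a"))
  naive <- apply(arr, c(2, 3), mean)
  # bisquare weighting has ~95% Gaussian efficiency, so per cell the
  # robust mean deviates from the arithmetic mean by ~0.03 noise SD;
  # bound the max over all sensor-time cells at 5 such deviations and the
  # average much tighter
  expect_lt(max(abs(ev$data - naive)), 0.16 * noise_sd)
  expect_lt(mean(abs(ev$data - naive)), 0.04 * noise_sd)

  # one corrupted trial (10x amplitude artifact): robust mean beats naive
  arr2 <- arr
  arr2[50, , ] <- 10 * max(abs(wave)) *
    matrix(sin(2 * pi * 40 * times / 1000), 2, np, byrow = TRUE)
  ep2 <- new_epoch_set(arr2, times, rep("a", 50))
  ev2 <- suppressWarnings(robust_average(ep2, "a"))
  naive2 <- apply(arr2, c(2, 3), mean)
  clean_mean <- rbind(wave, wave)
  err_robust <- max(abs(ev2$data - clean_mean))
  err_naive <- max(abs(naive2 - clean_mean))
  expect_lt(err_robust, err_naive)
  expect_true(all(ev2$weights >= 0 & ev2$weights <= 1))
  expect_error(robust_average(ep, "missing"), ">= 2 trials")
})

test_that("global field power is the sensor sum of squares", {
  times <- 0:9
  ev <- new_evoked(matrix(1:10, 1), times)
  expect_equal(global_field_power(ev)$values, (1:10)^2)
  ev2 <- new_evoked(rbind(rep(3, 10), rep(4, 10)), times)
  expect_equal(global_field_power(ev2)$values, rep(25, 10))
  # doubling the data quadruples GFP
  ev3 <- ev2; ev3$data <- 2 * ev2$data
  expect_equal(global_field_power(ev3)$values,
               4 * global_field_power(ev2)$values)
  # invariant under sensor permutation and sign flips
  set.seed(6)
  m <- matrix(stats::rnorm(5 * 10), 5)
  g1 <- global_field_power(new_evoked(m, times))$values
  g2 <- global_field_power(new_evoked(m[sample(5), ] *
                                        sample(c(-1, 1), 5, TRUE),
                                      times))$values
  expect_equal(g1, g2)
})

test_that("peak finding returns the in-window maximum, earliest on ties", {
  times <- seq(0, 400, by = 2)
  bump <- function(mu, a = 1) a * exp(-(times - mu)^2 / (2 * 10^2))
  g <- new_gfp(bump(170), times)
  expect_equal(find_peak(g), 170)
  g2 <- new_gfp(bump(160) + bump(200, 1.5), times)
  expect_equal(find_peak(g2), 200)
  # a larger bump outside the window is ignored
  g3 <- new_gfp(bump(300, 5) + bump(180), times)
  expect_equal(find_peak(g3), 180)
  # tie breaks to the earliest sample
  g4 <- new_gfp(rep(1, length(times)), times)
  expect_equal(find_peak(g4), 140)
  expect_error(find_peak(g, c(500, 600)), "no samples")
})

test_that("pointwise t-test matches the textbook formula and finds injected effects", {
  set.seed(7)
  times <- seq(0, 300, by = 1000 / 480)
  np <- length(times)
  a <- matrix(stats::rnorm(8 * np), 8)
  b <- matrix(stats::rnorm(8 * np), 8)
  res <- pointwise_ttest(a, b, times_ms = times)
  # oracle: stats::t.test per sample
  for (j in seq(1, np, by = 17)) {
    tt <- stats::t.test(a[, j], b[, j], var.equal = TRUE)
    expect_equal(res$t[j], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(res$p[j], tt$p.value, tolerance = 1e-10)
  }
  resp <- pointwise_ttest(a, b, paired = TRUE)
  for (j in seq(1, np, by = 29)) {
    tt <- stats::t.test(a[, j], b[, j], paired = TRUE)
    expect_equal(resp$t[j], unname(tt$statistic), tolerance = 1e-10)
  }
  # identical groups: nothing significant
  r0 <- pointwise_ttest(a, a, paired = FALSE)
  expect_equal(nrow(r0$windows), 0)
  # large offset injected at 120-135 ms is detected as a window
  sel <- times >= 120 & times <= 135
  b2 <- b; b2[, sel] <- b2[, sel] + 5
  r1 <- pointwise_ttest(a, b2, times_ms = times)
  hit <- any(r1$windows$start_ms <= 135 & r1$windows$end_ms >= 120)
  expect_true(hit)
  expect_error(pointwise_ttest(a[1:3, ], b, paired = TRUE), "same subjects")
})
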