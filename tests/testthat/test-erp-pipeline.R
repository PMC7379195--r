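test_that("baseline correction zeroes the pre-stimulus mean and is idempotent", {
  rec <- tiny_rec()
  n_samp <- length(epoch_times(rec))
  data <- array(5, dim = c(3, 3, n_samp))
  ep <- manual_epochs(data, rec)
  bc <- baseline_correct(ep)
  expect_true(all(bc$data == 0))

  set.seed(1)
  ep2 <- manual_epochs(array(rnorm(3 * 3 * n_samp), dim = c(3, 3, n_samp)), rec)
  once <- baseline_correct(ep2)
  twice <- baseline_correct(once)
  expect_equal(once$data, twice$data, tolerance = 1e-12)
  # post-stimulus shape preserved up to a per-trial/channel constant
  shift <- ep2$data - once$data
  dev_from_const <- sweep(shift, c(1, 2), shift[, , 1])
  expect_true(all(abs(dev_from_const) < 1e-12))
})

test_that("amplitude ranges are exact and baseline-invariant", {
  rec <- tiny_rec()
  n_samp <- length(epoch_times(rec))
  t_ms <- epoch_times(rec)

  ep <- manual_epochs(array(2, dim = c(2, 3, n_samp)), rec)
  expect_equal(amplitude_ranges(ep)$range_uv, c(0, 0))

  a <- 3.7
  # 10 Hz at fs 200: extrema fall exactly on grid samples
  sine <- sin(2 * pi * 10 * t_ms / 1000) * a
  data <- array(rep(sine, each = 2 * 3), dim = c(2, 3, n_samp))
  ep_sine <- manual_epochs(data, rec)
  expect_equal(amplitude_ranges(ep_sine)$range_uv, rep(2 * a, 2),
               tolerance = 1e-6)

  set.seed(2)
  ep_r <- manual_epochs(array(rnorm(4 * 3 * n_samp), dim = c(4, 3, n_samp)), rec)
  expect_equal(amplitude_ranges(ep_r)$range_uv,
               amplitude_ranges(baseline_correct(ep_r))$range_uv,
               tolerance = 1e-12)
})

test_that("amplitude ranges match a brute-force loop", {
  rec <- tiny_rec()
  n_samp <- length(epoch_times(rec))
  set.seed(3)
  ep <- manual_epochs(array(rnorm(6 * 3 * n_samp), dim = c(6, 3, n_samp)), rec)
  got <- amplitude_ranges(ep)$range_uv
  want <- vapply(1:6, function(tr) {
    per_chan <- numeric(3)
    for (ch in 1:3) {
      vals <- c()
      for (s in seq_len(n_samp)) vals <- c(vals, ep$data[tr, ch, s])
      per_chan[ch] <- max(vals) - min(vals)
    }
    max(per_chan)
  }, numeric(1))
  expect_equal(got, want, tolerance = 1e-9)
})

test_that("artifact rejection keeps exactly the sub-cutoff trials", {
  rec <- tiny_rec()
  n_samp <- length(epoch_times(rec))
  set.seed(4)
  data <- array(rnorm(100 * 3 * n_samp, sd = 5), dim = c(100, 3, n_samp))
  bad <- c(7, 23, 51, 77, 94)
  data[bad, 1, 10] <- 500
  ep <- manual_epochs(data, rec)

  res <- reject_artifacts(ep, rejection_policy("percentile", percentile = 0.95))
  rng <- amplitude_ranges(ep)$range_uv
  expect_true(all(!res$kept[bad]))
  expect_identical(res$kept, rng <= res$log$cutoff_uv)
  expect_equal(res$log$retention, res$log$n_kept / res$log$n_total)

  all_kept <- reject_artifacts(
    manual_epochs(array(rnorm(10 * 3 * n_samp), dim = c(10, 3, n_samp)), rec),
    rejection_policy("fixed_uv", threshold_uv = 200)
  )
  expect_equal(all_kept$log$n_kept, 10L)
})

test_that("averaging honours selectors, excludes warm-ups, and is linear", {
  rec <- tiny_rec()
  n_samp <- length(epoch_times(rec))
  set.seed(5)
  wave <- rnorm(3 * n_samp)
  one <- array(rep(wave, each = 1), dim = c(1, 3, n_samp))
  data <- array(0, dim = c(4, 3, n_samp))
  for (i in 1:3) data[i, , ] <- one[1, , ]
  data[4, , ] <- 1e6 # warm-up trial must never contribute
  ep <- manual_epochs(data, rec, roles = c("standard", "standard",
                                           "standard", "warmup"))
  avg <- average_erp(ep, role == "standard")
  expect_equal(avg$n_trials, 3L)
  expect_equal(as.numeric(avg$data), as.numeric(one[1, , ]), tolerance = 1e-12)
  avg_all <- average_erp(ep)
  expect_equal(avg_all$n_trials, 3L) # warm-up excluded even without selector
  expect_error(average_erp(ep, role == "deviant"), "no analyzed trials")
})

test_that("grand average equals the trial-weighted subject combination", {
  rec <- tiny_rec()
  n_samp <- length(epoch_times(rec))
  set.seed(6)
  d1 <- array(rnorm(2 * 3 * n_samp), dim = c(2, 3, n_samp))
  d2 <- array(rnorm(6 * 3 * n_samp), dim = c(6, 3, n_samp))
  e1 <- average_erp(manual_epochs(d1, rec))
  e2 <- average_erp(manual_epochs(d2, rec))
  ga <- grand_average(list(e1, e2))
  all_data <- array(0, dim = c(8, 3, n_samp))
  all_data[1:2, , ] <- d1
  all_data[3:8, , ] <- d2
  expect_equal(ga$data, average_erp(manual_epochs(all_data, rec))$data,
               tolerance = 1e-12)
  expect_equal(ga$n_trials, 8L)
})

test_that("the 30-Hz zero-phase filter has the expected frequency response", {
  fs <- 512
  t_s <- seq(0, 2, by = 1 / fs)
  slow <- sin(2 * pi * 5 * t_s)
  fast <- sin(2 * pi * 100 * t_s)
  erp <- manual_erp(rbind(slow, fast, 1), fs_hz = fs,
                    window_ms = c(0, 2000), channels = c("a", "b", "c"))
  filt <- lowpass_erp(erp, 30)
  core <- seq(fs / 4, length(t_s) - fs / 4) # avoid edge transients
  expect_gt(max(abs(filt$data[1, core])), 0.99)
  expect_lt(max(abs(filt$data[2, core])), 0.10)
  expect_equal(filt$data[3, core], rep(1, length(core)), tolerance = 1e-6)
})

test_that("peak finding hits a Gaussian trough and flags edges and ties", {
  fs <- 512
  rec <- tiny_rec(fs_hz = fs, channels = "Fz")
  t_ms <- epoch_times(rec)
  g <- -exp(-(t_ms - 93)^2 / (2 * 16^2))
  erp <- manual_erp(matrix(g, 1), fs_hz = fs, channels = "Fz")
  pk <- find_peak(erp, "negative", c(50, 150), channels = "Fz")
  expect_lt(abs(pk$latency_ms - 93), 1000 / fs + 1e-9)
  expect_false(pk$at_edge)

  # exact tie at two grid samples: the earlier one wins
  two <- rep(0, length(t_ms))
  i120 <- which.min(abs(t_ms - 120))
  i160 <- which.min(abs(t_ms - 160))
  two[c(i120, i160)] <- -1
  erp2 <- manual_erp(matrix(two, 1), fs_hz = fs, channels = "Fz")
  pk2 <- find_peak(erp2, "negative", c(100, 180), channels = "Fz",
                   lowpass_hz = NULL)
  expect_equal(pk2$latency_ms, t_ms[i120])

  ramp <- manual_erp(matrix(-t_ms, 1), fs_hz = fs, channels = "Fz")
  pk3 <- find_peak(ramp, "negative", c(50, 150), channels = "Fz",
                   lowpass_hz = NULL)
  expect_true(pk3$at_edge)
})

test_that("window means match a brute-force loop and basic identities", {
  rec <- tiny_rec()
  n_samp <- length(epoch_times(rec))
  t_ms <- epoch_times(rec)

  const <- manual_erp(matrix(2, 3, n_samp), fs_hz = rec$fs_hz,
                      channels = c("Fz", "FCz", "Cz"))
  w <- component_window("N1", 93, 15)
  expect_equal(window_mean(const, w), 2)

  anti <- manual_erp(matrix(rep(t_ms - 100, each = 3), 3), fs_hz = rec$fs_hz,
                     channels = c("Fz", "FCz", "Cz"))
  w100 <- component_window("X", 100, 25)
  expect_equal(window_mean(anti, w100), 0, tolerance = 1e-9)

  set.seed(7)
  r <- manual_erp(matrix(rnorm(3 * n_samp), 3), fs_hz = rec$fs_hz,
                  channels = c("Fz", "FCz", "Cz"))
  got <- window_mean(r, w)
  idx <- which(t_ms >= 78 & t_ms <= 108)
  vals <- c()
  for (ch in 1:3) for (i in idx) vals <- c(vals, r$data[ch, i])
  expect_equal(got, mean(vals), tolerance = 1e-9)

  expect_error(window_mean(r, component_window("X", 390, 25)), "beyond")
})

test_that("difference waves obey subtraction algebra", {
  rec <- tiny_rec()
  n_samp <- length(epoch_times(rec))
  set.seed(8)
  mk <- function() manual_erp(matrix(rnorm(3 * n_samp), 3),
                              fs_hz = rec$fs_hz,
                              channels = c("Fz", "FCz", "Cz"))
  a <- mk(); b <- mk(); c_ <- mk()
  expect_true(all(difference_wave(a, a)$data == 0))
  ab_bc <- difference_wave(a, b)$data + difference_wave(b, c_)$data
  expect_equal(ab_bc, difference_wave(a, c_)$data, tolerance = 1e-12)
  w <- component_window("N1", 93, 15)
  expect_equal(window_mean(difference_wave(a, b), w),
               window_mean(a, w) - window_mean(b, w), tolerance = 1e-12)
  other <- manual_erp(matrix(0, 3, n_samp), fs_hz = rec$fs_hz + 1,
                      channels = c("Fz", "FCz", "Cz"))
  expect_error(difference_wave(a, other), "grids")
})

test_that("exclusion rules flag behavior, retention, and absent N1", {
  base <- tibble::tibble(
    subject_id = sprintf("s%02d", 1:6),
    max_count_error = c(3, 3, 3, 3, 3, 3),
    min_retention = c(1, 1, 0.65, 1, 1, 1),
    n1_depth_uv = c(-2, -2, -2, -2, -2, 0.5),
    baseline_noise_sd = 0.2
  )
  rep1 <- apply_exclusions(base)
  expect_false(any(rep1$behavior_outlier)) # zero SD, strict inequality
  expect_identical(which(rep1$low_retention), 3L)
  expect_identical(which(rep1$no_n1), 6L)
  expect_identical(which(rep1$excluded), c(3L, 6L))

  outlier <- dplyr::mutate(base, max_count_error = c(2, 2, 2, 2, 2, 12))
  rep2 <- apply_exclusions(outlier)
  expect_identical(which(rep2$behavior_outlier), 6L)
})

test_that("an N1-free subject is caught by the automated proxy", {
  spec <- seq_spec(n_trials = 48)
  rec <- tiny_rec()
  set.seed(9)
  seqs <- list(oddball = make_oddball_sequence(spec))
  no_n1 <- simulate_subject(seqs, rec,
                            adapt = adaptation_params(base_n1_uv = 0),
                            noise = noise_spec(sd_uv = 1, model = "white"))
  with_n1 <- simulate_subject(seqs, rec,
                              noise = noise_spec(sd_uv = 1, model = "white"))
  w <- component_window("N1", 93, 15)
  d0 <- n1_diagnostics(average_erp(baseline_correct(no_n1$oddball),
                                   role == "standard"), w)
  d1 <- n1_diagnostics(average_erp(baseline_correct(with_n1$oddball),
                                   role == "standard"), w)
  expect_gt(d0$n1_depth_uv, -2 * d0$baseline_noise_sd) # flagged
  expect_lt(d1$n1_depth_uv, -2 * d1$baseline_noise_sd) # retained
})

test_that("condition summaries satisfy the contrast algebra", {
  set.seed(10)
  amps <- tidyr::expand_grid(
    subject_id = sprintf("s%02d", 1:8),
    window = c("N1", "MMN"),
    condition = c("standard", "deviant", "cascade", "norep")
  )
  amps$mean_uv <- rnorm(nrow(amps))
  s <- condition_summaries(amps)
  sc <- s$subject_contrasts
  expect_equal(sc$mmn_norep_minus_cascade,
               sc$norep_corrected_mmn - sc$cascade_corrected_mmn,
               tolerance = 1e-12)
  expect_equal(sc$oddball_vs_norep_mmn,
               sc$oddball_mmn - sc$norep_corrected_mmn, tolerance = 1e-12)
  # the critical contrast equals cascade minus norep directly
  wide <- tidyr::pivot_wider(amps, names_from = c(window, condition),
                             values_from = mean_uv)
  expect_equal(sc$mmn_norep_minus_cascade,
               wide$MMN_cascade - wide$MMN_norep, tolerance = 1e-12)
  # CI uses the t critical value with df = n - 1
  row <- s$contrasts[s$contrasts$contrast == "oddball_mmn", ]
  expect_equal(row$ci_high - row$mean_uv,
               qt(0.975, 7) * row$sd_uv / sqrt(8), tolerance = 1e-12)
})

test_that("scaling all epochs scales every window mean and contrast", {
  spec <- seq_spec(n_trials = 48)
  rec <- tiny_rec()
  eps <- noise_free_subject(spec, rec)
  erps <- role_erps(eps)
  w <- component_window("MMN", 140, 25)
  scaled <- lapply(eps, function(e) { e$data <- 3 * e$data; e })
  erps3 <- role_erps(scaled)
  for (nm in names(erps)) {
    expect_equal(window_mean(erps3[[nm]], w), 3 * window_mean(erps[[nm]], w),
                 tolerance = 1e-12)
  }
})
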