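test_that("adaptation gain honours its boundary cases", {
  p <- adaptation_params()
  expect_equal(adaptation_gain(500, numeric(0), p), 1)
  # identical-frequency history saturates the score regardless of tau
  p_inf <- adaptation_params(recency_tau_trials = 1e6)
  expect_equal(adaptation_gain(500, rep(500, 10), p_inf), 1 - p_inf$strength)
  expect_equal(adaptation_score(500, rep(500, 3), p), 1)
})

test_that("adaptation decreases with tonotopic distance and recency", {
  p <- adaptation_params()
  near <- adaptation_gain(500, c(550, 550), p)
  far <- adaptation_gain(500, c(732, 732), p)
  expect_lt(near, far)
  recent <- adaptation_gain(500, c(500, 732, 732), p)
  stale <- adaptation_gain(500, c(732, 732, 500), p)
  expect_lt(recent, stale)
})

test_that("vectorized scores match the per-event definition", {
  set.seed(10)
  s <- make_norep_sequence(seq_spec(n_trials = 40))
  p <- adaptation_params()
  vec <- adaptation_scores(s, p)
  loop <- vapply(seq_len(nrow(s)), function(i) {
    hist <- rev(s$frequency_hz[max(1, i - p$history_len):(i - 1)])
    if (i == 1) hist <- numeric(0)
    adaptation_score(s$frequency_hz[i], hist, p)
  }, numeric(1))
  expect_equal(vec, loop, tolerance = 1e-12)
})

test_that("without adaptation or MMN, all 500-Hz tones are equivalent", {
  comps <- default_components(mmn_uv = 0, rep_pos_slope_uv = 0)
  adapt <- adaptation_params(strength = 0)
  rec <- tiny_rec()
  eps <- noise_free_subject(seq_spec(n_trials = 48), rec, comps, adapt)
  erps <- role_erps(eps)
  w <- component_window("N1", 93, 15)
  m <- vapply(erps[c("deviant", "cascade", "norep")], window_mean,
              numeric(1), window = w)
  expect_equal(unname(diff(range(m))), 0, tolerance = 1e-10)
})

test_that("calibrated noise-free simulation reproduces reference window means", {
  eps <- noise_free_subject()
  erps <- role_erps(eps)
  wn1 <- component_window("N1", 93, 15)
  wmmn <- component_window("MMN", 140, 25)
  n1 <- vapply(erps, window_mean, numeric(1), window = wn1)
  mmn <- vapply(erps, window_mean, numeric(1), window = wmmn)
  ref_n1 <- c(standard = 0.66, deviant = -0.55, cascade = -0.58,
              norep = -0.72)
  ref_mmn <- c(standard = 1.91, deviant = -0.76, cascade = 0.74,
               norep = 0.76)
  expect_true(all(abs(n1 - ref_n1) < 0.15))
  expect_true(all(abs(mmn - ref_mmn) < 0.15))
})

test_that("the deviant N1 is less negative than the norep control N1", {
  eps <- noise_free_subject()
  erps <- role_erps(eps)
  w <- component_window("N1", 93, 15)
  expect_gt(window_mean(erps$deviant, w), window_mean(erps$norep, w))
})

test_that("the MMN reverses polarity at mastoid-proxy channels", {
  eps <- noise_free_subject()
  diffw <- difference_wave(average_erp(eps$oddball, role == "deviant"),
                           average_erp(eps$oddball, role == "standard"))
  w_fc <- component_window("MMN", 140, 25, channels = c("Fz", "FCz", "Cz"))
  w_m <- component_window("MMN", 140, 25, channels = c("M1p", "M2p"))
  fc <- window_mean(diffw, w_fc)
  m <- window_mean(diffw, w_m)
  expect_lt(fc, 0)
  expect_gt(m, 0)
})

test_that("doubling component amplitudes doubles window means", {
  spec <- seq_spec(n_trials = 48)
  rec <- tiny_rec()
  set.seed(5)
  seqs <- list(oddball = make_oddball_sequence(spec))
  e1 <- simulate_subject(seqs, rec, noise = noise_spec(sd_uv = 0),
                         amp_scale = 1)
  e2 <- simulate_subject(seqs, rec, noise = noise_spec(sd_uv = 0),
                         amp_scale = 2)
  a1 <- average_erp(baseline_correct(e1$oddball), role == "deviant")
  a2 <- average_erp(baseline_correct(e2$oddball), role == "deviant")
  w <- component_window("MMN", 140, 25)
  expect_equal(window_mean(a2, w), 2 * window_mean(a1, w), tolerance = 1e-12)
})

test_that("simulation is bit-identical under a fixed seed", {
  spec <- seq_spec(n_trials = 16)
  rec <- tiny_rec(fs_hz = 128)
  seqs <- list(cascade = make_cascade_sequence(spec))
  a <- simulate_subject(seqs, rec, noise = noise_spec(sd_uv = 2), seed = 123)
  b <- simulate_subject(seqs, rec, noise = noise_spec(sd_uv = 2), seed = 123)
  expect_identical(a, b)
})

test_that("a multi-subject study is reproducible and collapses without variability", {
  spec <- seq_spec(n_trials = 16)
  rec <- tiny_rec(fs_hz = 128)
  a <- simulate_study(3, spec, rec, noise = noise_spec(sd_uv = 1),
                      seed = 11)
  b <- simulate_study(3, spec, rec, noise = noise_spec(sd_uv = 1),
                      seed = 11)
  expect_identical(a, b)
  expect_equal(length(a$subjects), 3)

  z <- simulate_study(2, spec, rec, noise = noise_spec(sd_uv = 0),
                      between_subject_sd = 0, behavior_sd = 0, seed = 12)
  # identical component amplitudes; only the sequences differ by draw,
  # so regenerate with a shared sequence set for strict equality
  seqs <- list(cascade = make_cascade_sequence(spec))
  s1 <- simulate_subject(seqs, rec, noise = noise_spec(sd_uv = 0),
                         amp_scale = z$subjects[[1]]$amp_scale)
  s2 <- simulate_subject(seqs, rec, noise = noise_spec(sd_uv = 0),
                         amp_scale = z$subjects[[2]]$amp_scale)
  expect_identical(s1$cascade$data, s2$cascade$data)
})

test_that("AR(1) noise has the requested marginal SD and autocorrelation", {
  set.seed(6)
  spec <- seq_spec(n_trials = 64)
  rec <- tiny_rec(fs_hz = 256, channels = "Fz")
  seqs <- list(cascade = make_cascade_sequence(spec))
  comps <- default_components(mmn_uv = 0, rep_pos_base_uv = 0,
                              rep_pos_slope_uv = 0)
  adapt <- adaptation_params(base_n1_uv = 0)
  ep <- simulate_subject(seqs, rec, comps, adapt,
                         noise_spec(sd_uv = 5, ar1_rho = 0.9))$cascade
  x <- as.numeric(ep$data)
  expect_equal(sd(x), 5, tolerance = 0.05)
  m <- ep$data[, 1, ]
  r <- cor(as.numeric(m[, -1]), as.numeric(m[, -ncol(m)]))
  expect_equal(r, 0.9, tolerance = 0.02)
})
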