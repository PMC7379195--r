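#!/usr/bin/env Rscript
# Calibration of the synthetic-EEG defaults.
#
# Solves the component amplitudes (N1 base amplitude and adaptation
# strength, repetition-positivity base and slope, MMN amplitude) so that
# a noise-free simulation of the full design reproduces the reference
# frontocentral window means:
#   N1 window  (78-108 ms): 0.66, -0.55, -0.58, -0.72 µV
#   MMN window (115-165 ms): 1.91, -0.76, 0.74, 0.76 µV
# for standard / deviant / cascade / no-repetition tones, and tunes the
# trial-noise SD of the scaled recovery configuration so the
# across-subject SE of the cascade-vs-norep MMN contrast matches the
# order of the reference CIs (SE ~ 0.34 µV).
#
# The window means are linear in (P0, P1, B0, B1, M):
#   value(window w, condition c) =
#     P0*cp_w + P1*R_c*cp_w + B0*cn_w + B1*S_c*cn_w + M*dev_c*cm_w
# where S_c is the mean tonotopic adaptation score of the condition's
# analyzed tones, R_c the mean exact-repetition score, and cp/cn/cm the
# mean of each temporal profile over the window. The N1/recency kernel
# shape (tau, sigma) is grid-searched; amplitudes are solved by least
# squares at each grid point.
#
# Run from the repository root:  Rscript scripts/calibrate.R

library(mmncontrol)

targets <- data.frame(
  window = rep(c("N1", "MMN"), each = 4),
  condition = rep(c("standard", "deviant", "cascade", "norep"), 2),
  uv = c(0.66, -0.55, -0.58, -0.72, 1.91, -0.76, 0.74, 0.76)
)

spec <- seq_spec()
set.seed(20180924)
n_blocks <- 20
blocks <- list(
  oddball = replicate(n_blocks, make_oddball_sequence(spec), simplify = FALSE),
  cascade = replicate(n_blocks, make_cascade_sequence(spec), simplify = FALSE),
  norep = replicate(n_blocks, make_norep_sequence(spec), simplify = FALSE)
)

mean_scores <- function(params) {
  out <- c(standard = NA, deviant = NA, cascade = NA, norep = NA)
  pool <- function(cond, role) {
    mean(unlist(lapply(blocks[[cond]], function(b) {
      s <- adaptation_scores(b, params)
      s[!b$is_warmup & b$role == role]
    })))
  }
  out["standard"] <- pool("oddball", "standard")
  out["deviant"] <- pool("oddball", "deviant")
  out["cascade"] <- pool("cascade", "control")
  out["norep"] <- pool("norep", "control")
  out
}

# profile window factors on the 1024-Hz grid
rec <- recording_spec()
t_ms <- epoch_times(rec)
win_factor <- function(comp, lo, hi) {
  p <- mmncontrol:::component_profile(comp, t_ms)
  mean(p[t_ms >= lo & t_ms <= hi])
}
n1_c <- component_spec("N1", "gaussian", 93, 16, -1)
mmn_c <- component_spec("MMN", "gaussian", 140, 15, -1)
pos_c <- component_spec("pos", "plateau", 30, 50, 1)
cp <- c(N1 = win_factor(pos_c, 78, 108), MMN = win_factor(pos_c, 115, 165))
cn <- c(N1 = win_factor(n1_c, 78, 108), MMN = win_factor(n1_c, 115, 165))
cm <- c(N1 = win_factor(mmn_c, 78, 108), MMN = win_factor(mmn_c, 115, 165))
cat("window factors:\n")
print(rbind(pos = cp, n1 = cn, mmn = cm))

# exact-repetition score: narrow kernel, slow decay (fixed shape)
rep_params <- adaptation_params(0, 0, tonotopic_sd_oct = 0.02,
                                recency_tau_trials = 8, history_len = 16)
R <- mean_scores(rep_params)
cat("\nrepetition scores R:\n"); print(round(R, 4))

solve_amps <- function(S) {
  X <- t(vapply(seq_len(nrow(targets)), function(i) {
    w <- targets$window[i]; cnd <- targets$condition[i]
    c(P0 = cp[[w]], P1 = R[[cnd]] * cp[[w]], B0 = cn[[w]],
      B1 = S[[cnd]] * cn[[w]], M = (cnd == "deviant") * cm[[w]])
  }, numeric(5)))
  fit <- lm.fit(X, targets$uv)
  list(coef = fit$coefficients, rss = sum(fit$residuals^2),
       resid = fit$residuals)
}

grid <- expand.grid(tau = seq(0.4, 1.2, by = 0.1),
                    sigma = seq(0.10, 0.25, by = 0.025))
best <- NULL
for (i in seq_len(nrow(grid))) {
  p <- adaptation_params(0, 0, tonotopic_sd_oct = grid$sigma[i],
                         recency_tau_trials = grid$tau[i], history_len = 10)
  S <- mean_scores(p)
  sol <- solve_amps(S)
  k <- -sol$coef["B1"] / sol$coef["B0"]
  ok <- is.finite(k) && k > 0 && k <= 1 && sol$coef["B0"] < 0
  if (ok && (is.null(best) || sol$rss < best$rss)) {
    best <- c(sol, list(tau = grid$tau[i], sigma = grid$sigma[i],
                        S = S, k = k))
  }
}

cat(sprintf("\nbest kernel: tau = %.2f trials, sigma = %.3f oct, RSS = %.5f\n",
            best$tau, best$sigma, best$rss))
cat("adaptation scores S:\n"); print(round(best$S, 4))
co <- best$coef
cat(sprintf(
  "\ncalibrated amplitudes:\n  base_n1_uv = %.3f\n  strength = %.3f\n  rep_pos_base_uv = %.3f\n  rep_pos_slope_uv = %.3f\n  mmn_uv = %.3f\n",
  co["B0"], best$k, co["P0"], co["P1"], co["M"]
))
cat("residuals (µV):\n")
print(cbind(targets, resid = round(best$resid, 4)))

# ---- verification: noise-free simulation with the solved defaults ----
adapt <- adaptation_params(base_n1_uv = co[["B0"]], strength = best$k,
                           tonotopic_sd_oct = best$sigma,
                           recency_tau_trials = best$tau, history_len = 10)
comps <- default_components(mmn_uv = co[["M"]],
                            rep_pos_base_uv = co[["P0"]],
                            rep_pos_slope_uv = co[["P1"]])
comps[[3]]$mod_params <- rep_params
comps[[1]] <- component_spec("N1", "gaussian", 93, 16, NA_real_,
                             mastoid_gain = -0.5,
                             modulation = "adaptation_gain")

set.seed(1)
seqs <- list(oddball = make_oddball_sequence(spec),
             cascade = make_cascade_sequence(spec),
             norep = make_norep_sequence(spec))
eps <- simulate_subject(seqs, rec, comps, adapt, noise_spec(sd_uv = 0))
eps <- lapply(eps, baseline_correct)
erps <- list(
  standard = average_erp(eps$oddball, role == "standard"),
  deviant = average_erp(eps$oddball, role == "deviant"),
  cascade = average_erp(eps$cascade, role == "control"),
  norep = average_erp(eps$norep, role == "control")
)
wn1 <- component_window("N1", 93, 15)
wmmn <- component_window("MMN", 140, 25)
sim <- data.frame(
  window = rep(c("N1", "MMN"), each = 4),
  condition = rep(names(erps), 2),
  sim_uv = c(vapply(erps, window_mean, numeric(1), window = wn1),
             vapply(erps, window_mean, numeric(1), window = wmmn))
)
cat("\nnoise-free verification (one simulated block set):\n")
print(merge(targets, sim, sort = FALSE))

# ---- noise SD for the recovery configuration ----
# target: across-subject SE of the cascade-vs-norep MMN contrast ~ 0.342 µV
# (the reference CI half-width 0.705 / t(.975, 25)), at 26 subjects and
# 12 control trials per condition block.
cal_se <- function(sd_uv, n_rep = 6) {
  ses <- vapply(seq_len(n_rep), function(r) {
    cfg <- recovery_config(seed = 5000 + r)
    cfg$noise$sd_uv <- sd_uv
    res <- run_synthetic_study(cfg)
    row <- res$summary$contrasts
    row$se_uv[row$contrast == "mmn_norep_minus_cascade"]
  }, numeric(1))
  mean(ses)
}
for (sd_try in c(8, 10, 12)) {
  cat(sprintf("recovery noise sd %.1f -> mean contrast SE %.3f\n",
              sd_try, cal_se(sd_try)))
}
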