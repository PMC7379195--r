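#' Configuration of a synthetic study run
#'
#' A plain, JSON-serializable description of everything a synthetic
#' study needs: design (subjects, sequence block), recording, component
#' amplitudes, adaptation, noise, artifact rejection, exclusion rules,
#' and the programmed condition effect used by parameter-recovery runs.
#' Defaults mirror the full reference design (26 subjects, 360-trial
#' blocks at 1024 Hz) with the calibrated component set.
#'
#' `mmn_contrast_uv` programs a true cascade-vs-norepetition difference
#' in the MMN window: a slow plateau component of that amplitude is
#' added to cascade control trials, so a positive value makes the
#' cascade control more positive, i.e. the cascade-corrected MMN more
#' negative than the no-repetition-corrected MMN.
#'
#' @param n_subjects Number of simulated subjects.
#' @param sequence Named list of [seq_spec()] arguments.
#' @param recording Named list of [recording_spec()] arguments.
#' @param components Named list of [default_components()] arguments.
#' @param adaptation Named list of [adaptation_params()] arguments.
#' @param noise Named list of [noise_spec()] arguments.
#' @param rejection Named list of [rejection_policy()] arguments.
#' @param exclusion Named list: `behavior_sd_mult`, `min_retention`,
#'   `n1_z` (see [apply_exclusions()]).
#' @param behavior Named list: `mean`, `sd` of the per-subject maximum
#'   plus-count error.
#' @param between_subject_sd SD of the per-subject amplitude scale.
#' @param mmn_contrast_uv Programmed cascade-vs-norep MMN-window effect.
#' @param shared_sequences When `TRUE`, one sequence set is drawn and
#'   reused for every subject (useful for fully deterministic runs);
#'   by default each subject gets fresh block randomizations.
#' @param seed Integer seed for the whole run.
#' @return A list of class `"study_config"`.
#' @export
study_config <- function(n_subjects = 26,
                         sequence = list(),
                         recording = list(),
                         components = list(),
                         adaptation = list(),
                         noise = list(),
                         rejection = list(),
                         exclusion = list(behavior_sd_mult = 2,
                                          min_retention = 0.70, n1_z = 2),
                         behavior = list(mean = 5.05, sd = 1.04),
                         between_subject_sd = 0.15,
                         mmn_contrast_uv = 0,
                         shared_sequences = FALSE,
                         seed = 1L) {
  cfg <- list(
    n_subjects = as.integer(n_subjects),
    sequence = sequence, recording = recording, components = components,
    adaptation = adaptation, noise = noise, rejection = rejection,
    exclusion = exclusion, behavior = behavior,
    between_subject_sd = between_subject_sd,
    mmn_contrast_uv = mmn_contrast_uv,
    shared_sequences = isTRUE(shared_sequences),
    seed = as.integer(seed)
  )
  # validate by instantiating every block
  invisible(config_objects(cfg))
  structure(cfg, class = "study_config")
}

#' Scaled-down configuration for simulation studies
#'
#' Same generative model as the default configuration, but with block
#' length, sampling rate, and channel count reduced so that replicated
#' runs (parameter recovery, operating characteristics) are cheap. The
#' noise SD is calibrated for this design so that the across-subject SE
#' of the cascade-vs-norep contrasts matches the order of the reference
#' study's printed CIs.
#'
#' @inheritParams study_config
#' @param ... Overrides passed to [study_config()].
#' @export
recovery_config <- function(mmn_contrast_uv = 0, seed = 1L, ...) {
  study_config(
    sequence = list(n_trials = 96),
    recording = list(fs_hz = 160, channels = c("Fz", "FCz", "Cz"),
                     mastoid_channels = character(0)),
    noise = list(sd_uv = 6.7),
    mmn_contrast_uv = mmn_contrast_uv,
    seed = seed,
    ...
  )
}

config_objects <- function(cfg) {
  comps <- do.call(default_components, cfg$components)
  if (cfg$mmn_contrast_uv != 0) {
    # MMN-shaped pulse on cascade controls; peak amplitude normalized by
    # the pulse's nominal MMN-window factor so the programmed value is
    # (approximately) the induced window-mean contrast
    eff <- component_spec(
      "programmed_effect", "gaussian", center_ms = 140, width_ms = 15,
      amp_uv = 1, mastoid_gain = -0.5,
      roles = "control", conditions = "cascade"
    )
    rec_tmp <- do.call(recording_spec, cfg$recording)
    t_ms <- epoch_times(rec_tmp)
    fac <- mean(component_profile(eff, t_ms)[t_ms >= 115 & t_ms <= 165])
    eff$amp_uv <- cfg$mmn_contrast_uv / fac
    comps <- c(comps, list(eff))
  }
  list(
    spec = do.call(seq_spec, cfg$sequence),
    rec = do.call(recording_spec, cfg$recording),
    components = comps,
    adapt = do.call(adaptation_params, cfg$adaptation),
    noise = do.call(noise_spec, cfg$noise),
    policy = do.call(rejection_policy, cfg$rejection)
  )
}

#' Read/write a study configuration as JSON
#'
#' The configuration round-trips losslessly (it contains only scalars
#' and atomic vectors).
#'
#' @param config A [study_config()].
#' @param path File path.
#' @export
write_study_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(config)
}

#' @rdname write_study_config
#' @export
read_study_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$exclusion <- as.list(raw$exclusion)
  raw$behavior <- as.list(raw$behavior)
  for (nm in c("sequence", "recording", "components", "adaptation",
               "noise", "rejection")) {
    raw[[nm]] <- as.list(raw[[nm]])
  }
  # empty JSON arrays come back as lists; restore character vectors
  for (nm in c("channels", "mastoid_channels")) {
    if (!is.null(raw$recording[[nm]])) {
      raw$recording[[nm]] <- as.character(unlist(raw$recording[[nm]]))
    }
  }
  do.call(study_config, raw)
}

# Per-subject ERP extraction: baseline correction, artifact rejection,
# and the four primary-analysis averages, keeping only small objects.
process_subject <- function(epochs, policy) {
  erps <- list()
  retention <- c()
  logs <- list()
  for (cond in names(epochs)) {
    ep <- baseline_correct(epochs[[cond]])
    rej <- reject_artifacts(ep, policy)
    logs[[cond]] <- rej$log
    roles <- if (cond == "oddball") c("standard", "deviant") else "control"
    for (ro in roles) {
      key <- if (cond == "oddball") ro else cond
      erps[[key]] <- average_erp(rej$epochs, .data$role == !!ro)
      ev <- epochs[[cond]]$events
      analyzed <- !ev$is_warmup & ev$role == ro
      retention[key] <- sum(rej$kept & analyzed) / sum(analyzed)
    }
  }
  list(erps = erps, retention = retention,
       rejection_log = dplyr::bind_rows(logs))
}

subject_amplitudes <- function(erps, windows) {
  conds <- c("standard", "deviant", "cascade", "norep")
  conds <- conds[conds %in% names(erps)]
  purrr::map_dfr(conds, function(cn) {
    tibble::tibble(
      condition = cn,
      window = c("N1", "MMN"),
      mean_uv = c(window_mean(erps[[cn]], windows$n1),
                  window_mean(erps[[cn]], windows$mmn))
    )
  })
}

#' Condition summaries and contrasts with confidence intervals
#'
#' Takes per-subject window means (long format: `subject_id`, `window`,
#' `condition`, `mean_uv`) and produces the derived contrasts per
#' subject plus group-level means with t-based 95% CIs:
#' * `oddball_mmn`: deviant - standard (MMN window);
#' * `cascade_corrected_mmn`: deviant - cascade;
#' * `norep_corrected_mmn`: deviant - norep;
#' * `mmn_norep_minus_cascade`: (deviant - norep) - (deviant - cascade),
#'   the critical condition contrast (equal to cascade - norep);
#' * `oddball_vs_norep_mmn`: oddball MMN - norep-corrected MMN;
#' * `n1_cascade_minus_norep`: cascade - norep (N1 window).
#'
#' @param amplitudes Long tibble of per-subject window means.
#' @param ci_level Confidence level.
#' @return A list of class `"amplitude_summary"` with tibbles
#'   `amplitudes` (input), `condition_means`, `subject_contrasts`, and
#'   `contrasts` (group means, SE, CI, n).
#' @export
condition_summaries <- function(amplitudes, ci_level = 0.95) {
  wide <- amplitudes |>
    tidyr::pivot_wider(names_from = c("window", "condition"),
                       values_from = "mean_uv")
  sc <- wide |>
    dplyr::transmute(
      .data$subject_id,
      oddball_mmn = .data$MMN_deviant - .data$MMN_standard,
      cascade_corrected_mmn = .data$MMN_deviant - .data$MMN_cascade,
      norep_corrected_mmn = .data$MMN_deviant - .data$MMN_norep,
      mmn_norep_minus_cascade = .data$norep_corrected_mmn -
        .data$cascade_corrected_mmn,
      oddball_vs_norep_mmn = .data$oddball_mmn - .data$norep_corrected_mmn,
      n1_cascade_minus_norep = .data$N1_cascade - .data$N1_norep,
      n1_deviant_minus_norep = .data$N1_deviant - .data$N1_norep,
      n1_standard_minus_norep = .data$N1_standard - .data$N1_norep
    )
  long <- tidyr::pivot_longer(sc, -"subject_id", names_to = "contrast",
                              values_to = "value_uv")
  contrasts <- long |>
    dplyr::group_by(.data$contrast) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_uv = mean(.data$value_uv),
      sd_uv = stats::sd(.data$value_uv),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      se_uv = .data$sd_uv / sqrt(.data$n),
      ci_low = .data$mean_uv - stats::qt(1 - (1 - ci_level) / 2,
                                         .data$n - 1) * .data$se_uv,
      ci_high = .data$mean_uv + stats::qt(1 - (1 - ci_level) / 2,
                                          .data$n - 1) * .data$se_uv
    )
  condition_means <- amplitudes |>
    dplyr::group_by(.data$window, .data$condition) |>
    dplyr::summarise(mean_uv = mean(.data$mean_uv), .groups = "drop")
  structure(
    list(amplitudes = amplitudes, condition_means = condition_means,
         subject_contrasts = sc, contrasts = contrasts),
    class = "amplitude_summary"
  )
}

#' @export
print.amplitude_summary <- function(x, ...) {
  cat("<amplitude_summary>\n")
  print(x$condition_means)
  print(x$contrasts)
  invisible(x)
}

summary_effect <- function(summary, contrast) {
  row <- summary$contrasts[summary$contrasts$contrast == contrast, ]
  if (nrow(row) != 1) stop("unknown contrast: ", contrast, call. = FALSE)
  row
}

#' Run a full synthetic study end to end
#'
#' Simulates `n_subjects` subjects (sequences, epochs), applies the ERP
#' pipeline (baseline correction, artifact rejection, per-subject
#' averages), derives the N1 and MMN windows from oddball data only,
#' applies the exclusion rules, summarises condition amplitudes and
#' contrasts, and runs the Bayesian hypothesis tests with priors
#' constructed from the run's own observed quantities: the MMN
#' alternative is uniform from 0 to the observed absolute oddball MMN,
#' the N1 alternative uniform from 0 to the observed deviant-minus-norep
#' N1 difference. Raw epochs are discarded subject by subject, so memory
#' stays modest even at the full design size.
#'
#' @param config A [study_config()].
#' @return A list of class `"mmn_study"`: `summary`
#'   (an `amplitude_summary` over retained subjects), `windows`,
#'   `exclusions`, `rejection_log`, `bayes` (tibble of the two tests),
#'   `n_retained`, and the `config`.
#' @export
run_synthetic_study <- function(config = study_config()) {
  obj <- config_objects(config)
  set.seed(config$seed)

  shared <- if (isTRUE(config$shared_sequences)) {
    make_sequences(obj$spec, c("oddball", "cascade", "norep"))
  }
  subjects <- vector("list", config$n_subjects)
  for (i in seq_len(config$n_subjects)) {
    sub <- sim_one_subject(sprintf("s%02d", i), obj$spec, obj$rec,
                           obj$components, obj$adapt, obj$noise,
                           config$between_subject_sd,
                           config$behavior$mean, config$behavior$sd,
                           c("oddball", "cascade", "norep"),
                           sequences = shared)
    proc <- process_subject(sub$epochs, obj$policy)
    subjects[[i]] <- list(
      subject_id = sub$subject_id,
      max_count_error = sub$max_count_error,
      amp_scale = sub$amp_scale,
      erps = proc$erps, retention = proc$retention,
      rejection_log = proc$rejection_log
    )
  }

  # windows from oddball data only, over all subjects
  windows_all <- derive_windows(
    grand_average(purrr::map(subjects, ~ .x$erps$standard)),
    grand_average(purrr::map(subjects, ~ difference_wave(.x$erps$deviant,
                                                         .x$erps$standard),
                             ), weight_by_trials = FALSE)
  )

  diag <- purrr::map_dfr(subjects, function(s) {
    d <- n1_diagnostics(s$erps$standard, windows_all$n1)
    tibble::tibble(
      subject_id = s$subject_id,
      max_count_error = s$max_count_error,
      min_retention = min(s$retention),
      n1_depth_uv = d$n1_depth_uv,
      baseline_noise_sd = d$baseline_noise_sd
    )
  })
  exclusions <- apply_exclusions(diag, config$exclusion$behavior_sd_mult,
                                 config$exclusion$min_retention,
                                 config$exclusion$n1_z)
  retained <- subjects[!exclusions$excluded]
  if (length(retained) == 0) stop("all subjects excluded", call. = FALSE)

  # re-derive windows for the retained sample (as in the reference design)
  windows <- derive_windows(
    grand_average(purrr::map(retained, ~ .x$erps$standard)),
    grand_average(purrr::map(retained, ~ difference_wave(.x$erps$deviant,
                                                         .x$erps$standard)),
                  weight_by_trials = FALSE)
  )

  amplitudes <- purrr::map_dfr(retained, function(s) {
    dplyr::mutate(subject_amplitudes(s$erps, windows),
                  subject_id = s$subject_id, .before = 1)
  })
  summary <- condition_summaries(amplitudes)

  bayes <- study_bayes_tests(summary)

  structure(
    list(summary = summary, windows = windows, exclusions = exclusions,
         rejection_log = purrr::map_dfr(subjects, "rejection_log"),
         bayes = bayes, n_retained = length(retained), config = config),
    class = "mmn_study"
  )
}

# Priors are built from the same run's observed quantities, never from
# published constants.
study_bayes_tests <- function(summary) {
  mmn_eff <- summary_effect(summary, "mmn_norep_minus_cascade")
  n1_eff <- summary_effect(summary, "n1_cascade_minus_norep")
  mmn_upper <- abs(summary_effect(summary, "oddball_mmn")$mean_uv)
  n1_upper <- summary_effect(summary, "n1_deviant_minus_norep")$mean_uv

  one <- function(eff, upper, label) {
    if (eff$sd_uv == 0 || is.na(eff$sd_uv)) {
      warning("degenerate contrast (zero variance); skipping BF for ", label,
              call. = FALSE)
      return(tibble::tibble(analysis = label, mean_uv = eff$mean_uv,
                            se_uv = eff$se_uv, prior_upper = upper,
                            bf01 = NA_real_, bf10 = NA_real_,
                            evidence = NA_character_))
    }
    if (upper <= 0) {
      return(tibble::tibble(analysis = label, mean_uv = eff$mean_uv,
                            se_uv = eff$se_uv, prior_upper = upper,
                            bf01 = NA_real_, bf10 = NA_real_,
                            evidence = "prior bound not positive"))
    }
    r <- bf01(effect_estimate(eff$mean_uv, eff$n, se = eff$se_uv),
              uniform_prior(0, upper))
    tibble::tibble(analysis = label, mean_uv = eff$mean_uv,
                   se_uv = eff$se_uv, prior_upper = upper,
                   bf01 = r$bf01, bf10 = r$bf10,
                   evidence = r$evidence_label)
  }
  dplyr::bind_rows(
    one(mmn_eff, mmn_upper, "mmn_norep_minus_cascade"),
    one(n1_eff, n1_upper, "n1_cascade_minus_norep")
  )
}

#' @export
print.mmn_study <- function(x, ...) {
  cat(sprintf("<mmn_study> %d/%d subjects retained\n", x$n_retained,
              x$config$n_subjects))
  cat(sprintf("  N1 window %g +/- %g ms; MMN window %g +/- %g ms\n",
              x$windows$n1$center_ms, x$windows$n1$half_width_ms,
              x$windows$mmn$center_ms, x$windows$mmn$half_width_ms))
  print(x$bayes)
  invisible(x)
}

#' Parameter-recovery replicates
#'
#' Runs the full synthetic pipeline `n_replicates` times under a
#' configuration, records the estimated critical MMN contrast
#' (norep-corrected minus cascade-corrected) and its Bayes factor per
#' replicate, and computes the ground truth as the same configuration
#' run noise-free (trial noise and between-subject variability both
#' zero). The difference between the replicate mean and the truth
#' measures pipeline bias.
#'
#' @param config A [study_config()]; its `seed` is replaced per
#'   replicate.
#' @param n_replicates Number of replicated runs.
#' @param seed Base seed; replicate `r` uses `seed * 1000 + r`.
#' @return A tibble with one row per replicate (`estimate_uv`, `se_uv`,
#'   `bf01`, `n_retained`), with attributes `truth_uv` (noise-free
#'   pipeline value) and `programmed_uv` (the configured effect).
#' @export
run_recovery_study <- function(config = recovery_config(),
                               n_replicates = 100, seed = 1L) {
  truth_cfg <- config
  truth_cfg$noise$sd_uv <- 0
  truth_cfg$between_subject_sd <- 0
  truth_cfg$behavior$sd <- 0
  truth_cfg$n_subjects <- 12L # averages over sequence randomizations
  truth <- withCallingHandlers(
    run_synthetic_study(truth_cfg),
    warning = function(w) {
      if (grepl("degenerate contrast", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  truth_uv <- summary_effect(truth$summary, "mmn_norep_minus_cascade")$mean_uv

  reps <- purrr::map_dfr(seq_len(n_replicates), function(r) {
    cfg <- config
    cfg$seed <- (seed * 1000L + r) %% .Machine$integer.max
    res <- run_synthetic_study(cfg)
    row <- res$bayes[res$bayes$analysis == "mmn_norep_minus_cascade", ]
    tibble::tibble(replicate = r, estimate_uv = row$mean_uv,
                   se_uv = row$se_uv, bf01 = row$bf01, bf10 = row$bf10,
                   n_retained = res$n_retained)
  })
  attr(reps, "truth_uv") <- truth_uv
  attr(reps, "programmed_uv") <- config$mmn_contrast_uv
  reps
}
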