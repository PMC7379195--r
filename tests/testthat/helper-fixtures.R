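# Shared fixtures: small recording grids and hand-built epoch sets.

tiny_rec <- function(fs_hz = 200, channels = c("Fz", "FCz", "Cz"),
                     mastoids = character(0)) {
  recording_spec(fs_hz = fs_hz, channels = channels,
                 mastoid_channels = mastoids)
}

# epoch_set wrapping a given trials x channels x samples array
manual_epochs <- function(data, rec = tiny_rec(), roles = NULL,
                          condition = "oddball") {
  n_trial <- dim(data)[1]
  roles <- roles %||% rep("standard", n_trial)
  events <- tibble::tibble(
    trial_index = seq_len(n_trial) - 1L,
    onset_ms = (seq_len(n_trial) - 1L) * 500,
    frequency_hz = 550,
    role = roles,
    condition = condition,
    set_index = -1L,
    is_warmup = roles == "warmup"
  )
  structure(
    list(data = data, events = events, subject_id = "fix",
         ring_condition = "one_letter", fs_hz = rec$fs_hz,
         window_ms = rec$epoch_window_ms, channels = rec$channels,
         mastoid_channels = rec$mastoid_channels),
    class = "epoch_set"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# waveform-only erp_average on a given grid
manual_erp <- function(data, fs_hz = 200, window_ms = c(-100, 400),
                       channels = paste0("ch", seq_len(nrow(data)))) {
  structure(
    list(data = data, n_trials = 1L, selector = "manual", fs_hz = fs_hz,
         window_ms = window_ms, channels = channels),
    class = "erp_average"
  )
}

# noise-free single-subject simulation of the full three-condition design
noise_free_subject <- function(spec = seq_spec(), rec = recording_spec(),
                               components = default_components(),
                               adapt = adaptation_params(), seed = 1) {
  set.seed(seed)
  seqs <- list(oddball = make_oddball_sequence(spec),
               cascade = make_cascade_sequence(spec),
               norep = make_norep_sequence(spec))
  eps <- simulate_subject(seqs, rec, components, adapt,
                          noise_spec(sd_uv = 0))
  lapply(eps, baseline_correct)
}

role_erps <- function(eps) {
  list(standard = average_erp(eps$oddball, role == "standard"),
       deviant = average_erp(eps$oddball, role == "deviant"),
       cascade = average_erp(eps$cascade, role == "control"),
       norep = average_erp(eps$norep, role == "control"))
}
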