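#' Specify a simulated ratiometric calcium trace
#'
#' Builds the parameter set for [simulate_trace()]. The simulated experiment
#' mirrors fura-2 ratiometric imaging of an isolated taste cell: a long
#' baseline sampled sparsely, a depolarizing stimulus (e.g. 50 mM KCl) sampled
#' every 2 s, and a slow, roughly linear recovery sampled at an intermediate
#' rate. Ratios are in arbitrary units (AU).
#'
#' @param baseline_level Resting F340/F380 ratio (AU).
#' @param noise_sd Standard deviation of i.i.d. Gaussian noise added to every
#'   sample (AU). May be 0 for noiseless traces.
#' @param stim_onset_s Stimulus onset time (s). The baseline phase spans
#'   `[0, stim_onset_s)` and must last at least 120 s.
#' @param response_amplitude_sd Step amplitude of the evoked plateau, in
#'   multiples of `noise_sd`.
#' @param response_amplitude_au Optional absolute amplitude (AU); overrides
#'   `response_amplitude_sd`. Required to state a nonzero amplitude when
#'   `noise_sd = 0`.
#' @param plateau_s Duration (s) for which the noiseless signal holds at
#'   `baseline_level + amplitude`.
#' @param recovery_slope Linear decline rate back to baseline (AU/s). Default
#'   recovers the full amplitude over 60 s.
#' @param schedule Data frame with columns `phase`
#'   (`"baseline"`/`"stimulus"`/`"recovery"`), `duration_s` and `interval_s`
#'   giving the sampling interval in each phase. Default:
#'   baseline every 30 s, stimulus window every 2 s, recovery every 6 s.
#' @param seed Integer seed; every simulation stream is derived from it.
#'
#' @return A list of class `trace_sim_spec`.
#' @export
trace_sim_spec <- function(baseline_level = 1.0,
                           noise_sd = 0.01,
                           stim_onset_s = 150,
                           response_amplitude_sd = 40,
                           response_amplitude_au = NULL,
                           plateau_s = 30,
                           recovery_slope = NULL,
                           schedule = NULL,
                           seed = 1L) {
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (response_amplitude_sd < 0) abort("`response_amplitude_sd` must be >= 0.")
  if (plateau_s < 0) abort("`plateau_s` must be >= 0.")
  amplitude_au <- response_amplitude_au %||% (response_amplitude_sd * noise_sd)
  if (amplitude_au < 0) abort("response amplitude must be >= 0.")
  if (is.null(schedule)) {
    schedule <- tibble(
      phase      = c("baseline", "stimulus", "recovery"),
      duration_s = c(stim_onset_s, plateau_s + 10, 120),
      interval_s = c(30, 2, 6)
    )
  }
  schedule <- as_tibble(schedule)
  if (!all(c("phase", "duration_s", "interval_s") %in% names(schedule))) {
    abort("`schedule` needs columns phase, duration_s, interval_s.")
  }
  if (any(schedule$interval_s <= 0)) abort("sampling intervals must be > 0.")
  base_dur <- sum(schedule$duration_s[schedule$phase == "baseline"])
  if (base_dur < 120) {
    abort("baseline phase must last at least 120 s (the detector's window).")
  }
  if (abs(base_dur - stim_onset_s) > 1e-9) {
    abort("baseline phase duration must equal `stim_onset_s`.")
  }
  recovery_slope <- recovery_slope %||% (if (amplitude_au > 0) amplitude_au / 60 else 0)
  if (recovery_slope < 0) abort("`recovery_slope` must be >= 0.")
  structure(
    list(baseline_level = baseline_level, noise_sd = noise_sd,
         stim_onset_s = stim_onset_s, amplitude_au = amplitude_au,
         plateau_s = plateau_s, recovery_slope = recovery_slope,
         schedule = schedule, seed = as.integer(seed)),
    class = "trace_sim_spec"
  )
}

trace_sample_times <- function(schedule) {
  t0 <- 0
  times <- numeric(0)
  for (i in seq_len(nrow(schedule))) {
    dur <- schedule$duration_s[i]
    by <- schedule$interval_s[i]
    ph <- seq(t0, t0 + dur, by = by)
    # drop a boundary sample falling exactly on the next phase start; the
    # next phase owns it (stimulus onset belongs to the response window)
    ph <- ph[ph < t0 + dur - 1e-9]
    times <- c(times, ph)
    t0 <- t0 + dur
  }
  c(times, t0)  # final sample closes the record
}

trace_signal <- function(t, spec) {
  on <- spec$stim_onset_s
  up <- spec$amplitude_au
  sig <- rep(spec$baseline_level, length(t))
  in_plateau <- t >= on & t <= on + spec$plateau_s
  sig[in_plateau] <- spec$baseline_level + up
  post <- t > on + spec$plateau_s
  decay <- pmax(0, up - spec$recovery_slope * (t[post] - on - spec$plateau_s))
  sig[post] <- spec$baseline_level + decay
  sig
}

#' Simulate one calcium trace with known response status
#'
#' The noiseless signal is `baseline_level` before stimulus onset, steps to
#' `baseline_level + amplitude` for `plateau_s` seconds from onset, then
#' declines linearly at `recovery_slope` back to baseline. Gaussian noise of
#' SD `noise_sd` is added to every sample. The ground-truth `responded` flag
#' is recorded from the generating parameters (amplitude above 10 noise SD
#' and plateau of at least 10 s, the default detection rule), not inferred
#' from the realized samples.
#'
#' @param spec A [trace_sim_spec()].
#' @param cell_id Identifier stored in the trace.
#' @return A list with `trace` (tibble `cell_id`, `time_s`, `ratio_au`),
#'   `responded` (logical truth), `amplitude_au`, and `stim_onset_s`.
#' @export
simulate_trace <- function(spec, cell_id = "cell_1") {
  stopifnot(inherits(spec, "trace_sim_spec"))
  times <- trace_sample_times(spec$schedule)
  signal <- trace_signal(times, spec)
  noise <- with_seed(derive_seed(spec$seed, paste0("trace/", cell_id)),
                     rnorm(length(times), 0, spec$noise_sd))
  truth <- if (spec$noise_sd == 0) {
    spec$amplitude_au > 0 && spec$plateau_s >= 10
  } else {
    spec$amplitude_au > 10 * spec$noise_sd && spec$plateau_s >= 10
  }
  list(
    trace = tibble(cell_id = cell_id, time_s = times,
                   ratio_au = signal + noise),
    responded = truth,
    amplitude_au = spec$amplitude_au,
    stim_onset_s = spec$stim_onset_s
  )
}

#' Simulate a cohort of stimulated cells with known responder status
#'
#' Generates `n_responders` traces with a large evoked plateau and
#' `n_nonresponders` flat traces, all sharing one stimulus schedule, plus the
#' event table and ground truth. Defaults mimic the study design that
#' physiologically identified presynaptic (type III) taste cells with a
#' 50 mM KCl depolarization: responder amplitudes are far above the 10-SD
#' detection threshold, as KCl transients dwarf imaging noise.
#'
#' @param n_responders,n_nonresponders Cohort sizes (study sizes: 17 type III
#'   responders collected, 9 Tas1r3-GFP cells profiled).
#' @param amplitude_sd Responder amplitude in noise-SD multiples (default 40).
#' @param plateau_s Plateau duration (default 30 s; must be >= 10 s for
#'   responders to count as true positives).
#' @param noise_sd,baseline_level Passed to [trace_sim_spec()].
#' @param seed Integer seed.
#' @return List with `traces` (long tibble), `events` (one KCl event per
#'   cell), and `truth` (tibble `cell_id`, `responded`, `amplitude_au`).
#' @export
simulate_trace_cohort <- function(n_responders = 17, n_nonresponders = 9,
                                  amplitude_sd = 40, plateau_s = 30,
                                  noise_sd = 0.01, baseline_level = 1.0,
                                  seed = 1L) {
  ids <- sprintf("cell_%03d", seq_len(n_responders + n_nonresponders))
  amps <- c(rep(amplitude_sd, n_responders), rep(0, n_nonresponders))
  sims <- map2(ids, amps, function(id, a) {
    spec <- trace_sim_spec(baseline_level = baseline_level,
                           noise_sd = noise_sd,
                           response_amplitude_sd = a, plateau_s = plateau_s,
                           seed = derive_seed(seed, paste0("cohort/", id)))
    simulate_trace(spec, cell_id = id)
  })
  traces <- list_rbind(map(sims, "trace"))
  onset <- sims[[1]]$stim_onset_s
  list(
    traces = traces,
    events = tibble(cell_id = ids, onset_s = onset, duration_s = 4,
                    label = "KCl 50 mM"),
    truth = tibble(cell_id = ids,
                   responded = map_lgl(sims, "responded"),
                   amplitude_au = map_dbl(sims, "amplitude_au"))
  )
}

#' Read / write trace CSV files
#'
#' Traces are stored as CSV with header `time_s,ratio_au` (single cell) or
#' `cell_id,time_s,ratio_au` (long format); stimulus events as a sidecar CSV
#' `onset_s,label` (optionally `cell_id`, `duration_s`).
#'
#' @param path File path.
#' @return `read_traces_csv()` returns a tibble.
#' @export
read_traces_csv <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("time_s", "ratio_au") %in% names(x))) {
    abort("trace CSV must have columns time_s, ratio_au.")
  }
  as_tibble(x)
}

#' @rdname read_traces_csv
#' @param traces Tibble of trace samples.
#' @export
write_traces_csv <- function(traces, path) {
  readr::write_csv(traces, path)
  invisible(path)
}
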