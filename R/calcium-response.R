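#' Detector configuration for calcium response classification
#'
#' The classification rule for a depolarization-evoked calcium response: the
#' F340/F380 ratio must remain strictly more than `k_sd` baseline standard
#' deviations above the baseline mean for at least `min_duration_s` seconds
#' consecutively, with the baseline statistics taken from the
#' `baseline_window_s` seconds before stimulus onset.
#'
#' Because the sampling interval is reduced during the recovery phase (up to
#' 8 s between frames), "consecutively" on the irregular grid is defined as a
#' run of suprathreshold samples whose inter-sample gaps never exceed
#' `max_gap_s`; run duration is last minus first sample time.
#'
#' @param k_sd Threshold multiplier on the baseline SD (default 10).
#' @param min_duration_s Minimum run duration in seconds (default 10).
#' @param baseline_window_s Baseline window before onset (default 120).
#' @param max_gap_s Largest inter-sample gap allowed inside a run (default
#'   8 s, the maximum recovery-phase sampling interval).
#' @return A list of class `detector_config`.
#' @export
detector_config <- function(k_sd = 10, min_duration_s = 10,
                            baseline_window_s = 120, max_gap_s = 8) {
  vals <- c(k_sd = k_sd, min_duration_s = min_duration_s,
            baseline_window_s = baseline_window_s, max_gap_s = max_gap_s)
  if (any(vals <= 0)) abort("all detector parameters must be positive.")
  structure(as.list(vals), class = "detector_config")
}

validate_trace <- function(trace) {
  trace <- as_tibble(trace)
  if (!all(c("time_s", "ratio_au") %in% names(trace))) {
    abort("a trace needs columns `time_s` and `ratio_au`.")
  }
  if (nrow(trace) < 2) abort("a trace needs at least 2 samples.")
  if (any(diff(trace$time_s) <= 0)) {
    abort("trace timestamps must be strictly increasing.")
  }
  if (any(!is.finite(trace$ratio_au))) abort("trace ratios must be finite.")
  trace
}

#' Baseline statistics from the pre-stimulus window
#'
#' Mean and sample standard deviation (n - 1 denominator) of the ratio over
#' samples in `[onset - baseline_window_s, onset)`. A sample falling exactly
#' at stimulus onset belongs to the response window, not the baseline.
#'
#' @param trace Tibble with `time_s`, `ratio_au`.
#' @param stim_onset_s Stimulus onset (s), or a one-row event tibble with
#'   `onset_s`.
#' @param cfg A [detector_config()].
#' @return Tibble with one row: `mean_au`, `sd_au`, `window_start_s`,
#'   `window_end_s`, `n_samples`.
#' @export
compute_baseline <- function(trace, stim_onset_s, cfg = detector_config()) {
  trace <- validate_trace(trace)
  if (is.data.frame(stim_onset_s)) stim_onset_s <- stim_onset_s$onset_s[1]
  lo <- stim_onset_s - cfg$baseline_window_s
  in_win <- trace$time_s >= lo & trace$time_s < stim_onset_s
  n <- sum(in_win)
  if (n < 2) {
    abort(sprintf(
      "insufficient baseline: %d sample(s) in [%.1f, %.1f); need >= 2.",
      n, lo, stim_onset_s), class = "tastecellseq_baseline_error")
  }
  x <- trace$ratio_au[in_win]
  tibble(mean_au = mean(x), sd_au = sd(x),
         window_start_s = lo, window_end_s = stim_onset_s, n_samples = n)
}

# maximal runs of TRUE positions with inter-sample gaps <= max_gap
supra_runs <- function(time_s, above, max_gap) {
  idx <- which(above)
  if (length(idx) == 0) return(tibble(start_s = numeric(), end_s = numeric()))
  brk <- c(TRUE, diff(idx) > 1 | diff(time_s[idx]) > max_gap)
  grp <- cumsum(brk)
  tibble(
    start_s = as.numeric(tapply(time_s[idx], grp, min)),
    end_s = as.numeric(tapply(time_s[idx], grp, max))
  )
}

#' Detect a stimulus-evoked calcium response
#'
#' Applies the threshold-run rule: threshold `mean_au + k_sd * sd_au`
#' (strict inequality), samples examined from stimulus onset (inclusive) to
#' `end_s` (the next stimulus onset, if any) or the end of the trace; the
#' cell responded if any run of suprathreshold samples (gaps `<= max_gap_s`)
#' spans at least `min_duration_s` seconds. A zero baseline SD is
#' well-defined: the threshold is then the baseline mean.
#'
#' @inheritParams compute_baseline
#' @param baseline One-row tibble from [compute_baseline()], or `NULL` to
#'   compute it here.
#' @param end_s Exclusive end of the response window (default: trace end,
#'   inclusive).
#' @return One-row tibble: `responded`, `threshold_au`, `run_start_s`,
#'   `run_end_s` (NA unless responded), `max_run_duration_s`, `peak_au`.
#' @export
detect_response <- function(trace, stim_onset_s, baseline = NULL,
                            cfg = detector_config(), end_s = Inf) {
  trace <- validate_trace(trace)
  if (is.data.frame(stim_onset_s)) stim_onset_s <- stim_onset_s$onset_s[1]
  if (is.null(baseline)) baseline <- compute_baseline(trace, stim_onset_s, cfg)
  thr <- baseline$mean_au + cfg$k_sd * baseline$sd_au

  post <- trace$time_s >= stim_onset_s & trace$time_s < end_s
  t_post <- trace$time_s[post]
  r_post <- trace$ratio_au[post]
  runs <- supra_runs(t_post, r_post > thr, cfg$max_gap_s)
  runs$duration_s <- runs$end_s - runs$start_s
  best <- if (nrow(runs)) which.max(runs$duration_s) else integer(0)
  max_dur <- if (nrow(runs)) runs$duration_s[best] else 0
  responded <- max_dur >= cfg$min_duration_s
  tibble(
    responded = responded,
    threshold_au = thr,
    run_start_s = if (responded) runs$start_s[best] else NA_real_,
    run_end_s = if (responded) runs$end_s[best] else NA_real_,
    max_run_duration_s = max_dur,
    peak_au = if (length(r_post)) max(r_post) else NA_real_
  )
}

#' Classify cells as type III by their KCl response
#'
#' Runs baseline estimation and response detection per cell against that
#' cell's KCl event. Cells with a detected response are labelled
#' `"type III"`; cells without, `"unclassified"`; cells whose baseline
#' cannot be computed (fewer than 2 pre-stimulus samples) are labelled
#' `"unclassifiable"` rather than dropped.
#'
#' @param traces Long tibble with `cell_id`, `time_s`, `ratio_au`.
#' @param events Tibble with `cell_id` (optional if a single shared event),
#'   `onset_s`, and optionally `label`; events whose label contains "KCl"
#'   are used (all events if no label column).
#' @param cfg A [detector_config()].
#' @return Tibble with one row per cell: `cell_id`, `responded`, `peak_au`,
#'   `max_run_s`, `label`.
#' @export
classify_cells <- function(traces, events, cfg = detector_config()) {
  traces <- as_tibble(traces)
  if (!"cell_id" %in% names(traces)) {
    abort("`traces` must be long format with a `cell_id` column.")
  }
  events <- as_tibble(events)
  if (!"onset_s" %in% names(events)) abort("`events` needs an `onset_s` column.")
  if ("label" %in% names(events)) {
    kcl <- events[grepl("KCl", events$label, ignore.case = TRUE), ]
    if (nrow(kcl)) events <- kcl
  }

  ids <- unique(traces$cell_id)
  rows <- map(ids, function(id) {
    tr <- traces[traces$cell_id == id, ]
    ev <- if ("cell_id" %in% names(events)) {
      events[events$cell_id == id, ]
    } else {
      events
    }
    if (nrow(ev) == 0) {
      abort(paste0("no KCl event for cell ", id, "."))
    }
    onset <- ev$onset_s[1]
    res <- tryCatch(
      detect_response(tr, onset, cfg = cfg),
      tastecellseq_baseline_error = function(e) NULL
    )
    if (is.null(res)) {
      tibble(cell_id = id, responded = NA, peak_au = NA_real_,
             max_run_s = NA_real_, label = "unclassifiable")
    } else {
      tibble(cell_id = id, responded = res$responded, peak_au = res$peak_au,
             max_run_s = res$max_run_duration_s,
             label = if (res$responded) "type III" else "unclassified")
    }
  })
  list_rbind(rows)
}
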