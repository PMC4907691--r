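#' Filter and smooth a skin conductance waveform
#'
#' Applies the standard preprocessing chain for 200-Hz skin conductance
#' recordings: a 25-Hz low-pass FIR filter (windowed-sinc design, order 64,
#' Hamming window, applied forward-backward for zero phase) followed by
#' smoothing with a 10-sample Gaussian kernel (SD 2.5 samples, symmetric, so
#' also zero-phase). Output length equals input length and DC gain is unity.
#'
#' @param wf An `scr_waveform` tibble (`time_s`, `conductance_uS`) with a
#'   `rate_hz` attribute, or any data frame with those columns and uniform
#'   sampling.
#' @param cutoff_hz Low-pass cutoff (Hz).
#' @param fir_order FIR filter order.
#' @param kernel_samples Gaussian kernel width in samples.
#' @return The waveform with `conductance_uS` replaced by the filtered trace.
#' @export
preprocess_waveform <- function(wf, cutoff_hz = 25, fir_order = 64,
                                kernel_samples = 10) {
  check_cols(wf, c("time_s", "conductance_uS"), "preprocess_waveform")
  dt <- diff(wf$time_s)
  if (length(dt) < 2 || any(abs(dt - dt[1]) > 1e-9)) {
    stopf("preprocess_waveform(): sampling must be uniform.")
  }
  if (!all(is.finite(wf$conductance_uS))) {
    stopf("preprocess_waveform(): waveform contains non-finite samples.")
  }
  rate <- attr(wf, "rate_hz") %||% (1 / dt[1])
  x <- wf$conductance_uS

  b <- signal::fir1(fir_order, cutoff_hz / (rate / 2), type = "low")
  b <- b / sum(b)  # exact unit DC gain
  # Edge-replicate padding avoids the zero-padding transient of filtfilt.
  n_pad <- 3L * (fir_order + 1L)
  xp <- c(rep(x[1], n_pad), x, rep(x[length(x)], n_pad))
  xf <- signal::filtfilt(signal::Ma(b), xp)
  x <- xf[(n_pad + 1L):(n_pad + length(x))]

  sd_samp <- kernel_samples / 4
  half <- ceiling(kernel_samples / 2)
  k <- exp(-((-half:half)^2) / (2 * sd_samp^2))
  k <- k / sum(k)
  # Symmetric FIR smoothing with edge replication keeps length and phase.
  xp <- c(rep(x[1], half), x, rep(x[length(x)], half))
  x <- as.numeric(stats::filter(xp, k, sides = 2))[(half + 1):(half + length(wf$time_s))]

  out <- wf
  out$conductance_uS <- x
  out
}

#' Scoring rule configuration
#'
#' The algorithmic stand-in for hand scoring: a response onset is a local
#' minimum followed by a monotone rise of at least `slope_threshold` uS/s
#' sustained for `slope_duration` s, with the onset falling inside the
#' latency `window` after the scored event; the response peak is the next
#' local maximum, searched up to `max_peak_search` s after onset. Base-to-peak
#' amplitudes below `min_amplitude` count as non-responses (score 0).
#'
#' @param window Latency window after the event, seconds (c(from, to)).
#' @param min_amplitude Non-response floor (uS).
#' @param slope_threshold Minimum mean rise rate at onset (uS/s).
#' @param slope_duration Duration over which the rise must be sustained (s).
#' @param max_peak_search How far past the event to search for the peak (s).
#' @return An object of class `scoring_config`.
#' @export
scoring_config <- function(window = c(0.5, 4.5), min_amplitude = 0.02,
                           slope_threshold = 0.01, slope_duration = 0.25,
                           max_peak_search = 10) {
  structure(as.list(environment()), class = "scoring_config")
}

#' Score one trial's base-to-peak SCR amplitude
#'
#' Finds the first response whose onset falls within the latency window after
#' the event (cue onset for CS scoring; US presentation for US scoring, in
#' which case the caller passes the US time as `onset_s`) and returns its
#' base-to-peak amplitude, or 0 for a non-response.
#'
#' @param wf A (preprocessed) waveform tibble.
#' @param onset_s Event time, seconds.
#' @param config A [scoring_config()].
#' @return Raw amplitude in uS (0 if none found or below the floor).
#' @export
score_trial <- function(wf, onset_s, config = scoring_config()) {
  check_cols(wf, c("time_s", "conductance_uS"), "score_trial")
  rate <- attr(wf, "rate_hz") %||% (1 / diff(wf$time_s[1:2]))
  t <- wf$time_s
  x <- wf$conductance_uS
  win_end <- onset_s + config$window[2]
  if (onset_s + config$window[1] < t[1] || win_end > t[length(t)]) {
    stopf("score_trial(): latency window [%.2f, %.2f] exceeds the recording.",
          onset_s + config$window[1], win_end)
  }
  i_from <- which(t >= onset_s + config$window[1])[1]
  i_to <- max(which(t <= win_end))
  n_rise <- max(1L, round(config$slope_duration * rate))
  i_search_end <- min(length(x), max(which(t <= onset_s + config$max_peak_search)))

  dx <- diff(x)
  tol <- 1e-12
  for (i in seq(i_from, i_to)) {
    if (i <= 1L || i + n_rise > length(x)) next
    # Local minimum: non-increasing into i, rising out of it.
    if (dx[i - 1L] > tol || dx[i] <= tol) next
    rise <- x[i + n_rise] - x[i]
    if (rise / (n_rise / rate) < config$slope_threshold) next
    if (any(dx[i:(i + n_rise - 1L)] < -tol)) next
    # Peak: next local maximum (sustained non-rise), searched forward.
    j <- i + n_rise
    while (j < i_search_end && dx[j] > tol) j <- j + 1L
    amp <- x[j] - x[i]
    if (amp < config$min_amplitude) return(0)
    return(amp)
  }
  0
}

#' Score every trial of a sequence from a waveform
#'
#' CS responses are scored in the latency window after cue onset on all
#' trials; on reinforced trials the US response is additionally scored
#' relative to the US presentation (cue offset). US trials' CS-onset scores
#' are retained in the table but downstream CS-level analyses use
#' unreinforced trials only; the US scores feed normalization.
#'
#' @param wf A raw or preprocessed waveform tibble.
#' @param seq The `trial_sequence` describing event times.
#' @param config A [scoring_config()].
#' @param preprocess Apply [preprocess_waveform()] first (default TRUE).
#' @return A tibble with columns `trial`, `is_us`, `raw_uS` (CS-onset
#'   amplitude) and `us_raw_uS` (`NA` on unreinforced trials).
#' @export
score_trials <- function(wf, seq, config = scoring_config(),
                         preprocess = TRUE) {
  if (preprocess) wf <- preprocess_waveform(wf)
  stim <- (attr(seq, "config") %||% task_config())$stim_duration
  purrr::map_dfr(seq_len(nrow(seq)), function(k) {
    tibble(
      trial = seq$trial[k],
      is_us = seq$us[k] == 1,
      raw_uS = score_trial(wf, seq$onset_s[k], config),
      us_raw_uS = if (seq$us[k] == 1) {
        score_trial(wf, seq$onset_s[k] + stim, config)
      } else NA_real_
    )
  })
}

#' Square-root transform and US-normalize trial amplitudes
#'
#' Raw amplitudes are square-root transformed (to de-skew the amplitude
#' distribution) and then divided by the subject's mean square-root US
#' response, giving unitless values expressed relative to the unconditioned
#' response. Zeros stay zero. If a `subject` column is present, normalization
#' is per subject.
#'
#' @param data A data frame with one row per trial containing the CS
#'   amplitude column and a US amplitude column that is non-`NA` on
#'   reinforced trials (e.g. the output of [score_trials()] or a cohort from
#'   [simulate_cohort()]).
#' @param amplitude,us_amplitude Tidy-selected columns holding the CS and US
#'   raw amplitudes (uS).
#' @return `data` with added columns `sqrt_uS`, `normalized`, and `is_us`.
#'   Errors if a subject's mean US response is zero or no US trial is scored
#'   (such a subject is unanalyzable).
#' @export
#' @examples
#' cohort <- simulate_cohort(canonical_orders(), gen_params(n_subjects = 2))
#' scored <- transform_normalize(cohort)
transform_normalize <- function(data, amplitude = "amplitude_uS",
                                us_amplitude = "us_amplitude_uS") {
  check_cols(data, c(amplitude, us_amplitude), "transform_normalize")
  one <- function(d) {
    raw <- d[[amplitude]]
    us <- d[[us_amplitude]]
    if (any(raw < 0, na.rm = TRUE)) stopf("Raw amplitudes must be >= 0.")
    us_sqrt <- sqrt(us[!is.na(us)])
    if (length(us_sqrt) == 0L || mean(us_sqrt) <= 0) {
      stopf(paste0("transform_normalize(): mean US response is zero; ",
                   "subject is unanalyzable."))
    }
    d$sqrt_uS <- sqrt(raw)
    d$normalized <- d$sqrt_uS / mean(us_sqrt)
    d$is_us <- !is.na(us)
    d
  }
  out <- if ("subject" %in% names(data)) {
    data |>
      group_by(.data$subject) |>
      group_modify(~ one(.x)) |>
      ungroup() |>
      relocate("subject")
  } else {
    as_tibble(one(data))
  }
  # group_modify drops the cohort attributes; carry them forward.
  for (a in c("manifest", "sequences", "gen")) {
    attr(out, a) <- attr(data, a)
  }
  out
}

#' Classify a subject as a learner
#'
#' A learner shows greater mean normalized SCR to the CS+ than to the CS-
#' on the unreinforced trials of the second half of the first block (late
#' acquisition). The comparison is a strict inequality of means with no
#' significance requirement; ties classify as non-learner.
#'
#' @param data One subject's trial table with a `normalized` column, aligned
#'   to `seq`.
#' @param seq The subject's `trial_sequence`.
#' @return `TRUE` if learner, else `FALSE`.
#' @export
classify_learner <- function(data, seq) {
  check_cols(data, c("trial", "normalized"), "classify_learner")
  config <- attr(seq, "config") %||% task_config()
  tp <- config$trials_per_block
  half <- seq$trial > tp / 2 & seq$trial <= tp & seq$us == 0
  window <- seq[half, c("trial", "role")]
  d <- inner_join(window, data[, c("trial", "normalized")], by = "trial")
  m_plus <- d$normalized[d$role == "CS+"]
  m_minus <- d$normalized[d$role == "CS-"]
  if (length(m_plus) == 0L || length(m_minus) == 0L) {
    stopf("classify_learner(): a cue type is absent from late acquisition.")
  }
  mean(m_plus) > mean(m_minus)
}

#' Classify every subject in a cohort
#'
#' @param data A cohort table with `subject`, `trial_order`, `trial`,
#'   `normalized` columns.
#' @param seqs The list of trial orders the cohort was generated from.
#' @return A tibble with `subject` and `learner`.
#' @export
classify_learners <- function(data, seqs = attr(data, "sequences")) {
  check_cols(data, c("subject", "trial_order"), "classify_learners")
  if (is.null(seqs)) stopf("`seqs` must be supplied.")
  data |>
    group_by(.data$subject) |>
    group_modify(function(d, key) {
      tibble(learner = classify_learner(d, seqs[[d$trial_order[1]]]))
    }) |>
    ungroup()
}
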