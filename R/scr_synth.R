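#' Generating parameters for synthetic SCR cohorts
#'
#' Defines the statistical structure assumed by the downstream analysis, run
#' in the generative direction: a subject's trial-level skin conductance
#' amplitude is an affine function of the model-derived expected value of the
#' presented cue, plus linear habituation, Gaussian trial noise, and a
#' US-evoked response on reinforced trials, floored at zero. A mixture
#' proportion of "non-learner" subjects with near-zero EV slope emulates the
#' subset of participants whose SCR carries no conditioning signal.
#'
#' Default magnitudes (microsiemens) are chosen so that, after square-root
#' transform and normalization to the mean US response, differential CS+/CS-
#' effects land in the 0.04-0.10 range typical of normalized SCR betas in this
#' paradigm; they are configuration, not claims about any dataset.
#'
#' @param model A [model_params()] object holding the generating learning
#'   model. Its `variant` decides the cohort's group: instructed cohorts use
#'   the instructed EV trace, uninstructed (feedback) cohorts the feedback
#'   trace. Defaults to the instructed model at `alpha = 0.061`,
#'   `rho = 0.943`.
#' @param slope_mean,slope_sd Across-subject distribution of the EV-to-SCR
#'   scaling (uS per unit EV).
#' @param intercept_mean,intercept_sd Across-subject baseline amplitude (uS).
#' @param habituation_slope Per-trial linear drift (uS/trial, negative for
#'   habituation).
#' @param noise_sd Trial-level Gaussian noise SD (uS).
#' @param us_amp_mean,us_amp_sd US-evoked amplitude distribution (uS),
#'   truncated at zero.
#' @param p_nonlearner Probability that a subject is a non-learner (EV slope
#'   drawn near zero).
#' @param n_subjects Cohort size.
#' @param seed Master seed for the cohort.
#'
#' @return An object of class `gen_params`.
#' @export
gen_params <- function(model = model_params(alpha = 0.061, rho = 0.943),
                       slope_mean = 0.25, slope_sd = 0.05,
                       intercept_mean = 0.3, intercept_sd = 0.1,
                       habituation_slope = -0.002,
                       noise_sd = 0.1,
                       us_amp_mean = 1, us_amp_sd = 0.2,
                       p_nonlearner = 0.3,
                       n_subjects = 20L,
                       seed = 1L) {
  if (!inherits(model, "model_params")) {
    stopf("`model` must be created with model_params().")
  }
  for (nm in c("slope_sd", "intercept_sd", "noise_sd", "us_amp_sd")) {
    val <- get(nm)
    if (val < 0) stopf("`%s` must be >= 0.", nm)
  }
  check_range(p_nonlearner, "p_nonlearner")
  if (n_subjects < 0) stopf("`n_subjects` must be >= 0.")
  structure(
    list(model = model,
         slope_mean = slope_mean, slope_sd = slope_sd,
         intercept_mean = intercept_mean, intercept_sd = intercept_sd,
         habituation_slope = habituation_slope, noise_sd = noise_sd,
         us_amp_mean = us_amp_mean, us_amp_sd = us_amp_sd,
         p_nonlearner = p_nonlearner,
         n_subjects = as.integer(n_subjects), seed = as.integer(seed),
         group = if (model$variant == "instructed") "instructed" else "uninstructed"),
    class = "gen_params"
  )
}

#' Simulate one subject's trial-level SCR amplitudes
#'
#' `amplitude = max(0, intercept + slope * V_n(x_n) + habituation_slope * n +
#' noise)`, with an additional truncated-normal US-evoked amplitude on
#' reinforced trials. The subject's EV trace follows the generating model's
#' variant (instructed vs feedback).
#'
#' @param seq A `trial_sequence`.
#' @param gen A [gen_params()] object.
#' @param subject_seed Integer seed for this subject's draws.
#' @param subject_id Identifier stored in the output.
#' @return A tibble of class `subject_amplitudes` with columns `subject`,
#'   `trial`, `amplitude_uS` (CS-onset response) and `us_amplitude_uS` (`NA`
#'   on unreinforced trials). The true generating values (intercept, slope,
#'   non-learner flag) are attached as attribute `"truth"`.
#' @export
simulate_subject_amplitudes <- function(seq, gen, subject_seed,
                                        subject_id = 1L) {
  if (!inherits(gen, "gen_params")) stopf("`gen` must be a gen_params object.")
  n <- nrow(seq)
  trace <- simulate_ev_trace(seq, gen$model)
  if (nrow(trace) != n) stopf("EV trace and sequence length mismatch.")
  withr::with_seed(as.integer(subject_seed), {
    nonlearner <- runif(1) < gen$p_nonlearner
    slope <- if (nonlearner) {
      rnorm(1, 0, 0.1 * gen$slope_sd)
    } else {
      rnorm(1, gen$slope_mean, gen$slope_sd)
    }
    intercept <- rnorm(1, gen$intercept_mean, gen$intercept_sd)
    eps <- rnorm(n, 0, gen$noise_sd)
    amp <- pmax(0, intercept + slope * trace$v_presented +
                  gen$habituation_slope * seq_len(n) + eps)
    us_amp <- rep(NA_real_, n)
    us_idx <- which(seq$us == 1)
    if (length(us_idx)) {
      us_amp[us_idx] <- pmax(0, rnorm(length(us_idx), gen$us_amp_mean,
                                      gen$us_amp_sd))
    }
    out <- tibble(subject = subject_id, trial = seq$trial,
                  amplitude_uS = amp, us_amplitude_uS = us_amp)
    structure(out,
              truth = list(subject = subject_id, intercept = intercept,
                           slope = slope, nonlearner = nonlearner,
                           model = gen$model, seed = as.integer(subject_seed)),
              class = c("subject_amplitudes", class(out)))
  })
}

#' Simulate a cohort of subjects
#'
#' Subjects alternate between the supplied trial orders (the two canonical
#' pseudorandom orders by default) and are fully reproducible from
#' `gen$seed`, from which each subject's seed is derived.
#'
#' @param seqs A list of `trial_sequence` objects (one per trial order), or a
#'   single sequence.
#' @param gen A [gen_params()] object.
#' @return A tibble of class `scr_cohort` with columns `subject`, `group`,
#'   `trial_order`, `trial`, `amplitude_uS`, `us_amplitude_uS`. The manifest
#'   of true generating parameters is attached as attribute `"manifest"` and
#'   the trial orders as attribute `"sequences"`.
#' @export
#' @examples
#' cohort <- simulate_cohort(canonical_orders(), gen_params(n_subjects = 4))
#' attr(cohort, "manifest")
simulate_cohort <- function(seqs = canonical_orders(), gen = gen_params()) {
  if (inherits(seqs, "trial_sequence")) seqs <- list(seqs)
  if (gen$n_subjects == 0L) {
    stopf("simulate_cohort(): `n_subjects` must be at least 1.")
  }
  seeds <- derive_seeds(gen$seed, gen$n_subjects)
  subjects <- purrr::map(seq_len(gen$n_subjects), function(s) {
    order_idx <- (s - 1L) %% length(seqs) + 1L
    amp <- simulate_subject_amplitudes(seqs[[order_idx]], gen, seeds[s],
                                       subject_id = s)
    truth <- attr(amp, "truth")
    list(
      data = amp |> mutate(group = gen$group, trial_order = order_idx,
                           .after = "subject"),
      manifest = tibble(subject = s, group = gen$group,
                        trial_order = order_idx,
                        intercept = truth$intercept, slope = truth$slope,
                        nonlearner = truth$nonlearner, seed = seeds[s])
    )
  })
  out <- purrr::map_dfr(subjects, "data")
  structure(out,
            manifest = purrr::map_dfr(subjects, "manifest"),
            sequences = seqs,
            gen = gen,
            class = c("scr_cohort", class(out)))
}

#' Waveform rendering parameters
#'
#' Controls how trial-level amplitudes are rendered as a continuous 200-Hz
#' skin conductance waveform: each nonzero amplitude becomes a canonical SCR
#' impulse (difference of exponentials, rise time constant ~0.75 s, decay
#' ~2 s, unit peak) starting at a latency drawn uniformly within the scoring
#' window after cue onset, superposed on a baseline with optional slow drift
#' and white measurement noise.
#'
#' @param rate_hz Sampling rate; the recording convention is 200 Hz.
#' @param rise_tau,decay_tau Impulse time constants (s).
#' @param latency_range CS response latency window after cue onset (s).
#' @param us_latency_range US response latency window after US presentation
#'   (cue offset) (s).
#' @param baseline Tonic conductance level (uS).
#' @param drift_sd SD of the slow baseline drift increment per second (uS).
#' @param noise_sd White measurement noise SD (uS).
#' @return An object of class `waveform_params`.
#' @export
waveform_params <- function(rate_hz = 200, rise_tau = 0.75, decay_tau = 2,
                            latency_range = c(0.5, 4.5),
                            us_latency_range = c(0.5, 1.5),
                            baseline = 2, drift_sd = 0, noise_sd = 0) {
  if (rate_hz <= 0) stopf("`rate_hz` must be positive.")
  if (rise_tau >= decay_tau) stopf("`rise_tau` must be below `decay_tau`.")
  structure(as.list(environment()), class = "waveform_params")
}

# Canonical SCR impulse with unit peak.
scr_impulse <- function(t, rise_tau, decay_tau) {
  s <- exp(-t / decay_tau) - exp(-t / rise_tau)
  t_peak <- log(decay_tau / rise_tau) / (1 / rise_tau - 1 / decay_tau)
  peak <- exp(-t_peak / decay_tau) - exp(-t_peak / rise_tau)
  ifelse(t < 0, 0, s / peak)
}

#' Render trial amplitudes as a raw SCR waveform
#'
#' End-to-end test input for the scoring module: ground-truth latencies and
#' amplitudes are stored so that scored values can be compared against what
#' was injected.
#'
#' @param amps A `subject_amplitudes` tibble (from
#'   [simulate_subject_amplitudes()]).
#' @param seq The `trial_sequence` the amplitudes were generated from.
#' @param wf A [waveform_params()] object.
#' @param seed Seed for latencies, drift, and noise.
#' @return A tibble of class `scr_waveform` with columns `time_s`,
#'   `conductance_uS`; sampling rate in attribute `"rate_hz"` and the injected
#'   (trial, type, latency, amplitude) table in attribute `"truth"`.
#' @export
simulate_waveform <- function(amps, seq, wf = waveform_params(), seed = 1L) {
  if (nrow(amps) != nrow(seq)) stopf("`amps` and `seq` length mismatch.")
  config <- attr(seq, "config") %||% task_config()
  spacing <- config$stim_duration + config$isi
  support <- max(wf$latency_range) + 4 * wf$decay_tau
  if (spacing < support * 0.75) {
    stopf("Trial spacing (%.1f s) is shorter than the impulse support.", spacing)
  }
  withr::with_seed(as.integer(seed), {
    t_end <- max(seq$onset_s) + spacing + 10
    time_s <- seq(0, t_end, by = 1 / wf$rate_hz)
    x <- rep(wf$baseline, length(time_s))
    if (wf$drift_sd > 0) {
      steps <- rnorm(ceiling(t_end) + 1L, 0, wf$drift_sd)
      drift <- stats::approx(x = seq_along(steps) - 1, y = cumsum(steps),
                             xout = time_s)$y
      x <- x + drift
    }
    truth <- list()
    add_impulse <- function(x, t0, amp) {
      idx <- which(time_s >= t0 & time_s <= t0 + 6 * wf$decay_tau)
      x[idx] <- x[idx] + amp * scr_impulse(time_s[idx] - t0, wf$rise_tau,
                                           wf$decay_tau)
      x
    }
    for (k in seq_len(nrow(seq))) {
      a <- amps$amplitude_uS[k]
      if (!is.na(a) && a > 0) {
        lat <- runif(1, wf$latency_range[1], wf$latency_range[2])
        x <- add_impulse(x, seq$onset_s[k] + lat, a)
        truth[[length(truth) + 1L]] <- tibble(
          trial = seq$trial[k], type = "cs", latency_s = lat, amplitude = a)
      }
      ua <- amps$us_amplitude_uS[k]
      if (!is.na(ua) && ua > 0) {
        lat <- runif(1, wf$us_latency_range[1], wf$us_latency_range[2])
        x <- add_impulse(x, seq$onset_s[k] + config$stim_duration + lat, ua)
        truth[[length(truth) + 1L]] <- tibble(
          trial = seq$trial[k], type = "us", latency_s = lat, amplitude = ua)
      }
    }
    if (wf$noise_sd > 0) x <- x + rnorm(length(x), 0, wf$noise_sd)
    out <- tibble(time_s = time_s, conductance_uS = x)
    structure(out,
              rate_hz = wf$rate_hz,
              truth = if (length(truth)) bind_rows(truth) else
                tibble(trial = integer(), type = character(),
                       latency_s = double(), amplitude = double()),
              class = c("scr_waveform", class(out)))
  })
}

#' Write a cohort to per-subject TSV files plus a manifest
#'
#' @param cohort An `scr_cohort`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in unique(cohort$subject)) {
    d <- cohort[cohort$subject == s, c("trial", "amplitude_uS", "us_amplitude_uS")]
    write.table(as.data.frame(d),
                file.path(dir, sprintf("subject_%03d.tsv", s)),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest <- attr(cohort, "manifest")
  yaml::write_yaml(
    purrr::transpose(as.list(manifest)) |>
      setNames(sprintf("subject_%03d", manifest$subject)),
    file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Write / read a waveform as plain text with a JSON sidecar
#'
#' The sampled series goes to a CSV (`time_s`, `conductance_uS`); sampling
#' rate and units go to `<path>.json`.
#'
#' @param wf An `scr_waveform`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_waveform <- function(wf, path) {
  utils::write.csv(as.data.frame(wf)[, c("time_s", "conductance_uS")],
                   path, row.names = FALSE)
  jsonlite::write_json(
    list(rate_hz = attr(wf, "rate_hz") %||% (1 / diff(wf$time_s[1:2])),
         units = "uS"),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_waveform
#' @export
read_waveform <- function(path) {
  d <- as_tibble(utils::read.csv(path))
  meta <- jsonlite::read_json(paste0(path, ".json"))
  structure(d, rate_hz = meta$rate_hz,
            class = c("scr_waveform", class(d)))
}
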