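#' Plot an expected-value trace
#'
#' Both cues' EV timecourses with US trials marked and instruction events as
#' vertical lines.
#'
#' @param object An `ev_trace`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ev_trace <- function(object, ...) {
  long <- as_tibble(object) |>
    tidyr::pivot_longer(c("v_a", "v_b"), names_to = "cue_ev",
                        values_to = "ev") |>
    mutate(cue_ev = ifelse(.data$cue_ev == "v_a", "cue A", "cue B"))
  p <- ggplot(long, aes(x = .data$trial, y = .data$ev,
                        colour = .data$cue_ev)) +
    geom_line() +
    geom_point(data = as_tibble(object) |> filter(.data$us == 1),
               aes(x = .data$trial, y = .data$v_presented),
               inherit.aes = FALSE, shape = 4) +
    labs(x = "trial", y = "expected value", colour = NULL) +
    ylim(0, 1) +
    theme_minimal()
  instr <- attr(object, "instructions")
  if (!is.null(instr) && nrow(instr)) {
    p <- p + geom_vline(xintercept = instr$after_trial + 0.5,
                        linetype = "dashed", colour = "grey50")
  }
  p
}

#' Plot mean normalized SCR by current cue role
#'
#' Cohort mean (with standard-error ribbon) of the normalized response to
#' the current CS+ and CS- across trials, the descriptive counterpart of the
#' differential-conditioning analyses.
#'
#' @param data A scored cohort (needs `trial`, `normalized`, `trial_order`).
#' @param seqs The trial orders used by the cohort.
#' @return A ggplot.
#' @export
plot_cohort_scr <- function(data, seqs = attr(data, "sequences")) {
  check_cols(data, c("trial", "trial_order", "normalized"), "plot_cohort_scr")
  if (is.null(seqs)) stopf("`seqs` must be supplied.")
  roles <- purrr::imap_dfr(seqs, function(s, i) {
    tibble(trial_order = i, trial = s$trial, role = s$role, us = s$us)
  })
  data |>
    inner_join(roles, by = c("trial_order", "trial")) |>
    filter(.data$us == 0) |>
    group_by(.data$trial, .data$role) |>
    summarise(m = mean(.data$normalized),
              se = sd(.data$normalized) / sqrt(n()), .groups = "drop") |>
    ggplot(aes(x = .data$trial, y = .data$m, colour = .data$role,
               fill = .data$role)) +
    geom_ribbon(aes(ymin = .data$m - .data$se, ymax = .data$m + .data$se),
                alpha = 0.2, colour = NA) +
    geom_line() +
    labs(x = "trial", y = "normalized SCR", colour = NULL, fill = NULL) +
    theme_minimal()
}

#' Plot a fitted model against the cohort it was fit to
#'
#' The fitted EV timecourse for each trial order, with the fitted learning
#' parameters in the subtitle.
#'
#' @param object An `rw_fit`.
#' @param seqs Trial orders to display the fitted trace on.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rw_fit <- function(object, seqs = canonical_orders(), ...) {
  if (inherits(seqs, "trial_sequence")) seqs <- list(seqs)
  traces <- purrr::imap_dfr(seqs, function(s, i) {
    simulate_ev_trace(s, object$params) |>
      as_tibble() |>
      mutate(order = paste("order", i))
  })
  sub <- sprintf("alpha = %.3f%s", object$params$alpha,
                 if (object$variant == "instructed")
                   sprintf(", rho = %.3f", object$params$rho) else "")
  ggplot(traces, aes(x = .data$trial, y = .data$v_presented)) +
    geom_line(colour = "grey40") +
    geom_point(aes(colour = .data$role), size = 0.8) +
    facet_wrap(~order, ncol = 1) +
    labs(x = "trial", y = "fitted EV of presented cue",
         title = sprintf("%s model (%s-subjects fit)", object$variant,
                         object$fit_mode),
         subtitle = sub, colour = NULL) +
    theme_minimal()
}

#' Plot an fMRI design matrix
#'
#' Regressor timecourses stacked over acquisition time.
#'
#' @param object An `fmri_design`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fmri_design <- function(object, ...) {
  as_tibble(object) |>
    tidyr::pivot_longer(-"t_s", names_to = "regressor",
                        values_to = "value") |>
    mutate(regressor = factor(.data$regressor,
                              levels = setdiff(names(object), "t_s"))) |>
    ggplot(aes(x = .data$t_s, y = .data$value)) +
    geom_line() +
    facet_grid(rows = vars(.data$regressor), scales = "free_y") +
    labs(x = "time (s)", y = NULL) +
    theme_minimal()
}

#' Plot a waveform segment
#'
#' @param object An `scr_waveform`.
#' @param from,to Optional time range (s).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.scr_waveform <- function(object, from = NULL, to = NULL, ...) {
  d <- as_tibble(object)
  if (!is.null(from)) d <- d[d$time_s >= from, ]
  if (!is.null(to)) d <- d[d$time_s <= to, ]
  ggplot(d, aes(x = .data$time_s, y = .data$conductance_uS)) +
    geom_line() +
    labs(x = "time (s)", y = "conductance (uS)") +
    theme_minimal()
}

#' Plot two-level effect estimates
#'
#' Within-subject effect estimates with 95% confidence intervals, faceted by
#' level (within-subject vs group difference).
#'
#' @param object An `scr_lmm`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.scr_lmm <- function(object, ...) {
  tidy(object) |>
    mutate(se = .data$estimate / .data$t,
           lo = .data$estimate - qt(0.975, .data$df) * abs(.data$se),
           hi = .data$estimate + qt(0.975, .data$df) * abs(.data$se)) |>
    ggplot(aes(x = .data$effect, y = .data$estimate)) +
    geom_pointrange(aes(ymin = .data$lo, ymax = .data$hi)) +
    geom_hline(yintercept = 0, linetype = "dotted") +
    facet_wrap(~level) +
    labs(x = NULL, y = "estimate (normalized SCR units)") +
    theme_minimal()
}
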