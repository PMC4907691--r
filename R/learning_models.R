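#' Learning-model parameters
#'
#' Parameters of the Rescorla-Wagner model and its instructed extension. The
#' feedback-driven variant learns the expected value (EV) of each cue purely
#' from reinforcement with a constant learning rate `alpha`. The instructed
#' variant additionally mixes the two cues' EVs at each instruction event: with
#' mixing weight `rho = 0` each cue keeps its value (the model reduces to the
#' feedback-driven one), with `rho = 1` the cues exchange values completely.
#'
#' Default initial values follow the two study groups: the feedback-driven
#' variant starts both cues at 0.5 (no prior knowledge), while the instructed
#' variant starts the initially instructed CS+ at 0.75 and the CS- at 0.25
#' (asymmetric knowledge from the initial instruction).
#'
#' @param alpha Learning rate, in `[0, 1]`.
#' @param rho Instructed-reversal mixing weight, in `[0, 1]`; ignored (and may
#'   be `NULL`) for the feedback variant.
#' @param variant `"instructed"` or `"feedback"`.
#' @param v0_cs_plus,v0_cs_minus Initial EVs of the original CS+ / CS-, in
#'   `[0, 1]`. Defaults depend on `variant` (see above).
#'
#' @return An object of class `model_params`.
#' @export
#' @examples
#' model_params(alpha = 0.061, rho = 0.943)
#' model_params(alpha = 0.042, variant = "feedback")
model_params <- function(alpha,
                         rho = NULL,
                         variant = c("instructed", "feedback"),
                         v0_cs_plus = NULL,
                         v0_cs_minus = NULL) {
  variant <- match.arg(variant)
  check_range(alpha, "alpha")
  if (variant == "instructed") {
    if (is.null(rho)) stopf("`rho` is required for the instructed variant.")
    check_range(rho, "rho")
  } else {
    rho <- NA_real_
  }
  v0_cs_plus <- v0_cs_plus %||% if (variant == "instructed") 0.75 else 0.5
  v0_cs_minus <- v0_cs_minus %||% if (variant == "instructed") 0.25 else 0.5
  check_range(v0_cs_plus, "v0_cs_plus")
  check_range(v0_cs_minus, "v0_cs_minus")
  structure(
    list(alpha = alpha, rho = rho, variant = variant,
         v0_cs_plus = v0_cs_plus, v0_cs_minus = v0_cs_minus),
    class = "model_params"
  )
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf("<model_params> %s: alpha = %.4g", x$variant, x$alpha))
  if (x$variant == "instructed") cat(sprintf(", rho = %.4g", x$rho))
  cat(sprintf(", V0 = (%.3g, %.3g)\n", x$v0_cs_plus, x$v0_cs_minus))
  invisible(x)
}

#' One Rescorla-Wagner update
#'
#' The presented cue's expected value moves toward the outcome by a fraction
#' `alpha` of the prediction error: `delta = r - v`, `v_next = v + alpha *
#' delta`. Vectorized over all arguments.
#'
#' @param v Current EV of the presented cue, in `[0, 1]`.
#' @param r Outcome: 1 for shock, 0 for no shock.
#' @param alpha Learning rate in `[0, 1]`.
#' @return A tibble with columns `v_next` and `delta`.
#' @export
#' @examples
#' rw_update(v = 0.5, r = 1, alpha = 0.061)
rw_update <- function(v, r, alpha) {
  check_range(v, "v")
  if (!all(r %in% c(0, 1))) stopf("`r` must be 0 or 1.")
  check_range(alpha, "alpha")
  delta <- r - v
  tibble(v_next = v + alpha * delta, delta = delta)
}

#' Instructed mixing of the two cues' expected values
#'
#' At an instruction event each cue's EV becomes a `rho`-weighted mixture of
#' the two current values: `v_a_next = rho * v_b + (1 - rho) * v_a` and
#' symmetrically for `v_b`. The transform conserves `v_a + v_b` for every
#' `rho`; `rho = 0` is the identity and `rho = 1` a complete swap.
#'
#' @param v_a,v_b Current EVs of the two cues, in `[0, 1]`.
#' @param rho Mixing weight in `[0, 1]`.
#' @return A tibble with columns `v_a_next`, `v_b_next`.
#' @export
#' @examples
#' instructed_swap(0.8, 0.2, rho = 1)
instructed_swap <- function(v_a, v_b, rho) {
  check_range(v_a, "v_a")
  check_range(v_b, "v_b")
  check_range(rho, "rho")
  tibble(v_a_next = rho * v_b + (1 - rho) * v_a,
         v_b_next = rho * v_a + (1 - rho) * v_b)
}

#' Closed-form EV after repeated identical outcomes
#'
#' Iterating the Rescorla-Wagner update with a constant outcome `r` has the
#' closed form `v_n = r + (v0 - r) * (1 - alpha)^n`: EV decays geometrically toward
#' the outcome. Used as an analytic oracle for the iterated update.
#'
#' @param v0 Starting EV in `[0, 1]`.
#' @param alpha Learning rate in `[0, 1]`.
#' @param r Constant outcome, 0 or 1.
#' @param n Number of updates (non-negative integer).
#' @return The EV after `n` updates.
#' @export
closed_form_ev <- function(v0, alpha, r, n) {
  check_range(v0, "v0")
  check_range(alpha, "alpha")
  if (!all(r %in% c(0, 1))) stopf("`r` must be 0 or 1.")
  if (any(n < 0)) stopf("`n` must be non-negative.")
  r + (v0 - r) * (1 - alpha)^n
}

# Compact per-sequence state reused by the fast EV recursion: integer cue
# index (1 = cue A, 2 = cue B), numeric outcome vector, trial positions after
# which an instruction event occurs, and which cue is the original CS+.
seq_cache <- function(seq) {
  instr <- attr(seq, "instructions")
  list(
    cue_idx = ifelse(seq$cue == "A", 1L, 2L),
    us = as.numeric(seq$us),
    swap_after = if (is.null(instr)) integer() else
      instr$after_trial[instr$after_trial < nrow(seq)],
    a_is_original_plus = {
      i <- which(seq$original_role == "CS+")[1]
      seq$cue[i] == "A"
    }
  )
}

# Fast EV recursion over a cached sequence; returns per-trial vectors. Only
# the presented cue updates each trial; for the instructed variant both cues
# mix immediately after each instruction event's preceding trial. The loop
# runs in compiled code: it is the inner kernel of the fitting objective.
ev_recursion <- function(cache, alpha, rho, v0_plus, v0_minus, instructed) {
  v0 <- if (cache$a_is_original_plus) c(v0_plus, v0_minus) else c(v0_minus, v0_plus)
  .ev_recursion_cpp(cache$cue_idx, cache$us, cache$swap_after,
                    alpha, if (is.na(rho)) 0 else rho, v0[1], v0[2],
                    isTRUE(instructed))
}

#' Simulate a trial-by-trial expected-value trace
#'
#' Runs the learning model over a trial sequence: each trial the presented
#' cue's EV is read at onset, the prediction error `delta = r - V` is computed
#' at outcome, and the presented cue updates by `alpha * delta`. For the
#' instructed variant, the two cues' EVs are mixed by `rho` exactly once
#' immediately after each instruction event's preceding trial; the feedback
#' variant ignores instruction events.
#'
#' @param seq A `trial_sequence`.
#' @param params A [model_params()] object.
#' @return A tibble of class `ev_trace` with columns `trial`, `cue`, `role`,
#'   `us`, `v_presented` (EV of the shown cue at onset), `delta`, and `v_a`,
#'   `v_b` (both cues' EVs after the trial's update and any instruction
#'   event).
#' @export
#' @examples
#' seq1 <- generate_trial_sequence(task_config(), 1)
#' trace <- simulate_ev_trace(seq1, model_params(0.061, 0.943))
#' head(trace)
simulate_ev_trace <- function(seq, params) {
  if (!inherits(params, "model_params")) {
    stopf("`params` must be created with model_params().")
  }
  cache <- seq_cache(seq)
  instructed <- params$variant == "instructed"
  tr <- ev_recursion(cache, params$alpha, if (instructed) params$rho else 0,
                     params$v0_cs_plus, params$v0_cs_minus, instructed)
  out <- tibble(
    trial = seq$trial, cue = seq$cue, role = seq$role, us = seq$us,
    v_presented = tr$v_presented, delta = tr$delta,
    v_a = tr$v_a, v_b = tr$v_b
  )
  structure(out,
            params = params,
            instructions = attr(seq, "instructions"),
            class = c("ev_trace", class(out)))
}

#' Export an EV trace as TSV
#'
#' Writes the per-trial EV/PE table for use as fMRI modulators or fitting
#' regressors.
#'
#' @param trace An `ev_trace`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_ev_trace <- function(trace, path) {
  write.table(as.data.frame(trace), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
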