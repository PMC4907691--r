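#' Tidy a fitted learning model
#'
#' @param x An `rw_fit`.
#' @param ... Unused.
#' @return One row per fitted learning parameter: `term`, `estimate`.
#' @export
tidy.rw_fit <- function(x, ...) {
  out <- tibble(term = "alpha", estimate = x$params$alpha)
  if (x$variant == "instructed") {
    out <- bind_rows(out, tibble(term = "rho", estimate = x$params$rho))
  }
  out
}

#' @rdname tidy.rw_fit
#' @return For `glance()`: a one-row model summary (`sse`, `deviance`,
#'   `n_obs`, `n_subjects`, `variant`, `fit_mode`).
#' @export
glance.rw_fit <- function(x, ...) {
  tibble(sse = x$sse,
         deviance = if (x$degenerate_sse) NA_real_ else x$deviance,
         n_obs = x$n_obs, n_subjects = x$n_subjects,
         variant = x$variant, fit_mode = x$fit_mode)
}

#' Tidy a two-level SCR analysis
#'
#' The `scr_lmm` object is already a tidy effect table; `tidy()` strips the
#' attributes and returns it as a plain tibble.
#'
#' @param x An `scr_lmm` from [fit_two_level()].
#' @param ... Unused.
#' @export
tidy.scr_lmm <- function(x, ...) {
  as_tibble(as.data.frame(x))
}
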