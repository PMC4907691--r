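#' Expected-value regressor for one subject
#'
#' The per-trial EV of the presented cue at onset, under a candidate
#' parameter set applied to the subject's trial order — the model-derived
#' predictor that trial-level SCR is regressed on.
#'
#' @param seq A `trial_sequence`.
#' @param params A [model_params()] object.
#' @return A numeric vector, one EV per trial.
#' @export
ev_regressor <- function(seq, params) {
  simulate_ev_trace(seq, params)$v_presented
}

#' Fitting options
#'
#' @param restarts Number of simplex restarts from dispersed starting points
#'   for the two-parameter instructed fit.
#' @param restart_seed Optional seed; when supplied, starting points are drawn
#'   uniformly in the unconstrained (logit) space instead of using the fixed
#'   dispersed grid. Lets restart robustness be checked across independent
#'   start sets.
#' @param maxit,reltol Simplex iteration cap and relative tolerance.
#' @param v0 Optional length-2 numeric `c(v0_cs_plus, v0_cs_minus)` overriding
#'   the variant's default initial values (used e.g. for nesting checks with
#'   matched V0).
#' @return An object of class `fit_options`.
#' @export
fit_options <- function(restarts = 10L, restart_seed = NULL,
                        maxit = 500L, reltol = 1e-10, v0 = NULL) {
  if (!is.null(v0)) {
    if (length(v0) != 2L) stopf("`v0` must be c(v0_cs_plus, v0_cs_minus).")
    check_range(v0, "v0")
  }
  structure(list(restarts = as.integer(restarts), restart_seed = restart_seed,
                 maxit = as.integer(maxit), reltol = reltol, v0 = v0),
            class = "fit_options")
}

# Logistic reparameterization keeping alpha, rho in (0, 1) while the simplex
# search runs unconstrained.
to_unit <- function(x) 1 / (1 + exp(-x))
from_unit <- function(p) log(p / (1 - p))

# Assemble the per-subject response vectors and cached sequences the
# objective needs, once per fit. `data` must have columns subject,
# trial_order, trial and the response column; rows are ordered by trial
# within subject.
fit_data <- function(data, seqs, response, drop_degenerate = TRUE) {
  check_cols(data, c("subject", "trial_order", "trial", response), "fit")
  if (inherits(seqs, "trial_sequence")) seqs <- list(seqs)
  caches <- purrr::map(seqs, seq_cache)
  subjects <- split(data[order(data$subject, data$trial), ],
                    data$subject[order(data$subject, data$trial)])
  keep <- list()
  for (d in subjects) {
    y <- d[[response]]
    if (anyNA(y)) stopf("Response column contains NA for subject %s.",
                        d$subject[1])
    if (drop_degenerate && all(y == 0)) {
      warn(sprintf("Subject %s has all-zero responses; excluded from fitting.",
                   d$subject[1]))
      next
    }
    ord <- d$trial_order[1]
    if (length(caches[[ord]]$us) != length(y)) {
      stopf("Subject %s: response length does not match its trial order.",
            d$subject[1])
    }
    keep[[length(keep) + 1L]] <- list(subject = d$subject[1], y = y, order = ord)
  }
  if (!length(keep)) stopf("No analyzable subjects.")
  list(subjects = keep, caches = caches)
}

# Pooled SSE across subjects for candidate (alpha, rho): per subject an OLS of
# the response on (intercept + EV regressor), predictions concatenated,
# residuals aggregated. EV traces are computed once per distinct trial order.
pooled_sse <- function(fd, alpha, rho, v0, instructed, coefs = FALSE) {
  evs <- purrr::map(fd$caches, function(ca) {
    ev_recursion(ca, alpha, rho, v0[1], v0[2], instructed)$v_presented
  })
  sse <- 0
  cf <- if (coefs) vector("list", length(fd$subjects)) else NULL
  for (i in seq_along(fd$subjects)) {
    s <- fd$subjects[[i]]
    x <- evs[[s$order]]
    y <- s$y
    mx <- mean(x); my <- mean(y)
    sxx <- sum((x - mx)^2)
    sxy <- sum((x - mx) * (y - my))
    syy <- sum((y - my)^2)
    if (sxx > 1e-300) {
      b <- sxy / sxx
      sse <- sse + max(syy - b * sxy, 0)
    } else {
      b <- 0
      sse <- sse + syy
    }
    if (coefs) {
      cf[[i]] <- tibble(subject = s$subject, intercept = my - b * mx, slope = b)
    }
  }
  if (coefs) list(sse = sse, coefficients = bind_rows(cf)) else sse
}

#' Across-subjects objective: aggregated residual sum of squares
#'
#' For a candidate parameter set, each subject's EV regressor is generated on
#' that subject's trial order, ordinary least squares determines a per-subject
#' intercept and slope, and the concatenated predictions are compared with the
#' concatenated data. Learning parameters are thereby treated as fixed within
#' the cohort while response scaling varies by subject.
#'
#' @param params A [model_params()] object (the candidate).
#' @param data Cohort table with `subject`, `trial_order`, `trial` and the
#'   response column.
#' @param seqs List of trial orders referenced by `data$trial_order`.
#' @param response Name of the response column (default `"normalized"`).
#' @return The total sum of squared errors. Errors on a degenerate
#'   (zero-variance) EV regressor, reporting the subject.
#' @export
across_subjects_objective <- function(params, data, seqs,
                                      response = "normalized") {
  fd <- fit_data(data, seqs, response)
  instructed <- params$variant == "instructed"
  for (s in fd$subjects) {
    ev <- ev_recursion(fd$caches[[s$order]], params$alpha,
                       if (instructed) params$rho else 0,
                       params$v0_cs_plus, params$v0_cs_minus, instructed)$v_presented
    if (var(ev) < 1e-14) {
      stopf("Degenerate EV regressor (zero variance) for subject %s.",
            s$subject)
    }
  }
  pooled_sse(fd, params$alpha, if (instructed) params$rho else 0,
             c(params$v0_cs_plus, params$v0_cs_minus), instructed)
}

# Fixed dispersed starting grid for the 2-parameter search (alpha, rho).
start_grid <- function(restarts, restart_seed) {
  if (!is.null(restart_seed)) {
    return(withr::with_seed(as.integer(restart_seed), {
      tibble(alpha = to_unit(runif(restarts, -4, 2)),
             rho = to_unit(runif(restarts, -4, 4)))
    }))
  }
  base <- tibble(
    alpha = c(0.01, 0.03, 0.06, 0.10, 0.15, 0.25, 0.40, 0.06, 0.10, 0.20),
    rho = c(0.05, 0.50, 0.95, 0.30, 0.70, 0.10, 0.90, 0.98, 0.02, 0.50)
  )
  base[rep(seq_len(nrow(base)), length.out = restarts), ]
}

# Internal driver shared by across- and within-subject fitting.
fit_engine <- function(fd, variant, options) {
  instructed <- variant == "instructed"
  v0 <- options$v0 %||% if (instructed) c(0.75, 0.25) else c(0.5, 0.5)
  obj_sse <- function(alpha, rho) pooled_sse(fd, alpha, rho, v0, instructed)

  if (!instructed) {
    opt <- optimize(function(a) obj_sse(a, 0), interval = c(1e-6, 1 - 1e-6),
                    tol = 1e-10)
    trace <- tibble(start_alpha = NA_real_, start_rho = NA_real_,
                    alpha = opt$minimum, rho = NA_real_,
                    sse = opt$objective, convergence = 0L)
    best <- list(alpha = opt$minimum, rho = NA_real_, sse = opt$objective)
  } else {
    starts <- start_grid(options$restarts, options$restart_seed)
    runs <- purrr::map_dfr(seq_len(nrow(starts)), function(i) {
      p0 <- c(from_unit(starts$alpha[i]), from_unit(starts$rho[i]))
      o <- optim(p0, function(p) obj_sse(to_unit(p[1]), to_unit(p[2])),
                 method = "Nelder-Mead",
                 control = list(maxit = options$maxit, reltol = options$reltol))
      tibble(start_alpha = starts$alpha[i], start_rho = starts$rho[i],
             alpha = to_unit(o$par[1]), rho = to_unit(o$par[2]),
             sse = o$value, convergence = o$convergence)
    })
    if (all(!is.finite(runs$sse))) {
      stopf("All simplex restarts returned a non-finite objective.")
    }
    if (all(runs$convergence != 0L)) {
      warn("No simplex restart reported convergence; returning the best endpoint.")
    }
    trace <- runs
    b <- runs[which.min(runs$sse), ]
    best <- list(alpha = b$alpha, rho = b$rho, sse = b$sse)
  }

  final <- pooled_sse(fd, best$alpha, if (instructed) best$rho else 0, v0,
                      instructed, coefs = TRUE)
  n_obs <- sum(vapply(fd$subjects, function(s) length(s$y), integer(1)))
  params <- model_params(
    alpha = best$alpha,
    rho = if (instructed) best$rho else NULL,
    variant = variant, v0_cs_plus = v0[1], v0_cs_minus = v0[2])
  structure(
    list(params = params,
         coefficients = final$coefficients,
         sse = final$sse,
         deviance = if (final$sse > 0) gaussian_deviance(final$sse, n_obs) else NA_real_,
         degenerate_sse = final$sse <= 0,
         n_obs = n_obs,
         n_subjects = length(fd$subjects),
         variant = variant,
         fit_mode = if (length(fd$subjects) > 1L) "across" else "within",
         optimizer = trace,
         options = options),
    class = "rw_fit")
}

#' Fit the learning model across subjects
#'
#' Minimizes [across_subjects_objective()] over the learning parameters —
#' `alpha` for the feedback variant, `(alpha, rho)` for the instructed
#' variant — with learning parameters fixed across the cohort and per-subject
#' intercepts and slopes free. The two-parameter search is a derivative-free
#' Nelder-Mead simplex in logistic-transformed coordinates (so estimates stay
#' in `[0, 1]`) restarted from dispersed starting points; the one-parameter
#' feedback fit uses bounded golden-section search.
#'
#' @inheritParams across_subjects_objective
#' @param variant `"instructed"` or `"feedback"`.
#' @param options A [fit_options()] object.
#' @return An object of class `rw_fit`: fitted `params`, per-subject
#'   `coefficients`, pooled `sse`, Gaussian `deviance`, and the full restart
#'   `optimizer` trace. Subjects with all-zero responses are excluded with a
#'   warning.
#' @export
#' @examples
#' cohort <- simulate_cohort(canonical_orders(),
#'   gen_params(n_subjects = 4, p_nonlearner = 0, seed = 7))
#' scored <- transform_normalize(cohort)
#' fit <- fit_across_subjects(scored, canonical_orders(), "instructed",
#'   options = fit_options(restarts = 2))
#' tidy(fit)
fit_across_subjects <- function(data, seqs, variant = c("instructed", "feedback"),
                                response = "normalized",
                                options = fit_options()) {
  variant <- match.arg(variant)
  fd <- fit_data(data, seqs, response)
  fit_engine(fd, variant, options)
}

#' Fit the learning model to a single subject
#'
#' Identical machinery to [fit_across_subjects()] with one subject: learning
#' parameters and one (intercept, slope) pair are identified from that
#' subject's data alone.
#'
#' @param data One subject's trial table (columns `trial`, the response, and
#'   optionally `subject` / `trial_order`).
#' @param seq The subject's `trial_sequence`.
#' @inheritParams fit_across_subjects
#' @return An `rw_fit` with `fit_mode = "within"`.
#' @export
fit_within_subject <- function(data, seq, variant = c("instructed", "feedback"),
                               response = "normalized",
                               options = fit_options()) {
  variant <- match.arg(variant)
  if (!"subject" %in% names(data)) data$subject <- 1L
  data$trial_order <- 1L  # the single supplied sequence
  fd <- fit_data(data, list(seq), response)
  if (length(fd$subjects) != 1L) {
    stopf("fit_within_subject() expects exactly one subject.")
  }
  fit_engine(fd, variant, options)
}

#' Fit every subject of a cohort separately
#'
#' @param data Cohort table (`subject`, `trial_order`, `trial`, response).
#' @param seqs List of trial orders.
#' @inheritParams fit_across_subjects
#' @return A tibble with one row per analyzable subject: `subject`, `alpha`,
#'   `rho`, `intercept`, `slope`, `sse`, `deviance`.
#' @export
fit_within_subjects <- function(data, seqs, variant = c("instructed", "feedback"),
                                response = "normalized",
                                options = fit_options()) {
  variant <- match.arg(variant)
  check_cols(data, c("subject", "trial_order"), "fit_within_subjects")
  if (inherits(seqs, "trial_sequence")) seqs <- list(seqs)
  purrr::map_dfr(split(data, data$subject), function(d) {
    f <- tryCatch(
      fit_within_subject(d, seqs[[d$trial_order[1]]], variant, response, options),
      error = function(e) NULL)
    if (is.null(f)) return(tibble())
    tibble(subject = d$subject[1], alpha = f$params$alpha,
           rho = f$params$rho,
           intercept = f$coefficients$intercept[1],
           slope = f$coefficients$slope[1],
           sse = f$sse, deviance = f$deviance)
  })
}

#' Gaussian deviance from a residual sum of squares
#'
#' `-2` times the maximized Gaussian log-likelihood with the variance at its
#' maximum-likelihood value: `N * log(2 * pi * SSE / N) + N` for `N` fitted
#' observations. Reported alongside the raw SSE so either can be compared
#' across models.
#'
#' @param sse Residual sum of squares (must be positive).
#' @param n Number of fitted observations.
#' @return The deviance.
#' @export
gaussian_deviance <- function(sse, n) {
  if (sse <= 0) {
    stopf(paste0("gaussian_deviance(): SSE is zero (degenerate noiseless ",
                 "fit); the Gaussian deviance is undefined."))
  }
  n * log(2 * pi * sse / n) + n
}

#' @export
deviance.rw_fit <- function(object, ...) {
  if (object$degenerate_sse) {
    stopf("deviance(): fit has SSE = 0 (degenerate noiseless case).")
  }
  object$deviance
}

#' @export
print.rw_fit <- function(x, ...) {
  cat(sprintf("<rw_fit> %s model, %s-subjects fit\n", x$variant, x$fit_mode))
  cat(sprintf("  alpha = %.4f", x$params$alpha))
  if (x$variant == "instructed") cat(sprintf("  rho = %.4f", x$params$rho))
  cat(sprintf("\n  SSE = %.6g over %d observations (%d subjects)",
              x$sse, x$n_obs, x$n_subjects))
  if (!x$degenerate_sse) cat(sprintf("; deviance = %.4g", x$deviance))
  cat("\n")
  invisible(x)
}

#' Compare instructed-reversal parameters between groups
#'
#' Two-sample pooled-variance t-test on within-subject `rho` estimates from
#' the two groups, the test of whether instructions produced measurably more
#' value reversal in the instructed group.
#'
#' @param rho_instructed,rho_uninstructed Numeric vectors of within-subject
#'   `rho` estimates, or tibbles from [fit_within_subjects()] with a `rho`
#'   column.
#' @return A one-row tibble: `t`, `df` (`n1 + n2 - 2`), `p_value`, and group
#'   means/SDs/sizes.
#' @export
compare_rho_groups <- function(rho_instructed, rho_uninstructed) {
  pull_rho <- function(x) {
    if (is.data.frame(x)) {
      check_cols(x, "rho", "compare_rho_groups")
      x$rho
    } else as.numeric(x)
  }
  r1 <- pull_rho(rho_instructed)
  r2 <- pull_rho(rho_uninstructed)
  if (length(r1) < 2L || length(r2) < 2L) {
    stopf("compare_rho_groups(): need at least 2 subjects per group.")
  }
  pooled <- ((length(r1) - 1) * var(r1) + (length(r2) - 1) * var(r2)) /
    (length(r1) + length(r2) - 2)
  if (pooled <= 0) stopf("compare_rho_groups(): zero pooled variance.")
  ht <- t.test(r1, r2, var.equal = TRUE)
  tibble(
    t = unname(ht$statistic), df = unname(ht$parameter),
    p_value = ht$p.value,
    mean_instructed = mean(r1), sd_instructed = sd(r1), n_instructed = length(r1),
    mean_uninstructed = mean(r2), sd_uninstructed = sd(r2),
    n_uninstructed = length(r2)
  )
}
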