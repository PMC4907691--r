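test_that("EV regressors nest, initialize at V0, and freeze at alpha = 0", {
  fb <- model_params(0.12, variant = "feedback")
  ins0 <- model_params(0.12, rho = 0, v0_cs_plus = 0.5, v0_cs_minus = 0.5)
  expect_equal(ev_regressor(fix_seq, ins0), ev_regressor(fix_seq, fb))
  # alpha = 0: constant per cue except at instruction swaps
  r <- ev_regressor(fix_seq, model_params(0, rho = 1))
  expect_equal(r[1], if (fix_seq$original_role[1] == "CS+") 0.75 else 0.25)
  vals <- sort(unique(round(r, 12)))
  expect_equal(vals, c(0.25, 0.75))
  # first-trial value equals V0 of the presented cue
  r2 <- ev_regressor(fix_seq, model_params(0.3, rho = 0.5,
                                           v0_cs_plus = 0.6,
                                           v0_cs_minus = 0.1))
  expect_equal(r2[1], if (fix_seq$original_role[1] == "CS+") 0.6 else 0.1)
})

test_that("the across-subjects objective is an aggregated per-subject OLS", {
  co <- quick_cohort(alpha = 0.06, rho = 0.94, noise_sd = 0, seed = 3)
  truth <- model_params(0.06, 0.94)
  expect_lt(across_subjects_objective(truth, co, fix_orders,
                                      response = "amplitude_uS"), 1e-10)
  # zero-slope subjects: SSE at any candidate equals total variance about
  # per-subject means
  g0 <- gen_params(model = model_params(0.06, 0.9), slope_mean = 0,
                   slope_sd = 0, habituation_slope = 0, noise_sd = 0.1,
                   p_nonlearner = 0, n_subjects = 5, seed = 8)
  co0 <- simulate_cohort(fix_orders, g0)
  sse <- across_subjects_objective(model_params(0.2, 0.5), co0, fix_orders,
                                   response = "amplitude_uS")
  per_subject_tv <- co0 |>
    dplyr::group_by(subject) |>
    dplyr::summarise(tv = sum((amplitude_uS - mean(amplitude_uS))^2))
  # OLS can only reduce variance below the per-subject total
  expect_lte(sse, sum(per_subject_tv$tv))
  expect_gt(sse, 0.95 * sum(per_subject_tv$tv))
  # degenerate zero-variance regressor is reported
  expect_error(
    across_subjects_objective(model_params(0, variant = "feedback"), co,
                              fix_orders, response = "amplitude_uS"),
    "Degenerate")
})

test_that("noiseless cohorts are recovered exactly by both fit modes", {
  co <- quick_cohort(alpha = 0.06, rho = 0.94, noise_sd = 0, seed = 5)
  f <- fit_across_subjects(co, fix_orders, "instructed",
                           response = "amplitude_uS",
                           options = fit_options(restarts = 4))
  expect_equal(f$params$alpha, 0.06, tolerance = 1e-3)
  expect_equal(f$params$rho, 0.94, tolerance = 1e-3)
  expect_lt(f$sse, 1e-8)
  expect_true(f$degenerate_sse || f$sse > 0)
  # within-subject: one coefficient pair, exact self-fit
  one <- co[co$subject == 1, ]
  fw <- fit_within_subject(one, fix_orders[[1]], "instructed",
                           response = "amplitude_uS",
                           options = fit_options(restarts = 4))
  expect_equal(nrow(fw$coefficients), 1)
  expect_equal(fw$params$alpha, 0.06, tolerance = 1e-3)
  expect_equal(fw$fit_mode, "within")
  truth <- attr(co, "manifest")
  expect_equal(fw$coefficients$slope, truth$slope[1], tolerance = 1e-3)
})

test_that("estimates are invariant to duplication and per-subject rescaling", {
  co <- quick_cohort(alpha = 0.1, rho = 0.6, noise_sd = 0.05, n_subjects = 4,
                     seed = 9)
  opts <- fit_options(restarts = 3)
  f1 <- fit_across_subjects(co, fix_orders, "instructed",
                            response = "amplitude_uS", options = opts)
  dup <- dplyr::bind_rows(co, dplyr::mutate(co, subject = subject + 100L))
  f2 <- fit_across_subjects(dup, fix_orders, "instructed",
                            response = "amplitude_uS", options = opts)
  expect_equal(f2$params$alpha, f1$params$alpha, tolerance = 1e-5)
  expect_equal(f2$params$rho, f1$params$rho, tolerance = 1e-5)
  expect_equal(f2$sse, 2 * f1$sse, tolerance = 1e-6)
  # an affine change of the response scale is absorbed by the per-subject
  # intercept and slope: the objective scales by the slope factor squared
  resc <- dplyr::mutate(co, amplitude_uS = 3 * amplitude_uS + 1)
  cand <- model_params(0.08, 0.5)
  expect_equal(
    across_subjects_objective(cand, resc, fix_orders,
                              response = "amplitude_uS"),
    9 * across_subjects_objective(cand, co, fix_orders,
                                  response = "amplitude_uS"),
    tolerance = 1e-10)
  f3 <- fit_across_subjects(resc, fix_orders, "instructed",
                            response = "amplitude_uS", options = opts)
  expect_equal(f3$params$alpha, f1$params$alpha, tolerance = 1e-4)
  expect_equal(f3$params$rho, f1$params$rho, tolerance = 1e-4)
})

test_that("the deviance follows the Gaussian -2 logLik formula", {
  expect_equal(gaussian_deviance(2, 100), 100 * log(2 * pi * 2 / 100) + 100)
  # scaling SSE by c shifts deviance by N log c
  expect_equal(gaussian_deviance(6, 50) - gaussian_deviance(2, 50),
               50 * log(3))
  # doubling N with duplicated data follows the formula directly
  expect_equal(gaussian_deviance(4, 200),
               200 * log(2 * pi * 4 / 200) + 200)
  expect_error(gaussian_deviance(0, 10), "degenerate")
  co <- quick_cohort(alpha = 0.08, rho = 0.5, noise_sd = 0.1, n_subjects = 3,
                     seed = 12)
  f <- fit_across_subjects(co, fix_orders, "instructed",
                           response = "amplitude_uS",
                           options = fit_options(restarts = 2))
  expect_equal(deviance(f), gaussian_deviance(f$sse, f$n_obs))
})

test_that("restart sets agree on the optimum", {
  co <- quick_cohort(alpha = 0.07, rho = 0.8, noise_sd = 0.08, n_subjects = 4,
                     seed = 14)
  f1 <- fit_across_subjects(co, fix_orders, "instructed",
                            response = "amplitude_uS",
                            options = fit_options(restart_seed = 1))
  f2 <- fit_across_subjects(co, fix_orders, "instructed",
                            response = "amplitude_uS",
                            options = fit_options(restart_seed = 2))
  expect_lt(abs(f1$sse - f2$sse), 1e-6)
})

test_that("all-zero subjects are excluded with a warning", {
  co <- quick_cohort(alpha = 0.06, rho = 0.9, noise_sd = 0.05, n_subjects = 3,
                     seed = 15)
  co$amplitude_uS[co$subject == 2] <- 0
  expect_warning(
    f <- fit_across_subjects(co, fix_orders, "instructed",
                             response = "amplitude_uS",
                             options = fit_options(restarts = 2)),
    "all-zero")
  expect_equal(f$n_subjects, 2)
})

test_that("group comparison of rho reports a pooled two-sample test", {
  set.seed(7)
  r1 <- pmin(1, pmax(0, rnorm(20, 0.8, 0.2)))
  r2 <- pmin(1, pmax(0, rnorm(20, 0.1, 0.15)))
  cmp <- compare_rho_groups(r1, r2)
  expect_equal(cmp$df, 38)
  expect_lt(cmp$p_value, 0.001)
  expect_equal(cmp$mean_instructed, mean(r1))
  # identical groups: t = 0
  cmp0 <- compare_rho_groups(r1, r1)
  expect_equal(cmp0$t, 0)
  expect_error(compare_rho_groups(rep(0.5, 5), rep(0.5, 5)), "pooled variance")
  expect_error(compare_rho_groups(0.5, r2), "at least 2")
})
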