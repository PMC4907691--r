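test_that("a noiseless unit-slope subject reproduces the EV trace exactly", {
  g <- gen_params(model = model_params(0.07, 0.9),
                  slope_mean = 1, slope_sd = 0, intercept_mean = 0,
                  intercept_sd = 0, habituation_slope = 0, noise_sd = 0,
                  p_nonlearner = 0)
  a <- simulate_subject_amplitudes(fix_seq, g, subject_seed = 4)
  tr <- simulate_ev_trace(fix_seq, g$model)
  expect_equal(a$amplitude_uS, tr$v_presented)
  expect_equal(which(!is.na(a$us_amplitude_uS)), which(fix_seq$us == 1))
})

test_that("cohorts are reproducible and carry true parameters", {
  g <- gen_params(n_subjects = 6, seed = 21)
  a <- simulate_cohort(fix_orders, g)
  b <- simulate_cohort(fix_orders, g)
  expect_identical(as.data.frame(a), as.data.frame(b))
  man <- attr(a, "manifest")
  expect_equal(nrow(man), 6)
  expect_equal(man$trial_order, rep(c(1L, 2L), 3))
  expect_true(all(c("intercept", "slope", "nonlearner") %in% names(man)))
  expect_true(all(a$amplitude_uS >= 0))
})

test_that("group labels follow the generating model variant", {
  gi <- gen_params(model = model_params(0.06, 0.9), n_subjects = 2)
  gu <- gen_params(model = model_params(0.06, variant = "feedback"),
                   n_subjects = 2)
  expect_equal(unique(simulate_cohort(fix_orders, gi)$group), "instructed")
  expect_equal(unique(simulate_cohort(fix_orders, gu)$group), "uninstructed")
})

test_that("the non-learner mixture hits its expected rate", {
  g <- gen_params(p_nonlearner = 0.5, n_subjects = 200, seed = 31)
  man <- attr(simulate_cohort(fix_orders, g), "manifest")
  k <- sum(man$nonlearner)
  # binomial(200, .5): +-4 SD band
  expect_gt(k, 100 - 4 * sqrt(200 * 0.25))
  expect_lt(k, 100 + 4 * sqrt(200 * 0.25))
})

test_that("a zero-slope cohort shows no differential responding in expectation", {
  g <- gen_params(model = model_params(0.06, 0.9), slope_mean = 0,
                  slope_sd = 0, habituation_slope = 0, noise_sd = 0.1,
                  p_nonlearner = 0, n_subjects = 100, seed = 41)
  co <- simulate_cohort(fix_orders, g)
  roles <- purrr::imap_dfr(fix_orders, function(s, i) {
    tibble::tibble(trial_order = i, trial = s$trial, role = s$role, us = s$us)
  })
  d <- dplyr::inner_join(co, roles, by = c("trial_order", "trial")) |>
    dplyr::filter(us == 0)
  diff <- mean(d$amplitude_uS[d$role == "CS+"]) -
    mean(d$amplitude_uS[d$role == "CS-"])
  se <- 2 * 0.1 / sqrt(nrow(d) / 2)
  expect_lt(abs(diff), 4 * se)
})

test_that("a full-reversal cohort reverses in the pre-reinforcement window", {
  g <- gen_params(model = model_params(0.06, 1), noise_sd = 0.02,
                  habituation_slope = 0, p_nonlearner = 0,
                  n_subjects = 100, seed = 51)
  co <- simulate_cohort(fix_orders, g)
  w <- purrr::imap_dfr(fix_orders, function(s, i) {
    dplyr::mutate(instruction_windows(s), trial_order = i)
  })
  d <- dplyr::inner_join(co, w, by = c("trial_order", "trial")) |>
    dplyr::filter(phase == "post")
  m_new_plus <- mean(d$amplitude_uS[d$post_role == "CS+"])
  m_new_minus <- mean(d$amplitude_uS[d$post_role == "CS-"])
  expect_gt(m_new_plus, m_new_minus)
})

test_that("waveform rendering is flat without responses and errors on mismatch", {
  short <- fix_seq[1:3, ]
  attr(short, "config") <- fix_config
  attr(short, "instructions") <- instruction_events(fix_seq)[0, ]
  amps <- tibble::tibble(subject = 1L, trial = 1:3, amplitude_uS = 0,
                         us_amplitude_uS = NA_real_)
  wf <- simulate_waveform(amps, short, waveform_params(), seed = 1)
  expect_true(all(wf$conductance_uS == wf$conductance_uS[1]))
  expect_error(simulate_waveform(amps[1:2, ], short), "mismatch")
})

test_that("waveforms round-trip through CSV plus JSON sidecar", {
  short <- fix_seq[1:2, ]
  attr(short, "config") <- fix_config
  attr(short, "instructions") <- instruction_events(fix_seq)[0, ]
  amps <- tibble::tibble(subject = 1L, trial = 1:2,
                         amplitude_uS = c(0.4, 0.2),
                         us_amplitude_uS = NA_real_)
  wf <- simulate_waveform(amps, short, waveform_params(), seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_waveform(wf, path)
  back <- read_waveform(path)
  expect_equal(attr(back, "rate_hz"), 200)
  expect_equal(back$conductance_uS, wf$conductance_uS, tolerance = 1e-8)
})
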