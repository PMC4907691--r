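make_wave <- function(x, rate = 200) {
  structure(tibble::tibble(time_s = (seq_along(x) - 1) / rate,
                           conductance_uS = x),
            rate_hz = rate, class = c("scr_waveform", "tbl_df", "tbl",
                                      "data.frame"))
}

test_that("preprocessing preserves DC, attenuates 50 Hz, and is zero-phase", {
  t <- seq(0, 10, by = 1 / 200)
  # constant input -> constant output (unit DC gain)
  flat <- preprocess_waveform(make_wave(rep(2.5, length(t))))
  expect_equal(flat$conductance_uS, rep(2.5, length(t)), tolerance = 1e-9)
  # 50 Hz sinusoid attenuated by > 20 dB (25 Hz cutoff)
  sine <- preprocess_waveform(make_wave(sin(2 * pi * 50 * t)))
  mid <- seq(1000, length(t) - 1000)
  gain <- max(abs(sine$conductance_uS[mid]))
  expect_lt(20 * log10(gain), -20)
  # impulse response is symmetric around its peak (zero phase)
  imp <- numeric(4001); imp[2001] <- 1
  y <- preprocess_waveform(make_wave(imp))$conductance_uS
  expect_equal(which.max(y), 2001)
  expect_equal(y[2001 + 1:50], y[2001 - 1:50], tolerance = 1e-9)
  # non-uniform sampling is rejected
  bad <- make_wave(rep(1, 100))
  bad$time_s[50] <- bad$time_s[50] + 0.001
  expect_error(preprocess_waveform(bad), "uniform")
})

test_that("base-to-peak scoring finds responses in the latency window", {
  rate <- 200
  t <- seq(0, 30, by = 1 / rate)
  base <- rep(2, length(t))
  # flat waveform scores 0
  expect_equal(score_trial(make_wave(base), onset_s = 5), 0)
  # clean impulse of amplitude 0.5 at latency 1.5 s scores ~0.5
  shape <- function(amp, t0) {
    amp * pavlovr:::scr_impulse(t - t0, 0.75, 2)
  }
  w <- preprocess_waveform(make_wave(base + shape(0.5, 6.5)))
  expect_equal(score_trial(w, onset_s = 5), 0.5, tolerance = 0.01)
  # sub-threshold response floors to zero
  w2 <- preprocess_waveform(make_wave(base + shape(0.015, 6.5)))
  expect_equal(score_trial(w2, onset_s = 5), 0)
  # response outside the window is not scored
  w3 <- preprocess_waveform(make_wave(base + shape(0.5, 10.5)))
  expect_equal(score_trial(w3, onset_s = 5), 0)
  # window beyond the recording raises
  expect_error(score_trial(make_wave(base), onset_s = 29), "exceeds")
})

test_that("scoring is shift-equivariant and scales linearly", {
  rate <- 200
  t <- seq(0, 40, by = 1 / rate)
  shape <- 0.4 * pavlovr:::scr_impulse(t - 8, 0.75, 2)
  w <- preprocess_waveform(make_wave(2 + shape))
  s0 <- score_trial(w, onset_s = 6.5)
  # translate waveform and onset together
  w_shift <- w
  w_shift$time_s <- w$time_s + 12
  expect_equal(score_trial(w_shift, onset_s = 18.5), s0, tolerance = 1e-12)
  # scaling the response scales the score
  w2 <- preprocess_waveform(make_wave(2 + 2.5 * shape))
  expect_equal(score_trial(w2, onset_s = 6.5), 2.5 * s0, tolerance = 1e-6)
})

test_that("transform and normalization follow the sqrt / US-mean convention", {
  d <- tibble::tibble(
    trial = 1:4,
    amplitude_uS = c(0.09, 0, 0.25, 0.16),
    us_amplitude_uS = c(NA, NA, 0.25, 0.25))
  out <- transform_normalize(d)
  expect_equal(out$sqrt_uS, c(0.3, 0, 0.5, 0.4))
  # mean sqrt US response is 0.5, so normalized = sqrt / 0.5
  expect_equal(out$normalized, c(0.6, 0, 1, 0.8))
  expect_equal(out$is_us, c(FALSE, FALSE, TRUE, TRUE))
  # zero US response makes the subject unanalyzable
  d0 <- d
  d0$us_amplitude_uS <- c(NA, NA, 0, 0)
  expect_error(transform_normalize(d0), "unanalyzable")
  # rank order of nonzero amplitudes is preserved
  expect_equal(order(out$normalized[out$amplitude_uS > 0]),
               order(d$amplitude_uS[d$amplitude_uS > 0]))
})

test_that("learner classification uses late acquisition with strict inequality", {
  half <- fix_seq[fix_seq$trial > 10 & fix_seq$trial <= 20 & fix_seq$us == 0, ]
  d <- tibble::tibble(trial = half$trial,
                      normalized = ifelse(half$role == "CS+", 0.30, 0.22))
  expect_true(classify_learner(d, fix_seq))
  # exact tie -> non-learner
  d$normalized <- 0.25
  expect_false(classify_learner(d, fix_seq))
  # missing cue type raises
  d2 <- d[half$role == "CS+", ]
  expect_error(classify_learner(d2, fix_seq), "absent")
})

test_that("null subjects classify as learners about half the time", {
  g <- gen_params(model = model_params(0.06, 0.9), slope_mean = 0,
                  slope_sd = 0, habituation_slope = 0, noise_sd = 0.1,
                  p_nonlearner = 0, n_subjects = 200, seed = 61)
  sc <- transform_normalize(simulate_cohort(fix_orders, g))
  lrn <- classify_learners(sc, fix_orders)
  p <- mean(lrn$learner)
  expect_gt(p, 0.35)
  expect_lt(p, 0.65)
})
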