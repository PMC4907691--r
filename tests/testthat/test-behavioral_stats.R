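test_that("first-level codes flip at group-specific reversal boundaries", {
  d_i <- build_first_level_design(fix_seq, "instructed")
  # unreinforced trials only
  expect_true(all(fix_seq$us[match(d_i$trial, fix_seq$trial)] == 0))
  # instructed: reversal code flips right after trials 20, 40, 60
  rev_of <- function(d, tr) d$reversal[which(d$trial > tr)[1]]
  expect_equal(d_i$reversal[d_i$trial <= 20][1], 0.5)
  expect_equal(rev_of(d_i, 20), -0.5)
  expect_equal(rev_of(d_i, 40), 0.5)
  expect_equal(rev_of(d_i, 60), -0.5)
  # uninstructed: the flip waits for the first US of the new block
  d_u <- build_first_level_design(fix_seq, "uninstructed")
  first_us_b2 <- min(fix_seq$trial[fix_seq$block == 2 & fix_seq$us == 1])
  pre <- d_u$reversal[d_u$trial > 20 & d_u$trial < first_us_b2]
  post <- d_u$reversal[d_u$trial > first_us_b2 & d_u$trial <= 40]
  expect_true(all(pre == 0.5))
  expect_true(all(post == -0.5))
  # interaction column is the +-1/2 coding of the current CS+
  seq_rows <- fix_seq[match(d_i$trial, fix_seq$trial), ]
  expect_equal(d_i$interaction, ifelse(seq_rows$role == "CS+", 0.5, -0.5))
  expect_equal(d_i$interaction, 2 * d_i$stimulus * d_i$reversal)
})

test_that("design subsets drop acquisition or keep late-run trials", {
  d_post <- build_first_level_design(fix_seq, "instructed",
                                     subset = "post_first_reversal")
  expect_true(all(d_post$trial > 20))
  d_half <- build_first_level_design(fix_seq, "instructed",
                                     subset = "second_half_of_each_run")
  expect_true(all(d_half$trial %in%
                    c(11:20, 31:40, 51:60, 71:80)))
})

# Simulate a cohort whose normalized response is exactly X beta + noise.
design_cohort <- function(beta, n_subjects, noise_sd, seed,
                          groups = c("instructed", "uninstructed")) {
  designs <- list(build_first_level_design(fix_orders[[1]], groups[1]),
                  build_first_level_design(fix_orders[[2]], groups[1]))
  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(n_subjects), function(s) {
      ord <- (s - 1) %% 2 + 1
      X <- as.matrix(designs[[ord]][, c("intercept", "stimulus", "reversal",
                                        "interaction", "time")])
      tibble::tibble(
        subject = s,
        group = groups[(s - 1) %% length(groups) + 1],
        trial_order = ord,
        trial = designs[[ord]]$trial,
        normalized = as.numeric(X %*% beta) + rnorm(nrow(X), 0, noise_sd))
    })
  })
}

test_that("an injected interaction effect is recovered at the second level", {
  beta <- c(0.25, 0, 0, 0.06, 0)
  co <- design_cohort(beta, n_subjects = 20, noise_sd = 0.05, seed = 5,
                      groups = "instructed")
  res <- fit_two_level(co, fix_orders)
  est <- tidy(res)
  w <- est[est$level == "within", ]
  expect_lt(abs(w$estimate[w$effect == "interaction"] - 0.06), 0.015)
  expect_lt(abs(w$estimate[w$effect == "intercept"] - 0.25), 0.015)
  expect_lt(abs(w$estimate[w$effect == "stimulus"]), 0.02)
  expect_lt(abs(w$estimate[w$effect == "reversal"]), 0.02)
  expect_lt(w$p_value[w$effect == "interaction"], 0.001)
})

test_that("a habituation-only cohort loads on the time effect alone", {
  beta <- c(0.3, 0, 0, 0, -0.08)
  co <- design_cohort(beta, n_subjects = 16, noise_sd = 0.05, seed = 6,
                      groups = "instructed")
  res <- tidy(fit_two_level(co, fix_orders))
  w <- res[res$level == "within", ]
  expect_lt(w$estimate[w$effect == "time"], -0.05)
  expect_lt(abs(w$estimate[w$effect == "stimulus"]), 0.02)
  expect_lt(abs(w$estimate[w$effect == "interaction"]), 0.02)
})

test_that("group rows test differences across groups", {
  beta <- c(0.25, 0, 0, 0.05, 0)
  co <- design_cohort(beta, n_subjects = 20, noise_sd = 0.05, seed = 7)
  res <- tidy(fit_two_level(co, fix_orders))
  expect_setequal(unique(res$level), c("within", "group"))
  g <- res[res$level == "group", ]
  # both groups share the same generating betas: group differences are noise
  expect_true(all(abs(g$estimate) < 0.05))
  expect_equal(unique(g$df), 18)
})

test_that("two-stage estimates equal pooled OLS on balanced designs", {
  # all subjects share one trial order and design; noiseless subject-level
  # heterogeneity only in responses
  beta <- c(0.2, 0.01, 0, 0.05, -0.03)
  co <- design_cohort(beta, n_subjects = 6, noise_sd = 0.03, seed = 8,
                      groups = "instructed")
  co <- co[co$trial_order == 1, ]
  res <- fit_two_level(co, fix_orders)
  betas <- attr(res, "betas")
  d <- build_first_level_design(fix_orders[[1]], "instructed")
  X <- as.matrix(d[, c("intercept", "stimulus", "reversal", "interaction",
                       "time")])
  pooled <- lapply(split(co, co$subject), function(s) {
    stats::lm.fit(X, s$normalized)$coefficients
  })
  pooled_mean <- colMeans(do.call(rbind, pooled))
  two_stage <- colMeans(as.matrix(betas[, c("intercept", "stimulus",
                                            "reversal", "interaction",
                                            "time")]))
  expect_equal(unname(two_stage), unname(pooled_mean), tolerance = 1e-10)
})

test_that("the joint mixed-model cross-check agrees with the two-stage fit", {
  skip_if_not_installed("lme4")
  beta <- c(0.25, 0, 0, 0.06, -0.02)
  co <- design_cohort(beta, n_subjects = 12, noise_sd = 0.05, seed = 9,
                      groups = "instructed")
  mm <- mixed_model_check(co, fix_orders)
  res <- tidy(fit_two_level(co, fix_orders))
  w <- res[res$level == "within", ]
  expect_equal(mm$estimate[mm$effect == "interaction"],
               w$estimate[w$effect == "interaction"], tolerance = 0.01)
  expect_equal(mm$estimate[mm$effect == "time"],
               w$estimate[w$effect == "time"], tolerance = 0.01)
})

test_that("the instructed-reversal contrast detects immediate reversal", {
  # full instructed reversal: responding flips with instructions
  co1 <- quick_cohort(alpha = 0.06, rho = 1, noise_sd = 0, n_subjects = 20,
                      seed = 11)
  r1 <- instructed_reversal_contrast(co1, fix_orders,
                                     response = "amplitude_uS")
  expect_equal(r1$df, 19)
  expect_gt(r1$estimate, 0.05)
  expect_lt(r1$p_value, 0.001)
  # no instructed reversal: pre/post differentials cancel
  co0 <- quick_cohort(alpha = 0.06, rho = 0, noise_sd = 0, n_subjects = 20,
                      seed = 12)
  r0 <- instructed_reversal_contrast(co0, fix_orders,
                                     response = "amplitude_uS")
  expect_lt(abs(r0$estimate), 0.35 * r1$estimate)
  expect_gt(r1$estimate, r0$estimate)
})
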