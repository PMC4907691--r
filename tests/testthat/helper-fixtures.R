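# Shared fixtures, built once per test run. Everything is generated in code;
# no files are read.

fix_config <- task_config()
fix_orders <- canonical_orders(fix_config)
fix_seq <- fix_orders[[1]]

# A cohort tailored for fitting tests: optional noise on the amplitude scale,
# no habituation or non-learner mixture so that the generative model is
# exactly the fitted one (intercept + slope * EV).
quick_cohort <- function(alpha, rho = NULL, noise_sd = 0, n_subjects = 6,
                         seed = 1, variant = if (is.null(rho)) "feedback" else "instructed",
                         slope_sd = 0.05, intercept_sd = 0.1) {
  g <- gen_params(
    model = model_params(alpha = alpha, rho = rho, variant = variant),
    noise_sd = noise_sd, habituation_slope = 0, p_nonlearner = 0,
    slope_sd = slope_sd, intercept_sd = intercept_sd,
    n_subjects = n_subjects, seed = seed)
  simulate_cohort(fix_orders, g)
}

# Minimal hand-built trial sequence for targeted model tests: a single cue
# presented `n` times with a given outcome pattern and no instructions.
constant_sequence <- function(us, cue = "A") {
  n <- length(us)
  out <- tibble::tibble(
    trial = seq_len(n), block = 1L, cue = cue,
    role = ifelse(us > 0 | cue == "A", "CS+", "CS-"),
    original_role = ifelse(cue == "A", "CS+", "CS-"),
    us = as.integer(us), onset_s = (seq_len(n) - 1) * 16)
  structure(out,
            instructions = tibble::tibble(after_trial = integer(),
                                          onset_s = double(),
                                          new_cs_plus = character()),
            config = task_config(n_blocks = 1L, trials_per_block = n,
                                 cs_plus_per_block = n, cs_minus_per_block = 0L,
                                 reinforced_per_block = sum(us),
                                 instruction_after_trials = integer()),
            class = c("trial_sequence", class(out)))
}

expect_all_pass <- function(report) {
  failed <- report$constraint[!report$pass]
  expect(length(failed) == 0,
         sprintf("constraints failed: %s", paste(failed, collapse = ", ")))
}
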