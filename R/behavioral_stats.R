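# Reversal phase (0 = original contingencies, 1, 2, 3 ...) per trial, under
# the group-specific boundary rule: the instructed group's phases flip at
# instruction delivery; the uninstructed group's flip when the new CS+
# (previous CS-) is first reinforced in each block.
reversal_phase <- function(seq, group) {
  if (group == "instructed") {
    bounds <- instruction_events(seq)$after_trial
    vapply(seq$trial, function(tr) sum(bounds < tr), integer(1))
  } else {
    first_us <- seq |>
      filter(.data$us == 1) |>
      group_by(.data$block) |>
      summarise(t = min(.data$trial), .groups = "drop")
    bounds <- first_us$t[first_us$block > min(seq$block)]
    vapply(seq$trial, function(tr) sum(bounds <= tr), integer(1))
  }
}

#' Build a subject's first-level design for the two-level SCR analysis
#'
#' Codes each analyzed trial as a function of Stimulus (original CS+ vs
#' original CS-, `+1/2` / `-1/2`), Reversal (original vs reversed
#' contingencies, `+1/2` / `-1/2`), their interaction (coded `+1/2` for the
#' *current* CS+ and `-1/2` for the current CS-, so its beta is the mean
#' differential response), and a standardized linear Time regressor for
#' habituation. Reversal boundaries are group-specific: instruction delivery
#' for the instructed group, first reinforcement of the new contingencies for
#' the uninstructed group. Only unreinforced CS presentations enter the
#' design.
#'
#' @param seq A `trial_sequence`.
#' @param group `"instructed"` or `"uninstructed"`.
#' @param subset `"all"`, `"post_first_reversal"` (drops the acquisition
#'   phase), or `"second_half_of_each_run"` (keeps the later half of every
#'   run, runs being the spans between group-specific reversal boundaries).
#' @return A tibble of class `first_level_design`: `trial`, `intercept`,
#'   `stimulus`, `reversal`, `interaction`, `time`.
#' @export
#' @examples
#' d <- build_first_level_design(generate_trial_sequence(task_config(), 1),
#'                               group = "instructed")
#' head(d)
build_first_level_design <- function(seq,
                                     group = c("instructed", "uninstructed"),
                                     subset = c("all", "post_first_reversal",
                                                "second_half_of_each_run")) {
  group <- match.arg(group)
  subset <- match.arg(subset)
  phase <- reversal_phase(seq, group)
  d <- as_tibble(seq) |>
    mutate(
      phase = phase,
      stimulus = ifelse(.data$original_role == "CS+", 0.5, -0.5),
      reversal = ifelse(phase %% 2L == 0L, 0.5, -0.5),
      interaction = 2 * .data$stimulus * .data$reversal
    )
  keep <- d$us == 0
  if (subset == "post_first_reversal") {
    keep <- keep & d$phase >= 1L
  } else if (subset == "second_half_of_each_run") {
    d <- d |>
      group_by(.data$phase) |>
      mutate(run_pos = row_number(), run_len = n()) |>
      ungroup()
    keep <- keep & d$run_pos > d$run_len / 2
  }
  out <- d[keep, ]
  if (nrow(out) == 0L) stopf("build_first_level_design(): empty subset.")
  out <- out |>
    mutate(time = as.numeric(scale(.data$trial))) |>
    transmute(.data$trial, intercept = 1, .data$stimulus, .data$reversal,
              .data$interaction, .data$time)
  structure(out, group = group, subset = subset,
            class = c("first_level_design", class(out)))
}

# First-level OLS for one subject; NULL if the design is rank-deficient.
first_level_betas <- function(design, response) {
  X <- as.matrix(design[, c("intercept", "stimulus", "reversal",
                            "interaction", "time")])
  f <- lm.fit(X, response)
  if (f$rank < ncol(X)) return(NULL)
  as.list(coef(f))
}

#' Two-level summary-statistics analysis of normalized SCR
#'
#' Stage one fits each subject's normalized SCR by ordinary least squares on
#' the first-level design (intercept, Stimulus, Reversal, Stimulus x Reversal,
#' Time). Stage two tests each first-level beta across subjects: the
#' within-subject effect controlling for group (the intercept of a
#' second-level regression on centered group), and the group difference (its
#' slope); with a single group, a one-sample t-test.
#'
#' @param data Cohort table with `subject`, `group`, `trial_order`, `trial`
#'   and the response column.
#' @param seqs List of trial orders referenced by `data$trial_order`.
#' @param response Response column name (default `"normalized"`).
#' @param subset Trial subset passed to [build_first_level_design()].
#' @return A tibble of class `scr_lmm`: `effect`, `level` (`"within"` or
#'   `"group"`), `estimate`, `t`, `df`, `p_value`, `n_subjects`. Per-subject
#'   betas are attached as attribute `"betas"`; rank-deficient subjects are
#'   flagged in attribute `"excluded"`.
#' @export
fit_two_level <- function(data, seqs, response = "normalized",
                          subset = "all") {
  check_cols(data, c("subject", "group", "trial_order", "trial", response),
             "fit_two_level")
  if (inherits(seqs, "trial_sequence")) seqs <- list(seqs)
  designs <- list()
  betas <- list()
  excluded <- character()
  for (d in split(data, data$subject)) {
    grp <- d$group[1]
    key <- paste(grp, d$trial_order[1], subset)
    if (is.null(designs[[key]])) {
      designs[[key]] <- build_first_level_design(seqs[[d$trial_order[1]]],
                                                 grp, subset)
    }
    des <- designs[[key]]
    dd <- inner_join(des, d[, c("trial", response)], by = "trial")
    b <- first_level_betas(dd, dd[[response]])
    if (is.null(b)) {
      excluded <- c(excluded, as.character(d$subject[1]))
      next
    }
    betas[[length(betas) + 1L]] <- tibble(
      subject = d$subject[1], group = grp,
      intercept = b$intercept, stimulus = b$stimulus, reversal = b$reversal,
      interaction = b$interaction, time = b$time)
  }
  if (!length(betas)) stopf("fit_two_level(): no subject with full-rank design.")
  betas <- bind_rows(betas)

  groups <- unique(betas$group)
  effects <- c("intercept", "stimulus", "reversal", "interaction", "time")
  rows <- purrr::map_dfr(effects, function(eff) {
    y <- betas[[eff]]
    n <- length(y)
    if (length(groups) >= 2L) {
      gc <- ifelse(betas$group == groups[1], 0.5, -0.5)
      m <- summary(lm(y ~ gc))$coefficients
      tibble(effect = eff,
             level = c("within", "group"),
             estimate = m[, 1], t = m[, 3],
             df = n - 2, p_value = m[, 4], n_subjects = n)
    } else {
      ht <- t.test(y)
      tibble(effect = eff, level = "within",
             estimate = mean(y), t = unname(ht$statistic),
             df = n - 1, p_value = ht$p.value, n_subjects = n)
    }
  })
  structure(rows, betas = betas, excluded = excluded,
            group_order = groups,
            class = c("scr_lmm", class(rows)))
}

#' Immediate effect of instructions on differential SCR
#'
#' For each instructed-group subject, compares the differential response
#' (current CS+ minus current CS-, with "current" meaning the post-reversal
#' roles throughout) in the post-instruction, pre-reinforcement window with
#' the cue-matched trials immediately before the instruction, averaged over
#' the reversals; a positive value means responding reversed with the
#' instruction before any reinforcement confirmed it. Group level is a
#' one-sample t-test across subjects (df = n - 1).
#'
#' @param data Instructed-cohort table with `subject`, `trial_order`, `trial`
#'   and the response column.
#' @param seqs List of trial orders referenced by `data$trial_order`.
#' @param response Response column name.
#' @return A one-row tibble: `estimate`, `t`, `df`, `p_value`, `n_subjects`;
#'   per-subject contrasts in attribute `"subject_effects"`.
#' @export
instructed_reversal_contrast <- function(data, seqs, response = "normalized") {
  check_cols(data, c("subject", "trial_order", "trial", response),
             "instructed_reversal_contrast")
  if (inherits(seqs, "trial_sequence")) seqs <- list(seqs)
  windows <- purrr::map(seqs, instruction_windows)
  if (any(vapply(windows, nrow, integer(1)) == 0L)) {
    stopf("instructed_reversal_contrast(): missing reversal windows.")
  }
  per_subject <- purrr::map_dfr(split(data, data$subject), function(d) {
    w <- windows[[d$trial_order[1]]] |>
      inner_join(d[, c("trial", response)], by = "trial")
    eff <- w |>
      group_by(.data$reversal, .data$phase, .data$post_role) |>
      summarise(m = mean(.data[[response]]), .groups = "drop") |>
      tidyr::pivot_wider(names_from = c("phase", "post_role"),
                         values_from = "m") |>
      mutate(effect = (.data$`post_CS+` - .data$`post_CS-`) -
               (.data$`pre_CS+` - .data$`pre_CS-`))
    tibble(subject = d$subject[1], effect = mean(eff$effect))
  })
  ht <- t.test(per_subject$effect)
  out <- tibble(estimate = mean(per_subject$effect),
                t = unname(ht$statistic),
                df = unname(ht$parameter),
                p_value = ht$p.value,
                n_subjects = nrow(per_subject))
  structure(out, subject_effects = per_subject, class = class(out))
}

#' Cross-check a two-level effect with a joint mixed model
#'
#' Fits the same first-level design jointly across subjects with random
#' intercepts per subject via `lme4::lmer`, as an independent check of the
#' two-stage estimates. Requires the lme4 package.
#'
#' @inheritParams fit_two_level
#' @return A tibble of fixed-effect estimates (`effect`, `estimate`).
#' @export
mixed_model_check <- function(data, seqs, response = "normalized",
                              subset = "all") {
  if (!requireNamespace("lme4", quietly = TRUE)) {
    stopf("mixed_model_check() requires the lme4 package.")
  }
  if (inherits(seqs, "trial_sequence")) seqs <- list(seqs)
  long <- purrr::map_dfr(split(data, data$subject), function(d) {
    des <- build_first_level_design(seqs[[d$trial_order[1]]], d$group[1],
                                    subset)
    inner_join(des, d[, c("trial", response, "subject")], by = "trial")
  })
  fm <- stats::as.formula(paste0(
    "`", response, "` ~ stimulus + reversal + interaction + time + (1 | subject)"))
  fit <- lme4::lmer(fm, data = long, REML = FALSE)
  fe <- lme4::fixef(fit)
  tibble(effect = names(fe), estimate = unname(fe))
}
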