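#' Task configuration for the reversal-learning design
#'
#' Describes the structure of the Pavlovian aversive reversal-learning task:
#' four continuous blocks of twenty trials in which one of two face cues (the
#' CS+) is paired with mild electric shock (the US) on a third of its
#' presentations while the other cue (the CS-) is never reinforced, with the
#' cue roles exchanged between blocks. Instruction events (10 s epochs during
#' which the instructed group is told that contingencies reversed) separate
#' the blocks.
#'
#' @param n_blocks Number of contingency blocks (runs).
#' @param trials_per_block Trials per block.
#' @param cs_plus_per_block,cs_minus_per_block Presentations of the current
#'   CS+ / CS- per block. Must sum to `trials_per_block`.
#' @param reinforced_per_block Number of shocked (US) trials per block; all
#'   fall on CS+ presentations. `reinforced_per_block / cs_plus_per_block` is
#'   the reinforcement rate (1/3 under the defaults).
#' @param stim_duration,isi Cue duration and inter-stimulus interval, seconds.
#' @param instruction_after_trials Trial indices after which an instruction
#'   epoch occurs (the reversal points).
#' @param instruction_duration Duration of each instruction epoch, seconds.
#' @param min_unreinforced_after_instruction Minimum unreinforced
#'   presentations of *each* cue between an instruction and the first US of
#'   the new block.
#' @param max_run_same_cue Maximum number of consecutive presentations of the
#'   same cue.
#' @param max_attempts Retry budget for the rejection sampler in
#'   [generate_trial_sequence()].
#'
#' @return An object of class `task_config` (a named list).
#' @export
#' @examples
#' task_config()
task_config <- function(n_blocks = 4L,
                        trials_per_block = 20L,
                        cs_plus_per_block = 12L,
                        cs_minus_per_block = 8L,
                        reinforced_per_block = 4L,
                        stim_duration = 4,
                        isi = 12,
                        instruction_after_trials = NULL,
                        instruction_duration = 10,
                        min_unreinforced_after_instruction = 2L,
                        max_run_same_cue = 2L,
                        max_attempts = 10000L) {
  if (cs_plus_per_block + cs_minus_per_block != trials_per_block) {
    stopf("cs_plus_per_block + cs_minus_per_block must equal trials_per_block.")
  }
  if (reinforced_per_block > cs_plus_per_block) {
    stopf("reinforced_per_block cannot exceed cs_plus_per_block.")
  }
  if (is.null(instruction_after_trials)) {
    instruction_after_trials <- trials_per_block * seq_len(max(n_blocks - 1L, 0L))
  }
  structure(
    list(
      n_blocks = as.integer(n_blocks),
      trials_per_block = as.integer(trials_per_block),
      cs_plus_per_block = as.integer(cs_plus_per_block),
      cs_minus_per_block = as.integer(cs_minus_per_block),
      reinforced_per_block = as.integer(reinforced_per_block),
      reinforcement_rate = reinforced_per_block / cs_plus_per_block,
      stim_duration = stim_duration,
      isi = isi,
      instruction_after_trials = as.integer(instruction_after_trials),
      instruction_duration = instruction_duration,
      min_unreinforced_after_instruction = as.integer(min_unreinforced_after_instruction),
      max_run_same_cue = as.integer(max_run_same_cue),
      max_attempts = as.integer(max_attempts)
    ),
    class = "task_config"
  )
}

#' @export
print.task_config <- function(x, ...) {
  cat("<task_config>\n")
  cat(sprintf("  %d blocks x %d trials (%d CS+ / %d CS- by current role)\n",
              x$n_blocks, x$trials_per_block, x$cs_plus_per_block,
              x$cs_minus_per_block))
  cat(sprintf("  %d US per block (reinforcement rate %.0f%%)\n",
              x$reinforced_per_block, 100 * x$reinforcement_rate))
  cat(sprintf("  instructions after trials: %s\n",
              paste(x$instruction_after_trials, collapse = ", ")))
  invisible(x)
}

# Two-phase rejection sampling for one block, conditioning on the tail of
# the preceding block: first a cue arrangement satisfying the run-length
# constraint, then a US placement satisfying adjacency and post-instruction
# constraints. Each rejected draw is charged to the shared attempt budget.
# Returns NULL if a phase exceeds the remaining budget.
sample_block <- function(config, cs_plus_cue, prev_tail_cues, prev_last_us,
                         check_post_instruction, budget) {
  tp <- config$trials_per_block
  cs_minus_cue <- setdiff(c("A", "B"), cs_plus_cue)
  pool <- c(rep(cs_plus_cue, config$cs_plus_per_block),
            rep(cs_minus_cue, config$cs_minus_per_block))
  used <- 0L

  cues <- NULL
  while (used < budget) {
    used <- used + 1L
    cand <- sample(pool)
    runs <- rle(c(prev_tail_cues, cand))
    if (all(runs$lengths <= config$max_run_same_cue)) {
      cues <- cand
      break
    }
  }
  if (is.null(cues)) {
    return(list(failed = "max_run_same_cue", used = used))
  }

  us <- integer(tp)
  if (config$reinforced_per_block > 0L) {
    plus_idx <- which(cues == cs_plus_cue)
    m <- config$min_unreinforced_after_instruction
    ok <- FALSE
    while (used < budget) {
      used <- used + 1L
      shock_idx <- sort(sample(plus_idx, config$reinforced_per_block))
      if (any(diff(shock_idx) == 1L)) next
      if (prev_last_us && shock_idx[1] == 1L) next
      if (check_post_instruction) {
        before <- cues[seq_len(shock_idx[1] - 1L)]
        if (sum(before == cs_plus_cue) < m ||
              sum(before == cs_minus_cue) < m) next
      }
      ok <- TRUE
      break
    }
    if (!ok) {
      return(list(failed = "us_placement", used = used))
    }
    us[shock_idx] <- 1L
  }
  list(cue = cues, us = us, used = used)
}

#' Generate a pseudorandom trial sequence
#'
#' Rejection-samples a trial order satisfying the full constraint set of the
#' reversal design: exact per-block cue and US counts, no US on a CS- trial,
#' no two US trials adjacent, no cue repeated more than
#' `max_run_same_cue` times in a row, and at least
#' `min_unreinforced_after_instruction` unreinforced presentations of each cue
#' between every instruction and the first US of the new block. Cue roles
#' alternate between blocks (cue A is the CS+ in odd blocks). Onsets place
#' trial k at `(k-1) * (stim_duration + isi)` seconds, shifted by one
#' instruction epoch per preceding reversal.
#'
#' @param config A [task_config()].
#' @param seed Integer seed; the sequence is a deterministic function of
#'   `(config, seed)`.
#'
#' @return A tibble of class `trial_sequence` with one row per trial and
#'   columns `trial`, `block`, `cue` (`"A"`/`"B"`), `role` / `original_role`
#'   (`"CS+"`/`"CS-"` under current / block-1 contingencies), `us` (0/1) and
#'   `onset_s`. The instruction events are attached as attribute
#'   `"instructions"` (a tibble with `after_trial`, `onset_s`,
#'   `new_cs_plus`), and the configuration as attribute `"config"`.
#' @export
#' @examples
#' seq1 <- generate_trial_sequence(task_config(), seed = 1)
#' dplyr::count(seq1, block, role, us)
generate_trial_sequence <- function(config = task_config(), seed) {
  if (missing(seed)) stopf("`seed` is required for reproducible sequences.")
  withr::with_seed(as.integer(seed), {
    tp <- config$trials_per_block
    attempts <- 0L
    blocks <- vector("list", config$n_blocks)
    for (b in seq_len(config$n_blocks)) {
      cs_plus_cue <- if (b %% 2L == 1L) "A" else "B"
      prev <- if (b > 1L) blocks[[b - 1L]] else NULL
      cand <- sample_block(
        config, cs_plus_cue,
        prev_tail_cues = if (is.null(prev)) character() else
          tail(prev$cue, config$max_run_same_cue),
        prev_last_us = !is.null(prev) && tail(prev$us, 1L) == 1L,
        check_post_instruction = b > 1L,
        budget = config$max_attempts - attempts
      )
      attempts <- attempts + cand$used
      if (!is.null(cand$failed)) {
        stopf(paste0(
          "generate_trial_sequence(): retry budget (%d) exhausted at block %d ",
          "while satisfying the `%s` constraint; the constraint set appears ",
          "unsatisfiable under this config."),
          config$max_attempts, b, cand$failed)
      }
      blocks[[b]] <- cand
    }

    cue <- unlist(lapply(blocks, `[[`, "cue"))
    us <- unlist(lapply(blocks, `[[`, "us"))
    n <- config$n_blocks * tp
    block <- rep(seq_len(config$n_blocks), each = tp)
    cs_plus_by_block <- ifelse(seq_len(config$n_blocks) %% 2L == 1L, "A", "B")
    role <- ifelse(cue == cs_plus_by_block[block], "CS+", "CS-")
    original_role <- ifelse(cue == "A", "CS+", "CS-")

    trial_len <- config$stim_duration + config$isi
    n_instr_before <- vapply(seq_len(n), function(k) {
      sum(config$instruction_after_trials < k)
    }, integer(1))
    onset <- (seq_len(n) - 1) * trial_len +
      n_instr_before * config$instruction_duration

    instr <- tibble(
      after_trial = config$instruction_after_trials,
      onset_s = config$instruction_after_trials * trial_len +
        (seq_along(config$instruction_after_trials) - 1) *
          config$instruction_duration,
      new_cs_plus = cs_plus_by_block[
        pmin(config$instruction_after_trials %/% tp + 1L, config$n_blocks)]
    )

    out <- tibble(
      trial = seq_len(n), block = block, cue = cue, role = role,
      original_role = original_role, us = as.integer(us), onset_s = onset
    )
    structure(out,
              instructions = instr,
              config = config,
              seed = as.integer(seed),
              class = c("trial_sequence", class(out)))
  })
}

#' Instruction events of a trial sequence
#'
#' @param seq A `trial_sequence`.
#' @return The instruction-event tibble attached by
#'   [generate_trial_sequence()].
#' @export
instruction_events <- function(seq) {
  ev <- attr(seq, "instructions")
  if (is.null(ev)) stopf("`seq` carries no instruction events.")
  ev
}

#' The two canonical pseudorandom trial orders
#'
#' The experiment used two fixed pseudorandom trial orders; this returns the
#' package's two canonical orders (default configuration, seeds 1 and 2),
#' which play that role throughout simulation and fitting.
#'
#' @param config A [task_config()].
#' @return A list of two `trial_sequence` objects.
#' @export
canonical_orders <- function(config = task_config()) {
  list(generate_trial_sequence(config, seed = 1L),
       generate_trial_sequence(config, seed = 2L))
}

# One row of a validation report.
vrow <- function(constraint, pass, first_violation = NA_integer_) {
  tibble(constraint = constraint, pass = pass,
         first_violation = as.integer(first_violation))
}

#' Validate a trial sequence against the design constraints
#'
#' Checks every structural constraint of the reversal design and reports each
#' as pass/fail with the first violating trial index. Validation never raises,
#' so it can be used on deliberately broken sequences.
#'
#' @param seq A `trial_sequence` (or any data frame with the same columns).
#' @param config A [task_config()].
#' @return A tibble with columns `constraint`, `pass`, `first_violation`.
#' @export
#' @examples
#' ok <- validate_sequence(generate_trial_sequence(task_config(), 1))
#' all(ok$pass)
validate_sequence <- function(seq, config = attr(seq, "config") %||% task_config()) {
  n_expected <- config$n_blocks * config$trials_per_block
  out <- vrow("n_trials", nrow(seq) == n_expected)

  counts <- seq |>
    group_by(.data$block) |>
    summarise(n = n(),
              n_plus = sum(.data$role == "CS+"),
              n_minus = sum(.data$role == "CS-"),
              n_us = sum(.data$us), .groups = "drop")
  bad <- counts$block[counts$n != config$trials_per_block]
  out <- bind_rows(out, vrow("trials_per_block", length(bad) == 0, bad[1]))
  bad <- counts$block[counts$n_plus != config$cs_plus_per_block |
                        counts$n_minus != config$cs_minus_per_block]
  out <- bind_rows(out, vrow("cue_role_counts_per_block", length(bad) == 0, bad[1]))
  bad <- counts$block[counts$n_us != config$reinforced_per_block]
  out <- bind_rows(out, vrow("us_count_per_block", length(bad) == 0, bad[1]))

  bad <- seq$trial[seq$us == 1 & seq$role == "CS-"]
  out <- bind_rows(out, vrow("no_us_on_cs_minus", length(bad) == 0, bad[1]))

  adj <- which(seq$us[-1] == 1 & seq$us[-nrow(seq)] == 1) + 1L
  out <- bind_rows(out, vrow("no_adjacent_us", length(adj) == 0, seq$trial[adj[1]]))

  runs <- rle(seq$cue)
  over <- which(runs$lengths > config$max_run_same_cue)
  first_over <- if (length(over)) {
    cumsum(runs$lengths)[over[1]] - runs$lengths[over[1]] +
      config$max_run_same_cue + 1L
  } else NA_integer_
  out <- bind_rows(out, vrow("max_cue_run", length(over) == 0, first_over))

  # Roles must alternate between blocks: the block-b CS+ cue flips each block.
  plus_cue <- vapply(split(seq, seq$block), function(d) {
    u <- unique(d$cue[d$role == "CS+"])
    if (length(u) == 1L) u else NA_character_
  }, character(1))
  alt_ok <- !anyNA(plus_cue) &&
    (length(plus_cue) < 2L || all(plus_cue[-1] != plus_cue[-length(plus_cue)]))
  out <- bind_rows(out, vrow("roles_alternate_between_blocks", alt_ok))

  # Post-instruction: >= m unreinforced presentations of each cue before the
  # first US of each block after the first.
  m <- config$min_unreinforced_after_instruction
  viol <- NA_integer_
  post_ok <- TRUE
  for (b in setdiff(unique(seq$block), min(seq$block))) {
    d <- seq[seq$block == b, ]
    first_us <- which(d$us == 1)[1]
    if (is.na(first_us)) next
    before <- d$cue[seq_len(first_us - 1L)]
    if (any(table(factor(before, levels = c("A", "B"))) < m)) {
      post_ok <- FALSE
      viol <- d$trial[first_us]
      break
    }
  }
  out <- bind_rows(out, vrow("post_instruction_unreinforced", post_ok, viol))
  out
}

#' Post-instruction, pre-reinforcement windows around each reversal
#'
#' For each instruction event, the *post* window runs from the first
#' post-instruction trial up to (but excluding) the first US of the new
#' block — the span in which the instructed group knows the new contingencies
#' but no reinforcement has yet confirmed them. The *pre* window contains, per
#' cue, the same number of that cue's trials immediately before the
#' instruction, so pre and post are matched cue-wise.
#'
#' @param seq A `trial_sequence` with at least one instruction event.
#' @return A tibble with one row per (reversal, phase, trial): columns
#'   `reversal`, `phase` (`"pre"`/`"post"`), `trial`, `cue`, and `post_role`,
#'   the role the cue holds *after* the reversal (so `post_role == "CS+"`
#'   marks the new CS+ in both phases).
#' @export
instruction_windows <- function(seq) {
  instr <- instruction_events(seq)
  if (nrow(instr) == 0L) stopf("`seq` has no instruction events.")
  config <- attr(seq, "config") %||% task_config()
  m <- config$min_unreinforced_after_instruction

  purrr::map_dfr(seq_len(nrow(instr)), function(r) {
    after <- instr$after_trial[r]
    new_plus <- instr$new_cs_plus[r]
    nxt <- seq[seq$trial > after, ]
    nxt <- nxt[nxt$block == nxt$block[1], ]
    first_us <- which(nxt$us == 1)[1]
    post <- if (is.na(first_us)) nxt else nxt[seq_len(first_us - 1L), ]
    n_by_cue <- table(factor(post$cue, levels = c("A", "B")))
    if (!is.na(first_us) && any(n_by_cue < m)) {
      stopf(paste0("instruction_windows(): block following trial %d reinforces ",
                   "before %d presentations of each cue."), after, m)
    }
    pre <- purrr::map_dfr(c("A", "B"), function(cu) {
      k <- n_by_cue[[cu]]
      prior <- seq[seq$trial <= after & seq$cue == cu, ]
      tail(prior, k)
    })
    bind_rows(
      pre |> mutate(phase = "pre"),
      post |> mutate(phase = "post")
    ) |>
      transmute(reversal = r, phase = .data$phase, trial = .data$trial,
                cue = .data$cue,
                post_role = ifelse(.data$cue == new_plus, "CS+", "CS-")) |>
      arrange(.data$trial)
  })
}

#' Write / read a trial sequence as TSV
#'
#' The event table and instruction events are written as two tab-separated
#' files (`events.tsv`, `instructions.tsv`) in `dir`.
#'
#' @param seq A `trial_sequence`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_trial_sequence <- function(seq, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.table(as.data.frame(seq), file.path(dir, "events.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(as.data.frame(instruction_events(seq)),
              file.path(dir, "instructions.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_trial_sequence
#' @param config Configuration to attach when reading back.
#' @export
read_trial_sequence <- function(dir, config = task_config()) {
  ev <- as_tibble(read.delim(file.path(dir, "events.tsv")))
  instr <- as_tibble(read.delim(file.path(dir, "instructions.tsv")))
  structure(ev, instructions = instr, config = config,
            class = c("trial_sequence", class(ev)))
}
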