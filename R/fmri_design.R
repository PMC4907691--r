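#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma densities (unit rate) with modes at the response
#' peak and the undershoot, undershoot weighted `1/ratio`, normalized to unit
#' peak amplitude on a fine internal grid so that values at shared time
#' points are independent of `dt`.
#'
#' @param dt Sampling interval, seconds.
#' @param peak Time-to-peak of the positive lobe (s).
#' @param undershoot Time of the undershoot (s).
#' @param ratio Peak-to-undershoot amplitude ratio.
#' @param duration Kernel support (s).
#' @return Numeric kernel sampled at `seq(0, duration, by = dt)`, with
#'   attributes `dt` and `params`.
#' @export
#' @examples
#' h <- gamma_hrf(0.125)
#' plot(seq(0, 32, by = 0.125), h, type = "l")
gamma_hrf <- function(dt, peak = 6, undershoot = 16, ratio = 6,
                      duration = 32) {
  if (dt <= 0) stopf("`dt` must be positive.")
  shape_fn <- function(t) {
    dgamma(t, shape = peak + 1, rate = 1) -
      dgamma(t, shape = undershoot + 1, rate = 1) / ratio
  }
  fine <- seq(0, duration, by = 0.001)
  peak_val <- max(shape_fn(fine))
  t <- seq(0, duration, by = dt)
  structure(shape_fn(t) / peak_val, dt = dt,
            params = list(peak = peak, undershoot = undershoot,
                          ratio = ratio, duration = duration))
}

# Convolve a microtime neural vector with the HRF kernel and sample it on the
# TR grid. The dt scaling makes the result invariant to microtime resolution.
convolve_downsample <- function(x, hrf, dt, tr_idx) {
  y <- stats::convolve(x, rev(hrf), type = "open")[seq_along(x)] * dt
  y[tr_idx]
}

#' Build a first-level fMRI design matrix with EV parametric modulators
#'
#' Constructs the model-based design: a cue regressor at onset (4-s epoch by
#' default, or a stick), a stick at cue offset, one EV parametric modulator
#' per supplied trace on the onset event, optional shock and prediction-error
#' modulators on the offset event, and a 10-s instruction-epoch boxcar.
#' Everything is built at microtime resolution, convolved with the canonical
#' gamma HRF, and sampled at the TR grid. Modulator values are mean-centered
#' before convolution when `center = TRUE`. When `orthogonalize = TRUE`, each
#' modulator column is residualized against all earlier columns in declared
#' order; when `FALSE`, modulators keep their shared variance (so a joint fit
#' splits none of it preferentially).
#'
#' @param seq A `trial_sequence`.
#' @param traces An `ev_trace` or a named list of up to two (e.g.
#'   `list(instructed = ..., feedback = ...)`), aligned to `seq`.
#' @param tr Repetition time, seconds.
#' @param orthogonalize Residualize successive modulators (default FALSE).
#' @param center Mean-center modulators before convolution (default TRUE).
#' @param cue_shape `"epoch"` (boxcar over the stimulus duration) or
#'   `"stick"`.
#' @param include_shock_pe Also add shock and PE modulators at cue offset
#'   (uses the first trace's prediction errors).
#' @param microtime Microtime bins per TR.
#' @param hrf_args Named list of overrides passed to [gamma_hrf()].
#' @return A tibble of class `fmri_design`: `t_s` plus one column per
#'   regressor. Metadata (orthogonalization flag, HRF parameters, the
#'   trial-level modulator block) in attribute `"meta"`.
#' @export
build_fmri_design <- function(seq, traces, tr = 2,
                              orthogonalize = FALSE, center = TRUE,
                              cue_shape = c("epoch", "stick"),
                              include_shock_pe = FALSE,
                              microtime = 16L,
                              hrf_args = list()) {
  cue_shape <- match.arg(cue_shape)
  check_flag(orthogonalize, "orthogonalize")
  check_flag(center, "center")
  if (inherits(traces, "ev_trace")) traces <- list(ev = traces)
  if (!length(traces) || is.null(names(traces)) || any(names(traces) == "")) {
    stopf("`traces` must be a named list of ev_trace objects.")
  }
  for (tr_i in traces) {
    if (nrow(tr_i) != nrow(seq) || any(tr_i$trial != seq$trial)) {
      stopf("build_fmri_design(): trace is not aligned to `seq`.")
    }
  }
  config <- attr(seq, "config") %||% task_config()
  dt <- tr / microtime
  t_end <- max(seq$onset_s) + config$stim_duration + config$isi +
    (hrf_args$duration %||% 32)
  grid <- seq(0, t_end, by = dt)
  n <- length(grid)
  tr_times <- seq(0, t_end, by = tr)
  tr_idx <- round(tr_times / dt) + 1L
  tr_idx <- tr_idx[tr_idx <= n]
  hrf <- do.call(gamma_hrf, c(list(dt = dt), hrf_args))

  bin_of <- function(times) pmin(n, floor(times / dt) + 1L)
  event_vec <- function(times, amplitudes = 1, width = 0) {
    x <- numeric(n)
    amplitudes <- rep(amplitudes, length.out = length(times))
    for (i in seq_along(times)) {
      if (width > 0) {
        idx <- bin_of(times[i]):bin_of(times[i] + width - dt / 2)
        x[idx] <- x[idx] + amplitudes[i]
      } else {
        x[bin_of(times[i])] <- x[bin_of(times[i])] + amplitudes[i] / dt
      }
    }
    x
  }

  onset_w <- if (cue_shape == "epoch") config$stim_duration else 0
  offsets <- seq$onset_s + config$stim_duration
  cols <- list()
  cols$cue_onset <- event_vec(seq$onset_s, 1, onset_w)
  cols$cue_offset <- event_vec(offsets, 1, 0)
  modulator_block <- list()
  ctr <- function(v) if (center) v - mean(v) else v
  for (nm in names(traces)) {
    v <- traces[[nm]]$v_presented
    modulator_block[[paste0("ev_", nm)]] <- v
    cols[[paste0("ev_", nm)]] <- event_vec(seq$onset_s, ctr(v), onset_w)
  }
  if (include_shock_pe) {
    shock <- as.numeric(seq$us)
    pe <- traces[[1]]$delta
    modulator_block$shock <- shock
    modulator_block$pe <- pe
    cols$shock <- event_vec(offsets, ctr(shock), 0)
    cols$pe <- event_vec(offsets, ctr(pe), 0)
  }
  instr <- attr(seq, "instructions")
  if (!is.null(instr) && nrow(instr)) {
    cols$instruction <- event_vec(instr$onset_s, 1, config$instruction_duration)
  }

  dm <- purrr::map(cols, convolve_downsample, hrf = hrf, dt = dt,
                   tr_idx = tr_idx)
  dm <- as_tibble(dm)

  mod_cols <- setdiff(names(dm), c("cue_onset", "cue_offset", "instruction"))
  if (orthogonalize && length(mod_cols)) {
    ordered <- names(dm)
    for (k in seq_along(ordered)) {
      nm <- ordered[k]
      if (!nm %in% mod_cols || k == 1L) next
      earlier <- as.matrix(dm[, ordered[seq_len(k - 1L)]])
      f <- lm.fit(cbind(1, earlier), dm[[nm]])
      dm[[nm]] <- f$residuals
    }
  }

  out <- bind_cols(tibble(t_s = grid[tr_idx]), dm)
  structure(out,
            meta = list(orthogonalized = orthogonalize, centered = center,
                        cue_shape = cue_shape, tr = tr, microtime = microtime,
                        hrf = attr(hrf, "params"),
                        modulators = if (length(modulator_block))
                          as_tibble(modulator_block) else NULL),
            class = c("fmri_design", class(out)))
}

#' Collinearity diagnostics for a design matrix
#'
#' Pairwise correlations and variance inflation factors of the design
#' columns, plus the rank of the trial-level modulator block. An exactly
#' dependent modulator set — such as EV, shock, and PE from one trace, where
#' PE = shock - EV — is flagged as rank-deficient.
#'
#' @param dm An `fmri_design` (or any data frame of regressor columns; a
#'   `t_s` column is ignored).
#' @return An object of class `collinearity_report`: list with
#'   `correlations` (long tibble), `vif` (tibble), `modulator_rank`,
#'   `modulator_cols`, and `rank_deficient`.
#' @export
collinearity_report <- function(dm) {
  X <- as.matrix(dm[, setdiff(names(dm), "t_s"), drop = FALSE])
  if (ncol(X) < 2L) stopf("collinearity_report() needs at least 2 columns.")
  keep <- apply(X, 2, function(c) sd(c) > 0)
  Xs <- scale(X[, keep, drop = FALSE])
  R <- stats::cor(Xs)
  ut <- which(upper.tri(R), arr.ind = TRUE)
  cors <- tibble(col_a = colnames(R)[ut[, "row"]],
                 col_b = colnames(R)[ut[, "col"]],
                 r = R[ut])
  vif <- tryCatch({
    Ri <- solve(R)
    tibble(column = colnames(Xs), vif = diag(Ri))
  }, error = function(e) tibble(column = colnames(Xs), vif = Inf))

  meta <- attr(dm, "meta")
  mod <- meta$modulators
  if (!is.null(mod)) {
    M <- scale(as.matrix(mod), scale = FALSE)
    rank <- qr(M, tol = 1e-10)$rank
    mod_cols <- names(mod)
  } else {
    rank <- qr(Xs, tol = 1e-10)$rank
    mod_cols <- colnames(Xs)
  }
  structure(
    list(correlations = cors, vif = vif,
         modulator_cols = mod_cols, modulator_rank = rank,
         rank_deficient = rank < length(mod_cols),
         near_duplicates = cors |> filter(abs(.data$r) > 0.999)),
    class = "collinearity_report")
}

#' @export
print.collinearity_report <- function(x, ...) {
  cat("<collinearity_report>\n")
  cat(sprintf("  modulator block: %s — rank %d/%d%s\n",
              paste(x$modulator_cols, collapse = ", "),
              x$modulator_rank, length(x$modulator_cols),
              if (x$rank_deficient) "  ** RANK DEFICIENT **" else ""))
  worst <- x$correlations |> arrange(desc(abs(.data$r))) |> head(3)
  for (i in seq_len(nrow(worst))) {
    cat(sprintf("  r(%s, %s) = %.3f\n", worst$col_a[i], worst$col_b[i],
                worst$r[i]))
  }
  cat(sprintf("  max VIF = %.3g\n", max(x$vif$vif)))
  invisible(x)
}

#' Write a design matrix as TSV with JSON metadata
#'
#' @param dm An `fmri_design`.
#' @param path Output TSV path; metadata goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_fmri_design <- function(dm, path) {
  write.table(as.data.frame(dm), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  meta <- attr(dm, "meta")
  meta$modulators <- NULL
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
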