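#' Initialize a 3-down-1-up staircase
#'
#' A transformed up-down track on orientation-offset magnitude: after three
#' consecutive correct responses the offset is divided by `10^step_log10`,
#' after any error it is multiplied by `10^step_log10`. This rule converges on
#' the stimulus level yielding `0.5^(1/3) ~ 79.4%` correct.
#'
#' @param start_level_deg initial offset magnitude, degrees (> 0).
#' @param step_log10 step size in log10 units (default 0.05, i.e. a factor
#'   `10^0.05 ~ 1.122` per move).
#' @param id optional staircase identifier carried into trial records.
#' @return An object of class `staircase_state`: fields `level_deg`,
#'   `step_log10`, `consecutive_correct`, `last_move` (`"none"`, `"down"`,
#'   `"up"`), `history` (data frame of level/correct/moved per trial) and
#'   `reversal_levels`.
#' @export
staircase_state <- function(start_level_deg, step_log10 = 0.05, id = 1L) {
  if (!is.numeric(start_level_deg) || start_level_deg <= 0)
    stop("start_level_deg must be > 0")
  if (!is.numeric(step_log10) || step_log10 <= 0)
    stop("step_log10 must be > 0")
  st <- list(
    id = id,
    level_deg = start_level_deg,
    step_log10 = step_log10,
    consecutive_correct = 0L,
    last_move = "none",
    history = list(level = numeric(0), correct = logical(0),
                   moved = character(0)),
    reversal_levels = numeric(0)
  )
  class(st) <- "staircase_state"
  st
}

#' Update a staircase with one response
#'
#' Implements the 3-down-1-up rule with multiplicative log steps:
#' an incorrect response multiplies the level by `10^step`, resets the
#' correct counter, and moves up; a third consecutive correct response
#' multiplies the level by `10^-step`, resets the counter, and moves down;
#' other correct responses leave the level unchanged. A reversal is recorded
#' whenever the move direction differs from the previous non-null move; the
#' level at the reversal-triggering trial (i.e. before the move) is appended
#' to `reversal_levels`.
#'
#' @param state a [staircase_state()].
#' @param correct logical, whether the response on the current trial (shown at
#'   `state$level_deg`) was correct.
#' @return The updated `staircase_state`.
#' @export
update_staircase <- function(state, correct) {
  stopifnot(inherits(state, "staircase_state"))
  if (!is.logical(correct) || length(correct) != 1L || is.na(correct))
    stop("correct must be a single TRUE/FALSE")
  lev <- state$level_deg
  fac <- 10^state$step_log10
  if (correct) {
    state$consecutive_correct <- state$consecutive_correct + 1L
    if (state$consecutive_correct >= 3L) {
      move <- "down"
      state$level_deg <- lev / fac
      state$consecutive_correct <- 0L
    } else {
      move <- "none"
    }
  } else {
    move <- "up"
    state$level_deg <- lev * fac
    state$consecutive_correct <- 0L
  }
  if (move != "none") {
    if (state$last_move != "none" && move != state$last_move)
      state$reversal_levels <- c(state$reversal_levels, lev)
    state$last_move <- move
  }
  state$history$level <- c(state$history$level, lev)
  state$history$correct <- c(state$history$correct, correct)
  state$history$moved <- c(state$history$moved, move)
  state
}

#' Staircase block configuration
#'
#' Defaults mirror a standard threshold block: two interleaved staircases
#' starting at 1 and 3 degrees offset, 0.05 log10 step, block ends when every
#' staircase has 10 reversals or after 200 trials; the first 4 reversals are
#' discarded and the following 6 averaged for the threshold.
#'
#' @param start_levels_deg starting offsets for the interleaved staircases.
#' @param step_log10 staircase step, log10 units.
#' @param max_trials trial cap per block.
#' @param reversals_to_stop per-staircase stop criterion.
#' @param discard_reversals initial reversals dropped from the estimate.
#' @param average_reversals reversals averaged for the estimate; must satisfy
#'   `discard_reversals + average_reversals = reversals_to_stop`.
#' @param pool_staircases if `TRUE`, reversals of all staircases in a block
#'   are pooled (in trial order) before discarding/averaging instead of being
#'   estimated per staircase and averaged (the default).
#' @return An object of class `block_config`.
#' @export
block_config <- function(start_levels_deg = c(1, 3), step_log10 = 0.05,
                         max_trials = 200L, reversals_to_stop = 10L,
                         discard_reversals = 4L, average_reversals = 6L,
                         pool_staircases = FALSE) {
  if (any(start_levels_deg <= 0)) stop("start levels must be > 0")
  if (discard_reversals + average_reversals != reversals_to_stop)
    stop("discard_reversals + average_reversals must equal reversals_to_stop")
  out <- list(start_levels_deg = start_levels_deg, step_log10 = step_log10,
              max_trials = as.integer(max_trials),
              reversals_to_stop = as.integer(reversals_to_stop),
              discard_reversals = as.integer(discard_reversals),
              average_reversals = as.integer(average_reversals),
              pool_staircases = isTRUE(pool_staircases))
  class(out) <- "block_config"
  out
}

#' Run one block of interleaved staircases
#'
#' On each trial one unfinished staircase (fewer than `reversals_to_stop`
#' reversals) is chosen uniformly at random; the signed test offset is
#' `+/- level` with a uniform random sign; the observer is queried; the
#' staircase is updated. The block stops when all staircases are finished or
#' `max_trials` trials have elapsed. Uses R's global RNG (seed with
#' `set.seed()` for reproducibility).
#'
#' @param observer a function `function(offset_deg) -> TRUE/FALSE`, the
#'   correctness of the response to a signed offset (see
#'   [observer_function()]).
#' @param config a [block_config()].
#' @param scheme optional [randomization_scheme()]; when supplied, each trial
#'   record carries the sampled `phase_deg` and `contrast`.
#' @param base optional base [gabor_spec()] used with `scheme`.
#' @return A list with `trials` (data frame: `trial`, `staircase_id`,
#'   `level_deg`, `offset_deg` signed, `phase_deg`, `contrast`, `correct`) and
#'   `staircases` (list of final [staircase_state()]s).
#' @export
run_block <- function(observer, config = block_config(), scheme = NULL,
                      base = gabor_spec()) {
  stopifnot(is.function(observer), inherits(config, "block_config"))
  n_sc <- length(config$start_levels_deg)
  nmax <- config$max_trials
  need <- config$reversals_to_stop
  fac <- 10^config$step_log10
  # flat staircase state, one slot per track (update_staircase semantics;
  # see the replay-equivalence test)
  lev <- config$start_levels_deg
  ncorr <- integer(n_sc)
  lastmv <- rep("none", n_sc)
  revs <- vector("list", n_sc)
  hist_lev <- vector("list", n_sc); hist_ok <- vector("list", n_sc)
  hist_mv <- vector("list", n_sc)
  trial <- integer(nmax); sc_id <- integer(nmax)
  level <- numeric(nmax); offset <- numeric(nmax)
  phase <- numeric(nmax); contrast <- numeric(nmax); corr <- logical(nmax)
  nrev <- integer(n_sc)
  t <- 0L
  repeat {
    open <- which(nrev < need)
    if (length(open) == 0L || t >= nmax) break
    t <- t + 1L
    i <- if (length(open) == 1L) open else open[sample.int(length(open), 1L)]
    l0 <- lev[i]
    sgn <- if (stats::runif(1) < 0.5) -1 else 1
    off <- sgn * l0
    if (!is.null(scheme)) {
      spec <- sample_trial_stimulus(scheme, base)
      phase[t] <- spec$phase_deg; contrast[t] <- spec$contrast
    } else {
      phase[t] <- base$phase_deg; contrast[t] <- base$contrast
    }
    ok <- observer(off)
    if (!is.logical(ok) || length(ok) != 1L || is.na(ok))
      stop("observer must return a single TRUE/FALSE")
    if (ok) {
      ncorr[i] <- ncorr[i] + 1L
      if (ncorr[i] >= 3L) {
        mv <- "down"; lev[i] <- l0 / fac; ncorr[i] <- 0L
      } else mv <- "none"
    } else {
      mv <- "up"; lev[i] <- l0 * fac; ncorr[i] <- 0L
    }
    if (mv != "none") {
      if (lastmv[i] != "none" && mv != lastmv[i]) {
        revs[[i]] <- c(revs[[i]], l0)
        nrev[i] <- nrev[i] + 1L
      }
      lastmv[i] <- mv
    }
    hist_lev[[i]] <- c(hist_lev[[i]], l0)
    hist_ok[[i]] <- c(hist_ok[[i]], ok)
    hist_mv[[i]] <- c(hist_mv[[i]], mv)
    trial[t] <- t; sc_id[t] <- i; level[t] <- l0
    offset[t] <- off; corr[t] <- ok
  }
  states <- lapply(seq_len(n_sc), function(i) {
    st <- staircase_state(config$start_levels_deg[i], config$step_log10,
                          id = i)
    st$level_deg <- lev[i]
    st$consecutive_correct <- ncorr[i]
    st$last_move <- lastmv[i]
    st$history <- list(level = hist_lev[[i]] %||% numeric(0),
                       correct = hist_ok[[i]] %||% logical(0),
                       moved = hist_mv[[i]] %||% character(0))
    st$reversal_levels <- revs[[i]] %||% numeric(0)
    st
  })
  keep <- seq_len(t)
  list(
    trials = data.frame(trial = trial[keep], staircase_id = sc_id[keep],
                        level_deg = level[keep], offset_deg = offset[keep],
                        phase_deg = phase[keep], contrast = contrast[keep],
                        correct = corr[keep]),
    staircases = states
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Threshold estimate from staircase reversals
#'
#' Per staircase: a track qualifies if it has at least `reversals_to_stop`
#' reversals; the first `discard_reversals` are dropped and the next
#' `average_reversals` are averaged (reversals beyond `reversals_to_stop`,
#' e.g. from over-collected blocks, are ignored so the estimator is identical
#' across blocks). The block estimate is the mean of the qualifying per-track
#' thresholds; if no track qualifies the estimate is invalid. With
#' `config$pool_staircases = TRUE` the reversal lists of all staircases in
#' the block are concatenated (staircase by staircase) before
#' discarding/averaging.
#'
#' @param staircases a single [staircase_state()] or a list of them (as
#'   returned by [run_block()]`$staircases`).
#' @param config a [block_config()].
#' @return An object of class `threshold_estimate`: `threshold_deg` (NA when
#'   invalid), `n_reversals_used`, `valid`, `source` (per-staircase detail).
#' @export
block_threshold <- function(staircases, config = block_config()) {
  if (inherits(staircases, "staircase_state")) staircases <- list(staircases)
  stopifnot(all(vapply(staircases, inherits, logical(1), "staircase_state")))
  need <- config$reversals_to_stop
  lo <- config$discard_reversals + 1L
  hi <- config$discard_reversals + config$average_reversals
  if (config$pool_staircases) {
    rev_all <- unlist(lapply(staircases, `[[`, "reversal_levels"))
    valid <- length(rev_all) >= need
    thr <- if (valid) mean(rev_all[lo:hi]) else NA_real_
    used <- if (valid) config$average_reversals else 0L
    src <- data.frame(staircase_id = NA_integer_,
                      n_reversals = length(rev_all), valid = valid)
  } else {
    per <- vapply(staircases, function(s) {
      r <- s$reversal_levels
      if (length(r) >= need) mean(r[lo:hi]) else NA_real_
    }, numeric(1))
    nrev <- vapply(staircases, function(s) length(s$reversal_levels), integer(1))
    ok <- !is.na(per)
    valid <- any(ok)
    thr <- if (valid) mean(per[ok]) else NA_real_
    used <- sum(ok) * config$average_reversals
    src <- data.frame(
      staircase_id = vapply(staircases, `[[`, integer(1), "id"),
      n_reversals = nrev, valid = ok, threshold_deg = per)
  }
  out <- list(threshold_deg = thr, n_reversals_used = as.integer(used),
              valid = valid, source = src)
  class(out) <- "threshold_estimate"
  out
}

#' @export
print.threshold_estimate <- function(x, ...) {
  if (x$valid)
    cat(sprintf("Block threshold: %.4f deg (%d reversals used)\n",
                x$threshold_deg, x$n_reversals_used))
  else cat("Block threshold: invalid (insufficient reversals)\n")
  invisible(x)
}
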