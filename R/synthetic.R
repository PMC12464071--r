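#' Simulated 2AFC observer
#'
#' A Weibull psychometric observer for the orientation-discrimination task:
#' \deqn{p(\mathrm{correct} \mid x) = 0.5 + (0.5 - \lambda)
#'   [1 - e^{-(x/s)^\beta}]}
#' where `x` is the unsigned orientation offset. The scale `s` is solved so
#' that accuracy at `x = alpha_deg` equals `0.5^(1/3) ~ 0.794`, the
#' convergence point of the 3-down-1-up staircase; `alpha_deg` is therefore
#' directly comparable to staircase threshold estimates. Responses are
#' sign-blind.
#'
#' @param alpha_deg offset (deg) at the 79.4%-correct point (> 0).
#' @param beta psychometric slope (default 2, a typical value for orientation
#'   discrimination).
#' @param lapse lapse rate in \[0, 0.1\].
#' @return An object of class `observer_model`.
#' @export
observer_model <- function(alpha_deg, beta = 2, lapse = 0) {
  if (alpha_deg <= 0) stop("alpha_deg must be > 0")
  if (lapse < 0 || lapse > 0.1) stop("lapse must lie in [0, 0.1]")
  if (beta <= 0) stop("beta must be > 0")
  target <- 0.5^(1 / 3)
  w_alpha <- (target - 0.5) / (0.5 - lapse)
  if (w_alpha >= 1) stop("lapse too large to reach the 79.4% point")
  scale <- alpha_deg / (-log(1 - w_alpha))^(1 / beta)
  out <- list(alpha_deg = alpha_deg, beta = beta, lapse = lapse,
              guess = 0.5, scale = scale)
  class(out) <- "observer_model"
  out
}

#' Probability of a correct response
#'
#' @param model an [observer_model()].
#' @param offset_deg signed or unsigned orientation offset(s), deg.
#' @return Probability/ies of a correct response.
#' @export
observer_p_correct <- function(model, offset_deg) {
  stopifnot(inherits(model, "observer_model"))
  x <- abs(offset_deg)
  w <- 1 - exp(-(x / model$scale)^model$beta)
  model$guess + (0.5 - model$lapse) * w
}

#' Draw one response from a simulated observer
#'
#' Bernoulli draw with `observer_p_correct()`; uses R's global RNG.
#'
#' @inheritParams observer_p_correct
#' @return `TRUE` (correct) or `FALSE`.
#' @export
observer_respond <- function(model, offset_deg) {
  stats::runif(length(offset_deg)) < observer_p_correct(model, offset_deg)
}

#' Observer as a response function for [run_block()]
#'
#' @param model an [observer_model()].
#' @return `function(offset_deg) -> TRUE/FALSE`.
#' @export
observer_function <- function(model) {
  force(model)
  function(offset_deg) observer_respond(model, offset_deg)[1]
}

#' Cohort specification for the synthetic learning experiment
#'
#' Describes a four-group pre/post threshold experiment (randomization:
#' phase/contrast x training location: UVF/LVF) with thresholds at the
#' training, near-transfer (C) and far-transfer (F) locations. Per subject,
#' pre-training thresholds are log-normal; learning indices are drawn from a
#' normal distribution whose means encode the group's improvement per
#' location; the C- and F-transfer LIs are drawn jointly from a bivariate
#' normal with the group's target correlation `rho`.
#'
#' Pre-thresholds decompose on the log scale into a subject ability factor
#' shared across locations (`pre_sdlog`) plus a smaller location-specific
#' deviation (`pre_sdlog_loc`); peripheral thresholds of one observer are
#' strongly correlated across nearby retinal locations, and the analysis
#' model carries only a subject intercept.
#'
#' Presets (the stated world of the generator):
#' \describe{
#'   \item{`"paper-like"`}{29 subjects (phase 6 UVF + 7 LVF, contrast
#'     8 UVF + 8 LVF); pre-threshold median 4.0 deg at every location (the
#'     three locations are iso-eccentric) with 0.25 subject and 0.10
#'     location-specific log-SD; mean improvements (deg)
#'     phase: 1.53 / 1.70 / 1.99, contrast: 1.40 / 1.50 / 1.31; LI SD 0.15;
#'     transfer-LI correlation 0.7 (phase) and 0 (contrast).}
#'   \item{`"null"`}{same design, all improvements 0, both correlations 0.}
#'   \item{`"high-noise"`}{paper-like means with LI SD 0.25 and 0.35 / 0.2
#'     log-SD pre-thresholds.}
#' }
#'
#' @param preset `"paper-like"`, `"null"` or `"high-noise"`.
#' @param n_per_group named integer vector, subjects per
#'   `phase.UVF`, `phase.LVF`, `contrast.UVF`, `contrast.LVF`.
#' @param pre_median_deg named medians of the log-normal pre-threshold
#'   distribution per location.
#' @param pre_sdlog log-SD of the subject ability factor (shared across
#'   locations).
#' @param pre_sdlog_loc log-SD of the location-specific pre-threshold
#'   deviation.
#' @param improvement_deg 2x3 matrix (rows phase/contrast, columns
#'   training/C-transfer/F-transfer) of mean threshold improvements in deg.
#' @param li_sd between-subject SD of learning indices.
#' @param rho named transfer-LI correlations per randomization group.
#' @param observer_beta,observer_lapse psychometric parameters of the
#'   simulated observers.
#' @param blocks_per_cell threshold blocks per time x location cell.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(preset = c("paper-like", "null", "high-noise"),
                        n_per_group = NULL, pre_median_deg = NULL,
                        pre_sdlog = NULL, pre_sdlog_loc = NULL,
                        improvement_deg = NULL,
                        li_sd = NULL, rho = NULL,
                        observer_beta = 2, observer_lapse = 0.02,
                        blocks_per_cell = 3L) {
  preset <- match.arg(preset)
  def_n <- c(phase.UVF = 6L, phase.LVF = 7L, contrast.UVF = 8L,
             contrast.LVF = 8L)
  def_pre <- c(training = 4.0, `C-transfer` = 4.0, `F-transfer` = 4.0)
  def_imp <- rbind(phase = c(1.53, 1.70, 1.99),
                   contrast = c(1.40, 1.50, 1.31))
  colnames(def_imp) <- names(def_pre)
  spec <- list(
    preset = preset,
    n_per_group = if (is.null(n_per_group)) def_n else n_per_group,
    pre_median_deg = if (is.null(pre_median_deg)) def_pre else pre_median_deg,
    pre_sdlog = if (is.null(pre_sdlog))
      (if (preset == "high-noise") 0.35 else 0.25) else pre_sdlog,
    pre_sdlog_loc = if (is.null(pre_sdlog_loc))
      (if (preset == "high-noise") 0.2 else 0.1) else pre_sdlog_loc,
    improvement_deg = if (is.null(improvement_deg)) {
      if (preset == "null") def_imp * 0 else def_imp
    } else improvement_deg,
    li_sd = if (is.null(li_sd))
      (if (preset == "high-noise") 0.25 else 0.15) else li_sd,
    rho = if (is.null(rho)) {
      if (preset == "null") c(phase = 0, contrast = 0)
      else c(phase = 0.7, contrast = 0)
    } else rho,
    observer_beta = observer_beta, observer_lapse = observer_lapse,
    blocks_per_cell = as.integer(blocks_per_cell)
  )
  if (any(abs(spec$rho) >= 1)) stop("rho must lie in (-1, 1)")
  if (any(spec$n_per_group < 1)) stop("n_per_group must be positive")
  class(spec) <- "cohort_spec"
  spec
}

# bivariate standard-normal pair with correlation rho
.rbvn <- function(n, rho) {
  z1 <- stats::rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
  cbind(z1, z2)
}

#' Simulate a full learning cohort
#'
#' For every subject: draw location-wise pre-training thresholds
#' (log-normal); draw the training-location LI and the (C-transfer,
#' F-transfer) LI pair (bivariate normal at the group's target correlation);
#' form post thresholds as `pre * (1 + LI)` (resampling a subject at most 20
#' times if a post threshold would be nonpositive); then run the configured
#' number of staircase blocks per time x location cell against a Weibull
#' observer whose 79.4% point equals the subject's true threshold. Learning
#' is applied between sessions only (thresholds are constant within a block).
#'
#' With `method = "staircase"` (default) block thresholds come from actual
#' interleaved-staircase runs ([run_block()] + [block_threshold()]) and the
#' full trial logs are returned; `method = "direct"` skips the staircases and
#' draws block thresholds as `truth * exp(N(0, meas_sdlog))`, a fast stand-in
#' with log-normal measurement error.
#'
#' @param spec a [cohort_spec()].
#' @param config a [block_config()] for the staircase runs.
#' @param method `"staircase"` or `"direct"`.
#' @param meas_sdlog log-scale SD of block measurement error for
#'   `method = "direct"` (default 0.15, matching the spread of simulated
#'   staircase estimates).
#' @param include_training also simulate 4 training sessions x 5 blocks at
#'   the training location, with the subject's threshold decaying along a
#'   power law from pre to post (for learning-curve fits).
#' @param trial_logs keep per-trial logs (staircase method only).
#' @return A list: `cohort` (block-level [as_cohort_table()] table; invalid
#'   blocks are dropped and counted in `n_invalid_blocks`), `subjects`
#'   (per-subject truth: true thresholds and LIs), `trials` (trial-log data
#'   frame or `NULL`), `training` (training-session block thresholds or
#'   `NULL`), `n_invalid_blocks`.
#' @export
simulate_cohort <- function(spec = cohort_spec(), config = block_config(),
                            method = c("staircase", "direct"),
                            meas_sdlog = 0.15, include_training = FALSE,
                            trial_logs = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(spec, "cohort_spec"))
  locs <- c("training", "C-transfer", "F-transfer")
  groups <- names(spec$n_per_group)
  subj_rows <- list(); cohort_rows <- list(); trial_rows <- list()
  train_rows <- list()
  n_invalid <- 0L
  sid <- 0L
  for (g in groups) {
    parts <- strsplit(g, ".", fixed = TRUE)[[1]]
    rnd <- parts[1]; tloc <- parts[2]
    for (k in seq_len(spec$n_per_group[[g]])) {
      sid <- sid + 1L
      subject <- sprintf("S%02d", sid)
      for (try in 1:20) {
        ability <- stats::rnorm(1, 0, spec$pre_sdlog)
        pre <- exp(log(spec$pre_median_deg) + ability +
                     stats::rnorm(3, 0, spec$pre_sdlog_loc))
        names(pre) <- locs
        li_mu <- -spec$improvement_deg[rnd, locs] / spec$pre_median_deg[locs]
        z <- .rbvn(1, spec$rho[[rnd]])
        li <- c(stats::rnorm(1, li_mu[1], spec$li_sd),
                li_mu[2] + spec$li_sd * z[1],
                li_mu[3] + spec$li_sd * z[2])
        names(li) <- locs
        post <- pre * (1 + li)
        if (all(post > 0.05)) break
        if (try == 20) {
          warning("post-threshold resampling limit reached; clipping")
          post <- pmax(post, 0.05)
        }
      }
      subj_rows[[sid]] <- data.frame(
        subject_id = subject, randomization = rnd, training_location = tloc,
        location = locs, pre_true = as.numeric(pre),
        post_true = as.numeric(post), li_true = as.numeric(li),
        row.names = NULL)
      for (time in c("pre", "post")) for (loc in locs) {
        truth <- if (time == "pre") pre[[loc]] else post[[loc]]
        for (b in seq_len(spec$blocks_per_cell)) {
          if (method == "direct") {
            thr <- truth * exp(stats::rnorm(1, 0, meas_sdlog))
            valid <- TRUE
          } else {
            obs <- observer_function(observer_model(
              truth, beta = spec$observer_beta, lapse = spec$observer_lapse))
            blk <- run_block(obs, config)
            est <- block_threshold(blk$staircases, config)
            thr <- est$threshold_deg
            valid <- est$valid
            if (trial_logs) {
              tr <- blk$trials
              tr$subject_id <- subject; tr$randomization <- rnd
              tr$training_location <- tloc
              tr$session_type <- time; tr$session_index <- 1L
              tr$block <- b; tr$location <- loc
              trial_rows[[length(trial_rows) + 1L]] <- tr
            }
          }
          if (!valid || !is.finite(thr)) { n_invalid <- n_invalid + 1L; next }
          cohort_rows[[length(cohort_rows) + 1L]] <- data.frame(
            Subject = subject, Time = time, Randomization = rnd,
            Location = loc, TrainingLocation = tloc, block = b,
            threshold = thr)
        }
      }
      if (include_training) {
        # threshold decays as a + (pre - a) * b^(-0.6) over the 20 training
        # blocks, landing near the post threshold at the training location
        n_tb <- 20L
        a_inf <- post[["training"]]
        decay <- (seq_len(n_tb))^(-0.6)
        decay <- (decay - decay[n_tb]) / (decay[1] - decay[n_tb])
        tru <- a_inf + (pre[["training"]] - a_inf) * decay
        for (b in seq_len(n_tb)) {
          if (method == "direct") {
            thr <- tru[b] * exp(stats::rnorm(1, 0, meas_sdlog))
            valid <- TRUE
          } else {
            obs <- observer_function(observer_model(
              tru[b], beta = spec$observer_beta, lapse = spec$observer_lapse))
            est <- block_threshold(run_block(obs, config)$staircases, config)
            thr <- est$threshold_deg; valid <- est$valid
          }
          if (!valid || !is.finite(thr)) next
          train_rows[[length(train_rows) + 1L]] <- data.frame(
            subject_id = subject, session = (b - 1L) %/% 5L + 1L,
            block = b, threshold = thr, truth = tru[b])
        }
      }
    }
  }
  cohort <- as_cohort_table(do.call(rbind, cohort_rows))
  list(cohort = cohort,
       subjects = do.call(rbind, subj_rows),
       trials = if (length(trial_rows)) do.call(rbind, trial_rows) else NULL,
       training = if (length(train_rows)) do.call(rbind, train_rows) else NULL,
       n_invalid_blocks = n_invalid)
}

#' Subject-level threshold and learning-index summary
#'
#' Averages block thresholds per subject x time x location and computes the
#' learning index per location. The subject-level mean is the standard
#' summary layer; the block-level table remains available for the mixed
#' model.
#'
#' @param cohort a block-level cohort table (see [as_cohort_table()]).
#' @return Data frame with one row per subject: mean pre/post thresholds and
#'   LI per location (`pre_training`, `post_training`, `li_training`, ...,
#'   suffixes `training`, `C`, `F`), plus `randomization` and
#'   `training_location`.
#' @export
subject_summary <- function(cohort) {
  cohort <- as_cohort_table(cohort)
  agg <- stats::aggregate(
    threshold ~ Subject + Time + Location + Randomization + TrainingLocation,
    data = cohort, FUN = mean)
  suffix <- c(training = "training", `C-transfer` = "C", `F-transfer` = "F")
  out <- NULL
  for (s in levels(droplevels(agg$Subject))) {
    a <- agg[agg$Subject == s, ]
    row <- data.frame(subject_id = s,
                      randomization = as.character(a$Randomization[1]),
                      training_location = as.character(a$TrainingLocation[1]))
    for (loc in names(suffix)) {
      pre <- a$threshold[a$Time == "pre" & a$Location == loc]
      post <- a$threshold[a$Time == "post" & a$Location == loc]
      row[[paste0("pre_", suffix[[loc]])]] <-
        if (length(pre)) pre else NA_real_
      row[[paste0("post_", suffix[[loc]])]] <-
        if (length(post)) post else NA_real_
      row[[paste0("li_", suffix[[loc]])]] <-
        if (length(pre) && length(post)) learning_index(pre, post)
        else NA_real_
    }
    out <- rbind(out, row)
  }
  rownames(out) <- NULL
  out
}

#' Gaze-trace specification
#'
#' The stated world of the eye-trace generator: 1000-Hz positions are a
#' random-walk drift (step SD `drift_sd` dva/sample, a drift speed near 1
#' dva/s) plus white measurement noise (`noise_sd` dva, a high-precision
#' video tracker) and injected minimum-jerk microsaccades. Microsaccade
#' onsets follow a Poisson process at `ms_rate_hz` with an 80-ms refractory
#' gap; amplitudes are log-normal (median `amp_median_dva`, log-SD
#' `amp_sdlog`) truncated below 1 dva; peak velocity follows the main
#' sequence `gain * amplitude * (1 + eps)` with relative noise
#' `gain_noise`, which fixes the event duration at `1.875 / (gain (1+eps))`
#' seconds (the minimum-jerk peak-velocity identity). Blinks occur with
#' probability `blink_prob` per trial and last 100-300 ms.
#'
#' @param duration_ms trial duration (default 1334 ms = 200 pre-reference +
#'   92 reference + 600 ISI + 92 test + 350 post-test).
#' @param drift_sd random-walk step SD, dva/sample.
#' @param noise_sd white position-noise SD, dva.
#' @param ms_rate_hz microsaccade rate, events/s.
#' @param amp_median_dva,amp_sdlog amplitude distribution parameters.
#' @param amp_min_dva lower truncation of the amplitude distribution.
#' @param gain main-sequence gain, (dva/s)/dva.
#' @param gain_noise relative SD of peak velocity about the main sequence.
#' @param blink_prob per-trial blink probability.
#' @return An object of class `trace_spec`.
#' @export
trace_spec <- function(duration_ms = 1334, drift_sd = 0.002,
                       noise_sd = 0.005, ms_rate_hz = 1.5,
                       amp_median_dva = 0.3, amp_sdlog = 0.4,
                       amp_min_dva = 0.05, gain = 100,
                       gain_noise = 0.1, blink_prob = 0.05) {
  stopifnot(duration_ms >= 50, drift_sd >= 0, noise_sd >= 0,
            ms_rate_hz >= 0, gain > 0, gain_noise >= 0,
            blink_prob >= 0, blink_prob <= 1, amp_min_dva < 1)
  out <- list(duration_ms = as.integer(duration_ms), drift_sd = drift_sd,
              noise_sd = noise_sd, ms_rate_hz = ms_rate_hz,
              amp_median_dva = amp_median_dva, amp_sdlog = amp_sdlog,
              amp_min_dva = amp_min_dva,
              gain = gain, gain_noise = gain_noise, blink_prob = blink_prob)
  class(out) <- "trace_spec"
  out
}

# minimum-jerk displacement profile on [0, 1]
.minjerk <- function(tau) 10 * tau^3 - 15 * tau^4 + 6 * tau^5

#' Simulate one 1000-Hz gaze trace with ground-truth microsaccades
#'
#' @param spec a [trace_spec()].
#' @param trial_id identifier stamped on the samples.
#' @param t0_ms time of the first sample.
#' @return A list: `trace` (data frame `trial_id`, `t_ms`, `x_dva`, `y_dva`,
#'   `valid`, `blink`) and `events` (ground truth: `onset_ms`,
#'   `offset_ms`, `amplitude_dva`, `peak_velocity_dva_s`, `direction_rad`).
#' @export
simulate_trace <- function(spec = trace_spec(), trial_id = 1L, t0_ms = 0L) {
  stopifnot(inherits(spec, "trace_spec"))
  n <- spec$duration_ms
  t <- seq.int(t0_ms, length.out = n)
  x <- cumsum(stats::rnorm(n, 0, spec$drift_sd))
  y <- cumsum(stats::rnorm(n, 0, spec$drift_sd))
  # injected microsaccades: Poisson onsets with refractory spacing
  ev <- NULL
  if (spec$ms_rate_hz > 0) {
    pos <- 1
    repeat {
      gap <- stats::rexp(1, spec$ms_rate_hz / 1000) + 80
      pos <- pos + gap
      amp <- stats::rlnorm(1, log(spec$amp_median_dva), spec$amp_sdlog)
      if (amp >= 1 || amp < spec$amp_min_dva) next # truncated to [min, 1)
      eps <- stats::rnorm(1, 0, spec$gain_noise)
      peak <- spec$gain * amp * max(1 + eps, 0.2)
      dur <- max(6, round(1000 * 1.875 * amp / peak))
      if (pos + dur > n - 5) break
      i0 <- round(pos)
      idx <- i0:(i0 + dur - 1L)
      theta <- stats::runif(1, 0, 2 * pi)
      prof <- amp * .minjerk(seq(0, 1, length.out = dur))
      x[idx[1]:n] <- x[idx[1]:n] + c(prof, rep(amp, n - idx[1] - dur + 1)) *
        cos(theta)
      y[idx[1]:n] <- y[idx[1]:n] + c(prof, rep(amp, n - idx[1] - dur + 1)) *
        sin(theta)
      ev <- rbind(ev, data.frame(
        onset_ms = t[i0], offset_ms = t[i0 + dur - 1L], amplitude_dva = amp,
        peak_velocity_dva_s = 1.875 * amp / (dur / 1000),
        direction_rad = theta))
      pos <- pos + dur
    }
  }
  x <- x + stats::rnorm(n, 0, spec$noise_sd)
  y <- y + stats::rnorm(n, 0, spec$noise_sd)
  blink <- rep(FALSE, n)
  if (stats::runif(1) < spec$blink_prob) {
    bdur <- round(stats::runif(1, 100, 300))
    bstart <- sample.int(max(n - bdur, 1), 1)
    blink[bstart:min(bstart + bdur - 1, n)] <- TRUE
  }
  trace <- data.frame(trial_id = trial_id, t_ms = t, x_dva = x, y_dva = y,
                      valid = !blink, blink = blink)
  if (is.null(ev))
    ev <- data.frame(onset_ms = numeric(0), offset_ms = numeric(0),
                     amplitude_dva = numeric(0),
                     peak_velocity_dva_s = numeric(0),
                     direction_rad = numeric(0))
  list(trace = trace, events = ev)
}
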