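#' Mask blink intervals in a gaze trace
#'
#' Samples inside `[blink_start - pre_ms, blink_end + post_ms]` around every
#' blink are marked invalid. Blinks are the runs of `blink = TRUE` if the
#' trace carries a `blink` column; otherwise the runs of `valid = FALSE` are
#' taken as blinks and recorded in a new `blink` column, which makes the
#' operation idempotent (re-masking expands from the original blinks, not
#' from the already-expanded invalid runs). Overlapping margins merge into a
#' single invalid run.
#'
#' @param trace data frame with `t_ms` (strictly increasing, 1-ms steps
#'   within a trial), `x_dva`, `y_dva`, `valid`, optionally `blink` and
#'   `trial_id`.
#' @param pre_ms,post_ms exclusion margins before/after each blink (default
#'   100 and 150 ms).
#' @return The trace with updated `valid` and a `blink` column.
#' @export
mask_blinks <- function(trace, pre_ms = 100, post_ms = 150) {
  stopifnot(is.data.frame(trace),
            all(c("t_ms", "valid") %in% names(trace)))
  if (!"blink" %in% names(trace)) trace$blink <- !trace$valid
  ids <- if ("trial_id" %in% names(trace)) trace$trial_id else
    rep(1L, nrow(trace))
  valid <- !trace$blink
  for (id in unique(ids)) {
    i <- which(ids == id)
    bl <- trace$blink[i]
    if (!any(bl)) next
    t <- trace$t_ms[i]
    r <- rle(bl)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      lo <- t[starts[j]] - pre_ms
      hi <- t[ends[j]] + post_ms
      valid[i][t >= lo & t <= hi] <- FALSE
    }
  }
  trace$valid <- valid
  trace
}

#' Segment a continuous gaze trace into trial windows
#'
#' Cuts each trial's window from `pre_ref_ms` before reference onset to
#' `post_target_ms` after test-grating offset. Trials whose window contains
#' any blink sample are flagged invalid (they still appear in the output but
#' are excluded from microsaccade-percentage denominators). Trials with
#' missing markers are skipped with a warning.
#'
#' @param trace a gaze trace (see [mask_blinks()]); blinks should be masked
#'   first.
#' @param markers data frame with one row per trial: `trial_id`,
#'   `ref_onset_ms`, `ref_offset_ms`, `test_onset_ms`, `test_offset_ms`, and
#'   optionally `fix_x_dva`, `fix_y_dva`.
#' @param pre_ref_ms window start relative to reference onset (default 200).
#' @param post_target_ms window end relative to test offset (default 350).
#' @return A list of per-trial traces; each has attributes `markers` (its
#'   marker row), `window` (`c(start, end)` in ms) and `valid_trial`
#'   (no blink in the window).
#' @export
segment_trials <- function(trace, markers, pre_ref_ms = 200,
                           post_target_ms = 350) {
  stopifnot(is.data.frame(markers),
            all(c("trial_id", "ref_onset_ms", "test_offset_ms") %in%
                  names(markers)))
  if (!"blink" %in% names(trace)) trace$blink <- !trace$valid
  out <- list()
  for (k in seq_len(nrow(markers))) {
    m <- markers[k, ]
    if (is.na(m$ref_onset_ms) || is.na(m$test_offset_ms)) {
      warning(sprintf("trial %s: missing markers, skipped", m$trial_id))
      next
    }
    w <- c(m$ref_onset_ms - pre_ref_ms, m$test_offset_ms + post_target_ms)
    seg <- trace[trace$t_ms >= w[1] & trace$t_ms <= w[2], , drop = FALSE]
    seg$trial_id <- m$trial_id
    attr(seg, "markers") <- m
    attr(seg, "window") <- w
    attr(seg, "valid_trial") <- !any(seg$blink)
    out[[as.character(m$trial_id)]] <- seg
  }
  out
}

# 5-sample centered-difference velocity (Engbert-Kliegl kernel):
# v_t = (p_{t+2} + p_{t+1} - p_{t-1} - p_{t-2}) / (6 * dt)
.velocity5 <- function(p, dt_s) {
  n <- length(p)
  v <- rep(NA_real_, n)
  if (n >= 5)
    v[3:(n - 2)] <- (p[5:n] + p[4:(n - 1)] - p[2:(n - 3)] - p[1:(n - 4)]) /
      (6 * dt_s)
  v
}

#' Detect microsaccades in a single-trial gaze trace
#'
#' Velocity-based detection: 2-D velocities from a 5-sample centered
#' difference at the 1000-Hz sampling rate, scalar speed as the Euclidean
#' norm. A candidate is a maximal run of samples whose speed exceeds the
#' trial's threshold for at least `min_dur_ms`; candidates separated by less
#' than `min_gap_ms` are merged; events with amplitude of `max_amp_dva` or
#' more are discarded. Amplitude is the component-wise range,
#' `sqrt((max x - min x)^2 + (max y - min y)^2)`, over the event; peak
#' velocity is the maximum speed. The default threshold (`"median"`) is the
#' classical robust estimator of the velocity-threshold algorithm:
#' `sigma = sqrt(median(v^2) - median(v)^2)` per component, with the elliptic
#' criterion `(vx/(lambda sx))^2 + (vy/(lambda sy))^2 > 1` at `lambda = 6`.
#' The robust estimator is insensitive to the saccades themselves;
#' `threshold = "mean_sd"` (`mean(speed) + lambda * sd(speed)`) follows the
#' literal "6 SD above the average velocity" wording but is inflated by large
#' events in the trial and clips or misses small ones.
#'
#' @param trial data frame with `t_ms`, `x_dva`, `y_dva`, `valid` for one
#'   trial; invalid samples are excluded from velocities and thresholding.
#' @param lambda threshold multiplier (default 6).
#' @param min_dur_ms minimum duration above threshold (default 6).
#' @param min_gap_ms candidates closer than this are merged (default 10).
#' @param max_amp_dva amplitude cutoff; events at or above are discarded
#'   (default 1).
#' @param threshold `"median"` (default, robust) or `"mean_sd"` (literal).
#' @return Data frame of events: `onset_ms`, `offset_ms`, `amplitude_dva`,
#'   `peak_velocity_dva_s`, and `trial_id` when present in the input. Empty
#'   (zero rows) when fewer than 20 valid samples are available.
#' @export
detect_microsaccades <- function(trial, lambda = 6, min_dur_ms = 6,
                                 min_gap_ms = 10, max_amp_dva = 1,
                                 threshold = c("median", "mean_sd")) {
  threshold <- match.arg(threshold)
  stopifnot(all(c("t_ms", "x_dva", "y_dva", "valid") %in% names(trial)))
  empty <- data.frame(onset_ms = numeric(0), offset_ms = numeric(0),
                      amplitude_dva = numeric(0),
                      peak_velocity_dva_s = numeric(0))
  if ("trial_id" %in% names(trial)) empty$trial_id <- character(0)
  if (sum(trial$valid) < 20) return(empty)
  vx <- .velocity5(trial$x_dva, 1e-3)
  vy <- .velocity5(trial$y_dva, 1e-3)
  # a velocity sample is trusted only if the whole kernel support is valid
  ok <- trial$valid
  n <- length(ok)
  kernel_ok <- ok
  for (s in c(-2L, -1L, 1L, 2L)) {
    sh <- rep(FALSE, n)
    idx <- seq_len(n) + s
    inb <- idx >= 1 & idx <= n
    sh[inb] <- ok[idx[inb]]
    kernel_ok <- kernel_ok & sh
  }
  use <- kernel_ok & !is.na(vx) & !is.na(vy)
  if (sum(use) < 20) return(empty)
  if (threshold == "mean_sd") {
    speed <- sqrt(vx^2 + vy^2)
    thr <- mean(speed[use]) + lambda * stats::sd(speed[use])
    above <- use & speed > thr
  } else {
    sdx <- sqrt(stats::median(vx[use]^2) - stats::median(vx[use])^2)
    sdy <- sqrt(stats::median(vy[use]^2) - stats::median(vy[use])^2)
    sdx <- max(sdx, 1e-9); sdy <- max(sdy, 1e-9)
    speed <- sqrt(vx^2 + vy^2)
    above <- use & ((vx / (lambda * sdx))^2 + (vy / (lambda * sdy))^2 > 1)
  }
  above[is.na(above)] <- FALSE
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand <- data.frame(s = starts[r$values], e = ends[r$values])
  t <- trial$t_ms
  if (nrow(cand)) {
    dur <- t[cand$e] - t[cand$s] + 1
    cand <- cand[dur >= min_dur_ms, , drop = FALSE]
  }
  # merge candidates separated by < min_gap_ms
  if (nrow(cand) > 1) {
    merged <- cand[1, , drop = FALSE]
    for (k in 2:nrow(cand)) {
      gap <- t[cand$s[k]] - t[merged$e[nrow(merged)]]
      if (gap < min_gap_ms) merged$e[nrow(merged)] <- cand$e[k]
      else merged <- rbind(merged, cand[k, ])
    }
    cand <- merged
  }
  if (!nrow(cand)) return(empty)
  rows <- lapply(seq_len(nrow(cand)), function(k) {
    i <- cand$s[k]:cand$e[k]
    amp <- sqrt(diff(range(trial$x_dva[i]))^2 +
                  diff(range(trial$y_dva[i]))^2)
    data.frame(onset_ms = t[cand$s[k]], offset_ms = t[cand$e[k]],
               amplitude_dva = amp,
               peak_velocity_dva_s = max(speed[i], na.rm = TRUE))
  })
  ev <- do.call(rbind, rows)
  ev <- ev[ev$amplitude_dva < max_amp_dva, , drop = FALSE]
  if ("trial_id" %in% names(trial) && nrow(ev))
    ev$trial_id <- trial$trial_id[1]
  else if ("trial_id" %in% names(trial)) ev$trial_id <- character(0)
  rownames(ev) <- NULL
  ev
}

#' Microsaccade rate (events per second)
#'
#' The average number of event onsets per 1-ms time point across trials,
#' multiplied by the 1000-Hz sampling rate: `1000 * n_events /
#' total_trial_duration_ms`.
#'
#' @param events data frame of detected events (may be empty).
#' @param segments list of per-trial traces (see [segment_trials()]), used
#'   for the total duration.
#' @return Events per second.
#' @export
ms_rate <- function(events, segments) {
  if (length(segments) == 0L) stop("need at least one trial")
  total_ms <- sum(vapply(segments, nrow, numeric(1)))
  1000 * nrow(events) / total_ms
}

#' Microsaccades per valid trial
#'
#' `n_events / n_valid_trials`, where valid trials are those without a blink.
#'
#' @param n_events number of events in the window of interest.
#' @param n_valid_trials number of blink-free trials (> 0).
#' @return The per-trial microsaccade percentage (a ratio).
#' @export
ms_percentage <- function(n_events, n_valid_trials) {
  if (n_valid_trials <= 0) stop("no valid trials")
  n_events / n_valid_trials
}

#' Across-trial fixation variability
#'
#' Per trial, the mean Euclidean distance of valid gaze samples to the
#' fixation point during stimulus presentation (the union of the reference
#' and test windows by default); the returned value is the across-trial
#' sample standard deviation of those means, in dva.
#'
#' @param segments list of per-trial traces with marker attributes
#'   ([segment_trials()]).
#' @param fix_point length-2 numeric `c(x, y)` in dva; when `NULL`, taken
#'   from `fix_x_dva`/`fix_y_dva` in each trial's markers.
#' @param window `"both"` (default), `"reference"` or `"test"`.
#' @return Standard deviation (dva) of per-trial mean gaze-to-fixation
#'   distances.
#' @export
fixation_variability <- function(segments, fix_point = NULL,
                                 window = c("both", "reference", "test")) {
  window <- match.arg(window)
  dists <- vapply(segments, function(seg) {
    m <- attr(seg, "markers")
    fp <- if (!is.null(fix_point)) fix_point else
      c(m$fix_x_dva, m$fix_y_dva)
    inref <- seg$t_ms >= m$ref_onset_ms & seg$t_ms <= m$ref_offset_ms
    intst <- seg$t_ms >= m$test_onset_ms & seg$t_ms <= m$test_offset_ms
    sel <- switch(window, both = inref | intst, reference = inref,
                  test = intst)
    sel <- sel & seg$valid
    if (!any(sel)) return(NA_real_)
    mean(sqrt((seg$x_dva[sel] - fp[1])^2 + (seg$y_dva[sel] - fp[2])^2))
  }, numeric(1))
  dists <- dists[is.finite(dists)]
  if (length(dists) < 2) stop("need >= 2 trials with stimulus-window samples")
  stats::sd(dists)
}

#' Main-sequence correlation of detected microsaccades
#'
#' Pearson correlation between event amplitude and peak velocity (the
#' amplitude-velocity "main sequence"); delegates to [pearson_r_test()].
#'
#' @param events data frame with `amplitude_dva` and `peak_velocity_dva_s`;
#'   needs >= 4 events.
#' @return As [pearson_r_test()].
#' @export
main_sequence <- function(events) {
  if (nrow(events) < 4) stop("need >= 4 events")
  pearson_r_test(events$amplitude_dva, events$peak_velocity_dva_s)
}
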