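# balanced null cohort drawn from the analysis model itself:
# threshold = mu + subject intercept + iid noise, no fixed effects
null_model_cohort <- function(n_subj = 24, blocks = 1, subj_sd = 1,
                              resid_sd = 1, mu = 10) {
  groups <- expand.grid(Randomization = c("phase", "contrast"),
                        TrainingLocation = c("UVF", "LVF"),
                        stringsAsFactors = FALSE)
  per <- n_subj / nrow(groups)
  stopifnot(per == round(per))
  rows <- list()
  sid <- 0L
  for (g in seq_len(nrow(groups))) for (k in seq_len(per)) {
    sid <- sid + 1L
    b0 <- rnorm(1, 0, subj_sd)
    cell <- expand.grid(Time = c("pre", "post"),
                        Location = c("training", "C-transfer", "F-transfer"),
                        block = seq_len(blocks), stringsAsFactors = FALSE)
    cell$Subject <- sprintf("S%02d", sid)
    cell$Randomization <- groups$Randomization[g]
    cell$TrainingLocation <- groups$TrainingLocation[g]
    cell$threshold <- pmax(mu + b0 + rnorm(nrow(cell), 0, resid_sd), 0.1)
    rows[[sid]] <- cell
  }
  as_cohort_table(do.call(rbind, rows))
}

# flat gaze trace with optional injected minimum-jerk saccades
flat_trace <- function(n = 1200, noise_sd = 0.003, t0 = 0) {
  data.frame(trial_id = 1L, t_ms = seq.int(t0, length.out = n),
             x_dva = rnorm(n, 0, noise_sd), y_dva = rnorm(n, 0, noise_sd),
             valid = TRUE, blink = FALSE)
}

inject_saccade <- function(trace, onset_idx, amplitude, duration_ms = 20,
                           direction = 0) {
  n <- nrow(trace)
  prof <- amplitude * (10 * seq(0, 1, length.out = duration_ms)^3 -
                         15 * seq(0, 1, length.out = duration_ms)^4 +
                         6 * seq(0, 1, length.out = duration_ms)^5)
  idx <- onset_idx:(onset_idx + duration_ms - 1L)
  stopifnot(max(idx) <= n)
  shift <- c(rep(0, onset_idx - 1L), prof,
             rep(amplitude, n - onset_idx - duration_ms + 1L))
  trace$x_dva <- trace$x_dva + shift * cos(direction)
  trace$y_dva <- trace$y_dva + shift * sin(direction)
  trace
}
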