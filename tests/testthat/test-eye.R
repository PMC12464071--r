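test_that("blink masking expands by -100/+150 ms and is idempotent", {
  tr <- flat_trace(1000)
  tr$valid[tr$t_ms >= 500 & tr$t_ms <= 600] <- FALSE
  tr$blink <- NULL
  m1 <- mask_blinks(tr)
  expect_true(all(!m1$valid[m1$t_ms >= 400 & m1$t_ms <= 750]))
  expect_true(all(m1$valid[m1$t_ms < 400 | m1$t_ms > 750]))
  m2 <- mask_blinks(m1)
  expect_identical(m1, m2)
})

test_that("a blink-free trace is unchanged and adjacent blinks merge", {
  tr <- flat_trace(500)
  clean <- mask_blinks(tr)
  expect_true(all(clean$valid))
  tr2 <- flat_trace(1200)
  tr2$valid[tr2$t_ms %in% 300:350] <- FALSE
  tr2$valid[tr2$t_ms %in% 450:500] <- FALSE # margins overlap: 200-500+150
  tr2$blink <- NULL
  m <- mask_blinks(tr2)
  runs <- rle(m$valid)
  expect_equal(sum(!runs$values), 1L) # one merged invalid run
  expect_true(all(!m$valid[m$t_ms >= 200 & m$t_ms <= 650]))
})

test_that("trial segmentation cuts the stated window and flags blinks", {
  tr <- flat_trace(3000)
  tr$valid[tr$t_ms %in% 1500:1550] <- FALSE
  tr$blink <- NULL
  tr <- mask_blinks(tr)
  markers <- data.frame(trial_id = 1:2,
                        ref_onset_ms = c(1000, 2600),
                        ref_offset_ms = c(1092, 2692),
                        test_onset_ms = c(1692, 5000),
                        test_offset_ms = c(2184, NA))
  expect_warning(segs <- segment_trials(tr, markers), "missing markers")
  expect_length(segs, 1L)
  expect_equal(attr(segs[["1"]], "window"), c(800, 2534))
  expect_equal(range(segs[["1"]]$t_ms), c(800, 2534))
  expect_false(attr(segs[["1"]], "valid_trial")) # blink inside the window
  # partition: segments + skipped = total trials
  expect_equal(length(segs) + 1L, nrow(markers))
})

test_that("detector finds an injected saccade with accurate onset", {
  set.seed(50)
  tr <- inject_saccade(flat_trace(1200, noise_sd = 0.003), 600, 0.5,
                       duration_ms = 20)
  ev <- detect_microsaccades(tr)
  expect_equal(nrow(ev), 1L)
  expect_lte(abs(ev$onset_ms - (600 - 1)), 5)
  expect_equal(ev$amplitude_dva, 0.5, tolerance = 0.1)
  expect_gt(ev$peak_velocity_dva_s, 20)
})

test_that("detector discards large events and merges close ones", {
  set.seed(51)
  big <- inject_saccade(flat_trace(1200, noise_sd = 0.003), 600, 1.2,
                        duration_ms = 25)
  expect_equal(nrow(detect_microsaccades(big)), 0L)
  close2 <- inject_saccade(flat_trace(1200, noise_sd = 0.002), 500, 0.4,
                           duration_ms = 15)
  close2 <- inject_saccade(close2, 520, 0.4, duration_ms = 15) # 5 ms gap
  ev <- detect_microsaccades(close2)
  expect_equal(nrow(ev), 1L) # merged
})

test_that("detector returns empty output on unusable traces", {
  tr <- flat_trace(1200)
  tr$valid <- FALSE
  expect_equal(nrow(detect_microsaccades(tr)), 0L)
  short <- flat_trace(15)
  expect_equal(nrow(detect_microsaccades(short)), 0L)
})

test_that("ms rate and percentage follow their definitions", {
  segs <- lapply(1:100, function(i) flat_trace(1000))
  ev <- data.frame(onset_ms = rep(1, 100))
  expect_equal(ms_rate(ev, segs), 1.0)
  expect_equal(ms_rate(ev[0, , drop = FALSE], segs), 0)
  # doubling trials with identical statistics leaves the rate unchanged
  expect_equal(ms_rate(rbind(ev, ev), c(segs, segs)), 1.0)

  expect_equal(ms_percentage(50, 200), 0.25)
  expect_equal(ms_percentage(0, 10), 0)
  expect_error(ms_percentage(5, 0), "valid")
})

test_that("fixation variability is the across-trial SD of mean distances", {
  mk_seg <- function(dist) {
    seg <- flat_trace(400, noise_sd = 0)
    seg$x_dva <- dist
    attr(seg, "markers") <- data.frame(
      trial_id = 1, ref_onset_ms = 50, ref_offset_ms = 142,
      test_onset_ms = 250, test_offset_ms = 342,
      fix_x_dva = 0, fix_y_dva = 0)
    seg
  }
  segs <- list(mk_seg(0.1), mk_seg(0.3))
  expect_equal(fixation_variability(segs), sd(c(0.1, 0.3)))
  expect_equal(fixation_variability(segs), 0.1414214, tolerance = 1e-6)
  expect_equal(fixation_variability(list(mk_seg(0.2), mk_seg(0.2))), 0)
  expect_error(fixation_variability(segs[1]), ">= 2 trials")
})

test_that("fixation variability grows with drift amplitude", {
  gen <- function(drift) {
    set.seed(60)
    lapply(1:20, function(i) {
      seg <- simulate_trace(trace_spec(duration_ms = 800, drift_sd = drift,
                                       ms_rate_hz = 0,
                                       blink_prob = 0))$trace
      attr(seg, "markers") <- data.frame(
        trial_id = i, ref_onset_ms = 200, ref_offset_ms = 292,
        test_onset_ms = 500, test_offset_ms = 592,
        fix_x_dva = 0, fix_y_dva = 0)
      seg
    })
  }
  expect_gt(fixation_variability(gen(0.01)), fixation_variability(gen(0.001)))
})

test_that("main sequence correlation behaves like a correlation", {
  set.seed(61)
  amp <- runif(60, 0.1, 0.9)
  ev <- data.frame(amplitude_dva = amp,
                   peak_velocity_dva_s = 100 * amp * (1 + rnorm(60, 0, 0.1)))
  ms <- main_sequence(ev)
  expect_gt(ms$r, 0.9)
  # unit rescaling leaves r unchanged
  ev2 <- ev
  ev2$peak_velocity_dva_s <- ev2$peak_velocity_dva_s * 60
  expect_equal(main_sequence(ev2)$r, ms$r)
  const <- data.frame(amplitude_dva = rep(0.3, 10),
                      peak_velocity_dva_s = runif(10, 20, 40))
  expect_error(main_sequence(const), "zero-variance")
})
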