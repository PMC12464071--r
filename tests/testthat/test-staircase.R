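test_that("3-down-1-up updates move levels by 10^(+/-0.05)", {
  st <- staircase_state(1.0)
  st <- update_staircase(st, TRUE)
  st <- update_staircase(st, TRUE)
  expect_equal(st$level_deg, 1.0)
  expect_equal(st$consecutive_correct, 2L)
  st <- update_staircase(st, TRUE)
  expect_equal(st$level_deg, 10^(-0.05), tolerance = 1e-12) # ~0.8913
  expect_equal(st$consecutive_correct, 0L)

  st2 <- update_staircase(staircase_state(1.0), FALSE)
  expect_equal(st2$level_deg, 10^(0.05), tolerance = 1e-12) # ~1.1220
})

test_that("reversals record the level at the direction-changing trial", {
  st <- staircase_state(1.0)
  for (k in 1:3) st <- update_staircase(st, TRUE)   # down, no reversal yet
  expect_length(st$reversal_levels, 0)
  st <- update_staircase(st, FALSE)                 # up: reversal at 10^-0.05
  expect_equal(st$reversal_levels, 10^(-0.05))
  for (k in 1:3) st <- update_staircase(st, TRUE)   # down: reversal at 1.0
  expect_equal(st$reversal_levels, c(10^(-0.05), 1.0))
})

test_that("state invariants hold along random response sequences", {
  set.seed(1)
  st <- staircase_state(2.0)
  for (k in 1:300) {
    st <- update_staircase(st, runif(1) < 0.7)
    expect_lt(st$consecutive_correct, 3L)
    expect_gt(st$level_deg, 0)
  }
  # reversal moves alternate: number of reversals equals direction changes
  mv <- st$history$moved[st$history$moved != "none"]
  expect_equal(length(st$reversal_levels), sum(mv[-1] != mv[-length(mv)]))
})

test_that("block threshold averages reversals 5-10 and flags short blocks", {
  mk <- function(revs) {
    st <- staircase_state(1)
    st$reversal_levels <- revs
    st
  }
  revs <- c(5, 4, 3, 2, 1.5, 1.2, 1.0, 1.1, 0.9, 1.0)
  est <- block_threshold(mk(revs))
  expect_true(est$valid)
  expect_equal(est$threshold_deg, mean(revs[5:10])) # 1.116667
  expect_equal(est$threshold_deg, 1.1166667, tolerance = 1e-6)

  expect_false(block_threshold(mk(revs[1:9]))$valid)
  expect_true(is.na(block_threshold(mk(revs[1:9]))$threshold_deg))

  over <- block_threshold(mk(c(revs, 9, 9))) # over-collected reversals ignored
  expect_equal(over$threshold_deg, est$threshold_deg)
})

test_that("block estimate averages the qualifying staircases", {
  mk <- function(revs, id) {
    st <- staircase_state(1, id = id)
    st$reversal_levels <- revs
    st
  }
  a <- mk(rep(1, 10), 1L)
  b <- mk(rep(2, 10), 2L)
  expect_equal(block_threshold(list(a, b))$threshold_deg, 1.5)
  short <- mk(rep(2, 9), 2L)
  expect_equal(block_threshold(list(a, short))$threshold_deg, 1)
})

test_that("degenerate observers never reverse and leave blocks invalid", {
  set.seed(2)
  always <- run_block(function(off) TRUE)
  lv <- always$trials$level_deg
  expect_true(all(diff(tapply(lv, always$trials$staircase_id,
                              function(x) x)[[1]]) <= 0))
  expect_equal(nrow(always$trials), 200L)
  expect_false(block_threshold(always$staircases)$valid)

  set.seed(2)
  never <- run_block(function(off) FALSE)
  for (st in never$staircases) {
    expect_length(st$reversal_levels, 0)
    expect_true(all(diff(st$history$level) >= 0))
  }
  expect_false(block_threshold(never$staircases)$valid)
})

test_that("run_block trials replay exactly through update_staircase", {
  set.seed(5)
  blk <- run_block(observer_function(observer_model(1.5)))
  cfg <- block_config()
  sts <- lapply(seq_along(cfg$start_levels_deg), function(i)
    staircase_state(cfg$start_levels_deg[i], id = i))
  for (k in seq_len(nrow(blk$trials))) {
    i <- blk$trials$staircase_id[k]
    expect_equal(sts[[i]]$level_deg, blk$trials$level_deg[k])
    sts[[i]] <- update_staircase(sts[[i]], blk$trials$correct[k])
  }
  for (i in seq_along(sts)) {
    expect_equal(sts[[i]]$reversal_levels,
                 blk$staircases[[i]]$reversal_levels)
    expect_equal(sts[[i]]$history, blk$staircases[[i]]$history)
  }
})

test_that("visited levels scale with start levels for a scale-invariant observer", {
  run_scaled <- function(c) {
    obs <- observer_function(observer_model(c * 1.0))
    cfg <- block_config(start_levels_deg = c * c(1, 3))
    set.seed(99)
    run_block(obs, cfg)$trials$level_deg
  }
  l1 <- run_scaled(1)
  l3 <- run_scaled(3)
  expect_equal(l3, 3 * l1, tolerance = 1e-10)
})

test_that("blocks are reproducible under a fixed seed", {
  obs <- observer_function(observer_model(1))
  set.seed(123); a <- run_block(obs)$trials
  set.seed(123); b <- run_block(obs)$trials
  expect_identical(a, b)
})

test_that("pooled-reversal variant averages across staircases in order", {
  mk <- function(revs, id) {
    st <- staircase_state(1, id = id)
    st$reversal_levels <- revs
    st
  }
  cfg <- block_config(pool_staircases = TRUE)
  est <- block_threshold(list(mk(c(4, 3, 2, 1, 1.2, 1.0), 1L),
                              mk(c(2, 1.4, 1.0, 1.2), 2L)), cfg)
  pooled <- c(4, 3, 2, 1, 1.2, 1.0, 2, 1.4, 1.0, 1.2)
  expect_true(est$valid)
  expect_equal(est$threshold_deg, mean(pooled[5:10]))
})
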