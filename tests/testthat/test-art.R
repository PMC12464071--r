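test_that("alignment strips all non-target effects exactly on noise-free data", {
  set.seed(20)
  tab <- null_model_cohort(n_subj = 8, blocks = 1, subj_sd = 0, resid_sd = 0)
  tab$threshold <- 5 + 2 * (tab$Time == "post") # pure Time main effect
  for (eff in list("Location", "Randomization",
                   c("Time", "Location"),
                   c("Randomization", "TrainingLocation"),
                   c("Time", "Randomization", "Location"))) {
    ar <- align_rank(tab, eff)
    expect_equal(diff(range(ar$aligned)), 0)
    expect_true(all(ar$rank == (nrow(tab) + 1) / 2)) # all midranks tied
  }
  # aligning for Time itself keeps the effect
  art <- align_rank(tab, "Time")
  expect_gt(diff(range(art$aligned)), 1)
})

test_that("one-factor ART reduces to ANOVA on plain ranks", {
  set.seed(21)
  tab <- data.frame(Time = rep(c("pre", "post"), each = 12),
                    threshold = round(rlnorm(24, 1, 0.4), 3))
  ar <- align_rank(tab, "Time", factors = "Time")
  expect_equal(ar$rank, rank(tab$threshold)) # alignment is a pure shift
  f_art <- anova(lm(ar$rank ~ Time, data = tab))[1, "F value"]
  f_rank <- anova(lm(rank(threshold) ~ Time, data = tab))[1, "F value"]
  expect_identical(f_art, f_rank)
})

test_that("aligned ranks are a permutation of 1..N on tie-free data", {
  set.seed(22)
  tab <- null_model_cohort(n_subj = 8, blocks = 1)
  ar <- align_rank(tab, c("Time", "Randomization"))
  expect_equal(sort(ar$rank), as.numeric(seq_len(nrow(tab))))
})

test_that("art_anova is invariant to shifts and row permutations", {
  set.seed(23)
  tab <- null_model_cohort(n_subj = 8, blocks = 1)
  terms <- list("Time", c("Time", "Randomization", "Location"))
  r0 <- art_anova(tab, terms = terms)
  tab2 <- tab
  tab2$threshold <- tab2$threshold + 7
  r1 <- art_anova(tab2, terms = terms)
  expect_equal(r0$table$F, r1$table$F, tolerance = 1e-10)
  expect_equal(r0$table$p, r1$table$p, tolerance = 1e-10)
  perm <- sample(nrow(tab))
  r2 <- art_anova(tab[perm, ], terms = terms)
  expect_equal(r0$table$F, r2$table$F, tolerance = 1e-10)
})

test_that("aov and lmer engines agree on a balanced table", {
  set.seed(24)
  tab <- null_model_cohort(n_subj = 8, blocks = 2)
  terms <- list("Time", "Randomization", c("Time", "Location"),
                c("Randomization", "TrainingLocation"),
                c("Time", "Randomization", "Location"))
  ra <- art_anova(tab, terms = terms, engine = "aov")
  rl <- art_anova(tab, terms = terms, engine = "lmer")
  expect_equal(ra$table$F, rl$table$F, tolerance = 1e-3)
  expect_equal(ra$table$df1, rl$table$df1)
  expect_equal(ra$table$df2, rl$table$df2)
  expect_equal(ra$engine, "aov")
  expect_true(all(ra$table$p >= 0 & ra$table$p <= 1))
  expect_true(all(ra$table$eta2p >= 0 & ra$table$eta2p < 1))
})

test_that("unbalanced tables route to the mixed-model engine", {
  set.seed(25)
  tab <- null_model_cohort(n_subj = 8, blocks = 1)
  tab <- tab[tab$Subject != "S01" | tab$Time != "post", ] # break balance
  r <- art_anova(tab, terms = list("Time"))
  expect_equal(r$engine, "lmer")
  expect_true(is.finite(r$table$F))
})

test_that("art contrast estimates respect basic contrast algebra", {
  set.seed(26)
  tab <- null_model_cohort(n_subj = 8, blocks = 1)
  # cells are Time.Randomization.Location in canonical factor order
  w <- c("post.phase.F-transfer" = 1, "pre.phase.F-transfer" = -1,
         "post.contrast.F-transfer" = -1, "pre.contrast.F-transfer" = 1)
  r0 <- art_contrast(tab, c("Time", "Randomization", "Location"), w)
  tab2 <- tab
  tab2$threshold <- tab2$threshold + 3
  r1 <- art_contrast(tab2, c("Time", "Randomization", "Location"), w)
  expect_equal(r0$estimate, r1$estimate, tolerance = 1e-8)
  expect_error(art_contrast(tab, "Time", c(pre = 1, post = 1)), "sum to zero")
  expect_error(art_contrast(tab, "Time", c(pre = 1, nosuch = -1)),
               "do not match")
})

test_that("null group-difference contrasts are calibrated", {
  set.seed(27)
  w <- c(phase = 1, contrast = -1)
  ps <- replicate(150, {
    tab <- null_model_cohort(n_subj = 8, blocks = 1)
    art_contrast(tab, "Randomization", w)$p
  })
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.06)
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("the headline interaction contrast recovers the built-in sign", {
  set.seed(28)
  w <- c("post.phase.F-transfer" = 1, "pre.phase.F-transfer" = -1,
         "post.contrast.F-transfer" = -1, "pre.contrast.F-transfer" = 1)
  signs <- replicate(30, {
    sim <- simulate_cohort(cohort_spec("paper-like"), method = "direct")
    art_contrast(sim$cohort, c("Time", "Randomization", "Location"),
                 w)$estimate
  })
  # phase improves more at F-transfer: its pre-post drop is larger, so the
  # (post - pre) difference phase-minus-contrast is negative on ranks
  expect_gte(mean(signs < 0), 0.9)
})
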