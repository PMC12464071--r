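.enum_cols <- list(
  randomization = c("phase", "contrast"),
  training_location = c("UVF", "LVF"),
  session_type = c("pre", "train", "post"),
  location = c("training", "C", "F"),
  response = c("cw", "ccw")
)

.trial_log_cols <- c("subject_id", "randomization", "training_location",
                     "session_type", "session_index", "block", "trial",
                     "location", "reference_ori_deg", "offset_deg",
                     "phase_deg", "contrast", "staircase_id", "response",
                     "correct", "aborted")

#' Write a trial log CSV
#'
#' One row per trial with the canonical schema columns (see
#' [read_trial_log()]); plain RFC-4180 CSV.
#'
#' @param trials data frame of trials.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trial_log <- function(trials, path) {
  cols <- intersect(.trial_log_cols, names(trials))
  utils::write.csv(trials[cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and validate a trial log CSV
#'
#' Schema: `subject_id`, `randomization` (phase/contrast),
#' `training_location` (UVF/LVF), `session_type` (pre/train/post),
#' `session_index`, `block`, `trial`, `location` (training/C/F),
#' `reference_ori_deg`, `offset_deg` (signed, nonzero on scored trials),
#' `phase_deg` (optional; contrast-group files may omit it), `contrast`,
#' `staircase_id`, `response` (cw/ccw), `correct` (0/1), `aborted` (0/1).
#' Unknown enum values, duplicate (subject, session, block, trial) keys and
#' zero offsets on scored trials are hard errors naming the offending row;
#' aborted trials are retained but flagged. A validation report (trial counts
#' per subject and session) is attached as attribute `"report"`.
#'
#' @param path CSV path.
#' @return The validated trial table.
#' @export
read_trial_log <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- setdiff(.trial_log_cols, c("phase_deg", "reference_ori_deg",
                                     "staircase_id"))
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("trial log missing required columns: ", paste(miss, collapse = ", "))
  if (!"phase_deg" %in% names(df)) {
    warning("optional column phase_deg missing; filled with NA")
    df$phase_deg <- NA_real_
  }
  for (col in names(.enum_cols)) {
    bad <- which(!df[[col]] %in% .enum_cols[[col]])
    if (length(bad))
      stop(sprintf("row %d: unknown %s value '%s'", bad[1], col,
                   df[[col]][bad[1]]))
  }
  key <- interaction(df$subject_id, df$session_type, df$session_index,
                     df$block, df$trial, drop = TRUE)
  dup <- which(duplicated(key))
  if (length(dup))
    stop(sprintf("row %d: duplicate (subject, session, block, trial) key",
                 dup[1]))
  scored <- df$aborted == 0
  zero <- which(scored & df$offset_deg == 0)
  if (length(zero))
    stop(sprintf("row %d: offset_deg = 0 on a scored trial", zero[1]))
  for (f in c("randomization", "training_location")) {
    k <- tapply(df[[f]], df$subject_id, function(v) length(unique(v)))
    if (any(k > 1))
      stop("a subject carries more than one ", f)
  }
  rep_tab <- stats::aggregate(trial ~ subject_id + session_type,
                              data = df, FUN = length)
  names(rep_tab)[3] <- "n_trials"
  attr(df, "report") <- rep_tab
  df
}

#' Write / read eye-trace CSVs
#'
#' Plain CSV with columns `trial_id`, `t_ms`, `x_dva`, `y_dva`, `valid`
#' (0/1), optional `blink`.
#'
#' @param trace gaze-sample data frame.
#' @param path file path.
#' @return `path` / the trace data frame.
#' @export
write_eye_trace <- function(trace, path) {
  out <- trace
  out$valid <- as.integer(out$valid)
  if ("blink" %in% names(out)) out$blink <- as.integer(out$blink)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_eye_trace
#' @export
read_eye_trace <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("trial_id", "t_ms", "x_dva", "y_dva", "valid")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("eye trace missing columns: ", paste(miss, collapse = ", "))
  df$valid <- as.logical(df$valid)
  if ("blink" %in% names(df)) df$blink <- as.logical(df$blink)
  df
}

#' Default analysis configuration
#'
#' All pipeline constants in one nested list; the defaults are the task's
#' stated constants: Gabor of 2 dva at 2.5 cpd with 0.28 dva envelope SD on a
#' 52.42 cd/m2 background at 6 deg eccentricity, 45 deg reference; phase
#' randomization on \[0, 180) deg at fixed 45% contrast, or contrast
#' randomization on \[33%, 66%\] at fixed 0 deg phase; two interleaved
#' 3-down-1-up staircases from 1 and 3 deg with 0.05 log10 steps, stopping at
#' 10 reversals or 200 trials, threshold = mean of reversals 5-10; LI
#' exclusion criterion -0.20; blink margins 100/150 ms; trial windows -200 /
#' +350 ms; microsaccade detection at mean + 6 SD, >= 6 ms, >= 10 ms gap,
#' < 1 dva. Transfer-location geometry is given as polar angles (not
#' hard-coded chord distances, which are not jointly consistent on a single
#' 6-deg arc); inter-location distances should be recomputed from the
#' configured angles.
#'
#' @param ... named overrides merged over the defaults (top level only).
#' @return A nested list of class `analysis_config`.
#' @export
analysis_config <- function(...) {
  cfg <- list(
    stimulus = list(size_deg = 2, sf_cpd = 2.5, sigma_deg = 0.28,
                    background_lum = 52.42, eccentricity_deg = 6,
                    reference_ori_deg = 45, fixation_dot_deg = 0.23),
    randomization = list(phase_range_deg = c(0, 180),
                         contrast_range = c(0.33, 0.66),
                         fixed_phase_deg = 0, fixed_contrast = 0.45),
    staircase = list(start_levels_deg = c(1, 3), step_log10 = 0.05,
                     max_trials = 200L, reversals_to_stop = 10L,
                     discard_reversals = 4L, average_reversals = 6L),
    exclusion = list(criterion_li = -0.20),
    eye = list(sampling_hz = 1000, blink_pre_ms = 100, blink_post_ms = 150,
               pre_ref_ms = 200, post_target_ms = 350, lambda = 6,
               min_dur_ms = 6, min_gap_ms = 10, max_amp_dva = 1),
    locations = list(eccentricity_deg = 6,
                     polar_angle_deg = c(training = 90, `C-transfer` = 138,
                                         `F-transfer` = 186)),
    seed = 1L
  )
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  class(cfg) <- "analysis_config"
  cfg
}

#' Combined results report for a cohort
#'
#' Runs the standard analysis chain on a block-level cohort table: subject
#' summaries, learner exclusions, group learning-index means, the per-group
#' Pearson correlation between C- and F-transfer LIs, the one-sided Fisher
#' r-to-z comparison of those correlations (phase vs contrast), and the
#' aligned-rank-transform ANOVA table.
#'
#' @param cohort block-level cohort table (see [as_cohort_table()]).
#' @param criterion_li exclusion criterion (default -0.20).
#' @param art_terms terms for [art_anova()] (default all 15).
#' @param engine ANOVA engine, see [art_anova()].
#' @return A list of class `vpl_report`: `subjects`, `exclusions`,
#'   `group_li`, `transfer_correlations`, `fisher_z`, `anova`.
#' @export
vpl_report <- function(cohort, criterion_li = -0.20, art_terms = NULL,
                       engine = "auto") {
  cohort <- as_cohort_table(cohort)
  subj <- subject_summary(cohort)
  excl <- apply_exclusions(subj, criterion_li = criterion_li)
  kept <- excl$retained
  cohort_kept <- cohort[cohort$Subject %in% kept$subject_id, , drop = FALSE]
  cohort_kept$Subject <- droplevels(cohort_kept$Subject)
  group_li <- stats::aggregate(
    cbind(li_training, li_C, li_F) ~ randomization, data = kept, FUN = mean)
  cors <- lapply(split(kept, kept$randomization), function(d) {
    if (nrow(d) >= 4 && stats::var(d$li_C) > 0 && stats::var(d$li_F) > 0)
      pearson_r_test(d$li_C, d$li_F) else NULL
  })
  fz <- if (!is.null(cors$phase) && !is.null(cors$contrast))
    compare_independent_correlations(cors$phase$r, cors$phase$n,
                                     cors$contrast$r, cors$contrast$n,
                                     sided = "one") else NULL
  aov_res <- art_anova(cohort_kept, terms = art_terms, engine = engine)
  out <- list(subjects = subj, exclusions = excl, group_li = group_li,
              transfer_correlations = cors, fisher_z = fz, anova = aov_res)
  class(out) <- "vpl_report"
  out
}

#' @export
print.vpl_report <- function(x, ...) {
  cat("== Cohort report ==\n")
  cat(sprintf("Subjects: %d total, %d retained (criterion LI <= %.2f)\n",
              nrow(x$subjects), nrow(x$exclusions$retained),
              x$exclusions$criterion_li))
  cat("\nGroup mean learning indices:\n")
  print(x$group_li, row.names = FALSE)
  cat("\nTransfer-LI correlations (C vs F):\n")
  for (g in names(x$transfer_correlations)) {
    ct <- x$transfer_correlations[[g]]
    if (!is.null(ct))
      cat(sprintf("  %s: r = %.3f, t(%d) = %.3f, p = %.4f\n",
                  g, ct$r, ct$df, ct$t, ct$p))
  }
  if (!is.null(x$fisher_z)) print(x$fisher_z)
  cat("\n")
  print(x$anova)
  invisible(x)
}

#' Command-line dispatcher
#'
#' Thin shell entry point over the package functions; the script
#' `inst/cli/vpl` forwards `commandArgs(TRUE)` here. Subcommands:
#' `simulate` (`--preset`, `--seed`, `--out-prefix`), `threshold`
#' (`--trials <csv>`, `--out`), `li` (`--cohort <csv>`, `--out`),
#' `art-anova` (`--cohort <csv>`, `--out`), `detect-ms` (`--trace <csv>`,
#' `--out`), `report` (`--cohort <csv>`, `--out` JSON).
#'
#' @param args character vector of command-line arguments.
#' @return Exit status (0 on success), invisibly.
#' @export
vpl_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) < 1) {
    cat("usage: vpl <simulate|threshold|li|art-anova|detect-ms|report> [--flags]\n")
    return(invisible(1L))
  }
  cmd <- args[1]
  opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) && i[1] < length(args)) args[i[1] + 1] else default
  }
  seed <- as.integer(opt("--seed", "1"))
  set.seed(seed)
  status <- 0L
  switch(cmd,
    simulate = {
      preset <- opt("--preset", "paper-like")
      prefix <- opt("--out-prefix", "vpl")
      sim <- simulate_cohort(cohort_spec(preset), trial_logs = TRUE)
      utils::write.csv(sim$cohort, paste0(prefix, "_cohort.csv"),
                       row.names = FALSE)
      if (!is.null(sim$trials))
        utils::write.csv(sim$trials, paste0(prefix, "_trials.csv"),
                         row.names = FALSE)
      cat("wrote", paste0(prefix, "_cohort.csv"), "\n")
    },
    threshold = ,
    li = {
      cohort <- utils::read.csv(opt("--cohort"), stringsAsFactors = FALSE)
      subj <- subject_summary(as_cohort_table(cohort))
      out <- opt("--out", "subjects.csv")
      utils::write.csv(subj, out, row.names = FALSE)
      cat("wrote", out, "\n")
    },
    `art-anova` = {
      cohort <- utils::read.csv(opt("--cohort"), stringsAsFactors = FALSE)
      res <- art_anova(as_cohort_table(cohort))
      out <- opt("--out", "anova.csv")
      utils::write.csv(res$table, out, row.names = FALSE)
      cat("wrote", out, "\n")
    },
    `detect-ms` = {
      trace <- read_eye_trace(opt("--trace"))
      trace <- mask_blinks(trace)
      ev <- do.call(rbind, lapply(split(trace, trace$trial_id),
                                  detect_microsaccades))
      out <- opt("--out", "events.csv")
      utils::write.csv(ev, out, row.names = FALSE)
      cat("wrote", out, "\n")
    },
    report = {
      cohort <- utils::read.csv(opt("--cohort"), stringsAsFactors = FALSE)
      rep <- vpl_report(as_cohort_table(cohort))
      out <- opt("--out", "report.json")
      jsonlite::write_json(list(
        group_li = rep$group_li,
        correlations = lapply(rep$transfer_correlations, function(ct)
          if (is.null(ct)) NULL else ct[c("r", "t", "df", "p", "n")]),
        fisher_z = if (is.null(rep$fisher_z)) NULL else
          unclass(rep$fisher_z),
        anova = rep$anova$table,
        seed = seed), out, auto_unbox = TRUE, digits = NA, pretty = TRUE)
      print(rep)
      cat("wrote", out, "\n")
    },
    {
      cat("unknown subcommand:", cmd, "\n")
      status <- 1L
    })
  invisible(status)
}
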