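#' @importFrom lme4 lmer fixef lmerControl
NULL

.vpl_factors <- c("Time", "Randomization", "Location", "TrainingLocation")
.vpl_levels <- list(
  Time = c("pre", "post"),
  Randomization = c("phase", "contrast"),
  Location = c("training", "C-transfer", "F-transfer"),
  TrainingLocation = c("UVF", "LVF")
)

#' Validate and normalize a cohort threshold table
#'
#' Long-format table with one row per subject x time x location x block:
#' positive `threshold` plus the factors `Time` (pre/post), `Randomization`
#' (phase/contrast), `Location` (training/C-transfer/F-transfer),
#' `TrainingLocation` (UVF/LVF) and `Subject`. Each subject must carry exactly
#' one randomization and one training location.
#'
#' @param table data frame with the columns above.
#' @param response name of the response column (positivity is enforced only
#'   for `"threshold"`).
#' @return The table with factor columns coerced to the canonical levels.
#' @export
as_cohort_table <- function(table, response = "threshold") {
  stopifnot(is.data.frame(table))
  need <- c(response, "Subject", .vpl_factors)
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (any(!is.finite(table[[response]])))
    stop("response must be finite")
  if (response == "threshold" && any(table$threshold <= 0))
    stop("thresholds must be positive")
  for (f in .vpl_factors) {
    bad <- setdiff(unique(as.character(table[[f]])), .vpl_levels[[f]])
    if (length(bad))
      stop(sprintf("unknown %s level(s): %s", f, paste(bad, collapse = ", ")))
    table[[f]] <- factor(as.character(table[[f]]), levels = .vpl_levels[[f]])
  }
  table$Subject <- factor(table$Subject)
  for (f in c("Randomization", "TrainingLocation")) {
    k <- tapply(table[[f]], table$Subject, function(v) length(unique(v)))
    if (any(k > 1))
      stop(sprintf("each subject must have exactly one %s", f))
  }
  table
}

# unweighted marginal means of full-factorial cell means, ARTool-style:
# cell means over all fixed factors, then averaged down to the margin `by`
# (character(0) -> grand mean). Returns a per-row vector.
.cell_mean_vec <- function(y, table, by, factors) {
  cells <- interaction(table[factors], drop = TRUE, lex.order = TRUE)
  cm <- tapply(y, cells, mean)
  info <- unique(table[factors])
  info <- info[match(names(cm), interaction(info[factors], drop = TRUE,
                                            lex.order = TRUE)), , drop = FALSE]
  if (length(by) == 0L) {
    rep(mean(cm), length(y))
  } else {
    marg <- tapply(cm, interaction(info[by], drop = TRUE, lex.order = TRUE),
                   mean)
    marg[as.character(interaction(table[by], drop = TRUE, lex.order = TRUE))]
  }
}

#' Align and rank a response for one factorial effect
#'
#' The aligned-rank-transform step for a single target term: the response is
#' stripped of every effect except the target by subtracting the
#' full-factorial cell mean and adding back the target term's estimated
#' effect, obtained by inclusion-exclusion over unweighted marginal means of
#' the cell means (main effect A: `mean_A - grand`; interaction A:B:
#' `mean_AB - mean_A - mean_B + grand`; and so on). Aligned values are then
#' midranked ascending. On data containing only non-target effects and no
#' noise the aligned values are constant (all ranks tied); with a single
#' factor the ranks equal plain ranks of the response.
#'
#' @param table a cohort table (see [as_cohort_table()]).
#' @param effect character vector naming the target term's factors, a
#'   non-empty subset of `Time`, `Randomization`, `Location`,
#'   `TrainingLocation`.
#' @param response name of the response column (default `"threshold"`).
#' @param factors the full set of fixed factors in the design.
#' @return A data frame with columns `aligned` and `rank` (midranks), one row
#'   per row of `table`.
#' @export
align_rank <- function(table, effect, response = "threshold",
                       factors = .vpl_factors) {
  factors <- intersect(factors, names(table))
  if (length(effect) == 0L || !all(effect %in% factors))
    stop("effect must be a non-empty subset of the design factors: ",
         paste(factors, collapse = ", "))
  y <- table[[response]]
  full <- .cell_mean_vec(y, table, by = factors, factors = factors)
  k <- length(effect)
  est <- numeric(length(y))
  for (m in 0:k) {
    subs <- if (m == 0) list(character(0)) else
      utils::combn(effect, m, simplify = FALSE)
    for (s in subs)
      est <- est + (-1)^(k - m) * .cell_mean_vec(y, table, by = s,
                                                 factors = factors)
  }
  aligned <- y - full + est
  data.frame(aligned = aligned, rank = rank(aligned, ties.method = "average"))
}

.all_terms <- function(factors = .vpl_factors) {
  unlist(lapply(seq_along(factors), function(m)
    utils::combn(factors, m, simplify = FALSE)), recursive = FALSE)
}

.term_label <- function(effect, factors = .vpl_factors) {
  paste(factors[factors %in% effect], collapse = ":")
}

# TRUE when the design is a balanced split-plot: equal full-cell counts,
# equal rows per subject, equal subjects per between-subject group
.is_balanced <- function(table, factors = .vpl_factors) {
  n_cell <- table(interaction(table[factors], drop = FALSE))
  n_cell <- n_cell[n_cell > 0]
  if (length(unique(as.integer(n_cell))) != 1L) return(FALSE)
  if (length(n_cell) != prod(vapply(.vpl_levels[factors], length, 1L)))
    return(FALSE)
  per_subj <- table(table$Subject)
  if (length(unique(as.integer(per_subj))) != 1L) return(FALSE)
  grp <- unique(table[c("Subject", "Randomization", "TrainingLocation")])
  gsz <- table(interaction(grp$Randomization, grp$TrainingLocation))
  length(unique(as.integer(gsz[gsz > 0]))) == 1L
}

.between_terms <- function() c("Randomization", "TrainingLocation",
                               "Randomization:TrainingLocation")

# Wald F for each requested term from an lmer fit on ranks, sum-to-zero
# coding; denominator df by the between-within (containment) rule.
.lmer_wald <- function(dat, term_label) {
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old), add = TRUE)
  form <- stats::as.formula(
    ".r ~ Time * Randomization * Location * TrainingLocation + (1 | Subject)")
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(form, data = dat, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore"))))
  b <- lme4::fixef(fit)
  V <- as.matrix(stats::vcov(fit))
  X <- stats::model.matrix(fit)
  asgn <- attr(X, "assign")
  tl <- attr(stats::terms(
    ~ Time * Randomization * Location * TrainingLocation), "term.labels")
  ti <- match(term_label, tl)
  idx <- which(asgn == ti)
  q <- length(idx)
  bf <- b[idx]
  Fval <- drop(t(bf) %*% solve(V[idx, idx, drop = FALSE], bf)) / q
  n_subj <- nlevels(droplevels(dat$Subject))
  grp <- unique(dat[c("Subject", "Randomization", "TrainingLocation")])
  g <- nrow(unique(grp[c("Randomization", "TrainingLocation")]))
  p <- qr(X)$rank
  if (term_label %in% .between_terms())
    df2 <- n_subj - g
  else df2 <- nrow(dat) - p - (n_subj - g)
  singular <- tryCatch(lme4::isSingular(fit), error = function(e) NA)
  list(F = Fval, df1 = q, df2 = df2, singular = isTRUE(singular))
}

# classical split-plot ANOVA via aov Error(Subject); exact on balanced data
.aov_f <- function(dat, term_label) {
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old), add = TRUE)
  fit <- stats::aov(
    .r ~ Time * Randomization * Location * TrainingLocation + Error(Subject),
    data = dat)
  sm <- summary(fit)
  for (stratum in sm) {
    tab <- stratum[[1]]
    rn <- trimws(rownames(tab))
    j <- match(term_label, rn)
    if (!is.na(j) && !is.na(tab[j, "F value"])) {
      resid_df <- tab[rn == "Residuals", "Df"]
      return(list(F = tab[j, "F value"], df1 = tab[j, "Df"], df2 = resid_df,
                  singular = FALSE))
    }
  }
  stop("term not found in aov summary: ", term_label)
}

#' Aligned-rank-transform factorial ANOVA with subject random intercepts
#'
#' For each requested term of the `Time x Randomization x Location x
#' TrainingLocation` factorial (all 15 by default), the response is aligned
#' and midranked for that term ([align_rank()]) and the full factorial model
#' is fitted to the ranks with a subject random intercept; only the target
#' term is read from each fit. On balanced split-plot tables the default
#' engine is the exact classical ANOVA ([stats::aov()] with an
#' `Error(Subject)` stratum); otherwise a [lme4::lmer()] fit with a Wald F
#' and between-within (containment) denominator degrees of freedom is used.
#' Sum-to-zero factor coding throughout; no multiplicity correction across
#' terms. Partial eta squared is reported per term.
#'
#' @param table a cohort table (see [as_cohort_table()]).
#' @param terms list of character vectors naming the terms to test
#'   (default: all 15).
#' @param engine `"auto"` (aov when balanced, else lmer), `"aov"`, `"lmer"`.
#' @param response response column name.
#' @param keep_aligned keep the aligned/ranked columns for each term.
#' @return An object of class `art_result`: `table` (data frame with `term`,
#'   `F`, `df1`, `df2`, `p`, `eta2p`, `singular`), `engine`, `df_method`, and
#'   (optionally) `aligned`, a named list of [align_rank()] outputs.
#' @export
art_anova <- function(table, terms = NULL, engine = c("auto", "aov", "lmer"),
                      response = "threshold", keep_aligned = FALSE) {
  engine <- match.arg(engine)
  table <- as_cohort_table(table, response = response)
  if (is.null(terms)) terms <- .all_terms()
  if (is.character(terms)) terms <- list(terms)
  if (engine == "auto")
    engine <- if (.is_balanced(table)) "aov" else "lmer"
  dat <- table
  rows <- vector("list", length(terms))
  aligned <- if (keep_aligned) list() else NULL
  for (i in seq_along(terms)) {
    eff <- terms[[i]]
    lab <- .term_label(eff)
    ar <- align_rank(table, eff, response = response)
    dat$.r <- ar$rank
    res <- tryCatch(
      if (engine == "aov") .aov_f(dat, lab) else .lmer_wald(dat, lab),
      error = function(e) list(F = NA_real_, df1 = NA_real_, df2 = NA_real_,
                               singular = TRUE))
    p <- if (is.na(res$F)) NA_real_ else
      stats::pf(res$F, res$df1, res$df2, lower.tail = FALSE)
    e2 <- if (is.na(res$F)) NA_real_ else
      partial_eta_sq(res$F, res$df1, res$df2)
    rows[[i]] <- data.frame(term = lab, F = res$F, df1 = res$df1,
                            df2 = res$df2, p = p, eta2p = e2,
                            singular = res$singular)
    if (keep_aligned) aligned[[lab]] <- ar
  }
  out <- list(table = do.call(rbind, rows), engine = engine,
              df_method = if (engine == "aov")
                "split-plot ANOVA (exact, balanced)" else
                  "Wald F, between-within df",
              aligned = aligned)
  class(out) <- "art_result"
  out
}

#' @export
print.art_result <- function(x, ...) {
  cat("Aligned-rank-transform ANOVA (", x$engine, "; ", x$df_method, ")\n",
      sep = "")
  tab <- x$table
  tab$F <- round(tab$F, 3); tab$p <- signif(tab$p, 3)
  tab$eta2p <- round(tab$eta2p, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Post hoc contrast on aligned-rank data (ART-C)
#'
#' Concatenate-and-align for the factor combination of interest: the response
#' is aligned to the cells of the combined factor (full-cell mean removed,
#' combined-cell marginal mean added back), midranked, and a cell-means mixed
#' model `rank ~ 0 + cell + (1|Subject)` is fitted. The contrast is a named
#' weight vector over the combined-factor cells (weights summing to zero);
#' its estimate, t statistic, between-within degrees of freedom, p-value and
#' a Cohen's d computed from t and df (`d = 2t/sqrt(df)`) are returned.
#'
#' @param table a cohort table (see [as_cohort_table()]).
#' @param factors character vector of factors whose cells the contrast spans.
#' @param contrast named numeric vector of weights; names are combined-cell
#'   labels, `paste(levels, collapse = ".")` in the order of `factors`.
#'   Unnamed cells get weight 0.
#' @param sided `"two"` (default), `"greater"` or `"less"`.
#' @param response response column name.
#' @return A list: `estimate` (rank scale), `se`, `t`, `df`, `p`,
#'   `cohens_d`, `cells` (cell-mean estimates on the rank scale).
#' @export
art_contrast <- function(table, factors, contrast,
                         sided = c("two", "greater", "less"),
                         response = "threshold") {
  sided <- match.arg(sided)
  table <- as_cohort_table(table, response = response)
  if (!all(factors %in% .vpl_factors))
    stop("factors must be among: ", paste(.vpl_factors, collapse = ", "))
  factors <- .vpl_factors[.vpl_factors %in% factors]
  y <- table[[response]]
  full <- .cell_mean_vec(y, table, by = .vpl_factors, factors = .vpl_factors)
  comb <- .cell_mean_vec(y, table, by = factors, factors = .vpl_factors)
  dat <- table
  dat$.r <- rank(y - full + comb, ties.method = "average")
  dat$.cell <- interaction(dat[factors], drop = TRUE, lex.order = TRUE,
                           sep = ".")
  lev <- levels(dat$.cell)
  w <- stats::setNames(numeric(length(lev)), lev)
  bad <- setdiff(names(contrast), lev)
  if (length(bad))
    stop("contrast names do not match cells: ", paste(bad, collapse = ", "),
         "; available: ", paste(lev, collapse = ", "))
  w[names(contrast)] <- contrast
  if (abs(sum(w)) > 1e-8) stop("contrast weights must sum to zero")
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(.r ~ 0 + .cell + (1 | Subject), data = dat, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore"))))
  b <- lme4::fixef(fit)
  names(b) <- sub("^\\.cell", "", names(b))
  V <- as.matrix(stats::vcov(fit))
  b <- b[lev]; V <- V[paste0(".cell", lev), paste0(".cell", lev)]
  est <- sum(w * b)
  se <- sqrt(drop(t(w) %*% V %*% w))
  tt <- est / se
  n_subj <- nlevels(droplevels(dat$Subject))
  grp <- unique(dat[c("Subject", "Randomization", "TrainingLocation")])
  g <- nrow(unique(grp[c("Randomization", "TrainingLocation")]))
  within <- any(vapply(factors, function(f)
    any(tapply(dat[[f]], dat$Subject,
               function(v) length(unique(v))) > 1), logical(1)))
  df <- if (within) nrow(dat) - length(lev) - (n_subj - g) else n_subj - g
  p <- switch(sided,
              two = 2 * stats::pt(-abs(tt), df),
              greater = stats::pt(tt, df, lower.tail = FALSE),
              less = stats::pt(tt, df))
  list(estimate = est, se = se, t = tt, df = df, p = p,
       cohens_d = 2 * tt / sqrt(df), cells = b)
}
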