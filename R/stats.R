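# Inference stage: winsorization, time-on-task slopes, one-sample slope
# tests with Cohen's d, mixed-model group inference (Type-III ANOVA,
# Satterthwaite dfs) with BH-FDR-corrected post hoc contrasts, and the
# baseline/blinding tests computable from summary statistics.

#' Winsorize values against their own cell moments
#'
#' Values outside mean +/- z * SD (moments computed from the original
#' vector) are set to the nearer bound; everything else is unchanged. A
#' zero-variance cell is returned as is.
#'
#' @param x numeric vector (one block-by-assessment cell across subjects).
#' @param z clamping threshold in SD units.
#' @return the winsorized vector.
#' @export
winsorize <- function(x, z = 2.5) {
  if (length(x) < 2) stop("winsorization needs at least two values per cell")
  s <- stats::sd(x)
  if (is.na(s) || s == 0) return(x)
  m <- mean(x)
  pmin(m + z * s, pmax(m - z * s, x))
}

#' Winsorize a long table within cells
#'
#' Applies [winsorize()] to `value_col` separately within every combination
#' of the `by` columns (e.g. block x assessment, pooled across groups).
#'
#' @param df data frame.
#' @param value_col name of the value column.
#' @param by character vector of cell-defining columns.
#' @param z clamping threshold in SD units.
#' @return `df` with the value column winsorized.
#' @export
winsorize_cells <- function(df, value_col, by, z = 2.5) {
  key <- interaction(df[by], drop = TRUE)
  for (lev in levels(key)) {
    i <- which(key == lev)
    if (length(i) >= 2) df[[value_col]][i] <- winsorize(df[[value_col]][i], z)
  }
  df
}

#' Time-on-task slope
#'
#' Ordinary least-squares slope of y on x,
#' sum((x - xbar)(y - ybar)) / sum((x - xbar)^2), where x is the
#' measurement grid (task blocks 1-6 or VAS queries 1-4) and y the marker
#' in raw units.
#'
#' @param x time points.
#' @param y marker values.
#' @return the slope, in y-units per x-unit.
#' @export
time_on_task_slope <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2) stop("slope needs at least two points")
  dx <- x - mean(x)
  den <- sum(dx^2)
  if (den == 0) stop("time points must not all be equal")
  sum(dx * (y - mean(y))) / den
}

#' Per-subject slopes from a long marker table
#'
#' @param df long data frame.
#' @param x_col,y_col column names of the time grid and marker.
#' @param by grouping columns (e.g. subject, group, assessment).
#' @return data frame of `by` columns plus `slope`.
#' @export
compute_slopes <- function(df, x_col, y_col, by) {
  key <- interaction(df[by], drop = TRUE)
  rows <- lapply(levels(key), function(lev) {
    d <- df[key == lev, ]
    out <- d[1, by, drop = FALSE]
    out$slope <- time_on_task_slope(d[[x_col]], d[[y_col]])
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

# Cohen's d CI by inverting the noncentral-t distribution
d_ci_noncentral <- function(t, df, n_scale, conf = 0.95) {
  a <- (1 - conf) / 2
  lim <- max(abs(t) + 20, 40)
  ncp_for <- function(p) {
    f <- function(ncp) suppressWarnings(stats::pt(t, df, ncp)) - p
    if (f(-lim) * f(lim) > 0) return(sign(t) * lim)
    stats::uniroot(f, c(-lim, lim), tol = 1e-8)$root
  }
  c(lower = ncp_for(1 - a) / n_scale, upper = ncp_for(a) / n_scale)
}

#' One-sample t-test with Cohen's d and its noncentral-t CI
#'
#' Tests the mean of per-subject slopes against `mu0` (default 0); the
#' effect size d = mean / SD, with a confidence interval obtained by
#' inverting the noncentral-t distribution. A zero-variance sample is
#' flagged degenerate (infinite t).
#'
#' @param x numeric sample (per-subject slopes of one group).
#' @param mu0 null value.
#' @param conf confidence level for the d interval.
#' @return list: `statistic`, `df`, `p`, `d`, `d_lower`, `d_upper`,
#'   `mean`, `sd`, `n`, `degenerate`.
#' @export
one_sample_t <- function(x, mu0 = 0, conf = 0.95) {
  n <- length(x)
  if (n < 2) stop("need at least two observations")
  m <- mean(x); s <- stats::sd(x)
  if (s == 0) {
    return(list(statistic = sign(m - mu0) * Inf, df = n - 1, p = NA_real_,
                d = NA_real_, d_lower = NA_real_, d_upper = NA_real_,
                mean = m, sd = s, n = n, degenerate = TRUE))
  }
  t <- (m - mu0) / (s / sqrt(n))
  ci <- d_ci_noncentral(t, n - 1, sqrt(n), conf)
  list(statistic = t, df = n - 1, p = 2 * stats::pt(-abs(t), n - 1),
       d = (m - mu0) / s, d_lower = unname(ci[1]), d_upper = unname(ci[2]),
       mean = m, sd = s, n = n, degenerate = FALSE)
}

#' Mixed model on slopes with Type-III ANOVA
#'
#' Fits a linear mixed model of the slope on the fixed factors (all
#' interactions) with a random intercept per subject, using sum-to-zero
#' contrasts, and computes a Type-III ANOVA with Satterthwaite denominator
#' degrees of freedom. Partial eta-squared per term is derived from
#' F * df1 / (F * df1 + df2). Missing cells are handled by the likelihood
#' (missing at random); non-convergence is reported, not silenced.
#'
#' @param data data frame with one row per subject x condition cell.
#' @param dv name of the dependent-variable column.
#' @param fixed character vector of fixed-factor columns.
#' @param random name of the grouping column for the random intercept.
#' @param covariates optional additional fixed-effect columns (additive).
#' @return list: `model` (the `lmerModLmerTest` fit), `anova` (data frame
#'   `term`, `F`, `df1`, `df2`, `p`, `partial_eta2`), `converged`,
#'   `singular`.
#' @export
fit_slope_lmm <- function(data, dv = "slope",
                          fixed = c("group", "assessment"),
                          random = "subject", covariates = NULL) {
  for (f in fixed) {
    data[[f]] <- factor(data[[f]])
    if (nlevels(data[[f]]) < 2) stop("fixed factor ", f, " needs >= 2 levels")
    stats::contrasts(data[[f]]) <- stats::contr.sum(nlevels(data[[f]]))
  }
  rhs <- paste(fixed, collapse = " * ")
  if (!is.null(covariates)) rhs <- paste(rhs, "+", paste(covariates, collapse = " + "))
  fml <- stats::as.formula(paste(dv, "~", rhs, "+ (1 |", random, ")"))
  fit <- lmerTest::lmer(fml, data = data,
                        control = lme4::lmerControl(check.conv.singular = "ignore",
                                                    calc.derivs = TRUE))
  conv <- length(fit@optinfo$conv$lme4$messages) == 0
  aov <- stats::anova(fit, type = 3, ddf = "Satterthwaite")
  tab <- data.frame(
    term = rownames(aov),
    F = aov[["F value"]],
    df1 = aov[["NumDF"]],
    df2 = aov[["DenDF"]],
    p = aov[["Pr(>F)"]]
  )
  tab$partial_eta2 <- tab$F * tab$df1 / (tab$F * tab$df1 + tab$df2)
  list(model = fit, anova = tab, converged = conv,
       singular = lme4::isSingular(fit))
}

#' Post hoc contrasts with Benjamini-Hochberg correction
#'
#' Estimated-marginal-mean contrasts for a fitted mixed model. Raw p-values
#' are taken from the full contrast family of the call and adjusted with
#' the BH step-up procedure across that family (omnibus F-tests stay
#' unadjusted elsewhere). A standardized effect size per contrast divides
#' the estimate by the model's total SD (random-intercept plus residual
#' variance).
#'
#' @param fit result of [fit_slope_lmm()] (or a bare `lmerMod`).
#' @param specs an `emmeans` specification, e.g. `~ group | assessment`.
#' @param method contrast method, e.g. `"pairwise"`.
#' @return data frame with `contrast`, grouping columns, `estimate`, `SE`,
#'   `df`, `t`, `p_raw`, `p_adj`, `d`.
#' @export
posthoc_contrasts <- function(fit, specs, method = "pairwise") {
  model <- if (is.list(fit) && !inherits(fit, "merMod")) fit$model else fit
  emm <- emmeans::emmeans(model, specs, lmer.df = "satterthwaite")
  cs <- emmeans::contrast(emm, method = method, adjust = "none")
  s <- as.data.frame(summary(cs))
  if (!nrow(s)) stop("empty contrast family")
  vc <- as.data.frame(lme4::VarCorr(model))
  sd_total <- sqrt(sum(vc$vcov))
  names(s)[names(s) == "t.ratio"] <- "t"
  names(s)[names(s) == "p.value"] <- "p_raw"
  s$p_adj <- stats::p.adjust(s$p_raw, method = "BH")
  s$d <- s$estimate / sd_total
  s
}

#' Two-sample pooled-variance t-test from summary statistics
#'
#' Classic pooled t with df = n1 + n2 - 2, computable from printed group
#' means and SDs (as in a baseline characteristics table), plus Cohen's d
#' with a noncentral-t CI.
#'
#' @param m1,sd1,n1 mean, SD, and size of group 1.
#' @param m2,sd2,n2 mean, SD, and size of group 2.
#' @param conf confidence level for the d interval.
#' @return list: `statistic`, `df`, `p`, `d`, `d_lower`, `d_upper`.
#' @export
two_sample_t_pooled <- function(m1, sd1, n1, m2, sd2, n2, conf = 0.95) {
  if (n1 < 2 || n2 < 2) stop("both groups need n >= 2")
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- (m1 - m2) / se
  df <- n1 + n2 - 2
  d <- (m1 - m2) / sqrt(sp2)
  ci <- d_ci_noncentral(t, df, sqrt(n1 * n2 / (n1 + n2)), conf)
  list(statistic = t, df = df, p = 2 * stats::pt(-abs(t), df),
       d = d, d_lower = unname(ci[1]), d_upper = unname(ci[2]))
}

#' 2x2 chi-square test with Cramér's V
#'
#' Pearson chi-square on a 2x2 count table, with or without the Yates
#' continuity correction, plus Cramér's V = sqrt(chi2 / N).
#'
#' @param tab 2x2 matrix of non-negative counts with positive margins.
#' @param continuity apply the Yates correction?
#' @return list: `statistic`, `df`, `p`, `cramers_v`, `n`.
#' @export
chi_square_2x2 <- function(tab, continuity = FALSE) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == 2)) stop("`tab` must be a 2x2 table")
  if (any(tab < 0)) stop("counts must be non-negative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("both margins must be positive")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = continuity))
  n <- sum(tab)
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, cramers_v = sqrt(unname(ct$statistic) / n), n = n)
}
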