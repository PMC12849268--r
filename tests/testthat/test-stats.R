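test_that("winsorization clamps to the original cell moments", {
  # a lone extreme value in a wide cell is pulled to mean + 2.5 SD
  x <- c(rep(0, 20), 100)
  out <- winsorize(x)
  bound <- mean(x) + 2.5 * sd(x)
  expect_gt((100 - mean(x)) / sd(x), 2.5)
  expect_equal(out, c(rep(0, 20), bound))

  y <- c(1, 2, 3, 4, 5)
  expect_identical(winsorize(y), y)        # nothing beyond 2.5 SD
  expect_identical(winsorize(rep(3, 5)), rep(3, 5))  # zero-variance cell
  expect_error(winsorize(1), "at least two")

  set.seed(5)
  for (i in 1:50) {
    v <- rnorm(20, sd = runif(1, 0.5, 10)) + sample(c(0, 50), 20, TRUE, c(0.9, 0.1))
    w <- winsorize(v)
    z <- (w - mean(v)) / sd(v)
    expect_lte(max(abs(z)), 2.5 + 1e-12)
    # order statistics of non-outliers preserved
    inside <- abs((v - mean(v)) / sd(v)) <= 2.5
    expect_identical(w[inside], v[inside])
  }
})

test_that("cell-wise winsorization works independently per cell", {
  df <- data.frame(block = rep(1:2, times = c(21, 5)),
                   assessment = "pre",
                   value = c(rep(0, 20), 100, 1, 2, 3, 4, 5))
  out <- winsorize_cells(df, "value", c("block", "assessment"))
  expect_equal(out$value[22:26], 1:5)
  expect_lt(out$value[21], 100)
})

test_that("time-on-task slope equals the least-squares fit", {
  expect_equal(time_on_task_slope(1:4, c(10, 20, 30, 40)), 10)
  expect_equal(time_on_task_slope(1:6, rep(7, 6)), 0)
  expect_error(time_on_task_slope(c(2, 2, 2), 1:3), "must not all be equal")
  expect_error(time_on_task_slope(1, 1), "at least two")

  set.seed(21)
  for (i in 1:100) {
    x <- sample(1:10, 6)
    y <- rnorm(6, sd = 10)
    expect_equal(time_on_task_slope(x, y), unname(coef(lm(y ~ x))[2]),
                 tolerance = 1e-12)
  }
})

test_that("per-subject slope extraction matches direct computation", {
  df <- expand.grid(subject = c("a", "b"), assessment = "pre", block = 1:6,
                    stringsAsFactors = FALSE)
  df$value <- ifelse(df$subject == "a", 2 * df$block, 10 - df$block)
  s <- compute_slopes(df, "block", "value", c("subject", "assessment"))
  expect_equal(s$slope[s$subject == "a"], 2)
  expect_equal(s$slope[s$subject == "b"], -1)
})

test_that("one-sample t handles the null, degenerate, and typical cases", {
  x0 <- c(-2, -1, 0, 1, 2)
  r0 <- one_sample_t(x0)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p, 1)

  rdeg <- one_sample_t(rep(1, 10))
  expect_true(rdeg$degenerate)
  expect_equal(rdeg$statistic, Inf)

  set.seed(2)
  x <- rnorm(20, 1, 1)
  r <- one_sample_t(x)
  tt <- t.test(x)
  expect_equal(r$statistic, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(r$p, tt$p.value, tolerance = 1e-12)
  expect_equal(r$d, mean(x) / sd(x))
  # the noncentral-t CI endpoints reproduce the defining tail probabilities
  expect_equal(suppressWarnings(pt(r$statistic, r$df, r$d_lower * sqrt(20))),
               0.975, tolerance = 1e-6)
  expect_equal(suppressWarnings(pt(r$statistic, r$df, r$d_upper * sqrt(20))),
               0.025, tolerance = 1e-6)
})

test_that("rejection rate under an injected effect matches noncentral-t power", {
  n <- 20; d <- 1.07
  set.seed(31)
  rej <- vapply(1:400, function(i) one_sample_t(rnorm(n, d, 1))$p < 0.05,
                logical(1))
  power <- 1 - pt(qt(0.975, n - 1), n - 1, ncp = d * sqrt(n)) +
               pt(-qt(0.975, n - 1), n - 1, ncp = d * sqrt(n))
  expect_equal(mean(rej), power, tolerance = 3 * sqrt(power * (1 - power) / 400))
})

test_that("pooled two-sample t from summaries matches t.test on raw data", {
  make <- function(n, m, s) { x <- rnorm(n); m + s * (x - mean(x)) / sd(x) }
  set.seed(8)
  x <- make(15, 10, 3); y <- make(12, 8, 4)
  r <- two_sample_t_pooled(mean(x), sd(x), 15, mean(y), sd(y), 12)
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(r$statistic, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(r$p, tt$p.value, tolerance = 1e-10)
  expect_equal(r$df, unname(tt$parameter))
  expect_equal(two_sample_t_pooled(5, 1, 10, 5, 1, 10)$statistic, 0)
  expect_error(two_sample_t_pooled(1, 1, 1, 2, 1, 10), "n >= 2")
})

test_that("2x2 chi-square matches the textbook closed form to 1e-10", {
  set.seed(14)
  for (i in 1:25) {
    tab <- matrix(sample(1:30, 4, TRUE), 2)
    n <- sum(tab)
    a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
    r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
    c1 <- sum(tab[, 1]); c2 <- sum(tab[, 2])
    plain <- n * (a * d - b * c)^2 / (r1 * r2 * c1 * c2)
    yates <- n * max(0, abs(a * d - b * c) - n / 2)^2 / (r1 * r2 * c1 * c2)
    expect_equal(chi_square_2x2(tab, FALSE)$statistic, plain, tolerance = 1e-10)
    expect_equal(chi_square_2x2(tab, TRUE)$statistic, yates, tolerance = 1e-10)
    expect_equal(chi_square_2x2(tab, FALSE)$cramers_v, sqrt(plain / n),
                 tolerance = 1e-10)
  }
  # exactly proportional margins: no association
  expect_equal(chi_square_2x2(matrix(c(10, 20, 5, 10), 2), FALSE)$statistic, 0)
  expect_error(chi_square_2x2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)))
})

test_that("BH adjustment is monotone, bounded, and matches the step-up oracle", {
  expect_equal(p.adjust(c(0.01, 0.02, 0.04), "BH"), c(0.03, 0.03, 0.04))
  expect_equal(p.adjust(0.2, "BH"), 0.2)   # single contrast untouched
  set.seed(3)
  for (i in 1:50) {
    p <- runif(sample(2:8, 1))
    adj <- p.adjust(p, "BH")
    expect_equal(adj, bh_stepup(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-15))
    expect_true(all(adj <= 1))
  }
})

test_that("the slope LMM reproduces the balanced mixed-ANOVA F statistics", {
  st <- gen_slope_table(n_per_group = 8, seed = 77)
  fit <- fit_slope_lmm(st)
  st$subject <- factor(st$subject)
  a <- summary(stats::aov(slope ~ group * assessment + Error(subject / assessment),
                          data = st))
  f_between <- a[[1]][[1]]["group", "F value"]
  f_within <- a[[2]][[1]][c("assessment", "group:assessment"), "F value"]
  expect_equal(fit$anova$F[fit$anova$term == "group"], f_between,
               tolerance = 1e-6)
  expect_equal(fit$anova$F[fit$anova$term == "assessment"], f_within[1],
               tolerance = 1e-6)
  expect_equal(fit$anova$F[fit$anova$term == "group:assessment"], f_within[2],
               tolerance = 1e-6)
  expect_true(all(fit$anova$partial_eta2 >= 0 & fit$anova$partial_eta2 <= 1))
})

test_that("the LMM tolerates missing cells and reports convergence", {
  st <- gen_slope_table(n_per_group = 10, seed = 5)
  st <- st[-c(3, 17, 40), ]   # drop a few sessions (missing at random)
  fit <- fit_slope_lmm(st)
  expect_s4_class(fit$model, "lmerModLmerTest")
  expect_true(is.logical(fit$converged))
  expect_equal(nrow(fit$anova), 3)
  expect_error(fit_slope_lmm(transform(st, group = "verum")), ">= 2 levels")
})

test_that("post hoc contrasts recover an injected cell offset with BH-adjusted p", {
  off <- data.frame(group = "sham", assessment = "post", offset = 1.2)
  st <- gen_slope_table(n_per_group = 20, offsets = off, seed = 99)
  fit <- fit_slope_lmm(st)
  ph <- posthoc_contrasts(fit, ~ group | assessment)
  expect_equal(nrow(ph), 3)
  expect_equal(ph$p_adj, p.adjust(ph$p_raw, "BH"))
  at_post <- ph[ph$assessment == "post", ]
  # emmeans orders levels alphabetically: the contrast is sham - verum
  expect_gt(at_post$estimate, 0)
  expect_lt(at_post$p_adj, 0.05)
})
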