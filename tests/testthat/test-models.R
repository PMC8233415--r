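# simulate from the LMM itself: y = X beta + a_i + eps_ij
sim_lmm_data <- function(n_fish, n_per, beta = c(3, -0.6, 0.1),
                         tau = 0.3, sigma_range = c(0.2, 0.2), seed = 1) {
  set.seed(seed)
  fish <- sprintf("F%02d", seq_len(n_fish))
  sigmas <- seq(sigma_range[1], sigma_range[2], length.out = n_fish)
  d <- expand.grid(obs = seq_len(n_per), fish_id = fish,
                   KEEP.OUT.ATTRS = FALSE)
  d$period <- factor(sample(c("cold", "warm"), nrow(d), TRUE),
                     levels = c("cold", "warm"))
  d$diel_phase <- factor(sample(c("day", "night"), nrow(d), TRUE),
                         levels = c("day", "night"))
  a <- rnorm(n_fish, 0, tau)
  idx <- as.integer(d$fish_id <- factor(d$fish_id, levels = fish))
  X <- stats::model.matrix(~ period + diel_phase, d)
  d$y <- as.numeric(X %*% beta) + a[idx] + rnorm(nrow(d), 0, sigmas[idx])
  attr(d, "truth") <- list(beta = beta, tau = tau, sigmas = sigmas)
  d
}

test_that("with no random effect and pooled variance the fit is exactly OLS", {
  d <- sim_lmm_data(6, 40, seed = 31)
  fit <- fit_lmm(d, "y", ~ period + diel_phase,
                 random_intercept = FALSE, per_fish_variance = FALSE)
  ols <- lm(y ~ period + diel_phase, d)
  expect_equal(fit$coefficients$estimate, unname(coef(ols)), tolerance = 1e-8)
  expect_equal(fit$logLik, as.numeric(logLik(ols)), tolerance = 1e-8)
})

test_that("the LMM recovers generating parameters and per-fish variances", {
  d <- sim_lmm_data(17, 400, beta = c(3, -0.6, 0.02), tau = 0.3,
                    sigma_range = c(0.1, 0.6), seed = 32)
  truth <- attr(d, "truth")
  fit <- fit_lmm(d, "y", ~ period + diel_phase)
  expect_true(all(abs(fit$coefficients$estimate - truth$beta) <
                    2 * fit$coefficients$std_error +
                    c(2 * truth$tau / sqrt(17), 0, 0)))
  expect_gt(cor(fit$varcomp$per_fish_sd, truth$sigmas, method = "spearman"),
            0.9)
  expect_true(all(fit$varcomp$per_fish_sd > 0))
  # AIC identity
  expect_equal(fit$AIC, -2 * fit$logLik + 2 * fit$n_par, tolerance = 1e-8)
})

test_that("duplicating every row doubles the ML log-likelihood, estimates unchanged", {
  d <- sim_lmm_data(5, 30, seed = 33)
  f1 <- fit_lmm(d, "y", ~ period, random_intercept = FALSE,
                per_fish_variance = FALSE)
  f2 <- fit_lmm(rbind(d, d), "y", ~ period, random_intercept = FALSE,
                per_fish_variance = FALSE)
  expect_equal(f2$coefficients$estimate, f1$coefficients$estimate,
               tolerance = 1e-10)
  expect_equal(f2$logLik, 2 * f1$logLik, tolerance = 1e-8)
})

test_that("a singular design is rejected with the aliased column named", {
  d <- sim_lmm_data(4, 10, seed = 34)
  d$dup <- as.numeric(d$period == "warm")
  expect_error(fit_lmm(d, "y", ~ period + dup), "dup")
})

test_that("per-fish variance fit with ratios pinned to 1 equals the pooled fit", {
  d <- sim_lmm_data(6, 60, seed = 35)
  pooled <- fit_lmm(d, "y", ~ period, per_fish_variance = FALSE)
  lv <- levels(factor(d$fish_id))
  pinned <- nlme::lme(y ~ period, data = d, random = ~ 1 | fish_id,
                      method = "ML",
                      weights = nlme::varIdent(
                        form = ~ 1 | fish_id,
                        fixed = setNames(rep(1, length(lv) - 1), lv[-1])))
  expect_equal(pooled$logLik, as.numeric(logLik(pinned)), tolerance = 1e-6)
})

test_that("likelihood-ratio tests behave at the null and under strong effects", {
  d <- sim_lmm_data(6, 40, seed = 36)
  full <- fit_lmm(d, "y", ~ period + diel_phase, per_fish_variance = FALSE)
  expect_equal(lrt(full, full)$chi2, 0)
  expect_equal(lrt(full, full)$p_value, 1)
  red <- fit_lmm(d, "y", ~ period, per_fish_variance = FALSE)
  out <- lrt(full, red)
  expect_equal(out$df, 1L)
  expect_gte(out$chi2, 0)
  expect_error(lrt(red, full), "nested")
  d2 <- d[-(1:5), ]
  red2 <- fit_lmm(d2, "y", ~ period, per_fish_variance = FALSE)
  expect_error(lrt(full, red2), "rows")

  # power at a strong generated effect
  set.seed(37)
  rej <- 0
  n_rep <- 50
  for (r in seq_len(n_rep)) {
    ds <- sim_lmm_data(6, 30, beta = c(3, -0.6, 0), tau = 0.2,
                       seed = 1000 + r)
    f <- fit_lmm(ds, "y", ~ period, per_fish_variance = FALSE)
    r0 <- fit_lmm(ds, "y", ~ 1, per_fish_variance = FALSE)
    if (lrt(f, r0)$p_value < 0.05) rej <- rej + 1
  }
  expect_gt(rej / n_rep, 0.9)
})

test_that("confidence intervals cover the generating coefficients", {
  # ~95% nominal coverage for each fixed effect across replicates
  n_rep <- 100
  cover <- matrix(0L, n_rep, 3)
  for (r in seq_len(n_rep)) {
    d <- sim_lmm_data(8, 40, beta = c(3, -0.6, 0.1), tau = 0.25,
                      sigma_range = c(0.3, 0.3), seed = 2000 + r)
    fit <- fit_lmm(d, "y", ~ period + diel_phase, per_fish_variance = FALSE)
    lo <- fit$coefficients$estimate - 1.96 * fit$coefficients$std_error
    hi <- fit$coefficients$estimate + 1.96 * fit$coefficients$std_error
    cover[r, ] <- as.integer(attr(d, "truth")$beta >= lo &
                               attr(d, "truth")$beta <= hi)
  }
  rate <- colMeans(cover)
  # the intercept CI ignores random-intercept shrinkage of tau at n_fish=8,
  # so allow the documented band
  expect_true(all(rate >= 0.90 & rate <= 0.99))
})

test_that("AIC ordering is invariant to response rescaling", {
  d <- sim_lmm_data(6, 40, seed = 38)
  f1 <- fit_lmm(d, "y", ~ period + diel_phase, per_fish_variance = FALSE)
  r1 <- fit_lmm(d, "y", ~ period, per_fish_variance = FALSE)
  d$y <- d$y * 10
  f2 <- fit_lmm(d, "y", ~ period + diel_phase, per_fish_variance = FALSE)
  r2 <- fit_lmm(d, "y", ~ period, per_fish_variance = FALSE)
  # both AICs shift by 2 n log(c); differences are preserved
  expect_equal(f2$AIC - r2$AIC, f1$AIC - r1$AIC, tolerance = 1e-6)
  expect_equal(f2$AIC - f1$AIC, 2 * nrow(d) * log(10), tolerance = 1e-6)
})

sim_smooth_data <- function(n_fish = 6, n_per = 150, f, xlim = c(10, 25),
                            sigma = 0.15, tau = 0.2, seed = 1) {
  set.seed(seed)
  fish <- sprintf("F%02d", seq_len(n_fish))
  d <- expand.grid(obs = seq_len(n_per), fish_id = fish,
                   KEEP.OUT.ATTRS = FALSE)
  d$x <- runif(nrow(d), xlim[1], xlim[2])
  a <- rnorm(n_fish, 0, tau)
  d$y <- 2 + f(d$x) + a[as.integer(factor(d$fish_id))] +
    rnorm(nrow(d), 0, sigma)
  d
}

test_that("a linear generating effect is fitted as a line within its CI", {
  d <- sim_smooth_data(f = function(x) 0.05 * x, seed = 41)
  sm <- fit_smooth_mixed(d, "y", "x")
  line <- lm(fit ~ covariate, sm$smooth)
  expect_true(all(abs(residuals(line)) < (sm$smooth$upper - sm$smooth$fit)))
})

test_that("a U-shaped temperature effect has its minimum where generated", {
  d <- sim_smooth_data(f = function(x) 0.01 * (x - 17.5)^2, xlim = c(10, 25),
                       seed = 42)
  sm <- fit_smooth_mixed(d, "y", "x")
  expect_true(sm$smooth$covariate[which.min(sm$smooth$fit)] >= 15 &&
                sm$smooth$covariate[which.min(sm$smooth$fit)] <= 20)
  expect_lt(sm$p_value, 0.001)
})

test_that("an increasing effect is fitted monotone over the central 90% of the grid", {
  d <- sim_smooth_data(f = function(x) 0.08 * x, xlim = c(5, 45), seed = 43)
  sm <- fit_smooth_mixed(d, "y", "x")
  core <- sm$smooth[sm$smooth$covariate >= quantile(d$x, 0.05) &
                      sm$smooth$covariate <= quantile(d$x, 0.95), ]
  expect_true(all(diff(core$fit) > 0))
})

test_that("penalty limits: infinite penalty gives a line, zero penalty tracks bin means", {
  d <- sim_smooth_data(f = function(x) 0.02 * (x - 17)^2, seed = 44)
  # second-derivative penalty -> straight line as sp -> infinity
  sm_inf <- fit_smooth_mixed(d, "y", "x", sp = c(1e9, 1e9))
  second_diff <- diff(diff(sm_inf$smooth$fit))
  expect_lt(max(abs(second_diff)), 1e-6)

  # sp -> 0 with k = distinct x values interpolates the per-bin means
  xs <- seq(10, 25, length.out = 25)
  d2 <- data.frame(fish_id = rep(c("A", "B"), each = 250),
                   x = rep(xs, 20))
  set.seed(45)
  d2$y <- 1 + 0.03 * (d2$x - 17)^2 + rnorm(nrow(d2), 0, 0.1)
  sm0 <- fit_smooth_mixed(d2, "y", "x", k = 25, n_grid = 100,
                          sp = c(0, 1e9))
  bin_means <- tapply(d2$y, d2$x, mean)
  pred <- approx(sm0$smooth$covariate, sm0$smooth$fit, xout = xs)$y
  centred <- bin_means - mean(bin_means)
  expect_lt(max(abs(pred - (centred - mean(centred)))), 0.05)
})

test_that("too few distinct covariate values are rejected with advice", {
  d <- data.frame(fish_id = rep(c("A", "B"), each = 30),
                  x = rep(1:10, 6), y = rnorm(60))
  expect_error(fit_smooth_mixed(d, "y", "x"), "basis")
})

test_that("group/period tests report ANOVA and Kruskal-Wallis statistics", {
  pl <- small_pipeline()
  res <- group_period_tests(pl$hourly)
  av <- res[res$test == "two-way ANOVA", ]
  expect_setequal(av$term, c("group", "period", "group:period"))
  expect_true(all(av$p_value < 0.001))
  kw <- res[res$test == "Kruskal-Wallis", ]
  expect_equal(nrow(kw), 1L)
  expect_lt(kw$p_value, 0.001)
})

test_that("the Kruskal-Wallis statistic matches the closed-form rank formula", {
  # DS cold cells: fish A monthly means {1,2,3}, fish B {4,5,6}; filler rows
  # populate the other group and period levels
  mk <- function(depths_a, depths_b) {
    h <- make_hourly(
      c(rep(c("A", "B"), each = 3), "C", "C", "A"),
      c(rep(c("2017-01-05", "2017-02-05", "2017-03-05"), 2),
        "2017-01-10", "2017-04-10", "2017-04-10"),
      rep(10, 9), c(depths_a, depths_b, 2, 1, 2))
    h$group <- factor(c(rep("DS", 6), "SS", "SS", "DS"),
                      levels = c("DS", "SS"))
    h$period <- factor(c(rep("cold", 7), "warm", "warm"),
                       levels = c("cold", "warm"))
    h
  }
  res <- group_period_tests(mk(1:3, 4:6))
  kw <- res[res$test == "Kruskal-Wallis", ]
  expect_equal(kw$statistic, 12 / (6 * 7) * (6^2 / 3 + 15^2 / 3) - 3 * 7,
               tolerance = 1e-6)
  # identical samples give a zero statistic
  res0 <- group_period_tests(mk(1:3, 1:3))
  expect_equal(res0$statistic[res0$test == "Kruskal-Wallis"], 0,
               tolerance = 1e-12)
  h1 <- mk(1:3, 4:6)
  h1$period <- factor("cold", levels = "cold")
  expect_error(group_period_tests(h1), "two levels")
})
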