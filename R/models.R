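#' Linear mixed model with per-fish residual variance
#'
#' Fits \eqn{y = X\beta + a_i + \varepsilon_{ij}}, with a fish random
#' intercept \eqn{a_i \sim N(0, \tau^2)} and residuals
#' \eqn{\varepsilon_{ij} \sim N(0, \sigma_i^2)} whose variance may differ
#' between fish (`per_fish_variance = TRUE`, a `varIdent` structure).
#' Estimation is maximum likelihood by default so that nested fits can be
#' compared with likelihood-ratio tests; REML is available for final
#' estimates. With the random intercept and the variance structure both
#' switched off the fit collapses to ordinary least squares.
#'
#' Factor columns should be coded with the baseline first (the package
#' pipeline uses cold period, day phase and the DS group as reference
#' levels, so coefficient signs read as warm/night/SS contrasts).
#'
#' @param data Data.frame with the response, a `fish_id` column and every
#'   term of `fixed`.
#' @param response Name of the response column.
#' @param fixed One-sided formula of fixed effects, e.g.
#'   `~ period * diel_phase * group`.
#' @param random_intercept Include the per-fish random intercept?
#' @param per_fish_variance Allow a separate residual SD per fish?
#' @param method `"ML"` (default) or `"REML"`.
#'
#' @return A list of class `"bathyseg_lmm"`: `coefficients` (term, estimate,
#'   std_error, df, t_value, p_value), `varcomp` (`random_intercept_sd`,
#'   `sigma`, named `per_fish_sd`), `logLik`, `n_par`, `AIC`, `fitted`,
#'   `residuals`, `n`, `method`, and the underlying `fit` object.
#' @export
fit_lmm <- function(data, response, fixed = ~ 1,
                    random_intercept = TRUE, per_fish_variance = TRUE,
                    method = c("ML", "REML")) {
  method <- match.arg(method)
  d <- as.data.frame(data)
  if (!response %in% names(d)) stop("response column '", response, "' not found")
  if (!"fish_id" %in% names(d)) stop("data must carry a fish_id column")
  d$fish_id <- factor(d$fish_id)
  if (nlevels(d$fish_id) < 2L && (random_intercept || per_fish_variance))
    stop("at least two fish are required for mixed / per-fish structures")
  f <- stats::as.formula(paste(response, "~", deparse(fixed[[2]])))
  mm <- stats::model.matrix(f, d)
  if (qr(mm)$rank < ncol(mm)) {
    aliased <- colnames(mm)[qr(mm)$pivot[-seq_len(qr(mm)$rank)]]
    stop("singular fixed-effect design; aliased column(s): ",
         paste(aliased, collapse = ", "))
  }

  if (random_intercept) {
    args <- list(fixed = f, data = d, random = ~ 1 | fish_id, method = method,
                 control = nlme::lmeControl(maxIter = 200, msMaxIter = 200,
                                            niterEM = 50, returnObject = FALSE))
    if (per_fish_variance)
      args$weights <- nlme::varIdent(form = ~ 1 | fish_id)
    fit <- tryCatch(do.call(nlme::lme, args), error = function(e)
      stop("mixed-model fit failed to converge: ", conditionMessage(e)))
    tt <- summary(fit)$tTable
    coefs <- data.frame(term = rownames(tt), estimate = tt[, "Value"],
                        std_error = tt[, "Std.Error"], df = tt[, "DF"],
                        t_value = tt[, "t-value"], p_value = tt[, "p-value"],
                        row.names = NULL)
    tau <- as.numeric(nlme::VarCorr(fit)["(Intercept)", "StdDev"])
    sigma <- fit$sigma
  } else if (per_fish_variance) {
    fit <- nlme::gls(f, data = d, method = method,
                     weights = nlme::varIdent(form = ~ 1 | fish_id))
    tt <- summary(fit)$tTable
    rdf <- nrow(d) - nrow(tt)
    coefs <- data.frame(term = rownames(tt), estimate = tt[, "Value"],
                        std_error = tt[, "Std.Error"], df = rdf,
                        t_value = tt[, "t-value"], p_value = tt[, "p-value"],
                        row.names = NULL)
    tau <- 0
    sigma <- fit$sigma
  } else {
    fit <- lm(f, data = d)   # logLik(lm) is the ML log-likelihood
    sm <- summary(fit)$coefficients
    coefs <- data.frame(term = rownames(sm), estimate = sm[, 1],
                        std_error = sm[, 2], df = fit$df.residual,
                        t_value = sm[, 3], p_value = sm[, 4],
                        row.names = NULL)
    tau <- 0
    sigma <- summary(fit)$sigma
  }

  per_fish_sd <- setNames(rep(sigma, nlevels(d$fish_id)), levels(d$fish_id))
  if (per_fish_variance && !inherits(fit, "lm")) {
    vs <- fit$modelStruct$varStruct
    rel <- coef(vs, unconstrained = FALSE, allCoef = TRUE)
    per_fish_sd <- sigma * rel[levels(d$fish_id)]
    names(per_fish_sd) <- levels(d$fish_id)
  }
  ll <- logLik(fit)
  structure(list(
    coefficients = coefs,
    varcomp = list(random_intercept_sd = tau, sigma = sigma,
                   per_fish_sd = per_fish_sd),
    logLik = as.numeric(ll), n_par = attr(ll, "df"),
    AIC = -2 * as.numeric(ll) + 2 * attr(ll, "df"),
    fitted = as.numeric(stats::fitted(fit)),
    residuals = as.numeric(stats::residuals(fit)),
    n = nrow(d), method = method, response = response, fit = fit
  ), class = "bathyseg_lmm")
}

#' @export
print.bathyseg_lmm <- function(x, digits = 4, ...) {
  cat("Linear mixed model (", x$method, "), response: ", x$response,
      "\n", sep = "")
  print(cbind(x$coefficients[1],
              round(x$coefficients[-1], digits)), row.names = FALSE)
  cat(sprintf("random intercept SD %.4g, residual SD %.4g (%s)\n",
              x$varcomp$random_intercept_sd, x$varcomp$sigma,
              if (length(unique(round(x$varcomp$per_fish_sd, 10))) > 1)
                "per-fish" else "pooled"))
  cat(sprintf("logLik %.3f on %d parameters; AIC %.2f; n = %d\n",
              x$logLik, x$n_par, x$AIC, x$n))
  invisible(x)
}

#' Likelihood-ratio test between nested maximum-likelihood fits
#'
#' \eqn{\chi^2 = 2(\ell_{full} - \ell_{reduced})}, with degrees of freedom
#' equal to the difference in free-parameter counts and a chi-square
#' upper-tail p-value. Both fits must be ML fits on the same rows.
#'
#' @param full,reduced `"bathyseg_lmm"` fits; `reduced` nested in `full`.
#' @return A list: `chi2`, `df`, `p_value`.
#' @export
lrt <- function(full, reduced) {
  stopifnot(inherits(full, "bathyseg_lmm"), inherits(reduced, "bathyseg_lmm"))
  if (full$method != "ML" || reduced$method != "ML")
    stop("likelihood-ratio tests require ML fits")
  if (full$n != reduced$n)
    stop("fits use different numbers of rows; refit on a common data set")
  if (full$n_par < reduced$n_par)
    stop("'full' has fewer parameters than 'reduced'; models are not nested")
  chi2 <- max(0, 2 * (full$logLik - reduced$logLik))
  df <- full$n_par - reduced$n_par
  p <- if (df == 0L) as.numeric(chi2 <= 1e-8) else
    pchisq(chi2, df, lower.tail = FALSE)
  list(chi2 = chi2, df = df, p_value = p)
}

#' Penalized-smooth covariate effect with a fish random intercept
#'
#' Fits \eqn{y = \alpha + a_i + f(x) + \varepsilon} where `f` is a penalized
#' cubic regression spline (basis dimension `k`, second-derivative penalty,
#' smoothing parameter chosen by generalized cross-validation) and the fish
#' intercept enters through the mixed-model (random-effect smooth)
#' representation. Returns the centred smooth with 95% pointwise confidence
#' bounds on an `n_grid`-point covariate grid.
#'
#' @param data Data.frame with the response, `fish_id` and the covariate.
#' @param response Name of the response column.
#' @param covariate Name of the smooth covariate column.
#' @param k Spline basis dimension (default 10).
#' @param n_grid Grid size for the returned curve.
#' @param sp Optional fixed smoothing parameters (length 2: covariate
#'   smooth, fish random-effect smooth), bypassing GCV; mainly for studying
#'   the penalty limits.
#'
#' @return A list of class `"bathyseg_smooth"`: `smooth` (grid data.frame
#'   with `fit`, `se`, `lower`, `upper`), `edf`, `f_statistic`, `p_value`,
#'   `logLik`, `AIC`, and the `fit` object (a `gam`).
#' @export
fit_smooth_mixed <- function(data, response, covariate, k = 10, n_grid = 100,
                             sp = NULL) {
  d <- as.data.frame(data)
  stopifnot(response %in% names(d), covariate %in% names(d),
            "fish_id" %in% names(d))
  d$fish_id <- factor(d$fish_id)
  n_distinct <- length(unique(d[[covariate]]))
  if (n_distinct < 20L)
    stop("only ", n_distinct, " distinct covariate values; ",
         "use fewer basis functions (smaller k) or a parametric term")
  f <- stats::as.formula(sprintf("%s ~ s(%s, k = %d, bs = \"cr\") + s(fish_id, bs = \"re\")",
                                 response, covariate, k))
  fit <- mgcv::gam(f, data = d, method = "GCV.Cp", sp = sp)
  grid <- seq(min(d[[covariate]]), max(d[[covariate]]), length.out = n_grid)
  nd <- data.frame(grid, factor(levels(d$fish_id)[1], levels = levels(d$fish_id)))
  names(nd) <- c(covariate, "fish_id")
  sm_lab <- sprintf("s(%s)", covariate)
  pr <- predict(fit, newdata = nd, type = "terms", terms = sm_lab,
                se.fit = TRUE)
  est <- as.numeric(pr$fit[, sm_lab])
  se <- as.numeric(pr$se.fit[, sm_lab])
  st <- summary(fit)$s.table
  ll <- logLik(fit)
  structure(list(
    smooth = data.frame(covariate = grid, fit = est, se = se,
                        lower = est - 1.96 * se, upper = est + 1.96 * se),
    covariate = covariate, response = response,
    edf = st[sm_lab, "edf"], f_statistic = st[sm_lab, "F"],
    p_value = st[sm_lab, "p-value"],
    logLik = as.numeric(ll), AIC = stats::AIC(fit), n = nrow(d), fit = fit
  ), class = "bathyseg_smooth")
}

#' @export
print.bathyseg_smooth <- function(x, ...) {
  cat(sprintf("Penalized smooth of %s on %s: edf %.2f, F = %.2f, p = %.3g\n",
              x$response, x$covariate, x$edf, x$f_statistic, x$p_value))
  invisible(x)
}

#' Group/period tests of mean depth
#'
#' Two-way factorial ANOVA of the hourly mean depths on group x period, and
#' a Kruskal-Wallis test of cold-period monthly mean depth across DS
#' individuals (the depth-stratification test; tie-corrected rank
#' statistic).
#'
#' @param hourly Hourly table with `group`, `period`, `month`, `date_local`
#'   and `mean_depth` (e.g. `segment_cohort(...)$hourly`).
#' @return A data.frame: `test`, `term`, `statistic`, `df`, `p_value`.
#' @export
group_period_tests <- function(hourly) {
  h <- as.data.table(hourly)
  stopifnot(all(c("group", "period", "mean_depth") %in% names(h)))
  if (nlevels(factor(h$group)) < 2L || nlevels(factor(h$period)) < 2L)
    stop("both group and period need at least two levels")
  av <- aov(mean_depth ~ group * period, data = h)
  at <- summary(av)[[1]]
  terms <- trimws(rownames(at))
  keep <- terms != "Residuals"
  res <- data.frame(test = "two-way ANOVA", term = terms[keep],
                    statistic = at[keep, "F value"], df = at[keep, "Df"],
                    p_value = at[keep, "Pr(>F)"], row.names = NULL)
  ds <- h[group == "DS" & period == "cold"]
  if (nrow(ds) && data.table::uniqueN(ds$fish_id) >= 2L) {
    ds[, year := as.POSIXlt(date_local)$year + 1900L]
    mm <- ds[, .(mean_depth = mean(mean_depth)), by = .(fish_id, month, year)]
    kw <- kruskal.test(mm$mean_depth, factor(mm$fish_id))
    res <- rbind(res, data.frame(
      test = "Kruskal-Wallis", term = "fish (DS, cold months)",
      statistic = unname(kw$statistic), df = unname(kw$parameter),
      p_value = kw$p.value))
  }
  res
}
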