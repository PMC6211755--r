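## Probit dose-mortality analysis in the Polo tradition: maximum-likelihood
## fit on log10 dose, LC50, Fieller 95% fiducial limits with heterogeneity
## correction, the fiducial-limit-overlap significance rule, mortality
## summaries and Abbott control correction.

#' Abbott correction for control mortality
#'
#' `(observed - control) / (1 - control)`, floored at zero.
#'
#' @param observed observed mortality fraction in the treatment.
#' @param control mortality fraction in the untreated control (< 1).
#' @return corrected mortality fraction.
#' @examples
#' abbott_correct(0.5, 0.2) # 0.375
#' @export
abbott_correct <- function(observed, control) {
  stopifnot(all(observed >= 0), all(observed <= 1), all(control >= 0))
  if (any(control >= 1)) {
    stop_btchar("control mortality must be < 1", class = "btchar_bad_control")
  }
  pmax(0, (observed - control) / (1 - control))
}

validate_bioassay <- function(data) {
  stopifnot(is.data.frame(data), all(c("dose", "n", "dead") %in% names(data)))
  if (any(data$dose <= 0)) {
    stop_btchar("doses must be positive", class = "btchar_bad_dose")
  }
  if (any(data$dead < 0 | data$dead > data$n)) {
    stop_btchar("dead must lie in [0, n]", class = "btchar_bad_counts")
  }
  data
}

probit_loglik <- function(a, b, x, n, y) {
  eta <- pmin(pmax(a + b * x, -8), 8)
  p <- stats::pnorm(eta)
  sum(stats::dbinom(y, n, p, log = TRUE))
}

#' Fit a probit dose-mortality model by maximum likelihood
#'
#' Mortality probability `pnorm(a + b * log10(dose))` fitted to grouped
#' binomial counts by Fisher scoring with step halving (convergence when the
#' relative log-likelihood change falls below `1e-10`, at most 100
#' iterations). Goodness of fit is the Pearson chi-square over dose groups
#' with `groups - 2` degrees of freedom; when the heterogeneity factor
#' `chisq/df` exceeds 1, the covariance matrix is inflated by it and
#' interval critical values switch from the normal to the t distribution
#' with `df` degrees of freedom (the Polo convention). Optionally applies
#' the Abbott correction first, using a control row.
#'
#' @param data data.frame with columns `dose` (positive, >= 2 distinct
#'   values), `n` and `dead`; replicate rows at a dose are pooled.
#' @param abbott optional control mortality fraction; when supplied, dead
#'   counts are replaced by Abbott-corrected expected counts before fitting.
#' @return object of class `probit_fit` with elements `intercept`, `slope`,
#'   `slope_se`, `vcov` (heterogeneity-scaled when applicable), `loglik`,
#'   `lc50`, `fl95`, `chisq`, `df`, `heterogeneity`, `crit`
#'   (critical value used for intervals), `converged`, `data`.
#' @examples
#' d <- data.frame(dose = c(10, 100), n = c(1000, 1000), dead = c(200, 800))
#' fit <- fit_probit(d)
#' fit$lc50 # ~31.6
#' @export
fit_probit <- function(data, abbott = NULL) {
  data <- validate_bioassay(data)
  if (!is.null(abbott)) {
    frac <- abbott_correct(data$dead / data$n, abbott)
    data$dead <- round(frac * data$n)
  }
  # pool replicates per dose
  agg <- stats::aggregate(cbind(n, dead) ~ dose, data = data, FUN = sum)
  agg <- agg[order(agg$dose), ]
  if (nrow(agg) < 2) {
    stop_btchar("need at least 2 distinct doses", class = "btchar_fit_failure")
  }
  x <- log10(agg$dose)
  n <- agg$n
  y <- agg$dead
  if (sum(y) == 0 || sum(y) == sum(n)) {
    stop_btchar("all-alive or all-dead data: probit model undefined",
                class = "btchar_fit_failure")
  }
  # start values: empirical probit regression on adjusted proportions
  p_adj <- (y + 0.5) / (n + 1)
  start <- stats::coef(stats::lm(stats::qnorm(p_adj) ~ x))
  a <- start[[1]]
  b <- start[[2]]
  ll <- probit_loglik(a, b, x, n, y)
  converged <- FALSE
  for (iter in seq_len(100L)) {
    eta <- pmin(pmax(a + b * x, -8), 8)
    p <- stats::pnorm(eta)
    phi <- stats::dnorm(eta)
    w <- n * phi^2 / pmax(p * (1 - p), 1e-12)
    # Fisher scoring step via weighted least squares on the working response
    z <- eta + (y - n * p) / pmax(n * phi, 1e-12)
    X <- cbind(1, x)
    XtW <- t(X * w)
    step_coef <- solve(XtW %*% X, XtW %*% z)
    a_new <- step_coef[1]
    b_new <- step_coef[2]
    # step halving if the likelihood worsens
    frac <- 1
    ll_new <- probit_loglik(a_new, b_new, x, n, y)
    while (ll_new < ll && frac > 1e-4) {
      frac <- frac / 2
      a_new <- a + frac * (step_coef[1] - a)
      b_new <- b + frac * (step_coef[2] - b)
      ll_new <- probit_loglik(a_new, b_new, x, n, y)
    }
    done <- abs(ll_new - ll) < 1e-10 * (abs(ll) + 1e-10)
    a <- a_new
    b <- b_new
    ll <- ll_new
    if (done) {
      converged <- TRUE
      break
    }
  }
  if (!converged || !is.finite(a) || !is.finite(b) || abs(b) > 100) {
    stop_btchar("probit fit did not converge (possible complete separation); ",
                "last (a, b) = (", signif(a, 4), ", ", signif(b, 4), ")",
                class = "btchar_fit_failure")
  }
  # expected information at the optimum
  eta <- pmin(pmax(a + b * x, -8), 8)
  p <- stats::pnorm(eta)
  phi <- stats::dnorm(eta)
  w <- n * phi^2 / pmax(p * (1 - p), 1e-12)
  X <- cbind(1, x)
  info <- t(X * w) %*% X
  vcov <- solve(info)
  dimnames(vcov) <- list(c("intercept", "slope"), c("intercept", "slope"))
  chisq <- sum((y - n * p)^2 / pmax(n * p * (1 - p), 1e-12))
  df <- nrow(agg) - 2L
  het <- if (df > 0) chisq / df else NA_real_
  crit <- stats::qnorm(0.975)
  if (df > 0 && is.finite(het) && het > 1) {
    vcov <- vcov * het
    crit <- stats::qt(0.975, df)
  }
  fit <- structure(
    list(intercept = a, slope = b, slope_se = sqrt(vcov[2, 2]),
         vcov = vcov, loglik = ll, chisq = chisq, df = df,
         heterogeneity = het, crit = crit, converged = converged,
         data = agg),
    class = "probit_fit")
  fit$lc50 <- lc50(fit)
  fit$fl95 <- tryCatch(fiducial_limits(fit), btchar_undefined_interval = function(e) c(NA_real_, NA_real_))
  fit
}

#' @export
print.probit_fit <- function(x, ...) {
  cat("Probit dose-response fit (log10 dose)\n")
  cat(sprintf("  slope: %.3f +/- %.3f   intercept: %.3f\n",
              x$slope, x$slope_se, x$intercept))
  cat(sprintf("  LC50: %.4g   FL95: %.4g - %.4g\n",
              x$lc50, x$fl95[1], x$fl95[2]))
  cat(sprintf("  chisq: %.3f on %d df (heterogeneity %.3f)\n",
              x$chisq, x$df, x$heterogeneity))
  invisible(x)
}

#' Median lethal concentration from a probit fit
#'
#' `10^(-intercept/slope)`, the dose at which the fitted mortality is 50%.
#'
#' @param fit a `probit_fit`.
#' @return LC50 in the dose units of the input data.
#' @export
lc50 <- function(fit) {
  stopifnot(inherits(fit, "probit_fit"))
  if (fit$slope <= 0) {
    stop_btchar("non-positive slope: dose response is not monotone increasing",
                class = "btchar_bad_slope")
  }
  10^(-fit$intercept / fit$slope)
}

#' Fiducial limits for the LC50 (Fieller's theorem)
#'
#' Limits for `m = -intercept/slope` on the log10 scale are the roots of
#' `(a + b m)^2 = crit^2 * (v11 + 2 m v12 + m^2 v22)` with the fit's
#' (heterogeneity-scaled) covariance and critical value, back-transformed
#' with `10^m`. When `g = crit^2 * v22 / b^2 >= 1` the interval is
#' unbounded and an error is raised.
#'
#' @param fit a `probit_fit`.
#' @param level confidence level (default 0.95).
#' @return numeric `c(lo, hi)` in dose units.
#' @export
fiducial_limits <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "probit_fit"))
  a <- fit$intercept
  b <- fit$slope
  v11 <- fit$vcov[1, 1]
  v12 <- fit$vcov[1, 2]
  v22 <- fit$vcov[2, 2]
  crit <- if (identical(level, 0.95)) {
    fit$crit
  } else if (fit$df > 0 && is.finite(fit$heterogeneity) && fit$heterogeneity > 1) {
    stats::qt(1 - (1 - level) / 2, fit$df)
  } else {
    stats::qnorm(1 - (1 - level) / 2)
  }
  g <- crit^2 * v22 / b^2
  if (g >= 1) {
    stop_btchar("fiducial interval undefined: g = ", signif(g, 4), " >= 1",
                class = "btchar_undefined_interval")
  }
  # roots of (b^2 - c2 v22) m^2 + 2 (a b - c2 v12) m + (a^2 - c2 v11) = 0
  c2 <- crit^2
  A <- b^2 - c2 * v22
  B <- 2 * (a * b - c2 * v12)
  C <- a^2 - c2 * v11
  disc <- B^2 - 4 * A * C
  if (disc < 0) disc <- 0
  # the parabola opens upward (A > 0 when g < 1) so the estimate
  # m = -a/b lies between the two roots
  roots <- sort((-B + c(-1, 1) * sqrt(disc)) / (2 * A))
  10^roots
}

#' Compare two LC50s by the fiducial-limit-overlap rule
#'
#' Two LC50s are declared significantly different exactly when their 95%
#' fiducial intervals do not overlap (touching endpoints count as
#' overlapping). Accepts fitted objects or plain `c(lo, hi)` intervals,
#' so published limits can be compared directly.
#'
#' @param fitA,fitB `probit_fit` objects or numeric length-2 intervals.
#' @return list with `significant` (logical), `intervals` (2x2 matrix)
#'   and `rule`.
#' @examples
#' compare_lc50(c(30, 74), c(9, 24))$significant # TRUE
#' compare_lc50(c(30, 74), c(26, 92))$significant # FALSE
#' @export
compare_lc50 <- function(fitA, fitB) {
  as_interval <- function(f) {
    if (inherits(f, "probit_fit")) f$fl95 else {
      stopifnot(is.numeric(f), length(f) == 2)
      sort(f)
    }
  }
  ia <- as_interval(fitA)
  ib <- as_interval(fitB)
  disjoint <- ia[2] < ib[1] || ib[2] < ia[1]
  list(significant = disjoint,
       intervals = rbind(A = ia, B = ib),
       rule = "95% fiducial limits disjoint")
}

#' Average percent mortality per treatment
#'
#' Pools replicates within each treatment and reports percent dead to two
#' significant figures (29/32 dead reports 91).
#'
#' @param data data.frame with columns `treatment`, `n`, `dead`.
#' @return data.frame with `treatment` and `pct_mortality`.
#' @export
mortality_summary <- function(data) {
  stopifnot(all(c("treatment", "n", "dead") %in% names(data)))
  if (any(data$dead < 0 | data$dead > data$n)) {
    stop_btchar("dead must lie in [0, n]", class = "btchar_bad_counts")
  }
  agg <- stats::aggregate(cbind(n, dead) ~ treatment, data = data, FUN = sum)
  data.frame(treatment = agg$treatment,
             pct_mortality = signif(100 * agg$dead / agg$n, 2),
             stringsAsFactors = FALSE)
}
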