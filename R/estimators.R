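#' MR causal-effect estimate container
#'
#' Every estimator returns an `mr_estimate`: the causal effect `beta` on the
#' outcome scale (log-odds for binary outcomes, SD units for continuous),
#' its standard error, the symmetric normal-theory 95% interval, the same
#' triple exponentiated to the odds-ratio scale, a two-sided normal p-value,
#' the number of variants used, and a method-specific `extra` list.
#' @keywords internal
new_mr_estimate <- function(method, beta, se, n_snp, extra = list()) {
  structure(list(
    method = method, beta = beta, se = se,
    ci_low = beta - Z95 * se, ci_high = beta + Z95 * se,
    or_value = exp(beta), or_low = exp(beta - Z95 * se),
    or_high = exp(beta + Z95 * se),
    pval = norm_pval(beta / se), n_snp = as.integer(n_snp),
    extra = extra), class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s: beta = %.4f (se %.4f), OR = %.3f (95%% CI %.3f-%.3f), p = %.3g, nSNP = %d\n",
              x$method, x$beta, x$se, x$or_value, x$or_low, x$or_high,
              x$pval, x$n_snp))
  invisible(x)
}

#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  data.frame(method = x$method, n_snp = x$n_snp, beta = x$beta, se = x$se,
             ci_low = x$ci_low, ci_high = x$ci_high, or = x$or_value,
             or_low = x$or_low, or_high = x$or_high, pval = x$pval,
             stringsAsFactors = FALSE)
}

# pull the columns every estimator consumes, dropping unusable variants
h_cols <- function(h, drop_zero_bx = TRUE) {
  d <- as.data.frame(h)[, c("variant_id", "bx", "sex", "by", "sey")]
  if (drop_zero_bx && any(d$bx == 0)) {
    warning(sum(d$bx == 0), " variant(s) with bx = 0 excluded")
    d <- d[d$bx != 0, , drop = FALSE]
  }
  d
}

#' Wald ratio estimate for a single variant
#'
#' `beta = by/bx`. The default standard error is the first-order delta
#' method `sey/|bx|`; `second_order = TRUE` adds the gene-exposure
#' uncertainty term, `se^2 = sey^2/bx^2 + by^2 * sex^2 / bx^4`.
#'
#' @param bx,sex gene-exposure coefficient and standard error.
#' @param by,sey gene-outcome coefficient and standard error.
#' @param second_order use the second-order delta-method standard error.
#' @return An `mr_estimate`.
#' @export
mr_wald_ratio <- function(bx, sex, by, sey, second_order = FALSE) {
  if (bx == 0) stop("Wald ratio undefined for bx = 0")
  beta <- by / bx
  se <- if (second_order) sqrt(sey^2 / bx^2 + by^2 * sex^2 / bx^4) else sey / abs(bx)
  new_mr_estimate("wald", beta, se, 1L)
}

#' Inverse-variance-weighted estimate
#'
#' Pools per-variant Wald ratios with weights `w = bx^2/sey^2`, equivalent
#' to zero-intercept weighted regression of `by` on `bx` with weights
#' `1/sey^2`. Fixed effects: `se = 1/sqrt(sum(w))`. Multiplicative random
#' effects: the fixed se is scaled by `sqrt(max(Q/(L-1), 1))` where Q is
#' Cochran's statistic, so the random-effects se is never smaller than the
#' fixed one.
#'
#' @param h a [harmonized_set].
#' @param effects `"fixed"` or `"random"` (multiplicative).
#' @return An `mr_estimate`; `extra` carries `Q` and the scaling factor.
#' @export
mr_ivw <- function(h, effects = c("fixed", "random")) {
  effects <- match.arg(effects)
  d <- h_cols(h)
  L <- nrow(d)
  if (L == 0) stop("no usable variants")
  if (L == 1) {
    message("single variant: IVW degrades to the Wald ratio")
    est <- mr_wald_ratio(d$bx, d$sex, d$by, d$sey)
    est$method <- paste0("ivw_", effects)
    return(est)
  }
  w <- d$bx^2 / d$sey^2
  ratio <- d$by / d$bx
  beta <- sum(w * ratio) / sum(w)
  se_fixed <- sqrt(1 / sum(w))
  q <- sum(w * (ratio - beta)^2)
  scale <- if (effects == "random") sqrt(max(q / (L - 1), 1)) else 1
  new_mr_estimate(paste0("ivw_", effects), beta, se_fixed * scale, L,
                  extra = list(Q = q, df = L - 1, scale = scale))
}

# weighted least squares by explicit normal equations; X has named columns
wls_fit <- function(X, y, w) {
  XtW <- t(X * w)
  XtWX <- XtW %*% X
  qrx <- qr(XtWX)
  if (qrx$rank < ncol(X)) return(NULL)
  coefs <- drop(solve(XtWX, XtW %*% y))
  res <- drop(y - X %*% coefs)
  list(coefs = coefs, res = res, XtWX_inv = solve(XtWX),
       rss_w = sum(w * res^2))
}

#' MR-Egger regression
#'
#' Weighted linear regression of the gene-outcome on the gene-exposure
#' coefficients with an unconstrained intercept (weights `1/sey^2`). The
#' slope is the causal estimate; the intercept estimates average directional
#' pleiotropy. Because the regression is not invariant to allele
#' re-orientation, pairs are first sign-fixed so that `bx >= 0`. Standard
#' errors use multiplicative overdispersion with the residual-variance
#' factor bounded below by 1.
#'
#' @param h a [harmonized_set] with at least 3 variants.
#' @return An `mr_estimate` for the slope; `extra` carries `intercept`,
#'   `intercept_se`, `intercept_ci_low/high`, `intercept_p`, `sigma2`.
#' @export
mr_egger <- function(h) {
  d <- h_cols(h, drop_zero_bx = FALSE)
  L <- nrow(d)
  if (L < 3) stop("egger underdetermined: need at least 3 variants")
  s <- ifelse(d$bx < 0, -1, 1)
  bx <- s * d$bx
  by <- s * d$by
  if (stats::var(bx) == 0) stop("egger underdetermined: collinear design (constant bx)")
  w <- 1 / d$sey^2
  fit <- wls_fit(cbind(intercept = 1, slope = bx), by, w)
  if (is.null(fit)) stop("egger underdetermined: singular design")
  sigma2 <- fit$rss_w / (L - 2)
  scale <- max(1, sigma2)
  ses <- sqrt(diag(fit$XtWX_inv) * scale)
  est <- new_mr_estimate("egger", fit$coefs[["slope"]], ses[2], L,
                         extra = list(
                           intercept = fit$coefs[["intercept"]],
                           intercept_se = ses[1],
                           intercept_ci_low = fit$coefs[["intercept"]] - Z95 * ses[1],
                           intercept_ci_high = fit$coefs[["intercept"]] + Z95 * ses[1],
                           intercept_p = norm_pval(fit$coefs[["intercept"]] / ses[1]),
                           sigma2 = sigma2))
  est
}

# weighted-median point estimate: mid-point cumulative-weight convention
# with linear interpolation at cumulative weight 0.5
weighted_median_point <- function(ratio, w) {
  ord <- order(ratio)
  r <- ratio[ord]
  ww <- w[ord] / sum(w)
  p <- cumsum(ww) - ww / 2
  stats::approx(p, r, xout = 0.5, rule = 2, ties = "ordered")$y
}

#' Weighted-median estimate
#'
#' Consistent when at least half of the total instrument weight comes from
#' valid instruments. Per-variant Wald ratios are ordered and the estimate
#' interpolated at cumulative normalized inverse-variance weight 0.5
#' (weights `bx^2/sey^2`, mid-point convention). The standard error is the
#' standard deviation of the estimator over `n_boot` parametric bootstrap
#' resamples perturbing `bx` and `by` by their standard errors.
#'
#' @param h a [harmonized_set] with at least 3 variants.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed RNG seed for the bootstrap (default 20230828); the caller's
#'   RNG state is preserved.
#' @export
mr_weighted_median <- function(h, n_boot = 1000, seed = 20230828) {
  d <- h_cols(h)
  L <- nrow(d)
  if (L < 3) stop("weighted median needs at least 3 variants")
  w <- d$bx^2 / d$sey^2
  beta <- weighted_median_point(d$by / d$bx, w)
  boots <- with_preserved_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      bx <- stats::rnorm(L, d$bx, d$sex)
      by <- stats::rnorm(L, d$by, d$sey)
      ok <- bx != 0
      weighted_median_point(by[ok] / bx[ok], bx[ok]^2 / d$sey[ok]^2)
    }, numeric(1))
  })
  new_mr_estimate("weighted_median", beta, stats::sd(boots), L,
                  extra = list(n_boot = n_boot, seed = seed))
}

#' Maximum-likelihood estimate
#'
#' Models `bx_i ~ N(xi_i, sex_i^2)` and `by_i ~ N(theta * xi_i, sey_i^2)`
#' with per-variant nuisance means `xi_i` for the true gene-exposure
#' effects. Profiling out `xi` gives the objective
#' `sum((by - theta*bx)^2 / (sey^2 + theta^2 * sex^2)) / 2`, minimized over
#' `theta`; the standard error comes from the observed information of the
#' profile likelihood (numerical second derivative).
#'
#' @param h a [harmonized_set].
#' @export
mr_max_likelihood <- function(h) {
  d <- h_cols(h)
  L <- nrow(d)
  if (L == 0) stop("no usable variants")
  if (L == 1) return(new_mr_estimate("max_likelihood", d$by / d$bx,
                                     d$sey / abs(d$bx), 1L))
  nll <- function(theta) 0.5 * sum((d$by - theta * d$bx)^2 /
                                     (d$sey^2 + theta^2 * d$sex^2))
  ivw <- mr_ivw(h, "fixed")
  span <- 10 * (abs(ivw$beta) + ivw$se) + 1
  opt <- stats::optimize(nll, lower = ivw$beta - span, upper = ivw$beta + span,
                         tol = 1e-12)
  theta <- opt$minimum
  step <- 1e-5 * (1 + abs(theta))
  info <- (nll(theta + step) - 2 * nll(theta) + nll(theta - step)) / step^2
  if (!is.finite(info) || info <= 0) {
    stop("maximum-likelihood estimation failed: non-positive observed information (",
         "theta = ", signif(theta, 6), ", info = ", signif(info, 6), ")")
  }
  new_mr_estimate("max_likelihood", theta, 1 / sqrt(info), L,
                  extra = list(objective = opt$objective))
}

# Huber psi and its derivative; k = Inf reduces to the l2 loss
huber_psi <- function(t, k) pmax(pmin(t, k), -k)
huber_dpsi <- function(t, k) as.numeric(abs(t) <= k)
# E[psi(Z) * Z] for standard normal Z (used to calibrate overdispersion)
huber_delta <- function(k) if (is.infinite(k)) 1 else 2 * stats::pnorm(k) - 1

#' Robust adjusted profile score (RAPS) estimate
#'
#' Solves the robustified profile-score estimating equation
#' `sum(psi(t_i(theta)) * dt_i/dtheta) = 0` with standardized residuals
#' `t_i = (by_i - theta*bx_i) / sqrt(sey_i^2 + theta^2*sex_i^2 + tau2)`,
#' where `psi` is the derivative of the chosen loss (Huber with constant
#' `tuning_k`, or squared error) and `tau2 >= 0` is an overdispersion
#' parameter profiled by matching `mean(psi(t) * t)` to its standard-normal
#' expectation when `overdispersion = TRUE`. The root is found by bracketed
#' search around the IVW estimate; the standard error is the sandwich
#' formula.
#'
#' @param h a [harmonized_set] with at least 3 variants.
#' @param loss `"huber"` (default) or `"l2"`.
#' @param tuning_k Huber tuning constant (default 1.345, the conventional
#'   95% Gaussian-efficiency choice).
#' @param overdispersion profile a nonnegative overdispersion variance.
#' @param seed used only to randomize bracket-expansion restarts if the
#'   initial bracket fails; the estimate itself is deterministic.
#' @export
mr_raps <- function(h, loss = c("huber", "l2"), tuning_k = 1.345,
                    overdispersion = FALSE, seed = NULL) {
  loss <- match.arg(loss)
  k <- if (loss == "l2") Inf else tuning_k
  d <- h_cols(h)
  L <- nrow(d)
  if (L < 3) stop("raps needs at least 3 variants")

  score <- function(theta, tau2) {
    sig2 <- d$sey^2 + theta^2 * d$sex^2 + tau2
    sig <- sqrt(sig2)
    t <- (d$by - theta * d$bx) / sig
    # -dt/dtheta = bx/sig + t * theta * sex^2 / sig^2
    sum(huber_psi(t, k) * (d$bx / sig + t * theta * d$sex^2 / sig2))
  }
  solve_theta <- function(tau2) {
    ivw <- mr_ivw(h, "fixed")
    width <- max(10 * ivw$se, 0.5 * (1 + abs(ivw$beta)))
    lo <- ivw$beta - width
    hi <- ivw$beta + width
    for (tries in 1:8) {
      flo <- score(lo, tau2); fhi <- score(hi, tau2)
      if (is.finite(flo) && is.finite(fhi) && sign(flo) != sign(fhi)) {
        return(stats::uniroot(score, c(lo, hi), tau2 = tau2, tol = 1e-12)$root)
      }
      jitter <- if (is.null(seed)) 0 else
        with_preserved_seed(seed + tries, stats::runif(1, -width, width))
      lo <- lo - width * 2^tries + jitter
      hi <- hi + width * 2^tries + jitter
    }
    stop("raps root not bracketed")
  }
  solve_tau2 <- function(theta) {
    gap <- function(tau2) {
      t <- (d$by - theta * d$bx) / sqrt(d$sey^2 + theta^2 * d$sex^2 + tau2)
      sum(huber_psi(t, k) * t) - L * huber_delta(k)
    }
    if (gap(0) <= 0) return(0)
    upper <- max(d$sey^2)
    for (tries in 1:60) {
      if (gap(upper) < 0) {
        return(stats::uniroot(gap, c(0, upper), tol = 1e-12)$root)
      }
      upper <- upper * 4
    }
    stop("raps overdispersion not bracketed")
  }

  tau2 <- 0
  theta <- solve_theta(tau2)
  if (overdispersion) {
    for (it in 1:50) {
      tau2_new <- solve_tau2(theta)
      theta_new <- solve_theta(tau2_new)
      done <- abs(theta_new - theta) < 1e-10 && abs(tau2_new - tau2) < 1e-12
      theta <- theta_new; tau2 <- tau2_new
      if (done) break
    }
  }

  sig2 <- d$sey^2 + theta^2 * d$sex^2 + tau2
  sig <- sqrt(sig2)
  t <- (d$by - theta * d$bx) / sig
  infl <- huber_psi(t, k) * (d$bx / sig + t * theta * d$sex^2 / sig2)
  B <- sum(infl^2)
  step <- 1e-6 * (1 + abs(theta))
  A <- (score(theta + step, tau2) - score(theta - step, tau2)) / (2 * step)
  if (!is.finite(A) || A == 0) stop("raps sandwich information is degenerate")
  new_mr_estimate("raps", theta, sqrt(B) / abs(A), L,
                  extra = list(tau2 = tau2, loss = loss, tuning_k = tuning_k))
}

#' Fit one MR method by name
#'
#' Dispatch helper used by the leave-one-out diagnostics and the pipeline.
#' @param h a [harmonized_set].
#' @param method one of `"ivw_fixed"`, `"ivw_random"`, `"egger"`,
#'   `"weighted_median"`, `"max_likelihood"`, `"raps"`.
#' @param ... passed to the method.
#' @export
mr_fit <- function(h, method, ...) {
  switch(method,
         ivw_fixed = mr_ivw(h, "fixed"),
         ivw_random = mr_ivw(h, "random"),
         egger = mr_egger(h),
         weighted_median = mr_weighted_median(h, ...),
         max_likelihood = mr_max_likelihood(h),
         raps = mr_raps(h, ...),
         stop("unknown method: ", method))
}

#' Run the full estimator panel
#'
#' Fits IVW (fixed and multiplicative random effects), MR-Egger, weighted
#' median, maximum likelihood and RAPS on one harmonized set and returns a
#' tidy table, one row per method, in the layout of a forest-plot figure.
#'
#' @param h a [harmonized_set].
#' @param n_boot,seed weighted-median bootstrap settings.
#' @param huber_k RAPS Huber constant.
#' @return data frame with columns `exposure`, `outcome`, `method`, `n_snp`,
#'   `beta`, `se`, `ci_low`, `ci_high`, `or`, `or_low`, `or_high`, `pval`.
#' @export
mr_all_methods <- function(h, n_boot = 1000, seed = 20230828, huber_k = 1.345) {
  fitters <- list(
    function() mr_ivw(h, "fixed"),
    function() mr_ivw(h, "random"),
    function() mr_egger(h),
    function() mr_weighted_median(h, n_boot = n_boot, seed = seed),
    function() mr_max_likelihood(h),
    function() mr_raps(h, loss = "huber", tuning_k = huber_k,
                       overdispersion = TRUE)
  )
  skipped <- character(0)
  fits <- list()
  for (f in fitters) {
    fit <- tryCatch(f(), error = function(e) conditionMessage(e))
    if (inherits(fit, "mr_estimate")) fits[[length(fits) + 1]] <- fit
    else skipped <- c(skipped, fit)
  }
  if (length(skipped) > 0) {
    message("method(s) skipped: ", paste(skipped, collapse = " | "))
  }
  out <- do.call(rbind, lapply(fits, as.data.frame))
  cbind(data.frame(exposure = attr(h, "exposure"), outcome = attr(h, "outcome"),
                   stringsAsFactors = FALSE),
        out)
}
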