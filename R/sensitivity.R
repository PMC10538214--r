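#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum(w_i * (ratio_i - beta_ivw)^2)` with weights `w_i = bx^2/sey^2`
#' and the fixed-effect IVW estimate as center; the p-value comes from a
#' chi-square distribution with `L - 1` degrees of freedom, and
#' `I2 = max(0, (Q - df)/Q) * 100` (0 when Q = 0).
#'
#' @param h a [harmonized_set].
#' @return A `heterogeneity_report` list: `q`, `df`, `i2`, `p`,
#'   `chosen_model`, plus `NA` Egger-intercept slots to be filled by
#'   [egger_intercept_test()] / [sensitivity_report()]. A single-variant set
#'   yields `NA` fields with a warning (heterogeneity is undefined).
#' @export
cochran_q <- function(h) {
  d <- h_cols(h)
  L <- nrow(d)
  if (L < 2) {
    warning("heterogeneity undefined for a single variant")
    rep <- list(q = NA_real_, df = 0L, i2 = NA_real_, p = NA_real_,
                chosen_model = "fixed")
  } else {
    w <- d$bx^2 / d$sey^2
    ratio <- d$by / d$bx
    beta <- sum(w * ratio) / sum(w)
    q <- sum(w * (ratio - beta)^2)
    df <- L - 1L
    p <- stats::pchisq(q, df, lower.tail = FALSE)
    i2 <- if (q == 0) 0 else max(0, (q - df) / q) * 100
    rep <- list(q = q, df = df, i2 = i2, p = p,
                chosen_model = if (!is.na(p) && p < 0.05) "multiplicative_random" else "fixed")
  }
  structure(c(rep, list(egger_intercept = NA_real_,
                        intercept_ci = c(NA_real_, NA_real_),
                        intercept_p = NA_real_)),
            class = "heterogeneity_report")
}

#' Choose the IVW effects model from heterogeneity
#'
#' Multiplicative random effects when the Q-test p-value is strictly below
#' 0.05, otherwise fixed effects.
#'
#' @param rep a `heterogeneity_report` from [cochran_q()].
#' @return `"multiplicative_random"` or `"fixed"`.
#' @export
choose_effects_model <- function(rep) {
  if (!is.na(rep$p) && rep$p < 0.05) "multiplicative_random" else "fixed"
}

#' Egger-intercept test for directional pleiotropy
#'
#' The intercept of the MR-Egger regression estimates the average
#' pleiotropic effect across variants; a non-zero intercept (p < 0.05)
#' flags directional pleiotropy.
#'
#' @param h a [harmonized_set] with at least 3 variants.
#' @return list with `intercept`, `se`, `ci_low`, `ci_high`, `p`,
#'   `directional` (logical flag).
#' @export
egger_intercept_test <- function(h) {
  fit <- mr_egger(h)
  e <- fit$extra
  list(intercept = e$intercept, se = e$intercept_se,
       ci_low = e$intercept_ci_low, ci_high = e$intercept_ci_high,
       p = e$intercept_p, directional = e$intercept_p < 0.05)
}

#' Combined heterogeneity and pleiotropy report
#'
#' [cochran_q()] plus the Egger intercept in one report, mirroring the
#' columns of a standard MR sensitivity table.
#' @param h a [harmonized_set].
#' @export
sensitivity_report <- function(h) {
  rep <- cochran_q(h)
  if (nrow(h) >= 3) {
    eg <- egger_intercept_test(h)
    rep$egger_intercept <- eg$intercept
    rep$intercept_ci <- c(eg$ci_low, eg$ci_high)
    rep$intercept_p <- eg$p
  }
  rep
}

#' @export
print.heterogeneity_report <- function(x, ...) {
  cat(sprintf("Cochran's Q = %.3f (df %d), I2 = %.2f%%, p = %.3g -> %s effects\n",
              x$q, x$df, x$i2, x$p, x$chosen_model))
  if (!is.na(x$egger_intercept)) {
    cat(sprintf("Egger intercept = %.4f (95%% CI %.4f, %.4f), p = %.3g\n",
                x$egger_intercept, x$intercept_ci[1], x$intercept_ci[2],
                x$intercept_p))
  }
  invisible(x)
}

#' Leave-one-out influence analysis
#'
#' Refits the chosen estimator `L` times, dropping one variant each time.
#' A removal is flagged influential when the leave-one-out beta changes
#' sign relative to the full-set estimate or its 95% CI excludes the
#' full-set beta.
#'
#' @param h a [harmonized_set] with at least 3 variants.
#' @param method estimator name passed to [mr_fit()] (default fixed IVW).
#' @param ... passed to the estimator.
#' @return data frame: `variant_id`, `beta`, `se`, `ci_low`, `ci_high`,
#'   `influential`; the full-set estimate is attached as attribute `full`.
#' @export
leave_one_out <- function(h, method = "ivw_fixed", ...) {
  d <- as.data.frame(h)
  L <- nrow(d)
  if (L < 3) stop("leave-one-out needs at least 3 variants")
  full <- mr_fit(h, method, ...)
  rows <- lapply(seq_len(L), function(i) {
    sub <- harmonized_set(d$variant_id[-i], d$bx[-i], d$sex[-i],
                          d$by[-i], d$sey[-i],
                          exposure = attr(h, "exposure"),
                          outcome = attr(h, "outcome"))
    est <- mr_fit(sub, method, ...)
    data.frame(variant_id = d$variant_id[i], beta = est$beta, se = est$se,
               ci_low = est$ci_low, ci_high = est$ci_high,
               influential = sign(est$beta) != sign(full$beta) ||
                 full$beta < est$ci_low || full$beta > est$ci_high,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "full") <- full
  out
}
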