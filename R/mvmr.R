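#' Build a joint harmonized table for multivariable MR
#'
#' Orients every exposure's coefficients to the outcome's effect allele
#' (so all columns share one orientation) and intersects on variants present
#' in the outcome and in every exposure after harmonization drops.
#'
#' @param exposures named list of [sumstats] (primary exposure first,
#'   mediators after).
#' @param outcome a [sumstats].
#' @param palindromic_eaf_window passed to [harmonize()].
#' @return An `mvmr_set` data frame: `variant_id`, one `bx_<name>` and
#'   `sex_<name>` pair per exposure, and the outcome's `by`, `sey`.
#' @export
harmonize_mvmr <- function(exposures, outcome, palindromic_eaf_window = 0.08) {
  stopifnot(is.list(exposures), length(exposures) >= 1)
  nm <- names(exposures)
  if (is.null(nm) || any(!nzchar(nm))) stop("exposures must be a named list")
  # harmonize(outcome, exp) re-orients the *second* argument, leaving the
  # outcome's coefficients (bx slot) untouched: one shared orientation
  hs <- lapply(exposures, function(ex)
    harmonize(outcome, ex, palindromic_eaf_window = palindromic_eaf_window))
  ids <- Reduce(intersect, lapply(hs, function(h) h$variant_id))
  if (length(ids) == 0) stop("no variants shared by all exposures and the outcome")
  base <- hs[[1]][match(ids, hs[[1]]$variant_id), , drop = FALSE]
  out <- data.frame(variant_id = ids, stringsAsFactors = FALSE)
  for (k in seq_along(hs)) {
    hk <- hs[[k]][match(ids, hs[[k]]$variant_id), , drop = FALSE]
    out[[paste0("bx_", nm[k])]] <- hk$by
    out[[paste0("sex_", nm[k])]] <- hk$sey
  }
  out$by <- base$bx
  out$sey <- base$sex
  structure(out, class = c("mvmr_set", "data.frame"),
            exposures = nm, outcome = attr(outcome, "trait") %||% "outcome")
}

#' Multivariable MR by weighted multiple regression
#'
#' Regresses the gene-outcome coefficients on all gene-exposure coefficient
#' columns jointly, without intercept and with weights `1/sey^2`. Each
#' coefficient is the direct effect of that exposure on the outcome,
#' adjusted for the others. Standard errors use multiplicative
#' overdispersion with the residual-variance factor bounded below by 1.
#' A per-exposure conditional F diagnostic is reported: the weighted
#' residual variation of that exposure's coefficients after regression on
#' the other exposure columns, standardized by its standard errors.
#'
#' With `correction = "eiv"` the normal equations are corrected for the
#' sampling error of the gene-exposure coefficients (method-of-moments
#' errors-in-variables correction: `sex^2` terms are subtracted from the
#' weighted cross-product matrix), removing the attenuation of direct
#' effects that arises when an exposure's conditional instrument strength is
#' modest; standard errors are then the larger of a delete-one jackknife
#' (which captures the extra variability of the corrected design) and the
#' model-based standard error with the overdispersion floor.
#'
#' @param m an `mvmr_set` from [harmonize_mvmr()] with at least
#'   `exposures + 2` rows.
#' @param correction `"none"` for the conventional weighted regression
#'   (default) or `"eiv"` for the errors-in-variables-corrected fit.
#' @return An `mvmr_result` list: `exposures`, `betas`, `ses`, `pvals`,
#'   `ci_low`, `ci_high`, `n_snp`, `conditional_f`, `sigma2`.
#' @export
mr_mvmr <- function(m, correction = c("none", "eiv")) {
  correction <- match.arg(correction)
  nm <- attr(m, "exposures")
  p <- length(nm)
  L <- nrow(m)
  if (L < p + 2) stop("multivariable MR needs at least exposures + 2 variants")
  X <- as.matrix(m[, paste0("bx_", nm), drop = FALSE])
  colnames(X) <- nm
  SX2 <- as.matrix(m[, paste0("sex_", nm), drop = FALSE])^2
  w <- 1 / m$sey^2
  # rank check with a named diagnosis of the collinear pair
  qrx <- qr(sqrt(w) * X)
  if (qrx$rank < p) {
    cors <- stats::cor(X)
    pair <- which(abs(cors) > 1 - 1e-8 & upper.tri(cors), arr.ind = TRUE)
    detail <- if (nrow(pair) > 0)
      paste0(" (collinear pair: ", nm[pair[1, 1]], ", ", nm[pair[1, 2]], ")")
    else ""
    stop("rank-deficient multivariable design", detail)
  }
  if (correction == "eiv") {
    A <- t(X * w) %*% X - diag(colSums(SX2 * w), p)
    if (any(eigen(A, symmetric = TRUE, only.values = TRUE)$values <= 0)) {
      stop("errors-in-variables correction failed: corrected design not ",
           "positive definite (instruments too weak)")
    }
    cvec <- drop(t(X * w) %*% m$by)
    betas <- drop(solve(A, cvec))
    names(betas) <- nm
    res <- drop(m$by - X %*% betas)
    sigma2 <- sum(w * res^2) / (L - p)
    # delete-one jackknife via rank-one downdates of the normal equations
    jk <- vapply(seq_len(L), function(j) {
      Aj <- A - w[j] * (tcrossprod(X[j, ]) - diag(SX2[j, ], p))
      solve(Aj, cvec - w[j] * X[j, ] * m$by[j])
    }, numeric(p))
    jk <- matrix(jk, nrow = p)
    se_jack <- sqrt((L - 1) / L * rowSums((jk - rowMeans(jk))^2))
    se_model <- sqrt(diag(solve(A)) * max(1, sigma2))
    ses <- pmax(se_jack, se_model)
    names(ses) <- nm
  } else {
    fit <- wls_fit(X, m$by, w)
    sigma2 <- fit$rss_w / (L - p)
    scale <- max(1, sigma2)
    ses <- sqrt(diag(fit$XtWX_inv) * scale)
    betas <- fit$coefs
  }
  cond_f <- vapply(seq_len(p), function(j) {
    sexj <- m[[paste0("sex_", nm[j])]]
    resj <- if (p == 1) X[, j] else {
      fj <- wls_fit(X[, -j, drop = FALSE], X[, j], w)
      fj$res
    }
    sum(resj^2 / sexj^2) / (L - p + 1)
  }, numeric(1))
  structure(list(exposures = nm, betas = stats::setNames(betas, nm),
                 ses = stats::setNames(ses, nm),
                 pvals = stats::setNames(norm_pval(betas / ses), nm),
                 ci_low = stats::setNames(betas - Z95 * ses, nm),
                 ci_high = stats::setNames(betas + Z95 * ses, nm),
                 n_snp = L, conditional_f = stats::setNames(cond_f, nm),
                 sigma2 = sigma2, correction = correction),
            class = "mvmr_result")
}

#' @export
print.mvmr_result <- function(x, ...) {
  cat("Multivariable MR on", x$n_snp, "variants\n")
  print(data.frame(exposure = x$exposures, beta = x$betas, se = x$ses,
                   or = exp(x$betas), pval = x$pvals,
                   conditional_F = x$conditional_f, row.names = NULL))
  invisible(x)
}
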