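#' Product-method indirect effect
#'
#' `indirect = beta1 * beta2` with the delta-method (Sobel) standard error
#' `sqrt(beta2^2 * se1^2 + beta1^2 * se2^2)` and a symmetric normal 95% CI.
#'
#' @param beta1,se1 exposure-to-mediator effect and standard error.
#' @param beta2,se2 mediator-to-outcome (adjusted) effect and standard error.
#' @return list with `indirect`, `se`, `ci_low`, `ci_high`.
#' @export
product_indirect <- function(beta1, se1, beta2, se2) {
  ind <- beta1 * beta2
  se <- sqrt(beta2^2 * se1^2 + beta1^2 * se2^2)
  list(indirect = ind, se = se, ci_low = ind - Z95 * se, ci_high = ind + Z95 * se)
}

#' Proportion of the effect mediated
#'
#' `E% = 100 * sum(indirects) / (direct_beta3 + sum(indirects))`, where
#' `direct_beta3` is the direct (adjusted) effect of the exposure on the
#' outcome and `indirects` the product-method indirect effects through each
#' mediator. Values outside \[0, 100\] arise from opposite-sign paths and
#' are returned as computed with the attribute `inconsistent = TRUE`.
#'
#' @param direct_beta3 direct effect of the exposure on the outcome.
#' @param indirects numeric vector of per-mediator indirect effects.
#' @return percentage (numeric scalar) with attribute `inconsistent`.
#' @export
proportion_mediated <- function(direct_beta3, indirects) {
  denom <- direct_beta3 + sum(indirects)
  if (denom == 0) stop("proportion mediated undefined: zero denominator")
  pct <- 100 * sum(indirects) / denom
  attr(pct, "inconsistent") <- pct < 0 || pct > 100
  pct
}

# univariable IVW with the effects model chosen from Cochran's Q
ivw_chosen <- function(h) {
  het <- cochran_q(h)
  est <- mr_ivw(h, if (choose_effects_model(het) == "multiplicative_random")
    "random" else "fixed")
  est$extra$heterogeneity <- het
  est
}

# restrict a sumstats table to a set of variant ids, keeping class/attrs
subset_ids <- function(stats, ids) {
  out <- stats[stats$variant_id %in% ids, , drop = FALSE]
  attr(out, "trait") <- attr(stats, "trait")
  class(out) <- class(stats)
  out
}

#' Two-step mediation MR
#'
#' Runs the full mediation decomposition of an exposure -> mediator(s) ->
#' outcome design on GWAS summary statistics:
#'
#' 1. instrument selection per trait, with mutual exclusion of variants
#'    genome-wide significant for both the exposure and a mediator;
#' 2. total effect (exposure -> outcome) and step-1 effects
#'    (exposure -> each mediator, `beta1`) by univariable IVW with the
#'    effects model chosen from Cochran's Q;
#' 3. step-2 effects by multivariable MR: each mediator's direct effect on
#'    the outcome adjusted for the exposure (`beta2`), singly and jointly,
#'    giving the exposure's direct effect `beta3`;
#' 4. product-method indirect effects `beta1 * beta2`, the proportion
#'    mediated `E% = 100 * sum(beta1*beta2) / (beta3 + sum(beta1*beta2))`
#'    per mediator and combined, plus a diagnostic ratio against the
#'    independently estimated total effect.
#'
#' @param exposure a [sumstats] for the exposure.
#' @param mediators named list of [sumstats] for candidate mediators.
#' @param outcome a [sumstats] for the outcome.
#' @param cfg a [selection_config].
#' @param palindromic_eaf_window passed to [harmonize()].
#' @param mvmr_correction multivariable-MR flavor for step 2, see
#'   [mr_mvmr()]; the default `"eiv"` corrects the attenuation of direct
#'   effects caused by sampling error in the gene-exposure coefficients,
#'   which matters whenever an exposure's conditional instrument strength
#'   is modest (the binary-exposure case here).
#' @return A `mediation_result` list: `total` (`mr_estimate`),
#'   `direct_beta`/`direct_se` (joint model `beta3`), `mediators` (per-
#'   mediator table with `beta1`, `beta2`, `indirect` and its CI,
#'   `proportion_pct`, flags), `combined_indirect`, `combined_se`,
#'   `proportion_pct` (+`inconsistent` attribute), `proportion_vs_total`,
#'   and the underlying fits in `fits`.
#' @export
run_two_step <- function(exposure, mediators, outcome,
                         cfg = selection_config(),
                         palindromic_eaf_window = 0.08,
                         mvmr_correction = c("eiv", "none")) {
  mvmr_correction <- match.arg(mvmr_correction)
  stopifnot(is.list(mediators), length(mediators) >= 1)
  med_names <- names(mediators)
  if (is.null(med_names) || any(!nzchar(med_names)))
    stop("mediators must be a named list")
  stage <- function(label, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", label, "': ", conditionMessage(e), call. = FALSE))
  }

  # mutual exclusion: variants genome-wide significant for both the exposure
  # and any mediator instrument neither trait
  sig_exp <- exposure$variant_id[exposure$pval < cfg$p_threshold]
  sig_med <- lapply(mediators, function(m) m$variant_id[m$pval < cfg$p_threshold])
  shared <- lapply(sig_med, intersect, x = sig_exp)
  cfg_exp <- cfg
  cfg_exp$exposure_specific_exclusions <-
    union(cfg$exposure_specific_exclusions, unique(unlist(shared)))

  instr_exp <- stage("exposure instrument selection",
                     select_instruments(exposure, cfg_exp))
  strength_exp <- instrument_strength(instr_exp)
  instr_med <- lapply(med_names, function(nm) {
    cfg_m <- cfg
    cfg_m$exposure_specific_exclusions <-
      union(cfg$exposure_specific_exclusions, shared[[nm]])
    stage(paste0("instrument selection for ", nm),
          select_instruments(mediators[[nm]], cfg_m))
  })
  names(instr_med) <- med_names

  exp_sel <- subset_ids(exposure, instr_exp$variant_id)

  # total effect: exposure -> outcome
  h_total <- stage("total-effect harmonization",
                   harmonize(exp_sel, outcome, palindromic_eaf_window))
  total <- stage("total-effect estimation", ivw_chosen(h_total))

  # step 1: exposure -> mediator, and univariable mediator -> outcome
  step1 <- list(); med_on_outcome <- list()
  for (nm in med_names) {
    h1 <- stage(paste0("harmonization exposure -> ", nm),
                harmonize(exp_sel, mediators[[nm]], palindromic_eaf_window))
    step1[[nm]] <- stage(paste0("estimation exposure -> ", nm), ivw_chosen(h1))
    med_sel <- subset_ids(mediators[[nm]], instr_med[[nm]]$variant_id)
    h2 <- stage(paste0("harmonization ", nm, " -> outcome"),
                harmonize(med_sel, outcome, palindromic_eaf_window))
    med_on_outcome[[nm]] <- stage(paste0("estimation ", nm, " -> outcome"),
                                  ivw_chosen(h2))
  }

  # step 2: multivariable models, each mediator singly then all jointly
  exposure_name <- attr(exposure, "trait") %||% "exposure"
  mv_single <- list()
  for (nm in med_names) {
    ids <- union(instr_exp$variant_id, instr_med[[nm]]$variant_id)
    m <- stage(paste0("multivariable harmonization (", nm, ")"),
               harmonize_mvmr(stats::setNames(
                 list(subset_ids(exposure, ids), subset_ids(mediators[[nm]], ids)),
                 c(exposure_name, nm)), outcome, palindromic_eaf_window))
    mv_single[[nm]] <- stage(paste0("multivariable MR (", nm, ")"),
                             mr_mvmr(m, correction = mvmr_correction))
  }
  ids_joint <- Reduce(union, c(list(instr_exp$variant_id),
                               lapply(instr_med, function(x) x$variant_id)))
  m_joint <- stage("joint multivariable harmonization",
                   harmonize_mvmr(stats::setNames(
                     c(list(subset_ids(exposure, ids_joint)),
                       lapply(mediators, subset_ids, ids = ids_joint)),
                     c(exposure_name, med_names)), outcome,
                     palindromic_eaf_window))
  mv_joint <- stage("joint multivariable MR",
                    mr_mvmr(m_joint, correction = mvmr_correction))

  # decomposition
  rows <- lapply(med_names, function(nm) {
    b1 <- step1[[nm]]
    b2 <- mv_single[[nm]]
    ind <- product_indirect(b1$beta, b1$se, b2$betas[[nm]], b2$ses[[nm]])
    b3 <- b2$betas[[exposure_name]]
    pct <- proportion_mediated(b3, ind$indirect)
    data.frame(mediator = nm, n_snp = b2$n_snp,
               beta1 = b1$beta, se1 = b1$se,
               beta2 = b2$betas[[nm]], se2 = b2$ses[[nm]],
               direct_beta3 = b3, direct_se3 = b2$ses[[exposure_name]],
               indirect = ind$indirect, indirect_se = ind$se,
               indirect_ci_low = ind$ci_low, indirect_ci_high = ind$ci_high,
               proportion_pct = as.numeric(pct),
               inconsistent = attr(pct, "inconsistent"),
               non_mediating = ind$ci_low <= 0 && ind$ci_high >= 0,
               stringsAsFactors = FALSE)
  })
  med_tab <- do.call(rbind, rows)

  ind_joint <- mapply(function(nm) {
    b1 <- step1[[nm]]
    product_indirect(b1$beta, b1$se, mv_joint$betas[[nm]], mv_joint$ses[[nm]])
  }, med_names, SIMPLIFY = FALSE)
  combined_indirect <- sum(vapply(ind_joint, `[[`, numeric(1), "indirect"))
  combined_se <- sqrt(sum(vapply(ind_joint, `[[`, numeric(1), "se")^2))
  direct_beta <- mv_joint$betas[[exposure_name]]
  pct_combined <- proportion_mediated(direct_beta, vapply(
    ind_joint, `[[`, numeric(1), "indirect"))

  structure(list(
    total = total,
    total_beta = total$beta,
    direct_beta = direct_beta,
    direct_se = mv_joint$ses[[exposure_name]],
    mediators = med_tab,
    combined_indirect = combined_indirect,
    combined_se = combined_se,
    proportion_pct = pct_combined,
    # diagnostic: same numerator over the independently estimated total
    proportion_vs_total = 100 * combined_indirect / total$beta,
    instrument_strength = strength_exp,
    fits = list(step1 = step1, med_on_outcome = med_on_outcome,
                mv_single = mv_single, mv_joint = mv_joint,
                instruments = c(list(exposure = instr_exp), instr_med))),
    class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat("Two-step mediation MR\n")
  cat(sprintf("  total effect:  beta = %.4f (se %.4f), OR = %.3f\n",
              x$total$beta, x$total$se, x$total$or_value))
  cat(sprintf("  direct effect: beta = %.4f (se %.4f) [joint model]\n",
              x$direct_beta, x$direct_se))
  cat(sprintf("  combined indirect = %.4f, proportion mediated = %.1f%%%s\n",
              x$combined_indirect, as.numeric(x$proportion_pct),
              if (isTRUE(attr(x$proportion_pct, "inconsistent")))
                " [inconsistent]" else ""))
  print(x$mediators[, c("mediator", "n_snp", "beta1", "beta2", "indirect",
                        "proportion_pct", "non_mediating")], row.names = FALSE)
  invisible(x)
}
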