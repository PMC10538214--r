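#' Configuration for the synthetic summary-statistics generator
#'
#' Defines a three-cohort exposure -> mediator(s) -> outcome causal model
#' with known truths, emulating the structure of a binary-trait exposure
#' GWAS (~217k participants), continuous mediator GWASs (~404k) and a
#' binary-outcome GWAS (~172k): genome-wide-significant instruments per
#' trait, log-odds/SD-unit effect scales, and standard errors shrinking as
#' `1/sqrt(2*maf*(1-maf)*N)`.
#'
#' @param n_snp_exposure number of candidate exposure instruments.
#' @param n_snp_mediator named integer vector: candidate instruments per
#'   mediator (names become trait labels).
#' @param maf_range minor-allele frequency range, within (0, 0.5\].
#' @param cohort_n list with `exposure`, `mediator` (scalar or per-mediator
#'   vector) and `outcome` sample sizes.
#' @param beta_x_scale SD of the true per-SNP exposure effects (log-odds).
#' @param beta_m_scale SD of each mediator's own per-SNP instrument effects.
#' @param theta_direct true direct effect of the exposure on the outcome.
#' @param beta1 true exposure-to-mediator effects (one per mediator).
#' @param beta2 true mediator-to-outcome effects (one per mediator).
#' @param pleiotropy list `type` (`"none"`, `"balanced"`, `"directional"`)
#'   and `scale`: per-SNP direct outcome effects drawn `N(0, scale)` when
#'   balanced and `N(scale, scale)` when directional.
#' @param palindromic_frac fraction of variants assigned strand-ambiguous
#'   (A/T or C/G) allele pairs.
#' @param p_threshold the selection threshold the scenario is designed for
#'   (recorded so pipelines analyse the scenario under its own conditions).
#' @param exposure_name,outcome_name trait labels.
#' @param seed root seed; per-trait noise uses child streams derived from it.
#' @export
simulation_config <- function(n_snp_exposure = 12,
                              n_snp_mediator = c(mediator1 = 146,
                                                 mediator2 = 178,
                                                 mediator3 = 14),
                              maf_range = c(0.10, 0.50),
                              cohort_n = list(exposure = 216752,
                                              mediator = 403943,
                                              outcome = 171875),
                              beta_x_scale = 0.05,
                              beta_m_scale = 0.04,
                              theta_direct = 0.25,
                              beta1 = c(0.04, 0.05, 0.03),
                              beta2 = c(0.35, 0.40, 0.30),
                              pleiotropy = list(type = "none", scale = 0),
                              palindromic_frac = 0,
                              p_threshold = 5e-8,
                              exposure_name = "exposure",
                              outcome_name = "outcome",
                              seed = 20230828) {
  k <- length(n_snp_mediator)
  if (is.null(names(n_snp_mediator)))
    names(n_snp_mediator) <- paste0("mediator", seq_len(k))
  stopifnot(n_snp_exposure > 0, all(n_snp_mediator > 0),
            length(beta1) == k, length(beta2) == k,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            pleiotropy$type %in% c("none", "balanced", "directional"))
  med_n <- cohort_n$mediator
  if (length(med_n) == 1) med_n <- rep(med_n, k)
  stopifnot(length(med_n) == k, cohort_n$exposure > 0, all(med_n > 0),
            cohort_n$outcome > 0)
  cohort_n$mediator <- med_n
  structure(list(n_snp_exposure = n_snp_exposure,
                 n_snp_mediator = n_snp_mediator, maf_range = maf_range,
                 cohort_n = cohort_n, beta_x_scale = beta_x_scale,
                 beta_m_scale = beta_m_scale, theta_direct = theta_direct,
                 beta1 = beta1, beta2 = beta2, pleiotropy = pleiotropy,
                 palindromic_frac = palindromic_frac,
                 p_threshold = p_threshold,
                 exposure_name = exposure_name, outcome_name = outcome_name,
                 seed = seed),
            class = "simulation_config")
}

# the eight non-palindromic ordered allele pairs
NON_PALINDROMIC_PAIRS <- matrix(c("A", "C", "A", "G", "C", "A", "C", "T",
                                  "G", "A", "G", "T", "T", "C", "T", "G"),
                                ncol = 2, byrow = TRUE)
PALINDROMIC_PAIRS <- matrix(c("A", "T", "T", "A", "C", "G", "G", "C"),
                            ncol = 2, byrow = TRUE)

#' Simulate three-cohort GWAS summary statistics with known truths
#'
#' For every variant: `maf ~ Uniform(maf_range)`; true exposure effects
#' `xi ~ N(0, beta_x_scale^2)` on the exposure block, mediator-own effects
#' `zeta ~ N(0, beta_m_scale^2)` on each mediator block; per-trait standard
#' error `1/sqrt(2*maf*(1-maf)*N)`; observed betas are the trait's true
#' effects plus independent normal noise at that standard error, with
#' two-sided normal p-values. Mediator truth is `beta1_k * xi` plus its own
#' instruments; outcome truth is `theta_direct * xi + sum_k beta2_k *
#' (mediator truth) + pleiotropy`. Every trait reports all variants, so any
#' pair of tables can be harmonized.
#'
#' @param cfg a [simulation_config].
#' @return named list of [sumstats] (exposure, mediators, outcome) with a
#'   `truth` attribute recording the config, child seeds, per-variant true
#'   effects and the implied total effect.
#' @export
simulate_sumstats <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  k <- length(cfg$n_snp_mediator)
  med_names <- names(cfg$n_snp_mediator)
  M <- cfg$n_snp_exposure + sum(cfg$n_snp_mediator)
  blocks <- split(seq_len(M),
                  rep(c("exposure", med_names),
                      c(cfg$n_snp_exposure, cfg$n_snp_mediator)))

  with_preserved_seed(cfg$seed, {
    # shared genetics from the root stream
    maf <- stats::runif(M, cfg$maf_range[1], cfg$maf_range[2])
    eaf <- ifelse(stats::runif(M) < 0.5, maf, 1 - maf)
    pal <- stats::runif(M) < cfg$palindromic_frac
    pair_idx <- sample.int(nrow(NON_PALINDROMIC_PAIRS), M, replace = TRUE)
    alleles <- NON_PALINDROMIC_PAIRS[pair_idx, , drop = FALSE]
    if (any(pal)) {
      alleles[pal, ] <- PALINDROMIC_PAIRS[
        sample.int(nrow(PALINDROMIC_PAIRS), sum(pal), replace = TRUE), ,
        drop = FALSE]
    }
    # chromosomes cycle 1..22 with >10 Mb spacing so variants are
    # independent under the default distance-pruning window
    chrom <- as.character(((seq_len(M) - 1) %% 22) + 1)
    pos <- ceiling(seq_len(M) / 22) * 12e6

    xi <- numeric(M)
    xi[blocks$exposure] <- stats::rnorm(cfg$n_snp_exposure, 0, cfg$beta_x_scale)
    zeta <- matrix(0, M, k)
    for (j in seq_len(k)) {
      zeta[blocks[[med_names[j]]], j] <-
        stats::rnorm(cfg$n_snp_mediator[j], 0, cfg$beta_m_scale)
    }
    med_truth <- vapply(seq_len(k), function(j) cfg$beta1[j] * xi + zeta[, j],
                        numeric(M))
    # pleiotropy is expressed relative to the trait-increasing allele of
    # each variant's parent trait: the orientation Egger regression uses
    # after sign-fixing, so a directional mean is detectable as a non-zero
    # intercept rather than cancelling across alleles
    orient <- sign(xi + rowSums(zeta))
    orient[orient == 0] <- 1
    alpha <- switch(cfg$pleiotropy$type,
                    none = numeric(M),
                    balanced = stats::rnorm(M, 0, cfg$pleiotropy$scale),
                    directional = stats::rnorm(M, cfg$pleiotropy$scale,
                                               cfg$pleiotropy$scale))
    out_truth <- cfg$theta_direct * xi +
      drop(med_truth %*% cfg$beta2) + orient * alpha

    child <- sample.int(.Machine$integer.max - 1, k + 2)

    make_trait <- function(truth, n, trait, child_seed) {
      se <- 1 / sqrt(2 * maf * (1 - maf) * n)
      beta <- with_preserved_seed(child_seed, truth + stats::rnorm(M, 0, se))
      sumstats(data.frame(
        variant_id = sprintf("rs%05d", seq_len(M)), chrom = chrom, pos = pos,
        effect_allele = alleles[, 1], other_allele = alleles[, 2],
        eaf = eaf, beta = beta, se = se, pval = norm_pval(beta / se), n = n,
        stringsAsFactors = FALSE), trait = trait)
    }

    out <- c(
      stats::setNames(list(make_trait(xi, cfg$cohort_n$exposure,
                                      cfg$exposure_name, child[1])),
                      cfg$exposure_name),
      stats::setNames(lapply(seq_len(k), function(j)
        make_trait(med_truth[, j], cfg$cohort_n$mediator[j], med_names[j],
                   child[1 + j])), med_names),
      stats::setNames(list(make_trait(out_truth, cfg$cohort_n$outcome,
                                      cfg$outcome_name, child[k + 2])),
                      cfg$outcome_name))
    attr(out, "truth") <- list(
      config = cfg, child_seeds = child, xi = xi, zeta = zeta,
      mediator_truth = med_truth, outcome_truth = out_truth,
      total_effect = cfg$theta_direct + sum(cfg$beta1 * cfg$beta2),
      proportion_pct = 100 * sum(cfg$beta1 * cfg$beta2) /
        (cfg$theta_direct + sum(cfg$beta1 * cfg$beta2)))
    out
  })
}

#' Named library of simulation scenarios
#'
#' * `paper_shaped`: 12 exposure instruments, three mediators with positive
#'   `beta1` and `beta2` effects, a modest positive direct effect
#'   (proportion mediated about 15%).
#' * `null`: all causal paths zero, no pleiotropy (calibration runs).
#' * `pleiotropic`: `paper_shaped` plus directional pleiotropy.
#' * `weak_instrument`: many small exposure effects selected at a relaxed
#'   threshold (1e-4, recorded in the config): genome-wide significance
#'   forces every selected variant to a per-variant F above ~30, so a
#'   per-set F near the weak-instrument boundary of 10 is only reachable
#'   with a liberal threshold.
#'
#' @param seed root seed applied to every scenario.
#' @return named list of [simulation_config]s.
#' @export
scenario_library <- function(seed = 20230828) {
  list(
    paper_shaped = simulation_config(seed = seed),
    null = simulation_config(theta_direct = 0, beta1 = c(0, 0, 0),
                             beta2 = c(0, 0, 0), seed = seed),
    pleiotropic = simulation_config(
      pleiotropy = list(type = "directional", scale = 0.01), seed = seed),
    weak_instrument = simulation_config(n_snp_exposure = 200,
                                        beta_x_scale = 0.006,
                                        p_threshold = 1e-4, seed = seed)
  )
}

#' Write a simulated dataset as summary-statistics files plus manifest
#'
#' Emits one tab-separated file per trait in the dialect [read_sumstats()]
#' reads, and a `manifest.json` recording every truth parameter and child
#' seed for recovery tests.
#'
#' @param sims output of [simulate_sumstats()].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths.
#' @export
write_simulation <- function(sims, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(names(sims), function(nm) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    write_sumstats(sims[[nm]], p)
    p
  }, character(1))
  truth <- attr(sims, "truth")
  manifest <- list(
    traits = names(sims), files = as.list(paths),
    config = unclass(truth$config), child_seeds = truth$child_seeds,
    total_effect = truth$total_effect,
    proportion_pct = truth$proportion_pct)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
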