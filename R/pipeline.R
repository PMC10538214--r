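#' Read and validate a run configuration
#'
#' YAML or JSON (by extension). Expected layout:
#' ```
#' exposure: {name: ..., path: ...}            # column_map optional
#' mediators: [{name: ..., path: ...}, ...]
#' outcome: {name: ..., path: ...}
#' selection: {p_threshold: 5e-8, window_kb: 10000, r2_threshold: 0.001,
#'             exclusion_file: ...}            # all optional
#' estimators: {n_boot: 1000, huber_k: 1.345}  # optional
#' seed: 1
#' ```
#' Every referenced path must exist at validation time; validation happens
#' before any computation.
#'
#' @param path configuration file path.
#' @return validated config list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  for (slot in c("exposure", "outcome")) {
    if (is.null(cfg[[slot]]$path)) stop("config: missing ", slot, "$path")
    if (!file.exists(cfg[[slot]]$path))
      stop("config: ", slot, " file not found: ", cfg[[slot]]$path)
  }
  if (is.null(cfg$mediators) || length(cfg$mediators) == 0)
    stop("config: at least one mediator is required")
  for (m in cfg$mediators) {
    if (is.null(m$path) || !file.exists(m$path))
      stop("config: mediator file not found: ", m$path %||% "<missing path>")
  }
  ex_file <- cfg$selection$exclusion_file
  if (!is.null(ex_file) && !file.exists(ex_file))
    stop("config: exclusion file not found: ", ex_file)
  cfg
}

as_selection_config <- function(cfg) {
  sel <- cfg$selection %||% list()
  exclusion <- if (!is.null(sel$exclusion_file))
    read_exclusion_list(sel$exclusion_file) else character(0)
  selection_config(
    p_threshold = sel$p_threshold %||% 5e-8,
    window_kb = sel$window_kb %||% 10000,
    r2_threshold = sel$r2_threshold %||% 0.001,
    exclusion_ids = exclusion)
}

log_line <- function(log_con, ...) {
  msg <- paste0(...)
  if (!is.null(log_con)) writeLines(msg, log_con)
  message(msg)
}

#' Run the complete two-step mediation MR analysis
#'
#' Reads the configured summary statistics, runs the full estimator panel
#' for every univariable contrast (exposure -> each mediator, each mediator
#' -> outcome, exposure -> outcome), the heterogeneity/pleiotropy table,
#' and the two-step mediation decomposition, and writes:
#'
#' * `univariable_mr.tsv` — all estimators, beta and OR scale;
#' * `heterogeneity.tsv` — Q, I2, p, chosen model, Egger intercept;
#' * `mediation.tsv` — direct effects, mediation effects and E%;
#' * `estimates.json` — every estimate, machine-readable;
#' * `run.log` — every dropped/flipped/excluded variant count with reasons.
#'
#' Stage failures abort with a stage-labelled message; tables completed
#' before the failure are still written. No multiple-testing correction is
#' applied (single pre-specified causal questions; p < 0.05 is the
#' significance convention throughout, noted in the log).
#'
#' @param config config list (see [read_run_config()]) or a path to one.
#' @param out_dir output directory.
#' @param seed root seed for the bootstrap standard errors; overrides
#'   `config$seed`.
#' @return invisibly, a list with the three tables and the mediation result.
#' @export
run_all <- function(config, out_dir = "mr_output", seed = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  config <- validate_run_config(config)
  seed <- seed %||% config$seed %||% 20230828
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_con <- file(file.path(out_dir, "run.log"), open = "wt")
  on.exit(close(log_con))
  log_line(log_con, "seed: ", seed)
  log_line(log_con, "significance convention: p < 0.05, no multiple-testing correction")

  read_trait <- function(slot) {
    x <- read_sumstats(slot$path,
                       column_map = unlist(slot$column_map) %||% default_column_map(),
                       trait = slot$name %||% basename(slot$path))
    rej <- attr(x, "rejects")
    log_line(log_con, "read ", attr(x, "trait"), ": ", nrow(x), " variants, ",
             NROW(rej), " rejected rows")
    if (NROW(rej) > 0) {
      for (i in seq_len(nrow(rej)))
        log_line(log_con, "  rejected line ", rej$line[i], " (",
                 rej$variant_id[i], "): ", rej$reason[i])
    }
    x
  }
  exposure <- read_trait(config$exposure)
  mediators <- lapply(config$mediators, read_trait)
  names(mediators) <- vapply(mediators, attr, character(1), "trait")
  outcome <- read_trait(config$outcome)
  sel_cfg <- as_selection_config(config)
  est_cfg <- config$estimators %||% list()
  n_boot <- est_cfg$n_boot %||% 1000
  huber_k <- est_cfg$huber_k %||% 1.345

  results <- list()
  out_paths <- list(
    univariable = file.path(out_dir, "univariable_mr.tsv"),
    heterogeneity = file.path(out_dir, "heterogeneity.tsv"),
    mediation = file.path(out_dir, "mediation.tsv"),
    json = file.path(out_dir, "estimates.json"))
  persist <- function() {
    if (!is.null(results$univariable))
      utils::write.table(results$univariable, out_paths$univariable,
                         sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(results$heterogeneity))
      utils::write.table(results$heterogeneity, out_paths$heterogeneity,
                         sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(results$mediation))
      utils::write.table(results$mediation, out_paths$mediation,
                         sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(univariable = results$univariable,
           heterogeneity = results$heterogeneity,
           mediation = results$mediation,
           mediation_summary = results$mediation_summary),
      out_paths$json, auto_unbox = TRUE, digits = NA, pretty = TRUE,
      na = "null")
  }
  on.exit(persist(), add = TRUE)

  # univariable estimator panel for every contrast
  contrast <- function(from, to) {
    instr <- select_instruments(from, sel_cfg)
    log_line(log_con, attr(from, "trait"), " instruments: ", nrow(instr),
             " [", paste(attr(instr, "selection_log"), collapse = "; "), "]")
    strength <- instrument_strength(instr)
    log_line(log_con, sprintf("  per-set F = %.2f (K = %d, R2 = %.3g)",
                              strength$f_set, strength$k, strength$r2_total))
    h <- harmonize(subset_ids(from, instr$variant_id), to)
    log_line(log_con, "  harmonized ", nrow(h), " variants (",
             attr(h, "n_flipped"), " flipped, ",
             attr(h, "n_dropped_palindromic"), " palindromic dropped, ",
             attr(h, "n_dropped_mismatch"), " mismatch dropped)")
    list(h = h,
         table = mr_all_methods(h, n_boot = n_boot, seed = seed,
                                huber_k = huber_k))
  }
  uni <- list(); het <- list()
  pairs <- c(lapply(names(mediators),
                    function(nm) list(from = exposure, to = mediators[[nm]])),
             lapply(names(mediators),
                    function(nm) list(from = mediators[[nm]], to = outcome)),
             list(list(from = exposure, to = outcome)))
  for (pr in pairs) {
    cn <- contrast(pr$from, pr$to)
    uni[[length(uni) + 1]] <- cn$table
    rep <- sensitivity_report(cn$h)
    het[[length(het) + 1]] <- data.frame(
      exposure = attr(cn$h, "exposure"), outcome = attr(cn$h, "outcome"),
      n_snp = nrow(cn$h), method = "IVW", Q = rep$q, df = rep$df,
      I2_pct = rep$i2, p = rep$p, chosen_model = rep$chosen_model,
      egger_intercept = rep$egger_intercept,
      intercept_ci_low = rep$intercept_ci[1],
      intercept_ci_high = rep$intercept_ci[2],
      intercept_p = rep$intercept_p, stringsAsFactors = FALSE)
  }
  results$univariable <- do.call(rbind, uni)
  results$heterogeneity <- do.call(rbind, het)

  # two-step mediation decomposition
  med <- run_two_step(exposure, mediators, outcome, cfg = sel_cfg)
  med_rows <- rbind(
    data.frame(exposure = attr(exposure, "trait"),
               outcome = attr(outcome, "trait"),
               adjusted_for = "none", n_snp = med$total$n_snp,
               or = med$total$or_value, or_low = med$total$or_low,
               or_high = med$total$or_high, pval = med$total$pval,
               mediation_effect = NA_real_, mediation_ci_low = NA_real_,
               mediation_ci_high = NA_real_, mediation_pct = NA_real_,
               stringsAsFactors = FALSE),
    do.call(rbind, lapply(seq_len(nrow(med$mediators)), function(i) {
      r <- med$mediators[i, ]
      data.frame(exposure = attr(exposure, "trait"),
                 outcome = attr(outcome, "trait"),
                 adjusted_for = r$mediator, n_snp = r$n_snp,
                 or = exp(r$direct_beta3),
                 or_low = exp(r$direct_beta3 - Z95 * r$direct_se3),
                 or_high = exp(r$direct_beta3 + Z95 * r$direct_se3),
                 pval = norm_pval(r$direct_beta3 / r$direct_se3),
                 mediation_effect = r$indirect,
                 mediation_ci_low = r$indirect_ci_low,
                 mediation_ci_high = r$indirect_ci_high,
                 mediation_pct = r$proportion_pct, stringsAsFactors = FALSE)
    })),
    data.frame(exposure = attr(exposure, "trait"),
               outcome = attr(outcome, "trait"),
               adjusted_for = paste(names(mediators), collapse = " + "),
               n_snp = med$fits$mv_joint$n_snp,
               or = exp(med$direct_beta),
               or_low = exp(med$direct_beta - Z95 * med$direct_se),
               or_high = exp(med$direct_beta + Z95 * med$direct_se),
               pval = norm_pval(med$direct_beta / med$direct_se),
               mediation_effect = med$combined_indirect,
               mediation_ci_low = med$combined_indirect - Z95 * med$combined_se,
               mediation_ci_high = med$combined_indirect + Z95 * med$combined_se,
               mediation_pct = as.numeric(med$proportion_pct),
               stringsAsFactors = FALSE))
  results$mediation <- med_rows
  results$mediation_summary <- list(
    total_beta = med$total$beta, direct_beta = med$direct_beta,
    combined_indirect = med$combined_indirect,
    proportion_pct = as.numeric(med$proportion_pct),
    proportion_vs_total = med$proportion_vs_total,
    inconsistent = isTRUE(attr(med$proportion_pct, "inconsistent")))
  log_line(log_con, sprintf(
    "mediation: total = %.4f, direct = %.4f, combined indirect = %.4f, E%% = %.2f",
    med$total$beta, med$direct_beta, med$combined_indirect,
    as.numeric(med$proportion_pct)))

  invisible(c(results, list(mediation_result = med, files = out_paths)))
}
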