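#' Instrument selection configuration
#'
#' @param p_threshold genome-wide significance threshold for instrument
#'   inclusion (default `5e-8`, strict `<`).
#' @param window_kb physical pruning window in kilobases (default 10,000).
#' @param r2_threshold LD r-squared threshold for pruning (default 0.001).
#' @param exclusion_ids variant ids to drop a priori (e.g. variants
#'   associated with confounders such as body mass index or hypertension,
#'   compiled by the user from catalog lookups).
#' @param exposure_specific_exclusions additional ids excluded for this
#'   exposure only (e.g. instruments shared with another trait in a
#'   mediation design).
#' @export
selection_config <- function(p_threshold = 5e-8, window_kb = 10000,
                             r2_threshold = 0.001,
                             exclusion_ids = character(0),
                             exposure_specific_exclusions = character(0)) {
  stopifnot(p_threshold > 0, p_threshold < 1, window_kb > 0,
            r2_threshold > 0, r2_threshold < 1)
  structure(list(p_threshold = p_threshold, window_kb = window_kb,
                 r2_threshold = r2_threshold,
                 exclusion_ids = as.character(exclusion_ids),
                 exposure_specific_exclusions =
                   as.character(exposure_specific_exclusions)),
            class = "selection_config")
}

#' Select independent, strong, confounder-free instruments
#'
#' Applies, in order: the significance threshold (`pval < p_threshold`),
#' the exclusion lists, and greedy pruning in ascending p-value order
#' (ties broken by `variant_id`). Two variants conflict when they fall on
#' the same chromosome within `window_kb` (if positions are available) and
#' their LD r-squared is at or above `r2_threshold` (if an LD matrix is
#' supplied); with neither positions nor LD, the input is assumed pre-pruned
#' and only thresholding/exclusion apply (a message is emitted). Greedy
#' retention keeps the lower-p variant of every conflicting pair.
#'
#' @param stats a [sumstats] object.
#' @param cfg a [selection_config].
#' @param ld optional symmetric correlation (r) matrix with unit diagonal,
#'   dimnames covering all candidate variant ids; squared internally.
#' @return The retained rows of `stats` (still a `sumstats`), with columns
#'   `r2` (per-variant variance explained, normalized mode, `NA` when `eaf`
#'   is missing) and `f_stat` (per-instrument F, i.e. K = 1) appended, and
#'   a `selection_log` attribute describing each stage.
#' @export
select_instruments <- function(stats, cfg = selection_config(), ld = NULL) {
  log <- character(0)
  sig <- stats[stats$pval < cfg$p_threshold, , drop = FALSE]
  log <- c(log, sprintf("threshold p<%g: %d of %d retained",
                        cfg$p_threshold, nrow(sig), nrow(stats)))
  if (nrow(sig) == 0) stop("no instruments survive stage 'threshold'")

  excl <- union(cfg$exclusion_ids, cfg$exposure_specific_exclusions)
  sel <- sig[!(sig$variant_id %in% excl), , drop = FALSE]
  log <- c(log, sprintf("exclusion list: %d removed", nrow(sig) - nrow(sel)))
  if (nrow(sel) == 0) stop("no instruments survive stage 'exclusion'")

  have_pos <- !all(is.na(sel$pos)) && !all(is.na(sel$chrom))
  have_ld <- !is.null(ld)
  if (have_ld) {
    miss <- setdiff(sel$variant_id, rownames(ld))
    if (length(miss) > 0) stop("LD matrix does not cover: ",
                               paste(utils::head(miss, 5), collapse = ", "))
  }
  if (!have_pos && !have_ld) {
    message("no positions or LD matrix supplied; assuming pre-pruned input")
    log <- c(log, "pruning: skipped (assumed pre-pruned)")
  } else {
    ord <- order(sel$pval, sel$variant_id)
    sel <- sel[ord, , drop = FALSE]
    kept <- integer(0)
    for (i in seq_len(nrow(sel))) {
      conflict <- FALSE
      for (j in kept) {
        near <- if (have_pos) {
          !is.na(sel$chrom[i]) && !is.na(sel$chrom[j]) &&
            sel$chrom[i] == sel$chrom[j] &&
            !is.na(sel$pos[i]) && !is.na(sel$pos[j]) &&
            abs(sel$pos[i] - sel$pos[j]) <= cfg$window_kb * 1000
        } else TRUE
        linked <- if (have_ld) {
          ld[sel$variant_id[i], sel$variant_id[j]]^2 >= cfg$r2_threshold
        } else TRUE
        if (near && linked) { conflict <- TRUE; break }
      }
      if (!conflict) kept <- c(kept, i)
    }
    log <- c(log, sprintf("pruning (window %d kb, r2<%g): %d of %d retained",
                          cfg$window_kb, cfg$r2_threshold, length(kept), nrow(sel)))
    sel <- sel[kept, , drop = FALSE]
  }
  if (nrow(sel) == 0) stop("no instruments survive stage 'pruning'")

  # deterministic order regardless of input permutation
  sel <- sel[order(sel$pval, sel$variant_id), , drop = FALSE]
  maf <- fold_maf(sel$eaf)
  sel$r2 <- ifelse(is.na(maf) | maf <= 0, NA_real_,
                   variance_explained(pmin(maf, 0.5), sel$beta, sel$se, n = sel$n))
  sel$f_stat <- ifelse(is.na(sel$r2), NA_real_,
                       (sel$n - 2) * sel$r2 / (1 - sel$r2))
  rownames(sel) <- NULL
  attr(sel, "selection_log") <- log
  sel
}

#' Per-variant variance explained
#'
#' Computes `2 * (1 - MAF) * MAF * (beta/se)^2`. With `n` supplied the
#' quantity is divided by the sample size ("normalized" mode), giving the
#' usual variance-explained approximation bounded by 1 in realistic data;
#' without `n` the raw product is returned as printed in the source formula
#' (which can exceed 1 and should be interpreted with care).
#'
#' @param maf minor-allele frequency in (0, 0.5\]; fold `eaf > 0.5` first.
#' @param beta,se effect and standard error.
#' @param n optional per-variant sample size enabling normalized mode.
#' @export
variance_explained <- function(maf, beta, se, n = NULL) {
  if (any(is.na(maf)) || any(maf <= 0) || any(maf > 0.5))
    stop("maf must lie in (0, 0.5] after folding")
  if (any(se <= 0)) stop("se must be positive")
  r2 <- 2 * (1 - maf) * maf * (beta / se)^2
  if (!is.null(n)) r2 <- r2 / n
  r2
}

#' Instrument-strength F statistic
#'
#' `F = [(N - K - 1)/K] * [R2/(1 - R2)]` for `K` instruments jointly
#' explaining `r2_total` of the exposure variance in a sample of `n`.
#' With `k = 1` this is the per-instrument F.
#'
#' @param n exposure sample size.
#' @param k number of instruments (`n > k + 1`).
#' @param r2_total total variance explained, in \[0, 1).
#' @export
f_statistic <- function(n, k, r2_total) {
  if (any(n <= k + 1)) stop("need n > k + 1")
  if (any(r2_total < 0) || any(r2_total >= 1)) stop("r2_total must lie in [0,1)")
  ((n - k - 1) / k) * (r2_total / (1 - r2_total))
}

#' Summarize instrument strength for a selected set
#'
#' Sums per-instrument variance explained (variants with missing `eaf` are
#' excluded from the sum) and reports the per-set F statistic; warns when it
#' falls below the conventional weak-instrument threshold of 10.
#'
#' @param instruments output of [select_instruments()].
#' @return list with `k`, `n`, `r2_total`, `f_set`, `f_per_instrument`.
#' @export
instrument_strength <- function(instruments) {
  k <- nrow(instruments)
  n <- stats::median(instruments$n)
  r2_total <- sum(instruments$r2, na.rm = TRUE)
  f_set <- f_statistic(n, k, min(r2_total, 1 - 1e-12))
  if (is.finite(f_set) && f_set < 10) {
    warning(sprintf("weak instruments: per-set F = %.2f < 10", f_set))
  }
  list(k = k, n = n, r2_total = r2_total, f_set = f_set,
       f_per_instrument = instruments$f_stat)
}

#' Read a variant exclusion list
#'
#' Plain text, one variant id per line; `#` starts a comment.
#' @param path file path.
#' @export
read_exclusion_list <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines[nzchar(lines)]
}

#' Read an LD matrix
#'
#' Tab-separated with a header row and a leading column of variant ids;
#' values are correlations (r) in \[-1, 1\], squared internally by
#' [select_instruments()].
#' @param path file path.
#' @export
read_ld_matrix <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                          row.names = 1)
  m <- as.matrix(df)
  if (nrow(m) != ncol(m) || !isTRUE(all.equal(m, t(m), tolerance = 1e-8)))
    stop("LD matrix must be square and symmetric")
  if (any(abs(m) > 1 + 1e-8)) stop("LD values must lie in [-1, 1]")
  m
}
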