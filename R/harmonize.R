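#' Construct a harmonized exposure/outcome effect set
#'
#' The unit of all MR estimation: per-variant gene-exposure (`bx`, `sex`) and
#' gene-outcome (`by`, `sey`) coefficient pairs expressed on a common effect
#' allele. Usually produced by [harmonize()]; this constructor exists for
#' simulation and testing.
#'
#' @param variant_id,bx,sex,by,sey,eafx,eafy per-variant vectors;
#'   `sex`/`sey` must be positive.
#' @param exposure,outcome trait labels.
#' @param n_flipped,n_dropped_palindromic,n_dropped_mismatch harmonization
#'   bookkeeping counters.
#' @return A `harmonized_set` data frame.
#' @export
harmonized_set <- function(variant_id, bx, sex, by, sey,
                           eafx = NA_real_, eafy = NA_real_,
                           exposure = "exposure", outcome = "outcome",
                           n_flipped = 0L, n_dropped_palindromic = 0L,
                           n_dropped_mismatch = 0L) {
  df <- data.frame(variant_id = as.character(variant_id),
                   bx = bx, sex = sex, by = by, sey = sey,
                   eafx = eafx, eafy = eafy, stringsAsFactors = FALSE)
  if (anyDuplicated(df$variant_id)) stop("duplicate variant_id in harmonized set")
  if (any(df$sex <= 0) || any(df$sey <= 0)) stop("standard errors must be positive")
  structure(df, class = c("harmonized_set", "data.frame"),
            exposure = exposure, outcome = outcome,
            n_flipped = as.integer(n_flipped),
            n_dropped_palindromic = as.integer(n_dropped_palindromic),
            n_dropped_mismatch = as.integer(n_dropped_mismatch))
}

#' Harmonize exposure and outcome summary statistics
#'
#' Intersects two [sumstats] tables on `variant_id` and orients the outcome
#' coefficients to the exposure's effect allele. When the outcome's alleles
#' are swapped relative to the exposure, the outcome beta is negated and its
#' effect-allele frequency replaced by `1 - eaf`. Palindromic (A/T or C/G)
#' variants are strand-ambiguous: they are dropped when the minor-allele
#' frequency in either study lies within `palindromic_eaf_window` of 0.5 (or
#' when a frequency is missing), and otherwise oriented by frequency
#' agreement. Allele pairs matching neither orientation are dropped and
#' counted.
#'
#' @param exposure,outcome [sumstats] objects.
#' @param palindromic_eaf_window half-width of the ambiguous minor-allele
#'   frequency band below 0.5 (default 0.08, i.e. MAF in \[0.42, 0.5\] drops).
#' @return A [harmonized_set] with counters `n_flipped`,
#'   `n_dropped_palindromic`, `n_dropped_mismatch` as attributes.
#' @export
harmonize <- function(exposure, outcome, palindromic_eaf_window = 0.08) {
  shared <- intersect(exposure$variant_id, outcome$variant_id)
  if (length(shared) == 0) {
    stop("no shared instruments between '", attr(exposure, "trait") %||% "exposure",
         "' and '", attr(outcome, "trait") %||% "outcome", "'")
  }
  ex <- exposure[match(shared, exposure$variant_id), , drop = FALSE]
  ou <- outcome[match(shared, outcome$variant_id), , drop = FALSE]

  pal <- is_palindromic(ex$effect_allele, ex$other_allele)
  same <- ex$effect_allele == ou$effect_allele & ex$other_allele == ou$other_allele
  swapped <- ex$effect_allele == ou$other_allele & ex$other_allele == ou$effect_allele

  by <- ou$beta
  eafy <- ou$eaf
  flip <- rep(FALSE, length(shared))
  keep <- rep(TRUE, length(shared))
  drop_pal <- rep(FALSE, length(shared))

  # non-palindromic: letter matching is decisive
  np <- !pal
  flip[np & swapped] <- TRUE
  keep[np & !(same | swapped)] <- FALSE

  # palindromic: the reported letters cannot resolve strand; use frequencies
  if (any(pal)) {
    mafx <- fold_maf(ex$eaf)
    mafy <- fold_maf(ou$eaf)
    ambiguous <- pal & (!(same | swapped) | is.na(mafx) | is.na(mafy) |
                          mafx >= 0.5 - palindromic_eaf_window |
                          mafy >= 0.5 - palindromic_eaf_window)
    drop_pal[ambiguous] <- TRUE
    keep[ambiguous] <- FALSE
    resolvable <- pal & !ambiguous
    flip[resolvable] <- sign(ex$eaf[resolvable] - 0.5) != sign(ou$eaf[resolvable] - 0.5)
  }

  by[flip] <- -by[flip]
  eafy[flip] <- 1 - eafy[flip]

  sel <- keep
  if (!any(sel)) stop("no shared instruments survive harmonization")
  harmonized_set(
    variant_id = shared[sel],
    bx = ex$beta[sel], sex = ex$se[sel],
    by = by[sel], sey = ou$se[sel],
    eafx = ex$eaf[sel], eafy = eafy[sel],
    exposure = attr(exposure, "trait") %||% "exposure",
    outcome = attr(outcome, "trait") %||% "outcome",
    n_flipped = sum(flip & sel),
    n_dropped_palindromic = sum(drop_pal),
    n_dropped_mismatch = sum(!keep & !drop_pal)
  )
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat("Harmonized set: ", attr(x, "exposure"), " -> ", attr(x, "outcome"),
      " (", nrow(x), " variants; ", attr(x, "n_flipped"), " flipped, ",
      attr(x, "n_dropped_palindromic"), " palindromic dropped, ",
      attr(x, "n_dropped_mismatch"), " mismatch dropped)\n", sep = "")
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("... ", nrow(x) - 6, " more rows\n", sep = "")
  invisible(x)
}
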