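# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, evaluates `code`, and restores the caller's RNG state, so
#' seeded routines (bootstrap standard errors, the synthetic-data generator)
#' never perturb the global random stream. A `NULL` seed evaluates `code`
#' under the current stream.
#' @keywords internal
with_preserved_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# fold an effect-allele frequency onto the minor-allele scale
fold_maf <- function(eaf) ifelse(!is.na(eaf) & eaf > 0.5, 1 - eaf, eaf)

# strand-ambiguous allele pairs
is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

# two-sided normal p-value, kept strictly inside (0, 1]
norm_pval <- function(z) pmax(2 * stats::pnorm(-abs(z)), 1e-300)

# the reporting convention throughout is the symmetric normal-theory interval
Z95 <- 1.96
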