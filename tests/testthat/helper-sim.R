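# shared builders for estimator and harmonization tests

# harmonized set drawn from the linear instrumental model
# by = intercept + theta * xi + N(0, sey^2), bx = xi + N(0, sex^2)
h_sim <- function(L = 20, theta = 0.3, seed = 1, sex = 0.002, sey = 0.02,
                  bx_scale = 0.1, intercept = 0) {
  set.seed(seed)
  xi <- rnorm(L, 0.15, bx_scale) # offset keeps bx away from 0
  bx <- xi + rnorm(L, 0, sex)
  by <- intercept + theta * xi + rnorm(L, 0, sey)
  harmonized_set(sprintf("rs%03d", seq_len(L)), bx, rep(sex, L), by, rep(sey, L))
}

# restrict a sumstats table to the selected instruments
subset_instr <- function(stats, instruments) {
  out <- stats[stats$variant_id %in% instruments$variant_id, ]
  attr(out, "trait") <- attr(stats, "trait")
  class(out) <- class(stats)
  out
}

# minimal valid summary-statistics data frame
# (rng_seed, not "seed": a partial-matching trap for the se column otherwise)
ss_df <- function(n = 3, rng_seed = 1, ...) {
  set.seed(rng_seed)
  out <- data.frame(
    variant_id = sprintf("rs%03d", seq_len(n)),
    chrom = as.character(rep(1:22, length.out = n)),
    pos = ceiling(seq_len(n) / 22) * 12e6,
    effect_allele = rep(c("A", "C", "G"), length.out = n),
    other_allele = rep(c("G", "T", "A"), length.out = n),
    eaf = runif(n, 0.05, 0.95),
    beta = rnorm(n, 0, 0.1),
    se = runif(n, 0.01, 0.05),
    pval = runif(n, 1e-12, 0.9),
    n = 10000,
    stringsAsFactors = FALSE)
  args <- list(...)
  for (nm in names(args)) out[[nm]] <- args[[nm]]
  out
}
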