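test_that("significance thresholding is strict and counts correctly", {
  df <- ss_df(3, pval = c(1e-9, 1e-8, 1e-7), chrom = NA, pos = NA)
  sel <- suppressMessages(select_instruments(sumstats(df)))
  expect_equal(nrow(sel), 2)
  expect_setequal(sel$variant_id, c("rs001", "rs002"))
})

test_that("greedy pruning keeps the smaller p-value of a linked pair", {
  df <- ss_df(2, pval = c(1e-9, 1e-10), chrom = "1", pos = c(1e6, 6e6))
  ld <- matrix(c(1, sqrt(0.5), sqrt(0.5), 1), 2, 2,
               dimnames = list(df$variant_id, df$variant_id))
  sel <- select_instruments(sumstats(df), ld = ld)
  expect_equal(sel$variant_id, "rs002")
})

test_that("exclusion lists remove confounder-associated variants", {
  df <- ss_df(3, pval = 1e-9, chrom = NA, pos = NA)
  cfg <- selection_config(exclusion_ids = "rs002")
  sel <- suppressMessages(select_instruments(sumstats(df), cfg))
  expect_setequal(sel$variant_id, c("rs001", "rs003"))
  expect_error(suppressMessages(select_instruments(
    sumstats(df), selection_config(exclusion_ids = df$variant_id))),
    "stage 'exclusion'")
})

test_that("block-LD selection satisfies the brute-force feasibility oracle", {
  set.seed(42)
  n <- 20
  df <- ss_df(n, pval = 10^runif(n, -20, -8), chrom = "2",
              pos = seq(1e6, by = 2e6, length.out = n))
  # block-diagonal LD: blocks of 4, within-block r2 = 0.6, across = 0
  block <- (seq_len(n) - 1) %/% 4
  r <- outer(block, block, function(a, b) ifelse(a == b, sqrt(0.6), 0))
  diag(r) <- 1
  dimnames(r) <- list(df$variant_id, df$variant_id)
  cfg <- selection_config()
  sel <- select_instruments(sumstats(df), cfg, ld = r)

  kept <- sel$variant_id
  idx <- match(kept, df$variant_id)
  # feasibility: every retained pair satisfies the constraint
  for (i in idx) for (j in idx) {
    if (i < j) {
      conflict <- abs(df$pos[i] - df$pos[j]) <= cfg$window_kb * 1000 &&
        r[i, j]^2 >= cfg$r2_threshold
      expect_false(conflict)
    }
  }
  # greedy maximality: every discarded candidate conflicts with a retained
  # variant of smaller p (or equal p and earlier id)
  for (i in setdiff(seq_len(n), idx)) {
    conflicts <- vapply(idx, function(j) {
      near <- abs(df$pos[i] - df$pos[j]) <= cfg$window_kb * 1000
      better <- df$pval[j] < df$pval[i] ||
        (df$pval[j] == df$pval[i] && df$variant_id[j] < df$variant_id[i])
      near && r[i, j]^2 >= cfg$r2_threshold && better
    }, logical(1))
    expect_true(any(conflicts))
  }
})

test_that("selection is invariant to permutation of the input rows", {
  set.seed(9)
  n <- 15
  df <- ss_df(n, pval = 10^runif(n, -15, -8), chrom = "3",
              pos = seq(1e6, by = 3e6, length.out = n))
  base <- select_instruments(sumstats(df))
  for (rep in 1:5) {
    perm <- df[sample.int(n), ]
    sel <- select_instruments(sumstats(perm))
    expect_equal(sel$variant_id, base$variant_id)
  }
})

test_that("variance explained follows the printed formula, with a
           normalized mode dividing by sample size", {
  expect_equal(variance_explained(0.5, 1, 1), 0.5)
  expect_equal(variance_explained(0.3, 0, 0.01), 0)
  # hand arithmetic: 2 * 0.9 * 0.1 * (0.03/0.01)^2 = 1.62 (exceeds 1: the
  # printed form is not a bounded proportion)
  expect_equal(variance_explained(0.1, 0.03, 0.01), 1.62)
  expect_equal(variance_explained(0.1, 0.03, 0.01, n = 1000), 1.62e-3)
  expect_error(variance_explained(0.7, 0.1, 0.1), "maf")
  expect_error(variance_explained(0, 0.1, 0.1), "maf")
})

test_that("the F statistic matches the printed formula and is monotone", {
  expect_equal(f_statistic(100, 1, 0), 0)
  expect_equal(f_statistic(1001, 10, 0.5), 99 * 1)
  expect_error(f_statistic(10, 10, 0.1), "n > k")
  # monotone: increasing in r2 and n, decreasing in k
  set.seed(3)
  for (i in 1:20) {
    n <- sample(1000:100000, 1); k <- sample(2:50, 1)
    r2 <- runif(1, 1e-5, 0.3)
    expect_gt(f_statistic(n, k, r2 * 1.1), f_statistic(n, k, r2))
    expect_gt(f_statistic(n * 2, k, r2), f_statistic(n, k, r2))
    expect_lt(f_statistic(n, k + 1, r2), f_statistic(n, k, r2))
  }
})

test_that("per-set F below 10 triggers the weak-instrument warning", {
  # hand-built set: k = 2, n = 10000, per-variant normalized r2 = 8.2e-4
  # -> F = (10000-3)/2 * 0.00164/0.99836 = 8.21 < 10
  df <- ss_df(2, eaf = 0.5, beta = 0.0405, se = 0.01, pval = 1e-5)
  sel <- suppressMessages(select_instruments(
    sumstats(df), selection_config(p_threshold = 1e-4)))
  expect_warning(s <- instrument_strength(sel), "per-set F")
  expect_lt(s$f_set, 10)
  # and a strong set stays silent
  df2 <- ss_df(2, eaf = 0.5, beta = 0.2, se = 0.01, pval = 1e-12)
  sel2 <- suppressMessages(select_instruments(
    sumstats(df2), selection_config()))
  expect_no_warning(instrument_strength(sel2))
})

test_that("the weak-instrument scenario yields a per-set F near 10", {
  cfg <- scenario_library(seed = 5)$weak_instrument
  sims <- simulate_sumstats(cfg)
  sel <- select_instruments(sims$exposure,
                            selection_config(p_threshold = cfg$p_threshold))
  s <- suppressWarnings(instrument_strength(sel))
  expect_gt(s$f_set, 5)
  expect_lt(s$f_set, 15)
})

test_that("exclusion files parse ids and ignore comments", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# confounder-associated variants", "rs1 ", "", "rs2 # bmi"),
             path)
  expect_equal(read_exclusion_list(path), c("rs1", "rs2"))
})
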