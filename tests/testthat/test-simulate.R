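test_that("the generator is deterministic given its root seed", {
  cfg <- simulation_config(n_snp_exposure = 15, n_snp_mediator = c(m = 10),
                           beta1 = 0.1, beta2 = 0.2, seed = 41)
  a <- simulate_sumstats(cfg)
  b <- simulate_sumstats(cfg)
  expect_identical(lapply(a, as.data.frame), lapply(b, as.data.frame))
  # and byte-identical files
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_simulation(a, d1); write_simulation(b, d2)
  for (f in list.files(d1)) {
    if (f == "manifest.json") next
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  c <- simulate_sumstats(simulation_config(
    n_snp_exposure = 15, n_snp_mediator = c(m = 10), beta1 = 0.1,
    beta2 = 0.2, seed = 42))
  expect_false(identical(a$exposure$beta, c$exposure$beta))
})

test_that("standard errors shrink exactly as 1/sqrt(N)", {
  base <- simulation_config(n_snp_exposure = 10, n_snp_mediator = c(m = 5),
                            beta1 = 0.1, beta2 = 0.2, seed = 43)
  dbl <- base
  dbl$cohort_n$exposure <- 2 * base$cohort_n$exposure
  s1 <- simulate_sumstats(base)
  s2 <- simulate_sumstats(dbl)
  expect_equal(s2$exposure$se, s1$exposure$se / sqrt(2), tolerance = 1e-12)
})

test_that("the generator's stated structural truths hold", {
  cfg <- simulation_config(seed = 44)
  sims <- simulate_sumstats(cfg)
  truth <- attr(sims, "truth")
  expect_equal(length(sims), 5)
  expect_equal(truth$total_effect,
               cfg$theta_direct + sum(cfg$beta1 * cfg$beta2))
  # mediator truth on the exposure block is beta1 * xi
  expo_idx <- 1:cfg$n_snp_exposure
  expect_equal(truth$mediator_truth[expo_idx, 1],
               cfg$beta1[1] * truth$xi[expo_idx])
  # every trait reports every variant
  expect_true(all(vapply(sims, nrow, numeric(1)) ==
                    cfg$n_snp_exposure + sum(cfg$n_snp_mediator)))
  # non-palindromic alleles by default
  pal <- with(as.data.frame(sims$exposure),
              (effect_allele == "A" & other_allele == "T") |
                (effect_allele == "T" & other_allele == "A") |
                (effect_allele == "C" & other_allele == "G") |
                (effect_allele == "G" & other_allele == "C"))
  expect_false(any(pal))
})

test_that("a null IVW confidence interval covers zero at the nominal rate", {
  cfgs <- scenario_library(seed = 45)
  hits <- vapply(1:60, function(i) {
    cfg <- cfgs$null
    cfg$seed <- 45000 + i
    sims <- simulate_sumstats(cfg)
    instr <- select_instruments(sims$exposure)
    h <- harmonize(subset_instr(sims$exposure, instr), sims$outcome)
    est <- mr_ivw(h, "fixed")
    est$ci_low <= 0 && 0 <= est$ci_high
  }, logical(1))
  expect_gte(mean(hits), 0.85)
})

test_that("directional pleiotropy surfaces in the Egger intercept while
           balanced pleiotropy does not", {
  n_pos <- vapply(1:20, function(i) {
    cfg <- simulation_config(n_snp_exposure = 150,
                             n_snp_mediator = c(m = 5), beta1 = 0.02,
                             beta2 = 0.1,
                             pleiotropy = list(type = "directional",
                                               scale = 0.01),
                             seed = 46000 + i)
    sims <- simulate_sumstats(cfg)
    instr <- select_instruments(sims$exposure)
    h <- harmonize(subset_instr(sims$exposure, instr), sims$outcome)
    eg <- egger_intercept_test(h)
    eg$intercept > 0 && eg$p < 0.05
  }, logical(1))
  n_bal <- vapply(1:20, function(i) {
    cfg <- simulation_config(n_snp_exposure = 150,
                             n_snp_mediator = c(m = 5), beta1 = 0.02,
                             beta2 = 0.1,
                             pleiotropy = list(type = "balanced",
                                               scale = 0.01),
                             seed = 46000 + i)
    sims <- simulate_sumstats(cfg)
    instr <- select_instruments(sims$exposure)
    h <- harmonize(subset_instr(sims$exposure, instr), sims$outcome)
    egger_intercept_test(h)$p < 0.05
  }, logical(1))
  expect_gt(mean(n_pos), 0.5)
  expect_lt(mean(n_bal), mean(n_pos))
})

test_that("the scenario library ships the four study designs", {
  lib <- scenario_library(seed = 47)
  expect_setequal(names(lib),
                  c("paper_shaped", "null", "pleiotropic", "weak_instrument"))
  expect_equal(lib$null$theta_direct, 0)
  expect_true(all(lib$null$beta1 == 0) && all(lib$null$beta2 == 0))
  expect_equal(lib$pleiotropic$pleiotropy$type, "directional")
  expect_equal(lib$paper_shaped$n_snp_exposure, 12)
  expect_equal(length(lib$paper_shaped$beta1), 3)
  expect_true(all(lib$paper_shaped$beta1 > 0) &&
                all(lib$paper_shaped$beta2 > 0))
})

test_that("the paper-shaped scenario runs end to end with every mediator
           mediating", {
  sims <- simulate_sumstats(scenario_library(seed = 48)$paper_shaped)
  r <- suppressMessages(suppressWarnings(
    run_two_step(sims[[1]], sims[2:4], sims[[5]])))
  expect_equal(nrow(r$mediators), 3)
  expect_true(all(r$mediators$proportion_pct > 0 &
                    r$mediators$proportion_pct < 100))
  expect_false(attr(r$proportion_pct, "inconsistent"))
})
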