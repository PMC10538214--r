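test_that("Wald ratio matches its definition, both se orders", {
  est <- mr_wald_ratio(0.1, 0.01, 0.05, 0.02)
  expect_equal(est$beta, 0.5)
  expect_equal(est$se, 0.2)
  expect_equal(mr_wald_ratio(0.1, 0.01, 0, 0.02)$beta, 0)
  est2 <- mr_wald_ratio(0.1, 0.01, 0.05, 0.02, second_order = TRUE)
  expect_equal(est2$se, sqrt(0.04 + 0.0025))
  expect_error(mr_wald_ratio(0, 0.01, 0.05, 0.02), "bx = 0")
})

test_that("single-entry IVW equals the Wald ratio exactly", {
  h <- harmonized_set("rs1", 0.08, 0.01, 0.03, 0.02)
  est <- suppressMessages(mr_ivw(h))
  w <- mr_wald_ratio(0.08, 0.01, 0.03, 0.02)
  expect_identical(est$beta, w$beta)
  expect_identical(est$se, w$se)
})

test_that("identical Wald ratios collapse every estimator to that ratio", {
  bx <- c(0.05, 0.08, 0.12, 0.2)
  h <- harmonized_set(paste0("rs", 1:4), bx, rep(1e-6, 4), 0.4 * bx,
                      rep(0.01, 4))
  for (m in c("ivw_fixed", "ivw_random", "egger", "weighted_median",
              "max_likelihood", "raps")) {
    expect_equal(mr_fit(h, m)$beta, 0.4, tolerance = 1e-6)
  }
  # fixed and random IVW standard errors coincide when Q = 0
  expect_equal(mr_ivw(h, "fixed")$se, mr_ivw(h, "random")$se)
})

test_that("IVW matches the explicit normal-equations WLS oracle to 1e-10", {
  set.seed(101)
  for (rep in 1:100) {
    L <- sample(5:50, 1)
    bx <- rnorm(L, 0.1, 0.05); bx[bx == 0] <- 0.01
    sex <- runif(L, 0.001, 0.01)
    by <- rnorm(L, 0.3 * bx, 0.02)
    sey <- runif(L, 0.005, 0.05)
    h <- harmonized_set(paste0("rs", 1:L), bx, sex, by, sey)
    # oracle: zero-intercept WLS via explicit normal equations
    w <- 1 / sey^2
    beta_o <- sum(w * bx * by) / sum(w * bx^2)
    se_o <- sqrt(1 / sum(w * bx^2))
    q_o <- sum(w * (by - beta_o * bx)^2)
    fx <- mr_ivw(h, "fixed")
    rn <- mr_ivw(h, "random")
    expect_equal(fx$beta, beta_o, tolerance = 1e-10)
    expect_equal(fx$se, se_o, tolerance = 1e-10)
    expect_equal(rn$beta, beta_o, tolerance = 1e-10)
    expect_equal(rn$se, se_o * sqrt(max(q_o / (L - 1), 1)), tolerance = 1e-10)
    expect_gte(rn$se, fx$se)
  }
})

test_that("Egger reproduces an exact two-parameter fit and matches a
           two-column WLS oracle", {
  # exact interpolation on collinear points by = 0.01 + 0.4 * bx
  bx <- c(0.05, 0.10, 0.20)
  h <- harmonized_set(paste0("rs", 1:3), bx, rep(0.001, 3), 0.01 + 0.4 * bx,
                      rep(0.01, 3))
  est <- mr_egger(h)
  expect_equal(est$beta, 0.4, tolerance = 1e-10)
  expect_equal(est$extra$intercept, 0.01, tolerance = 1e-10)
  expect_lt(est$extra$sigma2, 1e-16)

  set.seed(202)
  for (rep in 1:20) {
    L <- sample(5:40, 1)
    bx <- abs(rnorm(L, 0.1, 0.05)) + 0.01
    by <- rnorm(L, 0.02 + 0.3 * bx, 0.02)
    sey <- runif(L, 0.005, 0.05)
    h <- harmonized_set(paste0("rs", 1:L), bx, rep(0.001, L), by, sey)
    w <- 1 / sey^2
    X <- cbind(1, bx)
    coef_o <- solve(t(X) %*% (X * w), t(X) %*% (w * by))
    est <- mr_egger(h)
    expect_equal(est$extra$intercept, coef_o[1], tolerance = 1e-10)
    expect_equal(est$beta, coef_o[2], tolerance = 1e-10)
  }
})

test_that("Egger is invariant to allele re-orientation of any subset", {
  h <- h_sim(L = 15, theta = 0.25, seed = 3, intercept = 0.01)
  est0 <- mr_egger(h)
  set.seed(4)
  flip <- sample(c(-1, 1), 15, replace = TRUE)
  h2 <- harmonized_set(h$variant_id, flip * h$bx, h$sex, flip * h$by, h$sey)
  est1 <- mr_egger(h2)
  expect_equal(est1$beta, est0$beta, tolerance = 1e-12)
  expect_equal(est1$extra$intercept, est0$extra$intercept, tolerance = 1e-12)
})

test_that("Egger slope agrees with IVW when the intercept is truly zero", {
  h <- h_sim(L = 100, theta = 0.3, seed = 5, intercept = 0)
  eg <- mr_egger(h)
  iv <- mr_ivw(h, "fixed")
  expect_lt(abs(eg$beta - iv$beta), 3 * eg$se)
  expect_error(mr_egger(h_sim(L = 2, seed = 1)), "underdetermined")
})

test_that("weighted median interpolates the mid-point cumulative convention", {
  # equal weights: plain median
  h <- harmonized_set(paste0("rs", 1:3), c(1, 1, 1), rep(0.001, 3),
                      c(1, 2, 3), rep(1, 3))
  expect_equal(mr_weighted_median(h, n_boot = 50)$beta, 2)
  # a dominant middle variant (> 50% of weight) returns its own ratio
  bx <- c(0.2, 0.6, 0.2) # weights bx^2 with sey = 1: 0.04, 0.36, 0.04
  h2 <- harmonized_set(paste0("rs", 1:3), sqrt(c(0.2, 0.6, 0.2)),
                       rep(0.001, 3),
                       sqrt(c(0.2, 0.6, 0.2)) * c(1, 2, 3), rep(1, 3))
  expect_equal(mr_weighted_median(h2, n_boot = 50)$beta, 2)
})

test_that("weighted-median bootstrap se is reproducible bit-for-bit", {
  h <- h_sim(L = 12, theta = 0.2, seed = 6)
  a <- mr_weighted_median(h, n_boot = 1000, seed = 99)
  b <- mr_weighted_median(h, n_boot = 1000, seed = 99)
  expect_identical(a$se, b$se)
  c <- mr_weighted_median(h, n_boot = 1000, seed = 100)
  expect_false(identical(a$se, c$se))
})

test_that("maximum likelihood reduces to IVW as gene-exposure error
           vanishes and recovers simulated effects", {
  h <- h_sim(L = 30, theta = 0.3, seed = 7, sex = 1e-8)
  ml <- mr_max_likelihood(h)
  iv <- mr_ivw(h, "fixed")
  expect_equal(ml$beta, iv$beta, tolerance = 1e-4)
  # single entry: the Wald ratio
  h1 <- harmonized_set("rs1", 0.1, 0.01, 0.05, 0.02)
  expect_equal(mr_max_likelihood(h1)$beta, 0.5)
  # parameter recovery on a 50-variant set
  h50 <- h_sim(L = 50, theta = 0.3, seed = 8, sex = 0.01)
  ml50 <- mr_max_likelihood(h50)
  expect_lt(abs(ml50$beta - 0.3), 3 * ml50$se)
})

test_that("RAPS with l2 loss and negligible gene-exposure error matches
           IVW, and Huber resists a gross outlier better than l2", {
  h <- h_sim(L = 30, theta = 0.25, seed = 9, sex = 1e-9)
  r2 <- mr_raps(h, loss = "l2")
  iv <- mr_ivw(h, "fixed")
  expect_equal(r2$beta, iv$beta, tolerance = 1e-3)

  # clean data: huber and l2 agree within half a standard error
  hclean <- h_sim(L = 40, theta = 0.25, seed = 10, sex = 0.002)
  rh <- mr_raps(hclean, loss = "huber")
  rl <- mr_raps(hclean, loss = "l2")
  expect_lt(abs(rh$beta - rl$beta), 0.5 * rl$se)

  # one gross outlier: the huber estimate moves strictly less
  d <- as.data.frame(hclean)
  d$by[1] <- d$by[1] + 0.5
  hout <- harmonized_set(d$variant_id, d$bx, d$sex, d$by, d$sey)
  rh2 <- mr_raps(hout, loss = "huber")
  rl2 <- mr_raps(hout, loss = "l2")
  expect_lt(abs(rh2$beta - rh$beta), abs(rl2$beta - rl$beta))
})

test_that("estimators are equivariant to outcome and exposure rescaling", {
  h <- h_sim(L = 25, theta = 0.3, seed = 11)
  d <- as.data.frame(h)
  cy <- 3.7
  hy <- harmonized_set(d$variant_id, d$bx, d$sex, cy * d$by, cy * d$sey)
  cx <- 0.4
  hx <- harmonized_set(d$variant_id, cx * d$bx, cx * d$sex, d$by, d$sey)
  for (m in c("ivw_fixed", "ivw_random", "egger", "max_likelihood")) {
    base <- mr_fit(h, m)
    sy <- mr_fit(hy, m)
    expect_equal(sy$beta, cy * base$beta, tolerance = 1e-6)
    expect_equal(sy$se, cy * base$se, tolerance = 1e-6)
    sx <- mr_fit(hx, m)
    expect_equal(sx$beta, base$beta / cx, tolerance = 1e-6)
  }
  # weighted median: equivariant point estimate (bootstrap se is stochastic)
  expect_equal(mr_weighted_median(hy, n_boot = 10)$beta,
               cy * mr_weighted_median(h, n_boot = 10)$beta, tolerance = 1e-10)
})

test_that("odds-ratio mapping follows the 1.96-se convention", {
  est <- mr_ivw(h_sim(L = 10, seed = 12), "fixed")
  expect_equal(est$or_value, exp(est$beta))
  expect_equal(est$or_low, exp(est$beta - 1.96 * est$se))
  expect_equal(est$or_high, exp(est$beta + 1.96 * est$se))
  expect_true(est$ci_low <= est$beta && est$beta <= est$ci_high)
})
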