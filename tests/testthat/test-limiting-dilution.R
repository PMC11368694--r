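test_that("single-dose estimate matches the closed form -log(1 - p) / d", {
  exp1 <- data.frame(dose = 100, tested = 10, responding = 5)
  est <- estimate_frequency(exp1)
  expect_equal(est$f_hat, -log(0.5) / 100, tolerance = 1e-6)
  expect_equal(est$denominator, 100 / log(2), tolerance = 1e-6)
  # grid-search oracle agrees
  expect_equal(est$f_hat, grid_mle_oracle(exp1), tolerance = 1e-3)
  expect_false(est$boundary)
  expect_true(est$ci_lower <= est$f_hat && est$f_hat <= est$ci_upper)
})

test_that("multi-dose MLE matches the brute-force grid oracle", {
  exp4 <- data.frame(dose = c(10, 50, 100, 1000), tested = 5,
                     responding = c(0, 3, 4, 5))
  est <- estimate_frequency(exp4)
  oracle <- grid_mle_oracle(exp4)
  expect_lt(abs(est$f_hat - oracle) / oracle, 1e-3)
  # Wald cross-check lands near the profile MLE
  expect_equal(est$wald$f_hat, est$f_hat, tolerance = 1e-4)
  # random experiments, same agreement
  set.seed(21)
  for (i in 1:20) {
    f <- 10^runif(1, -4, -1)
    doses <- sort(sample(c(5, 10, 50, 100, 500, 1000, 5000), 4))
    tested <- sample(4:8, 4, replace = TRUE)
    responding <- rbinom(4, tested, -expm1(-f * doses))
    e <- data.frame(dose = doses, tested = tested, responding = responding)
    if (sum(responding) == 0 || sum(tested - responding) == 0) next
    est_i <- estimate_frequency(e)
    oracle_i <- grid_mle_oracle(e)
    expect_lt(abs(est_i$f_hat - oracle_i) / oracle_i, 1e-3)
  }
})

test_that("boundary outcomes are flagged with one-sided intervals", {
  all_resp <- data.frame(dose = c(10, 100), tested = 5, responding = 5)
  est <- estimate_frequency(all_resp)
  expect_true(est$boundary)
  expect_gt(est$ci_lower, 0)
  expect_identical(est$ci_upper, Inf)
  none <- data.frame(dose = c(10, 100), tested = 5, responding = 0)
  est0 <- estimate_frequency(none)
  expect_true(est0$boundary)
  expect_identical(est0$f_hat, 0)
  # closed-form one-sided bound: f_up = qchisq(.95, 1) / (2 sum(t d))
  expect_equal(est0$ci_upper, qchisq(0.95, 1) / (2 * sum(5 * c(10, 100))))
  expect_error(estimate_frequency(data.frame(dose = numeric(),
                                             tested = numeric(),
                                             responding = numeric())),
               "empty")
})

test_that("parameter recovery and CI coverage behave over replications", {
  # reduced-size version of the full recovery study in the acceptance suite
  f_true <- 1 / 19
  n_sim <- 60
  f_hat <- numeric(n_sim); covered <- logical(n_sim)
  for (i in seq_len(n_sim)) {
    ld <- simulate_limiting_dilution(
      ld_sim_config(f_true, doses = c(10, 50, 100, 1000),
                    recipients_per_dose = 5, seed = 5000 + i))
    est <- estimate_frequency(ld)
    f_hat[i] <- est$f_hat
    covered[i] <- est$ci_lower <= f_true && f_true <= est$ci_upper
  }
  expect_lt(abs(median(f_hat) - f_true) / f_true, 0.2)
  expect_gte(mean(covered), 0.85)
})

test_that("subfraction adjustment scales the denominator by the fraction", {
  adj <- adjust_frequency_for_subfraction(1 / 34, 0.56)
  expect_equal(adj$denominator, 34 * 0.56)   # 19.04
  expect_identical(round(adj$denominator), 19)
  expect_equal(adjust_frequency_for_subfraction(1 / 19, 0.85)$denominator,
               16.15)
  # identity at fraction 1 and composition of fractions
  est <- estimate_frequency(
    data.frame(dose = c(10, 50, 100, 1000), tested = 5,
               responding = c(1, 3, 4, 5)))
  expect_equal(adjust_frequency_for_subfraction(est, 1)$f_hat, est$f_hat)
  two_step <- adjust_frequency_for_subfraction(
    adjust_frequency_for_subfraction(est, 0.8), 0.7)
  one_step <- adjust_frequency_for_subfraction(est, 0.8 * 0.7)
  expect_equal(two_step$f_hat, one_step$f_hat)
  expect_equal(two_step$ci_lower, one_step$ci_lower)
  # CI bounds scale identically with the point estimate
  adj2 <- adjust_frequency_for_subfraction(est, 0.5)
  expect_equal(adj2$ci_upper / est$ci_upper, 2)
  expect_error(adjust_frequency_for_subfraction(1 / 34, 0), "fraction")
  expect_error(adjust_frequency_for_subfraction(0.9, 0.5), "exceeds 1")
})

test_that("pool sizes are census times frequency, with propagated CI", {
  pool <- estimate_pool_size(1 / 19, 190)
  expect_equal(pool$pool, 10)
  expect_equal(estimate_pool_size(0, 190)$pool, 0)
  # homogeneity in the census count
  expect_equal(estimate_pool_size(1 / 19, 380)$pool, 2 * pool$pool)
  est <- estimate_frequency(
    data.frame(dose = c(10, 50, 100, 1000), tested = 5,
               responding = c(1, 3, 4, 5)))
  p <- estimate_pool_size(est, 1000, population = "x")
  expect_equal(p$ci_lower, 1000 * est$ci_lower)
  expect_equal(p$ci_upper, 1000 * est$ci_upper)
})

test_that("pool comparison reports ratios and shares summing to 100", {
  cmp <- compare_pools(c(iST = 20, iLT = 10))
  expect_equal(unname(cmp$ratio["iST", "iLT"]), 2)
  expect_equal(unname(cmp$shares_percent), c(200 / 3, 100 / 3))
  expect_equal(sum(cmp$shares_percent), 100)
  expect_equal(unname(compare_pools(c(5, 5))$shares_percent), c(50, 50))
  expect_error(compare_pools(c(0, 0)), "all pools are zero")
  expect_error(compare_pools(c(1)), "at least two")
  # pool_estimate objects are accepted
  pools <- list(estimate_pool_size(1 / 19, 380, "a"),
                estimate_pool_size(1 / 19, 190, "b"))
  expect_equal(unname(compare_pools(pools)$ratio["a", "b"]), 2)
})

test_that("slope diagnostic accepts single-hit data and flags two-hit data", {
  f <- 0.002
  doses <- c(25, 50, 100, 200, 400)
  n <- 2000
  set.seed(8)
  one_hit <- data.frame(
    dose = doses, tested = n,
    responding = rbinom(length(doses), n, -expm1(-f * doses)))
  d1 <- single_hit_adequacy(one_hit)
  expect_true(d1$available)
  expect_lt(abs(d1$slope - 1), 2 * d1$se)
  # two-hit response (1 - exp(-f d))^2: cloglog slope ~ 2 at small f d
  two_hit <- data.frame(
    dose = doses, tested = n,
    responding = rbinom(length(doses), n, (-expm1(-f * doses))^2))
  d2 <- single_hit_adequacy(two_hit)
  expect_gt(d2$slope, 1.5)
  expect_gt((d2$slope - 1) / d2$se, 2)
  # single-dose experiments carry no slope information
  d3 <- single_hit_adequacy(data.frame(dose = 100, tested = 10,
                                       responding = 5))
  expect_false(d3$available)
})
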