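test_that("sufficient statistics match direct summation", {
  ss <- suff_stats(bb_sample, bb_beta)
  # independent oracle: brute-force the defining sum
  w_direct <- 0
  for (i in 1:18)
    w_direct <- w_direct + (bb_removals[i] + 1) * bb_times[i]^(1 + bb_beta)
  expect_equal(ss$w, w_direct, tolerance = 1e-14)
  expect_equal(ss$w, 20.259, tolerance = 1e-4)
  expect_equal(ss$w_prime, ss$w / (1 + bb_beta))
  expect_equal(ss$m, 18)
  # complete sample, beta = 0: W is the plain total time on test
  s <- prog_cens_sample(censoring_scheme(4, 4, rep(0, 4)),
                        c(0.2, 0.5, 1.1, 2.0))
  expect_equal(suff_stats(s, 0)$w, sum(s$times))
  # prior rate shifts W'
  ssp <- suff_stats(bb_sample, bb_beta, gamma_prior(0.5, 0.001))
  expect_equal(ssp$w_prime, ss$w_prime + 0.001)
})

test_that("log-likelihood is stationary at the MLE and concave", {
  ah <- mle_alpha(bb_sample, bb_beta)
  h <- 1e-5
  grad <- (loglik_alpha(ah + h, bb_beta, bb_sample) -
           loglik_alpha(ah - h, bb_beta, bb_sample)) / (2 * h)
  expect_lt(abs(grad), 1e-6)
  # concavity: the MLE is the unique maximum on a grid
  grid <- seq(0.2, 5, by = 0.01)
  ll <- loglik_alpha(grid, bb_beta, bb_sample)
  expect_lt(max(ll), loglik_alpha(ah, bb_beta, bb_sample))
  # complete sample with beta = 0 reduces to the exponential log-likelihood
  s <- prog_cens_sample(censoring_scheme(4, 4, rep(0, 4)),
                        c(0.2, 0.5, 1.1, 2.0))
  for (a in c(0.3, 1, 2.5))
    expect_equal(loglik_alpha(a, 0, s), sum(dexp(s$times, a, log = TRUE)))
  # the scheme constant for a complete sample is log(n!)
  expect_equal(loglik_alpha(1, 0, s, include_constant = TRUE) -
                 loglik_alpha(1, 0, s),
               lfactorial(4))
})

test_that("ML estimators match pinned values and closed forms", {
  expect_equal(round(mle_alpha(bb_sample, bb_beta), 4), 1.1835)
  s <- prog_cens_sample(censoring_scheme(4, 4, rep(0, 4)),
                        c(0.2, 0.5, 1.1, 2.0))
  expect_equal(mle_alpha(s, 0), 4 / sum(s$times))
  # consistency at large complete samples
  set.seed(55)
  big <- prog_cens_sample(censoring_scheme(20000, 20000, rep(0, 20000)),
                          sort(rphfd(20000, phfd(1.092, 0.332))))
  expect_lt(abs(mle_alpha(big, 0.332) - 1.092) / 1.092, 0.02)
})

test_that("mle_c obeys functional invariance", {
  gc <- gamma_constants(bb_beta)
  expect_equal(mle_c(bb_sample, bb_beta, 0), gc$gamma1 / gc$gamma2)
  expect_equal(mle_c(bb_sample, bb_beta, 0.4411), 0.7398, tolerance = 1e-4)
  set.seed(60)
  for (k in 1:5) {
    sc <- build_scheme(sample(c("I", "II", "III"), 1), 18, 10)
    s <- rprogressive(sc, phfd(1.5, 0.7))
    fit <- phfd(mle_alpha(s, 0.7), 0.7)
    expect_equal(mle_c(s, 0.7, 0.3), c_index(fit, 0.3), tolerance = 1e-13)
  }
})

test_that("gamma prior construction and the improper limit", {
  expect_error(gamma_prior(0, 1), "positive")
  expect_error(gamma_prior(1, -1), "positive")
  expect_s3_class(gamma_prior(0, 0, improper = TRUE), "gamma_prior")
  pr0 <- gamma_prior(0, 0, improper = TRUE)
  expect_equal(bayes_alpha(bb_sample, bb_beta, pr0),
               mle_alpha(bb_sample, bb_beta))
  pp <- posterior_params(bb_sample, bb_beta, pr0)
  expect_equal(pp$shape, 18)
  expect_equal(pp$rate, suff_stats(bb_sample, bb_beta)$w / (1 + bb_beta))
})

test_that("conjugate posterior matches a brute-force grid posterior", {
  toy <- toy_sample()
  pr <- gamma_prior(2, 3)
  pp <- posterior_params(toy, 0.332, pr)
  expect_equal(pp$shape, 5 + 2)
  # independent oracle: normalise exp(loglik) * prior on a fine grid
  grid <- seq(1e-4, 15, length.out = 100000)
  dx <- grid[2] - grid[1]
  ll <- vapply(grid, loglik_alpha, 0, beta = 0.332, sample = toy)
  unnorm <- exp(ll) * dgamma(grid, pr$a, rate = pr$b)
  dens <- unnorm / (sum(unnorm) * dx)
  tv <- 0.5 * sum(abs(dens - dgamma(grid, pp$shape, rate = pp$rate))) * dx
  expect_lt(tv, 1e-4)
  grid_mean <- sum(grid * dens) * dx
  expect_equal(bayes_alpha(toy, 0.332, pr), grid_mean, tolerance = 1e-5)
})

test_that("Bayes point estimates match the fixture and a sampling oracle", {
  pr <- gamma_prior(0.001, 0.001)
  expect_equal(bayes_alpha(bb_sample, bb_beta, pr), 1.18346,
               tolerance = 1e-5)
  gc <- gamma_constants(bb_beta)
  expect_equal(bayes_c(bb_sample, bb_beta, 0, pr), gc$gamma1 / gc$gamma2)
  # posterior-sampling oracle for the index expectation
  pr2 <- gamma_prior(2, 3)
  pp <- posterior_params(bb_sample, bb_beta, pr2)
  set.seed(71)
  draws <- rgamma(20000, pp$shape, rate = pp$rate)
  ci <- vapply(draws, function(a) c_index(phfd(a, bb_beta), 0.4411), 0)
  se <- sd(ci) / sqrt(length(ci))
  expect_lt(abs(bayes_c(bb_sample, bb_beta, 0.4411, pr2) - mean(ci)), 3 * se)
})

test_that("the Bayes/ML estimate gap closes as m grows", {
  # the exact gamma-ratio factor over its plug-in approximation -> 1
  gap <- function(m) {
    p <- 1 / 1.332
    exp(lgamma(m + p) - lgamma(m)) / m^p
  }
  expect_lt(abs(gap(1000) - 1), abs(gap(10) - 1))
  expect_equal(gap(1000), 1, tolerance = 1e-3)
})

test_that("lower bounds reproduce the worked example", {
  lb_ml <- lower_bound_ml(0.9382, m = 18, beta = 0.332, delta = 0.05)
  expect_equal(lb_ml, 0.9201, tolerance = 2e-4)
  lb_bs <- lower_bound_bayes(0.9427, m = 18, a = 1, beta = 0.332,
                             delta = 0.05)
  expect_equal(lb_bs, 0.9274, tolerance = 1e-4)
  # the multiplier acts on the gap: zero gap is a fixed point
  gc <- gamma_constants(0.332)
  sup <- gc$gamma1 / gc$gamma2
  expect_equal(lower_bound_ml(sup, 18, 0.332, 0.05), sup)
  expect_equal(lower_bound_bayes(sup, 18, 1, 0.332, 0.05), sup)
  expect_equal(lower_bound_ml(sup, 18, 0.332, 0.05, calibrated = TRUE), sup)
})

test_that("closed-form bounds equal the direct statistic-based forms", {
  set.seed(77)
  for (k in 1:5) {
    sc <- build_scheme(c("I", "II", "III")[1 + k %% 3], 20, 12)
    p <- phfd(runif(1, 0.5, 3), 0.332)
    s <- rprogressive(sc, p)
    w <- suff_stats(s, 0.332)$w
    gc <- gamma_constants(0.332)
    q <- qchisq(0.95, 24)
    l_x <- 0.1
    ch <- mle_c(s, 0.332, l_x)
    direct_printed <- (gc$gamma1 -
      (q / (2 * 1.332 * w))^(1 / 1.332) * l_x) / gc$gamma2
    expect_equal(lower_bound_ml(ch, 12, 0.332, 0.05), direct_printed,
                 tolerance = 1e-12)
    direct_pivotal <- (gc$gamma1 -
      (q / (2 * w))^(1 / 1.332) * l_x) / gc$gamma2
    expect_equal(lower_bound_ml(ch, 12, 0.332, 0.05, calibrated = TRUE),
                 direct_pivotal, tolerance = 1e-12)
  }
})

test_that("the calibrated ML bound has exact frequentist coverage", {
  p <- phfd(1.092, 0.332)
  l_x <- 0.022
  ct <- c_index(p, l_x)
  sc <- build_scheme("III", 25, 15)
  set.seed(83)
  reps <- 1500
  cov <- mean(replicate(reps, {
    s <- rprogressive(sc, p)
    lower_bound_ml(mle_c(s, 0.332, l_x), 15, 0.332, 0.05,
                   calibrated = TRUE) <= ct
  }))
  se <- sqrt(0.95 * 0.05 / reps)
  expect_lt(abs(cov - 0.95), 3 * se)
})

test_that("exact credible bound is calibrated against the posterior", {
  toy <- toy_sample()
  pr <- gamma_prior(2, 3)
  lb <- lower_bound_bayes_exact(toy, 0.332, 0.5, pr, 0.05)
  pp <- posterior_params(toy, 0.332, pr)
  set.seed(91)
  draws <- rgamma(50000, pp$shape, rate = pp$rate)
  ci <- vapply(draws, function(a) c_index(phfd(a, 0.332), 0.5), 0)
  expect_lt(abs(mean(ci >= lb) - 0.95), 0.003)
  # delta -> 1 drives the chi-square quantile to 0 and the bound towards
  # the index supremum (the quantile decays like delta'^(1/(m+a)) so the
  # approach is slow; assert monotonicity and closeness, not equality)
  gc <- gamma_constants(0.332)
  lbs <- vapply(c(0.05, 0.5, 0.999, 1 - 1e-12),
                function(d) lower_bound_bayes_exact(toy, 0.332, 0.5, pr, d),
                0)
  expect_true(all(diff(lbs) > 0))
  expect_lt(gc$gamma1 / gc$gamma2 - lbs[4], 0.02)
  # closed-form credible bound approaches the exact one as m grows
  gap_at <- function(m) {
    sch <- censoring_scheme(m, m, rep(0L, m))
    set.seed(m)
    s <- rprogressive(sch, phfd(1.092, 0.332))
    ch <- bayes_c(s, 0.332, 0.1, pr)
    abs(lower_bound_bayes(ch, m, pr$a, 0.332, 0.05, calibrated = TRUE) -
          lower_bound_bayes_exact(s, 0.332, 0.1, pr, 0.05))
  }
  expect_lt(gap_at(200), gap_at(10))
})

test_that("Bayes machinery is self-consistent under prior draws", {
  # draw alpha from the prior, data given alpha; the 95% exact credible
  # bound should cover the realised index in ~95% of replicates
  pr <- gamma_prior(2, 3)
  sc <- build_scheme("I", 15, 10)
  l_x <- 0.1
  set.seed(97)
  reps <- 2000
  hits <- replicate(reps, {
    a <- rgamma(1, pr$a, rate = pr$b)
    s <- rprogressive(sc, phfd(a, 0.332))
    lb <- lower_bound_bayes_exact(s, 0.332, l_x, pr, 0.05)
    c_index(phfd(a, 0.332), l_x) >= lb
  })
  se <- sqrt(0.95 * 0.05 / reps)
  expect_lt(abs(mean(hits) - 0.95), 3 * se)
})

test_that("lpi_test reproduces the published decisions", {
  # Bayes path with the published point estimate and a = 1
  res_bs <- lpi_test(bb_sample, bb_beta, l_x = 0.4411, c = 0.90,
                     delta = 0.05, method = "Bayes",
                     prior = gamma_prior(1, 0.001), c_hat = 0.9427)
  expect_equal(res_bs$lower_bound, 0.9274, tolerance = 1e-4)
  expect_true(res_bs$reject_h0)
  res_ml <- lpi_test(bb_sample, bb_beta, l_x = 0.4411, c = 0.90,
                     delta = 0.05, method = "ML", c_hat = 0.9382)
  expect_equal(res_ml$lower_bound, 0.9201, tolerance = 2e-4)
  expect_true(res_ml$reject_h0)
  expect_equal(round(res_ml$alpha_hat, 4), 1.1835)
  # c above the bound: no rejection
  res2 <- lpi_test(bb_sample, bb_beta, 0.4411, c = 1.2, delta = 0.05,
                   method = "ML", c_hat = 0.9382)
  expect_false(res2$reject_h0)
  # boundary: c exactly at the bound is inside [LB, Inf)
  res3 <- lpi_test(bb_sample, bb_beta, 0.4411, c = res_ml$lower_bound,
                   delta = 0.05, method = "ML", c_hat = 0.9382)
  expect_false(res3$reject_h0)
  expect_error(lpi_test(bb_sample, bb_beta, 0.4411, 0.9, 0.05,
                        method = "Bayes"), "prior")
})

test_that("type-I error at the boundary does not exceed the level", {
  # place the true index exactly at the tested level c: rejections should
  # occur at rate <= delta (exactly delta for the calibrated ML route)
  p <- phfd(1.092, 0.332)
  l_x <- 0.022
  ct <- c_index(p, l_x)
  sc <- build_scheme("I", 20, 12)
  set.seed(103)
  reps <- 1200
  rej <- mean(replicate(reps, {
    s <- rprogressive(sc, p)
    lb <- lower_bound_ml(mle_c(s, 0.332, l_x), 12, 0.332, 0.05,
                         calibrated = TRUE)
    ct < lb
  }))
  expect_lt(rej, 0.05 + 3 * sqrt(0.05 * 0.95 / reps))
})
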