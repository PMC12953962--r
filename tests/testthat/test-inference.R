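test_that("log likelihood matches closed forms and stays finite at extremes", {
  prior <- default_prior()
  spec <- model_spec(rep(c(1, 0), c(3, 2)), NULL, rep("ON", 5), prior)
  params0 <- list(alpha = 0, beta = numeric(0), sigma = 1, b = 0)
  expect_equal(log_likelihood(params0, spec), 5 * log(0.5), tolerance = 1e-12)

  one <- model_spec(1, NULL, "ON", prior)
  p1 <- list(alpha = 0.45, beta = numeric(0), sigma = 1, b = 0)
  expect_equal(log_likelihood(p1, one), log(invlogit(0.45)),
               tolerance = 1e-12)

  # |eta| = 1000 with matching outcome: finite, no NaN
  expect_true(is.finite(log_likelihood(list(alpha = 1000, beta = numeric(0),
                                            sigma = 1, b = 0),
                                       model_spec(1, NULL, "ON", prior))))
  expect_true(is.finite(log_likelihood(list(alpha = -1000, beta = numeric(0),
                                            sigma = 1, b = 0),
                                       model_spec(0, NULL, "ON", prior))))
  expect_error(log_likelihood(list(alpha = 0, beta = c(1, 2), sigma = 1,
                                   b = 0), one),
               "one entry per covariate")
})

test_that("log prior matches a term-by-term oracle and rejects sigma <= 0", {
  prior <- default_prior()
  params <- list(alpha = prior$intercept_mean, beta = c(0.2, -0.1),
                 sigma = 1, b = c(0.3, -0.4))
  oracle <- dnorm(prior$intercept_mean, prior$intercept_mean, 1.18,
                  log = TRUE) +
    sum(dnorm(c(0.2, -0.1), 0, 0.5, log = TRUE)) +
    dexp(1, 1, log = TRUE) +
    sum(dnorm(c(0.3, -0.4), 0, 1, log = TRUE))
  expect_equal(log_prior(params, prior), oracle, tolerance = 1e-12)

  # doubling a province effect at fixed sigma strictly lowers the prior
  p2 <- params
  p2$b[1] <- 2 * p2$b[1]
  expect_lt(log_prior(p2, prior), log_prior(params, prior))

  # sigma -> 0 with nonzero b: density vanishes
  p3 <- params
  p3$sigma <- 1e-300
  expect_equal(log_prior(p3, prior), -Inf)
  p4 <- params
  p4$sigma <- -1
  expect_equal(log_prior(p4, prior), -Inf)
})

test_that("with no data the posterior reproduces the prior", {
  prior <- default_prior()
  spec <- model_spec(numeric(0), NULL, character(0), prior)
  fit <- quick_fit(spec, seed = 91, n_warmup = 600, n_iter = 1500)
  m <- as_draws_matrix(fit)
  mc_se <- sd(m[, "alpha"]) / sqrt(ess_mean(fit$draws[, , "alpha"]))
  expect_equal(mean(m[, "alpha"]), prior$intercept_mean,
               tolerance = 4 * mc_se + 0.02)
  expect_equal(sd(m[, "alpha"]), prior$intercept_sd, tolerance = 0.1)
  expect_equal(mean(m[, "sigma"]), 1, tolerance = 0.1)
})

test_that("MCMC matches 1-D quadrature for the model without random effects", {
  # 73 successes of 96 trials, single logistic intercept
  prior <- default_prior()
  y <- rep(c(1, 0), c(73, 23))
  spec <- model_spec(y, NULL, NULL, prior, include_re = FALSE)
  fit <- sample_posterior(spec, n_chains = 4, n_warmup = 1000, n_iter = 2000,
                          thin = 2, seed = 8)
  expect_true(fit$convergence$pass)
  m <- as_draws_matrix(fit)

  post <- function(a) {
    exp(73 * a - 96 * log1p(exp(a)) +
          dnorm(a, prior$intercept_mean, prior$intercept_sd, log = TRUE))
  }
  z <- integrate(post, -5, 5, rel.tol = 1e-10)$value
  mean_p <- integrate(function(a) invlogit(a) * post(a), -5, 5,
                      rel.tol = 1e-10)$value / z
  mean_a <- integrate(function(a) a * post(a), -5, 5,
                      rel.tol = 1e-10)$value / z
  expect_equal(mean(invlogit(m[, "alpha"])), mean_p, tolerance = 0.01)
  expect_equal(mean(m[, "alpha"]), mean_a, tolerance = 0.01)
})

test_that("sampling is deterministic under a fixed seed", {
  gen <- generate_survey(synthetic_config(n_respondents = 60, seed = 4))
  cc <- suppressMessages(complete_case_filter(gen$dataset))
  df <- cc$respondents
  spec <- model_spec(df$opioid_sparing, NULL, df$province, default_prior())
  f1 <- quick_fit(spec, seed = 77, n_warmup = 200, n_iter = 200)
  f2 <- quick_fit(spec, seed = 77, n_warmup = 200, n_iter = 200)
  expect_identical(f1$draws, f2$draws)
  f3 <- quick_fit(spec, seed = 78, n_warmup = 200, n_iter = 200)
  expect_false(identical(f1$draws, f3$draws))
})

test_that("log posterior is invariant under observation permutation", {
  gen <- generate_survey(synthetic_config(n_respondents = 50,
                                          missing_rate = 0, seed = 6))
  df <- gen$dataset$respondents
  prior <- default_prior()
  x <- dichotomize(gen$dataset, "age")
  spec <- model_spec(df$opioid_sparing, matrix(x, ncol = 1,
                                               dimnames = list(NULL, "age")),
                     df$province, prior)
  perm <- sample(seq_len(50))
  spec_p <- model_spec(df$opioid_sparing[perm],
                       matrix(x[perm], ncol = 1,
                              dimnames = list(NULL, "age")),
                       df$province[perm], prior)
  params <- list(alpha = 0.3, beta = 0.5, sigma = 0.7,
                 b = rnorm(length(spec$province_levels)))
  expect_equal(log_likelihood(params, spec), log_likelihood(params, spec_p),
               tolerance = 1e-12)
})

test_that("split R-hat and ESS behave on known chains", {
  set.seed(42)
  iid <- matrix(rnorm(4 * 2000), ncol = 4)
  expect_true(abs(split_rhat(iid) - 1) < 0.01)
  expect_gt(ess_mean(iid), 0.5 * 8000)

  apart <- cbind(rep(0, 100), rep(10, 100))
  expect_warning(r <- split_rhat(apart), "degenerate")
  # identical constant chains: degenerate path, reported as 1
  same <- cbind(rep(3, 100), rep(3, 100))
  expect_warning(expect_equal(split_rhat(same), 1), "degenerate")

  # two far-apart chains with a little within-chain noise: R-hat >> 1.1
  set.seed(1)
  noisy <- cbind(rnorm(200, 0, 0.1), rnorm(200, 10, 0.1))
  expect_gt(split_rhat(noisy), 10)
  expect_error(split_rhat(matrix(1:8, ncol = 1)), "at least 2 chains")
})

test_that("posterior summaries use equal-tailed interpolated quantiles", {
  const <- summarize_posterior(rep(2.5, 100))
  expect_equal(const$mean, 2.5)
  expect_equal(const$lower, 2.5)
  expect_equal(const$upper, 2.5)

  s <- summarize_posterior(as.numeric(1:1000), level = 0.90)
  expect_equal(s$lower, 50.95, tolerance = 1e-9)
  expect_equal(s$upper, 950.05, tolerance = 1e-9)

  set.seed(9)
  x <- rnorm(5000)
  s90 <- summarize_posterior(x, level = 0.90)
  s95 <- summarize_posterior(x, level = 0.95)
  expect_gte(s90$lower, s95$lower)
  expect_lte(s90$upper, s95$upper)
  expect_error(summarize_posterior(x, level = 0), "in \\(0, 1\\)")
})

test_that("probability-of-sparing functionals agree where they must", {
  zero <- fake_posterior_draws(alpha = rep(0, 400), sigma = rep(0.5, 400))
  expect_equal(probability_of_sparing(zero, "median_province"),
               rep(0.5, 400))

  degen <- fake_posterior_draws(alpha = rnorm(400, 0.45, 0.1),
                                sigma = rep(0, 400))
  expect_equal(probability_of_sparing(degen, "new_province", seed = 1),
               probability_of_sparing(degen, "median_province"))

  # fixed alpha = 0.45, sigma = 1: the marginal mean shrinks toward 0.5
  fixed <- fake_posterior_draws(alpha = rep(0.45, 20000),
                                sigma = rep(1, 20000))
  p_new <- probability_of_sparing(fixed, "new_province", seed = 2)
  expect_lt(mean(p_new), invlogit(0.45))
  expect_gt(mean(p_new), 0.5)
  # and reproducibly so
  expect_identical(p_new,
                   probability_of_sparing(fixed, "new_province", seed = 2))
})

test_that("an all-zero covariate leaves probability functionals unchanged", {
  gen <- generate_survey(synthetic_config(n_respondents = 80,
                                          missing_rate = 0, seed = 12))
  df <- gen$dataset$respondents
  prior <- default_prior()
  base <- model_spec(df$opioid_sparing, NULL, df$province, prior)
  zero <- model_spec(df$opioid_sparing,
                     matrix(0, nrow = 80, ncol = 1,
                            dimnames = list(NULL, "null")),
                     df$province, prior)
  f_base <- quick_fit(base, seed = 5, n_warmup = 600, n_iter = 1200)
  f_zero <- quick_fit(zero, seed = 5, n_warmup = 600, n_iter = 1200)
  p_base <- mean(probability_of_sparing(f_base, "median_province"))
  p_zero <- mean(probability_of_sparing(f_zero, "median_province"))
  expect_equal(p_base, p_zero, tolerance = 0.015)
})
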