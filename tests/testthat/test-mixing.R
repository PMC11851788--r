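test_that("log-posterior matches a hand-expanded arithmetic oracle", {
  src <- toy_sources_2()
  obs <- matrix(c(-17.5, 9.2), 1, 2,
                dimnames = list(NULL, c("d13c", "d15n")))
  pr <- mixing_problem(obs, src, residual_error = FALSE)
  p <- c(0.35, 0.65)
  # independent term-by-term evaluation
  mu_c <- 0.35 * (-21 + 1) + 0.65 * (-16 + 1)
  mu_n <- 0.35 * (5 + 3) + 0.65 * (11 + 3)
  v_c <- 0.35^2 * (0.8^2 + 0.3^2) + 0.65^2 * (0.8^2 + 0.3^2)
  v_n <- 0.35^2 * (0.7^2 + 0.3^2) + 0.65^2 * (0.7^2 + 0.3^2)
  by_hand <- dnorm(-17.5, mu_c, sqrt(v_c), log = TRUE) +
    dnorm(9.2, mu_n, sqrt(v_n), log = TRUE) +
    lgamma(2)  # Dirichlet(1,1) normalizing constant; (a-1)log p terms vanish
  expect_equal(log_posterior(p, pr), by_hand, tolerance = 1e-12)
})

test_that("log-posterior respects symmetry and the simplex contract", {
  # exchangeable sources + data at the midpoint: density symmetric in p
  src <- source_summary(c("L", "R"), mean_c = c(-20, -16), sd_c = 1,
                        mean_n = c(6, 10), sd_n = 1,
                        tef_mean_c = 0, tef_sd_c = 0.2,
                        tef_mean_n = 0, tef_sd_n = 0.2)
  obs <- matrix(c(-18, 8), 1, 2, dimnames = list(NULL, c("d13c", "d15n")))
  pr <- mixing_problem(obs, src, residual_error = FALSE)
  for (q in c(0.1, 0.3, 0.45)) {
    expect_equal(log_posterior(c(q, 1 - q), pr),
                 log_posterior(c(1 - q, q), pr), tolerance = 1e-12)
  }
  expect_error(log_posterior(c(0.6, 0.6), pr), "simplex")

  # single source: density does not depend on any free proportion
  src1 <- source_summary("only", -18, 0.5, 8, 0.5)
  pr1 <- mixing_problem(obs, src1, residual_error = FALSE)
  expect_true(is.finite(log_posterior(1, pr1)))
})

test_that("MCMC draws live on the simplex with nested credible intervals", {
  src <- toy_sources_3()
  obs <- simulate_obs(40, c(0.5, 0.3, 0.2), src, seed = 8)
  fit <- suppressWarnings(
    fit_mixture(mixing_problem(obs, src), chains = 2, iter = 3000,
                burn = 1500, thin = 3, seed = 8))
  pooled <- do.call(rbind, fit$draws)
  expect_true(all(abs(rowSums(pooled) - 1) < 1e-10))
  expect_true(all(pooled >= 0))
  s <- fit$summary
  expect_true(all(s$ci25_lo >= s$ci50_lo & s$ci25_hi <= s$ci50_hi))
  expect_true(all(s$ci50_lo >= s$ci75_lo & s$ci50_hi <= s$ci75_hi))
  expect_true(all(s$ci75_lo >= s$ci95_lo & s$ci75_hi <= s$ci95_hi))
  # seeding contract
  fit2 <- suppressWarnings(
    fit_mixture(mixing_problem(obs, src), chains = 2, iter = 3000,
                burn = 1500, thin = 3, seed = 8))
  expect_identical(fit$draws, fit2$draws)
})

test_that("data at one TEF-corrected source mean attributes to that source", {
  src <- source_summary(c("A", "B"), mean_c = c(-20, -15), sd_c = 0.05,
                        mean_n = c(5, 10), sd_n = 0.05,
                        tef_mean_c = 1, tef_sd_c = 0.05,
                        tef_mean_n = 3, tef_sd_n = 0.05)
  obs <- cbind(d13c = rep(-14, 20) + rnorm(20, 0, 0.01),
               d15n = rep(13, 20) + rnorm(20, 0, 0.01))
  fit <- suppressWarnings(
    fit_mixture(mixing_problem(obs, src), chains = 2, iter = 4000,
                burn = 2000, thin = 2, seed = 3))
  expect_gt(fit$summary$mean[fit$summary$source == "B"], 0.9)
})

test_that("with no consumers the posterior reverts to the Dirichlet prior", {
  src <- toy_sources_3()
  pr <- mixing_problem(matrix(numeric(0), 0, 2), src, residual_error = FALSE)
  fit <- suppressWarnings(fit_mixture(pr, chains = 2, iter = 8000,
                                      burn = 4000, thin = 2, seed = 5))
  expect_equal(fit$summary$mean, rep(1 / 3, 3), tolerance = 0.03)
})

test_that("single-source problems return certainty without sampling", {
  src1 <- source_summary("only", -18, 0.5, 8, 0.5)
  obs <- cbind(d13c = rnorm(5, -17), d15n = rnorm(5, 11))
  fit <- fit_mixture(mixing_problem(obs, src1, residual_error = FALSE))
  expect_equal(fit$summary$mean, 1)
  expect_true(fit$converged)
})

test_that("MCMC means agree with grid quadrature on a two-source toy", {
  src <- toy_sources_2()
  obs <- simulate_obs(25, c(0.6, 0.4), src, seed = 12)
  pr <- mixing_problem(obs, src, residual_error = FALSE)
  oracle <- grid_posterior_means(obs, src, step = 0.002)
  fit <- fit_mixture(pr, chains = 4, iter = 8000, burn = 4000, thin = 4,
                     seed = 12)
  expect_lt(mean(abs(fit$summary$mean - oracle)), 0.02)
})

test_that("problem validation catches malformed inputs", {
  src <- toy_sources_2()
  expect_error(mixing_problem(matrix(1, 2, 3), src), "two columns")
  expect_error(mixing_problem(cbind(d13c = NA_real_, d15n = 1), src),
               "finite")
  expect_error(mixing_problem(cbind(d13c = 1, d15n = 1), src,
                              prior = c(1, -1)))
  expect_error(source_summary("A", -20, -0.5, 5, 0.5), "SD")
})
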