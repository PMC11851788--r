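cov_toy_data <- function(n = 120, slope = c(0.8, -0.5), seed = 31,
                         src = toy_sources_3()) {
  set.seed(seed)
  depth <- runif(n, 10, 90)
  xs <- (depth - mean(depth)) / sd(depth)
  alpha <- ilr_transform(c(0.4, 0.35, 0.25))
  Z <- outer(xs, slope) + rep(alpha, each = n)
  P <- ilr_inverse(Z)
  mu <- cbind(src$mean_c + src$tef_mean_c, src$mean_n + src$tef_mean_n)
  w <- cbind(src$sd_c^2 + src$tef_sd_c^2, src$sd_n^2 + src$tef_sd_n^2)
  obs <- cbind(
    d13c = rnorm(n, P %*% mu[, 1], sqrt((P^2) %*% w[, 1] + 0.09)),
    d15n = rnorm(n, P %*% mu[, 2], sqrt((P^2) %*% w[, 2] + 0.09))
  )
  list(obs = obs, depth = depth, alpha = alpha, slope = slope, src = src)
}

test_that("covariate problems validate their inputs", {
  d <- cov_toy_data(20)
  expect_error(covariate_problem(d$obs, d$src, covariate = rep(40, 20)),
               "constant covariate")
  expect_error(covariate_problem(d$obs, d$src, covariate = d$depth[-1]),
               "one value per observation")
  expect_error(covariate_problem(d$obs, d$src,
                                 covariate = c(NA, d$depth[-1])), "finite")
})

test_that("null-slope data yield slope intervals covering zero and flat curves", {
  d <- cov_toy_data(100, slope = c(0, 0), seed = 32)
  cp <- covariate_problem(d$obs, d$src, covariate = d$depth)
  fit <- suppressWarnings(fit_covariate_mixture(cp, chains = 2, iter = 6000,
                                                burn = 3000, thin = 3,
                                                seed = 32))
  cs <- fit$coef_summary
  sl <- cs[grepl("slope", cs$coef), ]
  expect_true(all(sl$lo95 <= 0 & sl$hi95 >= 0))
  cv <- diet_curves(fit, grid = c(20, 50, 80))
  for (s in unique(cv$source)) {
    band <- cv[cv$source == s, ]
    expect_true(max(band$mean) - min(band$mean) <
                  max(band$hi95 - band$lo95))
  }
})

test_that("with slopes pinned to zero the fit matches the plain mixing model", {
  d <- cov_toy_data(120, slope = c(0, 0), seed = 33)
  cp <- covariate_problem(d$obs, d$src, covariate = d$depth)
  cfit <- suppressWarnings(fit_covariate_mixture(cp, chains = 2, iter = 8000,
                                                 burn = 4000, thin = 4,
                                                 seed = 33, fix_beta = TRUE))
  plain <- suppressWarnings(fit_mixture(mixing_problem(d$obs, d$src),
                                        chains = 2, iter = 8000, burn = 4000,
                                        thin = 4, seed = 33))
  at_mean <- diet_curves(cfit, grid = mean(d$depth))
  expect_lt(mean(abs(at_mean$mean - plain$summary$mean)), 0.02)
})

test_that("curves sum to one everywhere and respect the extrapolation guard", {
  d <- cov_toy_data(80, seed = 34)
  cp <- covariate_problem(d$obs, d$src, covariate = d$depth)
  fit <- suppressWarnings(fit_covariate_mixture(cp, chains = 2, iter = 4000,
                                                burn = 2000, thin = 4,
                                                seed = 34))
  cv <- diet_curves(fit, grid = seq(15, 85, by = 10))
  sums <- tapply(cv$mean, cv$covariate, sum)
  expect_true(all(abs(sums - 1) < 1e-6))
  expect_error(diet_curves(fit, grid = 200), "extrapolates")
})

test_that("curves are invariant to affine rescaling of the covariate", {
  d <- cov_toy_data(60, seed = 35)
  cp1 <- covariate_problem(d$obs, d$src, covariate = d$depth)
  cp2 <- covariate_problem(d$obs, d$src, covariate = 10 * d$depth + 500)
  f1 <- suppressWarnings(fit_covariate_mixture(cp1, chains = 2, iter = 3000,
                                               burn = 1500, thin = 3,
                                               seed = 35))
  f2 <- suppressWarnings(fit_covariate_mixture(cp2, chains = 2, iter = 3000,
                                               burn = 1500, thin = 3,
                                               seed = 35))
  g <- c(20, 50, 80)
  expect_equal(diet_curves(f1, g)$mean, diet_curves(f2, 10 * g + 500)$mean,
               tolerance = 1e-12)
})

test_that("a two-source dominance crossover is recovered near its true depth", {
  # truth: sources swap dominance where the single ILR coordinate crosses 0
  src <- toy_sources_2()
  n <- 200
  set.seed(36)
  depth <- runif(n, 10, 90)
  xs <- (depth - mean(depth)) / sd(depth)
  x40 <- (40 - mean(depth)) / sd(depth)
  b <- 1.2
  a <- -b * x40                       # z = 0 exactly at 40 m
  P <- ilr_inverse(cbind(a + b * xs))
  mu <- cbind(src$mean_c + src$tef_mean_c, src$mean_n + src$tef_mean_n)
  w <- cbind(src$sd_c^2 + src$tef_sd_c^2, src$sd_n^2 + src$tef_sd_n^2)
  obs <- cbind(
    d13c = rnorm(n, P %*% mu[, 1], sqrt((P^2) %*% w[, 1] + 0.04)),
    d15n = rnorm(n, P %*% mu[, 2], sqrt((P^2) %*% w[, 2] + 0.04))
  )
  cp <- covariate_problem(obs, src, covariate = depth)
  fit <- suppressWarnings(fit_covariate_mixture(cp, chains = 2, iter = 6000,
                                                burn = 3000, thin = 3,
                                                seed = 36))
  grid <- seq(15, 85, by = 0.5)
  cv <- diet_curves(fit, grid)
  gap <- cv$mean[cv$source == "A"] - cv$mean[cv$source == "B"]
  crossing <- grid[which.min(abs(gap))]
  expect_lt(abs(crossing - 40), 10)
})
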