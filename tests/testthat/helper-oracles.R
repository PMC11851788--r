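# Independent oracles and small fixture builders.
# The density below is coded directly from the mixture-of-moments formula
# with dnorm(), independently of isoweb::log_posterior().

# unnormalized posterior density of p for fixed residual SDs
oracle_density <- function(p, obs, src, resid_sd = c(0, 0), alpha = NULL) {
  if (is.null(alpha)) alpha <- rep(1, nrow(src))
  dens <- prod(p^(alpha - 1))
  mu <- cbind(src$mean_c + src$tef_mean_c, src$mean_n + src$tef_mean_n)
  w <- cbind(src$sd_c^2 + src$tef_sd_c^2, src$sd_n^2 + src$tef_sd_n^2)
  for (j in 1:2) {
    m <- sum(p * mu[, j])
    s <- sqrt(sum(p^2 * w[, j]) + resid_sd[j]^2)
    dens <- dens * prod(dnorm(obs[, j], m, s))
  }
  dens
}

# posterior proportion means by dense simplex-grid quadrature (K = 2 or 3)
grid_posterior_means <- function(obs, src, resid_sd = c(0, 0), step = 0.005,
                                 alpha = NULL) {
  K <- nrow(src)
  stopifnot(K %in% 2:3)
  eps <- step / 2
  g <- seq(eps, 1 - eps, by = step)
  if (K == 2) {
    pts <- cbind(g, 1 - g)
  } else {
    pts <- expand.grid(p1 = g, p2 = g)
    pts <- pts[pts$p1 + pts$p2 < 1 - eps, ]
    pts <- cbind(pts$p1, pts$p2, 1 - pts$p1 - pts$p2)
  }
  wts <- apply(pts, 1, oracle_density, obs = obs, src = src,
               resid_sd = resid_sd, alpha = alpha)
  colSums(pts * wts) / sum(wts)
}

# small well-separated source geometries for toy problems
toy_sources_2 <- function() {
  source_summary(c("A", "B"), mean_c = c(-21, -16), sd_c = c(0.8, 0.8),
                 mean_n = c(5, 11), sd_n = c(0.7, 0.7),
                 tef_mean_c = 1, tef_sd_c = 0.3,
                 tef_mean_n = 3, tef_sd_n = 0.3)
}

toy_sources_3 <- function() {
  source_summary(c("A", "B", "C"),
                 mean_c = c(-22, -17, -14), sd_c = c(0.8, 0.7, 0.9),
                 mean_n = c(4, 12, 7), sd_n = c(0.6, 0.8, 0.7),
                 tef_mean_c = 1, tef_sd_c = 0.3,
                 tef_mean_n = 3, tef_sd_n = 0.3)
}

# square-corner geometry in iso-space for the K = 4 recovery runs
recovery_sources_4 <- function() {
  source_summary(c("A", "B", "C", "D"),
                 mean_c = c(-22, -15, -15, -22), sd_c = rep(0.6, 4),
                 mean_n = c(4, 4, 12, 12), sd_n = rep(0.6, 4),
                 tef_mean_c = 1, tef_sd_c = 0.3,
                 tef_mean_n = 3, tef_sd_n = 0.3)
}

# simulate consumers straight from the mixing likelihood at fixed p
simulate_obs <- function(n, p, src, process_sd = c(0.3, 0.3), seed = 1) {
  set.seed(seed)
  mu <- cbind(src$mean_c + src$tef_mean_c, src$mean_n + src$tef_mean_n)
  w <- cbind(src$sd_c^2 + src$tef_sd_c^2, src$sd_n^2 + src$tef_sd_n^2)
  cbind(
    d13c = rnorm(n, sum(p * mu[, 1]), sqrt(sum(p^2 * w[, 1]) + process_sd[1]^2)),
    d15n = rnorm(n, sum(p * mu[, 2]), sqrt(sum(p^2 * w[, 2]) + process_sd[2]^2))
  )
}

# minimal stand-in posterior carrying a correlation matrix, for merge tests
fake_posterior <- function(corr, labels) {
  dimnames(corr) <- list(labels, labels)
  structure(list(correlation = corr), class = "mixing_posterior")
}
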