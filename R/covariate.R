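#' Define a continuous-covariate mixing problem
#'
#' Extends [mixing_problem()] with one covariate per consumer individual
#' (typically station depth in metres). Diet proportions vary with the
#' covariate through a linear model on ILR coordinates:
#' \eqn{p_i = ilr^{-1}(\alpha + \beta x_i)}, with the covariate standardized
#' to mean 0, SD 1 internally; reported curves are on the raw scale.
#'
#' @inheritParams mixing_problem
#' @param covariate Numeric vector, one value per observation row, finite,
#'   non-constant.
#' @return Object of class `covariate_problem` (also a `mixing_problem`).
#' @export
covariate_problem <- function(observations, sources, covariate, prior = NULL,
                              residual_error = TRUE, resid_scale = 2) {
  base <- mixing_problem(observations, sources, prior = prior,
                         residual_error = residual_error,
                         resid_scale = resid_scale)
  if (length(covariate) != nrow(base$observations)) {
    stop("`covariate` must have one value per observation", call. = FALSE)
  }
  if (!all(is.finite(covariate))) {
    stop("`covariate` must be finite", call. = FALSE)
  }
  if (stats::sd(covariate) == 0) {
    stop("constant covariate: use fit_mixture() instead", call. = FALSE)
  }
  if (base$K < 2) stop("need at least 2 sources", call. = FALSE)
  base$covariate <- covariate
  base$cov_center <- mean(covariate)
  base$cov_scale <- stats::sd(covariate)
  class(base) <- c("covariate_problem", class(base))
  base
}

# log target over (alpha, beta, log resid): N(0,1) priors on coefficients
# (standardized covariate scale), half-Cauchy on residual SDs.
.cov_target <- function(problem) {
  K <- problem$K
  basis <- ilr_basis(K)
  y <- problem$observations
  x <- (problem$covariate - problem$cov_center) / problem$cov_scale
  m <- .mix_matrices(problem$sources)
  re <- problem$residual_error
  s0 <- problem$resid_scale
  nc <- K - 1L
  function(theta) {
    alpha <- theta[seq_len(nc)]
    beta <- theta[nc + seq_len(nc)]
    resid2 <- c(0, 0)
    extra <- 0
    if (re) {
      u <- theta[2L * nc + 1:2]
      resid <- exp(u)
      resid2 <- resid^2
      extra <- sum(log(2 / (pi * s0 * (1 + (resid / s0)^2))) + u)
    }
    Z <- outer(x, beta) + rep(alpha, each = length(x))
    P <- ilr_inverse(Z, basis)
    ll <- 0
    for (j in 1:2) {
      mu <- P %*% m$mu[, j]
      v <- (P^2) %*% m$w[, j] + resid2[j]
      ll <- ll + sum(stats::dnorm(y[, j], mu, sqrt(v), log = TRUE))
    }
    ll + sum(stats::dnorm(c(alpha, beta), 0, 1, log = TRUE)) + extra
  }
}

#' Fit a mixing model with diet varying along a continuous covariate
#'
#' Random-walk Metropolis over ILR intercepts and slopes (plus residual SDs),
#' mirroring [fit_mixture()]'s sampler and convergence gate. Slope priors are
#' standard normal on the standardized covariate scale.
#'
#' @param problem A [covariate_problem()].
#' @param fix_beta Force all slopes to zero (used to compare against the
#'   covariate-free model); default `FALSE`.
#' @inheritParams fit_mixture
#' @return Object of class `covariate_fit` with `alpha`, `beta` (pooled draw
#'   matrices, columns = ILR coordinates), per-chain lists, `coef_summary`,
#'   `diagnostics`, `converged`, and the problem/settings. Use
#'   [diet_curves()] for proportion-vs-covariate curves.
#' @export
fit_covariate_mixture <- function(problem, chains = 4, iter = 10000,
                                  burn = iter / 2, thin = 5, seed = 1,
                                  fix_beta = FALSE) {
  stopifnot(inherits(problem, "covariate_problem"), iter > burn)
  K <- problem$K
  nc <- K - 1L
  target <- .cov_target(problem)
  d <- 2L * nc + if (problem$residual_error) 2L else 0L
  beta_idx <- nc + seq_len(nc)
  keep <- seq(burn + thin, iter, by = thin)
  alpha_l <- beta_l <- vector("list", chains)
  mask <- rep(FALSE, d)
  if (fix_beta) mask[beta_idx] <- TRUE
  for (ch in seq_len(chains)) {
    set.seed(seed + 1000L * (ch - 1L))
    theta <- stats::rnorm(d, 0, 0.3)
    if (fix_beta) theta[beta_idx] <- 0
    while (!is.finite(target(theta))) {
      theta <- stats::rnorm(d, 0, 0.1)
      if (fix_beta) theta[beta_idx] <- 0
    }
    out <- .rw_metropolis(target, theta, iter, burn, keep, mask = mask)
    alpha_l[[ch]] <- out[, seq_len(nc), drop = FALSE]
    beta_l[[ch]] <- out[, beta_idx, drop = FALSE]
  }
  alpha <- do.call(rbind, alpha_l)
  beta <- do.call(rbind, beta_l)
  colnames(alpha) <- paste0("ilr", seq_len(nc), "_intercept")
  colnames(beta) <- paste0("ilr", seq_len(nc), "_slope")
  qs <- function(m) {
    data.frame(coef = colnames(m), mean = colMeans(m),
               sd = apply(m, 2, stats::sd),
               lo95 = apply(m, 2, stats::quantile, 0.025, names = FALSE),
               hi95 = apply(m, 2, stats::quantile, 0.975, names = FALSE),
               row.names = NULL, stringsAsFactors = FALSE)
  }
  coef_summary <- rbind(qs(alpha), if (!fix_beta) qs(beta))
  diag <- NULL
  converged <- TRUE
  if (chains >= 2) {
    cols <- if (fix_beta) seq_len(nc) else seq_len(2L * nc)
    all_l <- lapply(seq_len(chains), function(ch) {
      cbind(alpha_l[[ch]], beta_l[[ch]])
    })
    rhat <- vapply(cols, function(k) {
      gelman_rubin(lapply(all_l, function(m) m[, k]))
    }, numeric(1))
    gew <- vapply(cols, function(k) {
      z <- vapply(all_l, function(m) geweke(m[, k]), numeric(1))
      abs(sum(z)) / sqrt(length(z))
    }, numeric(1))
    diag <- data.frame(coef = c(colnames(alpha), colnames(beta))[cols],
                       rhat = rhat, geweke_z = gew, stringsAsFactors = FALSE)
    converged <- all(rhat <= 1.1) && all(gew <= 2)
    if (!converged) {
      warning("covariate mixing model flagged as non-converged", call. = FALSE)
    }
  }
  structure(list(alpha = alpha, beta = beta, alpha_chains = alpha_l,
                 beta_chains = beta_l, coef_summary = coef_summary,
                 diagnostics = diag, converged = converged,
                 problem = problem, fix_beta = fix_beta,
                 settings = list(chains = chains, iter = iter, burn = burn,
                                 thin = thin, seed = seed)),
            class = "covariate_fit")
}

#' Diet-proportion curves along the covariate
#'
#' Evaluates posterior diet proportions on a covariate grid: for every
#' posterior draw, \eqn{p(x) = ilr^{-1}(\alpha + \beta x_{std})}; reports
#' the posterior mean and central 95% band per source and grid point. Grid
#' values beyond 10% extrapolation of the observed covariate range error out.
#'
#' @param fit A [fit_covariate_mixture()] result.
#' @param grid Covariate values (raw scale, e.g. depth in metres); default
#'   21 points over the observed range.
#' @return Data frame with columns `covariate`, `source`, `mean`, `lo95`,
#'   `hi95`; at every grid value the source means sum to 1.
#' @export
diet_curves <- function(fit, grid = NULL) {
  stopifnot(inherits(fit, "covariate_fit"))
  pr <- fit$problem
  rng <- range(pr$covariate)
  if (is.null(grid)) grid <- seq(rng[1], rng[2], length.out = 21)
  pad <- 0.1 * diff(rng)
  if (any(grid < rng[1] - pad | grid > rng[2] + pad)) {
    stop("grid extrapolates more than 10% beyond the observed covariate range",
         call. = FALSE)
  }
  basis <- ilr_basis(pr$K)
  xs <- (grid - pr$cov_center) / pr$cov_scale
  labs <- pr$sources$label
  out <- vector("list", length(grid))
  for (g in seq_along(grid)) {
    Z <- fit$alpha + fit$beta * xs[g]
    P <- ilr_inverse(Z, basis)
    out[[g]] <- data.frame(
      covariate = grid[g], source = labs,
      mean = colMeans(P),
      lo95 = apply(P, 2, stats::quantile, 0.025, names = FALSE),
      hi95 = apply(P, 2, stats::quantile, 0.975, names = FALSE),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}
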