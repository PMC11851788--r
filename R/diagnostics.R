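#' Gelman-Rubin potential scale reduction factor
#'
#' Compares between-chain and within-chain variance:
#' \eqn{\hat R = \sqrt{((n-1)/n\,W + B/n) / W}}, floored at 1 (the ratio it
#' estimates is >= 1 by construction, and identical chains give exactly 1).
#' Values near 1 indicate mixing; > 1.1 is the usual alarm.
#'
#' @param chains List of numeric vectors (one per chain, equal lengths,
#'   at least 2 chains and 4 draws each).
#' @return Scalar R-hat (>= 1).
#' @export
gelman_rubin <- function(chains) {
  if (!is.list(chains) || length(chains) < 2L) {
    stop("need at least 2 chains", call. = FALSE)
  }
  n <- unique(lengths(chains))
  if (length(n) != 1L) stop("chains must have equal lengths", call. = FALSE)
  if (n < 4L) stop("chains too short", call. = FALSE)
  means <- vapply(chains, mean, numeric(1))
  vars <- vapply(chains, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(if (B == 0) 1 else Inf)
  sqrt(max((W * (n - 1) / n + B / n) / W, 1))
}

# AR-based estimate of the spectral density at frequency zero,
# var(x) replaced by innovation variance / (1 - sum(phi))^2
.spectrum0_ar <- function(x) {
  x <- as.numeric(x)
  if (stats::var(x) == 0) return(0)
  fit <- stats::ar(x, aic = TRUE, order.max = min(length(x) - 1L,
                                                  floor(10 * log10(length(x)))))
  fit$var.pred / (1 - sum(fit$ar))^2
}

#' Geweke convergence score for a single chain
#'
#' Compares the mean of an early window against the mean of a late window,
#' standardized by spectral-density-at-zero standard errors:
#' \eqn{z = (\bar x_{first} - \bar x_{last}) / \sqrt{s_1/n_1 + s_2/n_2}}.
#' For a stationary chain z is approximately standard normal.
#'
#' @param chain Numeric vector of MCMC draws.
#' @param first Fraction of the chain in the early window (default 0.1).
#' @param last Fraction in the late window (default 0.5).
#' @return Scalar z score (0 for a constant chain).
#' @export
geweke <- function(chain, first = 0.1, last = 0.5) {
  stopifnot(first > 0, last > 0, first + last <= 1)
  n <- length(chain)
  n1 <- floor(first * n)
  n2 <- floor(last * n)
  if (n1 < 10L || n2 < 10L) {
    stop("chain too short for Geweke windows", call. = FALSE)
  }
  x1 <- chain[seq_len(n1)]
  x2 <- chain[(n - n2 + 1):n]
  s1 <- .spectrum0_ar(x1)
  s2 <- .spectrum0_ar(x2)
  denom <- sqrt(s1 / n1 + s2 / n2)
  if (denom == 0) return(0)
  (mean(x1) - mean(x2)) / denom
}
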