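# Shared adaptive random-walk Metropolis kernel.
#
# During burn-in only, the proposal adapts twice: a global scale steered
# toward ~30% acceptance, and (after enough draws) the proposal covariance
# is replaced by the empirical covariance of the burn-in history (Haario-
# style adaptive Metropolis), which aligns proposals with any posterior
# ridge. Both are frozen when burn-in ends, so kept draws come from a fixed
# kernel. `mask` marks coordinates held fixed at their initial value.
.rw_metropolis <- function(target, init, iter, burn, keep, mask = NULL) {
  d <- length(init)
  free <- if (is.null(mask)) rep(TRUE, d) else !mask
  df <- sum(free)
  theta <- init
  lt <- target(theta)
  stopifnot(is.finite(lt))
  scale <- 2.38 / sqrt(df)
  L <- diag(df)
  hist <- matrix(NA_real_, burn, d)
  acc <- 0L
  out <- matrix(NA_real_, length(keep), d)
  ki <- 1L
  for (it in seq_len(iter)) {
    step <- drop(L %*% stats::rnorm(df)) * scale
    prop <- theta
    prop[free] <- prop[free] + step
    lp <- target(prop)
    if (is.finite(lp) && log(stats::runif(1)) < lp - lt) {
      theta <- prop
      lt <- lp
      acc <- acc + 1L
    }
    if (it <= burn) {
      hist[it, ] <- theta
      if (it %% 50L == 0L) {
        scale <- scale * exp(1.5 * (acc / 50 - 0.3) / sqrt(it / 50))
        acc <- 0L
        if (it >= 400L && it %% 200L == 0L) {
          S <- stats::cov(hist[seq_len(it), free, drop = FALSE]) +
            diag(1e-8, df)
          ch <- tryCatch(chol(S), error = function(e) NULL)
          if (!is.null(ch)) {
            L <- t(ch)
            scale <- 2.38 / sqrt(df)
          }
        }
      }
    }
    if (ki <= length(keep) && it == keep[ki]) {
      out[ki, ] <- theta
      ki <- ki + 1L
    }
  }
  out
}
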