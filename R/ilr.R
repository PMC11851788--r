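#' Isometric log-ratio (ILR) basis for K-part compositions
#'
#' Returns a K x (K-1) matrix `V` with orthonormal columns spanning the
#' hyperplane orthogonal to `1`, built Helmert-style: coordinate j contrasts
#' the geometric mean of the first j parts with part j+1. The ILR transform is
#' `t(V) %*% log(p)` and its inverse is the closure of `exp(V %*% z)`.
#'
#' @param k Number of composition parts (>= 2).
#' @return K x (K-1) numeric matrix.
#' @export
ilr_basis <- function(k) {
  stopifnot(k >= 2)
  V <- matrix(0, k, k - 1L)
  for (j in seq_len(k - 1L)) {
    V[seq_len(j), j] <- 1 / j
    V[j + 1L, j] <- -1
    V[, j] <- V[, j] * sqrt(j / (j + 1))
  }
  V
}

#' ILR-transform a composition
#'
#' Maps an interior point of the K-simplex to K-1 unconstrained real
#' coordinates. For K = 2 this reduces to `sqrt(1/2) * log(p1/p2)`.
#'
#' @param p Composition: positive vector summing to 1, or a matrix with one
#'   composition per row.
#' @param basis ILR basis matrix (default [ilr_basis()]).
#' @return Numeric vector of length K-1, or a matrix with one row per input.
#' @export
ilr_transform <- function(p, basis = NULL) {
  vec <- is.null(dim(p))
  p <- rbind(p)
  if (any(p <= 0)) {
    stop("ILR is undefined on the simplex boundary (zero proportions)",
         call. = FALSE)
  }
  if (is.null(basis)) basis <- ilr_basis(ncol(p))
  z <- unname(log(p) %*% basis)
  if (vec) drop(z) else z
}

#' Inverse ILR transform
#'
#' Maps K-1 real coordinates back to the open K-simplex. Numerically safe:
#' the exponentials are shifted by their maximum before closure.
#'
#' @param z Real vector of length K-1, or a matrix with one row per point.
#' @param basis ILR basis matrix (default [ilr_basis()] for `ncol(z) + 1`).
#' @return Composition vector or matrix (rows sum to 1).
#' @export
ilr_inverse <- function(z, basis = NULL) {
  vec <- is.null(dim(z))
  z <- rbind(z)
  if (is.null(basis)) basis <- ilr_basis(ncol(z) + 1L)
  lp <- z %*% t(basis)
  lp <- lp - apply(lp, 1L, max)
  e <- exp(lp)
  p <- unname(e / rowSums(e))
  if (vec) drop(p) else p
}
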