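#' Cubic regression spline basis with curvature penalty
#'
#' Builds the design and penalty matrices for a single penalized smooth via
#' cubic regression splines (knots at quantiles of `x`), with an integrated
#' squared second derivative penalty. Linear functions of `x` lie in the
#' penalty null space. Used as the building block of [fit_additive()].
#'
#' @param x Covariate values; needs at least `k` distinct values.
#' @param k Basis dimension (default 10, minimum 3).
#' @param center Absorb the sum-to-zero identifiability constraint, dropping
#'   one column (default `FALSE`; [fit_additive()] uses `TRUE`).
#' @return List with `X` (n x k design), `S` (k x k penalty, symmetric PSD)
#'   and `smooth` (the underlying smooth object, reusable for prediction).
#' @export
spline_basis <- function(x, k = 10, center = FALSE) {
  stopifnot(k >= 3)
  if (length(unique(x)) < k) {
    stop("need at least `k` distinct covariate values", call. = FALSE)
  }
  dat <- data.frame(x = as.numeric(x))
  sm <- mgcv::smoothCon(mgcv::s(x, k = k, bs = "cr"), data = dat,
                        absorb.cons = center)[[1]]
  list(X = sm$X, S = sm$S[[1]], smooth = sm)
}

# penalized least squares at fixed lambda vector from precomputed
# cross-products; RSS and edf need no n-dimensional work
.pls_fit <- function(XtX, Xty, yty, blocks, S_list, lambda) {
  A <- XtX
  for (j in seq_along(S_list)) {
    idx <- blocks[[j]]
    A[idx, idx] <- A[idx, idx] + lambda[j] * S_list[[j]]
  }
  Ainv <- tryCatch(solve(A), error = function(e) NULL)
  if (is.null(Ainv)) return(NULL)
  b <- drop(Ainv %*% Xty)
  AX <- Ainv %*% XtX              # A^{-1} X'X, trace = edf
  rss <- max(drop(yty - 2 * crossprod(b, Xty) + crossprod(b, XtX %*% b)), 0)
  list(coef = b, rss = rss, edf = sum(diag(AX)),
       edf_by_col = diag(AX), Ainv = Ainv)
}

#' Fit a Gaussian additive model with GCV-chosen smoothing
#'
#' Penalized least squares over cubic-regression-spline smooths, one per
#' term, identity link. Per-term smoothing parameters are chosen by
#' coordinate descent of generalized cross-validation,
#' \eqn{GCV = n\,RSS/(n - tr(H))^2}, over a grid of `log10(lambda)` from -4
#' to 4 in steps of 0.25, two sweeps. Per-term F statistics are Wald-type
#' approximations on `n - tr(H)` residual degrees of freedom.
#'
#' @param response Name of the response column.
#' @param terms Character vector of smooth-term covariate names.
#' @param data Data frame holding response and covariates.
#' @param k Basis dimension per smooth (default 10).
#' @param lambda Optional fixed smoothing-parameter vector (one per term);
#'   when supplied the GCV search is skipped.
#' @return Object of class `smooth_fit`: selected `lambda` per term, `edf`
#'   (total and per term), `coef`, `fitted`, `rss`, `gcv`, `aic`, `aicc`,
#'   `dev_expl` (fraction in [0, 1]), `r2_adj`, and an `anova` table of
#'   approximate per-term F tests.
#' @export
fit_additive <- function(response, terms, data, k = 10, lambda = NULL) {
  stopifnot(is.character(response), length(response) == 1,
            length(terms) >= 1, all(c(response, terms) %in% names(data)))
  y <- data[[response]]
  n <- length(y)
  bases <- lapply(terms, function(v) spline_basis(data[[v]], k, center = TRUE))
  X <- cbind(`(Intercept)` = rep(1, n),
             do.call(cbind, lapply(bases, `[[`, "X")))
  pj <- vapply(bases, function(b) ncol(b$X), integer(1))
  stops <- cumsum(pj)
  blocks <- lapply(seq_along(terms), function(j) {
    (1L + c(0, stops)[j] + 1L):(1L + stops[j])
  })
  S_list <- lapply(bases, `[[`, "S")
  if (n <= 3) stop("too few observations", call. = FALSE)
  XtX <- crossprod(X)
  Xty <- drop(crossprod(X, y))
  yty <- sum(y^2)
  gcv_of <- function(lam) {
    f <- .pls_fit(XtX, Xty, yty, blocks, S_list, lam)
    if (is.null(f) || f$edf >= n) return(Inf)
    n * f$rss / (n - f$edf)^2
  }
  if (is.null(lambda)) {
    grid <- 10^seq(-4, 4, by = 0.25)
    lambda <- rep(1, length(terms))
    for (sweep in 1:2) {
      for (j in seq_along(terms)) {
        vals <- vapply(grid, function(g) {
          lam <- lambda
          lam[j] <- g
          gcv_of(lam)
        }, numeric(1))
        lambda[j] <- grid[which.min(vals)]
      }
    }
  } else {
    stopifnot(length(lambda) == length(terms), all(lambda >= 0))
  }
  fit <- .pls_fit(XtX, Xty, yty, blocks, S_list, lambda)
  if (is.null(fit)) {
    stop("rank-deficient additive design; collinear terms: ",
         paste(terms, collapse = ", "), call. = FALSE)
  }
  rss <- fit$rss
  tss <- sum((y - mean(y))^2)
  edf <- fit$edf
  edf_term <- vapply(blocks, function(ix) sum(fit$edf_by_col[ix]), numeric(1))
  sigma2 <- rss / (n - edf)
  gcv <- n * rss / (n - edf)^2
  kk <- edf + 1   # +1 for the error variance
  aic <- n * log(2 * pi * rss / n) + n + 2 * kk
  aicc <- if (n - kk - 1 > 0) aic + 2 * kk * (kk + 1) / (n - kk - 1) else Inf
  fstat <- vapply(seq_along(terms), function(j) {
    ix <- blocks[[j]]
    bj <- fit$coef[ix]
    num <- drop(crossprod(bj, XtX[ix, ix] %*% bj)) / edf_term[j]
    num / sigma2
  }, numeric(1))
  anova <- data.frame(term = terms, edf = edf_term, F = fstat,
                      p_value = stats::pf(fstat, edf_term, n - edf,
                                          lower.tail = FALSE),
                      stringsAsFactors = FALSE)
  structure(list(response = response, terms = terms, k = k, n = n,
                 lambda = lambda, coef = fit$coef,
                 fitted = drop(X %*% fit$coef),
                 edf = edf, edf_term = edf_term, rss = rss, tss = tss,
                 sigma2 = sigma2, gcv = gcv, aic = aic, aicc = aicc,
                 dev_expl = 1 - rss / tss,
                 r2_adj = 1 - (rss / (n - edf)) / (tss / (n - 1)),
                 anova = anova, bases = bases, blocks = blocks,
                 Ainv = fit$Ainv, XtX = XtX, data = data,
                 note = "per-term F tests are Wald-type approximations"),
            class = "smooth_fit")
}

#' Partial smooth curve with 95% band
#'
#' Evaluates one fitted smooth term (centered, intercept excluded) over a
#' covariate grid with a Bayesian-covariance 95% interval.
#'
#' @param fit A [fit_additive()] result.
#' @param term Term name.
#' @param grid Covariate values (default 50 points over the observed range).
#' @return Data frame `x`, `fit`, `lo95`, `hi95`.
#' @export
smooth_curve <- function(fit, term, grid = NULL) {
  j <- match(term, fit$terms)
  if (is.na(j)) stop("unknown term: ", term, call. = FALSE)
  x <- fit$data[[term]]
  if (is.null(grid)) grid <- seq(min(x), max(x), length.out = 50)
  Xg <- mgcv::PredictMat(fit$bases[[j]]$smooth, data.frame(x = grid))
  ix <- fit$blocks[[j]]
  est <- drop(Xg %*% fit$coef[ix])
  V <- fit$sigma2 * fit$Ainv[ix, ix]
  se <- sqrt(pmax(rowSums((Xg %*% V) * Xg), 0))
  data.frame(x = grid, fit = est, lo95 = est - 1.96 * se,
             hi95 = est + 1.96 * se)
}

#' Exhaustive AICc subset selection of additive-model terms
#'
#' Fits every non-empty subset of the candidate covariates up to `max_terms`
#' smooths (all combinations, as in progressive model building) and ranks
#' models by AICc; ties break toward fewer terms, then lower GCV.
#'
#' @param response Response column name.
#' @param candidates Character vector of candidate covariates.
#' @param data Data frame.
#' @param max_terms Largest subset size fitted (default 4).
#' @param k Basis dimension per smooth.
#' @return List with `ranking` (data frame: `model`, `n_terms`, `aicc`,
#'   `gcv`, `dev_expl`, `r2_adj`, ordered best first) and `fits` (named list
#'   of `smooth_fit` objects keyed by formula string).
#' @export
select_model <- function(response, candidates, data, max_terms = 4, k = 10) {
  stopifnot(length(candidates) >= 1, max_terms >= 1)
  max_terms <- min(max_terms, length(candidates))
  subsets <- unlist(lapply(seq_len(max_terms), function(m) {
    utils::combn(candidates, m, simplify = FALSE)
  }), recursive = FALSE)
  fits <- list()
  rows <- list()
  failures <- character(0)
  for (s in subsets) {
    key <- paste0(response, " ~ ", paste0("s(", s, ")", collapse = " + "))
    f <- tryCatch(fit_additive(response, s, data, k),
                  error = function(e) conditionMessage(e))
    if (is.character(f)) {
      failures[key] <- f
      next
    }
    fits[[key]] <- f
    rows[[key]] <- data.frame(model = key, n_terms = length(s),
                              aicc = f$aicc, gcv = f$gcv,
                              dev_expl = f$dev_expl, r2_adj = f$r2_adj,
                              stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    stop("all candidate fits failed:\n",
         paste(names(failures), failures, sep = ": ", collapse = "\n"),
         call. = FALSE)
  }
  ranking <- do.call(rbind, rows)
  ord <- order(ranking$aicc, ranking$n_terms, ranking$gcv)
  ranking <- ranking[ord, , drop = FALSE]
  rownames(ranking) <- NULL
  list(ranking = ranking, fits = fits, failures = failures)
}
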