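#' Merge isotopically confounded, ecologically similar sources
#'
#' In under-determined mixing models, overlapping sources produce strongly
#' negatively correlated posterior proportions. A source pair is merged when
#' its posterior proportion correlation exceeds the threshold in absolute
#' value (strictly; ties are left unmerged) AND the pair is declared
#' ecologically similar by the caller (same water layer, similar feeding).
#' Transitive chains are resolved by union-find. The caller must refit the
#' returned problem under the same MCMC settings.
#'
#' Combined moments are moment-matched pooling over members: mean of means,
#' and variance = mean of variances + population variance of means; the TEFs
#' pool the same way.
#'
#' @param posterior A [fit_mixture()] result carrying the proportion
#'   correlation matrix.
#' @param problem The [mixing_problem()] that produced it.
#' @param similar Two-column matrix or data frame of source label pairs the
#'   user declares ecologically similar; merged labels join with `" + "`
#'   unless a `label` column gives a name.
#' @param threshold Absolute-correlation threshold (default 0.5, strict).
#' @return List with `problem` (new [mixing_problem()], unchanged if nothing
#'   merged), `merged` (logical) and `log` (data frame of pair, correlation,
#'   new label).
#' @export
merge_sources <- function(posterior, problem, similar, threshold = 0.5) {
  stopifnot(inherits(posterior, "mixing_posterior"),
            inherits(problem, "mixing_problem"))
  labs <- problem$sources$label
  corr <- posterior$correlation
  if (is.null(corr) || nrow(corr) != length(labs)) {
    stop("posterior correlation matrix unavailable or mismatched",
         call. = FALSE)
  }
  label_col <- NULL
  if (is.data.frame(similar) && "label" %in% names(similar)) {
    label_col <- as.character(similar$label)
  }
  similar <- rbind(as.matrix(similar[, 1:2, drop = FALSE]))
  if (nrow(similar) > 0 && !all(similar %in% labs)) {
    stop("similarity flags name unknown sources: ",
         paste(setdiff(as.vector(similar), labs), collapse = ", "),
         call. = FALSE)
  }
  # union-find over sources
  parent <- seq_along(labs)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  log <- data.frame(source_a = character(), source_b = character(),
                    correlation = numeric(), new_label = character(),
                    stringsAsFactors = FALSE)
  pair_label <- character(0)
  for (r in seq_len(nrow(similar))) {
    i <- match(similar[r, 1], labs)
    j <- match(similar[r, 2], labs)
    if (i == j) stop("a source cannot be flagged similar to itself",
                     call. = FALSE)
    rho <- corr[i, j]
    if (abs(rho) > threshold) {
      ri <- find(i)
      rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      newlab <- if (!is.null(label_col) && nzchar(label_col[r])) {
        label_col[r]
      } else {
        NA_character_
      }
      log <- rbind(log, data.frame(source_a = labs[i], source_b = labs[j],
                                   correlation = rho,
                                   new_label = if (is.na(newlab)) "" else newlab,
                                   stringsAsFactors = FALSE))
      if (!is.na(newlab)) pair_label[as.character(find(i))] <- newlab
    }
  }
  roots <- vapply(seq_along(labs), find, integer(1))
  if (length(unique(roots)) == length(labs)) {
    return(list(problem = problem, merged = FALSE, log = log))
  }
  src <- problem$sources
  merged_rows <- lapply(unique(roots), function(rt) {
    idx <- which(roots == rt)
    if (length(idx) == 1L) return(src[idx, , drop = FALSE])
    lab <- pair_label[as.character(rt)]
    if (is.null(lab) || is.na(lab)) lab <- paste(src$label[idx], collapse = " + ")
    pool <- function(mu, sd) {
      m <- mean(mu[idx])
      v <- mean(sd[idx]^2) + mean((mu[idx] - m)^2)
      c(m, sqrt(v))
    }
    pc <- pool(src$mean_c, src$sd_c)
    pn <- pool(src$mean_n, src$sd_n)
    tc <- pool(src$tef_mean_c, src$tef_sd_c)
    tn <- pool(src$tef_mean_n, src$tef_sd_n)
    source_summary(lab, pc[1], pc[2], pn[1], pn[2],
                   tc[1], tc[2], tn[1], tn[2])
  })
  new_src <- do.call(rbind, merged_rows)
  class(new_src) <- c("source_summary", "data.frame")
  # prior concentrations of merged members add (aggregation of a Dirichlet)
  new_prior <- vapply(unique(roots), function(rt) {
    sum(problem$prior[roots == rt])
  }, numeric(1))
  newp <- mixing_problem(problem$observations, new_src, prior = new_prior,
                         residual_error = problem$residual_error,
                         resid_scale = problem$resid_scale)
  fill <- log$new_label == ""
  if (any(fill)) {
    for (r in which(fill)) {
      rt <- find(match(log$source_a[r], labs))
      log$new_label[r] <- new_src$label[match(rt, unique(roots))]
    }
  }
  list(problem = newp, merged = TRUE, log = log)
}
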