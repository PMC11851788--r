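#' Build source summaries from mean/SD specifications
#'
#' Thin validating wrapper turning a table of per-source isotope means and
#' SDs (plus optional TEFs) into a [source_summary()] usable both as
#' simulator ground truth and as mixing-model input.
#'
#' @param spec Data frame with columns `label`, `mean_c`, `sd_c`, `mean_n`,
#'   `sd_n` and optionally the four TEF columns of [source_summary()].
#' @return A `source_summary` table.
#' @export
generate_sources <- function(spec) {
  stopifnot(is.data.frame(spec),
            all(c("label", "mean_c", "sd_c", "mean_n", "sd_n") %in% names(spec)))
  args <- list(label = spec$label, mean_c = spec$mean_c, sd_c = spec$sd_c,
               mean_n = spec$mean_n, sd_n = spec$sd_n)
  for (col in c("tef_mean_c", "tef_sd_c", "tef_mean_n", "tef_sd_n")) {
    if (col %in% names(spec)) args[[col]] <- spec[[col]]
  }
  do.call(source_summary, args)
}

#' Simulated station environment table
#'
#' Stations are evenly spaced over the depth range; the other environment
#' variables are deterministic monotone functions of depth plus seeded noise,
#' emulating the correlated coastal-to-offshore gradients of a shallow
#' tropical gulf: temperatures fall with depth, salinity rises, and
#' chlorophyll-a decays roughly exponentially.
#'
#' @param n_stations Number of stations (default 24).
#' @param depth_range Depth range in metres (default `c(10, 90)`).
#' @param seed Integer seed.
#' @return Data frame: `station_id`, `depth`, `ss_temp`, `bot_temp`,
#'   `salinity`, `chla`.
#' @export
make_stations <- function(n_stations = 24, depth_range = c(10, 90), seed = 1) {
  stopifnot(n_stations >= 1, depth_range[1] < depth_range[2])
  set.seed(seed)
  depth <- if (n_stations == 1) {
    mean(depth_range)
  } else {
    seq(depth_range[1], depth_range[2], length.out = n_stations)
  }
  data.frame(
    station_id = sprintf("S%02d", seq_len(n_stations)),
    depth = depth,
    ss_temp = 30.5 - 0.015 * depth + stats::rnorm(n_stations, 0, 0.3),
    bot_temp = 30.0 - 0.110 * depth + stats::rnorm(n_stations, 0, 0.5),
    salinity = 30.0 + 0.045 * depth + stats::rnorm(n_stations, 0, 0.2),
    chla = exp(2.0 - 0.040 * depth + stats::rnorm(n_stations, 0, 0.2)),
    stringsAsFactors = FALSE
  )
}

#' Define a forward-simulation scenario
#'
#' Describes a synthetic food-web isotope study: the sources with their TEFs,
#' per-consumer-group true diet proportions (or ILR-linear depth trends),
#' sampling design, residual process noise and seed. The consumer model
#' mirrors the mixing likelihood exactly, so simulated data are conjugate to
#' the estimator for recovery tests.
#'
#' @param sources A [source_summary()] table (K sources).
#' @param true_diet Named list: one proportion vector of length K per
#'   consumer group (each sums to 1).
#' @param ilr_coeffs Optional named list (same names): each element a list
#'   with `intercept` and `slope`, length K-1 vectors on ILR scale applied to
#'   the group's standardized depths; overrides `true_diet` for that group.
#' @param n_consumers Consumers per group (default 30).
#' @param n_stations,depth_range Passed to [make_stations()].
#' @param process_sd Residual process SD per isotope, per mil
#'   (default `c(0.5, 0.5)`).
#' @param seed Integer seed; each group draws from its own substream so
#'   adding a group leaves others unchanged.
#' @return Object of class `scenario`.
#' @export
scenario <- function(sources, true_diet, ilr_coeffs = NULL, n_consumers = 30,
                     n_stations = 24, depth_range = c(10, 90),
                     process_sd = c(0.5, 0.5), seed = 1) {
  stopifnot(inherits(sources, "source_summary"), is.list(true_diet),
            length(true_diet) >= 1, !is.null(names(true_diet)))
  K <- nrow(sources)
  for (g in names(true_diet)) {
    p <- true_diet[[g]]
    if (length(p) != K || any(p < 0) || abs(sum(p) - 1) > 1e-12) {
      stop("true_diet[['", g, "']] must be length ", K,
           ", non-negative, summing to 1 within 1e-12", call. = FALSE)
    }
  }
  if (!is.null(ilr_coeffs)) {
    stopifnot(all(names(ilr_coeffs) %in% names(true_diet)))
    for (g in names(ilr_coeffs)) {
      stopifnot(length(ilr_coeffs[[g]]$intercept) == K - 1,
                length(ilr_coeffs[[g]]$slope) == K - 1)
    }
  }
  stopifnot(depth_range[1] < depth_range[2], n_stations >= 1,
            all(process_sd >= 0), length(process_sd) == 2, n_consumers >= 1)
  structure(list(sources = sources, true_diet = true_diet,
                 ilr_coeffs = ilr_coeffs, n_consumers = n_consumers,
                 n_stations = n_stations, depth_range = depth_range,
                 process_sd = process_sd, seed = as.integer(seed)),
            class = "scenario")
}

#' Forward-simulate consumers from a scenario
#'
#' Each consumer is assigned a station (round-robin over stations, so depths
#' are balanced within groups) and its isotope pair is drawn from the mixing
#' model's own distribution:
#' \eqn{y \sim N\big(\sum_k p_k(\mu_k+\Delta_k),\,
#' \sum_k p_k^2(\sigma_k^2+\tau_k^2) + \sigma_{proc}^2\big)} per isotope.
#' When a group has ILR coefficients, its diet varies with the group's
#' standardized depth through the inverse-ILR map; the realized per-consumer
#' proportions are recorded in the truth echo.
#'
#' @param scn A [scenario()].
#' @return Object of class `synthetic_dataset`: `samples` (one row per
#'   consumer: `sample_id`, `station_id`, `species`, `functional_group`,
#'   `d13c`, `d15n`, `c_to_n`, `depth`), `stations`, and `truth` (the
#'   scenario plus per-group realized proportion matrices).
#' @export
simulate_consumers <- function(scn) {
  stopifnot(inherits(scn, "scenario"))
  stations <- make_stations(scn$n_stations, scn$depth_range, scn$seed)
  m <- .mix_matrices(scn$sources)
  K <- nrow(scn$sources)
  basis <- if (K >= 2) ilr_basis(K) else NULL
  groups <- names(scn$true_diet)
  samples <- vector("list", length(groups))
  realized <- list()
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    n <- scn$n_consumers
    set.seed((scn$seed * 1000L + gi) %% 2147483647L)
    st_idx <- rep(seq_len(scn$n_stations), length.out = n)
    depth <- stations$depth[st_idx]
    cf <- scn$ilr_coeffs[[g]]
    if (!is.null(cf)) {
      xs <- if (stats::sd(depth) > 0) {
        (depth - mean(depth)) / stats::sd(depth)
      } else {
        rep(0, n)
      }
      Z <- outer(xs, cf$slope) + rep(cf$intercept, each = n)
      P <- ilr_inverse(Z, basis)
    } else {
      P <- matrix(scn$true_diet[[g]], n, K, byrow = TRUE)
    }
    mu_c <- P %*% m$mu[, 1]
    mu_n <- P %*% m$mu[, 2]
    v_c <- (P^2) %*% m$w[, 1] + scn$process_sd[1]^2
    v_n <- (P^2) %*% m$w[, 2] + scn$process_sd[2]^2
    samples[[gi]] <- data.frame(
      sample_id = sprintf("%s_%03d", gsub("[^A-Za-z0-9]", "", g), seq_len(n)),
      station_id = stations$station_id[st_idx],
      species = g,
      functional_group = g,
      d13c = stats::rnorm(n, mu_c, sqrt(v_c)),
      d15n = stats::rnorm(n, mu_n, sqrt(v_n)),
      c_to_n = 3.2,
      depth = depth,
      stringsAsFactors = FALSE
    )
    realized[[g]] <- P
  }
  samples <- do.call(rbind, samples)
  rownames(samples) <- NULL
  structure(list(samples = samples, stations = stations,
                 truth = list(scenario = scn, proportions = realized)),
            class = "synthetic_dataset")
}

#' Impose a per-station baseline gradient on a synthetic dataset
#'
#' Adds station-specific offsets to every sample's isotope values, emulating
#' spatial drift of the isotopic baseline; the offsets are stored in the
#' truth echo so that [baseline_correct()] can be tested for exact inversion.
#'
#' @param dataset A [simulate_consumers()] result.
#' @param gradient Data frame `station_id`, `offset_c`, `offset_n` covering
#'   every station in the dataset.
#' @return The dataset with shifted samples and the gradient recorded under
#'   `truth$baseline_gradient`.
#' @export
simulate_baseline_gradient <- function(dataset, gradient) {
  stopifnot(inherits(dataset, "synthetic_dataset"), is.data.frame(gradient),
            all(c("station_id", "offset_c", "offset_n") %in% names(gradient)))
  idx <- match(dataset$samples$station_id, gradient$station_id)
  if (anyNA(idx)) {
    stop("gradient missing station(s): ",
         paste(unique(dataset$samples$station_id[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  dataset$samples$d13c <- dataset$samples$d13c + gradient$offset_c[idx]
  dataset$samples$d15n <- dataset$samples$d15n + gradient$offset_n[idx]
  dataset$truth$baseline_gradient <- gradient
  dataset
}
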