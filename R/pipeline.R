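#' Per-station isotopic baselines from a baseline functional group
#'
#' Computes the local baseline (mean delta13C and delta15N of the baseline
#' group's samples) per station. Stations without baseline samples borrow the
#' nearest sampled station by depth; borrowed rows are flagged and reported
#' via a message.
#'
#' @param samples Sample table with `functional_group`, `station_id`, `d13c`,
#'   `d15n`.
#' @param stations Station table with `station_id` and `depth`.
#' @param baseline_group Name of the baseline functional group (a long-lived
#'   primary consumer such as a filter-feeding bivalve).
#' @return List with `stations` (per-station `base_c`, `base_n`, `borrowed`),
#'   `mean_c`, `mean_n` (study-wide means over baseline samples).
#' @export
compute_baselines <- function(samples, stations, baseline_group) {
  base <- samples[samples$functional_group == baseline_group, , drop = FALSE]
  if (nrow(base) == 0) {
    stop("baseline group '", baseline_group, "' has no samples", call. = FALSE)
  }
  agg_c <- tapply(base$d13c, base$station_id, mean)
  agg_n <- tapply(base$d15n, base$station_id, mean)
  out <- stations[, c("station_id", "depth")]
  out$base_c <- unname(agg_c[out$station_id])
  out$base_n <- unname(agg_n[out$station_id])
  out$borrowed <- is.na(out$base_c)
  if (any(out$borrowed)) {
    have <- which(!out$borrowed)
    for (i in which(out$borrowed)) {
      j <- have[which.min(abs(out$depth[have] - out$depth[i]))]
      out$base_c[i] <- out$base_c[j]
      out$base_n[i] <- out$base_n[j]
    }
    message(sum(out$borrowed), " station(s) borrowed the nearest-depth baseline")
  }
  list(stations = out, mean_c = mean(base$d13c), mean_n = mean(base$d15n))
}

#' Apply the spatial baseline correction to a sample table
#'
#' @param samples Sample table (see [compute_baselines()]).
#' @param baselines Result of [compute_baselines()].
#' @return The sample table with corrected `d13c` and `d15n`.
#' @export
apply_baseline <- function(samples, baselines) {
  bt <- baselines$stations
  idx <- match(samples$station_id, bt$station_id)
  if (anyNA(idx)) {
    stop("no baseline for station(s): ",
         paste(unique(samples$station_id[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  samples$d13c <- baseline_correct(samples$d13c, bt$base_c[idx],
                                   baselines$mean_c)
  samples$d15n <- baseline_correct(samples$d15n, bt$base_n[idx],
                                   baselines$mean_n)
  samples
}

#' A small packaged demonstration scenario
#'
#' Three basal sources and two consumer groups with known diets, one of them
#' depth-dependent; small enough for an end-to-end pipeline smoke run.
#'
#' @param seed Integer seed.
#' @return A [scenario()].
#' @export
demo_scenario <- function(seed = 1) {
  src <- source_summary(
    label = c("POM", "Phytoplankton", "SOM"),
    mean_c = c(-20.7, -19.6, -16.5), sd_c = c(0.9, 0.9, 0.8),
    mean_n = c(3.6, 5.6, 8.2), sd_n = c(0.9, 0.6, 0.8),
    tef_mean_c = 1.0, tef_sd_c = 0.4, tef_mean_n = 3.3, tef_sd_n = 0.3
  )
  scenario(
    sources = src,
    true_diet = list(grazer = c(0.25, 0.60, 0.15),
                     benthic_feeder = c(0.15, 0.25, 0.60)),
    ilr_coeffs = list(benthic_feeder = list(
      intercept = ilr_transform(c(0.15, 0.25, 0.60)), slope = c(0.5, -0.4))),
    n_consumers = 40, n_stations = 12, depth_range = c(10, 90),
    process_sd = c(0.3, 0.3), seed = seed
  )
}

#' Run the full analysis pipeline on simulated or supplied data
#'
#' Orchestrates the fixed stage order: simulate (or ingest) -> lipid
#' correction -> spatial baseline correction -> group summaries and TEFs ->
#' topology -> per-consumer mixing models -> correlation-driven source
#' merging with rerun -> optional depth-covariate mixing -> additive-model
#' selection -> reports. Deterministic given `config$seed`; every stage's
#' settings are echoed into a JSON run manifest.
#'
#' @param config Named list (or path to a YAML file) with entries:
#'   `scenario` (a [scenario()]; default [demo_scenario()]), `baseline_group`,
#'   `topology` (edge data frame; default: every consumer group eats every
#'   source), `similar` (ecological-similarity pairs for [merge_sources()]),
#'   `depth_covariate` (consumer groups to refit with depth), `mcmc` (list:
#'   chains, iter, burn, thin), `merge_threshold`, `gam` (list: responses,
#'   candidates, max_terms, k), `seed`.
#' @param out_dir Output directory (created if needed).
#' @return Invisible list of stage results and written file paths.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("isoweb_run_")) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs needs the 'yaml' package", call. = FALSE)
    }
    config <- yaml::yaml.load_file(config)
  }
  defaults <- list(
    seed = 1, baseline_group = NULL, similar = NULL,
    depth_covariate = character(0), merge_threshold = 0.5,
    mcmc = list(chains = 4, iter = 4000, burn = 2000, thin = 4),
    gam = list(responses = c("d13c", "d15n"),
               candidates = c("depth", "ss_temp", "bot_temp", "salinity",
                              "chla"),
               max_terms = 4, k = 6)
  )
  config <- utils::modifyList(defaults, config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  logline <- function(stage, ...) message("[", stage, "] ", ...)
  fail <- function(stage, e) {
    stop("pipeline failed in stage '", stage, "': ", conditionMessage(e),
         " (partial outputs in ", out_dir, ")", call. = FALSE)
  }
  wcsv <- function(x, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(x, p, row.names = FALSE)
    paths[[name]] <<- p
    p
  }

  # -- simulate / ingest ------------------------------------------------
  stage <- "simulate"
  res <- tryCatch({
    scn <- config$scenario
    if (is.null(scn)) scn <- demo_scenario(config$seed)
    ds <- simulate_consumers(scn)
    logline(stage, nrow(ds$samples), " samples over ",
            nrow(ds$stations), " stations")
    ds
  }, error = function(e) fail(stage, e))
  wcsv(res$samples, "samples.csv")
  wcsv(res$stations, "stations.csv")

  # -- prep: lipid then baseline ---------------------------------------
  stage <- "prep"
  prep <- tryCatch({
    s <- res$samples
    s$d13c <- lipid_correct(s$d13c, s$c_to_n)
    baselines <- NULL
    if (!is.null(config$baseline_group)) {
      baselines <- compute_baselines(s, res$stations, config$baseline_group)
      s <- apply_baseline(s, baselines)
      logline(stage, "baseline-corrected against '", config$baseline_group, "'")
    }
    base_n <- if (is.null(baselines)) {
      min(s$d15n)   # fall back: anchor TL at the most depleted group
    } else {
      baselines$mean_n
    }
    summaries <- summarize_groups(s, d15n_base = base_n)
    list(samples = s, baselines = baselines, summaries = summaries)
  }, error = function(e) fail(stage, e))
  wcsv(prep$summaries, "group_summaries.csv")

  # -- topology ---------------------------------------------------------
  stage <- "topology"
  topo <- tryCatch({
    if (!is.null(config$topology)) {
      config$topology
    } else {
      cons <- names(res$truth$scenario$true_diet)
      data.frame(
        predator_group = rep(cons, each = nrow(res$truth$scenario$sources)),
        prey_group = rep(res$truth$scenario$sources$label, length(cons)),
        stringsAsFactors = FALSE
      )
    }
  }, error = function(e) fail(stage, e))
  wcsv(topo, "topology.csv")

  # -- mixing per consumer group ---------------------------------------
  stage <- "mixing"
  mcmc <- config$mcmc
  scn_src <- res$truth$scenario$sources
  mixes <- tryCatch({
    out <- list()
    for (cg in unique(topo$predator_group)) {
      prey <- topo$prey_group[topo$predator_group == cg]
      obs <- prep$samples[prep$samples$functional_group == cg,
                          c("d13c", "d15n")]
      tefn <- proportional_tef(obs$d15n)
      src <- scn_src[match(prey, scn_src$label), , drop = FALSE]
      src$tef_mean_n <- mean(tefn)
      src$tef_sd_n <- stats::sd(tefn)
      class(src) <- c("source_summary", "data.frame")
      prob <- mixing_problem(as.matrix(obs), src)
      fit <- fit_mixture(prob, chains = mcmc$chains, iter = mcmc$iter,
                         burn = mcmc$burn, thin = mcmc$thin,
                         seed = config$seed)
      if (!is.null(config$similar)) {
        mg <- merge_sources(fit, prob, config$similar,
                            threshold = config$merge_threshold)
        if (mg$merged) {
          logline(stage, cg, ": merged ", nrow(mg$log), " source pair(s); rerun")
          fit <- fit_mixture(mg$problem, chains = mcmc$chains,
                             iter = mcmc$iter, burn = mcmc$burn,
                             thin = mcmc$thin, seed = config$seed)
          prob <- mg$problem
        }
      }
      logline(stage, cg, ": converged = ", fit$converged)
      out[[cg]] <- fit
    }
    out
  }, error = function(e) fail(stage, e))
  all_sum <- do.call(rbind, lapply(names(mixes), function(cg) {
    cbind(consumer = cg, mixes[[cg]]$summary)
  }))
  wcsv(all_sum, "mixing_summaries.csv")
  # diet matrix on the original topology only when no merging renamed sources
  dm <- tryCatch(assemble_diet_matrix(mixes, data.frame(
    predator_group = rep(names(mixes),
                         vapply(mixes, function(f) nrow(f$summary), 1L)),
    prey_group = unlist(lapply(mixes, function(f) f$summary$source)),
    stringsAsFactors = FALSE
  )), error = function(e) NULL)
  if (!is.null(dm)) {
    wcsv(data.frame(consumer = rownames(dm$formatted), dm$formatted,
                    check.names = FALSE), "diet_matrix.csv")
  }

  # -- depth-covariate mixing ------------------------------------------
  stage <- "covariate_mixing"
  curves <- tryCatch({
    out <- list()
    for (cg in config$depth_covariate) {
      sel <- prep$samples$functional_group == cg
      prey <- topo$prey_group[topo$predator_group == cg]
      src <- scn_src[match(prey, scn_src$label), , drop = FALSE]
      tefn <- proportional_tef(prep$samples$d15n[sel])
      src$tef_mean_n <- mean(tefn)
      src$tef_sd_n <- stats::sd(tefn)
      class(src) <- c("source_summary", "data.frame")
      cp <- covariate_problem(
        as.matrix(prep$samples[sel, c("d13c", "d15n")]), src,
        covariate = prep$samples$depth[sel])
      cf <- fit_covariate_mixture(cp, chains = mcmc$chains,
                                  iter = mcmc$iter, burn = mcmc$burn,
                                  thin = mcmc$thin, seed = config$seed)
      logline(stage, cg, ": converged = ", cf$converged)
      out[[cg]] <- cbind(consumer = cg, diet_curves(cf))
    }
    out
  }, error = function(e) fail(stage, e))
  if (length(curves) > 0) wcsv(do.call(rbind, curves), "diet_depth_curves.csv")

  # -- additive models --------------------------------------------------
  stage <- "gam"
  gams <- tryCatch({
    merged <- merge(prep$samples, res$stations, by = "station_id")
    out <- list()
    for (resp in config$gam$responses) {
      sel <- select_model(resp, config$gam$candidates, merged,
                          max_terms = config$gam$max_terms, k = config$gam$k)
      best <- sel$ranking[1, ]
      logline(stage, resp, ": best = ", best$model)
      out[[resp]] <- cbind(response = resp, n_obs = nrow(merged),
                           sel$ranking)
    }
    out
  }, error = function(e) fail(stage, e))
  wcsv(do.call(rbind, gams), "gam_selection.csv")

  # -- manifest ---------------------------------------------------------
  manifest <- list(
    package = "isoweb",
    version = as.character(utils::packageVersion("isoweb")),
    seed = config$seed,
    mcmc = mcmc,
    merge_threshold = config$merge_threshold,
    gam = config$gam,
    baseline_group = config$baseline_group,
    depth_covariate = config$depth_covariate,
    converged = vapply(mixes, function(f) isTRUE(f$converged), logical(1)),
    files = names(paths)
  )
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  paths[["manifest.json"]] <- mp
  invisible(list(dataset = res, prep = prep, topology = topo, mixing = mixes,
                 curves = curves, gams = gams, paths = paths,
                 out_dir = out_dir))
}
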