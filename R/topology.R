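#' Aggregate species-level stomach-content links to functional-group topology
#'
#' A group-level trophic link exists when at least one species of a predator
#' group was recorded eating at least one species of a prey group. Duplicate
#' species pairs collapse to a single edge; self-links are kept only if
#' present in the data.
#'
#' @param links Data frame with columns `predator` and `prey` (species
#'   labels).
#' @param group_map Named character vector mapping species label to
#'   functional-group label.
#' @return Data frame with columns `predator_group`, `prey_group`, one row
#'   per directed edge, ordered by predator then prey.
#' @export
build_topology <- function(links, group_map) {
  stopifnot(is.data.frame(links),
            all(c("predator", "prey") %in% names(links)))
  sp <- unique(c(as.character(links$predator), as.character(links$prey)))
  unmapped <- setdiff(sp, names(group_map))
  if (length(unmapped) > 0) {
    stop("species without a functional group: ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  }
  if (nrow(links) == 0L) {
    return(data.frame(predator_group = character(),
                      prey_group = character(), stringsAsFactors = FALSE))
  }
  edges <- unique(data.frame(
    predator_group = unname(group_map[as.character(links$predator)]),
    prey_group = unname(group_map[as.character(links$prey)]),
    stringsAsFactors = FALSE
  ))
  edges[order(edges$predator_group, edges$prey_group), , drop = FALSE]
}

#' Assemble a consumer-by-prey diet matrix from per-group posteriors
#'
#' Builds the standard diet matrix (consumers in rows, prey in columns, cell
#' `mean(sd)` of the posterior contribution) from one fitted mixing posterior
#' per consumer group, masked by the stomach-content topology: cells without
#' a trophic link stay blank.
#'
#' @param posteriors Named list of [fit_mixture()] results, one per consumer
#'   group; each posterior's source labels must cover the consumer's prey
#'   groups in `topology`.
#' @param topology Edge table from [build_topology()].
#' @return List of class `diet_matrix` with numeric matrices `mean` and `sd`
#'   (`NA` off-topology) and a character matrix `formatted` with `"m(sd)"`
#'   cells rounded to 2 digits.
#' @export
assemble_diet_matrix <- function(posteriors, topology) {
  consumers <- unique(topology$predator_group)
  missing <- setdiff(consumers, names(posteriors))
  if (length(missing) > 0) {
    stop("no posterior supplied for consumer group(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  prey <- unique(topology$prey_group)
  mean_m <- matrix(NA_real_, length(consumers), length(prey),
                   dimnames = list(consumers, prey))
  sd_m <- mean_m
  for (cg in consumers) {
    s <- posteriors[[cg]]$summary
    my_prey <- topology$prey_group[topology$predator_group == cg]
    absent <- setdiff(my_prey, s$source)
    if (length(absent) > 0) {
      stop("posterior for '", cg, "' lacks source(s): ",
           paste(absent, collapse = ", "), call. = FALSE)
    }
    idx <- match(my_prey, s$source)
    mean_m[cg, my_prey] <- s$mean[idx]
    sd_m[cg, my_prey] <- s$sd[idx]
  }
  fmt <- matrix("", nrow(mean_m), ncol(mean_m), dimnames = dimnames(mean_m))
  filled <- !is.na(mean_m)
  fmt[filled] <- sprintf("%.2f(%.2f)", mean_m[filled], sd_m[filled])
  structure(list(mean = mean_m, sd = sd_m, formatted = fmt),
            class = "diet_matrix")
}

#' @export
print.diet_matrix <- function(x, ...) {
  print(x$formatted, quote = FALSE)
  invisible(x)
}
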