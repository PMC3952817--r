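#' Fit Representatives: screen, anchors and Pareto front in one call
#'
#' The end-to-end estimation workflow: build the per-category objective
#' evaluator, run the hybrid global screen, solve the anchors and trace the
#' Pareto front with the Normalized Normal Constraint method.  When
#' `outdir` is given, writes `representatives.csv` (log10 parameters and
#' objective values, one row per Representative), `screen.csv`, and a
#' `manifest.json` recording the seed, budgets and fixture hash so the run
#' can be reproduced exactly.
#'
#' @param obs An `os_observations` table.
#' @param topology An `os_topology` (default [core_topology()]).
#' @param free Free parameter names (default: all edge half-maximal
#'   concentrations plus regulator production rates).
#' @param bounds Optional [param_bounds()] in log10 (default: two decades
#'   around the model's reference values).
#' @param budget Screen budget.
#' @param seed Master seed for all randomness in the run.
#' @param cfg An [nnc_config()] (its seed is overridden by `seed`).
#' @param scaling An [scaling_config()].
#' @param outdir Optional output directory.
#' @return An `os_pareto`, invisibly with attribute `screen`.
#' @export
fit_representatives <- function(obs, topology = core_topology(),
                                free = NULL, bounds = NULL,
                                budget = 2000L, seed = 1L,
                                cfg = nnc_config(), scaling = scaling_config(),
                                outdir = NULL) {
  model <- germarium_model(topology, rm = obs_region_map(obs))
  if (is.null(free)) {
    free <- c(grep("^K_", names(model$params), value = TRUE),
              paste0("phi_", topology$species))
  }
  if (is.null(bounds)) {
    ctr <- log10(model$params[free])
    bounds <- do.call(param_bounds, stats::setNames(
      lapply(free, function(f) unname(ctr[f]) + c(-1, 1)), free))
  }
  cfg$seed <- as.integer(seed)
  ev <- objective_evaluator(model, obs, free, scaling)
  scr <- screen(bounds, budget, seed, ev)
  front <- solve_front(ev, bounds, scr, cfg)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(front$representatives,
                     file.path(outdir, "representatives.csv"))
    readr::write_csv(tibble::as_tibble(as.data.frame(scr)),
                     file.path(outdir, "screen.csv"))
    write_manifest(outdir, list(
      workflow = "fit", topology = topology$name, free = free,
      budget = budget, seed = seed,
      n_observations = nrow(obs),
      obs_hash = obs_hash(obs),
      n_representatives = nrow(front$representatives)))
  }
  invisible(structure(front, screen = scr))
}

#' Screen alternative network topologies against Wild-Type data
#'
#' Runs the inhibitory strong/weak lattice screen over the supplied (or
#' enumerated) topologies and applies the parsimony filter.  Writes
#' `candidates.csv` and a manifest when `outdir` is given.
#'
#' @param obs An `os_observations` table (its WildType rows are used).
#' @param topologies List of topologies (default: inhibitory rewirings with
#'   at most `max_edges` edges).
#' @param max_edges Edge cap for the default enumeration (default 4,
#'   desk-scale).
#' @param threshold Acceptance threshold on the best Wild-Type error.
#' @param outdir Optional output directory.
#' @param ... Passed to [screen_wt()].
#' @return The candidate tibble with `parsimonious` flags.
#' @export
screen_networks <- function(obs, topologies = NULL, max_edges = 4L,
                            threshold = 0.05, outdir = NULL, ...) {
  obs_wt <- obs[obs$category == "WildType", ]
  attr(obs_wt, "region_map") <- obs_region_map(obs)
  if (nrow(obs_wt) == 0L) stop("no WildType observations", call. = FALSE)
  if (is.null(topologies)) topologies <- enumerate_inhibitory(max_edges)
  res <- screen_wt(topologies, obs_wt, threshold = threshold, ...)
  res <- parsimony_filter(res)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(res, file.path(outdir, "candidates.csv"))
    write_manifest(outdir, list(
      workflow = "screen-networks", n_topologies = length(topologies),
      threshold = threshold, obs_hash = obs_hash(obs_wt)))
  }
  res
}

#' Model-based experiment design over perturbation x measurement pairs
#'
#' Enumerates candidate experiments, simulates the qualitative prediction
#' ensembles of every model's Representatives, and scores each experiment
#' under the three qualitative design objectives (expected-prediction
#' variance and Jaccard dissimilarity for model discrimination; prediction
#' variance for parameter refinement).
#'
#' @param models Named list of `os_model`.
#' @param representatives Named list (same names) of Representative tibbles
#'   (log10 parameter columns).
#' @param conditions List of conditions (default [enumerate_conditions()];
#'   trim for desk-scale runs).
#' @param measured Species to measure (default the common observables).
#' @param outdir Optional output directory.
#' @return A DesignTable tibble: `experiment`, `species`, `objective`,
#'   `score`, `normalized`.
#' @export
design_experiments <- function(models, representatives,
                               conditions = enumerate_conditions(),
                               measured = c("pMad", "Bam", "Nos", "Brat",
                                            "dMyc", "Dpp"),
                               outdir = NULL) {
  if (length(models) < 2L)
    stop("discrimination objectives need at least two models", call. = FALSE)
  rows <- list()
  for (cond in conditions) {
    for (sp in measured) {
      ens <- prediction_ensembles(models, representatives, cond, sp)
      if (any(vapply(ens, nrow, integer(1)) == 0L)) next
      lab <- condition_label(cond)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        experiment = lab, species = sp,
        objective = c("expected_variance", "jaccard",
                      "prediction_variance"),
        score = c(objective_expected_variance(ens),
                  objective_jaccard(ens),
                  objective_prediction_variance(ens)))
    }
  }
  out <- rank_table(dplyr::bind_rows(rows))
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(out, file.path(outdir, "design.csv"))
    write_manifest(outdir, list(workflow = "design",
                                n_models = length(models),
                                n_conditions = length(conditions)))
  }
  out
}

obs_hash <- function(obs) {
  v <- utils::capture.output(utils::write.csv(as.data.frame(obs), ""))
  sum(utf8ToInt(paste(v, collapse = "\n")) *
        seq_along(utf8ToInt(paste(v, collapse = "\n")))) %% 2147483647
}

write_manifest <- function(outdir, fields) {
  fields$package_version <- as.character(utils::packageVersion("osfit"))
  fields$r_version <- as.character(getRversion())
  jsonlite::write_json(fields, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}
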