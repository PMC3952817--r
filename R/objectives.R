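#' Evaluate the per-category fitness objectives of a model
#'
#' Routes every observation through the right simulation protocol (steady
#' state, or post-division dynamic) and scores it by Optimal Scaling against
#' the corresponding model observable.  Simulations are shared across
#' observations with the same (condition, protocol), so the number of ODE
#' integrations never exceeds the number of distinct condition/protocol
#' pairs.  Each observation is scaled independently (scales differ between
#' antibodies and experiments, so no interval sharing across observations).
#'
#' Category values aggregate observation errors as
#' `E_cat = sqrt(sum_obs error_obs^2)`, i.e. the square root of the summed
#' per-domain mean cell errors over all of the category's observations.
#' Simulation failure marks the result failed with infinite values rather
#' than raising, so global screens survive pathological parameter corners.
#'
#' @param model An `os_model`.
#' @param obs An `os_observations` table.
#' @param params Optional replacement parameter vector (full, or a named
#'   subset overriding entries of `model$params`).
#' @param cfg An [scaling_config()].
#' @param keep_solutions Keep the per-observation `os_scaling` solutions
#'   (default `FALSE`; they are bulky).
#' @return An `os_objectives` object: list with `values` (named numeric,
#'   one entry per category present), `breakdown` (tibble: index, species,
#'   condition, category, error), `failed`, and optionally `solutions`.
#' @export
evaluate_objectives <- function(model, obs, params = NULL,
                                cfg = scaling_config(),
                                keep_solutions = FALSE) {
  if (!is.null(params)) {
    full <- model$params
    full[names(params)] <- params
    model$params <- full
  }
  rm <- obs_region_map(obs)
  cats <- intersect(OBS_CATEGORIES, unique(obs$category))
  key <- paste(obs$condition, obs$dynamic)
  sims <- list()
  n_obs <- nrow(obs)
  errors <- numeric(n_obs)
  failed <- FALSE
  solutions <- if (keep_solutions) vector("list", n_obs) else NULL

  for (i in seq_len(n_obs)) {
    k <- key[i]
    if (is.null(sims[[k]])) {
      cond <- parse_condition(obs$condition[i])
      sims[[k]] <- if (obs$dynamic[i]) simulate_dynamic(model, cond)
                   else simulate_steady(model, cond)
    }
    sim <- sims[[k]]
    if (sim$failed) { failed <- TRUE; break }
    y <- observable(sim, obs$species[i])
    ranks <- obs_cell_ranks(obs, i)
    observed <- which(!is.na(ranks))
    domains <- list()
    for (nm in rm$region_names) {
      d <- match(intersect(rm$regions[[nm]], observed), observed)
      if (length(d)) domains[[nm]] <- d
    }
    sol <- solve_scaling(y, ranks, obs$n_categories[i], domains, cfg)
    errors[i] <- sol$error
    if (keep_solutions) solutions[[i]] <- sol
  }

  if (failed) {
    values <- stats::setNames(rep(Inf, length(cats)), cats)
    errors <- rep(NA_real_, n_obs)
  } else {
    values <- vapply(cats, function(ct)
      sqrt(sum(errors[obs$category == ct]^2)), numeric(1))
  }
  structure(
    list(values = values,
         breakdown = tibble::tibble(index = obs$index, species = obs$species,
                                    condition = obs$condition,
                                    category = obs$category, error = errors),
         failed = failed,
         solutions = solutions),
    class = "os_objectives")
}

#' @export
print.os_objectives <- function(x, ...) {
  cat("<os_objectives>",
      if (x$failed) "FAILED (simulation)" else
        paste(names(x$values), "=", signif(x$values, 4), collapse = ", "),
      "\n")
  invisible(x)
}

#' Build a multi-objective evaluator over free parameters
#'
#' Returns a function mapping a log10 parameter vector (for the named free
#' parameters) to the per-category objective values — the plumbing between
#' the model/observation layer and the search/Pareto machinery, which works
#' in log10 space throughout.
#'
#' @param model An `os_model`.
#' @param obs An `os_observations` table.
#' @param free Character vector of free parameter names (entries of
#'   `model$params`).
#' @param cfg An [scaling_config()].
#' @return A function `f(theta_log10) -> named numeric` of objective values
#'   (infinite on simulation failure).
#' @export
objective_evaluator <- function(model, obs, free, cfg = scaling_config()) {
  stopifnot(all(free %in% names(model$params)))
  force(model); force(obs); force(cfg)
  function(theta) {
    p <- stats::setNames(10^as.numeric(theta), free)
    evaluate_objectives(model, obs, params = p, cfg = cfg)$values
  }
}
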