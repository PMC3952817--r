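#' Local relative sensitivity of model observables to a parameter
#'
#' Forward finite difference of the steady-state (or chosen condition's)
#' observables with respect to one parameter, scaled by the nominal
#' parameter and output values so entries are dimensionless:
#' `S = (y(p * (1 + h)) - y(p)) / (h * p) * p / max(y(p), floor)`,
#' with a small floor guarding division where the output vanishes.
#'
#' @param model An `os_model`.
#' @param parameter Name of the parameter to perturb (must be positive).
#' @param condition An `os_condition` (default Wild Type).
#' @param species Observables to report (default: all topology species).
#' @param h_rel Relative step (in `(0, 0.5)`, default 0.01).
#' @param params Optional named override of model parameters.
#' @return A tibble: `parameter`, `species`, `cell`, `value`; non-finite
#'   entries (simulation failure) are returned as `NA` for downstream
#'   exclusion.
#' @export
local_sensitivity <- function(model, parameter,
                              condition = genetic_condition(),
                              species = model$topology$species,
                              h_rel = 0.01, params = NULL) {
  stopifnot(h_rel > 0, h_rel < 0.5)
  if (!is.null(params)) {
    model$params[names(params)] <- params
  }
  p0 <- model$params[[parameter]]
  if (is.null(p0) || !is.finite(p0) || p0 <= 0)
    stop("parameter must exist and be positive: ", parameter, call. = FALSE)
  base <- simulate_steady(model, condition)
  pert <- model
  pert$params[[parameter]] <- p0 * (1 + h_rel)
  bump <- simulate_steady(pert, condition)
  rows <- lapply(species, function(sp) {
    if (base$failed || bump$failed) {
      val <- rep(NA_real_, model$region_map$n_cells_germline)
    } else {
      y0 <- observable(base, sp)
      y1 <- observable(bump, sp)
      floor_ <- 1e-12 * max(model_scale(y0), 1e-300)
      val <- (y1 - y0) / (h_rel * p0) * p0 / pmax(y0, floor_)
    }
    tibble::tibble(parameter = parameter, species = sp,
                   cell = seq_along(val), value = val)
  })
  dplyr::bind_rows(rows)
}

#' Sensitivity table across Representatives
#'
#' Evaluates [local_sensitivity()] for every (Representative, parameter)
#' pair, producing the tidy table consumed by quantitative experiment
#' design.
#'
#' @param model An `os_model`.
#' @param representatives Tibble of Representative parameter values in
#'   log10 (columns named by parameter, e.g. from an `os_pareto`).
#' @param parameters Parameters to perturb (default: the representative
#'   columns present in the model parameter vector).
#' @param species Observables (default: all topology species).
#' @param h_rel Relative step.
#' @return A tibble: `representative`, `parameter`, `species`, `cell`,
#'   `value`.
#' @export
sensitivity_table <- function(model, representatives,
                              parameters = NULL,
                              species = model$topology$species,
                              h_rel = 0.01) {
  if (is.null(parameters))
    parameters <- intersect(names(representatives), names(model$params))
  rows <- lapply(seq_len(nrow(representatives)), function(i) {
    ov <- stats::setNames(
      10^as.numeric(representatives[i, parameters]), parameters)
    tabs <- lapply(parameters, function(pm)
      local_sensitivity(model, pm, species = species, h_rel = h_rel,
                        params = ov))
    dplyr::mutate(dplyr::bind_rows(tabs), representative = i,
                  .before = 1L)
  })
  dplyr::bind_rows(rows)
}
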