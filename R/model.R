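#' Default parameter values for a germarium model
#'
#' Reference values chosen to give O(1) concentrations and hour-scale
#' kinetics: production 1 /h and degradation 0.5 /h for regulators (steady
#' level 2 when unrepressed), half-maximal concentrations at half the
#' unrepressed level (strong but saturable repression), and a Dpp
#' secretion/diffusion/uptake balance with a decay length under one cell
#' diameter, producing the anterior-restricted signaling gradient.
#'
#' @param topology An `os_topology`.
#' @return Named numeric vector with, per species `X`, `phi_X` (production,
#'   conc/h) and `delta_X` (degradation, /h); per edge, `K_from_to`
#'   (half-maximal concentration); and the signaling set: `dpp_secretion`
#'   (conc/h, CC only), `dpp_diffusion` (cell^2/h), `dpp_degradation` (/h),
#'   `k_on` (/conc/h), `k_off` (/h), `k_int` (complex internalization, /h),
#'   `receptor_total` (conc), `k_sig` (half-maximal complex for Mad
#'   phosphorylation), `hill_n` (2 throughout), `dx` (cell spacing, cell
#'   diameters), `oe_rate` (ectopic production for overexpression
#'   conditions, conc/h).
#' @export
default_parameters <- function(topology = core_topology()) {
  p <- c(dpp_secretion = 20, dpp_diffusion = 2, dpp_degradation = 1,
         k_on = 2, k_off = 0.1, k_int = 2, receptor_total = 1,
         k_sig = 0.05, hill_n = 2, dx = 1, oe_rate = 0.5)
  for (sp in topology$species) {
    p[paste0("phi_", sp)] <- 1
    p[paste0("delta_", sp)] <- if (sp == "pMad") 1 else 0.5
  }
  if (nrow(topology$edges)) {
    for (i in seq_len(nrow(topology$edges))) {
      e <- topology$edges[i, ]
      p[paste0("K_", e$from, "_", e$to)] <-
        if (e$to == "pMad") 1 else 0.5
    }
  }
  p
}

#' Construct a germarium model
#'
#' Binds a network topology, a parameter vector and the spatial region map
#' into a simulatable model: a 1-D line of ODE compartments (CC at the
#' anterior end, then the germline cells) with Dpp secretion from the CC,
#' finite-difference diffusion with no-flux ends, receptor binding (no
#' receptors in the CC), Mad phosphorylation driven by the bound complex,
#' and Hill-repression/activation intracellular regulation.
#'
#' @param topology An `os_topology` (default [core_topology()]).
#' @param params Named parameter vector (default
#'   [default_parameters()] for the topology).
#' @param rm Region map (default [region_map()]).
#' @return An object of class `os_model`.
#' @export
germarium_model <- function(topology = core_topology(),
                            params = default_parameters(topology),
                            rm = region_map()) {
  need <- c("dpp_secretion", "dpp_diffusion", "dpp_degradation", "k_on",
            "k_off", "k_int", "receptor_total", "k_sig", "hill_n", "dx",
            paste0("phi_", topology$species),
            paste0("delta_", topology$species))
  if (nrow(topology$edges))
    need <- c(need, paste0("K_", topology$edges$from, "_", topology$edges$to))
  missing <- setdiff(need, names(params))
  if (length(missing))
    stop("missing parameter(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  structure(list(topology = topology, params = params, region_map = rm),
            class = "os_model")
}

#' @export
print.os_model <- function(x, ...) {
  cat("<os_model>", x$topology$name, "network,",
      x$region_map$n_cells_total, "compartments,",
      length(state_names(x)), "states\n")
  invisible(x)
}

# state layout: Dpp[1..n], Cplx[1..n], then one block per species
state_names <- function(model) {
  n <- model$region_map$n_cells_total
  sp <- model$topology$species
  c(paste0("Dpp_", seq_len(n)), paste0("Cplx_", seq_len(n)),
    paste0(rep(sp, each = n), "_", seq_len(n)))
}

#' Apply a genetic condition to a parameter vector
#'
#' `null` zeroes the species' production, `heterozygous` halves it,
#' `doubled` doubles it, `overexpress` adds a uniform ectopic production
#' `oe_rate` on top of the endogenous gene.  `Dpp` perturbations act on the
#' secretion rate, `Rec` on the receptor level, `Mad` on the Mad
#' phosphorylation rate.
#'
#' @param params Named parameter vector.
#' @param condition An `os_condition`.
#' @param topology The model topology (used to validate species).
#' @return A modified parameter vector (ectopic production appears as
#'   `oe_<species>` entries).
#' @export
apply_condition <- function(params, condition, topology = core_topology()) {
  if (is_wild_type(condition)) return(params)
  factor_of <- c(null = 0, heterozygous = 0.5, doubled = 2)
  for (i in seq_len(nrow(condition))) {
    sp <- condition$species[i]
    kind <- condition$kind[i]
    target <- if (sp == "Dpp") "dpp_secretion"
      else if (sp == "Rec") "receptor_total"
      else if (sp %in% c("Mad", "pMad")) "phi_pMad"
      else paste0("phi_", sp)
    if (!target %in% names(params))
      stop("condition perturbs species absent from the model: ", sp,
           call. = FALSE)
    if (kind == "overexpress") {
      oe <- paste0("oe_", if (sp %in% c("Mad", "pMad")) "pMad" else sp)
      params[oe] <- (if (oe %in% names(params)) params[[oe]] else 0) +
        params[["oe_rate"]]
    } else {
      params[target] <- params[[target]] * factor_of[[kind]]
    }
  }
  params
}

# Pack model + condition parameters into the flat vector read by the
# compiled rhs (padded to the fixed length the C side copies).
pack_parms <- function(model, condition = genetic_condition()) {
  p <- apply_condition(model$params, condition, model$topology)
  n <- model$region_map$n_cells_total
  sp <- model$topology$species
  edges <- model$topology$edges
  oe <- vapply(sp, function(s) {
    nm <- paste0("oe_", s)
    if (nm %in% names(p)) p[[nm]] else 0
  }, numeric(1))
  head <- c(n, length(sp), p[["hill_n"]], p[["dx"]]^2,
            p[["dpp_diffusion"]], p[["dpp_degradation"]], p[["k_on"]],
            p[["k_off"]], p[["k_int"]], p[["k_sig"]],
            if ("oe_Dpp" %in% names(p)) p[["oe_Dpp"]] else 0,
            p[["dpp_secretion"]],
            if ("pMad" %in% sp) match("pMad", sp) else 0,
            p[["receptor_total"]], nrow(edges))
  spp <- as.vector(rbind(p[paste0("phi_", sp)], p[paste0("delta_", sp)], oe))
  epp <- if (nrow(edges)) as.vector(rbind(
    match(edges$to, sp), match(edges$from, sp),
    as.numeric(edges$sign == "repress"),
    p[paste0("K_", edges$from, "_", edges$to)])) else numeric(0)
  v <- c(head, spp, epp)
  if (length(v) > 1024L)
    stop("model too large for the compiled rhs buffer", call. = FALSE)
  c(v, numeric(1024L - length(v)))
}

# Build the deSolve rhs closure for a model + condition (pure-R reference
# implementation; the compiled rhs in src/ is used when available).
model_rhs <- function(model, condition = genetic_condition()) {
  p <- apply_condition(model$params, condition, model$topology)
  n <- model$region_map$n_cells_total
  sp <- model$topology$species
  nsp <- length(sp)
  hn <- p[["hill_n"]]
  dx2 <- p[["dx"]]^2
  Rtot <- rep(p[["receptor_total"]], n); Rtot[1L] <- 0   # no receptors in CC
  sec <- numeric(n); sec[1L] <- p[["dpp_secretion"]]     # secretion CC only
  oe_dpp <- if ("oe_Dpp" %in% names(p)) p[["oe_Dpp"]] else 0
  germ <- c(0, rep(1, n - 1L))   # intracellular production mask (none in CC)
  phi <- p[paste0("phi_", sp)]
  del <- p[paste0("delta_", sp)]
  oe <- vapply(sp, function(s) {
    nm <- paste0("oe_", s)
    if (nm %in% names(p)) p[[nm]] else 0
  }, numeric(1))
  edges <- model$topology$edges
  in_edges <- lapply(sp, function(s) {
    if (!nrow(edges)) return(NULL)
    e <- edges[edges$to == s, , drop = FALSE]
    if (!nrow(e)) return(NULL)
    list(from = match(e$from, sp), sign = e$sign,
         K = p[paste0("K_", e$from, "_", e$to)])
  })
  imad <- match("pMad", sp)
  ksig <- p[["k_sig"]]

  function(t, y, parms) {
    D <- y[seq_len(n)]
    C <- y[n + seq_len(n)]
    X <- matrix(y[-(seq_len(2L * n))], n, nsp)
    Rfree <- pmax(Rtot - C, 0)
    lap <- (c(D[-1L], D[n]) - 2 * D + c(D[1L], D[-n])) / dx2
    bind <- p[["k_on"]] * D * Rfree
    dD <- p[["dpp_diffusion"]] * lap + sec + oe_dpp - bind +
      p[["k_off"]] * C - p[["dpp_degradation"]] * D
    dC <- bind - p[["k_off"]] * C - p[["k_int"]] * C
    dX <- matrix(0, n, nsp)
    for (j in seq_len(nsp)) {
      prod <- rep(phi[j], n)
      if (!is.na(imad) && j == imad) {
        prod <- prod * C^hn / (ksig^hn + C^hn)
      }
      ie <- in_edges[[j]]
      if (!is.null(ie)) {
        for (k in seq_along(ie$from)) {
          R <- X[, ie$from[k]]
          Kh <- ie$K[k]^hn
          h <- if (ie$sign[k] == "repress") Kh / (Kh + R^hn)
               else R^hn / (Kh + R^hn)
          prod <- prod * h
        }
      }
      dX[, j] <- (prod + oe[j]) * germ - del[j] * X[, j]
    }
    list(c(dD, dC, as.vector(dX)))
  }
}

#' Simulate a model to its 24-hour state
#'
#' Integrates the full system from a null (all-zero) initial state over 24
#' hours with a stiff solver; the final snapshot is taken as the
#' steady-state output.  Integration failures are flagged on the result
#' rather than raised, so parameter screens survive pathological corners.
#'
#' @param model An `os_model`.
#' @param condition An `os_condition` (default Wild Type).
#' @param hours Simulation horizon (default 24).
#' @param times Optional explicit output time grid.
#' @return An `os_simulation`: list with `times`, `states` (time x state
#'   matrix), `model`, `condition`, `protocol`, `failed`.
#' @export
simulate_steady <- function(model, condition = genetic_condition(),
                            hours = 24, times = NULL) {
  y0 <- stats::setNames(numeric(length(state_names(model))),
                        state_names(model))
  if (is.null(times)) times <- c(0, hours)
  integrate_protocol(model, condition, y0, times, "steady")
}

compiled_rhs_available <- function() {
  is.loaded("osfit_derivs", PACKAGE = "osfit")
}

integrate_protocol <- function(model, condition, y0, times, protocol) {
  out <- tryCatch({
    if (compiled_rhs_available()) {
      deSolve::ode(y = y0, times = times, func = "osfit_derivs",
                   parms = pack_parms(model, condition),
                   dllname = "osfit", initfunc = "osfit_init",
                   method = "lsoda", rtol = 1e-6, atol = 1e-9)
    } else {
      deSolve::ode(y = y0, times = times, func = model_rhs(model, condition),
                   parms = NULL, method = "lsoda", rtol = 1e-6, atol = 1e-9)
    }
  }, error = function(e) NULL, warning = function(w) NULL)
  failed <- is.null(out) || nrow(out) < length(times) ||
    any(!is.finite(out[nrow(out), ]))
  if (failed) {
    states <- matrix(NA_real_, length(times), length(y0),
                     dimnames = list(NULL, names(y0)))
  } else {
    states <- out[, -1L, drop = FALSE]
  }
  structure(list(times = times, states = states, model = model,
                 condition = condition, protocol = protocol,
                 failed = failed),
            class = "os_simulation")
}

#' Cell-cycle displacement: shift zone states posteriorly
#'
#' Approximates a division/displacement event by setting, for each
#' intracellular species, every zone to the mean solved state of its
#' anterior neighbor zone (the GSC zone keeps its own mean).  Extracellular
#' states (Dpp, bound complex) and the CC compartment are untouched.
#'
#' @param snapshot Named state vector (one row of `$states`).
#' @param model The `os_model` the snapshot belongs to.
#' @return The shifted state vector.
#' @export
divide_and_shift <- function(snapshot, model) {
  rm <- model$region_map
  n <- rm$n_cells_total
  sp <- model$topology$species
  out <- snapshot
  zones <- rm$region_names
  for (j in seq_along(sp)) {
    block <- 2L * n + (j - 1L) * n
    cells <- function(zone) block + 1L + rm$regions[[zone]]  # +1: CC offset
    means <- vapply(zones, function(z) mean(snapshot[cells(z)]), numeric(1))
    for (zi in seq_along(zones)) {
      src <- if (zi == 1L) 1L else zi - 1L
      out[cells(zones[zi])] <- means[src]
    }
  }
  out
}

#' Simulate the post-division dynamic protocol
#'
#' Solves to the 24 h state, applies [divide_and_shift()], then integrates a
#' further 12 hours on a fine grid.  The phenotype output is the per-cell
#' mean Brat (or configured species) over the trailing 6 hours of this
#' window.
#'
#' @inheritParams simulate_steady
#' @param hours Length of the post-division window (default 12).
#' @return An `os_simulation` with `protocol = "dynamic"`.
#' @export
simulate_dynamic <- function(model, condition = genetic_condition(),
                             hours = 12) {
  pre <- simulate_steady(model, condition)
  if (pre$failed) {
    sim <- pre; sim$protocol <- "dynamic"
    return(sim)
  }
  y1 <- divide_and_shift(pre$states[nrow(pre$states), ], model)
  times <- seq(0, hours, by = 0.5)
  integrate_protocol(model, condition, y1, times, "dynamic")
}

#' Extract a per-cell observable from a simulation
#'
#' `Phenotype` maps to the trailing-6-hour mean Brat concentration (the
#' proxy for fusome development); any model species maps to its final
#' snapshot; `Dpp` to the final extracellular Dpp.  The CC is excluded, so
#' observables are vectors over the germline cells (length 17 by default).
#'
#' @param result An `os_simulation`.
#' @param species Observable name.
#' @return Numeric vector over germline cells.
#' @export
observable <- function(result, species) {
  model <- result$model
  n <- model$region_map$n_cells_total
  germ <- 2:n
  sp <- model$topology$species
  last <- result$states[nrow(result$states), ]
  if (species == "Phenotype") {
    j <- match("Brat", sp)
    if (is.na(j)) stop("Phenotype requires a Brat species", call. = FALSE)
    block <- 2L * n + (j - 1L) * n
    tail_w <- result$times >= max(result$times) - 6
    brat <- result$states[tail_w, block + germ, drop = FALSE]
    return(unname(colMeans(brat)))
  }
  if (species == "Dpp") return(unname(last[germ]))
  j <- match(species, sp)
  if (is.na(j)) stop("unknown observable: ", species, call. = FALSE)
  block <- 2L * n + (j - 1L) * n
  unname(last[block + germ])
}
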