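#' Enumerate inhibitory rewirings of the core regulators
#'
#' All subsets of the 12 possible directed repression edges among the four
#' regulators (pMad, Bam, Nos, Brat), excluding self-regulation, each
#' mounted on the fixed signaling backbone.  Uncapped this yields 4096
#' topologies.
#'
#' @param max_edges Optional cap on the number of edges.
#' @param regulators Regulator species (default the core four; dMyc is kept
#'   as a passenger species for condition compatibility).
#' @return List of `os_topology` objects.
#' @export
enumerate_inhibitory <- function(max_edges = NULL,
                                 regulators = c("pMad", "Bam", "Nos",
                                                "Brat")) {
  pairs <- expand.grid(from = regulators, to = regulators,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  ne <- nrow(pairs)
  subsets <- 0:(2^ne - 1L)
  out <- list()
  species <- c(regulators, "dMyc")
  for (s in subsets) {
    sel <- which(bitwAnd(s, 2^(seq_len(ne) - 1L)) > 0L)
    if (!is.null(max_edges) && length(sel) > max_edges) next
    e <- if (length(sel)) data.frame(from = pairs$from[sel],
                                     to = pairs$to[sel], sign = "repress",
                                     stringsAsFactors = FALSE) else NULL
    out[[length(out) + 1L]] <-
      network_topology(species, e, name = paste0("net", s))
  }
  out
}

#' Screen topologies against Wild-Type observations
#'
#' For each topology, evaluates the Wild-Type objective over an exhaustive
#' lattice of strong/weak regulatory parameters — every edge's half-maximal
#' concentration at 0.1 or 10 times the species reference scale — and
#' accepts the topology if its best error is at or below the threshold.
#' Simulation failures reject the parameter point only, not the topology.
#'
#' @param topologies List of `os_topology`.
#' @param obs_wt An `os_observations` table containing only
#'   WildType-category observations.
#' @param threshold Acceptance threshold on the best Wild-Type error
#'   (default 0.05).
#' @param k_levels Strong/weak multipliers for the edge half-maximal
#'   concentrations (default `c(0.1, 10)`; the reference scale is the
#'   unrepressed steady level `phi/delta` of the regulating species).
#' @param budget Cap on lattice points per topology (the first `budget`
#'   combinations in enumeration order when `2^edges` exceeds it).
#' @param base_params Baseline parameters for non-edge entries.
#' @return A tibble: `name`, `edge_count`, `edges` (label string),
#'   `best_wt_error`, `accepted`.
#' @export
screen_wt <- function(topologies, obs_wt, threshold = 0.05,
                      k_levels = c(0.1, 10), budget = 4096L,
                      base_params = NULL) {
  if (!all(obs_wt$category == "WildType"))
    stop("screen_wt expects WildType-category observations only",
         call. = FALSE)
  rows <- lapply(topologies, function(topo) {
    p <- default_parameters(topo)
    if (!is.null(base_params)) p[names(base_params)] <- base_params
    model <- germarium_model(topo, p, obs_region_map(obs_wt))
    enames <- if (nrow(topo$edges))
      paste0("K_", topo$edges$from, "_", topo$edges$to) else character(0)
    ref <- vapply(seq_len(nrow(topo$edges)), function(i) {
      sp <- topo$edges$from[i]
      p[[paste0("phi_", sp)]] / p[[paste0("delta_", sp)]]
    }, numeric(1))
    ne <- length(enames)
    n_comb <- min(2^ne, budget)
    best <- Inf
    for (ci in seq_len(n_comb) - 1L) {
      lv <- k_levels[1L + (bitwAnd(ci, 2^(seq_len(ne) - 1L)) > 0L)]
      kv <- stats::setNames(if (ne) lv * ref else numeric(0), enames)
      ov <- evaluate_objectives(model, obs_wt, params = kv)
      if (!ov$failed && is.finite(ov$values[["WildType"]]))
        best <- min(best, ov$values[["WildType"]])
    }
    tibble::tibble(name = topo$name, edge_count = nrow(topo$edges),
                   edges = paste(topo$edges$from, topo$edges$to,
                                 sep = ">", collapse = ";"),
                   best_wt_error = best,
                   accepted = best <= threshold)
  })
  dplyr::bind_rows(rows)
}

#' Parsimony filter over accepted topologies
#'
#' Keeps the accepted topologies whose edge sets contain no strictly
#' smaller accepted topology's edge set — the minimal antichain under
#' edge-set inclusion.
#'
#' @param candidates Tibble from [screen_wt()] (columns `edges`,
#'   `accepted`).
#' @return The input with a logical `parsimonious` column added.
#' @export
parsimony_filter <- function(candidates) {
  esets <- lapply(strsplit(candidates$edges, ";", fixed = TRUE),
                  function(e) e[nzchar(e)])
  n <- nrow(candidates)
  pars <- logical(n)
  acc <- which(candidates$accepted)
  for (i in acc) {
    ei <- esets[[i]]
    nested <- FALSE
    for (j in acc) {
      if (j == i) next
      ej <- esets[[j]]
      if (length(ej) < length(ei) && all(ej %in% ei)) { nested <- TRUE; break }
    }
    pars[i] <- !nested
  }
  candidates$parsimonious <- pars
  candidates
}
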