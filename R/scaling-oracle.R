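#' Brute-force reference solver for the Optimal Scaling problem
#'
#' Nested-grid exhaustive search over the raw interval boundary variables:
#' a full coarse lattice over all `2 * n_cat` bounds is enumerated (filtering
#' out candidates violating the ordering, minimum-range and minimum-gap
#' constraints), then the lattice is repeatedly contracted around the best
#' candidates.  Intended as an independent reference for [solve_scaling()] on
#' small instances (few cells, `n_categories <= 3`); its cost grows
#' exponentially with the number of categories.
#'
#' @inheritParams solve_scaling
#' @param rounds Number of contraction rounds after the initial lattice.
#' @return List with `error`, `lower`, `upper`.
#' @export
solve_scaling_oracle <- function(y, ranks,
                                 n_categories = max(ranks, na.rm = TRUE),
                                 domains = NULL, cfg = scaling_config(),
                                 rounds = 9L) {
  obs <- which(!is.na(ranks))
  y_obs <- y[obs]
  r_obs <- as.integer(ranks[obs])
  n_cat <- as.integer(n_categories)
  if (is.null(domains)) domains <- list(seq_along(obs))
  S <- model_scale(y)
  nu <- sum(abs(diff(y)))
  eps <- cfg$epsilon_fraction * S
  mg <- min_range_and_gap(n_cat, S, cfg)
  delta <- mg$delta_min; gap <- mg$gap_min
  lb <- cfg$lower_bound
  total_span <- n_cat * delta + (n_cat - 1) * gap
  cap <- max(max(y), lb) + total_span + delta
  # the coarse lattice must be able to express 2*n_cat escalating bounds
  G <- max(cfg$oracle_grid, 2L * n_cat + 1L)

  eval_lattice <- function(levels) {
    # levels: list of numeric vectors, one per variable (l_1,u_1,...,l_n,u_n)
    grid <- as.matrix(do.call(expand.grid, levels))
    L <- grid[, 2 * seq_len(n_cat) - 1L, drop = FALSE]
    U <- grid[, 2 * seq_len(n_cat), drop = FALSE]
    ok <- L[, 1L] >= lb - 1e-12
    for (r in seq_len(n_cat)) {
      ok <- ok & (U[, r] - L[, r] >= delta - 1e-9 * S)
    }
    if (n_cat > 1L) for (r in seq_len(n_cat - 1L)) {
      ok <- ok & (L[, r + 1L] - U[, r] >= gap - 1e-9 * S)
    }
    if (!any(ok)) return(NULL)
    L <- L[ok, , drop = FALSE]; U <- U[ok, , drop = FALSE]
    err <- interval_error_many(y_obs, r_obs, domains, L, U, nu + eps)
    list(L = L, U = U, err = err)
  }

  base_levels <- rep(list(seq(lb, cap, length.out = G)), 2L * n_cat)
  res <- eval_lattice(base_levels)
  if (is.null(res)) stop("oracle lattice found no feasible candidate",
                         call. = FALSE)
  ord <- order(res$err)[seq_len(min(5L, length(res$err)))]
  # interleave as l_1,u_1,l_2,u_2,...
  centers <- lapply(ord, function(i) {
    v <- numeric(2L * n_cat)
    v[2 * seq_len(n_cat) - 1L] <- res$L[i, ]
    v[2 * seq_len(n_cat)] <- res$U[i, ]
    v
  })
  best <- list(err = min(res$err))
  i0 <- which.min(res$err)
  best$lower <- res$L[i0, ]; best$upper <- res$U[i0, ]

  # pattern search: the inner problem is convex in the bounds (clipping
  # residuals are maxima of affine functions), so contracting the lattice
  # only when the best candidate is interior converges to the optimum
  radius <- (cap - lb) / (G - 1)
  for (ct in centers) {
    ctr <- ct
    rad <- radius
    for (rd in seq_len(rounds * 6L)) {
      levels <- lapply(seq_len(2L * n_cat), function(j)
        seq(max(lb, ctr[j] - rad), min(cap, ctr[j] + rad), length.out = 5L))
      res_r <- eval_lattice(levels)
      moved <- FALSE
      if (!is.null(res_r)) {
        i <- which.min(res_r$err)
        cand <- numeric(2L * n_cat)
        cand[2 * seq_len(n_cat) - 1L] <- res_r$L[i, ]
        cand[2 * seq_len(n_cat)] <- res_r$U[i, ]
        improved <- res_r$err[i] < best$err * (1 - 1e-12) - 1e-300
        if (improved) {
          best$err <- res_r$err[i]
          best$lower <- res_r$L[i, ]; best$upper <- res_r$U[i, ]
          at_edge <- any(abs(cand - ctr) > rad * 0.99)
          ctr <- cand
          moved <- at_edge
        }
      }
      if (!moved) rad <- rad / 2
      if (rad < 1e-7 * (cap - lb)) break
    }
  }
  list(error = best$err, lower = best$lower, upper = best$upper)
}
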