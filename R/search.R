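#' Parameter bounds table
#'
#' @param ... Named two-element numeric vectors `c(lower, upper)`.
#' @return A tibble with columns `name`, `lower`, `upper`.
#' @examples
#' param_bounds(k1 = c(-2, 2), k2 = c(-1, 3))
#' @export
param_bounds <- function(...) {
  bl <- list(...)
  stopifnot(length(bl) > 0, !is.null(names(bl)), all(lengths(bl) == 2L))
  tb <- tibble::tibble(name = names(bl),
                       lower = vapply(bl, `[`, numeric(1), 1L),
                       upper = vapply(bl, `[`, numeric(1), 2L))
  if (any(tb$upper <= tb$lower)) stop("upper must exceed lower", call. = FALSE)
  tb
}

# nested Chebyshev-Gauss-Lobatto nodes on [0, 1]
cgl_nodes <- function(level) {
  if (level == 0L) return(0.5)
  k <- 0:(2^level)
  (1 - cos(pi * k / 2^level)) / 2
}

# nodes new at `level` relative to level - 1 (difference sets)
cgl_diff_nodes <- function(level) {
  if (level == 0L) return(0.5)
  if (level == 1L) return(c(0, 1))
  k <- seq(1, 2^level - 1, by = 2)
  (1 - cos(pi * k / 2^level)) / 2
}

# multi-indices i >= 0 with sum(i) <= q
multi_indices <- function(d, q) {
  if (d == 1L) return(matrix(0:q, ncol = 1L))
  out <- NULL
  for (i in 0:q) {
    rest <- multi_indices(d - 1L, q - i)
    out <- rbind(out, cbind(i, rest))
  }
  unname(out)
}

#' Sparse-grid sample points
#'
#' Smolyak sparse grid on the unit cube built from nested
#' Chebyshev–Gauss–Lobatto node sets: the union, over multi-indices with
#' total level at most `q`, of tensor products of the per-level difference
#' node sets.  Nodes are nested across levels.
#'
#' @param d Dimension.
#' @param q Sparse-grid level (0 gives the single center point).
#' @return Matrix of points in `[0, 1]^d` (one row per point).
#' @export
sparse_grid <- function(d, q) {
  mi <- multi_indices(d, q)
  pts <- lapply(seq_len(nrow(mi)), function(r) {
    sets <- lapply(mi[r, ], cgl_diff_nodes)
    as.matrix(do.call(expand.grid, sets))
  })
  out <- do.call(rbind, pts)
  dimnames(out) <- NULL
  out
}

sparse_grid_size <- function(d, q) {
  mi <- multi_indices(d, q)
  sizes <- c(1, 2, 2^(2:10 - 1))   # |diff set| per level 0,1,2,...
  sum(apply(mi, 1L, function(i) prod(sizes[i + 1L])))
}

#' Hybrid global screen: deterministic sparse grid + Latin hypercube
#'
#' Allocates up to `grid_fraction` of the budget to the largest sparse-grid
#' level that fits (skipping the grid entirely when even the coarsest level
#' exceeds the cap), and the remainder to a seeded Latin hypercube.  Every
#' point is evaluated with the supplied objective.
#'
#' @param bounds A [param_bounds()] table (coordinates are taken as given;
#'   model pipelines pass log10 bounds and evaluators).
#' @param budget Total number of samples (>= 2 per dimension).
#' @param seed Integer seed for the Latin hypercube.
#' @param objective Function mapping a named parameter vector to a named
#'   numeric vector of objective values (or a single value).
#' @param grid_fraction Cap on the deterministic share (default 0.75).
#' @return An `os_screen` tibble: parameter columns, `obj_*` objective
#'   columns and `.source` (`"grid"`/`"lhs"`), with `bounds` and `seed`
#'   attributes.
#' @export
screen <- function(bounds, budget, seed, objective, grid_fraction = 0.75) {
  d <- nrow(bounds)
  if (budget < 2 * d) stop("budget must be at least 2 per dimension",
                           call. = FALSE)
  cap <- floor(grid_fraction * budget)
  q <- -1L
  while (sparse_grid_size(d, q + 1L) <= cap) q <- q + 1L
  grid_pts <- if (q >= 0L) sparse_grid(d, q) else
    matrix(numeric(0), 0L, d)
  n_lhs <- budget - nrow(grid_pts)
  set.seed(seed)
  lhs_pts <- if (n_lhs > 0L) lhs::randomLHS(n_lhs, d) else
    matrix(numeric(0), 0L, d)
  unit <- rbind(grid_pts, lhs_pts)
  pts <- sweep(sweep(unit, 2L, bounds$upper - bounds$lower, "*"),
               2L, bounds$lower, "+")
  colnames(pts) <- bounds$name
  vals <- lapply(seq_len(nrow(pts)), function(i)
    objective(stats::setNames(pts[i, ], bounds$name)))
  m <- length(vals[[1L]])
  obj_names <- names(vals[[1L]])
  if (is.null(obj_names)) obj_names <- paste0("f", seq_len(m))
  vmat <- do.call(rbind, vals)
  colnames(vmat) <- paste0("obj_", obj_names)
  out <- tibble::as_tibble(cbind(as.data.frame(pts), as.data.frame(vmat)))
  out$.source <- rep(c("grid", "lhs"), c(nrow(grid_pts), n_lhs))
  structure(out, bounds = bounds, seed = seed, obj_names = obj_names,
            class = c("os_screen", class(out)))
}

screen_params <- function(scr) {
  as.matrix(scr[attr(scr, "bounds")$name])
}

screen_objectives <- function(scr) {
  as.matrix(scr[paste0("obj_", attr(scr, "obj_names"))])
}

# scalarize an objective function: component `which` of its value,
# non-finite values replaced by a large penalty
scalar_objective <- function(objective, which = 1L) {
  function(theta) {
    v <- objective(theta)[[which]]
    if (!is.finite(v)) 1e10 else v
  }
}

#' Multi-start bounded local refinement
#'
#' Starts a bounded quasi-Newton search (`optim` L-BFGS-B, numerical
#' gradients) from the `k_starts` best distinct screen samples for the
#' chosen objective component, and returns all solutions sorted by value.
#' A solution is never worse than its start (falls back to the start point
#' otherwise), so the multistart result cannot be worse than the best
#' screened sample.
#'
#' @param scr An `os_screen`.
#' @param k_starts Number of local searches (the full-scale reference setup
#'   uses 64; desk-scale default 8).
#' @param objective The vector objective used for the screen.
#' @param which Objective component (index or name) to minimize.
#' @param maxit Iteration cap per local search.
#' @return A tibble: start/end parameters (`start_*`, columns named as the
#'   bounds), `value`, `converged`, `iterations`.
#' @export
multistart <- function(scr, k_starts = 8L, objective, which = 1L,
                       maxit = 100L) {
  bounds <- attr(scr, "bounds")
  if (is.character(which)) which <- match(which, attr(scr, "obj_names"))
  pmat <- screen_params(scr)
  vals <- screen_objectives(scr)[, which]
  ok <- is.finite(vals)
  ord <- order(vals[ok])
  idx <- which(ok)[ord]
  idx <- idx[!duplicated(round(pmat[idx, , drop = FALSE], 10))]
  idx <- utils::head(idx, k_starts)
  if (!length(idx)) {
    warning("no finite screen samples to start from")
    return(tibble::tibble())
  }
  f <- scalar_objective(objective, which)
  sols <- lapply(idx, function(i) {
    st <- stats::setNames(pmat[i, ], bounds$name)
    v0 <- vals[i]
    fit <- tryCatch(
      stats::optim(st, f, method = "L-BFGS-B",
                   lower = bounds$lower, upper = bounds$upper,
                   control = list(maxit = maxit)),
      error = function(e) NULL)
    if (is.null(fit) || fit$value > v0) {
      fit <- list(par = st, value = v0, convergence = 1L,
                  counts = c(0L, 0L))
    }
    tibble::tibble(!!!stats::setNames(as.list(fit$par), bounds$name),
                   !!!stats::setNames(as.list(st),
                                      paste0("start_", bounds$name)),
                   value = fit$value,
                   converged = fit$convergence == 0L,
                   iterations = unname(fit$counts[1L]))
  })
  out <- dplyr::arrange(dplyr::bind_rows(sols), .data$value)
  out
}

#' Seed a parameter point for a target in objective space
#'
#' Builds a rough polynomial response surface (quadratic least squares) of
#' each objective over the deterministic grid part of a screen, samples it
#' cheaply, and returns the candidate — among the cheap samples and all
#' screened points — whose (predicted or actual) objectives are nearest the
#' target in normalized objective space.  Falls back to the nearest screened
#' sample when the surface cannot be fit.
#'
#' @param scr An `os_screen`.
#' @param target Numeric vector in objective space (same order as the
#'   screen's objectives).
#' @param n_candidates Cheap surrogate samples to draw (seeded from the
#'   screen's seed).
#' @return Named parameter vector.
#' @export
interpolant_seed <- function(scr, target, n_candidates = 2000L) {
  bounds <- attr(scr, "bounds")
  d <- nrow(bounds)
  pmat <- screen_params(scr)
  omat <- screen_objectives(scr)
  fin <- apply(omat, 1L, function(r) all(is.finite(r)))
  rng <- apply(omat[fin, , drop = FALSE], 2L, function(c)
    max(c) - min(c))
  rng[rng == 0] <- 1
  lo <- apply(omat[fin, , drop = FALSE], 2L, min)
  norm <- function(m) sweep(sweep(m, 2L, lo, "-"), 2L, rng, "/")
  tgt <- (target - lo) / rng

  dist_actual <- sqrt(rowSums(sweep(norm(omat[fin, , drop = FALSE]),
                                    2L, tgt, "-")^2))
  best_actual <- which(fin)[which.min(dist_actual)]
  best <- list(par = stats::setNames(pmat[best_actual, ], bounds$name),
               dist = min(dist_actual))

  gi <- which(scr$.source == "grid" & fin)
  fit_rows <- if (length(gi) >= d + 2L) gi else which(fin)
  X <- pmat[fit_rows, , drop = FALSE]
  n_terms <- 1L + 2L * d + d * (d - 1L) / 2L
  form_terms <- c(colnames(X), paste0("I(", colnames(X), "^2)"))
  if (length(fit_rows) > n_terms + 2L && d > 1L) {
    cmb <- utils::combn(colnames(X), 2L)
    form_terms <- c(form_terms, paste0(cmb[1L, ], ":", cmb[2L, ]))
  }
  df <- as.data.frame(X)
  preds <- tryCatch({
    set.seed(attr(scr, "seed") + 1L)
    cand_unit <- lhs::randomLHS(n_candidates, d)
    cand <- sweep(sweep(cand_unit, 2L, bounds$upper - bounds$lower, "*"),
                  2L, bounds$lower, "+")
    colnames(cand) <- bounds$name
    cand_df <- as.data.frame(cand)
    pm <- sapply(seq_len(ncol(omat)), function(j) {
      df$.y <- omat[fit_rows, j]
      fml <- stats::as.formula(paste(".y ~", paste(form_terms,
                                                   collapse = " + ")))
      stats::predict(stats::lm(fml, data = df), newdata = cand_df)
    })
    list(cand = cand, pm = matrix(pm, ncol = ncol(omat)))
  }, error = function(e) NULL)
  if (!is.null(preds)) {
    dist_pred <- sqrt(rowSums(sweep(norm(preds$pm), 2L, tgt, "-")^2))
    j <- which.min(dist_pred)
    if (is.finite(dist_pred[j]) && dist_pred[j] < best$dist) {
      best <- list(par = stats::setNames(preds$cand[j, ], bounds$name),
                   dist = dist_pred[j])
    }
  }
  best$par
}
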