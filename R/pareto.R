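#' Configuration for the Normalized Normal Constraint solver
#'
#' @param n_plane_points Lattice density per simplex edge on the Utopian
#'   plane (desk-scale defaults: 7 for two objectives, 5 for three).
#' @param extra_start_fractions Fractions of the constraint-vector length at
#'   which additional inward search starts are seeded (guards against local
#'   minima along each normal constraint).
#' @param k_starts Starts per anchor optimization.
#' @param maxit Iteration cap per local search.
#' @param penalty Quadratic penalty weight enforcing the on-constraint-line
#'   condition in normalized objective space.
#' @param seed Integer seed.
#' @return A list of class `os_nnc_config`.
#' @export
nnc_config <- function(n_plane_points = NULL,
                       extra_start_fractions = c(0.25, 0.5, 0.75),
                       k_starts = 8L, maxit = 40L, penalty = 1e4,
                       seed = 1L) {
  stopifnot(all(extra_start_fractions > 0), all(extra_start_fractions < 1))
  structure(list(n_plane_points = n_plane_points,
                 extra_start_fractions = extra_start_fractions,
                 k_starts = as.integer(k_starts), maxit = as.integer(maxit),
                 penalty = penalty, seed = as.integer(seed)),
            class = "os_nnc_config")
}

#' Pareto dominance filter
#'
#' Keeps exactly the non-dominated rows: a point is dominated if another
#' point is no worse in every objective and strictly better in at least
#' one.  Duplicates are removed keeping the first occurrence.
#'
#' @param points Numeric matrix, one row per point, one column per
#'   objective (minimization).
#' @return Integer vector of retained row indices.
#' @export
pareto_filter <- function(points) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n == 0L) return(integer(0))
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    if (!keep[i]) next
    p <- points[i, ]
    leq <- points <= matrix(p, n, ncol(points), byrow = TRUE)
    lt <- points < matrix(p, n, ncol(points), byrow = TRUE)
    dominates_i <- rowSums(leq) == ncol(points) & rowSums(lt) > 0L
    dup <- rowSums(points == matrix(p, n, ncol(points), byrow = TRUE)) ==
      ncol(points)
    dup[seq_len(i)] <- FALSE
    if (any(dominates_i & keep)) keep[i] <- FALSE
    keep[dup] <- FALSE
  }
  which(keep)
}

#' Solve the anchor points of a multi-objective problem
#'
#' One multistart single-objective minimization per objective component,
#' all reusing the same global screen.
#'
#' @param objective Vector objective function.
#' @param bounds A [param_bounds()] table.
#' @param scr An `os_screen` evaluated with the full objective vector.
#' @param cfg An [nnc_config()].
#' @return A tibble with one row per objective: `objective` (name),
#'   parameter columns, and `obj_*` value columns.
#' @export
solve_anchors <- function(objective, bounds, scr, cfg = nnc_config()) {
  obj_names <- attr(scr, "obj_names")
  m <- length(obj_names)
  rows <- lapply(seq_len(m), function(j) {
    ms <- multistart(scr, cfg$k_starts, objective, which = j,
                     maxit = cfg$maxit)
    par <- stats::setNames(as.numeric(ms[1L, bounds$name]), bounds$name)
    vals <- objective(par)
    tibble::tibble(objective = obj_names[j],
                   !!!stats::setNames(as.list(par), bounds$name),
                   !!!stats::setNames(as.list(as.numeric(vals)),
                                      paste0("obj_", obj_names)))
  })
  dplyr::bind_rows(rows)
}

# Even barycentric lattice on the (m-1)-simplex with `density` points per
# edge; returns a matrix of barycentric weight rows.
simplex_lattice <- function(m, density) {
  if (m == 2L) {
    t <- seq(0, 1, length.out = density)
    return(cbind(1 - t, t))
  }
  k <- density - 1L
  grid <- multi_indices(m - 1L, k)
  grid <- grid[rowSums(grid) <= k, , drop = FALSE]
  w <- cbind(grid, k - rowSums(grid)) / k
  w
}

#' Points and normal of the Utopian plane
#'
#' In the normalized objective space spanned by the anchors, returns an
#' even barycentric lattice of start points on the Utopian (anchor) plane
#' and the common inward normal direction.
#'
#' @param anchors Anchor tibble from [solve_anchors()].
#' @param cfg An [nnc_config()].
#' @return List with `points` (matrix in normalized space), `normal` (unit
#'   vector), `normalize`/`denormalize` (affine maps), `utopia` (raw
#'   component-wise anchor minima).
#' @export
nnc_points <- function(anchors, cfg = nnc_config()) {
  obj_cols <- grep("^obj_", names(anchors), value = TRUE)
  A <- as.matrix(anchors[obj_cols])
  m <- nrow(A)
  if (m < 2L) stop("need at least two anchors", call. = FALSE)
  utopia <- apply(A, 2L, min)
  nadir <- apply(A, 2L, max)
  scale <- nadir - utopia
  if (any(scale == 0)) {
    warning("anchors affinely dependent in some objective; using unit scale")
    scale[scale == 0] <- 1
  }
  normalize <- function(v) (v - utopia) / scale
  denormalize <- function(v) v * scale + utopia
  An <- t(apply(A, 1L, normalize))
  density <- cfg$n_plane_points %||% (if (m == 2L) 7L else 5L)
  W <- simplex_lattice(m, density)
  pts <- W %*% An
  # inward normal: orthogonal to the plane spanned by anchor differences,
  # pointing toward lower objectives
  base <- An[1L, ]
  E <- t(An[-1L, , drop = FALSE]) - base   # m x (m-1) edge matrix
  nrm <- qr.Q(qr(cbind(E, diag(m))))[, m]
  if (sum(nrm) > 0) nrm <- -nrm
  nrm <- nrm / sqrt(sum(nrm^2))
  list(points = pts, normal = nrm, normalize = normalize,
       denormalize = denormalize, utopia = utopia,
       anchors_normalized = An)
}

#' Trace the Pareto front with the modified Normalized Normal Constraint
#'
#' For each lattice point on the Utopian plane, seeds local searches from
#' the response-surface interpolant (at the plane point and at inward
#' offsets along the normal) and minimizes progress along the normal
#' direction, holding solutions on their constraint line by a quadratic
#' penalty in normalized objective space.  Collected solutions plus the
#' anchors are filtered for Pareto optimality and deduplicated.
#'
#' @param objective Vector objective function.
#' @param bounds A [param_bounds()] table.
#' @param scr An `os_screen` evaluated with the full objective vector (one
#'   screen serves the anchors and every constraint search).
#' @param cfg An [nnc_config()].
#' @return An `os_pareto` object: list with `representatives` (tibble:
#'   parameter columns + `obj_*`), `anchors`, `utopia`, `obj_names`.
#' @export
solve_front <- function(objective, bounds, scr, cfg = nnc_config()) {
  obj_names <- attr(scr, "obj_names")
  anchors <- solve_anchors(objective, bounds, scr, cfg)
  A <- as.matrix(anchors[paste0("obj_", obj_names)])
  spread <- apply(A, 2L, function(x) max(x) - min(x))
  if (all(spread <= 1e-9 * pmax(1, abs(apply(A, 2L, min))))) {
    # all anchors coincide: the front is a single point, no trade-off
    reps <- anchors[c(bounds$name, paste0("obj_", obj_names))]
    reps <- reps[!duplicated(round(as.matrix(reps[bounds$name]), 8)), ]
    return(structure(list(representatives = tibble::as_tibble(reps),
                          anchors = anchors, utopia = apply(A, 2L, min),
                          obj_names = obj_names, bounds = bounds),
                     class = "os_pareto"))
  }
  geom <- nnc_points(anchors, cfg)
  m <- length(obj_names)
  nrm <- geom$normal

  cand_pars <- list()
  for (i in seq_len(nrow(geom$points))) {
    p0 <- geom$points[i, ]
    # seed targets: on the plane and at inward fractions along the normal
    t_seeds <- c(0, cfg$extra_start_fractions)
    for (fr in t_seeds) {
      tgt_n <- p0 + fr * nrm
      tgt <- geom$denormalize(tgt_n)
      seed_par <- interpolant_seed(scr, tgt)
      pen_obj <- function(theta) {
        v <- objective(theta)
        if (any(!is.finite(v))) return(1e10)
        vn <- geom$normalize(v)
        tt <- sum((vn - p0) * nrm)
        r <- (vn - p0) - tt * nrm
        tt + cfg$penalty * sum(r^2)
      }
      fit <- tryCatch(
        stats::optim(seed_par, pen_obj, method = "L-BFGS-B",
                     lower = bounds$lower, upper = bounds$upper,
                     control = list(maxit = cfg$maxit)),
        error = function(e) NULL)
      if (!is.null(fit)) cand_pars[[length(cand_pars) + 1L]] <- fit$par
    }
  }
  # evaluate candidates, append anchors, filter
  pmat <- do.call(rbind, cand_pars)
  vals <- t(apply(pmat, 1L, objective))
  amat <- as.matrix(anchors[bounds$name])
  avals <- as.matrix(anchors[paste0("obj_", obj_names)])
  pmat <- rbind(pmat, amat)
  vals <- rbind(vals, avals)
  fin <- apply(vals, 1L, function(r) all(is.finite(r)))
  pmat <- pmat[fin, , drop = FALSE]; vals <- vals[fin, , drop = FALSE]
  keep <- pareto_filter(vals)
  pmat <- pmat[keep, , drop = FALSE]; vals <- vals[keep, , drop = FALSE]
  # deduplicate by parameter-space distance
  if (nrow(pmat) > 1L) {
    dup <- rep(FALSE, nrow(pmat))
    for (i in 2:nrow(pmat)) {
      d <- sqrt(rowSums(sweep(pmat[seq_len(i - 1L), , drop = FALSE],
                              2L, pmat[i, ], "-")^2))
      if (any(d < 1e-6 & !dup[seq_len(i - 1L)])) dup[i] <- TRUE
    }
    pmat <- pmat[!dup, , drop = FALSE]; vals <- vals[!dup, , drop = FALSE]
  }
  colnames(pmat) <- bounds$name
  colnames(vals) <- paste0("obj_", obj_names)
  reps <- tibble::as_tibble(cbind(as.data.frame(pmat), as.data.frame(vals)))
  structure(list(representatives = reps, anchors = anchors,
                 utopia = geom$utopia, obj_names = obj_names,
                 bounds = bounds),
            class = "os_pareto")
}

#' @export
print.os_pareto <- function(x, ...) {
  cat("<os_pareto>", nrow(x$representatives), "representatives over",
      length(x$obj_names), "objectives (", paste(x$obj_names,
                                                 collapse = ", "), ")\n")
  cat(" utopia:", paste(signif(x$utopia, 4), collapse = ", "), "\n")
  invisible(x)
}
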