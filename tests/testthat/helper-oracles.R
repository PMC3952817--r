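# Independent brute-force reference implementations used to cross-check the
# package's algorithms.

# O(n^2) double-loop Pareto dominance check
brute_pareto <- function(points) {
  n <- nrow(points)
  keep <- logical(n)
  for (i in seq_len(n)) {
    dominated <- FALSE
    dup_earlier <- FALSE
    for (j in seq_len(n)) {
      if (j == i) next
      if (all(points[j, ] <= points[i, ]) && any(points[j, ] < points[i, ]))
        dominated <- TRUE
      if (j < i && all(points[j, ] == points[i, ]))
        dup_earlier <- TRUE
    }
    keep[i] <- !dominated && !dup_earlier
  }
  which(keep)
}

# Direct zero-error feasibility check for Optimal Scaling: intervals with the
# required widths and gaps exist containing every observed cell's value.
# Written as an explicit interval-propagation over rank data ranges,
# independent of the package's construction.
brute_zero_feasible <- function(y, ranks, n_cat, cfg = scaling_config()) {
  obs <- !is.na(ranks)
  yv <- y[obs]; rv <- ranks[obs]
  S <- model_scale(y)
  mg <- min_range_and_gap(n_cat, S, cfg)
  # minimal attainable upper bound of interval r, scanning anteriorly
  u_prev <- -Inf
  for (r in seq_len(n_cat)) {
    vals <- yv[rv == r]
    l_low <- max(cfg$lower_bound, u_prev + ifelse(r > 1, mg$gap_min, 0))
    if (length(vals)) {
      if (l_low > min(vals) + 1e-9 * S) return(FALSE)
      u_prev <- max(max(vals), l_low + mg$delta_min)
    } else {
      u_prev <- l_low + mg$delta_min
    }
  }
  TRUE
}

# direct recomputation of the design objectives from first principles
brute_expected_variance <- function(ensembles) {
  eps <- sapply(ensembles, function(m) {
    sapply(seq_len(ncol(m)), function(j) {
      v <- sort(m[, j])
      md <- stats::median(v)
      if (md %in% c(0, 1)) md else 0
    })
  })
  # eps: regions x models
  sum(apply(eps, 1L, function(x) mean(x^2) - mean(x)^2))
}

brute_jaccard <- function(ensembles) {
  key <- function(m) apply(m, 1, paste, collapse = "|")
  nm <- length(ensembles)
  total <- 0
  for (j in seq_len(nm - 1)) for (k in (j + 1):nm) {
    kj <- key(ensembles[[j]]); kk <- key(ensembles[[k]])
    Mjk <- sum(kj %in% kk); Mkj <- sum(kk %in% kj)
    total <- total + 1 - (Mjk + Mkj) / (length(kj) + length(kk))
  }
  total
}

brute_prediction_variance <- function(ensembles) {
  total <- 0
  for (m in ensembles) {
    if (nrow(m) < 2) next
    for (j in seq_len(ncol(m))) {
      v <- m[, j]
      total <- total + mean(v^2) - mean(v)^2
    }
  }
  total
}

# random small scaling instance generator
random_scaling_instance <- function(max_cells = 6L, max_cat = 3L) {
  n <- sample(3:max_cells, 1L)
  nc <- sample(2:max_cat, 1L)
  y <- runif(n)
  ranks <- sample(seq_len(nc), n, replace = TRUE)
  list(y = y, ranks = ranks, n_cat = max(ranks))
}
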