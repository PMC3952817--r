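#' Enumerate candidate genetic experiments
#'
#' All single and unordered pairwise combinations of perturbation kinds on
#' distinct species: `|S|*|T|` singles plus `C(|S|,2)*|T|^2` pairs.  The
#' standard set — seven species (Dpp, Rec, Mad, Bam, Nos, Brat, dMyc) by
#' three kinds (null, heterozygous, doubled) — yields 210 conditions.
#'
#' @param species Species that can be perturbed.
#' @param kinds Perturbation kinds.
#' @return List of `os_condition` objects.
#' @export
enumerate_conditions <- function(species = c("Dpp", "Rec", "Mad", "Bam",
                                             "Nos", "Brat", "dMyc"),
                                 kinds = c("null", "heterozygous",
                                           "doubled")) {
  stopifnot(length(species) > 0, length(kinds) > 0)
  out <- list()
  for (sp in species) for (k in kinds) {
    out[[length(out) + 1L]] <- do.call(genetic_condition,
                                       stats::setNames(list(k), sp))
  }
  if (length(species) > 1L) {
    cmb <- utils::combn(species, 2L)
    for (i in seq_len(ncol(cmb))) for (k1 in kinds) for (k2 in kinds) {
      out[[length(out) + 1L]] <- do.call(
        genetic_condition,
        stats::setNames(list(k1, k2), cmb[, i]))
    }
  }
  out
}

#' Discretize a model output into a per-region binary observation
#'
#' Translates a simulated per-cell output into the expected qualitative
#' (high/low) observation by reusing the Optimal Scaling interval
#' machinery: among all 2-level region labelings, the one achieving the
#' minimal scaling error is returned (ties broken toward fewer high
#' regions, then lexicographically).
#'
#' @param y Per-cell output over the germline cells.
#' @param rm Region map.
#' @param cfg An [scaling_config()].
#' @return Named integer vector of 0 (low) / 1 (high) per region.
#' @export
qualitative_discretize <- function(y, rm = region_map(),
                                   cfg = scaling_config()) {
  nr <- length(rm$region_names)
  labelings <- as.matrix(expand.grid(rep(list(0:1), nr)))[, nr:1,
                                                          drop = FALSE]
  colnames(labelings) <- rm$region_names
  # order by number of high regions then lexicographically: ties go to the
  # earlier row
  ord <- order(rowSums(labelings),
               apply(labelings, 1L, paste, collapse = ""))
  labelings <- labelings[ord, , drop = FALSE]
  errs <- apply(labelings, 1L, function(lab) {
    ranks <- integer(rm$n_cells_germline)
    for (j in seq_len(nr)) ranks[rm$regions[[rm$region_names[j]]]] <-
        lab[j] + 1L
    n_cat <- length(unique(lab)) # 1 if uniform, else 2
    if (n_cat == 1L) ranks[] <- 1L
    domains <- lapply(rm$region_names, function(nm)
      rm$regions[[nm]])
    solve_scaling(y, ranks, n_cat, domains, cfg)$error
  })
  best <- which.min(errs)  # first minimum respects the tie-break order
  labelings[best, ]
}

#' Qualitative prediction ensembles for one experiment
#'
#' Simulates one (condition, measured species) experiment for every
#' Representative of every model and discretizes the outputs to binary
#' region predictions.
#'
#' @param models Named list of `os_model`.
#' @param representatives Named list (same names) of tibbles of
#'   Representative log10 parameter values (columns named by parameter).
#' @param condition An `os_condition`.
#' @param species Measured species.
#' @param dynamic Use the post-division protocol (default FALSE).
#' @param cfg An [scaling_config()].
#' @return Named list (per model) of matrices, one row per Representative,
#'   one column per region (0/1).
#' @export
prediction_ensembles <- function(models, representatives, condition,
                                 species, dynamic = FALSE,
                                 cfg = scaling_config()) {
  out <- list()
  for (nm in names(models)) {
    model <- models[[nm]]
    reps <- representatives[[nm]]
    pcols <- intersect(names(reps), names(model$params))
    preds <- matrix(NA_integer_, nrow(reps),
                    length(model$region_map$region_names),
                    dimnames = list(NULL, model$region_map$region_names))
    for (i in seq_len(nrow(reps))) {
      m2 <- model
      m2$params[pcols] <- 10^as.numeric(reps[i, pcols])
      sim <- if (dynamic) simulate_dynamic(m2, condition)
             else simulate_steady(m2, condition)
      if (sim$failed) next
      y <- observable(sim, species)
      preds[i, ] <- qualitative_discretize(y, model$region_map, cfg)
    }
    out[[nm]] <- preds[stats::complete.cases(preds), , drop = FALSE]
  }
  out
}

#' Expected qualitative prediction of a model
#'
#' The per-region median across Representatives (for binary predictions,
#' the most likely observation with Representatives weighted equally);
#' exact ties go to low.
#'
#' @param ensemble Matrix of 0/1 predictions, Representatives by regions.
#' @return Integer vector of 0/1 per region.
#' @export
expected_prediction <- function(ensemble) {
  stopifnot(nrow(ensemble) >= 1L)
  med <- apply(ensemble, 2L, stats::median)
  as.integer(med > 0.5)
}

pop_var <- function(x) mean(x^2) - mean(x)^2

#' Discrimination score: variance of expected predictions across models
#'
#' Per region, the (population) variance over models of the expected
#' prediction, summed over regions (each region weighs equally — the
#' per-region mean of a region-constant prediction is the prediction
#' itself).
#'
#' @param ensembles Named list of per-model prediction matrices.
#' @return Non-negative scalar.
#' @export
objective_expected_variance <- function(ensembles) {
  if (length(ensembles) < 2L)
    stop("need at least two models", call. = FALSE)
  ep <- t(vapply(ensembles, expected_prediction,
                 integer(ncol(ensembles[[1L]]))))
  sum(apply(ep, 2L, pop_var))
}

#' Discrimination score: summed pairwise Jaccard dissimilarity
#'
#' For each model pair (j, k), the Jaccard-style similarity
#' `J = (M_jk + M_kj) / (R_j + R_k)` counts the Representatives of each
#' model whose full prediction vector also appears in the other model's
#' prediction set.  The score sums `1 - J` over pairs: 0 when all models
#' predict the same outcome sets, and the number of pairs when all
#' prediction sets are mutually exclusive.
#'
#' @param ensembles Named list of per-model prediction matrices.
#' @return Scalar in `[0, choose(n_models, 2)]`.
#' @export
objective_jaccard <- function(ensembles) {
  if (length(ensembles) < 2L)
    stop("need at least two models", call. = FALSE)
  if (any(vapply(ensembles, nrow, integer(1)) == 0L))
    stop("empty representative set", call. = FALSE)
  keys <- lapply(ensembles, function(m)
    apply(m, 1L, paste, collapse = ""))
  nm <- length(ensembles)
  score <- 0
  for (j in seq_len(nm - 1L)) for (k in (j + 1L):nm) {
    M_jk <- sum(keys[[j]] %in% keys[[k]])
    M_kj <- sum(keys[[k]] %in% keys[[j]])
    J <- (M_jk + M_kj) / (length(keys[[j]]) + length(keys[[k]]))
    score <- score + (1 - J)
  }
  score
}

#' Refinement score: within-model prediction variance
#'
#' Per model and region, the (population) variance of predictions across
#' Representatives, summed over regions and models.  Models with a single
#' Representative contribute zero.
#'
#' @param ensembles Named list of per-model prediction matrices.
#' @return Non-negative scalar.
#' @export
objective_prediction_variance <- function(ensembles) {
  sum(vapply(ensembles, function(m) {
    if (nrow(m) < 2L) return(0)
    sum(apply(m, 2L, pop_var))
  }, numeric(1)))
}

# region-mean-sum aggregation of a per-cell vector
region_mean_sum <- function(x, rm) {
  sum(vapply(rm$region_names, function(nm)
    mean(x[rm$regions[[nm]]]), numeric(1)))
}

#' Quantitative experiment design from sensitivity tables
#'
#' Ranks (perturbed parameter, measured species) experiments for
#' quantitative readouts.  `discriminate`: variance over models of the
#' Representative-mean sensitivity; `refine`: sum over models of the
#' Representative variance of sensitivity.  Cells are aggregated by region
#' means summed.
#'
#' @param tables Named list (per model) of sensitivity tibbles from
#'   [sensitivity_table()].
#' @param mode `"discriminate"` or `"refine"`.
#' @param rm Region map.
#' @return A `DesignTable` tibble: `parameter`, `species`, `objective`,
#'   `score`.
#' @export
quantitative_design <- function(tables, mode = c("discriminate", "refine"),
                                rm = region_map()) {
  mode <- match.arg(mode)
  axes <- lapply(tables, function(t) unique(t[c("parameter", "species")]))
  for (a in axes[-1L]) if (!identical(dim(a), dim(axes[[1L]])) ||
                           !all(a$parameter %in% axes[[1L]]$parameter) ||
                           !all(a$species %in% axes[[1L]]$species))
    stop("sensitivity tables must share (parameter, species) axes",
         call. = FALSE)
  pairs <- axes[[1L]]
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    pm <- pairs$parameter[i]; sp <- pairs$species[i]
    per_model <- lapply(tables, function(t) {
      tt <- t[t$parameter == pm & t$species == sp & is.finite(t$value), ]
      split(tt$value[order(tt$representative, tt$cell)],
            tt$representative[order(tt$representative, tt$cell)])
    })
    score <- if (mode == "discriminate") {
      means <- vapply(per_model, function(reps) {
        cm <- rowMeans(do.call(cbind, reps))
        region_mean_sum(cm, rm)
      }, numeric(1))
      pop_var(means)
    } else {
      sum(vapply(per_model, function(reps) {
        m <- do.call(cbind, reps)
        if (ncol(m) < 2L) return(0)
        region_mean_sum(apply(m, 1L, pop_var), rm)
      }, numeric(1)))
    }
    tibble::tibble(parameter = pm, species = sp,
                   objective = mode, score = score)
  })
  dplyr::bind_rows(rows)
}

#' Normalize and rank a design table
#'
#' Min-max normalizes scores within each objective (max maps to 1, min to
#' 0; a constant column maps to 0), sorts descending and keeps the top
#' rows.
#'
#' @param table Design tibble with columns `objective`, `score`.
#' @param top_k Rows to retain per objective (default all).
#' @return The table with a `normalized` column, sorted by score.
#' @export
rank_table <- function(table, top_k = Inf) {
  stopifnot(nrow(table) > 0)
  out <- dplyr::mutate(
    dplyr::group_by(table, .data$objective),
    normalized = {
      r <- range(.data$score)
      if (diff(r) == 0) rep(0, dplyr::n())
      else (.data$score - r[1L]) / diff(r)
    })
  out <- dplyr::slice_max(out, .data$score, n = top_k, with_ties = FALSE)
  dplyr::ungroup(dplyr::arrange(out, .data$objective,
                                dplyr::desc(.data$score)))
}
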