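test_that("condition enumeration covers singles and unordered pairs", {
  expect_length(enumerate_conditions(), 210L)
  expect_length(enumerate_conditions("Bam", "null"), 1L)
  expect_length(enumerate_conditions(c("Bam", "Nos"),
                                     c("null", "doubled")), 8L)
  # labels are unique
  labs <- vapply(enumerate_conditions(), condition_label, character(1))
  expect_equal(anyDuplicated(labs), 0L)
})

test_that("qualitative discretization picks the minimal-error labeling", {
  rm <- region_map()
  set.seed(41)
  for (k in 1:4) {
    y <- sort(runif(17), decreasing = TRUE) + rnorm(17, 0, 0.02)
    lab <- qualitative_discretize(y, rm)
    # exhaustive check: no labeling achieves a smaller scaling error
    err_of <- function(l) {
      ranks <- integer(17)
      for (j in 1:4) ranks[rm$regions[[rm$region_names[j]]]] <- l[j] + 1L
      nc <- length(unique(l)); if (nc == 1) ranks[] <- 1L
      solve_scaling(y, ranks, nc,
                    lapply(rm$region_names, function(nm)
                      rm$regions[[nm]]))$error
    }
    all_labs <- as.matrix(expand.grid(rep(list(0:1), 4)))
    colnames(all_labs) <- rm$region_names
    errs <- apply(all_labs, 1, err_of)
    expect_equal(err_of(lab), min(errs), tolerance = 1e-9)
  }
  # flat output: uniform-low by tie break
  expect_equal(unname(qualitative_discretize(rep(1, 17), rm)), rep(0L, 4))
  # strongly anterior-high output maps to high in the anterior
  y <- c(rep(1, 2), rep(0.98, 7), rep(0.02, 8))
  lab <- qualitative_discretize(y, rm)
  expect_equal(unname(lab), c(1L, 1L, 1L, 0L))
})

test_that("expected predictions are per-region medians with ties low", {
  expect_equal(expected_prediction(rbind(c(0, 1), c(0, 1), c(1, 1))),
               c(0L, 1L))
  expect_equal(expected_prediction(rbind(c(1, 0), c(1, 0))), c(1L, 0L))
  expect_equal(expected_prediction(rbind(c(0, 1), c(1, 0))), c(0L, 0L))
  expect_equal(expected_prediction(rbind(c(1, 0, 1, 0))), c(1L, 0L, 1L, 0L))
})

random_ensembles <- function(n_models = 3, regions = 4) {
  stats::setNames(lapply(seq_len(n_models), function(i)
    matrix(rbinom(sample(2:6, 1) * regions, 1, 0.5), ncol = regions)),
    paste0("m", seq_len(n_models)))
}

test_that("design objectives hit their boundary values", {
  same <- matrix(c(1, 0, 1, 0), 3, 4, byrow = TRUE)
  ens_same <- list(a = same, b = same, c = same)
  expect_equal(objective_expected_variance(ens_same), 0)
  expect_equal(objective_jaccard(ens_same), 0)
  expect_equal(objective_prediction_variance(ens_same), 0)
  # opposite uniform predictions: maximal expected-prediction variance
  ens_opp <- list(a = matrix(0, 2, 4), b = matrix(1, 2, 4))
  expect_equal(objective_expected_variance(ens_opp), 4 * 0.25)
  # mutually exclusive sets: Jaccard score = number of model pairs
  ens3 <- list(a = matrix(0, 2, 4), b = matrix(1, 2, 4),
               c = rbind(c(0, 1, 0, 1), c(1, 0, 1, 0)))
  expect_equal(objective_jaccard(ens3), choose(3, 2))
  expect_error(objective_expected_variance(ens_same[1]), "two models")
})

test_that("design objectives match independent recomputation", {
  set.seed(43)
  for (k in 1:10) {
    ens <- random_ensembles()
    expect_equal(objective_expected_variance(ens),
                 brute_expected_variance(ens))
    expect_equal(objective_jaccard(ens), brute_jaccard(ens))
    expect_equal(objective_prediction_variance(ens),
                 brute_prediction_variance(ens))
    # permutation of representatives changes nothing
    perm <- lapply(ens, function(m) m[sample(nrow(m)), , drop = FALSE])
    expect_equal(objective_jaccard(perm), objective_jaccard(ens))
    expect_equal(objective_prediction_variance(perm),
                 objective_prediction_variance(ens))
    # duplicating a representative re-weights the pairwise index exactly as
    # the representative-count definition prescribes
    dup <- ens
    dup[[1]] <- rbind(dup[[1]], dup[[1]][1, , drop = FALSE])
    expect_equal(objective_jaccard(dup), brute_jaccard(dup))
  }
})

test_that("quantitative design modes reduce to their variance formulas", {
  rm <- region_map()
  mk_table <- function(vals) {
    # vals: list of per-representative 17-cell vectors
    dplyr::bind_rows(lapply(seq_along(vals), function(i)
      tibble::tibble(representative = i, parameter = "phi_X",
                     species = "X", cell = 1:17, value = vals[[i]])))
  }
  t1 <- mk_table(list(rep(1, 17), rep(1, 17)))
  t2 <- mk_table(list(rep(1, 17), rep(1, 17)))
  # identical sensitivities: discriminate score 0
  d <- quantitative_design(list(a = t1, b = t2), "discriminate", rm)
  expect_equal(d$score, 0)
  # single representative per model: refine score 0
  t3 <- mk_table(list(rep(2, 17)))
  r <- quantitative_design(list(a = t3, b = t3), "refine", rm)
  expect_equal(r$score, 0)
  # random tables equal brute-force recomputation
  set.seed(44)
  va <- list(runif(17), runif(17)); vb <- list(runif(17), runif(17))
  ta <- mk_table(va); tb <- mk_table(vb)
  d2 <- quantitative_design(list(a = ta, b = tb), "discriminate", rm)
  rms <- function(x) sum(vapply(rm$region_names, function(nm)
    mean(x[rm$regions[[nm]]]), numeric(1)))
  means <- c(rms((va[[1]] + va[[2]]) / 2), rms((vb[[1]] + vb[[2]]) / 2))
  expect_equal(d2$score, mean(means^2) - mean(means)^2)
  r2 <- quantitative_design(list(a = ta, b = tb), "refine", rm)
  vr <- function(vs) rms(sapply(1:17, function(i) {
    v <- c(vs[[1]][i], vs[[2]][i]); mean(v^2) - mean(v)^2
  }))
  expect_equal(r2$score, vr(va) + vr(vb))
})

test_that("rank_table normalizes per objective and keeps order", {
  tb <- tibble::tibble(parameter = letters[1:4], species = "X",
                       objective = "discriminate",
                       score = c(4, 1, 3, 2))
  out <- rank_table(tb)
  expect_equal(out$score, c(4, 3, 2, 1))
  expect_equal(out$normalized, c(1, 2 / 3, 1 / 3, 0))
  out2 <- rank_table(tb, top_k = 2)
  expect_equal(nrow(out2), 2L)
  # constant column maps to zero
  tbc <- tibble::tibble(parameter = "a", species = "X",
                        objective = "refine", score = c(2, 2))
  expect_equal(rank_table(tbc)$normalized, c(0, 0))
})
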