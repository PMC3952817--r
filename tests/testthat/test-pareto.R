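test_that("pareto_filter handles dominated, incomparable and duplicates", {
  expect_equal(pareto_filter(rbind(c(1, 1), c(2, 2))), 1L)
  expect_equal(pareto_filter(rbind(c(1, 2), c(2, 1))), c(1L, 2L))
  expect_equal(pareto_filter(rbind(c(1, 1), c(1, 1))), 1L)
  expect_equal(pareto_filter(matrix(numeric(0), 0, 2)), integer(0))
})

test_that("pareto_filter matches the O(n^2) dominance oracle", {
  set.seed(21)
  for (k in 1:5) {
    pts <- matrix(runif(600), ncol = 3)
    expect_equal(pareto_filter(pts), brute_pareto(pts))
  }
  # with ties/duplicates
  pts <- matrix(sample(1:3, 300, replace = TRUE), ncol = 3)
  expect_equal(pareto_filter(pts), brute_pareto(pts))
})

test_that("pareto_filter is idempotent", {
  set.seed(22)
  pts <- matrix(runif(300), ncol = 3)
  k1 <- pareto_filter(pts)
  k2 <- pareto_filter(pts[k1, , drop = FALSE])
  expect_equal(k2, seq_along(k1))
})

toy <- make_toy_biobjective()
toy_scr <- screen(toy$bounds, 60, seed = 7, toy$objective)

test_that("anchors of the toy biobjective are exact", {
  an <- solve_anchors(toy$objective, toy$bounds, toy_scr,
                      nnc_config(seed = 7))
  expect_equal(nrow(an), 2L)
  expect_equal(an$x, c(1, -1), tolerance = 1e-5)
  expect_equal(an$obj_f1, c(0, 4), tolerance = 1e-6)
  expect_equal(an$obj_f2, c(4, 0), tolerance = 1e-6)
  # each anchor is minimal in its own coordinate among screened samples
  expect_lte(an$obj_f1[1], min(toy_scr$obj_f1))
  expect_lte(an$obj_f2[2], min(toy_scr$obj_f2))
})

test_that("plane points are evenly spaced with a common normal", {
  an <- solve_anchors(toy$objective, toy$bounds, toy_scr,
                      nnc_config(seed = 7))
  geom <- nnc_points(an, nnc_config(n_plane_points = 5))
  expect_equal(nrow(geom$points), 5L)
  # normalized anchor segment: points at t = 0, .25, .5, .75, 1
  t <- geom$points[, 1]
  expect_equal(sort(t), c(0, 0.25, 0.5, 0.75, 1), tolerance = 1e-9)
  expect_equal(sum(geom$normal^2), 1)
  expect_lt(sum(geom$normal), 0)  # points toward lower objectives
  # 3-objective lattice count: C(d + 1, 2) for density d
  an3 <- an[c(1, 2, 1), ]
  an3$obj_f1 <- c(0, 4, 2); an3$obj_f2 <- c(4, 0, 3)
  an3$obj_f3 <- c(1, 2, 0)
  geom3 <- nnc_points(an3, nnc_config(n_plane_points = 5))
  expect_equal(nrow(geom3$points), choose(5 + 1, 2))
})

test_that("NNC recovers the closed-form toy front", {
  front <- solve_front(toy$objective, toy$bounds, toy_scr,
                       nnc_config(seed = 7))
  reps <- front$representatives
  expect_gte(nrow(reps), 5L)
  dev <- abs(reps$obj_f2 - toy$front(reps$obj_f1))
  expect_lt(max(dev), 1e-3)
  # mutual non-dominance
  om <- as.matrix(reps[c("obj_f1", "obj_f2")])
  expect_equal(pareto_filter(om), seq_len(nrow(om)))
  # anchors survive
  expect_true(any(abs(reps$obj_f1 - 0) < 1e-6))
  expect_true(any(abs(reps$obj_f2 - 0) < 1e-6))
})

test_that("affinely rescaling one objective leaves the front unchanged", {
  scaled <- function(theta) {
    v <- toy$objective(theta)
    c(f1 = 10 * v[["f1"]] + 3, f2 = v[["f2"]])
  }
  scr2 <- screen(toy$bounds, 60, seed = 7, scaled)
  f1 <- solve_front(toy$objective, toy$bounds, toy_scr,
                    nnc_config(seed = 7))
  f2 <- solve_front(scaled, toy$bounds, scr2, nnc_config(seed = 7))
  x1 <- sort(f1$representatives$x)
  x2 <- sort(f2$representatives$x)
  expect_equal(length(x1), length(x2))
  expect_equal(x1, x2, tolerance = 1e-4)
})
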