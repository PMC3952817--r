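test_that("inhibitory enumeration counts are combinatorial", {
  expect_length(enumerate_inhibitory(max_edges = 0), 1L)
  e1 <- enumerate_inhibitory(max_edges = 1)
  expect_length(e1, 1L + 12L)          # 12 = 4 * 3 directed non-self edges
  # uncapped: 2^12 topologies (count without materializing all objects)
  expect_length(enumerate_inhibitory(max_edges = 2), 1L + 12L + choose(12, 2))
  expect_true(all(vapply(e1, function(t)
    all(t$edges$from != t$edges$to), logical(1))))
})

test_that("parsimony filter equals the brute-force antichain", {
  set.seed(31)
  edge_pool <- c("a>b", "b>c", "c>a", "a>c")
  for (rep in 1:10) {
    n <- 12
    esets <- lapply(seq_len(n), function(i)
      sort(sample(edge_pool, sample(0:4, 1))))
    cand <- tibble::tibble(
      name = paste0("t", seq_len(n)),
      edge_count = lengths(esets),
      edges = vapply(esets, paste, character(1), collapse = ";"),
      best_wt_error = runif(n),
      accepted = runif(n) < 0.6)
    out <- parsimony_filter(cand)
    # brute force: accepted with no strictly smaller accepted subset
    expected <- vapply(seq_len(n), function(i) {
      if (!cand$accepted[i]) return(FALSE)
      for (j in which(cand$accepted)) {
        if (j == i) next
        if (length(esets[[j]]) < length(esets[[i]]) &&
            all(esets[[j]] %in% esets[[i]])) return(FALSE)
      }
      TRUE
    }, logical(1))
    expect_equal(out$parsimonious, expected)
    # antichain: no parsimonious set strictly contains another
    keep <- which(out$parsimonious)
    for (i in keep) for (j in keep) {
      if (i == j) next
      expect_false(length(esets[[j]]) < length(esets[[i]]) &&
                     all(esets[[j]] %in% esets[[i]]))
    }
  }
  # simple nesting example
  cand <- tibble::tibble(name = c("s", "b"), edge_count = c(1L, 2L),
                         edges = c("a>b", "a>b;b>c"),
                         best_wt_error = c(0.01, 0.01),
                         accepted = c(TRUE, TRUE))
  expect_equal(parsimony_filter(cand)$parsimonious, c(TRUE, FALSE))
  cand2 <- tibble::tibble(name = c("x", "y"), edge_count = c(1L, 1L),
                          edges = c("a>b", "b>c"),
                          best_wt_error = c(0.01, 0.01),
                          accepted = c(TRUE, TRUE))
  expect_equal(parsimony_filter(cand2)$parsimonious, c(TRUE, TRUE))
})

test_that("the WT screen accepts the generating chain, rejects no-edges", {
  st <- synthetic_study()
  obs_wt <- st$observations[st$observations$category == "WildType", ]
  attr(obs_wt, "region_map") <- obs_region_map(st$observations)
  chain <- chain2_topology()
  empty <- network_topology(chain$species, NULL, name = "empty")
  res <- screen_wt(list(chain, empty), obs_wt, threshold = 0.05)
  expect_true(res$accepted[res$name == "chain2"])
  expect_false(res$accepted[res$name == "empty"])
  # threshold = Inf accepts everything
  res_inf <- screen_wt(list(chain, empty), obs_wt, threshold = Inf)
  expect_true(all(res_inf$accepted))
})

test_that("adding edges does not worsen the best WT error (nested lattice)", {
  st <- synthetic_study()
  obs_wt <- st$observations[st$observations$category == "WildType", ]
  attr(obs_wt, "region_map") <- obs_region_map(st$observations)
  chain <- chain2_topology()
  bigger <- network_topology(
    chain$species,
    rbind(chain$edges, data.frame(from = "Nos", to = "Bam",
                                  sign = "repress")),
    name = "chain2plus")
  res <- screen_wt(list(chain, bigger), obs_wt, threshold = 0.05)
  # the weak lattice level is nearly (not exactly) an absent edge, so
  # allow a small numerical slack
  expect_lte(res$best_wt_error[res$name == "chain2plus"],
             res$best_wt_error[res$name == "chain2"] + 1e-3)
})
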