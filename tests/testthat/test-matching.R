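test_that("build_bipartite mirrors the edge set exactly", {
  g <- star_graph()
  H <- build_bipartite(g)
  expect_equal(H$n, 3)
  # star: edges (x1^l, x2^r), (x1^l, x3^r)
  expect_equal(H$labels[H$left], c("x1", "x1"))
  expect_setequal(H$labels[H$right], c("x2", "x3"))

  expect_equal(length(build_bipartite(directed_graph())$left), 0)

  loop <- directed_graph(cbind("u", "u"))
  Hl <- build_bipartite(loop)
  expect_equal(cbind(Hl$left, Hl$right), cbind(1L, 1L), ignore_attr = TRUE)
})

test_that("hopcroft_karp solves the canonical small cases", {
  expect_equal(hopcroft_karp(build_bipartite(star_graph()))$size, 1)
  # n self-loops give the perfect ladder
  lab <- paste0("u", 1:6)
  ladder <- directed_graph(cbind(lab, lab))
  expect_equal(hopcroft_karp(build_bipartite(ladder))$size, 6)
  expect_equal(hopcroft_karp(build_bipartite(cycle_graph(3)))$size, 3)
  expect_equal(hopcroft_karp(build_bipartite(directed_graph()))$size, 0)
})

test_that("brute force oracle handles its canonical cases and refuses big ones", {
  expect_equal(brute_force_max_matching(build_bipartite(star_graph())), 1)
  expect_equal(brute_force_max_matching(build_bipartite(cycle_graph(3))), 3)
  expect_equal(brute_force_max_matching(build_bipartite(directed_graph())), 0)
  big <- random_digraph(10, p = 0.5)
  expect_error(brute_force_max_matching(build_bipartite(big)), "too large")
})

test_that("matching validity invariant holds on random instances", {
  set.seed(101)
  for (i in 1:25) {
    g <- random_digraph(sample(2:15, 1), p = runif(1, 0.1, 0.6),
                        self_loops = TRUE)
    m <- hopcroft_karp(build_bipartite(g))
    matched_l <- which(!is.na(m$match_left))
    expect_equal(length(matched_l), m$size)
    expect_false(anyDuplicated(m$match_left[matched_l]) > 0)
    # every matching edge is an edge of H
    expect_true(all(paste(matched_l, m$match_left[matched_l]) %in%
                      paste(g$from, g$to)))
    # reverse map consistent
    expect_equal(m$match_right[m$match_left[matched_l]], matched_l)
  }
})

test_that("matching size is invariant under left_order permutations", {
  set.seed(7)
  g <- random_digraph(12, p = 0.3)
  H <- build_bipartite(g)
  ref <- hopcroft_karp(H)$size
  for (i in 1:10) {
    expect_equal(hopcroft_karp(H, left_order = sample(H$n))$size, ref)
  }
  expect_error(hopcroft_karp(H, left_order = c(1, 1, 3:12)), "permutation")
})

test_that("hopcroft_karp is deterministic for a fixed left_order", {
  set.seed(13)
  g <- random_digraph(20, p = 0.2)
  H <- build_bipartite(g)
  ord <- sample(H$n)
  m1 <- hopcroft_karp(H, left_order = ord)
  m2 <- hopcroft_karp(H, left_order = ord)
  expect_identical(m1$match_left, m2$match_left)
})

test_that("hopcroft_karp equals brute force on all digraphs with N <= 3", {
  for (self in c(FALSE, TRUE)) {
    for (g in all_digraphs(3, self_loops = self)) {
      H <- build_bipartite(g)
      expect_equal(hopcroft_karp(H)$size, brute_force_max_matching(H))
    }
  }
})

test_that("hopcroft_karp agrees with igraph's matcher on random digraphs", {
  set.seed(31)
  for (i in 1:20) {
    g <- random_digraph(sample(3:12, 1), p = runif(1, 0.1, 0.5))
    H <- build_bipartite(g)
    el <- cbind(H$left, H$n + H$right)
    ig <- igraph::graph_from_edgelist(el, directed = FALSE)
    ig <- igraph::add_vertices(ig, max(0, 2 * H$n - igraph::vcount(ig)))
    types <- rep(c(FALSE, TRUE), each = H$n)
    ref <- igraph::max_bipartite_match(ig, types = types)$matching_size
    expect_equal(hopcroft_karp(H)$size, ref)
  }
})

test_that("matching_from_pairs validates its input", {
  H <- build_bipartite(star_graph())
  m <- matching_from_pairs(H, "x1", "x3")
  expect_equal(m$size, 1)
  expect_error(matching_from_pairs(H, "x2", "x3"), "not an edge")
  expect_error(matching_from_pairs(H, c("x1", "x1"), c("x2", "x3")),
               "share an endpoint")
})
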