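test_that("GLR reproduces the star walkthrough and trivial cases", {
  H <- build_bipartite(star_graph())
  res <- glr(H)
  # one (leaf, root) removal: root is x1^l, matching gains one edge
  expect_equal(res$matching$size, 1)
  expect_equal(res$roots$left, 1L)     # x1^l
  expect_equal(length(res$roots$right), 0)
  expect_equal(res$nc_plus, 0)
  expect_equal(res$nc_minus, 0)
  expect_equal(res$n_r, 1 / 3)

  e <- glr(build_bipartite(directed_graph()))
  expect_equal(e$matching$size, 0)

  # two self-loops on two nodes = bipartite 4-cycle: all core, no leaves
  two <- directed_graph(cbind(c("a", "a", "b", "b"), c("a", "b", "a", "b")))
  res2 <- glr(build_bipartite(two))
  expect_equal(res2$matching$size, 0)
  expect_equal(res2$nc_plus, 1)
  expect_equal(res2$nc_minus, 1)
})

test_that("GLR matching is valid, bounded by maximum, tight off-core", {
  set.seed(404)
  for (i in 1:25) {
    g <- random_digraph(sample(3:25, 1), p = runif(1, 0.05, 0.4))
    H <- build_bipartite(g)
    res <- glr(H)
    hk <- hopcroft_karp(H)$size
    expect_lte(res$matching$size, hk)
    ml <- res$matching$match_left
    matched <- which(!is.na(ml))
    expect_true(all(paste(matched, ml[matched]) %in% paste(g$from, g$to)))
    if (length(res$core$left) + length(res$core$right) == 0) {
      expect_equal(res$matching$size, hk)
    }
  }
})

test_that("empirical_distribution counts degrees exactly", {
  d <- empirical_distribution(star_graph())
  expect_equal(d$p_out, c(2 / 3, 0, 1 / 3))   # P(k+): {0: 2/3, 2: 1/3}
  expect_equal(d$p_in, c(1 / 3, 2 / 3))       # P(k-): {0: 1/3, 1: 2/3}
  expect_equal(d$mean_k, 2 / 3)

  dc <- empirical_distribution(cycle_graph(6))
  expect_equal(dc$p_in, c(0, 1))
  expect_equal(dc$p_out, c(0, 1))
  expect_error(empirical_distribution(directed_graph()), "empty")
})

test_that("degree_distribution validates mass and mean consistency", {
  expect_error(degree_distribution(c(0.5, 0.4), c(0.5, 0.5)), "sum to 1")
  expect_error(degree_distribution(c(0.5, 0.5), c(0.9, 0.1)), "differ")
  d <- degree_distribution(c(0.5, 0.5), c(0.5, 0.5))
  expect_equal(d$mean_k, 0.5)
})

test_that("fixed point: symmetry, convergence metadata, isolated limit", {
  d <- poisson_distribution(3)
  fp <- solve_fixed_point(d)
  expect_equal(fp$alpha_plus, fp$alpha_minus)
  expect_equal(fp$beta_plus, fp$beta_minus)
  expect_lt(fp$residual, 1e-12)
  expect_true(all(unlist(fp[1:4]) >= 0 & unlist(fp[1:4]) <= 1))

  # near-isolated limit: predicted n_D -> 1
  eps <- poisson_distribution(1e-6)
  pred <- predict_roles(eps)
  expect_gt(pred$n_D, 0.9999)
  expect_gt(pred$n_DS, 0.9999)

  expect_error(solve_fixed_point(d, tol = -1), "positive")
})

test_that("asymmetric distributions give asymmetric fixed points, and the
           reversal symmetry holds", {
  # in-degrees concentrated, out-degrees dispersed
  p_in <- c(0.2, 0.3, 0.5)                       # mean 1.3
  p_out <- c(0.45, 0.1, 0.15, 0.3); p_out <- p_out / sum(p_out)
  m_out <- sum((seq_along(p_out) - 1) * p_out)   # 1.3
  expect_equal(m_out, 1.3)
  d <- degree_distribution(p_in, p_out)
  fp <- solve_fixed_point(d)
  d_rev <- degree_distribution(p_out, p_in)
  fp_rev <- solve_fixed_point(d_rev)
  expect_equal(fp$alpha_plus, fp_rev$alpha_minus)
  expect_equal(fp$beta_plus, fp_rev$beta_minus)
  # n_D invariant under reversal
  expect_equal(predict_nD(core_and_root_fractions(d, fp)),
               predict_nD(core_and_root_fractions(d_rev, fp_rev)))
})

test_that("core/root fractions: degenerate and subcritical cases", {
  d0 <- degree_distribution(1, 1)       # all mass at k = 0
  fp0 <- solve_fixed_point(d0)
  pred0 <- core_and_root_fractions(d0, fp0)
  expect_equal(pred0$nc_plus, 0)
  expect_equal(pred0$nc_minus, 0)
  expect_equal(pred0$n_r, 0)
  expect_equal(predict_nD(pred0), 1)

  # below core percolation the predicted core vanishes and GLR agrees
  d <- poisson_distribution(1)
  pred <- core_and_root_fractions(d, solve_fixed_point(d))
  expect_lt(max(pred$nc_plus, pred$nc_minus), 1e-6)
  g <- generate_er(5000, 5000, seed = 3)
  res <- glr(build_bipartite(g))
  expect_lt(res$nc_plus, 0.01)
  expect_equal(res$matching$size, hopcroft_karp(build_bipartite(g))$size,
               tolerance = 0.002)
})

test_that("predict_nDS evaluates the leaf/isolate estimate literally", {
  expect_equal(predict_nDS(degree_distribution(1, 1)), 1)
  d <- poisson_distribution(1)
  expect_equal(predict_nDS(d), 3 * exp(-2), tolerance = 1e-9)
  # Poisson identity: the leaf/isolate estimate equals e^{-2k}(2k+1) for all k
  for (mk in c(0.5, 1, 2, 4, 8)) {
    expect_equal(predict_nDS(poisson_distribution(mk)),
                 exp(-2 * mk) * (2 * mk + 1), tolerance = 1e-10)
  }
})

test_that("er_closed_forms match the accounting identity", {
  for (mk in c(0.5, 1, 2, 4, 8)) {
    d <- poisson_distribution(mk)
    fp <- solve_fixed_point(d)
    cf <- er_closed_forms(mk, fp)
    expect_equal(cf$n_DS, exp(-2 * mk) * (2 * mk + 1))
    pred <- predict_roles(d)
    # the closed-form n_O equals n_DS - 2 n_D + 1 with the fixed-point n_D
    expect_equal(cf$n_O, cf$n_DS - 2 * pred$n_D + 1, tolerance = 1e-9)
  }
  expect_equal(er_closed_forms(0, structure(
    list(alpha_plus = 0, alpha_minus = 0, beta_plus = 1, beta_minus = 1),
    class = "fixed_point"))$n_DS, 1)
})

test_that("sf_distribution is a proper distribution with the right moments", {
  for (gm in c(2.5, 3, 4)) {
    d <- sf_distribution(4, gm)
    expect_equal(sum(d$p_in), 1, tolerance = 1e-9)
    expect_equal(d$mean_k, 4, tolerance = 0.04)   # within 1%
    # large-k ratio ~ (k/(k+1))^gamma
    k <- 500
    ratio <- d$p_in[k + 2] / d$p_in[k + 1]
    expect_equal(log(ratio) / log(k / (k + 1)), gm, tolerance = 0.05)
  }
  expect_error(sf_distribution(4, 1.8), "exceed 2")
})

test_that("gamma_inc_upper agrees with numerical integration on a grid", {
  for (s in c(-2.5, -2, -1, -0.5, -1e-3, 0.5, 1, 2.3, 5)) {
    for (x in c(0.1, 0.7, 1, 1.5, 3, 10)) {
      ref <- integrate(function(t) t^(s - 1) * exp(-t), x, Inf,
                       rel.tol = 1e-12)$value
      expect_equal(gamma_inc_upper(s, x), ref,
                   tolerance = 1e-8, label = paste("s =", s, "x =", x))
    }
  }
  expect_error(gamma_inc_upper(1, -2), "positive")
})

test_that("SF closed form equals the generic DS estimate to 1e-10 on a grid", {
  for (gm in c(2.5, 3, 4)) {
    for (mk in c(0.5, 1, 2, 4, 8)) {
      d <- sf_distribution(mk, gm)
      cf <- sf_closed_forms(mk, gm, solve_fixed_point(d))
      expect_equal(cf$n_DS, predict_nDS(d), tolerance = 1e-10,
                   label = paste("gamma =", gm, "mk =", mk))
    }
  }
})

test_that("sf closed-form n_O is consistent with the accounting identity", {
  # the SF ordinary closed form encodes n_O = n_DS - 2 n_D + 1 with
  # n_D = <k>a(1-b)(C1+C2+1) - 1; cross-check against the fixed-point route
  # (they agree closely away from the truncation-limited heavy-tail corner)
  for (mk in c(2, 4)) {
    d <- sf_distribution(mk, 3)
    fp <- solve_fixed_point(d)
    cf <- sf_closed_forms(mk, 3, fp)
    pred <- predict_roles(d)
    implied_nD <- (cf$n_DS - cf$n_O + 1) / 2
    expect_equal(implied_nD, pred$n_D, tolerance = 0.005)
  }
})

test_that("prediction from an empirical distribution matches simulation", {
  g <- generate_er(1e4, 2e4, seed = 29)
  g_r <- rewire_degree_preserving(g, seed = 30)
  pred <- predict_roles(empirical_distribution(g_r))
  sim <- sim_fractions(g_r)
  expect_lt(abs(pred$n_D - sim$n_D), 0.02)
})
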