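#' Solve the leaf/root fixed-point equations
#'
#' For a random digraph with degree distributions \eqn{P(k^-)},
#' \eqn{P(k^+)}, let \eqn{\alpha^\pm} and \eqn{\beta^\pm} be the
#' probabilities that, following an edge, the endpoint copy becomes a leaf
#' or a root during greedy leaf removal.  With the excess-degree
#' distribution \eqn{Q(k^\pm) = k^\pm P(k^\pm)/\langle k\rangle}, the
#' self-consistent equations are
#' \deqn{\alpha^\pm = \sum_{k \ge 1} Q(k^\pm)\,(\beta^\mp)^{k-1}, \qquad
#'       \beta^\pm = 1 - \sum_{k \ge 1} Q(k^\pm)\,(1-\alpha^\mp)^{k-1}.}
#' Solved by plain alternating iteration (first the \eqn{\alpha} map, then
#' the \eqn{\beta} map using the fresh \eqn{\alpha}) from
#' \eqn{\alpha^\pm = \beta^\pm = 0}, values clamped to \eqn{[0,1]}.
#'
#' @param dist a [degree_distribution()].
#' @param tol convergence tolerance on the max coordinate update
#'   (default `1e-12`).
#' @param max_iter iteration cap (default `1e5`).
#' @return object of class `fixed_point`: list with `alpha_plus`,
#'   `alpha_minus`, `beta_plus`, `beta_minus`, `iterations`, `residual`.
#' @export
solve_fixed_point <- function(dist, tol = 1e-12, max_iter = 1e5) {
  stopifnot(inherits(dist, "degree_distribution"))
  if (tol <= 0) stop("`tol` must be positive")
  if (dist$mean_k == 0) {
    # edgeless limit: every copy is trivially a "root" of nothing;
    # the sums over k >= 1 are empty, so alpha = 0, beta = 1 exactly
    return(structure(list(alpha_plus = 0, alpha_minus = 0,
                          beta_plus = 1, beta_minus = 1,
                          iterations = 0L, residual = 0),
                     class = "fixed_point"))
  }
  kin <- seq_along(dist$p_in) - 1
  kout <- seq_along(dist$p_out) - 1
  q_in <- kin * dist$p_in / dist$mean_k      # Q(k-) on k >= 1 (k=0 term is 0)
  q_out <- kout * dist$p_out / dist$mean_k

  # sum_{k>=1} Q(k) z^{k-1}
  qgen <- function(q, k, z) sum(q[k >= 1] * z^(k[k >= 1] - 1))

  ap <- am <- bp <- bm <- 0
  clamp <- function(v) min(max(v, 0), 1)
  for (it in seq_len(max_iter)) {
    ap2 <- clamp(qgen(q_out, kout, bm))
    am2 <- clamp(qgen(q_in, kin, bp))
    bp2 <- clamp(1 - qgen(q_out, kout, 1 - am2))
    bm2 <- clamp(1 - qgen(q_in, kin, 1 - ap2))
    resid <- max(abs(c(ap2 - ap, am2 - am, bp2 - bp, bm2 - bm)))
    ap <- ap2; am <- am2; bp <- bp2; bm <- bm2
    if (resid < tol) {
      return(structure(list(alpha_plus = ap, alpha_minus = am,
                            beta_plus = bp, beta_minus = bm,
                            iterations = it, residual = resid),
                       class = "fixed_point"))
    }
  }
  stop("fixed point did not converge in ", max_iter,
       " iterations (residual ", signif(resid, 3),
       "; last iterate alpha+ = ", signif(ap, 6), ", beta+ = ",
       signif(bp, 6), ")")
}

#' Core and root fractions from the fixed point
#'
#' Evaluates the core fractions of the left (\eqn{n_c^+}) and right
#' (\eqn{n_c^-}) copies and the total root fraction \eqn{n_r}:
#' \deqn{n_c^+ = \sum_k P(k^+)[(1-\alpha^-)^k - (\beta^-)^k]
#'       - \langle k\rangle \alpha^+ (1 - \alpha^- - \beta^-),}
#' symmetrically for \eqn{n_c^-}, and
#' \deqn{n_r = [1 - \sum_k P(k^+)(1-\alpha^-)^k]
#'       + [1 - \sum_k P(k^-)(1-\alpha^+)^k]
#'       - \langle k\rangle \alpha^+ \alpha^-.}
#' Series are truncated at the distribution's `k_max`; results are clamped
#' to \eqn{[0,1]}.
#'
#' @param dist a [degree_distribution()].
#' @param fp a converged [solve_fixed_point()] result.
#' @return object of class `analytic_prediction`: list with `nc_plus`,
#'   `nc_minus`, `n_r`, plus `n_D`, `n_S`, `n_DS`, `n_O` filled in by
#'   [predict_roles()] (here `NA`).
#' @export
core_and_root_fractions <- function(dist, fp) {
  stopifnot(inherits(dist, "degree_distribution"),
            inherits(fp, "fixed_point"))
  kin <- seq_along(dist$p_in) - 1
  kout <- seq_along(dist$p_out) - 1
  pgen <- function(p, k, z) sum(p * z^k)     # sum_k P(k) z^k (0^0 = 1)
  clamp01 <- function(v) min(max(v, 0), 1)

  nc_plus <- sum(dist$p_out * ((1 - fp$alpha_minus)^kout -
                                 fp$beta_minus^kout)) -
    dist$mean_k * fp$alpha_plus * (1 - fp$alpha_minus - fp$beta_minus)
  nc_minus <- sum(dist$p_in * ((1 - fp$alpha_plus)^kin -
                                 fp$beta_plus^kin)) -
    dist$mean_k * fp$alpha_minus * (1 - fp$alpha_plus - fp$beta_plus)
  n_r <- (1 - pgen(dist$p_out, kout, 1 - fp$alpha_minus)) +
    (1 - pgen(dist$p_in, kin, 1 - fp$alpha_plus)) -
    dist$mean_k * fp$alpha_plus * fp$alpha_minus

  structure(list(nc_plus = clamp01(nc_plus), nc_minus = clamp01(nc_minus),
                 n_r = clamp01(n_r), n_D = NA_real_, n_S = NA_real_,
                 n_DS = NA_real_, n_O = NA_real_),
            class = "analytic_prediction")
}

#' Driver fraction from core and root fractions
#'
#' The roots account for \eqn{n_r N} matching edges and the core for
#' \eqn{\min\{n_c^+, n_c^-\} N} more, so
#' \deqn{n_D = n_S = 1 - (n_r + \min\{n_c^+, n_c^-\}),}
#' clamped to \eqn{[0,1]}.
#'
#' @param pred an [core_and_root_fractions()] result.
#' @return the predicted driver (= sensor) fraction.
#' @export
predict_nD <- function(pred) {
  stopifnot(inherits(pred, "analytic_prediction"))
  min(max(1 - (pred$n_r + min(pred$nc_plus, pred$nc_minus)), 0), 1)
}

#' Dual-identity fraction from the degree distribution
#'
#' Heuristic estimate built from isolated nodes and in-/out-leaves (nodes of
#' degree pattern (1,0) or (0,1)), which dominate the unmatched-on-both-sides
#' set:
#' \deqn{n_{DS} = P(0^-)P(0^+) + P(0^-)P(1^+) + P(1^-)P(0^+).}
#' Multiplying by \eqn{N} gives the predicted DS node count.
#'
#' @param dist a [degree_distribution()].
#' @return the estimated DS fraction.
#' @export
predict_nDS <- function(dist) {
  stopifnot(inherits(dist, "degree_distribution"))
  p0i <- dist$p_in[1]
  p1i <- if (length(dist$p_in) > 1) dist$p_in[2] else 0
  p0o <- dist$p_out[1]
  p1o <- if (length(dist$p_out) > 1) dist$p_out[2] else 0
  p0i * p0o + p0i * p1o + p1i * p0o
}

#' Full analytic prediction from a degree distribution
#'
#' Chains [solve_fixed_point()], [core_and_root_fractions()],
#' [predict_nD()] and [predict_nDS()]; the ordinary fraction comes from the
#' accounting identity \eqn{n_O = 1 - 2 n_D + n_{DS}} (clamped to
#' \eqn{[0,1]}).
#'
#' @param dist a [degree_distribution()].
#' @param tol,max_iter passed to [solve_fixed_point()].
#' @return an `analytic_prediction` with all fields populated, plus the
#'   `fixed_point` attached as attribute `"fixed_point"`.
#' @export
predict_roles <- function(dist, tol = 1e-12, max_iter = 1e5) {
  fp <- solve_fixed_point(dist, tol = tol, max_iter = max_iter)
  pred <- core_and_root_fractions(dist, fp)
  pred$n_D <- pred$n_S <- predict_nD(pred)
  pred$n_DS <- predict_nDS(dist)
  pred$n_O <- min(max(1 - 2 * pred$n_D + pred$n_DS, 0), 1)
  attr(pred, "fixed_point") <- fp
  pred
}

#' @export
print.analytic_prediction <- function(x, ...) {
  cat(sprintf("analytic: n_D = n_S = %.4f  n_DS = %.4f  n_O = %.4f\n",
              x$n_D, x$n_DS, x$n_O))
  cat(sprintf("  nc+ = %.4f  nc- = %.4f  n_r = %.4f\n",
              x$nc_plus, x$nc_minus, x$n_r))
  invisible(x)
}

#' Closed forms for Erdos-Renyi networks
#'
#' Under the Poisson degree law the DS and ordinary fractions reduce to
#' \deqn{n_{DS}^{ER} = e^{-2\langle k\rangle}(2\langle k\rangle + 1), \qquad
#'       n_O^{ER} = n_{DS}^{ER}
#'         - 2[\alpha - \beta + \langle k\rangle \alpha(1-\beta)] + 1,}
#' where \eqn{\alpha = \alpha^\pm}, \eqn{\beta = \beta^\pm} is the symmetric
#' fixed point (in- and out-distributions coincide, so the fixed point must
#' be symmetric; an asymmetric one is rejected).  The bracket
#' \eqn{\alpha - \beta + \langle k\rangle\alpha(1-\beta)} coincides with the
#' driver fraction of [predict_nD()] under the Poisson law, so this is the
#' accounting identity \eqn{n_O = n_{DS} - 2 n_D + 1} in closed form.
#'
#' @param mean_k mean degree.
#' @param fp a [solve_fixed_point()] result computed under
#'   [poisson_distribution()] at the same `mean_k`.
#' @param sym_tol tolerance on \eqn{|\alpha^+ - \alpha^-|} (default `1e-8`).
#' @return list with `n_DS` and `n_O`.
#' @export
er_closed_forms <- function(mean_k, fp, sym_tol = 1e-8) {
  stopifnot(inherits(fp, "fixed_point"))
  if (abs(fp$alpha_plus - fp$alpha_minus) > sym_tol ||
      abs(fp$beta_plus - fp$beta_minus) > sym_tol) {
    stop("fixed point is not symmetric; was it solved under a Poisson ",
         "distribution?")
  }
  alpha <- fp$alpha_plus
  beta <- fp$beta_plus
  n_DS <- exp(-2 * mean_k) * (2 * mean_k + 1)
  n_O <- n_DS - 2 * (alpha - beta + mean_k * alpha * (1 - beta)) + 1
  list(n_DS = n_DS, n_O = n_O)
}

#' Closed forms for static-model scale-free networks
#'
#' With \eqn{a = 1/(\gamma-1)}, \eqn{x = \langle k\rangle(1-a)},
#' \eqn{\delta = x^{1/a}/a} (see [sf_distribution()]) and
#' \eqn{\Gamma_k = \Gamma(k - 1/a, x)/\Gamma(k+1)}:
#' \deqn{n_{DS}^{SF} = \delta^2\Gamma_0^2 + 2\delta^2\Gamma_0\Gamma_1,}
#' \deqn{n_O^{SF} = n_{DS}^{SF}
#'   - 2\langle k\rangle\alpha(1-\beta)(C_1 + C_2 + 1) + 3,}
#' with \eqn{C_1 = \Gamma(-1/a, x\alpha)/\Gamma(1-1/a, x\alpha)} and
#' \eqn{C_2} the same ratio at argument \eqn{x(1-\beta)}.  Requires the
#' upper incomplete gamma at negative first argument
#' ([gamma_inc_upper()]).
#'
#' @param mean_k mean degree.
#' @param gamma_exp power-law exponent \eqn{\gamma > 2}.
#' @param fp a [solve_fixed_point()] result computed under
#'   [sf_distribution()] at the same parameters.
#' @param sym_tol tolerance on fixed-point symmetry (default `1e-8`).
#' @return list with `n_DS` and `n_O`.
#' @export
sf_closed_forms <- function(mean_k, gamma_exp, fp, sym_tol = 1e-8) {
  stopifnot(inherits(fp, "fixed_point"))
  if (gamma_exp <= 2) stop("`gamma_exp` must exceed 2")
  if (abs(fp$alpha_plus - fp$alpha_minus) > sym_tol ||
      abs(fp$beta_plus - fp$beta_minus) > sym_tol) {
    stop("fixed point is not symmetric; was it solved under the ",
         "scale-free distribution?")
  }
  a <- 1 / (gamma_exp - 1)
  x <- mean_k * (1 - a)
  delta <- x^(1 / a) / a
  g0 <- gamma_inc_upper(-1 / a, x)            # Gamma_0 (Gamma(1) = 1)
  g1 <- gamma_inc_upper(1 - 1 / a, x)         # Gamma_1
  n_DS <- delta^2 * g0^2 + 2 * delta^2 * g0 * g1

  alpha <- fp$alpha_plus
  beta <- fp$beta_plus
  c_ratio <- function(z) {
    if (z <= 0) return(0)  # alpha or 1-beta vanished: term drops out
    gamma_inc_upper(-1 / a, z) / gamma_inc_upper(1 - 1 / a, z)
  }
  c1 <- c_ratio(x * alpha)
  c2 <- c_ratio(x * (1 - beta))
  n_O <- n_DS - 2 * mean_k * alpha * (1 - beta) * (c1 + c2 + 1) + 3
  list(n_DS = n_DS, n_O = n_O)
}
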