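#' Paired in/out degree distribution
#'
#' Container for the mass functions \eqn{P(k^-)} (in-degree) and
#' \eqn{P(k^+)} (out-degree) on \eqn{k = 0, 1, \dots, k_{max}}, together
#' with the mean degree \eqn{\langle k \rangle = M/N}.  In a directed graph
#' every edge contributes one in- and one out-degree, so both sides share
#' the same mean.
#'
#' @param p_in,p_out numeric vectors of probabilities for
#'   \eqn{k = 0, 1, \dots} (index 1 is \eqn{k = 0}).  Each must sum to 1
#'   within `1e-9` and their means must agree within `1e-6`.
#' @return object of class `degree_distribution`: list with `p_in`, `p_out`,
#'   `mean_k`.
#' @export
degree_distribution <- function(p_in, p_out) {
  p_in <- as.numeric(p_in)
  p_out <- as.numeric(p_out)
  if (any(p_in < 0) || any(p_out < 0)) stop("negative probability mass")
  if (abs(sum(p_in) - 1) > 1e-9 || abs(sum(p_out) - 1) > 1e-9) {
    stop("mass functions must sum to 1 (within 1e-9)")
  }
  mean_in <- sum((seq_along(p_in) - 1) * p_in)
  mean_out <- sum((seq_along(p_out) - 1) * p_out)
  if (abs(mean_in - mean_out) > 1e-6) {
    stop("in- and out-degree means differ (", mean_in, " vs ", mean_out, ")")
  }
  structure(list(p_in = p_in, p_out = p_out,
                 mean_k = (mean_in + mean_out) / 2),
            class = "degree_distribution")
}

#' @export
print.degree_distribution <- function(x, ...) {
  cat("degree_distribution: <k> =", format(x$mean_k),
      " k_max(in) =", length(x$p_in) - 1,
      " k_max(out) =", length(x$p_out) - 1, "\n")
  invisible(x)
}

#' Empirical degree distribution of a graph
#'
#' Exact in-/out-degree histograms normalized by N.
#'
#' @param graph a non-empty [directed_graph()].
#' @return a [degree_distribution()] with `mean_k = M/N`.
#' @export
empirical_distribution <- function(graph) {
  stopifnot(inherits(graph, "directed_graph"))
  if (graph$N < 1) stop("degree distribution undefined for an empty graph")
  k_in <- tabulate(graph$to, nbins = graph$N)
  k_out <- tabulate(graph$from, nbins = graph$N)
  hist_of <- function(k) tabulate(k + 1, nbins = max(k) + 1) / graph$N
  degree_distribution(hist_of(k_in), hist_of(k_out))
}

#' Truncated Poisson degree distribution
#'
#' The in- and out-degrees of an Erdos-Renyi digraph with mean degree
#' \eqn{\langle k \rangle = M/N} are asymptotically Poisson:
#' \eqn{P(k) = e^{-\langle k\rangle} \langle k\rangle^k / k!}, identical on
#' both sides.  Truncated where the tail mass drops below `tail_tol` and
#' renormalized.
#'
#' @param mean_k mean degree, > 0.
#' @param tail_tol tail mass cutoff (default `1e-12`).
#' @param k_cap hard truncation cap (default `1e4`).
#' @return a [degree_distribution()].
#' @export
poisson_distribution <- function(mean_k, tail_tol = 1e-12, k_cap = 1e4) {
  if (mean_k <= 0) stop("`mean_k` must be positive")
  k_max <- min(which(stats::ppois(0:k_cap, mean_k, lower.tail = FALSE)
                     < tail_tol)[1] - 1, k_cap)
  if (is.na(k_max)) k_max <- k_cap
  p <- stats::dpois(0:k_max, mean_k)
  p <- p / sum(p)
  degree_distribution(p, p)
}

#' Static-model scale-free degree distribution
#'
#' Degree law of the static model with weight exponent
#' \eqn{a = 1/(\gamma - 1)}:
#' \deqn{P(k) = \frac{[\langle k\rangle(1-a)]^{1/a}}{a} \;
#'       \frac{\Gamma(k - 1/a,\; \langle k\rangle(1-a))}{\Gamma(k+1)},}
#' identical for in- and out-degrees, with a \eqn{k^{-\gamma}} tail.  (With
#' \eqn{c = \langle k\rangle(1-a)}, \eqn{\sum_k \Gamma(k-1/a, c)/k! =
#' a\,c^{-1/a}}, so the prefactor \eqn{\delta = c^{1/a}/a} normalizes the
#' law exactly and gives mean \eqn{c/(1-a) = \langle k\rangle}.)
#' \eqn{\Gamma(s, x)} is the upper incomplete gamma function, which here
#' needs negative first arguments (see [gamma_inc_upper()]).  The mass
#' function is truncated where the tail mass falls below `tail_tol` (cap
#' `k_cap`); the residual tail mass is folded into the last bin so low-k
#' masses — which drive the dual-identity estimate — stay exact.
#'
#' @param mean_k mean degree, > 0.
#' @param gamma_exp power-law exponent \eqn{\gamma > 2} (so that
#'   \eqn{a \in (0,1)}).
#' @param k_cap hard truncation cap (default `1e4`).
#' @param tail_tol tail mass cutoff (default `1e-12`).
#' @return a [degree_distribution()].
#' @export
sf_distribution <- function(mean_k, gamma_exp, k_cap = 1e4,
                            tail_tol = 1e-12) {
  if (gamma_exp <= 2) stop("`gamma_exp` must exceed 2 (so a = 1/(gamma-1) < 1)")
  if (mean_k <= 0) stop("`mean_k` must be positive")
  a <- 1 / (gamma_exp - 1)
  x <- mean_k * (1 - a)
  delta <- x^(1 / a) / a

  # ratios r_k = Gamma(k - 1/a, x) / Gamma(k + 1) by upward recurrence:
  #   Gamma(s + 1, x) = s * Gamma(s, x) + x^s * exp(-x)
  # so r_{k+1} = ((k - 1/a) * r_k + t_k) / (k + 1),
  # with t_k = x^(k - 1/a) e^{-x} / k!  computed in log space.
  k_cap <- as.integer(k_cap)
  r <- numeric(k_cap + 1)
  r[1] <- gamma_inc_upper(-1 / a, x)            # k = 0
  for (k in 0:(k_cap - 1)) {
    t_k <- exp((k - 1 / a) * log(x) - x - lgamma(k + 1))
    r[k + 2] <- ((k - 1 / a) * r[k + 1] + t_k) / (k + 1)
  }
  p <- delta * r
  p[p < 0] <- 0                                  # guard tiny negative drift
  cum <- cumsum(p)
  k_max <- which(cum > 1 - tail_tol)[1]
  if (is.na(k_max)) k_max <- k_cap + 1
  p <- p[seq_len(k_max)]
  # fold the (heavy) residual tail into the last bin: keeps P(0), P(1)
  # exactly parametric and pulls the truncated mean back toward <k>
  p[k_max] <- p[k_max] + max(1 - sum(p), 0)
  p <- p / sum(p)
  degree_distribution(p, p)
}

#' Upper incomplete gamma function, any real first argument
#'
#' \eqn{\Gamma(s, x) = \int_x^\infty t^{s-1} e^{-t}\,dt} for \eqn{x > 0} and
#' any real \eqn{s}, including \eqn{s \le 0} where standard routines give
#' up.  For \eqn{s > 0} it is `pgamma`'s regularized survival function times
#' \eqn{\Gamma(s)}; for \eqn{s \le 0} the downward recurrence
#' \eqn{\Gamma(s, x) = (\Gamma(s+1, x) - x^s e^{-x}) / s} is applied from a
#' positive starting point, with \eqn{\Gamma(0, x) = E_1(x)} handled by the
#' exponential integral when the recurrence passes through zero.
#'
#' @param s real first argument (scalar).
#' @param x positive second argument (scalar).
#' @return \eqn{\Gamma(s, x)}.
#' @export
gamma_inc_upper <- function(s, x) {
  stopifnot(length(s) == 1, length(x) == 1)
  if (x <= 0) stop("`x` must be positive (x = ", x, ")")
  if (s > 0) {
    return(gamma(s) * stats::pgamma(x, s, lower.tail = FALSE))
  }
  m <- ceiling(-s) + 1          # s + m > 0
  s_top <- s + m
  val <- gamma(s_top) * stats::pgamma(x, s_top, lower.tail = FALSE)
  for (j in (m - 1):0) {        # step down exactly: t = s + j
    t <- s + j
    if (t == 0) {
      val <- exp_integral_e1(x) # recurrence would divide by zero
    } else {
      val <- (val - x^t * exp(-x)) / t
    }
  }
  if (!is.finite(val)) {
    stop("incomplete gamma evaluation failed at s = ", s, ", x = ", x)
  }
  val
}

#' Exponential integral E1
#'
#' \eqn{E_1(x) = \int_x^\infty e^{-t}/t \, dt = \Gamma(0, x)} for
#' \eqn{x > 0}.  Power series for \eqn{x \le 1}, modified Lentz continued
#' fraction for \eqn{x > 1} (standard split; both converge fast in their
#' range).
#'
#' @param x positive scalar.
#' @return \eqn{E_1(x)}.
#' @keywords internal
exp_integral_e1 <- function(x) {
  stopifnot(length(x) == 1, x > 0)
  if (x <= 1) {
    euler_gamma <- 0.57721566490153286060651209008240243
    s <- 0
    term <- 1
    for (n in 1:60) {
      term <- term * (-x) / n
      s <- s + term / n
      if (abs(term / n) < 1e-18) break
    }
    -euler_gamma - log(x) - s
  } else {
    # continued fraction: E1(x) = e^{-x} / (x + 1/(1 + 1/(x + 2/(1 + ...))))
    tiny <- 1e-300
    b <- x + 1
    c <- 1 / tiny
    d <- 1 / b
    h <- d
    for (i in 1:200) {
      an <- -i * i
      b <- b + 2
      d <- 1 / (an * d + b)
      c <- b + an / c
      del <- c * d
      h <- h * del
      if (abs(del - 1) < 1e-15) break
    }
    h * exp(-x)
  }
}
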