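#' Directed Erdos-Renyi network with exactly M edges
#'
#' Starts from `n` isolated nodes and adds directed edges between uniformly
#' chosen *distinct* node pairs until exactly `m` distinct edges exist
#' (the G(N, M) ensemble on simple digraphs, no self-loops).  Implemented by
#' sampling `m` of the `n(n-1)` ordered pairs without replacement, which is
#' distribution-identical to sequential insertion with rejection.
#'
#' @param n node count.
#' @param m edge count; must satisfy `m <= n * (n - 1)`.
#' @param seed optional integer seed (`set.seed` is called when non-NULL).
#' @return a [directed_graph()] with nodes labelled `"v1" ... "vn"`.
#' @export
generate_er <- function(n, m, seed = NULL) {
  check_capacity(n, m)
  if (!is.null(seed)) set.seed(seed)
  idx <- sample(n * (n - 1), m) - 1          # 0-based ordered-pair codes
  i <- idx %/% (n - 1)                       # 0-based source
  off <- idx %% (n - 1)
  j <- off + (off >= i)                      # skip the diagonal
  labels <- paste0("v", seq_len(n))
  directed_graph(cbind(labels[i + 1], labels[j + 1]), nodes = labels)
}

#' Directed static-model scale-free network
#'
#' Nodes carry rank weights \eqn{p_i = i^{-a_{out}}} (source) and
#' \eqn{q_j = j^{-a_{in}}} (target).  Each step draws a source with
#' probability \eqn{p_i / \sum_k p_k} and a target with
#' \eqn{q_j / \sum_k q_k}; the edge is kept unless it is a self-loop or
#' already present, and drawing repeats until exactly `m` distinct edges
#' exist.  The resulting in-/out-degree tails are power laws with exponent
#' \eqn{\gamma = 1 + 1/a}.
#'
#' @param n node count.
#' @param m edge count; must satisfy `m <= n * (n - 1)`.
#' @param a_in,a_out weight exponents in (0, 1); `a = 0.5` gives
#'   \eqn{\gamma = 3}.
#' @param seed optional integer seed.
#' @param max_draws total draw budget before a convergence error (default
#'   `100 * m`); dense, strongly skewed parameter sets can stall on
#'   rejections.
#' @return a [directed_graph()] with nodes labelled `"v1" ... "vn"`.
#' @export
generate_sf <- function(n, m, a_in = 0.5, a_out = 0.5, seed = NULL,
                        max_draws = 100 * m) {
  check_capacity(n, m)
  if (a_in <= 0 || a_in >= 1 || a_out <= 0 || a_out >= 1) {
    stop("`a_in` and `a_out` must lie in (0, 1)")
  }
  if (!is.null(seed)) set.seed(seed)
  p <- seq_len(n)^(-a_out)
  q <- seq_len(n)^(-a_in)
  have <- integer(0)                 # edge codes (i-1)*n + j, 1-based nodes
  drawn <- 0
  while (length(have) < m) {
    want <- m - length(have)
    batch <- max(2 * want, 256)
    if (drawn + batch > max_draws) batch <- max_draws - drawn
    if (batch <= 0) {
      stop("generate_sf: failed to place ", m, " edges within ",
           max_draws, " draws (", length(have), " placed)")
    }
    src <- sample.int(n, batch, replace = TRUE, prob = p)
    dst <- sample.int(n, batch, replace = TRUE, prob = q)
    drawn <- drawn + batch
    keep <- src != dst
    code <- (src[keep] - 1) * n + dst[keep]
    code <- code[!duplicated(code)]
    code <- setdiff(code, have)
    # sequential semantics: accept in draw order up to the quota
    have <- c(have, code[seq_len(min(want, length(code)))])
  }
  i <- (have - 1) %/% n + 1
  j <- (have - 1) %% n + 1
  labels <- paste0("v", seq_len(n))
  directed_graph(cbind(labels[i], labels[j]), nodes = labels)
}

#' Degree-preserving randomization ("rand-degree" null model)
#'
#' Repeated double-edge swaps: pick edges \eqn{(a,b)} and \eqn{(c,d)},
#' replace with \eqn{(a,d)} and \eqn{(c,b)}.  Swaps that would create a
#' self-loop or a duplicate edge are rejected, so the graph stays simple and
#' every node keeps its exact in- and out-degree.  The result is a random
#' network from (approximately) the uniform ensemble with the original
#' degree sequence — the reference model that isolates the effect of the
#' degree distribution.
#'
#' @param graph a [directed_graph()].
#' @param swaps number of successful swaps to perform (default `10 * M`, a
#'   standard mixing heuristic).
#' @param seed optional integer seed.
#' @return a [directed_graph()] with identical node set and degree
#'   sequences.  Graphs with fewer than 2 edges (or no admissible swap) are
#'   returned (effectively) unchanged.
#' @export
rewire_degree_preserving <- function(graph, swaps = 10 * graph$M,
                                     seed = NULL) {
  stopifnot(inherits(graph, "directed_graph"))
  if (graph$M < 2 || swaps <= 0) return(graph)
  if (!is.null(seed)) set.seed(seed)
  res <- .rewire_swaps_cpp(graph$from, graph$to, graph$N,
                           as.double(swaps), as.double(100 * swaps))
  g2 <- graph
  g2$from <- res$from
  g2$to <- res$to
  attr(g2, "swaps_performed") <- res$performed
  g2
}

check_capacity <- function(n, m) {
  if (n < 0 || m < 0) stop("`n` and `m` must be non-negative")
  if (m > n * (n - 1)) {
    stop("m = ", m, " exceeds simple-digraph capacity n(n-1) = ", n * (n - 1))
  }
  invisible(TRUE)
}
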