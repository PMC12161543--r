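# shared fixtures, all built in code

# the 3-node worked example: x1 -> x2, x1 -> x3
star_graph <- function() {
  directed_graph(cbind(c("x1", "x1"), c("x2", "x3")))
}

# directed n-cycle x1 -> x2 -> ... -> xn -> x1 (perfect matching exists)
cycle_graph <- function(n) {
  lab <- paste0("x", seq_len(n))
  directed_graph(cbind(lab, lab[c(2:n, 1)]), nodes = lab)
}

# Bernoulli(p) digraph on n nodes, optionally with self-loops
random_digraph <- function(n, p = 0.3, self_loops = FALSE, labels = NULL) {
  A <- matrix(stats::runif(n * n) < p, n, n)
  if (!self_loops) diag(A) <- FALSE
  idx <- which(A, arr.ind = TRUE)
  if (is.null(labels)) labels <- paste0("n", seq_len(n))
  directed_graph(cbind(labels[idx[, 1]], labels[idx[, 2]]), nodes = labels)
}

# all digraphs on n nodes as edge masks (optionally including self-loops)
all_digraphs <- function(n, self_loops = FALSE) {
  pairs <- expand.grid(i = seq_len(n), j = seq_len(n))
  if (!self_loops) pairs <- pairs[pairs$i != pairs$j, ]
  np <- nrow(pairs)
  labels <- paste0("n", seq_len(n))
  lapply(0:(2^np - 1), function(mask) {
    sel <- bitwAnd(mask, 2^(seq_len(np) - 1)) > 0
    directed_graph(cbind(labels[pairs$i[sel]], labels[pairs$j[sel]]),
                   nodes = labels)
  })
}

reverse_graph <- function(g) {
  directed_graph(cbind(g$nodes[g$to], g$nodes[g$from]), nodes = g$nodes)
}

sim_fractions <- function(g) role_fractions(classify_nodes(g))
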