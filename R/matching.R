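#' Bipartite representation H(A) of a directed graph
#'
#' Every node \eqn{x_i} is split into a left copy \eqn{x_i^l} (a column of
#' the state matrix, carrying the node's out-edges) and a right copy
#' \eqn{x_i^r} (a row, carrying its in-edges).  Each directed edge
#' \eqn{x_j \to x_i} (i.e. \eqn{a_{ij} \neq 0}) becomes the undirected
#' bipartite edge \eqn{(x_j^l, x_i^r)}.  A self-loop \eqn{(u, u)} maps to
#' \eqn{(u^l, u^r)}.
#'
#' @param graph a [directed_graph()].
#' @return An object of class `bipartite_rep`: list with `n` (nodes per
#'   side), `left` (edge left endpoints, node indices), `right` (edge right
#'   endpoints), `labels` (node labels shared by both sides), and `adj`
#'   (adjacency list: for each left node, the right nodes it touches, in
#'   edge-input order).
#' @export
build_bipartite <- function(graph) {
  stopifnot(inherits(graph, "directed_graph"))
  adj <- unname(split(graph$to, factor(graph$from, levels = seq_len(graph$N))))
  adj <- lapply(adj, as.integer)
  structure(
    list(n = graph$N, left = graph$from, right = graph$to,
         labels = graph$nodes, adj = adj),
    class = "bipartite_rep"
  )
}

#' @export
print.bipartite_rep <- function(x, ...) {
  cat("bipartite_rep: ", x$n, " + ", x$n, " nodes, ",
      length(x$left), " edges\n", sep = "")
  invisible(x)
}

#' Maximum bipartite matching (Hopcroft-Karp)
#'
#' Standard Hopcroft-Karp: BFS builds a layered graph from the free left
#' nodes, DFS augments along shortest augmenting paths, repeated until no
#' augmenting path exists.  The returned matching is always maximum; *which*
#' maximum matching is returned depends on the order in which left nodes are
#' processed, so a caller-supplied `left_order` makes runs reproducible.
#'
#' @param H a [build_bipartite()] representation.
#' @param left_order permutation of `1:H$n`; defaults to first-appearance
#'   node order.
#' @return An object of class `bip_matching`: list with `match_left`
#'   (for each left node the matched right index, `NA` if unmatched),
#'   `match_right` (reverse map), `size`, and `edges` (two-column integer
#'   matrix of matched (left, right) pairs).
#' @export
hopcroft_karp <- function(H, left_order = seq_len(H$n)) {
  stopifnot(inherits(H, "bipartite_rep"))
  if (length(left_order) != H$n || anyDuplicated(left_order) ||
      (H$n > 0 && !setequal(left_order, seq_len(H$n)))) {
    stop("`left_order` must be a permutation of 1:", H$n)
  }
  if (H$n == 0) {
    return(new_matching(integer(0), integer(0)))
  }
  res <- .hopcroft_karp_cpp(H$n, H$n, H$adj, as.integer(left_order))
  ml <- res$match_left
  mr <- res$match_right
  ml[ml == 0L] <- NA_integer_
  mr[mr == 0L] <- NA_integer_
  new_matching(ml, mr)
}

#' Construct a matching from explicit (left, right) pairs
#'
#' Builds a `bip_matching` from node labels or indices, validating that the
#' pairs are edges of `H` and share no endpoints.  Useful for studying a
#' specific maximum matching (e.g. a hand-picked one) rather than the one
#' [hopcroft_karp()] happens to return.
#'
#' @param H a [build_bipartite()] representation.
#' @param left,right parallel vectors: matched left/right endpoints, as node
#'   labels (character) or node indices (numeric).
#' @return a `bip_matching` (not necessarily maximum).
#' @export
matching_from_pairs <- function(H, left, right) {
  stopifnot(inherits(H, "bipartite_rep"), length(left) == length(right))
  to_idx <- function(v) {
    if (is.character(v)) {
      i <- match(v, H$labels)
      if (anyNA(i)) stop("unknown node label: ", v[which(is.na(i))[1]])
      i
    } else as.integer(v)
  }
  l <- to_idx(left)
  r <- to_idx(right)
  if (anyDuplicated(l) || anyDuplicated(r)) {
    stop("matching edges share an endpoint")
  }
  if (length(l)) {
    ekey <- (H$left - 1) * H$n + H$right
    if (!all(((l - 1) * H$n + r) %in% ekey)) stop("pair is not an edge of H")
  }
  ml <- rep(NA_integer_, H$n)
  mr <- rep(NA_integer_, H$n)
  ml[l] <- r
  mr[r] <- l
  new_matching(ml, mr)
}

new_matching <- function(match_left, match_right) {
  ml <- which(!is.na(match_left))
  structure(
    list(match_left = match_left, match_right = match_right,
         size = length(ml),
         edges = cbind(left = ml, right = match_left[ml])),
    class = "bip_matching"
  )
}

#' @export
print.bip_matching <- function(x, ...) {
  cat("bip_matching: size", x$size, "of", length(x$match_left),
      "left nodes\n")
  invisible(x)
}

#' Exact maximum matching size by exhaustive search
#'
#' Test oracle, independent of [hopcroft_karp()]: a depth-first search over
#' left nodes that tries, for each left node in turn, every incident right
#' node and also the option of leaving the node unmatched, and keeps the
#' best count.  Exponential; refuses instances with more than `max_edges`
#' edges.
#'
#' @param H a [build_bipartite()] representation.
#' @param max_edges guard against exponential blow-up (default 20).
#' @return integer: the maximum matching size.
#' @export
brute_force_max_matching <- function(H, max_edges = 20) {
  stopifnot(inherits(H, "bipartite_rep"))
  m <- length(H$left)
  if (m > max_edges) {
    stop("instance too large for brute force (", m, " > ", max_edges,
         " edges)")
  }
  if (m == 0) return(0L)
  adj <- H$adj
  used <- logical(H$n)
  best <- 0L
  recurse <- function(u, count) {
    if (u > H$n) {
      if (count > best) best <<- count
      return(invisible(NULL))
    }
    # upper bound prune: even matching every remaining left node can't win
    if (count + (H$n - u + 1) <= best) return(invisible(NULL))
    for (v in adj[[u]]) {
      if (!used[v]) {
        used[v] <<- TRUE
        recurse(u + 1, count + 1L)
        used[v] <<- FALSE
      }
    }
    recurse(u + 1, count)
  }
  recurse(1L, 0L)
  best
}

#' Check that a matching is a valid maximum matching of H
#'
#' Validity: edges of the matching are edges of `H` and no two share an
#' endpoint.  Maximality: no augmenting path exists, checked by comparing
#' against a fresh Hopcroft-Karp run (matching sizes are unique even though
#' matched sets are not).
#'
#' @param H a [build_bipartite()] representation.
#' @param matching a `bip_matching`.
#' @return `TRUE`, or a character string describing the failure.
#' @keywords internal
check_maximum_matching <- function(H, matching) {
  ml <- matching$match_left
  if (length(ml) != H$n) return("matching does not cover H")
  idx <- which(!is.na(ml))
  if (anyDuplicated(ml[idx])) return("two matching edges share a right node")
  if (length(idx)) {
    ekey <- (H$left - 1) * H$n + H$right
    mkey <- (idx - 1) * H$n + ml[idx]
    if (!all(mkey %in% ekey)) return("matching uses a non-edge of H")
  }
  if (matching$size != hopcroft_karp(H)$size) {
    return("matching is not maximum (an augmenting path exists)")
  }
  TRUE
}
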