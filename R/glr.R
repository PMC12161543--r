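#' Greedy leaf removal (GLR) on a bipartite representation
#'
#' Iteratively removes a degree-one node (*leaf*) together with its sole
#' remaining neighbor (*root*) and adds the connecting edge to the matching,
#' until no degree-one node remains.  When several leaves are available they
#' are processed in node order (left copies before right copies); the root
#' and core *sizes* do not depend on this tie-break, only the particular
#' matched pairs do.  Nodes left isolated along the way are discarded; what
#' survives with degree >= 2 is the *core*, whose emergence is the core
#' percolation transition.  The accumulated matching is a valid (not
#' necessarily maximum) matching; it is maximum whenever the core is empty.
#'
#' @param H a [build_bipartite()] representation.
#' @return list with `matching` (a `bip_matching`), `roots` and `core`
#'   (each a list with integer node-index vectors `left` and `right`), and
#'   `n_r`, `nc_plus`, `nc_minus`: root fraction (roots on both sides over
#'   \eqn{2N}... see Details) and core fractions per side (divided by N).
#'
#' @details `n_r` is the number of roots on both sides divided by N (each
#'   root contributes one matching edge, and the analytic theory counts the
#'   root fraction over all 2N copies relative to N nodes); `nc_plus` /
#'   `nc_minus` are the left/right core sizes divided by N.
#' @export
glr <- function(H) {
  stopifnot(inherits(H, "bipartite_rep"))
  n <- H$n
  nn <- 2L * n                         # left copies 1..n, right n+1..2n
  # adjacency over the 2n bipartite nodes
  adj <- vector("list", nn)
  if (length(H$left)) {
    adj[seq_len(n)] <- unname(split(H$right + n,
                                    factor(H$left, levels = seq_len(n))))
    adj[n + seq_len(n)] <- unname(split(H$left,
                                        factor(H$right, levels = seq_len(n))))
  }
  deg <- lengths(adj)
  alive <- rep(TRUE, nn)
  is_root <- rep(FALSE, nn)
  ml <- rep(NA_integer_, n)            # matched right index per left node
  mr <- rep(NA_integer_, n)

  init <- which(deg == 1L)             # a node re-enters at most once more
  queue <- c(init, integer(2L * nn))
  qtail <- length(init)
  qi <- 1L
  while (qi <= qtail) {
    u <- queue[qi]; qi <- qi + 1L
    if (!alive[u] || deg[u] != 1L) next
    nbrs <- adj[[u]]
    v <- nbrs[alive[nbrs]][1]          # the sole surviving neighbor: root
    alive[u] <- FALSE
    alive[v] <- FALSE
    is_root[v] <- TRUE
    l <- if (u <= n) u else v
    r <- if (u <= n) v - n else u - n
    ml[l] <- r
    mr[r] <- l
    for (w in adj[[v]]) {
      if (alive[w]) {
        deg[w] <- deg[w] - 1L
        if (deg[w] == 1L) {
          qtail <- qtail + 1L
          queue[qtail] <- w
        }
      }
    }
    deg[u] <- 0L
    deg[v] <- 0L
  }

  core_ids <- which(alive & deg >= 2L)
  root_ids <- which(is_root)
  list(
    matching = new_matching(ml, mr),
    roots = list(left = root_ids[root_ids <= n],
                 right = root_ids[root_ids > n] - n),
    core = list(left = core_ids[core_ids <= n],
                right = core_ids[core_ids > n] - n),
    n_r = length(root_ids) / n,
    nc_plus = sum(core_ids <= n) / n,
    nc_minus = sum(core_ids > n) / n
  )
}
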