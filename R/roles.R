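#' Classify nodes as driver, sensor, dual-identity or ordinary
#'
#' Roles follow from a single maximum matching of the bipartite
#' representation: a node is a driver iff its right copy is unmatched (it
#' needs an independent external input), a sensor iff its left copy is
#' unmatched (it must feed an independent output), dual-identity (DS) iff
#' both, and ordinary iff neither.  The driver and sensor counts both equal
#' \eqn{N - |\mathcal{M}|} and so are matching-independent; the DS/ordinary
#' split can differ between maximum matchings.
#'
#' When a perfect matching exists the classification is literal: no node is
#' flagged (every node is ordinary).  The minimum-input theory still
#' requires one driver (any node will do) to control such a network;
#' `lemma1_convention = TRUE` promotes the first node in node order to
#' driver and, dually, to sensor, for users who want that accounting.
#'
#' @param graph a [directed_graph()].
#' @param matching optional `bip_matching`; computed via [hopcroft_karp()]
#'   with first-appearance left order when omitted.  A supplied matching is
#'   checked for validity and maximality.
#' @param lemma1_convention see above; default `FALSE`.
#' @return An object of class `role_assignment`: data frame with columns
#'   `node`, `is_driver`, `is_sensor`, `category` (one of
#'   `"driver"`, `"sensor"`, `"ds"`, `"ordinary"`; `driver`/`sensor` mean
#'   *exclusively* so).
#' @examples
#' star <- directed_graph(cbind(c("x1", "x1"), c("x2", "x3")))
#' classify_nodes(star)
#' @export
classify_nodes <- function(graph, matching = NULL, lemma1_convention = FALSE) {
  stopifnot(inherits(graph, "directed_graph"))
  H <- build_bipartite(graph)
  if (is.null(matching)) {
    matching <- hopcroft_karp(H)
  } else {
    ok <- check_maximum_matching(H, matching)
    if (!isTRUE(ok)) stop("invalid matching: ", ok)
  }
  is_driver <- is.na(matching$match_right)  # right copy unmatched
  is_sensor <- is.na(matching$match_left)   # left copy unmatched
  if (lemma1_convention && graph$N > 0 && !any(is_driver)) {
    is_driver[1] <- TRUE
    is_sensor[1] <- TRUE
  }
  category <- character(graph$N)
  category[!is_driver & !is_sensor] <- "ordinary"
  category[is_driver & !is_sensor] <- "driver"
  category[!is_driver & is_sensor] <- "sensor"
  category[is_driver & is_sensor] <- "ds"
  structure(
    data.frame(node = graph$nodes, is_driver = is_driver,
               is_sensor = is_sensor, category = category,
               stringsAsFactors = FALSE),
    class = c("role_assignment", "data.frame")
  )
}

#' Category fractions of a role assignment
#'
#' `n_D`, `n_S`, `n_DS`, `n_O` are the fractions of driver, sensor,
#' dual-identity and ordinary nodes.  Driver and sensor sets overlap in the
#' DS nodes, so the accounting identity is
#' \eqn{n_D + n_S - n_{DS} + n_O = 1}; the exclusive fractions
#' `n_D_only = n_D - n_DS` and `n_S_only = n_S - n_DS` instead satisfy
#' \eqn{n_{D,only} + n_{S,only} + n_{DS} + n_O = 1}.  `n_D == n_S` always
#' (both equal \eqn{(N - |\mathcal{M}|)/N}).
#'
#' @param assignment a [classify_nodes()] result.
#' @param N node count; defaults to `nrow(assignment)`.
#' @return list of class `role_fractions` with elements `n_D`, `n_S`,
#'   `n_DS`, `n_O`, `n_D_only`, `n_S_only`.
#' @export
role_fractions <- function(assignment, N = nrow(assignment)) {
  stopifnot(inherits(assignment, "role_assignment"))
  if (N < 1) stop("fractions are undefined for an empty graph (N = 0)")
  n_D <- sum(assignment$is_driver) / N
  n_S <- sum(assignment$is_sensor) / N
  n_DS <- sum(assignment$is_driver & assignment$is_sensor) / N
  n_O <- sum(!assignment$is_driver & !assignment$is_sensor) / N
  structure(
    list(n_D = n_D, n_S = n_S, n_DS = n_DS, n_O = n_O,
         n_D_only = n_D - n_DS, n_S_only = n_S - n_DS),
    class = "role_fractions"
  )
}

#' @export
print.role_fractions <- function(x, ...) {
  cat(sprintf("n_D = %.4f  n_S = %.4f  n_DS = %.4f  n_O = %.4f\n",
              x$n_D, x$n_S, x$n_DS, x$n_O))
  invisible(x)
}

#' One-call node role analysis
#'
#' Convenience wrapper: bipartite representation, maximum matching,
#' classification and fractions in one step.  With `resamples > 1` the
#' matching is recomputed under `resamples` random left-node orders (seeded)
#' and the matching-dependent quantities `n_DS`, `n_O` are reported as mean
#' and standard deviation across resamples; `n_D`/`n_S` are
#' matching-invariant and reported once.
#'
#' @param graph a [directed_graph()].
#' @param resamples number of random left orders (default 1: deterministic,
#'   first-appearance order).
#' @param seed RNG seed used when `resamples > 1`.
#' @param lemma1_convention passed to [classify_nodes()].
#' @return list with `assignment` (from the deterministic order),
#'   `fractions`, `matching_size`, and when `resamples > 1` a `resampled`
#'   list with `n_DS_mean`, `n_DS_sd`, `n_O_mean`, `n_O_sd`.
#' @export
node_roles <- function(graph, resamples = 1, seed = 0,
                       lemma1_convention = FALSE) {
  stopifnot(inherits(graph, "directed_graph"))
  H <- build_bipartite(graph)
  matching <- hopcroft_karp(H)
  assignment <- classify_nodes(graph, matching,
                               lemma1_convention = lemma1_convention)
  out <- list(assignment = assignment,
              fractions = role_fractions(assignment),
              matching_size = matching$size)
  if (resamples > 1) {
    set.seed(seed)
    n_DS <- n_O <- numeric(resamples)
    for (r in seq_len(resamples)) {
      ord <- sample.int(graph$N)
      m_r <- hopcroft_karp(H, left_order = ord)
      a_r <- classify_nodes(graph, m_r, lemma1_convention = lemma1_convention)
      f_r <- role_fractions(a_r)
      n_DS[r] <- f_r$n_DS
      n_O[r] <- f_r$n_O
    }
    out$resampled <- list(n_DS_mean = mean(n_DS), n_DS_sd = stats::sd(n_DS),
                          n_O_mean = mean(n_O), n_O_sd = stats::sd(n_O))
  }
  out
}
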