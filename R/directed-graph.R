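#' Directed graph with opaque string node labels
#'
#' A minimal container for a simple directed graph \eqn{G(A)}: a set of
#' labelled nodes and a set of directed edges (ordered label pairs).  The
#' adjacency structure stands for the nonzero pattern of a state matrix
#' \eqn{A}: entry \eqn{a_{ij} \neq 0} corresponds to an edge
#' \eqn{x_j \to x_i}.  Edges are a set (duplicates collapse); self-loops are
#' permitted and preserved, since \eqn{a_{ii} \neq 0} is structurally
#' meaningful.
#'
#' Node labels are never coerced to numbers: real edge lists mix label
#' conventions and `"10"` must not collide with `"10.0"`.  Internal integer
#' indices follow first-appearance order and are an implementation detail.
#'
#' @param edges two-column character matrix or data frame, one directed edge
#'   `(from, to)` per row.  May have zero rows.
#' @param nodes optional character vector of node labels; labels appearing in
#'   `edges` but missing here are appended in first-appearance order.  Use
#'   this to declare isolated nodes.
#' @return An object of class `directed_graph` with elements `nodes`
#'   (character), `from`, `to` (integer node indices, one per edge), `N`, `M`.
#' @examples
#' g <- directed_graph(cbind(c("x1", "x1"), c("x2", "x3")))
#' g$N  # 3
#' g$M  # 2
#' @export
directed_graph <- function(edges = NULL, nodes = NULL) {
  if (is.null(edges)) {
    edges <- matrix(character(0), ncol = 2)
  }
  if (is.data.frame(edges)) {
    edges <- as.matrix(edges[, 1:2])
  }
  storage.mode(edges) <- "character"
  if (ncol(edges) != 2) stop("`edges` must have exactly two columns")

  labels <- unique(c(as.character(nodes), as.vector(t(edges))))
  from <- match(edges[, 1], labels)
  to <- match(edges[, 2], labels)

  # collapse duplicate edges: the structural matrix only records a_ij != 0
  if (length(from)) {
    key <- (from - 1) * length(labels) + to
    keep <- !duplicated(key)
    n_dup <- sum(!keep)
    if (n_dup > 0) {
      message(n_dup, " duplicate edge(s) collapsed")
      from <- from[keep]
      to <- to[keep]
    }
  }

  structure(
    list(nodes = labels, from = as.integer(from), to = as.integer(to),
         N = length(labels), M = length(from)),
    class = "directed_graph"
  )
}

#' @export
print.directed_graph <- function(x, ...) {
  cat("directed_graph: N =", x$N, "nodes, M =", x$M, "edges\n")
  invisible(x)
}

#' In- and out-degree of every node
#'
#' @param graph a [directed_graph()].
#' @return data frame with columns `node`, `k_out`, `k_in` in node order.
#' @export
degrees <- function(graph) {
  stopifnot(inherits(graph, "directed_graph"))
  data.frame(
    node = graph$nodes,
    k_out = tabulate(graph$from, nbins = graph$N),
    k_in = tabulate(graph$to, nbins = graph$N),
    stringsAsFactors = FALSE
  )
}

#' Read a directed edge list
#'
#' Parses plain-text edge lists, one `source target` pair per line.  Lines
#' with a single field declare an isolated node.  Duplicate edge lines
#' collapse to a single edge.  Node order is first appearance.
#'
#' @param path file path.
#' @param delimiter field separator; `NULL` (default) splits on any run of
#'   whitespace, otherwise a single character such as `","`.
#' @param comment_prefix lines starting with this prefix are ignored
#'   (default `"#"`).
#' @param strict if `TRUE` (default), a line with one field errors (with its
#'   line number) unless `allow_isolated` is `TRUE`.
#' @param allow_isolated treat single-field lines as isolated-node
#'   declarations (default `TRUE`).
#' @return a [directed_graph()].  An empty file gives the empty graph.
#' @export
read_edge_list <- function(path, delimiter = NULL, comment_prefix = "#",
                           strict = TRUE, allow_isolated = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !startsWith(trimws(lines), comment_prefix) & nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx)) return(directed_graph())

  split_one <- function(line) {
    if (is.null(delimiter)) strsplit(trimws(line), "[[:space:]]+")[[1]]
    else trimws(strsplit(line, delimiter, fixed = TRUE)[[1]])
  }
  fields <- lapply(lines[idx], split_one)
  nf <- lengths(fields)

  singles <- nf == 1
  if (any(singles) && !(allow_isolated)) {
    if (strict) {
      stop("malformed line ", idx[which(singles)[1]],
           ": expected at least 2 fields")
    }
    fields <- fields[!singles]
    nf <- nf[!singles]
    singles <- logical(length(fields))
  }
  if (any(nf == 0)) stop("malformed line ", idx[which(nf == 0)[1]])

  iso <- vapply(fields[singles], `[`, character(1), 1)
  pairs <- fields[!singles]
  edges <- if (length(pairs)) {
    cbind(vapply(pairs, `[`, character(1), 1),
          vapply(pairs, `[`, character(1), 2))
  } else {
    matrix(character(0), ncol = 2)
  }

  # preserve global first-appearance order across isolated + edge lines
  first_seen <- character(0)
  for (f in fields) first_seen <- c(first_seen, f[seq_len(min(2, length(f)))])
  directed_graph(edges, nodes = unique(first_seen))
}

#' Write a directed edge list
#'
#' Inverse of [read_edge_list()]: writes one `source<TAB>target` line per
#' edge and one single-field line per isolated node, so that a read/write
#' round trip preserves both `N` and `M`.
#'
#' @param graph a [directed_graph()].
#' @param path output file path.
#' @param declare_isolated write single-field lines for nodes with no
#'   incident edge (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(graph, path, declare_isolated = TRUE) {
  stopifnot(inherits(graph, "directed_graph"))
  lines <- character(0)
  if (declare_isolated) {
    touched <- unique(c(graph$from, graph$to))
    iso <- setdiff(seq_len(graph$N), touched)
    lines <- graph$nodes[iso]
  }
  lines <- c(lines,
             paste(graph$nodes[graph$from], graph$nodes[graph$to], sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Write a per-node role report
#'
#' Writes a TSV with columns `node`, `in_degree`, `out_degree`, `is_driver`,
#' `is_sensor`, `category`, plus a JSON sidecar `<path>.summary.json` with
#' the node and category counts
#' `{"N":..,"M":..,"n_D":..,"n_S":..,"n_DS":..,"n_O":..}` (counts, not
#' fractions, under keys `N_D` etc., and fractions under `n_D` etc.).
#'
#' @param graph a [directed_graph()].
#' @param roles a `role_assignment` from [classify_nodes()] covering every
#'   node of `graph`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_role_report <- function(graph, roles, path) {
  stopifnot(inherits(graph, "directed_graph"),
            inherits(roles, "role_assignment"))
  if (!identical(roles$node, graph$nodes)) {
    stop("`roles` does not cover the nodes of `graph`")
  }
  deg <- degrees(graph)
  out <- data.frame(
    node = roles$node,
    in_degree = deg$k_in,
    out_degree = deg$k_out,
    is_driver = roles$is_driver,
    is_sensor = roles$is_sensor,
    category = roles$category,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)

  cnt <- table(factor(roles$category,
                      levels = c("driver", "sensor", "ds", "ordinary")))
  summary <- list(
    N = graph$N, M = graph$M,
    N_D = sum(roles$is_driver), N_S = sum(roles$is_sensor),
    N_DS = unname(cnt[["ds"]]), N_O = unname(cnt[["ordinary"]]),
    n_D = sum(roles$is_driver) / graph$N,
    n_S = sum(roles$is_sensor) / graph$N,
    n_DS = unname(cnt[["ds"]]) / graph$N,
    n_O = unname(cnt[["ordinary"]]) / graph$N
  )
  jsonlite::write_json(summary, paste0(path, ".summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
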