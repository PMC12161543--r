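#' Per-category degree statistics
#'
#' Mean out-degree, in-degree, total degree and in/out difference for each
#' node category and for the whole graph.  By default the driver and sensor
#' categories are the *overlapping* sets (DS nodes belong to both), matching
#' how the category averages are defined; `exclusive = TRUE` restricts them
#' to exclusively-driver / exclusively-sensor nodes.
#'
#' For the `all` row, `diff` is exactly 0 (every edge contributes one
#' in-degree and one out-degree) and `total` equals \eqn{2M/N}.  Empty
#' categories get `NA` means rather than a fake 0.
#'
#' @param graph a [directed_graph()].
#' @param roles a [classify_nodes()] result covering `graph`.
#' @param exclusive use exclusive driver/sensor sets (default `FALSE`).
#' @return data frame with rows `all`, `driver`, `sensor`, `ds`, `ordinary`
#'   and columns `category`, `count`, `mean_out`, `mean_in`, `total`,
#'   `diff`.
#' @export
category_degree_stats <- function(graph, roles, exclusive = FALSE) {
  stopifnot(inherits(graph, "directed_graph"),
            inherits(roles, "role_assignment"))
  if (!identical(roles$node, graph$nodes)) {
    stop("`roles` does not cover the nodes of `graph`")
  }
  k_out <- tabulate(graph$from, nbins = graph$N)
  k_in <- tabulate(graph$to, nbins = graph$N)

  members <- list(
    all = rep(TRUE, graph$N),
    driver = if (exclusive) roles$is_driver & !roles$is_sensor
             else roles$is_driver,
    sensor = if (exclusive) roles$is_sensor & !roles$is_driver
             else roles$is_sensor,
    ds = roles$is_driver & roles$is_sensor,
    ordinary = !roles$is_driver & !roles$is_sensor
  )
  one <- function(sel) {
    n <- sum(sel)
    if (n == 0) {
      return(c(count = 0, mean_out = NA_real_, mean_in = NA_real_,
               total = NA_real_, diff = NA_real_))
    }
    mo <- mean(k_out[sel])
    mi <- mean(k_in[sel])
    c(count = n, mean_out = mo, mean_in = mi, total = mo + mi,
      diff = mo - mi)
  }
  rows <- t(vapply(members, one, numeric(5)))
  data.frame(category = rownames(rows), rows, row.names = NULL,
             stringsAsFactors = FALSE)
}
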