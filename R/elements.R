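#' Extract a hop-radius (d_i) structural element
#'
#' The element consists of the central residue and every node within `i`
#' graph hops, together with all induced edges; it is connected by
#' construction.
#'
#' @param graph a `ppi_graph`.
#' @param center node index (the `node` column of `graph$nodes`).
#' @param i hop radius, >= 0 (`i = 0` gives the center alone).
#' @return A `ppi_element`.
#' @export
extract_d_neighborhood <- function(graph, center, i) {
  stopifnot(i >= 0)
  check_center(graph, center)
  members <- center
  frontier <- center
  adj <- adjacency_list(graph)
  for (step in seq_len(i)) {
    nxt <- setdiff(unlist(adj[frontier], use.names = FALSE), members)
    if (length(nxt) == 0) break
    members <- c(members, nxt)
    frontier <- nxt
  }
  new_element(graph, center, sort(members), kind = "d", param = i)
}

#' Extract a k-nearest-neighbor (c_k) structural element
#'
#' The element consists of the central residue and the `k` nodes with the
#' smallest Euclidean CA distance to it, taken over the whole graph (not
#' only graph-adjacent nodes, and across chains), with all induced edges.
#' The result may be disconnected. Distance ties for the k-th slot are
#' broken deterministically by node index.
#'
#' @param graph a `ppi_graph`.
#' @param center node index.
#' @param k neighbor count, >= 0 (`k = 0` gives the center alone; `k > n-1`
#'   takes all nodes with a warning).
#' @return A `ppi_element`.
#' @export
extract_c_neighborhood <- function(graph, center, k) {
  stopifnot(k >= 0)
  check_center(graph, center)
  n <- nrow(graph$nodes)
  if (k > n - 1) {
    warning("k = ", k, " exceeds available nodes; taking all ", n - 1,
            call. = FALSE)
    k <- n - 1
  }
  xyz <- cbind(graph$nodes$ca_x, graph$nodes$ca_y, graph$nodes$ca_z)
  d <- sqrt((xyz[, 1] - xyz[center, 1])^2 + (xyz[, 2] - xyz[center, 2])^2 +
              (xyz[, 3] - xyz[center, 3])^2)
  others <- setdiff(graph$nodes$node, center)
  picked <- others[order(d[others], others)][seq_len(k)]
  new_element(graph, center, sort(c(center, picked)), kind = "c", param = k)
}

check_center <- function(graph, center) {
  if (length(center) != 1 || !center %in% graph$nodes$node) {
    stop("unknown center node: ", center, call. = FALSE)
  }
}

adjacency_list <- function(graph) {
  n <- nrow(graph$nodes)
  adj <- vector("list", n)
  e <- graph$edges
  if (nrow(e) > 0) {
    both <- c(e$from, e$to)
    nb <- c(e$to, e$from)
    adj_split <- split(nb, both)
    adj[as.integer(names(adj_split))] <- adj_split
  }
  adj
}

new_element <- function(graph, center, members, kind, param) {
  e <- graph$edges
  keep <- e$from %in% members & e$to %in% members
  structure(
    list(
      center = center, members = members, edges = e[keep, ],
      kind = kind, param = param,
      structure_id = graph$structure_id
    ),
    class = "ppi_element"
  )
}

#' @export
print.ppi_element <- function(x, ...) {
  cat("# ppi_element ", x$kind, "_", x$param, " centered at node ", x$center,
      ": ", length(x$members), " members, ", nrow(x$edges), " edges\n",
      sep = "")
  invisible(x)
}

#' Pairwise graph distances within a structural element
#'
#' Shortest-path hop counts over the element's *induced* subgraph (the
#' element is the stored pattern and must be self-contained). Pairs in
#' different components — possible for c_k elements — and any distance
#' exceeding `d_max` are clamped to the sentinel `d_max`.
#'
#' @param element a `ppi_element`.
#' @param d_max sentinel/clamp value (default 31 = 2^5 - 1, the 5-bit
#'   distance width).
#' @return Symmetric integer matrix with dimnames = member node indices.
#' @export
element_distances <- function(element, d_max = 31) {
  m <- element$members
  g <- igraph::graph_from_data_frame(
    d = element$edges, directed = FALSE,
    vertices = data.frame(name = m)
  )
  dm <- igraph::distances(g)
  dm <- dm[as.character(m), as.character(m), drop = FALSE]
  dm[!is.finite(dm) | dm > d_max] <- d_max
  storage.mode(dm) <- "integer"
  dm
}

#' Graph distance between two members of an element
#'
#' @inheritParams element_distances
#' @param a,b member node indices.
#' @return Integer hop count, or `d_max` if `a` and `b` lie in different
#'   components of the element.
#' @export
element_graph_distance <- function(element, a, b, d_max = 31) {
  if (!all(c(a, b) %in% element$members)) {
    stop("node outside element: ", paste(setdiff(c(a, b), element$members),
                                         collapse = ", "), call. = FALSE)
  }
  element_distances(element, d_max)[as.character(a), as.character(b)]
}
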