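#' Annotate residues of a structure
#'
#' Convenience wrapper joining the per-residue table with RASA (and its bin,
#' when edges are supplied) and, for multi-chain structures, interface labels.
#'
#' @param structure a `ppi_structure`.
#' @param bin_edges optional 9 decile edges from [derive_bin_edges()]; when
#'   given a `rasa_bin` column (0..9) is added.
#' @param label logical; compute ground-truth interface labels (requires a
#'   complex; single chains get all-FALSE with a warning).
#' @param interface_tolerance surface-gap tolerance in Angstrom.
#' @inheritParams compute_rasa
#' @return Residue tibble with `structure_id`, coordinates and annotations.
#' @export
annotate_residues <- function(structure, bin_edges = NULL, label = TRUE,
                              interface_tolerance = 0.5, probe = 1.4,
                              n_points = 960, context = "chain") {
  res <- residue_table(structure)
  rasa <- compute_rasa(structure, probe = probe, n_points = n_points,
                       context = context)
  res <- left_join(res, select(rasa, "res_id", "sasa", "rasa"), by = "res_id")
  if (!is.null(bin_edges)) res$rasa_bin <- bin_rasa(res$rasa, bin_edges)
  if (label) {
    lab <- label_interfaces(structure, tolerance = interface_tolerance)
    res <- left_join(res, select(lab, "res_id", "interface"), by = "res_id")
  }
  res <- mutate(res, structure_id = structure_id(structure), .before = 1)
  res
}

#' Build the residue contact graph
#'
#' Nodes are residues with alpha-carbon coordinates; two nodes are connected
#' iff their alpha carbons are at most `cutoff` Angstrom apart (inclusive, no
#' epsilon). Edges may cross chain boundaries within the same complex.
#' Residues lacking a CA atom are excluded from the graph with a warning.
#'
#' @param annotations residue tibble from [annotate_residues()] (or
#'   [residue_table()]), with `ca_x`/`ca_y`/`ca_z`.
#' @param cutoff CA-CA distance cutoff in Angstrom (default 6.0).
#' @param method `"cell"` (cell-list, default) or `"brute"` (all pairs); the
#'   two must agree and tests assert it.
#' @param edges_across_chains if `FALSE`, drop inter-chain edges.
#' @return A `ppi_graph`: list with `nodes` (tibble; `node` index, identity,
#'   coordinates, any annotation columns), `edges` (tibble `from` < `to`),
#'   `structure_id`, `cutoff`.
#' @export
build_graph <- function(annotations, cutoff = 6.0,
                        method = c("cell", "brute"),
                        edges_across_chains = TRUE) {
  method <- match.arg(method)
  nodes <- filter(annotations, is.finite(.data$ca_x))
  if (nrow(nodes) < nrow(annotations)) {
    warning(nrow(annotations) - nrow(nodes),
            " residue(s) without CA excluded from graph", call. = FALSE)
  }
  nodes <- mutate(nodes, node = row_number(), .before = 1)
  xyz <- cbind(nodes$ca_x, nodes$ca_y, nodes$ca_z)
  pairs <- if (method == "brute") {
    pairs_brute(xyz, cutoff)
  } else {
    pairs_cell(xyz, cutoff)
  }
  edges <- tibble(from = pairs[, 1], to = pairs[, 2])
  if (!edges_across_chains && nrow(edges) > 0) {
    edges <- filter(edges, nodes$chain[.data$from] == nodes$chain[.data$to])
  }
  structure(
    list(
      nodes = nodes, edges = edges,
      structure_id = annotations$structure_id[1] %||% NA_character_,
      cutoff = cutoff
    ),
    class = "ppi_graph"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pairs_brute <- function(xyz, cutoff) {
  n <- nrow(xyz)
  out <- list()
  for (i in seq_len(max(n - 1, 0))) {
    j <- (i + 1):n
    d <- sqrt((xyz[j, 1] - xyz[i, 1])^2 + (xyz[j, 2] - xyz[i, 2])^2 +
                (xyz[j, 3] - xyz[i, 3])^2)
    hit <- j[d <= cutoff]
    if (length(hit)) out[[length(out) + 1]] <- cbind(i, hit)
  }
  if (length(out) == 0) return(matrix(integer(0), ncol = 2))
  do.call(rbind, out)
}

pairs_cell <- function(xyz, cutoff) {
  n <- nrow(xyz)
  if (n < 2) return(matrix(integer(0), ncol = 2))
  ix <- floor(xyz[, 1] / cutoff)
  iy <- floor(xyz[, 2] / cutoff)
  iz <- floor(xyz[, 3] / cutoff)
  key <- paste(ix, iy, iz, sep = ",")
  cells <- split(seq_len(n), key)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  out <- list()
  for (i in seq_len(n)) {
    nb_keys <- paste(ix[i] + offs$dx, iy[i] + offs$dy, iz[i] + offs$dz,
                     sep = ",")
    cand <- unlist(cells[nb_keys], use.names = FALSE)
    cand <- cand[cand > i]
    if (length(cand) == 0) next
    d <- sqrt((xyz[cand, 1] - xyz[i, 1])^2 + (xyz[cand, 2] - xyz[i, 2])^2 +
                (xyz[cand, 3] - xyz[i, 3])^2)
    hit <- cand[d <= cutoff]
    if (length(hit)) out[[length(out) + 1]] <- cbind(i, sort(hit))
  }
  if (length(out) == 0) return(matrix(integer(0), ncol = 2))
  do.call(rbind, out)
}

#' @export
print.ppi_graph <- function(x, ...) {
  cat("# ppi_graph '", x$structure_id, "': ", nrow(x$nodes), " nodes, ",
      nrow(x$edges), " edges (cutoff ", x$cutoff, " A)\n", sep = "")
  invisible(x)
}

#' Degree statistics of a contact graph
#'
#' @param graph a `ppi_graph`.
#' @return One-row tibble: `n_nodes`, `n_edges`, `mean_degree`,
#'   `min_degree`, `max_degree`.
#' @export
degree_stats <- function(graph) {
  n <- nrow(graph$nodes)
  if (n == 0) {
    warning("empty graph", call. = FALSE)
    return(tibble(n_nodes = 0L, n_edges = 0L, mean_degree = 0,
                  min_degree = 0L, max_degree = 0L))
  }
  deg <- tabulate(c(graph$edges$from, graph$edges$to), nbins = n)
  tibble(
    n_nodes = n, n_edges = nrow(graph$edges),
    mean_degree = mean(deg), min_degree = min(deg), max_degree = max(deg)
  )
}

# igraph view of a ppi_graph (vertices named by node index)
graph_as_igraph <- function(graph) {
  igraph::graph_from_data_frame(
    d = graph$edges,
    directed = FALSE,
    vertices = data.frame(name = graph$nodes$node)
  )
}
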