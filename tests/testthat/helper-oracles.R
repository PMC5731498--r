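# Independent oracles and small fixture builders shared across tests.
# Every oracle here is deliberately implemented by a different route than
# the package code it checks.

# residue annotation tibble for a hand-placed CA trace; one row per residue
toy_annotations <- function(xyz, aa = NULL, chain = "A",
                            structure_id = "toy", rasa_bin = NULL) {
  n <- nrow(xyz)
  if (is.null(aa)) aa <- rep("A", n)
  if (length(chain) == 1) chain <- rep(chain, n)
  out <- tibble::tibble(
    structure_id = structure_id,
    chain = chain, resno = seq_len(n), icode = "",
    aa = aa,
    res_id = paste(chain, seq_len(n), "", sep = ":"),
    ca_x = xyz[, 1], ca_y = xyz[, 2], ca_z = xyz[, 3]
  )
  if (!is.null(rasa_bin)) out$rasa_bin <- rasa_bin
  out
}

# random geometric graph fixture (nodes <= nmax) with random letters
random_toy_graph <- function(seed, nmax = 50, cutoff = 6) {
  set.seed(seed)
  n <- sample(5:nmax, 1)
  xyz <- matrix(runif(3 * n, 0, 4 * n^(1 / 3)), ncol = 3)
  aa <- sample(unname(ppisite:::aa3to1[1:20]), n, replace = TRUE)
  build_graph(toy_annotations(xyz, aa), cutoff = cutoff)
}

# BFS-ball oracle via igraph shortest-path matrix (the implementation uses
# its own frontier expansion, not igraph)
oracle_d_members <- function(graph, center, i) {
  g <- igraph::graph_from_data_frame(
    graph$edges, directed = FALSE,
    vertices = data.frame(name = graph$nodes$node)
  )
  d <- igraph::distances(g, v = as.character(center))
  sort(as.integer(colnames(d)[d[1, ] <= i]))
}

# full distance-sort oracle for c_k membership
oracle_c_members <- function(graph, center, k) {
  xyz <- cbind(graph$nodes$ca_x, graph$nodes$ca_y, graph$nodes$ca_z)
  d <- sqrt(colSums((t(xyz) - xyz[center, ])^2))
  ids <- graph$nodes$node
  ord <- ids[ids != center][order(d[ids != center], ids[ids != center])]
  sort(c(center, ord[seq_len(min(k, length(ord)))]))
}

# all-pairs interface labeling oracle (double loop, no grid, no vector trick)
oracle_interface_residues <- function(structure, tolerance = 0.5) {
  a <- as.data.frame(structure)
  hit <- character(0)
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(a))) {
      if (a$chain[i] == a$chain[j]) next
      d <- sqrt(sum((c(a$x[i], a$y[i], a$z[i]) -
                       c(a$x[j], a$y[j], a$z[j]))^2))
      if (d - a$radius[i] - a$radius[j] <= tolerance) hit <- c(hit, a$res_id[i])
    }
  }
  unique(hit)
}

# independent query oracle: distances from bit-position sets, plain scan,
# tie-inclusive cutoff by counting
oracle_query <- function(kb, fp, central_key, n, exclude_structure = NULL) {
  r <- kb$records[kb$records$central_key == central_key, ]
  if (nrow(r) == 0) r <- kb$records
  if (!is.null(exclude_structure)) {
    r <- r[!r$structure_id %in% exclude_structure, ]
  }
  if (nrow(r) == 0) return(r[, c("structure_id", "res_id")])
  qb <- fingerprint_bits(fp)
  d <- vapply(r$fingerprint, function(f) {
    b <- fingerprint_bits(f)
    length(setdiff(b, qb)) + length(setdiff(qb, b))
  }, integer(1))
  cut <- sort(d)[min(n, length(d))]
  out <- r[d <= cut, c("structure_id", "res_id")]
  out$distance <- d[d <= cut]
  out[order(out$distance, out$structure_id, out$res_id), ]
}

# hand-built knowledge base whose key group contains fingerprints at the
# given bit distances from the all-zero query fingerprint
kb_with_distances <- function(distances, interface, l = 63,
                              central_key = "1",
                              structure_id = NULL) {
  stopifnot(length(distances) == length(interface))
  if (is.null(structure_id)) {
    structure_id <- sprintf("s%02d", seq_along(distances))
  }
  fps <- lapply(distances, function(d) {
    ppisite:::new_fingerprint(seq_len(d) - 1L, l)
  })
  cfg <- feature_config(l = l)
  structure(
    list(
      header = list(
        version = 1L, l = as.integer(l), widths = cfg$widths,
        dist_width = cfg$dist_width, d_max = cfg$d_max,
        fingerprint_features = "aa_type", central_features = "aa_type",
        neighborhood = "c", size = 4L, cutoff = 6, interface_tolerance = 0.5,
        bin_edges = NULL
      ),
      records = tibble::tibble(
        structure_id = structure_id,
        chain = "A", resno = seq_along(distances), icode = "",
        aa = "A",
        res_id = paste("A", seq_along(distances), "", sep = ":"),
        central_key = central_key,
        interface = interface,
        fingerprint = fps
      )
    ),
    class = "ppi_kb"
  )
}

zero_fp <- function(l = 63) ppisite:::new_fingerprint(integer(0), l)

# atom-level structure built from an explicit atom table (for surface-gap
# edge cases); each atom its own residue unless resno given
atoms_structure <- function(chain, x, y, z, element, resno = NULL,
                            aa = "G", structure_id = "gapfix") {
  n <- length(chain)
  if (is.null(resno)) resno <- seq_len(n)
  tbl <- tibble::tibble(
    chain = chain, resno = as.integer(resno), icode = "",
    resid = unname(ppisite:::aa1to3[rep_len(aa, n)]),
    aa = rep_len(aa, n),
    res_id = paste(chain, resno, "", sep = ":"),
    elety = "CA", element = element,
    x = x, y = y, z = z,
    radius = ppisite:::lookup_radius(element)
  )
  ppisite:::new_ppi_structure(tbl, structure_id)
}

# well-separated multi-chain CA-trace PDB file with given chain sizes
write_toy_pdb <- function(chain_sizes, path, gap_between = 100) {
  lines <- character(0)
  ser <- 0
  for (ci in seq_along(chain_sizes)) {
    ch <- LETTERS[ci]
    for (j in seq_len(chain_sizes[ci])) {
      ser <- ser + 1
      lines <- c(lines, sprintf(
        "ATOM  %5d  CA  GLY %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
        ser, ch, j, 3.8 * (j - 1), gap_between * (ci - 1), 0, 1, 0
      ))
    }
  }
  writeLines(c(lines, "END"), path)
  path
}
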