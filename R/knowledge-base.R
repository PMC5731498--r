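#' Build a fingerprint knowledge base from labeled complexes
#'
#' Applies the knowledge-base eligibility filters to each input complex
#' (chains >= `min_chain_len` residues, >= 2 chains), annotates residues
#' (RASA, interface labels by the vdW surface-gap rule), pools the RASA
#' distribution to derive decile bin edges when a `rasa_bin` feature is
#' configured, builds each complex's contact graph, and stores one record
#' per graph node: the fingerprint of the residue's structural element, the
#' central-residue feature key, the interface label and the source
#' structure id. Deterministic given the input order.
#'
#' @param structures list of `ppi_structure` objects.
#' @param config a [feature_config()].
#' @param neighborhood `"c"` (k nearest in space) or `"d"` (hop radius).
#' @param size the k or i parameter of the neighborhood.
#' @param cutoff CA-CA graph cutoff in Angstrom.
#' @param interface_tolerance vdW surface-gap tolerance in Angstrom.
#' @param min_chain_len chain-length filter for eligibility.
#' @param probe,n_points SASA parameters, see [compute_rasa()].
#' @param verbose print per-structure progress.
#' @return A `ppi_kb`: list with `header` (all configuration, bin edges) and
#'   `records` (tibble with `structure_id`, residue identity, `central_key`,
#'   `interface`, list-column `fingerprint`).
#' @export
build_kb <- function(structures, config = feature_config(),
                     neighborhood = c("c", "d"), size = 12,
                     cutoff = 6.0, interface_tolerance = 0.5,
                     min_chain_len = 5, probe = 1.4, n_points = 960,
                     verbose = FALSE) {
  neighborhood <- match.arg(neighborhood)
  if (length(structures) == 0) stop("empty structure list", call. = FALSE)
  kept <- list()
  for (s in structures) {
    f <- filter_chains_for_kb(s, min_chain_len = min_chain_len)
    if (is_kb_eligible(f)) {
      kept[[length(kept) + 1]] <- f
    } else if (verbose) {
      message("rejecting '", structure_id(s), "' (fewer than 2 usable chains)")
    }
  }
  if (length(kept) == 0) {
    stop("no structure passed the knowledge-base filters", call. = FALSE)
  }

  ann <- lapply(kept, function(s) {
    annotate_residues(s, label = TRUE,
                      interface_tolerance = interface_tolerance,
                      probe = probe, n_points = n_points)
  })

  uses_rasa <- "rasa_bin" %in% c(config$fingerprint_features,
                                 config$central_features)
  bin_edges <- if (uses_rasa) {
    derive_bin_edges(unlist(lapply(ann, `[[`, "rasa")))
  } else {
    NULL
  }

  records <- vector("list", length(kept))
  n_int <- 0L
  for (si in seq_along(kept)) {
    a <- ann[[si]]
    if (!is.null(bin_edges)) a$rasa_bin <- bin_rasa(a$rasa, bin_edges)
    g <- build_graph(a, cutoff = cutoff)
    records[[si]] <- kb_records_for_graph(g, config, neighborhood, size)
    n_int <- n_int + sum(records[[si]]$interface)
    if (verbose) {
      message("indexed '", g$structure_id, "': ", nrow(records[[si]]),
              " records")
    }
  }
  records <- bind_rows(records)
  if (verbose) {
    message("knowledge base: ", nrow(records), " records (", n_int,
            " interface, ", nrow(records) - n_int, " non-interface)")
  }

  structure(
    list(
      header = list(
        version = 1L,
        l = config$l,
        widths = config$widths,
        dist_width = config$dist_width,
        d_max = config$d_max,
        fingerprint_features = config$fingerprint_features,
        central_features = config$central_features,
        neighborhood = neighborhood,
        size = as.integer(size),
        cutoff = cutoff,
        interface_tolerance = interface_tolerance,
        bin_edges = bin_edges
      ),
      records = records
    ),
    class = "ppi_kb"
  )
}

# one record per node of a graph
kb_records_for_graph <- function(graph, config, neighborhood, size) {
  nodes <- graph$nodes
  ckeys <- central_keys(nodes, config)
  fps <- vector("list", nrow(nodes))
  for (v in nodes$node) {
    el <- if (neighborhood == "c") {
      extract_c_neighborhood(graph, v, size)
    } else {
      extract_d_neighborhood(graph, v, size)
    }
    fps[[v]] <- build_fingerprint(el, graph, config)
  }
  tibble(
    structure_id = graph$structure_id,
    chain = nodes$chain, resno = nodes$resno, icode = nodes$icode,
    aa = nodes$aa, res_id = nodes$res_id,
    central_key = ckeys,
    interface = as.logical(nodes$interface),
    fingerprint = fps
  )
}

# central-residue prefilter keys, e.g. "12" or "12:7"
central_keys <- function(nodes, config) {
  codes <- feature_code_matrix(nodes, config$central_features)
  apply(codes, 1, paste, collapse = ":")
}

#' @export
print.ppi_kb <- function(x, ...) {
  h <- x$header
  cat("# ppi_kb: ", nrow(x$records), " records from ",
      length(unique(x$records$structure_id)), " structure(s)\n",
      "#   element ", h$neighborhood, "_", h$size, ", l = ", h$l,
      ", pair features [", paste(h$fingerprint_features, collapse = ", "),
      "], central [", paste(h$central_features, collapse = ", "), "]\n",
      sep = "")
  invisible(x)
}

#' Summarise a knowledge base
#'
#' @param kb a `ppi_kb`.
#' @return Tibble with one row per central-feature key group: record count
#'   and interface count.
#' @export
kb_inspect <- function(kb) {
  kb$records |>
    group_by(.data$central_key) |>
    summarise(n_records = dplyr::n(), n_interface = sum(.data$interface),
              .groups = "drop") |>
    arrange(.data$central_key)
}

#' Tie-inclusive nearest-neighbor query against a knowledge base
#'
#' Restricts the search to records whose central-feature key equals
#' `central_key` (the K_A prefilter; if that key group is empty the whole
#' knowledge base is scanned with a warning), removes records from
#' `exclude_structure`, ranks the rest by fingerprint bit difference, and
#' returns every record whose distance is at most the n-th smallest —
#' including all records tied with the n-th, so the result can exceed `n`
#' rows. The result is a set: it does not depend on record storage order.
#'
#' @param kb a `ppi_kb`.
#' @param fp query `ppi_fingerprint` (length must match the KB header).
#' @param central_key query key string as produced by the KB's central
#'   feature configuration.
#' @param n number of most-similar elements requested (>= 1).
#' @param exclude_structure structure id(s) whose records are disregarded
#'   (self-exclusion), or `NULL`.
#' @return Tibble of matching records with a `distance` column; zero rows
#'   when nothing remains after exclusion.
#' @export
kb_query <- function(kb, fp, central_key, n = 1, exclude_structure = NULL) {
  stopifnot(n >= 1)
  if (attr(fp, "l") != kb$header$l) {
    stop("query fingerprint length ", attr(fp, "l"),
         " does not match knowledge base (l = ", kb$header$l, ")",
         call. = FALSE)
  }
  group <- kb$records[kb$records$central_key == central_key, ]
  if (nrow(group) == 0) {
    warning("central key '", central_key,
            "' unseen in knowledge base; scanning all records", call. = FALSE)
    group <- kb$records
  }
  if (!is.null(exclude_structure)) {
    group <- group[!group$structure_id %in% exclude_structure, ]
  }
  if (nrow(group) == 0) {
    return(mutate(group, distance = integer(0)))
  }
  d <- vapply(group$fingerprint, bit_difference, integer(1), f2 = fp)
  cutoff <- sort(d)[min(n, length(d))]
  out <- group[d <= cutoff, ]
  out$distance <- d[d <= cutoff]
  arrange(out, .data$distance, .data$structure_id, .data$res_id)
}

# ---- binary on-disk format ---------------------------------------------
# little-endian; layout:
#   magic "FPKB" | version i32
#   l i32 | width_aa i32 | width_rasa i32 | dist_width i32 | d_max i32
#   neighborhood u8 (1 = c, 2 = d) | size i32
#   cutoff f64 | interface_tolerance f64
#   fingerprint feature list: count i32, codes i32 (1 = aa_type, 2 = rasa_bin)
#   central feature list: same
#   bin edges: count i32, f64 each
#   structure table: count i32, each string (len i32 + utf8 bytes)
#   records: count i32, each
#     structure index i32 | chain str | resno i32 | icode str | aa str |
#     central_key str | interface u8 | fingerprint bytes (ceil(l / 8))

kb_magic <- charToRaw("FPKB")
.feat_code <- c(aa_type = 1L, rasa_bin = 2L)

w_i32 <- function(con, x) writeBin(as.integer(x), con, size = 4, endian = "little")
w_f64 <- function(con, x) writeBin(as.numeric(x), con, size = 8, endian = "little")
w_str <- function(con, s) {
  b <- charToRaw(enc2utf8(s))
  w_i32(con, length(b))
  writeBin(b, con)
}
r_i32 <- function(con, n = 1) {
  x <- readBin(con, "integer", n = n, size = 4, endian = "little")
  if (length(x) < n) stop("truncated knowledge-base file", call. = FALSE)
  x
}
r_f64 <- function(con, n = 1) {
  x <- readBin(con, "numeric", n = n, size = 8, endian = "little")
  if (length(x) < n) stop("truncated knowledge-base file", call. = FALSE)
  x
}
r_str <- function(con) {
  nb <- r_i32(con)
  if (nb == 0) return("")
  b <- readBin(con, "raw", n = nb)
  if (length(b) < nb) stop("truncated knowledge-base file", call. = FALSE)
  rawToChar(b)
}

#' Save a knowledge base to its binary file format
#'
#' The format is versioned and little-endian; the header carries the
#' fingerprint length, bit-widths, feature configurations, element spec and
#' bin edges, so a loaded knowledge base can refuse incompatible queries.
#' Saving the same knowledge base twice produces byte-identical files.
#'
#' @param kb a `ppi_kb`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_kb <- function(kb, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  h <- kb$header
  writeBin(kb_magic, con)
  w_i32(con, h$version)
  w_i32(con, h$l)
  w_i32(con, h$widths[["aa_type"]])
  w_i32(con, h$widths[["rasa_bin"]])
  w_i32(con, h$dist_width)
  w_i32(con, h$d_max)
  writeBin(as.raw(if (h$neighborhood == "c") 1L else 2L), con)
  w_i32(con, h$size)
  w_f64(con, h$cutoff)
  w_f64(con, h$interface_tolerance)
  for (fl in list(h$fingerprint_features, h$central_features)) {
    w_i32(con, length(fl))
    w_i32(con, unname(.feat_code[fl]))
  }
  w_i32(con, length(h$bin_edges))
  if (length(h$bin_edges)) w_f64(con, h$bin_edges)
  sids <- unique(kb$records$structure_id)
  w_i32(con, length(sids))
  for (s in sids) w_str(con, s)
  r <- kb$records
  w_i32(con, nrow(r))
  nbytes <- ceiling(h$l / 8)
  for (i in seq_len(nrow(r))) {
    w_i32(con, match(r$structure_id[i], sids))
    w_str(con, r$chain[i])
    w_i32(con, r$resno[i])
    w_str(con, r$icode[i])
    w_str(con, r$aa[i])
    w_str(con, r$central_key[i])
    writeBin(as.raw(as.integer(r$interface[i])), con)
    fp <- unclass(r$fingerprint[[i]])
    attributes(fp) <- NULL
    stopifnot(length(fp) == nbytes)
    writeBin(fp, con)
  }
  invisible(path)
}

#' Load a knowledge base from its binary file
#'
#' Refuses files with a wrong magic number or unsupported version, and
#' detects truncation. `load_kb(save_kb(kb))` reproduces `kb` exactly.
#'
#' @param path file written by [save_kb()].
#' @return A `ppi_kb`.
#' @export
load_kb <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 4)
  if (length(magic) < 4 || !identical(magic, kb_magic)) {
    stop("not a knowledge-base file (bad magic): ", path, call. = FALSE)
  }
  version <- r_i32(con)
  if (!identical(version, 1L)) {
    stop("unsupported knowledge-base version: ", version, call. = FALSE)
  }
  l <- r_i32(con)
  w_aa <- r_i32(con); w_rb <- r_i32(con)
  dist_width <- r_i32(con); d_max <- r_i32(con)
  nb <- readBin(con, "raw", n = 1)
  neighborhood <- if (as.integer(nb) == 1L) "c" else "d"
  size <- r_i32(con)
  cutoff <- r_f64(con)
  interface_tolerance <- r_f64(con)
  feats <- lapply(1:2, function(dummy) {
    k <- r_i32(con)
    names(.feat_code)[r_i32(con, k)]
  })
  ne <- r_i32(con)
  bin_edges <- if (ne > 0) r_f64(con, ne) else NULL
  ns <- r_i32(con)
  sids <- vapply(seq_len(ns), function(i) r_str(con), character(1))
  nr <- r_i32(con)
  nbytes <- ceiling(l / 8)
  rec <- vector("list", nr)
  for (i in seq_len(nr)) {
    si <- r_i32(con)
    chain <- r_str(con)
    resno <- r_i32(con)
    icode <- r_str(con)
    aa <- r_str(con)
    key <- r_str(con)
    interface <- as.logical(as.integer(readBin(con, "raw", n = 1)))
    fpb <- readBin(con, "raw", n = nbytes)
    if (length(fpb) < nbytes || length(interface) == 0) {
      stop("truncated knowledge-base file: ", path, call. = FALSE)
    }
    attr(fpb, "l") <- l
    class(fpb) <- "ppi_fingerprint"
    rec[[i]] <- list(structure_id = sids[si], chain = chain, resno = resno,
                     icode = icode, aa = aa, key = key,
                     interface = interface, fp = fpb)
  }
  records <- tibble(
    structure_id = vapply(rec, `[[`, character(1), "structure_id"),
    chain = vapply(rec, `[[`, character(1), "chain"),
    resno = vapply(rec, `[[`, integer(1), "resno"),
    icode = vapply(rec, `[[`, character(1), "icode"),
    aa = vapply(rec, `[[`, character(1), "aa"),
    res_id = paste(vapply(rec, `[[`, character(1), "chain"),
                   vapply(rec, `[[`, integer(1), "resno"),
                   vapply(rec, `[[`, character(1), "icode"), sep = ":"),
    central_key = vapply(rec, `[[`, character(1), "key"),
    interface = vapply(rec, `[[`, logical(1), "interface"),
    fingerprint = lapply(rec, `[[`, "fp")
  )
  structure(
    list(
      header = list(
        version = version, l = l,
        widths = c(aa_type = w_aa, rasa_bin = w_rb),
        dist_width = dist_width, d_max = d_max,
        fingerprint_features = feats[[1]], central_features = feats[[2]],
        neighborhood = neighborhood, size = size,
        cutoff = cutoff, interface_tolerance = interface_tolerance,
        bin_edges = bin_edges
      ),
      records = records
    ),
    class = "ppi_kb"
  )
}

# configuration implied by a KB header (for building query-side elements)
kb_config <- function(kb) {
  h <- kb$header
  cfg <- feature_config(
    fingerprint_features = h$fingerprint_features,
    central_features = h$central_features,
    l = h$l, dist_width = h$dist_width
  )
  cfg
}
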