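#' Prediction parameter set
#'
#' Bundles the element specification, feature configuration, number of
#' most-similar elements `n`, and the decision threshold. The `"published"`
#' preset is the configuration used for benchmark comparisons: c_12
#' neighborhood, 1023-bit fingerprints, amino-acid type as both the pair and
#' the central prefilter feature, one most similar element, and decision
#' threshold 0.5175 (a residue is called interface iff the retrieved
#' interface fraction is strictly greater than the threshold).
#'
#' @param preset `"published"` or `NULL` for fully manual settings.
#' @param neighborhood `"c"` or `"d"`.
#' @param size neighborhood parameter (k or i).
#' @param n number of most-similar elements (ties with the n-th distance are
#'   always included).
#' @param threshold decision threshold on the interface probability.
#' @param config a [feature_config()].
#' @return A `ppi_params` list.
#' @export
ppi_params <- function(preset = NULL, neighborhood = c("c", "d"), size = 12,
                       n = 1, threshold = 0.5175,
                       config = feature_config()) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, "published")
    return(structure(
      list(
        neighborhood = "c", size = 12L, n = 1L, threshold = 0.5175,
        config = feature_config(
          fingerprint_features = "aa_type",
          central_features = "aa_type",
          l = 1023L
        )
      ),
      class = "ppi_params"
    ))
  }
  neighborhood <- match.arg(neighborhood)
  stopifnot(size >= 0, n >= 1, threshold >= 0, threshold <= 1)
  structure(
    list(neighborhood = neighborhood, size = as.integer(size),
         n = as.integer(n), threshold = threshold, config = config),
    class = "ppi_params"
  )
}

#' @export
print.ppi_params <- function(x, ...) {
  cat("# ppi_params: ", x$neighborhood, "_", x$size, ", n = ", x$n,
      ", threshold = ", x$threshold, ", l = ", x$config$l, "\n", sep = "")
  invisible(x)
}

#' Parameters matching a knowledge base
#'
#' Derives a `ppi_params` whose element spec and feature configuration come
#' from the knowledge-base header (queries must be encoded exactly as the
#' records were), leaving only the query-time knobs `n` and `threshold`
#' free.
#'
#' @param kb a `ppi_kb`.
#' @inheritParams ppi_params
#' @return A `ppi_params`.
#' @export
kb_params <- function(kb, n = 1, threshold = 0.5175) {
  h <- kb$header
  ppi_params(neighborhood = h$neighborhood, size = h$size, n = n,
             threshold = threshold, config = kb_config(kb))
}

check_kb_compat <- function(kb, params) {
  h <- kb$header
  c_ok <- identical(params$config$l, h$l) &&
    identical(params$config$fingerprint_features, h$fingerprint_features) &&
    identical(params$config$central_features, h$central_features) &&
    identical(params$config$dist_width, h$dist_width) &&
    params$neighborhood == h$neighborhood &&
    params$size == h$size
  if (!c_ok) {
    stop("parameter set is incompatible with the knowledge base header ",
         "(element spec ", h$neighborhood, "_", h$size, ", l = ", h$l,
         "); use kb_params() to derive matching parameters", call. = FALSE)
  }
  invisible(TRUE)
}

#' Predict the interface probability of one residue
#'
#' Runs the full per-residue procedure: extract the structural element
#' centered at the node, fingerprint it, prefilter the knowledge base by the
#' central-residue features, retrieve the `n` most similar records
#' (tie-inclusive, optionally excluding the query's own structure), split
#' them into interface set I and non-interface set N, and report
#' `|I| / |S|` as the interface probability. The binary call is
#' `probability > threshold` (strict). When nothing can be retrieved the
#' probability is undefined: `NA` with a non-interface call and
#' `defined = FALSE`.
#'
#' @param graph annotated query `ppi_graph` (binned with the KB's edges when
#'   RASA features are configured).
#' @param center node index.
#' @param kb a `ppi_kb`.
#' @param params a [ppi_params()] compatible with the KB.
#' @param exclude_structure structure id(s) to disregard, or `NULL`.
#' @return One-row tibble: residue identity, `prob`, `n_interface`,
#'   `n_retrieved`, `nearest_dist`, `call`, `defined`.
#' @export
predict_residue <- function(graph, center, kb, params = kb_params(kb),
                            exclude_structure = NULL) {
  check_kb_compat(kb, params)
  node <- graph$nodes[match(center, graph$nodes$node), ]
  el <- if (params$neighborhood == "c") {
    extract_c_neighborhood(graph, center, params$size)
  } else {
    extract_d_neighborhood(graph, center, params$size)
  }
  fp <- build_fingerprint(el, graph, params$config)
  key <- central_keys(node, params$config)
  s <- kb_query(kb, fp, key, n = params$n,
                exclude_structure = exclude_structure)
  n_s <- nrow(s)
  n_i <- sum(s$interface)
  prob <- if (n_s > 0) n_i / n_s else NA_real_
  tibble(
    structure_id = graph$structure_id,
    chain = node$chain, resno = node$resno, icode = node$icode,
    aa = node$aa, res_id = node$res_id,
    rasa = if ("rasa" %in% names(node)) node$rasa else NA_real_,
    prob = prob,
    n_interface = n_i,
    n_retrieved = n_s,
    nearest_dist = if (n_s > 0) min(s$distance) else NA_integer_,
    call = isTRUE(prob > params$threshold),
    defined = n_s > 0
  )
}

#' Predict interface residues for a whole structure
#'
#' Annotates the query structure (RASA on isolated chains; RASA bins from
#' the knowledge-base edges when configured), builds its contact graph with
#' the knowledge base's cutoff, and applies [predict_residue()] to every
#' node. By default the knowledge base's records for the query's own
#' structure id are disregarded, mirroring the leave-query-protein-out
#' evaluation protocol.
#'
#' @param structure a `ppi_structure`.
#' @param kb a `ppi_kb`.
#' @param params a [ppi_params()]; defaults to the KB-derived set with
#'   `n = 1`, threshold 0.5175.
#' @param exclude_self disregard knowledge-base records whose structure id
#'   equals the query's.
#' @param probe,n_points SASA parameters.
#' @return Tibble of class `ppi_prediction`, one row per graph node, with
#'   `prob`, counts, `call` and `defined`.
#' @export
predict_structure <- function(structure, kb, params = kb_params(kb),
                              exclude_self = TRUE, probe = 1.4,
                              n_points = 960) {
  check_kb_compat(kb, params)
  ann <- annotate_residues(structure, bin_edges = kb$header$bin_edges,
                           label = FALSE, probe = probe, n_points = n_points)
  g <- build_graph(ann, cutoff = kb$header$cutoff)
  excl <- if (exclude_self) structure_id(structure) else NULL
  out <- purrr::map(g$nodes$node, function(v) {
    predict_residue(g, v, kb, params, exclude_structure = excl)
  })
  out <- bind_rows(out)
  class(out) <- c("ppi_prediction", class(out))
  attr(out, "params") <- params
  out
}
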