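#' Fingerprint feature configuration
#'
#' Fixes which residue features label the neighborhood pairs
#' (`fingerprint_features`) and which label the central residue for
#' knowledge-base prefiltering (`central_features`), the fingerprint length,
#' and the fixed bit-widths used when pair indices are assembled. The
#' configuration is stored in the knowledge-base header so records and
#' queries always agree.
#'
#' Bit-widths: amino-acid type codes are 1..26 (5 bits), RASA bins 0..9
#' (4 bits), graph distances 0..`2^dist_width - 1` (5 bits by default, so
#' distances clamp at the sentinel `d_max = 31`).
#'
#' @param fingerprint_features character subset of
#'   `c("aa_type", "rasa_bin")` used for pair encoding.
#' @param central_features character subset used for exact prefiltering.
#' @param l fingerprint length in bits; 63, 255 and 1023 are the standard
#'   presets.
#' @param dist_width bits reserved for the graph distance.
#' @return A `ppi_feature_config`.
#' @export
feature_config <- function(fingerprint_features = "aa_type",
                           central_features = "aa_type",
                           l = 1023L, dist_width = 5L) {
  valid <- c("aa_type", "rasa_bin")
  stopifnot(
    length(fingerprint_features) >= 1,
    all(fingerprint_features %in% valid),
    all(central_features %in% valid),
    l >= 1, dist_width >= 1
  )
  structure(
    list(
      fingerprint_features = fingerprint_features,
      central_features = central_features,
      l = as.integer(l),
      widths = c(aa_type = 5L, rasa_bin = 4L),
      dist_width = as.integer(dist_width),
      d_max = as.integer(2^dist_width - 1)
    ),
    class = "ppi_feature_config"
  )
}

#' @export
print.ppi_feature_config <- function(x, ...) {
  cat("# ppi_feature_config: l = ", x$l,
      ", pair features [", paste(x$fingerprint_features, collapse = ", "),
      "], central features [", paste(x$central_features, collapse = ", "),
      "], d_max = ", x$d_max, "\n", sep = "")
  invisible(x)
}

#' Encode a residue feature as a small integer
#'
#' Amino-acid type maps to the 1-based position of its one-letter code in
#' the Latin alphabet ('A' -> 1, 'C' -> 3, ..., 'Y' -> 25); a RASA bin is
#' its own index 0..9.
#'
#' @param aa one-letter amino-acid code(s).
#' @param rasa_bin integer bin index/indices (0..9); may be `NULL` when the
#'   feature is not requested.
#' @param feature `"aa_type"` or `"rasa_bin"`.
#' @return Integer code vector.
#' @export
encode_feature <- function(aa, rasa_bin = NULL, feature) {
  if (feature == "aa_type") {
    code <- match(aa, LETTERS)
    if (any(is.na(code))) {
      stop("cannot encode amino-acid letter(s): ",
           paste(unique(aa[is.na(code)]), collapse = ", "), call. = FALSE)
    }
    return(code)
  }
  if (feature == "rasa_bin") {
    if (is.null(rasa_bin) || any(is.na(rasa_bin)) ||
        any(rasa_bin < 0 | rasa_bin > 9)) {
      stop("rasa_bin must be available and in 0..9", call. = FALSE)
    }
    return(as.integer(rasa_bin))
  }
  stop("unknown feature: ", feature, call. = FALSE)
}

# code matrix (rows = residues, cols = features) for a node table
feature_code_matrix <- function(nodes, features) {
  mat <- vapply(
    features,
    function(f) encode_feature(nodes$aa, nodes$rasa_bin, f),
    integer(nrow(nodes))
  )
  matrix(mat, nrow = nrow(nodes),
         dimnames = list(NULL, features))
}

# widths (bits) for a feature vector under a config
feature_widths <- function(config) {
  unname(config$widths[config$fingerprint_features])
}

#' Assemble the pair index for two coded residues
#'
#' Concatenates the feature codes of residue A, the graph distance `d`, and
#' the codes of residue B — each as a fixed-width binary field, in that
#' order — into a single integer. The pair is canonicalized first (the
#' lexicographically smaller code tuple plays the role of A) so the index
#' does not depend on the orientation of the pair.
#'
#' @param codes_a,codes_b integer code vectors, one entry per fingerprint
#'   feature.
#' @param d graph distance (<= `d_max`).
#' @param config a `ppi_feature_config`.
#' @return A non-negative numeric (exact integer) index.
#' @export
encode_pair <- function(codes_a, codes_b, d, config) {
  w <- feature_widths(config)
  if (any(codes_a >= 2^w) || any(codes_b >= 2^w) || any(codes_a < 0) ||
      any(codes_b < 0)) {
    stop("feature code overflows its bit-width", call. = FALSE)
  }
  if (d < 0 || d > config$d_max) {
    stop("distance ", d, " outside 0..d_max", call. = FALSE)
  }
  # canonical order: lexicographically smaller tuple is A
  swap <- FALSE
  for (i in seq_along(codes_a)) {
    if (codes_a[i] != codes_b[i]) {
      swap <- codes_a[i] > codes_b[i]
      break
    }
  }
  if (swap) {
    tmp <- codes_a; codes_a <- codes_b; codes_b <- tmp
  }
  fields <- c(codes_a, d, codes_b)
  widths <- c(w, config$dist_width, w)
  v <- 0
  for (i in seq_along(fields)) v <- v * 2^widths[i] + fields[i]
  v
}

# ---- fingerprint bit arrays --------------------------------------------

# packed raw vector with attribute "l"; bit p (0-based) lives at byte
# p %/% 8, little-endian within the byte
new_fingerprint <- function(positions, l) {
  nbytes <- ceiling(l / 8)
  bits <- raw(nbytes * 8)
  if (length(positions)) bits[positions + 1] <- as.raw(1)
  fp <- packBits(bits, type = "raw")
  attr(fp, "l") <- as.integer(l)
  class(fp) <- "ppi_fingerprint"
  fp
}

#' Bit positions set in a fingerprint
#' @param fp a `ppi_fingerprint`.
#' @return 0-based integer positions of set bits.
#' @export
fingerprint_bits <- function(fp) {
  which(rawToBits(unclass(fp)) == as.raw(1)) - 1L
}

#' @export
print.ppi_fingerprint <- function(x, ...) {
  cat("# ppi_fingerprint: l = ", attr(x, "l"), ", ",
      length(fingerprint_bits(x)), " bits set\n", sep = "")
  invisible(x)
}

#' Build the fingerprint of a structural element
#'
#' For every unordered pair of distinct member residues (the center is an
#' ordinary member), the pair's feature codes and induced-subgraph distance
#' are assembled into an index `i` ([encode_pair()]) and bit `i mod l` of an
#' initially zero bit array is set. A single-member element therefore yields
#' the all-zero fingerprint. Hash collisions are tolerated by design:
#' distinct elements may share a fingerprint and no de-duplication is
#' attempted.
#'
#' @param element a `ppi_element`.
#' @param graph the `ppi_graph` the element came from (source of feature
#'   annotations; needs `rasa_bin` when that feature is configured).
#' @param config a `ppi_feature_config`.
#' @return A `ppi_fingerprint` of length `config$l`.
#' @export
build_fingerprint <- function(element, graph, config = feature_config()) {
  m <- element$members
  if (length(m) < 2) return(new_fingerprint(integer(0), config$l))
  nodes <- graph$nodes[match(m, graph$nodes$node), ]
  codes <- feature_code_matrix(nodes, config$fingerprint_features)
  dm <- element_distances(element, d_max = config$d_max)
  idx <- utils::combn(length(m), 2)
  pos <- numeric(ncol(idx))
  for (p in seq_len(ncol(idx))) {
    a <- idx[1, p]; b <- idx[2, p]
    i <- encode_pair(codes[a, ], codes[b, ], dm[a, b], config)
    pos[p] <- i %% config$l
  }
  new_fingerprint(unique(pos), config$l)
}

# byte-wise popcount lookup (index = byte value + 1)
popcount8 <- vapply(0:255, function(b) sum(bitwAnd(b, 2^(0:7)) > 0), numeric(1))

#' Number of differing bits between two fingerprints
#'
#' The Hamming distance between two equal-length fingerprints; 0 iff they
#' are identical. Smaller values mean more similar structural elements.
#'
#' @param f1,f2 `ppi_fingerprint`s of equal length.
#' @return Integer bit count.
#' @export
bit_difference <- function(f1, f2) {
  l1 <- attr(f1, "l"); l2 <- attr(f2, "l")
  if (is.null(l1) || is.null(l2) || l1 != l2 || length(f1) != length(f2)) {
    stop("fingerprint length mismatch", call. = FALSE)
  }
  as.integer(sum(popcount8[bitwXor(as.integer(unclass(f1)),
                                   as.integer(unclass(f2))) + 1L]))
}
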