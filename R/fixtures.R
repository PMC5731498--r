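#' Generate a synthetic two-chain complex with a planted interface
#'
#' Produces a schematic protein complex: each chain is a straight CA-only
#' trace with 3.8 A consecutive spacing; chain B runs parallel to chain A,
#' offset to its residue midpoints, at a per-residue distance chosen so that
#' residues inside `contact_window` satisfy the vdW surface-gap interface
#' rule with gap `contact_gap` (<= 0.5 A by construction) while all other
#' cross-chain atom pairs keep a gap of at least `far_gap` (>= 1.5 A, i.e.
#' at least 1 A beyond the rule). Ground-truth labels are computed by the
#' generator's own all-pairs distance loop over the constructed coordinates,
#' independent of the package's grid-accelerated labeling.
#'
#' Geometry is schematic on purpose: every rule in the method depends only
#' on distances, radii and labels, not on chemistry.
#'
#' @param structure_id identifier for the complex.
#' @param n_res integer vector of length 2: residues per chain.
#' @param contact_window residue positions (chain B numbering) pulled into
#'   contact; empty vector plants no interface.
#' @param contact_gap vdW surface gap in the contact window (A, <= 0.5).
#' @param far_gap minimal surface gap outside the window (A, >= 1.5).
#' @param seqs optional list of two character vectors of one-letter codes;
#'   sampled from the 20 standard letters when `NULL`.
#' @param jitter amplitude of deterministic z-jitter (A); kept small so no
#'   planted margin can flip.
#' @param seed integer seed; same seed and spec give byte-identical output.
#' @return List with `structure` (a `ppi_structure`), `truth` (tibble
#'   `structure_id`, `res_id`, `interface`) and `pdb` (character vector of
#'   PDB lines).
#' @export
make_complex <- function(structure_id = "synth1", n_res = c(14, 14),
                         contact_window = 5:8, contact_gap = 0.3,
                         far_gap = 2.0, seqs = NULL, jitter = 0,
                         seed = 1) {
  stopifnot(length(n_res) == 2, contact_gap <= 0.5, far_gap >= 1.5)
  if (length(contact_window)) {
    stopifnot(min(contact_window) >= 1, max(contact_window) <= n_res[2])
  }
  rng <- local_rng(seed)
  if (is.null(seqs)) {
    seqs <- list(
      sample_aa(rng, n_res[1]),
      sample_aa(rng, n_res[2])
    )
  }
  stopifnot(lengths(seqs) == n_res)
  r_c <- lookup_radius("C")
  spacing <- 3.8
  half <- spacing / 2
  # chain-B center distance realising a given surface gap against the two
  # nearest chain-A atoms (x-offset half)
  y_for_gap <- function(gap) {
    v <- (2 * r_c + gap)^2 - half^2
    if (v <= 0) {
      stop("infeasible fixture geometry for the requested gaps", call. = FALSE)
    }
    sqrt(v)
  }
  y_contact <- y_for_gap(contact_gap)
  y_far <- y_for_gap(far_gap)

  xa <- spacing * (seq_len(n_res[1]) - 1)
  xb <- spacing * (seq_len(n_res[2]) - 1) + half
  yb <- ifelse(seq_len(n_res[2]) %in% contact_window, y_contact, y_far)
  za <- round(jitter * (rng(n_res[1]) * 2 - 1), 3)
  zb <- round(jitter * (rng(n_res[2]) * 2 - 1), 3)

  atoms <- tibble(
    chain = rep(c("A", "B"), n_res),
    resno = c(seq_len(n_res[1]), seq_len(n_res[2])),
    icode = "",
    aa = c(seqs[[1]], seqs[[2]]),
    x = round(c(xa, xb), 3),
    y = round(c(rep(0, n_res[1]), yb), 3),
    z = c(za, zb)
  )
  atoms <- mutate(atoms,
    resid = unname(aa1to3[.data$aa]),
    res_id = paste(.data$chain, .data$resno, .data$icode, sep = ":"),
    elety = "CA", element = "C", radius = r_c
  )
  st <- new_ppi_structure(
    select(atoms, "chain", "resno", "icode", "resid", "aa", "res_id",
           "elety", "element", "x", "y", "z", "radius"),
    structure_id
  )
  truth <- tibble(
    structure_id = structure_id,
    res_id = atoms$res_id,
    interface = truth_by_brute_force(atoms, tolerance = 0.5)
  )
  list(structure = st, truth = truth, pdb = fixture_pdb_lines(st))
}

# generator-side ground truth: plain O(n^2) loop over its own coordinates
truth_by_brute_force <- function(atoms, tolerance) {
  n <- nrow(atoms)
  out <- rep(FALSE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (atoms$chain[i] == atoms$chain[j]) next
      d <- sqrt((atoms$x[i] - atoms$x[j])^2 + (atoms$y[i] - atoms$y[j])^2 +
                  (atoms$z[i] - atoms$z[j])^2)
      if (d - atoms$radius[i] - atoms$radius[j] <= tolerance) {
        out[i] <- TRUE
        break
      }
    }
  }
  out
}

# deterministic uniform(0,1) stream (linear congruential, 32-bit safe),
# independent of R's global RNG state
local_rng <- function(seed) {
  state <- (as.numeric(seed) %% 2147483647) + 1
  function(n) {
    out <- numeric(n)
    for (i in seq_len(n)) {
      state <<- (state * 48271) %% 2147483647
      out[i] <- state / 2147483647
    }
    out
  }
}

sample_aa <- function(rng, n) {
  letters20 <- unname(aa3to1[1:20])
  letters20[floor(rng(n) * 20) + 1]
}

# fixed-format PDB ATOM records for a CA-only structure
fixture_pdb_lines <- function(st) {
  a <- as_tibble(st)
  lines <- character(0)
  ser <- 0L
  for (ch in unique(a$chain)) {
    sub <- a[a$chain == ch, ]
    for (i in seq_len(nrow(sub))) {
      ser <- ser + 1L
      lines <- c(lines, sprintf(
        "ATOM  %5d  CA  %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        ser, sub$resid[i], ch, sub$resno[i],
        ifelse(sub$icode[i] == "", " ", sub$icode[i]),
        sub$x[i], sub$y[i], sub$z[i], 1.00, 0.00, sub$element[i]
      ))
    }
    lines <- c(lines, sprintf("TER   %5d      %3s %1s%4d",
                              ser + 1L, sub$resid[nrow(sub)], ch,
                              sub$resno[nrow(sub)]))
    ser <- ser + 1L
  }
  c(lines, "END")
}

#' Write a fixture structure as a PDB file
#'
#' @param structure a CA-trace `ppi_structure` (as produced by
#'   [make_complex()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fixture_pdb <- function(structure, path) {
  writeLines(fixture_pdb_lines(structure), path)
  invisible(path)
}

#' Generate a knowledge-base corpus with planted shared motifs
#'
#' Builds `n_complexes` synthetic complexes on a common backbone layout.
#' When `motif = TRUE` every complex carries the same sequence in a fixed
#' window around the contact region of both chains, so the structural
#' elements centered there are identical across complexes and cross-structure
#' fingerprint matches at distance 0 exist by construction (the flanking
#' sequence is sampled per complex). With `motif = FALSE` each complex is
#' sampled independently.
#'
#' @param n_complexes number of complexes (>= 1).
#' @param seed integer seed for all sampling.
#' @param n_res residues per chain (common layout).
#' @param contact_window contact positions, as in [make_complex()].
#' @param motif_span positions (both chains) whose sequence is shared
#'   across complexes; must cover `contact_window` plus enough margin that
#'   the motif centers' neighborhoods stay inside it.
#' @param motif logical; plant the shared motif?
#' @param contact_gap,far_gap,jitter forwarded to [make_complex()].
#' @return List of [make_complex()] results, structure ids `corpus01`, ...
#' @export
make_kb_corpus <- function(n_complexes = 10, seed = 42, n_res = c(16, 16),
                           contact_window = 7:10, motif_span = 4:13,
                           motif = TRUE, contact_gap = 0.3, far_gap = 2.0,
                           jitter = 0) {
  stopifnot(n_complexes >= 1)
  if (motif && length(contact_window)) {
    stopifnot(all(contact_window %in% motif_span),
              all((max(contact_window) + 1) <= max(motif_span)))
  }
  rng <- local_rng(seed)
  motif_seq <- list(sample_aa(rng, n_res[1]), sample_aa(rng, n_res[2]))
  out <- vector("list", n_complexes)
  for (s in seq_len(n_complexes)) {
    seqs <- list(sample_aa(rng, n_res[1]), sample_aa(rng, n_res[2]))
    if (motif) {
      keep <- intersect(motif_span, seq_len(n_res[1]))
      seqs[[1]][keep] <- motif_seq[[1]][keep]
      keep <- intersect(motif_span, seq_len(n_res[2]))
      seqs[[2]][keep] <- motif_seq[[2]][keep]
    }
    sid <- sprintf("corpus%02d", s)
    out[[s]] <- make_complex(
      structure_id = sid, n_res = n_res,
      contact_window = contact_window, contact_gap = contact_gap,
      far_gap = far_gap, seqs = seqs, jitter = jitter,
      seed = seed + 1000 + s
    )
  }
  out
}
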