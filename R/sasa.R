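# Evenly distributed unit sphere points (golden-spiral construction).
# Deterministic, so SASA is reproducible; orientation is fixed in the lab
# frame, which makes the quadrature exactly translation-invariant and
# rotation-invariant only up to the angular resolution ~ 1/sqrt(n).
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# Shrake-Rupley SASA for one atom set; returns per-atom areas in A^2
sasa_atoms <- function(xyz, radius, probe = 1.4, n_points = 960) {
  n <- nrow(xyz)
  pts <- fibonacci_sphere(n_points)
  area <- numeric(n)
  rr <- radius + probe
  for (i in seq_len(n)) {
    # neighbors whose expanded sphere can intersect atom i's test sphere
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
      (xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2 < (rr[i] + rr)^2 & d2 > 0)
    test <- sweep(pts * rr[i], 2, xyz[i, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(acc)) break
      dj <- (test[, 1] - xyz[j, 1])^2 + (test[, 2] - xyz[j, 2])^2 +
        (test[, 3] - xyz[j, 3])^2
      acc <- acc & dj >= rr[j]^2
    }
    area[i] <- sum(acc) / n_points * 4 * pi * rr[i]^2
  }
  area
}

#' Relative solvent accessibility per residue
#'
#' Computes solvent-accessible surface area with a Shrake-Rupley quadrature
#' and normalises each residue's area by its type's reference maximal ASA
#' (see [max_asa()]). By default each chain is treated in isolation, so
#' burial by a partner chain does not depress the value — interface labeling,
#' not RASA, is what looks at the complex.
#'
#' @param structure a `ppi_structure`.
#' @param probe probe radius in Angstrom (water, 1.4).
#' @param n_points sphere quadrature points per atom.
#' @param context `"chain"` (default, each chain isolated) or `"complex"`
#'   (all chains together).
#' @param max_asa_override optional named overrides for the reference table.
#' @param missing_ref what to do for a residue type with no reference ASA:
#'   `"skip"` gives `NA` RASA, `"fallback"` divides by the mean reference.
#' @return A tibble with one row per residue: `chain`, `resno`, `icode`,
#'   `aa`, `res_id`, `sasa` (A^2) and `rasa` (fraction, >= 0; can slightly
#'   exceed 1 for very exposed residues).
#' @export
compute_rasa <- function(structure, probe = 1.4, n_points = 960,
                         context = c("chain", "complex"),
                         max_asa_override = NULL,
                         missing_ref = c("skip", "fallback")) {
  context <- match.arg(context)
  missing_ref <- match.arg(missing_ref)
  a <- as_tibble(structure)
  groups <- if (context == "chain") split(seq_len(nrow(a)), a$chain) else
    list(seq_len(nrow(a)))
  a$sasa_atom <- NA_real_
  for (idx in groups) {
    a$sasa_atom[idx] <- sasa_atoms(cbind(a$x[idx], a$y[idx], a$z[idx]),
                                   a$radius[idx],
                                   probe = probe, n_points = n_points)
  }
  res <- a |>
    group_by(.data$chain, .data$resno, .data$icode) |>
    summarise(
      aa = .data$aa[1],
      res_id = .data$res_id[1],
      sasa = sum(.data$sasa_atom),
      .groups = "drop"
    ) |>
    arrange(match(.data$res_id, unique(a$res_id)))
  ref <- unname(max_asa(max_asa_override)[res$aa])
  if (missing_ref == "fallback") {
    ref[is.na(ref)] <- mean(max_asa(max_asa_override))
  }
  res$rasa <- pmax(res$sasa / ref, 0)
  res
}

#' Equal-frequency RASA bin edges
#'
#' Returns the 9 interior cut points at the empirical deciles of a RASA
#' distribution, defining 10 bins each holding approximately 10% of the
#' values. The edges are persisted in the knowledge base so queries are
#' binned identically to the records.
#'
#' @param rasa_values numeric vector of RASA values (>= 10 values, >= 10
#'   distinct).
#' @return Numeric vector of 9 strictly increasing edges.
#' @export
derive_bin_edges <- function(rasa_values) {
  v <- rasa_values[!is.na(rasa_values)]
  if (length(v) < 10 || length(unique(v)) < 10) {
    stop("degenerate RASA distribution: need at least 10 distinct values",
         call. = FALSE)
  }
  edges <- unname(quantile(v, probs = seq(0.1, 0.9, by = 0.1), type = 7))
  if (any(diff(edges) <= 0)) {
    stop("degenerate RASA distribution: deciles are not strictly increasing",
         call. = FALSE)
  }
  edges
}

#' Bin a RASA value against stored decile edges
#'
#' Bins are left-closed/right-open (a value equal to an edge falls in the
#' higher bin); values above the last edge map to bin 9.
#'
#' @param value numeric RASA value(s), >= 0.
#' @param edges 9 strictly increasing edges from [derive_bin_edges()].
#' @return Integer bin indices in 0..9.
#' @export
bin_rasa <- function(value, edges) {
  if (any(value < 0, na.rm = TRUE)) stop("RASA value must be >= 0", call. = FALSE)
  stopifnot(length(edges) == 9, all(diff(edges) > 0))
  findInterval(value, edges)
}
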