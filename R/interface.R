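#' Label interface residues of a complex
#'
#' A residue is an interface residue iff the van der Waals surface of at
#' least one of its atoms comes within `tolerance` Angstrom of the vdW
#' surface of any atom of a *different* chain, i.e. there exist atoms `a`,
#' `b` on different chains with `dist(a, b) - r(a) - r(b) <= tolerance`.
#'
#' The default implementation bins atoms into a spatial grid whose cell size
#' equals the largest possible contact distance, so only atoms in adjacent
#' cells are compared (subquadratic in practice); `method = "brute"` runs the
#' all-pairs check and is kept as a reference the grid must agree with.
#'
#' @param structure a `ppi_structure` with at least two chains (a
#'   single-chain input yields all-FALSE labels with a warning).
#' @param tolerance maximal surface-to-surface gap in Angstrom (default 0.5).
#' @param method `"grid"` or `"brute"`.
#' @return A tibble with one row per residue: `chain`, `resno`, `icode`,
#'   `aa`, `res_id`, `interface` (logical).
#' @export
label_interfaces <- function(structure, tolerance = 0.5,
                             method = c("grid", "brute")) {
  method <- match.arg(method)
  a <- as_tibble(structure)
  res <- residue_table(structure)
  if (length(unique(a$chain)) < 2) {
    warning("single-chain structure: all residues labeled non-interface",
            call. = FALSE)
    res$interface <- FALSE
    return(select(res, "chain", "resno", "icode", "aa", "res_id", "interface"))
  }
  contact_atom <- if (method == "brute") {
    contact_brute(a, tolerance)
  } else {
    contact_grid(a, tolerance)
  }
  hit <- unique(a$res_id[contact_atom])
  res$interface <- res$res_id %in% hit
  select(res, "chain", "resno", "icode", "aa", "res_id", "interface")
}

# all-pairs reference: logical per atom, any cross-chain surface gap <= tol
contact_brute <- function(a, tol) {
  n <- nrow(a)
  out <- rep(FALSE, n)
  xyz <- cbind(a$x, a$y, a$z)
  for (i in seq_len(n - 1)) {
    j <- (i + 1):n
    cross <- a$chain[j] != a$chain[i]
    if (!any(cross)) next
    jj <- j[cross]
    d <- sqrt((xyz[jj, 1] - xyz[i, 1])^2 + (xyz[jj, 2] - xyz[i, 2])^2 +
                (xyz[jj, 3] - xyz[i, 3])^2)
    hit <- d - a$radius[i] - a$radius[jj] <= tol
    if (any(hit)) {
      out[i] <- TRUE
      out[jj[hit]] <- TRUE
    }
  }
  out
}

# spatial-grid acceleration: cell size = max possible contact distance so
# contacting atoms always fall in the same or adjacent cells
contact_grid <- function(a, tol) {
  n <- nrow(a)
  cell <- 2 * max(a$radius) + tol
  ix <- floor(a$x / cell); iy <- floor(a$y / cell); iz <- floor(a$z / cell)
  key <- paste(ix, iy, iz, sep = ",")
  cells <- split(seq_len(n), key)
  out <- rep(FALSE, n)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  for (i in seq_len(n)) {
    nb_keys <- paste(ix[i] + offs$dx, iy[i] + offs$dy, iz[i] + offs$dz,
                     sep = ",")
    cand <- unlist(cells[nb_keys], use.names = FALSE)
    cand <- cand[a$chain[cand] != a$chain[i]]
    if (length(cand) == 0) next
    d <- sqrt((a$x[cand] - a$x[i])^2 + (a$y[cand] - a$y[i])^2 +
                (a$z[cand] - a$z[i])^2)
    if (any(d - a$radius[i] - a$radius[cand] <= tol)) out[i] <- TRUE
  }
  out
}
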