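#' Read a protein structure into an atom table
#'
#' Parses a PDB or mmCIF file and returns one row per atom, keeping protein
#' chains only. Non-protein polymer chains (DNA/RNA) and water/heteroatom-only
#' chains are dropped; for alternate locations the highest-occupancy altloc is
#' kept (first wins on ties); only the first model of multi-model files is
#' read. Residues whose name cannot be mapped to a one-letter code (after the
#' bundled nonstandard-residue map, e.g. MSE -> M) are excluded with a warning.
#'
#' @param path path to a structure file.
#' @param format `"pdb"`, `"cif"` or `"auto"` (by file extension).
#' @param structure_id identifier stored with the structure; defaults to the
#'   file name without extension.
#' @param vdw optional named vdW-radius overrides, see [vdw_radii()].
#' @return A tibble of class `ppi_structure` with columns `chain`, `resno`,
#'   `icode`, `resid`, `aa`, `res_id`, `elety`, `element`, `x`, `y`, `z`,
#'   `radius` and attribute `structure_id`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif"),
                           structure_id = NULL, vdw = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("structure file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)) "cif" else "pdb"
  }
  parsed <- tryCatch(
    if (format == "cif") {
      # read.cif emits advisory warnings (beta status, missing helix/sheet
      # records) that are not parse failures
      suppressWarnings(bio3d::read.cif(path, rm.alt = FALSE, verbose = FALSE))
    } else {
      bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
    },
    error = function(e) stop("failed to parse ", format, " file '", path,
                             "': ", conditionMessage(e), call. = FALSE)
  )
  if (is.null(structure_id)) {
    structure_id <- sub("\\.[^.]*$", "", basename(path))
  }
  as_ppi_structure(parsed$atom, structure_id = structure_id, vdw = vdw)
}

# build the canonical atom tibble from a bio3d-style atom data frame
as_ppi_structure <- function(atom, structure_id, vdw = NULL) {
  a <- as_tibble(atom)
  a$insert[is.na(a$insert) | a$insert == ""] <- ""
  a$alt[is.na(a$alt) | a$alt == ""] <- ""
  a$o[is.na(a$o)] <- 1
  if (is.null(a$elesy) || all(is.na(a$elesy) | a$elesy == "")) {
    # fall back to the first letter of the atom name
    a$elesy <- sub("^[0-9]*", "", a$elety)
    a$elesy <- substr(a$elesy, 1, 1)
  }

  # altloc: keep highest occupancy per (chain, residue, atom name), first on tie
  a <- a |>
    group_by(.data$chain, .data$resno, .data$insert, .data$elety) |>
    arrange(dplyr::desc(.data$o), .by_group = TRUE) |>
    dplyr::slice(1) |>
    ungroup()

  # classify chains: protein if amino-acid residues dominate
  cls <- a |>
    distinct(.data$chain, .data$resno, .data$insert, .data$resid) |>
    group_by(.data$chain) |>
    summarise(
      n_prot = sum(.data$resid %in% names(aa3to1)),
      n_nuc = sum(.data$resid %in% nucleic_resid)
    )
  keep_chains <- cls$chain[cls$n_prot > 0 & cls$n_prot >= cls$n_nuc]
  if (length(keep_chains) == 0) {
    stop("no protein chains in structure '", structure_id, "'", call. = FALSE)
  }
  a <- filter(a, .data$chain %in% keep_chains)

  unmapped <- setdiff(unique(a$resid), c(names(aa3to1), "HOH", nucleic_resid))
  if (length(unmapped) > 0) {
    warning("dropping unmappable residue types: ",
            paste(unmapped, collapse = ", "), call. = FALSE)
  }
  a <- filter(a, .data$resid %in% names(aa3to1))

  out <- tibble(
    chain = a$chain,
    resno = as.integer(a$resno),
    icode = a$insert,
    resid = a$resid,
    aa = unname(aa3to1[a$resid]),
    res_id = paste(a$chain, a$resno, a$insert, sep = ":"),
    elety = a$elety,
    element = toupper(a$elesy),
    x = a$x, y = a$y, z = a$z
  )
  out$radius <- lookup_radius(out$element, vdw)
  stopifnot(all(is.finite(out$x + out$y + out$z)), all(out$radius > 0))
  new_ppi_structure(out, structure_id)
}

new_ppi_structure <- function(tbl, structure_id) {
  structure(tbl,
    class = c("ppi_structure", class(tibble())),
    structure_id = structure_id
  )
}

#' @export
print.ppi_structure <- function(x, ...) {
  cat("# ppi_structure '", attr(x, "structure_id"), "': ",
      length(unique(x$chain)), " chain(s), ",
      nrow(distinct(as_tibble(x), .data$chain, .data$resno, .data$icode)),
      " residues, ", nrow(x), " atoms\n", sep = "")
  NextMethod()
}

#' Structure identifier
#' @param structure a `ppi_structure`.
#' @return Character scalar.
#' @export
structure_id <- function(structure) attr(structure, "structure_id")

#' Per-residue summary of an atom table
#'
#' @param structure a `ppi_structure` atom tibble.
#' @return A tibble with one row per residue in file order: `chain`, `resno`,
#'   `icode`, `aa`, `res_id`, alpha-carbon coordinates (`ca_x`, `ca_y`,
#'   `ca_z`, `NA` when the residue has no CA atom) and `n_atoms`.
#' @export
residue_table <- function(structure) {
  as_tibble(structure) |>
    group_by(.data$chain, .data$resno, .data$icode) |>
    summarise(
      aa = .data$aa[1],
      res_id = .data$res_id[1],
      ca_x = .data$x[match("CA", .data$elety)],
      ca_y = .data$y[match("CA", .data$elety)],
      ca_z = .data$z[match("CA", .data$elety)],
      n_atoms = dplyr::n(),
      .groups = "drop"
    ) |>
    arrange(match(.data$res_id, unique(structure$res_id)))
}

#' Apply knowledge-base eligibility filters to a structure
#'
#' Removes chains with fewer than `min_chain_len` residues; a structure with
#' fewer than two remaining chains is marked ineligible for knowledge-base
#' construction (query-side prediction does not apply the two-chain rule).
#' Rejection is a value, not an error: inspect it with [is_kb_eligible()].
#'
#' @param structure a `ppi_structure`.
#' @param min_chain_len minimum residues per chain (strict "less than" is
#'   removed; a 5-residue chain is kept at the default).
#' @return The filtered `ppi_structure` with attribute `kb_eligible`.
#' @export
filter_chains_for_kb <- function(structure, min_chain_len = 5) {
  sid <- structure_id(structure)
  sizes <- as_tibble(structure) |>
    distinct(.data$chain, .data$resno, .data$icode) |>
    dplyr::count(.data$chain)
  keep <- sizes$chain[sizes$n >= min_chain_len]
  out <- filter(as_tibble(structure), .data$chain %in% keep)
  out <- new_ppi_structure(out, sid)
  attr(out, "kb_eligible") <- length(keep) >= 2
  out
}

#' Is a filtered structure eligible for the knowledge base?
#' @param structure result of [filter_chains_for_kb()].
#' @return Logical scalar.
#' @export
is_kb_eligible <- function(structure) isTRUE(attr(structure, "kb_eligible"))
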