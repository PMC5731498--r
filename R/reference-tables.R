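#' Bundled van der Waals radii
#'
#' Element-to-radius lookup (Bondi-style values, in Angstrom) used for the
#' vdW-surface interface rule and for solvent-accessible surface areas.
#' Interface labels depend on these radii, so the table is bundled with the
#' package and can be overridden per call.
#'
#' @param override optional named numeric vector (names = element symbols,
#'   upper case) replacing or extending bundled values.
#' @return A named numeric vector of radii in Angstrom.
#' @export
#' @examples
#' vdw_radii()[["C"]]
vdw_radii <- function(override = NULL) {
  if (is.null(the$vdw)) {
    tab <- read.delim(system.file("extdata", "vdw_radii.tsv", package = "ppisite"))
    the$vdw <- setNames(tab$radius, tab$element)
  }
  out <- the$vdw
  if (!is.null(override)) out[toupper(names(override))] <- override
  out
}

#' Reference maximal accessible surface areas
#'
#' Theoretical per-residue maximal ASA values (Angstrom^2) used to normalise
#' solvent-accessible surface into relative solvent accessibility (RASA).
#'
#' @param override optional named numeric vector (names = one-letter codes).
#' @return Named numeric vector keyed by one-letter amino-acid code.
#' @export
max_asa <- function(override = NULL) {
  if (is.null(the$max_asa)) {
    tab <- read.delim(system.file("extdata", "max_asa.tsv", package = "ppisite"))
    the$max_asa <- setNames(tab$max_asa, tab$aa)
  }
  out <- the$max_asa
  if (!is.null(override)) out[names(override)] <- override
  out
}

# three-letter -> one-letter map; standard residues plus common nonstandard
# cases. Unmappable residues are dropped from graphs with a warning.
aa3to1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
  # nonstandard fallbacks
  MSE = "M", SEC = "C", PYL = "K", HYP = "P", SEP = "S",
  TPO = "T", PTR = "Y", CSO = "C", MLY = "K", KCX = "K"
)

# reverse map: one-letter -> standard three-letter residue name
aa1to3 <- setNames(names(aa3to1)[1:20], unname(aa3to1[1:20]))

# nucleic residue names used to recognise DNA/RNA chains
nucleic_resid <- c("DA", "DC", "DG", "DT", "DU", "A", "C", "G", "T", "U", "DI", "I")

# default fallback vdW radius for elements missing from the table
.default_radius <- 1.70

lookup_radius <- function(element, override = NULL) {
  tab <- vdw_radii(override)
  r <- unname(tab[toupper(element)])
  r[is.na(r)] <- .default_radius
  r
}
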