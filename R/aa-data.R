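# Amino-acid lookup tables shared across modules.

#' @keywords internal
.AA3 <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
  Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
  L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
  S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL"
)

.AA1 <- stats::setNames(names(.AA3), .AA3)

# Protonation variants map back to their parent one-letter code.
.AA1_EXT <- c(.AA1, ASH = "D", GLH = "E", HID = "H", HIE = "H", HIP = "H",
              LYN = "K", ARN = "R", CYX = "C", MSE = "M")

# Side chains expected to carry net charge at physiological pH.
.CHARGED_AA <- c("D", "E", "K", "R")

#' Convert between one- and three-letter amino acid codes
#'
#' `aa_three()` and `aa_one()` translate residue codes, accepting the
#' protonation-variant three-letter codes (ASH, GLH, HID/HIE/HIP, ...) that
#' appear in prepared structures.
#'
#' @param x character vector of codes.
#' @return character vector of translated codes; `NA` for unknown codes.
#' @examples
#' aa_three("E")
#' aa_one(c("GLU", "GLH"))
#' @export
aa_three <- function(x) unname(.AA3[toupper(x)])

#' @rdname aa_three
#' @export
aa_one <- function(x) unname(.AA1_EXT[toupper(x)])

#' Is a mutation charge-changing?
#'
#' A putative charge-changing mutation has exactly one end state among the
#' four side chains generally charged at physiological pH (ASP, GLU, LYS,
#' ARG).  The flag is symmetric under swapping the two end states.
#'
#' @param wt,mt one-letter codes of the two end states.
#' @return logical vector.
#' @export
is_charge_changing <- function(wt, mt) {
  (wt %in% .CHARGED_AA) != (mt %in% .CHARGED_AA)
}

#' Van der Waals radius table
#'
#' Bondi radii by element symbol, Angstrom.  The packaged table
#' (`inst/extdata/vdw_radii.tsv`) can be swapped for any two-column
#' (element, radius) TSV via the `path` argument; radii are a configurable
#' data asset because published interface SASA values depend on the
#' (often unstated) radius set used.
#'
#' @param path optional TSV override with columns `element`, `radius`.
#' @return named numeric vector, element symbol to radius in Angstrom.
#' @export
vdw_radii <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "vdw_radii.tsv", package = "fepscout",
                        mustWork = TRUE)
  }
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("element", "radius") %in% names(tab)),
            all(tab$radius > 0))
  stats::setNames(tab$radius, toupper(tab$element))
}

#' Reference maximum SASA per residue type
#'
#' Maximum solvent accessible surface area of residue X in a Gly-X-Gly
#' tripeptide, Angstrom^2, used to normalise residue SASA into fractional
#' SASA (fSASA).  The shipped defaults are heavy-atom values computed with
#' this package's own ideal-geometry extended tripeptides and its
#' deterministic Shrake-Rupley lattice, so that an isolated extended
#' residue normalises to fSASA ~ 1 by construction.  A published
#' theoretical table is shipped alongside
#' (`inst/extdata/max_sasa_gxg_theoretical.tsv`) and any two-column
#' (aa3, max_sasa) TSV can be supplied instead.
#'
#' @param path optional TSV override with columns `aa3`, `max_sasa`.
#' @return named numeric vector, three-letter code to area in Angstrom^2.
#' @export
reference_sasa <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "max_sasa_gxg.tsv", package = "fepscout",
                        mustWork = TRUE)
  }
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("aa3", "max_sasa") %in% names(tab)),
            all(tab$max_sasa > 0))
  out <- stats::setNames(tab$max_sasa, toupper(tab$aa3))
  # protonation variants share their parent residue's reference area
  extra <- c(ASH = "ASP", GLH = "GLU", HID = "HIS", HIE = "HIS", HIP = "HIS")
  for (v in names(extra)) if (!v %in% names(out) && extra[[v]] %in% names(out))
    out[[v]] <- out[[extra[[v]]]]
  out
}

# Element symbol from a PDB atom name (heavy atoms): strip digits/primes,
# take the leading letters; two-letter symbols only for the few that occur.
.element_from_name <- function(elety) {
  x <- toupper(gsub("[^A-Za-z]", "", elety))
  out <- substr(x, 1L, 1L)
  out[x %in% c("CL", "BR", "SE", "FE", "ZN", "MG", "NA", "MN")] <-
    x[x %in% c("CL", "BR", "SE", "FE", "ZN", "MG", "NA", "MN")]
  out
}
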