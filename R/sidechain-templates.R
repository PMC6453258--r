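# Ideal-geometry residue templates: side-chain internal coordinates,
# rotatable chi definitions and residue bond graphs.  Bond lengths and
# angles follow standard small-molecule/protein ideal values; geometry is
# analytic, never minimised.  These templates drive both the peptide
# fixture builder and mutant side-chain placement.

# One template row places one heavy atom from three previously placed atoms
# (p1, p2, p3): bond |p3-atom|, angle p2-p3-atom, dihedral p1-p2-p3-atom.
# chi = k > 0 means the dihedral is chi_k + offset; chi = 0 means fixed at
# offset.  CB is placed off the backbone with an improper-style dihedral
# chosen to give L-configuration.
.tmpl_row <- function(name, p1, p2, p3, bond, angle, chi, offset) {
  data.frame(name = name, p1 = p1, p2 = p2, p3 = p3, bond = bond,
             angle = angle, chi = chi, offset = offset,
             stringsAsFactors = FALSE)
}

.CB_ROW <- .tmpl_row("CB", "N", "C", "CA", 1.530, 110.5, 0L, -122.6)

.SIDECHAIN_TEMPLATES <- local({
  r <- .tmpl_row
  list(
    GLY = NULL,
    ALA = NULL, # CB only
    SER = r("OG", "N", "CA", "CB", 1.417, 110.8, 1L, 0),
    CYS = r("SG", "N", "CA", "CB", 1.808, 114.0, 1L, 0),
    VAL = rbind(r("CG1", "N", "CA", "CB", 1.527, 110.5, 1L, 0),
                r("CG2", "N", "CA", "CB", 1.527, 110.5, 1L, 122.3)),
    THR = rbind(r("OG1", "N", "CA", "CB", 1.433, 109.6, 1L, 0),
                r("CG2", "N", "CA", "CB", 1.521, 110.5, 1L, -122.3)),
    ILE = rbind(r("CG1", "N", "CA", "CB", 1.530, 110.4, 1L, 0),
                r("CG2", "N", "CA", "CB", 1.521, 110.5, 1L, -122.3),
                r("CD1", "CA", "CB", "CG1", 1.513, 113.8, 2L, 0)),
    LEU = rbind(r("CG", "N", "CA", "CB", 1.530, 116.3, 1L, 0),
                r("CD1", "CA", "CB", "CG", 1.521, 110.7, 2L, 0),
                r("CD2", "CA", "CB", "CG", 1.521, 110.7, 2L, 122.5)),
    ASP = rbind(r("CG", "N", "CA", "CB", 1.516, 112.6, 1L, 0),
                r("OD1", "CA", "CB", "CG", 1.249, 118.4, 2L, 0),
                r("OD2", "CA", "CB", "CG", 1.249, 118.4, 2L, 180)),
    ASN = rbind(r("CG", "N", "CA", "CB", 1.516, 112.6, 1L, 0),
                r("OD1", "CA", "CB", "CG", 1.231, 120.8, 2L, 0),
                r("ND2", "CA", "CB", "CG", 1.328, 116.4, 2L, 180)),
    GLU = rbind(r("CG", "N", "CA", "CB", 1.520, 114.1, 1L, 0),
                r("CD", "CA", "CB", "CG", 1.516, 112.6, 2L, 0),
                r("OE1", "CB", "CG", "CD", 1.249, 118.4, 3L, 0),
                r("OE2", "CB", "CG", "CD", 1.249, 118.4, 3L, 180)),
    GLN = rbind(r("CG", "N", "CA", "CB", 1.520, 114.1, 1L, 0),
                r("CD", "CA", "CB", "CG", 1.516, 112.6, 2L, 0),
                r("OE1", "CB", "CG", "CD", 1.231, 120.8, 3L, 0),
                r("NE2", "CB", "CG", "CD", 1.328, 116.4, 3L, 180)),
    MET = rbind(r("CG", "N", "CA", "CB", 1.520, 114.1, 1L, 0),
                r("SD", "CA", "CB", "CG", 1.803, 112.7, 2L, 0),
                r("CE", "CB", "CG", "SD", 1.791, 100.9, 3L, 0)),
    LYS = rbind(r("CG", "N", "CA", "CB", 1.520, 114.1, 1L, 0),
                r("CD", "CA", "CB", "CG", 1.520, 111.3, 2L, 0),
                r("CE", "CB", "CG", "CD", 1.508, 111.9, 3L, 0),
                r("NZ", "CG", "CD", "CE", 1.489, 111.7, 4L, 0)),
    ARG = rbind(r("CG", "N", "CA", "CB", 1.520, 114.1, 1L, 0),
                r("CD", "CA", "CB", "CG", 1.520, 111.3, 2L, 0),
                r("NE", "CB", "CG", "CD", 1.461, 112.0, 3L, 0),
                r("CZ", "CG", "CD", "NE", 1.329, 124.2, 4L, 0),
                r("NH1", "CD", "NE", "CZ", 1.326, 120.0, 0L, 0),
                r("NH2", "CD", "NE", "CZ", 1.326, 120.0, 0L, 180)),
    PHE = rbind(r("CG", "N", "CA", "CB", 1.502, 113.8, 1L, 0),
                r("CD1", "CA", "CB", "CG", 1.384, 120.8, 2L, 0),
                r("CD2", "CA", "CB", "CG", 1.384, 120.8, 2L, 180),
                r("CE1", "CB", "CG", "CD1", 1.382, 120.8, 0L, 180),
                r("CE2", "CB", "CG", "CD2", 1.382, 120.8, 0L, 180),
                r("CZ", "CG", "CD1", "CE1", 1.382, 120.0, 0L, 0)),
    TYR = rbind(r("CG", "N", "CA", "CB", 1.512, 113.8, 1L, 0),
                r("CD1", "CA", "CB", "CG", 1.389, 120.8, 2L, 0),
                r("CD2", "CA", "CB", "CG", 1.389, 120.8, 2L, 180),
                r("CE1", "CB", "CG", "CD1", 1.382, 121.2, 0L, 180),
                r("CE2", "CB", "CG", "CD2", 1.382, 121.2, 0L, 180),
                r("CZ", "CG", "CD1", "CE1", 1.378, 119.6, 0L, 0),
                r("OH", "CD1", "CE1", "CZ", 1.376, 119.9, 0L, 180)),
    TRP = rbind(r("CG", "N", "CA", "CB", 1.498, 113.6, 1L, 0),
                r("CD1", "CA", "CB", "CG", 1.365, 126.9, 2L, 0),
                r("CD2", "CA", "CB", "CG", 1.433, 126.8, 2L, 180),
                r("NE1", "CB", "CG", "CD1", 1.374, 110.2, 0L, 180),
                r("CE2", "CB", "CG", "CD2", 1.409, 107.2, 0L, 180),
                r("CE3", "CB", "CG", "CD2", 1.398, 133.9, 0L, 0),
                r("CZ2", "CG", "CD2", "CE2", 1.394, 122.4, 0L, 180),
                r("CZ3", "CG", "CD2", "CE3", 1.382, 118.6, 0L, 180),
                r("CH2", "CD2", "CE2", "CZ2", 1.368, 117.5, 0L, 0)),
    HIS = rbind(r("CG", "N", "CA", "CB", 1.497, 113.7, 1L, 0),
                r("ND1", "CA", "CB", "CG", 1.378, 122.8, 2L, 0),
                r("CD2", "CA", "CB", "CG", 1.354, 129.1, 2L, 180),
                r("CE1", "CB", "CG", "ND1", 1.321, 109.2, 0L, 180),
                r("NE2", "CB", "CG", "CD2", 1.374, 107.2, 0L, 180)),
    PRO = rbind(r("CG", "N", "CA", "CB", 1.492, 104.5, 0L, 30),
                r("CD", "CA", "CB", "CG", 1.503, 106.1, 0L, -35))
  )
})

# Torsion class of each rotatable chi: "sp3" (staggered threefold), "sp2"
# (planar carboxylate/amide twofold) or "ar" (aromatic ring twist).
.CHI_TYPES <- list(
  SER = "sp3", CYS = "sp3", VAL = "sp3", THR = "sp3",
  ILE = c("sp3", "sp3"), LEU = c("sp3", "sp3"),
  ASP = c("sp3", "sp2"), ASN = c("sp3", "sp2"),
  GLU = c("sp3", "sp3", "sp2"), GLN = c("sp3", "sp3", "sp2"),
  MET = c("sp3", "sp3", "sp3"), LYS = rep("sp3", 4), ARG = rep("sp3", 4),
  PHE = c("sp3", "ar"), TYR = c("sp3", "ar"), TRP = c("sp3", "ar"),
  HIS = c("sp3", "ar"),
  ALA = character(), GLY = character(), PRO = character()
)

# Ring-closure bonds missing from the placement tree, needed for the
# residue bond graph.
.RING_CLOSURES <- list(
  PHE = list(c("CE2", "CZ")),
  TYR = list(c("CE2", "CZ")),
  HIS = list(c("CE1", "NE2")),
  TRP = list(c("NE1", "CE2"), c("CZ3", "CH2")),
  PRO = list(c("CD", "N"))
)

.CHI_GRIDS <- c(sp3 = list(c(-60, 60, 180)),
                sp2 = list(c(-90, 0, 90)),
                ar = list(c(-90, -30, 30, 90)))

#' Number of rotatable chi angles of a residue type
#' @param aa3 three-letter code.
#' @return integer.
#' @export
n_chi <- function(aa3) length(.CHI_TYPES[[toupper(aa3)]])

#' Default rotamer library
#'
#' A compact backbone-independent rotamer library built from canonical
#' staggered (sp3: -60/60/180 degrees) and planar (sp2 / aromatic) chi
#' wells, fully enumerated per residue type.  Each entry is a matrix with
#' one rotamer per row and one chi angle (degrees, in (-180, 180]) per
#' column.  Any list of the same shape can be supplied wherever a
#' `lib` argument is accepted, e.g. a richer curated library.
#'
#' @return named list of chi matrices, one per residue type with >= 0 chis.
#' @export
default_rotamer_library <- function() {
  out <- lapply(names(.CHI_TYPES), function(aa) {
    types <- .CHI_TYPES[[aa]]
    if (length(types) == 0) {
      matrix(numeric(0), nrow = 1, ncol = 0)
    } else {
      as.matrix(expand.grid(.CHI_GRIDS[types], KEEP.OUT.ATTRS = FALSE))
    }
  })
  names(out) <- names(.CHI_TYPES)
  for (i in seq_along(out)) dimnames(out[[i]]) <- NULL
  out
}

# Chi values that maximise extension (used by fixture peptides).
.extended_chi <- function(aa3) {
  types <- .CHI_TYPES[[toupper(aa3)]]
  vapply(types, function(t) switch(t, sp3 = 180, sp2 = 0, ar = 90), 0)
}

#' Build side-chain heavy atoms on a backbone
#'
#' Places the side chain of `aa3` (CB onward) from its ideal-geometry
#' template at the given chi angles, on the backbone frame defined by the
#' N, CA and C coordinates.
#'
#' @param aa3 three-letter residue code (standard residue).
#' @param chi numeric vector of chi angles, degrees; length `n_chi(aa3)`.
#' @param backbone list with numeric length-3 elements `N`, `CA`, `C`.
#' @return data.frame with columns `name`, `element`, `x`, `y`, `z`;
#'   zero rows for glycine.
#' @export
build_sidechain <- function(aa3, chi = .extended_chi(aa3), backbone) {
  aa3 <- toupper(aa3)
  if (!aa3 %in% names(.SIDECHAIN_TEMPLATES))
    stop("no side-chain template for residue type ", aa3)
  if (aa3 == "GLY")
    return(data.frame(name = character(), element = character(),
                      x = numeric(), y = numeric(), z = numeric()))
  if (length(chi) != n_chi(aa3))
    stop(aa3, " needs ", n_chi(aa3), " chi angles, got ", length(chi))
  pos <- list(N = backbone$N, CA = backbone$CA, C = backbone$C)
  rows <- rbind(.CB_ROW, .SIDECHAIN_TEMPLATES[[aa3]])
  for (i in seq_len(nrow(rows))) {
    rw <- rows[i, ]
    dihed <- if (rw$chi > 0) chi[rw$chi] + rw$offset else rw$offset
    pos[[rw$name]] <- place_atom(pos[[rw$p1]], pos[[rw$p2]], pos[[rw$p3]],
                                 rw$bond, rw$angle, dihed)
  }
  nm <- rows$name
  xyz <- do.call(rbind, pos[nm])
  data.frame(name = nm, element = .element_from_name(nm),
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             stringsAsFactors = FALSE)
}

# Bond list (pairs of atom names) of a full residue incl. backbone.
.residue_bonds <- function(aa3) {
  aa3 <- toupper(aa3)
  bonds <- list(c("N", "CA"), c("CA", "C"), c("C", "O"))
  if (aa3 != "GLY") bonds <- c(bonds, list(c("CA", "CB")))
  tmpl <- .SIDECHAIN_TEMPLATES[[aa3]]
  if (!is.null(tmpl))
    bonds <- c(bonds, lapply(seq_len(nrow(tmpl)),
                             function(i) c(tmpl$p3[i], tmpl$name[i])))
  c(bonds, .RING_CLOSURES[[aa3]])
}

# All-pairs bond-graph distances within one residue (matrix of hops,
# Inf if disconnected); names = atom names.
.residue_graph_distances <- function(aa3) {
  bonds <- .residue_bonds(aa3)
  atoms <- unique(unlist(bonds))
  n <- length(atoms)
  d <- matrix(Inf, n, n, dimnames = list(atoms, atoms))
  diag(d) <- 0
  for (b in bonds) d[b[1], b[2]] <- d[b[2], b[1]] <- 1
  for (k in seq_len(n)) # Floyd-Warshall; residues are tiny
    d <- pmin(d, outer(d[, k], d[k, ], `+`))
  d
}
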