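# Structure model: PDB input/output, the fep_structure container, and
# mutation specification parsing/validation.

#' Construct a structure object from an atom table
#'
#' Low-level constructor used by [read_pdb()] and the fixture generators.
#' The atom table holds one row per heavy atom with author (PDB) numbering;
#' no renumbering is ever performed.  Chains are partitioned into the two
#' binding sides of the complex; for monomeric structures (e.g. reference
#' tripeptides) `side_b` may be empty.
#'
#' @param atoms data.frame with columns `chain`, `resno`, `insert`,
#'   `resid` (three-letter code), `elety` (atom name), `element`, `x`,
#'   `y`, `z`, and optionally `o` (occupancy) and `hetero`.
#' @param id structure identifier (PDB ID or fixture name).
#' @param side_a,side_b character vectors of chain IDs defining the two
#'   binding sides.  Together they must cover all polymer chains.
#' @param radius_table named vector of van der Waals radii by element, see
#'   [vdw_radii()].
#' @return an object of class `fep_structure`.
#' @export
new_structure <- function(atoms, id = "structure",
                          side_a = NULL, side_b = NULL,
                          radius_table = vdw_radii()) {
  need <- c("chain", "resno", "insert", "resid", "elety", "element",
            "x", "y", "z")
  if (!all(need %in% names(atoms)))
    stop("atom table lacks columns: ",
         paste(setdiff(need, names(atoms)), collapse = ", "))
  if (is.null(atoms$o)) atoms$o <- 1
  if (is.null(atoms$hetero)) atoms$hetero <- FALSE
  atoms$insert[is.na(atoms$insert)] <- ""
  if (!all(is.finite(c(atoms$x, atoms$y, atoms$z))))
    stop("non-finite atom coordinates")
  poly_chains <- unique(atoms$chain[!atoms$hetero])
  if (length(poly_chains) == 0) stop("structure has zero polymer atoms")
  if (is.null(side_a) && is.null(side_b)) {
    side_a <- poly_chains
    side_b <- character()
  }
  side_a <- as.character(side_a); side_b <- as.character(side_b)
  if (length(intersect(side_a, side_b)) > 0)
    stop("binding sides must be disjoint")
  missing_ch <- setdiff(c(side_a, side_b), poly_chains)
  if (length(missing_ch) > 0)
    stop("chain(s) absent from structure: ",
         paste(missing_ch, collapse = ", "))
  uncovered <- setdiff(poly_chains, c(side_a, side_b))
  if (length(uncovered) > 0)
    stop("chain partition must cover all polymer chains; uncovered: ",
         paste(uncovered, collapse = ", "))
  unknown <- setdiff(unique(atoms$element), names(radius_table))
  if (length(unknown) > 0) {
    warning("unknown element(s) ", paste(unknown, collapse = ", "),
            "; using default radius 1.7 A")
  }
  atoms$radius <- unname(radius_table[atoms$element])
  atoms$radius[is.na(atoms$radius)] <- 1.7
  rownames(atoms) <- NULL
  structure(list(id = id, atoms = atoms, side_a = side_a, side_b = side_b),
            class = "fep_structure")
}

#' @export
print.fep_structure <- function(x, ...) {
  a <- x$atoms[!x$atoms$hetero, ]
  cat("<fep_structure> ", x$id, "\n", sep = "")
  cat("  ", length(unique(a$chain)), " chain(s), ",
      nrow(unique(a[, c("chain", "resno", "insert")])), " residues, ",
      nrow(x$atoms), " atoms\n", sep = "")
  cat("  side A: {", paste(x$side_a, collapse = ","), "}  side B: {",
      paste(x$side_b, collapse = ","), "}\n", sep = "")
  invisible(x)
}

#' Residue keys
#'
#' A residue key is the string `chain:resno` or `chain:resno<icode>`
#' identifying one residue by author numbering.
#'
#' @param chain,resno,insert vectors of chain ID, residue number, insertion
#'   code ("" for none).
#' @return character vector of keys.
#' @export
residue_key <- function(chain, resno, insert = "") {
  insert[is.na(insert)] <- ""
  paste0(chain, ":", resno, insert)
}

# Keys for every atom row of a structure.
.atom_keys <- function(s) {
  residue_key(s$atoms$chain, s$atoms$resno, s$atoms$insert)
}

# Rows of s$atoms belonging to one residue key.
.residue_rows <- function(s, key) which(.atom_keys(s) == key)

#' List residues of a structure
#'
#' @param s an `fep_structure`.
#' @return data.frame with one row per residue: `key`, `chain`, `resno`,
#'   `insert`, `resid`, `n_atoms`, in file order.
#' @export
structure_residues <- function(s) {
  a <- s$atoms[!s$atoms$hetero, ]
  key <- residue_key(a$chain, a$resno, a$insert)
  first <- !duplicated(key)
  data.frame(key = key[first], chain = a$chain[first],
             resno = a$resno[first], insert = a$insert[first],
             resid = a$resid[first],
             n_atoms = as.vector(table(key)[key[first]]),
             stringsAsFactors = FALSE)
}

.WATER_RESID <- c("HOH", "WAT", "DOD", "H2O")

#' Read a protein complex from a PDB file
#'
#' Parses ATOM/HETATM records (via \pkg{bio3d}), resolves alternate
#' locations by keeping the highest-occupancy conformer (ties broken by
#' altloc letter order), drops hydrogens and all heteroatoms other than
#' water, optionally drops waters, and assigns van der Waals radii.
#'
#' @param path PDB file.
#' @param side_a,side_b chain-ID sets defining the two binding sides; by
#'   default all chains form side A (monomer context).
#' @param drop_waters drop crystallographic waters (default `TRUE`).
#' @param radius_table see [vdw_radii()].
#' @param id structure identifier; defaults to the file base name.
#' @return an `fep_structure`.
#' @export
read_pdb <- function(path, side_a = NULL, side_b = NULL, drop_waters = TRUE,
                     radius_table = vdw_radii(), id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$chain[is.na(at$chain)] <- " "
  is_water <- at$resid %in% .WATER_RESID
  keep <- at$type == "ATOM" | is_water
  if (drop_waters) keep <- keep & !is_water
  at <- at[keep, , drop = FALSE]
  if (nrow(at) == 0) stop("zero polymer atoms in ", path)
  # element: trust the element column where present, else derive from name
  elem <- toupper(at$elesy)
  bad <- is.na(elem) | elem == ""
  elem[bad] <- .element_from_name(at$elety[bad])
  drop_h <- elem == "H" | elem == "D"
  at <- at[!drop_h, , drop = FALSE]
  elem <- elem[!drop_h]
  # altloc policy: per (residue, atom name) keep highest occupancy,
  # ties by altloc letter order
  occ <- at$o
  occ[is.na(occ)] <- 1
  pos <- seq_len(nrow(at))
  ord <- order(at$chain, at$resno, at$insert, at$elety, -occ, at$alt)
  at <- at[ord, , drop = FALSE]
  elem <- elem[ord]; occ <- occ[ord]; pos <- pos[ord]
  dup <- duplicated(at[, c("chain", "resno", "insert", "resid", "elety")])
  at <- at[!dup, , drop = FALSE]
  elem <- elem[!dup]; occ <- occ[!dup]; pos <- pos[!dup]
  # restore file order of the surviving atoms
  ord2 <- order(pos)
  at <- at[ord2, , drop = FALSE]
  elem <- elem[ord2]; occ <- occ[ord2]
  atoms <- data.frame(chain = at$chain, resno = at$resno, insert = at$insert,
                      resid = at$resid, elety = at$elety, element = elem,
                      x = at$x, y = at$y, z = at$z, o = occ,
                      hetero = at$type == "HETATM",
                      stringsAsFactors = FALSE)
  if (is.null(id)) id <- sub("\\.(pdb|ent)$", "", basename(path))
  new_structure(atoms, id = id, side_a = side_a, side_b = side_b,
                radius_table = radius_table)
}

#' Write a structure to a PDB file
#'
#' @param s an `fep_structure`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(s, path) {
  a <- s$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   type = ifelse(a$hetero, "HETATM", "ATOM"),
                   resno = a$resno, resid = a$resid, chain = a$chain,
                   insert = a$insert, elety = a$elety, o = a$o,
                   b = rep(0, nrow(a)), elesy = a$element)
  invisible(path)
}

#' Select one binding side of a complex
#'
#' @param s an `fep_structure`.
#' @param side `"A"` or `"B"`.
#' @return an `fep_structure` restricted to that side's chains (monomer
#'   partition).
#' @export
structure_side <- function(s, side = c("A", "B")) {
  side <- match.arg(side)
  chains <- if (side == "A") s$side_a else s$side_b
  if (length(chains) == 0) stop("side ", side, " is empty")
  atoms <- s$atoms[s$atoms$chain %in% chains, , drop = FALSE]
  structure(list(id = paste0(s$id, ":side", side), atoms = atoms,
                 side_a = chains, side_b = character()),
            class = "fep_structure")
}

#' Parse a compact mutation specification
#'
#' The dialect is `CHAIN:RESNUM[ICODE]:WT>MT`, e.g. `"A:73:E>Q"` or
#' `"H:100A:S>K"` (insertion code appended to the residue number).
#'
#' @param text character vector of specifications.
#' @return for a single input, a `mutation_spec`; otherwise a list of them.
#' @export
parse_mutation <- function(text) {
  out <- lapply(text, function(tx) {
    m <- regmatches(tx, regexec(
      "^([A-Za-z0-9]):([0-9]+)([A-Za-z]?):([A-Za-z])>([A-Za-z])$", tx))[[1]]
    if (length(m) == 0)
      stop("malformed mutation '", tx,
           "'; expected CHAIN:RESNUM[ICODE]:WT>MT, e.g. A:73:E>Q")
    wt <- toupper(m[5]); mt <- toupper(m[6])
    for (aa in c(wt, mt)) if (!aa %in% names(.AA3))
      stop("unknown amino acid letter '", aa, "' in '", tx, "'")
    if (wt == mt)
      stop("degenerate mutation '", tx, "': wild-type equals mutant")
    structure(list(chain = m[2], resno = as.integer(m[3]),
                   insert = toupper(m[4]), wt = wt, mt = mt,
                   key = residue_key(m[2], as.integer(m[3]), toupper(m[4])),
                   charge_changing = is_charge_changing(wt, mt),
                   validated = FALSE),
              class = "mutation_spec")
  })
  if (length(out) == 1) out[[1]] else out
}

#' @export
print.mutation_spec <- function(x, ...) {
  cat("<mutation> ", x$key, " ", x$wt, ">", x$mt,
      if (isTRUE(x$charge_changing)) "  [charge-changing]" else "",
      if (isTRUE(x$validated)) "  (validated)" else "", "\n", sep = "")
  invisible(x)
}

#' @export
format.mutation_spec <- function(x, ...) {
  paste0(x$chain, ":", x$resno, x$insert, ":", x$wt, ">", x$mt)
}

#' Read a mutation list file
#'
#' Accepts either a TSV with columns `chain`, `resnum`, `icode` (optional),
#' `wt`, `mt`, or a plain list with one compact `CHAIN:RESNUM:WT>MT`
#' specification per line.
#'
#' @param path input file.
#' @return list of `mutation_spec`.
#' @export
read_mutations <- function(path) {
  first <- readLines(path, n = 1)
  if (grepl("\t", first) || grepl("^chain\\b", first)) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (is.null(tab$icode)) tab$icode <- ""
    tab$icode[is.na(tab$icode)] <- ""
    txt <- paste0(tab$chain, ":", tab$resnum, tab$icode, ":",
                  toupper(tab$wt), ">", toupper(tab$mt))
  } else {
    txt <- trimws(readLines(path))
    txt <- txt[nzchar(txt) & !startsWith(txt, "#")]
  }
  out <- parse_mutation(txt)
  if (inherits(out, "mutation_spec")) list(out) else out
}

#' Validate a mutation against a structure
#'
#' Confirms that the residue exists in the structure and that its residue
#' type matches the stated wild-type letter (protonation-variant codes such
#' as ASH/GLH match their parent).  Returns the spec annotated as validated,
#' with its charge-changing flag.
#'
#' @param s an `fep_structure`.
#' @param m a `mutation_spec`.
#' @return the validated `mutation_spec`.
#' @export
validate_mutation <- function(s, m) {
  stopifnot(inherits(s, "fep_structure"), inherits(m, "mutation_spec"))
  res <- structure_residues(s)
  hit <- res[res$key == m$key, , drop = FALSE]
  if (nrow(hit) == 0) {
    in_chain <- res[res$chain == m$chain, , drop = FALSE]
    stop("residue ", m$key, " absent from structure ", s$id,
         if (nrow(in_chain) == 0)
           paste0(" (no chain '", m$chain, "')")
         else
           paste0(" (chain ", m$chain, " spans ", min(in_chain$resno),
                  "-", max(in_chain$resno), ")"))
  }
  actual <- aa_one(hit$resid[1])
  if (is.na(actual) || actual != m$wt)
    stop("wild-type mismatch at ", m$key, ": structure has ",
         hit$resid[1], " (", actual, "), specification says ", m$wt)
  m$validated <- TRUE
  m
}
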