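# Synthetic fixture generators: ideal-geometry peptides, toy two-chain
# complexes with controlled burial and salt-bridge geometry, and synthetic
# prediction/experiment tables.  Everything is analytic (no minimisation,
# no downloads); stochastic generators take a mandatory seed.

# Ideal backbone parameters (Angstrom / degrees).
.BB <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
            ang_n_ca_c = 111.0, ang_ca_c_n = 117.2, ang_c_n_ca = 121.7,
            ang_ca_c_o = 120.1, omega = 180)

#' Build an ideal-geometry peptide
#'
#' Places backbone heavy atoms (N, CA, C, O) with ideal bond lengths and
#' angles at the given backbone dihedrals, and side chains from the
#' residue templates at maximally extended chi angles (overridable per
#' residue).
#'
#' @param seq1 character vector of one-letter residue codes (or a single
#'   string).
#' @param phi,psi backbone dihedrals, degrees; recycled over residues.
#'   Defaults are an extended (beta) conformation.
#' @param chain chain identifier.
#' @param start_resno author number of the first residue.
#' @param chi optional list (length = residues) of chi vectors; `NULL`
#'   entries use the extended default.
#' @return atom data.frame suitable for [new_structure()].
#' @export
build_peptide <- function(seq1, phi = -135, psi = 135, chain = "A",
                          start_resno = 1L, chi = NULL) {
  if (length(seq1) == 1 && nchar(seq1) > 1)
    seq1 <- strsplit(seq1, "")[[1]]
  seq1 <- toupper(seq1)
  nres <- length(seq1)
  stopifnot(nres >= 1, all(seq1 %in% names(.AA3)))
  phi <- rep_len(phi, nres); psi <- rep_len(psi, nres)
  rows <- vector("list", nres)
  # first residue backbone in the xy-plane
  N <- c(0, 0, 0)
  CA <- c(.BB$n_ca, 0, 0)
  th <- deg2rad(.BB$ang_n_ca_c)
  C <- CA + .BB$ca_c * c(-cos(th), sin(th), 0)
  for (i in seq_len(nres)) {
    aa3 <- .AA3[[seq1[i]]]
    O <- place_atom(N, CA, C, .BB$c_o, .BB$ang_ca_c_o, psi[i] + 180)
    bb <- data.frame(name = c("N", "CA", "C", "O"),
                     element = c("N", "C", "C", "O"),
                     x = c(N[1], CA[1], C[1], O[1]),
                     y = c(N[2], CA[2], C[2], O[2]),
                     z = c(N[3], CA[3], C[3], O[3]),
                     stringsAsFactors = FALSE)
    chi_i <- if (!is.null(chi) && !is.null(chi[[i]])) chi[[i]]
             else .extended_chi(aa3)
    sc <- build_sidechain(aa3, chi_i, list(N = N, CA = CA, C = C))
    res <- rbind(bb, sc)
    rows[[i]] <- data.frame(chain = chain, resno = start_resno + i - 1L,
                            insert = "", resid = aa3, elety = res$name,
                            element = res$element, x = res$x, y = res$y,
                            z = res$z, o = 1, hetero = FALSE,
                            stringsAsFactors = FALSE)
    if (i < nres) {
      N2 <- place_atom(N, CA, C, .BB$c_n, .BB$ang_ca_c_n, psi[i])
      CA2 <- place_atom(CA, C, N2, .BB$n_ca, .BB$ang_c_n_ca, .BB$omega)
      C2 <- place_atom(C, N2, CA2, .BB$ca_c, .BB$ang_n_ca_c, phi[i + 1])
      N <- N2; CA <- CA2; C <- C2
    }
  }
  do.call(rbind, rows)
}

#' Ideal extended Gly-X-Gly tripeptide
#'
#' The defining fixture of the fSASA normalisation: residue X in an
#' isolated extended tripeptide should have fractional SASA close to 1
#' under the shipped reference table.  The backbone is extended; the
#' middle side chain is set to its maximum-exposure rotamer (the
#' conformation the reference maxima are defined on), selected
#' deterministically over the default rotamer library.
#'
#' @param aa one-letter code of the central residue X.
#' @param conformation currently only `"extended"`.
#' @param path optional PDB file to write.
#' @param radius_table see [vdw_radii()].
#' @return an `fep_structure` with three residues in one chain; the middle
#'   residue has key `"A:2"`.
#' @export
make_tripeptide <- function(aa, conformation = "extended", path = NULL,
                            radius_table = vdw_radii()) {
  conformation <- match.arg(conformation)
  aa <- toupper(aa)
  aa3 <- .AA3[[aa]]
  lib <- default_rotamer_library()[[aa3]]
  cand <- lapply(seq_len(nrow(lib)), function(i) lib[i, ])
  if (n_chi(aa3) > 0) cand <- c(cand, list(.extended_chi(aa3)))
  best <- NULL; best_area <- -Inf
  cfg <- sasa_config(reference_table = c(stats::setNames(1, aa3)))
  for (ch in cand) {
    atoms <- build_peptide(c("G", aa, "G"), chi = list(NULL, ch, NULL))
    s <- new_structure(atoms, id = paste0("GxG_", aa),
                       radius_table = radius_table)
    area <- sum(atom_sasa(s, cfg)[s$atoms$resno == 2])
    if (area > best_area + 1e-9) { best_area <- area; best <- s }
  }
  if (!is.null(path)) write_pdb(best, path)
  best
}

#' Toy two-chain complex fixtures with known ground truth
#'
#' Constructs small synthetic complexes for which burial, side-chain
#' placeability and salt-bridge geometry are known analytically:
#'
#' * `"helix_pair"`: two alpha-helical chains (A, B) packed side by side;
#'   the middle residue of chain A faces the interface and the outward
#'   residues stay solvent exposed.
#' * `"cavity"`: a target residue on a short chain A enclosed by a chain B
#'   cage of CA-only glycine shells, so the target is buried (fSASA below
#'   any practical threshold) and no mutant rotamer of a large residue can
#'   be placed without steric overlap.
#' * `"bridge_pair"`: an ASP (chain A) facing an ARG (chain B) with the
#'   two carboxylate-guanidinium N-O distances placed analytically at
#'   `separation` Angstrom (a bidentate motif when within cutoff).
#'
#' @param kind fixture kind, see above.
#' @param separation N-O contact distance for `"bridge_pair"`, Angstrom.
#' @param cage_radii radii (Angstrom) of the concentric `"cavity"`
#'   enclosure shells around the target side chain; point density is set
#'   so no rotamer of a larger residue can thread between cage atoms.
#' @param target one-letter code of the `"cavity"`/`"helix_pair"` target
#'   residue.
#' @param radius_table see [vdw_radii()].
#' @return an `fep_structure`; attribute `"ground_truth"` records the
#'   constructed facts (target key, expected burial, bridge atom pairs).
#' @export
make_complex_fixture <- function(kind = c("helix_pair", "cavity",
                                          "bridge_pair"),
                                 separation = 2.8,
                                 cage_radii = c(2.4, 3.3, 4.2),
                                 target = "A",
                                 radius_table = vdw_radii()) {
  kind <- match.arg(kind)
  if (kind == "helix_pair") {
    a <- build_peptide(rep(c("L", "S", target, "S", "L"), 2)[1:7],
                       phi = -57, psi = -47, chain = "A")
    b <- build_peptide(rep("L", 7), phi = -57, psi = -47, chain = "B")
    # pack chain B alongside A, offset perpendicular to the helix axis
    bxyz <- as.matrix(b[, c("x", "y", "z")])
    axis <- stats::prcomp(as.matrix(a[a$elety == "CA", c("x", "y", "z")]))
    offset <- axis$rotation[, 3] * 9.5
    b[, c("x", "y", "z")] <- sweep(bxyz, 2, offset, `+`)
    s <- new_structure(rbind(a, b), id = "helix_pair",
                       side_a = "A", side_b = "B",
                       radius_table = radius_table)
    gt <- list(target_key = "A:3", interface_keys = "A:3",
               exposed_keys = c("A:1", "A:7"))
  } else if (kind == "cavity") {
    a <- build_peptide(c("G", "G", target, "G", "G"), chain = "A")
    ca <- unlist(a[a$resno == 3 & a$elety == "CB", c("x", "y", "z")])
    if (length(ca) == 0)
      ca <- unlist(a[a$resno == 3 & a$elety == "CA", c("x", "y", "z")])
    pts <- do.call(rbind, lapply(cage_radii, function(r)
      sweep(golden_spiral(ceiling(22 * r^2)) * r, 2, ca, `+`)))
    # drop cage atoms unphysically close to the chain A peptide itself
    axyz <- as.matrix(a[, c("x", "y", "z")])
    keep <- apply(pts, 1, function(p)
      min(sqrt(colSums((t(axyz) - p)^2))) > 1.7)
    pts <- pts[keep, , drop = FALSE]
    cage <- data.frame(chain = "B", resno = seq_len(nrow(pts)), insert = "",
                       resid = "GLY", elety = "CA", element = "C",
                       x = pts[, 1], y = pts[, 2], z = pts[, 3],
                       o = 1, hetero = FALSE, stringsAsFactors = FALSE)
    s <- new_structure(rbind(a, cage), id = "cavity",
                       side_a = "A", side_b = "B",
                       radius_table = radius_table)
    gt <- list(target_key = "A:3", buried = TRUE,
               exposed_keys = c("A:1", "A:5"))
  } else { # bridge_pair
    asp <- build_peptide(c("G", "D", "G"), chain = "A")
    arg <- build_peptide(c("G", "R", "G"), chain = "B")
    get <- function(df, resno, name)
      unlist(df[df$resno == resno & df$elety == name, c("x", "y", "z")])
    od1 <- get(asp, 2, "OD1"); od2 <- get(asp, 2, "OD2")
    cg <- get(asp, 2, "CG")
    nh1 <- get(arg, 2, "NH1"); nh2 <- get(arg, 2, "NH2")
    cz <- get(arg, 2, "CZ")
    # face the guanidinium fork head-on at the carboxylate fork:
    # NH1 opposite OD1 and NH2 opposite OD2 along the outward in-plane
    # carboxylate bisector dir_a, at exactly `separation`
    mid_o <- (od1 + od2) / 2
    dir_a <- .vunit(mid_o - cg)
    fork_a <- .vunit(od1 - od2)
    w_o <- .vnorm(od1 - od2)
    w_n <- .vnorm(nh1 - nh2)
    half_gap <- abs(w_o - w_n) / 2
    if (separation <= half_gap)
      stop("separation too small for head-on fork alignment")
    h <- sqrt(separation^2 - half_gap^2)
    mid_t <- mid_o + dir_a * h
    d_cz <- .vnorm(cz - (nh1 + nh2) / 2)
    tgt <- rbind(mid_t + fork_a * w_n / 2,
                 mid_t - fork_a * w_n / 2,
                 mid_t + dir_a * d_cz)
    src <- rbind(nh1, nh2, cz)
    # exact rigid superposition (Kabsch) of the isoceles triangles
    sc <- colMeans(src); tc <- colMeans(tgt)
    H <- t(sweep(src, 2, sc)) %*% sweep(tgt, 2, tc)
    sv <- svd(H)
    D <- diag(c(1, 1, sign(det(sv$v %*% t(sv$u)))))
    R <- sv$v %*% D %*% t(sv$u)
    bxyz <- as.matrix(arg[, c("x", "y", "z")])
    arg[, c("x", "y", "z")] <- sweep(sweep(bxyz, 2, sc) %*% t(R), 2, tc,
                                     `+`)
    s <- new_structure(rbind(asp, arg), id = "bridge_pair",
                       side_a = "A", side_b = "B",
                       radius_table = radius_table)
    gt <- list(acid_key = "A:2", base_key = "B:2",
               separation = separation)
  }
  attr(s, "ground_truth") <- gt
  s
}

#' Synthetic prediction/experiment table
#'
#' Emulates a per-case benchmark spreadsheet: experimental binding
#' free-energy changes are drawn from a mixture spanning the dynamic range
#' of interface mutation panels (roughly -2.5 to +7.7 kcal/mol: 75
#' percent near-neutral Gaussian, 25 percent strongly destabilising
#' uniform tail), and predictions are generated so that the best-fit line
#' of experiment on prediction has the planted slope:
#' `ddg_pred = ddg_exp / slope + noise / slope`.  With `slope = 1` this is
#' an unbiased predictor with Gaussian error `noise_sd` (FEP-like); small
#' slopes emulate overscaled implicit-solvent scores.
#'
#' @param n number of records.
#' @param slope planted experiment-on-prediction slope.
#' @param noise_sd Gaussian noise on the experiment scale, kcal/mol.
#' @param frac_buried fraction of records flagged buried.
#' @param seed mandatory RNG seed.
#' @param system system label for all records.
#' @param method method label.
#' @return data.frame with columns `system`, `mutation`, `ddg_exp`,
#'   `ddg_pred`, `buried`, `method`.
#' @export
make_stats_table <- function(n, slope = 1, noise_sd = 1, frac_buried = 0.3,
                             seed, system = "synthetic", method = "FEP") {
  stopifnot(n >= 1, slope > 0, noise_sd >= 0)
  if (missing(seed)) stop("seed is mandatory for stochastic fixtures")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  tail <- stats::runif(n) < 0.25
  ddg_exp <- ifelse(tail, stats::runif(n, 2, 7.66),
                    stats::rnorm(n, 0.4, 1.2))
  ddg_exp <- pmin(pmax(ddg_exp, -2.55), 7.66)
  ddg_pred <- ddg_exp / slope + stats::rnorm(n, 0, noise_sd) / slope
  buried <- seq_len(n) %in% sample.int(n, round(frac_buried * n))
  data.frame(system = system,
             mutation = sprintf("A:%d:%s>%s", seq_len(n),
                                sample(c("D", "E", "K", "R"), n, TRUE),
                                sample(c("A", "S", "N", "Q", "T"), n, TRUE)),
             ddg_exp = ddg_exp, ddg_pred = ddg_pred, buried = buried,
             method = method, stringsAsFactors = FALSE)
}

# save/restore global RNG state so generators are side-effect free
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
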