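# Side-chain placeability: rotamer-based placement of a mutant side chain
# on the wild-type backbone, strain energy relative to the optimised free
# rotamer, and the strain-increase suitability filter.
#
# The energy model is a deliberately small vacuum model: Lennard-Jones
# 12-6 between heavy atoms plus periodic chi torsion terms.  It is meant
# to detect gross steric infeasibility, not to score binding; the filter
# threshold is configurable for recalibration.

# LJ well depths (kcal/mol) and diameters (Angstrom) by element; geometric
# combining rules.
.LJ_EPS <- c(C = 0.066, N = 0.170, O = 0.210, S = 0.250)
.LJ_SIG <- c(C = 3.50, N = 3.25, O = 2.96, S = 3.55)

.lj_param <- function(element, table, default) {
  out <- unname(table[element])
  out[is.na(out)] <- default
  out
}

#' Strain filter configuration
#'
#' @param threshold maximum tolerated strain increase of the mutant over
#'   the wild type, kcal/mol (default 5).
#' @param neighbor_radius side chains with any atom within this distance
#'   (Angstrom) of the wild-type side chain are repacked jointly with the
#'   mutant.
#' @param hard_overlap heavy-atom distance (Angstrom) below which a
#'   placement counts as a hard steric overlap and is rejected outright.
#' @param env_cutoff neighbour-list cutoff for environment LJ terms,
#'   Angstrom.
#' @param combo_budget maximum number of rotamer combinations searched
#'   exhaustively; beyond it a deterministic greedy cycling search is used.
#' @param torsion_v torsion barrier heights, kcal/mol, per chi class.
#' @return a `strain_config` list.
#' @export
strain_config <- function(threshold = 5, neighbor_radius = 5,
                          hard_overlap = 1.0, env_cutoff = 8,
                          combo_budget = 1e5,
                          torsion_v = c(sp3 = 0.6, sp2 = 2.0, ar = 2.0)) {
  stopifnot(threshold > 0, neighbor_radius > 0, hard_overlap > 0,
            env_cutoff > hard_overlap,
            all(c("sp3", "sp2", "ar") %in% names(torsion_v)))
  structure(list(threshold = threshold, neighbor_radius = neighbor_radius,
                 hard_overlap = hard_overlap, env_cutoff = env_cutoff,
                 combo_budget = combo_budget, torsion_v = torsion_v),
            class = "strain_config")
}

# pairwise LJ energy between two atom sets (coords matrices + element
# vectors); `scale` optionally weights each pair (same length as pairs in
# row-major order) -- used for intra-residue 1-4 scaling.
.lj_pair_energy <- function(xyz1, el1, xyz2, el2, scale = NULL) {
  if (nrow(xyz1) == 0 || nrow(xyz2) == 0) return(0)
  d2 <- outer(rowSums(xyz1^2), rowSums(xyz2^2), `+`) -
    2 * xyz1 %*% t(xyz2)
  d2[d2 < 1e-12] <- 1e-12
  eps <- sqrt(outer(.lj_param(el1, .LJ_EPS, 0.066),
                    .lj_param(el2, .LJ_EPS, 0.066)))
  sig2 <- outer(.lj_param(el1, .LJ_SIG, 3.5),
                .lj_param(el2, .LJ_SIG, 3.5))  # sigma_i * sigma_j
  s6 <- (sig2 / d2)^3
  e <- 4 * eps * (s6^2 - s6)
  if (!is.null(scale)) e <- e * scale
  sum(e)
}

# torsion energy of one residue type at chi (degrees)
.torsion_energy <- function(aa3, chi, cfg) {
  types <- .CHI_TYPES[[aa3]]
  if (length(types) == 0) return(0)
  v <- cfg$torsion_v[types]
  x <- deg2rad(chi)
  per <- ifelse(types == "sp3",
                0.5 * v * (1 + cos(3 * x)),
                ifelse(types == "ar",
                       0.5 * v * (1 - cos(2 * (x - pi / 2))),
                       0.5 * v * (1 - cos(2 * x))))
  sum(per)
}

# canonical backbone frame used for conformer-intrinsic energies
.IDEAL_BB <- list(N = c(0, 0, 0), CA = c(1.458, 0, 0),
                  C = c(1.458 + 1.525 * cos(pi - deg2rad(111)),
                        1.525 * sin(pi - deg2rad(111)), 0))

#' Internal (intra-side-chain) energy of a conformer
#'
#' Vacuum LJ 12-6 over side-chain atom pairs separated by three or more
#' bonds (1-4 pairs scaled by 0.5) plus the chi torsion terms.  Depends
#' only on the residue type and chi angles, not on the backbone it is
#' built on.
#'
#' @param aa3 three-letter residue code.
#' @param chi chi angles, degrees.
#' @param cfg a [strain_config()].
#' @return energy in kcal/mol.
#' @export
sidechain_internal_energy <- function(aa3, chi, cfg = strain_config()) {
  aa3 <- toupper(aa3)
  sc <- build_sidechain(aa3, chi, .IDEAL_BB)
  e <- .torsion_energy(aa3, chi, cfg)
  if (nrow(sc) >= 2) {
    gd <- .residue_graph_distances(aa3)
    xyz <- as.matrix(sc[, c("x", "y", "z")])
    for (i in seq_len(nrow(sc) - 1)) {
      for (j in seq((i + 1), nrow(sc))) {
        d <- gd[sc$name[i], sc$name[j]]
        if (d < 3) next
        w <- if (d == 3) 0.5 else 1
        e <- e + w * .lj_pair_energy(xyz[i, , drop = FALSE], sc$element[i],
                                     xyz[j, , drop = FALSE], sc$element[j])
      }
    }
  }
  e
}

.strain_cache <- new.env(parent = emptyenv())

# internal energies of every rotamer of a type (cached on library content)
.rotamer_energies <- function(aa3, lib, cfg) {
  chis <- lib[[aa3]]
  if (is.null(chis)) stop("residue type ", aa3, " absent from rotamer library")
  key <- paste(aa3, paste(signif(c(chis, unlist(cfg$torsion_v)), 7),
                          collapse = ","), sep = "|")
  hit <- .strain_cache[[key]]
  if (!is.null(hit)) return(hit)
  e <- vapply(seq_len(nrow(chis)), function(i)
    sidechain_internal_energy(aa3, chis[i, ], cfg), 0)
  .strain_cache[[key]] <- e
  e
}

#' Minimum internal energy over the rotamer library
#'
#' The reference energy of the "optimised free rotamer": the minimum
#' internal energy of a residue type over all library rotamers, in vacuum
#' with ideal geometry.  Strain of any placed conformation is measured
#' relative to this minimum and is therefore non-negative by construction.
#'
#' @param aa3 three-letter residue code.
#' @param lib rotamer library, see [default_rotamer_library()].
#' @param cfg a [strain_config()].
#' @return minimum energy, kcal/mol.
#' @export
optimize_free_rotamer <- function(aa3, lib = default_rotamer_library(),
                                  cfg = strain_config()) {
  min(.rotamer_energies(toupper(aa3), lib, cfg))
}

# ---- placement ------------------------------------------------------------

.BB_NAMES <- c("N", "CA", "C", "O", "OXT")

# backbone frame of a residue in a structure
.backbone_of <- function(s, key) {
  rows <- .residue_rows(s, key)
  a <- s$atoms[rows, ]
  out <- list()
  for (nm in c("N", "CA", "C")) {
    i <- which(a$elety == nm)
    if (length(i) == 0) return(NULL)
    out[[nm]] <- c(a$x[i[1]], a$y[i[1]], a$z[i[1]])
  }
  out
}

# candidate conformations of one repacked residue: coords, elements,
# internal energy, env energy, validity
.residue_candidates <- function(s, key, aa3, lib, cfg, env_xyz, env_el,
                                env_key, env_elety) {
  bb <- .backbone_of(s, key)
  if (is.null(bb)) stop("incomplete backbone for residue ", key)
  chis <- lib[[aa3]]
  n_rot <- nrow(chis)
  e_int <- .rotamer_energies(aa3, lib, cfg)
  gd <- if (aa3 != "GLY") .residue_graph_distances(aa3) else NULL
  own <- env_key == key
  cands <- vector("list", n_rot)
  for (r in seq_len(n_rot)) {
    sc <- build_sidechain(aa3, chis[r, ], bb)
    xyz <- as.matrix(sc[, c("x", "y", "z")])
    valid <- TRUE
    e_env <- 0
    if (nrow(sc) > 0 && nrow(env_xyz) > 0) {
      # neighbour prefilter around the side chain
      ctr <- colMeans(xyz)
      reach <- max(sqrt(colSums((t(xyz) - ctr)^2))) + cfg$env_cutoff
      near <- which(colSums((t(env_xyz) - ctr)^2) < reach^2)
      for (i in seq_len(nrow(sc))) {
        if (length(near) == 0) break
        d2 <- colSums((t(env_xyz[near, , drop = FALSE]) - xyz[i, ])^2)
        w <- rep(1, length(near))
        if (!is.null(gd)) {
          ow <- own[near]
          if (any(ow)) {
            gdist <- gd[sc$name[i], env_elety[near][ow]]
            gdist[is.na(gdist)] <- Inf
            wow <- ifelse(gdist < 3, 0, ifelse(gdist == 3, 0.5, 1))
            w[ow] <- wow
          }
        }
        act <- d2 < cfg$env_cutoff^2 & w > 0
        if (any(d2[act] < cfg$hard_overlap^2)) { valid <- FALSE; break }
        if (any(act)) {
          e_env <- e_env + .lj_pair_energy(
            xyz[i, , drop = FALSE], sc$element[i],
            env_xyz[near[act], , drop = FALSE], env_el[near[act]]) *
            1 # scale folded below
          # apply 1-4 scaling by recomputing scaled subset cheaply
          sc14 <- act & w == 0.5
          if (any(sc14)) {
            e_env <- e_env - 0.5 * .lj_pair_energy(
              xyz[i, , drop = FALSE], sc$element[i],
              env_xyz[near[sc14], , drop = FALSE], env_el[near[sc14]])
          }
        }
      }
    }
    cands[[r]] <- list(chi = chis[r, ], xyz = xyz, element = sc$element,
                       e_int = e_int[r], e_env = e_env, valid = valid)
  }
  cands
}

# pairwise energy between two candidate conformations (different residues)
.cand_pair_energy <- function(c1, c2, cfg) {
  if (nrow(c1$xyz) == 0 || nrow(c2$xyz) == 0) return(0)
  dmin2 <- min(outer(rowSums(c1$xyz^2), rowSums(c2$xyz^2), `+`) -
                 2 * c1$xyz %*% t(c2$xyz))
  if (dmin2 < cfg$hard_overlap^2) return(Inf)
  .lj_pair_energy(c1$xyz, c1$element, c2$xyz, c2$element)
}

# joint rotamer search over repacked residues; returns selected candidate
# index per residue, or NULL if no overlap-free combination exists
.rotamer_search <- function(cand_sets, cfg) {
  k <- length(cand_sets)
  valid_idx <- lapply(cand_sets, function(cs)
    which(vapply(cs, `[[`, TRUE, "valid")))
  if (any(vapply(valid_idx, length, 0L) == 0)) return(NULL)
  self_e <- lapply(seq_len(k), function(i)
    vapply(cand_sets[[i]][valid_idx[[i]]],
           function(c) c$e_int + c$e_env, 0))
  # pairwise energy tables between residues
  pair_e <- list()
  if (k > 1) {
    for (i in seq_len(k - 1)) for (j in seq((i + 1), k)) {
      m <- matrix(0, length(valid_idx[[i]]), length(valid_idx[[j]]))
      for (a in seq_along(valid_idx[[i]]))
        for (b in seq_along(valid_idx[[j]]))
          m[a, b] <- .cand_pair_energy(
            cand_sets[[i]][[valid_idx[[i]][a]]],
            cand_sets[[j]][[valid_idx[[j]][b]]], cfg)
      pair_e[[paste(i, j)]] <- m
    }
  }
  n_combo <- prod(vapply(valid_idx, length, 0L))
  total_of <- function(sel) { # sel: index into valid_idx lists
    e <- sum(vapply(seq_len(k), function(i) self_e[[i]][sel[i]], 0))
    if (k > 1)
      for (i in seq_len(k - 1)) for (j in seq((i + 1), k))
        e <- e + pair_e[[paste(i, j)]][sel[i], sel[j]]
    e
  }
  if (n_combo <= cfg$combo_budget) {
    grid <- as.matrix(expand.grid(lapply(valid_idx, seq_along),
                                  KEEP.OUT.ATTRS = FALSE))
    tot <- vapply(seq_len(nrow(grid)), function(r) total_of(grid[r, ]), 0)
    if (!any(is.finite(tot))) return(NULL)
    best <- which.min(tot)
    sel <- grid[best, ]
  } else {
    # greedy one-at-a-time cycling from per-residue minima, deterministic
    sel <- vapply(self_e, which.min, 0L)
    for (sweep in 1:20) {
      changed <- FALSE
      for (i in seq_len(k)) {
        e_i <- vapply(seq_along(valid_idx[[i]]), function(a) {
          s2 <- sel; s2[i] <- a; total_of(s2)
        }, 0)
        a_best <- which.min(e_i)
        if (a_best != sel[i] && is.finite(e_i[a_best])) {
          sel[i] <- a_best; changed <- TRUE
        }
      }
      if (!changed) break
    }
    if (!is.finite(total_of(sel))) return(NULL)
  }
  list(idx = vapply(seq_len(k), function(i) valid_idx[[i]][sel[i]], 0L),
       energy = total_of(sel))
}

# repack the target residue (as type `aa3`) together with its neighbours;
# returns strain of the target and the selected chi
.repack <- function(s, m_key, aa3, neighbor_keys, lib, cfg) {
  repack_keys <- c(m_key, neighbor_keys)
  res <- structure_residues(s)
  types <- c(aa3, res$resid[match(neighbor_keys, res$key)])
  types <- vapply(types, function(t) {
    t1 <- aa_one(t)
    if (is.na(t1)) t else .AA3[[t1]] # normalise ASH/GLH etc. to parent
  }, "")
  akeys <- .atom_keys(s)
  sc_of_repacked <- akeys %in% repack_keys &
    !(s$atoms$elety %in% .BB_NAMES) & !s$atoms$hetero
  env <- s$atoms[!sc_of_repacked, , drop = FALSE]
  env_xyz <- as.matrix(env[, c("x", "y", "z")])
  cand_sets <- lapply(seq_along(repack_keys), function(i)
    .residue_candidates(s, repack_keys[i], types[i], lib, cfg,
                        env_xyz, env$element,
                        residue_key(env$chain, env$resno, env$insert),
                        env$elety))
  sol <- .rotamer_search(cand_sets, cfg)
  if (is.null(sol))
    return(list(valid = FALSE, strain = Inf, chi = NULL))
  tgt <- cand_sets[[1]][[sol$idx[1]]]
  free_min <- optimize_free_rotamer(types[1], lib, cfg)
  list(valid = TRUE, strain = tgt$e_int - free_min, chi = tgt$chi,
       energy = sol$energy)
}

#' Place a mutant side chain and evaluate its strain
#'
#' Jointly repacks the mutated residue (as the mutant type) and every
#' neighbouring side chain within `neighbor_radius` of the wild-type side
#' chain, over the rotamer library, minimising internal plus environment
#' Lennard-Jones energy with the backbone fixed.  Strain is the internal
#' energy of the selected conformation above the optimised free rotamer of
#' the same type; the same repacking applied to the wild-type residue
#' gives the baseline, and the mutation is placeable when the strain
#' increase does not exceed the threshold.
#'
#' Proline and histidine mutants are refused: proline's backbone is
#' non-standard, and histidine's protonation state cannot be assigned
#' reliably without crystallographic evidence.
#'
#' @param s an `fep_structure`.
#' @param m a validated `mutation_spec` (see [validate_mutation()]).
#' @param lib rotamer library.
#' @param cfg a [strain_config()].
#' @return a `placement_result` list: `mutation`, `strain_wt`,
#'   `strain_mt`, `delta_strain` (kcal/mol, `Inf` when no overlap-free
#'   rotamer exists), `placeable`, `chi_mt`, `n_repacked`, `reason`.
#' @export
place_mutant <- function(s, m, lib = default_rotamer_library(),
                         cfg = strain_config()) {
  stopifnot(inherits(s, "fep_structure"), inherits(m, "mutation_spec"))
  if (!isTRUE(m$validated))
    stop("mutation must be validated against the structure first")
  if (m$mt %in% c("P", "H"))
    stop("mutations to ", .AA3[[m$mt]], " are excluded from triage")
  # neighbour set from the wild-type side chain
  akeys <- .atom_keys(s)
  rows <- which(akeys == m$key & !(s$atoms$elety %in% .BB_NAMES))
  ref_xyz <- if (length(rows) > 0)
    as.matrix(s$atoms[rows, c("x", "y", "z")])
  else { # glycine wild type: measure from CA
    ca <- which(akeys == m$key & s$atoms$elety == "CA")
    as.matrix(s$atoms[ca, c("x", "y", "z"), drop = FALSE])
  }
  res <- structure_residues(s)
  neighbor_keys <- character()
  for (i in seq_len(nrow(res))) {
    key <- res$key[i]
    if (key == m$key) next
    t1 <- aa_one(res$resid[i])
    if (is.na(t1) || n_chi(.AA3[[t1]]) == 0) next
    rws <- which(akeys == key & !(s$atoms$elety %in% .BB_NAMES) &
                   !s$atoms$hetero)
    if (length(rws) == 0) next
    if (is.null(.backbone_of(s, key))) next
    xyz <- as.matrix(s$atoms[rws, c("x", "y", "z"), drop = FALSE])
    dmin2 <- min(outer(rowSums(xyz^2), rowSums(ref_xyz^2), `+`) -
                   2 * xyz %*% t(ref_xyz))
    if (dmin2 < cfg$neighbor_radius^2) neighbor_keys <- c(neighbor_keys, key)
  }
  wt <- .repack(s, m$key, .AA3[[m$wt]], neighbor_keys, lib, cfg)
  mt <- .repack(s, m$key, .AA3[[m$mt]], neighbor_keys, lib, cfg)
  strain_wt <- if (wt$valid) wt$strain else 0
  strain_mt <- mt$strain
  delta <- if (mt$valid) strain_mt - strain_wt else Inf
  placeable <- is.finite(delta) && delta <= cfg$threshold
  reason <- if (!mt$valid)
    "no rotamer free of hard steric overlap"
  else if (!placeable)
    sprintf("strain increase %.2f kcal/mol exceeds threshold %.2f",
            delta, cfg$threshold)
  else ""
  structure(list(mutation = format(m), key = m$key,
                 strain_wt = strain_wt, strain_mt = strain_mt,
                 delta_strain = delta, placeable = placeable,
                 chi_mt = if (mt$valid) mt$chi else NULL,
                 n_repacked = 1L + length(neighbor_keys),
                 reason = reason),
            class = "placement_result")
}

#' @export
print.placement_result <- function(x, ...) {
  cat("<placement> ", x$mutation,
      sprintf("  strain wt=%.2f mt=%.2f delta=%.2f  %s\n",
              x$strain_wt, x$strain_mt, x$delta_strain,
              if (x$placeable) "placeable" else paste0("REJECTED (",
                                                       x$reason, ")")))
  invisible(x)
}

#' Partition placements by the suitability filter
#'
#' @param results list of `placement_result`.
#' @return list with elements `kept` and `rejected` (each a list);
#'   rejected entries carry their `reason` string.
#' @export
filter_placeable <- function(results) {
  if (inherits(results, "placement_result")) results <- list(results)
  flag <- vapply(results, function(r) isTRUE(r$placeable), TRUE)
  list(kept = results[flag], rejected = results[!flag])
}
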