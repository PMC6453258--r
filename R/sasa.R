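# Solvent accessible surface area: deterministic Shrake-Rupley on a
# golden-spiral lattice, fractional SASA against tripeptide reference
# maxima, and the buried/exposed classification.

#' Deterministic unit-sphere point lattice
#'
#' Golden-spiral (Fibonacci) lattice of `n` near-uniform points on the
#' unit sphere.  No RNG is involved, so SASA results are exactly
#' reproducible for a given configuration.
#'
#' @param n number of points (>= 1).
#' @return `n` x 3 matrix of unit vectors.
#' @export
golden_spiral <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' SASA configuration
#'
#' @param probe_radius solvent probe radius, Angstrom (water: 1.4).
#' @param n_points lattice points per atom; >= 92, default 960.
#' @param reference_table residue reference maxima, see [reference_sasa()].
#' @param threshold_fsasa burial threshold on fractional SASA; residues
#'   with fSASA strictly below it are classified buried.
#' @param orientation optional 3x3 rotation applied to the lattice; used
#'   to express the lattice in a rotated frame so that SASA of a rigidly
#'   rotated system can be compared exactly.
#' @return a `sasa_config` list.
#' @export
sasa_config <- function(probe_radius = 1.4, n_points = 960,
                        reference_table = reference_sasa(),
                        threshold_fsasa = 0.10, orientation = NULL) {
  stopifnot(probe_radius > 0, n_points >= 92,
            all(reference_table > 0),
            threshold_fsasa > 0, threshold_fsasa < 1)
  if (!is.null(orientation))
    stopifnot(is.matrix(orientation), dim(orientation) == c(3, 3))
  structure(list(probe_radius = probe_radius, n_points = as.integer(n_points),
                 reference_table = reference_table,
                 threshold_fsasa = threshold_fsasa,
                 orientation = orientation),
            class = "sasa_config")
}

#' Per-atom solvent accessible surface area
#'
#' Shrake-Rupley: each atom's sphere is inflated by the probe radius and
#' sampled on the deterministic lattice; the accessible area is the
#' unoccluded point fraction times the inflated sphere area.
#'
#' @param s an `fep_structure` (radii assigned).
#' @param cfg a [sasa_config()].
#' @return numeric vector, one area (Angstrom^2) per atom row of
#'   `s$atoms`.
#' @export
atom_sasa <- function(s, cfg = sasa_config()) {
  stopifnot(inherits(s, "fep_structure"))
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")])
  r <- s$atoms$radius + cfg$probe_radius
  n <- nrow(xyz)
  pts <- golden_spiral(cfg$n_points)
  if (!is.null(cfg$orientation)) pts <- pts %*% t(cfg$orientation)
  # coincident atoms occlude each other (warn once)
  d2 <- as.matrix(stats::dist(xyz))^2
  if (n > 1 && any(d2[upper.tri(d2)] < 1e-12))
    warning("atoms with identical coordinates; treated as mutually occluding")
  out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (r[i] + r)^2 & seq_len(n) != i)
    sph <- pts * r[i]
    sph <- sweep(sph, 2, xyz[i, ], `+`)
    acc <- rep(TRUE, cfg$n_points)
    for (j in nb) {
      if (!any(acc)) break
      dj <- (sph[, 1] - xyz[j, 1])^2 + (sph[, 2] - xyz[j, 2])^2 +
        (sph[, 3] - xyz[j, 3])^2
      # a lattice point exactly on an occluder surface counts as occluded
      # (so coincident atoms occlude each other symmetrically)
      acc <- acc & (dj >= r[j]^2 + 1e-9)
    }
    out[i] <- sum(acc) / cfg$n_points * 4 * pi * r[i]^2
  }
  out
}

#' Fractional SASA and burial of residues
#'
#' `fsasa_residues()` computes, for each requested residue, its summed
#' heavy-atom SASA in the chosen context and normalises by the reference
#' maximum SASA of its residue type in a Gly-X-Gly tripeptide.
#' `residue_fsasa()` is the single-residue convenience wrapper.
#'
#' The default context is the whole bound complex ("the fraction
#' experienced by the residue in the interface"); `context = "side"`
#' computes it on the residue's isolated binding side instead.
#'
#' @param s an `fep_structure`.
#' @param keys residue key(s), see [residue_key()].
#' @param cfg a [sasa_config()].
#' @param context `"complex"` or `"side"`.
#' @return data.frame (class `burial_result`) with columns `key`, `resid`,
#'   `sasa`, `fsasa`, `buried`.
#' @export
fsasa_residues <- function(s, keys = structure_residues(s)$key,
                           cfg = sasa_config(),
                           context = c("complex", "side")) {
  context <- match.arg(context)
  res <- structure_residues(s)
  missing_k <- setdiff(keys, res$key)
  if (length(missing_k) > 0)
    stop("residue(s) not in structure: ", paste(missing_k, collapse = ", "))
  if (context == "complex") {
    ctx <- list(structure = s)
    areas <- atom_sasa(s, cfg)
    akeys <- .atom_keys(s)
    per_atom <- list(default = list(areas = areas, akeys = akeys))
    side_of <- function(key) "default"
  } else {
    per_atom <- list()
    chains <- sub(":.*", "", keys)
    side_of <- function(key) {
      ch <- sub(":.*", "", key)
      if (ch %in% s$side_a) "A"
      else if (ch %in% s$side_b) "B"
      else stop("chain ", ch, " not assigned to a binding side")
    }
    for (sd in unique(vapply(keys, side_of, ""))) {
      ss <- structure_side(s, sd)
      per_atom[[sd]] <- list(areas = atom_sasa(ss, cfg),
                             akeys = .atom_keys(ss))
    }
  }
  out <- lapply(keys, function(key) {
    aa3 <- res$resid[res$key == key]
    ref <- cfg$reference_table[toupper(aa3)]
    if (is.na(ref))
      stop("residue type ", aa3, " absent from the reference-area table; ",
           "extend the table passed to sasa_config()")
    pa <- per_atom[[side_of(key)]]
    sasa <- sum(pa$areas[pa$akeys == key])
    fs <- sasa / ref
    data.frame(key = key, resid = aa3, sasa = sasa, fsasa = fs,
               buried = fs < cfg$threshold_fsasa, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  class(out) <- c("burial_result", class(out))
  out
}

#' @rdname fsasa_residues
#' @param key single residue key.
#' @export
residue_fsasa <- function(s, key, cfg = sasa_config(),
                          context = c("complex", "side")) {
  fsasa_residues(s, key, cfg, context)
}

#' Partition residues into buried and exposed sets
#'
#' Buried means fractional SASA strictly below the configured threshold;
#' a residue exactly at the threshold is exposed (the exposed class is
#' fSASA >= threshold).
#'
#' @param results a `burial_result` data.frame from [fsasa_residues()].
#' @param cfg a [sasa_config()]; its threshold re-derives the flags.
#' @return list with `burial_result` elements `buried` and `exposed`.
#' @export
classify_burial <- function(results, cfg = sasa_config()) {
  buried <- results$fsasa < cfg$threshold_fsasa
  list(buried = results[buried, , drop = FALSE],
       exposed = results[!buried, , drop = FALSE])
}

#' Recompute the reference maximum-SASA table
#'
#' Rebuilds the shipped Gly-X-Gly reference maxima from first principles:
#' for each residue type, the maximum middle-residue heavy-atom SASA over
#' the default rotamer library in an ideal extended tripeptide.  Useful
#' after changing radii, probe or lattice density; write the result to a
#' TSV and pass it to [reference_sasa()].
#'
#' @param probe_radius,n_points see [sasa_config()].
#' @param radius_table see [vdw_radii()].
#' @return named numeric vector, three-letter code to area (Angstrom^2).
#' @export
compute_reference_sasa <- function(probe_radius = 1.4, n_points = 960,
                                   radius_table = vdw_radii()) {
  out <- vapply(names(.AA3), function(aa) {
    aa3 <- .AA3[[aa]]
    cfg <- sasa_config(probe_radius = probe_radius, n_points = n_points,
                       reference_table = stats::setNames(1, aa3))
    s <- make_tripeptide(aa, radius_table = radius_table)
    sum(atom_sasa(s, cfg)[s$atoms$resno == 2])
  }, 0)
  stats::setNames(unname(out), unname(.AA3[names(out)]))
}

#' Write a burial report
#'
#' TSV with integer-percent fSASA (rounded half-up, as burial tables are
#' conventionally printed); full precision stays in the R objects.
#'
#' @param results a `burial_result` data.frame.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_burial_report <- function(results, path) {
  parts <- strsplit(results$key, ":")
  tab <- data.frame(chain = vapply(parts, `[`, "", 1),
                    resnum = vapply(parts, `[`, "", 2),
                    aa3 = results$resid,
                    sasa_A2 = round(results$sasa, 2),
                    fsasa_percent = floor(results$fsasa * 100 + 0.5),
                    buried = results$buried)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
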