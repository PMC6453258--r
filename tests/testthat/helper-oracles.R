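# Independent oracles and small construction helpers shared across tests.
# Oracles deliberately re-derive quantities by brute force, not through the
# package's implementation paths.

# Brute-force Monte Carlo SASA: random points on each inflated sphere,
# point-in-any-other-sphere counting.  Independent of the deterministic
# golden-spiral lattice used by atom_sasa().
oracle_atom_sasa <- function(s, probe = 1.4, n_points = 10000, seed = 42) {
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")])
  r <- s$atoms$radius + probe
  n <- nrow(xyz)
  set.seed(seed)
  out <- numeric(n)
  for (i in seq_len(n)) {
    # uniform random directions via normalised Gaussians
    g <- matrix(stats::rnorm(3 * n_points), ncol = 3)
    g <- g / sqrt(rowSums(g^2))
    p <- sweep(g * r[i], 2, xyz[i, ], `+`)
    free <- rep(TRUE, n_points)
    for (j in seq_len(n)) {
      if (j == i) next
      dj2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      free <- free & dj2 >= r[j]^2 + 1e-9
    }
    out[i] <- mean(free) * 4 * pi * r[i]^2
  }
  out
}

# Brute-force salt-bridge scan: loop over every acid oxygen / basic
# nitrogen atom pair, no neighbour lists, no vectorised distance matrix.
oracle_bridges <- function(s, cutoff = 4.0) {
  a <- s$atoms[!s$atoms$hetero, ]
  keys <- residue_key(a$chain, a$resno, a$insert)
  acid <- (a$resid == "ASP" & a$elety %in% c("OD1", "OD2")) |
    (a$resid == "GLU" & a$elety %in% c("OE1", "OE2"))
  base <- (a$resid == "ARG" & a$elety %in% c("NE", "NH1", "NH2")) |
    (a$resid == "LYS" & a$elety == "NZ")
  hits <- list()
  for (i in which(acid)) for (j in which(base)) {
    d <- sqrt((a$x[i] - a$x[j])^2 + (a$y[i] - a$y[j])^2 +
                (a$z[i] - a$z[j])^2)
    if (d <= cutoff) {
      pid <- paste(keys[i], keys[j], sep = "~")
      hits[[pid]] <- rbind(hits[[pid]],
                           data.frame(o = a$elety[i], n = a$elety[j],
                                      d = d))
    }
  }
  if (length(hits) == 0)
    return(data.frame(acid = character(), base = character(),
                      dist = numeric(), bidentate = logical()))
  out <- do.call(rbind, lapply(names(hits), function(pid) {
    h <- hits[[pid]]
    ab <- strsplit(pid, "~", fixed = TRUE)[[1]]
    data.frame(acid = ab[1], base = ab[2], dist = min(h$d),
               bidentate = nrow(h) >= 2 &&
                 (length(unique(h$o)) >= 2 || length(unique(h$n)) >= 2))
  }))
  out[order(out$acid, out$base), ]
}

# Independent re-implementation of the conformer internal energy: plain
# double loops over side-chain atom pairs and chi terms, sharing only the
# parameter tables with the package.
oracle_internal_energy <- function(aa3, chi) {
  sc <- build_sidechain(aa3, chi, list(N = c(0, 0, 0),
                                       CA = c(1.458, 0, 0),
                                       C = c(1.458 + 1.525 *
                                               cos(pi - 111 * pi / 180),
                                             1.525 *
                                               sin(pi - 111 * pi / 180),
                                             0)))
  gd <- fepscout:::.residue_graph_distances(aa3)
  eps <- fepscout:::.LJ_EPS; sig <- fepscout:::.LJ_SIG
  getp <- function(tab, el, def) if (el %in% names(tab)) tab[[el]] else def
  e <- 0
  if (nrow(sc) >= 2) {
    for (i in 1:(nrow(sc) - 1)) for (j in (i + 1):nrow(sc)) {
      hops <- gd[sc$name[i], sc$name[j]]
      if (hops < 3) next
      w <- if (hops == 3) 0.5 else 1
      d <- sqrt((sc$x[i] - sc$x[j])^2 + (sc$y[i] - sc$y[j])^2 +
                  (sc$z[i] - sc$z[j])^2)
      e_ij <- sqrt(getp(eps, sc$element[i], 0.066) *
                     getp(eps, sc$element[j], 0.066))
      s_ij <- sqrt(getp(sig, sc$element[i], 3.5) *
                     getp(sig, sc$element[j], 3.5))
      e <- e + w * 4 * e_ij * ((s_ij / d)^12 - (s_ij / d)^6)
    }
  }
  types <- fepscout:::.CHI_TYPES[[aa3]]
  for (k in seq_along(types)) {
    x <- chi[k] * pi / 180
    e <- e + switch(types[k],
                    sp3 = 0.5 * 0.6 * (1 + cos(3 * x)),
                    sp2 = 0.5 * 2.0 * (1 - cos(2 * x)),
                    ar = 0.5 * 2.0 * (1 - cos(2 * (x - pi / 2))))
  }
  e
}

# minimal hand-built structure from explicit atom placements
manual_structure <- function(..., id = "manual", side_a = NULL,
                             side_b = NULL) {
  rows <- list(...)
  atoms <- do.call(rbind, lapply(rows, function(r)
    data.frame(chain = r$chain, resno = r$resno, insert = "",
               resid = r$resid, elety = r$elety,
               element = fepscout:::.element_from_name(r$elety),
               x = r$x, y = r$y, z = r$z, o = 1, hetero = FALSE,
               stringsAsFactors = FALSE)))
  new_structure(atoms, id = id, side_a = side_a, side_b = side_b)
}

atom_row <- function(chain, resno, resid, elety, x, y, z) {
  list(chain = chain, resno = resno, resid = resid, elety = elety,
       x = x, y = y, z = z)
}

# direct one-line metric recomputations
oracle_rmse <- function(tab) sqrt(sum((tab$ddg_pred - tab$ddg_exp)^2) /
                                    nrow(tab))
oracle_r2 <- function(tab) cor(tab$ddg_pred, tab$ddg_exp)^2
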