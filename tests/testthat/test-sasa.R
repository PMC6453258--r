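test_that("an isolated atom's SASA equals the closed-form sphere area", {
  iso <- manual_structure(atom_row("A", 1, "GLY", "CA", 0, 0, 0))
  expect_equal(atom_sasa(iso), 4 * pi * (1.7 + 1.4)^2, tolerance = 1e-12)
})

test_that("coincident atoms warn and occlude each other symmetrically", {
  s <- manual_structure(atom_row("A", 1, "GLY", "CA", 0, 0, 0),
                        atom_row("A", 2, "GLY", "CA", 0, 0, 0))
  expect_warning(a <- atom_sasa(s), "identical coordinates")
  expect_equal(a[1], a[2])
  expect_equal(a[1], 0) # fully inside each other's inflated sphere
})

test_that("lattice SASA agrees with the 10k-point Monte Carlo oracle within 2%", {
  for (aa in c("E", "W")) {
    s <- make_tripeptide(aa)
    impl <- atom_sasa(s)
    orac <- oracle_atom_sasa(s)
    keys <- fepscout:::.atom_keys(s)
    for (k in unique(keys)) {
      a <- sum(impl[keys == k]); b <- sum(orac[keys == k])
      expect_lt(abs(a - b) / max(b, 1), 0.02)
    }
  }
})

test_that("an atom at the centroid of a closed shell has zero SASA", {
  shell <- golden_spiral(30) * 2.5
  rows <- c(list(atom_row("A", 1, "GLY", "CA", 0, 0, 0)),
            lapply(seq_len(30), function(i)
              atom_row("B", i, "GLY", "CA", shell[i, 1], shell[i, 2],
                       shell[i, 3])))
  s <- do.call(manual_structure, c(rows, list(side_a = "A", side_b = "B")))
  a <- atom_sasa(s)
  expect_equal(a[1], 0)
  # oracle confirms full coverage
  expect_equal(oracle_atom_sasa(s, n_points = 2000)[1], 0)
})

test_that("adding an occluder never increases any atom's SASA", {
  s <- make_tripeptide("L")
  base <- atom_sasa(s)
  for (shift in list(c(4, 0, 0), c(0, 5, 1), c(2, -3, 2))) {
    atoms2 <- rbind(s$atoms[, !(names(s$atoms) %in% "radius")],
                    data.frame(chain = "A", resno = 99, insert = "",
                               resid = "GLY", elety = "CA", element = "C",
                               x = shift[1], y = shift[2], z = shift[3],
                               o = 1, hetero = FALSE))
    s2 <- new_structure(atoms2, id = "occluded")
    with_occ <- atom_sasa(s2)[seq_along(base)]
    expect_true(all(with_occ <= base + 1e-9))
  }
})

test_that("SASA is invariant under rigid transforms with the lattice re-expressed", {
  s <- make_tripeptide("F")
  base <- atom_sasa(s)
  R <- fepscout:::.rotation_matrix(c(1, 2, 3), 37.5)
  shift <- c(5, -3, 11)
  s2 <- s
  s2$atoms[, c("x", "y", "z")] <-
    fepscout:::.transform_xyz(as.matrix(s$atoms[, c("x", "y", "z")]),
                              R, shift)
  rotated <- atom_sasa(s2, sasa_config(orientation = R))
  expect_equal(rotated, base, tolerance = 1e-6)
  # translation alone never changes anything at all
  s3 <- s
  s3$atoms[, c("x", "y", "z")] <-
    sweep(as.matrix(s$atoms[, c("x", "y", "z")]), 2, shift, `+`)
  expect_equal(atom_sasa(s3), base, tolerance = 1e-12)
})

test_that("middle residue of an isolated Gly-X-Gly normalises to fSASA ~ 1", {
  for (aa in c("A", "W", "D", "K")) {
    r <- residue_fsasa(make_tripeptide(aa), "A:2")
    expect_equal(r$fsasa, 1.0, tolerance = 0.05)
    expect_false(r$buried)
  }
})

test_that("fSASA is non-negative and bounded near 1 for isolated residues", {
  for (aa in names(fepscout:::.AA3)) {
    r <- residue_fsasa(make_tripeptide(aa), "A:2")
    expect_gte(r$fsasa, 0)
    expect_lte(r$fsasa, 1.05)
  }
})

test_that("burial threshold is strict: fSASA at the cutoff is exposed", {
  cfg <- sasa_config(threshold_fsasa = 0.10)
  res <- data.frame(key = c("A:1", "A:2", "A:3"),
                    resid = "ALA",
                    sasa = c(1, 2, 3),
                    fsasa = c(0.099, 0.100, 0.101),
                    buried = NA)
  parts <- classify_burial(res, cfg)
  expect_equal(parts$buried$key, "A:1")
  expect_equal(parts$exposed$key, c("A:2", "A:3"))
  # empty input gives two empty sets
  empty <- classify_burial(res[0, ], cfg)
  expect_equal(nrow(empty$buried), 0L)
  expect_equal(nrow(empty$exposed), 0L)
})

test_that("complex vs single-side context changes interface burial only", {
  s <- make_complex_fixture("helix_pair")
  key <- attr(s, "ground_truth")$target_key
  in_complex <- residue_fsasa(s, key, context = "complex")
  alone <- residue_fsasa(s, key, context = "side")
  expect_gte(alone$fsasa, in_complex$fsasa) # partner can only occlude
})

test_that("unknown residue type in the reference table is a clear error", {
  s <- make_tripeptide("A")
  cfg <- sasa_config(reference_table = c(GLY = 86.4)) # no ALA entry
  expect_error(residue_fsasa(s, "A:2", cfg), "reference-area table")
})
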