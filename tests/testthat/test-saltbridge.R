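test_that("an isolated acid with no base in range yields an empty graph", {
  s <- make_tripeptide("D")
  g <- detect_bridges(s)
  expect_equal(nrow(g$edges), 0L)
  expect_equal(nrow(g$nodes), 0L)
})

test_that("the analytic ASP-ARG pair is a bidentate bridge at 2.8 A and absent at 4.5 A", {
  s <- make_complex_fixture("bridge_pair", separation = 2.8)
  g <- detect_bridges(s)
  expect_equal(nrow(g$edges), 1L)
  expect_equal(g$edges$acid, "A:2")
  expect_equal(g$edges$base, "B:2")
  expect_true(g$edges$bidentate)
  expect_equal(g$edges$dist, 2.8, tolerance = 1e-3)

  far <- make_complex_fixture("bridge_pair", separation = 4.5)
  expect_equal(nrow(detect_bridges(far)$edges), 0L)
  # but a looser cutoff sees it
  expect_equal(nrow(detect_bridges(far, saltbridge_config(5.0))$edges), 1L)
})

test_that("increasing the cutoff never removes edges", {
  s <- make_complex_fixture("bridge_pair", separation = 3.5)
  prev <- character(0)
  for (cut in c(2.5, 3.0, 3.6, 4.5, 6.0)) {
    g <- detect_bridges(s, saltbridge_config(cut))
    ids <- paste(g$edges$acid, g$edges$base)
    expect_true(all(prev %in% ids))
    prev <- ids
  }
})

test_that("detection equals the brute-force all-pairs oracle", {
  fixtures <- list(make_complex_fixture("bridge_pair", separation = 2.8),
                   make_complex_fixture("bridge_pair", separation = 3.9),
                   make_complex_fixture("helix_pair"),
                   make_tripeptide("D"))
  for (s in fixtures) {
    g <- detect_bridges(s)
    o <- oracle_bridges(s)
    expect_equal(nrow(g$edges), nrow(o))
    if (nrow(o) > 0) {
      expect_equal(g$edges$acid, o$acid)
      expect_equal(g$edges$base, o$base)
      expect_equal(g$edges$dist, o$dist, tolerance = 1e-9)
      expect_equal(g$edges$bidentate, o$bidentate)
    }
  }
})

test_that("the graph is invariant under rigid-body transforms and chain order", {
  s <- make_complex_fixture("bridge_pair", separation = 2.8)
  g0 <- detect_bridges(s)
  s2 <- s
  s2$atoms[, c("x", "y", "z")] <- fepscout:::.transform_xyz(
    as.matrix(s$atoms[, c("x", "y", "z")]),
    fepscout:::.rotation_matrix(c(0, 1, 1), 63), c(-4, 8, 2))
  g2 <- detect_bridges(s2)
  expect_equal(g2$edges[, c("acid", "base", "bidentate")],
               g0$edges[, c("acid", "base", "bidentate")])
  expect_equal(g2$edges$dist, g0$edges$dist, tolerance = 1e-9)
  # reorder chains in the atom table
  s3 <- s
  s3$atoms <- s3$atoms[order(s3$atoms$chain, decreasing = TRUE), ]
  g3 <- detect_bridges(s3)
  expect_equal(g3$edges, g0$edges)
})

test_that("extended-sampling flag follows the multiple-or-bidentate rule", {
  # one bidentate bridge -> flagged
  s <- make_complex_fixture("bridge_pair", separation = 2.8)
  g <- detect_bridges(s)
  f <- flag_extended_sampling(g, parse_mutation("A:2:D>N"))
  expect_true(f$flag)
  expect_match(f$reason, "bidentate")
  expect_match(f$reason, "B:2")
  # residue with no bridge -> not flagged
  f0 <- flag_extended_sampling(g, parse_mutation("A:1:G>D"))
  expect_false(f0$flag)
  expect_equal(f0$reason, "")

  # two monodentate bridges: ASP flanked by two lysine NZ atoms, each
  # near one carboxylate oxygen only
  asp <- build_peptide("GDG", chain = "A")
  od1 <- unlist(asp[asp$resno == 2 & asp$elety == "OD1", c("x", "y", "z")])
  od2 <- unlist(asp[asp$resno == 2 & asp$elety == "OD2", c("x", "y", "z")])
  cg <- unlist(asp[asp$resno == 2 & asp$elety == "CG", c("x", "y", "z")])
  d1 <- od1 + (od1 - cg) / sqrt(sum((od1 - cg)^2)) * 2.9
  d2 <- od2 + (od2 - cg) / sqrt(sum((od2 - cg)^2)) * 2.9
  rows <- lapply(seq_len(nrow(asp)), function(i)
    atom_row("A", asp$resno[i], asp$resid[i], asp$elety[i],
             asp$x[i], asp$y[i], asp$z[i]))
  rows <- c(rows, list(atom_row("B", 1, "LYS", "NZ", d1[1], d1[2], d1[3]),
                       atom_row("B", 2, "LYS", "NZ", d2[1], d2[2], d2[3])))
  s2 <- do.call(manual_structure, c(rows, list(side_a = "A", side_b = "B")))
  g2 <- detect_bridges(s2)
  expect_equal(nrow(g2$edges), 2L)
  expect_false(any(g2$edges$bidentate))
  f2 <- flag_extended_sampling(g2, "A:2")
  expect_true(f2$flag)
  expect_match(f2$reason, "2 salt bridge")
})

test_that("histidine bases are opt-in", {
  his <- build_peptide("GHG", chain = "A")
  ne2 <- unlist(his[his$resno == 2 & his$elety == "NE2", c("x", "y", "z")])
  rows <- lapply(seq_len(nrow(his)), function(i)
    atom_row("A", his$resno[i], his$resid[i], his$elety[i],
             his$x[i], his$y[i], his$z[i]))
  rows <- c(rows, list(atom_row("B", 1, "ASP", "OD1",
                                ne2[1] + 3.0, ne2[2], ne2[3])))
  s <- do.call(manual_structure, c(rows, list(side_a = "A", side_b = "B")))
  expect_equal(nrow(detect_bridges(s)$edges), 0L)
  expect_equal(nrow(detect_bridges(
    s, saltbridge_config(include_his = TRUE))$edges), 1L)
})

test_that("edge list and DOT exports are well formed", {
  s <- make_complex_fixture("bridge_pair", separation = 2.8)
  g <- detect_bridges(s)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_bridge_tsv(g, f)
  back <- read.delim(f)
  expect_equal(nrow(back), 1L)
  dot <- bridge_dot(g)
  expect_match(dot, "graph saltbridges")
  expect_match(dot, "A:2.*--.*B:2")
})
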