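test_that("state enumeration covers acids and leaves other mutations alone", {
  # no ionisable acid end state: single default assignment
  kn <- enumerate_states(parse_mutation("A:5:K>N"))
  expect_length(kn, 1)
  expect_equal(kn[[1]]$label, "standard")

  # mutant acid at a site buried only when bound: charged throughout, or
  # protonated in complex with charged unbound (penalised)
  ad <- enumerate_states(parse_mutation("I:15:A>D"), buried_unbound = FALSE)
  expect_length(ad, 2)
  labels <- vapply(ad, `[[`, "", "label")
  prot <- ad[[which(labels == "protonated")]]
  expect_equal(prot$complex_state, "ASH")
  expect_equal(prot$unbound_state, "ASP")
  expect_equal(prot$role, "mutant")

  # wild-type acid buried in both forms: protonated in both states
  ea <- enumerate_states(parse_mutation("A:73:E>A"), buried_unbound = TRUE)
  prot2 <- ea[[which(vapply(ea, `[[`, "", "label") == "protonated")]]
  expect_equal(prot2$complex_state, "GLH")
  expect_equal(prot2$unbound_state, "GLH")
  expect_equal(prot2$role, "wild_type")
})

test_that("state penalty follows the Henderson-Hasselbalch cost", {
  cfg <- protonation_config() # pH 7, ASP 3.8, GLU 4.4, 298.15 K
  # no state change -> no penalty
  expect_equal(state_penalty(
    state_assignment("wild_type", "GLH", "GLH", "protonated"), cfg), 0)
  # pH equal to pKa -> zero point of the formula
  cfg_eq <- protonation_config(pH = 3.8)
  expect_equal(state_penalty(
    state_assignment("mutant", "ASH", "ASP", "protonated"), cfg_eq), 0)
  # independently evaluated: 2.303 * RT * (7.0 - 3.8)
  rt <- 0.001987204259 * 298.15
  expect_equal(state_penalty(
    state_assignment("mutant", "ASH", "ASP", "protonated"), cfg),
    2.303 * rt * 3.2, tolerance = 1e-9)
  expect_equal(2.303 * rt * 3.2, 4.366, tolerance = 1e-3)
  # RT derivation invariant
  expect_equal(cfg$RT, rt, tolerance = 1e-6)
})

test_that("penalty is monotone increasing in pH and decreasing in pKa", {
  a <- state_assignment("mutant", "GLH", "GLU", "protonated")
  pens_ph <- vapply(c(5, 6, 7, 8), function(ph)
    state_penalty(a, protonation_config(pH = ph)), 0)
  expect_true(all(diff(pens_ph) > 0))
  pens_pka <- vapply(c(3.5, 4.4, 5.5), function(pk)
    state_penalty(a, protonation_config(model_pkas = c(ASP = 3.8,
                                                       GLU = pk))), 0)
  expect_true(all(diff(pens_pka) < 0))
})

test_that("missing model pKa is a fatal, named error", {
  a <- state_assignment("mutant", "GLH", "GLU", "protonated")
  expect_error(
    state_penalty(a, protonation_config(model_pkas = c(ASP = 3.8))),
    "GLU")
})

test_that("inconsistent complex/unbound state pairs are rejected", {
  expect_error(state_assignment("mutant", "ASH", "GLU", "x"),
               "inconsistent")
  expect_silent(state_assignment("mutant", "ASH", "ASP", "x"))
  expect_silent(state_assignment("mutant", "ASP", "ASH", "x"))
})

test_that("final value is the minimum implied free energy across states", {
  # per-state values with penalties already folded in
  p1 <- select_final(c(protonated = 3.23, charged = 28.89))
  expect_equal(p1$final_ddg, 3.23)
  expect_equal(p1$selected_state, "protonated")

  p2 <- select_final(c(protonated = 5.66, charged = 18.03))
  expect_equal(p2$final_ddg, 5.66)

  # single state: identity
  expect_equal(select_final(c(standard = 0.42))$final_ddg, 0.42)

  # order invariance
  p3 <- select_final(c(charged = 18.03, protonated = 5.66))
  expect_equal(p3$final_ddg, p2$final_ddg)
  expect_equal(p3$selected_state, p2$selected_state)

  # final <= every implied value, equality for the selected state
  expect_true(all(p1$final_ddg <= p1$per_state))
  expect_equal(unname(p1$per_state[p1$selected_state]), p1$final_ddg)

  expect_error(select_final(numeric(0)), "no per-state values")
})

test_that("penalties are applied only to not-yet-corrected values", {
  cfg <- protonation_config()
  states <- enumerate_states(parse_mutation("I:15:A>D"),
                             buried_unbound = FALSE)
  pen <- state_penalty(states[[2]], cfg) # protonated branch
  raw <- c(charged = 6.0, protonated = 4.0)
  plan <- select_final(raw, assignments = states, cfg = cfg,
                       penalty_included = FALSE)
  expect_equal(unname(plan$per_state["protonated"]), 4.0 + pen)
  expect_equal(unname(plan$per_state["charged"]), 6.0)
  # here the penalty flips the selection to the charged state
  expect_equal(plan$selected_state, "charged")
  # with penalties declared folded in, values pass through untouched
  plan2 <- select_final(raw, assignments = states, cfg = cfg,
                        penalty_included = TRUE)
  expect_equal(plan2$selected_state, "protonated")
})

test_that("the packaged example cases select the printed final values", {
  ex <- protonation_examples()
  expect_gt(nrow(ex), 10)
  mt <- ex[ex$role == "mutant", ]
  for (i in seq_len(nrow(mt))) {
    plan <- select_final(c(protonated = mt$ddg_protonated[i],
                           charged = mt$ddg_charged[i]),
                         penalty_included = mt$penalty_included[i])
    expect_equal(plan$final_ddg, mt$ddg_protonated[i])
    expect_equal(plan$selected_state, "protonated")
  }
})
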