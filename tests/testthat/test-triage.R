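triage_fixture <- function() {
  # cage loose enough that a serine fits (buried, placeable) while
  # glutamate cannot (rejected); terminal residues stay exposed
  make_complex_fixture("cavity", cage_radii = c(3.0, 3.9, 4.8))
}

test_that("the three verdicts map to occluded, buried and exposed cases", {
  s <- triage_fixture()
  tr <- run_triage(s, c("A:3:A>E", "A:3:A>S", "A:1:G>D"))
  df <- as.data.frame(tr)
  expect_equal(df[df$mutation == "A:3:A>E", "verdict"],
               "rejected_unplaceable")
  expect_equal(df[df$mutation == "A:3:A>S", "verdict"],
               "deprioritized_buried")
  expect_equal(df[df$mutation == "A:1:G>D", "verdict"], "send_to_fep")
  # the verdict partition is exhaustive and exclusive
  expect_equal(sum(tr$counts), length(tr$records))
  expect_true(all(df$verdict %in% c("rejected_unplaceable",
                                    "deprioritized_buried",
                                    "send_to_fep")))
  # invariant links: unplaceable <-> rejected; placeable & buried <->
  # deprioritized
  expect_identical(df$verdict == "rejected_unplaceable", !df$placeable)
  expect_identical(df$verdict == "deprioritized_buried",
                   df$placeable & df$buried)
})

test_that("an empty mutation list produces an empty report", {
  s <- triage_fixture()
  tr <- run_triage(s, list())
  expect_length(tr$records, 0)
  expect_equal(sum(tr$counts), 0)
  expect_equal(nrow(as.data.frame(tr)), 0L)
})

test_that("charge-changing mutations get 24 lambda windows and 8.5 A buffer", {
  s <- triage_fixture()
  tr <- run_triage(s, c("A:1:G>D", "A:5:G>S"))
  df <- as.data.frame(tr)
  cc <- df[df$mutation == "A:1:G>D", ]
  expect_true(cc$charge_changing)
  expect_equal(cc$lambda_windows, 24L)
  expect_equal(cc$buffer_A, 8.5)
  neutral <- df[df$mutation == "A:5:G>S", ]
  expect_false(neutral$charge_changing)
  expect_equal(neutral$lambda_windows, 12L)
  expect_equal(neutral$buffer_A, 5.0)
})

test_that("salt-bridge involvement and homology models trigger 100 ns sampling", {
  s <- make_complex_fixture("bridge_pair", separation = 2.8)
  tr <- run_triage(s, "A:2:D>N")
  rec <- tr$records[["A:2:D>N"]]
  expect_true(rec$saltbridge_flag)
  expect_equal(rec$recommendation$extended_ns, 100L)

  # same mutation, no bridge: no extended sampling unless homology model
  far <- make_complex_fixture("bridge_pair", separation = 6.0)
  tr2 <- run_triage(far, "A:2:D>N")
  expect_true(is.na(tr2$records[["A:2:D>N"]]$recommendation$extended_ns))
  tr3 <- run_triage(far, "A:2:D>N", homology_model = TRUE)
  expect_equal(tr3$records[["A:2:D>N"]]$recommendation$extended_ns, 100L)
})

test_that("per-mutation failures are collected without aborting the batch", {
  s <- triage_fixture()
  tr <- run_triage(s, c("A:1:G>D", "A:9:G>D", "A:2:G>P", "A:1:S>K"))
  expect_length(tr$records, 1)
  expect_equal(nrow(tr$failures), 3L)
  expect_match(tr$failures$error[tr$failures$mutation == "A:9:G>D"],
               "absent")
  expect_match(tr$failures$error[tr$failures$mutation == "A:2:G>P"],
               "excluded")
  expect_match(tr$failures$error[tr$failures$mutation == "A:1:S>K"],
               "mismatch")
})

test_that("protonation plans join in from per-state prediction columns", {
  s <- triage_fixture()
  preds <- data.frame(mutation = "A:1:G>D", ddg_protonated = 5.66,
                      ddg_charged = 18.03, penalty_included = TRUE)
  tr <- run_triage(s, "A:1:G>D", predictions = preds)
  plan <- tr$records[["A:1:G>D"]]$protonation
  expect_equal(plan$final_ddg, 5.66)
  expect_equal(plan$selected_state, "protonated")
  df <- as.data.frame(tr)
  expect_equal(df$final_ddg, 5.66)
})

test_that("reports round-trip through JSON and TSV carries one row per record", {
  s <- triage_fixture()
  tr <- run_triage(s, c("A:3:A>E", "A:3:A>S", "A:1:G>D"))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  json <- withr::local_tempfile(fileext = ".json")
  df <- write_report(tr, tsv = tsv, json = json)
  back <- read_report(json)
  expect_equal(back$mutation, df$mutation)
  expect_equal(back$verdict, df$verdict)
  expect_equal(back$delta_strain, df$delta_strain)
  expect_equal(back$fsasa_percent, df$fsasa_percent)
  tsv_tab <- read.delim(tsv)
  expect_equal(nrow(tsv_tab), 3L)
  expect_true(all(c("mutation", "delta_strain", "fsasa_percent",
                    "verdict") %in% names(tsv_tab)))
  # fSASA is printed as integer percent in the TSV
  expect_true(all(tsv_tab$fsasa_percent == floor(tsv_tab$fsasa_percent)))
})
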