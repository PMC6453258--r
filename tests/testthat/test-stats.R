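test_that("RMSE matches hand arithmetic and the one-line oracle", {
  perfect <- data.frame(ddg_pred = c(1, 2, 3), ddg_exp = c(1, 2, 3))
  expect_equal(rmse(perfect), 0)
  pm <- data.frame(ddg_pred = c(0, 0), ddg_exp = c(1, -1))
  expect_equal(rmse(pm), 1.0)
  for (seed in 1:5) {
    tab <- make_stats_table(50, slope = 1, noise_sd = 1.1, seed = seed)
    expect_equal(rmse(tab), oracle_rmse(tab), tolerance = 1e-12)
    expect_equal(r2(tab), oracle_r2(tab), tolerance = 1e-12)
  }
  expect_error(rmse(data.frame(ddg_pred = numeric(),
                               ddg_exp = numeric())), "at least one")
})

test_that("R^2 is 1 for exact linear relations and ~0 under independence", {
  lin <- data.frame(ddg_pred = 1:20, ddg_exp = 3.2 * (1:20) - 5)
  expect_equal(r2(lin), 1.0)
  set.seed(11)
  null <- data.frame(ddg_pred = rnorm(3000), ddg_exp = rnorm(3000))
  expect_lt(r2(null), 0.01)
  # zero variance is reported as missing with a warning
  flat <- data.frame(ddg_pred = rep(1, 5), ddg_exp = 1:5)
  expect_warning(v <- r2(flat), "zero variance")
  expect_true(is.na(v))
})

test_that("permutation p-value separates signal from noise", {
  tab <- make_stats_table(60, slope = 1, noise_sd = 0.8, seed = 2)
  rt <- r2_test(tab, n_perm = 2000, seed = 99)
  expect_lt(rt$p_value, 0.001)
  set.seed(5)
  null <- data.frame(ddg_pred = rnorm(40), ddg_exp = rnorm(40))
  rt0 <- r2_test(null, n_perm = 2000, seed = 99)
  expect_gt(rt0$p_value, 0.05)
  # reproducible given the seed
  expect_equal(r2_test(tab, n_perm = 500, seed = 7)$p_value,
               r2_test(tab, n_perm = 500, seed = 7)$p_value)
})

test_that("bootstrap degenerates to the point estimate when disabled", {
  tab <- make_stats_table(30, slope = 1, noise_sd = 1, seed = 4)
  ci <- bootstrap_ci(tab, rmse, n_boot = 1, resample = FALSE)
  expect_equal(ci[1], rmse(tab))
  expect_equal(ci[2], rmse(tab))
  # identical residuals: zero-width interval at the point value
  const <- data.frame(ddg_pred = 1:10 + 0.7, ddg_exp = as.numeric(1:10))
  ci2 <- bootstrap_ci(const, rmse, n_boot = 200, seed = 1)
  expect_equal(unname(ci2), c(0.7, 0.7))
})

test_that("bootstrap CI width shrinks like 1/sqrt(n)", {
  widths <- vapply(c(25, 100, 400), function(n) {
    tab <- data.frame(ddg_exp = numeric(n), ddg_pred = numeric(n))
    set.seed(123)
    tab$ddg_exp <- rnorm(n, 0, 1.5)
    tab$ddg_pred <- tab$ddg_exp + rnorm(n, 0, 1)
    ci <- bootstrap_ci(tab, rmse, n_boot = 1000, seed = 8)
    ci[2] - ci[1]
  }, 0)
  # each doubling of sqrt(n) should roughly halve the width
  expect_gt(widths[1] / widths[2], 1.4)
  expect_lt(widths[1] / widths[2], 3.0)
  expect_gt(widths[2] / widths[3], 1.4)
  expect_lt(widths[2] / widths[3], 3.0)
})

test_that("experimental truncation keeps strictly-below-limit records", {
  tab <- make_stats_table(80, slope = 1, noise_sd = 1, seed = 6)
  tab$ddg_exp[1] <- 1.0 # boundary case
  kept <- truncate_by_experiment(tab, 1.0)
  expect_identical(kept, tab[tab$ddg_exp < 1.0, ]) # brute-force filter
  expect_false(1 %in% as.integer(rownames(kept)))
  expect_identical(truncate_by_experiment(tab, Inf), tab)
})

test_that("slope rescaling recovers planted slopes and preserves correlation", {
  # exact relation: slope recovered exactly, rescaled == experiment
  exact <- data.frame(system = "s", ddg_pred = (1:10) * 10,
                      ddg_exp = (1:10))
  fit <- fit_rescale(exact)
  expect_equal(fit$slopes$slope, 0.1, tolerance = 1e-12)
  expect_equal(fit$records$ddg_rescaled, exact$ddg_exp, tolerance = 1e-9)

  # planted slopes with noise, recovered within 3 standard errors
  for (sl in c(0.07, 0.14)) {
    tab <- make_stats_table(120, slope = sl, noise_sd = 0.4, seed = 31)
    f <- fit_rescale(tab)
    se <- summary(lm(ddg_exp ~ ddg_pred, tab))$coefficients["ddg_pred", 2]
    expect_lt(abs(f$slopes$slope - sl), 3 * se)
    # positive rescaling leaves the Pearson correlation unchanged
    expect_equal(cor(f$records$ddg_rescaled, tab$ddg_exp),
                 cor(tab$ddg_pred, tab$ddg_exp), tolerance = 1e-12)
  }

  # degenerate subsets are skipped with a warning
  degen <- data.frame(system = "d", ddg_pred = c(1, 1), ddg_exp = c(1, 2))
  expect_warning(fd <- fit_rescale(degen), "degenerate")
  expect_equal(nrow(fd$slopes), 0L)
})

test_that("system selection enforces favourable-mutation and non-alanine rules", {
  mk <- function(ddg, mt) data.frame(ddg_exp = ddg, mt_aa = mt)
  tabs <- list(
    no_fav = mk(c(-0.4, 1, 2, 3), c("S", "T", "N", "Q")),
    ala_heavy = mk(c(-1, 0.2, 0.5, 1, 2, 0.1, 0.3, 0.9, 1.2, 2.2),
                   c("S", rep("A", 9))),
    good = mk(c(-0.6, 0.5, 1.5, -0.9), c("A", "S", "K", "N")))
  kept <- select_systems(tabs)
  expect_identical(kept, "good")
  # near-duplicates resolve to the most favourable member
  tabs2 <- list(v1 = mk(c(-0.6, 1), c("S", "N")),
                v2 = mk(c(-0.6, -0.8, 1), c("S", "N", "Q")))
  kept2 <- select_systems(tabs2, dup_groups = c(v1 = "g", v2 = "g"))
  expect_identical(kept2, "v2")
})

test_that("metrics are invariant under record permutation", {
  tab <- make_stats_table(40, slope = 1, noise_sd = 1, seed = 12)
  perm <- tab[rev(seq_len(nrow(tab))), ]
  expect_equal(rmse(perm), rmse(tab))
  expect_equal(r2(perm), r2(tab))
})

test_that("prediction tables round-trip through the TSV reader", {
  tab <- make_stats_table(15, slope = 1, noise_sd = 1, seed = 3)
  f <- withr::local_tempfile(fileext = ".tsv")
  write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_predictions(f)
  expect_equal(back$ddg_pred, tab$ddg_pred)
  expect_equal(back$buried, tab$buried)
  # missing required columns are fatal
  bad <- withr::local_tempfile(fileext = ".tsv")
  write.table(tab[, c("system", "mutation")], bad, sep = "\t",
              row.names = FALSE)
  expect_error(read_predictions(bad), "lack")
})
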