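# Benchmark statistics for predicted vs experimental binding free-energy
# changes: RMSE, coefficient of determination with permutation p-value,
# bootstrap confidence intervals, experimental truncation, per-subset
# slope rescaling, and data-set selection rules.

.check_records <- function(records, need = c("ddg_pred", "ddg_exp")) {
  stopifnot(is.data.frame(records))
  miss <- setdiff(need, names(records))
  if (length(miss) > 0)
    stop("records lack column(s): ", paste(miss, collapse = ", "))
  for (col in intersect(need, c("ddg_pred", "ddg_exp")))
    if (!all(is.finite(records[[col]])))
      stop("non-finite values in ", col)
  invisible(records)
}

#' Root mean square error of predictions
#'
#' @param records data.frame with columns `ddg_pred`, `ddg_exp`
#'   (kcal/mol).
#' @return RMSE in kcal/mol.
#' @export
rmse <- function(records) {
  .check_records(records)
  if (nrow(records) < 1) stop("rmse needs at least one record")
  sqrt(mean((records$ddg_pred - records$ddg_exp)^2))
}

#' Coefficient of determination
#'
#' Squared Pearson correlation between predicted and experimental values
#' (the convention under which rescaling predictions by a fitted slope
#' leaves the statistic unchanged).  `r2_test()` adds a two-sided
#' permutation p-value for the correlation.
#'
#' @param records data.frame with columns `ddg_pred`, `ddg_exp`.
#' @param method `"pearson_sq"` (default) or `"ss"` for the regression
#'   1 - SS_res/SS_tot variant of a least-squares fit of experiment on
#'   prediction.
#' @return `r2()`: numeric in \[0, 1\] (`NA` with a warning when either
#'   variable has zero variance).
#' @export
r2 <- function(records, method = c("pearson_sq", "ss")) {
  method <- match.arg(method)
  .check_records(records)
  if (nrow(records) < 3) stop("r2 needs at least three records")
  if (stats::sd(records$ddg_pred) == 0 || stats::sd(records$ddg_exp) == 0) {
    warning("zero variance: coefficient of determination undefined")
    return(NA_real_)
  }
  if (method == "pearson_sq") {
    stats::cor(records$ddg_pred, records$ddg_exp)^2
  } else {
    fit <- stats::lm(ddg_exp ~ ddg_pred, data = records)
    1 - sum(stats::residuals(fit)^2) /
      sum((records$ddg_exp - mean(records$ddg_exp))^2)
  }
}

#' @rdname r2
#' @param n_perm number of permutations.
#' @param seed RNG seed for the permutation draw.
#' @return `r2_test()`: list with `r2` and `p_value`.
#' @export
r2_test <- function(records, n_perm = 1e5, seed = 20190329) {
  val <- r2(records)
  if (is.na(val)) return(list(r2 = NA_real_, p_value = NA_real_))
  x <- records$ddg_pred
  y <- records$ddg_exp
  r_obs <- abs(stats::cor(x, y))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- length(x)
  xc <- x - mean(x); yc <- y - mean(y)
  denom <- sqrt(sum(xc^2) * sum(yc^2))
  hits <- 0L
  block <- 1000L
  done <- 0L
  while (done < n_perm) {
    k <- min(block, n_perm - done)
    perm <- matrix(0, n, k)
    for (j in seq_len(k)) perm[, j] <- yc[sample.int(n)]
    r_perm <- abs(crossprod(xc, perm)) / denom
    hits <- hits + sum(r_perm >= r_obs - 1e-12)
    done <- done + k
  }
  list(r2 = val, p_value = (hits + 1) / (n_perm + 1))
}

#' Bootstrap confidence interval for a benchmark metric
#'
#' Case-resampling percentile bootstrap: records are resampled with
#' replacement `n_boot` times and the metric recomputed on each
#' replicate; the interval is the 2.5/97.5 percentile (for `level`
#' 0.95).  Reproducible given the seed.
#'
#' @param records data.frame with columns `ddg_pred`, `ddg_exp`.
#' @param metric function of a records data.frame returning one number
#'   ([rmse], [r2], ...), or one of the strings `"rmse"`, `"r2"`.
#' @param n_boot number of bootstrap replicates (default 10000).
#' @param seed RNG seed (default 20190329).
#' @param level confidence level.
#' @param resample set `FALSE` to disable resampling (degenerates to the
#'   point estimate; useful for self-checks).
#' @return numeric `c(lo, hi)`.
#' @export
bootstrap_ci <- function(records, metric = rmse, n_boot = 10000,
                         seed = 20190329, level = 0.95, resample = TRUE) {
  .check_records(records)
  if (nrow(records) < 2) stop("bootstrap needs at least two records")
  if (is.character(metric))
    metric <- switch(metric, rmse = rmse, r2 = r2,
                     stop("unknown metric name ", metric))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- nrow(records)
  reps <- vapply(seq_len(n_boot), function(b) {
    idx <- if (resample) sample.int(n, n, replace = TRUE) else seq_len(n)
    suppressWarnings(metric(records[idx, , drop = FALSE]))
  }, 0)
  reps <- reps[is.finite(reps)]
  alpha <- (1 - level) / 2
  unname(stats::quantile(reps, c(alpha, 1 - alpha), type = 7))
}

#' Truncate a record set by experimental affinity change
#'
#' Keeps records whose experimental change in binding free energy is
#' strictly below `limit` (default +1 kcal/mol), the subset on which rank
#' ordering of favourable and near-neutral mutations is actually tested.
#'
#' @param records data.frame with column `ddg_exp`.
#' @param limit kcal/mol.
#' @return the row subset.
#' @export
truncate_by_experiment <- function(records, limit = 1.0) {
  .check_records(records, "ddg_exp")
  records[records$ddg_exp < limit, , drop = FALSE]
}

#' Combined benchmark metrics
#'
#' One-call evaluation of a prediction/experiment table: RMSE and
#' coefficient of determination with permutation p-value, each with a
#' case-resampling bootstrap confidence interval.
#'
#' @inheritParams bootstrap_ci
#' @param n_perm permutations for the p-value.
#' @return a `fep_metrics` list: `n`, `rmse`, `r2`, `p_value`, `ci_rmse`,
#'   `ci_r2`, `n_boot`, `seed`.
#' @export
eval_metrics <- function(records, n_boot = 10000, n_perm = 1e5,
                         seed = 20190329, level = 0.95) {
  .check_records(records)
  rt <- r2_test(records, n_perm = n_perm, seed = seed)
  structure(list(n = nrow(records),
                 rmse = rmse(records),
                 r2 = rt$r2, p_value = rt$p_value,
                 ci_rmse = bootstrap_ci(records, rmse, n_boot, seed, level),
                 ci_r2 = bootstrap_ci(records, r2, n_boot, seed, level),
                 n_boot = n_boot, seed = seed),
            class = "fep_metrics")
}

#' @export
print.fep_metrics <- function(x, ...) {
  cat(sprintf("n = %d cases\n", x$n))
  cat(sprintf("RMSE = %.2f [%.2f-%.2f] kcal/mol\n",
              x$rmse, x$ci_rmse[1], x$ci_rmse[2]))
  cat(sprintf("R^2  = %.2f [%.2f-%.2f], permutation p %s\n", x$r2,
              x$ci_r2[1], x$ci_r2[2],
              if (is.na(x$p_value)) "NA"
              else if (x$p_value < 0.001) "< 0.001"
              else sprintf("= %.3f", x$p_value)))
  invisible(x)
}

#' Per-subset slope rescaling
#'
#' Fits, per subset, the ordinary least-squares line of experiment on
#' prediction (intercept fitted but not applied) and rescales predictions
#' by the slope alone: `ddg_rescaled = slope * ddg_pred`.  This is the
#' standard correction for implicit-solvent scores whose optimal scale is
#' system dependent; it leaves each subset's correlation unchanged.
#'
#' @param records data.frame with `ddg_pred`, `ddg_exp` and the grouping
#'   column.
#' @param by name of the grouping column (default `"system"`).
#' @return list with `slopes` (data.frame subset/slope/n) and `records`
#'   (input with `ddg_rescaled` added); subsets with fewer than 3 records
#'   or zero prediction variance are skipped with a warning
#'   (`ddg_rescaled = NA`).
#' @export
fit_rescale <- function(records, by = "system") {
  .check_records(records, c("ddg_pred", "ddg_exp", by))
  groups <- split(seq_len(nrow(records)), records[[by]])
  records$ddg_rescaled <- NA_real_
  slopes <- data.frame(subset = character(), slope = numeric(),
                       n = integer(), stringsAsFactors = FALSE)
  for (g in names(groups)) {
    idx <- groups[[g]]
    sub <- records[idx, , drop = FALSE]
    if (nrow(sub) < 3 || stats::sd(sub$ddg_pred) == 0) {
      warning("subset ", g, " degenerate (n < 3 or zero variance); skipped")
      next
    }
    sl <- unname(stats::coef(stats::lm(ddg_exp ~ ddg_pred,
                                       data = sub))["ddg_pred"])
    records$ddg_rescaled[idx] <- sl * sub$ddg_pred
    slopes <- rbind(slopes, data.frame(subset = g, slope = sl,
                                       n = nrow(sub),
                                       stringsAsFactors = FALSE))
  }
  list(slopes = slopes, records = records)
}

#' Select benchmark systems for a prospective-optimisation test set
#'
#' Applies the two selection rules for assembling a mutation benchmark
#' that resembles a real affinity-optimisation project: each system must
#' contain at least one unambiguously favourable mutation
#' (`ddg_exp <= favorable_cutoff`, default -0.5 kcal/mol) and at least
#' `min_nonala` (default 25 percent) of its mutations must be to side
#' chains other than alanine.  Among near-duplicate systems (same
#' `dup_group` label) the one with the most favourable mutations is
#' kept.
#'
#' @param tables named list of data.frames, one per candidate system,
#'   each with columns `ddg_exp` and `mt_aa` (one-letter mutant code).
#' @param favorable_cutoff kcal/mol.
#' @param min_nonala minimum fraction of non-alanine mutations.
#' @param dup_groups optional named character vector mapping system name
#'   to a duplicate-group label.
#' @return character vector of kept system names.
#' @export
select_systems <- function(tables, favorable_cutoff = -0.5,
                           min_nonala = 0.25, dup_groups = NULL) {
  stopifnot(is.list(tables), length(names(tables)) == length(tables))
  ok <- vapply(tables, function(tab) {
    stopifnot(all(c("ddg_exp", "mt_aa") %in% names(tab)))
    any(tab$ddg_exp <= favorable_cutoff) &&
      mean(toupper(tab$mt_aa) != "A") >= min_nonala
  }, TRUE)
  kept <- names(tables)[ok]
  if (!is.null(dup_groups)) {
    n_fav <- vapply(tables, function(tab)
      sum(tab$ddg_exp <= favorable_cutoff), 0L)
    for (grp in unique(dup_groups[kept])) {
      members <- kept[!is.na(dup_groups[kept]) & dup_groups[kept] == grp]
      if (length(members) > 1) {
        best <- members[order(-n_fav[members], members)][1]
        kept <- setdiff(kept, setdiff(members, best))
      }
    }
  }
  kept
}

#' Read a predictions/experiment table
#'
#' TSV with columns `system`, `mutation`, `ddg_exp`, `ddg_pred`,
#' `buried`, `method`, and optionally the per-protonation-state columns
#' `ddg_protonated`, `ddg_charged`, `penalty_included`.
#'
#' @param path input TSV.
#' @return validated data.frame.
#' @export
read_predictions <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  .check_records(tab, c("system", "mutation", "ddg_exp", "ddg_pred"))
  if (!is.null(tab$buried)) tab$buried <- as.logical(tab$buried)
  tab
}
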