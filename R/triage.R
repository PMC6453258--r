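# Triage pipeline: validate -> strain filter -> burial classification ->
# salt-bridge flagging -> protonation planning, with per-mutation
# recommended FEP settings and TSV/JSON reports.

#' Recommended FEP settings for a mutation
#'
#' Charge-changing perturbations need denser lambda schedules (24 windows
#' rather than 12) and a larger solvent buffer (8.5 rather than 5
#' Angstrom) for the co-alchemical ion protocol; mutations touching
#' salt-bridge networks, and all cases built on homology models, warrant
#' extended sampling of 100 ns per window.
#'
#' @param charge_changing logical.
#' @param extended logical: extended-sampling trigger.
#' @return a `fep_recommendation` list: `lambda_windows`, `buffer_A`,
#'   `extended_ns`.
#' @export
fep_recommendation <- function(charge_changing, extended = FALSE) {
  structure(list(lambda_windows = if (charge_changing) 24L else 12L,
                 buffer_A = if (charge_changing) 8.5 else 5.0,
                 extended_ns = if (extended) 100L else NA_integer_),
            class = "fep_recommendation")
}

#' Run the pre-FEP triage pipeline
#'
#' For each proposed mutation: validates it against the structure
#' (proline and histidine mutants are refused), evaluates side-chain
#' placeability by rotamer strain, classifies the site's burial by
#' fractional SASA in the bound complex, flags salt-bridge involvement
#' for extended sampling, and -- when per-state predicted values are
#' supplied -- plans the protonation-state selection.  The verdict is
#' `rejected_unplaceable` when no acceptable side-chain placement exists,
#' `deprioritized_buried` for placeable but buried sites (kept for
#' scientific interest, unpromising for affinity optimisation), and
#' `send_to_fep` otherwise.
#'
#' @param s an `fep_structure`.
#' @param mutations list of `mutation_spec` (or character vector of
#'   compact specifications).
#' @param strain_cfg,sasa_cfg,bridge_cfg,prot_cfg module configurations.
#' @param lib rotamer library.
#' @param predictions optional data.frame in [read_predictions()] layout
#'   with per-state columns, matched by mutation string.
#' @param homology_model is the input a homology model?  If so, extended
#'   sampling is recommended for every case.
#' @return a `triage_result`: list with `records` (list of
#'   `triage_record`), `failures` (data.frame of invalid inputs) and
#'   `counts` (verdict tally).
#' @export
run_triage <- function(s, mutations,
                       strain_cfg = strain_config(),
                       sasa_cfg = sasa_config(),
                       bridge_cfg = saltbridge_config(),
                       prot_cfg = protonation_config(),
                       lib = default_rotamer_library(),
                       predictions = NULL,
                       homology_model = FALSE) {
  stopifnot(inherits(s, "fep_structure"))
  if (is.character(mutations)) mutations <- parse_mutation(mutations)
  if (inherits(mutations, "mutation_spec")) mutations <- list(mutations)
  graph <- detect_bridges(s, bridge_cfg)
  records <- list()
  failures <- data.frame(mutation = character(), error = character(),
                         stringsAsFactors = FALSE)
  for (m in mutations) {
    step <- tryCatch({
      m <- validate_mutation(s, m)
      if (m$mt %in% c("P", "H"))
        stop("mutant type ", .AA3[[m$mt]], " is excluded from triage ",
             "(nonstandard backbone / unresolvable protonation)")
      m
    }, error = function(e) e)
    if (inherits(step, "error")) {
      failures <- rbind(failures, data.frame(
        mutation = format(m), error = conditionMessage(step),
        stringsAsFactors = FALSE))
      next
    }
    m <- step
    placement <- place_mutant(s, m, lib, strain_cfg)
    burial <- residue_fsasa(s, m$key, sasa_cfg)
    bridge <- flag_extended_sampling(graph, m)
    plan <- NULL
    if (!is.null(predictions)) {
      row <- predictions[predictions$mutation == format(m), , drop = FALSE]
      if (nrow(row) == 1 && !is.null(row$ddg_protonated) &&
          is.finite(row$ddg_protonated) && is.finite(row$ddg_charged)) {
        plan <- select_final(
          c(protonated = row$ddg_protonated, charged = row$ddg_charged),
          cfg = prot_cfg,
          penalty_included = isTRUE(as.logical(row$penalty_included)))
      }
    }
    verdict <- if (!placement$placeable) "rejected_unplaceable"
    else if (burial$buried) "deprioritized_buried"
    else "send_to_fep"
    rec <- fep_recommendation(m$charge_changing,
                              extended = bridge$flag || homology_model)
    records[[format(m)]] <- structure(
      list(mutation = format(m), key = m$key, wt = m$wt, mt = m$mt,
           charge_changing = m$charge_changing,
           placement = placement, burial = burial,
           saltbridge_flag = bridge$flag,
           saltbridge_reason = bridge$reason,
           protonation = plan, recommendation = rec,
           verdict = verdict),
      class = "triage_record")
  }
  counts <- table(factor(vapply(records, `[[`, "", "verdict"),
                         levels = c("rejected_unplaceable",
                                    "deprioritized_buried",
                                    "send_to_fep")))
  structure(list(structure_id = s$id, records = records,
                 failures = failures, counts = counts),
            class = "triage_result")
}

#' @export
print.triage_result <- function(x, ...) {
  cat("<triage_result> ", x$structure_id, ": ", length(x$records),
      " mutation(s) triaged, ", nrow(x$failures), " invalid\n", sep = "")
  print(x$counts)
  invisible(x)
}

#' @export
as.data.frame.triage_result <- function(x, ...) {
  if (length(x$records) == 0)
    return(data.frame(mutation = character()))
  do.call(rbind, lapply(x$records, function(r) {
    data.frame(
      mutation = r$mutation,
      charge_changing = r$charge_changing,
      strain_wt = r$placement$strain_wt,
      strain_mt = r$placement$strain_mt,
      delta_strain = r$placement$delta_strain,
      placeable = r$placement$placeable,
      sasa_A2 = r$burial$sasa,
      fsasa_percent = floor(r$burial$fsasa * 100 + 0.5),
      buried = r$burial$buried,
      saltbridge = r$saltbridge_flag,
      final_ddg = if (is.null(r$protonation)) NA_real_
                  else r$protonation$final_ddg,
      selected_state = if (is.null(r$protonation)) ""
                       else r$protonation$selected_state,
      lambda_windows = r$recommendation$lambda_windows,
      buffer_A = r$recommendation$buffer_A,
      extended_ns = r$recommendation$extended_ns,
      verdict = r$verdict,
      reason = r$placement$reason,
      row.names = NULL, stringsAsFactors = FALSE)
  }))
}

#' Write and read triage reports
#'
#' `write_report()` emits a TSV (stable column order, integer-percent
#' fSASA) and a versioned JSON report (full precision);
#' `read_report()` restores the JSON into the data.frame form of
#' [as.data.frame.triage_result()].
#'
#' @param result a `triage_result`.
#' @param tsv,json output paths (either may be `NULL` to skip).
#' @return invisibly, the report data.frame.
#' @export
write_report <- function(result, tsv = NULL, json = NULL) {
  stopifnot(inherits(result, "triage_result"))
  df <- as.data.frame(result)
  if (!is.null(tsv)) {
    out <- df
    out$delta_strain <- ifelse(is.finite(out$delta_strain),
                               sprintf("%.3f", out$delta_strain), "inf")
    utils::write.table(out, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(json)) {
    payload <- list(schema = "fepscout/triage-report/1",
                    structure_id = result$structure_id,
                    counts = as.list(result$counts),
                    failures = result$failures,
                    records = df)
    jsonlite::write_json(payload, json, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  invisible(df)
}

#' @rdname write_report
#' @param path JSON report path.
#' @export
read_report <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$schema, "fepscout/triage-report/1"))
    stop("unrecognised report schema: ", payload$schema)
  df <- payload$records
  df$delta_strain[!is.finite(df$delta_strain)] <- Inf
  df$extended_ns <- as.integer(df$extended_ns)
  df
}
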