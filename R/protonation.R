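# Protonation-state planning for carboxylate side chains involved in a
# mutation: state enumeration, the pKa-based state penalty, and selection
# of the final binding free-energy change from per-state FEP estimates
# supplied as input.

.KB_KCAL <- 0.001987204259 # Boltzmann constant, kcal/mol/K

#' Protonation configuration
#'
#' @param pH assay pH (default 7.0).
#' @param model_pkas model pKa values of the ionisable acid side chains;
#'   textbook defaults ASP 3.8, GLU 4.4, configurable.
#' @param temperature Kelvin; RT in kcal/mol is derived from it.
#' @return a `protonation_config` list with derived element `RT`.
#' @export
protonation_config <- function(pH = 7.0,
                               model_pkas = c(ASP = 3.8, GLU = 4.4),
                               temperature = 298.15) {
  stopifnot(all(model_pkas > 0), temperature > 0)
  structure(list(pH = pH, model_pkas = model_pkas,
                 temperature = temperature,
                 RT = .KB_KCAL * temperature),
            class = "protonation_config")
}

#' One protonation-state assignment
#'
#' Describes the protonation state of the ionisable acid side chain (on
#' the wild-type or mutant side of the perturbation) in the bound complex
#' and in the unbound protein.  ASH/GLH are the neutral (protonated)
#' forms of ASP/GLU.
#'
#' @param role `"wild_type"` or `"mutant"`: which end state carries the
#'   acid.
#' @param complex_state,unbound_state three-letter codes (ASP/ASH or
#'   GLU/GLH, or any standard code for the trivial assignment).
#' @param label short state label, e.g. `"charged"` or `"protonated"`.
#' @param rationale free-text justification.
#' @return a `state_assignment` list.
#' @export
state_assignment <- function(role, complex_state, unbound_state,
                             label, rationale = "") {
  role <- match.arg(role, c("wild_type", "mutant"))
  pairs <- list(ASH = "ASP", GLH = "GLU")
  ok <- function(cs, us) {
    cs == us ||
      (cs %in% names(pairs) && pairs[[cs]] == us) ||
      (us %in% names(pairs) && pairs[[us]] == cs)
  }
  if (!ok(toupper(complex_state), toupper(unbound_state)))
    stop("inconsistent states: complex ", complex_state, " vs unbound ",
         unbound_state)
  structure(list(role = role, complex_state = toupper(complex_state),
                 unbound_state = toupper(unbound_state), label = label,
                 rationale = rationale),
            class = "state_assignment")
}

#' Enumerate protonation states for a mutation
#'
#' Mutations with no aspartate/glutamate end state get the single default
#' assignment (standard charged states).  When an end state is an acid,
#' two assignments are produced: charged throughout, and protonated in
#' the complex.  For the protonated branch the unbound state is
#' protonated only when the site is buried in the unbound protein as well
#' (`buried_unbound = TRUE`); otherwise the acid is taken as charged when
#' unbound, which later incurs the state penalty.
#'
#' Wild-type-side assignments that rest on system-specific evidence
#' (e.g. a neutral acid stabilised by an adjacent carboxylate) should be
#' constructed directly with [state_assignment()] and passed to
#' [select_final()]; they are inputs, not inferences.
#'
#' @param m a `mutation_spec`.
#' @param buried_unbound is the site buried in the unbound protein too?
#' @return list of `state_assignment`.
#' @export
enumerate_states <- function(m, buried_unbound = FALSE) {
  stopifnot(inherits(m, "mutation_spec"))
  acid_role <- if (m$mt %in% c("D", "E")) "mutant"
  else if (m$wt %in% c("D", "E")) "wild_type"
  else NA_character_
  if (is.na(acid_role)) {
    return(list(state_assignment(
      "mutant", .AA3[[m$mt]], .AA3[[m$mt]], "standard",
      "no ionisable acid end state")))
  }
  acid3 <- .AA3[[if (acid_role == "mutant") m$mt else m$wt]]
  prot3 <- c(ASP = "ASH", GLU = "GLH")[[acid3]]
  list(
    state_assignment(acid_role, acid3, acid3, "charged",
                     "acid charged throughout"),
    state_assignment(acid_role, prot3,
                     if (buried_unbound) prot3 else acid3, "protonated",
                     if (buried_unbound)
                       "buried in both forms: protonated throughout"
                     else
                       "protonates on binding; unbound charged at assay pH")
  )
}

#' State penalty for protonation on binding
#'
#' When the acid is charged in the unbound protein but protonated in the
#' complex, populating the neutral form in the unbound state at assay pH
#' costs `2.303 * RT * (pH - pKa)` kcal/mol (the Henderson-Hasselbalch
#' population cost; the bound form is assumed fully protonated, i.e. the
#' pKa shift on binding is taken as very large, so no bound-state term
#' appears).  Assignments whose state does not change between bound and
#' unbound incur no penalty.
#'
#' @param assignment a [state_assignment()].
#' @param cfg a [protonation_config()].
#' @return penalty in kcal/mol (0 when no state change).
#' @export
state_penalty <- function(assignment, cfg = protonation_config()) {
  stopifnot(inherits(assignment, "state_assignment"))
  cs <- assignment$complex_state
  us <- assignment$unbound_state
  prot_of <- c(ASH = "ASP", GLH = "GLU")
  # only protonated-in-complex / charged-when-unbound changes state on
  # binding and is penalised
  if (!(cs %in% names(prot_of) && identical(prot_of[[cs]], us)))
    return(0)
  if (!us %in% names(cfg$model_pkas))
    stop("no model pKa for residue type ", us,
         "; extend model_pkas in protonation_config()")
  pka <- cfg$model_pkas[[us]]
  2.303 * cfg$RT * (cfg$pH - pka)
}

#' Select the final binding free-energy change across protonation states
#'
#' Given externally supplied per-state FEP estimates of the relative
#' binding free energy, applies the state penalty to any state not
#' already penalty-corrected and selects the state with the lower implied
#' free energy of binding.
#'
#' @param values named numeric vector of per-state predicted changes in
#'   binding free energy, kcal/mol, named by state label (e.g.
#'   `c(protonated = 3.23, charged = 28.89)`).
#' @param assignments list of [state_assignment()] matching `values` by
#'   label (optional when `penalty_included` is all `TRUE`).
#' @param cfg a [protonation_config()].
#' @param penalty_included logical (recycled): is the state penalty
#'   already folded into the supplied value?  Spreadsheet FEP results
#'   normally are.
#' @return a `protonation_plan`: `per_state` (implied values after
#'   penalty), `penalty`, `selected_state`, `final_ddg`.
#' @export
select_final <- function(values, assignments = NULL,
                         cfg = protonation_config(),
                         penalty_included = TRUE) {
  if (length(values) == 0) stop("no per-state values supplied")
  if (is.null(names(values)) || any(!nzchar(names(values))))
    stop("per-state values must be named by state label")
  penalty_included <- rep_len(penalty_included, length(values))
  pen <- vapply(seq_along(values), function(i) {
    if (penalty_included[i]) return(0)
    if (is.null(assignments))
      stop("assignments needed to compute penalties for uncorrected values")
    a <- assignments[[which(vapply(assignments, `[[`, "", "label") ==
                              names(values)[i])[1]]]
    state_penalty(a, cfg)
  }, 0)
  implied <- values + pen
  # deterministic tie-break: first label in sorted order
  ord <- order(implied, names(values))
  sel <- ord[1]
  structure(list(per_state = implied, penalty = pen,
                 selected_state = names(values)[sel],
                 final_ddg = unname(implied[sel])),
            class = "protonation_plan")
}

#' @export
print.protonation_plan <- function(x, ...) {
  cat("<protonation_plan> final ddG =", sprintf("%.2f", x$final_ddg),
      "kcal/mol via state", shQuote(x$selected_state), "\n")
  for (i in seq_along(x$per_state))
    cat(sprintf("  %-12s implied %7.2f (penalty %+.2f)\n",
                names(x$per_state)[i], x$per_state[i], x$penalty[i]))
  invisible(x)
}

#' Packaged example of nonstandard protonation-state cases
#'
#' A curated example table of charge-changing interface mutations in
#' three well-studied complexes (barnase-barstar and two protease-
#' inhibitor systems, plus antibody cases) where a carboxylate is modelled
#' neutral: per-case state assignments and per-state predicted binding
#' free-energy changes (penalty already folded in), for exercising
#' [select_final()] and the triage report.
#'
#' @return data.frame with columns `system`, `chain`, `resnum`, `wt`,
#'   `mt`, `fsasa_pct`, `role`, `complex_state`, `unbound_state`,
#'   `comment`, `ddg_protonated`, `ddg_charged`, `penalty_included`.
#' @export
protonation_examples <- function() {
  path <- system.file("extdata", "protonation_cases_example.tsv",
                      package = "fepscout", mustWork = TRUE)
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
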