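#' Define an intervention scenario
#'
#' A scenario is a named set of lesion-resistance overrides (ohm) applied on
#' top of a model's lesion table -- the baseline state, stepwise PCI, or a
#' theoretical alternative.  Overrides apply to lesions only; segment or bed
#' resistances are edited on the model itself, an explicit separate
#' mechanism, to prevent silent misuse.
#'
#' @param name Scenario name.
#' @param overrides Named numeric vector or list: lesion id -> resistance.
#' @return An object of class `"scenario"`.
#' @export
scenario <- function(name, overrides = list()) {
  ov <- vapply(overrides, as.numeric, numeric(1))
  structure(list(name = as.character(name), overrides = ov),
            class = "scenario")
}

#' Simulate PCI to one lesion
#'
#' Returns a new model (the input is unmodified) with the lesion's
#' resistance replaced by the residual left by an effective stent, 0.1 ohm
#' by default.  A residual of exactly zero is disallowed (minimum 1e-9 ohm).
#'
#' @param spec A [coronary_spec()].
#' @param lesion_id Lesion to treat.
#' @param residual_resistance Post-stent residual resistance (ohm).
#' @return A new `coronary_spec`.
#' @export
apply_intervention <- function(spec, lesion_id, residual_resistance = 0.1) {
  stopifnot(inherits(spec, "coronary_spec"))
  if (!lesion_id %in% spec$lesions$id)
    stop(errorCondition(sprintf("unknown lesion '%s'", lesion_id),
                        class = c("coranalog_unknown_lesion",
                                  "coranalog_error")))
  if (!is.finite(residual_resistance) || residual_resistance < R_MIN)
    stop(sprintf("residual_resistance must be >= %g ohm", R_MIN))
  spec$lesions$resistance[spec$lesions$id == lesion_id] <-
    residual_resistance
  spec
}

# apply a scenario's lesion overrides to a spec (validated by the caller)
.apply_scenario <- function(spec, sc) {
  for (lid in names(sc$overrides))
    spec$lesions$resistance[spec$lesions$id == lid] <- sc$overrides[[lid]]
  spec
}

#' Run named scenarios and tabulate probe ratios and bed flows
#'
#' One DC solve per scenario, rows in input order, fully deterministic.
#' The result is the machine twin of a simulation results table: per
#' scenario, the lesion resistances applied, the FFR-analog voltage ratio
#' at every probe, and the current through every myocardial bed.
#'
#' @param spec A [coronary_spec()].
#' @param scenarios List of [scenario()] objects; defaults to the scenarios
#'   declared on the model.
#' @param convention FFR convention passed to [ffr_at()].
#' @return An object of class `"coronary_results"`: list with matrices
#'   `lesion_resistance` (lesions x scenarios), `ratios` and `voltages`
#'   (probes x scenarios), `currents` (beds x scenarios), plus the per-
#'   scenario `solutions` and the `spec`.
#' @section Errors: build or solve failures are re-signalled tagged with the
#'   failing scenario's name.
#' @export
run_scenarios <- function(spec, scenarios = NULL,
                          convention = c("input", "physiologic")) {
  stopifnot(inherits(spec, "coronary_spec"))
  convention <- match.arg(convention)
  if (is.null(scenarios)) scenarios <- spec$scenarios
  scenarios <- .normalize_scenarios(scenarios)
  for (sc in scenarios) {
    bad <- setdiff(names(sc$overrides), spec$lesions$id)
    if (length(bad))
      stop(errorCondition(
        sprintf("scenario '%s': unknown lesion(s) %s", sc$name,
                paste(sQuote(bad), collapse = ", ")),
        class = c("coranalog_schema_error", "coranalog_error")))
  }
  nsc <- length(scenarios)
  sn <- unname(vapply(scenarios, `[[`, character(1), "name"))
  lesion_resistance <- matrix(NA_real_, nrow(spec$lesions), nsc,
                              dimnames = list(spec$lesions$id, sn))
  ratios <- matrix(NA_real_, nrow(spec$probes), nsc,
                   dimnames = list(spec$probes$id, sn))
  voltages <- ratios
  currents <- matrix(NA_real_, nrow(spec$beds), nsc,
                     dimnames = list(spec$beds$id, sn))
  solutions <- stats::setNames(vector("list", nsc), sn)
  for (k in seq_len(nsc)) {
    sc <- scenarios[[k]]
    sp_k <- .apply_scenario(spec, sc)
    sol <- tryCatch(solve_dc(build_circuit(sp_k)), error = function(err)
      stop(errorCondition(
        sprintf("scenario '%s': %s", sc$name, conditionMessage(err)),
        class = c("coranalog_scenario_error", class(err)))))
    lesion_resistance[, k] <- sp_k$lesions$resistance
    for (p in spec$probes$id) {
      r <- ffr_at(sol, sp_k, p, convention)
      ratios[p, k] <- r$ffr_analog
      voltages[p, k] <- r$voltage
    }
    for (b in spec$beds$id)
      currents[b, k] <- element_current(sol, b)
    solutions[[k]] <- sol
  }
  structure(list(scenario_names = sn, lesion_resistance = lesion_resistance,
                 ratios = ratios, voltages = voltages, currents = currents,
                 solutions = solutions, spec = spec,
                 convention = convention),
            class = "coronary_results")
}

#' @export
print.coronary_results <- function(x, ...) {
  cat(format_results_text(x), sep = "\n")
  invisible(x)
}

#' @describeIn run_scenarios Long-format data frame of a results table:
#'   columns `scenario`, `quantity_kind` (`lesion_resistance`,
#'   `voltage_ratio`, `bed_current`), `location`, `value`.
#' @param x A `coronary_results` object.
#' @param row.names,optional,... Ignored; standard [as.data.frame()]
#'   arguments.
#' @export
as.data.frame.coronary_results <- function(x, row.names = NULL,
                                           optional = FALSE, ...) {
  blocks <- list(lesion_resistance = x$lesion_resistance,
                 voltage_ratio = x$ratios,
                 bed_current = x$currents)
  out <- do.call(rbind, lapply(names(blocks), function(kind) {
    m <- blocks[[kind]]
    if (length(m) == 0 || ncol(m) == 0)
      return(data.frame(scenario = character(), quantity_kind = character(),
                        location = character(), value = numeric(),
                        stringsAsFactors = FALSE))
    data.frame(scenario = rep(colnames(m), each = nrow(m)),
               quantity_kind = kind,
               location = rep(rownames(m), ncol(m)),
               value = as.vector(m), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

.lookup_scenario <- function(results, name) {
  if (!name %in% results$scenario_names)
    stop(errorCondition(sprintf("unknown scenario '%s'", name),
                        class = c("coranalog_unknown_scenario",
                                  "coranalog_error")))
  name
}

#' Voltage drop and current through a lesion in two scenarios
#'
#' Quantifies the interaction between serial stenoses: after relieving a
#' distal lesion, hyperemic flow through the artery rises and with it the
#' pressure drop across the remaining proximal lesion, even though that
#' lesion's own resistance is unchanged.
#'
#' @param results A [run_scenarios()] table.
#' @param scenario_a,scenario_b Scenario names to compare.
#' @param lesion_id Lesion (circuit element) to measure across.
#' @return List of class `"serial_gradient"`: `drop_a`, `drop_b` (V),
#'   `current_a`, `current_b` (A).
#' @export
serial_lesion_gradient <- function(results, scenario_a, scenario_b,
                                   lesion_id) {
  stopifnot(inherits(results, "coronary_results"))
  a <- .lookup_scenario(results, scenario_a)
  b <- .lookup_scenario(results, scenario_b)
  measure <- function(sol) {
    cur <- element_current(sol, lesion_id)   # errors if unknown
    e <- sol$circuit$elements
    e <- e[e$id == lesion_id, ]
    list(drop = sol$node_voltage[[e$node_a]] - sol$node_voltage[[e$node_b]],
         current = cur)
  }
  ma <- measure(results$solutions[[a]])
  mb <- measure(results$solutions[[b]])
  structure(list(lesion = lesion_id, scenario_a = a, scenario_b = b,
                 drop_a = ma$drop, drop_b = mb$drop,
                 current_a = ma$current, current_b = mb$current),
            class = "serial_gradient")
}

#' @export
print.serial_gradient <- function(x, ...) {
  cat(sprintf(
    "Lesion '%s': drop %.3g -> %.3g V, current %.3g -> %.3g A (%s -> %s)\n",
    x$lesion, x$drop_a, x$drop_b, x$current_a, x$current_b,
    x$scenario_a, x$scenario_b))
  invisible(x)
}

#' Coronary steal report for a myocardial bed
#'
#' Compares the flow into one bed between two scenarios.  `steal_index` is
#' the relative flow change `(flow_after - flow_before) / flow_before` (the
#' package's normalization of the raw ampere change); `is_steal` is `TRUE`
#' exactly when the index is negative, i.e. the intervention diverted flow
#' away from the bed (classically: PCI of a collateral donor vessel
#' lowering flow to the collateral-dependent territory).
#'
#' @inheritParams serial_lesion_gradient
#' @param bed_id Myocardial bed id.
#' @return List of class `"steal_report"`: `territory`, `flow_before`,
#'   `flow_after` (A), `steal_index`, `is_steal`.
#' @export
steal_report <- function(results, scenario_a, scenario_b, bed_id) {
  stopifnot(inherits(results, "coronary_results"))
  a <- .lookup_scenario(results, scenario_a)
  b <- .lookup_scenario(results, scenario_b)
  if (!bed_id %in% rownames(results$currents))
    stop(errorCondition(sprintf("unknown bed '%s'", bed_id),
                        class = c("coranalog_unknown_bed",
                                  "coranalog_error")))
  before <- results$currents[bed_id, a]
  after <- results$currents[bed_id, b]
  idx <- (after - before) / before
  structure(list(territory = bed_id, flow_before = before,
                 flow_after = after, steal_index = idx,
                 is_steal = idx < 0), class = "steal_report")
}

#' @export
print.steal_report <- function(x, ...) {
  cat(sprintf("Bed '%s': flow %.3f -> %.3f A (%+.1f%%)%s\n",
              x$territory, x$flow_before, x$flow_after,
              100 * x$steal_index,
              if (x$is_steal) " -- coronary steal" else ""))
  invisible(x)
}
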