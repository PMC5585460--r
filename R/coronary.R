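# Node names reserved for the compiled circuit.
ARTERIAL_NODE <- "arterial"
GROUND_NODE <- "gnd"

#' Leaman flow fractions by coronary dominance
#'
#' Fraction of left-ventricular flow subtended by each terminal coronary
#' territory, after the Leaman weighting.  In a right-dominant system the
#' RCA supplies 16% and the left main stem 84% of LV mass, with two-thirds
#' of left-main flow down the LAD and one-third to the LCx.  In a
#' left-dominant system the RCA share is taken up by the LCx: 58% of
#' left-main flow to the LAD and 42% to the LCx.
#'
#' @param dominance `"right"` or `"left"`.
#' @return Named numeric vector of percentages summing to 100 across
#'   terminal territories.
#' @examples
#' leaman_flow_fractions("right")  # LAD 56, LCx 28, RCA 16
#' @export
leaman_flow_fractions <- function(dominance = c("right", "left")) {
  dominance <- match.arg(dominance)
  if (dominance == "right") {
    lms <- 84
    c(LAD = 2 / 3 * lms, LCx = 1 / 3 * lms, RCA = 16)
  } else {
    c(LAD = 58, LCx = 42)
  }
}

#' Myocardial bed resistances
#'
#' Bed resistance is inversely related to the mass of myocardium perfused
#' (parallel resistive vessels).  Two modes:
#' \describe{
#'   \item{`preset`}{the package's reference values for a right-dominant
#'     system -- RCA 30, LCx 20, LAD 10 ohm.  Not defined for left
#'     dominance, which raises an unsupported-combination error.}
#'   \item{`leaman_inverse`}{`R_i = scale_constant / fraction_i`, with
#'     fractions from [leaman_flow_fractions()]; covers either dominance.}
#' }
#'
#' @param mode `"preset"` or `"leaman_inverse"`.
#' @param dominance `"right"` or `"left"`.
#' @param scale_constant Positive scale (ohm x percent) for
#'   `leaman_inverse`; ignored for `preset`.
#' @return Named numeric vector of resistances (ohm) per territory.
#' @examples
#' bed_resistances("preset", "right")
#' bed_resistances("leaman_inverse", "right", scale_constant = 560)
#' @export
bed_resistances <- function(mode = c("preset", "leaman_inverse"),
                            dominance = c("right", "left"),
                            scale_constant = NULL) {
  mode <- match.arg(mode)
  dominance <- match.arg(dominance)
  if (mode == "preset") {
    if (dominance != "right")
      stop(errorCondition(
        "preset bed resistances are only defined for right dominance; use mode = 'leaman_inverse' for a left-dominant system",
        class = c("coranalog_unsupported", "coranalog_error")))
    return(c(LAD = 10, LCx = 20, RCA = 30))
  }
  if (is.null(scale_constant) || !is.finite(scale_constant) ||
      scale_constant <= 0)
    stop("scale_constant must be a positive number for leaman_inverse mode")
  fr <- leaman_flow_fractions(dominance)
  scale_constant / fr
}

.spec_df <- function(x, cols) {
  # normalize a list-of-rows or data frame into a data frame with `cols`;
  # missing optional columns are filled with NA
  if (is.null(x) || (is.list(x) && length(x) == 0))
    x <- data.frame()
  if (!is.data.frame(x)) {
    x <- do.call(rbind, lapply(x, function(row) {
      row <- row[!vapply(row, is.null, logical(1))]
      as.data.frame(row, stringsAsFactors = FALSE)
    }))
    if (is.null(x)) x <- data.frame()
  }
  for (nm in names(cols)) {
    if (!nm %in% names(x))
      x[[nm]] <- if (nrow(x)) rep(cols[[nm]], nrow(x)) else cols[[nm]][0]
  }
  x <- x[, names(cols), drop = FALSE]
  rownames(x) <- NULL
  x
}

#' Declare a coronary tree model
#'
#' A vascular-domain description that [build_circuit()] compiles to a DC
#' resistor network: epicardial segments (near-zero resistance conductance
#' vessels), discrete lesions placed in series within a segment, myocardial
#' beds draining to a common venous node, optional collateral channels, the
#' arterial and venous source pressures, an inflow (aorta / left-main
#' equivalent) series resistance, probe locations, and named scenarios of
#' lesion-resistance overrides.
#'
#' All validation failures are collected and reported together (condition
#' class `coranalog_schema_error`), each prefixed with the offending field
#' path.
#'
#' @param segments Data frame (or list of rows) with `id`, `proximal_node`,
#'   `distal_node`, `resistance` (ohm, >= 1e-9; values at the minimum are
#'   compiled as ideal wires).
#' @param lesions Data frame with `id`, `segment_id`, `resistance` (ohm),
#'   optional `description`.
#' @param beds Data frame with `id`, `feeding_node`, `resistance` (ohm),
#'   optional `leaman_weight` (percent of LV mass, in (0, 100]),
#'   `drains_to` (the venous node; identical for all beds).
#' @param collaterals Data frame with `id`, `donor_node`, `recipient_node`,
#'   `resistance` (ohm); may be empty.
#' @param probes Data frame with `id`, `node`.
#' @param arterial_pressure Source voltage (V = mmHg), default 100.
#' @param venous_pressure Outflow voltage (V = mmHg), default 5.
#' @param inflow_resistance Series resistance between the arterial source
#'   and `root_node` (ohm).
#' @param root_node Name of the node the inflow resistor feeds.
#' @param dominance `"right"` or `"left"`.
#' @param scenarios Named list; each entry a list with `name` and
#'   `overrides` (named lesion id -> resistance map), or just the override
#'   map itself.
#' @param name Optional model name.
#' @param metadata Optional free-form list, carried through untouched.
#' @return An object of class `"coronary_spec"`.
#' @seealso [reference_case()] for a complete worked model.
#' @export
coronary_spec <- function(segments, lesions = NULL, beds,
                          collaterals = NULL, probes = NULL,
                          arterial_pressure = 100, venous_pressure = 5,
                          inflow_resistance = 1e-9, root_node = "ostium",
                          dominance = "right", scenarios = list(),
                          name = NULL, metadata = list()) {
  spec <- structure(list(
    name = name,
    segments = .spec_df(segments, list(id = NA_character_,
                                       proximal_node = NA_character_,
                                       distal_node = NA_character_,
                                       resistance = NA_real_)),
    lesions = .spec_df(lesions, list(id = NA_character_,
                                     segment_id = NA_character_,
                                     resistance = NA_real_,
                                     description = NA_character_)),
    beds = .spec_df(beds, list(id = NA_character_,
                               feeding_node = NA_character_,
                               resistance = NA_real_,
                               leaman_weight = NA_real_,
                               drains_to = "venous")),
    collaterals = .spec_df(collaterals, list(id = NA_character_,
                                             donor_node = NA_character_,
                                             recipient_node = NA_character_,
                                             resistance = NA_real_)),
    probes = .spec_df(probes, list(id = NA_character_,
                                   node = NA_character_)),
    arterial_pressure = as.numeric(arterial_pressure),
    venous_pressure = as.numeric(venous_pressure),
    inflow_resistance = as.numeric(inflow_resistance),
    root_node = root_node,
    dominance = dominance,
    scenarios = .normalize_scenarios(scenarios),
    metadata = metadata), class = "coronary_spec")
  problems <- validate_spec(spec)
  if (length(problems))
    stop(errorCondition(
      paste0("invalid coronary model:\n",
             paste("  -", problems, collapse = "\n")),
      class = c("coranalog_schema_error", "coranalog_error"),
      problems = problems))
  spec
}

.normalize_scenarios <- function(scenarios) {
  if (is.null(scenarios)) return(list())
  out <- list()
  nms <- names(scenarios)
  for (i in seq_along(scenarios)) {
    s <- scenarios[[i]]
    if (inherits(s, "scenario")) {
      out[[s$name]] <- s
    } else if (is.list(s) && !is.null(s$name)) {
      out[[s$name]] <- scenario(s$name, s$overrides)
    } else {
      out[[nms[i]]] <- scenario(nms[i], s)
    }
  }
  out
}

#' Validate a coronary model, collecting all problems
#'
#' @param spec A [coronary_spec()] (or a candidate list of the same shape).
#' @return Character vector of problems, each with a field path; empty if
#'   valid.
#' @export
validate_spec <- function(spec) {
  p <- character()
  add <- function(...) p <<- c(p, sprintf(...))
  seg <- spec$segments; les <- spec$lesions; beds <- spec$beds
  col <- spec$collaterals; pr <- spec$probes
  ids <- c(seg$id, les$id, beds$id, col$id, "inflow")
  for (d in unique(ids[duplicated(ids)]))
    add("id '%s' is not unique across segments/lesions/beds/collaterals (and the reserved id 'inflow')", d)
  # 'arterial' is the aortic root (legal anchor for vessels with their own
  # ostium, e.g. the RCA); 'gnd' is the solver reference and never a vessel
  vascular_nodes <- unique(c(ARTERIAL_NODE, spec$root_node,
                             seg$proximal_node, seg$distal_node))
  reserved <- GROUND_NODE
  for (n in intersect(c(seg$proximal_node, seg$distal_node), reserved))
    add("segments: node name '%s' is reserved", n)
  if (any(seg$distal_node == ARTERIAL_NODE))
    add("segments: '%s' may only be a proximal (ostial) node",
        ARTERIAL_NODE)
  if (nrow(seg) == 0) add("segments: at least one segment is required")
  for (i in seq_len(nrow(seg))) {
    if (is.na(seg$resistance[i]) || seg$resistance[i] < R_MIN)
      add("segments[%s].resistance: must be >= %g ohm", seg$id[i], R_MIN)
  }
  for (i in seq_len(nrow(les))) {
    if (!les$segment_id[i] %in% seg$id)
      add("lesions[%s].segment_id: references missing segment '%s'",
          les$id[i], les$segment_id[i])
    if (is.na(les$resistance[i]) || les$resistance[i] < R_MIN)
      add("lesions[%s].resistance: must be >= %g ohm", les$id[i], R_MIN)
  }
  if (nrow(beds) == 0) add("beds: at least one myocardial bed is required")
  ven <- unique(beds$drains_to)
  if (length(ven) > 1)
    add("beds.drains_to: all beds must drain to the same venous node (found %s)",
        paste(sQuote(ven), collapse = ", "))
  for (n in intersect(ven, c(vascular_nodes, reserved)))
    add("beds.drains_to: venous node '%s' collides with a vascular or reserved node", n)
  for (i in seq_len(nrow(beds))) {
    if (!beds$feeding_node[i] %in% vascular_nodes)
      add("beds[%s].feeding_node: unknown node '%s'", beds$id[i],
          beds$feeding_node[i])
    if (is.na(beds$resistance[i]) || beds$resistance[i] < R_MIN)
      add("beds[%s].resistance: must be >= %g ohm", beds$id[i], R_MIN)
    w <- beds$leaman_weight[i]
    if (!is.na(w) && (w <= 0 || w > 100))
      add("beds[%s].leaman_weight: must be in (0, 100]", beds$id[i])
  }
  for (i in seq_len(nrow(col))) {
    if (identical(col$donor_node[i], col$recipient_node[i]))
      add("collaterals[%s]: donor and recipient nodes coincide ('%s')",
          col$id[i], col$donor_node[i])
    for (fld in c("donor_node", "recipient_node"))
      if (!col[[fld]][i] %in% vascular_nodes)
        add("collaterals[%s].%s: unknown node '%s'", col$id[i], fld,
            col[[fld]][i])
    if (is.na(col$resistance[i]) || col$resistance[i] < R_MIN)
      add("collaterals[%s].resistance: must be >= %g ohm", col$id[i], R_MIN)
  }
  for (i in seq_len(nrow(pr))) {
    if (!pr$node[i] %in% vascular_nodes)
      add("probes[%s].node: unknown node '%s'", pr$id[i], pr$node[i])
  }
  if (!is.finite(spec$arterial_pressure) || !is.finite(spec$venous_pressure) ||
      !(spec$arterial_pressure > spec$venous_pressure &&
        spec$venous_pressure >= 0))
    add("pressures: need arterial_pressure > venous_pressure >= 0 (got %s, %s)",
        format(spec$arterial_pressure), format(spec$venous_pressure))
  if (!is.finite(spec$inflow_resistance) || spec$inflow_resistance < R_MIN)
    add("inflow_resistance: must be >= %g ohm", R_MIN)
  if (!spec$dominance %in% c("right", "left"))
    add("dominance: must be 'right' or 'left' (got '%s')", spec$dominance)
  for (s in spec$scenarios) {
    for (lid in names(s$overrides)) {
      if (!lid %in% les$id)
        add("scenarios[%s].overrides: unknown lesion '%s'", s$name, lid)
      else if (s$overrides[[lid]] < R_MIN)
        add("scenarios[%s].overrides[%s]: resistance must be >= %g ohm",
            s$name, lid, R_MIN)
    }
  }
  p
}

#' @export
print.coronary_spec <- function(x, ...) {
  cat(sprintf("Coronary tree model%s\n",
              if (is.null(x$name)) "" else paste0(" '", x$name, "'")))
  cat(sprintf("  %d segments, %d lesions, %d beds, %d collaterals, %d probes\n",
              nrow(x$segments), nrow(x$lesions), nrow(x$beds),
              nrow(x$collaterals), nrow(x$probes)))
  cat(sprintf("  arterial %g V, venous %g V, inflow %g ohm, %s dominant\n",
              x$arterial_pressure, x$venous_pressure, x$inflow_resistance,
              x$dominance))
  if (length(x$scenarios))
    cat("  scenarios:", paste(names(x$scenarios), collapse = ", "), "\n")
  invisible(x)
}

#' Compile a coronary tree model to a DC circuit
#'
#' Emits: an arterial voltage source (`arterial_pressure` to ground), a
#' venous source (`venous_pressure` to ground -- the outflow pressure is a
#' second ideal source, not a ground offset), the inflow series resistor,
#' one resistor per lesion placed in series within its segment, the segment
#' body resistor when its resistance exceeds the ideal-wire threshold
#' (1e-9 ohm; at the threshold the segment is compiled as a wire by node
#' merging), one resistor per myocardial bed from its feeding node to the
#' venous node, and one resistor per collateral channel.  Spec node names
#' are preserved so probes and scenario overrides resolve on the circuit.
#'
#' @param spec A [coronary_spec()].
#' @return A [circuit()] with attribute `probe_nodes` (named vector mapping
#'   probe id to its circuit node after wire merging).
#' @section Errors: Raises `coranalog_build_error` carrying any
#'   [validate_circuit()] diagnostics of the compiled network.
#' @export
build_circuit <- function(spec) {
  stopifnot(inherits(spec, "coronary_spec"))
  seg <- spec$segments; les <- spec$lesions
  ven <- unique(spec$beds$drains_to)

  # wire segments with no lesions collapse distal onto proximal
  alias <- character()
  resolve <- function(n) {
    while (n %in% names(alias)) n <- alias[[n]]
    n
  }
  rows <- list(
    voltage_source("arterial_source", ARTERIAL_NODE, GROUND_NODE,
                   spec$arterial_pressure),
    voltage_source("venous_source", ven, GROUND_NODE, spec$venous_pressure),
    resistor("inflow", ARTERIAL_NODE, spec$root_node,
             spec$inflow_resistance))
  for (i in seq_len(nrow(seg))) {
    s <- seg[i, ]
    chain <- list()
    if (s$resistance > R_MIN)
      chain[[length(chain) + 1]] <- list(id = s$id, value = s$resistance)
    for (j in which(les$segment_id == s$id))
      chain[[length(chain) + 1]] <- list(id = les$id[j],
                                         value = les$resistance[j])
    if (length(chain) == 0) {
      alias[[s$distal_node]] <- s$proximal_node
      next
    }
    path <- c(s$proximal_node,
              if (length(chain) > 1)
                paste0(s$id, "..", seq_len(length(chain) - 1)),
              s$distal_node)
    for (k in seq_along(chain))
      rows[[length(rows) + 1]] <- resistor(chain[[k]]$id, path[k],
                                           path[k + 1], chain[[k]]$value)
  }
  for (i in seq_len(nrow(spec$beds))) {
    b <- spec$beds[i, ]
    rows[[length(rows) + 1]] <- resistor(b$id, b$feeding_node, b$drains_to,
                                         b$resistance)
  }
  for (i in seq_len(nrow(spec$collaterals))) {
    co <- spec$collaterals[i, ]
    rows[[length(rows) + 1]] <- resistor(co$id, co$donor_node,
                                         co$recipient_node, co$resistance)
  }
  el <- do.call(rbind, rows)
  el$node_a <- vapply(el$node_a, resolve, character(1))
  el$node_b <- vapply(el$node_b, resolve, character(1))
  circ <- circuit(el, ground = GROUND_NODE)
  diags <- validate_circuit(circ)
  if (length(diags))
    stop(errorCondition(
      paste0("model does not compile to a solvable circuit:\n",
             paste("  -", diags, collapse = "\n")),
      class = c("coranalog_build_error", "coranalog_error"),
      diagnostics = diags))
  probe_nodes <- stats::setNames(
    vapply(spec$probes$node, resolve, character(1)), spec$probes$id)
  attr(circ, "probe_nodes") <- probe_nodes
  circ
}

#' FFR analog at a probe
#'
#' The default convention divides the probe voltage by the arterial input
#' pressure (`V_probe / Pa`), so with a 100 V input the probe voltages read
#' directly as FFR percentages.  The physiologic convention
#' `(V_probe - Pv) / (Pa - Pv)` is available behind `convention =
#' "physiologic"` but is never the default.
#'
#' @param solution A [solve_dc()] result for a circuit built by
#'   [build_circuit()].
#' @param spec The [coronary_spec()] the circuit was built from.
#' @param probe_id Probe name.
#' @param convention `"input"` (default) or `"physiologic"`.
#' @return An object of class `"probe_reading"`: list with `probe`, `node`,
#'   `voltage` (V) and `ffr_analog` (dimensionless).
#' @export
ffr_at <- function(solution, spec, probe_id,
                   convention = c("input", "physiologic")) {
  convention <- match.arg(convention)
  probe_nodes <- attr(solution$circuit, "probe_nodes")
  if (is.null(probe_nodes) || !probe_id %in% names(probe_nodes))
    stop(errorCondition(sprintf("unknown probe '%s'", probe_id),
                        class = c("coranalog_unknown_probe",
                                  "coranalog_error")))
  v <- solution$node_voltage[[probe_nodes[[probe_id]]]]
  ffr <- if (convention == "input") v / spec$arterial_pressure
  else (v - spec$venous_pressure) /
    (spec$arterial_pressure - spec$venous_pressure)
  structure(list(probe = probe_id, node = probe_nodes[[probe_id]],
                 voltage = v, ffr_analog = ffr, convention = convention),
            class = "probe_reading")
}

#' @export
print.probe_reading <- function(x, ...) {
  cat(sprintf("Probe '%s' (node %s): %.4g V, FFR analog %.3f [%s convention]\n",
              x$probe, x$node, x$voltage, x$ffr_analog, x$convention))
  invisible(x)
}
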