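# Smallest resistance the solver accepts; keeps the nodal matrix nonsingular.
# Ideal wires are handled upstream by node merging, never by 0-ohm resistors.
R_MIN <- 1e-9

#' Create a resistor element
#'
#' @param id Unique element name.
#' @param node_a,node_b Names of the two terminal nodes.
#' @param ohms Resistance in ohms; must be at least `1e-9`.
#' @return A one-row data frame describing the element, suitable for
#'   [circuit()].
#' @seealso [voltage_source()], [circuit()]
#' @export
resistor <- function(id, node_a, node_b, ohms) {
  data.frame(id = as.character(id), kind = "resistor",
             node_a = as.character(node_a), node_b = as.character(node_b),
             value = as.numeric(ohms), stringsAsFactors = FALSE)
}

#' Create an ideal DC voltage source element
#'
#' The source raises `node_a` relative to `node_b` by `volts`
#' (`node_a` is the positive terminal).
#'
#' @inheritParams resistor
#' @param volts Source voltage in volts (by the electronic-hydraulic
#'   analogy, mmHg).
#' @return A one-row data frame describing the element.
#' @export
voltage_source <- function(id, node_a, node_b, volts) {
  data.frame(id = as.character(id), kind = "voltage_source",
             node_a = as.character(node_a), node_b = as.character(node_b),
             value = as.numeric(volts), stringsAsFactors = FALSE)
}

#' Assemble a ground-referenced DC circuit
#'
#' A circuit is a set of two-terminal elements (resistors and ideal voltage
#' sources) over named nodes, one of which is the ground reference.  The
#' constructor is deliberately permissive: structural problems are reported
#' by [validate_circuit()], not raised here, so that malformed models can be
#' linted as a whole.
#'
#' @param elements A data frame of element rows (see [resistor()] and
#'   [voltage_source()]), or a list of such rows, or `NULL`.
#' @param nodes Extra node names not implied by any element terminal.
#' @param ground Name of the ground (zero-volt reference) node.
#' @return An object of class `"circuit"`.
#' @examples
#' cir <- circuit(rbind(
#'   voltage_source("SRC", "in", "gnd", 100),
#'   resistor("R1", "in", "mid", 10),
#'   resistor("R2", "mid", "gnd", 10)))
#' solve_dc(cir)$node_voltage[["mid"]]  # 50 V by symmetry
#' @export
circuit <- function(elements = NULL, nodes = character(), ground = "gnd") {
  if (is.list(elements) && !is.data.frame(elements))
    elements <- do.call(rbind, elements)
  if (is.null(elements))
    elements <- data.frame(id = character(), kind = character(),
                           node_a = character(), node_b = character(),
                           value = numeric(), stringsAsFactors = FALSE)
  stopifnot(is.data.frame(elements),
            all(c("id", "kind", "node_a", "node_b", "value") %in%
                  names(elements)))
  rownames(elements) <- NULL
  all_nodes <- unique(c(ground, as.character(nodes),
                        elements$node_a, elements$node_b))
  structure(list(elements = elements, nodes = all_nodes, ground = ground),
            class = "circuit")
}

#' @export
print.circuit <- function(x, ...) {
  cat(sprintf("DC circuit: %d nodes (ground '%s'), %d resistors, %d sources\n",
              length(x$nodes), x$ground,
              sum(x$elements$kind == "resistor"),
              sum(x$elements$kind == "voltage_source")))
  invisible(x)
}

#' Lint a circuit for structural problems
#'
#' Checks the invariants a solvable network must satisfy and returns one
#' human-readable diagnostic per violation.  Never raises; an empty character
#' vector means the circuit is well formed.
#'
#' Diagnosed problems: duplicate element ids, element terminals naming
#' unknown nodes, elements with coincident terminals, nonpositive (or
#' below-minimum, < 1e-9 ohm) resistances, absence of any voltage source,
#' and nodes unreachable from ground through the element graph.
#'
#' @param circ A [circuit()].
#' @return Character vector of diagnostics (empty if well formed).
#' @export
validate_circuit <- function(circ) {
  stopifnot(inherits(circ, "circuit"))
  el <- circ$elements
  out <- character()
  dup <- unique(el$id[duplicated(el$id)])
  for (d in dup)
    out <- c(out, sprintf("duplicate element id '%s'", d))
  bad_kind <- setdiff(unique(el$kind), c("resistor", "voltage_source"))
  for (k in bad_kind)
    out <- c(out, sprintf("unknown element kind '%s'", k))
  for (i in seq_len(nrow(el))) {
    e <- el[i, ]
    if (!(e$node_a %in% circ$nodes) || !(e$node_b %in% circ$nodes))
      out <- c(out, sprintf("element '%s' references unknown node", e$id))
    if (identical(e$node_a, e$node_b))
      out <- c(out, sprintf("element '%s' has coincident terminals ('%s')",
                            e$id, e$node_a))
    if (e$kind == "resistor" && (!is.finite(e$value) || e$value < R_MIN))
      out <- c(out, sprintf(
        "element '%s': nonpositive resistance (value %g below minimum %g ohm)",
        e$id, e$value, R_MIN))
  }
  if (!any(el$kind == "voltage_source"))
    out <- c(out, "no voltage source in circuit")
  # connectivity: every node reachable from ground through elements
  reach <- .reachable_from(circ, circ$ground)
  for (n in setdiff(circ$nodes, reach))
    out <- c(out, sprintf("node '%s' unreachable from ground", n))
  out
}

.reachable_from <- function(circ, start) {
  el <- circ$elements
  seen <- start
  frontier <- start
  while (length(frontier)) {
    nb <- unique(c(el$node_b[el$node_a %in% frontier],
                   el$node_a[el$node_b %in% frontier]))
    frontier <- setdiff(nb, seen)
    seen <- c(seen, frontier)
  }
  seen
}

#' Solve a DC circuit by modified nodal analysis
#'
#' Forms the modified-nodal-analysis system (Kirchhoff current balance in the
#' non-ground node voltages, plus one current unknown and one voltage
#' constraint per ideal source) and solves it with a dense direct solve.
#' The networks targeted here have tens of nodes, so no sparsity machinery
#' is used and the solution is deterministic.
#'
#' @param circ A [circuit()] for which [validate_circuit()] is clean.
#' @return An object of class `"dc_solution"`: a list with `node_voltage`
#'   (named vector, ground-referenced volts), `element_current` (named
#'   vector, amperes, positive from `node_a` to `node_b` through the
#'   element) and `circuit` (the solved circuit).
#' @section Errors: Raises a condition of class `coranalog_invalid_circuit`
#'   if validation fails, and `coranalog_singular` if the network is
#'   degenerate (for example a loop of ideal sources); the latter signals a
#'   malformed model, not numerical noise.
#' @export
solve_dc <- function(circ) {
  diags <- validate_circuit(circ)
  if (length(diags))
    stop(errorCondition(
      paste0("invalid circuit:\n", paste("  -", diags, collapse = "\n")),
      class = c("coranalog_invalid_circuit", "coranalog_error")))
  el <- circ$elements
  free <- setdiff(circ$nodes, circ$ground)
  n <- length(free)
  idx <- stats::setNames(seq_len(n), free)
  src <- which(el$kind == "voltage_source")
  m <- length(src)
  A <- matrix(0, n + m, n + m)
  b <- numeric(n + m)
  for (i in seq_len(nrow(el))) {
    e <- el[i, ]
    ia <- idx[e$node_a]; ib <- idx[e$node_b]   # NA when terminal is ground
    if (e$kind == "resistor") {
      g <- 1 / e$value
      if (!is.na(ia)) A[ia, ia] <- A[ia, ia] + g
      if (!is.na(ib)) A[ib, ib] <- A[ib, ib] + g
      if (!is.na(ia) && !is.na(ib)) {
        A[ia, ib] <- A[ia, ib] - g
        A[ib, ia] <- A[ib, ia] - g
      }
    } else {
      k <- n + match(i, src)
      # current unknown flows node_a -> node_b through the source
      if (!is.na(ia)) { A[ia, k] <- A[ia, k] + 1; A[k, ia] <- A[k, ia] + 1 }
      if (!is.na(ib)) { A[ib, k] <- A[ib, k] - 1; A[k, ib] <- A[k, ib] - 1 }
      b[k] <- e$value                            # V_a - V_b = value
    }
  }
  x <- tryCatch(solve(A, b), error = function(err)
    stop(errorCondition(
      paste0("degenerate network: nodal system is singular (",
             conditionMessage(err), ")"),
      class = c("coranalog_singular", "coranalog_error"))))
  v <- stats::setNames(numeric(length(circ$nodes)), circ$nodes)
  v[free] <- x[seq_len(n)]
  cur <- stats::setNames(numeric(nrow(el)), el$id)
  for (i in seq_len(nrow(el))) {
    e <- el[i, ]
    if (e$kind == "resistor") {
      cur[e$id] <- (v[[e$node_a]] - v[[e$node_b]]) / e$value
    } else {
      cur[e$id] <- x[n + match(i, src)]
    }
  }
  structure(list(node_voltage = v, element_current = cur, circuit = circ),
            class = "dc_solution")
}

#' @export
print.dc_solution <- function(x, digits = 4, ...) {
  cat("DC solution (V = mmHg, A = flow units)\n")
  cat("Node voltages:\n")
  print(round(x$node_voltage, digits))
  cat("Element currents (positive node_a -> node_b):\n")
  print(round(x$element_current, digits))
  invisible(x)
}

#' Signed current through one element
#'
#' @param solution A [solve_dc()] result.
#' @param element_id Element name.
#' @return Current in amperes, positive from `node_a` to `node_b`; for a
#'   resistor this equals `(V_a - V_b) / R` exactly as stored.
#' @export
element_current <- function(solution, element_id) {
  stopifnot(inherits(solution, "dc_solution"))
  if (!element_id %in% names(solution$element_current))
    stop(errorCondition(sprintf("unknown element '%s'", element_id),
                        class = c("coranalog_unknown_element",
                                  "coranalog_error")))
  solution$element_current[[element_id]]
}

#' Kirchhoff current residual at every node
#'
#' Sums, at each node, the currents leaving through all incident elements.
#' For a correctly solved circuit the residual at every node (including
#' ground, where the source return currents balance) is numerically zero.
#'
#' @param solution A [solve_dc()] result.
#' @return Named vector of per-node current residuals (amperes).
#' @export
kcl_residual <- function(solution) {
  el <- solution$circuit$elements
  res <- stats::setNames(numeric(length(solution$circuit$nodes)),
                         solution$circuit$nodes)
  for (i in seq_len(nrow(el))) {
    e <- el[i, ]
    cur <- solution$element_current[[e$id]]
    res[e$node_a] <- res[e$node_a] + cur
    res[e$node_b] <- res[e$node_b] - cur
  }
  res
}

#' Power balance of a solved circuit
#'
#' @param solution A [solve_dc()] result.
#' @return List with `source_power` (net power delivered by all sources,
#'   watts) and `resistor_power` (total I^2 R dissipation); the two are
#'   equal for any correct solution.
#' @export
power_balance <- function(solution) {
  el <- solution$circuit$elements
  p_src <- 0
  p_res <- 0
  for (i in seq_len(nrow(el))) {
    e <- el[i, ]
    cur <- solution$element_current[[e$id]]
    if (e$kind == "resistor") {
      p_res <- p_res + cur^2 * e$value
    } else {
      # current unknown flows + -> - internally; delivered power is V * (-I)
      p_src <- p_src + e$value * (-cur)
    }
  }
  list(source_power = p_src, resistor_power = p_res)
}

#' Format a circuit as a SPICE-dialect netlist
#'
#' One element per line -- `R<name> nodeA nodeB value` for resistors and
#' `V<name> node+ node- DC value` for sources -- in deterministic order
#' (sorted by element id), ASCII only, terminated by `.end`.
#'
#' @param circ A [circuit()].
#' @param title Optional comment line placed first (prefixed `* `).
#' @return Character vector of netlist lines.
#' @export
format_netlist <- function(circ, title = NULL) {
  el <- circ$elements[order(circ$elements$id), , drop = FALSE]
  lines <- character()
  if (!is.null(title)) lines <- paste0("* ", title)
  for (i in seq_len(nrow(el))) {
    e <- el[i, ]
    lines <- c(lines, if (e$kind == "resistor")
      sprintf("R%s %s %s %.15g", e$id, e$node_a, e$node_b, e$value)
    else
      sprintf("V%s %s %s DC %.15g", e$id, e$node_a, e$node_b, e$value))
  }
  c(lines, ".end")
}

#' Write a SPICE-dialect netlist to a file
#'
#' @inheritParams format_netlist
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_netlist <- function(circ, path, title = NULL) {
  writeLines(format_netlist(circ, title), path)
  invisible(path)
}
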