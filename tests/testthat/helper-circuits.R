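# Shared builders for small circuits and randomized coronary models.

divider_circuit <- function(r1 = 10, r2 = 10, volts = 100) {
  circuit(rbind(
    voltage_source("SRC", "in", "gnd", volts),
    resistor("R1", "in", "mid", r1),
    resistor("R2", "mid", "gnd", r2)))
}

# A symmetric three-branch tree with equal beds and no lesions.
symmetric_spec <- function(bed_r = 20, seg_r = 0.01) {
  coronary_spec(
    segments = data.frame(id = c("A", "B", "C"),
                          proximal_node = "ostium",
                          distal_node = c("a", "b", "c"),
                          resistance = seg_r),
    beds = data.frame(id = c("bedA", "bedB", "bedC"),
                      feeding_node = c("a", "b", "c"),
                      resistance = bed_r, drains_to = "venous"),
    probes = data.frame(id = c("a", "b", "c"), node = c("a", "b", "c")),
    inflow_resistance = 0.05)
}

# Randomized variant of the reference topology: same anatomy, perturbed
# component values (used for serialization / netlist round-trip checks).
random_case <- function(seed) {
  set.seed(seed)
  spec <- reference_case()
  spec$lesions$resistance <- 10^runif(4, -1, 2)
  spec$beds$resistance <- runif(3, 5, 50)
  spec$collaterals$resistance <- runif(1, 1, 20)
  spec$inflow_resistance <- runif(1, 0.01, 0.5)
  spec$arterial_pressure <- runif(1, 80, 120)
  spec$name <- paste0("random_case_", seed)
  spec
}

# Absolute-deviation expectation: half a unit in the last printed digit.
expect_within <- function(actual, expected, tol = 0.005) {
  expect_lt(abs(actual - expected), tol)
}

# Max |a - b| over all matching cells of two matrices.
max_cell_dev <- function(a, b) max(abs(a - b[rownames(a), colnames(a)]))

# Parse a SPICE netlist back into a comparable element table.
parse_netlist <- function(lines) {
  lines <- lines[!grepl("^\\*", lines) & lines != ".end" & nzchar(lines)]
  parts <- strsplit(lines, " +")
  do.call(rbind, lapply(parts, function(p) {
    kind <- if (startsWith(p[1], "R")) "resistor" else "voltage_source"
    data.frame(id = sub("^[RV]", "", p[1]), kind = kind,
               node_a = p[2], node_b = p[3],
               value = as.numeric(p[length(p)]),
               stringsAsFactors = FALSE)
  }))
}
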