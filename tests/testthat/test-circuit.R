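test_that("a symmetric voltage divider puts the midpoint at half the source", {
  sol <- solve_dc(divider_circuit(10, 10, 100))
  expect_equal(sol$node_voltage[["mid"]], 50)
  expect_equal(element_current(sol, "R1"), 5)
  expect_equal(sol$node_voltage[["gnd"]], 0)
})

test_that("validation reports every structural problem without raising", {
  expect_identical(validate_circuit(divider_circuit()), character(0))

  bare <- circuit(nodes = "orphan", ground = "gnd")
  d <- validate_circuit(bare)
  expect_true(any(grepl("no voltage source", d)))
  expect_true(any(grepl("'orphan' unreachable", d)))

  shorted <- circuit(rbind(voltage_source("S", "in", "gnd", 10),
                           resistor("R0", "in", "gnd", 0)))
  expect_true(any(grepl("nonpositive resistance",
                        validate_circuit(shorted))))

  dup <- circuit(rbind(voltage_source("S", "in", "gnd", 10),
                       resistor("X", "in", "gnd", 1),
                       resistor("X", "in", "gnd", 2),
                       resistor("L", "in", "in", 1)))
  d <- validate_circuit(dup)
  expect_true(any(grepl("duplicate element id 'X'", d)))
  expect_true(any(grepl("coincident terminals", d)))
})

test_that("solving refuses invalid circuits and flags degenerate source loops", {
  bad <- circuit(rbind(resistor("R0", "a", "gnd", 0)))
  expect_error(solve_dc(bad), class = "coranalog_invalid_circuit")

  loop <- circuit(rbind(voltage_source("S1", "in", "gnd", 100),
                        voltage_source("S2", "in", "gnd", 50),
                        resistor("R1", "in", "gnd", 10)))
  expect_identical(validate_circuit(loop), character(0))
  expect_error(solve_dc(loop), class = "coranalog_singular")

  sol <- solve_dc(divider_circuit())
  expect_error(element_current(sol, "nope"),
               class = "coranalog_unknown_element")
})

test_that("a resistor bridging equipotential nodes carries no current", {
  # balanced Wheatstone bridge: the galvanometer arm sees zero gradient
  bridge <- circuit(rbind(
    voltage_source("S", "top", "gnd", 100),
    resistor("Ra", "top", "l", 10), resistor("Rb", "l", "gnd", 20),
    resistor("Rc", "top", "r", 10), resistor("Rd", "r", "gnd", 20),
    resistor("Rg", "l", "r", 5)))
  sol <- solve_dc(bridge)
  expect_equal(sol$node_voltage[["l"]], sol$node_voltage[["r"]])
  expect_equal(element_current(sol, "Rg"), 0, tolerance = 1e-12)
})

test_that("stored currents are self-consistent with Ohm's law and node balance", {
  sol <- solve_dc(build_circuit(reference_case()))
  el <- sol$circuit$elements
  for (i in which(el$kind == "resistor")) {
    expect_identical(sol$element_current[[el$id[i]]],
                     (sol$node_voltage[[el$node_a[i]]] -
                        sol$node_voltage[[el$node_b[i]]]) / el$value[i])
  }
  imax <- max(abs(sol$element_current))
  expect_lt(max(abs(kcl_residual(sol))), 1e-9 * imax)
  # all inflow from the arterial source returns through the venous source
  expect_equal(abs(element_current(sol, "arterial_source")),
               abs(element_current(sol, "venous_source")),
               tolerance = 1e-9)
})

test_that("random series-parallel networks satisfy KCL, conservation and the reduction oracle", {
  for (seed in 1:60) {
    circ <- random_sp_network(seed, depth = 2 + seed %% 5)
    sol <- solve_dc(circ)
    imax <- max(abs(sol$element_current))
    expect_lt(max(abs(kcl_residual(sol))), 1e-9 * imax)
    pb <- power_balance(sol)
    expect_lt(abs(pb$source_power - pb$resistor_power),
              1e-9 * pb$source_power)
    if (seed <= 50) {
      oracle <- sp_reduce_oracle(circ)
      expect_lt(max(abs(sol$node_voltage - oracle$node_voltage)),
                1e-10 * max(abs(oracle$node_voltage)))
      expect_lt(max(abs(sol$element_current - oracle$element_current)),
                1e-10 * imax)
    }
  }
})

test_that("superposition and source scaling hold on the two-source network", {
  spec <- reference_case()
  full <- solve_dc(build_circuit(spec))

  # each source in turn replaced by a short (a zero-volt ideal source)
  art_only <- spec
  art_only$venous_pressure <- 0
  sa <- solve_dc(build_circuit(art_only))
  cb <- build_circuit(spec)
  cb$elements$value[cb$elements$id == "arterial_source"] <- 0
  sb <- solve_dc(cb)
  expect_equal(sa$node_voltage + sb$node_voltage, full$node_voltage,
               tolerance = 1e-12)
  expect_equal(sa$element_current + sb$element_current,
               full$element_current, tolerance = 1e-12)

  k <- 2.5
  ck <- build_circuit(spec)
  src <- ck$elements$kind == "voltage_source"
  ck$elements$value[src] <- k * ck$elements$value[src]
  sk <- solve_dc(ck)
  expect_equal(sk$node_voltage, k * full$node_voltage,
               tolerance = 1e-12)
  expect_equal(sk$element_current, k * full$element_current,
               tolerance = 1e-12)
})

test_that("netlist export is deterministic, sorted and complete", {
  circ <- build_circuit(reference_case())
  lines <- format_netlist(circ, title = "reference")
  expect_identical(lines[1], "* reference")
  expect_identical(lines[length(lines)], ".end")
  body <- parse_netlist(lines)
  expect_identical(body$id, sort(circ$elements$id))
  expect_identical(nrow(body), nrow(circ$elements))
  tmp <- tempfile(fileext = ".cir")
  on.exit(unlink(tmp))
  write_netlist(circ, tmp)
  expect_identical(readLines(tmp), format_netlist(circ))
})
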