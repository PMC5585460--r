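test_that("Leaman flow fractions follow dominance and sum to 100", {
  right <- leaman_flow_fractions("right")
  expect_equal(right, c(LAD = 56, LCx = 28, RCA = 16))
  left <- leaman_flow_fractions("left")
  expect_equal(left, c(LAD = 58, LCx = 42))
  expect_equal(sum(right), 100, tolerance = 1e-12)
  expect_equal(sum(left), 100, tolerance = 1e-12)
  expect_error(leaman_flow_fractions("codominant"))
})

test_that("bed resistances: presets, inverse weighting and refusals", {
  expect_equal(bed_resistances("preset", "right"),
               c(LAD = 10, LCx = 20, RCA = 30))
  expect_error(bed_resistances("preset", "left"),
               class = "coranalog_unsupported")
  r <- bed_resistances("leaman_inverse", "right", scale_constant = 560)
  expect_equal(r, c(LAD = 10, LCx = 20, RCA = 35))
  # conductance ratios equal flow-fraction ratios, by construction
  fr <- leaman_flow_fractions("right")
  expect_equal((1 / r) / sum(1 / r), fr / sum(fr), tolerance = 1e-12)
  left <- bed_resistances("leaman_inverse", "left", scale_constant = 100)
  expect_equal(left, c(LAD = 100 / 58, LCx = 100 / 42))
  expect_error(bed_resistances("leaman_inverse", "right"))
})

test_that("the compiled reference circuit has the expected shape", {
  circ <- build_circuit(reference_case())
  el <- circ$elements
  expect_identical(sum(el$kind == "voltage_source"), 2L)
  expect_identical(sum(el$kind == "resistor"), 9L)
  expect_setequal(el$id[el$kind == "resistor"],
                  c("inflow", "LAD1", "LAD2", "LCx", "RCA",
                    "collateral", "LADmyo", "LCxmyo", "RCAmyo"))
  expect_identical(validate_circuit(circ), character(0))
  pn <- attr(circ, "probe_nodes")
  expect_setequal(names(pn),
                  c("LAD_mid", "LAD_distal", "LCx_distal", "RCA_distal"))
})

test_that("model validation collects all problems with field paths", {
  err <- tryCatch(
    coronary_spec(
      segments = data.frame(id = "S", proximal_node = "ostium",
                            distal_node = "d", resistance = 1e-9),
      lesions = data.frame(id = "L", segment_id = "missing",
                           resistance = 0),
      beds = data.frame(id = "B", feeding_node = "nowhere",
                        resistance = 10, drains_to = "venous"),
      probes = data.frame(id = "P", node = "unknown")),
    condition = identity)
  expect_s3_class(err, "coranalog_schema_error")
  p <- err$problems
  expect_true(any(grepl("lesions\\[L\\]\\.segment_id", p)))
  expect_true(any(grepl("lesions\\[L\\]\\.resistance", p)))
  expect_true(any(grepl("beds\\[B\\]\\.feeding_node", p)))
  expect_true(any(grepl("probes\\[P\\]\\.node", p)))
})

test_that("a probe naming a missing node is rejected at build", {
  spec <- reference_case()
  spec$probes$node[1] <- "not_a_node"
  expect_error(coronary_spec(segments = spec$segments,
                             lesions = spec$lesions, beds = spec$beds,
                             collaterals = spec$collaterals,
                             probes = spec$probes,
                             inflow_resistance = spec$inflow_resistance),
               class = "coranalog_schema_error")
})

test_that("FFR analog readings match the reference scenarios", {
  spec <- reference_case()
  res <- run_scenarios(spec)
  sol1 <- res$solutions$sim1
  r <- ffr_at(sol1, spec, "LAD_distal")
  expect_within(r$ffr_analog, 0.36)
  expect_equal(r$voltage / spec$arterial_pressure, r$ffr_analog)
  expect_within(res$ratios["LAD_mid", "sim3"], 0.97)
  expect_error(ffr_at(sol1, spec, "femoral"),
               class = "coranalog_unknown_probe")
  # physiologic convention rescales by the venous offset
  phys <- ffr_at(sol1, spec, "LAD_distal", convention = "physiologic")
  expect_equal(phys$ffr_analog,
               (r$voltage - 5) / (100 - 5), tolerance = 1e-12)
})

test_that("a probe at the inflow root of an unobstructed tree reads 1", {
  spec <- symmetric_spec(seg_r = 1e-9)
  spec$inflow_resistance <- 1e-9
  spec$probes <- rbind(spec$probes,
                       data.frame(id = "root", node = "ostium"))
  sol <- solve_dc(build_circuit(spec))
  expect_equal(ffr_at(sol, spec, "root")$ffr_analog, 1, tolerance = 1e-9)
})

test_that("without epicardial disease every probe ratio is 1 within 1e-6", {
  spec <- reference_case()
  spec$lesions$resistance[] <- 1e-9
  spec$inflow_resistance <- 1e-9
  sol <- solve_dc(build_circuit(spec))
  for (p in spec$probes$id)
    expect_equal(ffr_at(sol, spec, p)$ffr_analog, 1, tolerance = 1e-6)
})

test_that("raising one lesion's resistance weakly lowers voltages at and downstream of it", {
  spec <- reference_case()
  grid <- 10^seq(log10(0.1), log10(100), length.out = 9)
  downstream <- list(LAD1 = c("LAD_mid", "LAD_distal", "RCA_distal"),
                     LAD2 = "LAD_distal",
                     LCx = "LCx_distal",
                     RCA = character(0))
  for (lesion in names(downstream)) {
    volts <- sapply(grid, function(r) {
      sp <- spec
      sp$lesions$resistance[sp$lesions$id == lesion] <- r
      sol <- solve_dc(build_circuit(sp))
      sapply(spec$probes$id, function(p) ffr_at(sol, sp, p)$voltage)
    })
    for (p in downstream[[lesion]])
      expect_true(all(diff(volts[p, ]) <= 1e-12),
                  info = paste(lesion, "->", p))
  }
})

test_that("equal beds with no lesions split flow symmetrically", {
  res <- run_scenarios(symmetric_spec(), list(scenario("base", list())))
  flows <- res$currents[, "base"]
  expect_lt(diff(range(flows)) / mean(flows), 1e-9)
})

test_that("inverse-Leaman beds perfuse in proportion to territory mass", {
  fr <- leaman_flow_fractions("right")
  r <- bed_resistances("leaman_inverse", "right", scale_constant = 560)
  spec <- symmetric_spec(seg_r = 1e-9)
  spec$inflow_resistance <- 1e-9
  spec$beds$resistance <- r[c("LAD", "LCx", "RCA")]
  sol <- solve_dc(build_circuit(spec))
  flows <- sapply(spec$beds$id, function(b) element_current(sol, b))
  expect_equal(flows / sum(flows), unname(fr / sum(fr)) ,
               tolerance = 1e-6, ignore_attr = TRUE)
})
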