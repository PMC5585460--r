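#' The packaged reference teaching case
#'
#' A complete coronary model of a clinically realistic teaching case: an
#' 80-year-old with two serial LAD stenoses (proximal 60%, modelled at 3
#' ohm; distal 90%, 15 ohm), moderate proximal LCx disease (0.75 ohm), a
#' chronic total occlusion of the proximal RCA (10 kohm) collateralized
#' from the mid LAD, right-dominant Leaman-preset myocardial beds (LAD 10 /
#' LCx 20 / RCA 30 ohm), a 100 V arterial and 5 V venous source, and probes
#' at the mid LAD, distal LAD, distal LCx and distal RCA.
#'
#' Two component values are not anatomically prescribed and were identified
#' by calibration against the case's frozen baseline readings (see
#' [calibrate_unprinted_parameters()]): the total inflow (aorta plus left
#' main) series resistance, 0.099 ohm, and the collateral channel
#' resistance, 5 ohm.  The near-normal left main alone is conventionally
#' described as about 10 mohm; that value is kept in the fixture metadata
#' but does not reproduce the frozen flows (the LCx bed current would read
#' 4.57 A instead of 4.53 A).
#'
#' Four scenarios are declared: `sim1` the presenting state (LAD1 3, LAD2
#' 15 ohm); `sim2` after distal LAD PCI (LAD2 0.1 ohm); `sim3` after
#' further proximal LAD PCI (both 0.1 ohm); `sim4` the theoretical
#' proximal-only PCI (LAD1 0.1, LAD2 15 ohm).
#'
#' The model ships as a YAML file under `extdata/` and is loaded through
#' [read_tree_config()], so the packaged case also exercises the
#' configuration schema.
#'
#' @return A [coronary_spec()].
#' @examples
#' res <- run_scenarios(reference_case())
#' res
#' @export
reference_case <- function() {
  path <- system.file("extdata", "reference_case.yaml",
                      package = "coranalog", mustWork = TRUE)
  read_tree_config(path)
}

#' Frozen reference readings for the teaching case
#'
#' The two-decimal probe ratios and bed flows (plus the lesion resistances
#' applied) that the packaged case is calibrated to reproduce across its
#' four scenarios, and against which the calibration of the unprinted
#' component values was performed.  Kept frozen: tests compare fresh solves
#' against these values within half a unit in the last digit (0.005).
#'
#' @return List of matrices `lesion_resistance`, `ratios`, `currents`
#'   (rows: lesions / probes / beds; columns: scenarios `sim1`..`sim4`).
#' @export
reference_expected <- function() {
  sims <- paste0("sim", 1:4)
  list(
    lesion_resistance = matrix(
      c(3, 15, 3, 0.1, 0.1, 0.1, 0.1, 15), 2, 4,
      dimnames = list(c("LAD1", "LAD2"), sims)),
    ratios = matrix(
      c(0.83, 0.36, 0.96, 0.72,
        0.73, 0.72, 0.95, 0.63,
        0.97, 0.96, 0.95, 0.84,
        0.98, 0.42, 0.96, 0.85), 4, 4,
      dimnames = list(c("LAD_mid", "LAD_distal", "LCx_distal", "RCA_distal"),
                      sims)),
    currents = matrix(
      c(3.12, 4.53, 2.23,
        6.71, 4.52, 1.94,
        9.13, 4.50, 2.63,
        3.73, 4.53, 2.67), 3, 4,
      dimnames = list(c("LADmyo", "LCxmyo", "RCAmyo"), sims)))
}

#' Identify the unprinted component values of the reference case
#'
#' The inflow and collateral resistances of the teaching case are not
#' anatomically prescribed; this audit recovers them by brute-force grid
#' search, minimizing the maximum absolute deviation of the baseline
#' (`sim1`) probe ratios and bed currents from their frozen two-decimal
#' targets.  A coarse grid (0.01 ohm / 0.25 ohm steps) over inflow in
#' [0.001, 1] ohm and collateral in [1, 20] ohm is refined around its
#' argmin (5e-4 ohm / 0.05 ohm steps).
#'
#' Because the targets are rounded to two decimals, the objective has a
#' flat valley: every grid point whose objective is at most the rounding
#' half-unit (0.005) is observationally equivalent given the baseline row
#' alone.  The returned `feasible` set makes that explicit; the packaged
#' case freezes the point of the valley that also reproduces the other
#' three scenarios (cross-validation on data not used in the fit).
#'
#' @param targets Baseline targets: list with named vectors `ratios` (per
#'   probe) and `currents` (per bed).  Defaults to the `sim1` column of
#'   [reference_expected()].
#' @param spec Model whose inflow/collateral values are searched over;
#'   defaults to [reference_case()].  Must contain exactly one collateral.
#' @param inflow_range,collateral_range Search intervals (ohm).
#' @return List of class `"calibration"`: `inflow`, `collateral` (argmin),
#'   `objective` (max abs deviation at the argmin), `feasible` (data frame
#'   of fine-grid points with objective <= 0.005) and `resolution` (fine
#'   grid steps).
#' @export
calibrate_unprinted_parameters <- function(targets = NULL, spec = NULL,
                                           inflow_range = c(0.001, 1),
                                           collateral_range = c(1, 20)) {
  if (is.null(spec)) spec <- reference_case()
  stopifnot(nrow(spec$collaterals) == 1)
  if (is.null(targets)) {
    exp <- reference_expected()
    targets <- list(ratios = exp$ratios[, "sim1"],
                    currents = exp$currents[, "sim1"])
  }
  base <- spec$scenarios[[1]]
  sp1 <- .apply_scenario(spec, base)
  circ <- build_circuit(sp1)
  coll_id <- spec$collaterals$id[1]
  objective <- function(inflow, coll) {
    circ$elements$value[circ$elements$id == "inflow"] <- inflow
    circ$elements$value[circ$elements$id == coll_id] <- coll
    sol <- solve_dc(circ)
    pn <- attr(circ, "probe_nodes")
    r <- sol$node_voltage[pn[names(targets$ratios)]] /
      spec$arterial_pressure
    i <- sol$element_current[names(targets$currents)]
    max(abs(c(r - targets$ratios, i - targets$currents)))
  }
  grid_min <- function(inflows, colls) {
    best <- list(obj = Inf)
    vals <- matrix(NA_real_, length(inflows), length(colls))
    for (a in seq_along(inflows)) for (b in seq_along(colls)) {
      o <- objective(inflows[a], colls[b])
      vals[a, b] <- o
      if (o < best$obj)
        best <- list(obj = o, inflow = inflows[a], coll = colls[b])
    }
    list(best = best, vals = vals)
  }
  coarse_i <- unique(c(seq(inflow_range[1], inflow_range[2], by = 0.01),
                       inflow_range[2]))
  coarse_c <- seq(collateral_range[1], collateral_range[2], by = 0.25)
  coarse <- grid_min(coarse_i, coarse_c)
  fine_i <- seq(max(inflow_range[1], coarse$best$inflow - 0.01),
                min(inflow_range[2], coarse$best$inflow + 0.01), by = 5e-4)
  fine_c <- seq(max(collateral_range[1], coarse$best$coll - 0.25),
                min(collateral_range[2], coarse$best$coll + 0.25), by = 0.05)
  fine <- grid_min(fine_i, fine_c)
  feas <- which(fine$vals <= 0.005, arr.ind = TRUE)
  feasible <- data.frame(inflow = fine_i[feas[, 1]],
                         collateral = fine_c[feas[, 2]],
                         objective = fine$vals[feas])
  feasible <- feasible[order(feasible$objective), ]
  rownames(feasible) <- NULL
  structure(list(inflow = fine$best$inflow, collateral = fine$best$coll,
                 objective = fine$best$obj, feasible = feasible,
                 resolution = c(inflow = 5e-4, collateral = 0.05)),
            class = "calibration")
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf("Calibration argmin: inflow %.4g ohm, collateral %.4g ohm (max abs deviation %.4g)\n",
              x$inflow, x$collateral, x$objective))
  cat(sprintf("%d grid points indistinguishable within print rounding (objective <= 0.005):\n",
              nrow(x$feasible)))
  cat(sprintf("  inflow in [%.4g, %.4g], collateral in [%.4g, %.4g]\n",
              min(x$feasible$inflow), max(x$feasible$inflow),
              min(x$feasible$collateral), max(x$feasible$collateral)))
  invisible(x)
}

#' Random series-parallel resistor network
#'
#' Generates a deterministic (per seed) series-parallel composition of
#' resistors -- values log-uniform in [0.1, 100] ohm -- across a single
#' voltage source, and records the composition tree so that
#' [sp_reduce_oracle()] can solve the same network without a matrix solve.
#' Used as an independent verification path for [solve_dc()].
#'
#' @param seed Integer seed.
#' @param depth Maximum composition depth (<= 6); `depth = 1` (or a branch
#'   collapsing early) gives a single resistor across the source.
#' @return A [circuit()] with attribute `sp_tree` (the composition tree).
#' @export
random_sp_network <- function(seed, depth) {
  stopifnot(depth <= 6, depth >= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  counter <- new.env()
  counter$elem <- 0L
  counter$node <- 0L
  gen <- function(d) {
    if (d <= 1 || (d < depth && stats::runif(1) < 0.4)) {
      counter$elem <- counter$elem + 1L
      return(list(type = "leaf", value = 10^stats::runif(1, -1, 2),
                  id = paste0("R", counter$elem)))
    }
    list(type = sample(c("series", "parallel"), 1),
         children = lapply(seq_len(sample(2:3, 1)), function(i) gen(d - 1)))
  }
  tree <- gen(depth)
  vsrc <- round(stats::runif(1, 10, 100), 3)
  assign_nodes <- function(tr, a, b) {
    tr$node_a <- a
    tr$node_b <- b
    if (tr$type == "leaf") return(tr)
    if (tr$type == "parallel") {
      tr$children <- lapply(tr$children, assign_nodes, a = a, b = b)
    } else {
      k <- length(tr$children)
      inner <- vapply(seq_len(k - 1), function(i) {
        counter$node <- counter$node + 1L
        paste0("n", counter$node)
      }, character(1))
      path <- c(a, inner, b)
      tr$children <- lapply(seq_len(k), function(i)
        assign_nodes(tr$children[[i]], path[i], path[i + 1]))
    }
    tr
  }
  tree <- assign_nodes(tree, "src", "gnd")
  collect <- function(tr) {
    if (tr$type == "leaf")
      return(list(resistor(tr$id, tr$node_a, tr$node_b, tr$value)))
    do.call(c, lapply(tr$children, collect))
  }
  rows <- c(list(voltage_source("SRC", "src", "gnd", vsrc)), collect(tree))
  circ <- circuit(rows, ground = "gnd")
  attr(circ, "sp_tree") <- tree
  attr(circ, "source_value") <- vsrc
  circ
}

.sp_req <- function(tr) {
  if (tr$type == "leaf") return(tr$value)
  r <- vapply(tr$children, .sp_req, numeric(1))
  if (tr$type == "series") sum(r) else 1 / sum(1 / r)
}

#' Solve a series-parallel network by reduction (oracle)
#'
#' Computes the equivalent resistance of a [random_sp_network()] by
#' recursive series/parallel reduction, then back-substitutes voltages and
#' currents down the recorded composition tree.  No matrix solve is
#' involved, so the result is an independent check on [solve_dc()].
#'
#' @param circ A circuit produced by [random_sp_network()].
#' @return A `"dc_solution"`-shaped object (node voltages, element
#'   currents, circuit).
#' @export
sp_reduce_oracle <- function(circ) {
  tree <- attr(circ, "sp_tree")
  if (is.null(tree))
    stop("circuit was not produced by random_sp_network()")
  vsrc <- attr(circ, "source_value")
  req <- .sp_req(tree)
  v <- stats::setNames(numeric(length(circ$nodes)), circ$nodes)
  cur <- stats::setNames(numeric(nrow(circ$elements)), circ$elements$id)
  v[["src"]] <- vsrc
  total <- vsrc / req
  descend <- function(tr, current) {
    if (tr$type == "leaf") {
      cur[[tr$id]] <<- current
      return(invisible())
    }
    if (tr$type == "series") {
      vtop <- v[[tr$node_a]]
      for (ch in tr$children) {
        vbot <- vtop - current * .sp_req(ch)
        v[[ch$node_b]] <<- if (identical(ch$node_b, tr$node_b))
          v[[tr$node_b]] else vbot
        descend(ch, current)
        vtop <- vbot
      }
    } else {
      dv <- v[[tr$node_a]] - v[[tr$node_b]]
      for (ch in tr$children) descend(ch, dv / .sp_req(ch))
    }
  }
  descend(tree, total)
  cur[["SRC"]] <- -total  # node_a -> node_b through the source
  structure(list(node_voltage = v, element_current = cur, circuit = circ),
            class = "dc_solution")
}
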