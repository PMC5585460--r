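.config_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) return("yaml")
  if (ext == "json") return("json")
  stop(errorCondition(
    sprintf("cannot detect config format from extension '.%s' (use .yaml/.yml or .json)", ext),
    class = c("coranalog_parse_error", "coranalog_error")))
}

#' Read a coronary model from YAML or JSON
#'
#' The format is detected from the file extension.  Malformed files raise a
#' parse error (`coranalog_parse_error`, carrying the path); well-formed
#' files with invalid content raise a schema error
#' (`coranalog_schema_error`) listing every violation with its field path.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` model file.
#' @return A validated [coronary_spec()].
#' @seealso [write_tree_config()]; the packaged JSON Schema at
#'   `system.file("extdata", "coronary_spec.schema.json", package =
#'   "coranalog")`.
#' @export
read_tree_config <- function(path) {
  if (!file.exists(path))
    stop(errorCondition(sprintf("config file '%s' does not exist", path),
                        class = c("coranalog_parse_error",
                                  "coranalog_error")))
  fmt <- .config_format(path)
  lst <- tryCatch(
    if (fmt == "yaml") yaml::read_yaml(path)
    else jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = TRUE),
    error = function(err) stop(errorCondition(
      sprintf("cannot parse '%s' as %s: %s", path, fmt,
              conditionMessage(err)),
      class = c("coranalog_parse_error", "coranalog_error"))))
  as_coronary_spec(lst)
}

#' Build a coronary model from a plain list
#'
#' @param lst List with the fields of [coronary_spec()] (as produced by
#'   parsing a YAML/JSON model file).
#' @return A validated [coronary_spec()].
#' @export
as_coronary_spec <- function(lst) {
  sc <- lst$scenarios
  if (!is.null(sc) && is.data.frame(sc)) {
    # jsonlite may simplify the scenario list to a data frame
    sc <- lapply(seq_len(nrow(sc)), function(i)
      list(name = sc$name[i], overrides = as.list(sc$overrides[i, ])))
  }
  coronary_spec(
    segments = lst$segments, lesions = lst$lesions, beds = lst$beds,
    collaterals = lst$collaterals, probes = lst$probes,
    arterial_pressure = lst$arterial_pressure %||% 100,
    venous_pressure = lst$venous_pressure %||% 5,
    inflow_resistance = lst$inflow_resistance %||% 1e-9,
    root_node = lst$root_node %||% "ostium",
    dominance = lst$dominance %||% "right",
    scenarios = sc %||% list(),
    name = lst$name, metadata = lst$metadata %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.df_rows <- function(df) {
  lapply(seq_len(nrow(df)), function(i) {
    row <- as.list(df[i, , drop = FALSE])
    row[!vapply(row, function(v) is.na(v) || is.null(v), logical(1))]
  })
}

#' Serialize a coronary model to YAML or JSON
#'
#' @param spec A [coronary_spec()].
#' @param path Output path; the extension selects the format.
#' @return Invisibly, the path.
#' @export
write_tree_config <- function(spec, path) {
  stopifnot(inherits(spec, "coronary_spec"))
  fmt <- .config_format(path)
  lst <- list(
    name = spec$name,
    arterial_pressure = spec$arterial_pressure,
    venous_pressure = spec$venous_pressure,
    inflow_resistance = spec$inflow_resistance,
    root_node = spec$root_node,
    dominance = spec$dominance,
    segments = .df_rows(spec$segments),
    lesions = .df_rows(spec$lesions),
    beds = .df_rows(spec$beds),
    collaterals = .df_rows(spec$collaterals),
    probes = .df_rows(spec$probes),
    scenarios = unname(lapply(spec$scenarios, function(s)
      list(name = s$name, overrides = as.list(s$overrides)))),
    metadata = spec$metadata)
  lst <- lst[!vapply(lst, is.null, logical(1))]
  if (fmt == "yaml") {
    yaml::write_yaml(lst, path, precision = 15)
  } else {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' Format a results table as an aligned text grid
#'
#' Scenarios as columns; three blocks -- lesion resistances (ohm), voltage
#' ratios, bed current flows (A) -- mirroring the layout of a simulation
#' results table.
#'
#' @param results A [run_scenarios()] table.
#' @return Character vector of lines.
#' @export
format_results_text <- function(results) {
  stopifnot(inherits(results, "coronary_results"))
  sn <- results$scenario_names
  if (length(sn) == 0) return("(no scenarios)")
  wlab <- max(nchar(c("Lesion resistance (ohm)",
                      rownames(results$lesion_resistance),
                      rownames(results$ratios),
                      rownames(results$currents))))
  wcol <- max(10, nchar(sn) + 2)
  pad <- function(s) formatC(s, width = wlab, flag = "-")
  num <- function(v, fmt) formatC(sprintf(fmt, v), width = wcol)
  hdr <- paste0(pad(""), paste(formatC(sn, width = wcol), collapse = ""))
  block <- function(title, m, fmt) {
    c(title,
      vapply(rownames(m), function(r)
        paste0(pad(r), paste(num(m[r, ], fmt), collapse = "")),
        character(1)))
  }
  c(hdr,
    block("Lesion resistance (ohm)", results$lesion_resistance, "%.4g"),
    block("Voltage ratio", results$ratios, "%.2f"),
    block("Current flow (A)", results$currents, "%.2f"))
}

#' Write a results table to disk
#'
#' Three deterministic writers: `csv` -- long format with columns
#' `scenario`, `quantity_kind`, `location`, `value` (full precision);
#' `text` -- the aligned grid of [format_results_text()]; `json` -- nested
#' by scenario, then quantity kind, then location.
#'
#' @param results A [run_scenarios()] table.
#' @param path Output path, or `"-"` for standard output.
#' @param format `"csv"`, `"text"` or `"json"`.
#' @return Invisibly, the path.
#' @export
write_report <- function(results, path, format = c("csv", "text", "json")) {
  stopifnot(inherits(results, "coronary_results"))
  format <- match.arg(format)
  lines <- switch(format,
    csv = {
      df <- as.data.frame(results)
      con <- textConnection("csv_out", "w", local = TRUE)
      utils::write.csv(format(df, digits = 15, trim = TRUE,
                              scientific = FALSE),
                       con, row.names = FALSE, quote = FALSE)
      close(con)
      csv_out
    },
    text = format_results_text(results),
    json = {
      nested <- stats::setNames(lapply(results$scenario_names, function(s)
        list(lesion_resistance = as.list(results$lesion_resistance[, s]),
             voltage_ratio = as.list(results$ratios[, s]),
             bed_current = as.list(results$currents[, s]))),
        results$scenario_names)
      strsplit(as.character(jsonlite::toJSON(
        nested, auto_unbox = TRUE, digits = NA, pretty = TRUE)), "\n")[[1]]
    })
  if (identical(path, "-")) {
    cat(lines, sep = "\n")
  } else {
    writeLines(lines, path)
  }
  invisible(path)
}
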