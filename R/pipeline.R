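# End-to-end pipeline: load or synthesise inputs, run the scenario, write
# the impact table, the savings and DALY report tables and a machine-readable
# run manifest. Deterministic for a fixed configuration; on any stage
# failure the partially written outputs are removed.

config_fingerprint <- function(cfg) {
  s <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA, force = TRUE)
  bytes <- utf8ToInt(as.character(s))
  # FNV-1a, 32 bit
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

load_pipeline_inputs <- function(input_cfg) {
  source <- input_cfg$source
  if (is.null(source)) {
    stop("pipeline config must name input$source ('synthetic' or 'files')",
         call. = FALSE)
  }
  if (identical(source, "synthetic")) {
    args <- input_cfg[setdiff(names(input_cfg), "source")]
    cfg <- do.call(generator_config, args)
    generate_inputs(cfg)
  } else if (identical(source, "files")) {
    for (key in c("che", "paf", "daly", "countries")) {
      if (is.null(input_cfg[[key]])) {
        stop(sprintf("input$%s path missing from pipeline config", key),
             call. = FALSE)
      }
    }
    list(
      che = read_che(input_cfg$che),
      paf = read_paf(input_cfg$paf),
      daly = read_daly(input_cfg$daly),
      countries = read_countries(input_cfg$countries)
    )
  } else {
    stop("input$source must be 'synthetic' or 'files'", call. = FALSE)
  }
}

#' Run the full pipeline from a configuration
#'
#' Loads inputs (from files, or from the synthetic generator with a seed),
#' runs the configured scenario, and writes to `out_dir`: `impact.csv` (per
#' country, risk factor, condition and year, undiscounted and discounted
#' million 2018 US$), `summary.csv` (cumulative discounted savings and
#' percent of base-case expenditure per country and risk factor),
#' `savings_table.csv`/`.md` and `daly_table.csv`/`.md` (the two report
#' shapes) and `manifest.json` (seed, configuration echo and fingerprint,
#' package and R versions). Progress is logged to stderr. The run is
#' idempotent for a fixed configuration; on failure, partial outputs are
#' removed and the error is re-signalled.
#'
#' @param config Path to a YAML/JSON configuration file, or an equivalent
#'   list. Keys: `input` (with `source: synthetic` plus [generator_config()]
#'   fields, or `source: files` plus `che`/`paf`/`daly`/`countries` paths),
#'   `scenario` ([cra_scenario()] fields) and optionally `daly_levels`.
#' @param out_dir Output directory, created if needed.
#' @param quiet Suppress stderr logging.
#' @return Invisibly, a list with the output paths, the scenario and the
#'   savings/DALY summaries.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  log_msg <- function(...) {
    if (!quiet) message("[ncdcra] ", sprintf(...))
  }
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) {
      stop(sprintf("config file not found: %s", config), call. = FALSE)
    }
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  if (!is.list(config) || is.null(config$input) || is.null(config$scenario)) {
    stop("pipeline config must contain `input` and `scenario` sections",
         call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  emit <- function(name, writer) {
    path <- file.path(out_dir, name)
    writer(path)
    written <<- c(written, path)
    path
  }
  tryCatch({
    scenario <- scenario_from_config(config$scenario)
    levels <- config$daly_levels %||% c(0.05, 0.10, 0.25)
    log_msg("loading inputs (source: %s)", config$input$source %||% "?")
    inputs <- load_pipeline_inputs(config$input)
    log_msg("running scenario %s-%d", scenario$start_year,
            scenario$horizon_end)
    impact <- run_scenario(inputs$che, default_condition_table(),
                           inputs$paf, scenario)
    savings <- cumulative_savings(impact, inputs$che, scenario)
    stable <- savings_table(savings, inputs$countries)
    dsummary <- daly_reduction(inputs$paf, inputs$daly,
                               reduction_levels = levels)
    dtable <- daly_table(dsummary)

    log_msg("writing outputs to %s", out_dir)
    paths <- list(
      impact = emit("impact.csv", function(p)
        readr::write_csv(impact, p, progress = FALSE)),
      summary = emit("summary.csv", function(p)
        readr::write_csv(savings, p, progress = FALSE)),
      savings_csv = emit("savings_table.csv", function(p)
        readr::write_csv(stable, p, progress = FALSE)),
      savings_md = emit("savings_table.md", function(p)
        writeLines(render_savings_markdown(stable), p)),
      daly_csv = emit("daly_table.csv", function(p)
        readr::write_csv(dtable, p, progress = FALSE)),
      daly_md = emit("daly_table.md", function(p)
        writeLines(render_daly_markdown(dtable), p)),
      manifest = emit("manifest.json", function(p)
        jsonlite::write_json(list(
          seed = config$input$seed %||% NA,
          config = config,
          config_fingerprint = config_fingerprint(config),
          package_version = as.character(utils::packageVersion("ncdcra")),
          r_version = R.version.string
        ), p, auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE))
    )
    log_msg("done")
    invisible(list(paths = paths, scenario = scenario,
                   savings = savings, savings_table = stable,
                   daly_summary = dsummary, daly_table = dtable))
  }, error = function(e) {
    unlink(written)
    stop(e)
  })
}

`%||%` <- function(x, y) if (is.null(x)) y else x
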