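#' File I/O and pipeline plumbing
#'
#' Flat CSV (comma-separated, UTF-8, "." decimal, mandatory header) is
#' the interchange format; a leading `# key=value` comment block carries
#' run metadata such as the RNG seed.  Writers are atomic: content goes
#' to a temporary file in the target directory which is then renamed.
#'
#' @name grapemx-io
NULL

atomic_write <- function(path, writer) {
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tmp <- tempfile(pattern = ".grapemx", tmpdir = dir, fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) {
    stop_grapemx("grapemx_data_error",
                 sprintf("could not move output into place at `%s`", path))
  }
  invisible(path)
}

#' Write a data frame as a grapemx CSV
#'
#' @param df data frame to write.
#' @param path output path.
#' @param meta optional named list written as `# key=value` header lines
#'   (a `seed` entry records the RNG seed of a stochastic run).
#' @param digits named list of per-column rounding (EUR columns default
#'   to 2 decimals, index columns to 4); `NULL` entries leave columns
#'   untouched.
#' @return the path, invisibly.
#' @export
write_grapemx_csv <- function(df, path, meta = NULL, digits = NULL) {
  digits <- digits %||% default_digits(df)
  for (col in names(digits)) {
    if (col %in% names(df) && is.numeric(df[[col]])) {
      df[[col]] <- round(df[[col]], digits[[col]])
    }
  }
  atomic_write(path, function(tmp) {
    con <- file(tmp, open = "wt", encoding = "UTF-8")
    on.exit(close(con), add = TRUE)
    for (key in names(meta)) {
      writeLines(sprintf("# %s=%s", key, format(meta[[key]])), con)
    }
    utils::write.csv(df, con, row.names = FALSE)
  })
}

default_digits <- function(df) {
  out <- list()
  for (col in intersect(INDEX_COLS, names(df))) out[[col]] <- 4L
  for (col in grep("_eur", names(df), value = TRUE)) out[[col]] <- 2L
  out
}

#' Read a grapemx CSV, returning data and header metadata
#'
#' @param path CSV path.
#' @return data frame; `# key=value` header lines are attached as the
#'   `"meta"` attribute.
#' @export
read_grapemx_csv <- function(path) {
  if (!file.exists(path)) {
    stop_grapemx("grapemx_data_error", sprintf("input file not found: %s", path))
  }
  head_lines <- readLines(path, n = 50L, warn = FALSE)
  meta_lines <- grep("^#", head_lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- strsplit(sub("^#\\s*", "", ln), "=", fixed = TRUE)[[1L]]
    if (length(kv) == 2L) meta[[trimws(kv[1L])]] <- trimws(kv[2L])
  }
  df <- tryCatch(
    utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                    encoding = "UTF-8"),
    error = function(e) {
      stop_grapemx("grapemx_data_error",
                   sprintf("malformed CSV `%s`: %s", path,
                           conditionMessage(e)))
    })
  attr(df, "meta") <- meta
  df
}

#' Read a table of fluorescence readings
#'
#' Requires columns `cultivar`, `doy`, `cluster_side`, `frf_r`, `frf_g`,
#' `frf_uv`, `rf_r`; validates channel positivity and metadata ranges.
#'
#' @param path CSV path.
#' @return validated fluorescence record data frame.
#' @export
read_fluorescence_csv <- function(path) {
  df <- read_grapemx_csv(path)
  required <- c("cultivar", "doy", "cluster_side", CHANNEL_COLS)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop_grapemx("grapemx_data_error",
                 sprintf("`%s` lacks column(s): %s", path,
                         paste(missing_cols, collapse = ", ")))
  }
  validate_fluorescence(df)
  df
}

#' Read a scenario / profile configuration file
#'
#' YAML (`.yml`/`.yaml`) or JSON (`.json`), mirroring the
#' [sampling_plan()] and [cost_parameters()] field names under `plan:`
#' and `costs:` keys, with optional `preset`, `scenario`, `lifetime`,
#' `seed`, `monte_carlo: {n_draws, rel_half_width}` entries.  Unknown
#' fields raise a config error naming the field.
#'
#' @param path config path.
#' @return a named list (`plan`, `costs`, `scenario`, `lifetime`,
#'   `seed`, `monte_carlo`).
#' @export
read_scenario_config <- function(path) {
  if (!file.exists(path)) {
    stop_grapemx("grapemx_config_error",
                 sprintf("config file not found: %s", path))
  }
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yml = , yaml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyVector = TRUE),
    stop_grapemx("grapemx_config_error",
                 sprintf("unsupported config extension `.%s`", ext)))
  known_top <- c("preset", "n_cultivars", "plan", "costs", "scenario",
                 "lifetime", "max_lifetime", "seed", "monte_carlo")
  unknown <- setdiff(names(raw), known_top)
  if (length(unknown)) {
    stop_grapemx("grapemx_config_error",
                 sprintf("unknown config field(s): %s",
                         paste(unknown, collapse = ", ")))
  }
  check_fields(raw$costs %||% list(), names(formals(cost_parameters)),
               "costs")
  plan <- if (!is.null(raw$preset)) {
    base <- farm_preset(raw$preset, n_cultivars = raw$n_cultivars)
    apply_overrides(base, raw$plan, sampling_plan, "plan")
  } else {
    args <- raw$plan %||% list()
    if (is.null(args$n_cultivars) && !is.null(raw$n_cultivars)) {
      args$n_cultivars <- raw$n_cultivars
    }
    check_fields(args, names(formals(sampling_plan)), "plan")
    if (is.null(args$n_cultivars)) {
      stop_grapemx("grapemx_config_error",
                   "config needs `n_cultivars` (top-level or under `plan:`)")
    }
    do.call(sampling_plan, args)
  }
  costs <- apply_overrides(cost_parameters(), raw$costs,
                           cost_parameters, "costs")
  mc <- raw$monte_carlo %||% list()
  check_fields(mc, c("n_draws", "rel_half_width"), "monte_carlo")
  list(plan = plan, costs = costs,
       scenario = raw$scenario %||% "average",
       lifetime = raw$lifetime %||% 7L,
       max_lifetime = raw$max_lifetime %||% 50L,
       seed = raw$seed %||% 1L,
       monte_carlo = list(n_draws = mc$n_draws %||% 1000L,
                          rel_half_width = mc$rel_half_width %||% 0.2))
}

check_fields <- function(x, allowed, where) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown)) {
    stop_grapemx("grapemx_config_error",
                 sprintf("unknown `%s` field(s): %s", where,
                         paste(unknown, collapse = ", ")))
  }
  invisible(x)
}

apply_overrides <- function(base, overrides, constructor, where) {
  if (is.null(overrides) || length(overrides) == 0L) return(base)
  check_fields(overrides, names(formals(constructor)), where)
  args <- unclass(base)
  args[names(overrides)] <- overrides
  do.call(constructor, args)
}

format_npv_report <- function(report) {
  lines <- c(sprintf("%-9s %14s %14s %11s", "scenario", "cashflow_eur_y",
                     "npv_eur", "breakeven_y"),
             sprintf("%-9s %14.2f %14.2f %11s", report$scenario,
                     report$cash_flow_eur_y, report$npv_eur,
                     ifelse(is.na(report$breakeven_y), "none",
                            report$breakeven_y)))
  paste(lines, collapse = "\n")
}

#' Run one pipeline step
#'
#' Subcommands bind the computational modules into reproducible runs:
#' * `simulate`: seeded season + fluorescence synthesis for chosen
#'   profiles; writes a chemistry CSV and a readings CSV.
#' * `indices`: read a readings CSV, append the five indices, write.
#' * `calibrate`: read a CSV, fit a calibration family to two named
#'   columns (with optional sugar-domain restriction), write JSON.
#' * `econ`: scenario grid (lower/upper/average NPV and breakeven) for a
#'   preset or config; writes CSV and prints an aligned table.
#' * `report`: `econ` grid for the standard presets side by side.
#'
#' Outputs are written atomically; every stochastic output records its
#' seed in the CSV header; the run log (stderr) records the config hash
#' and the files produced.  Identical config and seed give byte-identical
#' outputs.
#'
#' @param config named list; must contain `subcommand` plus the fields
#'   that subcommand needs (see Details in the vignette, or the CLI
#'   script's `--help`).
#' @return named list of output paths, invisibly.
#' @export
run_pipeline <- function(config) {
  sub <- config$subcommand %||%
    stop_grapemx("grapemx_config_error", "config needs a `subcommand`")
  sub <- match.arg(sub, c("simulate", "indices", "calibrate", "econ",
                          "report"))
  cfg_hash <- config_hash(config)
  log_info("run %s (config %s)", sub, cfg_hash)
  out <- switch(sub,
    simulate = pipeline_simulate(config),
    indices = pipeline_indices(config),
    calibrate = pipeline_calibrate(config),
    econ = pipeline_econ(config),
    report = pipeline_report(config))
  for (p in unlist(out)) log_info("wrote %s", p)
  invisible(out)
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(config[order(names(config))], tmp)
  unname(tools::md5sum(tmp))
}

log_info <- function(fmt, ...) {
  message(sprintf(paste0("[grapemx] ", fmt), ...))
}

pipeline_simulate <- function(config) {
  seed <- as.integer(config$seed %||% 1L)
  profiles <- cultivar_presets()
  wanted <- config$profiles %||% names(profiles)
  unknown <- setdiff(wanted, names(profiles))
  if (length(unknown)) {
    stop_grapemx("grapemx_config_error",
                 paste("unknown profile(s):", paste(unknown, collapse = ", ")))
  }
  noise_scale <- config$noise_scale %||% 1
  channel_sigma <- config$channel_sigma  # NULL -> per-profile default
  chem <- list(); recs <- list()
  for (i in seq_along(wanted)) {
    nm <- wanted[[i]]
    s <- simulate_season(profiles[[nm]], seed = seed + i,
                         n_replicates = config$n_replicates %||% 3L,
                         noise_scale = noise_scale)
    r <- synthesize_fluorescence(s, profiles[[nm]], seed = seed + 1000L + i,
                                 channel_sigma = channel_sigma)
    chem[[nm]] <- s; recs[[nm]] <- r
  }
  chem_path <- config$chemistry_out %||% "chemistry.csv"
  rec_path <- config$readings_out %||% "readings.csv"
  meta <- list(seed = seed, generator = "grapemx")
  write_grapemx_csv(do.call(rbind, chem), chem_path, meta = meta)
  write_grapemx_csv(do.call(rbind, recs), rec_path, meta = meta)
  list(chemistry = chem_path, readings = rec_path)
}

pipeline_indices <- function(config) {
  input <- config$input %||%
    stop_grapemx("grapemx_config_error", "`indices` needs an `input` CSV")
  rec <- read_fluorescence_csv(input)
  rec <- compute_indices(rec)
  out <- config$output %||% "indices.csv"
  write_grapemx_csv(rec, out, meta = attr(rec, "meta"))
  list(indices = out)
}

pipeline_calibrate <- function(config) {
  input <- config$input %||%
    stop_grapemx("grapemx_config_error", "`calibrate` needs an `input` CSV")
  df <- read_grapemx_csv(input)
  x_col <- config$x %||% stop_grapemx("grapemx_config_error",
                                      "`calibrate` needs `x` column name")
  y_col <- config$y %||% stop_grapemx("grapemx_config_error",
                                      "`calibrate` needs `y` column name")
  for (col in c(x_col, y_col)) {
    if (!col %in% names(df)) {
      stop_grapemx("grapemx_data_error",
                   sprintf("column `%s` not in `%s`", col, input))
    }
  }
  if (isTRUE(config$apply_tss_threshold) && "tss" %in% names(df)) {
    df <- filter_tss_domain(df, config$tss_threshold %||% 10)
  }
  family <- config$family %||% "linear"
  model <- switch(match.arg(family, c("linear", "polynomial", "sigmoid",
                                      "auto")),
    linear = fit_linear(df[[x_col]], df[[y_col]], x_col, y_col),
    polynomial = fit_polynomial(df[[x_col]], df[[y_col]],
                                config$degree %||% 2L, x_col, y_col),
    sigmoid = fit_sigmoid(df[[x_col]], df[[y_col]],
                          x_name = x_col, y_name = y_col),
    auto = select_model(df[[x_col]], df[[y_col]],
                        candidates = c("linear", "polynomial", "sigmoid"),
                        degree = config$degree %||% 4L,
                        x_name = x_col, y_name = y_col))
  out <- config$output %||% "calibration.json"
  write_calibration_json(model, out)
  csv_out <- sub("\\.json$", ".csv", out)
  write_grapemx_csv(calibration_table(model), csv_out)
  list(model_json = out, model_csv = csv_out)
}

pipeline_econ <- function(config, quiet = FALSE) {
  sc <- if (!is.null(config$config_file)) {
    read_scenario_config(config$config_file)
  } else {
    plan <- farm_preset(config$preset %||% "two-hectare",
                        n_cultivars = config$n_cultivars)
    list(plan = plan, costs = cost_parameters(),
         scenario = config$scenario %||% "average",
         lifetime = config$lifetime %||% 7L,
         max_lifetime = config$max_lifetime %||% 50L,
         seed = config$seed %||% 1L,
         monte_carlo = list(n_draws = config$n_draws %||% 1000L,
                            rel_half_width = config$rel_half_width %||% 0.2))
  }
  report <- npv_report(sc$plan, sc$costs, lifetime = sc$lifetime,
                       max_lifetime = sc$max_lifetime)
  names(report)[names(report) == "cash_flow_eur_y"] <- "cash_flow_eur_y"
  out <- config$output %||% "econ_report.csv"
  write_grapemx_csv(report, out,
                    meta = list(seed = sc$seed,
                                lifetime = sc$lifetime),
                    digits = list(cash_flow_eur_y = 2L, npv_eur = 2L))
  if (!quiet) cat(format_npv_report(report), "\n")
  list(report = out)
}

pipeline_report <- function(config) {
  grids <- lapply(list(
    `two-hectare-2` = farm_preset("two-hectare", 2L),
    `two-hectare-3` = farm_preset("two-hectare", 3L),
    mossi = farm_preset("mossi")), function(plan) {
      npv_report(plan, cost_parameters(),
                 lifetime = config$lifetime %||% 7L)
    })
  combined <- do.call(rbind, Map(function(nm, g) {
    g$case <- nm
    g[, c("case", setdiff(names(g), "case"))]
  }, names(grids), grids))
  rownames(combined) <- NULL
  out <- config$output %||% "npv_report.csv"
  write_grapemx_csv(combined, out,
                    digits = list(cash_flow_eur_y = 2L, npv_eur = 2L))
  cat(paste(utils::capture.output(print(combined, row.names = FALSE)),
            collapse = "\n"), "\n")
  list(report = out)
}
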