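# Readers/writers for the canonical long-format CSV tables, world
# directory serialization, and the end-to-end pipeline driver.

table_schemas <- function() {
  num6 <- setNames(rep("numeric", 6), lu_categories())
  list(
    watersheds = list(
      required = c(watershed_id = "character", huc2 = "character",
                   area_km2 = "numeric"),
      optional = c(in_marb = "logical", in_northeast = "logical"),
      key = "watershed_id"),
    regions = list(
      required = c(region_id = "character", watershed_id = "character"),
      key = c("region_id", "watershed_id")),
    landuse = list(
      required = c(c(watershed_id = "character", year = "integer"), num6),
      optional = c(scenario_id = "character"),
      key = c("watershed_id", "year")),
    crops = list(
      required = c(watershed_id = "character", year = "integer",
                   crop_type = "character", area_fraction = "numeric",
                   rate_kg_km2_yr = "numeric"),
      optional = c(scenario_id = "character"),
      key = c("watershed_id", "year", "crop_type")),
    precip = list(
      required = c(watershed_id = "character", model_id = "character",
                   date = "date", pr_mm = "numeric"),
      optional = c(scenario_id = "character"),
      key = c("watershed_id", "model_id", "date")),
    features = list(
      required = c(watershed_id = "character", model_id = "character",
                   year = "integer", p_annual_mm = "numeric",
                   p_mam_ext_mm = "numeric"),
      optional = c(scenario_id = "character"),
      key = c("watershed_id", "model_id", "year")),
    calibration = list(
      required = c(catchment_id = "character", year = "integer",
                   tn_flux_kg_km2_yr = "numeric", nani_kg_km2_yr = "numeric",
                   p_annual_mm = "numeric", p_mam_ext_mm = "numeric"),
      optional = setNames(rep("numeric", 6), lu_col(lu_categories())),
      key = c("catchment_id", "year")),
    nani_components = list(
      required = c(watershed_id = "character", year = "integer",
                   component = "character", value_kg_km2_yr = "numeric"),
      key = c("watershed_id", "year", "component")),
    import_history = list(
      required = c(huc2 = "character", year = "integer",
                   import_kg_km2_yr = "numeric",
                   fertilizer_kg_km2_yr = "numeric",
                   fixation_kg_km2_yr = "numeric"),
      key = c("huc2", "year")),
    reference_totals = list(
      required = c(huc2 = "character", total_kg = "numeric"),
      key = "huc2"),
    deposition = list(
      required = c(watershed_id = "character", year = "integer",
                   dep_kg_km2_yr = "numeric"),
      optional = c(scenario_id = "character"),
      key = c("watershed_id", "year")),
    nonfood = list(
      required = c(watershed_id = "character", year = "integer",
                   value_kg_km2_yr = "numeric"),
      key = c("watershed_id", "year")),
    flux = list(
      required = c(watershed_id = "character", model_id = "character",
                   year = "integer", flux_kg_km2_yr = "numeric"),
      key = c("watershed_id", "model_id", "year"))
  )
}

coerce_column <- function(x, type, col, path) {
  out <- switch(type,
    character = as.character(x),
    integer = suppressWarnings(as.integer(x)),
    numeric = suppressWarnings(as.numeric(x)),
    logical = as.logical(x),
    date = as.Date(x))
  if (type %in% c("integer", "numeric", "date", "logical") &&
      any(is.na(out) & !is.na(x))) {
    rn_schema_error(sprintf("column `%s` in %s is not of type %s",
                            col, basename(path), type))
  }
  out
}

#' Read and validate a canonical table
#'
#' Reads one of the package's long-format CSV tables, checks required
#' columns and types, coerces them, and rejects duplicate keys. Known
#' schema ids: `watersheds`, `regions`, `landuse`, `crops`, `precip`,
#' `features`, `calibration`, `nani_components`, `import_history`,
#' `reference_totals`, `deposition`, `nonfood`, `flux`.
#'
#' @param path CSV file path.
#' @param schema Schema id.
#' @return A validated tibble.
#' @export
read_table <- function(path, schema) {
  schemas <- table_schemas()
  if (!schema %in% names(schemas)) {
    rn_config_error(paste0("unknown table schema `", schema, "`"))
  }
  if (!file.exists(path)) {
    rn_missing_input(paste0("file not found: ", path))
  }
  sc <- schemas[[schema]]
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(names(sc$required), names(df))
  if (length(miss)) {
    rn_schema_error(sprintf("%s is missing required column(s): %s",
                            basename(path), paste(miss, collapse = ", ")))
  }
  types <- c(sc$required, sc$optional %||% character())
  for (col in intersect(names(types), names(df))) {
    df[[col]] <- coerce_column(df[[col]], types[[col]], col, path)
  }
  key <- sc$key
  if ("scenario_id" %in% names(df)) key <- union(key, "scenario_id")
  if ("model_id" %in% names(df) && !"model_id" %in% key &&
      schema %in% c("precip", "features")) {
    key <- union(key, "model_id")
  }
  if (anyDuplicated(df[key])) {
    rn_schema_error(sprintf("duplicate key (%s) in %s",
                            paste(key, collapse = ", "), basename(path)))
  }
  tibble::as_tibble(df)
}

#' Write a canonical table
#'
#' Plain CSV writer (no row names, no quoting surprises) used for all
#' package outputs so result directories are byte-reproducible.
#'
#' @param df Data frame.
#' @param path Output path; parent directories are created.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

add_scenario <- function(tbl, id) {
  tbl$scenario_id <- id
  tbl
}

#' Write / read a synthetic world directory
#'
#' Serializes a `tn_world` to plain CSV tables plus a `truth.yaml` carrying
#' the generator configuration and ground truth, and reads it back. Daily
#' precipitation can be omitted (`include_precip = FALSE`) when only the
#' reduced features are needed downstream.
#'
#' @param world A `tn_world` from [generate_world()].
#' @param dir Directory to create.
#' @param include_precip Write the (large) daily `precip.csv`?
#' @return `dir` (resp. the restored `tn_world`), invisibly.
#' @export
write_world <- function(world, dir, include_precip = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_table(world$watersheds, file.path(dir, "watersheds.csv"))
  write_table(world$regions, file.path(dir, "regions.csv"))

  lu <- dplyr::bind_rows(lapply(names(world$landuse), function(s) {
    add_scenario(world$landuse[[s]]$landuse, s)
  }))
  write_table(lu, file.path(dir, "landuse.csv"))
  crops <- dplyr::bind_rows(lapply(names(world$landuse), function(s) {
    add_scenario(world$landuse[[s]]$crops, s)
  }))
  write_table(crops, file.path(dir, "crops.csv"))

  if (include_precip && !is.null(world$precip)) {
    write_table(dplyr::bind_rows(world$precip), file.path(dir, "precip.csv"))
  }
  feats <- dplyr::bind_rows(lapply(names(world$precip_features), function(s) {
    add_scenario(world$precip_features[[s]], s)
  }))
  write_table(feats, file.path(dir, "features.csv"))

  comp_long <- world$components |>
    tidyr::pivot_longer(cols = c("fertilizer", "fixation", "deposition",
                                 "food_feed_import", "nonfood_crop_export",
                                 "nani"),
                        names_to = "component",
                        values_to = "value_kg_km2_yr")
  write_table(comp_long, file.path(dir, "nani_components.csv"))
  write_table(world$import_history, file.path(dir, "import_history.csv"))
  write_table(world$reference_fertilizer,
              file.path(dir, "reference_fertilizer.csv"))
  dep <- dplyr::bind_rows(lapply(names(world$deposition), function(s) {
    add_scenario(world$deposition[[s]], s)
  }))
  write_table(dep, file.path(dir, "deposition.csv"))
  write_table(world$nonfood, file.path(dir, "nonfood.csv"))

  cfg <- unclass(world$config)
  cfg$coefficients <- as.list(unclass(cfg$coefficients))
  yaml::write_yaml(list(config = cfg,
                        truth = rapply(world$truth, unclass, how = "list")),
                   file.path(dir, "truth.yaml"), precision = 17)
  invisible(dir)
}

#' @rdname write_world
#' @export
read_world <- function(dir) {
  doc <- yaml::read_yaml(file.path(dir, "truth.yaml"))
  cfgl <- doc$config
  cfgl$coefficients <- do.call(tn_coefficients, cfgl$coefficients)
  cfgl$n_models <- unlist(cfgl$n_models)
  for (f in c("years_historical", "years_baseline", "years_future",
              "census_years")) {
    cfgl[[f]] <- as.integer(unlist(cfgl[[f]]))
  }
  cfgl$nani_shares <- unlist(cfgl$nani_shares)
  cfg <- do.call(world_config, cfgl)

  split_scen <- function(tbl) {
    split(dplyr::select(tbl, -"scenario_id"), tbl$scenario_id)
  }
  lu_all <- read_table(file.path(dir, "landuse.csv"), "landuse")
  crops_all <- read_table(file.path(dir, "crops.csv"), "crops")
  lus <- split_scen(lu_all)
  crs <- split_scen(crops_all)
  landuse <- lapply(names(lus), function(s) {
    list(landuse = lus[[s]], crops = crs[[s]])
  })
  names(landuse) <- names(lus)

  feats <- split_scen(read_table(file.path(dir, "features.csv"), "features"))
  precip <- NULL
  ppath <- file.path(dir, "precip.csv")
  if (file.exists(ppath)) {
    precip_all <- read_table(ppath, "precip")
    precip <- split(precip_all, precip_all$scenario_id)
  }

  comp <- read_table(file.path(dir, "nani_components.csv"),
                     "nani_components") |>
    tidyr::pivot_wider(names_from = "component",
                       values_from = "value_kg_km2_yr")
  import_history <- read_table(file.path(dir, "import_history.csv"),
                               "import_history")
  dep <- split_scen(read_table(file.path(dir, "deposition.csv"), "deposition"))

  structure(list(
    config = cfg,
    watersheds = read_table(file.path(dir, "watersheds.csv"), "watersheds"),
    regions = read_table(file.path(dir, "regions.csv"), "regions"),
    landuse = landuse,
    precip = precip,
    precip_features = feats,
    components = comp,
    import_history = import_history,
    import_model = fit_import_regression(import_history),
    reference_fertilizer = read_table(
      file.path(dir, "reference_fertilizer.csv"), "reference_totals"),
    deposition = dep,
    nonfood = read_table(file.path(dir, "nonfood.csv"), "nonfood"),
    truth = doc$truth
  ), class = "tn_world")
}

pipeline_log <- function(fmt, ...) {
  message(sprintf(paste0("[rivertn %s] ", fmt),
                  format(Sys.time(), "%H:%M:%S"), ...))
}

#' Run the full projection pipeline
#'
#' Generates (or loads) a synthetic world, reduces precipitation to
#' features, projects TN flux for the historical baseline and for each
#' requested scenario — both land-management-only (historical
#' precipitation) and combined (paired-RCP precipitation) — and summarizes
#' regional percent changes with ensemble spread and robustness. Results
#' are written as CSV plus a JSON manifest; two runs with the same
#' configuration produce byte-identical result tables.
#'
#' @param config A list, or path to a YAML file, with elements:
#'   * `seed` — integer master seed (default 1);
#'   * `world` — named overrides passed to [world_config()];
#'   * `input_dir` — optional world directory from [write_world()]
#'     (bypasses generation);
#'   * `scenarios` — SSP ids (default: all six);
#'   * `hist_period`, `future_period` — `c(start, end)` overrides;
#'   * `coefficients` — path to a [write_fitted_model()] YAML, or omitted
#'     for the published default coefficients;
#'   * `outdir` — output directory (required).
#' @return Invisibly, a list with the `changes` tibble and `outdir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$outdir)) rn_config_error("config must name an `outdir`")
  seed <- as.integer(config$seed %||% 1L)
  scenarios <- config$scenarios %||% ssp_ids()

  coefficients <- if (!is.null(config$coefficients)) {
    if (!file.exists(config$coefficients)) {
      rn_missing_input(paste0("coefficient file not found: ",
                              config$coefficients))
    }
    as_tn_coefficients(read_fitted_model(config$coefficients))
  } else {
    tn_coefficients()
  }

  if (!is.null(config$input_dir)) {
    pipeline_log("loading world from %s", config$input_dir)
    world <- read_world(config$input_dir)
  } else {
    cfg <- do.call(world_config, c(config$world %||% list(),
                                   list(seed = seed)))
    pipeline_log("generating synthetic world (%d watersheds, seed %d)",
                 cfg$n_watersheds, seed)
    world <- generate_world(cfg, scenarios)
  }
  cfg <- world$config
  hist_period <- as.list(setNames(
    config$hist_period %||% range(cfg$years_historical), c("start", "end")))
  fut_period <- as.list(setNames(
    config$future_period %||% range(cfg$years_future), c("start", "end")))
  hist_years <- hist_period$start:hist_period$end
  fut_years <- fut_period$start:fut_period$end

  pipeline_log("historical baseline run")
  base_spec <- scenario_spec(scenarios[1], precipitation = "historical",
                             cropland = "historical",
                             developed = "historical",
                             fertilizer_rate = "historical",
                             nani_source = "observed")
  hist_field <- run_projection(base_spec, world, hist_years, coefficients)

  rows <- list()
  for (ssp in scenarios) {
    pipeline_log("scenario %s: land-management-only run", ssp)
    lm_spec <- scenario_spec(ssp, precipitation = "historical")
    lm_field <- run_projection(lm_spec, world, fut_years, coefficients)
    lm_res <- change_results(hist_field, lm_field, world,
                             hist_period = hist_period,
                             fut_period = fut_period)
    rows[[paste0(ssp, "/lm")]] <- dplyr::mutate(
      lm_res, scenario_id = ssp, precipitation = "historical",
      .before = 1)

    pipeline_log("scenario %s: combined run (paired %s)", ssp, pair_rcp(ssp))
    cb_spec <- scenario_spec(ssp, precipitation = "paired-rcp")
    cb_field <- run_projection(cb_spec, world, fut_years, coefficients)
    cb_res <- change_results(hist_field, cb_field, world,
                             hist_period = hist_period,
                             fut_period = fut_period)
    rows[[paste0(ssp, "/cb")]] <- dplyr::mutate(
      cb_res, scenario_id = ssp, precipitation = "paired-rcp",
      .before = 1)
  }
  changes <- dplyr::bind_rows(rows) |>
    dplyr::arrange(.data$scenario_id, .data$precipitation, .data$region_id)

  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_table(changes, file.path(outdir, "changes.csv"))
  manifest <- list(
    package = "rivertn",
    version = as.character(utils::packageVersion("rivertn")),
    seed = seed,
    scenarios = scenarios,
    hist_period = unlist(hist_period),
    future_period = unlist(fut_period),
    config = config[setdiff(names(config), "outdir")],
    changes_hash = rlang::hash(changes))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  pipeline_log("results written to %s", outdir)
  invisible(list(changes = changes, outdir = outdir))
}
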