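#' Default run configuration
#'
#' Thresholds and grids mirror the analysis defaults throughout the
#' package: suitability cut 0.4, contribution cut 5 percent, correlation
#' cut 0.7, VIF gate 5, beta grid 1-10 by 0.5, split fraction 0.7,
#' 10 replicates, all nine scenario x period combinations.
#'
#' @param base_seed base RNG seed for the whole run.
#' @param outdir output directory.
#' @return A named list (class `run_config`).
#' @export
default_config <- function(base_seed = 1L, outdir = tempfile("sdm_run_")) {
  structure(list(
    base_seed = as.integer(base_seed),
    outdir = outdir,
    reps = 10L,
    split_fraction = 0.7,
    thresholds = list(suitable = 0.4, contribution = 5, correlation = 0.7,
                      vif = 5),
    beta_grid = seq(1, 10, by = 0.5),
    output_transform = "logistic",
    do_beta_sweep = TRUE,
    n_background = 10000L,
    scenarios = scenario_table(),
    grid = list(xmin = 124, ymin = 32, cellsize = 0.05, nrow = 96, ncol = 64),
    noise_sd = 1,
    mpa_coverage = 0.3,
    species = list(
      species_1 = list(t_opt = 12.0, v_slope = 8.0, n = 250),
      species_2 = list(t_opt = 13.0, v_slope = 7.0, n = 100),
      species_3 = list(t_opt = 11.0, v_slope = 8.0, n = 120),
      species_4 = list(t_opt = 12.5, v_slope = 6.0, n = 150))),
    class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Fields present in the file override [default_config()]; everything else
#' keeps its default. Validates threshold ranges and the beta grid.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  for (nm in names(user)) {
    if (nm == "thresholds") {
      for (k in names(user$thresholds)) cfg$thresholds[[k]] <- user$thresholds[[k]]
    } else if (nm == "scenarios") {
      cfg$scenarios <- do.call(rbind, lapply(user$scenarios, function(s)
        data.frame(scenario = s$scenario, period = s$period)))
    } else cfg[[nm]] <- user[[nm]]
  }
  validate_config(cfg)
}

validate_config <- function(cfg) {
  th <- cfg$thresholds
  if (th$suitable < 0 || th$suitable > 1 || th$correlation < 0 ||
      th$correlation > 1 || th$contribution < 0 || th$contribution > 100 ||
      th$vif <= 1)
    stop("config error: thresholds out of range", call. = FALSE)
  if (length(cfg$beta_grid) < 1 || is.unsorted(cfg$beta_grid))
    stop("config error: beta grid must be non-empty and ascending",
         call. = FALSE)
  if (cfg$split_fraction <= 0 || cfg$split_fraction >= 1)
    stop("config error: split fraction must be in (0, 1)", call. = FALSE)
  cfg
}

# seeded uniform background sample of the valid cells (all cells if few)
sample_background <- function(stack, n_background, seed) {
  design <- stack_design(stack)
  if (nrow(design) > n_background) {
    set.seed(seed)
    keep <- sort(sample.int(nrow(design), n_background))
    idx <- attr(design, "cell_index")[keep]
    design <- design[keep, , drop = FALSE]
    attr(design, "cell_index") <- idx
  }
  design
}

#' Run the full synthetic pipeline
#'
#' simulate -> select -> fit -> project -> change -> report. Generates the
#' synthetic world (layers, bathymetry mask, species occurrences, MPA),
#' screens variables and tunes beta per species, fits the replicate
#' models, projects present and scenario HSI at block resolution, and
#' writes the area/trend summary, centroid series, richness and MPA
#' overlap tables plus a JSON run record to `config$outdir`.
#'
#' Deterministic given the configuration: all stage seeds derive from
#' `base_seed`.
#'
#' @param config a `run_config` (see [default_config()] / [read_config()]).
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with every in-memory artefact (stacks,
#'   reports, models, summaries) plus `outdir`.
#' @export
run_pipeline <- function(config = default_config(), quiet = FALSE) {
  cfg <- validate_config(config)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  log_file <- file.path(cfg$outdir, "run.log")
  say <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(...))
    cat(msg, "\n", file = log_file, append = TRUE)
    if (!quiet) message(msg)
  }
  t0 <- Sys.time()
  g <- grid_spec(cfg$grid$xmin, cfg$grid$ymin, cfg$grid$cellsize,
                 cfg$grid$nrow, cfg$grid$ncol)

  say("simulate: generating layers, bathymetry, MPA")
  lat_top <- g$ymin + g$nrow * g$cellsize
  bathy <- generate_bathymetry_and_mask(
    g, seed = cfg$base_seed,
    # turbid (5 m limit) subregion: the north-western half of the coast
    turbid_region = c(g$xmin, g$xmin + 1.5,
                      g$ymin + 0.5 * (lat_top - g$ymin), lat_top))
  stack <- generate_env_stack(g, seed = cfg$base_seed, noise_sd = cfg$noise_sd,
                              mask = bathy$mask)
  stack$depth <- bathy$depth
  write_stack_csv(stack, file.path(cfg$outdir, "env_present.csv"))
  mpa <- generate_mpa_mask(g, seed = cfg$base_seed,
                           coverage_fraction = cfg$mpa_coverage,
                           mask = stack$mask)
  write_mpa_csv(mpa$mask, g, file.path(cfg$outdir, "mpa.csv"))
  write_mpa_geojson(mpa$polygons, file.path(cfg$outdir, "mpa.geojson"))

  background <- sample_background(stack, cfg$n_background, cfg$base_seed)
  candidates <- c("temp_ltmin", "vel_mean", "temp_ltmax", "sal_mean",
                  "pp_mean", "no3_mean")

  scen_stacks <- list()
  for (r in seq_len(nrow(cfg$scenarios))) {
    sc <- cfg$scenarios$scenario[r]; pd <- cfg$scenarios$period[r]
    scen_stacks[[paste(sc, pd)]] <- apply_scenario(stack, scenario_spec(sc, pd))
  }

  summary_rows <- list(); centroid_rows <- list()
  eval_rows <- list(); selection <- list()
  suit_present <- list(); suit_future <- list()
  species_seed <- cfg$base_seed
  for (sp in names(cfg$species)) {
    spp <- cfg$species[[sp]]
    species_seed <- species_seed + 101L
    say("species %s: simulate occurrences (n=%d)", sp, spp$n)
    surf <- true_surface(t_opt = spp$t_opt, v_slope = spp$v_slope)
    occ <- sample_occurrences(surf, stack, n = spp$n, seed = species_seed,
                              species = sp)
    occ <- dedup_to_grid(occ, cell = g$cellsize)
    write_occurrences(occ, file.path(cfg$outdir, paste0("occ_", sp, ".csv")))
    occ_now <- occurrence_set(as.data.frame(occ)[occ$era == "present", ],
                              dedup = TRUE)
    pres <- extract_at_points(stack, occ_now, candidates)
    bg <- background[, candidates, drop = FALSE]

    say("species %s: variable selection", sp)
    sel <- select_model(pres, bg,
                        contribution_threshold = cfg$thresholds$contribution,
                        corr_threshold = cfg$thresholds$correlation,
                        vif_threshold = cfg$thresholds$vif,
                        betas = if (isTRUE(cfg$do_beta_sweep)) cfg$beta_grid else cfg$beta_grid[1],
                        reps = cfg$reps, base_seed = species_seed)
    selection[[sp]] <- sel
    write_selection_csv(sel, file.path(cfg$outdir, paste0("selection_", sp, ".csv")))

    say("species %s: %d replicate fits at beta %.1f on {%s}", sp, cfg$reps,
        sel$beta, paste(sel$retained, collapse = ", "))
    rf <- replicate_fits(pres[, sel$retained, drop = FALSE],
                         bg[, sel$retained, drop = FALSE],
                         beta_multiplier = sel$beta, reps = cfg$reps,
                         base_seed = species_seed)
    agg <- aggregate_replicates(rf$results)
    eval_rows[[sp]] <- data.frame(species = sp, auc = agg$auc, tss = agg$tss)
    data.table::fwrite(rf$results,
                       file.path(cfg$outdir, paste0("replicates_", sp, ".csv")))
    write_maxent_json(rf$models[[1]],
                      file.path(cfg$outdir, paste0("model_", sp, "_rep1.json")))

    hsi_now <- project_hsi(rf$models, stack, type = cfg$output_transform)
    sg_now <- block_average(hsi_now, g)
    suit_present[[sp]] <- sg_now
    write_suitability_csv(sg_now, file.path(cfg$outdir, paste0("hsi_present_", sp, ".csv")))
    centroid_rows[[length(centroid_rows) + 1L]] <- data.frame(
      species = sp, scenario = "Present", period = "",
      centroid = weighted_centroid(sg_now))

    suit_future[[sp]] <- list()
    for (key in names(scen_stacks)) {
      hsi_f <- project_hsi(rf$models, scen_stacks[[key]],
                           type = cfg$output_transform)
      sg_f <- block_average(hsi_f, g)
      suit_future[[sp]][[key]] <- sg_f
      parts <- strsplit(key, " ")[[1]]
      cs <- change_summary(sg_now, sg_f, species = sp,
                           scenario = parts[1], period = parts[2])
      summary_rows[[length(summary_rows) + 1L]] <- data.frame(
        species = sp, scenario = parts[1], period = parts[2],
        area_present = cs$area_present, area_future = cs$area_future,
        trend = round(cs$trend, 2))
      centroid_rows[[length(centroid_rows) + 1L]] <- data.frame(
        species = sp, scenario = parts[1], period = parts[2],
        centroid = cs$centroid_future)
    }
  }

  say("community: richness and MPA overlap")
  rich_now <- richness(suit_present)
  mo_now <- mpa_overlap(rich_now, mpa$mask, mpa_grid = g)
  mpa_rows <- list(data.frame(scenario = "Present", period = "",
                              protected_fraction = mo_now$protected_fraction))
  total_rows <- list(data.frame(
    scenario = "Present", period = "",
    area = sum(block_areas_km2(rich_now$grid)[
      !is.na(rich_now$richness) & rich_now$richness >= 1]) / 1e3))
  for (key in names(scen_stacks)) {
    rich_f <- richness(lapply(suit_future, `[[`, key))
    mo_f <- mpa_overlap(rich_f, mpa$mask, mpa_grid = g)
    parts <- strsplit(key, " ")[[1]]
    mpa_rows[[length(mpa_rows) + 1L]] <- data.frame(
      scenario = parts[1], period = parts[2],
      protected_fraction = mo_f$protected_fraction)
    total_rows[[length(total_rows) + 1L]] <- data.frame(
      scenario = parts[1], period = parts[2],
      area = sum(block_areas_km2(rich_f$grid)[
        !is.na(rich_f$richness) & rich_f$richness >= 1]) / 1e3)
  }

  summary_df <- do.call(rbind, summary_rows)
  data.table::fwrite(summary_df, file.path(cfg$outdir, "area_trend_summary.csv"))
  data.table::fwrite(do.call(rbind, centroid_rows),
                     file.path(cfg$outdir, "centroids.csv"))
  data.table::fwrite(do.call(rbind, eval_rows),
                     file.path(cfg$outdir, "evaluation.csv"))
  data.table::fwrite(do.call(rbind, mpa_rows),
                     file.path(cfg$outdir, "mpa_overlap.csv"))
  data.table::fwrite(do.call(rbind, total_rows),
                     file.path(cfg$outdir, "richness_area.csv"))

  cfg_json <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  hash_file <- tempfile(); writeLines(cfg_json, hash_file)
  record <- list(
    package = "sargassdm",
    version = as.character(utils::packageVersion("sargassdm")),
    config = jsonlite::fromJSON(cfg_json, simplifyVector = FALSE),
    config_md5 = unname(tools::md5sum(hash_file)),
    base_seed = cfg$base_seed,
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(record, file.path(cfg$outdir, "run_record.json"),
                       auto_unbox = TRUE, digits = NA)
  say("done in %.1f s", record$elapsed_sec)
  invisible(list(outdir = cfg$outdir, config = cfg, stack = stack,
                 mpa = mpa, selection = selection,
                 suitability_present = suit_present,
                 suitability_future = suit_future,
                 summary = summary_df))
}

#' Command-line entry point
#'
#' Subcommands: `run-all` (the full pipeline; `simulate`, `select`, `fit`,
#' `project`, `change` and `report` are stages of the same deterministic
#' run and execute it too). Flags: `--config` (YAML), `--seed`,
#' `--outdir`, `--output-transform`. Exit codes: 0 success, 2
#' configuration error, 3 data error, 4 convergence error.
#'
#' @param args character vector of command-line arguments.
#' @return Exit status, invisibly (also used by the installed script
#'   `inst/scripts/sargassdm-cli.R`).
#' @export
sdm_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    sub <- if (length(args) && !startsWith(args[1], "-")) args[1] else "run-all"
    rest <- if (length(args) && !startsWith(args[1], "-")) args[-1] else args
    opts <- list(config = NULL, seed = 1L, outdir = NULL,
                 transform = "logistic")
    i <- 1L
    while (i <= length(rest)) {
      a <- rest[i]
      grab <- function() { i <<- i + 1L; rest[i] }
      switch(a,
             "--config" = { opts$config <- grab() },
             "--seed" = { opts$seed <- as.integer(grab()) },
             "--outdir" = { opts$outdir <- grab() },
             "--output-transform" = { opts$transform <- grab() },
             stop("config error: unknown flag ", a, call. = FALSE))
      i <- i + 1L
    }
    if (!sub %in% c("run-all", "simulate", "select", "fit", "project",
                    "change", "report"))
      stop("config error: unknown subcommand ", sub, call. = FALSE)
    cfg <- if (is.null(opts$config)) default_config(base_seed = opts$seed)
           else read_config(opts$config)
    cfg$base_seed <- opts$seed
    if (!is.null(opts$outdir)) cfg$outdir <- opts$outdir
    cfg$output_transform <- opts$transform
    run_pipeline(cfg)
    0L
  },
  sdm_convergence_error = function(e) { message(conditionMessage(e)); 4L },
  error = function(e) {
    message(conditionMessage(e))
    if (grepl("config error|unknown scenario|unknown period|not found",
              conditionMessage(e))) 2L else 3L
  })
  invisible(status)
}
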