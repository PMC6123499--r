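#' Default pipeline configuration
#'
#' Desk-scale defaults for the four-stage pipeline: three pooled study
#' extracts totalling 20 000 panel individuals, raked to a synthetic
#' 3-million population and subsampled at 1% into a base population of
#' about 30 000, simulated monthly over 2014-2042 in ten replicate runs
#' with snapshots in 2015, 2025 and 2035.
#'
#' @param override Named list merged over the defaults (deep merge).
#' @return Nested configuration list.
#' @export
default_config <- function(override = NULL) {
  cfg <- list(
    seed = 20140101,
    cohort = list(
      studies = list(list(label = "study1", n = 13000),
                     list(label = "study2", n = 4400),
                     list(label = "study3", n = 2600)),
      margins_total = 3e6,
      sampling_fraction = 0.01,
      truth_override = NULL
    ),
    simulate = list(start = "2014-01", end = "2042-12",
                    output_years = c(2015, 2025, 2035),
                    snapshot_month = 6, n_runs = 10),
    fit = list(min_at_risk = 50)
  )
  .merge_params(cfg, override)
}

#' Read a pipeline configuration file
#' @param path YAML file.
#' @return Configuration list merged over [default_config()].
#' @export
read_config <- function(path) {
  default_config(yaml::read_yaml(path))
}

.md5_of <- function(paths) {
  h <- tools::md5sum(paths)
  names(h) <- basename(names(h))
  as.list(h)
}

.config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

.write_manifest <- function(dir, stage, config, seed, files, inputs = NULL,
                            extra = NULL) {
  man <- c(list(stage = stage, config_hash = .config_hash(config),
                seed = seed,
                version = as.character(utils::packageVersion("depsim")),
                timestamp = format(Sys.time(), tz = "UTC"),
                files = .md5_of(files),
                inputs = inputs),
           extra)
  path <- file.path(dir, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

.read_manifest <- function(dir, stage) {
  path <- file.path(dir, paste0("manifest_", stage, ".json"))
  if (!file.exists(path)) .stopf("missing manifest: %s", path)
  jsonlite::read_json(path)
}

.check_against_manifest <- function(manifest, dir) {
  for (nm in names(manifest$files)) {
    p <- file.path(dir, nm)
    if (!file.exists(p)) .stopf("manifest file missing on disk: %s", nm)
    if (!identical(unname(tools::md5sum(p))[1],
                   manifest$files[[nm]])) {
      .stopf("file '%s' does not match its manifest checksum: ", nm)
    }
  }
  invisible(TRUE)
}

#' Pipeline stage: generate synthetic datasets
#'
#' Generates the study extracts, lifetable, dementia allocation table and
#' base population from the ground-truth parameters, writes them as CSV
#' under `out_dir` with the truth serialised alongside, and records a
#' manifest sufficient to regenerate every file byte-identically.
#'
#' @param config Configuration list (see [default_config()]).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
stage_generate <- function(config = default_config(), out_dir = "data") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  params <- truth_params(config$cohort$truth_override)
  studies <- config$cohort$studies
  seeds <- .derive_seeds(config$seed, length(studies) + 1L)
  files <- character(0)
  extracts <- vector("list", length(studies))
  for (i in seq_along(studies)) {
    st <- studies[[i]]
    extracts[[i]] <- generate_study_extract(st$n, st$label, params, seeds[i])
    p <- file.path(out_dir, paste0("extract_", st$label, ".csv"))
    write_study_extract(extracts[[i]], p)
    files <- c(files, p)
  }
  lt <- generate_lifetable(params)
  p <- file.path(out_dir, "lifetable.csv")
  write_lifetable(lt, p); files <- c(files, p)
  dt <- generate_dementia_table(params)
  p <- file.path(out_dir, "dementia_table.csv")
  write_dementia_table(dt, p); files <- c(files, p)
  margins <- default_margins(config$cohort$margins_total)
  base <- build_base_population(extracts, margins,
                                config$cohort$sampling_fraction,
                                seed = seeds[length(seeds)])
  p <- file.path(out_dir, "base_population.csv")
  write_population(base, p); files <- c(files, p)
  truth_path <- file.path(out_dir, "truth_params.json")
  jsonlite::write_json(unclass(params), truth_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  files <- c(files, truth_path)
  invisible(.write_manifest(
    out_dir, "generate", config, config$seed, files,
    extra = list(scaling_factor = 1 / config$cohort$sampling_fraction)))
}

#' Pipeline stage: fit transition models
#'
#' Reads the generated study extracts (validated against the generate
#' manifest), fits every registry transition model by weighted logistic
#' regression and serialises the model set to JSON.
#'
#' @param config Configuration list.
#' @param data_dir Directory written by [stage_generate()].
#' @param out_file Path of the model JSON document.
#' @return Invisibly, the manifest path.
#' @export
stage_fit <- function(config = default_config(), data_dir = "data",
                      out_file = file.path(data_dir, "models.json")) {
  man <- .read_manifest(data_dir, "generate")
  .check_against_manifest(man, data_dir)
  paths <- list.files(data_dir, pattern = "^extract_.*\\.csv$",
                      full.names = TRUE)
  panel <- lapply(paths, read_study_extract)
  models <- fit_transition_models(panel, min_at_risk = config$fit$min_at_risk)
  write_models(models, out_file)
  invisible(.write_manifest(dirname(out_file), "fit", config, config$seed,
                            out_file, inputs = man$files))
}

#' Pipeline stage: run the simulation
#'
#' Loads the base population, fitted models, lifetable and dementia table
#' (checked against their manifests), runs the configured number of
#' replicates and writes one snapshot CSV per run and output year plus a
#' run manifest with per-year death and transition counts.
#'
#' @param config Configuration list.
#' @param data_dir Directory with generated data and fitted models.
#' @param out_dir Results directory.
#' @return Invisibly, the `simulation_results` object.
#' @export
stage_simulate <- function(config = default_config(), data_dir = "data",
                           out_dir = "results") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gman <- .read_manifest(data_dir, "generate")
  .check_against_manifest(gman, data_dir)
  fman <- .read_manifest(data_dir, "fit")
  base <- read_population(file.path(data_dir, "base_population.csv"),
                          scaling_factor = gman$scaling_factor %||% 1)
  models <- read_models(file.path(data_dir, "models.json"))
  lt <- read_lifetable(file.path(data_dir, "lifetable.csv"))
  dt <- read_dementia_table(file.path(data_dir, "dementia_table.csv"))
  sc <- config$simulate
  cfg <- simulation_config(start = sc$start, end = sc$end,
                           output_years = sc$output_years,
                           snapshot_month = sc$snapshot_month,
                           n_runs = sc$n_runs, master_seed = config$seed)
  res <- run_simulation(base, models, lt, dt, cfg)
  files <- character(0)
  events <- list()
  for (rr in res$runs) {
    for (yr in names(rr$snapshots)) {
      p <- file.path(out_dir, sprintf("run%02d_%s.csv", rr$run, yr))
      snap <- rr$snapshots[[yr]]
      write_population(snap, p)
      files <- c(files, p)
    }
    events[[length(events) + 1]] <-
      cbind(run = rr$run, rr$events)
  }
  ev <- do.call(rbind, events)
  evp <- file.path(out_dir, "events.csv")
  .write_csv(ev, evp)
  files <- c(files, evp)
  .write_manifest(out_dir, "simulate", config, config$seed, files,
                  inputs = c(gman$files, fman$files),
                  extra = list(scaling_factor = res$scaling_factor))
  invisible(res)
}

#' Pipeline stage: report
#'
#' Re-reads the simulation snapshots (refusing to run if any file fails
#' its manifest checksum or if the simulate manifest's configuration hash
#' does not match), rebuilds the `simulation_results`, and writes tidy CSV
#' reporting surfaces: the output cube, relative-change tables,
#' Sullivan health expectancies per output year and sex, the birth-cohort
#' independence trace and ten-run ranges.
#'
#' @param config Configuration list.
#' @param data_dir Generated-data directory (for the lifetable).
#' @param results_dir Directory written by [stage_simulate()].
#' @param out_dir Report directory.
#' @return Invisibly, a list of the report data.frames.
#' @export
stage_report <- function(config = default_config(), data_dir = "data",
                         results_dir = "results", out_dir = "reports") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sman <- .read_manifest(results_dir, "simulate")
  if (!identical(sman$config_hash, .config_hash(config))) {
    .stopf("configuration does not match the simulate manifest; refusing to report")
  }
  .check_against_manifest(sman, results_dir)
  scaling <- sman$scaling_factor %||% 1
  lt <- read_lifetable(file.path(data_dir, "lifetable.csv"))
  snaps <- list.files(results_dir, pattern = "^run\\d+_\\d{4}\\.csv$",
                      full.names = TRUE)
  runs <- list()
  for (p in snaps) {
    mm <- regmatches(basename(p), regexec("^run(\\d+)_(\\d{4})\\.csv$",
                                          basename(p)))[[1]]
    r <- as.integer(mm[2]); yr <- mm[3]
    pop <- .read_validated(p, c(.state_col_types(),
                                interval_of_need = "character"))
    if (is.null(runs[[as.character(r)]])) {
      runs[[as.character(r)]] <- list(run = r, seed = NA_integer_,
                                      snapshots = list(),
                                      events = data.frame())
    }
    runs[[as.character(r)]]$snapshots[[yr]] <- pop
  }
  res <- structure(list(runs = unname(runs[order(as.integer(names(runs)))]),
                        scaling_factor = scaling, config = NULL),
                   class = "simulation_results")
  cube <- tabulate_runs(res)
  .write_csv(as.data.frame(cube), file.path(out_dir, "output_cube.csv"))

  # dependency counts by age band with first-run headline and range
  years <- sort(unique(cube$year))
  dep <- cube_margin(cube, c("run", "year", "age_band", "interval_of_need"))
  dep$count_population <- dep$count * scaling
  .write_csv(dep, file.path(out_dir, "dependency_counts.csv"))

  rel <- NULL
  if (length(years) >= 2) {
    y0 <- min(years)
    first <- dep[dep$run == 1, ]
    key <- function(d) paste(d$age_band, d$interval_of_need)
    base_rows <- first[first$year == y0, ]
    rel <- do.call(rbind, lapply(setdiff(years, y0), function(y1) {
      now <- first[first$year == y1, ]
      m <- match(key(now), key(base_rows))
      ok <- !is.na(m) & base_rows$count[m] > 0
      data.frame(period = paste0(y0, "-", y1),
                 age_band = now$age_band[ok],
                 interval_of_need = now$interval_of_need[ok],
                 change_pct = relative_change(base_rows$count[m][ok],
                                              now$count[ok]))
    }))
    .write_csv(rel, file.path(out_dir, "relative_change.csv"))
  }

  he <- list()
  for (rr in res$runs) {
    for (yr in names(rr$snapshots)) {
      pv <- dependency_prevalence(rr$snapshots[[yr]], ages = 65:max(lt$age))
      h <- sullivan(pv, lt, from_age = 65, year = as.integer(yr))
      h$run <- rr$run
      he[[length(he) + 1]] <- h
    }
  }
  he <- do.call(rbind, he)
  .write_csv(he, file.path(out_dir, "health_expectancy.csv"))

  tr <- cohort_trace(res)
  .write_csv(tr, file.path(out_dir, "cohort_trace.csv"))

  rng <- range_over_runs(res, function(rr) {
    vapply(rr$snapshots, function(s) sum(s$alive & s$age_months >= 780),
           numeric(1))
  })
  names(rng)[1] <- "statistic"
  rng$statistic <- paste0("alive_65plus_", rng$statistic)
  .write_csv(rng, file.path(out_dir, "ranges.csv"))

  out_files <- list.files(out_dir, pattern = "\\.csv$", full.names = TRUE)
  .write_manifest(out_dir, "report", config, config$seed, out_files,
                  inputs = sman$files)
  invisible(list(cube = cube, dependency_counts = dep,
                 relative_change = rel, health_expectancy = he,
                 cohort_trace = tr, ranges = rng))
}
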