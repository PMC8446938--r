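#' Run the full estimation pipeline
#'
#' Executes the stages simulate (optional) -> validate -> fit (per outcome
#' and sex) -> post-process, writing all artifacts under `out_dir`:
#' input CSVs (when simulating), per-fit draw files, tidy summary rows,
#' change summaries, cascade stage proportions, and a `manifest.json`
#' recording the configuration hash, seed and package version. Runs are
#' deterministic given the seed; a rerun into the same `out_dir` with an
#' unchanged configuration skips stages whose outputs already exist
#' (resume-by-hash). Stage failures halt with the stage name; fatal
#' validation issues halt before any fitting, naming the offending rows.
#'
#' @param config list or path to a YAML file with components:
#'   * `out_dir` output directory (required);
#'   * `seed` integer seed (default 1);
#'   * `world` list of [world_config()] overrides to simulate a synthetic
#'     world, or `NULL` to read real inputs;
#'   * `inputs` paths (`crude`, `hierarchy`, `populations`, `standard`)
#'     when `world` is `NULL`;
#'   * `outcomes`, `sexes` which fits to run (defaults: prevalence,
#'     detection, treatment, control for females);
#'   * `model` list of [model_spec()] overrides;
#'   * `mcmc` list of [mcmc_config()] overrides;
#'   * `change_years` the two years compared (default 1990 and 2019).
#' @return invisibly, a list of output paths by stage.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$out_dir))
  cfg <- config
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$outcomes <- cfg$outcomes %||% c("prevalence", "detection", "treatment",
                                      "control")
  cfg$sexes <- cfg$sexes %||% "female"
  cfg$change_years <- cfg$change_years %||% c(1990L, 2019L)
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  cfg_hash <- config_hash(cfg)
  manifest_path <- file.path(out, "manifest.json")
  previous <- if (file.exists(manifest_path))
    tryCatch(jsonlite::read_json(manifest_path), error = function(e) NULL)
  resume <- !is.null(previous) && identical(previous$config_hash, cfg_hash)
  paths <- list()

  stage <- function(name, outputs, run) {
    t0 <- Sys.time()
    if (resume && all(file.exists(outputs))) {
      message("[", name, "] outputs exist and config hash matches; skipped")
      return(invisible(NULL))
    }
    res <- tryCatch(run(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    message("[", name, "] done in ",
            round(as.numeric(Sys.time() - t0, units = "secs"), 1), "s")
    res
  }

  # --- simulate ------------------------------------------------------------
  if (!is.null(cfg$world)) {
    paths$crude <- file.path(out, "crude.csv")
    paths$hierarchy <- file.path(out, "hierarchy.csv")
    paths$populations <- file.path(out, "populations.csv")
    paths$standard <- file.path(out, "standard_population.csv")
    truth_path <- file.path(out, "truth_age_standardised.csv")
    stage("simulate", c(paths$crude, paths$hierarchy, paths$populations,
                        paths$standard, truth_path), function() {
      wc <- do.call(world_config, cfg$world[names(cfg$world) != "enabled"])
      world <- make_world(wc, seed = cfg$seed)
      plan <- make_survey_plan(world, seed = cfg$seed + 1L)
      cells <- sample_surveys(world, plan, seed = cfg$seed + 2L)
      write_crude_cells(cells, paths$crude)
      write_hierarchy(world$hierarchy, paths$hierarchy)
      write_populations(world$populations, paths$populations)
      write_standard_population(world$standard_population, paths$standard)
      truth <- do.call(rbind, lapply(cfg$outcomes, function(oc)
        do.call(rbind, lapply(cfg$sexes, function(sx) {
          tm <- true_age_standardised(world, oc, sx)
          data.frame(unit = rep(rownames(tm), ncol(tm)), sex = sx,
                     outcome = oc,
                     year = rep(as.integer(colnames(tm)), each = nrow(tm)),
                     truth = as.vector(tm), stringsAsFactors = FALSE)
        }))))
      write_plain_csv(truth, truth_path)
    })
  } else {
    stopifnot(!is.null(cfg$inputs))
    paths$crude <- cfg$inputs$crude
    paths$hierarchy <- cfg$inputs$hierarchy
    paths$populations <- cfg$inputs$populations
    paths$standard <- cfg$inputs$standard
  }

  cells <- read_crude_cells(paths$crude)
  hierarchy <- read_hierarchy(paths$hierarchy)
  populations <- read_populations(paths$populations)
  std <- read_standard_population(paths$standard)

  # --- validate ------------------------------------------------------------
  spec <- do.call(model_spec, cfg$model %||% list())
  report <- validate_inputs(cells, hierarchy, populations,
                            years = range(spec$years))
  if (has_fatal(report)) {
    bad <- report[report$severity == "fatal", ]
    stop("stage 'validate' failed: ",
         paste(paste0(bad$issue, " (", bad$detail, ")"), collapse = "; "),
         call. = FALSE)
  }

  # --- fit -----------------------------------------------------------------
  mcfg_base <- cfg$mcmc %||% list()
  fits <- list()
  for (sx in cfg$sexes) {
    for (oc in cfg$outcomes) {
      key <- paste(oc, sx, sep = "_")
      dpath <- file.path(out, paste0("draws_", key, ".csv"))
      paths[[paste0("draws_", key)]] <- dpath
      mcfg <- do.call(mcmc_config, c(mcfg_base,
                                     list(seed = cfg$seed + 100L)))
      fit <- stage(paste0("fit:", key), dpath, function() {
        f <- fit_cascade_model(cells, hierarchy, oc, sx, spec, mcfg)
        write_draws(f, dpath)
        f
      })
      if (is.null(fit))
        fit <- fit_cascade_model(cells, hierarchy, oc, sx, spec, mcfg)
      fits[[key]] <- fit
    }
  }

  # --- post ----------------------------------------------------------------
  paths$summary <- file.path(out, "summary.csv")
  paths$change <- file.path(out, "change.csv")
  paths$stages <- file.path(out, "cascade_stages.csv")
  stage("post", c(paths$summary, paths$change), function() {
    members <- c(hierarchy_members(hierarchy, "region"),
                 hierarchy_members(hierarchy, "super_region"),
                 hierarchy_members(hierarchy, "world"))
    summary_rows <- list()
    change_rows <- list()
    stage_rows <- list()
    for (sx in cfg$sexes) {
      surfs <- lapply(cfg$outcomes, function(oc)
        predict_surface(fits[[paste(oc, sx, sep = "_")]]))
      names(surfs) <- cfg$outcomes
      aggs <- lapply(surfs, aggregate_units, populations = populations,
                     members = members)
      for (oc in cfg$outcomes) {
        for (lvl in c("country", "aggregate")) {
          s <- if (lvl == "country") surfs[[oc]] else aggs[[oc]]
          q <- if (lvl == "country") surfs[["prevalence"]] else aggs[["prevalence"]]
          std_draws <- if (oc == "prevalence")
            age_standardise_prevalence(s, std)
          else age_standardise_cascade(s, q, std)
          summary_rows[[paste(oc, sx, lvl)]] <-
            summarise_surface(std_draws, outcome = oc, sex = sx)
          y1 <- as.character(cfg$change_years[1])
          y2 <- as.character(cfg$change_years[2])
          ch <- do.call(rbind, lapply(dimnames(std_draws)[[1]], function(u)
            cbind(unit = u, sex = sx, outcome = oc,
                  change_stats(std_draws[u, y1, ], std_draws[u, y2, ]))))
          change_rows[[paste(oc, sx, lvl)]] <- ch
        }
      }
      casc <- c("detection", "treatment", "control")
      if (all(casc %in% cfg$outcomes)) {
        asd <- lapply(casc, function(oc) age_standardise_cascade(
          aggs[[oc]], aggs[["prevalence"]], std))
        names(asd) <- casc
        stream <- cascade_stream(asd$detection, asd$treatment, asd$control)
        for (stg in names(stream)) {
          stage_rows[[paste(sx, stg)]] <- cbind(
            summarise_surface(stream[[stg]], outcome = stg, sex = sx))
        }
      }
    }
    write_summary_rows(do.call(rbind, summary_rows), paths$summary)
    write_plain_csv(do.call(rbind, change_rows), paths$change)
    if (length(stage_rows))
      write_summary_rows(do.call(rbind, stage_rows), paths$stages)
  })

  manifest <- list(config_hash = cfg_hash, seed = cfg$seed,
                   package_version = as.character(utils::packageVersion("htncascade")),
                   created = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(paths)
}

config_hash <- function(cfg) {
  cfg$out_dir <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(cfg[order(names(cfg))]), tmp)
  unname(tools::md5sum(tmp))
}
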