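#' Pipeline configuration
#'
#' Assembles the full pipeline configuration: input paths, the simulation
#' block, and the analysis constants (tilt cutoff 0.80, rotation cutoff
#' 15 degrees, annulus 1-3 mm diameters, univariate screen level 0.10,
#' stepwise entry 0.05 / removal 0.10). All constants are overridable.
#'
#' @param paths list with optional `contours`, `maps`, `biometry` input
#'   locations.
#' @param simulation a [simulation_config] (or list of arguments for one).
#' @param analysis list of analysis options; unspecified entries take the
#'   defaults above.
#' @param seed integer seed.
#' @param out output directory.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(paths = list(), simulation = NULL,
                            analysis = list(), seed = 1, out = "out") {
  a <- list(tilt_cutoff = 0.80, rotation_cutoff = 15,
            annulus_inner_mm = 0.5, annulus_outer_mm = 1.5,
            screen_level = 0.10, step_enter = 0.05, step_remove = 0.10,
            threshold = 0.5)
  a[names(analysis)] <- analysis
  stopifnot(a$tilt_cutoff > 0, a$rotation_cutoff > 0,
            a$annulus_inner_mm < a$annulus_outer_mm)
  if (is.null(simulation)) simulation <- simulation_config(seed = seed)
  if (!inherits(simulation, "simulation_config"))
    simulation <- do.call(simulation_config, simulation)
  structure(list(paths = paths, simulation = simulation, analysis = a,
                 seed = as.integer(seed), out = out),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the [pipeline_config()] arguments: `paths`,
#' `simulation` (a list of [simulation_config()] arguments), `analysis`,
#' `seed`, `out`.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  pipeline_config(paths = if (is.null(y$paths)) list() else y$paths,
                  simulation = y$simulation,
                  analysis = if (is.null(y$analysis)) list() else y$analysis,
                  seed = if (is.null(y$seed)) 1L else y$seed,
                  out = if (is.null(y$out)) "out" else y$out)
}

# hash of the scientific configuration (paths and output location excluded,
# so the same analysis in a different directory carries the same hash)
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  cfg <- unclass(config)
  cfg$out <- NULL
  cfg$paths <- NULL
  cfg <- rapply(cfg, unclass, how = "replace")
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

log_stage <- function(stage, ...) {
  message(sprintf("[discmorph] %s: %s", stage, sprintf(...)))
}

#' Run the pipeline
#'
#' Executes one stage or the whole chain. Stages: `simulate` writes a
#' synthetic cohort CSV, per-eye contour JSONs, vessel-map CSV grids and a
#' ground-truth JSON; `morphometry` processes a directory of contour JSONs
#' into a morphometry CSV; `sectors` processes a directory of map grids
#' into a sector-density CSV; `derive` appends derived indices to a cohort
#' CSV; `analyze` runs the association chain and writes the report tables;
#' `all` runs simulate, derive and analyze end-to-end (deterministic under
#' the config seed). Every CSV written carries the configuration hash as a
#' leading `#` comment; a structured log goes to stderr.
#'
#' @param stage one of `"simulate"`, `"morphometry"`, `"sectors"`,
#'   `"derive"`, `"analyze"`, `"all"`.
#' @param config a [pipeline_config].
#' @param geometry passed to [generate_cohort()] for the simulate stage
#'   (`"none"` keeps large runs fast; `"contours"`/`"full"` emit per-eye
#'   geometry files).
#' @return invisibly, a list of artifact paths written.
#' @export
run_pipeline <- function(stage = c("all", "simulate", "morphometry",
                                   "sectors", "derive", "analyze"),
                         config = pipeline_config(),
                         geometry = "none") {
  stage <- match.arg(stage)
  stopifnot(inherits(config, "pipeline_config"))
  hash <- config_hash(config)
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  artifacts <- list()
  a <- config$analysis

  if (stage %in% c("simulate", "all")) {
    sim <- generate_cohort(config$simulation, geometry = geometry)
    cohort_path <- file.path(config$out, "cohort.csv")
    write_csv_hashed(sim$cohort, cohort_path, hash)
    jsonlite::write_json(
      list(seed = sim$truth$seed,
           logistic = sim$truth$logistic, linear = sim$truth$linear,
           tilt_ratio = sim$truth$tilt_ratio,
           rotation_deg = sim$truth$rotation_deg,
           config_hash = hash),
      file.path(config$out, "truth.json"), auto_unbox = TRUE, digits = NA)
    artifacts$cohort <- cohort_path
    artifacts$truth <- file.path(config$out, "truth.json")
    if (!is.null(sim$contours)) {
      cdir <- file.path(config$out, "contours")
      dir.create(cdir, showWarnings = FALSE)
      for (e in sim$contours)
        write_disc_contour(e$contour, e$fovea,
                           file.path(cdir, paste0(e$contour$source_id,
                                                  ".json")))
      artifacts$contours <- cdir
    }
    if (!is.null(sim$maps)) {
      mdir <- file.path(config$out, "maps")
      dir.create(mdir, showWarnings = FALSE)
      for (eye in sim$maps) for (m in eye)
        write_vessel_map(m, file.path(mdir, paste0(m$source_id, ".csv")))
      artifacts$maps <- mdir
    }
    log_stage("simulate", "n=%d eyes, seed=%d, hash=%s",
              config$simulation$n_eyes, config$simulation$seed, hash)
  }

  if (stage == "morphometry") {
    indir <- config$paths$contours
    if (is.null(indir) || !dir.exists(indir))
      stop("morphometry stage needs paths$contours (directory of JSONs)")
    files <- sort(list.files(indir, pattern = "\\.json$", full.names = TRUE))
    res <- lapply(files, function(f) {
      inp <- read_disc_contour(f)
      if (is.null(inp$fovea)) stop("contour file lacks fovea: ", f)
      morphometry(inp$contour, inp$fovea, tilt_cutoff = a$tilt_cutoff,
                  rotation_cutoff = a$rotation_cutoff)
    })
    p <- file.path(config$out, "morphometry.csv")
    write_morphometry_csv(res, p, hash)
    artifacts$morphometry <- p
    log_stage("morphometry", "n=%d contours processed, hash=%s",
              length(files), hash)
  }

  if (stage == "sectors") {
    indir <- config$paths$maps
    if (is.null(indir) || !dir.exists(indir))
      stop("sectors stage needs paths$maps (directory of grids + side-cars)")
    files <- sort(list.files(indir, pattern = "\\.(csv|png)$",
                             full.names = TRUE))
    res <- lapply(files, function(f)
      sector_densities(read_vessel_map(f),
                       inner_mm = a$annulus_inner_mm,
                       outer_mm = a$annulus_outer_mm,
                       threshold = a$threshold))
    p <- file.path(config$out, "sectors.csv")
    write_sector_csv(res, p, hash)
    artifacts$sectors <- p
    log_stage("sectors", "n=%d maps processed, hash=%s", length(files), hash)
  }

  if (stage %in% c("derive", "analyze", "all")) {
    cohort_path <- if (stage == "all") artifacts$cohort else {
      if (is.null(config$paths$biometry))
        stop("stage needs paths$biometry (cohort CSV)")
      config$paths$biometry
    }
    cohort <- read_cohort_csv(cohort_path)
    if (!"RLP" %in% names(cohort)) cohort <- derive_ocular(cohort)
    if (stage == "derive") {
      p <- file.path(config$out, "cohort_derived.csv")
      write_csv_hashed(cohort, p, hash)
      artifacts$derived <- p
      log_stage("derive", "n=%d rows, %d excluded (%s), hash=%s",
                nrow(cohort), sum(!cohort$included),
                paste(unique(cohort$exclusion_reason[
                  cohort$exclusion_reason != ""]), collapse = ","), hash)
    }
    if (stage %in% c("analyze", "all")) {
      kept <- cohort[cohort$included, , drop = FALSE]
      log_stage("analyze", "n=%d analyzed, %d excluded", nrow(kept),
                nrow(cohort) - nrow(kept))
      rep <- build_report(kept, screen_level = a$screen_level)
      for (nm in c("al_summary", "tilt_summary", "rotation_summary")) {
        p <- file.path(config$out, paste0(nm, ".csv"))
        write_csv_hashed(rep[[nm]]$table, p, hash)
        artifacts[[nm]] <- p
      }
      for (nm in c("tilt_model", "rotation_model")) {
        p <- file.path(config$out, paste0(nm, ".csv"))
        write_csv_hashed(rep[[nm]]$terms, p, hash)
        artifacts[[nm]] <- p
      }
      jsonlite::write_json(
        list(config_hash = hash, seed = config$seed,
             n = nrow(kept),
             prevalence = as.list(rep$prevalence),
             tilt_selected = rep$tilt_screen$selected,
             rotation_selected = rep$rotation_model$selected,
             rotation_r2 = rep$rotation_model$r2,
             rotation_adj_r2 = rep$rotation_model$adj_r2),
        file.path(config$out, "analysis.json"), auto_unbox = TRUE,
        digits = NA)
      artifacts$analysis <- file.path(config$out, "analysis.json")
    }
  }
  invisible(artifacts)
}
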