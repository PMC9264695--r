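#' Build a validated run configuration
#'
#' Collects every knob of the end-to-end pipeline: input locations (or a
#' synthetic-panel spec), filtering thresholds, optimization settings, and
#' the simulation/assignment evaluation. Validated up front; the resolved
#' configuration is written back into the output directory for provenance.
#'
#' @param genotypes path to genotype file, or `NULL` when `synthetic` is
#'   given.
#' @param format genotype file format, `"dosage-tsv"` or `"vcf"`.
#' @param maternal_id maternal sample id (ignored for synthetic runs).
#' @param map_path,lengths_path marker map / chromosome length TSVs.
#' @param synthetic a [synthetic_panel_spec] to generate inputs instead of
#'   reading files.
#' @param maf_min,window,r2_max,min_bp dataset-construction filters (see
#'   [filter_maf()], [prune_spacing_ld()]).
#' @param h heterozygosity weight.
#' @param method optimizer, as in [optimize_markers()].
#' @param v flip fraction for the neighborhood search.
#' @param time_limit exact-solver time limit (seconds).
#' @param evaluate simulate offspring and score exclusion assignment.
#' @param n_offspring offspring per candidate father in the evaluation.
#' @param mask_rate genotype masking rate in the evaluation.
#' @param max_mismatch assignment mismatch tolerance; `NULL` picks 0 for
#'   clean data and `ceiling(mask_rate * f)` otherwise.
#' @param seed integer seed driving all pipeline randomness.
#' @param out_dir artifact directory.
#' @return object of class `run_config`.
#' @export
run_config <- function(genotypes = NULL, format = "dosage-tsv",
                       maternal_id = NULL, map_path = NULL,
                       lengths_path = NULL, synthetic = NULL,
                       maf_min = 0.05, window = 50L, r2_max = 0.5,
                       min_bp = 10000, h = 8, method = "greedy+ns",
                       v = 0.2, time_limit = 3600, evaluate = TRUE,
                       n_offspring = 5L, mask_rate = 0,
                       max_mismatch = NULL, seed = 1L, out_dir = tempfile()) {
  if (is.null(synthetic)) {
    if (is.null(genotypes) || !file.exists(genotypes))
      stop("genotype file not found: ", genotypes)
    if (is.null(maternal_id)) stop("maternal_id is required")
    if (method != "ilp-count" &&
        (is.null(map_path) || is.null(lengths_path) ||
         !file.exists(map_path) || !file.exists(lengths_path)))
      stop("marker map and chromosome lengths are required for method '",
           method, "'")
  } else {
    stopifnot(inherits(synthetic, "synthetic_panel_spec"))
  }
  stopifnot(h > 0, v >= 0, v <= 1, mask_rate >= 0, mask_rate <= 1,
            n_offspring >= 1L)
  structure(as.list(environment()), class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Top-level keys mirror the [run_config()] arguments; a `synthetic` block
#' is forwarded to [synthetic_panel_spec()].
#'
#' @param path YAML file.
#' @param ... overrides applied on top of the file's values.
#' @return a `run_config`.
#' @export
read_run_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$synthetic)) {
    fb <- lapply(y$synthetic$family_blocks, function(b)
      list(type = b$type, size = as.integer(b$size)))
    y$synthetic$family_blocks <- fb
    y$synthetic <- do.call(synthetic_panel_spec, y$synthetic)
  }
  over <- list(...)
  y[names(over)] <- over
  do.call(run_config, y)
}

#' Run the full marker-selection pipeline
#'
#' Stages: load (or generate) the panel -> dataset-construction filters ->
#' optimize the marker set -> optionally simulate offspring, mask, assign,
#' and score. Every artifact (filtered panel, solution TSV + metrics,
#' assignments, run manifest with seeds and timings) is written under the
#' configured output directory; a failing stage leaves a `FAILED` marker
#' file naming the stage.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with the `panel`, `map`, `optimize_result`,
#'   `assignment` (or `NULL`), `summary`, and `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "setup"
  manifest <- list(package_version = as.character(utils::packageVersion("snppick")),
                   seed = config$seed, timings = list())
  t_stage <- function(expr, name) {
    stage <<- name
    t0 <- proc.time()[["elapsed"]]
    out <- expr
    manifest$timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    out
  }
  on_fail <- function(e) {
    writeLines(paste0("stage: ", stage, "\n", conditionMessage(e)),
               file.path(config$out_dir, "FAILED"))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  }
  tryCatch({
    inputs <- t_stage({
      if (!is.null(config$synthetic)) {
        generate_panel(config$synthetic)
      } else {
        list(panel = load_panel(config$genotypes, config$format,
                                config$maternal_id),
             map = if (!is.null(config$map_path))
               read_marker_map(config$map_path, config$lengths_path))
      }
    }, "load")
    panel <- inputs$panel
    map <- inputs$map

    panel <- t_stage({
      p <- filter_maf(panel, config$maf_min)
      if (!is.null(map))
        p <- prune_spacing_ld(p, map, config$window, config$r2_max,
                              config$min_bp)
      p
    }, "filter")
    write_dosage_tsv(panel, file.path(config$out_dir, "panel_filtered.tsv"))

    opt <- t_stage(
      optimize_markers(panel, map, h = config$h, method = config$method,
                       v = config$v, time_limit = config$time_limit),
      "optimize")
    write_solution(opt, map, config$out_dir)

    assignment <- NULL
    summary <- NULL
    if (config$evaluate) {
      assignment <- t_stage({
        off <- simulate_offspring(panel, config$n_offspring,
                                  seed = config$seed + 1L)
        if (config$mask_rate > 0)
          off <- mask_genotypes(off, config$mask_rate,
                                seed = config$seed + 2L)
        mm <- config$max_mismatch
        if (is.null(mm))
          mm <- if (config$mask_rate > 0)
            as.integer(ceiling(config$mask_rate * opt$solution$f)) else 0L
        write_offspring(off, config$out_dir)
        assign_paternity(off, panel, opt$solution, max_mismatch = mm)
      }, "assign")
      write_assignments(assignment, config$out_dir)
      summary <- score_assignments(assignment)
    }

    cfg <- config
    cfg$synthetic <- if (!is.null(cfg$synthetic)) unclass(cfg$synthetic)
    manifest$config <- unclass(cfg)
    manifest$solution <- list(f = opt$solution$f, g = opt$solution$g,
                              depth = opt$solution$depth,
                              feasible = opt$solution$feasible,
                              dropped_pairs = nrow(opt$dropped_pairs))
    manifest$assignment <- summary
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         na = "null", force = TRUE)
    invisible(list(panel = panel, map = map, optimize_result = opt,
                   assignment = assignment, summary = summary,
                   out_dir = config$out_dir))
  }, error = on_fail)
}
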