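#' Load a pipeline configuration
#'
#' The pipeline is driven by one declarative YAML (or JSON) document
#' instead of an edited parameter script. Top-level blocks: `seed`,
#' `output_dir`, `input` (`mode: detect` with `stack` + `stack_spacing`, or
#' `mode: import` with `cells_csv` [+ `cells_scale`]), `atlas`
#' (`annotation`, `ontology`), `landmarks` (`path`, optional `swap`),
#' `detection` (any [detection_params()] field), `registration` (`mode`,
#' `lambda`), `mapping` (`exclude_regions`), `heatmap` (`sigma_um`),
#' `flatmap` (optional: `masks` with `cortex`/`pia`/`wm` NRRD paths or
#' `"toy_shell"`, `parameterization`, `center`, `depth_bin_um`).
#'
#' @param path YAML or JSON file.
#' @return The configuration list (class `pipeline_config`).
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (tolower(tools::file_ext(path)) == "json") jsonlite::fromJSON(path)
         else yaml::read_yaml(path)
  cfg$.config_path <- normalizePath(path)
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Validate a pipeline configuration
#'
#' Checks every stage's preconditions before any computation starts and
#' returns all violations at once (stage, field, message). An empty report
#' means the config is runnable.
#'
#' @param config a `pipeline_config` (or plain list / path).
#' @return data.frame with columns `stage`, `field`, `message`;
#'   zero rows when valid.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  v <- list()
  flag <- function(stage, field, message)
    v[[length(v) + 1L]] <<- data.frame(stage = stage, field = field,
                                       message = message, stringsAsFactors = FALSE)
  inp <- config$input
  if (is.null(inp$mode) || !inp$mode %in% c("detect", "import"))
    flag("input", "mode", "mode must be 'detect' or 'import'")
  else if (inp$mode == "detect") {
    if (is.null(inp$stack)) flag("input", "stack", "detect mode needs a stack path")
    else if (!file.exists(inp$stack) && !dir.exists(inp$stack))
      flag("input", "stack", paste0("stack not found: ", inp$stack))
    is_tiff <- !is.null(inp$stack) &&
      (dir.exists(inp$stack) || tolower(tools::file_ext(inp$stack)) %in% c("tif", "tiff"))
    has_sidecar <- !is.null(inp$stack) &&
      (file.exists(file.path(inp$stack, "volume_meta.json")) ||
         file.exists(paste0(inp$stack, ".json")))
    if (is_tiff && is.null(inp$stack_spacing) && !has_sidecar)
      flag("input", "stack_spacing",
           "TIFF stacks carry no trusted spacing; stack_spacing (µm x/y/z) is required")
    if (!is.null(inp$stack_spacing) &&
        (length(inp$stack_spacing) != 3 || any(inp$stack_spacing <= 0)))
      flag("input", "stack_spacing", "stack_spacing must be 3 positive numbers")
  } else {
    if (is.null(inp$cells_csv)) flag("input", "cells_csv", "import mode needs cells_csv")
    else if (!file.exists(inp$cells_csv))
      flag("input", "cells_csv", paste0("file not found: ", inp$cells_csv))
  }
  if (is.null(config$atlas$annotation))
    flag("atlas", "annotation", "annotation volume path required")
  else if (!file.exists(config$atlas$annotation) && !dir.exists(config$atlas$annotation))
    flag("atlas", "annotation", paste0("not found: ", config$atlas$annotation))
  if (is.null(config$atlas$ontology))
    flag("atlas", "ontology", "ontology JSON path required")
  else if (!file.exists(config$atlas$ontology))
    flag("atlas", "ontology", paste0("not found: ", config$atlas$ontology))
  if (is.null(config$landmarks$path))
    flag("landmarks", "path", "landmark CSV path required")
  else if (!file.exists(config$landmarks$path))
    flag("landmarks", "path", paste0("not found: ", config$landmarks$path))
  det <- config$detection
  if (!is.null(det)) {
    dp <- utils::modifyList(as.list(detection_params()), det)
    ok <- tryCatch({ validate_detection_params(dp); TRUE },
                   error = function(e) { flag("detection", "params", conditionMessage(e)); FALSE })
  }
  reg <- config$registration
  if (!is.null(reg$mode) && !reg$mode %in% c("affine", "tps", "affine+tps"))
    flag("registration", "mode", "mode must be affine, tps, or affine+tps")
  if (!is.null(reg$lambda) && reg$lambda < 0)
    flag("registration", "lambda", "lambda must be >= 0")
  if (!is.null(config$heatmap$sigma_um) && config$heatmap$sigma_um < 0)
    flag("heatmap", "sigma_um", "sigma_um must be >= 0")
  if (length(v) == 0L)
    return(data.frame(stage = character(0), field = character(0),
                      message = character(0), stringsAsFactors = FALSE))
  do.call(rbind, v)
}

#' Run the full mapping pipeline
#'
#' Detect (or import) cells, fit the landmark transform, map cells to atlas
#' space, assign and aggregate regions, build the density heatmap, and
#' (optionally) project the cortical flatmap — writing every intermediate
#' artifact plus a run manifest (config hash, package version, seed, and
#' cell counts at every stage) into `output_dir`. Reruns with the same
#' config and seed are bit-identical.
#'
#' @param config path to a config file, or a `pipeline_config` list.
#' @param quiet suppress progress messages.
#' @return The output directory, invisibly; the manifest is
#'   `manifest.json` inside it.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  report <- validate_config(config)
  if (nrow(report) > 0)
    stop("invalid configuration:\n",
         paste(sprintf("  [%s] %s: %s", report$stage, report$field, report$message),
               collapse = "\n"))
  say <- function(...) if (!quiet) message(sprintf("[%s] %s",
                                                   format(Sys.time(), "%H:%M:%S"),
                                                   sprintf(...)))
  out_dir <- config$output_dir %||% "brainmapr_out"
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- config$seed %||% 1L
  manifest <- list(package_version = as.character(utils::packageVersion("brainmapr")),
                   seed = seed, counts = list())
  if (!is.null(config$.config_path))
    manifest$config_md5 <- unname(tools::md5sum(config$.config_path))

  stage <- "atlas"
  res <- tryCatch({
    annotation <- read_volume(config$atlas$annotation,
                              spacing = config$atlas$annotation_spacing)
    ontology <- read_ontology(config$atlas$ontology)
    validate_annotation(annotation, ontology)

    stage <- "cells"
    if (config$input$mode == "detect") {
      say("reading stack %s", config$input$stack)
      stack <- read_volume(config$input$stack, spacing = config$input$stack_spacing)
      params <- do.call(detection_params,
                        utils::modifyList(list(), config$detection %||% list()))
      say("detecting cells")
      cells_stack <- detect_cells(stack, params)
    } else {
      say("importing cells from %s", config$input$cells_csv)
      cells_stack <- read_cell_csv(config$input$cells_csv,
                                   column_map = config$input$column_map,
                                   scale_um_per_unit = config$input$cells_scale %||% c(1, 1, 1))
    }
    manifest$counts$cells_in <- nrow(cells_stack)
    write_cell_csv(cells_stack, file.path(out_dir, "cells_stack.csv"))

    stage <- "registration"
    landmarks <- suppressMessages(
      read_bigwarp_landmarks(config$landmarks$path,
                             swap = isTRUE(config$landmarks$swap)))
    mode <- config$registration$mode %||% "affine+tps"
    transform <- fit_landmark_transform(landmarks, mode = mode,
                                        lambda = config$registration$lambda)
    write_transform(transform, file.path(out_dir, "transform.json"))
    qc <- registration_report(transform, landmarks)
    utils::write.csv(qc$per_landmark, file.path(out_dir, "qc_landmarks.csv"),
                     row.names = FALSE)
    say("registration RMS %.2f um over %d landmarks", qc$rms_um, qc$n_active)

    stage <- "mapping"
    cells_atlas <- apply_transform(transform, cells_stack)
    cells_atlas <- assign_regions(cells_atlas, annotation,
                                  exclude_regions = config$mapping$exclude_regions,
                                  ontology = ontology)
    manifest$counts$assigned <- sum(cells_atlas$region_id != 0L)
    manifest$counts$unassigned <- sum(cells_atlas$region_id == 0L)
    write_cell_csv(cells_atlas, file.path(out_dir, "cells_atlas.csv"))
    region_table <- aggregate_counts(cells_atlas, ontology, annotation)
    write_region_table(region_table, file.path(out_dir, "region_table.csv"))

    stage <- "heatmap"
    dv <- voxelize(cells_atlas, annotation)
    manifest$counts$heatmap_in <- dv$n_cells_in
    manifest$counts$heatmap_out_of_bounds <- dv$n_out_of_bounds
    sm <- smooth_density(dv, config$heatmap$sigma_um %||% (3 * max(annotation$spacing)))
    write_volume(sm$grid, file.path(out_dir, "heatmap.nrrd"))

    stage <- "flatmap"
    if (!is.null(config$flatmap)) {
      fmcfg <- config$flatmap
      masks <- lapply(fmcfg$masks, function(p) read_volume(p)$values > 0)
      field <- solve_depth_field(masks$cortex, masks$pia, masks$wm,
                                 annotation,
                                 tol = fmcfg$tol %||% 1e-6)
      par <- if (identical(fmcfg$parameterization, "slab")) slab_parameterization()
             else shell_parameterization(fmcfg$center)
      flat <- project_cells(cells_atlas, field, par)
      manifest$counts$cortical_projected <- nrow(flat)
      manifest$counts$cortical_excluded <- attr(flat, "n_outside_cortex")
      manifest$counts$cortical_flagged <- attr(flat, "n_flagged")
      write_cell_csv(flat, file.path(out_dir, "flat_cells.csv"))
      prof <- depth_profile(flat, bin_width_um = fmcfg$depth_bin_um %||% 25)
      utils::write.csv(data.frame(depth_lo_um = prof$breaks[-length(prof$breaks)],
                                  depth_hi_um = prof$breaks[-1],
                                  density_per_um = prof$mean_density),
                       file.path(out_dir, "depth_profile.csv"), row.names = FALSE)
    }
    TRUE
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s (partial outputs kept in %s)",
                 stage, conditionMessage(e), out_dir))
  })
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("done: %s", out_dir)
  invisible(out_dir)
}
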