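# End-to-end orchestration: generate cohort scenes, segment (oracle or
# trained), detect and classify cells, quantify densities, and run the
# statistics layer, with a JSON manifest recording the seed, configuration
# hash and per-stage output checksums.
#
# Blinding contract: the detection stage sees only images and masks, never
# donor metadata; permuting donor ages changes statistics outputs but leaves
# detection and quantification outputs byte-identical.

#' Pipeline run configuration
#'
#' @param seed master seed for the run.
#' @param n_donors cohort size for the run (desk-scale default 5).
#' @param panel staining panel.
#' @param segmentation `"oracle"` (ground-truth masks) or `"trained"`
#'   (train stage-A/B models on the first scenes and segment with them).
#' @param image_size_px per-donor scene size.
#' @param eer_fraction scene EER fraction.
#' @param detection a [detection_params()].
#' @param analyses character subset of
#'   `c("age_regression", "paired", "unpaired_risk")`.
#' @param out_dir optional directory for CSV/JSON outputs (NULL = in-memory
#'   only).
#' @return object of class `run_config`.
#' @export
run_config <- function(seed = 1L, n_donors = 5L,
                       panel = c("triple", "double"),
                       segmentation = c("oracle", "trained"),
                       image_size_px = c(384, 384), eer_fraction = 0.75,
                       detection = detection_params(),
                       analyses = c("age_regression", "paired"),
                       out_dir = NULL) {
  panel <- match.arg(panel)
  segmentation <- match.arg(segmentation)
  n_ar <- ceiling(n_donors * 2 / 3)
  structure(list(seed = as.integer(seed), n_donors = as.integer(n_donors),
                 n_ar = n_ar, n_hr = as.integer(n_donors) - n_ar,
                 panel = panel, segmentation = segmentation,
                 image_size_px = image_size_px, eer_fraction = eer_fraction,
                 detection = detection, analyses = analyses,
                 out_dir = out_dir),
            class = "run_config")
}

#' Run the full pipeline
#'
#' Stages run strictly in order: cohort generation, scene rendering,
#' segmentation, detection (blind to donor metadata), density
#' quantification, statistics. Any stage error aborts with the stage name.
#'
#' @param config a [run_config()].
#' @param cohort optionally, a pre-built `cohort` (its donors' ages may have
#'   been permuted to exercise the blinding contract).
#' @return list of class `pipeline_run`: `cohort`, `densities` (per donor x
#'   class x compartment), `stats`, `manifest`.
#' @export
run_pipeline <- function(config, cohort = NULL) {
  stopifnot(inherits(config, "run_config"))
  stage <- "cohort"
  result <- tryCatch({
    if (is.null(cohort)) {
      classes <- if (config$panel == "triple") c("T", "B", "Mac") else c("M1", "M2")
      cs <- cohort_spec(n_donors = config$n_donors, n_ar = config$n_ar,
                        n_hr = config$n_hr, seed = config$seed)
      cohort <- generate_cohort(cs)
    }
    classes <- if (config$panel == "triple") c("T", "B", "Mac") else c("M1", "M2")

    stage <- "scenes"
    specs <- cohort_scene_specs(cohort, classes = classes,
                                image_size_px = config$image_size_px,
                                eer_fraction = config$eer_fraction,
                                panel = config$panel)
    scenes <- lapply(specs, generate_scene)

    stage <- "segmentation"
    masks <- if (config$segmentation == "oracle") {
      lapply(scenes, oracle_segmenter)
    } else {
      sp <- segmenter_params(epochs = 40L)
      tdA <- segmentation_tiles(scenes, "A", sp$tile_px, max_tiles = 48L)
      tdB <- segmentation_tiles(scenes, "B", sp$tile_px, max_tiles = 48L)
      mA <- train_segmenter(tdA$tiles, tdA$labels, "A", sp,
                            seed = child_seed(config$seed, 101))
      mB <- train_segmenter(tdB$tiles, tdB$labels, "B", sp,
                            seed = child_seed(config$seed, 102))
      lapply(scenes, function(sc) {
        eer <- segment_eer(sc$image, mA)
        segment_pe_ils(sc$image, eer, mB,
                       pixel_size_um = sc$spec$pixel_size_um)
      })
    }

    stage <- "detection"
    # the detection closure receives only image + mask: donor metadata is
    # out of scope by construction (blinding)
    density_records <- list()
    for (id in names(scenes)) {
      cells <- detect_cells(scenes[[id]]$image, config$panel,
                            config$detection,
                            pixel_size_um = scenes[[id]]$spec$pixel_size_um)
      cells <- assign_compartment(cells, masks[[id]])
      stage <- "quantification"
      density_records[[id]] <- compute_density(cells, masks[[id]],
                                               donor_id = id,
                                               classes = classes)
      stage <- "detection"
    }
    densities <- do.call(rbind, density_records)
    rownames(densities) <- NULL

    stage <- "statistics"
    measured <- list(donors = cohort$donors,
                     densities = stats::setNames(
                       densities[, c("donor_id", "cell_class", "compartment",
                                     "density")],
                       c("donor_id", "cell_class", "compartment", "density")))
    stats_out <- list()
    if ("age_regression" %in% config$analyses)
      stats_out$age_regression <- lapply(stats::setNames(classes, classes),
        function(cl) tryCatch(age_regression(measured, cl, "EER_total"),
                              error = function(e) e$message))
    if ("paired" %in% config$analyses)
      stats_out$paired <- lapply(stats::setNames(classes, classes),
        function(cl) tryCatch(paired_compare(measured, cl),
                              error = function(e) e$message))
    if ("unpaired_risk" %in% config$analyses)
      stats_out$unpaired_risk <- lapply(stats::setNames(classes, classes),
        function(cl) tryCatch(unpaired_compare(measured, "risk", cl),
                              error = function(e) e$message))

    stage <- "manifest"
    cfg_for_hash <- config; cfg_for_hash$out_dir <- NULL
    manifest <- list(
      package_version = as.character(utils::packageVersion("mammilieu")),
      seed = config$seed,
      config_checksum = object_checksum(cfg_for_hash),
      stage_checksums = list(
        cohort = object_checksum(cohort$densities),
        detection = object_checksum(densities),
        statistics = object_checksum(stats_out)))

    if (!is.null(config$out_dir)) {
      dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
      utils::write.csv(densities,
                       file.path(config$out_dir, "densities.csv"),
                       row.names = FALSE)
      utils::write.csv(cohort$donors,
                       file.path(config$out_dir, "donors.csv"),
                       row.names = FALSE)
      jsonlite::write_json(manifest,
                           file.path(config$out_dir, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE)
    }
    structure(list(cohort = cohort, densities = densities,
                   stats = stats_out, manifest = manifest),
              class = "pipeline_run")
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  result
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("pipeline_run: %d donors, %d density records (seed %d)\n",
              nrow(x$cohort$donors), nrow(x$densities), x$manifest$seed))
  invisible(x)
}
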