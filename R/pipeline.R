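#' Pipeline configuration and file plumbing
#'
#' The pipeline stages - simulate, segment/measure, evaluate - read and
#' write plain formats: images as 8-bit RGB PNG, masks and label maps as
#' single-channel PNG, tables as CSV with a provenance comment header
#' (tool version, configuration hash, seed), and configurations as YAML.
#'
#' @name pipeline
NULL

#' Pipeline configuration
#'
#' @param pixel_pitch_um Pixel pitch, micrometres per pixel (default
#'   0.34).
#' @param segmentation A [segmentation_config()].
#' @param scale A [scale_config()].
#' @param seed Integer seed recorded in every output's provenance header.
#' @param verbose Emit progress messages to stderr.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(pixel_pitch_um = 0.34,
                            segmentation = segmentation_config(),
                            scale = scale_config(), seed = 1L,
                            verbose = TRUE) {
  stopifnot(pixel_pitch_um > 0)
  structure(list(pixel_pitch_um = pixel_pitch_um, segmentation = segmentation,
                 scale = scale, seed = as.integer(seed), verbose = verbose),
            class = "pipeline_config")
}

config_hash <- function(config) {
  s <- paste(utils::capture.output(utils::str(config)), collapse = "\n")
  # small polynomial rolling hash over the printed config; stable across
  # sessions and platforms
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

provenance_header <- function(config, seed) {
  c(sprintf("# vesselmorph %s",
            as.character(utils::packageVersion("vesselmorph"))),
    sprintf("# config_hash=%s seed=%d", config_hash(config), seed))
}

write_table_with_provenance <- function(df, path, config, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(config, seed), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline CSV (skipping provenance comments)
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_pipeline_csv <- function(path) {
  utils::read.csv(path, comment.char = "#")
}

#' Write an image field as PNG
#'
#' @param image An [image_field()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_field_png <- function(image, path) {
  stopifnot(inherits(image, "image_field"))
  png::writePNG(image$rgb, path)
  invisible(path)
}

#' Read a PNG or render nothing
#'
#' @param path PNG file path.
#' @param pixel_pitch_um Pixel pitch to calibrate the image with.
#' @param field_id Field identifier (defaults to the file name).
#' @return An [image_field()].
#' @export
read_field_png <- function(path, pixel_pitch_um,
                           field_id = sub("\\.png$", "", basename(path))) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2) a <- array(rep(a, 3), c(dim(a), 3))
  if (dim(a)[3] > 3) a <- a[, , 1:3, drop = FALSE]
  image_field(a, pixel_pitch_um, field_id)
}

#' Write a label map as 16-bit single-channel PNG
#'
#' Pixels carry the vessel index (0 = background).
#'
#' @param profiles Profiles from [segment_field()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_label_png <- function(profiles, path) {
  dims <- attr(profiles, "dims")
  lab <- matrix(0L, dims[1], dims[2])
  for (p in profiles) {
    idx <- which(p$filled, arr.ind = TRUE)
    lab[cbind(idx[, 1] + p$offset[1], idx[, 2] + p$offset[2])] <- p$vessel_id
  }
  png::writePNG(lab / 65535, path, dpi = NULL)
  invisible(path)
}

#' Simulate a field and write its artefacts
#'
#' Writes the rendered image (`<stem>.png`), the ground-truth stain mask
#' (`<stem>_stain_mask.png`), the per-vessel truth table
#' (`<stem>_truth.csv`) and the field spec (`<stem>_spec.yaml`).
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if missing).
#' @param params Generator parameter overrides for [sample_field_spec()].
#' @param stem Output file stem.
#' @return Named list of written paths, invisibly.
#' @export
run_simulate_field <- function(config = pipeline_config(), out_dir,
                               params = list(), stem = "field") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  params$pixel_pitch_um <- config$pixel_pitch_um
  spec <- sample_field_spec(params, seed = config$seed)
  rf <- render_field(spec)
  paths <- list(
    image = file.path(out_dir, paste0(stem, ".png")),
    stain_mask = file.path(out_dir, paste0(stem, "_stain_mask.png")),
    truth = file.path(out_dir, paste0(stem, "_truth.csv")),
    spec = file.path(out_dir, paste0(stem, "_spec.yaml")))
  write_field_png(rf$image, paths$image)
  png::writePNG(matrix(as.numeric(rf$gt$stain_mask),
                       nrow(rf$gt$stain_mask)), paths$stain_mask)
  write_table_with_provenance(rf$gt$truth, paths$truth, config, config$seed)
  yaml::write_yaml(field_spec_to_list(spec), paths$spec)
  if (config$verbose)
    message(sprintf("simulated field '%s': %d vessels", stem,
                    rf$gt$n_vessels))
  invisible(paths)
}

field_spec_to_list <- function(spec) {
  out <- unclass(spec)
  out$vessels <- lapply(out$vessels, function(v) {
    v <- unclass(v)
    v[!vapply(v, is.null, logical(1))]
  })
  out
}

#' Measure one or more field images
#'
#' Segments each image and writes the per-vessel feature table and the
#' per-field marker table. Unreadable images are skipped with a warning;
#' if all fail, an error is raised.
#'
#' @param image_paths Character vector of PNG paths.
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @return List with `vessel_table` and `marker_table` data frames (also
#'   written to `vessels.csv` / `markers.csv`).
#' @export
run_measure <- function(image_paths, config = pipeline_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  vt <- list(); mt <- list(); failed <- 0L
  for (pth in image_paths) {
    img <- tryCatch(read_field_png(pth, config$pixel_pitch_um),
                    error = function(e) NULL)
    if (is.null(img)) {
      warning(sprintf("skipping unreadable image '%s'", pth))
      failed <- failed + 1L
      next
    }
    profiles <- segment_field(img, config$segmentation)
    if (config$verbose)
      message(sprintf("field '%s': %d vessels (%d objects discarded)",
                      img$field_id, length(profiles),
                      attr(profiles, "n_discarded")))
    vt[[length(vt) + 1]] <- vessel_table(profiles, img$field_id)
    mt[[length(mt) + 1]] <- compute_field_markers(profiles, cfg = config$scale)
  }
  if (length(image_paths) && failed == length(image_paths))
    stop("all images failed to load")
  vt <- do.call(rbind, vt); mt <- do.call(rbind, mt)
  write_table_with_provenance(vt, file.path(out_dir, "vessels.csv"),
                              config, config$seed)
  write_table_with_provenance(mt, file.path(out_dir, "markers.csv"),
                              config, config$seed)
  list(vessel_table = vt, marker_table = mt)
}

cohort_required_cols <- function(markers) {
  c("patient_id", markers, "ddfs_months", "ddfs_event", "bcss_months",
    "bcss_event")
}

#' Evaluate a cohort CSV against the marker panel protocol
#'
#' Validates the schema, runs the standardized continuous Cox panel with
#' the Bonferroni dual-endpoint gate, and for each prognostic marker the
#' median-dichotomized Kaplan-Meier/log-rank analysis plus, when the
#' columns are present, DTC/VI subgroup analyses.
#'
#' @param cohort_csv Path to a cohort CSV (schema: `patient_id`, marker
#'   columns, `ddfs_months`, `ddfs_event`, `bcss_months`, `bcss_event`,
#'   optional covariates), or a data frame.
#' @param markers Character vector of marker column names.
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory for `panel.csv`.
#' @param alpha Family-wise level.
#' @return List with `panel` (a `panel_result`), `dichotomized` (per
#'   prognostic marker x endpoint: HR, CI, log-rank p) and `subgroups`.
#' @export
run_evaluate <- function(cohort_csv, markers, config = pipeline_config(),
                         out_dir = NULL, alpha = 0.05) {
  cohort <- if (is.data.frame(cohort_csv)) cohort_csv else
    read_pipeline_csv(cohort_csv)
  missing_cols <- setdiff(cohort_required_cols(markers), names(cohort))
  if (length(missing_cols))
    stop("cohort is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  panel <- evaluate_marker_panel(cohort, markers, alpha = alpha)
  dich <- list(); subgroups <- list()
  for (mk in panel$marker[panel$prognostic]) {
    grp <- dichotomize_median(cohort[[mk]])
    for (ep in c("ddfs", "bcss")) {
      r <- km_logrank(cohort, grp, ep)
      dich[[length(dich) + 1]] <- data.frame(
        marker = mk, endpoint = ep, hr = r$hr, hr_lo = r$hr_ci[1],
        hr_hi = r$hr_ci[2], logrank_p = r$logrank_p, n = r$n,
        n_events = r$n_events)
      for (fac in intersect(c("dtc", "vi"), names(cohort))) {
        sg <- subgroup_survival(cohort, grp, fac, ep)
        sg$marker <- mk; sg$endpoint <- ep; sg$factor <- fac
        subgroups[[length(subgroups) + 1]] <- sg
      }
    }
  }
  out <- list(panel = panel,
              dichotomized = if (length(dich)) do.call(rbind, dich) else NULL,
              subgroups = if (length(subgroups)) do.call(rbind, subgroups)
              else NULL)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_table_with_provenance(panel, file.path(out_dir, "panel.csv"),
                                config, config$seed)
  }
  out
}

#' Simulate a cohort and write it as CSV
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @param spec A [cohort_spec()]; its seed is overridden by the pipeline
#'   seed.
#' @param stem Output file stem.
#' @return The written path, invisibly.
#' @export
run_simulate_cohort <- function(config = pipeline_config(), out_dir,
                                spec = cohort_spec(), stem = "cohort") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  spec$seed <- config$seed
  cohort <- generate_cohort(spec)
  path <- file.path(out_dir, paste0(stem, ".csv"))
  write_table_with_provenance(cohort, path, config, config$seed)
  invisible(path)
}
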