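#' Write a 16-bit grayscale TIFF
#'
#' @param img Integer-valued matrix in `[0, 65535]`.
#' @param path Output path.
#' @export
write_channel_tiff <- function(img, path) {
  tiff::writeTIFF(img / 65535, path, bits.per.sample = 16,
                  compression = "none")
  invisible(path)
}

#' Read a 16-bit grayscale TIFF written by [write_channel_tiff()]
#'
#' @param path TIFF path.
#' @return Integer-valued matrix in `[0, 65535]`.
#' @export
read_channel_tiff <- function(path) {
  if (!file.exists(path)) stop("missing image file: ", path, call. = FALSE)
  x <- tiff::readTIFF(path)
  matrix(as.integer(round(x * 65535)), nrow(x), ncol(x))
}

well_image_path <- function(dir, plate, well, field, channel)
  file.path(dir, sprintf("%s_%s_f%d_%s.tif", plate, well, field, channel))

#' Simulate a plate to disk (TIFFs + tables)
#'
#' Runs the synthetic generator for every non-empty well of `layout` and
#' writes one TIFF per well/field/channel
#' (`<plate>_<well>_f<field>_<channel>.tif`), the plate layout
#' (`layout.csv`), and the per-cell ground truth (`ground_truth_cells.csv`,
#' 0-based pixel coordinates, row/col order, origin top-left).
#'
#' @inheritParams simulate_well
#' @param layout Plate layout data.frame.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the output directory.
#' @export
write_simulated_plate <- function(layout, out_dir,
                                  populations = default_populations(),
                                  drug_models = default_drug_library(),
                                  seed = 1L, optics = default_optics(),
                                  design = default_assay_design(),
                                  channels = c("hoechst", "chalv1",
                                               "afp")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  truth_all <- NULL
  counts_all <- NULL
  for (i in seq_len(nrow(layout))) {
    entry <- layout[i, ]
    if (entry$role == "empty") next
    sim <- simulate_well(entry, populations, drug_models, seed, optics,
                         design, channels)
    for (f in seq_along(sim$fields))
      for (ch in names(sim$fields[[f]]))
        write_channel_tiff(sim$fields[[f]][[ch]],
                           well_image_path(out_dir, entry$plate,
                                           entry$well, f, ch))
    if (!is.null(sim$truth$cells)) {
      tc <- sim$truth$cells
      tc$row <- tc$row - 1   # 0-based coordinates in the CSV contract
      tc$col <- tc$col - 1
      truth_all <- rbind(truth_all, tc)
    }
    cw <- sim$truth$counts
    cw$plate <- entry$plate; cw$well <- entry$well
    counts_all <- rbind(counts_all, cw)
  }
  write.csv(layout, file.path(out_dir, "layout.csv"), row.names = FALSE)
  write.csv(truth_all, file.path(out_dir, "ground_truth_cells.csv"),
            row.names = FALSE)
  write.csv(counts_all, file.path(out_dir, "ground_truth_counts.csv"),
            row.names = FALSE)
  invisible(out_dir)
}

#' Image provider reading TIFFs from a directory
#'
#' Counterpart of [simulated_image_provider()] for plates on disk, following
#' the `<plate>_<well>_f<field>_<channel>.tif` naming contract.
#'
#' @param dir Directory holding the TIFFs.
#' @param n_fields Fields per well.
#' @param channels Channel names to read.
#' @return Function mapping one layout row to `list(fields = ...)`.
#' @export
tiff_image_provider <- function(dir, n_fields = 4,
                                channels = c("hoechst", "chalv1", "afp")) {
  force(dir); force(n_fields); force(channels)
  function(entry) {
    fields <- lapply(seq_len(n_fields), function(f) {
      chans <- lapply(channels, function(ch)
        read_channel_tiff(well_image_path(dir, entry$plate, entry$well,
                                          f, ch)))
      names(chans) <- channels
      chans
    })
    list(fields = fields)
  }
}

#' Write screen outputs (per-well, per-compound tables and plate report)
#'
#' @param res A `screen_result` from [run_pilot_screen()].
#' @param out_dir Output directory.
#' @export
write_screen_result <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(res$wells, file.path(out_dir, "screen_wells.csv"),
            row.names = FALSE)
  if (!is.null(res$compounds))
    write.csv(res$compounds, file.path(out_dir, "screen_compounds.csv"),
              row.names = FALSE)
  writeLines(res$report, file.path(out_dir, "plate_report.txt"))
  invisible(out_dir)
}

#' Convert dose-response fits to a CSV-ready table
#'
#' @param fits Named list of `dose_response_fit` objects.
#' @return Data.frame with parameters, standard errors and flags.
#' @export
fits_table <- function(fits) {
  do.call(rbind, lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    data.frame(fit_id = nm, top = f$top, bottom = f$bottom,
               ic50_M = f$ic50, hill = f$hill,
               se_top = f$se[["top"]], se_bottom = f$se[["bottom"]],
               se_log10_ic50 = f$se[["log10_ic50"]],
               se_hill = f$se[["hill"]], rss = f$rss,
               converged = f$converged, extrapolated = f$extrapolated,
               n_points = f$n_points, stringsAsFactors = FALSE)
  }))
}

#' Default run configuration
#'
#' One structured (YAML) configuration drives a whole run: simulation
#' parameters (populations, drug library geometry, plate design, optics),
#' segmentation parameters, screening thresholds and the global seed.
#'
#' @return Nested list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    seed = 1L,
    plate = list(n_compounds = 43, dose_M = 1e-5, replicates = 2,
                 n_controls = 8),
    optics = default_optics(),
    design = list(seed_counts = list(huh7 = 800, fa2n4 = 1500),
                  preincubation_h = 16, treatment_h = 72),
    segmentation = default_seg_params(),
    screening = list(min_cells = 100, zprime_gate = 0.5,
                     huh7_min_inhib = 50, fa2n4_max_inhib = 20),
    dose_ladder = dose_ladder()
  ), class = "run_config")
}

#' Read / write a run configuration
#'
#' YAML round-trip of the [default_run_config()] structure; unknown keys are
#' preserved, missing sections fall back to the defaults.
#'
#' @param path YAML file path.
#' @return For `read_run_config`, a `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("missing config file: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  base <- unclass(default_run_config())
  for (k in names(cfg)) base[[k]] <- modify_defaults(base[[k]], cfg[[k]])
  validate_run_config(structure(base, class = "run_config"))
}

modify_defaults <- function(base, new) {
  if (!is.list(new) || !is.list(base)) return(new)
  for (k in names(new)) base[[k]] <- modify_defaults(base[[k]], new[[k]])
  base
}

#' @rdname read_run_config
#' @param config A `run_config` object.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

validate_run_config <- function(config) {
  s <- config$screening
  if (s$min_cells < 0 || s$zprime_gate > 1 ||
      s$huh7_min_inhib < 0 || s$huh7_min_inhib > 100 ||
      s$fa2n4_max_inhib < 0 || s$fa2n4_max_inhib > 100)
    stop("screening thresholds out of domain", call. = FALSE)
  if (config$optics$imaged_fraction <= 0 ||
      config$optics$imaged_fraction > 1)
    stop("imaged_fraction must be in (0, 1]", call. = FALSE)
  config
}
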