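#' Default nuclei-segmentation parameters
#'
#' @param smooth_sigma Gaussian pre-smoothing SD in px.
#' @param min_area_px Minimum region area; defaults to the area of a disk of
#'   half the expected mean nucleus radius (radius 6 px -> 28 px).
#' @param watershed_tolerance Minimum object-depth separation for the
#'   distance-transform watershed.
#' @return Named list of parameters.
#' @export
default_seg_params <- function(smooth_sigma = 1.5,
                               min_area_px = floor(pi * 3^2),
                               watershed_tolerance = 1) {
  list(smooth_sigma = smooth_sigma, min_area_px = min_area_px,
       watershed_tolerance = watershed_tolerance)
}

#' Detect nuclei in a Hoechst image
#'
#' Gaussian smoothing, global Otsu threshold, distance-transform watershed
#' to split touching nuclei, and removal of sub-minimum-area regions.
#' Surviving regions are relabelled 1..n in increasing original-label order,
#' so label assignment is deterministic (lowest label wins ties).
#'
#' @param hoechst_image 2-D numeric matrix (single channel).
#' @param params See [default_seg_params()].
#' @return Integer label matrix; background is 0. A constant image yields
#'   zero labels.
#' @export
detect_nuclei <- function(hoechst_image, params = default_seg_params()) {
  if (!is.matrix(hoechst_image))
    stop("'hoechst_image' must be a 2-D matrix", call. = FALSE)
  rng <- range(hoechst_image)
  if (diff(rng) == 0)
    return(matrix(0L, nrow(hoechst_image), ncol(hoechst_image)))
  imgn <- (hoechst_image - rng[1]) / diff(rng)
  sm <- EBImage::gblur(EBImage::Image(imgn), sigma = params$smooth_sigma)
  th <- EBImage::otsu(sm, range = c(0, 1))
  mask <- sm > th
  if (!any(mask))
    return(matrix(0L, nrow(hoechst_image), ncol(hoechst_image)))
  dm <- EBImage::distmap(mask)
  labels <- EBImage::watershed(dm, tolerance = params$watershed_tolerance)
  lab <- matrix(as.integer(EBImage::imageData(labels)),
                nrow(hoechst_image), ncol(hoechst_image))
  # drop regions below the minimum area, relabel sequentially
  if (max(lab) > 0) {
    areas <- tabulate(lab, nbins = max(lab))
    keep <- which(areas >= params$min_area_px)
    remap <- integer(max(lab))
    remap[keep] <- seq_along(keep)
    lab <- matrix(ifelse(lab > 0, remap[pmax(lab, 1L)], 0L),
                  nrow(lab), ncol(lab))
  }
  lab
}

#' Measure per-cell channel intensities
#'
#' For each labelled nucleus, reports the mean intensity over the nucleus
#' mask and over a ring (the nucleus dilated by `ring_px`, minus the
#' nucleus) per channel, plus the 0-based centroid (row, col; origin
#' top-left) and nucleus area. Where rings of neighbouring cells would
#' overlap, each ring pixel is assigned to the lowest adjacent label
#' (deterministic tie-break).
#'
#' @param label_map Integer label matrix from [detect_nuclei()].
#' @param channel_images Named list of matrices, same shape as `label_map`.
#' @param ring_px Ring width in px (default 4, the cytoplasm proxy).
#' @return Data.frame with one row per label: `cell_id, centroid_row,
#'   centroid_col, nucleus_area_px`, and `nucleus_mean_<ch>` /
#'   `ring_mean_<ch>` per channel. Zero labels give an empty table.
#' @export
measure_markers <- function(label_map, channel_images, ring_px = 4) {
  for (ch in names(channel_images))
    if (!identical(dim(channel_images[[ch]]), dim(label_map)))
      stop(sprintf("channel '%s' shape does not match the label map", ch),
           call. = FALSE)
  n <- max(label_map)
  empty <- data.frame(cell_id = integer(0), centroid_row = numeric(0),
                      centroid_col = numeric(0), nucleus_area_px = integer(0))
  if (n == 0) {
    for (ch in names(channel_images)) {
      empty[[paste0("nucleus_mean_", ch)]] <- numeric(0)
      empty[[paste0("ring_mean_", ch)]] <- numeric(0)
    }
    return(empty)
  }
  idx <- which(label_map > 0)
  labs <- label_map[idx]
  rows <- (idx - 1) %% nrow(label_map)        # 0-based
  cols <- (idx - 1) %/% nrow(label_map)
  area <- tabulate(labs, nbins = n)
  out <- data.frame(
    cell_id = seq_len(n),
    centroid_row = as.numeric(rowsum(rows, labs)) / area,
    centroid_col = as.numeric(rowsum(cols, labs)) / area,
    nucleus_area_px = area)
  # ring labels: grayscale min-filter with background at +big so the lowest
  # adjacent nucleus label claims each ring pixel
  big <- n + 1L
  lm2 <- label_map
  lm2[lm2 == 0L] <- big
  kern <- EBImage::makeBrush(2 * ring_px + 1, shape = "disc")
  er <- EBImage::erode(EBImage::Image(lm2 / big), kern) * big
  ring_lab <- matrix(as.integer(round(er)), nrow(label_map), ncol(label_map))
  ring_idx <- which(label_map == 0L & ring_lab >= 1L & ring_lab <= n)
  ring_labs <- ring_lab[ring_idx]
  ring_area <- tabulate(ring_labs, nbins = n)
  for (ch in names(channel_images)) {
    img <- channel_images[[ch]]
    out[[paste0("nucleus_mean_", ch)]] <-
      as.numeric(rowsum(img[idx], labs)) / area
    rm_sum <- rep(0, n)
    if (length(ring_idx))
      rm_sum[sort(unique(ring_labs))] <-
        as.numeric(rowsum(img[ring_idx], ring_labs))
    out[[paste0("ring_mean_", ch)]] <-
      ifelse(ring_area > 0, rm_sum / ring_area, NA_real_)
  }
  out
}

#' Derive marker classification thresholds from control wells
#'
#' Pools control-well cells and computes, per marker, an Otsu split of the
#' log10 ring-intensity distribution. When the distribution is effectively
#' unimodal (the density at the candidate cut is not a deep enough valley
#' relative to the flanking peaks), the split is unreliable and the
#' configured fixed cutoff is used instead.
#'
#' @param control_features Feature table (from [measure_markers()]) pooled
#'   over at least one negative-control well; needs >= 50 cells.
#' @param markers Marker channel names (default CHALV1 and AFP).
#' @param fixed Optional named vector of fallback cutoffs (intensity units).
#' @param valley_ratio Maximum density ratio (cut / smaller flanking peak)
#'   still considered bimodal; above it the fallback applies.
#' @return Object of class `class_thresholds`: named `cutoffs` vector and
#'   per-marker `method` (`"otsu_on_controls"` or `"fixed"`).
#' @export
derive_thresholds_from_controls <- function(control_features,
                                            markers = c("chalv1", "afp"),
                                            fixed = NULL,
                                            valley_ratio = 0.8) {
  if (nrow(control_features) < 50)
    stop("need >= 50 pooled control cells for thresholding", call. = FALSE)
  cutoffs <- numeric(0)
  method <- character(0)
  for (m in markers) {
    colname <- paste0("ring_mean_", m)
    if (!colname %in% names(control_features))
      stop(sprintf("missing marker column '%s'", colname), call. = FALSE)
    x <- log10(pmax(control_features[[colname]], 1e-6))
    cut <- otsu_threshold(x)
    unimodal <- is.na(cut) || valley_depth_ratio(x, cut) > valley_ratio
    if (unimodal) {
      if (is.null(fixed) || is.na(fixed[m]))
        stop(sprintf(
          "marker '%s': control distribution is unimodal and no fixed cutoff was configured", m),
          call. = FALSE)
      cutoffs[m] <- unname(fixed[m])
      method[m] <- "fixed"
    } else {
      cutoffs[m] <- 10^cut
      method[m] <- "otsu_on_controls"
    }
  }
  structure(list(cutoffs = cutoffs, method = method),
            class = "class_thresholds")
}

#' Fixed classification thresholds
#'
#' @param ... Named cutoffs, e.g. `chalv1 = 500, afp = 400`.
#' @return Object of class `class_thresholds`.
#' @export
fixed_thresholds <- function(...) {
  cutoffs <- c(...)
  if (any(cutoffs <= 0)) stop("cutoffs must be > 0", call. = FALSE)
  structure(list(cutoffs = cutoffs,
                 method = setNames(rep("fixed", length(cutoffs)),
                                   names(cutoffs))),
            class = "class_thresholds")
}

#' Classify cells by the two-marker rule
#'
#' HCC iff both marker ring intensities strictly exceed their cutoffs;
#' HEPATOCYTE iff both are at or below; single-positive cells are AMBIGUOUS
#' and excluded from both population counts.
#'
#' @param features Feature table from [measure_markers()].
#' @param thresholds A `class_thresholds` object.
#' @return List: `features` (input plus `class` column), `counts` (named
#'   vector HCC / HEPATOCYTE / AMBIGUOUS), `fractions`.
#' @export
classify_cells <- function(features, thresholds) {
  markers <- names(thresholds$cutoffs)
  cols <- paste0("ring_mean_", markers)
  missing <- setdiff(cols, names(features))
  if (length(missing))
    stop("missing marker columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (nrow(features) == 0) {
    features$class <- character(0)
    counts <- c(HCC = 0L, HEPATOCYTE = 0L, AMBIGUOUS = 0L)
    return(list(features = features, counts = counts,
                fractions = counts))
  }
  above <- sapply(seq_along(markers), function(i)
    features[[cols[i]]] > thresholds$cutoffs[markers[i]])
  above <- matrix(above, nrow = nrow(features))
  n_above <- rowSums(above)
  cls <- ifelse(n_above == length(markers), "HCC",
                ifelse(n_above == 0, "HEPATOCYTE", "AMBIGUOUS"))
  features$class <- cls
  counts <- c(HCC = sum(cls == "HCC"),
              HEPATOCYTE = sum(cls == "HEPATOCYTE"),
              AMBIGUOUS = sum(cls == "AMBIGUOUS"))
  list(features = features, counts = counts,
       fractions = counts / sum(counts))
}

#' Well-level cell-count quality control
#'
#' A well passes only when it yields strictly more than `min_cells` cells
#' across its fields (the acquisition design collects four fields per well
#' to capture > 100 cells).
#'
#' @param features Feature table for the whole well.
#' @param min_cells QC minimum (default 100; strict inequality).
#' @return List with `pass`, `n_cells`, `reason`.
#' @export
qc_well <- function(features, min_cells = 100) {
  n <- nrow(features)
  pass <- n > min_cells
  list(pass = pass, n_cells = n,
       reason = if (pass) "" else
         sprintf("only %d cells (need > %d)", n, min_cells))
}
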