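#' Detect lysosomal puncta per cell
#'
#' Blob detection on the LysoTracker channel: a Laplacian-of-Gaussian-style
#' band-pass response (difference of Gaussians at `sigma` and `1.6 * sigma`)
#' is thresholded at `floor_quantile` of its positive tail plus an absolute
#' intensity floor, and connected components become puncta. Each punctum is
#' assigned to the cell footprint containing its centroid; orphan puncta
#' (centroid over background) are dropped and counted in the log attribute.
#'
#' @param lyso_image LysoTracker channel matrix.
#' @param cell_footprints Integer label map of cell footprints (from
#'   segmentation, or generator truth in fixtures).
#' @param sigma Blob scale in px (match the expected punctum radius).
#' @param intensity_floor Absolute minimum DoG response for a punctum pixel
#'   (arbitrary units); lowering it can only grow the detected mask.
#' @param min_area_px Minimum punctum area.
#' @return List of class `vesicle_stats`: `per_cell` data.frame (`cell_id`,
#'   `puncta_count`, `mean_puncta_area_px`, `total_lyso_intensity`),
#'   `puncta_labels` matrix, `summary` (n, mean, SD per statistic), and an
#'   `orphans` attribute with the dropped-puncta count.
#' @export
detect_puncta <- function(lyso_image, cell_footprints, sigma = 1.2,
                          intensity_floor = 100, min_area_px = 2) {
  if (is.null(cell_footprints))
    stop("cell footprints are required", call. = FALSE)
  if (!identical(dim(lyso_image), dim(cell_footprints)))
    stop("image and footprints must share a shape", call. = FALSE)
  img <- lyso_image / 65535
  dog <- EBImage::gblur(EBImage::Image(img), sigma) -
         EBImage::gblur(EBImage::Image(img), 1.6 * sigma)
  dogm <- matrix(EBImage::imageData(dog), nrow(img), ncol(img)) * 65535
  mask <- dogm > intensity_floor
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(EBImage::imageData(lab)), nrow(img), ncol(img))
  n_cells <- max(cell_footprints)
  per_cell <- data.frame(cell_id = seq_len(n_cells),
                         puncta_count = 0L,
                         mean_puncta_area_px = NA_real_,
                         total_lyso_intensity = 0)
  orphans <- 0L
  if (max(lab) > 0) {
    areas <- tabulate(lab, nbins = max(lab))
    keep <- which(areas >= min_area_px)
    idx <- which(lab > 0)
    labs <- lab[idx]
    rows <- round(as.numeric(rowsum((idx - 1) %% nrow(lab), labs)) / areas)
    cols <- round(as.numeric(rowsum((idx - 1) %/% nrow(lab), labs)) / areas)
    sums <- as.numeric(rowsum(lyso_image[idx], labs))
    for (p in keep) {
      owner <- cell_footprints[rows[p] + 1, cols[p] + 1]
      if (owner == 0) { orphans <- orphans + 1L; next }
      i <- owner
      k <- per_cell$puncta_count[i]
      per_cell$mean_puncta_area_px[i] <-
        if (k == 0) areas[p]
        else (per_cell$mean_puncta_area_px[i] * k + areas[p]) / (k + 1)
      per_cell$puncta_count[i] <- k + 1L
      per_cell$total_lyso_intensity[i] <-
        per_cell$total_lyso_intensity[i] + sums[p]
    }
  }
  summ <- data.frame(
    statistic = c("puncta_count", "mean_puncta_area_px",
                  "total_lyso_intensity"),
    n = nrow(per_cell),
    mean = c(mean(per_cell$puncta_count),
             mean(per_cell$mean_puncta_area_px, na.rm = TRUE),
             mean(per_cell$total_lyso_intensity)),
    sd = c(sd(per_cell$puncta_count),
           sd(per_cell$mean_puncta_area_px, na.rm = TRUE),
           sd(per_cell$total_lyso_intensity)))
  structure(list(per_cell = per_cell, puncta_labels = lab, summary = summ,
                 orphans = orphans), class = "vesicle_stats")
}

#' Cathepsin-B translocation index
#'
#' `1 - (background-subtracted signal inside the puncta mask) /
#' (background-subtracted signal over the whole footprint)`, clipped to
#' `[0, 1]`: 0 means fully punctate (lysosomal), 1 fully diffuse
#' (cytosolic). The background is the per-image median outside all
#' footprints. Invariant to positive rescaling of the channel when the
#' background scales with it.
#'
#' @param ctsb_image Cathepsin-B channel matrix.
#' @param puncta_mask Logical matrix of punctum pixels.
#' @param cell_footprint Logical matrix of the cell's footprint.
#' @param background Background level; default the median of the image
#'   outside `cell_footprint`.
#' @return Scalar index in `[0, 1]`, or `NA` (with a warning) when the cell
#'   carries no signal above background.
#' @export
translocation_index <- function(ctsb_image, puncta_mask, cell_footprint,
                                background = NULL) {
  if (is.null(background))
    background <- median(ctsb_image[!cell_footprint])
  inside <- sum(ctsb_image[puncta_mask & cell_footprint] - background)
  total <- sum(ctsb_image[cell_footprint] - background)
  if (!is.finite(total) || total <= 0) {
    warning("cell has no cathepsin-B signal above background; excluded")
    return(NA_real_)
  }
  min(1, max(0, 1 - inside / total))
}

#' Per-cell nuclear (or footprint) intensity statistics
#'
#' Mean channel intensity per labelled region plus a condition summary
#' (n, mean, SD). Optionally reports the fraction of positive cells above
#' an Otsu cut on the per-cell means (used for the EdU-positive fraction);
#' when the image carries no real signal (per-cell means spanning less than
#' `min_signal_range`), the positive fraction is 0.
#'
#' @param channel_image Channel matrix.
#' @param labels Integer label map (nuclei, or footprints for
#'   cytosolic/mitochondrial dyes).
#' @param condition Condition label for the summary row.
#' @param positive_fraction Also compute the Otsu-split positive fraction.
#' @param min_signal_range Minimum spread of per-cell means for the Otsu
#'   split to be attempted (arbitrary units).
#' @return List: `per_cell` (`cell_id`, `mean_intensity`, and `positive` if
#'   requested), `summary` data.frame, `positive_fraction` (or NA).
#' @export
nuclear_intensity_stats <- function(channel_image, labels,
                                    condition = NA_character_,
                                    positive_fraction = FALSE,
                                    min_signal_range = 200) {
  n <- max(labels)
  if (n == 0)
    return(list(per_cell = data.frame(cell_id = integer(0),
                                      mean_intensity = numeric(0)),
                summary = data.frame(condition = condition, n = 0L,
                                     mean = NA_real_, sd = NA_real_),
                positive_fraction = NA_real_))
  idx <- which(labels > 0)
  labs <- labels[idx]
  area <- tabulate(labs, nbins = n)
  means <- as.numeric(rowsum(channel_image[idx], labs)) / area
  per_cell <- data.frame(cell_id = seq_len(n), mean_intensity = means)
  pf <- NA_real_
  if (positive_fraction) {
    if (diff(range(means)) < min_signal_range) {
      per_cell$positive <- FALSE
      pf <- 0
    } else {
      cut <- otsu_threshold(means)
      per_cell$positive <- means > cut
      pf <- mean(per_cell$positive)
    }
  }
  list(per_cell = per_cell,
       summary = data.frame(condition = condition, n = n,
                            mean = mean(means), sd = sd(means)),
       positive_fraction = pf)
}

#' Caspase-3/7 fold activation
#'
#' Fold change of mean treated over mean control plate-reader readings
#' (optionally normalised per lysate by protein content) with a two-sample
#' Student's t-test.
#'
#' @param treated_readings,control_readings Numeric readings (>= 3 per arm
#'   for the t-test).
#' @param treated_norm,control_norm Optional per-lysate protein
#'   normalisation factors (readings are divided by them).
#' @return List of class `caspase_result`: `fold`, `p_value`,
#'   `significant`.
#' @export
caspase_fold_activation <- function(treated_readings, control_readings,
                                    treated_norm = NULL,
                                    control_norm = NULL) {
  if (length(treated_readings) < 3 || length(control_readings) < 3)
    stop("need >= 3 readings per arm", call. = FALSE)
  tr <- if (is.null(treated_norm)) treated_readings
        else treated_readings / treated_norm
  ct <- if (is.null(control_norm)) control_readings
        else control_readings / control_norm
  if (mean(ct) <= 0)
    stop("control mean must be positive", call. = FALSE)
  fold <- mean(tr) / mean(ct)
  p <- if (sd(tr) == 0 && sd(ct) == 0)
         (if (mean(tr) == mean(ct)) 1 else 0)
       else t.test(tr, ct)$p.value
  structure(list(fold = fold, p_value = p, significant = p < 0.05),
            class = "caspase_result")
}

#' @export
print.caspase_result <- function(x, ...) {
  cat(sprintf("Caspase-3/7 fold activation: %.3f (t-test p = %.3g%s)\n",
              x$fold, x$p_value, if (x$significant) ", significant" else ""))
  invisible(x)
}

#' Apoptotic fraction at a spheroid's mid-plane
#'
#' Extracts the mid-plane slice (`floor(n_slices/2)`, 0-based), segments its
#' nuclei, dilates them into footprints, and scores each cell
#' caspase-3-positive when its footprint mean exceeds an Otsu cut on the
#' per-cell means; a slice without real caspase-3 signal scores zero
#' positives.
#'
#' @param stack A `spheroid_stack` (see [simulate_spheroid_stack()]) or any
#'   list with `slices` (each `list(hoechst=, casp3=)`) and `n_slices`.
#' @param seg_params Nuclei segmentation parameters.
#' @param footprint_dilate_px Footprint ring in px.
#' @return List: `apoptotic_fraction`, `n_cells`, `midplane` (0-based). When
#'   the mid-plane holds no cells the fraction is `NA` and a warning is
#'   issued.
#' @export
analyze_spheroid_midplane <- function(stack,
                                      seg_params = default_seg_params(),
                                      footprint_dilate_px = 3) {
  mid <- midplane_index(stack$n_slices)
  sl <- stack$slices[[mid + 1]]
  lab <- detect_nuclei(sl$hoechst, seg_params)
  if (max(lab) == 0) {
    warning("no cells detected at the mid-plane")
    return(list(apoptotic_fraction = NA_real_, n_cells = 0L,
                midplane = mid))
  }
  kern <- EBImage::makeBrush(2 * footprint_dilate_px + 1, shape = "disc")
  fp <- EBImage::dilate(EBImage::Image(lab / (max(lab) + 1)), kern) *
    (max(lab) + 1)
  fp <- matrix(as.integer(round(fp)), nrow(lab), ncol(lab))
  st <- nuclear_intensity_stats(sl$casp3, fp)
  means <- st$per_cell$mean_intensity
  # three-way decision anchored on the image background:
  # (1) if the brightest pixels do not rise clearly above the background
  #     noise, the slice carries no caspase-3 signal -> fraction 0;
  # (2) otherwise split the per-cell means by Otsu; if even the dimmer class
  #     sits far above background, every cell is positive -> fraction 1;
  # (3) otherwise the Otsu split separates positive from negative cells.
  px <- as.numeric(sl$casp3)
  bg <- median(px); noise <- mad(px)
  frac <- if (quantile(px, 0.999) <= bg + 20 * noise) {
    0
  } else {
    cut_cells <- otsu_threshold(means)
    low <- means[means <= cut_cells]
    if (length(low) == 0 || median(low) > bg + 10 * noise) 1
    else mean(means > cut_cells)
  }
  list(apoptotic_fraction = frac, n_cells = max(lab), midplane = mid)
}
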