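# Shared fixture builders (all synthetic, generated at test time).

# Two hard-disk "nuclei" at a given centre distance, for watershed checks.
disk_pair_image <- function(d, r = 6, dim_px = 64, amplitude = 8000,
                            background = 100) {
  img <- matrix(0, dim_px, dim_px)
  rr <- seq_len(dim_px)
  add <- function(img, row, col) {
    d2 <- outer((rr - row)^2, (rr - col)^2, "+")
    img + amplitude * (d2 <= r^2)
  }
  img <- add(img, dim_px / 2, dim_px / 2 - d / 2)
  img <- add(img, dim_px / 2, dim_px / 2 + d / 2)
  matrix(as.integer(round(img + background)), dim_px, dim_px)
}

# A rendered field with n non-overlapping cells of the default populations,
# in a given HCC fraction; returns the field images plus the placed truth.
render_mixed_field <- function(n, hcc_frac, seed, optics = default_optics()) {
  set.seed(seed)
  pops <- default_populations()
  n_hcc <- round(n * hcc_frac)
  cells <- rbind(
    if (n_hcc > 0) hcscreen:::sample_cells(n_hcc, pops$huh7, optics),
    if (n - n_hcc > 0) hcscreen:::sample_cells(n - n_hcc, pops$fa2n4,
                                               optics))
  mean_diam <- 2 * 6.25
  pos <- hcscreen:::place_cells(nrow(cells), optics$width, optics$height,
                                optics$min_sep_factor * mean_diam,
                                margin = mean_diam, 400L)
  cells$row <- pos$row
  cells$col <- pos$col
  list(images = render_field(cells, c("hoechst", "chalv1", "afp"), optics),
       truth = cells)
}

# Segment + measure every field of a simulated well, returning the pooled
# feature table.
measure_well <- function(sim) {
  out <- NULL
  for (f in seq_along(sim$fields)) {
    lab <- detect_nuclei(sim$fields[[f]]$hoechst)
    m <- measure_markers(lab, sim$fields[[f]][c("chalv1", "afp")])
    if (nrow(m)) {
      m$field <- f
      out <- rbind(out, m)
    }
  }
  out
}

# Match detected features to ground-truth cells by nearest centroid
# (truth coordinates are 1-based matrix indices; features are 0-based).
match_to_truth <- function(features, truth, max_dist = 3) {
  hits <- integer(0)
  cls <- character(0)
  for (i in seq_len(nrow(features))) {
    d2 <- (truth$row - 1 - features$centroid_row[i])^2 +
          (truth$col - 1 - features$centroid_col[i])^2
    j <- which.min(d2)
    if (sqrt(d2[j]) <= max_dist) {
      hits <- c(hits, i)
      cls <- c(cls, if (truth$population[j] == "huh7") "HCC"
                    else "HEPATOCYTE")
    }
  }
  list(matched = hits, true_class = cls)
}
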