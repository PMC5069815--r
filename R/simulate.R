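#' Default imaging (optics) parameters for the synthetic generator
#'
#' Field geometry and noise for rendered wells: 512x512 px 16-bit fields,
#' 4 fields per well, nucleus rendered as a Gaussian blob, markers as a
#' uniform nucleus-plus-ring footprint, additive Gaussian read noise over a
#' constant background. `imaged_fraction` is the fraction of the physical
#' well's surviving cells captured by the four fields (fields cover only
#' part of a 384-well's area).
#'
#' @return Named list of optics parameters.
#' @export
default_optics <- function() {
  list(width = 512L, height = 512L, n_fields = 4L,
       background = 100, read_noise_sd = 5,
       ring_px = 4, min_sep_factor = 1.2,
       imaged_fraction = 0.05, well_cv = 0.02,
       max_place_attempts = 400L)
}

#' Default co-culture assay design
#'
#' Seeding densities (1500 Fa2N-4 : 800 Huh7 per well), 16 h pre-incubation
#' before compound addition and 72 h treatment; growth applies across the
#' whole 88 h, compound kill as an endpoint survival multiplier.
#'
#' @return Named list with `seed_counts`, `preincubation_h`, `treatment_h`.
#' @export
default_assay_design <- function() {
  list(seed_counts = c(huh7 = 800, fa2n4 = 1500),
       preincubation_h = 16, treatment_h = 72)
}

# Sample per-cell attributes for n cells of one population.
sample_cells <- function(n, pop, optics) {
  if (n == 0) return(NULL)
  r <- pmax(3, rnorm(n, pop$nucleus_radius_px[1], pop$nucleus_radius_px[2]))
  ints <- lapply(pop$marker_intensity, function(mi)
    rlnorm(n, meanlog = log(mi[1]), sdlog = log(mi[2])))
  df <- data.frame(population = pop$name, radius_px = r,
                   stringsAsFactors = FALSE)
  for (ch in names(ints)) df[[paste0("true_", ch)]] <- ints[[ch]]
  df
}

# Rejection-sample non-overlapping centroids for one field. Cells are placed
# in order; min_sep is the minimum centroid distance in px.
place_cells <- function(n, width, height, min_sep, margin, max_attempts) {
  if (n == 0)
    return(data.frame(row = numeric(0), col = numeric(0)))
  capacity <- (width - 2 * margin) * (height - 2 * margin) / min_sep^2
  if (n > capacity)
    stop(sprintf(
      "field too small: %d cells exceed the non-overlap capacity (~%d) of a %dx%d field at min separation %.1f px",
      n, floor(capacity), width, height, min_sep), call. = FALSE)
  rows <- numeric(n); cols <- numeric(n)
  min_sep2 <- min_sep^2
  for (i in seq_len(n)) {
    placed <- FALSE
    for (a in seq_len(max_attempts)) {
      rr <- runif(1, margin, height - margin)
      cc <- runif(1, margin, width - margin)
      if (i == 1 ||
          min((rows[seq_len(i - 1)] - rr)^2 +
              (cols[seq_len(i - 1)] - cc)^2) >= min_sep2) {
        rows[i] <- rr; cols[i] <- cc; placed <- TRUE; break
      }
    }
    if (!placed)
      stop(sprintf(
        "field too small: could not place cell %d of %d at min separation %.1f px after %d attempts",
        i, n, min_sep, max_attempts), call. = FALSE)
  }
  data.frame(row = rows, col = cols)
}

# Add a Gaussian blob (nucleus) to an image matrix in place.
add_gaussian_blob <- function(img, row, col, sigma, amplitude) {
  ext <- ceiling(3 * sigma)
  r0 <- max(1, round(row) - ext); r1 <- min(nrow(img), round(row) + ext)
  c0 <- max(1, round(col) - ext); c1 <- min(ncol(img), round(col) + ext)
  rr <- r0:r1; cc <- c0:c1
  d2 <- outer((rr - row)^2, (cc - col)^2, "+")
  img[rr, cc] <- img[rr, cc] + amplitude * exp(-d2 / (2 * sigma^2))
  img
}

# Set a uniform disk (marker footprint) to max(current, value).
add_disk <- function(img, row, col, radius, value) {
  off <- disk_offsets(radius)
  rr <- round(row) + off$dr; cc <- round(col) + off$dc
  keep <- rr >= 1 & rr <= nrow(img) & cc >= 1 & cc <= ncol(img)
  idx <- cbind(rr[keep], cc[keep])
  img[idx] <- pmax(img[idx], value)
  img
}

#' Render one field of a synthetic well
#'
#' @param cells Data.frame with `row`, `col`, `radius_px` and `true_<channel>`
#'   intensity columns (as produced inside [simulate_well()]).
#' @param channels Character vector of channels to render (subset of the
#'   `true_*` columns; `hoechst` is rendered as Gaussian nuclei, all others
#'   as uniform nucleus+ring footprints).
#' @param optics Optics list, see [default_optics()]. Marker footprints are
#'   rendered 3 px wider than the measured ring so that the measured ring
#'   (nucleus + `ring_px`) stays inside the simulated cytoplasm even when
#'   the segmented nucleus slightly exceeds the true radius.
#' @return Named list of integer-valued image matrices (height x width).
#' @export
render_field <- function(cells, channels, optics = default_optics()) {
  h <- optics$height; w <- optics$width
  n <- if (is.null(cells)) 0L else nrow(cells)
  out <- list()
  for (ch in channels) {
    img <- numeric(h * w)
    if (n > 0) {
      vals <- cells[[paste0("true_", ch)]]
      idx_all <- vector("list", n)
      val_all <- vector("list", n)
      for (i in seq_len(n)) {
        if (ch == "hoechst") {
          sigma <- cells$radius_px[i] / 1.5
          ext <- ceiling(3 * sigma)
          r0 <- max(1, round(cells$row[i]) - ext)
          r1 <- min(h, round(cells$row[i]) + ext)
          c0 <- max(1, round(cells$col[i]) - ext)
          c1 <- min(w, round(cells$col[i]) + ext)
          rr <- r0:r1; cc <- c0:c1
          d2 <- outer((rr - cells$row[i])^2, (cc - cells$col[i])^2, "+")
          idx_all[[i]] <- as.vector(outer(rr, (cc - 1) * h, "+"))
          val_all[[i]] <- as.vector(vals[i] * exp(-d2 / (2 * sigma^2)))
        } else {
          off <- disk_offsets(cells$radius_px[i] + optics$ring_px + 3)
          prr <- round(cells$row[i]) + off$dr
          pcc <- round(cells$col[i]) + off$dc
          keep <- prr >= 1 & prr <= h & pcc >= 1 & pcc <= w
          idx_all[[i]] <- prr[keep] + (pcc[keep] - 1) * h
          # carry the distance to the cell centre for compositing
          val_all[[i]] <- (off$dr[keep]^2 + off$dc[keep]^2)
          attr(idx_all[[i]], "value") <- vals[i]
        }
      }
      if (ch == "hoechst") {
        # nuclei add photometrically
        idx <- unlist(idx_all); v <- unlist(val_all)
        acc <- rowsum(v, idx)
        img[as.integer(rownames(acc))] <- acc
      } else {
        # overlapping footprints: the nearest cell centre claims the pixel
        # (cytoplasm boundary proxy)
        idx <- unlist(idx_all)
        d2 <- unlist(val_all)
        v <- unlist(lapply(idx_all, function(ii)
          rep(attr(ii, "value"), length(ii))))
        ord <- order(-d2)
        img[idx[ord]] <- v[ord]
      }
    }
    img <- img + optics$background +
      rnorm(length(img), 0, optics$read_noise_sd)
    out[[ch]] <- matrix(as.integer(pmin(65535, pmax(0, round(img)))), h, w)
  }
  out
}

# Survival fraction for one population in one well.
well_survival_fraction <- function(entry, pop, drug_models) {
  base <- 1 - pop$baseline_death_frac
  if (entry$role == "negative_control" || entry$dose_M <= 0 ||
      entry$compound %in% c("DMSO", "", NA)) return(base)
  dm <- drug_models[[entry$compound]]
  if (is.null(dm))
    stop(sprintf("no drug model for compound '%s'", entry$compound),
         call. = FALSE)
  e <- dm$effects[[pop$name]]
  if (is.null(e))
    stop(sprintf("drug '%s' has no effect model for population '%s'",
                 entry$compound, pop$name), call. = FALSE)
  base * viability_4pl(entry$dose_M, e$top, e$bottom, e$ic50, e$hill) / 100
}

#' Simulate one co-culture well (images + ground truth)
#'
#' Grows both populations over pre-incubation plus treatment, applies the
#' compound's per-population four-parameter-logistic survival at the well's
#' dose as an endpoint multiplier, samples the imaged subset of surviving
#' cells into `n_fields` fields, and renders one 16-bit image per channel
#' per field. All randomness flows from a per-well seed derived from
#' `seed` and the plate/well ids, so identical calls are bit-identical.
#'
#' @param entry One plate-layout row (list or single-row data.frame with
#'   `plate, well, role, compound, dose_M`).
#' @param populations Named list of [population_model()]s.
#' @param drug_models Named list of [drug_effect_model()]s.
#' @param seed Global integer seed.
#' @param optics See [default_optics()].
#' @param design See [default_assay_design()].
#' @param channels Channels to render.
#' @param render If `FALSE`, skip cell placement and image rendering and
#'   return counts-level truth only (fast path for statistical checks of
#'   the well model).
#' @return List with `fields` (list of per-field channel-image lists) and
#'   `truth` (list: `counts` data.frame per population with seeded, grown,
#'   surviving, rendered counts and expected survival fraction; `cells`
#'   per-rendered-cell data.frame with field, centroid, class, radius and
#'   sampled true intensities).
#' @export
simulate_well <- function(entry, populations, drug_models, seed,
                          optics = default_optics(),
                          design = default_assay_design(),
                          channels = c("hoechst", "chalv1", "afp"),
                          render = TRUE) {
  entry <- as.list(entry)
  set.seed(derive_well_seed(seed, entry$plate, entry$well))
  t_total <- design$preincubation_h + design$treatment_h
  counts <- NULL
  cells <- NULL
  for (pname in names(populations)) {
    pop <- populations[[pname]]
    n0 <- design$seed_counts[[pname]]
    grown <- if (entry$role == "empty") 0L else
      rpois(1, grow_population(n0, pop$doubling_time_h, t_total))
    surv_frac <- well_survival_fraction(entry, pop, drug_models)
    # well-to-well technical variability on the realised survival
    eff_frac <- min(1, surv_frac * rlnorm(1, 0, optics$well_cv))
    surviving <- rbinom(1, grown, eff_frac)
    rendered <- rbinom(1, surviving, optics$imaged_fraction)
    counts <- rbind(counts, data.frame(
      population = pname, seeded = n0, grown = grown,
      surviving = surviving, rendered = rendered,
      expected_survival = surv_frac, stringsAsFactors = FALSE))
    if (render) {
      cc <- sample_cells(rendered, pop, optics)
      if (!is.null(cc)) {
        cc$field <- sample(seq_len(optics$n_fields), rendered,
                           replace = TRUE)
        cells <- rbind(cells, cc)
      }
    }
  }
  if (!render)
    return(list(fields = NULL, truth = list(counts = counts, cells = NULL)))
  mean_diam <- 2 * mean(vapply(populations,
                               function(p) p$nucleus_radius_px[1], 0))
  min_sep <- optics$min_sep_factor * mean_diam
  fields <- vector("list", optics$n_fields)
  placed <- NULL
  for (f in seq_len(optics$n_fields)) {
    fc <- if (is.null(cells)) NULL else cells[cells$field == f, , drop = FALSE]
    n_f <- if (is.null(fc)) 0L else nrow(fc)
    pos <- place_cells(n_f, optics$width, optics$height, min_sep,
                       margin = mean_diam, optics$max_place_attempts)
    if (n_f > 0) {
      fc$row <- pos$row; fc$col <- pos$col
      placed <- rbind(placed, fc)
    }
    fields[[f]] <- render_field(fc, channels, optics)
  }
  if (!is.null(placed)) {
    placed$plate <- entry$plate; placed$well <- entry$well
    rownames(placed) <- NULL
  }
  list(fields = fields,
       truth = list(counts = counts, cells = placed))
}

#' Image provider backed by the synthetic generator
#'
#' Returns a function `(layout_entry) -> list(fields, truth)` for use with
#' [run_pilot_screen()], closing over the population/drug models, optics and
#' seed. Wells are simulated on demand so a full plate never has to be held
#' in memory.
#'
#' @inheritParams simulate_well
#' @return A function of one layout entry.
#' @export
simulated_image_provider <- function(populations = default_populations(),
                                     drug_models = default_drug_library(),
                                     seed = 1L,
                                     optics = default_optics(),
                                     design = default_assay_design(),
                                     channels = c("hoechst", "chalv1",
                                                  "afp")) {
  force(populations); force(drug_models); force(seed)
  force(optics); force(design); force(channels)
  function(entry) simulate_well(entry, populations, drug_models, seed,
                                optics, design, channels)
}
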