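#' Define a cell-population model
#'
#' Bundles the growth and imaging parameters of one cell type: doubling time,
#' nucleus size, per-channel log-normal marker intensity distributions, and a
#' baseline (drug-independent) death fraction.
#'
#' @param name Population name (e.g. `"huh7"`, `"fa2n4"`).
#' @param doubling_time_h Doubling time in hours (> 0).
#' @param nucleus_radius_px Length-2 numeric: mean and SD of the nucleus
#'   radius in pixels.
#' @param marker_intensity Named list; each element a length-2 numeric
#'   `c(median, gsd)` for one channel's log-normal intensity (median > 0,
#'   geometric SD >= 1), in arbitrary fluorescence units.
#' @param baseline_death_frac Fraction in `[0, 1)` of cells lost regardless
#'   of treatment.
#' @return An object of class `population_model`.
#' @export
population_model <- function(name, doubling_time_h, nucleus_radius_px,
                             marker_intensity, baseline_death_frac = 0) {
  stopifnot_scalar_positive(doubling_time_h, "doubling_time_h")
  if (length(nucleus_radius_px) != 2 || nucleus_radius_px[1] <= 0)
    stop("'nucleus_radius_px' must be c(mean, sd) with mean > 0",
         call. = FALSE)
  for (ch in names(marker_intensity)) {
    mi <- marker_intensity[[ch]]
    if (length(mi) != 2 || mi[1] <= 0 || mi[2] < 1)
      stop(sprintf("marker '%s': need c(median > 0, gsd >= 1)", ch),
           call. = FALSE)
  }
  if (baseline_death_frac < 0 || baseline_death_frac >= 1)
    stop("'baseline_death_frac' must be in [0, 1)", call. = FALSE)
  structure(list(name = name, doubling_time_h = doubling_time_h,
                 nucleus_radius_px = nucleus_radius_px,
                 marker_intensity = marker_intensity,
                 baseline_death_frac = baseline_death_frac),
            class = "population_model")
}

#' Define a compound's per-population kill model
#'
#' Four-parameter logistic survival per population:
#' \eqn{V(c) = bottom + (top - bottom) / (1 + (c/\mathrm{IC50})^h)} with
#' viability in percent and concentration in molar.
#'
#' @param compound_id Compound name.
#' @param effects Named list (one entry per population name); each a list
#'   with `top`, `bottom` (viability %, `top >= bottom`), `ic50` (molar, > 0),
#'   `hill` (> 0).
#' @return An object of class `drug_effect_model`.
#' @export
drug_effect_model <- function(compound_id, effects) {
  for (pop in names(effects)) {
    e <- effects[[pop]]
    if (is.null(e$top) || is.null(e$bottom) || is.null(e$ic50) ||
        is.null(e$hill))
      stop("each effect needs top, bottom, ic50, hill", call. = FALSE)
    if (e$top < e$bottom) stop("top must be >= bottom", call. = FALSE)
    if (e$ic50 <= 0 || e$hill <= 0)
      stop("ic50 and hill must be > 0", call. = FALSE)
  }
  structure(list(compound_id = compound_id, effects = effects),
            class = "drug_effect_model")
}

#' Four-parameter logistic viability
#'
#' @param dose Concentration(s), molar (>= 0). Dose 0 returns `top`.
#' @param top,bottom Upper/lower viability plateaus (%).
#' @param ic50 Half-maximal concentration, molar.
#' @param hill Hill slope (> 0).
#' @return Viability in percent.
#' @export
viability_4pl <- function(dose, top, bottom, ic50, hill) {
  ifelse(dose <= 0, top,
         bottom + (top - bottom) / (1 + (dose / ic50)^hill))
}

#' Default co-culture population models
#'
#' Huh7 (HCC) and Fa2N-4 (immortalized hepatocyte) models with the reported
#' doubling times (23.8 h and 43.5 h). The HCC population carries high
#' CHALV1/AFP medians, the hepatocyte population low ones; Hoechst is
#' comparable in both. Intensities are arbitrary 16-bit-range fluorescence
#' units.
#'
#' @return Named list of two [population_model()] objects (`huh7`, `fa2n4`).
#' @export
default_populations <- function() {
  list(
    huh7 = population_model(
      name = "huh7", doubling_time_h = 23.8,
      nucleus_radius_px = c(6, 1),
      marker_intensity = list(hoechst = c(8000, 1.2),
                              chalv1 = c(1500, 1.35),
                              afp = c(1200, 1.35)),
      baseline_death_frac = 0.03),
    fa2n4 = population_model(
      name = "fa2n4", doubling_time_h = 43.5,
      nucleus_radius_px = c(6.5, 1),
      marker_intensity = list(hoechst = c(8000, 1.2),
                              chalv1 = c(150, 1.35),
                              afp = c(120, 1.35)),
      baseline_death_frac = 0.03)
  )
}

#' Default synthetic compound library (43 compounds + controls)
#'
#' A pilot-screen library mirroring the two-class design of the screened
#' collection: three HCC-selective anti-folate-like compounds whose
#' HCC-side IC50s are the published resazurin values (methotrexate-like
#' 0.004074 uM, pyrimethamine-like 2.764 uM, aminopterin-like 0.0005194 uM)
#' with weak hepatocyte toxicity; a block of pan-toxic compounds that kill
#' both populations; and inactive/weak compounds. The `sorafenib` entry is
#' the positive control (kills both populations strongly at 10 uM).
#'
#' @return Named list of [drug_effect_model()] objects, including a
#'   `selective` attribute naming the three ground-truth-selective compounds.
#' @export
default_drug_library <- function() {
  eff <- function(top, bottom, ic50, hill)
    list(top = top, bottom = bottom, ic50 = ic50, hill = hill)
  lib <- list()
  # Positive control: broad kill of both populations.
  lib$sorafenib <- drug_effect_model("sorafenib", list(
    huh7 = eff(100, 0, 4e-6, 1.3), fa2n4 = eff(100, 0, 4e-6, 1.3)))
  # Three HCC-selective anti-folate-like hits; hepatocyte arm has a high
  # bottom (partial maximal kill), so hepatocyte inhibition at the 10 uM
  # screening dose stays below 20 %.
  lib$mtx_like <- drug_effect_model("mtx_like", list(
    huh7 = eff(100, 0, 4.074e-9, 1),
    fa2n4 = eff(100, 85, 1.518e-8, 1)))
  lib$pyrimethamine_like <- drug_effect_model("pyrimethamine_like", list(
    huh7 = eff(100, 0, 2.764e-6, 1),
    fa2n4 = eff(100, 80, 2.343e-5, 1)))
  lib$aminopterin_like <- drug_effect_model("aminopterin_like", list(
    huh7 = eff(100, 0, 5.194e-10, 1),
    fa2n4 = eff(100, 85, 1.688e-9, 1)))
  # 15 pan-toxic compounds: kill both populations (anticancer cytotoxics and
  # hepatotoxicants) -- fail the <20 % hepatocyte-inhibition arm.
  for (i in 1:15) {
    ic <- 10^(-6.5 + 0.1 * i)
    lib[[sprintf("toxic_%02d", i)]] <- drug_effect_model(
      sprintf("toxic_%02d", i),
      list(huh7 = eff(100, 0, ic, 1.2), fa2n4 = eff(100, 0, ic * 1.5, 1.2)))
  }
  # 25 inactive/weak compounds: IC50s far above 10 uM.
  for (i in 1:25) {
    ic <- 10^(-3.5 + 0.05 * i)
    lib[[sprintf("inactive_%02d", i)]] <- drug_effect_model(
      sprintf("inactive_%02d", i),
      list(huh7 = eff(100, 0, ic, 1), fa2n4 = eff(100, 0, ic * 2, 1)))
  }
  attr(lib, "selective") <- c("mtx_like", "pyrimethamine_like",
                              "aminopterin_like")
  lib
}

#' Build a 384-well pilot-screen plate layout
#'
#' Rows A-P, columns 1-24. Control wells (DMSO negative at dose 0, sorafenib
#' positive at 10 uM) are placed in column 1/24 blocks; each library compound
#' occupies `replicates` test wells at `dose`.
#'
#' @param compounds Character vector of test-compound ids.
#' @param plate_id Plate identifier.
#' @param dose Test dose in molar (default 10 uM, the pilot-screen dose).
#' @param replicates Wells per compound (default 2, "in duplicate").
#' @param n_controls Wells per control arm (default 8; at least 8 of each are
#'   required for a Z'-factor).
#' @return A data.frame with columns `plate, well, row, col, role, compound,
#'   dose_M, replicate`.
#' @export
plate_layout_384 <- function(compounds, plate_id = "P1", dose = 1e-5,
                             replicates = 2, n_controls = 8) {
  if (n_controls < 8)
    stop("need >= 8 wells per control arm for Z'", call. = FALSE)
  rows <- LETTERS[1:16]
  n_test <- length(compounds) * replicates
  if (n_test > 16 * 22)
    stop("too many test wells for a 384-well plate", call. = FALSE)
  entry <- function(row, col, role, compound, dose_M, replicate)
    data.frame(plate = plate_id, well = sprintf("%s%02d", row, col),
               row = row, col = col, role = role, compound = compound,
               dose_M = dose_M, replicate = replicate,
               stringsAsFactors = FALSE)
  out <- list()
  # Controls in columns 1 and 24, alternating rows.
  for (i in seq_len(n_controls)) {
    out[[length(out) + 1]] <- entry(rows[i], 1, "negative_control",
                                    "DMSO", 0, i)
    out[[length(out) + 1]] <- entry(rows[i], 24, "positive_control",
                                    "sorafenib", 1e-5, i)
  }
  # Test wells fill columns 2..23 row-major.
  slots <- expand.grid(col = 2:23, row = rows, stringsAsFactors = FALSE)
  slots <- slots[order(match(slots$row, rows), slots$col), ]
  k <- 1
  for (cmp in compounds) {
    for (r in seq_len(replicates)) {
      out[[length(out) + 1]] <- entry(slots$row[k], slots$col[k], "test",
                                      cmp, dose, r)
      k <- k + 1
    }
  }
  layout <- do.call(rbind, out)
  rownames(layout) <- NULL
  validate_layout(layout)
  layout
}

validate_layout <- function(layout) {
  need <- c("plate", "well", "role", "compound", "dose_M", "replicate")
  missing <- setdiff(need, names(layout))
  if (length(missing))
    stop("layout missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  roles <- c("negative_control", "positive_control", "test", "empty")
  if (!all(layout$role %in% roles))
    stop("invalid roles in layout", call. = FALSE)
  if (sum(layout$role == "negative_control") < 8 ||
      sum(layout$role == "positive_control") < 8)
    stop("every plate needs >= 8 negative and >= 8 positive control wells",
         call. = FALSE)
  if (any(layout$dose_M[layout$role == "negative_control"] != 0))
    stop("negative controls must carry dose 0", call. = FALSE)
  invisible(layout)
}
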