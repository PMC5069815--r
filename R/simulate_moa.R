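#' Simulate a lysosome / cathepsin-B organelle image
#'
#' Renders `n_cells` non-overlapping cell footprints on one field. Each cell
#' receives a Poisson number of lysosomal puncta (bright disks in the
#' LysoTracker channel). The cathepsin-B channel distributes each cell's
#' total signal between its puncta (lysosomal pool, fraction
#' `1 - translocated_frac`) and the rest of the cell footprint (cytosolic
#' pool, fraction `translocated_frac` spread uniformly outside the puncta),
#' so the per-cell ground-truth translocation index equals
#' `translocated_frac` exactly.
#'
#' @param condition Label stored in the truth table (e.g. `"control"`,
#'   `"treated"`).
#' @param n_cells Number of cells to render.
#' @param vesicle_rate Poisson mean puncta per cell (>= 0).
#' @param vesicle_radius Punctum radius in px.
#' @param translocated_frac Cytosolic cathepsin-B fraction in `[0, 1]`.
#' @param seed Integer seed.
#' @param footprint_radius_px Cell footprint radius in px. Puncta are placed
#'   without mutual overlap (blob detection cannot resolve fused puncta);
#'   a punctum that cannot be placed after 100 tries is skipped, and the
#'   truth table records the placed count.
#' @param background,read_noise_sd Additive background and Gaussian noise.
#' @return List: `lyso` and `ctsb` image matrices, `footprints` (integer
#'   label map, one label per cell), `puncta_mask` (logical matrix of true
#'   puncta pixels), and `truth` (per-cell data.frame with centroid, puncta
#'   count, translocated fraction, condition).
#' @export
simulate_organelle_image <- function(condition, n_cells, vesicle_rate,
                                     vesicle_radius = 1.2,
                                     translocated_frac = 0, seed = 1L,
                                     footprint_radius_px = 18,
                                     background = 50, read_noise_sd = 2) {
  if (vesicle_rate < 0) stop("'vesicle_rate' must be >= 0", call. = FALSE)
  if (translocated_frac < 0 || translocated_frac > 1)
    stop("'translocated_frac' must be in [0, 1]", call. = FALSE)
  set.seed(seed)
  # jittered-grid placement keeps footprints disjoint
  spacing <- 2 * footprint_radius_px + 6
  per_side <- ceiling(sqrt(n_cells))
  dim_px <- as.integer(per_side * spacing + 2 * spacing)
  lyso <- matrix(0, dim_px, dim_px)
  ctsb <- matrix(0, dim_px, dim_px)
  footprints <- matrix(0L, dim_px, dim_px)
  puncta_mask <- matrix(FALSE, dim_px, dim_px)
  fp_off <- disk_offsets(footprint_radius_px)
  pn_off <- disk_offsets(vesicle_radius)
  total_ctsb <- 4e5   # integrated cathepsin-B signal per cell, AFU*px
  truth <- NULL
  for (i in seq_len(n_cells)) {
    gr <- (i - 1) %/% per_side
    gc <- (i - 1) %% per_side
    cr <- spacing * (gr + 1) + runif(1, -2, 2)
    cc <- spacing * (gc + 1) + runif(1, -2, 2)
    fp_idx <- cbind(round(cr) + fp_off$dr, round(cc) + fp_off$dc)
    footprints[fp_idx] <- i
    k_drawn <- rpois(1, vesicle_rate)
    k <- 0L
    cell_puncta <- matrix(FALSE, dim_px, dim_px)
    if (k_drawn > 0) {
      max_r <- footprint_radius_px - vesicle_radius - 1
      min_sep2 <- (2 * vesicle_radius + 2.5)^2
      prs <- numeric(0); pcs <- numeric(0)
      for (j in seq_len(k_drawn)) {
        for (a in 1:100) {
          ang <- runif(1, 0, 2 * pi); rad <- sqrt(runif(1)) * max_r
          pr <- cr + rad * sin(ang); pc <- cc + rad * cos(ang)
          if (k == 0 || min((prs - pr)^2 + (pcs - pc)^2) >= min_sep2) {
            prs <- c(prs, pr); pcs <- c(pcs, pc); k <- k + 1L
            p_idx <- cbind(round(pr) + pn_off$dr, round(pc) + pn_off$dc)
            cell_puncta[p_idx] <- TRUE
            lyso[p_idx] <- pmax(lyso[p_idx], rlnorm(1, log(3000), log(1.2)))
            break
          }
        }
      }
    }
    puncta_mask <- puncta_mask | cell_puncta
    in_p <- footprints == i & cell_puncta
    out_p <- footprints == i & !cell_puncta
    a_in <- sum(in_p); a_out <- sum(out_p)
    if (a_in > 0)
      ctsb[in_p] <- ctsb[in_p] + (1 - translocated_frac) * total_ctsb / a_in
    # cytosolic pool (plus the lysosomal pool when there are no puncta)
    diffuse <- translocated_frac + if (a_in == 0) (1 - translocated_frac) else 0
    if (a_out > 0)
      ctsb[out_p] <- ctsb[out_p] + diffuse * total_ctsb / a_out
    truth <- rbind(truth, data.frame(
      cell_id = i, row = cr, col = cc, puncta_count = k,
      translocated_frac = translocated_frac, condition = condition,
      stringsAsFactors = FALSE))
  }
  noise <- function(img) matrix(
    as.integer(pmin(65535, pmax(0, round(
      img + background + rnorm(length(img), 0, read_noise_sd))))),
    nrow(img), ncol(img))
  list(lyso = noise(lyso), ctsb = noise(ctsb), footprints = footprints,
       puncta_mask = puncta_mask, truth = truth,
       background = background)
}

#' Mid-plane slice index of a z-stack
#'
#' 0-based index `floor(n_slices / 2)`; a 50-slice stack has mid-plane
#' index 25.
#'
#' @param n_slices Number of slices (>= 3).
#' @return Integer 0-based index.
#' @export
midplane_index <- function(n_slices) {
  if (n_slices < 3) stop("need >= 3 slices", call. = FALSE)
  as.integer(floor(n_slices / 2))
}

#' Simulate a spheroid z-stack
#'
#' Renders a spherical cell mass as `n_slices` two-channel slices (nuclei,
#' cleaved caspase-3). Per-slice disk radius follows the sphere's
#' cross-section; a fixed fraction of mid-plane cells (chosen exactly, not
#' binomially) carries cleaved-caspase-3 footprint signal.
#'
#' @param n_slices Number of slices (default 50).
#' @param apoptotic_frac Fraction of mid-plane cells that are
#'   caspase-3-positive, in `[0, 1]`.
#' @param seed Integer seed.
#' @param n_cells_midplane Cells rendered at the mid-plane.
#' @param dim_px Slice edge length in px.
#' @param spheroid_radius_px Mid-plane spheroid radius in px.
#' @return List of class `spheroid_stack`: `slices` (each a list with
#'   `hoechst` and `casp3` matrices), `n_slices`, `center`, `radius_px`,
#'   `midplane` (0-based), and `truth` (mid-plane cell table with
#'   `apoptotic` flags plus the true apoptotic fraction).
#' @export
simulate_spheroid_stack <- function(n_slices = 50, apoptotic_frac = 0,
                                    seed = 1L, n_cells_midplane = 160,
                                    dim_px = 300L,
                                    spheroid_radius_px = 130) {
  if (apoptotic_frac < 0 || apoptotic_frac > 1)
    stop("'apoptotic_frac' must be in [0, 1]", call. = FALSE)
  mid <- midplane_index(n_slices)
  set.seed(seed)
  center <- c(dim_px / 2, dim_px / 2)
  nucleus_r <- 5
  min_sep <- 14
  slices <- vector("list", n_slices)
  truth <- NULL
  for (s in seq_len(n_slices)) {
    z <- (s - 1 - mid) / (n_slices / 2)          # -1..1 across the sphere
    r_s <- spheroid_radius_px * sqrt(max(0, 1 - z^2))
    n_s <- round(n_cells_midplane * (r_s / spheroid_radius_px)^2)
    hoechst <- matrix(0, dim_px, dim_px)
    casp3 <- matrix(0, dim_px, dim_px)
    if (n_s > 0) {
      pos <- matrix(NA_real_, n_s, 2)
      for (i in seq_len(n_s)) {
        prev <- pos[seq_len(i - 1), , drop = FALSE]
        prev <- prev[!is.na(prev[, 1]), , drop = FALSE]
        for (a in 1:400) {
          ang <- runif(1, 0, 2 * pi); rad <- sqrt(runif(1)) * (r_s - nucleus_r)
          pr <- center[1] + rad * sin(ang); pc <- center[2] + rad * cos(ang)
          ok <- nrow(prev) == 0 ||
            min((prev[, 1] - pr)^2 + (prev[, 2] - pc)^2) >= min_sep^2
          if (ok) { pos[i, ] <- c(pr, pc); break }
        }
      }
      keep <- !is.na(pos[, 1])
      pos <- pos[keep, , drop = FALSE]
      n_s <- nrow(pos)
      n_pos <- round(apoptotic_frac * n_s)
      apop <- rep(FALSE, n_s)
      if (n_pos > 0) apop[sample(n_s, n_pos)] <- TRUE
      for (i in seq_len(n_s)) {
        hoechst <- add_gaussian_blob(hoechst, pos[i, 1], pos[i, 2],
                                     sigma = nucleus_r / 1.5,
                                     amplitude = rlnorm(1, log(8000),
                                                        log(1.2)))
        if (apop[i])
          casp3 <- add_disk(casp3, pos[i, 1], pos[i, 2], nucleus_r + 1,
                            rlnorm(1, log(2500), log(1.2)))
      }
      if (s - 1 == mid)
        truth <- data.frame(row = pos[, 1], col = pos[, 2], apoptotic = apop)
    }
    to16 <- function(img) matrix(as.integer(pmin(65535, pmax(0, round(
      img + 50 + rnorm(length(img), 0, 2))))), dim_px, dim_px)
    slices[[s]] <- list(hoechst = to16(hoechst), casp3 = to16(casp3))
  }
  structure(list(slices = slices, n_slices = n_slices, center = center,
                 radius_px = spheroid_radius_px, midplane = mid,
                 truth = truth,
                 true_apoptotic_frac = if (is.null(truth)) NA_real_
                                       else mean(truth$apoptotic)),
            class = "spheroid_stack")
}
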