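test_that("puncta detection matches rendered ground truth", {
  # blank channel: zero everywhere
  org0 <- simulate_organelle_image("c", 20, vesicle_rate = 0, seed = 1)
  v0 <- detect_puncta(org0$lyso, org0$footprints)
  expect_true(all(v0$per_cell$puncta_count == 0))
  # non-overlapping rendered puncta are counted exactly
  ex <- simulate_organelle_image("c", 40, vesicle_rate = 3, seed = 9)
  ve <- detect_puncta(ex$lyso, ex$footprints)
  expect_equal(ve$per_cell$puncta_count, ex$truth$puncta_count)
  expect_error(detect_puncta(ex$lyso, NULL), "footprints")
  expect_error(detect_puncta(ex$lyso, ex$footprints[1:10, 1:10]), "shape")
})

test_that("treated/control puncta ratio recovers the Poisson rates", {
  tr <- simulate_organelle_image("treated", 220, vesicle_rate = 12,
                                 seed = 3)
  ct <- simulate_organelle_image("control", 220, vesicle_rate = 4,
                                 seed = 4)
  vt <- detect_puncta(tr$lyso, tr$footprints)
  vc <- detect_puncta(ct$lyso, ct$footprints)
  ratio <- mean(vt$per_cell$puncta_count) / mean(vc$per_cell$puncta_count)
  expect_equal(ratio, 3, tolerance = 0.1)
  # summaries carry n, mean, SD with SD matching the two-pass formula
  s <- vt$summary
  expect_equal(s$n, rep(220, 3))
  x <- vt$per_cell$puncta_count
  sd_twopass <- sqrt(sum((x - mean(x))^2) / (length(x) - 1))
  expect_equal(s$sd[s$statistic == "puncta_count"], sd_twopass)
})

test_that("puncta counts respond monotonically to the intensity floor", {
  org <- simulate_organelle_image("t", 60, vesicle_rate = 6, seed = 12)
  totals <- sapply(c(400, 200, 100, 50), function(fl)
    sum(detect_puncta(org$lyso, org$footprints,
                      intensity_floor = fl)$per_cell$puncta_count))
  expect_true(all(diff(totals) >= 0))
})

test_that("translocation index obeys its closed forms and bounds", {
  # constructed cell: footprint disk radius 10, puncta disk radius 3
  n <- 41
  rr <- seq_len(n)
  d2c <- outer((rr - 21)^2, (rr - 21)^2, "+")
  fp <- d2c <= 100
  pm <- d2c <= 9
  # all signal inside puncta -> index 0
  img <- matrix(0, n, n); img[pm] <- 500
  expect_equal(translocation_index(img, pm, fp), 0)
  # uniform signal -> 1 - puncta/footprint area ratio
  img2 <- matrix(0, n, n); img2[fp] <- 300
  expect_equal(translocation_index(img2, pm, fp),
               1 - sum(pm) / sum(fp))
  # scale invariance under positive rescaling
  img3 <- matrix(10, n, n); img3[fp] <- 300; img3[pm] <- 800
  i1 <- translocation_index(img3, pm, fp)
  i2 <- translocation_index(img3 * 4.2, pm, fp)
  expect_equal(i1, i2, tolerance = 1e-12)
  # bounds hold over random images carrying real footprint signal
  set.seed(8)
  for (k in 1:20) {
    imgr <- matrix(runif(n * n, 0, 1000), n, n)
    imgr[fp] <- imgr[fp] + 2000
    ti <- translocation_index(imgr, pm, fp)
    expect_gte(ti, 0); expect_lte(ti, 1)
  }
  # a signal-free cell is excluded with a warning
  expect_warning(res <- translocation_index(matrix(5, n, n), pm, fp),
                 "excluded")
  expect_true(is.na(res))
})

test_that("generator translocation fractions are recovered per cell", {
  org <- simulate_organelle_image("treated", 60, vesicle_rate = 8,
                                  translocated_frac = 0.7, seed = 3)
  idx <- sapply(1:60, function(i)
    translocation_index(org$ctsb, org$puncta_mask, org$footprints == i,
                        background = org$background))
  expect_equal(mean(idx, na.rm = TRUE), 0.7, tolerance = 0.05)
})

test_that("nuclear intensity statistics summarise channels per cell", {
  lab <- matrix(0L, 30, 30)
  lab[5:9, 5:9] <- 1L; lab[20:24, 20:24] <- 2L
  flat <- matrix(111, 30, 30)
  st <- nuclear_intensity_stats(flat, lab, condition = "c")
  expect_equal(st$per_cell$mean_intensity, c(111, 111))
  expect_equal(st$summary$n, 2)
  # empty label set gives an empty result
  st0 <- nuclear_intensity_stats(flat, matrix(0L, 30, 30))
  expect_equal(nrow(st0$per_cell), 0)
  # a 2x intensity shift between conditions is recovered
  a <- nuclear_intensity_stats(flat, lab)
  b <- nuclear_intensity_stats(flat * 2, lab)
  expect_equal(b$summary$mean / a$summary$mean, 2, tolerance = 0.05)
})

test_that("positive-cell fraction recovers a 40% labelled subset", {
  set.seed(19)
  n_cells <- 100
  lab <- matrix(0L, 220, 220)
  img <- matrix(0, 220, 220)
  pos <- rep(c(TRUE, FALSE), c(40, 60))[sample(n_cells)]
  k <- 0
  for (gr in 0:9) for (gc in 0:9) {
    k <- k + 1
    r0 <- gr * 22 + 6; c0 <- gc * 22 + 6
    lab[r0:(r0 + 8), c0:(c0 + 8)] <- k
    img[r0:(r0 + 8), c0:(c0 + 8)] <-
      if (pos[k]) rnorm(81, 3000, 100) else rnorm(81, 150, 30)
  }
  st <- nuclear_intensity_stats(img, lab, positive_fraction = TRUE)
  expect_equal(st$positive_fraction, 0.40, tolerance = 0.03)
  # a signal-free channel yields zero positives
  st0 <- nuclear_intensity_stats(matrix(rnorm(220^2, 150, 30), 220, 220),
                                 lab, positive_fraction = TRUE)
  expect_equal(st0$positive_fraction, 0)
})

test_that("caspase activation folds and tests behave", {
  expect_equal(caspase_fold_activation(c(5, 5, 5), c(5, 5, 5))$fold, 1)
  r <- caspase_fold_activation(c(10, 10, 10), c(5, 5, 5))
  expect_equal(r$fold, 2)
  # normalisation rescales readings per lysate
  rn <- caspase_fold_activation(c(20, 20, 20), c(5, 5, 5),
                                treated_norm = rep(2, 3))
  expect_equal(rn$fold, 2)
  expect_error(caspase_fold_activation(c(1, 2), c(1, 2, 3)), ">= 3")
  expect_error(caspase_fold_activation(c(1, 2, 3), c(0, 0, 0)), "positive")
  # sampled arms at true fold 2.5, CV 10%
  set.seed(4)
  tr <- rnorm(3, 250, 25); ct <- rnorm(3, 100, 10)
  rf <- caspase_fold_activation(tr, ct)
  expect_equal(rf$fold, 2.5, tolerance = 0.4 / 2.5)
})

test_that("spheroid mid-plane apoptosis fractions are recovered", {
  st0 <- simulate_spheroid_stack(n_slices = 9, apoptotic_frac = 0,
                                 seed = 5, n_cells_midplane = 150)
  expect_equal(analyze_spheroid_midplane(st0)$apoptotic_fraction, 0)
  st1 <- simulate_spheroid_stack(n_slices = 9, apoptotic_frac = 1,
                                 seed = 6, n_cells_midplane = 150)
  expect_equal(analyze_spheroid_midplane(st1)$apoptotic_fraction, 1)
  st6 <- simulate_spheroid_stack(n_slices = 9, apoptotic_frac = 0.6,
                                 seed = 7, n_cells_midplane = 170)
  sp <- analyze_spheroid_midplane(st6)
  expect_gte(sp$n_cells, 150)
  expect_equal(sp$apoptotic_fraction, 0.6, tolerance = 0.05)
  expect_equal(sp$midplane, 4L)
})
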