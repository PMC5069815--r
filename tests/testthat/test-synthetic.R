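pyri_model <- function()
  drug_effect_model("pyrimethamine_like", list(
    huh7 = list(top = 100, bottom = 0, ic50 = 2.764e-6, hill = 1),
    fa2n4 = list(top = 100, bottom = 0, ic50 = 2.343e-5, hill = 1)))

test_that("four-parameter logistic evaluates its anchor points", {
  expect_equal(viability_4pl(0, 100, 0, 1e-6, 1), 100)
  expect_equal(viability_4pl(1e-6, 100, 0, 1e-6, 2.7), 50)   # midpoint
  # asymptote: a million-fold excess of the IC50 reaches the bottom
  expect_lt(viability_4pl(1e6 * 2.764e-6, 100, 0, 2.764e-6, 2), 1e-6)
  expect_lt(viability_4pl(1e6 * 2.764e-6, 100, 0, 2.764e-6, 1), 2e-4)
  # hand-computed value at 1 uM with IC50 2.764 uM, hill 1
  expect_equal(viability_4pl(1e-6, 100, 0, 2.764e-6, 1),
               0 + 100 / (1 + 1 / 2.764))
})

test_that("noise-free viability is monotone non-increasing in dose", {
  set.seed(5)
  for (i in 1:25) {
    top <- runif(1, 80, 120)
    bottom <- runif(1, 0, top)
    v <- viability_4pl(10^seq(-12, -4, length.out = 30), top, bottom,
                       10^runif(1, -9, -5), runif(1, 0.3, 4))
    expect_true(all(diff(v) <= 1e-12))
  }
})

test_that("dose-response tables reproduce the curve exactly at zero noise", {
  tab <- simulate_dose_response_table(pyri_model(), "huh7", replicates = 2,
                                      noise_sd = 0)
  expect_named(tab, c("compound", "dose_M", "replicate", "viability_pct"))
  expect_equal(nrow(tab), 20)
  expect_equal(tab$viability_pct[tab$dose_M == 0], c(100, 100))
  expect_equal(tab$viability_pct[tab$dose_M == 1e-6][1],
               100 / (1 + 1 / 2.764))
  # highest ladder dose is ~36x the IC50
  expect_equal(tab$viability_pct[tab$dose_M == 1e-4][1],
               viability_4pl(1e-4, 100, 0, 2.764e-6, 1))
})

test_that("dose-response tables reject malformed ladders", {
  m <- pyri_model()
  expect_error(simulate_dose_response_table(m, "huh7",
                                            doses = c(1e-9, 1e-8, 1e-7,
                                                      1e-6, 1e-5)),
               "zero-dose")
  expect_error(simulate_dose_response_table(m, "huh7",
                                            doses = c(0, 1e-8, 1e-8, 1e-7,
                                                      1e-6)),
               "strictly increasing")
  expect_error(simulate_dose_response_table(m, "huh7",
                                            doses = c(0, 1e-8, 1e-7, 1e-6)),
               "4 distinct")
  expect_error(simulate_dose_response_table(m, "hepg2"), "no effect model")
})

test_that("resazurin signal is linear in viable count", {
  expect_equal(simulate_resazurin(0, 0.02, 7), 7)
  expect_equal(simulate_resazurin(1000, 0.01, 5), 15)
  n <- 1234
  expect_equal(simulate_resazurin(2 * n, 0.01, 5) -
                 simulate_resazurin(n, 0.01, 5), 0.01 * n)
  expect_error(simulate_resazurin(10, 0, 5), "gain")
})

test_that("well simulation honours the survival model", {
  lay <- plate_layout_384("pyrimethamine_like")
  pops <- default_populations()
  lib <- default_drug_library()
  # DMSO well: expected survival is 1 - baseline death, both populations
  neg <- lay[lay$role == "negative_control", ][1, ]
  s <- simulate_well(neg, pops, lib, seed = 1, render = FALSE)
  expect_equal(s$truth$counts$expected_survival, c(0.97, 0.97))
  # dose at the HCC-side IC50 (top 100, bottom 0): 50 % survival of baseline
  entry <- lay[lay$role == "test", ][1, ]
  entry$dose_M <- 2.764e-6
  s2 <- simulate_well(entry, pops, lib, seed = 1, render = FALSE)
  huh <- s2$truth$counts[s2$truth$counts$population == "huh7", ]
  expect_equal(huh$expected_survival, 0.97 * 0.5)
  # selective compound at 10 uM: HCC survival far below hepatocyte survival
  entry$dose_M <- 1e-5
  s3 <- simulate_well(entry, pops, lib, seed = 1, render = FALSE)
  cs <- s3$truth$counts
  expect_lt(cs$expected_survival[cs$population == "huh7"],
            0.25 * cs$expected_survival[cs$population == "fa2n4"])
})

test_that("rendered wells are seeded-deterministic and truth-consistent", {
  lay <- plate_layout_384("pyrimethamine_like")
  entry <- lay[lay$role == "negative_control", ][1, ]
  a <- simulate_well(entry, default_populations(), default_drug_library(),
                     seed = 3)
  b <- simulate_well(entry, default_populations(), default_drug_library(),
                     seed = 3)
  expect_identical(a$fields, b$fields)
  expect_identical(a$truth, b$truth)
  # rendered nuclei per field match the truth table rows
  for (f in 1:4) {
    lab <- detect_nuclei(a$fields[[f]]$hoechst)
    expect_equal(max(lab), sum(a$truth$cells$field == f), tolerance = 0.02)
  }
  expect_equal(nrow(a$truth$cells),
               sum(a$truth$counts$rendered))
})

test_that("overfull fields fail with a capacity error", {
  expect_error(
    hcscreen:::place_cells(5000, 512, 512, 15, 13, 50L),
    "field too small")
})

test_that("organelle images carry exact per-cell puncta ground truth", {
  org <- simulate_organelle_image("control", n_cells = 25,
                                  vesicle_rate = 0, seed = 2)
  expect_true(all(org$truth$puncta_count == 0))
  expect_false(any(org$puncta_mask))
  # translocated_frac 0 keeps all cathepsin-B signal inside puncta masks
  org2 <- simulate_organelle_image("control", n_cells = 25,
                                   vesicle_rate = 5,
                                   translocated_frac = 0, seed = 2)
  bg <- org2$background
  inside <- sum(org2$ctsb[org2$puncta_mask] - bg)
  total <- sum(org2$ctsb[org2$footprints > 0] - bg)
  expect_equal(inside / total, 1, tolerance = 0.02)
  # Poisson rate ratio ~3 between treated and control arms
  tr <- simulate_organelle_image("treated", 220, vesicle_rate = 12,
                                 seed = 3)
  ct <- simulate_organelle_image("control", 220, vesicle_rate = 4,
                                 seed = 4)
  expect_equal(mean(tr$truth$puncta_count) / mean(ct$truth$puncta_count),
               3, tolerance = 0.1)
})

test_that("spheroid stacks place the mid-plane and its truth correctly", {
  expect_equal(midplane_index(50), 25L)
  expect_equal(midplane_index(3), 1L)
  expect_error(midplane_index(2), ">= 3")
  st <- simulate_spheroid_stack(n_slices = 5, apoptotic_frac = 0.5,
                                seed = 8, n_cells_midplane = 60)
  expect_s3_class(st, "spheroid_stack")
  expect_length(st$slices, 5)
  expect_equal(st$midplane, 2L)
  expect_equal(st$true_apoptotic_frac, 0.5, tolerance = 0.02)
  expect_error(simulate_spheroid_stack(apoptotic_frac = 1.2), "\\[0, 1\\]")
})
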