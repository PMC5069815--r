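test_that("degenerate images give zero nuclei, bad input errors", {
  expect_equal(max(detect_nuclei(matrix(0L, 64, 64))), 0)
  expect_equal(max(detect_nuclei(matrix(500L, 64, 64))), 0)
  expect_error(detect_nuclei(array(0, c(4, 4, 2))), "2-D")
  expect_error(detect_nuclei(1:10), "2-D")
})

test_that("detection recovers non-overlapping nuclei within 1 percent", {
  for (seed in c(2, 5)) {
    fx <- render_mixed_field(120, 0.35, seed)
    lab <- detect_nuclei(fx$images$hoechst)
    expect_lte(abs(max(lab) - 120), 0.01 * 120 + 1e-9)
    m <- measure_markers(lab, fx$images["chalv1"])
    mt <- match_to_truth(m, fx$truth, max_dist = 2)
    expect_gte(length(mt$matched) / 120, 0.99)
  }
})

test_that("detection error stays within 1 percent up to 300 cells/field", {
  fx <- render_mixed_field(300, 0.35, 13)
  lab <- detect_nuclei(fx$images$hoechst)
  expect_lte(abs(max(lab) - 300) / 300, 0.01)
})

test_that("watershed splits two disks overlapping by 30% of a radius", {
  expect_equal(max(detect_nuclei(disk_pair_image(10.2))), 2)
  expect_equal(max(detect_nuclei(disk_pair_image(20))), 2)
  # a fully merged pair stays one object
  expect_equal(max(detect_nuclei(disk_pair_image(1))), 1)
})

test_that("marker measurement is exact on uniform channels", {
  fx <- render_mixed_field(40, 0.5, 3)
  lab <- detect_nuclei(fx$images$hoechst)
  v <- matrix(777, nrow(lab), ncol(lab))
  m <- measure_markers(lab, list(flat = v))
  expect_equal(m$nucleus_mean_flat, rep(777, nrow(m)))
  expect_equal(m$ring_mean_flat, rep(777, nrow(m)))
  expect_error(measure_markers(lab, list(bad = matrix(0, 3, 3))), "shape")
  # zero labels give an empty, fully-formed table
  e <- measure_markers(matrix(0L, 8, 8), list(c1 = matrix(0, 8, 8)))
  expect_equal(nrow(e), 0)
  expect_true(all(c("cell_id", "nucleus_mean_c1", "ring_mean_c1") %in%
                    names(e)))
})

test_that("single-cell ring mean recovers the rendered marker intensity", {
  optics <- default_optics()
  optics$width <- optics$height <- 64L
  optics$read_noise_sd <- 0
  cells <- data.frame(population = "huh7", radius_px = 6,
                      true_hoechst = 8000, true_chalv1 = 1500,
                      row = 32, col = 32)
  imgs <- render_field(cells, c("hoechst", "chalv1"), optics)
  lab <- detect_nuclei(imgs$hoechst)
  m <- measure_markers(lab, imgs["chalv1"])
  expect_equal(nrow(m), 1)
  # ring mean = intensity + background (100), within rounding
  expect_equal(m$ring_mean_chalv1, 1600, tolerance = 1e-3)
  expect_equal(m$centroid_row, 31, tolerance = 0.5)  # 0-based centre
})

test_that("measurement conserves nucleus-mask totals", {
  fx <- render_mixed_field(80, 0.4, 9)
  lab <- detect_nuclei(fx$images$hoechst)
  m <- measure_markers(lab, fx$images["afp"])
  lhs <- sum(m$nucleus_mean_afp * m$nucleus_area_px)
  rhs <- sum(fx$images$afp[lab > 0])
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("control-derived thresholds split a bimodal marker correctly", {
  # brute-force oracle: exhaustive Otsu on the pooled log-intensity vector
  set.seed(21)
  lo <- rlnorm(400, log(100), log(1.3))
  hi <- rlnorm(400, log(1000), log(1.3))
  feats <- data.frame(ring_mean_chalv1 = c(lo, hi),
                      ring_mean_afp = c(lo, hi))
  th <- derive_thresholds_from_controls(feats)
  expect_gt(th$cutoffs[["chalv1"]], 100)
  expect_lt(th$cutoffs[["chalv1"]], 1000)
  expect_equal(unname(th$method["chalv1"]), "otsu_on_controls")
  # scale equivariance: scaling intensities by 10 scales cutoffs by 10
  feats10 <- feats * 10
  th10 <- derive_thresholds_from_controls(feats10)
  expect_equal(th10$cutoffs[["afp"]] / th$cutoffs[["afp"]], 10,
               tolerance = 0.02)
})

test_that("unimodal controls trigger the fixed fallback", {
  set.seed(22)
  x <- rlnorm(300, log(500), log(1.3))
  feats <- data.frame(ring_mean_chalv1 = x, ring_mean_afp = x)
  th <- derive_thresholds_from_controls(feats,
                                        fixed = c(chalv1 = 450, afp = 350))
  expect_equal(unname(th$method), c("fixed", "fixed"))
  expect_equal(unname(th$cutoffs), c(450, 350))
  expect_error(derive_thresholds_from_controls(feats), "unimodal")
  expect_error(derive_thresholds_from_controls(feats[1:30, ]), ">= 50")
})

test_that("two-marker rule classifies cells and counts each class", {
  th <- fixed_thresholds(chalv1 = 500, afp = 400)
  feats <- data.frame(ring_mean_chalv1 = c(900, 100, 900, 100),
                      ring_mean_afp = c(800, 90, 90, 800))
  cl <- classify_cells(feats, th)
  expect_equal(cl$features$class,
               c("HCC", "HEPATOCYTE", "AMBIGUOUS", "AMBIGUOUS"))
  expect_equal(unname(cl$counts),
               c(1L, 1L, 2L))
  expect_equal(sum(cl$fractions), 1)
  expect_error(classify_cells(feats[, 1, drop = FALSE], th), "missing")
})

test_that("a 65:35 co-culture well recovers its composition", {
  fx1 <- render_mixed_field(150, 0.35, 31)
  fx2 <- render_mixed_field(150, 0.35, 32)
  feats <- rbind(measure_well(list(fields = list(fx1$images))),
                 measure_well(list(fields = list(fx2$images))))
  th <- derive_thresholds_from_controls(feats)
  cl <- classify_cells(feats, th)
  expect_equal(unname(cl$fractions["HCC"]), 0.35, tolerance = 0.03)
  expect_lt(unname(cl$fractions["AMBIGUOUS"]), 0.02)
})

test_that("classification accuracy exceeds 98% at 10x marker separation", {
  correct <- 0; total <- 0
  for (seed in c(41, 42)) {
    fx <- render_mixed_field(200, 0.35, seed)
    lab <- detect_nuclei(fx$images$hoechst)
    m <- measure_markers(lab, fx$images[c("chalv1", "afp")])
    th <- derive_thresholds_from_controls(m)
    cl <- classify_cells(m, th)
    mt <- match_to_truth(cl$features, fx$truth)
    correct <- correct + sum(cl$features$class[mt$matched] == mt$true_class)
    total <- total + length(mt$matched)
  }
  expect_gte(correct / total, 0.98)
})

test_that("classification is invariant under common intensity rescaling", {
  fx <- render_mixed_field(150, 0.35, 51)
  lab <- detect_nuclei(fx$images$hoechst)
  m <- measure_markers(lab, fx$images[c("chalv1", "afp")])
  cl1 <- classify_cells(m, derive_thresholds_from_controls(m))
  k <- 7.5
  ms <- m
  ms$ring_mean_chalv1 <- ms$ring_mean_chalv1 * k
  ms$ring_mean_afp <- ms$ring_mean_afp * k
  cl2 <- classify_cells(ms, derive_thresholds_from_controls(ms))
  expect_gte(mean(cl1$features$class == cl2$features$class), 0.99)
})

test_that("cell-count QC uses a strict >100 rule", {
  f101 <- data.frame(cell_id = 1:101)
  f100 <- data.frame(cell_id = 1:100)
  expect_true(qc_well(f101)$pass)
  expect_false(qc_well(f100)$pass)
  expect_false(qc_well(f100[0, , drop = FALSE])$pass)
  expect_match(qc_well(f100)$reason, "100")
})
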