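test_that("blank stroma yields zero detections", {
  sc <- generate_slide(scene_params(seed = 41, n_tumor_nests = 0L,
                                    target_tsr_percent = 99,
                                    stromal_cell_density_per_mm2 = 0))
  det <- detect_stromal_cells(sc$slide, segmentation_from_truth(sc$ground_truth))
  expect_identical(det$n_cells, 0L)
})

test_that("zero stroma area is a QC error", {
  sc <- default_scene()
  seg <- segmentation_from_truth(sc$ground_truth)
  seg$stroma_area_mm2 <- 0
  expect_error(detect_stromal_cells(sc$slide, seg), "QC")
})

test_that("detection recovers the seeded count within 10 percent", {
  for (seed in c(42, 43)) {
    sc <- generate_slide(scene_params(seed = seed))
    det <- detect_stromal_cells(sc$slide,
                                segmentation_from_truth(sc$ground_truth))
    truth <- nrow(sc$ground_truth$nuclei_centers)
    expect_lte(abs(det$n_cells - truth) / truth, 0.10)
  }
})

test_that("epithelial-nest infiltration barely moves the stromal count", {
  base <- scene_params(seed = 44)
  on <- scene_params(seed = 44, epithelial_nest_infiltration = TRUE)
  sc0 <- generate_slide(base); sc1 <- generate_slide(on)
  d0 <- detect_stromal_cells(sc0$slide, segmentation_from_truth(sc0$ground_truth))
  d1 <- detect_stromal_cells(sc1$slide, segmentation_from_truth(sc1$ground_truth))
  expect_lt(abs(d1$n_cells - d0$n_cells) / d0$n_cells, 0.05)
})

test_that("nest exclusion removes exactly the constructed nest members", {
  # fixture: sparse singles plus one packed nest of known extent
  n <- 200L
  img <- array(255L, c(n, n, 3L))
  sl0 <- new_slide(img, mpp = 1)
  params <- detection_params()
  # paint 12 isolated nuclei and one 20-nucleus packed nest by hand
  dark <- c(62L, 52L, 120L)
  set.seed(5)
  singles <- cbind(sample(20:180, 12), sample(20:80, 12))
  for (i in 1:12) {
    img <- smequant:::paint_ellipse(img, singles[i, 1], singles[i, 2],
                                    3.5, 3.2, 0, dark)
  }
  ctr <- c(100, 150)
  for (j in 1:20) {
    img <- smequant:::paint_ellipse(img, ctr[1] + rnorm(1, 0, 5),
                                    ctr[2] + rnorm(1, 0, 5), 3.5, 3.2, 0, dark)
  }
  sl <- new_slide(img, mpp = 1)
  od <- optical_density_map(sl, params)
  fg <- od >= params$min_optical_density
  lab <- smequant:::label_regions(fg)
  nest_area <- max(tabulate(lab[lab > 0]))
  expect_gt(nest_area, params$nest_area_threshold_um2)  # nest really is big
  candidates <- tibble::tibble(row = c(singles[, 1], ctr[1]),
                               col = c(singles[, 2], ctr[2]))
  kept <- exclude_epithelial_nests(candidates, od, params, mpp = 1)
  expect_identical(nrow(kept), 12L)
  expect_true(all(kept$row %in% singles[, 1]))
  # disabled filter: identity
  off <- detection_params(nest_area_threshold_um2 = Inf)
  expect_identical(exclude_epithelial_nests(candidates, od, off, mpp = 1),
                   candidates)
  # nothing over threshold: identity
  tiny <- candidates[1:3, ]
  od_tiny <- od; od_tiny[lab == lab[ctr[1], ctr[2]]] <- 0
  expect_identical(exclude_epithelial_nests(tiny, od_tiny, params, mpp = 1),
                   tiny)
})

test_that("detections never leave the stroma mask", {
  sc <- generate_slide(scene_params(seed = 45))
  seg <- segmentation_from_truth(sc$ground_truth)
  det <- detect_stromal_cells(sc$slide, seg)
  labs <- seg$label_raster[cbind(det$cells$row, det$cells$col)]
  expect_true(all(labs == 2L))
})

test_that("gating is monotone in the OD floor and the minimum area", {
  # isolated hand-placed nuclei: with no touching pairs the OD floor
  # cannot re-partition the foreground, so counts are monotone in every gate
  n <- 120L
  img <- array(255L, c(n, n, 3L))
  pos <- expand.grid(row = c(20, 50, 80, 105), col = c(20, 50, 80, 105))
  for (i in seq_len(nrow(pos))) {
    img <- smequant:::paint_ellipse(img, pos$row[i], pos$col[i],
                                    3.8, 3.2, i / 5, c(62L, 52L, 120L))
  }
  sl <- new_slide(img, mpp = 1, slide_id = "isolated")
  seg <- structure(list(slide_id = "isolated",
                        label_raster = matrix(2L, n, n),
                        tumor_area_mm2 = 0,
                        stroma_area_mm2 = px_to_mm2(n * n, 1),
                        tissue_area_mm2 = px_to_mm2(n * n, 1),
                        mpp = 1, stride_px = 1L),
                   class = "tissue_segmentation")
  base <- detect_stromal_cells(sl, seg)
  expect_identical(base$n_cells, nrow(pos))
  sc <- list(slide = sl)
  prev <- base$n_cells
  for (od in c(0.7, 0.8, 2.5)) {
    n <- detect_stromal_cells(sc$slide, seg,
                              detection_params(min_optical_density = od))$n_cells
    expect_lte(n, prev)
    prev <- n
  }
  prev <- base$n_cells
  for (amin in c(25, 40, 119)) {
    n <- detect_stromal_cells(
      sc$slide, seg, detection_params(min_nuclear_area_um2 = amin))$n_cells
    expect_lte(n, prev)
    prev <- n
  }
  # dense scene: the area gate stays monotone even when nuclei touch
  sc2 <- generate_slide(scene_params(seed = 46))
  seg2 <- segmentation_from_truth(sc2$ground_truth)
  b2 <- detect_stromal_cells(sc2$slide, seg2)
  n2 <- detect_stromal_cells(
    sc2$slide, seg2, detection_params(min_nuclear_area_um2 = 40))$n_cells
  expect_lte(n2, b2$n_cells)
})

test_that("detection is deterministic", {
  sc <- generate_slide(scene_params(seed = 47))
  seg <- segmentation_from_truth(sc$ground_truth)
  d1 <- detect_stromal_cells(sc$slide, seg)
  d2 <- detect_stromal_cells(sc$slide, seg)
  expect_identical(d1$cells, d2$cells)
})

test_that("region counts partition the slide", {
  sc <- generate_slide(scene_params(height_px = 512L, width_px = 512L,
                                    background_margin_px = 6L, seed = 48))
  det <- detect_stromal_cells(sc$slide, segmentation_from_truth(sc$ground_truth))
  # 4 disjoint half-open 250-um tiles cover [1, 501) x [1, 501)
  tiles <- expand.grid(r = c(1, 251), c = c(1, 251))
  total <- sum(mapply(function(r, c) count_in_region(det, r, c, side_um = 250),
                      tiles$r, tiles$c))
  inside <- sum(det$cells$row >= 1 & det$cells$row < 501 &
                  det$cells$col >= 1 & det$cells$col < 501)
  expect_identical(total, inside)
  expect_error(count_in_region(det, 400, 400, side_um = 500), "outside")
})

test_that("a counting region in uniform stroma matches the Poisson oracle", {
  d <- 2500
  sc <- generate_slide(scene_params(height_px = 512L, width_px = 512L,
                                    n_tumor_nests = 0L, target_tsr_percent = 99,
                                    stromal_cell_density_per_mm2 = d,
                                    background_margin_px = 6L, seed = 49))
  gt <- sc$ground_truth
  # count ground-truth centers in a 500 x 500 um region
  r0 <- 7; c0 <- 7; side <- 500
  n <- sum(gt$nuclei_centers$row >= r0 & gt$nuclei_centers$row < r0 + side &
             gt$nuclei_centers$col >= c0 & gt$nuclei_centers$col < c0 + side)
  lambda <- d * 0.25
  expect_lte(abs(n - lambda), 3 * sqrt(lambda))
})

test_that("count concordance behaves as a correlation must", {
  x <- c(10, 25, 40, 55)
  expect_equal(concordance_vs_reference(x, x)$r, 1.0)
  expect_equal(concordance_vs_reference(x, -x)$r, -1.0)
  expect_warning(res <- concordance_vs_reference(x, rep(3, 4)), "variance")
  expect_true(is.na(res$r))
})

test_that("automated counts track seeded truth across densities", {
  densities <- seq(800, 3200, length.out = 8)
  auto <- truth <- numeric(8)
  for (i in seq_along(densities)) {
    sc <- generate_slide(scene_params(
      height_px = 256L, width_px = 256L, seed = 800 + i,
      stromal_cell_density_per_mm2 = densities[i]))
    det <- detect_stromal_cells(sc$slide,
                                segmentation_from_truth(sc$ground_truth))
    auto[i] <- det$n_cells
    truth[i] <- nrow(sc$ground_truth$nuclei_centers)
  }
  expect_gte(concordance_vs_reference(auto, truth)$r, 0.9)
})
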