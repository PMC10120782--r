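test_that("zero seeded density yields a slide without nuclei", {
  sc <- generate_slide(scene_params(seed = 11,
                                    stromal_cell_density_per_mm2 = 0))
  expect_identical(nrow(sc$ground_truth$nuclei_centers), 0L)
  expect_equal(sc$ground_truth$true_density_cells_per_mm2, 0)
})

test_that("a near-all-stroma scene realizes TSR within the stated tolerance", {
  sc <- generate_slide(scene_params(seed = 12, target_tsr_percent = 99,
                                    n_tumor_nests = 1L,
                                    nest_radius_um = c(15, 2)))
  expect_gte(sc$ground_truth$true_tsr_percent, 94)
})

test_that("realized TSR tracks the target across the dial", {
  for (target in c(40, 60, 85)) {
    sc <- generate_slide(scene_params(seed = 13, target_tsr_percent = target))
    expect_lte(abs(sc$ground_truth$true_tsr_percent - target), 5)
  }
})

test_that("seeded nuclei counts follow the Poisson point-process oracle", {
  p <- scene_params(height_px = 1024L, width_px = 1024L, mpp = 1.0,
                    stromal_cell_density_per_mm2 = 2500, seed = 14)
  sc <- generate_slide(p)
  gt <- sc$ground_truth
  lambda <- 2500 * gt$stroma_area_mm2   # Poisson mean from realized stroma
  n <- nrow(gt$nuclei_centers)
  expect_lte(abs(n - lambda), 3 * sqrt(lambda))
})

test_that("nuclei counts are unbiased for density x stroma area over seeds", {
  density <- 2000
  counts <- lambda <- numeric(20)
  for (i in 1:20) {
    sc <- generate_slide(scene_params(
      height_px = 256L, width_px = 256L, seed = 300 + i,
      stromal_cell_density_per_mm2 = density))
    counts[i] <- nrow(sc$ground_truth$nuclei_centers)
    lambda[i] <- density * sc$ground_truth$stroma_area_mm2
  }
  se <- sd(counts - lambda) / sqrt(20)
  expect_lte(abs(mean(counts - lambda)), 2 * se + 1e-9)
})

test_that("generation is bit-reproducible for a fixed seed", {
  a <- generate_slide(scene_params(seed = 15))
  b <- generate_slide(scene_params(seed = 15))
  expect_identical(a$slide$image, b$slide$image)
  expect_identical(a$ground_truth$tissue_mask, b$ground_truth$tissue_mask)
  expect_identical(a$ground_truth$nuclei_centers, b$ground_truth$nuclei_centers)
})

test_that("stored ground-truth TSR equals the mask-derived value exactly", {
  sc <- default_scene()
  gt <- sc$ground_truth
  mask_tsr <- 100 * sum(gt$tissue_mask == 2) /
    (sum(gt$tissue_mask == 2) + sum(gt$tissue_mask == 1))
  expect_identical(gt$true_tsr_percent, mask_tsr)
  expect_equal(compute_tsr(gt), gt$true_tsr_percent)
})

test_that("every seeded nucleus center lies on a stroma pixel", {
  sc <- default_scene()
  gt <- sc$ground_truth
  labs <- gt$tissue_mask[cbind(gt$nuclei_centers$row, gt$nuclei_centers$col)]
  expect_true(all(labs == 2))
})

test_that("degenerate geometry is an explicit error", {
  expect_error(
    generate_slide(scene_params(seed = 16, n_tumor_nests = 0L,
                                target_tsr_percent = 50)),
    "degenerate geometry")
})

test_that("annotation sampling honors counts, labels and interiority", {
  sc <- default_scene()
  ann <- sample_annotation_points(sc$ground_truth, n_tumor = 94L,
                                  n_stroma = 67L, seed = 21)
  expect_identical(nrow(ann), 161L)
  expect_identical(sum(ann$class == "tumor"), 94L)
  expect_identical(sum(ann$class == "stroma"), 67L)
  # labels in the mask match the annotated class
  codes <- c(tumor = 1L, stroma = 2L)
  mask_lab <- sc$ground_truth$tissue_mask[cbind(ann$row, ann$col)]
  expect_true(all(mask_lab == codes[ann$class]))
  # interior: the 8-neighborhood of each point keeps its class
  for (dr in -1:1) for (dc in -1:1) {
    lab <- sc$ground_truth$tissue_mask[cbind(ann$row + dr, ann$col + dc)]
    expect_true(all(lab == codes[ann$class]))
  }
})

test_that("single-class annotation requests work and absent classes error", {
  sc <- default_scene()
  ann <- sample_annotation_points(sc$ground_truth, n_tumor = 0L,
                                  n_stroma = 5L, seed = 22)
  expect_identical(nrow(ann), 5L)
  expect_true(all(ann$class == "stroma"))
  all_stroma <- generate_slide(scene_params(seed = 23, n_tumor_nests = 0L,
                                            target_tsr_percent = 99))
  expect_error(
    sample_annotation_points(all_stroma$ground_truth, n_tumor = 5L,
                             n_stroma = 5L),
    "tumor")
})
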