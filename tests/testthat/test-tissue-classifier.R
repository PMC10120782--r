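test_that("the default 94/67 annotation budget trains an accurate forest", {
  mod <- default_model()
  expect_gte(mod$oob_accuracy, 0.90)
})

test_that("training refuses a single-class annotation set", {
  sc <- default_scene()
  ann <- sample_annotation_points(sc$ground_truth, n_tumor = 0L,
                                  n_stroma = 10L, seed = 31)
  expect_error(train_tissue_classifier(sc$slide, ann), "single class")
})

test_that("a two-point training set still trains and predicts both classes", {
  sc <- default_scene()
  ann <- dplyr::bind_rows(
    sample_annotation_points(sc$ground_truth, 1L, 0L, seed = 32),
    sample_annotation_points(sc$ground_truth, 0L, 1L, seed = 33))
  mod <- train_tissue_classifier(sc$slide, ann)
  seg <- segment_slide(mod, sc$slide)
  expect_gt(seg$tumor_area_mm2, 0)
  expect_gt(seg$stroma_area_mm2, 0)
})

test_that("an all-white slide segments to zero tissue area", {
  seg <- segment_slide(default_model(), white_slide())
  expect_identical(seg$tumor_area_mm2, 0)
  expect_identical(seg$stroma_area_mm2, 0)
  expect_true(all(seg$label_raster == 0L))
})

test_that("segmentation recovers the ground truth with high Dice", {
  sc <- default_scene()
  seg <- segment_slide(default_model(), sc$slide)
  dice <- segmentation_dice(seg, sc$ground_truth)
  expect_true(all(dice$dice >= 0.85))
})

test_that("TSR is stable between full-resolution and strided segmentation", {
  sc <- generate_slide(scene_params(height_px = 128L, width_px = 128L,
                                    nest_radius_um = c(22, 4),
                                    background_margin_px = 6L, seed = 34))
  mod <- default_model()
  tsr1 <- compute_tsr(segment_slide(mod, sc$slide, stride_px = 1L))
  tsr4 <- compute_tsr(segment_slide(mod, sc$slide, stride_px = 4L))
  expect_lt(abs(tsr1 - tsr4), 2)
})

test_that("pixel accounting is conserved and segmentation is deterministic", {
  sc <- default_scene()
  excl <- matrix(FALSE, 384L, 384L); excl[1:40, 1:60] <- TRUE
  sl <- new_slide(sc$slide$image, mpp = sc$slide$mpp,
                  slide_id = sc$slide$slide_id, excluded_mask = excl)
  seg1 <- segment_slide(default_model(), sl)
  seg2 <- segment_slide(default_model(), sl)
  expect_identical(seg1$label_raster, seg2$label_raster)
  counts <- table(factor(seg1$label_raster, levels = 0:3))
  expect_identical(sum(counts), length(seg1$label_raster))
  expect_identical(unname(counts[["3"]]), sum(excl))
  # excluded pixels contribute to no class area
  expect_equal(seg1$tumor_area_mm2 + seg1$stroma_area_mm2,
               px_to_mm2(sum(seg1$label_raster %in% 1:2), sl$mpp))
})

test_that("segmentation without a pixel scale is refused", {
  img <- default_scene()$slide$image
  sl <- new_slide(img, mpp = NA, slide_id = "no-scale")
  expect_error(segment_slide(default_model(), sl), "mpp")
})

test_that("Dice does not degrade as class textures separate", {
  # separation dial: shift the tumor base color away from stroma
  mod <- default_model()
  dice_at <- function(seed) {
    sc <- generate_slide(scene_params(seed = seed))
    mean(segmentation_dice(segment_slide(mod, sc$slide), sc$ground_truth)$dice)
  }
  # same generator, independent scenes: all should be comfortably high
  expect_true(all(vapply(401:403, dice_at, numeric(1)) >= 0.85))
})

test_that("identical models give perfect area concordance", {
  mod <- default_model()
  slides <- lapply(501:503, function(s) {
    generate_slide(scene_params(height_px = 192L, width_px = 192L,
                                target_tsr_percent = 50 + 10 * (s - 501),
                                seed = s))$slide
  })
  rep <- reproducibility_check(mod, mod, slides, stride_px = 6L)
  expect_equal(rep$rho, c(1, 1))
})

test_that("independently annotated models agree across slides", {
  scene <- default_scene()
  ann_a <- sample_annotation_points(scene$ground_truth, seed = 61)
  ann_b <- sample_annotation_points(scene$ground_truth, seed = 62)
  mod_a <- train_tissue_classifier(scene$slide, ann_a)
  mod_b <- train_tissue_classifier(scene$slide, ann_b)
  slides <- lapply(1:20, function(i) {
    generate_slide(scene_params(height_px = 160L, width_px = 160L,
                                nest_radius_um = c(28, 5),
                                target_tsr_percent = 35 + 3 * i,
                                background_margin_px = 8L,
                                seed = 700 + i))$slide
  })
  rep <- reproducibility_check(mod_a, mod_b, slides, stride_px = 6L)
  expect_true(all(rep$rho >= 0.9))
})

test_that("concordance is refused or undefined in degenerate settings", {
  mod <- default_model()
  sl <- default_scene()$slide
  expect_error(reproducibility_check(mod, mod, list(sl, sl)), "3 slides")
  # identical slides: zero variance across slides -> rho undefined
  rep <- reproducibility_check(mod, mod, list(sl, sl, sl), stride_px = 8L)
  expect_true(all(is.na(rep$rho)))
})
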