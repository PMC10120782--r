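# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

default_scene <- function() {
  fixture("scene", function() generate_slide(scene_params(seed = 101)))
}

default_model <- function() {
  fixture("model", function() {
    sc <- default_scene()
    ann <- sample_annotation_points(sc$ground_truth, seed = 202)
    train_tissue_classifier(sc$slide, ann)
  })
}

# a small all-white slide (pure background)
white_slide <- function(n = 64L) {
  new_slide(array(255L, c(n, n, 3L)), mpp = 1, slide_id = "white")
}

# uniform-color slide
flat_slide <- function(rgb, n = 96L, mpp = 1) {
  img <- array(0L, c(n, n, 3L))
  for (ch in 1:3) img[, , ch] <- rgb[ch]
  new_slide(img, mpp = mpp, slide_id = "flat")
}
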