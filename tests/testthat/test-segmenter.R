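# encoder-decoder segmenter: gradients, training, inference, oracle

test_that("network gradients match finite differences", {
  set.seed(42)
  depth <- 2
  x <- array(rnorm(16 * 16 * 3), c(16, 16, 3))
  labels <- matrix(sample(0:2, 256, TRUE), 16, 16)
  p <- mammilieu:::unet_init(3, 4, depth, 2)
  fw <- mammilieu:::unet_forward(p, x, depth)
  sx <- mammilieu:::softmax_xent(fw$logits, labels)
  g <- mammilieu:::unet_backward(p, fw$cache, sx$dlogits, depth)
  eps <- 1e-5
  for (nm in sample(names(p), 6)) {
    i <- sample(length(p[[nm]]), 1)
    pp <- p; pp[[nm]][i] <- pp[[nm]][i] + eps
    l1 <- mammilieu:::softmax_xent(
      mammilieu:::unet_forward(pp, x, depth)$logits, labels)$loss
    pp[[nm]][i] <- pp[[nm]][i] - 2 * eps
    l2 <- mammilieu:::softmax_xent(
      mammilieu:::unet_forward(pp, x, depth)$logits, labels)$loss
    num <- (l1 - l2) / (2 * eps)
    expect_equal(g[[nm]][i], num, tolerance = 1e-4)
  }
})

scenes_for_training <- function(n = 3, seed0 = 300, eer = 0.7) {
  lapply(seq_len(n), function(s) generate_scene(scene_spec(
    image_size_px = c(384, 384), eer_fraction = eer,
    pe_fraction_of_eer = 0.35, seed = seed0 + s)))
}

test_that("stage-B training reaches the sub-10% validation error target", {
  scenes <- scenes_for_training(3)
  td <- segmentation_tiles(scenes, "B", 64, max_tiles = 32)
  m <- train_segmenter(td$tiles, td$labels, "B",
                       segmenter_params(epochs = 40), seed = 5)
  expect_lt(m$validation_error, 0.10)
  expect_true(m$converged)
})

test_that("training is deterministic and rejects single-class data", {
  scenes <- scenes_for_training(2)
  td <- segmentation_tiles(scenes, "A", 64, max_tiles = 16)
  m1 <- train_segmenter(td$tiles, td$labels, "A",
                        segmenter_params(epochs = 10), seed = 7)
  m2 <- train_segmenter(td$tiles, td$labels, "A",
                        segmenter_params(epochs = 10), seed = 7)
  expect_identical(m1$validation_error, m2$validation_error)
  expect_identical(m1$weights, m2$weights)
  one_class <- lapply(td$labels, function(y) { y[] <- 1L; y })
  expect_error(train_segmenter(td$tiles, one_class, "A",
                               segmenter_params(epochs = 2), seed = 1),
               "single class")
})

test_that("stage A separates EER from FSR on held-out scenes", {
  scenes <- scenes_for_training(3, seed0 = 310, eer = 0.5)
  td <- segmentation_tiles(scenes, "A", 64, max_tiles = 36)
  mA <- train_segmenter(td$tiles, td$labels, "A",
                        segmenter_params(epochs = 40), seed = 8)
  test_sc <- generate_scene(scene_spec(image_size_px = c(256, 256),
                                       eer_fraction = 0.4,
                                       pe_fraction_of_eer = 0.35, seed = 999))
  eer <- segment_eer(test_sc$image, mA)
  truth <- test_sc$truth$compartment_mask$labels > 0
  dice <- 2 * sum(eer & truth) / (sum(eer) + sum(truth))
  expect_gte(dice, 0.90)
  # negative control: an all-FSR scene yields almost no EER
  neg <- generate_scene(scene_spec(image_size_px = c(256, 256),
                                   eer_fraction = 0, seed = 998))
  eer0 <- segment_eer(neg$image, mA)
  expect_lt(mean(eer0), 0.01)
})

test_that("stage B assigns PE/ILS only inside the EER mask", {
  scenes <- scenes_for_training(3, seed0 = 320)
  td <- segmentation_tiles(scenes, "B", 64, max_tiles = 32)
  mB <- train_segmenter(td$tiles, td$labels, "B",
                        segmenter_params(epochs = 40), seed = 9)
  test_sc <- generate_scene(scene_spec(image_size_px = c(256, 256),
                                       eer_fraction = 0.5,
                                       pe_fraction_of_eer = 0.35, seed = 997))
  truth <- test_sc$truth$compartment_mask
  eer_mask <- truth$labels > 0
  cm <- segment_pe_ils(test_sc$image, eer_mask, mB)
  # containment: nothing labeled outside the EER mask
  expect_true(all(cm$labels[!eer_mask] == 0L))
  for (lab_val in 1:2) {
    d <- 2 * sum(cm$labels == lab_val & truth$labels == lab_val) /
      (sum(cm$labels == lab_val) + sum(truth$labels == lab_val))
    expect_gte(d, 0.85)
  }
  # empty EER: valid all-FSR mask with a warning
  expect_warning(cm0 <- segment_pe_ils(test_sc$image,
                                       matrix(FALSE, 256, 256), mB),
                 "empty EER")
  expect_equal(sum(cm0$labels), 0)
})

test_that("oracle segmenter returns the generator truth verbatim", {
  sc <- small_scene(seed = 41)
  m <- oracle_segmenter(sc)
  expect_identical(m, sc$truth$compartment_mask)
  truth <- sc$truth$compartment_mask$labels
  expect_equal(2 * sum((m$labels == 1) & (truth == 1)) /
                 (sum(m$labels == 1) + sum(truth == 1)), 1.0)
})
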