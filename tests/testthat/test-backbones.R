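# Backbone registry, head replacement, prediction and training contracts.

test_that("the registry carries the published input and batch sizes", {
  reg <- backbone_registry()
  sizes <- setNames(reg$input_size, reg$name)
  expect_identical(sizes[["EfficientNetB4"]], 380L)
  expect_identical(sizes[["EfficientNetB5"]], 299L)
  expect_identical(sizes[["NASNetLarge"]], 331L)
  expect_identical(sizes[["Xception"]], 299L)
  expect_identical(sizes[["InceptionResNetV2"]], 299L)
  batches <- setNames(reg$batch_size, reg$name)
  expect_identical(batches[c("EfficientNetB4", "EfficientNetB5",
                             "NASNetLarge", "Xception",
                             "InceptionResNetV2")],
                   c(EfficientNetB4 = 32L, EfficientNetB5 = 40L,
                     NASNetLarge = 64L, Xception = 64L,
                     InceptionResNetV2 = 32L))
  expect_error(backbone_spec("ResNet50"), class = "drh_config_error")
})

test_that("head replacement gives every backbone exactly 5 softmax outputs", {
  for (nm in backbone_registry()$name) {
    m <- build_basic_model(backbone_spec(nm), seed = 1)
    expect_identical(m$net$output_shape, 5L)
    types <- vapply(m$net$layers, `[[`, character(1), "type")
    expect_identical(types[length(types)], "softmax")
    if (nm == "InceptionResNetV2") {
      expect_false("dropout" %in% types)  # only the final layer is replaced
    } else {
      expect_true("dropout" %in% types)
      dr <- Filter(function(l) l$type == "dropout", m$net$layers)[[1]]
      expect_equal(dr$rate, 0.4)
    }
  }
})

test_that("pretrained weights are refused explicitly", {
  expect_error(build_basic_model(backbone_spec("Xception", pretrained = TRUE)),
               "not available", class = "drh_config_error")
})

test_that("models accept only their configured input size", {
  m <- build_basic_model(backbone_spec("EfficientNetB4"), seed = 1)
  ok <- array(runif(380 * 380 * 3 * 2), c(380, 380, 3, 2))
  p <- predict_probabilities(m, ok)
  expect_identical(dim(p), c(2L, 5L))
  bad <- array(runif(299 * 299 * 3 * 2), c(299, 299, 3, 2))
  expect_error(predict_probabilities(m, bad), class = "drh_shape_error")
})

test_that("predictions are valid probability vectors and deterministic", {
  m <- build_basic_model(backbone_spec("TinyCNN"), seed = 2)
  imgs <- tiny_image_set(2, seed = 3)         # 10 images
  t0 <- Sys.time()
  p <- predict_probabilities(m, c(imgs, imgs[1]))  # duplicate first image
  expect_lt(as.numeric(Sys.time() - t0, units = "secs"), 1)
  expect_identical(dim(p), c(11L, 5L))
  expect_true(all(p >= 0))
  expect_equal(rowSums(p), rep(1, 11), tolerance = 1e-6)
  expect_equal(p[11, ], p[1, ])               # inference determinism
  empty <- predict_probabilities(m, list())
  expect_identical(dim(empty), c(0L, 5L))
})

test_that("training reduces the loss, records history, and is seeded", {
  imgs <- tiny_image_set(12, seed = 4)        # 60 images
  cfg <- train_config("adam", 5e-3, epochs = 5, loss_name = "ce",
                      batch_size = 32, seed = 5)
  m1 <- train_basic_model(build_basic_model(backbone_spec("TinyCNN"), 6),
                          imgs, cfg)
  expect_identical(nrow(m1$history), 5L)
  expect_lt(m1$history$loss[5], m1$history$loss[1])
  m2 <- train_basic_model(build_basic_model(backbone_spec("TinyCNN"), 6),
                          imgs, cfg)
  expect_identical(m1$history, m2$history)    # same seed, same run
})

test_that("recorded ece loss always dominates its ce component", {
  imgs <- tiny_image_set(6, seed = 7)
  cfg <- train_config("adam", 5e-3, epochs = 4, loss_name = "ece",
                      penalty_mode = "hard", batch_size = 32, seed = 8)
  m <- train_basic_model(build_basic_model(backbone_spec("TinyCNN"), 9),
                         imgs, cfg)
  expect_true(all(m$history$loss >= m$history$ce_loss - 1e-12))
})

test_that("TinyCNN solves a separable 2-grade task within 20 epochs", {
  # grades 0 and 4 are visually far apart: no lesions versus many
  imgs <- c(lapply(1:20, function(i)
    graded_image(resize_for_model(
      gen_fundus_image(0, 64, seed = 900 + i)$pixels, "TinyCNN"), 0)),
    lapply(1:20, function(i)
      graded_image(resize_for_model(
        gen_fundus_image(4, 64, seed = 950 + i)$pixels, "TinyCNN"), 4)))
  cfg <- train_config("adam", 5e-3, epochs = 20, loss_name = "ce",
                      batch_size = 32, seed = 10)
  m <- train_basic_model(build_basic_model(backbone_spec("TinyCNN"), 11),
                         imgs, cfg)
  expect_gte(max(m$history$accuracy), 0.95)
})

test_that("degenerate training inputs are rejected", {
  m <- build_basic_model(backbone_spec("TinyCNN"), 1)
  expect_error(train_basic_model(m, list()), "empty")
  bad <- tiny_image_set(1, seed = 12)
  bad[[1]]$grade <- 9L
  expect_error(train_basic_model(m, bad), class = "drh_label_error")
})

test_that("cached outputs round-trip through the CSV layout", {
  dir <- withr::local_tempdir()
  labels <- gen_labels(20, seed = 13)
  set <- gen_base_outputs(labels, base_model_sim_spec(n_models = 3, seed = 14))
  df <- drhybrid:::outputs_set_to_df(set)
  path <- file.path(dir, "outputs.csv")
  write_outputs_csv(df, path)
  back <- read_outputs_csv(path)
  expect_identical(back$model_order, set$model_order)
  expect_identical(back$grades, set$grades)
  expect_equal(back$probs, set$probs, tolerance = 1e-6)
  expect_error(write_outputs_csv(df[, -1], path), "columns")
})
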