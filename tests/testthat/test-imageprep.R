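# Black-border cropping, per-backbone resizing, and augmentation.

test_that("crop_black_border finds the tight disc bounding box", {
  px <- array(0, c(100, 100, 3))
  px[21:80, 21:80, ] <- 200          # synthetic bright square, rows/cols 20..79
  cr <- crop_black_border(px, 10)
  # brute-force oracle: scan the binarised mask for min/max foreground indices
  mask <- (px[, , 1] + px[, , 2] + px[, , 3]) / 3 > 10
  rows <- range(which(apply(mask, 1, any)))
  cols <- range(which(apply(mask, 2, any)))
  expect_identical(unname(cr$bbox),
                   c(rows[1] - 1L, rows[2], cols[1] - 1L, cols[2]))
  expect_identical(unname(cr$bbox), c(20L, 80L, 20L, 80L))
  expect_identical(dim(cr$pixels), c(60L, 60L, 3L))
  expect_equal(cr$pixels, px[21:80, 21:80, ])
})

test_that("fully bright image crops to itself; all-black is rejected", {
  bright <- array(120, c(8, 11, 3))
  cr <- crop_black_border(bright, 10)
  expect_identical(unname(cr$bbox), c(0L, 8L, 0L, 11L))
  expect_equal(cr$pixels, bright)
  expect_error(crop_black_border(array(0, c(16, 16, 3))),
               class = "drh_empty_fundus")
  expect_error(crop_black_border(array(5, c(16, 16, 3)), 10),
               class = "drh_empty_fundus")
})

test_that("cropping is idempotent and never enlarges", {
  for (s in 1:5) {
    img <- gen_fundus_image(sample(0:4, 1), 64, seed = 500 + s)
    cr <- crop_black_border(img)
    area <- prod(dim(cr$pixels)[1:2])
    expect_lte(area, prod(dim(img$pixels)[1:2]))
    cr2 <- crop_black_border(cr$pixels)
    expect_identical(unname(cr2$bbox),
                     c(0L, nrow(cr$pixels), 0L, ncol(cr$pixels)))
    expect_equal(cr2$pixels, cr$pixels)
  }
})

test_that("resize_for_model honours each backbone's input size", {
  px <- gen_fundus_image(1, 64, seed = 7)$pixels
  expect_identical(dim(resize_for_model(px, "EfficientNetB4")),
                   c(380L, 380L, 3L))
  expect_identical(dim(resize_for_model(px, "NASNetLarge")),
                   c(331L, 331L, 3L))
  for (m in c("EfficientNetB5", "Xception", "InceptionResNetV2"))
    expect_identical(dim(resize_for_model(px, m)), c(299L, 299L, 3L))
  # identity resize returns the identical array
  sq <- array(runif(299 * 299 * 3, 0, 255), c(299, 299, 3))
  expect_identical(resize_for_model(sq, "Xception"), sq)
  expect_error(resize_for_model(px, "ResNet50"), class = "drh_config_error")
})

test_that("identity augmentation returns the input unchanged", {
  px <- gen_fundus_image(2, 64, seed = 8)$pixels
  cfg <- augment_config(rotation_degrees = 0, width_shift_frac = 0,
                        height_shift_frac = 0, shear_degrees = 0,
                        zoom_frac = 0, horizontal_flip = FALSE,
                        vertical_flip = FALSE)
  expect_equal(augment_image(px, cfg, seed = 1), px)
})

test_that("forced horizontal flip reverses columns and is an involution", {
  px <- gen_fundus_image(3, 64, seed = 9)$pixels
  cfg <- augment_config(rotation_degrees = 0, width_shift_frac = 0,
                        height_shift_frac = 0, shear_degrees = 0,
                        zoom_frac = 0, horizontal_flip = TRUE,
                        vertical_flip = FALSE, flip_prob = 1)
  out <- augment_image(px, cfg, seed = 2)
  expect_equal(out, px[, ncol(px):1, ])
  expect_equal(augment_image(out, cfg, seed = 3), px)
})

test_that("augmentation is seed-deterministic and preserves shape and range", {
  px <- gen_fundus_image(4, 64, seed = 10)$pixels
  cfg <- augment_config()
  a <- augment_image(px, cfg, seed = 11)
  b <- augment_image(px, cfg, seed = 11)
  expect_identical(a, b)
  expect_false(identical(a, augment_image(px, cfg, seed = 12)))
  for (s in 13:16) {
    out <- augment_image(px, cfg, seed = s)
    expect_identical(dim(out), dim(px))
    expect_true(is.double(out))
    expect_gte(min(out), 0); expect_lte(max(out), 255)
  }
})

test_that("the extra_augment hook runs after the geometric transforms", {
  px <- gen_fundus_image(0, 64, seed = 20)$pixels
  cfg <- augment_config(rotation_degrees = 0, width_shift_frac = 0,
                        height_shift_frac = 0, shear_degrees = 0,
                        zoom_frac = 0, horizontal_flip = FALSE,
                        vertical_flip = FALSE,
                        extra_augment = function(p) p * 0 + 7)
  expect_true(all(augment_image(px, cfg, seed = 1) == 7))
  expect_error(augment_config(rotation_degrees = -1), "magnitudes")
  expect_error(augment_config(zoom_frac = 1.5), "< 1")
})

test_that("PNG and manifest round trips preserve data", {
  dir <- withr::local_tempdir()
  px <- round(gen_fundus_image(2, 64, seed = 30)$pixels)
  p1 <- file.path(dir, "a.png")
  write_image(px, p1)
  expect_equal(read_image(p1), px, tolerance = 1e-8)
  df <- data.frame(image_path = "a.png", grade = 2L)
  mp <- file.path(dir, "manifest.csv")
  write_manifest(df, mp)
  back <- read_manifest(mp)
  expect_identical(back$grade, 2L)
  expect_identical(basename(back$image_path), "a.png")
  imgs <- load_graded_images(mp)
  expect_length(imgs, 1)
  expect_identical(imgs[[1]]$grade, 2L)
  expect_error(read_manifest(file.path(dir, "nope.csv")), "not found")
})

test_that("preprocess_manifest crops and resizes a whole manifest", {
  dir <- withr::local_tempdir()
  mp <- gen_fundus_dataset(4, file.path(dir, "raw"), size = 64, seed = 31)
  out <- preprocess_manifest(mp, file.path(dir, "prep"),
                             model_name = "TinyCNN")
  prep <- load_graded_images(out)
  expect_length(prep, 4)
  for (img in prep)
    expect_identical(dim(img$pixels), c(32L, 32L, 3L))
})
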