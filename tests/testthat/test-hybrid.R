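# Stacking, averaging, and the learned fusers.

test_that("stack_vertical concatenates rows in model order", {
  bo <- base_outputs(rbind(c(1, 0, 0, 0, 0), c(0, 0, 0, 0, 1)))
  expect_equal(stack_vertical(bo), c(1, 0, 0, 0, 0, 0, 0, 0, 0, 1))
  one <- base_outputs(matrix(c(0.2, 0.2, 0.2, 0.2, 0.2), 1))
  expect_equal(stack_vertical(one), rep(0.2, 5))
  five <- base_outputs(random_prob_rows(5))
  expect_length(stack_vertical(five), 25)
})

test_that("stack_horizontal is the transposed row stack with a unit channel", {
  m <- random_prob_rows(5)
  bo <- base_outputs(m)
  h <- stack_horizontal(bo)
  expect_identical(dim(h), c(5L, 5L, 1L))
  expect_equal(h[, , 1], t(m))
  h2 <- stack_horizontal(base_outputs(random_prob_rows(2)))
  expect_identical(dim(h2), c(5L, 2L, 1L))
})

test_that("fuse_average implements the elementwise model mean", {
  v <- as.vector(random_prob_rows(1))
  same <- base_outputs(rbind(v, v, v))
  expect_equal(fuse_average(same), v)
  bo <- base_outputs(rbind(c(1, 0, 0, 0, 0), c(0, 0, 0, 0, 1)))
  expect_equal(fuse_average(bo), c(0.5, 0, 0, 0, 0.5))
  m <- random_prob_rows(4)
  perm <- sample(4)
  expect_equal(fuse_average(base_outputs(m)),
               fuse_average(base_outputs(m[perm, ])))
  expect_equal(sum(fuse_average(base_outputs(m))), 1, tolerance = 1e-12)
})

test_that("hybrid-a fuses one-hot outputs exactly and breaks ties low", {
  bo <- base_outputs(rbind(one_hot(2), one_hot(2), one_hot(3)))
  pr <- predict_hybrid(build_hybrid_a(), bo)
  expect_equal(unname(pr$probabilities), c(0, 0, 2/3, 1/3, 0))
  expect_identical(pr$grade, 2L)
  # single model: hybrid-a is the model's own prediction
  v <- as.vector(random_prob_rows(1))
  solo <- base_outputs(matrix(v, 1), "only")
  pr1 <- predict_hybrid(build_hybrid_a(hybrid_spec("a", n_models = 1)), solo)
  expect_equal(unname(pr1$probabilities), v)
  expect_identical(pr1$grade, predicted_grade(v))
})

test_that("hybrid-f has the published layer widths and parameter count", {
  hf <- build_hybrid_f(hybrid_spec("f"), seed = 1)
  expect_equal(hybrid_shapes(hf)$n_params, 25 * 2048 + 2048 + 2048 * 5 + 5)
  expect_identical(hybrid_shapes(hf)$n_params, 63493L)
  bo <- base_outputs(random_prob_rows(5))
  p1 <- predict_hybrid(hf, bo)
  p2 <- predict_hybrid(hf, bo)
  expect_equal(sum(p1$probabilities), 1, tolerance = 1e-9)
  expect_identical(p1, p2)
})

test_that("hybrid-c reproduces the published shape table for M = 5", {
  hc <- build_hybrid_c(hybrid_spec("c"), seed = 1)
  sh <- hybrid_shapes(hc)
  expect_equal(sh$shapes,
               list(c(5L, 5L, 256L), c(5L, 5L, 256L), c(3L, 3L, 256L)))
  expect_identical(sh$flatten_dim, 2304L)
  expect_identical(sh$n_params, 2560L + 590080L + 590080L + 4720640L + 10245L)
  expect_identical(sh$n_params, 5913605L)
  # shapes propagate for other M
  h4 <- build_hybrid_c(hybrid_spec("c", n_models = 4, conv_filters = 8),
                       seed = 1)
  expect_identical(hybrid_shapes(h4)$flatten_dim, 3L * 2L * 8L)
  expect_error(build_hybrid_c(hybrid_spec("c", n_models = 2)),
               class = "drh_config_error")
  expect_error(hybrid_spec("c", n_models = 2), class = "drh_config_error")
})

test_that("fused outputs are valid probability vectors for all three kinds", {
  labels <- gen_labels(40, seed = 31)
  set <- gen_base_outputs(labels, base_model_sim_spec(seed = 32))
  for (fuser in list(build_hybrid_a(),
                     build_hybrid_f(hybrid_spec("f"), seed = 2),
                     build_hybrid_c(hybrid_spec("c", conv_filters = 8),
                                    seed = 3))) {
    pr <- predict_hybrid(fuser, set)
    expect_identical(dim(pr$probabilities), c(40L, 5L))
    expect_true(all(pr$probabilities >= -1e-12))
    expect_equal(rowSums(pr$probabilities), rep(1, 40), tolerance = 1e-6)
    expect_true(all(pr$grade %in% 0:4))
  }
})

test_that("hybrid-f learns a task realisable by a linear map", {
  # true grade is always model 0's arg-max: a fuser must learn to copy it
  labels <- gen_labels(500, seed = 33)
  set <- gen_base_outputs(labels, base_model_sim_spec(n_models = 3, seed = 34))
  set$grades <- apply(set$probs[, 1, ], 1, which.max) - 1L
  hf <- build_hybrid_f(hybrid_spec("f", n_models = 3), seed = 4)
  hf <- train_hybrid(hf, set, train_config("adam", 1e-3, epochs = 100,
                                           loss_name = "ce",
                                           batch_size = 128, seed = 5))
  expect_gte(tail(hf$history$accuracy, 1), 0.99)
  expect_lt(tail(hf$history$loss, 1), hf$history$loss[1])
})

test_that("training is seed-deterministic and records model order", {
  labels <- gen_labels(60, seed = 35)
  set <- gen_base_outputs(labels, base_model_sim_spec(n_models = 3, seed = 36))
  cfg <- train_config("adam", 1e-3, epochs = 5, loss_name = "ce",
                      batch_size = 32, seed = 6)
  h1 <- train_hybrid(build_hybrid_f(hybrid_spec("f", n_models = 3), 7),
                     set, cfg)
  h2 <- train_hybrid(build_hybrid_f(hybrid_spec("f", n_models = 3), 7),
                     set, cfg)
  expect_identical(h1$history, h2$history)
  expect_identical(h1$model_order, set$model_order)
})

test_that("model_order mismatches are explicit errors", {
  labels <- gen_labels(30, seed = 37)
  set <- gen_base_outputs(labels, base_model_sim_spec(n_models = 3, seed = 38))
  hf <- train_hybrid(build_hybrid_f(hybrid_spec("f", n_models = 3), 8), set,
                     train_config("adam", 1e-3, epochs = 2,
                                  batch_size = 32, seed = 9))
  swapped <- set
  swapped$model_order <- rev(set$model_order)
  expect_error(predict_hybrid(hf, swapped), class = "drh_order_error")
  bo <- base_outputs(random_prob_rows(3), c("x", "y", "z"))
  expect_error(predict_hybrid(hf, bo), class = "drh_order_error")
  # hybrid-a is permutation invariant and accepts any order
  expect_silent(predict_hybrid(build_hybrid_a(), swapped))
  expect_error(train_hybrid(build_hybrid_a(), set), "trainable")
})
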