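# Base classifier registry and training.
#
# The published method builds five basic models on ImageNet-pretrained
# backbones (EfficientNetB4/B5, NASNetLarge, Xception, InceptionResNetV2),
# replacing each head with dropout 0.4 + a 5-unit softmax layer
# (InceptionResNetV2: the final 1000-unit layer is replaced by the 5-unit
# softmax with no extra dropout).  This environment has no deep-learning
# backend and no weight downloads, so the named entries build a small
# *surrogate* convolutional trunk at the correct input size with the
# correct replaced head; `pretrained = TRUE` raises an explicit error.
# `TinyCNN` is the CPU-scale backbone the test suite exercises.

.backbone_table <- list(
  EfficientNetB4    = list(input_size = 380L, batch_size = 32L, dropout = 0.4),
  EfficientNetB5    = list(input_size = 299L, batch_size = 40L, dropout = 0.4),
  NASNetLarge       = list(input_size = 331L, batch_size = 64L, dropout = 0.4),
  Xception          = list(input_size = 299L, batch_size = 64L, dropout = 0.4),
  InceptionResNetV2 = list(input_size = 299L, batch_size = 32L, dropout = 0),
  TinyCNN           = list(input_size = 32L,  batch_size = 32L, dropout = 0.4)
)

#' Registered backbones
#'
#' @return Data frame of registered backbone names with their square input
#'   sizes, training batch sizes and head dropout rates.  The five named
#'   backbones follow the published input-size mapping (380 px for
#'   EfficientNetB4, 331 px for NASNetLarge, 299 px for the rest);
#'   `TinyCNN` is this package's desk-scale test backbone.
#' @export
backbone_registry <- function() {
  data.frame(name = names(.backbone_table),
             input_size = vapply(.backbone_table, `[[`, integer(1), "input_size"),
             batch_size = vapply(.backbone_table, `[[`, integer(1), "batch_size"),
             dropout = vapply(.backbone_table, `[[`, numeric(1), "dropout"),
             row.names = NULL)
}

#' Backbone specification
#'
#' @param name Registered backbone name (see [backbone_registry()]).
#' @param input_size Override of the square input size (only honoured for
#'   `TinyCNN`, whose size is configurable; the named backbones have fixed
#'   published sizes).
#' @param pretrained Request pretrained backbone weights.  No weights are
#'   obtainable in this environment, so `TRUE` always raises an explicit
#'   error — never a silent random initialisation.
#' @return A list with class `drh_backbone_spec`: `name`, `input_size`,
#'   `dropout_rate`, `n_outputs` (always 5), `batch_size`, `pretrained`.
#' @export
backbone_spec <- function(name, input_size = NULL, pretrained = FALSE) {
  entry <- .backbone_table[[name]]
  if (is.null(entry))
    stop_drh("unknown backbone '", name, "'; registered: ",
             paste(names(.backbone_table), collapse = ", "),
             class = "drh_config_error")
  size <- entry$input_size
  if (!is.null(input_size)) {
    if (name != "TinyCNN")
      stop_drh("input size of ", name, " is fixed at ", size,
               class = "drh_config_error")
    size <- as.integer(input_size)
  }
  structure(list(name = name, input_size = size,
                 dropout_rate = entry$dropout, n_outputs = 5L,
                 batch_size = entry$batch_size,
                 pretrained = isTRUE(pretrained)),
            class = "drh_backbone_spec")
}

#' Build a basic classifier
#'
#' Constructs a trainable classifier mapping an `S x S x 3` image batch to
#' 5-grade probability vectors, with the replaced head prescribed for the
#' backbone: dropout 0.4 followed by a 5-unit softmax layer, except
#' InceptionResNetV2 where only the final layer is replaced by the 5-unit
#' softmax (no added dropout).
#'
#' For the five named backbones the trunk built here is a small surrogate
#' convolutional network at the published input size, standing in for the
#' unobtainable pretrained architecture; it preserves every interface
#' contract (input size, head, probability outputs) but not the capacity
#' of the originals.
#'
#' @param spec A [backbone_spec()].
#' @param seed Integer seed for weight initialisation.
#' @return An object of class `drh_basic_model`.
#' @export
build_basic_model <- function(spec, seed = 1L) {
  if (!inherits(spec, "drh_backbone_spec"))
    stop_drh("spec must come from backbone_spec()")
  if (spec$pretrained)
    stop_drh("pretrained weights for ", spec$name, " are not available in ",
             "this environment; refusing silent random initialisation. ",
             "Build with pretrained = FALSE or use TinyCNN.",
             class = "drh_config_error")
  head <- if (spec$dropout_rate > 0)
    list(layer_dropout(spec$dropout_rate), layer_dense(5L), layer_softmax())
  else
    list(layer_dense(5L), layer_softmax())
  trunk <- if (spec$name == "TinyCNN") {
    # small spatial head: two conv/pool stages then a 64-unit embedding
    list(layer_conv2d(8L, 3L, 1L), layer_relu(), layer_avgpool(4L),
         layer_conv2d(16L, 3L, 1L), layer_relu(), layer_avgpool(4L),
         layer_flatten(), layer_dense(64L), layer_relu())
  } else {
    list(layer_conv2d(8L, 3L, 1L), layer_relu(), layer_avgpool(4L),
         layer_conv2d(16L, 3L, 1L), layer_relu(), layer_gap())
  }
  net <- nn_network(c(trunk, head),
                    input_shape = c(spec$input_size, spec$input_size, 3L),
                    seed = seed)
  structure(list(spec = spec, net = net, seed = as.integer(seed),
                 history = NULL),
            class = "drh_basic_model")
}

#' @export
print.drh_basic_model <- function(x, ...) {
  cat(sprintf("<drh_basic_model> %s (input %dx%dx3, %s)\n", x$spec$name,
              x$spec$input_size, x$spec$input_size,
              if (is.null(x$history)) "untrained" else "trained"))
  print(x$net)
  invisible(x)
}

# Assemble images (list of graded_image / arrays, or a 4-D array) into the
# (H, W, C, B) batch a model expects, scaling intensities to [0, 1].
#' @noRd
image_batch <- function(images, input_size) {
  if (is.array(images) && length(dim(images)) == 4L) {
    x <- images
  } else {
    if (inherits(images, "graded_image") ||
        (is.array(images) && length(dim(images)) == 3L))
      images <- list(images)
    if (length(images) == 0L)
      return(array(0, c(input_size, input_size, 3L, 0L)))
    px <- lapply(images, as_pixels)
    x <- array(0, c(dim(px[[1]]), length(px)))
    for (i in seq_along(px)) {
      if (!identical(dim(px[[i]]), dim(px[[1]])))
        stop_drh("images in a batch must share one shape",
                 class = "drh_shape_error")
      x[, , , i] <- px[[i]]
    }
  }
  d <- dim(x)
  if (d[1] != input_size || d[2] != input_size || d[3] != 3L)
    stop_drh("model expects ", input_size, "x", input_size, "x3 input, got ",
             d[1], "x", d[2], "x", d[3], class = "drh_shape_error")
  if (length(x) && max(x) > 1) x <- x / 255
  x
}

#' Predict grade probabilities with a basic model
#'
#' Dropout is inactive at inference, so predictions are deterministic.
#'
#' @param model A `drh_basic_model`.
#' @param images A list of [graded_image()]s / pixel arrays sized for the
#'   model, or an `S x S x 3 x n` batch array.
#' @return `n x 5` matrix; each row a probability vector summing to 1.
#' @export
predict_probabilities <- function(model, images) {
  x <- image_batch(images, model$spec$input_size)
  p <- nn_predict(model$net, x, batch_size = model$spec$batch_size)
  colnames(p) <- paste0("p", 0:4)
  p
}

#' Train a basic model
#'
#' Trains with the configured loss (`"ce"` or `"ece"`), by default with
#' RAdam at the published initial learning rate 8e-4, recording per-epoch
#' training loss (and its plain cross-entropy component), accuracy and
#' learning rate.  The learning rate is reduced on a training-loss plateau
#' (factor 0.5, patience 3, floor 1e-6).  Runs are deterministic given the
#' seed in `train_cfg`.
#'
#' @param model A `drh_basic_model` from [build_basic_model()].
#' @param data Training images: a manifest path, a manifest data frame, or
#'   a list of [graded_image()]s, already sized for the model.
#' @param train_cfg A [train_config()]; the published basic-model settings
#'   are `optimizer_name = "radam"`, `initial_learning_rate = 8e-4`,
#'   `epochs = 50`.
#' @param aug_cfg Optional [augment_config()]; when given, every training
#'   batch is re-augmented on the fly.
#' @return The model with updated weights and a `history` data frame
#'   (`epoch`, `loss`, `ce_loss`, `accuracy`, `lr`).
#' @export
train_basic_model <- function(model,
                              data,
                              train_cfg = train_config(
                                optimizer_name = "radam",
                                initial_learning_rate = 8e-4,
                                epochs = 50L,
                                batch_size = model$spec$batch_size),
                              aug_cfg = NULL) {
  imgs <- if (is.character(data) || is.data.frame(data))
    load_graded_images(data) else data
  if (length(imgs) == 0L) stop_drh("training set is empty")
  grades <- vapply(imgs, function(g) g$grade, integer(1))
  x <- image_batch(imgs, model$spec$input_size)
  augment_fn <- NULL
  if (!is.null(aug_cfg)) {
    augment_fn <- function(xb) {
      for (i in seq_len(dim(xb)[4]))
        xb[, , , i] <- augment_image(xb[, , , i] * 255, aug_cfg,
                                     seed = NULL) / 255
      xb
    }
  }
  fit <- nn_train(model$net, x, grades, train_cfg, augment_fn)
  model$net <- fit$net
  model$history <- fit$history
  model
}

#' Save / load model checkpoints
#'
#' Checkpoints use R's native serialisation (`.rds`).
#' @param model Any model object of this package.
#' @param path Checkpoint path.
#' @return `load_model` returns the model; `save_model` returns `path`
#'   invisibly.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)

#' Write cached base-model outputs
#'
#' One row per image and model:
#' `image_id,grade,p0,p1,p2,p3,p4,model_name`.
#'
#' @param df Data frame in that layout.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_outputs_csv <- function(df, path) {
  need <- c("image_id", "grade", paste0("p", 0:4), "model_name")
  if (!all(need %in% names(df)))
    stop_drh("outputs need columns ", paste(need, collapse = ","))
  write.csv(df[, need], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read cached base-model outputs
#'
#' Inverse of [write_outputs_csv()]: pivots the long per-model rows into a
#' `base_outputs_set` (samples x models x grades array plus the model
#' order, which is fixed to the order of first appearance in the file).
#'
#' @param path Outputs CSV path.
#' @return A `base_outputs_set`.
#' @export
read_outputs_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  models <- unique(df$model_name)
  ids <- unique(df$image_id)
  n <- length(ids); M <- length(models)
  probs <- array(NA_real_, c(n, M, 5L))
  grades <- integer(n)
  id_i <- match(df$image_id, ids)
  m_i <- match(df$model_name, models)
  for (k in seq_len(nrow(df))) {
    probs[id_i[k], m_i[k], ] <- as.numeric(df[k, paste0("p", 0:4)])
    grades[id_i[k]] <- df$grade[k]
  }
  if (anyNA(probs)) stop_drh("outputs file is missing model/image rows")
  structure(list(probs = probs, grades = check_grades(grades),
                 model_order = models, ids = ids),
            class = "base_outputs_set")
}
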