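# The three ensemble fusers of base-model probability outputs:
#   hybrid-a — elementwise averaging of the M probability vectors;
#   hybrid-f — a fully-connected meta-learner on the vertically stacked
#              (5*M)-vector (one 2048-unit hidden layer, 5-unit softmax);
#   hybrid-c — a convolutional meta-learner on the horizontally stacked
#              5 x M probability matrix (three 3x3 conv layers of 256
#              filters, the last unpadded, then flatten / 2048 / 5).

#' Base-model outputs for one image
#'
#' @param matrix `M x 5` matrix; row `m` is model `m`'s probability vector
#'   over the five grades.
#' @param model_order Character vector of `M` distinct model names fixing
#'   the row identity.
#' @return A list with class `base_outputs`.
#' @export
base_outputs <- function(matrix, model_order = paste0("model_", seq_len(nrow(matrix)))) {
  matrix <- as.matrix(matrix)
  if (ncol(matrix) != 5L || nrow(matrix) < 1L)
    stop_drh("matrix must be M x 5 with M >= 1")
  if (length(model_order) != nrow(matrix) || anyDuplicated(model_order))
    stop_drh("model_order must name each of the M rows, without duplicates")
  check_prob_rows(matrix)
  structure(list(matrix = matrix, model_order = as.character(model_order)),
            class = "base_outputs")
}

#' Stack base-model outputs vertically
#'
#' Concatenates the M probability vectors in `model_order` into one
#' `(5*M)`-vector — the input layout of the fully-connected fuser (a
#' 25-vector for the published five-model ensemble).
#'
#' @param outputs A [base_outputs()].
#' @return Numeric vector of length `5 * M`.
#' @export
stack_vertical <- function(outputs) {
  as.vector(t(outputs$matrix))
}

#' Stack base-model outputs horizontally
#'
#' Places model `m`'s probability vector in column `m`, giving the
#' `5 x M` matrix (plus a unit channel) that feeds the convolutional
#' fuser — `5 x 5 x 1` for the published five-model ensemble.
#'
#' @param outputs A [base_outputs()].
#' @return `5 x M x 1` array.
#' @export
stack_horizontal <- function(outputs) {
  m <- t(outputs$matrix)
  array(m, c(5L, nrow(outputs$matrix), 1L))
}

#' Average fusion (hybrid-a)
#'
#' The elementwise mean of the M base-model probability vectors,
#' \eqn{Y_g = \frac{1}{M}\sum_m y_m^{(g)}}; permutation-invariant in the
#' models and itself a valid probability vector.
#'
#' @param outputs A [base_outputs()].
#' @return Probability vector of length 5.
#' @export
fuse_average <- function(outputs) {
  colMeans(outputs$matrix)
}

#' Fuser architecture specification
#'
#' @param kind `"a"` (averaging), `"f"` (fully-connected) or `"c"`
#'   (convolutional).
#' @param n_models Number of base models `M`.
#' @param n_grades Number of grades (5).
#' @param hidden_units Hidden layer width of the dense head (published:
#'   2048).
#' @param conv_filters Filters per conv layer of the convolutional fuser
#'   (published: 256; reducible for desk-scale training).
#' @param conv_kernel Conv kernel size (published: 3).
#' @return A list with class `drh_hybrid_spec`.
#' @export
hybrid_spec <- function(kind = c("a", "f", "c"), n_models = 5L,
                        n_grades = 5L, hidden_units = 2048L,
                        conv_filters = 256L, conv_kernel = 3L) {
  kind <- match.arg(kind)
  if (hidden_units < 1) stop_drh("hidden_units must be > 0")
  if (kind == "c" && n_models < 3L)
    stop_drh("the convolutional fuser needs M >= 3: its third, unpadded ",
             "3x3 convolution shrinks each spatial dimension by 2",
             class = "drh_config_error")
  structure(list(kind = kind, n_models = as.integer(n_models),
                 n_grades = as.integer(n_grades),
                 hidden_units = as.integer(hidden_units),
                 conv_filters = as.integer(conv_filters),
                 conv_kernel = as.integer(conv_kernel)),
            class = "drh_hybrid_spec")
}

#' Build the averaging fuser (hybrid-a)
#'
#' @param spec A [hybrid_spec()] with `kind = "a"` (optional).
#' @return A `drh_hybrid_model` that fuses by [fuse_average()]; it has no
#'   trainable parameters.
#' @export
build_hybrid_a <- function(spec = hybrid_spec("a")) {
  structure(list(kind = "a", spec = spec, net = NULL, model_order = NULL),
            class = "drh_hybrid_model")
}

#' Build the fully-connected fuser (hybrid-f)
#'
#' Maps the vertically stacked `(5*M)`-vector through one `hidden_units`
#' ReLU layer to a 5-unit softmax layer.  For the published M = 5 / 2048
#' configuration this is 63,493 trainable parameters.
#'
#' @param spec A [hybrid_spec()] with `kind = "f"`.
#' @param seed Integer seed for weight initialisation.
#' @return An untrained `drh_hybrid_model`.
#' @export
build_hybrid_f <- function(spec = hybrid_spec("f"), seed = 1L) {
  if (spec$kind != "f") stop_drh("spec$kind must be 'f'")
  net <- nn_network(list(layer_dense(spec$hidden_units), layer_relu(),
                         layer_dense(spec$n_grades), layer_softmax()),
                    input_shape = spec$n_grades * spec$n_models, seed = seed)
  structure(list(kind = "f", spec = spec, net = net, model_order = NULL),
            class = "drh_hybrid_model")
}

#' Build the convolutional fuser (hybrid-c)
#'
#' Layer sequence on the `5 x M x 1` stacked input: two 3x3 convolutions
#' with padding 1, one 3x3 convolution with padding 0 (shrinking each
#' spatial dimension by 2), flatten, a `hidden_units` dense layer, and the
#' 5-unit softmax output.  ReLU follows each convolution and the hidden
#' dense layer (the published layer table lists no activations; ReLU is
#' this package's documented choice).  For M = 5 with 256 filters the
#' intermediate shapes are `5x5x256`, `5x5x256`, `3x3x256`, the flattened
#' dimension is 2304, and the parameter count is 5,913,605.
#'
#' @param spec A [hybrid_spec()] with `kind = "c"` and `n_models >= 3`.
#' @param seed Integer seed for weight initialisation.
#' @return An untrained `drh_hybrid_model`.
#' @export
build_hybrid_c <- function(spec = hybrid_spec("c"), seed = 1L) {
  if (spec$kind != "c") stop_drh("spec$kind must be 'c'")
  if (spec$n_models < 3L)
    stop_drh("the convolutional fuser needs M >= 3 (spatial collapse)",
             class = "drh_config_error")
  k <- spec$conv_kernel; f <- spec$conv_filters
  net <- nn_network(list(
    layer_conv2d(f, k, pad = 1L), layer_relu(),
    layer_conv2d(f, k, pad = 1L), layer_relu(),
    layer_conv2d(f, k, pad = 0L), layer_relu(),
    layer_flatten(),
    layer_dense(spec$hidden_units), layer_relu(),
    layer_dense(spec$n_grades), layer_softmax()),
    input_shape = c(spec$n_grades, spec$n_models, 1L), seed = seed)
  structure(list(kind = "c", spec = spec, net = net, model_order = NULL),
            class = "drh_hybrid_model")
}

#' @export
print.drh_hybrid_model <- function(x, ...) {
  cat(sprintf("<drh_hybrid_model> hybrid-%s (M = %d%s)\n", x$kind,
              x$spec$n_models,
              if (is.null(x$model_order)) ", untrained"
              else paste0(", trained on: ",
                          paste(x$model_order, collapse = ", "))))
  if (!is.null(x$net)) print(x$net)
  invisible(x)
}

#' Layer output shapes of a fuser network
#'
#' @param fuser A built `drh_hybrid_model` with a network (`kind` f or c).
#' @return List with `shapes` (per-layer output shapes, convolution and
#'   flatten layers only for `kind = "c"`), `flatten_dim`, and `n_params`.
#' @export
hybrid_shapes <- function(fuser) {
  if (is.null(fuser$net)) stop_drh("hybrid-a has no network")
  layers <- fuser$net$layers
  conv <- Filter(function(ly) ly$type == "conv2d", layers)
  fl <- Filter(function(ly) ly$type == "flatten", layers)
  list(shapes = lapply(conv, `[[`, "out_shape"),
       flatten_dim = if (length(fl)) fl[[1]]$out_shape else NULL,
       n_params = nn_n_params(fuser$net))
}

# Assemble a base_outputs_set into the input batch of a fuser.
#' @noRd
hybrid_inputs <- function(fuser, set) {
  if (fuser$kind == "f") {
    p <- aperm(set$probs, c(3L, 2L, 1L))          # grade, model, sample
    dim(p) <- c(prod(dim(p)[1:2]), dim(p)[3])
    t(p)                                           # n x (5*M), model-major
  } else {
    p <- aperm(set$probs, c(3L, 2L, 1L))          # 5 x M x n
    d <- dim(p)
    array(p, c(d[1], d[2], 1L, d[3]))             # 5 x M x 1 x n
  }
}

#' Train a learned fuser
#'
#' Trains hybrid-f or hybrid-c on cached base-model outputs with the
#' published fuser settings as defaults: Adam, initial learning rate
#' 0.001, plain cross-entropy loss, 100 epochs.  The model order of the
#' training data is stored with the fuser and enforced at prediction time.
#'
#' @param fuser An untrained `drh_hybrid_model` (`kind` f or c).
#' @param data A `base_outputs_set` (from [gen_base_outputs()] or
#'   [read_outputs_csv()]), or a list of `list(outputs = base_outputs,
#'   grade = g)` pairs.
#' @param train_cfg A [train_config()].
#' @return The trained fuser, with a `history` data frame attached.
#' @export
train_hybrid <- function(fuser, data,
                         train_cfg = train_config(
                           optimizer_name = "adam",
                           initial_learning_rate = 1e-3,
                           epochs = 100L, loss_name = "ce",
                           batch_size = 128L)) {
  if (fuser$kind == "a")
    stop_drh("hybrid-a has no trainable parameters")
  set <- as_outputs_set(data)
  if (length(set$grades) == 0L) stop_drh("training set is empty")
  if (dim(set$probs)[2] != fuser$spec$n_models)
    stop_drh("data has ", dim(set$probs)[2], " models but the fuser was ",
             "built for ", fuser$spec$n_models, class = "drh_config_error")
  x <- hybrid_inputs(fuser, set)
  fit <- nn_train(fuser$net, x, set$grades, train_cfg)
  fuser$net <- fit$net
  fuser$history <- fit$history
  fuser$model_order <- set$model_order
  fuser
}

#' @noRd
as_outputs_set <- function(data) {
  if (inherits(data, "base_outputs_set")) return(data)
  if (is.list(data) && length(data) &&
      !is.null(data[[1]]$outputs)) {
    M <- nrow(data[[1]]$outputs$matrix)
    probs <- array(NA_real_, c(length(data), M, 5L))
    grades <- integer(length(data))
    order1 <- data[[1]]$outputs$model_order
    for (i in seq_along(data)) {
      if (!identical(data[[i]]$outputs$model_order, order1))
        stop_drh("inconsistent model_order across samples",
                 class = "drh_order_error")
      probs[i, , ] <- data[[i]]$outputs$matrix
      grades[i] <- data[[i]]$grade
    }
    return(structure(list(probs = probs, grades = check_grades(grades),
                          model_order = order1),
                     class = "base_outputs_set"))
  }
  stop_drh("data must be a base_outputs_set or a list of ",
           "(outputs, grade) pairs")
}

#' Fuse base-model outputs and predict the grade
#'
#' Applies the fuser to one image's base-model outputs (or a whole set)
#' and returns the fused probability vector together with its arg-max
#' grade (ties broken toward the lowest grade).  For trained fusers the
#' `model_order` of the inputs must match the order seen at training time;
#' a mismatch is an explicit error, not a silent reordering.
#'
#' @param fuser A `drh_hybrid_model` (hybrid-a, or a trained hybrid-f/c).
#' @param outputs A [base_outputs()] or a `base_outputs_set`.
#' @return For a single `base_outputs`: `list(probabilities, grade)`.  For
#'   a set: `list(probabilities = n x 5 matrix, grade = integer vector)`.
#' @export
predict_hybrid <- function(fuser, outputs) {
  single <- inherits(outputs, "base_outputs")
  set <- if (single) {
    structure(list(probs = array(outputs$matrix,
                                 c(1L, dim(outputs$matrix))) ,
                   grades = integer(1), model_order = outputs$model_order),
              class = "base_outputs_set")
  } else as_outputs_set(outputs)
  if (!is.null(fuser$model_order) &&
      !identical(set$model_order, fuser$model_order))
    stop_drh("model_order mismatch: fuser was trained on (",
             paste(fuser$model_order, collapse = ", "), ") but got (",
             paste(set$model_order, collapse = ", "), ")",
             class = "drh_order_error")
  if (fuser$kind == "a") {
    p <- apply(set$probs, c(1L, 3L), mean)
    if (is.null(dim(p))) p <- matrix(p, 1L)
  } else {
    if (is.null(fuser$net)) stop_drh("fuser has not been built")
    p <- nn_predict(fuser$net, hybrid_inputs(fuser, set))
  }
  colnames(p) <- paste0("p", 0:4)
  g <- max.col(p, ties.method = "first") - 1L
  if (single) list(probabilities = drop(p), grade = g[[1L]])
  else list(probabilities = p, grade = g)
}
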