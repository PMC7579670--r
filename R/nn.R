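# Minimal feed-forward network engine (pure R, BLAS-backed).
#
# Layers are plain lists; a network is a list of layers plus shape metadata.
# Convolutions are stride-1 im2col + matrix product, which keeps all heavy
# lifting inside BLAS.  Batches of image data are arrays with dim
# (H, W, C, B); batches of flat features are (B x n) matrices.

layer_conv2d  <- function(filters, kernel = 3L, pad = 1L)
  list(type = "conv2d", filters = as.integer(filters),
       kernel = as.integer(kernel), pad = as.integer(pad))
layer_dense   <- function(units) list(type = "dense", units = as.integer(units))
layer_relu    <- function() list(type = "relu")
layer_dropout <- function(rate) list(type = "dropout", rate = rate)
layer_flatten <- function() list(type = "flatten")
layer_avgpool <- function(size) list(type = "avgpool", size = as.integer(size))
layer_gap     <- function() list(type = "gap")
layer_softmax <- function() list(type = "softmax")

# im2col gather indices for one image: (P x K) with positions (oh fastest)
# in rows and patch elements ordered (dh, dw, c) in columns.
#' @noRd
conv_indices <- function(H, W, C, k, pad) {
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  OH <- Hp - k + 1L; OW <- Wp - k + 1L
  stopifnot(OH >= 1L, OW >= 1L)
  pos_r <- rep(seq_len(OH), times = OW)
  pos_c <- rep(seq_len(OW), each = OH)
  q_dh <- rep(seq_len(k), times = k * C)
  q_dw <- rep(rep(seq_len(k), each = k), times = C)
  q_c  <- rep(seq_len(C), each = k * k)
  P <- OH * OW; K <- k * k * C
  idx <- outer(pos_r, q_dh - 1L, `+`) +
    Hp * (outer(pos_c, q_dw - 1L, `+`) - 1L) +
    matrix(rep(Hp * Wp * (q_c - 1L), each = P), P, K)
  list(idx = idx, OH = OH, OW = OW, Hp = Hp, Wp = Wp, P = P, K = K)
}

#' Build a network from a layer list
#' @noRd
nn_network <- function(layers, input_shape, seed = NULL) {
  with_seed_opt(seed, {
    shape <- input_shape  # c(H, W, C) or scalar n
    built <- vector("list", length(layers))
    for (i in seq_along(layers)) {
      ly <- layers[[i]]
      ly$in_shape <- shape
      if (ly$type == "conv2d") {
        stopifnot(length(shape) == 3L)
        ci <- conv_indices(shape[1], shape[2], shape[3], ly$kernel, ly$pad)
        ly$geom <- ci
        # geometry of the transposed convolution used for the input
        # gradient: a full correlation of dY with the rotated kernel
        ly$geom_bw <- conv_indices(ci$OH, ci$OW, ly$filters, ly$kernel,
                                   ly$kernel - 1L - ly$pad)
        ly$wrot_idx <- wrot_indices(ly$kernel, shape[3], ly$filters)
        fan_in <- ly$kernel^2 * shape[3]
        ly$W <- matrix(rnorm(fan_in * ly$filters, sd = sqrt(2 / fan_in)),
                       fan_in, ly$filters)
        ly$b <- numeric(ly$filters)
        shape <- c(ci$OH, ci$OW, ly$filters)
      } else if (ly$type == "dense") {
        stopifnot(length(shape) == 1L)
        ly$W <- matrix(rnorm(shape * ly$units, sd = sqrt(2 / shape)),
                       shape, ly$units)
        ly$b <- numeric(ly$units)
        shape <- ly$units
      } else if (ly$type == "flatten") {
        shape <- as.integer(prod(shape))
      } else if (ly$type == "avgpool") {
        s <- ly$size
        shape <- c(shape[1] %/% s, shape[2] %/% s, shape[3])
        stopifnot(all(shape >= 1L))
      } else if (ly$type == "gap") {
        shape <- shape[3]
      }
      # relu, dropout, softmax keep the shape
      ly$out_shape <- shape
      built[[i]] <- ly
    }
    structure(list(layers = built, input_shape = input_shape,
                   output_shape = shape, scratch = new.env(parent = emptyenv())),
              class = "drh_network")
  })
}

#' @export
print.drh_network <- function(x, ...) {
  cat("<drh_network> input", paste(x$input_shape, collapse = "x"),
      "->", paste(x$output_shape, collapse = "x"),
      "(", nn_n_params(x), "trainable parameters )\n")
  for (ly in x$layers)
    cat(sprintf("  %-8s -> %s\n", ly$type,
                paste(ly$out_shape, collapse = "x")))
  invisible(x)
}

#' Number of trainable parameters of a network
#' @param net A network as returned by the model builders.
#' @return Integer parameter count (weights plus biases).
#' @noRd
nn_n_params <- function(net) {
  as.integer(sum(vapply(net$layers, function(ly)
    if (!is.null(ly$W)) length(ly$W) + length(ly$b) else 0L, numeric(1))))
}

# Gather indices are cached per layer and batch size, laid out directly in
# the (P*B) x K order the matrix product wants, so each call is a single
# vector gather with no transposition.
#' @noRd
conv_im2col <- function(xp_vec, geom, B, img_len, scratch, key) {
  idx_key <- paste0(key, "_B", B)
  IDX <- scratch[[idx_key]]
  if (is.null(IDX)) {
    IDX <- geom$idx[rep(seq_len(geom$P), B), , drop = FALSE] +
      rep((seq_len(B) - 1L) * img_len, each = geom$P)
    scratch[[idx_key]] <- IDX
  }
  X <- xp_vec[IDX]
  dim(X) <- dim(IDX)
  X
}

#' @noRd
conv_forward <- function(ly, x, scratch, key) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; B <- d[4]
  g <- ly$geom; p <- ly$pad
  if (p > 0L) {
    xp <- array(0, c(g$Hp, g$Wp, C, B))
    xp[(p + 1):(p + H), (p + 1):(p + W), , ] <- x
  } else xp <- x
  X <- conv_im2col(as.vector(xp), g, B, g$Hp * g$Wp * C, scratch, key)
  Y <- add_bias(X %*% ly$W, ly$b)
  Fo <- ly$filters
  dim(Y) <- c(g$P, B, Fo)
  out <- aperm(Y, c(1L, 3L, 2L))
  dim(out) <- c(g$OH, g$OW, Fo, B)
  list(out = out, cache = list(X = X, B = B, C = C, H = H, W = W))
}

# Row/column permutation mapping the forward kernel matrix
# ((k*k*Cin) x F, rows ordered dh,dw,cin) onto the rotated, transposed
# kernel ((k*k*F) x Cin) of the input-gradient convolution.
#' @noRd
wrot_indices <- function(k, C, F_) {
  dhp <- rep(seq_len(k), times = k * F_)
  dwp <- rep(rep(seq_len(k), each = k), times = F_)
  f <- rep(seq_len(F_), each = k * k)
  base <- (k + 1L - dhp) + k * (k - dwp) + k * k * C * (f - 1L)
  matrix(base, k * k * F_, C) +
    rep(k * k * (seq_len(C) - 1L), each = k * k * F_)
}

#' @noRd
conv_backward <- function(ly, dout, cache, scratch, key, need_dx = TRUE) {
  g <- ly$geom; B <- cache$B; C <- cache$C
  k <- ly$kernel; Fo <- ly$filters
  dim(dout) <- c(g$P, Fo, B)
  dmat <- aperm(dout, c(1L, 3L, 2L))
  dim(dmat) <- c(g$P * B, Fo)
  dW <- crossprod(cache$X, dmat)
  db <- colSums(dmat)
  dx <- NULL
  if (need_dx) {
    # dx = full correlation of dY with the rotated kernel
    gb <- ly$geom_bw
    pb <- k - 1L - ly$pad
    dim(dout) <- c(g$OH, g$OW, Fo, B)
    if (pb > 0L) {
      dyp <- array(0, c(gb$Hp, gb$Wp, Fo, B))
      dyp[(pb + 1):(pb + g$OH), (pb + 1):(pb + g$OW), , ] <- dout
    } else dyp <- dout
    Dcol <- conv_im2col(as.vector(dyp), gb, B, gb$Hp * gb$Wp * Fo,
                        scratch, paste0(key, "bw"))
    Wrot <- matrix(ly$W[ly$wrot_idx], k * k * Fo, C)
    dxm <- Dcol %*% Wrot                        # (H*W*B) x C
    dim(dxm) <- c(gb$P, B, C)
    dxm <- aperm(dxm, c(1L, 3L, 2L))
    dim(dxm) <- c(cache$H, cache$W, C, B)
    dx <- dxm
  }
  list(dx = dx, dW = dW, db = db)
}

#' Forward pass.  Returns probabilities (if the last layer is softmax) and
#' per-layer caches for backprop when `training = TRUE`.
#' @noRd
nn_forward <- function(net, x, training = FALSE) {
  caches <- vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    ly <- net$layers[[i]]
    if (ly$type == "conv2d") {
      fw <- conv_forward(ly, x, net$scratch, paste0("L", i))
      x <- fw$out
      if (training) caches[[i]] <- fw$cache
    } else if (ly$type == "dense") {
      if (training) caches[[i]] <- list(X = x)
      x <- add_bias(x %*% ly$W, ly$b)
    } else if (ly$type == "relu") {
      if (training) caches[[i]] <- list(mask = x > 0)
      x <- pmax(x, 0)
    } else if (ly$type == "dropout") {
      if (training && ly$rate > 0) {
        mask <- array(runif(length(x)) >= ly$rate, dim = dim(x) %||% length(x))
        caches[[i]] <- list(mask = mask)
        x <- x * mask / (1 - ly$rate)
      }
    } else if (ly$type == "flatten") {
      d <- dim(x); B <- d[length(d)]
      if (training) caches[[i]] <- list(d = d)
      dim(x) <- c(prod(d) / B, B)
      x <- t(x)
    } else if (ly$type == "avgpool") {
      s <- ly$size; d <- dim(x)
      Ho <- d[1] %/% s; Wo <- d[2] %/% s
      xt <- x[seq_len(Ho * s), seq_len(Wo * s), , , drop = FALSE]
      dim(xt) <- c(s, Ho * Wo * s * d[3] * d[4])
      y1 <- colMeans(xt)                        # rows pooled
      dim(y1) <- c(Ho, Wo * s, d[3], d[4])
      y1 <- aperm(y1, c(2L, 1L, 3L, 4L))        # (Wo*s, Ho, C, B)
      dim(y1) <- c(s, Wo * Ho * d[3] * d[4])
      y2 <- colMeans(y1)
      dim(y2) <- c(Wo, Ho, d[3], d[4])
      x2 <- aperm(y2, c(2L, 1L, 3L, 4L))        # (Ho, Wo, C, B)
      if (training) caches[[i]] <- list(d = d, Ho = Ho, Wo = Wo)
      x <- x2
    } else if (ly$type == "gap") {
      d <- dim(x)
      xm <- x; dim(xm) <- c(d[1] * d[2], d[3] * d[4])
      m <- colMeans(xm); dim(m) <- c(d[3], d[4])
      if (training) caches[[i]] <- list(d = d)
      x <- t(m)                                  # B x C
    } else if (ly$type == "softmax") {
      z <- x - apply(x, 1L, max)
      e <- exp(z)
      x <- e / rowSums(e)
      if (training) caches[[i]] <- list(p = x)
    } else stop_drh("unknown layer type ", ly$type)
  }
  list(out = x, caches = caches)
}

# Backward pass from dL/d(probabilities).  Returns per-layer gradients.
#' @noRd
nn_backward <- function(net, caches, dprob) {
  n <- length(net$layers)
  grads <- vector("list", n)
  d <- dprob
  for (i in rev(seq_len(n))) {
    ly <- net$layers[[i]]
    cache <- caches[[i]]
    if (ly$type == "softmax") {
      p <- cache$p
      d <- p * (d - rowSums(d * p))
    } else if (ly$type == "dense") {
      grads[[i]] <- list(dW = crossprod(cache$X, d), db = colSums(d))
      d <- tcrossprod(d, ly$W)
    } else if (ly$type == "conv2d") {
      bk <- conv_backward(ly, d, cache, net$scratch, paste0("L", i),
                          need_dx = i > 1L)
      grads[[i]] <- list(dW = bk$dW, db = bk$db)
      d <- bk$dx
    } else if (ly$type == "relu") {
      d <- d * cache$mask
    } else if (ly$type == "dropout") {
      if (!is.null(cache)) d <- d * cache$mask / (1 - ly$rate)
    } else if (ly$type == "flatten") {
      d <- t(d)
      dim(d) <- cache$d
    } else if (ly$type == "avgpool") {
      s <- ly$size; dd <- cache$d
      dg <- d / (s * s)
      up <- dg[rep(seq_len(cache$Ho), each = s), , , , drop = FALSE]
      up <- up[, rep(seq_len(cache$Wo), each = s), , , drop = FALSE]
      if (cache$Ho * s == dd[1] && cache$Wo * s == dd[2]) {
        d <- up
      } else {
        full <- array(0, dd)
        full[seq_len(cache$Ho * s), seq_len(cache$Wo * s), , ] <- up
        d <- full
      }
    } else if (ly$type == "gap") {
      dd <- cache$d
      v <- t(d) / (dd[1] * dd[2])               # C x B
      d <- array(rep(as.vector(v), each = dd[1] * dd[2]), dd)
    }
  }
  grads
}

# ---- optimizers -----------------------------------------------------------

#' @noRd
opt_init <- function(net) {
  lapply(net$layers, function(ly) {
    if (is.null(ly$W)) return(NULL)
    list(mW = ly$W * 0, vW = ly$W * 0, mb = ly$b * 0, vb = ly$b * 0)
  })
}

# One Adam / RAdam update over all parameters; returns list(net, state).
# RAdam applies the variance rectification of the rectified-Adam scheme and
# falls back to momentum SGD while the rectification term is undefined.
#' @noRd
opt_step <- function(net, grads, state, t, lr, method = c("adam", "radam"),
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  method <- match.arg(method)
  b1t <- beta1^t; b2t <- beta2^t
  if (method == "radam") {
    rho_inf <- 2 / (1 - beta2) - 1
    rho_t <- rho_inf - 2 * t * b2t / (1 - b2t)
    rect <- rho_t > 4
    r_t <- if (rect)
      sqrt((rho_t - 4) * (rho_t - 2) * rho_inf /
           ((rho_inf - 4) * (rho_inf - 2) * rho_t)) else NA_real_
  }
  upd <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    mhat <- m / (1 - b1t)
    if (method == "adam") {
      p <- p - lr * mhat / (sqrt(v / (1 - b2t)) + eps)
    } else if (rect) {
      p <- p - lr * r_t * mhat / (sqrt(v / (1 - b2t)) + eps)
    } else {
      p <- p - lr * mhat
    }
    list(p = p, m = m, v = v)
  }
  for (i in seq_along(net$layers)) {
    if (is.null(grads[[i]])) next
    st <- state[[i]]
    uW <- upd(net$layers[[i]]$W, grads[[i]]$dW, st$mW, st$vW)
    ub <- upd(net$layers[[i]]$b, grads[[i]]$db, st$mb, st$vb)
    net$layers[[i]]$W <- uW$p
    net$layers[[i]]$b <- ub$p
    state[[i]] <- list(mW = uW$m, vW = uW$v, mb = ub$m, vb = ub$v)
  }
  list(net = net, state = state)
}

# ---- training -------------------------------------------------------------

#' Training configuration
#'
#' @param optimizer_name `"adam"` or `"radam"` (rectified Adam, used for the
#'   base classifiers).
#' @param initial_learning_rate Initial step size; the published settings
#'   are 8e-4 (base models, RAdam) and 1e-3 (fusers, Adam).
#' @param epochs Number of passes over the training data.
#' @param loss_name `"ce"` or `"ece"`.
#' @param penalty_mode Penalty mode for `"ece"`; see [loss_config()].
#' @param batch_size Mini-batch size.
#' @param seed Integer seed controlling initial shuffling and dropout; the
#'   same seed reproduces the run exactly.
#' @param lr_schedule Reduce-on-plateau parameters monitoring the training
#'   loss: `factor` (multiplier), `patience` (epochs without improvement),
#'   `min_lr` (floor), `min_delta` (improvement threshold).
#' @return A list with class `drh_train_config`.
#' @export
train_config <- function(optimizer_name = c("adam", "radam"),
                         initial_learning_rate = 1e-3,
                         epochs = 10L, loss_name = c("ce", "ece"),
                         penalty_mode = c("hard", "soft"),
                         batch_size = 32L, seed = 1L,
                         lr_schedule = list(factor = 0.5, patience = 3L,
                                            min_lr = 1e-6, min_delta = 1e-4)) {
  optimizer_name <- match.arg(optimizer_name)
  loss_name <- match.arg(loss_name)
  penalty_mode <- match.arg(penalty_mode)
  if (!is_count(epochs) || epochs < 1) stop_drh("epochs must be >= 1")
  if (initial_learning_rate <= 0) stop_drh("learning rate must be > 0")
  sched <- modifyList(list(factor = 0.5, patience = 3L, min_lr = 1e-6,
                           min_delta = 1e-4), lr_schedule %||% list())
  structure(list(optimizer_name = optimizer_name,
                 initial_learning_rate = initial_learning_rate,
                 epochs = as.integer(epochs), loss_name = loss_name,
                 penalty_mode = penalty_mode,
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 lr_schedule = sched),
            class = "drh_train_config")
}

#' @noRd
slice_batch <- function(x, idx) {
  if (is.matrix(x)) x[idx, , drop = FALSE] else x[, , , idx, drop = FALSE]
}

#' @noRd
n_samples <- function(x) if (is.matrix(x)) nrow(x) else dim(x)[4L]

# Core training loop shared by the basic models and the learned fusers.
#' @noRd
nn_train <- function(net, x, grades, cfg, augment_fn = NULL) {
  grades <- check_grades(grades, "labels")
  n <- n_samples(x)
  if (n == 0L) stop_drh("training set is empty")
  if (length(grades) != n) stop_drh("labels do not match the input batch")
  n_out <- net$output_shape
  Y <- one_hot(grades, n_out)
  if (is.null(dim(Y))) Y <- matrix(Y, 1L)
  lcfg <- loss_config(n_grades = n_out, penalty_mode = cfg$penalty_mode)
  state <- opt_init(net)
  lr <- cfg$initial_learning_rate
  sched <- cfg$lr_schedule
  best <- Inf; wait <- 0L; t <- 0L
  hist <- vector("list", cfg$epochs)
  set.seed(cfg$seed)
  for (ep in seq_len(cfg$epochs)) {
    idx <- sample.int(n)
    starts <- seq(1L, n, by = cfg$batch_size)
    tot_loss <- 0; tot_ce <- 0
    for (s in starts) {
      bi <- idx[s:min(s + cfg$batch_size - 1L, n)]
      xb <- slice_batch(x, bi)
      if (!is.null(augment_fn)) xb <- augment_fn(xb)
      yb <- Y[bi, , drop = FALSE]
      fw <- nn_forward(net, xb, training = TRUE)
      p <- fw$out
      lv <- loss_value(yb, p, lcfg, cfg$loss_name)
      g <- loss_grad_prob(yb, p, lcfg, cfg$loss_name)
      grads <- nn_backward(net, fw$caches, g)
      t <- t + 1L
      st <- opt_step(net, grads, state, t, lr, cfg$optimizer_name)
      net <- st$net; state <- st$state
      nb <- length(bi)
      tot_loss <- tot_loss + lv$total * nb
      tot_ce <- tot_ce + lv$ce * nb
    }
    ep_loss <- tot_loss / n
    # training accuracy at epoch end, with dropout inactive
    pe <- nn_predict(net, x, batch_size = max(cfg$batch_size, 256L))
    acc <- mean(max.col(pe, ties.method = "first") - 1L == grades)
    hist[[ep]] <- data.frame(epoch = ep, loss = ep_loss, ce_loss = tot_ce / n,
                             accuracy = acc, lr = lr)
    if (ep_loss < best - sched$min_delta) {
      best <- ep_loss; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= sched$patience) {
        lr <- max(lr * sched$factor, sched$min_lr)
        wait <- 0L
      }
    }
  }
  list(net = net, history = do.call(rbind, hist))
}

#' @noRd
nn_predict <- function(net, x, batch_size = 256L) {
  n <- n_samples(x)
  if (n == 0L) return(matrix(numeric(0), 0L, net$output_shape))
  starts <- seq(1L, n, by = batch_size)
  out <- lapply(starts, function(s) {
    bi <- s:min(s + batch_size - 1L, n)
    nn_forward(net, slice_batch(x, bi), training = FALSE)$out
  })
  do.call(rbind, out)
}
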