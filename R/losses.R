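#' Loss configuration
#'
#' Bundles the knobs shared by [ce_loss()], [grade_penalty()] and
#' [ece_loss()].  Note that the number of severity grades (`n_grades`) is a
#' different quantity from the number of base models fused by the hybrid
#' module; the two are deliberately kept as separate configuration fields.
#'
#' @param n_grades Number of severity grades (the `N` of the loss formulas);
#'   5 for the 0--4 DR scale.
#' @param epsilon Clip bound applied to predicted probabilities before
#'   taking logarithms, so that degenerate one-hot predictions yield a
#'   finite loss.  Must lie in (0, 0.5).
#' @param penalty_mode How the ordinal grade penalty is computed:
#'   `"hard"` uses the arg-max predicted grade (piecewise constant, no
#'   gradient; the published formulation), `"soft"` uses the expected grade
#'   under the predicted distribution (a differentiable surrogate that is an
#'   extension of this package, not part of the published method), `"off"`
#'   disables the penalty.
#' @param reduction Batch reduction; only `"mean"` is supported.
#' @return A list with class `drh_loss_config`.
#' @export
#' @examples
#' cfg <- loss_config()
#' ce_loss(one_hot(0), c(0.2, 0.2, 0.2, 0.2, 0.2), cfg)
loss_config <- function(n_grades = 5L, epsilon = 1e-7,
                        penalty_mode = c("hard", "soft", "off"),
                        reduction = "mean") {
  penalty_mode <- match.arg(penalty_mode)
  if (!is_count(n_grades) || n_grades < 2)
    stop_drh("n_grades must be an integer >= 2")
  if (!is.numeric(epsilon) || epsilon <= 0 || epsilon >= 0.5)
    stop_drh("epsilon must lie in (0, 0.5)")
  if (!identical(reduction, "mean"))
    stop_drh("only reduction = 'mean' is supported")
  structure(list(n_grades = as.integer(n_grades), epsilon = epsilon,
                 penalty_mode = penalty_mode, reduction = reduction),
            class = "drh_loss_config")
}

#' One-hot label encoding of a severity grade
#'
#' @param grade Integer grade(s) in `0..(n_grades-1)`.
#' @param n_grades Number of grades.
#' @return For a single grade, a numeric vector with a 1 at position
#'   `grade + 1`; for several grades, a matrix with one row per grade.
#' @export
one_hot <- function(grade, n_grades = 5L) {
  grade <- check_grades_n(grade, n_grades)
  m <- matrix(0, length(grade), n_grades)
  m[cbind(seq_along(grade), grade + 1L)] <- 1
  if (nrow(m) == 1L) drop(m) else m
}

#' @noRd
check_grades_n <- function(grade, n_grades) {
  if (any(is.na(grade)) || any(grade != as.integer(grade)) ||
      any(grade < 0) || any(grade >= n_grades))
    stop_drh("grade must be an integer in 0..", n_grades - 1)
  as.integer(grade)
}

# Coerce y / yhat to conforming row-matrices of width n_grades.
#' @noRd
as_prob_matrix <- function(x, n_grades, arg) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  if (ncol(x) != n_grades)
    stop_drh(arg, " must have ", n_grades, " columns, got ", ncol(x))
  x
}

#' @noRd
check_prob_rows <- function(p, tol = 1e-6) {
  if (any(p < -tol) || any(p > 1 + tol))
    stop_drh("probabilities must lie in [0, 1]")
  s <- rowSums(p)
  if (any(abs(s - 1) > tol))
    stop_drh("probability rows must sum to 1 (tolerance ", tol, ")")
  invisible(p)
}

# grade encoded by one-hot rows
#' @noRd
grade_of_onehot <- function(y) max.col(y, ties.method = "first") - 1L

#' Component-wise cross-entropy loss
#'
#' The loss used here treats the 5-way softmax output as five per-grade
#' binary predictions and averages their binary cross-entropies:
#' \deqn{L(\hat y, y) = -\frac{1}{N}\sum_{n=1}^{N}
#'   \big[y_n \log \hat y_n + (1-y_n)\log(1-\hat y_n)\big],}
#' with natural logarithms and `N = n_grades`.  This is *not* the usual
#' categorical cross-entropy \eqn{-\log \hat y_{true}}; the component-wise
#' form is implemented deliberately, as published.  Probabilities are
#' clipped to `[epsilon, 1 - epsilon]` before the logarithms.
#'
#' @param y True labels: a one-hot vector, a matrix of one-hot rows, or
#'   (equivalently) integer grades which are encoded internally.
#' @param yhat Predicted probabilities: vector or matrix conforming with
#'   `y`; each row must be non-negative and sum to 1 within 1e-6.
#' @param cfg A [loss_config()].
#' @return The mean loss over the batch (a non-negative scalar).
#' @seealso [ece_loss()] for the ordinal-penalty variant.
#' @export
ce_loss <- function(y, yhat, cfg = loss_config()) {
  N <- cfg$n_grades
  if (is.null(dim(y)) && length(y) != N && all(y == as.integer(y)))
    y <- one_hot(y, N)
  y <- as_prob_matrix(y, N, "y")
  yhat <- as_prob_matrix(yhat, N, "yhat")
  if (nrow(y) != nrow(yhat))
    stop_drh("y and yhat have different numbers of rows")
  check_prob_rows(yhat)
  p <- pmin(pmax(yhat, cfg$epsilon), 1 - cfg$epsilon)
  per_sample <- -rowMeans(y * log(p) + (1 - y) * log1p(-p))
  mean(per_sample)
}

#' Predicted grade from a probability vector
#'
#' Returns the arg-max grade; ties are broken toward the lowest grade so
#' the result is deterministic.
#'
#' @param yhat A probability vector of length `n_grades`, or a matrix with
#'   one such row per sample.
#' @return Integer grade(s) in `0..(n_grades-1)`.
#' @export
predicted_grade <- function(yhat) {
  if (is.null(dim(yhat))) yhat <- matrix(yhat, nrow = 1L)
  g <- max.col(as.matrix(yhat), ties.method = "first") - 1L
  if (length(g) == 1L) g[[1L]] else g
}

#' Normalised ordinal grade penalty
#'
#' The distance between the true grade \eqn{G_y} and the predicted grade
#' \eqn{G_{\hat y}}, normalised by the maximal distance `n_grades - 1` so
#' the penalty lies in `[0, 1]`.  In `"hard"` mode the predicted grade is
#' the arg-max (so for 5 grades the penalty takes only the values
#' 0, 0.25, 0.5, 0.75, 1); in `"soft"` mode it is the expected grade
#' \eqn{\sum_g g\,\hat y_g}, a differentiable surrogate.
#'
#' @inheritParams ce_loss
#' @return Mean penalty over the batch, in `[0, 1]`.
#' @export
grade_penalty <- function(y, yhat, cfg = loss_config()) {
  if (cfg$penalty_mode == "off")
    stop_drh("grade_penalty requires penalty_mode 'hard' or 'soft'")
  N <- cfg$n_grades
  if (is.null(dim(y)) && length(y) != N && all(y == as.integer(y)))
    y <- one_hot(y, N)
  y <- as_prob_matrix(y, N, "y")
  yhat <- as_prob_matrix(yhat, N, "yhat")
  gy <- grade_of_onehot(y)
  if (cfg$penalty_mode == "hard") {
    ghat <- max.col(as.matrix(yhat), ties.method = "first") - 1L
  } else {
    ghat <- as.vector(yhat %*% (seq_len(N) - 1))
  }
  mean(abs(gy - ghat)) / (N - 1)
}

#' Enhance cross-entropy (ordinal-penalty) loss
#'
#' [ce_loss()] plus the non-negative [grade_penalty()].  The farther the
#' predicted grade is from the true grade, the larger the extra loss; a
#' correctly graded sample incurs no penalty, so the loss then equals the
#' plain cross-entropy exactly.  In `"hard"` mode the penalty is piecewise
#' constant in the model output and therefore contributes no gradient;
#' gradients flow only through the cross-entropy term (the penalty still
#' changes the reported loss and anything driven by it, such as a
#' loss-monitoring learning-rate schedule).
#'
#' @inheritParams ce_loss
#' @return Mean loss over the batch.
#' @export
#' @examples
#' cfg <- loss_config(penalty_mode = "hard")
#' ece_loss(one_hot(2), c(0.6, 0.1, 0.1, 0.1, 0.1), cfg)  # 0.7070 + 0.5
ece_loss <- function(y, yhat, cfg = loss_config()) {
  mode <- if (cfg$penalty_mode == "off") "hard" else cfg$penalty_mode
  pen_cfg <- cfg
  pen_cfg$penalty_mode <- mode
  ce_loss(y, yhat, cfg) + grade_penalty(y, yhat, pen_cfg)
}

# Gradient of the batch-mean loss with respect to the predicted
# probabilities.  Used by the training engine; the hard penalty is detached
# (zero gradient), the soft penalty differentiates the expected grade.
#' @noRd
loss_grad_prob <- function(y, p, cfg, loss = c("ce", "ece")) {
  loss <- match.arg(loss)
  N <- cfg$n_grades
  B <- nrow(p)
  pc <- pmin(pmax(p, cfg$epsilon), 1 - cfg$epsilon)
  g <- -(y / pc - (1 - y) / (1 - pc)) / (N * B)
  # no gradient where clipping is active
  g[(p < cfg$epsilon & y < 0.5) | (p > 1 - cfg$epsilon & y > 0.5)] <- 0
  if (loss == "ece" && cfg$penalty_mode == "soft") {
    gy <- grade_of_onehot(y)
    s <- as.vector(p %*% (seq_len(N) - 1))
    sgn <- sign(s - gy)
    g <- g + outer(sgn, seq_len(N) - 1) / ((N - 1) * B)
  }
  g
}

# Batch loss value on probability matrix p; returns total and CE component.
#' @noRd
loss_value <- function(y, p, cfg, loss = c("ce", "ece")) {
  loss <- match.arg(loss)
  ce <- ce_loss(y, p, cfg)
  if (loss == "ce") return(list(total = ce, ce = ce))
  mode <- if (cfg$penalty_mode == "off") "hard" else cfg$penalty_mode
  pen_cfg <- cfg
  pen_cfg$penalty_mode <- mode
  list(total = ce + grade_penalty(y, p, pen_cfg), ce = ce)
}
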