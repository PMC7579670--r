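# Synthetic data: fundus-like disc images whose lesion load tracks the
# severity grade, and base-model probability outputs with a controllable
# ordinal confusion structure.  Everything is deterministic given a seed,
# so the whole pipeline is testable at desk scale without downloads.

#' Grade imbalance profile
#'
#' Class proportions for the five severity grades.  The default reproduces
#' the strongly imbalanced grade distribution of the 39,988-image fundus
#' corpus the method was evaluated on (70.41% grade 0, 7.38% grade 1,
#' 16.32% grade 2, 3.2% grade 3, 2.69% grade 4).
#'
#' @param proportions Numeric vector of 5 non-negative proportions summing
#'   to 1 (within 1e-6; renormalised exactly).
#' @return A list with class `drh_imbalance_profile`.
#' @export
imbalance_profile <- function(proportions = c(0.7041, 0.0738, 0.1632,
                                              0.032, 0.0269)) {
  if (length(proportions) != 5L || any(proportions < 0))
    stop_drh("proportions must be 5 non-negative values")
  if (abs(sum(proportions) - 1) > 1e-6)
    stop_drh("proportions must sum to 1")
  structure(list(proportions = proportions / sum(proportions)),
            class = "drh_imbalance_profile")
}

#' Reference grade-distribution counts
#'
#' The per-source image counts by severity grade for the full-scale corpus
#' (three public fundus datasets), shipped as a plain-text fixture.  Used
#' for bookkeeping checks and as the source of the default
#' [imbalance_profile()].
#'
#' @return Data frame with columns `dataset`, `g0`..`g4`.
#' @export
grade_distribution_counts <- function() {
  read.csv(system.file("extdata", "grade_distribution_counts.csv",
                       package = "drhybrid"), stringsAsFactors = FALSE)
}

#' Reference confusion matrix of the convolutional fuser
#'
#' The published 5x5 confusion matrix (rows = actual grade, columns =
#' predicted grade) of the convolutional fuser evaluated on 5,000 held-out
#' fundus images, shipped as a plain-text fixture.  Feeding it to the
#' metrics module reproduces the published metric row exactly.
#'
#' @return A `confusion_matrix` (5x5 integer matrix).
#' @export
reference_confusion_matrix <- function() {
  m <- as.matrix(read.csv(system.file("extdata", "hybridc_confusion_counts.csv",
                                      package = "drhybrid"), row.names = 1))
  m <- matrix(as.integer(m), 5L, 5L, dimnames = list(actual = 0:4,
                                                     predicted = 0:4))
  structure(m, class = c("confusion_matrix", class(m)))
}

#' Generate a synthetic fundus-like image
#'
#' Emulates the geometry the preprocessing stage relies on: a black border,
#' a centred bright circular disc occupying a random 60--90% of the frame,
#' and lesion-like blobs inside the disc whose number and size increase
#' monotonically with the grade (bright exudate-like spots and dark
#' haemorrhage-like spots).  Grade 0 has no blobs.  Rendering is
#' deliberately simple — the generator exists to exercise the pipeline's
#' contracts, not to look photorealistic.
#'
#' The true disc bounding box (0-based half-open) is attached as attribute
#' `disc_bbox` of the returned image for cropping tests.
#'
#' @param grade Integer severity grade 0--4.
#' @param size Square image size in pixels (`>= 64`).
#' @param seed Optional integer seed; the same seed reproduces the image.
#' @return A [graded_image()].
#' @export
gen_fundus_image <- function(grade, size = 64L, seed = NULL) {
  grade <- check_grades(grade, "grade")
  if (size < 64L) stop_drh("size must be >= 64")
  with_seed_opt(seed, {
    s <- as.integer(size)
    extent <- runif(1, 0.6, 0.9)
    r <- extent * s / 2
    cx <- s / 2 + runif(1, -0.02, 0.02) * s
    cy <- s / 2 + runif(1, -0.02, 0.02) * s
    xg <- matrix(rep(seq_len(s), each = s), s)   # column index
    yg <- matrix(rep(seq_len(s), times = s), s)  # row index
    dist2 <- (xg - cx)^2 + (yg - cy)^2
    disc <- dist2 <= r^2
    # radial shading of the retinal background
    shade <- 1 - 0.35 * sqrt(pmin(dist2, r^2)) / r
    base <- c(205, 120, 55)                      # orange retina tone
    px <- array(0, c(s, s, 3L))
    for (ch in 1:3)
      px[, , ch][disc] <- base[ch] * shade[disc] +
        rnorm(sum(disc), sd = 4)
    # lesions: counts and radii grow with grade
    n_bright <- grade * 2L
    n_dark <- grade * 2L
    put_blob <- function(px, colour, radius) {
      ang <- runif(1, 0, 2 * pi)
      rad <- runif(1, 0, max(0.01, 0.75 * r - radius))
      bx <- cx + rad * cos(ang); by <- cy + rad * sin(ang)
      blob <- (xg - bx)^2 + (yg - by)^2 <= radius^2
      for (ch in 1:3) px[, , ch][blob] <- colour[ch]
      px
    }
    if (grade > 0L) {
      for (i in seq_len(n_bright))
        px <- put_blob(px, c(250, 240, 190),
                       runif(1, 0.025 + 0.012 * grade,
                             0.035 + 0.018 * grade) * s)
      for (i in seq_len(n_dark))
        px <- put_blob(px, c(80, 20, 15),
                       runif(1, 0.025 + 0.012 * grade,
                             0.035 + 0.018 * grade) * s)
    }
    px <- pmin(pmax(px, 0), 255)
    # true disc extent, recorded from the rendered mask
    rows <- which(rowSums(disc) > 0); cols <- which(colSums(disc) > 0)
    img <- graded_image(px, grade,
                        source_id = sprintf("synthetic_g%d", grade))
    attr(img, "disc_bbox") <- c(row_min = rows[1L] - 1L,
                                row_max = rows[length(rows)],
                                col_min = cols[1L] - 1L,
                                col_max = cols[length(cols)])
    img
  })
}

#' Draw severity grades from an imbalance profile
#'
#' @param n Number of labels (`>= 1`).
#' @param profile An [imbalance_profile()].
#' @param seed Optional integer seed.
#' @return Integer vector of grades 0--4.
#' @export
gen_labels <- function(n, profile = imbalance_profile(), seed = NULL) {
  if (!is_count(n) || n < 1) stop_drh("n must be >= 1")
  if (!inherits(profile, "drh_imbalance_profile"))
    stop_drh("profile must come from imbalance_profile()")
  with_seed_opt(seed,
    sample(0:4, n, replace = TRUE, prob = profile$proportions))
}

#' Generate a synthetic image dataset with manifest
#'
#' Writes `n` synthetic fundus images (PNG) and a `manifest.csv` into
#' `out_dir`.
#'
#' @param n Number of images.
#' @param out_dir Output directory.
#' @param profile Grade [imbalance_profile()].
#' @param size Image size.
#' @param seed Integer seed (required, for reproducible corpora).
#' @return Path of the manifest, invisibly.
#' @export
gen_fundus_dataset <- function(n, out_dir, profile = imbalance_profile(),
                               size = 64L, seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  grades <- gen_labels(n, profile, seed = seed)
  paths <- character(n)
  for (i in seq_len(n)) {
    img <- gen_fundus_image(grades[i], size, seed = seed + i)
    paths[i] <- sprintf("img_%05d_g%d.png", i, grades[i])
    write_image(img$pixels, file.path(out_dir, paths[i]))
  }
  mpath <- file.path(out_dir, "manifest.csv")
  write_manifest(data.frame(image_path = paths, grade = grades), mpath)
  invisible(mpath)
}

#' Simulation settings for synthetic base-model outputs
#'
#' Describes an ensemble of `n_models` imperfect graders whose errors have
#' the ordinal structure observed in practice: misclassifications
#' concentrate on adjacent grades and decay geometrically with grade
#' distance.
#'
#' @param n_models Number of base models `M`.
#' @param per_model_accuracy Probability that a model's arg-max grade is
#'   the true grade; must lie in (0.2, 1).
#' @param ordinal_spread Decay scale of confusion mass with grade distance;
#'   the off-diagonal kernel weight at distance `d` is proportional to
#'   `exp(-d / ordinal_spread)`.  Must be `> 0`.
#' @param concentration Dirichlet weight on the sampled grade.  The
#'   probability vector for a sample is drawn from
#'   `Dirichlet(concentration * onehot(grade) + tail_alpha * kernel)`, so
#'   `concentration -> Inf` gives one-hot vectors; the default 28 together
#'   with `tail_alpha = 12` puts a mean of 28/40 = 0.7 on the sampled
#'   grade, resembling plausible softmax outputs.
#' @param tail_alpha Fixed Dirichlet weight spread over the other grades
#'   with the same ordinal decay.
#' @param seed Integer seed.
#' @return A list with class `drh_sim_spec`.
#' @export
base_model_sim_spec <- function(n_models = 5L, per_model_accuracy = 0.8,
                                ordinal_spread = 0.8, concentration = 28,
                                tail_alpha = 12, seed = 1L) {
  if (!is_count(n_models) || n_models < 1) stop_drh("n_models must be >= 1")
  if (per_model_accuracy <= 0.2 || per_model_accuracy >= 1)
    stop_drh("per_model_accuracy must lie in (0.2, 1)")
  if (ordinal_spread <= 0) stop_drh("ordinal_spread must be > 0")
  if (concentration <= 0 || tail_alpha < 0)
    stop_drh("concentration must be > 0 and tail_alpha >= 0")
  structure(list(n_models = as.integer(n_models),
                 per_model_accuracy = per_model_accuracy,
                 ordinal_spread = ordinal_spread,
                 concentration = concentration, tail_alpha = tail_alpha,
                 seed = as.integer(seed)),
            class = "drh_sim_spec")
}

# P(predicted = g | true = t) for g = 0..4: `acc` on the diagonal, the
# remaining mass spread over g != t with geometric decay in |g - t|.
#' @noRd
ordinal_kernel <- function(true_grade, acc, spread, n_grades = 5L) {
  g <- seq_len(n_grades) - 1L
  w <- exp(-abs(g - true_grade) / spread)
  w[true_grade + 1L] <- 0
  p <- (1 - acc) * w / sum(w)
  p[true_grade + 1L] <- acc
  p
}

#' Generate synthetic base-model probability outputs
#'
#' For every label and every model, a predicted grade is drawn from the
#' ordinal confusion kernel (correct with probability
#' `per_model_accuracy`, errors decaying geometrically with grade
#' distance), and a probability vector concentrated on that grade is then
#' drawn from a Dirichlet distribution whose mean puts 70% of the mass on
#' the sampled grade and spreads the rest with the same ordinal decay.
#' Model errors are independent across models, which is what gives an
#' ensemble fuser room to improve on every single model.
#'
#' @param labels Integer vector of true grades 0--4.
#' @param spec A [base_model_sim_spec()].
#' @return A `base_outputs_set`: list with `probs` (an
#'   `n x n_models x 5` array), `grades`, and `model_order`.  Use
#'   [base_outputs_at()] to extract one sample's `base_outputs` object.
#' @export
gen_base_outputs <- function(labels, spec = base_model_sim_spec()) {
  grades <- check_grades(labels, "labels")
  n <- length(grades); M <- spec$n_models
  kernels <- t(vapply(0:4, ordinal_kernel, numeric(5),
                      acc = spec$per_model_accuracy,
                      spread = spec$ordinal_spread))
  with_seed_opt(spec$seed, {
    # sampled arg-max grade for every (sample, model)
    u <- matrix(runif(n * M), n, M)
    cum <- t(apply(kernels, 1L, cumsum))
    pred <- matrix(0L, n, M)
    for (m in seq_len(M))
      pred[, m] <- max.col(u[, m] < cum[grades + 1L, , drop = FALSE],
                           ties.method = "first") - 1L
    # Dirichlet draw around each sampled grade: the concentration weight
    # sits on the grade itself, a fixed tail follows the ordinal decay
    alpha_rows <- t(vapply(0:4, function(g) {
      w <- exp(-abs(0:4 - g) / spec$ordinal_spread)
      w[g + 1L] <- 0
      spec$tail_alpha * w / sum(w) + spec$concentration * (0:4 == g)
    }, numeric(5)))
    alpha <- alpha_rows[as.vector(pred) + 1L, , drop = FALSE]
    gm <- matrix(rgamma(length(alpha), shape = alpha), nrow(alpha))
    probs <- gm / rowSums(gm)
    dim(probs) <- c(n, M, 5L)
    structure(list(probs = probs, grades = grades,
                   model_order = paste0("model_", seq_len(M)),
                   spec = spec),
              class = "base_outputs_set")
  })
}

#' @export
print.base_outputs_set <- function(x, ...) {
  cat(sprintf("<base_outputs_set> %d samples x %d models x 5 grades\n",
              length(x$grades), dim(x$probs)[2]))
  invisible(x)
}

#' Extract one sample's base-model outputs
#'
#' @param set A `base_outputs_set` from [gen_base_outputs()] or
#'   [read_outputs_csv()].
#' @param i Sample index.
#' @return A [base_outputs()] object (M x 5 matrix plus model order).
#' @export
base_outputs_at <- function(set, i) {
  base_outputs(matrix(set$probs[i, , ], dim(set$probs)[2], 5L),
               set$model_order)
}
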