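# Preprocessing of fundus photographs: black-border cropping, resizing,
# and the geometric training-time augmentations.

#' A graded fundus image
#'
#' The unit flowing through preprocessing and the base classifiers: an RGB
#' pixel array plus its integer severity grade.
#'
#' @param pixels `H x W x 3` numeric array, intensities in `[0, 255]`.
#' @param grade Integer severity grade 0--4.
#' @param source_id Opaque identifier (e.g. the source file name).
#' @return A list with class `graded_image`.
#' @export
graded_image <- function(pixels, grade, source_id = "") {
  d <- dim(pixels)
  if (is.null(d) || length(d) != 3L || d[3] != 3L || d[1] < 1L || d[2] < 1L)
    stop_drh("pixels must be a nonempty H x W x 3 array")
  if (min(pixels) < 0 || max(pixels) > 255)
    stop_drh("intensities must lie in [0, 255]")
  grade <- check_grades(grade, "grade")
  structure(list(pixels = pixels, grade = grade,
                 source_id = as.character(source_id)),
            class = "graded_image")
}

#' @export
print.graded_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<graded_image> %dx%d grade %d (%s)\n", d[1], d[2], x$grade,
              if (nzchar(x$source_id)) x$source_id else "unnamed"))
  invisible(x)
}

#' @noRd
as_pixels <- function(image) {
  if (inherits(image, "graded_image")) image$pixels
  else if (inherits(image, "crop_result")) image$pixels
  else image
}

#' Crop the uninformative black border of a fundus image
#'
#' Fundus photographs show a bright retinal disc on a black background; the
#' border carries no information and dilutes the features a classifier can
#' extract.  The image is binarised on its grayscale version (mean of the
#' three channels): pixels strictly above `intensity_threshold` are
#' foreground, and the tight bounding box of the foreground is cut out.
#'
#' The bounding box is reported in 0-based half-open coordinates
#' `(row_min, row_max_exclusive, col_min, col_max_exclusive)` of the source
#' image.  An image with no foreground pixel at all is rejected with an
#' `"empty fundus"` error rather than passed through.
#'
#' @param image A [graded_image()] or a raw `H x W x 3` pixel array.
#' @param intensity_threshold Binarisation threshold on the 0--255 grayscale
#'   scale; the default 10 tolerates JPEG noise inside nominally black
#'   borders.  Must satisfy `0 <= intensity_threshold < 255`.
#' @return A list with class `crop_result`: `pixels` (the cropped RGB
#'   content) and `bbox`.
#' @export
#' @examples
#' img <- gen_fundus_image(grade = 2, size = 64, seed = 1)
#' cr <- crop_black_border(img)
#' cr$bbox
crop_black_border <- function(image, intensity_threshold = 10) {
  px <- as_pixels(image)
  d <- dim(px)
  if (is.null(d) || length(d) != 3L || prod(d) == 0L)
    stop_drh("image must be a nonempty H x W x 3 array")
  if (intensity_threshold < 0 || intensity_threshold >= 255)
    stop_drh("intensity_threshold must satisfy 0 <= t < 255")
  gray <- (px[, , 1] + px[, , 2] + px[, , 3]) / 3
  fg <- gray > intensity_threshold
  rows <- which(rowSums(fg) > 0)
  cols <- which(colSums(fg) > 0)
  if (length(rows) == 0L)
    stop_drh("empty fundus: no pixel above the binarisation threshold",
             class = "drh_empty_fundus")
  r0 <- rows[1L]; r1 <- rows[length(rows)]
  c0 <- cols[1L]; c1 <- cols[length(cols)]
  structure(list(pixels = px[r0:r1, c0:c1, , drop = FALSE],
                 bbox = c(row_min = r0 - 1L, row_max = r1,
                          col_min = c0 - 1L, col_max = c1)),
            class = "crop_result")
}

#' Bilinear image resize
#'
#' @param pixels `H x W x C` array.
#' @param size Target `c(height, width)` (a single integer means square).
#' @return Resized array; the input is returned unchanged when it already
#'   has the target size.
#' @export
resize_bilinear <- function(pixels, size) {
  if (length(size) == 1L) size <- c(size, size)
  d <- dim(pixels)
  if (d[1] == size[1] && d[2] == size[2]) return(pixels)
  h <- size[1]; w <- size[2]
  # centre-aligned source coordinates, clamped to the frame
  sy <- pmin(pmax((seq_len(h) - 0.5) * d[1] / h + 0.5, 1), d[1])
  sx <- pmin(pmax((seq_len(w) - 0.5) * d[2] / w + 0.5, 1), d[2])
  i0 <- pmin(floor(sy), d[1] - 1L); fy <- sy - i0
  j0 <- pmin(floor(sx), d[2] - 1L); fx <- sx - j0
  if (d[1] == 1L) { i0 <- rep(1, h); fy <- rep(0, h) }
  if (d[2] == 1L) { j0 <- rep(1, w); fx <- rep(0, w) }
  out <- array(0, c(h, w, d[3]))
  fxr <- rep(fx, each = h)
  for (ch in seq_len(d[3])) {
    A <- pixels[, , ch]
    R0 <- A[i0, , drop = FALSE]
    R1 <- A[pmin(i0 + 1L, d[1]), , drop = FALSE]
    Rf <- R0 * (1 - fy) + R1 * fy
    C0 <- Rf[, j0, drop = FALSE]
    C1 <- Rf[, pmin(j0 + 1L, d[2]), drop = FALSE]
    out[, , ch] <- C0 * (1 - fxr) + C1 * fxr
  }
  out
}

#' Resize an image for a registered backbone
#'
#' Each backbone expects a fixed square input: 380 px for EfficientNetB4,
#' 331 px for NASNetLarge, 299 px for EfficientNetB5, Xception and
#' InceptionResNetV2, and the configured size of the `TinyCNN` test
#' backbone.  Interpolation is bilinear.
#'
#' @param pixels `H x W x 3` array.
#' @param model_name Name of a registered backbone; see
#'   [backbone_registry()].
#' @return `S x S x 3` array where `S` is the backbone's input size.
#' @export
resize_for_model <- function(pixels, model_name) {
  spec <- backbone_spec(model_name)
  resize_bilinear(as_pixels(pixels), spec$input_size)
}

#' Augmentation configuration
#'
#' Maximum magnitudes for the training-time geometric augmentations:
#' rotation, width/height shift, shear, zoom, and horizontal/vertical flip.
#' Each transform draws its parameter uniformly within the configured
#' magnitude.  The published experiments do not state magnitudes; the
#' defaults here are mild transforms standard for fundus imagery.
#'
#' @param rotation_degrees Maximum rotation magnitude (degrees).
#' @param width_shift_frac,height_shift_frac Maximum shift as a fraction of
#'   the image size; must be `< 1`.
#' @param shear_degrees Maximum shear angle (degrees).
#' @param zoom_frac Maximum relative zoom; scale drawn in
#'   `[1 - zoom_frac, 1 + zoom_frac]`.
#' @param horizontal_flip,vertical_flip Enable the flips (each applied with
#'   probability `flip_prob` when enabled).
#' @param flip_prob Probability of applying an enabled flip.
#' @param seed Optional integer seed making [augment_image()] deterministic.
#' @param extra_augment Optional callback `function(pixels) -> pixels`
#'   applied after the geometric transforms — a hook for plugging in
#'   external augmentation policies (e.g. RandAugment-style recipes, which
#'   this package deliberately does not reimplement).
#' @return A list with class `drh_augment_config`.
#' @export
augment_config <- function(rotation_degrees = 15, width_shift_frac = 0.1,
                           height_shift_frac = 0.1, shear_degrees = 10,
                           zoom_frac = 0.1, horizontal_flip = TRUE,
                           vertical_flip = TRUE, flip_prob = 0.5,
                           seed = NULL, extra_augment = NULL) {
  mags <- c(rotation_degrees, width_shift_frac, height_shift_frac,
            shear_degrees, zoom_frac)
  if (any(mags < 0)) stop_drh("augmentation magnitudes must be >= 0")
  if (width_shift_frac >= 1 || height_shift_frac >= 1 || zoom_frac >= 1)
    stop_drh("shift and zoom fractions must be < 1")
  if (!is.null(extra_augment) && !is.function(extra_augment))
    stop_drh("extra_augment must be a function(pixels)")
  structure(list(rotation_degrees = rotation_degrees,
                 width_shift_frac = width_shift_frac,
                 height_shift_frac = height_shift_frac,
                 shear_degrees = shear_degrees, zoom_frac = zoom_frac,
                 horizontal_flip = isTRUE(horizontal_flip),
                 vertical_flip = isTRUE(vertical_flip),
                 flip_prob = flip_prob, seed = seed,
                 extra_augment = extra_augment),
            class = "drh_augment_config")
}

#' Apply the training-time geometric augmentations
#'
#' Draws a rotation, shear, zoom, shift and flip decision uniformly within
#' the magnitudes of `config`, composes them into a single affine
#' transform, and resamples the image bilinearly.  Regions mapped from
#' outside the frame are filled with black, matching the black fundus
#' border.  The output always has the shape, numeric type and `[0, 255]`
#' intensity range of the input.
#'
#' @param pixels `H x W x C` array.
#' @param config An [augment_config()].
#' @param seed Optional seed (overrides `config$seed`); two calls with the
#'   same seed produce identical output.
#' @return Augmented array of identical shape.
#' @export
augment_image <- function(pixels, config = augment_config(), seed = config$seed) {
  if (!inherits(config, "drh_augment_config"))
    stop_drh("config must come from augment_config()")
  pixels <- as_pixels(pixels)
  d <- dim(pixels)
  out <- with_seed_opt(seed, {
    theta <- runif(1, -config$rotation_degrees, config$rotation_degrees) * pi / 180
    shear <- runif(1, -config$shear_degrees, config$shear_degrees) * pi / 180
    zoom <- runif(1, 1 - config$zoom_frac, 1 + config$zoom_frac)
    tx <- runif(1, -config$width_shift_frac, config$width_shift_frac) * d[2]
    ty <- runif(1, -config$height_shift_frac, config$height_shift_frac) * d[1]
    hf <- config$horizontal_flip && runif(1) < config$flip_prob
    vf <- config$vertical_flip && runif(1) < config$flip_prob
    affine_sample(pixels, theta, shear, zoom, tx, ty, hf, vf)
  })
  if (!is.null(config$extra_augment)) out <- config$extra_augment(out)
  pmin(pmax(out, 0), 255)
}

# Compose flip/zoom/shear/rotation/shift about the image centre and sample
# the source bilinearly (black fill outside the frame).  Coordinates are
# (x = column, y = row) in pixel centres.
#' @noRd
affine_sample <- function(px, theta, shear, zoom, tx, ty, hflip, vflip) {
  d <- dim(px); H <- d[1]; W <- d[2]
  identityT <- theta == 0 && shear == 0 && zoom == 1 && tx == 0 && ty == 0
  if (identityT && !hflip && !vflip) return(px)
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2L)
  Sh <- matrix(c(1, 0, tan(shear), 1), 2L)
  Z <- diag(c(zoom, zoom))
  Fl <- diag(c(if (hflip) -1 else 1, if (vflip) -1 else 1))
  M <- R %*% Sh %*% Z %*% Fl
  Minv <- solve(M)
  cx <- (W + 1) / 2; cy <- (H + 1) / 2
  xo <- rep(seq_len(W), each = H) - cx - tx
  yo <- rep(seq_len(H), times = W) - cy - ty
  xi <- Minv[1, 1] * xo + Minv[1, 2] * yo + cx
  yi <- Minv[2, 1] * xo + Minv[2, 2] * yo + cy
  j0 <- floor(xi); i0 <- floor(yi)
  fx <- xi - j0; fy <- yi - i0
  out <- array(0, d)
  gather <- function(A, ii, jj) {
    ok <- ii >= 1 & ii <= H & jj >= 1 & jj <= W
    v <- numeric(length(ii))
    v[ok] <- A[ii[ok] + H * (jj[ok] - 1L)]
    v
  }
  for (ch in seq_len(d[3])) {
    A <- px[, , ch]
    v <- gather(A, i0, j0) * (1 - fy) * (1 - fx) +
      gather(A, i0 + 1, j0) * fy * (1 - fx) +
      gather(A, i0, j0 + 1) * (1 - fy) * fx +
      gather(A, i0 + 1, j0 + 1) * fy * fx
    out[, , ch] <- v
  }
  out
}

#' Preprocess a manifest of images for one backbone
#'
#' Runs [crop_black_border()] then [resize_for_model()] on every image of a
#' manifest and writes the results as PNG plus a new manifest.
#'
#' @param manifest Input manifest path (columns `image_path,grade`).
#' @param out_dir Output directory (created if needed).
#' @param model_name Registered backbone the images are resized for.
#' @param intensity_threshold Passed to [crop_black_border()].
#' @return Path of the output manifest, invisibly.
#' @export
preprocess_manifest <- function(manifest, out_dir, model_name = "TinyCNN",
                                intensity_threshold = 10) {
  df <- read_manifest(manifest)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  out_paths <- character(nrow(df))
  for (i in seq_len(nrow(df))) {
    px <- read_image(df$image_path[i])
    cr <- crop_black_border(px, intensity_threshold)
    rs <- resize_for_model(cr$pixels, model_name)
    out_paths[i] <- file.path(out_dir, paste0(
      tools::file_path_sans_ext(basename(df$image_path[i])), ".png"))
    write_image(rs, out_paths[i])
  }
  out_manifest <- file.path(out_dir, "manifest.csv")
  write_manifest(data.frame(image_path = basename(out_paths),
                            grade = df$grade), out_manifest)
  invisible(out_manifest)
}
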