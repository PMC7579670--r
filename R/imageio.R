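# PNG/JPEG reading and writing plus the delimited image manifest.

#' Read a fundus image from disk
#'
#' Reads PNG or JPEG into an `H x W x 3` numeric array with intensities in
#' `[0, 255]`.  Grayscale images are replicated across channels and any
#' alpha channel is dropped.
#'
#' @param path Path to a `.png`, `.jpg` or `.jpeg` file.
#' @return Numeric `H x W x 3` array.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop_drh("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    jpg = ,
    jpeg = jpeg::readJPEG(path),
    stop_drh("unsupported image format '.", ext, "' (expected PNG or JPEG)"))
  if (length(dim(raw)) == 2L) raw <- array(rep(raw, 3L), c(dim(raw), 3L))
  if (dim(raw)[3] > 3L) raw <- raw[, , 1:3, drop = FALSE]
  raw * 255
}

#' Write an image as PNG
#'
#' @param pixels `H x W x 3` array with intensities in `[0, 255]`.
#' @param path Output path (`.png`).
#' @return `path`, invisibly.
#' @export
write_image <- function(pixels, path) {
  pixels <- pmin(pmax(pixels, 0), 255)
  png::writePNG(pixels / 255, path)
  invisible(path)
}

#' Read an image manifest
#'
#' A manifest is a delimited text file with header `image_path,grade`,
#' where `grade` is the integer severity 0--4.  Relative image paths are
#' resolved against the manifest's own directory.
#'
#' @param path Manifest file path.
#' @return A data frame with columns `image_path` (absolute) and `grade`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop_drh("manifest not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("image_path", "grade") %in% names(df)))
    stop_drh("manifest must have columns image_path,grade")
  df$grade <- check_grades(df$grade, "manifest grades")
  rel <- !grepl("^(/|[A-Za-z]:)", df$image_path)
  df$image_path[rel] <- file.path(dirname(path), df$image_path[rel])
  df
}

#' Write an image manifest
#'
#' @param df Data frame with columns `image_path` and `grade`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(df, path) {
  write.csv(df[, c("image_path", "grade")], path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' Load the images of a manifest as graded images
#'
#' @param manifest Path to a manifest file or a data frame from
#'   [read_manifest()].
#' @return List of [graded_image()] objects.
#' @export
load_graded_images <- function(manifest) {
  df <- if (is.character(manifest)) read_manifest(manifest) else manifest
  if (nrow(df) == 0L) stop_drh("manifest is empty")
  lapply(seq_len(nrow(df)), function(i)
    graded_image(read_image(df$image_path[i]), df$grade[i],
                 source_id = basename(df$image_path[i])))
}
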