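## File I/O: video cubes as multi-page TIFF (one frame per page, 32-bit
## float), 2D measurements as TIFF/PNG/CSV, masks as 0/255 images (binarized
## at half scale) or CSV of 0/1.

file_ext_lower <- function(path) tolower(tools::file_ext(path))

#' Write a video cube as a multi-page TIFF
#'
#' One 32-bit float page per frame. TIFF stores values in `[0, 1]`; cubes
#' outside that range are rescaled into it (with a warning) by shifting to
#' zero minimum and dividing by the span.
#'
#' @param cube 3D array `(ny, nx, nt)`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_cube_tiff <- function(cube, path) {
  rng <- range(cube)
  if (rng[1] < 0 || rng[2] > 1) {
    warning("cube values outside [0, 1]; rescaling for TIFF storage")
    span <- rng[2] - rng[1]
    cube <- if (span > 0) (cube - rng[1]) / span else cube * 0
  }
  frames <- lapply(seq_len(dim(cube)[3]), function(t) cube[, , t])
  tiff::writeTIFF(frames, path, bits.per.sample = 32L, compression = "none")
  invisible(path)
}

#' Read a multi-page TIFF as a video cube
#'
#' @param path TIFF path.
#' @param dt frame interval in seconds attached to the cube.
#' @return 3D array `(ny, nx, nt)`.
#' @export
read_cube_tiff <- function(path, dt = 330e-12) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3L) p[, , 1] else p)
  cube <- array(unlist(pages), c(dim(pages[[1]]), length(pages)))
  video_cube(cube, dt = dt)
}

#' Write a 2D image (measurement) to TIFF, PNG or CSV
#'
#' TIFF/PNG store values in `[0, 1]` (rescaled with a warning if outside);
#' CSV stores exact values.
#'
#' @param img numeric matrix.
#' @param path output path; format chosen by extension (`tif`/`tiff`, `png`,
#'   `csv`).
#' @return the path, invisibly.
#' @export
write_image <- function(img, path) {
  ext <- file_ext_lower(path)
  if (ext == "csv") {
    utils::write.table(img, path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
    return(invisible(path))
  }
  rng <- range(img)
  if (rng[1] < 0 || rng[2] > 1) {
    warning("image values outside [0, 1]; rescaling for storage")
    span <- rng[2] - rng[1]
    img <- if (span > 0) (img - rng[1]) / span else img * 0
  }
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(img, path, bits.per.sample = 32L, compression = "none")
  } else if (ext == "png") {
    png::writePNG(img, path)
  } else stop("unsupported image format: .", ext)
  invisible(path)
}

#' Read a 2D image (measurement) from TIFF, PNG or CSV
#'
#' @param path input path (`tif`/`tiff`, `png`, `csv`).
#' @return numeric matrix.
#' @export
read_image <- function(path) {
  ext <- file_ext_lower(path)
  img <- if (ext == "csv") {
    as.matrix(utils::read.table(path, sep = ","))
  } else if (ext %in% c("tif", "tiff")) {
    tiff::readTIFF(path)
  } else if (ext == "png") {
    png::readPNG(path)
  } else stop("unsupported image format: .", ext)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  dimnames(img) <- NULL
  img
}

#' Read a binary coding mask
#'
#' Images (PNG/TIFF) are binarized at half scale (>= 128/255 is open); CSV
#' files must contain 0/1 entries.
#'
#' @param path input path.
#' @return a [binary_mask()].
#' @export
read_mask <- function(path) {
  img <- read_image(path)
  if (file_ext_lower(path) != "csv") img <- (img >= 0.5) * 1
  binary_mask(img)
}

#' Write a binary coding mask
#'
#' @param mask 0/1 matrix.
#' @param path output path (`png`, `tif`/`tiff` or `csv`).
#' @return the path, invisibly.
#' @export
write_mask <- function(mask, path) write_image(mask, path)
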