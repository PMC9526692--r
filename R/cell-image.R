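#' Single-cell fluorescence image with cell-edge polygon
#'
#' Bundles a single-channel intensity grid with the manually drawn cell-edge
#' polygon and, optionally, the centrosome coordinate (the brightest point of
#' the microtubule network; located by [locate_centrosome()] when absent).
#'
#' @param pixels numeric matrix of non-negative intensities (rows x cols).
#' @param polygon (v x 2) matrix of (row, col) vertices delimiting the cell
#'   edge, v >= 3, in pixel-center coordinates (pixel `[i, j]` has center
#'   `(i, j)`).
#' @param centrosome optional length-2 (row, col) coordinate, must lie
#'   inside the polygon.
#' @return An object of class `"cell_image"`.
#' @export
cell_image <- function(pixels, polygon, centrosome = NULL) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix")
  if (any(pixels < 0)) stop("pixel intensities must be non-negative")
  polygon <- check_polygon(polygon)
  if (!is.null(centrosome)) {
    if (!point_in_polygon(rbind(centrosome), polygon))
      stop("centrosome must lie inside the cell polygon")
  }
  structure(list(pixels = pixels, polygon = polygon,
                 centrosome = centrosome),
            class = "cell_image")
}

#' @export
print.cell_image <- function(x, ...) {
  cat(sprintf("cell_image: %d x %d pixels, %d polygon vertices, centrosome %s\n",
              nrow(x$pixels), ncol(x$pixels), nrow(x$polygon),
              if (is.null(x$centrosome)) "unset"
              else sprintf("(%g, %g)", x$centrosome[1], x$centrosome[2])))
  invisible(x)
}

#' Specification for a synthetic cell image
#'
#' Describes a cell whose fluorescence decays exponentially with the
#' normalized radius from the centrosome: intensity inside the polygon is
#' `peak_intensity * exp(-decay_rate * rho) + noise` where `rho` is the
#' [normalized_radius()]. This emulates a microtubule network concentrated
#' around the centrosome and provides a closed-form ground truth for the
#' belt profile.
#'
#' @param image_size integer (rows, cols) or a single side length.
#' @param polygon cell-edge polygon, (v x 2) (row, col) vertices.
#' @param centrosome (row, col), strictly inside the polygon.
#' @param decay_rate radial decay constant per unit normalized radius
#'   (>= 0; 0 gives a uniform cell).
#' @param peak_intensity intensity at the centrosome (> 0).
#' @param noise_sd sd of additive Gaussian noise (clamped at 0 from below).
#' @param seed integer RNG seed.
#' @return A list of class `"image_sim_spec"`.
#' @export
image_sim_spec <- function(image_size, polygon, centrosome,
                           decay_rate = 2, peak_intensity = 10000,
                           noise_sd = 0, seed = 1L) {
  if (length(image_size) == 1) image_size <- c(image_size, image_size)
  polygon <- check_polygon(polygon)
  if (peak_intensity <= 0) stop("peak_intensity must be > 0")
  if (decay_rate < 0) stop("decay_rate must be >= 0")
  if (!point_in_polygon(rbind(centrosome), polygon))
    stop("centrosome must lie inside the polygon")
  structure(list(image_size = as.integer(image_size), polygon = polygon,
                 centrosome = as.numeric(centrosome),
                 decay_rate = decay_rate, peak_intensity = peak_intensity,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "image_sim_spec")
}

#' Generate a synthetic cell image
#'
#' @param spec an [image_sim_spec()].
#' @return A [cell_image()] whose brightest interior pixel is the specified
#'   centrosome (with noise, the centrosome pixel is raised above the
#'   interior maximum so the location stays identifiable by construction).
#' @examples
#' sq <- rbind(c(4, 4), c(4, 60), c(60, 60), c(60, 4))
#' img <- simulate_cell_image(image_sim_spec(64, sq, c(32, 32)))
#' img
#' @export
simulate_cell_image <- function(spec) {
  stopifnot(inherits(spec, "image_sim_spec"))
  withr::with_seed(spec$seed, {
    dims <- spec$image_size
    mask <- polygon_mask(dims, spec$polygon)
    idx <- which(mask, arr.ind = TRUE)
    rho <- normalized_radius(idx, spec$centrosome, spec$polygon)
    img <- matrix(0, dims[1], dims[2])
    img[mask] <- spec$peak_intensity * exp(-spec$decay_rate * rho)
    if (spec$noise_sd > 0) {
      img <- img + matrix(stats::rnorm(prod(dims), 0, spec$noise_sd),
                          dims[1], dims[2])
      img <- pmax(img, 0)
      # keep the designated centrosome the unambiguous interior maximum
      ci <- round(spec$centrosome)
      img[ci[1], ci[2]] <- max(img[mask]) + spec$noise_sd
    }
    cell_image(img, spec$polygon, spec$centrosome)
  })
}

#' Write a cell image as 16-bit grayscale TIFF plus JSON sidecar
#'
#' Intensities are stored as 16-bit counts (values are clamped to
#' \[0, 65535\] and rounded). The sidecar holds the polygon and centrosome
#' as 0-based (row, col) coordinates.
#'
#' @param img a [cell_image()].
#' @param image_path output `.tif` path.
#' @param roi_path output `.json` path.
#' @return `image_path`, invisibly.
#' @export
write_cell_image <- function(img, image_path, roi_path) {
  px <- pmin(pmax(round(img$pixels), 0), 65535)
  tiff::writeTIFF(px / 65535, image_path, bits.per.sample = 16)
  roi <- list(polygon = lapply(seq_len(nrow(img$polygon)),
                               function(i) unname(img$polygon[i, ] - 1)))
  if (!is.null(img$centrosome))
    roi$centrosome <- unname(img$centrosome - 1)
  jsonlite::write_json(roi, roi_path, auto_unbox = TRUE, digits = NA)
  invisible(image_path)
}

#' Read a cell image from TIFF/PNG plus JSON sidecar
#'
#' @param image_path single-channel `.tif`/`.tiff` or `.png` file; 16-bit
#'   grayscale values are rescaled back to integer counts.
#' @param roi_path JSON sidecar with `polygon` (list of 0-based (row, col)
#'   vertices) and optional `centrosome`.
#' @return A [cell_image()].
#' @export
read_cell_image <- function(image_path, roi_path) {
  ext <- tolower(tools::file_ext(image_path))
  px <- switch(ext,
               tif = , tiff = tiff::readTIFF(image_path),
               png = png::readPNG(image_path),
               stop("unsupported image format: ", ext))
  if (length(dim(px)) == 3) px <- px[, , 1]
  px <- round(px * 65535)
  roi <- jsonlite::read_json(roi_path, simplifyVector = TRUE)
  pol <- roi$polygon
  polygon <- if (is.matrix(pol)) pol + 1 else
    matrix(unlist(pol), ncol = 2, byrow = TRUE) + 1
  centro <- if (!is.null(roi$centrosome)) unlist(roi$centrosome) + 1
  cell_image(px, polygon, centro)
}
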