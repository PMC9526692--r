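#' Locate the centrosome as the brightest interior pixel
#'
#' The centrosome (microtubule-organizing center) is assigned to the
#' highest-intensity pixel strictly inside the cell polygon; intensity ties
#' break by smallest row, then smallest column, so the result is
#' deterministic.
#'
#' @param img a [cell_image()].
#' @return Integer (row, col) coordinate of the centrosome pixel.
#' @export
locate_centrosome <- function(img) {
  stopifnot(inherits(img, "cell_image"))
  mask <- polygon_mask(dim(img$pixels), img$polygon)
  idx <- which(mask, arr.ind = TRUE)
  if (!nrow(idx)) stop("polygon encloses no pixel centers")
  vals <- img$pixels[idx]
  best <- idx[order(-vals, idx[, 1], idx[, 2])[1], ]
  c(row = unname(best[1]), col = unname(best[2]))
}

#' Assign every interior pixel to a concentric belt
#'
#' Partitions the cell interior into `n_belts` concentric, equally
#' distributed belts running from the centrosome (belt 0) to the cell edge
#' (belt `n_belts - 1`): the belt index of a pixel is
#' `min(floor(rho * n_belts), n_belts - 1)` where `rho` is its
#' [normalized_radius()]. Because `rho` is normalized per ray, the belts
#' follow the drawn cell shape.
#'
#' @param img a [cell_image()]; if its centrosome is unset it is located
#'   with [locate_centrosome()].
#' @param n_belts number of belts (default 11, labelled 0..10).
#' @return An integer matrix the size of the image with the belt label per
#'   interior pixel and `NA` outside the polygon; the centrosome used is
#'   attached as attribute `"centrosome"`.
#' @export
generate_belts <- function(img, n_belts = 11L) {
  stopifnot(inherits(img, "cell_image"))
  if (n_belts < 1) stop("n_belts must be >= 1")
  centro <- img$centrosome
  if (is.null(centro)) centro <- locate_centrosome(img)
  mask <- polygon_mask(dim(img$pixels), img$polygon)
  idx <- which(mask, arr.ind = TRUE)
  if (!nrow(idx)) stop("polygon encloses no pixel centers")
  rho <- normalized_radius(idx, centro, img$polygon)
  belt <- pmin(floor(rho * n_belts), n_belts - 1L)
  labels <- matrix(NA_integer_, nrow(img$pixels), ncol(img$pixels))
  labels[mask] <- as.integer(belt)
  attr(labels, "centrosome") <- centro
  attr(labels, "n_belts") <- as.integer(n_belts)
  labels
}

#' Otsu threshold of a set of intensities
#'
#' Classic Otsu threshold maximizing the between-class variance of a
#' 256-bin histogram over the value range. For a constant input the
#' threshold falls back to half the value, so a uniformly positive region
#' counts as fully stained and an all-zero region as unstained.
#'
#' @param values numeric vector of intensities.
#' @param n_bins histogram bins (default 256).
#' @return The threshold; pixels strictly above it count as stained.
#' @export
otsu_threshold <- function(values, n_bins = 256L) {
  values <- values[is.finite(values)]
  rng <- range(values)
  if (diff(rng) == 0) return(rng[1] / 2)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- tabulate(findInterval(values, breaks, rightmost.closed = TRUE),
                nbins = n_bins)
  w <- h / sum(h)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  breaks[which.max(sigma_b) + 1]
}

#' Per-belt mean intensity and stained area fraction
#'
#' For each belt, computes the mean pixel intensity and the fraction of
#' pixels above a threshold computed once per cell on the interior pixels
#' (Otsu by default; pass a number for a fixed threshold). Empty belts get
#' `NA` statistics.
#'
#' @param img a [cell_image()].
#' @param labels belt label matrix from [generate_belts()].
#' @param threshold `"otsu"` (default) or a fixed numeric threshold.
#' @return A data.frame of class `"belt_profile"`: `belt`,
#'   `mean_intensity`, `area_fraction`, `n_pixels`; the threshold used is
#'   attached as attribute `"threshold"`.
#' @export
belt_statistics <- function(img, labels, threshold = "otsu") {
  stopifnot(inherits(img, "cell_image"))
  interior <- !is.na(labels)
  vals <- img$pixels[interior]
  belts <- labels[interior]
  thr <- if (identical(threshold, "otsu")) otsu_threshold(vals)
         else as.numeric(threshold)
  n_belts <- attr(labels, "n_belts")
  if (is.null(n_belts)) n_belts <- max(belts) + 1L
  lev <- factor(belts, levels = 0:(n_belts - 1L))
  cnt <- as.integer(table(lev))
  mean_int <- as.numeric(tapply(vals, lev, mean))
  frac <- as.numeric(tapply(vals > thr, lev, mean))
  out <- data.frame(belt = 0:(n_belts - 1L), mean_intensity = mean_int,
                    area_fraction = frac, n_pixels = cnt)
  attr(out, "threshold") <- thr
  class(out) <- c("belt_profile", "data.frame")
  out
}

#' Compare belt profiles between two cell groups
#'
#' Aggregates per-cell belt profiles (e.g. 15 cells per field in each of
#' the GC and RPM groups) into per-belt group means and standard
#' deviations, and tests each belt's mean intensity and area fraction
#' between the two groups with a two-sided pooled-variance Student's t
#' test at the 0.05 level.
#'
#' @param profiles list of `belt_profile` data.frames from
#'   [belt_statistics()], all with the same number of belts.
#' @param groups vector of group labels (exactly 2 distinct values, >= 2
#'   cells each), parallel to `profiles`.
#' @param alpha significance level (default 0.05).
#' @return A data.frame with one row per belt: per-group `n`, mean and sd
#'   of mean intensity and of area fraction, plus `p_intensity`,
#'   `p_area`, `sig_intensity`, `sig_area`.
#' @export
aggregate_cells <- function(profiles, groups, alpha = 0.05) {
  if (length(profiles) != length(groups))
    stop("one group label per profile required")
  nb <- vapply(profiles, nrow, 0L)
  if (length(unique(nb)) != 1)
    stop("profiles disagree on the number of belts")
  g <- factor(groups)
  if (nlevels(g) != 2) stop("exactly two groups required")
  if (any(table(g) < 2)) stop("each group needs >= 2 cells")
  lv <- levels(g)
  get <- function(col, grp) {
    sapply(profiles[g == grp], function(p) p[[col]])  # belts x cells
  }
  res <- lapply(seq_len(nb[1]), function(b) {
    row <- list(belt = b - 1L,
                n_1 = sum(g == lv[1]), n_2 = sum(g == lv[2]))
    for (col in c("mean_intensity", "area_fraction")) {
      a <- get(col, lv[1])[b, ]; bb <- get(col, lv[2])[b, ]
      tt <- student_t(a, bb)
      key <- if (col == "mean_intensity") "intensity" else "area"
      row[[paste0("mean_", key, "_1")]] <- mean(a)
      row[[paste0("sd_", key, "_1")]] <- stats::sd(a)
      row[[paste0("mean_", key, "_2")]] <- mean(bb)
      row[[paste0("sd_", key, "_2")]] <- stats::sd(bb)
      row[[paste0("p_", key)]] <- tt$p
      row[[paste0("sig_", key)]] <- tt$p < alpha
    }
    as.data.frame(row)
  })
  out <- do.call(rbind, res)
  attr(out, "groups") <- lv
  out
}

#' Total intensity and stained area of an image
#'
#' Whole-image summary used for extracellular-matrix protein
#' immunostaining: the sum of all pixel intensities and the count of
#' pixels above a threshold.
#'
#' @param pixels numeric matrix of intensities (or a [cell_image()], in
#'   which case its pixel grid is used).
#' @param threshold `"otsu"` (computed on all pixels) or a fixed numeric
#'   threshold.
#' @return A list with `total_intensity` and `stained_area` (pixel count).
#' @export
image_totals <- function(pixels, threshold = "otsu") {
  if (inherits(pixels, "cell_image")) pixels <- pixels$pixels
  thr <- if (identical(threshold, "otsu")) otsu_threshold(pixels)
         else as.numeric(threshold)
  list(total_intensity = sum(pixels), stained_area = sum(pixels > thr))
}

#' Write a belt profile as CSV
#'
#' @param profile a `belt_profile` from [belt_statistics()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_belt_csv <- function(profile, path) {
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE)
  invisible(path)
}
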