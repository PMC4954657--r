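#' Plate grid layout
#'
#' Rectangular pin grid on a grayscale plate image. Positions are numbered
#' row-major. Coordinates are (row, column) pixel indices of colony
#' centers.
#'
#' @param nrow,ncol grid dimensions (default 8 x 12, a 96-position plate).
#' @param pitch center-to-center spacing in pixels.
#' @param margin distance from the image edge to the first center, in
#'   pixels; must leave room for the measurement ROI and its background
#'   annulus.
#' @param radius colony ROI radius in pixels (default 50).
#' @return An object of class `plate_layout` with the center table and
#'   image dimensions.
#' @export
plate_layout <- function(nrow = 8, ncol = 12, pitch = 120, margin = 80,
                         radius = 50) {
  stopifnot(nrow >= 1, ncol >= 1, pitch >= 1, margin > radius)
  centers <- expand.grid(col = seq_len(ncol), row = seq_len(nrow))
  centers <- centers[, c("row", "col")]
  centers$y <- margin + (centers$row - 1) * pitch
  centers$x <- margin + (centers$col - 1) * pitch
  centers$position <- seq_len(nrow(centers))
  dim <- c(2 * margin + (nrow - 1) * pitch, 2 * margin + (ncol - 1) * pitch)
  structure(list(centers = centers, dim = dim, radius = radius,
                 pitch = pitch, margin = margin),
            class = "plate_layout")
}

#' Render a synthetic plate image
#'
#' Draws each colony as a radially decaying (Gaussian) spot whose
#' integrated intensity above background equals its growth value, on a
#' constant background with optional additive Gaussian noise. The
#' rendering is linear in growth by construction, which makes the
#' render/measure round trip a usable oracle for the quantification code.
#'
#' @param growth_values non-negative growth values, at most one per grid
#'   position, assigned row-major.
#' @param layout a [plate_layout()].
#' @param spot_sd Gaussian spot SD in pixels (default `radius / 3`).
#' @param background constant background level (default 100).
#' @param noise_sd SD of additive pixel noise (default 0).
#' @return Numeric image matrix (rows x columns of pixels).
#' @export
render_plate <- function(growth_values, layout, spot_sd = layout$radius / 3,
                         background = 100, noise_sd = 0) {
  stopifnot(inherits(layout, "plate_layout"),
            length(growth_values) <= nrow(layout$centers))
  if (any(growth_values < 0)) stop("growth values must be non-negative")
  img <- matrix(background, layout$dim[1], layout$dim[2])
  if (noise_sd > 0)
    img <- img + matrix(stats::rnorm(length(img), 0, noise_sd),
                        nrow(img), ncol(img))
  w <- ceiling(4 * spot_sd)
  off <- -w:w
  kern <- exp(-outer(off^2, off^2, "+") / (2 * spot_sd^2))
  kern <- kern / sum(kern)  # unit integrated intensity
  for (i in seq_along(growth_values)) {
    cy <- layout$centers$y[i]
    cx <- layout$centers$x[i]
    rows <- cy + off
    cols <- cx + off
    ok_r <- rows >= 1 & rows <= nrow(img)
    ok_c <- cols >= 1 & cols <= ncol(img)
    img[rows[ok_r], cols[ok_c]] <- img[rows[ok_r], cols[ok_c]] +
      growth_values[i] * kern[ok_r, ok_c]
  }
  img
}

#' Pixels of a circular region of interest
#'
#' Integer pixels whose center lies within Euclidean distance `radius` of
#' the ROI center. At the default radius of 50 the mask contains 7845
#' pixels.
#'
#' @param center numeric `c(row, col)` center in pixels.
#' @param radius ROI radius in pixels (default 50).
#' @param dim optional image dimensions `c(nrow, ncol)`; if given, an ROI
#'   extending beyond the image raises an error.
#' @return Two-column integer matrix of (row, col) pixel coordinates.
#' @export
circular_mask <- function(center, radius = 50, dim = NULL) {
  stopifnot(radius >= 1)
  r <- ceiling(radius)
  off <- -r:r
  d2 <- outer(off^2, off^2, "+")
  sel <- which(d2 <= radius^2, arr.ind = TRUE)
  px <- cbind(row = center[1] + off[sel[, 1]],
              col = center[2] + off[sel[, 2]])
  if (!is.null(dim)) {
    if (any(px[, 1] < 1) || any(px[, 1] > dim[1]) ||
        any(px[, 2] < 1) || any(px[, 2] > dim[2]))
      stop("ROI extends beyond image bounds")
  }
  px
}

annulus_pixels <- function(center, radius, width) {
  r_out <- radius + width
  r <- ceiling(r_out)
  off <- -r:r
  d2 <- outer(off^2, off^2, "+")
  sel <- which(d2 > radius^2 & d2 <= r_out^2, arr.ind = TRUE)
  cbind(row = center[1] + off[sel[, 1]],
        col = center[2] + off[sel[, 2]])
}

#' Measure one colony by circular-ROI pixel intensity
#'
#' Sums pixel intensity over a circular ROI and corrects for local
#' background estimated as the mean intensity over a surrounding annulus
#' (excluding any pixels belonging to other colonies' ROIs). The average
#' intensity is the background-corrected total divided by the ROI area;
#' negative averages are clamped to zero and flagged.
#'
#' @param img numeric image matrix.
#' @param center `c(row, col)` colony center in pixels.
#' @param radius ROI radius in pixels (default 50).
#' @param annulus_width background annulus width in pixels (default 10).
#' @param exclude_centers optional list/matrix of other colony centers
#'   whose ROIs are masked out of the annulus.
#' @param correct_background subtract the annulus-mean background
#'   (default TRUE).
#' @param area_divisor `"mask"` (default) divides by the actual lattice
#'   mask area; `"imagej"` forces the fixed divisor 7845 used by the
#'   original plate-analysis plugin at radius 50.
#' @return List with `total_intensity`, `mask_area_px`,
#'   `background_per_px`, `average_intensity`, `clamped`.
#' @export
measure_colony <- function(img, center, radius = 50, annulus_width = 10,
                           exclude_centers = NULL,
                           correct_background = TRUE,
                           area_divisor = c("mask", "imagej")) {
  area_divisor <- match.arg(area_divisor)
  dim <- dim(img)
  mask <- circular_mask(center, radius, dim)
  total <- sum(img[mask])
  area <- nrow(mask)
  bg <- 0
  if (correct_background) {
    ann <- annulus_pixels(center, radius, annulus_width)
    if (any(ann[, 1] < 1) || any(ann[, 1] > dim[1]) ||
        any(ann[, 2] < 1) || any(ann[, 2] > dim[2]))
      stop("background annulus extends beyond image bounds")
    if (!is.null(exclude_centers)) {
      if (is.matrix(exclude_centers))
        exclude_centers <- asplit(exclude_centers, 1)
      for (ct in exclude_centers) {
        keep <- (ann[, 1] - ct[1])^2 + (ann[, 2] - ct[2])^2 > radius^2
        ann <- ann[keep, , drop = FALSE]
      }
    }
    if (nrow(ann) == 0L)
      stop("background annulus fully occluded by neighbouring ROIs")
    bg <- mean(img[ann])
  }
  divisor <- if (area_divisor == "imagej") 7845 else area
  avg <- (total - bg * area) / divisor
  clamped <- avg < 0
  list(total_intensity = total, mask_area_px = area,
       background_per_px = bg,
       average_intensity = max(avg, 0), clamped = clamped)
}

#' Measure every grid position of a plate image
#'
#' Applies [measure_colony()] at each layout position (row-major), masking
#' the other positions' ROIs out of each background annulus. Positions
#' without a colony simply yield near-zero background-corrected averages.
#'
#' @param img numeric image matrix.
#' @param layout a [plate_layout()]; its dimensions must match `img`.
#' @param radius ROI radius in pixels (default: the layout's radius).
#' @param ... further arguments passed to [measure_colony()].
#' @return data.frame `position`, `row`, `col`, `total_intensity`,
#'   `mask_area_px`, `background_per_px`, `average_intensity`, `clamped`.
#' @export
measure_plate <- function(img, layout, radius = layout$radius, ...) {
  stopifnot(inherits(layout, "plate_layout"))
  if (!all(dim(img) == layout$dim))
    stop("image dimensions do not match the layout")
  cents <- cbind(layout$centers$y, layout$centers$x)
  out <- lapply(seq_len(nrow(cents)), function(i) {
    m <- measure_colony(img, cents[i, ], radius = radius,
                        exclude_centers = cents[-i, , drop = FALSE], ...)
    data.frame(position = layout$centers$position[i],
               row = layout$centers$row[i], col = layout$centers$col[i],
               total_intensity = m$total_intensity,
               mask_area_px = m$mask_area_px,
               background_per_px = m$background_per_px,
               average_intensity = m$average_intensity,
               clamped = m$clamped)
  })
  do.call(rbind, out)
}

#' Write a plate image as 16-bit grayscale TIFF
#'
#' Intensities are scaled by `scale` into `[0, 1]` and clipped.
#'
#' @param img numeric image matrix.
#' @param path output file.
#' @param scale value mapped to full white (default: the image maximum).
#' @export
write_plate_tiff <- function(img, path, scale = max(img)) {
  x <- pmin(pmax(img / scale, 0), 1)
  tiff::writeTIFF(x, path, bits.per.sample = 16)
  invisible(path)
}

#' Read a grayscale plate image from TIFF
#'
#' @param path TIFF file.
#' @return Numeric image matrix in `[0, 1]` (first channel if the file has
#'   several).
#' @export
read_plate_tiff <- function(path) {
  x <- tiff::readTIFF(path)
  if (length(dim(x)) == 3) x <- x[, , 1]
  x
}
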