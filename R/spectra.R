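#' Saturation-offset image stack
#'
#' One 2-D signal image per scheduled saturation offset plus the
#' unsaturated control image (S0).
#'
#' @param sat_images Numeric array `[rows, cols, n_offsets]`, planes in the
#'   schedule's acquisition order.
#' @param s0_image Numeric matrix, same in-plane dimensions.
#' @param schedule [acquisition_schedule()].
#' @param pixel_size In-plane pixel size in mm.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(sat_images, s0_image, schedule, pixel_size) {
  stopifnot(inherits(schedule, "acquisition_schedule"),
            is.array(sat_images), length(dim(sat_images)) == 3L,
            is.matrix(s0_image), pixel_size > 0)
  if (dim(sat_images)[3L] != length(schedule$offsets))
    stop(sprintf("stack has %d offset images but the schedule lists %d offsets",
                 dim(sat_images)[3L], length(schedule$offsets)), call. = FALSE)
  if (!all(dim(sat_images)[1:2] == dim(s0_image)))
    stop("S0 image dimensions differ from the saturation images", call. = FALSE)
  structure(list(sat_images = sat_images, s0_image = s0_image,
                 schedule = schedule, pixel_size = pixel_size),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$sat_images)
  cat(sprintf("Image stack: %d x %d pixels (%.3g mm), %d offsets + S0\n",
              d[1L], d[2L], x$pixel_size, d[3L]))
  invisible(x)
}

# Background noise level from an air corner patch of the S0 image. The
# patch spans 1/8 of the image side so it stays inside the air background
# at any resolution.
.background_noise <- function(s0_image, patch = NULL) {
  if (is.null(patch))
    patch <- max(4L, nrow(s0_image) %/% 8L)
  patch <- min(patch, dim(s0_image))
  stats::sd(as.vector(s0_image[seq_len(patch), seq_len(patch)]))
}

#' Assemble per-pixel z-spectra from an image stack
#'
#' Divides every saturation image by the control image and reorders offsets
#' ascending. Pixels whose S0 falls at or below `mask_k` times the
#' background noise level (estimated from an air corner patch of the S0
#' image) are masked out: lung air carries no signal and division by S0 is
#' meaningless there. No values are imputed for masked pixels.
#'
#' @param stack An [image_stack()].
#' @param mask_k Multiple of the background noise below which S0 is
#'   considered air/no-signal.
#' @param noise_level Background noise level override; estimated from the
#'   corner patch when `NULL`.
#' @return An object of class `zspectra_set`: array `z` of
#'   `[rows, cols, n_offsets]` normalized values (offsets ascending), the
#'   validity `mask`, the offsets, and the S0 image.
#' @export
assemble_zspectra <- function(stack, mask_k = 5, noise_level = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  if (!length(stack$schedule$offsets))
    stop("empty schedule", call. = FALSE)
  s0 <- stack$s0_image
  noise <- if (is.null(noise_level)) .background_noise(s0) else noise_level
  mask <- is.finite(s0) & s0 > mask_k * noise & s0 > 0
  ord <- order(stack$schedule$offsets)
  z <- stack$sat_images[, , ord, drop = FALSE]
  for (i in seq_len(dim(z)[3L])) {
    plane <- z[, , i] / s0
    plane[!mask] <- NA_real_
    z[, , i] <- plane
  }
  structure(list(z = z, mask = mask,
                 offsets = stack$schedule$offsets[ord],
                 s0_image = s0, noise_level = noise,
                 pixel_size = stack$pixel_size,
                 state = "raw"),
            class = "zspectra_set")
}

#' @export
print.zspectra_set <- function(x, ...) {
  cat(sprintf("Z-spectra set (%s): %d x %d pixels, %d offsets, %d valid (%.1f%%)\n",
              x$state, nrow(x$mask), ncol(x$mask), length(x$offsets),
              sum(x$mask), 100 * mean(x$mask)))
  invisible(x)
}

#' Extract one pixel's z-spectrum
#'
#' @param zset A `zspectra_set` from [assemble_zspectra()].
#' @param row,col Pixel coordinates, 1-based (R indexing).
#' @return A [zspectrum()], or error if the pixel is masked.
#' @export
pixel_spectrum <- function(zset, row, col) {
  stopifnot(inherits(zset, "zspectra_set"))
  if (!zset$mask[row, col])
    stop("pixel is masked (no signal)", call. = FALSE)
  zspectrum(zset$offsets, zset$z[row, col, ], state = zset$state,
            b0_estimate = if (!is.null(zset$b0)) zset$b0[row, col] else NA_real_,
            source = "pixel")
}

#' Circular region of interest
#'
#' @param label ROI kind: `"tumor"`, `"cord"` or `"other"`.
#' @param center_row,center_col Center in 0-based pixel coordinates
#'   (row-major, top-left pixel is (0, 0)).
#' @param area_mm2 ROI area in mm^2.
#' @param animal,group Optional identifiers for cohort bookkeeping.
#' @return An object of class `cest_roi`.
#' @export
roi_circle <- function(label = c("tumor", "cord", "other"),
                       center_row, center_col, area_mm2 = 0.34,
                       animal = NA_character_, group = NA_character_) {
  label <- match.arg(label)
  stopifnot(is.finite(center_row), is.finite(center_col), area_mm2 > 0)
  structure(list(label = label, center_row = center_row,
                 center_col = center_col, area_mm2 = area_mm2,
                 animal = animal, group = group),
            class = "cest_roi")
}

#' @export
print.cest_roi <- function(x, ...) {
  cat(sprintf("ROI [%s] center (%.1f, %.1f) px (0-based), %.3g mm^2\n",
              x$label, x$center_row, x$center_col, x$area_mm2))
  invisible(x)
}

#' Pixels covered by a circular ROI
#'
#' A pixel belongs to the ROI iff its center lies within the ROI radius
#' (`sqrt(area/pi)`) of the ROI center.
#'
#' @param roi A [roi_circle()].
#' @param zset A `zspectra_set` (supplies grid size and pixel size).
#' @param valid_only Drop masked pixels.
#' @return Integer matrix with columns `row`, `col` (1-based).
#' @export
roi_pixels <- function(roi, zset, valid_only = TRUE) {
  stopifnot(inherits(roi, "cest_roi"), inherits(zset, "zspectra_set"))
  radius_px <- sqrt(roi$area_mm2 / pi) / zset$pixel_size
  nr <- nrow(zset$mask); nc <- ncol(zset$mask)
  # 0-based ROI center -> 1-based pixel grid
  r0 <- roi$center_row + 1; c0 <- roi$center_col + 1
  rr <- max(1L, floor(r0 - radius_px)):min(nr, ceiling(r0 + radius_px))
  cc <- max(1L, floor(c0 - radius_px)):min(nc, ceiling(c0 + radius_px))
  g <- expand.grid(row = rr, col = cc)
  g <- g[(g$row - r0)^2 + (g$col - c0)^2 <= radius_px^2, , drop = FALSE]
  if (!nrow(g)) {
    # ROI smaller than the pixel grid: read the nearest pixel
    g <- data.frame(row = min(max(round(r0), 1L), nr),
                    col = min(max(round(c0), 1L), nc))
  }
  if (valid_only)
    g <- g[zset$mask[cbind(g$row, g$col)], , drop = FALSE]
  as.matrix(g)
}

#' Mean z-spectrum over an ROI
#'
#' Offset-wise unweighted mean of the member pixels' normalized spectra.
#'
#' @param zset A `zspectra_set`.
#' @param roi A [roi_circle()].
#' @return A [zspectrum()] with source `"roi"`.
#' @export
roi_spectrum <- function(zset, roi) {
  px <- roi_pixels(roi, zset)
  if (!nrow(px))
    stop(sprintf("ROI [%s] at (%.1f, %.1f) covers no valid pixels",
                 roi$label, roi$center_row, roi$center_col), call. = FALSE)
  vals <- vapply(seq_along(zset$offsets), function(i)
    mean(zset$z[, , i][cbind(px[, 1], px[, 2])]), numeric(1))
  b0 <- if (!is.null(zset$b0))
    mean(zset$b0[cbind(px[, 1], px[, 2])]) else NA_real_
  zspectrum(zset$offsets, vals, state = zset$state, b0_estimate = b0,
            source = "roi")
}

#' Read / write ROI definition CSVs
#'
#' Columns: `label`, `center_row`, `center_col` (0-based pixel
#' coordinates), `area_mm2`, and optionally `animal`, `group`.
#'
#' @param path CSV path.
#' @param rois List of [roi_circle()] objects.
#' @return `read_rois` returns a list of [roi_circle()];
#'   `write_rois` returns `path` invisibly.
#' @export
read_rois <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "center_row", "center_col", "area_mm2")
  if (!all(need %in% names(df)))
    stop("ROI CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  lapply(seq_len(nrow(df)), function(i)
    roi_circle(df$label[i], df$center_row[i], df$center_col[i],
               df$area_mm2[i],
               animal = if ("animal" %in% names(df)) as.character(df$animal[i]) else NA_character_,
               group = if ("group" %in% names(df)) as.character(df$group[i]) else NA_character_))
}

#' @rdname read_rois
#' @export
write_rois <- function(rois, path) {
  df <- do.call(rbind, lapply(rois, function(r)
    data.frame(label = r$label, center_row = r$center_row,
               center_col = r$center_col, area_mm2 = r$area_mm2,
               animal = r$animal, group = r$group)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
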