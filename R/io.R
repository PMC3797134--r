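#' Write an image stack to disk
#'
#' NIfTI (`.nii` / `.nii.gz`) stores one float32 3-D volume with the
#' saturation planes in acquisition order and the S0 control as the last
#' plane. Multi-page TIFF (`.tif` / `.tiff`) uses the same plane order;
#' since baseline TIFF samples are integer-scaled to [0, 1], the writer
#' applies an affine map recorded in a `<path>.scale.yaml` sidecar and the
#' reader inverts it (quantization ~4e-9, well below float32 precision).
#' The schedule is written alongside as `<path>.schedule.csv` unless a
#' schedule path is given.
#'
#' @param stack An [image_stack()].
#' @param path Output file; format chosen by extension.
#' @param schedule_path Where to write the schedule CSV (default derived
#'   from `path`).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, schedule_path = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$sat_images)
  planes <- array(0, dim = c(d[1L], d[2L], d[3L] + stack$schedule$includes_s0))
  planes[, , seq_len(d[3L])] <- stack$sat_images
  if (stack$schedule$includes_s0)
    planes[, , d[3L] + 1L] <- stack$s0_image
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    attr(planes, "pixdim") <- c(stack$pixel_size, stack$pixel_size, 1)
    RNifti::writeNifti(RNifti::asNifti(planes, datatype = "float"), path)
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    lo <- min(planes); hi <- max(planes)
    scale <- if (hi > lo) hi - lo else 1
    pages <- lapply(seq_len(dim(planes)[3L]), function(i)
      (planes[, , i] - lo) / scale)
    tiff::writeTIFF(pages, path, bits.per.sample = 32L,
                    compression = "deflate")
    yaml::write_yaml(list(offset = lo, scale = scale,
                          pixel_size_mm = stack$pixel_size),
                     paste0(path, ".scale.yaml"))
  } else stop("unsupported stack format: ", basename(path), call. = FALSE)
  if (is.null(schedule_path))
    schedule_path <- paste0(path, ".schedule.csv")
  write_schedule(stack$schedule, schedule_path)
  invisible(path)
}

#' Read an image stack
#'
#' Accepts NIfTI and multi-page TIFF as written by [write_stack()]. The
#' plane count must equal the schedule length plus one when the schedule
#' includes the S0 control (taken as the last plane).
#'
#' @param path Stack file.
#' @param schedule An [acquisition_schedule()] or path to a schedule CSV;
#'   defaults to the sidecar written by [write_stack()].
#' @param pixel_size Pixel size in mm; read from the file when available.
#' @return An [image_stack()].
#' @export
read_stack <- function(path, schedule = NULL, pixel_size = NULL) {
  if (!file.exists(path))
    stop("stack file not found: ", path, call. = FALSE)
  if (is.null(schedule))
    schedule <- paste0(path, ".schedule.csv")
  if (is.character(schedule)) {
    if (!file.exists(schedule))
      stop("schedule file not found: ", schedule, call. = FALSE)
    schedule <- read_schedule(schedule)
  }
  stopifnot(inherits(schedule, "acquisition_schedule"))
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    img <- RNifti::readNifti(path)
    planes <- array(as.numeric(img), dim = dim(img))
    if (is.null(pixel_size))
      pixel_size <- RNifti::pixdim(img)[1L]
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    pages <- tiff::readTIFF(path, all = TRUE)
    planes <- array(unlist(pages), dim = c(dim(pages[[1L]]), length(pages)))
    sidecar <- paste0(path, ".scale.yaml")
    if (file.exists(sidecar)) {
      sc <- yaml::read_yaml(sidecar)
      planes <- planes * sc$scale + sc$offset
      if (is.null(pixel_size)) pixel_size <- sc$pixel_size_mm
    }
  } else stop("unsupported stack format: ", basename(path), call. = FALSE)
  noff <- length(schedule$offsets)
  expected <- noff + schedule$includes_s0
  if (dim(planes)[3L] != expected)
    stop(sprintf("stack has %d planes but the schedule implies %d (%d offsets%s)",
                 dim(planes)[3L], expected, noff,
                 if (schedule$includes_s0) " + S0" else ""), call. = FALSE)
  if (is.null(pixel_size) || !is.finite(pixel_size) || pixel_size <= 0)
    pixel_size <- 30 / dim(planes)[1L]
  s0 <- if (schedule$includes_s0) planes[, , expected]
        else matrix(1, dim(planes)[1L], dim(planes)[2L])
  image_stack(planes[, , seq_len(noff), drop = FALSE], s0, schedule,
              pixel_size)
}

#' Write a phantom with its ground truth
#'
#' Stack (plus schedule sidecar), ground-truth maps as plain CSV matrices,
#' and generation parameters as a YAML sidecar.
#'
#' @param phantom A `cest_phantom`.
#' @param dir Output directory (created if needed).
#' @param format `"nifti"` or `"tiff"`.
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir, format = c("nifti", "tiff")) {
  format <- match.arg(format)
  stopifnot(inherits(phantom, "cest_phantom"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stack_file <- file.path(dir, if (format == "nifti") "stack.nii.gz"
                               else "stack.tif")
  write_stack(phantom$stack, stack_file,
              schedule_path = file.path(dir, "schedule.csv"))
  utils::write.csv(phantom$truth$b0_field,
                   file.path(dir, "truth_b0_ppm.csv"), row.names = FALSE)
  utils::write.csv(phantom$truth$true_asym,
                   file.path(dir, "truth_mtr_asym.csv"), row.names = FALSE)
  utils::write.csv(phantom$truth$tissue_map,
                   file.path(dir, "truth_tissue_map.csv"), row.names = FALSE)
  sp <- phantom$truth$spec
  yaml::write_yaml(list(image_size = sp$image_size, fov_mm = sp$fov_mm,
                        b0_amplitude = sp$b0_amplitude,
                        noise_sigma = sp$noise_sigma, seed = sp$seed,
                        target_offset = phantom$truth$target_offset),
                   file.path(dir, "truth_params.yaml"))
  invisible(dir)
}
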