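#' Synthetic mouse-thorax phantom specification
#'
#' Ground-truth geometry and tissue parameters for a single axial
#' thorax-like slice: an elliptical body of skeletal muscle on an air
#' background, two air-filled lung fields, one or two tumor nodules with
#' elevated amide exchange inside the lungs, and a spinal-cord disc used as
#' the reference tissue. A smooth static-field (B0) offset surface and
#' additive Gaussian noise emulate the main nuisance effects of in-vivo
#' acquisition.
#'
#' A positive local B0 offset shifts the apparent water center of that
#' pixel's z-spectrum downfield by the same amount (the pixel's spectrum is
#' the tissue spectrum evaluated at `offset - b0`).
#'
#' @param image_size Pixels per side of the square image.
#' @param fov_mm Field of view in mm (square).
#' @param tissues Named list of tissue definitions; each has `s0` (relative
#'   unsaturated signal; air 0) and `pools` (list of [pool_params()];
#'   `NULL` for air). Defaults from [default_tissues()].
#' @param tissue_map Optional label matrix overriding the built-in anatomy
#'   (entries must name `tissues`).
#' @param b0_amplitude Peak absolute value of the generated smooth B0
#'   surface, ppm.
#' @param b0_field Optional explicit B0 matrix in ppm (overrides
#'   `b0_amplitude`).
#' @param noise_sigma Additive Gaussian noise SD relative to muscle S0.
#' @param seed Integer seed; generation is bit-reproducible.
#' @param sim_grid Offset spacing (ppm) of the dense simulation grid from
#'   which pixel spectra at B0-shifted offsets are interpolated; nominal
#'   offsets are always evaluated exactly.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_size = 64, fov_mm = 30,
                         tissues = default_tissues(),
                         tissue_map = NULL,
                         b0_amplitude = 0.3, b0_field = NULL,
                         noise_sigma = 0.01, seed = 1L,
                         sim_grid = 0.05) {
  stopifnot(image_size >= 16, fov_mm > 0, noise_sigma >= 0, sim_grid > 0)
  if (!is.null(b0_field))
    stopifnot(is.matrix(b0_field),
              nrow(b0_field) == image_size, ncol(b0_field) == image_size)
  if (!is.null(tissue_map)) {
    stopifnot(is.matrix(tissue_map),
              nrow(tissue_map) == image_size, ncol(tissue_map) == image_size)
    if (!all(tissue_map %in% names(tissues)))
      stop("tissue_map contains labels not defined in 'tissues'", call. = FALSE)
  }
  structure(list(image_size = as.integer(image_size), fov_mm = fov_mm,
                 tissues = tissues, tissue_map = tissue_map,
                 b0_amplitude = b0_amplitude, b0_field = b0_field,
                 noise_sigma = noise_sigma, seed = as.integer(seed),
                 sim_grid = sim_grid),
            class = "phantom_spec")
}

#' Default phantom tissue definitions
#'
#' Water + amide two-pool systems with a broad semisolid MT pool whose
#' center sits slightly upfield of water, giving muscle and cord the
#' slightly negative intrinsic asymmetry seen in reference tissues. Tumor
#' tissue carries a three-fold amide fraction. Values are plausible for
#' high-field tissue and configurable; they are magnitude calibration, not
#' claimed biology.
#'
#' @param tumor_fraction Amide proton fraction of tumor tissue.
#' @param normal_fraction Amide proton fraction of muscle and cord.
#' @param amide_rate Amide-to-water exchange rate, 1/s.
#' @param mt MT pool shared by the soft tissues, a [pool_params()] or NULL.
#' @return Named list of tissue definitions (`s0`, `pools`).
#' @export
default_tissues <- function(tumor_fraction = 3e-3, normal_fraction = 1e-3,
                            amide_rate = 30, mt = mt_pool()) {
  soft <- function(frac, s0)
    list(s0 = s0,
         pools = c(default_pools(frac, amide_rate),
                   if (!is.null(mt)) list(mt)))
  list(air = list(s0 = 0, pools = NULL),
       muscle = soft(normal_fraction, 1.0),
       cord = soft(normal_fraction, 0.9),
       tumor_a = soft(tumor_fraction, 1.05),
       tumor_b = soft(tumor_fraction, 1.05))
}

# Built-in thorax-like anatomy: air background, muscle body ellipse, two
# air lung fields, tumors in the lungs, cord near the dorsal midline.
.default_tissue_map <- function(n) {
  map <- matrix("air", n, n)
  rc <- (row(map) - (n + 1) / 2) / n
  cc <- (col(map) - (n + 1) / 2) / n
  body <- (rc / 0.40)^2 + (cc / 0.44)^2 <= 1
  map[body] <- "muscle"
  lungL <- ((rc + 0.08) / 0.22)^2 + ((cc + 0.20) / 0.16)^2 <= 1
  lungR <- ((rc + 0.08) / 0.22)^2 + ((cc - 0.20) / 0.16)^2 <= 1
  map[lungL | lungR] <- "air"
  tumA <- (rc + 0.10)^2 + (cc + 0.20)^2 <= 0.07^2
  tumB <- (rc + 0.04)^2 + (cc - 0.22)^2 <= 0.06^2
  map[tumA] <- "tumor_a"
  map[tumB] <- "tumor_b"
  cord <- (rc - 0.30)^2 + cc^2 <= 0.045^2
  map[cord] <- "cord"
  map
}

# Smooth low-order B0 surface scaled to a peak amplitude (ppm).
.default_b0_field <- function(n, amplitude) {
  if (amplitude == 0) return(matrix(0, n, n))
  u <- matrix(seq(-1, 1, length.out = n), n, n)
  v <- t(u)
  raw <- 0.55 * u + 0.25 * v + 0.20 * sin(pi * u / 2) * sin(pi * v / 2)
  amplitude * raw / max(abs(raw))
}

# Dense-grid tissue z-spectrum with exact values at the nominal offsets;
# returns an interpolating spline function of offset (ppm).
.tissue_spline <- function(pools, sat, scanner, offsets, b0_range, sim_grid) {
  lo <- min(offsets) - max(0, b0_range[2L]) - sim_grid
  hi <- max(offsets) - min(0, b0_range[1L]) + sim_grid
  grid <- sort(unique(round(c(seq(lo, hi, by = sim_grid), offsets), 10)))
  zs <- simulate_zspectrum(pools, sat, scanner,
                           acquisition_schedule(grid, includes_s0 = FALSE))
  stats::splinefun(zs$offsets, zs$values, method = "natural")
}

#' Generate a synthetic phantom image stack
#'
#' Simulates, per tissue, the continuous-wave saturation z-spectrum on a
#' dense offset grid, evaluates it per pixel at `offset - b0(pixel)`,
#' scales by the tissue's unsaturated signal, and adds seeded Gaussian
#' noise. Returns the image stack together with the ground truth (tissue
#' map, B0 field, true per-pixel MTR asymmetry at the target offset).
#'
#' @param spec A [phantom_spec()].
#' @param schedule [acquisition_schedule()]; must include the S0 control.
#' @param sat,scanner Acquisition parameters.
#' @param target_offset Offset (ppm) at which the ground-truth asymmetry
#'   map is recorded.
#' @return An object of class `cest_phantom`: `$stack` (an [image_stack()])
#'   and `$truth` (tissue map, b0 field, true asymmetry map, parameters).
#' @export
generate_phantom_stack <- function(spec, schedule = acquisition_schedule(),
                                   sat = saturation_params(),
                                   scanner = scanner_params(),
                                   target_offset = 3.5) {
  stopifnot(inherits(spec, "phantom_spec"),
            inherits(schedule, "acquisition_schedule"))
  n <- spec$image_size
  map <- if (is.null(spec$tissue_map)) .default_tissue_map(n) else spec$tissue_map
  b0 <- if (is.null(spec$b0_field)) .default_b0_field(n, spec$b0_amplitude)
        else spec$b0_field
  offsets <- schedule$offsets
  noff <- length(offsets)

  sat_images <- array(0, dim = c(n, n, noff))
  s0_image <- matrix(0, n, n)
  true_asym <- matrix(NA_real_, n, n)

  spline_cache <- new.env(parent = emptyenv())
  for (lab in unique(as.vector(map))) {
    tis <- spec$tissues[[lab]]
    px <- which(map == lab)
    if (is.null(tis$pools) || tis$s0 <= 0) {
      true_asym[px] <- NA_real_
      next
    }
    key <- paste(deparse(tis$pools), collapse = "")
    spl <- spline_cache[[key]]
    if (is.null(spl)) {
      spl <- .tissue_spline(tis$pools, sat, scanner, offsets,
                            range(b0), spec$sim_grid)
      spline_cache[[key]] <- spl
    }
    for (i in seq_len(noff)) {
      plane <- sat_images[, , i]
      plane[px] <- tis$s0 * spl(offsets[i] - b0[px])
      sat_images[, , i] <- plane
    }
    s0_image[px] <- tis$s0
    true_asym[px] <- spl(-target_offset) - spl(target_offset)
  }

  if (spec$noise_sigma > 0) {
    old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
    set.seed(spec$seed)
    sat_images <- sat_images + array(stats::rnorm(length(sat_images),
                                                  sd = spec$noise_sigma),
                                     dim = dim(sat_images))
    s0_image <- s0_image + stats::rnorm(length(s0_image),
                                        sd = spec$noise_sigma)
  }

  stack <- image_stack(sat_images, s0_image, schedule,
                       pixel_size = spec$fov_mm / n)
  structure(list(
    stack = stack,
    truth = list(tissue_map = map, b0_field = b0, true_asym = true_asym,
                 target_offset = target_offset, spec = spec)
  ), class = "cest_phantom")
}

#' @export
print.cest_phantom <- function(x, ...) {
  tab <- table(x$truth$tissue_map)
  cat(sprintf("Synthetic CEST phantom: %d x %d pixels, %d offsets + S0\n",
              nrow(x$truth$tissue_map), ncol(x$truth$tissue_map),
              length(x$stack$schedule$offsets)))
  cat("  tissues:", paste(sprintf("%s (%d px)", names(tab), tab),
                          collapse = ", "), "\n")
  cat(sprintf("  b0 range: [%+.3f, %+.3f] ppm, noise sigma: %.3g\n",
              min(x$truth$b0_field), max(x$truth$b0_field),
              x$truth$spec$noise_sigma))
  invisible(x)
}

#' ROIs at the phantom's ground-truth tissue centroids
#'
#' Places one circular ROI at the pixel centroid of each requested tissue
#' label, the synthetic counterpart of manual ROI placement.
#'
#' @param phantom A `cest_phantom`.
#' @param labels Tissue labels to target.
#' @param area_mm2 ROI area in mm^2 (default matches a typical small-animal
#'   tumor ROI).
#' @return List of [roi_circle()] objects labelled `tumor`/`cord`.
#' @export
phantom_rois <- function(phantom, labels = c("tumor_a", "tumor_b", "cord"),
                         area_mm2 = 0.34) {
  map <- phantom$truth$tissue_map
  out <- list()
  for (lab in labels) {
    px <- which(map == lab, arr.ind = TRUE)
    if (!nrow(px)) next
    kind <- if (grepl("^tumor", lab)) "tumor" else
            if (lab == "cord") "cord" else "other"
    out[[lab]] <- roi_circle(label = kind,
                             center_row = mean(px[, 1]) - 1,
                             center_col = mean(px[, 2]) - 1,
                             area_mm2 = area_mm2)
  }
  out
}

#' Cohort specification
#'
#' Two (or more) groups of animals; each animal is a phantom whose tumor
#' amide fraction is drawn around its group mean with a fractional
#' inter-animal variability, and whose noise realization is seeded
#' per-animal.
#'
#' @param n_per_group Animals per group (>= 2).
#' @param groups Group labels.
#' @param tumor_fraction Named (per group) mean tumor amide fractions.
#' @param variability Fractional SD of the per-animal tumor amide fraction.
#' @param seed Master seed; per-animal seeds are derived from it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 6, groups = c("lineA", "lineB"),
                        tumor_fraction = c(lineA = 7.5e-3, lineB = 3e-3),
                        variability = 0.2, seed = 1L) {
  stopifnot(n_per_group >= 2, length(groups) >= 2,
            all(groups %in% names(tumor_fraction)), variability >= 0)
  structure(list(n_per_group = as.integer(n_per_group), groups = groups,
                 tumor_fraction = tumor_fraction,
                 variability = variability, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a multi-animal synthetic cohort
#'
#' @param cohort A [cohort_spec()].
#' @param template A [phantom_spec()] used for every animal (its seed is
#'   replaced by a per-animal derived seed).
#' @param schedule,sat,scanner Acquisition parameters.
#' @param target_offset Ground-truth asymmetry offset, ppm.
#' @return List of animals, each with `id`, `group`, `phantom`
#'   (a `cest_phantom`), and the drawn `tumor_fraction`; the ground-truth
#'   per-group mean fractions are attached as attribute `group_means`.
#' @export
generate_cohort <- function(cohort, template = phantom_spec(),
                            schedule = acquisition_schedule(),
                            sat = saturation_params(),
                            scanner = scanner_params(),
                            target_offset = 3.5) {
  stopifnot(inherits(cohort, "cohort_spec"), inherits(template, "phantom_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(cohort$seed)
  animals <- list()
  idx <- 0L
  for (g in cohort$groups) {
    fbar <- cohort$tumor_fraction[[g]]
    for (a in seq_len(cohort$n_per_group)) {
      idx <- idx + 1L
      frac <- max(fbar * (1 + cohort$variability * stats::rnorm(1)), 1e-6)
      tis <- template$tissues
      for (lab in grep("^tumor", names(tis), value = TRUE)) {
        pools <- tis[[lab]]$pools
        for (j in seq_along(pools))
          if (pools[[j]]$name == "amide") pools[[j]]$fraction <- frac
        tis[[lab]]$pools <- pools
      }
      spec_a <- template
      spec_a$tissues <- tis
      spec_a$seed <- cohort$seed + 1000L * idx
      ph <- generate_phantom_stack(spec_a, schedule, sat, scanner,
                                   target_offset)
      animals[[idx]] <- list(id = sprintf("%s_%02d", g, a), group = g,
                             phantom = ph, tumor_fraction = frac)
    }
  }
  gm <- tapply(vapply(animals, `[[`, numeric(1), "tumor_fraction"),
               vapply(animals, `[[`, character(1), "group"), mean)
  attr(animals, "group_means") <- gm
  animals
}
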