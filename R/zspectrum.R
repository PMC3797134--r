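#' Z-spectrum container
#'
#' Normalized water signal S_sat/S_0 versus saturation offset for one pixel,
#' one ROI, or one simulated tissue. Offsets are stored in ascending order
#' regardless of acquisition order; this is the package-wide convention.
#'
#' @param offsets Offsets in ppm.
#' @param values S_sat/S_0 at each offset.
#' @param state One of `"raw"`, `"fitted"`, `"b0-corrected"`.
#' @param b0_estimate Apparent water-center shift in ppm, required when
#'   `state = "b0-corrected"`.
#' @param source Provenance label: `"simulated"`, `"pixel"` or `"roi"`.
#' @param flags Optional logical vector marking offsets whose corrected
#'   value came from polynomial extrapolation beyond the measured range.
#' @return An object of class `zspectrum`.
#' @export
zspectrum <- function(offsets, values, state = c("raw", "fitted", "b0-corrected"),
                      b0_estimate = NA_real_,
                      source = c("simulated", "pixel", "roi"),
                      flags = NULL) {
  state <- match.arg(state)
  source <- match.arg(source)
  stopifnot(is.numeric(offsets), is.numeric(values),
            length(offsets) == length(values),
            all(is.finite(offsets)))
  if (anyDuplicated(offsets))
    stop("offsets must be unique", call. = FALSE)
  if (state == "b0-corrected" && !is.finite(b0_estimate))
    stop("b0-corrected spectra must carry a b0 estimate", call. = FALSE)
  ord <- order(offsets)
  if (is.null(flags)) flags <- logical(length(offsets))
  structure(list(offsets = offsets[ord], values = values[ord],
                 state = state, b0_estimate = b0_estimate,
                 source = source, flags = flags[ord]),
            class = "zspectrum")
}

#' @export
print.zspectrum <- function(x, ...) {
  cat(sprintf("Z-spectrum (%s, %s): %d offsets, %.3g to %.3g ppm",
              x$source, x$state, length(x$offsets),
              min(x$offsets), max(x$offsets)))
  if (is.finite(x$b0_estimate))
    cat(sprintf(", b0 = %+.3f ppm", x$b0_estimate))
  cat(sprintf("\n  Z range: [%.4f, %.4f]\n",
              min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE)))
  invisible(x)
}

#' @export
plot.zspectrum <- function(x, ..., xlab = "offset (ppm)",
                           ylab = expression(S[sat] / S[0])) {
  # downfield conventionally drawn on the left
  graphics::plot(x$offsets, x$values, type = "b", pch = 16,
                 xlim = rev(range(x$offsets)), xlab = xlab, ylab = ylab, ...)
  graphics::abline(v = 0, lty = 3)
  invisible(x)
}

#' @export
as.data.frame.zspectrum <- function(x, ...) {
  data.frame(offset_ppm = x$offsets, z_value = x$values,
             state = x$state, extrapolated = x$flags)
}

#' Magnetization transfer ratio
#'
#' MTR = 1 - S_sat/S_0.
#'
#' @param s_sat Saturated signal.
#' @param s0 Unsaturated control signal; must be positive.
#' @return 1 - s_sat/s0, vectorized.
#' @export
compute_mtr <- function(s_sat, s0) {
  if (any(!is.finite(s0)) || any(s0 <= 0))
    stop("S0 must be positive and finite", call. = FALSE)
  1 - s_sat / s0
}
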