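#' Saturation-offset acquisition schedule
#'
#' Ordered list of saturation frequency offsets plus a flag for the
#' unsaturated control (S0) acquisition. The default protocol acquires 25
#' offsets from +6 to -6 ppm in 0.5 ppm steps, stored high-to-low in
#' acquisition order, plus one S0 image.
#'
#' @param offsets Saturation offsets in ppm, acquisition order.
#' @param includes_s0 Whether an unsaturated control image is acquired.
#' @return An object of class `acquisition_schedule`.
#' @export
acquisition_schedule <- function(offsets = seq(6, -6, by = -0.5),
                                 includes_s0 = TRUE) {
  stopifnot(is.numeric(offsets), length(offsets) >= 1L,
            all(is.finite(offsets)))
  if (anyDuplicated(offsets))
    stop("offsets must be unique", call. = FALSE)
  structure(list(offsets = as.numeric(offsets),
                 includes_s0 = isTRUE(includes_s0)),
            class = "acquisition_schedule")
}

#' @export
print.acquisition_schedule <- function(x, ...) {
  cat(sprintf("Acquisition schedule: %d offsets, %.3g to %.3g ppm%s\n",
              length(x$offsets), x$offsets[1L],
              x$offsets[length(x$offsets)],
              if (x$includes_s0) ", plus S0 control" else ""))
  invisible(x)
}

#' @export
length.acquisition_schedule <- function(x) length(x$offsets)

#' Read / write a schedule CSV
#'
#' Plain CSV with columns `index` (1-based acquisition order) and
#' `offset_ppm`. The S0 control is not an offset and is not listed; its
#' presence is recorded in the optional `includes_s0` attribute column of
#' the first row if present, otherwise assumed TRUE.
#'
#' @param path File path.
#' @param schedule An [acquisition_schedule()].
#' @return `read_schedule` returns an [acquisition_schedule()];
#'   `write_schedule` returns `path` invisibly.
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "acquisition_schedule"))
  df <- data.frame(index = seq_along(schedule$offsets),
                   offset_ppm = schedule$offsets,
                   includes_s0 = schedule$includes_s0)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("index", "offset_ppm") %in% names(df)))
    stop("schedule CSV must have columns 'index' and 'offset_ppm'",
         call. = FALSE)
  df <- df[order(df$index), , drop = FALSE]
  incl <- if ("includes_s0" %in% names(df)) isTRUE(df$includes_s0[1L]) else TRUE
  acquisition_schedule(df$offset_ppm, includes_s0 = incl)
}
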