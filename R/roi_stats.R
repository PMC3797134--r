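#' Per-animal ROI summary with reference-tissue normalization
#'
#' Averages the asymmetry spectra of an animal's tumor ROIs (unweighted,
#' one value per animal when several tumors are measured) and subtracts the
#' spinal-cord reference spectrum offset-wise: corrected = tumor - cord.
#' The subtraction removes the intrinsically asymmetric background
#' (semisolid MT / NOE) contribution shared by the tissues.
#'
#' @param tumor_asyms List of [asym_spectrum()] objects, one per tumor ROI
#'   (at least one).
#' @param cord_asym The cord reference [asym_spectrum()] (exactly one).
#' @param animal,group Identifiers carried into the result.
#' @return An object of class `animal_result`: data frame with columns
#'   `offset_ppm`, `tumor`, `cord`, `corrected` (all dimensionless), plus
#'   `animal` and `group` fields.
#' @export
animal_summary <- function(tumor_asyms, cord_asym,
                           animal = NA_character_, group = NA_character_) {
  if (inherits(tumor_asyms, "asym_spectrum"))
    tumor_asyms <- list(tumor_asyms)
  if (!length(tumor_asyms))
    stop("at least one tumor ROI is required", call. = FALSE)
  if (is.null(cord_asym) || !inherits(cord_asym, "asym_spectrum"))
    stop("a cord reference ROI is required for normalization", call. = FALSE)
  offs <- tumor_asyms[[1L]]$offsets
  for (a in tumor_asyms)
    if (!isTRUE(all.equal(a$offsets, offs)))
      stop("tumor asymmetry spectra have differing offsets", call. = FALSE)
  if (!isTRUE(all.equal(cord_asym$offsets, offs)))
    stop("cord spectrum offsets differ from tumor offsets", call. = FALSE)
  tumor <- rowMeans(vapply(tumor_asyms, `[[`, numeric(length(offs)), "values"))
  structure(list(
    table = data.frame(offset_ppm = offs, tumor = tumor,
                       cord = cord_asym$values,
                       corrected = tumor - cord_asym$values),
    animal = animal, group = group, n_tumors = length(tumor_asyms)
  ), class = "animal_result")
}

#' @export
print.animal_result <- function(x, ...) {
  cat(sprintf("Animal %s (group %s), %d tumor ROI(s)\n",
              x$animal, x$group, x$n_tumors))
  i35 <- which(abs(x$table$offset_ppm - 3.5) <= 1e-6)
  if (length(i35))
    cat(sprintf("  tumor %.2f%%, cord %.2f%%, corrected %.2f%% at 3.5 ppm\n",
                100 * x$table$tumor[i35], 100 * x$table$cord[i35],
                100 * x$table$corrected[i35]))
  invisible(x)
}

# Per-animal values of one quantity at one offset.
.animal_values <- function(animals, offset, quantity) {
  vapply(animals, function(a) {
    i <- which(abs(a$table$offset_ppm - offset) <= 1e-6)
    if (length(i) != 1L)
      stop(sprintf("offset %.4g ppm not present in animal %s",
                   offset, a$animal), call. = FALSE)
    a$table[[quantity]][i]
  }, numeric(1))
}

#' Pooled two-sample Student's t-test from summary statistics
#'
#' Two-tailed pooled-variance t-test computed from group means, SDs
#' (n-1 denominator) and sizes; identical to the test on any raw data
#' having those summaries. Degenerate case: zero pooled variance gives
#' t = 0, p = 1 when the means agree and is flagged (p reported as 0,
#' t infinite) when they differ.
#'
#' @param mean1,sd1,n1 First group summary.
#' @param mean2,sd2,n2 Second group summary.
#' @return List with `t`, `df`, `p`, and `degenerate` flag.
#' @export
summary_from_stats <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  if (sp2 == 0) {
    if (mean1 == mean2)
      return(list(t = 0, df = df, p = 1, degenerate = FALSE))
    return(list(t = sign(mean1 - mean2) * Inf, df = df, p = 0,
                degenerate = TRUE))
  }
  t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df), degenerate = FALSE)
}

#' Group comparison at one offset
#'
#' Two-sample, two-tailed, pooled-variance Student's t-test on the
#' per-animal values of a quantity at one offset.
#'
#' @param animals List of [animal_summary()] results covering exactly two
#'   groups with at least two animals each.
#' @param offset Offset in ppm.
#' @param quantity `"corrected"` (tumor minus cord), `"tumor"` or `"cord"`.
#' @return List with `t`, `df`, `p`, group labels, per-group `means`,
#'   `sds`, `ns`, and a `degenerate` flag.
#' @export
group_compare <- function(animals, offset = 3.5,
                          quantity = c("corrected", "tumor", "cord")) {
  quantity <- match.arg(quantity)
  groups <- vapply(animals, `[[`, character(1), "group")
  glev <- unique(groups)
  if (length(glev) != 2L)
    stop("exactly two groups are required", call. = FALSE)
  vals <- .animal_values(animals, offset, quantity)
  x1 <- vals[groups == glev[1L]]; x2 <- vals[groups == glev[2L]]
  if (length(x1) < 2L || length(x2) < 2L)
    stop("at least two animals per group are required", call. = FALSE)
  res <- if (stats::var(x1) + stats::var(x2) > 0) {
    ht <- stats::t.test(x1, x2, var.equal = TRUE)
    list(t = unname(ht$statistic), df = unname(ht$parameter),
         p = ht$p.value, degenerate = FALSE)
  } else {
    summary_from_stats(mean(x1), 0, length(x1), mean(x2), 0, length(x2))
  }
  c(res, list(groups = glev,
              means = c(mean(x1), mean(x2)),
              sds = c(stats::sd(x1), stats::sd(x2)),
              ns = c(length(x1), length(x2))))
}

#' Per-offset group statistics table
#'
#' Assembles, for the raw tumor and the cord-corrected asymmetry, per-group
#' n, mean, and SD at every offset, together with the pooled two-tailed
#' t-test between the two groups. Values are reported in percent. The
#' per-offset tests are not adjusted for multiplicity by default, matching
#' common practice of testing each offset at alpha; an optional Holm
#' adjustment is available.
#'
#' @param animals List of [animal_summary()] results (two groups).
#' @param alpha Significance level.
#' @param holm Apply a Holm correction across offsets within each quantity.
#' @return Data frame of class `group_table` with one row per
#'   quantity x group x offset; the test columns (`t`, `p`,
#'   `significant`) are repeated on both group rows of a comparison.
#' @export
build_group_table <- function(animals, alpha = 0.05, holm = FALSE) {
  offs <- animals[[1L]]$table$offset_ppm
  rows <- list()
  for (quantity in c("tumor", "corrected")) {
    stats_off <- lapply(offs, function(o)
      group_compare(animals, o, quantity))
    p <- vapply(stats_off, `[[`, numeric(1), "p")
    if (holm) p <- stats::p.adjust(p, "holm")
    for (j in seq_along(offs)) {
      s <- stats_off[[j]]
      for (gi in 1:2) {
        rows[[length(rows) + 1L]] <- data.frame(
          quantity = quantity, group = s$groups[gi],
          offset_ppm = offs[j], n = s$ns[gi],
          mean_pct = 100 * s$means[gi], sd_pct = 100 * s$sds[gi],
          t = s$t, p = p[j], significant = p[j] < alpha,
          degenerate = s$degenerate)
      }
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$quantity, out$offset_ppm, out$group), ]
  rownames(out) <- NULL
  class(out) <- c("group_table", class(out))
  out
}

#' @export
print.group_table <- function(x, ...) {
  cat("Group comparison table (values in %):\n")
  print.data.frame(x, digits = 3, ...)
  invisible(x)
}
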