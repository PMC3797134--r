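test_that("noise-free spectra are fitted with negligible residual", {
  fit <- fit_zspectrum(fx_z0())
  expect_lt(sqrt(mean(residuals(fit)^2)), 1e-3)
  expect_s3_class(fit, "zspec_fit")
  expect_named(coef(fit), c("gaussian", "positive", "negative"))
})

test_that("a symmetric spectrum is located at center zero", {
  fit <- fit_zspectrum(simulate_zspectrum(default_pools(0), fx_sat(),
                                          fx_scanner()))
  expect_lt(abs(fit$gaussian$center), 0.01)
})

test_that("a flat spectrum yields no well and a constant interpolant", {
  flat <- zspectrum(seq(-6, 6, by = 0.5), rep(1, 25))
  fit <- fit_zspectrum(flat)
  expect_lt(fit$gaussian$amplitude, 1e-3)
  curve <- predict(fit)
  expect_equal(as.numeric(curve), rep(1, length(curve)), tolerance = 1e-6)
  b0 <- estimate_b0(fit)
  expect_false(attr(b0, "reliable"))
  expect_error(center_zspectrum(flat, fit, b0), "unreliable")
})

test_that("fitting requires enough points per side", {
  short <- zspectrum(seq(-2, 2, by = 0.5), rep(0.5, 9))
  expect_error(fit_zspectrum(short), "7 points")
})

test_that("injected water-center shifts are recovered accurately", {
  cases <- list(c(0, 0.01), c(0.3, 0.02), c(-0.5, 0.05))
  for (cs in cases) {
    zs <- simulate_zspectrum(fx_tumor_pools(), fx_sat(), fx_scanner(),
                             b0_offset = cs[1])
    b0 <- estimate_b0(fit_zspectrum(zs))
    expect_true(attr(b0, "reliable"))
    expect_lt(abs(as.numeric(b0) - cs[1]), cs[2])
  }
})

test_that("centering with b0 = 0 is the identity on the fitted values", {
  zs <- fx_z0()
  fit <- fit_zspectrum(zs)
  corr <- center_zspectrum(zs, fit, 0)
  expect_equal(corr$values, as.numeric(predict(fit, zs$offsets)))
  expect_identical(corr$state, "b0-corrected")
  expect_equal(corr$b0_estimate, 0)
})

test_that("centering refuses shifts outside the correctable range", {
  zs <- fx_z0()
  fit <- fit_zspectrum(zs)
  expect_error(center_zspectrum(zs, fit, 1.5), "correctable range")
})

test_that("shift-then-correct round trip recovers the unshifted asymmetry", {
  # resampling from 0.5 ppm samples bounds the recovery accuracy; the
  # tolerances here are the package's measured accuracy floor per tissue
  ref_tumor <- simulate_zspectrum(fx_tumor_pools(), fx_sat(), fx_scanner())
  ref_cord <- simulate_zspectrum(fx_cord_pools(), fx_sat(), fx_scanner())
  for (b0 in c(-0.4, -0.2, 0.1, 0.3)) {
    for (tissue in c("tumor", "cord")) {
      pools <- if (tissue == "tumor") fx_tumor_pools() else fx_cord_pools()
      ref <- if (tissue == "tumor") ref_tumor else ref_cord
      zs <- simulate_zspectrum(pools, fx_sat(), fx_scanner(), b0_offset = b0)
      fit <- fit_zspectrum(zs)
      corr <- center_zspectrum(zs, fit, estimate_b0(fit))
      err <- abs(mtr_asym(corr, 3.5) - mtr_asym(ref, 3.5))
      expect_lt(err, if (tissue == "tumor") 0.005 else 0.002)
    }
  }
})

test_that("offsets shifted beyond the measured range are flagged", {
  zs <- simulate_zspectrum(fx_tumor_pools(), fx_sat(), fx_scanner(),
                           b0_offset = 0.3)
  fit <- fit_zspectrum(zs)
  corr <- center_zspectrum(zs, fit, estimate_b0(fit))
  expect_true(corr$flags[which.max(corr$offsets)])
  expect_false(any(corr$flags[abs(corr$offsets) <= 5]))
})

test_that("correction is idempotent", {
  zs <- simulate_zspectrum(fx_tumor_pools(), fx_sat(), fx_scanner(),
                           b0_offset = 0.3)
  fit <- fit_zspectrum(zs)
  corr <- center_zspectrum(zs, fit, estimate_b0(fit))
  fit2 <- fit_zspectrum(corr)
  b0_2 <- estimate_b0(fit2)
  expect_lt(abs(as.numeric(b0_2)), 0.02)
  corr2 <- center_zspectrum(corr, fit2, b0_2)
  expect_lt(abs(mtr_asym(corr2, 3.5) - mtr_asym(corr, 3.5)), 5e-4)
})

test_that("pixel-wise B0 map recovers the smooth ground-truth field", {
  ph <- fx_phantom_free()
  bm <- b0_map(assemble_zspectra(ph$stack))
  err <- bm$values - ph$truth$b0_field
  err <- err[is.finite(err)]
  expect_gt(length(err), 100)
  expect_lt(sqrt(mean(err^2)), 0.03)
})

test_that("a zero B0 field maps to near-zero estimates, deterministically", {
  n <- 24L
  spec <- phantom_spec(image_size = n, noise_sigma = 0, b0_amplitude = 0,
                       tissue_map = matrix("muscle", n, n))
  ph <- generate_phantom_stack(spec)
  zset <- assemble_zspectra(ph$stack)
  bm1 <- b0_map(zset)
  expect_lt(max(abs(bm1$values)), 0.01)
  bm2 <- b0_map(zset)
  expect_identical(bm1$values, bm2$values)
})

test_that("a linear-ramp B0 field is recovered with the right slope", {
  n <- 24L
  ramp <- matrix(rep(seq(-0.3, 0.3, length.out = n), each = n), n, n)
  spec <- phantom_spec(image_size = n, noise_sigma = 0, b0_field = ramp,
                       tissue_map = matrix("muscle", n, n))
  ph <- generate_phantom_stack(spec)
  bm <- b0_map(assemble_zspectra(ph$stack))
  col_means <- colMeans(bm$values)
  slope <- stats::coef(stats::lm(col_means ~ seq_len(n)))[2L]
  true_slope <- (0.3 - (-0.3)) / (n - 1)
  expect_lt(abs(slope - true_slope) / true_slope, 0.05)
})

test_that("b0 estimate RMS error grows with the noise level", {
  n <- 24L
  rms <- vapply(c(0, 0.01, 0.04), function(sig) {
    spec <- phantom_spec(image_size = n, noise_sigma = sig, seed = 21,
                         tissue_map = matrix("muscle", n, n))
    ph <- generate_phantom_stack(spec)
    bm <- b0_map(assemble_zspectra(ph$stack))
    err <- (bm$values - ph$truth$b0_field)[is.finite(bm$values)]
    sqrt(mean(err^2))
  }, numeric(1))
  expect_true(all(diff(rms) >= 0))
})

test_that("whole-stack correction drops uncorrectable pixels from the mask", {
  ph <- fx_phantom_free()
  zset <- assemble_zspectra(ph$stack)
  cz <- correct_stack(zset)
  expect_identical(cz$state, "b0-corrected")
  expect_true(all(is.finite(cz$b0[cz$mask])))
  expect_true(all(!cz$mask | zset$mask))
})
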