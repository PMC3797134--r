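test_that("evolution system rejects invalid pools and orders water first", {
  expect_error(build_bm_generator(list(), fx_sat()), "at least one")
  sys <- build_bm_generator(rev(default_pools()), fx_sat(), fx_scanner(), 3.5)
  expect_identical(sys$pools[[1L]]$name, "water")
  expect_equal(dim(sys$A), c(6L, 6L))
})

test_that("exchange terms conserve magnetization and obey detailed balance", {
  pools <- c(default_pools(2e-3, 40), list(mt_pool(0.05)))
  sys <- build_bm_generator(pools, fx_sat(), fx_scanner(), 1)
  n <- length(sys$pools)
  iz <- 2 * n + (1:n)
  r1 <- vapply(sys$pools, function(p) 1 / p$t1, numeric(1))
  K <- sys$A[iz, iz] + diag(r1, n)
  # columns of the pure exchange sub-matrix sum to zero (conservation)
  expect_equal(colSums(K), rep(0, n), tolerance = 1e-12)
  # water->solute rate is fraction * solute->water rate
  for (s in 2:n)
    expect_equal(K[s, 1], sys$pools[[s]]$fraction * K[1, s])
})

test_that("no irradiation preserves equilibrium z-magnetization exactly", {
  sat0 <- saturation_params(b1_amplitude = 0)
  zs <- simulate_zspectrum(default_pools(), sat0, fx_scanner())
  expect_equal(zs$values, rep(1, length(zs$offsets)), tolerance = 1e-12)
})

test_that("zero saturation duration gives Z = 1 at every offset", {
  satd0 <- saturation_params(duration = 0)
  zs <- simulate_zspectrum(default_pools(), satd0, fx_scanner())
  expect_identical(zs$values, rep(1, 25L))
})

test_that("far off-resonance irradiation of pure water leaves Z near 1", {
  water <- list(pool_params("water", t1 = 1.8, t2 = 0.05))
  z <- bm_steady_state(water, fx_sat(), fx_scanner(), offset = 100)
  expect_equal(z, 1, tolerance = 1e-3)
  zt <- simulate_zspectrum(water, fx_sat(), fx_scanner(),
                           acquisition_schedule(100, includes_s0 = FALSE))
  expect_equal(zt$values, 1, tolerance = 1e-3)
})

test_that("matrix-exponential and stiff ODE propagators agree", {
  sched <- acquisition_schedule(c(6, 3.5, 1, 0.5, 0, -3.5), FALSE)
  pools <- fx_tumor_pools()
  zm <- simulate_zspectrum(pools, fx_sat(), fx_scanner(), sched)
  zo <- simulate_zspectrum(pools, fx_sat(), fx_scanner(), sched,
                           method = "ode")
  expect_equal(zm$values, zo$values, tolerance = 1e-6)
})

test_that("long-saturation ODE spectrum converges to the steady-state solve", {
  sched <- acquisition_schedule(c(6, 3.5, 1, 0, -1, -3.5), FALSE)
  sat30 <- saturation_params(duration = 30)
  z <- simulate_zspectrum(default_pools(), sat30, fx_scanner(), sched,
                          method = "ode")
  zss <- vapply(sched$offsets, function(o)
    bm_steady_state(default_pools(), sat30, fx_scanner(), o), numeric(1))
  expect_lt(max(abs(z$values - zss[order(sched$offsets)])), 1e-3)
})

test_that("simulated Z stays within [0, 1] for tissue-like parameter sets", {
  # bound holds once transverse coherence has damped out; tissue T2 and the
  # 4 s pulse are deep in that regime (coherent nutation with second-scale
  # T2 can ring below zero and is out of scope)
  systems <- list(
    default_pools(),
    default_pools(0.01, 200),
    fx_tumor_pools(),
    fx_cord_pools(),
    list(pool_params("water", t1 = 1.2, t2 = 0.03)))
  for (b1 in c(0.5, 1.7, 3)) {
    for (dur in c(2, 4)) {
      sat <- saturation_params(b1_amplitude = b1, duration = dur)
      for (pools in systems) {
        zs <- simulate_zspectrum(pools, sat, fx_scanner())
        expect_true(all(zs$values >= -1e-9 & zs$values <= 1 + 1e-9))
      }
    }
  }
})

test_that("zero amide fraction gives a symmetric spectrum with zero asymmetry", {
  zs <- simulate_zspectrum(default_pools(amide_fraction = 0), fx_sat(),
                           fx_scanner())
  expect_lt(abs(mtr_asym(zs, 3.5)), 1e-6)
  a <- asym_spectrum(zs)
  expect_lt(max(abs(a$values)), 1e-6)
})

test_that("MTR asymmetry at 3.5 ppm increases strictly with amide fraction", {
  fracs <- c(0, 0.001, 0.003, 0.006, 0.01)
  asym <- vapply(fracs, function(f)
    simulate_mtr_asym(default_pools(f), fx_sat(), fx_scanner()), numeric(1))
  expect_true(all(diff(asym) > 0))
})

test_that("zero-exchange amide pool reproduces the no-amide spectrum", {
  sched <- acquisition_schedule(c(4, 3.5, 3, -3, -3.5, -4), FALSE)
  z_none <- simulate_zspectrum(default_pools(0), fx_sat(), fx_scanner(), sched)
  pools0 <- list(pool_params("water", t1 = 1.8, t2 = 0.05),
                 pool_params("amide", t1 = 1, t2 = 0.01, fraction = 1e-3,
                             shift = 3.5, exchange_rate = 0))
  z_k0 <- simulate_zspectrum(pools0, fx_sat(), fx_scanner(), sched)
  expect_equal(z_k0$values, z_none$values, tolerance = 1e-9)
})

test_that("swapping (fraction, rate) at fixed product changes Z boundedly", {
  sched <- acquisition_schedule(c(3.5, -3.5), FALSE)
  z1 <- simulate_zspectrum(default_pools(1e-3, 60), fx_sat(), fx_scanner(),
                           sched)
  z2 <- simulate_zspectrum(default_pools(2e-3, 30), fx_sat(), fx_scanner(),
                           sched)
  expect_lt(max(abs(z1$values - z2$values)), 0.05)
})

test_that("amide fraction inversion reproduces the target asymmetry", {
  f <- amide_fraction_for_asym(0.05)
  expect_equal(simulate_mtr_asym(default_pools(f), fx_sat(), fx_scanner()),
               0.05, tolerance = 1e-5)
})
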