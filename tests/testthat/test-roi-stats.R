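make_asym <- function(values, offsets = c(2, 3.5)) {
  structure(list(offsets = offsets, values = values, source = "roi",
                 state = "b0-corrected"), class = "asym_spectrum")
}

test_that("animal summary averages tumors and subtracts the cord reference", {
  # zero reference: corrected equals raw
  a <- animal_summary(make_asym(c(0.02, 0.032)), make_asym(c(0, 0)))
  expect_equal(a$table$corrected, a$table$tumor)
  # magnitudes mirroring a tumor at 3.2% over a -4.6% reference
  a2 <- animal_summary(make_asym(c(0.02, 0.032)),
                       make_asym(c(-0.03, -0.046)))
  expect_equal(a2$table$corrected[2], 0.078)
  # multiple tumors enter as an unweighted mean
  a3 <- animal_summary(list(make_asym(c(0.01, 0.02)),
                            make_asym(c(0.03, 0.04))),
                       make_asym(c(0, 0)))
  expect_equal(a3$table$tumor, c(0.02, 0.03))
  expect_identical(a3$n_tumors, 2L)
})

test_that("corrected + cord equals tumor to machine precision", {
  set.seed(4)
  a <- animal_summary(make_asym(rnorm(2, 0.03, 0.01)),
                      make_asym(rnorm(2, -0.02, 0.01)))
  expect_identical(a$table$corrected + a$table$cord, a$table$tumor)
})

test_that("a missing cord reference is an error", {
  expect_error(animal_summary(make_asym(c(0.02, 0.03)), NULL), "cord")
  expect_error(animal_summary(list(), make_asym(c(0, 0))), "tumor")
  expect_error(animal_summary(make_asym(c(0.02, 0.03)),
                              make_asym(0.01, offsets = 3.5)),
               "offsets")
})

test_that("pooled t from summary statistics matches the closed form", {
  r <- summary_from_stats(7.8, 3.9, 6, 2.7, 1.9, 6)
  expect_equal(r$t, 2.879, tolerance = 1e-3)
  expect_equal(r$df, 10)
  expect_lt(r$p, 0.05)
  r0 <- summary_from_stats(5, 2, 8, 5, 2, 8)
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)
})

test_that("printed group summaries reproduce the expected p-values", {
  p2 <- summary_from_stats(6.0, 1.8, 6, 2.9, 1.5, 6)$p
  expect_gte(p2, 0.005)
  expect_lte(p2, 0.015)
  expect_equal(round(p2, 2), 0.01)
})

test_that("degenerate zero-variance comparisons are flagged", {
  r <- summary_from_stats(3, 0, 6, 1, 0, 6)
  expect_true(r$degenerate)
  expect_equal(r$p, 0)
  expect_true(is.infinite(r$t))
})

test_that("group_compare equals summary_from_stats on the same data", {
  set.seed(7)
  for (rep in 1:5) {
    x1 <- rnorm(6, 0.06, 0.02)
    x2 <- rnorm(6, 0.03, 0.015)
    animals <- c(fx_animal(x1, group = "g1"), fx_animal(x2, group = "g2"))
    gc <- group_compare(animals, 3.5)
    ss <- summary_from_stats(mean(x1), sd(x1), 6, mean(x2), sd(x2), 6)
    expect_equal(gc$t, ss$t, tolerance = 1e-12)
    expect_equal(gc$p, ss$p, tolerance = 1e-12)
  }
})

test_that("identical groups give t = 0, p = 1", {
  animals <- c(fx_animal(rep(0.05, 3), group = "g1"),
               fx_animal(rep(0.05, 3), group = "g2"))
  gc <- group_compare(animals, 3.5)
  expect_equal(gc$t, 0)
  expect_equal(gc$p, 1)
})

test_that("group_compare validates group structure", {
  expect_error(group_compare(fx_animal(c(1, 2), group = "only"), 3.5),
               "two groups")
  animals <- c(fx_animal(0.05, group = "g1"), fx_animal(c(0.04, 0.05),
                                                        group = "g2"))
  expect_error(group_compare(animals, 3.5), "two animals")
})

test_that("null-permutation rejection rate is near the nominal level", {
  set.seed(123)
  reps <- 500
  rej <- 0L
  for (i in seq_len(reps)) {
    x <- rnorm(12, 0.03, 0.015)
    g <- sample(rep(c("a", "b"), each = 6))
    animals <- c(fx_animal(x[g == "a"], group = "a"),
                 fx_animal(x[g == "b"], group = "b"))
    if (group_compare(animals, 3.5)$p < 0.05) rej <- rej + 1L
  }
  expect_gt(rej / reps, 0.02)
  expect_lt(rej / reps, 0.08)
})

test_that("group table covers quantities, groups and offsets deterministically", {
  set.seed(9)
  offs <- c(2, 3.5)
  mk <- function(v, g, i) {
    structure(list(table = data.frame(offset_ppm = offs, tumor = v,
                                      cord = -0.01,
                                      corrected = v + 0.01),
                   animal = paste0(g, i), group = g, n_tumors = 1L),
              class = "animal_result")
  }
  animals <- c(lapply(1:3, function(i) mk(rnorm(2, 0.05, 0.01), "g1", i)),
               lapply(1:3, function(i) mk(rnorm(2, 0.02, 0.01), "g2", i)))
  tab <- build_group_table(animals)
  slice <- tab[tab$quantity == "corrected", ]
  expect_equal(nrow(slice), 2L * length(offs))
  expect_equal(unique(tab$quantity), c("corrected", "tumor"))
  expect_true(all(tab$n == 3))
  # Holm adjustment never lowers a p-value
  tab_h <- build_group_table(animals, holm = TRUE)
  expect_true(all(tab_h$p >= tab$p - 1e-15))
  # zero-variability cohorts have zero SD columns
  animals0 <- c(lapply(1:3, function(i) mk(c(0.05, 0.06), "g1", i)),
                lapply(1:3, function(i) mk(c(0.02, 0.03), "g2", i)))
  tab0 <- build_group_table(animals0)
  expect_true(all(tab0$sd_pct == 0))
  expect_true(all(tab0$degenerate))
})
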