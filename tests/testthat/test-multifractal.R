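test_that("q grids contain the anchor points and reject bad bounds", {
  q <- q_grid()
  expect_true(any(abs(q) < 1e-9))
  expect_true(any(abs(q - 1) < 1e-9))
  expect_identical(length(q), 41L)
  expect_error(q_grid(5, -5), "q_min < q_max")
  expect_error(q_grid(-10, 10, 3), "q = 0|near q = 1")
})

test_that("scale windows respect the bounds and refuse too-small images", {
  w <- build_scale_window(c(1000, 1000))
  expect_true(all(w$sizes >= 10 & w$sizes <= 600))
  expect_gte(length(w$sizes), 3L)
  expect_true(all(diff(w$sizes) > 0))

  w2 <- build_scale_window(c(100, 100))
  expect_true(all(w2$sizes >= 10 & w2$sizes <= 60))

  expect_error(build_scale_window(c(20, 20)), "too small")
})

test_that("mass partitions match exhaustive enumeration on small fixtures", {
  m <- quadrant_fixture()
  p <- partition_masses(m, 4L)
  expect_setequal(p$masses, c(16, 4, 8))
  expect_identical(p$total_mass, 28L)
  expect_equal(p$coverage_fraction, 3 / 4)

  # all-foreground 8x8 at box 4: four boxes of 16
  pf <- partition_masses(matrix(TRUE, 8, 8), 4L)
  expect_identical(sort(pf$masses), c(16, 16, 16, 16))

  # box size 1: multiset of ones, one per foreground pixel
  p1 <- partition_masses(m, 1L)
  expect_true(all(p1$masses == 1))
  expect_identical(length(p1$masses), 28L)

  # random 8x8 and 16x16 fixtures, several box sizes and offsets
  set.seed(41)
  for (n in c(8L, 16L)) for (rep in 1:5) {
    mm <- matrix(runif(n * n) < 0.5, n, n)
    for (s in c(2L, 3L, 5L)) for (off in list(c(0L, 0L), c(1L, 2L))) {
      p <- partition_masses(mm, s, off)
      expect_identical(sort(p$masses), sort(oracle_masses(mm, s, off)))
      expect_identical(sum(p$masses), as.numeric(sum(mm)))
      expect_identical(sum(p$masses * 0 + p$areas > 0), length(p$masses))
    }
  }
})

test_that("the partition function matches hand computation and its identities", {
  masses <- c(16, 4, 8)
  expect_equal(partition_function(masses, 2), (256 + 16 + 64) / 784)
  expect_equal(partition_function(masses, 2), 3 / 7)
  expect_identical(partition_function(masses, 1), 1)
  expect_identical(partition_function(masses, 0), 3)
  # extreme q computed in log space without overflow
  expect_true(is.finite(partition_function(c(1, 1e6), -10)))
  expect_error(partition_function(numeric(0), 2), "empty")
  expect_error(partition_function(c(2, 0), 2), "positive")
  # exhaustive cross-check on the quadrant fixture across q
  p <- partition_masses(quadrant_fixture(), 4L)
  for (q in c(-10, -3, 0.5, 2, 7)) {
    ref <- sum((sort(p$masses) / 28)^q)
    expect_equal(partition_function(p$masses, q), ref, tolerance = 1e-12)
  }
})

test_that("density filter applies the coverage bounds", {
  mk <- function(cov) structure(list(masses = 1, areas = 1, total_mass = 1,
                                     coverage_fraction = cov, box_size_px = 4L,
                                     grid_offset = c(0L, 0L), n_boxes_total = 10),
                                class = "mass_partition")
  expect_false(density_filter(mk(0.05)))
  expect_false(density_filter(mk(0.99)))
  expect_true(density_filter(mk(0.5)))
  expect_true(density_filter(mk(0.10)))
  expect_true(density_filter(mk(0.98)))
})

test_that("spectrum estimation is exact on the uniform square", {
  sp <- mf_spectrum(gen_filled_square(243))
  expect_true(all(abs(sp$D - 2) < 0.1))
  expect_lt(sp$alpha_max - min(sp$alpha), 0.2)
  expect_false(multifractality_check(sp)$is_multifractal)
  expect_equal(sp$f_alpha_max, 2, tolerance = 0.05)
})

test_that("spectrum identities hold on heterogeneous fixtures", {
  cfg <- mf_config(min_density = 0, max_density = 1)
  cs <- gen_cascade_points(mode = "counts", seed = 3)
  sp <- mf_spectrum(cs, cfg)
  i0 <- which.min(abs(sp$q)); i1 <- which.min(abs(sp$q - 1))
  expect_lt(sp$mu_sum_max_dev, 1e-12)
  expect_lte(abs(sp$alpha[i1] - sp$f[i1]), 0.05)
  expect_lte(abs(sp$f[i0] - sp$D[i0]), 0.05)
  expect_equal(sp$alpha_max, max(sp$alpha))
  expect_equal(sp$f_alpha_max, max(sp$f))
  # tau(1) = 0 and D, alpha non-increasing within tolerance
  expect_lt(abs(sp$tau[i1]), 1e-6)
  expect_true(all(diff(sp$D) <= 0.05))
  expect_true(all(diff(sp$alpha) <= 0.05))
})

test_that("fewer than 3 distinct scales is an error", {
  m <- quadrant_fixture()
  parts <- list(partition_masses(m, 2L), partition_masses(m, 4L))
  expect_error(chhabra_jensen_spectrum(parts), ">= 3 distinct box sizes")
  expect_error(mf_spectrum(matrix(FALSE, 64, 64)), "empty image")
})

test_that("D(q)-vs-q linearity handles affine, constant and noisy spectra", {
  mk_spec <- function(D) structure(
    list(q = seq(-5, 5, 0.5), D = D, tau = D, alpha = D, f = D,
         per_q_fit_r2 = rep(1, 21)), class = "mf_spectrum")
  q <- seq(-5, 5, 0.5)
  lin <- dq_vs_q_linearity(mk_spec(1.5 - 0.03 * q))
  expect_equal(lin$r2, 1, tolerance = 1e-12)
  expect_false(lin$monofractal)

  flat <- dq_vs_q_linearity(mk_spec(rep(1.8, 21)))
  expect_identical(flat$r2, 1.0)
  expect_true(flat$monofractal)

  # independent regression oracle on a curved spectrum
  D <- 2 - 0.05 * q - 0.01 * q^2
  got <- dq_vs_q_linearity(mk_spec(D))
  ref <- summary(lm(D ~ q))$r.squared
  expect_equal(got$r2, ref, tolerance = 1e-10)
})

test_that("multifractality check distinguishes flat, descending and rising spectra", {
  mk_spec <- function(D, q = seq(-10, 10, 0.5)) structure(
    list(q = q, D = D, tau = D, alpha = D, f = D,
         per_q_fit_r2 = rep(1, length(q))), class = "mf_spectrum")
  q <- seq(-10, 10, 0.5)
  flat <- multifractality_check(mk_spec(rep(2, length(q))))
  expect_false(flat$is_multifractal)

  desc <- multifractality_check(mk_spec(2 - 0.02 * (q + 10)))
  expect_true(desc$is_descending)
  expect_true(desc$is_multifractal)
  expect_equal(desc$spectrum_drop, 0.4, tolerance = 1e-9)

  bump <- rep(2, length(q)); bump[30] <- 2.2
  expect_false(multifractality_check(mk_spec(bump))$is_descending)
})

test_that("the Legendre cross-check agrees with the direct estimates away from the ends", {
  cfg <- mf_config(min_density = 0, max_density = 1)
  sp <- mf_spectrum(gen_cascade_points(mode = "counts", seed = 5), cfg)
  lg <- legendre_check(sp)
  mid <- abs(sp$q) <= 3
  expect_lt(max(abs(lg$alpha_legendre[mid] - sp$alpha[mid])), 0.15)
  expect_lt(max(abs(lg$f_legendre[mid] - sp$f[mid])), 0.25)
})

test_that("alpha_max is stable under 2x upscaling at matched physical scales", {
  oc <- outline_contour(gen_pseudo_tumor(kappa = 0.5, seed = 1)$truth)
  a1 <- mf_spectrum(oc)$alpha_max
  up <- contour_image(kronecker(as_mask_matrix(oc), matrix(1, 2, 2)) > 0)
  a2 <- mf_spectrum(up, mf_config(min_box_px = 20L))$alpha_max
  expect_lt(abs(a2 - a1), 0.15)
})

test_that("case metrics are deterministic and flag empty contours as missing", {
  pt <- gen_pseudo_tumor(kappa = 0.4, hole_density = 2, seed = 6)
  cs <- extract_contours(pt$truth)
  m1 <- compute_case_metrics(cs$outline, cs$internal)
  m2 <- compute_case_metrics(cs$outline, cs$internal)
  expect_identical(m1, m2)
  expect_true(all(is.finite(unlist(m1[, 2:7]))))

  # solid square: no internal structure, so both variants agree
  sq <- square_in_canvas(canvas = 200, size = 120, at = 40)
  css <- extract_contours(sq)
  ms <- compute_case_metrics(css$outline, css$internal)
  expect_equal(ms$alpha_max, ms$alpha_max_internal)
  expect_equal(ms$f_alpha_max, ms$f_alpha_max_internal)

  # empty contour: metrics NA with a flag, not zero
  e <- contour_image(matrix(FALSE, 64, 64), "outline", case_id = "x")
  ei <- contour_image(matrix(FALSE, 64, 64), "internal_structure", case_id = "x")
  me <- compute_case_metrics(e, ei)
  expect_true(is.na(me$alpha_max) && is.na(me$f_alpha_max_internal))
  expect_match(me$qc_flags, "empty")
  # mismatched cases are rejected
  e2 <- contour_image(matrix(FALSE, 64, 64), "internal_structure", case_id = "y")
  expect_error(compute_case_metrics(e, e2), "different cases")
})
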