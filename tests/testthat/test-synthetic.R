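test_that("filled squares and carpets have the exact analytic pixel counts", {
  sq <- gen_filled_square(243)
  expect_identical(sum(as_mask_matrix(sq)), 243L * 243L)
  expect_identical(sum(as_mask_matrix(outline_contour(sq))), 4L * 243L - 4L)

  expect_identical(sum(as_mask_matrix(gen_sierpinski_carpet(3))), 512L)
  expect_identical(sum(as_mask_matrix(gen_sierpinski_carpet(5))), 32768L)
  expect_identical(dim(as_mask_matrix(gen_sierpinski_carpet(4))), c(81L, 81L))
  expect_error(gen_sierpinski_carpet(8), "refused")
})

test_that("cascade theory matches hand-computed Hoelder exponents", {
  w <- c(0.4, 0.3, 0.2, 0.1)
  # q = 0: plain average of -log2 w_i
  expect_equal(cascade_alpha_theory(w, 0), mean(-log2(w)), tolerance = 1e-12)
  # q -> large negative: dominated by the smallest weight
  expect_equal(cascade_alpha_theory(w, -50), -log2(0.1), tolerance = 1e-6)
  expect_equal(cascade_alpha_theory(w, -10), 3.320924, tolerance = 1e-5)
  # degenerate uniform cascade: alpha = 2 for every q
  expect_true(all(abs(cascade_alpha_theory(rep(0.25, 4), c(-5, 0, 5)) - 2) < 1e-12))
})

test_that("cascade sampling is reproducible and respects the weights", {
  a <- gen_cascade_points(seed = 12)
  b <- gen_cascade_points(seed = 12)
  expect_identical(as_mask_matrix(a), as_mask_matrix(b))
  expect_identical(dim(as_mask_matrix(a)), c(128L, 128L))

  cnt <- gen_cascade_points(mode = "counts", seed = 12)
  expect_s3_class(cnt, "count_raster")
  expect_equal(sum(cnt$counts), 2e5)
  expect_identical(cnt$counts > 0, unname(as_mask_matrix(a)))
  # quadrant mass fractions approach the weights (top split)
  half <- 64
  tot <- sum(cnt$counts)
  q11 <- sum(cnt$counts[1:half, 1:half]) / tot
  expect_equal(q11, 0.4, tolerance = 0.01)
  # uniform weights fill the square densely
  u <- gen_cascade_points(rep(0.25, 4), depth = 8, n_points = 2e5, seed = 1)
  expect_gt(mean(as_mask_matrix(u)), 0.99)
})

test_that("pseudo-tumors are reproducible with interpretable irregularity", {
  a <- gen_pseudo_tumor(kappa = 0.5, seed = 8)
  b <- gen_pseudo_tumor(kappa = 0.5, seed = 8)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(as_mask_matrix(a$truth), as_mask_matrix(b$truth))

  # kappa = 0 gives a near-circular blob: contour length close to 2*pi*r
  smooth <- gen_pseudo_tumor(kappa = 0, seed = 8)
  n_contour <- sum(as_mask_matrix(outline_contour(smooth$truth)))
  r0 <- 0.30 * 512
  expect_lt(abs(n_contour - 2 * pi * r0) / (2 * pi * r0), 0.35)

  # rougher boundaries are longer for matched seeds
  rough <- gen_pseudo_tumor(kappa = 0.9, seed = 8)
  expect_gt(sum(as_mask_matrix(outline_contour(rough$truth))), 1.5 * n_contour)

  # holes are punched only in the interior and excluded from the truth
  holed <- gen_pseudo_tumor(kappa = 0.2, hole_density = 3, seed = 8)
  expect_lt(sum(as_mask_matrix(holed$truth)),
            sum(as_mask_matrix(gen_pseudo_tumor(kappa = 0.2, seed = 8)$truth)))
  expect_identical(as_mask_matrix(outline_contour(holed$truth)),
                   as_mask_matrix(outline_contour(
                     gen_pseudo_tumor(kappa = 0.2, seed = 8)$truth)))
})

test_that("synthetic cohorts have the promised structure and reproducibility", {
  d <- gen_cohort(n = 400, seed = 5)
  expect_identical(nrow(d), 400L)
  expect_true(all(c("case_id", "age_years", "sex", "site", "mmr", "stage",
                    "adjuvant", "grade", "tbc", "budding_count",
                    "marker_value", "marker_high", "ttr_months", "ttr_event",
                    "css_months", "css_event") %in% names(d)))
  expect_identical(d, gen_cohort(n = 400, seed = 5))
  expect_true(all(d$ttr_months >= 0) && all(d$css_months >= 0))
  expect_true(all(d$ttr_event %in% 0:1) && all(d$css_event %in% 0:1))
  # death from disease cannot precede recurrence-time censoring structure
  expect_true(all(d$css_months >= d$ttr_months - 1e-9))
  # arms are about half/half (binomial noise)
  expect_lt(abs(mean(d$adjuvant == "yes") - 0.5), 0.1)
  # marker dichotomization is balanced by construction
  expect_equal(sum(d$marker_high), 200L)
})
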