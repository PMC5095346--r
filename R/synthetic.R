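# Synthetic fixtures with known ground truth: analytic fractals,
# multiplicative cascades with closed-form spectra, pseudo-tumor stained
# images with tunable boundary irregularity, and survival cohorts with
# planted effects. Every generator is bit-reproducible under a fixed seed.

#' Filled square mask
#'
#' @param size edge length in px.
#' @return `binary_mask`, all foreground.
#' @export
gen_filled_square <- function(size) {
  stopifnot(size >= 1)
  binary_mask(matrix(TRUE, size, size), case_id = sprintf("square_%d", size),
              provenance = "synthetic")
}

#' Sierpinski carpet mask
#'
#' Level-`level` carpet on a 3^level square: the center ninth is removed
#' recursively. Its box-counting dimension is log(8)/log(3) = 1.8928.
#'
#' @param level recursion depth, 1-7 (higher levels are refused as a memory
#'   guard).
#' @return `binary_mask` with `8^level` foreground pixels.
#' @export
gen_sierpinski_carpet <- function(level) {
  stopifnot(level >= 1)
  if (level > 7) stop("carpet level > 7 refused (3^level square too large)")
  cell <- matrix(TRUE, 3, 3); cell[2, 2] <- FALSE
  m <- cell
  for (i in seq_len(level - 1)) m <- kronecker(m, cell) & TRUE
  binary_mask(m, case_id = sprintf("carpet_L%d", level),
              provenance = "synthetic")
}

#' Theoretical Hoelder exponents of a quadrant multiplicative cascade
#'
#' For quadrant weights `w`, `alpha(q) = -sum(w^q * log2(w)) / sum(w^q)`
#' (base-2 logs because each cascade step halves the linear scale in each
#' axis, and both axes split, contributing two factors of 2 per level --
#' hence the conventional per-axis normalization used here counts dyadic
#' levels, giving alpha in units of dimension).
#'
#' @param weights 4 positive weights summing to 1.
#' @param q moment orders (vectorized).
#' @return numeric alpha(q).
#' @export
cascade_alpha_theory <- function(weights, q) {
  stopifnot(length(weights) == 4L, all(weights > 0),
            abs(sum(weights) - 1) < 1e-9)
  vapply(q, function(qi) {
    lw <- qi * log(weights)
    mx <- max(lw)
    wq <- exp(lw - mx)
    -sum(wq * log2(weights)) / sum(wq)
  }, numeric(1))
}

#' Sample a 2-D multiplicative cascade point set
#'
#' Each point independently descends `depth` levels of quadrant choices
#' drawn with the given weights, yielding dyadic coordinates in the unit
#' square; points are rasterized onto a pixel grid and the mask marks
#' pixels hit by at least one point (binary substrate, matching the
#' contour-image analysis).
#'
#' @param weights 4 positive quadrant weights summing to 1, ordered
#'   (low-x/low-y, high-x/low-y, low-x/high-y, high-x/high-y).
#' @param depth cascade depth (>= 1).
#' @param n_points number of sampled points.
#' @param canvas raster edge length in px. The default `2^(depth - 1)` is
#'   deliberately coarser than the cascade's terminal cells: each pixel
#'   aggregates several cells, so Poisson sampling noise does not leave
#'   isolated single-count atoms in the sparse regions that dominate the
#'   q < 0 moments.
#' @param mode `"binary"` returns the support mask (pixels hit by at least
#'   one point); `"counts"` returns the count-weighted raster, the faithful
#'   discretization of the cascade measure and the substrate used for
#'   spectrum validation.
#' @param seed RNG seed.
#' @return `binary_mask` or `count_raster`; the attribute `"n_points"`
#'   records the sample size used.
#' @export
gen_cascade_points <- function(weights = c(0.4, 0.3, 0.2, 0.1), depth = 8L,
                               n_points = 2e5, canvas = NULL,
                               mode = c("binary", "counts"), seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(length(weights) == 4L, all(weights > 0),
            abs(sum(weights) - 1) < 1e-9, depth >= 1L, n_points >= 1)
  if (is.null(canvas)) canvas <- 2L^(max(1L, depth - 1L))
  xy <- with_seed(seed, {
    ch <- matrix(sample.int(4L, n_points * depth, replace = TRUE,
                            prob = weights), nrow = depth)
    bx <- (ch - 1L) %% 2L          # quadrant bit in x
    by <- (ch - 1L) %/% 2L         # quadrant bit in y
    p2 <- 2^-(seq_len(depth))
    cbind(colSums(bx * p2), colSums(by * p2))
  })
  px <- pmin(canvas, floor(xy[, 1] * canvas) + 1L)
  py <- pmin(canvas, floor(xy[, 2] * canvas) + 1L)
  cid <- sprintf("cascade_d%d", depth)
  out <- if (mode == "binary") {
    m <- matrix(FALSE, canvas, canvas)
    m[cbind(py, px)] <- TRUE
    binary_mask(m, case_id = cid, provenance = "synthetic")
  } else {
    cnt <- matrix(0L, canvas, canvas)
    tb <- table((px - 1L) * canvas + py)
    cnt[as.integer(names(tb))] <- as.integer(tb)
    count_raster(cnt, case_id = cid)
  }
  attr(out, "n_points") <- n_points
  out
}

# band-limited radial roughness profile; kappa scales amplitude and shifts
# power toward high frequencies (rougher boundary)
.radial_profile <- function(theta, kappa, seed) {
  if (kappa <= 0) return(rep(0, length(theta)))
  J <- 7L                      # dyadic harmonics 2^1 .. 2^7
  H <- 1 - 0.6 * kappa         # roughness exponent: lower H = rougher
  with_seed(seed, {
    a <- rnorm(J); b <- rnorm(J)
    w <- 0
    for (j in seq_len(J)) {
      k <- 2^j
      amp <- k^(-H)
      w <- w + amp * (a[j] * cos(k * theta) + b[j] * sin(k * theta))
    }
    0.35 * kappa * w / sqrt(sum((2^(seq_len(J)))^(-2 * H)) / 2)
  })
}

#' Generate a DAB-stained pseudo-tumor section with ground truth
#'
#' Renders one or more lobulated tumor blobs through the Beer-Lambert
#' forward stain model (DAB-positive tumor, hematoxylin-stained stroma
#' collar, white glass elsewhere) with Gaussian intensity noise, and
#' returns the ground-truth tumor mask. The boundary is a radial curve
#' carrying dyadic harmonics whose amplitude (and high-frequency share)
#' grows with the irregularity knob `kappa`; `kappa = 0` gives a
#' near-circular smooth border. Elliptical holes (gland lumina) can be
#' punched into the blob interior.
#'
#' @param canvas image edge length, px.
#' @param n_lobes number of blobs.
#' @param kappa boundary irregularity in `[0, 1]`.
#' @param hole_density expected holes per 10000 tumor px.
#' @param tumor_dab_od,tumor_hem_od,stroma_hem_od,stroma_dab_od stain
#'   optical densities of the rendered classes.
#' @param noise_sd Gaussian noise sd on 0-255 intensities.
#' @param seed RNG seed; matched seeds give matched harmonic draws across
#'   different `kappa`.
#' @param case_id case identifier.
#' @return list with `image` (`section_image`), `truth` (`binary_mask`,
#'   holes excluded) and `kappa`.
#' @export
gen_pseudo_tumor <- function(canvas = 512L, n_lobes = 1L, kappa = 0.3,
                             hole_density = 0, tumor_dab_od = 0.9,
                             tumor_hem_od = 0.3, stroma_hem_od = 0.5,
                             stroma_dab_od = 0.05, noise_sd = 3,
                             seed = 1L, case_id = NULL) {
  stopifnot(kappa >= 0, kappa <= 1, n_lobes >= 1, canvas >= 64)
  if (is.null(case_id))
    case_id <- sprintf("pseudotumor_k%.2f_s%d", kappa, seed)
  cx <- col(matrix(0, canvas, canvas)); cy <- row(matrix(0, canvas, canvas))
  tumor <- matrix(FALSE, canvas, canvas)
  centers <- with_seed(seed * 1000L + 7L, {
    if (n_lobes == 1L) {
      cbind(canvas / 2, canvas / 2)
    } else {
      cbind(runif(n_lobes, 0.3, 0.7) * canvas,
            runif(n_lobes, 0.3, 0.7) * canvas)
    }
  })
  r0 <- canvas * (if (n_lobes == 1L) 0.30 else 0.30 / sqrt(n_lobes))
  for (l in seq_len(n_lobes)) {
    dx <- cx - centers[l, 1]; dy <- cy - centers[l, 2]
    theta <- atan2(dy, dx)
    r <- sqrt(dx^2 + dy^2)
    prof <- .radial_profile(as.vector(theta), kappa,
                            seed = seed * 1000L + l)
    rb <- r0 * pmax(0.25, 1 + prof)
    tumor <- tumor | (r <= matrix(rb, canvas, canvas))
  }
  # punch gland-like elliptical holes into the interior
  if (hole_density > 0) {
    # hole centers stay >= 12 px inside so no hole (semi-axes <= 10) can
    # breach the outer boundary and perturb the outline contour
    interior <- erode4(tumor)
    for (i in 1:11) interior <- erode4(interior)
    cand <- which(interior)
    if (length(cand) > 0) {
      holes <- with_seed(seed * 1000L + 99L, {
        n_h <- rpois(1, hole_density * sum(tumor) / 1e4)
        if (n_h == 0) NULL else {
          ctr <- cand[sample.int(length(cand), min(n_h, length(cand)))]
          list(ctr = ctr,
               ax = runif(length(ctr), 3, 10),
               bx = runif(length(ctr), 3, 10),
               th = runif(length(ctr), 0, pi))
        }
      })
      if (!is.null(holes)) {
        hr <- ((holes$ctr - 1L) %% canvas) + 1L
        hc <- ((holes$ctr - 1L) %/% canvas) + 1L
        for (i in seq_along(hr)) {
          u <- (cx - hc[i]) * cos(holes$th[i]) + (cy - hr[i]) * sin(holes$th[i])
          v <- -(cx - hc[i]) * sin(holes$th[i]) + (cy - hr[i]) * cos(holes$th[i])
          tumor[(u / holes$ax[i])^2 + (v / holes$bx[i])^2 <= 1] <- FALSE
        }
      }
    }
  }
  tissue <- dilate4(tumor, 12L)
  stroma <- tissue & !tumor
  sv <- hdab_stain_vectors()
  od_h <- matrix(0, canvas, canvas); od_d <- matrix(0, canvas, canvas)
  od_h[tumor] <- tumor_hem_od;  od_d[tumor] <- tumor_dab_od
  od_h[stroma] <- stroma_hem_od; od_d[stroma] <- stroma_dab_od
  od_rgb <- outer(as.vector(od_h), sv["hematoxylin", ]) +
            outer(as.vector(od_d), sv["dab", ])
  inten <- 256 * 10^(-od_rgb) - 1
  noise <- with_seed(seed * 1000L + 500L,
                     matrix(rnorm(length(inten), 0, noise_sd), nrow(inten)))
  px <- array(as.integer(pmin(255, pmax(0, round(inten + noise)))),
              c(canvas, canvas, 3L))
  list(image = section_image(px, case_id = case_id),
       truth = binary_mask(tumor, case_id = case_id, provenance = "synthetic"),
       kappa = kappa)
}

#' Generate a synthetic two-arm survival cohort with planted effects
#'
#' Emulates a stage II-III colon-cancer trial table: surgery alone vs
#' adjuvant chemotherapy, a continuous marker dichotomized at the median,
#' and recurrence times drawn from an exponential model whose log-hazard is
#' `marker_loghr * high + treatment_loghr * adjuvant + interaction_loghr *
#' high * adjuvant`. Cancer-specific death follows recurrence after an
#' independent exponential delay; censoring is independent exponential with
#' an administrative cap. Clinico-pathological covariates (age, sex, site,
#' MMR, stage, grade, tumor border configuration, budding) are drawn from
#' fixed realistic marginals and carry no planted effect.
#'
#' @param n cohort size (>= 4).
#' @param baseline_hazard recurrence hazard per month in the reference group.
#' @param marker_loghr,treatment_loghr,interaction_loghr planted log hazard
#'   ratios.
#' @param censor_rate hazard of random censoring per month.
#' @param admin_months administrative follow-up cap.
#' @param marker_mean,marker_sd distribution of the continuous marker.
#' @param seed RNG seed.
#' @return data.frame with PatientRecord columns: `case_id`, `age_years`,
#'   `sex`, `site`, `mmr`, `stage`, `adjuvant`, `grade`, `tbc`,
#'   `budding_count`, `marker_value`, `marker_high`, `ttr_months`,
#'   `ttr_event`, `css_months`, `css_event`.
#' @export
gen_cohort <- function(n = 300L, baseline_hazard = 0.010,
                       marker_loghr = 0, treatment_loghr = 0,
                       interaction_loghr = 0, censor_rate = 0.004,
                       admin_months = 120, marker_mean = 1.8,
                       marker_sd = 0.15, seed = 1L) {
  stopifnot(n >= 4, baseline_hazard > 0, censor_rate >= 0)
  with_seed(seed, {
    marker <- rnorm(n, marker_mean, marker_sd)
    high <- as.integer(marker > median(marker))
    adjuvant <- rbinom(n, 1L, 0.5)
    lp <- marker_loghr * high + treatment_loghr * adjuvant +
      interaction_loghr * high * adjuvant
    t_rec <- rexp(n, baseline_hazard * exp(lp))
    t_cens <- pmin(rexp(n, max(censor_rate, 1e-12)), admin_months)
    t_death <- t_rec + rexp(n, 0.03)
    data.frame(
      case_id = sprintf("case_%04d", seq_len(n)),
      age_years = pmin(90L, pmax(40L, round(rnorm(n, 66, 10)))),
      sex = sample(c("male", "female"), n, replace = TRUE),
      site = sample(c("proximal", "distal"), n, replace = TRUE,
                    prob = c(0.45, 0.55)),
      mmr = sample(c("proficient", "deficient"), n, replace = TRUE,
                   prob = c(0.85, 0.15)),
      stage = sample(c("II", "III"), n, replace = TRUE),
      adjuvant = ifelse(adjuvant == 1L, "yes", "no"),
      grade = sample(c("G1", "G2", "G3"), n, replace = TRUE,
                     prob = c(0.15, 0.65, 0.20)),
      tbc = sample(c("pushing", "intermediate", "infiltrative"), n,
                   replace = TRUE, prob = c(0.30, 0.40, 0.30)),
      budding_count = round(exp(rnorm(n, log(5), 0.6)), 1),
      marker_value = marker,
      marker_high = high,
      ttr_months = pmin(t_rec, t_cens),
      ttr_event = as.integer(t_rec <= t_cens),
      css_months = pmin(t_death, t_cens),
      css_event = as.integer(t_death <= t_cens),
      stringsAsFactors = FALSE
    )
  })
}
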