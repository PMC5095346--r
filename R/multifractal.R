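# Multifractal box-counting analysis of binary contour images.
#
# The measure is the normalized foreground pixel count per box. alpha(q) and
# f(q) are estimated with the direct (Chhabra-Jensen) method, which is stable
# at strongly negative q; tau(q)/D(q) come from log-partition-function
# regressions over the scale window. All per-q quantities are computed in
# log space so that q = +/-10 cannot overflow.

#' Evaluation grid of moment orders q
#'
#' @param q_min,q_max grid bounds (defaults -10, +10).
#' @param q_step grid spacing.
#' @return numeric vector of q values; the grid must contain q = 0 and a
#'   point within `q_step` of q = 1.
#' @export
q_grid <- function(q_min = -10, q_max = 10, q_step = 0.5) {
  stopifnot(q_min < q_max, q_step > 0)
  q <- seq(q_min, q_max, by = q_step)
  if (!any(abs(q) < 1e-9))
    stop("q grid must contain q = 0; adjust q_min/q_step")
  if (!any(abs(q - 1) < q_step + 1e-9))
    stop("q grid must contain a point near q = 1")
  q
}

#' Build the box-size scale window for an image
#'
#' Box edge lengths are approximately geometrically spaced from `min_box_px`
#' up to `max_box_fraction` of the smaller image dimension, deduplicated
#' after integer rounding.
#'
#' @param image_dims integer c(H, W) (or a mask-like object).
#' @param min_box_px smallest box edge, px (default 10).
#' @param max_box_fraction largest box edge as a fraction of min(H, W)
#'   (default 0.6).
#' @param n_scales number of sizes requested before deduplication.
#' @return object of class `scale_window`: list with `sizes` (strictly
#'   increasing integer vector) and the generating parameters.
#' @export
build_scale_window <- function(image_dims, min_box_px = 10L,
                               max_box_fraction = 0.6, n_scales = 12L) {
  if (!is.numeric(image_dims))
    image_dims <- dim(as_mask_matrix(image_dims))
  stopifnot(length(image_dims) >= 2L, min_box_px >= 1L,
            max_box_fraction > 0, max_box_fraction <= 1, n_scales >= 3L)
  max_box <- floor(min(image_dims[1:2]) * max_box_fraction)
  if (max_box < 2L * min_box_px)
    stop(sprintf(
      paste0("image too small for multifractal analysis: largest box %d px ",
             "< 2 x min_box_px (%d); smallest usable dimension is %d px"),
      max_box, min_box_px, ceiling(2 * min_box_px / max_box_fraction)))
  # Box sizes are nudged within +/-3 px toward sizes whose clipped edge
  # boxes are either absent or at least a third of the box wide: a 1-2 px
  # sliver box carries an artificially tiny mass and corrupts the q < 0
  # moments of the partition function.
  L <- min(image_dims[1:2])
  good <- function(s) {
    r <- L %% s
    r == 0L | r >= s / 3
  }
  raw <- exp(seq(log(min_box_px), log(max_box), length.out = n_scales))
  sizes <- vapply(raw, function(s0) {
    cand <- unique(as.integer(
      pmin(max_box, pmax(min_box_px, as.integer(round(s0)) + (-3:3)))))
    ok <- cand[good(cand)]
    if (length(ok)) ok[which.min(abs(ok - s0))]
    else as.integer(round(s0))
  }, integer(1))
  sizes <- sort(unique(sizes[sizes >= min_box_px & sizes <= max_box]))
  if (length(sizes) < 3L)
    stop("fewer than 3 distinct box sizes in the scale window")
  structure(list(sizes = sizes, min_box_px = as.integer(min_box_px),
                 max_box_fraction = max_box_fraction,
                 n_scales = as.integer(n_scales)),
            class = "scale_window")
}

#' Box-counting mass partition at one scale and grid offset
#'
#' The image is tiled by boxes of the given edge length, the grid anchored
#' at `grid_offset` (0-based; boxes clipped at the image edges are
#' included). Foreground pixel counts are recorded per box; empty boxes are
#' excluded.
#'
#' @param contour mask-like object (contour image or binary mask).
#' @param box_size box edge length in px (>= 1).
#' @param grid_offset integer c(row, col), each in `[0, box_size)`.
#' @return object of class `mass_partition`: `masses` (positive counts),
#'   `total_mass`, `coverage_fraction` (non-empty boxes / boxes intersecting
#'   the image), `box_size_px`, `grid_offset`, `n_boxes_total`.
#' @export
partition_masses <- function(contour, box_size, grid_offset = c(0L, 0L)) {
  wts <- NULL
  if (inherits(contour, "count_raster")) {
    wts <- contour$counts
    m <- wts > 0
  } else {
    m <- as_mask_matrix(contour)
  }
  stopifnot(box_size >= 1L, length(grid_offset) == 2L)
  box_size <- as.integer(box_size)
  off <- as.integer(grid_offset) %% box_size
  h <- nrow(m); w <- ncol(m)
  idx <- which(m)
  r0 <- ((idx - 1L) %% h)          # 0-based row
  c0 <- ((idx - 1L) %/% h)         # 0-based col
  br <- (r0 - off[1] + box_size) %/% box_size   # shift keeps indices >= 0
  bc <- (c0 - off[2] + box_size) %/% box_size
  nbr <- ((h - 1L - off[1] + box_size) %/% box_size) -
         ((0L - off[1] + box_size) %/% box_size) + 1L
  nbc <- ((w - 1L - off[2] + box_size) %/% box_size) -
         ((0L - off[2] + box_size) %/% box_size) + 1L
  n_boxes_total <- as.numeric(nbr) * as.numeric(nbc)
  masses <- numeric(0); areas <- numeric(0)
  total <- if (is.null(wts)) length(idx) else sum(wts[idx])
  if (length(idx) > 0L) {
    stride <- nbc + 2L
    key <- br * stride + bc          # unique per box, decodable
    vals <- if (is.null(wts)) rep(1, length(idx)) else as.numeric(wts[idx])
    agg <- rowsum(vals, key)         # ordered by sorted numeric key
    masses <- as.numeric(agg)
    k <- as.numeric(rownames(agg))
    kb <- k %/% stride; kc <- k %% stride
    # intersection of each box with the image (clipped boxes are narrower);
    # box index b spans pixel rows/cols [off + (b-1)*s, off + b*s)
    s <- box_size
    start_r <- off[1] + (kb - 1) * s
    start_c <- off[2] + (kc - 1) * s
    areas <- (pmin(h, start_r + s) - pmax(0, start_r)) *
             (pmin(w, start_c + s) - pmax(0, start_c))
  }
  structure(list(masses = masses,
                 areas = areas,
                 total_mass = total,
                 coverage_fraction = length(masses) / n_boxes_total,
                 box_size_px = box_size,
                 grid_offset = off,
                 n_boxes_total = n_boxes_total),
            class = "mass_partition")
}

#' Count-weighted raster (per-pixel event counts)
#'
#' A non-negative integer matrix treated as a measure rather than a binary
#' support: box masses are per-box count sums. Used for validation
#' substrates where multiplicity matters (sampled multiplicative
#' cascades); contour-image analysis always uses the binary route.
#'
#' @param counts non-negative numeric matrix.
#' @param case_id case identifier.
#' @return object of class `count_raster`.
#' @export
count_raster <- function(counts, case_id = "case") {
  stopifnot(is.matrix(counts), all(counts >= 0), !anyNA(counts))
  structure(list(counts = counts, case_id = case_id),
            class = "count_raster")
}

#' @export
print.count_raster <- function(x, ...) {
  cat(sprintf("<count_raster> case '%s': %d x %d, %d occupied px, total %g\n",
              x$case_id, nrow(x$counts), ncol(x$counts),
              sum(x$counts > 0), sum(x$counts)))
  invisible(x)
}

#' Density filter for a grid placement
#'
#' A placement is accepted when its coverage fraction (non-empty boxes over
#' boxes intersecting the image) lies within `[min_density, max_density]`;
#' rejected placements are excluded from the scaling regressions.
#'
#' @param partition `mass_partition`.
#' @param min_density,max_density acceptance bounds (defaults 0.1 and 0.98).
#' @return logical.
#' @export
density_filter <- function(partition, min_density = 0.1, max_density = 0.98) {
  stopifnot(inherits(partition, "mass_partition"))
  partition$coverage_fraction >= min_density &&
    partition$coverage_fraction <= max_density
}

#' Partition function Z(q) of a mass partition
#'
#' `Z(q) = sum_i P_i^q` with `P_i = m_i / sum_j m_j`; computed through
#' log-sum-exp so extreme q do not overflow. `Z(1) = 1` exactly and `Z(0)`
#' equals the number of non-empty boxes.
#'
#' @param masses positive per-box masses (or a `mass_partition`).
#' @param q moment order (vectorized).
#' @return numeric vector `Z(q)`.
#' @export
partition_function <- function(masses, q) {
  if (inherits(masses, "mass_partition")) masses <- masses$masses
  if (length(masses) == 0L) stop("empty mass partition")
  if (any(masses <= 0)) stop("masses must be strictly positive")
  lp <- log(masses) - log(sum(masses))
  vapply(q, function(qi) {
    if (abs(qi - 1) < 1e-12) return(1)
    if (abs(qi) < 1e-12) return(length(lp))
    x <- qi * lp
    mx <- max(x)
    exp(mx) * sum(exp(x - mx))
  }, numeric(1))
}

# Per-partition Chhabra-Jensen sufficient statistics at all q, in the
# area-referenced (edge-corrected) formulation: each box enters with weight
# w_i = a_i / s^2 (its intersection area with the image over the full box
# area) and the density-equivalent mass P~_i = (m_i / a_i) * s^2 / M, so a
# clipped edge box is not mistaken for a genuinely sparse one. For boxes
# fully inside the image w_i = 1 and the sums reduce to the standard
# Chhabra-Jensen sums; Z(1) = sum(m_i)/M = 1 survives exactly.
.cj_stats <- function(masses, q, areas = NULL, box_size = NULL) {
  M <- sum(masses)
  if (is.null(areas) || is.null(box_size)) {
    lw <- rep(0, length(masses))
    lp <- log(masses) - log(M)
  } else {
    lw <- log(areas) - 2 * log(box_size)          # log w_i <= 0
    lp <- log(masses) - log(areas) + 2 * log(box_size) - log(M)
  }
  X <- sweep(outer(lp, q), 1L, lw, `+`)   # B x nq: log w_i + q * log P~_i
  mx <- apply(X, 2L, max)
  logZ <- mx + log(colSums(exp(sweep(X, 2L, mx))))
  W <- exp(sweep(X, 2L, logZ))            # mu_i(q), columns sum to 1
  list(logZ = logZ,
       A = colSums(W * lp),               # sum mu log P~     -> alpha slope
       F = colSums(sweep(outer(lp, q), 2L, logZ) * W),
                                          # sum mu log(mu/w)  -> f slope
       S1 = sum(exp(lp + lw) * lp),       # sum (m/M) log P~  -> D(1) slope
       mu_dev = max(abs(colSums(W) - 1)))
}

.slope_r2 <- function(x, Y) {
  # OLS slope and r^2 of each column of Y against x
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  Yc <- sweep(Y, 2L, colMeans(Y))
  slope <- colSums(xc * Yc) / sxx
  ss_tot <- colSums(Yc^2)
  ss_reg <- slope^2 * sxx
  r2 <- ifelse(ss_tot < 1e-20, 1, pmin(1, ss_reg / ss_tot))
  list(slope = slope, r2 = r2)
}

#' Chhabra-Jensen multifractal spectrum from mass partitions
#'
#' For each q, the normalized measures `mu_i(q) = P_i^q / Z(q)` define
#' `alpha(q)` as the slope of `sum_i mu_i log P_i` against `log(box size)`
#' and `f(q)` as the slope of `sum_i mu_i log mu_i`; `tau(q)` is the slope
#' of `log Z(q)` and `D(q) = tau(q)/(q - 1)` (`D(1)` from the information
#' sum). Partitions sharing a box size (different grid offsets) are averaged
#' before the regression.
#'
#' @param partitions list of `mass_partition` objects spanning at least 3
#'   distinct box sizes.
#' @param q q grid (see [q_grid()]).
#' @param variant contour variant carried through to the result.
#' @param tol_mono tolerance for monotonicity QC flags.
#' @return object of class `mf_spectrum`: data columns `q`, `tau`, `D`,
#'   `alpha`, `f`, `per_q_fit_r2`, plus `alpha_max`, `f_alpha_max`,
#'   `dq_vs_q_r2`, `scales`, `qc_flags`, `mu_sum_max_dev`.
#' @export
chhabra_jensen_spectrum <- function(partitions, q = q_grid(),
                                    variant = c("outline", "internal_structure"),
                                    tol_mono = 0.05) {
  variant <- match.arg(variant)
  stopifnot(length(partitions) > 0L,
            all(vapply(partitions, inherits, logical(1), "mass_partition")))
  sizes <- vapply(partitions, function(p) p$box_size_px, integer(1))
  usz <- sort(unique(sizes))
  if (length(usz) < 3L)
    stop("need partitions at >= 3 distinct box sizes, got ", length(usz))
  nq <- length(q)
  logZ <- A <- Fm <- matrix(NA_real_, length(usz), nq)
  S1 <- numeric(length(usz))
  mu_dev <- 0
  for (i in seq_along(usz)) {
    ps <- partitions[sizes == usz[i]]
    st <- lapply(ps, function(p)
      .cj_stats(p$masses, q, areas = p$areas, box_size = p$box_size_px))
    logZ[i, ] <- rowMeans(vapply(st, `[[`, numeric(nq), "logZ"))
    A[i, ]    <- rowMeans(vapply(st, `[[`, numeric(nq), "A"))
    Fm[i, ]   <- rowMeans(vapply(st, `[[`, numeric(nq), "F"))
    S1[i]     <- mean(vapply(st, `[[`, numeric(1), "S1"))
    mu_dev    <- max(mu_dev, vapply(st, `[[`, numeric(1), "mu_dev"))
  }
  x <- log(usz)
  ft <- .slope_r2(x, logZ)
  fa <- .slope_r2(x, A)
  ff <- .slope_r2(x, Fm)
  f1 <- .slope_r2(x, matrix(S1, ncol = 1L))
  tau <- ft$slope
  D <- ifelse(abs(q - 1) < 1e-9, f1$slope, tau / (q - 1))
  alpha <- fa$slope
  fq <- ff$slope
  qc <- character(0)
  if (any(diff(alpha) > tol_mono)) qc <- c(qc, "alpha_not_monotone")
  if (any(diff(D) > tol_mono)) qc <- c(qc, "D_not_monotone")
  spec <- structure(list(
    q = q, tau = tau, D = D, alpha = alpha, f = fq,
    per_q_fit_r2 = ft$r2, alpha_fit_r2 = fa$r2,
    scales = usz,
    n_partitions = length(partitions),
    alpha_max = max(alpha), f_alpha_max = max(fq),
    mu_sum_max_dev = mu_dev,
    variant = variant, qc_flags = qc,
    dq_vs_q_r2 = NA_real_), class = "mf_spectrum")
  lin <- dq_vs_q_linearity(spec)
  spec$dq_vs_q_r2 <- lin$r2
  if (lin$monofractal) spec$qc_flags <- c(spec$qc_flags, "monofractal_flat_Dq")
  spec
}

#' @export
print.mf_spectrum <- function(x, ...) {
  cat(sprintf(
    paste0("<mf_spectrum> [%s] q in [%g, %g] (%d pts), %d scales %d-%d px\n",
           "  alpha_max = %.4f  f(alpha)_max = %.4f  D(0) = %.4f  ",
           "D(q)~q r2 = %.3f\n"),
    x$variant, min(x$q), max(x$q), length(x$q), length(x$scales),
    min(x$scales), max(x$scales), x$alpha_max, x$f_alpha_max,
    x$D[which.min(abs(x$q))], x$dq_vs_q_r2))
  if (length(x$qc_flags)) cat("  QC:", paste(x$qc_flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.mf_spectrum <- function(x, ...) {
  data.frame(q = x$q, tau = x$tau, D = x$D, alpha = x$alpha, f = x$f,
             fit_r2 = x$per_q_fit_r2)
}

#' Linearity of the D(q)-vs-q relation
#'
#' Ordinary least squares of `D(q)` on `q`. A constant `D(q)` (monofractal)
#' has undefined r-squared; by convention it is reported as 1.0 together
#' with a monofractal flag, since a horizontal line is a perfect fit.
#'
#' @param spectrum `mf_spectrum`.
#' @param tol_const variance of D(q) below which the spectrum counts as
#'   constant.
#' @return list with `r2`, `slope`, `monofractal`.
#' @export
dq_vs_q_linearity <- function(spectrum, tol_const = 1e-8) {
  stopifnot(inherits(spectrum, "mf_spectrum"), length(spectrum$q) >= 3L)
  D <- spectrum$D; q <- spectrum$q
  if (var(D) < tol_const)
    return(list(r2 = 1.0, slope = 0.0, monofractal = TRUE))
  sl <- .slope_r2(q, matrix(D, ncol = 1L))
  list(r2 = sl$r2, slope = sl$slope, monofractal = FALSE)
}

#' Multifractality check on an estimated spectrum
#'
#' The structure counts as multifractal when `D(q)` is non-increasing
#' (within `tol_mono`) and the total drop `D(q_min) - D(q_max)` reaches
#' `min_drop`; a flat spectrum is monofractal.
#'
#' @param spectrum `mf_spectrum`.
#' @param min_drop minimum spectrum drop (default 0.05).
#' @param tol_mono tolerated local increase of D(q).
#' @return list with `is_descending`, `spectrum_drop`, `is_multifractal`.
#' @export
multifractality_check <- function(spectrum, min_drop = 0.05, tol_mono = 0.05) {
  stopifnot(inherits(spectrum, "mf_spectrum"))
  desc <- all(diff(spectrum$D) <= tol_mono)
  drop <- spectrum$D[which.min(spectrum$q)] - spectrum$D[which.max(spectrum$q)]
  list(is_descending = desc, spectrum_drop = drop,
       is_multifractal = desc && drop >= min_drop)
}

# deterministic RNG scope that restores the caller's random state;
# the seed is forced first so a caller-supplied random seed expression is
# drawn from the caller's stream before the state is captured
with_seed <- function(seed, expr) {
  force(seed)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Multifractal analysis configuration
#'
#' Bundles every tunable of the box-counting chain. Defaults mirror the
#' conventional FracLac-style setup: scale window from 10 px to 60 percent
#' of the image, q from -10 to +10 in steps of 0.5, grid-placement density
#' bounds 0.1 and 0.98, and 4 grid offsets per scale (the origin plus 3
#' seeded pseudo-random offsets).
#'
#' @param min_box_px,max_box_fraction,n_scales see [build_scale_window()].
#' @param q_min,q_max,q_step see [q_grid()].
#' @param n_offsets grid placements per scale.
#' @param min_density,max_density see [density_filter()].
#' @param tol_mono monotonicity QC tolerance.
#' @param min_drop multifractality drop threshold.
#' @param seed seed for the pseudo-random grid offsets.
#' @return list of class `mf_config`.
#' @export
mf_config <- function(min_box_px = 10L, max_box_fraction = 0.6,
                      n_scales = 12L, q_min = -10, q_max = 10, q_step = 0.5,
                      n_offsets = 4L, min_density = 0.1, max_density = 0.98,
                      tol_mono = 0.05, min_drop = 0.05, seed = 1L) {
  structure(list(min_box_px = as.integer(min_box_px),
                 max_box_fraction = max_box_fraction,
                 n_scales = as.integer(n_scales),
                 q_min = q_min, q_max = q_max, q_step = q_step,
                 n_offsets = as.integer(n_offsets),
                 min_density = min_density, max_density = max_density,
                 tol_mono = tol_mono, min_drop = min_drop,
                 seed = as.integer(seed)),
            class = "mf_config")
}

#' Full multifractal spectrum of a binary image
#'
#' Runs the complete chain: scale window, per-scale mass partitions at
#' several grid offsets, density filtering of placements, and the
#' Chhabra-Jensen spectrum on the surviving partitions.
#'
#' Density-filter semantics: placements outside the coverage bounds are
#' excluded; a scale whose placements are all rejected is dropped with a
#' warning, and fewer than 3 surviving scales is an error. The one
#' exception is a homogeneous image on which *every* placement at *every*
#' scale is rejected (coverage ~1 everywhere): there is then no
#' unrepresentative placement to discard, so the filter is bypassed and the
#' spectrum carries the QC flag `density_filter_bypassed`.
#'
#' @param contour `contour_image`, `binary_mask` or logical matrix.
#' @param config `mf_config`.
#' @return `mf_spectrum`.
#' @export
mf_spectrum <- function(contour, config = mf_config()) {
  src <- contour
  m <- if (inherits(contour, "count_raster")) contour$counts > 0
       else as_mask_matrix(contour)
  variant <- if (inherits(contour, "contour_image")) contour$variant
             else "outline"
  if (!any(m)) stop("empty image: no foreground pixels to analyze")
  win <- build_scale_window(dim(m), config$min_box_px,
                            config$max_box_fraction, config$n_scales)
  q <- q_grid(config$q_min, config$q_max, config$q_step)
  # grid offsets are restricted so that every clipped edge box is either
  # absent or at least a third of the box wide (thin slivers corrupt q < 0)
  offsets_for <- function(s) {
    k <- max(0L, config$n_offsets - 1L)
    ok_dim <- function(L) {
      o <- 0:(s - 1L)
      last <- (L - o) %% s
      o[(o == 0L | o >= s / 3) & (last == 0L | last >= s / 3)]
    }
    vr <- ok_dim(nrow(m)); vc <- ok_dim(ncol(m))
    if (length(vr) == 0L) vr <- 0L
    if (length(vc) == 0L) vc <- 0L
    ro <- with_seed(config$seed + s,
                    cbind(vr[sample.int(length(vr), k, replace = TRUE)],
                          vc[sample.int(length(vc), k, replace = TRUE)]))
    unique(rbind(c(0L, 0L), ro))
  }
  all_parts <- list(); acc_parts <- list()
  dropped <- integer(0); relaxed <- integer(0)
  for (s in win$sizes) {
    offs <- if (s == 1L) matrix(0L, 1L, 2L) else offsets_for(s)
    ps <- lapply(seq_len(nrow(offs)), function(i)
      partition_masses(src, s, offs[i, ]))
    ps <- ps[vapply(ps, function(p) length(p$masses) > 0L, logical(1))]
    # Density guards in the estimation chain: placements whose coverage
    # exceeds max_density are structure-blind (nearly every box non-empty)
    # and are set aside in favour of lower-coverage placements at the same
    # scale; if every placement at a scale exceeds the bound the least-
    # covered ones are kept with a QC flag, so a scale is never dropped
    # and matched cases keep identical scale windows. Within an accepted
    # placement, boxes with mass below min_density x the placement's
    # median box mass are excluded from the moment sums as under-sampled
    # (grid boxes grazing a contour tangentially carry 1-2 px regardless
    # of scale and would dominate every q < 0 moment). Bounds (0, 1)
    # disable both guards.
    cov <- vapply(ps, `[[`, numeric(1), "coverage_fraction")
    ok <- cov <= config$max_density
    if (!any(ok)) {
      ok <- cov <= min(cov) + 1e-12
      relaxed <- c(relaxed, s)
    }
    ps_ok <- lapply(ps[ok], function(p) {
      keep <- p$masses >= config$min_density * median(p$masses)
      p$masses <- p$masses[keep]
      p$areas <- p$areas[keep]
      p
    })
    ps_ok <- ps_ok[vapply(ps_ok, function(p) length(p$masses) > 0L, logical(1))]
    all_parts <- c(all_parts, ps)
    if (length(ps_ok)) acc_parts <- c(acc_parts, ps_ok)
    else dropped <- c(dropped, s)
  }
  qc_extra <- character(0)
  if (length(relaxed) > 0L)
    qc_extra <- c(qc_extra, "coverage_guard_relaxed")
  if (length(acc_parts) == 0L) {
    # degenerate: nothing survives the guards anywhere
    acc_parts <- all_parts
    qc_extra <- c(qc_extra, "density_filter_bypassed")
  } else if (length(dropped) > 0L) {
    warning("density guards removed every box at box size(s) ",
            paste(dropped, collapse = ", "))
  }
  n_scales_left <- length(unique(vapply(acc_parts, `[[`, integer(1),
                                        "box_size_px")))
  if (n_scales_left < 3L)
    stop("fewer than 3 scales survive the density filter (",
         n_scales_left, " left)")
  spec <- chhabra_jensen_spectrum(acc_parts, q = q, variant = variant,
                                  tol_mono = config$tol_mono)
  spec$qc_flags <- c(spec$qc_flags, qc_extra)
  spec
}

#' Per-case multifractal metrics from the two contour variants
#'
#' Runs the full chain on the outline and internal-structure contour images
#' of one case and extracts the four exported metrics: `alpha_max` and
#' `f_alpha_max` per variant (maxima of alpha(q) and f(q) over the q grid),
#' plus the D(q)-vs-q regression r-squared per variant as fit diagnostics.
#'
#' @param outline `contour_image`, variant outline.
#' @param internal `contour_image`, variant internal_structure.
#' @param config `mf_config`.
#' @return one-row data.frame: `case_id`, `alpha_max`, `f_alpha_max`,
#'   `alpha_max_internal`, `f_alpha_max_internal`, `dq_vs_q_r2_outline`,
#'   `dq_vs_q_r2_internal`, `qc_flags`. An empty contour yields NA metrics
#'   flagged `empty_<variant>`, never zeros.
#' @export
compute_case_metrics <- function(outline, internal, config = mf_config()) {
  stopifnot(inherits(outline, "contour_image"),
            inherits(internal, "contour_image"))
  if (outline$case_id != internal$case_id)
    stop("contour images come from different cases: '", outline$case_id,
         "' vs '", internal$case_id, "'")
  run <- function(ci, flag) {
    if (ci$empty)
      return(list(alpha_max = NA_real_, f_alpha_max = NA_real_,
                  r2 = NA_real_, qc = paste0("empty_", flag)))
    sp <- mf_spectrum(ci, config)
    list(alpha_max = sp$alpha_max, f_alpha_max = sp$f_alpha_max,
         r2 = sp$dq_vs_q_r2,
         qc = if (length(sp$qc_flags))
           paste0(flag, ":", sp$qc_flags) else character(0))
  }
  o <- run(outline, "outline")
  i <- run(internal, "internal")
  data.frame(case_id = outline$case_id,
             alpha_max = o$alpha_max, f_alpha_max = o$f_alpha_max,
             alpha_max_internal = i$alpha_max,
             f_alpha_max_internal = i$f_alpha_max,
             dq_vs_q_r2_outline = o$r2, dq_vs_q_r2_internal = i$r2,
             qc_flags = paste(c(o$qc, i$qc), collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Legendre-transform cross-check of the direct spectrum
#'
#' Diagnostic only: computes `alpha = d tau / d q` by central differences
#' and `f = q * alpha - tau`, for comparison with the direct Chhabra-Jensen
#' estimates.
#'
#' @param spectrum `mf_spectrum`.
#' @return data.frame with `q`, `alpha_legendre`, `f_legendre`.
#' @export
legendre_check <- function(spectrum) {
  stopifnot(inherits(spectrum, "mf_spectrum"))
  q <- spectrum$q; tau <- spectrum$tau
  n <- length(q)
  al <- numeric(n)
  al[2:(n - 1)] <- (tau[3:n] - tau[1:(n - 2)]) / (q[3:n] - q[1:(n - 2)])
  al[1] <- (tau[2] - tau[1]) / (q[2] - q[1])
  al[n] <- (tau[n] - tau[n - 1]) / (q[n] - q[n - 1])
  data.frame(q = q, alpha_legendre = al, f_legendre = q * al - tau)
}
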