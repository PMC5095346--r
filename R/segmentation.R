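# Segmentation of pan-cytokeratin (DAB) stained sections into
# tumor / stroma / background, via Beer-Lambert color deconvolution and
# thresholding with object-level cleanup.

#' Standard H-DAB stain matrix in optical-density RGB space
#'
#' Rows are unit vectors for hematoxylin, DAB, and a residual channel
#' (normalized cross product of the first two). The hematoxylin and DAB
#' vectors are the widely used Ruifrok-Johnston calibration values.
#'
#' @return 3 x 3 numeric matrix with rownames `c("hematoxylin","dab","residual")`.
#' @export
hdab_stain_vectors <- function() {
  h <- c(0.650, 0.704, 0.286)
  d <- c(0.269, 0.568, 0.778)
  r <- c(h[2] * d[3] - h[3] * d[2],
         h[3] * d[1] - h[1] * d[3],
         h[1] * d[2] - h[2] * d[1])
  m <- rbind(hematoxylin = h / sqrt(sum(h^2)),
             dab = d / sqrt(sum(d^2)),
             residual = r / sqrt(sum(r^2)))
  colnames(m) <- c("R", "G", "B")
  m
}

#' Color deconvolution of an RGB section image into stain channels
#'
#' Per-pixel optical density is computed with the Beer-Lambert transform
#' `OD = -log10((I + 1) / 256)` and projected onto the stain basis by solving
#' the linear system; negative stain contributions are clamped to zero.
#'
#' @param image `section_image` (or H x W x 3 array of 0-255 intensities).
#' @param stain_vectors 3 x 3 matrix of unit stain vectors (rows); defaults
#'   to [hdab_stain_vectors()].
#' @return object of class `stain_channels` with matrices `od_dab`,
#'   `od_hematoxylin`, `od_residual`, `od_total` (sum of raw channel ODs)
#'   and the `stain_vectors` used.
#' @export
deconvolve_stains <- function(image, stain_vectors = hdab_stain_vectors()) {
  px <- if (inherits(image, "section_image")) image$pixels else image
  stopifnot(length(dim(px)) == 3L, dim(px)[3] == 3L)
  stain_vectors <- as.matrix(stain_vectors)
  if (nrow(stain_vectors) == 2L) {
    a <- stain_vectors[1, ]; b <- stain_vectors[2, ]
    r <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
           a[1] * b[2] - a[2] * b[1])
    stain_vectors <- rbind(stain_vectors, r / sqrt(sum(r^2)))
  }
  stopifnot(nrow(stain_vectors) == 3L, ncol(stain_vectors) == 3L)
  if (abs(det(stain_vectors)) < 1e-6)
    stop("degenerate (collinear) stain vectors: matrix is not invertible")
  stain_vectors <- stain_vectors / sqrt(rowSums(stain_vectors^2))

  h <- dim(px)[1]; w <- dim(px)[2]
  od <- -log10((matrix(as.numeric(px), h * w, 3L) + 1) / 256)
  conc <- od %*% solve(stain_vectors)      # pixels x stains
  conc[conc < 0] <- 0
  rn <- rownames(stain_vectors)
  ih <- if (!is.null(rn) && "hematoxylin" %in% rn) match("hematoxylin", rn) else 1L
  id <- if (!is.null(rn) && "dab" %in% rn) match("dab", rn) else 2L
  ir <- setdiff(1:3, c(ih, id))[1]
  structure(list(
    od_hematoxylin = matrix(conc[, ih], h, w),
    od_dab = matrix(conc[, id], h, w),
    od_residual = matrix(conc[, ir], h, w),
    od_total = matrix(rowSums(od), h, w),
    stain_vectors = stain_vectors
  ), class = "stain_channels")
}

#' Classify pixels into tumor / stroma / background
#'
#' Background (glass) is low total optical density. Within tissue, the DAB
#' channel is thresholded (Otsu on the tissue DAB-OD histogram by default,
#' floored at `dab_od_min` so that images without specific staining yield no
#' tumor) and the resulting tumor objects are cleaned at the object level.
#'
#' @param channels `stain_channels` from [deconvolve_stains()].
#' @param tissue_od_min total-OD split between glass and tissue.
#' @param dab_threshold fixed DAB-OD tumor threshold; `NULL` = Otsu.
#' @param dab_od_min lower bound applied to the automatic threshold.
#' @param min_object_px tumor objects below this size are reassigned to
#'   stroma.
#' @param fill_small_holes_px tumor holes below this size are filled.
#' @return object of class `tissue_class_map`: integer matrix `labels` with
#'   0 = background, 1 = stroma, 2 = tumor, plus the thresholds used.
#' @export
classify_tissue <- function(channels, tissue_od_min = 0.10,
                            dab_threshold = NULL, dab_od_min = 0.15,
                            min_object_px = 64L, fill_small_holes_px = 64L) {
  stopifnot(inherits(channels, "stain_channels"))
  tissue <- channels$od_total >= tissue_od_min
  if (!any(tissue)) {
    warning("all-background image: no tissue above total OD ", tissue_od_min)
    lab <- matrix(0L, nrow(channels$od_dab), ncol(channels$od_dab))
    return(structure(list(labels = lab, dab_threshold = NA_real_,
                          tissue_od_min = tissue_od_min),
                     class = "tissue_class_map"))
  }
  dab <- channels$od_dab
  if (is.null(dab_threshold)) {
    v <- dab[tissue]
    hi <- max(v)
    thr <- if (hi <= dab_od_min) {
      Inf            # no specific staining anywhere: nothing can be tumor
    } else {
      max(EBImage::otsu(EBImage::Image(v, dim = c(length(v), 1L)),
                        range = c(0, hi)),
          dab_od_min)
    }
  } else {
    thr <- dab_threshold
  }
  tumor <- tissue & dab > thr
  tumor <- clean_mask(tumor, min_object_px = min_object_px,
                      fill_small_holes_px = fill_small_holes_px)
  lab <- matrix(0L, nrow(dab), ncol(dab))
  lab[tissue] <- 1L
  lab[tumor] <- 2L
  structure(list(labels = lab, dab_threshold = thr,
                 tissue_od_min = tissue_od_min),
            class = "tissue_class_map")
}

#' @export
print.tissue_class_map <- function(x, ...) {
  n <- tabulate(x$labels + 1L, nbins = 3L)
  cat(sprintf(
    "<tissue_class_map> %d x %d: %d background, %d stroma, %d tumor px (DAB thr %.3f)\n",
    nrow(x$labels), ncol(x$labels), n[1], n[2], n[3], x$dab_threshold))
  invisible(x)
}

#' Binarize a tissue class map into a tumor vs non-tumor mask
#'
#' @param classmap `tissue_class_map`.
#' @param case_id case identifier for the resulting mask.
#' @return `binary_mask`, `TRUE` exactly where the label is tumor; an
#'   all-false mask is allowed and flagged via its `empty` field.
#' @export
binarize_tumor <- function(classmap, case_id = "case") {
  stopifnot(inherits(classmap, "tissue_class_map"))
  binary_mask(classmap$labels == 2L, case_id = case_id,
              provenance = "segmented")
}

#' Segment a section image into a tumor mask (one-call convenience)
#'
#' Chains [deconvolve_stains()], [classify_tissue()] and [binarize_tumor()].
#'
#' @param image `section_image`.
#' @param ... passed to [classify_tissue()].
#' @param stain_vectors stain basis, default H-DAB.
#' @return `binary_mask`.
#' @export
segment_tumor <- function(image, stain_vectors = hdab_stain_vectors(), ...) {
  ch <- deconvolve_stains(image, stain_vectors)
  cm <- classify_tissue(ch, ...)
  binarize_tumor(cm, case_id = if (inherits(image, "section_image"))
    image$case_id else "case")
}

#' k-nearest-neighbour pixel classifier (optional alternative to thresholding)
#'
#' Trains on user-labeled rectangles and classifies every pixel from its
#' stain-channel features, mirroring a nearest-neighbour object-based
#' workflow. Feature space: (OD_hematoxylin, OD_DAB, OD_total).
#'
#' @param channels `stain_channels`.
#' @param training data.frame with columns `row0`, `col0`, `row1`, `col1`
#'   (0-based inclusive rectangle corners) and `label` in
#'   `c("background","stroma","tumor")`.
#' @param k number of neighbours.
#' @param max_train_px per-class cap on training pixels (subsampled).
#' @return `tissue_class_map`.
#' @export
knn_classify_tissue <- function(channels, training, k = 5L,
                                max_train_px = 2000L) {
  stopifnot(inherits(channels, "stain_channels"),
            all(c("row0", "col0", "row1", "col1", "label") %in% names(training)))
  lab_levels <- c("background", "stroma", "tumor")
  stopifnot(all(training$label %in% lab_levels))
  feat <- cbind(as.vector(channels$od_hematoxylin),
                as.vector(channels$od_dab),
                as.vector(channels$od_total))
  h <- nrow(channels$od_dab)
  tr_idx <- integer(0); tr_lab <- character(0)
  for (i in seq_len(nrow(training))) {
    rr <- (training$row0[i]:training$row1[i]) + 1L
    cc <- (training$col0[i]:training$col1[i]) + 1L
    ii <- as.vector(outer(rr, (cc - 1L) * h, `+`))
    tr_idx <- c(tr_idx, ii)
    tr_lab <- c(tr_lab, rep(training$label[i], length(ii)))
  }
  keep <- unlist(lapply(split(seq_along(tr_lab), tr_lab), function(sel) {
    if (length(sel) > max_train_px)
      sel[round(seq(1, length(sel), length.out = max_train_px))]
    else sel
  }), use.names = FALSE)
  tr_idx <- tr_idx[keep]; tr_lab <- tr_lab[keep]
  tr <- feat[tr_idx, , drop = FALSE]
  # brute-force kNN in 3-D feature space, blockwise to bound memory
  n <- nrow(feat)
  pred <- integer(n)
  block <- 20000L
  labf <- factor(tr_lab, levels = lab_levels)
  for (s in seq(1L, n, by = block)) {
    e <- min(n, s + block - 1L)
    d2 <- outer(rowSums(feat[s:e, , drop = FALSE]^2), rowSums(tr^2), `+`) -
      2 * feat[s:e, , drop = FALSE] %*% t(tr)
    kk <- min(k, ncol(d2))
    for (j in seq_len(e - s + 1L)) {
      nb <- order(d2[j, ])[seq_len(kk)]
      tab <- tabulate(as.integer(labf[nb]), nbins = 3L)
      pred[s + j - 1L] <- which.max(tab) - 1L
    }
  }
  structure(list(labels = matrix(pred, h, ncol(channels$od_dab)),
                 dab_threshold = NA_real_, tissue_od_min = NA_real_),
            class = "tissue_class_map")
}
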