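#' @importFrom stats median rnorm runif rexp rbinom rpois sd lm coef cor var
#' @importFrom utils write.csv read.csv
NULL

# ---- light S3 records ------------------------------------------------------
# Masks are plain logical matrices (row-major mental model: [row, col],
# 0-based coordinates in the external interfaces, origin top-left). The S3
# wrappers only carry provenance metadata; every algorithm accepts either the
# wrapper or the bare matrix.

#' Construct a binary mask record
#'
#' @param mask logical matrix, `TRUE` = tumor/foreground.
#' @param case_id case identifier.
#' @param provenance one of `"segmented"`, `"synthetic"`, `"loaded"`.
#' @return object of class `binary_mask`.
#' @export
binary_mask <- function(mask, case_id = "case", provenance = c("segmented", "synthetic", "loaded")) {
  provenance <- match.arg(provenance)
  mask <- as_mask_matrix(mask)
  structure(
    list(mask = mask, case_id = case_id, provenance = provenance,
         empty = !any(mask)),
    class = "binary_mask"
  )
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> case '%s' (%s): %d x %d, %d foreground px%s\n",
              x$case_id, x$provenance, nrow(x$mask), ncol(x$mask),
              sum(x$mask), if (x$empty) " [EMPTY]" else ""))
  invisible(x)
}

#' Construct a contour image record
#'
#' @param mask logical matrix of boundary pixels.
#' @param variant `"outline"` (tumor-stroma interface only) or
#'   `"internal_structure"` (includes contours of lumina/internal stroma).
#' @param case_id case identifier.
#' @return object of class `contour_image`.
#' @export
contour_image <- function(mask, variant = c("outline", "internal_structure"),
                          case_id = "case") {
  variant <- match.arg(variant)
  mask <- as_mask_matrix(mask)
  structure(
    list(mask = mask, variant = variant, case_id = case_id,
         empty = !any(mask)),
    class = "contour_image"
  )
}

#' @export
print.contour_image <- function(x, ...) {
  cat(sprintf("<contour_image> case '%s' [%s]: %d x %d, %d boundary px\n",
              x$case_id, x$variant, nrow(x$mask), ncol(x$mask), sum(x$mask)))
  invisible(x)
}

#' Extract the logical matrix from a mask-like object
#'
#' @param x a `binary_mask`, `contour_image`, logical matrix, or numeric
#'   matrix (nonzero = foreground).
#' @return logical matrix.
#' @export
as_mask_matrix <- function(x) {
  if (inherits(x, "binary_mask") || inherits(x, "contour_image")) return(x$mask)
  if (is.matrix(x)) {
    m <- if (is.logical(x)) x else x != 0
    if (anyNA(m)) stop("mask contains NA pixels")
    return(m)
  }
  stop("cannot interpret object of class '", paste(class(x), collapse = "/"),
       "' as a binary mask")
}

# ---- vectorized morphology -------------------------------------------------

shift_mask <- function(m, dr, dc, fill = FALSE) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  rs <- max(1, 1 + dr):min(h, h + dr)
  cs <- max(1, 1 + dc):min(w, w + dc)
  if (length(rs) > 0 && length(cs) > 0)
    out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

#' Morphological erosion with the 4-connected cross element
#'
#' Border pixels are eroded (the outside counts as background).
#'
#' @param m logical matrix.
#' @return eroded logical matrix.
#' @export
erode4 <- function(m) {
  m <- as_mask_matrix(m)
  m &
    shift_mask(m, 1, 0) & shift_mask(m, -1, 0) &
    shift_mask(m, 0, 1) & shift_mask(m, 0, -1)
}

#' Morphological dilation with the 4-connected cross element
#' @param m logical matrix.
#' @param iterations number of successive dilations.
#' @return dilated logical matrix.
#' @export
dilate4 <- function(m, iterations = 1L) {
  m <- as_mask_matrix(m)
  for (i in seq_len(iterations)) {
    m <- m |
      shift_mask(m, 1, 0) | shift_mask(m, -1, 0) |
      shift_mask(m, 0, 1) | shift_mask(m, 0, -1)
  }
  m
}

#' Label connected components of a binary mask
#'
#' Pixel adjacency is turned into a graph and components are read off with
#' \code{igraph::components}, so the connectivity convention is explicit:
#' 8-connectivity for foreground objects, 4-connectivity for background/holes
#' (the standard complementary pairing).
#'
#' @param m logical matrix.
#' @param connectivity 4 or 8.
#' @return integer matrix of labels, 0 for background, components numbered
#'   from 1.
#' @export
label_components <- function(m, connectivity = 8L) {
  m <- as_mask_matrix(m)
  stopifnot(connectivity %in% c(4L, 8L))
  h <- nrow(m); w <- ncol(m)
  lab <- matrix(0L, h, w)
  idx <- which(m)                       # column-major linear indices
  n <- length(idx)
  if (n == 0L) return(lab)
  pos <- integer(h * w); pos[idx] <- seq_len(n)
  r <- ((idx - 1L) %% h) + 1L
  co <- ((idx - 1L) %/% h) + 1L
  offs <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8L) offs <- c(offs, list(c(1L, 1L), c(-1L, 1L)))
  edges <- vector("list", length(offs))
  for (k in seq_along(offs)) {
    dr <- offs[[k]][1]; dc <- offs[[k]][2]
    rr <- r + dr; cc <- co + dc
    ok <- rr >= 1L & rr <= h & cc >= 1L & cc <= w
    if (!any(ok)) next
    nb <- (cc[ok] - 1L) * h + rr[ok]
    keep <- m[nb]
    if (!any(keep)) next
    edges[[k]] <- rbind(pos[idx[ok]][keep], pos[nb][keep])
  }
  el <- do.call(cbind, edges)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (!is.null(el) && ncol(el) > 0)
    g <- igraph::add_edges(g, as.vector(el))
  memb <- igraph::components(g)$membership
  lab[idx] <- as.integer(memb)
  lab
}

#' Fill enclosed holes of a binary mask
#'
#' A hole is a 4-connected background region with no pixel on the image
#' border (i.e. not reachable by flood fill from outside the image).
#'
#' @param m logical matrix.
#' @param max_hole_px only fill holes of at most this many pixels
#'   (`Inf` = fill all).
#' @return logical matrix with holes filled.
#' @export
fill_holes <- function(m, max_hole_px = Inf) {
  m <- as_mask_matrix(m)
  bg <- !m
  if (!any(bg)) return(m)
  lab <- label_components(bg, connectivity = 4L)
  border_labels <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border_labels <- border_labels[border_labels > 0L]
  hole_lab <- setdiff(unique(lab[lab > 0L]), border_labels)
  if (length(hole_lab) == 0L) return(m)
  if (is.finite(max_hole_px)) {
    sizes <- tabulate(lab[lab > 0L])
    hole_lab <- hole_lab[sizes[hole_lab] <= max_hole_px]
    if (length(hole_lab) == 0L) return(m)
  }
  m | (lab %in% hole_lab & bg)
}

#' Remove small objects and fill small holes in a tumor mask
#'
#' Replaces the manual pathologist review of segmentation output: connected
#' components (8-connectivity) below `min_object_px` are dropped and enclosed
#' background regions (4-connectivity) below `fill_small_holes_px` are
#' filled. The operation is idempotent.
#'
#' @param mask `binary_mask` or logical matrix.
#' @param min_object_px minimum object size kept, in pixels.
#' @param fill_small_holes_px maximum hole size filled, in pixels.
#' @return object of the same kind as the input.
#' @export
clean_mask <- function(mask, min_object_px = 0L, fill_small_holes_px = 0L) {
  stopifnot(min_object_px >= 0, fill_small_holes_px >= 0)
  m <- as_mask_matrix(mask)
  if (min_object_px > 0 && any(m)) {
    lab <- label_components(m, connectivity = 8L)
    sizes <- tabulate(lab[lab > 0L])
    keep <- which(sizes >= min_object_px)
    m <- matrix(lab %in% keep & m, nrow(m), ncol(m))
  }
  if (fill_small_holes_px > 0 && any(m)) {
    m <- fill_holes(m, max_hole_px = fill_small_holes_px)
  }
  if (inherits(mask, "binary_mask"))
    binary_mask(m, case_id = mask$case_id, provenance = mask$provenance)
  else m
}

# ---- image I/O -------------------------------------------------------------

#' Read an RGB section image from PNG or TIFF
#'
#' Multi-page TIFFs use the first page. Pixels are returned as 8-bit
#' intensities 0-255.
#'
#' @param path file path ending in .png, .tif or .tiff.
#' @param resolution_um_per_px physical resolution; the default matches the
#'   0.65 um/px of a x10 brightfield scan.
#' @param case_id case identifier; default is the file stem.
#' @return object of class `section_image` with fields `pixels`
#'   (H x W x 3 integer array), `resolution_um_per_px`, `case_id`.
#' @export
read_section_image <- function(path, resolution_um_per_px = 0.65,
                               case_id = NULL) {
  if (!file.exists(path)) stop("image not found: ", path)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = {
      x <- tiff::readTIFF(path, all = TRUE)
      if (is.list(x)) x[[1]] else x
    },
    stop("unsupported image format '.", ext, "' (use PNG or TIFF)")
  )
  if (length(dim(arr)) == 2L) arr <- array(rep(arr, 3L), c(dim(arr), 3L))
  if (dim(arr)[3] > 3L) arr <- arr[, , 1:3, drop = FALSE]
  px <- array(as.integer(round(arr * 255)), dim(arr))
  section_image(px, resolution_um_per_px = resolution_um_per_px,
                case_id = if (is.null(case_id))
                  tools::file_path_sans_ext(basename(path)) else case_id)
}

#' Construct a section-image record
#'
#' @param pixels H x W x 3 integer array of 8-bit RGB intensities.
#' @param resolution_um_per_px positive physical resolution.
#' @param case_id case identifier.
#' @return object of class `section_image`.
#' @export
section_image <- function(pixels, resolution_um_per_px = 0.65,
                          case_id = "case") {
  stopifnot(length(dim(pixels)) == 3L, dim(pixels)[3] == 3L,
            dim(pixels)[1] >= 1L, dim(pixels)[2] >= 1L,
            resolution_um_per_px > 0)
  if (min(pixels) < 0 || max(pixels) > 255)
    stop("pixel intensities must lie in [0, 255]")
  structure(list(pixels = pixels,
                 resolution_um_per_px = resolution_um_per_px,
                 case_id = case_id),
            class = "section_image")
}

#' @export
print.section_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<section_image> case '%s': %d x %d RGB, %.2f um/px\n",
              x$case_id, d[1], d[2], x$resolution_um_per_px))
  invisible(x)
}

#' Write a binary mask or contour image as a {0, 255} PNG/TIFF
#'
#' @param mask mask-like object.
#' @param path output path (.png, .tif or .tiff).
#' @return `path`, invisibly.
#' @export
write_mask_image <- function(mask, path) {
  m <- as_mask_matrix(mask)
  img <- matrix(as.numeric(m), nrow(m), ncol(m))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png  = png::writePNG(img, target = path),
    tif  = ,
    tiff = tiff::writeTIFF(img, where = path),
    stop("unsupported output format '.", ext, "'"))
  invisible(path)
}

#' Read a {0, 255} mask image back as a logical matrix
#'
#' @param path PNG/TIFF path; any nonzero pixel is foreground.
#' @return logical matrix.
#' @export
read_mask_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = {
      x <- tiff::readTIFF(path, all = TRUE)
      if (is.list(x)) x[[1]] else x
    },
    stop("unsupported image format '.", ext, "'"))
  if (length(dim(arr)) == 3L) arr <- arr[, , 1]
  arr > 0.5
}
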