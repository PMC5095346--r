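# Contour extraction: the two contour-image variants analyzed downstream.
# Boundary operator: morphological inner boundary, mask XOR its 4-connected
# erosion, giving 1-px-wide contours.

#' Tumor-stroma interface contour (outline variant)
#'
#' Holes in the mask (background regions not connected to the image border)
#' are filled first, so only the interface with the surrounding stroma
#' survives; the boundary is then the filled mask minus its 4-connectivity
#' erosion. Multiple disjoint tumor regions all contribute contours unless
#' `largest_component_only` is set.
#'
#' @param mask `binary_mask` or logical matrix.
#' @param largest_component_only keep only the largest 8-connected tumor
#'   region before outlining.
#' @return `contour_image` with `variant = "outline"`. An empty input yields
#'   an empty contour flagged via its `empty` field.
#' @export
outline_contour <- function(mask, largest_component_only = FALSE) {
  m <- as_mask_matrix(mask)
  case_id <- if (inherits(mask, "binary_mask")) mask$case_id else "case"
  if (!any(m))
    return(contour_image(m, variant = "outline", case_id = case_id))
  if (largest_component_only) {
    lab <- label_components(m, connectivity = 8L)
    sizes <- tabulate(lab[lab > 0L])
    m <- lab == which.max(sizes)
  }
  filled <- fill_holes(m)
  contour_image(filled & !erode4(filled), variant = "outline",
                case_id = case_id)
}

#' Contours including internal structures
#'
#' The boundary of the mask without hole filling: lumen and internal-stroma
#' interfaces are retained in addition to the outer tumor-stroma interface.
#'
#' @param mask `binary_mask` or logical matrix.
#' @return `contour_image` with `variant = "internal_structure"`.
#' @export
internal_contour <- function(mask) {
  m <- as_mask_matrix(mask)
  case_id <- if (inherits(mask, "binary_mask")) mask$case_id else "case"
  contour_image(m & !erode4(m), variant = "internal_structure",
                case_id = case_id)
}

#' Extract both contour variants for a case
#'
#' @param mask `binary_mask` or logical matrix.
#' @param ... passed to [outline_contour()].
#' @return list with elements `outline` and `internal`.
#' @export
extract_contours <- function(mask, ...) {
  list(outline = outline_contour(mask, ...),
       internal = internal_contour(mask))
}
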