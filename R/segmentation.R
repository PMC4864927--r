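#' Fixed-threshold binarization
#'
#' A pixel is positive iff its intensity is greater than or equal to the
#' threshold (inclusive boundary, so integer-valued images behave
#' predictably). Thresholds are deliberately explicit configuration:
#' every run records the value used.
#'
#' @param channel Intensity matrix.
#' @param threshold Non-negative intensity cutoff.
#' @return Logical matrix of the same dimensions.
#' @export
threshold_fixed <- function(channel, threshold) {
  stopifnot(is.matrix(channel), is.numeric(threshold), length(threshold) == 1,
            threshold >= 0)
  channel >= threshold
}

#' Label connected components
#'
#' Maximal connected foreground components are labeled `1..K` in
#' raster-scan order (rows, then columns) of each object's first pixel,
#' under 4- or 8-connectivity.
#'
#' @param mask Logical matrix.
#' @param connectivity 4 (edge neighbors) or 8 (edge + diagonal).
#' @param pixel_size_um Micrometers per pixel, attached to the result.
#' @return An integer `label_map` matrix (0 = background) with
#'   attributes `pixel_size_um`, `connectivity` and `n_objects`.
#' @export
label_objects <- function(mask, connectivity = 8L, pixel_size_um = 0.75) {
  stopifnot(is.matrix(mask), connectivity %in% c(4L, 8L))
  mask <- mask & !is.na(mask)
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  fg <- which(mask)
  if (length(fg)) {
    id <- integer(H * W)   # position -> foreground vertex index
    id[fg] <- seq_along(fg)
    r <- ((fg - 1L) %% H) + 1L
    co <- ((fg - 1L) %/% H) + 1L
    edges <- integer(0)
    add_edges <- function(dr, dc) {
      ok <- r + dr >= 1L & r + dr <= H & co + dc >= 1L & co + dc <= W
      from <- fg[ok]
      to <- from + dr + dc * H
      keep <- mask[to]
      rbind(id[from[keep]], id[to[keep]])
    }
    steps <- list(c(1L, 0L), c(0L, 1L))
    if (connectivity == 8L) steps <- c(steps, list(c(1L, 1L), c(1L, -1L)))
    el <- do.call(cbind, lapply(steps, function(s) add_edges(s[1], s[2])))
    g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
    if (length(el)) g <- igraph::add_edges(g, as.vector(el))
    comp <- igraph::components(g)$membership
    lab[fg] <- as.integer(comp)
    lab <- canonicalize_labels(lab)
  }
  new_label_map(lab, pixel_size_um, connectivity)
}

new_label_map <- function(lab, pixel_size_um, connectivity) {
  structure(lab, pixel_size_um = pixel_size_um,
            connectivity = as.integer(connectivity),
            n_objects = as.integer(max(lab, 0L)),
            class = c("label_map", class(lab)))
}

# renumber labels to 1..K in raster-scan (row-major) order of first pixel
canonicalize_labels <- function(lab) {
  fg <- which(lab > 0L)
  if (!length(fg)) return(lab)
  H <- nrow(lab)
  raster <- (((fg - 1L) %% H)) * ncol(lab) + ((fg - 1L) %/% H) + 1L
  first <- tapply(raster, lab[fg], min)
  old <- as.integer(names(first))
  rank <- integer(max(old))
  rank[old[order(first)]] <- seq_along(old)
  lab[fg] <- rank[lab[fg]]
  lab
}

#' Remove small labeled objects
#'
#' Objects whose physical area (pixel count times squared pixel size)
#' is strictly less than `min_area_um2` are deleted; this implements
#' the "less than 9 square microns" staining-artifact rule at its
#' literal boundary, so a 16-pixel object at 0.75 um/px (exactly
#' 9 um^2) is retained. Surviving labels are renumbered `1..K'`.
#'
#' @param labels A `label_map` from [label_objects()].
#' @param min_area_um2 Area cutoff, default 9.
#' @return A filtered `label_map`.
#' @export
remove_small_objects <- function(labels, min_area_um2 = 9) {
  stopifnot(inherits(labels, "label_map"), min_area_um2 >= 0)
  px <- attr(labels, "pixel_size_um")
  k <- max(labels, 0L)
  if (k == 0L) return(labels)
  areas <- tabulate(labels[labels > 0L], nbins = k) * px^2
  drop <- which(areas < min_area_um2)
  out <- unclass(labels)
  if (length(drop)) {
    out[out %in% drop] <- 0L
    out <- canonicalize_labels(out)
  }
  new_label_map(out, px, attr(labels, "connectivity"))
}

#' Construct an exclusion region of interest
#'
#' Manual removal of necrosis and staining artifacts (folds, tears,
#' debris) is rendered as user-supplied mask files: the mask marks the
#' pixels to exclude from analysis.
#'
#' @param mask Logical matrix of pixels to exclude.
#' @param category `"necrosis"` or `"artifact"`.
#' @return An object of class `exclusion_roi`.
#' @export
exclusion_roi <- function(mask, category = c("necrosis", "artifact")) {
  category <- match.arg(category)
  stopifnot(is.matrix(mask))
  structure(list(mask = mask != 0 & !is.na(mask), category = category),
            class = "exclusion_roi")
}

#' Apply exclusion ROIs to a mask or label map
#'
#' Excluded pixels are set to background. For label maps, objects cut
#' apart by an exclusion are re-labeled as separate components. An
#' accounting of excluded area per category is attached as the
#' `exclusion_accounting` attribute (a data.frame with pixel and um^2
#' overlap per ROI).
#'
#' @param x Logical mask or `label_map`.
#' @param rois List of [exclusion_roi()] objects (possibly empty).
#' @param pixel_size_um Pixel size used for the accounting when `x` is a
#'   plain mask.
#' @return Object of the same type as `x`.
#' @export
apply_exclusions <- function(x, rois, pixel_size_um = 0.75) {
  stopifnot(is.list(rois))
  is_lab <- inherits(x, "label_map")
  px <- if (is_lab) attr(x, "pixel_size_um") else pixel_size_um
  acct <- data.frame(category = character(0), excluded_overlap_px = integer(0),
                     excluded_overlap_um2 = numeric(0))
  out <- x
  for (roi in rois) {
    stopifnot(inherits(roi, "exclusion_roi"))
    if (!identical(dim(roi$mask), dim(x))) stop("ROI dimension mismatch")
    ov <- sum(roi$mask & (unclass(out) > 0))
    acct <- rbind(acct, data.frame(category = roi$category,
                                   excluded_overlap_px = ov,
                                   excluded_overlap_um2 = ov * px^2))
    if (is_lab) out[roi$mask] <- 0L else out[roi$mask] <- FALSE
  }
  if (is_lab && length(rois)) {
    out <- label_objects(unclass(out) > 0L,
                         connectivity = attr(x, "connectivity"),
                         pixel_size_um = px)
  }
  attr(out, "exclusion_accounting") <- acct
  out
}

#' Delineate the tissue region from the Hoechst counterstain
#'
#' Thresholds the DNA counterstain, closes gaps between nuclei with a
#' disk of the stated radius, fills holes, and keeps the largest
#' connected component as the section's tissue footprint. This supplies
#' the denominator for every "percent tissue" quantity.
#'
#' @param hoechst Hoechst intensity matrix.
#' @param threshold Intensity cutoff.
#' @param closing_radius_um Radius of the morphological closing disk.
#' @param pixel_size_um Micrometers per pixel.
#' @return Logical tissue mask.
#' @export
tissue_mask <- function(hoechst, threshold, closing_radius_um = 6,
                        pixel_size_um = 0.75) {
  stopifnot(is.matrix(hoechst))
  m <- threshold_fixed(hoechst, threshold)
  if (!any(m)) {
    stop("tissue mask is empty: no Hoechst pixel reaches the threshold (",
         threshold, "); check the threshold against the image histogram")
  }
  r_px <- max(1L, round(closing_radius_um / pixel_size_um))
  brush <- EBImage::makeBrush(2L * r_px + 1L, shape = "disc")
  closed <- EBImage::closing(m * 1, brush)
  filled <- EBImage::fillHull(closed > 0)
  lab <- label_objects(filled > 0, connectivity = 8L,
                       pixel_size_um = pixel_size_um)
  k <- max(lab, 0L)
  if (k == 0L) stop("tissue mask is empty after morphology")
  sizes <- tabulate(lab[lab > 0L], nbins = k)
  unclass(lab) == which.max(sizes)
}
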