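#' Euclidean distance to the nearest vessel
#'
#' Computes, for every pixel, the Euclidean distance (in micrometers,
#' between pixel centers) to the nearest pixel of a reference vessel
#' object; pixels inside reference objects are at distance 0. The
#' reference set is either every CD31 object or a subset (e.g. the
#' perfused ones).
#'
#' @param vessels A `label_map` of vessel objects.
#' @param reference_ids `"all"` or an integer vector of object ids.
#' @return A numeric `distance_map` matrix (micrometers) with attributes
#'   `pixel_size_um` and `reference`.
#' @export
distance_to_nearest_vessel <- function(vessels, reference_ids = "all") {
  stopifnot(inherits(vessels, "label_map"))
  px <- attr(vessels, "pixel_size_um")
  if (identical(reference_ids, "all")) {
    ref <- unclass(vessels) > 0L
  } else {
    reference_ids <- as.integer(reference_ids)
    ref <- matrix(unclass(vessels) %in% reference_ids, nrow(vessels))
  }
  if (!any(ref)) stop("empty reference set: no vessel pixels to measure to")
  # exact EDT: distance of each non-reference pixel to the nearest
  # reference pixel, zero inside the reference objects
  d <- EBImage::distmap((!ref) * 1, metric = "euclidean")
  d <- matrix(as.numeric(d), nrow(ref)) * px
  structure(d, pixel_size_um = px,
            reference = if (identical(reference_ids, "all")) "all" else reference_ids,
            class = c("distance_map", "matrix", "array"))
}

#' Bin marker intensity by distance to the nearest vessel
#'
#' Viable-tissue pixels closer than `max_distance_um` are assigned to
#' left-closed, right-open distance bins `[k*w, (k+1)*w)` and the mean,
#' standard deviation and pixel count of the channel intensity are
#' tabulated per bin. Bins that receive no pixels carry `NA` (not 0).
#' The default bin width of one pixel (0.75 um) is the finest distance
#' resolution the imaging supports.
#'
#' @param dmap A `distance_map` from [distance_to_nearest_vessel()].
#' @param channel Intensity matrix (e.g. pimonidazole).
#' @param viable Logical mask of viable tissue to profile.
#' @param bin_width_um Bin width in micrometers.
#' @param max_distance_um Pixels at or beyond this distance are dropped.
#' @return A `distance_profile` data.frame with columns `bin_left_um`,
#'   `bin_right_um`, `mean_intensity`, `sd_intensity`, `pixel_count`,
#'   `mean_distance_um`; attributes `n_out_of_range` and `n_nonviable`
#'   make the pixel accounting explicit.
#' @export
intensity_distance_profile <- function(dmap, channel, viable,
                                       bin_width_um = 0.75,
                                       max_distance_um = 300) {
  stopifnot(inherits(dmap, "distance_map"), is.matrix(channel),
            is.matrix(viable), bin_width_um > 0, max_distance_um > 0)
  if (!identical(dim(dmap), dim(channel)) || !identical(dim(dmap), dim(viable))) {
    stop("dimension mismatch between distance map, channel and viable mask")
  }
  if (!any(viable)) stop("empty viable mask")
  n_bins <- ceiling(max_distance_um / bin_width_um)
  sel <- viable & (unclass(dmap) < max_distance_um)
  d <- dmap[sel]; x <- channel[sel]
  bin <- pmin(floor(d / bin_width_um), n_bins - 1L) + 1L
  cnt <- tabulate(bin, nbins = n_bins)
  sx <- rowsum_by(x, bin, n_bins)
  sd2 <- rowsum_by(x^2, bin, n_bins)
  sdist <- rowsum_by(d, bin, n_bins)
  mean_i <- ifelse(cnt > 0, sx / cnt, NA_real_)
  var_i <- ifelse(cnt > 1, (sd2 - sx^2 / pmax(cnt, 1)) / (cnt - 1), NA_real_)
  prof <- data.frame(
    bin_left_um = (seq_len(n_bins) - 1) * bin_width_um,
    bin_right_um = seq_len(n_bins) * bin_width_um,
    mean_intensity = mean_i,
    sd_intensity = sqrt(pmax(var_i, 0)),
    pixel_count = cnt,
    mean_distance_um = ifelse(cnt > 0, sdist / cnt, NA_real_)
  )
  structure(prof,
            n_out_of_range = sum(viable) - sum(sel),
            n_nonviable = length(viable) - sum(viable),
            class = c("distance_profile", "data.frame"))
}

rowsum_by <- function(x, bin, n_bins) {
  out <- numeric(n_bins)
  if (length(x)) {
    s <- rowsum(x, bin)
    out[as.integer(rownames(s))] <- s[, 1]
  }
  out
}

#' Pool distance profiles across sections
#'
#' Combines per-section profiles on identical bins by count-weighted
#' averaging (equivalent to profiling the pooled pixels).
#'
#' @param profiles List of `distance_profile` objects with identical
#'   bin edges.
#' @return A pooled `distance_profile`.
#' @export
pool_profiles <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  p0 <- profiles[[1]]
  for (p in profiles) {
    if (!isTRUE(all.equal(p$bin_left_um, p0$bin_left_um))) {
      stop("profiles have different bin edges")
    }
  }
  cnt <- Reduce(`+`, lapply(profiles, `[[`, "pixel_count"))
  sx <- Reduce(`+`, lapply(profiles, function(p) {
    ifelse(p$pixel_count > 0, p$mean_intensity * p$pixel_count, 0)
  }))
  ss <- Reduce(`+`, lapply(profiles, function(p) {
    n <- p$pixel_count
    ifelse(n > 0,
           ifelse(n > 1, p$sd_intensity^2 * (n - 1), 0) +
             n * ifelse(n > 0, p$mean_intensity, 0)^2,
           0)
  }))
  sdist <- Reduce(`+`, lapply(profiles, function(p) {
    ifelse(p$pixel_count > 0, p$mean_distance_um * p$pixel_count, 0)
  }))
  mean_i <- ifelse(cnt > 0, sx / cnt, NA_real_)
  var_i <- ifelse(cnt > 1, (ss - sx^2 / pmax(cnt, 1)) / (cnt - 1), NA_real_)
  out <- data.frame(
    bin_left_um = p0$bin_left_um,
    bin_right_um = p0$bin_right_um,
    mean_intensity = mean_i,
    sd_intensity = sqrt(pmax(var_i, 0)),
    pixel_count = cnt,
    mean_distance_um = ifelse(cnt > 0, sdist / cnt, NA_real_)
  )
  structure(out, class = c("distance_profile", "data.frame"))
}
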