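#' Perfused-vessel fraction from DiOC7 coverage
#'
#' For each CD31 object, the DiOC7 coverage is the fraction of the
#' object's pixels that are DiOC7-positive; the object counts as
#' perfused when coverage reaches the cutoff (inclusive at exactly 50%
#' by default). The perfused-vessel fraction is the share of perfused
#' objects among all objects. A section without vessels yields `NA`
#' with a warning rather than 0, so cohort means stay honest.
#'
#' @param cd31 A `label_map` of artifact-filtered CD31 objects.
#' @param dioc7 Logical DiOC7-positive mask.
#' @param coverage_cutoff Coverage at or above which a vessel is
#'   perfused (default 0.5).
#' @return A list with `fraction` and `records`, a data.frame with one
#'   row per vessel (`vessel_id`, `area_um2`, `dioc7_coverage`,
#'   `perfused`).
#' @export
vessel_perfusion_fraction <- function(cd31, dioc7, coverage_cutoff = 0.5) {
  stopifnot(inherits(cd31, "label_map"), is.matrix(dioc7))
  if (!identical(dim(cd31), dim(dioc7))) stop("dimension mismatch")
  px <- attr(cd31, "pixel_size_um")
  k <- max(cd31, 0L)
  if (k == 0L) {
    warning("no vessels in section: perfused fraction undefined")
    return(list(fraction = NA_real_,
                records = data.frame(vessel_id = integer(0),
                                     area_um2 = numeric(0),
                                     dioc7_coverage = numeric(0),
                                     perfused = logical(0))))
  }
  fg <- unclass(cd31) > 0L
  lab <- cd31[fg]
  npx <- tabulate(lab, nbins = k)
  cov_px <- rowsum_by((dioc7[fg]) * 1, lab, k)
  coverage <- cov_px / npx
  perfused <- coverage >= coverage_cutoff
  records <- data.frame(vessel_id = seq_len(k),
                        area_um2 = npx * px^2,
                        dioc7_coverage = coverage,
                        perfused = perfused)
  list(fraction = mean(perfused), records = records)
}

#' Percent of viable tissue positive for a marker
#'
#' @param marker Logical marker-positive mask.
#' @param viable Logical viable-tissue mask (nonempty).
#' @return Percentage in `[0, 100]`.
#' @export
positive_tissue_fraction <- function(marker, viable) {
  stopifnot(is.matrix(marker), is.matrix(viable))
  if (!identical(dim(marker), dim(viable))) stop("dimension mismatch")
  nv <- sum(viable)
  if (nv == 0) stop("empty viable mask")
  100 * sum(marker & viable) / nv
}

#' Mean intensity over viable tissue
#'
#' Average of a channel over the viable-tissue pixels, i.e. the whole
#' section after necrotic regions and tissue artifacts are removed.
#'
#' @param channel Intensity matrix.
#' @param viable Logical viable-tissue mask (nonempty).
#' @return Mean intensity.
#' @export
mean_intensity <- function(channel, viable) {
  stopifnot(is.matrix(channel), is.matrix(viable))
  if (!identical(dim(channel), dim(viable))) stop("dimension mismatch")
  if (!any(viable)) stop("empty viable mask")
  mean(channel[viable])
}

#' Unperfused tissue area fraction
#'
#' Operationalizes "gross vascular shutdown by area" as the viable
#' tissue lying farther than a supply radius from any perfused vessel,
#' expressed as a percentage of the whole tissue area. The criterion
#' (`distance_gt_supply_radius`) is recorded on the result so this rule
#' is never mistaken for a manual delineation.
#'
#' @param viable Logical viable-tissue mask.
#' @param perfused_vessels `label_map` restricted to perfused vessels
#'   (all remaining ids are treated as perfused).
#' @param supply_radius_um Supply radius in micrometers (default 150).
#' @param tissue Logical whole-tissue mask, the denominator.
#' @return Percentage of tissue area, with attribute `criterion`.
#' @export
unperfused_area_fraction <- function(viable, perfused_vessels,
                                     supply_radius_um = 150, tissue = viable) {
  stopifnot(is.matrix(viable), is.matrix(tissue))
  if (!identical(dim(viable), dim(tissue))) stop("dimension mismatch")
  nt <- sum(tissue)
  if (nt == 0) stop("empty tissue mask")
  if (max(perfused_vessels, 0L) == 0L) {
    unperf <- sum(viable)
  } else {
    if (!identical(dim(viable), dim(perfused_vessels))) stop("dimension mismatch")
    d <- distance_to_nearest_vessel(perfused_vessels, "all")
    unperf <- sum(viable & (unclass(d) > supply_radius_um))
  }
  structure(100 * unperf / nt, criterion = "distance_gt_supply_radius")
}

#' Necrotic tissue area fraction
#'
#' @param necrosis_rois List of [exclusion_roi()] objects; only those
#'   with category `"necrosis"` contribute.
#' @param tissue Logical whole-tissue mask.
#' @return Percentage of tissue area that is necrotic.
#' @export
necrotic_area_fraction <- function(necrosis_rois, tissue) {
  stopifnot(is.matrix(tissue))
  nt <- sum(tissue)
  if (nt == 0) stop("empty tissue mask")
  nec <- matrix(FALSE, nrow(tissue), ncol(tissue))
  for (roi in necrosis_rois) {
    if (!inherits(roi, "exclusion_roi") || roi$category != "necrosis") next
    if (!identical(dim(roi$mask), dim(tissue))) stop("dimension mismatch")
    nec <- nec | roi$mask
  }
  100 * sum(nec & tissue) / nt
}

#' Caliper tumor volume
#'
#' Ellipsoid volume from three orthogonal caliper diameters:
#' `volume = pi/6 * a * b * c`.
#'
#' @param a,b,c Orthogonal diameters in millimeters.
#' @return Volume in cubic millimeters.
#' @export
tumor_volume <- function(a, b, c) {
  if (any(c(a, b, c) < 0)) stop("diameters must be non-negative")
  pi / 6 * a * b * c
}

#' Default analysis configuration
#'
#' Thresholds are per-channel fixed intensity cutoffs; the defaults are
#' calibrated once against the synthetic generator as background mean
#' plus five noise standard deviations (Hoechst: half the necrotic
#' signal level, so necrotic tissue still counts as tissue).
#'
#' @param ... Named overrides of any default.
#' @return A named list of parameters.
#' @export
default_config <- function(...) {
  cfg <- list(
    thresholds = list(CD31 = 250, DiOC7 = 250, HIF1a = 250, BrdUrd = 250,
                      Hoechst = 1500),
    coverage_cutoff = 0.5,
    min_area_um2 = 9,
    supply_radius_um = 150,
    connectivity = 8L,
    closing_radius_um = 6,
    bin_width_um = 0.75,
    max_distance_um = 300,
    intensity_mode = "all_viable"   # or "positive_only"
  )
  dots <- list(...)
  utils::modifyList(cfg, dots)
}

#' Compute all per-section metrics
#'
#' Runs the fixed stage order -- exclusions, fixed thresholds, connected
#' component labeling, sub-9-um^2 artifact removal -- then fills every
#' metric computable from the channels present (fields for absent
#' channels are `NA`). Intermediate masks are attached for reuse by the
#' profiling stage.
#'
#' @param stack A [section_stack()] with at least CD31, DiOC7 and
#'   Hoechst channels.
#' @param config Parameter list from [default_config()].
#' @param rois List of [exclusion_roi()] objects (manual necrosis /
#'   artifact annotations); may be empty.
#' @return A one-row data.frame of section metrics with attributes
#'   `vessels` (per-vessel records), `masks` (tissue, viable, CD31
#'   labels, DiOC7 mask, perfused ids) and `criteria` (the boundary
#'   rules applied).
#' @export
compute_section_metrics <- function(stack, config = default_config(),
                                    rois = list()) {
  validate_section_stack(stack)
  px <- stack$pixel_size_um
  ch <- stack$channels
  need <- c("CD31", "DiOC7", "Hoechst")
  miss <- setdiff(need, names(ch))
  if (length(miss)) {
    stop("[stage tissue] required channel(s) missing: ",
         paste(miss, collapse = ", "))
  }

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("[stage ", stage, "] ", conditionMessage(e), call. = FALSE)
    })
  }

  tissue <- run_stage("tissue", tissue_mask(
    ch$Hoechst, config$thresholds$Hoechst, config$closing_radius_um, px))

  nec <- matrix(FALSE, nrow(tissue), ncol(tissue))
  art <- matrix(FALSE, nrow(tissue), ncol(tissue))
  for (roi in rois) {
    stopifnot(inherits(roi, "exclusion_roi"))
    if (!identical(dim(roi$mask), dim(tissue))) {
      stop("[stage exclusions] ROI dimension mismatch")
    }
    if (roi$category == "necrosis") nec <- nec | roi$mask else art <- art | roi$mask
  }
  viable <- tissue & !nec & !art

  seg_channel <- function(name) {
    m <- run_stage(paste0("threshold:", name),
                   threshold_fixed(ch[[name]], config$thresholds[[name]]))
    run_stage("exclusions", apply_exclusions(m, rois, pixel_size_um = px)) &
      tissue
  }

  cd31_mask <- seg_channel("CD31")
  dioc7_mask <- seg_channel("DiOC7")
  cd31_lab <- run_stage("label", label_objects(cd31_mask, config$connectivity, px))
  cd31_lab <- run_stage("artifact_filter",
                        remove_small_objects(cd31_lab, config$min_area_um2))

  perf <- run_stage("perfusion", vessel_perfusion_fraction(
    cd31_lab, dioc7_mask, config$coverage_cutoff))
  perfused_ids <- perf$records$vessel_id[perf$records$perfused]

  marker_pct <- function(name) {
    if (!name %in% names(ch)) return(NA_real_)
    m <- seg_channel(name)
    run_stage(paste0("fraction:", name), positive_tissue_fraction(m, viable))
  }
  marker_mean <- function(name) {
    if (!name %in% names(ch)) return(NA_real_)
    dom <- viable
    if (config$intensity_mode == "positive_only") dom <- viable & seg_channel(name)
    if (!any(dom)) return(NA_real_)
    run_stage(paste0("intensity:", name), mean_intensity(ch[[name]], dom))
  }

  unperf <- run_stage("unperfused_area", {
    if (length(perfused_ids)) {
      keep <- unclass(cd31_lab)
      keep[!(keep %in% perfused_ids)] <- 0L
      pv <- new_label_map(canonicalize_labels(keep), px,
                          attr(cd31_lab, "connectivity"))
      unperfused_area_fraction(viable, pv, config$supply_radius_um, tissue)
    } else {
      pv <- new_label_map(matrix(0L, nrow(tissue), ncol(tissue)), px, 8L)
      unperfused_area_fraction(viable, pv, config$supply_radius_um, tissue)
    }
  })
  nec_pct <- run_stage("necrotic_area", 100 * sum(nec & tissue) / sum(tissue))

  metrics <- data.frame(
    section_id = stack$section_id,
    tumor_line = stack$tumor_line,
    arm = stack$arm,
    staining_group = stack$staining_group,
    n_vessels = nrow(perf$records),
    perfused_vessel_fraction = perf$fraction,
    hif_positive_tissue_pct = marker_pct("HIF1a"),
    brdu_positive_tissue_pct = marker_pct("BrdUrd"),
    mean_pimonidazole_intensity = marker_mean("pimonidazole"),
    mean_hif_intensity = marker_mean("HIF1a"),
    unperfused_area_pct = as.numeric(unperf),
    necrotic_area_pct = nec_pct,
    viable_tissue_area_um2 = sum(viable) * px^2,
    stringsAsFactors = FALSE
  )
  structure(metrics,
            vessels = cbind(section_id = stack$section_id, perf$records),
            masks = list(tissue = tissue, viable = viable,
                         necrosis = nec, artifact = art,
                         cd31_labels = cd31_lab, dioc7_mask = dioc7_mask,
                         perfused_ids = perfused_ids),
            criteria = list(
              threshold_rule = "intensity >= threshold",
              coverage_rule = "coverage >= cutoff",
              artifact_rule = "area < min_area_um2 removed",
              unperfused_rule = "distance_gt_supply_radius",
              intensity_mode = config$intensity_mode,
              stage_order = "exclusions -> threshold -> label -> artifact_filter"
            ))
}
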