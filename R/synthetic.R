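# Signal levels painted by the generator (16-bit counts). Chosen so every
# structure sits far above the default 5-sigma thresholds.
SIGNAL_LEVELS <- list(vessel = 40000, dioc7 = 30000, hif = 20000,
                      hoechst_tissue = 15000, hoechst_necrosis = 3000,
                      speck = 40000)

#' Parameters of a synthetic tumor section
#'
#' Describes one simulated cryosection: vessel geometry and perfusion
#' probability, the hypoxia-versus-distance sigmoid, HIF1-alpha patch
#' rules, necrosis extent, staining-speck artifacts and sensor noise.
#' Defaults emulate the SCCVII regime: roughly 300 vessel
#' cross-sections per section with about one in five perfused, hypoxia
#' rising toward a plateau around the oxygen diffusion distance
#' (~100 um) from the nearest perfused vessel.
#'
#' @param height_px,width_px Section size in pixels.
#' @param pixel_size_um Micrometers per pixel edge.
#' @param n_vessels Number of vessel cross-sections (disks).
#' @param vessel_radius_um `(min, max)` disk radius range in um.
#' @param p_perfused Probability that a vessel carries the perfusion dye.
#' @param hypoxia_profile List `I0, Imax, d0, s`: pimonidazole intensity
#'   follows `I(d) = I0 + (Imax - I0) / (1 + exp(-(d - d0)/s))` with `d`
#'   the distance (um) to the nearest perfused vessel.
#' @param hypoxia_reference `"perfused"` (default) ties hypoxia to the
#'   perfused vessels only; `"all_vessels"` ties it to every vessel,
#'   mimicking intermittent perfusion where dye-negative vessels still
#'   oxygenate nearby tissue part of the time.
#' @param hif_distance_cutoff_um Distance beyond which tissue is
#'   HIF1-alpha positive with probability `p_hif` (as smoothed patches).
#' @param p_hif Expected positive fraction of the beyond-cutoff tissue.
#' @param necrosis_fraction Target fraction of tissue area that is
#'   necrotic (hit to within +/- 0.01).
#' @param n_specks Number of sub-9-um^2 staining specks injected into
#'   the CD31 channel (areas 1..15 px at 0.75 um/px).
#' @param noise_sd Additive Gaussian noise SD (clipped at 0; final
#'   intensities are rounded to integers for lossless 16-bit storage).
#' @param seed RNG seed; identical models give pixel-identical output.
#' @param tumor_line,arm,staining_group Metadata copied to the stack.
#'   `staining_group = NA` emits all six channels.
#' @return An object of class `section_model`.
#' @export
section_model <- function(height_px = 768, width_px = 768, pixel_size_um = 0.75,
                          n_vessels = 300, vessel_radius_um = c(3, 8),
                          p_perfused = 0.21,
                          hypoxia_profile = list(I0 = 200, Imax = 3000,
                                                 d0 = 100, s = 25),
                          hypoxia_reference = c("perfused", "all_vessels"),
                          hif_distance_cutoff_um = 100, p_hif = 0.5,
                          necrosis_fraction = 0.1, n_specks = 30,
                          noise_sd = 50, seed = 1,
                          tumor_line = "SCCVII", arm = "control",
                          staining_group = NA_character_) {
  hypoxia_reference <- match.arg(hypoxia_reference)
  m <- structure(as.list(environment()), class = "section_model")
  validate_section_model(m)
  m
}

validate_section_model <- function(m) {
  hp <- m$hypoxia_profile
  stopifnot(
    m$height_px >= 32, m$width_px >= 32, m$pixel_size_um > 0,
    m$n_vessels >= 0, length(m$vessel_radius_um) == 2,
    m$vessel_radius_um[1] > 0, m$vessel_radius_um[2] >= m$vessel_radius_um[1],
    m$p_perfused >= 0, m$p_perfused <= 1,
    hp$Imax >= hp$I0, hp$I0 >= 0, hp$d0 > 0, hp$s > 0,
    m$p_hif >= 0, m$p_hif <= 1,
    m$necrosis_fraction >= 0, m$necrosis_fraction < 1,
    m$n_specks >= 0, m$noise_sd >= 0
  )
  invisible(m)
}

#' Hypoxia marker intensity as a function of vessel distance
#'
#' The generator's 4-parameter sigmoid: baseline `I0` near vessels
#' rising to a plateau `Imax` with half-rise at `d0` and rise width `s`.
#'
#' @param d Distance(s) to the nearest perfused vessel, micrometers.
#' @param params List with `I0`, `Imax`, `d0`, `s`.
#' @return Intensity value(s).
#' @export
hypoxia_sigmoid <- function(d, params) {
  params$I0 + (params$Imax - params$I0) / (1 + exp(-(d - params$d0) / params$s))
}

# quantization applied to every emitted channel: clip to the 16-bit
# range and round, so stacks round-trip losslessly through TIFF
quantize_channel <- function(x) round(pmin(pmax(x, 0), INTENSITY_MAX))

#' Simulate one tumor section with ground truth
#'
#' Generates a registered multi-channel stack: CD31 disks at vessel
#' sites (plus sub-9-um^2 specks), DiOC7 over perfused vessels only,
#' pimonidazole following the configured distance sigmoid (low constant
#' `I0` in necrosis), HIF1-alpha patches beyond the distance cutoff,
#' and Hoechst marking tissue (weak in necrosis) -- all with additive
#' Gaussian noise, clipped and rounded to 16-bit integers. All
#' randomness derives from `model$seed`; the perfusion flags are the
#' first draws of the stream (`rbinom(n_vessels, 1, p_perfused)`), so
#' they can be replayed independently.
#'
#' @param model A [section_model()].
#' @param section_id Identifier stored on the stack.
#' @return A list with `stack` (a [section_stack()]) and `ground_truth`
#'   (class `ground_truth`: `vessel_labels`, `perfused_ids`,
#'   `necrosis_mask`, `tissue_mask`, `speck_mask`, `true_p_perfused`,
#'   `profile_params`, `distance_um`, `model`).
#' @export
simulate_section <- function(model, section_id = "sim") {
  validate_section_model(model)
  withr::with_seed(model$seed, simulate_section_impl(model, section_id),
                   .rng_kind = "Mersenne-Twister",
                   .rng_normal_kind = "Inversion",
                   .rng_sample_kind = "Rejection")
}

simulate_section_impl <- function(model, section_id) {
  H <- model$height_px; W <- model$width_px; px <- model$pixel_size_um
  n <- model$n_vessels

  # 1. perfusion flags: first draws of the stream (replayable oracle)
  flags <- stats::rbinom(n, 1L, model$p_perfused) == 1L
  # 2. vessel radii
  radii_um <- stats::runif(n, model$vessel_radius_um[1], model$vessel_radius_um[2])

  rows <- matrix(seq_len(H), H, W)
  cols <- matrix(seq_len(W), H, W, byrow = TRUE)

  # 3. tissue footprint: super-ellipse covering most of the frame
  tissue <- (abs((rows - (H + 1) / 2) / (0.46 * H))^3 +
               abs((cols - (W + 1) / 2) / (0.46 * W))^3) <= 1

  # 4. necrosis: smoothed random field thresholded inside tissue to hit
  #    the target fraction to within one pixel quantile step
  nec <- matrix(FALSE, H, W)
  nec_field <- smooth_field(H, W, sigma = max(4, H / 16))
  if (model$necrosis_fraction > 0) {
    thr <- stats::quantile(nec_field[tissue], 1 - model$necrosis_fraction,
                           names = FALSE, type = 7)
    nec <- tissue & (nec_field >= thr)
  }

  # 5. place non-overlapping vessel disks in viable tissue
  radii_px <- radii_um / px
  d_nec <- if (any(nec)) {
    matrix(as.numeric(EBImage::distmap((!nec) * 1)), H)
  } else {
    matrix(Inf, H, W)
  }
  centers <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    r <- radii_px[i]
    placed <- FALSE
    for (try in seq_len(1000L)) {
      rc <- stats::runif(1, 1 + r + 1, H - r - 1)
      cc <- stats::runif(1, 1 + r + 1, W - r - 1)
      ri <- round(rc); ci <- round(cc)
      if (!tissue[ri, ci]) next
      if (d_nec[ri, ci] <= r + 1) next
      if (i > 1) {
        j <- seq_len(i - 1)
        if (any((centers[j, 1] - rc)^2 + (centers[j, 2] - cc)^2 <
                (radii_px[j] + r + 2)^2)) next
      }
      centers[i, ] <- c(rc, cc)
      placed <- TRUE
      break
    }
    if (!placed) {
      stop("could not place vessel ", i, " without overlap after 1000 retries; ",
           "reduce n_vessels or vessel radii")
    }
  }

  vessel_labels <- matrix(0L, H, W)
  for (i in seq_len(n)) {
    idx <- disk_indices(centers[i, 1], centers[i, 2], radii_px[i], H, W)
    vessel_labels[idx] <- i
  }
  vessel_labels <- canonicalize_labels(vessel_labels)
  # canonicalization renumbers by raster order; remap per-vessel info
  map <- relabel_mapping(vessel_labels, centers, radii_px, H, W, n)
  flags <- flags[map]
  vessel_labels <- new_label_map(vessel_labels, px, 8L)
  perfused_ids <- which(flags)

  # 6. staining specks (< 9 um^2) injected into the CD31 channel
  speck_mask <- matrix(FALSE, H, W)
  vessel_free <- vessel_labels == 0L
  for (k in seq_len(model$n_specks)) {
    sz <- 1L + floor(stats::runif(1) * 15L)  # 1..15 px, < 9 um^2 at 0.75 um/px
    for (try in seq_len(1000L)) {
      ri <- 8L + floor(stats::runif(1) * (H - 16L))
      ci <- 8L + floor(stats::runif(1) * (W - 16L))
      win_r <- pmax(1L, ri - 7L):pmin(H, ri + 7L)
      win_c <- pmax(1L, ci - 7L):pmin(W, ci + 7L)
      if (!tissue[ri, ci]) next
      if (any(!vessel_free[win_r, win_c]) || any(speck_mask[win_r, win_c])) next
      speck_mask[grow_blob(ri, ci, sz, H, W)] <- TRUE
      break
    }
  }

  # 7. hypoxia distance field
  ref_ids <- if (model$hypoxia_reference == "perfused") perfused_ids else seq_len(n)
  if (length(ref_ids)) {
    ref <- matrix(unclass(vessel_labels) %in% ref_ids, H)
    d_um <- matrix(as.numeric(EBImage::distmap((!ref) * 1)), H) * px
  } else {
    d_um <- matrix(Inf, H, W)
  }

  hp <- model$hypoxia_profile
  pimo <- matrix(0, H, W)
  pimo[tissue] <- hypoxia_sigmoid(d_um[tissue], hp)
  pimo[nec] <- hp$I0

  cd31 <- matrix(0, H, W)
  cd31[unclass(vessel_labels) > 0L] <- SIGNAL_LEVELS$vessel
  cd31[speck_mask] <- SIGNAL_LEVELS$speck

  dioc7 <- matrix(0, H, W)
  if (length(perfused_ids)) {
    dioc7[matrix(unclass(vessel_labels) %in% perfused_ids, H)] <- SIGNAL_LEVELS$dioc7
  }

  hif_mask <- matrix(FALSE, H, W)
  eligible <- tissue & !nec & (d_um > model$hif_distance_cutoff_um)
  hif_field <- smooth_field(H, W, sigma = 4)
  if (model$p_hif > 0 && any(eligible)) {
    thr <- stats::quantile(hif_field[eligible], 1 - model$p_hif,
                           names = FALSE, type = 7)
    hif_mask <- eligible & (hif_field >= thr)
  }
  hif <- matrix(0, H, W)
  hif[hif_mask] <- SIGNAL_LEVELS$hif

  hoechst <- matrix(0, H, W)
  hoechst[tissue] <- SIGNAL_LEVELS$hoechst_tissue
  hoechst[nec] <- SIGNAL_LEVELS$hoechst_necrosis

  channels <- list(DiOC7 = dioc7, CD31 = cd31, pimonidazole = pimo,
                   BrdUrd = brdu_channel(tissue, nec, d_um, H, W),
                   HIF1a = hif, Hoechst = hoechst)
  if (!is.na(model$staining_group)) {
    channels <- channels[GROUP_CHANNELS[[model$staining_group]]]
  }
  channels <- lapply(channels, function(ch) {
    if (model$noise_sd > 0) ch <- ch + stats::rnorm(H * W, 0, model$noise_sd)
    quantize_channel(ch)
  })

  stack <- section_stack(channels, pixel_size_um = px, section_id = section_id,
                         tumor_line = model$tumor_line, arm = model$arm,
                         staining_group = model$staining_group)
  gt <- structure(list(
    vessel_labels = vessel_labels,
    perfused_ids = perfused_ids,
    necrosis_mask = nec,
    tissue_mask = tissue,
    speck_mask = speck_mask,
    hif_mask = hif_mask,
    true_p_perfused = if (n > 0) mean(flags) else NA_real_,
    profile_params = hp,
    distance_um = d_um,
    model = model
  ), class = "ground_truth")
  list(stack = stack, ground_truth = gt)
}

# proliferation marker: positive in the well-oxygenated band near
# perfused vessels, absent in distant (hypoxic) tissue
brdu_channel <- function(tissue, nec, d_um, H, W) {
  b <- matrix(0, H, W)
  v <- tissue & !nec
  b[v] <- ifelse(d_um[v] < 50, 10000, 0)
  b
}

smooth_field <- function(H, W, sigma) {
  f <- matrix(stats::runif(H * W), H, W)
  matrix(as.numeric(EBImage::gblur(f, sigma = sigma)), H, W)
}

disk_indices <- function(rc, cc, r_px, H, W) {
  rr <- max(1L, floor(rc - r_px)):min(H, ceiling(rc + r_px))
  cs <- max(1L, floor(cc - r_px)):min(W, ceiling(cc + r_px))
  g <- expand.grid(r = rr, c = cs)
  keep <- (g$r - rc)^2 + (g$c - cc)^2 <= r_px^2
  (g$c[keep] - 1L) * H + g$r[keep]
}

# after canonicalization, object k's original index is recovered by
# matching the original center pixel to the new label value
relabel_mapping <- function(lab, centers, radii_px, H, W, n) {
  map <- integer(n)
  for (i in seq_len(n)) {
    ri <- round(centers[i, 1]); ci <- round(centers[i, 2])
    map[lab[ri, ci]] <- i
  }
  if (any(map == 0L)) stop("internal: vessel relabeling failed")
  map
}

#' Simulate a cohort of sections across treatment arms
#'
#' Produces `n_per_arm` sections for each arm with distinct,
#' deterministically derived seeds, plus a manifest matching the cohort
#' CSV schema. If `out_dir` is given, stacks and ground truths are
#' written to disk and manifest paths filled in.
#'
#' @param models Named list mapping arm name to a [section_model()]
#'   (the model's `seed` is replaced by derived per-section seeds).
#' @param n_per_arm Sections per arm (default 6, the study's group size).
#' @param master_seed Integer master seed.
#' @param out_dir Optional output directory.
#' @return A list with `stacks`, `ground_truths` and `manifest`.
#' @export
simulate_cohort <- function(models, n_per_arm = 6L, master_seed = 1L,
                            out_dir = NULL) {
  stopifnot(is.list(models), length(models) >= 1, n_per_arm >= 1)
  arms <- names(models)
  if (is.null(arms) || any(arms == "") || anyDuplicated(arms)) {
    stop("models must be uniquely named by arm")
  }
  stacks <- list(); gts <- list(); rows <- list()
  idx <- 0L
  for (a in seq_along(arms)) {
    for (j in seq_len(n_per_arm)) {
      idx <- idx + 1L
      m <- models[[a]]
      m$seed <- derive_seed(master_seed, a, j)
      m$arm <- arms[a]
      sid <- sprintf("%s_%s_%02d", m$tumor_line, arms[a], j)
      sim <- simulate_section(m, section_id = sid)
      path <- ""
      if (!is.null(out_dir)) {
        dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
        path <- file.path(out_dir, paste0(sid, ".tif"))
        write_stack(sim$stack, path)
        write_ground_truth(sim$ground_truth, file.path(out_dir, paste0(sid, "_gt")))
      }
      stacks[[idx]] <- sim$stack
      gts[[idx]] <- sim$ground_truth
      rows[[idx]] <- data.frame(section_id = sid, tumor_line = m$tumor_line,
                                arm = arms[a],
                                staining_group = as.character(m$staining_group),
                                path = path, pixel_size_um = m$pixel_size_um,
                                stringsAsFactors = FALSE)
    }
  }
  list(stacks = stacks, ground_truths = gts, manifest = do.call(rbind, rows))
}

derive_seed <- function(master_seed, arm_idx, section_idx) {
  as.integer((as.numeric(master_seed) * 100003 + arm_idx * 1009 +
                section_idx * 101) %% 2147483647L) + 1L
}

#' Write ground truth to disk
#'
#' Masks and the vessel label map go to single-channel TIFFs; scalars
#' and the hypoxia profile parameters go to a key/value CSV at full
#' float precision.
#'
#' @param gt A `ground_truth` from [simulate_section()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_ground_truth <- function(gt, dir) {
  stopifnot(inherits(gt, "ground_truth"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create directory '", dir, "'")
  wr <- function(m, name) {
    tiff::writeTIFF(unclass(m) / INTENSITY_MAX, file.path(dir, name),
                    bits.per.sample = 16L, compression = "deflate")
  }
  if (max(gt$vessel_labels, 0L) > INTENSITY_MAX) {
    stop("too many vessels for 16-bit label storage")
  }
  wr(gt$vessel_labels, "vessel_labels.tif")
  wr(gt$necrosis_mask * 1, "necrosis_mask.tif")
  wr(gt$tissue_mask * 1, "tissue_mask.tif")
  wr(gt$speck_mask * 1, "speck_mask.tif")
  utils::write.csv(data.frame(vessel_id = gt$perfused_ids),
                   file.path(dir, "perfused_ids.csv"), row.names = FALSE)
  hp <- gt$profile_params
  params <- c(pixel_size_um = attr(gt$vessel_labels, "pixel_size_um"),
              true_p_perfused = gt$true_p_perfused,
              I0 = hp$I0, Imax = hp$Imax, d0 = hp$d0, s = hp$s)
  writeLines(c("key,value",
               sprintf("%s,%.17g", names(params), params)),
             file.path(dir, "params.csv"))
  invisible(dir)
}

#' Read ground truth written by [write_ground_truth()]
#'
#' @param dir Directory.
#' @return A `ground_truth` object (without the in-memory-only distance
#'   field and model).
#' @export
read_ground_truth <- function(dir) {
  rd <- function(name) {
    round(tiff::readTIFF(file.path(dir, name)) * INTENSITY_MAX)
  }
  params <- utils::read.csv(file.path(dir, "params.csv"))
  pv <- as.numeric(params$value); names(pv) <- params$key
  lab <- rd("vessel_labels.tif")
  storage.mode(lab) <- "integer"
  ids <- utils::read.csv(file.path(dir, "perfused_ids.csv"))$vessel_id
  structure(list(
    vessel_labels = new_label_map(lab, pv[["pixel_size_um"]], 8L),
    perfused_ids = as.integer(ids %||% integer(0)),
    necrosis_mask = rd("necrosis_mask.tif") > 0,
    tissue_mask = rd("tissue_mask.tif") > 0,
    speck_mask = rd("speck_mask.tif") > 0,
    true_p_perfused = pv[["true_p_perfused"]],
    profile_params = list(I0 = pv[["I0"]], Imax = pv[["Imax"]],
                          d0 = pv[["d0"]], s = pv[["s"]]),
    distance_um = NULL, model = NULL
  ), class = "ground_truth")
}

# random connected blob of `size` pixels grown by 4-neighbor accretion,
# confined to a 11x11 box around the seed so the caller's clearance
# window stays valid
grow_blob <- function(r0, c0, size, H, W) {
  pix <- matrix(c(r0, c0), 1, 2)
  while (nrow(pix) < size) {
    base <- pix[1L + floor(stats::runif(1) * nrow(pix)), ]
    step <- switch(1L + floor(stats::runif(1) * 4),
                   c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
    cand <- base + step
    if (abs(cand[1] - r0) > 5 || abs(cand[2] - c0) > 5) next
    if (cand[1] < 1 || cand[1] > H || cand[2] < 1 || cand[2] > W) next
    if (any(pix[, 1] == cand[1] & pix[, 2] == cand[2])) next
    pix <- rbind(pix, cand)
  }
  (pix[, 2] - 1L) * H + pix[, 1]
}
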