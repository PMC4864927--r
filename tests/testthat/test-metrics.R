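disk_label_map <- function(H, W, centers, r_px, px = 0.75) {
  m <- matrix(FALSE, H, W)
  for (ct in centers) {
    for (rr in seq_len(H)) for (cc in seq_len(W)) {
      if ((rr - ct[1])^2 + (cc - ct[2])^2 <= r_px^2) m[rr, cc] <- TRUE
    }
  }
  label_objects(m, 8L, pixel_size_um = px)
}

test_that("perfused fraction counts coverage with an inclusive 50% boundary", {
  # 10 objects: 3 fully covered, 7 untouched -> 0.3
  lab <- matrix(0L, 10, 30)
  for (i in 1:10) lab[((i - 1) %% 10) + 1, (i - 1) * 3 + 1:3] <- i
  lab <- label_objects(lab > 0, 4L, 0.75)
  dioc <- matrix(FALSE, 10, 30)
  dioc[unclass(lab) %in% 1:3] <- TRUE
  res <- vessel_perfusion_fraction(lab, dioc)
  expect_equal(res$fraction, 0.3)
  expect_identical(nrow(res$records), 10L)
  expect_identical(sum(res$records$perfused), 3L)

  # 100-pixel object: exactly 50 covered -> perfused; 49 -> not
  m <- matrix(FALSE, 10, 10); m[1:10, 1:10] <- TRUE
  lab1 <- label_objects(m, 8L, 0.75)
  for (ncov in c(50L, 49L)) {
    dioc <- matrix(FALSE, 10, 10); dioc[seq_len(ncov)] <- TRUE
    res <- vessel_perfusion_fraction(lab1, dioc, coverage_cutoff = 0.5)
    expect_identical(res$records$perfused, ncov >= 50L)
  }
})

test_that("zero vessels give an NA sentinel with a warning, not zero", {
  lab <- label_objects(matrix(FALSE, 5, 5))
  expect_warning(res <- vessel_perfusion_fraction(lab, matrix(FALSE, 5, 5)),
                 "no vessels")
  expect_true(is.na(res$fraction))
})

test_that("dilating the DiOC7 mask never lowers the perfused fraction", {
  set.seed(41)
  sim <- simulate_section(tiny_model(seed = 41), "mono")
  gt <- sim$ground_truth
  dioc <- matrix(unclass(gt$vessel_labels) %in% gt$perfused_ids,
                 nrow(gt$vessel_labels))
  f0 <- vessel_perfusion_fraction(gt$vessel_labels, dioc)$fraction
  grown <- EBImage::dilate(dioc * 1, EBImage::makeBrush(5, "disc")) > 0
  f1 <- vessel_perfusion_fraction(gt$vessel_labels, grown)$fraction
  expect_gte(f1, f0)
  expect_equal(f0, gt$true_p_perfused)
})

test_that("positive tissue fraction and mean intensity match pixel accounting", {
  v <- matrix(TRUE, 8, 8)
  expect_equal(positive_tissue_fraction(v, v), 100)
  expect_equal(positive_tissue_fraction(matrix(FALSE, 8, 8), v), 0)
  cb <- outer(1:8, 1:8, function(r, c) (r + c) %% 2 == 0)
  expect_equal(positive_tissue_fraction(cb, v), 50)
  expect_error(positive_tissue_fraction(cb, matrix(FALSE, 8, 8)), "empty")

  ch <- matrix(3.5, 6, 6)
  expect_equal(mean_intensity(ch, matrix(TRUE, 6, 6)), 3.5)
  two <- matrix(c(rep(10, 18), rep(30, 18)), 6, 6)
  left <- matrix(rep(c(TRUE, FALSE), each = 18), 6, 6)
  expect_equal(mean_intensity(two, left), 10)
  # accumulation oracle: mean over viable = (sum tissue - sum excluded)/counts
  set.seed(42)
  img <- matrix(runif(36, 0, 100), 6, 6)
  viable <- matrix(runif(36) < 0.6, 6, 6); viable[1, 1] <- TRUE
  excl <- !viable
  expect_equal(mean_intensity(img, viable),
               (sum(img) - sum(img[excl])) / (36 - sum(excl)))
})

test_that("unperfused area follows the supply-radius rule exactly", {
  # everything within reach -> 0%
  H <- 64; W <- 64
  lab <- disk_label_map(H, W, list(c(32, 32)), 3)
  viable <- matrix(TRUE, H, W)
  expect_equal(as.numeric(unperfused_area_fraction(viable, lab, 1000, viable)), 0)

  # no perfused vessels -> all viable tissue unperfused
  none <- label_objects(matrix(FALSE, H, W), pixel_size_um = 0.75)
  tissue <- matrix(TRUE, H, W)
  half <- matrix(rep(c(TRUE, FALSE), each = H * W / 2), H, W)
  expect_equal(as.numeric(unperfused_area_fraction(half, none, 150, tissue)),
               100 * sum(half) / sum(tissue))

  # single perfused pixel at the center of a 400x400 um frame, radius 100 um:
  # matches a per-pixel distance oracle
  H <- 533  # ~400 um at 0.75 um/px
  m <- matrix(FALSE, H, H); m[267, 267] <- TRUE
  lab1 <- label_objects(m, 8L, 0.75)
  tissue <- matrix(TRUE, H, H)
  got <- as.numeric(unperfused_area_fraction(tissue, lab1, 100, tissue))
  rr <- matrix(seq_len(H), H, H); cc <- t(rr)
  d_px <- sqrt((rr - 267)^2 + (cc - 267)^2) * 0.75
  expect_equal(got, 100 * sum(d_px > 100) / (H * H), tolerance = 1e-12)
  expect_equal(got, 100 * (1 - sum(d_px <= 100) / H^2), tolerance = 1e-12)
})

test_that("a larger supply radius never increases the unperfused fraction", {
  sim <- simulate_section(tiny_model(seed = 43), "mono2")
  gt <- sim$ground_truth
  keep <- unclass(gt$vessel_labels)
  keep[!(keep %in% gt$perfused_ids)] <- 0L
  skip_if(max(keep) == 0L)
  pv <- label_objects(keep > 0, 8L, 0.75)
  viable <- gt$tissue_mask & !gt$necrosis_mask
  fr <- vapply(c(30, 60, 90, 120), function(r) {
    as.numeric(unperfused_area_fraction(viable, pv, r, gt$tissue_mask))
  }, numeric(1))
  expect_true(all(diff(fr) <= 0))
})

test_that("necrotic fraction and caliper volume are computed as stated", {
  tissue <- matrix(TRUE, 10, 10)
  expect_equal(necrotic_area_fraction(list(), tissue), 0)
  all_nec <- list(exclusion_roi(tissue, "necrosis"))
  expect_equal(necrotic_area_fraction(all_nec, tissue), 100)

  # generator hits its necrosis target within +/- 1%
  sim <- simulate_section(tiny_model(seed = 44, necrosis_fraction = 0.2), "nec")
  gt <- sim$ground_truth
  meas <- necrotic_area_fraction(list(exclusion_roi(gt$necrosis_mask, "necrosis")),
                                 gt$tissue_mask)
  expect_lt(abs(meas - 20), 1)

  expect_equal(tumor_volume(1, 1, 1), pi / 6)
  expect_equal(tumor_volume(4, 0, 9), 0)
  # ~150 mm3 at the study's dosing trigger size
  expect_equal(tumor_volume(6.2, 6.2, 7.5), pi / 6 * 6.2 * 6.2 * 7.5)
  expect_equal(round(tumor_volume(6.2, 6.2, 7.5), 2), 150.95)
  expect_error(tumor_volume(-1, 2, 3), "non-negative")
})

test_that("section metrics recover ground truth and stay deterministic", {
  m <- tiny_model(seed = 45, noise_sd = 0)
  sim <- simulate_section(m, "gt0")
  gt <- sim$ground_truth
  rois <- list(exclusion_roi(gt$necrosis_mask, "necrosis"))
  sm <- compute_section_metrics(sim$stack, default_config(), rois)
  expect_equal(sm$perfused_vessel_fraction, gt$true_p_perfused)
  expect_identical(sm$n_vessels, as.integer(m$n_vessels))
  sm2 <- compute_section_metrics(sim$stack, default_config(), rois)
  expect_identical(as.data.frame(sm), as.data.frame(sm2))

  # area conservation: necrotic + viable + artifact-excluded = whole tissue
  masks <- attr(sm, "masks")
  expect_identical(sum(masks$necrosis & masks$tissue) + sum(masks$viable) +
                     sum(masks$artifact & masks$tissue & !masks$necrosis),
                   sum(masks$tissue))
  expect_equal(sm$necrotic_area_pct +
                 100 * sum(masks$viable) / sum(masks$tissue), 100)
})

test_that("channels absent from a staining group yield NA sentinels", {
  m <- tiny_model(seed = 46, staining_group = "group2")
  sim <- simulate_section(m, "g2")
  sm <- compute_section_metrics(sim$stack)
  expect_true(is.na(sm$brdu_positive_tissue_pct))
  expect_true(is.na(sm$mean_pimonidazole_intensity))
  expect_false(is.na(sm$hif_positive_tissue_pct))
})
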