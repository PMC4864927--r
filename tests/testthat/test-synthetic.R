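test_that("degenerate perfusion probabilities behave as expected", {
  sim1 <- simulate_section(tiny_model(seed = 61, p_perfused = 1), "all")
  gt1 <- sim1$ground_truth
  expect_identical(gt1$perfused_ids, seq_len(40L))
  expect_equal(gt1$true_p_perfused, 1)
  res <- vessel_perfusion_fraction(
    gt1$vessel_labels, sim1$stack$channels$DiOC7 >= 250)
  expect_equal(res$fraction, 1)

  sim0 <- simulate_section(tiny_model(seed = 62, p_perfused = 0, noise_sd = 0),
                           "none")
  gt0 <- sim0$ground_truth
  expect_length(gt0$perfused_ids, 0)
  # DiOC7 contains nothing but (zero) noise
  expect_true(all(sim0$stack$channels$DiOC7 == 0))
  res0 <- vessel_perfusion_fraction(
    gt0$vessel_labels, sim0$stack$channels$DiOC7 >= 250)
  expect_equal(res0$fraction, 0)
})

test_that("identical models give pixel-identical output", {
  m <- tiny_model(seed = 63)
  a <- simulate_section(m, "a")
  b <- simulate_section(m, "a")
  expect_identical(a$stack$channels, b$stack$channels)
  expect_identical(unclass(a$ground_truth$vessel_labels),
                   unclass(b$ground_truth$vessel_labels))
  expect_identical(a$ground_truth$perfused_ids, b$ground_truth$perfused_ids)
})

test_that("perfusion flags replay from the seeded stream", {
  m <- tiny_model(seed = 64, n_vessels = 200, p_perfused = 0.25,
                  height_px = 480, width_px = 480)
  sim <- simulate_section(m, "replay")
  replay <- withr::with_seed(64, rbinom(200, 1, 0.25) == 1,
                             .rng_kind = "Mersenne-Twister",
                             .rng_normal_kind = "Inversion",
                             .rng_sample_kind = "Rejection")
  expect_identical(length(sim$ground_truth$perfused_ids), sum(replay))
  expect_equal(sim$ground_truth$true_p_perfused, mean(replay))
})

test_that("thresholding the noiseless DiOC7 field recovers the perfused set", {
  sim <- simulate_section(tiny_model(seed = 65, noise_sd = 0), "rec")
  gt <- sim$ground_truth
  dioc <- sim$stack$channels$DiOC7 > 0
  res <- vessel_perfusion_fraction(gt$vessel_labels, dioc)
  expect_identical(res$records$vessel_id[res$records$perfused],
                   gt$perfused_ids)
  expect_true(all(res$records$dioc7_coverage[gt$perfused_ids] == 1))
  expect_true(all(res$records$dioc7_coverage[-gt$perfused_ids] == 0))
})

test_that("ground truth is consistent with the emitted channels", {
  sim <- simulate_section(tiny_model(seed = 66, noise_sd = 0), "con")
  gt <- sim$ground_truth
  ch <- sim$stack$channels
  # CD31 = vessels + specks, nothing else
  expect_identical(ch$CD31 > 0,
                   (unclass(gt$vessel_labels) > 0L) | gt$speck_mask)
  # specks are all strictly below 9 um2
  if (any(gt$speck_mask)) {
    sl <- label_objects(gt$speck_mask, 8L, 0.75)
    areas <- tabulate(sl[sl > 0L]) * 0.75^2
    expect_true(all(areas < 9))
  }
  # Hoechst marks tissue, weakly in necrosis
  expect_identical(ch$Hoechst > 0, gt$tissue_mask)
  expect_true(all(ch$Hoechst[gt$necrosis_mask] <
                    max(ch$Hoechst[gt$tissue_mask & !gt$necrosis_mask])))
  # HIF positives lie beyond the distance cutoff in viable tissue
  hif_pos <- ch$HIF1a > 0
  expect_true(all(gt$distance_um[hif_pos] > 100))
  expect_false(any(hif_pos & gt$necrosis_mask))
})

test_that("shell means track the configured sigmoid within noise tolerance", {
  m <- tiny_model(seed = 67, height_px = 384, width_px = 384, n_vessels = 100)
  sim <- simulate_section(m, "shell")
  gt <- sim$ground_truth
  viable <- gt$tissue_mask & !gt$necrosis_mask
  sel <- viable & (gt$distance_um < 80)
  shell <- floor(gt$distance_um[sel] / 10)  # 10-um shells
  vals <- sim$stack$channels$pimonidazole[sel]
  truth <- hypoxia_sigmoid(gt$distance_um[sel], gt$profile_params)
  for (s in unique(shell)) {
    n <- sum(shell == s)
    if (n < 500) next
    expect_lt(abs(mean(vals[shell == s]) - mean(truth[shell == s])),
              4 * m$noise_sd / sqrt(n) + 0.5)
  }
})

test_that("cohorts have the right size, determinism and perfusion regime", {
  models <- list(control = tiny_model(p_perfused = 0.21),
                 treated = tiny_model(p_perfused = 0.28))
  co <- simulate_cohort(models, n_per_arm = 6, master_seed = 99)
  expect_length(co$stacks, 12)
  expect_identical(nrow(co$manifest), 12L)
  expect_identical(sum(co$manifest$arm == "control"), 6L)

  co2 <- simulate_cohort(models, n_per_arm = 6, master_seed = 99)
  expect_identical(lapply(co$stacks, `[[`, "channels"),
                   lapply(co2$stacks, `[[`, "channels"))

  # per-arm realized fractions sit within 3 SE of nominal (binomial, 40 vessels)
  realized <- vapply(co$ground_truths, `[[`, numeric(1), "true_p_perfused")
  arm <- co$manifest$arm
  for (a in names(models)) {
    p <- models[[a]]$p_perfused
    se <- sqrt(p * (1 - p) / 40) / sqrt(6)
    expect_lt(abs(mean(realized[arm == a]) - p), 3 * se)
  }

  expect_error(simulate_cohort(list(tiny_model(), tiny_model())), "named")
})

test_that("ground truth round-trips through disk", {
  sim <- simulate_section(tiny_model(seed = 68), "rt")
  gt <- sim$ground_truth
  dir <- tempfile("gt")
  write_ground_truth(gt, dir)
  back <- read_ground_truth(dir)
  expect_identical(back$perfused_ids, gt$perfused_ids)
  expect_equal(unclass(back$vessel_labels), unclass(gt$vessel_labels),
               ignore_attr = TRUE)
  expect_identical(back$necrosis_mask, gt$necrosis_mask)
  expect_identical(back$tissue_mask, gt$tissue_mask)
  expect_identical(back$true_p_perfused, gt$true_p_perfused)
  expect_identical(back$profile_params, gt$profile_params)

  # empty necrosis round-trips as empty
  sim2 <- simulate_section(tiny_model(seed = 69, necrosis_fraction = 0), "rt2")
  dir2 <- tempfile("gt")
  write_ground_truth(sim2$ground_truth, dir2)
  expect_false(any(read_ground_truth(dir2)$necrosis_mask))
})

test_that("model invariants are enforced", {
  expect_error(tiny_model(p_perfused = 1.2))
  expect_error(tiny_model(necrosis_fraction = 1))
  expect_error(tiny_model(hypoxia_profile = list(I0 = 10, Imax = 5, d0 = 1, s = 1)))
  # unplaceable vessel demand fails with a clear error
  expect_error(
    simulate_section(section_model(height_px = 64, width_px = 64,
                                   n_vessels = 500, vessel_radius_um = c(3, 3),
                                   necrosis_fraction = 0)),
    "could not place")
})
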