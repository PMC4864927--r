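COHORT_METRICS <- c("perfused_vessel_fraction", "hif_positive_tissue_pct",
                    "brdu_positive_tissue_pct", "mean_pimonidazole_intensity",
                    "mean_hif_intensity", "unperfused_area_pct",
                    "necrotic_area_pct")

#' Read an exclusion ROI mask from a TIFF file
#'
#' @param path Single-channel TIFF; nonzero pixels are excluded.
#' @param category `"necrosis"` or `"artifact"`.
#' @return An [exclusion_roi()].
#' @export
read_exclusion_roi <- function(path, category) {
  if (!file.exists(path)) stop("ROI file '", path, "' does not exist")
  m <- tiff::readTIFF(path)
  exclusion_roi(m > 0, category)
}

#' Run the full cohort analysis pipeline
#'
#' Reads (or simulates) a cohort of sections, quantifies each section,
#' profiles marker intensity against vessel distance, summarizes per
#' arm, runs one-way ANOVA with Bonferroni post-tests, and writes CSVs,
#' plots and a run log to the output directory. Identical configuration
#' and master seed give byte-identical CSV outputs.
#'
#' @param config Path to a YAML configuration file, or an equivalent
#'   named list. Keys: `output_dir`; either `simulate` (with `arms`,
#'   optional `model` overrides, `n_per_arm`) plus `master_seed`, or
#'   `manifest` (cohort CSV; per-section ROI files under `rois`);
#'   optional `analysis` overrides of [default_config()]; optional
#'   `anova` (`alpha`, `comparisons`, `metrics`); and
#'   `profile_channel` (default `"pimonidazole"`).
#' @return Invisibly, a list with `metrics`, `vessels`, `profiles`,
#'   `summaries`, `anova` and the output file paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("[stage config] file '", config, "' not found")
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  out_dir <- config$output_dir %||% stop("[stage config] output_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  log_lines <- character(0)
  logit <- function(...) {
    line <- paste0(...)
    log_lines <<- c(log_lines, line)
    message(line)
  }

  acfg <- do.call(default_config, as.list(config$analysis %||% list()))
  logit("tumormapr pipeline")
  logit("stage order: exclusions -> threshold -> label -> artifact_filter -> metrics")
  logit("thresholds: ", paste(names(acfg$thresholds), unlist(acfg$thresholds),
                              sep = "=", collapse = ", "))
  logit("boundary rules: positive iff intensity >= threshold; ",
        "perfused iff coverage >= ", acfg$coverage_cutoff,
        "; artifacts: area < ", acfg$min_area_um2, " um2 removed")
  logit("unperfused criterion: distance to perfused vessel > ",
        acfg$supply_radius_um, " um (rule-based stand-in)")
  logit("intensity mode: ", acfg$intensity_mode)

  sections <- list()   # each: list(stack=, rois=)
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    master_seed <- config$master_seed %||% 1L
    logit("mode: simulate; master_seed = ", master_seed)
    if (is.null(sim$arms) || !length(sim$arms)) {
      stop("[stage simulate] simulate.arms is required")
    }
    models <- lapply(names(sim$arms), function(a) {
      args <- utils::modifyList(as.list(sim$model %||% list()),
                                as.list(sim$arms[[a]]) %||% list())
      args$arm <- a
      do.call(section_model, args)
    })
    names(models) <- names(sim$arms)
    co <- simulate_cohort(models, n_per_arm = sim$n_per_arm %||% 6L,
                          master_seed = master_seed)
    for (i in seq_along(co$stacks)) {
      # ground-truth necrosis stands in for the manual necrosis annotation
      rois <- list(exclusion_roi(co$ground_truths[[i]]$necrosis_mask, "necrosis"))
      sections[[i]] <- list(stack = co$stacks[[i]], rois = rois)
    }
    logit("simulated ", length(sections), " sections (",
          length(models), " arms x ", sim$n_per_arm %||% 6L, ")")
  } else if (!is.null(config$manifest)) {
    logit("mode: manifest; file = ", config$manifest)
    man <- tryCatch(read_manifest(config$manifest), error = function(e) {
      stop("[stage manifest] ", conditionMessage(e), call. = FALSE)
    })
    for (i in seq_len(nrow(man))) {
      stack <- tryCatch(read_stack(man$path[i], man[i, ]), error = function(e) {
        stop("[stage read] section '", man$section_id[i], "': ",
             conditionMessage(e), call. = FALSE)
      })
      rois <- list()
      rcfg <- config$rois[[man$section_id[i]]]
      for (rc in rcfg) {
        rois <- c(rois, list(read_exclusion_roi(rc$path, rc$category)))
      }
      sections[[i]] <- list(stack = stack, rois = rois)
    }
  } else {
    stop("[stage config] either 'simulate' or 'manifest' must be given")
  }

  profile_channel <- config$profile_channel %||% "pimonidazole"
  metrics <- list(); vessels <- list(); profiles <- list()
  for (i in seq_along(sections)) {
    st <- sections[[i]]$stack
    sm <- compute_section_metrics(st, acfg, sections[[i]]$rois)
    metrics[[i]] <- sm
    vessels[[i]] <- attr(sm, "vessels")
    masks <- attr(sm, "masks")
    if (profile_channel %in% names(st$channels) &&
        max(masks$cd31_labels, 0L) > 0L) {
      dmap <- distance_to_nearest_vessel(masks$cd31_labels, "all")
      pr <- intensity_distance_profile(dmap, st$channels[[profile_channel]],
                                       masks$viable, acfg$bin_width_um,
                                       acfg$max_distance_um)
      pr <- cbind(section_id = st$section_id, arm = st$arm,
                  as.data.frame(pr))
      profiles[[length(profiles) + 1L]] <- pr
    }
    logit("section ", st$section_id, ": ", sm$n_vessels, " vessels, ",
          "perfused fraction ", format(sm$perfused_vessel_fraction, digits = 4))
  }
  metrics <- do.call(rbind, metrics)
  rownames(metrics) <- NULL
  vessels <- do.call(rbind, vessels)
  profiles <- if (length(profiles)) do.call(rbind, profiles) else NULL

  acv <- config$anova %||% list()
  alpha <- acv$alpha %||% 0.05
  comparisons <- acv$comparisons %||% "all_pairwise"
  wanted <- unlist(acv$metrics %||% COHORT_METRICS)
  summaries <- list(); anova_rows <- list(); pairwise_rows <- list()
  for (met in wanted) {
    x <- metrics[[met]]
    arms_ok <- names(which(tapply(!is.na(x), metrics$arm, sum) >= 2))
    if (length(arms_ok) < 2) {
      logit("ANOVA skipped for ", met, ": fewer than 2 arms with n >= 2")
      next
    }
    su <- summarize_groups(metrics[metrics$arm %in% arms_ok, ], met)
    summaries[[met]] <- cbind(metric = met, su)
    grp <- split(x[metrics$arm %in% arms_ok], metrics$arm[metrics$arm %in% arms_ok])
    res <- anova_bonferroni(grp, alpha = alpha, comparisons = comparisons,
                            metric = met)
    anova_rows[[met]] <- data.frame(metric = met, F = res$F,
                                    df_between = res$df_between,
                                    df_within = res$df_within,
                                    p_value = res$p_value)
    pairwise_rows[[met]] <- cbind(metric = met, res$pairwise)
  }
  summaries <- if (length(summaries)) do.call(rbind, summaries) else NULL
  anova_tab <- if (length(anova_rows)) do.call(rbind, anova_rows) else NULL
  pairwise_tab <- if (length(pairwise_rows)) do.call(rbind, pairwise_rows) else NULL

  paths <- list(
    metrics = file.path(out_dir, "section_metrics.csv"),
    vessels = file.path(out_dir, "vessel_records.csv"),
    profiles = file.path(out_dir, "distance_profiles.csv"),
    summaries = file.path(out_dir, "group_summary.csv"),
    anova = file.path(out_dir, "anova_tests.csv"),
    pairwise = file.path(out_dir, "anova_pairwise.csv"),
    plots = file.path(out_dir, "plots.pdf"),
    log = file.path(out_dir, "run_log.txt")
  )
  utils::write.csv(metrics, paths$metrics, row.names = FALSE)
  utils::write.csv(vessels, paths$vessels, row.names = FALSE)
  if (!is.null(profiles)) utils::write.csv(profiles, paths$profiles, row.names = FALSE)
  if (!is.null(summaries)) utils::write.csv(summaries, paths$summaries, row.names = FALSE)
  if (!is.null(anova_tab)) utils::write.csv(anova_tab, paths$anova, row.names = FALSE)
  if (!is.null(pairwise_tab)) utils::write.csv(pairwise_tab, paths$pairwise,
                                               row.names = FALSE)

  tryCatch(write_pipeline_plots(metrics, summaries, profiles, paths$plots),
           error = function(e) logit("plotting skipped: ", conditionMessage(e)))
  writeLines(log_lines, paths$log)
  invisible(list(metrics = metrics, vessels = vessels, profiles = profiles,
                 summaries = summaries, anova = anova_tab,
                 pairwise = pairwise_tab, paths = paths))
}

write_pipeline_plots <- function(metrics, summaries, profiles, path) {
  grDevices::pdf(path, width = 7, height = 5)
  on.exit(grDevices::dev.off())
  if (!is.null(summaries)) {
    for (met in unique(summaries$metric)) {
      su <- summaries[summaries$metric == met, ]
      su$arm <- factor(su$arm, levels = unique(su$arm))
      p <- ggplot2::ggplot(su, ggplot2::aes(x = arm, y = mean)) +
        ggplot2::geom_col(fill = "grey60", color = "black", width = 0.6) +
        ggplot2::geom_errorbar(
          ggplot2::aes(ymin = mean - ifelse(is.na(sd), 0, sd),
                       ymax = mean + ifelse(is.na(sd), 0, sd)),
          width = 0.2) +
        ggplot2::labs(title = met, x = NULL,
                      y = paste0(met, " (mean ± SD)")) +
        ggplot2::theme_classic()
      print(p)
    }
  }
  if (!is.null(profiles)) {
    by_arm <- split(seq_len(nrow(profiles)), profiles$arm)
    pooled <- do.call(rbind, lapply(names(by_arm), function(a) {
      sub <- profiles[by_arm[[a]], ]
      pl <- pool_profiles(lapply(split(sub, sub$section_id), function(s) {
        structure(s[, c("bin_left_um", "bin_right_um", "mean_intensity",
                        "sd_intensity", "pixel_count", "mean_distance_um")],
                  class = c("distance_profile", "data.frame"))
      }))
      cbind(arm = a, pl)
    }))
    pooled <- pooled[pooled$pixel_count > 0, ]
    p <- ggplot2::ggplot(pooled,
                         ggplot2::aes(x = (bin_left_um + bin_right_um) / 2,
                                      y = mean_intensity,
                                      color = arm)) +
      ggplot2::geom_line() +
      ggplot2::labs(title = "Marker intensity vs distance to nearest vessel",
                    x = "distance to nearest CD31 object (um)",
                    y = "mean intensity") +
      ggplot2::theme_classic()
    print(p)
  }
  invisible(path)
}
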