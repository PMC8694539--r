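## End-to-end orchestration: simulate -> preprocess -> features -> screen ->
## classify, as a single seeded run with persisted intermediates, plus the
## plain-text I/O used for segments and manifests.
##
## The package is function-driven: these R entry points (rather than a shell
## wrapper) are the command surface, in keeping with how analysis packages
## in this area are used from scripts and vignettes.

#' Full-run configuration
#'
#' One global seed governs every stage; per-stage seeds are derived from it
#' with a fixed counter scheme so stages can be re-run in isolation.
#'
#' @param cohort An [cohort_config()].
#' @param preprocess An [preprocess_config()].
#' @param alpha Screen significance level.
#' @param protocol An [eval_protocol()].
#' @param tier `"signal"` (full chain) or `"feature"` (skip straight to the
#'   statistical stages using the feature-level generator).
#' @param seed Global integer seed.
#' @return An object of class `hrca_run_config`.
#' @export
run_config <- function(cohort = cohort_config(),
                       preprocess = preprocess_config(),
                       alpha = 0.05,
                       protocol = eval_protocol(),
                       tier = c("signal", "feature"),
                       seed = 1L) {
  tier <- match.arg(tier)
  structure(list(cohort = cohort, preprocess = preprocess, alpha = alpha,
                 protocol = protocol, tier = tier, seed = seed),
            class = "hrca_run_config")
}

#' Summarize segment durations by material
#'
#' Per-material mean and SD of segment duration in seconds, plus a two-sided
#' Welch test p-value for the water-vs-barium duration difference. With a
#' single segment in a group the SD is reported as `NA`; the Welch test
#' requires two segments per group.
#'
#' @param manifest Manifest data frame (0-based half-open sample indices).
#' @return Data frame with columns `material`, `n`, `mean_s`, `sd_s`;
#'   attribute `welch_p` carries the test p-value.
#' @export
summarize_durations <- function(manifest) {
  if (is.null(manifest) || nrow(manifest) == 0L) stopf("empty manifest")
  dur <- (manifest$offset_sample - manifest$onset_sample) / manifest$fs
  mats <- c("barium", "water")
  if (!all(mats %in% manifest$material)) {
    stopf("both materials must be present in the manifest")
  }
  out <- do.call(rbind, lapply(mats, function(m) {
    d <- dur[manifest$material == m]
    data.frame(material = m, n = length(d), mean_s = mean(d),
               sd_s = if (length(d) > 1L) sd(d) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  wp <- NA_real_
  db <- dur[manifest$material == "barium"]
  dw <- dur[manifest$material == "water"]
  if (length(db) > 1L && length(dw) > 1L && (var(db) > 0 || var(dw) > 0)) {
    wp <- t.test(dw, db)$p.value
  }
  attr(out, "welch_p") <- wp
  out
}

## Per-material mean and SD of every feature column (descriptive table).
summarize_features <- function(table) {
  feat_cols <- setdiff(names(table), KEY_COLUMNS)
  do.call(rbind, lapply(feat_cols, function(fc) {
    row <- data.frame(feature = fc, stringsAsFactors = FALSE)
    for (m in c("barium", "water")) {
      v <- table[[fc]][table$material == m]
      row[[paste0("mean_", m)]] <- mean(v, na.rm = TRUE)
      row[[paste0("sd_", m)]] <- sd(v, na.rm = TRUE)
    }
    row
  }))
}

#' Run the complete pipeline
#'
#' Signal tier: generate the synthetic cohort, fit per-participant baseline
#' AR models, run the conditioning chain on every segment, extract the
#' 36-feature table, screen it with the per-feature mixed models, and run
#' the repeated-holdout classifier battery with and without PCA. Feature
#' tier: generate the feature table directly and run the statistical stages.
#' All intermediates are persisted under `output_dir` when given (manifest
#' and features as CSV, screen and report as JSON, segments as per-segment
#' CSV).
#'
#' @param config An [run_config()].
#' @param output_dir Optional directory for persisted artifacts.
#' @param write_segments_files Also persist every processed segment (can be
#'   large); default `FALSE`.
#' @return An object of class `hrca_report`.
#' @export
run_pipeline <- function(config = run_config(), output_dir = NULL,
                         write_segments_files = FALSE) {
  stopifnot(inherits(config, "hrca_run_config"))
  cohort_cfg <- config$cohort
  cohort_cfg$seed <- derive_seed(config$seed, 1L)
  protocol <- config$protocol
  protocol$seed <- derive_seed(config$seed, 4L)

  manifest <- NULL
  duration_summary <- NULL
  if (config$tier == "signal") {
    cohort <- generate_cohort(cohort_cfg)
    manifest <- cohort$manifest
    duration_summary <- summarize_durations(manifest)
    segments <- vector("list", length(cohort$segments))
    for (i in seq_along(cohort$segments)) {
      seg <- cohort$segments[[i]]
      models <- fit_baseline_models(cohort$baselines[[seg$participant_id]],
                                    config$preprocess)
      segments[[i]] <- preprocess_segment(seg, config$preprocess, models)
    }
    feat_table <- extract_feature_table(segments)
  } else {
    segments <- NULL
    feat_table <- generate_feature_table(cohort_cfg)
  }

  screen <- run_feature_screen(feat_table, config$alpha)
  protocol_raw <- protocol
  protocol_raw$pca_components <- NULL
  performance_pca <- holdout_evaluate(feat_table, protocol)
  protocol_raw$seed <- derive_seed(config$seed, 5L)
  performance_raw <- holdout_evaluate(feat_table, protocol_raw)

  counts <- table(factor(feat_table$material, levels = c("barium", "water")))
  report <- structure(
    list(cohort_summary = list(
           n_swallows = nrow(feat_table),
           n_barium = as.integer(counts[["barium"]]),
           n_water = as.integer(counts[["water"]]),
           n_participants = length(unique(feat_table$participant_id)),
           durations = duration_summary),
         feature_summary = summarize_features(feat_table),
         screen = screen,
         performance = list(raw = performance_raw, pca = performance_pca),
         provenance = list(seed = config$seed, tier = config$tier,
                           alpha = config$alpha,
                           package_version = as.character(utils::packageVersion("hrcascreen")))),
    class = "hrca_report"
  )

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(manifest)) write_manifest(manifest, file.path(output_dir, "manifest.csv"))
    if (write_segments_files && !is.null(segments)) {
      write_segments(segments, file.path(output_dir, "segments"))
    }
    write.csv(feat_table, file.path(output_dir, "features.csv"), row.names = FALSE)
    write.csv(screen$per_feature, file.path(output_dir, "screen.csv"),
              row.names = FALSE)
    write_report(report, file.path(output_dir, "report.json"))
  }
  report
}

#' @export
print.hrca_report <- function(x, ...) {
  cs <- x$cohort_summary
  cat(sprintf("<hrca_report> %d swallows (%d barium, %d water) from %d participants\n",
              cs$n_swallows, cs$n_barium, cs$n_water, cs$n_participants))
  if (!is.null(cs$durations)) {
    print(cs$durations, row.names = FALSE, digits = 3)
  }
  print(x$screen)
  cat("-- raw features --\n")
  print(x$performance$raw)
  cat("-- PCA space --\n")
  print(x$performance$pca)
  invisible(x)
}

## ---- plain-text persistence -------------------------------------------

#' Write / read a segment manifest CSV
#'
#' Columns: participant_id, material, swallow_index, file, onset_sample,
#' offset_sample, true_onset_sample, true_offset_sample, fs; sample indices
#' are 0-based half-open.
#'
#' @param manifest Manifest data frame.
#' @param path CSV path.
#' @return `read_manifest` returns the manifest data frame.
#' @export
write_manifest <- function(manifest, path) {
  write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Persist segments as per-segment CSV files
#'
#' Each segment is written as a four-column CSV (MIC, AP, SI, ML), one row
#' per sample, under the file name recorded in the manifest
#' (`<participant>_<material>_<index>.csv`).
#'
#' @param segments List of `hrca_segment`s.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_segments <- function(segments, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(segments, function(seg) {
    path <- file.path(dir, sprintf("%s_%s_%02d.csv", seg$participant_id,
                                   seg$material, seg$swallow_index))
    data.table::fwrite(as.data.frame(seg$channels), path)
    path
  }, character(1))
  invisible(paths)
}

#' Read one segment back from a manifest row
#'
#' @param manifest_row One-row slice of a manifest data frame.
#' @param dir Directory holding the segment CSV files.
#' @return An `hrca_segment`.
#' @export
read_segment <- function(manifest_row, dir) {
  dat <- data.table::fread(file.path(dir, manifest_row$file), data.table = FALSE)
  new_segment(manifest_row$participant_id, manifest_row$material,
              manifest_row$swallow_index,
              as.list(dat[HRCA_CHANNELS]), manifest_row$fs,
              manifest_row$true_onset_sample, manifest_row$true_offset_sample)
}

#' Write a pipeline report as JSON
#'
#' @param report An `hrca_report`.
#' @param path Output JSON path.
#' @export
write_report <- function(report, path) {
  x <- list(
    cohort_summary = report$cohort_summary,
    feature_summary = report$feature_summary,
    screen = list(per_feature = report$screen$per_feature,
                  n_rejected = report$screen$n_rejected,
                  n_total = report$screen$n_total,
                  alpha = report$screen$alpha),
    performance = lapply(report$performance, function(p) {
      list(results = p$results, space = p$space,
           pca_components = p$pca_components,
           mean_explained_variance = p$mean_explained_variance,
           n_iterations = p$n_iterations, n_redrawn = p$n_redrawn,
           n_dropped_rows = p$n_dropped_rows)
    }),
    provenance = report$provenance
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(path)
}
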