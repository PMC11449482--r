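# End-to-end orchestration: simulate/load -> preprocess -> segment ->
# measure -> spatial, with a run directory, log, and machine-readable
# reports.  Every number in the reports is recomputable from the persisted
# intermediates.

log_line <- function(log, fmt, ...) {
  msg <- sprintf(fmt, ...)
  writeLines(msg, log$con)
  message(msg)
  invisible(NULL)
}

#' Run the full analysis pipeline
#'
#' Takes either a synthetic scene (rendered internally) or a real stack on
#' disk, applies the four processing steps (top-hat background subtraction,
#' median filtering, 3-D iterative thresholding with MSER selection,
#' morphological opening), measures per-cell 720/670 ratios, applies the
#' ratio exclusion, and runs the neighbour-correlation analysis for
#' k = 2, 5, 10 and the 20 um radius.  All artifacts are written under
#' `out_dir`: resolved config (with hash and seed), ground truth (if
#' simulated), preprocessed stack, label volume, CellRecords CSV,
#' correlation JSON + scatter CSVs, pseudo-colour PNG, and a log with
#' object counts at every filter stage.
#'
#' @param config A [pipeline_config()].
#' @param scene A `fret_scene` to simulate from (exactly one of `scene`,
#'   `stack_path`).
#' @param stack_path Path to a two-channel TIFF stack to analyse.
#' @param optics [optics_params()] used when rendering a scene.
#' @param out_dir Run directory (created; must not already contain a run).
#' @param write_stacks If `FALSE`, skip writing the preprocessed stack and
#'   label TIFFs (the CSV/JSON reports are always written).
#' @return An object of class `fret_run`: the run directory, records,
#'   correlation results and stage counts.
#' @export
run_pipeline <- function(config = pipeline_config(), scene = NULL,
                         stack_path = NULL, optics = optics_params(),
                         out_dir, write_stacks = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(scene) == is.null(stack_path)) {
    stop("provide exactly one of `scene` or `stack_path`")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- list(con = file(file.path(out_dir, "log.txt"), open = "wt"))
  on.exit(close(log$con), add = TRUE)

  cfg <- unclass(config)
  cfg$config_hash <- config_hash(unclass(config))
  jsonlite::write_json(cfg, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)

  stage <- "simulate/load"
  res <- try({
    if (!is.null(scene)) {
      log_line(log, "simulate: %d cells, %d distractors, seed %d",
               nrow(scene$cells), nrow(scene$distractors), config$seed)
      write_scene(scene, file.path(out_dir, "scene_truth.json"))
      stack <- render_stack(scene, optics)
    } else {
      log_line(log, "load: %s", stack_path)
      stack <- read_stack(stack_path)
    }

    stage <- "preprocess"
    log_line(log, "step 1: top-hat background subtraction (r = %d)",
             config$tophat_radius_vox)
    pre <- tophat_subtract(stack, config$tophat_radius_vox)
    log_line(log, "step 2: median filtering (r = %d)",
             config$median_radius_vox)
    pre <- median_filter(pre, config$median_radius_vox)
    if (write_stacks) {
      write_stack(pre, file.path(out_dir, "preprocessed.tif"))
    }

    stage <- "segment"
    log_line(log, "step 3: 3D iterative thresholding, %d levels, MSER band [%d, %d]",
             config$threshold_levels, config$volume_min_vox,
             config$volume_max_vox)
    v <- channel_volume(pre, 1) + channel_volume(pre, 2)
    tree <- build_component_tree(v, levels = config$threshold_levels,
                                 delta_levels = config$delta_levels,
                                 volume_min_vox = config$volume_min_vox,
                                 volume_max_vox = config$volume_max_vox)
    labels0 <- select_stable_regions(tree)
    n_initial <- max(labels0)
    log_line(log, "  ROIs after MSER selection: %d", n_initial)
    log_line(log, "step 4: morphological opening (r = %d)",
             config$opening_radius_vox)
    labels <- opening_filter(labels0, radius_vox = config$opening_radius_vox,
                             volume_min_vox = config$volume_min_vox)
    removed <- attr(labels, "removed")
    log_line(log, "  ROIs removed by opening: %d", nrow(removed))
    if (write_stacks) {
      write_labels(labels, stack$voxel_size_um,
                   file.path(out_dir, "labels.tif"))
    }

    stage <- "measure"
    rec <- measure_rois(pre, labels)
    if (nrow(removed)) {
      # removed ROIs are reported (measured on their pre-opening masks)
      gl <- labels0
      gl[!(gl %in% removed$label)] <- 0L
      gone <- measure_rois(pre, gl)
      gone$excluded_reason <- "opening"
      rec <- rbind(rec, gone)
      rec <- rec[order(rec$label), , drop = FALSE]
    }
    if (config$exclude_border) {
      b <- rec$excluded_reason == "none" & rec$touches_border
      rec$excluded_reason[b] <- "border"
      log_line(log, "  ROIs excluded at border: %d", sum(b))
    }
    fl <- filter_by_ratio(rec, config$ratio_threshold)
    rec <- rbind(fl$retained, fl$excluded)
    rec <- rec[order(rec$label), , drop = FALSE]
    counts <- table(factor(rec$excluded_reason,
                           levels = c("none", "volume", "opening", "ratio",
                                      "border")))
    log_line(log, "measure: %d ROIs total; retained %d; excluded: opening %d, ratio %d, border %d",
             nrow(rec), counts[["none"]], counts[["opening"]],
             counts[["ratio"]], counts[["border"]])
    stopifnot(nrow(rec) == counts[["none"]] + sum(counts[-1]))
    write_records_table(rec, file.path(out_dir, "cell_records.csv"))

    stage <- "spatial"
    retained <- rec[rec$excluded_reason == "none", , drop = FALSE]
    specs <- list(neighborhood_spec("knn", k = 2),
                  neighborhood_spec("knn", k = 5),
                  neighborhood_spec("knn", k = 10),
                  neighborhood_spec("radius", radius_um = config$neighbor_radius_um))
    cors <- list()
    report <- list()
    for (sp in specs) {
      nm <- spec_label(sp)
      co <- tryCatch(correlate_with_neighbors(retained, sp,
                                              alpha = config$alpha),
                     error = function(e) e)
      if (inherits(co, "error")) {
        log_line(log, "spatial [%s]: skipped (%s)", nm, conditionMessage(co))
        report[[nm]] <- list(spec = unclass(sp), error = conditionMessage(co))
        next
      }
      cors[[nm]] <- co
      report[[nm]] <- list(spec = unclass(sp), r = co$r,
                           p_value = co$p_value, n = co$n,
                           significant = co$significant, alpha = co$alpha)
      write_records_scatter(co, file.path(out_dir,
                                          sprintf("scatter_%s.csv", nm)))
      log_line(log, "spatial [%s]: r = %.4f, p = %.3g, n = %d (%s)",
               nm, co$r, co$p_value, co$n,
               if (co$significant) "significant" else "n.s.")
    }
    primary <- sprintf("knn%d", config$neighbor_k)
    if (!is.null(cors[[primary]])) {
      pn <- permutation_null(retained,
                             neighborhood_spec("knn", k = config$neighbor_k),
                             n_perm = 999,
                             seed = stage_seeds(config$seed)[["permutation"]])
      report[[primary]]$p_permutation <- pn$p_empirical
      log_line(log, "spatial [%s]: permutation p = %.4g (999 permutations)",
               primary, pn$p_empirical)
    }
    report$seed <- config$seed
    report$config_hash <- cfg$config_hash
    jsonlite::write_json(report, file.path(out_dir, "spatial_report.json"),
                         auto_unbox = TRUE, digits = NA)

    if (nrow(retained) > 0) {
      render_pseudocolor(rec, labels, file.path(out_dir, "pseudocolor.png"))
    }
    list(dir = out_dir, records = rec, correlations = cors,
         counts = as.list(counts), config = config)
  }, silent = TRUE)
  if (inherits(res, "try-error")) {
    log_line(log, "FAILED at stage '%s': %s", stage,
             attr(res, "condition")$message)
    stop(sprintf("pipeline failed at stage '%s': %s (partial outputs in %s)",
                 stage, attr(res, "condition")$message, out_dir))
  }
  structure(res, class = "fret_run")
}

write_records_scatter <- function(co, path) {
  df <- co$table
  for (j in which(vapply(df, is.numeric, logical(1)))) {
    df[[j]] <- sprintf("%.17g", df[[j]])
  }
  write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.fret_run <- function(x, ...) {
  cat("fretseg pipeline run:", x$dir, "\n")
  cat(sprintf("  ROIs: %d total, %d retained\n", nrow(x$records),
              x$counts$none))
  for (nm in names(x$correlations)) {
    co <- x$correlations[[nm]]
    cat(sprintf("  %s: r = %.4f, p = %.3g, n = %d\n", nm, co$r, co$p_value,
                co$n))
  }
  invisible(x)
}

#' Compare two completed runs
#'
#' Side-by-side report of two run directories (e.g. pre- and post-drug):
#' mean retained 720/670 ratio in each run, the relative difference in
#' percent (relative to run A), both runs' correlation results, and any
#' configuration mismatches.
#'
#' @param run_a,run_b Run directories as produced by [run_pipeline()] (or
#'   `fret_run` objects).
#' @return An object of class `fret_comparison`.
#' @export
compare_conditions <- function(run_a, run_b) {
  dir_a <- if (inherits(run_a, "fret_run")) run_a$dir else run_a
  dir_b <- if (inherits(run_b, "fret_run")) run_b$dir else run_b
  read_run <- function(d) {
    need <- file.path(d, c("cell_records.csv", "spatial_report.json",
                           "config.json"))
    miss <- need[!file.exists(need)]
    if (length(miss)) {
      stop("missing run artifact(s): ", paste(miss, collapse = ", "))
    }
    list(records = read_records_table(need[1]),
         spatial = jsonlite::read_json(need[2], simplifyVector = TRUE),
         config = jsonlite::read_json(need[3], simplifyVector = TRUE))
  }
  a <- read_run(dir_a)
  b <- read_run(dir_b)
  mean_ratio <- function(x) {
    mean(x$records$ratio_720_670[x$records$excluded_reason == "none"])
  }
  ma <- mean_ratio(a)
  mb <- mean_ratio(b)
  cmp_fields <- setdiff(names(a$config), c("seed", "config_hash"))
  mismatch <- cmp_fields[vapply(cmp_fields, function(f) {
    !identical(a$config[[f]], b$config[[f]])
  }, logical(1))]
  spat <- function(x) {
    x$spatial[setdiff(names(x$spatial), c("seed", "config_hash"))]
  }
  structure(list(dir_a = dir_a, dir_b = dir_b,
                 mean_ratio_a = ma, mean_ratio_b = mb,
                 relative_difference_pct = 100 * (ma - mb) / ma,
                 correlations_a = spat(a), correlations_b = spat(b),
                 config_mismatch = mismatch),
            class = "fret_comparison")
}

#' @export
print.fret_comparison <- function(x, ...) {
  cat("Condition comparison\n")
  cat(sprintf("  mean retained 720/670 ratio: A = %.4f, B = %.4f\n",
              x$mean_ratio_a, x$mean_ratio_b))
  cat(sprintf("  relative difference: %.2f%% (relative to A)\n",
              x$relative_difference_pct))
  for (nm in intersect(names(x$correlations_a), names(x$correlations_b))) {
    ca <- x$correlations_a[[nm]]; cb <- x$correlations_b[[nm]]
    if (is.null(ca$r) || is.null(cb$r)) next
    cat(sprintf("  %s: A r = %.3f (p = %.2g), B r = %.3f (p = %.2g)\n",
                nm, ca$r, ca$p_value, cb$r, cb$p_value))
  }
  if (length(x$config_mismatch)) {
    cat("  CONFIG MISMATCH in:", paste(x$config_mismatch, collapse = ", "),
        "\n")
  }
  invisible(x)
}
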