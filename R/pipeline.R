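#' Pipeline configuration
#'
#' Gathers every tunable of an end-to-end run. Fully serializable to YAML
#' ([write_pipeline_config()] / [read_pipeline_config()]); the resolved
#' configuration is echoed into the output directory of every run.
#'
#' @param input_dir Directory holding the input layout of
#'   [write_phantom()] (or equivalently organized real data).
#' @param output_dir Directory to write results into.
#' @param auc_mode `"analytic"` or `"numeric"` contrast AUC.
#' @param auc_range Integration window for numeric AUC, ppm.
#' @param contrast_pools Pools to quantify and map.
#' @param heatmap_pool Pool rendered as per-arm heatmaps.
#' @param b0_bound Maximum |B0| accepted, ppm.
#' @param posthoc_variant Variant of the treated-vs-untreated t-test.
#' @param paired Use paired t-tests for within-animal timepoint contrasts.
#' @param seed Seed recorded in the manifest (the analysis itself is
#'   deterministic; the seed feeds optional stochastic extensions such as
#'   multi-start fitting).
#' @param verbose Log stage progress.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir, output_dir,
                            auc_mode = c("analytic", "numeric"),
                            auc_range = c(-5, 5),
                            contrast_pools = c("water", "mt", "creatine",
                                               "glutamate", "noe"),
                            heatmap_pool = "glutamate",
                            b0_bound = 1.0,
                            posthoc_variant = c("pooled", "welch"),
                            paired = FALSE,
                            seed = 1L, verbose = TRUE) {
  structure(list(input_dir = input_dir, output_dir = output_dir,
                 auc_mode = match.arg(auc_mode),
                 auc_range = as.numeric(auc_range),
                 contrast_pools = contrast_pools,
                 heatmap_pool = heatmap_pool,
                 b0_bound = b0_bound,
                 posthoc_variant = match.arg(posthoc_variant),
                 paired = isTRUE(paired),
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param file YAML path.
#' @export
write_pipeline_config <- function(config, file) {
  yaml::write_yaml(unclass(config), file)
  invisible(file)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(file) {
  v <- yaml::read_yaml(file)
  do.call(pipeline_config, v)
}

#' Run the full quantification pipeline
#'
#' Stages: read and validate inputs; per subject, estimate the WASSR B0
#' map, re-reference the CEST stack, fit the five-pool model voxelwise
#' inside the labeled mask, and compute per-pool AUC contrast maps;
#' aggregate region means into the tidy group table; run the group
#' comparison suite; render per-arm heatmaps (shared color window) and
#' mean +/- SEM bar plots; write everything plus a manifest with the echoed
#' configuration, voxel counts and md5 checksums of all data artifacts.
#'
#' Deterministic: identical inputs and configuration give byte-identical
#' outputs (the run log carries timings and is excluded from checksums).
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `table`, `stats`, `manifest`,
#'   `output_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out, "run.log")
  cat("", file = logf)
  say <- function(fmt, ...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...))
    cat(line, "\n", file = logf, append = TRUE)
    if (config$verbose) message(line)
  }

  say("stage input: reading %s", config$input_dir)
  inp <- read_phantom_dir(config$input_dir)
  labels <- inp$labels
  regions <- attr(labels, "regions")
  mask <- labels > 0L
  fcfg <- fit_config()
  check_identifiability(fcfg, inp$axis)
  write_pipeline_config(config, file.path(out, "config.yaml"))

  rows <- list()
  cmaps <- list()
  counts <- c(fitted = 0L, skipped = 0L, not_converged = 0L)
  for (s in inp$subjects) {
    say("stage b0: subject %s", s$id)
    b0 <- estimate_b0_map(s$wassr, inp$wassr_axis, mask = mask,
                          bound = config$b0_bound)
    corr <- correct_stack(s$z, inp$axis, b0, bound = config$b0_bound)
    say("stage fit: subject %s (%d voxels)", s$id, sum(mask & corr$valid))
    fits <- fit_stack(corr$z, inp$axis, mask = mask, config = fcfg,
                      valid = corr$valid)
    counts <- counts + fits$counts
    write_map(b0$offset, file.path(out, sprintf("b0_%s.nii", s$id)))
    write_map(b0$valid * 1L, file.path(out, sprintf("b0_valid_%s.nii", s$id)))
    amp4 <- array(fits$amplitude,
                  dim = c(dim(fits$amplitude)[1:2], 1L,
                          dim(fits$amplitude)[3]))
    RNifti::writeNifti(amp4, file.path(out, sprintf("amplitude_%s.nii", s$id)),
                       datatype = "double")
    fw4 <- array(fits$fwhm, dim = dim(amp4))
    RNifti::writeNifti(fw4, file.path(out, sprintf("fwhm_%s.nii", s$id)),
                       datatype = "double")
    for (p in config$contrast_pools) {
      cm <- contrast_map(fits, p, mode = config$auc_mode,
                         range = config$auc_range)
      write_map(cm, file.path(out, sprintf("contrast_%s_%s.nii", p, s$id)))
      if (p == config$heatmap_pool) cmaps[[s$id]] <- cm
      rows[[paste(s$id, p)]] <-
        aggregate_regions(cm, labels, subject = s$id, arm = s$arm,
                          regions = regions, pool = p)
    }
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  write_table_csv(table, file.path(out, "region_group_table.csv"))

  say("stage stats: %d rows", nrow(table))
  st <- comparison_suite(table, posthoc_variant = config$posthoc_variant,
                         paired = config$paired)
  write_table_csv(st$tests, file.path(out, "test_reports.csv"))
  write_table_csv(st$summary, file.path(out, "group_summary.csv"))
  jsonlite::write_json(st, file.path(out, "test_reports.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")

  say("stage figures")
  # one representative subject per arm, shared color window across arms
  arms <- unique(inp$subject_table$arm)
  reps <- vapply(arms, function(a)
    inp$subject_table$subject[inp$subject_table$arm == a][1], character(1))
  reps <- reps[reps %in% names(cmaps)]
  if (length(reps)) {
    win <- range(unlist(lapply(cmaps[reps], function(m)
      range(m, na.rm = TRUE))))
    for (a in names(reps))
      render_heatmap(cmaps[[reps[[a]]]],
                     file.path(out, sprintf("heatmap_%s_%s.png",
                                            config$heatmap_pool, a)),
                     window = win)
  }
  for (p in config$contrast_pools)
    plot_region_bars(table, st, pool = p,
                     file.path(out, sprintf("bars_%s.png", p)))

  say("stage manifest")
  files <- setdiff(list.files(out), c("manifest.json", "run.log"))
  checksums <- as.list(tools::md5sum(file.path(out, files)))
  names(checksums) <- files
  manifest <- list(
    package_version = as.character(utils::packageVersion("cestquant")),
    config = unclass(config),
    config_hash = unname(tools::md5sum(file.path(out, "config.yaml"))),
    n_subjects = length(inp$subjects),
    voxel_counts = as.list(counts),
    checksums = checksums)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("done in %.1f s", as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(list(table = table, stats = st, manifest = manifest,
                 output_dir = out))
}

#' Bar plot of group means with SEM error bars and significance tiers
#'
#' One panel per region: mean contrast per arm with SEM whiskers, annotated
#' with the tier of the baseline-vs-untreated comparison (and of the
#' treated-vs-untreated comparison above the treated bar).
#'
#' @param table Tidy region/group table.
#' @param stats Result of [comparison_suite()] on that table.
#' @param pool Pool to plot.
#' @param file PNG path.
#' @return `file`, invisibly.
#' @export
plot_region_bars <- function(table, stats, pool, file) {
  tb <- table[table$pool == pool, , drop = FALSE]
  regions <- unique(tb$region)
  arms <- unique(tb$arm)
  grDevices::png(file, width = 220 * length(regions), height = 320,
                 type = "cairo")
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::par(mfrow = c(1, length(regions)), mar = c(6, 4, 3, 1))
  cols <- c("firebrick", "goldenrod2", "forestgreen", "steelblue")
  for (r in regions) {
    v <- tb[tb$region == r, , drop = FALSE]
    mu <- vapply(arms, function(a) mean(v$contrast[v$arm == a]), numeric(1))
    se <- vapply(arms, function(a) sem(v$contrast[v$arm == a]), numeric(1))
    ylim <- c(0, max(mu + se) * 1.25)
    bp <- graphics::barplot(mu, names.arg = arms, las = 2, main = r,
                            ylab = sprintf("%s AUC (ppm)", pool),
                            col = cols[seq_along(arms)], ylim = ylim)
    draw <- is.finite(se) & se > 0
    if (any(draw))
      suppressWarnings(
        graphics::arrows(bp[draw], (mu - se)[draw], bp[draw],
                         (mu + se)[draw], angle = 90, code = 3,
                         length = 0.04))
    ts <- stats$tests
    lab <- ts$tier[ts$region == r & ts$pool == pool &
                     ts$comparison == "baseline vs wk12_vehicle"]
    if (length(lab) == 1L && !is.na(lab) && lab != "ns")
      graphics::text(bp[match("wk12_vehicle", arms)],
                     ylim[2] * 0.95, lab)
    lab2 <- ts$tier[ts$region == r & ts$pool == pool &
                      ts$comparison == "wk12_art vs wk12_vehicle"]
    if (length(lab2) == 1L && !is.na(lab2) && lab2 != "ns")
      graphics::text(bp[match("wk12_art", arms)], ylim[2] * 0.95, lab2)
  }
  invisible(file)
}
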