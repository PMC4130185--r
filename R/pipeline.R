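#' Five-number box-plot summary per group
#'
#' Median, quartiles (linear-interpolation quantiles, R type 7), Tukey
#' whiskers (most extreme points within 1.5 IQR of the quartiles) and n, per
#' group -- the summary behind per-cell intensity box plots.
#'
#' @param data A data.frame.
#' @param value_col Name of the numeric column to summarise.
#' @param group_col Name of the grouping column.
#' @return A data.frame with one row per group: `group`, `n`, `whisker_low`,
#'   `q1`, `median`, `q3`, `whisker_high`.
#' @export
summarize_distributions <- function(data, value_col = "mean_marker_intensity",
                                    group_col = "condition") {
  if (!all(c(value_col, group_col) %in% names(data)))
    stop(sprintf("columns '%s' and '%s' must exist", value_col, group_col))
  groups <- split(data[[value_col]], data[[group_col]])
  if (any(lengths(groups) == 0)) stop("every group must be non-empty")
  rows <- lapply(names(groups), function(nm) {
    v <- groups[[nm]]
    q <- quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    iqr <- q[3] - q[1]
    data.frame(group = nm, n = length(v),
               whisker_low = min(v[v >= q[1] - 1.5 * iqr]),
               q1 = q[1], median = q[2], q3 = q[3],
               whisker_high = max(v[v <= q[3] + 1.5 * iqr]))
  })
  do.call(rbind, rows)
}

validate_config <- function(config) {
  known_top <- c("stages", "image", "calcium", "ephys", "stats")
  bad <- setdiff(names(config), known_top)
  if (length(bad))
    stop(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")))
  stages <- config$stages %||% stop("config must name `stages`")
  bad_st <- setdiff(stages, c("image", "calcium", "ephys"))
  if (length(bad_st))
    stop(sprintf("unknown stage(s): %s", paste(bad_st, collapse = ", ")))
  config
}

checksums <- function(files) {
  ok <- file.exists(files)
  as.list(setNames(unname(tools::md5sum(files[ok])), basename(files[ok])))
}

stage_image <- function(cfg, out_dir, seed) {
  cfg <- cfg %||% list()
  n_images <- cfg$n_images %||% 2L
  conditions <- cfg$conditions %||%
    rep(c("control", "treated"), length.out = n_images)
  spec <- do.call(image_spec, cfg$spec %||% list())
  files <- character(0)
  cells_all <- list()
  for (i in seq_len(n_images)) {
    sim <- gen_image(spec, seed = seed + i - 1L)
    tif <- file.path(out_dir, sprintf("image_%02d.tif", i))
    write_fluor_image(sim$image, tif, truth = sim$truth)
    seg <- do.call(segment_image, c(list(sim$image), cfg$segment %||% list()))
    lab <- file.path(out_dir, sprintf("labels_%02d.tif", i))
    write_label_map(seg$nuclear_labels, lab)
    cells <- seg$cells
    cells$image <- i
    cells$condition <- conditions[i]
    cells_all[[i]] <- cells
    files <- c(files, tif, paste0(tif, ".json"), lab)
  }
  cells <- do.call(rbind, cells_all)
  cells_csv <- file.path(out_dir, "cells.csv")
  write.csv(cells, cells_csv, row.names = FALSE)
  summ <- summarize_distributions(cells, "mean_marker_intensity", "condition")
  summ_csv <- file.path(out_dir, "intensity_summary.csv")
  write.csv(summ, summ_csv, row.names = FALSE)
  stats_rows <- NULL
  if (length(unique(cells$condition)) >= 2) {
    g <- split(cells$mean_marker_intensity, cells$condition)
    res <- if (length(g) == 2) mann_whitney(g[[1]], g[[2]])
           else kruskal_wallis(g)
    stats_rows <- data.frame(
      comparison = paste(names(g), collapse = " vs "),
      method = res$method, statistic = unname(res$statistic[1]),
      p_value = res$p_value)
  }
  stats_csv <- NULL
  if (!is.null(stats_rows)) {
    stats_csv <- file.path(out_dir, "image_stats.csv")
    write.csv(stats_rows, stats_csv, row.names = FALSE)
  }
  list(files = c(files, cells_csv, summ_csv, stats_csv),
       n_cells = nrow(cells), stats = stats_rows)
}

stage_calcium <- function(cfg, out_dir, seed) {
  cfg <- cfg %||% list()
  n_neuron <- cfg$n_neuron %||% 50L
  n_non_neuron <- cfg$n_non_neuron %||% 50L
  attenuation <- cfg$attenuation %||% 0.5
  gen <- function(att, sd_off) gen_traces(n_neuron, n_non_neuron,
                                          attenuation = att,
                                          seed = seed + sd_off)
  ctl <- gen(1, 0L)
  trt <- gen(attenuation, 1L)
  feats <- function(sim, label) {
    ft <- lapply(sim$traces, trace_features)
    data.frame(condition = label,
               cell_id = vapply(ft, `[[`, numeric(1), "cell_id"),
               f0 = vapply(ft, `[[`, numeric(1), "f0"),
               peak = vapply(ft, `[[`, numeric(1), "peak"),
               auc = vapply(ft, `[[`, numeric(1), "auc"),
               plateau_ratio = vapply(ft, `[[`, numeric(1), "plateau_ratio"),
               cell_class = vapply(ft, `[[`, character(1), "cell_class"),
               true_class = sim$truth$cell_class)
  }
  tab <- rbind(feats(ctl, "control"), feats(trt, "treated"))
  traces_csv <- file.path(out_dir, "traces_control.csv")
  write_traces_csv(ctl$traces, traces_csv)
  feat_csv <- file.path(out_dir, "calcium_features.csv")
  write.csv(tab, feat_csv, row.names = FALSE)
  cmp <- group_auc_compare(tab$auc[tab$condition == "control"],
                           tab$auc[tab$condition == "treated"])
  cmp_json <- file.path(out_dir, "calcium_compare.json")
  jsonlite::write_json(list(method = cmp$method, U = unname(cmp$statistic),
                            p_value = cmp$p_value,
                            median_control = cmp$median_control,
                            median_treated = cmp$median_treated),
                       cmp_json, auto_unbox = TRUE, digits = NA)
  list(files = c(traces_csv, paste0(traces_csv, ".json"), feat_csv, cmp_json),
       compare = cmp,
       accuracy = mean(tab$cell_class == tab$true_class))
}

stage_ephys <- function(cfg, out_dir, seed) {
  cfg <- cfg %||% list()
  truth <- do.call(ltp_truth, cfg$truth %||% list())
  protocol <- do.call(ltp_protocol, cfg$protocol %||% list())
  sim <- gen_ltp_series(truth, protocol, seed = seed)
  ft <- percent_of_baseline(sim$series)
  ser_csv <- file.path(out_dir, "fepsp_series.csv")
  write_fepsp_csv(sim$series, ser_csv)
  summ <- list(early_mean = ft$early_mean, late_mean = ft$late_mean,
               first10_mean = ft$first10_mean,
               baseline_mean = window_mean(ft, ft$baseline_window))
  summ_json <- file.path(out_dir, "ltp_summary.json")
  jsonlite::write_json(summ, summ_json, auto_unbox = TRUE, digits = NA)
  list(files = c(ser_csv, paste0(ser_csv, ".json"), summ_json),
       summary = summ)
}

#' Run the end-to-end pipeline from a single configuration
#'
#' Executes the requested stages (`image`: simulate, segment, measure,
#' summarise, compare; `calcium`: simulate control/treated traces, extract
#' features, compare AUCs; `ephys`: simulate an LTP series and compute window
#' means) and writes every artifact plus a run manifest (config snapshot,
#' package version, per-file MD5 checksums, per-stage wall-clock) to
#' `out_dir`. Reruns with identical config and seed produce identical
#' outputs; a failing stage leaves prior outputs in place and the manifest
#' records the failure point.
#'
#' @param config Nested list (e.g. from [yaml::read_yaml()]): `stages` plus
#'   per-stage parameter lists. Unknown keys are an error.
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed for every stochastic stage.
#' @return The manifest list, invisibly; also written as `manifest.json`.
#' @export
run_pipeline <- function(config, out_dir, seed = 1L) {
  config <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = config, seed = as.integer(seed),
                   package_version = as.character(packageVersion("hippoquant")),
                   stages = list())
  runners <- list(image = stage_image, calcium = stage_calcium,
                  ephys = stage_ephys)
  results <- list()
  for (st in config$stages) {
    t0 <- Sys.time()
    res <- tryCatch(runners[[st]](config[[st]], out_dir, seed),
                    error = function(e) e)
    elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    if (inherits(res, "error")) {
      manifest$stages[[st]] <- list(status = "failed",
                                    error = conditionMessage(res),
                                    elapsed_s = elapsed)
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, force = TRUE)
      stop(sprintf("stage '%s' failed: %s", st, conditionMessage(res)))
    }
    manifest$stages[[st]] <- list(status = "ok", elapsed_s = elapsed,
                                  checksums = checksums(res$files))
    results[[st]] <- res
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  manifest$results <- results
  invisible(manifest)
}
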