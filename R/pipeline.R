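#' Run a configured analysis end to end
#'
#' Config-driven orchestration: simulate (or read) activity data, score
#' sleep, summarize per fly, run the configured statistics, and write CSV /
#' JSON reports plus a run manifest. Identical config and seed give
#' byte-identical outputs.
#'
#' @param config A named list, or path to a YAML/JSON file holding one.
#'   Keys: \code{preset} and its parameters (see
#'   \code{\link{build_experiment}}), or \code{monitor_files} (named list
#'   \code{condition -> path}) with \code{beam_mode}; \code{lights_on}
#'   (clock time, default "09:00:00"); \code{window} (24-h window index,
#'   default 2); \code{posthoc} (\code{"tukey"}, \code{"sidak"},
#'   \code{"dunnett"}); \code{seed}. Unknown keys are rejected.
#' @param out_dir Output directory.
#' @param seed Overrides \code{config$seed} when given.
#' @return Invisibly, a list with the per-fly table, the stats report and
#'   the manifest.
#' @export
run_analysis <- function(config, out_dir, seed = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  known <- c("preset", "seed", "n_per_cell", "n_days", "contrast_min",
             "n_flies", "dwell_factor", "n_lines", "n_per_group",
             "planted_lines", "planted_effect", "monitor_files", "beam_mode",
             "lights_on", "window", "posthoc", "alpha")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) stop2("unknown config keys: ", paste(unknown, collapse = ", "))
  if (!is.null(seed)) config$seed <- seed
  config$seed <- config$seed %||% 1L
  schedule <- light_schedule(config$lights_on %||% "09:00:00")
  window <- config$window %||% 2L
  alpha <- config$alpha %||% 0.05
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_line <- function(...) message("[flysleep] ", ...)

  recs <- list()
  if (!is.null(config$monitor_files)) {
    for (cond in names(config$monitor_files)) {
      path <- config$monitor_files[[cond]]
      if (!file.exists(path)) stop2("stage dam_io: monitor file not found: ", path)
      rr <- read_monitor_file(path, config$beam_mode %||% "single",
                              condition = list(group = cond))
      recs <- c(recs, rr)
    }
  } else if (!is.null(config$preset)) {
    bkeys <- intersect(names(config), c("preset", "seed", "n_per_cell",
                                        "n_days", "contrast_min", "n_flies",
                                        "dwell_factor", "n_lines",
                                        "n_per_group", "planted_lines",
                                        "planted_effect"))
    exp <- build_experiment(config[bkeys])
    if (!is.null(exp$cells)) {
      recs <- lapply(unlist(exp$cells, recursive = FALSE), `[[`, "recording")
    } else if (!is.null(exp$flies)) {
      recs <- lapply(exp$flies, `[[`, "recording")
    } else {
      stop2("preset ", config$preset, " is not supported by run_analysis; ",
            "use build_experiment + screen_hits directly")
    }
  } else {
    stop2("config needs either monitor_files or preset")
  }

  log_line("scoring sleep for ", length(recs), " flies")
  per_fly <- sleep_summary_table(recs, schedule, window = window)
  dead <- vapply(recs, function(r) flag_dead(r)$dead, TRUE)
  if (any(dead)) log_line("WARN dead_flies: ",
                          paste(vapply(recs[dead], `[[`, "", "fly_id"),
                                collapse = ","))
  utils::write.csv(per_fly, file.path(out_dir, "per_fly_sleep.csv"),
                   row.names = FALSE)

  stats_report <- NULL
  if (all(c("sex_pairing", "diet") %in% names(per_fly)) &&
      length(unique(per_fly$sex_pairing)) > 1L &&
      length(unique(per_fly$diet)) > 1L) {
    ia <- interaction_anova(per_fly, "nighttime_sleep_min", "sex_pairing",
                            "diet", posthoc = config$posthoc %||% "tukey")
    stats_report <- write_stats_json(ia)
    cellmeans <- stats::aggregate(nighttime_sleep_min ~ sex_pairing + diet,
                                  per_fly, mean)
    utils::write.csv(cellmeans, file.path(out_dir, "cell_means.csv"),
                     row.names = FALSE)
  } else if ("group" %in% names(per_fly) &&
             length(unique(per_fly$group)) == 2L) {
    g <- split(per_fly$nighttime_sleep_min, per_fly$group)
    stats_report <- write_stats_json(
      choose_two_group_test(g[[1]], g[[2]], alpha = alpha))
  }
  if (!is.null(stats_report)) {
    jsonlite::write_json(stats_report, file.path(out_dir, "stats.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }

  manifest <- list(
    package = "flysleep",
    version = as.character(utils::packageVersion("flysleep")),
    seed = config$seed,
    config = config[order(names(config))],
    config_hash = sum(utf8ToInt(paste(deparse(config[order(names(config))]),
                                      collapse = ""))),
    n_flies = length(recs), n_dead = sum(dead))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(per_fly = per_fly, stats = stats_report, manifest = manifest))
}
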