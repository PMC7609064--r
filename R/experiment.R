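#' Calibrated 2x2 models with a known interaction contrast
#'
#' Builds the four cell models of a pairing-by-diet design in which the
#' expected scored nighttime sleep shows a pure interaction: three cells
#' share the base model and the (MF, fed) cell is recalibrated so that the
#' interaction contrast
#' \eqn{(\mu_{MF,fed}-\mu_{MF,dep})-(\mu_{MM,fed}-\mu_{MM,dep})}
#' equals \code{-contrast_min} minutes of scored sleep (0 gives a null
#' design). The base uses highly consolidated nighttime sleep (dwell times
#' around two hours), which puts the across-fly SD of scored nighttime
#' sleep near 120 minutes, the between-fly spread the design assumes.
#'
#' @param contrast_min Interaction contrast in minutes of nighttime sleep.
#' @param base Base \code{\link{fly_model}} shared by the unshifted cells.
#' @return Named list of four \code{fly_model}s
#'   (\code{MM_fed}, \code{MM_deprived}, \code{MF_fed},
#'   \code{MF_deprived}).
#' @export
interaction_design_models <- function(contrast_min = 120,
                                      base = fly_model(
                                        p_fall_asleep_day = 0.08,
                                        p_fall_asleep_night = 1 / 72,
                                        p_wake_day = 0.12,
                                        p_wake_night = 1 / 120)) {
  base_night <- expected_scored_sleep(base, n_days = 2)$expected_night_sleep[[2]]
  shifted <- if (contrast_min != 0) {
    calibrate_night_sleep(base, base_night - contrast_min)
  } else base
  lab <- function(m, pairing, diet) {
    m$condition <- list(sex_pairing = pairing, diet = diet); m
  }
  list(MM_fed = lab(base, "MM", "fed"),
       MM_deprived = lab(base, "MM", "yeast_deprived"),
       MF_fed = lab(shifted, "MF", "fed"),
       MF_deprived = lab(base, "MF", "yeast_deprived"))
}

simulate_cell <- function(model, n, n_days, seed, prefix, epochs = NULL,
                          activation_model = NULL) {
  lapply(seq_len(n), function(i) {
    simulate_fly(model, n_days = n_days, seed = seed,
                 fly_id = sprintf("%s_%03d", prefix, i),
                 channel = ((i - 1L) %% 32L) + 1L,
                 epochs = epochs, activation_model = activation_model)
  })
}

#' Nighttime sleep per fly for a list of simulations
#'
#' @param sims List of \code{\link{simulate_fly}} results.
#' @param window 24-h ZT window index.
#' @param schedule A \code{\link{light_schedule}}.
#' @return Numeric vector of scored nighttime sleep minutes.
#' @export
night_sleep_values <- function(sims, window = 2L,
                               schedule = light_schedule("09:00:00")) {
  vapply(sims, function(s) {
    zt <- to_zt(s$recording, schedule)
    sleep_summary(score_sleep(s$recording), zt, window)$nighttime_sleep_min
  }, 0L)
}

#' Build a complete synthetic experiment
#'
#' Generates every input the pipeline consumes, with ground truth, for one
#' of the study-style designs:
#' \describe{
#'   \item{\code{nutrition_by_pairing}}{2x2 MM/MF x fed/deprived cells
#'     using the condition presets (strong, realistic effects).}
#'   \item{\code{calibrated_interaction}}{2x2 design built by
#'     \code{\link{interaction_design_models}} with a specified interaction
#'     contrast (possibly 0).}
#'   \item{\code{thermogenetic_activation}}{1.5 baseline days at 22 C, 2
#'     activation days at 29 C (nighttime sleep dwell scaled by
#'     \code{dwell_factor}), then recovery at 22 C.}
#'   \item{\code{dual_control_screen}}{\code{n_lines} driver lines with
#'     experimental + per-line Gal4 control + shared UAS control;
#'     \code{planted_lines} get a \code{planted_effect}-minute nighttime
#'     sleep change; one extra line is constructed with its experimental
#'     group between the two controls.}
#' }
#'
#' @param config Named list: \code{preset}, \code{seed}, and preset
#'   parameters (\code{n_per_cell}, \code{n_days}, \code{contrast_min},
#'   \code{n_flies}, \code{dwell_factor}, \code{n_lines}, \code{n_per_group},
#'   \code{planted_lines}, \code{planted_effect}, \code{out_dir}). Unknown
#'   keys are rejected.
#' @return A list with preset-specific components, always including
#'   \code{truth}; when \code{out_dir} is given, monitor files and a truth
#'   JSON are written there.
#' @export
build_experiment <- function(config) {
  known <- c("preset", "seed", "n_per_cell", "n_days", "contrast_min",
             "n_flies", "dwell_factor", "n_lines", "n_per_group",
             "planted_lines", "planted_effect", "out_dir")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) stop2("unknown config keys: ", paste(unknown, collapse = ", "))
  preset <- config$preset %||% stop2("config$preset is required")
  seed <- config$seed %||% 1L
  out <- switch(preset,
    nutrition_by_pairing = {
      n <- config$n_per_cell %||% 32L
      if (n < 1L) stop2("n_per_cell must be >= 1")
      n_days <- config$n_days %||% 2L
      cells <- c("MM_fed", "MM_deprived", "MF_fed", "MF_deprived")
      sims <- lapply(cells, function(cl) {
        simulate_cell(fly_model_preset(cl), n, n_days, seed, cl)
      })
      names(sims) <- cells
      list(preset = preset, cells = sims,
           truth = list(seed = seed,
                        models = lapply(cells, fly_model_preset)))
    },
    calibrated_interaction = {
      n <- config$n_per_cell %||% 32L
      if (n < 1L) stop2("n_per_cell must be >= 1")
      n_days <- config$n_days %||% 2L
      models <- interaction_design_models(config$contrast_min %||% 120)
      sims <- lapply(names(models), function(cl) {
        simulate_cell(models[[cl]], n, n_days, seed, cl)
      })
      names(sims) <- names(models)
      exp_night <- vapply(models, function(m) {
        expected_scored_sleep(m, n_days = 2)$expected_night_sleep[[2]]
      }, 0)
      list(preset = preset, cells = sims,
           truth = list(seed = seed, models = models,
                        expected_night_sleep = exp_night))
    },
    thermogenetic_activation = {
      n <- config$n_flies %||% 60L
      if (n < 1L) stop2("n_flies must be >= 1")
      dwell_factor <- config$dwell_factor %||% 0.5
      n_days <- 5L
      epochs <- temperature_epochs(
        c("baseline", "activation", "recovery"),
        c(0L, 2160L, 5040L), c(2160L, 5040L, 7200L), c(22, 29, 22))
      base <- fly_model(p_fall_asleep_day = 0.08, p_fall_asleep_night = 0.1,
                        p_wake_day = 0.12, p_wake_night = 0.04)
      act <- base
      act$p_wake_night <- min(base$p_wake_night / dwell_factor, 0.95)
      sims <- simulate_cell(base, n, n_days, seed, "trpa1", epochs, act)
      list(preset = preset, flies = sims, epochs = epochs,
           truth = list(seed = seed, model = base, activation_model = act,
                        dwell_factor = dwell_factor))
    },
    dual_control_screen = {
      n_lines <- config$n_lines %||% 20L
      if (n_lines < 1L) stop2("n_lines must be >= 1")
      n <- config$n_per_group %||% 30L
      planted <- config$planted_lines %||% c(7L, 13L)
      effect <- config$planted_effect %||% -150
      base <- fly_model(p_fall_asleep_day = 0.08, p_fall_asleep_night = 0.1,
                        p_wake_day = 0.12, p_wake_night = 0.05)
      base_night <- expected_scored_sleep(base, n_days = 2)$expected_night_sleep[[2]]
      hit_model <- calibrate_night_sleep(base, base_night + effect)
      # extra line whose experimental group lies between its two controls
      between_gal4 <- calibrate_night_sleep(base, base_night + 150)
      between_exp <- calibrate_night_sleep(base, base_night + 75)
      uas <- simulate_cell(base, n, 2L, seed, "uas_control")
      lines <- lapply(seq_len(n_lines + 1L), function(l) {
        is_hit <- l %in% planted
        is_between <- l == n_lines + 1L
        exp_model <- if (is_hit) hit_model else if (is_between) between_exp else base
        gal4_model <- if (is_between) between_gal4 else base
        list(experimental = simulate_cell(exp_model, n, 2L, seed,
                                          sprintf("line%02d_exp", l)),
             gal4_control = simulate_cell(gal4_model, n, 2L, seed,
                                          sprintf("line%02d_gal4", l)))
      })
      names(lines) <- c(sprintf("line%02d", seq_len(n_lines)), "between_controls")
      list(preset = preset, lines = lines, uas_control = uas,
           truth = list(seed = seed, planted_lines = planted,
                        planted_effect = effect, base = base,
                        hit_model = hit_model,
                        expected_base_night = base_night))
    },
    stop2("unknown preset: ", preset))
  if (!is.null(config$out_dir)) {
    write_experiment(out, config$out_dir)
  }
  out
}

# Write monitor files (one per cohort of up to 32 flies) and a truth JSON.
write_experiment <- function(exp, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_cohort <- function(sims, stem) {
    recs <- lapply(sims, `[[`, "recording")
    chunks <- split(recs, (seq_along(recs) - 1L) %/% 32L)
    for (ci in seq_along(chunks)) {
      ch <- chunks[[ci]]
      for (i in seq_along(ch)) ch[[i]]$channel <- i
      write_monitor_file(ch, file.path(out_dir,
                                       sprintf("%s_M%02d.txt", stem, ci)))
    }
  }
  if (!is.null(exp$cells)) {
    for (cl in names(exp$cells)) write_cohort(exp$cells[[cl]], cl)
  }
  if (!is.null(exp$flies)) write_cohort(exp$flies, "trpa1")
  if (!is.null(exp$lines)) {
    write_cohort(exp$uas_control, "uas_control")
    for (nm in names(exp$lines)) {
      write_cohort(exp$lines[[nm]]$experimental, paste0(nm, "_exp"))
      write_cohort(exp$lines[[nm]]$gal4_control, paste0(nm, "_gal4"))
    }
  }
  truth <- exp$truth
  truth$models <- NULL; truth$model <- NULL; truth$activation_model <- NULL
  truth$base <- NULL; truth$hit_model <- NULL
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
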