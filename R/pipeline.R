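#' Default temperature-step schedules for a simulated study
#'
#' Three rising staircases covering 20-40 degC, respecting the protocol
#' constraints (first step at 20-30 degC held 2 h, later steps at least 1 h,
#' increments of at most 10 degC below 30 and 4 degC between 30 and 40).
#'
#' @return List of two-column matrices (Ta degC, minutes).
#' @export
default_schedules <- function() {
  list(cbind(c(20, 28, 32, 36), c(120, 80, 80, 80)),
       cbind(c(25, 30, 34, 38), c(120, 80, 80, 80)),
       cbind(c(30, 34, 37, 40), c(120, 80, 80, 80)))
}

#' Simulate a multi-animal respirometry study and extract resting bouts
#'
#' Draws per-trial physiology around the population parameters
#' ([jitter_physiology()]), simulates each trial with rotating temperature
#' schedules, and runs the full extraction ([extract_rmr()]) on every trace.
#'
#' @param n_trials Number of trials. Default 18 (about 2-4 retained bouts per
#'   trial yields the ~50-bout scale of a field-season study).
#' @param params Population [physiology_params()].
#' @param seed Integer seed; per-trial seeds are derived from it.
#' @param schedules List of schedules cycled across trials.
#' @param config A [run_config()].
#' @param ... Passed to [generate_respirometry_trial()].
#' @return List: `bouts` (combined bout table), `trials` (list of per-trial
#'   truth), `params`.
#' @export
simulate_respirometry_study <- function(n_trials = 18,
                                        params = physiology_params(),
                                        seed = 1,
                                        schedules = default_schedules(),
                                        config = run_config(), ...) {
  bouts <- list(); truths <- list()
  for (i in seq_len(n_trials)) {
    p_i <- jitter_physiology(params, seed = derive_seed(seed, 100 + i))
    sch <- schedules[[(i - 1) %% length(schedules) + 1]]
    sim <- generate_respirometry_trial(p_i, sch,
                                       seed = derive_seed(seed, 200 + i),
                                       ...)
    b <- extract_rmr(sim$trace, sim$truth$steps,
                     active_intervals = sim$truth$activity,
                     config = config, mass_g = p_i$mass_g,
                     trial_id = sprintf("trial%02d", i),
                     squirrel_id = sprintf("sq%02d", ((i - 1) %% 7) + 1))
    bouts[[i]] <- b
    truths[[i]] <- sim$truth
  }
  list(bouts = do.call(rbind, bouts), trials = truths, params = params)
}

#' Run the full synthetic pipeline
#'
#' Orchestrates simulate -> extract -> fit -> profile -> compare with a
#' single configuration and reproducible seeding (a per-stage seed is derived
#' from the global seed, so stages can be re-run in isolation). Any stage
#' failure halts downstream stages but still emits a partial report.
#'
#' @param config A [run_config()] (its `seed` drives all stages).
#' @param out_dir Output directory; created if needed.
#' @param n_trials Respirometry trials to simulate. Default 9.
#' @param n_days Days of free-ranging data per individual. Default 20.
#' @param n_individuals Free-ranging individuals. Default 3.
#' @return A `pipeline_report`: per-stage status, file manifest with MD5
#'   hashes, configuration snapshot and seed; also written as JSON to
#'   `out_dir/report.json`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = tempfile("run"),
                         n_trials = 9, n_days = 20, n_individuals = 3) {
  if (!inherits(config, "run_config"))
    stop("pre-flight error: config must be a run_config", call. = FALSE)
  if (is.na(config$site_lat) || is.na(config$site_lon))
    stop("pre-flight error: site coordinates missing", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  st <- site(config$site_lat, config$site_lon, config$site_tz)
  stages <- list()
  files <- character(0)
  failed <- FALSE
  run_stage <- function(name, fun) {
    if (failed) return(list(status = "skipped"))
    tryCatch({
      value <- fun()
      list(status = "ok", value = value)
    }, error = function(e) {
      failed <<- TRUE
      list(status = "failed", error = conditionMessage(e))
    })
  }

  stages$simulate_respirometry <- run_stage("simulate_respirometry",
    function() {
      study <- simulate_respirometry_study(n_trials = n_trials,
                                           seed = derive_seed(seed, 1),
                                           config = config)
      files <<- c(files, write_results(list(bouts = study$bouts),
                                       file.path(out_dir, "rmr"),
                                       config = config))
      study
    })
  failed <- stages$simulate_respirometry$status != "ok"

  stages$fit_breakpoints <- run_stage("fit_breakpoints", function() {
    suite <- fit_response_suite(stages$simulate_respirometry$value$bouts,
                                grid_step = config$grid_step)
    fits <- Filter(function(f) inherits(f, "piecewise_fit"),
                   suite[c("vo2", "ewl", "tsub", "ehl_mhp")])
    files <<- c(files, write_results(fits, file.path(out_dir, "breakpoint"),
                                     config = config))
    suite
  })
  if (!failed) failed <- stages$fit_breakpoints$status != "ok"

  stages$simulate_field <- run_stage("simulate_field", function() {
    lapply(seq_len(n_individuals), function(i)
      generate_free_ranging(rhythm_params(), st, n_days = n_days,
                            seed = derive_seed(seed, 10 + i),
                            individual = sprintf("sq%02d", i),
                            level_offset = stats::rnorm(1, 0, 0.15)))
  })
  if (!failed) failed <- stages$simulate_field$status != "ok"

  stages$profile_tb <- run_stage("profile_tb", function() {
    field <- stages$simulate_field$value
    profs <- lapply(field, function(f)
      thermal_profile(f$tb, f$ta, st, individual = f$truth$individual))
    prof <- do.call(rbind, profs)
    ps <- phase_summaries(prof, mode_bin = config$mode_bin)
    hi <- daily_hi(prof, mode_bin = config$mode_bin)
    torp <- do.call(rbind, lapply(field, function(f) {
      tt <- detect_torpor(f$tb, threshold = config$torpor_threshold,
                          min_duration = config$torpor_min_duration)
      if (nrow(tt)) cbind(individual = f$truth$individual, tt) else NULL
    }))
    if (is.null(torp))
      torp <- data.frame(individual = character(0),
                         start = as.POSIXct(character(0)),
                         end = as.POSIXct(character(0)),
                         min_tb = numeric(0), n_records = integer(0))
    rhythm <- daily_rhythm_by_date(prof)
    files <<- c(files, write_results(
      list(phase_summaries = ps$phases, daily_range = ps$days,
           heterothermy = hi, torpor = torp, rhythm = rhythm),
      file.path(out_dir, "tb"), config = config))
    list(profile = prof, phases = ps, hi = hi, torpor = torp,
         rhythm = rhythm)
  })
  if (!failed) failed <- stages$profile_tb$status != "ok"

  stages$compare_models <- run_stage("compare_models", function() {
    prof <- stages$profile_tb$value
    days <- prof$phases$days
    field <- stages$simulate_field$value
    daily <- do.call(rbind, lapply(field, function(f) {
      d <- f$truth$daily
      ds <- prof$phases$days
      ds <- ds[ds$individual == f$truth$individual, ]
      m <- merge(ds, d[, c("squirrel_date", "day_of_year", "ta_max")],
                 by = "squirrel_date")
      m
    }))
    daily <- daily[stats::complete.cases(daily[, c("max_tb", "day_of_year",
                                                   "ta_max")]), ]
    cmp <- compare_tb_models(daily, response = "max_tb")
    files <<- c(files, write_results(list(model_comparison =
                                            as.data.frame(cmp)),
                                     file.path(out_dir, "drivers"),
                                     config = config))
    cmp
  })

  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)))
  report <- list(
    stages = lapply(stages, function(s)
      s[intersect(names(s), c("status", "error"))]),
    manifest = manifest,
    config = unclass(config), config_hash = config_hash(config),
    seed = seed)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  structure(c(report, list(results = stages, out_dir = out_dir)),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Pipeline run (seed ", x$seed, ", config ", x$config_hash, ")\n",
      sep = "")
  for (nm in names(x$stages))
    cat(sprintf("  %-24s %s\n", nm, x$stages[[nm]]$status))
  cat("  outputs:", nrow(x$manifest), "files in", x$out_dir, "\n")
  invisible(x)
}
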