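#' Read and write pipeline artifact files
#'
#' CSV readers validate the schema and report the offending row and field
#' on failure; writers emit plain UTF-8 comma-separated files with ISO
#' 8601 timestamps so that parse -> serialize -> parse is the identity.
#'
#' @param path File path.
#' @param x The object to write.
#' @return Readers return tibbles; writers return `path` invisibly.
#' @name artifact_io
NULL

#' @rdname artifact_io
#' @export
read_ice_csv <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    year = readr::col_integer(), doy = readr::col_integer(),
    fraction = readr::col_double()))
  bad <- which(is.na(df$fraction) | df$fraction < 0 | df$fraction > 1)
  if (length(bad) > 0) {
    stop("ice CSV: fraction out of [0,1] at row ", bad[1], call. = FALSE)
  }
  # fill any missing days by linear interpolation, flagged
  df |>
    dplyr::group_by(.data$year) |>
    dplyr::group_modify(function(d, key) {
      full <- tibble::tibble(doy = seq_len(max(d$doy)))
      out <- dplyr::left_join(full, d, by = "doy")
      gap <- is.na(out$fraction)
      if (any(gap)) {
        message("read_ice_csv: year ", key$year, ": interpolated ",
                sum(gap), " missing day(s)")
        out$fraction <- stats::approx(out$doy[!gap], out$fraction[!gap],
                                      xout = out$doy, rule = 2)$y
      }
      dplyr::mutate(out, interpolated = gap)
    }) |>
    dplyr::ungroup() |>
    dplyr::select("year", "doy", "fraction", "interpolated")
}

#' @rdname artifact_io
#' @export
write_ice_csv <- function(x, path) {
  readr::write_csv(dplyr::select(x, "year", "doy", "fraction"), path)
  invisible(path)
}

#' @rdname artifact_io
#' @export
read_fixes_csv <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    bear_id = readr::col_character(), timestamp = readr::col_character(),
    lat = readr::col_double(), lon = readr::col_double(),
    quality = readr::col_character()))
  ts <- as.POSIXct(strptime(df$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC"))
  alt <- as.POSIXct(strptime(df$timestamp, "%Y-%m-%d %H:%M:%S", tz = "UTC"))
  ts[is.na(ts)] <- alt[is.na(ts)]
  if (anyNA(ts)) {
    stop("fixes CSV: malformed timestamp at row ", which(is.na(ts))[1],
         call. = FALSE)
  }
  bad <- abs(df$lat) > 90 | abs(df$lon) > 180
  if (any(bad)) {
    stop("fixes CSV: coordinate out of range at row ", which(bad)[1],
         call. = FALSE)
  }
  dplyr::arrange(dplyr::mutate(df, timestamp = ts),
                 .data$bear_id, .data$timestamp)
}

#' @rdname artifact_io
#' @export
write_fixes_csv <- function(x, path) {
  x |>
    dplyr::mutate(timestamp = format(.data$timestamp,
                                     "%Y-%m-%dT%H:%M:%S", tz = "UTC")) |>
    dplyr::select("bear_id", "timestamp", "lat", "lon", "quality") |>
    readr::write_csv(path)
  invisible(path)
}

#' @rdname artifact_io
#' @export
read_obs_csv <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    bear_id = readr::col_character(), date = readr::col_date(),
    class = readr::col_character(), fatness_index = readr::col_integer(),
    bcs = readr::col_integer(), litter_stage = readr::col_character(),
    litter_size = readr::col_integer()))
  ok_class <- df$class %in% c("AF_alone", "AFwC", "SUB", "AM")
  if (any(!ok_class)) {
    stop("observations CSV: unknown class at row ", which(!ok_class)[1],
         call. = FALSE)
  }
  both <- !is.na(df$fatness_index) & !is.na(df$bcs)
  mismatch <- both & recode_fi_to_bcs(df$fatness_index) != df$bcs
  if (any(mismatch)) {
    stop("observations CSV: bcs inconsistent with fatness_index at row ",
         which(mismatch)[1], call. = FALSE)
  }
  dplyr::mutate(df, year = as.integer(format(.data$date, "%Y")),
                decade = decade_of(.data$year))
}

#' @rdname artifact_io
#' @export
write_obs_csv <- function(x, path) {
  x |>
    dplyr::select("bear_id", "date", "class", "fatness_index", "bcs",
                  "litter_stage", "litter_size") |>
    readr::write_csv(path, na = "")
  invisible(path)
}

#' @rdname artifact_io
#' @export
write_metrics_csv <- function(x, path) {
  readr::write_csv(dplyr::select(x, "year", "spring_transition",
                                 "fall_transition", "ice_free_duration"),
                   path, na = "")
  invisible(path)
}

#' @rdname artifact_io
#' @export
read_metrics_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    year = readr::col_integer(),
    spring_transition = readr::col_integer(),
    fall_transition = readr::col_integer(),
    ice_free_duration = readr::col_integer()))
}

#' Write a fitted model or ranking as JSON
#'
#' Serializes the coefficient table and one-row summary of a `bcs_fit` /
#' `litter_fit`, or the table/averaged/importance components of a
#' `model_ranking`.
#'
#' @param x The fitted object.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(x, path) {
  obj <- if (inherits(x, "model_ranking")) {
    list(kind = "model_ranking",
         table = dplyr::mutate(x$table,
                               terms = purrr::map_chr(.data$terms, paste,
                                                      collapse = "+")),
         averaged = x$averaged, importance = x$importance,
         cutoff = x$cutoff)
  } else {
    list(kind = class(x)[1], coefficients = x$coefficients,
         summary = glance(x))
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}

#' @rdname artifact_io
#' @export
write_scenario_json <- function(x, path) {
  stopifnot(inherits(x, "ice_scenario"))
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname artifact_io
#' @export
read_scenario_json <- function(path) {
  obj <- jsonlite::read_json(path)
  do.call(ice_scenario, obj[setdiff(names(obj), "preset")])
}

#' @rdname artifact_io
#' @export
write_truth_json <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Default configuration for the synthetic end-to-end pipeline
#'
#' Problem sizes are chosen so a full run completes in a few minutes on a
#' single core while leaving every stage statistically meaningful; all are
#' overridable.
#'
#' @param seed Master seed; every stage derives its own stream from it.
#' @param ... Overrides of any config entry.
#' @return A named list.
#' @export
default_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = seed,
    years = 1990:2013,
    obs_years = c(1993:1995, 1997, 2011:2013),
    n_bears = 12,
    duty_cycle = 4,
    n_per_year = 120,
    buffer_km = 5,
    persistence_days = 14,
    vmax_kmh = 10,
    ice_threshold = 0.5,
    bootstrap_B = 500,
    projection_B = 100,
    projection_horizon = 35,
    scenario_preset = "declining",
    coastline = TRUE,
    out_dir = NULL,
    quiet = FALSE
  )
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Run the full synthetic pipeline
#'
#' Executes ice generation and metrics, telemetry simulation / filtering /
#' event detection, condition and litter-size model fitting with AIC
#' ranking over a compact candidate set, recruitment ratios with bootstrap
#' SEMs, and the litter-size projection, in order. Each stage is wrapped:
#' a failing or skipped stage is recorded in the report and later stages
#' that do not depend on it still run. The report is fully reproducible
#' under a fixed seed, and every stage entry carries the seed and a hash
#' of the configuration.
#'
#' @param config A list from [default_config()].
#' @return A `pipeline_report`: named list of stage results with `status`
#'   fields, plus `seed` and `config_hash`.
#' @export
run_pipeline <- function(config = default_config()) {
  seed <- config$seed
  hash <- rlang::hash(config)
  say <- function(...) if (!isTRUE(config$quiet)) message("[icebears] ", ...)
  report <- list(seed = seed, config_hash = hash, stages = list())
  stage <- function(name, deps = character(), f) {
    for (d in deps) {
      if (!identical(report$stages[[d]]$status, "ok")) {
        say(name, ": skipped (needs ", d, ")")
        return(list(status = paste0("skipped:", d)))
      }
    }
    say(name)
    out <- tryCatch(
      c(list(status = "ok", seed = seed, config_hash = hash), f()),
      error = function(e) {
        say(name, " FAILED: ", conditionMessage(e))
        list(status = "failed", error = conditionMessage(e))
      })
    out
  }

  env <- new.env()
  report$stages$seaice <- stage("seaice", character(), function() {
    sim <- gen_ice_series(ice_truth(), config$years, seed = seed)
    env$ice <- sim$series
    env$metrics <- season_metrics(sim$series,
                                  threshold = config$ice_threshold)
    list(metrics = env$metrics)
  })

  report$stages$telemetry <- stage("telemetry", "seaice", function() {
    if (!isTRUE(config$coastline)) stop("no coastline configured")
    env$coast <- gen_coastline(seed = seed + 1)
    trk <- gen_tracks(env$metrics, env$coast, n_bears = config$n_bears,
                      duty_cycle = config$duty_cycle, seed = seed + 2)
    filtered <- suppressWarnings(
      sda_filter(trk$fixes, vmax_kmh = config$vmax_kmh))
    daily <- daily_best_position(filtered)
    events <- detect_land_events(daily, env$coast, ice_series = env$ice,
                                 persistence = config$persistence_days,
                                 buffer_km = config$buffer_km)
    list(n_fixes = nrow(trk$fixes), n_retained = nrow(filtered),
         events = events, summary = phenology_summary(events),
         truth = trk$truth)
  })

  report$stages$condition <- stage("condition", "seaice", function() {
    obs <- gen_condition_obs(condition_truth(n_per_year = config$n_per_year),
                             env$metrics, config$obs_years, seed = seed + 3)
    env$obs <- obs
    des <- build_condition_design(obs, env$metrics)
    candidates <- list(
      bcs_low_aic_terms(),
      c(condition_main_terms(), condition_interaction_terms()),
      condition_main_terms(),
      c("springtran", "ts_springtran", "durfree_lag1"),
      character(0)
    )
    fits <- purrr::map(candidates, ~ fit_multinomial(des$design,
                                                     des$response,
                                                     terms = .x))
    ranking <- rank_models(fits)
    best <- fits[[ranking$table$model_id[1]]]
    list(n_obs = nrow(obs), ranking_table = ranking$table,
         importance = ranking$importance, low_aic = best$coefficients,
         gof = hl_gof(best))
  })

  report$stages$reproduction <- stage("reproduction", "condition",
                                      function() {
    lit <- gen_litter_obs(litter_truth(), env$obs, env$metrics,
                          seed = seed + 4)
    env$lit <- lit
    ld <- build_litter_design(lit, env$metrics, stage = "COY")
    fit <- fit_binary_logit(ld$design, ld$response,
                            terms = coy_low_aic_terms())
    obs_with_lit <- env$obs |>
      dplyr::left_join(dplyr::select(lit, bear_id = "mother_id",
                                     ls = "litter_size", st = "stage"),
                       by = "bear_id") |>
      dplyr::mutate(litter_stage = dplyr::coalesce(.data$st, "none"),
                    litter_size = .data$ls) |>
      dplyr::select(-"st", -"ls")
    rec <- recruitment_ratios(obs_with_lit, stage = "COY",
                              B = config$bootstrap_B, seed = seed + 5)
    list(n_litters = nrow(lit), fit = fit$coefficients, gof = hl_gof(fit),
         recruitment = rec)
  })

  report$stages$projection <- stage("projection",
                                    c("condition", "reproduction"),
                                    function() {
    scen <- make_scenario(env$metrics, horizon = config$projection_horizon)
    proj <- project_litter_size(env$obs, env$lit, env$metrics, scen,
                                B = config$projection_B, seed = seed + 6)
    list(scenario = unclass(scen), trajectory = proj$trajectory,
         n_refit_failures = proj$n_refit_failures)
  })

  class(report) <- "pipeline_report"
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_report_json(report, file.path(config$out_dir, "report.json"))
  }
  report
}

#' @rdname artifact_io
#' @export
write_report_json <- function(x, path) {
  jsonlite::write_json(strip_models(unclass(x)), path, auto_unbox = TRUE,
                       digits = 10, force = TRUE, null = "null")
  invisible(path)
}

# drop non-serializable members (fitted model objects, functions)
strip_models <- function(x) {
  if (is.function(x)) return(NULL)
  if (inherits(x, c("multinom", "glm", "lm"))) return(NULL)
  if (is.list(x) && !is.data.frame(x)) {
    x <- purrr::compact(purrr::map(x, strip_models))
  }
  x
}
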