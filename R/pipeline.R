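#' Default pipeline configuration
#'
#' One structured list drives the end-to-end pipeline: simulator
#' parameters, the event schedule, the day/night scheme, the statistical
#' test policy and the exposure scenarios. Every stage can be toggled.
#'
#' @param n_events synthetic training events (default 31)
#' @param seed master seed
#' @param stages character vector of enabled stages, in order, among
#'   `"simulate"`, `"score"`, `"windows"`, `"tests"`, `"sel"`
#' @param params [activity_params()] (its seed is overridden by `seed`)
#' @param test test policy for the day-scale comparisons
#' @return a `run_config` list
#' @export
default_config <- function(n_events = 31, seed = 1L,
                           stages = c("simulate", "score", "windows",
                                      "tests", "sel"),
                           params = activity_params(),
                           test = "auto") {
  params$seed <- as.integer(seed)
  structure(list(n_events = n_events, seed = as.integer(seed),
                 stages = stages, params = params, test = test,
                 scheme = day_night_scheme()),
            class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' The file may set any of `n_events`, `seed`, `stages`, `test` and a
#' `params` block whose entries are passed to [activity_params()];
#' anything omitted keeps its default. The resolved configuration is what
#' [run_pipeline()] logs in its manifest.
#'
#' @param path YAML file
#' @return a `run_config` list
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  params <- do.call(activity_params, y$params %||% list())
  default_config(
    n_events = y$n_events %||% 31,
    seed = y$seed %||% 1L,
    stages = y$stages %||% c("simulate", "score", "windows", "tests", "sel"),
    params = params,
    test = y$test %||% "auto")
}

#' Run the pipeline end-to-end
#'
#' Executes the enabled stages — simulate counts, score the activity
#' index, build event-relative windows, run the paired response tests and
#' tabulate detonation sound exposure — writing one CSV per stage plus a
#' manifest (seed, resolved parameters, row counts) into `out_dir`.
#' Re-running with the same config and seed reproduces every output
#' byte for byte.
#'
#' @param config a [default_config()] list
#' @param out_dir output directory (created if needed)
#' @return invisibly, a list of the in-memory stage results
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile("run")) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list()
  manifest <- list(seed = config$seed, stages = paste(config$stages,
                                                      collapse = ","))
  if ("simulate" %in% config$stages) {
    res$study <- simulate_training_study(config$n_events, config$params)
    write_segments_csv(res$study$counts, file.path(out_dir, "counts.csv"))
    utils::write.csv(res$study$events[, c("event_id", "first_undet_day",
                                          "last_undet_day")],
                     file.path(out_dir, "events.csv"), row.names = FALSE)
    manifest$n_segments <- nrow(res$study$counts)
    manifest$n_events <- nrow(res$study$events)
  }
  if ("score" %in% config$stages && !is.null(res$study)) {
    recs <- res$study$records
    out <- recs
    out$start_iso8601 <- format(out$start, "%Y-%m-%dT%H:%M:%S")
    out$start <- NULL
    utils::write.csv(out, file.path(out_dir, "activity.csv"),
                     row.names = FALSE)
    utils::write.csv(daily_detections(recs),
                     file.path(out_dir, "daily_detections.csv"),
                     row.names = FALSE)
    manifest$n_hours <- nrow(res$study$hourly)
  }
  if ("windows" %in% config$stages && !is.null(res$study)) {
    ev <- res$study$events
    eligible <- vapply(seq_len(nrow(ev)), function(i)
      check_baseline_eligibility(ev[i, ], ev), TRUE)
    series <- do.call(rbind, lapply(which(eligible), function(i)
      day_scale_series(ev[i, ], res$study$hourly, config$scheme)))
    res$series <- series
    utils::write.csv(series, file.path(out_dir, "windows.csv"),
                     row.names = FALSE)
    manifest$n_eligible_events <- sum(eligible)
  }
  if ("tests" %in% config$stages && !is.null(res$series)) {
    res$tests <- day_scale_tests(res$series, config$test)
    utils::write.csv(res$tests, file.path(out_dir, "response_tests.csv"),
                     row.names = FALSE)
  }
  if ("sel" %in% config$stages) {
    res$exposure <- exposure_table()
    utils::write.csv(res$exposure, file.path(out_dir, "exposure.csv"),
                     row.names = FALSE)
  }
  write.dcf(as.data.frame(manifest), file.path(out_dir, "manifest.dcf"))
  invisible(res)
}

#' Deterministic test/demo fixtures
#'
#' Writes the small fixtures used by the test-suite and the analysis
#' scripts.
#'
#' * `"waveforms"`: three rendered recordings whose single transients have
#'   reverberation time constants chosen so that the measured durations
#'   fall near 1, 5 and 8 s — one per size class — plus one noise-only
#'   recording, as WAV files.
#' * `"counts"`: a 4-day simulated counts table around one event.
#' * `"events"`: one single-day and one three-day training event.
#' * `"gam"`: a simulated (response, predictors) table with the generating
#'   parameters stored as attributes, serialized as CSV.
#'
#' @param kind one of `"waveforms"`, `"counts"`, `"events"`, `"gam"`
#' @param seed RNG seed
#' @param dir output directory
#' @return paths of the written files (invisibly, with the objects as an
#'   attribute)
#' @export
make_fixtures <- function(kind = c("waveforms", "counts", "events", "gam"),
                          seed = 1L, dir = tempfile("fixtures")) {
  kind <- match.arg(kind)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (kind == "waveforms") {
    taus <- c(small = 1 / 2.763, medium = 5 / 2.763, large = 8 / 2.763)
    paths <- character(0)
    for (nm in names(taus)) {
      spec <- waveform_spec(sample_rate = 4000, duration = 60,
                            transients = data.frame(onset = 35, peak_db = 30,
                                                    tau = taus[[nm]]),
                            seed = seed)
      p <- file.path(dir, paste0("transient_", nm, ".wav"))
      write_wav(synthesize_waveform(spec), 4000, p)
      paths <- c(paths, p)
    }
    p <- file.path(dir, "noise_only.wav")
    write_wav(synthesize_waveform(waveform_spec(sample_rate = 4000,
                                                duration = 60, seed = seed)),
              4000, p)
    return(invisible(c(paths, p)))
  }
  if (kind == "events") {
    ev <- data.frame(event_id = 1:2,
                     first_undet_day = as.Date(c("2014-05-10", "2014-06-20")),
                     last_undet_day = as.Date(c("2014-05-10", "2014-06-22")))
    p <- file.path(dir, "events.csv")
    utils::write.csv(ev, p, row.names = FALSE)
    return(invisible(p))
  }
  if (kind == "counts") {
    ev <- data.frame(event_id = 1L,
                     first_undet_day = as.Date("2014-05-10"),
                     last_undet_day = as.Date("2014-05-10"))
    sched <- build_recording_schedule(as.POSIXct("2014-05-09", tz = "UTC"),
                                      as.POSIXct("2014-05-13", tz = "UTC"))
    params <- activity_params(seed = seed)
    counts <- simulate_counts(sched, params, ev)
    p <- file.path(dir, "counts.csv")
    write_segments_csv(counts, p)
    return(invisible(p))
  }
  # gam
  d <- simulate_gam_data(n = 2000, seed = seed)
  p <- file.path(dir, "gam_data.csv")
  utils::write.csv(d, p, row.names = FALSE)
  invisible(p)
}
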