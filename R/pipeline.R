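#' Pipeline run configuration
#'
#' Bundles every input and threshold of an end-to-end run so it can be
#' snapshotted alongside the outputs and replayed exactly.
#'
#' @param input either a list of [vital_record] / `sim_record` objects, or
#'   a simulation spec created by [sim_spec()].
#' @param model a fitted `stratum_model`, a directory to load one from, or
#'   `NULL` to fit from `train`.
#' @param train training source when `model` is `NULL`: a matrix of
#'   complete parameter vectors, or an integer number of stable vectors to
#'   simulate from the record's stratum profile.
#' @param control a [detect_control()] list.
#' @param cutoffs a [static_cutoffs()] object.
#' @param svm an [svm_config()].
#' @param seed integer master seed.
#' @param out_dir optional output directory for CSVs, the config snapshot
#'   and the run log.
#' @return A classed list.
#' @export
run_config <- function(input, model = NULL, train = 20000L,
                       control = detect_control(), cutoffs = static_cutoffs(),
                       svm = svm_config(), seed = 1L, out_dir = NULL) {
  structure(list(input = input, model = model, train = train,
                 control = control, cutoffs = cutoffs, svm = svm,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Simulation spec for [run_config()]
#'
#' @inheritParams simulate_record
#' @export
sim_spec <- function(stratum = "LOW_SAT", duration = 21600L, events = list(),
                     seed = 1L) {
  structure(list(stratum = stratum, duration = as.integer(duration),
                 events = events, seed = as.integer(seed)),
            class = "sim_spec")
}

#' Run the full detection pipeline
#'
#' Executes read/simulate, preprocessing, the three submodels, label
#' fusion, episode-window smoothing, segmentation and — when ground truth
#' is available — scoring. Deterministic for a given configuration and
#' seed. When `out_dir` is set, writes the label timeline, episode table,
#' diagnostic trace, dysfunction mask, performance report, a YAML config
#' snapshot and a run log.
#'
#' @param config a [run_config()].
#' @return list with `timelines` (per record), `scores`, `report`
#'   (a [performance_report()] or `NULL`), `model`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  input <- config$input
  if (inherits(input, "sim_spec"))
    input <- list(simulate_record(stratum = input$stratum,
                                  duration = input$duration,
                                  events = input$events, seed = input$seed,
                                  warmup = config$control$warmup))
  if (inherits(input, c("vital_record", "sim_record"))) input <- list(input)
  records <- lapply(input, function(x)
    if (inherits(x, "sim_record")) x$record else x)
  truths <- lapply(input, function(x)
    if (inherits(x, "sim_record")) x$truth else NULL)
  # resolve the stratum model
  model <- config$model
  if (is.character(model)) model <- read_stratum_model(model)
  if (is.null(model)) {
    if (is.null(config$train))
      stop("no fitted model and no training data supplied")
    stratum <- stratify(records[[1L]])
    x <- config$train
    if (is.numeric(x) && length(x) == 1L)
      x <- simulate_stable_vectors(as.integer(x), stratum_profile(stratum),
                                   seed = config$seed)
    model <- fit_stratum_model(x, stratum = stratum, cutoffs = config$cutoffs,
                               config = config$svm)
  }
  timelines <- lapply(records, classify_record, model = model,
                      control = config$control)
  scores <- NULL; report <- NULL
  if (all(!vapply(truths, is.null, logical(1)))) {
    scores <- Map(evaluate_timeline, timelines, truths)
    report <- performance_report(scores)
  }
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_along(timelines)) {
      pfx <- file.path(config$out_dir, sprintf("record%02d", i))
      write_timeline(timelines[[i]], paste0(pfx, "_timeline.csv"),
                     paste0(pfx, "_episodes.csv"))
      write.csv(timelines[[i]]$trace, paste0(pfx, "_trace.csv"),
                row.names = FALSE, quote = FALSE)
      write.csv(mask_table(timelines[[i]]$mask, timelines[[i]]$timeline$t),
                paste0(pfx, "_dysfunction.csv"), row.names = FALSE,
                quote = FALSE)
    }
    if (!is.null(report))
      write.csv(report, file.path(config$out_dir, "report.csv"),
                row.names = FALSE, quote = FALSE)
    snapshot_config(config, model, file.path(config$out_dir, "run_config.yaml"))
    writeLines(run_log_lines(config, records), file.path(config$out_dir, "run.log"))
  }
  list(timelines = timelines, scores = scores, report = report, model = model)
}

snapshot_config <- function(config, model, path) {
  snap <- list(
    seed = config$seed,
    control = unclass(config$control),
    cutoffs = lapply(unclass(model$cutoffs), as.numeric),
    svm = list(nu = model$config$nu, gamma = model$gamma,
               train_fraction = model$config$train_fraction,
               prefilter_percentile = model$config$prefilter_percentile,
               seed = model$config$seed),
    input = if (inherits(config$input, "sim_spec"))
      list(kind = "simulated", stratum = config$input$stratum,
           duration = config$input$duration, seed = config$input$seed,
           n_events = length(config$input$events))
    else list(kind = "records", n = length(config$input)))
  writeLines(yaml::as.yaml(snap), path)
  invisible(path)
}

run_log_lines <- function(config, records) {
  c(sprintf("vitalwatch %s | R %s", as.character(utils::packageVersion("vitalwatch")),
            paste(R.version$major, R.version$minor, sep = ".")),
    sprintf("run at %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
    sprintf("seed: %d", config$seed),
    vapply(records, function(r)
      sprintf("record %s: %d s, digest %s", r$patient_id, nrow(r$data),
              record_digest(r)), character(1)))
}

# dependency-free content digest (djb2 over the serialized CSV text)
record_digest <- function(record) {
  txt <- paste(capture_csv(record$data), collapse = "\n")
  h <- 5381
  for (v in utf8ToInt(txt)) h <- (h * 33 + v) %% 2^31
  sprintf("%08x", h)
}

capture_csv <- function(df) {
  tc <- textConnection("out", "w", local = TRUE)
  write.csv(df, tc, row.names = FALSE, na = "")
  close(tc)
  out
}
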