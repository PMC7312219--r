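# End-to-end orchestration: features are computed once and cached, a
# selector is run, and CSV reports plus a resolved-config snapshot and a
# run log are written to the output directory.

#' Pipeline run configuration
#'
#' Exactly one input source: a [synth_config()] or an EDF file plus a
#' seizure-interval CSV.
#'
#' @param synth A [synth_config()] (synthetic source), or `NULL`.
#' @param edf_path,intervals_path EDF recording and intervals CSV (real
#'   source), or `NULL`.
#' @param method Feature method, `"DWT"` or `"EMD"`.
#' @param selector `"nsga2"`, `"nsga3"`, `"backward"` or `"all_channels"`.
#' @param ga A [ga_config()].
#' @param portfolio A [portfolio_spec()].
#' @param k CV folds.
#' @param out_dir Output directory.
#' @param seed Seed for epoching/CV (GA randomness comes from `ga$seed`).
#' @param target_fs Down-sample EDF input to this rate (Hz) before
#'   epoching.
#' @param epoch_s Epoch length for EDF input.
#' @return Object of class `run_config`.
#' @export
run_config <- function(synth = NULL, edf_path = NULL, intervals_path = NULL,
                       method = c("DWT", "EMD"),
                       selector = c("nsga2", "nsga3", "backward",
                                    "all_channels"),
                       ga = ga_config(), portfolio = portfolio_spec(),
                       k = 10, out_dir = tempfile("eegselect_run_"),
                       seed = 1, target_fs = 128, epoch_s = 6) {
  method <- match.arg(method)
  selector <- match.arg(selector)
  has_synth <- !is.null(synth)
  has_edf <- !is.null(edf_path)
  if (has_synth == has_edf) {
    stop("exactly one input source: synth config OR edf_path", call. = FALSE)
  }
  if (has_synth) stopifnot(inherits(synth, "synth_config"))
  if (has_edf && is.null(intervals_path)) {
    stop("EDF input needs an intervals CSV", call. = FALSE)
  }
  structure(list(synth = synth, edf_path = edf_path,
                 intervals_path = intervals_path, method = method,
                 selector = selector, ga = ga, portfolio = portfolio,
                 k = k, out_dir = out_dir, seed = seed,
                 target_fs = target_fs, epoch_s = epoch_s),
            class = "run_config")
}

load_pipeline_epochs <- function(config) {
  if (!is.null(config$synth)) {
    generate_epochs(config$synth)
  } else {
    rec <- load_recording(config$edf_path)
    if (rec$fs > config$target_fs) {
      sig <- t(apply(rec$signals, 1L, downsample, fs_in = rec$fs,
                     fs_out = config$target_fs))
      rec <- recording(sig, config$target_fs, rec$channel_labels)
    }
    intervals <- read_intervals(config$intervals_path)
    epoch_and_label(rec, intervals, epoch_s = config$epoch_s,
                    seed = config$seed)
  }
}

# Features are cached as CSV keyed by the input source + feature settings,
# so repeated selector runs on the same data skip extraction.
feature_cache_key <- function(config, epochs) {
  src <- if (!is.null(config$synth)) {
    paste(unlist(config$synth), collapse = "|")
  } else {
    paste(config$edf_path, file.info(config$edf_path)$mtime,
          config$intervals_path, config$seed, sep = "|")
  }
  key <- paste(src, config$method, dim(epochs$data)[1],
               dim(epochs$data)[3], sep = "|")
  sprintf("features_%08x.csv",
          sum(utf8ToInt(key) * seq_along(utf8ToInt(key))) %% .Machine$integer.max)
}

#' Run the end-to-end channel-selection pipeline
#'
#' Loads or generates the epochs, computes (or reads back) the feature
#' table, runs the configured selector, and writes `pareto.csv`,
#' `history.csv`, `classifier_usage.csv`, `run.log` and `config.json` to
#' the output directory.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `archive` (data.frame), `out_dir`,
#'   `selector`, plus selector-specific elements.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_file <- file.path(config$out_dir, "run.log")
  cat(sprintf("[%s] pipeline start: selector=%s method=%s\n",
              format(Sys.time()), config$selector, config$method),
      file = log_file)
  epochs <- load_pipeline_epochs(config)
  cache_path <- file.path(config$out_dir, feature_cache_key(config, epochs))
  if (file.exists(cache_path)) {
    table <- read_feature_table(cache_path)
    cat("feature cache hit\n", file = log_file, append = TRUE)
  } else {
    table <- build_feature_table(epochs, method = config$method)
    write_feature_table(table, cache_path)
    cat("feature table computed and cached\n", file = log_file,
        append = TRUE)
  }
  evaluator <- make_evaluator(table, config$portfolio, k = config$k,
                              seed = config$seed, log_file = log_file)
  C <- n_channels(table)
  label_subset <- function(subset) {
    paste(table$channel_labels[subset], collapse = ";")
  }
  result <- list(selector = config$selector, out_dir = config$out_dir)
  if (config$selector %in% c("nsga2", "nsga3")) {
    variant <- if (config$selector == "nsga2") "II" else "III"
    run <- run_nsga(variant, table = table, config = config$ga,
                    evaluator = evaluator)
    archive <- run$archive
    usage <- data.frame(family = names(run$classifier_usage),
                        pct = as.numeric(run$classifier_usage))
    write.csv(run$history, file.path(config$out_dir, "history.csv"),
              row.names = FALSE)
    write.csv(usage, file.path(config$out_dir, "classifier_usage.csv"),
              row.names = FALSE)
    result$nsga <- run
  } else if (config$selector == "backward") {
    path <- backward_elimination(table = table, evaluator = evaluator)
    archive <- path
    archive$generation_found <- NA_integer_
    write.csv(data.frame(level = seq_len(nrow(path)), acc = path$acc,
                         evaluations = attr(path, "n_calls")),
              file.path(config$out_dir, "history.csv"), row.names = FALSE)
    result$path <- path
  } else {                               # all_channels baseline
    sc <- evaluator(seq_len(C))
    archive <- data.frame(no = C, acc = sc$accuracy,
                          sensitivity = sc$sensitivity,
                          specificity = sc$specificity,
                          classifier = sc$classifier_id,
                          subset = I(list(seq_len(C))),
                          generation_found = NA_integer_)
  }
  pareto <- data.frame(
    n_channels = archive$no,
    accuracy = archive$acc,
    sensitivity = archive$sensitivity,
    specificity = archive$specificity,
    classifier = archive$classifier,
    channel_labels = vapply(archive$subset, label_subset, ""),
    generation_found = if ("generation_found" %in% names(archive))
      archive$generation_found else NA_integer_
  )
  write.csv(pareto, file.path(config$out_dir, "pareto.csv"),
            row.names = FALSE)
  snapshot <- config
  snapshot$synth <- if (is.null(config$synth)) NULL else
    unclass(config$synth)
  snapshot$ga <- unclass(config$ga)
  snapshot$portfolio <- unclass(config$portfolio)
  jsonlite::write_json(unclass(snapshot),
                       file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  cat(sprintf("[%s] pipeline done\n", format(Sys.time())),
      file = log_file, append = TRUE)
  result$archive <- archive
  result$pareto <- pareto
  result$table <- table
  invisible(result)
}

#' Compare NSGA search against backward elimination
#'
#' Runs both selectors on the same feature table and aligns them by
#' subset size; channel counts absent from the NSGA archive are blank
#' (`NA`), as in per-patient result tables.
#'
#' @param config A [run_config()]; its `selector` chooses the NSGA variant
#'   (`"nsga3"` for NSGA-III, anything else means NSGA-II).
#' @return data.frame with columns `n_channels`, `accuracy_nsga`,
#'   `accuracy_backward`.
#' @export
compare_selectors <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  epochs <- load_pipeline_epochs(config)
  table <- build_feature_table(epochs, method = config$method)
  evaluator <- make_evaluator(table, config$portfolio, k = config$k,
                              seed = config$seed)
  variant <- if (config$selector == "nsga3") "III" else "II"
  run <- run_nsga(variant, table = table, config = config$ga,
                  evaluator = evaluator)
  path <- backward_elimination(table = table, evaluator = evaluator)
  C <- n_channels(table)
  out <- data.frame(n_channels = seq_len(C))
  out$accuracy_nsga <- run$archive$acc[match(out$n_channels,
                                             run$archive$no)]
  out$accuracy_backward <- path$acc[match(out$n_channels, path$no)]
  out <- out[out$n_channels <= C, ]
  write.csv(out, file.path(config$out_dir, "comparison.csv"),
            row.names = FALSE)
  out
}
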