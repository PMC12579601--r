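# Configuration, file I/O and the pipeline front end.

MEASUREMENT_COLUMNS <- c("experiment", "participant", "block", "trial",
                         "space", "inducer_hue_deg", "inducer_chroma",
                         "inducer_Lstar", "response_hue_deg",
                         "response_chroma", "skipped")

#' Read a measurements CSV
#'
#' Expects the documented dialect: UTF-8, header row, columns `experiment,
#' participant, block, trial, space, inducer_hue_deg, inducer_chroma,
#' inducer_Lstar, response_hue_deg, response_chroma, skipped` (0/1).
#' Skipped rows may leave the response fields empty. Malformed rows are
#' rejected with their line numbers.
#'
#' @param path file path.
#' @return data.frame of typed measurement records.
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) stop("measurements file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(MEASUREMENT_COLUMNS, names(df))
  if (length(missing))
    stop("measurements file lacks required column(s): ",
         paste(missing, collapse = ", "))
  df <- df[MEASUREMENT_COLUMNS]
  df$skipped <- as.integer(df$skipped)
  lines <- seq_len(nrow(df)) + 1L   # header is line 1
  bad <- !is.na(df$response_hue_deg) &
    (df$response_hue_deg < 0 | df$response_hue_deg >= 360)
  bad <- bad | (df$inducer_hue_deg < 0 | df$inducer_hue_deg >= 360)
  bad <- bad | !(df$skipped %in% c(0L, 1L))
  bad <- bad | (df$skipped == 1L & !is.na(df$response_hue_deg))
  if (any(bad, na.rm = TRUE))
    stop("malformed measurement row(s) at line(s): ",
         paste(lines[which(bad)], collapse = ", "))
  df
}

#' Write measurement records to CSV
#'
#' @param records measurement records (columns as in [read_measurements()]).
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_measurements <- function(records, path) {
  write.csv(records[MEASUREMENT_COLUMNS], path, row.names = FALSE,
            quote = FALSE, na = "")
  invisible(path)
}

#' Read a monitor/viewing configuration file
#'
#' YAML (or JSON) with exactly the fields of [monitor_model()]: `primaries`
#' (named xyY triples `red, green, blue`), `gamma`, `white` (xyY), and
#' `background_Lstar`.
#'
#' @param path file path.
#' @return a [monitor_model()].
#' @export
read_monitor_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  need <- c("primaries", "gamma", "white", "background_Lstar")
  missing <- setdiff(need, names(cfg))
  if (length(missing))
    stop("monitor config lacks field(s): ", paste(missing, collapse = ", "))
  monitor_model(red = as.numeric(cfg$primaries$red),
                green = as.numeric(cfg$primaries$green),
                blue = as.numeric(cfg$primaries$blue),
                gamma = cfg$gamma,
                white = as.numeric(cfg$white),
                background_Lstar = cfg$background_Lstar)
}

#' Write a monitor configuration file
#'
#' @param m a [monitor_model()].
#' @param path output YAML file.
#' @return the path, invisibly.
#' @export
write_monitor_config <- function(m, path) {
  yaml::write_yaml(list(
    primaries = list(red = as.numeric(m$primaries["red", ]),
                     green = as.numeric(m$primaries["green", ]),
                     blue = as.numeric(m$primaries["blue", ])),
    gamma = m$gamma,
    white = as.numeric(m$white),
    background_Lstar = m$background_Lstar), path)
  invisible(path)
}

#' Write model predictions to CSV
#'
#' One row per model x inducer: `model, space, inducer_hue_deg,
#' inducer_chroma, pred_hue_deg, pred_chroma`.
#'
#' @param predictions data.frame from [predict_afterimage()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  out <- data.frame(model = predictions$model, space = predictions$space,
                    inducer_hue_deg = signif(predictions$inducer_hue, 6),
                    inducer_chroma = signif(predictions$inducer_chroma, 6),
                    pred_hue_deg = signif(predictions$pred_hue, 6),
                    pred_chroma = signif(predictions$pred_chroma, 6))
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read predictions written by [write_predictions()]
#' @param path file path.
#' @return data.frame with the [predict_afterimage()] column names.
#' @export
read_predictions <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  data.frame(model = df$model, space = df$space,
             inducer_hue = df$inducer_hue_deg,
             inducer_chroma = df$inducer_chroma,
             pred_hue = df$pred_hue_deg, pred_chroma = df$pred_chroma)
}

run_metadata <- function(cfg, seed) {
  list(package = "coneadapt",
       version = as.character(utils::packageVersion("coneadapt")),
       seed = seed,
       cone_fundamentals = cfg$cones$name,
       xyz2lms = as.numeric(cfg$cones$xyz2lms),
       timestamp_format = "none (deterministic outputs)")
}

#' Run the analysis pipeline
#'
#' A thin front end tying the modules together. Commands:
#' * `"predict"`: model predictions over a hue circle -> predictions CSV.
#' * `"simulate"`: synthetic-observer dataset -> measurements CSV.
#' * `"analyze"`: compare measurements with one model's predictions
#'   (deviation-from-opponency correlation, chroma correlation, histogram
#'   correlation) -> JSON report.
#' * `"compare"`: per-model error tables and sign tests against the first
#'   model -> JSON report.
#'
#' @param command one of `"predict"`, `"simulate"`, `"analyze"`,
#'   `"compare"`.
#' @param m a [monitor_model()].
#' @param cfg an [adaptation_config()].
#' @param models model labels (for predict/compare; first = reference).
#' @param inducers inducer specs; default 72-hue circle at chroma 50.
#' @param observer an [observer_config()] (simulate).
#' @param measurements measurement records or path (analyze/compare).
#' @param out output file path (CSV for predict/simulate, JSON for
#'   analyze/compare); `NULL` returns the object only.
#' @param sigma_hue response-noise sigma for histogram simulation; default
#'   estimated from the measured deviations.
#' @param seed seed recorded and used for histogram simulation.
#' @param ... passed to [predict_afterimage()] (`prototypes`, `munsell`).
#' @return the computed object (predictions, records, or report list),
#'   invisibly when written to `out`.
#' @export
run_pipeline <- function(command = c("predict", "simulate", "analyze",
                                     "compare"),
                         m = monitor_model(), cfg = adaptation_config(),
                         models = c("cone", "dkl"), inducers = NULL,
                         observer = observer_config(),
                         measurements = NULL, out = NULL,
                         sigma_hue = NULL, seed = 1L, ...) {
  command <- match.arg(command)
  if (is.null(inducers)) inducers <- hue_circle_set(5, 50, "luv", m)
  meta <- run_metadata(cfg, seed)
  if (command == "predict") {
    pred <- predict_afterimage(inducers, models, m, cfg, ...)
    if (!is.null(out)) { write_predictions(pred, out); return(invisible(pred)) }
    return(pred)
  }
  if (command == "simulate") {
    rec <- simulate_exp2_adjustment(inducers, observer, m, adaptation = cfg,
                                    ...)
    if (!is.null(out)) { write_measurements(rec, out); return(invisible(rec)) }
    return(rec)
  }
  if (is.character(measurements)) measurements <- read_measurements(measurements)
  if (is.null(measurements))
    stop("stage 'analyze/compare': measurements are required")
  agg <- aggregate_measurements(measurements)
  pred <- predict_afterimage(inducers, models, m, cfg, ...)
  if (is.null(sigma_hue)) {
    devs <- deviation_from_opponency(measurements$response_hue_deg,
                                     measurements$inducer_hue_deg)
    sigma_hue <- stats::sd(devs, na.rm = TRUE)
  }
  if (command == "analyze") {
    ref <- pred[pred$model == models[1], ]
    i <- match(round(agg$inducer_hue, 6), round(ref$inducer_hue, 6))
    ref <- ref[i, ]
    dev_m <- deviation_from_opponency(agg$matched_hue, agg$inducer_hue)
    dev_p <- deviation_from_opponency(ref$pred_hue, ref$inducer_hue)
    hist_m <- hue_histogram(measurements$response_hue_deg[
      !measurements$skipped], n_bins = 24)
    hc <- histogram_model_correlation(hist_m, ref$pred_hue, sigma_hue,
                                      seed = seed)
    chroma_cor <- if (!all(is.na(agg$matched_chroma)) &&
                      !all(is.na(ref$pred_chroma)))
      unclass(pearson_fisher_ci(agg$matched_chroma, ref$pred_chroma))
    else NULL
    report <- list(
      metadata = meta,
      model = models[1],
      n_inducers = nrow(agg),
      sigma_hue = sigma_hue,
      deviation_correlation = unclass(pearson_fisher_ci(dev_m, dev_p)),
      smoothed_variance_explained_pct =
        smoothed_variance_explained(dev_m, dev_p),
      chroma_correlation = chroma_cor,
      histogram_correlation = unclass(hc$correlation),
      hue_clusters = hue_clusters(hist_m))
  } else {
    err <- model_prediction_errors(agg, pred)
    mean_tbl <- do.call(rbind, lapply(split(err, err$model), function(d)
      data.frame(model = d$model[1],
                 mean_abs_hue_error = mean(d$hue_error),
                 mean_abs_chroma_error = mean(d$chroma_error))))
    ref <- models[1]
    signs <- lapply(setdiff(models, ref), function(mod) {
      sh <- compare_models_sign(err$hue_error[err$model == ref],
                                err$hue_error[err$model == mod])
      ce_ref <- err$chroma_error[err$model == ref]
      ce_mod <- err$chroma_error[err$model == mod]
      sc <- if (!all(is.na(ce_ref)) && !all(is.na(ce_mod)))
        unclass(compare_models_sign(ce_ref, ce_mod)) else NULL
      list(model = mod, hue = unclass(sh), chroma = sc)
    })
    report <- list(metadata = meta, reference_model = ref,
                   mean_errors = mean_tbl, sign_tests = signs)
  }
  if (!is.null(out)) {
    jsonlite::write_json(report, out, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
    return(invisible(report))
  }
  report
}
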