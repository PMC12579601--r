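# Synthetic psychophysical observers.
#
# Generates simulated datasets with the statistical structure the analyses
# assume: a generative "truth" model provides the afterimage colour for each
# inducer, and responses are that truth plus wrapped-Gaussian hue noise and
# rectified-Gaussian chroma noise (plus a skip probability for the
# forced-choice matching task).

#' Synthetic observer configuration
#'
#' @param truth_model prediction model generating the true afterimages (see
#'   [predict_afterimage()]).
#' @param sigma_hue wrapped-Gaussian response noise on hue (degrees).
#' @param sigma_chroma Gaussian response noise on chroma (truncated at 0).
#' @param p_skip probability of skipping a forced-choice trial.
#' @param n_participants simulated participants.
#' @param n_reps repetitions per inducer and participant.
#' @param seed integer seed; identical configurations yield identical
#'   records.
#' @return object of class `observer_config`.
#' @export
observer_config <- function(truth_model = "cone", sigma_hue = 10,
                            sigma_chroma = 5, p_skip = 0.02,
                            n_participants = 1L, n_reps = 1L, seed = 1L) {
  stopifnot(sigma_hue >= 0, sigma_chroma >= 0,
            p_skip >= 0, p_skip <= 1,
            n_participants >= 1, n_reps >= 1)
  structure(list(truth_model = truth_model, sigma_hue = sigma_hue,
                 sigma_chroma = sigma_chroma, p_skip = p_skip,
                 n_participants = as.integer(n_participants),
                 n_reps = as.integer(n_reps), seed = as.integer(seed)),
            class = "observer_config")
}

measurement_frame <- function(experiment, participant, block, trial, spec,
                              response_hue, response_chroma, skipped) {
  data.frame(experiment = experiment, participant = participant,
             block = block, trial = trial,
             space = spec$space,
             inducer_hue_deg = spec$hue,
             inducer_chroma = spec$chroma,
             inducer_Lstar = spec$Lstar,
             response_hue_deg = response_hue,
             response_chroma = response_chroma,
             skipped = as.integer(skipped),
             stringsAsFactors = FALSE)
}

truth_predictions <- function(inducers, cfg, m, adaptation, ...) {
  predict_afterimage(inducers, cfg$truth_model, m, cfg = adaptation, ...)
}

#' Simulate the nine-alternative afterimage matching task
#'
#' Per participant x inducer x repetition: the perceived afterimage hue is
#' the truth model's prediction plus wrapped-Gaussian noise; the response is
#' the comparison hue (opponent hue +/- 0, 10, ..., 40 degrees) closest in
#' circular distance (ties to the lower azimuth). Trials are skipped with
#' probability `p_skip`, yielding missing responses.
#'
#' @param inducers inducer spec data.frame.
#' @param cfg an [observer_config()].
#' @param m a [monitor_model()].
#' @param adaptation the [adaptation_config()] used for the truth model's
#'   predictions.
#' @param comparison_chroma chroma of the comparison colours (default 30).
#' @param ... passed to [predict_afterimage()] (e.g. `prototypes`, `axes`).
#' @return measurement records: one row per trial with the columns of the
#'   measurements CSV dialect (see [read_measurements()]).
#' @export
simulate_exp1_matching <- function(inducers, cfg, m = monitor_model(),
                                   adaptation = adaptation_config(),
                                   comparison_chroma = 30, ...) {
  pred <- truth_predictions(inducers, cfg, m, adaptation, ...)
  set.seed(cfg$seed)
  out <- vector("list", cfg$n_participants)
  for (p in seq_len(cfg$n_participants)) {
    rows <- vector("list", cfg$n_reps)
    for (rep in seq_len(cfg$n_reps)) {
      true_hue <- wrap_hue(pred$pred_hue +
                             rnorm(nrow(pred), 0, cfg$sigma_hue))
      resp <- vapply(seq_len(nrow(inducers)), function(i) {
        comps <- comparison_set(inducers[i, , drop = FALSE],
                                comparison_chroma, m = m)$hue
        d <- abs(circular_signed_difference(true_hue[i], comps))
        cand <- comps[d == min(d)]
        min(cand)                       # tie -> lower azimuth
      }, numeric(1))
      skip <- runif(nrow(inducers)) < cfg$p_skip
      rows[[rep]] <- measurement_frame(
        "exp1", sprintf("sim%02d", p), rep, seq_len(nrow(inducers)),
        inducers,
        ifelse(skip, NA_real_, resp), NA_real_, skip)
    }
    out[[p]] <- do.call(rbind, rows)
  }
  do.call(rbind, out)
}

#' Simulate the hue/chroma adjustment task
#'
#' Continuous matches: hue = truth prediction + wrapped-Gaussian noise,
#' chroma = truth prediction + Gaussian noise truncated at zero.
#'
#' @inheritParams simulate_exp1_matching
#' @return measurement records, one row per adjustment.
#' @export
simulate_exp2_adjustment <- function(inducers, cfg, m = monitor_model(),
                                     adaptation = adaptation_config(), ...) {
  pred <- truth_predictions(inducers, cfg, m, adaptation, ...)
  set.seed(cfg$seed)
  out <- vector("list", cfg$n_participants)
  n <- nrow(pred)
  for (p in seq_len(cfg$n_participants)) {
    rows <- vector("list", cfg$n_reps)
    for (rep in seq_len(cfg$n_reps)) {
      hue <- wrap_hue(pred$pred_hue + rnorm(n, 0, cfg$sigma_hue))
      chroma <- pmax(0, pred$pred_chroma + rnorm(n, 0, cfg$sigma_chroma))
      rows[[rep]] <- measurement_frame(
        "exp2", sprintf("sim%02d", p), rep, seq_len(n), inducers,
        hue, chroma, FALSE)
    }
    out[[p]] <- do.call(rbind, rows)
  }
  do.call(rbind, out)
}

#' Simulate the chroma-series adjustment experiment
#'
#' Adjustment-style records across a hue x chroma-level grid (see
#' [chroma_series_set()]).
#'
#' @param hues inducer hue azimuths.
#' @param levels chroma levels (numeric and/or `"max"`).
#' @inheritParams simulate_exp1_matching
#' @return measurement records.
#' @export
simulate_exp3_series <- function(hues, levels, cfg, m = monitor_model(),
                                 adaptation = adaptation_config(adapt_chroma_luv = NA),
                                 ...) {
  inducers <- chroma_series_set(hues, levels, m)
  rec <- simulate_exp2_adjustment(inducers, cfg, m, adaptation, ...)
  rec$experiment <- "exp3"
  rec
}

#' Aggregate measurement records per inducer
#'
#' Pools repeated adjustments within participant by circular mean (chroma by
#' arithmetic mean), then across participants by circular mean; skipped
#' trials are dropped. Set `pool = "all"` to pool all trials in one pass.
#'
#' @param records measurement records (see [read_measurements()]).
#' @param pool `"by_participant"` (default) or `"all"`.
#' @return data.frame with one row per inducer: `inducer_hue,
#'   inducer_chroma, matched_hue, matched_chroma, n`.
#' @export
aggregate_measurements <- function(records,
                                   pool = c("by_participant", "all")) {
  pool <- match.arg(pool)
  rec <- records[!records$skipped & !is.na(records$response_hue_deg), ]
  key <- paste(round(rec$inducer_hue_deg, 6), round(rec$inducer_chroma, 6))
  agg_one <- function(d) {
    data.frame(inducer_hue = d$inducer_hue_deg[1],
               inducer_chroma = d$inducer_chroma[1],
               matched_hue = circular_mean_hue(d$response_hue_deg),
               matched_chroma = if (all(is.na(d$response_chroma)))
                 NA_real_ else mean(d$response_chroma, na.rm = TRUE),
               n = nrow(d))
  }
  out <- lapply(split(rec, key), function(d) {
    if (pool == "by_participant" && length(unique(d$participant)) > 1) {
      per <- lapply(split(d, d$participant), agg_one)
      per <- do.call(rbind, per)
      data.frame(inducer_hue = per$inducer_hue[1],
                 inducer_chroma = per$inducer_chroma[1],
                 matched_hue = circular_mean_hue(per$matched_hue),
                 matched_chroma = if (all(is.na(per$matched_chroma)))
                   NA_real_ else mean(per$matched_chroma, na.rm = TRUE),
                 n = sum(per$n))
    } else agg_one(d)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$inducer_chroma, out$inducer_hue), ]
  rownames(out) <- NULL
  out
}

#' Model-recovery harness
#'
#' For each observer configuration, simulates an adjustment dataset, runs
#' the model-comparison pipeline (per-inducer absolute hue errors for each
#' candidate model), and reports which model wins (lowest mean absolute hue
#' error) together with sign tests of every other model against the winner.
#'
#' @param cfgs list of [observer_config()]s (or a single one).
#' @param models candidate model labels (>= 2).
#' @param inducers inducer spec data.frame (default: the 72-hue circle at
#'   chroma 50).
#' @param m a [monitor_model()].
#' @param ... passed to [predict_afterimage()] for both truth and candidate
#'   predictions.
#' @return data.frame with one row per configuration x non-winning model:
#'   `seed, truth_model, winner, model, S, n, p` (sign test of that model
#'   against the winner).
#' @export
run_model_recovery <- function(cfgs, models = c("cone", "dkl"),
                               inducers = NULL, m = monitor_model(),
                               adaptation = adaptation_config(), ...) {
  if (inherits(cfgs, "observer_config")) cfgs <- list(cfgs)
  if (length(models) < 2) stop("need at least 2 candidate models")
  if (is.null(inducers)) inducers <- hue_circle_set(5, 50, "luv", m)
  pred <- predict_afterimage(inducers, models, m, cfg = adaptation, ...)
  rows <- lapply(cfgs, function(cfg) {
    rec <- simulate_exp2_adjustment(inducers, cfg, m, adaptation, ...)
    agg <- aggregate_measurements(rec)
    err <- model_prediction_errors(agg, pred)
    mean_err <- tapply(err$hue_error, err$model, mean)
    winner <- names(which.min(mean_err))
    losers <- setdiff(names(mean_err), winner)
    do.call(rbind, lapply(losers, function(mod) {
      st <- compare_models_sign(err$hue_error[err$model == winner],
                                err$hue_error[err$model == mod])
      data.frame(seed = cfg$seed, truth_model = cfg$truth_model,
                 winner = winner, model = mod,
                 S = st$S, n = st$n, p = st$p)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
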