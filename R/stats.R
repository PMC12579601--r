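# Circular-statistics analysis pipeline for afterimage measurements.

#' Deviation of a matched hue from the cone-opponent hue
#'
#' Signed circular difference between the matched afterimage hue and the hue
#' directly opposite the inducer (`inducer + 180`), in (-180, 180].
#'
#' @param matched_hue,inducer_hue hue azimuths in degrees.
#' @return signed deviations in degrees.
#' @examples
#' deviation_from_opponency(250, 60) # +10
#' @export
deviation_from_opponency <- function(matched_hue, inducer_hue) {
  circular_signed_difference(matched_hue, inducer_hue + 180)
}

#' Circular (resultant-vector) mean of hue angles
#'
#' @param hues hue azimuths in degrees; `NA`s are dropped.
#' @return mean azimuth in `[0, 360)`.
#' @export
circular_mean_hue <- function(hues) {
  hues <- hues[!is.na(hues)]
  if (!length(hues)) stop("no hues to average")
  s <- mean(sin(deg2rad(hues)))
  c_ <- mean(cos(deg2rad(hues)))
  if (sqrt(s^2 + c_^2) < 1e-12)
    stop("circular mean undefined: zero resultant vector")
  wrap_hue(rad2deg(atan2(s, c_)))
}

# circular standard deviation (degrees), via the resultant length
circular_sd_hue <- function(hues) {
  hues <- hues[!is.na(hues)]
  R <- sqrt(mean(sin(deg2rad(hues)))^2 + mean(cos(deg2rad(hues)))^2)
  rad2deg(sqrt(-2 * log(R)))
}

#' Circular hue histogram
#'
#' Counts hues in uniform bins tiling `[0, 360)`, left-closed right-open,
#' first edge at 0.
#'
#' @param hues hue azimuths in degrees; `NA`s (skipped trials) are dropped.
#' @param n_bins number of bins; must divide 360.
#' @param normalize divide counts by the total so they sum to 1.
#' @return object of class `hue_histogram`: list with `breaks` (bin edges),
#'   `mids`, `counts`, `n`.
#' @export
hue_histogram <- function(hues, n_bins = 24, normalize = FALSE) {
  if (360 %% n_bins != 0) stop("n_bins must divide 360")
  hues <- wrap_hue(hues[!is.na(hues)])
  width <- 360 / n_bins
  idx <- floor(hues / width) + 1L
  counts <- tabulate(idx, nbins = n_bins)
  n <- length(hues)
  if (normalize) {
    if (n == 0) stop("cannot normalize an empty histogram")
    counts <- counts / n
  }
  structure(list(breaks = seq(0, 360, by = width),
                 mids = seq(width / 2, 360 - width / 2, by = width),
                 counts = counts, n = n, normalized = normalize),
            class = "hue_histogram")
}

#' Circular running mean
#'
#' Centre-aligned running mean with wrap-around, e.g. across 9 adjacent hue
#' bins. Preserves the series total.
#'
#' @param values numeric vector indexed by circularly adjacent bins.
#' @param window odd window length, at most `length(values)`.
#' @return smoothed vector of the same length.
#' @export
smooth_circular <- function(values, window = 9) {
  n <- length(values)
  if (window %% 2 == 0) stop("window must be odd")
  if (window > n) stop("window exceeds the number of bins")
  half <- (window - 1) / 2
  idx <- outer(seq_len(n), -half:half, `+`)
  idx <- ((idx - 1) %% n) + 1
  rowMeans(matrix(values[idx], nrow = n))
}

#' Pearson correlation with Fisher-transform confidence interval
#'
#' @param x,y equal-length numeric vectors (n >= 3, non-constant).
#' @param conf confidence level (default 0.95).
#' @return list of class `correlation_result` with `r`, `df`, `ci_low`,
#'   `ci_high` (Fisher z interval), `p` (two-tailed, t distribution), `n`.
#' @export
pearson_fisher_ci <- function(x, y, conf = 0.95) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0)
    stop("degenerate correlation: constant input")
  ct <- cor.test(x, y, conf.level = conf)   # Fisher z interval
  structure(list(r = unname(ct$estimate), df = unname(ct$parameter),
                 ci_low = ct$conf.int[1], ci_high = ct$conf.int[2],
                 p = ct$p.value, n = length(x)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("r(%d) = %.3f, CI95%% [%.3f, %.3f], p = %.3g\n",
              x$df, x$r, x$ci_low, x$ci_high, x$p))
  invisible(x)
}

#' One-sample t test of hue deviations against zero
#'
#' Used per inducer to test whether signed deviations from the cone-opponent
#' hue differ from 0 across participants. Cohen's d is `mean / sd = t /
#' sqrt(n)`; the Bonferroni-corrected alpha for the test family is reported
#' alongside.
#'
#' @param deviations signed deviations (degrees), one per participant.
#' @param n_tests_for_alpha size of the test family for the Bonferroni
#'   correction (default 1, i.e. alpha = 0.05).
#' @return list of class `t_test_result` with `t, df, ci_low, ci_high, p, d,
#'   mean, alpha`.
#' @export
one_sample_deviation_test <- function(deviations, n_tests_for_alpha = 1L) {
  deviations <- deviations[!is.na(deviations)]
  if (length(deviations) < 2) stop("need at least 2 deviations")
  if (sd(deviations) <= 1e-12 * max(1, abs(mean(deviations))))
    stop("degenerate test: zero variance in deviations")
  tt <- t.test(deviations)
  structure(list(t = unname(tt$statistic), df = unname(tt$parameter),
                 ci_low = tt$conf.int[1], ci_high = tt$conf.int[2],
                 p = tt$p.value,
                 d = mean(deviations) / sd(deviations),
                 mean = mean(deviations),
                 alpha = 0.05 / n_tests_for_alpha),
            class = "t_test_result")
}

#' @export
print.t_test_result <- function(x, ...) {
  cat(sprintf("t(%g) = %.2f, CI95%% [%.2f, %.2f], p = %.3g, d = %.2f\n",
              x$df, x$t, x$ci_low, x$ci_high, x$p, x$d))
  invisible(x)
}

#' z-score a vector (sample-sd convention)
#'
#' @param values numeric vector (n >= 2, non-constant).
#' @return values centred to mean 0 and scaled to sd 1 (denominator n - 1).
#' @export
zscore <- function(values) {
  if (length(values) < 2) stop("need at least 2 values")
  s <- sd(values)
  if (s == 0) stop("cannot z-score a constant vector")
  (values - mean(values)) / s
}

#' Per-inducer prediction errors for a set of models
#'
#' Aligns per-inducer aggregated measurements with model predictions and
#' returns, per model and inducer, the absolute circular hue error and (for
#' chroma-predicting models) the absolute difference of z-scored chromas.
#' Chroma is z-scored within measurement set and within model across
#' inducers, so only hue-dependent variation is compared.
#'
#' @param measurements data.frame with columns `inducer_hue`, `matched_hue`,
#'   and optionally `matched_chroma` (one row per inducer).
#' @param predictions data.frame as returned by [predict_afterimage()]
#'   (columns `model, inducer_hue, pred_hue, pred_chroma`).
#' @return data.frame with columns `model, inducer_hue, hue_error,
#'   chroma_error` (`NA` chroma error where a model predicts no chroma).
#' @export
model_prediction_errors <- function(measurements, predictions) {
  out <- lapply(split(predictions, predictions$model), function(pr) {
    i <- match(round(measurements$inducer_hue, 6), round(pr$inducer_hue, 6))
    if (anyNA(i))
      stop("prediction and measurement inducer sets are not aligned")
    pr <- pr[i, ]
    hue_error <- abs(circular_signed_difference(pr$pred_hue,
                                                measurements$matched_hue))
    chroma_error <- rep(NA_real_, nrow(pr))
    if (!all(is.na(pr$pred_chroma)) &&
        !is.null(measurements$matched_chroma) &&
        !all(is.na(measurements$matched_chroma))) {
      chroma_error <- abs(zscore(pr$pred_chroma) -
                            zscore(measurements$matched_chroma))
    }
    data.frame(model = pr$model, inducer_hue = measurements$inducer_hue,
               hue_error = hue_error, chroma_error = chroma_error)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Paired t test comparing two models' prediction errors
#'
#' Tests per-participant mean absolute errors of model B against model A
#' (positive mean difference = B worse). Cohen's d is for paired
#' differences, `mean(diff) / sd(diff)`.
#'
#' @param errors_model_A,errors_model_B paired error vectors (one entry per
#'   participant).
#' @return a `t_test_result` (see [one_sample_deviation_test()]) for B - A.
#' @export
compare_models_paired_t <- function(errors_model_A, errors_model_B) {
  d <- errors_model_B - errors_model_A
  one_sample_deviation_test(d)
}

#' Exact sign test comparing two models' prediction errors
#'
#' Counts the inducers on which model B's error exceeds model A's and tests
#' that count against an exact binomial null (p = 0.5, two-tailed). Ties are
#' dropped and reported.
#'
#' @param errors_model_A,errors_model_B paired error vectors (one entry per
#'   inducer).
#' @return list of class `sign_test_result` with `n` (untied pairs), `S`
#'   (count with B worse), `p`, `ties`.
#' @export
compare_models_sign <- function(errors_model_A, errors_model_B) {
  d <- errors_model_B - errors_model_A
  d <- d[!is.na(d)]
  ties <- sum(d == 0)
  d <- d[d != 0]
  if (!length(d)) stop("degenerate sign test: all pairs tied")
  S <- sum(d > 0)
  bt <- binom.test(S, length(d), p = 0.5)
  structure(list(n = length(d), S = S, p = bt$p.value, ties = ties),
            class = "sign_test_result")
}

#' @export
print.sign_test_result <- function(x, ...) {
  cat(sprintf("sign test: S = %d of n = %d, p = %.3g (%d ties dropped)\n",
              x$S, x$n, x$p, x$ties))
  invisible(x)
}

#' Percentage of variance explained against circularly smoothed data
#'
#' `100 * r^2` where `r` is the Pearson correlation between the smoothed
#' measured series (circular running mean, default 9 neighbours) and the
#' simulated/predicted series — a rough indicator of model fit with
#' measurement noise minimised.
#'
#' @param measured,simulated aligned numeric series over circularly adjacent
#'   bins or inducers.
#' @param window smoothing window (odd).
#' @return percentage in `[0, 100]`.
#' @export
smoothed_variance_explained <- function(measured, simulated, window = 9) {
  sm <- smooth_circular(measured, window)
  r <- pearson_fisher_ci(sm, simulated)$r
  100 * r^2
}

#' Correlate a measured hue histogram with a noise-convolved model histogram
#'
#' Simulates the model's hue histogram by drawing wrapped-Gaussian response
#' noise around each predicted hue (many draws, normalized) and correlates
#' it bin-wise with the measured histogram.
#'
#' @param measured a [hue_histogram()].
#' @param pred_hue vector of predicted hues (one per inducer).
#' @param sigma_hue response-noise standard deviation in degrees.
#' @param n_draws Monte-Carlo draws per prediction (default 1e5).
#' @param seed integer seed for the simulation.
#' @return list with the `correlation_result` (`$correlation`) and the
#'   simulated histogram (`$simulated`).
#' @export
histogram_model_correlation <- function(measured, pred_hue, sigma_hue,
                                        n_draws = 1e5, seed = NULL) {
  stopifnot(inherits(measured, "hue_histogram"))
  n_bins <- length(measured$counts)
  draws <- add_response_noise(pred_hue, sigma_hue, n_draws, seed)
  sim <- hue_histogram(draws, n_bins, normalize = TRUE)
  meas <- measured$counts
  if (!measured$normalized) meas <- meas / measured$n
  list(correlation = pearson_fisher_ci(meas, sim$counts),
       simulated = sim)
}

#' Count hue clusters in a histogram
#'
#' A cluster is a circular local maximum of the lightly smoothed histogram
#' whose density exceeds `prominence` times the deepest trough of the
#' smoothed density. The relative (peak-to-trough) criterion separates
#' genuinely multi-modal hue distributions from Poisson fluctuations on a
#' flat one: the cone-adaptation model compresses hues towards three
#' directions with peak/trough density ratios above about 1.5, whereas
#' counting noise at study-scale trial numbers keeps a uniform histogram's
#' smoothed max/min ratio near 1.2.
#'
#' @param hist a [hue_histogram()].
#' @param window smoothing window (odd; default 3 bins, i.e. 45 degrees at
#'   24 bins — narrow enough to keep peaks ~120 degrees apart distinct).
#' @param prominence minimum peak density relative to the deepest smoothed
#'   trough (default 1.35).
#' @return integer number of clusters.
#' @export
hue_clusters <- function(hist, window = 3, prominence = 1.35) {
  stopifnot(inherits(hist, "hue_histogram"))
  dens <- hist$counts
  if (!hist$normalized) dens <- dens / hist$n
  sm <- smooth_circular(dens, window)
  n <- length(sm)
  prev <- sm[c(n, 1:(n - 1))]
  nxt <- sm[c(2:n, 1)]
  is_max <- sm > prev & sm >= nxt
  trough <- min(sm)
  if (trough <= 0) return(sum(is_max))
  sum(is_max & sm >= prominence * trough)
}

#' Chroma-series analysis: hue changes across inducer chroma
#'
#' For each inducer hue measured at several chroma levels, the circular mean
#' of the measured (respectively predicted) afterimage hues across levels
#' defines a hue-specific reference line. Returns per-record deviations of
#' measurements and predictions (a) from the cone-opponent hue and (b) from
#' their respective reference lines, plus the two measured-versus-predicted
#' correlations.
#'
#' @param measurements data.frame with columns `inducer_hue,
#'   inducer_chroma, matched_hue` (aggregated, one row per inducer).
#' @param predictions data.frame with columns `inducer_hue, inducer_chroma,
#'   pred_hue` aligned to the same hue x chroma grid.
#' @return list with `records` (per-record deviations), `cor_opponency`,
#'   `cor_reference` (both `correlation_result`s), and `excluded_hues`
#'   (inducer hues with fewer than 2 chroma levels, dropped with a warning).
#' @export
chroma_series_analysis <- function(measurements, predictions) {
  key <- function(d) paste(round(d$inducer_hue, 6), round(d$inducer_chroma, 6))
  i <- match(key(measurements), key(predictions))
  if (anyNA(i)) stop("measurement and prediction grids are not aligned")
  pred <- predictions[i, ]
  levels_per_hue <- table(round(measurements$inducer_hue, 6))
  excluded <- as.numeric(names(levels_per_hue)[levels_per_hue < 2])
  if (length(excluded))
    warning("excluding inducer hue(s) with a single chroma level: ",
            paste(excluded, collapse = ", "))
  keep <- !(round(measurements$inducer_hue, 6) %in% round(excluded, 6))
  meas <- measurements[keep, ]
  pred <- pred[keep, ]
  ref_of <- function(hue_col, by) {
    ave_ <- tapply(hue_col, round(by, 6), circular_mean_hue)
    ave_[as.character(round(by, 6))]
  }
  ref_meas <- ref_of(meas$matched_hue, meas$inducer_hue)
  ref_pred <- ref_of(pred$pred_hue, pred$inducer_hue)
  rec <- data.frame(
    inducer_hue = meas$inducer_hue,
    inducer_chroma = meas$inducer_chroma,
    dev_opp_measured = deviation_from_opponency(meas$matched_hue,
                                                meas$inducer_hue),
    dev_opp_predicted = deviation_from_opponency(pred$pred_hue,
                                                 pred$inducer_hue),
    dev_ref_measured = circular_signed_difference(meas$matched_hue,
                                                  unname(ref_meas)),
    dev_ref_predicted = circular_signed_difference(pred$pred_hue,
                                                   unname(ref_pred)))
  # degenerate (constant) series arise for noise-free or chroma-flat input;
  # report NULL rather than a correlation in that case
  safe_cor <- function(x, y) tryCatch(pearson_fisher_ci(x, y),
                                      error = function(e) NULL)
  list(records = rec,
       cor_opponency = safe_cor(rec$dev_opp_measured, rec$dev_opp_predicted),
       cor_reference = safe_cor(rec$dev_ref_measured, rec$dev_ref_predicted),
       excluded_hues = excluded)
}
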