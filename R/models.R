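# Afterimage prediction models.
#
# Every model answers the same question: what colour does the neutral grey
# probe take on after local adaptation to an inducer, once re-embedded under
# global adaptation to the grey background? Predictions are reported as
# CIELUV hue azimuth and chroma so that all models share a common frame.

MODEL_LABELS <- c("cone", "dkl", "cieluv", "cielab", "ciecam02",
                  "munsell", "hering")

#' Adaptation configuration
#'
#' Collects the parameters shared by the prediction models.
#'
#' Adaptation to the inducer is partial: the effective adapting colour keeps
#' the inducer's hue but its chroma is replaced by the adaptation strength —
#' 27.0 CIELUV chroma units (the grand average chroma of afterimage
#' adjustments) for CIELUV-sampled inducers, 0.47 gamut-scaled radius for
#' DKL-sampled inducers. Setting a strength to `NA` requests complete
#' adaptation (effective colour = inducer).
#'
#' @param adapt_chroma_luv effective adapting chroma in CIELUV units
#'   (default 27.0; `NA` = complete adaptation).
#' @param adapt_radius_dkl effective adapting radius in gamut-scaled DKL
#'   units (default 0.47; `NA` = complete adaptation).
#' @param k optional explicit strength for the cone-opponent model; when
#'   `NULL` (default) the opponent prediction is the reflection of the
#'   effective adapting colour, i.e. k = strength / inducer chroma.
#' @param halfwave_rectify compute the opponent model through half-wave
#'   rectified single-signed mechanisms (a no-effect variant kept for
#'   completeness).
#' @param project_to_background_Lstar project predicted chromaticities onto
#'   the background-L* plane before computing chroma (default `TRUE`; hue is
#'   unaffected).
#' @param surround CAT02 viewing parameters: list with `F` (surround factor,
#'   1 = average), `La_div` (adapting luminance = background luminance /
#'   `La_div`), and optional fixed `D` overriding the CIECAM02 degree of
#'   adaptation.
#' @param cones a [cone_fundamentals()] object; reported in output metadata.
#' @return an object of class `adaptation_config`.
#' @export
adaptation_config <- function(adapt_chroma_luv = 27.0,
                              adapt_radius_dkl = 0.47,
                              k = NULL,
                              halfwave_rectify = FALSE,
                              project_to_background_Lstar = TRUE,
                              surround = list(F = 1, La_div = 5, D = NULL),
                              cones = cone_fundamentals()) {
  stopifnot(is.na(adapt_chroma_luv) || adapt_chroma_luv >= 0,
            is.na(adapt_radius_dkl) || adapt_radius_dkl >= 0)
  structure(list(adapt_chroma_luv = adapt_chroma_luv,
                 adapt_radius_dkl = adapt_radius_dkl,
                 k = k,
                 halfwave_rectify = isTRUE(halfwave_rectify),
                 project_to_background_Lstar =
                   isTRUE(project_to_background_Lstar),
                 surround = surround,
                 cones = cones),
            class = "adaptation_config")
}

#' Weber-fraction cone contrast
#'
#' `CC = (stimulus - adapting) / adapting`, computed independently per cone
#' class. Invariant to rescaling any cone channel of both inputs (the ratios
#' cancel).
#'
#' @param stimulus,adapting cone excitations (length-3 L, M, S vectors or
#'   n x 3 matrices; rows recycle against each other).
#' @return cone contrasts (same shape as `stimulus`).
#' @examples
#' cone_contrast(c(1, 1, 1), c(0.5, 1, 2)) # (1, 0, -0.5)
#' @export
cone_contrast <- function(stimulus, adapting) {
  s <- as_colour_matrix(stimulus, c("L", "M", "S"))
  a <- as_colour_matrix(adapting, c("L", "M", "S"))
  if (any(a <= 0))
    stop("adapting cone excitations must be strictly positive")
  n <- max(nrow(s), nrow(a))
  s <- s[rep_len(seq_len(nrow(s)), n), , drop = FALSE]
  a <- a[rep_len(seq_len(nrow(a)), n), , drop = FALSE]
  out <- (s - a) / a
  colnames(out) <- c("ccL", "ccM", "ccS")
  drop_row(out, is.null(dim(stimulus)) && is.null(dim(adapting)))
}

#' Effective adapting colour for partial adaptation
#'
#' The colour actually adapted to: the inducer's hue (and lightness plane)
#' with chroma replaced by the configured adaptation strength. Strength 0
#' returns the background grey; strength `NA` returns the inducer itself
#' (complete adaptation).
#'
#' @param inducer single-row inducer spec (see [hue_circle_set()]).
#' @param cfg an [adaptation_config()].
#' @param m a [monitor_model()].
#' @param axes optional precomputed [dkl_axes()].
#' @return cone excitations (L, M, S) of the effective adapting colour, with
#'   the XYZ tristimulus in attribute `"XYZ"`.
#' @export
effective_adapting_colour <- function(inducer, cfg = adaptation_config(),
                                      m = monitor_model(), axes = NULL) {
  stopifnot(nrow(inducer) == 1L)
  w <- monitor_white(m)
  if (inducer$space == "luv") {
    strength <- cfg$adapt_chroma_luv
    if (is.na(strength)) strength <- inducer$chroma
    xyz <- luv_polar_to_XYZ(inducer$Lstar, strength, inducer$hue, w)
  } else {
    if (is.null(axes)) axes <- dkl_axes(m, cfg$cones)
    strength <- cfg$adapt_radius_dkl
    if (is.na(strength)) strength <- inducer$chroma
    xyz <- dkl_polar_to_XYZ(strength, inducer$hue, axes)
  }
  if (!in_gamut(xyz, m))
    stop("effective adapting colour is outside the monitor gamut")
  lms <- XYZ_to_LMS(xyz, cfg$cones)
  attr(lms, "XYZ") <- xyz
  lms
}

# project a tristimulus onto the background-L* plane: keep u'v' chromaticity,
# set luminance to the background's
project_to_bg_plane <- function(XYZ, bg) {
  x <- as_colour_matrix(XYZ)
  uv <- uprime(x)
  Y <- as_colour_matrix(bg)[1, "Y"]
  X <- Y * 9 * uv[, "u"] / (4 * uv[, "v"])
  Z <- Y * (12 - 3 * uv[, "u"] - 20 * uv[, "v"]) / (4 * uv[, "v"])
  cbind(X = X, Y = Y, Z = Z)
}

# shared wrap-up: XYZ prediction -> (hue, chroma) in CIELUV, with optional
# projection to the background-L* plane
finish_prediction <- function(xyz, m, cfg, native = NULL) {
  bg <- monitor_background(m)
  w <- monitor_white(m)
  raw <- xyz
  if (cfg$project_to_background_Lstar) xyz <- project_to_bg_plane(xyz, bg)
  luv <- XYZ_to_luv(xyz, w)
  if (is.matrix(luv)) luv <- luv[1L, ]
  hue <- unname(luv["hue"])
  chroma <- unname(luv["chroma"])
  if (chroma < 1e-9) hue <- NA_real_  # achromatic: hue undefined
  list(hue = hue, chroma = chroma,
       native = c(native, list(XYZ = raw)))
}

#' Cone-adaptation (Weber-law) afterimage prediction
#'
#' Models divisive first-stage adaptation: the grey probe's cone signal is
#' contrast-coded against the effective adapting colour
#' (`CC = (bgLMS - iLMS) / iLMS`), then re-embedded under global adaptation
#' to the background, giving afterimage cone excitations
#' `bgLMS * (1 + CC) = bgLMS^2 / iLMS` componentwise.
#'
#' @inheritParams effective_adapting_colour
#' @return list with `hue` (CIELUV azimuth, degrees; `NA` when achromatic),
#'   `chroma` (CIELUV units), and `native` coordinates.
#' @export
predict_cone_adaptation <- function(inducer, m = monitor_model(),
                                    cfg = adaptation_config(), axes = NULL) {
  bg_lms <- XYZ_to_LMS(monitor_background(m), cfg$cones)
  i_lms <- effective_adapting_colour(inducer, cfg, m, axes)
  cc <- cone_contrast(bg_lms, as.numeric(i_lms))
  ai_lms <- bg_lms * (1 + cc)   # = bg^2 / inducer, componentwise
  xyz <- LMS_to_XYZ(ai_lms, cfg$cones)
  finish_prediction(xyz, m, cfg,
                    native = list(LMS = ai_lms, cone_contrast = cc))
}

#' Cone-opponent (subtractive DKL) afterimage prediction
#'
#' Subtractive second-site adaptation: the background's opponent signal is
#' zero, so the predicted afterimage sits at minus k times the inducer's DKL
#' coordinates — the hue exactly opposite the inducer, at k times its radius.
#' By default k is folded into the effective adapting colour (partial
#' adaptation); pass `cfg$k` for an explicit strength applied to the raw
#' inducer. With `cfg$halfwave_rectify` the computation runs through
#' rectified single-signed mechanisms (identical predictions).
#'
#' @inheritParams effective_adapting_colour
#' @return as [predict_cone_adaptation()], with DKL coordinates in `native`.
#' @export
predict_cone_opponent <- function(inducer, m = monitor_model(),
                                  cfg = adaptation_config(), axes = NULL) {
  if (is.null(axes)) axes <- dkl_axes(m, cfg$cones)
  if (is.null(cfg$k)) {
    i_lms <- effective_adapting_colour(inducer, cfg, m, axes)
    idkl <- XYZ_to_dkl(attr(i_lms, "XYZ"), axes)
    k <- 1
  } else {
    idkl <- XYZ_to_dkl(inducer_to_XYZ(inducer, m, axes), axes)
    k <- cfg$k
  }
  if (is.matrix(idkl)) idkl <- idkl[1L, ]
  if (cfg$halfwave_rectify) {
    # each opponent channel split into two single-signed mechanisms, adapted
    # separately and recombined; algebraically the same as the direct form
    rect <- function(v) c(pos = max(v, 0), neg = max(-v, 0))
    lm <- rect(idkl["lm"]); s <- rect(idkl["s"])
    pred <- c(lm = -k * (lm["pos"] - lm["neg"]),
              s = -k * (s["pos"] - s["neg"]))
  } else {
    pred <- c(lm = -k * unname(idkl["lm"]), s = -k * unname(idkl["s"]))
  }
  xyz <- dkl_to_XYZ(pred, axes)
  finish_prediction(xyz, m, cfg, native = list(dkl = pred))
}

# CAT02 chromatic adaptation matrix (CIECAM02)
.M_CAT02 <- matrix(c(0.7328, 0.4296, -0.1624,
                     -0.7036, 1.6975, 0.0061,
                     0.0030, 0.0136, 0.9834), nrow = 3, byrow = TRUE)

cat02_degree <- function(F, La) {
  F * (1 - (1 / 3.6) * exp(-(La + 42) / 92))
}

# corresponding colour of `xyz` seen under adapting white `wa`, re-rendered
# under reference white `w`, via the CAT02 von-Kries-like transform
cat02_corresponding <- function(xyz, wa, w, D) {
  rgb <- as.numeric(.M_CAT02 %*% xyz)
  rgb_wa <- as.numeric(.M_CAT02 %*% wa)
  rgb_w <- as.numeric(.M_CAT02 %*% w)
  gain_a <- D * wa[2] / rgb_wa + 1 - D
  gain_w <- D * w[2] / rgb_w + 1 - D
  as.numeric(solve(.M_CAT02, rgb * gain_a / gain_w))
}

#' Colour-appearance afterimage predictions (CIELUV, CIELAB, CAT02)
#'
#' Computes the appearance of the grey background when the adapting white is
#' the (partial-strength) effective inducer, then finds the corresponding
#' colour under the display white:
#' * `"cieluv"`: subtractive adaptation in u'v' chromaticity — the
#'   prediction lies at the chromaticity reflected through the background,
#'   so its hue coincides exactly with the cone-opponent hue.
#' * `"cielab"`: the CIELAB white-substitution (pseudo von-Kries on XYZ
#'   ratios).
#' * `"ciecam02"`: the CAT02 chromatic adaptation transform with the
#'   CIECAM02 degree of adaptation (average surround, adapting luminance =
#'   background luminance / 5 by default; override via `cfg$surround`).
#'
#' @inheritParams effective_adapting_colour
#' @param which one of `"cieluv"`, `"cielab"`, `"ciecam02"`.
#' @return as [predict_cone_adaptation()]. Predictions whose corresponding
#'   colour leaves the positive tristimulus range are flagged via
#'   `native$unrealizable`.
#' @export
predict_appearance_model <- function(inducer,
                                     which = c("cieluv", "cielab", "ciecam02"),
                                     m = monitor_model(),
                                     cfg = adaptation_config(), axes = NULL) {
  which <- match.arg(which)
  w <- monitor_white(m)
  bg <- monitor_background(m)
  i_lms <- effective_adapting_colour(inducer, cfg, m, axes)
  i_xyz <- as.numeric(attr(i_lms, "XYZ"))
  if (which == "cieluv") {
    uv_bg <- uprime(bg)[1, ]
    uv_i <- uprime(i_xyz)[1, ]
    uv_pred <- 2 * uv_bg - uv_i
    Y <- bg[2]
    xyz <- c(Y * 9 * uv_pred["u"] / (4 * uv_pred["v"]),
             Y,
             Y * (12 - 3 * uv_pred["u"] - 20 * uv_pred["v"]) /
               (4 * uv_pred["v"]))
  } else {
    # adapting white: effective inducer chromaticity at the display white's
    # luminance (luminance ratios then cancel)
    wa <- i_xyz * w[2] / i_xyz[2]
    if (which == "cielab") {
      xyz <- as.numeric(bg) * as.numeric(w) / wa
    } else {
      sur <- cfg$surround
      La <- bg[2] / sur$La_div
      D <- if (!is.null(sur$D)) sur$D else cat02_degree(sur$F, La)
      xyz <- cat02_corresponding(as.numeric(bg), wa, as.numeric(w), D)
    }
  }
  unreal <- any(xyz < 0)
  out <- finish_prediction(rbind(xyz), m, cfg,
                           native = list(unrealizable = unreal))
  out
}

#' Hering unique-hue prototypes
#'
#' @param red,yellow,green,blue CIELUV hue azimuths (degrees) of the
#'   empirically measured unique-hue prototypes. There are no universal
#'   default azimuths: prototypes are observer- and study-specific and must
#'   be supplied.
#' @return named numeric vector of class `hering_prototypes`.
#' @export
hering_prototypes <- function(red, yellow, green, blue) {
  p <- wrap_hue(c(red = red, yellow = yellow, green = green, blue = blue))
  gaps <- circular_signed_difference(c(p[-1], p[1]), p)
  gaps <- gaps %% 360
  if (abs(sum(gaps) - 360) > 1e-9)
    stop("prototypes must be in cyclic order red, yellow, green, blue")
  structure(p, class = "hering_prototypes")
}

#' Hering-opponency afterimage prediction
#'
#' The predicted hue is obtained by locating the inducer between its two
#' neighbouring unique-hue prototypes and transferring that fractional
#' position onto the opponent pair (red-green, yellow-blue). Hering
#' opponency makes no chroma prediction.
#'
#' @param inducer single-row inducer spec (only the hue is used; DKL-space
#'   inducers are first mapped to their CIELUV azimuth).
#' @param prototypes a [hering_prototypes()] object.
#' @param m a [monitor_model()].
#' @param axes optional [dkl_axes()] (DKL-space inducers only).
#' @return list with `hue` and `chroma = NA` (no prediction).
#' @export
predict_hering <- function(inducer, prototypes, m = monitor_model(),
                           axes = NULL) {
  stopifnot(inherits(prototypes, "hering_prototypes"))
  hue <- inducer$hue
  if (inducer$space == "dkl") {
    xyz <- inducer_to_XYZ(inducer, m, axes)
    hue <- unname(XYZ_to_luv(xyz, monitor_white(m))["hue"])
  }
  p <- unclass(prototypes)
  opp <- c(red = "green", yellow = "blue", green = "red", blue = "yellow")
  nms <- names(p)
  # sector containing the inducer: prototype A with the smallest forward gap
  fwd <- (hue - p) %% 360
  iA <- which.min(fwd)
  A <- nms[iA]; B <- nms[if (iA == 4L) 1L else iA + 1L]
  span <- (p[B] - p[A]) %% 360
  t <- if (span == 0) 0 else fwd[iA] / span
  oA <- p[opp[A]]; oB <- p[opp[B]]
  ospan <- (oB - oA) %% 360
  list(hue = unname(wrap_hue(oA + t * ospan)), chroma = NA_real_,
       native = list(sector = c(A, B), t = unname(t)))
}

#' Predict afterimages for a set of inducers under one or more models
#'
#' Vectorised front end over the per-model prediction functions; returns one
#' row per model x inducer in a common CIELUV polar frame.
#'
#' @param inducers inducer spec data.frame (see [hue_circle_set()]).
#' @param models subset of `c("cone", "dkl", "cieluv", "cielab", "ciecam02",
#'   "munsell", "hering")`.
#' @param m a [monitor_model()].
#' @param cfg an [adaptation_config()].
#' @param prototypes a [hering_prototypes()] object (required for
#'   `"hering"`).
#' @param munsell a Munsell renotation table from
#'   [read_munsell_renotation()] or [synthetic_munsell_table()] (required
#'   for `"munsell"`).
#' @param axes optional precomputed [dkl_axes()].
#' @return data.frame with columns `model, space, inducer_hue,
#'   inducer_chroma, pred_hue, pred_chroma`.
#' @export
predict_afterimage <- function(inducers, models = c("cone", "dkl"),
                               m = monitor_model(),
                               cfg = adaptation_config(),
                               prototypes = NULL, munsell = NULL,
                               axes = NULL) {
  models <- match.arg(models, MODEL_LABELS, several.ok = TRUE)
  if (is.null(axes) &&
      (any(models %in% c("dkl", "ciecam02")) || any(inducers$space == "dkl")))
    axes <- dkl_axes(m, cfg$cones)
  one <- function(model, i) {
    ind <- inducers[i, , drop = FALSE]
    p <- switch(model,
      cone = predict_cone_adaptation(ind, m, cfg, axes),
      dkl = predict_cone_opponent(ind, m, cfg, axes),
      cieluv = predict_appearance_model(ind, "cieluv", m, cfg, axes),
      cielab = predict_appearance_model(ind, "cielab", m, cfg, axes),
      ciecam02 = predict_appearance_model(ind, "ciecam02", m, cfg, axes),
      munsell = {
        if (is.null(munsell))
          stop("the 'munsell' model needs a renotation table")
        predict_munsell(ind, munsell, m, cfg, axes)
      },
      hering = {
        if (is.null(prototypes))
          stop("the 'hering' model needs unique-hue prototypes")
        predict_hering(ind, prototypes, m, axes)
      })
    data.frame(model = model, space = ind$space,
               inducer_hue = ind$hue, inducer_chroma = ind$chroma,
               pred_hue = p$hue, pred_chroma = p$chroma)
  }
  out <- do.call(rbind, lapply(models, function(mod)
    do.call(rbind, lapply(seq_len(nrow(inducers)), function(i) one(mod, i)))))
  rownames(out) <- NULL
  out
}

#' Draw wrapped-Gaussian response noise around predicted hues
#'
#' @param pred_hue vector of predicted hue azimuths (degrees).
#' @param sigma_hue wrapped-Gaussian standard deviation (degrees, >= 0).
#' @param n_per_inducer draws per prediction.
#' @param seed integer seed (draws are reproducible).
#' @return numeric vector of length `length(pred_hue) * n_per_inducer`
#'   (grouped by prediction) of noisy hues in `[0, 360)`.
#' @export
add_response_noise <- function(pred_hue, sigma_hue, n_per_inducer = 1L,
                               seed = NULL) {
  if (sigma_hue < 0) stop("sigma_hue must be >= 0")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  mu <- rep(pred_hue, each = n_per_inducer)
  wrap_hue(mu + rnorm(length(mu), 0, sigma_hue))
}
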