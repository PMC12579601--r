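# Stimulus generation for the hue-circle afterimage experiments.
#
# An inducer specification is a data.frame row with columns
# space ("luv" or "dkl"), hue, chroma, Lstar, label. "luv" hues/chromas are
# CIELUV polar coordinates at the given L*; "dkl" hues/radii live on the
# gamut-scaled isoluminant DKL plane (Lstar is then implied by the
# background).

inducer_frame <- function(space, hue, chroma, Lstar, label = "") {
  data.frame(space = space, hue = wrap_hue(hue), chroma = chroma,
             Lstar = Lstar, label = label, stringsAsFactors = FALSE)
}

#' Render inducer specifications to XYZ
#'
#' @param spec data.frame of inducer specs (columns `space, hue, chroma,
#'   Lstar`).
#' @param m a [monitor_model()].
#' @param axes optional precomputed [dkl_axes()] (required for DKL-space
#'   specs; computed on the fly if missing).
#' @return n x 3 matrix of XYZ tristimulus values.
#' @export
inducer_to_XYZ <- function(spec, m, axes = NULL) {
  w <- monitor_white(m)
  out <- matrix(NA_real_, nrow(spec), 3,
                dimnames = list(NULL, c("X", "Y", "Z")))
  is_luv <- spec$space == "luv"
  if (any(is_luv))
    out[is_luv, ] <- luv_polar_to_XYZ(spec$Lstar[is_luv],
                                      spec$chroma[is_luv],
                                      spec$hue[is_luv], w)
  if (any(!is_luv)) {
    if (is.null(axes)) axes <- dkl_axes(m)
    out[!is_luv, ] <- dkl_polar_to_XYZ(spec$chroma[!is_luv],
                                       spec$hue[!is_luv], axes)
  }
  out
}

#' Largest chroma along a hue ray that stays inside the monitor gamut
#'
#' Bisection search (resolution 1e-4 by default) on the radius of a colour at
#' a fixed hue azimuth and lightness; used to place "maximum chroma within
#' gamut" stimuli.
#'
#' @param hue hue azimuth in degrees (vectorised).
#' @param Lstar lightness of the stimulus plane (`"luv"` space only).
#' @param m a [monitor_model()].
#' @param space `"luv"` (CIELUV chroma) or `"dkl"` (gamut-scaled DKL radius).
#' @param axes optional precomputed [dkl_axes()].
#' @param resolution bracketing resolution of the search.
#' @return numeric vector of maximal chromas.
#' @export
max_chroma_in_gamut <- function(hue, Lstar = 70, m = monitor_model(),
                                space = c("luv", "dkl"), axes = NULL,
                                resolution = 1e-4) {
  space <- match.arg(space)
  if (space == "dkl" && is.null(axes)) axes <- dkl_axes(m)
  w <- monitor_white(m)
  if (!in_gamut(monitor_background(m), m))
    stop("monitor background is out of gamut; check the display configuration")
  one <- function(h) {
    ok <- function(ch) {
      xyz <- if (space == "luv") luv_polar_to_XYZ(Lstar, ch, h, w)
             else dkl_polar_to_XYZ(ch, h, axes)
      in_gamut(xyz, m)
    }
    lo <- 0; hi <- 1
    while (ok(hi) && hi < 1e5) { lo <- hi; hi <- 2 * hi }
    while (hi - lo > resolution) {
      mid <- (lo + hi) / 2
      if (ok(mid)) lo <- mid else hi <- mid
    }
    lo
  }
  vapply(hue, one, numeric(1))
}

#' Inducers sampled at equal steps around an isoluminant hue circle
#'
#' Generates the hue-circle inducer sets: e.g. 72 inducers in 5-degree steps,
#' or 24 inducers at chroma 71 in 15-degree steps.
#'
#' @param step_deg hue step in degrees; must divide 360.
#' @param chroma radius of the circle (CIELUV chroma or DKL radius), or the
#'   string `"max"` to use the per-hue maximum within gamut.
#' @param space `"luv"` or `"dkl"`.
#' @param m a [monitor_model()].
#' @param Lstar lightness of the circle (`"luv"` only).
#' @param start_deg azimuth of the first inducer.
#' @param label experiment tag stored with each inducer.
#' @param axes optional precomputed [dkl_axes()].
#' @return data.frame of inducer specs (one row per hue).
#' @examples
#' nrow(hue_circle_set(5, 50))   # 72
#' nrow(hue_circle_set(15, 71))  # 24
#' @export
hue_circle_set <- function(step_deg, chroma, space = c("luv", "dkl"),
                           m = monitor_model(), Lstar = 70, start_deg = 0,
                           label = "", axes = NULL) {
  space <- match.arg(space)
  if (step_deg <= 0 || 360 %% step_deg != 0)
    stop("step_deg must be a positive divisor of 360")
  hues <- wrap_hue(seq(start_deg, start_deg + 360 - step_deg, by = step_deg))
  if (identical(chroma, "max"))
    chroma <- max_chroma_in_gamut(hues, Lstar, m, space, axes)
  spec <- inducer_frame(space, hues, chroma,
                        if (space == "luv") Lstar else m$background_Lstar,
                        label)
  bad <- !in_gamut(inducer_to_XYZ(spec, m, axes), m)
  if (any(bad))
    stop("hue circle leaves the monitor gamut at hue(s) ",
         paste(spec$hue[bad], collapse = ", "))
  spec
}

#' Nine-alternative comparison set around the opponent hue
#'
#' The comparison colours of the matching task: the hue opposite the inducer
#' plus four hues in 10-degree steps to either side, at a fixed comparison
#' chroma.
#'
#' @param inducer single-row inducer spec.
#' @param comparison_chroma fixed chroma of the nine comparisons (default 30).
#' @param step_deg spacing of the comparisons (default 10).
#' @param n_side comparisons on each side of the opponent hue (default 4).
#' @param Lstar lightness of the comparisons.
#' @param m a [monitor_model()].
#' @return data.frame of 2 * n_side + 1 comparison specs, ordered from the
#'   lowest to the highest azimuth offset.
#' @examples
#' ind <- hue_circle_set(360, 71)[1, ]
#' comparison_set(ind)$hue # 140 150 ... 220
#' @export
comparison_set <- function(inducer, comparison_chroma = 30, step_deg = 10,
                           n_side = 4, Lstar = 70, m = monitor_model()) {
  stopifnot(nrow(inducer) == 1L)
  opponent <- wrap_hue(inducer$hue + 180)
  hues <- wrap_hue(opponent + step_deg * seq(-n_side, n_side))
  spec <- inducer_frame("luv", hues, comparison_chroma, Lstar,
                        label = "comparison")
  bad <- !in_gamut(inducer_to_XYZ(spec, m), m)
  if (any(bad))
    stop("comparison colours leave the monitor gamut at hue(s) ",
         paste(spec$hue[bad], collapse = ", "))
  spec
}

#' Hue-by-chroma inducer grid for the chroma-series experiment
#'
#' Cartesian product of inducer hues and chroma levels; the token `"max"`
#' among `levels` expands, per hue, to the maximum chroma within gamut.
#'
#' @param hues inducer hue azimuths (degrees).
#' @param levels chroma levels; numeric values and/or the string `"max"`.
#' @param m a [monitor_model()].
#' @param Lstar lightness of the grid.
#' @param label experiment tag.
#' @return data.frame of `length(hues) * length(levels)` inducer specs.
#' @examples
#' nrow(chroma_series_set(seq(0, 355, by = 5), c(20, 50, "max"))) # 216
#' @export
chroma_series_set <- function(hues, levels, m = monitor_model(), Lstar = 70,
                              label = "chroma_series") {
  specs <- lapply(levels, function(lev) {
    ch <- if (identical(lev, "max")) max_chroma_in_gamut(hues, Lstar, m)
          else as.numeric(lev)
    inducer_frame("luv", hues, ch, Lstar, label)
  })
  spec <- do.call(rbind, specs)
  bad <- !in_gamut(inducer_to_XYZ(spec, m), m)
  if (any(bad))
    stop("chroma series leaves the monitor gamut for ",
         sum(bad), " stimulus(es)")
  spec
}

#' Trial series partition of the 72-hue circle
#'
#' Splits the 72 inducers (5-degree steps) into nine series of eight colours
#' separated by 45 degrees, with starting azimuths 0, 5, ..., 40, so that the
#' series together cover every inducer exactly once.
#'
#' @return data.frame with columns `series_index` (0-8), `start_azimuth`, and
#'   `hue`; 72 rows.
#' @export
trial_series <- function() {
  out <- do.call(rbind, lapply(0:8, function(s) {
    data.frame(series_index = s, start_azimuth = 5 * s,
               hue = wrap_hue(5 * s + 45 * (0:7)))
  }))
  out
}

#' Export a stimulus set to CSV
#'
#' Writes the columns `experiment, space, hue_azimuth_deg, chroma, Lstar`
#' (plus `series_index` when present) with 6 significant digits.
#'
#' @param spec inducer spec data.frame.
#' @param path output file.
#' @param experiment experiment tag written to the first column.
#' @return the path, invisibly.
#' @export
write_stimulus_csv <- function(spec, path, experiment = unique(spec$label)) {
  out <- data.frame(experiment = if (length(experiment)) experiment[1] else "",
                    space = spec$space,
                    hue_azimuth_deg = signif(spec$hue, 6),
                    chroma = signif(spec$chroma, 6),
                    Lstar = signif(spec$Lstar, 6))
  if (!is.null(spec$series_index)) out$series_index <- spec$series_index
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
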