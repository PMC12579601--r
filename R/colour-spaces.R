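# ---- internal helpers -------------------------------------------------------

# coerce a length-3 vector or an n x 3 matrix/data.frame to an n x 3 matrix
as_colour_matrix <- function(x, names = c("X", "Y", "Z")) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(dim(x))) {
    if (length(x) != 3L)
      stop("colour input must have 3 components, got ", length(x))
    x <- matrix(x, nrow = 1L)
  }
  if (ncol(x) != 3L)
    stop("colour matrix must have 3 columns, got ", ncol(x))
  x <- unname(as.matrix(x))
  storage.mode(x) <- "double"
  colnames(x) <- names
  x
}

drop_row <- function(x, drop) {
  if (drop && nrow(x) == 1L) x[1L, ] else x
}

#' Wrap hue angles to [0, 360)
#'
#' @param deg numeric vector of angles in degrees.
#' @return angles wrapped to `[0, 360)`.
#' @export
wrap_hue <- function(deg) {
  out <- deg %% 360
  out[out >= 360] <- out[out >= 360] - 360
  out
}

#' Signed circular difference between two hue angles
#'
#' Computes `a - b` wrapped to the half-open interval (-180, 180], the
#' convention used for all deviation-from-opponency arithmetic.
#'
#' @param a,b hue angles in degrees (vectors recycle).
#' @return signed difference in degrees, in (-180, 180].
#' @examples
#' circular_signed_difference(250, 240) # +10
#' circular_signed_difference(10, 350)  # +20
#' @export
circular_signed_difference <- function(a, b) {
  d <- (a - b) %% 360
  d[d > 180] <- d[d > 180] - 360
  d
}

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

# ---- xyY <-> XYZ ------------------------------------------------------------

#' Convert CIE xyY chromaticity + luminance to XYZ tristimulus
#'
#' @param xyY length-3 vector or n x 3 matrix with columns x, y, Y
#'   (chromaticity coordinates and luminance in cd/m^2).
#' @return matrix (or vector for a single colour) of X, Y, Z.
#' @examples
#' xyY_to_XYZ(c(1 / 3, 1 / 3, 100)) # equal-energy: (100, 100, 100)
#' @export
xyY_to_XYZ <- function(xyY) {
  m <- as_colour_matrix(xyY, c("x", "y", "Y"))
  if (any(m[, "y"] <= 0))
    stop("degenerate chromaticity: y must be > 0")
  if (any(m[, "Y"] < 0))
    stop("luminance Y must be >= 0")
  X <- m[, "x"] * m[, "Y"] / m[, "y"]
  Z <- (1 - m[, "x"] - m[, "y"]) * m[, "Y"] / m[, "y"]
  drop_row(cbind(X = X, Y = m[, "Y"], Z = Z), is.null(dim(xyY)))
}

#' Convert XYZ tristimulus to xyY
#'
#' @param XYZ length-3 vector or n x 3 matrix of tristimulus values.
#' @return x, y chromaticity and luminance Y.
#' @export
XYZ_to_xyY <- function(XYZ) {
  m <- as_colour_matrix(XYZ)
  s <- rowSums(m)
  if (any(s <= 0))
    stop("degenerate tristimulus: X + Y + Z must be > 0")
  drop_row(cbind(x = m[, "X"] / s, y = m[, "Y"] / s, Y = m[, "Y"]),
           is.null(dim(XYZ)))
}

# ---- monitor model ----------------------------------------------------------

#' Calibrated-display model
#'
#' Bundles the colorimetric description of a gamma-corrected three-primary
#' display: xyY of the primaries at full drive, a shared gamma exponent, the
#' white point, and the lightness of the neutral adapting background. The
#' defaults reproduce the calibrated laboratory display on which the
#' afterimage measurements were made (10-bit wide-gamut monitor, gamma 2.2,
#' background at L* = 70).
#'
#' @param red,green,blue xyY (x, y, Y with Y in cd/m^2) of each primary at
#'   full drive.
#' @param gamma gamma exponent shared by the three channels.
#' @param white xyY of the display white point.
#' @param background_Lstar CIELUV/CIELAB lightness of the neutral background.
#' @return an object of class `monitor_model`.
#' @examples
#' m <- monitor_model()
#' monitor_background(m) # grey at the white chromaticity, L* = 70
#' @export
monitor_model <- function(red = c(0.6847, 0.3111, 26.4),
                          green = c(0.2138, 0.7263, 69.9),
                          blue = c(0.1521, 0.0453, 4.8),
                          gamma = 2.2,
                          white = c(0.3304, 0.3526, 101.1),
                          background_Lstar = 70) {
  stopifnot(gamma > 0, background_Lstar > 0, background_Lstar < 100)
  primaries <- rbind(red = red, green = green, blue = blue)
  colnames(primaries) <- c("x", "y", "Y")
  # columns of rgb2xyz are the primaries' tristimulus at full drive
  rgb2xyz <- t(xyY_to_XYZ(primaries))
  if (abs(det(rgb2xyz)) < 1e-12)
    stop("primaries are colorimetrically degenerate (singular RGB->XYZ matrix)")
  m <- structure(
    list(primaries = primaries,
         gamma = gamma,
         white = c(x = white[1], y = white[2], Y = white[3]),
         background_Lstar = background_Lstar,
         rgb2xyz = rgb2xyz,
         xyz2rgb = solve(rgb2xyz)),
    class = "monitor_model")
  m
}

#' @export
print.monitor_model <- function(x, ...) {
  cat("Calibrated display model\n")
  cat(sprintf("  gamma: %.2f   white xyY: (%.4f, %.4f, %.1f)   background L*: %g\n",
              x$gamma, x$white[1], x$white[2], x$white[3], x$background_Lstar))
  print(round(x$primaries, 4))
  invisible(x)
}

#' White-point tristimulus of a monitor
#' @param m a [monitor_model()].
#' @return XYZ of the display white.
#' @export
monitor_white <- function(m) {
  xyY_to_XYZ(m$white)
}

#' Neutral adapting background of a monitor
#'
#' The background grey has the white-point chromaticity at the luminance that
#' yields `m$background_Lstar` (computed from the CIE lightness function,
#' never hard-coded).
#'
#' @param m a [monitor_model()].
#' @return XYZ of the background grey.
#' @export
monitor_background <- function(m) {
  Yb <- m$white["Y"] * lab_finv((m$background_Lstar + 16) / 116)
  xyY_to_XYZ(c(m$white[1], m$white[2], unname(Yb)))
}

#' Render gamma-corrected RGB drive values to XYZ
#'
#' Linearises each channel as `drive^gamma` and sums the primaries'
#' tristimulus contributions.
#'
#' @param rgb length-3 vector or n x 3 matrix of drive values in `[0, 1]`.
#' @param m a [monitor_model()].
#' @return XYZ tristimulus.
#' @export
rgb_to_XYZ <- function(rgb, m) {
  x <- as_colour_matrix(rgb, c("R", "G", "B"))
  if (any(x < 0 | x > 1))
    stop("RGB drive values must lie in [0, 1]")
  lin <- x^m$gamma
  drop_row(lin %*% t(m$rgb2xyz), is.null(dim(rgb)))
}

#' Inverse rendering transform: XYZ to linear drive values
#'
#' Returns the *linear* (pre-gamma) drive values; values outside `[0, 1]`
#' indicate out-of-gamut colours.
#'
#' @inheritParams rgb_to_XYZ
#' @param XYZ tristimulus input.
#' @return n x 3 matrix of linear drives.
#' @export
XYZ_to_linear_rgb <- function(XYZ, m) {
  x <- as_colour_matrix(XYZ)
  drop_row(x %*% t(m$xyz2rgb), is.null(dim(XYZ)))
}

#' Is a tristimulus value inside the monitor gamut?
#'
#' @param XYZ tristimulus value(s).
#' @param m a [monitor_model()].
#' @param tol tolerance on linear drive values (default 1e-6).
#' @return logical vector.
#' @export
in_gamut <- function(XYZ, m, tol = 1e-6) {
  d <- as_colour_matrix(XYZ) %*% t(m$xyz2rgb)
  apply(d >= -tol & d <= 1 + tol, 1L, all)
}

# ---- cone fundamentals ------------------------------------------------------

# Cone-fundamental tristimulus relation (CIE 170-2): rows express the
# fundamental-based x,y,z colour-matching functions in terms of l,m,s.
.LMS_TO_XYZ_CIE2006_2DEG <- matrix(
  c(1.94735469, -1.41445123, 0.36476327,
    0.68990272,  0.34832189, 0.00000000,
    0.00000000,  0.00000000, 1.93485343),
  nrow = 3, byrow = TRUE)

#' Cone-fundamental transform definition
#'
#' Defines the fixed 3 x 3 transform from CIE XYZ to cone excitations and its
#' scaling conventions. The default is the 2-degree physiologically based
#' (Stockman-Sharpe) fundamentals via the published cone-fundamental
#' tristimulus matrix, rescaled so that (i) L + M equals luminance Y
#' (luminous-efficiency scaling) and (ii) the equal-energy white has
#' S = L + M. The cone-adaptation afterimage model is provably invariant to
#' per-channel rescaling, so any documented convention yields the same
#' predictions; the matrix is carried in the object so alternates can be
#' swapped and reported.
#'
#' @param lms_to_xyz 3 x 3 matrix mapping (l, m, s) fundamentals to the
#'   fundamental tristimulus x, y, z.
#' @param name identifier reported in output metadata.
#' @return object of class `cone_fundamentals` with elements `xyz2lms`,
#'   `lms2xyz`, `name`.
#' @export
cone_fundamentals <- function(lms_to_xyz = .LMS_TO_XYZ_CIE2006_2DEG,
                              name = "ss2deg") {
  raw_xyz2lms <- solve(lms_to_xyz)
  # luminous-efficiency scaling: Y = w_L * L_raw + w_M * M_raw
  wL <- lms_to_xyz[2, 1]
  wM <- lms_to_xyz[2, 2]
  # S scale: equal-energy white (1,1,1) gets S = L + M = Y = 1
  s_raw_ee <- sum(raw_xyz2lms[3, ])
  scale <- diag(c(wL, wM, 1 / s_raw_ee))
  xyz2lms <- scale %*% raw_xyz2lms
  structure(list(xyz2lms = xyz2lms, lms2xyz = solve(xyz2lms), name = name),
            class = "cone_fundamentals")
}

#' Convert XYZ tristimulus to cone excitations
#'
#' @param XYZ tristimulus value(s).
#' @param cones a [cone_fundamentals()] object.
#' @return L, M, S cone excitations with L + M = Y.
#' @export
XYZ_to_LMS <- function(XYZ, cones = cone_fundamentals()) {
  x <- as_colour_matrix(XYZ)
  out <- x %*% t(cones$xyz2lms)
  colnames(out) <- c("L", "M", "S")
  drop_row(out, is.null(dim(XYZ)))
}

#' Convert cone excitations back to XYZ
#'
#' @param LMS cone excitations.
#' @inheritParams XYZ_to_LMS
#' @return XYZ tristimulus.
#' @export
LMS_to_XYZ <- function(LMS, cones = cone_fundamentals()) {
  x <- as_colour_matrix(LMS, c("L", "M", "S"))
  out <- x %*% t(cones$lms2xyz)
  colnames(out) <- c("X", "Y", "Z")
  drop_row(out, is.null(dim(LMS)))
}

# ---- CIELUV -----------------------------------------------------------------

lab_f <- function(t) {
  d <- (6 / 29)
  ifelse(t > d^3, t^(1 / 3), t / (3 * d^2) + 4 / 29)
}

lab_finv <- function(ft) {
  d <- 6 / 29
  ifelse(ft > d, ft^3, 3 * d^2 * (ft - 4 / 29))
}

uprime <- function(XYZ) {
  m <- as_colour_matrix(XYZ)
  den <- m[, "X"] + 15 * m[, "Y"] + 3 * m[, "Z"]
  cbind(u = 4 * m[, "X"] / den, v = 9 * m[, "Y"] / den)
}

#' Convert XYZ to CIELUV (Cartesian and polar)
#'
#' Standard CIELUV: lightness from the CIE cube-root function, chromatic
#' coordinates `u* = 13 L* (u' - u'_n)`, `v* = 13 L* (v' - v'_n)`. Hue
#' azimuth is `atan2(v*, u*)` in degrees, counterclockwise, 0 along +u*,
#' wrapped to `[0, 360)`.
#'
#' @param XYZ tristimulus value(s).
#' @param white XYZ of the reference white (`white[2]` must be > 0).
#' @return matrix with columns `Lstar, ustar, vstar, chroma, hue`.
#' @export
XYZ_to_luv <- function(XYZ, white) {
  w <- as_colour_matrix(white)
  if (w[1, "Y"] <= 0) stop("reference white must have positive luminance")
  m <- as_colour_matrix(XYZ)
  uvw <- uprime(w)
  uv <- uprime(m)
  Lstar <- 116 * lab_f(m[, "Y"] / w[1, "Y"]) - 16
  ustar <- 13 * Lstar * (uv[, "u"] - uvw[1, "u"])
  vstar <- 13 * Lstar * (uv[, "v"] - uvw[1, "v"])
  chroma <- sqrt(ustar^2 + vstar^2)
  hue <- wrap_hue(rad2deg(atan2(vstar, ustar)))
  hue[chroma == 0] <- 0
  drop_row(cbind(Lstar = Lstar, ustar = ustar, vstar = vstar,
                 chroma = chroma, hue = hue),
           is.null(dim(XYZ)))
}

#' Convert CIELUV coordinates back to XYZ
#'
#' @param luv matrix/vector with columns `Lstar, ustar, vstar` (extra polar
#'   columns are ignored).
#' @param white XYZ of the reference white.
#' @return XYZ tristimulus.
#' @export
luv_to_XYZ <- function(luv, white) {
  w <- as_colour_matrix(white)
  if (is.null(dim(luv))) luv <- matrix(luv[1:3], nrow = 1L)
  luv <- as.matrix(luv)[, 1:3, drop = FALSE]
  colnames(luv) <- c("Lstar", "ustar", "vstar")
  uvw <- uprime(w)
  Y <- w[1, "Y"] * lab_finv((luv[, "Lstar"] + 16) / 116)
  L13 <- 13 * luv[, "Lstar"]
  u <- ifelse(L13 == 0, uvw[1, "u"], luv[, "ustar"] / L13 + uvw[1, "u"])
  v <- ifelse(L13 == 0, uvw[1, "v"], luv[, "vstar"] / L13 + uvw[1, "v"])
  X <- Y * 9 * u / (4 * v)
  Z <- Y * (12 - 3 * u - 20 * v) / (4 * v)
  out <- cbind(X = X, Y = Y, Z = Z)
  drop_row(out, FALSE)
}

#' Construct XYZ from CIELUV polar coordinates
#'
#' @param Lstar lightness.
#' @param chroma CIELUV chroma (radius in the u*v* plane).
#' @param hue hue azimuth in degrees.
#' @param white XYZ of the reference white.
#' @return XYZ tristimulus (vectorised over the arguments).
#' @export
luv_polar_to_XYZ <- function(Lstar, chroma, hue, white) {
  n <- max(length(Lstar), length(chroma), length(hue))
  Lstar <- rep_len(Lstar, n); chroma <- rep_len(chroma, n)
  hue <- rep_len(hue, n)
  luv <- cbind(Lstar,
               chroma * cos(deg2rad(hue)),
               chroma * sin(deg2rad(hue)))
  luv_to_XYZ(luv, white)
}

# ---- CIELAB -----------------------------------------------------------------

#' Convert XYZ to CIELAB
#'
#' @param XYZ tristimulus value(s).
#' @param white XYZ of the reference white.
#' @return matrix with columns `Lstar, astar, bstar`.
#' @export
XYZ_to_lab <- function(XYZ, white) {
  w <- as_colour_matrix(white)
  if (any(w[1, ] <= 0)) stop("reference white must be strictly positive")
  m <- as_colour_matrix(XYZ)
  fx <- lab_f(m[, "X"] / w[1, "X"])
  fy <- lab_f(m[, "Y"] / w[1, "Y"])
  fz <- lab_f(m[, "Z"] / w[1, "Z"])
  drop_row(cbind(Lstar = 116 * fy - 16,
                 astar = 500 * (fx - fy),
                 bstar = 200 * (fy - fz)),
           is.null(dim(XYZ)))
}

#' Convert CIELAB back to XYZ
#'
#' @param lab matrix/vector with columns `Lstar, astar, bstar`.
#' @param white XYZ of the reference white.
#' @return XYZ tristimulus.
#' @export
lab_to_XYZ <- function(lab, white) {
  w <- as_colour_matrix(white)
  if (is.null(dim(lab))) lab <- matrix(lab[1:3], nrow = 1L)
  lab <- as.matrix(lab)[, 1:3, drop = FALSE]
  fy <- (lab[, 1] + 16) / 116
  fx <- fy + lab[, 2] / 500
  fz <- fy - lab[, 3] / 200
  cbind(X = w[1, "X"] * lab_finv(fx),
        Y = w[1, "Y"] * lab_finv(fy),
        Z = w[1, "Z"] * lab_finv(fz))
}

# ---- DKL --------------------------------------------------------------------

#' Gamut-scaled DKL axes for a monitor
#'
#' Constructs the isoluminant cone-opponent (DKL) plane around the neutral
#' background: the L-M axis varies L minus M at constant S and constant
#' luminance, the S axis varies S at constant L and M. Raw mechanism
#' coordinates are cone contrasts relative to the background
#' (`dL/Lbg - dM/Mbg` and `dS/Sbg`); each axis is then rescaled so that
#' coordinate +/-1 touches the monitor gamut boundary along that axis at the
#' background luminance (the smaller of the two half-axis extents, so both
#' signs are realisable). The scaling constants are stored in the returned
#' object.
#'
#' @param m a [monitor_model()].
#' @param cones a [cone_fundamentals()] object.
#' @return object of class `dkl_axes` with the background LMS and the per-axis
#'   gamut scaling factors.
#' @export
dkl_axes <- function(m, cones = cone_fundamentals()) {
  bg <- monitor_background(m)
  bg_lms <- XYZ_to_LMS(bg, cones)
  # extent of the gamut along +/- each mechanism direction, in raw
  # cone-contrast units, found by bisection on the in-gamut predicate
  extent <- function(axis, sign) {
    f <- function(a) {
      lms <- dkl_raw_to_LMS(a * sign * (axis == "lm"),
                            a * sign * (axis == "s"), bg_lms)
      all(lms > 0) && in_gamut(LMS_to_XYZ(lms, cones), m)
    }
    lo <- 0; hi <- 1
    while (f(hi) && hi < 1e4) { lo <- hi; hi <- hi * 2 }
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      if (f(mid)) lo <- mid else hi <- mid
    }
    lo
  }
  scale_lm <- min(extent("lm", 1), extent("lm", -1))
  scale_s <- min(extent("s", 1), extent("s", -1))
  structure(list(bg_lms = bg_lms, bg_xyz = bg, cones = cones,
                 scale_lm = scale_lm, scale_s = scale_s),
            class = "dkl_axes")
}

# raw cone-contrast DKL coordinates -> LMS (isoluminant plane, bg luminance)
dkl_raw_to_LMS <- function(lm_raw, s_raw, bg_lms) {
  # dL/Lbg - dM/Mbg = lm_raw with dL + dM = 0 (L+M = Y is luminance)
  dL <- lm_raw / (1 / bg_lms["L"] + 1 / bg_lms["M"])
  cbind(L = bg_lms["L"] + dL,
        M = bg_lms["M"] - dL,
        S = bg_lms["S"] * (1 + s_raw))
}

#' Convert XYZ (isoluminant with the background) to DKL coordinates
#'
#' @param XYZ tristimulus value(s), isoluminant with the monitor background
#'   to relative tolerance `tol`.
#' @param axes a [dkl_axes()] object.
#' @param tol relative luminance tolerance for the isoluminance check.
#' @return matrix with columns `lm, s, radius, hue` (hue in degrees,
#'   `atan2(s, lm)` wrapped to `[0, 360)`).
#' @export
XYZ_to_dkl <- function(XYZ, axes, tol = 1e-6) {
  x <- as_colour_matrix(XYZ)
  Yb <- axes$bg_xyz["Y"]
  if (any(abs(x[, "Y"] - Yb) / Yb > tol))
    stop("input is not isoluminant with the background")
  lms <- XYZ_to_LMS(x, axes$cones)
  if (is.null(dim(lms))) lms <- matrix(lms, nrow = 1,
                                       dimnames = list(NULL, c("L", "M", "S")))
  bg <- axes$bg_lms
  lm_raw <- (lms[, "L"] - bg["L"]) / bg["L"] - (lms[, "M"] - bg["M"]) / bg["M"]
  s_raw <- (lms[, "S"] - bg["S"]) / bg["S"]
  lm <- lm_raw / axes$scale_lm
  s <- s_raw / axes$scale_s
  radius <- sqrt(lm^2 + s^2)
  hue <- wrap_hue(rad2deg(atan2(s, lm)))
  hue[radius == 0] <- 0
  drop_row(cbind(lm = lm, s = s, radius = radius, hue = hue),
           is.null(dim(XYZ)))
}

#' Convert DKL coordinates back to XYZ on the isoluminant plane
#'
#' @param dkl vector/matrix with columns `lm, s` (gamut-scaled units).
#' @param axes a [dkl_axes()] object.
#' @return XYZ tristimulus at the background luminance.
#' @export
dkl_to_XYZ <- function(dkl, axes) {
  if (is.null(dim(dkl))) dkl <- matrix(dkl[1:2], nrow = 1L)
  dkl <- as.matrix(dkl)[, 1:2, drop = FALSE]
  lms <- dkl_raw_to_LMS(dkl[, 1] * axes$scale_lm,
                        dkl[, 2] * axes$scale_s, axes$bg_lms)
  LMS_to_XYZ(lms, axes$cones)
}

#' Construct XYZ from DKL polar coordinates
#'
#' @param radius DKL radius in gamut-scaled units.
#' @param hue DKL hue azimuth in degrees.
#' @param axes a [dkl_axes()] object.
#' @return XYZ tristimulus.
#' @export
dkl_polar_to_XYZ <- function(radius, hue, axes) {
  n <- max(length(radius), length(hue))
  radius <- rep_len(radius, n); hue <- rep_len(hue, n)
  dkl_to_XYZ(cbind(radius * cos(deg2rad(hue)),
                   radius * sin(deg2rad(hue))), axes)
}
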