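# Munsell-system opponency.
#
# Opponent colours in the Munsell system sit 50 steps away on the 100-step
# hue circle at the same value and chroma. Locating an arbitrary colour in
# Munsell coordinates (and mapping the opponent back out) is done by
# interpolation in CIELAB over a renotation-style table.

.MUNSELL_SECTORS <- c("R", "YR", "Y", "GY", "G", "BG", "B", "PB", "P", "RP")

#' Parse Munsell hue labels to positions on the 100-step hue circle
#'
#' `"5R"` is step 5 of sector R; sectors advance R, YR, Y, GY, G, BG, B, PB,
#' P, RP in steps of 10, so e.g. `"7.5GY"` is 37.5.
#'
#' @param label character vector of hue labels.
#' @return numeric positions in (0, 100].
#' @export
munsell_hue_position <- function(label) {
  mat <- regmatches(label, regexec("^([0-9.]+)([A-Z]+)$", label))
  vapply(mat, function(m) {
    if (length(m) != 3L) stop("unparseable Munsell hue label")
    step <- as.numeric(m[2])
    sec <- match(m[3], .MUNSELL_SECTORS)
    if (is.na(sec) || step <= 0 || step > 10)
      stop("unparseable Munsell hue label: ", m[1])
    (sec - 1) * 10 + step
  }, numeric(1))
}

#' Munsell hue label opposite on the 100-step circle
#'
#' @param label character vector of hue labels (grid steps only).
#' @return the label 50 steps away (e.g. `"5R"` -> `"5BG"`).
#' @export
munsell_opposite_label <- function(label) {
  pos <- (munsell_hue_position(label) + 50) %% 100
  pos[pos == 0] <- 100
  sec <- ceiling(pos / 10 - 1e-9)
  step <- pos - (sec - 1) * 10
  paste0(vapply(step, function(s) formatC(s, format = "fg"), character(1)),
         .MUNSELL_SECTORS[sec])
}

#' Read a Munsell renotation table
#'
#' Expects the standard renotation layout: delimited text with columns
#' hue label (`h`), `value` (`V`), `chroma` (`C`), and chromaticity `x`,
#' `y`, `Y` (luminance factor, white = 100). CIELAB coordinates are
#' derived under the configured white chromaticity.
#'
#' @param path file path.
#' @param white_xy chromaticity (x, y) of the white under which CIELAB
#'   coordinates are computed.
#' @param sep field separator passed to [utils::read.csv()].
#' @return object of class `munsell_table`: the parsed records plus derived
#'   `Lab` coordinates.
#' @export
read_munsell_renotation <- function(path, white_xy = c(0.3304, 0.3526),
                                    sep = ",") {
  raw <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  nm <- names(raw)
  col <- function(...) {
    hit <- which(nm %in% c(...))
    if (length(hit) != 1L)
      stop("renotation table must have columns h, V, C, x, y, Y (found: ",
           paste(nm, collapse = ", "), ")")
    raw[[hit]]
  }
  df <- data.frame(hue_label = col("h", "H", "hue_label", "hue"),
                   value = col("V", "value"),
                   chroma = col("C", "chroma"),
                   x = col("x"), y = col("y"),
                   Y = col("Y", "Y.1", "luminance"),
                   stringsAsFactors = FALSE)
  munsell_table(df, white_xy)
}

munsell_table <- function(df, white_xy = c(0.3304, 0.3526)) {
  key <- paste(df$hue_label, df$value, df$chroma)
  if (anyDuplicated(key))
    stop("duplicate (hue, value, chroma) entries in renotation table")
  df$hue100 <- munsell_hue_position(df$hue_label)
  white <- xyY_to_XYZ(c(white_xy[1], white_xy[2], 100))
  lab <- XYZ_to_lab(xyY_to_XYZ(as.matrix(df[, c("x", "y", "Y")])), white)
  df$Lstar <- lab[, "Lstar"]; df$astar <- lab[, "astar"]
  df$bstar <- lab[, "bstar"]
  structure(list(records = df, white = white, white_xy = white_xy),
            class = "munsell_table")
}

#' Synthetic renotation-style Munsell table
#'
#' Builds a smooth, invertible stand-in for the Munsell renotation table so
#' the interpolation machinery can run (and be tested) without the external
#' data file: hue pages at 2.5-step intervals are laid out at a constant
#' angular rate in CIELAB, value maps to L* = 10 V and Munsell chroma to
#' C*ab = 5.5 C. It reproduces the renotation *layout*, not the measured
#' renotation colorimetry.
#'
#' @param values Munsell values included (rows of the table).
#' @param chromas Munsell chromas included per hue page.
#' @param white_xy white chromaticity for the derived CIELAB coordinates.
#' @param azimuth_offset CIELAB hue angle of Munsell position 0 (degrees).
#' @return a `munsell_table` object.
#' @export
synthetic_munsell_table <- function(values = 5:8,
                                    chromas = seq(2, 16, by = 2),
                                    white_xy = c(0.3304, 0.3526),
                                    azimuth_offset = 20) {
  pages <- as.vector(outer(c(2.5, 5, 7.5, 10),
                           10 * (seq_along(.MUNSELL_SECTORS) - 1), "+"))
  labels <- paste0(rep(c("2.5", "5", "7.5", "10"),
                       length(.MUNSELL_SECTORS)),
                   rep(.MUNSELL_SECTORS, each = 4L))
  grid <- expand.grid(i = seq_along(pages), value = values, chroma = chromas)
  ang <- deg2rad(azimuth_offset + 3.6 * pages[grid$i])
  lab <- cbind(Lstar = 10 * grid$value,
               astar = 5.5 * grid$chroma * cos(ang),
               bstar = 5.5 * grid$chroma * sin(ang))
  white <- xyY_to_XYZ(c(white_xy[1], white_xy[2], 100))
  xyz <- lab_to_XYZ(lab, white)
  xyY <- XYZ_to_xyY(xyz)
  df <- data.frame(hue_label = labels[grid$i], value = grid$value,
                   chroma = grid$chroma,
                   x = xyY[, "x"], y = xyY[, "y"], Y = xyY[, "Y"],
                   stringsAsFactors = FALSE)
  munsell_table(df, white_xy)
}

# interpolate (astar, bstar) along one hue page's chroma column at Munsell
# chroma `C` (linear; errors outside the tabulated range)
page_ab_at_chroma <- function(page, C) {
  page <- page[order(page$chroma), ]
  if (C < min(page$chroma) - 1e-9 || C > max(page$chroma) + 1e-9)
    stop("Munsell chroma outside the tabulated range")
  a <- approx(page$chroma, page$astar, xout = C, rule = 1)$y
  b <- approx(page$chroma, page$bstar, xout = C, rule = 1)$y
  c(astar = a, bstar = b)
}

# Munsell chroma on one page whose CIELAB radius equals `radius`
page_chroma_at_radius <- function(page, radius) {
  page <- page[order(page$chroma), ]
  r <- sqrt(page$astar^2 + page$bstar^2)
  if (radius < min(r) - 1e-9 || radius > max(r) + 1e-9)
    stop("colour outside the interpolable chroma range of the table")
  approx(r, page$chroma, xout = radius, rule = 2)$y
}

# locate a CIELAB colour's Munsell hue position and chroma on a value plane
munsell_locate <- function(astar, bstar, plane) {
  radius <- sqrt(astar^2 + bstar^2)
  phi <- wrap_hue(rad2deg(atan2(bstar, astar)))
  pages <- split(plane, plane$hue100)
  h100 <- as.numeric(names(pages))
  info <- lapply(pages, function(pg) {
    C <- page_chroma_at_radius(pg, radius)
    ab <- page_ab_at_chroma(pg, C)
    c(C = unname(C),
      angle = unname(wrap_hue(rad2deg(atan2(ab[["bstar"]], ab[["astar"]])))))
  })
  Cs <- vapply(info, `[[`, numeric(1), "C")
  angles <- vapply(info, `[[`, numeric(1), "angle")
  # bracketing pages: smallest non-negative angular gap on each side
  fwd <- (phi - angles) %% 360
  iA <- which.min(fwd)                       # page at or just below phi
  bwd <- (angles - phi) %% 360
  iB <- which.min(bwd)                       # page at or just above phi
  if (iA == iB)
    return(list(hue100 = h100[iA], chroma = Cs[iA]))
  span <- (angles[iB] - angles[iA]) %% 360
  t <- if (span == 0) 0 else fwd[iA] / span
  dh <- (h100[iB] - h100[iA]) %% 100
  list(hue100 = (h100[iA] + t * dh) %% 100,
       chroma = (1 - t) * Cs[iA] + t * Cs[iB])
}

# CIELAB (astar, bstar) at an arbitrary Munsell hue position and chroma on a
# value plane, bilinear in hue page x chroma
munsell_ab_at <- function(hue100, chroma, plane) {
  pages <- split(plane, plane$hue100)
  h100 <- as.numeric(names(pages))
  hue100 <- hue100 %% 100
  if (hue100 == 0) hue100 <- 100
  dist_fwd <- (hue100 - h100) %% 100
  iA <- which.min(dist_fwd)
  dist_bwd <- (h100 - hue100) %% 100
  iB <- which.min(dist_bwd)
  abA <- page_ab_at_chroma(pages[[iA]], chroma)
  if (iA == iB) return(abA)
  abB <- page_ab_at_chroma(pages[[iB]], chroma)
  span <- (h100[iB] - h100[iA]) %% 100
  t <- dist_fwd[iA] / span
  (1 - t) * abA + t * abB
}

#' Munsell-opponency afterimage prediction
#'
#' Locates the (partial-strength) effective adapting colour in Munsell
#' coordinates by interpolation in CIELAB over a renotation table, takes the
#' hue 50 steps away on the 100-step circle at the same value and chroma,
#' and maps it back out. By convention the lookup uses the tabulated value
#' plane nearest the background L*; the interpolated Munsell chroma of the
#' inducer is retained for the opponent.
#'
#' @inheritParams effective_adapting_colour
#' @param table a `munsell_table` (see [read_munsell_renotation()],
#'   [synthetic_munsell_table()]).
#' @return as [predict_cone_adaptation()]; `native` carries the Munsell
#'   coordinates used.
#' @export
predict_munsell <- function(inducer, table, m = monitor_model(),
                            cfg = adaptation_config(), axes = NULL) {
  stopifnot(inherits(table, "munsell_table"))
  i_lms <- effective_adapting_colour(inducer, cfg, m, axes)
  i_xyz <- as.numeric(attr(i_lms, "XYZ"))
  w <- monitor_white(m)
  lab <- XYZ_to_lab(i_xyz, w)
  if (sqrt(lab["astar"]^2 + lab["bstar"]^2) < 1e-9) {
    # achromatic adapting colour: no opponent shift, afterimage is grey
    return(list(hue = NA_real_, chroma = 0,
                native = list(munsell = NULL, achromatic = TRUE)))
  }
  rec <- table$records
  values <- sort(unique(rec$value))
  v <- values[which.min(abs(10 * values - m$background_Lstar))]
  plane <- rec[rec$value == v, ]
  loc <- munsell_locate(lab["astar"], lab["bstar"], plane)
  opp_h <- (loc$hue100 + 50) %% 100
  ab <- munsell_ab_at(opp_h, loc$chroma, plane)
  out_lab <- c(10 * v, ab[["astar"]], ab[["bstar"]])
  xyz <- lab_to_XYZ(out_lab, w)
  finish_prediction(xyz, m, cfg,
                    native = list(munsell = c(hue100 = loc$hue100,
                                              value = v,
                                              chroma = loc$chroma),
                                  opposite_hue100 = opp_h))
}
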