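cfg_std <- adaptation_config()

test_that("cone contrast is the componentwise Weber fraction", {
  expect_equal(unname(cone_contrast(c(1, 1, 1), c(1, 1, 1))), c(0, 0, 0))
  expect_equal(unname(cone_contrast(c(1, 1, 1), c(0.5, 1, 2))),
               c(1, 0, -0.5))
  expect_error(cone_contrast(c(1, 1, 1), c(0, 1, 1)), "positive")
  # ratio cancellation: rescaling one channel of both inputs changes nothing
  s <- c(1, 1, 1); a <- c(0.4, 1.3, 2.1)
  for (ch in 1:3) {
    s2 <- s; a2 <- a; s2[ch] <- 3 * s2[ch]; a2[ch] <- 3 * a2[ch]
    expect_equal(cone_contrast(s2, a2), cone_contrast(s, a))
  }
})

test_that("the effective adapting colour keeps hue and takes the strength", {
  eff <- effective_adapting_colour(luv_inducer(60, 50), cfg_std, fix_monitor)
  luv <- XYZ_to_luv(attr(eff, "XYZ"), fix_white)
  expect_equal(unname(luv[1, c("hue", "chroma", "Lstar")]), c(60, 27, 70),
               tolerance = 1e-9)
  # complete adaptation: effective colour is the inducer itself
  eff_full <- effective_adapting_colour(
    luv_inducer(60, 50), adaptation_config(adapt_chroma_luv = NA),
    fix_monitor)
  luv_full <- XYZ_to_luv(attr(eff_full, "XYZ"), fix_white)
  expect_equal(unname(luv_full[1, "chroma"]), 50, tolerance = 1e-9)
  # strength 0: effective colour is the background grey
  eff0 <- effective_adapting_colour(
    luv_inducer(60, 50), adaptation_config(adapt_chroma_luv = 0),
    fix_monitor)
  expect_equal(unname(attr(eff0, "XYZ")[1, ]), unname(fix_bg),
               tolerance = 1e-9)
})

test_that("cone-adaptation prediction matches an independent step oracle", {
  # the oracle spells out every step with its own arithmetic: polar CIELUV
  # construction, cone projection, Weber re-embedding bg^2/i, u'v'
  # projection onto the background plane, polar CIELUV readout
  oracle <- function(hue_deg, strength) {
    wx <- 0.3304; wy <- 0.3526; wY <- 101.1
    W <- c(wx * wY / wy, wY, (1 - wx - wy) * wY / wy)
    Yb <- wY * ((70 + 16) / 116)^3
    BG <- c(wx * Yb / wy, Yb, (1 - wx - wy) * Yb / wy)
    upr <- function(x) c(4 * x[1], 9 * x[2]) / (x[1] + 15 * x[2] + 3 * x[3])
    uvn <- upr(W)
    us <- strength * cos(hue_deg * pi / 180)
    vs <- strength * sin(hue_deg * pi / 180)
    u <- us / (13 * 70) + uvn[1]; v <- vs / (13 * 70) + uvn[2]
    I <- c(Yb * 9 * u / (4 * v), Yb,
           Yb * (12 - 3 * u - 20 * v) / (4 * v))
    M <- fix_cones$xyz2lms
    ai <- as.numeric(M %*% BG)^2 / as.numeric(M %*% I)
    XYZai <- as.numeric(solve(M) %*% ai)
    uva <- upr(XYZai)
    P <- c(Yb * 9 * uva[1] / (4 * uva[2]), Yb,
           Yb * (12 - 3 * uva[1] - 20 * uva[2]) / (4 * uva[2]))
    upv <- upr(P)
    ustar <- 13 * 70 * (upv[1] - uvn[1]); vstar <- 13 * 70 * (upv[2] - uvn[2])
    c(hue = (atan2(vstar, ustar) * 180 / pi) %% 360,
      chroma = sqrt(ustar^2 + vstar^2))
  }
  for (hue in c(0, 60, 117, 240, 333)) {
    p <- predict_cone_adaptation(luv_inducer(hue), fix_monitor, cfg_std)
    o <- oracle(hue, 27)
    expect_equal(p$hue, unname(o["hue"]), tolerance = 1e-9)
    expect_equal(p$chroma, unname(o["chroma"]), tolerance = 1e-9)
  }
  # frozen regression values for the 60-degree inducer at strength 27
  p60 <- predict_cone_adaptation(luv_inducer(60, 50), fix_monitor, cfg_std)
  expect_equal(p60$hue, 251.0052783752, tolerance = 1e-9)
  expect_equal(p60$chroma, 34.6276882158, tolerance = 1e-8)
})

test_that("every model predicts grey when there is nothing to adapt to", {
  cfg0 <- adaptation_config(adapt_chroma_luv = 0, adapt_radius_dkl = 0)
  tb <- synthetic_munsell_table()
  ind <- luv_inducer(123)
  for (fn in list(
    function() predict_cone_adaptation(ind, fix_monitor, cfg0, fix_axes),
    function() predict_cone_opponent(ind, fix_monitor, cfg0, fix_axes),
    function() predict_appearance_model(ind, "cieluv", fix_monitor, cfg0),
    function() predict_appearance_model(ind, "cielab", fix_monitor, cfg0),
    function() predict_appearance_model(ind, "ciecam02", fix_monitor, cfg0),
    function() predict_munsell(ind, tb, fix_monitor, cfg0))) {
    p <- fn()
    expect_equal(p$chroma, 0, tolerance = 1e-6)
    expect_true(is.na(p$hue))
  }
})

test_that("opponent predictions are exactly 180 degrees from the inducer", {
  for (hue in seq(0, 350, by = 37)) {
    ind <- luv_inducer(hue)
    idkl <- XYZ_to_dkl(inducer_to_XYZ(
      data.frame(space = "luv", hue = hue, chroma = 27, Lstar = 70,
                 label = ""), fix_monitor), fix_axes)
    p <- predict_cone_opponent(ind, fix_monitor, cfg_std, fix_axes)
    pdkl <- p$native$dkl
    pred_hue_dkl <- unname(wrap_hue(atan2(pdkl["s"], pdkl["lm"]) * 180 / pi))
    expect_equal(circular_signed_difference(pred_hue_dkl,
                                            idkl[1, "hue"] + 180), 0,
                 tolerance = 1e-9, ignore_attr = TRUE)
    # CIELUV-adaptation hue is identical to the cone-opponent hue
    pl <- predict_appearance_model(ind, "cieluv", fix_monitor, cfg_std,
                                   fix_axes)
    expect_equal(circular_signed_difference(pl$hue, p$hue), 0,
                 tolerance = 1e-6)
    # and, since stimulus rays are preserved, equals inducer + 180 in CIELUV
    expect_equal(circular_signed_difference(p$hue, hue + 180), 0,
                 tolerance = 1e-6)
  }
})

test_that("explicit k scales the opponent radius but not its hue", {
  ind <- dkl_inducer(60, 0.5)
  cfg_k <- adaptation_config(k = 0.5)
  p <- predict_cone_opponent(ind, fix_monitor, cfg_k, fix_axes)
  pdkl <- XYZ_to_dkl(p$native$XYZ, fix_axes)
  expect_equal(unname(pdkl[1, "radius"]), 0.25, tolerance = 1e-9)
  expect_equal(unname(pdkl[1, "hue"]), 240, tolerance = 1e-9)
  hue_half <- predict_cone_opponent(ind, fix_monitor,
                                    adaptation_config(k = 0.25), fix_axes)$hue
  expect_equal(p$hue, hue_half, tolerance = 1e-9)
})

test_that("cone predictions are invariant to per-channel cone rescaling", {
  set.seed(101)
  base <- fix_cones
  for (i in 1:10) {
    d <- runif(3, 0.1, 10)
    scaled <- structure(list(xyz2lms = diag(d) %*% base$xyz2lms,
                             lms2xyz = solve(diag(d) %*% base$xyz2lms),
                             name = "rescaled"),
                        class = "cone_fundamentals")
    cfg_s <- adaptation_config(cones = scaled)
    for (hue in c(20, 140, 260)) {
      p0 <- predict_cone_adaptation(luv_inducer(hue), fix_monitor, cfg_std)
      p1 <- predict_cone_adaptation(luv_inducer(hue), fix_monitor, cfg_s)
      expect_equal(p1$hue, p0$hue, tolerance = 1e-9)
      expect_equal(p1$chroma, p0$chroma, tolerance = 1e-9)
    }
  }
})

test_that("cone adaptation approaches the subtractive model at low strength", {
  hues <- seq(0, 315, by = 45)
  strengths <- c(27, 9, 3, 1)
  for (hue in hues) {
    devs <- vapply(strengths, function(s) {
      cfg <- adaptation_config(adapt_chroma_luv = s)
      p <- predict_cone_adaptation(luv_inducer(hue), fix_monitor, cfg)
      abs(circular_signed_difference(p$hue, hue + 180))
    }, numeric(1))
    expect_true(all(diff(devs) < 0))   # strictly decreasing
    cfg_tiny <- adaptation_config(adapt_chroma_luv = 0.01)
    p <- predict_cone_adaptation(luv_inducer(hue), fix_monitor, cfg_tiny)
    expect_lt(abs(circular_signed_difference(p$hue, hue + 180)), 0.1)
  }
})

test_that("cone-model chroma peaks three times and deviations cross zero six times", {
  circ <- hue_circle_set(5, 50, "luv", fix_monitor)
  pred <- predict_afterimage(circ, "cone", fix_monitor, cfg_std,
                             axes = fix_axes)
  dev <- deviation_from_opponency(pred$pred_hue, circ$hue)
  expect_equal(count_local_maxima(pred$pred_chroma), 3)
  expect_equal(count_zero_crossings(dev), 6)
})

test_that("the three-peak counts persist on a dense half-degree grid", {
  hues <- seq(0, 359.5, by = 0.5)
  chroma <- numeric(length(hues)); dev <- numeric(length(hues))
  for (i in seq_along(hues)) {
    p <- predict_cone_adaptation(luv_inducer(hues[i]), fix_monitor, cfg_std)
    chroma[i] <- p$chroma
    dev[i] <- circular_signed_difference(p$hue, hues[i] + 180)
  }
  expect_equal(count_local_maxima(chroma), 3)
  expect_equal(count_zero_crossings(dev), 6)
})

test_that("cone-adaptation afterimages are not reciprocal", {
  worst <- 0
  for (hue in seq(0, 355, by = 5)) {
    h1 <- predict_cone_adaptation(luv_inducer(hue), fix_monitor, cfg_std)$hue
    h2 <- predict_cone_adaptation(luv_inducer(h1), fix_monitor, cfg_std)$hue
    worst <- max(worst, abs(circular_signed_difference(h2, hue)))
  }
  expect_gt(worst, 2)
})

test_that("half-wave rectification leaves opponent predictions unchanged", {
  cfg_hw <- adaptation_config(halfwave_rectify = TRUE)
  for (hue in seq(0, 355, by = 5)) {
    a <- predict_cone_opponent(luv_inducer(hue), fix_monitor, cfg_std,
                               fix_axes)
    b <- predict_cone_opponent(luv_inducer(hue), fix_monitor, cfg_hw,
                               fix_axes)
    expect_equal(abs(circular_signed_difference(a$hue, b$hue)), 0,
                 tolerance = 1e-6)
    expect_equal(a$chroma, b$chroma, tolerance = 1e-9)
  }
})

test_that("opponent mechanisms equal minus the inducer cone contrasts", {
  # at isoluminance the subtractive opponent prediction, read out in raw
  # cone-contrast units, is minus the inducer's cone-contrast opponent signal
  cfg_full <- adaptation_config(adapt_chroma_luv = NA, adapt_radius_dkl = NA)
  bg_lms <- XYZ_to_LMS(fix_bg, fix_cones)
  for (hue in c(15, 100, 222, 301)) {
    ind <- dkl_inducer(hue, 0.4)
    i_lms <- XYZ_to_LMS(inducer_to_XYZ(ind, fix_monitor, fix_axes),
                        fix_cones)
    icc <- cone_contrast(i_lms, rbind(bg_lms))
    p <- predict_cone_opponent(ind, fix_monitor, cfg_full, fix_axes)
    pred_lm_raw <- unname(p$native$dkl["lm"]) * fix_axes$scale_lm
    pred_s_raw <- unname(p$native$dkl["s"]) * fix_axes$scale_s
    expect_equal(pred_lm_raw, -(icc[1, "ccL"] - icc[1, "ccM"]),
                 tolerance = 1e-9, ignore_attr = TRUE)
    expect_equal(pred_s_raw, -icc[1, "ccS"], tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("the CAT02 route matches a second formula-faithful implementation", {
  # independent implementation: explicit matrix entries, no shared helpers
  cat02_oracle <- function(xyz, wa, w, D) {
    M <- rbind(c(0.7328, 0.4296, -0.1624),
               c(-0.7036, 1.6975, 0.0061),
               c(0.0030, 0.0136, 0.9834))
    to <- function(v) c(M[1, ] %*% v, M[2, ] %*% v, M[3, ] %*% v)
    rgb <- to(xyz); ra <- to(wa); rw <- to(w)
    rc <- rgb * (D * wa[2] / ra + 1 - D)
    rout <- rc / (D * w[2] / rw + 1 - D)
    as.numeric(solve(M) %*% rout)
  }
  w <- as.numeric(fix_white)
  bg <- as.numeric(fix_bg)
  La <- bg[2] / 5
  D <- 1 * (1 - (1 / 3.6) * exp(-(La + 42) / 92))
  for (hue in seq(0, 315, by = 45)) {
    p <- predict_appearance_model(luv_inducer(hue), "ciecam02",
                                  fix_monitor, cfg_std)
    eff <- effective_adapting_colour(luv_inducer(hue), cfg_std, fix_monitor)
    wa <- as.numeric(attr(eff, "XYZ")); wa <- wa * w[2] / wa[2]
    ref <- cat02_oracle(bg, wa, w, D)
    ref_luv <- XYZ_to_luv(rbind(ref * bg[2] / ref[2]), fix_white)
    # compare hue after the same background-plane projection
    expect_equal(abs(circular_signed_difference(p$hue, ref_luv[1, "hue"])),
                 0, tolerance = 0.1)
  }
})

test_that("Hering interpolation transfers fractional position to the opponent pair", {
  pr <- hering_prototypes(red = 10, yellow = 70, green = 160, blue = 250)
  expect_equal(predict_hering(luv_inducer(10), pr)$hue, 160)   # red -> green
  expect_equal(predict_hering(luv_inducer(250), pr)$hue, 70)   # blue -> yellow
  expect_equal(predict_hering(luv_inducer(40), pr)$hue, 205)   # midpoint
  # t = 0.25 between yellow and green, against a parametric oracle
  t <- 0.25
  ind_hue <- 70 + t * ((160 - 70) %% 360)
  oracle <- 250 + t * ((10 - 250) %% 360)   # blue -> red arc
  expect_equal(predict_hering(luv_inducer(ind_hue), pr)$hue,
               wrap_hue(oracle), tolerance = 1e-9)
  expect_true(is.na(predict_hering(luv_inducer(40), pr)$chroma))
  expect_error(hering_prototypes(10, 250, 160, 70), "cyclic")
})

test_that("Munsell hue labels follow the 100-step circle arithmetic", {
  expect_equal(munsell_hue_position("5R"), 5)
  expect_equal(munsell_hue_position("7.5GY"), 37.5)
  expect_equal(munsell_opposite_label("5R"), "5BG")
  labels <- c("2.5R", "5Y", "10GY", "7.5PB")
  expect_equal(munsell_opposite_label(munsell_opposite_label(labels)),
               labels)
  expect_error(munsell_hue_position("12Q"), "unparseable")
})

test_that("a renotation grid point maps to the opposite grid entry exactly", {
  tb <- synthetic_munsell_table()
  rec <- tb$records
  pt <- rec[rec$hue_label == "5R" & rec$value == 7 & rec$chroma == 8, ]
  luv <- XYZ_to_luv(lab_to_XYZ(c(pt$Lstar, pt$astar, pt$bstar), fix_white),
                    fix_white)
  ind <- luv_inducer(luv[1, "hue"], luv[1, "chroma"], luv[1, "Lstar"])
  cfg_full <- adaptation_config(adapt_chroma_luv = NA)
  p <- predict_munsell(ind, tb, fix_monitor, cfg_full)
  opp <- rec[rec$hue_label == "5BG" & rec$value == 7 & rec$chroma == 8, ]
  oluv <- XYZ_to_luv(
    coneadapt:::project_to_bg_plane(
      lab_to_XYZ(c(opp$Lstar, opp$astar, opp$bstar), fix_white), fix_bg),
    fix_white)
  expect_equal(p$hue, unname(oluv[1, "hue"]), tolerance = 1e-6)
  expect_equal(p$chroma, unname(oluv[1, "chroma"]), tolerance = 1e-6)
  expect_equal(unname(p$native$munsell), c(5, 7, 8), tolerance = 1e-9)
})

test_that("response noise is wrapped-Gaussian, seeded and calibrated", {
  expect_equal(add_response_noise(c(10, 350), 0, 3, seed = 1),
               rep(c(10, 350), each = 3))
  a <- add_response_noise(180, 15, 100, seed = 42)
  b <- add_response_noise(180, 15, 100, seed = 42)
  expect_identical(a, b)
  expect_error(add_response_noise(10, -1, 5), "sigma")
  big <- add_response_noise(90, 15, 1e5, seed = 7)
  sd_hat <- coneadapt:::circular_sd_hue(big)
  expect_lt(abs(sd_hat - 15) / 15, 0.01)
})

test_that("the prediction front end returns one row per model and inducer", {
  circ <- hue_circle_set(45, 50, "luv", fix_monitor)
  tb <- synthetic_munsell_table()
  pr <- hering_prototypes(10, 70, 160, 250)
  pred <- predict_afterimage(circ, c("cone", "dkl", "cieluv", "cielab",
                                     "ciecam02", "munsell", "hering"),
                             fix_monitor, cfg_std, prototypes = pr,
                             munsell = tb, axes = fix_axes)
  expect_equal(nrow(pred), 8 * 7)
  expect_true(all(is.na(pred$pred_chroma[pred$model == "hering"])))
  expect_true(all(!is.na(pred$pred_hue)))
  expect_error(predict_afterimage(circ, "hering", fix_monitor, cfg_std),
               "prototypes")
})
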