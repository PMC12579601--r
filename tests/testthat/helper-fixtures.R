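# Shared fixtures: the study display, cone transform and DKL axes are
# deterministic, so compute them once per test run.

fix_monitor <- monitor_model()
fix_cones <- cone_fundamentals()
fix_axes <- dkl_axes(fix_monitor, fix_cones)
fix_white <- monitor_white(fix_monitor)
fix_bg <- monitor_background(fix_monitor)

# random colours strictly inside the monitor gamut (rendered from RGB)
random_in_gamut_XYZ <- function(n, margin = 0.05) {
  rgb <- matrix(runif(3 * n, margin, 1 - margin), ncol = 3)
  rgb_to_XYZ(rgb, fix_monitor)
}

luv_inducer <- function(hue, chroma = 50, Lstar = 70) {
  data.frame(space = "luv", hue = hue, chroma = chroma, Lstar = Lstar,
             label = "test")
}

dkl_inducer <- function(hue, radius = 0.5) {
  data.frame(space = "dkl", hue = hue, chroma = radius,
             Lstar = fix_monitor$background_Lstar, label = "test")
}

# count circular local maxima / sign changes of a series over a closed circle
count_local_maxima <- function(v) {
  n <- length(v)
  sum(v > v[c(n, 1:(n - 1))] & v >= v[c(2:n, 1)])
}

count_zero_crossings <- function(v) {
  n <- length(v)
  sum(sign(v) * sign(v[c(2:n, 1)]) < 0)
}
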