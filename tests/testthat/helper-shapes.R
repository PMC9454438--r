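# Shared fixture builders. Everything is generated in code; no files.

# Random star-shaped simple polygon: angles drawn from a jittered
# regular grid so that no angular gap reaches pi (which guarantees
# simplicity for any radius pattern).
star_polygon <- function(n, cx = 0, cy = 0, rmin = 0.3, rmax = 1.2) {
  th <- 2 * pi * (seq_len(n) - 1) / n + runif(n, 0.03, 0.97) * 2 * pi / n
  r <- runif(n, rmin, rmax)
  cbind(cx + r * cos(th), cy + r * sin(th))
}

unit_square <- function(ox = 0, oy = 0, s = 1) {
  rbind(c(ox, oy), c(ox + s, oy), c(ox + s, oy + s), c(ox, oy + s))
}

# Random hip-shaped polygon pair (cup + head) without ground truth.
random_hip_polygons <- function() {
  R <- runif(1, 80, 120)
  p <- hip_shape_params(
    acetabular_radius = R,
    femoral_radius = R * runif(1, 0.75, 0.95),
    displacement = R * runif(1, 0, 1.2),
    opening_halfangle = runif(1, 30, 90),
    n_vertices = sample(64:128, 1))
  hcindex:::.hip_polygons(p, center = runif(2, 400, 1600),
                          side = sample(c("left", "right"), 1))
}

# Independent two-way ANOVA computation for the ICC oracle: explicit
# elementwise sums, no matrix shortcuts shared with icc_3_1().
brute_force_icc31 <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- sum(m) / (n * k)
  ss_rows <- 0
  for (i in seq_len(n)) ss_rows <- ss_rows + k * (mean(m[i, ]) - grand)^2
  ss_cols <- 0
  for (j in seq_len(k)) ss_cols <- ss_cols + n * (mean(m[, j]) - grand)^2
  ss_tot <- 0
  for (i in seq_len(n)) for (j in seq_len(k))
    ss_tot <- ss_tot + (m[i, j] - grand)^2
  ms_r <- ss_rows / (n - 1)
  ms_e <- (ss_tot - ss_rows - ss_cols) / ((n - 1) * (k - 1))
  (ms_r - ms_e) / (ms_r + (k - 1) * ms_e)
}
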