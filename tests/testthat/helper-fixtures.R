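# Shared fixtures: everything is generated in code at test time.

# A coarse phantom for fast unit tests (full-size defaults are exercised in
# the acceptance suite).
tiny_spec <- function(...) {
  phantom_spec(dim = c(40, 40, 16), spacing = c(4, 4, 6),
               neck_semi_axes = c(60, 50), spine_center = c(0, -22),
               spine_radius = 10, airway_center = c(0, 18),
               airway_radius = 7, ctv_center = c(12, 0), ctv_radius = 16,
               ctv_slices = c(5, 12), ...)
}

# Smooth random HU volume: low-frequency structure plus voxel noise, so
# gamma values span pass and fail without saturating everywhere.
rand_volume <- function(dm = c(16, 16, 16), spacing = c(2, 2, 2),
                        seed = 1, lf_amp = 120, noise = 40) {
  set.seed(seed)
  ph <- runif(6, 0, 2 * pi)
  xs <- seq_len(dm[1]); ys <- seq_len(dm[2]); zs <- seq_len(dm[3])
  lf <- outer(outer(sin(xs / 3 + ph[1]) + cos(xs / 7 + ph[2]),
                    sin(ys / 4 + ph[3]), "+"),
              cos(zs / 5 + ph[4]), "+")
  vals <- lf_amp * lf + rnorm(prod(dm), 0, noise)
  volume3d(array(vals, dm), spacing)
}

# Central ellipsoid mask covering roughly half the volume.
central_mask <- function(vol, frac = 0.8) {
  dm <- dim(vol$values)
  cx <- (dm + 1) / 2
  idx <- expand.grid(i = seq_len(dm[1]), j = seq_len(dm[2]),
                     k = seq_len(dm[3]))
  r <- sqrt(((idx$i - cx[1]) / (dm[1] * frac / 2))^2 +
            ((idx$j - cx[2]) / (dm[2] * frac / 2))^2 +
            ((idx$k - cx[3]) / (dm[3] * frac / 2))^2)
  mask3d(array(r <= 1, dm), vol$spacing, vol$origin)
}

full_mask <- function(vol) {
  mask3d(array(TRUE, dim(vol$values)), vol$spacing, vol$origin)
}

# Minimal hand-built mqp_series for decision-rule tests (no volumes needed).
fake_series <- function(mqp, fractions = seq_along(mqp), segment_id = 1L,
                        rect_order_fraction = NA) {
  rec <- data.frame(fraction = as.integer(fractions),
                    n_masked = 1000L, n_failed = 100L,
                    gamma_x = 1.5 - mqp, mqp = mqp)
  anatgamma:::new_mqp_series(segment_id, rec, 1.5, 80,
                             gamma_criteria(3, 30),
                             rect_order_fraction = rect_order_fraction)
}
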