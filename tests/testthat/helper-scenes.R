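# Shared fixtures: scenes are always built in code from seeded templates.

scene_for <- function(condition, seed = 1L, ...) {
  generate_scene(params_for_condition(condition, seed = seed, ...))
}

# a plain normal eye with hand-picked geometry (subject-left, no jitter)
manual_params <- function(peak_mm = 4, dip_mm = 1, cornea_dx = 0,
                          noise_sd = 0, seed = 1L, ...) {
  eye_scene_params(
    laterality = "left",
    inner_canthus = c(133, 140), outer_canthus = c(283, 140),
    upper_curve_peak_mm = peak_mm, lower_curve_dip_mm = dip_mm,
    cornea_center = c(208 + cornea_dx, 140),
    noise_sd = noise_sd, seed = seed, ...)
}

# one shared config; rules/thresholds are the package defaults
test_config <- local({
  cfg <- NULL
  function() {
    if (is.null(cfg)) cfg <<- pipeline_config()
    cfg
  }
})

# independent quadratic-margin oracle (duplicates the documented geometry on
# purpose: tests must not lean on lid_curves())
oracle_margins <- function(p) {
  xi <- p$inner_canthus[1]; yi <- p$inner_canthus[2]
  xo <- p$outer_canthus[1]; yo <- p$outer_canthus[2]
  s <- p$mm_per_px
  list(
    yu = function(x) {
      t <- (x - xi) / (xo - xi)
      yi + t * (yo - yi) - (p$upper_curve_peak_mm / s) * 4 * t * (1 - t)
    },
    yl = function(x) {
      t <- (x - xi) / (xo - xi)
      yi + t * (yo - yi) + (p$lower_curve_dip_mm / s) * 4 * t * (1 - t)
    })
}

# distinct deterministic seeds per (condition, replicate)
derive_seed_test <- function(cond, s) {
  (sum(utf8ToInt(cond)) * 131L + s * 101L) %% 100000L
}

# rasterise a disc the way an independent oracle would (pixel-centre rule)
oracle_disc_mask <- function(h, w, center, radius, label = 5L, background = 1L) {
  d2 <- outer((seq_len(h) - 1 - center[2])^2, (seq_len(w) - 1 - center[1])^2, `+`)
  m <- matrix(background, h, w)
  m[d2 <= radius^2] <- label
  m
}
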