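# Shared fixture builders: everything generated in code, seeded.

random_structure <- function(n_atoms, cell = unit_cell(20, 25, 30),
                             space_group = "P1", seed = 1,
                             elements = c("C", "N", "O", "S"),
                             u_range = c(0.01, 0.05)) {
  withr::with_seed(seed, {
    crystal_structure(cell, data.frame(
      element = sample(elements, n_atoms, replace = TRUE),
      x = runif(n_atoms), y = runif(n_atoms), z = runif(n_atoms),
      occ = 1, u_iso = runif(n_atoms, u_range[1], u_range[2])),
      space_group = space_group)
  })
}

# the seeded 500-atom orthorhombic P1 benchmark structure
benchmark_structure <- function(n = 500, seed = 20130618) {
  random_structure(n, cell = unit_cell(40, 50, 60), seed = seed,
                   u_range = c(0.02, 0.05))
}

# compact test detector reaching ~2.4 A at the corner
test_geometry <- function(image_size = c(256, 256), distance = 40,
                          wavelength = 1.0, pixel_size = 0.1) {
  detector_geometry(distance, wavelength,
                    beam_center = image_size / 2 * pixel_size,
                    pixel_size = pixel_size, image_size = image_size)
}

# frame with n well-separated bright planted spots, optionally off a d* band
planted_frame <- function(n_spots = 30, seed = 1, geometry = test_geometry(),
                          background = 10, intensity = 2000, sigma = 1.5,
                          min_sep = 12, rings = NULL, exclude_band = NULL) {
  excl <- NULL
  if (!is.null(exclude_band)) {
    g <- geometry
    excl <- function(s, f) {
      r <- sqrt((s * g$pixel_size - g$beam_center[1])^2 +
                  (f * g$pixel_size - g$beam_center[2])^2)
      ds <- 2 * sin(0.5 * atan(r / g$distance)) / g$wavelength
      ds >= exclude_band[1] & ds <= exclude_band[2]
    }
  }
  ctr <- place_spot_centers(n_spots, geometry$image_size, min_sep = min_sep,
                            margin = 10, seed = seed, exclude = excl)
  ctr$intensity <- intensity
  ctr$sigma <- sigma
  frame_spec(geometry, background_mean = background, spots = ctr,
             rings = rings, seed = seed)
}

# spot-recovery score against planted ground truth
recovery_score <- function(spots, truth, tol_px = 1.5) {
  if (nrow(truth) == 0) {
    return(list(tp = 0, fp = nrow(spots), fn = 0))
  }
  if (nrow(spots) == 0) {
    return(list(tp = 0, fp = 0, fn = nrow(truth)))
  }
  d <- sqrt(outer(spots$centroid_slow, truth$slow, "-")^2 +
              outer(spots$centroid_fast, truth$fast, "-")^2)
  matched <- apply(d, 2, min) <= tol_px
  list(tp = sum(matched),
       fp = nrow(spots) - sum(apply(d, 1, min) <= tol_px),
       fn = sum(!matched))
}
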