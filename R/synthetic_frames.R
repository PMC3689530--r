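#' Synthetic frame specification
#'
#' Everything needed to generate one detector frame with known ground
#' truth: Poisson background, planted pixel-integrated Gaussian spots,
#' optional azimuthal powder/ice rings, masked rectangles and a saturation
#' cap.  One seed drives the single random source of the frame.
#'
#' @param geometry A [detector_geometry()].
#' @param background_mean Poisson mean per pixel in ADU (>= 0).
#' @param spots data.frame with columns `slow`, `fast` (continuous pixel
#'   coordinates of the planted centers), `intensity` (integrated ADU) and
#'   `sigma` (Gaussian width in pixels, > 0); may be empty.
#' @param rings data.frame with columns `d` (Angstrom), `amplitude` (peak
#'   ADU) and `width` (Gaussian width in 1/Angstrom); may be empty.
#' @param masked_regions List of length-4 vectors `c(slow0, slow1, fast0,
#'   fast1)` (0-based inclusive pixel ranges) zeroed and flagged inactive.
#' @param saturation ADU cap (default 65535, must exceed the background mean).
#' @param seed Integer seed for the frame's random source.
#' @return List of class `frame_spec`.
#' @export
frame_spec <- function(geometry, background_mean = 0,
                       spots = NULL, rings = NULL, masked_regions = list(),
                       saturation = 65535, seed = 1) {
  stopifnot(inherits(geometry, "detector_geometry"), background_mean >= 0,
            saturation > background_mean)
  if (is.null(spots)) {
    spots <- data.frame(slow = numeric(0), fast = numeric(0),
                        intensity = numeric(0), sigma = numeric(0))
  }
  if (is.null(rings)) {
    rings <- data.frame(d = numeric(0), amplitude = numeric(0),
                        width = numeric(0))
  }
  if (nrow(spots) > 0) {
    if (any(spots$sigma <= 0)) stop("spot sigma must be positive")
    ok <- spots$slow >= 0 & spots$slow <= geometry$image_size[1] &
      spots$fast >= 0 & spots$fast <= geometry$image_size[2]
    if (!all(ok)) {
      stop(sprintf("spot center(s) %s outside the image",
                   paste(which(!ok), collapse = ", ")))
    }
  }
  structure(list(geometry = geometry, background_mean = background_mean,
                 spots = spots, rings = rings,
                 masked_regions = masked_regions,
                 saturation = saturation, seed = as.integer(seed)),
            class = "frame_spec")
}

# integral of a unit 2D Gaussian over pixel rows/cols: error-function
# differences, exact per pixel (no point sampling)
.gauss_pixel_profile <- function(center, sigma, n) {
  lo <- max(0L, floor(center - 6 * sigma))
  hi <- min(n, ceiling(center + 6 * sigma))
  if (hi <= lo) return(list(idx = integer(0), w = numeric(0)))
  edges <- lo:hi
  cdf <- stats::pnorm(edges, mean = center, sd = sigma)
  list(idx = (lo + 1):hi, w = diff(cdf))   # 1-based pixel indices
}

#' Generate a detector frame with ground truth
#'
#' Pixel counts are `Poisson(background) + planted spots + rings`, rounded,
#' clipped at saturation and zeroed on masked regions.  Spots are
#' pixel-integrated 2D Gaussians (error-function differences along each
#' axis), so the planted integrated intensity is conserved on the image;
#' rings are azimuthal Gaussian profiles in d*.  The frame's single random
#' source is seeded once from `spec$seed` (background draw first), so
#' identical specs give byte-identical frames.
#'
#' @param spec A [frame_spec()].
#' @return List: `frame` (a [detector_frame()]) and `ground_truth` (planted
#'   spot table, ring d* intervals, masked regions).
#' @export
generate_frame <- function(spec) {
  stopifnot(inherits(spec, "frame_spec"))
  g <- spec$geometry
  ns <- g$image_size[1]; nf <- g$image_size[2]
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)
  img <- matrix(if (spec$background_mean > 0) {
    stats::rpois(ns * nf, spec$background_mean)
  } else 0, ns, nf)
  img <- img * 1.0
  for (i in seq_len(nrow(spec$spots))) {
    ps <- .gauss_pixel_profile(spec$spots$slow[i], spec$spots$sigma[i], ns)
    pf <- .gauss_pixel_profile(spec$spots$fast[i], spec$spots$sigma[i], nf)
    img[ps$idx, pf$idx] <- img[ps$idx, pf$idx] +
      spec$spots$intensity[i] * outer(ps$w, pf$w)
  }
  ring_truth <- NULL
  if (nrow(spec$rings) > 0) {
    dstar_px <- 1 / .radius_to_d(.pixel_radius_mm(g), g)
    for (i in seq_len(nrow(spec$rings))) {
      s0 <- 1 / spec$rings$d[i]; wd <- spec$rings$width[i]
      img <- img + spec$rings$amplitude[i] * exp(-(dstar_px - s0)^2 / (2 * wd^2))
    }
    ring_truth <- data.frame(d_star_min = 1 / spec$rings$d - 3 * spec$rings$width,
                             d_star_max = 1 / spec$rings$d + 3 * spec$rings$width)
  }
  img <- pmin(round(img), spec$saturation)
  mask <- matrix(TRUE, ns, nf)
  for (rc in spec$masked_regions) {
    rs <- (rc[1]:rc[2]) + 1; cs <- (rc[3]:rc[4]) + 1
    rs <- rs[rs >= 1 & rs <= ns]; cs <- cs[cs >= 1 & cs <= nf]
    img[rs, cs] <- 0
    mask[rs, cs] <- FALSE
  }
  storage.mode(img) <- "integer"
  list(frame = detector_frame(img, g, mask),
       ground_truth = list(spots = spec$spots, rings = ring_truth,
                           masked_regions = spec$masked_regions))
}

#' Place spot centers with a minimum pairwise separation
#'
#' Seeded rejection sampler for well-separated planted spots inside a
#' margin; used by the stream generator and the recovery tests.
#'
#' @param n Number of centers.
#' @param image_size Length-2 `(slow, fast)` pixel counts.
#' @param min_sep Minimum center-to-center distance in pixels.
#' @param margin Border kept free of centers, pixels (default 8).
#' @param seed Integer seed.
#' @param exclude Optional function(slow, fast) returning TRUE for positions
#'   to reject (e.g. to keep spots off a planted ring).
#' @return data.frame with columns `slow`, `fast`.
#' @export
place_spot_centers <- function(n, image_size, min_sep, margin = 8, seed = 1,
                               exclude = NULL) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  pts <- matrix(numeric(0), 0, 2)
  tries <- 0
  while (nrow(pts) < n && tries < 20000 * n) {
    tries <- tries + 1
    p <- c(stats::runif(1, margin, image_size[1] - margin),
           stats::runif(1, margin, image_size[2] - margin))
    if (!is.null(exclude) && exclude(p[1], p[2])) next
    if (nrow(pts) == 0 || min(sqrt((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2)) >= min_sep) {
      pts <- rbind(pts, p)
    }
  }
  if (nrow(pts) < n) stop("could not place the requested spot count at this separation")
  data.frame(slow = pts[, 1], fast = pts[, 2])
}

#' Predicted spot positions for two lattices on one frame
#'
#' Synthetic stand-in for a two-crystal exposure: each lattice's reflections
#' to `d_min` are projected onto the detector for a still shot, keeping
#' those whose reciprocal node lies within a tolerance band of the Ewald
#' sphere.  Orientations are random rotations (drawn from the seed) applied
#' to each crystal; the result is one predicted-centroid list per lattice
#' for overlap analysis.
#'
#' @param geometry A [detector_geometry()].
#' @param cell_a,cell_b [unit_cell()]s of the two crystals.
#' @param d_min Resolution limit in Angstrom.
#' @param angle_offset_deg Rotation (degrees, about the slow axis) applied
#'   to lattice b relative to lattice a's random orientation; small values
#'   give heavily overlapping predictions, large values mostly separated
#'   ones.
#' @param tolerance Half-width of the still-diffraction excitation band in
#'   1/Angstrom (default 0.002).
#' @param seed Integer seed for the base orientation.
#' @return List of two data.frames (`a`, `b`) with columns `slow`, `fast`
#'   (pixels) and `hkl` columns.
#' @export
sample_two_lattice_positions <- function(geometry, cell_a, cell_b, d_min,
                                         angle_offset_deg = 5,
                                         tolerance = 0.002, seed = 1) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  base <- .random_rotation()
  off <- .axis_rotation(angle_offset_deg * pi / 180)
  list(a = .project_lattice(geometry, cell_a, d_min, base, tolerance),
       b = .project_lattice(geometry, cell_b, d_min, off %*% base, tolerance))
}

.random_rotation <- function() {
  # QR of a Gaussian matrix, sign-fixed; uniform over rotations
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

.axis_rotation <- function(angle) {
  matrix(c(1, 0, 0,
           0, cos(angle), -sin(angle),
           0, sin(angle), cos(angle)), 3, 3, byrow = TRUE)
}

# still-shot projection: reciprocal nodes near the Ewald sphere, gnomonic
# projection to the flat detector
.project_lattice <- function(geometry, cell, d_min, rot, tolerance) {
  hkl <- miller_index_set(cell, d_min, friedel = FALSE)
  # reciprocal Cartesian coordinates: q = A* H with A* = (orth^-1)^T
  q <- hkl %*% cell$frac %*% t(rot)                # n x 3, 1/Angstrom
  k0 <- 1 / geometry$wavelength                    # beam along +z
  # distance of node from the Ewald sphere centered at (0,0,-k0)
  r_ewald <- sqrt(q[, 1]^2 + q[, 2]^2 + (q[, 3] + k0)^2)
  excited <- abs(r_ewald - k0) <= tolerance & (q[, 3] + k0) > 0
  q <- q[excited, , drop = FALSE]
  hkl <- hkl[excited, , drop = FALSE]
  # diffracted ray through the node direction; detector at distance D
  s <- q
  s[, 3] <- s[, 3] + k0
  t <- geometry$distance / s[, 3]
  xs <- s[, 1] * t + geometry$beam_center[1]
  yf <- s[, 2] * t + geometry$beam_center[2]
  px <- xs / geometry$pixel_size
  py <- yf / geometry$pixel_size
  on_det <- px >= 0 & px <= geometry$image_size[1] &
    py >= 0 & py <= geometry$image_size[2]
  data.frame(slow = px[on_det], fast = py[on_det],
             h = hkl[on_det, 1], k = hkl[on_det, 2], l = hkl[on_det, 3])
}

#' Generate a synthetic monitoring stream
#'
#' A Bernoulli(hit_probability) label per frame: hits are assigned
#' `spots_per_hit` planted spots and misses `spots_per_miss` (choose the
#' two to straddle the monitoring threshold for deterministic ground
#' truth).  Timestamps follow the acquisition cadence `i / rate_hz`.
#' Returns light-weight frame specs — frames are only rendered on demand by
#' [generate_frame()].
#'
#' @param n_frames Number of frames.
#' @param hit_probability Probability a frame is a hit, in `[0, 1]`.
#' @param spots_per_hit,spots_per_miss Planted spot counts (default 20 / 4).
#' @param rate_hz Acquisition rate (default 120).
#' @param geometry Frame geometry (default: compact 96 x 96 pixel frame).
#' @param background_mean,spot_intensity,spot_sigma Frame rendering
#'   parameters (defaults 10 ADU, 2000 ADU, 1 px).
#' @param seed Integer master seed (labels and per-frame seeds derive from it).
#' @return List: `frames` (list of [frame_spec()]), `records` (data.frame
#'   `timestamp`, `frame_id`, `n_spots_planted`, `hit`).
#' @export
generate_stream <- function(n_frames, hit_probability, spots_per_hit = 20,
                            spots_per_miss = 4, rate_hz = 120,
                            geometry = NULL, background_mean = 10,
                            spot_intensity = 2000, spot_sigma = 1, seed = 1) {
  stopifnot(hit_probability >= 0, hit_probability <= 1)
  if (is.null(geometry)) {
    geometry <- detector_geometry(distance = 100, wavelength = 1.3,
                                  beam_center = c(4.8, 4.8),
                                  pixel_size = 0.1, image_size = c(96, 96))
  }
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  hits <- stats::runif(n_frames) < hit_probability
  sub_seeds <- sample.int(.Machine$integer.max - 1, n_frames)
  frames <- vector("list", n_frames)
  for (i in seq_len(n_frames)) {
    n_sp <- if (hits[i]) spots_per_hit else spots_per_miss
    centers <- place_spot_centers(n_sp, geometry$image_size,
                                  min_sep = 10 * spot_sigma, margin = 6,
                                  seed = sub_seeds[i])
    centers$intensity <- spot_intensity
    centers$sigma <- spot_sigma
    frames[[i]] <- frame_spec(geometry, background_mean = background_mean,
                              spots = centers, seed = sub_seeds[i])
  }
  list(frames = frames,
       records = data.frame(timestamp = (seq_len(n_frames) - 1) / rate_hz,
                            frame_id = seq_len(n_frames) - 1L,
                            n_spots_planted = ifelse(hits, spots_per_hit,
                                                     spots_per_miss),
                            hit = hits))
}
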