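#' Detector geometry
#'
#' @param distance Crystal-to-detector distance in mm.
#' @param wavelength X-ray wavelength in Angstrom.
#' @param beam_center Length-2 `(x, y)` beam position in mm, in (slow, fast)
#'   axis order.
#' @param pixel_size Pixel edge in mm.
#' @param image_size Length-2 `(slow, fast)` pixel counts.
#' @return Object of class `detector_geometry`.
#' @export
detector_geometry <- function(distance, wavelength, beam_center, pixel_size,
                              image_size) {
  stopifnot(distance > 0, wavelength > 0, pixel_size > 0,
            length(beam_center) == 2, length(image_size) == 2,
            all(image_size >= 1))
  structure(list(distance = distance, wavelength = wavelength,
                 beam_center = as.numeric(beam_center),
                 pixel_size = pixel_size,
                 image_size = as.integer(image_size)),
            class = "detector_geometry")
}

#' Detector frame
#'
#' A 2D pixel-count image with its geometry and an active-pixel mask.  Pixel
#' coordinates are 0-based in (slow, fast) order with pixel centers at
#' half-integers, so pixel `(i, j)` is centered at
#' `((i + 0.5) * pixel_size, (j + 0.5) * pixel_size)` mm.
#'
#' @param counts Integer matrix (rows = slow, cols = fast), counts >= 0.
#' @param geometry A [detector_geometry()]; sizes must match `counts`.
#' @param mask Logical matrix, TRUE = active; defaults to all active.
#' @return Object of class `detector_frame`.
#' @export
detector_frame <- function(counts, geometry, mask = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (!all(dim(counts) == geometry$image_size)) {
    stop("counts dimensions do not match geometry image_size")
  }
  if (is.null(mask)) mask <- matrix(TRUE, nrow(counts), ncol(counts))
  if (!all(dim(mask) == dim(counts))) stop("mask shape must match counts")
  structure(list(counts = counts, geometry = geometry,
                 mask = mask & TRUE),
            class = "detector_frame")
}

# d-spacing (Angstrom) at radius r mm from the beam center
.radius_to_d <- function(r, geometry) {
  theta2 <- atan(r / geometry$distance)
  geometry$wavelength / (2 * sin(theta2 / 2))
}

# per-pixel radius (mm) from the beam center, pixel centers at half-integers
.pixel_radius_mm <- function(geometry) {
  ns <- geometry$image_size[1]; nf <- geometry$image_size[2]
  xs <- ((0:(ns - 1)) + 0.5) * geometry$pixel_size - geometry$beam_center[1]
  yf <- ((0:(nf - 1)) + 0.5) * geometry$pixel_size - geometry$beam_center[2]
  sqrt(outer(xs^2, yf^2, "+"))
}

#' Classify pixels as signal or noise
#'
#' Estimates a robust background per square tile — median and a
#' MAD-derived sigma over the tile's active pixels — and flags a pixel as
#' signal when it is active and exceeds `median + n_sigma * sigma`.  Tiles
#' with too few active pixels fall back to the global statistics; inactive
#' pixels are never signal.  Poisson shot noise sets a floor of
#' `sqrt(max(median, 1))` on sigma so that flat low-count backgrounds do not
#' produce a zero spread.
#'
#' @param frame A [detector_frame()].
#' @param n_sigma Threshold in robust sigmas (default 3.5).
#' @param tile Tile edge in pixels (default 64, minimum 8).
#' @return Logical signal mask of the frame's shape.
#' @export
classify_pixels <- function(frame, n_sigma = 3.5, tile = 64) {
  stopifnot(inherits(frame, "detector_frame"), n_sigma > 0, tile >= 8)
  cnt <- frame$counts; act <- frame$mask
  if (!any(act)) {
    warning("frame is fully masked; no signal pixels")
    return(matrix(FALSE, nrow(cnt), ncol(cnt)))
  }
  gmed <- stats::median(cnt[act])
  gsig <- max(stats::mad(cnt[act]), sqrt(max(gmed, 1)))
  sig <- matrix(FALSE, nrow(cnt), ncol(cnt))
  rs <- split(seq_len(nrow(cnt)), ceiling(seq_len(nrow(cnt)) / tile))
  cs <- split(seq_len(ncol(cnt)), ceiling(seq_len(ncol(cnt)) / tile))
  for (ri in rs) for (ci in cs) {
    blk <- cnt[ri, ci, drop = FALSE]
    a <- act[ri, ci, drop = FALSE]
    if (sum(a) >= 16) {
      med <- stats::median(blk[a])
      sg <- max(stats::mad(blk[a]), sqrt(max(med, 1)))
    } else {
      med <- gmed; sg <- gsig
    }
    sig[ri, ci] <- a & (blk > med + n_sigma * sg)
  }
  sig
}

# robust per-tile background estimate (median), used for spot integration
.background_map <- function(frame, tile = 64) {
  cnt <- frame$counts; act <- frame$mask
  bg <- matrix(if (any(act)) stats::median(cnt[act]) else 0,
               nrow(cnt), ncol(cnt))
  rs <- split(seq_len(nrow(cnt)), ceiling(seq_len(nrow(cnt)) / tile))
  cs <- split(seq_len(ncol(cnt)), ceiling(seq_len(ncol(cnt)) / tile))
  for (ri in rs) for (ci in cs) {
    a <- act[ri, ci, drop = FALSE]
    if (sum(a) >= 16) bg[ri, ci] <- stats::median(cnt[ri, ci][a])
  }
  bg
}

# 8-connected component labelling over the TRUE pixels of a logical matrix.
# Works on the signal-pixel list only (spot masks are sparse), union-find
# with path halving.
label_components <- function(mask) {
  idx <- which(mask)
  if (length(idx) == 0) return(list(labels = integer(0), idx = idx))
  nr <- nrow(mask)
  pos <- integer(length(mask)); pos[idx] <- seq_along(idx)
  parent <- seq_along(idx)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  r <- ((idx - 1) %% nr) + 1
  c <- ((idx - 1) %/% nr) + 1
  # backward 8-neighbours: W, NW, N, NE
  for (d in list(c(0, -1), c(-1, -1), c(-1, 0), c(1, -1))) {
    rr <- r + d[1]; cc <- c + d[2]
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= ncol(mask)
    nb <- (cc[ok] - 1) * nr + rr[ok]
    here <- which(ok)[pos[nb] > 0]
    nb <- nb[pos[nb] > 0]
    for (t in seq_along(here)) {
      a <- find(here[t]); b <- find(pos[nb[t]])
      if (a != b) parent[a] <- b
    }
  }
  roots <- vapply(seq_along(idx), find, integer(1))
  list(labels = match(roots, unique(roots)), idx = idx)
}

#' Identify Bragg spots from a signal mask
#'
#' Groups signal pixels into 8-connected components; components with at
#' least `min_pixels` pixels become spots.  The centroid is the
#' intensity-weighted mean pixel position (background-subtracted weights),
#' the total intensity is the background-subtracted sum, and the resolution
#' follows from the centroid radius r via `d = lambda / (2 sin(atan(r/D)/2))`.
#'
#' @param frame A [detector_frame()].
#' @param signal_mask Logical matrix from [classify_pixels()].
#' @param min_pixels Minimum component size (default 2).
#' @param tile Tile size used for the background map (default 64).
#' @return A `spot_list`: data.frame with columns `centroid_slow`,
#'   `centroid_fast` (0-based continuous pixel coordinates),
#'   `n_pixels`, `total_intensity`, `peak_height`, `d_spacing` (from the
#'   centroid radius), `d_star_mean` (intensity-weighted mean pixel d*,
#'   the robust estimate used for ring rejection: it stays on the ring for
#'   azimuthally extended components whose centroid degenerates towards the
#'   beam center), plus bounding-box columns used by the quality filter.
#' @export
find_spots <- function(frame, signal_mask, min_pixels = 2, tile = 64) {
  stopifnot(all(dim(signal_mask) == dim(frame$counts)))
  lab <- label_components(signal_mask & frame$mask)
  empty <- data.frame(centroid_slow = numeric(0), centroid_fast = numeric(0),
                      n_pixels = integer(0), total_intensity = numeric(0),
                      peak_height = numeric(0), d_spacing = numeric(0),
                      d_star_mean = numeric(0),
                      bbox_slow = integer(0), bbox_fast = integer(0))
  if (length(lab$idx) == 0) return(structure(empty, class = c("spot_list", "data.frame")))
  bg <- .background_map(frame, tile = tile)
  nr <- nrow(frame$counts)
  r <- ((lab$idx - 1) %% nr)          # 0-based slow
  c <- ((lab$idx - 1) %/% nr)         # 0-based fast
  w <- pmax(frame$counts[lab$idx] - bg[lab$idx], 0)
  g <- frame$geometry
  px_dstar <- 1 / .radius_to_d(.pixel_radius_mm(g), g)
  spots <- do.call(rbind, lapply(split(seq_along(lab$idx), lab$labels), function(ii) {
    if (length(ii) < min_pixels) return(NULL)
    wi <- w[ii]
    if (sum(wi) <= 0) return(NULL)
    # centroid over pixel centers (index + 0.5), reported 0-based continuous
    cs <- sum((r[ii] + 0.5) * wi) / sum(wi)
    cf <- sum((c[ii] + 0.5) * wi) / sum(wi)
    rad <- sqrt((cs * g$pixel_size - g$beam_center[1])^2 +
                (cf * g$pixel_size - g$beam_center[2])^2)
    data.frame(centroid_slow = cs, centroid_fast = cf,
               n_pixels = length(ii), total_intensity = sum(wi),
               peak_height = max(wi),
               d_spacing = .radius_to_d(rad, g),
               d_star_mean = sum(px_dstar[lab$idx[ii]] * wi) / sum(wi),
               bbox_slow = diff(range(r[ii])) + 1L,
               bbox_fast = diff(range(c[ii])) + 1L)
  }))
  if (is.null(spots)) spots <- empty
  rownames(spots) <- NULL
  spots <- spots[order(spots$centroid_slow, spots$centroid_fast), , drop = FALSE]
  rownames(spots) <- NULL
  structure(spots, class = c("spot_list", "data.frame"))
}

#' Detect ice/powder rings from the signal-pixel radial distribution
#'
#' Histograms the signal-pixel occupancy (signal / active pixel count) in
#' equal-width d* shells; shells above `occupancy_cut` are flagged as ring
#' intervals and adjacent flagged shells are merged.  An azimuthally
#' complete ring lights up its whole shell, while even many isolated Bragg
#' spots occupy a tiny shell fraction.  Known ice d-spacings can pre-seed
#' intervals via `seed_d`.
#'
#' @param frame A [detector_frame()].
#' @param signal_mask Logical matrix from [classify_pixels()].
#' @param shell_width Shell width in 1/Angstrom (default 0.002).
#' @param occupancy_cut Flagging threshold on the shell signal fraction
#'   (default 0.25).
#' @param min_shell_pixels Shells with fewer active pixels are never flagged
#'   (default 128): very small shells — the few pixels right at the beam
#'   center — cannot carry an azimuthally meaningful ring, and a single
#'   compact spot there would otherwise dominate its shell.
#' @param seed_d Optional d-spacings (Angstrom) seeding one shell-wide
#'   interval each (e.g. hexagonal-ice rings 3.90, 3.67, 3.44).
#' @return data.frame of intervals with columns `d_star_min`, `d_star_max`.
#' @export
detect_rings <- function(frame, signal_mask, shell_width = 0.002,
                         occupancy_cut = 0.25, min_shell_pixels = 128,
                         seed_d = NULL) {
  g <- frame$geometry
  dstar <- 1 / .radius_to_d(.pixel_radius_mm(g), g)
  act <- frame$mask
  shell <- floor(dstar / shell_width)
  n_act <- tapply(act, shell, sum)
  n_sig <- tapply(signal_mask & act, shell, sum)
  occ <- as.numeric(n_sig) / pmax(as.numeric(n_act), 1)
  ids <- as.numeric(names(n_act))
  flagged <- ids[occ > occupancy_cut & as.numeric(n_act) >= min_shell_pixels]
  if (!is.null(seed_d)) flagged <- union(flagged, floor((1 / seed_d) / shell_width))
  flagged <- sort(flagged)
  if (length(flagged) == 0) {
    return(data.frame(d_star_min = numeric(0), d_star_max = numeric(0)))
  }
  brk <- c(0, which(diff(flagged) > 1), length(flagged))
  do.call(rbind, lapply(seq_len(length(brk) - 1), function(i) {
    run <- flagged[(brk[i] + 1):brk[i + 1]]
    data.frame(d_star_min = min(run) * shell_width,
               d_star_max = (max(run) + 1) * shell_width)
  }))
}

#' Apply ring rejection and spot-quality heuristics
#'
#' Removes spots whose d* falls inside a ring interval, then applies
#' quality heuristics: a pixel-count cap, a peak-concentration bound
#' (peak pixel must not carry more than `concentration_max` of the total
#' intensity, guarding against single-pixel glitches dressed with faint
#' neighbours) and an elongation bound on the bounding box
#' (longest/shortest side).
#'
#' @param spots A `spot_list` from [find_spots()].
#' @param rings Ring intervals from [detect_rings()] (may be empty).
#' @param max_pixels Maximum pixels per spot (default 200).
#' @param concentration_max Peak/total bound (default 0.98).
#' @param elongation_max Bounding-box aspect bound (default 4).
#' @return List: `spots` (accepted `spot_list`), `n_ring_rejected`,
#'   `n_quality_rejected`.
#' @export
filter_spots <- function(spots, rings = NULL, max_pixels = 200,
                         concentration_max = 0.98, elongation_max = 4) {
  if (nrow(spots) == 0) {
    return(list(spots = spots, n_ring_rejected = 0L, n_quality_rejected = 0L))
  }
  in_ring <- rep(FALSE, nrow(spots))
  if (!is.null(rings) && nrow(rings) > 0) {
    ds <- if (!is.null(spots$d_star_mean)) spots$d_star_mean else 1 / spots$d_spacing
    for (i in seq_len(nrow(rings))) {
      in_ring <- in_ring | (ds >= rings$d_star_min[i] & ds <= rings$d_star_max[i])
    }
  }
  elong <- pmax(spots$bbox_slow, spots$bbox_fast) /
    pmin(spots$bbox_slow, spots$bbox_fast)
  bad_quality <- !in_ring & (spots$n_pixels > max_pixels |
                               spots$peak_height > concentration_max * spots$total_intensity |
                               elong > elongation_max)
  keep <- !in_ring & !bad_quality
  out <- spots[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(spots = structure(out, class = c("spot_list", "data.frame")),
       n_ring_rejected = sum(in_ring),
       n_quality_rejected = sum(bad_quality))
}

#' Spotfinder parameter set
#'
#' @param n_sigma Signal threshold in robust sigmas (default 3.5).
#' @param tile Background tile edge in pixels (default 64).
#' @param min_pixels Minimum pixels per spot (default 2).
#' @param max_pixels Maximum pixels per spot (default 200).
#' @param concentration_max Peak/total intensity bound (default 0.98).
#' @param elongation_max Bounding-box aspect bound (default 4).
#' @param shell_width Ring-detection shell width, 1/Angstrom (default 0.002).
#' @param occupancy_cut Ring-detection occupancy threshold (default 0.25).
#' @param min_shell_pixels Minimum active pixels for a shell to be
#'   ring-flaggable (default 128).
#' @param ice_seed_d Optional d-spacings pre-seeding ring intervals.
#' @param d_limits Optional `c(d_max, d_min)` resolution annulus (Angstrom):
#'   spots outside it are ignored for the hit-counting statistics.
#' @param resolution_percentile Percentile of accepted-spot d* defining the
#'   reported resolution limit (default 0.8).
#' @return List of class `spotfinder_params`.
#' @export
spotfinder_params <- function(n_sigma = 3.5, tile = 64, min_pixels = 2,
                              max_pixels = 200, concentration_max = 0.98,
                              elongation_max = 4, shell_width = 0.002,
                              occupancy_cut = 0.25, min_shell_pixels = 128,
                              ice_seed_d = NULL, d_limits = NULL,
                              resolution_percentile = 0.8) {
  structure(as.list(environment()), class = "spotfinder_params")
}

#' Per-image signal-strength report
#'
#' Runs the full per-frame sequence — pixel classification, spot
#' identification, ring elimination, quality heuristics — and summarizes the
#' image quality: number of accepted spots, total spot intensity and the
#' resolution limit (the `resolution_percentile` quantile of accepted-spot
#' d*, reported in Angstrom).  Deterministic: identical frame and parameters
#' give a byte-identical text rendering.
#'
#' @param frame A [detector_frame()].
#' @param params A [spotfinder_params()].
#' @return Object of class `spot_stats` with fields `n_spots`,
#'   `total_intensity`, `resolution_limit` (NA when no spots),
#'   `n_ring_rejected`, `n_quality_rejected`, and the accepted `spots`.
#' @export
signal_strength_report <- function(frame, params = spotfinder_params()) {
  sig <- classify_pixels(frame, n_sigma = params$n_sigma, tile = params$tile)
  spots <- find_spots(frame, sig, min_pixels = params$min_pixels,
                      tile = params$tile)
  rings <- detect_rings(frame, sig, shell_width = params$shell_width,
                        occupancy_cut = params$occupancy_cut,
                        min_shell_pixels = params$min_shell_pixels,
                        seed_d = params$ice_seed_d)
  flt <- filter_spots(spots, rings, max_pixels = params$max_pixels,
                      concentration_max = params$concentration_max,
                      elongation_max = params$elongation_max)
  acc <- flt$spots
  if (!is.null(params$d_limits)) {
    keep <- acc$d_spacing <= params$d_limits[1] & acc$d_spacing >= params$d_limits[2]
    acc <- structure(acc[keep, , drop = FALSE], class = c("spot_list", "data.frame"))
  }
  res <- if (nrow(acc) > 0) {
    1 / stats::quantile(1 / acc$d_spacing, params$resolution_percentile,
                        names = FALSE, type = 7)
  } else NA_real_
  structure(list(n_spots = nrow(acc),
                 total_intensity = if (nrow(acc)) sum(acc$total_intensity) else 0,
                 resolution_limit = res,
                 n_ring_rejected = flt$n_ring_rejected,
                 n_quality_rejected = flt$n_quality_rejected,
                 spots = acc),
            class = "spot_stats")
}

#' Render spot statistics as the stable text report
#'
#' @param stats A `spot_stats` object.
#' @return Character vector of `key : value` lines.
#' @export
format_spot_stats <- function(stats) {
  c(sprintf("Spot Total : %d", stats$n_spots),
    sprintf("Ring Rejected : %d", stats$n_ring_rejected),
    sprintf("Quality Rejected : %d", stats$n_quality_rejected),
    sprintf("Total Intensity : %.1f", stats$total_intensity),
    if (is.na(stats$resolution_limit)) "Resolution Limit : none"
    else sprintf("Resolution Limit : %.2f", stats$resolution_limit))
}

#' @export
print.spot_stats <- function(x, ...) {
  cat(format_spot_stats(x), sep = "\n")
  invisible(x)
}

#' Render spot statistics as XML
#'
#' Same fields and formatted values as the text report, as child elements of
#' a `<spotfinder>` root.
#'
#' @param stats A `spot_stats` object.
#' @return An `xml2::xml_document`.
#' @export
spot_stats_xml <- function(stats) {
  doc <- xml2::xml_new_root("spotfinder")
  vals <- list(
    spot_total = sprintf("%d", stats$n_spots),
    ring_rejected = sprintf("%d", stats$n_ring_rejected),
    quality_rejected = sprintf("%d", stats$n_quality_rejected),
    total_intensity = sprintf("%.1f", stats$total_intensity),
    resolution_limit = if (is.na(stats$resolution_limit)) "none"
    else sprintf("%.2f", stats$resolution_limit))
  for (nm in names(vals)) {
    xml2::xml_add_child(doc, nm, vals[[nm]])
  }
  doc
}

#' Classify spot overlap between two lattices
#'
#' For every cross-lattice pair of predicted centroids closer than
#' `2 * box` pixels: `"overlapping"` when the center distance is at most
#' `box` (each peak falls inside the other's integration box),
#' `"close"` when it is between `box` and `2 * box` (the neighbour impinges
#' on the integration box), pairs farther apart are `"separated"` and not
#' listed individually.
#'
#' @param spots_a,spots_b Two-column matrices/data.frames of predicted
#'   centroid positions in pixels (slow, fast).
#' @param box Integration-box half-width in pixels (> 0).
#' @return List: `pairs` (data.frame `i_a`, `i_b`, `distance`, `label`) and
#'   `counts` (named vector over separated/close/overlapping, where
#'   `separated` counts the cross pairs beyond `2 * box`).
#' @export
classify_lattice_overlap <- function(spots_a, spots_b, box) {
  stopifnot(box > 0)
  a <- as.matrix(spots_a); b <- as.matrix(spots_b)
  if (nrow(a) == 0 || nrow(b) == 0) {
    return(list(pairs = data.frame(i_a = integer(0), i_b = integer(0),
                                   distance = numeric(0), label = character(0)),
                counts = c(separated = 0L, close = 0L, overlapping = 0L)))
  }
  d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  d <- sqrt(d2)
  near <- which(d <= 2 * box, arr.ind = TRUE)
  label <- ifelse(d[near] <= box, "overlapping", "close")
  pairs <- data.frame(i_a = near[, 1], i_b = near[, 2],
                      distance = d[near], label = label)
  pairs <- pairs[order(pairs$i_a, pairs$i_b), , drop = FALSE]
  rownames(pairs) <- NULL
  counts <- c(separated = length(d) - nrow(pairs),
              close = sum(label == "close"),
              overlapping = sum(label == "overlapping"))
  list(pairs = pairs, counts = counts)
}
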