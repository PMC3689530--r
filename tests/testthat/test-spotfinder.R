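test_that("pixel classification flags outliers and respects the mask", {
  g <- test_geometry(c(128, 128))
  flat <- detector_frame(matrix(100L, 128, 128), g)
  expect_false(any(classify_pixels(flat, 3.5)))

  spec <- frame_spec(g, background_mean = 10, seed = 3)
  fr <- generate_frame(spec)$frame
  cnt <- fr$counts
  cnt[40, 60] <- 1e6
  hot <- detector_frame(cnt, g)
  sig <- classify_pixels(hot, 3.5)
  expect_true(sig[40, 60])

  # planted bright region inside an inactive area is never signal
  mask <- matrix(TRUE, 128, 128); mask[30:50, 50:70] <- FALSE
  hot_masked <- detector_frame(cnt, g, mask)
  expect_false(any(classify_pixels(hot_masked, 3.5)[30:50, 50:70]))

  # raising n_sigma never adds signal pixels
  s1 <- classify_pixels(hot, 3); s2 <- classify_pixels(hot, 5)
  expect_true(all(s1 | !s2))

  allmask <- detector_frame(cnt, g, matrix(FALSE, 128, 128))
  expect_warning(s0 <- classify_pixels(allmask, 3.5), "masked")
  expect_false(any(s0))
})

test_that("connected-component labelling is 8-connected", {
  m <- matrix(FALSE, 6, 6)
  m[2, 2] <- m[3, 3] <- m[4, 4] <- TRUE  # diagonal chain: one component
  m[1, 6] <- TRUE                        # far corner: its own component
  lab <- label_components(m)
  expect_equal(length(unique(lab$labels)), 2)
  expect_equal(sum(lab$labels == lab$labels[which(lab$idx == which(m)[1])]), 3)
})

test_that("spot identification recovers planted centroids and geometry", {
  g <- test_geometry()
  spec <- planted_frame(n_spots = 2, seed = 5, background = 0, intensity = 5000)
  fr <- generate_frame(spec)
  sig <- classify_pixels(fr$frame, 5)
  spots <- find_spots(fr$frame, sig)
  expect_equal(nrow(spots), 2)
  sc <- recovery_score(spots, fr$ground_truth$spots, tol_px = 0.5)
  expect_equal(sc$tp, 2)

  expect_equal(nrow(find_spots(fr$frame, matrix(FALSE, 256, 256))), 0)

  # closed-form resolution at a known radius: r = 50 mm, D = 100 mm, wl 1 A
  g2 <- detector_geometry(100, 1.0, beam_center = c(0, 0), pixel_size = 1,
                          image_size = c(64, 64))
  ctr <- data.frame(slow = 50, fast = 0.5, intensity = 4000, sigma = 0.8)
  fr2 <- generate_frame(frame_spec(g2, spots = ctr, seed = 1))
  sp2 <- find_spots(fr2$frame, fr2$frame$counts > 0)
  expect_equal(sp2$d_spacing[1], 2.1762508995, tolerance = 1e-3)
})

test_that("ring detection finds planted powder rings and nothing else", {
  g <- test_geometry()
  spec_plain <- planted_frame(n_spots = 10, seed = 7, exclude_band = c(0.25, 0.3))
  fr <- generate_frame(spec_plain)
  sig <- classify_pixels(fr$frame, 5)
  expect_equal(nrow(detect_rings(fr$frame, sig)), 0)

  ring <- data.frame(d = 3.67, amplitude = 40, width = 0.003)
  spec_ring <- planted_frame(n_spots = 10, seed = 7, rings = ring,
                             exclude_band = c(0.25, 0.3))
  frr <- generate_frame(spec_ring)
  sigr <- classify_pixels(frr$frame, 5)
  iv <- detect_rings(frr$frame, sigr)
  expect_equal(nrow(iv), 1)
  expect_true(iv$d_star_min <= 1 / 3.67 && 1 / 3.67 <= iv$d_star_max)

  # isolated spots elsewhere do not change the detected interval
  spec_spotless <- frame_spec(g, background_mean = 10, rings = ring, seed = 7)
  fr0 <- generate_frame(spec_spotless)
  sig0 <- classify_pixels(fr0$frame, 5)
  iv0 <- detect_rings(fr0$frame, sig0)
  expect_equal(iv, iv0)
})

test_that("spot filtering applies ring and quality heuristics with counts", {
  g <- test_geometry()
  spec <- planted_frame(n_spots = 8, seed = 11)
  fr <- generate_frame(spec)
  spots <- find_spots(fr$frame, classify_pixels(fr$frame, 5))
  noop <- filter_spots(spots, rings = NULL)
  expect_equal(nrow(noop$spots), nrow(spots))
  expect_equal(noop$n_ring_rejected + noop$n_quality_rejected, 0)

  # a spot inside a declared ring interval is ring-rejected
  iv <- data.frame(d_star_min = spots$d_star_mean[1] - 1e-3,
                   d_star_max = spots$d_star_mean[1] + 1e-3)
  fl <- filter_spots(spots, iv)
  expect_equal(fl$n_ring_rejected, 1)
  expect_equal(nrow(fl$spots), nrow(spots) - 1)

  # a 1 x 20 streak fails the elongation bound
  cnt <- matrix(0L, 256, 256)
  cnt[100, 101:120] <- 1000L
  streak <- detector_frame(cnt, g)
  sp <- find_spots(streak, cnt > 0)
  fq <- filter_spots(sp, elongation_max = 4)
  expect_equal(fq$n_quality_rejected, 1)
  expect_equal(nrow(fq$spots), 0)
})

test_that("signal-strength report summarizes the full pipeline deterministically", {
  g <- test_geometry()
  blank <- detector_frame(matrix(0L, 256, 256), g)
  st0 <- signal_strength_report(blank)
  expect_equal(st0$n_spots, 0)
  expect_true(is.na(st0$resolution_limit))
  expect_equal(format_spot_stats(st0)[5], "Resolution Limit : none")

  spec <- planted_frame(n_spots = 25, seed = 13)
  fr <- generate_frame(spec)
  params <- spotfinder_params(n_sigma = 5)
  st <- signal_strength_report(fr$frame, params)
  expect_equal(st$n_spots, 25)
  r1 <- format_spot_stats(st)
  r2 <- format_spot_stats(signal_strength_report(generate_frame(spec)$frame, params))
  expect_identical(r1, r2)

  # XML mirrors the text fields value for value
  x <- spot_stats_xml(st)
  expect_equal(xml2::xml_text(xml2::xml_find_first(x, "//spot_total")), "25")
  expect_equal(xml2::xml_text(xml2::xml_find_first(x, "//total_intensity")),
               sub("Total Intensity : ", "", r1[4]))

  # resolution limit: planted uniform d* ladder, 80th percentile convention
  g3 <- detector_geometry(100, 1.0, c(0, 0), 0.1, c(512, 512))
  radii_mm <- 100 * tan(2 * asin(0.5 / seq(10, 3, length.out = 8)))
  ctr <- data.frame(slow = radii_mm / 0.1, fast = 5,
                    intensity = 5000, sigma = 1)
  fr3 <- generate_frame(frame_spec(g3, background_mean = 10, spots = ctr, seed = 17))
  st3 <- signal_strength_report(fr3$frame, spotfinder_params(n_sigma = 5))
  expect_equal(st3$n_spots, 8)
  dstars <- 2 * sin(atan(radii_mm / 100) / 2)
  expect_equal(1 / st3$resolution_limit,
               quantile(dstars, 0.8, names = FALSE), tolerance = 0.02)
})

test_that("extra spots planted only in masked regions do not change counts", {
  g <- test_geometry()
  base <- planted_frame(n_spots = 15, seed = 19)
  masked_box <- c(0, 49, 0, 49)
  ok <- with(base$spots, !(slow <= 55 & fast <= 55))
  base$spots <- base$spots[ok, ]
  extra <- base$spots
  extra <- rbind(extra, data.frame(slow = c(20, 35), fast = c(20, 40),
                                   intensity = 3000, sigma = 1.5))
  spec_a <- frame_spec(g, background_mean = 10, spots = base$spots,
                       masked_regions = list(masked_box), seed = 19)
  spec_b <- frame_spec(g, background_mean = 10, spots = extra,
                       masked_regions = list(masked_box), seed = 19)
  pa <- spotfinder_params(n_sigma = 5)
  na <- signal_strength_report(generate_frame(spec_a)$frame, pa)$n_spots
  nb <- signal_strength_report(generate_frame(spec_b)$frame, pa)$n_spots
  expect_equal(na, nb)
  expect_equal(na, sum(ok))
})

test_that("two-lattice overlap taxonomy follows the box thresholds", {
  a <- data.frame(slow = c(10, 50, 100), fast = c(10, 50, 100))
  b <- data.frame(slow = c(10, 50 + 7.5, 200), fast = c(10, 50, 200))
  ov <- classify_lattice_overlap(a, b, box = 5)
  expect_equal(unname(ov$counts["overlapping"]), 1)   # distance 0
  expect_equal(unname(ov$counts["close"]), 1)         # distance 1.5 box
  expect_equal(unname(ov$counts["separated"]), 9 - 2)
  expect_equal(ov$pairs$label[ov$pairs$distance == 0], "overlapping")

  far <- classify_lattice_overlap(a, b + 1000, box = 5)
  expect_equal(nrow(far$pairs), 0)
  expect_equal(unname(far$counts["separated"]), 9)

  # boundary cases sit on the definition: d = box -> overlapping, d = 2 box -> close
  p <- data.frame(slow = 0, fast = 0)
  q <- data.frame(slow = c(5, 10), fast = 0)
  ovb <- classify_lattice_overlap(p, q, box = 5)
  expect_equal(ovb$pairs$label, c("overlapping", "close"))
})

test_that("synthetic two-lattice exposures produce the expected overlap trend", {
  gg <- detector_geometry(150, 1.3, c(19.2, 19.2), 0.15, c(256, 256))
  ca <- unit_cell(79, 79, 38)
  tw0 <- sample_two_lattice_positions(gg, ca, ca, d_min = 3,
                                      angle_offset_deg = 0, seed = 5)
  ov0 <- classify_lattice_overlap(tw0$a[, 1:2], tw0$b[, 1:2], box = 5)
  expect_equal(unname(ov0$counts["overlapping"]), nrow(tw0$a))

  tw1 <- sample_two_lattice_positions(gg, ca, ca, d_min = 3,
                                      angle_offset_deg = 20, seed = 5)
  ov1 <- classify_lattice_overlap(tw1$a[, 1:2], tw1$b[, 1:2], box = 5)
  frac_sep0 <- ov0$counts["separated"] / sum(ov0$counts)
  frac_sep1 <- ov1$counts["separated"] / sum(ov1$counts)
  expect_gt(frac_sep1, frac_sep0)

  tw2 <- sample_two_lattice_positions(gg, ca, ca, d_min = 3,
                                      angle_offset_deg = 20, seed = 5)
  expect_identical(tw1, tw2)
})
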