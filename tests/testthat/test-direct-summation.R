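test_that("single-cell F matches hand-computable cases", {
  uc <- unit_cell(10, 10, 10)
  st <- crystal_structure(uc, data.frame(element = "C", x = 0, y = 0, z = 0))
  f <- sf_single_cell(st, c(2, 1, 0))
  expect_equal(Im(f), 0, tolerance = 1e-12)
  expect_equal(Re(f), form_factor_value(form_factor_coeffs("C"),
                                        d_star(uc, c(2, 1, 0))))

  st2 <- crystal_structure(uc, data.frame(element = "C", x = 0.5, y = 0, z = 0))
  expect_equal(sf_single_cell(st2, c(1, 0, 0)),
               -form_factor_value(form_factor_coeffs("C"), 0.1) + 0i,
               tolerance = 1e-12)

  # P21 forces the 0k0 (k odd) systematic absence at any general position
  st3 <- crystal_structure(uc, data.frame(element = "C", x = 0.13, y = 0.27,
                                          z = 0.41), space_group = "P21")
  expect_lt(Mod(sf_single_cell(st3, c(0, 1, 0))), 1e-12)
  expect_lt(Mod(sf_single_cell(st3, c(0, 3, 0))), 1e-12)
  expect_gt(Mod(sf_single_cell(st3, c(0, 2, 0))), 0.1)
})

test_that("Friedel symmetry and occupancy linearity hold", {
  withr::with_seed(17, {
    st <- random_structure(8, seed = 23)
    for (i in 1:20) {
      h <- sample(-8:8, 3, replace = TRUE)
      expect_equal(Mod(sf_single_cell(st, h)), Mod(sf_single_cell(st, -h)),
                   tolerance = 1e-10)
    }
  })
  st <- random_structure(6, seed = 29)
  half <- st
  half$scatterers$occ <- half$scatterers$occ * 0.5
  h <- c(3, -2, 4)
  expect_equal(Mod(sf_single_cell(half, h)), 0.5 * Mod(sf_single_cell(st, h)))
})

test_that("Laue interference has closed-form values, zeros and bounds", {
  expect_equal(laue_interference(crystallite_extent(1, 1, 1), c(0.3, 0.7, -0.2)),
               1 + 0i)
  expect_equal(Mod(laue_interference(crystallite_extent(2, 1, 1), c(0.5, 0, 0))),
               0, tolerance = 1e-12)
  expect_equal(laue_interference(crystallite_extent(10, 12, 14), c(2, 3, 4)),
               1680 + 0i, tolerance = 1e-12)

  # per-axis factor: N-1 zeros per unit interval, |sum| <= N, brute force oracle
  brute <- function(h, n) sum(exp(2i * pi * h * (0:(n - 1))))
  withr::with_seed(31, {
    for (i in 1:30) {
      n <- sample(2:9, 1); h <- runif(1, -2, 2)
      expect_equal(laue_interference(crystallite_extent(n, 1, 1), c(h, 0, 0)),
                   brute(h, n), tolerance = 1e-10)
    }
  })
  n <- 8
  zeros <- (1:(n - 1)) / n
  vals <- vapply(zeros, function(h)
    Mod(laue_interference(crystallite_extent(n, 1, 1), c(h, 0, 0))), numeric(1))
  expect_true(all(vals < 1e-9))
  hs <- seq(0, 1, by = 1 / 128)
  mods <- vapply(hs, function(h)
    Mod(laue_interference(crystallite_extent(n, 1, 1), c(h, 0, 0))), numeric(1))
  expect_true(all(mods <= n + 1e-9))
})

test_that("finite-crystal F: explicit lattice sum equals the factorization", {
  st <- random_structure(5, seed = 37)
  withr::with_seed(41, {
    for (i in 1:25) {
      ext <- crystallite_extent(sample(1:4, 1), sample(1:4, 1), sample(1:4, 1))
      h <- runif(3, -2, 2)
      fe <- sf_finite_crystal(st, ext, h, method = "explicit")
      ff <- sf_finite_crystal(st, ext, h, method = "factorized")
      expect_equal(fe, ff, tolerance = 1e-8)
    }
  })
  # continuum limit: one unit cell reproduces the single-cell F exactly
  h <- c(0.37, 1.12, -0.58)
  expect_identical(sf_finite_crystal(st, crystallite_extent(1, 1, 1), h),
                   sf_single_cell(st, h))
  # integer H: every lattice phase is unity
  expect_equal(sf_finite_crystal(st, crystallite_extent(2, 3, 4), c(2, -1, 3)),
               24 * sf_single_cell(st, c(2, -1, 3)), tolerance = 1e-10)
  expect_error(sf_finite_crystal(st, crystallite_extent(200, 200, 200),
                                 h, method = "explicit"), "cap")
})

test_that("batch kernel agrees with the R oracle and is chunk-invariant", {
  st <- random_structure(12, space_group = "P212121", seed = 43)
  withr::with_seed(47, hkl <- matrix(runif(60, -4, 4), 20, 3))
  rs <- sf_batch(st, hkl)
  ref <- vapply(seq_len(nrow(hkl)),
                function(i) sf_single_cell(st, hkl[i, ]), complex(1))
  expect_equal(rs$f, ref, tolerance = 1e-12)

  rs1 <- sf_batch(st, hkl, chunk_size = 1)
  rs64 <- sf_batch(st, hkl, chunk_size = 64)
  expect_identical(rs1$f, rs64$f)
  rs1s <- sf_batch(st, hkl, precision = "single", chunk_size = 1)
  rs64s <- sf_batch(st, hkl, precision = "single", chunk_size = 64)
  expect_identical(rs1s$f, rs64s$f)

  expect_equal(nrow(sf_batch(st, matrix(numeric(0), 0, 3))$hkl), 0)
  expect_error(sf_batch(st, hkl, precision = "half"), "arg")

  # extent multiplies in the Laue factor
  ext <- crystallite_extent(3, 2, 2)
  rse <- sf_batch(st, hkl[1:5, ], extent = ext)
  for (i in 1:5) {
    expect_equal(rse$f[i], sf_finite_crystal(st, ext, hkl[i, ]),
                 tolerance = 1e-10)
  }
})

test_that("single precision tracks double precision closely", {
  st <- random_structure(40, seed = 53)
  hkl <- miller_index_set(st$cell, 3.5)
  fd <- sf_batch(st, hkl, precision = "double")
  fs <- sf_batch(st, hkl, precision = "single")
  cmp <- compare_amplitudes(fd, fs)
  expect_lt(cmp$mean_rel_err, 1e-4)
  expect_gt(cmp$correlation, 0.999999)
})

test_that("amplitude comparison statistics are correct", {
  st <- random_structure(5, seed = 59)
  rs <- sf_batch(st, miller_index_set(st$cell, 4))
  self <- compare_amplitudes(rs, rs)
  expect_equal(self$mean_rel_err, 0)
  expect_equal(self$correlation, 1)
  doubled <- reflection_set(rs$hkl, 2 * rs$f)
  expect_equal(compare_amplitudes(rs, doubled)$mean_rel_err, 1.0)
  other <- reflection_set(matrix(c(99, 99, 99), 1, 3), complex(real = 1))
  expect_error(compare_amplitudes(rs, other), "no Miller indices")
})

test_that("reflection TSV writer round-trips", {
  st <- random_structure(4, seed = 61)
  rs <- sf_batch(st, miller_index_set(st$cell, 5))
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_reflections_tsv(rs, tf)
  rt <- read_reflections_tsv(tf)
  expect_equal(rt$hkl, rs$hkl, ignore_attr = TRUE)
  expect_equal(Mod(rt$f), Mod(rs$f), tolerance = 1e-8)
})

test_that("FFT reference converges to direct summation", {
  # single atom at the origin: amplitudes follow the form-factor curve
  st <- crystal_structure(unit_cell(20, 20, 20),
                          data.frame(element = "C", x = 0, y = 0, z = 0))
  rs_fft <- fft_reference_sf(st, d_min = 2, grid_factor = 3)
  curve <- form_factor_value(form_factor_coeffs("C"), d_star(st$cell, rs_fft$hkl))
  expect_lt(max(abs(Mod(rs_fft$f) - curve) / curve), 0.02)

  st0 <- crystal_structure(unit_cell(15, 15, 15),
                           data.frame(element = character(0), x = numeric(0),
                                      y = numeric(0), z = numeric(0)))
  expect_true(all(Mod(fft_reference_sf(st0, 3)$f) == 0))

  # 100-atom structure: high amplitude correlation, monotone grid convergence
  st2 <- random_structure(100, cell = unit_cell(25, 30, 35), seed = 67,
                          u_range = c(0.02, 0.05))
  dirr <- sf_batch(st2, miller_index_set(st2$cell, 2.5))
  errs <- vapply(c(2, 3, 4), function(gf) {
    cmp <- compare_amplitudes(dirr, fft_reference_sf(st2, 2.5, grid_factor = gf))
    if (gf == 3) expect_gt(cmp$correlation, 0.99)
    cmp$mean_rel_err
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_error(fft_reference_sf(st2, 2.5, max_grid = 100), "cap")
  expect_error(fft_reference_sf(random_structure(2, space_group = "P21", seed = 1), 3),
               "P1")
})
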