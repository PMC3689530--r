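#' FFT-based reference structure factors
#'
#' The conventional alternative to direct summation: sample the model
#' electron density on a real-space grid and obtain F on integer Miller
#' indices by discrete Fourier transform.  Each scatterer's density is the
#' analytic Fourier mate of its sum-of-Gaussians form factor: a Gaussian
#' with reciprocal coefficient `(a, b)` contributes
#' `a (4 pi / b')^{3/2} exp(-4 pi^2 r^2 / b')` with the isotropic
#' displacement folded in analytically as `b' = b + 8 pi^2 u_iso`, so no
#' separate temperature-factor convolution is needed.  Terms too sharp for
#' the grid (notably the constant `c`, a delta function in real space)
#' would alias badly, so every term is additionally broadened by an
#' artificial width `b_extra` matched to the grid spacing and the resulting
#' F is rescaled by `exp(+b_extra (d*/2)^2)` — an exact reciprocal-space
#' correction, leaving only residual aliasing and density-truncation error.
#'
#' This is an approximation to direct summation, used as a cross-check;
#' agreement improves as `grid_factor` grows (finer grid, hence smaller
#' artificial broadening).  Requires a P1 (or pre-expanded, see
#' [expand_to_p1()]) structure.
#'
#' @param structure A [crystal_structure()] in P1.
#' @param d_min Resolution limit in Angstrom for the output reflections.
#' @param grid_factor Grid spacing is at most `d_min / grid_factor`
#'   (default 3).
#' @param friedel Passed to [miller_index_set()].
#' @param trunc_frac Truncate each Gaussian where its density falls below
#'   this fraction of its peak (default 1e-6).
#' @param smear_sigma_px Artificial broadening, expressed as a real-space
#'   Gaussian sigma in grid-spacing units (default 0.8); `b_extra =
#'   8 pi^2 (smear_sigma_px * spacing)^2`.
#' @param max_grid Memory cap: maximum total grid points (default 2^24).
#' @return A `reflection_set` on the integer indices to `d_min`.
#' @export
fft_reference_sf <- function(structure, d_min, grid_factor = 3,
                             friedel = TRUE, trunc_frac = 1e-6,
                             smear_sigma_px = 0.8, max_grid = 2^24) {
  stopifnot(inherits(structure, "crystal_structure"), d_min > 0)
  if (length(structure$symops) > 1) {
    stop("fft_reference_sf needs a P1 structure; run expand_to_p1() first")
  }
  cell <- structure$cell
  hkl <- miller_index_set(cell, d_min, friedel = friedel)
  sc <- structure$scatterers
  if (nrow(sc) == 0) {
    return(reflection_set(hkl, complex(real = numeric(nrow(hkl)),
                                       imaginary = numeric(nrow(hkl)))))
  }
  spacing <- d_min / grid_factor
  hmax <- apply(abs(hkl), 2, max)
  axis_len <- c(cell$a, cell$b, cell$c)
  n <- pmax(ceiling(axis_len / spacing), 2 * hmax + 2)
  n <- vapply(n, .good_fft_size, numeric(1))
  if (prod(n) > max_grid) {
    stop(sprintf("FFT grid %s exceeds the configured cap of %g points",
                 paste(n, collapse = "x"), max_grid))
  }
  # actual (finest) spacing achieved sets the broadening
  b_extra <- 8 * pi^2 * (smear_sigma_px * max(axis_len / n))^2
  rho <- array(0, dim = n)
  for (i in seq_len(nrow(sc))) {
    co <- structure$form_factors[[sc$element[i]]]
    a <- c(co$a, co$c)
    b <- c(co$b, 0) + 8 * pi^2 * sc$u_iso[i] + b_extra
    keep <- a != 0
    rho <- .add_atom_density(rho, cell, n,
                             frac = c(sc$x[i], sc$y[i], sc$z[i]),
                             a = a[keep] * sc$occ[i], b = b[keep],
                             trunc_frac = trunc_frac)
  }
  # F(H) = sum_x rho(x) exp(+2 pi i H.x) dV  (unnormalized inverse DFT)
  Fgrid <- stats::fft(rho, inverse = TRUE) * (cell$volume / prod(n))
  idx <- cbind(hkl[, 1] %% n[1], hkl[, 2] %% n[2], hkl[, 3] %% n[3]) + 1
  f <- Fgrid[idx] * exp(b_extra * (d_star(cell, hkl) / 2)^2)
  reflection_set(hkl, f)
}

# next integer >= n whose prime factors are all <= 7 (keeps stats::fft fast)
.good_fft_size <- function(n) {
  n <- as.integer(ceiling(n))
  repeat {
    m <- n
    for (p in c(2L, 3L, 5L, 7L)) while (m %% p == 0L) m <- m %/% p
    if (m == 1L) return(n)
    n <- n + 1L
  }
}

# accumulate one atom's Gaussian-sum density into rho (periodic wrap)
.add_atom_density <- function(rho, cell, n, frac, a, b, trunc_frac) {
  # cutoff radius: widest Gaussian falls to trunc_frac of its own peak
  rmax <- sqrt(max(b) * log(1 / trunc_frac)) / (2 * pi)
  # fractional half-width of the bounding box along axis i is rmax * |a*_i|
  ext <- ceiling(rmax * sqrt(diag(cell$g_star)) * n) + 1L
  ext <- pmin(ext, floor((n - 1) / 2))
  ctr <- frac * n                    # atom position in grid units
  i0 <- round(ctr)
  off <- lapply(1:3, function(ax) (i0[ax] - ext[ax]):(i0[ax] + ext[ax]))
  # fractional offsets of the voxel block from the atom
  df1 <- (off[[1]] - ctr[1]) / n[1]
  df2 <- (off[[2]] - ctr[2]) / n[2]
  df3 <- (off[[3]] - ctr[3]) / n[3]
  # Cartesian r^2 through the direct metric tensor
  g <- cell$g
  r2 <- outer(outer(df1^2 * g[1, 1], df2^2 * g[2, 2], "+"), df3^2 * g[3, 3], "+") +
    2 * (outer(outer(df1 * g[1, 2], df2, "*"), rep(1, length(df3)), "*") +
         outer(outer(df1 * g[1, 3], rep(1, length(df2)), "*"), df3, "*") +
         outer(outer(rep(1, length(df1)), df2 * g[2, 3], "*"), df3, "*"))
  dens <- 0
  for (t in seq_along(a)) {
    dens <- dens + a[t] * (4 * pi / b[t])^1.5 * exp(-4 * pi^2 * r2 / b[t])
  }
  ix <- (off[[1]] %% n[1]) + 1; iy <- (off[[2]] %% n[2]) + 1
  iz <- (off[[3]] %% n[3]) + 1
  rho[ix, iy, iz] <- rho[ix, iy, iz] + dens
  rho
}
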