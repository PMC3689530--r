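#' Single-unit-cell structure factor by direct summation
#'
#' Evaluates, for one (possibly fractional) Miller index H,
#' \deqn{F_H = \sum_S \sum_n w_n f_n(d^*) e^{-2\pi^2 u_n d^{*2}}
#'             e^{2\pi i H\cdot(R_S x_n + T_S)}}
#' over the symmetry operators S and asymmetric-unit scatterers n.  This pure
#' R path (always double precision) is deliberately independent of the
#' compiled batch kernel and serves as its oracle in the test suite.
#'
#' @param structure A [crystal_structure()].
#' @param hkl Numeric length-3 Miller index (fractional values allowed).
#' @return A complex scalar F.
#' @export
sf_single_cell <- function(structure, hkl) {
  stopifnot(inherits(structure, "crystal_structure"))
  hkl <- as.numeric(hkl)
  ds <- d_star(structure$cell, hkl)
  sc <- structure$scatterers
  f_el <- vapply(unique(sc$element),
                 function(e) form_factor_value(structure$form_factors[[e]], ds),
                 numeric(1))
  coef <- sc$occ * f_el[sc$element] * debye_waller(sc$u_iso, ds)
  xyz <- as.matrix(sc[, c("x", "y", "z")])
  f <- 0 + 0i
  for (op in structure$symops) {
    phase <- 2 * pi * (xyz %*% crossprod(op$R, hkl) + sum(hkl * op$T))
    f <- f + sum(coef * complex(real = cos(phase), imaginary = sin(phase)))
  }
  f
}

#' Finite-crystallite extent
#'
#' Number of unit cells along each cell axis; the lattice offsets span
#' `{0..N1-1} x {0..N2-1} x {0..N3-1}`.
#'
#' @param n1,n2,n3 Positive integer cell counts.
#' @return Object of class `crystallite_extent`.
#' @export
crystallite_extent <- function(n1, n2 = n1, n3 = n1) {
  n <- as.integer(c(n1, n2, n3))
  if (any(is.na(n)) || any(n < 1)) stop("extent counts must be integers >= 1")
  structure(list(n = n), class = "crystallite_extent")
}

#' Laue interference function of a finite lattice
#'
#' The lattice sum over a block of `N1 x N2 x N3` unit cells factorizes per
#' axis into the geometric series
#' \eqn{\sum_{u=0}^{N-1} e^{2\pi i h u} = e^{i\pi h(N-1)}\sin(\pi N h)/\sin(\pi h)}.
#' Near integer h (|sin(pi h)| < 1e-9) the smooth limit
#' `N exp(i pi (h - round(h)) (N-1))` is used, so at exact integers the axis
#' factor is exactly N.  Between adjacent integers the axis factor has N-1
#' zeros and N-2 subsidiary maxima: the origin of the fringe pattern of
#' small crystallites.
#'
#' @param extent A [crystallite_extent()].
#' @param hkl Numeric length-3 fractional Miller index.
#' @return Complex lattice sum; modulus at most `N1*N2*N3`.
#' @export
laue_interference <- function(extent, hkl) {
  stopifnot(inherits(extent, "crystallite_extent"))
  prod(mapply(laue_axis_factor, as.numeric(hkl), extent$n))
}

laue_axis_factor <- function(h, n) {
  sp <- sin(pi * h)
  if (abs(sp) < 1e-9) {
    eps <- h - round(h)
    n * exp(1i * pi * eps * (n - 1))
  } else {
    exp(1i * pi * h * (n - 1)) * sin(pi * n * h) / sp
  }
}

#' Structure factor of a finite crystallite
#'
#' Extends the direct summation over all unit cells of the crystallite.  The
#' `"explicit"` method brute-force sums `exp(2 pi i H . dU)` over every
#' lattice offset dU; the `"factorized"` method uses the per-axis
#' geometric-series closed form ([laue_interference()]).  Both multiply the
#' single-cell F and agree to floating-point tolerance; with extent (1,1,1)
#' the continuum single-cell expression is recovered exactly.
#'
#' @inheritParams sf_single_cell
#' @param extent A [crystallite_extent()].
#' @param method `"explicit"` or `"factorized"`.
#' @param cell_cap Maximum cell count for the explicit method (default 1e6).
#' @return Complex F for the whole crystallite.
#' @export
sf_finite_crystal <- function(structure, extent, hkl,
                              method = c("factorized", "explicit"),
                              cell_cap = 1e6) {
  method <- match.arg(method)
  stopifnot(inherits(extent, "crystallite_extent"))
  hkl <- as.numeric(hkl)
  lattice <- switch(method,
    factorized = laue_interference(extent, hkl),
    explicit = {
      n <- extent$n
      if (prod(n) > cell_cap) {
        stop(sprintf("explicit lattice sum over %d cells exceeds the cap (%g); use method='factorized'",
                     prod(n), cell_cap))
      }
      du <- as.matrix(expand.grid(0:(n[1] - 1), 0:(n[2] - 1), 0:(n[3] - 1)))
      ph <- 2 * pi * as.numeric(du %*% hkl)
      sum(complex(real = cos(ph), imaginary = sin(ph)))
    })
  lattice * sf_single_cell(structure, hkl)
}

#' Batch structure-factor computation with a precision switch
#'
#' Computes F for a list of (possibly fractional) Miller indices through the
#' compiled direct-summation kernel.  `precision = "single"` performs every
#' inner operation — d*, form factors, Debye-Waller factors, phases,
#' trigonometry and the (Kahan-compensated) accumulation — in 32-bit IEEE
#' arithmetic, mirroring single-precision GPU behaviour; `"double"` uses 64-bit
#' throughout.  Results are aligned with the input order and independent of
#' `chunk_size`, which only partitions the work.
#'
#' A non-trivial `extent` multiplies each F by the (double-precision) Laue
#' interference factor of the crystallite.
#'
#' @inheritParams sf_finite_crystal
#' @param hkl_list n x 3 numeric matrix (or list of length-3 vectors).
#' @param precision `"double"` (default) or `"single"`.
#' @param chunk_size Reflections per kernel call (default: all at once).
#' @return A `reflection_set`: list with `hkl` (n x 3 matrix), `f` (complex
#'   vector) and `precision`.
#' @export
sf_batch <- function(structure, hkl_list, extent = crystallite_extent(1),
                     precision = c("double", "single"), chunk_size = NULL) {
  precision <- match.arg(precision)
  stopifnot(inherits(structure, "crystal_structure"))
  if (is.list(hkl_list) && !is.matrix(hkl_list)) {
    hkl_list <- do.call(rbind, hkl_list)
  }
  hkl <- matrix(as.numeric(hkl_list), ncol = 3)
  if (nrow(hkl) == 0) {
    return(reflection_set(hkl, complex(0), precision))
  }
  sc <- structure$scatterers
  els <- unique(sc$element)
  ff <- structure$form_factors[els]
  ng <- max(vapply(ff, function(f) length(f$a), integer(1)))
  ff_a <- ff_b <- matrix(0, length(els), ng)
  ff_c <- numeric(length(els))
  for (i in seq_along(els)) {
    ff_a[i, seq_along(ff[[i]]$a)] <- ff[[i]]$a
    ff_b[i, seq_along(ff[[i]]$b)] <- ff[[i]]$b
    ff_c[i] <- ff[[i]]$c
  }
  ffidx <- match(sc$element, els) - 1L
  rot <- do.call(rbind, lapply(structure$symops, function(op) op$R))
  tra <- do.call(rbind, lapply(structure$symops, function(op) op$T))
  xyz <- as.matrix(sc[, c("x", "y", "z")])

  idx <- seq_len(nrow(hkl))
  chunks <- if (is.null(chunk_size)) list(idx) else split(idx, ceiling(idx / chunk_size))
  f <- complex(nrow(hkl))
  for (ch in chunks) {
    f[ch] <- .sf_direct_cpp(hkl[ch, , drop = FALSE], xyz, sc$occ, sc$u_iso,
                            ffidx, ff_a, ff_b, ff_c, rot, tra,
                            structure$cell$g_star, precision == "single")
  }
  if (any(extent$n > 1)) {
    lat <- apply(hkl, 1, function(h) laue_interference(extent, h))
    f <- f * lat
  }
  reflection_set(hkl, f, precision)
}

#' Reflection set container
#'
#' @param hkl n x 3 numeric matrix of Miller indices.
#' @param f Complex structure factors aligned with `hkl`.
#' @param precision `"double"` or `"single"` provenance tag.
#' @return Object of class `reflection_set`.
#' @export
reflection_set <- function(hkl, f, precision = "double") {
  hkl <- matrix(as.numeric(hkl), ncol = 3,
                dimnames = list(NULL, c("h", "k", "l")))
  if (nrow(hkl) != length(f)) stop("hkl and f lengths differ")
  structure(list(hkl = hkl, f = as.complex(f), precision = precision),
            class = "reflection_set")
}

#' @export
print.reflection_set <- function(x, ...) {
  cat(sprintf("Reflection set: %d reflection(s), %s precision\n",
              nrow(x$hkl), x$precision))
  invisible(x)
}

#' Compare two reflection sets' amplitudes
#'
#' Matches reflections on their (rounded to 1e-6) indices and reports the
#' mean and maximum relative amplitude error and the Pearson correlation of
#' amplitudes.  Reflections whose reference amplitude falls below
#' `floor_frac * max(|F_A|)` are excluded from the relative-error statistics
#' (near-extinct reflections would otherwise dominate through division).
#'
#' @param A,B `reflection_set` objects; A is the reference.
#' @param floor_frac Amplitude floor as a fraction of the maximum (default 1e-8).
#' @return List of class `amplitude_comparison`: `n_common`, `mean_rel_err`,
#'   `max_rel_err`, `correlation`.
#' @export
compare_amplitudes <- function(A, B, floor_frac = 1e-8) {
  key <- function(m) paste(round(m[, 1], 6), round(m[, 2], 6), round(m[, 3], 6))
  ka <- key(A$hkl); kb <- key(B$hkl)
  common <- intersect(ka, kb)
  if (length(common) == 0) stop("reflection sets share no Miller indices")
  fa <- Mod(A$f[match(common, ka)])
  fb <- Mod(B$f[match(common, kb)])
  keep <- fa > floor_frac * max(fa)
  rel <- abs(fa[keep] - fb[keep]) / fa[keep]
  structure(list(n_common = length(common),
                 mean_rel_err = mean(rel),
                 max_rel_err = max(rel),
                 correlation = stats::cor(fa, fb)),
            class = "amplitude_comparison")
}

#' @export
print.amplitude_comparison <- function(x, ...) {
  cat(sprintf("Amplitude comparison: n=%d  mean rel err=%.3g  max rel err=%.3g  r=%.6f\n",
              x$n_common, x$mean_rel_err, x$max_rel_err, x$correlation))
  invisible(x)
}

#' Write a reflection set as tab-separated text (h k l Fabs phase)
#' @param rs A `reflection_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reflections_tsv <- function(rs, path) {
  df <- data.frame(h = rs$hkl[, 1], k = rs$hkl[, 2], l = rs$hkl[, 3],
                   Fabs = Mod(rs$f), phase = Arg(rs$f) * 180 / pi)
  utils::write.table(format(df, digits = 10, trim = TRUE), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a reflection set written by [write_reflections_tsv()]
#' @param path Input path.
#' @return A `reflection_set`.
#' @export
read_reflections_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  reflection_set(as.matrix(df[, c("h", "k", "l")]),
                 complex(modulus = df$Fabs, argument = df$phase * pi / 180))
}
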