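#' Fractional-index grid for a reciprocal-plane section
#'
#' @param h_range,k_range Length-3 vectors `c(min, max, step)` in
#'   reciprocal-lattice units; `step > 0`, `max > min`.
#' @param l_fixed Fixed third index of the plane section (default 0).
#' @return Object of class `fractional_grid` with the evaluated `h` and `k`
#'   axis vectors.
#' @export
fractional_grid <- function(h_range, k_range = h_range, l_fixed = 0) {
  chk <- function(r, nm) {
    if (length(r) != 3 || r[3] <= 0 || r[2] <= r[1]) {
      stop(sprintf("%s must be c(min, max, step) with step > 0 and max > min", nm))
    }
    seq(r[1], r[2], by = r[3])
  }
  structure(list(h = chk(h_range, "h_range"), k = chk(k_range, "k_range"),
                 l_fixed = l_fixed), class = "fractional_grid")
}

#' Finite-crystallite intensity map over a fractional-index grid
#'
#' Evaluates `|F|^2` of the crystallite on a plane section of reciprocal
#' space sampled at fractional Miller indices, using the factorized
#' finite-crystal expression (Laue interference per axis times the
#' single-cell F from the compiled batch kernel).  For a crystallite of N
#' cells along an axis the map shows N-2 subsidiary fringe maxima between
#' adjacent main Bragg peaks along that axis.
#'
#' @param structure A [crystal_structure()].
#' @param extent A [crystallite_extent()].
#' @param grid A [fractional_grid()].
#' @param point_cap Maximum number of grid points (default 1e6).
#' @return Object of class `intensity_image`: `values` (length(h) x
#'   length(k) matrix of `|F|^2`), `h`, `k`, `l_fixed`.
#' @export
fringe_intensity_map <- function(structure, extent, grid, point_cap = 1e6) {
  stopifnot(inherits(grid, "fractional_grid"))
  nh <- length(grid$h); nk <- length(grid$k)
  if (nh * nk > point_cap) {
    stop(sprintf("grid has %d points, exceeding the cap of %g", nh * nk, point_cap))
  }
  hkl <- cbind(rep(grid$h, times = nk), rep(grid$k, each = nh), grid$l_fixed)
  rs <- sf_batch(structure, hkl, extent = extent, precision = "double")
  structure(list(values = matrix(Mod(rs$f)^2, nh, nk),
                 h = grid$h, k = grid$k, l_fixed = grid$l_fixed),
            class = "intensity_image")
}

#' Render an intensity map as an 8-bit grayscale raster
#'
#' Monotone mapping of intensities to gray levels 0-255: linear, or
#' `log10(1 + I)` for the high dynamic range typical of fringe patterns,
#' followed by a gamma correction.  Deterministic for fixed input; an
#' all-zero map renders uniform black.
#'
#' @param img An `intensity_image` (or plain non-negative matrix).
#' @param scale `"log"` (default) or `"linear"`.
#' @param gamma Gamma exponent applied after normalization (default 1).
#' @param path Optional PNG output path.
#' @return Integer matrix of gray levels 0-255 (invisibly when `path` given).
#' @export
render_image <- function(img, scale = c("log", "linear"), gamma = 1,
                         path = NULL) {
  scale <- match.arg(scale)
  v <- if (inherits(img, "intensity_image")) img$values else img
  if (!all(is.finite(v))) stop("intensity values must be finite")
  if (any(v < 0)) stop("intensity values must be non-negative")
  u <- if (scale == "log") log10(1 + v) else v
  mx <- max(u)
  u <- if (mx > 0) u / mx else u
  levels <- matrix(as.integer(round(255 * u^gamma)), nrow(v), ncol(v))
  if (!is.null(path)) {
    png::writePNG(t(levels)[rev(seq_len(ncol(levels))), , drop = FALSE] / 255,
                  target = path)
    return(invisible(levels))
  }
  levels
}
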