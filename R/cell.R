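#' Unit cell
#'
#' Construct a crystallographic unit cell from the six standard parameters.
#'
#' @param a,b,c Cell edge lengths in Angstrom; must be positive.
#' @param alpha,beta,gamma Cell angles in degrees; must lie in (0, 180) and
#'   describe a positive-definite metric.
#' @return An object of class `unit_cell` with the six parameters plus the
#'   direct metric tensor `g`, the reciprocal metric tensor `g_star`, the
#'   orthogonalization matrix `orth` (fractional -> Cartesian Angstrom, PDB
#'   convention: a along x, b in the xy plane) and its inverse `frac`.
#' @examples
#' uc <- unit_cell(40, 50, 60)
#' d_star(uc, c(1, 0, 0))   # 1/40
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  p <- c(a = a, b = b, c = c, alpha = alpha, beta = beta, gamma = gamma)
  if (!all(is.finite(p))) stop("unit cell parameters must be finite numbers")
  if (any(p[1:3] <= 0)) stop("unit cell lengths must be positive")
  if (any(p[4:6] <= 0 | p[4:6] >= 180)) {
    stop("unit cell angles must lie strictly between 0 and 180 degrees")
  }
  ca <- cos(alpha * pi / 180); cb <- cos(beta * pi / 180)
  cg <- cos(gamma * pi / 180); sg <- sin(gamma * pi / 180)
  g <- matrix(c(a * a,       a * b * cg,  a * c * cb,
                a * b * cg,  b * b,       b * c * ca,
                a * c * cb,  b * c * ca,  c * c), 3, 3)
  det_g <- det(g)
  if (!is.finite(det_g) || det_g <= 1e-10 * (a * b * c)^2) {
    stop("degenerate unit cell: metric tensor is not positive definite")
  }
  # PDB orthogonalization convention
  vfac <- sqrt(1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg)
  orth <- matrix(c(a, 0, 0,
                   b * cg, b * sg, 0,
                   c * cb, c * (ca - cb * cg) / sg, c * vfac / sg), 3, 3)
  structure(list(a = a, b = b, c = c,
                 alpha = alpha, beta = beta, gamma = gamma,
                 g = g, g_star = solve(g),
                 volume = sqrt(det_g),
                 orth = orth, frac = solve(orth)),
            class = "unit_cell")
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("Unit cell: a=%.4g b=%.4g c=%.4g  alpha=%.4g beta=%.4g gamma=%.4g  V=%.6g A^3\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma, x$volume))
  invisible(x)
}

#' Reciprocal-lattice spacing d* of a reflection
#'
#' Computes d* = |h a* + k b* + l c*| (in 1/Angstrom) through the reciprocal
#' metric tensor.  Accepts fractional Miller indices, as needed for
#' finite-crystallite fringe work; d* is invariant under negation of the index.
#'
#' @param cell A [unit_cell()].
#' @param hkl Numeric length-3 Miller index, or an n x 3 matrix of indices.
#' @return d* in 1/Angstrom (vector of length n).
#' @export
d_star <- function(cell, hkl) {
  stopifnot(inherits(cell, "unit_cell"))
  h <- as_hkl_matrix(hkl)
  sqrt(pmax(rowSums((h %*% cell$g_star) * h), 0))
}

#' Resolution d (Angstrom) of a reflection, 1/d*
#' @inheritParams d_star
#' @return d in Angstrom (Inf for the (0,0,0) index).
#' @export
d_spacing_hkl <- function(cell, hkl) 1 / d_star(cell, hkl)

as_hkl_matrix <- function(hkl) {
  if (is.matrix(hkl)) {
    if (ncol(hkl) != 3) stop("hkl matrix must have 3 columns")
    hkl
  } else {
    if (length(hkl) != 3) stop("hkl must have length 3")
    matrix(as.numeric(hkl), 1, 3)
  }
}

#' Enumerate integer Miller indices to a resolution limit
#'
#' Generates all integer reflections with 0 < d* <= 1/d_min.  By default one
#' member of each Friedel pair is kept (the conventional unique half sphere:
#' h > 0, or h = 0 and k > 0, or h = k = 0 and l > 0); set `friedel = FALSE`
#' for the full sphere.
#'
#' @param cell A [unit_cell()].
#' @param d_min Resolution limit in Angstrom (> 0).
#' @param friedel Keep one reflection per Friedel pair (default TRUE).
#' @return Integer matrix with columns h, k, l.
#' @export
miller_index_set <- function(cell, d_min, friedel = TRUE) {
  stopifnot(inherits(cell, "unit_cell"), d_min > 0)
  smax <- 1 / d_min
  # |h| = |H . a_vec| <= d*max * |a|: safe per-axis bounds for any cell
  hmax <- floor(smax * cell$a); kmax <- floor(smax * cell$b)
  lmax <- floor(smax * cell$c)
  grid <- as.matrix(expand.grid(h = -hmax:hmax, k = -kmax:kmax, l = -lmax:lmax))
  ds <- d_star(cell, grid)
  keep <- ds > 0 & ds <= smax
  if (friedel) {
    h <- grid[, 1]; k <- grid[, 2]; l <- grid[, 3]
    keep <- keep & (h > 0 | (h == 0 & k > 0) | (h == 0 & k == 0 & l > 0))
  }
  m <- grid[keep, , drop = FALSE]
  storage.mode(m) <- "integer"
  dimnames(m) <- list(NULL, c("h", "k", "l"))
  m[order(m[, 1], m[, 2], m[, 3]), , drop = FALSE]
}
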