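# Atomic form factors: 4-Gaussian + constant parametrization
#   f(s) = sum_i a_i exp(-b_i s^2) + c,   s = sin(theta)/lambda = d*/2
# Coefficients for common biological elements from the standard
# International Tables (IT92 / Cromer-Mann) 4-Gaussian fits.
.FORM_FACTORS <- list(
  H  = list(a = c(0.493002, 0.322912, 0.140191, 0.040810),
            b = c(10.5109, 26.1257, 3.14236, 57.7997), c = 0.003038),
  C  = list(a = c(2.31000, 1.02000, 1.58860, 0.865000),
            b = c(20.8439, 10.2075, 0.568700, 51.6512), c = 0.215600),
  N  = list(a = c(12.2126, 3.13220, 2.01250, 1.16630),
            b = c(0.005700, 9.89330, 28.9975, 0.582600), c = -11.529),
  O  = list(a = c(3.04850, 2.28680, 1.54630, 0.867000),
            b = c(13.2771, 5.70110, 0.323900, 32.9089), c = 0.250800),
  P  = list(a = c(6.43450, 4.17910, 1.78000, 1.49080),
            b = c(1.90670, 27.1570, 0.526000, 68.1645), c = 1.11490),
  S  = list(a = c(6.90530, 5.20340, 1.43790, 1.58630),
            b = c(1.46790, 22.2151, 0.253600, 56.1720), c = 0.866900),
  Fe = list(a = c(11.7695, 7.35730, 3.52220, 2.30450),
            b = c(4.76110, 0.307200, 15.3535, 76.8805), c = 1.03690)
)

#' Form-factor coefficients for an element
#'
#' @param element Element symbol; built-in table covers H, C, N, O, P, S, Fe.
#' @return List with components `a`, `b` (Gaussian coefficient vectors) and
#'   constant `c`, class `form_factor_coeffs`.
#' @export
form_factor_coeffs <- function(element) {
  key <- paste0(toupper(substr(element, 1, 1)),
                tolower(substr(element, 2, 2)))
  key <- trimws(key)
  if (!key %in% names(.FORM_FACTORS)) {
    stop(sprintf("unknown element '%s': built-in form factors cover %s; supply explicit coefficients",
                 element, paste(names(.FORM_FACTORS), collapse = ", ")))
  }
  structure(.FORM_FACTORS[[key]], class = "form_factor_coeffs", element = key)
}

#' Evaluate an atomic form factor
#'
#' `f(d*) = sum_i a_i exp(-b_i (d*/2)^2) + c`.
#'
#' @param coeffs A `form_factor_coeffs` list (or any list with `a`, `b`, `c`).
#' @param d_star Reciprocal spacing(s) in 1/Angstrom, non-negative.
#' @return Scattering factor (electrons), same length as `d_star`.
#' @export
form_factor_value <- function(coeffs, d_star) {
  if (any(d_star < 0)) stop("d_star must be non-negative")
  s2 <- (d_star / 2)^2
  f <- rep(coeffs$c, length(s2))
  for (i in seq_along(coeffs$a)) f <- f + coeffs$a[i] * exp(-coeffs$b[i] * s2)
  f
}

#' Debye-Waller attenuation for isotropic displacement
#'
#' Returns `exp(-2 pi^2 u_iso d*^2)`, equivalently `exp(-B s^2)` with
#' `B = 8 pi^2 u_iso` and `s = d*/2`.  Equals 1 at `u_iso = 0` or `d* = 0`
#' and is strictly decreasing in both arguments otherwise.
#'
#' @param u_iso Isotropic mean-square displacement in Angstrom^2 (>= 0).
#' @param d_star Reciprocal spacing in 1/Angstrom.
#' @return Attenuation factor in (0, 1].
#' @export
debye_waller <- function(u_iso, d_star) {
  if (any(u_iso < 0)) stop("u_iso must be non-negative")
  exp(-2 * pi^2 * u_iso * d_star^2)
}

#' Convert a crystallographic B factor to u_iso
#'
#' `u = B / (8 pi^2)`; inverse of [u_iso_to_b()].
#' @param b_factor B factor in Angstrom^2 (>= 0).
#' @return u_iso in Angstrom^2.
#' @export
b_to_u_iso <- function(b_factor) {
  if (any(b_factor < 0)) stop("B factor must be non-negative")
  b_factor / (8 * pi^2)
}

#' Convert u_iso to a crystallographic B factor
#' @param u_iso Isotropic displacement in Angstrom^2 (>= 0).
#' @return B in Angstrom^2.
#' @export
u_iso_to_b <- function(u_iso) {
  if (any(u_iso < 0)) stop("u_iso must be non-negative")
  u_iso * 8 * pi^2
}

#' Crystal structure (asymmetric unit + symmetry)
#'
#' The container over which the direct summation runs: a unit cell, the
#' space-group operator list and the asymmetric-unit scatterers.
#'
#' @param cell A [unit_cell()].
#' @param scatterers data.frame with columns `label`, `element`, `x`, `y`,
#'   `z` (fractional coordinates, reduced to `[0,1)` on input), `occ`
#'   (occupancy in `[0,1]`) and `u_iso` (Angstrom^2, >= 0).  Missing `label`
#'   defaults to element + row number; missing `occ`/`u_iso` default to 1/0.
#' @param space_group Label looked up in the built-in table (see
#'   [space_group_ops()]), ignored when `symops` is given.
#' @param symops Optional explicit operator list; first must be the identity.
#' @param form_factors Optional named list mapping element symbols to
#'   coefficient lists, overriding/extending the built-in table.
#' @return Object of class `crystal_structure`.
#' @export
crystal_structure <- function(cell, scatterers, space_group = "P1",
                              symops = NULL, form_factors = NULL) {
  stopifnot(inherits(cell, "unit_cell"))
  sc <- as.data.frame(scatterers, stringsAsFactors = FALSE)
  need <- c("element", "x", "y", "z")
  if (!all(need %in% names(sc))) {
    stop("scatterers need columns: ", paste(need, collapse = ", "))
  }
  if (is.null(sc$occ)) sc$occ <- rep(1, nrow(sc))
  if (is.null(sc$u_iso)) sc$u_iso <- rep(0, nrow(sc))
  if (is.null(sc$label)) sc$label <- paste0(sc$element, seq_len(nrow(sc)))
  if (any(sc$occ < 0 | sc$occ > 1)) stop("occupancies must lie in [0, 1]")
  if (any(sc$u_iso < 0)) stop("u_iso must be non-negative")
  sc$x <- sc$x %% 1; sc$y <- sc$y %% 1; sc$z <- sc$z %% 1
  if (is.null(symops)) symops <- space_group_ops(space_group)
  if (length(symops) == 0) stop("operator list must be non-empty")
  if (!is_identity_op(symops[[1]])) stop("first symmetry operator must be the identity")
  ff <- .FORM_FACTORS
  if (!is.null(form_factors)) ff[names(form_factors)] <- form_factors
  missing_el <- setdiff(unique(sc$element), names(ff))
  if (length(missing_el)) {
    stop("no form-factor coefficients for element(s): ",
         paste(missing_el, collapse = ", "))
  }
  structure(list(cell = cell, symops = symops,
                 scatterers = sc[, c("label", "element", "x", "y", "z", "occ", "u_iso")],
                 space_group = space_group,
                 form_factors = ff),
            class = "crystal_structure")
}

#' @export
print.crystal_structure <- function(x, ...) {
  cat(sprintf("Crystal structure: %d scatterer(s), space group %s (%d op(s))\n",
              nrow(x$scatterers), x$space_group, length(x$symops)))
  print(x$cell)
  invisible(x)
}

#' Read a structure from the toolkit's JSON fixture format
#'
#' The native fixture document is
#' `{cell: {a,b,c,alpha,beta,gamma}, space_group,
#'   scatterers: [{element,x,y,z,occ,u_iso}, ...]}`.
#'
#' @param path JSON file path, or a JSON string.
#' @return A [crystal_structure()].
#' @export
read_structure_json <- function(path) {
  doc <- jsonlite::fromJSON(path)
  if (is.null(doc$cell)) stop("structure JSON lacks a 'cell' object")
  cl <- doc$cell
  cell <- unit_cell(cl$a, cl$b, cl$c,
                    alpha = cl$alpha %||% 90, beta = cl$beta %||% 90,
                    gamma = cl$gamma %||% 90)
  crystal_structure(cell, doc$scatterers,
                    space_group = doc$space_group %||% "P1")
}

#' Write a structure to the JSON fixture format
#' @param structure A [crystal_structure()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure_json <- function(structure, path) {
  doc <- list(cell = structure$cell[c("a", "b", "c", "alpha", "beta", "gamma")],
              space_group = structure$space_group,
              scatterers = structure$scatterers)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
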