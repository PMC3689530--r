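#' Symmetry operator
#'
#' A space-group operation x -> R x + T in fractional coordinates.
#'
#' @param R 3x3 integer rotation part, det(R) = +-1.
#' @param T Length-3 translation; components are reduced mod 1.
#' @return Object of class `symop`.
#' @export
symop <- function(R, T = c(0, 0, 0)) {
  R <- matrix(as.numeric(R), 3, 3)
  if (!isTRUE(all.equal(R, round(R)))) stop("rotation part must be integral")
  if (abs(abs(det(R)) - 1) > 1e-9) stop("rotation part must have det +-1")
  structure(list(R = round(R), T = as.numeric(T) %% 1), class = "symop")
}

symop_identity <- function() symop(diag(3))

is_identity_op <- function(op) {
  all(op$R == diag(3)) && all(abs(op$T) < 1e-9)
}

#' Parse an "x,y,z"-style symmetry triplet
#'
#' @param triplet Text such as `"-x,y+1/2,-z"`.
#' @return A [symop()].
#' @export
parse_symop <- function(triplet) {
  parts <- strsplit(gsub(" ", "", tolower(triplet)), ",")[[1]]
  if (length(parts) != 3) stop("symmetry triplet must have three components")
  R <- matrix(0, 3, 3); T <- numeric(3)
  axes <- c(x = 1, y = 2, z = 3)
  for (i in 1:3) {
    # split into signed terms
    s <- gsub("([+-])", " \\1", parts[i])
    for (term in strsplit(trimws(s), "\\s+")[[1]]) {
      if (term == "") next
      sign <- if (startsWith(term, "-")) -1 else 1
      term <- sub("^[+-]", "", term)
      if (term %in% names(axes)) {
        R[i, axes[[term]]] <- sign
      } else if (grepl("/", term)) {
        fr <- as.numeric(strsplit(term, "/")[[1]])
        T[i] <- T[i] + sign * fr[1] / fr[2]
      } else {
        T[i] <- T[i] + sign * as.numeric(term)
      }
    }
  }
  symop(R, T)
}

#' @export
print.symop <- function(x, ...) {
  axes <- c("x", "y", "z")
  comp <- vapply(1:3, function(i) {
    s <- ""
    for (j in 1:3) {
      if (x$R[i, j] != 0) {
        s <- paste0(s, if (x$R[i, j] > 0 && nzchar(s)) "+" else if (x$R[i, j] < 0) "-" else "",
                    axes[j])
      }
    }
    if (abs(x$T[i]) > 1e-9) {
      fr <- .as_fraction(x$T[i])
      s <- paste0(s, "+", fr)
    }
    s
  }, character(1))
  cat(paste(comp, collapse = ","), "\n")
  invisible(x)
}

.as_fraction <- function(t) {
  for (den in c(2L, 3L, 4L, 6L)) {
    if (abs(t * den - round(t * den)) < 1e-9) {
      return(sprintf("%d/%d", as.integer(round(t * den)), den))
    }
  }
  format(t)
}

# Built-in space-group table: minimal, explicit operator lists.
# Triplets cross-checked against the standard tables.
.SPACE_GROUPS <- list(
  "P1"       = c("x,y,z"),
  "P21"      = c("x,y,z", "-x,y+1/2,-z"),
  "C2"       = c("x,y,z", "-x,y,-z", "x+1/2,y+1/2,z", "-x+1/2,y+1/2,-z"),
  "P212121"  = c("x,y,z", "-x+1/2,-y,z+1/2", "x+1/2,-y+1/2,-z", "-x,y+1/2,-z+1/2"),
  "P63"      = c("x,y,z", "x-y,x,z+1/2", "-y,x-y,z", "-x,-y,z+1/2",
                 "-x+y,-x,z", "y,-x+y,z+1/2")
)

.canon_sg_label <- function(label) {
  lab <- toupper(gsub("[ ()_]", "", label))
  # map a few common aliases onto the canonical keys
  alias <- c("P1" = "P1", "P121" = "P21", "P1211" = "P21", "P21" = "P21",
             "C121" = "C2", "C2" = "C2",
             "P212121" = "P212121", "P63" = "P63")
  if (!lab %in% names(alias)) return(NA_character_)
  alias[[lab]]
}

#' Built-in space-group operator lists
#'
#' The toolkit ships a minimal explicit table: P1, P2\eqn{_1}, C2,
#' P2\eqn{_1}2\eqn{_1}2\eqn{_1} and P6\eqn{_3} (the group used for the
#' finite-crystallite fringe demonstration).  Other groups must be supplied as
#' explicit operator lists.
#'
#' @param label Space-group label, e.g. `"P 21 21 21"` (spaces optional).
#' @return List of [symop()] objects; the first is always the identity.
#' @export
space_group_ops <- function(label) {
  key <- .canon_sg_label(label)
  if (is.na(key)) {
    stop(sprintf("unsupported space group '%s'; supported: %s",
                 label, paste(names(.SPACE_GROUPS), collapse = ", ")))
  }
  lapply(.SPACE_GROUPS[[key]], parse_symop)
}

#' Supported space-group labels
#' @return Character vector of canonical labels.
#' @export
supported_space_groups <- function() names(.SPACE_GROUPS)

#' Expand a structure to space group P1
#'
#' Replaces the asymmetric unit by its full orbit under the structure's
#' symmetry operators: every scatterer is mapped through every operator,
#' positions reduced to `[0, 1)`, and the operator list collapses to the
#' identity.  Special positions are not merged and occupancies are carried
#' verbatim, so the scatterer count is always
#' `n_scatterers * n_symops`; structure factors computed from the expansion
#' equal the symmetry-aware ones.
#'
#' @param structure A [crystal_structure()].
#' @return A [crystal_structure()] in P1.
#' @export
expand_to_p1 <- function(structure) {
  stopifnot(inherits(structure, "crystal_structure"))
  sc <- structure$scatterers
  out <- vector("list", length(structure$symops))
  for (i in seq_along(structure$symops)) {
    op <- structure$symops[[i]]
    xyz <- as.matrix(sc[, c("x", "y", "z")]) %*% t(op$R)
    xyz <- sweep(xyz, 2, op$T, "+") %% 1
    part <- sc
    part$x <- xyz[, 1]; part$y <- xyz[, 2]; part$z <- xyz[, 3]
    out[[i]] <- part
  }
  all_sc <- do.call(rbind, out)
  rownames(all_sc) <- NULL
  crystal_structure(structure$cell, scatterers = all_sc,
                    space_group = "P1",
                    form_factors = structure$form_factors)
}
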