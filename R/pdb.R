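#' Read a minimal PDB file into a crystal structure
#'
#' Parses CRYST1 (cell and space-group label) plus ATOM/HETATM records.
#' Cartesian coordinates are fractionalized with the standard PDB
#' orthogonalization convention; the occupancy column maps to `occ` and the
#' B-factor column to `u_iso` via `u = B / (8 pi^2)`.  The element is taken
#' from columns 77-78 when present, otherwise inferred from the atom name.
#' Symmetry operators come from the built-in table keyed by the CRYST1
#' space-group field.
#'
#' @param path Path to a PDB file, or a character vector of PDB lines.
#' @return A [crystal_structure()].
#' @export
parse_pdb_minimal <- function(path) {
  lines <- if (length(path) == 1 && file.exists(path)) readLines(path, warn = FALSE) else path
  cr <- grep("^CRYST1", lines, value = TRUE)
  if (length(cr) == 0) stop("PDB input has no CRYST1 record")
  cr <- cr[1]
  cell <- unit_cell(as.numeric(substr(cr, 7, 15)),
                    as.numeric(substr(cr, 16, 24)),
                    as.numeric(substr(cr, 25, 33)),
                    alpha = as.numeric(substr(cr, 34, 40)),
                    beta  = as.numeric(substr(cr, 41, 47)),
                    gamma = as.numeric(substr(cr, 48, 54)))
  sg_label <- trimws(substr(cr, 56, 66))

  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf))
  writeLines(lines, tf)
  pdb <- bio3d::read.pdb(tf, verbose = FALSE)
  at <- pdb$atom
  if (nrow(at) == 0) stop("PDB input has no ATOM/HETATM records")

  el <- trimws(at$elesy)
  noel <- is.na(el) | el == ""
  if (any(noel)) {
    # heuristic: first alphabetic character of the atom name
    guess <- toupper(substr(gsub("[^A-Za-z].*", "",
                                 sub("^[0-9 ]*", "", at$elety[noel])), 1, 1))
    el[noel] <- guess
  }
  el <- paste0(toupper(substr(el, 1, 1)), tolower(substr(el, 2, 2)))
  el <- trimws(el)
  bad <- !el %in% names(.FORM_FACTORS)
  if (any(bad)) {
    stop(sprintf("unknown element for atom(s) %s: no built-in form factor",
                 paste(unique(at$elety[bad]), collapse = ", ")))
  }
  frac <- cbind(at$x, at$y, at$z) %*% t(cell$frac)
  sc <- data.frame(label = trimws(at$elety), element = el,
                   x = frac[, 1], y = frac[, 2], z = frac[, 3],
                   occ = at$o, u_iso = b_to_u_iso(at$b),
                   stringsAsFactors = FALSE)
  crystal_structure(cell, sc, space_group = sg_label)
}

#' Write a crystal structure as a minimal PDB file
#'
#' Intended for synthetic fixtures: emits a CRYST1 record and one HETATM
#' record per scatterer (Cartesian coordinates from the cell's
#' orthogonalization matrix, occupancy from `occ`, B from `8 pi^2 u_iso`).
#'
#' @param structure A [crystal_structure()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb_minimal <- function(structure, path) {
  cell <- structure$cell
  sg <- .canon_sg_label(structure$space_group)
  sg_field <- switch(sg,
                     P1 = "P 1", P21 = "P 1 21 1", C2 = "C 1 2 1",
                     P212121 = "P 21 21 21", P63 = "P 63", "P 1")
  lines <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s%4d",
                   cell$a, cell$b, cell$c, cell$alpha, cell$beta, cell$gamma,
                   sg_field, length(structure$symops))
  sc <- structure$scatterers
  xyz <- as.matrix(sc[, c("x", "y", "z")]) %*% t(cell$orth)
  for (i in seq_len(nrow(sc))) {
    lines <- c(lines, sprintf(
      "HETATM%5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      i, substr(sc$label[i], 1, 4), "UNK", i,
      xyz[i, 1], xyz[i, 2], xyz[i, 3],
      sc$occ[i], u_iso_to_b(sc$u_iso[i]), toupper(sc$element[i])))
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}
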