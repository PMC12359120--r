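#' Construct a dihedral scan object
#'
#' A torsion scan: angles (degrees), relative reference energies (kJ/mol,
#' zero-shifted on construction) and, optionally, the per-frame geometries.
#'
#' @param quad 0-based atom quadruple the scan rotates
#' @param angles scan angles, degrees, all within one 360-degree window
#' @param energies reference energies, kJ/mol (shifted so min = 0)
#' @param geometries optional list of N x 3 coordinate matrices
#' @return object of class `dihedral_scan`
#' @export
dihedral_scan <- function(quad, angles, energies, geometries = NULL) {
  angles <- as.numeric(angles); energies <- as.numeric(energies)
  if (length(angles) != length(energies)) stop("angles/energies length mismatch")
  if (!all(is.finite(energies))) stop("energies must be finite")
  if (diff(range(angles)) >= 360) stop("angles must lie within one 360-degree window")
  if (!is.null(geometries) && length(geometries) != length(angles)) {
    stop("geometries must match the number of scan points")
  }
  structure(list(quad = as.integer(quad), angles = angles,
                 energies = energies - min(energies), geometries = geometries),
            class = "dihedral_scan")
}

#' @export
print.dihedral_scan <- function(x, ...) {
  cat(sprintf("dihedral scan %s: %d points, %.1f..%.1f deg, span %.2f kJ/mol%s\n",
              paste(x$quad + 1L, collapse = "-"), length(x$angles),
              min(x$angles), max(x$angles), max(x$energies),
              if (is.null(x$geometries)) "" else ", with geometries"))
  invisible(x)
}

#' Read a multi-frame XYZ scan file
#'
#' Each frame is a standard XYZ block whose comment line carries the scan
#' metadata: `Scan <i>-<j>-<k>-<l> Dihedral <deg> Energy <value> [unit]`,
#' 1-based atom labels, unit `hartree` (default) or `kj/mol` / `kcal/mol`.
#' Energies are converted to kJ/mol and shifted so the minimum is zero.
#'
#' @param path path to the scan file
#' @return a `dihedral_scan` with geometries
#' @export
read_scan_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[seq_len(max(which(nzchar(trimws(lines))), 0L))]
  offset <- 0L; frame <- 0L
  quad <- NULL; n_ref <- NULL
  angles <- numeric(0); energies <- numeric(0); geoms <- list()
  while (offset < length(lines)) {
    frame <- frame + 1L
    parsed <- parse_xyz_frame(lines, offset)
    mol <- parsed$mol
    if (is.null(n_ref)) n_ref <- n_atoms(mol)
    if (n_atoms(mol) != n_ref) {
      stop("scan file frame ", frame, ": atom count ", n_atoms(mol),
           " differs from first frame (", n_ref, ")")
    }
    meta <- parse_scan_comment(mol$comment, frame)
    if (is.null(quad)) quad <- meta$quad
    else if (!identical(quad, meta$quad)) {
      stop("scan file frame ", frame, ": scan quadruple changed")
    }
    angles <- c(angles, meta$angle)
    energies <- c(energies, meta$energy)
    geoms[[frame]] <- mol$coordinates
    offset <- offset + parsed$consumed
  }
  if (!frame) stop("empty scan file: ", path)
  dihedral_scan(quad, angles, energies, geoms)
}

parse_scan_comment <- function(comment, frame) {
  tok <- strsplit(trimws(comment), "\\s+")[[1]]
  iq <- which(tolower(tok) == "scan")
  ia <- which(tolower(tok) == "dihedral")
  ie <- which(tolower(tok) == "energy")
  if (!length(iq) || !length(ia) || !length(ie) ||
      iq + 1L > length(tok) || ia + 1L > length(tok) || ie + 1L > length(tok)) {
    stop("scan file frame ", frame, ": unparsable comment line '", comment, "'")
  }
  quad <- suppressWarnings(as.integer(strsplit(tok[iq + 1L], "-")[[1]])) - 1L
  angle <- suppressWarnings(as.numeric(tok[ia + 1L]))
  energy <- suppressWarnings(as.numeric(tok[ie + 1L]))
  if (length(quad) != 4L || any(is.na(quad)) || is.na(angle) || is.na(energy)) {
    stop("scan file frame ", frame, ": unparsable comment line '", comment, "'")
  }
  unit <- if (ie + 2L <= length(tok)) tolower(tok[ie + 2L]) else "hartree"
  fac <- switch(unit,
                hartree = .hartree_kjmol,
                "kj/mol" = , kjmol = , kj = 1,
                "kcal/mol" = , kcal = 4.184,
                stop("scan file frame ", frame, ": unknown energy unit '",
                     unit, "'"))
  list(quad = quad, angle = angle, energy = energy * fac)
}

#' Write a dihedral scan to the multi-frame XYZ dialect
#' @param scan a `dihedral_scan` with geometries
#' @param elements element symbols for the frames
#' @param path output path
#' @param unit energy unit token to write (`"kj/mol"` or `"hartree"`)
#' @return `path`, invisibly
#' @export
write_scan_file <- function(scan, elements, path, unit = "kj/mol") {
  if (is.null(scan$geometries)) stop("scan has no geometries to write")
  fac <- if (unit == "hartree") 1 / .hartree_kjmol else 1
  blocks <- vapply(seq_along(scan$angles), function(f) {
    mol <- molecule(elements, scan$geometries[[f]])
    cm <- sprintf("Scan %s Dihedral %.6f Energy %.12g %s",
                  paste(scan$quad + 1L, collapse = "-"),
                  scan$angles[f], scan$energies[f] * fac, unit)
    write_xyz_string(mol, comment = cm)
  }, character(1))
  writeLines(paste(blocks, collapse = "\n"), path)
  invisible(path)
}

#' MM energies along a scan
#'
#' Evaluates the force field at each scan point: on the stored geometries when
#' present, otherwise on rigid-rotation geometries obtained by setting the
#' scanned dihedral on `mol`. Energies are returned relative (min = 0), in the
#' scan's ordering.
#'
#' @param mol a `molecule` (the conformer used for rigid rotation)
#' @param ff a `forcefield`
#' @param scan a `dihedral_scan`
#' @return numeric vector, kJ/mol, min exactly 0
#' @export
mm_scan <- function(mol, ff, scan) {
  ff <- cache_pairs(ff)
  e <- vapply(seq_along(scan$angles), function(f) {
    m <- scan_frame_molecule(mol, scan, f)
    evaluate_mm(m, ff, gradient = FALSE)$energy[["total"]]
  }, numeric(1))
  e - min(e)
}

scan_frame_molecule <- function(mol, scan, f) {
  if (!is.null(scan$geometries)) {
    mol$coordinates <- scan$geometries[[f]]
    mol
  } else {
    set_dihedral_in_degrees(mol, scan$quad, scan$angles[f])
  }
}
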