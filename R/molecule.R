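#' Construct a molecule object
#'
#' The central structure container: element symbols, Cartesian coordinates in
#' Angstrom, formal charge, spin multiplicity and an (optional) undirected bond
#' graph over 0-based atom indices. All other modules consume this object.
#'
#' @param elements character vector of element symbols
#' @param coordinates N x 3 numeric matrix, Angstrom
#' @param charge integer formal charge (e)
#' @param multiplicity positive integer spin multiplicity
#' @param bonds two-column integer matrix of 0-based atom index pairs, or NULL
#' @param comment free-text comment carried through XYZ round trips
#' @return an object of class `molecule`
#' @export
molecule <- function(elements, coordinates, charge = 0L, multiplicity = 1L,
                     bonds = NULL, comment = "") {
  elements <- normalize_element(as.character(elements))
  if (!all(element_known(elements))) {
    stop("unknown element symbol(s): ",
         paste(unique(elements[!element_known(elements)]), collapse = ", "))
  }
  coordinates <- as.matrix(coordinates)
  storage.mode(coordinates) <- "double"
  n <- length(elements)
  if (!is.matrix(coordinates) || nrow(coordinates) != n || ncol(coordinates) != 3) {
    stop("coordinates must be an N x 3 matrix matching length(elements)")
  }
  if (!all(is.finite(coordinates))) stop("coordinates must be finite")
  if (multiplicity < 1) stop("multiplicity must be a positive integer")
  mol <- structure(
    list(elements = elements, coordinates = coordinates,
         charge = as.integer(charge), multiplicity = as.integer(multiplicity),
         bonds = normalize_bonds(bonds, n), comment = as.character(comment)),
    class = "molecule")
  mol
}

normalize_bonds <- function(bonds, n_atoms) {
  if (is.null(bonds) || NROW(bonds) == 0) {
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("a", "b"))))
  }
  bonds <- matrix(as.integer(bonds), ncol = 2)
  if (any(bonds < 0L) || any(bonds >= n_atoms)) {
    stop("bond indices out of range (0-based, < n_atoms)")
  }
  if (any(bonds[, 1] == bonds[, 2])) stop("self-bonds are not allowed")
  bonds <- t(apply(bonds, 1, sort))
  bonds <- unique(bonds)
  bonds <- bonds[order(bonds[, 1], bonds[, 2]), , drop = FALSE]
  dimnames(bonds) <- list(NULL, c("a", "b"))
  bonds
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("molecule: %d atoms (%s), charge %+d, multiplicity %d, %d bonds\n",
              n_atoms(x), paste(unique(x$elements), collapse = ","),
              x$charge, x$multiplicity, nrow(x$bonds)))
  invisible(x)
}

#' Number of atoms in a molecule
#' @param mol a `molecule`
#' @return integer atom count
#' @export
n_atoms <- function(mol) length(mol$elements)

# adjacency list over 0-based indices; returns list indexed by atom+1
adjacency_list <- function(mol) {
  adj <- vector("list", n_atoms(mol))
  for (i in seq_along(adj)) adj[[i]] <- integer(0)
  if (nrow(mol$bonds)) {
    for (r in seq_len(nrow(mol$bonds))) {
      a <- mol$bonds[r, 1]; b <- mol$bonds[r, 2]
      adj[[a + 1L]] <- c(adj[[a + 1L]], b)
      adj[[b + 1L]] <- c(adj[[b + 1L]], a)
    }
  }
  adj
}

has_bond <- function(mol, a, b) {
  any(mol$bonds[, 1] == min(a, b) & mol$bonds[, 2] == max(a, b))
}

#' Parse an XYZ-format string into a molecule
#'
#' Standard XYZ: integer atom count, comment line, then one
#' `element x y z` line per atom (coordinates in Angstrom).
#'
#' @param text a single string (may contain newlines) or character vector of lines
#' @return a `molecule` with an empty bond set
#' @export
read_xyz_string <- function(text) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  parse_xyz_frame(lines, offset = 0L)$mol
}

#' Read a (single-frame) XYZ file
#' @param path path to an XYZ file
#' @return a `molecule`
#' @export
read_xyz <- function(path) read_xyz_string(readLines(path, warn = FALSE))

# Parse one XYZ frame starting at lines[offset+1]; returns mol + lines consumed.
parse_xyz_frame <- function(lines, offset = 0L) {
  if (length(lines) < offset + 2L) stop("XYZ parse error: truncated header at line ",
                                        offset + 1L)
  n_line <- trimws(lines[offset + 1L])
  n <- suppressWarnings(as.integer(n_line))
  if (is.na(n) || n < 1L) {
    stop("XYZ parse error at line ", offset + 1L, ": expected atom count, got '",
         n_line, "'")
  }
  if (length(lines) < offset + 2L + n) {
    stop("XYZ parse error: header declares ", n, " atoms but file ends at line ",
         length(lines))
  }
  comment <- lines[offset + 2L]
  elements <- character(n); coords <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    ln <- offset + 2L + i
    tok <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(tok) < 4L) stop("XYZ parse error at line ", ln,
                               ": expected 'element x y z'")
    if (!element_known(tok[1])) stop("XYZ parse error at line ", ln,
                                     ": unknown element '", tok[1], "'")
    xyz <- suppressWarnings(as.numeric(tok[2:4]))
    if (any(is.na(xyz))) stop("XYZ parse error at line ", ln,
                              ": non-numeric coordinate")
    elements[i] <- tok[1]; coords[i, ] <- xyz
  }
  # a trailing line that itself looks like an atom entry means the count lied
  nxt <- offset + 2L + n + 1L
  if (nxt <= length(lines)) {
    tok <- strsplit(trimws(lines[nxt]), "\\s+")[[1]]
    if (length(tok) >= 4L && element_known(tok[1]) &&
        !any(is.na(suppressWarnings(as.numeric(tok[2:4]))))) {
      stop("XYZ parse error at line ", offset + 1L,
           ": header declares ", n, " atoms but more atom lines follow")
    }
  }
  list(mol = molecule(elements, coords, comment = comment),
       consumed = n + 2L)
}

#' Serialize a molecule to an XYZ-format string
#' @param mol a `molecule`
#' @param comment comment line (defaults to the molecule's stored comment)
#' @param digits printed coordinate precision
#' @return a single string
#' @export
write_xyz_string <- function(mol, comment = mol$comment, digits = 10) {
  fmt <- sprintf("%%-3s %%%d.%df %%%d.%df %%%d.%df",
                 digits + 6, digits, digits + 6, digits, digits + 6, digits)
  body <- vapply(seq_len(n_atoms(mol)), function(i) {
    sprintf(fmt, mol$elements[i], mol$coordinates[i, 1],
            mol$coordinates[i, 2], mol$coordinates[i, 3])
  }, character(1))
  paste(c(as.character(n_atoms(mol)), comment, body), collapse = "\n")
}

#' Write a molecule to an XYZ file
#' @inheritParams write_xyz_string
#' @param path output path
#' @return `path`, invisibly
#' @export
write_xyz <- function(mol, path, comment = mol$comment, digits = 10) {
  writeLines(write_xyz_string(mol, comment, digits), path)
  invisible(path)
}

#' Read a PDB file (coordinate subset)
#'
#' Reads ATOM/HETATM records only: element (column 77-78, falling back to the
#' atom name) and orthogonal coordinates. Alternate locations, occupancies and
#' connectivity records are ignored.
#'
#' @param path path to a PDB file
#' @return a `molecule` with an empty bond set
#' @export
read_pdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  keep <- lines[rec %in% c("ATOM  ", "HETATM")]
  if (!length(keep)) stop("no ATOM/HETATM records in ", path)
  n <- length(keep)
  elements <- character(n); coords <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    ln <- keep[i]
    coords[i, ] <- as.numeric(c(substr(ln, 31, 38), substr(ln, 39, 46),
                                substr(ln, 47, 54)))
    el <- trimws(substr(ln, 77, 78))
    if (!nzchar(el)) {
      # fall back to the first alphabetic run of the atom-name field
      el <- sub("^[0-9 ]*([A-Za-z]+).*$", "\\1", substr(ln, 13, 16))
      if (nchar(el) > 1 && !element_known(el)) el <- substr(el, 1, 1)
    }
    elements[i] <- el
  }
  if (any(is.na(coords))) stop("non-numeric coordinates in PDB file ", path)
  molecule(elements, coords)
}

#' Perceive covalent bonds from interatomic distances
#'
#' A bond a-b is assigned whenever the distance is at most
#' `tolerance * (r_cov(a) + r_cov(b))`.
#'
#' @param mol a `molecule`
#' @param tolerance scale factor on the covalent-radius sum (default 1.3)
#' @return the molecule with its bond set replaced
#' @export
perceive_bonds <- function(mol, tolerance = 1.3) {
  n <- n_atoms(mol)
  if (n < 2L) { mol$bonds <- normalize_bonds(NULL, n); return(mol) }
  d <- as.matrix(stats::dist(mol$coordinates))
  if (any(d[upper.tri(d)] < 0.4)) {
    stop("overlapping atoms: interatomic distance below 0.4 Angstrom")
  }
  r <- covalent_radius(mol$elements)
  thresh <- outer(r, r, `+`) * tolerance
  hit <- which(d <= thresh & upper.tri(d), arr.ind = TRUE)
  mol$bonds <- normalize_bonds(cbind(hit[, 1] - 1L, hit[, 2] - 1L), n)
  mol
}
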