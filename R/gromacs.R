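#' Write a GROMACS topology for a single molecule
#'
#' Emits an .itp with `[ moleculetype ]`, `[ atoms ]`, `[ bonds ]` (funct 1),
#' `[ pairs ]` (funct 1, the 1-4 list), `[ angles ]` (funct 1) and
#' `[ dihedrals ]` (funct 9, one line per cosine term), plus a .top wrapper
#' with `[ defaults ]`, `[ atomtypes ]`, `[ system ]` and `[ molecules ]`.
#' Units follow the format: nm, kJ/mol, degrees; force constants are converted
#' from the internal Angstrom/radian units.
#'
#' @param mol a `molecule`
#' @param ff a `forcefield` covering it
#' @param path output basename; `<path>.itp` and `<path>.top` are written
#' @param name moleculetype name
#' @return invisibly, the paths written
#' @export
write_gromacs <- function(mol, ff, path, name = "MOL") {
  itp <- c("[ moleculetype ]",
           "; name  nrexcl",
           sprintf("%s  3", name),
           "",
           "[ atoms ]",
           ";  nr  type resnr residue atom cgnr charge mass")
  for (i in seq_len(ff$n_atoms)) {
    itp <- c(itp, sprintf("%6d %6s %5d %6s %4s%d %4d %12.6f %10.5f",
                          i, paste0(ff$types[i], i), 1L, name,
                          mol$elements[i], i, i, ff$charges[i],
                          atomic_mass(mol$elements[i])))
  }
  itp <- c(itp, "", "[ bonds ]", ";  ai  aj funct      r0(nm)  k(kJ/mol/nm2)")
  if (nrow(ff$bonds)) for (r in seq_len(nrow(ff$bonds))) {
    tr <- ff$bonds[r, ]
    itp <- c(itp, sprintf("%6d %6d %5d %12.6f %14.4f",
                          tr$a + 1L, tr$b + 1L, 1L, tr$r0 / 10, tr$k * 100))
  }
  pr <- nonbonded_pairs(ff)
  pr <- pr[pr$scale14, , drop = FALSE]
  itp <- c(itp, "", "[ pairs ]", ";  ai  aj funct")
  if (nrow(pr)) for (r in seq_len(nrow(pr))) {
    itp <- c(itp, sprintf("%6d %6d %5d", pr$a[r] + 1L, pr$b[r] + 1L, 1L))
  }
  itp <- c(itp, "", "[ angles ]",
           ";  ai  aj  ak funct  theta0(deg)  k(kJ/mol/rad2)")
  if (nrow(ff$angles)) for (r in seq_len(nrow(ff$angles))) {
    tr <- ff$angles[r, ]
    itp <- c(itp, sprintf("%6d %6d %6d %5d %12.4f %14.4f",
                          tr$a + 1L, tr$b + 1L, tr$c + 1L, 1L,
                          tr$theta0 * 180 / pi, tr$k))
  }
  itp <- c(itp, "", "[ dihedrals ]",
           ";  ai  aj  ak  al funct  phase(deg)  k(kJ/mol)  pn")
  if (nrow(ff$dihedrals)) for (r in seq_len(nrow(ff$dihedrals))) {
    tr <- ff$dihedrals[r, ]
    itp <- c(itp, sprintf("%6d %6d %6d %6d %5d %12.4f %14.6f %3d",
                          tr$i + 1L, tr$j + 1L, tr$k + 1L, tr$l + 1L, 9L,
                          wrap_angle(tr$phi0) * 180 / pi, tr$A, tr$p))
  }
  itp_path <- paste0(path, ".itp")
  writeLines(itp, itp_path)

  top <- c("[ defaults ]",
           "; nbfunc comb-rule gen-pairs fudgeLJ fudgeQQ",
           sprintf("1 2 yes %.6f %.6f", ff$scale14_lj, ff$scale14_coulomb),
           "",
           "[ atomtypes ]",
           "; name at.num mass charge ptype sigma(nm) epsilon(kJ/mol)")
  for (i in seq_len(ff$n_atoms)) {
    top <- c(top, sprintf("%6s %4d %10.5f %10.6f  A %12.6f %12.6f",
                          paste0(ff$types[i], i),
                          .element_table[mol$elements[i], "number"],
                          atomic_mass(mol$elements[i]), 0,
                          ff$sigma[i] / 10, ff$epsilon[i]))
  }
  top <- c(top, "", sprintf('#include "%s"', basename(itp_path)), "",
           "[ system ]", name, "", "[ molecules ]", sprintf("%s 1", name))
  top_path <- paste0(path, ".top")
  writeLines(top, top_path)
  invisible(c(itp = itp_path, top = top_path))
}

# Internal reader for round-trip checks: parses the .itp/.top pair written by
# write_gromacs back into a forcefield (internal units restored).
read_gromacs <- function(path) {
  itp <- readLines(paste0(path, ".itp"), warn = FALSE)
  top <- readLines(paste0(path, ".top"), warn = FALSE)
  strip <- function(lines) {
    lines <- sub(";.*$", "", lines)
    trimws(lines)
  }
  sec_rows <- function(lines, sec) {
    lines <- strip(lines)
    starts <- grep("^\\[", lines)
    names <- gsub("[][ ]", "", lines[starts])
    w <- which(names == sec)
    if (!length(w)) return(character(0))
    from <- starts[w[1]] + 1L
    to <- if (any(starts > from)) min(starts[starts > from]) - 1L else length(lines)
    out <- lines[from:to]
    out[nzchar(out) & !startsWith(out, "#")]
  }
  tok <- function(rows) lapply(strsplit(rows, "\\s+"), identity)

  atoms <- tok(sec_rows(itp, "atoms"))
  n <- length(atoms)
  charges <- vapply(atoms, function(t) as.numeric(t[7]), numeric(1))
  types <- vapply(atoms, function(t) sub("[0-9]+$", "", t[2]), character(1))
  at <- tok(sec_rows(top, "atomtypes"))
  sigma <- vapply(at, function(t) as.numeric(t[6]) * 10, numeric(1))
  eps <- vapply(at, function(t) as.numeric(t[7]), numeric(1))
  def <- tok(sec_rows(top, "defaults"))[[1]]
  ff <- forcefield(n, charges = charges, sigma = sigma, epsilon = eps,
                   types = types, scale14_lj = as.numeric(def[4]),
                   scale14_coulomb = as.numeric(def[5]))
  for (t in tok(sec_rows(itp, "bonds"))) {
    ff <- add_bond_term(ff, as.integer(t[1]) - 1L, as.integer(t[2]) - 1L,
                        k = as.numeric(t[5]) / 100, r0 = as.numeric(t[4]) * 10)
  }
  for (t in tok(sec_rows(itp, "angles"))) {
    ff <- add_angle_term(ff, as.integer(t[1]) - 1L, as.integer(t[2]) - 1L,
                         as.integer(t[3]) - 1L, k = as.numeric(t[6]),
                         theta0 = as.numeric(t[5]) * pi / 180)
  }
  for (t in tok(sec_rows(itp, "dihedrals"))) {
    ff <- add_dihedral_term(ff, as.integer(t[1:4]) - 1L,
                            A = as.numeric(t[7]), p = as.integer(t[8]),
                            phi0 = as.numeric(t[6]) * pi / 180)
  }
  ff
}
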