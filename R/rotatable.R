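#' Detect rotatable bonds
#'
#' A rotatable bond is an acyclic bond between two non-terminal atoms. Each
#' detected bond carries a reference torsion quadruple and a multiplicity (the
#' number of torsional minima): 3 when both bond ends are sp3-like, 2 when
#' either end is sp2-like, with hybridization inferred from the neighbor count
#' (3 neighbors on C/N -> sp2; otherwise sp3-like). Methyl rotors (a carbon
#' whose only substituents beyond the axis are three hydrogens) can be
#' excluded, as conformer enumeration usually wants.
#'
#' @param mol a `molecule` with perceived bonds
#' @param exclude_methyl drop bonds whose rotation only spins a CH3 group
#' @return a data.frame of class `rotatable_bonds` with 0-based columns
#'   `j`, `k` (the axis), `i`, `l` (the reference quadruple) and `multiplicity`
#' @export
detect_rotatable_bonds <- function(mol, exclude_methyl = TRUE) {
  adj <- adjacency_list(mol)
  deg <- lengths(adj)
  out <- NULL
  if (nrow(mol$bonds)) {
    for (r in seq_len(nrow(mol$bonds))) {
      j <- mol$bonds[r, 1]; k <- mol$bonds[r, 2]
      if (deg[j + 1L] < 2L || deg[k + 1L] < 2L) next
      if (bond_in_ring(mol, j, k)) next
      if (exclude_methyl && (is_methyl_end(mol, adj, j, k) ||
                             is_methyl_end(mol, adj, k, j))) next
      i <- pick_reference_neighbor(mol, adj, j, k)
      l <- pick_reference_neighbor(mol, adj, k, j)
      out <- rbind(out, data.frame(
        j = j, k = k, i = i, l = l,
        multiplicity = bond_multiplicity(mol, deg, j, k)))
    }
  }
  if (is.null(out)) {
    out <- data.frame(j = integer(0), k = integer(0), i = integer(0),
                      l = integer(0), multiplicity = integer(0))
  }
  class(out) <- c("rotatable_bonds", "data.frame")
  out
}

# end atom `a` (bonded to axis partner `other`) is a methyl rotor carbon
is_methyl_end <- function(mol, adj, other, a) {
  if (mol$elements[a + 1L] != "C") return(FALSE)
  nb <- setdiff(adj[[a + 1L]], other)
  length(nb) == 3L && all(mol$elements[nb + 1L] == "H")
}

# heaviest (then lowest-index) neighbor of `a` other than `other`
pick_reference_neighbor <- function(mol, adj, a, other) {
  nb <- setdiff(adj[[a + 1L]], other)
  m <- atomic_mass(mol$elements[nb + 1L])
  nb[order(-m, nb)][1]
}

bond_multiplicity <- function(mol, deg, j, k) {
  sp2 <- function(a) {
    el <- mol$elements[a + 1L]
    deg[a + 1L] == 3L && el %in% c("C", "N", "B")
  }
  if (sp2(j) || sp2(k)) 2L else 3L
}
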