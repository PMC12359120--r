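# Per-element data for the subset of the periodic table this toolkit targets
# (organic chemistry + common counterions/metals). Covalent radii follow the
# Cordero 2008 consensus set; vdW radii are Bondi values with the Rowland/Taylor
# H adjustment; masses are standard atomic weights.

.element_table <- local({
  tab <- read.table(header = TRUE, stringsAsFactors = FALSE, text = "
symbol  number  mass      r_cov  r_vdw
H       1       1.008     0.31   1.20
He      2       4.0026    0.28   1.40
Li      3       6.94      1.28   1.82
Be      4       9.0122    0.96   1.53
B       5       10.81     0.84   1.92
C       6       12.011    0.76   1.70
N       7       14.007    0.71   1.55
O       8       15.999    0.66   1.52
F       9       18.998    0.57   1.47
Ne      10      20.180    0.58   1.54
Na      11      22.990    1.66   2.27
Mg      12      24.305    1.41   1.73
Al      13      26.982    1.21   1.84
Si      14      28.085    1.11   2.10
P       15      30.974    1.07   1.80
S       16      32.06     1.05   1.80
Cl      17      35.45     1.02   1.75
Ar      18      39.948    1.06   1.88
K       19      39.098    2.03   2.75
Ca      20      40.078    1.76   2.31
Fe      26      55.845    1.32   2.04
Cu      29      63.546    1.32   1.96
Zn      30      65.38     1.22   2.01
Br      35      79.904    1.20   1.85
I       53      126.90    1.39   1.98
")
  rownames(tab) <- tab$symbol
  tab
})

normalize_element <- function(sym) {
  s <- paste0(toupper(substr(sym, 1, 1)), tolower(substr(sym, 2, nchar(sym))))
  s
}

element_known <- function(sym) normalize_element(sym) %in% rownames(.element_table)

element_field <- function(sym, field) {
  s <- normalize_element(sym)
  bad <- !(s %in% rownames(.element_table))
  if (any(bad)) {
    stop("unknown element symbol(s): ", paste(unique(sym[bad]), collapse = ", "),
         call. = FALSE)
  }
  .element_table[s, field]
}

#' Covalent radii (Angstrom) for element symbols
#' @param symbols character vector of element symbols
#' @return numeric vector of covalent radii in Angstrom
#' @export
covalent_radius <- function(symbols) element_field(symbols, "r_cov")

#' van der Waals radii (Angstrom) for element symbols
#' @param symbols character vector of element symbols
#' @return numeric vector of vdW radii in Angstrom
#' @export
vdw_radius <- function(symbols) element_field(symbols, "r_vdw")

#' Atomic masses (amu) for element symbols
#' @param symbols character vector of element symbols
#' @return numeric vector of masses in amu
#' @export
atomic_mass <- function(symbols) element_field(symbols, "mass")

# Physical constants, internal units: Angstrom, kJ/mol, radian, e
.kB <- 0.008314462618     # kJ/mol/K
.coulomb_ke <- 1389.35458 # kJ mol^-1 Angstrom e^-2
.hartree_kjmol <- 2625.4996394799
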