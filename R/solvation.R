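#' Solvent specifications
#'
#' Shipped templates: SPC/E and TIP3P three-site water (rigid geometries and
#' point charges). Any other solvent is supplied as a user `molecule` template
#' with a target density and molar mass.
#'
#' @param name `"spce"` or `"tip3p"`, or a custom label when `template` given
#' @param template optional `molecule` used as the solvent
#' @param density target density, g/cm^3
#' @param mass molar mass, g/mol (derived from the template when omitted)
#' @param charges per-atom charges of the template
#' @return object of class `solvent_spec`
#' @export
solvent_spec <- function(name = "spce", template = NULL, density = NULL,
                         mass = NULL, charges = NULL) {
  if (is.null(template)) {
    name <- tolower(name)
    water <- water_template(name)
    template <- water$mol; charges <- water$charges
    if (is.null(density)) density <- 0.997
  }
  if (is.null(density) || density <= 0) stop("density must be positive")
  if (!n_atoms(template)) stop("solvent template must have at least one atom")
  if (is.null(mass)) mass <- sum(atomic_mass(template$elements))
  if (is.null(charges)) charges <- rep(0, n_atoms(template))
  structure(list(name = name, template = template, density = density,
                 mass = mass, charges = rep_len(charges, n_atoms(template))),
            class = "solvent_spec")
}

water_template <- function(name) {
  geom <- switch(name,
    spce = list(r_oh = 1.0, ang = 109.47, q = c(-0.8476, 0.4238, 0.4238)),
    tip3p = list(r_oh = 0.9572, ang = 104.52, q = c(-0.834, 0.417, 0.417)),
    stop("unknown water model '", name, "'; shipped models: spce, tip3p"))
  a <- geom$ang * pi / 180
  coords <- rbind(c(0, 0, 0),
                  c(geom$r_oh, 0, 0),
                  c(geom$r_oh * cos(a), geom$r_oh * sin(a), 0))
  list(mol = molecule(c("O", "H", "H"), coords, comment = name),
       charges = geom$q)
}

# ---- spatial index: uniform cell list ---------------------------------------
# Cells of edge >= cutoff; only the 27 neighboring cells need checking, so
# decisions are identical to the brute-force all-pairs scan.
cell_index <- function(cutoff, box) {
  ncell <- max(1L, floor(box / cutoff))
  edge <- box / ncell
  list(cutoff = cutoff, box = box, ncell = ncell, edge = edge,
       cells = new.env(parent = emptyenv()), points = NULL)
}

cell_key <- function(idx, p) {
  c3 <- pmin(pmax(floor(p / idx$edge), 0), idx$ncell - 1)
  paste(c3[1], c3[2], c3[3], sep = ",")
}

cell_insert <- function(idx, pts) {
  start <- NROW(idx$points)
  idx$points <- rbind(idx$points, pts)
  for (r in seq_len(NROW(pts))) {
    key <- cell_key(idx, pts[r, ])
    idx$cells[[key]] <- c(idx$cells[[key]], start + r)
  }
  idx
}

# TRUE iff any stored point lies within cutoff of any row of pts
cell_any_within <- function(idx, pts) {
  if (!NROW(idx$points)) return(FALSE)
  for (r in seq_len(NROW(pts))) {
    p <- pts[r, ]
    c3 <- pmin(pmax(floor(p / idx$edge), 0), idx$ncell - 1)
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      cc <- c3 + c(dx, dy, dz)
      if (any(cc < 0) || any(cc >= idx$ncell)) next
      ids <- idx$cells[[paste(cc[1], cc[2], cc[3], sep = ",")]]
      if (is.null(ids)) next
      q <- idx$points[ids, , drop = FALSE]
      d2 <- (q[, 1] - p[1])^2 + (q[, 2] - p[2])^2 + (q[, 3] - p[3])^2
      if (any(d2 < idx$cutoff^2)) return(TRUE)
    }
  }
  FALSE
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
         else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

#' Solvate a solute in a cubic box by random batch insertion
#'
#' The solute is centered in a cubic box of edge
#' `max axis-aligned solute extent + 2 x padding`. Solvent templates are then
#' inserted at random positions/orientations in batches, accepting a candidate
#' only when no atom falls within `cutoff` of any already-placed atom
#' (cell-list spatial index, decisions identical to the brute-force scan).
#' The target count is `floor(density * (L^3 - V_solute) / mass)` with the
#' solute volume from summed vdW spheres.
#'
#' @param solute a `molecule`
#' @param solvent a [solvent_spec()]
#' @param padding_nm box padding around the solute, nm (default 1.0)
#' @param seed RNG seed for reproducible packing
#' @param cutoff minimum allowed cross-molecule atom distance, Angstrom
#' @param max_attempts insertion attempt cap (default `200 * N_target`)
#' @param neutralize add counterions to cancel the solute formal charge
#' @return object of class `solvated_system`
#' @export
solvate <- function(solute, solvent = solvent_spec("spce"), padding_nm = 1.0,
                    seed = NULL, cutoff = 1.8, max_attempts = NULL,
                    neutralize = TRUE) {
  stopifnot(padding_nm > 0)
  centered <- sweep(solute$coordinates, 2,
                    (apply(solute$coordinates, 2, max) +
                       apply(solute$coordinates, 2, min)) / 2)
  extent <- max(apply(centered, 2, function(v) diff(range(v))))
  L <- extent + 2 * padding_nm * 10
  solute$coordinates <- sweep(centered, 2, rep(L / 2, 3), `+`)
  v_solute <- sum(4 / 3 * pi * vdw_radius(solute$elements)^3)
  n_target <- floor(solvent$density * 0.6022140762 / solvent$mass *
                      (L^3 - v_solute))
  with_seed(seed, {
    sys <- insert_batch(solute, solvent, L, n_target, cutoff, max_attempts,
                        extent = extent, padding_nm = padding_nm)
    if (neutralize && solute$charge != 0) neutralize(sys) else sys
  })
}

insert_batch <- function(solute, solvent, L, n_target, cutoff, max_attempts,
                         extent, padding_nm, exact = FALSE) {
  idx <- cell_index(cutoff, L)
  if (n_atoms(solute)) idx <- cell_insert(idx, solute$coordinates)
  tmpl <- sweep(solvent$template$coordinates, 2,
                colMeans(solvent$template$coordinates))
  if (is.null(max_attempts)) max_attempts <- max(200 * n_target, 20000L)
  placed <- list()
  attempts <- 0L
  while (length(placed) < n_target && attempts < max_attempts) {
    attempts <- attempts + 1L
    cand <- tmpl %*% t(random_rotation())
    cand <- sweep(cand, 2, stats::runif(3, 0, L), `+`)
    if (any(cand < 0) || any(cand > L)) next
    if (cell_any_within(idx, cand)) next
    placed[[length(placed) + 1L]] <- cand
    idx <- cell_insert(idx, cand)
  }
  achieved <- length(placed) * solvent$mass /
    (0.6022140762 * max(L^3 - sum(4 / 3 * pi * vdw_radius(solute$elements)^3),
                        1e-9))
  if (exact && length(placed) < n_target) {
    stop("could not place requested solvent count: achieved ", length(placed),
         " of ", n_target, " after ", attempts, " attempts")
  }
  if (!exact && n_target > 0 && length(placed) < 0.9 * n_target) {
    stop(sprintf(paste0("random insertion reached only %d of %d target solvent",
                        " molecules (%.1f%% of target density) after %d attempts"),
                 length(placed), n_target,
                 100 * length(placed) / n_target, attempts))
  }
  structure(list(solute = solute, solvent = solvent,
                 solvent_positions = placed,
                 ions = data.frame(species = character(0), charge = integer(0),
                                   x = numeric(0), y = numeric(0),
                                   z = numeric(0)),
                 box = L, cutoff = cutoff,
                 extent = extent, padding_nm = padding_nm,
                 n_target = n_target,
                 achieved_density = achieved),
            class = "solvated_system")
}

#' @export
print.solvated_system <- function(x, ...) {
  cat(sprintf(paste0("solvated system: %d solute atoms + %d x %s + %d ion(s), ",
                     "box %.2f A, density %.3f g/cm3\n"),
              n_atoms(x$solute), length(x$solvent_positions), x$solvent$name,
              nrow(x$ions), x$box, x$achieved_density))
  invisible(x)
}

#' Solvate with explicit component counts
#'
#' Inserts exactly the requested number of each component molecule with the
#' same overlap rules as [solvate()].
#'
#' @inheritParams solvate
#' @param components list of `list(molecule, count)` pairs (or a single
#'   `solvent_spec` with a `count`)
#' @return a `solvated_system`; its `solvent_positions` carry an attribute
#'   `component` giving each replica's component index
#' @export
custom_solvate <- function(solute, components, padding_nm = 1.0, seed = NULL,
                           cutoff = 1.8, max_attempts = NULL) {
  stopifnot(padding_nm > 0)
  centered <- sweep(solute$coordinates, 2,
                    (apply(solute$coordinates, 2, max) +
                       apply(solute$coordinates, 2, min)) / 2)
  extent <- max(apply(centered, 2, function(v) diff(range(v))))
  L <- extent + 2 * padding_nm * 10
  solute$coordinates <- sweep(centered, 2, rep(L / 2, 3), `+`)
  with_seed(seed, {
    idx <- cell_index(cutoff, L)
    if (n_atoms(solute)) idx <- cell_insert(idx, solute$coordinates)
    placed <- list(); comp_of <- integer(0)
    for (ci in seq_along(components)) {
      comp <- components[[ci]]
      tmpl_mol <- comp$molecule; count <- comp$count
      stopifnot(count >= 0)
      tmpl <- sweep(tmpl_mol$coordinates, 2, colMeans(tmpl_mol$coordinates))
      attempts <- 0L; done <- 0L
      cap <- if (is.null(max_attempts)) max(200 * count, 20000L) else max_attempts
      while (done < count && attempts < cap) {
        attempts <- attempts + 1L
        cand <- tmpl %*% t(random_rotation())
        cand <- sweep(cand, 2, stats::runif(3, 0, L), `+`)
        if (any(cand < 0) || any(cand > L)) next
        if (cell_any_within(idx, cand)) next
        placed[[length(placed) + 1L]] <- cand
        comp_of <- c(comp_of, ci)
        idx <- cell_insert(idx, cand)
        done <- done + 1L
      }
      if (done < count) {
        stop("custom_solvate: component ", ci, " placed ", done, " of ", count,
             " requested molecules")
      }
    }
    attr(placed, "component") <- comp_of
    structure(list(solute = solute,
                   solvent = list(name = "custom", template = NULL,
                                  components = components),
                   solvent_positions = placed,
                   ions = data.frame(species = character(0),
                                     charge = integer(0), x = numeric(0),
                                     y = numeric(0), z = numeric(0)),
                   box = L, cutoff = cutoff, extent = extent,
                   padding_nm = padding_nm, n_target = NA_integer_,
                   achieved_density = NA_real_),
              class = "solvated_system")
  })
}

#' Neutralize a solvated system with counterions
#'
#' A solute charge of q < 0 adds |q| Na+; q > 0 adds q Cl-. Ions are placed at
#' random overlap-checked positions inside the box.
#'
#' @param system a `solvated_system`
#' @param solute_charge integer charge to cancel (default: the solute's)
#' @param seed RNG seed
#' @return the system with ions added and net charge 0
#' @export
neutralize <- function(system, solute_charge = system$solute$charge,
                       seed = NULL) {
  q <- as.integer(solute_charge)
  if (q == 0L) return(system)
  species <- if (q < 0) "Na" else "Cl"
  ion_charge <- if (q < 0) 1L else -1L
  n_ions <- abs(q)
  with_seed(seed, {
    idx <- cell_index(system$cutoff, system$box)
    idx <- cell_insert(idx, system$solute$coordinates)
    for (p in system$solvent_positions) idx <- cell_insert(idx, p)
    if (nrow(system$ions)) {
      idx <- cell_insert(idx, as.matrix(system$ions[, c("x", "y", "z")]))
    }
    placed <- 0L; attempts <- 0L
    while (placed < n_ions && attempts < 20000L) {
      attempts <- attempts + 1L
      p <- matrix(stats::runif(3, 0, system$box), 1, 3)
      if (cell_any_within(idx, p)) next
      system$ions <- rbind(system$ions,
                           data.frame(species = species, charge = ion_charge,
                                      x = p[1], y = p[2], z = p[3]))
      idx <- cell_insert(idx, p)
      placed <- placed + 1L
    }
    if (placed < n_ions) stop("no room to place ", n_ions, " counterions")
    system
  })
}

#' Net charge of a solvated system
#' @param system a `solvated_system`
#' @return solute formal charge plus ion charges (solvent models are neutral)
#' @export
system_net_charge <- function(system) {
  system$solute$charge + sum(system$ions$charge)
}

# ---- Galvani correction -----------------------------------------------------

.galvani_registry <- list(spce = -57.7)  # kJ/mol per unit charge

#' Galvani-potential correction for ionic solvation free energies
#'
#' Transferring an ion across the vacuum-liquid interface picks up the water
#' model's Galvani surface potential; computed solvation free energies of
#' species with formal charge q are corrected by `-q * phi_G`. For SPC/E
#' water `phi_G = -57.7` kJ/mol per unit charge.
#'
#' @param dG uncorrected solvation free energy, kJ/mol
#' @param q formal charge, e
#' @param water_model registry key (currently `"spce"`)
#' @return corrected free energy, kJ/mol
#' @export
galvani_correct <- function(dG, q, water_model = "spce") {
  key <- tolower(water_model)
  if (!key %in% names(.galvani_registry)) {
    stop("no Galvani potential registered for '", water_model,
         "'; registry: ", paste(names(.galvani_registry), collapse = ", "))
  }
  dG + (-q * .galvani_registry[[key]])
}

#' Galvani surface potential of a registered water model
#' @param water_model registry key
#' @return phi_G in kJ/mol per unit charge
#' @export
galvani_potential <- function(water_model = "spce") {
  key <- tolower(water_model)
  if (!key %in% names(.galvani_registry)) {
    stop("no Galvani potential registered for '", water_model,
         "'; registry: ", paste(names(.galvani_registry), collapse = ", "))
  }
  .galvani_registry[[key]]
}

# ---- writers ----------------------------------------------------------------

# flattened atom table of a system: element, resname, resid, x, y, z (Angstrom)
system_atom_table <- function(system) {
  rows <- data.frame(element = system$solute$elements, resname = "MOL",
                     resid = 1L,
                     x = system$solute$coordinates[, 1],
                     y = system$solute$coordinates[, 2],
                     z = system$solute$coordinates[, 3])
  resid <- 1L
  comp_of <- attr(system$solvent_positions, "component")
  for (i in seq_along(system$solvent_positions)) {
    resid <- resid + 1L
    pos <- system$solvent_positions[[i]]
    els <- if (!is.null(comp_of)) {
      system$solvent$components[[comp_of[i]]]$molecule$elements
    } else system$solvent$template$elements
    rows <- rbind(rows, data.frame(element = els, resname = "SOL",
                                   resid = resid, x = pos[, 1], y = pos[, 2],
                                   z = pos[, 3]))
  }
  if (nrow(system$ions)) for (i in seq_len(nrow(system$ions))) {
    resid <- resid + 1L
    rows <- rbind(rows, data.frame(element = system$ions$species[i],
                                   resname = toupper(system$ions$species[i]),
                                   resid = resid, x = system$ions$x[i],
                                   y = system$ions$y[i], z = system$ions$z[i]))
  }
  rows
}

#' Write a solvated system to disk
#'
#' Formats: `gro` (nm), `pdb` (Angstrom) or `top` (GROMACS molecule-count
#' topology skeleton). Residues are numbered contiguously
#' solute -> solvent -> ions.
#'
#' @param system a `solvated_system`
#' @param path output path
#' @param format `"gro"`, `"pdb"` or `"top"` (default from the file extension)
#' @return `path`, invisibly
#' @export
write_system <- function(system, path,
                         format = tools::file_ext(path)) {
  format <- tolower(format)
  tab <- system_atom_table(system)
  if (format == "gro") {
    lines <- c("solvated system", sprintf("%5d", nrow(tab)))
    for (i in seq_len(nrow(tab))) {
      lines <- c(lines, sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                                tab$resid[i] %% 100000L, tab$resname[i],
                                tab$element[i], i %% 100000L,
                                tab$x[i] / 10, tab$y[i] / 10, tab$z[i] / 10))
    }
    lines <- c(lines, sprintf("%10.5f%10.5f%10.5f", system$box / 10,
                              system$box / 10, system$box / 10))
  } else if (format == "pdb") {
    lines <- sprintf("CRYST1%9.3f%9.3f%9.3f  90.00  90.00  90.00 P 1           1",
                     system$box, system$box, system$box)
    for (i in seq_len(nrow(tab))) {
      lines <- c(lines, sprintf(
        "%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        "ATOM", i %% 100000L, tab$element[i], "", tab$resname[i], "A",
        tab$resid[i] %% 10000L, "", tab$x[i], tab$y[i], tab$z[i], 1, 0,
        toupper(tab$element[i])))
    }
    lines <- c(lines, "END")
  } else if (format == "top") {
    counts <- c(MOL = 1L)
    if (length(system$solvent_positions)) {
      counts <- c(counts, SOL = length(system$solvent_positions))
    }
    if (nrow(system$ions)) {
      for (sp in unique(system$ions$species)) {
        counts[toupper(sp)] <- sum(system$ions$species == sp)
      }
    }
    lines <- c("[ system ]", "solvated system", "", "[ molecules ]",
               sprintf("%-8s %d", names(counts), counts))
  } else {
    stop("unknown format '", format, "' (gro, pdb or top)")
  }
  writeLines(lines, path)
  invisible(path)
}

# internal reader for round-trip checks on the gro writer
read_gro <- function(path) {
  lines <- readLines(path, warn = FALSE)
  n <- as.integer(trimws(lines[2]))
  coords <- matrix(NA_real_, n, 3)
  elements <- character(n)
  for (i in seq_len(n)) {
    ln <- lines[2 + i]
    elements[i] <- trimws(substr(ln, 11, 15))
    coords[i, ] <- as.numeric(c(substr(ln, 21, 28), substr(ln, 29, 36),
                                substr(ln, 37, 44))) * 10
  }
  box <- as.numeric(strsplit(trimws(lines[3 + n]), "\\s+")[[1]])[1] * 10
  list(elements = elements, coordinates = coords, box = box)
}
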