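#' Construct a molecule object
#'
#' A `molecule` is the substrate of every descriptor in the package: an
#' ordered set of atoms with 3D coordinates (Angstrom) and a bond graph.
#' Hydrogens are kept as supplied; most 3D descriptors are conventionally
#' computed on hydrogen-included structures.
#'
#' @param id character identifier.
#' @param elements character vector of chemical symbols, one per atom.
#' @param coords numeric n x 3 matrix of coordinates in Angstrom.
#' @param bonds integer matrix with columns `i`, `j`, `order`; each bonded
#'   pair stored once, 1-based indices. May have zero rows.
#' @param formal_charges integer vector of per-atom formal charges
#'   (default all zero).
#' @param flags optional character vector of quality flags (e.g. `"2d_only"`).
#' @return An object of class `molecule` with components `id`, `elements`,
#'   `atomic_numbers`, `coords`, `bonds`, `formal_charges`, `flags`.
#' @examples
#' m <- molecule("diatomic", c("C", "O"),
#'               rbind(c(0, 0, 0), c(1.13, 0, 0)),
#'               bonds = cbind(i = 1L, j = 2L, order = 3L))
#' n_atoms(m)
#' @export
molecule <- function(id, elements, coords, bonds = NULL,
                     formal_charges = NULL, flags = character()) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L)
    stop("coords must be an n x 3 matrix")
  n <- nrow(coords)
  if (length(elements) != n)
    stop("length(elements) must equal nrow(coords)")
  if (!all(is.finite(coords)))
    stop("molecule '", id, "': non-finite coordinates")
  tab <- atom_property_table()
  unknown <- setdiff(unique(elements), tab$element)
  if (length(unknown))
    stop("element(s) not in the atomic property table: ",
         paste(unknown, collapse = ", "))
  if (is.null(bonds)) {
    bonds <- matrix(integer(), ncol = 3L,
                    dimnames = list(NULL, c("i", "j", "order")))
  } else {
    bonds <- as.matrix(bonds)
    if (ncol(bonds) == 2L) bonds <- cbind(bonds, 1L)
    colnames(bonds) <- c("i", "j", "order")
    storage.mode(bonds) <- "integer"
    if (nrow(bonds)) {
      if (any(bonds[, 1:2] < 1L) || any(bonds[, 1:2] > n))
        stop("bond atom index out of range")
      if (any(bonds[, 1L] == bonds[, 2L]))
        stop("self-bond not allowed")
      key <- paste(pmin(bonds[, 1L], bonds[, 2L]),
                   pmax(bonds[, 1L], bonds[, 2L]))
      if (anyDuplicated(key))
        stop("duplicate bond (each pair must be stored once)")
    }
  }
  if (is.null(formal_charges)) formal_charges <- integer(n)
  zs <- tab$atomic_number[match(elements, tab$element)]
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  structure(
    list(id = as.character(id), elements = as.character(elements),
         atomic_numbers = as.integer(zs), coords = coords, bonds = bonds,
         formal_charges = as.integer(formal_charges),
         flags = as.character(flags)),
    class = "molecule")
}

#' @export
print.molecule <- function(x, ...) {
  cat("<molecule>", x$id, ":", n_atoms(x), "atoms,", nrow(x$bonds), "bonds\n")
  cat("  formula:", paste0(names(table(x$elements)), table(x$elements),
                           collapse = " "), "\n")
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Number of atoms in a molecule
#' @param mol a [molecule].
#' @return integer atom count.
#' @export
n_atoms <- function(mol) nrow(mol$coords)

.tyroqsar_cache <- new.env(parent = emptyenv())

#' Atomic property table
#'
#' Per-element atomic mass (u), Sanderson electronegativity (dimensionless),
#' polarizability (A^3) and van der Waals volume (A^3), used as weighting
#' schemes for the weighted descriptors. Shipped as a plain-text CSV under
#' `inst/extdata` so descriptor values are reproducible.
#'
#' @return data.frame with columns `element`, `atomic_number`, `mass`,
#'   `sanderson_en`, `polarizability`, `vdw_volume`.
#' @export
atom_property_table <- function() {
  if (is.null(.tyroqsar_cache$props)) {
    path <- system.file("extdata", "atom_properties.csv", package = "tyroqsar")
    if (path == "") # during in-source development
      path <- file.path("inst", "extdata", "atom_properties.csv")
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    stopifnot("C" %in% tab$element, all(tab$mass > 0),
              all(tab$sanderson_en > 0), all(tab$polarizability > 0),
              all(tab$vdw_volume > 0))
    .tyroqsar_cache$props <- tab
  }
  .tyroqsar_cache$props
}

#' Quantum-chemical record for one molecule
#'
#' Frontier orbital energies and the dipole vector, used for the quantum
#' indices (hardness, softness, electronegativity, electrophilicity) and the
#' `dipx` descriptor. A record with `e_homo > e_lumo` is accepted with a
#' warning (the orbital ordering is unexpected but the printed index
#' formulas still evaluate).
#'
#' @param e_homo highest occupied molecular orbital energy, eV.
#' @param e_lumo lowest unoccupied molecular orbital energy, eV.
#' @param dipole numeric length-3 dipole vector, Debye; the x-component is
#'   the `dipx` descriptor.
#' @return object of class `quantum_record`.
#' @export
quantum_record <- function(e_homo, e_lumo, dipole = c(0, 0, 0)) {
  stopifnot(is.finite(e_homo), is.finite(e_lumo), length(dipole) == 3L)
  if (e_homo > e_lumo)
    warning("e_homo > e_lumo: unexpected orbital ordering")
  structure(list(e_homo = as.numeric(e_homo), e_lumo = as.numeric(e_lumo),
                 dipole = as.numeric(dipole)),
            class = "quantum_record")
}
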