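#' Read molecules from an SDF/MOL V2000 file
#'
#' Parses the fixed-width V2000 connection table: counts line, atom block
#' (coordinates in Angstrom + element symbol), bond block. Atom order and
#' explicit hydrogens are preserved. Records are delimited by `$$$$`; a
#' single MOL file (no delimiter) yields one molecule. Molecules whose
#' z-coordinates are all zero are flagged `"2d_only"` rather than rejected.
#'
#' @param path file path.
#' @return list of [molecule] objects (possibly empty).
#' @export
read_sdf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || all(!nzchar(trimws(lines)))) return(list())
  ends <- grep("^\\$\\$\\$\\$", lines)
  starts <- c(1L, ends + 1L)
  stops <- c(ends - 1L, length(lines))
  keep <- starts <= stops
  records <- Map(function(a, b) lines[a:b], starts[keep], stops[keep])
  records <- Filter(function(r) any(nzchar(trimws(r))), records)
  out <- lapply(seq_along(records), function(k)
    parse_mol_v2000(records[[k]], sprintf("record %d", k)))
  out
}

parse_mol_v2000 <- function(rec, label) {
  if (length(rec) < 4L)
    stop("SDF ", label, ": too short for a V2000 connection table")
  id <- trimws(rec[1L])
  counts <- rec[4L]
  natom <- suppressWarnings(as.integer(substr(counts, 1L, 3L)))
  nbond <- suppressWarnings(as.integer(substr(counts, 4L, 6L)))
  if (is.na(natom) || is.na(nbond) || natom < 0L || nbond < 0L)
    stop("SDF ", label, ": malformed counts line: '", counts, "'")
  if (length(rec) < 4L + natom + nbond)
    stop("SDF ", label, ": truncated atom/bond block")
  atoms <- rec[4L + seq_len(natom)]
  xs <- as.numeric(substr(atoms, 1L, 10L))
  ys <- as.numeric(substr(atoms, 11L, 20L))
  zs <- as.numeric(substr(atoms, 21L, 30L))
  el <- trimws(substr(atoms, 31L, 34L))
  if (anyNA(xs) || anyNA(ys) || anyNA(zs))
    stop("SDF ", label, ": unparseable atom coordinates")
  bonds <- NULL
  if (nbond > 0L) {
    bl <- rec[4L + natom + seq_len(nbond)]
    bi <- suppressWarnings(as.integer(substr(bl, 1L, 3L)))
    bj <- suppressWarnings(as.integer(substr(bl, 4L, 6L)))
    bo <- suppressWarnings(as.integer(substr(bl, 7L, 9L)))
    if (anyNA(bi) || anyNA(bj))
      stop("SDF ", label, ": unparseable bond block")
    if (any(bi < 1L) || any(bj < 1L))
      stop("SDF ", label, ": bond atom index < 1 (V2000 indices are 1-based)")
    bo[is.na(bo) | bo < 1L] <- 1L
    bonds <- cbind(i = bi, j = bj, order = bo)
  }
  flags <- character()
  if (natom > 0L && all(zs == 0)) flags <- "2d_only"
  molecule(if (nzchar(id)) id else label, el, cbind(xs, ys, zs),
           bonds = bonds, flags = flags)
}

#' Write molecules to an SDF V2000 file
#'
#' Inverse of [read_sdf()]: coordinates are written at `%10.4f`, so a
#' read/write round trip reproduces them to four decimals.
#'
#' @param mols a [molecule] or list of molecules.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sdf <- function(mols, path) {
  if (inherits(mols, "molecule")) mols <- list(mols)
  con <- file(path, "w")
  on.exit(close(con))
  for (m in mols) {
    n <- n_atoms(m); nb <- nrow(m$bonds)
    writeLines(c(m$id, "  tyroqsar", ""), con)
    writeLines(sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb), con)
    for (i in seq_len(n))
      writeLines(sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                         m$coords[i, 1L], m$coords[i, 2L], m$coords[i, 3L],
                         m$elements[i]), con)
    for (b in seq_len(nb))
      writeLines(sprintf("%3d%3d%3d  0", m$bonds[b, 1L], m$bonds[b, 2L],
                         m$bonds[b, 3L]), con)
    writeLines(c("M  END", "$$$$"), con)
  }
  invisible(path)
}

#' Read a molecule from an XYZ file
#'
#' Standard XYZ: atom-count line, comment line, then `element x y z` rows
#' (Angstrom; plain or scientific notation). XYZ carries no connectivity, so
#' the bond list is empty; attach bonds with [perceive_bonds()] when
#' topological descriptors are needed.
#'
#' @param path file path.
#' @return a [molecule] with an empty bond list.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) | seq_along(lines) == 2L]
  if (length(lines) < 1L) stop("XYZ: empty file")
  n <- suppressWarnings(as.integer(trimws(lines[1L])))
  if (is.na(n) || n < 0L) stop("XYZ: bad atom-count line")
  rows <- lines[-(1:2)]
  rows <- rows[nzchar(trimws(rows))]
  if (length(rows) != n)
    stop("XYZ: count line says ", n, " atoms but ", length(rows),
         " atom rows found")
  parts <- strsplit(trimws(rows), "\\s+")
  el <- vapply(parts, `[`, "", 1L)
  xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3L)))
  if (anyNA(xyz)) stop("XYZ: unparseable coordinates")
  molecule(sub("\\.[^.]*$", "", basename(path)), el, xyz)
}

#' Perceive bonds from interatomic distances
#'
#' Connects every atom pair closer than `scale` times the sum of their
#' covalent radii — a simple deterministic rule for structures read from
#' XYZ, which carries no bond table. Bond orders are set to 1.
#'
#' @param mol a [molecule].
#' @param scale multiplier on the covalent-radius sum (default 1.15).
#' @return the molecule with a perceived bond list.
#' @export
perceive_bonds <- function(mol, scale = 1.15) {
  rcov <- c(H = 0.31, B = 0.84, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
            Si = 1.11, P = 1.07, S = 1.05, Cl = 1.02, Br = 1.20, I = 1.39)
  miss <- setdiff(unique(mol$elements), names(rcov))
  if (length(miss))
    stop("no covalent radius for element(s): ", paste(miss, collapse = ", "))
  n <- n_atoms(mol)
  d <- geom_distance_matrix(mol)
  rs <- rcov[mol$elements]
  bonds <- NULL
  if (n >= 2L) {
    cut <- outer(rs, rs, `+`) * scale
    hit <- which(d < cut & upper.tri(d), arr.ind = TRUE)
    if (nrow(hit))
      bonds <- cbind(i = hit[, 1L], j = hit[, 2L], order = 1L)
  }
  molecule(mol$id, mol$elements, mol$coords, bonds = bonds,
           formal_charges = mol$formal_charges, flags = mol$flags)
}
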