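#' Parse a canonical descriptor name
#'
#' The name grammar mirrors the naming of the classical descriptor
#' catalogues: `IC1`; `Mor<ss><w>` (3D-MoRSE, 2-digit signal + weight
#' letter); `RDF<rrr><w>` (radius in tenths of an Angstrom);
#' `GATS<lag><w>`; `HATS<lag><w>`; `R<lag><w>0` (maximal R
#' autocorrelation); `G<m><w>` / `E<m><w>` / `L<m><w>` (WHIM component m);
#' `SP<k>` (shape profile); `dipx`; and the quantum indices `eta`, `S`,
#' `chi`, `omega`. Parsing is bijective: `spec$name` always reproduces the
#' input.
#'
#' @param name descriptor name string.
#' @return list with components `name`, `family`, `index`, `weight`.
#' @export
parse_descriptor <- function(name) {
  w_class <- "([umepv])"
  spec <- function(family, index = NA_integer_, weight = NA_character_)
    list(name = name, family = family, index = as.integer(index),
         weight = weight)
  if (grepl("^IC[0-9]+$", name))
    return(spec("IC", sub("^IC", "", name)))
  m <- regmatches(name, regexec(paste0("^Mor([0-9]{2})", w_class, "$"), name))[[1L]]
  if (length(m)) {
    if (as.integer(m[2L]) < 1L || as.integer(m[2L]) > 32L)
      stop("3D-MoRSE signal out of range in '", name, "'")
    return(spec("MoRSE", m[2L], m[3L]))
  }
  m <- regmatches(name, regexec(paste0("^RDF([0-9]{3})", w_class, "$"), name))[[1L]]
  if (length(m)) return(spec("RDF", m[2L], m[3L]))
  m <- regmatches(name, regexec(paste0("^GATS([0-9]+)", w_class, "$"), name))[[1L]]
  if (length(m)) return(spec("GATS", m[2L], m[3L]))
  m <- regmatches(name, regexec(paste0("^HATS([0-9]+)", w_class, "$"), name))[[1L]]
  if (length(m)) return(spec("HATS", m[2L], m[3L]))
  m <- regmatches(name, regexec(paste0("^R([0-9]+)", w_class, "0$"), name))[[1L]]
  if (length(m)) return(spec("Rmax", m[2L], m[3L]))
  m <- regmatches(name, regexec(paste0("^([LGE])([1-3])", w_class, "$"), name))[[1L]]
  if (length(m)) return(spec(paste0("WHIM_", m[2L]), m[3L], m[4L]))
  m <- regmatches(name, regexec("^SP([0-9]+)$", name))[[1L]]
  if (length(m)) return(spec("SP", m[2L]))
  if (name == "dipx") return(spec("dipole"))
  if (name %in% c("eta", "S", "chi", "omega")) return(spec("quantum"))
  stop("unrecognized descriptor name: '", name, "'")
}

#' The published descriptor set
#'
#' The 25 named descriptors that appear across the ten reported stepwise
#' models and the two final equations: Table-style union of IC1, 3D-MoRSE,
#' RDF, WHIM (G/E), GETAWAY (HATS/Rmax), GATS8p, SP20 and dipx.
#'
#' @return character vector of canonical descriptor names.
#' @export
paper_descriptor_set <- function() {
  c("IC1", "RDF135e", "Mor24m", "RDF035u", "E3u", "RDF120m", "Mor15e",
    "G3p", "R7e0", "dipx", "GATS8p", "RDF065m", "SP20", "Mor28e", "Mor09e",
    "G2u", "Mor27u", "RDF115m", "RDF115e", "HATS3p", "G3m", "Mor26m",
    "Mor32e", "RDF035v", "RDF135m")
}

compute_descriptor <- function(mol, spec, quantum = NULL, rdf_B = 100) {
  if (is.character(spec)) spec <- parse_descriptor(spec)
  fam <- spec$family
  if (fam %in% c("dipole", "quantum")) {
    if (is.null(quantum))
      stop("descriptor '", spec$name, "' needs a quantum record for molecule '",
           mol$id, "'")
    if (fam == "dipole") return(quantum$dipole[1L])
    return(unname(quantum_indices(quantum)[spec$name]))
  }
  switch(fam,
    IC = if (spec$index == 1L) ic1(mol) else
      stop("only first-order information content (IC1) is implemented"),
    MoRSE = morse_signal(mol, spec$index, spec$weight),
    RDF = rdf_value(mol, spec$index / 10, spec$weight, B = rdf_B),
    GATS = gats(mol, spec$index, spec$weight),
    HATS = getaway_autocorr(mol, spec$index, spec$weight, kind = "HATS"),
    Rmax = getaway_autocorr(mol, spec$index, spec$weight, kind = "Rmax"),
    WHIM_L = unname(whim_set(mol, spec$weight)[paste0("L", spec$index)]),
    WHIM_G = unname(whim_set(mol, spec$weight)[paste0("G", spec$index)]),
    WHIM_E = unname(whim_set(mol, spec$weight)[paste0("E", spec$index)]),
    SP = shape_profile(mol, spec$index),
    stop("unhandled descriptor family: ", fam))
}

#' Build a descriptor matrix for a set of molecules
#'
#' Computes every requested descriptor for every molecule and assembles the
#' descriptor matrix D (rows = molecules in input order, columns = canonical
#' descriptor names) that the preprocessing and model-building steps
#' consume. Undefined values (e.g. a Geary lag with no atom pairs)
#' propagate as `NA` so that near-constant filtering can treat them
#' explicitly rather than as silent zeros.
#'
#' @param mols list of [molecule] objects.
#' @param specs character vector of descriptor names (default: the
#'   [paper_descriptor_set()] preset).
#' @param quantum optional named list of [quantum_record] objects keyed by
#'   molecule id (required when quantum/dipole descriptors are requested).
#' @param rdf_B RDF smoothing parameter, 1/A^2.
#' @return numeric matrix, `rownames` = molecule ids, `colnames` = specs.
#' @export
build_descriptor_table <- function(mols, specs = paper_descriptor_set(),
                                   quantum = NULL, rdf_B = 100) {
  parsed <- lapply(specs, parse_descriptor)
  needs_q <- vapply(parsed, function(s)
    s$family %in% c("dipole", "quantum"), TRUE)
  X <- matrix(NA_real_, nrow = length(mols), ncol = length(specs),
              dimnames = list(vapply(mols, `[[`, "", "id"), specs))
  for (i in seq_along(mols)) {
    q <- NULL
    if (any(needs_q)) {
      q <- quantum[[mols[[i]]$id]]
      if (is.null(q))
        stop("missing quantum record for molecule '", mols[[i]]$id, "'")
    }
    for (j in seq_along(parsed))
      X[i, j] <- compute_descriptor(mols[[i]], parsed[[j]], quantum = q,
                                    rdf_B = rdf_B)
  }
  X
}
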