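#' Topological distance matrix
#'
#' Shortest path length in bonds between every atom pair, by breadth-first
#' search from each atom. Pairs in different connected components are
#' marked `Inf`.
#'
#' @param mol a [molecule] with a non-empty bond graph.
#' @return symmetric numeric matrix; zero diagonal; `Inf` for unreachable
#'   pairs.
#' @export
topo_distance_matrix <- function(mol) {
  n <- n_atoms(mol)
  if (n == 0L) stop("molecule has no atoms")
  adj <- vector("list", n)
  if (nrow(mol$bonds)) {
    for (b in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds[b, 1L]; j <- mol$bonds[b, 2L]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (s in seq_len(n)) {
    frontier <- s
    depth <- 0L
    while (length(frontier)) {
      depth <- depth + 1L
      nxt <- unique(unlist(adj[frontier], use.names = FALSE))
      nxt <- nxt[!is.finite(d[s, nxt])]
      d[s, nxt] <- depth
      frontier <- nxt
    }
  }
  d
}

#' Geometric (Euclidean) distance matrix
#'
#' @param mol a [molecule] with 3D coordinates.
#' @return symmetric numeric matrix of interatomic distances, Angstrom.
#' @export
geom_distance_matrix <- function(mol) {
  as.matrix(stats::dist(mol$coords))
}

#' Carbon-scaled atomic property weights
#'
#' The weighting schemes of the weighted 3D/topological descriptors:
#' `w_i = property(element_i) / property(C)`, so carbon always weighs 1 and
#' the descriptors stay dimensionless. Scheme `"u"` (unweighted) gives all
#' ones.
#'
#' @param mol a [molecule].
#' @param property one of `"u"` (unit), `"m"` (atomic mass), `"e"`
#'   (Sanderson electronegativity), `"p"` (polarizability), `"v"` (van der
#'   Waals volume).
#' @return numeric vector of per-atom weights.
#' @export
carbon_scaled_weights <- function(mol, property = c("u", "m", "e", "p", "v")) {
  property <- match.arg(property)
  n <- n_atoms(mol)
  if (property == "u") return(rep(1, n))
  tab <- atom_property_table()
  col <- switch(property, m = "mass", e = "sanderson_en",
                p = "polarizability", v = "vdw_volume")
  idx <- match(mol$elements, tab$element)
  if (anyNA(idx))
    stop("element(s) without tabulated properties: ",
         paste(unique(mol$elements[is.na(idx)]), collapse = ", "))
  tab[[col]][idx] / tab[[col]][tab$element == "C"]
}
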