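#' First-order neighborhood-symmetry information content (IC1)
#'
#' Atoms are partitioned into equivalence classes by the triple
#' (atomic number, degree, multiset of neighbor (atomic number, bond order)
#' pairs); IC1 is the Shannon entropy of the class-size distribution,
#' `-sum (n_g/n) log2 (n_g/n)`, in bits. It grows with molecular size and
#' branching heterogeneity: 0 for a homonuclear diatomic, `log2 n` when
#' every atom is in a class of its own.
#'
#' @param mol a [molecule] with a bond graph.
#' @return IC1 in bits.
#' @export
ic1 <- function(mol) {
  n <- n_atoms(mol)
  if (n == 0L) stop("atom-free molecule")
  nb <- vector("list", n)
  if (nrow(mol$bonds)) {
    for (b in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds[b, 1L]; j <- mol$bonds[b, 2L]; o <- mol$bonds[b, 3L]
      nb[[i]] <- c(nb[[i]], paste0(mol$atomic_numbers[j], ":", o))
      nb[[j]] <- c(nb[[j]], paste0(mol$atomic_numbers[i], ":", o))
    }
  }
  keys <- vapply(seq_len(n), function(i)
    paste(mol$atomic_numbers[i], length(nb[[i]]),
          paste(sort(nb[[i]]), collapse = ","), sep = "|"), "")
  p <- as.numeric(table(keys)) / n
  -sum(p * log2(p))
}

#' 3D-MoRSE descriptor
#'
#' Simulated electron-diffraction transform of the weighted interatomic
#' distance spectrum: `Mor(s) = sum_{i<j} w_i w_j sin(s r_ij)/(s r_ij)`,
#' with the sinc term equal to 1 at `s = 0`. Signal numbering follows the
#' 32-signal catalogue: signal k uses scattering parameter
#' `s = k - 1` (1/Angstrom), so Mor01 is the plain pair-weight sum and
#' Mor24 uses s = 23.
#'
#' @param mol a [molecule] with 3D coordinates.
#' @param signal integer 1..32.
#' @param weight weighting scheme, see [carbon_scaled_weights()].
#' @return dimensionless descriptor value.
#' @export
morse_signal <- function(mol, signal, weight = "u") {
  stopifnot(signal >= 1, signal <= 32)
  s <- signal - 1
  w <- carbon_scaled_weights(mol, weight)
  r <- geom_distance_matrix(mol)
  n <- n_atoms(mol)
  if (n < 2L) return(0)
  iu <- upper.tri(r)
  sr <- s * r[iu]
  term <- ifelse(sr == 0, 1, sin(sr) / sr)
  ww <- tcrossprod(w)[iu]
  sum(ww * term)
}

#' Radial distribution function descriptor
#'
#' Gaussian-smoothed radial distribution of weighted atom pairs evaluated
#' at radius R: `RDF(R) = sum_{i<j} w_i w_j exp(-B (R - r_ij)^2)`. Canonical
#' names encode the radius in tenths of an Angstrom on the grid
#' 1.0..15.5 step 0.5 (RDF035 = 3.5 A, RDF115 = 11.5 A). The smoothing
#' parameter B is not part of the name; the default 100 (1/A^2) gives a
#' ~0.1 A resolution window.
#'
#' @param mol a [molecule] with 3D coordinates.
#' @param R radius, Angstrom (> 0).
#' @param weight weighting scheme.
#' @param B Gaussian smoothing parameter, 1/A^2.
#' @return dimensionless descriptor value (0 for a single atom).
#' @export
rdf_value <- function(mol, R, weight = "u", B = 100) {
  stopifnot(R > 0, B > 0)
  n <- n_atoms(mol)
  if (n < 2L) return(0)
  w <- carbon_scaled_weights(mol, weight)
  r <- geom_distance_matrix(mol)
  iu <- upper.tri(r)
  sum(tcrossprod(w)[iu] * exp(-B * (R - r[iu])^2))
}

#' Geary autocorrelation at a topological lag (GATS)
#'
#' The Geary spatial autocorrelation coefficient of an atomic property over
#' atom pairs at a fixed topological distance:
#' `c(lag) = [(n-1) sum_{d_ij = lag} (w_i - w_j)^2] / [2 D sum_i (w_i - wbar)^2]`
#' with both sums over ordered pairs and `D` the ordered-pair count at the
#' lag. For i.i.d. random weights its expectation is ~1; values below 1
#' indicate positive spatial association of the property.
#'
#' @param mol a [molecule] with a bond graph.
#' @param lag topological distance (>= 1).
#' @param weight weighting scheme.
#' @return Geary coefficient, or `NA` when no pair sits at the lag or the
#'   weight variance is zero.
#' @export
gats <- function(mol, lag, weight = "m") {
  stopifnot(lag >= 1)
  w <- carbon_scaled_weights(mol, weight)
  n <- n_atoms(mol)
  td <- topo_distance_matrix(mol)
  sel <- which(td == lag, arr.ind = TRUE)           # ordered pairs
  ss <- sum((w - mean(w))^2)
  if (nrow(sel) == 0L || ss == 0) return(NA_real_)
  num <- (n - 1) * sum((w[sel[, 1L]] - w[sel[, 2L]])^2)
  num / (2 * nrow(sel) * ss)
}

#' Molecular influence (hat) leverages
#'
#' Diagonal of the molecular influence matrix `H = M (M'M)^- M'` with `M`
#' the centered n x 3 coordinate matrix (pseudo-inverse for degenerate
#' geometries). Leverages measure how far each atom sits from the molecular
#' centre along the principal axes; they sum to the rank of `M` (3 for a
#' non-planar molecule, 2 for a planar one).
#'
#' @param mol a [molecule] with 3D coordinates.
#' @return numeric vector of per-atom leverages.
#' @export
molecular_influence_leverages <- function(mol) {
  M <- scale(mol$coords, center = TRUE, scale = FALSE)
  if (all(abs(M) < 1e-12))
    stop("degenerate geometry: all atoms coincident")
  sv <- svd(M)
  tol <- max(dim(M)) * max(sv$d) * .Machine$double.eps
  pos <- sv$d > tol
  U <- sv$u[, pos, drop = FALSE]
  rowSums(U^2)
}

#' GETAWAY autocorrelation descriptors (HATS, R, Rmax)
#'
#' Autocorrelations built on the molecular influence leverages `h_i`, taken
#' over unordered atom pairs at a fixed topological lag:
#' * `HATS`: `sum (w_i sqrt(h_i)) (w_j sqrt(h_j))`
#' * `R`:    `sum (sqrt(h_i h_j) / r_ij) w_i w_j`
#' * `Rmax`: the largest single R summand (maximal autocorrelation).
#' An empty pair set (lag beyond the graph diameter) gives 0.
#'
#' @param mol a [molecule] with bonds and 3D coordinates.
#' @param lag topological distance (>= 1).
#' @param weight weighting scheme.
#' @param kind one of `"HATS"`, `"R"`, `"Rmax"`.
#' @return dimensionless descriptor value.
#' @export
getaway_autocorr <- function(mol, lag, weight = "u",
                             kind = c("HATS", "R", "Rmax")) {
  kind <- match.arg(kind)
  stopifnot(lag >= 1)
  h <- molecular_influence_leverages(mol)
  w <- carbon_scaled_weights(mol, weight)
  td <- topo_distance_matrix(mol)
  gd <- geom_distance_matrix(mol)
  sel <- which(td == lag & upper.tri(td), arr.ind = TRUE)
  if (nrow(sel) == 0L) return(0)
  i <- sel[, 1L]; j <- sel[, 2L]
  if (kind == "HATS")
    return(sum(w[i] * sqrt(h[i]) * w[j] * sqrt(h[j])))
  if (any(gd[sel] == 0))
    stop("coincident atoms at topological lag ", lag)
  terms <- sqrt(h[i] * h[j]) / gd[sel] * w[i] * w[j]
  if (kind == "R") sum(terms) else max(terms)
}

#' WHIM descriptors (size, symmetry, accessibility)
#'
#' Weighted holistic invariant molecular descriptors from the
#' eigen-decomposition of the weighted covariance matrix of centered
#' coordinates (weights normalized to sum 1):
#' * `L1..L3`: eigenvalues in decreasing order (directional size);
#' * `G1..G3`: directional symmetry in (0, 1] — 1 when every atom has a
#'   counterpart at the mirrored score `-t` along that axis (within
#'   `sym_tol`), less as the unmatched fraction grows, via
#'   `G = 1/(1 + H)` with `H` the binary entropy of the
#'   matched/unmatched split;
#' * `E1..E3`: directional accessibility `E_m = L_m^2 n / sum_i t_im^4`
#'   (inverse kurtosis of the axis scores).
#'
#' @param mol a [molecule] with at least 3 atoms.
#' @param weight weighting scheme.
#' @param sym_tol symmetry matching tolerance on axis scores, Angstrom.
#' @return named numeric vector `L1..L3, G1..G3, E1..E3`.
#' @export
whim_set <- function(mol, weight = "u", sym_tol = 0.1) {
  n <- n_atoms(mol)
  stopifnot(n >= 3L)
  w <- carbon_scaled_weights(mol, weight)
  w <- w / sum(w)
  ctr <- colSums(mol$coords * w)
  M <- sweep(mol$coords, 2L, ctr)
  if (all(abs(M) < 1e-12)) stop("degenerate geometry: all atoms coincident")
  S <- crossprod(M * sqrt(w))                       # weighted covariance
  eig <- eigen(S, symmetric = TRUE)
  L <- pmax(eig$values, 0)
  Tm <- M %*% eig$vectors                           # axis scores t_im
  E <- vapply(1:3, function(m) {
    s4 <- sum(Tm[, m]^4)
    if (s4 == 0) 0 else (L[m]^2 * n) / s4
  }, 0)
  G <- vapply(1:3, function(m) {
    t <- Tm[, m]
    matched <- logical(n)
    # canonical matching: visit atoms by decreasing |score| and pair each
    # with its best mirror candidate, so the result does not depend on
    # atom input order or on eigenvector sign
    for (i in order(-abs(t))) {
      if (matched[i]) next
      if (abs(t[i]) <= sym_tol / 2) { matched[i] <- TRUE; next }
      cand <- which(!matched & seq_len(n) != i)
      if (length(cand)) {
        gap <- abs(t[cand] + t[i])
        j <- cand[which.min(gap)]
        if (min(gap) <= sym_tol) matched[c(i, j)] <- TRUE
      }
    }
    ns <- sum(matched); na_ <- n - ns
    H <- 0
    if (ns > 0 && na_ > 0)
      H <- -(ns / n) * log2(ns / n) - (na_ / n) * log2(na_ / n)
    1 / (1 + H)
  }, 0)
  stats::setNames(c(L, G, E),
                  c("L1", "L2", "L3", "G1", "G2", "G3", "E1", "E2", "E3"))
}

#' Shape profile descriptor
#'
#' k-th moment of the interatomic distance distribution scaled by k!:
#' `SP_k = [ (2/(n(n-1))) sum_{i<j} r_ij^k ] / k!`. High-order profiles
#' (e.g. SP20) are dominated by the largest interatomic distances and so
#' characterize molecular elongation.
#'
#' @param mol a [molecule] with 3D coordinates.
#' @param k moment order (>= 1).
#' @return dimensionless value (0 for a single atom).
#' @export
shape_profile <- function(mol, k) {
  stopifnot(k >= 1)
  n <- n_atoms(mol)
  if (n < 2L) return(0)
  r <- geom_distance_matrix(mol)[upper.tri(diag(n))]
  mean(r^k) / factorial(k)
}

#' Quantum-chemical reactivity indices
#'
#' Hardness, softness, electronegativity and electrophilicity from the
#' frontier orbital energies. The default `convention = "as_printed"`
#' follows the source formulas exactly:
#' `eta = 0.5 (E_HOMO + E_LUMO)`, `S = 1/eta`,
#' `chi = 0.5 (E_HOMO - E_LUMO)`, `omega = chi^2 / (2 eta)`.
#' `convention = "textbook"` uses the usual conceptual-DFT definitions
#' `eta = 0.5 (E_LUMO - E_HOMO)`, `chi = -0.5 (E_HOMO + E_LUMO)`.
#' `S` and `omega` are `NA` when `eta = 0`.
#'
#' @param q a [quantum_record].
#' @param convention `"as_printed"` or `"textbook"`.
#' @return named numeric vector `eta, S, chi, omega` (eV-derived units).
#' @export
quantum_indices <- function(q, convention = c("as_printed", "textbook")) {
  convention <- match.arg(convention)
  if (convention == "as_printed") {
    eta <- 0.5 * (q$e_homo + q$e_lumo)
    chi <- 0.5 * (q$e_homo - q$e_lumo)
  } else {
    eta <- 0.5 * (q$e_lumo - q$e_homo)
    chi <- -0.5 * (q$e_homo + q$e_lumo)
  }
  if (eta == 0) {
    S <- NA_real_; omega <- NA_real_
  } else {
    S <- 1 / eta
    omega <- chi^2 / (2 * eta)
  }
  c(eta = eta, S = S, chi = chi, omega = omega)
}
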