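# Small molecules built in code, plus independent brute-force oracles.
# The oracles deliberately re-derive every quantity with naive double loops
# so they share no code path with the package internals.

mol_pair <- function(d = 1.5, elements = c("C", "C")) {
  molecule("pair", elements, rbind(c(0, 0, 0), c(d, 0, 0)),
           bonds = cbind(1L, 2L, 1L))
}

mol_path4 <- function() {
  molecule("path4", c("C", "C", "C", "C"),
           cbind(seq(0, 4.5, by = 1.5), 0, 0),
           bonds = cbind(i = 1:3, j = 2:4, order = 1L))
}

mol_methane_star <- function() {
  molecule("methane", c("C", "H", "H", "H", "H"),
           rbind(c(0, 0, 0), c(1.09, 0, 0), c(-1.09, 0, 0),
                 c(0, 1.09, 0), c(0, -1.09, 0)),
           bonds = cbind(i = 1L, j = 2:5, order = 1L))
}

# random rigid rotation + translation of a molecule's coordinates
transform_molecule <- function(mol, seed = 1) {
  set.seed(seed)
  M <- matrix(rnorm(9), 3)
  Q <- qr.Q(qr(M))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  shift <- runif(3, -10, 10)
  molecule(mol$id, mol$elements,
           sweep(mol$coords %*% Q, 2, -shift), bonds = mol$bonds)
}

permute_molecule <- function(mol, perm) {
  inv <- order(perm)
  b <- mol$bonds
  if (nrow(b)) {
    b[, 1L] <- inv[b[, 1L]]
    b[, 2L] <- inv[b[, 2L]]
    sw <- b[, 1L] > b[, 2L]
    tmp <- b[sw, 1L]; b[sw, 1L] <- b[sw, 2L]; b[sw, 2L] <- tmp
  }
  molecule(mol$id, mol$elements[perm], mol$coords[perm, , drop = FALSE], b)
}

# breadth-first shortest path lengths, written independently of the package
bfs_oracle <- function(n, bonds) {
  adj <- lapply(seq_len(n), function(i)
    c(bonds[bonds[, 1] == i, 2], bonds[bonds[, 2] == i, 1]))
  out <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n); dist[s] <- 0
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (u in adj[[v]]) if (dist[u] > dist[v] + 1) {
        dist[u] <- dist[v] + 1
        queue <- c(queue, u)
      }
    }
    out[s, ] <- dist
  }
  out
}

# naive double-loop descriptor oracles
bf_morse <- function(coords, w, s) {
  n <- nrow(coords); acc <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    r <- sqrt(sum((coords[i, ] - coords[j, ])^2))
    acc <- acc + w[i] * w[j] * (if (s * r == 0) 1 else sin(s * r) / (s * r))
  }
  acc
}

bf_rdf <- function(coords, w, R, B) {
  n <- nrow(coords); acc <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    r <- sqrt(sum((coords[i, ] - coords[j, ])^2))
    acc <- acc + w[i] * w[j] * exp(-B * (R - r)^2)
  }
  acc
}

bf_gats <- function(td, w, lag) {
  n <- length(w)
  num <- 0; cnt <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && td[i, j] == lag) {
      num <- num + (w[i] - w[j])^2
      cnt <- cnt + 1
    }
  }
  ss <- sum((w - mean(w))^2)
  if (cnt == 0 || ss == 0) return(NA_real_)
  (n - 1) * num / (2 * cnt * ss)
}

bf_hats <- function(td, h, w, lag) {
  n <- length(w); acc <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (td[i, j] == lag)
      acc <- acc + (w[i] * sqrt(h[i])) * (w[j] * sqrt(h[j]))
  acc
}

bf_r_autocorr <- function(td, gd, h, w, lag, max_only = FALSE) {
  n <- length(w); terms <- numeric()
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (td[i, j] == lag)
      terms <- c(terms, sqrt(h[i] * h[j]) / gd[i, j] * w[i] * w[j])
  if (!length(terms)) return(0)
  if (max_only) max(terms) else sum(terms)
}

# normal-equations OLS oracle
ne_ols <- function(X, y) {
  Xd <- cbind(1, X)
  solve(t(Xd) %*% Xd, t(Xd) %*% y)[, 1]
}
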