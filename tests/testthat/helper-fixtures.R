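# Shared fixtures and independent oracles used across the suite.

# relaxation record with negligible uncertainties, built from the forward
# model (the generator is the independent side of round-trip checks)
exact_relaxation_record <- function(S2, tau_c, tau_e = 50e-12, Rex = 0,
                                    ctx = spectrometer_context()) {
  r <- modelfree_rates(S2, tau_c, tau_e, Rex, ctx)
  rec <- data.frame(residue_index = seq_along(S2),
                    R1 = r$R1, sigma_R1 = 0, R2 = r$R2, sigma_R2 = 0,
                    noe = r$noe, sigma_noe = 0)
  attr(rec, "context") <- ctx
  class(rec) <- c("relaxation_record", "data.frame")
  rec
}

# quaternion-based (Theobald) fitted RMSD: an implementation independent of
# the svd/Kabsch route used by the package
qcp_rmsd <- function(p, q) {
  p <- scale(p, scale = FALSE); q <- scale(q, scale = FALSE)
  s <- t(p) %*% q
  k <- matrix(c(
    s[1,1]+s[2,2]+s[3,3], s[2,3]-s[3,2], s[3,1]-s[1,3], s[1,2]-s[2,1],
    s[2,3]-s[3,2], s[1,1]-s[2,2]-s[3,3], s[1,2]+s[2,1], s[3,1]+s[1,3],
    s[3,1]-s[1,3], s[1,2]+s[2,1], -s[1,1]+s[2,2]-s[3,3], s[2,3]+s[3,2],
    s[1,2]-s[2,1], s[3,1]+s[1,3], s[2,3]+s[3,2], -s[1,1]-s[2,2]+s[3,3]),
    4, 4, byrow = TRUE)
  lambda <- max(eigen(k, symmetric = TRUE, only.values = TRUE)$values)
  sqrt(max(0, (sum(p^2) + sum(q^2) - 2 * lambda) / nrow(p)))
}

# exhaustive neighbour-counting cluster oracle on a distance matrix:
# plain-loop re-derivation kept deliberately naive
oracle_cluster_membership <- function(d, cutoff) {
  n <- nrow(d)
  left <- seq_len(n)
  membership <- integer(n)
  k <- 0L
  while (length(left)) {
    k <- k + 1L
    best <- left[1]; best_n <- -1L
    for (i in left) {
      cnt <- 0L
      for (j in left) if (d[i, j] <= cutoff) cnt <- cnt + 1L
      if (cnt > best_n) { best <- i; best_n <- cnt }
    }
    members <- left[d[best, left] <= cutoff]
    membership[members] <- k
    left <- setdiff(left, members)
  }
  sizes <- tabulate(membership, k)
  ord <- order(-sizes, seq_len(k))
  match(seq_len(k), ord)[membership]
}

# exhaustive 1-D 4-group partition oracle: minimises within-group sum of
# squares over all ordered 3-cut partitions of the sorted values
oracle_partition4 <- function(x) {
  ord <- order(x)
  xs <- x[ord]
  n <- length(xs)
  wss <- function(v) if (length(v) <= 1L) 0 else sum((v - mean(v))^2)
  best <- NULL; best_w <- Inf
  for (a in 1:(n - 3)) for (b in (a + 1):(n - 2)) for (cc in (b + 1):(n - 1)) {
    w <- wss(xs[1:a]) + wss(xs[(a + 1):b]) + wss(xs[(b + 1):cc]) +
      wss(xs[(cc + 1):n])
    if (w < best_w) { best_w <- w; best <- c(a, b, cc) }
  }
  g <- integer(n)
  g[ord] <- findInterval(seq_len(n), best + 1L) + 1L
  g
}

# small random coordinate ensemble (n atoms jittered around a base shape)
random_ensemble <- function(n_snap, n_atoms = 5L, spread = 1.0) {
  base <- matrix(stats::rnorm(n_atoms * 3, sd = 3), n_atoms, 3)
  coords <- array(NA_real_, c(n_atoms, 3, n_snap))
  for (m in seq_len(n_snap))
    coords[, , m] <- base + matrix(stats::rnorm(n_atoms * 3, sd = spread),
                                   n_atoms, 3)
  atoms <- data.frame(chain = "A", residue_index = seq_len(n_atoms),
                      residue_type = "A", atom_name = "CA", element = "C",
                      stringsAsFactors = FALSE)
  ensemble(coords, atoms)
}

# single-snapshot ensemble from explicit coordinates
coords_ensemble <- function(xyz, atoms) {
  ensemble(array(unlist(xyz), c(nrow(xyz), 3, 1)), atoms)
}

# ideal poly-alanine helix ensemble (identical snapshots)
ideal_helix_ensemble <- function(n_res = 12L, n_snap = 1L,
                                 phi = -57, psi = -47) {
  bb <- fuzzynmr:::build_backbone(rep(phi, n_res), rep(psi, n_res),
                                  rep("A", n_res))
  coords <- array(rep(bb$xyz, n_snap), c(nrow(bb$xyz), 3, n_snap))
  ensemble(coords, bb$atoms)
}
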