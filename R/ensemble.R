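# Structural statistics over conformational ensembles: superposition,
# cutoff-based clustering, B-factors, helix assignment, hydrogen bonds,
# inter-chain contacts and NOE-constraint verification.

# Optimal rotation (Kabsch/orthogonal Procrustes) mapping mobile onto fixed.
kabsch_rotation <- function(mobile, fixed) {
  a <- t(mobile) %*% fixed
  s <- svd(a)
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

# RMSD between two coordinate matrices after optional least-squares fit.
pair_rmsd <- function(p, q, fit = TRUE) {
  if (fit) {
    pc <- scale(p, scale = FALSE)
    qc <- scale(q, scale = FALSE)
    q <- qc %*% kabsch_rotation(qc, pc)
    p <- pc
  }
  sqrt(mean(rowSums((p - q)^2)))
}

#' Least-squares superposition of an ensemble
#'
#' Each snapshot is rotated/translated to minimise the RMSD of the selected
#' atoms to the reference (Kabsch algorithm). With `reference = "mean"` the
#' ensemble is first aligned to the first snapshot and then re-aligned to the
#' resulting mean structure.
#'
#' @param ens An `ensemble`.
#' @param selection Atom indices to superpose on (default: all main-chain
#'   N/CA/C/O atoms); at least 3 atoms.
#' @param reference `"mean"`, or a snapshot index.
#' @return The aligned `ensemble`, with per-snapshot RMSD of the selection
#'   in attribute `"rmsd"`.
#' @export
superpose <- function(ens, selection = NULL, reference = "mean") {
  if (is.null(selection))
    selection <- select_atoms(ens, atom_names = c("N", "CA", "C", "O"))
  if (length(selection) < 3L)
    stop("need at least 3 atoms in the superposition selection")
  align_to <- function(ens, ref_xyz) {
    out <- ens
    for (m in seq_len(n_snapshots(ens))) {
      sel_xyz <- ens$coords[selection, , m]
      cm <- colMeans(sel_xyz)
      cr <- colMeans(ref_xyz)
      rot <- kabsch_rotation(sweep(sel_xyz, 2, cm), sweep(ref_xyz, 2, cr))
      out$coords[, , m] <-
        sweep(sweep(ens$coords[, , m], 2, cm) %*% rot, 2, cr, `+`)
    }
    out
  }
  ref_idx <- if (identical(reference, "mean")) 1L else as.integer(reference)
  aligned <- align_to(ens, ens$coords[selection, , ref_idx])
  if (identical(reference, "mean")) {
    mean_xyz <- apply(aligned$coords[selection, , , drop = FALSE], c(1, 2),
                      mean)
    aligned <- align_to(aligned, mean_xyz)
    ref_xyz <- apply(aligned$coords[selection, , , drop = FALSE], c(1, 2),
                     mean)
  } else {
    ref_xyz <- aligned$coords[selection, , ref_idx]
  }
  attr(aligned, "rmsd") <- vapply(seq_len(n_snapshots(aligned)), function(m)
    pair_rmsd(ref_xyz, aligned$coords[selection, , m], fit = FALSE), 0)
  aligned
}

#' Pairwise fitted RMSD matrix over snapshots
#'
#' @param ens An `ensemble`.
#' @param selection Atom indices (default main-chain N/CA/C/O).
#' @return Symmetric matrix of least-squares-fitted RMSDs (Angstrom).
#' @export
rmsd_matrix <- function(ens, selection = NULL) {
  if (is.null(selection))
    selection <- select_atoms(ens, atom_names = c("N", "CA", "C", "O"))
  n <- n_snapshots(ens)
  xyz <- lapply(seq_len(n), function(m)
    scale(ens$coords[selection, , m], scale = FALSE))
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- pair_rmsd(xyz[[i]], xyz[[j]], fit = TRUE)
    }
  }
  d
}

#' Cutoff-based (GROMOS-style) conformational clustering
#'
#' Daura-style iterative neighbour counting on the pairwise fitted RMSD of a
#' selection: the snapshot with the most neighbours within `cutoff` becomes
#' the mid-structure of the first cluster, the cluster members are removed,
#' and the procedure repeats. Ties are broken deterministically by the
#' lowest snapshot index. Clusters are reported ordered by size
#' (descending, formation order breaking ties).
#'
#' @param ens An `ensemble`.
#' @param selection Atom indices defining the conformation (default
#'   main-chain N/CA/C/O).
#' @param cutoff RMSD cutoff in Angstrom (default 1.0).
#' @param dist Optional precomputed RMSD matrix (overrides
#'   `ens`/`selection`).
#' @return Object of class `cluster_result`: list with `membership`
#'   (cluster id per snapshot), `mid_structures` (snapshot index per
#'   cluster), `sizes`, `coverage` (cumulative size fraction) and `cutoff`.
#' @export
gromos_cluster <- function(ens, selection = NULL, cutoff = 1.0, dist = NULL) {
  if (is.null(dist)) dist <- rmsd_matrix(ens, selection)
  n <- nrow(dist)
  adj <- dist <= cutoff
  remaining <- rep(TRUE, n)
  membership <- integer(n)
  centers <- integer(0)
  k <- 0L
  while (any(remaining)) {
    k <- k + 1L
    counts <- rowSums(adj[, remaining, drop = FALSE]) * remaining
    center <- which.max(counts)      # which.max takes the lowest index on ties
    members <- which(adj[center, ] & remaining)
    membership[members] <- k
    centers[k] <- center
    remaining[members] <- FALSE
  }
  sizes <- tabulate(membership, k)
  ord <- order(-sizes, seq_len(k))
  relabel <- match(seq_len(k), ord)
  out <- list(membership = relabel[membership],
              mid_structures = centers[ord],
              sizes = sizes[ord],
              coverage = cumsum(sizes[ord]) / n,
              cutoff = cutoff)
  class(out) <- "cluster_result"
  out
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("%d cluster(s) at %.2f A cutoff; top sizes: %s\n",
              length(x$sizes), x$cutoff,
              paste(utils::head(x$sizes, 5), collapse = ", ")))
  cat(sprintf("coverage of top %d cluster(s): %.1f%%\n",
              min(2L, length(x$sizes)),
              100 * x$coverage[min(2L, length(x$sizes))]))
  invisible(x)
}

#' Calculated B-factors from positional fluctuations
#'
#' `B = (8 pi^2 / 3) * <|r - <r>|^2>` per atom over the snapshots of an
#' aligned ensemble; rigid, well-anchored regions show characteristically
#' low values, wiggling solvent-exposed segments very high ones.
#'
#' @param ens An aligned `ensemble` with >= 2 snapshots (see
#'   [superpose()]).
#' @param per_residue Average over main-chain atoms per residue.
#' @return data.frame: per-atom (`atom`, `chain`, `residue_index`, `B`) or
#'   per-residue (`chain`, `residue_index`, `B`); B in Angstrom^2.
#' @export
bfactors <- function(ens, per_residue = TRUE) {
  if (n_snapshots(ens) < 2L)
    stop("B-factors require at least 2 snapshots")
  mean_xyz <- apply(ens$coords, c(1, 2), mean)
  msd <- rowMeans(apply(ens$coords, 3, function(x)
    rowSums((x - mean_xyz)^2)))
  B <- (8 * pi^2 / 3) * msd
  a <- ens$atoms
  if (!per_residue)
    return(data.frame(atom = a$atom_name, chain = a$chain,
                      residue_index = a$residue_index, B = B,
                      stringsAsFactors = FALSE))
  mc <- a$atom_name %in% c("N", "CA", "C", "O")
  key <- paste(a$chain, a$residue_index)[mc]
  agg <- tapply(B[mc], key, mean)
  parts <- do.call(rbind, strsplit(names(agg), " "))
  out <- data.frame(chain = parts[, 1],
                    residue_index = as.integer(parts[, 2]),
                    B = unname(agg), stringsAsFactors = FALSE)
  out <- out[order(out$chain, out$residue_index), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---------------------------------------------------------------------------
# backbone geometry

# torsion angle (degrees) for the four points of an a-b-c-d chain
dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

#' Backbone phi/psi angles of one snapshot
#'
#' phi(i) needs residue i-1 (C'), psi(i) needs residue i+1 (N): terminal
#' residues therefore have one undefined angle each.
#'
#' @param ens An `ensemble`.
#' @param snapshot Snapshot index.
#' @param chain Chain identifier (default: first chain).
#' @return data.frame `residue_index`, `phi`, `psi` (degrees, NA where
#'   undefined).
#' @export
phi_psi <- function(ens, snapshot = 1L, chain = NULL) {
  a <- ens$atoms
  if (is.null(chain)) chain <- a$chain[1]
  xyz <- ens$coords[, , snapshot]
  res <- sort(unique(a$residue_index[a$chain == chain]))
  get <- function(r, nm) {
    i <- which(a$chain == chain & a$residue_index == r & a$atom_name == nm)
    if (length(i) != 1L) NULL else xyz[i, ]
  }
  out <- data.frame(residue_index = res, phi = NA_real_, psi = NA_real_)
  for (k in seq_along(res)) {
    r <- res[k]
    N <- get(r, "N"); CA <- get(r, "CA"); C <- get(r, "C")
    if (is.null(N) || is.null(CA) || is.null(C)) next
    Cprev <- if (k > 1L && res[k - 1L] == r - 1L) get(r - 1L, "C") else NULL
    Nnext <- if (k < length(res) && res[k + 1L] == r + 1L) get(r + 1L, "N")
             else NULL
    if (!is.null(Cprev)) out$phi[k] <- dihedral_angle(Cprev, N, CA, C)
    if (!is.null(Nnext)) out$psi[k] <- dihedral_angle(N, CA, C, Nnext)
  }
  out
}

#' Assign helical segments from backbone dihedrals
#'
#' A residue is helical when (phi, psi) falls in the alpha-helical window
#' (defaults phi in \[-100, -30\], psi in \[-80, 0\] degrees); segments are
#' runs of at least `min_len` consecutive helical residues.
#'
#' @param ens An `ensemble`.
#' @param snapshot Snapshot index.
#' @param chain Chain identifier (default: first chain).
#' @param phi_range,psi_range Helical dihedral windows (degrees).
#' @param min_len Minimum segment length.
#' @return data.frame `start`, `end`, `length` of helical segments.
#' @export
assign_helix <- function(ens, snapshot = 1L, chain = NULL,
                         phi_range = c(-100, -30), psi_range = c(-80, 0),
                         min_len = 4L) {
  pp <- phi_psi(ens, snapshot, chain)
  hel <- !is.na(pp$phi) & !is.na(pp$psi) &
    pp$phi >= phi_range[1] & pp$phi <= phi_range[2] &
    pp$psi >= psi_range[1] & pp$psi <= psi_range[2]
  r <- rle(hel)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  data.frame(start = pp$residue_index[starts[keep]],
             end = pp$residue_index[ends[keep]],
             length = r$lengths[keep])
}

#' Per-residue helical fraction across an ensemble
#'
#' Fraction of snapshots in which a residue's (phi, psi) falls in the
#' helical window (no minimum run length applied).
#'
#' @inheritParams assign_helix
#' @return data.frame `residue_index`, `helix_fraction`.
#' @export
helix_fraction <- function(ens, chain = NULL, phi_range = c(-100, -30),
                           psi_range = c(-80, 0)) {
  n <- n_snapshots(ens)
  acc <- NULL
  for (m in seq_len(n)) {
    pp <- phi_psi(ens, m, chain)
    hel <- !is.na(pp$phi) & !is.na(pp$psi) &
      pp$phi >= phi_range[1] & pp$phi <= phi_range[2] &
      pp$psi >= psi_range[1] & pp$psi <= psi_range[2]
    if (is.null(acc)) acc <- data.frame(residue_index = pp$residue_index,
                                        n_hel = 0L)
    acc$n_hel <- acc$n_hel + hel
  }
  data.frame(residue_index = acc$residue_index,
             helix_fraction = acc$n_hel / n)
}

# ---------------------------------------------------------------------------
# hydrogen bonds, contacts, NOE constraints

# reconstruct amide H 1.02 A from N along the bisector of (CA-N, C'prev-N)
infer_amide_h <- function(N, CA, Cprev, bond = 1.02) {
  u1 <- (CA - N) / sqrt(sum((CA - N)^2))
  u2 <- (Cprev - N) / sqrt(sum((Cprev - N)^2))
  d <- -(u1 + u2)
  N + bond * d / sqrt(sum(d^2))
}

#' Detect backbone amide hydrogen bonds
#'
#' Geometric criterion per snapshot: donor-acceptor heavy-atom distance
#' `<= d_cut` (default 3.5 A) and a donor-H...acceptor angle within
#' `angle_cut` of linear (default 30 degrees, i.e. angle >= 150). Amide
#' hydrogens missing from the roster are reconstructed from backbone
#' geometry (N-H 1.02 A along the bisector convention) and flagged in the
#' output.
#'
#' @param ens An `ensemble`.
#' @param donors Atom indices of donor heavy atoms (default: backbone N of
#'   non-proline residues with a preceding residue).
#' @param acceptors Atom indices of acceptor atoms (default: backbone O).
#' @param d_cut Donor-acceptor distance cutoff (Angstrom).
#' @param angle_cut Maximum deviation from linearity (degrees).
#' @return data.frame `donor_chain`, `donor_residue`, `acceptor_chain`,
#'   `acceptor_residue`, `frequency` (fraction of snapshots),
#'   `h_inferred`; intra-residue and sequential same-chain pairs are
#'   excluded.
#' @export
detect_hbonds <- function(ens, donors = NULL, acceptors = NULL, d_cut = 3.5,
                          angle_cut = 30) {
  a <- ens$atoms
  if (is.null(donors))
    donors <- select_atoms(ens, atom_names = "N")
  donors <- donors[a$residue_type[donors] != "P"]
  if (is.null(acceptors))
    acceptors <- select_atoms(ens, atom_names = "O")
  n <- n_snapshots(ens)
  counts <- list()
  inferred <- logical(0)
  for (m in seq_len(n)) {
    xyz <- ens$coords[, , m]
    for (di in donors) {
      dres <- a$residue_index[di]; dch <- a$chain[di]
      hi <- which(a$chain == dch & a$residue_index == dres &
                    a$atom_name %in% c("H", "HN"))
      if (length(hi)) {
        H <- xyz[hi[1], ]
        h_inf <- FALSE
      } else {
        ca <- which(a$chain == dch & a$residue_index == dres &
                      a$atom_name == "CA")
        cp <- which(a$chain == dch & a$residue_index == dres - 1L &
                      a$atom_name == "C")
        if (!length(ca) || !length(cp)) next
        H <- infer_amide_h(xyz[di, ], xyz[ca[1], ], xyz[cp[1], ])
        h_inf <- TRUE
      }
      dvec <- sweep(xyz[acceptors, , drop = FALSE], 2, xyz[di, ])
      dist <- sqrt(rowSums(dvec^2))
      for (k in which(dist <= d_cut)) {
        ai <- acceptors[k]
        ares <- a$residue_index[ai]; ach <- a$chain[ai]
        if (ach == dch && abs(ares - dres) <= 1L) next
        v1 <- xyz[di, ] - H
        v2 <- xyz[ai, ] - H
        ang <- acos(pmin(pmax(sum(v1 * v2) /
                                sqrt(sum(v1^2) * sum(v2^2)), -1), 1)) * 180 / pi
        if (ang >= 180 - angle_cut) {
          key <- paste(dch, dres, ach, ares)
          counts[[key]] <- (counts[[key]] %||% 0L) + 1L
          inferred[key] <- h_inf
        }
      }
    }
  }
  if (!length(counts))
    return(data.frame(donor_chain = character(), donor_residue = integer(),
                      acceptor_chain = character(),
                      acceptor_residue = integer(), frequency = numeric(),
                      h_inferred = logical()))
  parts <- do.call(rbind, strsplit(names(counts), " "))
  out <- data.frame(donor_chain = parts[, 1],
                    donor_residue = as.integer(parts[, 2]),
                    acceptor_chain = parts[, 3],
                    acceptor_residue = as.integer(parts[, 4]),
                    frequency = unlist(counts) / n,
                    h_inferred = inferred[names(counts)],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(-out$frequency), , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Inter-chain residue contact frequencies
#'
#' A residue pair is in contact in a snapshot when the minimum heavy-atom
#' distance is at most `cutoff` (default 4.5 A); the frequency is the
#' fraction of snapshots with contact.
#'
#' @param ens An `ensemble`.
#' @param chain_a,chain_b Chain identifiers of the two (disjoint) partners.
#' @param cutoff Heavy-atom distance cutoff (Angstrom).
#' @return data.frame of class `contact_map`: `residue_a`, `residue_b`,
#'   `frequency`.
#' @export
residue_contacts <- function(ens, chain_a, chain_b, cutoff = 4.5) {
  ia <- select_atoms(ens, chain = chain_a, heavy = TRUE)
  ib <- select_atoms(ens, chain = chain_b, heavy = TRUE)
  if (!length(ia) || !length(ib)) stop("empty chain selection")
  ra <- ens$atoms$residue_index[ia]
  rb <- ens$atoms$residue_index[ib]
  n <- n_snapshots(ens)
  ures_a <- sort(unique(ra)); ures_b <- sort(unique(rb))
  hits <- matrix(0L, length(ures_a), length(ures_b),
                 dimnames = list(ures_a, ures_b))
  for (m in seq_len(n)) {
    xa <- ens$coords[ia, , m, drop = FALSE][, , 1, drop = FALSE]
    xb <- ens$coords[ib, , m, drop = FALSE][, , 1, drop = FALSE]
    dim(xa) <- c(length(ia), 3); dim(xb) <- c(length(ib), 3)
    d2 <- outer(rowSums(xa^2), rowSums(xb^2), `+`) - 2 * xa %*% t(xb)
    close <- d2 <= cutoff^2
    if (!any(close)) next
    pairs <- which(close, arr.ind = TRUE)
    keys <- unique(cbind(match(ra[pairs[, 1]], ures_a),
                         match(rb[pairs[, 2]], ures_b)))
    hits[keys] <- hits[keys] + 1L
  }
  idx <- which(hits > 0, arr.ind = TRUE)
  out <- data.frame(residue_a = ures_a[idx[, 1]], residue_b = ures_b[idx[, 2]],
                    frequency = hits[idx] / n)
  out <- out[order(out$residue_a, out$residue_b), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "chains") <- c(chain_a, chain_b)
  class(out) <- c("contact_map", "data.frame")
  out
}

#' Partner residues forming a persistent pocket around a query residue
#'
#' @param contacts A `contact_map` from [residue_contacts()].
#' @param query_residue Residue index on the `chain_a` side.
#' @param min_freq Minimum contact frequency (default 0.5).
#' @return Integer vector of partner residue indices.
#' @export
pocket_report <- function(contacts, query_residue, min_freq = 0.5) {
  sort(contacts$residue_b[contacts$residue_a == query_residue &
                            contacts$frequency >= min_freq])
}

#' Verify NOE distance constraints against an ensemble
#'
#' The effective distance of each atom pair is the `<r^-6>^(-1/6)` ensemble
#' average (NOE intensities average as r^-6, so transient close approaches
#' dominate); a constraint is satisfied when the effective distance does not
#' exceed its upper bound. With `per_snapshot = TRUE` the plain per-snapshot
#' distances are checked instead and the violated fraction reported.
#'
#' @param ens An `ensemble`.
#' @param constraints A `distance_constraints` table.
#' @param per_snapshot Also report the fraction of snapshots violating each
#'   constraint.
#' @return data.frame: constraint columns plus `effective_distance`,
#'   `satisfied` and `status` (`satisfied`, `violated` or `unresolvable`
#'   when an atom is missing from the roster).
#' @export
check_noe_constraints <- function(ens, constraints, per_snapshot = FALSE) {
  a <- ens$atoms
  find_atom <- function(res, nm, ch) {
    i <- which(a$residue_index == res & a$atom_name == nm &
                 (is.na(ch) | a$chain == ch))
    if (length(i)) i[1] else NA_integer_
  }
  out <- as.data.frame(constraints)
  out$effective_distance <- NA_real_
  out$violated_fraction <- NA_real_
  out$status <- "unresolvable"
  for (k in seq_len(nrow(out))) {
    i <- find_atom(out$residue_a[k], out$atom_a[k], out$chain_a[k])
    j <- find_atom(out$residue_b[k], out$atom_b[k], out$chain_b[k])
    if (is.na(i) || is.na(j)) next
    d <- sqrt(colSums((matrix(ens$coords[i, , ], nrow = 3) -
                         matrix(ens$coords[j, , ], nrow = 3))^2))
    eff <- mean(d^-6)^(-1 / 6)
    out$effective_distance[k] <- eff
    out$violated_fraction[k] <- mean(d > out$upper_bound[k])
    out$status[k] <- if (eff <= out$upper_bound[k]) "satisfied" else "violated"
  }
  out$satisfied <- out$status == "satisfied"
  if (!per_snapshot) out$violated_fraction <- NULL
  out
}
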