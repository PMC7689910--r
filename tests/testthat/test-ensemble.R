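# Superposition, clustering, B-factors, helices, H-bonds, contacts, NOEs.

rotation_z <- function(theta) {
  matrix(c(cos(theta), -sin(theta), 0, sin(theta), cos(theta), 0, 0, 0, 1),
         3, 3, byrow = TRUE)
}

test_that("superposition recovers rigid-body transformed copies exactly", {
  set.seed(21)
  base <- matrix(rnorm(30, sd = 4), 10, 3)
  coords <- array(NA_real_, c(10, 3, 4))
  for (m in 1:4)
    coords[, , m] <- base %*% rotation_z(m) + matrix(m * 2, 10, 3)
  atoms <- data.frame(chain = "A", residue_index = 1:10, residue_type = "A",
                      atom_name = "CA", element = "C")
  ens <- ensemble(coords, atoms)
  al <- superpose(ens, selection = 1:10)
  expect_lt(max(attr(al, "rmsd")), 1e-6)
  expect_error(superpose(ens, selection = 1:2), "3 atoms")
})

pair_rmsd_pkg <- function(p, q) fuzzynmr:::pair_rmsd(p, q, fit = TRUE)

test_that("fitted RMSD agrees with an independent quaternion implementation", {
  set.seed(22)
  ens <- random_ensemble(6, n_atoms = 8)
  d <- rmsd_matrix(ens, selection = 1:8)
  for (i in 1:5) for (j in (i + 1):6) {
    expect_equal(d[i, j],
                 qcp_rmsd(ens$coords[, , i], ens$coords[, , j]),
                 tolerance = 1e-6)
  }
  # a known displacement: shift one atom by 2*sqrt(n) A in a large structure
  p <- matrix(c(seq(0, 900, by = 100), rep(0, 20)), 10, 3)
  q <- p; q[1, 2] <- q[1, 2] + 5
  expect_equal(qcp_rmsd(p, q), pair_rmsd_pkg(p, q), tolerance = 1e-6)
})

test_that("cutoff clustering handles degenerate and two-family ensembles", {
  set.seed(23)
  # identical snapshots: one cluster covering everything
  ens <- random_ensemble(5, spread = 0)
  cl <- gromos_cluster(ens, selection = 1:5, cutoff = 1.0)
  expect_equal(length(cl$sizes), 1L)
  expect_equal(cl$coverage[1], 1.0)
  # two families 30+20 with tight intra- and wide inter-family spread
  base1 <- matrix(rnorm(24, sd = 4), 8, 3)
  base2 <- base1
  base2[1:4, 1] <- base2[1:4, 1] + 3  # internal deformation, not rigid-body
  coords <- array(NA_real_, c(8, 3, 50))
  for (m in 1:30) coords[, , m] <- base1 + matrix(rnorm(24, sd = 0.05), 8, 3)
  for (m in 31:50) coords[, , m] <- base2 + matrix(rnorm(24, sd = 0.05), 8, 3)
  atoms <- data.frame(chain = "A", residue_index = 1:8, residue_type = "A",
                      atom_name = "CA", element = "C")
  ens2 <- ensemble(coords, atoms)
  cl2 <- gromos_cluster(ens2, selection = 1:8, cutoff = 1.0)
  expect_equal(cl2$sizes, c(30L, 20L))
  expect_equal(sort(unique(cl2$membership[1:30])), 1L)
  # cutoff above the largest pairwise distance: a single cluster
  cl3 <- gromos_cluster(ens2, selection = 1:8, cutoff = 100)
  expect_equal(cl3$sizes, 50L)
})

test_that("clustering equals the exhaustive neighbour-count oracle", {
  set.seed(24)
  for (rep in 1:40) {
    ens <- random_ensemble(sample(5:20, 1), n_atoms = 4,
                           spread = runif(1, 0.3, 2))
    d <- rmsd_matrix(ens, selection = 1:4)
    cutoff <- stats::median(d)
    cl <- gromos_cluster(dist = d, cutoff = cutoff)
    expect_equal(cl$membership, oracle_cluster_membership(d, cutoff))
  }
})

test_that("B-factors obey the isotropic closed form and linearity", {
  set.seed(25)
  n_atoms <- 10; n_snap <- 2000
  base <- matrix(rnorm(n_atoms * 3, sd = 5), n_atoms, 3)
  jitter <- function(v) {
    coords <- array(NA_real_, c(n_atoms, 3, n_snap))
    for (m in seq_len(n_snap))
      coords[, , m] <- base + matrix(rnorm(n_atoms * 3, sd = sqrt(v)),
                                     n_atoms, 3)
    coords
  }
  atoms <- data.frame(chain = "A", residue_index = seq_len(n_atoms),
                      residue_type = "A", atom_name = "CA", element = "C")
  b1 <- bfactors(ensemble(jitter(0.01), atoms), per_residue = FALSE)
  expect_equal(mean(b1$B), 8 * pi^2 / 3 * 0.03, tolerance = 0.05)
  b2 <- bfactors(ensemble(jitter(0.02), atoms), per_residue = FALSE)
  expect_equal(mean(b2$B) / mean(b1$B), 2, tolerance = 0.1)
  # static ensemble: exactly zero
  b0 <- bfactors(ensemble(jitter(0), atoms), per_residue = FALSE)
  expect_true(all(b0$B == 0))
  expect_error(bfactors(ensemble(array(base, c(n_atoms, 3, 1)), atoms)),
               "2 snapshots")
})

test_that("B-factors are invariant under a global rotation applied before superposition", {
  set.seed(26)
  ens <- random_ensemble(40, n_atoms = 8, spread = 0.3)
  rot <- rotation_z(1.1)
  ens_rot <- ens
  for (m in 1:40) ens_rot$coords[, , m] <- ens$coords[, , m] %*% rot
  b1 <- bfactors(superpose(ens, selection = 1:8))
  b2 <- bfactors(superpose(ens_rot, selection = 1:8))
  expect_equal(b1$B, b2$B, tolerance = 1e-6)
})

test_that("helix assignment finds ideal helices and respects the run length", {
  ens <- ideal_helix_ensemble(10)
  seg <- assign_helix(ens)
  # terminal residues lack phi or psi, so the segment is 2..9
  expect_equal(seg, data.frame(start = 2L, end = 9L, length = 8L))
  # extended chain: nothing helical
  ext <- ideal_helix_ensemble(10, phi = -120, psi = 120)
  expect_equal(nrow(assign_helix(ext)), 0L)
  # 3 consecutive helical residues in an extended context: below min length
  bb <- fuzzynmr:::build_backbone(
    c(rep(-120, 4), rep(-57, 3), rep(-120, 4)),
    c(rep(120, 4), rep(-47, 3), rep(120, 4)), rep("A", 11))
  ens3 <- coords_ensemble(bb$xyz, bb$atoms)
  expect_equal(nrow(assign_helix(ens3)), 0L)
})

test_that("hydrogen bond detection applies distance and angle gates", {
  # donor N with H pointing at the acceptor O
  mk <- function(o_pos, angle_offset = 0) {
    atoms <- data.frame(
      chain = c("A", "A", "A", "B"),
      residue_index = c(2L, 2L, 2L, 10L),
      residue_type = "A",
      atom_name = c("N", "H", "CA", "O"),
      element = c("N", "H", "C", "O"))
    h <- c(1.02 * cos(angle_offset), 1.02 * sin(angle_offset), 0)
    xyz <- rbind(c(0, 0, 0), h, c(-0.8, -1.2, 0), o_pos)
    coords_ensemble(xyz, atoms)
  }
  # N...O 2.9 A, nearly linear N-H...O
  hb <- detect_hbonds(mk(c(2.9, 0, 0)))
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$frequency, 1.0)
  expect_false(hb$h_inferred)
  # far acceptor
  expect_equal(nrow(detect_hbonds(mk(c(10, 0, 0)))), 0L)
  # bent geometry (~120 deg at H) fails the angle gate
  expect_equal(nrow(detect_hbonds(mk(c(2.9, 0, 0), angle_offset = 1.05))), 0L)
})

test_that("amide hydrogens are reconstructed when absent", {
  ens <- ideal_helix_ensemble(12)
  hb <- detect_hbonds(ens)
  expect_gt(nrow(hb), 3L)
  expect_true(all(hb$h_inferred))
  # ideal alpha helix: O(i) accepts from N-H(i+4)
  expect_true(all(hb$donor_residue - hb$acceptor_residue == 4L))
})

test_that("contact frequencies count snapshots below the heavy-atom cutoff", {
  atoms <- data.frame(chain = c("A", "B"), residue_index = c(1L, 50L),
                      residue_type = "A", atom_name = "CB", element = "C")
  n <- 10L
  coords <- array(0, c(2, 3, n))
  # 4.0 A apart in half the snapshots, 8 A in the rest
  for (m in seq_len(n)) coords[2, 1, m] <- if (m <= 5) 4.0 else 8.0
  ens <- ensemble(coords, atoms)
  cm <- residue_contacts(ens, "A", "B", cutoff = 4.5)
  expect_equal(cm$frequency, 0.5)
  coords[2, 1, ] <- 4.0
  expect_equal(residue_contacts(ensemble(coords, atoms), "A", "B")$frequency, 1.0)
  expect_error(residue_contacts(ens, "A", "Z"), "empty")
})

test_that("a persistent 8-residue pocket is reported around the anchor", {
  n_pocket <- 8L
  atoms <- rbind(
    data.frame(chain = "A", residue_index = 26L, residue_type = "L",
               atom_name = "CB", element = "C"),
    data.frame(chain = "B", residue_index = seq_len(n_pocket),
               residue_type = "L", atom_name = "CB", element = "C"))
  coords <- array(0, c(n_pocket + 1, 3, 4))
  ang <- 2 * pi * seq_len(n_pocket) / n_pocket
  for (m in 1:4)
    coords[-1, , m] <- cbind(4 * cos(ang), 4 * sin(ang), 0)
  ens <- ensemble(coords, atoms)
  cm <- residue_contacts(ens, "A", "B", cutoff = 4.5)
  expect_equal(pocket_report(cm, 26L), seq_len(n_pocket))
})

test_that("NOE constraints use r^-6 ensemble averaging", {
  atoms <- data.frame(chain = "A", residue_index = c(1L, 5L),
                      residue_type = "A", atom_name = "HA", element = "H")
  mk <- function(dists) {
    coords <- array(0, c(2, 3, length(dists)))
    coords[2, 1, ] <- dists
    ensemble(coords, atoms)
  }
  con <- distance_constraints(1L, "HA", 5L, "HA", upper_bound = 5)
  expect_equal(check_noe_constraints(mk(rep(4.2, 4)), con)$status, "satisfied")
  expect_equal(check_noe_constraints(mk(rep(6.0, 4)), con)$status, "violated")
  # alternating 3/8 A: (0.5*3^-6 + 0.5*8^-6)^(-1/6) = 3.366 -> satisfied
  out <- check_noe_constraints(mk(c(3, 8, 3, 8)), con)
  expect_equal(out$effective_distance, 3.3659, tolerance = 1e-4)
  expect_equal(out$status, "satisfied")
  # missing atom: unresolvable, not dropped
  con2 <- distance_constraints(1L, "HB", 5L, "HA")
  expect_equal(check_noe_constraints(mk(rep(4, 2)), con2)$status,
               "unresolvable")
})

test_that("tightening the NOE bound is monotone in the verdict", {
  set.seed(27)
  atoms <- data.frame(chain = "A", residue_index = c(1L, 9L),
                      residue_type = "A", atom_name = "HA", element = "H")
  coords <- array(0, c(2, 3, 20))
  coords[2, 1, ] <- runif(20, 2, 9)
  ens <- ensemble(coords, atoms)
  bounds <- seq(9, 2, by = -0.5)
  status <- vapply(bounds, function(b)
    check_noe_constraints(
      ens, distance_constraints(1L, "HA", 9L, "HA", b))$satisfied, TRUE)
  expect_false(is.unsorted(rev(status)))  # TRUE..TRUE then FALSE..FALSE
})
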