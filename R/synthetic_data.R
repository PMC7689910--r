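# Ground-truth generators emulating the data shapes of an IDP-partner
# titration study: shift tables, titration peak lists, relaxation decays and
# conformational ensembles, all with known per-residue parameters.

#' Model-free spectral density
#'
#' Two-Lorentzian Lipari-Szabo form
#' `J(w) = (2/5) (S2 tau_c / (1 + (w tau_c)^2) + (1 - S2) tau' / (1 + (w
#' tau')^2))` with `1/tau' = 1/tau_c + 1/tau_e`. With `S2 = 1` it collapses
#' to the single-Lorentzian (single motion) form.
#'
#' @param omega Angular frequency (rad/s), vectorised.
#' @param S2 Generalised order parameter in \[0, 1\].
#' @param tau_c Global correlation time (s).
#' @param tau_e Effective internal correlation time (s).
#' @return J in s/rad.
#' @examples
#' modelfree_J(0, S2 = 0.8, tau_c = 4e-9, tau_e = 50e-12)  # ~1.284e-9
#' @export
modelfree_J <- function(omega, S2, tau_c, tau_e = 50e-12) {
  stopifnot(tau_c > 0, S2 >= 0, S2 <= 1)
  tau_p <- 1 / (1 / tau_c + 1 / tau_e)
  0.4 * (S2 * tau_c / (1 + (omega * tau_c)^2) +
           (1 - S2) * tau_p / (1 + (omega * tau_p)^2))
}

#' 15N relaxation rates from model-free parameters
#'
#' Evaluates R1, R2 and the steady-state heteronuclear NOE from the full
#' dipolar + CSA expressions with the model-free spectral density (plus an
#' optional exchange contribution to R2). This is the forward model whose
#' inversion is [reduced_spectral_density()].
#'
#' @param S2,tau_c,tau_e Model-free parameters (vectorised over `S2`).
#' @param Rex Exchange contribution to R2 (s^-1).
#' @param ctx A [spectrometer_context()].
#' @return data.frame `S2`, `R1`, `R2`, `noe`.
#' @export
modelfree_rates <- function(S2, tau_c, tau_e = 50e-12, Rex = 0,
                            ctx = spectrometer_context()) {
  Rex <- rep_len(Rex, length(S2))
  J <- function(w, s) modelfree_J(w, s, tau_c, tau_e)
  ## gammaN < 0: the combination frequency wH + wN lies BELOW wH
  wH <- ctx$omega_H
  wN <- ctx$omega_N
  wHpN <- wH - wN   # |wH + wN| with signed wN
  wHmN <- wH + wN   # |wH - wN|
  out <- t(vapply(seq_along(S2), function(i) {
    s <- S2[i]
    R1 <- ctx$d2 / 4 * (J(wHmN, s) + 3 * J(wN, s) + 6 * J(wHpN, s)) +
      ctx$c2 * J(wN, s)
    R2 <- ctx$d2 / 8 * (4 * J(0, s) + J(wHmN, s) + 3 * J(wN, s) +
                          6 * J(wH, s) + 6 * J(wHpN, s)) +
      ctx$c2 / 6 * (4 * J(0, s) + 3 * J(wN, s)) + Rex[i]
    sigma_NH <- ctx$d2 / 4 * (6 * J(wHpN, s) - J(wHmN, s))
    noe <- 1 + (1 / ctx$gamma_ratio_NH) * sigma_NH / R1
    c(R1 = R1, R2 = R2, noe = noe)
  }, c(R1 = 0, R2 = 0, noe = 0)))
  data.frame(S2 = S2, R1 = out[, "R1"], R2 = out[, "R2"], noe = out[, "noe"])
}

#' Ground-truth model of an IDP binding study
#'
#' The `"p53tad_like"` preset encodes a 60-residue disordered chain with
#' mobile termini (1-13, 56-60), three binding-induced helices (18-29,
#' 36-47, 50-55), hydrophobic anchor residues 26/40/53 carrying the largest
#' endpoint shift changes, an intermediate-exchange-broadened third binding
#' region, exchange-prone sites (23, 24, 32, 51) and per-observable noise
#' levels typical of well-resolved HSQC data.
#'
#' @param preset Currently `"p53tad_like"`.
#' @return Object of class `ground_truth_model`: sequence, per-residue
#'   helical fractions (`helix_free`, `helix_bound`), model-free parameters
#'   (`S2`, `tau_c`, `tau_e`, `rex`; bound state), `binding` table
#'   (endpoint `delta_H`/`delta_N` in ppm, `broadened` flag), `tempco`
#'   ground-truth slopes (ppb/K), `anchors`, and `noise` levels.
#' @export
ground_truth_model <- function(preset = "p53tad_like") {
  preset <- match.arg(preset)
  seq <- protein_sequence(P53TAD_SEQ, id = "p53TAD1-60")
  n <- length(seq$residues)
  idx <- residue_indices(seq)
  helices <- list(18:29, 36:47, 50:55)
  in_helix <- idx %in% unlist(helices)
  termini <- idx <= 13 | idx >= 56
  helix_bound <- ifelse(in_helix, 0.90, ifelse(termini, 0.02, 0.05))
  helix_free <- ifelse(idx %in% 19:24, 0.30,
                       ifelse(idx %in% c(41:43, 49:51), 0.12, 0.05))
  S2 <- ifelse(in_helix, 0.85,
               ifelse(idx <= 13, 0.25, ifelse(idx >= 56, 0.30, 0.50)))
  rex <- ifelse(idx %in% c(23, 24, 32, 51), 3, 0)
  regions <- c(20:29, 39:44, 48:55)
  broadened <- idx %in% c(48:52, 54:55)
  delta_H <- ifelse(idx %in% regions, 0.13, 0.01)
  delta_N <- ifelse(idx %in% regions, 0.80, 0.05)
  anchors <- c(26, 40, 53)
  delta_H[match(anchors, idx)] <- c(0.30, 0.26, 0.32)
  delta_N[match(anchors, idx)] <- c(1.5, 1.3, 1.6)
  tempco <- ifelse(idx %in% c(20:25, 39:45, 55), -3.0,
                   ifelse(idx %in% c(5:7, 11:14, 28, 32, 33, 57), -9.5, -6.5))
  out <- list(
    sequence = seq,
    helix_free = stats::setNames(helix_free, idx),
    helix_bound = stats::setNames(helix_bound, idx),
    helices = helices,
    S2 = stats::setNames(S2, idx),
    tau_c = 8e-9, tau_e = 50e-12,
    rex = stats::setNames(rex, idx),
    binding = data.frame(residue_index = idx, delta_H = delta_H,
                         delta_N = delta_N, broadened = broadened),
    tempco = stats::setNames(tempco, idx),
    anchors = anchors,
    noise = list(shift_H = 0.004, shift_N = 0.04, shift_C = 0.05,
                 shift_HA = 0.004, intensity = 0.01))
  class(out) <- "ground_truth_model"
  out
}

# coil + helical-fraction shifts for one state (no binding terms)
state_shifts <- function(model, rc, f, noise) {
  seq <- model$sequence
  idx <- residue_indices(seq)
  full <- full_shift_table()
  fullv <- stats::setNames(full$helix, full$nucleus)
  rows <- list()
  for (nuc in c("CA", "CB", "HA", "H", "N")) {
    coil <- coil_shift(rc, seq, idx, nuc)
    ok <- !is.na(coil)
    sigma <- switch(nuc, CA = noise$shift_C, CB = noise$shift_C,
                    HA = noise$shift_HA, H = noise$shift_H, N = noise$shift_N)
    helical <- if (nuc %in% names(fullv)) f[as.character(idx)] * fullv[nuc]
               else numeric(length(idx))
    rows[[nuc]] <- data.frame(
      residue_index = idx[ok],
      residue_type = seq$residues[ok],
      nucleus = nuc,
      shift = coil[ok] + helical[ok] + stats::rnorm(sum(ok), 0, sigma))
  }
  do.call(rbind, rows)
}

#' Simulate free and bound chemical shift tables
#'
#' Shifts are built as coil + helical-fraction-weighted full secondary
#' shifts + Gaussian noise (CA/CB/HA); amide H/N additionally receive the
#' binding endpoint changes in the bound state. Broadened residues are
#' omitted from the bound table entirely, as their resonances are lost
#' below the detection limit.
#'
#' @param model A [ground_truth_model()].
#' @param rc A [random_coil_table()].
#' @param seed Random seed.
#' @return List with `free` and `bound` `shift_table`s.
#' @export
simulate_shift_tables <- function(model, rc = random_coil_table(),
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  free_df <- state_shifts(model, rc, model$helix_free, model$noise)
  bound_df <- state_shifts(model, rc, model$helix_bound, model$noise)
  b <- model$binding
  amide <- bound_df$nucleus %in% c("H", "N")
  m <- match(bound_df$residue_index, b$residue_index)
  dd <- ifelse(bound_df$nucleus == "H", b$delta_H[m], b$delta_N[m])
  bound_df$shift[amide] <- bound_df$shift[amide] + dd[amide]
  bound_df <- bound_df[!b$broadened[m], , drop = FALSE]
  list(free = shift_table(free_df$residue_index, free_df$residue_type,
                          free_df$nucleus, free_df$shift,
                          protein_id = model$sequence$id, state = "free"),
       bound = shift_table(bound_df$residue_index, bound_df$residue_type,
                           bound_df$nucleus, bound_df$shift,
                           protein_id = model$sequence$id, state = "bound"))
}

#' Simulate a titration peak-list series
#'
#' Fast-exchange peaks move linearly with the bound fraction toward their
#' endpoint positions (saturating at a molar ratio of 1); broadened residues
#' fade and drop below the detection limit past `fade_fraction`. The first
#' point (free state) is assigned, later points are unassigned, as when
#' assignments are transferred by peak tracking.
#'
#' @param model A [ground_truth_model()].
#' @param n_points Number of titration points (>= 2), covering molar ratios
#'   0 and 0.3-1.15.
#' @param rc A [random_coil_table()].
#' @param seed Random seed.
#' @param noise Peak-position noise in ppm (1H; the 15N noise is 10x).
#' @param fade_fraction Molar ratio beyond which broadened peaks are
#'   undetectable.
#' @return List of `peak_list`s ordered by titration fraction.
#' @export
simulate_titration <- function(model, n_points = 7L,
                               rc = random_coil_table(), seed = NULL,
                               noise = 0, fade_fraction = 0.6) {
  stopifnot(n_points >= 2L)
  if (!is.null(seed)) set.seed(seed)
  seq <- model$sequence
  idx <- residue_indices(seq)
  H0 <- coil_shift(rc, seq, idx, "H")
  N0 <- coil_shift(rc, seq, idx, "N")
  ok <- !is.na(H0) & !is.na(N0)
  b <- model$binding
  fractions <- c(0, rev(seq(1.15, 0.30, length.out = n_points - 1L)))
  lapply(seq_along(fractions), function(k) {
    f <- fractions[k]
    bf <- min(f, 1)
    keep <- ok & !(b$broadened & f >= fade_fraction)
    h <- 1 - pmin(1, ifelse(b$broadened, f / fade_fraction, 0))
    lab <- if (k == 1L) paste0(seq$residues, idx, "N-H")
           else rep("?-?", length(idx))
    peak_list(lab[keep],
              w1 = N0[keep] + bf * b$delta_N[keep] +
                stats::rnorm(sum(keep), 0, 10 * noise),
              w2 = H0[keep] + bf * b$delta_H[keep] +
                stats::rnorm(sum(keep), 0, noise),
              height = h[keep],
              spectrum_id = sprintf("titration_%03d", k),
              titration_fraction = f)
  })
}

#' Simulate peak lists across a temperature series
#'
#' Amide 1H positions follow the ground-truth temperature coefficients
#' (ppb/K) linearly; assignments are retained at every temperature.
#'
#' @param model A [ground_truth_model()].
#' @param temperatures Temperatures in K.
#' @param rc A [random_coil_table()].
#' @param seed Random seed.
#' @param noise 1H position noise in ppm (default 0.002 = 2 ppb).
#' @param ref_temperature Temperature at which peaks sit at their coil
#'   positions.
#' @return List of assigned `peak_list`s with `temperature` attributes.
#' @export
simulate_tempco_series <- function(model, temperatures = c(288, 298, 308, 318),
                                   rc = random_coil_table(), seed = NULL,
                                   noise = 0.002, ref_temperature = 298) {
  if (!is.null(seed)) set.seed(seed)
  seq <- model$sequence
  idx <- residue_indices(seq)
  H0 <- coil_shift(rc, seq, idx, "H")
  N0 <- coil_shift(rc, seq, idx, "N")
  ok <- !is.na(H0) & !is.na(N0)
  lab <- paste0(seq$residues, idx, "N-H")
  lapply(temperatures, function(tt) {
    w2 <- H0 + model$tempco * (tt - ref_temperature) / 1000 +
      stats::rnorm(length(idx), 0, noise)
    peak_list(lab[ok], w1 = N0[ok], w2 = w2[ok], height = 1,
              spectrum_id = sprintf("T%dK", tt), temperature = tt)
  })
}

#' Simulate relaxation decay series and hetNOE intensity pairs
#'
#' Per (non-proline) residue, R1/R2/NOE are computed from the model-free
#' spectral density via the full dipolar + CSA expressions (including the
#' exchange contribution to R2) and emitted as single-exponential intensity
#' decays on the standard delay schedules (10 delays 0.01-2 s, 11 delays
#' 0.03-1.36 s, one delay duplicated) plus saturated/unsaturated intensity
#' pairs, all with multiplicative Gaussian noise.
#'
#' @param model A [ground_truth_model()].
#' @param ctx A [spectrometer_context()].
#' @param seed Random seed.
#' @param I0 Reference intensity.
#' @return List: `t1`, `t2` (`decay_series`), `noe_sat`, `noe_unsat`
#'   (data.frames `residue_index`, `intensity`), `noise` (absolute intensity
#'   sigma) and `truth` (per-residue S2, Rex, R1, R2, noe).
#' @export
simulate_relaxation <- function(model, ctx = spectrometer_context(),
                                seed = NULL, I0 = 100) {
  if (!is.null(seed)) set.seed(seed)
  seq <- model$sequence
  idx <- residue_indices(seq)
  use <- seq$residues != "P"
  idx <- idx[use]
  rates <- modelfree_rates(model$S2[as.character(idx)], model$tau_c,
                           model$tau_e, model$rex[as.character(idx)], ctx)
  sigma <- model$noise$intensity * I0
  d1 <- t1_delay_schedule(); d2 <- t2_delay_schedule()
  mk <- function(delays, R, exp) {
    df <- expand.grid(delay = delays, residue_index = idx)[, 2:1]
    Rr <- R[match(df$residue_index, idx)]
    decay_series(df$residue_index, df$delay,
                 I0 * exp(-Rr * df$delay) + stats::rnorm(nrow(df), 0, sigma),
                 experiment = exp)
  }
  list(t1 = mk(d1, rates$R1, "T1"),
       t2 = mk(d2, rates$R2, "T2"),
       noe_sat = data.frame(residue_index = idx,
                            intensity = I0 * rates$noe +
                              stats::rnorm(length(idx), 0, sigma)),
       noe_unsat = data.frame(residue_index = idx,
                              intensity = I0 +
                                stats::rnorm(length(idx), 0, sigma)),
       noise = sigma,
       truth = data.frame(residue_index = idx, S2 = rates$S2,
                          rex = model$rex[as.character(idx)],
                          R1 = rates$R1, R2 = rates$R2, noe = rates$noe))
}

# ---------------------------------------------------------------------------
# ensemble generator (ideal-geometry backbone from phi/psi sampling)

CROSS3 <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                           u[3] * v[1] - u[1] * v[3],
                           u[1] * v[2] - u[2] * v[1])

# natural extension reference frame: place D given A-B-C with bond |C-D|,
# angle B-C-D and torsion A-B-C-D (degrees)
place_atom <- function(a, b, c, bond, angle, torsion) {
  angle <- angle * pi / 180; torsion <- torsion * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  n <- CROSS3(b - a, bc); n <- n / sqrt(sum(n^2))
  m <- CROSS3(n, bc)
  d <- c(-bond * cos(angle), bond * sin(angle) * cos(torsion),
         -bond * sin(angle) * sin(torsion))
  c + d[1] * bc + d[2] * m + d[3] * n
}

# backbone (N, CA, C, O, CB) from per-residue phi/psi with ideal geometry
build_backbone <- function(phi, psi, residues, chain = "A", offset = 0L) {
  n <- length(phi)
  atoms <- list(); coords <- list()
  N <- c(0, 0, 0); CA <- c(1.46, 0, 0)
  C <- CA + 1.52 * c(cos(69 * pi / 180), sin(69 * pi / 180), 0)
  for (i in seq_len(n)) {
    if (i > 1L) {
      Nn <- place_atom(Np, CAp, Cp, 1.33, 116, psi[i - 1L])
      CAn <- place_atom(CAp, Cp, Nn, 1.46, 121, 180)
      Cn <- place_atom(Cp, Nn, CAn, 1.52, 111, phi[i])
      N <- Nn; CA <- CAn; C <- Cn
    }
    O <- place_atom(N, CA, C, 1.23, 120.5, psi[i] - 180)
    res_atoms <- list(N = N, CA = CA, C = C, O = O)
    if (residues[i] != "G")
      res_atoms$CB <- place_atom(N, C, CA, 1.53, 110.1, 122.6)
    for (nm in names(res_atoms)) {
      atoms[[length(atoms) + 1L]] <- data.frame(
        chain = chain, residue_index = i + offset,
        residue_type = residues[i], atom_name = nm,
        element = substr(nm, 1, 1), stringsAsFactors = FALSE)
      coords[[length(coords) + 1L]] <- res_atoms[[nm]]
    }
    Np <- N; CAp <- CA; Cp <- C
  }
  list(atoms = do.call(rbind, atoms), xyz = do.call(rbind, coords))
}

#' Simulate a conformational ensemble with helices and flexible linkers
#'
#' Backbones are built residue-by-residue with ideal bond geometry from
#' sampled (phi, psi) angles: residues with bound-state helical fraction of
#' at least 0.5 sample tightly around the alpha-helical (-57, -47) point, other
#' residues sample broadly (disordered linkers and termini). In
#' `two_family` mode all residues sample tightly but the linkers alternate
#' between two distinct mean conformations, producing two well-separated
#' conformational families for clustering tests. When `partner = TRUE`,
#' synthetic partner pocket pseudo-atoms (chain "P") are placed at contact
#' distance from the anchor-residue CB atoms in every snapshot, emulating
#' persistent anchoring in the partner's hydrophobic pockets.
#'
#' @param model A [ground_truth_model()].
#' @param n_snapshots Number of snapshots (>= 2).
#' @param seed Random seed.
#' @param two_family Generate two tight conformational families.
#' @param family_split Fraction of snapshots in the first family.
#' @param partner Add synthetic partner pocket pseudo-atoms.
#' @param chain Chain identifier of the IDP.
#' @return An `ensemble`; attribute `"family"` gives the ground-truth family
#'   of each snapshot in `two_family` mode.
#' @export
simulate_ensemble <- function(model, n_snapshots = 50L, seed = NULL,
                              two_family = FALSE, family_split = 0.6,
                              partner = TRUE, chain = "A") {
  stopifnot(n_snapshots >= 2L)
  if (!is.null(seed)) set.seed(seed)
  seq <- model$sequence
  nres <- length(seq$residues)
  helical <- model$helix_bound >= 0.5
  family <- if (two_family)
    rep(1:2, c(round(family_split * n_snapshots),
               n_snapshots - round(family_split * n_snapshots)))
  else rep(1L, n_snapshots)
  snaps <- vector("list", n_snapshots)
  atoms <- NULL
  for (m in seq_len(n_snapshots)) {
    if (two_family) {
      lk_mean <- if (family[m] == 1L) c(-75, 150) else c(-150, 80)
      sd_hel <- 0.5; sd_lk <- 0.5
      phi <- ifelse(helical, stats::rnorm(nres, -57, sd_hel),
                    stats::rnorm(nres, lk_mean[1], sd_lk))
      psi <- ifelse(helical, stats::rnorm(nres, -47, sd_hel),
                    stats::rnorm(nres, lk_mean[2], sd_lk))
    } else {
      phi <- ifelse(helical, stats::rnorm(nres, -57, 5),
                    stats::rnorm(nres, -90, 40))
      psi <- ifelse(helical, stats::rnorm(nres, -47, 5),
                    stats::rnorm(nres, 130, 50))
    }
    bb <- build_backbone(phi, psi, seq$residues, chain = chain,
                         offset = seq$offset)
    xyz <- bb$xyz
    a <- bb$atoms
    if (partner) {
      for (k in seq_along(model$anchors)) {
        r <- model$anchors[k]
        ca <- which(a$chain == chain & a$residue_index == r &
                      a$atom_name == "CA")
        cb <- which(a$chain == chain & a$residue_index == r &
                      a$atom_name == "CB")
        u <- xyz[cb, ] - xyz[ca, ]
        u <- u / sqrt(sum(u^2))
        pos <- xyz[cb, ] + 3.5 * u + stats::rnorm(3, 0, 0.2)
        a <- rbind(a, data.frame(chain = "P", residue_index = 100L + k,
                                 residue_type = "G", atom_name = "CA",
                                 element = "C", stringsAsFactors = FALSE))
        xyz <- rbind(xyz, pos)
      }
    }
    if (is.null(atoms)) atoms <- a
    snaps[[m]] <- xyz
  }
  coords <- array(NA_real_, c(nrow(atoms), 3L, n_snapshots))
  for (m in seq_len(n_snapshots)) coords[, , m] <- snaps[[m]]
  ens <- ensemble(coords, atoms, id = "synthetic")
  attr(ens, "family") <- family
  ens
}
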