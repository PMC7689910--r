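# Physical constants and reference tables shared across modules.

## IUPAC frequency ratios Xi relative to 1H of DSS (unified scale)
XI_13C <- 0.251449530
XI_15N <- 0.101329118

## gyromagnetic constants for the 15N-1H spin pair
GAMMA_H <- 2.6752218744e8   # rad s^-1 T^-1
GAMMA_RATIO_NH <- -0.10136  # gammaN / gammaH, negative for 15N
MU0_OVER_4PI <- 1e-7        # T m A^-1
HBAR <- 1.054571817e-34     # J s

R_NH_DEFAULT <- 1.02e-10        # N-H bond length, m
DSIGMA_N_DEFAULT <- -160e-6     # 15N CSA, dimensionless (ppm * 1e-6)

WATER_MASS <- 18.02  # Da, added once per chain

AMINO_ACIDS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

AA_THREE_TO_ONE <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V")

AA_ONE_TO_THREE <- stats::setNames(names(AA_THREE_TO_ONE),
                                   unname(AA_THREE_TO_ONE))

## average (isotope-abundance weighted) residue masses in Da
AVERAGE_RESIDUE_MASS <- c(
  G = 57.05,  A = 71.08,  S = 87.08,  P = 97.12,  V = 99.13,
  T = 101.10, C = 103.14, L = 113.16, I = 113.16, N = 114.10,
  D = 115.09, Q = 128.13, K = 128.17, E = 129.12, M = 131.19,
  H = 137.14, F = 147.18, R = 156.19, Y = 163.18, W = 186.21)

## human p53 transactivation domain, UniProt P04637 residues 1-60
P53TAD_SEQ <- "MEEPQSDPSVEPPLSQETFSDLWKLLPENNVLSPLPSQAMDDLMLSPDDIEQWFTEDPGP"

VALID_NUCLEI <- c("H", "N", "HA", "CA", "CB", "C")

#' Spectrometer field context
#'
#' Bundles the static magnetic field and the Larmor frequencies needed to
#' convert between 1H, 13C and 15N frequency scales and to evaluate the
#' dipolar and CSA interaction constants used in relaxation analysis.
#'
#' @param freq_1H 1H Larmor frequency in MHz (e.g. 700.17).
#' @param r_NH N-H internuclear distance in metres (default 1.02 Angstrom).
#' @param delta_sigma_N 15N chemical shift anisotropy (dimensionless;
#'   default -160 ppm).
#' @param gamma_ratio gammaN/gammaH (dimensionless, negative for 15N).
#'
#' @return An object of class `spectrometer_context` with fields `B0` (tesla),
#'   `freq_1H`, `freq_13C`, `freq_15N` (MHz), angular frequencies `omega_H`,
#'   `omega_N` (rad/s, magnitudes), and interaction constants `d2`
#'   (squared dipolar coupling, s^-2) and `c2` (squared CSA coupling, s^-2).
#' @examples
#' ctx <- spectrometer_context(700.17)
#' ctx$freq_15N  # ~70.95 MHz
#' @export
spectrometer_context <- function(freq_1H = 700.17,
                                 r_NH = R_NH_DEFAULT,
                                 delta_sigma_N = DSIGMA_N_DEFAULT,
                                 gamma_ratio = GAMMA_RATIO_NH) {
  stopifnot(is.numeric(freq_1H), length(freq_1H) == 1L, freq_1H > 0)
  lf <- larmor_frequencies(freq_1H)
  omega_H <- 2 * pi * freq_1H * 1e6
  omega_N <- 2 * pi * lf$freq_15N * 1e6
  gamma_N <- GAMMA_H * abs(gamma_ratio)
  d <- MU0_OVER_4PI * HBAR * GAMMA_H * gamma_N / r_NH^3
  ctx <- list(
    B0 = omega_H / GAMMA_H,
    freq_1H = freq_1H,
    freq_13C = lf$freq_13C,
    freq_15N = lf$freq_15N,
    omega_H = omega_H,
    omega_N = omega_N,
    gamma_ratio_NH = gamma_ratio,
    r_NH = r_NH,
    delta_sigma_N = delta_sigma_N,
    d2 = d^2,
    c2 = (omega_N * delta_sigma_N)^2 / 3)
  stopifnot(abs(ctx$freq_15N / ctx$freq_1H - XI_15N) / XI_15N < 1e-4)
  class(ctx) <- "spectrometer_context"
  ctx
}

#' @export
print.spectrometer_context <- function(x, ...) {
  cat(sprintf("spectrometer context: B0 = %.2f T\n", x$B0))
  cat(sprintf("  1H %.2f MHz | 13C %.2f MHz | 15N %.2f MHz\n",
              x$freq_1H, x$freq_13C, x$freq_15N))
  invisible(x)
}

#' Indirect referencing of 13C and 15N Larmor frequencies
#'
#' Heteronuclear frequencies are derived from the 1H frequency through the
#' IUPAC frequency ratios of the DSS-referenced unified scale, the standard
#' practice when shifts are referenced indirectly via the gyromagnetic
#' ratios.
#'
#' @param freq_1H 1H Larmor frequency in MHz.
#' @return A list with `freq_13C` and `freq_15N` in MHz.
#' @examples
#' larmor_frequencies(700.17)
#' @export
larmor_frequencies <- function(freq_1H) {
  stopifnot(is.numeric(freq_1H), all(freq_1H > 0))
  list(freq_13C = freq_1H * XI_13C, freq_15N = freq_1H * XI_15N)
}

#' Sequence-corrected random-coil chemical shift reference
#'
#' Reference random-coil shifts per residue type for the nuclei used in
#' secondary-shift analysis (H, N, HA, CA, CB), together with
#' nearest-neighbour sequence corrections (positions i-2..i+2) and the
#' reference temperature. The only non-zero correction shipped by default is
#' the well-known upfield CA/HA effect of a following proline; additional
#' corrections can be supplied by editing the returned object.
#'
#' @param ref_temperature Reference temperature of the table in K.
#' @return An object of class `random_coil_table`: list with `shifts`
#'   (data.frame residue_type x nucleus, ppm), `corrections` (data.frame
#'   `nucleus`, `offset`, `neighbour`, `delta`), `ref_temperature` and
#'   `temp_coeff` (ppb/K per nucleus applied as delta * (T - ref)).
#' @export
random_coil_table <- function(ref_temperature = 298) {
  shifts <- data.frame(
    residue_type = AMINO_ACIDS,
    CA = c(52.5, 56.0, 53.1, 54.2, 58.2, 55.7, 56.6, 45.1, 55.0, 61.1,
           55.1, 56.2, 55.4, 57.7, 63.3, 58.3, 61.8, 57.5, 57.9, 62.2),
    CB = c(19.1, 30.9, 38.9, 41.1, 28.0, 29.4, 29.9, NA, 29.0, 38.8,
           42.4, 33.1, 32.9, 39.6, 32.1, 63.8, 69.8, 29.6, 38.8, 32.9),
    HA = c(4.32, 4.34, 4.74, 4.64, 4.71, 4.34, 4.35, 3.96, 4.73, 4.17,
           4.34, 4.32, 4.48, 4.62, 4.42, 4.47, 4.35, 4.66, 4.55, 4.12),
    H  = c(8.24, 8.23, 8.40, 8.34, 8.32, 8.32, 8.42, 8.33, 8.42, 8.00,
           8.16, 8.29, 8.28, 8.30, NA, 8.31, 8.15, 8.25, 8.12, 8.03),
    N  = c(123.8, 120.5, 118.7, 120.4, 118.8, 119.8, 120.2, 108.8, 118.2,
           119.9, 121.8, 120.4, 119.6, 120.3, NA, 115.7, 113.6, 121.3,
           120.3, 119.2),
    stringsAsFactors = FALSE)
  corrections <- data.frame(
    nucleus = c("CA", "HA"),
    offset = c(1L, 1L),           # position relative to the observed residue
    neighbour = c("P", "P"),
    delta = c(-2.0, 0.10),
    stringsAsFactors = FALSE)
  out <- list(shifts = shifts,
              corrections = corrections,
              ref_temperature = ref_temperature,
              temp_coeff = c(H = 0, N = 0, HA = 0, CA = 0, CB = 0))
  class(out) <- "random_coil_table"
  out
}

#' Full secondary-shift reference magnitudes
#'
#' Expected secondary chemical shifts (observed minus random coil, ppm) for
#' residues in fully formed helix or extended strand, used to normalise
#' propensity scores. Consensus per-nucleus magnitudes from published
#' compilations, applied uniformly across residue types.
#'
#' @return data.frame with columns `nucleus`, `helix`, `sheet` (ppm).
#' @export
full_shift_table <- function() {
  data.frame(
    nucleus = c("CA", "CB", "HA"),
    helix = c(2.8, -0.38, -0.39),
    sheet = c(-1.5, 2.25, 0.37),
    stringsAsFactors = FALSE)
}
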