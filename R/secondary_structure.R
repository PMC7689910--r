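# Secondary chemical shifts, secondary structure propensities and amide
# temperature coefficients.

#' Sequence-corrected secondary chemical shifts
#'
#' Subtracts the random-coil reference (with nearest-neighbour sequence
#' corrections and optional temperature correction) from observed shifts.
#' Only nuclei present in the coil table are evaluated; combinations without
#' a coil entry (e.g. glycine CB) are skipped with a message.
#'
#' @param obs A `shift_table` of observed shifts.
#' @param seq `protein_sequence` covering all observed residues.
#' @param rc A [random_coil_table()].
#' @param temperature Sample temperature (K).
#' @param nuclei Nuclei to evaluate.
#' @return data.frame `residue_index`, `residue_type`, `nucleus`,
#'   `secondary_shift` (ppm, observed minus coil).
#' @export
secondary_shifts <- function(obs, seq, rc = random_coil_table(),
                             temperature = rc$ref_temperature,
                             nuclei = c("CA", "CB", "HA")) {
  sel <- obs$nucleus %in% nuclei
  o <- obs[sel, , drop = FALSE]
  stype <- residue_type_at(seq, o$residue_index)
  if (anyNA(stype))
    stop("residue(s) outside the sequence: ",
         paste(unique(o$residue_index[is.na(stype)]), collapse = ", "))
  mism <- which(stype != o$residue_type)
  if (length(mism))
    stop("sequence/table residue type mismatch at residue ",
         o$residue_index[mism[1]], " (", o$residue_type[mism[1]], " vs ",
         stype[mism[1]], ")")
  coil <- coil_shift(rc, seq, o$residue_index, o$nucleus, temperature)
  skip <- is.na(coil)
  if (any(skip))
    message("skipping ", sum(skip), " shift(s) without a random-coil entry ",
            "(e.g. ", o$residue_type[skip][1], " ", o$nucleus[skip][1], ")")
  data.frame(residue_index = o$residue_index[!skip],
             residue_type = o$residue_type[!skip],
             nucleus = o$nucleus[!skip],
             secondary_shift = o$shift[!skip] - coil[!skip],
             stringsAsFactors = FALSE)
}

#' Random-coil shift prediction for residues of a sequence
#'
#' @param rc A [random_coil_table()].
#' @param seq `protein_sequence`.
#' @param index Residue indices.
#' @param nucleus Nucleus per entry (recycled).
#' @param temperature Sample temperature (K).
#' @return Coil shifts in ppm (NA where the table has no entry).
#' @export
coil_shift <- function(rc, seq, index, nucleus,
                       temperature = rc$ref_temperature) {
  nucleus <- rep_len(nucleus, length(index))
  rt <- residue_type_at(seq, index)
  base <- mapply(function(r, n) {
    if (is.na(r) || !n %in% names(rc$shifts)) return(NA_real_)
    rc$shifts[[n]][match(r, rc$shifts$residue_type)]
  }, rt, nucleus)
  corr <- numeric(length(index))
  if (nrow(rc$corrections)) {
    for (k in seq_len(nrow(rc$corrections))) {
      cr <- rc$corrections[k, ]
      neigh <- residue_type_at(seq, index + cr$offset)
      hit <- !is.na(neigh) & neigh == cr$neighbour & nucleus == cr$nucleus
      corr[hit] <- corr[hit] + cr$delta
    }
  }
  tc <- rc$temp_coeff[nucleus]
  tc[is.na(tc)] <- 0
  unname(base + corr + tc * (temperature - rc$ref_temperature) / 1000)
}

#' Secondary structure propensity profile
#'
#' For each residue the secondary shifts of the available nuclei in a
#' centred window are summed (CB and HA contributions sign-inverted so that
#' helix-like deviations count positive) and normalised by the corresponding
#' full-structure secondary-shift magnitudes: helix magnitudes when the sum
#' is positive, strand magnitudes otherwise. +1 corresponds to a fully
#' formed helix, -1 to fully extended structure, 0 to random coil.
#'
#' @param sec Output of [secondary_shifts()].
#' @param window Odd window length in residues (default 5, i.e. i-2..i+2).
#' @param full Full secondary-shift reference, see [full_shift_table()].
#' @param nuclei Nuclei to use (intersection with available data).
#' @return data.frame of class `ssp_profile`: `residue_index`, `ssp`,
#'   `n_obs` (shifts contributing in the window); residues with no data in
#'   the window are absent.
#' @export
ssp_profile <- function(sec, window = 5L, full = full_shift_table(),
                        nuclei = c("CA", "CB", "HA")) {
  stopifnot(window >= 1L, window %% 2L == 1L)
  sec <- sec[sec$nucleus %in% nuclei, , drop = FALSE]
  if (!nrow(sec)) stop("no usable secondary shifts")
  sign_of <- stats::setNames(ifelse(full$nucleus == "CA", 1, -1), full$nucleus)
  helix_mag <- stats::setNames(abs(full$helix), full$nucleus)
  sheet_mag <- stats::setNames(abs(full$sheet), full$nucleus)
  half <- (window - 1L) %/% 2L
  res <- sort(unique(sec$residue_index))
  rows <- lapply(res, function(i) {
    w <- sec[abs(sec$residue_index - i) <= half, , drop = FALSE]
    if (!nrow(w)) return(NULL)
    num <- sum(sign_of[w$nucleus] * w$secondary_shift)
    mag <- if (num >= 0) helix_mag else sheet_mag
    den <- sum(mag[w$nucleus])
    data.frame(residue_index = i, ssp = num / den, n_obs = nrow(w))
  })
  out <- do.call(rbind, rows)
  attr(out, "window") <- window
  class(out) <- c("ssp_profile", "data.frame")
  out
}

#' Contiguous positive-propensity (helical) regions
#'
#' @param ssp An `ssp_profile`.
#' @param threshold Minimum propensity to count a residue helical.
#' @param min_len Minimum run length.
#' @return data.frame `start`, `end`, `length`.
#' @export
ssp_regions <- function(ssp, threshold = 0.2, min_len = 4L) {
  rng <- range(ssp$residue_index)
  idx <- rng[1]:rng[2]
  hit <- idx %in% ssp$residue_index[ssp$ssp >= threshold]
  r <- rle(hit)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  data.frame(start = idx[starts[keep]], end = idx[ends[keep]],
             length = r$lengths[keep])
}

#' Amide proton temperature coefficients
#'
#' Fits the amide 1H shift of each assigned residue against temperature by
#' least squares and classifies the slope: values above -4.5 ppb/K indicate
#' intramolecular hydrogen bonding, values below -9 ppb/K indicate amides in
#' fast exchange with solvent; the boundaries themselves fall in the
#' intermediate class.
#'
#' @param series List of assigned `peak_list`s, each carrying a
#'   `temperature` attribute (K); at least 3 temperatures spanning >= 10 K.
#' @param temperatures Optional explicit temperature vector overriding the
#'   attributes.
#' @return data.frame of class `tempco_profile`: `residue_index`,
#'   `slope_ppb_per_K`, `intercept_ppm`, `r_squared`, `n_points`, `class`.
#' @export
temp_coefficients <- function(series, temperatures = NULL) {
  if (is.null(temperatures))
    temperatures <- vapply(series, function(p) {
      tt <- attr(p, "temperature")
      if (is.null(tt)) NA_real_ else tt
    }, 0)
  if (anyNA(temperatures)) stop("missing temperatures for some peak lists")
  if (length(series) < 3L) stop("need peak lists at >= 3 temperatures")
  if (diff(range(temperatures)) < 10)
    stop("temperature range must span at least 10 K")
  res_all <- sort(unique(unlist(lapply(series, function(p)
    p$residue_index[!is.na(p$residue_index)]))))
  rows <- lapply(res_all, function(r) {
    w2 <- vapply(series, function(p) {
      i <- match(r, p$residue_index)
      if (is.na(i)) NA_real_ else p$w2[i]
    }, 0)
    ok <- !is.na(w2)
    if (sum(ok) < 3L) {
      message("residue ", r, ": fewer than 3 temperature points, skipped")
      return(NULL)
    }
    fit <- stats::lm(w2[ok] * 1000 ~ temperatures[ok])  # ppb vs K
    sl <- unname(stats::coef(fit)[2])
    y <- w2[ok] * 1000
    ss_tot <- sum((y - mean(y))^2)
    r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
    data.frame(residue_index = r, slope_ppb_per_K = sl,
               intercept_ppm = unname(stats::coef(fit)[1]) / 1000,
               r_squared = r2, n_points = sum(ok),
               class = classify_temp_coefficient(sl),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("tempco_profile", "data.frame")
  out
}

#' Classify an amide temperature coefficient
#'
#' @param slope Temperature coefficient(s) in ppb/K.
#' @param hbond_limit Slopes strictly above this value are `hbonded`.
#' @param exchange_limit Slopes strictly below this value are
#'   `fast_exchange`.
#' @return Character vector: `"hbonded"`, `"intermediate"` or
#'   `"fast_exchange"`.
#' @export
classify_temp_coefficient <- function(slope, hbond_limit = -4.5,
                                      exchange_limit = -9) {
  ifelse(slope > hbond_limit, "hbonded",
         ifelse(slope < exchange_limit, "fast_exchange", "intermediate"))
}
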