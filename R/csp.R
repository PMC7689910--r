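# Chemical-shift perturbation mapping across a titration.

#' Scaled 1H/15N peak distance
#'
#' Euclidean distance in ppm with the 15N axis compressed by `alpha`, the
#' metric used throughout for peak matching and cumulative shift changes.
#' @param dH,dN 1H and 15N differences (ppm).
#' @param alpha 15N scaling weight.
#' @return Numeric distances.
#' @keywords internal
scaled_ppm_distance <- function(dH, dN, alpha = 0.14) {
  sqrt(dH^2 + (alpha * dN)^2)
}

#' Cumulative amide chemical-shift changes between two states
#'
#' For every residue with amide H and N shifts in both states the combined
#' change is `sqrt(ddH^2 + (alpha*ddN)^2)`. Residues observed in the free
#' state but absent from the bound state are flagged `broadened` (signal lost
#' to intermediate-exchange line broadening); their `delta_cum` is NA.
#'
#' @param free,bound `shift_table`s of the two states (must share residue
#'   numbering).
#' @param alpha 15N weight (default 0.14, the common amide convention).
#' @return data.frame of class `csp_profile`: `residue_index`,
#'   `residue_type`, `delta_H`, `delta_N`, `delta_cum`, `broadened`,
#'   `perturbed` (NA until classified).
#' @examples
#' free <- shift_table(1:2, c("A","L"), rep("H",2), c(8.2, 8.3))
#' @export
cumulative_delta <- function(free, bound, alpha = 0.14) {
  stopifnot(alpha > 0)
  fH <- shifts_of(free, "H"); fN <- shifts_of(free, "N")
  bH <- shifts_of(bound, "H"); bN <- shifts_of(bound, "N")
  res_free <- intersect(names(fH), names(fN))
  res_bound <- intersect(names(bH), names(bN))
  if (!length(res_free))
    stop("no residues with amide shifts in the free state")
  both <- intersect(res_free, res_bound)
  if (!length(both))
    stop("no overlapping residues between the two tables")
  res <- sort(as.integer(res_free))
  rs <- as.character(res)
  broad <- !(rs %in% res_bound)
  dH <- ifelse(broad, NA_real_, abs(bH[rs] - fH[rs]))
  dN <- ifelse(broad, NA_real_, abs(bN[rs] - fN[rs]))
  types <- free$residue_type[match(res, free$residue_index)]
  out <- data.frame(residue_index = res, residue_type = types,
                    delta_H = unname(dH), delta_N = unname(dN),
                    delta_cum = unname(scaled_ppm_distance(dH, dN, alpha)),
                    broadened = broad, perturbed = NA,
                    stringsAsFactors = FALSE)
  attr(out, "alpha") <- alpha
  class(out) <- c("csp_profile", "data.frame")
  out
}

#' Classify residues as perturbed by binding
#'
#' A residue is perturbed when its cumulative shift change reaches the
#' threshold (default 0.15 ppm, the conventional limit below which residues
#' are regarded as non-perturbed) or when its resonance is broadened below
#' the detection limit.
#'
#' @param profile A `csp_profile`.
#' @param threshold Cumulative shift threshold in ppm.
#' @return The profile with `perturbed` filled in.
#' @export
classify_perturbed <- function(profile, threshold = 0.15) {
  stopifnot(threshold > 0)
  profile$perturbed <- (!is.na(profile$delta_cum) &
                          profile$delta_cum >= threshold) | profile$broadened
  attr(profile, "threshold") <- threshold
  profile
}

#' Contiguous perturbed regions
#'
#' Maximal runs of perturbed/broadened residues of at least `min_len`
#' residues. A single-residue gap is bridged only when the gap residue has no
#' data at all (e.g. a proline or an unassigned position), never when it was
#' observed and classified unperturbed.
#'
#' @param profile A classified `csp_profile`.
#' @param min_len Minimum region length.
#' @return data.frame with columns `start`, `end`, `length`.
#' @export
contiguous_regions <- function(profile, min_len = 3L) {
  if (all(is.na(profile$perturbed)))
    stop("profile not classified; run classify_perturbed() first")
  rng <- range(profile$residue_index)
  idx <- rng[1]:rng[2]
  status <- rep("nodata", length(idx))
  m <- match(profile$residue_index, idx)
  status[m] <- ifelse(profile$perturbed, "hit", "miss")
  status[m[is.na(profile$delta_cum) & !profile$broadened]] <- "nodata"
  # bridge single no-data residues flanked by hits
  n <- length(status)
  bridged <- status
  for (i in seq_len(n)) {
    if (status[i] == "nodata" && i > 1L && i < n &&
        status[i - 1L] == "hit" && status[i + 1L] == "hit")
      bridged[i] <- "hit"
  }
  r <- rle(bridged == "hit")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  data.frame(start = idx[starts[keep]], end = idx[ends[keep]],
             length = r$lengths[keep])
}

#' Fit a Lorentzian line to a 1D intensity profile
#'
#' Estimates the full width at half maximum of a single resonance in the
#' direct (1H) dimension by nonlinear least squares on
#' `A / (1 + ((x - x0)/(w/2))^2) + b`.
#'
#' @param freq_hz Sample positions (Hz), at least 8 spanning the peak.
#' @param intensity Intensities at those positions.
#' @return List with `fwhm_hz`, `center_hz`, `amplitude`, `baseline`,
#'   `se_fwhm` (standard error from the fit).
#' @export
linewidth_fwhm <- function(freq_hz, intensity) {
  stopifnot(length(freq_hz) == length(intensity))
  if (length(freq_hz) < 8L) stop("need at least 8 samples across the peak")
  if (any(!is.finite(intensity)) || diff(range(intensity)) <= 0)
    stop("flat or non-finite intensity profile")
  if (!is.unsorted(intensity) || !is.unsorted(rev(intensity)))
    stop("monotone intensity profile: no peak in window")
  b0 <- min(intensity)
  a0 <- max(intensity) - b0
  x0 <- freq_hz[which.max(intensity)]
  above <- freq_hz[intensity - b0 >= a0 / 2]
  w0 <- max(diff(range(above)), diff(range(freq_hz)) / 10)
  fit <- try(minpack.lm::nlsLM(
    intensity ~ A / (1 + ((freq_hz - x0)/(w/2))^2) + b,
    start = list(A = a0, x0 = x0, w = w0, b = b0),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error")) stop("Lorentzian fit failed to converge")
  co <- summary(fit)$coefficients
  if (co["w", "Estimate"] <= 0) stop("non-physical (non-positive) line width")
  list(fwhm_hz = abs(co["w", "Estimate"]), center_hz = co["x0", "Estimate"],
       amplitude = co["A", "Estimate"], baseline = co["b", "Estimate"],
       se_fwhm = co["w", "Std. Error"])
}

#' Track assigned peaks through a titration series
#'
#' Starting from the assigned first point, peaks are matched between
#' consecutive titration points by nearest neighbour in the scaled ppm metric
#' (1H weight 1, 15N weight `alpha`) subject to a maximum-jump gate. A
#' trajectory that finds no partner within the gate terminates (`broadened`);
#' two trajectories claiming the same target peak are both terminated and
#' flagged `ambiguous`.
#'
#' @param series List of `peak_list`s ordered by titration fraction; the
#'   first must be assigned.
#' @param alpha 15N weight in the matching metric.
#' @param gate Maximum scaled-ppm jump between consecutive points.
#' @return data.frame with one row per (residue, titration point):
#'   `residue_index`, `step`, `titration_fraction`, `w1`, `w2`, `height`,
#'   plus a `status` column per residue on the last tracked row
#'   (`complete`, `broadened` or `ambiguous`).
#' @export
track_titration <- function(series, alpha = 0.14, gate = 0.05) {
  stopifnot(length(series) >= 2L)
  first <- series[[1]]
  if (all(is.na(first$residue_index))) stop("first peak list is unassigned")
  fr <- vapply(series, function(p) {
    f <- attr(p, "titration_fraction")
    if (is.null(f) || is.na(f)) NA_real_ else f
  }, 0)
  if (!anyNA(fr) && is.unsorted(fr))
    stop("series not ordered by titration fraction")
  cur <- first[!is.na(first$residue_index), , drop = FALSE]
  traj <- data.frame(residue_index = cur$residue_index, step = 1L,
                     titration_fraction = fr[1], w1 = cur$w1, w2 = cur$w2,
                     height = cur$height, stringsAsFactors = FALSE)
  active <- stats::setNames(seq_len(nrow(cur)), cur$residue_index)
  pos <- cur[, c("w1", "w2")]
  status <- stats::setNames(rep("complete", nrow(cur)), cur$residue_index)
  for (s in seq_along(series)[-1]) {
    nxt <- series[[s]]
    if (!nrow(nxt) || !length(active)) {
      status[names(active)] <- "broadened"
      active <- active[0]
      next
    }
    target <- integer(0)
    dist_ok <- logical(0)
    for (r in names(active)) {
      i <- active[[r]]
      d <- scaled_ppm_distance(nxt$w2 - pos$w2[i], nxt$w1 - pos$w1[i], alpha)
      j <- which.min(d)
      target[r] <- j
      dist_ok[r] <- d[j] <= gate
    }
    lost <- names(active)[!dist_ok]
    status[lost] <- "broadened"
    kept <- names(active)[dist_ok]
    dup_targets <- unique(target[kept][duplicated(target[kept])])
    amb <- kept[target[kept] %in% dup_targets]
    status[amb] <- "ambiguous"
    kept <- setdiff(kept, amb)
    if (length(kept)) {
      j <- target[kept]
      traj <- rbind(traj, data.frame(
        residue_index = as.integer(kept), step = s,
        titration_fraction = fr[s], w1 = nxt$w1[j], w2 = nxt$w2[j],
        height = nxt$height[j], stringsAsFactors = FALSE))
      pos <- nxt[j, c("w1", "w2")]
      active <- stats::setNames(seq_along(kept), kept)
    } else {
      active <- active[0]
    }
  }
  traj$status <- status[as.character(traj$residue_index)]
  traj[order(traj$residue_index, traj$step), , drop = FALSE]
}

#' Detect peak doubling against one-chain reference positions
#'
#' For a homodimer whose two chains become inequivalent on asymmetric ligand
#' binding, residues may show two resolved amide peaks. Counts the peaks
#' lying within `gate` (scaled ppm) of each reference amide position: a count
#' of 2 marks chain asymmetry, 0 an intermediate-exchange-broadened
#' candidate.
#'
#' @param peaks A `peak_list` of the bound spectrum.
#' @param reference `shift_table` with amide H/N shifts of one chain.
#' @param gate Match radius in scaled ppm.
#' @param alpha 15N weight.
#' @return data.frame `residue_index`, `n_matched`, `asymmetric`.
#' @export
detect_peak_doubling <- function(peaks, reference, gate = 0.05, alpha = 0.14) {
  H <- shifts_of(reference, "H"); N <- shifts_of(reference, "N")
  res <- sort(as.integer(intersect(names(H), names(N))))
  n <- vapply(res, function(r) {
    d <- scaled_ppm_distance(peaks$w2 - H[[as.character(r)]],
                             peaks$w1 - N[[as.character(r)]], alpha)
    sum(d <= gate)
  }, 0L)
  data.frame(residue_index = res, n_matched = n, asymmetric = n == 2L)
}
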