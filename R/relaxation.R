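# 15N relaxation: decay fitting, heteronuclear NOE, reduced spectral density
# mapping and mobility grouping.

#' Default longitudinal (T1) delay schedule
#'
#' Ten variable delays spanning 0.01-2 s with one delay recorded twice for a
#' reproducibility check.
#' @param duplicate Record one delay twice.
#' @return Numeric vector of delays (s); the repeated delay appears twice.
#' @export
t1_delay_schedule <- function(duplicate = TRUE) {
  d <- exp(seq(log(0.01), log(2), length.out = 10))
  d <- round(d, 4)
  if (duplicate) d <- sort(c(d, d[5]))
  d
}

#' Default transverse (T2) delay schedule
#'
#' Eleven delays spanning 0.03-1.36 s with one delay recorded twice.
#' @param duplicate Record one delay twice.
#' @return Numeric vector of delays (s).
#' @export
t2_delay_schedule <- function(duplicate = TRUE) {
  d <- round(seq(0.03, 1.36, length.out = 11), 4)
  if (duplicate) d <- sort(c(d, d[4]))
  d
}

#' Construct a relaxation decay series
#'
#' @param residue_index,delay,intensity Parallel vectors: residue, delay (s)
#'   and peak intensity.
#' @param experiment `"T1"` or `"T2"`.
#' @return data.frame of class `decay_series`.
#' @export
decay_series <- function(residue_index, delay, intensity,
                         experiment = c("T1", "T2")) {
  experiment <- match.arg(experiment)
  df <- data.frame(residue_index = as.integer(residue_index),
                   delay = as.numeric(delay),
                   intensity = as.numeric(intensity))
  if (any(df$delay < 0)) stop("negative delay")
  attr(df, "experiment") <- experiment
  class(df) <- c("decay_series", "data.frame")
  df
}

#' Read a decay series from TSV (`residue delay_s intensity`)
#' @param path Input file.
#' @param experiment `"T1"` or `"T2"`.
#' @return A `decay_series`.
#' @export
read_decay_series <- function(path, experiment = c("T1", "T2")) {
  df <- utils::read.table(path, header = FALSE, comment.char = "#",
                          col.names = c("residue_index", "delay", "intensity"))
  decay_series(df$residue_index, df$delay, df$intensity,
               experiment = match.arg(experiment))
}

#' Fit single-exponential intensity decays
#'
#' Per residue, fits `I(t) = I0 * exp(-R * t)` by nonlinear least squares
#' (Levenberg-Marquardt, log-linear start). Residues whose intensities
#' increase with delay (non-positive rate) are flagged `unfittable` and
#' should be excluded downstream. When a delay occurs twice, the pair is
#' used as a reproducibility check: a discrepancy beyond 3x the fit residual
#' noise flags the residue `irreproducible`.
#'
#' @param series A `decay_series`.
#' @param min_delays Minimum usable delays per residue.
#' @return data.frame of class `rate_table`: `residue_index`, `rate` (s^-1),
#'   `sigma` (s^-1), `I0`, `flag` (`ok`, `unfittable`, `irreproducible`).
#' @export
fit_exponential_decay <- function(series, min_delays = 5L) {
  rows <- lapply(split(series, series$residue_index), function(d) {
    r <- d$residue_index[1]
    if (nrow(d) < min_delays)
      return(data.frame(residue_index = r, rate = NA_real_, sigma = NA_real_,
                        I0 = NA_real_, flag = "too_few_delays"))
    pos <- d$intensity > 0
    slope <- if (sum(pos) >= 2L)
      unname(stats::coef(stats::lm(log(d$intensity[pos]) ~ d$delay[pos]))[2])
    else 0
    if (!is.finite(slope) || slope >= 0)
      return(data.frame(residue_index = r, rate = NA_real_, sigma = NA_real_,
                        I0 = NA_real_, flag = "unfittable"))
    i0 <- max(d$intensity)
    fit <- try(minpack.lm::nlsLM(
      intensity ~ I0 * exp(-R * delay), data = d,
      start = list(I0 = i0, R = -slope),
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    if (inherits(fit, "try-error"))
      return(data.frame(residue_index = r, rate = NA_real_, sigma = NA_real_,
                        I0 = NA_real_, flag = "unfittable"))
    co <- summary(fit)$coefficients
    if (co["R", "Estimate"] <= 0)
      return(data.frame(residue_index = r, rate = NA_real_, sigma = NA_real_,
                        I0 = NA_real_, flag = "unfittable"))
    flag <- "ok"
    dup <- d$delay[duplicated(d$delay)]
    if (length(dup)) {
      noise <- stats::sd(stats::residuals(fit))
      for (t0 in unique(dup)) {
        ii <- d$intensity[d$delay == t0]
        if (noise > 0 && abs(diff(range(ii))) > 3 * noise) flag <- "irreproducible"
      }
    }
    data.frame(residue_index = r, rate = co["R", "Estimate"],
               sigma = co["R", "Std. Error"], I0 = co["I0", "Estimate"],
               flag = flag, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$residue_index), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("rate_table", "data.frame")
  out
}

#' Steady-state heteronuclear NOE from saturated/unsaturated intensities
#'
#' `hetNOE = I_sat / I_unsat` per residue. Residues whose unsaturated
#' intensity is below the noise floor are returned as NA with a message.
#'
#' @param sat,unsat data.frames with `residue_index` and `intensity`.
#' @param noise Intensity noise level (same units); used both for the noise
#'   floor (`3 * noise`) and for the propagated NOE uncertainty.
#' @return data.frame `residue_index`, `noe`, `sigma_noe`.
#' @export
het_noe <- function(sat, unsat, noise = 0) {
  res <- intersect(sat$residue_index, unsat$residue_index)
  is_ <- sat$intensity[match(res, sat$residue_index)]
  iu <- unsat$intensity[match(res, unsat$residue_index)]
  undef <- abs(iu) <= 3 * noise
  if (any(undef))
    message("hetNOE undefined for residue(s) ",
            paste(res[undef], collapse = ", "),
            " (unsaturated intensity at the noise floor)")
  noe <- ifelse(undef, NA_real_, is_ / iu)
  sig <- ifelse(undef, NA_real_,
                abs(noe) * sqrt((noise / is_)^2 + (noise / iu)^2))
  out <- data.frame(residue_index = res, noe = noe, sigma_noe = sig)
  out[order(out$residue_index), , drop = FALSE]
}

#' Assemble a per-residue relaxation record
#'
#' @param R1,R2 `rate_table`s from [fit_exponential_decay()] (T1 and T2
#'   experiments; rates in s^-1).
#' @param noe Output of [het_noe()].
#' @param ctx A [spectrometer_context()].
#' @return data.frame of class `relaxation_record`: `residue_index`, `R1`,
#'   `sigma_R1`, `R2`, `sigma_R2`, `noe`, `sigma_noe`; unfittable residues
#'   are dropped. hetNOE values above ~1.1 are physically implausible at
#'   high field and trigger a warning only.
#' @export
relaxation_record <- function(R1, R2, noe, ctx = spectrometer_context()) {
  ok1 <- R1[R1$flag %in% c("ok", "irreproducible"), ]
  ok2 <- R2[R2$flag %in% c("ok", "irreproducible"), ]
  res <- Reduce(intersect, list(ok1$residue_index, ok2$residue_index,
                                noe$residue_index[!is.na(noe$noe)]))
  res <- sort(res)
  out <- data.frame(
    residue_index = res,
    R1 = ok1$rate[match(res, ok1$residue_index)],
    sigma_R1 = ok1$sigma[match(res, ok1$residue_index)],
    R2 = ok2$rate[match(res, ok2$residue_index)],
    sigma_R2 = ok2$sigma[match(res, ok2$residue_index)],
    noe = noe$noe[match(res, noe$residue_index)],
    sigma_noe = noe$sigma_noe[match(res, noe$residue_index)])
  if (any(out$noe > 1.1))
    warning("hetNOE > 1.1 for residue(s) ",
            paste(out$residue_index[out$noe > 1.1], collapse = ", "),
            ": physically implausible for 15N at high field")
  attr(out, "context") <- ctx
  class(out) <- c("relaxation_record", "data.frame")
  out
}

#' Reduced spectral density mapping
#'
#' Inverts R1, R2 and hetNOE into the spectral density sampled at three
#' frequencies, using the standard single-high-frequency reduction in which
#' the 1H-frequency combinations are represented by J(0.87 wH):
#' \deqn{\sigma_{NH} = R_1 (NOE - 1) \gamma_N/\gamma_H}
#' \deqn{J(0.87\omega_H) = 4\sigma_{NH}/(5 d^2)}
#' \deqn{J(\omega_N) = (R_1 - 7 d^2/4 \, J(0.87\omega_H)) / (3 d^2/4 + c^2)}
#' \deqn{J(0) = (R_2 - (3d^2/8 + c^2/2) J(\omega_N) - 13 d^2/8 \,
#'   J(0.87\omega_H)) / (d^2/2 + 2 c^2/3)}
#' with `d2` the squared N-H dipolar coupling constant and
#' `c2 = (wN * dsigma)^2 / 3`. No exchange term is separated: conformational
#' exchange inflates the apparent J(0), which is how elevated J(0) values
#' are read as exchange candidates.
#'
#' Uncertainties are propagated by Monte Carlo resampling of (R1, R2, NOE)
#' from their fitted standard errors.
#'
#' @param rec A `relaxation_record`.
#' @param n_mc Monte Carlo draws for error propagation (0 disables).
#' @return data.frame of class `spectral_density_map`: `residue_index`,
#'   `J0`, `JwN`, `JwH087` (s/rad) with `sigma_*` columns and a `clamped`
#'   flag for residues whose hetNOE > 1 forced J(0.87 wH) below 0.
#' @export
reduced_spectral_density <- function(rec, n_mc = 200L) {
  ctx <- attr(rec, "context")
  if (is.null(ctx)) stop("relaxation record lacks a spectrometer context")
  invert <- function(R1, R2, noe) {
    sigma_NH <- R1 * (noe - 1) * ctx$gamma_ratio_NH
    JH <- 4 * sigma_NH / (5 * ctx$d2)
    clamped <- JH < 0
    JH[clamped] <- 0
    JN <- (R1 - (7 * ctx$d2 / 4) * JH) / (3 * ctx$d2 / 4 + ctx$c2)
    J0 <- (R2 - (3 * ctx$d2 / 8 + ctx$c2 / 2) * JN -
             (13 * ctx$d2 / 8) * JH) / (ctx$d2 / 2 + 2 * ctx$c2 / 3)
    list(J0 = J0, JN = JN, JH = JH, clamped = clamped)
  }
  est <- invert(rec$R1, rec$R2, rec$noe)
  if (any(est$clamped))
    warning("hetNOE > 1 for residue(s) ",
            paste(rec$residue_index[est$clamped], collapse = ", "),
            ": J(0.87wH) clamped to 0")
  sJ0 <- sJN <- sJH <- rep(NA_real_, nrow(rec))
  if (n_mc > 0 && all(is.finite(rec$sigma_R1)) && all(is.finite(rec$sigma_R2))) {
    draws <- replicate(n_mc, {
      mc <- invert(stats::rnorm(nrow(rec), rec$R1, rec$sigma_R1),
                   stats::rnorm(nrow(rec), rec$R2, rec$sigma_R2),
                   stats::rnorm(nrow(rec), rec$noe,
                                ifelse(is.na(rec$sigma_noe), 0,
                                       rec$sigma_noe)))
      c(mc$J0, mc$JN, mc$JH)
    })
    n <- nrow(rec)
    sJ0 <- apply(draws[seq_len(n), , drop = FALSE], 1, stats::sd)
    sJN <- apply(draws[n + seq_len(n), , drop = FALSE], 1, stats::sd)
    sJH <- apply(draws[2 * n + seq_len(n), , drop = FALSE], 1, stats::sd)
  }
  out <- data.frame(residue_index = rec$residue_index,
                    J0 = est$J0, JwN = est$JN, JwH087 = est$JH,
                    sigma_J0 = sJ0, sigma_JwN = sJN, sigma_JwH087 = sJH,
                    clamped = est$clamped)
  nonmono <- stats::na.omit(out$J0 < out$JwN | out$JwN < out$JwH087)
  if (any(nonmono))
    warning("non-monotone spectral density for some residues ",
            "(exchange or noise can inflate/deflate individual points)")
  attr(out, "context") <- ctx
  class(out) <- c("spectral_density_map", "data.frame")
  out
}

#' Single-motion locus in the (J(0), J(wN)) plane
#'
#' Parametric curve traced by a single-correlation-time (one-Lorentzian)
#' spectral density: `J(0) = (2/5) tau`, `J(wN) = (2/5) tau / (1 + (wN
#' tau)^2)`. Residues falling on the curve behave as single-timescale
#' (highly mobile, exchange-free) sites; points far above it at a given
#' J(wN) indicate slowed tumbling and/or exchange.
#'
#' @param ctx A [spectrometer_context()].
#' @param tau Correlation-time grid in seconds.
#' @return data.frame `tau`, `J0`, `JwN` (s/rad).
#' @export
single_motion_curve <- function(ctx = spectrometer_context(),
                                tau = 10^seq(-11, -7.5, length.out = 400)) {
  data.frame(tau = tau, J0 = 0.4 * tau,
             JwN = 0.4 * tau / (1 + (ctx$omega_N * tau)^2))
}

#' Correlation time(s) on the single-motion curve for a given J(wN)
#'
#' Solves `JwN = 0.4 tau / (1 + (wN tau)^2)`. Returns the slow-motion (larger
#' tau) root, or NA when `JwN` exceeds the curve maximum.
#' @param JwN J(wN) values (s/rad).
#' @param ctx A [spectrometer_context()].
#' @return tau in seconds.
#' @keywords internal
tau_from_JwN <- function(JwN, ctx) {
  a <- JwN * ctx$omega_N^2
  disc <- 0.16 - 4 * a * JwN
  ifelse(disc < 0, NA_real_, (0.4 + sqrt(pmax(disc, 0))) / (2 * a))
}

#' Group residues by mobility from their spectral densities
#'
#' Partitions residues into four ordered groups of increasing J(0) (group I:
#' most mobile termini-like residues; group IV: most rigid / exchange-prone
#' sites), either at user-supplied J(0) boundaries or by deterministic 1-D
#' k-means (k = 4, quantile initialisation). Residues whose J(0) exceeds the
#' single-motion-curve value consistent with their J(wN) by at least
#' `exchange_factor` are additionally flagged exchange-suspect.
#'
#' @param jmap A `spectral_density_map`.
#' @param boundaries Optional increasing vector of 3 J(0) cut points.
#' @param exchange_factor Flag threshold on J0 / J0_curve(JwN).
#' @return `jmap` with columns `group` (factor I-IV) and
#'   `exchange_suspect`.
#' @export
group_residues <- function(jmap, boundaries = NULL, exchange_factor = 2) {
  ok <- is.finite(jmap$J0)
  x <- jmap$J0[ok]
  grp <- rep(NA_character_, nrow(jmap))
  labels <- c("I", "II", "III", "IV")
  if (length(x) < 4L || length(unique(x)) < 4L) {
    warning("fewer than 4 distinct J(0) values: single-group fallback")
    grp[ok] <- "I"
  } else if (!is.null(boundaries)) {
    stopifnot(length(boundaries) == 3L, !is.unsorted(boundaries))
    grp[ok] <- labels[findInterval(x, boundaries) + 1L]
  } else {
    centers <- stats::quantile(x, c(0.125, 0.375, 0.625, 0.875), names = FALSE)
    centers <- centers + seq(0, 1e-12, length.out = 4L)  # force distinct
    km <- stats::kmeans(x, centers = matrix(centers, ncol = 1))
    ord <- order(km$centers)
    grp[ok] <- labels[match(km$cluster, ord)]
  }
  curve_J0 <- 0.4 * tau_from_JwN(jmap$JwN, attr(jmap, "context"))
  jmap$group <- factor(grp, levels = labels)
  jmap$exchange_suspect <- !is.na(curve_J0) & is.finite(jmap$J0) &
    jmap$J0 >= exchange_factor * curve_J0
  jmap
}
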