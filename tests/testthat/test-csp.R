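# Chemical-shift perturbation mapping.

amide_table <- function(idx, H, N, types = NULL, state = "free") {
  if (is.null(types)) types <- rep("A", length(idx))
  shift_table(c(idx, idx), c(types, types),
              c(rep("H", length(idx)), rep("N", length(idx))), c(H, N),
              state = state)
}

test_that("cumulative delta combines 1H and scaled 15N changes", {
  free <- amide_table(1:3, c(8.2, 8.3, 8.1), c(120, 121, 119))
  bound <- amide_table(1:3, c(8.2, 8.39, 8.1), c(120, 121.857, 119),
                       state = "bound")
  prof <- cumulative_delta(free, bound, alpha = 0.14)
  expect_equal(prof$delta_cum[1], 0)
  # ddH = 0.09, ddN = 0.857: sqrt(0.0081 + 0.0144) = 0.15
  expect_equal(prof$delta_cum[2], 0.15, tolerance = 1e-3)
  expect_false(any(prof$broadened))
})

test_that("cumulative delta is symmetric in the states and homogeneous", {
  set.seed(42)
  for (rep in 1:20) {
    idx <- 1:6
    f <- amide_table(idx, 8 + runif(6, 0, 0.5), 115 + runif(6, 0, 10))
    b <- amide_table(idx, 8 + runif(6, 0, 0.5), 115 + runif(6, 0, 10),
                     state = "bound")
    p1 <- cumulative_delta(f, b)
    p2 <- cumulative_delta(b, f)
    expect_equal(p1$delta_cum, p2$delta_cum)
    # scaling both component deltas by k scales delta_cum by k
    k <- 3
    b2 <- amide_table(idx, f$shift[1:6] + k * (b$shift[1:6] - f$shift[1:6]),
                      f$shift[7:12] + k * (b$shift[7:12] - f$shift[7:12]),
                      state = "bound")
    expect_equal(cumulative_delta(f, b2)$delta_cum, k * p1$delta_cum,
                 tolerance = 1e-10)
  }
})

test_that("residues lost from the bound spectrum are flagged broadened", {
  free <- amide_table(1:3, c(8.2, 8.3, 8.1), c(120, 121, 119))
  bound <- amide_table(c(1L, 3L), c(8.2, 8.1), c(120, 119), state = "bound")
  prof <- cumulative_delta(free, bound)
  expect_equal(prof$broadened, c(FALSE, TRUE, FALSE))
  expect_true(is.na(prof$delta_cum[2]))
  prof <- classify_perturbed(prof)
  expect_true(prof$perturbed[2])  # broadened counts as perturbed
})

test_that("cumulative delta requires overlapping residues", {
  free <- amide_table(1:2, c(8.2, 8.3), c(120, 121))
  bound <- amide_table(10:11, c(8.2, 8.3), c(120, 121), state = "bound")
  # no shared residues at all: every free residue would look broadened
  expect_error(cumulative_delta(free, bound), "overlap")
})

test_that("perturbation classification switches exactly at the threshold", {
  prof <- data.frame(residue_index = 1:3, residue_type = "A",
                     delta_H = 0, delta_N = 0,
                     delta_cum = c(0.16, 0.14, 0.15), broadened = FALSE,
                     perturbed = NA)
  class(prof) <- c("csp_profile", "data.frame")
  out <- classify_perturbed(prof, threshold = 0.15)
  expect_equal(out$perturbed, c(TRUE, FALSE, TRUE))
})

test_that("contiguous regions bridge data-free gaps but not observed dips", {
  mk <- function(idx, cum, broad = rep(FALSE, length(idx))) {
    p <- data.frame(residue_index = idx, residue_type = "A", delta_H = cum,
                    delta_N = 0, delta_cum = cum, broadened = broad,
                    perturbed = NA)
    class(p) <- c("csp_profile", "data.frame")
    classify_perturbed(p)
  }
  # single run
  p <- mk(15:35, ifelse(15:35 %in% 20:29, 0.3, 0.01))
  expect_equal(contiguous_regions(p, min_len = 3),
               data.frame(start = 20L, end = 29L, length = 10L))
  # residue 25 has no data (absent row): gap bridged
  idx <- setdiff(15:35, 25L)
  p <- mk(idx, ifelse(idx %in% 20:29, 0.3, 0.01))
  expect_equal(contiguous_regions(p, min_len = 3)$start, 20L)
  expect_equal(contiguous_regions(p, min_len = 3)$end, 29L)
  # residue 25 observed but unperturbed: run splits
  p <- mk(15:35, ifelse(15:35 %in% setdiff(20:29, 25L), 0.3, 0.01))
  r <- contiguous_regions(p, min_len = 3)
  expect_equal(nrow(r), 2L)
  # nothing perturbed
  p <- mk(15:35, rep(0.01, 21))
  expect_equal(nrow(contiguous_regions(p)), 0L)
})

test_that("Lorentzian line-width fits recover known widths", {
  x <- seq(-150, 150, length.out = 61)
  lor <- function(x, w) 1 / (1 + (x / (w / 2))^2)
  fit <- linewidth_fwhm(x, lor(x, 20))
  expect_equal(fit$fwhm_hz, 20, tolerance = 0.1 / 20)
  # 5% additive noise on a 120 Hz line, repeated fits stay within 10 Hz
  set.seed(7)
  x2 <- seq(-400, 400, length.out = 121)
  est <- replicate(50, {
    linewidth_fwhm(x2, lor(x2, 120) + rnorm(121, 0, 0.05))$fwhm_hz
  })
  expect_lt(max(abs(est - 120)), 10)
  expect_error(linewidth_fwhm(x, rep(1, 61)), "flat")
  expect_error(linewidth_fwhm(x, seq(0.1, 1, length.out = 61)), "monotone")
  expect_error(linewidth_fwhm(x[1:5], lor(x[1:5], 20)), "8 samples")
})

test_that("titration tracking follows, terminates and disambiguates trajectories", {
  mk_list <- function(frac, w1, w2, lab = NULL) {
    if (is.null(lab)) lab <- rep("?-?", length(w1))
    peak_list(lab, w1, w2, 1, titration_fraction = frac)
  }
  # residue 1 moves steadily; residue 2 vanishes after step 2
  s <- list(
    mk_list(0.0, c(120, 115), c(8.00, 8.50), c("A1N-H", "A2N-H")),
    mk_list(0.3, c(120, 115), c(8.01, 8.51)),
    mk_list(0.6, 120, 8.02),
    mk_list(0.9, 120, 8.03),
    mk_list(1.15, 120, 8.04))
  tr <- track_titration(s, gate = 0.05)
  t1 <- tr[tr$residue_index == 1, ]
  t2 <- tr[tr$residue_index == 2, ]
  expect_equal(nrow(t1), 5L)
  expect_equal(t1$status[1], "complete")
  expect_equal(t1$w2, seq(8.00, 8.04, by = 0.01))
  expect_equal(nrow(t2), 2L)
  expect_equal(t2$status[1], "broadened")
  # two assigned peaks collapsing onto one target peak -> both ambiguous
  s2 <- list(
    mk_list(0, c(120.0, 120.2), c(8.00, 8.004), c("A1N-H", "A2N-H")),
    mk_list(0.5, 120.1, 8.002))
  tr2 <- track_titration(s2, gate = 0.1)
  expect_setequal(unique(tr2$status), "ambiguous")
  expect_equal(max(tr2$step), 1L)
})

test_that("peak doubling counts resolved chain copies", {
  ref <- shift_table(c(10L, 10L, 11L, 11L, 12L, 12L),
                     rep(c("A", "L", "S"), each = 2),
                     rep(c("H", "N"), 3), c(8.2, 120, 8.5, 122, 8.8, 118))
  pk <- peak_list(rep("?-?", 4),
                  w1 = c(120, 122, 122.05, 125),
                  w2 = c(8.2, 8.475, 8.525, 8.0))
  out <- detect_peak_doubling(pk, ref, gate = 0.06)
  expect_equal(out$n_matched, c(1L, 2L, 0L))
  expect_equal(out$asymmetric, c(FALSE, TRUE, FALSE))
})
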