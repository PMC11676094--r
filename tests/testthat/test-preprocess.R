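test_that("reference calibration shifts the axis so the peak sits at the reference", {
  ax <- seq(-0.2, 0.6, by = 0.001)
  tsp <- nmr_spectrum(ax, lorentzian_profile(0, 0.002, ax), "s1")
  expect_equal(reference_calibrate(tsp, 0)$ppm, ax)   # already calibrated

  shifted <- nmr_spectrum(ax, lorentzian_profile(0.004, 0.002, ax), "s2")
  cal <- reference_calibrate(shifted, 0, c(-0.2, 0.2))
  expect_equal(cal$ppm, ax - 0.004, tolerance = 1e-12)
  expect_identical(cal$intensity, shifted$intensity)

  flat <- nmr_spectrum(ax, rep(1, length(ax)), "s3")
  expect_error(reference_calibrate(flat, 0), "flat")
  expect_error(reference_calibrate(tsp, 0, c(5, 6)), "no points")
})

test_that("two spectra differing by a rigid shift coincide after calibration", {
  ax <- seq(0.5, 2.5, by = 0.001)
  shape <- function(x) {
    lorentzian_profile(1.33, 0.003, x) + 0.5 * lorentzian_profile(2.0, 0.004, x)
  }
  a <- nmr_spectrum(ax, shape(ax), "a")
  b <- nmr_spectrum(ax, shape(ax - 0.01), "b")   # +0.01 ppm apparent shift
  ca <- reference_calibrate(a, 1.33, c(1.2, 1.5))
  cb <- reference_calibrate(b, 1.33, c(1.2, 1.5))
  common <- seq(1.0, 2.2, by = 0.001)
  ia <- stats::approx(ca$ppm, ca$intensity, common)$y
  ib <- stats::approx(cb$ppm, cb$intensity, common)$y
  expect_lt(max(abs(ia - ib)), 1e-9)
})

test_that("binning tiles the axis and conserves the total integral", {
  # constant intensity: every bin integral is c * width
  ax <- seq(0, 1, by = 0.0005)
  const <- nmr_spectrum(ax, rep(3, length(ax)), "c")
  bc <- bin_spectrum(const, 0.005)
  expect_length(bc$bin_integrals, 200)
  expect_equal(bc$bin_integrals, rep(3 * 0.005, 200), tolerance = 1e-12)
  expect_equal(bc$bin_centers[1], 0.0025)

  # irregular spectrum: sum of bins equals full-axis quadrature
  set.seed(42)
  ax2 <- seq(0, 10, length.out = 7001)
  y2 <- abs(stats::filter(rnorm(7001), rep(0.2, 5), circular = TRUE)) + 0.1
  sp <- nmr_spectrum(ax2, as.numeric(y2), "r")
  b2 <- bin_spectrum(sp, 0.005)
  expect_lt(abs(sum(b2$bin_integrals) - trapz(ax2, sp$intensity)) /
              trapz(ax2, sp$intensity), 1e-9)

  # narrow Lorentzian inside one bin interior carries >99% of the integral
  ax3 <- seq(0.9, 1.1, by = 2e-6)
  y3 <- lorentzian_profile(1.0025, 2e-5, ax3)
  b3 <- bin_spectrum(nmr_spectrum(ax3, y3, "l"), 0.005)
  expect_gt(max(b3$bin_integrals) / sum(b3$bin_integrals), 0.99)

  expect_error(bin_spectrum(const, 0), "positive")
  expect_error(bin_spectrum(const, -1), "positive")
})

test_that("exclusion schemes drop exactly the bins with centres in the windows", {
  centers <- seq(0.0025, 9.9975, by = 0.005)
  values <- matrix(1, nrow = 2, ncol = length(centers))
  bm <- nmrstress:::new_binned_matrix(centers, values, c("a", "b"),
                                      c("control", "case"), "none", NULL)
  schemes <- list(
    plasma = cbind(c(4.20, 5.40), c(5.10, 5.90)),
    urine  = cbind(c(4.14, 5.35), c(5.25, 5.90)),
    tissue = cbind(c(3.31, 4.67), c(3.40, 5.22)))
  for (mt in names(schemes)) {
    kept <- apply_exclusions(bm, exclusion_scheme(mt))$bin_centers
    w <- schemes[[mt]]
    # brute-force membership oracle over every bin centre
    inside <- vapply(centers, function(p) {
      any(p >= w[, 1] & p < w[, 2])
    }, logical(1))
    expect_identical(kept, centers[!inside], info = mt)
  }
  # spot checks: plasma drops 5.50 and 4.50, retains 6.00
  plasma_kept <- apply_exclusions(bm, exclusion_scheme("plasma"))$bin_centers
  expect_false(any(abs(plasma_kept - 5.50) < 0.0024))
  expect_false(any(abs(plasma_kept - 4.50) < 0.0024))
  expect_true(any(abs(plasma_kept - 6.0025) < 1e-9))
})

test_that("excluding after binning equals binning the retained segments (edge-aligned windows)", {
  set.seed(9)
  ax <- seq(0, 10, by = 0.0025)   # grid and bin edges hit window borders exactly
  y <- abs(as.numeric(stats::filter(rnorm(length(ax)), rep(0.25, 4),
                                    circular = TRUE))) + 0.05
  sp <- nmr_spectrum(ax, y, "s")
  full <- bin_cohort(list(sp), 0.005)
  dropped <- apply_exclusions(full, exclusion_scheme("plasma"))

  segs <- list(c(0, 4.20), c(5.10, 5.40), c(5.90, 10))
  seg_bins <- lapply(segs, function(sg) {
    sel <- ax >= sg[1] - 1e-12 & ax <= sg[2] + 1e-12
    bin_spectrum(nmr_spectrum(ax[sel], y[sel], "s"), 0.005)
  })
  expect_equal(dropped$bin_centers,
               unlist(lapply(seg_bins, `[[`, "bin_centers")),
               tolerance = 1e-9)
  expect_equal(as.numeric(dropped$values),
               unlist(lapply(seg_bins, `[[`, "bin_integrals")),
               tolerance = 1e-9)
})

test_that("row normalization rescales, is idempotent, and PQN undoes dilution", {
  centers <- seq(0.0025, 0.9975, by = 0.005)
  profile <- exp(-((centers - 0.5) / 0.1)^2) + 0.05
  mk <- function(v) nmrstress:::new_binned_matrix(
    centers, v, paste0("s", seq_len(nrow(v))),
    rep(c("control", "case"), length.out = nrow(v)), "none", NULL)

  # a row already at the target stays put; proportional rows coincide
  v <- rbind(profile * (100 / sum(profile)), 2 * profile, 5 * profile)
  n1 <- normalize_rows(mk(v), "total_area", target = 100)
  expect_equal(n1$values[1, ], v[1, ], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(n1$values[2, ], n1$values[3, ], tolerance = 1e-12)
  expect_equal(unname(rowSums(n1$values)), rep(100, 3), tolerance = 1e-9)
  # idempotence
  n2 <- normalize_rows(n1, "total_area", target = 100)
  expect_equal(n2$values, n1$values, tolerance = 1e-12)

  # PQN recovers a common profile from exact scalar dilutions
  dil <- c(1, 0.5, 0.25, 0.8)
  vd <- t(vapply(dil, function(a) a * profile, numeric(length(profile))))
  np <- normalize_rows(mk(vd), "probabilistic_quotient")
  for (i in 2:4) expect_lt(max(abs(np$values[i, ] - np$values[1, ])), 1e-9)
  expect_identical(np$normalization_tag, "probabilistic_quotient")

  zero <- mk(rbind(profile, 0 * profile))
  expect_error(normalize_rows(zero, "total_area"), "s2")
})
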