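#' Rigid peak-position calibration of a spectrum
#'
#' Shifts the ppm axis rigidly so that the tallest point inside
#' `search_window` sits exactly at `reference_ppm`. Used to reference plasma
#' spectra to the lactate CH3 signal at 1.33 ppm and urine/tissue spectra to
#' TSP at 0 ppm. Intensities are unchanged; only the axis moves.
#'
#' @param spectrum An [nmr_spectrum()].
#' @param reference_ppm Target position of the reference peak.
#' @param search_window Numeric length-2 vector `(low, high)` bracketing the
#'   reference peak on the current axis.
#' @return The calibrated [nmr_spectrum()].
#' @export
reference_calibrate <- function(spectrum, reference_ppm,
                                search_window = reference_ppm + c(-0.1, 0.1)) {
  stopifnot(inherits(spectrum, "nmr_spectrum"), length(search_window) == 2)
  search_window <- sort(search_window)
  inside <- spectrum$ppm >= search_window[1] & spectrum$ppm <= search_window[2]
  if (!any(inside)) stop("calibration failure: search window contains no points")
  y <- spectrum$intensity[inside]
  if (max(y) - min(y) <= 0) {
    stop("calibration failure: search window is flat (no local maximum)")
  }
  peak_ppm <- spectrum$ppm[inside][which.max(y)]
  spectrum$ppm <- spectrum$ppm + (reference_ppm - peak_ppm)
  spectrum
}

#' Bin a spectrum into fixed-width buckets
#'
#' Segments the axis into half-open bins `[low, low + width)` anchored at the
#' axis minimum and integrates the piecewise-linear (trapezoid) interpolant
#' of the intensity over each bin. Because bin integrals are differences of
#' the exact cumulative integral at the bin edges, their sum telescopes to
#' the total spectrum integral to machine precision.
#'
#' @param spectrum An [nmr_spectrum()].
#' @param bin_width_ppm Bucket width in ppm; the field-standard default is
#'   0.005.
#' @return List with `bin_centers` (ppm, ascending) and `bin_integrals`.
#' @export
bin_spectrum <- function(spectrum, bin_width_ppm = 0.005) {
  stopifnot(inherits(spectrum, "nmr_spectrum"))
  if (!is.numeric(bin_width_ppm) || length(bin_width_ppm) != 1 ||
      bin_width_ppm <= 0) {
    stop("`bin_width_ppm` must be a single positive number")
  }
  ppm <- spectrum$ppm
  y <- spectrum$intensity
  if (ppm[1] > ppm[length(ppm)]) { ppm <- rev(ppm); y <- rev(y) }
  lo <- ppm[1]; hi <- ppm[length(ppm)]
  if (hi - lo < bin_width_ppm) stop("axis narrower than one bin")
  n_bins <- ceiling((hi - lo) / bin_width_ppm - 1e-9)
  edges <- lo + bin_width_ppm * (0:n_bins)
  edges[n_bins + 1] <- min(edges[n_bins + 1], hi)
  cum_at <- cumulative_integral_at(ppm, y, edges)
  list(bin_centers = lo + bin_width_ppm * (seq_len(n_bins) - 0.5),
       bin_integrals = diff(cum_at))
}

# Exact integral of the piecewise-linear interpolant of (x, y) from x[1] to
# each point in `at` (points clamped to the axis range, assumed sorted).
cumulative_integral_at <- function(x, y, at) {
  cum <- c(0, cumsum(diff(x) * (y[-length(y)] + y[-1]) / 2))
  at <- pmin(pmax(at, x[1]), x[length(x)])
  k <- findInterval(at, x, rightmost.closed = TRUE)
  k <- pmin(k, length(x) - 1)
  frac <- at - x[k]
  slope <- (y[k + 1] - y[k]) / (x[k + 1] - x[k])
  cum[k] + y[k] * frac + slope * frac^2 / 2
}

#' Exclusion windows for a biological matrix
#'
#' Returns the ppm windows removed before multivariate analysis, as used for
#' each sample type: plasma drops the urea region (5.40-5.90) and the
#' water/anomeric region (4.20-5.10); urine drops 5.35-5.90 and 4.14-5.25;
#' tissue extracts drop residual water (4.67-5.22) and methanol (3.31-3.40).
#' Windows are half-open `[low, high)` and tested against bin centres.
#'
#' @param matrix_type One of `"plasma"`, `"urine"`, `"tissue"`.
#' @param windows Optional custom windows as a 2-column matrix or data frame
#'   `(ppm_low, ppm_high)`; overrides the built-in scheme.
#' @return List of class `exclusion_scheme` with `matrix_type` and `windows`
#'   (data frame, sorted, non-overlapping).
#' @export
exclusion_scheme <- function(matrix_type = c("plasma", "urine", "tissue"),
                             windows = NULL) {
  matrix_type <- match.arg(matrix_type)
  if (is.null(windows)) {
    windows <- switch(matrix_type,
      plasma = data.frame(ppm_low = c(4.20, 5.40), ppm_high = c(5.10, 5.90)),
      urine  = data.frame(ppm_low = c(4.14, 5.35), ppm_high = c(5.25, 5.90)),
      tissue = data.frame(ppm_low = c(3.31, 4.67), ppm_high = c(3.40, 5.22)))
  } else {
    windows <- as.data.frame(windows)
    names(windows) <- c("ppm_low", "ppm_high")
  }
  if (any(windows$ppm_low >= windows$ppm_high)) {
    stop("each window needs ppm_low < ppm_high")
  }
  windows <- windows[order(windows$ppm_low), , drop = FALSE]
  rownames(windows) <- NULL
  if (nrow(windows) > 1 &&
      any(windows$ppm_high[-nrow(windows)] > windows$ppm_low[-1])) {
    stop("exclusion windows overlap")
  }
  structure(list(matrix_type = matrix_type, windows = windows),
            class = "exclusion_scheme")
}

#' Assemble a binned sample-by-bin matrix from a cohort
#'
#' Bins every spectrum on its own axis (all cohort spectra share one axis, so
#' bins align) and stacks the integrals into a samples x bins matrix.
#'
#' @param cohort An [simulate_cohort()] result, or a list of
#'   [nmr_spectrum()] objects.
#' @param bin_width_ppm Bucket width in ppm.
#' @return Object of class `binned_matrix`: list with `bin_centers`, `values`
#'   (samples x bins), `sample_ids`, `groups`, `normalization_tag`,
#'   `exclusions`.
#' @export
bin_cohort <- function(cohort, bin_width_ppm = 0.005) {
  spectra <- if (inherits(cohort, "nmr_cohort")) cohort$spectra else cohort
  stopifnot(length(spectra) >= 1)
  binned <- lapply(spectra, bin_spectrum, bin_width_ppm = bin_width_ppm)
  centers <- binned[[1]]$bin_centers
  for (b in binned) {
    if (length(b$bin_centers) != length(centers) ||
        max(abs(b$bin_centers - centers)) > 1e-9) {
      stop("spectra are binned on different grids; calibrate to a common axis first")
    }
  }
  values <- do.call(rbind, lapply(binned, `[[`, "bin_integrals"))
  new_binned_matrix(centers, values,
                    vapply(spectra, `[[`, character(1), "sample_id"),
                    vapply(spectra, `[[`, character(1), "group"),
                    normalization_tag = "none", exclusions = NULL)
}

new_binned_matrix <- function(bin_centers, values, sample_ids, groups,
                              normalization_tag, exclusions) {
  values <- as.matrix(values)
  stopifnot(ncol(values) == length(bin_centers),
            nrow(values) == length(sample_ids),
            length(groups) == length(sample_ids))
  if (!all(is.finite(values))) stop("binned values must be finite")
  dimnames(values) <- list(sample_ids, sprintf("%.4f", bin_centers))
  structure(list(bin_centers = as.numeric(bin_centers), values = values,
                 sample_ids = as.character(sample_ids),
                 groups = as.character(groups),
                 normalization_tag = normalization_tag,
                 exclusions = exclusions),
            class = "binned_matrix")
}

#' @export
print.binned_matrix <- function(x, ...) {
  cat(sprintf("<binned_matrix> %d samples x %d bins (%.3f..%.3f ppm), normalization: %s\n",
              nrow(x$values), ncol(x$values), min(x$bin_centers),
              max(x$bin_centers), x$normalization_tag))
  invisible(x)
}

#' Drop bins falling inside exclusion windows
#'
#' Removes every bin whose centre lies in any half-open window
#' `[ppm_low, ppm_high)` of the scheme; column order is otherwise preserved.
#'
#' @param binned A `binned_matrix`.
#' @param scheme An [exclusion_scheme()].
#' @return The filtered `binned_matrix` (with the scheme recorded).
#' @export
apply_exclusions <- function(binned, scheme) {
  stopifnot(inherits(binned, "binned_matrix"), inherits(scheme, "exclusion_scheme"))
  drop <- rep(FALSE, length(binned$bin_centers))
  for (k in seq_len(nrow(scheme$windows))) {
    drop <- drop | (binned$bin_centers >= scheme$windows$ppm_low[k] &
                      binned$bin_centers < scheme$windows$ppm_high[k])
  }
  if (all(drop)) warning("all bins removed by the exclusion scheme")
  new_binned_matrix(binned$bin_centers[!drop],
                    binned$values[, !drop, drop = FALSE],
                    binned$sample_ids, binned$groups,
                    binned$normalization_tag, scheme)
}

#' Normalize binned rows for cross-sample comparability
#'
#' `total_area` rescales every sample (row) to a common total integral
#' (`target`, default 100). `probabilistic_quotient` (PQN) first applies
#' total-area scaling, then divides each row by the median ratio of its bins
#' to the cohort median spectrum, which is robust to a few large fold
#' changes.
#'
#' @param binned A `binned_matrix`.
#' @param method `"total_area"` or `"probabilistic_quotient"`.
#' @param target Row-sum constant for total-area scaling.
#' @return The normalized `binned_matrix` with `normalization_tag` recording
#'   the method.
#' @export
normalize_rows <- function(binned,
                           method = c("total_area", "probabilistic_quotient"),
                           target = 100) {
  stopifnot(inherits(binned, "binned_matrix"), target > 0)
  method <- match.arg(method)
  v <- binned$values
  sums <- rowSums(v)
  if (any(sums <= 0)) {
    stop("degenerate sample (non-positive total area): ",
         paste(binned$sample_ids[sums <= 0], collapse = ", "))
  }
  v <- v * (target / sums)
  if (method == "probabilistic_quotient") {
    ref <- apply(v, 2, stats::median)
    keep <- ref > 0
    if (!any(keep)) stop("PQN reference spectrum is non-positive everywhere")
    quo <- apply(v[, keep, drop = FALSE], 1, function(r) stats::median(r / ref[keep]))
    if (any(!is.finite(quo) | quo <= 0)) {
      stop("degenerate sample (non-positive median quotient): ",
           paste(binned$sample_ids[!is.finite(quo) | quo <= 0], collapse = ", "))
    }
    v <- v / quo
  }
  new_binned_matrix(binned$bin_centers, v, binned$sample_ids, binned$groups,
                    normalization_tag = method, exclusions = binned$exclusions)
}
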