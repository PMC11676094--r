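#' Unit-height Lorentzian lineshape
#'
#' Evaluates a Lorentzian profile with unit peak height,
#' \eqn{\gamma^2 / ((\delta - \delta_0)^2 + \gamma^2)}, on a chemical-shift
#' axis. This is the absorption-mode lineshape used for all synthetic
#' metabolite lines.
#'
#' @param center_ppm Peak centre \eqn{\delta_0} in ppm.
#' @param halfwidth_ppm Half-width at half-maximum \eqn{\gamma} in ppm
#'   (strictly positive).
#' @param axis Monotone numeric vector of chemical shifts (ppm).
#' @return Numeric vector of intensities, same length as `axis`, with value 1
#'   at the peak centre and 1/2 at `center_ppm` +/- `halfwidth_ppm`.
#' @examples
#' ax <- seq(0, 3, by = 0.001)
#' y <- lorentzian_profile(1.33, 0.002, ax)
#' max(y) # ~1 at the centre
#' @export
lorentzian_profile <- function(center_ppm, halfwidth_ppm, axis) {
  if (!is.numeric(halfwidth_ppm) || length(halfwidth_ppm) != 1 ||
      !is.finite(halfwidth_ppm) || halfwidth_ppm <= 0) {
    stop("`halfwidth_ppm` must be a single strictly positive number")
  }
  if (length(axis) > 1 && !is_monotone(axis)) {
    stop("`axis` must be strictly monotone")
  }
  halfwidth_ppm^2 / ((axis - center_ppm)^2 + halfwidth_ppm^2)
}

is_monotone <- function(x) {
  d <- diff(x)
  all(d > 0) || all(d < 0)
}

#' Construct a single 1D NMR spectrum object
#'
#' @param ppm Strictly monotone chemical-shift axis (ppm).
#' @param intensity Finite numeric vector, same length as `ppm`.
#' @param sample_id Sample identifier.
#' @param group Group label, `"control"` or `"case"`.
#' @return Object of class `nmr_spectrum`.
#' @export
nmr_spectrum <- function(ppm, intensity, sample_id, group = c("control", "case")) {
  group <- match.arg(group)
  if (length(ppm) != length(intensity)) stop("ppm and intensity lengths differ")
  if (!is_monotone(ppm)) stop("ppm axis must be strictly monotone")
  if (!all(is.finite(intensity))) stop("intensity must be finite everywhere")
  structure(list(ppm = as.numeric(ppm), intensity = as.numeric(intensity),
                 sample_id = as.character(sample_id), group = group),
            class = "nmr_spectrum")
}

#' @export
print.nmr_spectrum <- function(x, ...) {
  cat(sprintf("<nmr_spectrum> %s (%s): %d points, %.3f..%.3f ppm\n",
              x$sample_id, x$group, length(x$ppm), min(x$ppm), max(x$ppm)))
  invisible(x)
}

#' Specify a synthetic cohort design
#'
#' Defines the study design emulated by the simulator. The defaults mirror
#' the acute restraint-stress experiment: 6 control animals vs 7 stressed
#' animals, spectra over 0-10 ppm, with modest instrument noise, small
#' chemical-shift jitter between animals, and a slow sinusoidal baseline
#' ripple mimicking imperfect baseline correction.
#'
#' @param n_control,n_case Group sizes (each at least 2).
#' @param metabolite_effects Named numeric vector of fold changes applied to
#'   case-group concentrations; 1 means no effect. Names must match template
#'   metabolite names.
#' @param noise_sd Standard deviation of additive homoscedastic Gaussian
#'   noise, in intensity units (peak heights are of order 1).
#' @param shift_jitter_sd SD of the per-sample Gaussian chemical-shift jitter
#'   applied to every line centre, in ppm.
#' @param baseline_amplitude Amplitude of the slow sinusoidal baseline drift,
#'   in intensity units.
#' @param ppm_min,ppm_max,n_points Chemical-shift axis (n_points >= 1000).
#' @param seed Integer seed making the cohort reproducible.
#' @return A list of class `cohort_design`.
#' @export
cohort_design <- function(n_control = 6, n_case = 7,
                          metabolite_effects = numeric(0),
                          noise_sd = 0.01, shift_jitter_sd = 0.001,
                          baseline_amplitude = 0.02,
                          ppm_min = 0, ppm_max = 10, n_points = 8192,
                          seed = 1L) {
  if (n_control < 2 || n_case < 2) stop("each group needs at least 2 samples")
  if (n_points < 1000) stop("n_points must be at least 1000")
  if (ppm_min >= ppm_max) stop("ppm_min must be below ppm_max")
  if (length(metabolite_effects) > 0) {
    if (is.null(names(metabolite_effects)) || any(names(metabolite_effects) == "")) {
      stop("metabolite_effects must be a named vector")
    }
    if (any(!is.finite(metabolite_effects)) || any(metabolite_effects <= 0)) {
      stop("fold changes must be finite and strictly positive")
    }
  }
  stopifnot(noise_sd >= 0, shift_jitter_sd >= 0, baseline_amplitude >= 0)
  structure(list(n_control = as.integer(n_control), n_case = as.integer(n_case),
                 metabolite_effects = metabolite_effects,
                 noise_sd = noise_sd, shift_jitter_sd = shift_jitter_sd,
                 baseline_amplitude = baseline_amplitude,
                 ppm_min = ppm_min, ppm_max = ppm_max,
                 n_points = as.integer(n_points), seed = as.integer(seed)),
            class = "cohort_design")
}

#' Simulate a cohort of 1D NMR spectra with known group effects
#'
#' Each sample spectrum is the concentration-weighted sum of its metabolite
#' template profiles, plus a slow sinusoidal baseline with random phase and
#' additive i.i.d. Gaussian noise. Case-group concentrations are multiplied
#' by the design's fold changes; per-sample chemical-shift jitter displaces
#' every line centre by a common Gaussian offset per metabolite line.
#'
#' @param templates Template table from [metabolite_templates()].
#' @param design Design from [cohort_design()].
#' @return A list of class `nmr_cohort` with elements `spectra` (list of
#'   [nmr_spectrum()] objects, controls first) and `ground_truth` (data frame
#'   of the metabolites whose fold change differs from 1).
#' @examples
#' coh <- simulate_cohort(metabolite_templates(),
#'                        cohort_design(metabolite_effects = c(lactate = 2),
#'                                      n_points = 2048, seed = 7))
#' coh$ground_truth
#' @export
simulate_cohort <- function(templates, design) {
  validate_templates(templates)
  stopifnot(inherits(design, "cohort_design"))
  unknown <- setdiff(names(design$metabolite_effects), unique(templates$name))
  if (length(unknown) > 0) {
    stop("unknown metabolite in effects: ", paste(unknown, collapse = ", "))
  }
  axis <- seq(design$ppm_min, design$ppm_max, length.out = design$n_points)
  groups <- c(rep("control", design$n_control), rep("case", design$n_case))
  ids <- sprintf("%s_%02d", ifelse(groups == "control", "ctrl", "case"),
                 c(seq_len(design$n_control), seq_len(design$n_case)))

  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(design$seed)

  spectra <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    intensity <- numeric(design$n_points)
    for (m in unique(templates$name)) {
      conc <- templates$base_concentration[match(m, templates$name)]
      fc <- design$metabolite_effects[m]
      if (groups[i] == "case" && !is.na(fc)) conc <- conc * fc
      lines <- templates[templates$name == m, , drop = FALSE]
      for (j in seq_len(nrow(lines))) {
        jitter <- if (design$shift_jitter_sd > 0) {
          stats::rnorm(1, 0, design$shift_jitter_sd)
        } else 0
        intensity <- intensity + conc * lines$relative_height[j] *
          lorentzian_profile(lines$center_ppm[j] + jitter,
                             lines$halfwidth_ppm[j], axis)
      }
    }
    if (design$baseline_amplitude > 0) {
      phase <- stats::runif(1, 0, 2 * pi)
      intensity <- intensity + design$baseline_amplitude *
        sin(2 * pi * (axis - design$ppm_min) /
              (design$ppm_max - design$ppm_min) + phase)
    }
    if (design$noise_sd > 0) {
      intensity <- intensity + stats::rnorm(design$n_points, 0, design$noise_sd)
    }
    spectra[[i]] <- nmr_spectrum(axis, intensity, ids[i], groups[i])
  }

  effects <- design$metabolite_effects
  truth <- data.frame(metabolite = names(effects)[effects != 1],
                      fold_change = unname(effects[effects != 1]),
                      stringsAsFactors = FALSE)
  structure(list(spectra = spectra, ground_truth = truth, design = design),
            class = "nmr_cohort")
}

#' @export
print.nmr_cohort <- function(x, ...) {
  g <- vapply(x$spectra, function(s) s$group, character(1))
  cat(sprintf("<nmr_cohort> %d control + %d case spectra, %d points each\n",
              sum(g == "control"), sum(g == "case"),
              length(x$spectra[[1]]$ppm)))
  if (nrow(x$ground_truth) > 0) {
    cat("perturbed:", paste(sprintf("%s (x%.2f)", x$ground_truth$metabolite,
                                    x$ground_truth$fold_change),
                            collapse = ", "), "\n")
  } else cat("null cohort (no perturbed metabolites)\n")
  invisible(x)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}
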