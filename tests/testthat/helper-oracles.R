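# Shared oracles and fixture builders, independent of the code paths they
# check.

# Plain trapezoid quadrature of y over x.
trapz <- function(x, y) sum(diff(x) * (y[-length(y)] + y[-1]) / 2)

# Small template set away from all exclusion windows, for fast cohorts.
small_templates <- function() {
  data.frame(
    name = c("lactate", "lactate", "creatine", "succinate"),
    base_concentration = c(1.6, 1.6, 1.0, 1.0),
    center_ppm = c(1.326, 1.340, 3.030, 2.408),
    relative_height = c(1.5, 1.5, 3.0, 4.0),
    halfwidth_ppm = c(0.0025, 0.0025, 0.002, 0.002),
    diagnostic = c(1, 1, 1, 1),
    stringsAsFactors = FALSE)
}

quiet_design <- function(...) {
  cohort_design(noise_sd = 0, shift_jitter_sd = 0, baseline_amplitude = 0,
                n_points = 4096, ...)
}

# Empirical best-bin signal-to-noise for each perturbed metabolite: largest
# (over the metabolite's annotated bins) ratio of the absolute between-group
# mean difference to the pooled within-group SD.
effect_bin_snr <- function(binned, bin_map, metabolites) {
  ctrl <- binned$groups == "control"
  vapply(metabolites, function(m) {
    w <- bin_map[bin_map$metabolite == m, ]
    cols <- which(binned$bin_centers >= w$ppm_low &
                    binned$bin_centers < w$ppm_high)
    max(vapply(cols, function(j) {
      v1 <- binned$values[ctrl, j]; v2 <- binned$values[!ctrl, j]
      d <- abs(mean(v2) - mean(v1))
      sp <- sqrt(((length(v1) - 1) * stats::var(v1) +
                    (length(v2) - 1) * stats::var(v2)) /
                   (length(v1) + length(v2) - 2))
      d / sp
    }, numeric(1)))
  }, numeric(1))
}
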