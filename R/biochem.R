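#' Constants of the xanthine oxidoreductase absorbance assay
#'
#' Beer-Lambert constants for converting a 290-nm absorbance change into
#' uric acid formed per minute per millilitre of serum. Defaults: total
#' reaction volume 2.6e-4 L, molar extinction coefficient of uric acid
#' 1.22e4 L/mol/cm, optical path 0.6 cm (96-well plate), sample volume
#' 0.01 mL, reaction time 30 min.
#'
#' @param v_total Total reaction volume (L).
#' @param epsilon Molar extinction coefficient (L/mol/cm).
#' @param d Optical path length (cm).
#' @param v_sample Sample volume (mL).
#' @param t_min Reaction time (minutes).
#' @return List of class `enzyme_constants`.
#' @export
enzyme_constants <- function(v_total = 2.6e-4, epsilon = 1.22e4, d = 0.6,
                             v_sample = 0.01, t_min = 30) {
  vals <- c(v_total = v_total, epsilon = epsilon, d = d,
            v_sample = v_sample, t_min = t_min)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all assay constants must be finite and strictly positive")
  }
  structure(as.list(vals), class = "enzyme_constants")
}

#' Enzyme activity from an absorbance change
#'
#' Converts net 290-nm absorbance changes into enzyme activity in U/mL,
#' where one unit forms 1 umol of uric acid per minute in the reaction
#' volume:
#' \deqn{(\Delta A_{test} - \Delta A_{blank}) \cdot V_{total} \cdot 10^6 /
#'       (\epsilon \cdot d \cdot V_{sample} \cdot T)}
#' Negative activities are reported (with a warning) rather than clipped,
#' so assay quality problems stay visible.
#'
#' @param delta_a_test Absorbance change of the test reaction (end - start).
#' @param delta_a_blank Absorbance change of the blank.
#' @param constants An [enzyme_constants()] object.
#' @return Activity in U/mL (vectorized over the absorbance arguments).
#' @examples
#' enzyme_activity(0.1, 0) # 0.01184 U/mL with the default constants
#' @export
enzyme_activity <- function(delta_a_test, delta_a_blank,
                            constants = enzyme_constants()) {
  stopifnot(inherits(constants, "enzyme_constants"))
  if (any(!is.finite(delta_a_test)) || any(!is.finite(delta_a_blank))) {
    stop("absorbance changes must be finite")
  }
  act <- (delta_a_test - delta_a_blank) * constants$v_total * 1e6 /
    (constants$epsilon * constants$d * constants$v_sample * constants$t_min)
  if (any(act < 0)) warning("negative enzyme activity computed; check assay readings")
  act
}

#' Xanthine dehydrogenase activity by subtraction
#'
#' XOR (assayed with NAD+) carries both dehydrogenase and oxidase activity;
#' XO is assayed without NAD+. The NAD-dependent dehydrogenase (XDH)
#' activity is the difference.
#'
#' @param xor_activity Total xanthine oxidoreductase activity (U/mL).
#' @param xo_activity Xanthine oxidase activity (U/mL).
#' @return XDH activity (U/mL); negative results trigger a warning.
#' @examples
#' xdh_from_xor_xo(0.802, 0.556) # 0.246 U/mL
#' @export
xdh_from_xor_xo <- function(xor_activity, xo_activity) {
  if (any(!is.finite(xor_activity)) || any(!is.finite(xo_activity))) {
    stop("activities must be finite")
  }
  xdh <- xor_activity - xo_activity
  if (any(xdh < 0)) warning("negative XDH activity (XO exceeds XOR); check assays")
  xdh
}

#' Per-group summary statistics for a scalar analyte
#'
#' @param mean Group mean (analyte units).
#' @param sd Group standard deviation (same units, non-negative).
#' @param n Group size (at least 2).
#' @return List of class `group_summary`.
#' @export
group_summary <- function(mean, sd, n) {
  if (!is.finite(mean) || !is.finite(sd) || sd < 0) {
    stop("mean must be finite and sd non-negative")
  }
  if (n < 2) stop("group size must be at least 2")
  structure(list(mean = mean, sd = sd, n = as.integer(n)),
            class = "group_summary")
}

#' Two-sample t-test from group summary statistics
#'
#' Unpaired two-tailed Student's t-test computed directly from per-group
#' means, SDs and sizes — the form needed when only published summaries are
#' available. The default pools the variances (Student); `welch = TRUE`
#' gives the unequal-variance alternative with Welch-Satterthwaite degrees
#' of freedom.
#'
#' @param g1,g2 [group_summary()] objects.
#' @param welch Use the Welch test instead of the pooled-variance test.
#' @return List with `t`, `df`, `p` (two-tailed).
#' @examples
#' pooled_t_test(group_summary(164.67, 78.32, 6),
#'               group_summary(104.58, 26.78, 7)) # p = 0.082
#' @export
pooled_t_test <- function(g1, g2, welch = FALSE) {
  stopifnot(inherits(g1, "group_summary"), inherits(g2, "group_summary"))
  if (g1$n + g2$n < 3) stop("too few observations")
  if (g1$sd == 0 && g2$sd == 0) {
    if (g1$mean == g2$mean) stop("undefined statistic: both SDs zero and equal means")
    return(list(t = sign(g1$mean - g2$mean) * Inf, df = g1$n + g2$n - 2, p = 0))
  }
  if (welch) {
    v1 <- g1$sd^2 / g1$n; v2 <- g2$sd^2 / g2$n
    t_stat <- (g1$mean - g2$mean) / sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (g1$n - 1) + v2^2 / (g2$n - 1))
  } else {
    df <- g1$n + g2$n - 2
    sp2 <- ((g1$n - 1) * g1$sd^2 + (g2$n - 1) * g2$sd^2) / df
    t_stat <- (g1$mean - g2$mean) / sqrt(sp2 * (1 / g1$n + 1 / g2$n))
  }
  list(t = t_stat, df = df, p = 2 * stats::pt(-abs(t_stat), df))
}

#' Relative gene expression by the 2^-ddCt method
#'
#' Fold change of a target transcript in the case condition relative to the
#' control condition, each normalized to a housekeeping reference gene:
#' \deqn{2^{-((Ct_{target,case} - Ct_{ref,case}) -
#'            (Ct_{target,control} - Ct_{ref,control}))}}
#'
#' @param ct_target_case,ct_ref_case,ct_target_control,ct_ref_control PCR
#'   cycle-threshold values (finite; typically 5-40).
#' @return The fold change (1 = no change; swapping case and control roles
#'   returns the reciprocal).
#' @examples
#' ddct_fold_change(24, 18, 25, 18) # one cycle later in case -> 0.5
#' @export
ddct_fold_change <- function(ct_target_case, ct_ref_case,
                             ct_target_control, ct_ref_control) {
  cts <- c(ct_target_case, ct_ref_case, ct_target_control, ct_ref_control)
  if (any(!is.finite(cts))) stop("Ct values must be finite")
  ddct <- (ct_target_case - ct_ref_case) - (ct_target_control - ct_ref_control)
  2^(-ddct)
}

#' Shipped serum biochemistry summaries
#'
#' Per-analyte group means/SDs (non-stressed n = 6 vs stressed n = 7) for
#' the restraint-stress experiment, ready for [pooled_t_test()].
#'
#' @return Data frame, one row per analyte.
#' @export
serum_biochemistry <- function() {
  utils::read.csv(system.file("extdata", "serum_biochemistry.csv",
                              package = "nmrstress"),
                  comment.char = "#", stringsAsFactors = FALSE)
}

#' Shipped xanthine oxidoreductase activity summaries
#'
#' Group means/SDs of serum XOR and XO activity (U/mL) for the
#' restraint-stress experiment.
#'
#' @return Data frame, one row per group.
#' @export
xor_activity_summaries <- function() {
  utils::read.csv(system.file("extdata", "xor_activity.csv",
                              package = "nmrstress"),
                  comment.char = "#", stringsAsFactors = FALSE)
}
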