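#' Built-in metabolite template library
#'
#' Loads the shipped library of metabolite line templates used by the
#' synthetic spectrum generator. Each template describes one metabolite as a
#' set of Lorentzian lines (centre, relative height, half-width at
#' half-maximum, all in ppm or dimensionless) plus a base concentration for
#' the control condition. Chemical shifts follow standard reference values
#' for aqueous biofluid spectra referenced to TSP at 0 ppm.
#'
#' @param file Path to a template table. Defaults to the library shipped with
#'   the package. The file is comma-separated with comment lines starting
#'   with `#` and columns `name`, `base_concentration`, `center_ppm`,
#'   `relative_height`, `halfwidth_ppm`, `diagnostic`.
#' @return A data frame of class `nmr_templates` with one row per Lorentzian
#'   line.
#' @examples
#' tpl <- metabolite_templates()
#' length(unique(tpl$name)) # >= 12 metabolites
#' @export
metabolite_templates <- function(file = system.file("extdata",
                                                    "metabolite_templates.csv",
                                                    package = "nmrstress")) {
  tpl <- utils::read.csv(file, comment.char = "#", stringsAsFactors = FALSE)
  validate_templates(tpl)
  class(tpl) <- c("nmr_templates", "data.frame")
  tpl
}

validate_templates <- function(tpl) {
  required <- c("name", "base_concentration", "center_ppm",
                "relative_height", "halfwidth_ppm")
  missing <- setdiff(required, names(tpl))
  if (length(missing) > 0) {
    stop("template table lacks columns: ", paste(missing, collapse = ", "))
  }
  if (nrow(tpl) == 0) stop("template table is empty")
  if (any(tpl$center_ppm < 0 | tpl$center_ppm > 10)) {
    stop("template line centres must lie within [0, 10] ppm")
  }
  if (any(tpl$relative_height <= 0) || any(tpl$halfwidth_ppm <= 0)) {
    stop("template heights and halfwidths must be strictly positive")
  }
  if (any(tpl$base_concentration <= 0)) {
    stop("base concentrations must be strictly positive")
  }
  invisible(tpl)
}

#' Default bin-to-metabolite annotation map
#'
#' Builds the ppm-window annotation map used to assign significant bins to
#' metabolite names. One window per metabolite, centred on its diagnostic
#' multiplet (the lines flagged `diagnostic` in the template library), padded
#' by `pad` ppm on each side. Windows are checked for cross-metabolite
#' overlap so every bin maps to at most one metabolite.
#'
#' @param templates Template table from [metabolite_templates()].
#' @param pad Padding in ppm added on both sides of the diagnostic multiplet.
#' @return Data frame with columns `metabolite`, `ppm_low`, `ppm_high`.
#' @export
template_bin_map <- function(templates = metabolite_templates(), pad = 0.01) {
  stopifnot(pad > 0)
  diag <- templates[templates$diagnostic == 1, , drop = FALSE]
  if (nrow(diag) == 0) stop("no diagnostic lines flagged in template table")
  map <- do.call(rbind, lapply(split(diag, diag$name), function(d) {
    data.frame(metabolite = d$name[1],
               ppm_low = min(d$center_ppm) - pad,
               ppm_high = max(d$center_ppm) + pad,
               stringsAsFactors = FALSE)
  }))
  rownames(map) <- NULL
  map <- map[order(map$ppm_low), , drop = FALSE]
  if (nrow(map) > 1 && any(map$ppm_high[-nrow(map)] > map$ppm_low[-1])) {
    stop("diagnostic windows overlap between metabolites; reduce `pad`")
  }
  map
}
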