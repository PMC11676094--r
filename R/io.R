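#' Write a cohort as tidy delimited text plus a ground-truth sidecar
#'
#' One tab-separated file with columns `sample_id`, `group`, `ppm`,
#' `intensity` (long format, one row per point) and a JSON sidecar
#' (`<path>.truth.json`) holding the ground-truth effect table and design
#' parameters.
#'
#' @param cohort An `nmr_cohort` from [simulate_cohort()].
#' @param path Output file path for the spectra table.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "nmr_cohort"))
  tidy <- do.call(rbind, lapply(cohort$spectra, function(s) {
    data.frame(sample_id = s$sample_id, group = s$group,
               ppm = s$ppm, intensity = s$intensity,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(tidy, path, sep = "\t", row.names = FALSE, quote = FALSE)
  sidecar <- list(ground_truth = cohort$ground_truth,
                  design = unclass(cohort$design))
  jsonlite::write_json(sidecar, paste0(path, ".truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param path Path to the tidy spectra table.
#' @return An `nmr_cohort` (design metadata restored from the sidecar when
#'   present).
#' @export
read_cohort <- function(path) {
  tidy <- utils::read.delim(path, stringsAsFactors = FALSE)
  spectra <- lapply(split(tidy, factor(tidy$sample_id,
                                       levels = unique(tidy$sample_id))),
                    function(d) nmr_spectrum(d$ppm, d$intensity,
                                             d$sample_id[1], d$group[1]))
  names(spectra) <- NULL
  truth_path <- paste0(path, ".truth.json")
  truth <- data.frame(metabolite = character(0), fold_change = numeric(0))
  design <- NULL
  if (file.exists(truth_path)) {
    sidecar <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
    if (length(sidecar$ground_truth) > 0 &&
        NROW(sidecar$ground_truth) > 0) truth <- as.data.frame(sidecar$ground_truth)
    design <- sidecar$design
  }
  structure(list(spectra = spectra, ground_truth = truth, design = design),
            class = "nmr_cohort")
}

#' Write a binned matrix with a JSON header sidecar
#'
#' The matrix goes to a tab-separated table (samples in rows, one column per
#' bin named by its ppm centre); bin centres, the normalization tag and any
#' applied exclusion scheme go to `<path>.meta.json`.
#'
#' @param binned A `binned_matrix`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_binned_matrix <- function(binned, path) {
  stopifnot(inherits(binned, "binned_matrix"))
  tab <- data.frame(sample_id = binned$sample_ids, group = binned$groups,
                    binned$values, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- list(bin_centers = binned$bin_centers,
               normalization_tag = binned$normalization_tag,
               exclusions = if (is.null(binned$exclusions)) NULL else
                 list(matrix_type = binned$exclusions$matrix_type,
                      windows = binned$exclusions$windows))
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a binned matrix written by [write_binned_matrix()]
#'
#' @param path Path to the matrix table.
#' @return A `binned_matrix`.
#' @export
read_binned_matrix <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"), simplifyVector = TRUE)
  values <- as.matrix(tab[, -(1:2), drop = FALSE])
  exclusions <- NULL
  if (!is.null(meta$exclusions)) {
    exclusions <- exclusion_scheme(meta$exclusions$matrix_type,
                                   windows = as.data.frame(meta$exclusions$windows))
  }
  new_binned_matrix(meta$bin_centers, values, tab$sample_id, tab$group,
                    meta$normalization_tag, exclusions)
}
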