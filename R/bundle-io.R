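# TSV/JSON serialization of cohort bundles. TSV (not CSV) because LC-MS
# feature annotations routinely contain commas; '.' decimal throughout.

#' Write a cohort bundle to a directory
#'
#' Emits `features.tsv` (samples x features, first column `sample_id`),
#' `features_meta.tsv` (feature_id, mz, rt), `clinical.tsv`, `truth.json`
#' and a `manifest.json` listing each file with its row/column counts.
#'
#' @param bundle A `cohort_bundle` from [simulate_cohorts()].
#' @param dir Output directory; created if absent.
#' @return Invisibly, the manifest as a list.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create directory: ", dir, call. = FALSE)
  paths <- file.path(dir, c("features.tsv", "features_meta.tsv",
                            "clinical.tsv", "truth.json"))
  readr::write_tsv(bundle$features, paths[1])
  readr::write_tsv(bundle$feature_meta, paths[2])
  readr::write_tsv(bundle$clinical, paths[3])
  truth <- list(
    causal = bundle$truth$causal,
    blocks = bundle$truth$blocks
  )
  jsonlite::write_json(truth, paths[4], digits = NA, dataframe = "columns")
  manifest <- list(
    files = basename(paths),
    n_samples = nrow(bundle$features),
    n_features = nrow(bundle$feature_meta),
    cohort = unique(bundle$clinical$cohort)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(manifest)
}

#' Read a cohort bundle written by [write_bundle()]
#'
#' @param dir Directory containing the bundle files.
#' @return A `cohort_bundle`.
#' @export
read_bundle <- function(dir) {
  need <- file.path(dir, c("features.tsv", "features_meta.tsv",
                           "clinical.tsv", "truth.json"))
  missing <- need[!file.exists(need)]
  if (length(missing)) {
    stop("bundle file(s) not found: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  features <- readr::read_tsv(need[1], show_col_types = FALSE,
                              progress = FALSE)
  feature_meta <- readr::read_tsv(need[2], show_col_types = FALSE,
                                  progress = FALSE)
  clinical <- readr::read_tsv(need[3], show_col_types = FALSE,
                              progress = FALSE)
  raw <- jsonlite::read_json(need[4], simplifyVector = TRUE)
  as_truth_tbl <- function(x, proto) {
    if (is.null(x) || length(x) == 0 || all(lengths(x) == 0)) proto
    else tibble::as_tibble(lapply(x, unlist))
  }
  truth <- list(
    causal = as_truth_tbl(raw$causal,
      tibble::tibble(feature_id = character(), effect = numeric(),
                     block = integer())),
    blocks = as_truth_tbl(raw$blocks,
      tibble::tibble(feature_id = character(), block = integer()))
  )
  structure(list(features = features, feature_meta = feature_meta,
                 clinical = clinical, truth = truth),
            class = "cohort_bundle")
}
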