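#' Relative standard deviation (RSD%)
#'
#' Injection-precision metric for LC-MS quality-control replicates:
#' `100 * sample SD / mean`, applied to repeated measurements of one
#' quantity (retention time in minutes, or peak area in intensity units)
#' of a QC ion. Scale-invariant: multiplying all replicates by a positive
#' constant leaves the RSD% unchanged.
#'
#' @param x Numeric vector of at least two positive replicate measurements.
#' @return RSD as a percentage.
#' @examples
#' rsd_percent(c(90, 110))
#' @export
rsd_percent <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) stop("need at least two replicates", call. = FALSE)
  if (any(x <= 0)) stop("replicate measurements must be positive",
                        call. = FALSE)
  100 * stats::sd(x) / mean(x)
}

#' RSD% summary for a table of QC replicate series
#'
#' @param qc A data frame with columns `ion` (label), `quantity` (e.g.
#'   `"retention_time"` or `"peak_area"`) and `value` (replicates).
#' @return A tibble with one row per ion x quantity and its `rsd_percent`
#'   and replicate count `n`.
#' @export
qc_summary <- function(qc) {
  need <- c("ion", "quantity", "value")
  missing <- setdiff(need, names(qc))
  if (length(missing)) {
    stop("QC table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  qc |>
    dplyr::group_by(.data$ion, .data$quantity) |>
    dplyr::summarise(n = dplyr::n(),
                     rsd_percent = rsd_percent(.data$value),
                     .groups = "drop")
}
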