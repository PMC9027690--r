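# broom-style tidiers for the package's fitted objects

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an OLS blood-pressure fit
#'
#' @param x A `bp_ols` from [ols_fit()].
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`. Term names are the bare column names (backticks stripped).
#' @method tidy bp_ols
#' @export
tidy.bp_ols <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(
    term = gsub("`", "", rownames(s)),
    estimate = unname(s[, "Estimate"]),
    std.error = unname(s[, "Std. Error"]),
    statistic = unname(s[, "t value"]),
    p.value = unname(s[, "Pr(>|t|)"])
  )
}

#' One-row model summary of an OLS blood-pressure fit
#'
#' @param x A `bp_ols`.
#' @param ... Unused.
#' @return A tibble with `r.squared`, `adj.r.squared` (the
#'   `1 - (1 - R^2)(n - 1)/(n - p - 1)` penalty), `sigma`, `nobs`, `df`.
#' @method glance bp_ols
#' @export
glance.bp_ols <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(
    r.squared = s$r.squared,
    adj.r.squared = s$adj.r.squared,
    sigma = s$sigma,
    nobs = length(s$residuals),
    df = x$fit$rank
  )
}

#' Tidy a cluster set into one row per feature
#'
#' @param x A `cluster_set` from [correlation_cluster()].
#' @param ... Unused.
#' @return A tibble with `feature_id`, `cluster`, `pivot` (the cluster's
#'   pivot) and `is_pivot`.
#' @method tidy cluster_set
#' @export
tidy.cluster_set <- function(x, ...) {
  tidyr::unnest(
    tibble::tibble(cluster = x$clusters$cluster,
                   pivot = x$clusters$pivot,
                   feature_id = x$clusters$members),
    "feature_id") |>
    dplyr::mutate(is_pivot = .data$feature_id == .data$pivot) |>
    dplyr::select("feature_id", "cluster", "pivot", "is_pivot")
}

#' One-row summary of a cluster set
#'
#' @param x A `cluster_set`.
#' @param ... Unused.
#' @return A tibble with `n_features`, `n_clusters`, `n_singletons`,
#'   `max_size`, `t`, `seed`.
#' @method glance cluster_set
#' @export
glance.cluster_set <- function(x, ...) {
  sizes <- lengths(x$clusters$members)
  tibble::tibble(
    n_features = sum(sizes),
    n_clusters = nrow(x$clusters),
    n_singletons = sum(sizes == 1L),
    max_size = if (length(sizes)) max(sizes) else 0L,
    t = x$t, seed = x$seed
  )
}

#' One-row summary of a trained stage classifier
#'
#' @param x A `bp_net` from [train_classifier()].
#' @param ... Unused.
#' @return A tibble with `accuracy`, `n_train`, `n_test`, `n_inputs`,
#'   `classes`, `seed`.
#' @method glance bp_net
#' @export
glance.bp_net <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, n_train = x$n_train,
                 n_test = x$n_test, n_inputs = length(x$center),
                 classes = x$spec$classes, seed = x$seed)
}
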