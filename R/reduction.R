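# Greedy pivot-based correlation clustering of collinear LC-MS features.
# A random pivot is drawn from the surviving pool; every remaining feature
# whose absolute Pearson correlation with the pivot exceeds the threshold
# joins the pivot's cluster and is removed; repeat until the pool is empty.

#' Absolute-Pearson collinearity check
#'
#' Tests whether two feature vectors are collinear at threshold `t`:
#' returns `|pearson(i, j)| > t` (strict inequality; a tie at exactly `t`
#' counts as not collinear). The absolute value ignores correlation
#' direction, so anti-correlated features (adducts measured in opposite
#' modes, for instance) cluster together.
#'
#' @param i,j Equal-length numeric vectors (length >= 3) with nonzero
#'   variance.
#' @param t Threshold in `[0, 1)`.
#' @param min_overlap Minimum number of pairwise-complete observations; pairs
#'   with fewer are treated as not collinear.
#' @return Logical scalar, or `NA` if the correlation is undefined
#'   (zero variance on the complete cases).
#' @examples
#' pearson_threshold_check(1:4, c(1, 2, 4, 3), t = 0.45)
#' @export
pearson_threshold_check <- function(i, j, t = 0.45, min_overlap = 10L) {
  if (length(i) != length(j)) {
    stop("feature vectors must have equal length", call. = FALSE)
  }
  if (length(i) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (t < 0 || t >= 1) stop("threshold t must lie in [0, 1)", call. = FALSE)
  ok <- stats::complete.cases(i, j)
  if (sum(ok) < max(3L, min_overlap)) return(FALSE)
  if (stats::sd(i[ok]) == 0 || stats::sd(j[ok]) == 0) return(NA)
  abs(stats::cor(i[ok], j[ok])) > t
}

#' Pivot-based correlation clustering of a feature table
#'
#' Partitions features into collinearity clusters by the greedy pivot
#' algorithm: draw a uniform-random pivot from the remaining features (seeded
#' RNG), gather every remaining feature with `|r| > t` against the pivot into
#' the pivot's cluster, remove them, and repeat until no features remain.
#' Every non-pivot member therefore has `|r| > t` with its pivot, and any two
#' pivots have `|r| <= t`.
#'
#' Correlations are computed on pairwise-complete observations with a minimum
#' overlap of `min_overlap` samples (sparser pairs count as not collinear).
#' Zero-variance features carry no correlation signal and are set aside as
#' singleton clusters before pivoting starts.
#'
#' @param features A data frame whose numeric columns are features (a
#'   `sample_id` column, if present, is ignored), or a numeric matrix.
#' @param t Absolute-correlation threshold in `[0, 1)`; default 0.45.
#' @param seed Integer seed for the pivot draws.
#' @param min_overlap Minimum pairwise-complete overlap for a correlation.
#' @return A `cluster_set`: list with `clusters` (tibble: `cluster`, `pivot`,
#'   `members` list-column including the pivot), `pivot_order` (pivots in
#'   draw order; zero-variance singletons listed first), `t`, `seed`.
#' @examples
#' x <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
#' x[, 2] <- x[, 1] + rnorm(100, sd = 0.1)
#' correlation_cluster(x, t = 0.45, seed = 1)
#' @export
correlation_cluster <- function(features, t = 0.45, seed = 1L,
                                min_overlap = 10L) {
  m <- as_feature_matrix(features)
  if (t < 0 || t >= 1) stop("threshold t must lie in [0, 1)", call. = FALSE)
  ids <- colnames(m)
  if (length(ids) == 0) {
    return(new_cluster_set(tibble::tibble(cluster = integer(),
                                          pivot = character(),
                                          members = list()),
                           character(), t, seed))
  }
  variances <- apply(m, 2, stats::var, na.rm = TRUE)
  degenerate <- ids[is.na(variances) | variances == 0]
  pool <- setdiff(ids, degenerate)

  clusters <- list()
  pivots <- character()
  for (id in degenerate) {
    clusters[[length(clusters) + 1L]] <- list(pivot = id, members = id)
    pivots <- c(pivots, id)
  }
  with_local_seed(seed, {
    while (length(pool) > 0) {
      pivot <- pool[sample.int(length(pool), 1L)]
      rest <- setdiff(pool, pivot)
      hits <- character()
      if (length(rest)) {
        r <- suppressWarnings(
          stats::cor(m[, pivot], m[, rest, drop = FALSE],
                     use = "pairwise.complete.obs"))
        n_ok <- crossprod(!is.na(m[, pivot, drop = FALSE]),
                          !is.na(m[, rest, drop = FALSE]))
        pass <- !is.na(r) & abs(r) > t & n_ok >= min_overlap
        hits <- rest[as.vector(pass)]
      }
      clusters[[length(clusters) + 1L]] <-
        list(pivot = pivot, members = c(pivot, hits))
      pivots <- c(pivots, pivot)
      pool <- setdiff(rest, hits)
    }
  })
  tbl <- tibble::tibble(
    cluster = seq_along(clusters),
    pivot = vapply(clusters, `[[`, character(1), "pivot"),
    members = lapply(clusters, `[[`, "members")
  )
  new_cluster_set(tbl, pivots, t, seed)
}

new_cluster_set <- function(clusters, pivot_order, t, seed) {
  structure(list(clusters = clusters, pivot_order = pivot_order,
                 t = t, seed = as.integer(seed)),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  sizes <- lengths(x$clusters$members)
  cat("<cluster_set>", sum(sizes), "features in", nrow(x$clusters),
      "clusters (t =", x$t, ", seed =", x$seed, ")\n")
  if (length(sizes)) {
    cat("  cluster sizes: min", min(sizes), "| median", stats::median(sizes),
        "| max", max(sizes), "\n")
  }
  invisible(x)
}

#' Reduce a feature table to one representative per cluster
#'
#' Keeps one column per cluster. The default representative is the pivot:
#' it is the only member guaranteed collinear (at `|r| > t`) with every
#' other member, i.e. the hub of its cluster.
#'
#' @param features The feature table (data frame with `sample_id`, or
#'   matrix) to reduce; must contain every clustered feature.
#' @param clusters A `cluster_set` from [correlation_cluster()].
#' @return The reduced feature table, same type as the input, with
#'   representative columns in cluster order (a `sample_id` column is
#'   preserved in front).
#' @export
select_representatives <- function(features, clusters) {
  stopifnot(inherits(clusters, "cluster_set"))
  keep <- clusters$clusters$pivot
  all_members <- unlist(clusters$clusters$members)
  if (is.matrix(features)) {
    missing <- setdiff(all_members, colnames(features))
    if (length(missing)) {
      stop("cluster members absent from feature table: ",
           paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
    }
    return(features[, keep, drop = FALSE])
  }
  missing <- setdiff(all_members, names(features))
  if (length(missing)) {
    stop("cluster members absent from feature table: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  id_cols <- intersect("sample_id", names(features))
  tibble::as_tibble(features)[, c(id_cols, keep), drop = FALSE]
}

# coerce a feature table (matrix or data frame, optional sample_id) to a
# numeric matrix with feature names
as_feature_matrix <- function(features) {
  if (is.matrix(features)) {
    if (is.null(colnames(features))) {
      colnames(features) <- sprintf("F%04d", seq_len(ncol(features)))
    }
    return(features)
  }
  df <- as.data.frame(features)
  df <- df[, setdiff(names(df), c("sample_id", "cohort")), drop = FALSE]
  num <- vapply(df, is.numeric, logical(1))
  as.matrix(df[, num, drop = FALSE])
}
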