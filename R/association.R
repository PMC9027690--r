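# Per-feature linear-regression association with the blood-pressure code:
# discovery screening with a CKD-stage interaction, validation replication,
# combined covariate-adjusted fit, Benjamini-Hochberg correction, nested
# adjusted-R2 accounting and rank-based ROC AUC.

#' Join a cohort bundle into one analysis table
#'
#' Stages the clinical table (adds `bp_code5`/`bp_code4`/`bp_binary`) and
#' joins the feature columns by `sample_id`.
#'
#' @param bundle A `cohort_bundle`.
#' @param features Optional reduced feature table (e.g. from
#'   [select_representatives()]); defaults to the bundle's full table.
#' @return A tibble with clinical, staging and feature columns.
#' @export
cohort_table <- function(bundle, features = NULL) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  if (is.null(features)) features <- bundle$features
  clinical <- stage_bp(bundle$clinical)
  if (!identical(clinical$sample_id, features$sample_id)) {
    stop("feature and clinical tables must share sample IDs in order",
         call. = FALSE)
  }
  dplyr::left_join(clinical, features, by = "sample_id")
}

#' Ordinary least squares fit of blood pressure on a feature
#'
#' Fits `outcome ~ feature + covariates`, optionally with a
#' `feature x CKD stage` interaction, by OLS via [stats::lm()]. The outcome
#' is the numeric blood-pressure code treated as continuous.
#'
#' @param data A data frame containing all referenced columns.
#' @param outcome Name of the outcome column (default `"bp_code5"`).
#' @param feature Name of the feature column, or `NULL` for a
#'   covariates-only model.
#' @param covariates Character vector of covariate column names.
#' @param interaction If `TRUE`, adds `feature:ckd_stage` (requires
#'   `"ckd_stage"` among the covariates and a non-`NULL` feature).
#' @return A `bp_ols` object wrapping the [stats::lm] fit; see
#'   [tidy.bp_ols()] and [glance.bp_ols()].
#' @examples
#' d <- data.frame(bp_code5 = c(0, 1, 2), x = c(0, 1, 2))
#' coef(ols_fit(d, feature = "x")$fit)
#' @export
ols_fit <- function(data, outcome = "bp_code5", feature = NULL,
                    covariates = character(), interaction = FALSE) {
  cols <- c(outcome, feature, covariates)
  missing <- setdiff(cols, names(data))
  if (length(missing)) {
    stop("column(s) not found: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (interaction) {
    if (is.null(feature)) {
      stop("interaction requires a feature term", call. = FALSE)
    }
    if (!"ckd_stage" %in% covariates) {
      stop("interaction requires 'ckd_stage' among the covariates",
           call. = FALSE)
    }
  }
  rhs <- c(sprintf("`%s`", feature),
           sprintf("`%s`", covariates),
           if (interaction) sprintf("`%s`:`ckd_stage`", feature))
  if (!length(rhs)) rhs <- "1"
  fml <- stats::as.formula(paste(sprintf("`%s`", outcome), "~",
                                 paste(rhs, collapse = " + ")))
  mf <- stats::model.frame(fml, data = data, na.action = stats::na.omit)
  p <- ncol(stats::model.matrix(fml, mf))
  # need at least one residual degree of freedom
  if (nrow(mf) < p + 1L) {
    stop("too few complete observations (", nrow(mf), ") for ", p,
         " model terms", call. = FALSE)
  }
  fit <- stats::lm(fml, data = mf)
  if (anyNA(stats::coef(fit))) {
    bad <- names(which(is.na(stats::coef(fit))))
    stop("singular design: collinear term(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(fit = fit, outcome = outcome, feature = feature,
                 covariates = covariates, interaction = interaction),
            class = "bp_ols")
}

#' @export
print.bp_ols <- function(x, ...) {
  cat("<bp_ols>", x$outcome, "~",
      paste(c(x$feature, x$covariates,
              if (x$interaction) paste0(x$feature, ":ckd_stage")),
            collapse = " + "), "\n")
  print(tidy(x))
  invisible(x)
}

# p-value of the feature main-effect row, with the interaction present
feature_effect <- function(object) {
  stopifnot(inherits(object, "bp_ols"))
  tt <- tidy(object)
  row <- tt[tt$term == object$feature, ]
  if (nrow(row) != 1L) {
    stop("feature term not found in fit: ", object$feature, call. = FALSE)
  }
  row
}

#' Screen features across discovery and validation cohorts
#'
#' For every feature, fits the discovery model
#' `outcome ~ feature * ckd_stage` (the interaction term absorbs the
#' correlation between metabolite levels and CKD severity) and reads the
#' feature *main-effect* p-value; fits the same model in the validation
#' cohort; flags a feature as replicated when the main effect is significant
#' at `alpha` in both cohorts.
#'
#' @param discovery,validation Analysis tables from [cohort_table()], built
#'   with the same representative feature set.
#' @param features Character vector of feature columns to screen; defaults to
#'   all columns shared by both tables that look like feature IDs (numeric,
#'   not clinical/staging columns).
#' @param outcome Outcome column (default `"bp_code5"`).
#' @param covariates Covariates for the cohort-specific models (default
#'   `"ckd_stage"` only).
#' @param interaction Include the `feature:ckd_stage` interaction (default
#'   `TRUE`).
#' @param alpha Significance level for screening and replication.
#' @return An `assoc_table` tibble with one row per screened feature:
#'   `estimate_discovery`, `p_discovery`, `estimate_validation`,
#'   `p_validation`, `replicated`.
#' @export
screen_features <- function(discovery, validation, features = NULL,
                            outcome = "bp_code5",
                            covariates = "ckd_stage",
                            interaction = TRUE, alpha = 0.05) {
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]", call. = FALSE)
  if (is.null(features)) {
    reserved <- c("sample_id", "cohort", "stratum", "ckd_stage", "sex",
                  "age", "egfr", "weight", "bmi", "systolic", "diastolic",
                  "bp_code5", "bp_code4", "bp_binary")
    features <- intersect(setdiff(names(discovery), reserved),
                          names(validation))
    features <- features[vapply(discovery[features], is.numeric, logical(1))]
  }
  absent <- setdiff(features, intersect(names(discovery), names(validation)))
  if (length(absent)) {
    stop("feature(s) missing from a cohort: ",
         paste(utils::head(absent, 5), collapse = ", "), call. = FALSE)
  }
  one_cohort <- function(data, feat) {
    fit <- ols_fit(data, outcome = outcome, feature = feat,
                   covariates = covariates, interaction = interaction)
    feature_effect(fit)
  }
  rows <- purrr::map(features, function(feat) {
    d <- one_cohort(discovery, feat)
    v <- one_cohort(validation, feat)
    tibble::tibble(
      feature_id = feat,
      estimate_discovery = d$estimate, se_discovery = d$std.error,
      p_discovery = d$p.value,
      estimate_validation = v$estimate, se_validation = v$std.error,
      p_validation = v$p.value
    )
  })
  out <- dplyr::bind_rows(rows)
  out$replicated <- out$p_discovery < alpha & out$p_validation < alpha
  attr(out, "alpha") <- alpha
  class(out) <- c("assoc_table", class(out))
  out
}

#' Combined-cohort fit and multiple-testing correction
#'
#' Refits each replicated feature on the pooled cohorts with the full
#' clinical adjustment (`outcome ~ feature + ckd_stage + egfr + age +
#' weight + bmi` by default; no interaction, sex excluded as it shows no
#' association with blood pressure in this design), then applies
#' Benjamini-Hochberg correction to the combined p-values of the replicated
#' set.
#'
#' @param assoc An `assoc_table` from [screen_features()].
#' @param pooled A pooled analysis table (both cohorts row-bound; keep a
#'   `cohort` column for provenance).
#' @param outcome Outcome column.
#' @param covariates Covariates for the combined model.
#' @param only_replicated Fit only replicated features (default `TRUE`,
#'   mirroring the replication design).
#' @return The `assoc_table` with `estimate_combined`, `se_combined`,
#'   `p_combined`, `adj_r2_combined`, `p_adjusted` (BH over the fitted set),
#'   and logical flags `significant_raw` (`p_combined < alpha`) and
#'   `significant_adjusted` (`p_adjusted < alpha`), ordered by `p_combined`.
#' @export
combined_fit <- function(assoc, pooled, outcome = "bp_code5",
                         covariates = c("ckd_stage", "egfr", "age",
                                        "weight", "bmi"),
                         only_replicated = TRUE) {
  stopifnot(inherits(assoc, "assoc_table"))
  alpha <- attr(assoc, "alpha") %||% 0.05
  target <- if (only_replicated) assoc$feature_id[assoc$replicated]
            else assoc$feature_id
  res <- purrr::map(target, function(feat) {
    fit <- ols_fit(pooled, outcome = outcome, feature = feat,
                   covariates = covariates, interaction = FALSE)
    eff <- feature_effect(fit)
    tibble::tibble(feature_id = feat,
                   estimate_combined = eff$estimate,
                   se_combined = eff$std.error,
                   p_combined = eff$p.value,
                   adj_r2_combined = glance(fit)$adj.r.squared)
  })
  res <- dplyr::bind_rows(res)
  if (nrow(res) == 0) {
    res <- tibble::tibble(feature_id = character(),
                          estimate_combined = numeric(),
                          se_combined = numeric(), p_combined = numeric(),
                          adj_r2_combined = numeric(),
                          p_adjusted = numeric())
  } else {
    res$p_adjusted <- bh_adjust(res$p_combined)
  }
  out <- dplyr::left_join(tibble::as_tibble(assoc), res, by = "feature_id")
  out$significant_raw <- !is.na(out$p_combined) & out$p_combined < alpha
  out$significant_adjusted <- !is.na(out$p_adjusted) & out$p_adjusted < alpha
  out <- dplyr::arrange(out, .data$p_combined)
  attr(out, "alpha") <- alpha
  class(out) <- c("assoc_table", class(out))
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate correction: the adjusted value of `p_i` is
#' `min over j with p_j >= p_i of (m * p_j / rank_j)`, capped at 1. Wraps
#' [stats::p.adjust()] with input validation.
#'
#' @param p Numeric vector of raw p-values in `(0, 1]`.
#' @return Adjusted p-values, same order as the input.
#' @examples
#' bh_adjust(c(0.001, 0.01, 0.04, 0.5))
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric())
  if (anyNA(p) || any(p <= 0 | p > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Cumulative adjusted R-squared over nested models
#'
#' Fits the covariates-only model, then adds the given features one at a
#' time (in the supplied order, conventionally by ascending combined
#' p-value), recording the adjusted R-squared of each nested model. This is
#' the variance-explained accounting behind "clinical covariates explain X%,
#' adding the metabolites raises it to Y%".
#'
#' @param data Pooled analysis table.
#' @param features Feature columns in the order they are added.
#' @param outcome Outcome column.
#' @param covariates Base covariates (may be empty for a metabolites-only
#'   trajectory; the intercept-only model then opens the sequence).
#' @return A tibble with `step` (0 = covariates only), `feature_added`,
#'   `r2`, `adj_r2`, `n`.
#' @export
cumulative_r2 <- function(data, features, outcome = "bp_code5",
                          covariates = c("ckd_stage", "egfr", "age",
                                         "weight", "bmi")) {
  steps <- c(list(character(0)), lapply(seq_along(features),
                                        function(k) features[seq_len(k)]))
  purrr::map2_dfr(steps, c(NA_character_, features), function(feats, added) {
    fit <- if (length(feats) == 0 && length(covariates) == 0) {
      ols_fit(data, outcome = outcome, feature = NULL,
              covariates = character())
    } else if (length(feats) == 1 && length(covariates) == 0) {
      ols_fit(data, outcome = outcome, feature = feats,
              covariates = character())
    } else {
      ols_fit(data, outcome = outcome,
              feature = if (length(feats)) feats[length(feats)] else NULL,
              covariates = c(covariates, feats[-length(feats)]))
    }
    g <- glance(fit)
    tibble::tibble(step = length(feats), feature_added = added,
                   r2 = g$r.squared, adj_r2 = g$adj.r.squared, n = g$nobs)
  })
}

#' Rank-based ROC AUC
#'
#' Area under the ROC curve for a continuous score against binary labels,
#' computed as the Mann-Whitney rank statistic with midranks for ties:
#' `AUC = (R1 - n1 (n1 + 1) / 2) / (n1 n0)` where `R1` is the rank sum of the
#' positive class. Equals the probability that a random positive scores above
#' a random negative (ties count 1/2).
#'
#' @param values Numeric score (e.g. a metabolite intensity).
#' @param labels Binary labels: logical, 0/1, or a two-level factor whose
#'   *second* level (e.g. `"high"` from [bp_binary()]) is the positive class.
#' @return AUC in `[0, 1]`.
#' @examples
#' roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))
#' @export
roc_auc <- function(values, labels) {
  pos <- as_positive(labels)
  ok <- !is.na(values) & !is.na(pos)
  values <- values[ok]; pos <- pos[ok]
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) {
    stop("both classes must be present to compute an AUC", call. = FALSE)
  }
  r <- rank(values)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Empirical ROC curve
#'
#' @inheritParams roc_auc
#' @return A tibble with `threshold`, `tpr`, `fpr`, ordered from the
#'   all-positive corner to the origin, of class `bp_roc` (see
#'   [autoplot.bp_roc()]).
#' @export
roc_curve <- function(values, labels) {
  pos <- as_positive(labels)
  ok <- !is.na(values) & !is.na(pos)
  values <- values[ok]; pos <- pos[ok]
  if (!any(pos) || all(pos)) {
    stop("both classes must be present to compute a ROC curve",
         call. = FALSE)
  }
  cuts <- c(-Inf, sort(unique(values)))
  out <- tibble::tibble(
    threshold = cuts,
    tpr = vapply(cuts, function(c) mean(values[pos] > c), numeric(1)),
    fpr = vapply(cuts, function(c) mean(values[!pos] > c), numeric(1))
  )
  class(out) <- c("bp_roc", class(out))
  out
}

as_positive <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.factor(labels)) {
    if (nlevels(labels) != 2L) {
      stop("labels must have exactly two levels", call. = FALSE)
    }
    return(labels == levels(labels)[2])
  }
  u <- sort(unique(stats::na.omit(labels)))
  if (length(u) > 2L) stop("labels must be binary", call. = FALSE)
  labels == max(u)
}
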