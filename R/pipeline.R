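# End-to-end orchestration: simulate (or load) -> stage -> reduce ->
# associate -> (optionally) importance, with TSV/JSON outputs and a
# provenance record sufficient to re-execute the run bit-identically.

#' Run the full association pipeline
#'
#' Executes, in order: cohort simulation (or loading of previously written
#' bundles), blood-pressure staging, correlation-clustering feature
#' reduction fit on the discovery cohort and applied to both, two-cohort
#' replication screening, the pooled covariate-adjusted combined fit with
#' Benjamini-Hochberg correction, and (optionally) the neural-network
#' ablation importance of the significant features. Stage outputs and a
#' provenance log are written under `dir` when given.
#'
#' @param config A [sim_config()], or a list with `discovery`/`validation`
#'   `cohort_bundle`s (e.g. from [read_bundle()]).
#' @param dir Optional output directory for TSV/JSON stage outputs.
#' @param t Absolute-correlation threshold of the reduction (default 0.45).
#' @param alpha Significance level for screening/replication.
#' @param covariates Covariates of the combined model.
#' @param reduce_on `"discovery"` (default: fit the clustering on discovery
#'   and reuse its representatives for validation, avoiding validation
#'   leakage) or `"pooled"`.
#' @param run_importance If `TRUE`, computes ablation importance of the
#'   `significant_raw` features (plus clinical covariates) with
#'   `importance_spec`/`importance_seeds`.
#' @param importance_spec Optional [net_spec()] template arguments as a
#'   list (e.g. `list(epochs = 100)`).
#' @param importance_seeds Seeds for the importance averaging.
#' @param seed Seed for the reduction's pivot draws.
#' @return A list of class `bp_run`: `config`, `cohorts`, `clusters`,
#'   `assoc` (the association table), `pooled` (pooled analysis table),
#'   `importance` (or `NULL`), and `provenance` (per-stage row/column
#'   counts, seeds, parameters).
#' @export
run_pipeline <- function(config, dir = NULL, t = 0.45, alpha = 0.05,
                         covariates = c("ckd_stage", "egfr", "age",
                                        "weight", "bmi"),
                         reduce_on = c("discovery", "pooled"),
                         run_importance = FALSE,
                         importance_spec = list(),
                         importance_seeds = 1:5,
                         seed = 1L) {
  reduce_on <- match.arg(reduce_on)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      if (!is.null(dir)) {
        writeLines(paste("FAILED at stage:", name, "-", conditionMessage(e)),
                   file.path(dir, "FAILED"))
      }
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  if (!is.null(dir) && !dir.exists(dir)) dir.create(dir, recursive = TRUE)

  cohorts <- stage("simulate", {
    if (inherits(config, "sim_config")) simulate_cohorts(config)
    else {
      stopifnot(inherits(config$discovery, "cohort_bundle"),
                inherits(config$validation, "cohort_bundle"))
      config
    }
  })

  clusters <- stage("reduce", {
    feats <- if (reduce_on == "discovery") {
      cohorts$discovery$features
    } else {
      dplyr::bind_rows(cohorts$discovery$features,
                       cohorts$validation$features)
    }
    correlation_cluster(feats, t = t, seed = seed)
  })

  tables <- stage("stage", {
    lapply(cohorts, function(b) {
      cohort_table(b, select_representatives(b$features, clusters))
    })
  })
  pooled <- dplyr::bind_rows(tables$discovery, tables$validation)

  assoc <- stage("associate", {
    screened <- screen_features(tables$discovery, tables$validation,
                                alpha = alpha)
    combined_fit(screened, pooled, covariates = covariates)
  })

  importance <- NULL
  if (run_importance) {
    importance <- stage("importance", {
      mets <- assoc$feature_id[assoc$significant_raw]
      if (length(mets) == 0) {
        warning("no significant features; skipping importance stage",
                call. = FALSE)
        NULL
      } else {
        args <- utils::modifyList(
          list(features = c("age", "weight", "bmi", "egfr", mets)),
          importance_spec)
        spec <- do.call(net_spec, args)
        ablation_importance(pooled, spec, features_to_test = mets,
                            seeds = importance_seeds)
      }
    })
  }

  provenance <- list(
    seed = seed, t = t, alpha = alpha, covariates = covariates,
    reduce_on = reduce_on,
    sim_seed = if (inherits(config, "sim_config")) config$seed else NA,
    n_discovery = nrow(tables$discovery),
    n_validation = nrow(tables$validation),
    n_features_input = ncol(cohorts$discovery$features) - 1L,
    n_features_reduced = nrow(clusters$clusters),
    n_screened = nrow(assoc),
    n_replicated = sum(assoc$replicated),
    n_significant_raw = sum(assoc$significant_raw),
    n_significant_adjusted = sum(assoc$significant_adjusted),
    timestamp = format(Sys.time(), tz = "UTC")
  )

  if (!is.null(dir)) {
    stage("write", {
      readr::write_tsv(tibble::as_tibble(assoc), file.path(dir, "assoc.tsv"))
      jsonlite::write_json(
        list(t = clusters$t, seed = clusters$seed,
             pivot_order = clusters$pivot_order,
             clusters = lapply(seq_len(nrow(clusters$clusters)), function(i) {
               list(pivot = clusters$clusters$pivot[i],
                    members = clusters$clusters$members[[i]])
             })),
        file.path(dir, "clusters.json"), auto_unbox = TRUE)
      if (!is.null(importance)) {
        readr::write_tsv(tibble::as_tibble(importance),
                         file.path(dir, "importance.tsv"))
      }
      jsonlite::write_json(provenance, file.path(dir, "provenance.json"),
                           auto_unbox = TRUE, digits = NA)
    })
  }

  structure(list(config = config, cohorts = cohorts, clusters = clusters,
                 tables = tables, pooled = pooled, assoc = assoc,
                 importance = importance, provenance = provenance),
            class = "bp_run")
}

#' @export
print.bp_run <- function(x, ...) {
  p <- x$provenance
  cat("<bp_run>\n")
  cat("  cohorts:", p$n_discovery, "discovery +", p$n_validation,
      "validation samples\n")
  cat("  features:", p$n_features_input, "->", p$n_features_reduced,
      "representatives (t =", p$t, ")\n")
  cat("  replicated:", p$n_replicated, "| combined p <", p$alpha, ":",
      p$n_significant_raw, "| BH-adjusted <", p$alpha, ":",
      p$n_significant_adjusted, "\n")
  invisible(x)
}
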