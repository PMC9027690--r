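# Two-cohort synthetic generator: block-collinear log-normal LC-MS features,
# stratified clinical covariates, and a blood-pressure code produced by
# discretizing a latent linear predictor.

# run expr with a private RNG stream; leaves the caller's stream untouched
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# inverse-CDF truncated normal; exact, vectorized
rtrunc_norm <- function(n, mean, sd, lower, upper) {
  lo <- stats::pnorm((lower - mean) / sd)
  hi <- stats::pnorm((upper - mean) / sd)
  mean + sd * stats::qnorm(stats::runif(n, lo, hi))
}

# (systolic, diastolic) boxes guaranteed to map back to each 5-level code
bp_stage_boxes <- function() {
  list(
    `1` = c(sys_lo = 95, sys_hi = 119.5, dia_lo = 55, dia_hi = 79.5),
    `2` = c(sys_lo = 120, sys_hi = 129.5, dia_lo = 55, dia_hi = 79.5),
    `3` = c(sys_lo = 130, sys_hi = 139.5, dia_lo = 80, dia_hi = 89.5),
    `4` = c(sys_lo = 140, sys_hi = 180, dia_lo = 90, dia_hi = 120),
    `5` = c(sys_lo = 181, sys_hi = 230, dia_lo = 121, dia_hi = 140)
  )
}

#' Simulate paired discovery and validation cohorts
#'
#' Generates two independent cohorts from the same generative process:
#'
#' 1. Clinical covariates (sex, age, eGFR, weight, BMI) are drawn per CKD
#'    stratum as truncated normals around the reference means/SDs of
#'    [stratum_reference()] (age 18--95, weight 35--150, BMI 14--45,
#'    eGFR > 1).
#' 2. Feature intensities are log-normal: each of the `n_clusters` blocks has
#'    one latent Gaussian factor per sample; a feature's log intensity mixes
#'    its block factor with independent noise (random sign per feature, so
#'    within-block correlations can be negative) and is exponentiated. The
#'    factor loading is calibrated so the expected pairwise Pearson |r| of
#'    *intensities* within a block matches `within_cluster_r`.
#' 3. A latent blood-pressure score is the linear combination of the clinical
#'    covariates (`covariate_effects`), the causal feature intensities
#'    (`effect_sizes`), and Gaussian noise (`noise_sd`). Within each cohort
#'    the score is cut at the `stage_probs` quantiles into stage codes 1--5,
#'    and a (systolic, diastolic) pair is sampled uniformly inside that
#'    stage's definition box, so [bp_code5()] recovers the latent stage
#'    exactly.
#'
#' Causal features are placed in distinct blocks (the first member of a
#' block by default, or a later member when `causal_member > 1`, to study
#' whether planted signal survives reduction to a different representative).
#'
#' @param config A [sim_config()].
#' @param causal_member 1-based position within its block at which each
#'   causal feature is placed (clipped to the block size). Default 1.
#' @return A list with elements `discovery` and `validation`, each a
#'   `cohort_bundle`: a list with `features` (tibble, `sample_id` + one
#'   column per feature), `feature_meta` (feature_id, mz, rt), `clinical`
#'   (sample_id, cohort, stratum, ckd_stage, sex, age, egfr, weight, bmi,
#'   systolic, diastolic), and `truth` (list: `causal` tibble of feature_id,
#'   effect, block; `blocks` tibble of feature_id, block).
#' @examples
#' cohorts <- simulate_cohorts(sim_config(n_discovery = rep(5, 6),
#'   n_validation = rep(5, 6), n_features = 20, n_clusters = 5,
#'   n_causal = 2, seed = 7))
#' dim(cohorts$discovery$features)
#' @export
simulate_cohorts <- function(config, causal_member = 1L) {
  stopifnot(inherits(config, "sim_config"))
  with_local_seed(config$seed, {
    blocks <- rep(seq_len(config$n_clusters), times = config$cluster_sizes)
    n_feat <- config$n_features
    feature_ids <- sprintf("F%04d", seq_len(n_feat))
    feature_meta <- tibble::tibble(
      feature_id = feature_ids,
      mz = round(stats::runif(n_feat, 50, 1200), 4),
      rt = round(stats::runif(n_feat, 0.5, 18), 2)
    )
    signs <- ifelse(stats::runif(n_feat) < 0.5, -1, 1)
    # first member of each block anchors the block's orientation
    signs[!duplicated(blocks)] <- 1

    # calibrate the log-scale factor correlation so that the Pearson
    # correlation of the exponentiated intensities hits within_cluster_r
    s2 <- config$feature_sdlog^2
    rho <- log(1 + config$within_cluster_r * (exp(s2) - 1)) / s2
    rho <- min(rho, 0.999)

    causal_idx <- integer(0)
    if (config$n_causal > 0) {
      causal_blocks <- seq_len(config$n_causal)
      causal_idx <- vapply(causal_blocks, function(b) {
        members <- which(blocks == b)
        members[min(max(causal_member, 1L), length(members))]
      }, integer(1))
    }
    truth <- list(
      causal = tibble::tibble(
        feature_id = feature_ids[causal_idx],
        effect = config$effect_sizes,
        block = blocks[causal_idx]
      ),
      blocks = tibble::tibble(feature_id = feature_ids, block = blocks)
    )

    make_cohort <- function(cohort, sizes, prefix) {
      n <- sum(sizes)
      strata <- rep(c("control", paste0("ckd", 1:5)), times = sizes)
      ref <- config$stratum_params[config$stratum_params$cohort == cohort, ]
      ref <- ref[match(strata, ref$stratum), ]
      clinical <- tibble::tibble(
        sample_id = sprintf("%s%04d", prefix, seq_len(n)),
        cohort = cohort,
        stratum = strata,
        ckd_stage = ref$ckd_stage,
        sex = ifelse(stats::runif(n) < ref$male_frac, "male", "female"),
        age = rtrunc_norm(n, ref$age_mean, ref$age_sd, 18, 95),
        egfr = rtrunc_norm(n, ref$egfr_mean, ref$egfr_sd, 1, Inf),
        weight = rtrunc_norm(n, ref$weight_mean, ref$weight_sd, 35, 150),
        bmi = rtrunc_norm(n, ref$bmi_mean, ref$bmi_sd, 14, 45)
      )

      factors <- matrix(stats::rnorm(n * config$n_clusters), n)
      noise <- matrix(stats::rnorm(n * n_feat), n)
      g <- factors[, blocks, drop = FALSE] * sqrt(rho) + noise * sqrt(1 - rho)
      g <- sweep(g, 2, signs, `*`)
      intens <- exp(config$feature_sdlog * g)
      colnames(intens) <- feature_ids

      eff <- config$covariate_effects
      eta <- eff[["ckd_stage"]] * clinical$ckd_stage +
        eff[["egfr"]] * clinical$egfr + eff[["age"]] * clinical$age +
        eff[["weight"]] * clinical$weight + eff[["bmi"]] * clinical$bmi +
        stats::rnorm(n, 0, config$noise_sd)
      if (length(causal_idx)) {
        eta <- eta + drop(intens[, causal_idx, drop = FALSE] %*%
                            config$effect_sizes)
      }
      cuts <- stats::quantile(eta, cumsum(config$stage_probs)[1:4],
                              names = FALSE)
      code <- 1L + rowSums(outer(eta, cuts, `>`))
      boxes <- bp_stage_boxes()
      box <- do.call(rbind, boxes)[code, , drop = FALSE]
      clinical$systolic <- round(stats::runif(n, box[, "sys_lo"],
                                              box[, "sys_hi"]), 1)
      clinical$diastolic <- round(stats::runif(n, box[, "dia_lo"],
                                               box[, "dia_hi"]), 1)

      features <- tibble::as_tibble(as.data.frame(intens))
      features <- tibble::add_column(features,
                                     sample_id = clinical$sample_id,
                                     .before = 1)
      structure(list(features = features, feature_meta = feature_meta,
                     clinical = clinical, truth = truth),
                class = "cohort_bundle")
    }

    list(discovery = make_cohort("discovery", config$n_discovery, "D"),
         validation = make_cohort("validation", config$n_validation, "V"))
  })
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat("<cohort_bundle>", unique(x$clinical$cohort), "\n")
  cat("  samples:", nrow(x$clinical),
      "| features:", nrow(x$feature_meta),
      "| causal:", nrow(x$truth$causal), "\n")
  invisible(x)
}

#' Feature matrix of a cohort bundle
#'
#' @param bundle A `cohort_bundle`.
#' @return Numeric matrix (samples x features) with sample IDs as row names.
#' @export
feature_matrix <- function(bundle) {
  m <- as.matrix(bundle$features[, -1, drop = FALSE])
  rownames(m) <- bundle$features$sample_id
  m
}
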