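test_that("ols_fit recovers exact fits and the closed-form line", {
  d <- tibble::tibble(bp_code5 = c(0, 1, 2), x = c(0, 1, 2))
  # noiseless designs make summary.lm warn about the perfect fit; expected here
  fit <- suppressWarnings(ols_fit(d, feature = "x"))
  tt <- suppressWarnings(tidy(fit))
  expect_equal(tt$estimate[tt$term == "x"], 1)
  expect_equal(tt$estimate[tt$term == "(Intercept)"], 0)

  withr::with_seed(10, {
    d2 <- tibble::tibble(x = rnorm(30))
    d2$bp_code5 <- 2 + 3 * d2$x
  })
  fit2 <- ols_fit(d2, feature = "x")
  tt2 <- suppressWarnings(tidy(fit2))
  expect_equal(tt2$estimate[2], 3, tolerance = 1e-10)
  expect_equal(suppressWarnings(glance(fit2))$r.squared, 1, tolerance = 1e-10)
  expect_lt(tt2$p.value[2], 1e-10)
})

test_that("ols_fit matches the normal-equations closed form on random designs", {
  for (case in 1:20) {
    withr::with_seed(case, {
      n <- sample(10:30, 1)
      p <- sample(1:5, 1)
      X <- matrix(rnorm(n * p), n, p)
      y <- rnorm(n)
    })
    d <- tibble::as_tibble(as.data.frame(X))
    names(d) <- paste0("v", seq_len(p))
    d$bp_code5 <- y
    fit <- ols_fit(d, feature = "v1",
                   covariates = if (p > 1) paste0("v", 2:p) else character())
    tt <- tidy(fit)

    Xd <- cbind(1, X)
    beta <- solve(crossprod(Xd), crossprod(Xd, y))
    resid <- y - Xd %*% beta
    s2 <- sum(resid^2) / (n - p - 1)
    se <- sqrt(diag(s2 * solve(crossprod(Xd))))
    pval <- 2 * pt(abs(beta / se), df = n - p - 1, lower.tail = FALSE)

    ord <- match(c("(Intercept)", paste0("v", 1:p)), tt$term)
    expect_equal(tt$estimate[ord], as.vector(beta), tolerance = 1e-8)
    expect_equal(tt$std.error[ord], as.vector(se), tolerance = 1e-8)
    expect_equal(tt$p.value[ord], as.vector(pval), tolerance = 1e-8)

    g <- glance(fit)
    r2 <- 1 - sum(resid^2) / sum((y - mean(y))^2)
    expect_equal(g$r.squared, r2, tolerance = 1e-8)
    expect_equal(g$adj.r.squared, 1 - (1 - r2) * (n - 1) / (n - p - 1),
                 tolerance = 1e-8)
  }
})

test_that("ols_fit p-values are calibrated under the null", {
  hits <- withr::with_seed(77, {
    vapply(1:400, function(i) {
      d <- tibble::tibble(bp_code5 = rnorm(25), x = rnorm(25))
      tidy(ols_fit(d, feature = "x"))$p.value[2] < 0.05
    }, logical(1))
  })
  expect_true(abs(mean(hits) - 0.05) < 3 * sqrt(0.05 * 0.95 / 400))
})

test_that("degenerate designs are rejected with informative errors", {
  d <- tibble::tibble(bp_code5 = rnorm(20), x = rnorm(20))
  d$x2 <- d$x
  expect_error(ols_fit(d, feature = "x", covariates = "x2"), "singular|collinear")
  expect_error(ols_fit(d[1:3, ], feature = "x", covariates = "x2"), "few")
  expect_error(ols_fit(d, feature = "missing"), "not found")
  expect_error(ols_fit(d, feature = "x", covariates = "x2",
                       interaction = TRUE), "ckd_stage")
})

test_that("bh_adjust matches a brute-force step-up oracle", {
  # adjusted_i = min over j with p_j >= p_i of m * p_j / rank_j, capped at 1
  bh_oracle <- function(p) {
    m <- length(p)
    vapply(p, function(pi) {
      min(1, vapply(p[p >= pi],
                    function(pj) m * pj / sum(p <= pj), numeric(1)))
    }, numeric(1))
  }
  withr::with_seed(123, {
    for (case in 1:200) {
      m <- sample(1:50, 1)
      p <- runif(m)
      if (case %% 5 == 0) p <- pmin(round(p, 1) + 1e-6, 1)  # force ties
      expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
    }
  })
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(0.02, 8)), rep(0.02, 8))
  expect_error(bh_adjust(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bh_adjust(c(0.5, 1.2)), "\\(0, 1\\]")
})

test_that("BH over the reference combined p-values reproduces the published column", {
  ref <- read_reference_associations()
  adj <- bh_adjust(ref$p_combined)
  expect_equal(signif(adj, 3), ref$p_adjusted_published)
})

test_that("screening flags replication only when both cohorts are significant", {
  cfg <- small_config(n_discovery = rep(40L, 6), n_validation = rep(40L, 6),
                      n_causal = 1L, seed = 31)
  cohorts <- simulate_cohorts(cfg)
  disc <- cohort_table(cohorts$discovery)
  val <- cohort_table(cohorts$validation)
  assoc <- screen_features(disc, val)
  expect_identical(nrow(assoc), 40L)
  expect_identical(assoc$replicated,
                   assoc$p_discovery < 0.05 & assoc$p_validation < 0.05)

  none <- screen_features(disc, val, alpha = 0)
  expect_false(any(none$replicated))

  # identical cohorts give symmetric discovery/validation columns
  sym <- screen_features(disc, disc)
  expect_equal(sym$p_discovery, sym$p_validation)
  expect_equal(sym$estimate_discovery, sym$estimate_validation)

  expect_error(screen_features(disc, val, features = "nope"), "missing")
})

test_that("the combined fit is deterministic and BH-corrected over the fitted set", {
  cfg <- small_config(n_discovery = rep(30L, 6), n_validation = rep(30L, 6),
                      n_causal = 2L, seed = 41)
  cohorts <- simulate_cohorts(cfg)
  disc <- cohort_table(cohorts$discovery)
  val <- cohort_table(cohorts$validation)
  pooled <- dplyr::bind_rows(disc, val)
  # duplicate a feature under a second ID
  feat <- cohorts$discovery$truth$causal$feature_id[1]
  disc$dup <- disc[[feat]]; val$dup <- val[[feat]]; pooled$dup <- pooled[[feat]]
  assoc <- screen_features(disc, val, features = c(feat, "dup"))
  out <- combined_fit(assoc, pooled, only_replicated = FALSE)
  expect_equal(out$estimate_combined[out$feature_id == feat],
               out$estimate_combined[out$feature_id == "dup"])
  expect_equal(out$p_combined[out$feature_id == feat],
               out$p_combined[out$feature_id == "dup"])
  fitted <- !is.na(out$p_combined)
  expect_equal(out$p_adjusted[fitted], bh_adjust(out$p_combined[fitted]))
  expect_true(all(out$p_adjusted[fitted] >= out$p_combined[fitted]))
})

test_that("a pure-noise feature does not raise adjusted R-squared", {
  deltas <- vapply(1:20, function(s) {
    withr::with_seed(s, {
      d <- tibble::tibble(bp_code5 = rnorm(120), ckd_stage = rnorm(120),
                          noise = rnorm(120))
    })
    traj <- cumulative_r2(d, features = "noise", covariates = "ckd_stage")
    diff(traj$adj_r2)
  }, numeric(1))
  expect_lte(mean(deltas), 0.005)
})

test_that("cumulative_r2 walks the nested models and rejects collinear additions", {
  cfg <- small_config(n_discovery = rep(25L, 6), n_validation = rep(25L, 6),
                      n_causal = 2L, seed = 51)
  cohorts <- simulate_cohorts(cfg)
  pooled <- dplyr::bind_rows(cohort_table(cohorts$discovery),
                             cohort_table(cohorts$validation))
  feats <- cohorts$discovery$truth$causal$feature_id
  traj <- cumulative_r2(pooled, features = feats)
  expect_identical(nrow(traj), length(feats) + 1L)
  expect_identical(traj$step, 0:length(feats))
  expect_true(is.na(traj$feature_added[1]))
  # causal features add real variance explained
  expect_gt(traj$adj_r2[nrow(traj)], traj$adj_r2[1])

  pooled$copy_of_age <- pooled$age
  expect_error(cumulative_r2(pooled, features = "copy_of_age"),
               "singular|collinear")
})

test_that("roc_auc equals pairwise enumeration on every 4-point label pattern", {
  auc_enum <- function(values, labels) {
    pos <- which(labels == 1); neg <- which(labels == 0)
    cmp <- outer(values[pos], values[neg],
                 function(a, b) (a > b) + 0.5 * (a == b))
    mean(cmp)
  }
  values_sets <- list(c(1, 2, 3, 4), c(1, 2, 2, 3), c(5, 5, 5, 5))
  for (v in values_sets) {
    for (mask in 1:14) {  # all non-degenerate 4-bit label patterns
      labels <- as.integer(intToBits(mask))[1:4]
      if (all(labels == 0) || all(labels == 1)) next
      expect_equal(roc_auc(v, labels), auc_enum(v, labels),
                   label = paste("values", paste(v, collapse = ","),
                                 "labels", paste(labels, collapse = ",")))
    }
  }
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1.0)
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 1, 0, 1)), 0.75)
})

test_that("roc_auc is calibrated under the null and validated against pROC", {
  withr::with_seed(19, {
    x <- rnorm(2000)
    y <- sample(rep(0:1, 1000))
  })
  expect_true(abs(roc_auc(x, y) - 0.5) < 3 * sqrt(1 / 12 / 1000))
  withr::with_seed(20, {
    v <- rnorm(150)
    lab <- rbinom(150, 1, plogis(v))
  })
  expect_equal(roc_auc(v, lab),
               as.numeric(suppressMessages(pROC::auc(lab, v))),
               tolerance = 1e-12)
  expect_error(roc_auc(1:5, rep(1, 5)), "both classes")
})

test_that("roc_curve starts at (1,1), ends at (0,0) and integrates to the AUC", {
  withr::with_seed(30, {
    v <- rnorm(80)
    lab <- rbinom(80, 1, plogis(2 * v))
  })
  rc <- roc_curve(v, lab)
  expect_equal(rc$tpr[1], 1); expect_equal(rc$fpr[1], 1)
  expect_equal(rc$tpr[nrow(rc)], 0); expect_equal(rc$fpr[nrow(rc)], 0)
  # trapezoidal area under the empirical curve equals the rank AUC (no ties)
  area <- -sum(diff(rc$fpr) * (head(rc$tpr, -1) + tail(rc$tpr, -1)) / 2)
  expect_equal(area, roc_auc(v, lab), tolerance = 1e-10)
})
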