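test_that("the collinearity check applies |r| > t with a hand-computed oracle", {
  v <- c(3, 1, 4, 1, 5, 9, 2, 6)
  expect_true(pearson_threshold_check(v, v, t = 0.45, min_overlap = 3))
  expect_true(pearson_threshold_check(v, -v, t = 0.45, min_overlap = 3))
  # r((1,2,3,4), (1,2,4,3)) = 4 / 5 = 0.8 by the definitional formula
  i <- c(1, 2, 3, 4); j <- c(1, 2, 4, 3)
  r_manual <- sum((i - mean(i)) * (j - mean(j))) /
    sqrt(sum((i - mean(i))^2) * sum((j - mean(j))^2))
  expect_equal(r_manual, 0.8)
  expect_true(pearson_threshold_check(i, j, t = 0.45, min_overlap = 3))
  expect_false(pearson_threshold_check(i, j, t = 0.8, min_overlap = 3))  # tie
  expect_false(pearson_threshold_check(i, j, t = 0.9, min_overlap = 3))
})

test_that("degenerate collinearity-check inputs are signalled", {
  expect_error(pearson_threshold_check(1:4, 1:5), "equal length")
  expect_error(pearson_threshold_check(1:2, 1:2), "at least 3")
  expect_error(pearson_threshold_check(1:4, 1:4, t = 1), "\\[0, 1\\)")
  expect_true(is.na(pearson_threshold_check(rep(1, 5), c(1:5), t = 0.45,
                                            min_overlap = 3)))
})

test_that("uncorrelated features become singletons and duplicates one cluster", {
  withr::with_seed(4, m <- matrix(rnorm(200 * 8), 200, 8,
                                  dimnames = list(NULL, paste0("f", 1:8))))
  cs <- correlation_cluster(m, t = 0.45, seed = 1)
  expect_identical(nrow(cs$clusters), 8L)
  expect_true(all(lengths(cs$clusters$members) == 1L))

  dup <- cbind(m[, 1:3], f1b = m[, 1], f1c = m[, 1])
  for (s in 1:5) {
    cs2 <- correlation_cluster(dup, t = 0.45, seed = s)
    tc <- tidy(cs2)
    copies <- tc$cluster[tc$feature_id %in% c("f1", "f1b", "f1c")]
    expect_identical(length(unique(copies)), 1L)
  }
})

test_that("well-separated blocks are recovered exactly for every seed", {
  m <- block_matrix(300, c(3, 3), within = 0.9, seed = 7)
  truth <- substr(colnames(m), 1, 3)
  for (s in 1:10) {
    cs <- correlation_cluster(m, t = 0.45, seed = s)
    expect_identical(nrow(cs$clusters), 2L)
    for (k in 1:2) {
      members <- cs$clusters$members[[k]]
      expect_identical(length(unique(truth[match(members, colnames(m))])), 1L)
    }
  }
})

test_that("cluster sets satisfy the partition contract on random instances", {
  for (case in 1:50) {
    n_blocks <- 1 + case %% 4
    sizes <- 1 + (case + seq_len(n_blocks)) %% 3
    m <- block_matrix(200, sizes, within = 0.75, seed = case)
    cs <- correlation_cluster(m, t = 0.45, seed = case * 13)
    cm <- cor(m)

    members <- unlist(cs$clusters$members)
    expect_identical(sort(members), sort(colnames(m)))   # disjoint cover
    expect_false(any(duplicated(members)))

    for (k in seq_len(nrow(cs$clusters))) {
      pv <- cs$clusters$pivot[k]
      others <- setdiff(cs$clusters$members[[k]], pv)
      if (length(others)) {
        expect_true(all(abs(cm[pv, others]) > 0.45))
      }
    }
    pivots <- cs$clusters$pivot
    if (length(pivots) > 1) {
      pp <- abs(cm[pivots, pivots])
      expect_true(all(pp[upper.tri(pp)] <= 0.45))
    }

    # brute-force replay from the recorded pivot order reproduces the set
    replay <- replay_clusters(cm, cs$pivot_order, t = 0.45)
    expect_identical(length(replay), nrow(cs$clusters))
    for (k in seq_along(replay)) {
      expect_identical(replay[[k]]$pivot, cs$clusters$pivot[k])
      expect_setequal(replay[[k]]$members, cs$clusters$members[[k]])
    }
  }
})

test_that("clustering is seed-deterministic and size-stable for separated blocks", {
  m <- block_matrix(250, c(4, 3, 2, 1), within = 0.85, seed = 3)
  a <- correlation_cluster(m, t = 0.45, seed = 42)
  b <- correlation_cluster(m, t = 0.45, seed = 42)
  expect_identical(a$clusters, b$clusters)
  expect_identical(a$pivot_order, b$pivot_order)
  counts <- vapply(1:8, function(s) {
    nrow(correlation_cluster(m, t = 0.45, seed = s)$clusters)
  }, integer(1))
  expect_true(all(counts == 4L))
})

test_that("zero-variance features are set aside as singletons", {
  withr::with_seed(2, m <- cbind(const = rep(2, 100),
                                 a = rnorm(100), b = rnorm(100)))
  cs <- correlation_cluster(m, t = 0.45, seed = 1)
  tc <- tidy(cs)
  expect_true(tc$is_pivot[tc$feature_id == "const"])
  expect_identical(length(cs$clusters$members[[which(cs$clusters$pivot == "const")]]), 1L)
})

test_that("an empty feature set yields an empty cluster set", {
  cs <- correlation_cluster(matrix(numeric(), 10, 0), t = 0.45, seed = 1)
  expect_identical(nrow(cs$clusters), 0L)
})

test_that("representative selection keeps exactly the pivots", {
  withr::with_seed(9, m <- matrix(rnorm(200 * 6), 200, 6,
                                  dimnames = list(NULL, paste0("f", 1:6))))
  cs <- correlation_cluster(m, t = 0.45, seed = 1)
  red <- select_representatives(m, cs)
  expect_identical(sort(colnames(red)), sort(colnames(m)))  # all singletons

  dup <- cbind(m, f1b = m[, "f1"])
  cs2 <- correlation_cluster(dup, t = 0.45, seed = 1)
  red2 <- select_representatives(dup, cs2)
  expect_identical(ncol(red2), nrow(cs2$clusters))
  expect_identical(sum(c("f1", "f1b") %in% colnames(red2)), 1L)

  expect_error(select_representatives(m[, 1:3], cs), "absent")
})

test_that("reduction of a simulated cohort returns one column per configured block", {
  cohorts <- simulate_cohorts(small_config(n_discovery = rep(40L, 6),
                                           seed = 17))
  cs <- correlation_cluster(cohorts$discovery$features, t = 0.45, seed = 5)
  red <- select_representatives(cohorts$discovery$features, cs)
  cfg_clusters <- small_config()$n_clusters
  expect_identical(nrow(cs$clusters), cfg_clusters)
  expect_identical(ncol(red) - 1L, cfg_clusters)  # sample_id retained
})
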