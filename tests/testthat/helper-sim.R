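# shared fixtures, built in code

small_config <- function(seed = 1L, ...) {
  args <- list(n_discovery = rep(10L, 6), n_validation = rep(10L, 6),
               n_features = 40L, n_clusters = 10L, n_causal = 2L,
               seed = seed)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

# n samples x (sum of block sizes) matrix with exact latent-block structure
# on the observed scale (no exponentiation, so correlations are controlled)
block_matrix <- function(n, block_sizes, within = 0.9, seed = 1L) {
  withr::with_seed(seed, {
    cols <- lapply(seq_along(block_sizes), function(b) {
      z <- rnorm(n)
      sapply(seq_len(block_sizes[b]), function(j) {
        sqrt(within) * z + sqrt(1 - within) * rnorm(n)
      })
    })
    m <- do.call(cbind, cols)
    colnames(m) <- sprintf("B%02d_%02d",
                           rep(seq_along(block_sizes), block_sizes),
                           unlist(lapply(block_sizes, seq_len)))
    m
  })
}

# greedy re-execution of the pivot algorithm from a recorded pivot order;
# independent oracle for the clustering contract
replay_clusters <- function(cor_mat, pivot_order, t) {
  pool <- colnames(cor_mat)
  out <- list()
  for (pv in pivot_order) {
    if (!pv %in% pool) next
    rest <- setdiff(pool, pv)
    hits <- rest[abs(cor_mat[pv, rest]) > t]
    out[[length(out) + 1L]] <- list(pivot = pv, members = c(pv, hits))
    pool <- setdiff(rest, hits)
  }
  out
}
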