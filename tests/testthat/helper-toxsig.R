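# shared fixtures, generated in code

.sim_cache <- new.env(parent = emptyenv())

# the full-scale default simulated study (cached across test files)
default_sim <- function() {
  if (is.null(.sim_cache$sim))
    .sim_cache$sim <- generate_synthetic_dataset(synthetic_design(seed = 0))
  .sim_cache$sim
}

# a scaled-down study for fast structural tests
small_sim <- function(seed = 1) {
  key <- paste0("small", seed)
  if (is.null(.sim_cache[[key]]))
    .sim_cache[[key]] <- generate_synthetic_dataset(
      synthetic_design(n_probesets = 300, n_shared = 10, n_gc = 10,
                       n_ngc = 10, seed = seed))
  .sim_cache[[key]]
}

# profiles x features matrix with the first `n_inf` features carrying a
# class-mean shift of `effect` SDs; returns list(X, y)
planted_matrix <- function(n = 40, P = 100, n_inf = 2, effect = 2,
                           seed = 1) {
  set.seed(seed)
  y <- factor(rep(c("neg", "pos"), each = n / 2), levels = c("neg", "pos"))
  X <- matrix(rnorm(n * P), n, P,
              dimnames = list(NULL, paste0("f", seq_len(P))))
  X[y == "pos", seq_len(n_inf)] <- X[y == "pos", seq_len(n_inf)] + effect
  list(X = X, y = y)
}

# a tiny linearly separable two-feature dataset
separable_toy <- function(n_per_class = 6, gap = 4, seed = 3) {
  set.seed(seed)
  y <- factor(rep(c("neg", "pos"), each = n_per_class),
              levels = c("neg", "pos"))
  X <- matrix(rnorm(2 * 2 * n_per_class, sd = 0.5), ncol = 2,
              dimnames = list(NULL, c("fa", "fb")))
  X[y == "pos", 1] <- X[y == "pos", 1] + gap
  list(X = X, y = y)
}

# O(n1*n0) pair-enumeration AUC used as the independent oracle
brute_auc <- function(scores, pos) {
  sp <- scores[pos]; sn <- scores[!pos]
  tot <- 0
  for (a in sp) for (b in sn)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(sp) * length(sn))
}

write_tsv_fixture <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
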