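# brute-force oracles used across tests: everything here enumerates states
# directly from coordinate vectors, independent of the package's label
# arithmetic and spectral machinery.

# all coordinate vectors of a (p, n) tree, one per row, in label order
enumerate_coords <- function(p, n) {
  g <- do.call(expand.grid, rev(replicate(n, 0:(p - 1), simplify = FALSE)))
  as.matrix(g[, rev(seq_len(n)), drop = FALSE])
}

# longest-common-prefix distance computed naively on two coordinate vectors
brute_dist <- function(x, y) {
  n <- length(x)
  k <- 0L
  while (k < n && x[k + 1L] == y[k + 1L]) k <- k + 1L
  n - k
}

demo_model <- function(p = 2, n = 3, delta = 1, ...) {
  hop_model(social_tree(p, n), barrier_profile(delta = delta), ...)
}

# dense matrix exponential through base eigen(), independent of the package
brute_expm_probs <- function(Q, origin_label, t) {
  eg <- eigen(Q, symmetric = TRUE)
  as.vector(eg$vectors %*% (exp(eg$values * t) *
                              eg$vectors[origin_label + 1L, ]))
}
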