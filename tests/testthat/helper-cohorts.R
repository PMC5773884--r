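# Shared fixtures: small family structures and cohorts built in code.

pairs_structure <- function(n_mz, n_dz, n_singletons = 0L)
  family_structure_spec(n_mz_pairs = n_mz, n_dz_pairs = n_dz,
                        n_singletons = n_singletons)

# FANNY objective recomputed independently (matrix arithmetic only),
# used by brute-force oracles.
fanny_obj_oracle <- function(U, D, r = 2) {
  M <- U^r
  total <- 0
  for (v in seq_len(ncol(U)))
    total <- total + (M[, v] %*% D %*% M[, v]) / (2 * sum(M[, v]))
  as.numeric(total)
}

# Two-block toy dissimilarity: zero within, one between.
two_block_D <- function(sizes = c(5, 5)) {
  lab <- rep(seq_along(sizes), sizes)
  D <- 1 - outer(lab, lab, "==")
  diag(D) <- 0
  D
}

# Natural-spline space via the truncated-power construction (independent
# of splines::ns): {1, x, d_k(x) - d_{K-1}(x)} with
# d_k(x) = ((x - xi_k)_+^3 - (x - xi_K)_+^3) / (xi_K - xi_k).
truncated_power_ns_space <- function(x) {
  bk <- range(x)
  ik <- unname(quantile(x, c(1, 2) / 3, type = 7))
  xi <- c(bk[1], ik, bk[2])
  K <- length(xi)
  dk <- function(k) (pmax(x - xi[k], 0)^3 - pmax(x - xi[K], 0)^3) /
    (xi[K] - xi[k])
  cbind(1, x, dk(1) - dk(K - 1), dk(2) - dk(K - 1))
}
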