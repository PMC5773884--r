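test_that("residualisation projects out the covariate design exactly", {
  set.seed(11)
  n <- 40
  covs <- data.frame(a = rnorm(n), b = rnorm(n))
  Y <- matrix(rnorm(n * 3), n, 3)
  R <- residualize(Y, covs)
  expect_lt(max(abs(cor(R, as.matrix(covs)))), 1e-10)

  # intercept-only design: residual equals the demeaned column
  zero <- residualize(Y, covs, formula = ~ 1)
  expect_equal(zero, scale(Y, scale = FALSE), ignore_attr = TRUE,
               tolerance = 1e-12)

  # 5x2 toy design against the explicit hat matrix
  X <- cbind(1, c(1, 2, 3, 4, 5))
  y5 <- matrix(c(2, 1, 4, 3, 6), ncol = 1)
  H <- X %*% solve(crossprod(X)) %*% t(X)
  expect_equal(residualize(y5, data.frame(x = X[, 2])),
               (diag(5) - H) %*% y5, ignore_attr = TRUE, tolerance = 1e-12)

  expect_error(residualize(Y, data.frame(a = covs$a, a2 = 2 * covs$a)),
               "rank deficient")
})

test_that("moment genetic correlations recover planted block structure", {
  fams <- build_family_structure(pairs_structure(750, 750))
  arch <- architecture_spec(n_vertices = 60, n_blocks = 2,
                            within_block_rg = 0.8, between_block_rg = 0,
                            h2_vertex = 0.5)
  X <- simulate_vertex_phenotypes(fams, arch, seed = 17)
  G <- pairwise_genetic_correlations(X, fams, "moment")
  expect_true(all(diag(G$rg)[!G$nonidentified] == 1))
  expect_lt(max(abs(G$rg - t(G$rg)), na.rm = TRUE), 1e-10)
  blk <- arch$block_assignment
  within <- G$rg[outer(blk, blk, "==") & upper.tri(G$rg)]
  between <- G$rg[outer(blk, blk, "!=") & upper.tri(G$rg)]
  expect_lt(abs(mean(within, na.rm = TRUE) - 0.8), 0.1)
  expect_lt(abs(mean(between, na.rm = TRUE) - 0), 0.1)

  # duplicated vertex pins rG at 1
  Gd <- pairwise_genetic_correlations(cbind(X[, 1], X[, 1]), fams, "moment")
  expect_equal(Gd$rg[1, 2], 1)
})

test_that("moment and FIML estimators agree on a 30-vertex benchmark", {
  fams <- build_family_structure(pairs_structure(750, 750))
  arch <- architecture_spec(n_vertices = 30, n_blocks = 5,
                            within_block_rg = 0.7, h2_vertex = 0.5)
  X <- simulate_vertex_phenotypes(fams, arch, seed = 19)
  Gm <- pairwise_genetic_correlations(X, fams, "moment")
  Gf <- pairwise_genetic_correlations(X, fams, "fiml")
  up <- upper.tri(Gm$rg)
  diffs <- abs(Gm$rg[up] - Gf$rg[up])
  expect_gt(mean(diffs <= 0.1, na.rm = TRUE), 0.95)
})

test_that("the correlation-to-dissimilarity transform is 1 - rG", {
  G <- matrix(c(1, 0.25, -1, 0.25, 1, 1, -1, 1, 1), 3, 3)
  D <- to_dissimilarity(G)
  expect_equal(D[1, 2], 0.75)
  expect_equal(D[1, 3], 2)
  expect_equal(D[2, 3], 0)
  expect_equal(diag(D), rep(0, 3))

  # missing entries are imputed and counted, never silently zeroed
  G[1, 2] <- G[2, 1] <- NA
  D2 <- to_dissimilarity(G)
  expect_equal(attr(D2, "n_imputed"), 2)
  expect_false(anyNA(D2))
})

test_that("fanny reaches the brute-force optimum on a 5-point instance", {
  set.seed(23)
  P <- matrix(rnorm(10), 5, 2)
  D <- as.matrix(dist(P)); D <- D / max(D)
  ours <- fanny_cluster(D, 2)

  # exhaustive 0.05-step grid over the first-cluster memberships
  g <- seq(0, 1, by = 0.05)
  g4 <- as.matrix(expand.grid(g, g, g, g))
  best <- Inf
  for (u1 in g) {
    U1 <- cbind(u1, g4)
    M1 <- U1^2; M2 <- (1 - U1)^2
    obj <- rowSums((M1 %*% D) * M1) / (2 * rowSums(M1)) +
      rowSums((M2 %*% D) * M2) / (2 * rowSums(M2))
    best <- min(best, min(obj, na.rm = TRUE))
  }
  expect_lte(ours$objective, best + 1e-8)
})

test_that("fanny memberships are proper and the objective never increases", {
  D <- two_block_D(c(5, 5))
  cl <- fanny_cluster(D, 2)
  expect_lt(max(abs(rowSums(cl$membership) - 1)), 1e-9)
  expect_true(all(diff(cl$objective_trace) <= 1e-12))
  expect_true(all(apply(cl$membership, 1, max) >= 0.9))
  expect_lt(cl$objective, 1e-6)
  # crisp labels separate the blocks
  expect_equal(length(unique(cl$clustering[1:5])), 1)
  expect_equal(length(unique(cl$clustering[6:10])), 1)
  expect_false(cl$clustering[1] == cl$clustering[6])

  # fuzzy relaxation can only improve on the crisp assignment
  U_crisp <- matrix(0, 10, 2)
  U_crisp[cbind(1:10, cl$clustering)] <- 1
  expect_lte(cl$objective, fanny_obj_oracle(U_crisp, D) + 1e-12)

  expect_error(fanny_cluster(D, 10), "k must satisfy")
  expect_error(fanny_cluster(matrix(0, 4, 4), 2), "identical")
})

test_that("fanny agrees with the reference fuzzy-analysis implementation", {
  skip_if_not_installed("cluster")
  set.seed(29)
  P <- matrix(rnorm(40), 20, 2)
  P[11:20, ] <- P[11:20, ] + 4
  D <- as.matrix(dist(P)); D <- D / max(D)
  ours <- fanny_cluster(D, 2)
  ref <- cluster::fanny(as.dist(D), 2, memb.exp = 2)
  expect_equal(ours$objective, unname(ref$objective[1]), tolerance = 1e-5)
  # same partition up to label swap
  agree <- mean((ours$clustering == ours$clustering[1]) ==
                (ref$clustering == ref$clustering[1]))
  expect_equal(agree, 1)
})

test_that("crisp assignment breaks ties toward the smaller index", {
  expect_equal(crisp_assignment(matrix(c(0.7, 0.3), 1)), 1)
  expect_equal(crisp_assignment(matrix(c(0.5, 0.5), 1)), 1)
  U <- diag(3)[c(2, 3, 1), ]
  expect_equal(crisp_assignment(U), c(2, 3, 1))
})

test_that("silhouette widths match hand arithmetic and the reference", {
  # two tight pairs at distance 0 within, 1 between: perfect separation
  D <- two_block_D(c(2, 2))
  expect_equal(silhouette_mean(c(1, 1, 2, 2), D)$mean, 1)

  # hand-computed instance
  Dh <- matrix(0, 4, 4)
  Dh[1, 2] <- 0.1; Dh[1, 3] <- 0.9; Dh[1, 4] <- 1.0
  Dh[2, 3] <- 0.8; Dh[2, 4] <- 0.9; Dh[3, 4] <- 0.2
  Dh <- Dh + t(Dh)
  s <- silhouette_mean(c(1, 1, 2, 2), Dh)
  expect_equal(s$widths, c(17 / 19, 15 / 17, 13 / 17, 15 / 19),
               tolerance = 1e-12)
  expect_equal(s$mean, mean(c(17 / 19, 15 / 17, 13 / 17, 15 / 19)),
               tolerance = 1e-12)

  # random labels on random dissimilarities: near-zero mean width
  set.seed(31)
  Dr <- as.matrix(dist(matrix(rnorm(200), 100, 2)))
  lab <- sample(1:4, 100, replace = TRUE)
  expect_lt(abs(silhouette_mean(lab, Dr)$mean), 0.15)

  skip_if_not_installed("cluster")
  ref <- cluster::silhouette(lab, as.dist(Dr))
  expect_equal(silhouette_mean(lab, Dr)$widths, unname(ref[, 3]),
               tolerance = 1e-10)

  expect_error(silhouette_mean(rep(1, 4), Dh), "two non-empty")
})

test_that("silhouette of a clean two-block instance survives permutation", {
  D <- two_block_D(c(4, 6))
  lab <- rep(1:2, c(4, 6))
  base <- silhouette_mean(lab, D)$mean
  set.seed(37)
  perm <- sample(10)
  expect_equal(silhouette_mean(lab[perm], D[perm, perm])$mean, base)
})

test_that("silhouette selection finds planted k and flags weak structure", {
  D <- two_block_D(c(6, 6)) + 0.01
  diag(D) <- 0
  sel <- select_k(D, 2:6)
  expect_equal(sel$recommended_k, 2)
  expect_false(sel$low_confidence)

  set.seed(41)
  Dn <- as.matrix(dist(matrix(rnorm(60), 30, 2)))
  Dn <- Dn / max(Dn)
  seln <- select_k(Dn, 2:6)
  expect_equal(nrow(seln$curve), 5)
  if (max(seln$curve$silhouette, na.rm = TRUE) < 0.1)
    expect_true(seln$low_confidence)
})

test_that("cluster means average exactly their member vertices", {
  X <- cbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(10, 20, 30))
  M <- cluster_mean_phenotypes(X, c(1, 1, 2))
  expect_equal(M[, "1"], c(1, 2, 3))
  expect_equal(M[, "2"], c(10, 20, 30))
  M3 <- cluster_mean_phenotypes(cbind(X, d = c(0, 0, 0)), c(1, 1, 2, 2))
  expect_equal(M3[, "2"], c(5, 10, 15))
  expect_error(cluster_mean_phenotypes(X, c(1, 1)), "cover all")
})

test_that("the fuzzy pipeline is deterministic for fixed inputs", {
  set.seed(43)
  D <- as.matrix(dist(matrix(rnorm(60), 30, 2)))
  a <- fanny_cluster(D, 3)
  b <- fanny_cluster(D, 3)
  expect_identical(a$membership, b$membership)
  expect_identical(a$objective, b$objective)
})
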