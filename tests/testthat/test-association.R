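test_that("winsorisation caps the upper tail at mean + k SD", {
  x <- c(rnorm(50), 0)
  w <- winsorise(x)
  expect_equal(as.numeric(w), x, ignore_attr = TRUE)
  expect_equal(attr(w, "n_modified"), 0)

  y <- c(rnorm(100))
  y2 <- c(y, mean(y) + 6 * sd(y))
  m <- mean(y2); s <- sd(y2)
  w2 <- winsorise(y2)
  expect_equal(max(w2), m + 4 * s)
  expect_equal(attr(w2, "n_modified"), 1)
  expect_equal(as.numeric(w2[seq_along(y)]),
               pmin(y, m + 4 * s))  # lower tail untouched

  # heavy-tail sample: modified count matches a direct threshold scan
  set.seed(3)
  z <- exp(rnorm(500))
  wz <- winsorise(z)
  expect_equal(attr(wz, "n_modified"),
               sum(z > mean(z) + 4 * sd(z)))

  expect_error(winsorise(rep(1, 5)), "distinct")
})

test_that("spline basis is orthonormal and spans the natural-spline space", {
  x <- as.numeric(1:20)
  b <- natural_spline_basis(x)
  # Gram matrix identity, columns orthogonal to the intercept
  expect_lt(max(abs(crossprod(b$basis) - diag(3))), 1e-8)
  expect_lt(max(abs(colSums(b$basis))), 1e-8)
  # knots at terciles and the range
  expect_equal(b$boundary_knots, c(1, 20))
  expect_equal(b$knots, unname(quantile(x, c(1, 2) / 3)))

  # matches the independent truncated-power construction after the same
  # ordered orthogonalisation (proves the columns are natural splines,
  # hence linear beyond the boundary knots)
  S <- truncated_power_ns_space(x)
  Q <- qr.Q(qr(S))
  P <- tcrossprod(Q)
  z <- (x - mean(x)) / sd(x)
  prev <- matrix(1 / sqrt(20), 20, 1)
  oracle <- matrix(0, 20, 3)
  for (j in 1:3) {
    t_ <- P %*% z^j
    t_ <- t_ - prev %*% crossprod(prev, t_)
    oracle[, j] <- t_ / sqrt(sum(t_^2))
    prev <- cbind(prev, oracle[, j])
  }
  expect_lt(max(abs(b$basis - oracle)), 1e-8)

  expect_error(natural_spline_basis(rep(1:3, 5)), "distinct")
})

test_that("kinship coefficients follow relationship codes", {
  fams <- build_family_structure(
    family_structure_spec(n_mz_pairs = 1, n_dz_pairs = 1, n_sib_pairs = 1,
                          n_mz_trios = 1, n_singletons = 1))
  K <- kinship_from_table(fams)
  expect_equal(diag(K), rep(0.5, nrow(fams)), ignore_attr = TRUE)
  expect_equal(K[1, 2], 0.5)    # MZ pair
  expect_equal(K[3, 4], 0.25)   # DZ pair
  expect_equal(K[5, 6], 0.25)   # sibling pair
  expect_equal(K[7, 8], 0.5)    # MZ pair inside the trio
  expect_equal(K[7, 9], 0.25)   # twin-sibling
  expect_equal(K[1, 3], 0)      # across families
  expect_true(isSymmetric(K))
  expect_gte(min(eigen(2 * K, symmetric = TRUE)$values), -1e-12)

  bad <- fams
  bad$rel[4] <- "MZ"  # lone MZ in the DZ family
  expect_error(kinship_from_table(bad), "lone MZ")
})

test_that("the kinship mixed model reduces to OLS without relatedness", {
  set.seed(5)
  n <- 120
  X <- cbind(`(Intercept)` = 1, x1 = rnorm(n), x2 = rnorm(n))
  y <- X %*% c(1, 2, -1) + rnorm(n)
  f <- fit_kinship_lmm(y, X, diag(0.5, n))
  ols <- lm.fit(X, y)
  expect_lt(max(abs(f$coefficients$beta - ols$coefficients)), 1e-8)
  # t = beta/se and the effect-size correlation share the sign of beta
  expect_equal(f$coefficients$t,
               f$coefficients$beta / f$coefficients$se)
  expect_equal(sign(f$coefficients$r), sign(f$coefficients$t))
  expect_true(all(abs(f$coefficients$r) < 1))

  expect_error(fit_kinship_lmm(y, cbind(X, x1b = X[, 2]), diag(0.5, n)),
               "rank deficient")
})

test_that("the mixed model recovers fixed effects and the variance ratio", {
  fams <- build_family_structure(pairs_structure(150, 150))
  n <- nrow(fams)
  set.seed(13)
  g <- endotwin:::simulate_bivariate_traits(fams, 0.99, 0.99, 0)[, 1]
  X <- cbind(`(Intercept)` = 1, x = rnorm(n))
  beta_true <- c(0.5, 0.3)
  h2_true <- 0.5
  y <- X %*% beta_true + sqrt(h2_true) * g +
    sqrt(1 - h2_true) * rnorm(n)
  K <- kinship_from_table(fams)
  f <- fit_kinship_lmm(y, X, K)
  expect_lt(abs(f$coefficients$beta[2] - beta_true[2]),
            3 * f$coefficients$se[2])
  ratio <- f$sigma2_g / (f$sigma2_g + f$sigma2_e)
  expect_lt(abs(ratio - h2_true), 0.12)
})

test_that("kinship-aware p values are calibrated where OLS inflates", {
  fams <- build_family_structure(pairs_structure(100, 100))
  eig <- endotwin:::family_block_eigen(fams)
  n <- nrow(fams)
  set.seed(17)
  n_rep <- 400
  p_lmm <- numeric(n_rep); p_ols <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    Y <- endotwin:::simulate_bivariate_traits(fams, 0.8, 0.8, 0, 0)
    X <- cbind(`(Intercept)` = 1, x = Y[, 2])
    f1 <- fit_kinship_lmm(Y[, 1], X, eig = eig)
    f0 <- fit_kinship_lmm(Y[, 1], X, K = NULL)
    p_lmm[i] <- f1$coefficients$p[2]
    p_ols[i] <- f0$coefficients$p[2]
  }
  # mixed-model p values uniform under the null ...
  expect_gt(ks.test(p_lmm, "punif")$p.value, 0.01)
  expect_lt(abs(mean(p_lmm < 0.05) - 0.05), 0.035)
  # ... while ignoring kinship inflates the type-I error
  expect_gt(mean(p_ols < 0.05), mean(p_lmm < 0.05))
  expect_gt(mean(p_ols < 0.05), 0.085)
})

test_that("Li-Ji effective test counts match closed-form spectra", {
  expect_equal(effective_number_of_tests(diag(48))$meff, 48)
  expect_equal(effective_number_of_tests(matrix(1, 7, 7))$meff, 1)
  ex <- matrix(0.5, 3, 3); diag(ex) <- 1
  expect_equal(effective_number_of_tests(ex)$meff, 2.0)
  # permutation invariance
  set.seed(19)
  C <- cor(matrix(rnorm(300), 50, 6))
  perm <- sample(6)
  expect_equal(effective_number_of_tests(C)$meff,
               effective_number_of_tests(C[perm, perm])$meff,
               tolerance = 1e-10)
  expect_lte(effective_number_of_tests(C)$meff, 6)
  expect_error(effective_number_of_tests(matrix(c(1, 0.2, 0.4, 1), 2)),
               "symmetric")
})

test_that("Sidak thresholds reproduce closed-form FWER control", {
  expect_equal(sidak_threshold(1), 0.05)
  ns <- c(1, 2, 6, 33, 99, 144)
  th <- sidak_threshold(ns)
  expect_true(all(diff(th) < 0))
  expect_equal(bonferroni_threshold(10), 0.005)
  plan <- multiple_testing_plan(33)
  expect_equal(plan$n_tests, 99)
})

test_that("association scans return three spline effects per phenotype", {
  fams <- build_family_structure(pairs_structure(100, 100, 20))
  arch <- architecture_spec(n_vertices = 6, n_blocks = 6, h2_vertex = 0.5,
                            score_tail = 0.5)
  co <- simulate_cohort(fams, arch, seed = 23)
  covs <- co$individuals[, c("sex", "age_scan")]
  scan <- run_association_scan(co$vertices, co$score, covs,
                               kinship = co$individuals)
  expect_equal(nrow(scan$table), 18)
  expect_equal(unname(table(scan$table$phenotype)), rep(3L, 6),
               ignore_attr = TRUE)
  expect_equal(scan$table$order, rep(1:3, 6))
  expect_true(all(scan$table$significant ==
                  (scan$table$p < scan$plan$threshold_sidak)))
  # the flagged-hit list equals the table filtered at the threshold
  expect_equal(scan$hits, scan$table[scan$table$significant, ],
               ignore_attr = TRUE)

  expect_error(run_association_scan(co$vertices[-1, ], co$score, covs,
                                    kinship = co$individuals),
               "length|misaligned")
})
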