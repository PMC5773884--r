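mz_icc <- function(X, fams, r_level = 1) {
  pr <- endotwin:::relative_pairs(fams)
  sel <- pr$r == r_level
  mean(vapply(seq_len(ncol(X)), function(v)
    cor(X[pr$i[sel], v], X[pr$j[sel], v]), 0))
}

test_that("planted heritability shows in cross-twin correlations", {
  fs <- pairs_structure(2000, 2000)
  fams <- build_family_structure(fs)

  # h2 = 0: no familial resemblance
  arch0 <- architecture_spec(n_vertices = 4, n_blocks = 2, h2_vertex = 0,
                             score_tail = 0)
  X0 <- simulate_vertex_phenotypes(fams, arch0, seed = 21)
  expect_lt(abs(mz_icc(X0, fams)), 0.05)

  # h2 = 0.6: Falconer estimate 2(rMZ - rDZ) recovers it
  arch6 <- architecture_spec(n_vertices = 4, n_blocks = 2, h2_vertex = 0.6,
                             score_tail = 0)
  X6 <- simulate_vertex_phenotypes(fams, arch6, seed = 22)
  falconer <- 2 * (mz_icc(X6, fams, 1) - mz_icc(X6, fams, 0.5))
  expect_lt(abs(falconer - 0.6), 0.05)

  # ordering invariant: rMZ >= rDZ whenever h2 > 0 (several seeds)
  for (s in 1:3) {
    X <- simulate_vertex_phenotypes(fams, arch6, seed = 30 + s)
    expect_gt(mz_icc(X, fams, 1) - mz_icc(X, fams, 0.5), -0.02)
  }

  # columns have unit variance in expectation
  expect_lt(max(abs(apply(X6, 2, var) - 1)), 0.1)
})

test_that("perfect within-block genetic correlation gives phenotypic r = h2", {
  fams <- build_family_structure(pairs_structure(1500, 1500))
  arch <- architecture_spec(n_vertices = 2, n_blocks = 1,
                            within_block_rg = 1, h2_vertex = 0.6,
                            score_tail = 0)
  X <- simulate_vertex_phenotypes(fams, arch, seed = 5)
  # cov(x1, x2) = h2 * rg_within = 0.6 when E terms are independent
  expect_lt(abs(cor(X[, 1], X[, 2]) - 0.6), 0.05)
})

test_that("zero genetic variance makes relatives exchangeable with strangers", {
  fams <- build_family_structure(pairs_structure(2000, 0))
  arch <- architecture_spec(n_vertices = 1, n_blocks = 1, h2_vertex = 0,
                            score_tail = 0)
  X <- simulate_vertex_phenotypes(fams, arch, seed = 8)
  pr <- endotwin:::relative_pairs(fams)
  ct <- cor.test(X[pr$i, 1], X[pr$j, 1])
  expect_gt(ct$p.value, 0.01)
})

test_that("the score carries its planted heritability and heavy right tail", {
  fams <- build_family_structure(pairs_structure(1500, 1500))
  arch <- architecture_spec(n_vertices = 2, n_blocks = 1, h2_score = 0.28,
                            score_tail = 0)
  sc <- simulate_score(fams, arch, seed = 13)
  fit <- fit_ae(as.numeric(sc), fams, ci = FALSE)
  expect_lt(abs(fit$h2 - 0.28), 0.05)

  # tail inflation: more mass beyond 3 SD than a Gaussian, upper side only
  arch_t <- architecture_spec(n_vertices = 2, n_blocks = 1, h2_score = 0.28,
                              score_tail = 0.8)
  st <- as.numeric(simulate_score(fams, arch_t, seed = 13))
  z <- (st - mean(st)) / sd(st)
  expect_gt(mean(z > 3), 2 * pnorm(-3))
  expect_gt(attr(winsorise(st), "n_modified"), 0)
})

test_that("cohort generation is deterministic and records its truth", {
  fs <- pairs_structure(40, 40, 10)
  arch <- architecture_spec(n_vertices = 12, n_blocks = 3,
                            rg_score_target = 0.1,
                            spline_effect = c(0, 0, -0.1))
  a <- simulate_cohort(fs, arch, seed = 99)
  b <- simulate_cohort(fs, arch, seed = 99)
  expect_identical(a$vertices, b$vertices)
  expect_identical(a$score, b$score)
  expect_identical(a$individuals, b$individuals)
  expect_equal(a$truth$arch, arch)
  expect_equal(a$truth$seed, 99)

  d <- simulate_cohort(fs, arch, seed = 100)
  expect_false(identical(a$vertices, d$vertices))
})

test_that("configurable covariate effects reach the phenotypes", {
  fs <- pairs_structure(300, 300)
  arch <- architecture_spec(n_vertices = 4, n_blocks = 2,
                            covariate_effects = c(sex = 0.5))
  co <- simulate_cohort(fs, arch, seed = 3)
  expect_gt(cor(co$vertices[, 1], co$individuals$sex), 0.15)
  # and residualisation removes them
  res <- residualize(co$vertices, co$individuals[, "sex", drop = FALSE])
  expect_lt(abs(cor(res[, 1], co$individuals$sex)), 1e-10)
})

test_that("cohorts round-trip through plain-text files", {
  co <- simulate_cohort(pairs_structure(5, 5, 2),
                        architecture_spec(n_vertices = 6, n_blocks = 2),
                        seed = 2)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  ind <- read.delim(file.path(dir, "individuals.tsv"))
  vert <- read.delim(file.path(dir, "vertices.tsv"), check.names = FALSE)
  expect_equal(nrow(ind), 22)
  expect_equal(as.matrix(vert[, -1]), co$vertices,
               ignore_attr = TRUE, tolerance = 1e-12)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth$seed, 2)
  expect_equal(truth$arch$h2_score, 0.28)
})
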