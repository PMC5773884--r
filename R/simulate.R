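#' Specify a planted genetic architecture
#'
#' Describes the generative model for a synthetic cohort: vertices are
#' abstract cortical phenotypes organised in blocks of genetically
#' correlated traits, a continuous symptom score is heritable and may be
#' genetically correlated with one target block, and the target block's
#' phenotypes may additionally carry a nonlinear (spline-shaped) phenotypic
#' effect of the score.
#'
#' Each vertex v in block b is generated as
#' \deqn{x_v = \sqrt{h^2}\, G_v + \sqrt{1-h^2}\, E_v,}
#' with \eqn{G_v = \sqrt{w}\,F_b + \sqrt{1-w}\,A_v} mixing a block-shared
#' genetic factor \eqn{F_b} (weight `within_block_rg` = w, the within-block
#' genetic correlation) with a vertex-specific factor. Block factors may
#' themselves share a global factor with weight `between_block_rg`. All
#' genetic factors are drawn jointly within families with cross-relative
#' correlation equal to the expected additive relatedness (1 for MZ
#' co-twins, 0.5 for DZ twins and siblings); environmental terms are
#' independent. Columns have unit variance in expectation.
#'
#' @param n_vertices number of vertex phenotypes.
#' @param n_blocks number of equal-sized blocks (used when
#'   `block_assignment` is `NULL`).
#' @param block_assignment optional integer vector of length `n_vertices`
#'   mapping each vertex to a block.
#' @param within_block_rg genetic correlation between vertices of the same
#'   block, in \[0, 1\].
#' @param between_block_rg correlation between block genetic factors, in
#'   \[0, 1\].
#' @param h2_vertex heritability of each vertex; scalar or one value per
#'   block.
#' @param h2_score heritability of the symptom score.
#' @param rg_score_target genetic correlation between the score and the
#'   target block's shared genetic factor, in \[-1, 1\].
#' @param target_block index of the block carrying the planted effects.
#' @param spline_effect length-3 numeric: planted effect sizes (as
#'   correlations r) on the three orthogonal spline orders of the score,
#'   added to every vertex of the target block.
#' @param score_tail right-tail inflation parameter (>= 0); 0 keeps the
#'   score Gaussian, larger values exponentially tilt values above the 90th
#'   percentile, producing the heavy right tail typical of symptom sum
#'   scores.
#' @param covariate_effects named numeric vector of linear effects of the
#'   generated covariates (`sex`, `age_scan`, `age_score`, `wave`,
#'   `acquisition`) on every vertex, in phenotype SD per covariate SD;
#'   defaults to all zero.
#' @return an object of class `architecture_spec`.
#' @export
architecture_spec <- function(n_vertices = 96L, n_blocks = 12L,
                              block_assignment = NULL,
                              within_block_rg = 0.8, between_block_rg = 0,
                              h2_vertex = 0.5, h2_score = 0.28,
                              rg_score_target = 0, target_block = 1L,
                              spline_effect = c(0, 0, 0), score_tail = 0.8,
                              covariate_effects = NULL) {
  if (is.null(block_assignment)) {
    block_assignment <- rep(seq_len(n_blocks), length.out = n_vertices)
    block_assignment <- sort(block_assignment)
  }
  if (length(block_assignment) != n_vertices)
    stop("block_assignment must cover all vertices")
  n_blocks <- length(unique(block_assignment))
  if (any(h2_vertex < 0 | h2_vertex > 1) || h2_score < 0 || h2_score > 1)
    stop("heritabilities must lie in [0, 1]")
  if (abs(rg_score_target) > 1)
    stop("|rg_score_target| must not exceed 1")
  if (within_block_rg < 0 || within_block_rg > 1 ||
      between_block_rg < 0 || between_block_rg > 1)
    stop("block genetic correlations must lie in [0, 1]")
  if (length(h2_vertex) == 1L) h2_vertex <- rep(h2_vertex, n_blocks)
  if (length(h2_vertex) != n_blocks)
    stop("h2_vertex must be scalar or one value per block")
  if (length(spline_effect) != 3L)
    stop("spline_effect must have length 3")
  if (any(abs(spline_effect) >= 1))
    stop("spline_effect entries are correlations and must lie in (-1, 1)")
  covs <- c(sex = 0, age_scan = 0, age_score = 0, wave = 0, acquisition = 0)
  if (!is.null(covariate_effects)) {
    bad <- setdiff(names(covariate_effects), names(covs))
    if (length(bad)) stop("unknown covariate effects: ",
                          paste(bad, collapse = ", "))
    covs[names(covariate_effects)] <- covariate_effects
  }
  structure(list(n_vertices = as.integer(n_vertices),
                 block_assignment = as.integer(block_assignment),
                 n_blocks = n_blocks,
                 within_block_rg = within_block_rg,
                 between_block_rg = between_block_rg,
                 h2_vertex = h2_vertex, h2_score = h2_score,
                 rg_score_target = rg_score_target,
                 target_block = as.integer(target_block),
                 spline_effect = spline_effect, score_tail = score_tail,
                 covariate_effects = covs),
            class = "architecture_spec")
}

# symmetric square root of a small PSD matrix (handles singular MZ blocks)
sqrtm_psd <- function(R) {
  e <- eigen(R, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  e$vectors %*% (sqrt(vals) * t(e$vectors))
}

# Draw n_factors independent standard-normal factor sets, each correlated
# within families according to the expected additive relatedness. Returns an
# N x n_factors matrix aligned with the rows of fams. Uses the current RNG
# stream.
draw_family_normals <- function(fams, n_factors) {
  n <- nrow(fams)
  out <- matrix(0, n, n_factors)
  for (tp in unique(fams$family_type)) {
    rows <- which(fams$family_type == tp)
    m <- sum(fams$family_type == tp & fams$family_id == fams$family_id[rows[1]])
    n_fam <- length(rows) / m
    rel <- fams$rel[rows[seq_len(m)]]
    S <- sqrtm_psd(relatedness_matrix(rel))
    Z <- matrix(stats::rnorm(m * n_fam * n_factors), m, n_fam * n_factors)
    out[rows, ] <- matrix(S %*% Z, m * n_fam, n_factors)
  }
  out
}

#' Simulate block-correlated vertex phenotypes
#'
#' Draws the vertex phenotype matrix for a family set under an
#' [architecture_spec()]: additive-genetic factors are shared across
#' relatives in proportion to expected relatedness (correlation 1 between
#' MZ co-twins, 0.5 between DZ twins/siblings) and mixed across vertices by
#' block, unique-environment terms are independent. Columns have unit
#' variance in expectation.
#'
#' @param fams a `family_set` from [build_family_structure()].
#' @param arch an [architecture_spec()].
#' @param seed integer seed (optional; uses the current RNG state when
#'   `NULL`).
#' @return an N x V matrix with vertex ids as column names; the block
#'   genetic factors (N x n_blocks) are attached as attribute
#'   `block_factors` so a score can be simulated with a genetic correlation
#'   to one block.
#' @export
simulate_vertex_phenotypes <- function(fams, arch, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(fams); V <- arch$n_vertices; B <- arch$n_blocks
  blk <- arch$block_assignment
  A <- draw_family_normals(fams, B + 1L + V)
  A_global <- A[, 1L]
  A_block <- A[, 1L + seq_len(B), drop = FALSE]
  A_vertex <- A[, B + 1L + seq_len(V), drop = FALSE]
  wb <- sqrt(arch$between_block_rg)
  F_block <- wb * A_global + sqrt(1 - wb^2) * A_block  # recycles column-wise
  w <- arch$within_block_rg
  G <- sqrt(w) * F_block[, blk, drop = FALSE] +
    sqrt(1 - w) * A_vertex
  h2 <- arch$h2_vertex[blk]
  E <- matrix(stats::rnorm(n * V), n, V)
  X <- sweep(G, 2, sqrt(h2), `*`) + sweep(E, 2, sqrt(1 - h2), `*`)
  colnames(X) <- sprintf("V%04d", seq_len(V))
  rownames(X) <- fams$individual_id
  attr(X, "block_factors") <- F_block
  X
}

#' Simulate a heritable, right-skewed symptom score
#'
#' The score has heritability `h2_score` and genetic correlation
#' `rg_score_target` with the supplied target-block genetic factor. When
#' `score_tail > 0`, values above the 90th percentile are exponentially
#' tilted, \eqn{q + (e^{\tau (z - q)} - 1)/\tau}, mimicking the heavy right
#' tail of symptom sum scores (and giving the winsorisation step something
#' to do).
#'
#' @param fams a `family_set`.
#' @param arch an [architecture_spec()].
#' @param target_block_genetic_factor numeric vector (length N): the genetic
#'   factor of the target block, e.g. the relevant column of the
#'   `block_factors` attribute of [simulate_vertex_phenotypes()]. When
#'   `NULL` the score's genetic factor is drawn independently.
#' @param seed integer seed (optional).
#' @return numeric score vector (length N) with the untilted Gaussian score
#'   attached as attribute `score_raw`.
#' @export
simulate_score <- function(fams, arch, target_block_genetic_factor = NULL,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(fams)
  A <- draw_family_normals(fams, 1L)[, 1L]
  rg <- arch$rg_score_target
  if (is.null(target_block_genetic_factor)) {
    if (rg != 0)
      stop("rg_score_target != 0 requires the target block's genetic factor")
    A_score <- A
  } else {
    A_score <- rg * target_block_genetic_factor + sqrt(1 - rg^2) * A
  }
  h2 <- arch$h2_score
  z <- sqrt(h2) * A_score + sqrt(1 - h2) * stats::rnorm(n)
  score <- z
  tau <- arch$score_tail
  if (tau > 0) {
    q <- stats::quantile(z, 0.9, names = FALSE)
    hi <- z > q
    score[hi] <- q + (exp(tau * (z[hi] - q)) - 1) / tau
  }
  attr(score, "score_raw") <- z
  score
}

#' Generate a complete synthetic twin cohort
#'
#' Composes [build_family_structure()], covariate generation,
#' [simulate_vertex_phenotypes()] and [simulate_score()] into a cohort with
#' a planted genetic architecture, including (when `spline_effect` is
#' non-zero) a nonlinear phenotypic effect of the score on the target
#' block's vertices: the planted effect sizes are correlations r per
#' orthogonal spline order, injected as `r/sqrt(1-r^2)` times the
#' unit-variance basis column.
#'
#' @param structure a [family_structure_spec()] (or a `family_set`).
#' @param arch an [architecture_spec()].
#' @param seed integer seed; the cohort is a deterministic function of
#'   (structure, arch, seed).
#' @return an object of class `synthetic_cohort`: a list with `individuals`
#'   (covariate table), `vertices` (N x V matrix), `score`, `block_factors`
#'   and `truth` (the generating parameters, reproduced exactly).
#' @export
simulate_cohort <- function(structure, arch = architecture_spec(),
                            seed = 1L) {
  fams <- if (inherits(structure, "family_set")) structure
          else build_family_structure(structure)
  set.seed(seed)
  n <- nrow(fams)
  if (n == 0L) stop("empty family structure")
  # covariates: twin ages shared within family, siblings offset
  fam_age <- stats::rnorm(length(unique(fams$family_id)), 17, 2.2)
  names(fam_age) <- unique(fams$family_id)
  age_score <- fam_age[fams$family_id] +
    ifelse(fams$rel == "SIB", stats::rnorm(n, 0, 2), 0)
  age_score <- pmin(pmax(age_score, 10), 24)
  age_scan <- age_score + pmax(stats::rnorm(n, 4.4, 2.1), 0.6)
  individuals <- data.frame(
    fams,
    sex = stats::rbinom(n, 1, 0.66),            # 1 = female
    age_score = round(unname(age_score), 1),
    age_scan = round(unname(age_scan), 1),
    wave = sample(1:3, n, replace = TRUE),
    acquisition = stats::rbinom(n, 1, 0.14),    # 1 = sagittal
    stringsAsFactors = FALSE)
  X <- simulate_vertex_phenotypes(fams, arch)
  Fb <- attr(X, "block_factors")
  score <- simulate_score(fams, arch, Fb[, arch$target_block])
  if (any(arch$spline_effect != 0)) {
    sb <- natural_spline_basis(as.numeric(score))
    Bv <- sb$basis * sqrt(n - 1)               # unit-variance columns
    r <- arch$spline_effect
    shift <- Bv %*% (r / sqrt(1 - r^2))
    tgt <- which(arch$block_assignment == arch$target_block)
    X[, tgt] <- X[, tgt] + as.vector(shift)
  }
  ce <- arch$covariate_effects
  if (any(ce != 0)) {
    C <- scale(as.matrix(individuals[, names(ce)]))
    C[is.nan(C)] <- 0
    X <- X + as.vector(C %*% ce)
  }
  attr(X, "block_factors") <- NULL
  out <- list(individuals = individuals, vertices = X,
              score = as.numeric(score), block_factors = Fb,
              truth = list(structure = attr(fams, "spec"), arch = arch,
                           seed = seed))
  class(out) <- "synthetic_cohort"
  out
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic twin cohort:", nrow(x$individuals), "individuals,",
      ncol(x$vertices), "vertex phenotypes,",
      x$truth$arch$n_blocks, "planted blocks\n")
  cat(sprintf("  h2(vertex) = %s | h2(score) = %.2f | rG(score, block %d) = %.3f\n",
              paste(format(unique(x$truth$arch$h2_vertex)), collapse = "/"),
              x$truth$arch$h2_score, x$truth$arch$target_block,
              x$truth$arch$rg_score_target))
  if (any(x$truth$arch$spline_effect != 0))
    cat("  planted spline effect (r):",
        format(x$truth$arch$spline_effect), "\n")
  invisible(x)
}

#' Write a synthetic cohort to plain-text files
#'
#' Writes `individuals.tsv`, `vertices.tsv` (individuals x vertices, header
#' = vertex ids), `score.tsv` and `truth.json` under `dir`.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("individuals.tsv", "vertices.tsv", "score.tsv",
                            "truth.json"))
  utils::write.table(cohort$individuals, paths[1], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  vt <- data.frame(individual_id = rownames(cohort$vertices),
                   cohort$vertices, check.names = FALSE)
  utils::write.table(vt, paths[2], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(individual_id = cohort$individuals$individual_id,
               score = cohort$score),
    paths[3], sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- cohort$truth
  truth$arch <- unclass(truth$arch)
  truth$structure <- unclass(truth$structure)
  jsonlite::write_json(truth, paths[4], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
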