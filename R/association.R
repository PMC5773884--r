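#' Winsorise outlying scores
#'
#' Caps values beyond `k_sd` standard deviations from the mean (both
#' computed on the input) at the cutoff, limiting the influence of the
#' heavy right tail typical of symptom sum scores. Upper-tail-only by
#' default.
#'
#' @param scores numeric vector with at least two distinct values.
#' @param k_sd cutoff in SD units (default 4).
#' @param side `"upper"` (default) or `"both"`.
#' @return the adjusted vector, with attribute `n_modified`.
#' @export
winsorise <- function(scores, k_sd = 4, side = c("upper", "both")) {
  side <- match.arg(side)
  if (length(unique(scores[!is.na(scores)])) < 2)
    stop("scores must contain at least two distinct values")
  m <- mean(scores, na.rm = TRUE)
  s <- stats::sd(scores, na.rm = TRUE)
  hi <- m + k_sd * s
  lo <- m - k_sd * s
  n_mod <- sum(scores > hi, na.rm = TRUE)
  out <- pmin(scores, hi)
  if (side == "both") {
    n_mod <- n_mod + sum(scores < lo, na.rm = TRUE)
    out <- pmax(out, lo)
  }
  attr(out, "n_modified") <- n_mod
  out
}

#' Kinship matrix from an individual table
#'
#' Builds the N x N matrix of kinship coefficients \eqn{\varphi} from
#' family ids and relationship codes: 0.5 on the diagonal and between MZ
#' co-twins, 0.25 between DZ twins and full siblings, 0 across families.
#' The expected additive relationship used by the mixed model is
#' \eqn{2\varphi}.
#'
#' @param individuals data frame with columns `individual_id`, `family_id`
#'   and `rel` (codes `MZ`, `DZ`, `SIB`, `SINGLETON`), e.g. a `family_set`.
#' @return N x N symmetric matrix with individual ids as dimnames.
#' @export
kinship_from_table <- function(individuals) {
  need <- c("individual_id", "family_id", "rel")
  if (!all(need %in% names(individuals)))
    stop("individual table needs columns: ", paste(need, collapse = ", "))
  n <- nrow(individuals)
  K <- diag(0.5, n)
  for (rows in split(seq_len(n), individuals$family_id)) {
    if (length(rows) < 2L) next
    if (length(rows) > 3L)
      stop("families of more than three members are not supported")
    rel <- individuals$rel[rows]
    if (sum(rel == "MZ") == 1L)
      stop("inconsistent relationship codes in family ",
           individuals$family_id[rows[1]], ": lone MZ member")
    phi <- relatedness_matrix(rel) / 2
    K[rows, rows] <- phi
  }
  dimnames(K) <- list(individuals$individual_id, individuals$individual_id)
  K
}

# Eigendecompose the relationship matrix G = 2K. Kinship is block diagonal
# by family, so when the connected components are small the decomposition
# is done per block (exact, and linear in N) instead of densely.
relationship_eigen <- function(G) {
  n <- nrow(G)
  # connected components via label propagation on the sparsity pattern
  comp <- seq_len(n)
  adj <- abs(G) > 1e-12
  diag(adj) <- FALSE
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      nb <- which(adj[i, ])
      if (length(nb)) {
        mn <- min(comp[i], comp[nb])
        if (any(c(comp[i], comp[nb]) != mn)) {
          comp[c(i, nb)] <- mn; changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  blocks <- split(seq_len(n), comp)
  if (max(lengths(blocks)) > 16L) {
    e <- eigen(G, symmetric = TRUE)
    return(list(values = e$values,
                rotate = function(M) crossprod(e$vectors, as.matrix(M))))
  }
  values <- numeric(n)
  vecs <- vector("list", length(blocks))
  pos <- 0L
  for (b in seq_along(blocks)) {
    rows <- blocks[[b]]
    e <- eigen(G[rows, rows, drop = FALSE], symmetric = TRUE)
    values[pos + seq_along(rows)] <- e$values
    vecs[[b]] <- list(rows = rows, slot = pos + seq_along(rows),
                      U = e$vectors)
    pos <- pos + length(rows)
  }
  rotate <- function(M) {
    M <- as.matrix(M)
    out <- matrix(0, nrow(M), ncol(M))
    for (v in vecs)
      out[v$slot, ] <- crossprod(v$U, M[v$rows, , drop = FALSE])
    out
  }
  list(values = values, rotate = rotate)
}

#' Gaussian mixed model with a kinship random effect (REML)
#'
#' Fits \eqn{y = X\beta + g + e} with \eqn{g \sim N(0, \sigma^2_g\, 2K)}
#' and \eqn{e \sim N(0, \sigma^2_e I)} by restricted maximum likelihood.
#' A single eigendecomposition of the relationship matrix \eqn{2K}
#' diagonalises the covariance, reducing estimation to a 1-d profile over
#' the variance ratio \eqn{\gamma = \sigma^2_g/\sigma^2_e}; fixed effects
#' are then generalised least squares at the optimum. Each coefficient is
#' tested with a Student t statistic \eqn{\beta/SE(\beta)} on
#' \eqn{N - \mathrm{rank}(X)} degrees of freedom, and reported with the
#' effect-size correlation \eqn{r = \mathrm{sign}(\beta)\,
#' |t|/\sqrt{t^2 + df}}.
#'
#' @param y response vector.
#' @param X design matrix (including the intercept); must be full rank.
#' @param K N x N kinship matrix (see [kinship_from_table()]), or `NULL`
#'   for independent observations.
#' @param eig optional precomputed result of the internal eigendecomposition
#'   (reused across phenotypes by [run_association_scan()]).
#' @return an object of class `kinship_lmm`: `coefficients` (data frame
#'   with beta, se, t, p, r per column of X), `sigma2_g`, `sigma2_e`,
#'   `gamma`, `df`, `reml_loglik`.
#' @export
fit_kinship_lmm <- function(y, X, K = NULL, eig = NULL) {
  X <- as.matrix(X)
  n <- length(y)
  if (nrow(X) != n) stop("X and y dimensions disagree")
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; aliased columns: ",
         paste(bad, collapse = ", "))
  }
  p <- ncol(X)
  if (is.null(eig)) {
    if (is.null(K)) {
      eig <- list(values = rep(1, n), rotate = identity)
    } else {
      K <- as.matrix(K)
      if (!isTRUE(all.equal(K, t(K), tolerance = 1e-8)))
        stop("kinship matrix must be symmetric")
      G <- 2 * K
      eig <- relationship_eigen(G)
      if (min(eig$values) < -1e-8)
        stop("2K is not positive semi-definite (min eigenvalue ",
             format(min(eig$values)), ")")
    }
  }
  lam <- pmax(eig$values, 0)
  yt <- as.vector(eig$rotate(matrix(y, ncol = 1)))
  Xt <- eig$rotate(X)
  out <- reml_fit_rotated(yt, Xt, lam, colnames(X))
  class(out) <- "kinship_lmm"
  out
}

# REML fit on eigen-rotated data: Var(yt) = sigma2_e (gamma * lam + 1).
reml_fit_rotated <- function(yt, Xt, lam, coef_names = colnames(Xt)) {
  n <- length(yt)
  p <- ncol(Xt)
  reml <- function(log_gamma) {
    g <- exp(log_gamma)
    v <- g * lam + 1
    w <- 1 / v
    XtW <- Xt * w
    XtWX <- crossprod(XtW, Xt)
    ch <- chol(XtWX)
    beta <- backsolve(ch, backsolve(ch, crossprod(XtW, yt),
                                    transpose = TRUE))
    resid <- yt - Xt %*% beta
    rss <- sum(w * resid^2)
    s2e <- rss / (n - p)
    ll <- -0.5 * ((n - p) * log(s2e) + sum(log(v)) +
                  2 * sum(log(diag(ch))) + (n - p))
    list(ll = ll, beta = beta, s2e = s2e, XtWX = XtWX, gamma = g)
  }
  # profile the variance ratio on the log scale; gamma -> 0 is OLS
  obj <- function(lg) -reml(lg)$ll
  opt <- stats::optimize(obj, c(-14, 14), tol = 1e-8)
  cand <- reml(opt$minimum)
  ols <- reml(-30)                      # effectively gamma = 0
  if (ols$ll >= cand$ll) { cand <- ols; cand$gamma <- 0 }
  se <- sqrt(cand$s2e * diag(chol2inv(chol(cand$XtWX))))
  beta <- as.vector(cand$beta)
  df <- n - p
  t <- beta / se
  pval <- 2 * stats::pt(-abs(t), df)
  r <- sign(t) * abs(t) / sqrt(t^2 + df)
  coefs <- data.frame(beta = beta, se = se, t = t, p = pval, r = r,
                      row.names = coef_names)
  list(coefficients = coefs,
       sigma2_g = cand$gamma * cand$s2e, sigma2_e = cand$s2e,
       gamma = cand$gamma, df = df, reml_loglik = cand$ll, n = n)
}

# Eigendecomposition of 2K directly from family blocks of an individual
# table, never forming the dense N x N matrix.
family_block_eigen <- function(individuals) {
  n <- nrow(individuals)
  values <- numeric(n)
  vecs <- list()
  pos <- 0L
  for (rows in split(seq_len(n), individuals$family_id)) {
    R <- relatedness_matrix(individuals$rel[rows])
    e <- eigen(R, symmetric = TRUE)
    values[pos + seq_along(rows)] <- e$values
    vecs[[length(vecs) + 1L]] <- list(rows = rows,
                                      slot = pos + seq_along(rows),
                                      U = e$vectors)
    pos <- pos + length(rows)
  }
  rotate <- function(M) {
    M <- as.matrix(M)
    out <- matrix(0, nrow(M), ncol(M))
    for (v in vecs)
      out[v$slot, ] <- crossprod(v$U, M[v$rows, , drop = FALSE])
    out
  }
  list(values = values, rotate = rotate)
}

#' @export
print.kinship_lmm <- function(x, ...) {
  cat("Kinship linear mixed model (REML)\n")
  cat(sprintf("  sigma2_g = %.4f  sigma2_e = %.4f  (ratio %.3f)  df = %d\n",
              x$sigma2_g, x$sigma2_e, x$gamma, x$df))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
coef.kinship_lmm <- function(object, ...) {
  stats::setNames(object$coefficients$beta,
                  rownames(object$coefficients))
}

#' Effective number of independent tests (eigenvalue method)
#'
#' Li–Ji estimate of the effective number of independent phenotypes from
#' the eigenvalues \eqn{\lambda_i} of their correlation matrix:
#' \deqn{M_{eff} = \sum_i \left[ \mathbf{1}(\lambda_i \ge 1) +
#'       (\lambda_i - \lfloor \lambda_i \rfloor) \right].}
#' Perfectly correlated phenotypes count once, independent ones count
#' fully, so the multiple-testing burden reflects the true dimensionality.
#'
#' @param corr correlation matrix of the (covariate-residualised)
#'   phenotypes.
#' @return a list of class `meff`: `meff`, `eigenvalues`, `n`.
#' @export
effective_number_of_tests <- function(corr) {
  corr <- as.matrix(corr)
  if (!isTRUE(all.equal(corr, t(corr), tolerance = 1e-8)))
    stop("correlation matrix must be symmetric")
  lam <- pmax(eigen(corr, symmetric = TRUE, only.values = TRUE)$values, 0)
  # guard the floor() against eigenvalues that are integers up to rounding
  lam_r <- ifelse(abs(lam - round(lam)) < 1e-9, round(lam), lam)
  meff <- sum((lam_r >= 1) + (lam_r - floor(lam_r)))
  out <- list(meff = meff, eigenvalues = lam, n = nrow(corr))
  class(out) <- "meff"
  out
}

#' @export
print.meff <- function(x, ...) {
  cat(sprintf("Effective number of independent tests: %.2f (of %d)\n",
              x$meff, x$n))
  invisible(x)
}

#' Sidak per-test significance threshold
#'
#' \eqn{\alpha = 1 - (1 - \mathrm{FWER})^{1/m}} for m independent tests.
#'
#' @param n_tests number of independent tests (>= 1).
#' @param fwer family-wise error rate (default 0.05).
#' @return per-test alpha.
#' @export
sidak_threshold <- function(n_tests, fwer = 0.05) {
  if (any(n_tests < 1)) stop("n_tests must be at least 1")
  1 - (1 - fwer)^(1 / n_tests)
}

#' Bonferroni per-test significance threshold
#'
#' @inheritParams sidak_threshold
#' @return per-test alpha `fwer / n_tests`.
#' @export
bonferroni_threshold <- function(n_tests, fwer = 0.05) {
  if (any(n_tests < 1)) stop("n_tests must be at least 1")
  fwer / n_tests
}

#' Multiple-testing plan for a spline association scan
#'
#' Combines the Li–Ji effective number of phenotypes with the number of
#' effects tested per phenotype (three spline orders) into a total test
#' count and per-test thresholds. The effective count is rounded to the
#' nearest integer before multiplication, matching the convention of
#' reporting an integer number of effective phenotypes; Sidak is the
#' primary conversion and Bonferroni is reported alongside.
#'
#' @param meff effective number of phenotypes (a number or a `meff`
#'   object).
#' @param n_effects effects tested per phenotype (default 3).
#' @param fwer family-wise error rate.
#' @return a list of class `mt_plan`: `meff`, `meff_rounded`,
#'   `n_effects`, `n_tests`, `fwer`, `threshold_sidak`,
#'   `threshold_bonferroni`.
#' @export
multiple_testing_plan <- function(meff, n_effects = 3, fwer = 0.05) {
  m_raw <- if (inherits(meff, "meff")) meff$meff else as.numeric(meff)
  m <- max(round(m_raw), 1)
  n_tests <- m * n_effects
  out <- list(meff = m_raw, meff_rounded = m, n_effects = n_effects,
              n_tests = n_tests, fwer = fwer,
              threshold_sidak = sidak_threshold(n_tests, fwer),
              threshold_bonferroni = bonferroni_threshold(n_tests, fwer))
  class(out) <- "mt_plan"
  out
}

#' @export
print.mt_plan <- function(x, ...) {
  cat(sprintf(
    "Multiple testing: Meff = %.2f (rounded %d) x %d effects = %d tests\n",
    x$meff, x$meff_rounded, x$n_effects, x$n_tests))
  cat(sprintf("  FWER %.2f -> per-test alpha: %.3g (Sidak), %.3g (Bonferroni)\n",
              x$fwer, x$threshold_sidak, x$threshold_bonferroni))
  invisible(x)
}

#' Kinship-aware spline association scan
#'
#' Tests each phenotype (genetic-cluster mean, ROI, or vertex) for linear,
#' quadratic and cubic effects of a continuous symptom score: the score is
#' winsorised, expanded into three orthogonal natural-spline columns
#' ([natural_spline_basis()]), and entered together with covariates into a
#' kinship mixed model ([fit_kinship_lmm()]) with the phenotype as
#' response. Family-wise error is controlled at `fwer` over
#' `Meff x 3` tests, where Meff is the Li–Ji effective number of
#' covariate-residualised phenotypes.
#'
#' @param phenotypes N x P matrix of phenotypes (individuals in rows).
#' @param score numeric score vector.
#' @param covariates optional data frame of covariates (residualised into
#'   the fixed effects).
#' @param kinship N x N kinship matrix, or an individual table from which
#'   to build it, or `NULL` for unrelated individuals.
#' @param ids optional individual ids for alignment checks; defaults to
#'   the phenotype rownames.
#' @param fwer family-wise error rate (default 0.05).
#' @param winsor_k winsorisation cutoff in SD units (default 4).
#' @return an object of class `association_scan`: `table` (one row per
#'   phenotype x spline order with beta, se, t, p, r and the significance
#'   flag), `plan` (the [multiple_testing_plan()]), `hits`,
#'   `n_winsorised`.
#' @export
run_association_scan <- function(phenotypes, score, covariates = NULL,
                                 kinship = NULL, ids = NULL,
                                 fwer = 0.05, winsor_k = 4) {
  phenotypes <- as.matrix(phenotypes)
  n <- nrow(phenotypes)
  if (length(score) != n)
    stop("score and phenotypes have different lengths")
  eig <- NULL
  if (is.data.frame(kinship)) {
    # individual table: exploit the family-block structure directly
    if (nrow(kinship) != n) stop("kinship and phenotypes misaligned")
    if (!is.null(ids) &&
        !identical(as.character(ids), as.character(kinship$individual_id)))
      stop("individual ids of kinship and phenotypes do not match")
    eig <- family_block_eigen(kinship)
  } else if (!is.null(kinship)) {
    kinship <- as.matrix(kinship)
    if (nrow(kinship) != n) stop("kinship and phenotypes misaligned")
    if (!is.null(ids) && !is.null(rownames(kinship)) &&
        !identical(as.character(ids), rownames(kinship)))
      stop("individual ids of kinship and phenotypes do not match")
    if (!isTRUE(all.equal(kinship, t(kinship), tolerance = 1e-8)))
      stop("kinship matrix must be symmetric")
    eig <- relationship_eigen(2 * kinship)
  }
  pn <- colnames(phenotypes)
  if (is.null(pn)) pn <- sprintf("P%03d", seq_len(ncol(phenotypes)))
  ws <- winsorise(score, k_sd = winsor_k)
  sb <- natural_spline_basis(as.numeric(ws))
  B <- sb$basis
  if (!is.null(covariates)) {
    C <- stats::model.matrix(~ ., data = as.data.frame(covariates))[, -1,
                                                                    drop = FALSE]
  } else C <- NULL
  X <- cbind(`(Intercept)` = 1, C, B)
  # Meff on covariate-residualised phenotypes
  resid_ph <- if (is.null(C)) scale(phenotypes, scale = FALSE)
              else residualize(phenotypes, as.data.frame(C))
  sds <- apply(resid_ph, 2, stats::sd)
  if (any(sds < 1e-12)) stop("phenotype with zero residual variance")
  meff <- effective_number_of_tests(stats::cor(resid_ph))
  plan <- multiple_testing_plan(meff, n_effects = 3, fwer = fwer)
  if (is.null(eig)) eig <- list(values = rep(1, n), rotate = identity)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; aliased columns: ",
         paste(bad, collapse = ", "))
  }
  lam <- pmax(eig$values, 0)
  Xt <- eig$rotate(X)
  Yt <- eig$rotate(phenotypes)
  spl_idx <- ncol(X) - 2:0
  rows <- vector("list", ncol(phenotypes))
  for (j in seq_len(ncol(phenotypes))) {
    fit <- reml_fit_rotated(Yt[, j], Xt, lam, colnames(X))
    cf <- fit$coefficients[spl_idx, ]
    rows[[j]] <- data.frame(phenotype = pn[j], order = 1:3,
                            beta = cf$beta, se = cf$se, t = cf$t,
                            p = cf$p, r = cf$r,
                            stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  tab$significant <- tab$p < plan$threshold_sidak
  rownames(tab) <- NULL
  out <- list(table = tab, plan = plan,
              hits = tab[tab$significant, , drop = FALSE],
              n_winsorised = attr(ws, "n_modified"),
              meff = meff, spline_basis = sb)
  class(out) <- "association_scan"
  out
}

#' @export
print.association_scan <- function(x, ...) {
  cat(sprintf(
    "Association scan: %d phenotypes x 3 spline orders (%d winsorised)\n",
    nrow(x$table) / 3, x$n_winsorised))
  print(x$plan)
  if (nrow(x$hits)) {
    cat("Significant associations:\n")
    print(x$hits, row.names = FALSE, digits = 4)
  } else cat("No association survives the family-wise threshold.\n")
  invisible(x)
}

#' @export
summary.association_scan <- function(object, ...) {
  list(n_phenotypes = nrow(object$table) / 3,
       meff = object$plan$meff,
       n_tests = object$plan$n_tests,
       threshold_sidak = object$plan$threshold_sidak,
       threshold_bonferroni = object$plan$threshold_bonferroni,
       n_hits = nrow(object$hits),
       n_winsorised = object$n_winsorised)
}
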