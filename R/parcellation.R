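#' Residualise a phenotype matrix on covariates
#'
#' Removes covariate effects (global brain measures, sex, age, acquisition,
#' ...) from every column of a phenotype matrix by ordinary least squares,
#' returning residuals that are exactly orthogonal to the design columns.
#'
#' @param Y numeric matrix (individuals x phenotypes) or vector.
#' @param covariates data frame (or matrix) of covariates, rows aligned
#'   with `Y`.
#' @param formula model formula applied to `covariates` (default `~ .`,
#'   all columns plus an intercept).
#' @return residual matrix with the dimensions and dimnames of `Y`.
#' @export
residualize <- function(Y, covariates, formula = ~ .) {
  Y <- as.matrix(Y)
  X <- stats::model.matrix(formula, data = as.data.frame(covariates))
  if (nrow(X) != nrow(Y))
    stop("covariates and phenotypes have different numbers of rows")
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("covariate design is rank deficient; aliased columns: ",
         paste(bad, collapse = ", "))
  }
  res <- qr.resid(qx, Y)
  dimnames(res) <- dimnames(Y)
  res
}

#' Pairwise genetic correlations between vertex phenotypes
#'
#' Estimates the V x V matrix of additive-genetic correlations between
#' residualised vertex phenotypes from twin/sibling families.
#'
#' Two estimators are available. `"fiml"` fits a bivariate AE model
#' ([fit_bivariate_ae()]) to every pair — the reference estimator, but
#' quadratic in V. `"moment"` uses cross-relative covariances: under the
#' AE model the cross-relative cross-trait covariance equals
#' \eqn{r\,A_{12}} at expected relatedness r, so the genetic covariance
#' matrix is estimated in one vectorised pass by pair-count-weighted least
#' squares over the relatedness classes,
#' \eqn{\hat A = \sum_r n_r\, r\, C_r / \sum_r n_r\, r^2}, and
#' \eqn{r_{G,uv} = A_{uv}/\sqrt{A_{uu}A_{vv}}}. (Like the FIML fit, this
#' assumes no shared-environment component; unlike Falconer-style
#' differencing of MZ and DZ covariances it does not pay a variance
#' penalty for robustness to one.) Vertices with a non-positive estimated
#' genetic variance have no identified genetic correlation; their entries
#' are set to `NA` and flagged (never silently zeroed).
#'
#' @param X residualised phenotype matrix (individuals x vertices), rows
#'   aligned with `fams`.
#' @param fams a `family_set`.
#' @param estimator `"moment"` (default) or `"fiml"`.
#' @return an object of class `genetic_correlation`: list with `rg` (V x V,
#'   diagonal 1, symmetric), `a_diag` (per-vertex genetic variance in
#'   standardised units), `nonidentified` (logical per vertex),
#'   `estimator`.
#' @export
pairwise_genetic_correlations <- function(X, fams,
                                          estimator = c("moment", "fiml")) {
  estimator <- match.arg(estimator)
  X <- as.matrix(X)
  V <- ncol(X)
  ids <- colnames(X)
  if (is.null(ids)) ids <- sprintf("V%04d", seq_len(V))
  if (estimator == "moment") {
    Z <- scale(X)
    pr <- relative_pairs(fams)
    cross_cov <- function(sel) {
      i <- pr$i[sel]; j <- pr$j[sel]
      (crossprod(Z[i, , drop = FALSE], Z[j, , drop = FALSE]) +
       crossprod(Z[j, , drop = FALSE], Z[i, , drop = FALSE])) /
        (2 * length(i))
    }
    if (nrow(pr) == 0)
      stop("moment estimator needs relative pairs")
    num <- 0; den <- 0
    for (r_level in unique(pr$r)) {
      sel <- pr$r == r_level
      num <- num + sum(sel) * r_level * cross_cov(sel)
      den <- den + sum(sel) * r_level^2
    }
    A <- num / den
    A <- (A + t(A)) / 2
    a <- diag(A)
    nonid <- a <= 0
    rg <- A / sqrt(outer(pmax(a, 1e-300), pmax(a, 1e-300)))
    rg <- pmin(pmax(rg, -1), 1)
    rg[nonid, ] <- NA_real_
    rg[, nonid] <- NA_real_
    diag(rg)[!nonid] <- 1
  } else {
    a <- numeric(V); nonid <- logical(V)
    rg <- diag(1, V)
    for (u in seq_len(V)) {
      fu <- fit_ae(X[, u], fams, ci = FALSE)
      a[u] <- fu$a2
      nonid[u] <- fu$h2 <= 1e-6
    }
    for (u in seq_len(V - 1L)) for (v in (u + 1L):V) {
      if (nonid[u] || nonid[v]) { rg[u, v] <- rg[v, u] <- NA_real_; next }
      f <- fit_bivariate_ae(X[, c(u, v)], fams, n_starts = 1)
      rg[u, v] <- rg[v, u] <- f$rg
    }
    rg[nonid, ] <- NA_real_; rg[, nonid] <- NA_real_
    diag(rg)[!nonid] <- 1
  }
  dimnames(rg) <- list(ids, ids)
  out <- list(rg = rg, a_diag = a, nonidentified = nonid,
              estimator = estimator, vertex_ids = ids)
  class(out) <- "genetic_correlation"
  out
}

#' @export
print.genetic_correlation <- function(x, ...) {
  cat("Genetic correlation matrix:", length(x$vertex_ids), "vertices,",
      "estimator =", x$estimator, "\n")
  if (any(x$nonidentified))
    cat("  non-identified vertices (zero genetic variance):",
        sum(x$nonidentified), "\n")
  invisible(x)
}

#' Genetic correlations to clustering dissimilarities
#'
#' Transforms a genetic-correlation matrix into the dissimilarity matrix
#' consumed by the fuzzy clustering step, \eqn{d = 1 - r_G} (range
#' \[0, 2\], zero diagonal). Non-identified entries are imputed with the
#' row-median dissimilarity — fuzzy clustering needs a complete matrix —
#' and the number of imputed entries is reported as an attribute.
#'
#' @param G a `genetic_correlation` object or a plain correlation matrix.
#' @return a V x V dissimilarity matrix with attribute `n_imputed`.
#' @export
to_dissimilarity <- function(G) {
  rg <- if (inherits(G, "genetic_correlation")) G$rg else as.matrix(G)
  D <- 1 - rg
  diag(D) <- 0
  n_imp <- sum(is.na(D))
  if (n_imp > 0) {
    med <- apply(D, 1, stats::median, na.rm = TRUE)
    med[is.na(med)] <- stats::median(D, na.rm = TRUE)
    for (i in seq_len(nrow(D))) {
      na <- is.na(D[i, ])
      D[i, na] <- pmax(med[i], med[na], na.rm = TRUE)
    }
    D <- (D + t(D)) / 2
    diag(D) <- 0
  }
  attr(D, "n_imputed") <- n_imp
  D
}

# PAM-style BUILD step: greedy medoid selection, deterministic.
pam_build_medoids <- function(D, k) {
  V <- nrow(D)
  med <- which.min(rowSums(D))
  dmin <- D[, med]
  while (length(med) < k) {
    gains <- vapply(seq_len(V), function(cand) {
      if (cand %in% med) return(-Inf)
      sum(pmax(dmin - D[, cand], 0))
    }, 0)
    med <- c(med, which.max(gains))
    dmin <- pmin(dmin, D[, med[length(med)]])
  }
  med
}

# FANNY objective: sum over clusters of (m' D m) / (2 sum m), m = U^r.
fanny_objective <- function(U, D, memb_exp = 2) {
  M <- U^memb_exp
  s <- colSums(M)
  num <- colSums(M * (D %*% M))
  sum(num / (2 * pmax(s, 1e-300)))
}

#' Fuzzy clustering of a dissimilarity matrix (FANNY)
#'
#' Minimises the Kaufman–Rousseeuw fuzzy-analysis objective
#' \deqn{\sum_{v=1}^{k} \frac{\sum_{i,j} u_{iv}^r u_{jv}^r d_{ij}}
#'       {2 \sum_j u_{jv}^r}}
#' over membership matrices U (entries >= 0, rows summing to 1), with
#' membership exponent r. Memberships are initialised from a deterministic
#' PAM-style medoid BUILD step (smoothed one-hot) and updated by the
#' Lagrangian fixed-point rule \eqn{u_{iv} \propto (1/g_{iv})^{1/(r-1)}},
#' where \eqn{g_{iv}} is the partial derivative of the objective with
#' respect to the transformed membership; a step-halving safeguard keeps
#' the objective non-increasing at every accepted iteration.
#'
#' @param D symmetric dissimilarity matrix with zero diagonal.
#' @param k number of clusters, `2 <= k < nrow(D)`.
#' @param memb_exp membership exponent r (> 1), default 2.
#' @param tol relative objective-change convergence tolerance.
#' @param max_iter maximum iterations.
#' @return an object of class `fuzzy_clustering`: `membership` (V x k, rows
#'   sum to 1), `objective`, `objective_trace`, `iterations`, `converged`,
#'   `memb_exp`, `k`, `medoids` (the initialisation), `clustering` (crisp
#'   argmax labels).
#' @export
fanny_cluster <- function(D, k, memb_exp = 2, tol = 1e-9, max_iter = 500) {
  D <- as.matrix(D)
  V <- nrow(D)
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8)))
    stop("D must be symmetric")
  if (any(diag(D) != 0)) stop("D must have a zero diagonal")
  if (any(D < 0)) stop("D must be non-negative")
  if (k < 2 || k >= V) stop("k must satisfy 2 <= k < number of points")
  if (max(D) <= 0) stop("all points are identical: nothing to cluster")
  if (memb_exp <= 1) stop("membership exponent must exceed 1")
  med <- pam_build_medoids(D, k)
  lab <- apply(D[, med, drop = FALSE], 1, which.min)  # ties -> smallest
  U <- matrix(0.25 / k, V, k)
  U[cbind(seq_len(V), lab)] <- U[cbind(seq_len(V), lab)] + 0.75
  obj <- fanny_objective(U, D, memb_exp)
  trace <- obj
  converged <- FALSE
  iter <- 0
  inv_pow <- 1 / (memb_exp - 1)
  while (iter < max_iter) {
    iter <- iter + 1
    M <- U^memb_exp
    s <- pmax(colSums(M), 1e-300)
    G <- D %*% M
    Fv <- colSums(M * G) / (2 * s)
    gder <- sweep(sweep(G, 2, Fv, `-`), 2, s, `/`)
    Unew <- matrix(0, V, k)
    for (i in seq_len(V)) {
      g <- gder[i, ]
      if (any(g <= 1e-12)) {
        Unew[i, which.min(g)] <- 1
      } else {
        w <- (1 / g)^inv_pow
        Unew[i, ] <- w / sum(w)
      }
    }
    onew <- fanny_objective(Unew, D, memb_exp)
    halv <- 0
    while (onew > obj + 1e-15 && halv < 30) {
      Unew <- (Unew + U) / 2
      onew <- fanny_objective(Unew, D, memb_exp)
      halv <- halv + 1
    }
    if (onew > obj + 1e-15) { converged <- TRUE; break }
    delta <- obj - onew
    U <- Unew; obj <- onew
    trace <- c(trace, obj)
    if (delta <= tol * max(abs(obj), 1e-12)) { converged <- TRUE; break }
  }
  out <- list(membership = U, objective = obj, objective_trace = trace,
              iterations = iter, converged = converged,
              memb_exp = memb_exp, k = k, medoids = med,
              clustering = crisp_assignment(U))
  class(out) <- "fuzzy_clustering"
  out
}

#' @export
print.fuzzy_clustering <- function(x, ...) {
  cat(sprintf("FANNY fuzzy clustering: %d points, k = %d, r = %g\n",
              nrow(x$membership), x$k, x$memb_exp))
  cat(sprintf("  objective = %.6g after %d iterations (%s)\n",
              x$objective, x$iterations,
              if (x$converged) "converged" else "max_iter reached"))
  cat("  crisp cluster sizes:",
      paste(tabulate(x$clustering, x$k), collapse = ", "), "\n")
  invisible(x)
}

#' Crisp labels from a fuzzy membership matrix
#'
#' @param U membership matrix (rows sum to 1). Ties are broken toward the
#'   smallest cluster index, deterministically.
#' @return integer vector of cluster labels.
#' @export
crisp_assignment <- function(U) {
  apply(as.matrix(U), 1, which.max)
}

#' Silhouette widths of a crisp clustering
#'
#' For each point, \eqn{s(i) = (b_i - a_i)/\max(a_i, b_i)} where \eqn{a_i}
#' is the mean dissimilarity to the other members of its own cluster and
#' \eqn{b_i} the smallest mean dissimilarity to any other cluster. Points
#' in singleton clusters get \eqn{s(i) = 0}. The mean width summarises how
#' cohesive and well separated the clustering is.
#'
#' @param labels integer/character cluster labels.
#' @param D dissimilarity matrix.
#' @return an object of class `silhouette_result`: `widths` (per point),
#'   `mean`, `k`.
#' @export
silhouette_mean <- function(labels, D) {
  D <- as.matrix(D)
  labels <- as.vector(labels)
  V <- nrow(D)
  if (length(labels) != V) stop("labels must cover all points")
  lev <- sort(unique(labels))
  if (length(lev) < 2) stop("need at least two non-empty clusters")
  sizes <- table(factor(labels, levels = lev))
  # mean dissimilarity from each point to each cluster
  ind <- outer(labels, lev, `==`) * 1
  sums <- D %*% ind
  widths <- numeric(V)
  for (i in seq_len(V)) {
    li <- match(labels[i], lev)
    if (sizes[li] == 1L) { widths[i] <- 0; next }
    a <- sums[i, li] / (sizes[li] - 1L)
    b <- min(sums[i, -li] / sizes[-li])
    widths[i] <- (b - a) / max(a, b)
  }
  out <- list(widths = widths, mean = mean(widths), k = length(lev))
  class(out) <- "silhouette_result"
  out
}

#' @export
print.silhouette_result <- function(x, ...) {
  cat(sprintf("Silhouette: k = %d, mean width = %.4f\n", x$k, x$mean))
  invisible(x)
}

#' Choose the number of clusters by silhouette plateau
#'
#' Runs [fanny_cluster()] for each candidate k, computes the mean
#' silhouette width of the crisp labels, and recommends the smallest k
#' whose silhouette is within `plateau_frac` of the curve maximum — the
#' plateau-onset rule that mirrors choosing a parsimonious parcellation
#' once the silhouette curve flattens. When even the best silhouette is
#' weak (< 0.1) the recommendation is flagged low-confidence.
#'
#' @param D dissimilarity matrix.
#' @param k_range candidate numbers of clusters.
#' @param plateau_frac plateau tolerance as a fraction of the maximum
#'   (default 0.02).
#' @param ... passed to [fanny_cluster()].
#' @return an object of class `k_selection`: `curve` (data frame of k and
#'   mean silhouette), `recommended_k`, `best_k`, `low_confidence`.
#' @export
select_k <- function(D, k_range = 2:16, plateau_frac = 0.02, ...) {
  D <- as.matrix(D)
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 2) || any(k_range >= nrow(D)))
    stop("k_range must lie within [2, V - 1]")
  sil <- vapply(k_range, function(k) {
    cl <- fanny_cluster(D, k, ...)
    if (length(unique(cl$clustering)) < 2) return(NA_real_)
    silhouette_mean(cl$clustering, D)$mean
  }, 0)
  curve <- data.frame(k = k_range, silhouette = sil)
  smax <- max(sil, na.rm = TRUE)
  ok <- which(!is.na(sil) & sil >= smax - plateau_frac * abs(smax))
  rec <- k_range[min(ok)]
  out <- list(curve = curve, recommended_k = rec,
              best_k = k_range[which.max(sil)],
              low_confidence = smax < 0.1)
  class(out) <- "k_selection"
  out
}

#' @export
print.k_selection <- function(x, ...) {
  cat("Silhouette-based selection of k\n")
  print(x$curve, row.names = FALSE)
  cat(sprintf("  recommended k = %d (plateau onset; curve max at k = %d)%s\n",
              x$recommended_k, x$best_k,
              if (x$low_confidence) "  [low confidence: weak silhouette]"
              else ""))
  invisible(x)
}

#' @export
plot.k_selection <- function(x, ...) {
  plot(x$curve$k, x$curve$silhouette, type = "b", xlab = "number of clusters",
       ylab = "mean silhouette width", ...)
  graphics::abline(v = x$recommended_k, lty = 2)
  invisible(x)
}

#' Per-individual cluster mean phenotypes
#'
#' Averages the vertex columns of each cluster into one phenotype per
#' cluster per individual (the unweighted mean over member vertices),
#' reducing the cortex to k analysable traits.
#'
#' @param X vertex matrix (individuals x vertices).
#' @param labels cluster label per vertex.
#' @return N x k matrix with cluster labels as column names.
#' @export
cluster_mean_phenotypes <- function(X, labels) {
  X <- as.matrix(X)
  if (length(labels) != ncol(X))
    stop("labels must cover all vertices")
  lev <- sort(unique(labels))
  ind <- outer(labels, lev, `==`) * 1
  sizes <- colSums(ind)
  if (any(sizes == 0)) stop("empty cluster")
  M <- X %*% sweep(ind, 2, sizes, `/`)
  colnames(M) <- as.character(lev)
  rownames(M) <- rownames(X)
  M
}
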