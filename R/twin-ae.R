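#' Log-likelihood of one family under the univariate AE model
#'
#' Multivariate-normal log-density of the observed (non-missing) members of
#' one family under the classical AE variance decomposition: the family
#' covariance is \eqn{a^2 R + e^2 I}, where R is the expected additive
#' relatedness (1 between MZ co-twins, 0.5 between DZ twins/siblings) and
#' \eqn{a^2}, \eqn{e^2} are the additive-genetic and unique-environment
#' variances. Missing members are marginalised out (full-information
#' likelihood).
#'
#' @param a2,e2 additive-genetic and unique-environment variances.
#' @param mu trait mean.
#' @param values numeric vector of the family members' trait values; `NA`
#'   entries are treated as missing.
#' @param relatedness the family's relatedness matrix (see
#'   [relatedness_matrix()]).
#' @return the log-density (scalar); `-Inf` is never returned silently —
#'   a non-positive-definite covariance raises an error naming the
#'   offending parameters.
#' @export
loglik_ae <- function(a2, e2, mu, values, relatedness) {
  if (a2 < 0 || e2 <= 0)
    stop("invalid variances: a2 = ", a2, ", e2 = ", e2)
  obs <- which(!is.na(values))
  if (length(obs) == 0L) stop("at least one non-missing value required")
  S <- a2 * relatedness[obs, obs, drop = FALSE] +
    e2 * diag(length(obs))
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(ch))
    stop("family covariance not positive definite for a2 = ", a2,
         ", e2 = ", e2)
  d <- values[obs] - mu
  z <- backsolve(ch, d, transpose = TRUE)
  -0.5 * (length(obs) * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(z^2))
}

# All within-family pairs with their expected additive relatedness
# (1 for MZ co-twins, 0.5 otherwise). Row indices into fams.
relative_pairs <- function(fams) {
  idx <- family_indices(fams)
  out <- list(i = integer(0), j = integer(0), r = numeric(0))
  for (rows in idx) {
    m <- length(rows)
    if (m < 2L) next
    for (a in seq_len(m - 1L)) for (b in (a + 1L):m) {
      out$i <- c(out$i, rows[a]); out$j <- c(out$j, rows[b])
      out$r <- c(out$r,
                 if (fams$rel[rows[a]] == "MZ" && fams$rel[rows[b]] == "MZ")
                   1 else 0.5)
    }
  }
  as.data.frame(out)
}

# Group families by (relatedness pattern, missingness pattern) and collect
# the sufficient statistics needed for the FIML likelihood: counts, per-group
# sums and cross-products of the observed sub-vectors. `Y` is N x t.
fiml_groups <- function(Y, fams) {
  Y <- as.matrix(Y)
  t_ <- ncol(Y)
  idx <- family_indices(fams)
  keys <- character(length(idx)); payload <- vector("list", length(idx))
  for (f in seq_along(idx)) {
    rows <- idx[[f]]
    rel <- fams$rel[rows]
    y <- as.vector(t(Y[rows, , drop = FALSE]))  # individual-major stacking
    obs <- which(!is.na(y))
    if (length(obs) == 0L) { keys[f] <- ""; next }
    keys[f] <- paste(paste(rel, collapse = ","),
                     paste(obs, collapse = ","), sep = "|")
    payload[[f]] <- list(rel = rel, obs = obs, y = y[obs])
  }
  keep <- which(nzchar(keys))
  groups <- list()
  for (key in unique(keys[keep])) {
    members <- keep[keys[keep] == key]
    p1 <- payload[[members[1]]]
    m <- length(p1$rel)
    ymat <- vapply(members, function(f) payload[[f]]$y,
                   numeric(length(p1$obs)))
    Yg <- if (length(p1$obs) == 1L) matrix(ymat, ncol = 1) else t(ymat)
    groups[[key]] <- list(
      rel = p1$rel, m = m, obs = p1$obs, n = length(members),
      n_obs = length(p1$obs),
      sumy = colSums(Yg), Syy = crossprod(Yg),
      R = relatedness_matrix(p1$rel))
  }
  groups
}

# Negative log-likelihood over FIML groups for a given family covariance
# builder `make_sigma(group)` and mean vector builder `make_mu(group)`.
fiml_negloglik <- function(groups, make_sigma, make_mu) {
  nll <- 0
  for (g in groups) {
    S <- make_sigma(g)
    ch <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    Si <- chol2inv(ch)
    mu <- make_mu(g)
    M <- g$Syy - outer(g$sumy, mu) - outer(mu, g$sumy) +
      g$n * outer(mu, mu)
    nll <- nll + 0.5 * (g$n * (g$n_obs * log(2 * pi) +
                               2 * sum(log(diag(ch)))) + sum(Si * M))
  }
  nll
}

# Profile log-likelihood of the univariate AE model at fixed h2: the mean
# and the total variance have closed-form maximisers, so the model reduces
# to a 1-d optimisation over h2 in [0, 1).
ae_profile_loglik <- function(h2, groups) {
  num <- 0; den <- 0; ldet <- 0; Ntot <- 0
  pre <- vector("list", length(groups))
  for (k in seq_along(groups)) {
    g <- groups[[k]]
    C <- h2 * g$R[g$obs, g$obs, drop = FALSE] +
      (1 - h2) * diag(g$n_obs)
    ch <- tryCatch(chol(C), error = function(e) NULL)
    if (is.null(ch)) return(list(loglik = -Inf))
    Ci <- chol2inv(ch)
    one <- rep(1, g$n_obs)
    num <- num + sum(Ci %*% g$sumy)
    den <- den + g$n * sum(Ci)
    ldet <- ldet + g$n * 2 * sum(log(diag(ch)))
    Ntot <- Ntot + g$n * g$n_obs
    pre[[k]] <- Ci
  }
  mu <- num / den
  Q <- 0
  for (k in seq_along(groups)) {
    g <- groups[[k]]; Ci <- pre[[k]]
    M <- g$Syy - outer(g$sumy, rep(mu, g$n_obs)) -
      outer(rep(mu, g$n_obs), g$sumy) + g$n * mu^2
    Q <- Q + sum(Ci * M)
  }
  if (Q <= 0) return(list(loglik = -Inf))
  s2 <- Q / Ntot
  ll <- -0.5 * (Ntot * (log(2 * pi) + log(s2) + 1) + ldet)
  list(loglik = ll, mu = mu, s2 = s2)
}

#' Fit the univariate AE twin model by full-information maximum likelihood
#'
#' Decomposes the variance of one trait measured on twin/sibling families
#' (at most three members each) into additive-genetic (\eqn{a^2}) and
#' unique-environment (\eqn{e^2}) components. The per-family likelihood is
#' multivariate normal with covariance \eqn{a^2 R + e^2 I}; missing members
#' are marginalised. Internally the likelihood is profiled: for fixed
#' heritability \eqn{h^2 = a^2/(a^2+e^2)} the mean and total variance have
#' closed-form maximisers, so estimation is an exact 1-d search over
#' \eqn{h^2}, which is boundary-safe by construction. The 95% CI for
#' \eqn{h^2} inverts the 1-df likelihood-ratio test (profile interval);
#' a symmetric normal-approximation interval is substituted if profiling
#' fails.
#'
#' @param values numeric trait vector aligned with the rows of `fams`
#'   (`NA` = missing).
#' @param fams a `family_set`.
#' @param constrain_h2 optionally fix the heritability (e.g. 0 for the null
#'   model of an LRT).
#' @param ci compute the profile 95% CI for h2 (default `TRUE`).
#' @return an object of class `ae_fit` with components `a2`, `e2`, `h2`,
#'   `mean`, `loglik`, `ci95_h2`, `identified`, `n_families`.
#' @export
fit_ae <- function(values, fams, constrain_h2 = NULL, ci = TRUE) {
  groups <- fiml_groups(matrix(values, ncol = 1), fams)
  if (length(groups) == 0L) stop("no observed data")
  v <- stats::var(values, na.rm = TRUE)
  if (!is.finite(v) || v < 1e-12)
    stop("degenerate data: trait has (near-)zero variance")
  # identification diagnostic: relatedness levels present among observed pairs
  lev <- unique(unlist(lapply(groups, function(g) {
    if (g$n_obs < 2) return(numeric(0))
    # observed entries map to members obs (univariate: obs == member index)
    Ro <- g$R[g$obs, g$obs, drop = FALSE]
    unique(Ro[upper.tri(Ro)])
  })))
  identified <- length(lev) >= 2
  if (!is.null(constrain_h2)) {
    pr <- ae_profile_loglik(min(constrain_h2, 1 - 1e-8), groups)
    fit <- list(h2 = constrain_h2, loglik = pr$loglik, mu = pr$mu,
                s2 = pr$s2)
  } else {
    opt <- stats::optimize(function(h)
      ae_profile_loglik(h, groups)$loglik, c(0, 1 - 1e-7),
      maximum = TRUE, tol = 1e-9)
    # the optimum can sit at the h2 = 0 boundary
    p0 <- ae_profile_loglik(0, groups)
    if (p0$loglik >= opt$objective) {
      h2_hat <- 0; pr <- p0
    } else {
      h2_hat <- opt$maximum; pr <- ae_profile_loglik(h2_hat, groups)
    }
    fit <- list(h2 = h2_hat, loglik = pr$loglik, mu = pr$mu, s2 = pr$s2)
  }
  ci95 <- c(NA_real_, NA_real_)
  if (ci && is.null(constrain_h2)) {
    cut <- fit$loglik - stats::qchisq(0.95, 1) / 2
    f <- function(h) ae_profile_loglik(h, groups)$loglik - cut
    lo <- if (f(0) >= 0) 0 else
      tryCatch(stats::uniroot(f, c(0, fit$h2), tol = 1e-6)$root,
               error = function(e) NA_real_)
    hi_end <- 1 - 1e-7
    hi <- if (f(hi_end) >= 0) 1 else
      tryCatch(stats::uniroot(f, c(fit$h2, hi_end), tol = 1e-6)$root,
               error = function(e) NA_real_)
    ci95 <- c(lo, hi)
  }
  out <- list(a2 = fit$h2 * fit$s2, e2 = (1 - fit$h2) * fit$s2,
              h2 = fit$h2, mean = fit$mu, loglik = fit$loglik,
              ci95_h2 = ci95, identified = identified,
              n_families = sum(vapply(groups, `[[`, 0, "n")),
              constrained = !is.null(constrain_h2))
  if (!identified)
    out$note <- paste("only one relatedness level among observed relative",
                      "pairs: additive-genetic and familial variance are",
                      "confounded (flat likelihood direction)")
  class(out) <- "ae_fit"
  out
}

#' @export
print.ae_fit <- function(x, ...) {
  cat("Univariate AE model (FIML)\n")
  cat(sprintf("  a2 = %.4f  e2 = %.4f  h2 = %.3f", x$a2, x$e2, x$h2))
  if (all(is.finite(x$ci95_h2)))
    cat(sprintf("  (95%% CI %.3f-%.3f)", x$ci95_h2[1], x$ci95_h2[2]))
  cat("\n")
  cat(sprintf("  mean = %.4f  logLik = %.3f  families = %d\n",
              x$mean, x$loglik, x$n_families))
  if (!x$identified) cat("  note:", x$note, "\n")
  invisible(x)
}

#' @export
coef.ae_fit <- function(object, ...)
  c(a2 = object$a2, e2 = object$e2, h2 = object$h2, mean = object$mean)

#' @export
logLik.ae_fit <- function(object, ...) {
  val <- object$loglik
  attr(val, "df") <- if (object$constrained) 2 else 3
  class(val) <- "logLik"
  val
}

#' @export
confint.ae_fit <- function(object, parm = "h2", level = 0.95, ...) {
  if (!identical(parm, "h2") || level != 0.95)
    stop("only the profile 95% interval for h2 is available")
  matrix(object$ci95_h2, 1, dimnames = list("h2", c("2.5 %", "97.5 %")))
}

# ---- bivariate AE ---------------------------------------------------------

# Build the stacked family covariance R (x) A + I (x) E on observed entries.
biv_sigma <- function(g, A, E) {
  S <- kronecker(g$R, A) + kronecker(diag(g$m), E)
  S[g$obs, g$obs, drop = FALSE]
}

biv_theta_unpack <- function(theta, constraint) {
  mu <- theta[1:2]
  if (constraint == "none") {
    La <- matrix(c(theta[3], theta[4], 0, theta[5]), 2, 2)
    Le <- matrix(c(theta[6], theta[7], 0, theta[8]), 2, 2)
  } else if (constraint == "rg_zero") {
    La <- diag(theta[3:4])
    Le <- matrix(c(theta[5], theta[6], 0, theta[7]), 2, 2)
  } else {  # independent traits
    La <- diag(theta[3:4])
    Le <- diag(theta[5:6])
  }
  list(mu = mu, A = La %*% t(La), E = Le %*% t(Le))
}

biv_moment_start <- function(Y, fams) {
  pr <- relative_pairs(fams)
  v1 <- stats::var(Y[, 1], na.rm = TRUE); v2 <- stats::var(Y[, 2], na.rm = TRUE)
  mz <- pr$r == 1
  ct <- function(a, b, sel) {  # cross-relative covariance, symmetrised
    i <- pr$i[sel]; j <- pr$j[sel]
    ok <- !is.na(Y[i, a]) & !is.na(Y[j, b]) & !is.na(Y[j, a]) & !is.na(Y[i, b])
    if (sum(ok) < 3) return(0)
    (stats::cov(Y[i[ok], a], Y[j[ok], b]) +
     stats::cov(Y[j[ok], a], Y[i[ok], b])) / 2
  }
  a11 <- max(2 * (ct(1, 1, mz) - ct(1, 1, !mz)), 0.05 * v1)
  a22 <- max(2 * (ct(2, 2, mz) - ct(2, 2, !mz)), 0.05 * v2)
  a11 <- min(a11, 0.95 * v1); a22 <- min(a22, 0.95 * v2)
  a12 <- 2 * (ct(1, 2, mz) - ct(1, 2, !mz))
  cap <- 0.9 * sqrt(a11 * a22)
  a12 <- max(min(a12, cap), -cap)
  cp <- stats::cov(Y[, 1], Y[, 2], use = "complete.obs")
  e11 <- v1 - a11; e22 <- v2 - a22
  e12 <- cp - a12
  cap_e <- 0.9 * sqrt(e11 * e22)
  e12 <- max(min(e12, cap_e), -cap_e)
  list(mu = colMeans(Y, na.rm = TRUE),
       A = matrix(c(a11, a12, a12, a22), 2),
       E = matrix(c(e11, e12, e12, e22), 2))
}

chol_params <- function(M) {
  L <- tryCatch(t(chol(M)), error = function(e) t(chol(M + diag(2) * 1e-4)))
  c(L[1, 1], L[2, 1], L[2, 2])
}

#' Fit the bivariate AE (Cholesky) twin model
#'
#' Joint FIML fit of two traits on twin/sibling families. The 2x2
#' additive-genetic (A) and unique-environment (E) covariance blocks are
#' parameterised by their Cholesky factors, so the implied family
#' covariance \eqn{R \otimes A + I \otimes E} is positive semi-definite by
#' construction. Reports the genetic correlation
#' \eqn{r_G = A_{12}/\sqrt{A_{11}A_{22}}}, the environmental correlation
#' \eqn{r_E} analogously, and the implied phenotypic correlation.
#'
#' @param Y N x 2 matrix (or data frame) of the two traits, rows aligned
#'   with `fams`; `NA` = missing.
#' @param fams a `family_set`.
#' @param constraint `"none"` (full model), `"rg_zero"` (genetic covariance
#'   fixed at 0; the null of the rG likelihood-ratio test) or
#'   `"independent"` (A and E both diagonal).
#' @param n_starts number of optimisation starts: the first is moment-based
#'   (cross-relative cross-trait covariances), the second near-null, the
#'   third mid-range; the best log-likelihood wins, ties to the first.
#' @param reltol relative convergence tolerance passed to the optimiser.
#' @return an object of class `biv_ae_fit` with `A`, `E`, `rg`, `re`,
#'   `rp`, per-trait `a2`/`e2`/`h2`, `mu`, `loglik`, `boundary` flag and
#'   `convergence` codes.
#' @export
fit_bivariate_ae <- function(Y, fams, constraint = c("none", "rg_zero",
                                                     "independent"),
                             n_starts = 3, reltol = 1e-10) {
  constraint <- match.arg(constraint)
  Y <- as.matrix(Y)
  if (ncol(Y) != 2) stop("Y must have exactly two trait columns")
  groups <- fiml_groups(Y, fams)
  nll <- function(theta) {
    p <- biv_theta_unpack(theta, constraint)
    fiml_negloglik(groups,
                   function(g) biv_sigma(g, p$A, p$E),
                   function(g) rep(p$mu, g$m)[g$obs])
  }
  ms <- biv_moment_start(Y, fams)
  v <- diag(ms$A) + diag(ms$E)
  pack <- function(mu, A, E) {
    if (constraint == "none") c(mu, chol_params(A), chol_params(E))
    else if (constraint == "rg_zero")
      c(mu, sqrt(pmax(diag(A), 1e-6)), chol_params(E))
    else c(mu, sqrt(pmax(diag(A), 1e-6)), sqrt(pmax(diag(E), 1e-6)))
  }
  starts <- list(pack(ms$mu, ms$A, ms$E))
  if (n_starts >= 2)
    starts <- c(starts, list(pack(ms$mu, diag(0.1 * v), diag(0.9 * v))))
  if (n_starts >= 3)
    starts <- c(starts, list(pack(ms$mu, diag(0.5 * v), diag(0.5 * v))))
  best <- NULL
  for (s in starts) {
    o <- stats::optim(s, nll, method = "BFGS",
                      control = list(maxit = 1000, reltol = reltol))
    if (is.null(best) || o$value < best$value - 1e-9) best <- o
  }
  p <- biv_theta_unpack(best$par, constraint)
  A <- p$A; E <- p$E
  rg <- if (constraint == "none")
    A[1, 2] / sqrt(max(A[1, 1] * A[2, 2], 1e-300)) else 0
  re <- if (constraint != "independent")
    E[1, 2] / sqrt(max(E[1, 1] * E[2, 2], 1e-300)) else 0
  rp <- (A[1, 2] + E[1, 2]) /
    sqrt((A[1, 1] + E[1, 1]) * (A[2, 2] + E[2, 2]))
  out <- list(A = A, E = E, mu = p$mu,
              a2 = diag(A), e2 = diag(E),
              h2 = diag(A) / (diag(A) + diag(E)),
              rg = rg, re = re, rp = rp,
              loglik = -best$value,
              boundary = abs(rg) > 0.995 || abs(re) > 0.995,
              convergence = best$convergence,
              constraint = constraint,
              n_families = sum(vapply(groups, `[[`, 0, "n")))
  class(out) <- "biv_ae_fit"
  out
}

#' @export
print.biv_ae_fit <- function(x, ...) {
  cat("Bivariate AE model (FIML, Cholesky)\n")
  cat(sprintf("  h2: %.3f / %.3f   rG = %.3f   rE = %.3f   rP = %.3f\n",
              x$h2[1], x$h2[2], x$rg, x$re, x$rp))
  cat(sprintf("  logLik = %.3f  constraint = %s  families = %d\n",
              x$loglik, x$constraint, x$n_families))
  if (x$boundary) cat("  note: correlation estimate at the boundary\n")
  invisible(x)
}

#' @export
coef.biv_ae_fit <- function(object, ...)
  c(a2_1 = object$a2[1], a2_2 = object$a2[2],
    e2_1 = object$e2[1], e2_2 = object$e2[2],
    rg = object$rg, re = object$re)

#' @export
logLik.biv_ae_fit <- function(object, ...) {
  val <- object$loglik
  attr(val, "df") <- switch(object$constraint, none = 8, rg_zero = 7,
                            independent = 6)
  class(val) <- "logLik"
  val
}

#' Likelihood-ratio test of nested variance-component models
#'
#' @param full,reduced fitted models (anything with a `loglik` component or
#'   a [logLik()] method), `reduced` nested in `full`.
#' @param df degrees of freedom of the test (number of constrained
#'   parameters).
#' @param tol tolerance for the reduced model exceeding the full one; a
#'   larger excess signals a failed optimisation and raises a warning.
#' @return a list of class `lrt_result`: `statistic` (clipped at 0), `df`,
#'   `p`.
#' @export
lrt <- function(full, reduced, df = 1, tol = 1e-4) {
  ll <- function(x) if (is.numeric(x)) x
    else if (!is.null(x$loglik)) x$loglik else as.numeric(stats::logLik(x))
  lf <- ll(full); lr <- ll(reduced)
  if (lr > lf + tol)
    warning("reduced model log-likelihood exceeds the full model's by ",
            format(lr - lf), ": refit with more starts")
  stat <- max(2 * (lf - lr), 0)
  out <- list(statistic = stat, df = df,
              p = stats::pchisq(stat, df, lower.tail = FALSE))
  class(out) <- "lrt_result"
  out
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("LRT: chi2 = %.4f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p))
  invisible(x)
}

# Draw one replicate of two traits with planted (h2_a, h2_b, rg, re) from
# the bivariate AE model, directly from the per-family-type multivariate
# normal. Complete data. Returns an N x 2 matrix aligned with fams.
simulate_bivariate_traits <- function(fams, h2_a, h2_b, rg, re = 0) {
  A <- matrix(c(h2_a, rg * sqrt(h2_a * h2_b),
                rg * sqrt(h2_a * h2_b), h2_b), 2)
  E <- matrix(c(1 - h2_a, re * sqrt((1 - h2_a) * (1 - h2_b)),
                re * sqrt((1 - h2_a) * (1 - h2_b)), 1 - h2_b), 2)
  Y <- matrix(0, nrow(fams), 2)
  for (tp in unique(fams$family_type)) {
    rows <- which(fams$family_type == tp)
    m <- sum(fams$family_type == tp &
             fams$family_id == fams$family_id[rows[1]])
    n_fam <- length(rows) / m
    R <- relatedness_matrix(fams$rel[rows[seq_len(m)]])
    S <- kronecker(R, A) + kronecker(diag(m), E)
    L <- sqrtm_psd(S)
    Z <- matrix(stats::rnorm(2 * m * n_fam), 2 * m, n_fam)
    W <- L %*% Z                        # (2m) x n_fam
    Y[rows, 1] <- as.vector(W[seq(1, 2 * m, by = 2), ])
    Y[rows, 2] <- as.vector(W[seq(2, 2 * m, by = 2), ])
  }
  Y
}

#' Simulation-based power to detect a genetic correlation
#'
#' Estimates, by parametric simulation, the power of the 1-df
#' likelihood-ratio test (bivariate AE model with rG free versus rG fixed
#' at 0) to detect a genetic correlation `rg` between two traits with
#' heritabilities `h2_a` and `h2_b`, under a given family structure.
#'
#' @param structure a [family_structure_spec()] (or `family_set`).
#' @param h2_a,h2_b heritabilities of the two traits.
#' @param rg true genetic correlation.
#' @param re true environmental correlation (default 0; the published
#'   power analyses of small rG are insensitive to this choice).
#' @param alpha test level.
#' @param n_reps number of simulation replicates (>= 100).
#' @param seed integer seed.
#' @param n_starts optimisation starts per fit; 1 (the moment-based start)
#'   is accurate and fast for power runs.
#' @return a list of class `rg_power`: `power` (in \[0, 1\]), `ci95`
#'   (binomial), `rejections`, `n_reps`.
#' @export
power_detect_rg <- function(structure, h2_a, h2_b, rg, re = 0,
                            alpha = 0.05, n_reps = 500, seed = 1,
                            n_starts = 1) {
  if (n_reps < 100) stop("n_reps must be at least 100")
  fams <- if (inherits(structure, "family_set")) structure
          else build_family_structure(structure)
  set.seed(seed)
  rej <- logical(n_reps)
  for (i in seq_len(n_reps)) {
    Y <- simulate_bivariate_traits(fams, h2_a, h2_b, rg, re)
    full <- fit_bivariate_ae(Y, fams, "none", n_starts = n_starts)
    red <- fit_bivariate_ae(Y, fams, "rg_zero", n_starts = n_starts)
    rej[i] <- suppressWarnings(lrt(full, red, df = 1)$p) < alpha
  }
  k <- sum(rej)
  ci <- stats::binom.test(k, n_reps)$conf.int
  out <- list(power = k / n_reps, ci95 = as.numeric(ci),
              rejections = k, n_reps = n_reps, alpha = alpha,
              params = list(h2_a = h2_a, h2_b = h2_b, rg = rg, re = re))
  class(out) <- "rg_power"
  out
}

#' @export
print.rg_power <- function(x, ...) {
  cat(sprintf(
    "Power to detect rG = %.3f (h2 = %.2f/%.2f, alpha = %.2f): %.1f%% ",
    x$params$rg, x$params$h2_a, x$params$h2_b, x$alpha, 100 * x$power))
  cat(sprintf("(95%% CI %.1f-%.1f%%, %d/%d replicates)\n",
              100 * x$ci95[1], 100 * x$ci95[2], x$rejections, x$n_reps))
  invisible(x)
}
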