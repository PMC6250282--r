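# Maximum-likelihood ACE variance decomposition for twin data.
#
# All three fits share the same machinery: pairs contribute bivariate-normal
# (or bivariate-orthant) likelihood terms with expected twin correlation
# a2 + c2 for MZ and a2/2 + c2 for DZ pairs; singletons and incomplete pairs
# contribute univariate terms.  Variance fractions are optimized on an
# unconstrained scale via a softmax map (a2, c2, e2 >= 0, summing to 1) and
# cross-trait component correlations via atanh, so boundary solutions are
# approached smoothly and never overshoot.

# Split complete-case rows into MZ pairs, DZ pairs and single contributions.
.twin_layout <- function(cohort, complete) {
  idx <- which(complete)
  fam <- cohort$family_id[idx]
  zyg <- cohort$zygosity[idx]
  pair_rows <- function(z) {
    i <- idx[zyg == z]
    f <- cohort$family_id[i]
    keep <- f %in% names(which(table(f) == 2L))
    i <- i[keep]
    i <- i[order(cohort$family_id[i], cohort$twin_order[i])]
    if (!length(i)) return(matrix(integer(0), ncol = 2))
    matrix(i, ncol = 2, byrow = TRUE)
  }
  mz <- pair_rows("MZ")
  dz <- pair_rows("DZ")
  singles <- setdiff(idx, c(mz, dz))
  list(mz = mz, dz = dz, singles = singles)
}

.covar_matrix <- function(covariates, n) {
  if (is.null(covariates)) return(matrix(numeric(0), nrow = n, ncol = 0))
  m <- as.matrix(as.data.frame(covariates))
  storage.mode(m) <- "double"
  if (nrow(m) != n) stop("covariates must have one row per cohort individual")
  if (is.null(colnames(m))) colnames(m) <- paste0("x", seq_len(ncol(m)))
  m
}

# Deterministic start-point offsets for the multi-start strategy.
.start_offsets <- function(n_starts, k) {
  base <- rbind(rep(0, k),
                diag(1.5, k),
                -diag(1.5, k),
                matrix(0.75, 1, k),
                matrix(-0.75, 1, k))
  base[seq_len(min(n_starts, nrow(base))), , drop = FALSE]
}

# Delta-method SEs for reported parameters g(par); J by central differences.
.delta_se <- function(par, vcov, g, eps = 1e-5) {
  g0 <- g(par)
  J <- matrix(0, length(g0), length(par))
  for (j in seq_along(par)) {
    pp <- pm <- par
    pp[j] <- pp[j] + eps
    pm[j] <- pm[j] - eps
    J[, j] <- (g(pp) - g(pm)) / (2 * eps)
  }
  v <- J %*% vcov %*% t(J)
  se <- sqrt(pmax(diag(v), 0))
  names(se) <- names(g0)
  se
}

.optimize_ml <- function(nll, start, offsets, jitter_idx, tol = 1e-8) {
  best <- NULL
  for (s in seq_len(nrow(offsets))) {
    st <- start
    st[jitter_idx] <- st[jitter_idx] + offsets[s, ]
    fit <- tryCatch(
      stats::nlminb(st, nll,
                    control = list(rel.tol = tol, eval.max = 2000, iter.max = 1500)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$objective)) next
    # nlminb can report false convergence on likelihood ridges; polish with
    # a quasi-Newton pass and keep whichever point is better
    pol <- tryCatch(
      stats::optim(fit$par, nll, method = "BFGS",
                   control = list(maxit = 500, reltol = tol)),
      error = function(e) NULL)
    if (!is.null(pol) && is.finite(pol$value) && pol$value < fit$objective) {
      fit$par <- pol$par
      fit$objective <- pol$value
      fit$convergence <- pol$convergence
    } else if (fit$convergence != 0 && !is.null(pol) &&
               is.finite(pol$value) && pol$convergence == 0 &&
               pol$value <= fit$objective + 1e-6) {
      fit$convergence <- 0
    }
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  if (is.null(best)) stop("all optimizer starts failed")
  best
}

.fit_vcov <- function(nll, par) {
  H <- tryCatch(stats::optimHess(par, nll), error = function(e) NULL)
  if (is.null(H) || any(!is.finite(H))) return(NULL)
  V <- tryCatch(solve(H), error = function(e) NULL)
  if (!is.null(V) && all(is.finite(V)) && all(diag(V) >= 0)) return(V)
  # boundary solutions make the observed information singular in the
  # direction of the pinned parameter; pseudo-invert over the identified
  # subspace so the remaining SEs stay usable (boundary SEs are unreliable)
  ei <- eigen((H + t(H)) / 2, symmetric = TRUE)
  tol <- max(ei$values) * 1e-10
  inv <- ifelse(ei$values > tol, 1 / ei$values, 0)
  V <- ei$vectors %*% (inv * t(ei$vectors))
  if (any(!is.finite(V))) return(NULL)
  V
}

#' Univariate ACE maximum-likelihood fit for a continuous trait
#'
#' Fits the classical twin ACE model by maximizing the bivariate-normal pair
#' likelihood with expected twin correlations `a2 + c2` (MZ) and
#' `a2/2 + c2` (DZ). Covariates enter the mean structure; singletons and
#' members of incomplete pairs contribute univariate normal terms. Variance
#' fractions are standardized (`a2 + c2 + e2 = 1` on the residual scale).
#'
#' @param trait numeric vector, one value per cohort row.
#' @param cohort data frame with `individual_id`, `family_id`, `zygosity`
#'   (`"MZ"`, `"DZ"`, `"singleton"`) and `twin_order`.
#' @param covariates optional matrix/data frame of covariates (one row per
#'   cohort row); an intercept is always included.
#' @param n_starts number of deterministic optimizer restarts.
#' @param se compute delta-method standard errors (observed information).
#' @param tol relative log-likelihood convergence tolerance.
#' @return object of class `varcomp_fit`.
#' @export
fit_ace_univariate <- function(trait, cohort, covariates = NULL,
                               n_starts = 5, se = TRUE, tol = 1e-8) {
  n <- nrow(cohort)
  stopifnot(length(trait) == n)
  Xc <- .covar_matrix(covariates, n)
  complete <- !is.na(trait) & stats::complete.cases(Xc)
  lay <- .twin_layout(cohort, complete)
  for (z in c("mz", "dz"))
    if (nrow(lay[[z]]) < 20)
      stop(sprintf("need >= 20 complete %s pairs, have %d",
                   toupper(z), nrow(lay[[z]])))
  X <- cbind(`(Intercept)` = 1, Xc)
  y <- trait

  p <- ncol(X)
  nll <- function(par) {
    beta <- par[seq_len(p)]
    s2 <- exp(par[p + 1])
    ace <- softmax_ace(par[p + 2], par[p + 3])
    e <- y - drop(X %*% beta)
    ll <- 0
    for (z in c("mz", "dz")) {
      pr <- lay[[z]]
      if (!nrow(pr)) next
      r <- if (z == "mz") ace[1] + ace[2] else ace[1] / 2 + ace[2]
      r <- min(r, 1 - 1e-10)
      e1 <- e[pr[, 1]]; e2 <- e[pr[, 2]]
      ll <- ll + sum(-log(2 * pi) - log(s2) - 0.5 * log(1 - r^2) -
                       (e1^2 + e2^2 - 2 * r * e1 * e2) / (2 * s2 * (1 - r^2)))
    }
    if (length(lay$singles))
      ll <- ll + sum(stats::dnorm(e[lay$singles], 0, sqrt(s2), log = TRUE))
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  cc <- which(complete)
  ols <- stats::lm.fit(X[cc, , drop = FALSE], y[cc])
  res <- rep(NA_real_, n); res[cc] <- ols$residuals
  rmz <- stats::cor(res[lay$mz[, 1]], res[lay$mz[, 2]])
  rdz <- stats::cor(res[lay$dz[, 1]], res[lay$dz[, 2]])
  a2_0 <- min(max(2 * (rmz - rdz), 0.05), 0.9)
  c2_0 <- min(max(2 * rdz - rmz, 0.05), 0.9 - a2_0 + 0.05)
  start <- c(ols$coefficients, log(stats::var(ols$residuals)),
             softmax_ace_inv(a2_0, c2_0))
  start[is.na(start)] <- 0

  jidx <- p + 2:3
  best <- .optimize_ml(nll, start, .start_offsets(n_starts, 2), jidx, tol)
  par <- best$par
  ace <- softmax_ace(par[p + 2], par[p + 3])

  report <- function(pp) {
    a <- softmax_ace(pp[p + 2], pp[p + 3])
    c(a2 = unname(a[1]), c2 = unname(a[2]), e2 = unname(a[3]))
  }
  ses <- rep(NA_real_, 3); names(ses) <- c("a2", "c2", "e2")
  if (se) {
    V <- .fit_vcov(nll, par)
    if (!is.null(V)) ses <- .delta_se(par, V, report)
  }
  boundary <- ace[1] < 0.005 || ace[2] < 0.005
  structure(list(
    a2 = unname(ace[1]), c2 = unname(ace[2]), e2 = unname(ace[3]),
    sigma2 = exp(par[p + 1]),
    beta = stats::setNames(par[seq_len(p)], colnames(X)),
    se = ses, threshold = NA_real_, rg = NA_real_, rc = NA_real_, re = NA_real_,
    loglik = -best$objective,
    converged = best$convergence == 0,
    boundary = boundary,
    n_pairs_used = c(MZ = nrow(lay$mz), DZ = nrow(lay$dz)),
    n_singletons = length(lay$singles),
    method = "ace_univariate"
  ), class = "varcomp_fit")
}

#' Liability-threshold ACE fit for a dichotomous trait
#'
#' The binary trait is modelled as the indicator that a standard-normal
#' latent liability exceeds a threshold; covariates shift the threshold
#' linearly (probit scale). Twin pairs contribute bivariate-normal orthant
#' probabilities with tetrachoric correlation `a2 + c2` (MZ) or `a2/2 + c2`
#' (DZ); singletons contribute Bernoulli terms. An individual is affected
#' when liability > `threshold + covariates %*% gamma`.
#'
#' @inheritParams fit_ace_univariate
#' @param binary_trait 0/1 vector, one value per cohort row.
#' @return object of class `varcomp_fit` (with `threshold` and `beta` the
#'   threshold shifts, reported on the liability scale).
#' @export
fit_liability_threshold <- function(binary_trait, cohort, covariates = NULL,
                                    n_starts = 5, se = TRUE, tol = 1e-8) {
  n <- nrow(cohort)
  stopifnot(length(binary_trait) == n, all(binary_trait %in% c(0, 1, NA)))
  Xc <- .covar_matrix(covariates, n)
  complete <- !is.na(binary_trait) & stats::complete.cases(Xc)
  lay <- .twin_layout(cohort, complete)
  for (z in c("mz", "dz"))
    if (nrow(lay[[z]]) < 20)
      stop(sprintf("need >= 20 complete %s pairs, have %d",
                   toupper(z), nrow(lay[[z]])))
  for (zz in unique(cohort$zygosity[complete])) {
    cls <- unique(binary_trait[complete & cohort$zygosity == zz])
    if (length(cls) < 2)
      stop("both outcome classes must be present in zygosity group ", zz)
  }
  d <- binary_trait
  q <- ncol(Xc)

  nll <- function(par) {
    tau <- par[1]
    gamma <- if (q) par[1 + seq_len(q)] else numeric(0)
    ace <- softmax_ace(par[q + 2], par[q + 3])
    th <- rep(tau, n) + (if (q) drop(Xc %*% gamma) else 0)
    ll <- 0
    for (z in c("mz", "dz")) {
      pr <- lay[[z]]
      if (!nrow(pr)) next
      r <- if (z == "mz") ace[1] + ace[2] else ace[1] / 2 + ace[2]
      r <- min(r, 1 - 1e-10)
      ll <- ll + sum(log(pair_orthant_prob(d[pr[, 1]], d[pr[, 2]],
                                           th[pr[, 1]], th[pr[, 2]], r)))
    }
    if (length(lay$singles)) {
      i <- lay$singles
      p1 <- pnorm(th[i], lower.tail = FALSE)
      ll <- ll + sum(log(pmax(ifelse(d[i] == 1, p1, 1 - p1), 1e-300)))
    }
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  cc <- which(complete)
  glm0 <- suppressWarnings(stats::glm.fit(
    cbind(1, Xc[cc, , drop = FALSE]), d[cc],
    family = stats::binomial(link = "probit")))
  # glm parameterizes P(D=1) = pnorm(b0 + X b); ours = pnorm(-(tau + X g))
  b <- glm0$coefficients
  sep_flag <- any(abs(b) > 8)
  start <- c(-b[1], if (q) -b[-1], softmax_ace_inv(0.3, 0.2))
  start[is.na(start)] <- 0
  jidx <- q + 2:3
  best <- .optimize_ml(nll, start, .start_offsets(n_starts, 2), jidx, tol)
  par <- best$par
  ace <- softmax_ace(par[q + 2], par[q + 3])
  report <- function(pp) {
    a <- softmax_ace(pp[q + 2], pp[q + 3])
    c(a2 = unname(a[1]), c2 = unname(a[2]), e2 = unname(a[3]),
      threshold = pp[1])
  }
  ses <- rep(NA_real_, 4); names(ses) <- c("a2", "c2", "e2", "threshold")
  if (se) {
    V <- .fit_vcov(nll, par)
    if (!is.null(V)) ses <- .delta_se(par, V, report)
  }
  structure(list(
    a2 = unname(ace[1]), c2 = unname(ace[2]), e2 = unname(ace[3]),
    sigma2 = 1,
    threshold = par[1],
    beta = if (q) stats::setNames(par[1 + seq_len(q)], colnames(Xc)) else numeric(0),
    se = ses, rg = NA_real_, rc = NA_real_, re = NA_real_,
    loglik = -best$objective,
    converged = best$convergence == 0 && !sep_flag,
    separation = sep_flag,
    boundary = ace[1] < 0.005 || ace[2] < 0.005,
    n_pairs_used = c(MZ = nrow(lay$mz), DZ = nrow(lay$dz)),
    n_singletons = length(lay$singles),
    method = "liability_threshold"
  ), class = "varcomp_fit")
}

#' Bivariate continuous-binary ACE fit with genetic correlation
#'
#' Joint maximum-likelihood fit of a continuous trait and the latent
#' liability of a dichotomous trait. Cross-twin cross-trait covariances are
#' `rg*aX*aY + rc*cX*cY` for MZ and `rg*aX*aY/2 + rc*cX*cY` for DZ pairs
#' (`aX = sqrt(a2_X)` etc.); the within-person cross-trait covariance adds
#' `re*eX*eY`. The pair likelihood factorizes exactly as (bivariate normal
#' density of the continuous pair) x (conditional bivariate orthant
#' probability of the binary pair), i.e. analytic conditioning, no
#' quadrature.
#'
#' @inheritParams fit_ace_univariate
#' @param trait_cont continuous trait vector.
#' @param trait_bin 0/1 trait vector.
#' @return object of class `varcomp_fit` with elements `rg`, `rc`, `re`,
#'   per-trait fractions `a2_cont`/`a2_bin` (etc.) and delta-method SEs.
#'   When a component variance is (near) zero for either trait the
#'   corresponding correlation is reported `NA` with `identified = FALSE`.
#' @export
fit_bivariate <- function(trait_cont, trait_bin, cohort, covariates = NULL,
                          n_starts = 3, se = TRUE, tol = 1e-8) {
  n <- nrow(cohort)
  stopifnot(length(trait_cont) == n, length(trait_bin) == n,
            all(trait_bin %in% c(0, 1, NA)))
  Xc <- .covar_matrix(covariates, n)
  complete <- !is.na(trait_cont) & !is.na(trait_bin) & stats::complete.cases(Xc)
  lay <- .twin_layout(cohort, complete)
  for (z in c("mz", "dz"))
    if (nrow(lay[[z]]) < 20)
      stop(sprintf("need >= 20 complete %s pairs, have %d",
                   toupper(z), nrow(lay[[z]])))
  y <- trait_cont; d <- trait_bin
  X <- cbind(`(Intercept)` = 1, Xc)
  p <- ncol(X); q <- ncol(Xc)
  # parameter layout:
  # beta_x (p), log_s2, tax, tcx, tau, gamma (q), tad, tcd, zg, zc, ze
  i_logs2 <- p + 1; i_tax <- p + 2; i_tcx <- p + 3; i_tau <- p + 4
  i_gam <- if (q) p + 4 + seq_len(q) else integer(0)
  i_tad <- p + q + 5; i_tcd <- p + q + 6
  i_zg <- p + q + 7; i_zc <- p + q + 8; i_ze <- p + q + 9

  nll <- function(par) {
    beta <- par[seq_len(p)]
    s <- exp(par[i_logs2] / 2)
    aX <- softmax_ace(par[i_tax], par[i_tcx])
    aD <- softmax_ace(par[i_tad], par[i_tcd])
    rg <- tanh(par[i_zg]); rc <- tanh(par[i_zc]); re <- tanh(par[i_ze])
    tau <- par[i_tau]
    gamma <- if (q) par[i_gam] else numeric(0)
    sq <- sqrt
    rw <- rg * sq(aX[1] * aD[1]) + rc * sq(aX[2] * aD[2]) + re * sq(aX[3] * aD[3])
    e <- (y - drop(X %*% beta)) / s
    th <- rep(tau, n) + (if (q) drop(Xc %*% gamma) else 0)
    ll <- 0
    for (z in c("mz", "dz")) {
      pr <- lay[[z]]
      if (!nrow(pr)) next
      kz <- if (z == "mz") 1 else 0.5
      rX <- min(if (z == "mz") aX[1] + aX[2] else aX[1] / 2 + aX[2], 1 - 1e-10)
      rD <- min(if (z == "mz") aD[1] + aD[2] else aD[1] / 2 + aD[2], 1 - 1e-10)
      rx <- kz * rg * sq(aX[1] * aD[1]) + rc * sq(aX[2] * aD[2])
      e1 <- e[pr[, 1]]; e2 <- e[pr[, 2]]
      ll <- ll + sum(-log(2 * pi) - 0.5 * log(1 - rX^2) -
                       (e1^2 + e2^2 - 2 * rX * e1 * e2) / (2 * (1 - rX^2)) -
                       2 * log(s))
      k1 <- (rw - rx * rX) / (1 - rX^2)
      k2 <- (rx - rw * rX) / (1 - rX^2)
      m1 <- k1 * e1 + k2 * e2
      m2 <- k2 * e1 + k1 * e2
      c11 <- 1 - (k1 * rw + k2 * rx)
      c12 <- rD - (k1 * rx + k2 * rw)
      if (c11 < 1e-8) return(1e10)
      rC <- max(min(c12 / c11, 1 - 1e-10), -1 + 1e-10)
      t1 <- (th[pr[, 1]] - m1) / sq(c11)
      t2 <- (th[pr[, 2]] - m2) / sq(c11)
      ll <- ll + sum(log(pair_orthant_prob(d[pr[, 1]], d[pr[, 2]], t1, t2, rC)))
    }
    if (length(lay$singles)) {
      i <- lay$singles
      ll <- ll + sum(stats::dnorm(e[i], log = TRUE) - log(s))
      cv <- 1 - rw^2
      if (cv < 1e-8) return(1e10)
      t1 <- (th[i] - rw * e[i]) / sq(cv)
      p1 <- pnorm(t1, lower.tail = FALSE)
      ll <- ll + sum(log(pmax(ifelse(d[i] == 1, p1, 1 - p1), 1e-300)))
    }
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  # starting values from the marginal fits
  ux <- fit_ace_univariate(y, cohort, covariates, n_starts = 1, se = FALSE, tol = tol)
  ud <- fit_liability_threshold(d, cohort, covariates, n_starts = 1, se = FALSE, tol = tol)
  start <- numeric(p + q + 9)
  start[seq_len(p)] <- ux$beta
  start[i_logs2] <- log(ux$sigma2)
  start[c(i_tax, i_tcx)] <- softmax_ace_inv(ux$a2, ux$c2)
  start[i_tau] <- ud$threshold
  if (q) start[i_gam] <- ud$beta
  start[c(i_tad, i_tcd)] <- softmax_ace_inv(ud$a2, ud$c2)
  start[c(i_zg, i_zc, i_ze)] <- c(atanh(0.4), 0, 0)

  jidx <- c(i_zg, i_zc, i_ze)
  best <- .optimize_ml(nll, start, .start_offsets(n_starts, 3), jidx, tol)
  par <- best$par
  aX <- softmax_ace(par[i_tax], par[i_tcx])
  aD <- softmax_ace(par[i_tad], par[i_tcd])
  rg <- tanh(par[i_zg]); rc <- tanh(par[i_zc]); re <- tanh(par[i_ze])
  ident <- c(rg = aX[1] > 0.01 && aD[1] > 0.01,
             rc = aX[2] > 0.01 && aD[2] > 0.01,
             re = aX[3] > 0.01 && aD[3] > 0.01)

  report <- function(pp) {
    ax <- softmax_ace(pp[i_tax], pp[i_tcx])
    ad <- softmax_ace(pp[i_tad], pp[i_tcd])
    c(a2_cont = unname(ax[1]), c2_cont = unname(ax[2]), e2_cont = unname(ax[3]),
      a2_bin = unname(ad[1]), c2_bin = unname(ad[2]), e2_bin = unname(ad[3]),
      rg = tanh(pp[i_zg]), rc = tanh(pp[i_zc]), re = tanh(pp[i_ze]),
      threshold = pp[i_tau])
  }
  ses <- rep(NA_real_, 10)
  names(ses) <- c("a2_cont", "c2_cont", "e2_cont", "a2_bin", "c2_bin",
                  "e2_bin", "rg", "rc", "re", "threshold")
  if (se) {
    V <- .fit_vcov(nll, par)
    if (!is.null(V)) ses <- .delta_se(par, V, report)
  }
  structure(list(
    a2 = unname(aX[1]), c2 = unname(aX[2]), e2 = unname(aX[3]),
    a2_cont = unname(aX[1]), c2_cont = unname(aX[2]), e2_cont = unname(aX[3]),
    a2_bin = unname(aD[1]), c2_bin = unname(aD[2]), e2_bin = unname(aD[3]),
    sigma2 = exp(par[i_logs2]),
    beta = stats::setNames(par[seq_len(p)], colnames(X)),
    threshold = par[i_tau],
    rg = if (ident["rg"]) rg else NA_real_,
    rc = if (ident["rc"]) rc else NA_real_,
    re = if (ident["re"]) re else NA_real_,
    identified = ident,
    se = ses,
    loglik = -best$objective,
    converged = best$convergence == 0,
    boundary = aX[1] < 0.005 || aD[1] < 0.005,
    n_pairs_used = c(MZ = nrow(lay$mz), DZ = nrow(lay$dz)),
    n_singletons = length(lay$singles),
    method = "ace_bivariate"
  ), class = "varcomp_fit")
}

#' @export
print.varcomp_fit <- function(x, ...) {
  cat("ACE fit (", x$method, ")\n", sep = "")
  cat(sprintf("  a2 = %.3f  c2 = %.3f  e2 = %.3f\n", x$a2, x$c2, x$e2))
  if (x$method == "ace_bivariate")
    cat(sprintf("  binary trait: a2 = %.3f  c2 = %.3f  e2 = %.3f\n",
                x$a2_bin, x$c2_bin, x$e2_bin),
        sprintf("  rg = %.3f  rc = %.3f  re = %.3f\n",
                x$rg, x$rc, x$re))
  if (!is.na(x$threshold))
    cat(sprintf("  threshold = %.3f\n", x$threshold))
  cat(sprintf("  loglik = %.2f  converged = %s\n", x$loglik, x$converged))
  cat("  pairs used: MZ", x$n_pairs_used["MZ"], " DZ", x$n_pairs_used["DZ"],
      " singles", x$n_singletons, "\n")
  invisible(x)
}
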