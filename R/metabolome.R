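#' Median- then inverse-normalize a metabolite matrix
#'
#' Each metabolite is first divided by its run-day median (removing daily
#' fluctuations of the assay), then transformed to rank-normal scores with
#' the Blom offset `c = 3/8`: `qnorm((rank - 3/8) / (n + 1/4))`, using
#' midranks for ties. Missing values stay missing; a run-day in which a
#' metabolite is entirely missing (or has median zero) stays missing for
#' that day.
#'
#' @param raw numeric matrix, individuals x metabolites.
#' @param run_day vector of run-day labels, one per individual.
#' @return matrix of the same shape with normalized values.
#' @export
normalize_metabolites <- function(raw, run_day) {
  raw <- as.matrix(raw)
  stopifnot(length(run_day) == nrow(raw))
  out <- raw
  for (day in unique(run_day)) {
    i <- run_day == day
    med <- apply(raw[i, , drop = FALSE], 2, stats::median, na.rm = TRUE)
    med[!is.na(med) & med == 0] <- NA_real_
    out[i, ] <- sweep(raw[i, , drop = FALSE], 2, med, `/`)
  }
  out <- apply(out, 2, inverse_normal)
  dimnames(out) <- dimnames(raw)
  out
}

#' Filter metabolites on missingness and identity
#'
#' Removes metabolites with a missing fraction strictly greater than
#' `max_missing` and, optionally, metabolites of unknown chemical identity.
#'
#' @param mat metabolite matrix (individuals x metabolites).
#' @param info data frame with columns `metabolite` and logical `known`.
#' @param max_missing maximum tolerated missing fraction (strict inequality).
#' @param drop_unknown drop metabolites flagged unknown.
#' @return list with the filtered `matrix` and a `removed` data frame
#'   (metabolite, reason).
#' @export
filter_metabolites <- function(mat, info, max_missing = 0.20,
                               drop_unknown = TRUE) {
  mat <- as.matrix(mat)
  stopifnot(all(colnames(mat) %in% info$metabolite))
  known <- info$known[match(colnames(mat), info$metabolite)]
  miss <- colMeans(is.na(mat))
  drop_miss <- miss > max_missing
  drop_unk <- drop_unknown & !known
  removed <- data.frame(
    metabolite = colnames(mat)[drop_miss | drop_unk],
    reason = ifelse(drop_miss[drop_miss | drop_unk], "missingness", "unknown_identity")
  )
  keep <- !(drop_miss | drop_unk)
  if (!any(keep)) stop("no metabolites left after filtering")
  list(matrix = mat[, keep, drop = FALSE], removed = removed)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up FDR adjustment with monotonicity enforcement.
#'
#' @param pvals numeric vector of p-values in (0, 1].
#' @return vector of BH-adjusted values, same order as input.
#' @export
bh_fdr <- function(pvals) {
  stopifnot(all(is.na(pvals) | (pvals > 0 & pvals <= 1)))
  stats::p.adjust(pvals, method = "BH")
}

# Least-squares fit of y ~ x + covars returning the x coefficient row.
.ls_assoc <- function(y, x, covars = NULL) {
  ok <- !is.na(y) & !is.na(x)
  if (!is.null(covars)) ok <- ok & stats::complete.cases(covars)
  n <- sum(ok)
  X <- cbind(1, x[ok], if (!is.null(covars)) as.matrix(covars)[ok, , drop = FALSE])
  if (qr(X)$rank < ncol(X)) return(NULL)
  fit <- stats::lm.fit(X, y[ok])
  rss <- sum(fit$residuals^2)
  df <- n - ncol(X)
  s2 <- rss / df
  XtXinv <- chol2inv(qr.R(fit$qr))
  se <- sqrt(s2 * XtXinv[2, 2])
  beta <- fit$coefficients[2]
  tstat <- beta / se
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  c(beta = unname(beta), se = unname(se), statistic = unname(tstat),
    p = max(unname(p), 1e-300), n = n)
}

#' Screen each metabolite against the Frailty Index
#'
#' Per metabolite, fits `FI ~ metabolite + age` by least squares (the
#' metabolite standardized to unit SD, so effects are per SD), takes the
#' two-sided p-value of the metabolite coefficient, and BH-adjusts across
#' all tested metabolites. Metabolites with fewer than `min_n` complete
#' observations or a degenerate (constant) distribution are skipped with a
#' warning.
#'
#' @param fi data frame from [compute_fi()] (or any `individual_id`/`fi`).
#' @param metabolites normalized metabolite matrix with individual rownames.
#' @param age numeric vector named by (or aligned with) the metabolite rows.
#' @param min_n minimum complete observations per metabolite.
#' @return data frame (class `assoc_result`): `feature`, `beta`, `se`,
#'   `statistic`, `p`, `q`, `direction`, `n`.
#' @export
single_metabolite_scan <- function(fi, metabolites, age, min_n = 30) {
  metabolites <- as.matrix(metabolites)
  ids <- rownames(metabolites)
  y <- fi$fi[match(ids, fi$individual_id)]
  stopifnot(length(age) == length(y))
  rows <- lapply(colnames(metabolites), function(m) {
    x <- metabolites[, m]
    if (sum(!is.na(x) & !is.na(y)) < min_n) return(NULL)
    sdx <- stats::sd(x, na.rm = TRUE)
    if (!is.finite(sdx) || sdx == 0) return(NULL)
    r <- .ls_assoc(y, x / sdx, cbind(age = age))
    if (is.null(r)) return(NULL)
    data.frame(feature = m, t(r))
  })
  skipped <- colnames(metabolites)[vapply(rows, is.null, TRUE)]
  if (length(skipped))
    warning("skipped ", length(skipped), " metabolite(s): ",
            paste(utils::head(skipped, 5), collapse = ", "),
            if (length(skipped) > 5) ", ...")
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  out$q <- bh_fdr(out$p)
  out$direction <- sign(out$beta)
  class(out) <- c("assoc_result", class(out))
  out
}

#' Joint multivariable model of FI on selected metabolites
#'
#' Fits FI on all selected metabolites plus covariates in two variants:
#' ordinary least squares, and generalized least squares with a family-level
#' random intercept (via `lme4::lmer`) to account for the familial
#' clustering of twins. Reports both coefficient tables, which metabolites
#' remain significant at `alpha` in each variant, the design condition
#' number, and warns on near-collinear metabolite pairs (`|r| > 0.99`).
#'
#' @param fi data frame with `individual_id`, `fi`.
#' @param metabolites normalized metabolite matrix restricted (by the
#'   caller) to the selected metabolites.
#' @param covariates matrix/data frame of covariates aligned to the
#'   metabolite rows (e.g. age, relative fat mass).
#' @param cohort cohort data frame providing `family_id`.
#' @param alpha significance level for the "stays significant" report.
#' @return list of class `multivar_fit`: `ols`, `gls` (coefficient tables),
#'   `significant_ols`, `significant_gls`, `condition_number`, `n`.
#' @export
multivariable_selection <- function(fi, metabolites, covariates, cohort,
                                    alpha = 0.05) {
  metabolites <- as.matrix(metabolites)
  if (!ncol(metabolites)) stop("selected metabolite set is empty")
  ids <- rownames(metabolites)
  y <- fi$fi[match(ids, fi$individual_id)]
  fam <- cohort$family_id[match(ids, cohort$individual_id)]
  Xc <- as.matrix(as.data.frame(covariates))
  dat <- data.frame(y = y, metabolites, Xc, fam = fam, check.names = FALSE)
  dat <- dat[stats::complete.cases(dat), ]
  mm <- as.matrix(dat[, colnames(metabolites), drop = FALSE])
  if (ncol(mm) > 1) {
    cm <- stats::cor(mm)
    hi <- which(abs(cm) > 0.99 & upper.tri(cm), arr.ind = TRUE)
    if (nrow(hi))
      warning("near-collinear metabolite pair(s): ",
              paste(colnames(mm)[hi[, 1]], colnames(mm)[hi[, 2]],
                    sep = " ~ ", collapse = ", "))
  }
  preds <- c(colnames(metabolites), colnames(Xc))
  form <- stats::reformulate(sprintf("`%s`", preds), response = "y")
  ols <- stats::lm(form, data = dat)
  cond <- kappa(stats::model.matrix(ols), exact = TRUE)
  ols_tab <- summary(ols)$coefficients
  form_g <- stats::update(form, . ~ . + (1 | fam))
  gls <- lme4::lmer(form_g, data = dat, REML = TRUE)
  gt <- summary(gls)$coefficients
  # Wald z p-values for the mixed model (large-sample; df in the thousands)
  gls_tab <- cbind(gt, p = 2 * pnorm(abs(gt[, "t value"]), lower.tail = FALSE))
  sig <- function(tab, pcol) {
    rn <- gsub("`", "", rownames(tab))
    rn[rn %in% colnames(metabolites) & tab[, pcol] < alpha]
  }
  structure(list(
    ols = ols_tab, gls = gls_tab,
    significant_ols = sig(ols_tab, "Pr(>|t|)"),
    significant_gls = sig(gls_tab, "p"),
    condition_number = cond,
    family_variance = as.data.frame(lme4::VarCorr(gls))$vcov[1],
    n = nrow(dat), alpha = alpha
  ), class = "multivar_fit")
}
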