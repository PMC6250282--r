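# Two-stage path analysis: covariates -> CWP liability (probit), then
# CWP status + covariates (+ metabolites) -> FI, with direct/indirect
# decomposition via the product of coefficients.

#' Stage 1: probit regression of CWP on covariates
#'
#' Liability-scale (probit) regression of CWP status on the candidate
#' covariates (age, smoking, relative fat mass, selected metabolites,
#' leading SNP dosages). A logit link is available behind `link`.
#' Quasi-separation (absurdly large coefficients or non-convergence) flags
#' the fit rather than erroring.
#'
#' @param cwp 0/1 vector.
#' @param covariates matrix/data frame of predictors (one row per
#'   individual).
#' @param link `"probit"` (default) or `"logit"`.
#' @return list of class `stage_fit`: `coefficients` (term, estimate, se,
#'   statistic, p), `fitted`, `converged`, `separation`, `n`, `model`.
#' @export
fit_cwp_stage <- function(cwp, covariates, link = "probit") {
  X <- as.data.frame(covariates)
  stopifnot(all(cwp %in% c(0, 1, NA)))
  dat <- data.frame(.cwp = cwp, X, check.names = FALSE)
  dat <- dat[stats::complete.cases(dat), ]
  if (length(unique(dat$.cwp)) < 2) stop("both CWP classes must be present")
  form <- stats::reformulate(sprintf("`%s`", names(X)), response = ".cwp")
  fit <- suppressWarnings(stats::glm(form, data = dat,
                                     family = stats::binomial(link = link)))
  tab <- summary(fit)$coefficients
  sep <- !fit$converged || any(abs(tab[, "Estimate"]) > 8 & tab[, "Std. Error"] > 10)
  coefs <- data.frame(term = gsub("`", "", rownames(tab)),
                      estimate = tab[, 1], se = tab[, 2],
                      statistic = tab[, 3], p = tab[, 4], row.names = NULL)
  structure(list(coefficients = coefs, fitted = stats::fitted(fit),
                 converged = fit$converged, separation = sep,
                 n = nrow(dat), model = fit, link = link,
                 ids = rownames(dat)),
            class = "stage_fit")
}

#' Stage 2: linear model of FI on CWP status and covariates
#'
#' Least-squares (optionally family-random-intercept) regression of the FI
#' score on CWP status, covariates and any selected metabolites. Warns on
#' near-collinear predictor pairs as in the multivariable metabolite model.
#'
#' @param fi numeric FI vector.
#' @param cwp 0/1 CWP status.
#' @param covariates matrix/data frame of further predictors.
#' @param family_id optional family ids; when given, a family random
#'   intercept is fitted via `lme4::lmer` and Wald z p-values reported.
#' @return list of class `stage_fit` with a `coefficients` table as in
#'   [fit_cwp_stage()].
#' @export
fit_fi_stage <- function(fi, cwp, covariates, family_id = NULL) {
  X <- as.data.frame(covariates)
  dat <- data.frame(.fi = fi, cwp = cwp, X, check.names = FALSE)
  has_fam <- !is.null(family_id)
  if (has_fam) dat$.fam <- family_id
  dat <- dat[stats::complete.cases(dat), ]
  preds <- as.matrix(dat[, c("cwp", names(X)), drop = FALSE])
  if (ncol(preds) > 1) {
    cm <- suppressWarnings(stats::cor(preds))
    hi <- which(abs(cm) > 0.99 & upper.tri(cm), arr.ind = TRUE)
    if (nrow(hi))
      warning("near-collinear predictor pair(s): ",
              paste(colnames(preds)[hi[, 1]], colnames(preds)[hi[, 2]],
                    sep = " ~ ", collapse = ", "))
  }
  form <- stats::reformulate(sprintf("`%s`", c("cwp", names(X))), response = ".fi")
  if (has_fam) {
    fit <- lme4::lmer(stats::update(form, . ~ . + (1 | .fam)), data = dat, REML = TRUE)
    tab <- summary(fit)$coefficients
    p <- 2 * pnorm(abs(tab[, "t value"]), lower.tail = FALSE)
    coefs <- data.frame(term = gsub("`", "", rownames(tab)),
                        estimate = tab[, 1], se = tab[, 2],
                        statistic = tab[, 3], p = p, row.names = NULL)
  } else {
    fit <- stats::lm(form, data = dat)
    tab <- summary(fit)$coefficients
    coefs <- data.frame(term = gsub("`", "", rownames(tab)),
                        estimate = tab[, 1], se = tab[, 2],
                        statistic = tab[, 3], p = tab[, 4], row.names = NULL)
  }
  structure(list(coefficients = coefs, converged = TRUE, separation = FALSE,
                 n = nrow(dat), model = fit, ids = rownames(dat)),
            class = "stage_fit")
}

#' Direct, indirect and total effects from the two stages
#'
#' For each covariate present in both stages, the indirect effect on FI via
#' CWP is the product of its stage-1 coefficient (effect on CWP liability)
#' and the stage-2 CWP coefficient (effect of CWP on FI); the delta-method
#' SE is `sqrt(b^2 se_a^2 + a^2 se_b^2)`; the total effect is direct +
#' indirect. Note the stage-1 coefficients live on the probit liability
#' scale, so the indirect effect is in (liability SD) x (FI per CWP status)
#' units.
#'
#' @param stage1 `stage_fit` from [fit_cwp_stage()].
#' @param stage2 `stage_fit` from [fit_fi_stage()].
#' @return data frame of class `path_effects`: `term`, `direct`,
#'   `direct_se`, `indirect`, `indirect_se`, `total`, `total_se`.
#' @export
decompose_effects <- function(stage1, stage2) {
  if (stage1$n != stage2$n)
    stop("stage-1 and stage-2 samples differ (", stage1$n, " vs ", stage2$n,
         " observations); fit both stages on the same individuals")
  s1 <- stage1$coefficients
  s2 <- stage2$coefficients
  bcwp <- s2[s2$term == "cwp", ]
  if (!nrow(bcwp)) stop("stage 2 has no CWP term")
  terms <- setdiff(intersect(s1$term, s2$term), "(Intercept)")
  out <- do.call(rbind, lapply(terms, function(tm) {
    a <- s1[s1$term == tm, ]
    dd <- s2[s2$term == tm, ]
    ind <- a$estimate * bcwp$estimate
    ind_se <- sqrt(bcwp$estimate^2 * a$se^2 + a$estimate^2 * bcwp$se^2)
    data.frame(term = tm,
               direct = dd$estimate, direct_se = dd$se,
               indirect = ind, indirect_se = ind_se,
               total = dd$estimate + ind,
               total_se = sqrt(dd$se^2 + ind_se^2))
  }))
  attr(out, "cwp_effect") <- bcwp$estimate
  attr(out, "cwp_effect_se") <- bcwp$se
  class(out) <- c("path_effects", class(out))
  out
}

#' Full two-stage path analysis
#'
#' Convenience wrapper: fits the CWP stage on the covariates, the FI stage
#' on CWP plus the same covariates, and decomposes direct/indirect/total
#' effects, using the common complete-case sample for both stages.
#'
#' @param fi numeric FI vector.
#' @param cwp 0/1 CWP status.
#' @param covariates matrix/data frame of covariates (may include selected
#'   metabolites and SNP dosages).
#' @param family_id optional family ids for a stage-2 random intercept.
#' @param link stage-1 link function.
#' @return list of class `path_fit`: `stage1`, `stage2`, `effects`.
#' @export
fit_path <- function(fi, cwp, covariates, family_id = NULL, link = "probit") {
  X <- as.data.frame(covariates)
  keep <- stats::complete.cases(data.frame(fi = fi, cwp = cwp, X))
  X <- X[keep, , drop = FALSE]
  s1 <- fit_cwp_stage(cwp[keep], X, link = link)
  s2 <- fit_fi_stage(fi[keep], cwp[keep], X,
                     family_id = if (!is.null(family_id)) family_id[keep])
  eff <- decompose_effects(s1, s2)
  structure(list(stage1 = s1, stage2 = s2, effects = eff),
            class = "path_fit")
}

#' @export
print.path_fit <- function(x, ...) {
  cat("Two-stage path analysis (", x$stage1$link, " stage 1, n = ",
      x$stage1$n, ")\n", sep = "")
  cat(sprintf("CWP -> FI effect: %.4f (se %.4f)\n",
              attr(x$effects, "cwp_effect"), attr(x$effects, "cwp_effect_se")))
  print(as.data.frame(x$effects), digits = 4)
  invisible(x)
}
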