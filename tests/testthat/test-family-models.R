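# Oracles used here:
#  - Falconer closed form a2 = 2(rMZ - rDZ), c2 = 2 rDZ - rMZ on data built
#    with exact sample correlations;
#  - an independent likelihood evaluator written below, used to verify the
#    ML solution dominates the generating parameters;
#  - a brute-force grid search over the orthant-probability likelihood for
#    the liability-threshold model.

# independent univariate ACE log-likelihood at given (a2, c2, mu, s2),
# complete pairs only
ace_loglik_oracle <- function(y, cohort, a2, c2, mu = 0, s2 = 1) {
  ll <- 0
  for (z in c("MZ", "DZ")) {
    r <- if (z == "MZ") a2 + c2 else a2 / 2 + c2
    m <- matrix(y[cohort$zygosity == z], ncol = 2, byrow = TRUE)
    S <- s2 * matrix(c(1, r, r, 1), 2)
    Sinv <- solve(S)
    e <- cbind(m[, 1] - mu, m[, 2] - mu)
    ll <- ll + sum(-log(2 * pi) - 0.5 * log(det(S)) -
                     0.5 * rowSums((e %*% Sinv) * e))
  }
  s <- cohort$zygosity == "singleton"
  if (any(s)) ll <- ll + sum(dnorm(y[s], mu, sqrt(s2), log = TRUE))
  ll
}

test_that("ACE estimates agree with the Falconer closed form on exact correlations", {
  skip_if_not_installed("MASS")
  co <- make_cohort_frame(600, 600)
  y <- trait_with_pair_cor(co, r_mz = 0.8, r_dz = 0.5, seed = 11)
  fit <- fit_ace_univariate(y, co)
  expect_true(fit$converged)
  expect_equal(fit$a2, 0.6, tolerance = 0.02 / 0.6)
  expect_equal(fit$c2, 0.2, tolerance = 0.02 / 0.2)
})

test_that("a trait with no familial structure yields near-zero A and C", {
  co <- make_cohort_frame(400, 400, 100)
  set.seed(3)
  y <- rnorm(nrow(co))
  fit <- fit_ace_univariate(y, co)
  expect_lt(fit$a2, 0.08)
  expect_lt(fit$c2, 0.08)
  expect_true(fit$boundary)
})

test_that("the ML solution dominates the generating parameters and is invariant to twin order", {
  co <- make_cohort_frame(300, 300)
  y <- ace_trait(co, a2 = 0.5, c2 = 0.2, seed = 21)
  fit <- fit_ace_univariate(y, co)
  expect_gte(fit$loglik + 1e-6,
             ace_loglik_oracle(y, co, 0.5, 0.2, mu = 0, s2 = 1))

  # swap twins within every pair
  swap <- unlist(lapply(seq(1, nrow(co), by = 2), function(i) c(i + 1, i)))
  fit2 <- fit_ace_univariate(y[swap], co)
  expect_equal(fit2$a2, fit$a2, tolerance = 1e-5)
  expect_equal(fit2$loglik, fit$loglik, tolerance = 1e-8)
})

test_that("covariates are absorbed into the mean structure", {
  co <- make_cohort_frame(300, 300)
  set.seed(4)
  x <- rnorm(nrow(co))
  y <- ace_trait(co, 0.4, 0.2, seed = 5) + 2 * x
  fit <- fit_ace_univariate(y, co, cbind(x = x))
  expect_equal(unname(fit$beta["x"]), 2, tolerance = 0.05)
  expect_equal(fit$a2, 0.4, tolerance = 0.35)  # 600 pairs: sampling noise
  expect_lt(abs(fit$a2 - 0.4), 3 * fit$se["a2"] + 0.02)
})

test_that("liability-threshold fit recovers the threshold at 50% prevalence", {
  co <- make_cohort_frame(400, 400)
  y <- ace_trait(co, 0.4, 0.2, seed = 31)
  d <- as.integer(y > 0)
  fit <- fit_liability_threshold(d, co)
  expect_true(fit$converged)
  expect_lt(abs(fit$threshold), 0.08)
})

test_that("independent binary responses give near-zero tetrachoric components", {
  co <- make_cohort_frame(500, 500)
  set.seed(41)
  d <- rbinom(nrow(co), 1, 0.3)
  fit <- fit_liability_threshold(d, co)
  expect_lt(fit$a2 + fit$c2, 0.1)
})

test_that("liability fit matches a grid search over the orthant likelihood", {
  # concordance data simulated from a single tetrachoric correlation, with
  # a2 free and c2 pinned by fitting MZ-only structure against the grid
  co <- make_cohort_frame(1500, 1500)
  y <- ace_trait(co, 0.6, 0.1, seed = 51)
  d <- as.integer(y > qnorm(0.7))
  fit <- fit_liability_threshold(d, co, n_starts = 3)

  # oracle: profile the exact pair likelihood over (a2, c2, tau) on a grid
  lik <- function(a2, c2, tau) {
    ll <- 0
    for (z in c("MZ", "DZ")) {
      r <- if (z == "MZ") a2 + c2 else a2 / 2 + c2
      m <- matrix(d[co$zygosity == z], ncol = 2, byrow = TRUE)
      pr <- frailtyomics:::pair_orthant_prob(m[, 1], m[, 2],
                                             rep(tau, nrow(m)),
                                             rep(tau, nrow(m)), r)
      ll <- ll + sum(log(pr))
    }
    ll
  }
  grid <- expand.grid(a2 = seq(0, 0.9, 0.05), c2 = seq(0, 0.5, 0.05),
                      tau = seq(0.3, 0.8, 0.025))
  grid <- grid[grid$a2 + grid$c2 < 1, ]
  ll <- mapply(lik, grid$a2, grid$c2, grid$tau)
  best <- grid[which.max(ll), ]
  expect_lt(abs(fit$a2 - best$a2), 0.051)
  expect_lt(abs(fit$threshold - best$tau), 0.026)
  expect_gte(fit$loglik + 1e-6, max(ll))  # ML at least as good as the grid
})

test_that("thresholding the continuous trait's own liability gives rg near 1", {
  co <- make_cohort_frame(500, 500)
  y <- ace_trait(co, 0.5, 0.2, seed = 61)
  d <- as.integer(y + 0.3 * rnorm(length(y)) > qnorm(0.7))
  fit <- fit_bivariate(y, d, co, n_starts = 2)
  expect_gt(fit$rg, 0.85)
})

test_that("independent traits give rg within 3 SEs of zero", {
  co <- make_cohort_frame(600, 600)
  y <- ace_trait(co, 0.5, 0.1, seed = 71)
  d2_liab <- ace_trait(co, 0.5, 0.1, seed = 72)  # independent draw
  d <- as.integer(d2_liab > qnorm(0.75))
  fit <- fit_bivariate(y, d, co, n_starts = 2)
  expect_lt(abs(fit$rg), 3 * fit$se["rg"] + 0.02)
})

test_that("bivariate margins agree with the univariate fits", {
  co <- make_cohort_frame(500, 500)
  sim <- simulate_cohort(cohort_config(
    n_mz_pairs = 500, n_dz_pairs = 500, n_singletons = 0,
    n_metabolites = 2, n_unknown_metabolites = 0, n_snps = 0, n_bins = 0,
    n_genes = 0, seed = 81))
  cc <- sim$cohort
  X <- cbind(age = cc$age, fat = cc$fat_h2, smoking = cc$smoking)
  biv <- fit_bivariate(cc$fi_liability, cc$cwp_status, cc, X, n_starts = 1)
  uni <- fit_ace_univariate(cc$fi_liability, cc, X, n_starts = 1)
  # the continuous-binary likelihood does not factorize exactly, so joint
  # margins can differ slightly from the marginal ML fit
  expect_lt(abs(biv$a2_cont - uni$a2), 0.05)
  expect_lt(abs(biv$c2_cont - uni$c2), 0.05)
})

test_that("Wald intervals for rg have near-nominal coverage", {
  # 200 replicates at 500 pairs per zygosity; truth rg = 0.6
  hits <- 0L
  n_ok <- 0L
  for (rep in 1:200) {
    cfg <- cohort_config(n_mz_pairs = 500, n_dz_pairs = 500, n_singletons = 0,
                         a2_fi = 0.5, c2_fi = 0.1, a2_cwp = 0.5, c2_cwp = 0.1,
                         rg = 0.6, rc = 0.2, re = 0.1, cwp_prevalence = 0.3,
                         n_metabolites = 2, n_unknown_metabolites = 0,
                         n_snps = 0, n_bins = 0, n_genes = 0,
                         beta_age_fi = 0, beta_fat_fi = 0, beta_smoking_fi = 0,
                         beta_age_cwp = 0, beta_fat_cwp = 0, beta_smoking_cwp = 0,
                         seed = 1000 + rep)
    s <- simulate_cohort(cfg)
    fit <- tryCatch(
      fit_bivariate(s$cohort$fi_liability, s$cohort$cwp_status, s$cohort,
                    n_starts = 1),
      error = function(e) NULL)
    if (is.null(fit) || is.na(fit$rg) || !is.finite(fit$se["rg"]) ||
        fit$se["rg"] == 0) next
    n_ok <- n_ok + 1L
    ci <- fit$rg + c(-1.96, 1.96) * fit$se["rg"]
    if (ci[1] <= 0.6 && 0.6 <= ci[2]) hits <- hits + 1L
  }
  expect_gt(n_ok, 180)
  coverage <- hits / n_ok
  expect_gte(coverage, 0.90)
  expect_lte(coverage, 0.98)
})

test_that("too few pairs or one-class groups raise informative errors", {
  co <- make_cohort_frame(10, 10)
  expect_error(fit_ace_univariate(rnorm(nrow(co)), co), ">= 20")
  co2 <- make_cohort_frame(50, 50)
  set.seed(1)
  d <- rep(0L, nrow(co2))  # every MZ individual unaffected
  d[co2$zygosity == "DZ"] <- rbinom(sum(co2$zygosity == "DZ"), 1, 0.5)
  expect_error(fit_liability_threshold(d, co2), "both outcome classes")
})
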