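test_that("run-day medians are removed and marginals are rank-normal", {
  # two run-days whose medians differ 2-fold: a sample at its day median
  # must receive the same normalized value on either day
  raw <- cbind(m1 = c(5, 10, 20, 10, 20, 40))
  rownames(raw) <- paste0("s", 1:6)
  day <- c(1, 1, 1, 2, 2, 2)
  z <- normalize_metabolites(raw, day)
  expect_equal(z[2], z[5])  # both at their day median
  expect_equal(z[1], z[4])
  expect_equal(z[3], z[6])

  set.seed(2)
  raw2 <- cbind(m = rlnorm(400))
  z2 <- normalize_metabolites(raw2, rep(1:4, each = 100))
  expect_equal(mean(z2), 0, tolerance = 1e-8)
  expect_equal(var(z2[, 1]), 1, tolerance = 0.02)

  # constant metabolite: all midranks map to the same (near-zero) score
  zc <- normalize_metabolites(cbind(k = rep(7, 10)), rep(1, 10))
  expect_true(all(zc == zc[1]))
  expect_equal(unname(zc[1]), qnorm((5.5 - 3 / 8) / 10.25))

  # missing values stay missing
  raw3 <- cbind(m = c(1, NA, 3, 4))
  expect_true(is.na(normalize_metabolites(raw3, rep(1, 4))[2]))
})

test_that("metabolite filtering uses strict missingness and identity rules", {
  set.seed(3)
  n <- 100
  mat <- matrix(rnorm(n * 4), n, 4,
                dimnames = list(NULL, paste0("met", 1:4)))
  mat[1:21, 1] <- NA   # 21% missing -> removed
  mat[1:20, 2] <- NA   # exactly 20% -> retained
  info <- data.frame(metabolite = paste0("met", 1:4),
                     known = c(TRUE, TRUE, TRUE, FALSE))
  f <- filter_metabolites(mat, info)
  expect_identical(colnames(f$matrix), c("met2", "met3"))
  expect_setequal(f$removed$metabolite, c("met1", "met4"))

  # 305 known + 103 unknown, no missingness -> 305 retained
  big <- matrix(rnorm(10 * 408), 10, 408,
                dimnames = list(NULL, paste0("m", 1:408)))
  info_big <- data.frame(metabolite = paste0("m", 1:408),
                         known = rep(c(TRUE, FALSE), c(305, 103)))
  expect_equal(ncol(filter_metabolites(big, info_big)$matrix), 305)
})

test_that("BH adjustment matches hand computation and a brute-force step-up rule", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.04), 0.04)

  brute_bh <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- p[o] * m / seq_len(m)
    q <- rev(cummin(rev(q)))
    pmin(q, 1)[order(o)]
  }
  set.seed(4)
  for (i in 1:200) {
    p <- runif(sample(1:40, 1))
    q <- bh_fdr(p)
    expect_equal(q, brute_bh(p))
    expect_true(all(q >= p))
  }
})

test_that("the single-metabolite scan matches a normal-equations oracle", {
  set.seed(5)
  n <- 200
  age <- runif(n, 20, 90)
  M <- matrix(rnorm(n * 10), n, 10,
              dimnames = list(sprintf("i%03d", 1:n), paste0("met", 1:10)))
  fi_val <- 0.25 - 0.1 * scale(M[, 3])[, 1] + 0.002 * age + rnorm(n, 0, 0.05)
  fi <- data.frame(individual_id = rownames(M), fi = fi_val)
  scan <- single_metabolite_scan(fi, M, age)
  expect_equal(nrow(scan), 10)
  for (m in c("met1", "met3", "met7")) {
    x <- M[, m] / sd(M[, m])
    X <- cbind(1, x, age)
    b <- solve(t(X) %*% X, t(X) %*% fi_val)
    r <- fi_val - X %*% b
    s2 <- sum(r^2) / (n - 3)
    se <- sqrt(s2 * solve(t(X) %*% X)[2, 2])
    row <- scan[scan$feature == m, ]
    expect_equal(row$beta, b[2], tolerance = 1e-10)
    expect_equal(row$se, se, tolerance = 1e-10)
  }
  expect_lt(scan$q[scan$feature == "met3"], 0.001)
  expect_equal(scan$direction[scan$feature == "met3"], -1)
})

test_that("null metabolites give uniform scan p-values", {
  set.seed(6)
  n <- 150
  M <- matrix(rnorm(n * 1000), n, 1000,
              dimnames = list(sprintf("i%03d", 1:n), paste0("met", 1:1000)))
  age <- runif(n, 20, 90)
  fi <- data.frame(individual_id = rownames(M), fi = runif(n, 0, 0.6))
  scan <- single_metabolite_scan(fi, M, age)
  expect_gt(ks.test(scan$p, "punif")$p.value, 0.01)
  expect_lte(mean(scan$q < 0.05), 0.05)
})

test_that("a metabolite identical to FI hits the underflow-guarded minimum", {
  set.seed(7)
  n <- 100
  fi_val <- scale(runif(n, 0, 0.6))[, 1]  # standardized so beta is 1
  M <- cbind(met1 = fi_val)
  rownames(M) <- sprintf("i%03d", 1:n)
  fi <- data.frame(individual_id = rownames(M), fi = fi_val)
  scan <- suppressWarnings(single_metabolite_scan(fi, M, rnorm(n)))
  expect_equal(scan$beta, 1, tolerance = 1e-10)
  expect_equal(scan$p, 1e-300)
})

test_that("only the planted metabolite survives the joint model across replicates", {
  hits_planted <- 0; false_hits <- 0
  for (r in 1:200) {
    set.seed(100 + r)
    n <- 300
    M <- matrix(rnorm(n * 5), n, 5,
                dimnames = list(sprintf("i%03d", 1:n), paste0("met", 1:5)))
    fam <- rep(sprintf("f%03d", 1:(n / 2)), each = 2)
    fi_val <- 0.3 - 0.05 * M[, 2] + rnorm(n, 0, 0.1)
    fi <- data.frame(individual_id = rownames(M), fi = fi_val)
    co <- data.frame(individual_id = rownames(M), family_id = fam)
    mv <- multivariable_selection(fi, M, cbind(age = rnorm(n)), co,
                                  alpha = 0.01)
    hits_planted <- hits_planted + ("met2" %in% mv$significant_ols)
    false_hits <- false_hits +
      length(setdiff(mv$significant_ols, "met2"))
  }
  expect_gte(hits_planted / 200, 0.95)
  expect_lte(false_hits / (200 * 4), 0.03)  # per-test level 0.01
})

test_that("family GLS equals OLS without clustering and widens SEs with it", {
  set.seed(8)
  n <- 400
  fam <- rep(sprintf("f%03d", 1:(n / 2)), each = 2)
  M <- cbind(met1 = rnorm(n))
  rownames(M) <- sprintf("i%03d", 1:n)
  co <- data.frame(individual_id = rownames(M), family_id = fam)
  # no family variance: GLS collapses to OLS
  fi0 <- data.frame(individual_id = rownames(M),
                    fi = 0.3 + 0.1 * M[, 1] + rnorm(n, 0, 0.1))
  mv0 <- multivariable_selection(fi0, M, cbind(age = rnorm(n)), co)
  expect_equal(unname(mv0$gls[, "Estimate"]), unname(mv0$ols[, "Estimate"]),
               tolerance = 1e-4)

  # strong family clustering + family-level predictor: GLS SEs larger on average
  wider <- 0
  for (r in 1:200) {
    set.seed(800 + r)
    u <- rep(rnorm(n / 2, 0, 0.3), each = 2)
    xf <- rep(rnorm(n / 2), each = 2)  # between-family predictor
    Mf <- cbind(met1 = xf)
    rownames(Mf) <- rownames(M)
    fi1 <- data.frame(individual_id = rownames(M),
                      fi = 0.3 + u + rnorm(n, 0, 0.1))
    mv1 <- multivariable_selection(fi1, Mf, cbind(age = rnorm(n)), co)
    wider <- wider + (mv1$gls["met1", "Std. Error"] >
                        mv1$ols["met1", "Std. Error"])
  }
  expect_gt(wider / 200, 0.9)
})
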