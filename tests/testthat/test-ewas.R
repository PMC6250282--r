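bin_matrix <- function(n, m, seed = 1) {
  set.seed(seed)
  matrix(rnorm(n * m), n, m,
         dimnames = list(sprintf("i%04d", seq_len(n)),
                         paste0("bin", seq_len(m))))
}

test_that("stability filter keeps reproducible bins and behaves like its null", {
  B1 <- bin_matrix(80, 400, seed = 21)
  B2 <- B1  # perfectly stable
  f <- ls_bin_filter(B1, B2)
  expect_setequal(f$retained, colnames(B1))

  # constant bin excluded with a flag
  B1c <- B1; B1c[, 1] <- 5
  B2c <- B1c
  fc <- ls_bin_filter(B1c, B2c)
  expect_identical(fc$degenerate, "bin1")
  expect_false("bin1" %in% fc$retained)

  # independent noise at both timepoints: retention rate near alpha/2
  B2n <- bin_matrix(80, 400, seed = 22)
  fn <- ls_bin_filter(B1, B2n, alpha = 0.05)
  rate <- length(fn$retained) / 400
  expect_lt(abs(rate - 0.025), 3 * sqrt(0.025 * 0.975 / 400))
})

test_that("stability filter sensitivity matches the correlation-test power formula", {
  # stable bins at autocorrelation rho: power of the two-sided test at alpha
  # from the Fisher-z approximation
  n <- 120; rho <- 0.6; alpha <- 0.05
  s <- simulate_cohort(cohort_config(
    n_mz_pairs = n / 2, n_dz_pairs = 0, n_singletons = 0,
    n_metabolites = 2, n_unknown_metabolites = 0, n_snps = 0,
    n_bins = 2000, n_genes = 0, stable_bin_fraction = 0.5,
    bin_autocorrelation = rho, seed = 23))
  f <- ls_bin_filter(s$bins_t1, s$bins_t2, alpha)
  stable <- s$truth$stable_bins
  unstable <- setdiff(colnames(s$bins_t1), stable)
  sens <- mean(stable %in% f$retained)
  spec <- mean(!unstable %in% f$retained)
  power <- 1 - pnorm(qnorm(1 - alpha / 2) - atanh(rho) * sqrt(n - 3))
  expect_lt(abs(sens - power), 3 * sqrt(power * (1 - power) / length(stable)) + 0.02)
  expect_lt(abs(spec - (1 - alpha / 2)),
            3 * sqrt(alpha / 2 * (1 - alpha / 2) / length(unstable)) + 0.01)
})

test_that("paired test matches t.test and handles degenerate bins by convention", {
  B <- bin_matrix(100, 50, seed = 24)
  pairs <- data.frame(family_id = sprintf("f%02d", 1:50),
                      id_high = rownames(B)[seq(1, 99, 2)],
                      id_low = rownames(B)[seq(2, 100, 2)])
  res <- paired_bin_test(B, pairs)
  for (j in c(3, 17, 42)) {
    d <- B[pairs$id_high, j] - B[pairs$id_low, j]
    tt <- t.test(d)
    row <- res[res$bin == paste0("bin", j), ]
    expect_equal(row$statistic, unname(tt$statistic), tolerance = 1e-12)
    expect_equal(row$p, tt$p.value, tolerance = 1e-12)
  }
  # identical methylation within every pair: p = 1, sign = 0
  Bz <- B
  Bz[pairs$id_low, 1] <- Bz[pairs$id_high, 1]
  rz <- paired_bin_test(Bz, pairs)
  expect_equal(rz$p[rz$bin == "bin1"], 1)
  expect_equal(rz$sign[rz$bin == "bin1"], 0)
})

test_that("a planted FI-associated bin shows the planted direction in most replicates", {
  ok_dir <- 0
  for (r in 1:40) {
    pe <- data.frame(feature = "bin1", layer = "bin", target = "fi",
                     effect = 0.5, mediated = FALSE)
    s <- simulate_cohort(cohort_config(
      n_mz_pairs = 120, n_dz_pairs = 0, n_singletons = 0,
      n_metabolites = 2, n_unknown_metabolites = 0, n_snps = 0,
      n_bins = 5, n_genes = 0, planted_effects = pe, seed = 3000 + r))
    fi <- compute_fi(s$deficits)
    pt <- pair_fi_table(fi, s$cohort)
    disc <- pair_discordance(pt$fi_high, pt$fi_low, pt$family_id)
    sel <- select_discordant_pairs(disc[!is.na(disc$d), ], 50)
    res <- paired_bin_test(s$bins_t1, pt[pt$family_id %in% sel, ])
    ok_dir <- ok_dir + (res$sign[res$bin == "bin1"] == 1)
  }
  expect_gte(ok_dir / 40, 0.95)
})

test_that("the Gr2 correlation scan matches cor.test and rejects overlap", {
  B <- bin_matrix(60, 20, seed = 25)
  fi <- data.frame(individual_id = rownames(B), fi = runif(60, 0, 0.5))
  gr2 <- rownames(B)[1:40]
  gr1 <- rownames(B)[41:60]
  res <- correlation_bin_scan(B, fi, gr2, gr1)
  for (j in c(2, 11)) {
    ct <- cor.test(B[gr2, j], fi$fi[1:40])
    row <- res[res$bin == paste0("bin", j), ]
    expect_equal(row$r, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(row$p, ct$p.value, tolerance = 1e-12)
  }
  expect_error(correlation_bin_scan(B, fi, rownames(B)[30:50], gr1),
               "overlap")
  # a bin equal to FI itself: r = 1, minimal p
  B2 <- B
  B2[, 1] <- fi$fi
  res2 <- correlation_bin_scan(B2, fi, gr2, gr1)
  expect_equal(res2$r[1], 1, tolerance = 1e-12)
  expect_lt(res2$p[1], 1e-200)
})

test_that("Fisher combination matches the chi-square oracle and is calibrated", {
  f0 <- fisher_combine(1, 1)
  expect_equal(f0$fisher_stat, 0)
  expect_equal(f0$p_combined, 1)

  f <- fisher_combine(0.05, 0.05)
  expect_equal(f$fisher_stat, -4 * log(0.05), tolerance = 1e-12)
  expect_equal(f$fisher_stat, 11.98293, tolerance = 1e-3)
  expect_equal(f$p_combined, pchisq(-4 * log(0.05), 4, lower.tail = FALSE),
               tolerance = 1e-10)

  # commutativity and monotonicity
  expect_equal(fisher_combine(0.01, 0.2), fisher_combine(0.2, 0.01))
  expect_lt(fisher_combine(0.01, 0.2)$p_combined,
            fisher_combine(0.02, 0.2)$p_combined)
  expect_error(fisher_combine(-0.1, 0.5), "0, 1")

  # uniform under the null
  set.seed(26)
  pc <- fisher_combine(runif(1e4), runif(1e4))$p_combined
  expect_gt(ks.test(pc, "punif")$p.value, 0.01)
})

test_that("concordance filtering keeps same-sign bins and halves the null set", {
  df <- data.frame(bin = c("a", "b", "c"),
                   p_discordant = 0.01, sign_discordant = c(1, 1, 1),
                   p_correlation = 0.02, sign_correlation = c(1, -1, 0))
  comb <- combine_ewas(
    data.frame(bin = df$bin, p = df$p_discordant, sign = df$sign_discordant),
    data.frame(bin = df$bin, p = df$p_correlation, sign = df$sign_correlation))
  kept <- concordance_filter(comb)
  expect_identical(kept$bin, "a")

  set.seed(27)
  n <- 4000
  comb2 <- combine_ewas(
    data.frame(bin = paste0("b", 1:n), p = runif(n),
               sign = sample(c(-1, 1), n, TRUE)),
    data.frame(bin = paste0("b", 1:n), p = runif(n),
               sign = sample(c(-1, 1), n, TRUE)))
  frac <- nrow(concordance_filter(comb2)) / n
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / n))
})

test_that("full-design type-I error is at most alpha/2 under the global null", {
  # 10^4 null bins through paired test + correlation + Fisher + concordance
  set.seed(28)
  n_bins <- 10000
  B <- bin_matrix(400, n_bins, seed = 28)
  pairs <- data.frame(family_id = sprintf("f%03d", 1:50),
                      id_high = rownames(B)[seq(1, 99, 2)],
                      id_low = rownames(B)[seq(2, 100, 2)])
  fi <- data.frame(individual_id = rownames(B), fi = runif(400, 0, 0.5))
  gr1 <- c(pairs$id_high, pairs$id_low)
  gr2 <- setdiff(rownames(B), gr1)
  comb <- combine_ewas(paired_bin_test(B, pairs),
                       correlation_bin_scan(B, fi, gr2, gr1))
  hit <- mean(comb$p_combined < 0.05 & comb$concordant)
  expect_lte(hit, 0.025 + 3 * sqrt(0.025 * 0.975 / n_bins))
})

test_that("bins map to the nearest gene with the documented tie rule", {
  genes <- data.frame(chrom = "chr1", start = c(1000, 5000),
                      end = c(2000, 6000), gene = c("gA", "gB"))
  bins <- data.frame(chrom = c("chr1", "chr1", "chr1", "chr2"),
                     start = c(1200, 3250, 2600, 100),
                     end = c(1700, 3750, 3100, 600),
                     bin = c("in_gene", "equidistant", "nearer_A", "off_chrom"))
  res <- data.frame(bin = bins$bin, p_combined = c(0.01, 0.02, 0.03, 0.04))
  ga <- assign_bins_to_genes(res, bins, genes)
  a <- ga$assignments
  expect_equal(a$distance[a$bin == "in_gene"], 0)
  expect_equal(a$gene[a$bin == "in_gene"], "gA")
  # midpoint 3500 is 1500 from gA's end and from gB's start: lower start wins
  expect_equal(a$gene[a$bin == "equidistant"], "gA")
  expect_equal(a$gene[a$bin == "nearer_A"], "gA")
  expect_identical(ga$unassigned, "off_chrom")
  # best bin per gene
  expect_equal(ga$per_gene$bin[ga$per_gene$gene == "gA"], "in_gene")
})

test_that("gene assignment equals a brute-force all-pairs minimization", {
  set.seed(29)
  genes <- data.frame(chrom = "chr1",
                      start = seq(0, 45000, 5000) + sample(0:2000, 10),
                      gene = paste0("g", 1:10))
  genes$end <- genes$start + sample(500:2500, 10)
  bins <- data.frame(chrom = "chr1", start = sample(0:48000, 60))
  bins$end <- bins$start + 500
  bins$bin <- paste0("b", 1:60)
  res <- data.frame(bin = bins$bin, p_combined = runif(60))
  ga <- assign_bins_to_genes(res, bins, genes)
  for (i in seq_len(nrow(bins))) {
    mid <- (bins$start[i] + bins$end[i]) / 2
    d <- numeric(nrow(genes))
    for (j in seq_len(nrow(genes))) {
      ov <- bins$start[i] < genes$end[j] && genes$start[j] < bins$end[i]
      d[j] <- if (ov) 0 else min(abs(mid - genes$start[j]), abs(mid - genes$end[j]))
    }
    cand <- which(d == min(d))
    pick <- cand[which.min(genes$start[cand])]
    expect_equal(ga$assignments$gene[ga$assignments$bin == bins$bin[i]],
                 genes$gene[pick])
  }
})
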