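# Shared fixtures built in code.

# Minimal cohort frame for the family-model fits: n_mz + n_dz pairs plus
# singletons, ids in deterministic order.
make_cohort_frame <- function(n_mz, n_dz, n_singles = 0) {
  n_fam <- n_mz + n_dz + n_singles
  zyg <- rep(c("MZ", "DZ", "singleton"), c(n_mz, n_dz, n_singles))
  size <- ifelse(zyg == "singleton", 1L, 2L)
  data.frame(
    individual_id = sprintf("i%05d", seq_len(sum(size))),
    family_id = sprintf("f%05d", rep(seq_len(n_fam), size)),
    zygosity = rep(zyg, size),
    twin_order = unlist(lapply(size, function(s) if (s == 2) 1:2 else NA_integer_))
  )
}

# Draw a continuous twin trait with exact (empirical) MZ/DZ correlations.
trait_with_pair_cor <- function(cohort, r_mz, r_dz, seed = 1) {
  set.seed(seed)
  y <- numeric(nrow(cohort))
  for (z in c("MZ", "DZ")) {
    r <- if (z == "MZ") r_mz else r_dz
    rows <- which(cohort$zygosity == z)
    npair <- length(rows) / 2
    m <- MASS::mvrnorm(npair, c(0, 0), matrix(c(1, r, r, 1), 2),
                       empirical = TRUE)
    y[rows] <- as.vector(t(m))
  }
  s <- which(cohort$zygosity == "singleton")
  if (length(s)) y[s] <- rnorm(length(s))
  y
}

# Draw an ACE twin trait (unit variance) with known fractions.
ace_trait <- function(cohort, a2, c2, seed = 1) {
  set.seed(seed)
  n_fam <- length(unique(cohort$family_id))
  fam_idx <- match(cohort$family_id, unique(cohort$family_id))
  A_f <- rnorm(n_fam)
  A <- A_f[fam_idx]
  dz2 <- cohort$zygosity == "DZ" & cohort$twin_order == 2
  A[dz2] <- 0.5 * A[dz2] + sqrt(0.75) * rnorm(sum(dz2))
  sing <- cohort$zygosity == "singleton"
  A[sing] <- rnorm(sum(sing))
  C <- rnorm(n_fam)[fam_idx]
  E <- rnorm(nrow(cohort))
  sqrt(a2) * A + sqrt(c2) * C + sqrt(1 - a2 - c2) * E
}
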