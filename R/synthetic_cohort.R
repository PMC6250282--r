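#' Configuration for a synthetic twin cohort
#'
#' Builds and validates the parameter set for [simulate_cohort()]. The
#' defaults describe a female twin registry of 848 MZ pairs, 576 DZ pairs and
#' 778 singletons (ages 17--93), a Frailty Index (FI) liability with additive
#' genetic fraction 0.34, a dichotomous chronic widespread pain (CWP) trait
#' with population prevalence 0.20 modelled on a latent liability scale, and
#' a cross-trait additive-genetic correlation of 0.69.
#'
#' Variance fractions refer to the standardized residual liability after
#' covariate effects (age, relative fat mass, smoking) are added to the
#' linear predictor. `planted_effects` is a data frame with columns
#' `feature`, `layer` (`"metabolite"`, `"snp"` or `"bin"`), `target`
#' (`"fi"`, `"cwp"`, or a metabolite id for SNPs), `effect` (per-SD units)
#' and `mediated` (logical; a mediated metabolite enters the CWP liability
#' only, so any FI association flows through the CWP status indicator, whose
#' causal effect on FI liability is `cwp_fi_effect`).
#'
#' @param n_mz_pairs,n_dz_pairs,n_singletons cohort composition (pairs/individuals).
#' @param age_range length-2 numeric, uniform age range in years.
#' @param a2_fi,c2_fi additive-genetic and shared-environment fractions of FI liability.
#' @param a2_cwp,c2_cwp same for the CWP liability.
#' @param rg,rc,re cross-trait correlations of the A, C and E components.
#' @param cwp_prevalence population prevalence of CWP, in (0,1).
#' @param n_deficits number of binary deficit items (>= 2).
#' @param n_metabolites total metabolites, of which `n_unknown_metabolites`
#'   are flagged as chemically unidentified.
#' @param n_snps,n_bins,n_genes sizes of the genotype and methylation layers.
#' @param metabolite_missing_rate per-entry missingness probability.
#' @param n_run_days number of assay run-days for metabolite batch effects.
#' @param bin_width,bin_step methylation bin geometry in bp.
#' @param stable_bin_fraction fraction of bins longitudinally stable.
#' @param bin_autocorrelation correlation of a stable bin across timepoints.
#' @param cwp_fi_effect causal effect of CWP status on FI liability (0 disables
#'   the mediation path).
#' @param beta_age_fi,beta_fat_fi,beta_smoking_fi covariate effects (per SD /
#'   per category) on FI liability; `*_cwp` analogues for the CWP liability.
#' @param planted_effects data frame of planted feature effects (see Details).
#' @param seed integer seed; every layer derives its own sub-seed from it.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_mz_pairs = 848, n_dz_pairs = 576, n_singletons = 778,
                          age_range = c(17, 93),
                          a2_fi = 0.34, c2_fi = 0.20,
                          a2_cwp = 0.45, c2_cwp = 0.10,
                          rg = 0.69, rc = 0.30, re = 0.10,
                          cwp_prevalence = 0.20,
                          n_deficits = 33,
                          n_metabolites = 408, n_unknown_metabolites = 103,
                          n_snps = 1000, n_bins = 2000, n_genes = 100,
                          metabolite_missing_rate = 0.01,
                          n_run_days = 20,
                          bin_width = 500, bin_step = 250,
                          stable_bin_fraction = 0.8,
                          bin_autocorrelation = 0.6,
                          cwp_fi_effect = 0,
                          beta_age_fi = 0.25, beta_fat_fi = 0.15, beta_smoking_fi = 0.10,
                          beta_age_cwp = 0.20, beta_fat_cwp = 0.15, beta_smoking_cwp = 0.10,
                          planted_effects = NULL,
                          seed = 1L) {
  cfg <- as.list(environment())
  cfg$planted_effects <- planted_effects %||%
    data.frame(feature = character(), layer = character(), target = character(),
               effect = numeric(), mediated = logical())
  stopifnot(
    n_mz_pairs >= 0, n_dz_pairs >= 0, n_singletons >= 0,
    length(age_range) == 2, age_range[1] < age_range[2]
  )
  for (v in c("a2_fi", "c2_fi", "a2_cwp", "c2_cwp"))
    if (cfg[[v]] < 0 || cfg[[v]] > 1)
      stop(sprintf("variance fraction `%s` must lie in [0,1]", v))
  if (a2_fi + c2_fi > 1) stop("a2_fi + c2_fi exceeds 1")
  if (a2_cwp + c2_cwp > 1) stop("a2_cwp + c2_cwp exceeds 1")
  for (v in c("rg", "rc", "re"))
    if (abs(cfg[[v]]) > 1) stop(sprintf("correlation `%s` must lie in [-1,1]", v))
  if (cwp_prevalence <= 0 || cwp_prevalence >= 1)
    stop("cwp_prevalence must lie in (0,1)")
  if (n_deficits < 2) stop("n_deficits must be >= 2")
  if (n_unknown_metabolites > n_metabolites)
    stop("n_unknown_metabolites exceeds n_metabolites")
  pe <- cfg$planted_effects
  if (nrow(pe)) {
    stopifnot(all(c("feature", "layer", "target", "effect", "mediated") %in% names(pe)))
    if (!all(pe$layer %in% c("metabolite", "snp", "bin")))
      stop("planted_effects: unknown layer")
    met_ids <- paste0("met", seq_len(n_metabolites))
    bad <- (pe$layer == "metabolite" & !pe$feature %in% met_ids) |
      (pe$layer == "snp" & !pe$feature %in% paste0("snp", seq_len(n_snps))) |
      (pe$layer == "bin" & !pe$feature %in% paste0("bin", seq_len(n_bins)))
    if (any(bad))
      stop("planted_effects references unknown feature(s): ",
           paste(pe$feature[bad], collapse = ", "))
    badt <- (pe$layer %in% c("metabolite", "bin") & !pe$target %in% c("fi", "cwp")) |
      (pe$layer == "snp" & !pe$target %in% met_ids)
    if (any(badt))
      stop("planted_effects references unknown target(s): ",
           paste(pe$target[badt], collapse = ", "))
    if (any(pe$mediated & pe$layer != "metabolite"))
      stop("mediated flag is only meaningful for metabolites")
    if (any(pe$mediated) && cwp_fi_effect == 0)
      warning("mediated metabolite planted but cwp_fi_effect is 0: ",
              "no FI association will arise")
  }
  structure(cfg, class = "cohort_config")
}

#' Default planted-effect table for demonstration pipelines
#'
#' One metabolite with a direct negative FI effect, one mediated metabolite
#' (an epiandrosterone-sulphate analogue acting on FI only through CWP), one
#' metabolite QTL, and five FI-associated methylation bins.
#'
#' @param config a `cohort_config` (used only for feature-id ranges).
#' @return data frame suitable for the `planted_effects` field.
#' @export
default_planted_effects <- function(config) {
  data.frame(
    feature = c("met1", "met2", "snp1", paste0("bin", 1:5)),
    layer = c("metabolite", "metabolite", "snp", rep("bin", 5)),
    target = c("fi", "cwp", "met1", rep("fi", 5)),
    effect = c(-0.15, -0.30, 0.5, rep(0.4, 5)),
    mediated = c(FALSE, TRUE, FALSE, rep(FALSE, 5))
  )
}

# Draw per-family / per-individual bivariate component pairs with the given
# cross-trait correlation (unit marginal variance).
.draw_biv <- function(n, r) {
  z1 <- rnorm(n)
  z2 <- r * z1 + sqrt(max(0, 1 - r^2)) * rnorm(n)
  cbind(z1, z2)
}

#' Simulate a twin cohort with linked omics layers
#'
#' Generates, deterministically for a given seed, a twin cohort (MZ pairs
#' sharing A and C, DZ pairs sharing C with A-correlation 1/2, independent
#' singletons), latent FI and CWP liabilities built from standardized A/C/E
#' components plus covariate and planted metabolite effects, a binary deficit
#' table whose item probabilities rise with FI liability, CWP status from
#' thresholding the standardized CWP liability at its prevalence quantile, a
#' metabolite matrix with run-day batch factors and missingness, a biallelic
#' SNP dosage matrix with planted metabolite QTLs, methylation levels in
#' overlapping bins at two timepoints at least three years apart, and a
#' non-overlapping gene annotation.
#'
#' Every layer draws from its own sub-seed derived from `config$seed`, so
#' adding or resizing one layer leaves the others untouched.
#'
#' @param config a [cohort_config()].
#' @return list of class `twin_cohort_sim` with elements `cohort`, `deficits`,
#'   `metabolites` (raw abundances), `metabolite_info`, `genotypes`, `snps`,
#'   `bins_t1`, `bins_t2`, `bins`, `genes`, `truth` and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- config
  n_mz <- cfg$n_mz_pairs; n_dz <- cfg$n_dz_pairs; n_sg <- cfg$n_singletons
  n_fam <- n_mz + n_dz + n_sg
  n_ind <- 2 * (n_mz + n_dz) + n_sg

  ## --- layer 1: family structure, covariates, A/C/E components -----------
  set.seed(derive_seed(cfg$seed, 1L))
  fam_zyg <- rep(c("MZ", "DZ", "singleton"), c(n_mz, n_dz, n_sg))
  fam_size <- ifelse(fam_zyg == "singleton", 1L, 2L)
  family_id <- sprintf("fam%05d", rep(seq_len(n_fam), fam_size))
  zygosity <- rep(fam_zyg, fam_size)
  twin_order <- unlist(lapply(fam_size, function(s) if (s == 2L) 1:2 else NA_integer_),
                       use.names = FALSE)
  individual_id <- sprintf("ind%05d", seq_len(n_ind))

  # co-twins share age: draw per individual, then copy the first of family
  age <- runif(n_ind, cfg$age_range[1], cfg$age_range[2])
  age <- stats::ave(age, family_id, FUN = function(a) a[1])
  fat_h2 <- rnorm(n_ind)
  smoking <- sample(0:2, n_ind, replace = TRUE, prob = c(0.5, 0.3, 0.2))

  # A components: per family one draw; DZ twin 2 gets 0.5*A1 + sqrt(.75)*A'
  A_fam <- .draw_biv(n_fam, cfg$rg)
  A <- A_fam[rep(seq_len(n_fam), fam_size), , drop = FALSE]
  dz2 <- zygosity == "DZ" & twin_order == 2L
  if (any(dz2)) {
    Anew <- .draw_biv(sum(dz2), cfg$rg)
    A[dz2, ] <- 0.5 * A[dz2, , drop = FALSE] + sqrt(0.75) * Anew
  }
  C_fam <- .draw_biv(n_fam, cfg$rc)
  C <- C_fam[rep(seq_len(n_fam), fam_size), , drop = FALSE]
  E <- .draw_biv(n_ind, cfg$re)

  e2_fi <- 1 - cfg$a2_fi - cfg$c2_fi
  e2_cwp <- 1 - cfg$a2_cwp - cfg$c2_cwp
  fi_ace <- sqrt(cfg$a2_fi) * A[, 1] + sqrt(cfg$c2_fi) * C[, 1] + sqrt(e2_fi) * E[, 1]
  cwp_ace <- sqrt(cfg$a2_cwp) * A[, 2] + sqrt(cfg$c2_cwp) * C[, 2] + sqrt(e2_cwp) * E[, 2]

  ## --- layer 2: SNPs ------------------------------------------------------
  set.seed(derive_seed(cfg$seed, 2L))
  n_snps <- cfg$n_snps
  if (n_snps > 0) {
    maf <- runif(n_snps, 0.05, 0.5)
    G <- vapply(maf, function(p) rbinom(n_ind, 2L, p), integer(n_ind))
    if (n_ind == 1) G <- matrix(G, nrow = 1)
    colnames(G) <- paste0("snp", seq_len(n_snps))
    rownames(G) <- individual_id
    snps <- data.frame(
      snp = colnames(G),
      chrom = paste0("chr", rep_len(1:2, n_snps)),
      pos = 10000L + 500L * seq_len(n_snps),
      allele_ref = "A", allele_alt = "G",
      maf_true = maf
    )
  } else {
    G <- matrix(integer(0), nrow = n_ind, ncol = 0,
                dimnames = list(individual_id, NULL))
    snps <- data.frame(snp = character(), chrom = character(), pos = integer(),
                       allele_ref = character(), allele_alt = character(),
                       maf_true = numeric())
  }

  ## --- layer 3: metabolites ----------------------------------------------
  set.seed(derive_seed(cfg$seed, 3L))
  n_met <- cfg$n_metabolites
  met_ids <- paste0("met", seq_len(n_met))
  Z <- matrix(rnorm(n_ind * n_met), n_ind, n_met,
              dimnames = list(individual_id, met_ids))
  pe <- cfg$planted_effects
  for (i in which(pe$layer == "snp")) {
    g <- G[, pe$feature[i]]
    Z[, pe$target[i]] <- Z[, pe$target[i]] +
      pe$effect[i] * (g - mean(g)) / max(stats::sd(g), 1e-12)
  }
  run_day <- sample(seq_len(cfg$n_run_days), n_ind, replace = TRUE)
  day_factor <- exp(rnorm(cfg$n_run_days, 0, 0.25))
  base_level <- exp(rnorm(n_met, 3, 0.5))
  raw <- exp(0.4 * Z) * rep(day_factor[run_day], n_met) *
    matrix(base_level, n_ind, n_met, byrow = TRUE)
  if (cfg$metabolite_missing_rate > 0) {
    raw[matrix(runif(n_ind * n_met) < cfg$metabolite_missing_rate,
               n_ind, n_met)] <- NA_real_
  }
  known <- rep(TRUE, n_met)
  if (cfg$n_unknown_metabolites > 0)
    known[seq(n_met - cfg$n_unknown_metabolites + 1L, n_met)] <- FALSE
  metabolite_info <- data.frame(metabolite = met_ids, known = known)

  ## --- liabilities, CWP status, FI causal path ----------------------------
  age_z <- (age - mean(age)) / stats::sd(age)
  fi_liab <- cfg$beta_age_fi * age_z + cfg$beta_fat_fi * fat_h2 +
    cfg$beta_smoking_fi * smoking + fi_ace
  cwp_liab <- cfg$beta_age_cwp * age_z + cfg$beta_fat_cwp * fat_h2 +
    cfg$beta_smoking_cwp * smoking + cwp_ace
  for (i in which(pe$layer == "metabolite")) {
    tgt <- if (pe$mediated[i]) "cwp" else pe$target[i]
    if (tgt == "fi") fi_liab <- fi_liab + pe$effect[i] * Z[, pe$feature[i]]
    else cwp_liab <- cwp_liab + pe$effect[i] * Z[, pe$feature[i]]
  }
  cwp_std <- (cwp_liab - mean(cwp_liab)) / stats::sd(cwp_liab)
  cwp_status <- as.integer(cwp_std > qnorm(1 - cfg$cwp_prevalence))
  fi_liab <- fi_liab + cfg$cwp_fi_effect * cwp_status

  ## --- layer 4: deficits ---------------------------------------------------
  set.seed(derive_seed(cfg$seed, 4L))
  item_p0 <- runif(cfg$n_deficits, 0.05, 0.35)
  alpha <- qlogis(item_p0)
  fi_z <- (fi_liab - mean(fi_liab)) / stats::sd(fi_liab)
  P <- plogis(outer(fi_z, alpha, `+`))
  deficits <- matrix(as.integer(runif(length(P)) < P), nrow = n_ind,
                     dimnames = list(individual_id,
                                     paste0("item", seq_len(cfg$n_deficits))))

  ## --- layer 5: methylation bins ------------------------------------------
  set.seed(derive_seed(cfg$seed, 5L))
  n_bins <- cfg$n_bins
  bin_ids <- paste0("bin", seq_len(n_bins))
  if (n_bins > 0) {
    per_chr <- ceiling(n_bins / 2)
    chrom <- paste0("chr", rep(1:2, c(per_chr, n_bins - per_chr)))
    idx_in_chr <- unlist(lapply(rle(chrom)$lengths, seq_len), use.names = FALSE)
    start <- (idx_in_chr - 1L) * cfg$bin_step
    bins <- data.frame(chrom = chrom, start = start,
                       end = start + cfg$bin_width, bin = bin_ids)
    planted_bins <- pe$feature[pe$layer == "bin"]
    base <- rnorm(n_bins, 5, 1)
    B1 <- matrix(rnorm(n_ind * n_bins), n_ind, n_bins,
                 dimnames = list(individual_id, bin_ids))
    B1 <- sweep(B1, 2, base, `+`)
    for (i in which(pe$layer == "bin")) {
      lz <- if (pe$target[i] == "fi") fi_z else cwp_std
      B1[, pe$feature[i]] <- B1[, pe$feature[i]] + pe$effect[i] * lz
    }
    stable <- runif(n_bins) < cfg$stable_bin_fraction
    stable[match(planted_bins, bin_ids)] <- TRUE  # planted bins are stable
    rho <- cfg$bin_autocorrelation
    noise <- matrix(rnorm(n_ind * n_bins), n_ind, n_bins)
    B1c <- sweep(B1, 2, colMeans(B1))
    B2 <- sweep(rho * B1c + sqrt(1 - rho^2) * noise, 2, base, `+`)
    B2[, !stable] <- sweep(noise[, !stable, drop = FALSE], 2,
                           base[!stable], `+`)
    dimnames(B2) <- dimnames(B1)
  } else {
    bins <- data.frame(chrom = character(), start = integer(),
                       end = integer(), bin = character())
    B1 <- B2 <- matrix(numeric(0), nrow = n_ind, ncol = 0,
                       dimnames = list(individual_id, NULL))
    stable <- logical(0)
  }

  ## --- layer 6: gene annotation -------------------------------------------
  set.seed(derive_seed(cfg$seed, 6L))
  n_genes <- cfg$n_genes
  if (n_genes > 0) {
    per_chr_g <- ceiling(n_genes / 2)
    gchrom <- paste0("chr", rep(1:2, c(per_chr_g, n_genes - per_chr_g)))
    gidx <- unlist(lapply(rle(gchrom)$lengths, seq_len), use.names = FALSE)
    # non-overlapping: each gene inside its own 5-kb slot
    gstart <- (gidx - 1L) * 5000L + sample(0:2000, n_genes, replace = TRUE)
    glen <- sample(500:2500, n_genes, replace = TRUE)
    genes <- data.frame(chrom = gchrom, start = gstart, end = gstart + glen,
                        gene = paste0("gene", seq_len(n_genes)))
  } else {
    genes <- data.frame(chrom = character(), start = integer(),
                        end = integer(), gene = character())
  }

  cohort <- data.frame(
    individual_id = individual_id, family_id = family_id,
    zygosity = zygosity, twin_order = twin_order,
    age = age, fat_h2 = fat_h2, smoking = smoking,
    fi_liability = fi_liab, cwp_liability = cwp_liab,
    cwp_status = cwp_status,
    A_fi = A[, 1], C_fi = C[, 1], E_fi = E[, 1],
    A_cwp = A[, 2], C_cwp = C[, 2], E_cwp = E[, 2]
  )

  structure(list(
    cohort = cohort, deficits = deficits,
    metabolites = raw, metabolite_info = metabolite_info, run_day = run_day,
    genotypes = G, snps = snps,
    bins_t1 = B1, bins_t2 = B2, bins = bins, genes = genes,
    truth = list(planted_effects = pe, item_baseline_prevalence = item_p0,
                 stable_bins = bin_ids[stable],
                 cwp_threshold = qnorm(1 - cfg$cwp_prevalence)),
    config = cfg
  ), class = "twin_cohort_sim")
}

#' @export
print.twin_cohort_sim <- function(x, ...) {
  cat("Synthetic twin cohort:", nrow(x$cohort), "individuals (",
      sum(x$cohort$zygosity == "MZ") / 2, "MZ pairs,",
      sum(x$cohort$zygosity == "DZ") / 2, "DZ pairs,",
      sum(x$cohort$zygosity == "singleton"), "singletons )\n")
  cat("Layers:", ncol(x$deficits), "deficits,", ncol(x$metabolites),
      "metabolites,", ncol(x$genotypes), "SNPs,", ncol(x$bins_t1), "bins\n")
  invisible(x)
}

#' Write all cohort layers as tab-separated files
#'
#' Emits `cohort.tsv`, `deficits.tsv`, `metabolites.tsv`, `run_days.tsv`,
#' `genotypes.tsv`, `snps.tsv`, `bins_t1.tsv`, `bins_t2.tsv`, `bins.bed`,
#' `genes.bed` (0-based half-open coordinates) and `truth.json` into `dir`.
#'
#' @param sim a `twin_cohort_sim`.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of file paths written.
#' @export
write_cohort <- function(sim, dir) {
  stopifnot(inherits(sim, "twin_cohort_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  mat_df <- function(m) data.frame(individual_id = rownames(m), m,
                                   check.names = FALSE)
  write_tsv(sim$cohort, p("cohort.tsv"))
  write_tsv(mat_df(sim$deficits), p("deficits.tsv"))
  write_tsv(mat_df(sim$metabolites), p("metabolites.tsv"))
  write_tsv(data.frame(individual_id = rownames(sim$metabolites),
                       run_day = sim$run_day), p("run_days.tsv"))
  write_tsv(sim$metabolite_info, p("metabolite_info.tsv"))
  write_tsv(mat_df(sim$genotypes), p("genotypes.tsv"))
  write_tsv(sim$snps, p("snps.tsv"))
  write_tsv(mat_df(sim$bins_t1), p("bins_t1.tsv"))
  write_tsv(mat_df(sim$bins_t2), p("bins_t2.tsv"))
  utils::write.table(sim$bins[, c("chrom", "start", "end", "bin")], p("bins.bed"),
                     sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(sim$genes[, c("chrom", "start", "end", "gene")], p("genes.bed"),
                     sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(sim$truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(vapply(c("cohort.tsv", "deficits.tsv", "metabolites.tsv",
                     "run_days.tsv", "metabolite_info.tsv", "genotypes.tsv",
                     "snps.tsv", "bins_t1.tsv", "bins_t2.tsv", "bins.bed",
                     "genes.bed", "truth.json"), p, character(1)))
}
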