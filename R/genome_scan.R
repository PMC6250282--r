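#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact test on genotype counts `(n_AA, n_Aa, n_aa)`: given the
#' allele counts, the p-value is the sum of probabilities of all heterozygote
#' counts whose conditional probability does not exceed that of the observed
#' count. Monomorphic markers return p = 1.
#'
#' @param n_aa_major,n_het,n_aa_minor genotype counts (scalars).
#' @return exact p-value.
#' @export
hwe_test <- function(n_aa_major, n_het, n_aa_minor) {
  stopifnot(n_aa_major >= 0, n_het >= 0, n_aa_minor >= 0)
  n <- n_aa_major + n_het + n_aa_minor
  if (n == 0) stop("no genotypes")
  nr <- 2 * min(n_aa_major, n_aa_minor) + n_het  # rare allele count
  if (nr == 0) return(1)
  hets <- seq(nr %% 2, nr, by = 2)  # feasible heterozygote counts
  # log conditional probability of each het count given n and nr
  lp <- lchoose(n, hets) + lchoose(n - hets, (nr - hets) / 2) +
    hets * log(2) - lchoose(2 * n, nr)
  # normalize within the conditional distribution
  lp <- lp - max(lp)
  pr <- exp(lp) / sum(exp(lp))
  obs <- pr[match(n_het, hets)]
  if (is.na(obs)) stop("inconsistent genotype counts")
  sum(pr[pr <= obs * (1 + 1e-12)])
}

#' SNP quality control
#'
#' Retains SNPs with call rate at least `min_call` and exact
#' Hardy-Weinberg p-value at least `min_hwe_p` (both boundaries inclusive,
#' i.e. a SNP exactly at either threshold is kept).
#'
#' @param genotypes dosage matrix (individuals x SNPs) with values 0/1/2/NA.
#' @param snps SNP metadata data frame with a `snp` column matching the
#'   dosage columns.
#' @param min_call minimum genotyping call rate.
#' @param min_hwe_p minimum HWE exact-test p-value.
#' @return list: `genotypes`, `snps` (filtered, with `call_rate`, `maf`,
#'   `hwe_p` columns added), and `report` counting removals per reason.
#' @export
snp_qc <- function(genotypes, snps, min_call = 0.95, min_hwe_p = 1e-4) {
  G <- as.matrix(genotypes)
  stopifnot(identical(colnames(G), snps$snp))
  call_rate <- colMeans(!is.na(G))
  n0 <- colSums(G == 0, na.rm = TRUE)
  n1 <- colSums(G == 1, na.rm = TRUE)
  n2 <- colSums(G == 2, na.rm = TRUE)
  af <- (2 * n2 + n1) / (2 * pmax(n0 + n1 + n2, 1L))
  maf <- pmin(af, 1 - af)
  hwe_p <- vapply(seq_len(ncol(G)),
                  function(j) hwe_test(n0[j], n1[j], n2[j]), numeric(1))
  fail_call <- call_rate < min_call
  fail_hwe <- hwe_p < min_hwe_p
  keep <- !(fail_call | fail_hwe)
  if (!any(keep)) stop("all SNPs removed by QC")
  snps <- cbind(snps, call_rate = call_rate, maf = maf, hwe_p = hwe_p)
  list(
    genotypes = G[, keep, drop = FALSE],
    snps = snps[keep, , drop = FALSE],
    report = data.frame(
      n_input = ncol(G),
      n_fail_call_rate = sum(fail_call),
      n_fail_hwe = sum(fail_hwe & !fail_call),
      n_retained = sum(keep)
    )
  )
}

#' Additive single-marker association scan
#'
#' Per SNP, least-squares regression of the trait on allele dosage plus
#' covariates (complete cases per SNP); reports the dosage coefficient with
#' its two-sided p-value, and the genomic-control inflation factor
#' `lambda = median(chi-square) / 0.4549` over the scan. SNPs monomorphic
#' after missingness are skipped and flagged.
#'
#' @param trait numeric vector aligned with dosage rows.
#' @param genotypes dosage matrix (individuals x SNPs).
#' @param snps SNP metadata with `snp`, `chrom`, `pos`.
#' @param covariates optional covariate matrix aligned with rows.
#' @return data frame (class `assoc_result`) with `feature`, `chrom`, `pos`,
#'   `beta`, `se`, `statistic`, `p`, `q`, `direction`, `n`, plus attributes
#'   `lambda` and `skipped`.
#' @export
additive_scan <- function(trait, genotypes, snps, covariates = NULL) {
  G <- as.matrix(genotypes)
  stopifnot(length(trait) == nrow(G), identical(colnames(G), snps$snp))
  covars <- if (!is.null(covariates)) as.matrix(as.data.frame(covariates))
  rows <- vector("list", ncol(G))
  for (j in seq_len(ncol(G))) {
    x <- G[, j]
    ok <- !is.na(x) & !is.na(trait)
    if (!is.null(covars)) ok <- ok & stats::complete.cases(covars)
    if (length(unique(x[ok])) < 2) next
    r <- .ls_assoc(trait, x, covars)
    if (!is.null(r)) rows[[j]] <- data.frame(feature = snps$snp[j],
                                             chrom = snps$chrom[j],
                                             pos = snps$pos[j], t(r))
  }
  skipped <- snps$snp[vapply(rows, is.null, TRUE)]
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out)) stop("no testable SNPs")
  out$q <- bh_fdr(out$p)
  out$direction <- sign(out$beta)
  chisq <- stats::qchisq(out$p, df = 1, lower.tail = FALSE)
  attr(out, "lambda") <- stats::median(chisq) / stats::qchisq(0.5, 1, lower.tail = FALSE)
  attr(out, "skipped") <- skipped
  class(out) <- c("assoc_result", class(out))
  out
}
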