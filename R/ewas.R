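# Discordant-MZ-twin EWAS design: longitudinal-stability filter, paired test
# in the most FI-discordant pairs (Gr1), correlation scan in the remainder
# (Gr2), Fisher combination, direction-concordance filter, nearest-gene
# assignment.

# Vectorized Pearson correlation of matrix columns against y (or pairwise
# between two matrices' matching columns); returns r, t, two-sided p, n.
.cor_cols <- function(M, y) {
  ok <- !is.na(y)
  M <- M[ok, , drop = FALSE]
  y <- y[ok]
  n <- nrow(M)
  My <- crossprod(M, y) / n - colMeans(M) * mean(y)
  vx <- colMeans(M^2) - colMeans(M)^2
  vy <- mean(y^2) - mean(y)^2
  r <- drop(My / sqrt(vx * vy))
  r[vx == 0] <- NA
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-300))
  p <- 2 * stats::pt(abs(tt), n - 2, lower.tail = FALSE)
  data.frame(r = r, statistic = tt, p = pmax(p, 1e-300), n = n)
}

#' Longitudinal-stability filter for methylation bins
#'
#' Retains bins whose methylation levels correlate positively and
#' significantly (two-sided p < `alpha` with r > 0) between two timepoints
#' measured on the same individuals years apart ("lsBINs"). Bins constant at
#' either timepoint are excluded and flagged.
#'
#' @param bins_t1,bins_t2 matrices (individuals x bins), same dimnames.
#' @param alpha significance level of the correlation test.
#' @return list: `retained` (bin ids), `stats` (per-bin r, p), `degenerate`
#'   (constant bins).
#' @export
ls_bin_filter <- function(bins_t1, bins_t2, alpha = 0.05) {
  stopifnot(identical(dimnames(bins_t1), dimnames(bins_t2)))
  B1 <- as.matrix(bins_t1); B2 <- as.matrix(bins_t2)
  n <- nrow(B1)
  r <- vapply(seq_len(ncol(B1)), function(j) {
    s1 <- stats::sd(B1[, j]); s2 <- stats::sd(B2[, j])
    if (s1 == 0 || s2 == 0) return(NA_real_)
    stats::cor(B1[, j], B2[, j])
  }, numeric(1))
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-300))
  # r == 1 exactly (e.g. t2 copied from t1) has infinite t: p = 0
  p <- ifelse(is.infinite(tt), 0,
              2 * stats::pt(abs(tt), n - 2, lower.tail = FALSE))
  stats_df <- data.frame(bin = colnames(B1), r = r, p = p)
  keep <- !is.na(r) & r > 0 & p < alpha
  list(retained = colnames(B1)[keep], stats = stats_df,
       degenerate = colnames(B1)[is.na(r)])
}

#' Paired t test of methylation within discordant twin pairs
#'
#' For each bin, a two-sided paired t test of the within-pair methylation
#' differences, higher-FI twin minus lower-FI twin. The sign is the sign of
#' the mean difference. When every difference is zero the test is undefined
#' and the bin reports p = 1, sign = 0 (convention); bins with fewer than 3
#' complete pairs report NA.
#'
#' @param bins methylation matrix (individuals x bins, rownames ids).
#' @param pairs data frame from [pair_fi_table()] restricted to the selected
#'   (Gr1) pairs: columns `id_high`, `id_low`.
#' @return data frame: `bin`, `statistic`, `p`, `sign`, `n_pairs`.
#' @export
paired_bin_test <- function(bins, pairs) {
  B <- as.matrix(bins)
  miss <- setdiff(c(pairs$id_high, pairs$id_low), rownames(B))
  if (length(miss))
    stop("individuals missing from bin matrix: ", paste(miss, collapse = ", "))
  D <- B[pairs$id_high, , drop = FALSE] - B[pairs$id_low, , drop = FALSE]
  k <- nrow(D)
  if (k < 3) stop("fewer than 3 complete pairs")
  m <- colMeans(D)
  s <- sqrt(colSums(sweep(D, 2, m)^2) / (k - 1))
  tt <- m / (s / sqrt(k))
  p <- 2 * stats::pt(abs(tt), k - 1, lower.tail = FALSE)
  zero <- s == 0 & m == 0
  degen <- s == 0 & m != 0
  p[zero] <- 1
  p[degen] <- 1e-300
  tt[zero] <- 0
  sgn <- sign(m)
  data.frame(bin = colnames(B), statistic = tt, p = pmax(p, 1e-300),
             sign = sgn, n_pairs = k, row.names = NULL)
}

#' Correlation of methylation with FI in the independent sample
#'
#' Pearson correlation of each bin with the FI score over the Gr2
#' individuals. Errors if any Gr2 individual belongs to the discordant-pair
#' sample (Gr1): the downstream Fisher combination requires the two samples
#' to be non-overlapping.
#'
#' @param bins methylation matrix (individuals x bins).
#' @param fi data frame with `individual_id`, `fi`.
#' @param individuals ids of the Gr2 sample.
#' @param gr1_individuals ids of the Gr1 sample (for the disjointness check).
#' @return data frame: `bin`, `r`, `statistic`, `p`, `sign`, `n`.
#' @export
correlation_bin_scan <- function(bins, fi, individuals, gr1_individuals) {
  overlap <- intersect(individuals, gr1_individuals)
  if (length(overlap))
    stop("Gr1 and Gr2 samples overlap (", length(overlap),
         " individuals); Fisher combination requires independence")
  B <- as.matrix(bins)[individuals, , drop = FALSE]
  y <- fi$fi[match(individuals, fi$individual_id)]
  cs <- .cor_cols(B, y)
  data.frame(bin = colnames(B), r = cs$r, statistic = cs$statistic,
             p = cs$p, sign = sign(cs$r), n = cs$n, row.names = NULL)
}

#' Fisher combination of two independent p-values
#'
#' `stat = -2 (ln p1 + ln p2)`, referred to the upper tail of a chi-square
#' distribution with 4 degrees of freedom. P-values of exactly zero (from
#' underflow) are floored at 1e-300 before the log.
#'
#' @param p1,p2 p-values in (0, 1] (vectorized).
#' @return data frame with `fisher_stat` and `p_combined`.
#' @export
fisher_combine <- function(p1, p2) {
  if (any(p1 < 0 | p1 > 1 | p2 < 0 | p2 > 1, na.rm = TRUE))
    stop("p-values must lie in (0, 1]")
  p1 <- pmax(p1, 1e-300)
  p2 <- pmax(p2, 1e-300)
  stat <- -2 * (log(p1) + log(p2))
  data.frame(fisher_stat = stat,
             p_combined = stats::pchisq(stat, df = 4, lower.tail = FALSE))
}

#' Combine the two EWAS arms for every bin
#'
#' Joins the paired-test (Gr1) and correlation (Gr2) results, Fisher-combines
#' their p-values and flags direction concordance.
#'
#' @param discordant result of [paired_bin_test()].
#' @param correlation result of [correlation_bin_scan()].
#' @return data frame (class `ewas_result`): `bin`, `p_discordant`,
#'   `sign_discordant`, `p_correlation`, `sign_correlation`, `fisher_stat`,
#'   `p_combined`, `concordant`.
#' @export
combine_ewas <- function(discordant, correlation) {
  m <- merge(
    data.frame(bin = discordant$bin, p_discordant = discordant$p,
               sign_discordant = discordant$sign),
    data.frame(bin = correlation$bin, p_correlation = correlation$p,
               sign_correlation = correlation$sign),
    by = "bin")
  fc <- fisher_combine(m$p_discordant, m$p_correlation)
  m$fisher_stat <- fc$fisher_stat
  m$p_combined <- fc$p_combined
  m$concordant <- m$sign_discordant == m$sign_correlation & m$sign_discordant != 0
  class(m) <- c("ewas_result", class(m))
  m
}

#' Keep bins with the same direction of association in both subsamples
#'
#' @param results data frame from [combine_ewas()].
#' @return the concordant subset.
#' @export
concordance_filter <- function(results) {
  results[results$concordant, , drop = FALSE]
}

#' Assign bins to nearest genes and keep the best bin per gene
#'
#' Each bin is assigned to the gene minimizing genomic distance: 0 when the
#' bin interval overlaps the gene, otherwise the distance from the bin
#' midpoint to the nearest gene edge; ties go to the gene with the lower
#' start. Per gene the assigned bin with the smallest combined p is
#' retained. Bins on chromosomes absent from the annotation stay
#' unassigned.
#'
#' @param results data frame with at least `bin` and `p_combined`.
#' @param bins BED-like data frame: `chrom`, `start`, `end`, `bin`
#'   (0-based half-open).
#' @param genes BED-like data frame: `chrom`, `start`, `end`, `gene`
#'   (non-overlapping).
#' @return list: `assignments` (bin, gene, distance), `per_gene` (gene, bin,
#'   p_combined of the best bin), `unassigned` (bin ids).
#' @export
assign_bins_to_genes <- function(results, bins, genes) {
  b <- merge(results, bins, by = "bin")
  gene_v <- rep(NA_character_, nrow(b))
  dist_v <- rep(NA_real_, nrow(b))
  for (ch in unique(b$chrom)) {
    gi <- genes[genes$chrom == ch, , drop = FALSE]
    bi <- which(b$chrom == ch)
    if (!nrow(gi)) next
    gi <- gi[order(gi$start), , drop = FALSE]
    mid <- (b$start[bi] + b$end[bi]) / 2
    for (t in seq_along(bi)) {
      i <- bi[t]
      overlap <- b$start[i] < gi$end & gi$start < b$end[i]
      d <- ifelse(overlap, 0, pmin(abs(mid[t] - gi$start), abs(mid[t] - gi$end)))
      best <- which(d == min(d))[1]  # gi sorted by start: tie -> lower start
      gene_v[i] <- gi$gene[best]
      dist_v[i] <- min(d)
    }
  }
  assignments <- data.frame(bin = b$bin, gene = gene_v, distance = dist_v)
  assigned <- !is.na(gene_v)
  per_gene <- do.call(rbind, lapply(
    split(data.frame(bin = b$bin[assigned], gene = gene_v[assigned],
                     p_combined = b$p_combined[assigned]),
          gene_v[assigned]),
    function(g) g[which.min(g$p_combined), ]))
  rownames(per_gene) <- NULL
  list(assignments = assignments,
       per_gene = per_gene[order(per_gene$p_combined), ],
       unassigned = b$bin[!assigned])
}
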