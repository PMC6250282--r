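#' Gene-set overrepresentation by Fisher's exact test
#'
#' For each gene set, builds the 2x2 table of set membership against
#' significance over the gene universe and tests for overrepresentation with
#' a one-sided Fisher exact test (enrichment direction), reporting the
#' sample odds ratio and BH q-values across sets.
#'
#' @param significant_genes character vector, subset of `universe`.
#' @param universe character vector of all genes with an assigned p-value.
#' @param sets data frame with columns `set`, `label`, `gene` (one row per
#'   set membership) or a named list of gene-id vectors.
#' @return data frame: `set`, `label`, `a`, `b`, `c`, `d` (table counts),
#'   `odds_ratio`, `p`, `q`.
#' @export
overrepresentation_test <- function(significant_genes, universe, sets) {
  if (is.list(sets) && !is.data.frame(sets))
    sets <- data.frame(set = rep(names(sets), lengths(sets)),
                       label = rep(names(sets), lengths(sets)),
                       gene = unlist(sets, use.names = FALSE))
  if (!all(significant_genes %in% universe))
    stop("significant_genes must be a subset of the universe")
  sets <- sets[sets$gene %in% universe, , drop = FALSE]
  sig <- unique(significant_genes)
  out <- do.call(rbind, lapply(split(sets, sets$set), function(s) {
    members <- unique(s$gene)
    a <- length(intersect(members, sig))
    b <- length(sig) - a
    cc <- length(members) - a
    d <- length(universe) - a - b - cc
    p <- if (!length(sig)) 1 else
      stats::fisher.test(matrix(c(a, b, cc, d), 2), alternative = "greater")$p.value
    or <- (a * d) / max(b * cc, .Machine$double.xmin)
    data.frame(set = s$set[1], label = s$label[1], a = a, b = b, c = cc,
               d = d, odds_ratio = or, p = p)
  }))
  rownames(out) <- NULL
  out$q <- bh_fdr(out$p)
  out[order(out$p), ]
}

#' Gene sets enriched in two independent scans
#'
#' Runs [overrepresentation_test()] on the nominally significant genes of
#' two per-gene scans sharing a universe and reports the sets enriched at
#' `alpha` in both.
#'
#' @param genes_a,genes_b data frames with `gene` and `p` columns (per-gene
#'   p-values of scans A and B over the same universe).
#' @param sets gene-set map as for [overrepresentation_test()].
#' @param sig_p per-gene threshold defining "significant genes" (nominal).
#' @param alpha enrichment significance threshold applied to each scan.
#' @return list: `common` (sets enriched in both, with both p-values),
#'   `scan_a`, `scan_b` (full enrichment tables).
#' @export
compare_scans <- function(genes_a, genes_b, sets, sig_p = 0.05, alpha = 0.05) {
  ua <- unique(genes_a$gene); ub <- unique(genes_b$gene)
  universe <- intersect(ua, ub)
  if (!length(universe)) stop("scans share no genes")
  ea <- overrepresentation_test(genes_a$gene[genes_a$p < sig_p & genes_a$gene %in% universe],
                                universe, sets)
  eb <- overrepresentation_test(genes_b$gene[genes_b$p < sig_p & genes_b$gene %in% universe],
                                universe, sets)
  common_sets <- intersect(ea$set[ea$p < alpha], eb$set[eb$p < alpha])
  common <- merge(ea[ea$set %in% common_sets, c("set", "label", "p")],
                  eb[eb$set %in% common_sets, c("set", "p")],
                  by = "set", suffixes = c("_a", "_b"))
  list(common = common, scan_a = ea, scan_b = eb)
}
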