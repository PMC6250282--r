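#' Rockwood-style Frailty Index from a binary deficit table
#'
#' The Frailty Index (FI) of an individual is the proportion of health
#' deficits present among those assessed: `fi = deficits present / items
#' used`. Items can be excluded wholesale (e.g. a pain item, to avoid overlap
#' with a pain phenotype); items missing for an individual are dropped from
#' both numerator and denominator. Individuals missing more than
#' `max_missing_fraction` of the usable items receive a missing FI.
#'
#' @param deficits numeric matrix (individuals x items) with entries 0, 1 or
#'   NA; rownames are individual ids.
#' @param exclude_items character vector of item (column) names to exclude.
#' @param max_missing_fraction maximum tolerated fraction of missing items.
#' @return data frame with columns `individual_id`, `fi`, `n_items_used`.
#' @export
compute_fi <- function(deficits, exclude_items = character(),
                       max_missing_fraction = 0.2) {
  deficits <- as.matrix(deficits)
  bad <- !is.na(deficits) & !(deficits %in% c(0, 1))
  if (any(bad)) stop("deficit table has non-binary entries")
  unknown <- setdiff(exclude_items, colnames(deficits))
  if (length(unknown))
    stop("exclude_items not found: ", paste(unknown, collapse = ", "))
  keep <- setdiff(colnames(deficits), exclude_items)
  if (!length(keep)) stop("all items excluded")
  d <- deficits[, keep, drop = FALSE]
  n_used <- rowSums(!is.na(d))
  fi <- rowSums(d, na.rm = TRUE) / pmax(n_used, 1L)
  miss_frac <- 1 - n_used / length(keep)
  drop <- miss_frac > max_missing_fraction | n_used == 0L
  if (any(n_used == 0L))
    warning(sum(n_used == 0L), " individual(s) with zero usable items; FI set missing")
  fi[drop] <- NA_real_
  data.frame(individual_id = rownames(d) %||% as.character(seq_len(nrow(d))),
             fi = fi, n_items_used = as.integer(n_used), row.names = NULL)
}

#' Within-pair FI discordance, weighted by the pair mean
#'
#' For co-twins with FI scores `fi1` and `fi2`, the discordance is
#' `d = (fi1 - fi2) / (0.5 * (fi1 + fi2))`: the intrapair difference relative
#' to the pair mean. It is antisymmetric in twin order, scale-invariant, and
#' bounded in \[-2, 2\]. Undefined when both FI scores are zero.
#'
#' @param fi_twin1,fi_twin2 FI scores of the two co-twins (vectorized).
#' @param family_id optional family ids for the output.
#' @return data frame with columns `family_id`, `d`, `abs_d`; `d` is NA (with
#'   a warning) where both scores are zero.
#' @export
pair_discordance <- function(fi_twin1, fi_twin2, family_id = NULL) {
  stopifnot(length(fi_twin1) == length(fi_twin2))
  s <- fi_twin1 + fi_twin2
  zero <- !is.na(s) & s == 0
  if (any(zero))
    warning(sum(zero), " pair(s) with both FI scores zero; discordance undefined")
  d <- ifelse(zero, NA_real_, (fi_twin1 - fi_twin2) / (0.5 * s))
  data.frame(
    family_id = family_id %||% as.character(seq_along(d)),
    d = d, abs_d = abs(d), row.names = NULL
  )
}

#' Select the k most FI-discordant twin pairs
#'
#' Ranks pairs by `|d|` (two-sided discordance; the downstream paired test is
#' two-sided) and returns the top `k` family ids. Ties are broken by family
#' id in increasing order, so the selection is stable and reproducible.
#' Pairs with undefined discordance are excluded before ranking.
#'
#' @param discordances data frame as returned by [pair_discordance()].
#' @param k number of pairs to select.
#' @return character vector of `k` family ids.
#' @export
select_discordant_pairs <- function(discordances, k) {
  ok <- discordances[!is.na(discordances$abs_d), , drop = FALSE]
  if (k > nrow(ok))
    stop(sprintf("k = %d exceeds the %d pairs with defined discordance",
                 k, nrow(ok)))
  ord <- order(-ok$abs_d, ok$family_id)
  ok$family_id[ord[seq_len(k)]]
}

#' FI per twin of each complete pair, oriented higher-FI twin first
#'
#' Convenience used by the discordant-twin EWAS: joins FI scores onto the
#' cohort, keeps complete MZ pairs, and orients each pair so the twin with
#' the higher FI comes first ("affected" convention for the paired test).
#'
#' @param fi data frame from [compute_fi()].
#' @param cohort cohort data frame (`individual_id`, `family_id`, `zygosity`,
#'   `twin_order`).
#' @param zygosity which zygosity to keep (default MZ).
#' @return data frame with one row per pair: `family_id`, `id_high`, `id_low`,
#'   `fi_high`, `fi_low`.
#' @export
pair_fi_table <- function(fi, cohort, zygosity = "MZ") {
  m <- merge(cohort[cohort$zygosity %in% zygosity,
                    c("individual_id", "family_id", "twin_order")],
             fi, by = "individual_id")
  m <- m[!is.na(m$fi), ]
  sp <- split(m, m$family_id)
  sp <- sp[vapply(sp, nrow, 0L) == 2L]
  out <- do.call(rbind, lapply(sp, function(p) {
    p <- p[order(p$twin_order), ]
    hi <- which.max(p$fi)  # ties: lower twin_order is "high"
    data.frame(family_id = p$family_id[1],
               id_high = p$individual_id[hi], id_low = p$individual_id[3 - hi],
               fi_high = p$fi[hi], fi_low = p$fi[3 - hi])
  }))
  rownames(out) <- NULL
  out
}
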