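#' Default pipeline configuration
#'
#' Declarative configuration for [run_pipeline()]: a synthetic-cohort
#' specification (any [cohort_config()] argument under `cohort`), stage
#' toggles, and the analysis thresholds (metabolite FDR threshold 5e-4,
#' 50 discordant pairs, SNP QC call rate 0.95 and HWE p 1e-4).
#'
#' @param out_dir output directory.
#' @param seed integer seed for the whole run.
#' @param ... overrides for any top-level field.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, ...) {
  cfg <- list(
    out_dir = out_dir,
    seed = seed,
    cohort = list(n_mz_pairs = 300, n_dz_pairs = 200, n_singletons = 100,
                  n_metabolites = 120, n_unknown_metabolites = 20,
                  n_snps = 500, n_bins = 2000, n_genes = 100,
                  cwp_fi_effect = 0.3, use_default_planted = TRUE),
    stages = list(simulate = TRUE, fi = TRUE, metab = TRUE, gwas = TRUE,
                  ewas = TRUE, enrich = TRUE, varcomp = TRUE, path = TRUE),
    fdr_alpha = 5e-4,
    k_pairs = 50,
    qc = list(min_call = 0.95, min_hwe_p = 1e-4),
    ls_alpha = 0.05,
    exclude_items = character(),
    enrich_sig_p = 0.05
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(cfg[[nm]]) && is.list(dots[[nm]]))
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    else cfg[[nm]] <- dots[[nm]]
  }
  structure(cfg, class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' @param path YAML file with top-level fields as in [pipeline_config()].
#' @return `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$out_dir)) stop("config must name out_dir")
  do.call(pipeline_config,
          c(list(out_dir = y$out_dir, seed = y$seed %||% 1L),
            y[setdiff(names(y), c("out_dir", "seed"))]))
}

#' Run the full analysis pipeline
#'
#' Executes, in order: cohort simulation, Frailty Index construction and
#' discordance ranking, metabolite normalization/filtering/scan/joint model,
#' SNP QC and genome scans, the discordant-twin EWAS with Fisher combination
#' and gene assignment, gene-set enrichment comparison of the EWAS and GWAS
#' gene lists, ACE variance decomposition (univariate FI, bivariate
#' FI x CWP), and the two-stage path analysis. Every stage writes its
#' outputs as TSV under `config$out_dir`; a machine-readable run report
#' (`report.json`) records seeds, versions, per-stage record counts and
#' wall-times. Runs are deterministic given identical config and seed.
#'
#' Disabling a stage skips it; stages depending on a disabled one are
#' skipped with a warning.
#'
#' @param config a [pipeline_config()] (or path to a YAML file).
#' @return invisibly, the run report list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(seed = config$seed,
                 r_version = R.version.string,
                 package_version = as.character(utils::packageVersion("frailtyomics")),
                 stages = list())
  t_all <- proc.time()[3]
  stage <- function(name, enabled, deps, fun) {
    if (!enabled) {
      message("stage ", name, ": disabled")
      return(NULL)
    }
    missing_dep <- deps[!deps %in% names(report$stages)]
    if (length(missing_dep)) {
      warning("stage ", name, " skipped: requires disabled stage(s) ",
              paste(missing_dep, collapse = ", "))
      return(NULL)
    }
    t0 <- proc.time()[3]
    out <- tryCatch(fun(), error = function(e)
      stop("stage `", name, "` failed: ", conditionMessage(e), call. = FALSE))
    report$stages[[name]] <<- c(out$counts,
                                list(seconds = round(proc.time()[3] - t0, 2)))
    out$value
  }
  st <- config$stages
  p <- function(f) file.path(config$out_dir, f)

  sim <- stage("simulate", st$simulate, character(), function() {
    cc_args <- config$cohort
    use_def <- isTRUE(cc_args$use_default_planted)
    cc_args$use_default_planted <- NULL
    cc_args$seed <- config$seed
    cfg <- do.call(cohort_config, cc_args)
    if (use_def && is.null(cc_args$planted_effects)) {
      cc_args$planted_effects <- default_planted_effects(cfg)
      cfg <- do.call(cohort_config, cc_args)
    }
    s <- simulate_cohort(cfg)
    write_cohort(s, config$out_dir)
    list(value = s, counts = list(n_individuals = nrow(s$cohort),
                                  n_metabolites = ncol(s$metabolites),
                                  n_snps = ncol(s$genotypes),
                                  n_bins = ncol(s$bins_t1)))
  })

  fi_res <- stage("fi", st$fi, "simulate", function() {
    fi <- compute_fi(sim$deficits, exclude_items = config$exclude_items)
    write_tsv(fi, p("fi.tsv"))
    pt <- pair_fi_table(fi, sim$cohort)
    disc <- pair_discordance(pt$fi_high, pt$fi_low, pt$family_id)
    write_tsv(disc, p("discordance.tsv"))
    sel <- select_discordant_pairs(disc, min(config$k_pairs, nrow(disc)))
    gr1 <- pt[pt$family_id %in% sel, ]
    write_tsv(gr1, p("pairs.tsv"))
    list(value = list(fi = fi, pairs = gr1),
         counts = list(n_fi = sum(!is.na(fi$fi)), n_selected_pairs = nrow(gr1)))
  })

  metab <- stage("metab", st$metab, c("simulate", "fi"), function() {
    norm <- normalize_metabolites(sim$metabolites, sim$run_day)
    filt <- filter_metabolites(norm, sim$metabolite_info)
    co <- sim$cohort
    scan <- single_metabolite_scan(fi_res$fi, filt$matrix, co$age)
    write_tsv(scan, p("metab_scan.tsv"))
    sel <- scan$feature[scan$q < config$fdr_alpha]
    joint <- NULL
    if (length(sel)) {
      joint <- multivariable_selection(
        fi_res$fi, filt$matrix[, sel, drop = FALSE],
        cbind(age = co$age, fat_h2 = co$fat_h2), co)
      write_tsv(data.frame(term = rownames(joint$gls), joint$gls,
                           check.names = FALSE), p("metab_joint.tsv"))
    }
    list(value = list(matrix = filt$matrix, scan = scan, selected = sel,
                      joint = joint),
         counts = list(n_tested = nrow(scan), n_selected = length(sel)))
  })

  gwas <- stage("gwas", st$gwas, c("simulate", "fi"), function() {
    qc <- snp_qc(sim$genotypes, sim$snps,
                 config$qc$min_call, config$qc$min_hwe_p)
    co <- sim$cohort
    fi_v <- fi_res$fi$fi[match(rownames(qc$genotypes), fi_res$fi$individual_id)]
    covars <- cbind(age = co$age, fat_h2 = co$fat_h2)
    scan_fi <- additive_scan(fi_v, qc$genotypes, qc$snps, covars)
    write_tsv(scan_fi, p("gwas_fi.tsv"))
    met_scans <- list()
    if (!is.null(metab) && length(metab$selected)) {
      for (m in metab$selected) {
        met_scans[[m]] <- additive_scan(metab$matrix[, m], qc$genotypes,
                                        qc$snps, covars)
        write_tsv(met_scans[[m]], p(paste0("gwas_", m, ".tsv")))
      }
    }
    list(value = list(qc = qc, fi = scan_fi, metabolites = met_scans),
         counts = list(n_snps_retained = nrow(qc$snps),
                       lambda_fi = round(attr(scan_fi, "lambda"), 3)))
  })

  ewas <- stage("ewas", st$ewas, c("simulate", "fi"), function() {
    ls <- ls_bin_filter(sim$bins_t1, sim$bins_t2, config$ls_alpha)
    B <- sim$bins_t1[, ls$retained, drop = FALSE]
    gr1_ids <- c(fi_res$pairs$id_high, fi_res$pairs$id_low)
    pt <- paired_bin_test(B, fi_res$pairs)
    gr2_ids <- setdiff(rownames(B), gr1_ids)
    cs <- correlation_bin_scan(B, fi_res$fi, gr2_ids, gr1_ids)
    comb <- combine_ewas(pt, cs)
    write_tsv(comb, p("ewas.tsv"))
    conc <- concordance_filter(comb)
    ga <- assign_bins_to_genes(
      conc, sim$bins, sim$genes)
    write_tsv(ga$per_gene, p("ewas_genes.tsv"))
    list(value = list(combined = comb, concordant = conc, genes = ga),
         counts = list(n_ls_bins = length(ls$retained),
                       n_concordant = nrow(conc),
                       n_genes = nrow(ga$per_gene)))
  })

  enrich <- stage("enrich", st$enrich, c("ewas", "gwas"), function() {
    # gene lists: EWAS per-gene combined p; GWAS per-gene best-SNP p via
    # nearest-gene assignment of SNP positions
    snp_bed <- data.frame(chrom = gwas$fi$chrom, start = gwas$fi$pos - 1,
                          end = gwas$fi$pos, bin = gwas$fi$feature)
    snp_genes <- assign_bins_to_genes(
      data.frame(bin = gwas$fi$feature, p_combined = gwas$fi$p),
      snp_bed, sim$genes)
    ewas_genes <- ewas$genes$per_gene
    # synthetic gene sets: contiguous blocks of the annotation
    genes_all <- sim$genes$gene
    sets <- data.frame(
      set = paste0("set", (seq_along(genes_all) - 1) %/% 10 + 1),
      label = paste0("block", (seq_along(genes_all) - 1) %/% 10 + 1),
      gene = genes_all)
    cmp <- compare_scans(
      data.frame(gene = ewas_genes$gene, p = ewas_genes$p_combined),
      data.frame(gene = snp_genes$per_gene$gene, p = snp_genes$per_gene$p_combined),
      sets, sig_p = config$enrich_sig_p)
    write_tsv(cmp$scan_a, p("enrich_ewas.tsv"))
    write_tsv(cmp$scan_b, p("enrich_gwas.tsv"))
    write_tsv(cmp$common, p("enrich_common.tsv"))
    list(value = cmp, counts = list(n_sets = length(unique(sets$set)),
                                    n_common = nrow(cmp$common)))
  })

  varcomp <- stage("varcomp", st$varcomp, c("simulate", "fi"), function() {
    co <- sim$cohort
    covars <- cbind(age = co$age, fat_h2 = co$fat_h2, smoking = co$smoking)
    uni <- fit_ace_univariate(fi_res$fi$fi[match(co$individual_id,
                                                 fi_res$fi$individual_id)],
                              co, covars)
    biv <- fit_bivariate(co$fi_liability, co$cwp_status, co, covars)
    rep_fit <- function(f) f[c("a2", "c2", "e2", "rg", "rc", "re",
                               "threshold", "loglik", "converged")]
    jsonlite::write_json(list(univariate_fi = rep_fit(uni),
                              bivariate = rep_fit(biv)),
                         p("varcomp.json"), auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    list(value = list(univariate = uni, bivariate = biv),
         counts = list(a2_fi = round(uni$a2, 4),
                       rg = round(biv$rg, 4)))
  })

  path <- stage("path", st$path, c("simulate", "fi", "metab"), function() {
    co <- sim$cohort
    fi_v <- fi_res$fi$fi[match(co$individual_id, fi_res$fi$individual_id)]
    med <- sim$truth$planted_effects
    med_ids <- med$feature[med$layer == "metabolite" & med$mediated]
    covars <- data.frame(age = co$age, fat_h2 = co$fat_h2,
                         smoking = co$smoking)
    for (m in intersect(med_ids, colnames(metab$matrix)))
      covars[[m]] <- metab$matrix[, m]
    pf <- fit_path(fi_v, co$cwp_status, covars, family_id = co$family_id)
    jsonlite::write_json(list(
      cwp_effect = attr(pf$effects, "cwp_effect"),
      cwp_effect_se = attr(pf$effects, "cwp_effect_se"),
      stage1 = pf$stage1$coefficients,
      stage2 = pf$stage2$coefficients,
      effects = as.data.frame(pf$effects)),
      p("path.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
    list(value = pf, counts = list(n = pf$stage1$n))
  })

  report$total_seconds <- round(proc.time()[3] - t_all, 2)
  jsonlite::write_json(report, p("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(report)
}
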