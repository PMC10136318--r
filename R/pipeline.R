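#' Run the divergence scan end to end
#'
#' Reads the VCF, population map and (optionally) gene annotation, builds
#' the sliding-window grid, computes window statistics, calls joint
#' top-quantile outlier windows, merges them into divergent regions,
#' assigns genes and ranks candidates. Writes
#' `<out_prefix>.windows.tsv`, `<out_prefix>.regions.bed`,
#' `<out_prefix>.genes.tsv` (when an annotation is given) and
#' `<out_prefix>.manifest.txt`. Identical inputs and parameters
#' reproduce the outputs byte for byte (the pipeline draws no random
#' numbers).
#'
#' @param vcf path to the VCF.
#' @param popmap path to the population map (sample, population).
#' @param group_a,group_b population labels for the contrast sides.
#' @param genes optional path to the gene BED.
#' @param out_prefix output path prefix.
#' @param window_size_bp,step_bp,outlier_quantile,min_snps scan
#'   parameters (defaults 40000, 10000, 0.95, 10).
#' @param min_call_rate_per_group site filter applied at read time.
#' @param n_fst,n_pi gene-ranking list sizes.
#' @return list: `windows` (with `selected`), `regions`, `gene_ranking`
#'   (or `NULL`), `manifest` (named counts), `paths`.
#' @export
run_scan_pipeline <- function(vcf, popmap, group_a, group_b,
                              genes = NULL, out_prefix,
                              window_size_bp = 40000, step_bp = 10000,
                              outlier_quantile = 0.95, min_snps = 10,
                              min_call_rate_per_group = 0.5,
                              n_fst = 50, n_pi = 50) {
  if (step_bp > window_size_bp) {
    stop("usage error: step_bp (", step_bp,
         ") exceeds window_size_bp (", window_size_bp, ")")
  }
  if (!file.exists(vcf)) stop("usage error: VCF not found: ", vcf)
  if (!file.exists(popmap)) stop("usage error: popmap not found: ", popmap)
  contrast <- read_popmap(popmap, group_a, group_b)
  tab <- read_vcf(vcf, contrast, min_call_rate_per_group)
  gene_models <- if (!is.null(genes)) read_genes_bed(genes) else NULL

  grid <- make_windows(tab$contig_lengths, window_size_bp, step_bp)
  stats <- window_stats(tab, contrast, grid, min_snps = min_snps)
  stats <- call_outlier_windows(stats, outlier_quantile)
  regions <- merge_regions(stats)
  ranking <- NULL
  if (!is.null(gene_models)) {
    regions <- assign_genes(regions, gene_models)
    ranking <- rank_top_genes(stats, gene_models, n_fst, n_pi)
  }

  paths <- list(windows = paste0(out_prefix, ".windows.tsv"),
                regions = paste0(out_prefix, ".regions.bed"),
                genes = paste0(out_prefix, ".genes.tsv"),
                manifest = paste0(out_prefix, ".manifest.txt"))
  write_window_stats(stats, paths$windows)
  write_regions_bed(regions, paths$regions)
  if (!is.null(ranking)) {
    out_rank <- ranking
    out_rank$best_pi_ratio <- ifelse(is.finite(out_rank$best_pi_ratio),
                                     sprintf("%.6g", out_rank$best_pi_ratio),
                                     "Inf")
    out_rank$best_fst <- sprintf("%.6g", as.numeric(ranking$best_fst))
    utils::write.table(out_rank, paths$genes, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    paths$genes <- NULL
  }
  manifest <- c(
    n_sites = n_sites(tab), n_samples = n_samples(tab),
    windows_total = nrow(stats), windows_retained = sum(stats$retained),
    windows_selected = sum(stats$selected), regions = nrow(regions),
    genes_in_regions =
      if (!is.null(attr(regions, "n_genes_union")))
        attr(regions, "n_genes_union") else NA,
    genes_ranked = if (!is.null(ranking)) nrow(ranking) else NA
  )
  write_manifest(paths$manifest, "scan", manifest, list(
    vcf = vcf, popmap = popmap, genes = genes,
    group_a = paste(group_a, collapse = ","),
    group_b = paste(group_b, collapse = ","),
    window_size_bp = window_size_bp, step_bp = step_bp,
    outlier_quantile = outlier_quantile, min_snps = min_snps,
    min_call_rate_per_group = min_call_rate_per_group,
    n_fst = n_fst, n_pi = n_pi))
  list(windows = stats, regions = regions, gene_ranking = ranking,
       manifest = manifest, paths = paths)
}

#' Run the candidate-variant follow-up end to end
#'
#' Inside one region of interest, runs the fixed stage order: exact
#' allele-frequency tests, then genotype-differentiation flags on the
#' significant sites, then genotype-phenotype segregation of the
#' differentiated sites (expected genotypes derived from the modal
#' genotypes of the phenotype classes within the discovery contrast
#' groups), then composite-LD grouping of the differentiated sites. Each
#' stage consumes the previous stage's survivors. Writes
#' `<out_prefix>.snps.tsv`, `<out_prefix>.segregation.tsv`,
#' `<out_prefix>.ld_r2.tsv` and `<out_prefix>.manifest.txt`.
#'
#' @param vcf path to the VCF.
#' @param popmap path to the population map.
#' @param group_a,group_b contrast population labels.
#' @param region region of interest, `"contig:start-end"`.
#' @param phenotype path to the phenotype TSV (sample, class).
#' @param out_prefix output path prefix.
#' @param alpha significance level for the frequency test.
#' @param fix_threshold modal-genotype frequency for differentiation.
#' @param min_call_rate_per_group site filter applied at read time.
#' @return list: `tests`, `differentiation`, `segregation` (per-site
#'   list), `ld` (or `NULL`), `manifest`, `paths`.
#' @export
run_followup_pipeline <- function(vcf, popmap, group_a, group_b, region,
                                  phenotype, out_prefix, alpha = 0.05,
                                  fix_threshold = 0.8,
                                  min_call_rate_per_group = 0.5) {
  for (f in c(vcf, popmap, phenotype)) {
    if (!file.exists(f)) stop("usage error: input not found: ", f)
  }
  reg <- parse_region(region)
  contrast <- read_popmap(popmap, group_a, group_b,
                          phenotype_path = phenotype)
  tab <- read_vcf(vcf, contrast, min_call_rate_per_group)
  idx <- sites_in_region(tab, reg$contig, reg$start, reg$end)

  paths <- list(snps = paste0(out_prefix, ".snps.tsv"),
                segregation = paste0(out_prefix, ".segregation.tsv"),
                ld = paste0(out_prefix, ".ld_r2.tsv"),
                manifest = paste0(out_prefix, ".manifest.txt"))
  if (length(idx) == 0) {
    warning("region ", region, " contains no SNP; writing empty outputs")
    utils::write.table(
      data.frame(site = integer(), contig = character(), pos = integer(),
                 p_value = numeric(), significant = logical(),
                 differentiated = logical()),
      paths$snps, sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines("snp\tpopulation\tn\tyes\tno", paths$segregation)
    writeLines("", paths$ld)
    write_manifest(paths$manifest, "followup",
                   c(n_region_snps = 0, n_significant = 0,
                     n_differentiated = 0, n_ld_groups = 0),
                   list(vcf = vcf, region = region))
    return(list(tests = NULL, differentiation = NULL, segregation = NULL,
                ld = NULL,
                manifest = c(n_region_snps = 0, n_significant = 0,
                             n_differentiated = 0, n_ld_groups = 0),
                paths = paths))
  }

  tests <- allele_freq_test(tab, contrast, idx, alpha = alpha)
  sig <- tests$site[tests$significant]
  diff <- if (length(sig) > 0) {
    genotype_differentiation(tab, contrast, sig, fix_threshold)
  } else NULL
  surv <- if (!is.null(diff)) diff$site[diff$differentiated] else integer(0)

  seg_tabs <- list()
  if (length(surv) > 0) {
    for (s in surv) {
      rule <- derive_segregation_rule(tab, contrast, s)
      seg <- segregation_score(tab$dosage[, s],
                               contrast$phenotype,
                               contrast$populations, rule)
      seg$snp <- paste0(tab$sites$contig[s], ":", tab$sites$pos[s])
      seg_tabs[[as.character(s)]] <- seg
    }
  }
  ld <- if (length(surv) >= 2) ld_r2(tab, surv) else NULL

  out_tests <- merge(tests,
                     if (!is.null(diff))
                       diff[, c("site", "modal_a", "modal_b",
                                "differentiated")]
                     else data.frame(site = integer(), modal_a = numeric(),
                                     modal_b = numeric(),
                                     differentiated = logical()),
                     by = "site", all.x = TRUE, sort = TRUE)
  utils::write.table(out_tests, paths$snps, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (length(seg_tabs) > 0) {
    seg_all <- do.call(rbind, seg_tabs)
    seg_all <- seg_all[, c("snp", "population", "n", "yes", "no")]
    utils::write.table(seg_all, paths$segregation, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else {
    writeLines("snp\tpopulation\tn\tyes\tno", paths$segregation)
  }
  if (!is.null(ld)) {
    utils::write.table(ld$r2, paths$ld, sep = "\t", quote = FALSE,
                       row.names = TRUE, col.names = NA)
  } else {
    writeLines("", paths$ld)
  }
  manifest <- c(n_region_snps = length(idx),
                n_significant = length(sig),
                n_differentiated = length(surv),
                n_ld_groups = if (!is.null(ld)) length(ld$groups) else 0)
  write_manifest(paths$manifest, "followup", manifest, list(
    vcf = vcf, popmap = popmap, phenotype = phenotype, region = region,
    group_a = paste(group_a, collapse = ","),
    group_b = paste(group_b, collapse = ","),
    alpha = alpha, fix_threshold = fix_threshold,
    min_call_rate_per_group = min_call_rate_per_group))
  list(tests = tests, differentiation = diff, segregation = seg_tabs,
       ld = ld, manifest = manifest, paths = paths)
}

#' Derive the expected-genotype rule for segregation scoring
#'
#' The phenotype-positive (case) class expects the modal genotype of the
#' case individuals belonging to the discovery contrast groups; the
#' control class expects the modal genotype of the discovery controls.
#'
#' @param x a [variant_table()].
#' @param contrast a [contrast_map()] carrying a phenotype.
#' @param site site index.
#' @return list with `case` and `control` dosage sets.
#' @export
derive_segregation_rule <- function(x, contrast, site) {
  disc <- c(contrast_samples(contrast, "a"), contrast_samples(contrast, "b"))
  modal_of <- function(class) {
    smp <- disc[contrast$phenotype[disc] == class]
    d <- x$dosage[smp, site]
    d <- d[!is.na(d)]
    if (length(d) == 0) return(numeric(0))
    tab <- tabulate(d + 1, nbins = 3)
    which.max(tab) - 1
  }
  list(case = modal_of("case"), control = modal_of("control"))
}

parse_region <- function(region) {
  m <- regmatches(region,
                  regexec("^([^:]+):([0-9,]+)-([0-9,]+)$", region))[[1]]
  if (length(m) != 4) {
    stop("usage error: region must be contig:start-end, got ", region)
  }
  start <- as.integer(gsub(",", "", m[3]))
  end <- as.integer(gsub(",", "", m[4]))
  if (start > end) stop("usage error: region start exceeds end")
  list(contig = m[2], start = start, end = end)
}

write_manifest <- function(path, stage, counts, params) {
  lines <- c(
    paste0("stage\t", stage),
    paste0("param.", names(params), "\t",
           vapply(params, function(p)
             if (is.null(p)) "NA" else as.character(p), "")),
    paste0("count.", names(counts), "\t", as.character(counts))
  )
  writeLines(lines, path)
  invisible(path)
}
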