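#' Configure the two-population genotype simulator
#'
#' Defaults describe a desk-scale stand-in for a domestication
#' resequencing study: a 10-Mb genome in ten 1-Mb contigs at 2.2 SNPs/kb,
#' 20 + 20 diploids, background differentiation F = 0.1 under the
#' Balding-Nichols model, and (unless disabled) twenty 40-kb sweeps in
#' which the domestic-side population loses diversity tenfold and the
#' ancestral major allele is pushed to a frequency of at least 0.95.
#'
#' @param seed integer seed governing every draw.
#' @param n_contigs number of contigs.
#' @param contig_length_bp length of each contig (bp).
#' @param snp_density_per_kb expected SNPs per kb (default 2.2).
#' @param n_diploids_a,n_diploids_b samples per group (group A = wild
#'   side, group B = domestic side).
#' @param background_fst Balding-Nichols divergence parameter F.
#' @param sweep_intervals data.frame (`contig`, `start`, `end`) of
#'   implanted sweeps; `NULL` places `sweeps_per_contig` non-overlapping
#'   40-kb sweeps per contig on the 10-kb grid; use a 0-row data.frame
#'   for a neutral (no-sweep) genome.
#' @param sweeps_per_contig used only when `sweep_intervals` is `NULL`.
#' @param sweep_length_bp sweep length for auto placement.
#' @param sweep_pi_reduction minimum expected fold-reduction of group-B
#'   per-site diversity inside sweeps (default 10).
#' @param sweep_freq_shift minimum group-B frequency of the ancestral
#'   major allele inside sweeps (default 0.95).
#' @param n_causal_phenotype_snps causal SNPs (each with a copied linked
#'   partner) implanted in the first sweep interval(s).
#' @param n_genes genes tiled uniformly over the genome.
#' @param gene_length_bp gene length for the tiling.
#' @param ancestral_beta shape parameters of the ancestral-frequency law
#'   (Beta, truncated to `ancestral_range`).
#' @param ancestral_range truncation keeping every site polymorphic
#'   somewhere.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_contigs = 10,
                       contig_length_bp = 1e6,
                       snp_density_per_kb = 2.2,
                       n_diploids_a = 20,
                       n_diploids_b = 20,
                       background_fst = 0.1,
                       sweep_intervals = NULL,
                       sweeps_per_contig = 2,
                       sweep_length_bp = 40000,
                       sweep_pi_reduction = 10,
                       sweep_freq_shift = 0.95,
                       n_causal_phenotype_snps = 1,
                       n_genes = 200,
                       gene_length_bp = 20000,
                       ancestral_beta = c(0.8, 0.8),
                       ancestral_range = c(0.05, 0.95)) {
  stopifnot(snp_density_per_kb > 0,
            background_fst > 0, background_fst < 1)
  contigs <- sprintf("ctg%02d", seq_len(n_contigs))
  if (is.null(sweep_intervals)) {
    sweep_intervals <- auto_sweeps(contigs, contig_length_bp,
                                   sweeps_per_contig, sweep_length_bp)
  }
  if (nrow(sweep_intervals) > 0) {
    bad <- sweep_intervals$start < 1 |
      sweep_intervals$end > contig_length_bp |
      !(sweep_intervals$contig %in% contigs)
    if (any(bad)) stop("sweep interval outside its contig")
    for (ctg in unique(sweep_intervals$contig)) {
      s <- sweep_intervals[sweep_intervals$contig == ctg, , drop = FALSE]
      s <- s[order(s$start), , drop = FALSE]
      if (nrow(s) > 1 && any(s$start[-1] <= s$end[-nrow(s)])) {
        stop("overlapping sweep intervals on ", ctg)
      }
    }
  }
  structure(list(
    seed = seed, n_contigs = n_contigs,
    contigs = contigs,
    contig_length_bp = contig_length_bp,
    snp_density_per_kb = snp_density_per_kb,
    n_diploids_a = n_diploids_a, n_diploids_b = n_diploids_b,
    background_fst = background_fst,
    sweep_intervals = sweep_intervals,
    sweep_pi_reduction = sweep_pi_reduction,
    sweep_freq_shift = sweep_freq_shift,
    n_causal_phenotype_snps = n_causal_phenotype_snps,
    n_genes = n_genes, gene_length_bp = gene_length_bp,
    ancestral_beta = ancestral_beta,
    ancestral_range = ancestral_range
  ), class = "sim_config")
}

# evenly spaced sweep starts on the 10-kb grid, clear of contig edges
auto_sweeps <- function(contigs, len, per_contig, sweep_len) {
  if (per_contig == 0) {
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  starts <- round(len * seq_len(per_contig) / (per_contig + 1))
  starts <- floor(starts / 10000) * 10000 + 1
  do.call(rbind, lapply(contigs, function(ctg) {
    data.frame(contig = ctg, start = as.integer(starts),
               end = as.integer(starts + sweep_len - 1),
               stringsAsFactors = FALSE)
  }))
}

#' Simulate a two-population genotype dataset with implanted sweeps
#'
#' Draws SNP positions uniformly at the configured density (Poisson site
#' counts), ancestral frequencies from the truncated Beta law, population
#' frequencies from the Balding-Nichols model
#' `p_g ~ Beta(p0 (1-F)/F, (1-p0)(1-F)/F)` and genotypes as
#' `Binomial(2, p_g)` per diploid (Hardy-Weinberg within populations).
#' Inside sweep intervals the group-B (domestic-side) minor-allele
#' frequency relative to the ancestral major allele is set to
#' `min(eps, 1 - sweep_freq_shift) / sweep_pi_reduction`, which pushes
#' the major allele to at least `sweep_freq_shift` and reduces expected
#' group-B per-site diversity at least `sweep_pi_reduction`-fold. Causal
#' phenotype SNPs (dosage 2 in every case, 0 in every control, phenotype
#' = group membership) are implanted in the first sweep interval(s),
#' each with a linked partner site carrying a copied dosage vector.
#'
#' With `out_dir` set, writes `sim.vcf`, `popmap.tsv`, `genes.bed`,
#' `phenotype.tsv`, `truth_sweeps.bed` and `truth_causal.tsv`; the same
#' config and seed reproduce the files byte for byte.
#'
#' @param config a [sim_config()].
#' @param out_dir optional output directory (created if needed).
#' @return list with `table` ([variant_table()]), `contrast`
#'   ([contrast_map()] incl. phenotype), `genes`, `truth` (list:
#'   `sweeps`, `causal`, `freq_a`, `freq_b`) and, when written, `paths`.
#' @export
simulate_two_pop <- function(config, out_dir = NULL) {
  set.seed(config$seed)
  na <- config$n_diploids_a
  nb <- config$n_diploids_b
  samples_a <- sprintf("W%03d", seq_len(na))
  samples_b <- sprintf("D%03d", seq_len(nb))
  lambda <- config$snp_density_per_kb / 1000 * config$contig_length_bp

  site_list <- list()
  pa_list <- list()
  pb_list <- list()
  for (ctg in config$contigs) {
    n_snp <- stats::rpois(1, lambda)
    pos <- sort(sample.int(config$contig_length_bp, n_snp))
    p0 <- rbeta_trunc(n_snp, config$ancestral_beta[1],
                      config$ancestral_beta[2], config$ancestral_range)
    bg_f <- config$background_fst
    shp <- (1 - bg_f) / bg_f
    p_a <- stats::rbeta(n_snp, p0 * shp, (1 - p0) * shp)
    p_b <- stats::rbeta(n_snp, p0 * shp, (1 - p0) * shp)

    sw <- config$sweep_intervals
    sw <- sw[sw$contig == ctg, , drop = FALSE]
    if (nrow(sw) > 0) {
      in_sweep <- rep(FALSE, n_snp)
      for (k in seq_len(nrow(sw))) {
        in_sweep <- in_sweep | (pos >= sw$start[k] & pos <= sw$end[k])
      }
      if (any(in_sweep)) {
        p_b[in_sweep] <- sweep_shift_freq(
          p_b[in_sweep], p0[in_sweep],
          config$sweep_freq_shift, config$sweep_pi_reduction)
      }
    }
    alleles <- t(vapply(seq_len(n_snp), function(i)
      sample(c("A", "C", "G", "T"), 2), character(2)))
    site_list[[ctg]] <- data.frame(
      contig = ctg, pos = pos,
      ref = alleles[, 1], alt = alleles[, 2],
      stringsAsFactors = FALSE
    )
    pa_list[[ctg]] <- p_a
    pb_list[[ctg]] <- p_b
  }
  sites <- do.call(rbind, site_list)
  rownames(sites) <- NULL
  p_a <- unlist(pa_list, use.names = FALSE)
  p_b <- unlist(pb_list, use.names = FALSE)
  m <- nrow(sites)

  dosage <- rbind(
    matrix(stats::rbinom(na * m, 2, rep(p_a, each = na)), nrow = na),
    matrix(stats::rbinom(nb * m, 2, rep(p_b, each = nb)), nrow = nb)
  )
  rownames(dosage) <- c(samples_a, samples_b)

  contig_lengths <- stats::setNames(
    rep(config$contig_length_bp, config$n_contigs), config$contigs)
  table <- variant_table(sites, dosage, contig_lengths)

  populations <- stats::setNames(
    c(rep("wild", na), rep("domestic", nb)),
    c(samples_a, samples_b))
  phenotype <- stats::setNames(
    c(rep("control", na), rep("case", nb)),
    c(samples_a, samples_b))
  contrast <- contrast_map(populations, "wild", "domestic",
                           phenotype = phenotype)

  truth <- list(sweeps = config$sweep_intervals,
                causal = data.frame(contig = character(), pos = integer(),
                                    site = integer(), partner_site = integer(),
                                    stringsAsFactors = FALSE),
                freq_a = p_a, freq_b = p_b)
  n_causal <- min(config$n_causal_phenotype_snps,
                  nrow(config$sweep_intervals))
  if (n_causal > 0) {
    for (k in seq_len(n_causal)) {
      iv <- config$sweep_intervals[k, ]
      idx <- sites_in_region(table, iv$contig, iv$start, iv$end)
      if (length(idx) < 2) next
      causal <- idx[ceiling(length(idx) / 2)]
      partner <- idx[ceiling(length(idx) / 2) + 1]
      imp <- implant_causal_snp(table, iv, phenotype, penetrance = 1.0,
                                site = causal)
      table <- imp$table
      table$dosage[, partner] <- table$dosage[, causal]
      truth$causal <- rbind(truth$causal, data.frame(
        contig = iv$contig, pos = table$sites$pos[causal],
        site = causal, partner_site = partner, stringsAsFactors = FALSE))
    }
  }

  genes <- tile_genes(config)

  out <- list(table = table, contrast = contrast, genes = genes,
              truth = truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(
      vcf = file.path(out_dir, "sim.vcf"),
      popmap = file.path(out_dir, "popmap.tsv"),
      genes = file.path(out_dir, "genes.bed"),
      phenotype = file.path(out_dir, "phenotype.tsv"),
      truth_sweeps = file.path(out_dir, "truth_sweeps.bed"),
      truth_causal = file.path(out_dir, "truth_causal.tsv")
    )
    hdr <- sprintf(
      "##sweepscan_sim=<seed=%d,n_contigs=%d,contig_length=%d,density=%g,na=%d,nb=%d,fst=%g>",
      config$seed, config$n_contigs, as.integer(config$contig_length_bp),
      config$snp_density_per_kb, na, nb, config$background_fst)
    write_vcf(table, paths$vcf, extra_header = hdr)
    utils::write.table(
      data.frame(names(populations), unname(populations)),
      paths$popmap, sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE)
    writeLines(sprintf("%s\t%d\t%d\t%s\t0\t+", genes$contig,
                       genes$start - 1L, genes$end, genes$gene),
               paths$genes)
    utils::write.table(
      data.frame(names(phenotype), unname(phenotype)),
      paths$phenotype, sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE)
    sw <- truth$sweeps
    writeLines(c("#contig\tstart\tend",
                 if (nrow(sw)) sprintf("%s\t%d\t%d", sw$contig,
                                       sw$start - 1L, sw$end)),
               paths$truth_sweeps)
    utils::write.table(truth$causal, paths$truth_causal, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    out$paths <- paths
  }
  out
}

# truncated Beta via inverse-CDF so the truncation wastes no draws
rbeta_trunc <- function(n, shape1, shape2, range) {
  lo <- stats::pbeta(range[1], shape1, shape2)
  hi <- stats::pbeta(range[2], shape1, shape2)
  stats::qbeta(stats::runif(n, lo, hi), shape1, shape2)
}

# push swept-population frequencies toward fixation of the ancestral
# major allele: resulting minor-allele frequency is
# min(eps, 1 - shift) / pi_reduction
sweep_shift_freq <- function(p_b, p0, shift, pi_reduction) {
  alt_major <- p0 >= 0.5
  major_freq <- ifelse(alt_major, p_b, 1 - p_b)
  eps <- pmin(1 - major_freq, 1 - shift) / pi_reduction
  ifelse(alt_major, 1 - eps, eps)
}

# n_genes genes tiled evenly across contigs
tile_genes <- function(config) {
  per_contig <- ceiling(config$n_genes / config$n_contigs)
  rows <- list()
  g <- 0
  for (ctg in config$contigs) {
    starts <- round(seq(1, config$contig_length_bp - config$gene_length_bp,
                        length.out = per_contig))
    for (s in starts) {
      g <- g + 1
      if (g > config$n_genes) break
      rows[[g]] <- data.frame(
        gene = sprintf("gene%04d", g), contig = ctg,
        start = as.integer(s),
        end = as.integer(s + config$gene_length_bp - 1),
        strand = "+", stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Implant a phenotype-linked causal SNP
#'
#' Overwrites the genotypes at one site inside `interval` so that, at
#' penetrance 1, the genotype segregates perfectly with the phenotype
#' (dosage 2 for every case, 0 for every control). At penetrance `q`,
#' `round((1 - q) * n)` individuals are forced to carry the contradicting
#' homozygous genotype instead, chosen at random from the current RNG
#' state.
#'
#' @param table a [variant_table()].
#' @param interval one-row data.frame (`contig`, `start`, `end`).
#' @param phenotype_map named character vector sample -> `case`/`control`.
#' @param penetrance fraction of individuals whose genotype matches their
#'   phenotype (default 1.0).
#' @param site optional explicit site index inside the interval.
#' @return list with the modified `table` and `truth` (`site`, `contig`,
#'   `pos`, `rule`, `contradicted` sample ids).
#' @export
implant_causal_snp <- function(table, interval, phenotype_map,
                               penetrance = 1.0, site = NULL) {
  idx <- sites_in_region(table, interval$contig, interval$start,
                         interval$end)
  if (length(idx) == 0) stop("interval contains no site")
  if (is.null(site)) site <- idx[ceiling(length(idx) / 2)]
  if (!site %in% idx) stop("explicit site lies outside the interval")
  known <- names(phenotype_map)[phenotype_map %in% c("case", "control")]
  known <- intersect(known, table$samples)
  geno <- ifelse(phenotype_map[known] == "case", 2, 0)
  n_contra <- round((1 - penetrance) * length(known))
  contradicted <- character(0)
  if (n_contra > 0) {
    contradicted <- sample(known, n_contra)
    geno[contradicted] <- 2 - geno[contradicted]
  }
  table$dosage[known, site] <- geno
  list(
    table = table,
    truth = list(site = site, contig = table$sites$contig[site],
                 pos = table$sites$pos[site],
                 rule = list(case = 2, control = 0),
                 contradicted = contradicted)
  )
}
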