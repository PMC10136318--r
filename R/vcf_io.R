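#' Read a multi-sample VCF into a variant table
#'
#' Parses a VCF 4.x file (plain or gzipped) with `vcfR`, keeps biallelic
#' SNP records only, converts GT fields to alternate-allele dosages and
#' applies a per-group call-rate filter when a contrast is supplied.
#' Multiallelic and non-SNP records are skipped and counted; the count is
#' reported through [message()].
#'
#' @param path path to the VCF file.
#' @param contrast optional [contrast_map()]. When given, sites whose call
#'   rate falls below `min_call_rate_per_group` in either contrast group
#'   are dropped, and every sample named in the contrast must be present
#'   in the VCF.
#' @param min_call_rate_per_group minimum fraction of called genotypes
#'   required in each contrast group (default 0.5).
#' @return a [variant_table()].
#' @export
read_vcf <- function(path, contrast = NULL, min_call_rate_per_group = 0.5) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  fmt <- unname(vcf@gt[, "FORMAT"])
  no_gt <- !vapply(strsplit(fmt, ":", fixed = TRUE),
                   function(f) "GT" %in% f, logical(1))
  if (any(no_gt)) {
    i <- which(no_gt)[1]
    stop("record without GT field at ", fix[i, "CHROM"], ":", fix[i, "POS"])
  }

  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  is_snp <- !is.na(alt) & !grepl(",", alt, fixed = TRUE) &
    nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_skipped <- sum(!is_snp)
  if (n_skipped > 0) {
    message("read_vcf: skipped ", n_skipped,
            " multiallelic or non-SNP record(s)")
  }

  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[is_snp, , drop = FALSE]
  fix <- fix[is_snp, , drop = FALSE]
  dosage <- t(gt_to_dosage(gt))

  sites <- data.frame(
    contig = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"],
    alt = fix[, "ALT"],
    stringsAsFactors = FALSE
  )
  contig_lengths <- contig_lengths_from_meta(vcf@meta)

  if (!is.null(contrast)) {
    for (side in c("a", "b")) {
      missing_smp <- setdiff(contrast_samples(contrast, side),
                             rownames(dosage))
      if (length(missing_smp) > 0) {
        stop("sample(s) in population map absent from VCF: ",
             paste(missing_smp, collapse = ", "))
      }
    }
    keep <- site_call_rate_ok(dosage, contrast, min_call_rate_per_group)
    if (any(!keep)) {
      message("read_vcf: dropped ", sum(!keep),
              " site(s) below call rate ", min_call_rate_per_group,
              " in a contrast group")
    }
    sites <- sites[keep, , drop = FALSE]
    dosage <- dosage[, keep, drop = FALSE]
  }
  variant_table(sites, dosage, contig_lengths)
}

# GT strings (sites x samples) -> dosage matrix, NA for missing; phase
# separators "/" and "|" treated identically.
gt_to_dosage <- function(gt) {
  d <- matrix(NA_real_, nrow = nrow(gt), ncol = ncol(gt),
              dimnames = dimnames(gt))
  a1 <- substr(gt, 1, 1)
  a2 <- substr(gt, 3, 3)
  called <- !is.na(gt) & a1 %in% c("0", "1") & a2 %in% c("0", "1")
  d[called] <- (a1 == "1")[called] + (a2 == "1")[called]
  d
}

site_call_rate_ok <- function(dosage, contrast, min_rate) {
  ok <- rep(TRUE, ncol(dosage))
  for (side in c("a", "b")) {
    smp <- contrast_samples(contrast, side)
    rate <- colMeans(!is.na(dosage[smp, , drop = FALSE]))
    ok <- ok & rate >= min_rate
  }
  ok
}

contig_lengths_from_meta <- function(meta) {
  ctg <- grep("^##contig=", meta, value = TRUE)
  if (length(ctg) == 0) return(NULL)
  ids <- sub(".*ID=([^,>]+).*", "\\1", ctg)
  has_len <- grepl("length=", ctg)
  if (!all(has_len)) return(NULL)
  lens <- as.numeric(sub(".*length=([0-9]+).*", "\\1", ctg))
  stats::setNames(lens, ids)
}

#' Write a variant table as a VCF 4.2 file
#'
#' Emits a plain-text VCF with GT-only FORMAT; dosages 0/1/2 become
#' `0/0`, `0/1`, `1/1` and missing calls `./.`. Reading the file back
#' with [read_vcf()] reproduces contigs, positions, alleles and dosages.
#'
#' @param x a [variant_table()].
#' @param path output path.
#' @param extra_header character vector of additional `##` header lines
#'   (e.g. a run-configuration record).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path, extra_header = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  for (ctg in x$contigs) {
    writeLines(sprintf("##contig=<ID=%s,length=%d>", ctg,
                       as.integer(x$contig_lengths[[ctg]])), con)
  }
  if (length(extra_header) > 0) writeLines(extra_header, con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                     "FILTER", "INFO", "FORMAT", x$samples),
                   collapse = "\t"), con)
  gt_codes <- c("0/0", "0/1", "1/1")
  n <- n_sites(x)
  if (n > 0) {
    gt <- matrix("./.", nrow = n, ncol = n_samples(x))
    d <- t(x$dosage)  # sites x samples
    called <- !is.na(d)
    gt[called] <- gt_codes[d[called] + 1]
    lines <- paste(
      x$sites$contig, x$sites$pos, ".", x$sites$ref, x$sites$alt,
      ".", "PASS", ".", "GT",
      apply(gt, 1, paste, collapse = "\t"),
      sep = "\t"
    )
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a population map and declare a contrast
#'
#' The population map is a two-column, tab- or space-separated file
#' (`sample<TAB>population`, no header, `#` comments allowed). The
#' contrast itself — which population labels form each side — is given by
#' the caller, mirroring a command-line declaration.
#'
#' @param path path to the population map.
#' @param group_a,group_b character vectors of population labels for the
#'   two sides of the contrast.
#' @param phenotype_path optional two-column file `sample<TAB>class` with
#'   classes `case`/`control`/`unknown`.
#' @return a [contrast_map()].
#' @export
read_popmap <- function(path, group_a, group_b, phenotype_path = NULL) {
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           col.names = c("sample", "population"),
                           colClasses = "character")
  if (anyDuplicated(tab$sample)) {
    stop("sample listed more than once in population map: ",
         tab$sample[duplicated(tab$sample)][1])
  }
  pops <- stats::setNames(tab$population, tab$sample)
  for (g in list(a = group_a, b = group_b)) {
    if (!any(pops %in% g)) {
      stop("contrast group {", paste(g, collapse = ","),
           "} matches no sample in the population map")
    }
  }
  phen <- NULL
  if (!is.null(phenotype_path)) phen <- read_phenotype(phenotype_path)
  contrast_map(pops, group_a, group_b, phenotype = phen)
}

#' @rdname read_popmap
#' @export
read_phenotype <- function(path) {
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           col.names = c("sample", "class"),
                           colClasses = "character")
  bad <- setdiff(unique(tab$class), c("case", "control", "unknown"))
  if (length(bad) > 0) {
    stop("phenotype classes must be case/control/unknown; found: ",
         paste(bad, collapse = ", "))
  }
  stats::setNames(tab$class, tab$sample)
}

#' Read gene models from a BED file
#'
#' Consumes BED4+ (0-based half-open, columns contig/start/end/name and
#' optionally score/strand) and returns 1-based inclusive gene models
#' sorted by contig then start.
#'
#' @param path path to the BED file.
#' @return data.frame with columns `gene`, `contig`, `start`, `end`
#'   (1-based inclusive), `strand`.
#' @export
read_genes_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0) {
    return(data.frame(gene = character(), contig = character(),
                      start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield < 4)) stop("BED input must have at least 4 columns")
  bed_start <- as.integer(vapply(parts, `[[`, "", 2))
  bed_end <- as.integer(vapply(parts, `[[`, "", 3))
  if (any(bed_start >= bed_end)) {
    stop("BED interval with start >= end at line ",
         which(bed_start >= bed_end)[1])
  }
  genes <- data.frame(
    gene = vapply(parts, `[[`, "", 4),
    contig = vapply(parts, `[[`, "", 1),
    start = bed_start + 1L,  # to 1-based inclusive
    end = bed_end,
    strand = ifelse(nfield >= 6, vapply(parts, function(p)
      if (length(p) >= 6) p[[6]] else ".", ""), "."),
    stringsAsFactors = FALSE
  )
  genes[order(genes$contig, genes$start), , drop = FALSE]
}

#' Write / read the per-window statistics table
#'
#' Tab-separated, one row per window, numeric values at 6 significant
#' digits: `contig start end n_snps fst pi_a pi_b pi_ratio selected`.
#' Coordinates are 1-based inclusive (matching the in-memory convention);
#' `pi_ratio` is `Inf` where group-B diversity is zero and group A is
#' polymorphic, `NA` where undefined.
#'
#' @param stats a window-statistics data.frame as produced by
#'   [window_stats()] (optionally carrying a `selected` column from
#'   [call_outlier_windows()]).
#' @param path output path.
#' @return `path` (write) or the data.frame (read).
#' @export
write_window_stats <- function(stats, path) {
  out <- stats
  if (!"selected" %in% names(out)) out$selected <- NA
  out <- out[, c("contig", "start", "end", "n_snps", "fst",
                 "pi_a", "pi_b", "pi_ratio", "selected")]
  for (col in c("fst", "pi_a", "pi_b", "pi_ratio")) {
    out[[col]] <- ifelse(is.finite(out[[col]]),
                         sprintf("%.6g", out[[col]]),
                         as.character(out[[col]]))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_window_stats
#' @export
read_window_stats <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  for (col in c("fst", "pi_a", "pi_b", "pi_ratio")) {
    tab[[col]] <- as.numeric(tab[[col]])
  }
  tab
}

#' Write merged divergent regions as BED
#'
#' Regions are written 0-based half-open (BED convention) with the peak
#' statistics and overlapping genes as extra columns. A `#`-prefixed
#' header names the columns; an empty region set yields a header-only
#' file.
#'
#' @param regions a region data.frame from [merge_regions()] /
#'   [assign_genes()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("#contig", "start", "end", "n_windows", "peak_fst",
                   "peak_pi_ratio", "genes", sep = "\t"), con)
  if (nrow(regions) > 0) {
    genes <- if ("genes" %in% names(regions)) {
      vapply(regions$genes, function(g)
        if (length(g) == 0) "." else paste(g, collapse = ","), "")
    } else rep(".", nrow(regions))
    writeLines(paste(regions$contig,
                     regions$start - 1L,  # to BED 0-based half-open
                     regions$end,
                     regions$n_windows,
                     sprintf("%.6g", regions$peak_fst),
                     ifelse(is.finite(regions$peak_pi_ratio),
                            sprintf("%.6g", regions$peak_pi_ratio), "Inf"),
                     genes, sep = "\t"), con)
  }
  invisible(path)
}
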