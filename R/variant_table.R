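#' Build a variant table of biallelic SNP genotypes
#'
#' The central in-memory container of the package: an ordered table of
#' biallelic SNP sites together with an individuals-by-sites matrix of
#' alternate-allele dosages (0, 1, 2, or `NA` for a missing call).
#' Genotype phase is deliberately discarded; every statistic in the
#' package is defined on unphased dosages.
#'
#' @param sites data.frame with columns `contig` (character), `pos`
#'   (1-based integer position), `ref`, `alt` (single-base alleles).
#'   Positions must be strictly increasing within each contig.
#' @param dosage numeric matrix, `n_samples x n_sites`, entries in
#'   `{0, 1, 2, NA}`; row names are the sample ids.
#' @param contig_lengths named numeric vector of contig lengths in bp.
#'   Defaults to the largest observed position per contig.
#'
#' @return An object of class `variant_table` with elements `sites`,
#'   `dosage`, `samples`, `contigs`, `contig_lengths`.
#' @export
variant_table <- function(sites, dosage, contig_lengths = NULL) {
  stopifnot(is.data.frame(sites), is.matrix(dosage))
  sites <- as.data.frame(sites)[, c("contig", "pos", "ref", "alt")]
  sites$contig <- as.character(sites$contig)
  sites$pos <- as.integer(sites$pos)
  sites$ref <- as.character(sites$ref)
  sites$alt <- as.character(sites$alt)
  if (is.null(rownames(dosage))) {
    stop("dosage matrix must carry sample ids as row names")
  }
  contigs <- unique(sites$contig)
  if (is.null(contig_lengths)) {
    contig_lengths <- vapply(
      split(sites$pos, factor(sites$contig, levels = contigs)),
      function(p) as.numeric(max(p)), numeric(1)
    )
  }
  obj <- structure(
    list(
      sites = sites,
      dosage = dosage,
      samples = rownames(dosage),
      contigs = contigs,
      contig_lengths = contig_lengths
    ),
    class = "variant_table"
  )
  validate_variant_table(obj)
  obj
}

#' @rdname variant_table
#' @param x a `variant_table`
#' @export
validate_variant_table <- function(x) {
  sites <- x$sites
  if (ncol(x$dosage) != nrow(sites)) {
    stop("dosage has ", ncol(x$dosage), " columns but sites has ",
         nrow(sites), " rows")
  }
  bad <- !(x$dosage %in% c(0, 1, 2) | is.na(x$dosage))
  if (any(bad)) stop("dosage entries must be 0, 1, 2 or NA")
  for (ctg in x$contigs) {
    p <- sites$pos[sites$contig == ctg]
    if (any(diff(p) <= 0)) {
      stop("positions not strictly increasing on contig ", ctg)
    }
    if (!ctg %in% names(x$contig_lengths)) {
      stop("no length recorded for contig ", ctg)
    }
  }
  snp <- nchar(sites$ref) == 1L & nchar(sites$alt) == 1L &
    sites$ref %in% c("A", "C", "G", "T") & sites$alt %in% c("A", "C", "G", "T")
  if (!all(snp)) stop("all sites must be single-base biallelic SNPs")
  invisible(x)
}

#' @export
print.variant_table <- function(x, ...) {
  cat("variant_table:", nrow(x$sites), "SNPs,", length(x$samples),
      "samples,", length(x$contigs), "contig(s)\n")
  miss <- mean(is.na(x$dosage))
  cat(sprintf("  missing genotype rate: %.3f\n", miss))
  invisible(x)
}

#' Number of sites / samples in a variant table
#' @param x a `variant_table`
#' @return integer count.
#' @export
n_sites <- function(x) nrow(x$sites)

#' @rdname n_sites
#' @export
n_samples <- function(x) length(x$samples)

#' Subset a variant table to a set of site indices
#'
#' @param x a `variant_table`
#' @param idx integer or logical index into the sites (column order).
#' @return a `variant_table` restricted to those sites.
#' @export
subset_sites <- function(x, idx) {
  variant_table(x$sites[idx, , drop = FALSE],
                x$dosage[, idx, drop = FALSE],
                x$contig_lengths)
}

#' Indices of sites falling in a genomic interval
#'
#' @param x a `variant_table`
#' @param contig contig id
#' @param start,end 1-based inclusive bounds
#' @return integer vector of site indices.
#' @export
sites_in_region <- function(x, contig, start, end) {
  which(x$sites$contig == contig & x$sites$pos >= start & x$sites$pos <= end)
}

#' Define a two-group population contrast
#'
#' Maps each sample to a population label and names the two disjoint sets
#' of labels being contrasted (group A is conventionally the wild or
#' broody side, group B the domestic or non-broody side). Samples whose
#' population belongs to neither group are carried along (e.g. an extended
#' validation population) but take no part in the contrast statistics.
#'
#' @param populations named character vector: `sample -> population label`.
#' @param group_a,group_b character vectors of population labels; must be
#'   disjoint and non-empty.
#' @param phenotype optional named character vector `sample -> class`
#'   with classes `"case"`, `"control"` or `"unknown"`.
#' @return An object of class `contrast_map`.
#' @export
contrast_map <- function(populations, group_a, group_b, phenotype = NULL) {
  if (is.null(names(populations)) || any(names(populations) == "")) {
    stop("populations must be a named vector (sample -> population)")
  }
  if (anyDuplicated(names(populations))) {
    dup <- names(populations)[duplicated(names(populations))][1]
    stop("sample listed more than once in population map: ", dup)
  }
  group_a <- unique(as.character(group_a))
  group_b <- unique(as.character(group_b))
  if (length(group_a) == 0 || length(group_b) == 0) {
    stop("both contrast groups must be non-empty")
  }
  if (length(intersect(group_a, group_b)) > 0) {
    stop("contrast groups must be disjoint; shared label(s): ",
         paste(intersect(group_a, group_b), collapse = ", "))
  }
  structure(
    list(populations = populations, group_a = group_a, group_b = group_b,
         phenotype = phenotype),
    class = "contrast_map"
  )
}

#' Samples belonging to one side of a contrast
#'
#' @param contrast a `contrast_map`
#' @param side `"a"` or `"b"`
#' @return character vector of sample ids.
#' @export
contrast_samples <- function(contrast, side = c("a", "b")) {
  side <- match.arg(side)
  labels <- if (side == "a") contrast$group_a else contrast$group_b
  names(contrast$populations)[contrast$populations %in% labels]
}

#' @export
print.contrast_map <- function(x, ...) {
  cat("contrast_map:", length(x$populations), "samples;",
      "group A =", paste(x$group_a, collapse = ","),
      sprintf("(n=%d);", length(contrast_samples(x, "a"))),
      "group B =", paste(x$group_b, collapse = ","),
      sprintf("(n=%d)\n", length(contrast_samples(x, "b"))))
  invisible(x)
}
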