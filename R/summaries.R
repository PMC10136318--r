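#' Summarize SNP functional-annotation counts
#'
#' Bookkeeping for the SNP-table summary: given the total SNP count and
#' named category counts (e.g. nonsynonymous, synonymous), returns each
#' category with its percentage of the total, the convention used when
#' reporting a resequencing SNP table.
#'
#' @param n_total total number of SNPs.
#' @param ... named category counts.
#' @return data.frame `category`, `count`, `percent` (of `n_total`).
#' @export
snp_annotation_summary <- function(n_total, ...) {
  counts <- c(...)
  stopifnot(n_total > 0, all(counts >= 0), all(counts <= n_total))
  data.frame(
    category = names(counts),
    count = as.numeric(counts),
    percent = 100 * as.numeric(counts) / n_total,
    stringsAsFactors = FALSE
  )
}
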