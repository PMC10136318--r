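#' Build the sliding-window scan grid
#'
#' Windows start at 1, 1+step, 1+2*step, ...; the last window is the
#' final full-length window fitting in the contig. A contig shorter than
#' the window size yields a single truncated window covering the whole
#' contig (its true span is used as the diversity denominator).
#'
#' @param contig_lengths named numeric vector, contig -> length in bp.
#' @param window_size_bp window size (default 40000).
#' @param step_bp step between window starts (default 10000); must not
#'   exceed `window_size_bp`.
#' @return data.frame `contig`, `start`, `end` (1-based inclusive),
#'   ordered by contig then start.
#' @export
make_windows <- function(contig_lengths, window_size_bp = 40000,
                         step_bp = 10000) {
  stopifnot(all(contig_lengths > 0))
  if (step_bp > window_size_bp) {
    stop("step_bp must not exceed window_size_bp")
  }
  res <- lapply(names(contig_lengths), function(ctg) {
    len <- contig_lengths[[ctg]]
    if (len < window_size_bp) {
      data.frame(contig = ctg, start = 1L, end = as.integer(len),
                 stringsAsFactors = FALSE)
    } else {
      starts <- seq(1L, as.integer(len - window_size_bp + 1), by = step_bp)
      data.frame(contig = ctg, start = starts,
                 end = starts + as.integer(window_size_bp) - 1L,
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, res)
}

# Empirical top-quantile threshold: the smallest observed value v such
# that at least q*n of the n values lie strictly below v; +Inf when no
# value qualifies (e.g. all values identical). Values equal to the
# threshold count as selected (inclusive "top 5%").
top_quantile_threshold <- function(values, q) {
  n <- length(values)
  if (n == 0) return(Inf)
  u <- sort(unique(values))
  counts <- tabulate(match(values, u), nbins = length(u))
  below <- cumsum(c(0, counts[-length(counts)]))
  i <- which(below >= q * n)
  if (length(i) == 0) Inf else u[i[1]]
}

#' Call joint top-quantile outlier windows
#'
#' Thresholds are the empirical `outlier_quantile` (default 95th)
#' percentiles of window F_ST and of the pi ratio over retained windows
#' — those not excluded for SNP count and with both statistics defined
#' (`pi_ratio = Inf`, group-B diversity lost entirely, is defined and
#' ranks above every finite ratio). A window is selected when it meets
#' or exceeds BOTH thresholds.
#'
#' @param stats window statistics from [window_stats()].
#' @param outlier_quantile quantile defining "top" (default 0.95).
#' @return `stats` with logical columns `retained` and `selected` plus
#'   attributes `fst_threshold` and `pi_ratio_threshold`.
#' @export
call_outlier_windows <- function(stats, outlier_quantile = 0.95) {
  stopifnot(outlier_quantile > 0, outlier_quantile < 1)
  retained <- !stats$excluded & !is.na(stats$fst) & stats$ratio_defined
  if (sum(retained) < 20) {
    warning("only ", sum(retained),
            " retained windows; empirical quantile is unstable")
  }
  thr_fst <- top_quantile_threshold(stats$fst[retained], outlier_quantile)
  thr_ratio <- top_quantile_threshold(stats$pi_ratio[retained],
                                      outlier_quantile)
  sel <- retained & stats$fst >= thr_fst & stats$pi_ratio >= thr_ratio
  sel[is.na(sel)] <- FALSE
  stats$retained <- retained
  stats$selected <- sel
  attr(stats, "fst_threshold") <- thr_fst
  attr(stats, "pi_ratio_threshold") <- thr_ratio
  stats
}

#' Merge selected windows into divergent regions
#'
#' Overlapping or book-ended (end + 1 == start) selected windows on the
#' same contig are merged into one region; peak statistics are the
#' maxima over member windows.
#'
#' @param stats output of [call_outlier_windows()] (or any window
#'   data.frame with a logical `selected` column).
#' @return data.frame `contig`, `start`, `end`, `n_windows`, `peak_fst`,
#'   `peak_pi_ratio`, ordered by contig then start.
#' @export
merge_regions <- function(stats) {
  sel <- stats[stats$selected, , drop = FALSE]
  empty <- data.frame(contig = character(), start = integer(),
                      end = integer(), n_windows = integer(),
                      peak_fst = numeric(), peak_pi_ratio = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(sel) == 0) return(empty)
  res <- lapply(unique(sel$contig), function(ctg) {
    w <- sel[sel$contig == ctg, , drop = FALSE]
    ir <- IRanges::IRanges(start = w$start, end = w$end)
    merged <- IRanges::reduce(ir, min.gapwidth = 1L)
    ov <- IRanges::findOverlaps(ir, merged)
    grp <- S4Vectors::subjectHits(ov)
    data.frame(
      contig = ctg,
      start = IRanges::start(merged),
      end = IRanges::end(merged),
      n_windows = as.integer(tabulate(grp, nbins = length(merged))),
      peak_fst = as.numeric(tapply(w$fst, grp, max)),
      peak_pi_ratio = as.numeric(tapply(w$pi_ratio, grp, max)),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  out[order(out$contig, out$start), , drop = FALSE]
}

#' Assign genes to divergent regions
#'
#' A gene is assigned to a region when they overlap by at least one bp
#' (both in 1-based inclusive coordinates). A gene spanning two regions
#' is listed in both; the deduplicated union is reported in the
#' `n_genes_union` attribute.
#'
#' @param regions region data.frame from [merge_regions()].
#' @param genes gene models from [read_genes_bed()].
#' @return `regions` with a list-column `genes`; attribute
#'   `n_genes_union` counts distinct genes over all regions.
#' @export
assign_genes <- function(regions, genes) {
  gene_lists <- rep(list(character(0)), nrow(regions))
  for (ctg in unique(regions$contig)) {
    ri <- which(regions$contig == ctg)
    gi <- which(genes$contig == ctg)
    if (length(gi) == 0) next
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(start = regions$start[ri], end = regions$end[ri]),
      IRanges::IRanges(start = genes$start[gi], end = genes$end[gi])
    )
    for (k in seq_along(ri)) {
      hit <- gi[S4Vectors::subjectHits(ov)[S4Vectors::queryHits(ov) == k]]
      gene_lists[[ri[k]]] <- genes$gene[hit]
    }
  }
  regions$genes <- gene_lists
  attr(regions, "n_genes_union") <-
    length(unique(unlist(gene_lists, use.names = FALSE)))
  regions
}

#' Rank candidate genes by F_ST then by pi ratio
#'
#' Each gene overlapping at least one selected window carries the best
#' (maximum) window F_ST and pi ratio over the selected windows that
#' overlap it. The ranking takes the top `n_fst` genes by descending
#' best F_ST, then the top `n_pi` genes by descending best pi ratio
#' excluding genes already chosen; ties are broken by genomic order
#' (contig, then start).
#'
#' @param stats output of [call_outlier_windows()] (selected windows are
#'   used).
#' @param genes gene models from [read_genes_bed()].
#' @param n_fst,n_pi list sizes (defaults 50 and 50).
#' @return data.frame `gene`, `contig`, `start`, `best_fst`,
#'   `best_pi_ratio`, `selected_by` (`"fst"` entries first, then
#'   `"pi_ratio"`); no gene appears twice.
#' @export
rank_top_genes <- function(stats, genes, n_fst = 50, n_pi = 50) {
  sel <- stats[stats$selected, , drop = FALSE]
  best <- gene_best_stats(sel, genes)
  if (nrow(best) < n_fst + n_pi) {
    message("rank_top_genes: only ", nrow(best),
            " candidate gene(s) for ", n_fst + n_pi, " slots")
  }
  ord_genome <- order(best$contig, best$start)
  best <- best[ord_genome, , drop = FALSE]
  by_fst <- best[order(-best$best_fst), , drop = FALSE]
  pick_fst <- utils::head(by_fst, n_fst)
  rest <- best[!best$gene %in% pick_fst$gene, , drop = FALSE]
  by_pi <- rest[order(-rest$best_pi_ratio), , drop = FALSE]
  pick_pi <- utils::head(by_pi, n_pi)
  pick_fst$selected_by <- rep("fst", nrow(pick_fst))
  pick_pi$selected_by <- rep("pi_ratio", nrow(pick_pi))
  out <- rbind(pick_fst, pick_pi)
  rownames(out) <- NULL
  out
}

# best (max) fst and pi_ratio per gene over selected windows
gene_best_stats <- function(sel_windows, genes) {
  best <- data.frame(gene = character(), contig = character(),
                     start = integer(), best_fst = numeric(),
                     best_pi_ratio = numeric(), stringsAsFactors = FALSE)
  if (nrow(sel_windows) == 0 || nrow(genes) == 0) return(best)
  rows <- list()
  for (ctg in unique(genes$contig)) {
    wi <- which(sel_windows$contig == ctg)
    gi <- which(genes$contig == ctg)
    if (length(wi) == 0) next
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(start = genes$start[gi], end = genes$end[gi]),
      IRanges::IRanges(start = sel_windows$start[wi],
                       end = sel_windows$end[wi])
    )
    if (length(ov) == 0) next
    q <- S4Vectors::queryHits(ov)
    h <- wi[S4Vectors::subjectHits(ov)]
    for (k in unique(q)) {
      wsub <- h[q == k]
      rows[[length(rows) + 1]] <- data.frame(
        gene = genes$gene[gi[k]], contig = ctg, start = genes$start[gi[k]],
        best_fst = max(sel_windows$fst[wsub]),
        best_pi_ratio = max(sel_windows$pi_ratio[wsub]),
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0) return(best)
  out <- do.call(rbind, rows)
  # a gene duplicated in the annotation keeps its best stats once
  out <- out[!duplicated(out$gene), , drop = FALSE]
  out
}

#' Score called regions against simulated truth
#'
#' A truth sweep counts as recovered when at least half of its span lies
#' inside called regions; recall is the recovered fraction of truth
#' sweeps. Precision is the fraction of the total called span that
#' overlaps truth. With no calls, precision is undefined (`NA`); with no
#' truth, recall is undefined.
#'
#' @param regions called regions (`contig`, `start`, `end`).
#' @param truth truth sweep intervals (`contig`, `start`, `end`).
#' @return list with `recall`, `precision`, `n_truth`, `n_recovered`,
#'   `called_bp`, `overlap_bp`.
#' @export
evaluate_recovery <- function(regions, truth) {
  called_bp <- if (nrow(regions)) sum(regions$end - regions$start + 1) else 0
  overlap_bp <- 0
  recovered <- logical(nrow(truth))
  for (ctg in unique(c(regions$contig, truth$contig))) {
    ri <- which(regions$contig == ctg)
    ti <- which(truth$contig == ctg)
    if (length(ri) == 0) next
    rr <- IRanges::reduce(IRanges::IRanges(start = regions$start[ri],
                                           end = regions$end[ri]))
    if (length(ti) > 0) {
      tt <- IRanges::IRanges(start = truth$start[ti], end = truth$end[ti])
      inter <- IRanges::intersect(rr, IRanges::reduce(tt))
      overlap_bp <- overlap_bp + sum(IRanges::width(inter))
      ov <- IRanges::findOverlaps(tt, rr)
      for (k in unique(S4Vectors::queryHits(ov))) {
        hit <- rr[S4Vectors::subjectHits(ov)[S4Vectors::queryHits(ov) == k]]
        cov <- sum(IRanges::width(IRanges::intersect(hit, tt[k])))
        span <- IRanges::width(tt[k])
        if (cov >= 0.5 * span) recovered[ti[k]] <- TRUE
      }
    }
  }
  list(
    recall = if (nrow(truth)) mean(recovered) else NA_real_,
    precision = if (called_bp > 0) overlap_bp / called_bp else NA_real_,
    n_truth = nrow(truth),
    n_recovered = sum(recovered),
    called_bp = called_bp,
    overlap_bp = overlap_bp
  )
}
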