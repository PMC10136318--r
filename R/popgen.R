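#' Per-site allele and genotype counts for a contrast
#'
#' Tallies, separately for the two contrast groups, the number of called
#' diploids, the alternate-allele count and the observed heterozygote
#' count at one site. Missing dosages are excluded from every count
#' (site-level exclusion: a sample missing here still contributes at
#' other sites).
#'
#' @param x a [variant_table()].
#' @param contrast a [contrast_map()].
#' @param site_index index of the site (column of the dosage matrix).
#' @return list with elements `a` and `b`, each `list(n, alt, het)`, and
#'   `defined` — `FALSE` when a group has no called diploids.
#' @export
site_counts <- function(x, contrast, site_index) {
  out <- lapply(c(a = "a", b = "b"), function(side) {
    d <- x$dosage[contrast_samples(contrast, side), site_index]
    d <- d[!is.na(d)]
    list(n = length(d), alt = sum(d), het = sum(d == 1))
  })
  out$defined <- out$a$n > 0 && out$b$n > 0
  out
}

# Vectorized group tallies over all sites: returns list(n, alt, het),
# each a numeric vector of length n_sites.
group_counts <- function(x, samples) {
  d <- x$dosage[samples, , drop = FALSE]
  called <- !is.na(d)
  list(
    n = colSums(called),
    alt = colSums(d, na.rm = TRUE),
    het = colSums(d == 1, na.rm = TRUE)
  )
}

#' Weir-Cockerham per-site F_ST variance components (two populations)
#'
#' Evaluates the Weir & Cockerham (1984) among-population (`a`),
#' among-individual (`b`) and within-individual (`c`) variance components
#' for two populations from diploid genotype counts, and the per-site
#' estimator `theta = a / (a + b + c)`. The estimate is undefined
#' (`NA`) when either group has fewer than two called diploids or when
#' the site is monomorphic overall (`a + b + c == 0`); negative estimates
#' are retained (they are part of an unbiased window mean).
#'
#' @param counts output of [site_counts()], or a list of the same shape.
#' @return list with `a`, `b`, `c`, `theta`.
#' @export
site_fst_wc <- function(counts) {
  comp <- fst_wc_components(counts$a$n, counts$a$alt, counts$a$het,
                            counts$b$n, counts$b$alt, counts$b$het)
  list(a = comp$a, b = comp$b, c = comp$c, theta = comp$theta)
}

# Vectorized Weir-Cockerham (1984) components for r = 2 populations.
# Arguments are per-site vectors of called diploids, alt-allele counts
# and heterozygote counts for each group.
fst_wc_components <- function(n1, alt1, het1, n2, alt2, het2) {
  r <- 2
  ok <- n1 >= 2 & n2 >= 2
  p1 <- ifelse(n1 > 0, alt1 / (2 * n1), NA_real_)
  p2 <- ifelse(n2 > 0, alt2 / (2 * n2), NA_real_)
  h1 <- ifelse(n1 > 0, het1 / n1, NA_real_)
  h2 <- ifelse(n2 > 0, het2 / n2, NA_real_)

  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)

  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2

  a[!ok] <- NA_real_
  b[!ok] <- NA_real_
  cc[!ok] <- NA_real_
  denom <- a + b + cc
  theta <- ifelse(ok & denom != 0, a / denom, NA_real_)
  list(a = a, b = b, c = cc, theta = theta)
}

#' Per-site nucleotide diversity
#'
#' Unbiased expected heterozygosity at one SNP site for one group:
#' `pi = 2 p (1 - p) * 2n / (2n - 1)` with `p` the sample alternate-allele
#' frequency over `2n` sampled alleles. This equals the mean pairwise
#' difference over all C(2n, 2) allele pairs at the site. Undefined
#' (`NA`) for fewer than two called diploids.
#'
#' @param n called diploids (vectorized).
#' @param alt alternate-allele count out of `2n` alleles (vectorized).
#' @return per-site diversity (substitutions per site).
#' @export
site_pi <- function(n, alt) {
  p <- alt / (2 * n)
  ifelse(n >= 2, 2 * p * (1 - p) * (2 * n) / (2 * n - 1), NA_real_)
}

#' Per-window F_ST, diversity and the pi ratio
#'
#' For each window of the scan grid: `n_snps`, the window F_ST (the
#' arithmetic mean of defined per-site Weir-Cockerham estimates, clamped
#' at zero for reporting), the per-bp diversity of each group
#' (sum of per-site pi over the window's SNPs divided by the window span)
#' and the pi ratio `pi_a / pi_b`. Windows with `pi_b == 0 < pi_a` get
#' `pi_ratio = Inf` (maximal evidence of diversity lost in group B);
#' windows with `pi_a == pi_b == 0` have an undefined ratio. Windows with
#' fewer than `min_snps` SNPs are flagged `excluded`.
#'
#' @param x a [variant_table()].
#' @param contrast a [contrast_map()].
#' @param windows window grid from [make_windows()] (columns `contig`,
#'   `start`, `end`, 1-based inclusive).
#' @param min_snps minimum SNPs for a window to enter outlier calling
#'   (default 10).
#' @param fst_window `"mean"` (default) averages per-site theta;
#'   `"ratio_of_sums"` uses `sum(a) / sum(a + b + c)` over the window's
#'   defined sites (the weighted variant).
#' @return data.frame with one row per window: `contig`, `start`, `end`,
#'   `n_snps`, `fst`, `pi_a`, `pi_b`, `pi_ratio`, `ratio_defined`,
#'   `excluded`.
#' @export
window_stats <- function(x, contrast, windows, min_snps = 10,
                         fst_window = c("mean", "ratio_of_sums")) {
  fst_window <- match.arg(fst_window)
  ca <- group_counts(x, contrast_samples(contrast, "a"))
  cb <- group_counts(x, contrast_samples(contrast, "b"))
  comp <- fst_wc_components(ca$n, ca$alt, ca$het, cb$n, cb$alt, cb$het)
  pi_a_site <- site_pi(ca$n, ca$alt)
  pi_b_site <- site_pi(cb$n, cb$alt)

  hits <- overlap_sites_windows(x$sites, windows)
  w <- hits$window
  s <- hits$site

  nwin <- nrow(windows)
  acc <- function(v, f = identity) {
    ok <- !is.na(v[s])
    out <- rep(0, nwin)
    if (any(ok)) {
      agg <- rowsum(v[s][ok], w[ok])
      out[as.integer(rownames(agg))] <- agg[, 1]
    }
    out
  }
  n_snps <- tabulate(w, nbins = nwin)
  n_theta <- tabulate(w[!is.na(comp$theta[s])], nbins = nwin)

  if (fst_window == "mean") {
    fst <- acc(comp$theta) / ifelse(n_theta > 0, n_theta, NA_real_)
  } else {
    num <- acc(comp$a)
    den <- acc(comp$a + comp$b + comp$c)
    fst <- ifelse(n_theta > 0 & den != 0, num / den, NA_real_)
    fst[n_theta == 0] <- NA_real_
  }
  fst <- pmax(fst, 0)  # clamp only the reported window value

  span <- windows$end - windows$start + 1
  pi_a <- acc(pi_a_site) / span
  pi_b <- acc(pi_b_site) / span
  pi_ratio <- ifelse(pi_b > 0, pi_a / pi_b,
                     ifelse(pi_a > 0, Inf, NA_real_))
  out <- data.frame(
    contig = windows$contig, start = windows$start, end = windows$end,
    n_snps = n_snps, fst = fst, pi_a = pi_a, pi_b = pi_b,
    pi_ratio = pi_ratio,
    ratio_defined = !is.na(pi_ratio),
    excluded = n_snps < min_snps,
    stringsAsFactors = FALSE
  )
  out$fst[n_snps == 0] <- NA_real_
  out$pi_a[n_snps == 0] <- NA_real_
  out$pi_b[n_snps == 0] <- NA_real_
  out
}

# site (point) vs window overlap within contigs; returns data.frame
# (site index, window index).
overlap_sites_windows <- function(sites, windows) {
  res_s <- integer(0)
  res_w <- integer(0)
  for (ctg in unique(windows$contig)) {
    wi <- which(windows$contig == ctg)
    si <- which(sites$contig == ctg)
    if (length(si) == 0 || length(wi) == 0) next
    q <- IRanges::IRanges(start = sites$pos[si], width = 1)
    sbj <- IRanges::IRanges(start = windows$start[wi],
                            end = windows$end[wi])
    ov <- IRanges::findOverlaps(q, sbj)
    res_s <- c(res_s, si[S4Vectors::queryHits(ov)])
    res_w <- c(res_w, wi[S4Vectors::subjectHits(ov)])
  }
  data.frame(site = res_s, window = res_w)
}

#' Principal component analysis of genotype dosages
#'
#' Sanity-check PCA on simulated (or real) genotypes: monomorphic sites
#' are dropped, missing dosages are imputed with the site mean, each site
#' is mean-centered and scaled by `sqrt(p(1-p))` (the expected binomial
#' standard deviation at the site's allele frequency), and the matrix is
#' decomposed by SVD. Scores are deterministic up to sign.
#'
#' @param x a [variant_table()].
#' @param n_components number of PCs to return.
#' @return matrix of sample scores (`n_samples x n_components`).
#' @export
pca_genotypes <- function(x, n_components = 2) {
  if (n_samples(x) < 2 || n_sites(x) < 2) {
    stop("PCA needs at least 2 samples and 2 sites")
  }
  d <- x$dosage
  mu <- colMeans(d, na.rm = TRUE)
  v <- apply(d, 2, stats::var, na.rm = TRUE)
  idx <- which(!is.na(mu) & mu > 0 & mu < 2 & !is.na(v) & v > 0)
  d <- d[, idx, drop = FALSE]
  mu <- mu[idx]
  if (ncol(d) < 2) stop("fewer than 2 polymorphic sites; PCA degenerate")
  for (j in seq_len(ncol(d))) d[is.na(d[, j]), j] <- mu[j]
  p <- mu / 2
  z <- sweep(d, 2, mu, "-")
  z <- sweep(z, 2, sqrt(p * (1 - p)), "/")
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  pc$x[, seq_len(k), drop = FALSE]
}
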