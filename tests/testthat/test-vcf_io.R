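test_that("a minimal VCF is parsed into the expected dosage matrix", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf_text(path, samples = c("s1", "s2", "s3"), records = c(
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "chr1\t200\t.\tC\tT\t.\tPASS\t.\tGT\t./.\t0|1\t0/0"
  ))
  tab <- read_vcf(path)
  expect_equal(dim(tab$dosage), c(3, 2))
  expect_equal(unname(tab$dosage[, 1]), c(0, 1, 2))
  # "./." becomes the missing sentinel; phase bar is ignored
  expect_equal(unname(tab$dosage[, 2]), c(NA, 1, 0))
  expect_equal(tab$sites$pos, c(100L, 200L))
  expect_equal(tab$contig_lengths[["chr1"]], 100000)
})

test_that("multiallelic and non-SNP records are skipped and counted", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf_text(path, samples = c("s1", "s2"), records = c(
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1",
    "chr1\t200\t.\tA\tA,T\t.\tPASS\t.\tGT\t0/0\t0/1",
    "chr1\t300\t.\tAT\tA\t.\tPASS\t.\tGT\t0/0\t0/1"
  ))
  expect_message(tab <- read_vcf(path), "skipped 2")
  expect_equal(n_sites(tab), 1L)
})

test_that("a record without GT is a hard error naming the site", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf_text(path, samples = c("s1", "s2"), records = c(
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tDP\t10\t12"
  ))
  expect_error(read_vcf(path), "chr1:100")
})

test_that("per-group call-rate filtering drops undercalled sites", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf_text(path, samples = c("a1", "a2", "b1", "b2"), records = c(
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1\t0/0",
    "chr1\t200\t.\tC\tT\t.\tPASS\t.\tGT\t./.\t./.\t0/0\t0/1",
    "chr1\t300\t.\tG\tA\t.\tPASS\t.\tGT\t0/0\t./.\t0/0\t./."
  ))
  contrast <- contrast_map(
    c(a1 = "A", a2 = "A", b1 = "B", b2 = "B"), "A", "B")
  tab <- suppressMessages(read_vcf(path, contrast,
                                   min_call_rate_per_group = 0.5))
  # site 200 has call rate 0 in group A; 300 passes at exactly 0.5
  expect_equal(tab$sites$pos, c(100L, 300L))
  expect_error(
    read_vcf(path, contrast_map(c(a1 = "A", zz = "A", b1 = "B"), "A", "B")),
    "zz")
})

test_that("VCF round trip preserves sites and dosages", {
  sim <- small_neutral_sim()
  set.seed(5)
  keep <- sample(seq_len(n_sites(sim$table)), 200)
  tab <- subset_sites(sim$table, sort(keep))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(tab, path)
  back <- read_vcf(path)
  expect_equal(back$sites, tab$sites, ignore_attr = TRUE)
  expect_equal(unname(back$dosage), unname(tab$dosage))
  expect_equal(back$contig_lengths, tab$contig_lengths)
})

test_that("call-rate and biallelic filters commute", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf_text(path, samples = c("a1", "a2", "b1", "b2"), records = c(
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1\t0/0",
    "chr1\t150\t.\tA\tG,T\t.\tPASS\t.\tGT\t./.\t./.\t0/0\t0/1",
    "chr1\t200\t.\tC\tT\t.\tPASS\t.\tGT\t./.\t./.\t0/0\t0/1"
  ))
  contrast <- contrast_map(
    c(a1 = "A", a2 = "A", b1 = "B", b2 = "B"), "A", "B")
  # read_vcf applies biallelic-then-callrate; emulate the reverse order
  # from the unfiltered parse and compare
  both <- suppressMessages(read_vcf(path, contrast))
  all_sites <- suppressMessages(read_vcf(path))
  rate_a <- colMeans(!is.na(all_sites$dosage[c("a1", "a2"), ]))
  rate_b <- colMeans(!is.na(all_sites$dosage[c("b1", "b2"), ]))
  reversed <- subset_sites(all_sites, rate_a >= 0.5 & rate_b >= 0.5)
  expect_equal(both$sites, reversed$sites, ignore_attr = TRUE)
})

test_that("popmap reading enforces contrast invariants", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("SW1\tSW", "SW2\tSW", "HY1\tHY", "TH1\tTH", "ST1\tST",
               "WL1\tWL"), path)
  cm <- read_popmap(path, group_a = "SW",
                    group_b = c("HY", "WL", "TH", "ST"))
  expect_setequal(contrast_samples(cm, "a"), c("SW1", "SW2"))
  expect_length(contrast_samples(cm, "b"), 4)
  writeLines(c("SW1\tSW", "SW1\tSW", "HY1\tHY"), path)
  expect_error(read_popmap(path, "SW", "HY"), "more than once")
  writeLines(c("SW1\tSW", "HY1\tHY"), path)
  expect_error(read_popmap(path, "SW", "ZZ"), "no sample")
  expect_error(contrast_map(c(s = "SW"), "SW", character(0)), "non-empty")
  expect_error(contrast_map(c(s = "SW"), c("SW", "HY"), "HY"), "disjoint")
})

test_that("BED gene input converts to 1-based inclusive and sorts", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr2\t500\t900\tgeneB",
               "chr1\t100\t200\tgeneA\t0\t-",
               "chr1\t50\t80\tgeneC"), path)
  genes <- read_genes_bed(path)
  expect_equal(genes$gene, c("geneC", "geneA", "geneB"))
  expect_equal(genes$start[genes$gene == "geneA"], 101L)
  expect_equal(genes$end[genes$gene == "geneA"], 200L)
  expect_equal(genes$strand, c(".", "-", "."))
  writeLines("chr1\t200\t100\tbad", path)
  expect_error(read_genes_bed(path), "start >= end")
  writeLines(character(0), path)
  expect_equal(nrow(read_genes_bed(path)), 0L)
})

test_that("window stats table round-trips through disk at 6 sig digits", {
  stats <- data.frame(
    contig = c("c1", "c1"), start = c(1L, 10001L),
    end = c(40000L, 50000L), n_snps = c(12L, 0L),
    fst = c(0.123456789, NA), pi_a = c(3.333333e-5, NA),
    pi_b = c(1.111111e-5, NA), pi_ratio = c(3.0000001, NA),
    ratio_defined = c(TRUE, FALSE), excluded = c(FALSE, TRUE),
    selected = c(TRUE, FALSE))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_window_stats(stats, path)
  back <- read_window_stats(path)
  expect_equal(nrow(back), 2L)
  expect_equal(back$fst[1], signif(stats$fst[1], 6), tolerance = 1e-6)
  expect_equal(back$pi_a[1], stats$pi_a[1], tolerance = 1e-6)
  # Inf ratios survive the round trip
  stats$pi_ratio[1] <- Inf
  write_window_stats(stats, path)
  expect_equal(read_window_stats(path)$pi_ratio[1], Inf)
})

test_that("regions BED is written 0-based half-open with a header", {
  regions <- data.frame(contig = "c1", start = 52001L, end = 92000L,
                        n_windows = 5L, peak_fst = 0.7,
                        peak_pi_ratio = 3.2)
  regions$genes <- list(c("geneA", "geneB"))
  path <- withr::local_tempfile(fileext = ".bed")
  write_regions_bed(regions, path)
  lines <- readLines(path)
  expect_match(lines[1], "^#contig")
  fields <- strsplit(lines[2], "\t")[[1]]
  expect_equal(fields[2], "52000")
  expect_equal(fields[3], "92000")
  expect_equal(fields[7], "geneA,geneB")
  write_regions_bed(regions[0, ], path)
  expect_length(readLines(path), 1L)
})
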