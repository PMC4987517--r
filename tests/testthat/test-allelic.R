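test_that("SNP discovery keeps differing consensus sites and drops the rest", {
  pa <- make_pileup(c(100L, 200L), c("A", "C"),
                    c(strrep("A", 50), strrep("C", 40)),
                    c(qstr(40, 50), qstr(40, 40)))
  pb <- make_pileup(c(100L, 200L), c("A", "C"),
                    c(strrep("G", 50), strrep("C", 40)),
                    c(qstr(40, 50), qstr(40, 40)))
  snps <- discover_het_snps(pa, pb, min_depth = 10)
  expect_equal(nrow(snps), 1L)
  expect_equal(snps$pos, 100L)
  expect_equal(snps$allele1, "A")
  expect_equal(snps$allele2, "G")
})

test_that("SNP discovery on simulated clones recovers all sites with no false positives", {
  truth <- simulate_allelic_dataset(simulation_config(n_genes = 10L,
                                                      total_snps = 10L,
                                                      seed = 31L))$snps
  pl <- simulate_clone_pileups(truth, depth = 100, error_rate = 0.01,
                               seed = 32L, n_null_sites = 1000L)
  found <- discover_het_snps(pl$clone_a, pl$clone_b, min_depth = 10,
                             min_purity = 0.9)
  expect_setequal(found$pos, truth$pos)
})

test_that("malformed pileup rows raise parse errors naming the line", {
  p <- tempfile(fileext = ".tsv")
  writeLines(c("chrX\t100\tA\t3\tAAA\tIII", "chrX\t200\tC\t4\tCC\tII"), p)
  expect_error(read_pileup(p), "line 2")
  writeLines(c("chrX\t100\tA\t3\tAAA"), p)
  expect_error(read_pileup(p), "line 1")
})

test_that("species filtering removes dual-mapped reads and is idempotent", {
  expect_setequal(filter_species_specific(c("r1", "r2", "r3"), "r2"),
                  c("r1", "r3"))
  expect_setequal(filter_species_specific(c("r1", "r2"), c("x1")),
                  c("r1", "r2"))
  expect_length(filter_species_specific(c("r1", "r2"), c("r1", "r2", "m1")), 0L)
  once <- filter_species_specific(sprintf("r%d", 1:100), sprintf("r%d", 50:80))
  expect_identical(filter_species_specific(once, sprintf("r%d", 50:80)), once)
})

test_that("allele counting matches the stated example and handles edge cases", {
  snps <- data.frame(chrom = "chrX", pos = 100L, allele1 = "A", allele2 = "G",
                     gene = "g1", stringsAsFactors = FALSE)
  p <- make_pileup(100L, "A", "AAGT", qstr(30, 4))
  ac <- count_alleles(p, snps)
  expect_equal(ac$count_allele1, 2L)
  expect_equal(ac$count_allele2, 1L)
  expect_equal(ac$count_other, 1L)
  expect_equal(ac$qualsum_allele1, 60L)
  expect_equal(ac$qualsum_allele2, 30L)

  # SNP absent from the pileup: zero-count row, not an error
  snps2 <- rbind(snps, data.frame(chrom = "chrX", pos = 500L, allele1 = "C",
                                  allele2 = "T", gene = "g2"))
  ac2 <- count_alleles(p, snps2)
  expect_equal(ac2$count_allele1[2], 0L)
  expect_equal(ac2$qualsum_allele1[2], 0L)

  # all reads filtered out by read-id restriction
  p3 <- make_pileup(100L, "A", "AAGT", qstr(30, 4), read_ids = "r1,r2,r3,r4")
  ac3 <- count_alleles(p3, snps, kept_reads = c("zz"))
  expect_equal(ac3$count_allele1 + ac3$count_allele2 + ac3$count_other, 0L)

  # dot/comma reference shorthand and lowercase strand symbols
  p4 <- make_pileup(100L, "A", ".,gG", qstr(30, 4))
  ac4 <- count_alleles(p4, snps)
  expect_equal(ac4$count_allele1, 2L)
  expect_equal(ac4$count_allele2, 2L)

  # base-quality floor removes bases from counts and quality sums
  p5 <- make_pileup(100L, "A", "AAGG", paste0(qstr(30, 2), qstr(5, 2)))
  ac5 <- count_alleles(p5, snps, min_baseq = 13)
  expect_equal(ac5$count_allele1, 2L)
  expect_equal(ac5$count_allele2, 0L)
  expect_equal(ac5$qualsum_allele2, 0L)
})

test_that("allele counting matches a brute-force per-character recount", {
  set.seed(99)
  for (rep in 1:10) {
    n <- sample(1:20, 1)
    a <- sample(c("A", "C", "G", "T"), 2)
    bases <- paste(sample(c("A", "C", "G", "T", "a", "g", ".", ","), n, TRUE),
                   collapse = "")
    quals <- intToUtf8(sample(2:41, n, TRUE) + 33L)
    ids <- paste(sprintf("r%d", sample(1:8, n, TRUE)), collapse = ",")
    kept <- sprintf("r%d", 1:5)
    p <- make_pileup(100L, "A", bases, quals, read_ids = ids)
    snps <- data.frame(chrom = "chrX", pos = 100L, allele1 = a[1],
                       allele2 = a[2], gene = "g", stringsAsFactors = FALSE)
    got <- count_alleles(p, snps, kept_reads = kept, min_baseq = 13)
    want <- brute_count_row(bases, quals, "A", a[1], a[2], ids, kept, 13)
    expect_equal(got$count_allele1, unname(want["c1"]))
    expect_equal(got$count_allele2, unname(want["c2"]))
    expect_equal(got$count_other, unname(want["other"]))
    expect_equal(got$qualsum_allele1, unname(want["q1"]))
    expect_equal(got$qualsum_allele2, unname(want["q2"]))
  }
})

test_that("haplotype assignment follows the day-0 majority with flagged ties", {
  cnt <- data.frame(chrom = "chrX", pos = c(1L, 2L, 3L), gene = "g",
                    sample = "day0", count_allele1 = c(30L, 10L, 5L),
                    count_allele2 = c(10L, 30L, 5L), count_other = 0L,
                    qualsum_allele1 = 0L, qualsum_allele2 = 0L,
                    stringsAsFactors = FALSE)
  asn <- assign_haplotypes(cnt)
  expect_equal(asn$xa_allele, c(1L, 2L, 1L))
  expect_equal(asn$tie_flag, c(FALSE, FALSE, TRUE))
  expect_identical(assign_haplotypes(cnt), asn)   # re-run is bit-identical
})

test_that("gene aggregation sums Xa/Xi reads and conserves counts", {
  cnt <- data.frame(chrom = "chrX", pos = c(1L, 2L), gene = "g",
                    sample = "day5",
                    count_allele1 = c(40L, 5L), count_allele2 = c(0L, 60L),
                    count_other = c(1L, 0L),
                    qualsum_allele1 = c(1600L, 200L),
                    qualsum_allele2 = c(0L, 2400L), stringsAsFactors = FALSE)
  asn <- data.frame(chrom = "chrX", pos = c(1L, 2L), gene = "g",
                    xa_allele = c(1L, 2L), tie_flag = FALSE,
                    stringsAsFactors = FALSE)
  s <- aggregate_gene(cnt, asn)
  expect_equal(s$xa_reads, 100L)
  expect_equal(s$xi_reads, 5L)
  expect_equal(s$xi_ratio, 5 / 105)
  expect_equal(s$xi_qualsum, 200L)
  expect_equal(s$n_snps, 2L)
  # the assignment maps different allele indices to Xa at the two SNPs,
  # so the gene is flagged phase-inconsistent (counts still aggregate)
  expect_false(s$hap_consistent)
})

test_that("phase-inconsistent genes are flagged and zero-read genes undefined", {
  cnt <- data.frame(chrom = "chrX", pos = c(1L, 2L, 3L), gene = c("g1", "g1", "g2"),
                    sample = "day0",
                    count_allele1 = c(40L, 5L, 0L), count_allele2 = c(0L, 60L, 0L),
                    count_other = 0L, qualsum_allele1 = 0L, qualsum_allele2 = 0L,
                    stringsAsFactors = FALSE)
  asn <- assign_haplotypes(cnt)
  s <- aggregate_gene(cnt, asn, drop_ties = FALSE)
  g1 <- s[s$gene == "g1", ]
  expect_false(g1$hap_consistent)
  g2 <- s[s$gene == "g2", ]
  expect_false(g2$defined)
  expect_true(is.na(g2$xi_ratio))
  # with the default tie exclusion the zero-count (tied) SNP drops out
  expect_false("g2" %in% aggregate_gene(cnt, asn)$gene)
})

test_that("counting a simulated dataset's pileups reproduces its bookkept counts", {
  ds <- simulate_allelic_dataset(simulation_config(n_genes = 15L,
                                                   depth_per_gene = list(min = 20, max = 150),
                                                   frac_escape = 0.2, seed = 55L),
                                 keep_read_level = TRUE)
  for (s in ds$samples) {
    got <- count_alleles(ds$pileups[[s]], ds$snps, min_baseq = 0, sample = s)
    want <- ds$counts[ds$counts$sample == s, ]
    rownames(want) <- NULL
    expect_equal(got$count_allele1, want$count_allele1)
    expect_equal(got$count_allele2, want$count_allele2)
    expect_equal(got$count_other, want$count_other)
    expect_equal(got$qualsum_allele1, want$qualsum_allele1)
    expect_equal(got$qualsum_allele2, want$qualsum_allele2)
  }
})

test_that("count conservation holds from SNP counts to gene summaries", {
  ds <- simulate_allelic_dataset(simulation_config(n_genes = 40L, seed = 77L))
  asn <- assign_haplotypes(ds$counts[ds$counts$sample == "day0", ])
  s <- aggregate_gene(ds$counts, asn, drop_ties = FALSE)
  per_gene <- aggregate(cbind(count_allele1, count_allele2) ~ gene + sample,
                        ds$counts, sum)
  m <- merge(s, per_gene, by = c("gene", "sample"))
  expect_equal(m$xa_reads + m$xi_reads, m$count_allele1 + m$count_allele2)
})

test_that("a deep escape gene's observed Xi ratio tracks its true fraction", {
  # true Xi fraction 0.3 at depth 1000: binomial s.d. of the ratio is
  # sqrt(0.3 * 0.7 / 1000) per gene (fraction fixed, so no beta spread)
  cfg <- simulation_config(n_genes = 40L, frac_escape = 1, frac_reactivated = 0,
                           xi_fraction_expressed = list(alpha = 3e5, beta = 7e5),
                           depth_per_gene = list(min = 1000, max = 1000),
                           total_snps = 80L, seed = 12L)
  ds <- simulate_allelic_dataset(cfg)
  asn <- assign_haplotypes(ds$counts[ds$counts$sample == "day0", ])
  s <- aggregate_gene(ds$counts, asn)
  s <- s[s$sample == "day5", ]
  expect_true(all(abs(s$xi_ratio - 0.3) < 3 * sqrt(0.3 * 0.7 / 1000) + 3e-3))
})

test_that("SNP VCF round-trips through write and read", {
  snps <- simulate_allelic_dataset(simulation_config(n_genes = 12L,
                                                     seed = 3L))$snps
  f <- tempfile(fileext = ".vcf")
  write_snp_vcf(snps, f)
  back <- read_snp_vcf(f)
  rownames(snps) <- rownames(back) <- NULL
  expect_equal(back, snps)
})
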