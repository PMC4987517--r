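#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study dataset.
#
# Writes a "paperlike" fixture bundle: 183 X-linked genes carrying 379
# clone-ascertained heterozygous SNPs, allele-specific read counts at day 0
# and day 5 around fusion, isogenic clone pileups for SNP discovery,
# dual-genome read-identifier sets, a qPCR Ct table and RNA-FISH intensity
# profiles, plus the generating ground truth.

library(xcireact)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 1L

dir <- file.path("results", "fixtures")
files <- make_fixtures("paperlike", seed = seed, dir = dir)

truth <- read.delim(files$ground_truth)
snps <- read_snp_vcf(files$snp_vcf)
cat("Simulated dataset written to", dir, "\n")
cat(sprintf("  %d genes, %d heterozygous SNPs\n", nrow(truth), nrow(snps)))
cat("  true class mix:\n")
print(table(truth$class))
cat("  read-depth summary (day-0 allelic reads per gene):\n")
counts <- read.delim(files$allele_counts)
d0 <- counts[counts$sample == "day0", ]
print(summary(tapply(d0$count_allele1 + d0$count_allele2, d0$gene, sum)))
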