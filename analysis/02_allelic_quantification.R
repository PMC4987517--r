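#!/usr/bin/env Rscript
# Stage 2: heterozygous-SNP ascertainment and allele-specific quantification.
#
# Discovers SNPs as positions where the two isogenic clones (opposite X
# haplotypes) show different consensus bases, restricts counting to
# human-specific reads, counts allele-supporting reads per SNP from the
# day-0 and day-5 pileups, assigns Xa/Xi from the day-0 majority, and
# aggregates to per-gene Xi ratios.

library(xcireact)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 1L
fx <- file.path("results", "fixtures")
if (!file.exists(file.path(fx, "manifest.yaml")))
  make_fixtures("paperlike", seed = seed, dir = fx)

clone_a <- read_pileup(file.path(fx, "pileup_clone_a.tsv"))
clone_b <- read_pileup(file.path(fx, "pileup_clone_b.tsv"))
snps_known <- read_snp_vcf(file.path(fx, "snps.vcf"))
discovered <- discover_het_snps(clone_a, clone_b, min_depth = 10,
                                min_purity = 0.9,
                                gene_map = snps_known[, c("chrom", "pos", "gene")])
cat(sprintf("SNP discovery: %d sites found, %d/%d known heterozygous SNPs recovered\n",
            nrow(discovered), sum(discovered$pos %in% snps_known$pos),
            nrow(snps_known)))

human <- readLines(file.path(fx, "read_ids_human.txt"))
mouse <- readLines(file.path(fx, "read_ids_mouse.txt"))
kept <- filter_species_specific(human, mouse)
cat(sprintf("Species filter: %d/%d human reads are human-specific (%.1f%% cross-mapped)\n",
            length(kept), length(human),
            100 * (1 - length(kept) / length(human))))

counts <- do.call(rbind, lapply(c("day0", "day5"), function(s)
  count_alleles(read_pileup(file.path(fx, sprintf("pileup_%s.tsv", s))),
                snps_known, min_baseq = 0, sample = s)))
assignment <- assign_haplotypes(counts[counts$sample == "day0", ])
cat(sprintf("Haplotype assignment: %d SNPs, %d ties excluded\n",
            nrow(assignment), sum(assignment$tie_flag)))

summaries <- aggregate_gene(counts, assignment)
out <- file.path("results", "gene_allelic_summaries.tsv")
dir.create("results", showWarnings = FALSE)
write.table(summaries, out, sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("Per-gene summaries written to %s (%d gene x sample rows)\n",
            out, nrow(summaries)))
cat("Xi-ratio distribution at day 5:\n")
print(summary(summaries$xi_ratio[summaries$sample == "day5"]))
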