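#' Ascertain heterozygous SNPs from two isogenic clone pileups
#'
#' Two clonal fibroblast populations expressing opposite X haplotypes behave
#' as haploid at X-linked heterozygous sites: a site whose consensus base
#' differs between the clones is a heterozygous SNP of the parental line.
#' A site is reported when both clones reach `min_depth`, the consensus base
#' accounts for at least `min_purity` of counted bases in each clone, and the
#' two consensus bases differ; allele1 is the clone-a consensus and allele2
#' the clone-b consensus.
#'
#' @param pileup_a,pileup_b Pileup tables of the two clones (see
#'   [read_pileup()] for the dialect).
#' @param min_depth Minimum counted depth per clone (>= 1).
#' @param min_purity Minimum consensus fraction per clone.
#' @param min_baseq Base-quality floor; lower-quality bases are ignored.
#' @param gene_map Optional data frame (chrom, pos, gene) assigning genes;
#'   sites without an assignment get `chrom:pos` as a placeholder identifier.
#' @return SnpSite data frame (chrom, pos, allele1, allele2, gene).
#' @export
discover_het_snps <- function(pileup_a, pileup_b, min_depth = 10L,
                              min_purity = 0.9, min_baseq = 13L,
                              gene_map = NULL) {
  if (min_depth < 1L) stop("'min_depth' must be >= 1", call. = FALSE)
  validate_pileup(pileup_a); validate_pileup(pileup_b)
  key_a <- paste(pileup_a$chrom, pileup_a$pos)
  key_b <- paste(pileup_b$chrom, pileup_b$pos)
  common <- intersect(key_a, key_b)
  ia <- match(common, key_a); ib <- match(common, key_b)

  consensus <- function(row) {
    b <- expand_bases(row$bases, row$ref)
    q <- phred_from_string(row$quals)
    keep <- q >= min_baseq & b %in% BASES
    b <- b[keep]
    if (length(b) < min_depth) return(c(NA_character_, "0"))
    tab <- table(factor(b, levels = BASES))
    top <- which.max(tab)
    if (tab[top] / length(b) < min_purity) return(c(NA_character_, "0"))
    c(BASES[top], "1")
  }
  cons_a <- t(vapply(ia, function(i) consensus(pileup_a[i, ]), character(2)))
  cons_b <- t(vapply(ib, function(i) consensus(pileup_b[i, ]), character(2)))
  ok <- cons_a[, 2] == "1" & cons_b[, 2] == "1" & cons_a[, 1] != cons_b[, 1]
  out <- data.frame(chrom = pileup_a$chrom[ia][ok], pos = pileup_a$pos[ia][ok],
                    allele1 = cons_a[ok, 1], allele2 = cons_b[ok, 1],
                    stringsAsFactors = FALSE)
  if (!is.null(gene_map)) {
    gi <- match(paste(out$chrom, out$pos), paste(gene_map$chrom, gene_map$pos))
    out$gene <- gene_map$gene[gi]
    out$gene[is.na(out$gene)] <- paste0(out$chrom[is.na(out$gene)], ":",
                                        out$pos[is.na(out$gene)])
  } else {
    out$gene <- paste0(out$chrom, ":", out$pos)
  }
  out[order(out$chrom, out$pos), , drop = FALSE]
}

#' Keep human-specific reads
#'
#' Reads aligning to both the human and the mouse genome are ambiguous in
#' inter-species fusions and are excluded: the result is the human-aligned
#' set minus the mouse-aligned set.
#'
#' @param human_ids,mouse_ids Character vectors of read identifiers.
#' @return Character vector of human-specific read identifiers.
#' @export
filter_species_specific <- function(human_ids, mouse_ids) {
  setdiff(human_ids, mouse_ids)
}

expand_bases <- function(bases, ref) {
  b <- strsplit(bases, "", fixed = TRUE)[[1]]
  b[b == "." | b == ","] <- ref
  toupper(b)
}

phred_from_string <- function(quals) {
  if (!nzchar(quals)) return(integer(0))
  utf8ToInt(quals) - 33L
}

#' Count allele-supporting reads at heterozygous SNPs
#'
#' Re-implements mpileup-style per-base counting on pileup text: at each SNP,
#' bases matching allele1 or allele2 are tallied with their summed Phred
#' qualities, any other base goes to `count_other`, reverse-strand symbols are
#' folded to uppercase, bases below the quality floor are dropped from counts
#' and quality sums, and (when read identifiers are present) reads outside
#' `kept_reads` are skipped.
#'
#' @param pileup Pileup table for one sample.
#' @param snps SnpSite table.
#' @param kept_reads `"all"` or a character vector of read identifiers to
#'   keep (e.g. the human-specific set from [filter_species_specific()]).
#' @param min_baseq Base-quality floor (Phred); default 13.
#' @param sample Sample label stored in the output.
#' @return AlleleCount data frame: chrom, pos, gene, sample, count_allele1,
#'   count_allele2, count_other, qualsum_allele1, qualsum_allele2. A SNP
#'   absent from the pileup yields a zero-count row, not an error.
#' @export
count_alleles <- function(pileup, snps, kept_reads = "all", min_baseq = 13L,
                          sample = "sample") {
  validate_pileup(pileup)
  validate_snps(snps)
  use_ids <- !(length(kept_reads) == 1L && identical(kept_reads, "all"))
  if (use_ids && is.null(pileup$read_ids))
    stop("kept_reads was given but the pileup carries no read identifiers",
         call. = FALSE)
  idx <- match(paste(snps$chrom, snps$pos), paste(pileup$chrom, pileup$pos))
  n <- nrow(snps)
  c1 <- c2 <- co <- q1 <- q2 <- integer(n)
  for (k in seq_len(n)) {
    i <- idx[k]
    if (is.na(i) || pileup$depth[i] == 0L) next
    b <- expand_bases(pileup$bases[i], pileup$ref[i])
    q <- phred_from_string(pileup$quals[i])
    keep <- q >= min_baseq
    if (use_ids) {
      ids <- strsplit(pileup$read_ids[i], ",", fixed = TRUE)[[1]]
      keep <- keep & ids %in% kept_reads
    }
    b <- b[keep]; q <- q[keep]
    i1 <- b == snps$allele1[k]; i2 <- b == snps$allele2[k]
    c1[k] <- sum(i1); c2[k] <- sum(i2); co[k] <- sum(!i1 & !i2)
    q1[k] <- sum(q[i1]); q2[k] <- sum(q[i2])
  }
  data.frame(chrom = snps$chrom, pos = snps$pos, gene = snps$gene,
             sample = sample, count_allele1 = c1, count_allele2 = c2,
             count_other = co, qualsum_allele1 = q1, qualsum_allele2 = q2,
             stringsAsFactors = FALSE)
}

#' Assign Xa/Xi haplotypes from day-0 allele counts
#'
#' At each SNP, the allele carrying the majority of reads in the unfused
#' fibroblasts (day 0) is the major, active-X (Xa) allele; the minor allele
#' is assigned to the inactive X (Xi). Ties are flagged and resolved to
#' allele1; downstream aggregation excludes tie-flagged SNPs by default.
#'
#' @param day0_counts AlleleCount table for the day-0 sample.
#' @return Data frame: chrom, pos, gene, xa_allele (1 or 2), tie_flag.
#' @export
assign_haplotypes <- function(day0_counts) {
  tie <- day0_counts$count_allele1 == day0_counts$count_allele2
  xa <- ifelse(day0_counts$count_allele1 >= day0_counts$count_allele2, 1L, 2L)
  data.frame(chrom = day0_counts$chrom, pos = day0_counts$pos,
             gene = day0_counts$gene, xa_allele = xa, tie_flag = tie,
             stringsAsFactors = FALSE)
}

#' Aggregate allele counts to per-gene Xa/Xi summaries
#'
#' Maps each SNP's allele1/allele2 counts onto Xa/Xi through the day-0
#' haplotype assignment and sums over the gene's SNPs, yielding per
#' (gene, sample) the Xa and Xi read totals, the Xi ratio Xi/(Xa+Xi), and the
#' summed Phred quality of Xi-supporting bases (a mixture-model input).
#' Genes whose (non-tied) SNPs disagree on which allele index is Xa are
#' phase-inconsistent and flagged; genes with zero allelic reads get an
#' undefined (NA) ratio and `defined = FALSE`.
#'
#' @param counts AlleleCount table (any number of samples).
#' @param assignment Haplotype table from [assign_haplotypes()].
#' @param drop_ties Exclude tie-flagged SNPs from aggregation (default TRUE).
#' @return GeneAllelicSummary data frame: gene, sample, xa_reads, xi_reads,
#'   n_reads, xi_ratio, xi_qualsum, n_snps, hap_consistent, defined.
#' @export
aggregate_gene <- function(counts, assignment, drop_ties = TRUE) {
  key <- paste(counts$chrom, counts$pos)
  akey <- paste(assignment$chrom, assignment$pos)
  ai <- match(key, akey)
  if (anyNA(ai))
    stop("every counted SNP needs a haplotype assignment; missing at ",
         key[which(is.na(ai))[1]], call. = FALSE)
  xa_allele <- assignment$xa_allele[ai]
  tie <- assignment$tie_flag[ai]
  keep <- if (drop_ties) !tie else rep(TRUE, length(tie))
  d <- counts[keep, , drop = FALSE]
  xa_allele <- xa_allele[keep]

  xa <- ifelse(xa_allele == 1L, d$count_allele1, d$count_allele2)
  xi <- ifelse(xa_allele == 1L, d$count_allele2, d$count_allele1)
  xi_q <- ifelse(xa_allele == 1L, d$qualsum_allele2, d$qualsum_allele1)

  grp <- interaction(d$gene, d$sample, drop = TRUE, sep = "\r")
  sum_by <- function(x) as.vector(tapply(x, grp, sum))
  lev <- levels(grp)
  parts <- do.call(rbind, strsplit(lev, "\r", fixed = TRUE))
  out <- data.frame(gene = parts[, 1], sample = parts[, 2],
                    xa_reads = sum_by(xa), xi_reads = sum_by(xi),
                    stringsAsFactors = FALSE)
  out$n_reads <- out$xa_reads + out$xi_reads
  out$xi_ratio <- ifelse(out$n_reads > 0, out$xi_reads / out$n_reads, NA_real_)
  out$xi_qualsum <- sum_by(xi_q)
  out$n_snps <- as.vector(tapply(rep(1L, nrow(d)), grp, sum))
  hap_ok <- tapply(xa_allele, grp, function(x) length(unique(x)) == 1L)
  out$hap_consistent <- as.vector(hap_ok)
  out$defined <- out$n_reads > 0
  rownames(out) <- NULL
  out[order(out$sample, out$gene), , drop = FALSE]
}
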