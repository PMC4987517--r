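#' Read a pileup table
#'
#' Parses the tab-separated pileup dialect used throughout the package: one
#' row per site with columns chrom, pos (1-based), ref, depth, base string,
#' quality string (Phred+33), and an optional 7th column of comma-joined read
#' identifiers. The base string holds one character per read: `ACGTN` (either
#' case; reverse-strand lowercase is folded to uppercase when counting) or
#' `.`/`,` for a match to the reference base.
#'
#' @param path File to read.
#' @return Data frame with columns chrom, pos, ref, depth, bases, quals, and
#'   read_ids when present.
#' @export
read_pileup <- function(path) {
  if (!file.exists(path))
    stop("missing input file '", path, "'", call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 6L | nf > 7L)
  if (length(bad))
    stop("pileup parse error at line ", bad[1], ": expected 6 or 7 fields, got ",
         nf[bad[1]], call. = FALSE)
  m <- matrix("", length(fields), 7L)
  for (i in seq_along(fields)) m[i, seq_len(nf[i])] <- fields[[i]]
  df <- data.frame(chrom = m[, 1], pos = suppressWarnings(as.integer(m[, 2])),
                   ref = m[, 3], depth = suppressWarnings(as.integer(m[, 4])),
                   bases = m[, 5], quals = m[, 6], stringsAsFactors = FALSE)
  if (any(nf == 7L)) df$read_ids <- m[, 7]
  bad <- which(is.na(df$pos) | is.na(df$depth) | df$pos < 1L)
  if (length(bad))
    stop("pileup parse error at line ", bad[1], ": invalid position or depth",
         call. = FALSE)
  validate_pileup(df)
  df
}

validate_pileup <- function(df) {
  nb <- nchar(df$bases); nq <- nchar(df$quals)
  bad <- which(nb != df$depth | nq != df$depth)
  if (length(bad))
    stop("pileup parse error at line ", bad[1],
         ": base/quality string length does not match depth", call. = FALSE)
  if (!is.null(df$read_ids)) {
    nid <- vapply(strsplit(df$read_ids, ",", fixed = TRUE), length, integer(1))
    nid[!nzchar(df$read_ids)] <- 0L
    bad <- which(nzchar(df$read_ids) & nid != df$depth)
    if (length(bad))
      stop("pileup parse error at line ", bad[1],
           ": read-id count does not match depth", call. = FALSE)
  }
  invisible(df)
}

#' Write a pileup table
#'
#' @param df Pileup data frame as returned by [read_pileup()].
#' @param path Output file.
#' @export
write_pileup <- function(df, path) {
  cols <- c("chrom", "pos", "ref", "depth", "bases", "quals")
  if (!is.null(df$read_ids)) cols <- c(cols, "read_ids")
  utils::write.table(df[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a heterozygous-SNP table as minimal VCF
#'
#' One record per site with REF = allele1 and ALT = allele2 and the gene
#' assignment carried as `GENE=` in INFO.
#'
#' @param snps SnpSite table (chrom, pos, allele1, allele2, gene).
#' @param path Output file.
#' @export
write_snp_vcf <- function(snps, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene assignment\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\t.\tGENE=%s",
                     snps$chrom, snps$pos, snps$allele1, snps$allele2,
                     snps$gene), con)
  invisible(path)
}

#' Read a heterozygous-SNP table from a minimal VCF
#'
#' @param path VCF file written by [write_snp_vcf()] (or any VCF whose REF and
#'   ALT are single bases and whose INFO contains `GENE=`).
#' @return SnpSite data frame (chrom, pos, allele1, allele2, gene).
#' @export
read_snp_vcf <- function(path) {
  if (!file.exists(path))
    stop("missing input file '", path, "'", call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gene <- sub(".*GENE=([^;]+).*", "\\1", fix$INFO)
  gene[!grepl("GENE=", fix$INFO)] <- NA_character_
  snps <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                     allele1 = fix$REF, allele2 = fix$ALT, gene = gene,
                     stringsAsFactors = FALSE)
  validate_snps(snps)
  snps
}

validate_snps <- function(snps) {
  if (any(!snps$allele1 %in% BASES) || any(!snps$allele2 %in% BASES))
    stop("invalid SNP table: alleles must be single bases A/C/G/T", call. = FALSE)
  if (any(snps$allele1 == snps$allele2))
    stop("invalid SNP table: alleles must differ", call. = FALSE)
  if (any(is.na(snps$pos) | snps$pos < 1L))
    stop("invalid SNP table: positions must be >= 1", call. = FALSE)
  if (any(is.na(snps$gene) | !nzchar(snps$gene)))
    stop("invalid SNP table: gene assignment must be non-empty", call. = FALSE)
  invisible(snps)
}

#' Write RNA-FISH intensity profiles as CSV
#'
#' Long format with one row per pixel, carrying the spatial scale and
#' background statistics so profiles can be reconstructed exactly.
#'
#' @param profiles List of [fish_profile()] objects.
#' @param path Output CSV.
#' @param labels Optional per-profile labels stored alongside.
#' @export
write_fish_profiles <- function(profiles, path, labels = NULL) {
  rows <- lapply(seq_along(profiles), function(i) {
    p <- profiles[[i]]
    data.frame(profile_id = i,
               label = if (is.null(labels)) NA_character_ else labels[i],
               channel = p$channel, pixels_per_um = p$pixels_per_um,
               background_mean = p$background_mean,
               background_sd = p$background_sd,
               pixel = seq_along(p$values), value = p$values,
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read RNA-FISH intensity profiles from CSV
#'
#' @param path CSV written by [write_fish_profiles()].
#' @return List with `profiles` and `labels`.
#' @export
read_fish_profiles <- function(path) {
  if (!file.exists(path))
    stop("missing input file '", path, "'", call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  ids <- unique(df$profile_id)
  profiles <- lapply(ids, function(i) {
    d <- df[df$profile_id == i, ]
    d <- d[order(d$pixel), ]
    fish_profile(d$value, d$pixels_per_um[1], channel = d$channel[1],
                 background_mean = d$background_mean[1],
                 background_sd = d$background_sd[1])
  })
  labels <- vapply(ids, function(i) df$label[df$profile_id == i][1], character(1))
  list(profiles = profiles, labels = labels)
}
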