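#' Configuration for the synthetic allele-specific XCI dataset
#'
#' Bundles the knobs of the synthetic RNA-seq generator. Defaults emulate the
#' statistical structure of the clone-based allele-specific study: ~183
#' X-linked genes carrying ~2 heterozygous SNPs each, per-gene SNP-overlapping
#' depths spanning tens to thousands of reads, a silenced majority of genes
#' whose Xi-allele reads arise purely from sequencing error, and a minority of
#' escaping / reactivation-sensitive genes with overdispersed Xi fractions.
#'
#' @param n_genes Number of simulated X-linked genes.
#' @param snps_per_gene List with `mean` and `dispersion`: SNPs per gene are
#'   drawn as 1 + NegBinom(mu = mean - 1, size = dispersion).
#' @param total_snps Optional exact total SNP count; when given, every gene
#'   receives one SNP and the remainder is spread multinomially (overrides
#'   `snps_per_gene`).
#' @param depth_per_gene Either `list(min, max)` for a discrete uniform depth,
#'   or `list(meanlog, sdlog, min, max)` for a log-normal depth truncated to
#'   `[min, max]`. Depth is the number of SNP-overlapping allelic reads per
#'   gene per sample.
#' @param frac_escape Expected proportion of genes escaping XCI (Xi-expressed
#'   at day 0 and after fusion).
#' @param frac_reactivated Expected proportion of reactivation-sensitive genes
#'   (Xi-silent at day 0, Xi-expressed after fusion).
#' @param frac_late_reactivated Expected proportion of genes reactivating only
#'   at the optional third timepoint (requires `include_day6 = TRUE`).
#' @param xi_fraction_expressed List with Beta shape parameters `alpha`,
#'   `beta`: the true Xi fraction of an Xi-expressing gene is drawn once per
#'   gene from this distribution and shared across its SNPs.
#' @param phred_quality_dist List with integer vector `q` and weights `prob`:
#'   per-read Phred base qualities are i.i.d. draws from this distribution.
#' @param cross_map_fraction Proportion of human reads that also align to the
#'   mouse genome (excluded downstream).
#' @param xi_error_share Share of base-call errors that hit the Xi allele.
#'   Under standard Phred semantics a miscall lands uniformly on the 3
#'   alternative bases, hence the default 1/3.
#' @param include_day6 Add a third timepoint ("day6") to the simulated
#'   samples.
#' @param seed Integer seed; identical seed + config gives identical output.
#'
#' @return An object of class `xci_sim_config` (a validated list).
#' @export
simulation_config <- function(n_genes = 183L,
                              snps_per_gene = list(mean = 379 / 183, dispersion = 2),
                              total_snps = NULL,
                              depth_per_gene = list(meanlog = log(200), sdlog = 1,
                                                    min = 5, max = 5000),
                              frac_escape = 0.08,
                              frac_reactivated = 0.10,
                              frac_late_reactivated = 0,
                              xi_fraction_expressed = list(alpha = 3, beta = 7),
                              phred_quality_dist = list(q = c(30L, 35L, 40L),
                                                        prob = c(0.15, 0.25, 0.60)),
                              cross_map_fraction = 0.05,
                              xi_error_share = 1 / 3,
                              include_day6 = FALSE,
                              seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), snps_per_gene = snps_per_gene,
              total_snps = if (!is.null(total_snps)) as.integer(total_snps),
              depth_per_gene = depth_per_gene, frac_escape = frac_escape,
              frac_reactivated = frac_reactivated,
              frac_late_reactivated = frac_late_reactivated,
              xi_fraction_expressed = xi_fraction_expressed,
              phred_quality_dist = phred_quality_dist,
              cross_map_fraction = cross_map_fraction,
              xi_error_share = xi_error_share,
              include_day6 = isTRUE(include_day6), seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "xci_sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  chk_prop <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
      stop("configuration error: '", nm, "' must be a proportion in [0, 1]",
           call. = FALSE)
  }
  if (!is.finite(cfg$n_genes) || cfg$n_genes < 1L)
    stop("configuration error: 'n_genes' must be >= 1", call. = FALSE)
  chk_prop(cfg$frac_escape, "frac_escape")
  chk_prop(cfg$frac_reactivated, "frac_reactivated")
  chk_prop(cfg$frac_late_reactivated, "frac_late_reactivated")
  chk_prop(cfg$cross_map_fraction, "cross_map_fraction")
  chk_prop(cfg$xi_error_share, "xi_error_share")
  tot <- cfg$frac_escape + cfg$frac_reactivated + cfg$frac_late_reactivated
  if (tot > 1)
    stop("configuration error: class fractions must sum to <= 1", call. = FALSE)
  if (cfg$frac_late_reactivated > 0 && !cfg$include_day6)
    stop("configuration error: 'frac_late_reactivated' requires include_day6 = TRUE",
         call. = FALSE)
  bp <- cfg$xi_fraction_expressed
  if (!is.numeric(bp$alpha) || !is.numeric(bp$beta) || bp$alpha <= 0 || bp$beta <= 0)
    stop("configuration error: Beta parameters of 'xi_fraction_expressed' must be > 0",
         call. = FALSE)
  pq <- cfg$phred_quality_dist
  if (length(pq$q) != length(pq$prob) || any(pq$prob < 0) || sum(pq$prob) <= 0 ||
      any(pq$q < 0))
    stop("configuration error: invalid 'phred_quality_dist'", call. = FALSE)
  dp <- cfg$depth_per_gene
  if (!is.null(dp$min) && dp$min < 1)
    stop("configuration error: minimum depth must be >= 1", call. = FALSE)
  if (!is.null(cfg$total_snps) && cfg$total_snps < cfg$n_genes)
    stop("configuration error: 'total_snps' must be >= n_genes", call. = FALSE)
  invisible(cfg)
}

draw_depths <- function(n, spec) {
  if (!is.null(spec$meanlog)) {
    lo <- if (is.null(spec$min)) 1 else spec$min
    hi <- if (is.null(spec$max)) Inf else spec$max
    d <- round(stats::rlnorm(n, spec$meanlog, spec$sdlog))
    bad <- which(d < lo | d > hi)
    for (i in seq_len(20L)) {         # truncation by resampling, then clamp
      if (!length(bad)) break
      d[bad] <- round(stats::rlnorm(length(bad), spec$meanlog, spec$sdlog))
      bad <- which(d < lo | d > hi)
    }
    pmin(pmax(d, lo), hi)
  } else {
    vals <- seq.int(spec$min, spec$max)
    vals[sample.int(length(vals), n, replace = TRUE)]
  }
}

BASES <- c("A", "C", "G", "T")

# Emit the allelic reads overlapping one SNP in one sample.
# For a silenced gene (xi_frac = 0) every read is an Xa template; a read with
# Phred quality q is miscalled with probability 10^(-q/10), and a miscall hits
# the Xi allele with probability `share` (the other errors are counted as
# "other" bases). For an Xi-expressing gene each read is an Xi template with
# probability xi_frac, with no further error layer.
emit_snp_reads <- function(n, xi_frac, qdist, share) {
  q <- qdist$q[sample.int(length(qdist$q), n, replace = TRUE, prob = qdist$prob)]
  if (xi_frac <= 0) {
    e <- 10^(-q / 10)
    u <- stats::runif(n)
    is_xi <- u < share * e
    is_other <- !is_xi & u < e
  } else {
    is_xi <- stats::runif(n) < xi_frac
    is_other <- rep(FALSE, n)
  }
  list(q = q, is_xi = is_xi, is_other = is_other)
}

#' Simulate a full allele-specific RNA-seq count dataset
#'
#' Draws a gene universe with per-gene true classes (escape,
#' reactivation-sensitive, refractory), heterozygous SNPs, per-sample depths,
#' and per-SNP allele counts with summed base qualities, for timepoints
#' "day0" and "day5" (plus "day6" when configured). The mapping of the true
#' Xa allele onto allele1/allele2 is randomized per SNP so that haplotype
#' assignment from day-0 majorities is genuinely exercised.
#'
#' @param config An [simulation_config()] object.
#' @param keep_read_level Keep per-read base/quality strings so that pileup
#'   tables can be emitted (costs memory; needed by [write_pileup()]-based
#'   round trips and [make_fixtures()]).
#' @return A list of class `xci_dataset` with elements `snps` (SnpSite table:
#'   chrom, pos, allele1, allele2, gene), `counts` (AlleleCount table, one row
#'   per SNP x sample), `truth` (per-gene class and true Xi fractions),
#'   `truth_snp` (per-SNP true Xa allele index), `samples`, and — when
#'   `keep_read_level` — `pileups`, a named list of pileup tables per sample.
#' @export
simulate_allelic_dataset <- function(config = simulation_config(),
                                     keep_read_level = FALSE) {
  validate_sim_config(config)
  set.seed(config$seed)
  G <- config$n_genes

  probs <- c(config$frac_escape, config$frac_reactivated,
             config$frac_late_reactivated)
  cls <- sample(c("escape", "reactivation_sensitive", "late_sensitive",
                  "refractory"),
                G, replace = TRUE, prob = c(probs, 1 - sum(probs)))

  bp <- config$xi_fraction_expressed
  f_gene <- ifelse(cls == "refractory", 0, stats::rbeta(G, bp$alpha, bp$beta))

  samples <- c("day0", "day5", if (config$include_day6) "day6")
  xi_frac <- matrix(0, G, length(samples), dimnames = list(NULL, samples))
  xi_frac[cls == "escape", ] <- f_gene[cls == "escape"]
  xi_frac[cls == "reactivation_sensitive", setdiff(samples, "day0")] <-
    f_gene[cls == "reactivation_sensitive"]
  if (config$include_day6)
    xi_frac[cls == "late_sensitive", "day6"] <- f_gene[cls == "late_sensitive"]

  truth <- data.frame(
    gene = sprintf("gene_%03d", seq_len(G)),
    class = ifelse(cls == "late_sensitive", "reactivation_sensitive", cls),
    reactivation_day = ifelse(cls == "reactivation_sensitive", "day5",
                       ifelse(cls == "late_sensitive", "day6", NA_character_)),
    stringsAsFactors = FALSE
  )
  for (s in samples) truth[[paste0("xi_frac_", s)]] <- xi_frac[, s]

  if (!is.null(config$total_snps)) {
    extra <- stats::rmultinom(1, config$total_snps - G, rep(1, G))[, 1]
    n_snps <- 1L + extra
  } else {
    sp <- config$snps_per_gene
    n_snps <- 1L + stats::rnbinom(G, size = sp$dispersion,
                                  mu = max(sp$mean - 1, 1e-9))
  }
  S <- sum(n_snps)
  pos <- sort(sample.int(154e6, S))
  snp_gene <- rep(truth$gene, n_snps)
  gene_idx <- rep(seq_len(G), n_snps)
  al <- t(vapply(seq_len(S), function(i) sample(BASES, 2L), character(2)))
  # clone-derived allele labels are phased within a gene, so the Xa <-> index
  # mapping is drawn per gene and shared by its SNPs
  xa_is_allele1 <- (stats::runif(G) < 0.5)[gene_idx]

  snps <- data.frame(chrom = "chrX", pos = pos, allele1 = al[, 1],
                     allele2 = al[, 2], gene = snp_gene,
                     stringsAsFactors = FALSE)
  truth_snp <- data.frame(chrom = "chrX", pos = pos, gene = snp_gene,
                          xa_allele = ifelse(xa_is_allele1, 1L, 2L),
                          stringsAsFactors = FALSE)

  qdist <- config$phred_quality_dist
  rows <- vector("list", length(samples))
  pile <- if (keep_read_level) vector("list", length(samples))
  for (si in seq_along(samples)) {
    s <- samples[si]
    depth_g <- draw_depths(G, config$depth_per_gene)
    c1 <- c2 <- co <- q1 <- q2 <- integer(S)
    bstr <- qstr <- character(S)
    for (g in seq_len(G)) {
      ii <- which(gene_idx == g)
      # split the gene's depth across its SNPs
      nn <- stats::rmultinom(1, depth_g[g], rep(1, length(ii)))[, 1]
      for (k in seq_along(ii)) {
        i <- ii[k]
        n <- nn[k]
        if (n == 0L) { bstr[i] <- qstr[i] <- ""; next }
        em <- emit_snp_reads(n, xi_frac[g, si], qdist, config$xi_error_share)
        xa_base <- if (xa_is_allele1[i]) al[i, 1] else al[i, 2]
        xi_base <- if (xa_is_allele1[i]) al[i, 2] else al[i, 1]
        n_xi <- sum(em$is_xi); n_ot <- sum(em$is_other)
        n_xa <- n - n_xi - n_ot
        qs_xa <- sum(em$q[!em$is_xi & !em$is_other])
        qs_xi <- sum(em$q[em$is_xi])
        if (xa_is_allele1[i]) {
          c1[i] <- n_xa; c2[i] <- n_xi; q1[i] <- qs_xa; q2[i] <- qs_xi
        } else {
          c1[i] <- n_xi; c2[i] <- n_xa; q1[i] <- qs_xi; q2[i] <- qs_xa
        }
        co[i] <- n_ot
        if (keep_read_level) {
          b <- rep(xa_base, n)
          b[em$is_xi] <- xi_base
          if (n_ot > 0) {
            others <- setdiff(BASES, c(al[i, 1], al[i, 2]))
            b[em$is_other] <- sample(others, n_ot, replace = TRUE)
          }
          bstr[i] <- paste(b, collapse = "")
          qstr[i] <- intToUtf8(em$q + 33L)
        }
      }
    }
    rows[[si]] <- data.frame(chrom = "chrX", pos = pos, gene = snp_gene,
                             sample = s, count_allele1 = c1,
                             count_allele2 = c2, count_other = co,
                             qualsum_allele1 = q1, qualsum_allele2 = q2,
                             stringsAsFactors = FALSE)
    if (keep_read_level) {
      dp <- c1 + c2 + co
      pile[[si]] <- data.frame(chrom = "chrX", pos = pos, ref = al[, 1],
                               depth = dp, bases = bstr, quals = qstr,
                               stringsAsFactors = FALSE)
    }
  }

  out <- list(snps = snps, counts = do.call(rbind, rows), truth = truth,
              truth_snp = truth_snp, samples = samples, config = config)
  if (keep_read_level) {
    names(pile) <- samples
    out$pileups <- pile
  }
  class(out) <- "xci_dataset"
  out
}

#' @export
print.xci_dataset <- function(x, ...) {
  cat("Synthetic allele-specific XCI dataset\n")
  cat("  genes:", nrow(x$truth), " SNPs:", nrow(x$snps),
      " samples:", paste(x$samples, collapse = ", "), "\n")
  print(table(x$truth$class))
  invisible(x)
}

#' Simulate pileups of two isogenic clones with opposite haplotype expression
#'
#' Clone a expresses allele 1 at every heterozygous site and clone b allele 2,
#' each contaminated by a per-base miscall rate; these are the inputs from
#' which heterozygous SNPs are ascertained. Optional null sites (same
#' consensus in both clones) let false-positive discovery be measured.
#'
#' @param snps SnpSite table (chrom, pos, allele1, allele2, gene).
#' @param depth Reads per site per clone (must be >= 1).
#' @param error_rate Per-base miscall probability in `[0, 1)`; a miscalled
#'   base is uniform over the 3 alternatives.
#' @param seed Integer seed.
#' @param qual Phred quality written for every base.
#' @param n_null_sites Number of extra non-SNP sites emitted with a shared
#'   consensus base.
#' @return List with pileup tables `clone_a` and `clone_b`.
#' @export
simulate_clone_pileups <- function(snps, depth, error_rate, seed = 1L,
                                   qual = 40L, n_null_sites = 0L) {
  if (length(depth) != 1L || !is.finite(depth) || depth < 1)
    stop("configuration error: 'depth' must be a positive count", call. = FALSE)
  if (error_rate < 0 || error_rate >= 1)
    stop("configuration error: 'error_rate' must be in [0, 1)", call. = FALSE)
  set.seed(seed)
  emit <- function(true_base) {
    b <- rep(true_base, depth)
    err <- stats::runif(depth) < error_rate
    if (any(err))
      b[err] <- vapply(which(err), function(j)
        sample(setdiff(BASES, true_base), 1L), character(1))
    paste(b, collapse = "")
  }
  build <- function(truths, chrom, pos, ref) {
    data.frame(chrom = chrom, pos = pos, ref = ref, depth = depth,
               bases = vapply(truths, emit, character(1)),
               quals = strrep(intToUtf8(qual + 33L), depth),
               stringsAsFactors = FALSE)
  }
  chrom <- snps$chrom; pos <- snps$pos
  if (n_null_sites > 0L) {
    null_pos <- setdiff(sample.int(154e6, n_null_sites + nrow(snps)), snps$pos)
    null_pos <- sort(null_pos[seq_len(n_null_sites)])
    null_base <- sample(BASES, n_null_sites, replace = TRUE)
    chrom <- c(chrom, rep("chrX", n_null_sites))
    pos_all <- c(pos, null_pos)
    a_truth <- c(snps$allele1, null_base)
    b_truth <- c(snps$allele2, null_base)
    ref <- c(snps$allele1, null_base)
    o <- order(pos_all)
    list(clone_a = build(a_truth[o], chrom[o], pos_all[o], ref[o]),
         clone_b = build(b_truth[o], chrom[o], pos_all[o], ref[o]))
  } else {
    list(clone_a = build(snps$allele1, chrom, pos, snps$allele1),
         clone_b = build(snps$allele2, chrom, pos, snps$allele1))
  }
}

#' Simulate read-identifier sets from dual-genome alignment
#'
#' Emulates aligning one RNA-seq library independently to the human and mouse
#' genomes: each human-aligned read also appears in the mouse-aligned set with
#' probability `cross_map_fraction`, and the mouse set additionally contains
#' `n_mouse` mouse-specific identifiers.
#'
#' @param n_human,n_mouse Counts of human-aligned reads and mouse-only reads.
#' @param cross_map_fraction Probability that a human read cross-maps.
#' @param seed Integer seed.
#' @return List with character vectors `human` and `mouse`.
#' @export
simulate_dual_genome_reads <- function(n_human, n_mouse, cross_map_fraction,
                                       seed = 1L) {
  if (cross_map_fraction < 0 || cross_map_fraction > 1)
    stop("configuration error: 'cross_map_fraction' must be in [0, 1]",
         call. = FALSE)
  if (n_human < 0 || n_mouse < 0)
    stop("configuration error: read counts must be >= 0", call. = FALSE)
  set.seed(seed)
  human <- sprintf("hsread%08d", seq_len(n_human))
  cross <- stats::runif(n_human) < cross_map_fraction
  mouse <- c(human[cross], sprintf("mmread%08d", seq_len(n_mouse)))
  list(human = human, mouse = mouse)
}

#' Simulate labelled 1-D XIST intensity profiles
#'
#' Generates line-scan pixel-intensity profiles of the three nuclear XIST
#' patterns: "compact" (one contiguous plateau of at least 2 um with nearly
#' constant intensity), "diffuse" (several sub-2-um peaks), and "none"
#' (background only). Background has mean 1 (arbitrary units) and s.d.
#' `noise_sd`; the same noise is added on top of the signal.
#'
#' @param n_per_class Profiles per class.
#' @param pixels_per_um Spatial sampling rate.
#' @param noise_sd Intensity noise standard deviation (background s.d.).
#' @param length_um Physical length of each line scan.
#' @param seed Integer seed.
#' @return List with `profiles` (list of [fish_profile()] objects) and
#'   `labels` (character vector, the construction classes).
#' @export
simulate_fish_profiles <- function(n_per_class = 100L, pixels_per_um = 20,
                                   noise_sd = 0.05, length_um = 10, seed = 1L) {
  if (pixels_per_um <= 0)
    stop("configuration error: 'pixels_per_um' must be > 0", call. = FALSE)
  set.seed(seed)
  npx <- round(length_um * pixels_per_um)
  bg_mean <- 1
  one <- function(label) {
    v <- rep(bg_mean, npx)
    if (label == "compact") {
      w <- round(stats::runif(1, 2.2, 3.5) * pixels_per_um)
      start <- sample.int(npx - w, 1L)
      v[start + seq_len(w)] <- bg_mean + stats::runif(1, 1.5, 2.5)
    } else if (label == "diffuse") {
      k <- sample(2:4, 1L)
      seg <- floor(npx / k)
      for (j in seq_len(k)) {
        w <- round(stats::runif(1, 0.3, 0.8) * pixels_per_um)
        lo <- (j - 1L) * seg + 1L
        start <- lo + sample.int(max(seg - w - 2L, 1L), 1L)
        idx <- start + seq_len(w)
        idx <- idx[idx <= npx]
        v[idx] <- bg_mean + stats::runif(1, 1.5, 2.5)
      }
    }
    if (noise_sd > 0) v <- v + stats::rnorm(npx, 0, noise_sd)
    fish_profile(v, pixels_per_um, channel = "XIST",
                 background_mean = bg_mean, background_sd = noise_sd)
  }
  labels <- rep(c("compact", "diffuse", "none"), each = n_per_class)
  list(profiles = lapply(labels, one), labels = labels)
}

#' Simulate a qPCR Ct table for relative-expression analysis
#'
#' Forward model of SYBR-green qPCR under perfect doubling: the reference
#' amplicon has a fixed Ct and each target's Ct is offset by -log2 of its true
#' expression relative to the reference, plus replicate noise.
#'
#' @param true_expression Named list or vector: per-target expression relative
#'   to the reference (one value per condition is recycled across replicates),
#'   given as a matrix/data.frame with conditions as rows and targets as
#'   columns, or a single named vector for one condition.
#' @param conditions Character vector of condition (sample) labels.
#' @param n_replicates Replicates per condition.
#' @param reference Name of the reference amplicon.
#' @param ct_reference Mean Ct of the reference amplicon.
#' @param noise_sd Ct measurement noise (cycles).
#' @param seed Integer seed.
#' @return Data frame with columns sample, target, replicate, ct.
#' @export
simulate_ct_table <- function(true_expression, conditions = rownames(true_expression),
                              n_replicates = 3L, reference = "GAPDH",
                              ct_reference = 18, noise_sd = 0.1, seed = 1L) {
  set.seed(seed)
  true_expression <- as.matrix(true_expression)
  targets <- colnames(true_expression)
  out <- list()
  for (ci in seq_along(conditions)) {
    for (r in seq_len(n_replicates)) {
      ct_ref <- ct_reference + stats::rnorm(1, 0, noise_sd)
      rows <- data.frame(sample = conditions[ci],
                         target = c(reference, targets),
                         replicate = r,
                         ct = c(ct_ref, ct_ref - log2(true_expression[ci, ]) +
                                  stats::rnorm(length(targets), 0, noise_sd)),
                         stringsAsFactors = FALSE)
      out[[length(out) + 1L]] <- rows
    }
  }
  do.call(rbind, out)
}
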