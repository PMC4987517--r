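# Independent oracles used to cross-check package computations. These stay
# deliberately naive: per-character loops and numeric integration, no shared
# code with the implementation.

# Brute-force allele recount of a single pileup row.
brute_count_row <- function(bases, quals, ref, allele1, allele2,
                            read_ids = NULL, kept = NULL, min_baseq = 13L) {
  b <- strsplit(bases, "")[[1]]
  q <- as.integer(charToRaw(quals)) - 33L
  ids <- if (!is.null(read_ids)) strsplit(read_ids, ",")[[1]]
  res <- c(c1 = 0L, c2 = 0L, other = 0L, q1 = 0L, q2 = 0L)
  for (j in seq_along(b)) {
    base <- toupper(b[j])
    if (base == "." || base == ",") base <- toupper(ref)
    if (q[j] < min_baseq) next
    if (!is.null(kept) && !(ids[j] %in% kept)) next
    if (base == allele1) {
      res["c1"] <- res["c1"] + 1L; res["q1"] <- res["q1"] + q[j]
    } else if (base == allele2) {
      res["c2"] <- res["c2"] + 1L; res["q2"] <- res["q2"] + q[j]
    } else {
      res["other"] <- res["other"] + 1L
    }
  }
  res
}

# Beta-binomial pmf by numeric integration over the latent success
# probability (independent of the lbeta closed form used in the package).
bb_pmf_quad <- function(x, n, alpha, beta) {
  stats::integrate(function(p) stats::dbinom(x, n, p) * stats::dbeta(p, alpha, beta),
                   0, 1, rel.tol = 1e-10)$value
}

# Mixture log-likelihood of data (x, n, err) at given parameters.
mixture_loglik_at <- function(x, n, err, pi0, alpha, beta) {
  l0 <- stats::dbinom(x, n, err, log = TRUE)
  l1 <- bb_lpmf(x, n, alpha, beta)
  la <- log(pi0) + l0
  lb <- log1p(-pi0) + l1
  mx <- pmax(la, lb)
  sum(mx + log(exp(la - mx) + exp(lb - mx)))
}

# Best mixture log-likelihood over a (pi0, mean, concentration) grid.
grid_search_loglik <- function(x, n, err, n_grid = 50L) {
  pi0s <- seq(0.01, 0.99, length.out = n_grid)
  means <- seq(0.02, 0.98, length.out = n_grid)
  concs <- 10^seq(0, 3, length.out = n_grid)
  l0 <- stats::dbinom(x, n, err, log = TRUE)
  lp <- log(pi0s); lq <- log1p(-pi0s)
  best <- -Inf
  for (m in means) {
    for (cc in concs) {
      l1 <- bb_lpmf(x, n, m * cc, (1 - m) * cc)
      la <- outer(l0, lp, "+")          # genes x pi0 grid
      lb <- outer(l1, lq, "+")
      mx <- pmax(la, lb)
      ll <- colSums(mx + log(exp(la - mx) + exp(lb - mx)))
      if (max(ll) > best) best <- max(ll)
    }
  }
  best
}

# Small hand-assembled pileup table.
make_pileup <- function(pos, ref, bases, quals, read_ids = NULL,
                        chrom = "chrX") {
  df <- data.frame(chrom = chrom, pos = pos, ref = ref,
                   depth = nchar(bases), bases = bases, quals = quals,
                   stringsAsFactors = FALSE)
  if (!is.null(read_ids)) df$read_ids <- read_ids
  df
}

# Phred string of n identical qualities.
qstr <- function(q, n) strrep(intToUtf8(q + 33L), n)

# Summary table built directly from per-gene (xi, n) pairs with all-Xi bases
# at quality q.
make_summaries <- function(xi, n, q = 40, sample = "day0",
                           gene = sprintf("g%03d", seq_along(xi))) {
  data.frame(gene = gene, sample = sample, xa_reads = n - xi, xi_reads = xi,
             n_reads = n, xi_ratio = ifelse(n > 0, xi / n, NA_real_),
             xi_qualsum = xi * q, n_snps = 1L, hap_consistent = TRUE,
             defined = n > 0, stringsAsFactors = FALSE)
}
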