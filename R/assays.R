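#' Relative expression by the 2^-DeltaCt method
#'
#' @param ct_target Ct of the gene of interest (cycles).
#' @param ct_reference Ct of the reference amplicon (e.g. GAPDH) measured on
#'   the same material.
#' @param efficiency Amplification efficiency per cycle; 2 means perfect
#'   doubling, giving the classic `2^-(ct_target - ct_reference)`.
#' @return Expression relative to the reference (vectorized; NA Ct values
#'   propagate as NA).
#' @export
relative_expression <- function(ct_target, ct_reference, efficiency = 2) {
  efficiency^-(ct_target - ct_reference)
}

sem <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

# Two-sided t-test of x against baseline y on replicate-level values, with
# the degenerate exact-zero-variance path handled explicitly.
ttest_vs_baseline <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L)
    return(list(p = NA_real_, flag = "single_replicate"))
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    # pooled variance is exactly zero: p degenerates to 0/1
    return(list(p = if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0,
                flag = "zero_variance"))
  }
  list(p = stats::t.test(x, y)$p.value, flag = NA_character_)
}

#' Summarize 2^-DeltaCt expression across replicates
#'
#' Computes per-replicate relative expression against the reference amplicon
#' (pairing reference and target Ct by sample and replicate), then reduces to
#' mean +/- s.e.m. per (sample, target) with an unadjusted two-sided t-test
#' against the baseline sample.
#'
#' @param ct_table Data frame with columns sample, target, replicate, ct.
#'   Ct values outside `(0, 45)` are flagged undetermined and treated as NA.
#' @param reference Reference amplicon name (default "GAPDH").
#' @param baseline Baseline sample for the t-test (e.g. "day0"); NULL skips
#'   testing.
#' @param efficiency Amplification efficiency per cycle.
#' @return Data frame: sample, target, mean_expression, sem, n_replicates,
#'   p_value, flag.
#' @export
summarize_ddct <- function(ct_table, reference = "GAPDH", baseline = NULL,
                           efficiency = 2) {
  ct <- ct_table$ct
  ct[!is.na(ct) & (ct <= 0 | ct >= 45)] <- NA_real_
  ct_table$ct <- ct
  ref <- ct_table[ct_table$target == reference, ]
  tgt <- ct_table[ct_table$target != reference, ]
  if (!nrow(ref)) stop("reference amplicon '", reference, "' not found",
                       call. = FALSE)
  ri <- match(paste(tgt$sample, tgt$replicate),
              paste(ref$sample, ref$replicate))
  tgt$expr <- relative_expression(tgt$ct, ref$ct[ri], efficiency)
  grp <- interaction(tgt$sample, tgt$target, drop = TRUE, sep = "\r")
  lev <- levels(grp)
  parts <- do.call(rbind, strsplit(lev, "\r", fixed = TRUE))
  out <- data.frame(sample = parts[, 1], target = parts[, 2],
                    mean_expression = as.vector(tapply(tgt$expr, grp, mean,
                                                       na.rm = TRUE)),
                    sem = as.vector(tapply(tgt$expr, grp, sem)),
                    n_replicates = as.vector(tapply(!is.na(tgt$expr), grp, sum)),
                    stringsAsFactors = FALSE)
  out$p_value <- NA_real_
  out$flag <- NA_character_
  if (!is.null(baseline)) {
    for (i in seq_len(nrow(out))) {
      if (out$sample[i] == baseline) next
      xs <- tgt$expr[tgt$sample == out$sample[i] & tgt$target == out$target[i]]
      ys <- tgt$expr[tgt$sample == baseline & tgt$target == out$target[i]]
      tt <- ttest_vs_baseline(xs, ys)
      out$p_value[i] <- tt$p
      out$flag[i] <- tt$flag
    }
  }
  rownames(out) <- NULL
  out
}

#' Digestion-efficiency-corrected allele-1 fraction
#'
#' In the SNP-restriction (RFLP-qPCR) assay, the restriction enzyme destroys
#' allele-2 templates at the SNP site and all templates at a control site in
#' the same exon. On digested material the SNP-site amplicon measures
#' `R = f + u (1 - f)`, where `f` is the true allele-1 fraction and `u` the
#' residual undigested template fraction reported by the control site; this
#' function inverts that model: `f = (R - u) / (1 - u)`, clamped to `[0, 1]`.
#'
#' @param r_ratio Measured SNP-site/total expression ratio on digested
#'   material (from `efficiency^-(ct_snp - ct_total)`).
#' @param undigested_frac Residual undigested fraction `u` from the control
#'   site; `u >= 0.5` is treated as digestion failure.
#' @param clamp_tol Negative corrected fractions larger than `-clamp_tol` are
#'   clamped to 0 with a warning; more negative values are an error.
#' @return Corrected allele-1 fraction in `[0, 1]` (vectorized).
#' @export
allele1_fraction <- function(r_ratio, undigested_frac, clamp_tol = 0.05) {
  if (any(undigested_frac < 0 | undigested_frac > 1, na.rm = TRUE))
    stop("undigested fraction must be in [0, 1]", call. = FALSE)
  if (any(undigested_frac >= 0.5, na.rm = TRUE))
    stop("digestion failure: residual undigested fraction >= 0.5; the assay ",
         "cannot resolve alleles", call. = FALSE)
  f <- (r_ratio - undigested_frac) / (1 - undigested_frac)
  if (any(f < -clamp_tol, na.rm = TRUE))
    stop("corrected allele-1 fraction below -", clamp_tol,
         ": inconsistent Ct inputs", call. = FALSE)
  if (any(f < 0, na.rm = TRUE)) {
    warning("negative corrected fraction clamped to 0", call. = FALSE)
    f <- pmax(f, 0)
  }
  pmin(f, 1)
}

#' Allele-1 fraction from restriction-assay Ct values
#'
#' Computes the raw ratio `R` and the residual undigested fraction `u` from
#' Ct measurements and applies [allele1_fraction()]. Two pairings for the
#' control site are supported: against the total amplicon on the same
#' digested material (default), or against the control site measured on
#' undigested material.
#'
#' @param ct_snp_digested Ct of the allele-1-specific SNP-site amplicon on
#'   digested cDNA.
#' @param ct_total Ct of the total (both-allele) amplicon on the same
#'   digested material.
#' @param ct_control_digested Ct of the control restriction-site amplicon on
#'   digested material; NA/undetermined means no residual signal (u = 0).
#' @param ct_control_undigested Ct of the control amplicon on undigested
#'   material (required for pairing `"digested_undigested"`).
#' @param pairing How the control site is normalized.
#' @param efficiency Amplification efficiency per cycle.
#' @param clamp_tol Passed to [allele1_fraction()].
#' @return Corrected allele-1 fraction (vectorized).
#' @export
rflp_fraction <- function(ct_snp_digested, ct_total, ct_control_digested,
                          ct_control_undigested = NULL,
                          pairing = c("digested_total", "digested_undigested"),
                          efficiency = 2, clamp_tol = 0.05) {
  pairing <- match.arg(pairing)
  r <- efficiency^-(ct_snp_digested - ct_total)
  r[is.na(ct_snp_digested)] <- 0   # undetermined SNP amplicon = no allele-1 signal
  u <- if (pairing == "digested_total") {
    efficiency^-(ct_control_digested - ct_total)
  } else {
    if (is.null(ct_control_undigested))
      stop("'ct_control_undigested' is required for pairing 'digested_undigested'",
           call. = FALSE)
    efficiency^-(ct_control_digested - ct_control_undigested)
  }
  u[is.na(ct_control_digested)] <- 0   # undetermined control = complete digestion
  allele1_fraction(r, u, clamp_tol = clamp_tol)
}

#' Forward model of the restriction assay (for simulation and validation)
#'
#' Generates the noiseless Ct values the assay would measure for a true
#' allele-1 fraction `f` and residual undigested fraction `u`; the exact
#' inverse of [rflp_fraction()] with pairing `"digested_total"`. A value of
#' `u = 0` yields an undetermined (NA) control Ct.
#'
#' @param f True allele-1 fraction in `[0, 1]`.
#' @param u Residual undigested fraction in `[0, 0.5)`.
#' @param ct_total Ct of the total amplicon on digested material.
#' @param efficiency Amplification efficiency per cycle.
#' @return Data frame: f, u, ct_snp_digested, ct_total, ct_control_digested.
#' @export
rflp_forward_ct <- function(f, u, ct_total = 25, efficiency = 2) {
  r <- f + u * (1 - f)
  lg <- function(x) ifelse(x > 0, -log(x) / log(efficiency), NA_real_)
  data.frame(f = f, u = u,
             ct_snp_digested = ct_total + lg(r),
             ct_total = ct_total,
             ct_control_digested = ct_total + lg(u))
}
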