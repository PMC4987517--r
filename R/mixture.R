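#' Beta-binomial log probability mass
#'
#' `P(X = x | n, alpha, beta)` for X ~ BetaBinomial(n, alpha, beta), i.e. a
#' binomial whose success probability is itself Beta(alpha, beta)-distributed.
#'
#' @param x Number of Xi-supporting reads.
#' @param n Total allelic reads.
#' @param alpha,beta Beta shape parameters (> 0).
#' @return Log probability (vectorized).
#' @export
bb_lpmf <- function(x, n, alpha, beta) {
  lchoose(n, x) + lbeta(x + alpha, n - x + beta) - lbeta(alpha, beta)
}

#' Settings for the beta-binomial mixture fit
#'
#' @param init_pi0 Initial weight of the silenced component.
#' @param init_mean,init_conc Initial mean and concentration
#'   (alpha + beta) of the expressed beta-binomial component.
#' @param restarts Number of seeded random restarts; each runs a short EM
#'   (capped at `restart_iter` iterations) and the best chain by
#'   log-likelihood is continued to convergence.
#' @param restart_iter Iteration cap for the restart phase.
#' @param tol Relative log-likelihood change below which EM stops.
#' @param max_iter Maximum EM iterations for the final chain.
#' @param err_share Share of base-call errors hitting the Xi allele (1/3
#'   under uniform miscalls over the 3 alternative bases).
#' @param err_bounds Bounds on the per-gene effective Xi miscall rate.
#' @param ab_bounds Bounds on alpha and beta, enforced by projection.
#' @param default_qbar Mean Phred quality assumed when the dataset contains
#'   no Xi-supporting reads at all.
#' @param seed Seed for the restart jitter.
#' @return A list of class `xci_mixture_config`.
#' @export
mixture_config <- function(init_pi0 = 0.8, init_mean = 0.3, init_conc = 20,
                           restarts = 10L, restart_iter = 25L,
                           tol = 1e-8, max_iter = 500L,
                           err_share = 1 / 3, err_bounds = c(1e-6, 0.05),
                           ab_bounds = c(1e-3, 1e4), default_qbar = 40,
                           seed = 1L) {
  cfg <- list(init_pi0 = init_pi0, init_mean = init_mean, init_conc = init_conc,
              restarts = as.integer(restarts),
              restart_iter = as.integer(restart_iter), tol = tol,
              max_iter = as.integer(max_iter), err_share = err_share,
              err_bounds = err_bounds, ab_bounds = ab_bounds,
              default_qbar = default_qbar, seed = as.integer(seed))
  class(cfg) <- "xci_mixture_config"
  cfg
}

# Per-gene effective Xi miscall rate from the summed Phred quality of
# Xi-supporting bases: err = share * 10^(-qbar/10) with qbar the mean quality
# of the gene's Xi reads, falling back to the dataset-wide mean when a gene
# has no Xi reads.
xi_error_rates <- function(xi_reads, xi_qualsum, config) {
  tot_reads <- sum(xi_reads)
  fallback <- if (tot_reads > 0) sum(xi_qualsum) / tot_reads else config$default_qbar
  qbar <- ifelse(xi_reads > 0, xi_qualsum / xi_reads, fallback)
  pmin(pmax(config$err_share * 10^(-qbar / 10), config$err_bounds[1]),
       config$err_bounds[2])
}

project_ab <- function(a, b, bounds) {
  c(min(max(a, bounds[1]), bounds[2]), min(max(b, bounds[1]), bounds[2]))
}

# One EM chain. x, n, l0 are per-gene data (l0 = silenced-component
# log-likelihood, fixed); returns parameters, the log-likelihood trace and
# convergence state. The (alpha, beta) M-step is numeric (L-BFGS-B on
# logit-mean/log-concentration), accepted only when it does not decrease the
# weighted expressed-component likelihood, so the EM ascent property holds.
run_em <- function(x, n, l0, pi0, a, b, tol, max_iter, ab_bounds) {
  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    l1 <- bb_lpmf(x, n, a, b)
    la <- log(pi0) + l0
    lb <- log1p(-pi0) + l1
    mx <- pmax(la, lb)
    ll_g <- mx + log(exp(la - mx) + exp(lb - mx))
    z <- exp(la - ll_g)
    ll <- sum(ll_g)
    trace <- c(trace, ll)
    if (is.finite(ll_old) && (ll - ll_old) <= tol * (abs(ll_old) + 1e-12)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    pi0 <- min(max(mean(z), 1e-8), 1 - 1e-8)
    w <- 1 - z
    if (sum(w) > 1e-8) {
      # lchoose(n, x) is constant in (alpha, beta) and dropped from the
      # objective
      neg_q <- function(th) {
        m <- stats::plogis(th[1]); cc <- exp(th[2])
        a_ <- m * cc; b_ <- (1 - m) * cc
        -sum(w * (lbeta(x + a_, n - x + b_) - lbeta(a_, b_)))
      }
      # the concentration box keeps alpha, beta <= ab_bounds[2] for any mean,
      # so the final projection can only lift a tiny shape upwards
      th0 <- c(stats::qlogis(a / (a + b)), log(a + b))
      opt <- try(stats::optim(th0, neg_q, method = "L-BFGS-B",
                              lower = c(-9, log(2 * ab_bounds[1])),
                              upper = c(9, log(ab_bounds[2])),
                              control = list(maxit = 15L)), silent = TRUE)
      if (!inherits(opt, "try-error") && is.finite(opt$value)) {
        m <- stats::plogis(opt$par[1]); cc <- exp(opt$par[2])
        ab <- project_ab(m * cc, (1 - m) * cc, ab_bounds)
        # accept the projected update only if it does not decrease Q
        if (sum(w * bb_lpmf(x, n, ab[1], ab[2])) >=
            sum(w * bb_lpmf(x, n, a, b)) - 1e-12) {
          a <- ab[1]; b <- ab[2]
        }
      }
    }
  }
  list(pi0 = pi0, alpha = a, beta = b, loglik = trace[length(trace)],
       loglik_trace = trace, converged = converged, n_iter = length(trace))
}

#' Fit the silenced/expressed beta-binomial mixture across genes
#'
#' Models each gene's Xi read count x out of n allelic reads as a two-
#' component mixture: with prior weight `pi0` the gene is silenced and its Xi
#' reads are base-call errors, x ~ Binomial(n, err) with a per-gene error
#' rate derived from the summed Phred quality of the Xi-supporting bases;
#' with weight `1 - pi0` the gene is expressed from the Xi and
#' x ~ BetaBinomial(n, alpha, beta), capturing overdispersed Xi fractions
#' across escaping/reactivated genes. Fitting is by EM with seeded random
#' restarts; the expressed-component M-step is numeric.
#'
#' @param summaries GeneAllelicSummary table from [aggregate_gene()] (one row
#'   per gene and sample; multiple samples are fitted jointly, sharing the
#'   error model and the expressed component). Rows with undefined ratios or
#'   phase-inconsistent genes are excluded when the corresponding flag
#'   columns are present.
#' @param config A [mixture_config()].
#' @return Object of class `xci_mixture_fit`: pi0, alpha, beta, mean, conc,
#'   err_rate (mean per-gene rate), fallback_qbar, loglik_trace (of the
#'   winning chain, non-decreasing), converged, n_iter, degenerate, n_obs,
#'   plus the config needed to score new genes.
#' @export
fit_mixture <- function(summaries, config = mixture_config()) {
  d <- summaries
  if (!is.null(d$defined)) d <- d[d$defined, , drop = FALSE]
  if (!is.null(d$hap_consistent)) d <- d[d$hap_consistent, , drop = FALSE]
  d <- d[d$n_reads > 0, , drop = FALSE]
  if (nrow(d) < 10L)
    stop("mixture fit needs at least 10 genes with defined Xi ratios",
         call. = FALSE)
  x <- d$xi_reads; n <- d$n_reads
  err <- xi_error_rates(d$xi_reads, d$xi_qualsum, config)
  tot_xi <- sum(d$xi_reads)
  fallback_qbar <- if (tot_xi > 0) sum(d$xi_qualsum) / tot_xi else config$default_qbar
  l0 <- stats::dbinom(x, n, err, log = TRUE)

  base <- list(pi0 = config$init_pi0, mean = config$init_mean,
               conc = config$init_conc)
  if (all(x == 0L)) {
    # degenerate: nothing for the expressed component to explain
    ab <- project_ab(base$mean * base$conc, (1 - base$mean) * base$conc,
                     config$ab_bounds)
    fit <- list(pi0 = 1, alpha = ab[1], beta = ab[2],
                loglik_trace = sum(l0), converged = TRUE, n_iter = 1L,
                degenerate = TRUE)
  } else {
    set.seed(config$seed)
    starts <- list(base)
    if (config$restarts > 1L) {
      for (r in seq_len(config$restarts - 1L)) {
        starts[[r + 1L]] <- list(pi0 = stats::runif(1, 0.5, 0.95),
                                 mean = stats::runif(1, 0.05, 0.6),
                                 conc = 10^stats::runif(1, 0.5, 2.5))
      }
    }
    chains <- lapply(starts, function(s) {
      ab <- project_ab(s$mean * s$conc, (1 - s$mean) * s$conc, config$ab_bounds)
      run_em(x, n, l0, s$pi0, ab[1], ab[2], config$tol,
             config$restart_iter, config$ab_bounds)
    })
    best <- chains[[which.max(vapply(chains, `[[`, numeric(1), "loglik"))]]
    fin <- run_em(x, n, l0, best$pi0, best$alpha, best$beta, config$tol,
                  config$max_iter, config$ab_bounds)
    fit <- list(pi0 = fin$pi0, alpha = fin$alpha, beta = fin$beta,
                loglik_trace = c(best$loglik_trace, fin$loglik_trace),
                converged = fin$converged, n_iter = best$n_iter + fin$n_iter,
                degenerate = FALSE)
    if (!fin$converged)
      warning("EM did not converge within ", config$max_iter, " iterations",
              call. = FALSE)
  }
  fit$mean <- fit$alpha / (fit$alpha + fit$beta)
  fit$conc <- fit$alpha + fit$beta
  fit$err_rate <- mean(err)
  fit$fallback_qbar <- fallback_qbar
  fit$n_obs <- nrow(d)
  fit$loglik <- fit$loglik_trace[length(fit$loglik_trace)]
  fit$config <- config
  class(fit) <- "xci_mixture_fit"
  fit
}

#' @export
print.xci_mixture_fit <- function(x, ...) {
  cat("Beta-binomial mixture fit (", x$n_obs, " gene observations)\n", sep = "")
  cat(sprintf("  pi0 (silenced weight): %.4f\n", x$pi0))
  cat(sprintf("  expressed component: mean %.4f, concentration %.2f (alpha %.3g, beta %.3g)\n",
              x$mean, x$conc, x$alpha, x$beta))
  cat(sprintf("  mean Xi miscall rate: %.3g\n", x$err_rate))
  cat(sprintf("  log-likelihood %.4f after %d iterations (%s%s)\n",
              x$loglik, x$n_iter,
              if (x$converged) "converged" else "NOT converged",
              if (x$degenerate) ", degenerate: all genes at zero Xi reads" else ""))
  invisible(x)
}

#' Per-gene probability of being silenced (tau0)
#'
#' The escape-probability score tau0 is the posterior probability that a gene
#' belongs to the silenced mixture component, given its Xi read count, total
#' allelic depth, and the base-quality-derived error rate:
#' `tau0 = pi0 L0 / (pi0 L0 + (1 - pi0) L1)`. Small tau0 means strong
#' evidence of Xi expression; tau0 is monotone non-increasing in the Xi read
#' count at fixed depth.
#'
#' @param summaries GeneAllelicSummary rows to score (must all have
#'   n_reads > 0; filter undefined genes first).
#' @param fit An `xci_mixture_fit`.
#' @return Numeric vector of tau0 values in `[0, 1]`.
#' @export
escape_probability <- function(summaries, fit) {
  if (any(summaries$n_reads <= 0 | is.na(summaries$n_reads)))
    stop("zero allelic depth: filter genes with undefined Xi ratios before ",
         "computing escape probabilities", call. = FALSE)
  cfg <- fit$config
  cfg$default_qbar <- fit$fallback_qbar
  err <- xi_error_rates(summaries$xi_reads, summaries$xi_qualsum, cfg)
  l0 <- stats::dbinom(summaries$xi_reads, summaries$n_reads, err, log = TRUE)
  l1 <- bb_lpmf(summaries$xi_reads, summaries$n_reads, fit$alpha, fit$beta)
  la <- log(fit$pi0) + l0
  lb <- log1p(-fit$pi0) + l1
  mx <- pmax(la, lb)
  tau0 <- exp(la - (mx + log(exp(la - mx) + exp(lb - mx))))
  pmin(pmax(tau0, 0), 1)
}

#' Call Xi expression per gene and sample
#'
#' A gene is called expressed from the Xi when its Xi ratio exceeds
#' `xi_ratio_min` (default 10%) OR its probability of being silenced is at
#' most `tau0_max` (default 0.05). No multiple-testing correction is applied.
#'
#' @param summaries GeneAllelicSummary rows (n_reads > 0).
#' @param fit An `xci_mixture_fit` used to compute tau0 (ignored when `tau0`
#'   is supplied).
#' @param tau0 Optional pre-computed silenced-posterior vector.
#' @param xi_ratio_min Xi-ratio threshold.
#' @param tau0_max Significance threshold on the silenced posterior.
#' @param tau_direction `"silenced_posterior"` reports tau0 as the posterior
#'   of the silenced component (small = expressed); `"escape_posterior"`
#'   reports its complement. The call itself is identical either way.
#' @return GeneCall data frame: gene, sample, tau0, xi_ratio, n_reads,
#'   expressed_from_xi, reason (ratio_rule / tau0_rule / both / none).
#' @export
call_xi_expression <- function(summaries, fit = NULL, tau0 = NULL,
                               xi_ratio_min = 0.10, tau0_max = 0.05,
                               tau_direction = c("silenced_posterior",
                                                 "escape_posterior")) {
  tau_direction <- match.arg(tau_direction)
  if (is.null(tau0)) {
    if (is.null(fit)) stop("either 'fit' or 'tau0' must be given", call. = FALSE)
    tau0 <- escape_probability(summaries, fit)
  }
  ratio_hit <- summaries$xi_ratio > xi_ratio_min
  tau_hit <- tau0 <= tau0_max
  reason <- ifelse(ratio_hit & tau_hit, "both",
            ifelse(ratio_hit, "ratio_rule",
            ifelse(tau_hit, "tau0_rule", "none")))
  data.frame(gene = summaries$gene, sample = summaries$sample,
             tau0 = if (tau_direction == "silenced_posterior") tau0 else 1 - tau0,
             xi_ratio = summaries$xi_ratio, n_reads = summaries$n_reads,
             expressed_from_xi = ratio_hit | tau_hit, reason = reason,
             stringsAsFactors = FALSE)
}

#' Classify genes across two timepoints
#'
#' Applies the read filter first — a gene must carry at least `min_reads`
#' SNP-overlapping allelic reads at BOTH timepoints — then assigns: `escape`
#' (Xi-expressed at day 0 and after fusion), `reactivation_sensitive`
#' (Xi-expressed after fusion only), `refractory` (expressed at neither).
#' Genes expressed at day 0 only have no named category and are binned
#' refractory with `day0_only = TRUE`. Genes present at a single timepoint
#' are `filtered` with reason `missing_timepoint`.
#'
#' @param day0_calls,dayN_calls GeneCall tables from [call_xi_expression()].
#' @param min_reads Read filter (default 20; genes with 19 reads are dropped,
#'   genes with exactly 20 pass).
#' @param strict Use a strictly-greater filter (> min_reads) instead of >=.
#' @return GeneClass data frame, one row per gene in the union universe.
#' @export
classify_genes <- function(day0_calls, dayN_calls, min_reads = 20L,
                           strict = FALSE) {
  genes <- union(day0_calls$gene, dayN_calls$gene)
  i0 <- match(genes, day0_calls$gene)
  iN <- match(genes, dayN_calls$gene)
  n0 <- day0_calls$n_reads[i0]
  nN <- dayN_calls$n_reads[iN]
  pass_n <- function(n) !is.na(n) & (if (strict) n > min_reads else n >= min_reads)
  present <- !is.na(i0) & !is.na(iN)
  passed <- present & pass_n(n0) & pass_n(nN)
  e0 <- day0_calls$expressed_from_xi[i0]
  eN <- dayN_calls$expressed_from_xi[iN]
  category <- ifelse(!passed, "filtered",
              ifelse(e0 & eN, "escape",
              ifelse(!e0 & eN, "reactivation_sensitive", "refractory")))
  data.frame(gene = genes, category = category,
             passed_read_filter = passed,
             filter_reason = ifelse(passed, NA_character_,
                              ifelse(!present, "missing_timepoint",
                                     "below_min_reads")),
             expressed_day0 = e0, expressed_dayN = eN,
             n_reads_day0 = n0, n_reads_dayN = nN,
             tau0_day0 = day0_calls$tau0[i0], tau0_dayN = dayN_calls$tau0[iN],
             xi_ratio_day0 = day0_calls$xi_ratio[i0],
             xi_ratio_dayN = dayN_calls$xi_ratio[iN],
             day0_only = passed & e0 & !eN,
             reactivation_timepoint = ifelse(category == "reactivation_sensitive",
                                             "dayN", NA_character_),
             stringsAsFactors = FALSE)
}

#' Promote refractory genes expressed at a later timepoint
#'
#' Genes classified refractory across day 0 / day N but showing significant
#' Xi expression at an additional, later timepoint (and not at day 0) are
#' promoted to reactivation-sensitive with the timepoint recorded. Escape and
#' already-sensitive genes are unchanged; filtered genes stay filtered.
#'
#' @param base GeneClass table from [classify_genes()].
#' @param extra_calls GeneCall table for the later timepoint.
#' @param timepoint Label recorded for promoted genes (e.g. "day6").
#' @param min_reads Read filter applied to the extra timepoint.
#' @return Updated GeneClass table.
#' @export
merge_timepoints <- function(base, extra_calls, timepoint = "day6",
                             min_reads = 20L) {
  ie <- match(base$gene, extra_calls$gene)
  expressed_extra <- !is.na(ie) & extra_calls$expressed_from_xi[ie] &
    extra_calls$n_reads[ie] >= min_reads
  promote <- base$category == "refractory" & !base$day0_only & expressed_extra
  base$category[promote] <- "reactivation_sensitive"
  base$reactivation_timepoint[promote] <- timepoint
  base
}
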