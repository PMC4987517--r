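# Helper: simulate gene summaries from a known mixture (silenced genes emit
# error reads at rate err_share * 10^(-q/10); expressed genes draw a Beta Xi
# fraction) without going through the full dataset generator.
sim_mixture_summaries <- function(n_genes, pi0, alpha, beta, q = 40,
                                  depth = c(50, 1000), seed = 1) {
  set.seed(seed)
  n <- sample(depth[1]:depth[2], n_genes, replace = TRUE)
  silenced <- runif(n_genes) < pi0
  err <- (1 / 3) * 10^(-q / 10)
  x <- integer(n_genes)
  x[silenced] <- rbinom(sum(silenced), n[silenced], err)
  f <- rbeta(sum(!silenced), alpha, beta)
  x[!silenced] <- rbinom(sum(!silenced), n[!silenced], f)
  make_summaries(x, n, q = q)
}

test_that("beta-binomial pmf matches numeric integration over the latent fraction", {
  for (par in list(c(5, 0.3, 20), c(100, 0.1, 3), c(200, 0.5, 150))) {
    n <- par[1]; m <- par[2]; cc <- par[3]
    a <- m * cc; b <- (1 - m) * cc
    for (x in unique(c(0L, 1L, round(n * m), n))) {
      expect_equal(exp(bb_lpmf(x, n, a, b)), bb_pmf_quad(x, n, a, b),
                   tolerance = 1e-7)
    }
  }
})

test_that("EM recovers mixture parameters on well-separated populations", {
  s <- sim_mixture_summaries(500, pi0 = 0.8, alpha = 30, beta = 70, seed = 13)
  fit <- fit_mixture(s)
  expect_true(fit$converged)
  expect_lt(abs(fit$pi0 - 0.8), 0.05)
  expect_lt(abs(fit$mean - 0.3), 0.03)
})

test_that("EM log-likelihood trace is non-decreasing on random inputs", {
  for (seed in c(2, 3, 4, 5)) {
    s <- sim_mixture_summaries(80, pi0 = runif(1, 0.5, 0.95),
                               alpha = runif(1, 2, 40), beta = runif(1, 10, 80),
                               depth = c(20, 400), seed = seed)
    fit <- fit_mixture(s, mixture_config(seed = seed))
    expect_true(all(diff(fit$loglik_trace) >= -1e-8))
  }
})

test_that("the fit is invariant to gene order and duplication", {
  s <- sim_mixture_summaries(120, pi0 = 0.8, alpha = 30, beta = 70, seed = 17)
  fit1 <- fit_mixture(s)
  perm <- fit_mixture(s[sample(nrow(s)), ])
  expect_equal(perm$pi0, fit1$pi0, tolerance = 1e-10)
  expect_equal(perm$alpha, fit1$alpha, tolerance = 1e-8)
  dup <- fit_mixture(rbind(s, s))
  expect_equal(dup$pi0, fit1$pi0, tolerance = 1e-6)
  expect_equal(dup$mean, fit1$mean, tolerance = 1e-5)
  expect_equal(dup$loglik, 2 * fit1$loglik, tolerance = 1e-5)
})

test_that("an all-zero dataset gives a flagged degenerate fit, not an error", {
  s <- make_summaries(rep(0L, 30), rep(100L, 30))
  fit <- fit_mixture(s)
  expect_true(fit$degenerate)
  expect_equal(fit$pi0, 1)
  expect_true(fit$converged)
  expect_true(all(escape_probability(s, fit) == 1))
})

test_that("fewer than 10 defined genes is an error", {
  expect_error(fit_mixture(make_summaries(c(0L, 2L), c(50L, 60L))),
               "at least 10 genes")
})

test_that("EM reaches at least the grid-search optimum on small instances", {
  for (seed in c(7, 8, 9)) {
    s <- sim_mixture_summaries(25, pi0 = 0.7, alpha = 10, beta = 30,
                               depth = c(30, 300), seed = seed)
    fit <- fit_mixture(s, mixture_config(seed = seed))
    err <- pmin(pmax((1 / 3) * 10^(-(s$xi_qualsum / pmax(s$xi_reads, 1)) / 10),
                     1e-6), 0.05)
    err[s$xi_reads == 0] <- pmin(pmax((1 / 3) * 10^(-fit$fallback_qbar / 10),
                                      1e-6), 0.05)
    best_grid <- grid_search_loglik(s$xi_reads, s$n_reads, err, n_grid = 30L)
    expect_gte(fit$loglik, best_grid - 1e-3)
  }
})

test_that("tau0 is a posterior probability consistent with direct computation", {
  s <- sim_mixture_summaries(200, pi0 = 0.8, alpha = 30, beta = 70, seed = 23)
  fit <- fit_mixture(s)
  # independent route: integrate the expressed likelihood numerically
  probe <- make_summaries(c(0L, 3L, 30L), c(100L, 100L, 100L))
  tau <- escape_probability(probe, fit)
  for (i in seq_len(3)) {
    x <- probe$xi_reads[i]; n <- probe$n_reads[i]
    err <- if (x > 0) (1 / 3) * 1e-4 else
      pmin(pmax((1 / 3) * 10^(-fit$fallback_qbar / 10), 1e-6), 0.05)
    l0 <- dbinom(x, n, max(err, 1e-6), log = FALSE)
    l1 <- bb_pmf_quad(x, n, fit$alpha, fit$beta)
    want <- fit$pi0 * l0 / (fit$pi0 * l0 + (1 - fit$pi0) * l1)
    expect_equal(tau[i], want, tolerance = 1e-6)
  }
  # zero Xi reads at high quality: overwhelmingly silenced
  expect_gte(tau[1], 0.95)
  # half the reads from the Xi at n = 200: silenced is inconceivable
  half <- make_summaries(100L, 200L)
  expect_lte(escape_probability(half, fit), 1e-6)
})

test_that("tau0 is monotone non-increasing in Xi reads at fixed depth", {
  s <- sim_mixture_summaries(200, pi0 = 0.8, alpha = 30, beta = 70, seed = 29)
  fit <- fit_mixture(s)
  probe <- make_summaries(0:50, rep(100L, 51))
  tau <- escape_probability(probe, fit)
  expect_true(all(diff(tau) <= 1e-12))
  expect_gte(escape_probability(make_summaries(5L, 100L), fit),
             escape_probability(make_summaries(20L, 100L), fit))
})

test_that("zero-depth genes are rejected with advice to filter", {
  s <- sim_mixture_summaries(50, 0.8, 30, 70, seed = 2)
  fit <- fit_mixture(s)
  bad <- make_summaries(0L, 0L)
  expect_error(escape_probability(bad, fit), "filter")
})

test_that("the call rule is the stated disjunction with its reason codes", {
  s <- make_summaries(c(12L, 2L, 2L, 30L), rep(100L, 4))
  calls <- call_xi_expression(s, tau0 = c(0.5, 0.01, 0.5, 0.01))
  expect_equal(calls$expressed_from_xi, c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(calls$reason, c("ratio_rule", "tau0_rule", "none", "both"))
  # escape-posterior reporting flips the number, never the call
  flipped <- call_xi_expression(s, tau0 = c(0.5, 0.01, 0.5, 0.01),
                                tau_direction = "escape_posterior")
  expect_equal(flipped$expressed_from_xi, calls$expressed_from_xi)
  expect_equal(flipped$tau0, 1 - calls$tau0)
})

make_call <- function(gene, expressed, n_reads, sample = "s") {
  data.frame(gene = gene, sample = sample, tau0 = ifelse(expressed, 0.01, 0.9),
             xi_ratio = ifelse(expressed, 0.3, 0.001), n_reads = n_reads,
             expressed_from_xi = expressed,
             reason = ifelse(expressed, "both", "none"),
             stringsAsFactors = FALSE)
}

test_that("three-way classification applies the read filter first", {
  d0 <- make_call(c("a", "b", "c", "d", "e"), c(TRUE, FALSE, FALSE, TRUE, TRUE),
                  c(100L, 100L, 100L, 19L, 100L))
  dN <- make_call(c("a", "b", "c", "d", "f"), c(TRUE, TRUE, FALSE, TRUE, TRUE),
                  c(100L, 100L, 100L, 100L, 100L))
  cls <- classify_genes(d0, dN, min_reads = 20L)
  get <- function(g) cls$category[cls$gene == g]
  expect_equal(get("a"), "escape")
  expect_equal(get("b"), "reactivation_sensitive")
  expect_equal(get("c"), "refractory")
  expect_equal(get("d"), "filtered")    # 19 reads at day 0, calls irrelevant
  expect_equal(get("e"), "filtered")    # absent at day N
  expect_equal(cls$filter_reason[cls$gene == "e"], "missing_timepoint")
  expect_equal(get("f"), "filtered")
})

test_that("exactly 20 reads pass the default filter and 19 are dropped", {
  d0 <- make_call(c("pass", "fail"), c(TRUE, TRUE), c(20L, 19L))
  dN <- make_call(c("pass", "fail"), c(TRUE, TRUE), c(20L, 20L))
  cls <- classify_genes(d0, dN, min_reads = 20L)
  expect_true(cls$passed_read_filter[cls$gene == "pass"])
  expect_false(cls$passed_read_filter[cls$gene == "fail"])
  strict <- classify_genes(d0, dN, min_reads = 20L, strict = TRUE)
  expect_false(any(strict$passed_read_filter))
})

test_that("genes expressed at day 0 only are refractory with an explicit flag", {
  d0 <- make_call("g", TRUE, 100L)
  dN <- make_call("g", FALSE, 100L)
  cls <- classify_genes(d0, dN)
  expect_equal(cls$category, "refractory")
  expect_true(cls$day0_only)
})

test_that("later-timepoint calls promote refractory genes only", {
  d0 <- make_call(c("r", "e", "s", "f", "d"), c(FALSE, TRUE, FALSE, FALSE, TRUE),
                  c(100L, 100L, 100L, 10L, 100L))
  dN <- make_call(c("r", "e", "s", "f", "d"), c(FALSE, TRUE, TRUE, FALSE, FALSE),
                  c(100L, 100L, 100L, 10L, 100L))
  base <- classify_genes(d0, dN)
  extra <- make_call(c("r", "e", "s", "f", "d"), c(TRUE, TRUE, TRUE, TRUE, TRUE),
                     c(100L, 100L, 100L, 100L, 100L), sample = "day6")
  merged <- merge_timepoints(base, extra, timepoint = "day6")
  get <- function(g) merged$category[merged$gene == g]
  expect_equal(get("r"), "reactivation_sensitive")   # promoted
  expect_equal(merged$reactivation_timepoint[merged$gene == "r"], "day6")
  expect_equal(get("e"), "escape")                   # unchanged
  expect_equal(get("s"), "reactivation_sensitive")   # already sensitive
  expect_equal(get("f"), "filtered")                 # stays filtered
  expect_equal(get("d"), "refractory")               # day0-only is not promoted
})
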