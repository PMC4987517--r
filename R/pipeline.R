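#' Pipeline configuration
#'
#' Collects every threshold and setting of the allele-specific XCI pipeline.
#' Defaults are the analysis' published operating point: a gene is
#' Xi-expressed when its Xi ratio exceeds 0.10 or tau0 <= 0.05, and only
#' genes with at least 20 SNP-overlapping reads at both timepoints are
#' classified.
#'
#' @param xi_ratio Xi-ratio call threshold.
#' @param tau0 Significance threshold on the silenced posterior.
#' @param min_reads Per-gene read filter applied at both timepoints.
#' @param min_baseq Base-quality floor for allele counting (Phred).
#' @param min_depth Minimum clone depth for SNP discovery.
#' @param min_purity Minimum consensus purity for SNP discovery.
#' @param strict_min_reads Use > instead of >= for the read filter.
#' @param tau_direction Reporting convention for tau0 (see
#'   [call_xi_expression()]).
#' @param mixture A [mixture_config()].
#' @param timepoints Named list with `day0`, `dayN`, and optional `extra`
#'   sample labels.
#' @param paths Named list of input file paths (used by [run_pipeline()] when
#'   no in-memory dataset is given): `snp_vcf`, `pileup_day0`, `pileup_dayN`,
#'   optional `pileup_extra`, `human_read_ids`, `mouse_read_ids`.
#' @param seed Pipeline seed (propagated to the mixture fit).
#' @return Object of class `xci_pipeline_config`.
#' @export
pipeline_config <- function(xi_ratio = 0.10, tau0 = 0.05, min_reads = 20L,
                            min_baseq = 13L, min_depth = 10L,
                            min_purity = 0.9, strict_min_reads = FALSE,
                            tau_direction = "silenced_posterior",
                            mixture = mixture_config(),
                            timepoints = list(day0 = "day0", dayN = "day5",
                                              extra = NULL),
                            paths = list(), seed = 1L) {
  cfg <- list(xi_ratio = xi_ratio, tau0 = tau0,
              min_reads = as.integer(min_reads),
              min_baseq = as.integer(min_baseq),
              min_depth = as.integer(min_depth), min_purity = min_purity,
              strict_min_reads = isTRUE(strict_min_reads),
              tau_direction = tau_direction, mixture = unclass(mixture),
              timepoints = timepoints, paths = paths, seed = as.integer(seed))
  class(cfg) <- "xci_pipeline_config"
  cfg
}

#' Write a pipeline configuration as YAML
#' @param config An [pipeline_config()] object.
#' @param path Output file.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#' @param path YAML file written by [write_pipeline_config()].
#' @return An `xci_pipeline_config` with thresholds identical to the written
#'   ones (round-trip safe).
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path))
    stop("missing input file '", path, "'", call. = FALSE)
  raw <- yaml::read_yaml(path)
  mix <- do.call(mixture_config, raw$mixture)
  raw$mixture <- NULL
  cfg <- do.call(pipeline_config, c(raw, list(mixture = mix)))
  cfg
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full allele-specific XCI classification pipeline
#'
#' Composes the analysis stages in order: load or accept allele counts,
#' assign Xa/Xi haplotypes from day-0 majorities, aggregate to per-gene
#' summaries, fit the beta-binomial mixture jointly across timepoints,
#' compute tau0 and Xi-expression calls per timepoint, apply the read filter
#' and three-way classification, and (when configured) promote genes
#' reactivating only at the extra timepoint. Identical config and inputs give
#' identical output.
#'
#' @param dataset Optional in-memory dataset (an `xci_dataset` from
#'   [simulate_allelic_dataset()], or any list with `counts` and `samples`).
#'   When NULL, inputs are read from `config$paths`: a SNP VCF plus one
#'   pileup per timepoint, optionally restricted to human-specific reads.
#' @param config An [pipeline_config()].
#' @return Object of class `xci_pipeline_result`: `classes` (GeneClass
#'   table), `calls` (per-timepoint GeneCall tables), `summaries`, `fit`,
#'   `assignment`, and `report` (seeds, thresholds, and gene counts at every
#'   filter stage).
#' @export
run_pipeline <- function(dataset = NULL, config = pipeline_config()) {
  tp <- config$timepoints
  if (is.null(dataset)) {
    counts <- with_stage("load_inputs", {
      p <- config$paths
      for (nm in c("snp_vcf", "pileup_day0", "pileup_dayN")) {
        if (is.null(p[[nm]]))
          stop("config$paths$", nm, " is not set")
        if (!file.exists(p[[nm]]))
          stop("missing input file '", p[[nm]], "' (", nm, ")")
      }
      snps <- read_snp_vcf(p$snp_vcf)
      kept <- "all"
      if (!is.null(p$human_read_ids)) {
        human <- readLines(p$human_read_ids)
        mouse <- if (!is.null(p$mouse_read_ids)) readLines(p$mouse_read_ids)
                 else character(0)
        kept <- filter_species_specific(human, mouse)
      }
      pl <- list(read_pileup(p$pileup_day0), read_pileup(p$pileup_dayN))
      labels <- c(tp$day0, tp$dayN)
      if (!is.null(tp$extra) && !is.null(p$pileup_extra)) {
        pl <- c(pl, list(read_pileup(p$pileup_extra)))
        labels <- c(labels, tp$extra)
      }
      do.call(rbind, lapply(seq_along(pl), function(i)
        count_alleles(pl[[i]], snps, kept_reads = kept,
                      min_baseq = config$min_baseq, sample = labels[i])))
    })
  } else {
    counts <- dataset$counts
  }

  day0 <- counts[counts$sample == tp$day0, , drop = FALSE]
  if (!nrow(day0))
    stop("pipeline stage 'assign_haplotypes' failed: no counts for day-0 sample '",
         tp$day0, "'", call. = FALSE)
  assignment <- with_stage("assign_haplotypes", assign_haplotypes(day0))
  summaries <- with_stage("aggregate_gene", aggregate_gene(counts, assignment))

  mix_cfg <- do.call(mixture_config, config$mixture)
  mix_cfg$seed <- config$seed
  fit_rows <- summaries[summaries$sample %in% c(tp$day0, tp$dayN), , drop = FALSE]
  fit <- with_stage("fit_mixture", fit_mixture(fit_rows, mix_cfg))

  call_one <- function(label) {
    s <- summaries[summaries$sample == label & summaries$defined &
                     summaries$hap_consistent, , drop = FALSE]
    with_stage("call_xi_expression",
               call_xi_expression(s, fit, xi_ratio_min = config$xi_ratio,
                                  tau0_max = config$tau0,
                                  tau_direction = config$tau_direction))
  }
  calls <- list(day0 = call_one(tp$day0), dayN = call_one(tp$dayN))
  classes <- with_stage("classify_genes",
                        classify_genes(calls$day0, calls$dayN,
                                       min_reads = config$min_reads,
                                       strict = config$strict_min_reads))
  if (!is.null(tp$extra) && tp$extra %in% summaries$sample) {
    calls$extra <- call_one(tp$extra)
    classes <- with_stage("merge_timepoints",
                          merge_timepoints(classes, calls$extra,
                                           timepoint = tp$extra,
                                           min_reads = config$min_reads))
  }

  report <- list(
    package_version = as.character(utils::packageVersion("xcireact")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    thresholds = list(xi_ratio = config$xi_ratio, tau0 = config$tau0,
                      min_reads = config$min_reads,
                      min_baseq = config$min_baseq),
    timepoints = tp[!vapply(tp, is.null, logical(1))],
    mixture = list(pi0 = fit$pi0, mean = fit$mean, conc = fit$conc,
                   err_rate = fit$err_rate, converged = fit$converged,
                   degenerate = fit$degenerate, n_iter = fit$n_iter),
    stage_counts = list(
      n_snps = length(unique(paste(counts$chrom, counts$pos))),
      n_snps_tied = sum(assignment$tie_flag),
      n_genes = length(unique(summaries$gene)),
      n_gene_obs_defined = sum(summaries$defined),
      n_genes_hap_inconsistent =
        length(unique(summaries$gene[!summaries$hap_consistent])),
      n_genes_pass_read_filter = sum(classes$passed_read_filter),
      class_counts = as.list(table(classes$category))
    )
  )
  structure(list(classes = classes, calls = calls, summaries = summaries,
                 fit = fit, assignment = assignment, report = report),
            class = "xci_pipeline_result")
}

#' @export
print.xci_pipeline_result <- function(x, ...) {
  cat("Allele-specific XCI classification\n")
  sc <- x$report$stage_counts
  cat("  SNPs:", sc$n_snps, "(", sc$n_snps_tied, "tied )  genes:", sc$n_genes,
      " passing read filter:", sc$n_genes_pass_read_filter, "\n")
  cat("  mixture: pi0", sprintf("%.3f", x$report$mixture$pi0),
      " expressed mean", sprintf("%.3f", x$report$mixture$mean), "\n")
  print(table(x$classes$category))
  invisible(x)
}

#' Write a small on-disk fixture bundle
#'
#' Generates and writes a self-contained bundle of every input format the
#' pipeline consumes: clone pileups and a SNP VCF for discovery, per-sample
#' pileups with allele counts and ground truth for classification, a qPCR Ct
#' table, RNA-FISH intensity profiles, and dual-genome read-identifier lists,
#' plus a YAML manifest. Preset `"tiny"` is a 20-gene bundle for fast tests
#' and examples; `"paperlike"` matches the study's scale: 183 genes carrying
#' 379 heterozygous SNPs with ~8% escapees and ~10% reactivation-sensitive
#' genes.
#'
#' @param preset `"tiny"` or `"paperlike"`.
#' @param seed Integer seed; same preset and seed give an identical bundle.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the written paths.
#' @export
make_fixtures <- function(preset = c("tiny", "paperlike"), seed = 1L,
                          dir = tempfile("xci_fixtures_")) {
  presets <- c("tiny", "paperlike")
  if (!is.character(preset) || !preset[1] %in% presets)
    stop("unknown preset '", preset[1], "'; available presets: ",
         paste(presets, collapse = ", "), call. = FALSE)
  preset <- preset[1]
  cfg <- fixture_config(preset, seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(dir, f)

  ds <- simulate_allelic_dataset(cfg, keep_read_level = TRUE)
  clones <- simulate_clone_pileups(ds$snps, depth = 100, error_rate = 0.01,
                                   seed = seed + 101L,
                                   n_null_sites = if (preset == "tiny") 50L else 500L)
  ids <- simulate_dual_genome_reads(5000L, 5000L, cfg$cross_map_fraction,
                                    seed = seed + 202L)
  fish <- simulate_fish_profiles(n_per_class = if (preset == "tiny") 5L else 30L,
                                 noise_sd = 0.05, seed = seed + 303L)
  expr <- matrix(c(0.001, 0.05, 0.04, 0.03), nrow = 2, byrow = TRUE,
                 dimnames = list(c("day0", "day5"), c("OCT4", "NANOG")))
  ct <- simulate_ct_table(expr, seed = seed + 404L)

  files <- list(
    snp_vcf = path("snps.vcf"), clone_a = path("pileup_clone_a.tsv"),
    clone_b = path("pileup_clone_b.tsv"),
    pileup_day0 = path("pileup_day0.tsv"),
    pileup_day5 = path("pileup_day5.tsv"),
    allele_counts = path("allele_counts.tsv"),
    ground_truth = path("ground_truth.tsv"),
    human_read_ids = path("read_ids_human.txt"),
    mouse_read_ids = path("read_ids_mouse.txt"),
    qpcr_ct = path("qpcr_ct.csv"), fish_profiles = path("fish_profiles.csv"),
    manifest = path("manifest.yaml"))

  write_snp_vcf(ds$snps, files$snp_vcf)
  write_pileup(clones$clone_a, files$clone_a)
  write_pileup(clones$clone_b, files$clone_b)
  write_pileup(ds$pileups$day0, files$pileup_day0)
  write_pileup(ds$pileups$day5, files$pileup_day5)
  utils::write.table(ds$counts, files$allele_counts, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(ds$truth, files$ground_truth, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(ids$human, files$human_read_ids)
  writeLines(ids$mouse, files$mouse_read_ids)
  utils::write.csv(ct, files$qpcr_ct, row.names = FALSE)
  write_fish_profiles(fish$profiles, files$fish_profiles, fish$labels)
  yaml::write_yaml(list(preset = preset, seed = seed,
                        package_version =
                          as.character(utils::packageVersion("xcireact")),
                        n_genes = cfg$n_genes,
                        n_snps = nrow(ds$snps)),
                   files$manifest)
  invisible(files)
}

fixture_config <- function(preset, seed) {
  switch(preset,
    tiny = simulation_config(n_genes = 20L, total_snps = 40L,
                             depth_per_gene = list(min = 30, max = 200),
                             frac_escape = 0.10, frac_reactivated = 0.15,
                             seed = seed),
    paperlike = simulation_config(n_genes = 183L, total_snps = 379L,
                                  frac_escape = 0.08, frac_reactivated = 0.10,
                                  seed = seed))
}
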