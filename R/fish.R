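#' A 1-D RNA-FISH intensity profile
#'
#' A line scan of pixel intensities through a nucleus, with its spatial scale
#' and the background statistics needed for thresholding.
#'
#' @param values Ordered intensity samples (arbitrary units, >= 2).
#' @param pixels_per_um Spatial sampling rate (> 0).
#' @param channel Channel label (e.g. "XIST").
#' @param background_mean,background_sd Background intensity statistics.
#' @return Object of class `fish_profile`.
#' @export
fish_profile <- function(values, pixels_per_um, channel = "XIST",
                         background_mean, background_sd) {
  if (length(values) < 2L)
    stop("a profile needs at least 2 intensity samples", call. = FALSE)
  if (pixels_per_um <= 0)
    stop("'pixels_per_um' must be > 0", call. = FALSE)
  structure(list(values = as.numeric(values), pixels_per_um = pixels_per_um,
                 channel = channel, background_mean = background_mean,
                 background_sd = background_sd),
            class = "fish_profile")
}

#' Classify an XIST signal as compact, diffuse or absent
#'
#' Applies the pixel-profile rule used to score XIST nuclear patterns:
#' "compact" — a contiguous run of at least `min_span_um` (2 um) above the
#' signal threshold with near-constant intensity (coefficient of variation at
#' most `max_cv` within the run); "diffuse" — above-threshold runs exist but
#' none qualifies as compact (discontinuous sub-2-um peaks, or a long run
#' with high internal variation); "none" — no signal above threshold. The
#' threshold is background mean + `k_sd` background s.d.; runs shorter than
#' `min_signal_um` are ignored as pixel noise. The rule is invariant to
#' uniform intensity rescaling.
#'
#' @param profile A [fish_profile()].
#' @param min_span_um Span a compact signal must reach (default 2 um).
#' @param k_sd Background s.d. multiples above background mean for the
#'   signal threshold.
#' @param max_cv Maximum coefficient of variation within a compact run.
#' @param min_signal_um Minimum run length treated as signal.
#' @return One of `"compact"`, `"diffuse"`, `"none"`.
#' @export
classify_xist_profile <- function(profile, min_span_um = 2, k_sd = 3,
                                  max_cv = 0.35, min_signal_um = 0.2) {
  v <- profile$values
  ppu <- profile$pixels_per_um
  if (length(v) / ppu < min_span_um)
    stop("unscorable profile: physical extent shorter than ", min_span_um,
         " um", call. = FALSE)
  if (is.null(profile$background_mean) || is.null(profile$background_sd) ||
      is.na(profile$background_mean) || is.na(profile$background_sd))
    stop("unscorable profile: background statistics missing", call. = FALSE)
  thr <- profile$background_mean + k_sd * profile$background_sd
  above <- v > thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sig <- which(r$values & r$lengths / ppu >= min_signal_um)
  if (!length(sig)) return("none")
  for (i in sig) {
    if (r$lengths[i] / ppu >= min_span_um) {
      run <- v[starts[i]:ends[i]]
      if (stats::sd(run) / mean(run) <= max_cv) return("compact")
    }
  }
  "diffuse"
}

#' Count allelic nascent-transcript signals in a nucleus
#'
#' Two RNA signals more than 1 um apart represent bi-allelic expression;
#' signals at most `merge_dist` apart are merged into a single transcription
#' site (single-linkage clustering). The count of merged sites is reported as
#' a category: "1", "2", ">2", or "undetected" for an empty signal list.
#'
#' @param positions Numeric matrix or data frame of signal coordinates in um
#'   (one row per signal, 2 columns), or a numeric vector for 1-D positions.
#' @param merge_dist Merge distance in um (default 1).
#' @return Factor with levels `undetected`, `1`, `2`, `>2`.
#' @export
count_allelic_signals <- function(positions, merge_dist = 1) {
  lev <- c("undetected", "1", "2", ">2")
  if (is.null(positions) || NROW(positions) == 0L)
    return(factor("undetected", levels = lev))
  m <- as.matrix(positions)
  if (is.null(dim(m)) || ncol(m) == 1L) m <- cbind(as.numeric(m), 0)
  n <- nrow(m)
  if (n == 1L) return(factor("1", levels = lev))
  hc <- stats::hclust(stats::dist(m), method = "single")
  k <- length(unique(stats::cutree(hc, h = merge_dist)))
  factor(if (k <= 2L) as.character(k) else ">2", levels = lev)
}

#' Summarize scored observations into per-condition proportions
#'
#' Proportions are computed within each biological replicate (the replicate,
#' not the cell, is the unit of independence), then averaged per condition:
#' mean +/- s.e.m. with an unadjusted two-sided t-test of each condition
#' against the baseline (day 0) condition. Per condition and replicate the
#' category proportions sum to 1 exactly.
#'
#' @param observations Data frame with columns `condition`, `replicate`, and
#'   `category` (one row per scored cell).
#' @param baseline Baseline condition label for the t-tests; NULL skips
#'   testing.
#' @return Data frame: condition, category, mean_proportion, sem,
#'   n_replicates, p_value, flag (`single_replicate` when a condition has
#'   one replicate, `zero_variance` for the degenerate exact-zero-variance
#'   t-test path).
#' @export
summarize_proportions <- function(observations, baseline = "day0") {
  obs <- observations
  cats <- if (is.factor(obs$category)) levels(obs$category) else
    sort(unique(as.character(obs$category)))
  obs$category <- factor(obs$category, levels = cats)
  conds <- unique(obs$condition)
  # per (condition, replicate) category proportions
  props <- list()
  for (cond in conds) {
    d <- obs[obs$condition == cond, ]
    for (rep_id in unique(d$replicate)) {
      dd <- d[d$replicate == rep_id, ]
      tab <- table(dd$category) / nrow(dd)
      props[[length(props) + 1L]] <-
        data.frame(condition = cond, replicate = rep_id, category = cats,
                   proportion = as.vector(tab), stringsAsFactors = FALSE)
    }
  }
  props <- do.call(rbind, props)
  out <- list()
  for (cond in conds) {
    for (cat in cats) {
      x <- props$proportion[props$condition == cond & props$category == cat]
      row <- data.frame(condition = cond, category = cat,
                        mean_proportion = mean(x), sem = sem(x),
                        n_replicates = length(x), p_value = NA_real_,
                        flag = NA_character_, stringsAsFactors = FALSE)
      if (length(x) < 2L) row$flag <- "single_replicate"
      if (!is.null(baseline) && cond != baseline) {
        y <- props$proportion[props$condition == baseline &
                                props$category == cat]
        tt <- ttest_vs_baseline(x, y)
        row$p_value <- tt$p
        if (!is.na(tt$flag)) row$flag <- tt$flag
      }
      out[[length(out) + 1L]] <- row
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
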