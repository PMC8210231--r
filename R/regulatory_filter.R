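#' Keep positions contained in a set of intervals
#'
#' Containment filter used for open-chromatin peaks and for annotation
#' interval sets (e.g. miRNA target sites): a position survives iff at
#' least one interval contains its 1-based coordinate.
#'
#' @param positions data.frame with chrom and pos columns (mutations or
#'   recurrent positions).
#' @param intervals `GRanges` of containing intervals.
#' @return list with `positions` (surviving subset) and `annotation`, a
#'   data.frame listing every (position, interval) containment with the
#'   interval's name/index.
#' @export
overlap_intervals <- function(positions, intervals) {
  if (!nrow(positions)) {
    return(list(positions = positions,
                annotation = data.frame(chrom = character(), pos = integer(),
                                        interval = integer(),
                                        interval_name = character())))
  }
  hits <- quiet_overlaps(position_granges(positions), intervals)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  nm <- if (!is.null(intervals$name)) as.character(intervals$name)
        else as.character(seq_along(intervals))
  annotation <- data.frame(chrom = positions$chrom[qh],
                           pos = positions$pos[qh],
                           interval = sh,
                           interval_name = nm[sh],
                           stringsAsFactors = FALSE)
  out <- positions[sort(unique(qh)), , drop = FALSE]
  rownames(out) <- NULL
  list(positions = out, annotation = annotation)
}

#' Keep positions inside chromatin-interaction anchors
#'
#' A position survives iff it is contained in either anchor of at least
#' one interaction; the anchors are treated symmetrically. The matched
#' interactions are recorded because they later determine candidate
#' target genes.
#'
#' @param positions data.frame with chrom and pos.
#' @param interactions `chromatin_interactions` data.frame.
#' @return list with `positions` (surviving subset) and `matches`
#'   (position, interaction index, which anchor contained it).
#' @export
overlap_interaction_anchors <- function(positions, interactions) {
  matches <- data.frame(chrom = character(), pos = integer(),
                        interaction = integer(), anchor = character(),
                        stringsAsFactors = FALSE)
  if (!nrow(positions) || !nrow(interactions)) {
    return(list(positions = positions[0, , drop = FALSE], matches = matches))
  }
  gr <- position_granges(positions)
  keep <- rep(FALSE, nrow(positions))
  for (side in c("a", "b")) {
    hits <- quiet_overlaps(gr, anchor_granges(interactions, side))
    qh <- S4Vectors::queryHits(hits)
    keep[unique(qh)] <- TRUE
    if (length(qh)) {
      matches <- rbind(matches, data.frame(
        chrom = positions$chrom[qh], pos = positions$pos[qh],
        interaction = S4Vectors::subjectHits(hits), anchor = side,
        stringsAsFactors = FALSE))
    }
  }
  out <- positions[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(positions = out, matches = matches)
}

#' Keep positions inside predicted TF binding sites
#'
#' Sites scoring below `min_score` are ignored. A position may fall in
#' several overlapping sites; all containments are reported, since each
#' (site, mutation) pair feeds the motif-impact and expression screens.
#'
#' @param positions data.frame with chrom and pos.
#' @param tfbs_instances `GRanges` from [read_tfbs_sites()].
#' @param min_score minimum database match score (default 400).
#' @return list with `positions` (surviving subset) and `site_positions`,
#'   a data.frame of (site_id, motif_id, chrom, pos) containments.
#' @export
overlap_tfbs <- function(positions, tfbs_instances, min_score = 400) {
  sites <- tfbs_instances[tfbs_instances$score >= min_score]
  site_positions <- data.frame(site_id = character(), motif_id = character(),
                               chrom = character(), pos = integer(),
                               stringsAsFactors = FALSE)
  if (!nrow(positions) || !length(sites)) {
    return(list(positions = positions[0, , drop = FALSE],
                site_positions = site_positions))
  }
  hits <- quiet_overlaps(position_granges(positions), sites)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  if (length(qh)) {
    site_positions <- data.frame(site_id = sites$site_id[sh],
                                 motif_id = sites$motif_id[sh],
                                 chrom = positions$chrom[qh],
                                 pos = positions$pos[qh],
                                 stringsAsFactors = FALSE)
  }
  out <- positions[sort(unique(qh)), , drop = FALSE]
  rownames(out) <- NULL
  list(positions = out, site_positions = site_positions)
}

#' Resampled null for the open-chromatin fraction
#'
#' Draws `n_draw` mutations from the background catalog `n_reps` times and
#' computes, per draw, the fraction of drawn positions inside the peak
#' set. The observed statistic is the in-peak fraction of `observed_set`.
#' Empirical p values use the (r + 1) / (n + 1) estimator; the two-sided p
#' is twice the smaller tail, capped at 1.
#'
#' @param background_mutations background mutation data.frame.
#' @param peaks `GRanges` of open-chromatin peaks.
#' @param n_draw mutations per draw.
#' @param n_reps number of draws.
#' @param observed_set data.frame of focal positions.
#' @param seed RNG seed (mandatory).
#' @param replace draw with replacement? Default FALSE.
#' @return object of class `resample_null`: values, expected, observed,
#'   p_upper, p_lower, p_two_sided, n_draw, n_reps, seed.
#' @export
resample_open_chromatin_fraction <- function(background_mutations, peaks,
                                             n_draw, n_reps, observed_set,
                                             seed, replace = FALSE) {
  if (missing(seed) || is.null(seed)) stop_format("seed is mandatory")
  n_bg <- nrow(background_mutations)
  if (!replace && n_draw > n_bg) {
    stop_format("n_draw (%d) exceeds background size (%d)", n_draw, n_bg)
  }
  in_peak <- quiet_count(position_granges(background_mutations), peaks) > 0L
  observed <- mean(quiet_count(position_granges(observed_set), peaks) > 0L)
  values <- with_seed(seed, vapply(seq_len(n_reps), function(r) {
    mean(in_peak[sample.int(n_bg, n_draw, replace = replace)])
  }, 0))
  new_resample_null(values, observed, n_draw, n_reps, seed)
}

new_resample_null <- function(values, observed, n_draw, n_reps, seed) {
  p_upper <- (sum(values >= observed) + 1) / (n_reps + 1)
  p_lower <- (sum(values <= observed) + 1) / (n_reps + 1)
  structure(list(values = values, expected = mean(values), observed = observed,
                 p_upper = p_upper, p_lower = p_lower,
                 p_two_sided = min(1, 2 * min(p_upper, p_lower)),
                 n_draw = n_draw, n_reps = n_reps, seed = seed),
            class = "resample_null")
}

#' @export
print.resample_null <- function(x, ...) {
  cat(sprintf(
    "resample null: observed %.4f, expected %.4f (%d draws x %d reps)\n",
    x$observed, x$expected, x$n_draw, x$n_reps))
  cat(sprintf("  empirical p: upper %.4g, lower %.4g, two-sided %.4g\n",
              x$p_upper, x$p_lower, x$p_two_sided))
  invisible(x)
}

#' Per-peak mutation rates, split by recurrent-mutation content
#'
#' For each peak, the rate is (#mutations in the peak) / n_samples. Peaks
#' are partitioned into those containing at least one recurrent position
#' and those containing none, and the two rate vectors are compared with a
#' two-sided Wilcoxon rank-sum test (tie-corrected normal approximation).
#'
#' @param mutations mutation data.frame.
#' @param peaks `GRanges` of peaks.
#' @param n_samples number of samples in the cohort.
#' @param recurrent_positions recurrent-position data.frame.
#' @return list with rates_with, rates_without, their means, and p (NA,
#'   with `flag`, when a partition is empty).
#' @export
per_peak_mutation_rate <- function(mutations, peaks, n_samples,
                                   recurrent_positions) {
  stopifnot(n_samples > 0)
  counts <- quiet_count(peaks, position_granges(mutations))
  has_rec <- quiet_count(peaks, position_granges(recurrent_positions)) > 0L
  rates <- counts / n_samples
  rates_with <- rates[has_rec]
  rates_without <- rates[!has_rec]
  if (!length(rates_with) || !length(rates_without)) {
    return(list(rates_with = rates_with, rates_without = rates_without,
                mean_with = mean(rates_with), mean_without = mean(rates_without),
                p = NA_real_, flag = "empty partition"))
  }
  p <- if (length(unique(c(rates_with, rates_without))) == 1L) {
    1  # all rates tied: no evidence of a difference
  } else {
    suppressWarnings(
      wilcox.test(rates_with, rates_without, exact = FALSE,
                  correct = FALSE)$p.value)
  }
  list(rates_with = rates_with, rates_without = rates_without,
       mean_with = mean(rates_with), mean_without = mean(rates_without),
       p = p, flag = NULL)
}
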