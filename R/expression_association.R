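#' Assign candidate target genes to a TF binding site
#'
#' Gene G is a target of site S iff some chromatin interaction has one
#' anchor overlapping S and the other anchor containing G's TSS; the union
#' over all interactions is returned, deduplicated. Anchors are treated
#' symmetrically.
#'
#' @param site one-row `GRanges` for the site.
#' @param interactions `chromatin_interactions` data.frame.
#' @param genes `gene_models` object.
#' @return character vector of target gene_ids (possibly empty).
#' @export
assign_target_genes <- function(site, interactions, genes) {
  if (!nrow(interactions)) return(character())
  gdf <- genes$genes
  tss_gr <- GenomicRanges::GRanges(gdf$chrom,
                                   IRanges::IRanges(gdf$tss, gdf$tss))
  targets <- character()
  for (sides in list(c("a", "b"), c("b", "a"))) {
    near <- anchor_granges(interactions, sides[1])
    far <- anchor_granges(interactions, sides[2])
    site_hits <- S4Vectors::subjectHits(
      quiet_overlaps(site, near))
    if (!length(site_hits)) next
    tss_hits <- quiet_overlaps(tss_gr, far[site_hits])
    targets <- c(targets, gdf$gene_id[S4Vectors::queryHits(tss_hits)])
  }
  sort(unique(targets))
}

#' Standardize expression within cancer types
#'
#' Computes z = (x - mean) / sd per gene within each cancer-type stratum
#' (sample sd, denominator n - 1), so expression is comparable across
#' heterogeneous cohorts. Strata with fewer than 2 samples or zero
#' variance are masked to NA (with a warning for single-sample strata) and
#' excluded from downstream tests.
#'
#' @param expr numeric genes x samples matrix.
#' @param meta data.frame with sample_id and cancer_type covering all
#'   columns of `expr`.
#' @return genes x samples z-score matrix (same dimnames as `expr`).
#' @export
zscore_by_cancer_type <- function(expr, meta) {
  idx <- match(colnames(expr), meta$sample_id)
  if (anyNA(idx)) stop_format("samples missing from metadata: %s",
                              paste(colnames(expr)[is.na(idx)], collapse = ", "))
  type <- meta$cancer_type[idx]
  z <- expr
  z[] <- NA_real_
  for (ct in unique(type)) {
    cols <- which(type == ct)
    if (length(cols) < 2L) {
      warning(sprintf("cancer type %s has %d sample(s); stratum masked",
                      ct, length(cols)), call. = FALSE)
      next
    }
    sub <- expr[, cols, drop = FALSE]
    mu <- rowMeans(sub)
    sdv <- apply(sub, 1, sd)
    zi <- (sub - mu) / sdv
    zi[sdv == 0, ] <- NA_real_
    z[, cols] <- zi
  }
  z
}

#' Compare expression between mutated and wild-type samples
#'
#' Two-sided Wilcoxon rank-sum test on the z-scores of one gene, mutated
#' samples versus all remaining samples. When both groups have at most 8
#' observations the exact permutation distribution of the rank sum is
#' used (full enumeration, valid with ties); otherwise the tie-corrected
#' normal approximation. Direction is the sign of
#' (median z mutated - median z wild-type).
#'
#' @param z z-score matrix from [zscore_by_cancer_type()].
#' @param gene gene_id (row of `z`).
#' @param mutated_samples sample ids carrying a mutation.
#' @return list: statistic (W), p, direction, n_mutated, n_wt, and `flag`
#'   when a group is empty after masking (then p is NA).
#' @export
compare_expression <- function(z, gene, mutated_samples) {
  if (!gene %in% rownames(z)) stop_format("gene %s not in matrix", gene)
  mut_cols <- intersect(colnames(z), mutated_samples)
  wt_cols <- setdiff(colnames(z), mut_cols)
  x <- z[gene, mut_cols]
  y <- z[gene, wt_cols]
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (!length(x) || !length(y)) {
    return(list(statistic = NA_real_, p = NA_real_, direction = NA_real_,
                n_mutated = length(x), n_wt = length(y),
                flag = "empty group"))
  }
  if (length(x) <= 8 && length(y) <= 8) {
    res <- exact_rank_sum_test(x, y)
  } else {
    wt <- suppressWarnings(
      wilcox.test(x, y, alternative = "two.sided", exact = FALSE,
                  correct = FALSE))
    res <- list(statistic = unname(wt$statistic), p = wt$p.value)
  }
  list(statistic = res$statistic, p = res$p,
       direction = sign(median(x) - median(y)),
       n_mutated = length(x), n_wt = length(y), flag = NULL)
}

# Exact two-sided rank-sum p by enumerating every assignment of the
# pooled values to the first group; correct in the presence of ties,
# where the large-sample wilcox.test approximation degrades. The
# two-sided p doubles the smaller tail (capped at 1), the same
# convention wilcox.test uses for its exact path.
exact_rank_sum_test <- function(x, y) {
  vals <- c(x, y)
  k <- length(x)
  r <- rank(vals)
  obs <- sum(r[seq_len(k)])
  W <- utils::combn(length(vals), k, function(idx) sum(r[idx]))
  p <- min(1, 2 * min(mean(W <= obs), mean(W >= obs)))
  # report the Mann-Whitney U, matching wilcox.test's statistic
  list(statistic = obs - k * (k + 1) / 2, p = p)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pvalues numeric vector of p values in [0, 1] (NAs preserved).
#' @return adjusted values (FDR q-values) in the original order.
#' @export
bh_adjust <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1)) {
    stop_format("p values must lie in [0, 1]")
  }
  out <- rep(NA_real_, length(pvalues))
  out[ok] <- p.adjust(pvalues[ok], method = "BH")
  out
}

#' Screen TF binding sites for target-gene expression association
#'
#' For every site with at least `min_mutated` mutated samples having
#' expression data, tests each of its target genes (mutated vs wild-type
#' z-scores, [compare_expression()]). BH adjustment is applied once across
#' all (site, gene) tests in the screen.
#'
#' @param site_mutation_map data.frame (site_id, sample_id): samples with
#'   any mutation in the site, recurrent or not.
#' @param z z-score matrix.
#' @param targets named list: site_id -> character vector of target
#'   gene_ids.
#' @param min_mutated minimum mutated samples per site (default 5).
#' @param fdr_threshold significance threshold on FDR (default 0.25).
#' @param p_threshold reporting threshold on p (default 0.1).
#' @return data.frame of association results: site_id, gene_id, n_mutated,
#'   n_wt, statistic, p, fdr, direction, significant.
#' @export
screen_tfbs_expression <- function(site_mutation_map, z, targets,
                                   min_mutated = 5L, fdr_threshold = 0.25,
                                   p_threshold = 0.1) {
  empty <- data.frame(site_id = character(), gene_id = character(),
                      n_mutated = integer(), n_wt = integer(),
                      statistic = numeric(), p = numeric(), fdr = numeric(),
                      direction = numeric(), significant = logical(),
                      stringsAsFactors = FALSE)
  if (!nrow(site_mutation_map)) return(empty)
  by_site <- split(site_mutation_map$sample_id, site_mutation_map$site_id)
  rows <- list()
  for (sid in names(by_site)) {
    mut_samples <- intersect(unique(by_site[[sid]]), colnames(z))
    if (length(mut_samples) < min_mutated) next
    for (g in intersect(targets[[sid]], rownames(z))) {
      res <- compare_expression(z, g, mut_samples)
      if (is.na(res$p)) next
      rows[[length(rows) + 1L]] <- data.frame(
        site_id = sid, gene_id = g, n_mutated = res$n_mutated,
        n_wt = res$n_wt, statistic = res$statistic, p = res$p,
        direction = res$direction, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out$fdr <- bh_adjust(out$p)
  out$significant <- out$fdr < fdr_threshold
  out$below_p_threshold <- out$p < p_threshold
  rownames(out) <- NULL
  out
}

#' Specificity check against neighboring genes
#'
#' Applies the same mutated-vs-wild-type comparison to each neighbor of
#' the focal gene, without multiplicity adjustment: if the mutation effect
#' is specific, only the focal gene should show a signal.
#'
#' @param focal_gene focal gene_id.
#' @param neighbor_genes character vector of neighbor gene_ids.
#' @param z z-score matrix.
#' @param mutated_samples sample ids carrying a mutation in the site.
#' @return data.frame (gene_id, role, p, direction), focal gene first.
#' @export
neighbor_specificity <- function(focal_gene, neighbor_genes, z,
                                 mutated_samples) {
  genes <- c(focal_gene, neighbor_genes)
  if (!length(genes)) {
    return(data.frame(gene_id = character(), role = character(),
                      p = numeric(), direction = numeric()))
  }
  rows <- lapply(seq_along(genes), function(k) {
    res <- compare_expression(z, genes[k], mutated_samples)
    data.frame(gene_id = genes[k],
               role = if (k == 1) "focal" else "neighbor",
               p = res$p, direction = res$direction,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Nearest neighboring genes by TSS distance
#'
#' @param genes `gene_models` object.
#' @param focal_gene focal gene_id.
#' @param k number of neighbors (default 4).
#' @return character vector of up to `k` gene_ids on the focal gene's
#'   chromosome, nearest TSS first.
#' @export
nearest_neighbor_genes <- function(genes, focal_gene, k = 4L) {
  gdf <- genes$genes
  f <- gdf[gdf$gene_id == focal_gene, ]
  if (!nrow(f)) stop_format("unknown gene %s", focal_gene)
  cand <- gdf[gdf$chrom == f$chrom & gdf$gene_id != focal_gene, ]
  cand <- cand[order(abs(cand$tss - f$tss), cand$gene_id), ]
  utils::head(cand$gene_id, k)
}

#' Null simulation validating the FDR threshold
#'
#' Per repetition: draw `n_genes` eligible genes and `n_mut` pseudo-mutated
#' samples at random, run the mutated-vs-wild-type comparison for every
#' drawn gene, BH-adjust within the repetition, and count genes with
#' FDR < `fdr_threshold`. With no true signal the mean count estimates the
#' false-discovery yield of the screen's threshold.
#'
#' @param z z-score matrix (the expression pool).
#' @param eligible_genes genes to draw from (default: all rows of `z`).
#' @param n_genes genes per repetition (default 1000).
#' @param n_mut pseudo-mutated samples per repetition (default 38).
#' @param n_reps repetitions (default 100).
#' @param fdr_threshold threshold counted as a discovery (default 0.25).
#' @param seed RNG seed (mandatory).
#' @param mutated_samples optional fixed pseudo-mutated sample set; when
#'   NULL (the null simulation proper) `n_mut` samples are redrawn at
#'   random in every repetition. Supplying the true carrier set turns the
#'   simulation into a power check against planted effects.
#' @return list: per-rep `counts`, `mean_discoveries`, and the settings.
#' @export
fdr_null_simulation <- function(z, eligible_genes = rownames(z),
                                n_genes = 1000L, n_mut = 38L, n_reps = 100L,
                                fdr_threshold = 0.25, seed,
                                mutated_samples = NULL) {
  if (missing(seed) || is.null(seed)) stop_format("seed is mandatory")
  if (n_genes > length(eligible_genes)) {
    stop_format("n_genes exceeds eligible gene count")
  }
  if (n_mut >= ncol(z)) stop_format("n_mut must be below the sample count")
  counts <- with_seed(seed, vapply(seq_len(n_reps), function(r) {
    gs <- sample(eligible_genes, n_genes)
    mut <- if (is.null(mutated_samples)) sample(colnames(z), n_mut)
           else mutated_samples
    p <- vapply(gs, function(g) compare_expression(z, g, mut)$p, 0)
    sum(bh_adjust(p) < fdr_threshold, na.rm = TRUE)
  }, 0))
  list(counts = counts, mean_discoveries = mean(counts),
       n_genes = n_genes, n_mut = n_mut, n_reps = n_reps,
       fdr_threshold = fdr_threshold, seed = seed)
}
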