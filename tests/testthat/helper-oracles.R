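# Independent brute-force oracles and small fixture builders used across
# the test suite. Oracles are deliberately naive (quadratic scans, direct
# enumeration) and share no code with the implementation they check.

make_mutations <- function(chrom, pos, ref = "C", alt = "T",
                           sample_id = "S1", individual_id = sample_id,
                           cancer_type = "BRCA",
                           tissue_site = "solid_tissue",
                           somatic_confirmed = TRUE, snp_flagged = FALSE) {
  data.frame(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
             sample_id = sample_id, individual_id = individual_id,
             cancer_type = cancer_type, tissue_site = tissue_site,
             somatic_confirmed = somatic_confirmed, snp_flagged = snp_flagged,
             stringsAsFactors = FALSE)
}

make_gene_models <- function(genes_df, exons_list) {
  structure(list(genes = genes_df,
                 exons = GenomicRanges::GRangesList(exons_list)),
            class = "gene_models")
}

make_motif <- function(freq, motif_id = "M1") {
  rownames(freq) <- c("A", "C", "G", "T")
  structure(list(motif_id = motif_id, name = motif_id, length = ncol(freq),
                 freq = freq, counts = freq * 100),
            class = "motif_model")
}

random_column <- function() {
  p <- stats::runif(4)
  p / sum(p)
}

# O(n * u) recurrence grouping: distinct samples / cancer types / allele
# pairs per position, by direct scan.
bf_recurrent <- function(mut, min_samples = 2L) {
  keys <- unique(paste(mut$chrom, mut$pos))
  out <- list()
  for (k in keys) {
    sel <- paste(mut$chrom, mut$pos) == k
    samples <- unique(mut$sample_id[sel])
    if (length(samples) < min_samples) next
    out[[k]] <- list(
      chrom = mut$chrom[sel][1], pos = mut$pos[sel][1],
      recurrence = length(samples),
      n_types = length(unique(mut$cancer_type[sel])),
      same = length(unique(paste(mut$ref[sel], mut$alt[sel]))) == 1L)
  }
  out
}

# Direct containment scan of 1-based positions in 1-based closed intervals.
bf_contained <- function(chrom, pos, iv_chrom, iv_start, iv_end) {
  vapply(seq_along(pos), function(i) {
    any(iv_chrom == chrom[i] & iv_start <= pos[i] & iv_end >= pos[i])
  }, TRUE)
}

# Reference BH step-up, written independently of stats::p.adjust.
bf_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  out <- numeric(m)
  out[o] <- q_sorted
  out
}

# Exact two-sided rank-sum p by full enumeration of group assignments.
bf_exact_wilcox <- function(x, y) {
  vals <- c(x, y)
  n <- length(vals)
  k <- length(x)
  r <- rank(vals)
  obs <- sum(r[seq_len(k)])
  combs <- utils::combn(n, k)
  W <- apply(combs, 2, function(idx) sum(r[idx]))
  lower <- mean(W <= obs)
  upper <- mean(W >= obs)
  min(1, 2 * min(lower, upper))
}

# Brute-force target assignment: scan every interaction in both anchor
# orientations for (site overlap, TSS containment).
bf_targets <- function(site_chrom, site_start, site_end, interactions, genes) {
  gdf <- genes$genes
  hit <- character()
  for (i in seq_len(nrow(interactions))) {
    for (sides in list(c("a", "b"), c("b", "a"))) {
      nc <- interactions[[paste0("chrom_", sides[1])]][i]
      ns <- interactions[[paste0("start_", sides[1])]][i]
      ne <- interactions[[paste0("end_", sides[1])]][i]
      fc <- interactions[[paste0("chrom_", sides[2])]][i]
      fs <- interactions[[paste0("start_", sides[2])]][i]
      fe <- interactions[[paste0("end_", sides[2])]][i]
      if (nc == site_chrom && ns <= site_end && ne >= site_start) {
        for (g in seq_len(nrow(gdf))) {
          if (gdf$chrom[g] == fc && fs <= gdf$tss[g] && fe >= gdf$tss[g]) {
            hit <- c(hit, gdf$gene_id[g])
          }
        }
      }
    }
  }
  sort(unique(hit))
}

# Tiny two-gene toy annotation reused by several tests:
# GENE_A: chr1 + strand, span [1000, 2999], exons [1000,1299] & [2700,2999]
# GENE_B: chr1 - strand, span [5000, 6999], exons [5000,5299] & [6700,6999]
toy_two_genes <- function() {
  genes_df <- data.frame(
    gene_id = c("GENE_A", "GENE_B"), gene_name = c("A", "B"),
    chrom = "chr1", strand = c("+", "-"),
    start = c(1000L, 5000L), end = c(2999L, 6999L),
    tss = c(1000L, 6999L), stringsAsFactors = FALSE)
  exons <- list(
    GENE_A = GenomicRanges::GRanges("chr1", IRanges::IRanges(
      c(1000, 2700), c(1299, 2999))),
    GENE_B = GenomicRanges::GRanges("chr1", IRanges::IRanges(
      c(5000, 6700), c(5299, 6999))))
  make_gene_models(genes_df, exons)
}

small_cohort_config <- function(seed, ...) {
  defaults <- list(seed = seed, n_genes = 30L, n_samples_cohort1 = 45L,
                   n_samples_cohort2 = 60L, muts_per_sample = 15L,
                   planted_samples_cohort1 = 3L, planted_samples_cohort2 = 5L,
                   n_background_peaks = 150L, n_background_interactions = 25L)
  do.call(cohort_config, utils::modifyList(defaults, list(...)))
}
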