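#' Configuration for a synthetic two-cohort study
#'
#' Describes the study conditions emulated by [generate_cohort()]: a toy
#' genome with gene models, a curated discovery cohort ("cohort 1",
#' COSMIC-like, with tissue/individual/somatic/SNP annotations), a WGS
#' validation cohort with linked expression ("cohort 2", TCGA-like),
#' open-chromatin peaks covering ~8% of the genome, chromatin interaction
#' anchor pairs, motif models with planted binding-site instances, and a
#' genes x samples expression matrix with planted down-regulation in
#' mutated samples.
#'
#' @param seed RNG seed; the whole bundle is deterministic given the seed.
#' @param n_chroms,chrom_length toy genome shape.
#' @param n_genes number of genes (6 kb span, 3 exons each).
#' @param n_samples_cohort1,n_samples_cohort2 cohort sizes.
#' @param cancer_types cancer-type labels, assigned round-robin (uniform
#'   proportions).
#' @param muts_per_sample background somatic SNVs per sample.
#' @param n_planted_cnrms planted true CNRMs (each satisfies all ten
#'   criteria by construction).
#' @param planted_samples_cohort1,planted_samples_cohort2 supporting
#'   samples per planted CNRM in each cohort (cohort-1 carriers span >= 2
#'   cancer types by construction).
#' @param n_background_peaks,peak_width open-chromatin peak set (the
#'   defaults put ~8% of the genome in peaks, matching the genome-wide
#'   open-chromatin fraction the screen assumes).
#' @param n_background_interactions,anchor_width background interaction
#'   anchor pairs.
#' @param n_motifs,motif_length,consensus_count,other_count motif models:
#'   per-column counts of the consensus base vs each other base.
#' @param effect_size planted expression shift in within-type SD units.
#' @param effect_fraction fraction of planted sites whose target gene
#'   carries the expression effect (default all).
#' @param expression_sd within-stratum SD of log2 expression.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(seed = 1L,
                          n_chroms = 2L, chrom_length = 1e6, n_genes = 40L,
                          n_samples_cohort1 = 60L, n_samples_cohort2 = 80L,
                          cancer_types = c("BRCA", "LUAD", "COAD", "STAD"),
                          muts_per_sample = 30L,
                          n_planted_cnrms = 7L,
                          planted_samples_cohort1 = 3L,
                          planted_samples_cohort2 = 6L,
                          n_background_peaks = 380L, peak_width = 400L,
                          n_background_interactions = 50L,
                          anchor_width = 1000L,
                          n_motifs = 5L, motif_length = 10L,
                          consensus_count = 85L, other_count = 5L,
                          effect_size = 2, effect_fraction = 1,
                          expression_sd = 0.5) {
  cfg <- as.list(environment())
  if (length(cancer_types) < 2L) stop_format("need >= 2 cancer types")
  if (planted_samples_cohort1 < 2L) stop_format("planted CNRMs need >= 2 cohort-1 samples")
  n_decoys <- 11L
  genes_per_chrom <- ceiling(n_genes / n_chroms)
  if (n_planted_cnrms + n_decoys > n_genes - n_chroms) {
    stop_format("too many planted loci for %d genes", n_genes)
  }
  needed1 <- n_planted_cnrms * planted_samples_cohort1 + 16L +
    length(cancer_types)
  if (needed1 > n_samples_cohort1) {
    stop_format("cohort 1 too small: planted + decoy carriers need %d samples", needed1)
  }
  needed2 <- n_planted_cnrms * planted_samples_cohort2 + 8L
  if (needed2 > n_samples_cohort2) {
    stop_format("cohort 2 too small: planted + decoy carriers need %d samples", needed2)
  }
  span <- chrom_length / (genes_per_chrom + 1)
  if (span < 20000) stop_format("chrom_length too small for gene layout")
  class(cfg) <- c("cohort_config", "list")
  cfg
}

# Deterministic toy gene layout: genes evenly spaced per chromosome,
# alternating strand, 3 exons of 300 bp each over a 6 kb span.
build_toy_genes <- function(cfg) {
  per <- as.integer(ceiling(cfg$n_genes / cfg$n_chroms))
  spacing <- as.integer(cfg$chrom_length %/% (per + 1L))
  rows <- list(); exons <- list()
  g <- 0L
  for (c in seq_len(cfg$n_chroms)) {
    chrom <- paste0("chr", c)
    for (i in seq_len(per)) {
      g <- g + 1L
      if (g > cfg$n_genes) break
      center <- i * spacing              # integer arithmetic throughout
      start <- center - 3000L; end <- center + 2999L
      strand <- if (g %% 2L == 1L) "+" else "-"
      gid <- sprintf("GENE%03d", g)
      rows[[g]] <- data.frame(
        gene_id = gid, gene_name = paste0("Gn", g), chrom = chrom,
        strand = strand, start = start, end = end,
        tss = if (strand == "-") end else start, stringsAsFactors = FALSE)
      exons[[gid]] <- GenomicRanges::GRanges(chrom, IRanges::IRanges(
        c(start, center - 150L, end - 299L),
        c(start + 299L, center + 149L, end)))
    }
  }
  genes <- do.call(rbind, rows)
  structure(list(genes = genes,
                 exons = GenomicRanges::GRangesList(exons)),
            class = "gene_models")
}

build_toy_motifs <- function(cfg) {
  motifs <- vector("list", cfg$n_motifs)
  for (m in seq_len(cfg$n_motifs)) {
    consensus <- sample(BASES, cfg$motif_length, replace = TRUE)
    counts <- matrix(cfg$other_count, 4, cfg$motif_length,
                     dimnames = list(BASES, NULL))
    for (j in seq_len(cfg$motif_length)) counts[consensus[j], j] <- cfg$consensus_count
    freq <- sweep(counts, 2, colSums(counts), "/")
    motifs[[m]] <- structure(
      list(motif_id = sprintf("MA%04d.1", m), name = sprintf("TF%d", m),
           length = cfg$motif_length, freq = freq, counts = counts),
      class = "motif_model")
  }
  names(motifs) <- vapply(motifs, `[[`, "", "motif_id")
  motifs
}

# Intergenic midpoint after gene k (same chromosome), used to place
# planted and decoy loci well away from exons and from each other.
gap_after_gene <- function(genes, k) {
  gdf <- genes$genes
  g <- gdf[k, ]
  nxt <- gdf[gdf$chrom == g$chrom & gdf$start > g$end, , drop = FALSE]
  right <- if (nrow(nxt)) min(nxt$start) else g$end + 40000L
  as.integer(floor((g$end + right) / 2))
}

#' Generate a complete synthetic fixture bundle with planted truth
#'
#' Builds, deterministically under `config$seed`, every input the CNRM
#' pipeline consumes plus a truth manifest. Planted CNRMs satisfy all ten
#' filtering criteria by construction: each sits at a consensus column of
#' a planted TF binding-site instance (score >= 480), inside an
#' open-chromatin peak that is itself an interaction anchor whose partner
#' anchor contains the target gene's TSS, and is carried by multiple
#' samples spanning multiple cancer types in both cohorts. Eleven decoys
#' each fail exactly one named criterion (hematopoietic tissue,
#' same-individual duplicate, unconfirmed somatic, SNP-flagged, exonic,
#' single sample, single cancer type, absent from cohort 2, outside
#' peaks, outside anchors, sub-threshold site score).
#'
#' Background mutation positions are disjoint from every planted/decoy
#' position; background peaks and interaction anchors are kept clear of
#' the planted/decoy windows so each decoy fails only its own criterion.
#'
#' @param config a [cohort_config()].
#' @return list: `genes`, `cosmic` (cohort-1 mutations), `tcga` (cohort-2
#'   mutations), `peaks`, `interactions`, `motifs`, `sites`, `expression`,
#'   `meta`, and `truth` (planted + decoy manifest).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  genes <- build_toy_genes(cfg)
  motifs <- build_toy_motifs(cfg)
  gdf <- genes$genes
  types <- cfg$cancer_types
  nT <- length(types)
  np <- cfg$n_planted_cnrms
  genome <- data.frame(chrom = paste0("chr", seq_len(cfg$n_chroms)),
                       length = cfg$chrom_length)

  ## ---- planted loci -------------------------------------------------
  site_rows <- list(); peak_rows <- list(); int_rows <- list()
  planted <- list()
  for (k in seq_len(np)) {
    host <- k                      # gene whose downstream gap hosts the site
    target <- gdf$gene_id[k]       # interaction partner: same gene's TSS
    loc <- gap_after_gene(genes, host)
    strand <- if (k %% 2L == 1L) "+" else "-"
    motif <- motifs[[(k - 1L) %% cfg$n_motifs + 1L]]
    s <- loc; e <- loc + motif$length - 1L
    info <- motif_information(motif)
    j <- which.max(info)
    consensus <- BASES[which.max(motif$freq[, j])]
    weakest <- BASES[which.min(motif$freq[, j])]
    if (weakest == consensus) weakest <- setdiff(BASES, consensus)[1]
    pos <- if (strand == "-") e - j + 1L else s + j - 1L
    ref <- if (strand == "-") COMPLEMENT[[consensus]] else consensus
    alt <- if (strand == "-") COMPLEMENT[[weakest]] else weakest
    sid <- sprintf("SITE%03d", k)
    site_rows[[k]] <- data.frame(chrom = gdf$chrom[host], start = s, end = e,
                                 site_id = sid, motif_id = motif$motif_id,
                                 score = 480 + k, strand = strand,
                                 stringsAsFactors = FALSE)
    half <- floor((cfg$peak_width - motif$length) / 2)
    peak_rows[[k]] <- data.frame(chrom = gdf$chrom[host], start = s - half,
                                 end = s - half + cfg$peak_width - 1L,
                                 name = sprintf("peak_planted_%02d", k),
                                 stringsAsFactors = FALSE)
    int_rows[[k]] <- data.frame(
      chrom_a = gdf$chrom[host], start_a = s - half,
      end_a = s - half + cfg$peak_width - 1L,
      chrom_b = gdf$chrom[host], start_b = gdf$tss[host] - 200L,
      end_b = gdf$tss[host] + 200L,
      cell_type = "synthetic", method = "Hi-C", stringsAsFactors = FALSE)
    planted[[k]] <- data.frame(
      chrom = gdf$chrom[host], pos = pos, ref = ref, alt = alt,
      site_id = sid, motif_id = motif$motif_id, motif_column = j,
      target_gene = target, effect_size = cfg$effect_size,
      direction = "down", expected_delta_bit_sign = "negative",
      stringsAsFactors = FALSE)
  }
  planted <- do.call(rbind, planted)

  ## ---- decoys (one per criterion) -----------------------------------
  decoy_labels <- c("1_hematopoietic_tissue", "2_same_individual",
                    "3_not_somatic_confirmed", "4_snp_flagged", "5_exonic",
                    "6_single_sample", "6_single_cancer_type",
                    "7_absent_from_cohort2", "8_outside_peaks",
                    "9_outside_anchors", "10_tfbs_score_below_threshold")
  dpos <- integer(11); dchrom <- character(11)
  for (d in seq_len(11L)) {
    host <- np + d
    dchrom[d] <- gdf$chrom[host]
    dpos[d] <- gap_after_gene(genes, host)
  }
  # exonic decoy sits mid-exon of its host gene instead of in the gap
  host5 <- np + 5L
  dpos[5] <- gdf$start[host5] + 150L
  # decoy 9 must be outside every peak: its gap position is excluded from
  # background peak placement below.
  # decoy 10: own peak, excluded from anchors.
  half <- floor(cfg$peak_width / 2)
  peak_rows[[length(peak_rows) + 1L]] <- data.frame(
    chrom = dchrom[10], start = dpos[10] - half,
    end = dpos[10] + half - 1L, name = "peak_decoy_anchorless",
    stringsAsFactors = FALSE)
  # decoy 11: sub-threshold site inside a peak that is an anchor.
  m11 <- motifs[[1L]]
  s11 <- dpos[11] - 4L
  site_rows[[length(site_rows) + 1L]] <- data.frame(
    chrom = dchrom[11], start = s11, end = s11 + m11$length - 1L,
    site_id = "SITE_LOWSCORE", motif_id = m11$motif_id, score = 399,
    strand = "+", stringsAsFactors = FALSE)
  peak_rows[[length(peak_rows) + 1L]] <- data.frame(
    chrom = dchrom[11], start = dpos[11] - half, end = dpos[11] + half - 1L,
    name = "peak_decoy_lowscore", stringsAsFactors = FALSE)
  int_rows[[length(int_rows) + 1L]] <- data.frame(
    chrom_a = dchrom[11], start_a = dpos[11] - half, end_a = dpos[11] + half - 1L,
    chrom_b = gdf$chrom[host5], start_b = gdf$tss[host5] - 200L,
    end_b = gdf$tss[host5] + 200L,
    cell_type = "synthetic", method = "IM-PET", stringsAsFactors = FALSE)
  decoys <- data.frame(chrom = dchrom, pos = dpos, criterion = decoy_labels,
                       stringsAsFactors = FALSE)

  forbidden <- pos_key(c(planted$chrom, decoys$chrom),
                       c(planted$pos, decoys$pos))
  # windows around every engineered locus that background features avoid
  locus_windows <- GenomicRanges::GRanges(
    c(planted$chrom, decoys$chrom),
    IRanges::IRanges(c(planted$pos, decoys$pos) - 1500L,
                     c(planted$pos, decoys$pos) + 1500L))

  ## ---- background peaks and interactions ----------------------------
  draw_intervals <- function(n, width) {
    out <- GenomicRanges::GRanges(); guard <- 0L
    while (length(out) < n) {
      guard <- guard + 1L
      if (guard > 50L) stop_format("could not place background intervals")
      ch <- sample(genome$chrom, 2L * n, replace = TRUE)
      st <- floor(runif(2L * n, 1, cfg$chrom_length - width - 1))
      gr <- GenomicRanges::GRanges(ch, IRanges::IRanges(st, st + width - 1L))
      gr <- gr[GenomicRanges::countOverlaps(gr, locus_windows) == 0L]
      out <- c(out, gr)
    }
    out[seq_len(n)]
  }
  bg_peaks <- draw_intervals(cfg$n_background_peaks, cfg$peak_width)
  bg_a <- draw_intervals(cfg$n_background_interactions, cfg$anchor_width)
  bg_b <- draw_intervals(cfg$n_background_interactions, cfg$anchor_width)
  int_rows[[length(int_rows) + 1L]] <- data.frame(
    chrom_a = as.character(GenomicRanges::seqnames(bg_a)),
    start_a = GenomicRanges::start(bg_a), end_a = GenomicRanges::end(bg_a),
    chrom_b = as.character(GenomicRanges::seqnames(bg_b)),
    start_b = GenomicRanges::start(bg_b), end_b = GenomicRanges::end(bg_b),
    cell_type = "synthetic",
    method = rep(c("Hi-C", "ChIA-PET", "IM-PET"),
                 length.out = cfg$n_background_interactions),
    stringsAsFactors = FALSE)

  peak_df <- do.call(rbind, peak_rows)
  bg_peak_df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(bg_peaks)),
    start = GenomicRanges::start(bg_peaks),
    end = GenomicRanges::end(bg_peaks),
    name = sprintf("peak_bg_%04d", seq_along(bg_peaks)),
    stringsAsFactors = FALSE)
  peak_df <- rbind(peak_df, bg_peak_df)
  peaks <- GenomicRanges::GRanges(peak_df$chrom,
                                  IRanges::IRanges(peak_df$start, peak_df$end))
  peaks$name <- peak_df$name
  peaks$score <- rep(100L, length(peaks))

  interactions <- do.call(rbind, int_rows)
  class(interactions) <- c("chromatin_interactions", "data.frame")

  site_df <- do.call(rbind, site_rows)
  sites <- GenomicRanges::GRanges(site_df$chrom,
                                  IRanges::IRanges(site_df$start, site_df$end),
                                  strand = site_df$strand)
  sites$site_id <- site_df$site_id
  sites$motif_id <- site_df$motif_id
  sites$score <- site_df$score

  ## ---- cohort assembly ----------------------------------------------
  draw_background <- function(sample_ids, individual_ids, sample_types) {
    n_mut <- cfg$muts_per_sample * length(sample_ids)
    ch <- sample(genome$chrom, n_mut, replace = TRUE)
    pos <- floor(runif(n_mut, 1, cfg$chrom_length))
    bad <- pos_key(ch, pos) %in% forbidden
    while (any(bad)) {
      pos[bad] <- floor(runif(sum(bad), 1, cfg$chrom_length))
      bad <- pos_key(ch, pos) %in% forbidden
    }
    ref <- sample(BASES, n_mut, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(BASES, b), 1L), "")
    data.frame(chrom = ch, pos = as.integer(pos), ref = ref, alt = unname(alt),
               sample_id = rep(sample_ids, each = cfg$muts_per_sample),
               individual_id = rep(individual_ids, each = cfg$muts_per_sample),
               cancer_type = rep(sample_types, each = cfg$muts_per_sample),
               tissue_site = "solid_tissue", somatic_confirmed = TRUE,
               snp_flagged = FALSE, stringsAsFactors = FALSE)
  }
  record <- function(d, pos_row, sample_id, individual_id, cancer_type,
                     tissue = "solid_tissue", somatic = TRUE, snp = FALSE,
                     ref = NULL, alt = NULL) {
    data.frame(chrom = pos_row$chrom, pos = pos_row$pos,
               ref = if (is.null(ref)) "C" else ref,
               alt = if (is.null(alt)) "T" else alt,
               sample_id = sample_id, individual_id = individual_id,
               cancer_type = cancer_type, tissue_site = tissue,
               somatic_confirmed = somatic, snp_flagged = snp,
               stringsAsFactors = FALSE)
  }

  ## cohort 1 (curated, cosmic dialect)
  s1 <- sprintf("SC%03d", seq_len(cfg$n_samples_cohort1))
  i1 <- sprintf("IC%03d", seq_len(cfg$n_samples_cohort1))
  t1 <- types[(seq_len(cfg$n_samples_cohort1) - 1L) %% nT + 1L]
  cosmic <- draw_background(s1, i1, t1)
  k1 <- cfg$planted_samples_cohort1
  extra <- list()
  for (k in seq_len(np)) {
    idx <- ((k - 1L) * k1 + 1L):(k * k1)
    for (i in idx) {
      extra[[length(extra) + 1L]] <- record(NULL, planted[k, ], s1[i], i1[i],
                                            t1[i], ref = planted$ref[k],
                                            alt = planted$alt[k])
    }
  }
  base <- np * k1
  same_type_pair <- function(i) c(i, i + nT)   # round-robin => same type
  drow <- function(d) decoys[d, ]
  # d1: dedicated hematopoietic samples
  for (i in 1:2) {
    extra[[length(extra) + 1L]] <- record(NULL, drow(1), sprintf("SH%02d", i),
      sprintf("IH%02d", i), types[i],
      tissue = "haematopoietic_and_lymphoid_tissue")
  }
  # d2: two samples, one individual (both would be multi-type if kept)
  extra[[length(extra) + 1L]] <- record(NULL, drow(2), "SDUPA", "IDUP", types[1])
  extra[[length(extra) + 1L]] <- record(NULL, drow(2), "SDUPB", "IDUP", types[2])
  # d3/d4: flagged records in regular samples
  for (i in base + 1:2) extra[[length(extra) + 1L]] <-
    record(NULL, drow(3), s1[i], i1[i], t1[i], somatic = FALSE)
  for (i in base + 3:4) extra[[length(extra) + 1L]] <-
    record(NULL, drow(4), s1[i], i1[i], t1[i], snp = TRUE)
  # d5: exonic; d6: single sample; d7: single cancer type
  for (i in base + 5:6) extra[[length(extra) + 1L]] <-
    record(NULL, drow(5), s1[i], i1[i], t1[i])
  extra[[length(extra) + 1L]] <- record(NULL, drow(6), s1[base + 7L],
                                        i1[base + 7L], t1[base + 7L])
  for (i in same_type_pair(base + 8L)) extra[[length(extra) + 1L]] <-
    record(NULL, drow(7), s1[i], i1[i], t1[i])
  # d8-d11: recurrent multi-type pairs
  dd <- base + 8L + nT
  for (d in 8:11) {
    for (i in dd + 1:2) extra[[length(extra) + 1L]] <-
      record(NULL, drow(d), s1[i], i1[i], t1[i])
    dd <- dd + 2L
  }
  cosmic <- rbind(cosmic, do.call(rbind, extra))
  cosmic$pos <- as.integer(cosmic$pos)
  rownames(cosmic) <- NULL

  ## cohort 2 (WGS validation, simple dialect + cancer_type)
  s2 <- sprintf("ST%03d", seq_len(cfg$n_samples_cohort2))
  i2 <- sprintf("IT%03d", seq_len(cfg$n_samples_cohort2))
  t2 <- types[(seq_len(cfg$n_samples_cohort2) - 1L) %% nT + 1L]
  tcga <- draw_background(s2, i2, t2)
  k2 <- cfg$planted_samples_cohort2
  extra2 <- list()
  planted_c2_samples <- vector("list", np)
  for (k in seq_len(np)) {
    idx <- ((k - 1L) * k2 + 1L):(k * k2)
    planted_c2_samples[[k]] <- s2[idx]
    for (i in idx) {
      extra2[[length(extra2) + 1L]] <- record(NULL, planted[k, ], s2[i], i2[i],
                                              t2[i], ref = planted$ref[k],
                                              alt = planted$alt[k])
    }
  }
  base2 <- np * k2
  dd <- base2
  for (d in c(5L, 9L, 10L, 11L)) {     # decoys that must exist in cohort 2
    for (i in dd + 1:2) extra2[[length(extra2) + 1L]] <-
      record(NULL, drow(d), s2[i], i2[i], t2[i])
    dd <- dd + 2L
  }
  tcga <- rbind(tcga, do.call(rbind, extra2))
  tcga <- tcga[, c("chrom", "pos", "ref", "alt", "sample_id", "cancer_type")]
  tcga$pos <- as.integer(tcga$pos)
  rownames(tcga) <- NULL

  meta <- data.frame(sample_id = s2, cancer_type = t2, stringsAsFactors = FALSE)

  n_effect <- round(cfg$effect_fraction * np)
  planted$has_effect <- seq_len(np) <= n_effect
  planted$cohort1_samples <- vapply(seq_len(np), function(k) {
    paste(s1[((k - 1L) * k1 + 1L):(k * k1)], collapse = ",")
  }, "")
  planted$cohort2_samples <- vapply(planted_c2_samples, paste, "",
                                    collapse = ",")

  expression <- generate_expression(cfg, list(planted = planted), genes, meta)

  list(config = cfg, genes = genes, cosmic = cosmic, tcga = tcga,
       peaks = peaks, interactions = interactions, motifs = motifs,
       sites = sites, expression = expression, meta = meta,
       truth = list(planted = planted, decoys = decoys))
}

#' Generate a synthetic expression matrix with planted effects
#'
#' Per cancer type, gene baselines are drawn from a log-normal family
#' (Gaussian on the log2 scale: gene baseline + type offset + noise of SD
#' `config$expression_sd`). For every planted site with an expression
#' effect, the target gene of each mutated cohort-2 sample is shifted by
#' `config$effect_size` within-type SDs in the planted direction (down).
#' Unaffected genes are pure noise. Downstream analysis is rank-based on
#' within-type z-scores, so results are invariant to the monotone
#' location-scale choices made here.
#'
#' @param config a [cohort_config()].
#' @param truth truth manifest (list with `planted`: target_gene,
#'   has_effect, direction, comma-separated cohort2_samples).
#' @param genes `gene_models` for the toy genome.
#' @param meta cohort-2 sample metadata (sample_id, cancer_type).
#' @param seed optional RNG seed; when NULL (as in [generate_cohort()])
#'   the ambient RNG stream is used.
#' @return genes x samples expression matrix (linear scale).
#' @export
generate_expression <- function(config, truth, genes, meta, seed = NULL) {
  gen <- function() {
    gdf <- genes$genes
    types <- unique(meta$cancer_type)
    base_mu <- rnorm(nrow(gdf), mean = 8, sd = 1)
    type_off <- matrix(rnorm(nrow(gdf) * length(types), 0, 0.3),
                       nrow(gdf), length(types),
                       dimnames = list(gdf$gene_id, types))
    logmat <- matrix(NA_real_, nrow(gdf), nrow(meta),
                     dimnames = list(gdf$gene_id, meta$sample_id))
    for (j in seq_len(nrow(meta))) {
      mu <- base_mu + type_off[, meta$cancer_type[j]]
      logmat[, j] <- rnorm(nrow(gdf), mu, config$expression_sd)
    }
    pl <- truth$planted
    for (k in seq_len(NROW(pl))) {
      if (!isTRUE(pl$has_effect[k])) next
      g <- pl$target_gene[k]
      carriers <- intersect(strsplit(pl$cohort2_samples[k], ",")[[1]],
                            colnames(logmat))
      shift <- config$effect_size * config$expression_sd
      sgn <- if (identical(pl$direction[k], "up")) 1 else -1
      logmat[g, carriers] <- logmat[g, carriers] + sgn * shift
    }
    2^logmat
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Write a synthetic bundle to disk in the pipeline's external formats
#'
#' Emits cosmic_mutations.tsv, tcga_mutations.tsv, genes.gtf, peaks.bed,
#' interactions.tsv, motifs.pfm, tfbs_sites.tsv, expression.tsv,
#' sample_metadata.tsv and truth_manifest.json. Every file re-parses
#' through the package's readers with zero rejected records.
#'
#' @param bundle output of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_mutation_table(bundle$cosmic, p("cosmic_mutations.tsv"))
  write_mutation_table(bundle$tcga, p("tcga_mutations.tsv"))
  write_gene_gtf(bundle$genes, p("genes.gtf"))
  write_bed(bundle$peaks, p("peaks.bed"))
  write_interactions(bundle$interactions, p("interactions.tsv"))
  write_jaspar_pfm(bundle$motifs, p("motifs.pfm"))
  write_tfbs_sites(bundle$sites, p("tfbs_sites.tsv"))
  write_expression_matrix(round(bundle$expression, 6), p("expression.tsv"))
  write.table(bundle$meta, p("sample_metadata.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(bundle$truth, p("truth_manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}

# Gene models -> Ensembl-dialect GTF (gene + exon features).
write_gene_gtf <- function(genes, path) {
  gdf <- genes$genes
  lines <- character()
  attr_str <- function(gid, gname) {
    sprintf('gene_id "%s"; gene_name "%s";', gid, gname)
  }
  for (i in seq_len(nrow(gdf))) {
    g <- gdf[i, ]
    lines <- c(lines, paste(g$chrom, "toy", "gene", g$start, g$end, ".",
                            g$strand, ".", attr_str(g$gene_id, g$gene_name),
                            sep = "\t"))
    ex <- genes$exons[[g$gene_id]]
    if (!is.null(ex) && length(ex)) {
      for (j in seq_along(ex)) {
        lines <- c(lines, paste(g$chrom, "toy", "exon",
                                GenomicRanges::start(ex)[j],
                                GenomicRanges::end(ex)[j], ".", g$strand, ".",
                                attr_str(g$gene_id, g$gene_name), sep = "\t"))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a bundle directory written by [write_cohort()]
#' @param dir bundle directory.
#' @return list shaped like [generate_cohort()] output (without `truth`
#'   unless truth_manifest.json is present).
#' @export
read_cohort <- function(dir) {
  p <- function(f) file.path(dir, f)
  truth <- if (file.exists(p("truth_manifest.json"))) {
    jsonlite::read_json(p("truth_manifest.json"), simplifyVector = TRUE)
  } else NULL
  list(genes = read_gtf_genes(p("genes.gtf")),
       cosmic = read_mutation_table(p("cosmic_mutations.tsv"), "cosmic"),
       tcga = read_mutation_table(p("tcga_mutations.tsv"), "simple"),
       peaks = read_bed(p("peaks.bed")),
       interactions = read_interactions(p("interactions.tsv")),
       motifs = read_jaspar_pfm(p("motifs.pfm")),
       sites = read_tfbs_sites(p("tfbs_sites.tsv")),
       expression = read_expression_matrix(p("expression.tsv")),
       meta = read_sample_metadata(p("sample_metadata.tsv")),
       truth = truth)
}
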