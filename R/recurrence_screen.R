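#' Apply the source-level mutation filters
#'
#' The first four steps of the screening cascade, applied to a curated
#' ("cosmic" dialect) mutation table in order:
#' 1. drop records from haematopoietic-and-lymphoid tissue samples (solid
#'    tumors only);
#' 2. keep one sample per individual (the lexicographically smallest
#'    sample_id; duplicate samples of the same individual are removed);
#' 3. keep only mutations confirmed somatic in tumor and matched normal;
#' 4. drop mutations flagged as SNPs.
#'
#' The four predicates are record-level and commute; the fixed order exists
#' only so the per-step removal counts are comparable between runs.
#'
#' @param mutations cosmic-dialect mutation data.frame.
#' @return list with `mutations` (the surviving records) and `funnel`, a
#'   data.frame of per-step in/out counts.
#' @export
apply_source_filters <- function(mutations) {
  steps <- list()
  note <- function(label, n_in, n_out) {
    steps[[length(steps) + 1L]] <<- data.frame(
      step = length(steps) + 1L, label = label,
      n_in = n_in, n_out = n_out, stringsAsFactors = FALSE)
  }

  n0 <- nrow(mutations)
  heme <- grepl("h(a)?ematopoietic_and_lymphoid_tissue",
                mutations$tissue_site, ignore.case = TRUE)
  mutations <- mutations[!heme, , drop = FALSE]
  note("remove_hematopoietic_lymphoid", n0, nrow(mutations))

  n1 <- nrow(mutations)
  if (n1 > 0 && (!"individual_id" %in% names(mutations) ||
                 anyNA(mutations$individual_id))) {
    stop_format("individual_id required to deduplicate samples per individual")
  }
  if (n1 > 0) {
    keep_sample <- tapply(mutations$sample_id, mutations$individual_id,
                          function(s) min(s))
    mutations <- mutations[
      mutations$sample_id == keep_sample[as.character(mutations$individual_id)], ,
      drop = FALSE]
  }
  note("one_sample_per_individual", n1, nrow(mutations))

  n2 <- nrow(mutations)
  mutations <- mutations[mutations$somatic_confirmed %in% TRUE, , drop = FALSE]
  note("confirmed_somatic_only", n2, nrow(mutations))

  n3 <- nrow(mutations)
  mutations <- mutations[!(mutations$snp_flagged %in% TRUE), , drop = FALSE]
  note("remove_snp_flagged", n3, nrow(mutations))

  rownames(mutations) <- NULL
  list(mutations = mutations, funnel = do.call(rbind, steps))
}

#' Remove mutations falling in exonic regions
#'
#' A mutation is removed iff its 1-based position lies inside the exon
#' union of any gene, on either strand.
#'
#' @param mutations mutation data.frame.
#' @param genes `gene_models` object.
#' @return the non-exonic subset of `mutations`.
#' @export
remove_exonic <- function(mutations, genes) {
  if (!nrow(mutations)) return(mutations)
  hits <- quiet_count(position_granges(mutations), exon_union(genes))
  out <- mutations[hits == 0L, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call recurrent positions
#'
#' Groups mutations by genomic position (chrom, pos) regardless of allele
#' and keeps positions supported by at least `min_samples` distinct
#' samples. Pattern consistency is `"same"` when exactly one (ref, alt)
#' pair is observed across the supporting records, in which case the
#' substitution is collapsed to its pyrimidine-reference six-class pattern.
#'
#' @param mutations filtered mutation data.frame.
#' @param min_samples minimum number of distinct supporting samples
#'   (default 2).
#' @return data.frame of recurrent positions: chrom, pos, recurrence,
#'   n_cancer_types, consistency, six_class, plus list-columns `samples`,
#'   `cancer_types` and `alleles`.
#' @export
call_recurrent_positions <- function(mutations, min_samples = 2L) {
  empty <- data.frame(
    chrom = character(), pos = integer(), recurrence = integer(),
    n_cancer_types = integer(), consistency = character(),
    six_class = character(), stringsAsFactors = FALSE)
  empty$samples <- list(); empty$cancer_types <- list(); empty$alleles <- list()
  if (!nrow(mutations)) return(empty)

  key <- pos_key(mutations$chrom, mutations$pos)
  idx <- split(seq_len(nrow(mutations)), key)
  recs <- lapply(idx, function(i) {
    samples <- sort(unique(mutations$sample_id[i]))
    if (length(samples) < min_samples) return(NULL)
    types <- if ("cancer_type" %in% names(mutations)) {
      sort(unique(mutations$cancer_type[i]))
    } else character()
    alleles <- sort(unique(paste0(mutations$ref[i], ">", mutations$alt[i])))
    same <- length(alleles) == 1L
    list(chrom = mutations$chrom[i[1]], pos = mutations$pos[i[1]],
         recurrence = length(samples), n_cancer_types = length(types),
         consistency = if (same) "same" else "different",
         six_class = if (same) six_class_collapse(mutations$ref[i[1]],
                                                  mutations$alt[i[1]])
                     else NA_character_,
         samples = samples, cancer_types = types, alleles = alleles)
  })
  recs <- Filter(Negate(is.null), recs)
  if (!length(recs)) return(empty)
  out <- data.frame(
    chrom = vapply(recs, `[[`, "", "chrom"),
    pos = vapply(recs, `[[`, 1L, "pos"),
    recurrence = vapply(recs, `[[`, 1L, "recurrence"),
    n_cancer_types = vapply(recs, `[[`, 1L, "n_cancer_types"),
    consistency = vapply(recs, `[[`, "", "consistency"),
    six_class = vapply(recs, `[[`, "", "six_class"),
    stringsAsFactors = FALSE)
  out$samples <- lapply(recs, `[[`, "samples")
  out$cancer_types <- lapply(recs, `[[`, "cancer_types")
  out$alleles <- lapply(recs, `[[`, "alleles")
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Collapse a substitution to the pyrimidine-reference six-class pattern:
# purine-reference substitutions are reverse-complemented (G>A == C>T).
six_class_collapse <- function(ref, alt) {
  if (ref %in% c("G", "A")) {
    ref <- COMPLEMENT[[ref]]
    alt <- COMPLEMENT[[alt]]
  }
  paste0(ref, ">", alt)
}

#' Keep recurrent positions shared by at least `min_types` cancer types
#'
#' Applied to remove sequencing/mapping artifacts and localized,
#' cancer-type-specific mutational processes: a position recurring only
#' within one cancer type is excluded.
#'
#' @param recurrents output of [call_recurrent_positions()].
#' @param min_types minimum distinct cancer types (default 2).
#' @return subset of `recurrents`.
#' @export
require_multi_cancer_type <- function(recurrents, min_types = 2L) {
  out <- recurrents[recurrents$n_cancer_types >= min_types, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Intersect recurrent positions with a second cohort
#'
#' Keeps positions whose (chrom, pos) also carries a mutation in a second
#' cohort (e.g. WGS calls with linked expression data), and attaches that
#' cohort's supporting sample ids for the downstream expression screen.
#'
#' @param recurrents recurrent-position data.frame.
#' @param second_cohort_mutations mutation data.frame for the second cohort.
#' @return subset of `recurrents` with an added `cohort2_samples`
#'   list-column.
#' @export
intersect_positions <- function(recurrents, second_cohort_mutations) {
  key1 <- pos_key(recurrents$chrom, recurrents$pos)
  key2 <- pos_key(second_cohort_mutations$chrom, second_cohort_mutations$pos)
  keep <- key1 %in% key2
  out <- recurrents[keep, , drop = FALSE]
  by_key <- split(second_cohort_mutations$sample_id, key2)
  out$cohort2_samples <- lapply(pos_key(out$chrom, out$pos),
                                function(k) sort(unique(by_key[[k]])))
  rownames(out) <- NULL
  out
}

#' Six-class substitution spectrum of consistent recurrent positions
#'
#' Tabulates the pyrimidine-reference substitution classes over the
#' positions whose supporting samples all carry the identical substitution
#' (`consistency == "same"`).
#'
#' @param recurrents recurrent-position data.frame.
#' @return data.frame with class, count and proportion (proportions sum
#'   to 1 over the "same" subset).
#' @export
six_class_spectrum <- function(recurrents) {
  same <- recurrents[recurrents$consistency == "same", , drop = FALSE]
  counts <- table(factor(same$six_class, levels = SIX_CLASSES))
  data.frame(class = SIX_CLASSES,
             count = as.integer(counts),
             proportion = if (nrow(same)) as.numeric(counts) / nrow(same)
                          else rep(NA_real_, 6L),
             stringsAsFactors = FALSE)
}

#' Test enrichment of mutations in coding regions
#'
#' Compares the observed fraction of mutations inside the exon union with
#' the fraction of the genome that is exonic, via a one-sided exact
#' binomial test (upper tail: enrichment).
#'
#' @param mutations mutation data.frame (must be non-empty).
#' @param genes `gene_models` object.
#' @param genome_length total genome length in bp.
#' @return list with observed_fraction, expected_fraction, n_coding, n and
#'   the one-sided p value.
#' @export
coding_fraction_test <- function(mutations, genes, genome_length) {
  if (!nrow(mutations)) stop_format("coding_fraction_test: no mutations")
  stopifnot(genome_length > 0)
  ex <- exon_union(genes)
  n_coding <- sum(quiet_count(position_granges(mutations), ex) > 0L)
  n <- nrow(mutations)
  expected <- sum(GenomicRanges::width(ex)) / genome_length
  p <- binom.test(n_coding, n, p = expected, alternative = "greater")$p.value
  list(observed_fraction = n_coding / n, expected_fraction = expected,
       n_coding = n_coding, n = n, p = p)
}

#' Annotate the genomic context of mutations
#'
#' Labels each mutation exonic (inside the exon union), intronic (inside a
#' gene span but outside every exon) or intergenic, and reports the signed
#' distance to the nearest gene TSS: 0 at the TSS, positive downstream of
#' the TSS in the direction of transcription, negative upstream.
#'
#' @param mutations mutation data.frame.
#' @param genes `gene_models` object.
#' @return list with `annotation` (per-mutation chrom, pos, context,
#'   nearest_gene, tss_distance) and `fractions`, the aggregate
#'   exonic/intronic/intergenic proportions.
#' @export
genomic_context <- function(mutations, genes) {
  n <- nrow(mutations)
  gdf <- genes$genes
  mut_gr <- position_granges(mutations)
  exonic <- quiet_count(mut_gr, exon_union(genes)) > 0L
  span_gr <- GenomicRanges::GRanges(gdf$chrom,
                                    IRanges::IRanges(gdf$start, gdf$end))
  in_span <- quiet_count(mut_gr, span_gr) > 0L
  context <- ifelse(exonic, "exonic", ifelse(in_span, "intronic", "intergenic"))

  nearest_gene <- rep(NA_character_, n)
  tss_distance <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    cand <- which(gdf$chrom == mutations$chrom[i])
    if (!length(cand)) next
    signed <- ifelse(gdf$strand[cand] == "-",
                     gdf$tss[cand] - mutations$pos[i],
                     mutations$pos[i] - gdf$tss[cand])
    ord <- cand[order(abs(signed), gdf$gene_id[cand])]
    best <- ord[1]
    nearest_gene[i] <- gdf$gene_id[best]
    tss_distance[i] <- signed[match(best, cand)]
  }
  annotation <- data.frame(chrom = mutations$chrom, pos = mutations$pos,
                           context = context, nearest_gene = nearest_gene,
                           tss_distance = tss_distance,
                           stringsAsFactors = FALSE)
  fractions <- vapply(c("exonic", "intronic", "intergenic"),
                      function(ct) mean(context == ct), 0)
  list(annotation = annotation, fractions = fractions)
}
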