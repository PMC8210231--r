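#' Per-column information content of a motif column
#'
#' For a frequency column p over A/C/G/T, the information content is
#' `C = 2 + sum_b p_b * log2(p_b)` bits, with the convention that a term
#' with p_b = 0 contributes 0. Ranges from 0 (uniform column) to 2
#' (invariant column).
#'
#' @param freq_column numeric vector of 4 base frequencies summing to 1.
#' @return information content in bits.
#' @export
column_information <- function(freq_column) {
  if (any(freq_column < 0)) stop_format("negative frequency")
  if (abs(sum(freq_column) - 1) > 1e-6) {
    stop_format("frequency column must sum to 1 (got %.6f)", sum(freq_column))
  }
  nz <- freq_column > 0
  2 + sum(freq_column[nz] * log2(freq_column[nz]))
}

# Vector of C_i over all motif columns.
motif_information <- function(motif) {
  apply(motif$freq, 2, column_information)
}

#' Information change of a single-base substitution in a motif (delta-bit)
#'
#' Quantifies how a substitution at motif column `i` alters the motif
#' information carried by the observed base. The default `"letter_height"`
#' convention uses sequence-logo letter heights h(b) = p_b * C_i, so
#' `delta_bit = (p_alt - p_ref) * C_i`: negative values mean the mutation
#' moves away from the preferred base, i.e. a weakened site. The
#' `"log_ratio"` alternative returns `log2(p_alt) - log2(p_ref)` (infinite
#' when a frequency is 0).
#'
#' Antisymmetric in (ref, alt) under both conventions.
#'
#' @param motif `motif_model`.
#' @param i motif column, 1..L.
#' @param ref,alt reference and alternate bases (must differ).
#' @param method `"letter_height"` (default) or `"log_ratio"`.
#' @return delta-bit in bits.
#' @export
delta_bit <- function(motif, i, ref, alt,
                      method = c("letter_height", "log_ratio")) {
  method <- match.arg(method)
  if (i < 1 || i > motif$length) {
    stop_format("motif column %d out of range 1..%d", i, motif$length)
  }
  if (!(ref %in% BASES) || !(alt %in% BASES) || ref == alt) {
    stop_format("ref and alt must be distinct A/C/G/T bases")
  }
  p <- motif$freq[, i]
  if (method == "letter_height") {
    ci <- column_information(p)
    unname((p[alt] - p[ref]) * ci)
  } else {
    unname(log2(p[alt]) - log2(p[ref]))
  }
}

#' Average delta-bit of the mutations in one TF binding site
#'
#' Maps each genomic mutation onto its motif column (for minus-strand
#' sites the motif is read on the reverse strand: the column index is
#' reversed and ref/alt are complemented), computes the per-mutation
#' delta-bit, and averages. Each sample's mutation is counted once
#' (duplicate (sample, pos, ref, alt) records are collapsed).
#'
#' @param site one-row `GRanges` (or length-1 subset) with strand, from
#'   [read_tfbs_sites()].
#' @param mutations_in_site mutation data.frame; every position must lie
#'   inside the site interval.
#' @param motif the site's `motif_model`.
#' @param method delta-bit convention, see [delta_bit()].
#' @return list: site_id, per_mutation data.frame (pos, column, ref, alt,
#'   delta_bit) and average_delta_bit.
#' @export
average_delta_bit <- function(site, mutations_in_site, motif,
                              method = "letter_height") {
  stopifnot(length(site) == 1L)
  s <- GenomicRanges::start(site)
  e <- GenomicRanges::end(site)
  if (any(mutations_in_site$pos < s | mutations_in_site$pos > e)) {
    stop_format("mutation outside site %s [%d, %d]",
                site$site_id, s, e)
  }
  minus <- as.character(GenomicRanges::strand(site)) == "-"
  keep_cols <- intersect(c("sample_id", "pos", "ref", "alt"),
                         names(mutations_in_site))
  mut <- unique(mutations_in_site[, keep_cols, drop = FALSE])
  column <- if (minus) e - mut$pos + 1L else mut$pos - s + 1L
  ref <- if (minus) COMPLEMENT[mut$ref] else mut$ref
  alt <- if (minus) COMPLEMENT[mut$alt] else mut$alt
  db <- vapply(seq_len(nrow(mut)), function(k) {
    delta_bit(motif, column[k], ref[k], alt[k], method = method)
  }, 0)
  per_mutation <- data.frame(pos = mut$pos, column = column,
                             ref = unname(ref), alt = unname(alt),
                             delta_bit = db, stringsAsFactors = FALSE)
  list(site_id = site$site_id, per_mutation = per_mutation,
       average_delta_bit = mean(db))
}

#' Resampled expectation of the average delta-bit
#'
#' Draws `n_draw` mutations from the pool of per-mutation delta-bit
#' values (all mutations falling in any TF binding site), averages them,
#' and repeats `n_reps` times; the mean over repetitions estimates the
#' expected average delta-bit of randomly chosen TFBS mutations.
#' Sampling is without replacement within a repetition and independent
#' across repetitions.
#'
#' @param tfbs_mutation_pool numeric vector of per-mutation delta-bit
#'   values, or a data.frame with a `delta_bit` column.
#' @param n_draw mutations per draw (default 100).
#' @param n_reps repetitions (default 1000).
#' @param seed RNG seed (mandatory).
#' @return `resample_null` object; `expected` is the mean of the per-rep
#'   averages, `observed` is the pool mean.
#' @export
expected_delta_bit_null <- function(tfbs_mutation_pool, n_draw = 100L,
                                    n_reps = 1000L, seed) {
  if (missing(seed) || is.null(seed)) stop_format("seed is mandatory")
  pool <- if (is.data.frame(tfbs_mutation_pool)) {
    tfbs_mutation_pool$delta_bit
  } else {
    as.numeric(tfbs_mutation_pool)
  }
  if (length(pool) < n_draw) {
    stop_format("pool (%d) smaller than n_draw (%d)", length(pool), n_draw)
  }
  values <- with_seed(seed, vapply(seq_len(n_reps), function(r) {
    mean(pool[sample.int(length(pool), n_draw)])
  }, 0))
  new_resample_null(values, observed = mean(pool), n_draw = n_draw,
                    n_reps = n_reps, seed = seed)
}
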