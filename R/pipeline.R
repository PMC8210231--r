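#' Run the full CNRM screening pipeline
#'
#' Applies the ten filtering criteria in their canonical order to a
#' two-cohort bundle, then runs the motif-impact and expression-association
#' analyses on the surviving binding sites:
#'
#' 1-4. source filters on cohort 1 (tissue, individual dedup, somatic
#'      confirmation, SNP flag);
#' 5.   exon exclusion;
#' 6.   recurrence (>= `min_samples` distinct samples) and cross-cancer-type
#'      recurrence (>= `min_cancer_types`);
#' 7.   position intersection with cohort 2;
#' 8.   open-chromatin peak containment;
#' 9.   chromatin-interaction anchor containment;
#' 10.  TF binding-site containment (score >= `jaspar_min_score`).
#'
#' Counts are recorded per stage in a funnel report (stages 1-5 count
#' mutation records, stages 6-10 count recurrent positions). Downstream,
#' every surviving site's average delta-bit is computed from all cohort-2
#' mutations inside the site, target genes are assigned through
#' interaction anchors, and target-gene expression is screened
#' (mutated vs wild-type z-scores, BH-adjusted).
#'
#' @param bundle list with `cosmic`, `tcga`, `genes`, `peaks`,
#'   `interactions`, `motifs`, `sites`, `expression`, `meta` (as produced
#'   by [generate_cohort()] or [read_cohort()]).
#' @param min_samples,min_cancer_types recurrence thresholds (defaults 2, 2).
#' @param jaspar_min_score site score threshold (default 400).
#' @param min_mutated,fdr_threshold,p_threshold expression-screen
#'   thresholds (defaults 5, 0.25, 0.1).
#' @param delta_bit_method delta-bit convention, see [delta_bit()].
#' @param out_dir optional output directory for TSV/JSON reports.
#' @return object of class `ncrm_run`: `funnel`, `cnrms` (final
#'   positions), `stages` (intermediate sets), `delta_bits`,
#'   `associations`, `site_mutations`, `targets`, `params`, `config_hash`.
#' @export
run_pipeline <- function(bundle,
                         min_samples = 2L, min_cancer_types = 2L,
                         jaspar_min_score = 400, min_mutated = 5L,
                         fdr_threshold = 0.25, p_threshold = 0.1,
                         delta_bit_method = "letter_height",
                         out_dir = NULL) {
  params <- list(min_samples = min_samples, min_cancer_types = min_cancer_types,
                 jaspar_min_score = jaspar_min_score, min_mutated = min_mutated,
                 fdr_threshold = fdr_threshold, p_threshold = p_threshold,
                 delta_bit_method = delta_bit_method)
  funnel <- list()
  note <- function(label, n_in, n_out, unit) {
    funnel[[length(funnel) + 1L]] <<- data.frame(
      step = length(funnel) + 1L, label = label, n_in = n_in, n_out = n_out,
      unit = unit, stringsAsFactors = FALSE)
  }

  src <- apply_source_filters(bundle$cosmic)
  for (i in seq_len(nrow(src$funnel))) {
    note(src$funnel$label[i], src$funnel$n_in[i], src$funnel$n_out[i],
         "mutations")
  }
  m5 <- remove_exonic(src$mutations, bundle$genes)
  note("remove_exonic", nrow(src$mutations), nrow(m5), "mutations")

  rec <- call_recurrent_positions(m5, min_samples = min_samples)
  note("recurrent_min_samples", nrow(m5), nrow(rec), "positions")
  rec_mt <- require_multi_cancer_type(rec, min_types = min_cancer_types)
  note("multi_cancer_type", nrow(rec), nrow(rec_mt), "positions")
  rec_c2 <- intersect_positions(rec_mt, bundle$tcga)
  note("in_second_cohort", nrow(rec_mt), nrow(rec_c2), "positions")

  s8 <- overlap_intervals(rec_c2, bundle$peaks)
  note("in_open_chromatin", nrow(rec_c2), nrow(s8$positions), "positions")
  s9 <- overlap_interaction_anchors(s8$positions, bundle$interactions)
  note("in_interaction_anchor", nrow(s8$positions), nrow(s9$positions),
       "positions")
  s10 <- overlap_tfbs(s9$positions, bundle$sites,
                      min_score = jaspar_min_score)
  note("in_tfbs", nrow(s9$positions), nrow(s10$positions), "positions")
  cnrms <- s10$positions

  ## downstream: sites carrying >= 1 CNRM
  surviving_site_ids <- unique(s10$site_positions$site_id)
  sites <- bundle$sites[bundle$sites$site_id %in% surviving_site_ids]
  site_mutations <- data.frame(site_id = character(), sample_id = character(),
                               stringsAsFactors = FALSE)
  delta_rows <- list()
  targets <- list()
  if (length(sites)) {
    hits <- quiet_overlaps(position_granges(bundle$tcga), sites)
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    if (length(qh)) {
      site_mutations <- unique(data.frame(
        site_id = sites$site_id[sh],
        sample_id = bundle$tcga$sample_id[qh], stringsAsFactors = FALSE))
    }
    for (k in seq_along(sites)) {
      site <- sites[k]
      muts <- bundle$tcga[qh[sh == k], , drop = FALSE]
      motif <- bundle$motifs[[site$motif_id]]
      if (nrow(muts) && !is.null(motif)) {
        res <- average_delta_bit(site, muts, motif,
                                 method = delta_bit_method)
        delta_rows[[length(delta_rows) + 1L]] <- data.frame(
          site_id = site$site_id, motif_id = site$motif_id,
          n_mutations = nrow(res$per_mutation),
          average_delta_bit = res$average_delta_bit, stringsAsFactors = FALSE)
      }
      targets[[site$site_id]] <- assign_target_genes(site,
                                                     bundle$interactions,
                                                     bundle$genes)
    }
  }
  delta_bits <- if (length(delta_rows)) do.call(rbind, delta_rows) else
    data.frame(site_id = character(), motif_id = character(),
               n_mutations = integer(), average_delta_bit = numeric(),
               stringsAsFactors = FALSE)

  z <- suppressWarnings(zscore_by_cancer_type(bundle$expression, bundle$meta))
  associations <- screen_tfbs_expression(site_mutations, z, targets,
                                         min_mutated = min_mutated,
                                         fdr_threshold = fdr_threshold,
                                         p_threshold = p_threshold)

  funnel <- do.call(rbind, funnel)
  run <- structure(list(
    funnel = funnel, cnrms = cnrms,
    stages = list(source_filtered = src$mutations, nonexonic = m5,
                  recurrent = rec, multi_type = rec_mt,
                  in_cohort2 = rec_c2, in_peaks = s8$positions,
                  in_anchors = s9$positions, cnrms = cnrms),
    site_mutations = site_mutations, targets = targets,
    delta_bits = delta_bits, associations = associations,
    params = params, config_hash = config_hash(params)),
    class = "ncrm_run")
  if (!is.null(out_dir)) write_run_outputs(run, out_dir)
  run
}

# Polynomial rolling hash of the deparsed parameter list; recorded in
# every output so identical settings are recognizable across runs.
config_hash <- function(params) {
  s <- paste(deparse(params), collapse = "")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' @export
print.ncrm_run <- function(x, ...) {
  cat("CNRM screening run (config", x$config_hash, ")\n")
  print(report_funnel(x$funnel))
  cat(sprintf("final CNRMs: %d; sites tested for expression: %d; significant: %d\n",
              nrow(x$cnrms), length(unique(x$associations$site_id)),
              sum(x$associations$significant, na.rm = TRUE)))
  invisible(x)
}

#' Render a funnel report with per-stage retention percentages
#'
#' @param funnel funnel data.frame (step, label, n_in, n_out).
#' @param path optional output path.
#' @param format `"tsv"` or `"json"` (used when `path` is given).
#' @return the funnel with a `retention_pct` column (percent of the
#'   stage's input retained, rounded to 0.1).
#' @export
report_funnel <- function(funnel, path = NULL, format = c("tsv", "json")) {
  format <- match.arg(format)
  out <- funnel
  out$retention_pct <- ifelse(out$n_in > 0,
                              round(100 * out$n_out / out$n_in, 1), NA_real_)
  if (!is.null(path)) {
    if (format == "tsv") {
      write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    } else {
      jsonlite::write_json(out, path, dataframe = "rows", digits = NA)
    }
  }
  out
}

write_run_outputs <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  hash_line <- paste0("# config_hash: ", run$config_hash)

  cn <- run$cnrms
  if (nrow(cn)) {
    cn_out <- data.frame(chrom = cn$chrom, pos = cn$pos,
                         recurrence = cn$recurrence,
                         n_cancer_types = cn$n_cancer_types,
                         consistency = cn$consistency,
                         six_class = cn$six_class,
                         samples = vapply(cn$samples, paste, "", collapse = ","),
                         stringsAsFactors = FALSE)
  } else {
    cn_out <- data.frame(chrom = character(), pos = integer(),
                         recurrence = integer(), n_cancer_types = integer(),
                         consistency = character(), six_class = character(),
                         samples = character())
  }
  writeLines(hash_line, p("cnrm_positions.tsv"))
  suppressWarnings(write.table(cn_out, p("cnrm_positions.tsv"), sep = "\t",
                               quote = FALSE, row.names = FALSE, append = TRUE))
  report_funnel(run$funnel, p("funnel.tsv"), "tsv")
  report_funnel(run$funnel, p("funnel.json"), "json")
  writeLines(hash_line, p("delta_bits.tsv"))
  suppressWarnings(write.table(run$delta_bits, p("delta_bits.tsv"), sep = "\t",
                               quote = FALSE, row.names = FALSE, append = TRUE))
  writeLines(hash_line, p("associations.tsv"))
  suppressWarnings(write.table(run$associations, p("associations.tsv"),
                               sep = "\t", quote = FALSE, row.names = FALSE,
                               append = TRUE))
  jsonlite::write_json(c(list(config_hash = run$config_hash), run$params),
                       p("run_config.json"), auto_unbox = TRUE)
  invisible(out_dir)
}

#' Run the pipeline from files on disk
#'
#' Thin wrapper: reads every input through the package's readers, then
#' calls [run_pipeline()].
#'
#' @param paths named list/vector of input paths: cosmic, tcga, gtf,
#'   peaks, interactions, motifs, sites, expression, metadata.
#' @param ... thresholds passed to [run_pipeline()].
#' @param out_dir optional report directory.
#' @return an `ncrm_run` object.
#' @export
run_pipeline_files <- function(paths, ..., out_dir = NULL) {
  need <- c("cosmic", "tcga", "gtf", "peaks", "interactions", "motifs",
            "sites", "expression", "metadata")
  missing <- setdiff(need, names(paths))
  if (length(missing)) {
    stop_format("missing input path(s): %s", paste(missing, collapse = ", "))
  }
  bundle <- list(
    cosmic = read_mutation_table(paths[["cosmic"]], "cosmic"),
    tcga = read_mutation_table(paths[["tcga"]], "simple"),
    genes = read_gtf_genes(paths[["gtf"]]),
    peaks = read_bed(paths[["peaks"]]),
    interactions = read_interactions(paths[["interactions"]]),
    motifs = read_jaspar_pfm(paths[["motifs"]]),
    sites = read_tfbs_sites(paths[["sites"]]),
    expression = read_expression_matrix(paths[["expression"]]),
    meta = read_sample_metadata(paths[["metadata"]]))
  run_pipeline(bundle, ..., out_dir = out_dir)
}
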