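#' Read a somatic mutation table
#'
#' Ingests a TSV of single-nucleotide somatic variants. Two dialects are
#' supported: `"simple"` (a WGS-call table with at least chrom, pos, ref,
#' alt, sample_id, optionally cancer_type) and `"cosmic"` (a curated
#' non-coding-variant table that additionally carries individual_id,
#' tissue_site, somatic_confirmed and snp_flagged, the fields the source
#' filters act on). Positions are 1-based, matching VCF/COSMIC convention.
#'
#' Records that are not single-base A/C/G/T substitutions (indels, MNVs,
#' ambiguity codes, ref == alt) are rejected, counted, and reported via the
#' `"n_rejected"` attribute and a message; they are never silently dropped.
#'
#' @param path path to a tab-separated file with a header line.
#' @param dialect `"simple"` or `"cosmic"`.
#' @return a `data.frame` of mutations with normalized chromosome names,
#'   integer `pos`, and (for the cosmic dialect) logical
#'   `somatic_confirmed` / `snp_flagged` columns. Attribute `n_rejected`
#'   carries the number of dropped records.
#' @export
read_mutation_table <- function(path, dialect = c("simple", "cosmic")) {
  dialect <- match.arg(dialect)
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("chrom", "pos", "ref", "alt", "sample_id")
  if (dialect == "cosmic") {
    required <- c(required, "individual_id", "cancer_type", "tissue_site",
                  "somatic_confirmed", "snp_flagged")
  }
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop_format("mutation table %s is missing mandatory column(s): %s",
                path, paste(missing, collapse = ", "))
  }
  validate_mutations(tab, source = path)
}

# Shared record-level validation: SNV-only contract, coordinate sanity.
validate_mutations <- function(tab, source = "mutations") {
  tab$chrom <- normalize_chrom(tab$chrom)
  tab$pos <- as.integer(tab$pos)
  tab$ref <- toupper(as.character(tab$ref))
  tab$alt <- toupper(as.character(tab$alt))
  if ("somatic_confirmed" %in% names(tab)) {
    tab$somatic_confirmed <- as.logical(tab$somatic_confirmed)
  }
  if ("snp_flagged" %in% names(tab)) {
    tab$snp_flagged <- as.logical(tab$snp_flagged)
  }
  ok <- tab$ref %in% BASES & tab$alt %in% BASES & tab$ref != tab$alt &
    !is.na(tab$pos) & tab$pos >= 1L
  n_rejected <- sum(!ok)
  if (n_rejected > 0) {
    message(sprintf("%s: rejected %d non-SNV or malformed record(s)",
                    source, n_rejected))
  }
  out <- tab[ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_rejected") <- n_rejected
  out
}

#' Write a mutation table (inverse of [read_mutation_table()])
#' @param mutations mutation data.frame.
#' @param path output TSV path.
#' @export
write_mutation_table <- function(mutations, path) {
  attr(mutations, "n_rejected") <- NULL
  write.table(mutations, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read intervals from a BED or narrowPeak file
#'
#' BED coordinates are 0-based half-open on disk; the returned
#' [GenomicRanges::GRanges] is 1-based closed, so the BED line
#' `chr1 99 100` becomes the single 1-based position 100.
#'
#' @param path BED3+ or 10-column narrowPeak file.
#' @return `GRanges`; `score` (and narrowPeak statistics columns) retained
#'   when present.
#' @export
read_bed <- function(path) {
  raw <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                    comment.char = "#")
  if (nrow(raw)) {
    bad <- which(as.numeric(raw[[3]]) <= as.numeric(raw[[2]]))
    if (length(bad)) {
      stop_format("%s: start >= end at line %d", path, bad[1])
    }
  }
  fmt <- if (ncol(raw) == 10) "narrowPeak" else "BED"
  if (fmt == "narrowPeak") {
    gr <- rtracklayer::import(path, format = "BED",
      extraCols = c(signalValue = "numeric", pValue = "numeric",
                    qValue = "numeric", peak = "integer"))
  } else {
    gr <- rtracklayer::import(path, format = "BED")
  }
  GenomeInfoDb::seqlevels(gr) <- normalize_chrom(GenomeInfoDb::seqlevels(gr))
  gr
}

#' Write intervals to BED (inverse of [read_bed()])
#' @param gr a `GRanges`.
#' @param path output path.
#' @export
write_bed <- function(gr, path) {
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read chromatin interaction anchor pairs
#'
#' Dialect: 8-column TSV `chrom_a start_a end_a chrom_b start_b end_b
#' cell_type method`, anchors 0-based half-open on disk (converted to
#' 1-based closed internally). Anchor order is preserved as read, but all
#' overlap queries in the package treat the two anchors symmetrically.
#'
#' @param path interaction TSV with header.
#' @return data.frame of class `chromatin_interactions` with 1-based closed
#'   anchor coordinates.
#' @export
read_interactions <- function(path) {
  known_methods <- c("3C", "4C", "5C", "Hi-C", "ChIA-PET", "Capture-C", "IM-PET")
  need <- c("chrom_a", "start_a", "end_a", "chrom_b", "start_b", "end_b",
            "cell_type", "method")
  empty <- as.data.frame(setNames(
    list(character(), integer(), integer(), character(), integer(), integer(),
         character(), character()), need))
  tab <- tryCatch(read.delim(path, stringsAsFactors = FALSE),
                  error = function(e) empty)
  if (nrow(tab) == 0 && ncol(tab) < length(need)) tab <- empty
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop_format("interaction table %s missing column(s): %s",
                path, paste(missing, collapse = ", "))
  }
  for (side in c("a", "b")) {
    ch <- paste0("chrom_", side); s <- paste0("start_", side); e <- paste0("end_", side)
    tab[[ch]] <- normalize_chrom(tab[[ch]])
    if (any(as.numeric(tab[[e]]) <= as.numeric(tab[[s]]))) {
      stop_format("%s: anchor_%s with start >= end", path, side)
    }
    tab[[s]] <- as.integer(tab[[s]]) + 1L  # to 1-based closed
    tab[[e]] <- as.integer(tab[[e]])
  }
  unknown <- setdiff(unique(tab$method), known_methods)
  if (length(unknown)) {
    warning(sprintf("%s: unknown interaction method(s) kept: %s",
                    path, paste(unknown, collapse = ", ")), call. = FALSE)
  }
  rownames(tab) <- NULL
  class(tab) <- c("chromatin_interactions", "data.frame")
  tab
}

#' Write interaction anchor pairs (inverse of [read_interactions()])
#' @param interactions `chromatin_interactions` data.frame.
#' @param path output TSV path.
#' @export
write_interactions <- function(interactions, path) {
  out <- as.data.frame(interactions)
  out$start_a <- out$start_a - 1L   # back to 0-based half-open
  out$start_b <- out$start_b - 1L
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extract one anchor set of an interaction table as a GRanges
#' @param interactions `chromatin_interactions` data.frame.
#' @param which `"a"` or `"b"`.
#' @return `GRanges` with an `interaction` index column.
#' @export
anchor_granges <- function(interactions, which = c("a", "b")) {
  which <- match.arg(which)
  ch <- interactions[[paste0("chrom_", which)]]
  s <- interactions[[paste0("start_", which)]]
  e <- interactions[[paste0("end_", which)]]
  gr <- GenomicRanges::GRanges(ch, IRanges::IRanges(s, e))
  gr$interaction <- seq_len(nrow(interactions))
  gr
}

#' Read JASPAR-format position frequency matrices
#'
#' Parses the JASPAR text PFM format: a `>ID NAME` header followed by four
#' rows of per-position counts, one per base, optionally wrapped in
#' `A [ ... ]` brackets. Counts are normalized per column to frequencies.
#'
#' @param path JASPAR PFM text file (may contain several motifs).
#' @return list of `motif_model` objects: `motif_id`, `name`, `length`,
#'   `freq` (4 x L frequency matrix, rows A/C/G/T, columns summing to 1),
#'   and the raw `counts`.
#' @export
read_jaspar_pfm <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  headers <- grep("^>", lines)
  if (!length(headers)) stop_format("%s: no '>' motif header found", path)
  bounds <- c(headers, length(lines) + 1L)
  motifs <- vector("list", length(headers))
  for (k in seq_along(headers)) {
    head_line <- sub("^>\\s*", "", lines[headers[k]])
    fields <- strsplit(trimws(head_line), "\\s+")[[1]]
    body <- lines[(headers[k] + 1L):(bounds[k + 1L] - 1L)]
    if (length(body) != 4L) {
      stop_format("%s: motif %s has %d count rows (expected 4)",
                  path, fields[1], length(body))
    }
    rows <- lapply(body, function(ln) {
      ln <- gsub("^[ACGTacgt]\\s*\\[|\\]", "", ln)
      vals <- as.numeric(strsplit(trimws(ln), "\\s+")[[1]])
      if (anyNA(vals)) stop_format("%s: non-numeric count in motif %s",
                                   path, fields[1])
      vals
    })
    lens <- lengths(rows)
    if (length(unique(lens)) != 1L) {
      stop_format("%s: unequal count-row lengths in motif %s", path, fields[1])
    }
    counts <- do.call(rbind, rows)
    rownames(counts) <- BASES
    if (any(counts < 0)) stop_format("%s: negative count in motif %s",
                                     path, fields[1])
    tot <- colSums(counts)
    if (any(tot == 0)) stop_format("%s: zero-total column in motif %s",
                                   path, fields[1])
    freq <- sweep(counts, 2, tot, "/")
    motifs[[k]] <- structure(
      list(motif_id = fields[1],
           name = if (length(fields) > 1) fields[2] else fields[1],
           length = ncol(freq), freq = freq, counts = counts),
      class = "motif_model")
  }
  names(motifs) <- vapply(motifs, `[[`, "", "motif_id")
  motifs
}

#' Write motifs in JASPAR PFM text format
#' @param motifs list of `motif_model` objects.
#' @param path output path.
#' @export
write_jaspar_pfm <- function(motifs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in motifs) {
    writeLines(sprintf(">%s %s", m$motif_id, m$name), con)
    counts <- if (!is.null(m$counts)) m$counts else round(m$freq * 100)
    for (b in BASES) {
      writeLines(sprintf("%s  [ %s ]", b,
                         paste(format(counts[b, ], trim = TRUE), collapse = " ")),
                 con)
    }
  }
  invisible(path)
}

#' Read gene models from an Ensembl-dialect GTF
#'
#' Builds one model per gene: strand-aware TSS (the 5'-most gene boundary),
#' gene span, and the exon union over all transcripts. GTF coordinates are
#' 1-based inclusive and are kept as such internally.
#'
#' @param path GTF with `gene` and `exon` features; `gene_id` attribute
#'   required, `gene_name` used when present.
#' @return object of class `gene_models`: `$genes` data.frame (gene_id,
#'   gene_name, chrom, strand, start, end, tss) and `$exons`, a named
#'   `GRangesList` of reduced exon unions (possibly empty per gene).
#' @export
read_gtf_genes <- function(path) {
  gtf <- rtracklayer::import(path, format = "gtf")
  GenomeInfoDb::seqlevels(gtf) <- normalize_chrom(GenomeInfoDb::seqlevels(gtf))
  genes_gr <- gtf[gtf$type == "gene"]
  exons_gr <- gtf[gtf$type == "exon"]
  if (!length(genes_gr)) stop_format("%s: no gene features", path)
  gene_id <- as.character(genes_gr$gene_id)
  gene_name <- if (!is.null(genes_gr$gene_name)) {
    ifelse(is.na(genes_gr$gene_name), gene_id, as.character(genes_gr$gene_name))
  } else gene_id
  strand <- as.character(GenomicRanges::strand(genes_gr))
  genes <- data.frame(
    gene_id = gene_id,
    gene_name = gene_name,
    chrom = as.character(GenomicRanges::seqnames(genes_gr)),
    strand = strand,
    start = GenomicRanges::start(genes_gr),
    end = GenomicRanges::end(genes_gr),
    tss = ifelse(strand == "-", GenomicRanges::end(genes_gr),
                 GenomicRanges::start(genes_gr)),
    stringsAsFactors = FALSE)
  ex_by_gene <- GenomicRanges::reduce(
    GenomicRanges::split(exons_gr, factor(as.character(exons_gr$gene_id),
                                          levels = genes$gene_id)))
  no_exon <- genes$gene_id[!(genes$gene_id %in% unique(exons_gr$gene_id))]
  if (length(no_exon)) {
    warning(sprintf("%s: gene(s) without exons kept with empty exon set: %s",
                    path, paste(no_exon, collapse = ", ")), call. = FALSE)
  }
  structure(list(genes = genes, exons = ex_by_gene), class = "gene_models")
}

# Pooled exon union across all genes, as one reduced GRanges.
exon_union <- function(genes) {
  GenomicRanges::reduce(unlist(genes$exons, use.names = FALSE))
}

#' Read an expression matrix (genes x samples TSV, first column gene_id)
#' @param path TSV path.
#' @return numeric matrix with gene rownames and sample colnames.
#' @export
read_expression_matrix <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  mat <- as.matrix(tab[, -1, drop = FALSE])
  mode(mat) <- "numeric"
  rownames(mat) <- tab[[1]]
  mat
}

#' Write an expression matrix (inverse of [read_expression_matrix()])
#' @param mat numeric matrix, gene rownames, sample colnames.
#' @param path output TSV path.
#' @export
write_expression_matrix <- function(mat, path) {
  out <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-sample metadata (sample_id, cancer_type)
#' @param path TSV path.
#' @return data.frame with sample_id and cancer_type.
#' @export
read_sample_metadata <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("sample_id", "cancer_type"), names(tab))
  if (length(missing)) {
    stop_format("metadata %s missing column(s): %s", path,
                paste(missing, collapse = ", "))
  }
  if (anyNA(tab$cancer_type) || any(!nzchar(tab$cancer_type))) {
    stop_format("metadata %s: missing cancer_type label(s)", path)
  }
  tab
}

#' Read predicted TFBS instances
#'
#' Dialect: TSV `chrom start end site_id motif_id score strand`,
#' 0-based half-open on disk (converted to 1-based closed).
#'
#' @param path TSV path with header.
#' @return `GRanges` with `site_id`, `motif_id`, `score` columns and strand.
#' @export
read_tfbs_sites <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "site_id", "motif_id", "score", "strand")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop_format("TFBS table %s missing column(s): %s", path,
                paste(missing, collapse = ", "))
  }
  if (any(tab$end <= tab$start)) stop_format("%s: site with start >= end", path)
  gr <- GenomicRanges::GRanges(
    normalize_chrom(tab$chrom),
    IRanges::IRanges(tab$start + 1L, tab$end),
    strand = tab$strand)
  gr$site_id <- tab$site_id
  gr$motif_id <- tab$motif_id
  gr$score <- tab$score
  gr
}

#' Write TFBS instances (inverse of [read_tfbs_sites()])
#' @param sites `GRanges` with site_id, motif_id, score.
#' @param path output TSV path.
#' @export
write_tfbs_sites <- function(sites, path) {
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(sites)),
    start = GenomicRanges::start(sites) - 1L,
    end = GenomicRanges::end(sites),
    site_id = sites$site_id,
    motif_id = sites$motif_id,
    score = sites$score,
    strand = as.character(GenomicRanges::strand(sites)),
    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Width-1 GRanges for a mutation table or recurrent-position table.
position_granges <- function(x) {
  GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$pos, x$pos))
}
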