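#' @importFrom stats median p.adjust rnorm runif sd setNames wilcox.test binom.test
#' @importFrom utils read.delim write.table
NULL

BASES <- c("A", "C", "G", "T")
COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")
SIX_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' Normalize chromosome names to "chrN" form
#'
#' Sources differ: COSMIC-style tables use bare names ("1", "X") while BED
#' and peak files use UCSC-style names ("chr1"). All readers funnel through
#' this so that every internal object shares one naming scheme.
#'
#' @param x character vector of chromosome names.
#' @return character vector with a "chr" prefix guaranteed.
#' @export
normalize_chrom <- function(x) {
  x <- as.character(x)
  bare <- !startsWith(x, "chr")
  x[bare] <- paste0("chr", x[bare])
  x
}

# Evaluate expr with a fixed RNG state, restoring the caller's state after.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

# Position key used wherever mutations are grouped or intersected by locus.
pos_key <- function(chrom, pos) paste(chrom, pos, sep = ":")

# findOverlaps/countOverlaps with the benign seqlevel-mismatch notice
# silenced: query and subject routinely see different chromosome sets
# (e.g. positions on a chromosome that carries no peaks).
quiet_overlaps <- function(query, subject) {
  withCallingHandlers(
    GenomicRanges::findOverlaps(query, subject),
    warning = function(w) {
      if (grepl("sequence levels", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
}

quiet_count <- function(query, subject) {
  withCallingHandlers(
    GenomicRanges::countOverlaps(query, subject),
    warning = function(w) {
      if (grepl("sequence levels", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
}

stop_format <- function(...) stop(sprintf(...), call. = FALSE)
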