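test_that("interval containment respects 1-based boundaries", {
  # BED [99,100) covers only 1-based 100; BED [100,200) starts at 101
  iv <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(100, 101), c(100, 200)))
  pos <- data.frame(chrom = "chr1", pos = 100L)
  res <- overlap_intervals(pos, iv[1])
  expect_equal(nrow(res$positions), 1L)
  res <- overlap_intervals(pos, iv[2])
  expect_equal(nrow(res$positions), 0L)
})

test_that("interval containment matches an exhaustive scan at scale", {
  set.seed(21)
  pos <- data.frame(chrom = sample(c("chr1", "chr2"), 1000, replace = TRUE),
                    pos = sample.int(5e4, 1000, replace = TRUE))
  st <- sample.int(5e4, 100)
  iv <- GenomicRanges::GRanges(sample(c("chr1", "chr2"), 100, replace = TRUE),
                               IRanges::IRanges(st, st + 500))
  res <- overlap_intervals(pos, iv)
  bf <- bf_contained(pos$chrom, pos$pos,
                     as.character(GenomicRanges::seqnames(iv)),
                     GenomicRanges::start(iv), GenomicRanges::end(iv))
  expect_equal(sort(paste(res$positions$chrom, res$positions$pos)),
               sort(paste(pos$chrom, pos$pos)[bf]))
  # every annotated containment is genuine
  for (i in seq_len(nrow(res$annotation))) {
    k <- res$annotation$interval[i]
    expect_true(as.character(GenomicRanges::seqnames(iv)[k]) ==
                  res$annotation$chrom[i] &&
                GenomicRanges::start(iv)[k] <= res$annotation$pos[i] &&
                GenomicRanges::end(iv)[k] >= res$annotation$pos[i])
  }
})

make_interactions <- function(ca, sa, ea, cb, sb, eb, method = "Hi-C") {
  x <- data.frame(chrom_a = ca, start_a = sa, end_a = ea,
                  chrom_b = cb, start_b = sb, end_b = eb,
                  cell_type = "test", method = method,
                  stringsAsFactors = FALSE)
  class(x) <- c("chromatin_interactions", "data.frame")
  x
}

test_that("anchor overlap treats the two anchors symmetrically", {
  ia <- make_interactions("chr1", 100, 200, "chr1", 900, 1000)
  in_b <- data.frame(chrom = "chr1", pos = 950L)
  in_neither <- data.frame(chrom = "chr1", pos = 500L)
  expect_equal(nrow(overlap_interaction_anchors(in_b, ia)$positions), 1L)
  expect_equal(overlap_interaction_anchors(in_b, ia)$matches$anchor, "b")
  expect_equal(nrow(overlap_interaction_anchors(in_neither, ia)$positions), 0L)

  set.seed(33)
  pos <- data.frame(chrom = "chr1", pos = sample.int(2000, 300))
  sa <- sample.int(2000, 20); sb <- sample.int(2000, 20)
  ia <- make_interactions("chr1", sa, sa + 60, "chr1", sb, sb + 60)
  res <- overlap_interaction_anchors(pos, ia)
  bf <- bf_contained(pos$chrom, pos$pos, rep("chr1", 40),
                     c(ia$start_a, ia$start_b), c(ia$end_a, ia$end_b))
  expect_setequal(res$positions$pos, pos$pos[bf])
})

test_that("TFBS overlap applies the score threshold and reports multiplicity", {
  sites <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(95, 98, 90),
                                                           c(104, 107, 99)),
                                  strand = "+")
  sites$site_id <- c("A", "B", "C")
  sites$motif_id <- "M1"
  sites$score <- c(450, 500, 399)

  pos <- data.frame(chrom = "chr1", pos = 100L)
  res <- overlap_tfbs(pos, sites)
  # one surviving position, two site records; sub-threshold site C ignored
  expect_equal(nrow(res$positions), 1L)
  expect_setequal(res$site_positions$site_id, c("A", "B"))

  only_low <- data.frame(chrom = "chr1", pos = 92L)
  expect_equal(nrow(overlap_tfbs(only_low, sites)$positions), 0L)

  set.seed(8)
  pos <- data.frame(chrom = "chr1", pos = sample.int(3000, 400))
  st <- sample.int(3000, 50)
  sites <- GenomicRanges::GRanges("chr1", IRanges::IRanges(st, st + 9),
                                  strand = "+")
  sites$site_id <- sprintf("S%02d", 1:50)
  sites$motif_id <- "M1"
  sites$score <- sample(c(350, 450), 50, replace = TRUE)
  res <- overlap_tfbs(pos, sites)
  bf_pairs <- character()
  for (i in seq_len(nrow(pos))) {
    for (j in which(sites$score >= 400)) {
      if (GenomicRanges::start(sites)[j] <= pos$pos[i] &&
          GenomicRanges::end(sites)[j] >= pos$pos[i]) {
        bf_pairs <- c(bf_pairs, paste(sites$site_id[j], pos$pos[i]))
      }
    }
  }
  expect_setequal(paste(res$site_positions$site_id, res$site_positions$pos),
                  unique(bf_pairs))
})

test_that("the three regulatory containment filters commute on the final set", {
  set.seed(55)
  pos <- data.frame(chrom = "chr1", pos = sample.int(5000, 500),
                    stringsAsFactors = FALSE)
  pk <- sample.int(5000, 30)
  peaks <- GenomicRanges::GRanges("chr1", IRanges::IRanges(pk, pk + 200))
  sa <- sample.int(5000, 15); sb <- sample.int(5000, 15)
  ia <- make_interactions("chr1", sa, sa + 300, "chr1", sb, sb + 300)
  st <- sample.int(5000, 40)
  sites <- GenomicRanges::GRanges("chr1", IRanges::IRanges(st, st + 9),
                                  strand = "+")
  sites$site_id <- sprintf("S%02d", 1:40); sites$motif_id <- "M1"
  sites$score <- 450

  apply_order <- function(order) {
    cur <- pos
    for (step in order) {
      cur <- switch(step,
        peaks = overlap_intervals(cur, peaks)$positions,
        anchors = overlap_interaction_anchors(cur, ia)$positions,
        tfbs = overlap_tfbs(cur, sites)$positions)
    }
    sort(cur$pos)
  }
  ref <- apply_order(c("peaks", "anchors", "tfbs"))
  expect_equal(apply_order(c("tfbs", "peaks", "anchors")), ref)
  expect_equal(apply_order(c("anchors", "tfbs", "peaks")), ref)
})

test_that("open-chromatin resampling null is deterministic with bounded p", {
  set.seed(2)
  bg <- make_mutations("chr1", sample.int(1e5, 2000),
                       sample_id = sprintf("S%04d", 1:2000))
  pk <- seq(1000, 99000, by = 2000)
  peaks <- GenomicRanges::GRanges("chr1", IRanges::IRanges(pk, pk + 160))
  obs <- bg[1:100, ]
  r1 <- resample_open_chromatin_fraction(bg, peaks, n_draw = 100,
                                         n_reps = 199, observed_set = obs,
                                         seed = 42)
  r2 <- resample_open_chromatin_fraction(bg, peaks, n_draw = 100,
                                         n_reps = 199, observed_set = obs,
                                         seed = 42)
  expect_identical(r1$values, r2$values)
  expect_equal(r1$expected, mean(r1$values), tolerance = 1e-12)
  expect_gte(r1$p_upper, 1 / 200)
  expect_lte(r1$p_upper, 1)
  expect_error(resample_open_chromatin_fraction(bg, peaks, n_draw = 5000,
                                                n_reps = 10, observed_set = obs,
                                                seed = 1), "exceeds")
})

test_that("a peak-only observed set maximizes enrichment significance", {
  set.seed(4)
  bg <- make_mutations("chr1", sample.int(1e5, 1500),
                       sample_id = sprintf("S%04d", 1:1500))
  pk <- seq(1000, 99000, by = 2000)
  peaks <- GenomicRanges::GRanges("chr1", IRanges::IRanges(pk, pk + 100))
  in_pk <- bf_contained(bg$chrom, bg$pos, rep("chr1", length(pk)), pk, pk + 100)
  obs <- bg[in_pk, ][1:30, ]
  r <- resample_open_chromatin_fraction(bg, peaks, n_draw = 200, n_reps = 199,
                                        observed_set = obs, seed = 5)
  expect_equal(r$observed, 1)
  expect_equal(r$p_upper, 1 / 200)

  # observed equal to every null value: two-sided p is 1
  all_in <- bg[in_pk, ]
  r2 <- resample_open_chromatin_fraction(all_in, peaks, n_draw = 50,
                                         n_reps = 99, observed_set = all_in,
                                         seed = 6)
  expect_equal(r2$p_two_sided, 1)
})

test_that("empirical p is calibrated when the observed set is a null draw", {
  # The in-peak fraction lives on a coarse lattice, so tied null values
  # make the (r+1)/(n+1) estimator conservative rather than exactly
  # uniform. Calibration is therefore checked two ways: validity
  # (P(p <= alpha) never exceeds alpha beyond Monte Carlo error) and
  # exchangeability of the observed draw among the null draws, which a
  # randomized tie-broken rank turns into an exactly uniform variate.
  set.seed(77)
  bg <- make_mutations("chr1", sample.int(1e5, 1200),
                       sample_id = sprintf("S%04d", 1:1200))
  pk <- seq(500, 99500, by = 1500)
  peaks <- GenomicRanges::GRanges("chr1", IRanges::IRanges(pk, pk + 120))
  n_iter <- 200
  pvals <- numeric(n_iter)
  u <- numeric(n_iter)
  for (i in seq_len(n_iter)) {
    obs <- bg[sample.int(nrow(bg), 50), ]
    r <- resample_open_chromatin_fraction(bg, peaks, n_draw = 50, n_reps = 99,
                                          observed_set = obs, seed = 1000 + i)
    pvals[i] <- r$p_upper
    n_greater <- sum(r$values > r$observed)
    n_tied <- sum(r$values == r$observed)
    u[i] <- (n_greater + stats::runif(1) * (n_tied + 1)) / (r$n_reps + 1)
  }
  for (alpha in c(0.05, 0.1, 0.25, 0.5)) {
    mc_se <- sqrt(alpha * (1 - alpha) / n_iter)
    expect_lte(mean(pvals <= alpha), alpha + 3 * mc_se)
  }
  ks <- stats::ks.test(u, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("per-peak mutation rates match direct counts and handle ties", {
  peaks <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(100, 500, 900),
                                                           c(200, 600, 1000)))
  mut <- make_mutations("chr1", c(150, 150, 160, 170, 180, 190, 550),
                        sample_id = paste0("S", 1:7))
  rec <- data.frame(chrom = "chr1", pos = 150L)
  res <- per_peak_mutation_rate(mut, peaks, n_samples = 3, rec)
  expect_equal(res$rates_with, 2)       # 6 mutations / 3 samples
  expect_equal(sort(res$rates_without), c(0, 1/3))

  # identical rate vectors in both partitions: p = 1
  mut2 <- make_mutations("chr1", c(150, 550, 950), sample_id = paste0("S", 1:3))
  res2 <- per_peak_mutation_rate(mut2, peaks, n_samples = 3, rec)
  expect_equal(res2$p, 1)

  # empty partition is flagged
  res3 <- per_peak_mutation_rate(mut, peaks, n_samples = 3,
                                 data.frame(chrom = "chr9", pos = 1L))
  expect_true(is.na(res3$p))
  expect_equal(res3$flag, "empty partition")
})
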