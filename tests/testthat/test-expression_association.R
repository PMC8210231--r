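make_ia <- function(ca, sa, ea, cb, sb, eb) {
  x <- data.frame(chrom_a = ca, start_a = sa, end_a = ea,
                  chrom_b = cb, start_b = sb, end_b = eb,
                  cell_type = "t", method = "Hi-C", stringsAsFactors = FALSE)
  class(x) <- c("chromatin_interactions", "data.frame")
  x
}

make_site <- function(chrom = "chr1", start = 3500, end = 3509, id = "S1") {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                               strand = "+")
  gr$site_id <- id; gr$motif_id <- "M1"; gr$score <- 500
  gr
}

test_that("target genes are assigned through either anchor orientation", {
  genes <- toy_two_genes()  # TSS at 1000 (+) and 6999 (-)
  site <- make_site()

  # anchor_a covers the site, anchor_b the GENE_A TSS
  ia <- make_ia("chr1", 3400, 3600, "chr1", 900, 1100)
  expect_equal(assign_target_genes(site, ia, genes), "GENE_A")
  # swapped orientation gives the same answer
  ia_sw <- make_ia("chr1", 900, 1100, "chr1", 3400, 3600)
  expect_equal(assign_target_genes(site, ia_sw, genes), "GENE_A")

  # site overlapping no anchor
  far <- make_ia("chr2", 1, 100, "chr2", 200, 300)
  expect_equal(assign_target_genes(site, far, genes), character())

  # two interactions to two genes: union, order-independent
  ia2 <- rbind(ia, make_ia("chr1", 3400, 3600, "chr1", 6900, 7100))
  class(ia2) <- c("chromatin_interactions", "data.frame")
  expect_equal(assign_target_genes(site, ia2, genes), c("GENE_A", "GENE_B"))
  ia2r <- ia2[2:1, ]
  class(ia2r) <- c("chromatin_interactions", "data.frame")
  expect_equal(assign_target_genes(site, ia2r, genes),
               assign_target_genes(site, ia2, genes))
})

test_that("target assignment equals a brute-force interaction scan", {
  set.seed(23)
  genes <- toy_two_genes()
  for (rep in 1:20) {
    sa <- sample.int(8000, 5); sb <- sample.int(8000, 5)
    ia <- make_ia("chr1", sa, sa + 400, "chr1", sb, sb + 400)
    st <- sample.int(8000, 1)
    site <- make_site(start = st, end = st + 9)
    expect_equal(assign_target_genes(site, ia, genes),
                 bf_targets("chr1", st, st + 9, ia, genes))
  }
})

test_that("z-scores standardize within cancer type and mask degenerate strata", {
  expr <- rbind(g1 = c(1, 2, 3, 10, 20, 30, 40),
                g2 = c(5, 5, 5, 1, 2, 3, 4))
  colnames(expr) <- paste0("s", 1:7)
  meta <- data.frame(sample_id = paste0("s", 1:7),
                     cancer_type = c(rep("A", 3), rep("B", 4)))
  z <- zscore_by_cancer_type(expr, meta)
  expect_equal(unname(z["g1", 1:3]), c(-1, 0, 1))       # sd = 1 stratum
  expect_true(all(is.na(z["g2", 1:3])))                  # constant stratum
  # each live stratum: mean 0, sample sd 1
  expect_equal(mean(z["g1", 4:7]), 0, tolerance = 1e-12)
  expect_equal(sd(z["g1", 4:7]), 1, tolerance = 1e-12)
  # pooled mean across independently standardized strata is ~0
  expect_equal(mean(z["g1", ]), 0, tolerance = 1e-12)

  meta1 <- data.frame(sample_id = paste0("s", 1:7),
                      cancer_type = c("A", rep("B", 6)))
  expect_warning(z1 <- zscore_by_cancer_type(expr, meta1), "masked")
  expect_true(is.na(z1["g1", 1]))
})

test_that("expression comparison matches exact permutation enumeration", {
  # the planted extreme case: all mutated below all wild-type (with ties)
  z <- matrix(c(-2, -2, -2, 1, 1, 1, 1), 1,
              dimnames = list("g", paste0("s", 1:7)))
  res <- compare_expression(z, "g", paste0("s", 1:3))
  p_bf <- bf_exact_wilcox(c(-2, -2, -2), c(1, 1, 1, 1))
  expect_equal(res$direction, -1)
  expect_lt(abs(res$p - p_bf), 0.02)

  # continuous data, both groups <= 8: exact path equals enumeration
  set.seed(41)
  for (rep in 1:10) {
    nx <- sample(3:8, 1); ny <- sample(3:8, 1)
    vals <- round(rnorm(nx + ny), 6)
    z <- matrix(vals, 1, dimnames = list("g", paste0("s", seq_along(vals))))
    res <- compare_expression(z, "g", paste0("s", seq_len(nx)))
    expect_equal(res$p, bf_exact_wilcox(vals[seq_len(nx)], vals[-seq_len(nx)]),
                 tolerance = 1e-12)
  }

  # identical groups: no signal
  z <- matrix(rep(c(1, 2, 3, 4), 2), 1,
              dimnames = list("g", paste0("s", 1:8)))
  expect_equal(compare_expression(z, "g", paste0("s", 1:4))$p, 1)

  # label swap: same p, opposite direction
  set.seed(42)
  vals <- rnorm(12)
  z <- matrix(vals, 1, dimnames = list("g", paste0("s", 1:12)))
  a <- compare_expression(z, "g", paste0("s", 1:5))
  b <- compare_expression(z, "g", paste0("s", 6:12))
  expect_equal(a$p, b$p, tolerance = 1e-12)
  expect_equal(a$direction, -b$direction)

  # empty group flagged
  none <- compare_expression(z, "g", character())
  expect_true(is.na(none$p))
  expect_equal(none$flag, "empty group")
})

test_that("BH adjustment reproduces the step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")

  set.seed(19)
  p <- runif(50)
  q <- bh_adjust(p)
  # monotone in sorted p
  expect_true(all(diff(q[order(p)]) >= -1e-15))
  expect_equal(q, bf_bh(p), tolerance = 1e-12)
})

test_that("the screen enforces the mutated-sample minimum and recovers planted pairs", {
  set.seed(53)
  n_samples <- 120
  genes <- sprintf("G%02d", 1:51)
  z <- matrix(rnorm(51 * n_samples), 51, n_samples,
              dimnames = list(genes, sprintf("s%03d", 1:n_samples)))
  mut <- sprintf("s%03d", 1:10)
  z["G01", mut] <- z["G01", mut] - 2          # planted 2 SD down-shift

  map <- data.frame(site_id = "SITE_T", sample_id = mut)
  targets <- list(SITE_T = genes)             # 1 true pair among 50 nulls
  res <- screen_tfbs_expression(map, z, targets)
  expect_equal(nrow(res), 51L)
  expect_equal(res$gene_id[which.min(res$p)], "G01")
  planted <- res[res$gene_id == "G01", ]
  expect_true(planted$significant)
  expect_equal(planted$direction, -1)
  expect_equal(planted$n_mutated, 10L)

  # a site with too few mutated samples is not tested
  map4 <- data.frame(site_id = "SITE_S", sample_id = sprintf("s%03d", 1:4))
  expect_equal(nrow(screen_tfbs_expression(map4, z, list(SITE_S = genes))), 0L)
})

test_that("neighbor specificity separates focal signal from null neighbors", {
  set.seed(71)
  genes <- c("FOCAL", paste0("N", 1:4))
  z <- matrix(rnorm(5 * 100), 5, 100,
              dimnames = list(genes, sprintf("s%03d", 1:100)))
  mut <- sprintf("s%03d", 1:10)
  z["FOCAL", mut] <- z["FOCAL", mut] - 3
  res <- neighbor_specificity("FOCAL", paste0("N", 1:4), z, mut)
  expect_equal(res$role, c("focal", rep("neighbor", 4)))
  expect_lt(res$p[1], 0.1)
  expect_true(all(res$p[-1] >= 0.1))

  # no neighbors: nothing but the focal row
  solo <- neighbor_specificity("FOCAL", character(), z, mut)
  expect_equal(nrow(solo[solo$role == "neighbor", ]), 0L)
})

test_that("neighbor p-values are uniform under the null", {
  set.seed(72)
  z <- matrix(rnorm(200 * 60), 200, 60,
              dimnames = list(sprintf("G%03d", 1:200), sprintf("s%02d", 1:60)))
  mut <- sprintf("s%02d", 1:12)
  p <- vapply(rownames(z), function(g) compare_expression(z, g, mut)$p, 0)
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("test sizes are calibrated at the reporting threshold", {
  set.seed(73)
  n_tests <- 400
  hits <- vapply(seq_len(n_tests), function(i) {
    vals <- rnorm(40)
    z <- matrix(vals, 1, dimnames = list("g", sprintf("s%02d", 1:40)))
    compare_expression(z, "g", sprintf("s%02d", 1:10))$p < 0.1
  }, TRUE)
  mc_se <- sqrt(0.1 * 0.9 / n_tests)
  expect_lt(abs(mean(hits) - 0.1), 3 * mc_se + 0.015)
})

test_that("nearest neighbors are picked by TSS distance on the same chromosome", {
  gdf <- data.frame(
    gene_id = paste0("G", 1:6), gene_name = paste0("G", 1:6),
    chrom = c(rep("chr1", 5), "chr2"), strand = "+",
    start = c(100, 2000, 5000, 9000, 20000, 50), end = c(1000, 3000, 6000,
                                                         10000, 21000, 950),
    tss = c(100, 2000, 5000, 9000, 20000, 50))
  gm <- make_gene_models(gdf, setNames(
    lapply(seq_len(6), function(i) GenomicRanges::GRanges(
      gdf$chrom[i], IRanges::IRanges(gdf$start[i], gdf$start[i] + 10))),
    gdf$gene_id))
  expect_equal(nearest_neighbor_genes(gm, "G2", k = 2), c("G1", "G3"))
  expect_equal(nearest_neighbor_genes(gm, "G2", k = 10), c("G1", "G3", "G4", "G5"))
  expect_error(nearest_neighbor_genes(gm, "NOPE"), "unknown gene")
})

test_that("the FDR null simulation is deterministic and detects planted power", {
  set.seed(81)
  z <- matrix(rnorm(150 * 50), 150, 50,
              dimnames = list(sprintf("G%03d", 1:150), sprintf("s%02d", 1:50)))
  r1 <- fdr_null_simulation(z, n_genes = 50, n_mut = 8, n_reps = 5, seed = 4)
  r2 <- fdr_null_simulation(z, n_genes = 50, n_mut = 8, n_reps = 5, seed = 4)
  expect_identical(r1$counts, r2$counts)

  # planted: 10% of genes strongly down in a fixed carrier set
  zp <- z
  carriers <- sprintf("s%02d", 1:10)
  shifted <- sprintf("G%03d", 1:15)
  zp[shifted, carriers] <- zp[shifted, carriers] - 3
  null_run <- fdr_null_simulation(z, n_genes = 150, n_mut = 10, n_reps = 5,
                                  seed = 7)
  power_run <- fdr_null_simulation(zp, n_genes = 150, n_mut = 10, n_reps = 5,
                                   seed = 7, mutated_samples = carriers)
  expect_gt(power_run$mean_discoveries, null_run$mean_discoveries + 5)

  expect_error(fdr_null_simulation(z, n_genes = 1000, n_mut = 8, n_reps = 2,
                                   seed = 1), "eligible")
  expect_error(fdr_null_simulation(z, n_genes = 50, n_mut = 50, n_reps = 2,
                                   seed = 1), "below the sample count")
})
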