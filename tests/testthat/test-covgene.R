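cov_records <- function(chrom, pos, alen = 150) {
  n <- length(pos)
  data.frame(qname = sprintf("c%d", seq_len(n)), rname = rep_len(chrom, n),
             pos = pos, strand = rep_len("+", n),
             score = rep_len(as.integer(alen), n), nm = rep_len(0L, n),
             aln_len = rep_len(as.integer(alen), n),
             clip_left = rep_len(0L, n), clip_right = rep_len(0L, n),
             n_best = rep_len(1L, n),
             ambiguous_placement = rep_len(FALSE, n),
             tie_refs = rep_len(chrom, n),
             partner_rname = rep_len(NA_character_, n),
             partner_pos = rep_len(NA_integer_, n),
             partner_len = rep_len(NA_integer_, n),
             partner_side = rep_len(NA_character_, n),
             mapped = rep_len(TRUE, n),              stringsAsFactors = FALSE)
}

test_that("gene breadth is the covered fraction of gene bases", {
  cl <- c(chr1A = 10000L)
  genes <- data.frame(chrom = "chr1A", start = 1000, end = 1300,
                      gene_id = "g1", stringsAsFactors = FALSE)
  full <- cov_records("chr1A", seq(900, 1300, by = 50))
  expect_equal(unname(gene_breadth(full, genes, cl)), 1.0)
  half <- cov_records("chr1A", 1075)  # 150 bp fully inside a 300 bp gene
  expect_equal(unname(gene_breadth(half, genes, cl)), 0.5)
  none <- cov_records("chr1A", integer(0))
  expect_equal(unname(gene_breadth(none, genes, cl)), 0.0)
  bad <- data.frame(chrom = "chr1A", start = 9000, end = 10500,
                    gene_id = "g2")
  expect_error(gene_breadth(full, bad, cl), "outside")
})

test_that("gene status calls follow the 20%/90% thresholds", {
  expect_equal(call_gene_status(0.15, 0.10), "lost")
  expect_equal(call_gene_status(0.15, 0.95), "within-HE")
  expect_equal(call_gene_status(0.99, 0.99), "present")
  expect_equal(call_gene_status(0.20, 0.0), "present")  # boundary: >= 0.20
  expect_equal(call_gene_status(0.199, 0.90), "lost")   # 0.90 not > 0.90
  # monotonicity: raising lost_thresh never shrinks the lost set
  set.seed(6)
  bs <- runif(200); bo <- runif(200)
  lost1 <- call_gene_status(bs, bo, pav_params(0.2, 0.9)) == "lost"
  lost2 <- call_gene_status(bs, bo, pav_params(0.4, 0.9)) == "lost"
  expect_true(all(lost2[lost1]))
})

test_that("core/dispensable sets partition the gene universe", {
  m <- matrix("present", 5, 3,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:3)))
  cd <- core_dispensable(m)
  expect_equal(length(cd$dispensable), 0)
  expect_setequal(cd$core, paste0("g", 1:5))
  m["g3", "s2"] <- "lost"
  cd2 <- core_dispensable(m)
  expect_equal(cd2$dispensable, "g3")
  expect_equal(length(cd2$core), 4)
  expect_setequal(c(cd2$core, cd2$dispensable), rownames(m))
  m[2, 3] <- NA
  expect_error(core_dispensable(m), "ragged")
})

test_that("depth profiles are median-normalized per window", {
  cl <- c(chr1A = 100000L)
  set.seed(14)
  pos <- sample(0:99850, 10000, TRUE)
  prof <- depth_profile(cov_records("chr1A", pos), cl, window = 10000)
  expect_equal(nrow(prof), 10)
  expect_true(all(abs(prof$norm_depth - 1) < 0.15))
  # deleted region: ~0; heterozygous deletion: ~0.5
  het_pool <- pos[pos >= 60000 & pos < 80000]
  pos2 <- c(pos[pos < 40000 | pos >= 80000],
            sample(het_pool, length(het_pool) %/% 2))
  prof2 <- depth_profile(cov_records("chr1A", sort(pos2)), cl,
                         window = 10000)
  expect_true(all(prof2$norm_depth[5:6] < 0.05))
  expect_true(all(abs(prof2$norm_depth[7:8] - 0.5) < 0.15))
  expect_error(depth_profile(cov_records("chr1A", 1L), integer(0)),
               "zero-length")
})

test_that("CNV segmentation recovers constructed copy states", {
  # constructed profile: 1.0 everywhere, one 200 kb 0.5x stretch,
  # one 150 kb 2x stretch
  win <- 10000
  nw <- 100
  nd <- rep(1, nw)
  nd[31:50] <- 0.5
  nd[71:85] <- 2
  set.seed(3)
  nd <- nd + rnorm(nw, 0, 0.04)
  prof <- data.frame(chrom = "chr1A", start = (0:(nw - 1)) * win,
                     end = (1:nw) * win, depth = nd * 30, norm_depth = nd)
  segs <- segment_cnv(prof, cnv_params(window = win))
  expect_equal(segs$state, c(1, 0.5, 1, 2, 1))
  expect_equal(segs$start[2], 300000)
  expect_equal(segs$end[2], 500000)
  expect_equal(segs$start[4], 700000)
  # flat profile: single state-1 segment covering the chromosome
  flat <- prof; flat$norm_depth <- 1 + rnorm(nw, 0, 0.03)
  sf <- segment_cnv(flat, cnv_params(window = win))
  expect_equal(nrow(sf), 1)
  expect_equal(sf$state, 1)
  expect_equal(sf$end, 1e6)
  # segments partition the chromosome, adjacent states differ
  expect_equal(segs$start[-1], segs$end[-nrow(segs)])
  expect_true(all(diff(segs$state) != 0))
})

test_that("split reads refine breakpoints to the modal clip position", {
  segs <- data.frame(chrom = "chr1A", start = c(0, 300000, 500000),
                     end = c(300000, 500000, 1000000),
                     state = c(1, 0, 1), mean_norm_depth = c(1, 0, 1),
                     bp_start_exact = NA_integer_,
                     bp_end_exact = NA_integer_, approximate = TRUE,
                     partner_chrom = NA_character_,
                     partner_pos = NA_integer_, stringsAsFactors = FALSE)
  # no split reads: unchanged and approximate
  plain <- cov_records("chr1A", c(1000L, 2000L))
  s0 <- refine_breakpoints(segs, plain)
  expect_true(all(s0$approximate))
  expect_true(all(is.na(s0$bp_start_exact)))
  # clips clustering at the true junction 302345 / partner at 498765
  n <- 6
  sp <- cov_records("chr1A", rep(302345L - 100L, n), alen = 100)
  sp$clip_right <- 50L
  sp$partner_rname <- "chr1A"
  sp$partner_pos <- 498765L
  sp$partner_len <- 50L
  sp$partner_side <- "R"
  s1 <- refine_breakpoints(segs, rbind(plain, sp))
  expect_equal(s1$bp_start_exact[2], 302345)
  # the remapped partner side pins the other junction too
  expect_equal(s1$bp_end_exact[2], 498765)
  expect_false(s1$approximate[2])
  expect_equal(s1$partner_chrom[2], "chr1A")
  # the partner recorded at a boundary is the junction's other side
  expect_equal(s1$partner_pos[2], 302345)
  # state-1 segments are never touched
  expect_true(is.na(s1$bp_start_exact[1]))
})

test_that("simulated PAV truth is recovered exactly", {
  bench <- he_bench()
  pp <- pav_pipeline(bench$samples, bench$study$truth$genes,
                     bench$chrom_lengths)
  pm <- pav_metrics(pp$status, bench$study$truth$pav_truth)
  expect_equal(pm$precision, 1.0)
  expect_equal(pm$recall, 1.0)
  # deleted genes are dispensable, everything else with full breadth core
  expect_true(all(bench$study$truth$pav_truth$gene_id %in%
                    pp$core_dispensable$dispensable))
})
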