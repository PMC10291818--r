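test_that("directional chi-square matches the closed form and chisq.test", {
  r <- chisq_equal(823, 385)
  expect_equal(r$statistic, (823 - 385)^2 / 1208, tolerance = 1e-12)
  expect_equal(r$statistic, 158.81, tolerance = 1e-3)
  expect_lt(r$p_value, 1e-30)
  expect_equal(r$direction, "B")  # A-to-B excess accumulates in B
  # independent route: stats::chisq.test goodness of fit
  ref <- stats::chisq.test(c(823, 385), p = c(0.5, 0.5))
  expect_equal(r$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(r$p_value, ref$p.value, tolerance = 1e-12)
  # balanced counts
  r0 <- chisq_equal(50, 50)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  expect_equal(r0$direction, "none")
  r2 <- chisq_equal(60, 40)
  expect_equal(r2$statistic, 4.0)
  expect_equal(r2$p_value, 0.0455, tolerance = 1e-3)
  # swap invariance with direction flip
  rs <- chisq_equal(385, 823)
  expect_equal(rs$statistic, r$statistic)
  expect_equal(rs$p_value, r$p_value)
  expect_equal(rs$direction, "A")
  # degenerate and small-count behavior
  expect_error(chisq_equal(0, 0), "zero")
  small <- chisq_equal(1, 5)
  expect_equal(small$method, "exact-binomial")
  expect_equal(small$p_value, stats::binom.test(1, 6, 0.5)$p.value)
})

test_that("integer percentages round half-up like the printed summaries", {
  expect_equal(proportion(823, 385), 68)
  expect_equal(proportion(847, 126), 87)
  expect_equal(proportion(1, 1), 50)
  expect_equal(proportion(1, 3), 25)
  expect_equal(proportion(125, 875), 13)  # 12.5 rounds up
  expect_error(proportion(0, 0), "zero")
  # unrounded shares always sum to exactly 100%
  set.seed(8)
  for (i in 1:20) {
    a <- sample(1e4, 1); b <- sample(1e4, 1)
    expect_equal(100 * a / (a + b) + 100 * b / (a + b), 100)
  }
})

test_that("homoeolog counting conserves assigned alignments", {
  genes <- data.frame(chrom = c("chr1A", "chr1B", "chr1A"),
                      start = c(1000, 1000, 5000),
                      end = c(2000, 2000, 6000),
                      gene_id = c("g1_A", "g1_B", "orphan_A"),
                      stringsAsFactors = FALSE)
  pm <- data.frame(pair_id = "g1", gene_A = "g1_A", gene_B = "g1_B",
                   stringsAsFactors = FALSE)
  mk <- function(chrom, pos, tag) {
    n <- length(pos)
    data.frame(qname = sprintf("h%d", seq_len(n)), rname = rep_len(chrom, n),
               pos = pos, strand = rep_len("+", n),
               score = rep_len(150L, n), nm = rep_len(0L, n),
               aln_len = rep_len(150L, n),
               clip_left = rep_len(0L, n), clip_right = rep_len(0L, n),
               n_best = rep_len(1L, n),
               ambiguous_placement = rep_len(FALSE, n),
               tie_refs = rep_len(chrom, n),
               partner_rname = rep_len(NA_character_, n),
               partner_pos = rep_len(NA_integer_, n),
               partner_len = rep_len(NA_integer_, n),
               partner_side = rep_len(NA_character_, n),
               mapped = rep_len(TRUE, n), origin_tag = rep_len(tag, n),
               stringsAsFactors = FALSE)
  }

  empty <- homoeolog_counts(mk("chr1A", integer(0), character(0)),
                            genes, pm)
  expect_equal(empty$matrix$count_a, 0L)
  expect_equal(empty$matrix$count_b, 0L)
  rec <- rbind(mk("chr1A", rep(1200L, 10), rep("A", 10)),
               mk("chr1B", rep(1300L, 30), rep("B", 30)),
               mk("chr1A", rep(5100L, 7), rep("A", 7)),    # unpaired gene
               mk("chr1A", rep(1250L, 5), rep("U", 5)))    # excluded
  hc <- homoeolog_counts(rec, genes, pm)
  expect_equal(hc$matrix$count_a, 10L)
  expect_equal(hc$matrix$count_b, 30L)
  expect_equal(unname(hc$unpaired["orphan_A"]), 7L)
  expect_equal(hc$n_assigned, 47L)  # every unambiguous alignment once
})

test_that("the genome-wide Wilcoxon matches an exact permutation oracle", {
  set.seed(17)
  for (rep in 1:5) {
    n <- sample(8:12, 1)
    repeat {  # draw until zero- and tie-free so the exact path applies
      cm <- data.frame(count_a = rpois(n, 40), count_b = rpois(n, 40))
      lr0 <- log2((cm$count_b + 0.5) / (cm$count_a + 0.5))
      if (all(lr0 != 0) && !anyDuplicated(abs(lr0))) break
    }
    res <- expression_bias_test(cm, min_total = 1, min_pairs = 5)
    lr <- log2((cm$count_b + 0.5) / (cm$count_a + 0.5))
    expect_equal(res$p_value[1], exact_signed_rank_p(lr),
                 tolerance = 1e-10)
  }
  # a single testable pair is an error
  expect_error(expression_bias_test(
    data.frame(count_a = 5, count_b = 50), min_total = 1), "testable")
})

test_that("expression bias detection has direction and power", {
  # 20% of 500 pairs shifted two-fold toward B
  set.seed(27)
  n <- 500
  base <- rnbinom(n, mu = 60, size = 5) + 1
  shift <- rep(c(2, 1), c(100, 400))
  cm <- data.frame(count_a = rpois(n, base),
                   count_b = rpois(n, base * shift),
                   chrom = rep(c("chr1", "chr2"), each = 250))
  res <- expression_bias_test(cm)
  expect_equal(res$scope[1], "genome")
  expect_equal(res$direction[1], "B")
  expect_lt(res$p_value[1], 0.01)
  expect_equal(nrow(res), 3)  # genome + two chromosome pairs
  # symmetric counts stay undetected at a fixed seed
  set.seed(37)
  cm0 <- data.frame(count_a = rpois(300, 50), count_b = rpois(300, 50))
  res0 <- expression_bias_test(cm0)
  expect_gt(res0$p_value[1], 0.05)
  expect_equal(res0$direction[1], "none")
})

test_that("origin-tagged reads from a balanced transcriptome split evenly", {
  bench <- he_bench()
  truth <- bench$study$truth
  hc <- homoeolog_counts(bench$ref$records, truth$genes,
                         truth$homoeolog_map)
  m <- hc$matrix[hc$matrix$count_a + hc$matrix$count_b >= 30, ]
  # genes inside HEs are legitimately one-sided; restrict to balanced loci
  frac <- m$count_a / (m$count_a + m$count_b)
  balanced <- frac > 0.1 & frac < 0.9
  expect_gt(mean(balanced), 0.85)
  expect_lt(abs(mean(frac[balanced]) - 0.5), 0.05)
})
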