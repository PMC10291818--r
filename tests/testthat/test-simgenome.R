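test_that("ancestor generation respects the size contract and determinism", {
  cfg <- sim_config(n_chromosomes = 1, chrom_length = 10000, n_genes = 5,
                    gene_length = 300, ltr_bursts = list(),
                    he_events = NULL, seed = 1)
  anc <- generate_ancestor(cfg)
  expect_equal(nchar(anc$seq[[1]]), 10000)
  expect_equal(nrow(anc$genes), 5)
  g <- anc$genes[order(anc$genes$start), ]
  expect_true(all(g$start[-1] >= g$end[-nrow(g)]))  # disjoint
  # phase-0 frames free of internal stops
  for (i in seq_len(nrow(g))) {
    cds <- substr0(anc$seq[[1]], g$start[i], 300)
    codons <- substring(cds, seq(1, 298, 3), seq(3, 300, 3))
    expect_false(any(codons[-100] %in% c("TAA", "TAG", "TGA")))
  }
  anc2 <- generate_ancestor(cfg)
  expect_identical(anc, anc2)
})

test_that("infeasible gene packing is rejected", {
  expect_error(sim_config(n_chromosomes = 1, chrom_length = 1000,
                          n_genes = 5, gene_length = 300,
                          he_events = NULL),
               "packing")
})

test_that("lineage evolution follows the Jukes-Cantor expectation", {
  set.seed(42)
  s <- paste(sample(c("A", "C", "G", "T"), 100000, TRUE), collapse = "")
  expect_identical(evolve_lineage(s, 0, 1e-8), s)
  expect_error(evolve_lineage(s, -1, 1e-8), "years")
  # branch length 0.065: expected mismatch (3/4)(1 - exp(-4/3 * 0.065))
  b <- 0.065
  e1 <- evolve_lineage(s, b / 2e-8, 2e-8)
  p <- mean(strsplit(s, "")[[1]] != strsplit(e1, "")[[1]])
  exp_p <- 0.75 * (1 - exp(-4 / 3 * b))
  se <- sqrt(exp_p * (1 - exp_p) / 100000)
  expect_lt(abs(p - exp_p), 3 * se)
  # saturation: long branch converges to 3/4 mismatch
  e2 <- evolve_lineage(substr(s, 1, 20000), 10 / 1e-8, 1e-8)
  p2 <- mean(strsplit(substr(s, 1, 20000), "")[[1]] !=
               strsplit(e2, "")[[1]])
  expect_lt(abs(p2 - 0.75), 3 * sqrt(0.75 * 0.25 / 20000))
})

test_that("gene-aware evolution never creates internal stops", {
  set.seed(9)
  cfg <- sim_config(n_chromosomes = 1, chrom_length = 20000, n_genes = 10,
                    gene_length = 900, ltr_bursts = list(),
                    he_events = NULL, seed = 5)
  anc <- generate_ancestor(cfg)
  g <- anc$genes
  ev <- evolve_lineage(anc$seq[[1]], 0.2 / 1e-8, 1e-8, genes = g)
  for (i in seq_len(nrow(g))) {
    cds <- substr0(ev, g$start[i], 900)
    codons <- substring(cds, seq(1, 898, 3), seq(3, 900, 3))
    expect_false(any(codons[-300] %in% c("TAA", "TAG", "TGA")))
  }
})

test_that("LTR bursts insert intact elements outside genes", {
  cfg <- sim_config(n_chromosomes = 1, chrom_length = 50000, n_genes = 10,
                    gene_length = 300, ltr_bursts = list(),
                    he_events = NULL, seed = 2)
  anc <- generate_ancestor(cfg)
  pa <- evolve_genome(anc, "A", 0, 1e-8, 0.2)
  burst0 <- list(role = "A", age = 0, n_copies = 5,
                 element_length = 2000, ltr_length = 500)
  g0 <- insert_ltr_burst(pa, burst0, 1.3e-8)
  lp <- ltr_repeat_pairs(g0)
  expect_equal(nrow(lp), 5)
  expect_identical(lp$repeat5, lp$repeat3)  # identical at insertion
  expect_true(all(g0$tes$age == 0))
  # aged burst: repeats diverge, K ~ 2 mu t
  g1 <- insert_ltr_burst(pa, modifyList(burst0, list(age = 5e5,
                                                     n_copies = 60)),
                         1.3e-8)
  lp1 <- ltr_repeat_pairs(g1)
  kk <- vapply(seq_len(nrow(lp1)), function(i)
    ltr_pair_divergence(lp1$repeat5[i], lp1$repeat3[i])$k, numeric(1))
  expect_lt(abs(mean(kk) / (2 * 1.3e-8 * 5e5) - 1), 0.25)
  # no insertion lands inside a gene (gene sequences unchanged)
  for (i in seq_len(nrow(g1$genes))) {
    expect_identical(
      substr0(g1$seq[[1]], g1$genes$start[i], 300),
      substr0(pa$seq[[1]], pa$genes$start[i], 300))
  }
})

test_that("tetraploid assembly applies HEs at the recorded coordinates", {
  cfg <- sim_config(chrom_length = 1e5, n_genes = 20,
                    ltr_bursts = list(), he_events = NULL, seed = 8)
  anc <- generate_ancestor(cfg)
  pa <- evolve_genome(anc, "A", cfg$t_div, cfg$mu, 0.2)
  pb <- evolve_genome(anc, "B", cfg$t_div, cfg$mu, 0.2)
  # no HE: plain union of parents
  t0 <- make_tetraploid(pa, pb, NULL)
  expect_identical(t0$seq, c(pa$seq, pb$seq))
  expect_equal(nrow(t0$genes), nrow(pa$genes) + nrow(pb$genes))
  # one 16 kb A -> B event
  he <- data.frame(chrom = "chr1", start = 30000, end = 46000,
                   donor = "A")
  tt <- make_tetraploid(pa, pb, he)
  ht <- tt$he_truth
  expect_equal(ht$end - ht$start, 16000)
  seg <- substr0(tt$seq[["chr1B"]], ht$start, 16000)
  expect_identical(seg, substr0(pa$seq[["chr1A"]], 30000, 16000))
  # identity contract: ~100% to donor, <= 1 - d to recipient parent
  rec_seg <- substr0(pb$seq[["chr1B"]], 30000, 16000)
  ident_b <- mean(strsplit(seg, "")[[1]] == strsplit(rec_seg, "")[[1]])
  expect_lt(ident_b, 1 - 0.03)
  # overlapping events rejected
  he2 <- rbind(he, data.frame(chrom = "chr1", start = 40000, end = 50000,
                              donor = "A"))
  expect_error(make_tetraploid(pa, pb, he2), "overlap")
})

test_that("sample variation edits haplotypes as specified", {
  cfg <- sim_config(chrom_length = 1e5, n_genes = 20, ltr_bursts = list(),
                    he_events = NULL, seed = 12)
  st <- simulate_study(cfg)
  truth <- st$truth
  s0 <- apply_sample_variation(truth, "plain")
  expect_identical(unname(s0$haplotypes[["chr1A_hap1"]]),
                   unname(truth$seq[["chr1A"]]))
  expect_identical(s0$haplotypes[["chr1A_hap1"]],
                   s0$haplotypes[["chr1A_hap2"]])
  # heterozygous deletion: exactly one haplotype loses the interval
  cnv <- data.frame(chrom = "chr1A", start = 20000, end = 30000,
                    copy_state = 0.5)
  s1 <- apply_sample_variation(truth, "het", cnv_events = cnv)
  expect_equal(nchar(s1$haplotypes[["chr1A_hap1"]]), 1e5)
  expect_equal(nchar(s1$haplotypes[["chr1A_hap2"]]), 9e4)
  # gene deletion removes the gene from both haplotypes
  gid <- truth$genes$gene_id[5]
  gseq <- gene_sequences(truth)[[gid]]
  s2 <- apply_sample_variation(truth, "del", pav_genes = gid)
  ch <- truth$genes$chrom[5]
  expect_false(grepl(gseq, s2$haplotypes[[paste0(ch, "_hap1")]],
                     fixed = TRUE))
  expect_false(grepl(gseq, s2$haplotypes[[paste0(ch, "_hap2")]],
                     fixed = TRUE))
  # overlapping CNVs rejected
  cnv2 <- rbind(cnv, data.frame(chrom = "chr1A", start = 25000,
                                end = 40000, copy_state = 2))
  expect_error(apply_sample_variation(truth, "bad", cnv_events = cnv2),
               "overlap")
})

test_that("read simulation honors the pair-count rule and error model", {
  seqs <- toy_genome(n = 1e6, n_chrom = 1)
  empty <- simulate_reads(seqs, 0)
  expect_equal(nrow(empty$r1), 0)
  set.seed(3)
  rd <- simulate_reads(seqs, 10, read_length = 150, insert_size = 350)
  expect_equal(nrow(rd$r1), 33333)  # round(10 * 1e6 / 300)
  expect_equal(nrow(rd$r2), 33333)
  expect_error(simulate_reads(seqs, 1, read_length = 150,
                              insert_size = 100), "insert")
  # error-free reads are exact (reverse-complemented) substrings
  pos <- as.integer(sub(".*\\|pos=([0-9]+).*", "\\1", rd$r1$name[1:50]))
  for (i in 1:50) {
    expect_identical(rd$r1$seq[i], substr0(seqs[[1]], pos[i], 150))
    expect_identical(rd$r2$seq[i],
                     revcomp(substr0(seqs[[1]], pos[i] + 200, 150)))
  }
  # stated error rate is realised (errors always change the base)
  set.seed(3)
  rd2 <- simulate_reads(seqs, 10, error_rate = 0.01)
  obs <- mean(vapply(1:2000, function(i) {
    p <- as.integer(sub(".*\\|pos=([0-9]+).*", "\\1", rd2$r1$name[i]))
    mean(strsplit(rd2$r1$seq[i], "")[[1]] !=
           strsplit(substr0(seqs[[1]], p, 150), "")[[1]])
  }, numeric(1)))
  expect_lt(abs(obs - 0.01), 0.002)
})

test_that("whole-study simulation is deterministic and conserves genes", {
  cfg <- sim_config(chrom_length = 1e5, n_genes = 20,
                    ltr_bursts = list(list(role = "A", age = 1e5,
                                           n_copies = 5,
                                           element_length = 1000,
                                           ltr_length = 300)),
                    seed = 77,
                    he_events = data.frame(
                      chrom = c("chr1", "chr2"),
                      start = c(30000, 50000), end = c(42000, 58000),
                      donor = c("A", "B")))
  st1 <- simulate_study(cfg, reads = TRUE)
  st2 <- simulate_study(cfg, reads = TRUE)
  expect_identical(st1$truth$seq, st2$truth$seq)
  expect_identical(st1$truth$he_truth, st2$truth$he_truth)
  expect_identical(st1$reads, st2$reads)
  expect_equal(nrow(st1$truth$genes),
               nrow(st1$parents$A$genes) + nrow(st1$parents$B$genes))
})

test_that("a simulated study round-trips through the standard formats", {
  cfg <- sim_config(chrom_length = 5e4, n_genes = 10,
                    ltr_bursts = list(list(role = "B", age = 2e5,
                                           n_copies = 3,
                                           element_length = 800,
                                           ltr_length = 200)),
                    he_events = data.frame(chrom = "chr1", start = 10000,
                                           end = 20000, donor = "A"),
                    depth = 2, seed = 4)
  st <- simulate_study(cfg, reads = TRUE)
  out <- file.path(tempdir(), "study_out")
  write_study(st, out)
  fa <- read_fasta(file.path(out, "tetraploid.fa"))
  expect_identical(fa, st$truth$seq)
  gf <- read_gff3(file.path(out, "tes.gff3"))
  expect_equal(nrow(gf), nrow(st$truth$tes))
  expect_true(all(as.numeric(gf$ltr_age) == 2e5))
  bed <- read_bed(file.path(out, "he_truth.bed"))
  expect_equal(bed$start, st$truth$he_truth$start)
  fq <- read_fastq(file.path(out, "reads_1.fastq"))
  expect_identical(fq$seq, st$reads$r1$seq)
  unlink(out, recursive = TRUE)
})
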