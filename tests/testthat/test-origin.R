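test_that("diagnostic variants come from mismatching columns only", {
  expect_equal(nrow(find_diagnostic_variants("ACGTACGTAC", "ACGTACGTAC")),
               0)
  v <- find_diagnostic_variants("ACGTACGTAC", "ACCTACGTAC")
  expect_equal(v$pos_a, 2)
  expect_equal(v$allele_a, "G")
  expect_equal(v$allele_b, "C")
  # columns within 2 bp of a gap are excluded (supplied alignment):
  # the column-12 mismatch sits 2 columns after the gap and is masked,
  # the column-19 mismatch survives
  a <- "AAAAAAA---CCCCCCCCCC"
  b <- "AAAAAAATTTCTCCCCCCAC"
  v2 <- find_diagnostic_variants(a, b, aligned = TRUE)
  expect_equal(nrow(v2), 1)
  expect_equal(v2$allele_a, "C")
  expect_equal(v2$allele_b, "A")
  expect_equal(v2$pos_a, 15)
  # non-homologous input is rejected
  set.seed(2)
  r1 <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  r2 <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  expect_error(find_diagnostic_variants(r1, r2), "identity")
})

test_that("anchor alignment recovers variants around an indel", {
  set.seed(15)
  base <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  a <- base
  # b: 3 bp deletion at 200 plus one substitution at 100
  bb <- strsplit(base, "")[[1]]
  bb[101] <- setdiff(c("A", "C", "G", "T"), bb[101])[1]
  b <- paste(c(bb[1:200], bb[204:400]), collapse = "")
  v <- find_diagnostic_variants(a, b)
  expect_true(100 %in% v$pos_a)
  expect_false(any(v$pos_a >= 198 & v$pos_a <= 205))
})

test_that("likelihood classification follows the stated model exactly", {
  v <- data.frame(pair_id = "p", pos_a = c(10, 20, 30),
                  pos_b = c(10, 20, 30),
                  allele_a = c("A", "C", "G"),
                  allele_b = c("T", "G", "A"), stringsAsFactors = FALSE)
  read <- paste(rep("N", 50), collapse = "")
  substr(read, 11, 11) <- "A"; substr(read, 21, 21) <- "C"
  substr(read, 31, 31) <- "G"
  cl <- classify_read_llr(read, 0, v)
  per_site <- log(0.99 / (0.01 / 3))
  expect_equal(cl$llr, 3 * per_site, tolerance = 1e-12)
  expect_equal(cl$llr, 17.0812, tolerance = 1e-4)
  expect_equal(cl$origin, "A")
  expect_equal(cl$n_sites, 3)
  # swapping the alleles negates the llr exactly
  v_sw <- v
  v_sw$allele_a <- v$allele_b; v_sw$allele_b <- v$allele_a
  cl_sw <- classify_read_llr(read, 0, v_sw)
  expect_equal(cl_sw$llr, -cl$llr)
  expect_equal(cl_sw$origin, "B")
  # no covered site: ambiguous with llr 0
  cl0 <- classify_read_llr(read, 1000, v)
  expect_equal(cl0$origin, "ambiguous")
  expect_equal(cl0$llr, 0)
  expect_equal(cl0$n_sites, 0)
})

test_that("label swap antisymmetry holds on random reads", {
  set.seed(44)
  a <- paste(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = "")
  b <- evolve_lineage(a, 0.05 / 1e-8, 1e-8)
  v <- find_diagnostic_variants(a, b)
  v_sw <- v
  v_sw$allele_a <- v$allele_b; v_sw$allele_b <- v$allele_a
  for (p in seq(0, 1800, by = 200)) {
    rd <- substr0(a, p, 150)
    expect_equal(classify_read_llr(rd, p, v_sw)$llr,
                 -classify_read_llr(rd, p, v)$llr)
  }
})

test_that("primary-mapping classification captures origin and HE signal", {
  cfg <- sim_config(chrom_length = 1e5, n_genes = 20, ltr_bursts = list(),
                    he_events = data.frame(chrom = "chr1", start = 40000,
                                           end = 60000, donor = "A"),
                    seed = 19)
  st <- simulate_study(cfg)
  ia <- build_index(st$parents$A$seq)
  ib <- build_index(st$parents$B$seq)
  # error-free read from a non-HE A region
  rd_a <- substr0(st$parents$A$seq[["chr2A"]], 10000, 150)
  expect_equal(classify_by_primary_mapping(rd_a, ia, ib)$origin, "A")
  # read from inside the A->B HE on the tetraploid B chromosome: the HE
  # signal is an A call on B-subgenome coordinates
  rd_he <- substr0(st$truth$seq[["chr1B"]], 50000, 150)
  expect_equal(classify_by_primary_mapping(rd_he, ia, ib)$origin, "A")
  # a region identical in both parents is ambiguous
  same <- paste(rep("ACGT", 100), collapse = "")
  ia2 <- build_index(c(chrA = paste0(st$parents$A$seq[[1]], same)))
  ib2 <- build_index(c(chrB = paste0(st$parents$B$seq[[1]], same)))
  rd_same <- substr(same, 1, 160)
  expect_equal(classify_by_primary_mapping(rd_same, ia2, ib2)$origin,
               "ambiguous")
})

test_that("tagging and re-mapping carries origin onto the tetraploid", {
  cfg <- sim_config(chrom_length = 5e4, n_genes = 10, ltr_bursts = list(),
                    he_events = NULL, seed = 23)
  st <- simulate_study(cfg)
  ia <- build_index(st$parents$A$seq)
  ib <- build_index(st$parents$B$seq)
  it <- build_index(st$truth$seq)
  set.seed(7)
  rd <- simulate_reads(st$parents$A$seq, depth = 1, error_rate = 0)
  reads <- combine_pairs(rd)
  calls <- classify_by_primary_mapping(reads, ia, ib)
  rec <- tag_and_remap(reads, calls, it)
  # every informative tag is A; reads from stretches that happen to be
  # identical between the parents are correctly ambiguous
  expect_true(all(rec$origin_tag[rec$mapped] %in% c("A", "U")))
  expect_gt(mean(rec$origin_tag[rec$mapped] == "A"), 0.98)
  # a missing origin call is an error
  expect_error(tag_and_remap(reads, calls[-1, ], it), "missing origin")
  # SAM round trip preserves the tags
  sam <- tempfile(fileext = ".sam")
  write_sam(rec, attr(it, "chrom_lengths"), sam)
  expect_identical(read_sam(sam)$origin_tag, rec$origin_tag)
  unlink(sam)
})

test_that("llr and primary-mapping strategies agree on clean reads", {
  cfg <- sim_config(chrom_length = 1e5, n_genes = 20, ltr_bursts = list(),
                    he_events = NULL, seed = 29)
  st <- simulate_study(cfg)
  a1 <- st$parents$A$seq[["chr1A"]]
  b1 <- st$parents$B$seq[["chr1B"]]
  v <- find_diagnostic_variants(a1, b1)
  set.seed(8)
  rd <- simulate_reads(c(st$parents$A$seq["chr1A"],
                         st$parents$B$seq["chr1B"]),
                       depth = 0.5, error_rate = 0)
  reads <- combine_pairs(rd)
  truth <- ifelse(grepl("origin=chr1A", reads$name), "A", "B")
  pos <- as.integer(sub(".*\\|pos=([0-9]+).*", "\\1", reads$name))
  pos <- ifelse(grepl("/2$", reads$name), pos + 200, pos)
  seqs <- ifelse(grepl("/2$", reads$name), revcomp(reads$seq), reads$seq)
  llr_calls <- vapply(seq_len(nrow(reads)), function(i)
    classify_read_llr(seqs[i], pos[i], v, on = truth[i])$origin,
    character(1))
  pm <- classify_by_primary_mapping(reads,
                                    build_index(st$parents$A$seq),
                                    build_index(st$parents$B$seq))
  both <- llr_calls != "ambiguous" & pm$origin %in% c("A", "B")
  expect_gt(mean(llr_calls[both] == pm$origin[both]), 0.95)
  # with >= 1 diagnostic site covered, llr calls are perfect
  sites <- vapply(seq_len(nrow(reads)), function(i)
    classify_read_llr(seqs[i], pos[i], v, on = truth[i])$n_sites,
    numeric(1))
  expect_true(all(llr_calls[sites >= 1] == truth[sites >= 1]))
})

test_that("llr accuracy is monotone in site density and error rate", {
  set.seed(55)
  base <- paste(sample(c("A", "C", "G", "T"), 100000, TRUE), collapse = "")
  acc <- matrix(NA_real_, 2, 2)
  for (di in 1:2) {
    dens <- c(0.005, 0.02)[di]
    b <- evolve_lineage(base, dens / 1e-8, 1e-8)
    v <- find_diagnostic_variants(base, b)
    set.seed(100 * di)
    clean <- simulate_reads(c(chrA = base), depth = 4, error_rate = 0)$r1
    pos <- as.integer(sub(".*\\|pos=([0-9]+).*", "\\1", clean$name))
    for (ei in 1:2) {
      err <- c(0, 0.1)[ei]
      seqs <- clean$seq
      if (err > 0) {  # corrupt the same read set
        set.seed(100 * di + ei)
        seqs <- vapply(seqs, function(s) {
          x <- strsplit(s, "")[[1]]
          flip <- runif(length(x)) < err
          x[flip] <- sample(c("A", "C", "G", "T"), sum(flip), TRUE)
          paste(x, collapse = "")
        }, character(1), USE.NAMES = FALSE)
      }
      calls <- vapply(seq_along(seqs), function(i)
        classify_read_llr(seqs[i], pos[i], v)$origin, character(1))
      acc[di, ei] <- mean(calls == "A")
    }
  }
  expect_true(all(acc[2, ] >= acc[1, ]))  # denser sites never hurt
  expect_true(all(acc[, 2] <= acc[, 1]))  # more error never helps
})

test_that("diagnostic variants export as minimal VCF", {
  v <- find_diagnostic_variants("ACGTACGTAC", "ACCTACGTAC")
  f <- tempfile(fileext = ".vcf")
  write_vcf(v, f, chrom = "chr1A")
  lines <- readLines(f)
  expect_true(any(grepl("^##fileformat=VCF", lines)))
  body <- lines[!startsWith(lines, "#")]
  expect_equal(length(body), 1)
  fields <- strsplit(body, "\t")[[1]]
  expect_equal(fields[1], "chr1A")
  expect_equal(as.integer(fields[2]), 3)  # 1-based POS
  expect_equal(fields[4], "G")
  expect_equal(fields[5], "C")
  unlink(f)
})
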