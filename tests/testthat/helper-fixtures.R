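# Shared fixtures. The read-based benchmark studies are expensive, so they
# are built lazily once per test run and cached for every file that needs
# them.

.cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.cache[[key]])) .cache[[key]] <- builder()
  .cache[[key]]
}

he_bench <- function() {
  cached("he_bench", function() {
    study <- study_he_pav(seed = 101)
    ia <- build_index(study$parents$A$seq)
    ib <- build_index(study$parents$B$seq)
    it <- build_index(study$truth$seq)
    ref <- origin_pipeline(combine_pairs(study$reads), ia, ib, it)
    samples <- lapply(seq_along(study$samples), function(i)
      map_sample(study$samples[[i]], study, ia, ib, it,
                 seed = 1000 + i)$records)
    names(samples) <- names(study$samples)
    list(study = study, ref = ref, samples = samples,
         chrom_lengths = attr(it, "chrom_lengths"))
  })
}

cnv_bench <- function() {
  cached("cnv_bench", function() {
    study <- study_cnv(seed = 202)
    ia <- build_index(study$parents$A$seq)
    ib <- build_index(study$parents$B$seq)
    it <- build_index(study$truth$seq)
    op <- map_sample(study$samples$cnv1, study, ia, ib, it, seed = 2000)
    list(study = study, op = op, chrom_lengths = attr(it, "chrom_lengths"))
  })
}

dating_bench <- function() {
  cached("dating_bench", function() study_dating(seed = 303))
}

# small fixed random genome for mapper unit tests
toy_genome <- function(n = 10000, n_chrom = 2, seed = 7) {
  set.seed(seed)
  stats::setNames(
    vapply(seq_len(n_chrom), function(i)
      paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
            collapse = ""), character(1)),
    paste0("chr", seq_len(n_chrom)))
}

substr0 <- function(s, start, len) substr(s, start + 1, start + len)
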