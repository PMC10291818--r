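# Canned synthetic study conditions. These are the package's reference
# benchmarks, used by the test suite and the reproduction script: a
# read-based HE + gene-loss study, a read-based CNV study, and a read-free
# molecular-dating study. Each is a pure function of its seed.

#' Synthetic HE + gene-loss study
#'
#' Two 1 Mb chromosomes per parent, ten HEs of 8-30 kb, 15x 150 bp paired
#' reads at 0.5% error for the reference individual, and three resequenced
#' samples carrying ten gene deletions in total. Deleted genes are drawn
#' away from HE-homologous loci: a deletion there would be masked by the
#' reads of the identical exchanged copy, as it would in real data.
#'
#' @param seed integer seed.
#' @return [simulate_study()] result (with `reads` for the reference).
#' @export
study_he_pav <- function(seed = 1) {
  cfg <- sim_config(chrom_length = 1e6, n_chromosomes = 2, n_genes = 200,
                    gene_length = 600, ltr_bursts = list(),
                    he_events = default_he_events(2, 1e6),
                    depth = 15, error_rate = 0.005, seed = seed)
  anc <- generate_ancestor(cfg)
  g <- anc$genes
  he <- cfg$he_events
  near_he <- rep(FALSE, nrow(g))
  for (i in seq_len(nrow(he))) {
    near_he <- near_he | (g$chrom == he$chrom[i] &
                            g$start < he$end[i] + 1000 &
                            g$end > he$start[i] - 1000)
  }
  cand <- g$gene_id[!near_he]
  pick <- cand[round(seq(5, length(cand) - 5, length.out = 10))]
  # alternate the deleted subgenome copy
  pick <- paste0(pick, "_", rep_len(c("A", "B"), 10))
  cfg$pav_deletions <- data.frame(
    sample = rep(c("s1", "s2", "s3"), c(4, 3, 3)),
    gene_id = pick, stringsAsFactors = FALSE)
  simulate_study(cfg, reads = TRUE)
}

#' Synthetic CNV study
#'
#' One resequenced sample carrying a homozygous deletion (0x), a
#' heterozygous deletion (0.5x) and a homozygous tandem duplication (2x),
#' each at least 200 kb, at coordinates deliberately off the analysis
#' window grid so breakpoint refinement is actually exercised.
#'
#' @param seed integer seed.
#' @return [simulate_study()] result.
#' @export
study_cnv <- function(seed = 1) {
  cnv <- data.frame(sample = "cnv1",
                    chrom = c("chr1A", "chr2A", "chr1B"),
                    start = c(312345, 403210, 507777),
                    end = c(515570, 621999, 709898),
                    copy_state = c(0, 0.5, 2),
                    stringsAsFactors = FALSE)
  cfg <- sim_config(chrom_length = 1e6, n_chromosomes = 2, n_genes = 200,
                    gene_length = 600, ltr_bursts = list(),
                    he_events = NULL, cnv_events = cnv,
                    depth = 15, error_rate = 0.005, seed = seed)
  simulate_study(cfg)
}

#' Synthetic molecular-dating study
#'
#' 240 homoeologous gene pairs of 1.2 kb diverged at synonymous Ks 0.065,
#' plus the default LTR bursts (340 ky in A, 50 ky in B; 150 copies each).
#' No reads: dating works from sequences and annotations.
#'
#' @param seed integer seed.
#' @return [simulate_study()] result.
#' @export
study_dating <- function(seed = 1) {
  cfg <- sim_config(chrom_length = 1e6, n_chromosomes = 2, n_genes = 240,
                    gene_length = 1200, he_events = NULL, depth = 0,
                    seed = seed)
  simulate_study(cfg)
}

#' Map one sample's reads through the origin pipeline
#'
#' Convenience wrapper used by the benchmarks: simulates reads from a
#' sample's haplotypes (half the nominal depth per haplotype set, i.e. the
#' nominal depth per reference position) and runs [origin_pipeline()].
#'
#' @param sample [apply_sample_variation()] result.
#' @param study the enclosing [simulate_study()] result.
#' @param index_a,index_b,index_t prebuilt indexes (parents, tetraploid).
#' @param seed seed for read simulation.
#' @return [origin_pipeline()] result.
#' @export
map_sample <- function(sample, study, index_a, index_b, index_t,
                       seed = 1) {
  set.seed(seed)
  cfg <- study$config
  rd <- simulate_reads(sample$haplotypes, cfg$depth / 2, cfg$read_length,
                       cfg$insert_size, cfg$error_rate,
                       prefix = paste0(sample$sample_id, "_r"))
  origin_pipeline(combine_pairs(rd), index_a, index_b, index_t)
}
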