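# polyhekit

Subgenome analysis for allotetraploid genomes whose two diploid
progenitors have also been sequenced. The package assigns each
sequencing read a parent of origin (A or B), paints the tetraploid
reference with those origins, and builds on that painting:

* **Homoeologous exchange (HE) detection** — runs of coordinates whose
  observed origin contradicts the chromosome's expected subgenome are
  called as exchange blocks, with read-extent boundary refinement and
  per-gene HE status (a gene is "within HE" at ≥ 50% overlap).
* **Gene presence/absence (PAV)** — breadth-of-coverage calls per gene
  and sample: breadth < 20% in the gene's own subgenome reads marks it
  absent; > 90% breadth by opposite-origin reads at the same locus
  re-classes it as a gene within an HE; statuses aggregate into core
  and dispensable gene sets.
* **Large CNVs** — windowed depth normalized by the genome-wide median
  is quantized to copy states {0, ½, 1, 1½, 2} (half-steps are
  haplotype-specific events), and soft-clipped split reads refine
  segment boundaries to base precision with a partner locus linking,
  e.g., a duplication to the region it copies.
* **Molecular dating** — Nei–Gojobori (1986) synonymous divergence for
  homoeologous coding pairs and Jukes–Cantor-corrected divergence
  between LTR terminal-repeat pairs, both converted to years by
  T = K / (2µ) (defaults: 5.76174 × 10⁻⁹ substitutions/synonymous
  site/year for Ks, 1.3 × 10⁻⁸ for LTRs), with kernel-density peak
  detection for divergence and burst-age distributions.
* **Bias statistics** — directional χ² against equal expectation
  ((a − b)²/(a + b), 1 df), rounded directional proportions, homoeolog
  count matrices from origin-tagged alignments, and the genome-wide
  Wilcoxon signed-rank test of homoeolog expression bias on per-pair
  log2 count ratios.

A deterministic synthetic allotetraploid generator (diverged parents,
LTR bursts of known age, HEs at known coordinates, per-sample gene
deletions and CNVs, paired-end reads) and a minimal exact-seed read
mapper make the entire pipeline runnable and testable offline; real
alignments enter through plain SAM.

## Worked example

Simulate a small allotetraploid (two 200 kb chromosomes per parent,
four HEs), classify its reads against the parents, and call the
exchanges:

```r
library(polyhekit)

cfg <- sim_config(chrom_length = 2e5, n_genes = 40, gene_length = 1200,
                  ltr_bursts = list(),
                  he_events = data.frame(
                    chrom = c("chr1", "chr1", "chr2", "chr2"),
                    start = c(50000, 120000, 60000, 140000),
                    end   = c(62000, 136000, 70000, 160000),
                    donor = c("A", "A", "B", "B")),
                  depth = 15, error_rate = 0.005, seed = 7)
study <- simulate_study(cfg, reads = TRUE)

pipe <- origin_pipeline(combine_pairs(study$reads),
                        study$parents$A$seq, study$parents$B$seq,
                        study$truth$seq)
table(pipe$calls$origin)
#>         A ambiguous         B
#>     40004       103     39893

he <- he_pipeline(pipe$records, pipe$chrom_lengths)
he$blocks[, c("chrom", "start", "end", "donor", "recipient",
              "supporting_reads")]
#>   chrom  start    end donor recipient supporting_reads
#> 3 chr1B  49952  62067     A         B             1172
#> 4 chr1B 119939 136060     A         B             1609
#> 1 chr2A  59918  70057     B         A             1068
#> 2 chr2A 139956 160080     B         A             1904
```

All four simulated exchanges (truth: chr1B 50000–62000 and
120000–136000 from A, chr2A 60000–70000 and 140000–160000 from B) are
recovered within ~100 bp of their true boundaries; ~0.1% of reads come
from stretches identical between the parents and stay unassigned.

Dating the parental split from the simulated homoeologous gene pairs:

```r
hm <- study$truth$homoeolog_map
ks <- ks_pairs(gene_sequences(study$parents$A)[hm$gene_A],
               gene_sequences(study$parents$B)[hm$gene_B])
round(ks_peak(ks$ks)$peak[1], 4)
#> [1] 0.0645
round(divergence_time(ks_peak(ks$ks)$peak[1], rate_constants()$mu_ks) / 1e6, 2)
#> [1] 5.6
```

The density peak sits at Ks ≈ 0.0645 (the generator's target is 0.065),
i.e. a split ~5.6 million years ago at the default synonymous rate.

Directional bias arithmetic works straight from counts — here, 823
A-origin genes found in the B subgenome against 385 the other way:

```r
chisq_equal(823, 385)
#>   statistic     p_value direction    n method context
#> 1  158.8113 2.05769e-36         B 1208  chisq
proportion(823, 385)
#> [1] 68
```

A thin command-line wrapper over the same functions is installed at
`inst/scripts/polyhekit` (subcommands `simulate`, `map`, `classify`,
`date`, `bias`).

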