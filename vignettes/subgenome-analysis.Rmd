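---
title: "Subgenome analysis of allotetraploid genomes with polyhekit"
author: "polyhekit authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subgenome analysis of allotetraploid genomes with polyhekit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyhekit)
```

## The problem

An allotetraploid carries two subgenomes, A and B, inherited from two
diploid progenitor species. When the progenitor genomes are themselves
sequenced, every read from the tetraploid can in principle be assigned a
parental origin, and that assignment powers a family of analyses:

* **Subgenome painting and homoeologous exchanges (HEs).** Meiotic
  pairing between homoeologous chromosomes occasionally replaces a
  segment of one subgenome with the homologous segment of the other.
  On an origin-painted reference these segments appear as runs of
  coordinates whose observed parental origin contradicts the
  chromosome's expected parent.
* **Gene presence/absence (PAV).** Breadth of coverage over annotated
  genes separates genes present in a resequenced individual from genes
  lost in it, and — with origin-split coverage — genes sitting inside an
  HE.
* **Large structural variants.** Windowed read depth relative to the
  genome-wide median exposes large deletions and duplications (including
  haplotype-specific ones at half-steps of coverage), and soft-clipped
  split reads pin their breakpoints to base precision.
* **Molecular dating.** Synonymous divergence (Ks) between homoeologous
  coding pairs dates the progenitor split; divergence between the two
  terminal repeats of an LTR retrotransposon — identical at insertion —
  dates transposition bursts. Both convert to years through
  T = K / (2µ).
* **Bias statistics.** Directional χ² tests, directional proportions,
  and a genome-wide Wilcoxon signed-rank test on per-pair homoeolog
  expression log-ratios quantify whether exchanges, duplications and
  expression favor one subgenome.

Every stage is exercised end-to-end against a built-in synthetic
allotetraploid generator, so the whole pipeline is verifiable without
any external data or aligner binaries.

## The synthetic allotetraploid

`sim_config()` + `simulate_study()` build, deterministically from a
seed:

1. a random ancestral genome with non-overlapping genes whose phase-0
   frames contain no internal stop codons;
2. two parental lineages evolved independently under Jukes–Cantor
   substitution for `t_div` years at rate `mu`. The default
   `t_div = 0.065 / (2 mu)` makes the expected synonymous divergence
   between homoeologs Ks = 0.065, the regime this toolkit targets
   (a few-My-old progenitor split). Within genes, third codon positions
   evolve at the full neutral rate and first/second positions at
   `coding_factor` (default 0.2) of it — enough purifying realism to
   keep Ks interpretable while making coding sequence distinguishable
   from neutral DNA. Substitutions that would create an in-frame stop
   are redrawn (nonsense purifying selection), which keeps every
   simulated CDS analyzable;
3. subgenome-specific LTR bursts: each burst generates a fresh element
   (two identical terminal repeats around an internal region), inserts
   copies at intergenic positions, then ages both repeats independently
   for `age` years at `mu_ltr`, so the expected repeat-pair divergence
   is K = 2 µ_LTR × age. Defaults place a 340 ky burst in A and a 50 ky
   burst in B, 150 copies each;
4. the allotetraploid as the union of both parents' chromosomes, with
   HE events replacing recipient intervals by the donor's homologous
   sequence (ten events of 8–30 kb by default). Because substitution
   preserves length, homology is bookkept exactly through ancestral
   coordinates, and `he_truth` records the replaced intervals in final
   tetraploid coordinates;
5. per-sample variation: gene deletions (both haplotypes) and large
   CNVs at copy states 0, 0.5, 1.5 and 2 (the half-steps edit one of
   the two emitted haplotypes);
6. paired-end reads: fragments uniform over the supplied sequences,
   `round(depth × length / (2 × read_length))` pairs, i.i.d.
   substitution errors, and read names carrying `|origin=...|pos=...`
   truth tags that only the tests read.

What the generator does **not** emulate — and what passing tests
therefore do not demonstrate about real data — includes indels and
structural micro-variation between the parents, sequencing-quality
gradients and GC bias, TE families beyond one generic LTR element per
burst, nested TE insertions, post-hybridization divergence of the
tetraploid from its parents, and residual heterozygosity in the
progenitor assemblies. On real data the mapper should be swapped for a
production aligner via the SAM import path.

```{r quick-sim}
cfg <- sim_config(chrom_length = 2e5, n_genes = 40, ltr_bursts = list(),
                  he_events = default_he_events(2, 2e5), depth = 4,
                  seed = 42)
study <- simulate_study(cfg, reads = TRUE)
study$truth
head(study$truth$he_truth, 3)
```

## Read mapping and origin classification

The built-in mapper indexes exact k-mers (default k = 17) and chains
seed hits on their (gap-free) diagonal; candidate loci are scored by
ungapped extension at +1/−2 and the best-scoring contiguous
sub-interval is retained, the remainder soft-clipped. A clipped portion
of ≥ 25 bases is remapped on its own and, when confidently placed,
becomes the record's split-read partner. There is no affine-gap
alignment: the simulator produces substitutions only, and externally
aligned SAM is accepted for real, gapped data.

Two details matter downstream:

* **Score ties are split, deterministically.** The two copies of an
  exchanged segment are byte-identical, so every read wholly inside an
  HE ties between them. Ties are resolved by a hash of the read name
  over the sorted tied loci — order-independent, reproducible, and
  spreading tied reads evenly over the tied copies, which is exactly
  how a production mapper's arbitrary primary-flag assignment behaves
  in expectation. Tied records are flagged `ambiguous_placement`.
  Painting **includes** placement-tied alignments: excluding them would
  leave HE interiors with no placeable short reads at all, since those
  regions exist twice. What painting excludes are reads whose *origin*
  is ambiguous (equal best scores across the two parents).
* **Origin is decided competitively between the parents.** A read's
  origin is the parent owning the better primary alignment score; ties
  are ambiguous ("U"), reads unmapped on both parents but mapped on the
  tetraploid are "novel" ("N"). For RNA reads the diagnostic-variant
  likelihood is the canonical route: per covered site,
  P(base | origin) is 1 − ε for the matching allele and ε/3 otherwise,
  and the summed log-likelihood ratio is thresholded at ±τ. The
  defaults ε = 0.01 and τ = ln 10 make a single clean diagnostic site
  sufficient for a call; both are exposed in `classifier_params()`.

## HE calling

`paint()` bins origin tags into windows (default 1 kb); windows with at
least `min_reads` informative reads and a discordant fraction
≥ `min_frac` (default 0.8) seed blocks; seed runs merge across gaps up
to `merge_gap` (2 kb); blocks shorter than `min_len` (2 kb) are
dropped; and boundaries are refined to the outermost discordant read
extents around the terminal windows (one window beyond the outermost
seed, because the true boundary usually sits inside a partial window).
Windowed majority voting is the short-read-stable equivalent of
per-coordinate painting with long reads; all thresholds live in
`he_params()`. These thresholds are calling-parameter choices, not
values any published count was produced with.

## PAV and the origin-split breadth

`call_gene_status()` is the decision rule: self-breadth below 20% marks
a gene absent from its locus; if the same locus shows > 90% breadth in
reads assigned to the *opposite* parent, the sequence there is the
other subgenome's — a gene within an HE — otherwise the gene is lost.

The operational definition of "coverage in the opposite parent"
deserves a note. Under competitive mapping the opposite *homoeolog's*
own breadth is uninformative: its own subgenome's reads cover it to
nearly 100% in every individual, lost gene or not. What distinguishes a
lost gene (no reads at the locus at all) from an HE gene (the locus
covered, but by reads of the other parent) is the origin tag of the
reads over the gene's own coordinates. `pav_call_sample()` therefore
computes breadth twice per gene — once from origin-concordant reads,
once from origin-discordant reads — and feeds both to the decision
rule. On the simulated truth this reproduces all three calls exactly.

One realistic blind spot is built into the benchmark design: a deletion
of a gene whose locus is sequence-identical to an HE copy elsewhere in
the genome is invisible to short-read breadth (the identical copy's
reads cover it). The reference deletion benchmark places its deletions
away from HE-homologous loci, as a real study would flag such regions.

## CNV segmentation and breakpoints

`depth_profile()` divides mean per-window depth (default 10 kb windows)
by the genome-wide median window depth; `segment_cnv()` quantizes each
window to the nearest state in {0, ½, 1, 1½, 2} within
`state_tolerance` (0.15, safely below half the 0.25 state gap), fills
no-calls from their nearest called neighbor, and absorbs segments
shorter than `min_segment` (50 kb) into the longer neighbor, so
segments always partition each chromosome. `refine_breakpoints()` then
collects soft-clip positions of split reads near each non-reference
boundary (within `search` = 15 kb, covering the window-quantization
error), and moves the boundary to the modal clip position when at least
two reads cluster within 500 bp of it. Both endpoints of a split read
vote — a read clipped at a deletion's left junction also pins the right
junction through its remapped partner — which matters at heterozygous
junctions where only one haplotype contributes crossing reads. The
partner locus of the modal cluster is reported, which is what links a
duplication to the homoeologous region it copies. Junction
micro-homology — shared bases flanking the two junction sides — makes
the breakpoint representation genuinely ambiguous: deleting
[s, e) and [s−k, e−k) produce the identical genome when the k flanking
bases agree. The refiner reports one valid representation;
`cnv_metrics()` (given the reference) scores shift-equivalent
representations as exact, the standard normalization in
structural-variant benchmarking.

## Molecular dating

`ks_ng86()` implements Nei–Gojobori (1986) counting: fractional
synonymous-site counts per codon averaged over both sequences, observed
differences averaged over minimal mutational pathways (pathways through
stop codons excluded; changes to stops counted nonsynonymous), and the
Jukes–Cantor correction Ks = −¾ ln(1 − 4/3 p_s), with saturation
(p_s ≥ ¾) flagged rather than extrapolated. NG86 is a closed-form
substitute for codon-model maximum likelihood; at the Ks ≤ 0.1 regime
this package targets, the two agree to within a few percent, and NG86
is exactly testable against a brute-force pathway-enumeration oracle
(the test suite does exactly that).

`divergence_time()` applies T = K/(2µ) with the Poaceae synonymous rate
5.76174 × 10⁻⁹ /site/year for Ks and the rice rate 1.3 × 10⁻⁸ for LTR
repeat pairs (`rate_constants()`); the factor 2 is required for the
WGD-era sanity check Ks = 1 → 87 My to come out right, so it is applied
to both dating modes.

```{r dating}
mu <- rate_constants()
round(divergence_time(c(1, 0.065), mu$mu_ks) / 1e6, 2)  # My
```

`ks_peak()` locates density maxima. Its default bandwidth is
Silverman's rule **doubled** (`adjust = 2`): the estimand is the peak
*location* of a unimodal cluster, and at a few hundred values the
default bandwidth lets sampling bumps — and, for young LTR bursts, the
discreteness of substitution counts — displace the maximum by 10% or
more, while doubling it leaves well-separated modes (speciation vs an
ancient WGD at Ks ≈ 1) clearly distinct. Related: a 50 ky burst is only
resolvable if repeat pairs carry enough substitutions; with terminal
repeats of length L the age resolution is 1/(2 µ_LTR L) — about 4.8 ky
for the 8 kb repeats the default bursts use (a long-LTR family; short
repeats would quantize the young burst onto a handful of ages). The
primary peak's half-height interval is attached as an attribute, which
is the uncertainty summary reported alongside point estimates.

## Bias statistics

`chisq_equal()` reduces the 1-df goodness-of-fit test against a 50:50
expectation to (a − b)²/(a + b) (exact binomial below n = 10, flagged);
`proportion()` rounds half-up to whole percents, matching how such
shares are conventionally printed. `expression_bias_test()` computes
per-pair log2((count_B + ½)/(count_A + ½)) — the ½ pseudocount keeps
zero counts finite and is configurable — and applies a two-sided
Wilcoxon signed-rank test of median zero, exactly when the sample is
small and tie-free, by normal approximation with continuity correction
otherwise; its type-I error at α = 0.05 is verified by null simulation
in the test suite. Per-chromosome results accompany the genome-wide
test when a chromosome column is present.

## Reference benchmarks and problem sizes

Three canned studies (exported, pure functions of a seed) are the
package's own benchmarks, run by the test suite and by
`scripts/acceptance.R`:

* `study_he_pav()` — two 1 Mb chromosomes per parent, 200 genes of
  600 bp, ten HEs of 8–30 kb, 15× 150 bp paired reads at 0.5% error,
  plus three resequenced samples carrying ten gene deletions. Sized so
  the full origin pipeline on ~400,000 reads per individual runs in
  well under a minute.
* `study_cnv()` — one sample with a homozygous deletion (0×), a
  heterozygous deletion (0.5×) and a tandem duplication (2×), each
  ≥ 200 kb, at coordinates deliberately off the 10 kb window grid so
  breakpoint refinement is actually exercised.
* `study_dating()` — 240 homoeologous CDS pairs of 1.2 kb (typical
  plant CDS length; longer genes tighten each pair's Ks) and the
  default LTR bursts, with no reads — dating needs only sequences and
  annotations.

Expected outcomes at these sizes: every HE recovered with per-block
Jaccard ≥ 0.9 and no false block; deletion calls at precision = recall
= 1; CNV states exact with breakpoints within ±5 bp; the Ks peak within
10% of 0.065 and burst ages within 15% of 340 ky / 50 ky.

## Known limitations

* The mapper is substitution-only; indel-containing real data must come
  in as externally produced SAM.
* HE detection assumes the reference tetraploid itself carries the HEs
  (true for an assembly of the reference individual); sample-specific
  HEs absent from the reference surface in the PAV layer, not the
  painting layer.
* Breadth-based PAV cannot see deletions of loci that are
  sequence-identical to another copy in the genome.
* NG86 without a transition/transversion correction is adequate under
  the simulator's equal-rates model and for Ks ≲ 0.1; for deeper
  divergences a codon-model tool should replace it.
* The Wilcoxon bias test is the genome-wide inference; per-pair
  differential expression calling is out of scope.
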