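# Synthetic allotetraploid generator. An ancestral diploid genome is evolved
# into two parental lineages (roles "A" and "B") under Jukes-Cantor
# substitution, each lineage receives subgenome-specific LTR bursts of known
# age, and the two parents are concatenated into an allotetraploid carrying
# homoeologous exchanges (HEs) at known coordinates. Per-sample gene
# deletions and CNVs, plus paired-end read simulation, complete the fixture.
#
# Coordinate bookkeeping: substitution never changes length, so the only
# length changes in a parent are LTR insertions. Each parent carries an
# `insertions` table in ancestral coordinates; ancestral positions map to
# parent positions by adding the lengths of all insertions at or before
# them. HE events are specified in ancestral coordinates, which makes the
# donor and recipient intervals of an event homologous by construction.

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Simulation configuration
#'
#' Bundles every knob of the synthetic allotetraploid study. Defaults are the
#' package's toy-scale study conditions: two 1 Mb chromosomes per parent,
#' 200 homoeologous gene pairs, parental divergence set so that synonymous
#' divergence Ks equals 0.065, subgenome-specific LTR bursts aged 340 ky (A)
#' and 50 ky (B), ten HEs of 8-30 kb, and 15x paired-end 150 bp reads with a
#' 0.5% per-base error rate.
#'
#' @param n_chromosomes chromosomes per parent.
#' @param chrom_length ancestral chromosome length in bases.
#' @param n_genes total genes across the genome (split evenly over
#'   chromosomes).
#' @param gene_length gene length in bases (multiple of 3).
#' @param mu substitution rate at neutral sites, substitutions/site/year.
#' @param coding_factor fraction of `mu` applying to first/second codon
#'   positions (third positions and intergenic sequence evolve at `mu`).
#' @param t_div parental divergence time in years; the default gives
#'   2 * mu * t_div = 0.065.
#' @param mu_ltr LTR-specific rate, substitutions/site/year.
#' @param ltr_bursts list of bursts, each a list with `role` ("A"/"B"),
#'   `age` (years), `n_copies`, `element_length`, `ltr_length` (bases).
#' @param he_events data.frame of HE events with columns `chrom` (ancestral
#'   name, e.g. "chr1"), `start`, `end` (ancestral 0-based half-open) and
#'   `donor` ("A" or "B"); the recipient is the opposite subgenome's copy.
#' @param pav_deletions data.frame with `sample` and `gene_id` (tetraploid
#'   gene instance, e.g. "chr1_g005_B").
#' @param cnv_events data.frame with `sample`, `chrom` (tetraploid name),
#'   `start`, `end`, `copy_state` (0, 0.5, 1.5 or 2).
#' @param read_length,insert_size read geometry in bases.
#' @param depth fold coverage of the sequenced genome.
#' @param error_rate per-base substitution error probability.
#' @param seed integer seed; the whole study is a pure function of the
#'   configuration.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes = 2,
                       chrom_length = 1e6,
                       n_genes = 200,
                       gene_length = 600,
                       mu = 5.76174e-9,
                       coding_factor = 0.2,
                       t_div = 0.065 / (2 * 5.76174e-9),
                       mu_ltr = 1.3e-8,
                       ltr_bursts = default_ltr_bursts(),
                       he_events = default_he_events(n_chromosomes,
                                                     chrom_length),
                       pav_deletions = NULL,
                       cnv_events = NULL,
                       read_length = 150,
                       insert_size = 350,
                       depth = 15,
                       error_rate = 0.005,
                       seed = 1) {
  cfg <- list(n_chromosomes = as.integer(n_chromosomes),
              chrom_length = as.integer(chrom_length),
              n_genes = as.integer(n_genes),
              gene_length = as.integer(gene_length),
              mu = mu, coding_factor = coding_factor, t_div = t_div,
              mu_ltr = mu_ltr, ltr_bursts = ltr_bursts,
              he_events = he_events, pav_deletions = pav_deletions,
              cnv_events = cnv_events,
              read_length = as.integer(read_length),
              insert_size = as.integer(insert_size),
              depth = depth, error_rate = error_rate,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$gene_length %% 3 == 0,
            cfg$depth >= 0,
            cfg$error_rate >= 0, cfg$error_rate < 1,
            cfg$t_div >= 0, cfg$mu > 0)
  if (cfg$n_chromosomes * cfg$chrom_length < cfg$n_genes * cfg$gene_length)
    stop("infeasible gene packing: ", cfg$n_genes, " genes of ",
         cfg$gene_length, " bp do not fit in the genome")
  he <- cfg$he_events
  if (!is.null(he) && nrow(he)) {
    stopifnot(all(he$donor %in% c("A", "B")),
              all(he$start >= 0), all(he$end > he$start),
              all(he$end <= cfg$chrom_length))
    for (key in unique(paste(he$chrom, he$donor))) {
      sub <- he[paste(he$chrom, he$donor) == key, , drop = FALSE]
      sub <- sub[order(sub$start), , drop = FALSE]
      if (nrow(sub) > 1 && any(sub$start[-1] < sub$end[-nrow(sub)]))
        stop("overlapping HE events on ", key)
    }
  }
  cnv <- cfg$cnv_events
  if (!is.null(cnv) && nrow(cnv)) {
    stopifnot(all(cnv$copy_state %in% c(0, 0.5, 1.5, 2)))
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_chromosomes, "chromosomes x", x$chrom_length,
      "bp per parent;", x$n_genes, "genes;",
      length(x$ltr_bursts), "LTR bursts;",
      if (is.null(x$he_events)) 0 else nrow(x$he_events), "HE events;",
      "depth", x$depth, "x; seed", x$seed, "\n")
  invisible(x)
}

#' Default LTR bursts (A subgenome aged 340 ky, B aged 50 ky)
#'
#' Long terminal repeats of 8 kb give the repeat-pair divergence counter an
#' age resolution of 1/(2 * mu_LTR * L), about 4.8 ky; a young 50 ky burst
#' is not resolvable with short repeats because repeat pairs then differ by
#' only zero to a few substitutions.
#'
#' @param n_copies copies per burst.
#' @return list of burst specifications.
#' @export
default_ltr_bursts <- function(n_copies = 150) {
  list(list(role = "A", age = 340e3, n_copies = n_copies,
            element_length = 17000, ltr_length = 8000),
       list(role = "B", age = 50e3, n_copies = n_copies,
            element_length = 17000, ltr_length = 8000))
}

#' Default HE events: ten exchanges of 8-30 kb
#'
#' A fixed, deterministic layout spread over the chromosomes with donors
#' alternating between subgenomes (lengths span the 8-30 kb range).
#'
#' @param n_chromosomes,chrom_length genome geometry (see [sim_config()]).
#' @return data.frame of HE events in ancestral coordinates.
#' @export
default_he_events <- function(n_chromosomes = 2, chrom_length = 1e6) {
  n <- 10
  len <- round(seq(8000, 30000, length.out = n))
  chrom <- paste0("chr", rep_len(seq_len(n_chromosomes), n))
  per <- ave(seq_len(n), chrom, FUN = seq_along)
  n_per <- ave(seq_len(n), chrom, FUN = length)
  start <- round(chrom_length * (per / (n_per + 1)))
  data.frame(chrom = chrom, start = start, end = start + len,
             donor = rep_len(c("A", "B"), n),
             stringsAsFactors = FALSE)
}

# ---- ancestor ----

#' Generate the ancestral diploid genome
#'
#' Uniform-random sequence with non-overlapping gene intervals whose
#' phase-0 reading frames contain no internal stop codons (gene bodies are
#' drawn codon-wise from the 61 sense codons). Deterministic for a fixed
#' `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return object of class `parental_genome` with `role = "ancestor"`.
#' @export
generate_ancestor <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  bases <- c("A", "C", "G", "T")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  sense <- setdiff(codons, STOP_CODONS)
  g_per <- cfg$n_genes / cfg$n_chromosomes
  if (g_per != round(g_per))
    stop("n_genes must be divisible by n_chromosomes")
  g_per <- as.integer(g_per)
  if (g_per * cfg$gene_length > cfg$chrom_length)
    stop("infeasible gene packing on a chromosome")
  seqs <- character(cfg$n_chromosomes)
  genes <- vector("list", cfg$n_chromosomes)
  for (ci in seq_len(cfg$n_chromosomes)) {
    chrom <- paste0("chr", ci)
    s <- sample(bases, cfg$chrom_length, replace = TRUE)
    # place genes: distribute the slack uniformly between ordered genes
    slack <- cfg$chrom_length - g_per * cfg$gene_length
    cuts <- sort(sample.int(slack + 1L, g_per, replace = TRUE)) - 1L
    starts <- cuts + (seq_len(g_per) - 1L) * cfg$gene_length
    for (gi in seq_len(g_per)) {
      cdn <- sample(sense, cfg$gene_length / 3, replace = TRUE)
      body <- strsplit(paste(cdn, collapse = ""), "")[[1]]
      s[(starts[gi] + 1):(starts[gi] + cfg$gene_length)] <- body
    }
    seqs[ci] <- paste(s, collapse = "")
    genes[[ci]] <- data.frame(
      chrom = chrom, start = starts, end = starts + cfg$gene_length,
      strand = "+",
      gene_id = sprintf("%s_g%03d", chrom, seq_len(g_per)),
      anc_start = starts, anc_end = starts + cfg$gene_length,
      stringsAsFactors = FALSE)
  }
  names(seqs) <- paste0("chr", seq_len(cfg$n_chromosomes))
  structure(list(role = "ancestor", seq = seqs,
                 genes = do.call(rbind, genes),
                 tes = empty_te_table(),
                 insertions = empty_insertion_table()),
            class = "parental_genome")
}

empty_te_table <- function() {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             te_id = character(0), ltr_length = integer(0),
             age = numeric(0), burst_role = character(0),
             anc_pos = integer(0), length = integer(0),
             stringsAsFactors = FALSE)
}

empty_insertion_table <- function() {
  data.frame(chrom = character(0), anc_pos = integer(0), length = integer(0),
             stringsAsFactors = FALSE)
}

#' @export
print.parental_genome <- function(x, ...) {
  cat("parental_genome (role ", x$role, "): ", length(x$seq),
      " chromosomes, ", sum(nchar(x$seq)), " bp, ", nrow(x$genes),
      " genes, ", nrow(x$tes), " TEs\n", sep = "")
  invisible(x)
}

# map ancestral coordinates to current coordinates given an insertion table
# (one chromosome). An insertion "at anc_pos u" sits between ancestral bases
# u-1 and u, so the ancestral base at u maps past it.
map_anc_pos <- function(pos, ins) {
  if (is.null(ins) || !nrow(ins)) return(pos)
  ins <- ins[order(ins$anc_pos), , drop = FALSE]
  shift <- c(0, cumsum(ins$length))
  pos + shift[findInterval(pos, ins$anc_pos) + 1L]
}

# strict variant for interval endpoints: an element inserted exactly at the
# start of an ancestral interval belongs to the interval, one at its end
# does not, matching the [start, end) annotation criterion
map_anc_boundary <- function(pos, ins) {
  if (is.null(ins) || !nrow(ins)) return(pos)
  ins <- ins[order(ins$anc_pos), , drop = FALSE]
  shift <- c(0, cumsum(ins$length))
  pos + shift[findInterval(pos - 0.5, ins$anc_pos) + 1L]
}

frame_vector <- function(len, genes) {
  fr <- integer(len)
  if (!is.null(genes) && nrow(genes)) {
    for (i in seq_len(nrow(genes))) {
      idx <- (genes$start[i] + 1):genes$end[i]
      fr[idx] <- rep_len(1:3, length(idx))
    }
  }
  fr
}

# ---- lineage evolution ----

#' Evolve a sequence forward under Jukes-Cantor substitution
#'
#' Substitution events arrive as a Poisson process at `rate` per site per
#' year; each event replaces the base by one of the other three, uniformly.
#' Inside `genes`, first/second codon positions evolve at
#' `coding_factor * rate` and substitutions that would create an in-frame
#' stop codon are redrawn (purifying selection against nonsense). Length is
#' always preserved. The expected observed mismatch fraction against the
#' input is (3/4)(1 - exp(-(4/3) * rate * years)).
#'
#' Uses the current R random number generator state; seed with
#' [set.seed()] for reproducibility.
#'
#' @param seq a single DNA string.
#' @param years branch length in years (>= 0).
#' @param rate substitutions/site/year at neutral sites.
#' @param genes optional data.frame with `start`, `end` (0-based half-open)
#'   delimiting plus-strand phase-0 coding intervals within `seq`.
#' @param coding_factor rate multiplier for first/second codon positions.
#' @return the evolved sequence.
#' @export
evolve_lineage <- function(seq, years, rate, genes = NULL,
                           coding_factor = 0.2) {
  if (years < 0) stop("years must be >= 0")
  stopifnot(length(seq) == 1)
  fr <- frame_vector(nchar(seq), genes)
  .ph_evolve(seq, years, rate, fr, coding_factor)
}

# evolve every chromosome of a genome and stamp its role
evolve_genome <- function(ancestor, role, years, rate, coding_factor) {
  g <- ancestor
  g$role <- role
  for (ci in seq_along(g$seq)) {
    chrom <- names(g$seq)[ci]
    gen <- g$genes[g$genes$chrom == chrom, , drop = FALSE]
    g$seq[ci] <- evolve_lineage(g$seq[[ci]], years, rate, gen, coding_factor)
  }
  # suffix chromosome and gene identity with the subgenome role
  names(g$seq) <- paste0(names(g$seq), role)
  g$genes$pair_id <- g$genes$gene_id
  g$genes$gene_id <- paste0(g$genes$gene_id, "_", role)
  g$genes$anc_chrom <- g$genes$chrom
  g$genes$chrom <- paste0(g$genes$chrom, role)
  g
}

# ---- LTR bursts ----

#' Insert a burst of LTR retrotransposon copies
#'
#' A fresh element (two identical terminal repeats flanking an internal
#' region) is generated for the burst, inserted at `n_copies` random
#' intergenic positions, and both terminal repeats of each copy are then
#' evolved independently for `age` years at `mu_ltr`, so the expected
#' repeat-pair divergence is K = 2 * mu_ltr * age. Repeats are identical at
#' insertion (age 0 leaves them identical). Annotations record the true age.
#'
#' @param genome a `parental_genome` (after role assignment).
#' @param burst list with `age`, `n_copies`, `element_length`, `ltr_length`.
#' @param mu_ltr substitutions/site/year within the terminal repeats.
#' @return the genome with elements inserted and annotations updated.
#' @export
insert_ltr_burst <- function(genome, burst, mu_ltr) {
  el_len <- as.integer(burst$element_length)
  ltr_len <- as.integer(burst$ltr_length)
  n <- as.integer(burst$n_copies)
  if (2 * ltr_len > el_len) stop("ltr_length too long for element_length")
  bases <- c("A", "C", "G", "T")
  ltr0 <- paste(sample(bases, ltr_len, replace = TRUE), collapse = "")
  internal <- paste(sample(bases, el_len - 2 * ltr_len, replace = TRUE),
                    collapse = "")
  # candidate ancestral positions: intergenic, distinct, away from existing
  # insertion points so elements never nest
  anc_names <- sub("[AB]$", "", names(genome$seq))
  per_chrom <- tabulate(sample.int(length(genome$seq), n, replace = TRUE),
                        nbins = length(genome$seq))
  new_rows <- list()
  for (ci in seq_along(genome$seq)) {
    if (per_chrom[ci] == 0) next
    anc_chrom <- anc_names[ci]
    anc_len <- nchar(genome$seq[[ci]]) -
      sum(genome$insertions$length[genome$insertions$chrom == anc_chrom])
    gen <- genome$genes[genome$genes$anc_chrom == anc_chrom, , drop = FALSE]
    used <- genome$insertions$anc_pos[genome$insertions$chrom == anc_chrom]
    ok <- rep(TRUE, anc_len + 1L)
    if (nrow(gen)) {
      for (i in seq_len(nrow(gen)))
        ok[(gen$anc_start[i] + 1):(gen$anc_end[i] + 1)] <- FALSE
    }
    if (length(used)) {
      for (u in used) ok[max(1, u - 9):min(anc_len + 1, u + 11)] <- FALSE
    }
    cand <- which(ok) - 1L
    if (length(cand) < per_chrom[ci])
      stop("element does not fit: no intergenic gap left on ", anc_chrom)
    pos <- sample(cand, per_chrom[ci])
    new_rows[[ci]] <- data.frame(chrom = anc_chrom, anc_pos = sort(pos),
                                 length = el_len, stringsAsFactors = FALSE)
  }
  new_ins <- do.call(rbind, new_rows)
  # materialise: splice elements into the current sequences, high to low
  te_rows <- list()
  for (ci in seq_along(genome$seq)) {
    anc_chrom <- anc_names[ci]
    rows <- new_ins[new_ins$chrom == anc_chrom, , drop = FALSE]
    if (!nrow(rows)) next
    ins_old <- genome$insertions[genome$insertions$chrom == anc_chrom, ,
                                 drop = FALSE]
    cur_pos <- map_anc_pos(rows$anc_pos, ins_old)
    s <- genome$seq[[ci]]
    ord <- order(cur_pos, decreasing = TRUE)
    for (i in ord) {
      l5 <- evolve_lineage(ltr0, burst$age, mu_ltr)
      l3 <- evolve_lineage(ltr0, burst$age, mu_ltr)
      element <- paste0(l5, internal, l3)
      s <- paste0(substr(s, 1, cur_pos[i]), element,
                  substr(s, cur_pos[i] + 1, nchar(s)))
    }
    genome$seq[ci] <- s
    te_rows[[ci]] <- data.frame(
      chrom = names(genome$seq)[ci], start = NA_integer_, end = NA_integer_,
      te_id = NA_character_,
      ltr_length = ltr_len, age = burst$age, burst_role = genome$role,
      anc_pos = rows$anc_pos, length = el_len, stringsAsFactors = FALSE)
  }
  new_tes <- do.call(rbind, te_rows)
  new_tes$te_id <- sprintf("te_%s_%04d", genome$role,
                           nrow(genome$tes) + seq_len(nrow(new_tes)))
  genome$insertions <- rbind(genome$insertions, new_ins)
  genome$tes <- rbind(genome$tes, new_tes)
  refresh_coordinates(genome)
}

# recompute current coordinates of genes and TEs from ancestral coordinates
refresh_coordinates <- function(genome) {
  anc_names <- sub("[AB]$", "", names(genome$seq))
  for (ci in seq_along(genome$seq)) {
    anc_chrom <- anc_names[ci]
    ins <- genome$insertions[genome$insertions$chrom == anc_chrom, ,
                             drop = FALSE]
    gi <- genome$genes$anc_chrom == anc_chrom
    if (any(gi)) {
      genome$genes$start[gi] <- map_anc_pos(genome$genes$anc_start[gi], ins)
      genome$genes$end[gi] <- genome$genes$start[gi] +
        (genome$genes$anc_end[gi] - genome$genes$anc_start[gi])
    }
    ti <- genome$tes$chrom == names(genome$seq)[ci]
    if (any(ti)) {
      ins_sorted <- ins[order(ins$anc_pos), , drop = FALSE]
      shift <- c(0, cumsum(ins_sorted$length))
      # a TE sits after all insertions strictly before it and, among
      # insertions at its own point, occupies the slot itself
      k <- findInterval(genome$tes$anc_pos[ti] - 0.5, ins_sorted$anc_pos)
      genome$tes$start[ti] <- genome$tes$anc_pos[ti] + shift[k + 1L]
      genome$tes$end[ti] <- genome$tes$start[ti] + genome$tes$length[ti]
    }
  }
  genome
}

# ---- tetraploid assembly ----

#' Assemble the allotetraploid and apply homoeologous exchanges
#'
#' The tetraploid is the union of the A and B chromosome copies. For each HE
#' event the recipient interval (the copy opposite the donor) is replaced by
#' the donor's homologous sequence; `he_truth` records the exact replaced
#' intervals in final tetraploid coordinates. Gene and TE annotations are
#' lifted, with features inside an HE taken from the donor.
#'
#' @param parent_a,parent_b `parental_genome` objects with roles "A"/"B".
#' @param he_events data.frame as in [sim_config()] (ancestral coordinates);
#'   `NULL` for none.
#' @return object of class `tetraploid_truth`.
#' @export
make_tetraploid <- function(parent_a, parent_b, he_events = NULL) {
  stopifnot(parent_a$role == "A", parent_b$role == "B")
  parents <- list(A = parent_a, B = parent_b)
  seqs <- c(parent_a$seq, parent_b$seq)
  genes <- rbind(parent_a$genes, parent_b$genes)
  genes$subgenome <- sub("^.*([AB])$", "\\1", genes$chrom)
  tes <- rbind(parent_a$tes, parent_b$tes)
  he_truth <- data.frame(chrom = character(0), start = integer(0),
                         end = integer(0), donor = character(0),
                         stringsAsFactors = FALSE)
  if (!is.null(he_events) && nrow(he_events)) {
    he <- he_events
    he$recipient <- ifelse(he$donor == "A", "B", "A")
    for (rc in unique(paste0(he$chrom, he$recipient))) {
      sub <- he[paste0(he$chrom, he$recipient) == rc, , drop = FALSE]
      sub <- sub[order(sub$start), , drop = FALSE]
      if (nrow(sub) > 1 && any(sub$start[-1] < sub$end[-nrow(sub)]))
        stop("overlapping HE events on recipient ", rc)
      anc_chrom <- sub$chrom[1]
      r_role <- sub$recipient[1]
      d_role <- sub$donor[1]
      rec <- parents[[r_role]]
      don <- parents[[d_role]]
      ins_r <- rec$insertions[rec$insertions$chrom == anc_chrom, ,
                              drop = FALSE]
      ins_d <- don$insertions[don$insertions$chrom == anc_chrom, ,
                              drop = FALSE]
      r_start <- map_anc_boundary(sub$start, ins_r)
      r_end <- map_anc_boundary(sub$end, ins_r)
      d_start <- map_anc_boundary(sub$start, ins_d)
      d_end <- map_anc_boundary(sub$end, ins_d)
      d_chrom <- paste0(anc_chrom, d_role)
      s <- seqs[[rc]]
      for (i in order(sub$start, decreasing = TRUE)) {
        # donor sequence always comes from the untouched parental genome
        donor_seg <- substr(don$seq[[d_chrom]], d_start[i] + 1, d_end[i])
        s <- paste0(substr(s, 1, r_start[i]), donor_seg,
                    substr(s, r_end[i] + 1, nchar(s)))
      }
      seqs[rc] <- s
      # final coordinates: cumulative length changes from earlier events
      d_len <- d_end - d_start
      r_len <- r_end - r_start
      delta_before <- c(0, cumsum(d_len - r_len))[seq_len(nrow(sub))]
      t_start <- r_start + delta_before
      t_end <- t_start + d_len
      he_truth <- rbind(he_truth, data.frame(
        chrom = rc, start = t_start, end = t_end, donor = d_role,
        stringsAsFactors = FALSE))
      # lift annotations on the recipient chromosome
      lift <- function(pos, anc_pos) {
        out <- pos
        hit_any <- rep(FALSE, length(pos))
        for (i in seq_len(nrow(sub))) {
          hit <- !is.na(anc_pos) & anc_pos >= sub$start[i] &
            anc_pos < sub$end[i]
          out[hit] <- t_start[i] +
            (map_anc_pos(anc_pos[hit], ins_d) - d_start[i])
          hit_any <- hit_any | hit
        }
        plain <- !hit_any
        if (any(plain)) {
          k <- findInterval(pos[plain], r_end + 1e-9) + 1L
          out[plain] <- pos[plain] + c(0, cumsum(d_len - r_len))[k]
        }
        out
      }
      gi <- genes$chrom == rc
      if (any(gi)) {
        glen <- genes$end[gi] - genes$start[gi]
        genes$start[gi] <- lift(genes$start[gi], genes$anc_start[gi])
        genes$end[gi] <- genes$start[gi] + glen
      }
      # TEs: drop recipient TEs inside the exchanged intervals, bring in the
      # donor's (they carry the donor's true insertion ages)
      ti <- which(tes$chrom == rc)
      if (length(ti)) {
        drop <- rep(FALSE, length(ti))
        for (i in seq_len(nrow(sub)))
          drop <- drop | (tes$anc_pos[ti] >= sub$start[i] &
                          tes$anc_pos[ti] < sub$end[i])
        if (any(drop)) tes <- tes[-ti[drop], , drop = FALSE]
        ti <- which(tes$chrom == rc)
        if (length(ti)) {
          k <- findInterval(tes$start[ti], r_end + 1e-9) + 1L
          sh <- c(0, cumsum(d_len - r_len))[k]
          tes$start[ti] <- tes$start[ti] + sh
          tes$end[ti] <- tes$end[ti] + sh
        }
        dti <- which(tes$chrom == d_chrom)
        for (i in seq_len(nrow(sub))) {
          hit <- dti[tes$anc_pos[dti] >= sub$start[i] &
                     tes$anc_pos[dti] < sub$end[i]]
          if (length(hit)) {
            moved <- tes[hit, , drop = FALSE]
            off <- t_start[i] - d_start[i]
            moved$chrom <- rc
            moved$start <- moved$start + off
            moved$end <- moved$end + off
            moved$te_id <- paste0(moved$te_id, "_he")
            tes <- rbind(tes, moved)
          }
        }
      }
    }
  }
  expected <- stats::setNames(sub("^.*([AB])$", "\\1", names(seqs)),
                              names(seqs))
  hm <- merge(
    parent_a$genes[c("pair_id", "gene_id", "chrom")],
    parent_b$genes[c("pair_id", "gene_id", "chrom")],
    by = "pair_id", suffixes = c("_A", "_B"))
  names(hm)[names(hm) == "gene_id_A"] <- "gene_A"
  names(hm)[names(hm) == "gene_id_B"] <- "gene_B"
  structure(list(seq = seqs, genes = genes, tes = tes,
                 he_truth = he_truth, expected_origin = expected,
                 homoeolog_map = hm,
                 pav_truth = NULL, cnv_truth = NULL),
            class = "tetraploid_truth")
}

#' @export
print.tetraploid_truth <- function(x, ...) {
  cat("tetraploid_truth: ", length(x$seq), " chromosomes, ",
      sum(nchar(x$seq)), " bp, ", nrow(x$genes), " genes, ",
      nrow(x$tes), " TEs, ", nrow(x$he_truth), " HE blocks\n", sep = "")
  invisible(x)
}

# ---- per-sample variation ----

#' Apply per-sample gene deletions and CNVs
#'
#' Emits the sample genome as two haplotype sequences per chromosome. Gene
#' deletions remove the gene interval from both haplotypes. CNV copy states:
#' 0 deletes the interval from both haplotypes, 0.5 from one; 2 tandem-
#' duplicates it in both haplotypes, 1.5 in one.
#'
#' @param truth a `tetraploid_truth`.
#' @param sample_id sample label.
#' @param pav_genes character vector of tetraploid gene instance ids to
#'   delete (e.g. "chr1_g005_B").
#' @param cnv_events data.frame with `chrom` (tetraploid name), `start`,
#'   `end` (reference coordinates), `copy_state` in {0, 0.5, 1.5, 2}.
#' @return list with `sample_id`, `haplotypes` (named sequences, two per
#'   chromosome), `pav_truth`, `cnv_truth`.
#' @export
apply_sample_variation <- function(truth, sample_id, pav_genes = NULL,
                                   cnv_events = NULL) {
  edits <- list()
  if (!is.null(pav_genes) && length(pav_genes)) {
    gi <- match(pav_genes, truth$genes$gene_id)
    if (anyNA(gi)) stop("unknown gene id(s): ",
                        paste(pav_genes[is.na(gi)], collapse = ", "))
    edits[[1]] <- data.frame(chrom = truth$genes$chrom[gi],
                             start = truth$genes$start[gi],
                             end = truth$genes$end[gi],
                             copy_state = 0, stringsAsFactors = FALSE)
  }
  if (!is.null(cnv_events) && nrow(cnv_events)) {
    stopifnot(all(cnv_events$copy_state %in% c(0, 0.5, 1.5, 2)))
    for (ch in unique(cnv_events$chrom)) {
      sub <- cnv_events[cnv_events$chrom == ch, , drop = FALSE]
      sub <- sub[order(sub$start), , drop = FALSE]
      if (nrow(sub) > 1 && any(sub$start[-1] < sub$end[-nrow(sub)]))
        stop("overlapping CNV events on ", ch, " in sample ", sample_id)
    }
    edits[[length(edits) + 1]] <-
      cnv_events[c("chrom", "start", "end", "copy_state")]
  }
  ed <- if (length(edits)) do.call(rbind, edits) else NULL
  haps <- character(0)
  for (ch in names(truth$seq)) {
    h1 <- h2 <- truth$seq[[ch]]
    if (!is.null(ed)) {
      sub <- ed[ed$chrom == ch, , drop = FALSE]
      for (i in order(sub$start, decreasing = TRUE)) {
        st <- sub$start[i]; en <- sub$end[i]; cs <- sub$copy_state[i]
        cut <- function(s) paste0(substr(s, 1, st), substr(s, en + 1,
                                                           nchar(s)))
        dup <- function(s) paste0(substr(s, 1, en),
                                  substr(s, st + 1, en),
                                  substr(s, en + 1, nchar(s)))
        if (cs == 0) { h1 <- cut(h1); h2 <- cut(h2) }
        else if (cs == 0.5) h2 <- cut(h2)
        else if (cs == 1.5) h1 <- dup(h1)
        else if (cs == 2) { h1 <- dup(h1); h2 <- dup(h2) }
      }
    }
    haps[paste0(ch, "_hap1")] <- h1
    haps[paste0(ch, "_hap2")] <- h2
  }
  pav_truth <- if (!is.null(pav_genes) && length(pav_genes))
    data.frame(sample = sample_id, gene_id = pav_genes, status = "deleted",
               stringsAsFactors = FALSE) else NULL
  cnv_truth <- if (!is.null(cnv_events) && nrow(cnv_events))
    cbind(sample = sample_id,
          cnv_events[c("chrom", "start", "end", "copy_state")]) else NULL
  list(sample_id = sample_id, haplotypes = haps,
       pav_truth = pav_truth, cnv_truth = cnv_truth)
}

# ---- read simulation ----

#' Simulate paired-end reads
#'
#' Fragments are uniform over the supplied sequences; the number of pairs is
#' `round(depth * total_length / (2 * read_length))`. Errors are i.i.d.
#' substitutions. Read names carry `|origin=<chrom>|pos=<start>` truth tags,
#' a test-only convention that the analysis modules ignore.
#'
#' Uses the current RNG state; seed with [set.seed()].
#'
#' @param seqs named character vector (a genome or a pair of haplotype
#'   sets; coverage is spread over everything supplied).
#' @param depth fold coverage of the supplied sequences.
#' @param read_length,insert_size read geometry; `insert_size` must be >=
#'   `read_length`.
#' @param error_rate per-base substitution error probability.
#' @param prefix read-name prefix.
#' @return list with data.frames `r1` and `r2` (columns `name`, `seq`).
#' @export
simulate_reads <- function(seqs, depth, read_length = 150,
                           insert_size = 350, error_rate = 0,
                           prefix = "r") {
  if (insert_size < read_length) stop("insert_size < read_length")
  if (depth < 0) stop("depth must be >= 0")
  if (depth == 0 || sum(nchar(seqs)) == 0) {
    empty <- data.frame(name = character(0), seq = character(0),
                        stringsAsFactors = FALSE)
    return(list(r1 = empty, r2 = empty))
  }
  out <- .ph_sim_reads(seqs, depth, as.integer(read_length),
                       as.integer(insert_size), error_rate, prefix)
  list(r1 = data.frame(name = out$name1, seq = out$seq1,
                       stringsAsFactors = FALSE),
       r2 = data.frame(name = out$name2, seq = out$seq2,
                       stringsAsFactors = FALSE))
}

# ---- study driver ----

#' Run the full synthetic study from a configuration
#'
#' Deterministic end-to-end: ancestor, two evolved parents, LTR bursts,
#' tetraploid with HEs, per-sample variation, and (optionally) reads for
#' the reference individual.
#'
#' @param cfg a [sim_config()].
#' @param reads if `TRUE`, also simulate reads for the reference tetraploid.
#' @return list with `config`, `parents` (list A/B), `truth`
#'   (`tetraploid_truth` including any `pav_truth`/`cnv_truth`), `samples`
#'   (list of [apply_sample_variation()] results) and optionally `reads`.
#' @export
simulate_study <- function(cfg, reads = FALSE) {
  anc <- generate_ancestor(cfg)  # seeds the RNG from cfg$seed
  pa <- evolve_genome(anc, "A", cfg$t_div, cfg$mu, cfg$coding_factor)
  pb <- evolve_genome(anc, "B", cfg$t_div, cfg$mu, cfg$coding_factor)
  for (b in cfg$ltr_bursts) {
    if (b$role == "A") pa <- insert_ltr_burst(pa, b, cfg$mu_ltr)
    else pb <- insert_ltr_burst(pb, b, cfg$mu_ltr)
  }
  truth <- make_tetraploid(pa, pb, cfg$he_events)
  samples <- list()
  sample_ids <- unique(c(cfg$pav_deletions$sample, cfg$cnv_events$sample))
  for (sid in sample_ids) {
    pav <- cfg$pav_deletions$gene_id[cfg$pav_deletions$sample == sid]
    cnv <- cfg$cnv_events[cfg$cnv_events$sample == sid, , drop = FALSE]
    if (!is.null(cnv) && !nrow(cnv)) cnv <- NULL
    samples[[sid]] <- apply_sample_variation(truth, sid, pav, cnv)
    truth$pav_truth <- rbind(truth$pav_truth, samples[[sid]]$pav_truth)
    truth$cnv_truth <- rbind(truth$cnv_truth, samples[[sid]]$cnv_truth)
  }
  out <- list(config = cfg, parents = list(A = pa, B = pb), truth = truth,
              samples = samples)
  if (reads) {
    out$reads <- simulate_reads(truth$seq, cfg$depth, cfg$read_length,
                                cfg$insert_size, cfg$error_rate)
  }
  out
}

#' Extract gene (CDS) sequences from a genome or tetraploid
#'
#' @param obj a `parental_genome` or `tetraploid_truth`.
#' @return named character vector of plus-strand gene sequences.
#' @export
gene_sequences <- function(obj) {
  g <- obj$genes
  out <- substring(obj$seq[g$chrom], g$start + 1, g$end)
  stats::setNames(out, g$gene_id)
}

#' Extract the two terminal repeats of every annotated LTR element
#'
#' @param obj a `parental_genome` or `tetraploid_truth`.
#' @return data.frame with `te_id`, `chrom`, `age`, `burst_role`,
#'   `repeat5`, `repeat3`.
#' @export
ltr_repeat_pairs <- function(obj) {
  t <- obj$tes
  if (is.null(t) || !nrow(t)) {
    return(data.frame(te_id = character(0), chrom = character(0),
                      age = numeric(0), burst_role = character(0),
                      repeat5 = character(0), repeat3 = character(0),
                      stringsAsFactors = FALSE))
  }
  r5 <- substring(obj$seq[t$chrom], t$start + 1, t$start + t$ltr_length)
  r3 <- substring(obj$seq[t$chrom], t$end - t$ltr_length + 1, t$end)
  data.frame(te_id = t$te_id, chrom = t$chrom, age = t$age,
             burst_role = t$burst_role, repeat5 = r5, repeat3 = r3,
             stringsAsFactors = FALSE)
}

#' Write a simulated study to disk in standard formats
#'
#' FASTA for genomes and haplotypes, GFF3 for genes and TEs (with a
#' `ltr_age` attribute), BED for the HE/CNV truth sets, FASTQ for reads.
#'
#' @param study result of [simulate_study()].
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_study <- function(study, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(study$parents$A$seq, file.path(outdir, "parent_A.fa"))
  write_fasta(study$parents$B$seq, file.path(outdir, "parent_B.fa"))
  write_fasta(study$truth$seq, file.path(outdir, "tetraploid.fa"))
  g <- study$truth$genes
  write_gff3(data.frame(chrom = g$chrom, start = g$start, end = g$end,
                        strand = g$strand, type = "gene", ID = g$gene_id),
             file.path(outdir, "genes.gff3"))
  t <- study$truth$tes
  if (nrow(t)) {
    write_gff3(data.frame(chrom = t$chrom, start = t$start, end = t$end,
                          strand = "+", type = "LTR_retrotransposon",
                          ID = t$te_id, ltr_age = t$age,
                          ltr_length = t$ltr_length),
               file.path(outdir, "tes.gff3"))
  }
  ht <- study$truth$he_truth
  if (nrow(ht)) {
    write_bed(data.frame(chrom = ht$chrom, start = ht$start, end = ht$end,
                         name = paste0(ht$donor, "_to_",
                                       ifelse(ht$donor == "A", "B", "A"))),
              file.path(outdir, "he_truth.bed"))
  }
  ct <- study$truth$cnv_truth
  if (!is.null(ct) && nrow(ct)) {
    write_bed(data.frame(chrom = ct$chrom, start = ct$start, end = ct$end,
                         name = paste0(ct$sample, "_state", ct$copy_state)),
              file.path(outdir, "cnv_truth.bed"))
  }
  for (s in study$samples) {
    write_fasta(s$haplotypes,
                file.path(outdir, paste0("sample_", s$sample_id, ".fa")))
  }
  if (!is.null(study$reads)) {
    write_fastq(study$reads$r1, file.path(outdir, "reads_1.fastq"))
    write_fastq(study$reads$r2, file.path(outdir, "reads_2.fastq"))
  }
  invisible(outdir)
}
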