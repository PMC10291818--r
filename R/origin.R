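# Parent-of-origin classification. Two strategies, mirroring the two data
# types: DNA reads are classified by competitive primary mapping against the
# two parental genomes; RNA reads by a diagnostic-variant likelihood over
# the homoeologous gene pair. Subgenome roles are "A" and "B"; chromosome
# names end in their role letter (e.g. "chr1A").

#' Classifier parameters for the likelihood strategy
#'
#' @param epsilon per-base error probability (in (0, 0.25)).
#' @param tau log-likelihood-ratio call threshold (>= 0). The default ln 10
#'   lets a single clean diagnostic site decide a call.
#' @param min_sites minimum diagnostic sites covered for a call.
#' @return list of validated parameters.
#' @export
classifier_params <- function(epsilon = 0.01, tau = log(10),
                              min_sites = 1) {
  stopifnot(epsilon > 0, epsilon < 0.25, tau >= 0, min_sites >= 1)
  list(epsilon = epsilon, tau = tau, min_sites = as.integer(min_sites))
}

#' Find diagnostic variants between a homoeologous sequence pair
#'
#' Aligns the two near-identical sequences (trivially, column by column,
#' when they are equal length — the no-indel case — otherwise by shared
#' unique-anchor decomposition) and reports every column where the two carry
#' distinct non-gap bases. Columns inside or within `gap_pad` bases of a gap
#' are excluded. Alternatively a pre-computed alignment (two equal-length
#' gapped strings) can be supplied.
#'
#' @param seq_a,seq_b the homoeologous sequences (subgenome A and B).
#' @param pair_id identifier for the homoeolog pair.
#' @param aligned if `TRUE`, `seq_a`/`seq_b` are gapped alignment rows of
#'   equal length ("-" for gaps).
#' @param gap_pad exclusion radius around gap columns (bases).
#' @param min_identity minimum alignment identity; below it the sequences
#'   are declared non-homologous and an error is raised.
#' @return data.frame with `pair_id`, `pos_a`, `pos_b` (0-based positions
#'   on the ungapped sequences), `allele_a`, `allele_b`.
#' @export
find_diagnostic_variants <- function(seq_a, seq_b, pair_id = "pair1",
                                     aligned = FALSE, gap_pad = 2,
                                     min_identity = 0.8) {
  if (!aligned && nchar(seq_a) != nchar(seq_b)) {
    al <- anchor_align(seq_a, seq_b)
    seq_a <- al[1]; seq_b <- al[2]
    aligned <- TRUE
  }
  if (aligned && nchar(seq_a) != nchar(seq_b))
    stop("aligned rows must have equal length")
  a <- strsplit(toupper(seq_a), "")[[1]]
  b <- strsplit(toupper(seq_b), "")[[1]]
  gap <- a == "-" | b == "-"
  near_gap <- gap
  if (any(gap) && gap_pad > 0) {
    for (d in seq_len(gap_pad)) {
      near_gap <- near_gap | c(gap[-seq_len(d)], rep(FALSE, d)) |
        c(rep(FALSE, d), gap[seq_len(length(gap) - d)])
    }
  }
  ident <- mean(a[!gap] == b[!gap])
  if (is.nan(ident) || ident < min_identity)
    stop("alignment identity ", round(ident, 3),
         " below ", min_identity, ": sequences not homoeologous enough")
  pos_a <- cumsum(a != "-") - 1L
  pos_b <- cumsum(b != "-") - 1L
  hit <- which(!near_gap & a != b & a %in% c("A", "C", "G", "T") &
                 b %in% c("A", "C", "G", "T"))
  data.frame(pair_id = rep_len(pair_id, length(hit)),
             pos_a = pos_a[hit], pos_b = pos_b[hit],
             allele_a = a[hit], allele_b = b[hit],
             stringsAsFactors = FALSE)
}

# anchor-and-extend alignment of two near-identical sequences: unique
# shared k-mers in collinear order anchor the alignment; equal-length
# inter-anchor segments are paired column-wise, unequal ones are padded
# with gaps (left-justified), which the gap exclusion then masks.
anchor_align <- function(seq_a, seq_b, k = 21) {
  kmerize <- function(s) {
    n <- nchar(s) - k + 1
    if (n < 1) return(character(0))
    substring(s, 1:n, k:(nchar(s)))
  }
  ka <- kmerize(seq_a); kb <- kmerize(seq_b)
  ua <- which(!(duplicated(ka) | duplicated(ka, fromLast = TRUE)))
  ub <- which(!(duplicated(kb) | duplicated(kb, fromLast = TRUE)))
  common <- intersect(ka[ua], kb[ub])
  pa <- ua[match(common, ka[ua])]
  pb <- ub[match(common, kb[ub])]
  o <- order(pa)
  pa <- pa[o]; pb <- pb[o]
  # greedy collinear chain: keep anchors advancing on both sequences, and
  # non-overlapping so inter-anchor segments are well defined
  keep <- logical(length(pa))
  last_a <- -k; last_b <- -k
  for (i in seq_along(pa)) {
    if (pa[i] >= last_a + k && pb[i] >= last_b + k) {
      keep[i] <- TRUE; last_a <- pa[i]; last_b <- pb[i]
    }
  }
  pa <- pa[keep]; pb <- pb[keep]
  if (!length(pa)) stop("no unique shared anchors: cannot align")
  starts_a <- c(0, pa - 1 + k); ends_a <- c(pa - 1, nchar(seq_a))
  starts_b <- c(0, pb - 1 + k); ends_b <- c(pb - 1, nchar(seq_b))
  row_a <- character(0); row_b <- character(0)
  for (i in seq_along(starts_a)) {
    sa <- substr(seq_a, starts_a[i] + 1, ends_a[i])
    sb <- substr(seq_b, starts_b[i] + 1, ends_b[i])
    w <- max(nchar(sa), nchar(sb))
    row_a <- c(row_a, paste0(sa, strrep("-", w - nchar(sa))))
    row_b <- c(row_b, paste0(sb, strrep("-", w - nchar(sb))))
    if (i <= length(pa)) {
      anchor <- substr(seq_a, pa[i], pa[i] + k - 1)
      row_a <- c(row_a, anchor)
      row_b <- c(row_b, substr(seq_b, pb[i], pb[i] + k - 1))
    }
  }
  c(paste(row_a, collapse = ""), paste(row_b, collapse = ""))
}

#' Classify one read by diagnostic-variant likelihood
#'
#' For each diagnostic site the read covers, the base contributes
#' P(base | origin o) = 1 - epsilon if it equals that origin's allele and
#' epsilon/3 otherwise; the log-likelihood ratio is
#' llr = sum log P(. | A) - sum log P(. | B). Calls: A if llr > tau, B if
#' llr < -tau, else ambiguous; fewer than `min_sites` covered sites forces
#' ambiguous.
#'
#' @param read read sequence as aligned (already reverse-complemented for
#'   minus-strand alignments).
#' @param pos 0-based alignment start on the coordinate system named by
#'   `on`.
#' @param variants data.frame from [find_diagnostic_variants()].
#' @param params a [classifier_params()].
#' @param on which subgenome's coordinates `pos` refers to ("A" or "B").
#' @return one-row data.frame: `origin`, `llr`, `n_sites`.
#' @export
classify_read_llr <- function(read, pos, variants,
                              params = classifier_params(), on = "A") {
  pcol <- if (on == "A") "pos_a" else "pos_b"
  len <- nchar(read)
  cov <- variants[variants[[pcol]] >= pos &
                    variants[[pcol]] < pos + len, , drop = FALSE]
  n <- nrow(cov)
  if (n == 0) {
    return(data.frame(origin = "ambiguous", llr = 0, n_sites = 0L,
                      stringsAsFactors = FALSE))
  }
  base <- substring(read, cov[[pcol]] - pos + 1, cov[[pcol]] - pos + 1)
  eps <- params$epsilon
  p_given <- function(allele) ifelse(base == allele, 1 - eps, eps / 3)
  llr <- sum(log(p_given(cov$allele_a))) - sum(log(p_given(cov$allele_b)))
  origin <- if (n < params$min_sites) "ambiguous"
  else if (llr > params$tau) "A"
  else if (llr < -params$tau) "B"
  else "ambiguous"
  data.frame(origin = origin, llr = llr, n_sites = n,
             stringsAsFactors = FALSE)
}

# role of a reference sequence: the trailing A/B of its chromosome name
# (haplotype suffixes like "_hap1" are tolerated)
chrom_role <- function(rname) {
  core <- sub("_hap[12]$", "", rname)
  role <- sub("^.*([AB])$", "\\1", core)
  ifelse(role %in% c("A", "B"), role, NA_character_)
}

# roles present among a record's tied reference sequences
tie_roles <- function(tie_refs) {
  vapply(strsplit(ifelse(is.na(tie_refs), "", tie_refs), ",", fixed = TRUE),
         function(x) {
           r <- unique(chrom_role(x[x != "..." & nzchar(x)]))
           r <- r[!is.na(r)]
           if (length(r) == 1) r else if (length(r) > 1) "both" else "none"
         }, character(1))
}

#' Classify reads by competitive primary mapping
#'
#' Each read is mapped to both parental genomes; its origin is the parent
#' owning the better-scoring primary alignment. Equal best scores across
#' the parents, or failure to map to either, yield "ambiguous"/"unmapped".
#' `llr` here is the raw score difference (A minus B) — a different scale
#' from the probabilistic log-likelihood ratio of [classify_read_llr()].
#'
#' @param reads character vector or data.frame (`name`, `seq`).
#' @param index_a,index_b [build_index()] handles for the two parents.
#' @param ... further arguments to [map_reads()].
#' @return data.frame with `qname`, `origin` ("A", "B", "ambiguous",
#'   "unmapped"), `llr` (score difference), `score_a`, `score_b`.
#' @export
classify_by_primary_mapping <- function(reads, index_a, index_b, ...) {
  ra <- map_reads(index_a, reads, ...)
  rb <- map_reads(index_b, reads, ...)
  stopifnot(identical(ra$qname, rb$qname))
  sa <- ifelse(ra$mapped, ra$score, 0L)
  sb <- ifelse(rb$mapped, rb$score, 0L)
  origin <- ifelse(!ra$mapped & !rb$mapped, "unmapped",
            ifelse(sa > sb, "A", ifelse(sb > sa, "B", "ambiguous")))
  data.frame(qname = ra$qname, origin = origin, llr = sa - sb,
             score_a = sa, score_b = sb, stringsAsFactors = FALSE)
}

#' Tag reads with their parental origin and re-map to the tetraploid
#'
#' Mirrors the resequencing pipeline: reads classified against the parents
#' are re-mapped to the allotetraploid reference and each alignment carries
#' an origin tag (`A`, `B`, `U` = ambiguous between parents, `N` = mapped
#' on the tetraploid but on neither parent, i.e. novel).
#'
#' @param reads character vector or data.frame (`name`, `seq`).
#' @param origin_calls data.frame from [classify_by_primary_mapping()].
#' @param index_tetra [build_index()] handle for the tetraploid reference.
#' @param ... further arguments to [map_reads()].
#' @return alignment records with an `origin_tag` column.
#' @export
tag_and_remap <- function(reads, origin_calls, index_tetra, ...) {
  rec <- map_reads(index_tetra, reads, ...)
  m <- match(rec$qname, origin_calls$qname)
  if (anyNA(m[rec$mapped]))
    stop("missing origin call for ",
         sum(is.na(m[rec$mapped])), " mapped read(s)")
  origin <- origin_calls$origin[m]
  rec$origin_tag <- ifelse(is.na(origin), NA_character_,
                    ifelse(origin == "A", "A",
                    ifelse(origin == "B", "B",
                    ifelse(origin == "unmapped", "N", "U"))))
  rec
}
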