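# Minimal deterministic read mapper: exact k-mer seeds chained on the
# (gap-free) diagonal, ungapped extension scored match +1 / mismatch -2,
# best-scoring contiguous sub-interval retained and the rest soft-clipped.
# A clipped portion of at least `min_split` bases is remapped on its own;
# a confident hit becomes the record's split-read partner. No affine gaps:
# simulated data carries substitutions only, and externally produced SAM is
# accepted for gapped real data.

#' Build an exact k-mer index over a genome
#'
#' @param seqs named character vector of reference sequences.
#' @param k k-mer size, 8-31 (default 17).
#' @return an opaque index handle (external pointer) with attributes
#'   `chroms` and `chrom_lengths`.
#' @export
build_index <- function(seqs, k = 17) {
  if (!length(seqs) || sum(nchar(seqs)) == 0) stop("empty genome")
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  xp <- .ph_build_index(seqs, as.integer(k))
  attr(xp, "chroms") <- names(seqs)
  attr(xp, "chrom_lengths") <- stats::setNames(nchar(seqs), names(seqs))
  attr(xp, "k") <- as.integer(k)
  class(xp) <- "ph_index"
  xp
}

#' @export
print.ph_index <- function(x, ...) {
  info <- .ph_index_info(x)
  cat("ph_index: k =", info$k, "|", length(info$chroms), "sequences |",
      format(info$n_positions, big.mark = ","), "indexed k-mers\n")
  invisible(x)
}

#' Look up the reference positions of one k-mer
#'
#' @param index a [build_index()] handle.
#' @param kmer a string of length `k`.
#' @return data.frame with `chrom` and `pos` (0-based) of every forward
#'   occurrence.
#' @export
lookup_kmer <- function(index, kmer) {
  gp <- .ph_lookup_kmer(index, kmer)
  cl <- attr(index, "chrom_lengths")
  offs <- c(0, cumsum(as.numeric(cl)))
  ci <- findInterval(gp, offs[-length(offs)] - 1e-9)
  data.frame(chrom = names(cl)[ci], pos = gp - offs[ci],
             stringsAsFactors = FALSE)
}

#' Map reads against an index
#'
#' Every mapped read gets exactly one primary record. Score ties are
#' resolved by a deterministic hash of the read name over the
#' lexicographically sorted tied loci, so the result is independent of read
#' input order and tied reads spread evenly over identical repeat copies;
#' such records carry `ambiguous_placement = TRUE` and `tie_refs` lists the
#' tied reference sequences.
#'
#' @param index a [build_index()] handle.
#' @param reads character vector of read sequences, or a data.frame with
#'   `name` and `seq` columns.
#' @param names read names (ignored when `reads` is a data.frame).
#' @param stride distance between successive seed starts in the read.
#' @param min_chain minimum seeds on a diagonal to evaluate it.
#' @param max_candidates cap on evaluated loci per read.
#' @param min_score minimum alignment score to report a mapping.
#' @param min_split minimum soft-clip length to attempt partner mapping.
#' @return data.frame of alignment records (`qname`, `rname`, 0-based
#'   `pos`, `strand`, `score`, `nm`, `aln_len`, `clip_left`, `clip_right`,
#'   `n_best`, `ambiguous_placement`, `tie_refs`, `partner_*`, `mapped`).
#' @export
map_reads <- function(index, reads, names = NULL, stride = 7,
                      min_chain = 2, max_candidates = 64, min_score = 40,
                      min_split = 25) {
  if (is.data.frame(reads)) {
    names <- reads$name
    reads <- reads$seq
  }
  if (is.null(names)) names <- paste0("q", seq_along(reads))
  k <- attr(index, "k")
  if (any(nchar(reads) < k)) stop("reads shorter than the index k-mer size")
  .ph_map_reads(index, reads, names, as.integer(stride),
                as.integer(min_chain), as.integer(max_candidates),
                as.integer(min_score), as.integer(min_split))
}

#' Map a single read
#'
#' @inheritParams map_reads
#' @param read one read sequence.
#' @param name read name.
#' @return a one-row alignment record (see [map_reads()]).
#' @export
map_read <- function(index, read, name = "q1", ...) {
  map_reads(index, read, name, ...)
}
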