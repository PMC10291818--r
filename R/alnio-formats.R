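# Standard-format I/O. FASTA/FASTQ go through Biostrings, BED/GFF3 through
# rtracklayer/GenomicRanges. SAM is plain text (M/S CIGARs only) written and
# parsed here. All in-memory coordinates are 0-based half-open; GFF3 is
# converted to/from 1-based closed at the file boundary.

#' Read a FASTA file into a named character vector
#'
#' @param path path to an (optionally gzipped) FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a FASTQ file
#'
#' @param path path to a FASTQ file.
#' @return data.frame with columns `name`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  # the metadata-column drop is internal Biostrings bookkeeping
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  data.frame(name = sub("\\s.*$", "", names(x)),
             seq = as.character(x),
             qual = as.character(Biostrings::quality(x)),
             stringsAsFactors = FALSE)
}

#' Write reads to FASTQ
#'
#' @param reads data.frame with columns `name`, `seq` and optionally `qual`
#'   (defaults to constant Phred 40, "I").
#' @param path output path (".gz" suffix compresses).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("name", "seq") %in% names(reads)))
  qual <- reads$qual
  if (is.null(qual)) qual <- vapply(nchar(reads$seq), function(n)
    strrep("I", n), character(1))
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(stats::setNames(reads$seq, reads$name)),
    Biostrings::PhredQuality(qual))
  Biostrings::writeQualityScaledXStringSet(x, path)
  invisible(path)
}

#' Read a BED file of intervals
#'
#' @param path BED3+ file.
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open) and,
#'   when present, `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   stringsAsFactors = FALSE)
  md <- as.data.frame(S4Vectors::mcols(gr))
  if (ncol(md)) df <- cbind(df, md)
  df
}

#' Write intervals to BED
#'
#' @param df data.frame with `chrom`, `start`, `end` (0-based half-open);
#'   an optional `name` column becomes the BED name field.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  gr <- GenomicRanges::GRanges(df$chrom,
          IRanges::IRanges(df$start + 1L, df$end))
  if (!is.null(df$name)) gr$name <- df$name
  if (!is.null(df$score)) gr$score <- df$score
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read gene/TE features from GFF3
#'
#' @param path GFF3 file (1-based closed on disk).
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open),
#'   `strand`, `type`, `ID` and any other attributes present.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "GFF3")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   type = as.character(gr$type),
                   stringsAsFactors = FALSE)
  md <- as.data.frame(S4Vectors::mcols(gr))
  md$type <- NULL
  keep <- vapply(md, function(x) is.atomic(x) || is.character(x), logical(1))
  if (any(keep)) df <- cbind(df, md[keep])
  df
}

#' Write features to GFF3
#'
#' @param df data.frame with `chrom`, `start`, `end` (0-based half-open),
#'   optionally `strand`, `type`, `ID`, and extra attribute columns
#'   (e.g. `ltr_age`).
#' @param path output path.
#' @param source value of the GFF3 source column.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(df, path, source = "polyhekit") {
  strand <- if (is.null(df$strand)) "+" else df$strand
  gr <- GenomicRanges::GRanges(df$chrom,
          IRanges::IRanges(df$start + 1L, df$end), strand = strand)
  gr$type <- if (is.null(df$type)) "gene" else df$type
  gr$source <- source
  for (col in setdiff(names(df),
                      c("chrom", "start", "end", "strand", "type"))) {
    S4Vectors::mcols(gr)[[col]] <- df[[col]]
  }
  rtracklayer::export(gr, path, format = "GFF3")
  invisible(path)
}

# ---- SAM ----

#' Write alignment records as SAM
#'
#' Emits a valid header plus one line per mapped record (primary mappings
#' only, M/S CIGARs). The parental-origin tag, when present, is written as
#' `XO:Z:` (A, B, U = ambiguous, N = novel), a split-read partner as
#' `XP:Z:rname,pos,len,side`.
#'
#' @param records alignment data.frame as returned by [map_reads()], with an
#'   optional `origin_tag` column.
#' @param chrom_lengths named integer vector of reference lengths.
#' @param path output path.
#' @param seqs optional named character vector of read sequences (by
#'   `qname`); otherwise SEQ is "*".
#' @return `path`, invisibly.
#' @export
write_sam <- function(records, chrom_lengths, path, seqs = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                     as.integer(chrom_lengths)), con)
  writeLines("@PG\tID:polyhekit\tPN:polyhekit", con)
  r <- records
  flag <- ifelse(!r$mapped, 4L, ifelse(r$strand == "-", 16L, 0L))
  cigar <- ifelse(!r$mapped, "*", paste0(
    ifelse(r$clip_left > 0, paste0(r$clip_left, "S"), ""),
    r$aln_len, "M",
    ifelse(r$clip_right > 0, paste0(r$clip_right, "S"), "")))
  seqf <- rep("*", nrow(r))
  if (!is.null(seqs)) {
    m <- match(r$qname, names(seqs))
    seqf <- ifelse(is.na(m), "*", seqs[m])
  }
  mapq <- ifelse(!r$mapped, 0L, ifelse(r$ambiguous_placement, 0L, 60L))
  lines <- paste(r$qname, flag,
                 ifelse(r$mapped, r$rname, "*"),
                 ifelse(r$mapped, r$pos + 1L, 0L),
                 mapq, cigar, "*", 0L, 0L, seqf, "*", sep = "\t")
  lines <- paste0(lines, ifelse(is.na(r$score), "",
                                sprintf("\tAS:i:%d", r$score)))
  lines <- paste0(lines, ifelse(is.na(r$nm), "", sprintf("\tNM:i:%d", r$nm)))
  if (!is.null(r$origin_tag)) {
    lines <- paste0(lines, sprintf("\tXO:Z:%s", r$origin_tag))
  }
  has_p <- r$mapped & !is.na(r$partner_rname)
  lines <- paste0(lines, ifelse(has_p,
    sprintf("\tXP:Z:%s,%d,%d,%s", r$partner_rname, r$partner_pos,
            r$partner_len, r$partner_side), ""))
  writeLines(lines, con)
  invisible(path)
}

#' Parse a SAM file into alignment records
#'
#' Accepts externally produced SAM and restricts itself to the fields the
#' pipeline uses: position, strand, primary flag, M/S CIGAR geometry, and
#' the `XO`/`XP` tags when present. Records with corrupt mandatory fields
#' raise an error naming the line.
#'
#' @param path SAM file.
#' @return alignment data.frame (0-based `pos`) with a `chrom_lengths`
#'   attribute taken from the header.
#' @export
read_sam <- function(path) {
  all_lines <- readLines(path)
  hdr <- grepl("^@", all_lines)
  sq <- all_lines[grepl("^@SQ", all_lines)]
  cl <- stats::setNames(
    as.integer(sub(".*\tLN:([0-9]+).*", "\\1", sq)),
    sub(".*\tSN:([^\t]+).*", "\\1", sq))
  body_idx <- which(!hdr & nzchar(all_lines))
  parse_one <- function(i) {
    f <- strsplit(all_lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 11) stop("malformed SAM record at line ", i)
    flag <- suppressWarnings(as.integer(f[2]))
    pos1 <- suppressWarnings(as.integer(f[4]))
    if (is.na(flag) || is.na(pos1)) stop("malformed SAM record at line ", i)
    mapped <- !bitwAnd(flag, 4L)
    cig <- f[6]
    cl_l <- 0L; cl_r <- 0L; alen <- NA_integer_
    if (mapped && cig != "*") {
      ops <- regmatches(cig, gregexpr("[0-9]+[MIDNSHP=X]", cig))[[1]]
      if (!length(ops) || nchar(paste(ops, collapse = "")) != nchar(cig))
        stop("malformed CIGAR at line ", i)
      n <- as.integer(sub("[A-Z=]$", "", ops))
      op <- sub("^[0-9]+", "", ops)
      if (any(!op %in% c("M", "S", "=", "X", "H")))
        stop("unsupported CIGAR operation at line ", i)
      mlen <- sum(n[op %in% c("M", "=", "X")])
      if (op[1] == "S") cl_l <- n[1]
      if (op[length(op)] == "S") cl_r <- n[length(op)]
      alen <- mlen
    }
    tags <- if (length(f) > 11) f[12:length(f)] else character(0)
    grab <- function(tag) {
      hit <- tags[startsWith(tags, tag)]
      if (length(hit)) sub(tag, "", hit[1]) else NA_character_
    }
    xo <- grab("XO:Z:")
    xp <- grab("XP:Z:")
    asv <- suppressWarnings(as.integer(grab("AS:i:")))
    nmv <- suppressWarnings(as.integer(grab("NM:i:")))
    p_rn <- NA_character_; p_pos <- NA_integer_
    p_len <- NA_integer_; p_side <- NA_character_
    if (!is.na(xp)) {
      pf <- strsplit(xp, ",", fixed = TRUE)[[1]]
      p_rn <- pf[1]; p_pos <- as.integer(pf[2])
      p_len <- as.integer(pf[3]); p_side <- pf[4]
    }
    data.frame(qname = f[1],
               rname = if (mapped) f[3] else NA_character_,
               pos = if (mapped) pos1 - 1L else NA_integer_,
               strand = if (mapped)
                 (if (bitwAnd(flag, 16L)) "-" else "+") else NA_character_,
               score = asv, nm = nmv, aln_len = alen,
               clip_left = cl_l, clip_right = cl_r,
               n_best = NA_integer_,
               ambiguous_placement = mapped && f[5] == "0",
               tie_refs = NA_character_,
               partner_rname = p_rn, partner_pos = p_pos,
               partner_len = p_len, partner_side = p_side,
               mapped = mapped,
               is_primary = !bitwAnd(flag, 256L),
               origin_tag = xo,
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(body_idx, parse_one))
  if (is.null(out)) out <- data.frame()
  attr(out, "chrom_lengths") <- cl
  out
}

#' Write diagnostic variants as a minimal VCF
#'
#' @param variants data.frame from [find_diagnostic_variants()].
#' @param path output path.
#' @param chrom reference (subgenome A) chromosome name for the CHROM column.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path, chrom = "chrA") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=POSB,Number=1,Type=Integer,Description=\"0-based position on the B homoeolog\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(variants)) {
    writeLines(sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\tPOSB=%d",
                       chrom, variants$pos_a + 1L, variants$pair_id,
                       variants$allele_a, variants$allele_b,
                       variants$pos_b), con)
  }
  invisible(path)
}

#' Reverse complement
#'
#' @param seqs character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(seqs) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs)))
}
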