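# Subgenome painting and homoeologous-exchange calling. Origin-tagged
# alignments on the tetraploid are binned into fixed windows; windows where
# the observed parental origin contradicts the chromosome's expected parent
# seed HE blocks. Origin-ambiguous reads (tag "U") never enter the nA/nB
# vote; placement ties on the tetraploid do (the two copies of an exchanged
# segment are near-identical, so tied placements are exactly the reads that
# carry the painting signal — they spread evenly over the tied loci).

#' HE calling parameters
#'
#' @param w window size in bases.
#' @param min_frac discordant-origin fraction required to seed a block
#'   (in (0.5, 1]).
#' @param min_reads minimum origin-informative reads per window.
#' @param min_len minimum reported block length in bases.
#' @param merge_gap maximum gap between seed runs to merge, in bases.
#' @return list of validated parameters.
#' @export
he_params <- function(w = 1000, min_frac = 0.8, min_reads = 5,
                      min_len = 2000, merge_gap = 2000) {
  stopifnot(w > 0, min_frac > 0.5, min_frac <= 1, min_reads >= 1,
            min_len > 0, merge_gap >= 0)
  list(w = as.integer(w), min_frac = min_frac,
       min_reads = as.integer(min_reads), min_len = as.integer(min_len),
       merge_gap = as.integer(merge_gap))
}

#' Paint the tetraploid with per-window origin counts
#'
#' Each mapped primary alignment increments exactly one window — the window
#' containing its start — of its chromosome: `n_a`/`n_b` for A/B tags,
#' `n_ambiguous` for tag "U", `n_novel` for tag "N" (mapped here, on
#' neither parent).
#'
#' @param records origin-tagged alignment records ([tag_and_remap()]).
#' @param chrom_lengths named vector of tetraploid chromosome lengths.
#' @param params a [he_params()].
#' @return data.frame (`chrom`, `window`, `start`, `end`, `n_a`, `n_b`,
#'   `n_ambiguous`, `n_novel`) with `ceiling(length / w)` rows per
#'   chromosome; class `origin_track`.
#' @export
paint <- function(records, chrom_lengths, params = he_params()) {
  r <- records[records$mapped, , drop = FALSE]
  if (is.null(r$origin_tag)) stop("records carry no origin tags")
  bad <- setdiff(unique(r$rname), names(chrom_lengths))
  if (length(bad)) stop("alignment to unknown chromosome: ",
                        paste(bad, collapse = ", "))
  w <- params$w
  out <- lapply(names(chrom_lengths), function(ch) {
    nw <- max(1L, as.integer(ceiling(chrom_lengths[[ch]] / w)))
    sub <- r[r$rname == ch, , drop = FALSE]
    win <- pmin(sub$pos %/% w, nw - 1L) + 1L
    cnt <- function(tag) tabulate(win[sub$origin_tag %in% tag], nbins = nw)
    data.frame(chrom = ch, window = seq_len(nw) - 1L,
               start = (seq_len(nw) - 1L) * w,
               end = pmin(seq_len(nw) * w, as.integer(chrom_lengths[[ch]])),
               n_a = cnt("A"), n_b = cnt("B"),
               n_ambiguous = cnt("U"), n_novel = cnt("N"),
               stringsAsFactors = FALSE)
  })
  track <- do.call(rbind, out)
  class(track) <- c("origin_track", class(track))
  attr(track, "w") <- w
  attr(track, "chrom_lengths") <- chrom_lengths
  track
}

#' Call HE blocks from an origin track
#'
#' Windows with at least `min_reads` informative reads and a discordant
#' fraction `>= min_frac` seed blocks; seed runs separated by at most
#' `merge_gap` merge; blocks shorter than `min_len` are dropped. When the
#' alignment records are supplied, block boundaries are refined to the
#' outermost discordant read extents within the terminal windows.
#'
#' @param track an `origin_track` from [paint()].
#' @param expected_origin named vector mapping every chromosome to its
#'   expected subgenome ("A"/"B").
#' @param params a [he_params()].
#' @param records optional origin-tagged records for boundary refinement.
#' @return data.frame of HE blocks: `chrom`, `start`, `end`, `donor`,
#'   `recipient`, `mean_discordant_frac`, `supporting_reads`.
#' @export
call_blocks <- function(track, expected_origin, params = he_params(),
                        records = NULL) {
  missing_ch <- setdiff(unique(track$chrom), names(expected_origin))
  if (length(missing_ch)) stop("no expected origin for: ",
                               paste(missing_ch, collapse = ", "))
  w <- attr(track, "w")
  if (is.null(w)) w <- params$w
  blocks <- list()
  for (ch in unique(track$chrom)) {
    tr <- track[track$chrom == ch, , drop = FALSE]
    exp_o <- expected_origin[[ch]]
    disc <- if (exp_o == "A") tr$n_b else tr$n_a
    conc <- if (exp_o == "A") tr$n_a else tr$n_b
    tot <- disc + conc
    seed <- tot >= params$min_reads & disc / pmax(tot, 1) >= params$min_frac
    if (!any(seed)) next
    idx <- which(seed)
    gap_w <- max(0L, as.integer(ceiling(params$merge_gap / w)))
    brk <- c(TRUE, diff(idx) > gap_w + 1L)
    grp <- cumsum(brk)
    for (g in unique(grp)) {
      run <- idx[grp == g]
      start <- tr$start[run[1]]
      end <- tr$end[run[length(run)]]
      if (!is.null(records)) {
        dr <- records[records$mapped & records$rname == ch &
                        records$origin_tag %in%
                          (if (exp_o == "A") "B" else "A"), , drop = FALSE]
        # outermost discordant read extents around the terminal windows
        # (the true boundary can sit inside the partial window just beyond
        # the outermost seed window, so search one window further out)
        first_w <- c(tr$start[run[1]] - w, tr$end[run[1]])
        last_w <- c(tr$start[run[length(run)]],
                    tr$end[run[length(run)]] + w)
        in_first <- dr$pos >= first_w[1] & dr$pos < first_w[2]
        in_last <- dr$pos >= last_w[1] & dr$pos < last_w[2]
        if (any(in_first)) start <- min(dr$pos[in_first])
        if (any(in_last))
          end <- max(dr$pos[in_last] + dr$aln_len[in_last])
      }
      support <- sum(disc[run])
      blocks[[length(blocks) + 1]] <- data.frame(
        chrom = ch, start = start, end = end,
        donor = if (exp_o == "A") "B" else "A", recipient = exp_o,
        mean_discordant_frac = mean((disc / pmax(tot, 1))[run]),
        supporting_reads = support, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(blocks)) do.call(rbind, blocks) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               donor = character(0), recipient = character(0),
               mean_discordant_frac = numeric(0),
               supporting_reads = integer(0), stringsAsFactors = FALSE)
  out <- out[out$end - out$start >= params$min_len, , drop = FALSE]
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Classify every window as parent-derived, novel, or no-call
#'
#' Majority vote per window: the dominating parent when enough informative
#' reads are present, "novel" when novel reads dominate (mapped on the
#' tetraploid but on neither parent), "no-call" below `min_reads`.
#'
#' @param track an `origin_track`.
#' @param params a [he_params()].
#' @param labels length-3 labels for A-derived, B-derived and novel
#'   windows; substitute the parental species names if preferred.
#' @return the track with a `class_label` column.
#' @export
coordinate_class <- function(track, params = he_params(),
                             labels = c("A-derived", "B-derived",
                                        "novel")) {
  n_inf <- track$n_a + track$n_b + track$n_novel
  lab <- rep("no-call", nrow(track))
  enough <- n_inf >= params$min_reads
  novel_dom <- track$n_novel > track$n_a & track$n_novel > track$n_b
  lab[enough & novel_dom] <- labels[3]
  ab <- enough & !novel_dom
  lab[ab & track$n_a >= track$n_b] <- labels[1]
  lab[ab & track$n_b > track$n_a] <- labels[2]
  track$class_label <- lab
  track
}

#' Per-gene HE status and directional counts
#'
#' A gene is "within HE" when at least `min_overlap` of its length lies in
#' an HE block; directional counts (A donor into B subgenome and vice
#' versa) feed the bias statistics.
#'
#' @param blocks HE blocks from [call_blocks()].
#' @param genes data.frame with `chrom`, `start`, `end`, `gene_id`.
#' @param min_overlap minimum overlapping fraction of the gene length.
#' @return list with `genes` (the gene table plus `he_overlap_frac`,
#'   `within_he`, `donor`) and `counts` (`n_a_to_b`, `n_b_to_a`).
#' @export
he_gene_overlap <- function(blocks, genes, min_overlap = 0.5) {
  frac <- numeric(nrow(genes))
  donor <- rep(NA_character_, nrow(genes))
  if (nrow(blocks)) {
    g <- GenomicRanges::GRanges(genes$chrom,
           IRanges::IRanges(genes$start + 1L, genes$end))
    b <- GenomicRanges::GRanges(blocks$chrom,
           IRanges::IRanges(blocks$start + 1L, blocks$end))
    ov <- GenomicRanges::findOverlaps(g, b)
    if (length(ov)) {
      qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
      wdt <- GenomicRanges::width(GenomicRanges::pintersect(g[qh], b[sh]))
      covfrac <- wdt / (genes$end[qh] - genes$start[qh])
      agg <- tapply(covfrac, qh, sum)
      frac[as.integer(names(agg))] <- as.numeric(agg)
      # donor of the block with the largest overlap
      best <- tapply(seq_along(qh), qh, function(i) i[which.max(covfrac[i])])
      donor[as.integer(names(best))] <- blocks$donor[sh[unlist(best)]]
    }
  }
  genes$he_overlap_frac <- frac
  genes$within_he <- frac >= min_overlap
  genes$donor <- ifelse(genes$within_he, donor, NA_character_)
  counts <- data.frame(
    n_a_to_b = sum(genes$within_he & genes$donor == "A", na.rm = TRUE),
    n_b_to_a = sum(genes$within_he & genes$donor == "B", na.rm = TRUE))
  list(genes = genes, counts = counts)
}
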