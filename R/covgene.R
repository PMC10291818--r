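# Breadth-of-coverage gene presence/absence (PAV) and HE-gene calling,
# plus windowed read-depth segmentation of large CNVs with split-read
# breakpoint refinement. Breadth uses primary alignments only, consistent
# with the origin pipeline.

#' PAV thresholds
#'
#' A gene with breadth below `lost_thresh` in the reads of its own
#' subgenome is a candidate loss; if the same locus shows breadth above
#' `he_thresh` in reads assigned to the opposite parent, it is instead a
#' gene within an HE.
#'
#' @param lost_thresh breadth fraction below which a gene is lost (default
#'   0.20).
#' @param he_thresh opposite-parent breadth fraction above which a lost
#'   candidate is re-classed as within an HE (default 0.90).
#' @return validated parameter list.
#' @export
pav_params <- function(lost_thresh = 0.20, he_thresh = 0.90) {
  stopifnot(lost_thresh > 0, lost_thresh < he_thresh, he_thresh <= 1)
  list(lost_thresh = lost_thresh, he_thresh = he_thresh)
}

#' CNV segmentation parameters
#'
#' @param window window size in bases for the depth profile.
#' @param state_tolerance maximum distance from a copy state for a window
#'   to adopt it (must stay below half the minimum state gap, 0.25).
#' @param min_segment minimum reported segment length in bases.
#' @return validated parameter list; copy states are fixed at
#'   {0, 0.5, 1, 1.5, 2} (relative to the genome-wide median).
#' @export
cnv_params <- function(window = 10000, state_tolerance = 0.15,
                       min_segment = 50000) {
  stopifnot(window > 0, state_tolerance > 0, state_tolerance < 0.25,
            min_segment > 0)
  list(window = as.integer(window), states = c(0, 0.5, 1, 1.5, 2),
       state_tolerance = state_tolerance,
       min_segment = as.integer(min_segment))
}

# per-chromosome coverage from alignment records (primary, mapped)
records_coverage <- function(records, chrom_lengths) {
  r <- records[records$mapped, , drop = FALSE]
  gr <- GenomicRanges::GRanges(
    factor(r$rname, levels = names(chrom_lengths)),
    IRanges::IRanges(r$pos + 1L, r$pos + r$aln_len),
    seqlengths = chrom_lengths)
  gr <- GenomicRanges::trim(gr)
  GenomicRanges::coverage(gr)
}

#' Per-gene breadth of coverage
#'
#' Fraction of gene bases covered by at least one primary alignment.
#'
#' @param records alignment records.
#' @param genes data.frame with `chrom`, `start`, `end`, `gene_id`.
#' @param chrom_lengths named reference lengths.
#' @return named numeric vector of covered fractions in [0, 1].
#' @export
gene_breadth <- function(records, genes, chrom_lengths) {
  if (any(!genes$chrom %in% names(chrom_lengths)) ||
      any(genes$end > chrom_lengths[genes$chrom]))
    stop("gene interval outside the reference")
  cov <- records_coverage(records, chrom_lengths)
  out <- numeric(nrow(genes))
  for (ch in unique(genes$chrom)) {
    gi <- which(genes$chrom == ch)
    v <- cov[[ch]] > 0
    cs <- c(0, cumsum(as.integer(v)))
    out[gi] <- (cs[genes$end[gi] + 1L] - cs[genes$start[gi] + 1L]) /
      (genes$end[gi] - genes$start[gi])
  }
  stats::setNames(out, genes$gene_id)
}

#' Call gene status from self and opposite-parent breadth
#'
#' Breadth below `lost_thresh` in the gene's own subgenome reads marks the
#' gene as absent from that locus; breadth above `he_thresh` by reads of
#' the opposite parent at the same locus means the sequence there is the
#' other parent's — a gene within an HE — otherwise the gene is lost.
#'
#' @param breadth_self,breadth_opposite numeric vectors (recycled to
#'   common length).
#' @param params a [pav_params()].
#' @return character vector: "present", "lost" or "within-HE".
#' @export
call_gene_status <- function(breadth_self, breadth_opposite,
                             params = pav_params()) {
  n <- max(length(breadth_self), length(breadth_opposite))
  bs <- rep_len(breadth_self, n)
  bo <- rep_len(breadth_opposite, n)
  ifelse(bs >= params$lost_thresh, "present",
         ifelse(bo > params$he_thresh, "within-HE", "lost"))
}

#' PAV pipeline for one sample
#'
#' Computes, for every annotated gene, the breadth of its locus on the
#' tetraploid reference by origin-concordant reads (`breadth_self`) and by
#' origin-discordant reads (`breadth_opposite`), then applies
#' [call_gene_status()].
#'
#' @param records origin-tagged records for one sample ([tag_and_remap()]).
#' @param genes gene table with `chrom`, `start`, `end`, `gene_id`,
#'   `subgenome`.
#' @param chrom_lengths named reference lengths.
#' @param params a [pav_params()].
#' @return data.frame: `gene_id`, `breadth_self`, `breadth_opposite`,
#'   `status`.
#' @export
pav_call_sample <- function(records, genes, chrom_lengths,
                            params = pav_params()) {
  rec_a <- records[records$mapped & records$origin_tag %in% "A", ,
                   drop = FALSE]
  rec_b <- records[records$mapped & records$origin_tag %in% "B", ,
                   drop = FALSE]
  br_a <- gene_breadth(rec_a, genes, chrom_lengths)
  br_b <- gene_breadth(rec_b, genes, chrom_lengths)
  self <- ifelse(genes$subgenome == "A", br_a, br_b)
  opp <- ifelse(genes$subgenome == "A", br_b, br_a)
  data.frame(gene_id = genes$gene_id, breadth_self = self,
             breadth_opposite = opp,
             status = call_gene_status(self, opp, params),
             stringsAsFactors = FALSE)
}

#' Core and dispensable gene sets across samples
#'
#' @param status_table data.frame or matrix of statuses, genes in rows,
#'   samples in columns (values "present"/"lost"/"within-HE"); rownames are
#'   gene ids.
#' @return list with `core` and `dispensable` character vectors; the two
#'   partition the gene universe.
#' @export
core_dispensable <- function(status_table) {
  m <- as.matrix(status_table)
  if (is.null(rownames(m))) rownames(m) <- seq_len(nrow(m))
  if (any(is.na(m))) stop("ragged status table")
  all_present <- apply(m == "present", 1, all)
  list(core = rownames(m)[all_present],
       dispensable = rownames(m)[!all_present])
}

#' Windowed normalized depth profile
#'
#' Mean per-base depth per window divided by the genome-wide median window
#' depth (the mean and median raw depths are attached as attributes, the
#' plotting convention for coverage figures).
#'
#' @param records alignment records.
#' @param chrom_lengths named reference lengths.
#' @param window window size in bases.
#' @return data.frame `chrom`, `start`, `end`, `depth` (raw mean),
#'   `norm_depth`; attributes `mean_depth`, `median_depth`.
#' @export
depth_profile <- function(records, chrom_lengths, window = 10000) {
  if (!length(chrom_lengths) || sum(chrom_lengths) == 0)
    stop("zero-length genome")
  cov <- records_coverage(records, chrom_lengths)
  out <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    nw <- as.integer(ceiling(len / window))
    starts <- (seq_len(nw) - 1L) * window
    ends <- pmin(seq_len(nw) * window, len)
    v <- as.numeric(cov[[ch]])
    cs <- c(0, cumsum(v))
    data.frame(chrom = ch, start = starts, end = ends,
               depth = (cs[ends + 1L] - cs[starts + 1L]) / (ends - starts),
               stringsAsFactors = FALSE)
  })
  prof <- do.call(rbind, out)
  med <- stats::median(prof$depth)
  prof$norm_depth <- if (med > 0) prof$depth / med else prof$depth
  attr(prof, "mean_depth") <- mean(prof$depth)
  attr(prof, "median_depth") <- med
  attr(prof, "window") <- window
  prof
}

#' Segment a depth profile into copy-number states
#'
#' Each window adopts the nearest copy state within `state_tolerance`
#' (others inherit by neighbor majority during merging); maximal runs of
#' equal state form segments; segments shorter than `min_segment` are
#' absorbed into the dominant (longer) neighbor. Segments partition each
#' chromosome and adjacent segments differ in state.
#'
#' @param profile from [depth_profile()].
#' @param params a [cnv_params()].
#' @return data.frame of segments: `chrom`, `start`, `end`, `state`,
#'   `mean_norm_depth`, plus breakpoint columns filled by
#'   [refine_breakpoints()].
#' @export
segment_cnv <- function(profile, params = cnv_params()) {
  segs <- list()
  for (ch in unique(profile$chrom)) {
    p <- profile[profile$chrom == ch, , drop = FALSE]
    d <- abs(outer(p$norm_depth, params$states, "-"))
    nearest <- apply(d, 1, which.min)
    state <- params$states[nearest]
    state[d[cbind(seq_len(nrow(p)), nearest)] > params$state_tolerance] <- NA
    # no-call windows inherit the nearest called neighbor's state
    if (anyNA(state) && !all(is.na(state))) {
      called <- which(!is.na(state))
      for (i in which(is.na(state))) {
        state[i] <- state[called[which.min(abs(called - i))]]
      }
    }
    if (all(is.na(state))) state[] <- 1
    r <- rle(state)
    repeat {
      if (length(r$lengths) <= 1) break
      lens_bp <- r$lengths * (p$end[1] - p$start[1])
      small <- which(lens_bp < params$min_segment)
      if (!length(small)) break
      i <- small[which.min(r$lengths[small])]
      left <- if (i > 1) r$lengths[i - 1] else -1
      right <- if (i < length(r$lengths)) r$lengths[i + 1] else -1
      r$values[i] <- if (left >= right) r$values[i - 1] else r$values[i + 1]
      r <- rle(inverse.rle(r))
    }
    ends_i <- cumsum(r$lengths)
    starts_i <- c(1, utils::head(ends_i, -1) + 1)
    for (j in seq_along(r$values)) {
      idx <- starts_i[j]:ends_i[j]
      segs[[length(segs) + 1]] <- data.frame(
        chrom = ch, start = p$start[starts_i[j]], end = p$end[ends_i[j]],
        state = r$values[j], mean_norm_depth = mean(p$norm_depth[idx]),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, segs)
  out$bp_start_exact <- NA_integer_
  out$bp_end_exact <- NA_integer_
  out$approximate <- TRUE
  out$partner_chrom <- NA_character_
  out$partner_pos <- NA_integer_
  out
}

#' Refine segment breakpoints with split reads
#'
#' Segment boundaries from depth segmentation carry window-resolution
#' coordinates. For each boundary of a non-reference-state segment, clip
#' positions of split reads within `search` bases of the boundary are
#' examined; when at least `min_support` of them cluster within `radius`
#' of the modal clip position, the boundary moves to that position and
#' the partner locus becomes the modal clipped-partner locus (linking,
#' e.g., a duplication to the region it copies). Boundaries without split
#' support keep their window-resolution coordinates and stay flagged
#' approximate.
#'
#' @param segments from [segment_cnv()].
#' @param records alignment records with partner fields ([map_reads()]).
#' @param search how far from the window-resolution boundary the true
#'   junction may sit, in bases (at least the profile window size).
#' @param radius clustering radius around the modal clip position.
#' @param min_support minimum clustered split reads.
#' @param min_clip minimum soft-clip length for a read to vote.
#' @return `segments` with `bp_start_exact`, `bp_end_exact`,
#'   `approximate`, `partner_chrom`, `partner_pos` filled where supported.
#' @export
refine_breakpoints <- function(segments, records, search = 15000,
                               radius = 500, min_support = 2,
                               min_clip = 10) {
  # every clip of at least min_clip bases votes for a boundary position
  # (error-induced clips are shorter); partner loci come from the subset
  # whose clipped portion itself mapped
  sp <- records[records$mapped &
                  (pmax(records$clip_left, records$clip_right) >= min_clip), ,
                drop = FALSE]
  if (!nrow(sp)) return(segments)
  clip_pos <- ifelse(sp$clip_left >= sp$clip_right, sp$pos,
                     sp$pos + sp$aln_len)
  partner_junction <- ifelse(is.na(sp$partner_side), NA_integer_,
                      ifelse(sp$partner_side == "R", sp$partner_pos,
                             sp$partner_pos + sp$partner_len))
  # a split read marks two junction endpoints; both vote for boundaries,
  # each carrying the opposite endpoint as its partner locus
  has_p <- !is.na(sp$partner_rname)
  ev <- rbind(
    data.frame(chrom = sp$rname, pos = clip_pos,
               other_chrom = sp$partner_rname, other_pos = partner_junction,
               stringsAsFactors = FALSE),
    data.frame(chrom = sp$partner_rname[has_p],
               pos = partner_junction[has_p],
               other_chrom = sp$rname[has_p], other_pos = clip_pos[has_p],
               stringsAsFactors = FALSE))
  modal <- function(x) as.integer(names(sort(table(x),
                                             decreasing = TRUE))[1])
  for (i in seq_len(nrow(segments))) {
    if (segments$state[i] == 1) next
    ch <- segments$chrom[i]
    for (side in c("start", "end")) {
      b <- segments[[side]][i]
      near <- which(ev$chrom == ch & abs(ev$pos - b) <= search)
      if (length(near) >= min_support) {
        bp <- modal(ev$pos[near])
        at_mode <- near[abs(ev$pos[near] - bp) <= radius]
        if (length(at_mode) < min_support) next
        at_mode <- at_mode[ev$pos[at_mode] == bp]
        col <- if (side == "start") "bp_start_exact" else "bp_end_exact"
        segments[[col]][i] <- bp
        segments$approximate[i] <- FALSE
        with_p <- at_mode[!is.na(ev$other_chrom[at_mode])]
        if (length(with_p)) {
          segments$partner_chrom[i] <-
            names(sort(table(ev$other_chrom[with_p]),
                       decreasing = TRUE))[1]
          segments$partner_pos[i] <- modal(ev$other_pos[with_p])
        }
      }
    }
  }
  segments
}
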