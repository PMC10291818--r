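# Truth-set comparison helpers for simulated studies: per-block interval
# Jaccard for HE recovery, precision/recall for PAV calls, and breakpoint
# errors for CNV segments.

#' Per-truth-block Jaccard overlap of called intervals
#'
#' For each truth interval, the called blocks on the same chromosome are
#' merged and the Jaccard index |called ∩ truth| / |called ∪ truth| is
#' computed against the union of calls overlapping that truth interval.
#' Called blocks overlapping no truth interval are false blocks.
#'
#' @param called data.frame with `chrom`, `start`, `end`.
#' @param truth data.frame with `chrom`, `start`, `end`.
#' @return list: `per_truth` (truth table plus `jaccard`), `n_recovered`
#'   (`jaccard > 0`), `false_blocks` (called rows overlapping no truth).
#' @export
interval_jaccard <- function(called, truth) {
  gr_c <- GenomicRanges::GRanges(called$chrom,
            IRanges::IRanges(called$start + 1L, called$end))
  gr_t <- GenomicRanges::GRanges(truth$chrom,
            IRanges::IRanges(truth$start + 1L, truth$end))
  jac <- numeric(nrow(truth))
  hit_called <- rep(FALSE, nrow(called))
  ov <- GenomicRanges::findOverlaps(gr_t, gr_c)
  for (i in seq_len(nrow(truth))) {
    ci <- S4Vectors::subjectHits(ov)[S4Vectors::queryHits(ov) == i]
    if (!length(ci)) next
    hit_called[ci] <- TRUE
    u <- GenomicRanges::reduce(c(gr_c[ci], gr_t[i]))
    inter <- GenomicRanges::intersect(GenomicRanges::reduce(gr_c[ci]),
                                      gr_t[i])
    jac[i] <- sum(GenomicRanges::width(inter)) /
      sum(GenomicRanges::width(u))
  }
  truth$jaccard <- jac
  list(per_truth = truth, n_recovered = sum(jac > 0),
       false_blocks = called[!hit_called, , drop = FALSE])
}

#' Precision and recall of lost-gene calls against a deletion truth set
#'
#' @param status genes x samples status table ([pav_pipeline()]).
#' @param pav_truth data.frame with `sample`, `gene_id` of true deletions.
#' @return list with `precision`, `recall`, `tp`, `fp`, `fn`.
#' @export
pav_metrics <- function(status, pav_truth) {
  called <- which(as.matrix(status) == "lost", arr.ind = TRUE)
  called_keys <- paste(colnames(status)[called[, 2]],
                       rownames(status)[called[, 1]])
  truth_keys <- paste(pav_truth$sample, pav_truth$gene_id)
  tp <- sum(called_keys %in% truth_keys)
  fp <- sum(!called_keys %in% truth_keys)
  fn <- sum(!truth_keys %in% called_keys)
  list(precision = if (tp + fp) tp / (tp + fp) else NA_real_,
       recall = if (tp + fn) tp / (tp + fn) else NA_real_,
       tp = tp, fp = fp, fn = fn)
}

#' Match CNV segments to a truth set and report state and breakpoint errors
#'
#' Each truth event is matched to the same-state segment with the largest
#' overlap; the breakpoint error is measured against the refined
#' coordinates where available, else the window-resolution ones. When the
#' reference sequences are supplied, a called interval that is
#' shift-equivalent to the truth under junction micro-homology — both
#' breakpoints displaced by the same k with identical flanking sequence,
#' so the edited genome is byte-identical — counts as exact: the
#' breakpoint is genuinely ambiguous in such cases.
#'
#' @param segments from [segment_cnv()]/[refine_breakpoints()].
#' @param cnv_truth data.frame with `chrom`, `start`, `end`, `copy_state`.
#' @param ref optional named character vector of reference sequences for
#'   micro-homology normalization.
#' @return the truth table plus `state_called`, `state_correct`,
#'   `bp_start_err`, `bp_end_err`.
#' @export
cnv_metrics <- function(segments, cnv_truth, ref = NULL) {
  out <- cnv_truth
  out$state_called <- NA_real_
  out$state_correct <- FALSE
  out$bp_start_err <- NA_integer_
  out$bp_end_err <- NA_integer_
  for (i in seq_len(nrow(cnv_truth))) {
    s <- segments[segments$chrom == cnv_truth$chrom[i] &
                    segments$state != 1, , drop = FALSE]
    if (!nrow(s)) next
    ovl <- pmin(s$end, cnv_truth$end[i]) - pmax(s$start, cnv_truth$start[i])
    j <- which.max(ovl)
    if (ovl[j] <= 0) next
    out$state_called[i] <- s$state[j]
    out$state_correct[i] <- s$state[j] == cnv_truth$copy_state[i]
    bs <- if (!is.na(s$bp_start_exact[j])) s$bp_start_exact[j] else
      s$start[j]
    be <- if (!is.na(s$bp_end_exact[j])) s$bp_end_exact[j] else s$end[j]
    err_s <- abs(bs - cnv_truth$start[i])
    err_e <- abs(be - cnv_truth$end[i])
    if (!is.null(ref) &&
        breakpoints_equivalent(ref[[cnv_truth$chrom[i]]],
                               cnv_truth$start[i], cnv_truth$end[i],
                               bs, be)) {
      err_s <- 0L; err_e <- 0L
    }
    out$bp_start_err[i] <- err_s
    out$bp_end_err[i] <- err_e
  }
  out
}

# called interval [s2, e2) is an equivalent representation of [s1, e1)
# when both breakpoints shift by the same k and the k flanking bases agree
# between the two junction sides (deletion and tandem duplication alike)
breakpoints_equivalent <- function(seq, s1, e1, s2, e2, max_shift = 100) {
  k <- s2 - s1
  if (k != e2 - e1 || abs(k) > max_shift) return(FALSE)
  if (k == 0) return(TRUE)
  if (k > 0) {
    identical(substr(seq, s1 + 1, s1 + k), substr(seq, e1 + 1, e1 + k))
  } else {
    identical(substr(seq, s1 + k + 1, s1), substr(seq, e1 + k + 1, e1))
  }
}
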