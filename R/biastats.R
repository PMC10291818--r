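# Subgenome bias statistics: directional chi-square against equal
# expectation, rounded directional proportions, homoeolog-pair count
# matrices from origin-tagged alignments, and the genome-wide Wilcoxon
# signed-rank test of homoeolog expression bias.

#' Chi-square test of directional counts against equal expectation
#'
#' For counts a (A into B) and b (B into A), the 1-df goodness-of-fit
#' statistic against a 50:50 expectation reduces to (a - b)^2 / (a + b);
#' the p-value is the chi-square survival function. Totals below 10 fall
#' back to an exact binomial test (flagged).
#'
#' @param n_a_to_b,n_b_to_a the two directional counts.
#' @param context free-text label carried through.
#' @return data.frame: `statistic`, `p_value`, `direction` ("A", "B" or
#'   "none" — the larger side's recipient subgenome), `n`, `method`,
#'   `context`.
#' @export
chisq_equal <- function(n_a_to_b, n_b_to_a, context = "") {
  a <- n_a_to_b; b <- n_b_to_a
  if (a == 0 && b == 0) stop("both directional counts are zero")
  n <- a + b
  direction <- if (a > b) "B" else if (b > a) "A" else "none"
  if (n >= 10) {
    stat <- (a - b)^2 / n
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
    method <- "chisq"
  } else {
    stat <- NA_real_
    p <- stats::binom.test(a, n, 0.5)$p.value
    method <- "exact-binomial"
  }
  data.frame(statistic = stat, p_value = p, direction = direction, n = n,
             method = method, context = context, stringsAsFactors = FALSE)
}

#' Directional proportion as an integer percent
#'
#' 100 * a / (a + b), rounded half-up to a whole percent (matching how
#' such shares are conventionally printed).
#'
#' @param n_a_to_b,n_b_to_a the two directional counts.
#' @return integer percent.
#' @export
proportion <- function(n_a_to_b, n_b_to_a) {
  tot <- n_a_to_b + n_b_to_a
  if (tot == 0) stop("zero total count")
  as.integer(floor(100 * n_a_to_b / tot + 0.5))
}

#' Homoeolog-specific count matrix from origin-tagged alignments
#'
#' Every unambiguously tagged alignment overlapping a gene increments that
#' gene's subgenome counter in its homoeolog pair's row (ambiguous and
#' novel tags are excluded; an alignment overlapping several genes counts
#' once, toward the largest overlap). Alignments on genes absent from the
#' pair map land in an "unpaired" bucket, reported alongside.
#'
#' @param records origin-tagged alignment records.
#' @param genes gene table (`chrom`, `start`, `end`, `gene_id`).
#' @param pair_map data.frame with `pair_id`, `gene_A`, `gene_B`.
#' @return list: `matrix` (data.frame `pair_id`, `count_a`, `count_b`),
#'   `n_assigned`, `unpaired` (named counts per unpaired gene).
#' @export
homoeolog_counts <- function(records, genes, pair_map) {
  r <- records[records$mapped & records$origin_tag %in% c("A", "B"), ,
               drop = FALSE]
  counts <- stats::setNames(integer(nrow(genes)), genes$gene_id)
  if (nrow(r)) {
    gr_g <- GenomicRanges::GRanges(genes$chrom,
              IRanges::IRanges(genes$start + 1L, genes$end))
    gr_r <- GenomicRanges::GRanges(r$rname,
              IRanges::IRanges(r$pos + 1L, r$pos + r$aln_len))
    ov <- GenomicRanges::findOverlaps(gr_r, gr_g)
    if (length(ov)) {
      qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
      wdt <- GenomicRanges::width(GenomicRanges::pintersect(gr_r[qh],
                                                            gr_g[sh]))
      # one gene per alignment: the largest overlap, ties to the first
      o <- order(qh, -wdt, sh)
      first <- !duplicated(qh[o])
      hit_read <- qh[o][first]; hit_gene <- sh[o][first]
      tab <- table(hit_gene)
      counts[as.integer(names(tab))] <- as.integer(tab)
    }
  }
  gene_to_pair_a <- stats::setNames(pair_map$pair_id, pair_map$gene_A)
  gene_to_pair_b <- stats::setNames(pair_map$pair_id, pair_map$gene_B)
  m <- data.frame(pair_id = pair_map$pair_id,
                  count_a = as.integer(counts[pair_map$gene_A]),
                  count_b = as.integer(counts[pair_map$gene_B]),
                  stringsAsFactors = FALSE)
  m$count_a[is.na(m$count_a)] <- 0L
  m$count_b[is.na(m$count_b)] <- 0L
  m$testable <- (m$count_a + m$count_b) > 0
  paired_genes <- c(pair_map$gene_A, pair_map$gene_B)
  unpaired <- counts[!names(counts) %in% paired_genes]
  unpaired <- unpaired[unpaired > 0]
  list(matrix = m, n_assigned = sum(counts), unpaired = unpaired)
}

#' Genome-wide homoeolog expression-bias test
#'
#' Per testable pair the log2 ratio (count_B + 0.5)/(count_A + 0.5) is
#' computed; a two-sided Wilcoxon signed-rank test checks whether the
#' log-ratios are centered on zero. Direction follows the sign of the
#' median log-ratio. When a `chrom` column (homoeologous chromosome pair)
#' is present, the test is repeated per chromosome.
#'
#' @param count_matrix data.frame with `count_a`, `count_b` and optionally
#'   `pair_id`, `chrom`.
#' @param min_total minimum pair total count to be testable.
#' @param min_pairs minimum testable pairs required.
#' @param pseudocount added to both counts in the log-ratio.
#' @return data.frame of `BiasResult` rows (`scope`, `statistic`,
#'   `p_value`, `direction`, `n`, `median_log2_ratio`), genome-wide first.
#' @export
expression_bias_test <- function(count_matrix, min_total = 10,
                                 min_pairs = 20, pseudocount = 0.5) {
  cm <- count_matrix
  cm$total <- cm$count_a + cm$count_b
  test_one <- function(sub, scope) {
    sub <- sub[sub$total >= min_total, , drop = FALSE]
    lr <- log2((sub$count_b + pseudocount) / (sub$count_a + pseudocount))
    lr <- lr[is.finite(lr)]
    if (length(lr) < min_pairs)
      return(data.frame(scope = scope, statistic = NA_real_,
                        p_value = NA_real_, direction = NA_character_,
                        n = length(lr), median_log2_ratio = NA_real_,
                        stringsAsFactors = FALSE))
    # exact signed-rank null when feasible (small n, no ties/zeros),
    # normal approximation with continuity correction otherwise
    wt <- suppressWarnings(
      stats::wilcox.test(lr, mu = 0, alternative = "two.sided",
                         correct = TRUE))
    med <- stats::median(lr)
    direction <- if (wt$p.value < 0.05) {
      if (med > 0) "B" else if (med < 0) "A" else "none"
    } else "none"
    data.frame(scope = scope, statistic = unname(wt$statistic),
               p_value = wt$p.value, direction = direction,
               n = length(lr), median_log2_ratio = med,
               stringsAsFactors = FALSE)
  }
  out <- test_one(cm, "genome")
  if (out$n < min_pairs)
    stop("fewer than ", min_pairs, " testable homoeolog pairs")
  if (!is.null(cm$chrom)) {
    for (ch in sort(unique(cm$chrom))) {
      out <- rbind(out, test_one(cm[cm$chrom == ch, , drop = FALSE], ch))
    }
  }
  out
}
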