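# End-to-end drivers tying the modules together: classify reads against
# the parents, re-map to the tetraploid with origin tags, then paint/call
# HEs, call PAV, or segment CNVs.

#' Flatten a paired read set into one read table
#'
#' @param reads list with `r1`/`r2` data.frames ([simulate_reads()]).
#' @return single data.frame with `name`, `seq`.
#' @export
combine_pairs <- function(reads) {
  rbind(reads$r1, reads$r2)
}

#' Classify reads against the parents and re-map to the tetraploid
#'
#' The DNA-read origin pipeline: competitive primary mapping against each
#' parental genome, then re-mapping to the allotetraploid reference with
#' origin tags (`A`/`B`/`U`/`N`).
#'
#' @param reads_df data.frame with `name`, `seq` ([combine_pairs()]).
#' @param parent_a,parent_b named character vectors (parental genomes) or
#'   prebuilt [build_index()] handles.
#' @param tetraploid named character vector or index of the tetraploid.
#' @param k k-mer size for indexes built here.
#' @param ... further arguments to [map_reads()].
#' @return list: `calls` (per-read origin), `records` (tagged tetraploid
#'   alignments), `chrom_lengths` (tetraploid).
#' @export
origin_pipeline <- function(reads_df, parent_a, parent_b, tetraploid,
                            k = 17, ...) {
  ia <- if (inherits(parent_a, "ph_index")) parent_a else
    build_index(parent_a, k)
  ib <- if (inherits(parent_b, "ph_index")) parent_b else
    build_index(parent_b, k)
  it <- if (inherits(tetraploid, "ph_index")) tetraploid else
    build_index(tetraploid, k)
  calls <- classify_by_primary_mapping(reads_df, ia, ib, ...)
  records <- tag_and_remap(reads_df, calls, it, ...)
  list(calls = calls, records = records,
       chrom_lengths = attr(it, "chrom_lengths"))
}

#' Call HE blocks from tagged records
#'
#' @param records origin-tagged records.
#' @param chrom_lengths named tetraploid chromosome lengths.
#' @param expected_origin named vector of expected subgenome per
#'   chromosome; derived from trailing A/B letters when `NULL`.
#' @param params a [he_params()].
#' @return list with `track` ([paint()]) and `blocks` ([call_blocks()]).
#' @export
he_pipeline <- function(records, chrom_lengths, expected_origin = NULL,
                        params = he_params()) {
  if (is.null(expected_origin)) {
    expected_origin <- stats::setNames(chrom_role(names(chrom_lengths)),
                                       names(chrom_lengths))
  }
  track <- paint(records, chrom_lengths, params)
  blocks <- call_blocks(track, expected_origin, params, records = records)
  list(track = track, blocks = blocks)
}

#' PAV status table across samples
#'
#' @param sample_records named list of tagged record sets, one per sample.
#' @param genes gene table with `subgenome` column.
#' @param chrom_lengths named tetraploid chromosome lengths.
#' @param params a [pav_params()].
#' @return list: `status` (genes x samples data.frame of calls),
#'   `core_dispensable` ([core_dispensable()]).
#' @export
pav_pipeline <- function(sample_records, genes, chrom_lengths,
                         params = pav_params()) {
  cols <- lapply(sample_records, function(rec)
    pav_call_sample(rec, genes, chrom_lengths, params)$status)
  status <- as.data.frame(cols, optional = TRUE)
  rownames(status) <- genes$gene_id
  colnames(status) <- names(sample_records)
  list(status = status, core_dispensable = core_dispensable(status))
}
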