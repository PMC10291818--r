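# Molecular dating. Synonymous divergence between coding pairs by the
# Nei-Gojobori (1986) counting method with Jukes-Cantor correction, LTR
# terminal-repeat divergence, kernel-density peak detection, and conversion
# of divergence K to time via T = K / (2 * mu).

#' Rate constants for dating
#'
#' @param mu_ks substitutions per synonymous site per year for Ks dating
#'   (default the Poaceae rate 5.76174e-9).
#' @param mu_ltr substitutions per site per year for LTR dating (default
#'   the rice rate 1.3e-8).
#' @return validated list.
#' @export
rate_constants <- function(mu_ks = 5.76174e-9, mu_ltr = 1.3e-8) {
  stopifnot(mu_ks > 0, mu_ltr > 0)
  list(mu_ks = mu_ks, mu_ltr = mu_ltr)
}

# genetic code, stop codons excluded from synonymy but present for lookup
GENCODE <- local({
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
})

# fractional synonymous site count of one codon: per position, the
# fraction of the three possible changes that are synonymous; changes to
# stop codons count as nonsynonymous
codon_syn_sites <- function(codon) {
  if (GENCODE[[codon]] == "*") return(NA_real_)
  bases <- c("A", "C", "G", "T")
  s <- 0
  for (p in 1:3) {
    for (b in setdiff(bases, substr(codon, p, p))) {
      mut <- codon
      substr(mut, p, p) <- b
      if (GENCODE[[mut]] != "*" && GENCODE[[mut]] == GENCODE[[codon]])
        s <- s + 1 / 3
    }
  }
  s
}

SYN_SITES <- vapply(names(GENCODE), codon_syn_sites, numeric(1))

# average synonymous/nonsynonymous differences between two codons over all
# minimal mutational pathways; pathways through stop codons are excluded
# (all-blocked falls back to including them)
codon_path_diffs <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  nd <- length(pos)
  if (nd == 0) return(c(sd = 0, nd = 0))
  perms <- switch(nd, list(1L), list(c(1L, 2L), c(2L, 1L)),
                  list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                       c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))
  walk <- function(order_idx, allow_stop) {
    cur <- c1
    sd <- 0; ndn <- 0
    for (oi in order_idx) {
      p <- pos[oi]
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (!allow_stop && GENCODE[[nxt]] == "*") return(NULL)
      if (GENCODE[[nxt]] == GENCODE[[cur]] && GENCODE[[nxt]] != "*")
        sd <- sd + 1
      else ndn <- ndn + 1
      cur <- nxt
    }
    c(sd = sd, nd = ndn)
  }
  res <- Filter(Negate(is.null), lapply(perms, walk, allow_stop = FALSE))
  if (!length(res)) res <- lapply(perms, walk, allow_stop = TRUE)
  colMeans(do.call(rbind, res))
}

#' Synonymous divergence of a coding pair (Nei-Gojobori 1986)
#'
#' Fractional synonymous/nonsynonymous site counts averaged over both
#' sequences; observed differences averaged over minimal mutational
#' pathways per codon; Jukes-Cantor correction
#' Ks = -(3/4) ln(1 - (4/3) p_s). Saturation (p_s >= 3/4) is flagged
#' rather than extrapolated.
#'
#' @param cds_a,cds_b in-frame coding sequences of equal length (multiple
#'   of 3, no internal stop codons).
#' @return data.frame: `ks`, `ka`, `syn_sites`, `nonsyn_sites`,
#'   `syn_diffs`, `nonsyn_diffs`, `p_s`, `saturated`.
#' @export
ks_ng86 <- function(cds_a, cds_b) {
  cds_a <- toupper(cds_a); cds_b <- toupper(cds_b)
  if (nchar(cds_a) != nchar(cds_b)) stop("coding sequences differ in length")
  if (nchar(cds_a) %% 3 != 0) stop("length not a multiple of 3")
  n_cod <- nchar(cds_a) / 3
  ca <- substring(cds_a, 3 * seq_len(n_cod) - 2, 3 * seq_len(n_cod))
  cb <- substring(cds_b, 3 * seq_len(n_cod) - 2, 3 * seq_len(n_cod))
  keep <- !vapply(ca, function(x) is.na(SYN_SITES[[x]]), logical(1),
                  USE.NAMES = FALSE) &
          !vapply(cb, function(x) is.na(SYN_SITES[[x]]), logical(1),
                  USE.NAMES = FALSE)
  internal <- seq_len(n_cod) < n_cod
  if (any(!keep & internal))
    stop("internal stop codon in coding sequence")
  ca <- ca[keep]; cb <- cb[keep]
  S <- sum((SYN_SITES[ca] + SYN_SITES[cb]) / 2)
  N <- 3 * length(ca) - S
  diffs <- mapply(function(x, y) codon_path_diffs(x, y), ca, cb)
  Sd <- sum(diffs["sd", ])
  Nd <- sum(diffs["nd", ])
  p_s <- if (S > 0) Sd / S else 0
  p_n <- if (N > 0) Nd / N else 0
  sat <- p_s >= 0.75
  ks <- if (sat) NA_real_ else -0.75 * log(1 - (4 / 3) * p_s)
  ka <- if (p_n >= 0.75) NA_real_ else -0.75 * log(1 - (4 / 3) * p_n)
  data.frame(ks = ks, ka = ka, syn_sites = S, nonsyn_sites = N,
             syn_diffs = Sd, nonsyn_diffs = Nd, p_s = p_s,
             saturated = sat)
}

#' Ks for a set of homoeologous gene pairs
#'
#' @param cds_a,cds_b named character vectors of paired coding sequences
#'   (matched by position).
#' @param pair_ids identifiers (defaults to names of `cds_a`).
#' @return data.frame with one [ks_ng86()] row per pair plus `pair_id`.
#' @export
ks_pairs <- function(cds_a, cds_b, pair_ids = names(cds_a)) {
  stopifnot(length(cds_a) == length(cds_b))
  if (is.null(pair_ids)) pair_ids <- paste0("pair", seq_along(cds_a))
  out <- do.call(rbind, mapply(ks_ng86, cds_a, cds_b, SIMPLIFY = FALSE))
  out$pair_id <- pair_ids
  rownames(out) <- NULL
  out
}

#' Density peaks of a set of divergence values
#'
#' Gaussian kernel density estimate; local maxima in descending density
#' order. The half-height interval of the primary peak is attached. The
#' default bandwidth is Silverman's rule doubled (`adjust = 2`): peak
#' *location* is the target here, and mild oversmoothing stops sampling
#' bumps — and the substitution-count discreteness of young divergences —
#' from displacing the maximum, while leaving well-separated modes (e.g. a
#' speciation peak versus an ancient-WGD peak) distinct.
#'
#' @param values numeric vector (at least 5 values).
#' @param bw kernel bandwidth, or "nrd0" for Silverman's default.
#' @param adjust bandwidth multiplier (as in [stats::density()]).
#' @return data.frame `peak`, `density`, ordered by density; attributes
#'   `halfheight_low`/`halfheight_high` for the primary peak.
#' @export
ks_peak <- function(values, bw = "nrd0", adjust = 2) {
  values <- values[is.finite(values)]
  if (length(values) < 5) stop("need at least 5 values for a density peak")
  if (length(unique(values)) == 1) {
    out <- data.frame(peak = values[1], density = Inf)
    attr(out, "halfheight_low") <- values[1]
    attr(out, "halfheight_high") <- values[1]
    return(out)
  }
  d <- stats::density(values, bw = bw, adjust = adjust)
  y <- d$y
  locmax <- which(diff(sign(diff(y))) == -2) + 1L
  if (y[1] > y[2]) locmax <- c(1L, locmax)
  n <- length(y)
  if (y[n] > y[n - 1]) locmax <- c(locmax, n)
  locmax <- locmax[order(y[locmax], decreasing = TRUE)]
  out <- data.frame(peak = d$x[locmax], density = y[locmax])
  half <- y[locmax[1]] / 2
  above <- which(y >= half)
  attr(out, "halfheight_low") <- d$x[min(above)]
  attr(out, "halfheight_high") <- d$x[max(above)]
  out
}

#' Convert divergence to time: T = K / (2 mu)
#'
#' @param k divergence (substitutions per site), >= 0.
#' @param mu substitution rate per site per year, > 0.
#' @return time in years.
#' @export
divergence_time <- function(k, mu) {
  if (any(k < 0)) stop("K must be >= 0")
  if (any(mu <= 0)) stop("mu must be > 0")
  k / (2 * mu)
}

#' Divergence between the two terminal repeats of an LTR element
#'
#' Repeats are compared column-wise after end-trimming to a common length
#' (simulated repeats carry no indels; supply externally aligned repeats
#' for gapped real data). Mismatch fraction is Jukes-Cantor corrected
#' unless `raw = TRUE`.
#'
#' @param repeat5,repeat3 the two terminal repeat sequences.
#' @param raw if `TRUE`, return the raw mismatch fraction.
#' @return data.frame `k`, `p`, `n_sites`, `saturated`.
#' @export
ltr_pair_divergence <- function(repeat5, repeat3, raw = FALSE) {
  len <- min(nchar(repeat5), nchar(repeat3))
  if (len == 0) stop("empty repeat sequence")
  a <- strsplit(toupper(substr(repeat5, 1, len)), "")[[1]]
  b <- strsplit(toupper(substr(repeat3, 1, len)), "")[[1]]
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  p <- sum(a[ok] != b[ok]) / sum(ok)
  sat <- p >= 0.75
  k <- if (raw) p else if (sat) NA_real_ else -0.75 * log(1 - (4 / 3) * p)
  data.frame(k = k, p = p, n_sites = sum(ok), saturated = sat)
}

#' Insertion-age distribution of LTR elements
#'
#' Ages are T = K / (2 mu_ltr); kernel-density peaks as in [ks_peak()].
#'
#' @param k_values repeat-pair divergences.
#' @param mu_ltr substitution rate per site per year.
#' @param bw,adjust bandwidth controls passed to [ks_peak()].
#' @return list with `ages` (years) and `peaks` (data.frame as in
#'   [ks_peak()], on the age axis).
#' @export
insertion_age_distribution <- function(k_values, mu_ltr = 1.3e-8,
                                       bw = "nrd0", adjust = 2) {
  k_values <- k_values[is.finite(k_values)]
  ages <- divergence_time(k_values, mu_ltr)
  list(ages = ages, peaks = ks_peak(ages, bw = bw, adjust = adjust))
}
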