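# Independent brute-force Nei-Gojobori oracle. Deliberately written as a
# different algorithm from the package implementation: the codon table is
# hard-coded, site counts are enumerated mutation by mutation, and pathway
# averaging enumerates permutations recursively.

.aa <- local({
  tab <- c(
    TTT = "F", TTC = "F", TTA = "L", TTG = "L", CTT = "L", CTC = "L",
    CTA = "L", CTG = "L", ATT = "I", ATC = "I", ATA = "I", ATG = "M",
    GTT = "V", GTC = "V", GTA = "V", GTG = "V", TCT = "S", TCC = "S",
    TCA = "S", TCG = "S", CCT = "P", CCC = "P", CCA = "P", CCG = "P",
    ACT = "T", ACC = "T", ACA = "T", ACG = "T", GCT = "A", GCC = "A",
    GCA = "A", GCG = "A", TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
    CAT = "H", CAC = "H", CAA = "Q", CAG = "Q", AAT = "N", AAC = "N",
    AAA = "K", AAG = "K", GAT = "D", GAC = "D", GAA = "E", GAG = "E",
    TGT = "C", TGC = "C", TGA = "*", TGG = "W", CGT = "R", CGC = "R",
    CGA = "R", CGG = "R", AGT = "S", AGC = "S", AGA = "R", AGG = "R",
    GGT = "G", GGC = "G", GGA = "G", GGG = "G")
  tab
})

oracle_syn_sites_codon <- function(codon) {
  nt <- c("A", "C", "G", "T")
  total <- 0
  for (p in 1:3) {
    orig <- substr(codon, p, p)
    for (b in nt[nt != orig]) {
      mut <- paste0(substr(codon, 1, p - 1), b, substr(codon, p + 1, 3))
      if (.aa[[mut]] != "*" && .aa[[mut]] == .aa[[codon]])
        total <- total + 1 / 3
    }
  }
  total
}

# recursive enumeration of substitution orderings between two codons
oracle_paths <- function(from, to, skip_stops = TRUE) {
  diff_pos <- which(strsplit(from, "")[[1]] != strsplit(to, "")[[1]])
  if (!length(diff_pos)) return(list(c(sd = 0, nd = 0)))
  out <- list()
  for (p in diff_pos) {
    step <- paste0(substr(from, 1, p - 1), substr(to, p, p),
                   substr(from, p + 1, 3))
    if (skip_stops && .aa[[step]] == "*") next
    syn <- .aa[[step]] == .aa[[from]] && .aa[[step]] != "*"
    rest <- oracle_paths(step, to, skip_stops)
    for (r in rest) {
      out[[length(out) + 1]] <- r + c(sd = as.integer(syn),
                                      nd = as.integer(!syn))
    }
  }
  out
}

oracle_ng86 <- function(a, b) {
  n <- nchar(a) / 3
  S <- 0; Sd <- 0; Nd <- 0
  for (i in seq_len(n)) {
    ca <- substr(a, 3 * i - 2, 3 * i)
    cb <- substr(b, 3 * i - 2, 3 * i)
    if (.aa[[ca]] == "*" || .aa[[cb]] == "*") next
    S <- S + (oracle_syn_sites_codon(ca) + oracle_syn_sites_codon(cb)) / 2
    paths <- oracle_paths(ca, cb, skip_stops = TRUE)
    if (!length(paths)) paths <- oracle_paths(ca, cb, skip_stops = FALSE)
    m <- do.call(rbind, paths)
    Sd <- Sd + mean(m[, "sd"])
    Nd <- Nd + mean(m[, "nd"])
  }
  Nsites <- 3 * sum(vapply(seq_len(n), function(i) {
    ca <- substr(a, 3 * i - 2, 3 * i); cb <- substr(b, 3 * i - 2, 3 * i)
    .aa[[ca]] != "*" && .aa[[cb]] != "*"
  }, logical(1))) - S
  p_s <- if (S > 0) Sd / S else 0
  list(S = S, N = Nsites, Sd = Sd, Nd = Nd, p_s = p_s,
       ks = if (p_s < 0.75) -0.75 * log(1 - 4 / 3 * p_s) else NA_real_)
}

# random in-frame CDS without internal stops
random_cds <- function(n_codons, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sense <- names(.aa)[.aa != "*"]
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}

# exact two-sided signed-rank p-value by full sign enumeration
exact_signed_rank_p <- function(x) {
  x <- x[x != 0]
  n <- length(x)
  r <- rank(abs(x))
  v_obs <- sum(r[x > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- signs %*% r
  ev <- n * (n + 1) / 4
  mean(abs(v_all - ev) >= abs(v_obs - ev) - 1e-9)
}
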