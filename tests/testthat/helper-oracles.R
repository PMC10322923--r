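# Independent brute-force oracles. Deliberately naive: plain loops and
# enumeration, no shared code with the implementation paths they check.

# every 0-based start of "TTAA" in a character string
oracle_ttaa_scan <- function(seq_str) {
  out <- integer()
  for (i in seq_len(nchar(seq_str) - 3L))
    if (substr(seq_str, i, i + 3L) == "TTAA") out <- c(out, i - 1L)
  out
}

# distinct events / sites by explicit string sets
oracle_collapse_counts <- function(records) {
  ev <- unique(paste(records$experiment_id, records$chrom, records$pos,
                     records$orientation))
  si <- unique(paste(records$chrom, records$pos, records$orientation))
  list(n_events = length(ev), n_sites = length(si))
}

# all-pairs nearest gene within window; ties broken by gene_id
oracle_nearest_gene <- function(sites, genes, window) {
  res <- vector("list", nrow(sites))
  for (i in seq_len(nrow(sites))) {
    best_d <- Inf; best_g <- NA_character_
    for (j in seq_len(nrow(genes))) {
      if (genes$chrom[j] != sites$chrom[i]) next
      p <- sites$pos[i]
      d <- if (p >= genes$start[j] && p < genes$end[j]) 0L
        else min(abs(genes$start[j] - p), abs(p - (genes$end[j] - 1L)))
      if (d < best_d || (d == best_d && !is.na(best_g) &&
                         genes$gene_id[j] < best_g)) {
        best_d <- d; best_g <- genes$gene_id[j]
      }
    }
    if (is.finite(best_d) && best_d <= window)
      res[[i]] <- data.frame(pos = sites$pos[i], chrom = sites$chrom[i],
                             gene_id = best_g, distance_bp = best_d)
  }
  do.call(rbind, res)
}

# upper binomial tail by direct summation
oracle_binom_upper <- function(k, n, p) {
  if (k <= 0) return(1)
  s <- 0
  for (x in k:n) s <- s + choose(n, x) * p^x * (1 - p)^(n - x)
  s
}

# lower binomial CDF by direct summation
oracle_binom_lower <- function(k, n, p) {
  s <- 0
  for (x in 0:k) s <- s + choose(n, x) * p^x * (1 - p)^(n - x)
  s
}

# P(overlap >= k) by exhaustive enumeration of query draws (N <= ~20)
oracle_hyper_enum <- function(k, N, n_set, n_query) {
  marked <- seq_len(n_set)
  combos <- utils::combn(N, n_query)
  hits <- apply(combos, 2L, function(cc) sum(cc %in% marked))
  mean(hits >= k)
}

# one-sided Fisher p for a 2x2 table (a b / c d) by hypergeometric
# summation over tables with the same margins and larger 'a'
oracle_fisher_greater <- function(a, b, c_, d) {
  m <- a + c_; n <- b + d; k <- a + b
  s <- 0
  for (x in a:min(m, k))
    s <- s + choose(m, x) * choose(n, k - x) / choose(m + n, k)
  s
}

# IUPAC consensus hits at every offset, both strands, by char loops
oracle_consensus_scan <- function(seq_str, consensus) {
  codes <- list(A = "A", C = "C", G = "G", T = "T",
                R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                B = c("C", "G", "T"), D = c("A", "G", "T"),
                H = c("A", "C", "T"), V = c("A", "C", "G"),
                N = c("A", "C", "G", "T"))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rc <- function(s) paste(rev(comp[strsplit(s, "")[[1L]]]), collapse = "")
  match_at <- function(s, pat, off) {
    for (k in seq_len(nchar(pat))) {
      ch <- substr(s, off + k, off + k)
      if (!(ch %in% codes[[substr(pat, k, k)]])) return(FALSE)
    }
    TRUE
  }
  w <- nchar(consensus)
  L <- nchar(seq_str)
  hits <- list()
  for (off in 0:(L - w)) {
    if (match_at(seq_str, consensus, off))
      hits[[length(hits) + 1L]] <- c(off, "+")
    if (match_at(rc(seq_str), consensus, L - w - off))
      hits[[length(hits) + 1L]] <- c(off, "-")
  }
  if (!length(hits)) return(data.frame(offset = integer(),
                                       strand = character()))
  m <- do.call(rbind, hits)
  data.frame(offset = as.integer(m[, 1L]), strand = m[, 2L],
             stringsAsFactors = FALSE)
}

# random integration records
random_records <- function(n, n_exp = 3L, n_chrom = 2L, max_pos = 5000L,
                          seed = 1L) {
  set.seed(seed)
  data.frame(
    experiment_id = sprintf("exp%d", sample.int(n_exp, n, TRUE)),
    sample_id = sprintf("s%d", sample.int(4L, n, TRUE)),
    chrom = sprintf("chr%d", sample.int(n_chrom, n, TRUE)),
    pos = sample.int(max_pos, n, TRUE) - 1L,
    orientation = sample(c("+", "-"), n, TRUE),
    read_count = sample.int(20L, n, TRUE),
    stringsAsFactors = FALSE)
}

tiny_genome <- function(seqs) Biostrings::DNAStringSet(seqs)
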