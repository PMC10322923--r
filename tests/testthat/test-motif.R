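demo_genome <- local({
  set.seed(77)
  tiny_genome(c(chr1 = paste(sample(c("A", "C", "G", "T"), 12000,
                                    replace = TRUE), collapse = "")))
})

test_that("promoter windows: coordinates, reverse complement, truncation", {
  genes <- data.frame(
    gene_id = c("plus", "minus", "edge"), chrom = "chr1",
    start = c(5000L, 2000L, 0L), end = c(6000L, 3000L, 500L),
    strand = c("+", "-", "+"), tss = c(5000L, 2999L, 10L),
    stringsAsFactors = FALSE)
  pr <- extract_promoters(genes, demo_genome)
  expect_identical(c(pr$start[1L], pr$end[1L]), c(4000L, 5100L))
  expect_identical(nchar(pr$seq[1L]), 1100L)
  expect_identical(pr$truncated, c(FALSE, FALSE, TRUE))
  ## minus-strand promoter is the reverse complement of its window
  raw <- substr(as.character(demo_genome[[1L]]), pr$start[2L] + 1L,
                pr$end[2L])
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rc <- paste(rev(comp[strsplit(raw, "")[[1L]]]), collapse = "")
  expect_identical(pr$seq[2L], rc)
  expect_error(extract_promoters(
    data.frame(gene_id = "x", chrom = "chr1", start = 1L, end = 2L,
               strand = "+", tss = 90000L), demo_genome), "outside")
})

test_that("a window equal to the consensus gives one forward hit at 0", {
  prom <- data.frame(gene_id = "g1", seq = "TGCACGC",
                     stringsAsFactors = FALSE)
  sc <- scan_motif(prom, motif_model(consensus = mre_consensus()))
  expect_identical(sc$hits$offset, 0L)
  expect_identical(sc$hits$strand, "+")
  expect_true(sc$gene_has_hit[["g1"]])
})

test_that("consensus scanning matches the exhaustive oracle", {
  set.seed(101)
  motif <- motif_model(consensus = "TGCRCNC")
  for (rep in 1:20) {
    seq <- paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = "")
    prom <- data.frame(gene_id = "g", seq = seq,
                       stringsAsFactors = FALSE)
    got <- scan_motif(prom, motif)$hits
    want <- oracle_consensus_scan(seq, "TGCRCNC")
    got <- got[order(got$offset, got$strand), c("offset", "strand")]
    want <- want[order(want$offset, want$strand), ]
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("PWM scanning matches brute-force scoring on both strands", {
  set.seed(55)
  pfm <- matrix(sample(0:20, 4 * 8, TRUE), 4,
                dimnames = list(c("A", "C", "G", "T"), NULL))
  pfm <- sweep(pfm, 2L, colSums(pfm), function(x, s) round(100 * x / s))
  motif <- motif_model(pfm = pfm, pvalue = 1e-3)
  seqs <- vapply(1:30, function(i)
    paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = ""), "")
  prom <- data.frame(gene_id = sprintf("g%02d", 1:30), seq = seqs,
                     stringsAsFactors = FALSE)
  sc <- scan_motif(prom, motif)
  ## brute force: recompute log-odds with the same (symmetrised) bg,
  ## score every offset/strand with plain loops, threshold by the same
  ## integer cutoff implied by the hit scores present
  tab <- Biostrings::alphabetFrequency(Biostrings::DNAStringSet(seqs))
  tot <- colSums(tab[, c("A", "C", "G", "T")])
  bg0 <- tot / sum(tot)
  bg <- c(A = (bg0[["A"]] + bg0[["T"]]) / 2,
          C = (bg0[["C"]] + bg0[["G"]]) / 2,
          G = (bg0[["C"]] + bg0[["G"]]) / 2,
          T = (bg0[["A"]] + bg0[["T"]]) / 2)
  prob <- sweep(pfm + 0.8, 2L, colSums(pfm + 0.8), `/`)
  ilom <- round(log2(prob / bg) * 100)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  score_at <- function(s, off) {
    tot <- 0
    for (k in 1:8) tot <- tot + ilom[substr(s, off + k, off + k), k]
    tot
  }
  ## independent threshold: exact enumeration of all 4^8 words
  words <- as.matrix(expand.grid(rep(list(1:4), 8)))
  wscore <- integer(nrow(words))
  wprob <- rep(1, nrow(words))
  bgv <- bg[c("A", "C", "G", "T")]
  for (k in 1:8) {
    wscore <- wscore + ilom[cbind(words[, k], k)]
    wprob <- wprob * bgv[words[, k]]
  }
  svals <- sort(unique(wscore))
  tails <- vapply(svals, function(s) sum(wprob[wscore >= s]), 0)
  thr_obs <- svals[which(tails <= 1e-3)[1L]]
  expect_gte(min(round(sc$hits$score * 100)), thr_obs)
  brute <- list()
  for (i in 1:30) {
    s <- seqs[i]
    rc <- paste(rev(comp[strsplit(s, "")[[1L]]]), collapse = "")
    for (off in 0:(500 - 8)) {
      if (score_at(s, off) >= thr_obs)
        brute[[length(brute) + 1L]] <-
          data.frame(gene_id = sprintf("g%02d", i), offset = off,
                     strand = "+", score = score_at(s, off) / 100)
      if (score_at(rc, 500 - 8 - off) >= thr_obs)
        brute[[length(brute) + 1L]] <-
          data.frame(gene_id = sprintf("g%02d", i), offset = off,
                     strand = "-",
                     score = score_at(rc, 500 - 8 - off) / 100)
    }
  }
  want <- do.call(rbind, brute)
  ord <- function(d) {
    d <- d[order(d$gene_id, d$offset, d$strand), ]
    rownames(d) <- NULL
    d
  }
  expect_equal(ord(sc$hits), ord(want), tolerance = 1e-12)
  ## per-position FPR of the exact-distribution threshold is respected:
  ## expected false hits ~ 2 * n_offsets * pvalue
  expect_lt(nrow(sc$hits), 2 * 30 * 493 * 1e-3 * 5 + 10)
})

test_that("scanning is strand-symmetric under window reverse complement", {
  set.seed(7)
  seqs <- vapply(1:10, function(i)
    paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = ""), "")
  prom <- data.frame(gene_id = sprintf("g%02d", 1:10), seq = seqs,
                     stringsAsFactors = FALSE)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  prom_rc <- prom
  prom_rc$seq <- vapply(seqs, function(s)
    paste(rev(comp[strsplit(s, "")[[1L]]]), collapse = ""), "",
    USE.NAMES = FALSE)
  for (motif in list(motif_model(consensus = "TGCRCNC"),
                     motif_model(pfm = matrix(c(5, 1, 1, 13,
                                                2, 2, 14, 2,
                                                1, 16, 2, 1,
                                                9, 4, 4, 3,
                                                2, 12, 3, 3), 4),
                                 pvalue = 5e-3))) {
    a <- scan_motif(prom, motif)$hits
    b <- scan_motif(prom_rc, motif)$hits
    w <- motif$width
    b$offset <- 300L - w - b$offset
    b$strand <- ifelse(b$strand == "+", "-", "+")
    ord <- function(d) {
      d <- d[order(d$gene_id, d$offset, d$strand), ]
      rownames(d) <- NULL
      d
    }
    expect_equal(ord(a), ord(b), tolerance = 1e-12)
  }
})

test_that("a degenerate 0/1 PWM agrees with its consensus", {
  cons <- "TGCACAC"
  letters_ <- strsplit(cons, "")[[1L]]
  pfm <- matrix(0, 4, 7, dimnames = list(c("A", "C", "G", "T"), NULL))
  for (k in seq_along(letters_)) pfm[letters_[k], k] <- 1000
  pwm <- motif_model(pfm = pfm, pvalue = 1e-4)
  set.seed(3)
  seqs <- vapply(1:40, function(i)
    paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = ""), "")
  prom <- data.frame(gene_id = sprintf("g%02d", 1:40), seq = seqs,
                     stringsAsFactors = FALSE)
  hc <- scan_motif(prom, motif_model(consensus = cons))$hits
  hp <- scan_motif(prom, pwm)$hits
  key <- function(d) sort(paste(d$gene_id, d$offset, d$strand))
  expect_identical(key(hc), key(hp))
})

test_that("Ns never match in either mode", {
  prom <- data.frame(gene_id = "g1",
                     seq = paste0("TGNACGC", strrep("N", 20), "TGCACGC"),
                     stringsAsFactors = FALSE)
  sc <- scan_motif(prom, motif_model(consensus = mre_consensus()))
  expect_identical(sc$hits$offset, 27L)
})

test_that("MRE Fisher enrichment matches the hypergeometric oracle", {
  ## table (8,2,20,70): 8/10 regulated genes bear the motif vs 20/90
  uni <- sprintf("g%03d", 1:100)
  reg <- uni[1:10]
  hits <- c(uni[1:8], uni[11:30])
  res <- mre_enrichment(hits, reg, uni)
  expect_equal(res$p_fisher, oracle_fisher_greater(8, 2, 20, 70),
               tolerance = 1e-12)
  expect_equal(res$fraction_pct, 80)
  ## Fisher p is invariant under transposing the 2x2 table
  expect_equal(oracle_fisher_greater(8, 20, 2, 70),
               res$p_fisher, tolerance = 1e-12)
  ## equal fractions in a large balanced table are not significant
  uni2 <- sprintf("h%03d", 1:400)
  reg2 <- uni2[1:200]
  hits2 <- c(uni2[1:50], uni2[201:250])
  expect_gte(mre_enrichment(hits2, reg2, uni2)$p_fisher, 0.4)
  ## degenerate margins warn and return 1
  expect_warning(r0 <- mre_enrichment(character(), reg, uni),
                 "degenerate")
  expect_equal(r0$p_fisher, 1)
})

test_that("planted motifs are fully recovered and enrich strongly", {
  prom <- sim_promoters(200L, width = 400L, seed = 5)
  motif <- motif_model(consensus = mre_consensus())
  pos <- prom$gene_id[1:50]
  pl <- plant_motifs(prom, motif, pos, seed = 6)
  sc <- scan_motif(pl$promoters, motif)
  expect_true(all(sc$gene_has_hit[pos]))
  expect_false(any(sc$gene_has_hit[setdiff(prom$gene_id, pos)]))
  res <- mre_enrichment(sc$gene_has_hit, pos, prom$gene_id)
  expect_lt(res$p_fisher, 1e-10)
  ## all / none edge cases
  pl_all <- plant_motifs(prom[1:20, ], motif, prom$gene_id[1:20],
                         seed = 8)
  expect_true(all(scan_motif(pl_all$promoters, motif)$gene_has_hit))
  pl_none <- plant_motifs(prom[1:20, ], motif, character(), seed = 9)
  expect_false(any(scan_motif(pl_none$promoters, motif)$gene_has_hit))
  expect_error(plant_motifs(prom, motif, "nope", seed = 1), "not in")
  short <- data.frame(gene_id = "s", seq = "ACG",
                      stringsAsFactors = FALSE)
  expect_error(plant_motifs(short, motif, "s"), "shorter")
})

test_that("JASPAR PFM files parse into working models", {
  path <- withr::local_tempfile(fileext = ".jaspar")
  writeLines(c(">MA0001.1 DEMO",
               "A  [ 10  0 80  5 ]",
               "C  [ 20 90  5  5 ]",
               "G  [ 60  5 10  5 ]",
               "T  [ 10  5  5 85 ]"), path)
  m <- read_jaspar_pfm(path)
  expect_identical(m$mode, "pwm")
  expect_identical(m$width, 4L)
  expect_identical(m$id, "MA0001.1 DEMO")
  expect_identical(unname(colSums(m$pfm)), rep(100, 4))
  writeLines(c(">bad", "A [ 1 1 ]", "C [ 50 1 ]", "G [ 1 1 ]",
               "T [ 1 1 ]"), path)
  expect_error(read_jaspar_pfm(path), "equal totals")
})
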