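## Promoter extraction, MRE motif scanning (IUPAC consensus or JASPAR
## PFM -> log-odds PWM with an exact score-distribution threshold) and
## Fisher over-representation of motif-bearing genes.

.IUPAC <- list(A = "A", C = "C", G = "G", T = "T",
               R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
               W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
               B = c("C", "G", "T"), D = c("A", "G", "T"),
               H = c("A", "C", "T"), V = c("A", "C", "G"),
               N = c("A", "C", "G", "T"))

#' Bundled fallback MRE consensus
#'
#' The canonical metal-responsive-element core, `TGCRCNC`, provided for
#' fixtures and demonstrations only; real analyses should supply a
#' JASPAR PFM for the transcription factor of interest.
#'
#' @return the consensus string.
#' @export
mre_consensus <- function() "TGCRCNC"

#' Read a JASPAR-format position frequency matrix
#'
#' Accepts the standard JASPAR layout: a `>ID name` header followed by
#' four rows `A [ n n ... ]` (brackets and row letters optional).
#'
#' @param path PFM file.
#' @param pvalue per-position false-positive bound for the PWM threshold
#'   (see [motif_model()]).
#' @param bg optional fixed background frequencies (default: empirical
#'   per promoter set at scan time).
#' @return a [motif_model()] in PWM mode.
#' @export
read_jaspar_pfm <- function(path, pvalue = 1e-4, bg = NULL) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  hdr <- grepl("^>", lines)
  id <- if (any(hdr)) sub("^>\\s*", "", lines[which(hdr)[1L]]) else
    basename(path)
  rows <- lines[!hdr][1:4]
  parse_row <- function(x) {
    x <- gsub("^[ACGTacgt]\\s*", "", x)
    x <- gsub("[][]", " ", x)
    as.numeric(strsplit(trimws(x), "\\s+")[[1L]])
  }
  pfm <- do.call(rbind, lapply(rows, parse_row))
  rownames(pfm) <- c("A", "C", "G", "T")
  tot <- colSums(pfm)
  if (max(tot) - min(tot) > 0.01 * max(tot) + 1)
    .stopf("PFM columns must sum to (near-)equal totals")
  motif_model(pfm = pfm, id = id, pvalue = pvalue, bg = bg)
}

#' Build a motif model
#'
#' Either an IUPAC consensus (exact ambiguity-code matching) or a
#' position frequency matrix, converted to a log2-odds PWM against a
#' background composition with a score threshold chosen so that the
#' per-position false-positive rate under the background model is at
#' most `pvalue` (computed from the exact discretised score
#' distribution).
#'
#' @param consensus IUPAC consensus string (consensus mode).
#' @param pfm 4 x width numeric matrix, rows A/C/G/T (PWM mode).
#' @param id motif identifier.
#' @param pvalue per-position false-positive bound for the PWM
#'   threshold.
#' @param bg named background frequencies (A/C/G/T); default uniform,
#'   overridden per promoter set at scan time unless fixed here.
#' @param pseudocount added to PFM cells before normalising.
#' @return object of class `motif_model`.
#' @export
motif_model <- function(consensus = NULL, pfm = NULL, id = "motif",
                        pvalue = 1e-4, bg = NULL, pseudocount = 0.8) {
  if (is.null(consensus) == is.null(pfm))
    .stopf("supply exactly one of consensus or pfm")
  if (!is.null(consensus)) {
    consensus <- toupper(consensus)
    bad <- setdiff(strsplit(consensus, "")[[1L]], names(.IUPAC))
    if (length(bad))
      .stopf("invalid IUPAC code(s): %s", paste(bad, collapse = ", "))
    return(structure(list(mode = "consensus", consensus = consensus,
                          id = id, width = nchar(consensus)),
                     class = "motif_model"))
  }
  stopifnot(is.matrix(pfm), nrow(pfm) == 4L)
  rownames(pfm) <- c("A", "C", "G", "T")
  structure(list(mode = "pwm", pfm = pfm, id = id, width = ncol(pfm),
                 pvalue = pvalue, bg = bg, pseudocount = pseudocount),
            class = "motif_model")
}

## log2-odds matrix for a PFM against background bg
.pwm_logodds <- function(motif, bg) {
  prob <- sweep(motif$pfm + motif$pseudocount, 2L,
                colSums(motif$pfm + motif$pseudocount), `/`)
  log2(prob / bg[c("A", "C", "G", "T")])
}

## Exact distribution of the integer-discretised score under bg;
## returns the smallest integer threshold with upper-tail <= pvalue.
.pwm_threshold <- function(ilom, bg, pvalue) {
  offset <- apply(ilom, 2L, min)
  shifted <- sweep(ilom, 2L, offset)          # non-negative integers
  dist <- 1
  for (k in seq_len(ncol(shifted))) {
    col <- shifted[, k]
    width <- max(col)
    step <- numeric(width + 1L)
    for (b in 1:4) step[col[b] + 1L] <- step[col[b] + 1L] + bg[b]
    new <- numeric(length(dist) + width)
    nz <- which(step > 0)
    for (v in nz)
      new[seq_along(dist) + v - 1L] <-
        new[seq_along(dist) + v - 1L] + dist * step[v]
    dist <- new
  }
  tail_p <- rev(cumsum(rev(dist)))
  scores <- seq_along(dist) - 1L + sum(offset)
  ok <- which(tail_p <= pvalue)
  if (!length(ok)) max(scores) + 1L else scores[ok[1L]]
}

.encode_dna <- function(seq)
  match(strsplit(toupper(seq), "")[[1L]], c("A", "C", "G", "T"))

## integer scores of every offset of ilom (4 x w, integer) along codes
.pwm_scan_codes <- function(codes, ilom) {
  w <- ncol(ilom)
  n <- length(codes) - w + 1L
  if (n < 1L) return(integer())
  sc <- rep(0L, n)
  valid <- rep(TRUE, n)
  for (k in seq_len(w)) {
    ck <- codes[k:(k + n - 1L)]
    na <- is.na(ck)
    valid <- valid & !na
    ck[na] <- 1L
    sc <- sc + ilom[cbind(ck, k)]
  }
  sc[!valid] <- NA_integer_
  sc
}

.revcomp <- function(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))

#' Extract promoter windows around TSSs
#'
#' The window spans `upstream` bp before to `downstream` bp after the
#' TSS, oriented 5'->3' on the gene strand (minus-strand promoters are
#' reverse-complemented). Windows truncated at chromosome ends are
#' flagged.
#'
#' @param genes gene annotation data.frame (`gene_id`, `chrom`,
#'   `strand`, `tss`).
#' @param genome named [Biostrings::DNAStringSet].
#' @param upstream,downstream window extent in bp (defaults -1000/+100).
#' @return data.frame of class `promoter_set`: `gene_id`, `chrom`,
#'   `start`, `end` (0-based half-open genomic), `strand`, `seq`,
#'   `truncated`.
#' @export
extract_promoters <- function(genes, genome, upstream = 1000L,
                              downstream = 100L) {
  miss <- setdiff(unique(genes$chrom), names(genome))
  if (length(miss))
    .stopf("genome lacks chromosome(s): %s", paste(miss, collapse = ", "))
  lens <- Biostrings::width(genome)[match(genes$chrom, names(genome))]
  if (any(genes$tss < 0L | genes$tss >= lens))
    .stopf("TSS outside chromosome for gene %s",
           genes$gene_id[which(genes$tss < 0L | genes$tss >= lens)[1L]])
  plus <- genes$strand != "-"
  ## half-open genomic window: "+" -> [tss - up, tss + down);
  ## "-" -> the mirror image [tss - down + 1, tss + up + 1)
  start <- ifelse(plus, genes$tss - upstream, genes$tss - downstream + 1L)
  end <- ifelse(plus, genes$tss + downstream, genes$tss + upstream + 1L)
  tstart <- pmax(start, 0L)
  tend <- pmin(end, lens)
  seqs <- character(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    s <- as.character(Biostrings::extractAt(
      genome[[genes$chrom[i]]],
      IRanges::IRanges(tstart[i] + 1L, tend[i]))[[1L]])
    seqs[i] <- if (plus[i]) s else .revcomp(s)
  }
  out <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                    start = as.integer(tstart), end = as.integer(tend),
                    strand = genes$strand, seq = seqs,
                    truncated = start < 0L | end > lens,
                    stringsAsFactors = FALSE)
  class(out) <- c("promoter_set", "data.frame")
  out
}

#' Scan promoters for a motif on both strands
#'
#' Consensus mode matches the IUPAC pattern exactly at every offset of
#' the window and of its reverse complement. PWM mode computes
#' integer-discretised log2-odds scores at every offset on both strands
#' and reports those at or above the model's exact-FPR threshold.
#' Offsets are 0-based in window coordinates (forward strand); a minus
#' hit at offset o means the motif matches the reverse complement
#' starting there. Positions containing N never score.
#'
#' @param promoters a `promoter_set` (or data.frame with `gene_id`,
#'   `seq`).
#' @param motif a [motif_model()].
#' @return list with `hits` (data.frame `gene_id`, `offset`, `strand`,
#'   `score`) and `gene_has_hit` (named logical over all promoter
#'   genes).
#' @export
scan_motif <- function(promoters, motif) {
  stopifnot(inherits(motif, "motif_model"))
  if (any(nchar(promoters$seq) < motif$width))
    .stopf("motif (%d bp) longer than shortest promoter window",
           motif$width)
  hits <- vector("list", nrow(promoters))
  if (motif$mode == "pwm") {
    bg <- motif$bg
    if (is.null(bg)) {
      tab <- Biostrings::alphabetFrequency(
        Biostrings::DNAStringSet(promoters$seq))
      tot <- colSums(tab[, c("A", "C", "G", "T"), drop = FALSE])
      bg <- if (sum(tot) == 0) setNames(rep(0.25, 4),
                                        c("A", "C", "G", "T"))
        else tot / sum(tot)
      ## strand-symmetrise so scanning is invariant under
      ## reverse-complementing the windows
      bg <- c(A = (bg[["A"]] + bg[["T"]]) / 2,
              C = (bg[["C"]] + bg[["G"]]) / 2,
              G = (bg[["C"]] + bg[["G"]]) / 2,
              T = (bg[["A"]] + bg[["T"]]) / 2)
      bg <- pmax(bg, 1e-6)
    }
    lom <- .pwm_logodds(motif, bg)
    ilom <- round(lom * 100)
    storage.mode(ilom) <- "integer"
    thr <- .pwm_threshold(ilom, bg[c("A", "C", "G", "T")], motif$pvalue)
  }
  for (i in seq_len(nrow(promoters))) {
    seq <- promoters$seq[i]
    L <- nchar(seq)
    if (motif$mode == "consensus") {
      fwd <- .consensus_offsets(seq, motif$consensus)
      rev0 <- .consensus_offsets(.revcomp(seq), motif$consensus)
      rev <- L - motif$width - rev0            # map back to fwd coords
      off <- c(fwd, rev)
      hits[[i]] <- data.frame(
        gene_id = rep(promoters$gene_id[i], length(off)),
        offset = off,
        strand = rep(c("+", "-"), c(length(fwd), length(rev))),
        score = rep(NA_real_, length(off)), stringsAsFactors = FALSE)
    } else {
      codes <- .encode_dna(seq)
      sf <- .pwm_scan_codes(codes, ilom)
      sr0 <- .pwm_scan_codes(rev(5L - codes), ilom)
      hf <- which(!is.na(sf) & sf >= thr)
      hr0 <- which(!is.na(sr0) & sr0 >= thr)
      hr <- L - motif$width + 2L - hr0 - 1L    # 1-based rc -> 0-based fwd
      off <- c(hf - 1L, hr)
      hits[[i]] <- data.frame(
        gene_id = rep(promoters$gene_id[i], length(off)),
        offset = off,
        strand = rep(c("+", "-"), c(length(hf), length(hr))),
        score = c(sf[hf], sr0[hr0]) / 100,
        stringsAsFactors = FALSE)
    }
  }
  hits <- do.call(rbind, hits)
  has <- setNames(promoters$gene_id %in% hits$gene_id,
                  promoters$gene_id)
  list(hits = hits, gene_has_hit = has)
}

## 0-based offsets where an IUPAC consensus matches exactly
.consensus_offsets <- function(seq, consensus) {
  m <- Biostrings::matchPattern(consensus, Biostrings::DNAString(seq),
                                fixed = c(pattern = FALSE,
                                          subject = TRUE))
  Biostrings::start(m) - 1L
}

#' Motif over-representation among regulated genes
#'
#' Builds the 2x2 table (regulated vs not) x (bears motif vs not) over
#' the universe and reports the one-sided Fisher exact p for
#' over-representation plus the regulated-set motif fraction.
#'
#' @param hit_genes character vector of motif-bearing gene ids (or the
#'   `gene_has_hit` logical from [scan_motif()]).
#' @param regulated character vector of regulated gene ids.
#' @param universe character vector of all tested genes.
#' @return data.frame with `n_regulated`, `n_universe`,
#'   `hits_regulated`, `hits_other`, `fraction_pct`, `p_fisher`.
#' @export
mre_enrichment <- function(hit_genes, regulated, universe) {
  if (is.logical(hit_genes)) hit_genes <- names(hit_genes)[hit_genes]
  universe <- unique(universe)
  regulated <- unique(regulated)
  if (length(setdiff(regulated, universe)))
    .stopf("regulated genes must be a subset of the universe")
  hit_genes <- intersect(unique(hit_genes), universe)
  a <- length(intersect(regulated, hit_genes))
  b <- length(regulated) - a
  c_ <- length(setdiff(hit_genes, regulated))
  d <- length(universe) - length(regulated) - c_
  if ((a + b == 0) || (c_ + d == 0) || (a + c_ == 0) || (b + d == 0)) {
    .warnf("degenerate 2x2 margins; p set to 1")
    p <- 1
  } else {
    p <- fisher.test(matrix(c(a, b, c_, d), 2L, byrow = TRUE),
                     alternative = "greater")$p.value
  }
  data.frame(n_regulated = length(regulated),
             n_universe = length(universe),
             hits_regulated = a, hits_other = c_,
             fraction_pct = if (length(regulated))
               100 * a / length(regulated) else NA_real_,
             p_fisher = p, stringsAsFactors = FALSE)
}
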