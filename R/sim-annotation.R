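## Toy genome + annotation generator for screen simulations.
##
## The genome is synthesised with a TTAA-free background into which TTAA
## tetranucleotides are planted at a controlled density, so the planted
## set IS the complete occurrence set (planting TTAA blocks >= 4 bp apart
## cannot create additional overlapping occurrences: no proper prefix of
## TTAA is also a suffix). Genes are laid out on a regular grid of
## non-overlapping slots so that per-gene windows do not collide.

#' Configuration for screen simulations
#'
#' Defaults emulate a desk-scale version of a genome-wide piggyBac
#' gain-of-function screen: 4 independent mutagenesis experiments, a few
#' populations each, roughly 10,000 integration events in total, TTAA
#' density close to the uniform-composition expectation (~3.9 per kb).
#'
#' @param n_chroms number of toy chromosomes.
#' @param chrom_length_bp length of each chromosome (bp).
#' @param ttaa_rate expected TTAA sites per kb.
#' @param n_genes total genes, distributed evenly across chromosomes.
#' @param gene_length_bp gene body length (bp).
#' @param n_experiments independent mutagenesis experiments.
#' @param events_per_experiment integration events drawn per experiment.
#' @param suppressor_genes character vector of gene ids with elevated
#'   integration propensity (the planted suppressors).
#' @param enrichment_multiplier relative integration propensity at TTAA
#'   sites within a suppressor gene +/- `suppressor_window_bp` (>= 1).
#' @param suppressor_window_bp half-window defining a suppressor's
#'   territory (defaults to the 20 kb assignment window).
#' @param clonal_read_mean mean reads per integration event (clonal
#'   expansion); reads are 1 + Poisson(`clonal_read_mean` - 1).
#' @param populations_per_experiment mutant populations (samples) per
#'   experiment over which an event's reads may be split.
#' @param seed integer seed; all randomness derives from it.
#' @return an object of class `sim_screen_config`.
#' @export
sim_screen_config <- function(n_chroms = 4L,
                              chrom_length_bp = 1e6,
                              ttaa_rate = 3.9,
                              n_genes = 80L,
                              gene_length_bp = 5000L,
                              n_experiments = 4L,
                              events_per_experiment = 2500L,
                              suppressor_genes = character(),
                              enrichment_multiplier = 1,
                              suppressor_window_bp = 20000L,
                              clonal_read_mean = 8,
                              populations_per_experiment = 4L,
                              seed = 1L) {
  .check_number(n_chroms, "n_chroms", 1, integer = TRUE)
  .check_number(chrom_length_bp, "chrom_length_bp", 1000)
  .check_number(ttaa_rate, "ttaa_rate", 0)
  .check_number(n_genes, "n_genes", 1, integer = TRUE)
  .check_number(gene_length_bp, "gene_length_bp", 100)
  .check_number(n_experiments, "n_experiments", 1, integer = TRUE)
  .check_number(events_per_experiment, "events_per_experiment", 1,
                integer = TRUE)
  .check_number(enrichment_multiplier, "enrichment_multiplier", 1)
  .check_number(suppressor_window_bp, "suppressor_window_bp", 0)
  .check_number(clonal_read_mean, "clonal_read_mean", 1)
  .check_number(populations_per_experiment, "populations_per_experiment",
                1, integer = TRUE)
  structure(list(
    n_chroms = as.integer(n_chroms),
    chrom_length_bp = as.integer(chrom_length_bp),
    ttaa_rate = ttaa_rate,
    n_genes = as.integer(n_genes),
    gene_length_bp = as.integer(gene_length_bp),
    n_experiments = as.integer(n_experiments),
    events_per_experiment = as.integer(events_per_experiment),
    suppressor_genes = as.character(suppressor_genes),
    enrichment_multiplier = enrichment_multiplier,
    suppressor_window_bp = as.integer(suppressor_window_bp),
    clonal_read_mean = clonal_read_mean,
    populations_per_experiment = as.integer(populations_per_experiment),
    seed = as.integer(seed)), class = "sim_screen_config")
}

## Replace every TTAA occurrence with a mutated copy until none remain.
.scrub_ttaa <- function(seq) {
  repeat {
    hits <- Biostrings::start(Biostrings::matchPattern("TTAA", seq))
    if (!length(hits)) return(seq)
    repl <- sample(c("C", "G"), length(hits), replace = TRUE)
    seq <- Biostrings::replaceLetterAt(seq, hits + 1L,
                                       paste(repl, collapse = ""))
  }
}

#' Simulate a toy genome, gene annotation and TTAA index
#'
#' Builds `n_chroms` random chromosomes whose TTAA occurrences are fully
#' controlled (background scrubbed, sites planted at `ttaa_rate` per kb),
#' places non-overlapping genes on a regular grid with randomly chosen
#' strands, and returns the exhaustive TTAA occurrence index.
#'
#' @param config a [sim_screen_config()].
#' @param emit_sequence if `FALSE`, skip nucleotide synthesis: TTAA
#'   positions are placed directly and `genome` is `NULL` (fast path for
#'   large simulation batteries; sequence-level invariants are then not
#'   checkable on the result).
#' @return list of class `screen_annotation` with elements `genome`
#'   ([Biostrings::DNAStringSet] or `NULL`), `genes` (data.frame:
#'   `gene_id`, `chrom`, `start`, `end` 0-based half-open, `strand`,
#'   `tss`), `ttaa` (data.frame: `chrom`, `pos` 0-based start) and
#'   `config`.
#' @export
simulate_annotation <- function(config, emit_sequence = TRUE) {
  stopifnot(inherits(config, "sim_screen_config"))
  genes_per_chrom <- .distribute(config$n_genes, config$n_chroms)
  slot <- config$chrom_length_bp %/% max(max(genes_per_chrom), 1L)
  if (slot < config$gene_length_bp)
    .stopf(paste0("chromosome too short: %d bp cannot host %d genes of ",
                  "%d bp"), config$chrom_length_bp, max(genes_per_chrom),
           config$gene_length_bp)
  .with_seed(.stage_seed(config$seed, "annotation"), {
    chroms <- sprintf("chr%d", seq_len(config$n_chroms))
    n_sites <- round(config$ttaa_rate * config$chrom_length_bp / 1000)
    site_list <- lapply(chroms, function(ch)
      .place_spaced(n_sites, config$chrom_length_bp, min_gap = 4L))
    genome <- NULL
    if (emit_sequence) {
      seqs <- lapply(seq_along(chroms), function(i) {
        s <- Biostrings::DNAString(paste(
          sample(c("A", "C", "G", "T"), config$chrom_length_bp,
                 replace = TRUE), collapse = ""))
        s <- .scrub_ttaa(s)
        pos <- site_list[[i]]
        if (length(pos)) {
          at <- as.integer(outer(1:4, pos, `+`))  # 1-based letter indices
          s <- Biostrings::replaceLetterAt(
            s, at, strrep("TTAA", length(pos)))
        }
        s
      })
      genome <- Biostrings::DNAStringSet(seqs)
      names(genome) <- chroms
      ## authoritative index: exhaustive scan of the emitted sequence
      site_list <- lapply(seq_along(chroms), function(i)
        Biostrings::start(
          Biostrings::matchPattern("TTAA", genome[[i]])) - 1L)
    }
    ttaa <- data.frame(
      chrom = rep(chroms, lengths(site_list)),
      pos = as.integer(unlist(site_list)),
      stringsAsFactors = FALSE)
    genes <- .place_genes(chroms, genes_per_chrom, slot,
                          config$gene_length_bp)
    structure(list(genome = genome, genes = genes, ttaa = ttaa,
                   config = config), class = "screen_annotation")
  })
}

.distribute <- function(n, k) {
  base <- n %/% k
  extra <- n %% k
  as.integer(base + (seq_len(k) <= extra))
}

## Sample n positions in [0, L-4] pairwise >= min_gap apart.
.place_spaced <- function(n, len, min_gap = 4L) {
  if (n <= 0) return(integer())
  pos <- integer()
  for (round in 1:50) {
    cand <- sort(unique(c(pos, sample.int(len - 3L, n - length(pos)) - 1L)))
    keep <- c(TRUE, diff(cand) >= min_gap)
    pos <- cand[keep]
    if (length(pos) >= n) return(pos[seq_len(n)])
  }
  pos  # dense genomes: return what fits
}

.place_genes <- function(chroms, genes_per_chrom, slot, gene_len) {
  rows <- lapply(seq_along(chroms), function(i) {
    k <- genes_per_chrom[i]
    if (k == 0L) return(NULL)
    offs <- (seq_len(k) - 1L) * slot + as.integer((slot - gene_len) / 2)
    data.frame(chrom = chroms[i], start = offs, end = offs + gene_len,
               strand = sample(c("+", "-"), k, replace = TRUE),
               stringsAsFactors = FALSE)
  })
  genes <- do.call(rbind, rows)
  genes$gene_id <- sprintf("gene%04d", seq_len(nrow(genes)))
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  genes[, c("gene_id", "chrom", "start", "end", "strand", "tss")]
}

#' Exhaustively index TTAA occurrences in a genome
#'
#' TTAA is its own reverse complement, so a single forward-strand scan
#' lists every site.
#'
#' @param genome named [Biostrings::DNAStringSet].
#' @return data.frame with `chrom`, `pos` (0-based occurrence start).
#' @export
scan_ttaa <- function(genome) {
  hits <- lapply(seq_along(genome), function(i)
    Biostrings::start(Biostrings::matchPattern("TTAA", genome[[i]])) - 1L)
  data.frame(chrom = rep(names(genome), lengths(hits)),
             pos = as.integer(unlist(hits)), stringsAsFactors = FALSE)
}
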