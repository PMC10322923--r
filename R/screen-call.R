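## Integration-site hit calling: collapse reads -> events / unique sites,
## assign sites to genes within a window, tally per-experiment recurrence,
## and test per-gene site counts against a TTAA-density binomial null.

#' Screen-calling configuration
#'
#' @param window_bp maximum site-to-gene distance (bp); the field
#'   convention is 20 kb measured to the gene body.
#' @param min_experiments recurrence filter: candidates must be hit in at
#'   least this many independent experiments.
#' @param fdr_q Benjamini-Hochberg q-value cutoff for candidates.
#' @param assignment_mode `"nearest"` (single closest gene, lexicographic
#'   tie-break) or `"all-within-window"`.
#' @return object of class `screen_call_config`.
#' @export
screen_call_config <- function(window_bp = 20000L, min_experiments = 2L,
                               fdr_q = 0.05,
                               assignment_mode = c("nearest",
                                                   "all-within-window")) {
  .check_number(window_bp, "window_bp", 0, strict_lower = TRUE)
  .check_number(min_experiments, "min_experiments", 1, integer = TRUE)
  .check_number(fdr_q, "fdr_q", 0, 1)
  if (fdr_q <= 0 || fdr_q >= 1) .stopf("fdr_q must be in (0, 1)")
  structure(list(window_bp = as.integer(window_bp),
                 min_experiments = as.integer(min_experiments),
                 fdr_q = fdr_q,
                 assignment_mode = match.arg(assignment_mode)),
            class = "screen_call_config")
}

#' Collapse read records into events and unique sites
#'
#' An *event* is a distinct (experiment, chrom, pos, orientation); a
#' *unique site* is a distinct (chrom, pos, orientation) possibly
#' recurring across experiments. Read multiplicities and sample ids are
#' discarded from the calling path but summarised in a provenance table.
#'
#' @param records integration-record data.frame (see
#'   [read_integration_bed()]).
#' @return list with `events`, `sites` and `provenance` (per-site total
#'   reads, records and contributing samples) data.frames.
#' @export
collapse_records <- function(records) {
  if (is.null(records) || nrow(records) == 0L)
    .stopf("no integration records supplied")
  records <- validate_integration_records(records)
  ekey <- paste(records$experiment_id, records$chrom, records$pos,
                records$orientation, sep = "\r")
  events <- records[!duplicated(ekey),
                    c("experiment_id", "chrom", "pos", "orientation")]
  skey <- paste(records$chrom, records$pos, records$orientation,
                sep = "\r")
  first <- !duplicated(skey)
  sites <- records[first, c("chrom", "pos", "orientation")]
  fkey <- skey[first]
  reads <- rowsum(records$read_count, skey)
  nrec <- as.vector(table(skey)[fkey])
  pair <- !duplicated(paste(skey, records$sample_id, sep = "\r"))
  nsamp <- as.vector(table(skey[pair])[fkey])
  prov <- data.frame(sites, total_reads = reads[fkey, 1L],
                     n_records = nrec, n_samples = nsamp,
                     stringsAsFactors = FALSE)
  rownames(events) <- rownames(sites) <- rownames(prov) <- NULL
  list(events = events, sites = sites, provenance = prov)
}

#' Validate that sites fall on genomic TTAA tetranucleotides
#'
#' @param sites data.frame with `chrom`, `pos` (0-based TTAA start) and
#'   optionally `orientation`.
#' @param genome named [Biostrings::DNAStringSet] covering all site
#'   chromosomes.
#' @return the `sites` data.frame with a logical `ttaa_ok` column.
#' @export
validate_ttaa <- function(sites, genome) {
  miss <- setdiff(unique(sites$chrom), names(genome))
  if (length(miss))
    .stopf("genome lacks chromosome(s): %s", paste(miss, collapse = ", "))
  lens <- Biostrings::width(genome)[match(sites$chrom, names(genome))]
  if (any(sites$pos + 4L > lens))
    .stopf("site beyond chromosome end (row %d)",
           which(sites$pos + 4L > lens)[1L])
  ok <- logical(nrow(sites))
  for (ch in unique(sites$chrom)) {
    i <- which(sites$chrom == ch)
    v <- Biostrings::extractAt(
      genome[[ch]], IRanges::IRanges(sites$pos[i] + 1L, width = 4L))
    ok[i] <- as.character(v) == "TTAA"
  }
  sites$ttaa_ok <- ok
  sites
}

#' Assign unique sites to genes within a window
#'
#' Distance is to the gene body: 0 inside, otherwise the gap to the
#' nearest gene edge. In `"nearest"` mode each site maps to the single
#' closest gene (ties broken lexicographically by gene id); in
#' `"all-within-window"` mode one assignment is emitted per qualifying
#' gene. Sites with no gene within `window_bp` are dropped (reported via
#' the `n_unassigned` attribute).
#'
#' @param sites data.frame (`chrom`, `pos`, optional `orientation`).
#' @param genes gene annotation data.frame (`gene_id`, `chrom`, `start`,
#'   `end` 0-based half-open, `strand`).
#' @param config a [screen_call_config()].
#' @return data.frame with `chrom`, `pos`, `orientation`, `gene_id`,
#'   `distance_bp`, `relative_orientation` (sense/antisense) and
#'   `location` (upstream/inside/downstream relative to gene strand).
#' @export
assign_genes <- function(sites, genes, config = screen_call_config()) {
  w <- config$window_bp
  gr_sites <- GenomicRanges::GRanges(
    sites$chrom, IRanges::IRanges(sites$pos + 1L, width = 1L))
  gr_genes <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start + 1L, genes$end))
  ov <- GenomicRanges::findOverlaps(gr_sites, gr_genes, maxgap = w,
                                    ignore.strand = TRUE)
  si <- S4Vectors::queryHits(ov)
  gi <- S4Vectors::subjectHits(ov)
  dist <- pmax(0L,
               pmax(genes$start[gi] - sites$pos[si],
                    sites$pos[si] - (genes$end[gi] - 1L)))
  keep <- dist <= w
  si <- si[keep]; gi <- gi[keep]; dist <- dist[keep]
  if (config$assignment_mode == "nearest" && length(si)) {
    ord <- order(si, dist, genes$gene_id[gi])
    si <- si[ord]; gi <- gi[ord]; dist <- dist[ord]
    first <- !duplicated(si)
    si <- si[first]; gi <- gi[first]; dist <- dist[first]
  }
  ori <- if ("orientation" %in% names(sites))
    sites$orientation[si] else rep(NA_character_, length(si))
  before <- sites$pos[si] < genes$start[gi]
  after <- sites$pos[si] >= genes$end[gi]
  location <- ifelse(!before & !after, "inside",
              ifelse(xor(before, genes$strand[gi] == "-"),
                     "upstream", "downstream"))
  out <- data.frame(
    chrom = sites$chrom[si], pos = sites$pos[si], orientation = ori,
    gene_id = genes$gene_id[gi], distance_bp = as.integer(dist),
    relative_orientation = ifelse(is.na(ori), NA_character_,
      ifelse(ori == genes$strand[gi], "sense", "antisense")),
    location = location, stringsAsFactors = FALSE)
  attr(out, "n_unassigned") <- nrow(sites) - length(unique(si))
  out
}

#' Tally events, unique sites and experiments per gene
#'
#' @param assignments output of [assign_genes()].
#' @param events event data.frame from [collapse_records()].
#' @return data.frame with `gene_id`, `n_unique_sites`, `n_events`
#'   (distinct experiment x site pairs) and `n_experiments`; genes with
#'   no assigned site are absent.
#' @export
tally_gene_events <- function(assignments, events) {
  if (nrow(assignments) == 0L)
    return(data.frame(gene_id = character(), n_unique_sites = integer(),
                      n_events = integer(), n_experiments = integer(),
                      stringsAsFactors = FALSE))
  skey_a <- paste(assignments$chrom, assignments$pos,
                  assignments$orientation, sep = "\r")
  skey_e <- paste(events$chrom, events$pos, events$orientation,
                  sep = "\r")
  if (length(setdiff(skey_a, skey_e)))
    .stopf("assignment references a site absent from the event set")
  ev_by_site <- split(events$experiment_id, skey_e)
  rows <- lapply(split(seq_len(nrow(assignments)), assignments$gene_id),
    function(i) {
      sk <- unique(skey_a[i])
      exps_per_site <- ev_by_site[sk]
      data.frame(
        gene_id = assignments$gene_id[i[1L]],
        n_unique_sites = length(sk),
        n_events = sum(lengths(lapply(exps_per_site, unique))),
        n_experiments = length(unique(unlist(exps_per_site))),
        stringsAsFactors = FALSE)
    })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$gene_id), , drop = FALSE]
}

#' Per-gene TTAA counts supporting the null model
#'
#' `T_g` counts TTAA starts within `[start - window_bp, end + window_bp)`
#' of each gene; `T` is the genome-wide total.
#'
#' @param annotation either a `screen_annotation`, or a genome
#'   [Biostrings::DNAStringSet] (scanned exhaustively), or a TTAA
#'   data.frame (`chrom`, `pos`).
#' @param genes gene annotation data.frame.
#' @param config a [screen_call_config()].
#' @return list of class `ttaa_index`: `per_gene` (data.frame `gene_id`,
#'   `T_g`), `total` (T).
#' @export
build_ttaa_index <- function(annotation, genes,
                             config = screen_call_config()) {
  ttaa <- if (inherits(annotation, "screen_annotation")) annotation$ttaa
    else if (methods::is(annotation, "DNAStringSet")) scan_ttaa(annotation)
    else annotation
  stopifnot(all(c("chrom", "pos") %in% names(ttaa)))
  w <- config$window_bp
  tg <- integer(nrow(genes))
  for (ch in unique(genes$chrom)) {
    gi <- which(genes$chrom == ch)
    pos <- sort(ttaa$pos[ttaa$chrom == ch])
    if (!length(pos)) next
    lo <- findInterval(genes$start[gi] - w - 1L, pos)     # sites < lo bound
    hi <- findInterval(genes$end[gi] + w - 1L, pos)       # sites < hi bound
    tg[gi] <- hi - lo
  }
  structure(list(per_gene = data.frame(gene_id = genes$gene_id, T_g = tg,
                                       stringsAsFactors = FALSE),
                 total = nrow(ttaa)),
            class = "ttaa_index")
}

#' Call candidate suppressor genes against the TTAA null
#'
#' Under the null, each of the `K` observed unique sites falls into gene
#' g's window with probability `p_g = T_g / T`; the per-gene p-value is
#' the upper binomial tail `P(X >= n_unique_sites)`, corrected by
#' Benjamini-Hochberg across all genes with `T_g > 0`. A candidate must
#' pass the q cutoff and the recurrence filter (`min_experiments`).
#' Unique sites (not reads or events) are tested, for robustness to
#' clonal expansion.
#'
#' @param tallies output of [tally_gene_events()].
#' @param index a `ttaa_index` from [build_ttaa_index()].
#' @param n_sites total number of unique sites `K` (from
#'   [collapse_records()]).
#' @param config a [screen_call_config()].
#' @return data.frame, one row per gene with `T_g > 0` (plus any
#'   null-violating genes), columns `gene_id`, `n_unique_sites`,
#'   `n_events`, `n_experiments`, `T_g`, `expected_fraction`, `p`, `q`,
#'   `candidate`, `flag`; sorted by q then gene_id.
#' @export
call_candidates <- function(tallies, index, n_sites,
                            config = screen_call_config()) {
  stopifnot(inherits(index, "ttaa_index"))
  .check_number(n_sites, "n_sites", 1, integer = TRUE)
  if (index$total <= 0) .stopf("TTAA index is empty")
  per <- index$per_gene
  df <- merge(per, tallies, by = "gene_id", all.x = TRUE)
  for (col in c("n_unique_sites", "n_events", "n_experiments"))
    df[[col]][is.na(df[[col]])] <- 0L
  df$expected_fraction <- df$T_g / index$total
  df$flag <- ifelse(df$T_g == 0L & df$n_unique_sites > 0L,
                    "null-violation", "ok")
  testable <- df$T_g > 0L
  df$p <- NA_real_
  df$p[testable] <- pbinom(df$n_unique_sites[testable] - 1L, n_sites,
                           df$expected_fraction[testable],
                           lower.tail = FALSE)
  df$p[df$flag == "null-violation"] <- 0
  df$q <- NA_real_
  df$q[testable] <- p.adjust(df$p[testable], method = "BH")
  df$candidate <- !is.na(df$q) & df$q < config$fdr_q &
    df$n_experiments >= config$min_experiments
  df <- df[testable | df$flag == "null-violation", , drop = FALSE]
  df <- df[order(df$q, df$gene_id), , drop = FALSE]
  rownames(df) <- NULL
  df[, c("gene_id", "n_unique_sites", "n_events", "n_experiments", "T_g",
         "expected_fraction", "p", "q", "candidate", "flag")]
}

#' Bubble-plot summary table (alphabetical by gene)
#'
#' @param tallies output of [tally_gene_events()].
#' @return data.frame (`gene_id`, `n_events`, `n_experiments`) ordered
#'   alphabetically by gene id.
#' @export
summarize_bubble <- function(tallies) {
  if (nrow(tallies) == 0L) .stopf("no tallies to summarise")
  out <- tallies[order(tallies$gene_id),
                 c("gene_id", "n_events", "n_experiments")]
  rownames(out) <- NULL
  out
}

#' End-to-end screen calling
#'
#' Convenience wrapper: collapse -> (optional TTAA validation) ->
#' assign -> tally -> index -> candidate calling.
#'
#' @param records integration-record data.frame.
#' @param genes gene annotation data.frame.
#' @param annotation genome `DNAStringSet`, TTAA data.frame or
#'   `screen_annotation` used for validation and the null index.
#' @param config a [screen_call_config()].
#' @param keep_invalid keep sites failing TTAA validation (default drop).
#' @return list with `collapsed`, `assignments`, `tallies`, `index`,
#'   `hits`.
#' @export
screen_call <- function(records, genes, annotation,
                        config = screen_call_config(),
                        keep_invalid = FALSE) {
  col <- collapse_records(records)
  sites <- col$sites
  if (methods::is(annotation, "DNAStringSet") ||
      (inherits(annotation, "screen_annotation") &&
       !is.null(annotation$genome))) {
    genome <- if (inherits(annotation, "screen_annotation"))
      annotation$genome else annotation
    sites <- validate_ttaa(sites, genome)
    if (!keep_invalid) {
      bad <- !sites$ttaa_ok
      if (any(bad)) {
        skey <- paste(sites$chrom, sites$pos, sites$orientation)
        ekey <- paste(col$events$chrom, col$events$pos,
                      col$events$orientation)
        col$events <- col$events[!(ekey %in% skey[bad]), , drop = FALSE]
        sites <- sites[!bad, , drop = FALSE]
      }
    }
  }
  asn <- assign_genes(sites, genes, config)
  tal <- tally_gene_events(asn, col$events)
  idx <- build_ttaa_index(annotation, genes, config)
  hits <- call_candidates(tal, idx, n_sites = nrow(sites), config)
  list(collapsed = col, assignments = asn, tallies = tal, index = idx,
       hits = hits)
}
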