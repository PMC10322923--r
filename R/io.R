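## Readers/writers for the package's tabular dialect and the standard
## genomics formats. TSV: tab-separated, UTF-8, '.' decimal, '#'-prefixed
## header comment lines carrying tool version + parameters. BED is 0-based
## half-open; GTF 1-based inclusive (converted on read); all internal
## coordinates 0-based half-open.

#' Write a data frame as commented TSV
#'
#' Writes tab-separated values preceded by `#`-prefixed comment lines
#' recording the tool version and any parameters, so every artifact is
#' self-describing.
#'
#' @param x data.frame to write.
#' @param path output file path.
#' @param params optional named list echoed into the header comments.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path, params = list()) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# gofscreen %s", .gof_version()), con)
  writeLines(sprintf("# date: %s", format(Sys.time(), "%Y-%m-%d")), con)
  for (nm in names(params))
    writeLines(sprintf("# %s: %s", nm,
                       paste(format(params[[nm]]), collapse = ",")), con)
  write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a commented TSV written by [write_tsv()]
#'
#' @param path file path.
#' @return data.frame (comment lines skipped).
#' @export
read_tsv <- function(path) {
  if (!file.exists(path)) .stopf("input file not found: %s", path)
  read.table(path, sep = "\t", header = TRUE, comment.char = "#",
             stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read integration records from BED6
#'
#' One row per mapped splinkerette read group: `chrom`, 0-based TTAA
#' `start`, `end = start + 4`, `name = "experiment:sample"`,
#' `score = read count`, `strand` = integration orientation.
#'
#' @param path BED6 file.
#' @return data.frame of integration records with columns
#'   `experiment_id`, `sample_id`, `chrom`, `pos`, `orientation`,
#'   `read_count`.
#' @export
read_integration_bed <- function(path) {
  bed <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                    stringsAsFactors = FALSE)
  if (ncol(bed) < 6L)
    .stopf("BED6 required (6 columns), got %d in '%s'", ncol(bed), path)
  nm <- strsplit(as.character(bed[[4L]]), ":", fixed = TRUE)
  bad <- which(lengths(nm) < 2L)
  if (length(bad))
    .stopf("row %d: BED name must be 'experiment:sample'", bad[1L])
  rec <- data.frame(
    experiment_id = vapply(nm, `[[`, "", 1L),
    sample_id     = vapply(nm, function(x) paste(x[-1L], collapse = ":"), ""),
    chrom         = as.character(bed[[1L]]),
    pos           = as.integer(bed[[2L]]),
    orientation   = as.character(bed[[6L]]),
    read_count    = as.integer(bed[[5L]]),
    stringsAsFactors = FALSE)
  validate_integration_records(rec)
}

#' Write integration records as BED6
#'
#' @param records integration-record data.frame (see
#'   [read_integration_bed()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_integration_bed <- function(records, path) {
  records <- validate_integration_records(records)
  bed <- data.frame(records$chrom, records$pos, records$pos + 4L,
                    paste(records$experiment_id, records$sample_id, sep = ":"),
                    records$read_count, records$orientation)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Validate integration records
#'
#' Checks the record invariants (non-negative position, positive read
#' count, non-empty labels, strand in +/-) and fails naming the first
#' offending row.
#'
#' @param records data.frame with columns `experiment_id`, `sample_id`,
#'   `chrom`, `pos`, `orientation`, `read_count`.
#' @return the validated data.frame (types normalised).
#' @export
validate_integration_records <- function(records) {
  need <- c("experiment_id", "sample_id", "chrom", "pos", "orientation",
            "read_count")
  miss <- setdiff(need, names(records))
  if (length(miss))
    .stopf("integration records lack column(s): %s",
           paste(miss, collapse = ", "))
  records$pos <- as.integer(records$pos)
  records$read_count <- as.integer(records$read_count)
  chk <- function(ok, what) {
    i <- which(!ok)
    if (length(i)) .stopf("integration record row %d: %s", i[1L], what)
  }
  chk(!is.na(records$pos) & records$pos >= 0L, "pos must be >= 0")
  chk(!is.na(records$read_count) & records$read_count >= 1L,
      "read_count must be >= 1")
  chk(nzchar(records$experiment_id), "empty experiment_id")
  chk(nzchar(records$sample_id), "empty sample_id")
  chk(nzchar(records$chrom), "empty chrom")
  chk(records$orientation %in% c("+", "-"), "orientation must be + or -")
  records
}

#' Read a gene annotation from GTF
#'
#' Keeps `gene` features (or collapses transcripts when no gene rows are
#' present) and converts to the package's 0-based half-open convention.
#'
#' @param path GTF file.
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open), `strand`, `tss`.
#' @export
read_gene_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  if (any(gr$type == "gene")) gr <- gr[gr$type == "gene"]
  df <- data.frame(
    gene_id = as.character(gr$gene_id),
    chrom   = as.character(GenomicRanges::seqnames(gr)),
    start   = GenomicRanges::start(gr) - 1L,
    end     = GenomicRanges::end(gr),
    strand  = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE)
  if (anyDuplicated(df$gene_id)) {  # collapse transcript rows per gene
    sp <- split(seq_len(nrow(df)), df$gene_id)
    df <- do.call(rbind, lapply(sp, function(i) {
      data.frame(gene_id = df$gene_id[i[1L]], chrom = df$chrom[i[1L]],
                 start = min(df$start[i]), end = max(df$end[i]),
                 strand = df$strand[i[1L]], stringsAsFactors = FALSE)
    }))
    rownames(df) <- NULL
  }
  df$tss <- ifelse(df$strand == "+", df$start, df$end - 1L)
  df
}

#' Write a gene annotation as GTF
#'
#' @param genes gene data.frame (`gene_id`, `chrom`, `start`, `end`
#'   0-based half-open, `strand`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_gtf <- function(genes, path) {
  lines <- sprintf(
    "%s\tgofscreen\tgene\t%d\t%d\t.\t%s\t.\tgene_id \"%s\";",
    genes$chrom, genes$start + 1L, genes$end, genes$strand, genes$gene_id)
  writeLines(lines, path)
  invisible(path)
}

#' Read a genome FASTA
#'
#' @param path FASTA file.
#' @return a [Biostrings::DNAStringSet] named by chromosome.
#' @export
read_genome_fasta <- function(path) Biostrings::readDNAStringSet(path)

#' Write a genome FASTA (60-column wrap)
#'
#' @param genome named [Biostrings::DNAStringSet].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path, width = 60L)
  invisible(path)
}

#' Read a count matrix and sample sheet
#'
#' @param counts_path TSV whose first column is `gene_id`, remaining
#'   columns are per-sample integer counts.
#' @param samples_path TSV with columns `sample_id` and `condition`.
#' @return list with `counts` (integer matrix, genes x samples) and
#'   `samples` (data.frame), samples matched and ordered to columns.
#' @export
read_counts_tsv <- function(counts_path, samples_path) {
  tab <- read_tsv(counts_path)
  counts <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(counts) <- "integer"
  rownames(counts) <- as.character(tab[[1L]])
  samples <- read_tsv(samples_path)
  if (!all(c("sample_id", "condition") %in% names(samples)))
    .stopf("sample sheet needs columns sample_id, condition")
  miss <- setdiff(colnames(counts), samples$sample_id)
  if (length(miss))
    .stopf("samples missing from sheet: %s", paste(miss, collapse = ", "))
  samples <- samples[match(colnames(counts), samples$sample_id), ,
                     drop = FALSE]
  rownames(samples) <- NULL
  list(counts = counts, samples = samples)
}

#' Write a count matrix (+ sample sheet) as TSV
#'
#' @param counts integer matrix, genes x samples.
#' @param samples data.frame with `sample_id`, `condition`.
#' @param counts_path,samples_path output paths.
#' @return invisibly, a character vector of the two paths.
#' @export
write_counts_tsv <- function(counts, samples, counts_path, samples_path) {
  tab <- data.frame(gene_id = rownames(counts), counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(tab, counts_path)
  write_tsv(samples, samples_path)
  invisible(c(counts_path, samples_path))
}
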