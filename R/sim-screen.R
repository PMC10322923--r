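## Integration-event simulator with planted suppressor enrichment.

#' Simulate a piggyBac screen over a toy annotation
#'
#' Each experiment draws `events_per_experiment` integration events from
#' the TTAA site index with probability proportional to 1 (background) or
#' `enrichment_multiplier` for sites within a suppressor gene +/-
#' `suppressor_window_bp`. Each event is expanded into one or more read
#' records sharing (experiment, site): reads follow a shifted-Poisson
#' clonal distribution and may be split across mutant populations, so
#' callers must distinguish reads, events, and unique sites.
#'
#' @param annotation a `screen_annotation` from [simulate_annotation()].
#' @param config a [sim_screen_config()]; its `suppressor_genes` must be
#'   a subset of the annotation's gene ids.
#' @return list of class `screen_sim`: `records` (integration-record
#'   data.frame as in [read_integration_bed()]) and `truth` (list with
#'   `true_suppressors` and `true_sites`, the distinct
#'   (chrom, pos, orientation, experiment) events).
#' @export
simulate_screen <- function(annotation, config = annotation$config) {
  stopifnot(inherits(annotation, "screen_annotation"),
            inherits(config, "sim_screen_config"))
  ttaa <- annotation$ttaa
  if (nrow(ttaa) == 0L)
    .stopf("empty TTAA index: cannot place integrations")
  unknown <- setdiff(config$suppressor_genes, annotation$genes$gene_id)
  if (length(unknown))
    .stopf("suppressor gene(s) not in annotation: %s",
           paste(unknown, collapse = ", "))

  w <- rep(1, nrow(ttaa))
  sup <- annotation$genes[
    annotation$genes$gene_id %in% config$suppressor_genes, , drop = FALSE]
  if (nrow(sup) && config$enrichment_multiplier > 1) {
    for (i in seq_len(nrow(sup))) {
      hit <- ttaa$chrom == sup$chrom[i] &
        ttaa$pos >= sup$start[i] - config$suppressor_window_bp &
        ttaa$pos < sup$end[i] + config$suppressor_window_bp
      w[hit] <- config$enrichment_multiplier
    }
  }

  .with_seed(.stage_seed(config$seed, "screen"), {
    recs <- vector("list", config$n_experiments)
    for (e in seq_len(config$n_experiments)) {
      idx <- sample.int(nrow(ttaa), config$events_per_experiment,
                        replace = TRUE, prob = w)
      ori <- sample(c("+", "-"), length(idx), replace = TRUE)
      pop <- sample.int(config$populations_per_experiment, length(idx),
                        replace = TRUE)
      reads <- 1L + rpois(length(idx), max(config$clonal_read_mean - 1, 0))
      df <- data.frame(
        experiment_id = sprintf("exp%d", e),
        sample_id = sprintf("exp%d_pop%d", e, pop),
        chrom = ttaa$chrom[idx], pos = ttaa$pos[idx], orientation = ori,
        read_count = reads, stringsAsFactors = FALSE)
      ## split ~30% of multi-read events across a second population, to
      ## exercise read-level collapsing downstream
      splittable <- which(df$read_count >= 2L & runif(nrow(df)) < 0.3)
      if (length(splittable)) {
        part <- pmax(1L, as.integer(df$read_count[splittable] / 2))
        extra <- df[splittable, , drop = FALSE]
        extra$read_count <- part
        extra$sample_id <- sprintf("exp%d_pop%d", e,
          1L + (pop[splittable] %% config$populations_per_experiment))
        df$read_count[splittable] <- df$read_count[splittable] - part
        df <- rbind(df, extra)
      }
      recs[[e]] <- df
    }
    records <- do.call(rbind, recs)
    rownames(records) <- NULL
    key <- paste(records$experiment_id, records$chrom, records$pos,
                 records$orientation)
    first <- !duplicated(key)
    truth <- list(
      true_suppressors = config$suppressor_genes,
      true_sites = data.frame(
        chrom = records$chrom[first], pos = records$pos[first],
        orientation = records$orientation[first],
        experiment_id = records$experiment_id[first],
        stringsAsFactors = FALSE))
    structure(list(records = records, truth = truth), class = "screen_sim")
  })
}
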