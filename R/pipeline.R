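## End-to-end orchestration: simulate -> screen-call and
## simulate -> DE -> rescue (-> motif), with a JSON run manifest.

.log <- local({
  levels <- c(debug = 1L, info = 2L, warn = 3L, error = 4L)
  threshold <- 2L
  function(level, fmt, ...) {
    if (identical(fmt, "set")) { threshold <<- levels[[level]]; return(invisible()) }
    if (levels[[level]] >= threshold)
      message(sprintf("[%s] %s", toupper(level), sprintf(fmt, ...)))
  }
})

#' Set the pipeline log level
#' @param level one of "debug", "info", "warn", "error".
#' @export
set_log_level <- function(level = c("info", "debug", "warn", "error")) {
  .log(match.arg(level), "set")
}

#' Read a pipeline configuration file (JSON)
#'
#' @param path JSON config: fields `stages` (character), `outdir`,
#'   `seed`, and optional parameter blocks `sim_counts`, `sim_screen`,
#'   `filter`, `thresholds`, `rescue`, `screen`, `motif`, plus
#'   `contrasts` (named: `disease`, `reference`, `suppressors`).
#' @return the config list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) .stopf("config file not found: %s", path)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

.manifest_add <- function(manifest, name, path) {
  rbind(manifest, data.frame(artifact = name, path = path,
                             md5 = unname(tools::md5sum(path)),
                             stringsAsFactors = FALSE))
}

#' Run the pipeline end to end
#'
#' Executes the selected stages in dependency order:
#' `sim_counts` -> `de` -> `rescue`, `sim_screen` -> `screen_call`.
#' Every artifact is a commented TSV under `outdir`; a JSON manifest
#' listing artifact paths, parameters and md5 checksums is written last.
#' Any stage failure aborts downstream stages.
#'
#' @param config config list (see [read_pipeline_config()]) or a path
#'   to a JSON config file.
#' @param seed optional override of the config seed.
#' @return the manifest, invisibly (list with `parameters` and
#'   `artifacts`).
#' @export
run_end_to_end <- function(config, seed = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stages <- config$stages %||% c("sim_counts", "de", "rescue")
  outdir <- config$outdir %||% .stopf("config needs 'outdir'")
  seed <- as.integer(seed %||% config$seed %||% 1L)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- data.frame(artifact = character(), path = character(),
                         md5 = character(), stringsAsFactors = FALSE)
  pth <- function(f) file.path(outdir, f)

  needs_counts <- any(c("de", "rescue") %in% stages)
  if ("sim_counts" %in% stages) {
    .log("info", "stage sim_counts (seed %d)", seed)
    cc <- do.call(sim_counts_config,
                  c(config$sim_counts %||% list(), list(seed = seed)))
    sim <- simulate_counts(cc)
    write_counts_tsv(sim$counts, sim$samples, pth("counts.tsv"),
                     pth("samples.tsv"))
    write_tsv(data.frame(gene_id = rownames(sim$truth$true_lfc),
                         sim$truth$true_lfc, check.names = FALSE),
              pth("truth_lfc.tsv"))
    manifest <- Reduce(function(m, f) .manifest_add(m, f, pth(f)),
                       c("counts.tsv", "samples.tsv", "truth_lfc.tsv"),
                       manifest)
  } else if (needs_counts) {
    inp <- read_counts_tsv(config$counts %||%
                             .stopf("stage 'de' needs 'counts'"),
                           config$samples %||%
                             .stopf("stage 'de' needs 'samples'"))
    sim <- list(counts = inp$counts, samples = inp$samples)
  }

  de_tabs <- NULL
  if ("de" %in% stages) {
    ct <- config$contrasts %||% list(reference = "Q15",
                                     disease = "Q128",
                                     suppressors = "Q128_Mtf1")
    rule <- do.call(filter_rule, config$filter %||% list())
    filtered <- filter_low_counts(sim$counts, rule)
    .log("info", "stage de: %d genes after filtering", nrow(filtered))
    sf <- estimate_size_factors(filtered)
    run1 <- function(a, b) {
      disp <- estimate_dispersions(filtered, sf,
                                   sim$samples$condition, c(a, b))
      wald_de(filtered, sf, disp, sim$samples$condition, c(a, b))
    }
    de_tabs <- list(disease_vs_ref = run1(ct$disease, ct$reference))
    for (sc in ct$suppressors) {
      de_tabs[[paste0(sc, "_vs_ref")]] <- run1(sc, ct$reference)
      de_tabs[[paste0(sc, "_vs_disease")]] <- run1(sc, ct$disease)
    }
    for (nm in names(de_tabs)) {
      f <- sprintf("de_%s.tsv", nm)
      write_tsv(de_tabs[[nm]], pth(f), params = list(contrast = nm))
      manifest <- .manifest_add(manifest, f, pth(f))
    }
    thr <- do.call(deg_thresholds, config$thresholds %||% list())
    degs <- call_degs(de_tabs$disease_vs_ref, thr)
    write_tsv(degs, pth("degs.tsv"))
    manifest <- .manifest_add(manifest, "degs.tsv", pth("degs.tsv"))
  }

  if ("rescue" %in% stages) {
    if (is.null(de_tabs)) .stopf("stage 'rescue' requires stage 'de'")
    ct <- config$contrasts %||% list(suppressors = "Q128_Mtf1")
    rr <- do.call(rescue_rule, config$rescue %||% list())
    degs <- read_tsv(pth("degs.tsv"))
    if (nrow(degs) == 0L) .stopf("no DEGs; rescue undefined")
    for (sc in ct$suppressors %||% "Q128_Mtf1") {
      res <- classify_rescue(degs, de_tabs[[paste0(sc, "_vs_ref")]],
                             de_tabs[[paste0(sc, "_vs_disease")]], rr)
      f <- sprintf("rescue_%s.tsv", sc)
      write_tsv(res$calls, pth(f),
                params = list(condition = sc,
                              fraction_pct = res$fraction_pct))
      manifest <- .manifest_add(manifest, f, pth(f))
      .log("info", "stage rescue: %s fraction %.1f%%", sc,
           res$fraction_pct)
    }
  }

  if ("sim_screen" %in% stages || "screen_call" %in% stages) {
    sc_cfg <- do.call(sim_screen_config,
                      c(config$sim_screen %||% list(),
                        list(seed = seed)))
    ann <- simulate_annotation(sc_cfg)
    scr <- simulate_screen(ann)
    write_genome_fasta(ann$genome, pth("genome.fa"))
    write_gene_gtf(ann$genes, pth("genes.gtf"))
    write_integration_bed(scr$records, pth("integrations.bed"))
    for (f in c("genome.fa", "genes.gtf", "integrations.bed"))
      manifest <- .manifest_add(manifest, f, pth(f))
    if ("screen_call" %in% stages) {
      call_cfg <- do.call(screen_call_config, config$screen %||% list())
      res <- screen_call(scr$records, ann$genes, ann, call_cfg)
      write_tsv(res$hits, pth("screen_hits.tsv"),
                params = list(window_bp = call_cfg$window_bp,
                              min_experiments = call_cfg$min_experiments,
                              fdr_q = call_cfg$fdr_q))
      manifest <- .manifest_add(manifest, "screen_hits.tsv",
                                pth("screen_hits.tsv"))
      .log("info", "stage screen_call: %d candidates",
           sum(res$hits$candidate))
    }
  }

  out <- list(version = .gof_version(), seed = seed, stages = stages,
              parameters = config, artifacts = manifest)
  jsonlite::write_json(out, pth("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(out)
}
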