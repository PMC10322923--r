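test_that("collapsing distinguishes reads, events and unique sites", {
  rec <- data.frame(
    experiment_id = c("e1", "e1", "e1", "e2"),
    sample_id = c("s1", "s2", "s1", "s1"),
    chrom = "chr1", pos = 100L, orientation = "+",
    read_count = c(5L, 2L, 9L, 3L), stringsAsFactors = FALSE)
  col <- collapse_records(rec)
  expect_identical(nrow(col$events), 2L)   # same site in 2 experiments
  expect_identical(nrow(col$sites), 1L)
  expect_identical(col$provenance$total_reads, 19L)
  expect_identical(col$provenance$n_samples, 2L)
  ## idempotence: collapsing the collapsed events changes nothing
  ev <- col$events
  ev$sample_id <- "x"; ev$read_count <- 1L
  col2 <- collapse_records(ev)
  expect_identical(col2$events[, names(col$events)], col$events)
})

test_that("collapse counts equal brute-force set cardinalities", {
  rec <- random_records(1000L, seed = 4)
  col <- collapse_records(rec)
  want <- oracle_collapse_counts(rec)
  expect_identical(nrow(col$events), want$n_events)
  expect_identical(nrow(col$sites), want$n_sites)
  expect_gte(nrow(col$events), nrow(col$sites))
})

test_that("malformed records fail naming the offending row", {
  rec <- random_records(5L)
  rec$pos[3L] <- -1L
  expect_error(collapse_records(rec), "row 3")
  rec2 <- random_records(4L)
  rec2$experiment_id[2L] <- ""
  expect_error(collapse_records(rec2), "row 2")
  expect_error(collapse_records(rec2[0L, ]), "no integration records")
})

test_that("TTAA validation checks the exact 4-mer and bounds", {
  genome <- tiny_genome(c(chr1 = "ACGTTTAAACGTACGT"))
  sites <- data.frame(chrom = "chr1", pos = c(4L, 0L),
                      orientation = c("+", "-"),
                      stringsAsFactors = FALSE)
  v <- validate_ttaa(sites, genome)
  expect_identical(v$ttaa_ok, c(TRUE, FALSE))
  expect_error(validate_ttaa(
    data.frame(chrom = "chr1", pos = 14L), genome), "beyond")
  expect_error(validate_ttaa(
    data.frame(chrom = "chrX", pos = 0L), genome), "lacks chromosome")
})

test_that("nearest-gene assignment matches the all-pairs oracle", {
  set.seed(42)
  genes <- data.frame(
    gene_id = sprintf("g%02d", 1:20),
    chrom = sample(c("chr1", "chr2"), 20, TRUE),
    start = sample.int(200000L, 20) - 1L, stringsAsFactors = FALSE)
  genes$end <- genes$start + sample.int(5000L, 20) + 99L
  genes$strand <- sample(c("+", "-"), 20, TRUE)
  sites <- data.frame(
    chrom = sample(c("chr1", "chr2"), 200, TRUE),
    pos = sample.int(210000L, 200) - 1L,
    orientation = sample(c("+", "-"), 200, TRUE),
    stringsAsFactors = FALSE)
  cfg <- screen_call_config(window_bp = 20000)
  asn <- assign_genes(sites, genes, cfg)
  want <- oracle_nearest_gene(sites, genes, 20000L)
  got <- asn[order(asn$chrom, asn$pos), c("chrom", "pos", "gene_id",
                                          "distance_bp")]
  want <- want[order(want$chrom, want$pos), c("chrom", "pos", "gene_id",
                                              "distance_bp")]
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got, want)
})

test_that("assignment location/orientation semantics and windowing", {
  genes <- data.frame(gene_id = "gA", chrom = "chr1", start = 10000L,
                      end = 15000L, strand = "+",
                      stringsAsFactors = FALSE)
  sites <- data.frame(chrom = "chr1", pos = c(5000L, 12000L, 16000L,
                                              40000L),
                      orientation = c("+", "-", "+", "+"),
                      stringsAsFactors = FALSE)
  asn <- assign_genes(sites, genes, screen_call_config())
  expect_identical(nrow(asn), 3L)          # 40 kb site unassignable
  expect_identical(asn$location, c("upstream", "inside", "downstream"))
  expect_identical(asn$distance_bp, c(5000L, 0L, 1001L))
  expect_identical(asn$relative_orientation,
                   c("sense", "antisense", "sense"))
  ## minus-strand gene flips upstream/downstream
  genes$strand <- "-"
  asn2 <- assign_genes(sites, genes, screen_call_config())
  expect_identical(asn2$location, c("downstream", "inside", "upstream"))
  ## translation invariance
  genes3 <- genes; genes3$start <- genes3$start + 777L
  genes3$end <- genes3$end + 777L
  sites3 <- sites; sites3$pos <- sites3$pos + 777L
  asn3 <- assign_genes(sites3, genes3, screen_call_config())
  expect_identical(asn3$distance_bp, asn2$distance_bp)
  expect_identical(asn3$location, asn2$location)
})

test_that("equidistant ties break lexicographically by gene id", {
  genes <- data.frame(gene_id = c("gB", "gA"), chrom = "chr1",
                      start = c(0L, 2001L), end = c(500L, 2501L),
                      strand = "+", stringsAsFactors = FALSE)
  ## site at 1250: distance 751 to gB's last base (499) and to gA's
  ## start (2001) alike
  sites <- data.frame(chrom = "chr1", pos = 1250L, orientation = "+",
                      stringsAsFactors = FALSE)
  asn <- assign_genes(sites, genes, screen_call_config())
  expect_identical(asn$gene_id, "gA")
})

test_that("tallies equal brute-force group-by counts", {
  rec <- random_records(800L, n_chrom = 1L, max_pos = 3000L, seed = 6)
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                      start = c(0L, 1500L), end = c(1400L, 3000L),
                      strand = "+", stringsAsFactors = FALSE)
  col <- collapse_records(rec)
  asn <- assign_genes(col$sites, genes, screen_call_config(window_bp = 10))
  tal <- tally_gene_events(asn, col$events)
  for (g in tal$gene_id) {
    sk <- paste(asn$chrom, asn$pos, asn$orientation)[asn$gene_id == g]
    evk <- paste(col$events$chrom, col$events$pos,
                 col$events$orientation)
    ing <- evk %in% sk
    expect_identical(tal$n_unique_sites[tal$gene_id == g],
                     length(unique(sk)))
    expect_identical(tal$n_events[tal$gene_id == g], sum(ing))
    expect_identical(tal$n_experiments[tal$gene_id == g],
                     length(unique(col$events$experiment_id[ing])))
  }
  expect_true(all(tal$n_experiments <= tal$n_events))
  expect_true(all(tal$n_unique_sites <= tal$n_events))
  ## single gene, one site, three experiments
  rec1 <- data.frame(experiment_id = c("e1", "e2", "e3"),
                     sample_id = "s", chrom = "chr1", pos = 10L,
                     orientation = "+", read_count = 1L,
                     stringsAsFactors = FALSE)
  c1 <- collapse_records(rec1)
  a1 <- assign_genes(c1$sites, genes, screen_call_config())
  t1 <- tally_gene_events(a1, c1$events)
  expect_identical(t1$n_events, 3L)
  expect_identical(t1$n_unique_sites, 1L)
  expect_identical(t1$n_experiments, 3L)
})

test_that("TTAA window counts match a string-scan oracle and conserve", {
  genome <- tiny_genome(c(
    chr1 = paste0(strrep("C", 50), "TTAA", strrep("G", 30), "TTAA",
                  strrep("C", 112)),
    chr2 = strrep("AC", 100)))
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = c("chr1", "chr2"),
                      start = c(40L, 50L), end = c(90L, 150L),
                      strand = "+", stringsAsFactors = FALSE)
  idx <- build_ttaa_index(genome, genes, screen_call_config(window_bp = 5))
  scan1 <- oracle_ttaa_scan(as.character(genome[[1L]]))
  expect_identical(idx$per_gene$T_g[1L],
                   sum(scan1 >= 35 & scan1 < 95))
  expect_identical(idx$per_gene$T_g[2L], 0L)   # TTAA-free chromosome
  expect_identical(idx$total, length(scan1))
  ## whole-chromosome windows conserve the total
  genes_all <- data.frame(gene_id = c("c1", "c2"),
                          chrom = c("chr1", "chr2"), start = c(0L, 0L),
                          end = c(200L, 200L), strand = "+",
                          stringsAsFactors = FALSE)
  idx2 <- build_ttaa_index(genome, genes_all,
                           screen_call_config(window_bp = 1))
  expect_identical(sum(idx2$per_gene$T_g), idx2$total)
})

test_that("candidate p-values equal the exact binomial tail", {
  tal <- data.frame(gene_id = "g1", n_unique_sites = 5L, n_events = 7L,
                    n_experiments = 3L, stringsAsFactors = FALSE)
  idx <- structure(list(per_gene = data.frame(
    gene_id = c("g1", "g2"), T_g = c(10L, 100L),
    stringsAsFactors = FALSE), total = 10000L), class = "ttaa_index")
  hits <- call_candidates(tal, idx, n_sites = 20L)
  expect_equal(hits$p[hits$gene_id == "g1"],
               oracle_binom_upper(5L, 20L, 10 / 10000), tolerance = 1e-12)
  expect_equal(hits$p[hits$gene_id == "g2"], 1)   # zero observed sites
  expect_true(all(hits$q >= hits$p - 1e-15))
  ## null-violation: observed sites where T_g = 0
  idx0 <- structure(list(per_gene = data.frame(
    gene_id = "g1", T_g = 0L, stringsAsFactors = FALSE),
    total = 500L), class = "ttaa_index")
  h0 <- call_candidates(tal, idx0, n_sites = 20L)
  expect_identical(h0$flag, "null-violation")
  expect_false(any(h0$candidate))
})

test_that("bubble summary is alphabetical and matches tallies", {
  tal <- data.frame(gene_id = c("zeta", "alpha", "mid"),
                    n_unique_sites = c(1L, 2L, 3L),
                    n_events = c(4L, 5L, 6L),
                    n_experiments = c(1L, 2L, 2L),
                    stringsAsFactors = FALSE)
  bub <- summarize_bubble(tal)
  expect_identical(bub$gene_id, c("alpha", "mid", "zeta"))
  expect_identical(bub$n_events, c(5L, 6L, 4L))
  expect_error(summarize_bubble(tal[0L, ]), "no tallies")
})

test_that("BED6 round-trip preserves records", {
  rec <- random_records(50L, seed = 12)
  path <- withr::local_tempfile(fileext = ".bed")
  write_integration_bed(rec, path)
  back <- read_integration_bed(path)
  expect_equal(back, rec, ignore_attr = TRUE)
})
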