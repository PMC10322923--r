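## Transcriptional rescue classification and exact set statistics.

#' Rescue rule
#'
#' A disease DEG counts as rescued by a suppressor when its expression
#' under the suppressor is statistically indistinguishable from healthy
#' (`p >= p_ns_threshold` in the suppressor-vs-healthy contrast) while
#' shifted away from the disease state
#' (`|log2FC| > lfc_threshold` in the suppressor-vs-disease contrast).
#'
#' @param p_ns_threshold non-significance threshold vs healthy.
#' @param lfc_threshold |log2FC| threshold vs disease (strict).
#' @return object of class `rescue_rule`.
#' @export
rescue_rule <- function(p_ns_threshold = 0.05, lfc_threshold = 0.5) {
  .check_number(p_ns_threshold, "p_ns_threshold", 0, strict_lower = TRUE)
  .check_number(lfc_threshold, "lfc_threshold", 0, strict_lower = TRUE)
  structure(list(p_ns_threshold = p_ns_threshold,
                 lfc_threshold = lfc_threshold), class = "rescue_rule")
}

#' Classify disease DEGs as rescued by a suppressor
#'
#' Evaluated only on the disease-vs-healthy DEG set. Genes missing from
#' either DE table are conservatively not rescued.
#'
#' @param deg_set data.frame from [call_degs()] (needs `gene_id`,
#'   optionally `direction`) or a character vector of gene ids.
#' @param de_suppr_vs_healthy DE table ([wald_de()]) for suppressor vs
#'   healthy.
#' @param de_suppr_vs_disease DE table for suppressor vs disease.
#' @param rule a [rescue_rule()].
#' @return list of class `rescue_result`: `calls` (data.frame `gene_id`,
#'   `mHTT_direction`, `p_vs_healthy`, `lfc_vs_disease`, `rescued`),
#'   `n_rescued`, `fraction_pct` (100 * rescued / |DEG set|).
#' @export
classify_rescue <- function(deg_set, de_suppr_vs_healthy,
                            de_suppr_vs_disease, rule = rescue_rule()) {
  if (is.character(deg_set))
    deg_set <- data.frame(gene_id = deg_set, stringsAsFactors = FALSE)
  if (nrow(deg_set) == 0L)
    .stopf("empty DEG set: rescue fraction undefined")
  ih <- match(deg_set$gene_id, de_suppr_vs_healthy$gene_id)
  id <- match(deg_set$gene_id, de_suppr_vs_disease$gene_id)
  p_h <- de_suppr_vs_healthy$p[ih]
  lfc_d <- de_suppr_vs_disease$log2FC[id]
  rescued <- !is.na(p_h) & !is.na(lfc_d) &
    p_h >= rule$p_ns_threshold & abs(lfc_d) > rule$lfc_threshold
  calls <- data.frame(
    gene_id = deg_set$gene_id,
    mHTT_direction = deg_set$direction %||% NA_character_,
    p_vs_healthy = p_h, lfc_vs_disease = lfc_d, rescued = rescued,
    stringsAsFactors = FALSE)
  structure(list(calls = calls, n_rescued = sum(rescued),
                 fraction_pct = 100 * sum(rescued) / nrow(deg_set)),
            class = "rescue_result")
}

#' One-sided binomial under-representation test for a set overlap
#'
#' Conditions on the smaller set: with `n1 = |smaller|`,
#' `n2 = |larger|`, the overlap under independence is
#' `Binomial(n1, n2 / N)`; the reported p is the lower tail
#' `P(X <= k_obs)` (is the overlap smaller than chance?).
#'
#' @param universe_size N, size of the gene universe.
#' @param set_a,set_b character vectors (subsets of the universe) or
#'   integers giving set sizes, in which case `overlap` must be supplied.
#' @param overlap observed intersection size (only when sizes are given).
#' @return data.frame with `N`, `n1`, `n2`, `overlap`,
#'   `expected_overlap`, `p_under`, `direction`.
#' @export
overlap_binomial_test <- function(universe_size, set_a, set_b,
                                  overlap = NULL) {
  .check_number(universe_size, "universe_size", 1, integer = TRUE)
  if (is.character(set_a) || is.character(set_b)) {
    set_a <- unique(set_a); set_b <- unique(set_b)
    if (max(length(set_a), length(set_b)) > universe_size)
      .stopf("sets larger than the universe")
    overlap <- length(intersect(set_a, set_b))
    na <- length(set_a); nb <- length(set_b)
  } else {
    na <- set_a; nb <- set_b
    if (is.null(overlap)) .stopf("overlap required when sizes are given")
  }
  n1 <- min(na, nb); n2 <- max(na, nb)
  if (overlap > n1) .stopf("overlap exceeds the smaller set")
  expected <- n1 * n2 / universe_size
  p <- pbinom(overlap, n1, n2 / universe_size)
  data.frame(N = universe_size, n1 = n1, n2 = n2, overlap = overlap,
             expected_overlap = expected, p_under = p,
             direction = ifelse(overlap < expected, "under", "over"),
             stringsAsFactors = FALSE)
}

#' Hypergeometric over-representation test
#'
#' `p = P(overlap >= observed)` when drawing `|query|` genes from a
#' universe of `N` containing `|gene_set|` marked genes.
#'
#' @param query character vector of query genes.
#' @param gene_set character vector, the annotated set.
#' @param universe character vector containing both.
#' @return data.frame with `query_size`, `set_size`, `universe_size`,
#'   `overlap`, `p_over`.
#' @export
geneset_overrepresentation <- function(query, gene_set, universe) {
  query <- unique(query); gene_set <- unique(gene_set)
  universe <- unique(universe)
  if (length(query) == 0L) .stopf("empty query set")
  if (length(setdiff(query, universe)) ||
      length(setdiff(gene_set, universe)))
    .stopf("query and gene_set must be subsets of the universe")
  k <- length(intersect(query, gene_set))
  p <- phyper(k - 1L, length(gene_set),
              length(universe) - length(gene_set), length(query),
              lower.tail = FALSE)
  data.frame(query_size = length(query), set_size = length(gene_set),
             universe_size = length(universe), overlap = k, p_over = p,
             stringsAsFactors = FALSE)
}

## Plain two-proportion z-test (no continuity correction); identical
## proportions give z = 0, p = 1.
.two_prop_z <- function(k1, k2, n) {
  p1 <- k1 / n; p2 <- k2 / n
  pbar <- (k1 + k2) / (2 * n)
  if (pbar <= 0 || pbar >= 1) return(1)
  z <- (p1 - p2) / sqrt(pbar * (1 - pbar) * 2 / n)
  2 * pnorm(-abs(z))
}

#' Compare rescue fractions across suppressor conditions
#'
#' Runs [classify_rescue()] per condition over the common DEG
#' denominator and tests every pair of rescued counts with a
#' two-proportion z-test.
#'
#' @param deg_set as in [classify_rescue()].
#' @param de_tables named list: per condition, a list with elements
#'   `vs_healthy` and `vs_disease` (DE tables).
#' @param rule a [rescue_rule()].
#' @return list with `fractions` (data.frame `condition`, `n_rescued`,
#'   `n_degs`, `fraction_pct`), `pairwise` (data.frame `condition_a`,
#'   `condition_b`, `p`), `calls` (named list of per-condition call
#'   tables).
#' @export
compare_rescue_profiles <- function(deg_set, de_tables,
                                    rule = rescue_rule()) {
  if (length(de_tables) < 2L) .stopf("need >= 2 suppressor conditions")
  res <- lapply(de_tables, function(tt)
    classify_rescue(deg_set, tt$vs_healthy, tt$vs_disease, rule))
  n_deg <- nrow(res[[1L]]$calls)
  fr <- data.frame(
    condition = names(de_tables),
    n_rescued = vapply(res, `[[`, 0L, "n_rescued"),
    n_degs = n_deg,
    fraction_pct = vapply(res, `[[`, 0, "fraction_pct"),
    stringsAsFactors = FALSE, row.names = NULL)
  prs <- utils::combn(names(de_tables), 2L)
  pw <- data.frame(
    condition_a = prs[1L, ], condition_b = prs[2L, ],
    p = apply(prs, 2L, function(ab)
      .two_prop_z(fr$n_rescued[fr$condition == ab[1L]],
                  fr$n_rescued[fr$condition == ab[2L]], n_deg)),
    stringsAsFactors = FALSE)
  list(fractions = fr, pairwise = pw,
       calls = lapply(res, `[[`, "calls"))
}
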