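## Negative-binomial count simulator with planted disease and rescue
## structure. Parameterisation throughout: var = mu + alpha * mu^2
## (rnbinom size = 1/alpha).

#' Configuration for count-matrix simulations
#'
#' The default layout emulates a 30-sample overexpression experiment:
#' healthy control (Q15, n = 6), disease (Q128, n = 7) and three
#' suppressor-overexpression conditions on the disease background. Genes
#' in `de_fraction` carry a planted log2 fold change in every
#' disease-background condition; `rescue_fraction` of those have the
#' effect fully reverted (log2FC set to 0) per suppressor condition.
#'
#' @param n_genes number of genes.
#' @param condition_layout named integer vector: replicates per
#'   condition (each >= 2).
#' @param baseline_log_mean `c(mu, sigma)` of the log-normal baseline
#'   mean expression (natural log scale).
#' @param dispersion_dist `c(shape, scale)` of the per-gene gamma
#'   dispersion alpha.
#' @param de_fraction fraction of genes with a planted disease effect.
#' @param lfc_dist `c(mean, sd, sign_balance)`: planted |log2FC| is
#'   normal(mean, sd) truncated at 0.1; `sign_balance` is the up-regulated
#'   share.
#' @param rescue_fraction fraction of planted-DE genes fully reverted in
#'   each suppressor condition.
#' @param libsize_factors optional per-sample positive scalars; default
#'   log-normal(0, 0.15) draws.
#' @param reference_condition healthy baseline label.
#' @param disease_condition disease label.
#' @param suppressor_conditions labels of suppressor conditions (disease
#'   background); default: all conditions other than reference/disease.
#' @param rescued_sets optional named list (per suppressor condition) of
#'   gene ids to revert, overriding the random draw.
#' @param suppressor_extra_fraction fraction of non-DE genes given an
#'   own-program effect in each suppressor condition (the suppressor's
#'   independent transcriptional program), default 0.
#' @param seed integer seed.
#' @return object of class `sim_counts_config`.
#' @export
sim_counts_config <- function(n_genes = 2000L,
                              condition_layout = c(Q15 = 6L, Q128 = 7L,
                                                   Q128_Mtf1 = 6L,
                                                   Q128_Kdm2b = 6L,
                                                   Q128_Mtf1_Kdm2b = 5L),
                              baseline_log_mean = c(mu = 5, sigma = 1.5),
                              dispersion_dist = c(shape = 2, scale = 0.025),
                              de_fraction = 0.15,
                              lfc_dist = c(mean = 2, sd = 0.5,
                                           sign_balance = 0.5),
                              rescue_fraction = 0.4,
                              libsize_factors = NULL,
                              reference_condition = "Q15",
                              disease_condition = "Q128",
                              suppressor_conditions = NULL,
                              rescued_sets = NULL,
                              suppressor_extra_fraction = 0,
                              seed = 1L) {
  .check_number(n_genes, "n_genes", 1, integer = TRUE)
  ## JSON configs deliver vectors as named lists
  if (is.list(condition_layout)) condition_layout <- unlist(condition_layout)
  if (is.list(baseline_log_mean)) baseline_log_mean <- unlist(baseline_log_mean)
  if (is.list(dispersion_dist)) dispersion_dist <- unlist(dispersion_dist)
  if (is.list(lfc_dist)) lfc_dist <- unlist(lfc_dist)
  if (is.null(names(condition_layout)) || any(!nzchar(names(condition_layout))))
    .stopf("condition_layout must be a named vector")
  if (any(condition_layout < 2))
    .stopf("every condition needs >= 2 replicates")
  .check_fraction(de_fraction, "de_fraction")
  .check_fraction(rescue_fraction, "rescue_fraction")
  .check_fraction(suppressor_extra_fraction, "suppressor_extra_fraction")
  .check_fraction(lfc_dist[["sign_balance"]], "lfc_dist['sign_balance']")
  if (any(dispersion_dist <= 0))
    .stopf("dispersion_dist parameters must be > 0")
  conds <- names(condition_layout)
  if (!all(c(reference_condition, disease_condition) %in% conds))
    .stopf("reference/disease condition not in layout")
  if (is.null(suppressor_conditions))
    suppressor_conditions <- setdiff(conds, c(reference_condition,
                                              disease_condition))
  n_samples <- sum(condition_layout)
  if (!is.null(libsize_factors)) {
    if (length(libsize_factors) != n_samples || any(libsize_factors <= 0))
      .stopf("libsize_factors must be %d positive scalars", n_samples)
  }
  structure(list(
    n_genes = as.integer(n_genes),
    condition_layout = condition_layout,
    baseline_log_mean = baseline_log_mean,
    dispersion_dist = dispersion_dist,
    de_fraction = de_fraction,
    lfc_dist = lfc_dist,
    rescue_fraction = rescue_fraction,
    libsize_factors = libsize_factors,
    reference_condition = reference_condition,
    disease_condition = disease_condition,
    suppressor_conditions = suppressor_conditions,
    rescued_sets = rescued_sets,
    suppressor_extra_fraction = suppressor_extra_fraction,
    seed = as.integer(seed)), class = "sim_counts_config")
}

#' Simulate an NB count matrix with planted effects
#'
#' Counts are NB with mean `mu_gs = baseline_g * 2^lfc[g, cond(s)] *
#' libsize_s` and variance `mu + alpha mu^2`. The planted log2FC matrix
#' (vs the reference condition) is returned as truth, alongside the
#' planted-DE and per-suppressor rescued gene sets.
#'
#' @param config a [sim_counts_config()].
#' @return list of class `counts_sim`: `counts` (integer matrix),
#'   `samples` (data.frame `sample_id`, `condition`), `truth` (list:
#'   `true_lfc` gene x condition matrix, `de_genes`, `true_rescued`
#'   named list, `baseline`, `alpha`, `libsize_factors`).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_counts_config"))
  lay <- config$condition_layout
  conds <- names(lay)
  cond_of <- rep(conds, lay)
  n_s <- length(cond_of)
  sample_id <- sprintf("%s_r%d", cond_of,
                       unlist(lapply(lay, seq_len), use.names = FALSE))
  gene_id <- sprintf("g%05d", seq_len(config$n_genes))

  .with_seed(.stage_seed(config$seed, "counts"), {
    baseline <- rlnorm(config$n_genes,
                       config$baseline_log_mean[[1L]],
                       config$baseline_log_mean[[2L]])
    alpha <- pmax(rgamma(config$n_genes,
                         shape = config$dispersion_dist[[1L]],
                         scale = config$dispersion_dist[[2L]]), 1e-8)
    sf <- config$libsize_factors
    if (is.null(sf)) {
      sf <- rlnorm(n_s, 0, 0.15)
      sf <- sf / exp(mean(log(sf)))
    }

    lfc <- matrix(0, config$n_genes, length(conds),
                  dimnames = list(gene_id, conds))
    n_de <- round(config$de_fraction * config$n_genes)
    de_genes <- sort(sample(gene_id, n_de))
    if (n_de > 0L) {
      mag <- pmax(abs(rnorm(n_de, config$lfc_dist[["mean"]],
                            config$lfc_dist[["sd"]])), 0.1)
      sgn <- ifelse(runif(n_de) < config$lfc_dist[["sign_balance"]], 1, -1)
      disease_cols <- c(config$disease_condition,
                        config$suppressor_conditions)
      lfc[de_genes, disease_cols] <- mag * sgn
    }
    true_rescued <- list()
    for (sc in config$suppressor_conditions) {
      res <- config$rescued_sets[[sc]]
      if (is.null(res)) {
        k <- round(config$rescue_fraction * n_de)
        res <- if (k > 0L) sort(sample(de_genes, k)) else character()
      }
      if (length(setdiff(res, de_genes)))
        .stopf("rescued set for %s is not a subset of planted-DE genes", sc)
      lfc[res, sc] <- 0
      true_rescued[[sc]] <- res
    }
    if (config$suppressor_extra_fraction > 0) {
      pool <- setdiff(gene_id, de_genes)
      for (sc in config$suppressor_conditions) {
        k <- round(config$suppressor_extra_fraction * length(pool))
        own <- sample(pool, k)
        lfc[own, sc] <- lfc[own, sc] +
          sample(c(-1, 1), k, TRUE) *
          pmax(abs(rnorm(k, config$lfc_dist[["mean"]],
                         config$lfc_dist[["sd"]])), 0.1)
      }
    }

    mu <- baseline * 2^lfc[, match(cond_of, conds), drop = FALSE]
    mu <- sweep(mu, 2L, sf, `*`)
    counts <- matrix(
      rnbinom(length(mu), mu = mu, size = rep(1 / alpha, n_s)),
      nrow = config$n_genes,
      dimnames = list(gene_id, sample_id))
    storage.mode(counts) <- "integer"

    structure(list(
      counts = counts,
      samples = data.frame(sample_id = sample_id, condition = cond_of,
                           stringsAsFactors = FALSE),
      truth = list(true_lfc = lfc, de_genes = de_genes,
                   true_rescued = true_rescued, baseline = baseline,
                   alpha = alpha, libsize_factors = sf)),
      class = "counts_sim")
  })
}
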