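## Negative-binomial Wald differential expression: low-count filtering,
## median-of-ratios size factors, per-gene method-of-moments dispersion,
## and a two-group log-link NB GLM fitted by IRLS at fixed dispersion.
## Deliberate simplifications relative to the large DE packages: no
## dispersion trend/shrinkage, no LFC shrinkage, no independent filtering
## -- raw LFC and unadjusted two-sided Wald p are thresholded directly.

.ALPHA_MIN <- 1e-8

#' Low-count gene filter
#'
#' `literal-exclusion` removes gene g iff `count < min_count` in at least
#' `min_samples` samples; `detection-keep` removes g iff fewer than
#' `min_samples` samples have `count >= min_count`. The first reading is
#' the default.
#'
#' @param min_count count threshold.
#' @param min_samples sample threshold.
#' @param mode `"literal-exclusion"` or `"detection-keep"`.
#' @return object of class `filter_rule`.
#' @export
filter_rule <- function(min_count = 5L, min_samples = 3L,
                        mode = c("literal-exclusion", "detection-keep")) {
  .check_number(min_count, "min_count", 0, integer = TRUE)
  .check_number(min_samples, "min_samples", 1, integer = TRUE)
  structure(list(min_count = as.integer(min_count),
                 min_samples = as.integer(min_samples),
                 mode = match.arg(mode)), class = "filter_rule")
}

#' Filter low-count genes
#'
#' @param counts integer matrix, genes x samples.
#' @param rule a [filter_rule()].
#' @return the matrix restricted to retained genes, order preserved.
#' @export
filter_low_counts <- function(counts, rule = filter_rule()) {
  stopifnot(inherits(rule, "filter_rule"))
  if (rule$min_samples > ncol(counts))
    .stopf("min_samples (%d) exceeds sample count (%d)",
           rule$min_samples, ncol(counts))
  n_low <- rowSums(counts < rule$min_count)
  keep <- if (rule$mode == "literal-exclusion")
    n_low < rule$min_samples
  else (ncol(counts) - n_low) >= rule$min_samples
  if (!any(keep)) .warnf("filter removed every gene")
  counts[keep, , drop = FALSE]
}

#' Median-of-ratios size factors
#'
#' `factor_s = median_g count_gs / geomean_g`, the median taken over
#' genes with positive counts in every sample; factors are not rescaled
#' afterwards.
#'
#' @param counts integer matrix, genes x samples.
#' @return named numeric vector of per-sample size factors.
#' @export
estimate_size_factors <- function(counts) {
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos))
    .stopf(paste0("no gene has positive counts in every sample; ",
                  "consider a pseudocount or stricter filtering"))
  logc <- log(counts[pos, , drop = FALSE])
  loggeo <- rowMeans(logc)
  sf <- apply(exp(logc - loggeo), 2L, median)
  setNames(sf, colnames(counts))
}

#' Per-gene method-of-moments dispersion
#'
#' On size-factor-normalised counts, within each condition of the
#' contrast: `alpha_c = (s^2 - mbar) / mbar^2`, floored at `1e-8`; the
#' returned estimate is the mean across the contrast's conditions.
#'
#' @param counts integer matrix, genes x samples.
#' @param size_factors per-sample factors from
#'   [estimate_size_factors()].
#' @param conditions per-sample condition labels.
#' @param contrast character(2): the two condition labels used.
#' @return named numeric vector of per-gene alpha (var = mu + alpha mu^2).
#' @export
estimate_dispersions <- function(counts, size_factors, conditions,
                                 contrast) {
  stopifnot(length(conditions) == ncol(counts), length(contrast) == 2L)
  norm <- sweep(counts, 2L, size_factors, `/`)
  per_cond <- sapply(contrast, function(cc) {
    j <- which(conditions == cc)
    if (length(j) < 2L)
      .stopf("condition '%s' needs >= 2 replicates", cc)
    m <- rowMeans(norm[, j, drop = FALSE])
    v <- apply(norm[, j, drop = FALSE], 1L, var)
    a <- (v - m) / m^2
    a[!is.finite(a)] <- .ALPHA_MIN
    a
  })
  alpha <- pmax(rowMeans(per_cond), .ALPHA_MIN)
  setNames(alpha, rownames(counts))
}

#' Two-group negative-binomial Wald test
#'
#' Fits, per gene, `count_gs ~ NB(mu_gs, alpha_g)` with
#' `log mu_gs = log size_factor_s + b0 + b1 * [s in A]` by iteratively
#' reweighted least squares at fixed `alpha_g`. Reports
#' `log2FC = b1 / ln 2` for A versus B, its standard error from the
#' expected information, the Wald statistic and a two-sided normal-tail
#' p-value with no multiplicity adjustment. Genes all-zero in both
#' groups get status `all-zero`; genes with one all-zero group (the LFC
#' is unbounded) get `low-count`; IRLS failures get `not-converged`; in
#' all three cases p is `NA`.
#'
#' @param counts integer matrix, genes x samples.
#' @param size_factors per-sample factors.
#' @param dispersions per-gene alpha.
#' @param conditions per-sample condition labels.
#' @param contrast character(2) `c(A, B)`: log2FC is A over B.
#' @param max_iter IRLS iteration cap.
#' @param tol convergence tolerance on coefficients.
#' @return data.frame with `gene_id`, `base_mean` (mean normalised
#'   count), `log2FC`, `SE`, `stat`, `p`, `status`.
#' @export
wald_de <- function(counts, size_factors, dispersions, conditions,
                    contrast, max_iter = 50L, tol = 1e-8) {
  stopifnot(length(contrast) == 2L)
  jA <- which(conditions == contrast[1L])
  jB <- which(conditions == contrast[2L])
  if (length(jA) < 2L || length(jB) < 2L)
    .stopf("both contrast conditions need >= 2 replicates")
  j <- c(jA, jB)
  y <- counts[, j, drop = FALSE]
  sf <- size_factors[j]
  x <- rep(c(1, 0), c(length(jA), length(jB)))
  alpha <- rep_len(dispersions, nrow(y))
  ng <- nrow(y)
  off <- matrix(log(sf), ng, length(j), byrow = TRUE)

  base_mean <- rowMeans(sweep(y, 2L, sf, `/`))
  mA <- rowMeans(sweep(y[, seq_along(jA), drop = FALSE], 2L, sf[seq_along(jA)], `/`))
  mB <- rowMeans(sweep(y[, length(jA) + seq_along(jB), drop = FALSE], 2L,
                       sf[length(jA) + seq_along(jB)], `/`))
  status <- rep("ok", ng)
  status[mA == 0 & mB == 0] <- "all-zero"
  status[xor(mA == 0, mB == 0)] <- "low-count"
  fit <- status == "ok"

  ## vectorised IRLS over all genes at once (closed-form 2x2 solve)
  b0 <- ifelse(fit, log(pmax(mB, 1e-8)), NA_real_)
  b1 <- ifelse(fit, log(pmax(mA, 1e-8)) - b0, NA_real_)
  conv <- !fit
  xm <- matrix(x, ng, length(j), byrow = TRUE)
  for (it in seq_len(max_iter)) {
    act <- fit & !conv
    if (!any(act)) break
    eta <- off + b0 + b1 * xm
    mu <- pmin(exp(eta), 1e12)
    wgt <- mu / (1 + alpha * mu)
    z <- (eta - off) + (y - mu) / mu
    wz <- wgt * z
    Sw <- rowSums(wgt);  Swx <- rowSums(wgt * xm)
    Swz <- rowSums(wz);  Swxz <- rowSums(wz * xm)
    det <- Sw * Swx - Swx * Swx            # Swxx == Swx (x is 0/1)
    nb0 <- (Swx * Swz - Swx * Swxz) / det
    nb1 <- (Sw * Swxz - Swx * Swz) / det
    step_ok <- is.finite(nb0) & is.finite(nb1)
    delta <- pmax(abs(nb0 - b0), abs(nb1 - b1))
    upd <- act & step_ok
    b0[upd] <- nb0[upd]; b1[upd] <- nb1[upd]
    conv[act & step_ok & delta < tol] <- TRUE
    conv[act & !step_ok] <- TRUE  # degenerate; flagged below
  }
  status[fit & !conv] <- "not-converged"
  ok <- status == "ok"

  se <- rep(NA_real_, ng)
  if (any(ok)) {
    eta <- off + b0 + b1 * xm
    mu <- pmin(exp(eta), 1e12)
    wgt <- mu / (1 + alpha * mu)
    Sw <- rowSums(wgt); Swx <- rowSums(wgt * xm)
    det <- Sw * Swx - Swx * Swx
    se[ok] <- sqrt(Sw / det)[ok]
  }
  log2fc <- b1 / log(2)
  stat <- log2fc / (se / log(2))
  p <- 2 * pnorm(-abs(stat))
  p[!ok] <- NA_real_
  log2fc[status %in% c("all-zero")] <- NA_real_
  data.frame(gene_id = rownames(counts) %||% as.character(seq_len(ng)),
             base_mean = base_mean, log2FC = log2fc, SE = se / log(2),
             stat = stat, p = p, status = status,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' DEG thresholds
#'
#' @param lfc_threshold |log2FC| cutoff (strict).
#' @param p_threshold unadjusted p cutoff (strict).
#' @return object of class `deg_thresholds`.
#' @export
deg_thresholds <- function(lfc_threshold = 0.5, p_threshold = 0.05) {
  .check_number(lfc_threshold, "lfc_threshold", 0)
  .check_number(p_threshold, "p_threshold", 0, 1)
  if (p_threshold <= 0 || p_threshold >= 1)
    .stopf("p_threshold must be in (0, 1)")
  structure(list(lfc_threshold = lfc_threshold,
                 p_threshold = p_threshold), class = "deg_thresholds")
}

#' Call differentially expressed genes
#'
#' DEG iff `|log2FC| > lfc_threshold` and `p < p_threshold` (both
#' strict); direction from the sign of log2FC.
#'
#' @param results data.frame from [wald_de()].
#' @param thresholds a [deg_thresholds()].
#' @return data.frame (`gene_id`, `log2FC`, `p`, `direction`) restricted
#'   to DEGs.
#' @export
call_degs <- function(results, thresholds = deg_thresholds()) {
  if (nrow(results) == 0L) .stopf("empty DE result table")
  sel <- !is.na(results$p) &
    abs(results$log2FC) > thresholds$lfc_threshold &
    results$p < thresholds$p_threshold
  out <- results[sel, c("gene_id", "log2FC", "p")]
  out$direction <- ifelse(out$log2FC > 0, "up", "down")
  rownames(out) <- NULL
  out
}

#' One-call DE pipeline for a contrast
#'
#' Filter, normalise, estimate dispersions and run the Wald test for one
#' two-condition contrast.
#'
#' @param counts integer matrix, genes x samples.
#' @param samples data.frame with `sample_id`, `condition` matching the
#'   matrix columns.
#' @param contrast character(2) `c(A, B)`.
#' @param rule a [filter_rule()] (or `NULL` to skip filtering).
#' @return data.frame from [wald_de()].
#' @export
run_de <- function(counts, samples, contrast, rule = filter_rule()) {
  if (!is.null(rule)) counts <- filter_low_counts(counts, rule)
  sf <- estimate_size_factors(counts)
  disp <- estimate_dispersions(counts, sf, samples$condition, contrast)
  wald_de(counts, sf, disp, samples$condition, contrast)
}
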