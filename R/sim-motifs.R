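## Promoter fixtures with planted motif occurrences.

#' Simulate a promoter set
#'
#' Random iid-composition promoter windows, used as a substrate for
#' [plant_motifs()].
#'
#' @param n_genes number of promoters.
#' @param width window width (bp).
#' @param bg named A/C/G/T composition (default uniform).
#' @param seed integer seed.
#' @return a `promoter_set` data.frame (`gene_id`, `seq`).
#' @export
sim_promoters <- function(n_genes, width = 1100L,
                          bg = c(A = .25, C = .25, G = .25, T = .25),
                          seed = 1L) {
  .with_seed(.stage_seed(seed, "promoters"), {
    seqs <- vapply(seq_len(n_genes), function(i)
      paste(sample(names(bg), width, replace = TRUE, prob = bg),
            collapse = ""), "")
    out <- data.frame(gene_id = sprintf("g%05d", seq_len(n_genes)),
                      seq = seqs, stringsAsFactors = FALSE)
    class(out) <- c("promoter_set", "data.frame")
    out
  })
}

## one concrete instantiation of an IUPAC consensus
.consensus_instance <- function(consensus) {
  paste(vapply(strsplit(consensus, "")[[1L]], function(cc) {
    opts <- .IUPAC[[cc]]
    opts[sample.int(length(opts), 1L)]
  }, ""), collapse = "")
}

#' Plant motif occurrences into promoters
#'
#' Positive genes receive at least one exact consensus occurrence at a
#' random offset; negative genes are made motif-free by rejection
#' sampling (resampling the whole window until [scan_motif()] finds no
#' hit on either strand).
#'
#' @param promoters a `promoter_set`.
#' @param motif a [motif_model()]; planting uses the consensus (for PWM
#'   models, the per-position max-frequency consensus).
#' @param positive_genes gene ids to receive the motif (subset of the
#'   promoter set).
#' @param seed integer seed.
#' @param max_tries rejection-sampling cap per negative.
#' @return list with `promoters` (modified set) and `truth` (list:
#'   `positives`, `offsets` named by gene).
#' @export
plant_motifs <- function(promoters, motif, positive_genes, seed = 1L,
                         max_tries = 200L) {
  stopifnot(inherits(motif, "motif_model"))
  unknown <- setdiff(positive_genes, promoters$gene_id)
  if (length(unknown))
    .stopf("positive gene(s) not in promoter set: %s",
           paste(unknown, collapse = ", "))
  widths <- nchar(promoters$seq)
  if (any(widths < motif$width))
    .stopf("promoter shorter than the motif (%d bp)", motif$width)
  consensus <- if (motif$mode == "consensus") motif$consensus else
    paste(c("A", "C", "G", "T")[apply(motif$pfm, 2L, which.max)],
          collapse = "")
  .with_seed(.stage_seed(seed, "plant_motifs"), {
    offsets <- setNames(rep(NA_integer_, nrow(promoters)),
                        promoters$gene_id)
    for (i in seq_len(nrow(promoters))) {
      g <- promoters$gene_id[i]
      if (g %in% positive_genes) {
        off <- sample.int(widths[i] - motif$width + 1L, 1L) - 1L
        inst <- .consensus_instance(consensus)
        substr(promoters$seq[i], off + 1L, off + motif$width) <- inst
        offsets[g] <- off
      } else {
        tries <- 0L
        repeat {
          sc <- scan_motif(promoters[i, , drop = FALSE], motif)
          if (!any(sc$gene_has_hit)) break
          tries <- tries + 1L
          if (tries > max_tries)
            .stopf("could not make a motif-free promoter for %s", g)
          promoters$seq[i] <- paste(
            sample(c("A", "C", "G", "T"), widths[i], replace = TRUE),
            collapse = "")
        }
      }
    }
    list(promoters = promoters,
         truth = list(positives = intersect(promoters$gene_id,
                                            positive_genes),
                      offsets = offsets))
  })
}
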