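# qPCR validation: 2^-ddCt relative expression and qPCR/DGE concordance.

#' Relative expression by the 2^-ddCt method
#'
#' For each gene and sample, dCt = Ct_target - Ct_reference is averaged over
#' replicates; ddCt is taken against the calibrator sample and relative
#' expression is `2^-ddCt` (amplification efficiency assumed exactly 2).
#' The replicate SD is the SD of replicate-wise folds computed against the
#' calibrator's mean dCt.
#'
#' @param ct Data frame with columns `gene`, `sample`, `replicate`,
#'   `ct_target`, `ct_reference` (see [simulate_ct_table()]).
#' @param calibrator_sample Sample label used as baseline; must be present
#'   for every gene.
#' @return Data frame with `gene`, `sample`, `fold`, `log2_fold`, `sd_fold`,
#'   `n_replicates` for every non-calibrator sample.
#' @export
ddct_fold_change <- function(ct, calibrator_sample) {
  need <- c("gene", "sample", "replicate", "ct_target", "ct_reference")
  stopifnot(all(need %in% names(ct)))
  if (any(ct$ct_target <= 0 | ct$ct_target >= 45 |
          ct$ct_reference <= 0 | ct$ct_reference >= 45))
    stop("Ct values must lie in (0, 45) cycles", call. = FALSE)
  if (any(is.na(ct$ct_reference)))
    stop("missing reference-gene Ct values", call. = FALSE)

  ct$dct <- ct$ct_target - ct$ct_reference
  genes <- unique(ct$gene)
  cal <- ct[ct$sample == calibrator_sample, ]
  miss <- setdiff(genes, cal$gene)
  if (length(miss))
    stop("calibrator sample '", calibrator_sample, "' missing for gene ",
         miss[1L], call. = FALSE)
  cal_mean <- tapply(cal$dct, cal$gene, mean)

  other <- ct[ct$sample != calibrator_sample, , drop = FALSE]
  if (!nrow(other)) stop("no non-calibrator samples", call. = FALSE)
  key <- interaction(other$gene, other$sample, drop = TRUE)
  rows <- split(seq_len(nrow(other)), key)
  out <- do.call(rbind, lapply(rows, function(r) {
    g <- other$gene[r[1L]]
    ddct <- mean(other$dct[r]) - cal_mean[[g]]
    rep_folds <- 2^-(other$dct[r] - cal_mean[[g]])
    data.frame(gene = g, sample = other$sample[r[1L]],
               fold = 2^-ddct, log2_fold = -ddct,
               sd_fold = if (length(r) > 1L) sd(rep_folds) else NA_real_,
               n_replicates = length(r), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Concordance between DGE and qPCR fold changes
#'
#' Direction agreement (fraction of shared genes whose log2 fold changes
#' have the same sign; exact zeros agree with anything) and Spearman rank
#' correlation over the shared genes.
#'
#' @param dge_lfc,qpcr_lfc Named numeric vectors of per-gene log2 fold
#'   changes; at least 3 shared genes required.
#' @return List with `agreement`, `rank_correlation`, `n_shared`.
#' @export
concordance <- function(dge_lfc, qpcr_lfc) {
  shared <- intersect(names(dge_lfc), names(qpcr_lfc))
  if (length(shared) < 3L)
    stop("need at least 3 shared genes", call. = FALSE)
  a <- dge_lfc[shared]
  b <- qpcr_lfc[shared]
  agree <- mean(sign(a) == sign(b) | sign(a) == 0 | sign(b) == 0)
  rho <- cor(a, b, method = "spearman")
  list(agreement = agree, rank_correlation = unname(rho),
       n_shared = length(shared))
}
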