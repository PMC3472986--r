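# Hypergeometric functional enrichment of DEG sets against GO-like terms
# (Bonferroni) and pathway-like sets (BH Q-values).

#' Hypergeometric enrichment p-value
#'
#' Upper-tail probability that at least `m` of the `n` differentially
#' expressed genes fall in a term of `M` genes, out of `N` annotated genes:
#' \deqn{P = 1 - \sum_{i=0}^{m-1} \binom{M}{i}\binom{N-M}{n-i} / \binom{N}{n},}
#' computed as the direct upper-tail sum of log-binomial terms.
#'
#' @param N Number of annotated genes (universe).
#' @param n Number of DEGs within the universe.
#' @param M Genes annotated to the term.
#' @param m DEGs annotated to the term.
#' @return `P(X >= m)` under hypergeometric(N, M, n).
#' @export
hypergeom_enrich_p <- function(N, n, M, m) {
  if (any(c(N, n, M, m) < 0) || m > min(n, M) || n > N || M > N)
    stop("infeasible (N, n, M, m) configuration", call. = FALSE)
  if (m == 0) return(1)
  i <- m:min(n, M)
  terms <- lchoose(M, i) + lchoose(N - M, n - i) - lchoose(N, n)
  min(1, max(0, exp(logsumexp(terms[is.finite(terms)]))))
}

# shared engine for GO-term and pathway enrichment
enrich_sets <- function(degs, assignments, set_col) {
  universe <- unique(assignments$gene)
  dropped <- setdiff(degs, universe)
  degs_u <- intersect(degs, universe)
  if (!length(degs_u))
    warning("no DEG carries an annotation; all terms non-enriched")
  N <- length(universe)
  n <- length(degs_u)
  sets <- split(assignments$gene, assignments[[set_col]])
  M <- vapply(sets, function(g) length(unique(g)), integer(1))
  m <- vapply(sets, function(g) length(intersect(unique(g), degs_u)),
              integer(1))
  p <- vapply(seq_along(sets),
              function(k) hypergeom_enrich_p(N, n, M[k], m[k]), numeric(1))
  structure(
    data.frame(id = names(sets), N = N, n = n, M = as.integer(M),
               m = as.integer(m), p_value = p, stringsAsFactors = FALSE),
    dropped_degs = dropped)
}

#' GO-term enrichment of differentially expressed genes
#'
#' Hypergeometric upper-tail test per term over the universe of genes with
#' at least one term annotation; DEGs without annotation are dropped from
#' `n` (and recorded in the `dropped_degs` attribute). P-values are
#' Bonferroni-corrected by the number of terms tested; a term is enriched
#' when the corrected p-value is at most `alpha`.
#'
#' @param degs Character vector of DEG gene ids.
#' @param annotation An `annotation_map` (or data frame with columns `gene`
#'   and `term`).
#' @param alpha Corrected-p threshold (default 0.05).
#' @return Data frame of class `enrichment_result`: `id`, `ontology`, `N`,
#'   `n`, `M`, `m`, `p_value`, `corrected_p`, `enriched`.
#' @export
go_enrichment <- function(degs, annotation, alpha = 0.05) {
  ann <- if (inherits(annotation, "annotation_map")) annotation$terms
         else annotation
  stopifnot(all(c("gene", "term") %in% names(ann)))
  out <- enrich_sets(degs, ann, "term")
  out$corrected_p <- pmin(1, out$p_value * nrow(out))
  out$enriched <- out$corrected_p <= alpha
  ont <- if (inherits(annotation, "annotation_map"))
    setNames(annotation$term_ontology$ontology, annotation$term_ontology$term)
  else NULL
  dropped <- attr(out, "dropped_degs")
  out <- cbind(out[1L],
               ontology = if (is.null(ont)) NA_character_ else unname(ont[out$id]),
               out[-1L])
  attr(out, "dropped_degs") <- dropped
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Pathway enrichment of differentially expressed genes
#'
#' Same hypergeometric test as [go_enrichment()], over the pathway
#' annotation universe, with Benjamini-Hochberg Q-values across pathways; a
#' pathway is enriched when `q_value <= q_threshold`.
#'
#' @param degs Character vector of DEG gene ids.
#' @param annotation An `annotation_map` (or data frame with columns `gene`
#'   and `pathway`).
#' @param q_threshold Q-value threshold (default 0.05).
#' @return Data frame of class `enrichment_result`: `id`, `N`, `n`, `M`,
#'   `m`, `p_value`, `q_value`, `enriched`.
#' @export
pathway_enrichment <- function(degs, annotation, q_threshold = 0.05) {
  ann <- if (inherits(annotation, "annotation_map")) annotation$pathways
         else annotation
  stopifnot(all(c("gene", "pathway") %in% names(ann)))
  out <- enrich_sets(degs, ann, "pathway")
  out$q_value <- bh_fdr(out$p_value)
  out$enriched <- out$q_value <= q_threshold
  class(out) <- c("enrichment_result", "data.frame")
  out
}
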