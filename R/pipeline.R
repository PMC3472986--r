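# End-to-end convenience: raw reads from two libraries -> clean tags ->
# mapping -> expression -> differential expression.

#' Run the full tag-profiling pipeline on two read libraries
#'
#' Cleans both read sets, builds the virtual CATG+17 libraries (genes, both
#' strands; genome if present), maps clean tags, derives unambiguous gene
#' counts with TPM, and screens differentially expressed genes.
#'
#' @param reads1,reads2 `raw_reads` objects or character vectors of 49nt
#'   reads for condition 1 and condition 2.
#' @param reference A `dge_reference`.
#' @param adaptor 3' adaptor used for trimming.
#' @param fdr_threshold,lfc_threshold DE thresholds (0.001 and 1).
#' @param tpm_floor TPM floor for log2 ratios.
#' @return List with `tags1`, `tags2` (tag count tables), `mapping1`,
#'   `mapping2`, `expr1`, `expr2` (TPM-normalised expression tables),
#'   `de` (the `dge_de` table), `gene_lib`, `genome_lib`, and
#'   `summary1`/`summary2` (library summaries with mapping tallies).
#' @export
run_dge_pipeline <- function(reads1, reads2, reference,
                             adaptor = default_adaptor(),
                             fdr_threshold = 0.001, lfc_threshold = 1,
                             tpm_floor = 0.001) {
  tags1 <- extract_clean_tags(reads1, adaptor, library = "lib1")
  tags2 <- extract_clean_tags(reads2, adaptor, library = "lib2")
  gene_lib <- build_virtual_tag_library(reference)
  genome_lib <- if (!is.null(reference$genome))
    build_virtual_tag_library(reference$genome) else NULL

  mapping1 <- map_tags(tags1, gene_lib, genome_lib)
  mapping2 <- map_tags(tags2, gene_lib, genome_lib)
  expr1 <- tpm_normalize(gene_counts(mapping1))
  expr2 <- tpm_normalize(gene_counts(mapping2))
  de <- diff_expression(expr1, expr2,
                        N1 = tags1$total_clean, N2 = tags2$total_clean,
                        fdr_threshold = fdr_threshold,
                        lfc_threshold = lfc_threshold, tpm_floor = tpm_floor)
  list(tags1 = tags1, tags2 = tags2,
       mapping1 = mapping1, mapping2 = mapping2,
       expr1 = expr1, expr2 = expr2, de = de,
       gene_lib = gene_lib, genome_lib = genome_lib,
       summary1 = library_summary(tags1, tallies = mapping_tallies(mapping1),
                                  n_ref_genes = length(ref_genes(reference))),
       summary2 = library_summary(tags2, tallies = mapping_tallies(mapping2),
                                  n_ref_genes = length(ref_genes(reference))))
}
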