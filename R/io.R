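# Plain-text interchange: FASTA references, FASTQ reads, TSV tables.

#' Write/read reference sequences as FASTA
#'
#' @param reference A `dge_reference`.
#' @param path Output FASTA path for the gene sequences.
#' @param genome_path Optional FASTA path for the genome sequence.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(reference, path, genome_path = NULL) {
  genes <- ref_genes(reference)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genes), path)
  if (!is.null(genome_path) && !is.null(reference$genome)) {
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(c(genome = reference$genome)), genome_path)
  }
  invisible(path)
}

#' @rdname write_reference_fasta
#' @export
read_reference_fasta <- function(path, genome_path = NULL) {
  genes <- Biostrings::readDNAStringSet(path)
  genome <- NULL
  if (!is.null(genome_path)) {
    genome <- as.character(Biostrings::readDNAStringSet(genome_path))[[1L]]
  }
  structure(list(genes = setNames(as.character(genes), names(genes)),
                 genome = genome),
            spacers = character(0), class = "dge_reference")
}

#' Write/read raw tag reads as FASTQ
#'
#' Reads are written with a constant quality string (`I`), as the protocol
#' carries no per-base quality model.
#'
#' @param reads A `raw_reads` object or character vector.
#' @param path FASTQ path.
#' @return `path` (write) or a character vector of reads (read).
#' @export
write_reads_fastq <- function(reads, path) {
  if (inherits(reads, "raw_reads")) reads <- reads$reads
  x <- Biostrings::DNAStringSet(reads)
  names(x) <- sprintf("read%d", seq_along(x))
  qual <- Biostrings::PhredQuality(rep(strrep("I", READ_LENGTH), length(x)))
  Biostrings::writeXStringSet(Biostrings::QualityScaledDNAStringSet(x, qual),
                              path, format = "fastq")
  invisible(path)
}

#' @rdname write_reads_fastq
#' @export
read_reads_fastq <- function(path) {
  unname(as.character(Biostrings::readDNAStringSet(path, format = "fastq")))
}

#' Write a tag count table, expression table or truth table as TSV
#'
#' @param x Object to serialise.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tag_table_tsv <- function(x, path) {
  stopifnot(inherits(x, "tag_count_table"))
  write_tsv_file(data.frame(tag = names(x$counts), count = x$counts,
                            row.names = NULL), path)
}

#' @rdname write_tag_table_tsv
#' @export
read_tag_table_tsv <- function(path, library = NULL) {
  df <- read_tsv_file(path)
  counts <- sort(setNames(as.integer(df$count), df$tag), decreasing = TRUE)
  new_tag_count_table(counts, library,
                      raw_total = NA_integer_, raw_distinct = NA_integer_)
}

#' @rdname write_tag_table_tsv
#' @export
write_truth_tsv <- function(x, path) {
  stopifnot(inherits(x, "expression_truth"))
  write_tsv_file(as.data.frame(x), path)
}

#' Write/read gene annotations as TSV (gene, id, kind)
#'
#' @param annotation An `annotation_map`.
#' @param path TSV path.
#' @return `path` (write) or an `annotation_map` (read).
#' @export
write_annotation_tsv <- function(annotation, path) {
  stopifnot(inherits(annotation, "annotation_map"))
  ont <- setNames(annotation$term_ontology$ontology,
                  annotation$term_ontology$term)
  df <- rbind(
    data.frame(gene = annotation$terms$gene, id = annotation$terms$term,
               kind = unname(ont[annotation$terms$term]),
               stringsAsFactors = FALSE),
    data.frame(gene = annotation$pathways$gene, id = annotation$pathways$pathway,
               kind = "pathway", stringsAsFactors = FALSE))
  write_tsv_file(df, path)
}

#' @rdname write_annotation_tsv
#' @export
read_annotation_tsv <- function(path) {
  df <- read_tsv_file(path)
  is_path <- df$kind == "pathway"
  terms <- data.frame(gene = df$gene[!is_path], term = df$id[!is_path],
                      stringsAsFactors = FALSE)
  pathways <- data.frame(gene = df$gene[is_path], pathway = df$id[is_path],
                         stringsAsFactors = FALSE)
  uniq <- !duplicated(terms$term)
  structure(list(terms = terms, pathways = pathways,
                 term_ontology = data.frame(term = terms$term[uniq],
                                            ontology = df$kind[!is_path][uniq],
                                            stringsAsFactors = FALSE)),
            class = "annotation_map")
}
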