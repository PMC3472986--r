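# Virtual CATG+17 tag library, exact/one-mismatch tag-to-gene mapping with
# category classification, gene-level unambiguous counts and TPM.

MAPPING_CATEGORIES <- c("PM-gene-sense", "PM-gene-antisense",
                        "1MM-gene-sense", "1MM-gene-antisense",
                        "PM-genome-1pos", "PM-genome-npos",
                        "1MM-genome", "unknown")

#' Build the virtual CATG+17 tag library
#'
#' Enumerates, for every reference sequence, every CATG occurrence with at
#' least 17nt downstream, yielding the 21nt tag, and (optionally) the same
#' for the reverse complement, labelled antisense. Offsets are 0-based
#' positions of the CATG start on the sense strand.
#'
#' @param reference A `dge_reference`, a named character vector of
#'   sequences, or a single string (indexed as target `"genome"`).
#' @param include_antisense Index the reverse-complement strand too.
#' @return Data frame of class `virtual_tag_library` with columns `tag`,
#'   `target`, `strand` (`sense`/`antisense`), `offset`.
#' @export
build_virtual_tag_library <- function(reference, include_antisense = TRUE) {
  seqs <- if (inherits(reference, "dge_reference")) {
    reference$genes
  } else if (is.character(reference) && is.null(names(reference)) &&
             length(reference) == 1L) {
    c(genome = reference)
  } else {
    ref_genes(reference)
  }
  if (!length(seqs)) stop("empty reference", call. = FALSE)

  one_strand <- function(seq, target, strand) {
    s <- tag_sites(seq)
    if (!length(s)) return(NULL)
    L <- nchar(seq)
    offset <- if (strand == "sense") s - 1L else L - 3L - s
    data.frame(tag = substring(seq, s, s + TAG_LENGTH - 1L),
               target = target, strand = strand, offset = offset,
               stringsAsFactors = FALSE)
  }
  pieces <- vector("list", length(seqs) * 2L)
  for (i in seq_along(seqs)) {
    pieces[[2L * i - 1L]] <- one_strand(seqs[[i]], names(seqs)[i], "sense")
    if (include_antisense) {
      pieces[[2L * i]] <- one_strand(revcomp(seqs[[i]]), names(seqs)[i],
                                     "antisense")
    }
  }
  lib <- do.call(rbind, pieces)
  if (is.null(lib)) {
    lib <- data.frame(tag = character(0), target = character(0),
                      strand = character(0), offset = integer(0),
                      stringsAsFactors = FALSE)
  }
  structure(lib, targets = unique(names(seqs)),
            class = c("virtual_tag_library", "data.frame"))
}

# hash-style index: unique tag keys plus a list of entry-row indices per key
lib_index <- function(lib) {
  keys <- unique(lib$tag)
  rows <- split(seq_len(nrow(lib)), factor(lib$tag, levels = keys))
  list(keys = keys, rows = rows)
}

# for each query, the library entry rows at Hamming distance exactly 1,
# found by enumerating single-base substitutions at `positions`
one_mismatch_rows <- function(qtags, index, positions) {
  hits <- vector("list", length(qtags))
  if (!length(qtags) || !length(index$keys)) return(hits)
  bases <- c("A", "C", "G", "T")
  for (p in positions) {
    orig <- substr(qtags, p, p)
    for (b in bases) {
      sel <- which(orig != b)
      if (!length(sel)) next
      cand <- qtags[sel]
      substr(cand, p, p) <- b
      mi <- match(cand, index$keys)
      found <- which(!is.na(mi))
      for (k in found) {
        q <- sel[k]
        hits[[q]] <- c(hits[[q]], index$rows[[mi[k]]])
      }
    }
  }
  hits
}

#' Map clean tags against the virtual tag libraries
#'
#' Classifies every clean tag into one of eight mutually exclusive
#' categories with the precedence: perfect gene match, one-mismatch gene
#' match, perfect genome match (single or multiple positions), one-mismatch
#' genome match, unknown. Within gene matches, sense and antisense hits are
#' both recorded and a tag hitting both strands of a gene is classified
#' sense (sense priority). Tags whose gene set at the winning level contains
#' more than one gene are marked ambiguous (`multiplicity = "many"`) and
#' carry no assigned gene. One-mismatch search enumerates the single-base
#' substitutions of the 17 non-anchor positions (the CATG anchor is shared
#' by every clean tag and library key) against a hash of library keys;
#' set `mismatch_in_anchor = TRUE` to enumerate all 21 positions.
#'
#' @param tags A `tag_count_table` or named integer vector (tag -> count).
#' @param gene_lib `virtual_tag_library` built from the reference genes.
#' @param genome_lib Optional `virtual_tag_library` built from the genome.
#' @param mismatch_in_anchor Also allow mismatches inside the CATG anchor.
#' @return Data frame of class `tag_mapping` with columns `tag`, `count`,
#'   `category`, `multiplicity` (`one`/`many`/`n/a`), `gene` (assigned gene
#'   for unambiguous gene matches, else `NA`), `strand`, `genes_hit`
#'   (semicolon-joined gene set at the winning level). Attributes:
#'   `gene_ids` (library targets), `clean_total`.
#' @export
map_tags <- function(tags, gene_lib, genome_lib = NULL,
                     mismatch_in_anchor = FALSE) {
  if (inherits(tags, "tag_count_table")) {
    counts <- tags$counts
  } else {
    counts <- tags
  }
  qtags <- names(counts)
  if (is.null(qtags)) stop("`tags` must be named by tag sequence", call. = FALSE)
  if (any(nchar(qtags) != TAG_LENGTH))
    stop("all tags must be exactly 21nt", call. = FALSE)

  nq <- length(qtags)
  category <- rep("unknown", nq)
  multiplicity <- rep("n/a", nq)
  gene <- rep(NA_character_, nq)
  strand <- rep(NA_character_, nq)
  genes_hit <- rep(NA_character_, nq)

  positions <- if (mismatch_in_anchor) seq_len(TAG_LENGTH) else
    seq.int(nchar(TAG_ANCHOR) + 1L, TAG_LENGTH)

  gidx <- lib_index(gene_lib)

  classify_gene <- function(i, rows, level) {
    g <- unique(gene_lib$target[rows])
    has_sense <- any(gene_lib$strand[rows] == "sense")
    category[i] <<- paste0(level, "-gene-", if (has_sense) "sense" else "antisense")
    genes_hit[i] <<- paste(sort(g), collapse = ";")
    if (length(g) == 1L) {
      multiplicity[i] <<- "one"
      gene[i] <<- g
      strand[i] <<- if (has_sense) "sense" else "antisense"
    } else {
      multiplicity[i] <<- "many"
    }
  }

  # perfect gene matches
  mi <- match(qtags, gidx$keys)
  pm <- which(!is.na(mi))
  for (i in pm) classify_gene(i, gidx$rows[[mi[i]]], "PM")

  # one-mismatch gene matches
  todo <- which(is.na(mi))
  mm_hits <- one_mismatch_rows(qtags[todo], gidx, positions)
  got_mm <- lengths(mm_hits) > 0L
  for (k in which(got_mm)) classify_gene(todo[k], mm_hits[[k]], "1MM")

  # genome matches for the remainder
  todo <- todo[!got_mm]
  if (!is.null(genome_lib) && length(todo)) {
    xidx <- lib_index(genome_lib)
    mi2 <- match(qtags[todo], xidx$keys)
    pm2 <- which(!is.na(mi2))
    for (k in pm2) {
      i <- todo[k]
      npos <- length(xidx$rows[[mi2[k]]])
      category[i] <- if (npos == 1L) "PM-genome-1pos" else "PM-genome-npos"
    }
    rest <- todo[is.na(mi2)]
    mm2 <- one_mismatch_rows(qtags[rest], xidx, positions)
    category[rest[lengths(mm2) > 0L]] <- "1MM-genome"
  }

  structure(
    data.frame(tag = qtags, count = as.integer(counts),
               category = factor(category, levels = MAPPING_CATEGORIES),
               multiplicity = multiplicity, gene = gene, strand = strand,
               genes_hit = genes_hit, stringsAsFactors = FALSE),
    gene_ids = attr(gene_lib, "targets"),
    clean_total = sum(counts),
    class = c("tag_mapping", "data.frame"))
}

#' Mapping tallies for the library summary
#'
#' Copy-weighted and distinct-tag tallies per summary category: all tags
#' mapping to a gene (perfect or one mismatch, either strand, ambiguous
#' included), unambiguous gene tags, tags mapping only to the genome, and
#' unknown tags, plus the numbers of genes hit by any tag and by at least
#' one unambiguous tag.
#'
#' @param mapping A `tag_mapping`.
#' @return Named list consumed by [library_summary()].
#' @export
mapping_tallies <- function(mapping) {
  stopifnot(inherits(mapping, "tag_mapping"))
  cat <- as.character(mapping$category)
  is_gene <- cat %in% c("PM-gene-sense", "PM-gene-antisense",
                        "1MM-gene-sense", "1MM-gene-antisense")
  is_genome <- cat %in% c("PM-genome-1pos", "PM-genome-npos", "1MM-genome")
  is_unknown <- cat == "unknown"
  is_unambig <- is_gene & mapping$multiplicity == "one"
  all_genes <- unique(unlist(strsplit(mapping$genes_hit[is_gene], ";",
                                      fixed = TRUE)))
  list(
    gene_total = sum(mapping$count[is_gene]),
    gene_distinct = sum(is_gene),
    unambig_total = sum(mapping$count[is_unambig]),
    unambig_distinct = sum(is_unambig),
    genome_total = sum(mapping$count[is_genome]),
    genome_distinct = sum(is_genome),
    unknown_total = sum(mapping$count[is_unknown]),
    unknown_distinct = sum(is_unknown),
    genes_all = length(all_genes),
    genes_unambig = length(unique(mapping$gene[is_unambig]))
  )
}

#' Gene-level unambiguous tag counts
#'
#' Sums the copy numbers of the unambiguous sense-strand tags assigned to
#' each gene; unambiguous antisense assignments are tallied separately and
#' never added to the expression count.
#'
#' @param mapping A `tag_mapping`.
#' @param gene_ids Gene universe (defaults to the mapping's library targets).
#' @return Data frame of class `gene_expression` with columns `gene`,
#'   `count`, `antisense_count`, zero-filled over the gene universe;
#'   attribute `clean_total` carries the library's clean-tag total.
#' @export
gene_counts <- function(mapping, gene_ids = NULL) {
  stopifnot(inherits(mapping, "tag_mapping"))
  if (is.null(gene_ids)) gene_ids <- attr(mapping, "gene_ids")
  ok <- mapping$multiplicity == "one" & !is.na(mapping$gene)
  sum_by_gene <- function(rows) {
    if (!any(rows)) return(setNames(numeric(length(gene_ids)), gene_ids))
    agg <- tapply(mapping$count[rows], mapping$gene[rows], sum)
    out <- setNames(numeric(length(gene_ids)), gene_ids)
    out[names(agg)] <- agg
    out
  }
  sense <- sum_by_gene(ok & mapping$strand == "sense")
  anti <- sum_by_gene(ok & mapping$strand == "antisense")
  structure(
    data.frame(gene = gene_ids, count = as.integer(sense),
               antisense_count = as.integer(anti), stringsAsFactors = FALSE),
    clean_total = attr(mapping, "clean_total"),
    class = c("gene_expression", "data.frame"))
}

#' TPM normalisation
#'
#' Transcripts per million clean tags: `count / clean_total * 1e6`. The
#' denominator is the library's total clean-tag count, not the sum of
#' gene-assigned counts.
#'
#' @param counts A `gene_expression` data frame.
#' @param clean_total Library clean-tag total (defaults to the attribute
#'   recorded at mapping time).
#' @return The input with a `tpm` column added.
#' @export
tpm_normalize <- function(counts, clean_total = NULL) {
  stopifnot(inherits(counts, "gene_expression"))
  if (is.null(clean_total)) clean_total <- attr(counts, "clean_total")
  if (is.null(clean_total) || clean_total <= 0)
    stop("`clean_total` must be a positive count", call. = FALSE)
  counts$tpm <- counts$count / clean_total * 1e6
  attr(counts, "clean_total") <- clean_total
  counts
}
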