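# Raw-read cleaning into clean-tag count tables, library summary statistics,
# copy-number distribution and saturation (rarefaction) analysis.

#' Extract clean tags from raw 49bp reads
#'
#' Applies the five cleaning rules, in order: (1) trim each read at the
#' first occurrence of the 3' adaptor prefix (minimum overlap
#' `min_overlap` nt); (2) drop empty reads (adaptor at position 1, nothing
#' before it); (3) drop tags containing 'N'; (4) keep only tags of exactly
#' 21nt that begin with the CATG anchor; (5) drop tags whose total copy
#' number is 1 (presumed sequencing errors).
#'
#' @param reads A `raw_reads` object or character vector of 49nt reads.
#' @param adaptor The 3' adaptor sequence.
#' @param min_overlap Minimum adaptor prefix length searched for (nt).
#' @param library Optional library label (e.g. `"PF"`).
#' @param min_copy Minimum copy number kept (default 2).
#' @return Object of class `tag_count_table`: list with `counts` (named
#'   integer vector, tag -> copy number, sorted decreasing), `library`,
#'   `total_clean`, `distinct_clean`, `raw_total`, `raw_distinct`.
#' @export
extract_clean_tags <- function(reads, adaptor = default_adaptor(),
                               min_overlap = 8L, library = NULL,
                               min_copy = 2L) {
  if (inherits(reads, "raw_reads")) reads <- reads$reads
  if (!is.character(reads)) stop("`reads` must be character", call. = FALSE)
  if (!nzchar(adaptor) || nchar(adaptor) < min_overlap)
    stop("`adaptor` must be at least `min_overlap` nt", call. = FALSE)

  raw_total <- length(reads)
  raw_distinct <- length(unique(reads))
  if (raw_total == 0L) {
    return(new_tag_count_table(integer(0), library, 0L, 0L))
  }
  bad <- which(nchar(reads) != READ_LENGTH)
  if (length(bad)) {
    stop(sprintf("read %d has length %d, expected %d",
                 bad[1L], nchar(reads[bad[1L]]), READ_LENGTH), call. = FALSE)
  }

  # rule 1: trim at the first adaptor-prefix occurrence
  key <- substr(adaptor, 1L, min_overlap)
  pos <- regexpr(key, reads, fixed = TRUE)
  tag <- ifelse(pos > 0L, substr(reads, 1L, pos - 1L), reads)
  # rule 2: empty reads (only adaptor, no tag)
  tag <- tag[nchar(tag) > 0L]
  # rule 3: unknown bases
  tag <- tag[!grepl("N", tag, fixed = TRUE)]
  # rule 4: exactly 21nt, anchored at CATG
  tag <- tag[nchar(tag) == TAG_LENGTH & startsWith(tag, TAG_ANCHOR)]
  # rule 5: copy number >= min_copy
  counts <- table(tag)
  counts <- counts[counts >= min_copy]
  counts <- sort(setNames(as.integer(counts), names(counts)),
                 decreasing = TRUE)

  new_tag_count_table(counts, library, raw_total, raw_distinct)
}

new_tag_count_table <- function(counts, library, raw_total, raw_distinct) {
  structure(list(counts = counts, library = library,
                 total_clean = sum(counts),
                 distinct_clean = length(counts),
                 raw_total = raw_total, raw_distinct = raw_distinct),
            class = "tag_count_table")
}

#' @export
print.tag_count_table <- function(x, ...) {
  cat(sprintf("Clean tag table%s: %d clean tags (%d distinct) from %d raw reads\n",
              if (is.null(x$library)) "" else paste0(" [", x$library, "]"),
              x$total_clean, x$distinct_clean, x$raw_total))
  invisible(x)
}

#' Library summary statistics with percentages of clean tags
#'
#' Produces the standard DGE sequencing summary: raw and clean totals, and —
#' when mapping tallies are supplied — per-category totals and distinct-tag
#' counts with their percentages of the clean totals (and of the reference
#' gene count for gene tallies). Percentages are `100 * numerator /
#' denominator` rounded half-up to 2 decimals; copy-weighted tallies are
#' divided by the clean-tag total, distinct tallies by the distinct
#' clean-tag count.
#'
#' @param table A `tag_count_table`, or `NULL` if `clean_total` and
#'   `clean_distinct` are given directly.
#' @param raw_total,raw_distinct Raw read totals (defaulted from `table`).
#' @param tallies Optional named list of mapping tallies, as produced by
#'   [mapping_tallies()]: `gene_total`, `gene_distinct`, `unambig_total`,
#'   `unambig_distinct`, `genome_total`, `genome_distinct`, `unknown_total`,
#'   `unknown_distinct`, `genes_all`, `genes_unambig`.
#' @param n_ref_genes Optional reference gene count (denominator for the
#'   gene percentages).
#' @param clean_total,clean_distinct Clean totals when `table` is `NULL`.
#' @return A data frame (class `library_summary`) with columns `statistic`
#'   and `value`.
#' @export
library_summary <- function(table = NULL, raw_total = NULL, raw_distinct = NULL,
                            tallies = NULL, n_ref_genes = NULL,
                            clean_total = NULL, clean_distinct = NULL) {
  if (!is.null(table)) {
    stopifnot(inherits(table, "tag_count_table"))
    clean_total <- table$total_clean
    clean_distinct <- table$distinct_clean
    if (is.null(raw_total)) raw_total <- table$raw_total
    if (is.null(raw_distinct)) raw_distinct <- table$raw_distinct
  }
  if (is.null(clean_total) || is.null(clean_distinct))
    stop("supply `table` or both `clean_total` and `clean_distinct`",
         call. = FALSE)
  if (clean_total == 0L) stop("clean-tag total is zero", call. = FALSE)

  stats <- c(raw_total = raw_total, raw_distinct = raw_distinct,
             clean_total = clean_total, clean_distinct = clean_distinct)
  if (!is.null(tallies)) {
    need <- c("gene_total", "gene_distinct", "unambig_total",
              "unambig_distinct", "genome_total", "genome_distinct",
              "unknown_total", "unknown_distinct")
    missing <- setdiff(need, names(tallies))
    if (length(missing))
      stop("tallies missing: ", paste(missing, collapse = ", "), call. = FALSE)
    for (cat in c("gene", "unambig", "genome", "unknown")) {
      tot <- tallies[[paste0(cat, "_total")]]
      dis <- tallies[[paste0(cat, "_distinct")]]
      stats[paste0(cat, "_total")] <- tot
      stats[paste0(cat, "_total_pct")] <- pct_of(tot, clean_total)
      stats[paste0(cat, "_distinct")] <- dis
      stats[paste0(cat, "_distinct_pct")] <- pct_of(dis, clean_distinct)
    }
    for (g in c("genes_all", "genes_unambig")) {
      if (!is.null(tallies[[g]])) {
        stats[g] <- tallies[[g]]
        if (!is.null(n_ref_genes))
          stats[paste0(g, "_pct")] <- pct_of(tallies[[g]], n_ref_genes)
      }
    }
  }
  structure(data.frame(statistic = names(stats),
                       value = as.numeric(unname(stats)),
                       stringsAsFactors = FALSE),
            class = c("library_summary", "data.frame"))
}

#' Copy-number distribution of clean tags
#'
#' Bins clean tags by copy number into the standard bins 2-5, 6-10, 11-20,
#' 21-50, 51-100 and >100, reporting per bin the summed copy number (total
#' clean tags) and the number of distinct tags. The bins partition
#' `[2, Inf)`, so the bin totals sum to the clean totals.
#'
#' @param table A `tag_count_table`.
#' @return Data frame with columns `bin`, `total`, `distinct`.
#' @export
copy_number_distribution <- function(table) {
  stopifnot(inherits(table, "tag_count_table"))
  edges <- c(1, 5, 10, 20, 50, 100, Inf)
  labels <- c("2-5", "6-10", "11-20", "21-50", "51-100", ">100")
  bin <- cut(table$counts, edges, labels = labels)
  total <- vapply(split(table$counts, bin), sum, numeric(1))
  distinct <- as.integer(table(bin))
  data.frame(bin = labels, total = as.numeric(total), distinct = distinct,
             stringsAsFactors = FALSE)
}

#' Expand a tag count table into a stream of tag occurrences
#'
#' @param table A `tag_count_table`.
#' @return Character vector of length `total_clean`, each tag repeated by
#'   its copy number.
#' @export
tag_stream <- function(table) {
  stopifnot(inherits(table, "tag_count_table"))
  rep(names(table$counts), table$counts)
}

#' Saturation (rarefaction) curve of a tag library
#'
#' Shuffles the tag occurrence stream once (seeded) and counts, at each grid
#' point k, the distinct tags — and, when a mapping is supplied, the
#' distinct unambiguously assigned genes — among the first k occurrences. A
#' plateau indicates the library was sequenced to saturation.
#'
#' @param stream Character vector of tag occurrences (see [tag_stream()]).
#' @param grid Increasing integer sample sizes (default: 20 evenly spaced
#'   points up to the stream length).
#' @param mapping Optional `tag_mapping` result used to translate tags to
#'   genes (unambiguous assignments only).
#' @param seed Integer seed for the single shuffle.
#' @return Data frame (class `saturation_curve`) with `tags_sampled`,
#'   `distinct_tags` and (if mapping given) `genes_detected`.
#' @export
saturation_curve <- function(stream, grid = NULL, mapping = NULL, seed = 1L) {
  n <- length(stream)
  if (n == 0L) stop("empty tag stream", call. = FALSE)
  if (is.null(grid)) {
    grid <- unique(pmax(1L, round(seq(n / 20, n, length.out = 20L))))
  }
  if (is.unsorted(grid, strictly = FALSE) || max(grid) > n || min(grid) < 1)
    stop("`grid` must be ascending and within the stream length", call. = FALSE)

  with_seed(seed, {
    perm <- sample(stream)
    cum_tags <- cumsum(!duplicated(perm))
    out <- data.frame(tags_sampled = grid, distinct_tags = cum_tags[grid])
    if (!is.null(mapping)) {
      tag2gene <- setNames(mapping$gene, mapping$tag)
      g <- tag2gene[perm]
      cum_genes <- cumsum(!duplicated(g) & !is.na(g))
      out$genes_detected <- cum_genes[grid]
    }
    structure(out, class = c("saturation_curve", "data.frame"))
  })
}
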