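# Independent oracles and fixture builders shared across tests.

# random 17nt tail; tags are CATG + tail
rand_tail <- function(n) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), 17, replace = TRUE), collapse = "")
  }, character(1))
}

rand_tags <- function(n) paste0("CATG", rand_tail(n))

# mutate each tag at k random non-anchor positions (may hit the same base)
mutate_tags <- function(tags, k) {
  for (i in seq_len(k)) {
    p <- sample(5:21, length(tags), replace = TRUE)
    b <- sample(c("A", "C", "G", "T"), length(tags), replace = TRUE)
    substr(tags, p, p) <- b
  }
  tags
}

# minimal gene_expression table from a named count vector
make_expr <- function(counts, clean_total) {
  structure(
    data.frame(gene = names(counts), count = as.integer(counts),
               antisense_count = 0L, stringsAsFactors = FALSE),
    clean_total = clean_total,
    class = c("gene_expression", "data.frame"))
}

# minimal tag_count_table from a named count vector
make_tag_table <- function(counts, raw_total = sum(counts),
                           raw_distinct = length(counts)) {
  structure(list(counts = sort(counts, decreasing = TRUE), library = NULL,
                 total_clean = sum(counts), distinct_clean = length(counts),
                 raw_total = raw_total, raw_distinct = raw_distinct),
            class = "tag_count_table")
}

# Audic-Claverie two-sided p through the negative-binomial identity:
# y | x ~ NB(size = x + 1, prob = N1 / (N1 + N2)); tails via direct
# summation of dnbinom mass (independent of the package's log-gamma path)
ac_oracle <- function(x, y, N1, N2) {
  pr <- N1 / (N1 + N2)
  lower <- sum(dnbinom(0:y, size = x + 1, prob = pr))
  upper <- if (y == 0) 1 else
    1 - sum(dnbinom(0:(y - 1), size = x + 1, prob = pr))
  min(1, 2 * min(lower, upper))
}

# encode 21nt tags as a 21-row integer matrix (one column per tag)
encode_tags <- function(tags) {
  matrix(as.integer(charToRaw(paste(tags, collapse = ""))), nrow = 21)
}

# brute-force all-pairs Hamming mapper over a gene library: for every query
# tag, scan every library entry, keep distance-0 entries, else distance-1,
# and apply the sense-priority / ambiguity rules
brute_force_map <- function(qtags, gene_lib) {
  K <- encode_tags(gene_lib$tag)
  Q <- encode_tags(qtags)
  category <- character(length(qtags))
  multiplicity <- rep("n/a", length(qtags))
  gene <- rep(NA_character_, length(qtags))
  for (j in seq_along(qtags)) {
    d <- colSums(K != Q[, j])
    rows <- which(d == 0)
    level <- "PM"
    if (!length(rows)) {
      rows <- which(d == 1)
      level <- "1MM"
    }
    if (length(rows)) {
      g <- unique(gene_lib$target[rows])
      sense <- any(gene_lib$strand[rows] == "sense")
      category[j] <- paste0(level, "-gene-",
                            if (sense) "sense" else "antisense")
      if (length(g) == 1L) {
        multiplicity[j] <- "one"
        gene[j] <- g
      } else {
        multiplicity[j] <- "many"
      }
    } else {
      category[j] <- "unknown"
    }
  }
  list(category = category, multiplicity = multiplicity, gene = gene)
}

# virtual_tag_library from explicit columns (bypasses sequence scanning)
make_lib <- function(tag, target, strand = "sense", offset = 0L) {
  structure(data.frame(tag = tag, target = target, strand = strand,
                       offset = offset, stringsAsFactors = FALSE),
            targets = unique(target),
            class = c("virtual_tag_library", "data.frame"))
}

# printed two-library summary statistics of the flower-bud experiment,
# used as fixed inputs for the arithmetic identity checks
published_table1 <- function() {
  list(
    PF = list(raw_total = 3476249, raw_distinct = 274206,
              clean_total = 3331468, clean_distinct = 129933,
              gene_total = 1783091, gene_distinct = 64599,
              unambig_total = 1564689, unambig_distinct = 57871,
              genome_total = 776068, genome_distinct = 34698,
              unknown_total = 772309, unknown_distinct = 30636,
              pct = c(gene_total_pct = 53.52, gene_distinct_pct = 49.72,
                      unambig_total_pct = 46.97, unambig_distinct_pct = 44.54,
                      genome_total_pct = 23.30, genome_distinct_pct = 26.70,
                      unknown_total_pct = 23.18, unknown_distinct_pct = 23.58),
              bins = c(208111, 153194, 213051, 396739, 382603, 1977770)),
    IF = list(raw_total = 3580677, raw_distinct = 271884,
              clean_total = 3434800, clean_distinct = 126485,
              gene_total = 1703889, gene_distinct = 58309,
              unambig_total = 1496735, unambig_distinct = 52144,
              genome_total = 849241, genome_distinct = 34806,
              unknown_total = 881670, unknown_distinct = 33370,
              pct = c(gene_total_pct = 49.61, gene_distinct_pct = 46.10,
                      unambig_total_pct = 43.58, unambig_distinct_pct = 41.23,
                      genome_total_pct = 24.72, genome_distinct_pct = 27.52,
                      unknown_total_pct = 25.67, unknown_distinct_pct = 26.38),
              bins = c(199910, 147600, 205594, 395033, 392318, 2094345))
  )
}
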