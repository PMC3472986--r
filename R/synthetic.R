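# Synthetic-data generator emulating the NlaIII/MmeI tag-sequencing protocol:
# reference sequences, term/pathway annotations, two-library expression with
# known differential-expression truth, and raw 49bp tag reads.

#' Generate a synthetic reference gene set (and genome)
#'
#' Draws random transcript sequences and, optionally, a genome formed by
#' concatenating the genes with random intergenic spacers. Because every
#' downstream stage keys on the 3'-most CATG site, a minimum fraction of
#' genes is guaranteed to carry an extractable CATG+17 tag: genes lacking
#' one have a CATG planted at a position with at least 17nt downstream.
#'
#' @param n_genes Number of genes (>= 1).
#' @param length_range Integer vector of length 2: min/max gene length in nt
#'   (min >= 25 so a 21nt tag can exist with margin).
#' @param intergenic_fraction Fraction of the genome made of intergenic
#'   spacer sequence, in `[0, 1)`. `0` suppresses the genome.
#' @param seed Integer seed; output is deterministic given the seed.
#' @param min_tag_fraction Minimum fraction of genes with an extractable tag.
#' @param base_probs Sampling probabilities for A, C, G, T.
#' @return An object of class `dge_reference`: a list with `genes` (named
#'   character vector of sequences), `genome` (single string or `NULL`) and
#'   attribute `spacers` (the intergenic spacer sequences).
#' @export
generate_reference <- function(n_genes, length_range = c(200L, 2000L),
                               intergenic_fraction = 0.1, seed = 1L,
                               min_tag_fraction = 0.9,
                               base_probs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  check_scalar_count(n_genes, "n_genes", min = 1)
  if (length(length_range) != 2L || any(length_range < 25))
    stop("`length_range` must be two lengths >= 25 nt", call. = FALSE)
  if (intergenic_fraction < 0 || intergenic_fraction >= 1)
    stop("`intergenic_fraction` must be in [0, 1)", call. = FALSE)

  with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    lens <- sample(length_range[1L]:length_range[2L], n_genes, replace = TRUE)
    genes <- vapply(lens, function(L) {
      paste(sample(bases, L, replace = TRUE, prob = base_probs), collapse = "")
    }, character(1))
    names(genes) <- sprintf("gene%0*d", nchar(n_genes), seq_len(n_genes))

    # guarantee the extractable-tag fraction by planting CATG where missing
    has_tag <- vapply(genes, function(g) length(tag_sites(g)) > 0L, logical(1))
    need <- ceiling(min_tag_fraction * n_genes) - sum(has_tag)
    if (need > 0L) {
      fix <- which(!has_tag)[seq_len(need)]
      for (i in fix) {
        pos <- sample.int(nchar(genes[i]) - TAG_LENGTH + 1L, 1L)
        substr(genes[i], pos, pos + 3L) <- TAG_ANCHOR
      }
    }

    genome <- NULL
    spacers <- character(0)
    if (intergenic_fraction > 0) {
      gene_nt <- sum(nchar(genes))
      spacer_nt <- round(gene_nt * intergenic_fraction / (1 - intergenic_fraction))
      w <- runif(n_genes + 1L)
      sp_lens <- pmax(1L, round(spacer_nt * w / sum(w)))
      spacers <- vapply(sp_lens, function(L) {
        paste(sample(bases, L, replace = TRUE, prob = base_probs), collapse = "")
      }, character(1))
      pieces <- character(2L * n_genes + 1L)
      pieces[seq(1L, by = 2L, length.out = n_genes + 1L)] <- spacers
      pieces[seq(2L, by = 2L, length.out = n_genes)] <- genes
      genome <- paste(pieces, collapse = "")
    }

    structure(list(genes = genes, genome = genome),
              spacers = spacers, class = "dge_reference")
  })
}

#' @export
print.dge_reference <- function(x, ...) {
  cat(sprintf("Synthetic reference: %d genes (%d-%d nt)%s\n",
              length(x$genes), min(nchar(x$genes)), max(nchar(x$genes)),
              if (is.null(x$genome)) "" else
                sprintf(", genome %d nt", nchar(x$genome))))
  invisible(x)
}

#' Generate synthetic GO-like and pathway-like annotations
#'
#' Assigns genes to functional terms (split over the three GO ontologies)
#' and to pathways. Term sizes are drawn log-uniformly between ~3 genes and
#' ~a fifth of the gene set, mimicking the skewed size distribution of real
#' ontologies.
#'
#' @param reference A `dge_reference` (or named character vector of genes).
#' @param n_terms Number of GO-like terms (>= 1).
#' @param n_pathways Number of pathway-like terms.
#' @param seed Integer seed.
#' @return An object of class `annotation_map`: list with data frames
#'   `terms` (gene, term), `pathways` (gene, pathway) and `term_ontology`
#'   (term, ontology).
#' @export
generate_annotations <- function(reference, n_terms = 50L, n_pathways = 20L,
                                 seed = 1L) {
  check_scalar_count(n_terms, "n_terms", min = 1)
  check_scalar_count(n_pathways, "n_pathways", min = 0)
  gene_ids <- names(ref_genes(reference))

  with_seed(seed, {
    assign_sets <- function(n_sets, prefix) {
      if (n_sets == 0L) {
        return(data.frame(gene = character(0), set = character(0),
                          stringsAsFactors = FALSE))
      }
      max_size <- max(3, length(gene_ids) / 5)
      sizes <- pmin(length(gene_ids),
                    round(exp(runif(n_sets, log(3), log(max_size)))))
      ids <- sprintf("%s%0*d", prefix, nchar(n_sets), seq_len(n_sets))
      data.frame(
        gene = unlist(lapply(sizes, function(s) sample(gene_ids, s))),
        set = rep(ids, sizes),
        stringsAsFactors = FALSE
      )
    }
    terms <- assign_sets(n_terms, "term")
    names(terms)[2L] <- "term"
    pathways <- assign_sets(n_pathways, "path")
    names(pathways)[2L] <- "pathway"
    term_ids <- sprintf("term%0*d", nchar(n_terms), seq_len(n_terms))
    ontology <- data.frame(
      term = term_ids,
      ontology = sample(c("molecular function", "cellular component",
                          "biological process"), n_terms, replace = TRUE),
      stringsAsFactors = FALSE
    )
    structure(list(terms = terms, pathways = pathways,
                   term_ontology = ontology),
              class = "annotation_map")
  })
}

#' @export
print.annotation_map <- function(x, ...) {
  cat(sprintf("Annotation map: %d term assignments over %d terms; %d pathway assignments over %d pathways\n",
              nrow(x$terms), length(unique(x$terms$term)),
              nrow(x$pathways), length(unique(x$pathways$pathway))))
  invisible(x)
}

#' Simulate two-library expression with known differential-expression truth
#'
#' Baseline relative abundances are log-normal (heterogeneity plus
#' redundancy: few abundant transcripts, many rare ones). A designated
#' fraction of genes is differentially expressed with fold-change magnitudes
#' drawn log-uniformly from `fold_range` and random direction; all other
#' genes have fold change exactly 1. Per-library tag counts are multinomial
#' draws, so each library's counts sum exactly to its depth.
#'
#' @param reference A `dge_reference` (or named character vector).
#' @param de_fraction Fraction of genes truly differentially expressed.
#' @param fold_range Magnitude range (min >= 2) for DE fold changes.
#' @param depth1,depth2 Library depths (total tag counts, >= 1000).
#' @param seed Integer seed.
#' @param abundance_sdlog Log-normal sd of baseline abundances.
#' @param min_log2_fold Minimum |log2 fold| of DE genes after balancing.
#' @details Fold changes are interpreted relative to the unchanged majority
#' of the transcriptome: directions are assigned as a balanced half-up /
#' half-down split and the DE fold magnitudes are rescaled by a common
#' factor so that `sum(baseline * fold) = 1`. Unchanged genes therefore keep
#' identical sampling probabilities in both conditions — the assumption
#' under which between-library TPM comparison is meaningful.
#' @return A list with `truth` (class `expression_truth`: data frame of
#'   gene, baseline, fold, is_de, with attribute `depths`) and named integer
#'   vectors `counts1`, `counts2`.
#' @export
simulate_expression <- function(reference, de_fraction = 0.05,
                                fold_range = c(4, 16),
                                depth1 = 1e5, depth2 = 1e5, seed = 1L,
                                abundance_sdlog = 1.2, min_log2_fold = 1) {
  if (de_fraction < 0 || de_fraction > 1)
    stop("`de_fraction` must be in [0, 1]", call. = FALSE)
  if (depth1 < 1000 || depth2 < 1000)
    stop("library depths below 1000 give unstable downstream statistics",
         call. = FALSE)
  if (de_fraction > 0 && min(fold_range) < 2)
    stop("`fold_range` magnitudes must be >= 2 (|log2 fold| >= 1)",
         call. = FALSE)
  genes <- names(ref_genes(reference))
  n <- length(genes)

  with_seed(seed, {
    ab <- rlnorm(n, meanlog = 0, sdlog = abundance_sdlog)
    baseline <- ab / sum(ab)
    n_de <- round(de_fraction * n)
    is_de <- rep(FALSE, n)
    fold <- rep(1, n)
    if (n_de > 0L) {
      idx <- sample.int(n, n_de)
      is_de[idx] <- TRUE
      mag <- 2^runif(n_de, log2(fold_range[1L]), log2(fold_range[2L]))
      fold[idx] <- balance_folds(baseline[idx], mag, 2^min_log2_fold)
    }
    p2 <- baseline * fold
    p2 <- p2 / sum(p2)
    counts1 <- setNames(as.integer(rmultinom(1L, depth1, baseline)), genes)
    counts2 <- setNames(as.integer(rmultinom(1L, depth2, p2)), genes)
    truth <- structure(
      data.frame(gene = genes, baseline = baseline, fold = fold,
                 is_de = is_de, stringsAsFactors = FALSE),
      depths = c(N1 = depth1, N2 = depth2), class = c("expression_truth", "data.frame"))
    list(truth = truth, counts1 = counts1, counts2 = counts2)
  })
}

#' Simulate raw 49bp tag reads from per-gene counts
#'
#' Each count of a gene yields one 49nt read: the gene's CATG+17 tag at its
#' 3'-most CATG site followed by the 3' adaptor (recycled to fill 49nt).
#' Optional artefacts reproduce what real libraries contain: per-base
#' substitution errors, 'N' base calls, adaptor-only (empty) reads,
#' antisense reads (tags from the reverse-complement strand) and intergenic
#' reads (tags from genome spacer sequence). Genes without an extractable
#' tag contribute no reads and are reported in attribute `skipped_genes`.
#'
#' @param counts Named integer vector of per-gene tag counts.
#' @param reference A `dge_reference`.
#' @param adaptor 3' adaptor sequence (non-empty).
#' @param error_rate Per-base substitution probability in `[0, 1)`.
#' @param n_rate Per-base probability of an 'N' call in `[0, 1)`.
#' @param empty_read_rate Adaptor-only reads appended, as a fraction of
#'   gene-derived reads.
#' @param antisense_rate,intergenic_rate Fractions of extra reads drawn from
#'   reverse-complement gene tags and from intergenic genome tags.
#' @param seed Integer seed.
#' @return Object of class `raw_reads`: list with `reads` (49nt strings) and
#'   `provenance` (source gene id, `antisense:<gene>`, `intergenic`, or
#'   `empty`, retained for testing only).
#' @export
simulate_reads <- function(counts, reference, adaptor = default_adaptor(),
                           error_rate = 0, n_rate = 0, empty_read_rate = 0,
                           antisense_rate = 0, intergenic_rate = 0,
                           seed = 1L) {
  if (!nzchar(adaptor)) stop("`adaptor` must be non-empty", call. = FALSE)
  rates <- c(error_rate, n_rate, empty_read_rate, antisense_rate, intergenic_rate)
  if (any(rates < 0) || any(rates >= 1))
    stop("rates must be in [0, 1)", call. = FALSE)
  genes <- ref_genes(reference)
  if (is.null(names(counts)) || !all(names(counts) %in% names(genes)))
    stop("`counts` must be named by reference gene ids", call. = FALSE)

  with_seed(seed, {
    tags <- vapply(genes[names(counts)], gene_tag, character(1))
    usable <- !is.na(tags) & counts > 0
    skipped <- names(counts)[is.na(tags) & counts > 0]

    pad <- recycle_to(adaptor, READ_LENGTH - TAG_LENGTH)
    reads <- rep(paste0(tags[usable], pad), counts[usable])
    prov <- rep(names(counts)[usable], counts[usable])
    n_core <- length(reads)

    # antisense transcription artefacts: tag of the reverse-complement strand
    n_anti <- round(n_core * antisense_rate)
    if (n_anti > 0L) {
      anti_tags <- vapply(revcomp(genes), gene_tag, character(1))
      names(anti_tags) <- names(genes)
      anti_tags <- anti_tags[!is.na(anti_tags)]
      if (length(anti_tags)) {
        pick <- sample(names(anti_tags), n_anti, replace = TRUE)
        reads <- c(reads, paste0(anti_tags[pick], pad))
        prov <- c(prov, paste0("antisense:", pick))
      }
    }

    # intergenic transcription artefacts: tags from genome spacer sequence
    n_inter <- round(n_core * intergenic_rate)
    if (n_inter > 0L) {
      spacer_tags <- unlist(lapply(attr(reference, "spacers"), all_tags),
                            use.names = FALSE)
      if (length(spacer_tags)) {
        pick <- sample(spacer_tags, n_inter, replace = TRUE)
        reads <- c(reads, paste0(pick, pad))
        prov <- c(prov, rep("intergenic", n_inter))
      }
    }

    # substitution errors, applied per base over the whole read
    if (error_rate > 0 && length(reads)) {
      reads <- inject_substitutions(reads, error_rate)
    }
    if (n_rate > 0 && length(reads)) {
      for (j in seq_len(READ_LENGTH)) {
        hit <- which(runif(length(reads)) < n_rate)
        if (length(hit)) substr(reads[hit], j, j) <- "N"
      }
    }

    # adaptor-only (empty) reads
    n_empty <- round(n_core * empty_read_rate)
    if (n_empty > 0L) {
      reads <- c(reads, rep(recycle_to(adaptor, READ_LENGTH), n_empty))
      prov <- c(prov, rep("empty", n_empty))
    }

    structure(list(reads = reads, provenance = prov),
              skipped_genes = skipped, class = "raw_reads")
  })
}

# Balance DE fold changes so the expression mass of the DE set is conserved
# (sum(b * f) = sum(b)): unchanged genes then keep identical sampling
# probabilities in both conditions. With every fold magnitude >= min_fold,
# conservation forces the up-regulated mass to stay small, so up calls go to
# the rarest transcripts (which keep their sampled magnitudes) while
# abundant DE genes are down-regulated; the down folds absorb the up-side
# excess exactly, capped at 1/min_fold so every |log2 fold| >=
# log2(min_fold).
balance_folds <- function(b, mag, min_fold) {
  n <- length(b)
  if (n == 1L) return(mag)  # a single DE gene cannot be mass-balanced
  delta_up <- b * (mag - 1)
  up <- logical(n)
  excess <- 0
  bd <- sum(b)
  for (i in order(b)) {  # rarest first, while the down side can absorb
    if (bd - b[i] > 0 && excess + delta_up[i] <= 0.9 * (bd - b[i])) {
      up[i] <- TRUE
      excess <- excess + delta_up[i]
      bd <- bd - b[i]
    }
  }
  f <- mag
  target_d <- bd - excess
  cap <- 1 / min_fold
  if (target_d > sum(b[!up]) * cap) cap <- 0.5  # rare: widen the down band
  if (target_d >= sum(b[!up]) * cap) {
    f[!up] <- cap  # degenerate masses: accept the residual imbalance
    return(f)
  }
  d_fun <- function(k) sum(b[!up] * pmin(cap, k / mag[!up]))
  kap <- uniroot(function(k) d_fun(k) - target_d, c(0, 1e12), tol = 1e-15)$root
  f[!up] <- pmin(cap, kap / mag[!up])
  f
}

# vectorised per-position substitution: for each read position, flip a
# Bernoulli(error_rate) coin per read and replace hits by one of the 3
# alternative bases
inject_substitutions <- function(reads, error_rate) {
  bases <- c("A", "C", "G", "T")
  for (j in seq_len(READ_LENGTH)) {
    hit <- which(runif(length(reads)) < error_rate)
    if (!length(hit)) next
    old <- substr(reads[hit], j, j)
    shift <- sample.int(3L, length(hit), replace = TRUE)
    new <- bases[(match(old, bases) - 1L + shift) %% 4L + 1L]
    substr(reads[hit], j, j) <- new
  }
  reads
}

#' @export
print.raw_reads <- function(x, ...) {
  cat(sprintf("Raw read set: %d reads of %dnt\n", length(x$reads), READ_LENGTH))
  invisible(x)
}

#' Simulate a qPCR Ct table from known fold changes
#'
#' Generates target and reference-gene Ct values for two samples and a set
#' of genes whose condition-2/condition-1 expression ratios are given, with
#' Gaussian replicate noise, for exercising the 2^-ddCt workflow.
#'
#' @param folds Named numeric vector: true fold change (condition2 relative
#'   to condition1) per gene.
#' @param n_replicates Replicates per gene and sample.
#' @param ct_noise_sd Gaussian sd of Ct replicate noise (cycles).
#' @param seed Integer seed.
#' @return A data frame (gene, sample, replicate, ct_target, ct_reference)
#'   with samples labelled `condition1` and `condition2`.
#' @export
simulate_ct_table <- function(folds, n_replicates = 3L, ct_noise_sd = 0.1,
                              seed = 1L) {
  stopifnot(!is.null(names(folds)), all(folds > 0))
  with_seed(seed, {
    out <- expand.grid(gene = names(folds),
                       sample = c("condition1", "condition2"),
                       replicate = seq_len(n_replicates),
                       stringsAsFactors = FALSE)
    base_dct <- setNames(runif(length(folds), 2, 10), names(folds))
    dct <- ifelse(out$sample == "condition2",
                  base_dct[out$gene] - log2(folds[out$gene]),
                  base_dct[out$gene])
    out$ct_reference <- 18 + rnorm(nrow(out), 0, ct_noise_sd)
    out$ct_target <- out$ct_reference + dct + rnorm(nrow(out), 0, ct_noise_sd)
    out[order(out$gene, out$sample, out$replicate), ]
  })
}

#' Simulate a complete two-library DGE experiment
#'
#' Convenience generator tying the pieces together under one master seed:
#' reference and annotations, two-condition expression with known truth, and
#' raw 49bp reads for both libraries under the study's artefact rates
#' (1% substitution errors, 0.1% 'N' calls, 1% empty reads, 2% antisense and
#' 2% intergenic reads).
#'
#' @param n_genes,length_range,intergenic_fraction Passed to
#'   [generate_reference()].
#' @param n_terms,n_pathways Passed to [generate_annotations()].
#' @param de_fraction,fold_range,depth1,depth2 Passed to
#'   [simulate_expression()].
#' @param adaptor,error_rate,n_rate,empty_read_rate,antisense_rate,intergenic_rate
#'   Passed to [simulate_reads()].
#' @param seed Master seed; sub-generators receive seeds derived from it.
#' @return List with `reference`, `annotations`, `truth`, `counts1`,
#'   `counts2`, `reads1`, `reads2`, `adaptor`.
#' @export
simulate_dge_experiment <- function(n_genes = 1000L,
                                    length_range = c(200L, 2000L),
                                    intergenic_fraction = 0.1,
                                    n_terms = 50L, n_pathways = 20L,
                                    de_fraction = 0.05, fold_range = c(4, 16),
                                    depth1 = 1e5, depth2 = 1e5,
                                    adaptor = default_adaptor(),
                                    error_rate = 0.01, n_rate = 0.001,
                                    empty_read_rate = 0.01,
                                    antisense_rate = 0.02,
                                    intergenic_rate = 0.02,
                                    seed = 1L) {
  seeds <- derive_seeds(seed, 5L)
  reference <- generate_reference(n_genes, length_range, intergenic_fraction,
                                  seed = seeds[1L])
  annotations <- generate_annotations(reference, n_terms, n_pathways,
                                      seed = seeds[2L])
  expr <- simulate_expression(reference, de_fraction, fold_range,
                              depth1, depth2, seed = seeds[3L])
  reads1 <- simulate_reads(expr$counts1, reference, adaptor, error_rate,
                           n_rate, empty_read_rate, antisense_rate,
                           intergenic_rate, seed = seeds[4L])
  reads2 <- simulate_reads(expr$counts2, reference, adaptor, error_rate,
                           n_rate, empty_read_rate, antisense_rate,
                           intergenic_rate, seed = seeds[5L])
  list(reference = reference, annotations = annotations,
       truth = expr$truth, counts1 = expr$counts1, counts2 = expr$counts2,
       reads1 = reads1, reads2 = reads2, adaptor = adaptor)
}

# accept a dge_reference or a plain named character vector of sequences
ref_genes <- function(reference) {
  if (inherits(reference, "dge_reference")) return(reference$genes)
  if (is.character(reference) && !is.null(names(reference))) return(reference)
  stop("`reference` must be a dge_reference or named character vector",
       call. = FALSE)
}
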