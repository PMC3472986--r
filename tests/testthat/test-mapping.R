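# Virtual tag library construction, exact/one-mismatch mapping, gene counts,
# TPM.

test_that("virtual library enumerates CATG+17 windows on both strands", {
  # one sense site at offset 3; the reverse complement's CATG lacks 17nt
  gene <- c(gA = "AAACATGTTTTTTTTTTTTTTTTTGG")
  lib <- build_virtual_tag_library(gene)
  expect_identical(nrow(lib), 1L)
  expect_identical(lib$tag, paste0("CATG", strrep("T", 17)))
  expect_identical(lib$strand, "sense")
  expect_identical(lib$offset, 3L)

  # no CATG anywhere: no entries
  expect_identical(nrow(build_virtual_tag_library(c(g = strrep("A", 50)))), 0L)

  # the same tag in two genes keeps both loci
  tag <- paste0("CATG", strrep("A", 17))
  two <- c(g1 = paste0("GG", tag, "GG"), g2 = paste0(tag, "CCCC"))
  lib2 <- build_virtual_tag_library(two, include_antisense = FALSE)
  hits <- lib2[lib2$tag == tag, ]
  expect_identical(sort(hits$target), c("g1", "g2"))
  expect_identical(sort(hits$offset), c(0L, 2L))
})

test_that("map_tags applies category precedence and ambiguity filtering", {
  set.seed(11)
  k <- rand_tags(8)
  gene_lib <- make_lib(tag = c(k[1], k[2], k[2], k[3]),
                       target = c("g1", "g2", "g3", "g4"),
                       strand = c("sense", "sense", "sense", "antisense"))
  genome_lib <- make_lib(tag = c(k[4], k[5], k[5]),
                         target = "genome",
                         strand = c("sense", "sense", "antisense"),
                         offset = c(0L, 10L, 20L))
  q1mm <- mutate_tags(k[6], 0)       # plain copy
  substr(q1mm, 9, 9) <- if (substr(k[6], 9, 9) == "A") "C" else "A"
  gene_lib2 <- rbind(gene_lib, make_lib(k[6], "g5"))
  attr(gene_lib2, "targets") <- c(attr(gene_lib, "targets"), "g5")
  class(gene_lib2) <- class(gene_lib)

  counts <- setNames(c(10L, 4L, 3L, 6L, 2L, 5L, 7L),
                     c(k[1], k[2], k[3], q1mm, k[4], k[5], k[7]))
  mp <- map_tags(counts, gene_lib2, genome_lib)
  got <- setNames(as.character(mp$category), mp$tag)

  expect_identical(got[[k[1]]], "PM-gene-sense")       # one gene, sense
  expect_identical(mp$multiplicity[mp$tag == k[1]], "one")
  expect_identical(mp$gene[mp$tag == k[1]], "g1")

  expect_identical(got[[k[2]]], "PM-gene-sense")       # two genes
  expect_identical(mp$multiplicity[mp$tag == k[2]], "many")
  expect_true(is.na(mp$gene[mp$tag == k[2]]))

  expect_identical(got[[k[3]]], "PM-gene-antisense")
  expect_identical(got[[q1mm]], "1MM-gene-sense")      # distance-1 from k[6]
  expect_identical(mp$gene[mp$tag == q1mm], "g5")
  expect_identical(got[[k[4]]], "PM-genome-1pos")
  expect_identical(got[[k[5]]], "PM-genome-npos")
  expect_identical(got[[k[7]]], "unknown")

  expect_error(map_tags(setNames(3L, "CATGAA"), gene_lib), "21nt")
})

test_that("every clean tag gets exactly one category and tallies conserve", {
  set.seed(12)
  keys <- rand_tags(400)
  gene_lib <- make_lib(sample(keys[1:200], 300, replace = TRUE),
                       target = sample(sprintf("g%02d", 1:40), 300, TRUE),
                       strand = sample(c("sense", "antisense"), 300, TRUE))
  genome_lib <- make_lib(keys[201:260], "genome")
  q <- unique(c(sample(keys[1:200], 100), mutate_tags(sample(keys, 150, TRUE), 1),
                rand_tags(80)))
  counts <- setNames(sample(2:50, length(q), replace = TRUE), q)
  mp <- map_tags(counts, gene_lib, genome_lib)

  expect_false(any(is.na(mp$category)))
  tal <- mapping_tallies(mp)
  expect_identical(tal$gene_distinct + tal$genome_distinct + tal$unknown_distinct,
                   length(q))
  expect_identical(tal$gene_total + tal$genome_total + tal$unknown_total,
                   sum(counts))
  expect_true(all(is.na(mp$gene[mp$multiplicity == "many"])))
})

test_that("map_tags equals the brute-force Hamming scan", {
  set.seed(13)
  keys <- rand_tags(600)
  gene_lib <- make_lib(sample(keys, 800, replace = TRUE),
                       target = sample(sprintf("g%03d", 1:150), 800, TRUE),
                       strand = sample(c("sense", "antisense"), 800, TRUE,
                                       prob = c(0.7, 0.3)))
  q <- unique(c(sample(keys, 250, TRUE),
                mutate_tags(sample(keys, 250, TRUE), 1),
                mutate_tags(sample(keys, 150, TRUE), 2),
                rand_tags(150)))
  mp <- map_tags(setNames(rep(2L, length(q)), q), gene_lib)
  oracle <- brute_force_map(q, gene_lib)
  expect_identical(as.character(mp$category), oracle$category)
  expect_identical(mp$multiplicity, oracle$multiplicity)
  expect_identical(mp$gene, oracle$gene)
})

test_that("gene counts sum unambiguous sense tags; antisense kept apart", {
  k <- rand_tags(4)
  gene_lib <- make_lib(tag = c(k[1], k[2], k[3], k[4], k[4]),
                       target = c("g1", "g1", "g2", "g3", "g4"),
                       strand = c("sense", "sense", "antisense", "sense", "sense"))
  counts <- setNames(c(10L, 5L, 8L, 4L), k)
  mp <- map_tags(counts, gene_lib)
  expr <- gene_counts(mp)
  expect_identical(expr$count[expr$gene == "g1"], 15L)           # t1 + t2
  expect_identical(expr$count[expr$gene == "g2"], 0L)            # antisense only
  expect_identical(expr$antisense_count[expr$gene == "g2"], 8L)
  expect_identical(expr$count[expr$gene == "g3"], 0L)            # ambiguous
  expect_identical(sort(expr$gene), sort(c("g1", "g2", "g3", "g4")))
})

test_that("TPM is count per million clean tags", {
  expr <- make_expr(c(gA = 10, gB = 0, gC = 465), clean_total = NA)
  expect_error(tpm_normalize(expr, 0), "positive")
  out <- tpm_normalize(expr, 1e6)
  expect_identical(out$tpm, c(10, 0, 465))
  out2 <- tpm_normalize(expr, 3434800)
  expect_equal(out2$tpm[3], 465 / 3434800 * 1e6, tolerance = 1e-12)
  expect_equal(out2$tpm[3], 135.3777, tolerance = 1e-4)
})

test_that("noiseless simulated counts round-trip through the pipeline", {
  ref <- generate_reference(120, c(150, 600), 0.1, seed = 17)
  sim <- simulate_expression(ref, de_fraction = 0, depth1 = 20000,
                             depth2 = 20000, seed = 18)
  rd <- simulate_reads(sim$counts1, ref, seed = 19)
  tab <- extract_clean_tags(rd)
  gene_lib <- build_virtual_tag_library(ref)
  mp <- map_tags(tab, gene_lib, build_virtual_tag_library(ref$genome))
  expr <- gene_counts(mp)

  # genes whose protocol tag occurs exactly once in the whole gene library
  tags <- vapply(ref$genes, tagdge:::gene_tag, character(1))
  key_count <- table(gene_lib$tag)
  uniq <- !is.na(tags) & as.integer(key_count[tags]) == 1L
  got <- setNames(expr$count, expr$gene)
  for (g in names(ref$genes)[which(uniq)]) {
    truth <- sim$counts1[[g]]
    if (truth >= 2) expect_identical(got[[g]], as.integer(truth))
    if (truth == 0) expect_identical(got[[g]], 0L)
  }
})
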