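# Synthetic-data generator: determinism, invariants, noise calibration.

test_that("generate_reference validates input and is deterministic", {
  expect_error(generate_reference(0), "n_genes")
  expect_error(generate_reference(10, length_range = c(10, 50)), ">= 25")
  expect_error(generate_reference(10, intergenic_fraction = 1), "intergenic")

  a <- generate_reference(100, c(100, 400), 0.1, seed = 1)
  b <- generate_reference(100, c(100, 400), 0.1, seed = 1)
  expect_identical(a, b)
  expect_false(identical(a$genes,
                         generate_reference(100, c(100, 400), 0.1, seed = 2)$genes))
  expect_identical(anyDuplicated(names(a$genes)), 0L)
  expect_true(all(nchar(a$genes) >= 100))
})

test_that("most generated genes carry an extractable CATG+17 tag", {
  ref <- generate_reference(500, c(200, 2000), 0, seed = 7)
  # direct scan: a tag exists iff some CATG starts >= 17nt before the end
  has_tag <- vapply(ref$genes, function(g) {
    hits <- gregexpr("CATG", g, fixed = TRUE)[[1]]
    any(hits > 0 & hits + 20 <= nchar(g))
  }, logical(1))
  expect_gte(sum(has_tag), 450)
})

test_that("genome contains every gene plus intergenic spacers", {
  ref <- generate_reference(30, c(100, 300), 0.2, seed = 3)
  expect_true(all(vapply(ref$genes, grepl, logical(1), x = ref$genome,
                         fixed = TRUE)))
  expect_gt(nchar(ref$genome), sum(nchar(ref$genes)))
  expect_null(generate_reference(5, c(100, 200), 0, seed = 1)$genome)
})

test_that("generate_annotations is reproducible and covers the gene set", {
  ref <- generate_reference(100, c(100, 300), 0, seed = 5)
  a <- generate_annotations(ref, 20, 8, seed = 3)
  expect_identical(a, generate_annotations(ref, 20, 8, seed = 3))
  expect_true(all(a$terms$gene %in% names(ref$genes)))
  # with >= 1 mean assignment per gene, total term membership exceeds n_genes
  M <- tapply(a$terms$gene, a$terms$term, function(g) length(unique(g)))
  expect_gte(sum(M), 100)
  expect_true(all(a$term_ontology$ontology %in%
                    c("molecular function", "cellular component",
                      "biological process")))
})

test_that("simulate_expression conserves depth and honours the truth table", {
  ref <- generate_reference(300, c(100, 500), 0, seed = 2)
  expect_error(simulate_expression(ref, de_fraction = 0.05, depth1 = 500),
               "depths")
  expect_error(simulate_expression(ref, de_fraction = 0.05,
                                   fold_range = c(1.5, 3)), "fold_range")

  s0 <- simulate_expression(ref, de_fraction = 0, depth1 = 1e4, depth2 = 1e4,
                            seed = 9)
  expect_true(all(s0$truth$fold == 1))
  expect_false(any(s0$truth$is_de))

  s <- simulate_expression(ref, de_fraction = 0.05, fold_range = c(4, 16),
                           depth1 = 1e5, depth2 = 1e5, seed = 11)
  expect_identical(sum(s$counts1), 100000L)
  expect_identical(sum(s$counts2), 100000L)
  expect_equal(sum(s$truth$baseline), 1, tolerance = 1e-9)
  expect_true(all(abs(log2(s$truth$fold[s$truth$is_de])) >= 1))

  # the fold-mass balance keeps unchanged genes' probabilities identical
  expect_equal(sum(s$truth$baseline * s$truth$fold), 1, tolerance = 1e-6)
  # observed log2 count ratios of DE genes track the planted folds
  de <- s$truth$is_de & s$counts1 > 20
  obs <- log2((s$counts2[de] + 0.5) / (s$counts1[de] + 0.5))
  expect_lt(abs(mean(obs - log2(s$truth$fold[de]))), 0.5)
})

test_that("simulate_reads is exact in the noiseless case", {
  ref <- generate_reference(50, c(100, 300), 0, seed = 4)
  sim <- simulate_expression(ref, de_fraction = 0, depth1 = 2000,
                             depth2 = 2000, seed = 1)
  rd <- simulate_reads(sim$counts1, ref, seed = 6)
  expect_true(all(nchar(rd$reads) == 49))

  tags <- vapply(ref$genes, tagdge:::gene_tag, character(1))
  expressed <- names(sim$counts1)[sim$counts1 > 0 & !is.na(tags)]
  # noiseless identity: distinct read sequences = distinct expressed tags
  expect_identical(length(unique(rd$reads)),
                   length(unique(tags[expressed])))
  # conservation: one read per count of every tag-bearing gene
  expect_identical(length(rd$reads),
                   sum(sim$counts1[!is.na(tags[names(sim$counts1)])]))
  # per-gene provenance equals the simulated counts
  prov <- table(rd$provenance)
  expect_identical(as.integer(prov[expressed]),
                   as.integer(sim$counts1[expressed]))
  # determinism
  expect_identical(rd, simulate_reads(sim$counts1, ref, seed = 6))
})

test_that("substitution errors hit the expected fraction of tags", {
  ref <- generate_reference(40, c(150, 400), 0, seed = 8)
  counts <- setNames(rep(2500L, 40), names(ref$genes))
  rd <- simulate_reads(counts, ref, error_rate = 0.01, seed = 5)
  tags <- vapply(ref$genes, tagdge:::gene_tag, character(1))
  src <- tags[rd$provenance]
  changed <- substr(rd$reads, 1, 21) != src
  expect_equal(mean(changed), 1 - 0.99^21, tolerance = 0.01)
})

test_that("artefact reads carry their provenance classes", {
  ref <- generate_reference(100, c(200, 600), 0.15, seed = 10)
  counts <- setNames(rep(50L, 100), names(ref$genes))
  rd <- simulate_reads(counts, ref, empty_read_rate = 0.01,
                       antisense_rate = 0.02, intergenic_rate = 0.02,
                       seed = 3)
  n_core <- sum(rd$provenance %in% names(ref$genes))
  expect_identical(sum(rd$provenance == "empty"),
                   as.integer(round(0.01 * n_core)))
  expect_identical(sum(startsWith(rd$provenance, "antisense:")),
                   as.integer(round(0.02 * n_core)))
  expect_identical(sum(rd$provenance == "intergenic"),
                   as.integer(round(0.02 * n_core)))
})

test_that("fastq and fasta round-trips preserve sequences", {
  ref <- generate_reference(10, c(100, 200), 0.1, seed = 12)
  fa <- tempfile(fileext = ".fa"); ga <- tempfile(fileext = ".fa")
  write_reference_fasta(ref, fa, ga)
  back <- read_reference_fasta(fa, ga)
  expect_identical(back$genes, ref$genes)
  expect_identical(back$genome, ref$genome)

  counts <- setNames(rep(3L, 10), names(ref$genes))
  rd <- simulate_reads(counts, ref, seed = 2)
  fq <- tempfile(fileext = ".fastq")
  write_reads_fastq(rd, fq)
  expect_identical(read_reads_fastq(fq), rd$reads)

  ann <- generate_annotations(ref, 5, 3, seed = 1)
  tsv <- tempfile(fileext = ".tsv")
  write_annotation_tsv(ann, tsv)
  back <- read_annotation_tsv(tsv)
  expect_identical(back$terms, ann$terms)
  expect_identical(back$pathways, ann$pathways)
})
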