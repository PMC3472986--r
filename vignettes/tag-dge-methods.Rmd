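---
title: "Tag-based digital gene expression profiling with tagdge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tag-based digital gene expression profiling with tagdge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tagdge)
```

## The measurement model

Restriction-tag digital gene expression (DGE, the sequencing-era successor
of SAGE) quantifies a transcriptome by counting short cDNA tags rather than
whole reads. NlaIII cuts bead-bound cDNA at its CATG sites, leaving the
3'-most fragment attached; MmeI then cuts 17 bp downstream of that CATG, so
each transcript is represented by a single 21 nt tag (the 4 nt CATG anchor
plus 17 nt). Sequencing yields 49 bp raw reads — the tag followed by the 3'
adaptor — and a transcript's expression is the copy number of its tag.

`tagdge` implements the complete downstream analysis for a two-condition,
one-library-per-condition design, plus a synthetic-data generator that
emulates the protocol so every stage can be tested end to end without any
sequencing data.

## Read cleaning

`extract_clean_tags()` applies five rules, in order:

1. trim each 49 nt read at the first occurrence of the 3' adaptor prefix;
2. drop empty reads (adaptor at position 1, i.e. no tag);
3. drop tags containing an unknown base `N`;
4. keep only tags of exactly 21 nt that begin with the CATG anchor;
5. drop tags with a library-wide copy number of 1 (likely sequencing
   errors).

Trimming searches for the first `min_overlap` (default 8) nt of the adaptor
rather than the full adaptor, so a substitution error late in the adaptor
region does not destroy the read; an error inside the first 8 adaptor bases
does, and such reads are lost at rule 4. With a 1% per-base error rate this
costs roughly 8% of reads — a known, uniform loss that cancels between
libraries. An 8-mer has a ~`r signif(14 * 4^-8 * 100, 2)`% chance of
occurring by chance inside a random tag region, in which case the read is
trimmed early and likewise discarded at rule 4.

The surviving *clean tags* are summarised by `library_summary()` (totals,
distinct counts, and the per-category percentages of the clean totals,
rounded half-up to two decimals as in the field's summary tables),
`copy_number_distribution()` (bins 2–5, 6–10, 11–20, 21–50, 51–100, >100,
which partition the clean library exactly) and `saturation_curve()` (a
single seeded shuffle of the tag occurrence stream; distinct tags and genes
detected among the first *k* occurrences, for a 20-point grid by default).

## Virtual tag library and mapping

`build_virtual_tag_library()` enumerates **all** CATG+17 windows of every
reference gene, on both strands (and of the genome, as a separate library).
The asymmetry with the generator — reads originate only from the 3'-most
CATG, while the library indexes every site — mirrors the protocol: bead
capture selects the 3' fragment, but a mapper cannot know which site a tag
came from.

`map_tags()` classifies each clean tag with the precedence

perfect gene match → 1-mismatch gene match → perfect genome match (one or
multiple positions) → 1-mismatch genome match → unknown,

recording sense/antisense hits within gene matches (a tag hitting both
strands of one gene is counted sense). Tags whose gene set holds more than
one gene are ambiguous and excluded from gene counts. The one-mismatch
search enumerates single-base substitutions against a hash of library keys;
the CATG anchor positions are excluded from enumeration because every clean
tag and every key begins with CATG (set `mismatch_in_anchor = TRUE` to
include them). Genome mapping is a residual category after gene mapping,
matching how the summary tables report it.

`gene_counts()` sums copy numbers of unambiguous *sense* tags per gene;
unambiguous antisense assignments are reported separately and never enter
the expression values (whether the original pipeline added them is
unknowable; excluding them is the conservative reading). `tpm_normalize()`
scales by the library's clean-tag total: TPM = count / clean_total × 10^6.

## Differential expression

For a gene with `x` tags among `N1` clean tags in library 1 and `y` among
`N2` in library 2, the Audic–Claverie conditional under equal expression is

$$p(y \mid x) = \left(\frac{N_2}{N_1}\right)^{y}
  \frac{(x+y)!}{x!\,y!\,(1+N_2/N_1)^{x+y+1}},$$

which is the negative binomial with size $x+1$ and success probability
$N_1/(N_1+N_2)$. `ac_pvalue()` accumulates the tails of this distribution
in log space (log-gamma terms), stable for counts into the millions, and
reports the two-sided p-value $\min(1,\, 2\min(P(Y\le y), P(Y\ge y)))$. The
reference leaves sidedness implicit; the doubled min-tail is the standard
choice. Note that this statistic conditions on the first library's count,
so swapping the libraries changes the p-value by at most one point mass of
the conditional — an exact identity the test suite asserts — but not
bit-for-bit.

Multiplicity is controlled with the Benjamini–Hochberg step-up
(`bh_fdr()`), and `screen_degs()` calls a gene up or down when FDR ≤ 0.001
and |log2 ratio| ≥ 1 (both thresholds adjustable). Log ratios use a TPM
floor (default 0.001 TPM) so genes absent from one library keep finite
ratios. The test uses raw unambiguous counts with the clean totals, never
TPMs.

## Functional enrichment

`hypergeom_enrich_p()` is the upper tail
$P = 1 - \sum_{i=0}^{m-1} \binom{M}{i}\binom{N-M}{n-i}\big/\binom{N}{n}$
over a universe of $N$ annotated genes, $n$ of them differentially
expressed, with $M$ genes in the term and $m$ DE genes among those.
The universe is restricted to genes carrying at least one annotation of the
relevant kind (DEGs without annotation are dropped from $n$ and recorded).
GO-like terms are Bonferroni-corrected by the number of terms actually
tested (enriched when corrected P ≤ 0.05); pathway-like sets use BH
Q-values (Q ≤ 0.05). Term sets are flat: no ontology-graph propagation, as
the formula operates on direct annotations.

## qPCR validation

`ddct_fold_change()` implements 2^-ddCt with an assumed amplification
efficiency of exactly 2: per gene and sample, dCt = Ct(target) −
Ct(reference) is averaged over replicates before taking ddCt against the
calibrator sample; the replicate SD is propagated as the SD of
replicate-wise folds. `concordance()` summarises agreement between DGE and
qPCR log2 fold changes as the sign-agreement fraction (exact zeros agree
with anything) and the Spearman rank correlation over shared genes.

## The synthetic-data generator

`simulate_dge_experiment()` emulates the study conditions end to end:

* **Reference** — `generate_reference()`: uniform-composition random genes
  (default 1,000 genes of 200–2,000 nt; the published experiment used a
  ~29k-gene reference at 3.4M tags per library, which the desk scale of
  10^5 represents at ~1/30 of the depth with proportionally fewer genes);
  at least 90% of genes are guaranteed an extractable tag (a CATG is
  planted where missing). A genome is built by concatenating the genes with
  random intergenic spacers (default 10% of the genome).
* **Annotations** — `generate_annotations()`: term sizes log-uniform from
  ~3 genes to a fifth of the gene set, split over the three GO ontologies,
  plus pathway-like sets. Annotations are independent of the DE truth, so
  enrichment on simulated DEG sets behaves as a null — planted-signal tests
  construct their term memberships explicitly.
* **Expression** — `simulate_expression()`: log-normal baseline abundances
  (sdlog 1.2: few abundant transcripts, many rare ones), multinomial
  sampling so each library sums exactly to its depth, 5% DE genes with fold
  magnitudes log-uniform in [4, 16] by default. Fold changes are defined
  relative to the unchanged majority of the transcriptome: the generator
  conserves the DE set's expression mass (`sum(baseline × fold)` = baseline
  mass), so unchanged genes keep identical sampling probabilities in both
  conditions — the assumption under which between-library TPM comparison is
  meaningful at all. With every fold magnitude ≥ 4, mass conservation
  forces the up-regulated mass to be small, so up-regulation is assigned to
  the rarest DE transcripts (which keep their sampled magnitudes) while
  abundant DE genes are down-regulated, their folds solving the mass
  balance exactly (capped at 1/4, so |log2 fold| ≥ 2 always holds). A
  single DE gene cannot be balanced and keeps its sampled fold.
* **Reads** — `simulate_reads()`: one 49 nt read per tag count (tag at the
  3'-most CATG + adaptor), 1% per-base substitution errors, 0.1% `N`
  calls, 1% adaptor-only reads, and 2% antisense plus 2% intergenic reads
  to populate every mapping category. The adaptor sequence is a fixed 28 nt
  placeholder (`default_adaptor()`); the real one is platform-specific and
  unpublished. The error model is substitution-only — tags are fixed-length,
  so indels would only manifest as substitutions downstream anyway.

One master seed is split deterministically across the sub-generators; all
outputs are bit-identical for a fixed seed.

What the generator does **not** emulate: PCR duplication, per-base quality
(FASTQ qualities are constant), transcript isoforms sharing 3' ends,
sequence-composition bias, or annotation structure correlated with
expression. Passing tests therefore demonstrate the correctness of the
computational pipeline under the protocol's generative model, not
robustness to every artefact of real libraries.

## Numerical choices

* Tail sums (exact test, hypergeometric) accumulate log-space terms with a
  log-sum-exp reduction; agreement with direct summation is asserted to
  1e-10 (counts to 500, libraries to 10^6) and 1e-12 (all hypergeometric
  configurations with N ≤ 60).
* Percentages round half-up to two decimals, matching the printed style of
  DGE summary tables (R's `round()` is banker's rounding).
* The extreme upper tail of the exact test is computed as 1 minus the lower
  tail; below ~1e-16 it underflows to 0, which is irrelevant at any usable
  significance threshold.
* Ties in BH are handled by `stats::p.adjust`; the saturation curve uses a
  single seeded shuffle (matching how such curves are reported — one curve
  per library, not an average).

## Worked example

```{r example, eval = FALSE}
exp <- simulate_dge_experiment(n_genes = 1000, depth1 = 1e5, depth2 = 1e5,
                               de_fraction = 0.05, seed = 1)
out <- run_dge_pipeline(exp$reads1, exp$reads2, exp$reference,
                        adaptor = exp$adaptor)
out$tags1            # clean-tag table, library 1
attr(out$de, "summary")  # up/down/ns counts
head(out$de[out$de$call != "ns", ])
go <- go_enrichment(out$de$gene[out$de$call != "ns"], exp$annotations)
```

Problem sizes in the test suite (1,000 genes at 10^5 tags per library for
pipeline round trips; 10,000 genes at 10^6 for the count-level screening
properties; 200 replicates for null calibrations) were chosen so the whole
suite exercises every stage at depths where the statistics are stable.

## Known limitations

* One library per condition: no biological replication, hence no dispersion
  modelling — the exact test treats all variation as sampling noise, as the
  design dictates.
* Genes whose 3'-most tag is not unique in the virtual library are
  unquantifiable (ambiguous tags are filtered); the round-trip guarantees
  apply only to unique-tag genes.
* The copy-number ≥ 2 rule makes single-copy expression invisible by
  design.
* Enrichment treats annotations as flat sets; results for hierarchical
  ontologies will differ from propagation-aware tools.
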