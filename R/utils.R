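# Shared internal helpers.

TAG_LENGTH <- 21L
TAG_ANCHOR <- "CATG"
READ_LENGTH <- 49L

#' Default 3' adaptor sequence
#'
#' The sequencing protocol ligates a 3' adaptor after the 21nt tag so that
#' every 49bp raw read is tag + adaptor. The true adaptor sequence is
#' platform-specific; this 28nt placeholder (Illumina small-RNA adaptor
#' prefix padded to the 28nt that exactly fill a 49bp read) is used
#' throughout the package wherever no adaptor is supplied.
#'
#' @return A 28-character string over \{A,C,G,T\}.
#' @export
default_adaptor <- function() "TCGTATGCCGTCTTCTGCTTGAAACAAA"

# round-half-up (printed tables round 0.005 up, unlike banker's rounding)
round_half_up <- function(x, digits = 0L) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

# percentage of `num` in `den`, rounded half-up to 2 decimals
pct_of <- function(num, den) round_half_up(100 * num / den, 2L)

logsumexp <- function(lx) {
  lx <- lx[!is.nan(lx)]
  if (!length(lx)) return(-Inf)
  m <- max(lx)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(lx - m)))
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# deterministic sub-seeds from one master seed (kept < 2^31)
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old), add = TRUE)
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# run `expr` under `seed` without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# 1-based start positions of every CATG whose 21nt window fits in `seq`
tag_sites <- function(seq) {
  hits <- gregexpr(TAG_ANCHOR, seq, fixed = TRUE)[[1L]]
  if (hits[1L] == -1L) return(integer(0))
  hits <- as.integer(hits)
  hits[hits + TAG_LENGTH - 1L <= nchar(seq)]
}

# all CATG+17 tags of a sequence, with their 1-based start positions
all_tags <- function(seq) {
  s <- tag_sites(seq)
  if (!length(s)) return(character(0))
  setNames(substring(seq, s, s + TAG_LENGTH - 1L), s)
}

# the tag produced by the protocol: at the 3'-most CATG site (NA if none)
gene_tag <- function(seq) {
  s <- tag_sites(seq)
  if (!length(s)) return(NA_character_)
  substr(seq, max(s), max(s) + TAG_LENGTH - 1L)
}

# recycle `x` to exactly `width` characters
recycle_to <- function(x, width) {
  substr(strrep(x, ceiling(width / nchar(x))), 1L, width)
}

check_scalar_count <- function(x, name, min = 0) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    stop(sprintf("`%s` must be a single integer >= %s", name, format(min)),
         call. = FALSE)
  }
  invisible(as.numeric(x))
}

write_tsv_file <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_file <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
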