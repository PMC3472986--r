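# Two-library differential expression: Audic-Claverie exact test on
# unambiguous tag counts, Benjamini-Hochberg FDR, fold-change thresholds.

#' Audic-Claverie exact test p-value
#'
#' For a gene observed `x` times in a library of `N1` clean tags and `y`
#' times in a library of `N2`, the conditional probability of `y` given `x`
#' under equal expression is
#' \deqn{p(y|x) = (N2/N1)^y \frac{(x+y)!}{x!\,y!\,(1+N2/N1)^{x+y+1}}.}
#' The two-sided p-value is `min(1, 2 * min(P(Y <= y | x), P(Y >= y | x)))`.
#' Tails are accumulated in log space (log-gamma terms), numerically stable
#' for counts up to millions.
#'
#' @param x,y Non-negative observed counts (vectorised).
#' @param N1,N2 Library clean-tag totals (>= 1).
#' @return Two-sided p-values in `[0, 1]`.
#' @export
ac_pvalue <- function(x, y, N1, N2) {
  if (any(x < 0) || any(y < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(N1 < 1) || any(N2 < 1)) stop("library sizes must be >= 1", call. = FALSE)
  n <- max(length(x), length(y), length(N1), length(N2))
  x <- rep_len(x, n); y <- rep_len(y, n)
  N1 <- rep_len(N1, n); N2 <- rep_len(N2, n)
  vapply(seq_len(n), function(i) ac_pvalue_one(x[i], y[i], N1[i], N2[i]),
         numeric(1))
}

ac_pvalue_one <- function(x, y, N1, N2) {
  t <- ac_tails(x, y, N1, N2)
  min(1, 2 * min(t[["lower"]], t[["upper"]]))
}

# inclusive tails P(Y <= y | x) and P(Y >= y | x) plus the point mass p(y|x)
ac_tails <- function(x, y, N1, N2) {
  lr <- log(N2) - log(N1)
  yy <- 0:y
  # log p(y'|x) for y' = 0..y
  lp <- yy * lr + lgamma(x + yy + 1) - lgamma(x + 1) - lgamma(yy + 1) -
    (x + yy + 1) * log1p(exp(lr))
  lower <- min(1, exp(logsumexp(lp)))
  upper <- if (y == 0L) 1 else min(1, max(0, 1 - exp(logsumexp(lp[-(y + 1L)]))))
  c(lower = lower, upper = upper, point = exp(lp[y + 1L]))
}

#' Benjamini-Hochberg false discovery rate
#'
#' Standard step-up adjustment (`fdr_(i) = min_{j >= i} p_(j) * n / j`,
#' capped at 1), returned in input order.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return FDR-adjusted p-values.
#' @export
bh_fdr <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop("p-values must be in [0, 1]", call. = FALSE)
  p.adjust(p_values, method = "BH")
}

#' Floored log2 expression ratio
#'
#' `log2(max(tpm2, floor) / max(tpm1, floor))`; the floor keeps ratios
#' finite for genes absent from one library.
#'
#' @param tpm1,tpm2 TPM values (vectorised).
#' @param floor Positive TPM floor (default 0.001).
#' @return log2 ratios.
#' @export
log2_ratio <- function(tpm1, tpm2, floor = 0.001) {
  if (floor <= 0) stop("`floor` must be positive", call. = FALSE)
  log2(pmax(tpm2, floor) / pmax(tpm1, floor))
}

#' Differential-expression table for two libraries
#'
#' Joins two gene-expression tables over the gene union, computes TPMs (if
#' absent), log2 ratios, Audic-Claverie p-values on the raw unambiguous
#' counts with the libraries' clean-tag totals, BH FDR, and up/down/ns calls
#' at the given thresholds.
#'
#' @param expr1,expr2 `gene_expression` tables (conditions 1 and 2).
#' @param N1,N2 Clean-tag totals (defaulted from the tables' attributes).
#' @param fdr_threshold,lfc_threshold Significance thresholds (defaults:
#'   FDR <= 0.001 and |log2 ratio| >= 1).
#' @param tpm_floor Floor for [log2_ratio()].
#' @return Data frame of class `dge_de` with columns `gene`, `x`, `y`,
#'   `tpm1`, `tpm2`, `log2_ratio`, `p_value`, `fdr`, `call`.
#' @export
diff_expression <- function(expr1, expr2, N1 = NULL, N2 = NULL,
                            fdr_threshold = 0.001, lfc_threshold = 1,
                            tpm_floor = 0.001) {
  if (is.null(N1)) N1 <- attr(expr1, "clean_total")
  if (is.null(N2)) N2 <- attr(expr2, "clean_total")
  if (is.null(N1) || is.null(N2))
    stop("clean-tag totals N1 and N2 are required", call. = FALSE)
  genes <- union(expr1$gene, expr2$gene)
  x <- setNames(numeric(length(genes)), genes)
  y <- x
  x[expr1$gene] <- expr1$count
  y[expr2$gene] <- expr2$count
  tab <- data.frame(gene = genes, x = as.integer(x), y = as.integer(y),
                    tpm1 = x / N1 * 1e6, tpm2 = y / N2 * 1e6,
                    stringsAsFactors = FALSE)
  tab$log2_ratio <- log2_ratio(tab$tpm1, tab$tpm2, tpm_floor)
  tab$p_value <- ac_pvalue(tab$x, tab$y, N1, N2)
  tab$fdr <- bh_fdr(tab$p_value)
  tab <- structure(tab, N1 = N1, N2 = N2, class = c("dge_de", "data.frame"))
  screen_degs(tab, fdr_threshold, lfc_threshold)
}

#' Screen differentially expressed genes
#'
#' Calls each gene `up` (FDR <= threshold and log2 ratio >= threshold),
#' `down` (FDR <= threshold and log2 ratio <= -threshold) or `ns`.
#'
#' @param table A `dge_de` data frame with `fdr` and `log2_ratio` columns.
#' @param fdr_threshold,lfc_threshold Thresholds (defaults 0.001 and 1).
#' @return The table with a `call` column; attribute `summary` holds
#'   `n_up`, `n_down`, `n_ns`.
#' @export
screen_degs <- function(table, fdr_threshold = 0.001, lfc_threshold = 1) {
  stopifnot(all(c("fdr", "log2_ratio") %in% names(table)))
  call <- rep("ns", nrow(table))
  sig <- table$fdr <= fdr_threshold
  call[sig & table$log2_ratio >= lfc_threshold] <- "up"
  call[sig & table$log2_ratio <= -lfc_threshold] <- "down"
  table$call <- call
  attr(table, "summary") <- c(n_up = sum(call == "up"),
                              n_down = sum(call == "down"),
                              n_ns = sum(call == "ns"))
  if (!inherits(table, "dge_de")) class(table) <- c("dge_de", class(table))
  table
}

#' @export
print.dge_de <- function(x, n = 6L, ...) {
  if ("call" %in% names(x)) {
    s <- c(n_up = sum(x$call == "up"), n_down = sum(x$call == "down"),
           n_ns = sum(x$call == "ns"))
  } else {
    s <- attr(x, "summary")
  }
  cat(sprintf("Differential expression over %d genes: %d up, %d down, %d ns\n",
              nrow(x), s[["n_up"]], s[["n_down"]], s[["n_ns"]]))
  if (nrow(x) > 0L) {
    print(head(as.data.frame(x), n), digits = 4)
    if (nrow(x) > n) cat("... and", nrow(x) - n, "more genes\n")
  }
  invisible(x)
}
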