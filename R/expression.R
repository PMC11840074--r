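# TPM normalisation, two-group differential expression, and the shared
# Benjamini-Hochberg FDR utility.

#' TPM normalisation
#'
#' Transcripts per million: per sample, each gene's count is divided by its
#' length in kilobases to give a rate, and rates are rescaled to sum to 1e6.
#'
#' @param counts genes x samples matrix of non-negative counts (rownames =
#'   gene ids).
#' @param lengths_nt per-gene lengths in nucleotides (> 0), recycled by
#'   position against the rows of `counts`.
#' @return Object of class `expression_matrix`: list with `counts`, `tpm`,
#'   `lengths_nt`. TPM columns sum to 1e6.
#' @export
tpm_normalize <- function(counts, lengths_nt) {
  counts <- as.matrix(counts)
  if (any(lengths_nt <= 0)) stop("gene lengths must be positive")
  if (any(counts < 0)) stop("counts must be non-negative")
  rate <- counts / (lengths_nt / 1000)
  totals <- colSums(rate)
  if (any(totals == 0)) {
    stop(sprintf("sample %s has all-zero counts; TPM undefined",
                 colnames(counts)[which(totals == 0)[1]]))
  }
  tpm <- sweep(rate, 2, totals, "/") * 1e6
  structure(list(counts = counts, tpm = tpm, lengths_nt = lengths_nt),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples\n",
              nrow(x$tpm), ncol(x$tpm)))
  invisible(x)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up procedure with monotonicity enforcement (via
#' \code{stats::p.adjust}); input order is preserved in the output.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Differential expression between two groups
#'
#' Welch two-sided t-test per gene on log2(TPM + 1), BH adjustment, and the
#' compound call rule: adjusted p below `fdr` AND linear fold change above
#' `fc` in either direction. The fold change is computed on group mean TPM
#' with a pseudo-count of 1: `log2_fc = log2((mean1 + 1) / (mean2 + 1))`
#' (group 1 = first label in sorted order).
#'
#' @param expr an [tpm_normalize()] `expression_matrix` (or a bare TPM
#'   matrix).
#' @param groups named vector mapping sample -> group label (two labels).
#' @param fdr adjusted-p cutoff (default 0.05).
#' @param fc linear fold-change cutoff (default 1.5).
#' @return data.frame: gene_id, log2_fc, p, adj_p, deg_flag.
#' @export
diff_expression <- function(expr, groups, fdr = 0.05, fc = 1.5) {
  tpm <- if (inherits(expr, "expression_matrix")) expr$tpm else as.matrix(expr)
  groups <- groups[colnames(tpm)]
  labs <- sort(unique(stats::na.omit(unname(groups))))
  if (length(labs) != 2L) stop("exactly two group labels required")
  i1 <- which(groups == labs[1]); i2 <- which(groups == labs[2])
  if (length(i1) < 3L || length(i2) < 3L) stop("need >= 3 samples per group")
  lg <- log2(tpm + 1)
  p <- vapply(seq_len(nrow(lg)), function(g) {
    x <- lg[g, i1]; y <- lg[g, i2]
    if (stats::var(x) == 0 && stats::var(y) == 0) {
      return(if (mean(x) == mean(y)) 1 else 0)
    }
    stats::t.test(x, y, var.equal = FALSE)$p.value
  }, 0)
  log2_fc <- log2((rowMeans(tpm[, i1, drop = FALSE]) + 1) /
                  (rowMeans(tpm[, i2, drop = FALSE]) + 1))
  adj_p <- bh_fdr(p)
  data.frame(gene_id = rownames(tpm), log2_fc = unname(log2_fc), p = p,
             adj_p = adj_p,
             deg_flag = adj_p < fdr & abs(log2_fc) > log2(fc),
             stringsAsFactors = FALSE, row.names = NULL)
}
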