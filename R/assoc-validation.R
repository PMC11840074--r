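# Validation-arm statistics: relative qPCR quantification (2^-ddCt fold
# changes), genotype-group comparisons, and rank correlation of transcript
# measures with blood phenotypes.

#' 2^-ddCt qPCR fold changes
#'
#' Per sample and target gene: `delta_ct = Ct_target - Ct_reference`,
#' `delta_delta_ct = delta_ct - mean(control-group delta_ct)` (arithmetic
#' mean over control samples, per gene), `fold = 2^(-delta_delta_ct)`.
#' Amplification efficiency is fixed at 2 (perfect doubling per cycle).
#' Samples without a reference-gene Ct are excluded and listed in the
#' `"excluded"` attribute.
#'
#' @param ct data.frame with columns `sample`, `gene`, `ct`, `group`
#'   (long format; one row per sample x gene, technical replicates averaged
#'   upstream).
#' @param control_group group label of the calibrator samples.
#' @param reference_gene name of the reference (housekeeping) gene.
#' @return data.frame: sample, gene, group, delta_ct, delta_delta_ct, fold.
#' @export
ddct_fold_change <- function(ct, control_group, reference_gene) {
  stopifnot(all(c("sample", "gene", "ct", "group") %in% names(ct)))
  if (any(ct$ct <= 0, na.rm = TRUE)) stop("Ct values must be positive")
  ref <- ct[ct$gene == reference_gene, ]
  ref_ct <- stats::setNames(ref$ct, ref$sample)
  tgt <- ct[ct$gene != reference_gene, ]
  has_ref <- tgt$sample %in% names(ref_ct)[!is.na(ref_ct)]
  excluded <- unique(tgt$sample[!has_ref])
  tgt <- tgt[has_ref, , drop = FALSE]
  if (nrow(tgt) == 0L) stop("no target-gene measurements with a reference Ct")
  tgt$delta_ct <- tgt$ct - ref_ct[tgt$sample]
  out <- do.call(rbind, lapply(split(tgt, tgt$gene), function(g) {
    ctrl <- g$delta_ct[g$group == control_group]
    if (length(ctrl) == 0L) {
      stop(sprintf("control group '%s' empty for gene %s", control_group, g$gene[1]))
    }
    g$delta_delta_ct <- g$delta_ct - mean(ctrl)
    g$fold <- 2^(-g$delta_delta_ct)
    g
  }))
  rownames(out) <- NULL
  out <- out[, c("sample", "gene", "group", "delta_ct", "delta_delta_ct", "fold")]
  attr(out, "excluded") <- excluded
  out
}

#' Two-group difference test
#'
#' @param values numeric vector of measurements.
#' @param group_labels parallel vector with exactly two labels.
#' @param method `"mann_whitney"` (two-sided; exact enumeration when both
#'   groups have <= 8 untied observations, tie-corrected normal approximation
#'   otherwise; fully tied input gives p = 1 by convention), `"t_unpaired"`
#'   (two-sided pooled-variance t), or `"t_paired"` (values paired by
#'   position within group, equal group sizes required).
#' @return List: method, statistic, p, n1, n2.
#' @export
group_difference_test <- function(values, group_labels,
                                  method = c("mann_whitney", "t_unpaired", "t_paired")) {
  method <- match.arg(method)
  labs <- sort(unique(group_labels))
  if (length(labs) != 2L) stop("exactly two group labels required")
  x <- values[group_labels == labs[1]]
  y <- values[group_labels == labs[2]]
  if (length(x) < 2L || length(y) < 2L) stop("each group needs >= 2 values")
  if (method == "mann_whitney") {
    if (length(unique(c(x, y))) == 1L) {
      return(list(method = method, statistic = length(x) * length(y) / 2, p = 1,
                  n1 = length(x), n2 = length(y)))
    }
    exact <- length(x) <= 8L && length(y) <= 8L && !anyDuplicated(c(x, y))
    fit <- suppressWarnings(stats::wilcox.test(x, y, exact = exact))
    return(list(method = method, statistic = unname(fit$statistic),
                p = fit$p.value, n1 = length(x), n2 = length(y)))
  }
  if (method == "t_paired" && length(x) != length(y)) {
    stop("paired test requires equal group sizes")
  }
  fit <- stats::t.test(x, y, paired = method == "t_paired",
                       var.equal = method == "t_unpaired")
  list(method = method, statistic = unname(fit$statistic), p = fit$p.value,
       n1 = length(x), n2 = length(y))
}

#' Spearman rank correlation
#'
#' Average-rank tie handling; the two-sided p-value uses the t approximation
#' for n >= 10 and exact enumeration for n < 10 (when tie-free).
#'
#' @param x,y paired numeric vectors; incomplete pairs are dropped; n >= 4
#'   required.
#' @return List: r, p, n. A constant vector yields `r = NA` with a `reason`.
#' @export
spearman_assoc <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) stop("need at least 4 complete pairs")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = n, reason = "constant input"))
  }
  fit <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                          exact = n < 10L))
  list(r = unname(fit$estimate), p = fit$p.value, n = n)
}
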