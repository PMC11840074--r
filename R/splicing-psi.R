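# Percent spliced in (PSI) from junction read counts, and two-group
# differential splicing.

#' Compute PSI from junction counts
#'
#' Junction-count-only PSI: per event and sample, the inclusion evidence I is
#' the arithmetic mean of the event's inclusion-junction counts, the skipping
#' evidence S the mean of its skipping-junction counts, and
#' PSI = I / (I + S). A value of 0 means every transcript skipped the
#' alternative exon; 1 means every transcript includes it. Cells with
#' I + S < `min_reads` informative reads are reported missing (`NA`).
#' Junction keys absent from the count matrix count as zero.
#'
#' @param events list of `as_event` from [enumerate_events()].
#' @param junctions a [junction_counts()] object.
#' @param min_reads minimum informative reads per event per sample
#'   (default 10).
#' @return Matrix of class `psi_matrix`, events x samples, values in
#'   \[0, 1\] or `NA`.
#' @export
compute_psi <- function(events, junctions, min_reads = 10) {
  stopifnot(inherits(junctions, "junction_counts"))
  counts <- junctions$counts
  n_s <- ncol(counts)
  get_mean <- function(keys) {
    hit <- keys[keys %in% rownames(counts)]
    m <- matrix(0, nrow = length(keys), ncol = n_s)
    if (length(hit) > 0L) {
      m[match(hit, keys), ] <- counts[hit, , drop = FALSE]
    }
    colMeans(m)
  }
  psi <- matrix(NA_real_, nrow = length(events), ncol = n_s,
                dimnames = list(vapply(events, function(e) e$event_id, ""),
                                colnames(counts)))
  for (k in seq_along(events)) {
    I <- get_mean(events[[k]]$inclusion_junctions)
    S <- get_mean(events[[k]]$skipping_junctions)
    tot <- I + S
    v <- ifelse(tot > 0, I / tot, NA_real_)
    v[tot < min_reads] <- NA_real_
    psi[k, ] <- v
  }
  structure(psi, class = c("psi_matrix", "matrix"))
}

# Two-sided rank-sum p-value: exact enumeration when both groups have <= 8
# observations and no ties, tie-corrected normal approximation otherwise.
.ranksum_p <- function(x, y) {
  if (length(unique(c(x, y))) == 1L) return(1)  # fully tied convention
  exact <- length(x) <= 8L && length(y) <= 8L && !anyDuplicated(c(x, y))
  suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                      alternative = "two.sided")$p.value)
}

#' Differential splicing between two groups
#'
#' Per event, a two-sided rank-sum (Mann-Whitney) test on per-sample PSI,
#' Benjamini-Hochberg adjustment across tested events, and the compound
#' significance rule: adjusted p below `fdr` AND |delta PSI| above `dpsi`
#' (default 0.1, i.e. a 10 percentage-point PSI difference).
#'
#' @param psi a [compute_psi()] matrix.
#' @param groups named vector mapping sample -> group label (exactly two
#'   labels among the PSI columns).
#' @param fdr adjusted-p cutoff (default 0.05).
#' @param dpsi minimum |delta PSI| (default 0.1).
#' @param min_per_group minimum non-missing samples per group per event
#'   (default 3); events below it are skipped and listed in the `"skipped"`
#'   attribute with a reason.
#' @return data.frame with event_id, group means, `delta_psi`
#'   (group1 - group2, groups in sorted label order), `p`, `adj_p`,
#'   `significant`.
#' @export
diff_splicing <- function(psi, groups, fdr = 0.05, dpsi = 0.1, min_per_group = 3) {
  groups <- groups[colnames(psi)]
  labs <- sort(unique(stats::na.omit(unname(groups))))
  if (length(labs) != 2L) stop("exactly two group labels required")
  g1 <- which(groups == labs[1]); g2 <- which(groups == labs[2])
  rows <- list(); skipped <- list()
  for (k in seq_len(nrow(psi))) {
    x <- psi[k, g1]; x <- x[!is.na(x)]
    y <- psi[k, g2]; y <- y[!is.na(y)]
    if (length(x) < min_per_group || length(y) < min_per_group) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        event_id = rownames(psi)[k],
        reason = sprintf("fewer than %d non-missing samples in a group", min_per_group))
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      event_id = rownames(psi)[k],
      mean_psi_1 = mean(x), mean_psi_2 = mean(y),
      delta_psi = mean(x) - mean(y),
      p = .ranksum_p(x, y), stringsAsFactors = FALSE)
  }
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(event_id = character(0), mean_psi_1 = numeric(0),
               mean_psi_2 = numeric(0), delta_psi = numeric(0), p = numeric(0))
  res$adj_p <- bh_fdr(res$p)
  res$significant <- res$adj_p < fdr & abs(res$delta_psi) > dpsi
  attr(res, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(event_id = character(0), reason = character(0))
  attr(res, "groups") <- labs
  rownames(res) <- NULL
  res
}
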