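# cis-QTL mapping: window construction, per-(variant, feature) ordinary
# least squares on allele dosage, and permutation-based empirical p-values.

#' Promoter cis windows
#'
#' One window per transcript, anchored at the transcript start site (TSS, the
#' first transcribed base) and strand-aware: 1500 bp upstream and 200 bp
#' downstream of the TSS. Windows are clipped at position 1. For genes with
#' several transcripts each transcript contributes a window with the gene as
#' the feature id; [map_cis_qtl()] unions overlapping windows of the same
#' feature.
#'
#' @param transcripts list of [transcript_model()].
#' @param upstream,downstream window extents in bp (defaults 1500 / 200).
#' @return data.frame: feature_id (gene), transcript_id, kind = "promoter",
#'   chrom, start, end (1-based inclusive).
#' @export
define_promoter_windows <- function(transcripts, upstream = 1500, downstream = 200) {
  rows <- lapply(transcripts, function(m) {
    if (m$strand == "+") {
      tss <- m$exons[1, "start"]
      w <- c(tss - upstream, tss + downstream)
    } else {
      tss <- m$exons[nrow(m$exons), "end"]
      w <- c(tss - downstream, tss + upstream)
    }
    data.frame(feature_id = m$gene_id, transcript_id = m$transcript_id,
               kind = "promoter", chrom = m$chrom,
               start = max(1L, w[1]), end = w[2], stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Splicing cis windows
#'
#' The sQTL search window of each event: the alternative exon(s) plus
#' flanking introns. ES and MXE: from the start of the upstream flanking
#' intron to the end of the downstream flanking intron. A5SS/A3SS: the long
#' intron bounds (covering both alternative splice sites). IR: the retained
#' intron itself (it is both the alternative region and its own flanks).
#' These bounds are recorded on each event at enumeration time.
#'
#' @param events list of `as_event`.
#' @return data.frame: feature_id (event id), kind = "splice", chrom, start,
#'   end.
#' @export
define_splice_windows <- function(events) {
  if (length(events) == 0L) {
    return(data.frame(feature_id = character(0), kind = character(0),
                      chrom = character(0), start = integer(0), end = integer(0)))
  }
  do.call(rbind, lapply(events, function(e) {
    data.frame(feature_id = e$event_id, kind = "splice", chrom = e$chrom,
               start = e$window_start, end = e$window_end,
               stringsAsFactors = FALSE)
  }))
}

# OLS of y on x with intercept; returns beta, se, t, p (two-sided).
# Zero outcome variance -> p = 1 by convention (constant feature).
.ols_assoc <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  if (sxx == 0) return(NULL)   # monomorphic, caller handles
  syy <- sum((y - my)^2)
  sxy <- sum((x - mx) * (y - my))
  beta <- sxy / sxx
  if (syy == 0) {
    return(list(beta = 0, se = 0, t = 0, p = 1, n = n))
  }
  rss <- syy - beta * sxy
  rss <- max(rss, 0)
  sigma2 <- rss / (n - 2)
  se <- sqrt(sigma2 / sxx)
  if (se == 0) {
    # perfect fit with non-zero slope
    return(list(beta = beta, se = 0,
                t = sign(beta) * Inf, p = 0, n = n))
  }
  t <- beta / se
  list(beta = beta, se = se, t = t,
       p = 2 * stats::pt(-abs(t), df = n - 2), n = n)
}

#' Map cis QTL associations
#'
#' Ordinary least squares of each molecular feature (PSI for sQTL, TPM for
#' eQTL) on alternate-allele dosage (additive 0/1/2 coding, intercept +
#' slope), for every variant inside the feature's cis window. Samples with a
#' missing dosage or missing feature value are dropped pairwise.
#'
#' @param genotypes a [genotype_matrix()].
#' @param features features x samples matrix (rownames = feature ids matching
#'   `windows$feature_id`, colnames = sample ids).
#' @param windows window data.frame from [define_promoter_windows()] or
#'   [define_splice_windows()].
#' @param min_pairs minimum complete (dosage, feature) pairs (default 4);
#'   below it the association is skipped with a reason.
#' @param log_features if `TRUE`, regress on log2(feature + 1) (an option for
#'   eQTL mapping on TPM).
#' @return data.frame: variant_id, feature_id, n_used, beta, se, t_stat,
#'   p_nominal, reason (`NA` for tested associations, `"monomorphic"` or
#'   `"too_few_pairs"` otherwise).
#' @export
map_cis_qtl <- function(genotypes, features, windows, min_pairs = 4,
                        log_features = FALSE) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  feats <- as.matrix(features)
  if (log_features) feats <- log2(feats + 1)
  common <- intersect(genotypes$samples, colnames(feats))
  dos <- genotypes$dosage[common, , drop = FALSE]
  feats <- feats[, common, drop = FALSE]
  v <- genotypes$variants
  rows <- list()
  for (fid in unique(windows$feature_id)) {
    win <- windows[windows$feature_id == fid, , drop = FALSE]
    if (!fid %in% rownames(feats)) next
    in_win <- rep(FALSE, nrow(v))
    for (w in seq_len(nrow(win))) {
      in_win <- in_win | (v$chrom == win$chrom[w] &
                          v$pos >= win$start[w] & v$pos <= win$end[w])
    }
    y_all <- feats[fid, ]
    for (j in which(in_win)) {
      x <- dos[, j]
      ok <- !is.na(x) & !is.na(y_all)
      row <- data.frame(variant_id = v$id[j], feature_id = fid,
                        n_used = sum(ok), beta = NA_real_, se = NA_real_,
                        t_stat = NA_real_, p_nominal = NA_real_,
                        reason = NA_character_, stringsAsFactors = FALSE)
      if (sum(ok) < min_pairs) {
        row$reason <- "too_few_pairs"
      } else {
        fit <- .ols_assoc(x[ok], y_all[ok])
        if (is.null(fit)) {
          row$reason <- "monomorphic"
        } else {
          row$beta <- fit$beta; row$se <- fit$se
          row$t_stat <- fit$t; row$p_nominal <- fit$p
        }
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(variant_id = character(0), feature_id = character(0),
                      n_used = integer(0), beta = numeric(0), se = numeric(0),
                      t_stat = numeric(0), p_nominal = numeric(0),
                      reason = character(0)))
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

# nominal p of y regressed on x for many permuted copies of y at once.
# X: centred dosage vector; Yp: n x n_perm matrix of permuted outcomes.
.perm_pvalues <- function(x, Yp) {
  n <- length(x)
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  Yc <- sweep(Yp, 2, colMeans(Yp))
  syy <- colSums(Yc^2)
  sxy <- as.vector(crossprod(xc, Yc))
  beta <- sxy / sxx
  rss <- pmax(syy - beta * sxy, 0)
  se <- sqrt(rss / (n - 2) / sxx)
  t <- ifelse(se > 0, beta / se, ifelse(beta == 0, 0, Inf))
  p <- 2 * stats::pt(-abs(t), df = n - 2)
  p[syy == 0] <- 1
  p
}

#' Permutation-based empirical p-values
#'
#' For each association, the sample labels of the feature vector are permuted
#' relative to the genotypes `n_perm` times (one shared permutation schedule,
#' drawn once from `seed`, reused across all associations), the nominal
#' regression p-value is recomputed for each permutation, and the empirical
#' p-value is the pseudo-count estimator
#' `(1 + #\{p_perm <= p_nominal\}) / (n_perm + 1)`.
#'
#' @param genotypes a [genotype_matrix()].
#' @param features features x samples matrix (as in [map_cis_qtl()]).
#' @param associations data.frame from [map_cis_qtl()] (rows with `NA`
#'   `p_nominal` are passed through unchanged).
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed for the permutation schedule.
#' @param log_features as in [map_cis_qtl()]; must match the nominal pass.
#' @return `associations` with columns `p_empirical` and `n_perm` added.
#'   `p_empirical >= 1 / (n_perm + 1)` always.
#' @export
empirical_pvalues <- function(genotypes, features, associations, n_perm = 1000,
                              seed = 1, log_features = FALSE) {
  stopifnot(n_perm >= 1)
  feats <- as.matrix(features)
  if (log_features) feats <- log2(feats + 1)
  common <- intersect(genotypes$samples, colnames(feats))
  dos <- genotypes$dosage[common, , drop = FALSE]
  feats <- feats[, common, drop = FALSE]
  n <- length(common)
  set.seed(as.integer(seed))
  perms <- replicate(n_perm, sample.int(n))   # shared schedule

  p_emp <- rep(NA_real_, nrow(associations))
  for (i in seq_len(nrow(associations))) {
    if (is.na(associations$p_nominal[i])) next
    x <- dos[, associations$variant_id[i]]
    y <- feats[associations$feature_id[i], ]
    Yp <- matrix(y[perms], nrow = n)
    # permute the full feature vector, then drop incomplete pairs case-wise
    if (anyNA(y) || anyNA(x)) {
      pp <- vapply(seq_len(n_perm), function(k) {
        yk <- Yp[, k]
        sel <- !is.na(x) & !is.na(yk)
        fit <- .ols_assoc(x[sel], yk[sel])
        if (is.null(fit)) NA_real_ else fit$p
      }, 0)
      pp <- pp[!is.na(pp)]
    } else {
      pp <- .perm_pvalues(x, Yp)
    }
    p_emp[i] <- (1 + sum(pp <= associations$p_nominal[i])) / (length(pp) + 1)
  }
  associations$p_empirical <- p_emp
  associations$n_perm <- n_perm
  associations
}
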