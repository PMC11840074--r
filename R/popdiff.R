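# Population differentiation: allele frequencies, the chi-square / delta-MAF
# adapted-variant test against a reference population, Hudson Fst, the
# population branch statistic (PBS) and its normalised form PBSn1,
# contingency trend tests, and LD r^2.

#' Per-population allele frequencies
#'
#' Missing dosages are excluded from both the allele count and the total.
#' Variants with zero genotyped samples in a population are omitted from that
#' population's rows.
#'
#' @param genotypes a [genotype_matrix()] with population labels.
#' @return data.frame: variant_id, population, alt_count, total
#'   (2 x genotyped samples), af, maf.
#' @export
allele_frequencies <- function(genotypes) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  if (is.null(genotypes$population)) stop("genotype matrix has no population labels")
  pops <- sort(unique(unname(genotypes$population)))
  rows <- lapply(pops, function(p) {
    d <- genotypes$dosage[genotypes$population == p, , drop = FALSE]
    alt <- colSums(d, na.rm = TRUE)
    total <- 2 * colSums(!is.na(d))
    keep <- total > 0
    af <- alt[keep] / total[keep]
    data.frame(variant_id = genotypes$variants$id[keep], population = p,
               alt_count = alt[keep], total = total[keep], af = af,
               maf = pmin(af, 1 - af), stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

# Vectorised 2x2 Pearson chi-square (no continuity correction) on allele
# counts: (alt, ref) x (population, reference).
.chi2_2x2 <- function(a1, n1, a2, n2) {
  b1 <- n1 - a1; b2 <- n2 - a2
  N <- n1 + n2
  num <- N * (a1 * b2 - a2 * b1)^2
  den <- as.numeric(n1) * n2 * (a1 + a2) * (b1 + b2)
  ifelse(den > 0, num / den, NA_real_)
}

#' Adapted-variant test against a reference population
#'
#' Per variant, a 2x2 chi-square test (alternate vs reference allele counts,
#' study vs reference population; no continuity correction), BH adjustment
#' across variants, and the compound call: adjusted p below `fdr` AND allele
#' frequency difference above `dmaf`. By default the difference is the
#' unfolded same-allele `|af_pop - af_ref|`; set `fold_maf = TRUE` for the
#' folded `|maf_pop - maf_ref|` variant.
#'
#' @param pop_counts data.frame for the study population: variant_id,
#'   alt_count, total (total = 2 x genotyped samples).
#' @param ref_counts same columns for the reference population (e.g. a
#'   public-database frequency export); matched to `pop_counts` by
#'   variant_id.
#' @param fdr adjusted-p cutoff (default 0.05).
#' @param dmaf frequency-difference cutoff (default 0.3).
#' @param fold_maf fold each population's frequency to the minor allele
#'   before differencing (default `FALSE`).
#' @return data.frame: variant_id, af_pop, af_ref, chi2, p, adj_p, delta_maf,
#'   adapted. Variants with zero total in either population get `NA`
#'   statistics and `reason = "no_data"`.
#' @export
adapted_variant_test <- function(pop_counts, ref_counts, fdr = 0.05, dmaf = 0.3,
                                 fold_maf = FALSE) {
  m <- merge(pop_counts, ref_counts, by = "variant_id",
             suffixes = c("_pop", "_ref"), sort = FALSE)
  ok <- m$total_pop > 0 & m$total_ref > 0
  af_pop <- ifelse(ok, m$alt_count_pop / m$total_pop, NA_real_)
  af_ref <- ifelse(ok, m$alt_count_ref / m$total_ref, NA_real_)
  chi2 <- ifelse(ok, .chi2_2x2(m$alt_count_pop, m$total_pop,
                               m$alt_count_ref, m$total_ref), NA_real_)
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  adj_p <- rep(NA_real_, length(p))
  adj_p[!is.na(p)] <- bh_fdr(p[!is.na(p)])
  delta <- if (fold_maf) {
    abs(pmin(af_pop, 1 - af_pop) - pmin(af_ref, 1 - af_ref))
  } else {
    abs(af_pop - af_ref)
  }
  data.frame(variant_id = m$variant_id, af_pop = af_pop, af_ref = af_ref,
             chi2 = chi2, p = p, adj_p = adj_p, delta_maf = delta,
             adapted = !is.na(adj_p) & adj_p < fdr & delta > dmaf,
             reason = ifelse(ok, NA_character_, "no_data"),
             stringsAsFactors = FALSE)
}

#' Hudson Fst
#'
#' Hudson's Fst estimator with finite-sample correction:
#' numerator `(p1 - p2)^2 - p1(1-p1)/(2 n1 - 1) - p2(1-p2)/(2 n2 - 1)`,
#' denominator `p1(1-p2) + p2(1-p1)`. The windowed (multi-variant) value is
#' the ratio of averages: sum of numerators over sum of denominators.
#'
#' @param af1,af2 allele frequencies in the two populations (vectors).
#' @param n1,n2 diploid sample counts per population.
#' @return data.frame: fst (per variant; `NA` where the denominator is 0,
#'   i.e. both populations fixed for the same allele), num, den.
#' @export
hudson_fst <- function(af1, n1, af2, n2) {
  stopifnot(n1 >= 1, n2 >= 1, all(af1 >= 0 & af1 <= 1), all(af2 >= 0 & af2 <= 1))
  num <- (af1 - af2)^2 - af1 * (1 - af1) / (2 * n1 - 1) - af2 * (1 - af2) / (2 * n2 - 1)
  den <- af1 * (1 - af2) + af2 * (1 - af1)
  data.frame(fst = ifelse(den > 0, num / den, NA_real_), num = num, den = den)
}

#' Windowed Hudson Fst (ratio of averages)
#'
#' @param fst_table output of [hudson_fst()] for the variants in the window.
#' @return Single Fst value: `sum(num) / sum(den)` over variants with a
#'   defined denominator.
#' @export
fst_windowed <- function(fst_table) {
  keep <- fst_table$den > 0
  if (!any(keep)) return(NA_real_)
  sum(fst_table$num[keep]) / sum(fst_table$den[keep])
}

#' Population branch statistic (PBS)
#'
#' Branch lengths `T = -log(1 - Fst)` for the three population pairs; each
#' population's PBS is half the excess of its two branch lengths over the
#' opposite one: `pbs_a = (t_ab + t_ac - t_bc) / 2`, cyclically for b and c.
#' Fst values are floored at 0 and capped just below 1 before the log.
#'
#' @param fst_ab,fst_ac,fst_bc pairwise Fst values (vectors).
#' @return data.frame: pbs_a, pbs_b, pbs_c.
#' @export
pbs_stat <- function(fst_ab, fst_ac, fst_bc) {
  tt <- function(f) -log(1 - pmin(pmax(f, 0), 1 - 1e-12))
  t_ab <- tt(fst_ab); t_ac <- tt(fst_ac); t_bc <- tt(fst_bc)
  data.frame(pbs_a = (t_ab + t_ac - t_bc) / 2,
             pbs_b = (t_ab + t_bc - t_ac) / 2,
             pbs_c = (t_ac + t_bc - t_ab) / 2)
}

#' Normalised population branch statistic (PBSn1)
#'
#' `pbsn1 = max(pbs_a, 0) / (1 + max(pbs_a, 0) + max(pbs_b, 0) + max(pbs_c, 0))`,
#' bounding the focal branch by the total tree length; lies in \[0, 1).
#'
#' @param pbs_a,pbs_b,pbs_c PBS values (focal population first).
#' @return PBSn1 value(s).
#' @export
pbsn1_stat <- function(pbs_a, pbs_b, pbs_c) {
  a <- pmax(pbs_a, 0); b <- pmax(pbs_b, 0); c <- pmax(pbs_c, 0)
  a / (1 + a + b + c)
}

#' Contingency trend test across groups
#'
#' Pearson chi-square on a contingency table of allele or genotype counts
#' across two or more groups (e.g. sampling sites at different altitudes),
#' without continuity correction; df = (rows - 1)(cols - 1).
#'
#' @param counts matrix or table of non-negative counts (groups x
#'   categories).
#' @return List: chi2, df, p, low_expected (`TRUE` when any expected cell is
#'   below 1; recorded rather than raised).
#' @export
genotype_trend_test <- function(counts) {
  counts <- as.matrix(counts)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("empty group (all-zero row or column) in contingency table")
  }
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  fit <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(chi2 = unname(fit$statistic), df = unname(fit$parameter),
       p = fit$p.value, low_expected = any(expected < 1))
}

#' Linkage disequilibrium r^2 from dosages
#'
#' Squared Pearson correlation of the two dosage vectors over complete pairs
#' (composite LD; no phasing).
#'
#' @param dosage_x,dosage_y dosage vectors in \{0, 1, 2, NA\}.
#' @return r^2, or `NA` if either variant is monomorphic among complete
#'   pairs.
#' @export
ld_r2 <- function(dosage_x, dosage_y) {
  ok <- !is.na(dosage_x) & !is.na(dosage_y)
  x <- dosage_x[ok]; y <- dosage_y[ok]
  if (length(x) < 2 || stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}
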