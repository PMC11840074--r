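test_that("promoter windows are strand-aware, clipped, and 1701 bp long", {
  plus <- transcript_model("g1", "t1", "1", "+",
                           cbind(start = c(10000L, 12000L), end = c(10100L, 12200L)))
  minus <- transcript_model("g2", "t2", "1", "-",
                            cbind(start = c(8000L, 9900L), end = c(8100L, 10000L)))
  near_edge <- transcript_model("g3", "t3", "1", "+",
                                cbind(start = 1000L, end = 1400L))
  w <- define_promoter_windows(list(plus, minus, near_edge))
  expect_equal(unlist(w[w$feature_id == "g1", c("start", "end")], use.names = FALSE),
               c(8500L, 10200L))
  expect_equal(unlist(w[w$feature_id == "g2", c("start", "end")], use.names = FALSE),
               c(9800L, 11500L))
  expect_equal(unlist(w[w$feature_id == "g3", c("start", "end")], use.names = FALSE),
               c(1L, 1200L))   # clipped at 1
  unclipped <- w$start > 1
  expect_true(all(w$end[unclipped] - w$start[unclipped] + 1L == 1701L))
})

test_that("splice windows cover the alternative exon plus flanking introns", {
  ev <- make_es_event(up_intron = c(1500L, 1999L), dn_intron = c(2101L, 2600L))
  w <- define_splice_windows(list(ev))
  expect_equal(c(w$start, w$end), c(1500L, 2600L))
  # window always contains the event target
  expect_true(w$start <= ev$target["exon_start"] && w$end >= ev$target["exon_end"])

  # IR windows are the retained intron bounds
  t1 <- transcript_model("g", "t1", "1", "+",
                         cbind(start = c(100L, 400L), end = c(250L, 600L)))
  t2 <- transcript_model("g", "t2", "1", "+", cbind(start = 100L, end = 600L))
  ir <- enumerate_events(list(t1, t2))
  wir <- define_splice_windows(ir)
  expect_equal(c(wir$start, wir$end), c(251L, 399L))
})

.toy_qtl_data <- function(dosages, y) {
  n <- length(dosages)
  samples <- sprintf("s%02d", seq_len(n))
  gm <- genotype_matrix(
    data.frame(chrom = "1", pos = 500L, id = "v1", ref = "C", alt = "T"),
    samples, matrix(dosages, ncol = 1), NULL)
  feats <- matrix(y, nrow = 1, dimnames = list("f1", samples))
  win <- data.frame(feature_id = "f1", kind = "splice", chrom = "1",
                    start = 1L, end = 1000L)
  list(gm = gm, feats = feats, win = win)
}

test_that("a noiseless linear relation is recovered exactly", {
  d <- .toy_qtl_data(rep(c(0, 1, 2), each = 4), 0.2 + 0.1 * rep(c(0, 1, 2), each = 4))
  res <- map_cis_qtl(d$gm, d$feats, d$win)
  expect_equal(res$beta, 0.1)
  expect_equal(res$p_nominal, 0)
  expect_equal(res$n_used, 12L)
})

test_that("monomorphic variants and sparse pairs are reported with reasons", {
  d <- .toy_qtl_data(rep(1, 10), runif(10))
  expect_equal(map_cis_qtl(d$gm, d$feats, d$win)$reason, "monomorphic")
  d2 <- .toy_qtl_data(c(0, 1, 2, rep(NA, 7)), runif(10))
  expect_equal(map_cis_qtl(d2$gm, d2$feats, d2$win)$reason, "too_few_pairs")
})

test_that("the OLS slope equals the closed-form ratio and matches lm()", {
  set.seed(8)
  for (rep in 1:10) {
    x <- sample(0:2, 30, replace = TRUE)
    y <- 0.3 * x + rnorm(30)
    d <- .toy_qtl_data(x, y)
    res <- map_cis_qtl(d$gm, d$feats, d$win)
    expect_equal(res$beta, cov(x, y) / var(x), tolerance = 1e-12)
    fit <- summary(lm(y ~ x))$coefficients
    expect_equal(res$beta, unname(fit["x", "Estimate"]), tolerance = 1e-10)
    expect_equal(res$se, unname(fit["x", "Std. Error"]), tolerance = 1e-10)
    expect_equal(res$p_nominal, unname(fit["x", "Pr(>|t|)"]), tolerance = 1e-10)
  }
})

test_that("missing data are dropped pairwise", {
  set.seed(9)
  x <- c(NA, sample(0:2, 19, replace = TRUE))
  y <- c(rnorm(19), NA)
  d <- .toy_qtl_data(x, y)
  res <- map_cis_qtl(d$gm, d$feats, d$win)
  ok <- !is.na(x) & !is.na(y)
  expect_equal(res$n_used, sum(ok))
  expect_equal(res$beta, cov(x[ok], y[ok]) / var(x[ok]), tolerance = 1e-12)
})

test_that("empirical p-values honour the pseudo-count bounds", {
  set.seed(10)
  x <- rep(c(0, 1, 2), each = 10)
  y <- x + rnorm(30, 0, 0.05)          # overwhelming signal
  d <- .toy_qtl_data(x, y)
  res <- map_cis_qtl(d$gm, d$feats, d$win)
  res <- empirical_pvalues(d$gm, d$feats, res, n_perm = 1000, seed = 3)
  expect_equal(res$p_empirical, 1 / 1001)

  # constant feature vector: every permutation identical -> p_empirical = 1
  dc <- .toy_qtl_data(rep(c(0, 1, 2), each = 4), rep(0.5, 12))
  rc <- map_cis_qtl(dc$gm, dc$feats, dc$win)
  expect_equal(rc$p_nominal, 1)
  rc <- empirical_pvalues(dc$gm, dc$feats, rc, n_perm = 200, seed = 3)
  expect_equal(rc$p_empirical, 1)
})

test_that("empirical p-values are deterministic given the seed", {
  set.seed(11)
  d <- .toy_qtl_data(sample(0:2, 20, replace = TRUE), rnorm(20))
  res <- map_cis_qtl(d$gm, d$feats, d$win)
  a <- empirical_pvalues(d$gm, d$feats, res, n_perm = 100, seed = 5)
  b <- empirical_pvalues(d$gm, d$feats, res, n_perm = 100, seed = 5)
  expect_identical(a$p_empirical, b$p_empirical)
})

test_that("nominal p-values are calibrated under the global null", {
  set.seed(12)
  n <- 60
  hits <- 0; m <- 400
  for (i in seq_len(m)) {
    x <- rbinom(n, 2, 0.4)
    if (var(x) == 0) next
    y <- rnorm(n)
    d <- .toy_qtl_data(x, y)
    p <- map_cis_qtl(d$gm, d$feats, d$win)$p_nominal
    if (p < 0.05) hits <- hits + 1
  }
  rate <- hits / m
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / m))
})

test_that("a planted logit-PSI effect is recovered with the right sign and scale", {
  reps <- 30; good <- 0
  for (r in seq_len(reps)) {
    cfg <- sim_config(n_pop1 = 35, n_pop2 = 35, n_variants = 1, n_genes = 1,
                      fst_divergence = 0, coverage_mean = 100, beta_psi = 0.8,
                      noise_sd_psi = 0.1, seed = 1000 + r)
    models <- simulate_gene_models(cfg)
    events <- enumerate_events(models)[1]
    sim_g <- simulate_genotypes(cfg)
    truth <- data.frame(event_id = events[[1]]$event_id, baseline_logit = 0,
                        beta = 0.8, causal_variant = "var0001", pop_shift = 0)
    out <- simulate_splicing_counts(sim_g$genotypes, events, truth, cfg)
    psi <- compute_psi(events, out$junctions)
    win <- data.frame(feature_id = events[[1]]$event_id, kind = "splice",
                      chrom = "1", start = 1L, end = 3e6)
    res <- map_cis_qtl(sim_g$genotypes, psi, win)
    dos <- sim_g$genotypes$dosage[, "var0001"]
    # the junction-count PSI averages the two inclusion junctions, so its
    # expectation is psi/(2 - psi); linearize the planted effect on that
    # measurement scale
    tp <- out$true_psi[1, ]
    truth_lin <- cov(tp / (2 - tp), dos) / var(dos)
    if (sign(res$beta) == sign(truth_lin) &&
        abs(res$beta - truth_lin) < 3 * res$se) good <- good + 1
  }
  expect_gte(good / reps, 0.9)
})
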