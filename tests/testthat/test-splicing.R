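test_that("a skipped internal exon yields exactly one ES event with the expected junctions", {
  t1 <- transcript_model("g", "t1", "1", "+",
                         cbind(start = c(1000L, 1500L, 2000L),
                               end = c(1199L, 1619L, 2299L)))
  t2 <- transcript_model("g", "t2", "1", "+",
                         cbind(start = c(1000L, 2000L), end = c(1199L, 2299L)))
  ev <- enumerate_events(list(t1, t2))
  expect_length(ev, 1L)
  expect_equal(ev[[1]]$type, "ES")
  expect_setequal(ev[[1]]$inclusion_junctions,
                  c("1:1200-1499:+", "1:1620-1999:+"))
  expect_equal(ev[[1]]$skipping_junctions, "1:1200-1999:+")
  # single-transcript genes yield nothing
  expect_length(enumerate_events(list(t1)), 0L)
})

test_that("alternative donors sharing an acceptor classify as A5SS on the plus strand", {
  # exon 1 donor differs between isoforms; acceptor of exon 2 shared
  t1 <- transcript_model("g", "t1", "1", "+",
                         cbind(start = c(100L, 500L), end = c(200L, 700L)))
  t2 <- transcript_model("g", "t2", "1", "+",
                         cbind(start = c(100L, 500L), end = c(260L, 700L)))
  ev <- enumerate_events(list(t1, t2))
  expect_length(ev, 1L)
  expect_equal(ev[[1]]$type, "A5SS")
  expect_equal(event_signatures(ev), oracle_events(list(t1, t2)))
  # same geometry on the minus strand is an alternative 3' site
  m1 <- transcript_model("g", "t1", "1", "-", t1$exons)
  m2 <- transcript_model("g", "t2", "1", "-", t2$exons)
  expect_equal(enumerate_events(list(m1, m2))[[1]]$type, "A3SS")
})

test_that("mutually exclusive internal exons with shared flanks classify as MXE", {
  t1 <- transcript_model("g", "t1", "1", "+",
                         cbind(start = c(100L, 300L, 800L), end = c(200L, 380L, 900L)))
  t2 <- transcript_model("g", "t2", "1", "+",
                         cbind(start = c(100L, 500L, 800L), end = c(200L, 580L, 900L)))
  ev <- enumerate_events(list(t1, t2))
  expect_length(ev, 1L)
  expect_equal(ev[[1]]$type, "MXE")
  expect_equal(event_signatures(ev), oracle_events(list(t1, t2)))
  # inclusion = first exclusive exon by coordinate
  expect_setequal(ev[[1]]$inclusion_junctions, c("1:201-299:+", "1:381-799:+"))
  expect_setequal(ev[[1]]$skipping_junctions, c("1:201-499:+", "1:581-799:+"))
})

test_that("a retained intron classifies as IR with pseudo-junction inclusion keys", {
  t1 <- transcript_model("g", "t1", "1", "+",
                         cbind(start = c(100L, 400L), end = c(250L, 600L)))
  t2 <- transcript_model("g", "t2", "1", "+",
                         cbind(start = 100L, end = 600L))
  ev <- enumerate_events(list(t1, t2))
  expect_length(ev, 1L)
  expect_equal(ev[[1]]$type, "IR")
  expect_setequal(ev[[1]]$inclusion_junctions,
                  c("1:251-399:+:IR5", "1:251-399:+:IR3"))
  expect_equal(ev[[1]]$skipping_junctions, "1:251-399:+")
})

test_that("event enumeration matches the brute-force comparator on random gene models", {
  set.seed(424)
  n_disagreements <- 0L
  for (g in seq_len(150)) {
    tx <- random_gene_models(sprintf("g%03d", g))
    got <- event_signatures(enumerate_events(tx))
    want <- oracle_events(tx)
    if (!identical(got, want)) n_disagreements <- n_disagreements + 1L
  }
  expect_equal(n_disagreements, 0L)
})

test_that("PSI follows the junction-count formula including the boundary values", {
  ev <- make_es_event()
  # only skipping reads -> 0; only inclusion reads -> 1
  jc <- jc_from_counts(ev, incl1 = c(12, 0, 6), incl2 = c(8, 0, 10),
                       skip = c(0, 25, 8))
  psi <- compute_psi(list(ev), jc, min_reads = 10)
  expect_equal(unname(psi[1, ]), c(1, 0, 0.5))  # mean(6,10)=8 vs 8 -> 0.5
})

test_that("PSI is missing below the informative-read threshold and scale-invariant above it", {
  ev <- make_es_event()
  jc <- jc_from_counts(ev, incl1 = c(3, 30), incl2 = c(5, 50), skip = c(4, 40))
  psi <- compute_psi(list(ev), jc, min_reads = 10)
  expect_true(is.na(psi[1, 1]))   # (3+5)/2 + 4 = 8 < 10
  expect_false(is.na(psi[1, 2]))
  expect_equal(psi[1, 2], 40 / (40 + 40))
  # scaling all counts by a positive constant leaves PSI unchanged
  jc10 <- jc_from_counts(ev, incl1 = c(30, 300), incl2 = c(50, 500),
                         skip = c(40, 400))
  expect_equal(compute_psi(list(ev), jc10, min_reads = 10)[1, 2], psi[1, 2])
})

test_that("differential splicing applies the compound FDR + delta-PSI rule", {
  ev_ids <- sprintf("e%02d", 1:3)
  groups <- stats::setNames(rep(c("A", "B"), each = 20), sprintf("s%02d", 1:40))
  set.seed(99)
  base <- matrix(NA_real_, 3, 40, dimnames = list(ev_ids, names(groups)))
  base[1, ] <- 0.5                                        # identical
  base[2, ] <- c(rep(0.50, 20), rep(0.42, 20)) + stats::runif(40, 0, 1e-3)
  base[3, ] <- c(rep(0.80, 20), rep(0.30, 20)) + stats::runif(40, 0, 1e-3)
  res <- diff_splicing(structure(base, class = c("psi_matrix", "matrix")), groups)
  expect_equal(res$delta_psi[1], 0)
  expect_false(res$significant[1])
  # strong p but |dPSI| = 0.08 < 0.1 -> not significant
  expect_lt(res$adj_p[2], 1e-6)
  expect_false(res$significant[2])
  expect_true(res$significant[3])
})

test_that("a planted 0.9 vs 0.5 PSI difference is detected with the right effect size", {
  cfg <- sim_config(n_pop1 = 30, n_pop2 = 30, n_variants = 1, n_genes = 1,
                    coverage_mean = 200, noise_sd_psi = 0, seed = 47)
  models <- simulate_gene_models(cfg)
  events <- enumerate_events(models)[1]
  # target PSI on the junction-count measurement scale (two inclusion
  # junctions averaged): latent isoform fraction g_inv(x) = 2x/(1+x)
  g_inv <- function(x) stats::qlogis(2 * x / (1 + x))
  truth <- data.frame(event_id = events[[1]]$event_id,
                      baseline_logit = g_inv(0.5), beta = 0,
                      causal_variant = NA_character_,
                      pop_shift = g_inv(0.9) - g_inv(0.5))
  sim_g <- simulate_genotypes(cfg)
  out <- simulate_splicing_counts(sim_g$genotypes, events, truth, cfg)
  psi <- compute_psi(events, out$junctions)
  res <- diff_splicing(psi, sim_g$genotypes$population)
  expect_true(res$significant[1])
  expect_lt(abs(res$delta_psi[1] - 0.4), 0.05)
})

test_that("events with too few informative samples are skipped with a reason", {
  psi <- matrix(c(rep(NA, 5), 0.5, 0.6, 0.4, 0.5, 0.7), nrow = 1,
                dimnames = list("e1", sprintf("s%02d", 1:10)))
  groups <- stats::setNames(rep(c("A", "B"), each = 5), colnames(psi))
  res <- diff_splicing(structure(psi, class = c("psi_matrix", "matrix")), groups)
  expect_equal(nrow(res), 0L)
  expect_equal(attr(res, "skipped")$event_id, "e1")
})

test_that("differential splicing under the null keeps the discovery rate controlled", {
  cfg <- sim_config(n_pop1 = 25, n_pop2 = 25, n_variants = 1, n_genes = 40,
                    coverage_mean = 100, noise_sd_psi = 0.3, causal_fraction = 0,
                    seed = 53)
  models <- simulate_gene_models(cfg)
  events <- enumerate_events(models)
  set.seed(53)
  truth <- data.frame(event_id = vapply(events, function(e) e$event_id, ""),
                      baseline_logit = stats::runif(length(events), -1, 1),
                      beta = 0, causal_variant = NA_character_, pop_shift = 0)
  sim_g <- simulate_genotypes(cfg)
  out <- simulate_splicing_counts(sim_g$genotypes, events, truth, cfg)
  psi <- compute_psi(events, out$junctions)
  res <- diff_splicing(psi, sim_g$genotypes$population)
  se <- sqrt(0.05 * 0.95 / nrow(res))
  expect_lte(mean(res$significant), 0.05 + 3 * se)
})
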