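test_that("zero divergence leaves both population frequencies at the ancestral value", {
  cfg <- sim_config(n_pop1 = 5, n_pop2 = 5, n_variants = 50, fst_divergence = 0,
                    seed = 11)
  sim <- simulate_genotypes(cfg)
  expect_identical(sim$truth$af_pop1, sim$truth$af_ancestral)
  expect_identical(sim$truth$af_pop2, sim$truth$af_ancestral)
})

test_that("generators are pure functions of (config, seed)", {
  cfg <- sim_config(n_pop1 = 15, n_pop2 = 10, n_variants = 60, n_genes = 4,
                    seed = 7)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$genotypes$dosage, b$genotypes$dosage)
  expect_identical(a$junctions$counts, b$junctions$counts)
  expect_identical(a$expression$tpm, b$expression$tpm)
  expect_identical(a$samples, b$samples)
  expect_identical(a$qpcr, b$qpcr)
})

test_that("sample allele frequencies stay within 3 binomial SE of the drawn frequency", {
  cfg <- sim_config(n_pop1 = 200, n_pop2 = 200, n_variants = 400, seed = 13)
  sim <- simulate_genotypes(cfg)
  af <- allele_frequencies(sim$genotypes)
  for (pop in c("pop1", "pop2")) {
    a <- af[af$population == pop, ]
    p <- sim$truth[[paste0("af_", pop)]][match(a$variant_id, sim$truth$variant_id)]
    se <- sqrt(p * (1 - p) / a$total)
    frac_in <- mean(abs(a$af - p) <= 3 * se)
    expect_gte(frac_in, 0.985)
  }
})

test_that("genotypes are in Hardy-Weinberg proportions within population", {
  cfg <- sim_config(n_pop1 = 300, n_pop2 = 5, n_variants = 500, seed = 17)
  sim <- simulate_genotypes(cfg)
  d <- sim$genotypes$dosage[sim$genotypes$population == "pop1", ]
  p_hat <- colMeans(d) / 2
  rejected <- vapply(seq_len(ncol(d)), function(j) {
    p <- p_hat[j]
    if (p < 0.05 || p > 0.95) return(FALSE)  # expected counts too small to test
    obs <- tabulate(d[, j] + 1, nbins = 3)
    expc <- nrow(d) * c((1 - p)^2, 2 * p * (1 - p), p^2)
    x2 <- sum((obs - expc)^2 / expc)
    stats::pchisq(x2, df = 1, lower.tail = FALSE) < 0.01
  }, TRUE)
  expect_lte(mean(rejected), 0.02)
})

test_that("junction counts saturate at the PSI extremes", {
  cfg <- sim_config(n_pop1 = 20, n_pop2 = 5, n_variants = 1, n_genes = 1,
                    coverage_mean = 200, noise_sd_psi = 0, seed = 19)
  models <- simulate_gene_models(cfg)
  events <- enumerate_events(models)[1]
  truth <- data.frame(event_id = events[[1]]$event_id, baseline_logit = 8,
                      beta = 0, causal_variant = NA_character_, pop_shift = 0)
  sim_g <- simulate_genotypes(cfg)
  out <- simulate_splicing_counts(sim_g$genotypes, events, truth, cfg)
  psi <- compute_psi(events, out$junctions)
  expect_true(all(psi > 0.99))
})

test_that("under the null the two population PSI means coincide", {
  cfg <- sim_config(n_pop1 = 100, n_pop2 = 100, n_variants = 1, n_genes = 1,
                    coverage_mean = 200, noise_sd_psi = 0, seed = 23)
  models <- simulate_gene_models(cfg)
  events <- enumerate_events(models)[1]
  truth <- data.frame(event_id = events[[1]]$event_id, baseline_logit = 0.4,
                      beta = 0, causal_variant = NA_character_, pop_shift = 0)
  sim_g <- simulate_genotypes(cfg)
  out <- simulate_splicing_counts(sim_g$genotypes, events, truth, cfg)
  psi <- compute_psi(events, out$junctions)
  pop <- sim_g$genotypes$population
  expect_lt(abs(mean(psi[1, pop == "pop1"]) - mean(psi[1, pop == "pop2"])), 0.02)
})

test_that("every planted causal variant lies inside its feature's cis window", {
  ds <- simulate_dataset(sim_config(n_pop1 = 10, n_pop2 = 10, n_variants = 80,
                                    n_genes = 6, seed = 29))
  swin <- define_splice_windows(ds$events)
  pwin <- define_promoter_windows(ds$models)
  v <- ds$genotypes$variants
  ev <- ds$truth$events
  for (k in which(!is.na(ev$causal_variant))) {
    pos <- v$pos[v$id == ev$causal_variant[k]]
    w <- swin[swin$feature_id == ev$event_id[k], ]
    expect_true(pos >= w$start && pos <= w$end)
  }
  gn <- ds$truth$genes
  for (k in which(!is.na(gn$causal_variant))) {
    pos <- v$pos[v$id == gn$causal_variant[k]]
    w <- pwin[pwin$feature_id == gn$gene_id[k], ]
    expect_true(any(pos >= w$start & pos <= w$end))
  }
})

test_that("noiseless expression reflects the planted model exactly", {
  cfg <- sim_config(n_pop1 = 15, n_pop2 = 15, n_variants = 1, noise_sd_expr = 0,
                    de_log2fc = 0, seed = 31)
  sim_g <- simulate_genotypes(cfg)
  truth0 <- data.frame(gene_id = "gA", baseline_log2 = 6, beta = 0,
                       causal_variant = NA_character_, de = FALSE, length_nt = 1000)
  expr0 <- simulate_expression(sim_g$genotypes, truth0, cfg)
  expect_true(all(expr0$counts == expr0$counts[1, 1]))  # constant rows

  truth1 <- data.frame(gene_id = c("gA", "gB"), baseline_log2 = c(6, 6),
                       beta = c(1, 0), causal_variant = c("var0001", NA),
                       de = FALSE, length_nt = 1000)
  expr1 <- simulate_expression(sim_g$genotypes, truth1, cfg)
  dos <- sim_g$genotypes$dosage[, "var0001"]
  if (any(dos == 0) && any(dos == 2)) {
    fc <- mean(expr1$counts["gA", dos == 2]) / mean(expr1$counts["gA", dos == 0])
    expect_equal(fc, 4, tolerance = 0.01)  # beta_expr = 1 per allele -> 2^2
  }
})

test_that("phenotypes decouple from PSI when the coupling is zero", {
  psi <- stats::setNames(stats::runif(70, 0.2, 0.8), sprintf("s%02d", 1:70))
  cfg0 <- sim_config(pheno_effect = 0, wbc_effect = 0, platelet_effect = 0,
                     seed = 37)
  ph <- simulate_phenotypes(psi, cfg0)
  r <- spearman_assoc(psi, ph$hb)$r
  expect_lt(abs(r), 0.2)
  # monotone limit: strong coupling, vanishing noise
  cfg1 <- sim_config(pheno_effect = 5, noise_sd_pheno = 1e-9, seed = 37)
  ph1 <- simulate_phenotypes(psi, cfg1)
  expect_equal(spearman_assoc(psi, ph1$hb)$r, 1)
})

test_that("qPCR Ct construction encodes planted fold changes", {
  folds <- data.frame(sample = sprintf("s%d", 1:8),
                      group = rep(c("control", "case"), each = 4),
                      fold = rep(c(1, 2), each = 4))
  cfg <- sim_config(noise_sd_ct = 0, seed = 41)
  ct <- simulate_qpcr_cts(folds, cfg)
  fc <- ddct_fold_change(ct, control_group = "control", reference_gene = "REF")
  expect_equal(fc$delta_delta_ct[fc$group == "control"], rep(0, 4))
  expect_equal(fc$fold[fc$group == "control"], rep(1, 4))
  expect_equal(fc$delta_delta_ct[fc$group == "case"], rep(-1, 4))  # fold 2
  expect_equal(fc$fold[fc$group == "case"], rep(2, 4))
})

test_that("dataset files written to disk round-trip through the parsers", {
  dir <- withr::local_tempdir()
  ds <- simulate_dataset(sim_config(n_pop1 = 8, n_pop2 = 8, n_variants = 40,
                                    n_genes = 3, seed = 43), out_dir = dir)
  gm <- parse_genotypes(file.path(dir, "genotypes.vcf"))
  expect_identical(gm$dosage, ds$genotypes$dosage)
  jc <- parse_junction_counts(file.path(dir, "junctions.tsv"))
  expect_identical(jc$counts[rownames(ds$junctions$counts), ],
                   ds$junctions$counts)
  models <- parse_gene_models(file.path(dir, "models.gtf"))
  expect_equal(length(models), length(ds$models))
  expect_true(file.exists(file.path(dir, "truth.json")))
})
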