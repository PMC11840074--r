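# Synthetic-data generator with recorded ground truth.
#
# Emulates the structure of a paired genotype/transcriptome study of two
# diverged populations: Balding-Nichols allele-frequency divergence,
# Hardy-Weinberg genotypes within population, planted additive cis effects on
# logit-PSI and log2 expression, Poisson junction coverage with binomial
# inclusion sampling, phenotypes linearly coupled to splicing, and qPCR Ct
# tables. Every generator is a pure function of (config, seed): identical
# seeds give byte-identical output.

#' Simulation configuration
#'
#' Defaults describe the emulated study: a granulocyte transcriptome cohort
#' of 67 highland-population and 18 control samples, moderate genome-wide
#' divergence (Balding-Nichols F = 0.1), junction coverage of ~100 informative
#' reads per event per sample, and additive cis effects of 0.8 per alternate
#' allele on logit-PSI and 1.0 on log2 expression.
#'
#' @param n_pop1,n_pop2 diploid sample counts per population.
#' @param n_variants number of biallelic SNPs.
#' @param fst_divergence Balding-Nichols divergence parameter F in \[0, 1).
#' @param n_genes number of genes (each with two transcript isoforms).
#' @param n_events number of splicing events carrying junction reads
#'   (defaults to `n_genes`; capped at the number of enumerable events).
#' @param causal_fraction fraction of events/genes given a causal cis
#'   variant.
#' @param beta_psi additive effect per alternate allele on logit(PSI).
#' @param beta_expr additive effect per alternate allele on log2 expression.
#' @param de_fraction,de_log2fc fraction of genes with a planted
#'   population-level expression shift, and its log2 magnitude.
#' @param coverage_mean mean total junction reads per event per sample.
#' @param pheno_effect hemoglobin change (g/dL) per unit PSI.
#' @param wbc_effect,platelet_effect analogous coefficients for white-blood
#'   cell count (10^3/uL) and platelet count (10^3/uL).
#' @param noise_sd_psi sd of Gaussian noise on logit-PSI.
#' @param noise_sd_expr sd of Gaussian noise on log2 expression.
#' @param noise_sd_pheno sd of Gaussian noise on hemoglobin (g/dL); WBC and
#'   platelet noise scale with their coefficients.
#' @param noise_sd_ct sd of Gaussian noise on qPCR Ct values (cycles).
#' @param overdispersion beta-binomial overdispersion of inclusion reads
#'   (0 = plain binomial, the default).
#' @param seed integer RNG seed.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_pop1 = 67, n_pop2 = 18, n_variants = 200,
                       fst_divergence = 0.1, n_genes = 20, n_events = n_genes,
                       causal_fraction = 0.5, beta_psi = 0.8, beta_expr = 1,
                       de_fraction = 0.2, de_log2fc = 1, coverage_mean = 100,
                       pheno_effect = 5, wbc_effect = 4, platelet_effect = 100,
                       noise_sd_psi = 0.3, noise_sd_expr = 0.5,
                       noise_sd_pheno = 1.5, noise_sd_ct = 0.1,
                       overdispersion = 0, seed = 1) {
  cfg <- list(n_pop1 = n_pop1, n_pop2 = n_pop2, n_variants = n_variants,
              fst_divergence = fst_divergence, n_genes = n_genes,
              n_events = n_events, causal_fraction = causal_fraction,
              beta_psi = beta_psi, beta_expr = beta_expr,
              de_fraction = de_fraction, de_log2fc = de_log2fc,
              coverage_mean = coverage_mean, pheno_effect = pheno_effect,
              wbc_effect = wbc_effect, platelet_effect = platelet_effect,
              noise_sd_psi = noise_sd_psi, noise_sd_expr = noise_sd_expr,
              noise_sd_pheno = noise_sd_pheno, noise_sd_ct = noise_sd_ct,
              overdispersion = overdispersion, seed = as.integer(seed))
  with(cfg, stopifnot(n_pop1 >= 1, n_pop2 >= 1, n_variants >= 1, n_genes >= 1,
                      fst_divergence >= 0, fst_divergence < 1,
                      coverage_mean > 0, causal_fraction >= 0,
                      causal_fraction <= 1))
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("sim_config: %d + %d samples, %d variants (F = %g), ",
                     "%d genes, beta_psi = %g, beta_expr = %g, coverage = %g, seed = %d\n"),
              x$n_pop1, x$n_pop2, x$n_variants, x$fst_divergence, x$n_genes,
              x$beta_psi, x$beta_expr, x$coverage_mean, x$seed))
  invisible(x)
}

#' Simulate genotypes under the Balding-Nichols model
#'
#' Ancestral frequency p ~ Uniform(0.05, 0.95) per variant; each population's
#' frequency is drawn from Beta(p(1-F)/F, (1-p)(1-F)/F) (exactly p when
#' F = 0); genotypes are Hardy-Weinberg binomial draws within population.
#'
#' @param config a [sim_config()].
#' @param positions optional variant positions (1-based, chromosome "1");
#'   defaults to a uniform draw over 1..2e6.
#' @param ids optional variant ids aligned with `positions`.
#' @return List: `genotypes` (a [genotype_matrix()]) and `truth` (data.frame
#'   of ancestral and per-population frequencies per variant).
#' @export
simulate_genotypes <- function(config, positions = NULL, ids = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_v <- config$n_variants
  p_anc <- stats::runif(n_v, 0.05, 0.95)
  F <- config$fst_divergence
  draw_pop <- function() {
    if (F == 0) return(p_anc)
    pmin(pmax(stats::rbeta(n_v, p_anc * (1 - F) / F,
                           (1 - p_anc) * (1 - F) / F), 1e-4), 1 - 1e-4)
  }
  p1 <- draw_pop(); p2 <- draw_pop()
  if (is.null(positions)) {
    positions <- sort(sample.int(2e6, n_v))
  }
  if (is.null(ids)) ids <- sprintf("var%04d", seq_len(n_v))
  n1 <- config$n_pop1; n2 <- config$n_pop2
  d1 <- matrix(stats::rbinom(n1 * n_v, 2, rep(p1, each = n1)), nrow = n1)
  d2 <- matrix(stats::rbinom(n2 * n_v, 2, rep(p2, each = n2)), nrow = n2)
  samples <- c(sprintf("p1_s%03d", seq_len(n1)), sprintf("p2_s%03d", seq_len(n2)))
  population <- stats::setNames(rep(c("pop1", "pop2"), c(n1, n2)), samples)
  variants <- data.frame(chrom = "1", pos = as.integer(positions), id = ids,
                         ref = "C", alt = "T", stringsAsFactors = FALSE)
  gm <- genotype_matrix(variants, samples, rbind(d1, d2), population = population)
  truth <- data.frame(variant_id = ids, af_ancestral = p_anc,
                      af_pop1 = p1, af_pop2 = p2, stringsAsFactors = FALSE)
  list(genotypes = gm, truth = truth)
}

#' Simulate two-isoform gene models
#'
#' Each gene gets 4-8 exons on chromosome "1", a full-length transcript with
#' a CDS, and a second transcript skipping one internal exon, so that event
#' enumeration yields one exon-skipping event per gene.
#'
#' @param config a [sim_config()].
#' @return List of [transcript_model()].
#' @export
simulate_gene_models <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 101L)
  models <- list()
  cursor <- 100000L
  for (g in seq_len(config$n_genes)) {
    n_ex <- sample(4:8, 1)
    widths <- sample(80:300, n_ex, replace = TRUE)
    gaps <- sample(500:3000, n_ex - 1, replace = TRUE)
    starts <- integer(n_ex); ends <- integer(n_ex)
    pos <- cursor
    for (i in seq_len(n_ex)) {
      starts[i] <- pos
      ends[i] <- pos + widths[i] - 1L
      if (i < n_ex) pos <- ends[i] + gaps[i] + 1L
    }
    gene_id <- sprintf("gene%03d", g)
    strand <- sample(c("+", "-"), 1)
    exons <- cbind(start = starts, end = ends)
    len <- sum(widths)
    cds <- c(10L, len - 10L)
    skip_k <- sample(2:(n_ex - 1), 1)
    models[[paste0(gene_id, ".t1")]] <-
      transcript_model(gene_id, paste0(gene_id, ".t1"), "1", strand, exons, cds = cds)
    models[[paste0(gene_id, ".t2")]] <-
      transcript_model(gene_id, paste0(gene_id, ".t2"), "1", strand,
                       exons[-skip_k, , drop = FALSE])
    cursor <- ends[n_ex] + 50000L
  }
  models
}

#' Simulate junction read counts for splicing events
#'
#' Per sample and event, the true PSI is
#' `logistic(baseline_logit + beta * dosage + pop_shift * [pop1] + N(0, noise_sd_psi))`,
#' the total informative read count is Poisson(`coverage_mean`), inclusion
#' reads are Binomial(total, PSI) (beta-binomial when `overdispersion` > 0)
#' split uniformly between the two inclusion junctions of an exon-skipping
#' event, and skipping reads are the remainder.
#'
#' @param genotypes a [genotype_matrix()].
#' @param events list of `as_event`.
#' @param truth data.frame with one row per event: `event_id`,
#'   `baseline_logit`, `beta`, `causal_variant` (`NA` if none), `pop_shift`.
#' @param config a [sim_config()].
#' @return List: `junctions` (a [junction_counts()]) and `true_psi`
#'   (events x samples matrix of the latent PSI values).
#' @export
simulate_splicing_counts <- function(genotypes, events, truth, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 202L)
  samples <- genotypes$samples
  n_s <- length(samples)
  is_pop1 <- if (is.null(genotypes$population)) rep(FALSE, n_s) else
    unname(genotypes$population[samples] == "pop1")
  key_rows <- list(); counts <- list()
  true_psi <- matrix(NA_real_, nrow = length(events), ncol = n_s,
                     dimnames = list(vapply(events, function(e) e$event_id, ""),
                                     samples))
  for (k in seq_along(events)) {
    e <- events[[k]]
    tr <- truth[truth$event_id == e$event_id, ]
    if (nrow(tr) != 1L) stop(sprintf("no truth row for event %s", e$event_id))
    logit <- rep(tr$baseline_logit, n_s)
    if (!is.na(tr$causal_variant) && tr$beta != 0) {
      dos <- genotypes$dosage[, tr$causal_variant]
      dos[is.na(dos)] <- 0
      logit <- logit + tr$beta * dos
    }
    if (tr$pop_shift != 0) logit <- logit + tr$pop_shift * is_pop1
    if (config$noise_sd_psi > 0) {
      logit <- logit + stats::rnorm(n_s, 0, config$noise_sd_psi)
    }
    psi <- stats::plogis(logit)
    true_psi[k, ] <- psi
    total <- stats::rpois(n_s, config$coverage_mean)
    psi_draw <- psi
    if (config$overdispersion > 0) {
      rho <- config$overdispersion
      psi_draw <- stats::rbeta(n_s, psi * (1 - rho) / rho,
                               (1 - psi) * (1 - rho) / rho)
    }
    incl <- stats::rbinom(n_s, total, psi_draw)
    skip <- total - incl
    inc_keys <- e$inclusion_junctions
    if (length(inc_keys) == 2L) {
      first <- stats::rbinom(n_s, incl, 0.5)
      inc_counts <- rbind(first, incl - first)
    } else {
      inc_counts <- matrix(incl, nrow = 1)
    }
    skip_counts <- matrix(0L, nrow = length(e$skipping_junctions), ncol = n_s)
    skip_counts[1, ] <- skip
    for (j in seq_along(inc_keys)) {
      key_rows[[length(key_rows) + 1L]] <- c(e$chrom, inc_keys[j], e$strand)
      counts[[length(counts) + 1L]] <- inc_counts[j, ]
    }
    for (j in seq_along(e$skipping_junctions)) {
      key_rows[[length(key_rows) + 1L]] <- c(e$chrom, e$skipping_junctions[j], e$strand)
      counts[[length(counts) + 1L]] <- skip_counts[j, ]
    }
  }
  keys <- vapply(key_rows, `[`, "", 2)
  cmat <- do.call(rbind, counts)
  # events may share junctions (e.g. the same flanking intron); sum per key
  agg <- rowsum(cmat, keys)
  keys_u <- rownames(agg)
  coord <- regmatches(keys_u, regexec("^(.+):([0-9]+)-([0-9]+):([+-])", keys_u))
  jdf <- data.frame(
    chrom = vapply(coord, `[`, "", 2),
    intron_start = as.integer(vapply(coord, `[`, "", 3)),
    intron_end = as.integer(vapply(coord, `[`, "", 4)),
    strand = vapply(coord, `[`, "", 5),
    key = keys_u, stringsAsFactors = FALSE)
  colnames(agg) <- samples
  list(junctions = junction_counts(jdf, agg), true_psi = true_psi)
}

#' Simulate a gene expression matrix
#'
#' log2 expression = baseline + beta * dosage (causal variant) +
#' de_log2fc * \[pop1 and DE gene\] + N(0, noise_sd_expr); exported both as
#' rounded counts and TPM.
#'
#' @param genotypes a [genotype_matrix()].
#' @param truth data.frame with one row per gene: `gene_id`,
#'   `baseline_log2`, `beta`, `causal_variant` (`NA` if none), `de`
#'   (logical), `length_nt`.
#' @param config a [sim_config()].
#' @return An `expression_matrix` (see [tpm_normalize()]).
#' @export
simulate_expression <- function(genotypes, truth, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 303L)
  samples <- genotypes$samples
  n_s <- length(samples)
  is_pop1 <- if (is.null(genotypes$population)) rep(FALSE, n_s) else
    unname(genotypes$population[samples] == "pop1")
  counts <- matrix(0, nrow = nrow(truth), ncol = n_s,
                   dimnames = list(truth$gene_id, samples))
  for (g in seq_len(nrow(truth))) {
    lg <- rep(truth$baseline_log2[g], n_s)
    if (!is.na(truth$causal_variant[g]) && truth$beta[g] != 0) {
      dos <- genotypes$dosage[, truth$causal_variant[g]]
      dos[is.na(dos)] <- 0
      lg <- lg + truth$beta[g] * dos
    }
    if (truth$de[g]) lg <- lg + config$de_log2fc * is_pop1
    if (config$noise_sd_expr > 0) lg <- lg + stats::rnorm(n_s, 0, config$noise_sd_expr)
    counts[g, ] <- round(2^lg)
  }
  tpm_normalize(counts, truth$length_nt)
}

#' Simulate phenotypes coupled to splicing
#'
#' Hemoglobin, white-blood-cell count and platelet count are each linear in
#' the supplied per-sample PSI with Gaussian noise; the causal structure is
#' mediation through splicing, not genotype.
#'
#' @param true_psi named per-sample PSI vector of the focal splicing event.
#' @param config a [sim_config()].
#' @param population optional named population vector (carried through).
#' @param altitude altitude in meters assigned to every sample (default
#'   3650, a highland sampling site).
#' @return data.frame: sample, population, altitude, hb, wbc, platelets.
#' @export
simulate_phenotypes <- function(true_psi, config, population = NULL,
                                altitude = 3650) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 404L)
  n <- length(true_psi)
  samples <- names(true_psi)
  hb <- 14 + config$pheno_effect * true_psi + stats::rnorm(n, 0, config$noise_sd_pheno)
  wbc <- 6 + config$wbc_effect * true_psi +
    stats::rnorm(n, 0, config$noise_sd_pheno)
  plt <- 250 + config$platelet_effect * true_psi +
    stats::rnorm(n, 0, 20 * config$noise_sd_pheno)
  data.frame(sample = samples,
             population = if (is.null(population)) NA_character_ else
               unname(population[samples]),
             altitude = altitude, hb = unname(hb), wbc = unname(wbc),
             platelets = unname(plt), stringsAsFactors = FALSE, row.names = NULL)
}

#' Simulate qPCR Ct tables
#'
#' Reference-gene Ct ~ N(20, noise_sd_ct); target Ct = reference Ct +
#' control delta-Ct offset - log2(planted fold) + N(0, noise_sd_ct), so that
#' the 2^-ddCt method recovers the planted fold changes.
#'
#' @param fold_changes data.frame: `sample`, `group`, `fold` (planted fold
#'   change relative to the control-group expectation; control samples have
#'   fold 1).
#' @param config a [sim_config()].
#' @param target_gene,reference_gene gene labels in the output table.
#' @param dct_control baseline delta-Ct of the control group (cycles).
#' @return data.frame in [ddct_fold_change()] input format: sample, gene,
#'   ct, group.
#' @export
simulate_qpcr_cts <- function(fold_changes, config, target_gene = "TARGET",
                              reference_gene = "REF", dct_control = 2) {
  stopifnot(inherits(config, "sim_config"),
            all(c("sample", "group", "fold") %in% names(fold_changes)))
  set.seed(config$seed + 505L)
  n <- nrow(fold_changes)
  ref_ct <- stats::rnorm(n, 20, config$noise_sd_ct)
  tgt_ct <- ref_ct + dct_control - log2(fold_changes$fold) +
    stats::rnorm(n, 0, config$noise_sd_ct)
  rbind(
    data.frame(sample = fold_changes$sample, gene = reference_gene, ct = ref_ct,
               group = fold_changes$group, stringsAsFactors = FALSE),
    data.frame(sample = fold_changes$sample, gene = target_gene, ct = tgt_ct,
               group = fold_changes$group, stringsAsFactors = FALSE))
}

#' Deterministic synthetic genome sequence provider
#'
#' Returns a `function(chrom, start, end)` producing an arbitrary but
#' deterministic A/C/G/T sequence for any interval (a positional hash; no
#' genome is stored). Used to exercise sequence-dependent stages on synthetic
#' data.
#'
#' @param seed integer; different seeds give different genomes.
#' @return A sequence-provider closure.
#' @export
make_sequence_provider <- function(seed = 1) {
  bases <- c("A", "C", "G", "T")
  offset <- as.integer(seed) * 7919
  function(chrom, start, end) {
    i <- seq(start, end) + offset
    h <- (1103515245 * (i %% 65536) + 12345 * (i %/% 65536) + i) %% 104729
    paste(bases[(h %% 4) + 1], collapse = "")
  }
}

#' Simulate a complete study dataset
#'
#' Orchestrates the generators into one coherent dataset: gene models ->
#' splicing events -> cis windows -> variant placement (causal variants
#' inside their feature's window) -> genotypes -> junction counts ->
#' expression -> phenotypes -> qPCR, with the full ground truth recorded.
#'
#' @param config a [sim_config()].
#' @param out_dir optional directory; when given, writes `genotypes.vcf`,
#'   `models.gtf`, `junctions.tsv`, `expression_tpm.tsv`, `samples.tsv` and
#'   `truth.json`.
#' @return List of class `sim_dataset`: genotypes, models, events, junctions,
#'   expression, samples (phenotype table), qpcr, truth.
#' @export
simulate_dataset <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  models <- simulate_gene_models(config)
  events <- enumerate_events(models)
  n_events <- min(config$n_events, length(events))
  events <- events[seq_len(n_events)]
  swin <- define_splice_windows(events)
  pwin <- define_promoter_windows(models)

  set.seed(config$seed + 606L)
  n_causal_s <- ceiling(config$causal_fraction * n_events)
  causal_events <- if (n_causal_s > 0) seq_len(n_causal_s) else integer(0)
  gene_ids <- unique(vapply(models, function(m) m$gene_id, ""))
  n_causal_e <- ceiling(config$causal_fraction * length(gene_ids))
  causal_genes <- if (n_causal_e > 0) gene_ids[seq_len(n_causal_e)] else character(0)

  pos <- integer(0); tag <- character(0)
  for (k in causal_events) {
    pos <- c(pos, sample(swin$start[k]:swin$end[k], 1))
    tag <- c(tag, paste0("sqtl:", swin$feature_id[k]))
  }
  for (g in causal_genes) {
    w <- pwin[pwin$feature_id == g, ][1, ]
    pos <- c(pos, sample(w$start:w$end, 1))
    tag <- c(tag, paste0("eqtl:", g))
  }
  n_bg <- max(0L, config$n_variants - length(pos))
  span <- max(vapply(models, function(m) max(m$exons[, "end"]), 0)) + 100000L
  bg <- sample.int(span, n_bg)
  pos <- c(pos, bg); tag <- c(tag, rep("background", n_bg))
  while (anyDuplicated(pos)) pos[duplicated(pos)] <- pos[duplicated(pos)] + 1L
  ids <- sprintf("var%04d", seq_along(pos))

  cfg_g <- config
  cfg_g$n_variants <- length(pos)
  sim_g <- simulate_genotypes(cfg_g, positions = pos, ids = ids)
  gm <- sim_g$genotypes

  set.seed(config$seed + 707L)
  ev_truth <- data.frame(
    event_id = vapply(events, function(e) e$event_id, ""),
    baseline_logit = stats::runif(n_events, -1, 1),
    beta = 0, causal_variant = NA_character_, pop_shift = 0,
    stringsAsFactors = FALSE)
  for (k in causal_events) {
    ev_truth$beta[k] <- config$beta_psi
    ev_truth$causal_variant[k] <- ids[match(paste0("sqtl:", ev_truth$event_id[k]), tag)]
  }
  sim_s <- simulate_splicing_counts(gm, events, ev_truth, config)

  gene_truth <- data.frame(
    gene_id = gene_ids,
    baseline_log2 = stats::runif(length(gene_ids), 4, 10),
    beta = 0, causal_variant = NA_character_,
    de = seq_along(gene_ids) <= ceiling(config$de_fraction * length(gene_ids)),
    length_nt = vapply(gene_ids, function(g) {
      models[[paste0(g, ".t1")]]$length
    }, 0),
    stringsAsFactors = FALSE)
  for (g in causal_genes) {
    i <- match(g, gene_truth$gene_id)
    gene_truth$beta[i] <- config$beta_expr
    gene_truth$causal_variant[i] <- ids[match(paste0("eqtl:", g), tag)]
  }
  expr <- simulate_expression(gm, gene_truth, config)

  focal <- if (n_causal_s > 0) 1L else 1L
  samples_tab <- simulate_phenotypes(sim_s$true_psi[focal, ], config,
                                     population = gm$population)

  qpcr_folds <- data.frame(
    sample = gm$samples,
    group = ifelse(gm$population == "pop2", "control", "case"),
    fold = ifelse(gm$population == "pop2", 1, 2),
    stringsAsFactors = FALSE)
  qpcr <- simulate_qpcr_cts(qpcr_folds, config)

  truth <- structure(list(af = sim_g$truth, events = ev_truth,
                          genes = gene_truth, true_psi = sim_s$true_psi,
                          focal_event = ev_truth$event_id[focal],
                          qpcr_folds = qpcr_folds,
                          pheno_coefs = c(hb = config$pheno_effect,
                                          wbc = config$wbc_effect,
                                          platelets = config$platelet_effect)),
                     class = "sim_truth")

  out <- structure(list(genotypes = gm, models = models, events = events,
                        junctions = sim_s$junctions, expression = expr,
                        samples = samples_tab, qpcr = qpcr, truth = truth),
                   class = "sim_dataset")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_genotypes(gm, file.path(out_dir, "genotypes.vcf"))
    write_gene_models(models, file.path(out_dir, "models.gtf"))
    write_junction_counts(sim_s$junctions, file.path(out_dir, "junctions.tsv"))
    tpm_df <- data.frame(gene_id = rownames(expr$tpm),
                         length_nt = expr$lengths_nt, expr$tpm,
                         check.names = FALSE)
    utils::write.table(tpm_df, file.path(out_dir, "expression_tpm.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(samples_tab, file.path(out_dir, "samples.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    tr <- truth; class(tr) <- NULL
    tr$true_psi <- NULL   # large; regenerate via the seed instead
    jsonlite::write_json(tr, file.path(out_dir, "truth.json"),
                         dataframe = "columns", auto_unbox = TRUE, digits = NA)
  }
  out
}
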