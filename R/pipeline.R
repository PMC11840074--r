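# End-to-end orchestration: simulate (or load) -> PSI -> differential
# expression/splicing -> cis-QTL with permutations -> population
# differentiation and selection statistics -> qPCR/phenotype validation.
# Every stage writes its table to disk, each output carries a JSON provenance
# block, and a rerun with the same configuration is byte-identical.

#' Pipeline configuration
#'
#' Thresholds default to the study's stated values: DEG FDR 0.05 and fold
#' change 1.5; differential-splicing FDR 0.05 and |delta PSI| 0.1; QTL alpha
#' 0.05 with 1000 permutations; adapted-variant FDR 0.05 and |delta MAF|
#' 0.3; NMD distance 55 nt; minimum 10 informative reads per PSI value.
#'
#' @param sim a [sim_config()] describing the synthetic dataset to analyse.
#' @param out_dir output directory for stage tables and the manifest.
#' @param deg_fdr,deg_fc,dsg_fdr,dpsi,qtl_alpha,n_perm,adapted_fdr,adapted_dmaf,nmd_nt,psi_min_reads
#'   analysis thresholds (see description).
#' @param seed integer seed controlling permutation schedules (the synthetic
#'   data uses `sim$seed`).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), out_dir = tempfile("splicepop_run_"),
                            deg_fdr = 0.05, deg_fc = 1.5, dsg_fdr = 0.05,
                            dpsi = 0.1, qtl_alpha = 0.05, n_perm = 1000,
                            adapted_fdr = 0.05, adapted_dmaf = 0.3, nmd_nt = 55,
                            psi_min_reads = 10, seed = 1) {
  cfg <- list(sim = sim, out_dir = out_dir, deg_fdr = deg_fdr, deg_fc = deg_fc,
              dsg_fdr = dsg_fdr, dpsi = dpsi, qtl_alpha = qtl_alpha,
              n_perm = n_perm, adapted_fdr = adapted_fdr,
              adapted_dmaf = adapted_dmaf, nmd_nt = nmd_nt,
              psi_min_reads = psi_min_reads, seed = as.integer(seed))
  stopifnot(deg_fdr > 0, deg_fc > 0, dsg_fdr > 0, dpsi > 0, qtl_alpha > 0,
            n_perm >= 1, adapted_fdr > 0, adapted_dmaf > 0, nmd_nt > 0,
            psi_min_reads > 0)
  structure(cfg, class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Top-level keys are [pipeline_config()] arguments; the optional `sim` block
#' holds [sim_config()] arguments.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
pipeline_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- do.call(sim_config, if (is.null(y$sim)) list() else y$sim)
  y$sim <- NULL
  do.call(pipeline_config, c(list(sim = sim), y))
}

.stage_log <- function(stage, msg) {
  message(sprintf("[%s] %s: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), stage, msg))
}

.config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL   # hash the analysis settings, not the output location
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(deparse(cfg), collapse = "\n"), tmp)
  unname(tools::md5sum(tmp))
}

.write_stage <- function(df, schema, path, provenance) {
  write_results_table(df, schema, path)
  jsonlite::write_json(provenance, paste0(path, ".provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  path
}

#' Run the full pipeline
#'
#' Executes all stages in dependency order on a synthetic dataset generated
#' from `config$sim`, writing one TSV per stage (plus a JSON provenance block
#' per output and a final manifest with MD5 hashes). The final adapted-sQTL
#' table is the intersection of (1) events significantly differentially
#' spliced between the populations, (2) variant-event sQTL associations with
#' empirical p below `qtl_alpha`, and (3) variants called adapted against the
#' second population's allele counts used as the reference.
#'
#' @param config a [pipeline_config()].
#' @return Manifest (named list of stage -> list(path, md5)), invisibly
#'   written to `manifest.json` in `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  prov <- list(config_hash = .config_hash(config), seed = config$seed,
               package_version = as.character(utils::packageVersion("splicepop")))
  outputs <- list()
  stage_out <- function(stage, df, schema, file) {
    path <- file.path(config$out_dir, file)
    .write_stage(df, schema, path, c(list(stage = stage), prov))
    outputs[[stage]] <<- path
    .stage_log(stage, sprintf("%d rows -> %s", nrow(df), file))
  }

  .stage_log("simulate", "generating synthetic dataset")
  ds <- simulate_dataset(config$sim, out_dir = file.path(config$out_dir, "input"))
  gm <- ds$genotypes
  groups <- gm$population

  ## PSI
  psi <- compute_psi(ds$events, ds$junctions, min_reads = config$psi_min_reads)
  psi_df <- data.frame(event_id = rownames(psi), as.data.frame(unclass(psi)),
                       check.names = FALSE)
  stage_out("psi", psi_df,
            list(columns = names(psi_df), sort_key = "event_id"), "psi.tsv")

  ## differential expression
  de <- diff_expression(ds$expression, groups, fdr = config$deg_fdr,
                        fc = config$deg_fc)
  stage_out("diffexp", de, list(columns = names(de), sort_key = "gene_id"),
            "diffexp.tsv")

  ## differential splicing
  dsg <- diff_splicing(psi, groups, fdr = config$dsg_fdr, dpsi = config$dpsi)
  stage_out("diffsplice", dsg, list(columns = names(dsg), sort_key = "event_id"),
            "diffsplice.tsv")

  ## consequence annotation (exon-skipping events on the inclusion isoform)
  seqp <- make_sequence_provider(config$sim$seed)
  cons <- do.call(rbind, lapply(ds$events, function(e) {
    if (e$type != "ES") return(NULL)
    tx <- ds$models[[paste0(e$gene_id, ".t1")]]
    cq <- annotate_consequence(e, tx, seqp, nmd_nt = config$nmd_nt)
    data.frame(event_id = cq$event_id, frame_status = cq$frame_status,
               ptc_position = cq$ptc_position,
               ptc_to_last_junction = cq$ptc_to_last_junction,
               nmd_predicted = cq$nmd_predicted, stringsAsFactors = FALSE)
  }))
  stage_out("consequence", cons,
            list(columns = names(cons), sort_key = "event_id"), "consequence.tsv")

  ## sQTL mapping with permutations
  swin <- define_splice_windows(ds$events)
  sqtl <- map_cis_qtl(gm, psi, swin)
  sqtl <- empirical_pvalues(gm, psi, sqtl, n_perm = config$n_perm,
                            seed = config$seed)
  stage_out("sqtl", sqtl,
            list(columns = names(sqtl), sort_key = c("feature_id", "variant_id")),
            "sqtl.tsv")

  ## eQTL mapping with permutations
  pwin <- define_promoter_windows(ds$models)
  pwin <- pwin[, setdiff(names(pwin), "transcript_id")]
  eqtl <- map_cis_qtl(gm, ds$expression$tpm, pwin)
  eqtl <- empirical_pvalues(gm, ds$expression$tpm, eqtl, n_perm = config$n_perm,
                            seed = config$seed)
  stage_out("eqtl", eqtl,
            list(columns = names(eqtl), sort_key = c("feature_id", "variant_id")),
            "eqtl.tsv")

  ## population differentiation: pop1 vs pop2-as-reference
  af <- allele_frequencies(gm)
  stage_out("allele_freq", af,
            list(columns = names(af), sort_key = c("variant_id", "population")),
            "allele_frequencies.tsv")
  pop1 <- af[af$population == "pop1", c("variant_id", "alt_count", "total")]
  pop2 <- af[af$population == "pop2", c("variant_id", "alt_count", "total")]
  adapted <- adapted_variant_test(pop1, pop2, fdr = config$adapted_fdr,
                                  dmaf = config$adapted_dmaf)
  stage_out("adapted", adapted,
            list(columns = names(adapted), sort_key = "variant_id"),
            "adapted_variants.tsv")

  ## selection scan: per-variant Fst between the two populations
  m <- merge(pop1, pop2, by = "variant_id", suffixes = c("_1", "_2"))
  fst <- hudson_fst(m$alt_count_1 / m$total_1, m$total_1 / 2,
                    m$alt_count_2 / m$total_2, m$total_2 / 2)
  scan <- data.frame(variant_id = m$variant_id, fst = fst$fst,
                     stringsAsFactors = FALSE)
  stage_out("scan", scan, list(columns = names(scan), sort_key = "variant_id"),
            "fst_scan.tsv")

  ## qPCR fold changes + phenotype associations
  fc <- ddct_fold_change(ds$qpcr, control_group = "control",
                         reference_gene = "REF")
  stage_out("qpcr", fc,
            list(columns = names(fc), sort_key = c("gene", "sample")),
            "qpcr_fold_changes.tsv")
  focal_psi <- psi[ds$truth$focal_event, ds$samples$sample]
  assoc_rows <- do.call(rbind, lapply(c("hb", "wbc", "platelets"), function(ph) {
    a <- spearman_assoc(focal_psi, ds$samples[[ph]])
    data.frame(pair = paste0("psi_vs_", ph), method = "spearman",
               statistic = a$r, p = a$p, n = a$n, stringsAsFactors = FALSE)
  }))
  mw <- group_difference_test(fc$fold[fc$gene == "TARGET"],
                              fc$group[fc$gene == "TARGET"], "mann_whitney")
  assoc_rows <- rbind(assoc_rows,
                      data.frame(pair = "qpcr_fold_case_vs_control",
                                 method = "mann_whitney", statistic = mw$statistic,
                                 p = mw$p, n = mw$n1 + mw$n2,
                                 stringsAsFactors = FALSE))
  stage_out("assoc", assoc_rows,
            list(columns = names(assoc_rows), sort_key = "pair"), "assoc.tsv")

  ## final intersection: adapted sQTLs
  sig_events <- dsg$event_id[dsg$significant]
  sig_sqtl <- sqtl[!is.na(sqtl$p_empirical) & sqtl$p_empirical < config$qtl_alpha, ]
  adapted_ids <- adapted$variant_id[adapted$adapted]
  final <- sig_sqtl[sig_sqtl$feature_id %in% sig_events &
                    sig_sqtl$variant_id %in% adapted_ids, ]
  stage_out("adapted_sqtl", final,
            list(columns = names(final), sort_key = c("feature_id", "variant_id")),
            "adapted_sqtl.tsv")

  manifest <- lapply(outputs, function(p) {
    list(path = basename(p), md5 = unname(tools::md5sum(p)))
  })
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  .stage_log("done", sprintf("%d stage outputs in %s", length(outputs),
                             config$out_dir))
  invisible(manifest)
}
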