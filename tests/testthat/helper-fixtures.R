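# Small in-code fixtures shared across test files.

vcf_fixture <- function() {
  paste(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", "s3", sep = "\t"),
    paste("1", "100", "rs1", "C", "T", ".", "PASS", ".", "GT", "0/0", "0/1", "1/1", sep = "\t"),
    paste("1", "200", "rs2", "A", "G", ".", "PASS", ".", "GT", "./.", "0/1", "0/0", sep = "\t"),
    paste("1", "300", "rs3", "G", "A", ".", "PASS", ".", "GT", "1/1", "1/1", "0/1", sep = "\t"),
    paste("2", "150", "rs4", "T", "C", ".", "PASS", ".", "GT", "0/1", "0/0", "0/0", sep = "\t"),
    paste("2", "250", "rs5", "C", "G", ".", "PASS", ".", "GT", "0/0", "0/0", "1/1", sep = "\t"),
    sep = "\n")
}

# two-transcript gene: t1 has three exons, t2 skips the middle one
gtf_fixture <- function() {
  attr1 <- 'gene_id "g1"; transcript_id "g1.t1";'
  attr2 <- 'gene_id "g1"; transcript_id "g1.t2";'
  paste(
    paste("1", "test", "exon", "1000", "1199", ".", "+", ".", attr1, sep = "\t"),
    paste("1", "test", "exon", "1500", "1619", ".", "+", ".", attr1, sep = "\t"),
    paste("1", "test", "exon", "2000", "2299", ".", "+", ".", attr1, sep = "\t"),
    paste("1", "test", "CDS", "1100", "1199", ".", "+", "0", attr1, sep = "\t"),
    paste("1", "test", "CDS", "1500", "1619", ".", "+", "0", attr1, sep = "\t"),
    paste("1", "test", "CDS", "2000", "2149", ".", "+", "0", attr1, sep = "\t"),
    paste("1", "test", "exon", "1000", "1199", ".", "+", ".", attr2, sep = "\t"),
    paste("1", "test", "exon", "2000", "2299", ".", "+", ".", attr2, sep = "\t"),
    sep = "\n")
}

junction_tsv_fixture <- function() {
  paste(
    paste("chrom", "intron_start", "intron_end", "strand", "sA", "sB", "sC", sep = "\t"),
    paste("1", "1200", "1499", "+", "10", "0", "7", sep = "\t"),
    paste("1", "1620", "1999", "+", "3", "25", "0", sep = "\t"),
    sep = "\n")
}

# deterministic random genome string (for sequence-provider tests)
random_genome <- function(len, seed = 42) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

provider_from_string <- function(genome) {
  function(chrom, start, end) substr(genome, start, end)
}

# minimal hand-built exon-skipping event for PSI tests
make_es_event <- function(chrom = "1", strand = "+",
                          up_intron = c(1200L, 1499L),
                          dn_intron = c(1620L, 1999L)) {
  up_intron <- unname(up_intron)
  dn_intron <- unname(dn_intron)
  structure(list(
    event_id = "ES|test",
    type = "ES", gene_id = "g1", chrom = chrom, strand = strand,
    target = c(exon_start = up_intron[2] + 1L, exon_end = dn_intron[1] - 1L),
    inclusion_junctions = c(junction_key(chrom, up_intron[1], up_intron[2], strand),
                            junction_key(chrom, dn_intron[1], dn_intron[2], strand)),
    skipping_junctions = junction_key(chrom, up_intron[1], dn_intron[2], strand),
    window_start = up_intron[1], window_end = dn_intron[2]),
    class = "as_event")
}

# ES event for skipping exon k of a transcript (k internal)
es_event_for <- function(tx, k) {
  ex <- tx$exons
  up <- c(ex[k - 1, "end"] + 1L, ex[k, "start"] - 1L)
  dn <- c(ex[k, "end"] + 1L, ex[k + 1, "start"] - 1L)
  make_es_event(chrom = tx$chrom, strand = tx$strand,
                up_intron = up, dn_intron = dn)
}

jc_from_counts <- function(event, incl1, incl2, skip, samples = NULL) {
  n <- length(incl1)
  if (is.null(samples)) samples <- sprintf("s%d", seq_len(n))
  keys <- c(event$inclusion_junctions, event$skipping_junctions)
  coords <- do.call(rbind, regmatches(keys, regexec("^(.+):([0-9]+)-([0-9]+):([+-])", keys)))
  jdf <- data.frame(chrom = coords[, 2], intron_start = as.integer(coords[, 3]),
                    intron_end = as.integer(coords[, 4]), strand = coords[, 5],
                    key = keys, stringsAsFactors = FALSE)
  m <- rbind(incl1, incl2, skip)
  colnames(m) <- samples
  junction_counts(jdf, m)
}
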