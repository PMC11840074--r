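#' Construct a transcript model
#'
#' @param gene_id,transcript_id identifiers.
#' @param chrom chromosome name.
#' @param strand "+" or "-".
#' @param exons two-column matrix or data.frame of exon (start, end),
#'   1-based inclusive genomic coordinates. Stored sorted ascending by start
#'   regardless of strand.
#' @param cds optional length-2 vector: (start, end) of the coding region in
#'   transcript coordinates (1 = first transcribed base).
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(gene_id, transcript_id, chrom, strand, exons, cds = NULL) {
  stopifnot(strand %in% c("+", "-"))
  exons <- as.matrix(exons)
  dimnames(exons) <- list(NULL, c("start", "end"))
  exons <- exons[order(exons[, "start"]), , drop = FALSE]
  if (any(exons[, "start"] > exons[, "end"])) {
    stop(sprintf("transcript %s: exon with start > end", transcript_id))
  }
  if (nrow(exons) > 1L && any(exons[-1L, "start"] <= exons[-nrow(exons), "end"])) {
    stop(sprintf("transcript %s: overlapping exons", transcript_id))
  }
  len <- sum(exons[, "end"] - exons[, "start"] + 1L)
  if (!is.null(cds)) {
    cds <- as.integer(cds)
    if (length(cds) != 2L || cds[1] < 1L || cds[2] > len || cds[1] > cds[2]) {
      stop(sprintf("transcript %s: CDS span outside spliced transcript", transcript_id))
    }
  }
  structure(list(gene_id = gene_id, transcript_id = transcript_id, chrom = chrom,
                 strand = strand, exons = exons, cds = cds, length = len),
            class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("transcript_model %s (gene %s) %s:%s %d exons, %d nt%s\n",
              x$transcript_id, x$gene_id, x$chrom, x$strand, nrow(x$exons), x$length,
              if (is.null(x$cds)) "" else sprintf(", CDS %d-%d", x$cds[1], x$cds[2])))
  invisible(x)
}

# Genomic position -> transcript coordinate (1 = first transcribed base).
# NA for intronic positions.
.genomic_to_tx <- function(pos, exons, strand) {
  widths <- exons[, "end"] - exons[, "start"] + 1L
  total <- sum(widths)
  before <- c(0L, cumsum(widths))[seq_len(nrow(exons))]
  out <- rep(NA_integer_, length(pos))
  for (i in seq_len(nrow(exons))) {
    inside <- pos >= exons[i, "start"] & pos <= exons[i, "end"]
    out[inside] <- before[i] + (pos[inside] - exons[i, "start"]) + 1L
  }
  if (strand == "-") out <- total - out + 1L
  out
}

# Transcript interval -> list of genomic (start, end) intervals, ascending.
.tx_to_genomic <- function(tx_start, tx_end, exons, strand) {
  widths <- exons[, "end"] - exons[, "start"] + 1L
  total <- sum(widths)
  if (strand == "-") {
    tmp <- total - tx_end + 1L
    tx_end <- total - tx_start + 1L
    tx_start <- tmp
  }
  before <- c(0L, cumsum(widths))
  res <- NULL
  for (i in seq_len(nrow(exons))) {
    a <- max(tx_start, before[i] + 1L)
    b <- min(tx_end, before[i + 1L])
    if (a <= b) {
      g1 <- exons[i, "start"] + (a - before[i]) - 1L
      g2 <- exons[i, "start"] + (b - before[i]) - 1L
      res <- rbind(res, c(g1, g2))
    }
  }
  dimnames(res) <- list(NULL, c("start", "end"))
  res
}

#' Parse gene models from GTF
#'
#' Reads GTF 2.2 `exon` (and optional `CDS`) features via
#' \code{rtracklayer::import} and groups them into [transcript_model()]
#' objects. Exons are stored sorted ascending by genomic start regardless of
#' strand; CDS features are converted to transcript coordinates respecting
#' strand.
#'
#' @param input GTF text or a path to a GTF file.
#' @return Named list of `transcript_model` (names = transcript ids).
#' @export
parse_gene_models <- function(input) {
  lines <- .input_lines(input)
  path <- tempfile(fileext = ".gtf")
  on.exit(unlink(path))
  writeLines(lines, path)
  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  keep <- md$type %in% c("exon", "CDS")
  gr <- gr[keep]; md <- md[keep, , drop = FALSE]
  if (length(gr) == 0L) stop("no exon features in GTF input")
  tid <- as.character(md$transcript_id)
  if (any(is.na(tid) | !nzchar(tid))) {
    stop("GTF feature without transcript_id attribute")
  }
  gid <- as.character(md$gene_id)
  type <- as.character(md$type)
  chrom <- as.character(GenomicRanges::seqnames(gr))
  strand <- as.character(GenomicRanges::strand(gr))
  start <- GenomicRanges::start(gr)
  end <- GenomicRanges::end(gr)

  out <- list()
  for (t in unique(tid)) {
    sel <- tid == t
    ex <- which(sel & type == "exon")
    if (length(ex) == 0L) stop(sprintf("transcript %s has CDS but no exon features", t))
    exons <- cbind(start = start[ex], end = end[ex])
    str <- strand[ex[1]]
    if (!str %in% c("+", "-")) stop(sprintf("transcript %s: missing strand", t))
    cds <- NULL
    cd <- which(sel & type == "CDS")
    if (length(cd) > 0L) {
      exons_sorted <- exons[order(exons[, "start"]), , drop = FALSE]
      tx <- .genomic_to_tx(c(start[cd], end[cd]), exons_sorted, str)
      if (anyNA(tx)) stop(sprintf("transcript %s: CDS outside exons", t))
      cds <- c(min(tx), max(tx))
    }
    out[[t]] <- transcript_model(gid[ex[1]], t, chrom[ex[1]], str, exons, cds = cds)
  }
  out
}

#' Write gene models as GTF
#'
#' @param models list of [transcript_model()].
#' @param path output file path.
#' @param source source field for the GTF lines.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(models, path, source = "splicepop") {
  lines <- character(0)
  for (m in models) {
    attr_str <- sprintf('gene_id "%s"; transcript_id "%s";', m$gene_id, m$transcript_id)
    for (i in seq_len(nrow(m$exons))) {
      lines <- c(lines, paste(m$chrom, source, "exon", m$exons[i, "start"],
                              m$exons[i, "end"], ".", m$strand, ".", attr_str,
                              sep = "\t"))
    }
    if (!is.null(m$cds)) {
      gi <- .tx_to_genomic(m$cds[1], m$cds[2], m$exons, m$strand)
      for (i in seq_len(nrow(gi))) {
        lines <- c(lines, paste(m$chrom, source, "CDS", gi[i, "start"],
                                gi[i, "end"], ".", m$strand, "0", attr_str,
                                sep = "\t"))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}
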