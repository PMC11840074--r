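# Coding consequence of exon-skipping isoforms: reading frame, premature
# termination codon (PTC), and the 55-nt nonsense-mediated decay (NMD) rule.
#
# The NMD prediction follows the exon-junction-complex model: a transcript is
# predicted to be degraded when its first in-frame stop codon lies strictly
# more than `nmd_nt` nucleotides upstream of the final exon-exon junction of
# the (altered) transcript.

.STOP_CODONS <- c("TAA", "TAG", "TGA")

.revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# Spliced transcript sequence (5'->3') from exon chain + genomic sequence
# provider. `provider(chrom, start, end)` must return the + strand genomic
# sequence of the interval, 1-based inclusive.
.spliced_seq <- function(chrom, strand, exons, provider) {
  pieces <- vapply(seq_len(nrow(exons)), function(i) {
    provider(chrom, exons[i, "start"], exons[i, "end"])
  }, "")
  if (strand == "-") {
    pieces <- rev(vapply(pieces, .revcomp, ""))
  }
  paste(pieces, collapse = "")
}

# First stop codon scanning in frame from `from` (1-based) in `seq`;
# returns the transcript coordinate of the stop codon's first base, or NA.
.first_stop <- function(seq, from) {
  n <- nchar(seq)
  pos <- seq(from, n - 2L, by = 3L)
  if (length(pos) == 0L) return(NA_integer_)
  codons <- substring(seq, pos, pos + 2L)
  hit <- which(codons %in% .STOP_CODONS)
  if (length(hit) == 0L) return(NA_integer_) else pos[hit[1L]]
}

#' Annotate the coding consequence of an exon-skipping event
#'
#' Removes the skipped exon from the transcript (for MXE: swaps the
#' transcript's exclusive exon for the alternative one), re-threads the open
#' reading frame from the original CDS start, and reports the reading-frame
#' status, the first stop codon of the altered ORF, its distance to the final
#' exon-exon junction of the altered transcript, and the resulting NMD
#' prediction.
#'
#' @param event an `as_event` of type ES or MXE. Other types yield a
#'   `frame_status = "non_coding"` result (unsupported, not an error).
#' @param transcript the [transcript_model()] carrying the event's inclusion
#'   form; must have a CDS.
#' @param seq_provider `function(chrom, start, end)` returning the + strand
#'   genomic sequence (A/C/G/T) of the interval.
#' @param nmd_nt NMD distance threshold in nucleotides (default 55; the rule
#'   is strict: distance must exceed it).
#' @return List of class `isoform_consequence`: `event_id`, `frame_status`
#'   (`in_frame`, `frameshift` or `non_coding`), `ptc_position` (transcript
#'   coordinate of the first base of the first stop in the altered ORF, or
#'   `NA`), `ptc_to_last_junction` (nt from the stop codon's last base to the
#'   final exon-exon junction; negative if the stop is in the last exon), and
#'   `nmd_predicted`.
#' @export
annotate_consequence <- function(event, transcript, seq_provider, nmd_nt = 55) {
  if (is.null(transcript$cds)) {
    stop("transcript has no CDS; mark the event non_coding instead")
  }
  res <- function(frame, ptc = NA_integer_, dist = NA_real_, nmd = FALSE) {
    structure(list(event_id = event$event_id, frame_status = frame,
                   ptc_position = ptc, ptc_to_last_junction = dist,
                   nmd_predicted = nmd), class = "isoform_consequence")
  }
  if (!event$type %in% c("ES", "MXE")) return(res("non_coding"))

  exons <- transcript$exons
  if (event$type == "ES") {
    k <- which(exons[, "start"] == event$target["exon_start"] &
               exons[, "end"] == event$target["exon_end"])
    if (length(k) != 1L) stop("skipped exon not found on transcript")
    alt_exons <- exons[-k, , drop = FALSE]
    removed <- unname(exons[k, ])
  } else {
    k1 <- which(exons[, "start"] == event$target["exon1_start"] &
                exons[, "end"] == event$target["exon1_end"])
    k2 <- which(exons[, "start"] == event$target["exon2_start"] &
                exons[, "end"] == event$target["exon2_end"])
    own <- if (length(k1) == 1L) k1 else k2
    if (length(own) != 1L) stop("neither exclusive exon found on transcript")
    other <- if (length(k1) == 1L) {
      c(event$target["exon2_start"], event$target["exon2_end"])
    } else c(event$target["exon1_start"], event$target["exon1_end"])
    removed <- unname(exons[own, ])
    alt_exons <- rbind(exons[-own, , drop = FALSE],
                       cbind(start = other[1], end = other[2]))
    alt_exons <- alt_exons[order(alt_exons[, "start"]), , drop = FALSE]
  }

  # transcript coordinates of the removed exon on the original transcript
  tx_rm <- sort(.genomic_to_tx(removed, exons, transcript$strand))
  cds <- transcript$cds
  ov <- c(max(tx_rm[1], cds[1]), min(tx_rm[2], cds[2]))
  if (ov[1] > ov[2]) return(res("non_coding"))   # event entirely in UTR

  removed_cds_len <- ov[2] - ov[1] + 1L
  if (event$type == "MXE") {
    # net length change decides the frame for an exon swap
    removed_cds_len <- removed_cds_len - (other[2] - other[1] + 1L)
  }
  frame <- if (removed_cds_len %% 3 == 0) "in_frame" else "frameshift"

  alt_seq <- .spliced_seq(transcript$chrom, transcript$strand, alt_exons, seq_provider)
  # CDS start in altered coordinates: shifted left by transcript sequence
  # removed upstream of it (the skipped exon must not contain the start)
  removed_upstream <- max(0L, min(tx_rm[2], cds[1] - 1L) - tx_rm[1] + 1L)
  if (tx_rm[1] <= cds[1] && tx_rm[2] >= cds[1]) {
    return(res("non_coding"))  # start codon lost with the exon
  }
  cds_start_alt <- cds[1] - removed_upstream
  ptc <- .first_stop(alt_seq, cds_start_alt)
  if (is.na(ptc)) return(res(frame))

  widths <- alt_exons[, "end"] - alt_exons[, "start"] + 1L
  last_junction <- sum(widths) - widths[if (transcript$strand == "+")
    length(widths) else 1L]
  dist <- last_junction - (ptc + 2L)
  res(frame, ptc = ptc, dist = dist, nmd = dist > nmd_nt)
}

#' @export
print.isoform_consequence <- function(x, ...) {
  cat(sprintf("isoform_consequence %s: %s, PTC %s, %s nt to last junction, NMD %s\n",
              x$event_id, x$frame_status,
              ifelse(is.na(x$ptc_position), "none", x$ptc_position),
              ifelse(is.na(x$ptc_to_last_junction), "-", x$ptc_to_last_junction),
              x$nmd_predicted))
  invisible(x)
}
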