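# Alternative-splicing event enumeration from transcript models.
#
# Events are found by pairwise comparison of exon chains within each gene and
# classified into the five canonical classes: exon skipping (ES), alternative
# 5'/3' splice site (A5SS/A3SS), intron retention (IR) and mutually exclusive
# exons (MXE). Inclusion/skipping evidence is expressed as sets of junction
# keys; for IR the inclusion evidence (reads over the exon-intron boundaries)
# is not observable in a junction-only matrix and is represented by
# pseudo-junction keys with :IR5/:IR3 suffixes that callers must supply as
# extra rows in the junction count table.

.introns_of <- function(exons) {
  n <- nrow(exons)
  if (n < 2L) return(cbind(start = integer(0), end = integer(0)))
  cbind(start = exons[-n, "end"] + 1L, end = exons[-1L, "start"] - 1L)
}

.has_intron <- function(introns, s, e) {
  any(introns[, "start"] == s & introns[, "end"] == e)
}

.has_exon <- function(exons, s, e) {
  any(exons[, "start"] == s & exons[, "end"] == e)
}

.new_event <- function(type, gene_id, chrom, strand, target, incl, skip,
                       window_start, window_end) {
  id <- sprintf("%s|%s|%s:%s:%s", type, gene_id, chrom,
                paste(target, collapse = "-"), strand)
  structure(list(event_id = id, type = type, gene_id = gene_id, chrom = chrom,
                 strand = strand, target = target,
                 inclusion_junctions = sort(unique(incl)),
                 skipping_junctions = sort(unique(skip)),
                 window_start = window_start, window_end = window_end),
            class = "as_event")
}

#' @export
print.as_event <- function(x, ...) {
  cat(sprintf("as_event %s [%s] incl={%s} skip={%s}\n", x$event_id, x$type,
              paste(x$inclusion_junctions, collapse = ","),
              paste(x$skipping_junctions, collapse = ",")))
  invisible(x)
}

# Classify the events implied by one ordered transcript pair (A = inclusion
# of more sequence where the classes make that distinction).
.pair_events <- function(A, B) {
  exA <- A$exons; exB <- B$exons
  inA <- .introns_of(exA); inB <- .introns_of(exB)
  chrom <- A$chrom; strand <- A$strand; gene <- A$gene_id
  jk <- function(s, e) junction_key(chrom, s, e, strand)
  events <- list()

  ## Exon skipping: internal exon k of A absent from B, B splices straight
  ## from A's upstream flank to A's downstream flank.
  nA <- nrow(exA)
  if (nA >= 3L) {
    for (k in 2:(nA - 1L)) {
      up <- inA[k - 1L, ]; dn <- inA[k, ]
      if (.has_intron(inB, up["start"], dn["end"])) {
        ev <- .new_event("ES", gene, chrom, strand,
                         target = c(exon_start = unname(exA[k, "start"]),
                                    exon_end = unname(exA[k, "end"])),
                         incl = c(jk(up["start"], up["end"]), jk(dn["start"], dn["end"])),
                         skip = jk(up["start"], dn["end"]),
                         window_start = unname(up["start"]),
                         window_end = unname(dn["end"]))
        events <- c(events, list(ev))
      }
    }
  }

  ## Mutually exclusive exons: internal exon a of A and b of B, neither in
  ## the other transcript, non-overlapping, sharing both flanking junction
  ## outer boundaries.
  if (nA >= 3L && nrow(exB) >= 3L) {
    for (ka in 2:(nA - 1L)) {
      a <- exA[ka, ]
      if (.has_exon(exB, a["start"], a["end"])) next
      upA <- inA[ka - 1L, ]; dnA <- inA[ka, ]
      for (kb in 2:(nrow(exB) - 1L)) {
        b <- exB[kb, ]
        if (.has_exon(exA, b["start"], b["end"])) next
        if (a["start"] <= b["end"] && b["start"] <= a["end"]) next  # overlap
        upB <- inB[kb - 1L, ]; dnB <- inB[kb, ]
        if (upA["start"] == upB["start"] && dnA["end"] == dnB["end"]) {
          first <- if (a["start"] < b["start"]) {
            list(e = a, up = upA, dn = dnA)
          } else list(e = b, up = upB, dn = dnB)
          second <- if (a["start"] < b["start"]) {
            list(e = b, up = upB, dn = dnB)
          } else list(e = a, up = upA, dn = dnA)
          ev <- .new_event("MXE", gene, chrom, strand,
                           target = c(exon1_start = unname(first$e["start"]),
                                      exon1_end = unname(first$e["end"]),
                                      exon2_start = unname(second$e["start"]),
                                      exon2_end = unname(second$e["end"])),
                           incl = c(jk(first$up["start"], first$up["end"]),
                                    jk(first$dn["start"], first$dn["end"])),
                           skip = c(jk(second$up["start"], second$up["end"]),
                                    jk(second$dn["start"], second$dn["end"])),
                           window_start = unname(upA["start"]),
                           window_end = unname(dnA["end"]))
          events <- c(events, list(ev))
        }
      }
    }
  }

  ## Alternative 5'/3' splice sites: introns of A and B sharing exactly one
  ## boundary, where the differing stretch is exonic in the short-intron
  ## transcript (contiguous with its flanking exon). Strand decides which
  ## side is the 5' splice site.
  if (nrow(inA) > 0L && nrow(inB) > 0L) {
    for (ia in seq_len(nrow(inA))) {
      a <- inA[ia, ]
      for (ib in seq_len(nrow(inB))) {
        b <- inB[ib, ]
        share_start <- a["start"] == b["start"] && a["end"] != b["end"]
        share_end <- a["end"] == b["end"] && a["start"] != b["start"]
        if (!share_start && !share_end) next
        # short intron = more exon included
        if (share_start) {
          short <- if (a["end"] < b["end"]) a else b
          long <- if (a["end"] < b["end"]) b else a
          short_tx_ex <- if (a["end"] < b["end"]) exA else exB
          # differing region must sit inside the exon downstream of the short intron
          reg <- c(short["end"] + 1L, long["end"])
          dn_ex <- short_tx_ex[short_tx_ex[, "start"] == short["end"] + 1L, , drop = FALSE]
          if (nrow(dn_ex) != 1L || dn_ex[1, "end"] < reg[2]) next
          type <- if (strand == "+") "A3SS" else "A5SS"
          target <- c(long_start = unname(long["start"]), long_end = unname(long["end"]),
                      short_start = unname(short["start"]), short_end = unname(short["end"]))
        } else {
          short <- if (a["start"] > b["start"]) a else b
          long <- if (a["start"] > b["start"]) b else a
          short_tx_ex <- if (a["start"] > b["start"]) exA else exB
          reg <- c(long["start"], short["start"] - 1L)
          up_ex <- short_tx_ex[short_tx_ex[, "end"] == short["start"] - 1L, , drop = FALSE]
          if (nrow(up_ex) != 1L || up_ex[1, "start"] > reg[1]) next
          type <- if (strand == "+") "A5SS" else "A3SS"
          target <- c(long_start = unname(long["start"]), long_end = unname(long["end"]),
                      short_start = unname(short["start"]), short_end = unname(short["end"]))
        }
        ev <- .new_event(type, gene, chrom, strand, target,
                         incl = jk(short["start"], short["end"]),
                         skip = jk(long["start"], long["end"]),
                         window_start = unname(long["start"]),
                         window_end = unname(long["end"]))
        events <- c(events, list(ev))
      }
    }
  }

  ## Intron retention: intron of A fully contained (with its flanking bases)
  ## in a single exon of B, and B has no intron overlapping it.
  if (nrow(inA) > 0L) {
    for (ia in seq_len(nrow(inA))) {
      a <- inA[ia, ]
      contained <- any(exB[, "start"] <= a["start"] - 1L & exB[, "end"] >= a["end"] + 1L)
      overlapped <- nrow(inB) > 0L &&
        any(inB[, "start"] <= a["end"] & inB[, "end"] >= a["start"])
      if (contained && !overlapped) {
        key <- jk(a["start"], a["end"])
        ev <- .new_event("IR", gene, chrom, strand,
                         target = c(intron_start = unname(a["start"]),
                                    intron_end = unname(a["end"])),
                         incl = paste0(key, c(":IR5", ":IR3")),
                         skip = key,
                         window_start = unname(a["start"]),
                         window_end = unname(a["end"]))
        events <- c(events, list(ev))
      }
    }
  }

  events
}

#' Enumerate alternative-splicing events
#'
#' Compares all transcript pairs within each gene and returns the deduplicated
#' set of ES, A5SS, A3SS, IR and MXE events, each with its inclusion and
#' skipping junction key sets and its sQTL search window (the event target
#' plus flanking introns; see [define_splice_windows()]).
#'
#' @param transcripts list of [transcript_model()].
#' @return List of `as_event` objects. Genes with a single transcript
#'   contribute nothing.
#' @export
enumerate_events <- function(transcripts) {
  genes <- split(transcripts, vapply(transcripts, function(m) m$gene_id, ""))
  out <- list()
  for (tx in genes) {
    if (length(tx) < 2L) next
    for (i in seq_along(tx)) {
      for (j in seq_along(tx)) {
        if (i == j) next
        out <- c(out, .pair_events(tx[[i]], tx[[j]]))
      }
    }
  }
  if (length(out) == 0L) return(list())
  ids <- vapply(out, function(e) e$event_id, "")
  out[!duplicated(ids)]
}

#' Tabulate events
#'
#' @param events list of `as_event`.
#' @return data.frame with one row per event (coordinates, type, junction
#'   keys joined by ";").
#' @export
events_table <- function(events) {
  if (length(events) == 0L) {
    return(data.frame(event_id = character(0), type = character(0),
                      gene_id = character(0), chrom = character(0),
                      strand = character(0), target = character(0),
                      inclusion_junctions = character(0),
                      skipping_junctions = character(0),
                      window_start = integer(0), window_end = integer(0)))
  }
  do.call(rbind, lapply(events, function(e) {
    data.frame(event_id = e$event_id, type = e$type, gene_id = e$gene_id,
               chrom = e$chrom, strand = e$strand,
               target = paste(sprintf("%s=%d", names(e$target), e$target),
                              collapse = ";"),
               inclusion_junctions = paste(e$inclusion_junctions, collapse = ";"),
               skipping_junctions = paste(e$skipping_junctions, collapse = ";"),
               window_start = e$window_start, window_end = e$window_end,
               stringsAsFactors = FALSE)
  }))
}
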