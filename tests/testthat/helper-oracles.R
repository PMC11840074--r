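# Independent oracles used to cross-check the package implementation.
# These deliberately take different computational routes (per-base masks,
# base-by-base walks, manual codon scans) from the code under test.

## ---- exhaustive coordinate walk: genomic -> transcript coordinate --------
# Walks the spliced transcript base by base and returns the transcript
# coordinate of a genomic position (NA if intronic).
oracle_tx_coord <- function(gpos, exons, strand) {
  genomic <- unlist(lapply(seq_len(nrow(exons)), function(i) {
    seq(exons[i, "start"], exons[i, "end"])
  }))
  if (strand == "-") genomic <- rev(genomic)
  match(gpos, genomic)
}

## ---- brute-force splicing event comparator -------------------------------
# Per-base exonic masks over a small coordinate range; events classified by
# direct definition checks on the masks and exon runs.
oracle_events <- function(transcripts) {
  introns_of <- function(ex) {
    n <- nrow(ex)
    if (n < 2) return(cbind(start = integer(0), end = integer(0)))
    cbind(start = ex[-n, "end"] + 1L, end = ex[-1L, "start"] - 1L)
  }
  lim <- max(vapply(transcripts, function(m) max(m$exons[, "end"]), 0)) + 2L
  masks <- lapply(transcripts, function(m) {
    z <- logical(lim)
    for (i in seq_len(nrow(m$exons))) z[m$exons[i, "start"]:m$exons[i, "end"]] <- TRUE
    z
  })
  all_exonic <- function(mask, a, b) a <= b && all(mask[a:b])

  sigs <- character(0)
  genes <- split(seq_along(transcripts),
                 vapply(transcripts, function(m) m$gene_id, ""))
  for (idx in genes) {
    if (length(idx) < 2) next
    for (ia in idx) for (ib in idx) {
      if (ia == ib) next
      A <- transcripts[[ia]]; B <- transcripts[[ib]]
      exA <- A$exons; exB <- B$exons
      inA <- introns_of(exA); inB <- introns_of(exB)
      mB <- masks[[ib]]
      str <- A$strand

      # ES: two introns of A bracketing a single exon of A, fused in B
      if (nrow(inA) >= 2) {
        for (i1 in seq_len(nrow(inA) - 1L)) {
          i2 <- i1 + 1L
          between_is_exon <- any(exA[, "start"] == inA[i1, "end"] + 1L &
                                 exA[, "end"] == inA[i2, "start"] - 1L)
          fused_in_B <- nrow(inB) > 0 &&
            any(inB[, "start"] == inA[i1, "start"] & inB[, "end"] == inA[i2, "end"])
          if (between_is_exon && fused_in_B) {
            sigs <- c(sigs, sprintf("ES:%d-%d", inA[i1, "end"] + 1L,
                                    inA[i2, "start"] - 1L))
          }
        }
      }

      # A5SS/A3SS: introns sharing one boundary; the differing stretch is
      # entirely exonic in the short-intron transcript
      for (i in seq_len(nrow(inA))) for (j in seq_len(nrow(inB))) {
        a <- inA[i, ]; b <- inB[j, ]
        if (a["start"] == b["start"] && a["end"] != b["end"]) {
          short_end <- min(a["end"], b["end"]); long_end <- max(a["end"], b["end"])
          short_mask <- if (a["end"] < b["end"]) masks[[ia]] else mB
          if (all_exonic(short_mask, short_end + 1L, long_end)) {
            type <- if (str == "+") "A3SS" else "A5SS"
            sigs <- c(sigs, sprintf("%s:%d-%d/%d-%d", type,
                                    a["start"], long_end, a["start"], short_end))
          }
        }
        if (a["end"] == b["end"] && a["start"] != b["start"]) {
          short_start <- max(a["start"], b["start"]); long_start <- min(a["start"], b["start"])
          short_mask <- if (a["start"] > b["start"]) masks[[ia]] else mB
          if (all_exonic(short_mask, long_start, short_start - 1L)) {
            type <- if (str == "+") "A5SS" else "A3SS"
            sigs <- c(sigs, sprintf("%s:%d-%d/%d-%d", type,
                                    long_start, a["end"], short_start, a["end"]))
          }
        }
      }

      # IR: intron of A whose whole span (plus one flanking base each side)
      # is exonic in B
      for (i in seq_len(nrow(inA))) {
        a <- inA[i, ]
        if (all_exonic(mB, a["start"] - 1L, a["end"] + 1L)) {
          sigs <- c(sigs, sprintf("IR:%d-%d", a["start"], a["end"]))
        }
      }

      # MXE: internal exons a (A only) and b (B only), non-overlapping,
      # sharing outer flanking-intron boundaries
      if (nrow(exA) >= 3 && nrow(exB) >= 3) {
        for (ka in 2:(nrow(exA) - 1L)) for (kb in 2:(nrow(exB) - 1L)) {
          ea <- exA[ka, ]; eb <- exB[kb, ]
          if (any(exB[, "start"] == ea["start"] & exB[, "end"] == ea["end"])) next
          if (any(exA[, "start"] == eb["start"] & exA[, "end"] == eb["end"])) next
          if (ea["start"] <= eb["end"] && eb["start"] <= ea["end"]) next
          if (inA[ka - 1L, "start"] == inB[kb - 1L, "start"] &&
              inA[ka, "end"] == inB[kb, "end"]) {
            pair <- sort(c(sprintf("%d-%d", ea["start"], ea["end"]),
                           sprintf("%d-%d", eb["start"], eb["end"])))
            sigs <- c(sigs, sprintf("MXE:%s/%s", pair[1], pair[2]))
          }
        }
      }
    }
  }
  sort(unique(sigs))
}

# Signature view of the package enumerator, comparable to oracle_events()
event_signatures <- function(events) {
  sigs <- vapply(events, function(e) {
    t <- e$target
    switch(e$type,
      ES = sprintf("ES:%d-%d", t["exon_start"], t["exon_end"]),
      IR = sprintf("IR:%d-%d", t["intron_start"], t["intron_end"]),
      A5SS = sprintf("A5SS:%d-%d/%d-%d", t["long_start"], t["long_end"],
                     t["short_start"], t["short_end"]),
      A3SS = sprintf("A3SS:%d-%d/%d-%d", t["long_start"], t["long_end"],
                     t["short_start"], t["short_end"]),
      MXE = {
        pair <- sort(c(sprintf("%d-%d", t["exon1_start"], t["exon1_end"]),
                       sprintf("%d-%d", t["exon2_start"], t["exon2_end"])))
        sprintf("MXE:%s/%s", pair[1], pair[2])
      })
  }, "")
  sort(unique(sigs))
}

## ---- random gene models for the enumeration property test ---------------
# A master exon chain plus transcripts derived by dropping an exon, shifting
# a splice site, merging exons across an intron, or swapping in an
# alternative exon; all five event classes arise.
random_gene_models <- function(gene_id, n_tx = 3) {
  n_ex <- sample(3:6, 1)
  widths <- sample(20:60, n_ex, replace = TRUE)
  gaps <- sample(40:120, n_ex - 1, replace = TRUE)
  starts <- cumsum(c(10L, (widths + c(gaps, 0))[-n_ex]))
  ends <- starts + widths - 1L
  master <- cbind(start = starts, end = ends)
  strand <- sample(c("+", "-"), 1)
  pick <- function(v) v[sample.int(length(v), 1)]   # safe even for length 1
  mutate <- function(ex) {
    op <- sample(c("drop", "shift", "merge", "swap", "none"), 1)
    n <- nrow(ex)
    if (op == "drop" && n >= 3) {
      k <- pick(2:(n - 1))
      return(ex[-k, , drop = FALSE])
    }
    if (op == "shift" && n >= 2) {
      k <- pick(seq_len(n - 1))  # shift donor/acceptor of intron k
      gap <- ex[k + 1, "start"] - ex[k, "end"] - 1L
      if (gap > 12) {
        d <- sample(4:(gap - 4), 1)
        if (stats::runif(1) < 0.5) ex[k, "end"] <- ex[k, "end"] + d
        else ex[k + 1, "start"] <- ex[k + 1, "start"] - d
      }
      return(ex)
    }
    if (op == "merge" && n >= 2) {
      k <- pick(seq_len(n - 1))
      ex[k, "end"] <- ex[k + 1, "end"]
      return(ex[-(k + 1), , drop = FALSE])
    }
    if (op == "swap" && n >= 3) {
      k <- pick(2:(n - 1))
      gap_up <- ex[k, "start"] - ex[k - 1, "end"] - 1L
      gap_dn <- ex[k + 1, "start"] - ex[k, "end"] - 1L
      side <- if (gap_up >= gap_dn) "up" else "dn"
      gap <- max(gap_up, gap_dn)
      if (gap > 16) {
        w <- sample(6:(gap - 10), 1)
        s <- if (side == "up") ex[k - 1, "end"] + 5L else ex[k, "end"] + 5L
        ex[k, ] <- c(s, s + w - 1L)
        ex <- ex[order(ex[, "start"]), , drop = FALSE]
      }
      return(ex)
    }
    ex
  }
  tx <- list(transcript_model(gene_id, paste0(gene_id, ".t1"), "1", strand, master))
  for (t in 2:n_tx) {
    tx[[t]] <- transcript_model(gene_id, sprintf("%s.t%d", gene_id, t), "1",
                                strand, mutate(master))
  }
  tx
}

## ---- manual-translation oracle for isoform consequences ------------------
# Builds the altered transcript base by base, scans codons with substr in an
# explicit loop, and applies the NMD rule directly.
oracle_consequence <- function(exons, strand, drop_exon, cds_start_tx,
                               genome, nmd_nt = 55) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  base_at <- function(g) substr(genome, g, g)
  chain <- exons[-drop_exon, , drop = FALSE]
  gpos <- unlist(lapply(seq_len(nrow(chain)), function(i) {
    seq(chain[i, "start"], chain[i, "end"])
  }))
  if (strand == "-") {
    seqc <- rev(vapply(gpos, function(g) unname(comp[base_at(g)]), ""))
  } else {
    seqc <- vapply(gpos, function(g) base_at(g), "")
  }
  # removed transcript length upstream of CDS start (original coordinates)
  all_gpos <- unlist(lapply(seq_len(nrow(exons)), function(i) {
    seq(exons[i, "start"], exons[i, "end"])
  }))
  if (strand == "-") all_gpos <- rev(all_gpos)
  rm_gpos <- seq(exons[drop_exon, "start"], exons[drop_exon, "end"])
  rm_tx <- match(rm_gpos, all_gpos)
  removed_upstream <- sum(rm_tx < cds_start_tx)
  start_alt <- cds_start_tx - removed_upstream
  s <- paste(seqc, collapse = "")
  ptc <- NA_integer_
  i <- start_alt
  while (i + 2 <= nchar(s)) {
    if (substr(s, i, i + 2) %in% c("TAA", "TAG", "TGA")) { ptc <- i; break }
    i <- i + 3
  }
  widths <- chain[, "end"] - chain[, "start"] + 1L
  last_w <- if (strand == "+") widths[length(widths)] else widths[1]
  last_junction <- sum(widths) - last_w
  dist <- if (is.na(ptc)) NA_real_ else last_junction - (ptc + 2)
  list(ptc = ptc, dist = dist,
       nmd = !is.na(ptc) && dist > nmd_nt,
       frame = if ((exons[drop_exon, "end"] - exons[drop_exon, "start"] + 1L) %% 3 == 0)
         "in_frame" else "frameshift")
}
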