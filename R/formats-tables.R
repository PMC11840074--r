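#' Junction key
#'
#' Junctions are keyed by the intron's first and last base (1-based
#' inclusive) plus strand: `"chrom:start-end:strand"`. Subtract 1 from the
#' start for BED conversion.
#'
#' @param chrom,start,end,strand junction (intron) coordinates.
#' @return Character vector of keys.
#' @export
junction_key <- function(chrom, start, end, strand) {
  sprintf("%s:%d-%d:%s", chrom, as.integer(start), as.integer(end), strand)
}

#' Construct a junction count matrix
#'
#' @param junctions data.frame with columns `chrom`, `intron_start`,
#'   `intron_end`, `strand` (1-based inclusive first/last intronic base).
#'   An optional `key` column overrides the default [junction_key()]; this is
#'   how intron-retention pseudo-junction rows (key suffix `:IR5` / `:IR3`)
#'   enter the matrix.
#' @param counts integer matrix, junctions x samples, non-negative.
#' @return An object of class `junction_counts`.
#' @export
junction_counts <- function(junctions, counts) {
  stopifnot(is.data.frame(junctions),
            all(c("chrom", "intron_start", "intron_end", "strand") %in% names(junctions)))
  counts <- as.matrix(counts)
  if (nrow(counts) != nrow(junctions)) stop("counts rows must match junctions")
  if (anyNA(counts)) stop("missing junction count")
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("junction counts must be non-negative integers")
  }
  if (is.null(junctions$key)) {
    junctions$key <- junction_key(junctions$chrom, junctions$intron_start,
                                  junctions$intron_end, junctions$strand)
  }
  dup <- duplicated(junctions$key)
  if (any(dup)) {
    stop(sprintf("duplicate junction key: %s", junctions$key[which(dup)[1]]))
  }
  rownames(counts) <- junctions$key
  rownames(junctions) <- NULL
  structure(list(junctions = junctions, counts = counts), class = "junction_counts")
}

#' @export
print.junction_counts <- function(x, ...) {
  cat(sprintf("junction_counts: %d junctions x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' Parse a junction count table
#'
#' TSV with columns `chrom`, `intron_start`, `intron_end`, `strand`, then one
#' integer count column per sample. An optional `key` column (before the
#' sample columns) carries pseudo-junction keys.
#'
#' @param input TSV text or path.
#' @return A [junction_counts()] object.
#' @export
parse_junction_counts <- function(input) {
  lines <- .input_lines(input)
  df <- utils::read.delim(text = paste(lines, collapse = "\n"),
                          stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("chrom", "intron_start", "intron_end", "strand")
  if (!all(req %in% names(df))) {
    stop("junction table must have columns chrom, intron_start, intron_end, strand")
  }
  meta_cols <- c(req, intersect("key", names(df)))
  sample_cols <- setdiff(names(df), meta_cols)
  if (length(sample_cols) == 0L) stop("junction table has no sample columns")
  counts <- as.matrix(df[, sample_cols, drop = FALSE])
  if (anyNA(counts)) {
    bad <- which(is.na(counts), arr.ind = TRUE)[1, ]
    stop(sprintf("empty/non-numeric count for junction %s:%d-%d, sample %s",
                 df$chrom[bad[1]], df$intron_start[bad[1]], df$intron_end[bad[1]],
                 sample_cols[bad[2]]))
  }
  junction_counts(df[, meta_cols, drop = FALSE], counts)
}

#' Write a junction count table
#'
#' @param jc a [junction_counts()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_junction_counts <- function(jc, path) {
  stopifnot(inherits(jc, "junction_counts"))
  df <- cbind(jc$junctions[, c("chrom", "intron_start", "intron_end", "strand", "key")],
              as.data.frame(jc$counts, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a results table with a declared schema
#'
#' Deterministic TSV output: rows are sorted by the schema's sort key,
#' floating point columns are rendered at a declared precision, and the
#' column set must match the schema exactly.
#'
#' @param rows data.frame of results.
#' @param schema list with `columns` (character vector, the exact column set
#'   and order), optional `sort_key` (columns to sort by) and `digits`
#'   (significant digits for numeric columns; default 6).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(rows, schema, path) {
  stopifnot(is.list(schema), !is.null(schema$columns))
  if (!setequal(names(rows), schema$columns) && nrow(rows) > 0) {
    stop(sprintf("row columns (%s) do not match schema (%s)",
                 paste(names(rows), collapse = ","),
                 paste(schema$columns, collapse = ",")))
  }
  if (nrow(rows) == 0L) {
    writeLines(paste(schema$columns, collapse = "\t"), path)
    return(invisible(path))
  }
  rows <- rows[, schema$columns, drop = FALSE]
  if (!is.null(schema$sort_key)) {
    rows <- rows[do.call(order, rows[schema$sort_key]), , drop = FALSE]
  }
  digits <- if (is.null(schema$digits)) 6L else schema$digits
  for (cn in names(rows)) {
    if (is.double(rows[[cn]])) {
      rows[[cn]] <- formatC(rows[[cn]], digits = digits, format = "g")
    }
  }
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
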