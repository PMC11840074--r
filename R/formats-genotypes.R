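# Input helper shared by all text-or-path readers: a single string without a
# newline that names an existing file is read from disk, anything else is
# treated as the literal text content.
.input_lines <- function(input) {
  if (is.character(input) && length(input) == 1L && !grepl("\n", input, fixed = TRUE) &&
      file.exists(input)) {
    return(readLines(input, warn = FALSE))
  }
  unlist(strsplit(paste(input, collapse = "\n"), "\n", fixed = TRUE), use.names = FALSE)
}

#' Construct a genotype matrix
#'
#' The central genotype container of the pipeline: a samples x variants
#' dosage matrix (alternate-allele counts 0/1/2, `NA` for missing) with
#' variant metadata and a population label per sample.
#'
#' @param variants data.frame with columns `chrom`, `pos`, `id`, `ref`, `alt`
#'   (one row per biallelic SNP).
#' @param samples character vector of unique sample identifiers.
#' @param dosage numeric matrix, `length(samples)` rows x `nrow(variants)`
#'   columns, entries in `{0, 1, 2, NA}`.
#' @param population named character vector mapping sample -> population label
#'   (optional; may be `NULL`).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(variants, samples, dosage, population = NULL) {
  stopifnot(is.data.frame(variants),
            all(c("chrom", "pos", "id", "ref", "alt") %in% names(variants)))
  if (anyDuplicated(samples)) stop("sample ids must be unique")
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  if (nrow(dosage) != length(samples) || ncol(dosage) != nrow(variants)) {
    stop("dosage dimensions do not match sample and variant counts")
  }
  bad <- !(dosage %in% c(0, 1, 2)) & !is.na(dosage)
  if (any(bad)) stop("dosage values must be 0, 1, 2 or NA")
  if (any(variants$pos < 1)) stop("variant positions must be >= 1")
  if (any(!nzchar(variants$ref)) || any(!nzchar(variants$alt)) ||
      any(variants$ref == variants$alt)) {
    stop("ref and alt alleles must be non-empty and differ")
  }
  ord <- order(variants$chrom, variants$pos)
  variants <- variants[ord, , drop = FALSE]
  rownames(variants) <- NULL
  dosage <- dosage[, ord, drop = FALSE]
  dimnames(dosage) <- list(samples, variants$id)
  if (!is.null(population)) {
    if (is.null(names(population))) names(population) <- samples
    population <- population[samples]
  }
  structure(list(variants = variants, samples = samples,
                 dosage = dosage, population = population),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d variants\n",
              length(x$samples), nrow(x$variants)))
  if (!is.null(x$population)) {
    tab <- table(x$population)
    cat("populations:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Parse genotypes from a VCF
#'
#' Reads a VCF v4.x (text or path) restricted to biallelic SNP records with a
#' GT field, and returns dosages as alternate-allele counts. `./.` (or any
#' genotype containing a missing allele) becomes `NA`. Multi-allelic records,
#' a missing header line, and malformed GT fields are rejected with an error
#' naming the offending line number.
#'
#' @param input VCF text or a path to a VCF file.
#' @param population optional named character vector sample -> population.
#' @return A [genotype_matrix()].
#' @export
parse_genotypes <- function(input, population = NULL) {
  lines <- .input_lines(input)
  hdr_i <- which(startsWith(lines, "#CHROM"))
  if (length(hdr_i) != 1L) stop("missing #CHROM header line in VCF input")
  hdr <- strsplit(lines[hdr_i], "\t", fixed = TRUE)[[1]]
  if (length(hdr) < 10L) stop("VCF header has no sample columns")
  samples <- hdr[-(1:9)]
  rec_i <- which(!startsWith(lines, "#") & nzchar(lines))
  rec_i <- rec_i[rec_i > hdr_i]

  n <- length(rec_i)
  chrom <- character(n); pos <- integer(n); id <- character(n)
  ref <- character(n); alt <- character(n)
  dosage <- matrix(NA_real_, nrow = length(samples), ncol = n)
  for (k in seq_len(n)) {
    ln <- rec_i[k]
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(f) != length(hdr)) {
      stop(sprintf("VCF line %d: %d fields, expected %d", ln, length(f), length(hdr)))
    }
    if (grepl(",", f[5], fixed = TRUE)) {
      stop(sprintf("VCF line %d: multi-allelic record (ALT = %s) rejected", ln, f[5]))
    }
    chrom[k] <- f[1]; pos[k] <- as.integer(f[2]); id[k] <- f[3]
    ref[k] <- f[4]; alt[k] <- f[5]
    fmt <- strsplit(f[9], ":", fixed = TRUE)[[1]]
    gt_i <- match("GT", fmt)
    if (is.na(gt_i)) stop(sprintf("VCF line %d: FORMAT lacks GT", ln))
    gts <- vapply(strsplit(f[-(1:9)], ":", fixed = TRUE), `[`, "", gt_i)
    m <- regmatches(gts, regexec("^([0-9.])[/|]([0-9.])$", gts))
    for (s in seq_along(gts)) {
      if (length(m[[s]]) != 3L) {
        stop(sprintf("VCF line %d, sample %s: malformed GT '%s'", ln, samples[s], gts[s]))
      }
      a <- m[[s]][2:3]
      if (any(a == ".")) next   # missing stays NA
      a <- as.integer(a)
      if (any(a > 1L)) {
        stop(sprintf("VCF line %d, sample %s: allele index > 1 in biallelic record",
                     ln, samples[s]))
      }
      dosage[s, k] <- sum(a)
    }
  }
  variants <- data.frame(chrom = chrom, pos = pos, id = id, ref = ref, alt = alt,
                         stringsAsFactors = FALSE)
  genotype_matrix(variants, samples, dosage, population = population)
}

#' Write a genotype matrix as VCF
#'
#' Minimal VCF v4.2 writer (GT field only). `parse_genotypes()` of the written
#' file reproduces the dosage matrix exactly.
#'
#' @param gm a [genotype_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  gt_of <- function(d) {
    out <- rep("./.", length(d))
    out[!is.na(d) & d == 0] <- "0/0"
    out[!is.na(d) & d == 1] <- "0/1"
    out[!is.na(d) & d == 2] <- "1/1"
    out
  }
  hdr <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", gm$samples), collapse = "\t"))
  v <- gm$variants
  body <- vapply(seq_len(nrow(v)), function(k) {
    paste(c(v$chrom[k], v$pos[k], v$id[k], v$ref[k], v$alt[k], ".", "PASS", ".",
            "GT", gt_of(gm$dosage[, k])), collapse = "\t")
  }, "")
  writeLines(c(hdr, body), path)
  invisible(path)
}
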