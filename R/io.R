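# Plain-text table dialects used throughout the pipeline.
#
# Variant table  : TSV, 1-based positions, columns
#                  sample chrom pos ref alt depth alt_reads qphred vclass
#                  gene consequence pop_freq context5 context3
# Coverage table : BED-like TSV, 0-based half-open, columns
#                  chrom start end depth
# Germline catalog: TSV, columns chrom pos ref alt frequency
# Segment table  : SEG-like TSV, columns
#                  sample chrom start end n_bins smoothed_value state

.VARIANT_COLS <- c("sample", "chrom", "pos", "ref", "alt", "depth",
                   "alt_reads", "qphred", "vclass", "gene", "consequence",
                   "pop_freq", "context5", "context3")

.CONSEQUENCES <- c("synonymous", "missense", "nonsense", "splice",
                   "frameshift", "inframe_indel", "other")

#' Validate a variant table
#'
#' Checks column presence, read-count sanity (`0 <= alt_reads <= depth`),
#' positive 1-based positions, non-negative qualities, and the SNV/indel
#' allele-length contract (`vclass == "SNV"` iff both alleles are single
#' bases).
#'
#' @param variants a variant-table `data.frame`.
#' @return the table, invisibly; errors describe the offending rows.
#' @export
validate_variants <- function(variants) {
  stopifnot(is.data.frame(variants))
  missing_cols <- setdiff(.VARIANT_COLS, names(variants))
  if (length(missing_cols) > 0L) {
    stop("variant table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(variants) == 0L) return(invisible(variants))
  bad <- which(variants$alt_reads < 0 | variants$alt_reads > variants$depth)
  if (length(bad) > 0L) {
    stop("alt_reads outside [0, depth] at rows: ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  if (any(variants$pos < 1L)) stop("positions must be 1-based (>= 1)")
  if (any(variants$qphred < 0)) stop("qphred must be >= 0")
  is_snv <- nchar(variants$ref) == 1L & nchar(variants$alt) == 1L
  bad <- which((variants$vclass == "SNV") != is_snv)
  if (length(bad) > 0L) {
    stop("vclass/allele-length mismatch at rows: ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  invisible(variants)
}

#' Read a variant table
#'
#' @param path TSV file with the variant-table header.
#' @return validated `data.frame`.
#' @export
read_variants <- function(path) {
  x <- utils::read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE,
                         colClasses = c(pop_freq = "numeric"))
  validate_variants(x)
  x
}

#' Write a variant table
#' @param variants variant `data.frame`.
#' @param path output TSV path.
#' @export
write_variants <- function(variants, path) {
  validate_variants(variants)
  utils::write.table(variants, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a binned coverage table (BED-like, 0-based half-open)
#' @param path TSV with columns `chrom start end depth`.
#' @return `data.frame`, bins sorted within chromosome.
#' @export
read_coverage <- function(path) {
  x <- utils::read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "depth")
  if (!all(need %in% names(x))) {
    stop("coverage table needs columns: ", paste(need, collapse = ", "))
  }
  if (nrow(x) > 0L && any(x$end <= x$start)) stop("coverage bins need end > start")
  x[order(x$chrom, x$start), , drop = FALSE]
}

#' Write a binned coverage table
#' @param coverage `data.frame` with `chrom start end depth`.
#' @param path output TSV path.
#' @export
write_coverage <- function(coverage, path) {
  utils::write.table(coverage, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a germline population-frequency catalog
#'
#' Each row records one allele seen in public germline databases together
#' with its population frequency.  Malformed rows (missing fields or
#' non-numeric / out-of-range frequency) raise an error naming the line.
#'
#' @param path TSV with columns `chrom pos ref alt frequency`.
#' @return `data.frame`.
#' @export
read_germline_catalog <- function(path) {
  x <- utils::read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt", "frequency")
  if (!all(need %in% names(x))) {
    stop("germline catalog needs columns: ", paste(need, collapse = ", "))
  }
  freq <- suppressWarnings(as.numeric(x$frequency))
  bad <- which(is.na(freq) | freq < 0 | freq > 1 | is.na(x$pos))
  if (length(bad) > 0L) {
    # +1 for the header so the message points at file lines
    stop("malformed germline catalog rows at lines: ",
         paste(utils::head(bad + 1L, 5L), collapse = ", "))
  }
  x$frequency <- freq
  x
}

#' Write a germline catalog
#' @param catalog `data.frame` with `chrom pos ref alt frequency`.
#' @param path output TSV path.
#' @export
write_germline_catalog <- function(catalog, path) {
  utils::write.table(catalog, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a cancer-gene list (one symbol per line, optional `gene` header)
#' @param path text file of gene symbols.
#' @return character vector of symbols.
#' @export
read_gene_list <- function(path) {
  x <- readLines(path)
  x <- trimws(x)
  x <- x[nzchar(x)]
  x <- setdiff(x, "gene")
  unique(x)
}

#' Read a protein-domain annotation table
#' @param path TSV with columns `gene domain start_aa end_aa`
#'   (1-based inclusive amino-acid coordinates).
#' @return `data.frame`.
#' @export
read_domain_table <- function(path) {
  x <- utils::read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("gene", "domain", "start_aa", "end_aa")
  if (!all(need %in% names(x))) {
    stop("domain table needs columns: ", paste(need, collapse = ", "))
  }
  if (nrow(x) > 0L && any(x$end_aa < x$start_aa)) {
    stop("domain table needs end_aa >= start_aa")
  }
  x
}

#' Write a SEG-like segment table
#' @param segments `data.frame` with `sample chrom start end n_bins
#'   smoothed_value state`.
#' @param path output TSV path.
#' @export
write_segments <- function(segments, path) {
  utils::write.table(segments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
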