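# Reliability filtering of per-sample variant calls and germline-catalog
# exclusion, the two rules that stand in for a matched normal.

#' Quality-control thresholds for variant retention
#'
#' Defaults are the study's stated reliability filters: a variant is kept
#' only if sequenced in at least 10 reads, supported by at least 3 variant
#' reads making up at least 15% of reads at the site, with call quality
#' QPHRED >= 20 for SNVs and >= 30 for indels.  Variants found in public
#' germline catalogs at population frequency >= 1e-5 are excluded as
#' likely germline.
#'
#' @param min_depth minimum total reads at the site.
#' @param min_alt_reads minimum variant-supporting reads.
#' @param min_vaf minimum variant allele fraction (inclusive).
#' @param min_qphred_snv minimum phred quality for SNVs.
#' @param min_qphred_indel minimum phred quality for indels.
#' @param max_pop_freq catalog frequency at or above which a variant is
#'   excluded as germline.
#' @return a `qc_thresholds` list.
#' @export
qc_thresholds <- function(min_depth = 10,
                          min_alt_reads = 3,
                          min_vaf = 0.15,
                          min_qphred_snv = 20,
                          min_qphred_indel = 30,
                          max_pop_freq = 1e-5) {
  t <- list(min_depth = min_depth, min_alt_reads = min_alt_reads,
            min_vaf = min_vaf, min_qphred_snv = min_qphred_snv,
            min_qphred_indel = min_qphred_indel, max_pop_freq = max_pop_freq)
  if (any(unlist(t) < 0)) stop("thresholds must be >= 0")
  if (t$min_vaf <= 0 || t$min_vaf > 1) stop("min_vaf must lie in (0, 1]")
  class(t) <- "qc_thresholds"
  t
}

#' Per-variant reliability filter
#'
#' A variant passes iff `depth >= min_depth`, `alt_reads >= min_alt_reads`,
#' `alt_reads / depth >= min_vaf` (inclusive, evaluated in exact integer
#' arithmetic so e.g. 3/20 passes a 15% threshold), and `qphred` meets the
#' SNV or indel floor according to `vclass`.  Zero-depth sites fail.
#'
#' @param v `data.frame` with columns `depth`, `alt_reads`, `qphred`,
#'   `vclass`.
#' @param thresholds a [qc_thresholds()].
#' @return logical vector, one element per row of `v`.
#' @export
passes_quality <- function(v, thresholds = qc_thresholds()) {
  t <- thresholds
  min_q <- ifelse(v$vclass == "indel", t$min_qphred_indel, t$min_qphred_snv)
  v$depth >= t$min_depth &
    v$alt_reads >= t$min_alt_reads &
    frac_ge(v$alt_reads, v$depth, t$min_vaf) &
    v$qphred >= min_q
}

#' Germline-catalog exclusion
#'
#' Looks each variant up in a population-frequency catalog by exact
#' (chrom, pos, ref, alt) allele identity.  Returns `TRUE` when the
#' variant is retained as putatively somatic: absent from the catalog, or
#' present with frequency strictly below `max_pop_freq`.
#'
#' @param v `data.frame` with columns `chrom`, `pos`, `ref`, `alt`.
#' @param catalog germline catalog `data.frame`
#'   (`chrom pos ref alt frequency`), as from [read_germline_catalog()].
#' @param max_pop_freq exclusion threshold (inclusive), default `1e-5`.
#' @return logical vector (`TRUE` = retain).
#' @export
exclude_germline <- function(v, catalog, max_pop_freq = 1e-5) {
  need <- c("chrom", "pos", "ref", "alt", "frequency")
  if (!all(need %in% names(catalog))) {
    stop("germline catalog needs columns: ", paste(need, collapse = ", "))
  }
  bad <- which(is.na(catalog$frequency) | catalog$frequency < 0 |
                 catalog$frequency > 1)
  if (length(bad) > 0L) {
    stop("malformed germline catalog rows: ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  if (nrow(v) == 0L) return(logical(0))
  key_v <- variant_key(v$chrom, v$pos, v$ref, v$alt)
  key_c <- variant_key(catalog$chrom, catalog$pos, catalog$ref, catalog$alt)
  freq <- catalog$frequency[match(key_v, key_c)]
  is.na(freq) | freq < max_pop_freq
}

#' Quality + germline filtering of one sample's variant table
#'
#' Applies [passes_quality()] first and [exclude_germline()] to the
#' survivors, so the attrition report attributes each removed variant to
#' exactly one rule.
#'
#' @param variants a variant table.
#' @param thresholds a [qc_thresholds()].
#' @param catalog germline catalog `data.frame`.
#' @return list with `variants` (retained rows) and `attrition`
#'   (named integer counts removed by `quality` and `germline`).
#' @export
qc_pipeline <- function(variants, thresholds = qc_thresholds(), catalog) {
  validate_variants(variants)
  ok_q <- passes_quality(variants, thresholds)
  after_q <- variants[ok_q, , drop = FALSE]
  ok_g <- exclude_germline(after_q, catalog, thresholds$max_pop_freq)
  out <- after_q[ok_g, , drop = FALSE]
  rownames(out) <- NULL
  list(variants = out,
       attrition = c(quality = sum(!ok_q), germline = sum(!ok_g)))
}
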