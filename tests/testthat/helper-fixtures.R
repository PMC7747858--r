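# In-code fixture builders shared across test files.

# one or more variant rows with sensible defaults, overridable per field
mk_variants <- function(n = 1, sample = "S1", chrom = "chr1",
                        pos = seq_len(n), ref = "C", alt = "A",
                        depth = 100L, alt_reads = 30L, qphred = 60,
                        vclass = "SNV", gene = "GENE0001",
                        consequence = "missense", pop_freq = NA_real_,
                        context5 = "A", context3 = "G") {
  data.frame(sample = rep_len(sample, n), chrom = rep_len(chrom, n),
             pos = rep_len(pos, n), ref = rep_len(ref, n),
             alt = rep_len(alt, n), depth = rep_len(depth, n),
             alt_reads = rep_len(alt_reads, n), qphred = rep_len(qphred, n),
             vclass = rep_len(vclass, n), gene = rep_len(gene, n),
             consequence = rep_len(consequence, n),
             pop_freq = rep_len(pop_freq, n),
             context5 = rep_len(context5, n),
             context3 = rep_len(context3, n),
             stringsAsFactors = FALSE)
}

mk_catalog <- function(chrom = character(0), pos = integer(0),
                       ref = character(0), alt = character(0),
                       frequency = numeric(0)) {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             frequency = frequency, stringsAsFactors = FALSE)
}

empty_catalog <- function() mk_catalog()

mk_coverage <- function(depth, chrom = "chr1", bin_width = 1000L) {
  n <- length(depth)
  start <- (seq_len(n) - 1L) * bin_width
  data.frame(chrom = rep_len(chrom, n), start = start,
             end = start + bin_width, depth = depth,
             stringsAsFactors = FALSE)
}

# independent brute-force search for the maximizing circular arc,
# written against the definition (direct means over arc and complement),
# lexicographic-first tie-break with strict improvement
brute_max_arc <- function(x, min_width) {
  n <- length(x)
  best <- list(i = -1L, j = -1L, stat = 0)
  s <- stats::sd(x)
  if (n < 2 * min_width || !is.finite(s) || s == 0) return(best)
  for (i in 0:(n - min_width)) {
    for (j in (i + min_width):min(n, i + n - min_width)) {
      arc <- x[(i + 1):j]
      comp <- x[-((i + 1):j)]
      k <- j - i
      stat <- abs(mean(arc) - mean(comp)) /
        (s * sqrt(1 / k + 1 / (n - k)))
      if (stat > best$stat) best <- list(i = i, j = j, stat = stat)
    }
  }
  best
}

# independently coded paired-classification oracle: a literal transcription
# of the two read-count rules, evaluated scalar-wise
oracle_status <- function(primary_alt, primary_depth, met_alt, met_depth,
                          passed_primary_qc) {
  if (passed_primary_qc) {
    shared <- met_depth > 0 && met_alt >= 2 && met_alt / met_depth >= 0.05
    if (shared) "shared" else "primary_specific"
  } else {
    prim_prop <- if (primary_depth == 0) 0 else primary_alt / primary_depth
    ms <- met_depth > 0 && met_alt >= 3 && met_alt / met_depth >= 0.15 &&
      primary_alt <= 1 && prim_prop < 0.05
    if (ms) "met_specific" else "unresolved"
  }
}

# small, fully separable cohort for fast end-to-end tests
small_cohort_config <- function(seed = 1L, n_patients = 3L, ...) {
  cohort_config(n_patients = n_patients, n_truncal = 30, n_primary_private = 5,
                n_met_private = 10, n_germline = 40, seed = seed, ...)
}
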