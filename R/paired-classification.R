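# Three-way classification of each patient's variants: shared between the
# primary tumor and the metastasis (truncal), specific to the primary, or
# acquired in the metastasis.  Both rules are read-count rules evaluated
# on paired evidence at the same genomic site.

.STATUSES <- c("shared", "primary_specific", "met_specific", "unresolved")

#' Classify a primary-tumor variant as shared or primary-specific
#'
#' A putatively somatic variant of the primary tumor is considered also
#' present in the metastasis iff it is supported by at least 2 metastasis
#' reads making up at least 5% of metastasis reads at the site; otherwise
#' it is specific to the primary tumor.  Zero metastasis depth makes the
#' proportion condition unsatisfiable, hence primary-specific.
#'
#' @param pv `data.frame` with columns `met_alt_reads` and `met_depth`.
#' @param min_met_reads,min_met_fraction sharing rule arms (default 2 reads,
#'   5%).
#' @return character vector, `"shared"` or `"primary_specific"`.
#' @export
classify_from_primary <- function(pv, min_met_reads = 2,
                                  min_met_fraction = 0.05) {
  shared <- pv$met_alt_reads >= min_met_reads &
    frac_ge(pv$met_alt_reads, pv$met_depth, min_met_fraction)
  ifelse(shared, "shared", "primary_specific")
}

#' Test whether a metastasis variant is metastasis-specific
#'
#' A variant is specific to the metastasis iff it is seen in at least 3
#' metastasis reads making up at least 15% of reads at that position, and
#' in at most 1 primary-tumor read making up strictly less than 5% of
#' primary reads there.  A site with zero primary depth and zero primary
#' variant reads counts as primary proportion 0 (condition satisfied).
#'
#' @param pv `data.frame` with columns `met_alt_reads`, `met_depth`,
#'   `primary_alt_reads`, `primary_depth`.
#' @param min_met_reads,min_met_fraction metastasis evidence arms
#'   (default 3 reads, 15%).
#' @param max_primary_reads,max_primary_fraction primary absence arms
#'   (default at most 1 read, strictly below 5%).
#' @return logical vector.
#' @export
classify_met_specific <- function(pv, min_met_reads = 3,
                                  min_met_fraction = 0.15,
                                  max_primary_reads = 1,
                                  max_primary_fraction = 0.05) {
  pv$met_alt_reads >= min_met_reads &
    frac_ge(pv$met_alt_reads, pv$met_depth, min_met_fraction) &
    pv$primary_alt_reads <= max_primary_reads &
    frac_lt(pv$primary_alt_reads, pv$primary_depth, max_primary_fraction)
}

# evidence (depth, alt_reads) at arbitrary keys, preferring the QC'd table
# and falling back to a per-site lookup table, then to zero coverage
evidence_at <- function(keys, qc_table, sites_table) {
  depth <- rep(0L, length(keys))
  alt <- rep(0L, length(keys))
  filled <- rep(FALSE, length(keys))
  fill <- function(tab) {
    if (is.null(tab) || nrow(tab) == 0L) return(invisible())
    k <- variant_key(tab$chrom, tab$pos, tab$ref, tab$alt)
    m <- match(keys, k)
    hit <- !is.na(m) & !filled
    depth[hit] <<- tab$depth[m[hit]]
    alt[hit] <<- tab$alt_reads[m[hit]]
    filled[hit] <<- TRUE
    invisible()
  }
  fill(qc_table)
  fill(sites_table)
  list(depth = depth, alt_reads = alt)
}

#' Classify all of a patient's QC-passing variants
#'
#' Aligns the primary and metastasis QC'd variant sets on exact
#' (chrom, pos, ref, alt) identity.  Variants passing QC in the primary
#' are classified by [classify_from_primary()] (this also covers variants
#' passing QC in both compartments).  Variants passing QC only in the
#' metastasis are tested with [classify_met_specific()]; those failing it
#' are reported as `unresolved` rather than dropped.
#'
#' Evidence in the opposite compartment is taken from that compartment's
#' QC'd table when the site is present there, else from the optional
#' per-site lookup tables (e.g. the full pre-QC tables, or pileup-derived
#' depths for real data), else treated as zero coverage.
#'
#' @param primary,met QC'd variant tables for the two compartments.
#' @param primary_sites,met_sites optional tables supplying `depth` and
#'   `alt_reads` at sites absent from the QC'd tables.
#' @param patient_id identifier stored in the output.
#' @return list with `pairs` (one row per variant: key columns, paired
#'   evidence, annotations, `status`) and `counts` (named integer vector
#'   over the four statuses).
#' @export
classify_patient <- function(primary, met,
                             primary_sites = NULL, met_sites = NULL,
                             patient_id = NA_character_) {
  for (nm in c("primary", "met")) {
    tab <- if (nm == "primary") primary else met
    if (nrow(tab) > 0L) {
      k <- variant_key(tab$chrom, tab$pos, tab$ref, tab$alt)
      dup <- unique(k[duplicated(k)])
      if (length(dup) > 0L) {
        stop("duplicate variant keys in ", nm, " table: ",
             paste(utils::head(dup, 5L), collapse = ", "))
      }
    }
  }

  kp <- if (nrow(primary) > 0L)
    variant_key(primary$chrom, primary$pos, primary$ref, primary$alt) else character(0)
  km <- if (nrow(met) > 0L)
    variant_key(met$chrom, met$pos, met$ref, met$alt) else character(0)
  keys <- union(kp, km)

  if (length(keys) == 0L) {
    empty <- data.frame(patient_id = character(0), chrom = character(0),
                        pos = integer(0), ref = character(0),
                        alt = character(0), primary_depth = integer(0),
                        primary_alt_reads = integer(0), met_depth = integer(0),
                        met_alt_reads = integer(0), vclass = character(0),
                        gene = character(0), consequence = character(0),
                        status = character(0), stringsAsFactors = FALSE)
    return(list(pairs = empty,
                counts = stats::setNames(rep(0L, 4L), .STATUSES)))
  }

  ep <- evidence_at(keys, primary, primary_sites)
  em <- evidence_at(keys, met, met_sites)

  # annotations travel from whichever compartment called the variant
  src <- ifelse(keys %in% kp, "p", "m")
  ann_from <- function(col) {
    out <- rep(NA_character_, length(keys))
    if (nrow(primary) > 0L) out[src == "p"] <-
        primary[[col]][match(keys[src == "p"], kp)]
    if (nrow(met) > 0L) out[src == "m"] <-
        met[[col]][match(keys[src == "m"], km)]
    out
  }

  parts <- strsplit(keys, ":", fixed = TRUE)
  pairs <- data.frame(
    patient_id = patient_id,
    chrom = vapply(parts, `[`, "", 1L),
    pos = as.integer(vapply(parts, `[`, "", 2L)),
    ref = vapply(parts, `[`, "", 3L),
    alt = vapply(parts, `[`, "", 4L),
    primary_depth = ep$depth, primary_alt_reads = ep$alt_reads,
    met_depth = em$depth, met_alt_reads = em$alt_reads,
    vclass = ann_from("vclass"), gene = ann_from("gene"),
    consequence = ann_from("consequence"),
    stringsAsFactors = FALSE)

  in_primary_qc <- keys %in% kp
  status <- character(length(keys))
  status[in_primary_qc] <-
    classify_from_primary(pairs[in_primary_qc, , drop = FALSE])
  met_only <- !in_primary_qc
  if (any(met_only)) {
    is_ms <- classify_met_specific(pairs[met_only, , drop = FALSE])
    status[met_only] <- ifelse(is_ms, "met_specific", "unresolved")
  }
  pairs$status <- status
  counts <- vapply(.STATUSES, function(s) sum(status == s), integer(1))
  list(pairs = pairs, counts = counts)
}
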