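# End-to-end driver: QC -> paired classification -> copy-number
# segmentation -> mutational spectra -> trunk/branch and recurrence
# report, for every patient of a cohort, with a machine-readable run
# manifest.

param_entry <- function(value, provenance) list(value = value,
                                                provenance = provenance)

#' Run the full paired-exome pipeline on a cohort
#'
#' Takes either a generated synthetic cohort (from [generate_cohort()])
#' or an equivalently shaped list of real inputs: per-sample variant
#' tables named `<patient>_primary` / `<patient>_met`, per-sample
#' coverage tables with the same names, and a germline catalog.  Runs,
#' per patient: quality + germline filtering of both compartments, paired
#' classification, CBS copy-number analysis, and the trunk/branch tree;
#' then cohort-level spectra, clustering, copy-number recurrence, gene
#' recurrence, and (optionally) cancer-gene and domain annotation.
#'
#' @param cohort cohort list with `variants`, `coverage`, `germline`, and
#'   optionally `truth`.
#' @param thresholds a [qc_thresholds()].
#' @param alpha,n_perm,min_width CBS parameters.
#' @param min_patients recurrence threshold (distinct metastases).
#' @param gene_list optional character vector of cancer genes.
#' @param domain_table optional protein-domain `data.frame`.
#' @param seed seed for the CBS permutation tests.
#' @param outdir optional directory; when given, per-stage TSV/JSON
#'   outputs and the manifest are written there.
#' @return list with `patients` (per-patient: QC attrition, classified
#'   pairs, counts, tree, segments, zero level), `spectra`, `clustering`,
#'   `recurrent_genes`, `recurrent_gains`, `recurrent_deletions`,
#'   `cancer_gene_summary` (if `gene_list` given), `confusion` (if truth
#'   available), and `manifest`.
#' @export
run_pipeline <- function(cohort,
                         thresholds = qc_thresholds(),
                         alpha = 0.01, n_perm = 1000, min_width = 3,
                         min_patients = 2,
                         gene_list = NULL, domain_table = NULL,
                         seed = 1L, outdir = NULL) {
  stopifnot(is.list(cohort), !is.null(cohort$variants),
            !is.null(cohort$coverage))
  if (is.null(cohort$germline)) {
    stop("stage qc: missing germline catalog")
  }
  sample_names <- names(cohort$variants)
  patient_ids <- unique(sub("_(primary|met)$", "", sample_names))
  set.seed(seed)

  patients <- list()
  all_pairs <- list()
  qc_met_tables <- list()
  seg_tables <- list()

  for (pid in patient_ids) {
    pn <- paste0(pid, "_primary")
    mn <- paste0(pid, "_met")
    if (!all(c(pn, mn) %in% sample_names)) {
      stop("stage qc: incomplete pair for patient ", pid)
    }
    qc_p <- qc_pipeline(cohort$variants[[pn]], thresholds, cohort$germline)
    qc_m <- qc_pipeline(cohort$variants[[mn]], thresholds, cohort$germline)
    cls <- classify_patient(qc_p$variants, qc_m$variants,
                            primary_sites = cohort$variants[[pn]],
                            met_sites = cohort$variants[[mn]],
                            patient_id = pid)
    cna <- cna_pipeline(cohort$coverage[[pn]], cohort$coverage[[mn]],
                        sample_id = mn, alpha = alpha, n_perm = n_perm,
                        min_width = min_width)
    tree <- build_tree(cls$counts, patient_id = pid)

    patients[[pid]] <- list(
      attrition = list(primary = qc_p$attrition, met = qc_m$attrition),
      pairs = cls$pairs, counts = cls$counts, tree = tree,
      segments = cna$segments, zero = cna$zero)
    all_pairs[[pid]] <- cls$pairs
    qc_met_tables[[mn]] <- qc_m$variants
    seg_tables[[pid]] <- cna$segments
  }

  pairs <- do.call(rbind, unname(all_pairs))
  rownames(pairs) <- NULL

  # cohort-level spectra over metastasis-sample QC'd variants
  spectra <- spectrum_matrix(qc_met_tables)
  clustering <- if (nrow(spectra) >= 2L && sum(rowSums(spectra) > 0) >= 2L) {
    suppressWarnings(cluster_samples(spectra))
  } else {
    NULL
  }

  rec_genes <- recurrent_genes(pairs, min_patients = min_patients)
  rec_gain <- if (length(seg_tables) >= 2L) {
    recurrent_regions(seg_tables, min_patients, "gain")
  } else NULL
  rec_del <- if (length(seg_tables) >= 2L) {
    recurrent_regions(seg_tables, min_patients, "deletion")
  } else NULL

  cg <- if (!is.null(gene_list)) annotate_cancer_genes(pairs, gene_list)
        else NULL
  dom <- if (!is.null(domain_table) && !is.null(pairs$protein_pos)) {
    domain_overlap(pairs, domain_table)
  } else NULL

  confusion <- NULL
  if (!is.null(cohort$truth)) {
    calls <- data.frame(
      variant_id = paste(pairs$patient_id,
                         variant_key(pairs$chrom, pairs$pos, pairs$ref,
                                     pairs$alt),
                         sep = ":"),
      class = pairs$status, stringsAsFactors = FALSE)
    confusion <- truth_confusion(cohort$truth, calls)
  }

  manifest <- list(
    tool = "pairedexome",
    version = as.character(utils::packageVersion("pairedexome")),
    seed = seed,
    parameters = list(
      qc = list(
        min_depth = param_entry(thresholds$min_depth, "stated"),
        min_alt_reads = param_entry(thresholds$min_alt_reads, "stated"),
        min_vaf = param_entry(thresholds$min_vaf, "stated"),
        min_qphred_snv = param_entry(thresholds$min_qphred_snv, "stated"),
        min_qphred_indel = param_entry(thresholds$min_qphred_indel, "stated"),
        max_pop_freq = param_entry(thresholds$max_pop_freq, "stated")),
      pairing = list(
        shared_min_met_reads = param_entry(2, "stated"),
        shared_min_met_fraction = param_entry(0.05, "stated"),
        met_specific_min_reads = param_entry(3, "stated"),
        met_specific_min_fraction = param_entry(0.15, "stated"),
        met_specific_max_primary_reads = param_entry(1, "stated"),
        met_specific_max_primary_fraction = param_entry(0.05, "stated")),
      cna = list(
        gain_threshold = param_entry(0.15, "stated"),
        high_threshold = param_entry(2, "stated"),
        alpha = param_entry(alpha, "assumed"),
        n_perm = param_entry(n_perm, "assumed"),
        min_width = param_entry(min_width, "assumed"),
        depth_floor = param_entry(10, "assumed"),
        zero_mode_bin_width = param_entry(0.05, "assumed")),
      report = list(
        min_patients = param_entry(min_patients, "stated"))),
    counts = lapply(patients, function(p) as.list(p$counts)))

  result <- list(patients = patients, pairs = pairs, spectra = spectra,
                 clustering = clustering, recurrent_genes = rec_genes,
                 recurrent_gains = rec_gain, recurrent_deletions = rec_del,
                 cancer_gene_summary = if (!is.null(cg)) cg$summary else NULL,
                 domain_summary = if (!is.null(dom)) dom$summary else NULL,
                 confusion = confusion, manifest = manifest)

  if (!is.null(outdir)) write_pipeline_outputs(result, outdir)
  invisible(result)
}

write_pipeline_outputs <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(result$pairs, file.path(outdir, "pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  segs <- do.call(rbind, unname(lapply(result$patients, `[[`, "segments")))
  write_segments(segs, file.path(outdir, "segments.tsv"))
  utils::write.table(cbind(sample = rownames(result$spectra),
                           as.data.frame(result$spectra)),
                     file.path(outdir, "spectra.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(result$clustering)) {
    writeLines(result$clustering$newick, file.path(outdir, "spectrum_tree.nwk"))
  }
  utils::write.table(result$recurrent_genes,
                     file.path(outdir, "recurrent_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  trees <- vapply(result$patients, function(p) p$tree$newick, character(1))
  writeLines(trees, file.path(outdir, "patient_trees.nwk"))
  jsonlite::write_json(result$manifest,
                       file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(outdir)
}
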