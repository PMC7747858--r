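# Per-patient trunk/branch trees, cross-patient recurrence of
# metastasis-acquired mutations, cancer-gene annotation, and
# protein-domain overlap (lollipop-ready) tables.

.NONSYN <- c("missense", "nonsense", "splice", "frameshift", "inframe_indel")

#' Trunk/branch tree of one patient
#'
#' The trunk length is the number of shared (truncal) variants — those
#' attributed to the common precursor of the primary tumor and the
#' metastasis — and the two branch lengths are the compartment-private
#' variant counts.
#'
#' @param counts named counts from [classify_patient()] (uses `shared`,
#'   `primary_specific`, `met_specific`).
#' @param patient_id identifier.
#' @return object of class `patient_tree`: list with `patient_id`,
#'   `n_shared`, `n_primary_private`, `n_met_private`, and `newick` of the
#'   form `((primary:n_p,met:n_m)trunk:n_s);`.
#' @export
build_tree <- function(counts, patient_id = NA_character_) {
  tr <- list(patient_id = patient_id,
             n_shared = unname(counts[["shared"]]),
             n_primary_private = unname(counts[["primary_specific"]]),
             n_met_private = unname(counts[["met_specific"]]))
  tr$newick <- sprintf("((primary:%d,met:%d)trunk:%d);",
                       tr$n_primary_private, tr$n_met_private, tr$n_shared)
  class(tr) <- "patient_tree"
  tr
}

#' @export
print.patient_tree <- function(x, ...) {
  cat(sprintf("Patient %s: trunk %d | primary branch %d | met branch %d\n",
              x$patient_id, x$n_shared, x$n_primary_private,
              x$n_met_private))
  cat(" ", x$newick, "\n")
  invisible(x)
}

#' Genes recurrently mutated across metastases
#'
#' Counts, per gene, the number of distinct patients whose
#' metastasis-specific variants hit that gene (two hits in one patient
#' count once), restricted to non-synonymous consequences by default, and
#' reports genes reaching `min_patients`.
#'
#' @param pairs `data.frame` of classified paired variants (rows from
#'   [classify_patient()] across patients, needing `patient_id`, `gene`,
#'   `consequence`, `status`).
#' @param min_patients minimum distinct patients (default 2, i.e. "more
#'   than one metastasis").
#' @param nonsynonymous_only if `TRUE` (default), only missense, nonsense,
#'   splice, frameshift and in-frame indel variants are counted.
#' @return `data.frame` `gene n_patients patients`, sorted by descending
#'   count then gene symbol.
#' @export
recurrent_genes <- function(pairs, min_patients = 2,
                            nonsynonymous_only = TRUE) {
  v <- pairs[pairs$status == "met_specific" & !is.na(pairs$gene) &
               nzchar(pairs$gene), , drop = FALSE]
  if (nonsynonymous_only) {
    v <- v[v$consequence %in% .NONSYN, , drop = FALSE]
  }
  if (nrow(v) == 0L) {
    return(data.frame(gene = character(0), n_patients = integer(0),
                      patients = character(0), stringsAsFactors = FALSE))
  }
  v <- unique(v[, c("gene", "patient_id")])
  tab <- tapply(v$patient_id, v$gene,
                function(p) paste(sort(unique(p)), collapse = ","))
  n <- vapply(strsplit(unname(tab), ",", fixed = TRUE), length, integer(1))
  out <- data.frame(gene = names(tab), n_patients = n,
                    patients = unname(tab), stringsAsFactors = FALSE)
  out <- out[out$n_patients >= min_patients, , drop = FALSE]
  out <- out[order(-out$n_patients, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Flag variants in a cancer-gene list
#'
#' Marks each variant as in/out of a curated cancer-gene list (e.g. a
#' local Cancer Gene Census extract) and summarizes flagged
#' non-synonymous SNVs and flagged indels, overall and per classification
#' status when a `status` column is present.
#'
#' @param variants `data.frame` with `gene`, `vclass`, `consequence` and
#'   optionally `status`.
#' @param gene_list character vector of gene symbols.
#' @return list with `variants` (input plus `in_cancer_list` flag) and
#'   `summary` (`data.frame` of counts: flagged non-synonymous SNVs and
#'   flagged indels, by status where available).
#' @export
annotate_cancer_genes <- function(variants, gene_list) {
  if (length(gene_list) == 0L) {
    warning("empty cancer-gene list; no variant flagged")
  }
  variants$in_cancer_list <- variants$gene %in% gene_list
  flagged <- variants[variants$in_cancer_list, , drop = FALSE]
  grp <- if (!is.null(flagged$status)) flagged$status else
    rep("all", nrow(flagged))
  levels <- unique(c(grp, if (is.null(flagged$status)) "all" else character(0)))
  summarize <- function(g) {
    f <- flagged[grp == g, , drop = FALSE]
    data.frame(status = g,
               nonsyn_snv = sum(f$vclass == "SNV" &
                                  f$consequence %in% .NONSYN),
               indel = sum(f$vclass == "indel"),
               stringsAsFactors = FALSE)
  }
  summary <- if (length(levels) > 0L) {
    do.call(rbind, lapply(levels, summarize))
  } else {
    data.frame(status = character(0), nonsyn_snv = integer(0),
               indel = integer(0), stringsAsFactors = FALSE)
  }
  list(variants = variants, summary = summary)
}

#' Overlap variants with protein functional domains
#'
#' Joins each variant carrying a protein position to the functional
#' domain covering it (1-based inclusive amino-acid bounds), producing a
#' lollipop-plot-ready table.
#'
#' @param variants `data.frame` with `gene`, `protein_pos`, `consequence`.
#'   Variants lacking a protein position get domain `none` and are
#'   counted separately in the summary.
#' @param domain_table `data.frame` `gene domain start_aa end_aa`.
#' @return list with `hits` (`gene protein_pos consequence domain
#'   in_functional_domain has_position`) and `summary` (per-gene: any
#'   in-domain variant), plus `n_genes_in_domain`.
#' @export
domain_overlap <- function(variants, domain_table) {
  n <- nrow(variants)
  domain <- rep("none", n)
  has_pos <- !is.na(variants$protein_pos)
  for (i in which(has_pos)) {
    d <- domain_table[domain_table$gene == variants$gene[i] &
                        domain_table$start_aa <= variants$protein_pos[i] &
                        domain_table$end_aa >= variants$protein_pos[i],
                      , drop = FALSE]
    if (nrow(d) > 0L) domain[i] <- d$domain[1L]
  }
  hits <- data.frame(gene = variants$gene,
                     protein_pos = variants$protein_pos,
                     consequence = variants$consequence,
                     domain = domain,
                     in_functional_domain = domain != "none",
                     has_position = has_pos,
                     stringsAsFactors = FALSE)
  by_gene <- tapply(hits$in_functional_domain, hits$gene, any)
  summary <- data.frame(gene = names(by_gene),
                        any_in_domain = as.logical(by_gene),
                        stringsAsFactors = FALSE)
  rownames(summary) <- NULL
  list(hits = hits, summary = summary,
       n_genes_in_domain = sum(summary$any_in_domain))
}
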