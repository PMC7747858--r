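# Trunk/branch trees, recurrence tallies, cancer-gene and domain
# annotation.

test_that("trees map counts to branch lengths and round-trip via Newick", {
  tr <- build_tree(c(shared = 50L, primary_specific = 10L,
                     met_specific = 12L, unresolved = 0L), "P1")
  expect_identical(tr$newick, "((primary:10,met:12)trunk:50);")
  phy <- ape::read.tree(text = tr$newick)
  expect_setequal(phy$tip.label, c("primary", "met"))
  expect_identical(unname(phy$edge.length[phy$edge[, 2] == 1]), 10)
  expect_identical(unname(phy$edge.length[phy$edge[, 2] == 2]), 12)
  # trunk edge: the internal node that is not the root
  internal <- phy$edge[, 2] > ape::Ntip(phy)
  expect_identical(unname(phy$edge.length[internal]), 50)
  # degenerate all-zero tree is still valid Newick
  z <- build_tree(c(shared = 0L, primary_specific = 0L, met_specific = 0L,
                    unresolved = 0L), "P0")
  expect_s3_class(ape::read.tree(text = z$newick), "phylo")
})

test_that("tree counts reconcile with paired classification", {
  co <- generate_cohort(small_cohort_config(seed = 19, n_patients = 1))
  thr <- qc_thresholds()
  qp <- qc_pipeline(co$variants$P1_primary, thr, co$germline)
  qm <- qc_pipeline(co$variants$P1_met, thr, co$germline)
  cls <- classify_patient(qp$variants, qm$variants,
                          primary_sites = co$variants$P1_primary,
                          met_sites = co$variants$P1_met, patient_id = "P1")
  tr <- build_tree(cls$counts, "P1")
  expect_identical(tr$n_shared, unname(cls$counts["shared"]))
  expect_identical(tr$n_primary_private,
                   unname(cls$counts["primary_specific"]))
  expect_identical(tr$n_met_private, unname(cls$counts["met_specific"]))
  expect_gt(tr$n_met_private, tr$n_primary_private)  # generator plants more
})

test_that("recurrent_genes counts distinct patients, not variants", {
  pairs <- data.frame(
    patient_id = c("P1", "P1", "P2", "P3", "P1", "P2"),
    gene = c("GENEX", "GENEX", "GENEX", "GENEX", "GENEY", "GENEZ"),
    consequence = c("missense", "nonsense", "missense", "missense",
                    "missense", "synonymous"),
    status = c("met_specific", "met_specific", "met_specific",
               "met_specific", "met_specific", "met_specific"),
    stringsAsFactors = FALSE)
  rec <- recurrent_genes(pairs, min_patients = 2)
  expect_identical(rec$gene, "GENEX")
  expect_identical(rec$n_patients, 3L)  # two P1 hits count once
  expect_identical(rec$patients, "P1,P2,P3")
  # all genes private to single patients: empty
  solo <- pairs[c(3, 5), ]
  expect_identical(nrow(recurrent_genes(solo, min_patients = 2)), 0L)
  # synonymous-only recurrence appears only when the filter is disabled
  syn <- data.frame(patient_id = c("P1", "P2"), gene = "GENES",
                    consequence = "synonymous", status = "met_specific",
                    stringsAsFactors = FALSE)
  expect_identical(nrow(recurrent_genes(syn, 2)), 0L)
  expect_identical(recurrent_genes(syn, 2, nonsynonymous_only = FALSE)$gene,
                   "GENES")
})

test_that("planted recurrent gene is reported across the cohort", {
  co <- generate_cohort(small_cohort_config(seed = 29, n_patients = 3))
  res <- run_pipeline(co, n_perm = 200, seed = 2)
  rec <- res$recurrent_genes
  expect_true("METREC1" %in% rec$gene)
  expect_identical(rec$n_patients[rec$gene == "METREC1"], 3L)
})

test_that("cancer-gene annotation flags and counts by consequence class", {
  v <- data.frame(
    gene = c("KRAS", "KRAS", "STK11", "OTHER1"),
    vclass = c("SNV", "SNV", "indel", "SNV"),
    consequence = c("missense", "synonymous", "frameshift", "missense"),
    status = c("shared", "shared", "met_specific", "shared"),
    stringsAsFactors = FALSE)
  res <- annotate_cancer_genes(v, c("KRAS", "STK11"))
  expect_identical(res$variants$in_cancer_list, c(TRUE, TRUE, TRUE, FALSE))
  s <- res$summary
  expect_identical(s$nonsyn_snv[s$status == "shared"], 1L)  # synonymous excluded
  expect_identical(s$indel[s$status == "met_specific"], 1L)
  expect_warning(annotate_cancer_genes(v, character(0)), "empty")
})

test_that("domain overlap joins on inclusive amino-acid bounds", {
  dom <- data.frame(gene = c("G1", "G1", "G2"),
                    domain = c("kinase", "SH2", "zf"),
                    start_aa = c(100L, 300L, 10L),
                    end_aa = c(200L, 350L, 50L), stringsAsFactors = FALSE)
  v <- data.frame(gene = c("G1", "G1", "G1", "G2", "G3"),
                  protein_pos = c(150L, 99L, 200L, NA, 5L),
                  consequence = "missense", stringsAsFactors = FALSE)
  res <- domain_overlap(v, dom)
  expect_identical(res$hits$domain, c("kinase", "none", "kinase", "none",
                                      "none"))
  expect_identical(res$hits$in_functional_domain,
                   c(TRUE, FALSE, TRUE, FALSE, FALSE))
  expect_identical(res$hits$has_position, c(TRUE, TRUE, TRUE, FALSE, TRUE))
  expect_identical(res$n_genes_in_domain, 1L)
})
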