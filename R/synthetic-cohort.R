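# Seeded synthetic paired-cohort generator.
#
# Emulates the study design of a paired whole-exome cohort: for each
# patient, one primary lung tumor and one brain metastasis sample at a
# median depth of 135X, carrying planted germline variants (present in
# both compartments at VAF ~0.5 and listed in a public-style frequency
# catalog), truncal somatic variants (shared by both compartments),
# compartment-private somatic variants, and planted copy-number segments
# in the metastasis coverage.  Every emitted variant carries a
# ground-truth origin label so downstream filtering and classification
# can be scored exactly.

.BASES <- c("A", "C", "G", "T")
.SUBSTITUTIONS <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
.ORIGINS <- c("germline", "truncal", "primary_private", "met_private")

#' Configure a synthetic paired cohort
#'
#' Defaults reflect the study conditions the pipeline targets: 7 patients
#' (14 samples), median sequencing depth 135X, per-patient somatic burden
#' of ~138 truncal variants, a handful of primary-private variants and
#' ~52 metastasis-acquired variants, and a smoking-like substitution
#' profile in which C>A transversions dominate.  One metastasis-private
#' missense variant in a designated gene is planted in several patients so
#' cross-patient recurrence detection has a known positive.
#'
#' @param n_patients number of patients (two samples each).
#' @param median_depth median per-site sequencing depth (reads).
#' @param n_truncal somatic variants shared by both compartments, per patient.
#' @param n_primary_private somatic variants private to the primary tumor.
#' @param n_met_private somatic variants acquired in the metastasis.
#' @param n_germline germline variants per patient (present in both
#'   compartments at VAF 0.5 and listed in the catalog).
#' @param germline_freq_range population-frequency range for planted
#'   germline variants; both ends must be `>= 1e-5` so the catalog filter
#'   removes them.
#' @param vaf_truncal variant allele fraction of truncal variants.
#' @param vaf_private variant allele fraction of compartment-private variants.
#' @param qphred_mean mean phred-scaled call quality (sd fixed at 5,
#'   truncated at 0, rounded).
#' @param indel_fraction fraction of somatic variants emitted as indels.
#' @param substitution_weights length-6 non-negative weights over the
#'   pyrimidine-referenced substitution types C>A, C>G, C>T, T>A, T>C, T>G
#'   used for somatic SNVs.
#' @param n_chrom number of synthetic chromosomes (`chr1..chrN`).
#' @param n_bins coverage bins per chromosome.
#' @param bin_width coverage bin width in bp.
#' @param planted_segments `data.frame` with columns `chrom start_bin
#'   end_bin log2_ratio` (1-based inclusive bin indices) of copy-number
#'   segments planted in the metastasis coverage; must be non-overlapping
#'   within a chromosome.
#' @param bin_noise_sd sd of per-bin log2 coverage noise.
#' @param recurrent_gene gene symbol receiving a planted metastasis-private
#'   missense variant in `recurrent_gene_patients` (synthetic symbol; it
#'   mirrors the pattern of one gene recurrently mutated across several
#'   brain metastases).
#' @param recurrent_gene_patients integer patient indices carrying the
#'   planted recurrent variant; default the first `min(3, n_patients)`.
#' @param seed RNG seed; generation is deterministic given the config.
#' @return a `cohort_config` list, validated.
#' @export
cohort_config <- function(n_patients = 7,
                          median_depth = 135,
                          n_truncal = 138,
                          n_primary_private = 3,
                          n_met_private = 52,
                          n_germline = 200,
                          germline_freq_range = c(1e-4, 1e-2),
                          vaf_truncal = 0.40,
                          vaf_private = 0.35,
                          qphred_mean = 60,
                          indel_fraction = 0.15,
                          substitution_weights = c(0.35, 0.08, 0.27, 0.08, 0.14, 0.08),
                          n_chrom = 4,
                          n_bins = 150,
                          bin_width = 10000,
                          planted_segments = data.frame(
                            chrom = c("chr2", "chr3"),
                            start_bin = c(41L, 51L),
                            end_bin = c(90L, 100L),
                            log2_ratio = c(0.6, -0.7)),
                          bin_noise_sd = 0.1,
                          recurrent_gene = "METREC1",
                          recurrent_gene_patients = seq_len(min(3, n_patients)),
                          seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              median_depth = median_depth,
              n_truncal = as.integer(n_truncal),
              n_primary_private = as.integer(n_primary_private),
              n_met_private = as.integer(n_met_private),
              n_germline = as.integer(n_germline),
              germline_freq_range = germline_freq_range,
              vaf_truncal = vaf_truncal,
              vaf_private = vaf_private,
              qphred_mean = qphred_mean,
              indel_fraction = indel_fraction,
              substitution_weights = substitution_weights,
              n_chrom = as.integer(n_chrom),
              n_bins = as.integer(n_bins),
              bin_width = as.integer(bin_width),
              planted_segments = planted_segments,
              bin_noise_sd = bin_noise_sd,
              recurrent_gene = recurrent_gene,
              recurrent_gene_patients = as.integer(recurrent_gene_patients),
              seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  counts <- c(cfg$n_patients, cfg$n_truncal, cfg$n_primary_private,
              cfg$n_met_private, cfg$n_germline, cfg$n_chrom, cfg$n_bins)
  if (any(counts < 0L)) stop("all counts must be >= 0")
  vafs <- c(cfg$vaf_truncal, cfg$vaf_private)
  if (any(vafs <= 0 | vafs > 1)) stop("VAFs must lie in (0, 1]")
  if (cfg$bin_noise_sd < 0) stop("bin_noise_sd must be >= 0")
  if (cfg$median_depth < 1) stop("median_depth must be >= 1")
  if (length(cfg$substitution_weights) != 6L ||
      any(cfg$substitution_weights < 0) ||
      sum(cfg$substitution_weights) <= 0) {
    stop("substitution_weights must be 6 non-negative weights with positive sum")
  }
  if (any(cfg$germline_freq_range < 1e-5) ||
      cfg$germline_freq_range[1] > cfg$germline_freq_range[2]) {
    stop("germline_freq_range must be an increasing pair with both ends >= 1e-5")
  }
  n_somatic <- cfg$n_truncal + cfg$n_primary_private + cfg$n_met_private
  # requested VAFs must be observable at the configured depth:
  # the expected number of variant-supporting reads must reach 1
  if (n_somatic > 0L && cfg$median_depth * min(vafs) < 1) {
    stop("requested VAFs are unobservable at median_depth ",
         cfg$median_depth, ": expected variant reads < 1")
  }
  ps <- cfg$planted_segments
  if (nrow(ps) > 0L) {
    if (any(ps$end_bin < ps$start_bin) || any(ps$start_bin < 1L) ||
        any(ps$end_bin > cfg$n_bins)) {
      stop("planted segments must satisfy 1 <= start_bin <= end_bin <= n_bins")
    }
    for (ch in unique(ps$chrom)) {
      s <- ps[ps$chrom == ch, , drop = FALSE]
      s <- s[order(s$start_bin), , drop = FALSE]
      if (nrow(s) > 1L && any(s$start_bin[-1L] <= s$end_bin[-nrow(s)])) {
        stop("planted segments overlap on ", ch)
      }
    }
    if (!all(ps$chrom %in% paste0("chr", seq_len(cfg$n_chrom)))) {
      stop("planted segment chromosomes outside chr1..chr", cfg$n_chrom)
    }
  }
  if (any(cfg$recurrent_gene_patients > cfg$n_patients) ||
      any(cfg$recurrent_gene_patients < 1L)) {
    stop("recurrent_gene_patients must index existing patients")
  }
  invisible(cfg)
}

rc_base <- function(b) c(A = "T", C = "G", G = "C", T = "A")[b]

# draw a substitution on the pyrimidine strand, then place it on either
# strand with equal probability, so strand-collapse is exercised
random_snv_alleles <- function(n, weights) {
  sub <- sample(.SUBSTITUTIONS, n, replace = TRUE, prob = weights)
  ref <- substr(sub, 1L, 1L)
  alt <- substr(sub, 3L, 3L)
  flip <- runif(n) < 0.5
  ref[flip] <- unname(rc_base(ref[flip]))
  alt[flip] <- unname(rc_base(alt[flip]))
  list(ref = ref, alt = alt)
}

#' Generate a synthetic paired cohort with ground truth
#'
#' For each patient, draws per-site depths as Poisson around
#' `median_depth` (floored at 1) and variant-supporting reads as
#' Binomial(depth, VAF); germline VAF is fixed at 0.5 (diploid
#' heterozygote).  Each sample's variant table carries a row for every
#' patient-level variant site, with `alt_reads = 0` in the compartment
#' that does not carry the variant, so paired classification always has
#' per-site depth available in both compartments.  Metastasis coverage
#' inside planted segments is the primary coverage scaled by
#' `2^log2_ratio`, with multiplicative log-normal bin noise on both
#' compartments.
#'
#' @param config a [cohort_config()].
#' @return list with elements `variants` (named list of per-sample variant
#'   tables, names `P<i>_primary` / `P<i>_met`), `coverage` (named list of
#'   per-sample coverage tables on a shared grid), `germline` (catalog
#'   `data.frame`), `truth` (`data.frame` with `variant_id`, `origin`,
#'   `passes_qc_by_construction`), and the `config`.
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  set.seed(config$seed)
  cfg <- config
  chroms <- paste0("chr", seq_len(cfg$n_chrom))
  genome_span <- cfg$n_bins * cfg$bin_width

  variants <- list()
  coverage <- list()
  truth_rows <- list()
  germline_rows <- list()

  n_per_patient <- cfg$n_germline + cfg$n_truncal +
    cfg$n_primary_private + cfg$n_met_private

  for (p in seq_len(cfg$n_patients)) {
    pid <- paste0("P", p)

    if (n_per_patient > 0L) {
      origin <- rep(.ORIGINS,
                    times = c(cfg$n_germline, cfg$n_truncal,
                              cfg$n_primary_private, cfg$n_met_private))
      n <- length(origin)
      chrom <- sample(chroms, n, replace = TRUE)
      is_somatic <- origin != "germline"
      # positions unique within a patient; germline sites take even and
      # somatic sites odd coordinates so a somatic variant can never
      # collide with a germline catalog entry from another patient
      pos <- integer(n)
      for (ch in chroms) {
        idx <- which(chrom == ch)
        base <- sample.int(genome_span %/% 2L, length(idx))
        pos[idx] <- 2L * base - ifelse(is_somatic[idx], 1L, 0L)
      }
      vclass <- rep("SNV", n)
      vclass[is_somatic & runif(n) < cfg$indel_fraction] <- "indel"

      ref <- alt <- character(n)
      snv <- vclass == "SNV"
      al <- random_snv_alleles(sum(snv), cfg$substitution_weights)
      ref[snv] <- al$ref
      alt[snv] <- al$alt
      if (any(!snv)) {
        ins <- runif(sum(!snv)) < 0.5
        base1 <- sample(.BASES, sum(!snv), replace = TRUE)
        base2 <- sample(.BASES, sum(!snv), replace = TRUE)
        ref[!snv] <- ifelse(ins, base1, paste0(base1, base2))
        alt[!snv] <- ifelse(ins, paste0(base1, base2), base1)
      }

      context5 <- sample(.BASES, n, replace = TRUE)
      context3 <- sample(.BASES, n, replace = TRUE)
      gene <- paste0("GENE", sprintf("%04d", sample.int(2000L, n, replace = TRUE)))
      consequence <- character(n)
      consequence[snv] <- sample(c("synonymous", "missense", "nonsense",
                                   "splice", "other"),
                                 sum(snv), replace = TRUE,
                                 prob = c(0.25, 0.55, 0.05, 0.05, 0.10))
      consequence[!snv] <- sample(c("frameshift", "inframe_indel"),
                                  sum(!snv), replace = TRUE,
                                  prob = c(0.7, 0.3))

      # plant the recurrent metastasis-private missense variant
      if (p %in% cfg$recurrent_gene_patients && cfg$n_met_private > 0L) {
        i <- which(origin == "met_private")[1L]
        gene[i] <- cfg$recurrent_gene
        consequence[i] <- "missense"
        vclass[i] <- "SNV"
        al1 <- random_snv_alleles(1L, cfg$substitution_weights)
        ref[i] <- al1$ref
        alt[i] <- al1$alt
      }

      pop_freq <- rep(NA_real_, n)
      gl <- origin == "germline"
      pop_freq[gl] <- runif(sum(gl), cfg$germline_freq_range[1],
                            cfg$germline_freq_range[2])

      vaf <- ifelse(gl, 0.5,
                    ifelse(origin == "truncal", cfg$vaf_truncal, cfg$vaf_private))

      depth_p <- pmax(1L, rpois(n, cfg$median_depth))
      depth_m <- pmax(1L, rpois(n, cfg$median_depth))
      in_primary <- origin %in% c("germline", "truncal", "primary_private")
      in_met <- origin %in% c("germline", "truncal", "met_private")
      alt_p <- ifelse(in_primary, rbinom(n, depth_p, vaf), 0L)
      alt_m <- ifelse(in_met, rbinom(n, depth_m, vaf), 0L)
      qp <- round(pmax(0, rnorm(n, cfg$qphred_mean, 5)))
      qm <- round(pmax(0, rnorm(n, cfg$qphred_mean, 5)))

      base_cols <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                              vclass = vclass, gene = gene,
                              consequence = consequence, pop_freq = pop_freq,
                              context5 = context5, context3 = context3,
                              stringsAsFactors = FALSE)
      prim <- cbind(sample = paste0(pid, "_primary"),
                    base_cols[, c("chrom", "pos", "ref", "alt")],
                    depth = depth_p, alt_reads = alt_p, qphred = qp,
                    base_cols[, c("vclass", "gene", "consequence",
                                  "pop_freq", "context5", "context3")])
      met <- cbind(sample = paste0(pid, "_met"),
                   base_cols[, c("chrom", "pos", "ref", "alt")],
                   depth = depth_m, alt_reads = alt_m, qphred = qm,
                   base_cols[, c("vclass", "gene", "consequence",
                                 "pop_freq", "context5", "context3")])

      # a variant "passes QC by construction" when it clears the default
      # quality thresholds in every compartment that carries it
      thr <- qc_thresholds()
      ok_p <- passes_quality(data.frame(depth = depth_p, alt_reads = alt_p,
                                        qphred = qp, vclass = vclass), thr)
      ok_m <- passes_quality(data.frame(depth = depth_m, alt_reads = alt_m,
                                        qphred = qm, vclass = vclass), thr)
      passes <- (!in_primary | ok_p) & (!in_met | ok_m)

      truth_rows[[pid]] <- data.frame(
        variant_id = paste(pid, variant_key(chrom, pos, ref, alt), sep = ":"),
        patient_id = pid,
        origin = origin,
        passes_qc_by_construction = passes,
        stringsAsFactors = FALSE)
      germline_rows[[pid]] <- data.frame(
        chrom = chrom[gl], pos = pos[gl], ref = ref[gl], alt = alt[gl],
        frequency = pop_freq[gl], stringsAsFactors = FALSE)
    } else {
      prim <- met <- empty_variant_table()
      truth_rows[[pid]] <- data.frame(variant_id = character(0),
                                      patient_id = character(0),
                                      origin = character(0),
                                      passes_qc_by_construction = logical(0))
      germline_rows[[pid]] <- data.frame(chrom = character(0), pos = integer(0),
                                         ref = character(0), alt = character(0),
                                         frequency = numeric(0))
    }

    variants[[paste0(pid, "_primary")]] <- prim
    variants[[paste0(pid, "_met")]] <- met

    cov <- simulate_coverage(cfg, chroms)
    coverage[[paste0(pid, "_primary")]] <- cov$primary
    coverage[[paste0(pid, "_met")]] <- cov$met
  }

  germline <- do.call(rbind, unname(germline_rows))
  germline <- germline[!duplicated(variant_key(germline$chrom, germline$pos,
                                               germline$ref, germline$alt)),
                       , drop = FALSE]
  rownames(germline) <- NULL
  truth <- do.call(rbind, unname(truth_rows))
  rownames(truth) <- NULL

  list(variants = variants, coverage = coverage, germline = germline,
       truth = truth, config = cfg)
}

empty_variant_table <- function(sample_id = character(0)) {
  data.frame(sample = sample_id[0], chrom = character(0), pos = integer(0),
             ref = character(0), alt = character(0), depth = integer(0),
             alt_reads = integer(0), qphred = numeric(0),
             vclass = character(0), gene = character(0),
             consequence = character(0), pop_freq = numeric(0),
             context5 = character(0), context3 = character(0),
             stringsAsFactors = FALSE)
}

simulate_coverage <- function(cfg, chroms) {
  rows_p <- rows_m <- list()
  for (ch in chroms) {
    start <- (seq_len(cfg$n_bins) - 1L) * cfg$bin_width
    lr <- rep(0, cfg$n_bins)
    ps <- cfg$planted_segments
    ps <- ps[ps$chrom == ch, , drop = FALSE]
    for (k in seq_len(nrow(ps))) {
      lr[ps$start_bin[k]:ps$end_bin[k]] <- ps$log2_ratio[k]
    }
    dp <- cfg$median_depth * 2^rnorm(cfg$n_bins, 0, cfg$bin_noise_sd)
    dm <- dp * 2^(lr + rnorm(cfg$n_bins, 0, cfg$bin_noise_sd))
    rows_p[[ch]] <- data.frame(chrom = ch, start = start,
                               end = start + cfg$bin_width, depth = dp,
                               stringsAsFactors = FALSE)
    rows_m[[ch]] <- data.frame(chrom = ch, start = start,
                               end = start + cfg$bin_width, depth = dm,
                               stringsAsFactors = FALSE)
  }
  list(primary = do.call(rbind, unname(rows_p)),
       met = do.call(rbind, unname(rows_m)))
}

#' Cross-tabulate ground-truth origins against assigned classes
#'
#' @param truth the `truth` table from [generate_cohort()].
#' @param calls `data.frame` with columns `variant_id` (patient-scoped, as
#'   in `truth`) and `class` (whatever label the pipeline assigned, e.g.
#'   `shared`, `met_specific`, `removed_germline`).
#' @return a contingency `table`, truth origins as rows; rows sum to the
#'   number of generated variants appearing in `calls`.
#' @export
truth_confusion <- function(truth, calls) {
  stopifnot(all(c("variant_id", "class") %in% names(calls)))
  orphans <- setdiff(calls$variant_id, truth$variant_id)
  if (length(orphans) > 0L) {
    stop("calls contain variant ids absent from truth: ",
         paste(utils::head(orphans, 5L), collapse = ", "))
  }
  origin <- truth$origin[match(calls$variant_id, truth$variant_id)]
  table(origin = factor(origin, levels = .ORIGINS),
        class = factor(calls$class))
}
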