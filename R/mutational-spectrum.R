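# 96-trinucleotide mutational spectra and spectrum-based sample
# clustering.  SNVs are collapsed onto the pyrimidine strand so every
# substitution maps into the six canonical types C>A, C>G, C>T, T>A,
# T>C, T>G, each resolved by the bases immediately 5' and 3' of the
# mutated base (6 x 4 x 4 = 96 categories).

#' Canonical 96-category labels
#'
#' Order: substitution types C>A, C>G, C>T, T>A, T>C, T>G (outer), then
#' 5' base A,C,G,T, then 3' base A,C,G,T; labels like `"A[C>A]G"`.
#'
#' @return character vector of length 96.
#' @export
spectrum_levels <- function() {
  labs <- character(0)
  for (s in .SUBSTITUTIONS) {
    for (f in .BASES) {
      for (t in .BASES) {
        labs <- c(labs, paste0(f, "[", s, "]", t))
      }
    }
  }
  labs
}

#' Assign SNVs to 96-trinucleotide categories
#'
#' Mutations whose reference base is a purine (A/G) are reverse
#' complemented — substitution and both flanks — before classification,
#' so the category is strand-independent.  Records with bases outside
#' A/C/G/T yield `NA`.
#'
#' @param ref,alt single reference/alternate bases (`ref != alt`).
#' @param context5,context3 single bases immediately 5' and 3' of the site.
#' @return character vector of category labels (or `NA` for unclassifiable
#'   records).
#' @export
classify_context <- function(ref, alt, context5, context3) {
  n <- length(ref)
  ok <- ref %in% .BASES & alt %in% .BASES &
    context5 %in% .BASES & context3 %in% .BASES & ref != alt
  out <- rep(NA_character_, n)
  if (!any(ok)) return(out)
  r <- ref[ok]; a <- alt[ok]; f <- context5[ok]; t <- context3[ok]
  pur <- r %in% c("A", "G")
  # pyrimidine-strand collapse: complement the alleles and swap the
  # complemented flanks
  new_f <- ifelse(pur, unname(rc_base(t)), f)
  new_t <- ifelse(pur, unname(rc_base(f)), t)
  new_r <- ifelse(pur, unname(rc_base(r)), r)
  new_a <- ifelse(pur, unname(rc_base(a)), a)
  out[ok] <- paste0(new_f, "[", new_r, ">", new_a, "]", new_t)
  out
}

#' 96-trinucleotide spectrum of one sample
#'
#' Counts the sample's SNVs over the 96 canonical categories; indels
#' contribute nothing.  Records with ambiguous bases are skipped with a
#' warning.  The six-type marginal (counts per substitution type) is
#' attached as attribute `"marginal"`.
#'
#' @param variants variant `data.frame` with columns `ref`, `alt`,
#'   `context5`, `context3` and (if present) `vclass` to exclude indels.
#' @return named integer vector of length 96 in canonical order.
#' @export
spectrum96 <- function(variants) {
  levels <- spectrum_levels()
  counts <- stats::setNames(integer(96L), levels)
  if (!is.null(variants$vclass)) {
    variants <- variants[variants$vclass == "SNV", , drop = FALSE]
  }
  if (nrow(variants) > 0L) {
    cat96 <- classify_context(variants$ref, variants$alt,
                              variants$context5, variants$context3)
    n_skip <- sum(is.na(cat96))
    if (n_skip > 0L) {
      warning(n_skip, " record(s) with ambiguous bases skipped")
    }
    tab <- table(factor(cat96[!is.na(cat96)], levels = levels))
    counts <- counts + as.integer(tab)
    names(counts) <- levels
  }
  marg <- vapply(.SUBSTITUTIONS, function(s) {
    sum(counts[grepl(s, names(counts), fixed = TRUE)])
  }, integer(1))
  attr(counts, "marginal") <- marg
  counts
}

#' Spectrum matrix for a set of samples
#'
#' @param variant_tables named list of variant tables.
#' @return integer matrix, samples in rows, 96 canonical categories in
#'   columns.
#' @export
spectrum_matrix <- function(variant_tables) {
  m <- t(vapply(variant_tables, function(v) as.integer(spectrum96(v)),
                integer(96L)))
  colnames(m) <- spectrum_levels()
  rownames(m) <- names(variant_tables)
  m
}

cosine_distance <- function(m) {
  norms <- sqrt(rowSums(m^2))
  sim <- (m %*% t(m)) / outer(norms, norms)
  d <- 1 - sim
  d[d < 0] <- 0  # guard tiny negative rounding
  diag(d) <- 0
  d
}

#' Cluster samples by mutational spectrum
#'
#' Spectra are normalized to proportions; samples are embedded by PCA
#' (on mean-centered proportions) and clustered hierarchically on cosine
#' distances with Ward linkage (Ward's minimum-variance update applied to
#' the cosine dissimilarity matrix as given — the procedure is followed
#' as stated even though Ward's derivation assumes squared Euclidean
#' distances).  All-zero spectra are excluded with a warning.
#'
#' @param spectra matrix, samples x 96 counts (as from
#'   [spectrum_matrix()]).
#' @param n_components number of principal components returned.
#' @param k number of clusters cut from the dendrogram.
#' @return list with `pca` (coordinates `data.frame`), `hclust` (the
#'   `hclust` object), `newick` (dendrogram serialized with labels and
#'   merge heights), `clusters` (named integer cluster labels), and
#'   `distance` (the cosine-distance matrix).
#' @export
cluster_samples <- function(spectra, n_components = 2, k = 2) {
  stopifnot(is.matrix(spectra))
  zero <- rowSums(spectra) == 0
  if (any(zero)) {
    warning("excluding all-zero spectra: ",
            paste(rownames(spectra)[zero], collapse = ", "))
    spectra <- spectra[!zero, , drop = FALSE]
  }
  if (nrow(spectra) < 2L) stop("need at least 2 non-empty spectra")
  p <- spectra / rowSums(spectra)
  d <- cosine_distance(p)
  hc <- stats::hclust(stats::as.dist(d), method = "ward.D")
  pc <- stats::prcomp(p, center = TRUE, scale. = FALSE)
  n_components <- min(n_components, ncol(pc$x))
  coords <- as.data.frame(pc$x[, seq_len(n_components), drop = FALSE])
  phy <- ape::as.phylo(hc)
  list(pca = coords,
       hclust = hc,
       newick = ape::write.tree(phy),
       clusters = stats::cutree(hc, k = min(k, nrow(spectra))),
       distance = d)
}
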