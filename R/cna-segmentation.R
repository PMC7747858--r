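# Copy-number alteration detection from paired coverage: per-bin
# metastasis-vs-primary log2 ratios, circular binary segmentation (CBS),
# mode-based zero level, and threshold state calling.

.CNA_STATES <- c("neutral", "gain", "deletion", "amplification",
                 "homozygous_deletion")

#' Per-bin metastasis-vs-primary coverage log ratio
#'
#' Depths are first library-size normalized (each sample's bin depths
#' divided by that sample's total) so the ratio is not dominated by global
#' sequencing-depth differences; the per-bin value is
#' `log2(met_norm / primary_norm)`.  Bins with raw primary depth below
#' `depth_floor` (default 10, matching the read-evidence floor used for
#' variants) or non-positive metastasis depth are masked (`NA`).
#'
#' @param primary,met coverage tables (`chrom start end depth`) on an
#'   identical bin grid.
#' @param depth_floor minimum raw primary depth for a bin to be used.
#' @param normalize library-size normalize before taking the ratio
#'   (default `TRUE`); when `FALSE` the raw per-bin depth ratio is used
#'   and any global depth difference is left for the zero level to absorb.
#' @return `data.frame` `chrom start end log2_ratio` (masked bins `NA`).
#' @export
log_ratio <- function(primary, met, depth_floor = 10, normalize = TRUE) {
  if (nrow(primary) != nrow(met) ||
      !all(primary$chrom == met$chrom) ||
      !all(primary$start == met$start) ||
      !all(primary$end == met$end)) {
    stop("mismatched bin grids between primary and metastasis coverage")
  }
  pn <- if (normalize) primary$depth / sum(primary$depth) else primary$depth
  mn <- if (normalize) met$depth / sum(met$depth) else met$depth
  lr <- log2(mn / pn)
  lr[primary$depth < depth_floor | met$depth <= 0] <- NA_real_
  data.frame(chrom = primary$chrom, start = primary$start,
             end = primary$end, log2_ratio = lr,
             stringsAsFactors = FALSE)
}

#' Segment one chromosome's log-ratio profile by CBS
#'
#' Recursive change-point search on the circularized sequence: the arc
#' maximizing the two-sample t-like statistic against its complement is
#' accepted as a change if its permutation p-value is below `alpha`, and
#' the resulting intervals are segmented recursively.  Masked (`NA`) bins
#' belong to no segment; segment bounds are reported in the original bin
#' indexing.
#'
#' @param values numeric vector of per-bin log2 ratios (possibly with
#'   `NA` masked bins) for one chromosome.
#' @param alpha permutation significance level for accepting a split.
#' @param n_perm number of permutations (>= 100).
#' @param min_width minimum segment width in bins; arcs leaving either
#'   side narrower are not considered.
#' @param seed optional RNG seed for the permutation test.
#' @return `data.frame` with `start_bin`, `end_bin` (1-based inclusive
#'   indices into `values`), `n_bins` (unmasked bins in the segment) and
#'   `smoothed_value` (mean log2 ratio of member bins).
#' @export
cbs_segment <- function(values, alpha = 0.01, n_perm = 1000,
                        min_width = 3, seed = NULL) {
  stopifnot(alpha > 0, alpha < 1, n_perm >= 100, min_width >= 1)
  if (!is.null(seed)) set.seed(seed)
  idx <- which(is.finite(values))
  empty <- data.frame(start_bin = integer(0), end_bin = integer(0),
                      n_bins = integer(0), smoothed_value = numeric(0))
  if (length(idx) == 0L) {
    warning("all bins masked; returning empty segmentation")
    return(empty)
  }
  x <- values[idx]

  # iterative recursion over (start, end) intervals of the unmasked series
  out <- list()
  stack <- list(c(1L, length(x)))
  while (length(stack) > 0L) {
    iv <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    a <- iv[1]; b <- iv[2]
    xi <- x[a:b]
    cut <- NULL
    if (length(xi) >= 2L * min_width) {
      arc <- cbs_max_arc(xi, min_width)
      if (arc$i >= 0L) {
        p <- cbs_perm_pvalue(xi, min_width, arc$stat, n_perm, alpha)
        if (p < alpha) cut <- c(arc$i, arc$j)
      }
    }
    if (is.null(cut)) {
      out[[length(out) + 1L]] <- c(a, b)
    } else {
      # arc (i, j] splits [a, b] into up to three pieces
      i <- cut[1]; j <- cut[2]; n <- length(xi)
      pieces <- list()
      if (i > 0L) pieces[[length(pieces) + 1L]] <- c(a, a + i - 1L)
      pieces[[length(pieces) + 1L]] <- c(a + i, a + j - 1L)
      if (j < n) pieces[[length(pieces) + 1L]] <- c(a + j, b)
      # push in reverse so pieces are processed left-to-right
      for (k in rev(seq_along(pieces))) stack[[length(stack) + 1L]] <- pieces[[k]]
    }
  }

  segs <- do.call(rbind, out)
  segs <- segs[order(segs[, 1]), , drop = FALSE]
  data.frame(
    start_bin = idx[segs[, 1]],
    end_bin = idx[segs[, 2]],
    n_bins = segs[, 2] - segs[, 1] + 1L,
    smoothed_value = vapply(seq_len(nrow(segs)),
                            function(r) mean(x[segs[r, 1]:segs[r, 2]]),
                            numeric(1)))
}

#' Mode-based copy-neutral zero level of a sample
#'
#' The most frequent smoothed segment value, estimated with a fixed-width
#' histogram (default width 0.05 log2 units, below the 0.15 calling
#' threshold) over segment values weighted by segment bin counts.  The
#' returned zero is the bin-count-weighted mean of the smoothed values in
#' the modal histogram bin; histogram breaks are anchored at the data
#' minimum so the estimate is exactly translation-equivariant.  A tie
#' between modal bins is broken toward the candidate nearest 0, with a
#' warning.
#'
#' @param segments segment `data.frame` with `smoothed_value` and `n_bins`.
#' @param bin_width histogram bin width in log2 units.
#' @return the zero level (log2-ratio units).
#' @export
zero_level <- function(segments, bin_width = 0.05) {
  if (nrow(segments) < 1L) stop("zero_level needs at least one segment")
  v <- segments$smoothed_value
  w <- segments$n_bins
  b <- floor((v - min(v)) / bin_width)
  counts <- tapply(w, b, sum)
  cand <- names(counts)[counts == max(counts)]
  rep_val <- vapply(cand, function(id) {
    sel <- b == as.numeric(id)
    sum(v[sel] * w[sel]) / sum(w[sel])
  }, numeric(1))
  if (length(cand) > 1L) {
    warning("tie between modal histogram bins; choosing value nearest 0")
    pick <- which.min(abs(rep_val))
  } else {
    pick <- 1L
  }
  unname(rep_val[pick])
}

#' Call copy-number states against a zero level
#'
#' Strict thresholds relative to the zero level: gain above `zero + 0.15`,
#' deletion below `zero - 0.15`, with high-level amplification above
#' `zero + 2` and homozygous deletion below `zero - 2` subsuming the
#' milder labels.  A value exactly at a threshold stays in the milder
#' class ("above" is strict).
#'
#' @param segments segment `data.frame` with `smoothed_value`.
#' @param zero the sample's zero level.
#' @param gain_threshold,high_threshold offsets from zero for gain/deletion
#'   and amplification/homozygous-deletion calls.
#' @return `segments` with a `state` column added.
#' @export
call_states <- function(segments, zero, gain_threshold = 0.15,
                        high_threshold = 2) {
  stopifnot(is.finite(zero))
  v <- segments$smoothed_value
  state <- rep("neutral", length(v))
  state[v > zero + gain_threshold] <- "gain"
  state[v < zero - gain_threshold] <- "deletion"
  state[v > zero + high_threshold] <- "amplification"
  state[v < zero - high_threshold] <- "homozygous_deletion"
  segments$state <- state
  segments
}

#' Full copy-number analysis of one patient
#'
#' Computes per-bin log ratios, segments each chromosome with CBS,
#' derives the sample zero level from all segments jointly, and calls
#' states.  Coordinates in the output are genomic (taken from the bin
#' grid) alongside bin indices.
#'
#' @param primary,met coverage tables on a shared grid.
#' @param sample_id label for the output `sample` column.
#' @inheritParams cbs_segment
#' @param depth_floor passed to [log_ratio()].
#' @return list with `segments` (SEG-like `data.frame`: `sample chrom
#'   start end start_bin end_bin n_bins smoothed_value state`), `zero`,
#'   and the per-bin `log_ratio` table.
#' @export
cna_pipeline <- function(primary, met, sample_id = "sample",
                         alpha = 0.01, n_perm = 1000, min_width = 3,
                         depth_floor = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lr <- log_ratio(primary, met, depth_floor)
  seg_rows <- list()
  for (ch in unique(lr$chrom)) {
    sel <- lr$chrom == ch
    segs <- suppressWarnings(cbs_segment(lr$log2_ratio[sel], alpha = alpha,
                                         n_perm = n_perm,
                                         min_width = min_width))
    if (nrow(segs) == 0L) next
    starts <- lr$start[sel]
    ends <- lr$end[sel]
    seg_rows[[ch]] <- data.frame(
      sample = sample_id, chrom = ch,
      start = starts[segs$start_bin], end = ends[segs$end_bin],
      start_bin = segs$start_bin, end_bin = segs$end_bin,
      n_bins = segs$n_bins, smoothed_value = segs$smoothed_value,
      stringsAsFactors = FALSE)
  }
  if (length(seg_rows) == 0L) {
    stop("no usable bins on any chromosome")
  }
  segments <- do.call(rbind, unname(seg_rows))
  rownames(segments) <- NULL
  zero <- zero_level(segments)
  segments <- call_states(segments, zero)
  list(segments = segments, zero = zero, log_ratio = lr)
}

#' Regions altered in multiple patients
#'
#' Counts, per bin, how many patients carry a gain-like
#' (gain/amplification) or deletion-like (deletion/homozygous deletion)
#' segment over it, and reports maximal runs of bins where the count
#' reaches `min_patients`.
#'
#' @param segment_tables named list (one per patient) of segment
#'   `data.frame`s with `chrom`, `start_bin`, `end_bin`, `state`, on a
#'   shared bin grid.
#' @param min_patients minimum number of altered patients.
#' @param state `"gain"` or `"deletion"` (high-level states are included
#'   with their milder class).
#' @return `data.frame` `chrom start_bin end_bin n_bins max_patients`.
#' @export
recurrent_regions <- function(segment_tables, min_patients,
                              state = c("gain", "deletion")) {
  state <- match.arg(state)
  if (length(segment_tables) < 2L) {
    stop("recurrent_regions needs at least 2 patients")
  }
  wanted <- if (state == "gain") c("gain", "amplification") else
    c("deletion", "homozygous_deletion")

  grids <- lapply(segment_tables, function(s) {
    tapply(s$end_bin, s$chrom, max)
  })
  ref <- grids[[1]]
  for (g in grids[-1]) {
    if (!identical(sort(names(g)), sort(names(ref))) ||
        !all(g[names(ref)] == ref)) {
      stop("inconsistent bin grids across patients")
    }
  }

  out <- list()
  for (ch in names(ref)) {
    n <- ref[[ch]]
    count <- integer(n)
    for (s in segment_tables) {
      si <- s[s$chrom == ch & s$state %in% wanted, , drop = FALSE]
      for (r in seq_len(nrow(si))) {
        rng <- si$start_bin[r]:si$end_bin[r]
        count[rng] <- count[rng] + 1L
      }
    }
    hit <- count >= min_patients
    if (!any(hit)) next
    r <- rle(hit)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    out[[ch]] <- data.frame(
      chrom = ch, start_bin = starts[keep], end_bin = ends[keep],
      n_bins = r$lengths[keep],
      max_patients = vapply(keep, function(k) max(count[starts[k]:ends[k]]),
                            integer(1)),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    return(data.frame(chrom = character(0), start_bin = integer(0),
                      end_bin = integer(0), n_bins = integer(0),
                      max_patients = integer(0)))
  }
  res <- do.call(rbind, unname(out))
  rownames(res) <- NULL
  res
}
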