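# cfDNA fragment-length profiling: TLEN-based extraction with mapping
# filters, binned normalized profiles, pooled healthy reference, profile
# correlation / deviation score, and the short-fragment fraction.

#' Construct a fragment-length sample
#'
#' @param lengths Positive integer fragment lengths in bp.
#' @param id Sample identifier.
#' @param n_pairs_total Total filtered read pairs the profile is normalized
#'   by (defaults to `length(lengths)`; may be larger when an external
#'   total-pairs denominator is supplied).
#' @param n_excluded Named integer vector of excluded-pair counts by reason.
#' @return Object of class `fragment_sample`.
#' @export
fragment_sample <- function(lengths, id = "sample",
                            n_pairs_total = length(lengths),
                            n_excluded = integer(0)) {
  lengths <- as.integer(lengths)
  if (any(lengths <= 0L)) stop("fragment lengths must be positive")
  if (length(lengths) > n_pairs_total) {
    stop("n_pairs_total cannot be smaller than the number of lengths")
  }
  structure(list(id = id, lengths = lengths,
                 n_pairs_total = as.integer(n_pairs_total),
                 n_excluded = n_excluded),
            class = "fragment_sample")
}

#' @export
print.fragment_sample <- function(x, ...) {
  cat(sprintf("Fragment-length sample '%s': %d lengths (of %d pairs)",
              x$id, length(x$lengths), x$n_pairs_total))
  if (length(x$lengths)) {
    cat(sprintf("; median %d bp", as.integer(stats::median(x$lengths))))
  }
  cat("\n")
  if (length(x$n_excluded)) {
    cat("  excluded:", paste(names(x$n_excluded), x$n_excluded,
                             sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Extract fragment lengths from deduplicated read pairs
#'
#' One length per read pair, taken as `|TLEN|` of the leftmost mate
#' (positive template length), so each pair is counted once. Pairs are
#' excluded -- and counted by reason -- when either mate falls below
#' `min_mapq`, when mates map to different chromosomes, or when `TLEN` is
#' zero.
#'
#' @param reads Aligned, UMI-deduplicated read pairs (RawRead-style
#'   data.frame as from [simulate_umi_readset()] or [read_sam()]).
#' @param regions Optional target intervals; when given, only pairs whose
#'   fragment overlaps a region are kept (others counted as `off_target`).
#' @param min_mapq Minimum mapping quality for both mates (default 10).
#' @param id Sample identifier.
#' @return A [fragment_sample()].
#' @export
extract_fragment_lengths <- function(reads, regions = NULL, min_mapq = 10L,
                                     id = "sample") {
  stop_if_not_df_with(reads, c("qname", "chrom", "pos", "mapq", "mate_chrom",
                               "tlen"), "reads")
  excl <- c(low_mapq = 0L, interchrom = 0L, no_tlen = 0L, off_target = 0L)
  if (!nrow(reads)) return(fragment_sample(integer(0), id, 0L, excl))
  # pair-level mapq: minimum over mates sharing a read name
  pair_min_mapq <- stats::ave(reads$mapq, reads$qname, FUN = min)
  left <- !is.na(reads$tlen) & reads$tlen > 0L
  interchrom <- !is.na(reads$mate_chrom) & !is.na(reads$chrom) &
    reads$mate_chrom != reads$chrom
  cand <- reads[left, , drop = FALSE]
  cand_minq <- pair_min_mapq[left]
  pairs_total <- length(unique(reads$qname))
  excl["interchrom"] <- length(unique(reads$qname[interchrom]))
  keep <- !(cand$qname %in% reads$qname[interchrom])
  cand <- cand[keep, , drop = FALSE]
  cand_minq <- cand_minq[keep]
  excl["no_tlen"] <- pairs_total - excl[["interchrom"]] - nrow(cand)
  low <- cand_minq < min_mapq
  excl["low_mapq"] <- sum(low)
  cand <- cand[!low, , drop = FALSE]
  if (!is.null(regions)) {
    regions <- validate_regions(regions)
    frag_end <- cand$pos + cand$tlen - 1L
    on_target <- rep(FALSE, nrow(cand))
    for (i in seq_len(nrow(regions))) {
      on_target <- on_target | (cand$chrom == regions$chrom[i] &
                                cand$pos <= regions$end[i] &
                                frag_end >= regions$start[i])
    }
    excl["off_target"] <- sum(!on_target)
    cand <- cand[on_target, , drop = FALSE]
  }
  fragment_sample(abs(cand$tlen), id = id,
                  n_pairs_total = nrow(cand), n_excluded = excl)
}

#' Binned, normalized fragment-length profile
#'
#' Histogram of fragment lengths over uniform bins, each bin count divided
#' by the sample's total filtered read pairs; lengths outside the range
#' (plus any pairs in the denominator without a length) appear as
#' out-of-range mass, so bin densities and out-of-range mass sum to 1.
#'
#' @param sample A [fragment_sample()].
#' @param bin_width Bin width in bp (default 5).
#' @param range Profile range `c(lo, hi)` in bp, covering `[lo, hi)`
#'   (default 50-500).
#' @return Object of class `fragment_profile`: `bin_edges` (length
#'   `n_bins + 1`), `density`, `out_of_range`, `range`, `bin_width`,
#'   `n_pairs`, `id`.
#' @export
build_profile <- function(sample, bin_width = 5L, range = c(50L, 500L)) {
  stopifnot(inherits(sample, "fragment_sample"), bin_width >= 1L,
            range[2] > range[1])
  edges <- seq(range[1], range[2], by = bin_width)
  if (edges[length(edges)] < range[2]) edges <- c(edges, range[2])
  n_bins <- length(edges) - 1L
  counts <- integer(n_bins)
  in_range <- sample$lengths >= range[1] & sample$lengths < range[2]
  if (any(in_range)) {
    bin <- findInterval(sample$lengths[in_range], edges,
                        rightmost.closed = FALSE)
    counts <- tabulate(bin, nbins = n_bins)
  }
  n <- sample$n_pairs_total
  structure(
    list(bin_edges = edges,
         density = if (n > 0L) counts / n else rep(0, n_bins),
         out_of_range = if (n > 0L) (n - sum(in_range)) / n else 0,
         range = range, bin_width = as.integer(bin_width),
         n_pairs = n, id = sample$id),
    class = "fragment_profile"
  )
}

#' @export
print.fragment_profile <- function(x, ...) {
  cat(sprintf("Fragment profile '%s': %d bins of %d bp over [%d, %d), n = %d pairs%s\n",
              x$id, length(x$density), x$bin_width, x$range[1], x$range[2],
              x$n_pairs, if (x$n_pairs == 0L) " (empty)" else ""))
  invisible(x)
}

#' Pooled reference profile from several samples
#'
#' Concatenates all fragment lengths (read-weighted, not sample-averaged)
#' and builds a single profile -- the combined healthy reference.
#'
#' @param samples List of [fragment_sample()] objects (at least one).
#' @inheritParams build_profile
#' @return A `fragment_profile` with id `"pooled_reference"`.
#' @export
pool_reference <- function(samples, bin_width = 5L, range = c(50L, 500L)) {
  if (!length(samples)) stop("at least one sample is required")
  stopifnot(all(vapply(samples, inherits, logical(1), "fragment_sample")))
  pooled <- fragment_sample(
    unlist(lapply(samples, `[[`, "lengths"), use.names = FALSE),
    id = "pooled_reference",
    n_pairs_total = sum(vapply(samples, `[[`, integer(1), "n_pairs_total"))
  )
  build_profile(pooled, bin_width = bin_width, range = range)
}

#' Pearson correlation between two fragment profiles
#'
#' @param a,b `fragment_profile` objects with identical bin edges.
#' @return Pearson's r over matched bin densities; `NA` (with a warning)
#'   when either profile has zero variance.
#' @export
profile_correlation <- function(a, b) {
  stopifnot(inherits(a, "fragment_profile"), inherits(b, "fragment_profile"))
  if (!identical(a$bin_edges, b$bin_edges)) {
    stop("profiles have mismatched bin edges")
  }
  if (stats::sd(a$density) == 0 || stats::sd(b$density) == 0) {
    warning("zero-variance profile; correlation undefined")
    return(NA_real_)
  }
  pearson_r(a$density, b$density)$r
}

#' Deviation of a profile from a reference
#'
#' `1 - r(profile, reference)`: 0 for a profile identical to the reference,
#' up to 2 for perfect anti-correlation. Tracks tumour burden in cfDNA.
#'
#' @param profile,reference `fragment_profile` objects with matched bins.
#' @return Deviation score in `[0, 2]`.
#' @export
deviation_score <- function(profile, reference) {
  1 - profile_correlation(profile, reference)
}

#' Short-fragment fraction
#'
#' Proportion of fragments shorter than `cutoff` bp (default 150), the
#' sub-mononucleosomal fraction enriched in tumour-derived cfDNA.
#'
#' @param sample A [fragment_sample()].
#' @param cutoff Length cutoff in bp.
#' @return Fraction in `[0, 1]`; `NA` (with a warning) for an empty sample.
#' @export
short_fraction <- function(sample, cutoff = 150L) {
  stopifnot(inherits(sample, "fragment_sample"))
  if (!length(sample$lengths)) {
    warning("empty fragment sample; short fraction undefined")
    return(NA_real_)
  }
  mean(sample$lengths < cutoff)
}
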