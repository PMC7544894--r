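# Step-1 variant screening on consensus reads: pileup construction, the
# default/stringent filter presets, and the panel-of-normals, impact and
# matched-normal filters.

#' Screening filter presets
#'
#' The `default` preset screens candidates at base quality 30, minimum
#' coverage 100, at least 3 alt-supporting consensus reads, signal-to-noise
#' ratio >= 4 and mean position of the variant in the read > 10. The
#' `stringent` preset raises the signal-to-noise requirement to 20 and the
#' mean read position to > 15.
#'
#' The signal-to-noise ratio (SNR) of a candidate is defined as
#' `hq / max(lq, 0.5)` where `hq`/`lq` count alt-supporting consensus reads
#' with base quality at/above vs below `min_bq`. The mean read position is
#' the mean, over alt-supporting reads, of the 1-based distance of the
#' variant base from the nearer read end (an edge-artifact guard).
#'
#' @param mode `"default"` or `"stringent"`.
#' @param min_bq,min_cov,min_alt,min_snr,min_mean_pos Individual threshold
#'   overrides.
#' @return Object of class `screen_params`.
#' @export
screen_params <- function(mode = c("default", "stringent"),
                          min_bq = 30L, min_cov = 100L, min_alt = 3L,
                          min_snr = NULL, min_mean_pos = NULL) {
  mode <- match.arg(mode)
  p <- list(
    mode = mode, min_bq = as.integer(min_bq), min_cov = as.integer(min_cov),
    min_alt = as.integer(min_alt),
    min_snr = as.numeric(min_snr %||% if (mode == "stringent") 20 else 4),
    min_mean_pos = as.numeric(min_mean_pos %||% if (mode == "stringent") 15 else 10)
  )
  if (any(unlist(p[-1]) < 0)) stop("screening thresholds must be >= 0")
  structure(p, class = "screen_params")
}

#' @export
print.screen_params <- function(x, ...) {
  cat(sprintf(paste0("Screening parameters (%s): BQ >= %d, coverage >= %d, ",
                     "alt reads >= %d, SNR >= %g, mean read position > %g\n"),
              x$mode, x$min_bq, x$min_cov, x$min_alt, x$min_snr, x$min_mean_pos))
  invisible(x)
}

#' Build a per-site allele pileup from consensus reads
#'
#' One row per (site, observed allele) over the target regions, with
#' consensus-read depth, allele counts split by base quality, mean base
#' quality, mean distance of the site from the nearer read end, and
#' forward/reverse family counts.
#'
#' @param consensus Consensus read data.frame (from [dedup_readset()] or
#'   [simulate_consensus_readset()]).
#' @param regions Target intervals (`chrom`, `start`, `end`; 1-based
#'   inclusive).
#' @param reference Reference object (see [ref_base()]).
#' @param min_bq Base-quality split for high/low-quality counts.
#' @return data.frame of class `pileup` with columns `chrom`, `pos`, `ref`,
#'   `depth`, `allele`, `count`, `hq`, `lq`, `mean_bq`, `mean_read_pos`,
#'   `fwd`, `rev`. `depth` sums all allele counts at the site.
#' @export
build_pileup <- function(consensus, regions, reference, min_bq = 30L) {
  stop_if_not_df_with(consensus, c("chrom", "start", "end", "seq", "qual",
                                   "orientation"), "consensus")
  regions <- validate_regions(regions)
  if (nrow(regions) == 0L) stop("regions must be nonempty")
  bad <- !(regions$chrom %in% names(reference))
  if (any(bad)) {
    stop("region outside any reference contig: ",
         paste(regions$chrom[bad], regions$start[bad], sep = ":")[1])
  }
  rows <- list()
  for (i in seq_len(nrow(regions))) {
    ch <- regions$chrom[i]
    on_chrom <- which(consensus$chrom == ch)
    for (p in seq.int(regions$start[i], regions$end[i])) {
      cov <- on_chrom[consensus$start[on_chrom] <= p & consensus$end[on_chrom] >= p]
      refb <- ref_base(reference, ch, p)
      if (!length(cov)) {
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = ch, pos = p, ref = refb, depth = 0L, allele = refb,
          count = 0L, hq = 0L, lq = 0L, mean_bq = NA_real_,
          mean_read_pos = NA_real_, fwd = 0L, rev = 0L, stringsAsFactors = FALSE)
        next
      }
      off <- p - consensus$start[cov] + 1L
      base <- substr(consensus$seq[cov], off, off)
      bq <- char_to_phred(substr(consensus$qual[cov], off, off))
      read_pos <- pmin(off, consensus$end[cov] - p + 1L)
      fwd <- consensus$orientation[cov] == "F"
      per_allele <- lapply(sort(unique(base)), function(a) {
        j <- base == a
        data.frame(
          chrom = ch, pos = p, ref = refb, depth = length(cov), allele = a,
          count = sum(j), hq = sum(j & bq >= min_bq), lq = sum(j & bq < min_bq),
          mean_bq = mean(bq[j]), mean_read_pos = mean(read_pos[j]),
          fwd = sum(j & fwd), rev = sum(j & !fwd), stringsAsFactors = FALSE)
      })
      rows[[length(rows) + 1L]] <- do.call(rbind, per_allele)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("pileup", "data.frame")
  out
}

#' Screen pileup columns for variant candidates
#'
#' Evaluates every non-reference allele (except `N`) against the four
#' filter predicates of the given preset: coverage, alt-read count,
#' signal-to-noise ratio and mean read position. All candidates are
#' returned with their failed-filter labels; a candidate passes iff no
#' filter failed.
#'
#' @param pileup A [build_pileup()] result.
#' @param params A [screen_params()] preset.
#' @return data.frame of class `variant_candidates`: `chrom`, `pos`, `ref`,
#'   `alt`, `depth`, `alt_count`, `vaf`, `snr`, `mean_read_pos`, `fwd`,
#'   `rev`, `filter_status` (`;`-joined failed filters, `""` when passing)
#'   and `pass`.
#' @export
screen <- function(pileup, params = screen_params()) {
  stopifnot(inherits(params, "screen_params"))
  cand <- pileup[pileup$allele != pileup$ref & pileup$allele != "N" &
                 pileup$count > 0L, , drop = FALSE]
  snr <- cand$hq / pmax(cand$lq, 0.5)
  fails <- cbind(
    min_cov = cand$depth < params$min_cov,
    min_alt = cand$count < params$min_alt,
    min_snr = snr < params$min_snr,
    min_mean_pos = !(cand$mean_read_pos > params$min_mean_pos)
  )
  status <- apply(fails, 1L, function(f) paste(colnames(fails)[f], collapse = ";"))
  out <- data.frame(
    chrom = cand$chrom, pos = cand$pos, ref = cand$ref, alt = cand$allele,
    depth = cand$depth, alt_count = cand$count, vaf = cand$count / cand$depth,
    snr = snr, mean_read_pos = cand$mean_read_pos, fwd = cand$fwd,
    rev = cand$rev, filter_status = if (nrow(cand)) status else character(0),
    stringsAsFactors = FALSE
  )
  out$pass <- out$filter_status == ""
  rownames(out) <- NULL
  class(out) <- c("variant_candidates", "data.frame")
  out
}

#' Keep only candidates passing all filters
#' @param candidates A `variant_candidates` data.frame.
#' @return The passing subset (class preserved).
#' @export
passing_variants <- function(candidates) {
  candidates[candidates$pass, , drop = FALSE]
}

#' Panel-of-normals filter
#'
#' Removes candidates whose (chrom, pos, ref, alt) key is present in two or
#' more healthy-plasma call sets -- recurrent technical artifacts.
#'
#' @param candidates A `variant_candidates` data.frame.
#' @param healthy_call_sets List of variant data.frames (each with `chrom`,
#'   `pos`, `ref`, `alt`).
#' @param min_samples Minimum number of healthy sets a variant must recur in
#'   to be removed (default 2).
#' @return Filtered candidates.
#' @export
filter_panel_of_normals <- function(candidates, healthy_call_sets, min_samples = 2L) {
  if (!nrow(candidates) || !length(healthy_call_sets)) return(candidates)
  key <- variant_key(candidates$chrom, candidates$pos, candidates$ref, candidates$alt)
  hits <- Reduce(`+`, lapply(healthy_call_sets, function(h) {
    key %in% unique(variant_key(h$chrom, h$pos, h$ref, h$alt))
  }))
  candidates[hits < min_samples, , drop = FALSE]
}

#' Variant-impact filter
#'
#' Retains candidates annotated with damaging impact (`MODERATE` or `HIGH`).
#' Candidates missing from the annotation are dropped by default (with a
#' warning), matching the stringency posture of the calling pipeline.
#'
#' @param candidates A `variant_candidates` data.frame.
#' @param annotation data.frame mapping variants to impact labels (`chrom`,
#'   `pos`, `ref`, `alt`, `impact`), e.g. read with [read_impact_table()].
#' @param keep Impact labels retained.
#' @param missing `"drop"` (default) or `"keep"` for unannotated candidates.
#' @return Filtered candidates.
#' @export
filter_impact <- function(candidates, annotation,
                          keep = c("MODERATE", "HIGH"),
                          missing = c("drop", "keep")) {
  missing <- match.arg(missing)
  if (!nrow(candidates)) return(candidates)
  stop_if_not_df_with(annotation, c("chrom", "pos", "ref", "alt", "impact"),
                      "annotation")
  key <- variant_key(candidates$chrom, candidates$pos, candidates$ref, candidates$alt)
  akey <- variant_key(annotation$chrom, annotation$pos, annotation$ref, annotation$alt)
  impact <- annotation$impact[match(key, akey)]
  unannotated <- is.na(impact)
  if (any(unannotated) && missing == "drop") {
    warning(sum(unannotated), " candidate(s) without impact annotation dropped")
  }
  retain <- if (missing == "keep") (impact %in% keep) | unannotated else impact %in% keep
  candidates[retain, , drop = FALSE]
}

#' Matched-normal (buffy coat) filter
#'
#' Removes candidates with any alternate-allele support in the matched
#' normal, or with insufficient normal coverage to rule such support out.
#' Sites absent from the normal counts are treated as coverage 0 (removed).
#'
#' @param candidates A `variant_candidates` data.frame.
#' @param normal_counts Per-site normal counts (`chrom`, `pos`, `alt_reads`,
#'   `coverage`), e.g. a samtools-mpileup-style tally.
#' @param min_normal_cov Minimum normal coverage required (default 100).
#' @param max_normal_alt Maximum tolerated normal alt reads (default 0).
#' @return Filtered candidates.
#' @export
filter_matched_normal <- function(candidates, normal_counts,
                                  min_normal_cov = 100L, max_normal_alt = 0L) {
  if (!nrow(candidates)) return(candidates)
  stop_if_not_df_with(normal_counts, c("chrom", "pos", "alt_reads", "coverage"),
                      "normal_counts")
  i <- match(paste(candidates$chrom, candidates$pos),
             paste(normal_counts$chrom, normal_counts$pos))
  alt <- ifelse(is.na(i), 0L, normal_counts$alt_reads[i])
  cov <- ifelse(is.na(i), 0L, normal_counts$coverage[i])
  candidates[!(alt > max_normal_alt | cov < min_normal_cov), , drop = FALSE]
}
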