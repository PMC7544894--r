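# Step-2 confirmation: a candidate is retained only when supported by two
# read families with distinct UMIs at the same fragment coordinates in
# complementary orientation -- evidence that the variant was present on both
# strands of one original molecule.

#' Collect alt-supporting families for a variant
#'
#' @param consensus Consensus read data.frame.
#' @param chrom,pos,alt Variant site and alternate allele.
#' @return Object of class `duplex_evidence`: the variant key and a
#'   `supporters` data.frame (`frag_start`, `frag_end`, `orientation`,
#'   `umi`, `family_size`) listing every alt-bearing family covering the
#'   site. Empty when the site is uncovered.
#' @export
collect_alt_families <- function(consensus, chrom, pos, alt) {
  cov <- which(consensus$chrom == chrom & consensus$start <= pos &
               consensus$end >= pos)
  off <- pos - consensus$start[cov] + 1L
  hit <- cov[substr(consensus$seq[cov], off, off) == alt]
  structure(
    list(chrom = chrom, pos = as.integer(pos), alt = alt,
         supporters = data.frame(
           frag_start = consensus$start[hit], frag_end = consensus$end[hit],
           orientation = consensus$orientation[hit], umi = consensus$umi[hit],
           family_size = consensus$family_size[hit], stringsAsFactors = FALSE)),
    class = "duplex_evidence"
  )
}

#' @export
print.duplex_evidence <- function(x, ...) {
  cat(sprintf("Duplex evidence for %s:%d>%s -- %d supporting families (%d F / %d R)\n",
              x$chrom, x$pos, x$alt, nrow(x$supporters),
              sum(x$supporters$orientation == "F"),
              sum(x$supporters$orientation == "R")))
  invisible(x)
}

supporter_pairs <- function(supporters, coord_mode = c("endpoints", "start")) {
  coord_mode <- match.arg(coord_mode)
  if (!nrow(supporters)) return(0L)
  key <- if (coord_mode == "endpoints") {
    paste(supporters$frag_start, supporters$frag_end)
  } else {
    as.character(supporters$frag_start)
  }
  total <- 0L
  for (k in unique(key)) {
    s <- supporters[key == k, , drop = FALSE]
    f <- s[s$orientation == "F", , drop = FALSE]
    r <- s[s$orientation == "R", , drop = FALSE]
    if (!nrow(f) || !nrow(r)) next
    total <- total + sum(outer(f$umi, r$umi, `!=`))
  }
  total
}

#' Test a variant for double-strand support
#'
#' `TRUE` iff some fragment coordinate carries at least two alt-supporting
#' families with distinct UMIs covering both orientations (one family on
#' the forward and one on the reverse strand).
#'
#' @param evidence A [collect_alt_families()] result.
#' @param coord_mode `"endpoints"` requires identical fragment start and
#'   end (the strict reading of "same genomic coordinates"); `"start"`
#'   relaxes to fragment start only.
#' @return Logical flag.
#' @export
has_double_strand_support <- function(evidence, coord_mode = c("endpoints", "start")) {
  stopifnot(inherits(evidence, "duplex_evidence"))
  supporter_pairs(evidence$supporters, coord_mode) > 0L
}

#' Confirm screened candidates by double-strand support
#'
#' Retains, in order, the candidates with at least one pair of
#' complementary-orientation, distinct-UMI alt families at shared fragment
#' coordinates, annotating each with the supporting-pair count (`ds_pairs`).
#'
#' @param candidates Passing `variant_candidates` (step-1 output).
#' @param consensus Consensus read data.frame the candidates were screened
#'   on.
#' @inheritParams has_double_strand_support
#' @return The confirmed subset of `candidates` with a `ds_pairs` column.
#' @export
confirm <- function(candidates, consensus, coord_mode = c("endpoints", "start")) {
  coord_mode <- match.arg(coord_mode)
  if (!nrow(candidates)) {
    candidates$ds_pairs <- integer(0)
    return(candidates)
  }
  pairs <- vapply(seq_len(nrow(candidates)), function(i) {
    ev <- collect_alt_families(consensus, candidates$chrom[i],
                               candidates$pos[i], candidates$alt[i])
    as.integer(supporter_pairs(ev$supporters, coord_mode))
  }, integer(1))
  out <- candidates[pairs > 0L, , drop = FALSE]
  out$ds_pairs <- pairs[pairs > 0L]
  rownames(out) <- NULL
  out
}
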