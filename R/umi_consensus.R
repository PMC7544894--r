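# UMI extraction, adjacency grouping of aligned reads into UMI families,
# and consensus building with singleton discard.

#' Extract the UMI token from read identifiers
#'
#' The UMI is carried as the final `:`-separated token of the read name
#' (as placed there during FASTQ pre-processing).
#'
#' @param names Character vector of read identifiers.
#' @param umi_len Expected UMI length.
#' @return data.frame with columns `id` (identifier with the UMI token
#'   removed) and `umi`.
#' @examples
#' extract_umi("r1:ACGTACGT")
#' @export
extract_umi <- function(names, umi_len = 8L) {
  m <- regmatches(names, regexec("^(.*):([ACGTN]+)$", names))
  bad <- vapply(m, function(x) length(x) != 3L || nchar(x[3]) != umi_len, logical(1))
  if (any(bad)) {
    stop("read name lacks a terminal ", umi_len, "-base UMI token: ",
         names[which(bad)[1]], call. = FALSE)
  }
  data.frame(id = vapply(m, `[`, character(1), 2L),
             umi = vapply(m, `[`, character(1), 3L),
             stringsAsFactors = FALSE)
}

# Orientation of a read's family: F iff the first-in-pair read maps to the
# forward strand. (The leftmost-mapped read of a proper pair is always on
# "+", so read-1 strand is the informative duplex label.)
read_orientation <- function(first_in_pair, strand) {
  ifelse(is.na(first_in_pair), ifelse(strand == "+", "F", "R"),
         ifelse(first_in_pair == (strand == "+"), "F", "R"))
}

fragment_coords <- function(reads) {
  mate_pos <- ifelse(is.na(reads$mate_pos), reads$pos, reads$mate_pos)
  frag_start <- pmin(reads$pos, mate_pos)
  span <- ifelse(!is.na(reads$tlen) & reads$tlen != 0L, abs(reads$tlen),
                 nchar(reads$seq))
  data.frame(frag_start = as.integer(frag_start),
             frag_end = as.integer(frag_start + span - 1L),
             orientation = read_orientation(reads$first_in_pair, reads$strand),
             stringsAsFactors = FALSE)
}

#' Merge UMIs within one fragment-coordinate bucket by the adjacency rule
#'
#' Directed edge `u -> v` iff `Hamming(u, v) <= max_mismatch` and
#' `count(u) >= 2 * count(v) - 1`; components are grown breadth-first from
#' the highest-count unassigned UMI, so each family's canonical UMI is its
#' most abundant member. Deterministic under input reordering (ties broken
#' lexicographically).
#'
#' @param umis Character vector of distinct UMIs.
#' @param counts Integer vector of read(-pair) counts per UMI.
#' @param max_mismatch Maximum Hamming distance merged (default 1).
#' @return Integer vector assigning each UMI to a component, with the
#'   canonical UMI of each component in `attr(, "canonical")`.
#' @export
adjacency_components <- function(umis, counts, max_mismatch = 1L) {
  stopifnot(length(umis) == length(counts), !anyDuplicated(umis))
  n <- length(umis)
  comp <- integer(n)
  if (n == 0L) return(structure(comp, canonical = character(0)))
  ord <- order(-counts, umis)
  canonical <- character(0)
  next_comp <- 0L
  for (seed in ord) {
    if (comp[seed] != 0L) next
    next_comp <- next_comp + 1L
    canonical <- c(canonical, umis[seed])
    comp[seed] <- next_comp
    queue <- seed
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      for (v in seq_len(n)) {
        if (comp[v] == 0L && counts[u] >= 2L * counts[v] - 1L &&
            hamming(umis[u], umis[v]) <= max_mismatch) {
          comp[v] <- next_comp
          queue <- c(queue, v)
        }
      }
    }
  }
  structure(comp, canonical = canonical)
}

#' Group aligned reads into UMI families
#'
#' Reads are bucketed by fragment coordinates (contig, fragment start,
#' fragment end, orientation); within each bucket UMIs are merged by the
#' adjacency rule of [adjacency_components()]. Reads below `min_mapq`,
#' unmapped reads, and reads whose mate maps to another contig are excluded
#' and counted.
#'
#' @param reads Aligned read data.frame (columns `qname`, `umi`, `chrom`,
#'   `pos`, `mapq`, `strand`, `first_in_pair`, `mate_chrom`, `mate_pos`,
#'   `tlen`, `seq`, `qual`), e.g. from [simulate_umi_readset()] or
#'   [read_sam()].
#' @param max_mismatch Maximum UMI Hamming distance merged (default 1).
#' @param min_mapq Minimum mapping quality retained (default 20).
#' @return Object of class `umi_grouping`: list with `members` (retained
#'   reads annotated with `family` and `canonical_umi`), `families`
#'   (per-family summary; `size` counts read pairs, i.e. distinct read
#'   names) and `counters`.
#' @export
group_families <- function(reads, max_mismatch = 1L, min_mapq = 20L) {
  stop_if_not_df_with(reads, c("qname", "umi", "chrom", "pos", "mapq", "strand",
                               "first_in_pair", "mate_chrom", "mate_pos",
                               "tlen", "seq", "qual"), "reads")
  n_input <- nrow(reads)
  unmapped <- is.na(reads$chrom)
  interchrom <- !unmapped & !is.na(reads$mate_chrom) & reads$mate_chrom != reads$chrom
  lowmapq <- !unmapped & !interchrom & reads$mapq < min_mapq
  keep <- !(unmapped | interchrom | lowmapq)
  counters <- c(input_reads = n_input, unmapped = sum(unmapped),
                interchrom = sum(interchrom), low_mapq = sum(lowmapq),
                retained = sum(keep))
  members <- reads[keep, , drop = FALSE]
  members <- cbind(members, fragment_coords(members))
  key <- paste(members$chrom, members$frag_start, members$frag_end,
               members$orientation, sep = "\r")
  members$family <- rep(NA_integer_, nrow(members))
  members$canonical_umi <- rep(NA_character_, nrow(members))

  fam_rows <- list()
  next_family <- 0L
  for (bucket in split(seq_len(nrow(members)), key)) {
    # read-pair counts per UMI (mates counted once)
    u <- members$umi[bucket]
    qn <- members$qname[bucket]
    tab <- rowsum(as.integer(!duplicated(qn)), u)
    umis <- rownames(tab)
    counts <- as.integer(tab[, 1])
    comp <- adjacency_components(umis, counts, max_mismatch)
    canonical <- attr(comp, "canonical")
    fam_of_read <- comp[match(u, umis)]
    members$family[bucket] <- next_family + fam_of_read
    members$canonical_umi[bucket] <- canonical[fam_of_read]
    for (cid in seq_along(canonical)) {
      rows <- bucket[fam_of_read == cid]
      fam_rows[[length(fam_rows) + 1L]] <- data.frame(
        family = next_family + cid,
        chrom = members$chrom[rows[1]],
        frag_start = members$frag_start[rows[1]],
        frag_end = members$frag_end[rows[1]],
        orientation = members$orientation[rows[1]],
        canonical_umi = canonical[cid],
        size = length(unique(members$qname[rows])),
        stringsAsFactors = FALSE
      )
    }
    next_family <- next_family + length(canonical)
  }
  families <- if (length(fam_rows)) do.call(rbind, fam_rows) else
    data.frame(family = integer(0), chrom = character(0), frag_start = integer(0),
               frag_end = integer(0), orientation = character(0),
               canonical_umi = character(0), size = integer(0),
               stringsAsFactors = FALSE)
  families <- families[order(families$family), , drop = FALSE]
  rownames(families) <- NULL
  structure(list(members = members, families = families, counters = counters),
            class = "umi_grouping")
}

#' @export
print.umi_grouping <- function(x, ...) {
  cat("UMI grouping:", nrow(x$families), "families from",
      x$counters[["retained"]], "retained reads\n")
  cat("  excluded: unmapped", x$counters[["unmapped"]],
      "| inter-chromosomal", x$counters[["interchrom"]],
      "| low mapq", x$counters[["low_mapq"]], "\n")
  invisible(x)
}

#' Build the consensus read of one UMI family
#'
#' Per reference position over the fragment span, the majority base across
#' member reads is taken; ties give `N` (quality 2) and the consensus base
#' quality is the sum of supporting Phred scores, capped at 60. Families
#' smaller than `min_family_size` read pairs (singletons, by default) are
#' discarded and yield `NULL` -- single-read molecules carry no error
#' correction.
#'
#' @param members Data.frame of member reads of a single family (rows of
#'   `umi_grouping$members` with one `family` value).
#' @param min_family_size Minimum read-pair count to emit a consensus
#'   (default 2).
#' @return One-row consensus data.frame (`chrom`, `start`, `end`, `seq`,
#'   `qual`, `family_size`, `umi`, `orientation`), or `NULL`.
#' @export
build_consensus <- function(members, min_family_size = 2L) {
  stopifnot(nrow(members) >= 1L)
  size <- length(unique(members$qname))
  if (size < min_family_size) return(NULL)
  span_start <- members$frag_start[1]
  span_end <- members$frag_end[1]
  L <- span_end - span_start + 1L
  counts <- matrix(0L, nrow = 4L, ncol = L, dimnames = list(DNA_BASES, NULL))
  qsum <- matrix(0, nrow = 4L, ncol = L, dimnames = list(DNA_BASES, NULL))
  clipped <- 0L
  for (i in seq_len(nrow(members))) {
    bases <- strsplit(members$seq[i], "", fixed = TRUE)[[1]]
    quals <- char_to_phred(members$qual[i])
    at <- members$pos[i] - span_start + seq_along(bases)
    inside <- at >= 1L & at <= L
    if (!all(inside)) clipped <- clipped + 1L
    bi <- match(bases[inside], DNA_BASES)
    at <- at[inside][!is.na(bi)]
    q <- quals[inside][!is.na(bi)]
    bi <- bi[!is.na(bi)]
    idx <- cbind(bi, at)
    # accumulate (duplicate indices possible across reads, not within one)
    counts[idx] <- counts[idx] + 1L
    qsum[idx] <- qsum[idx] + q
  }
  top <- apply(counts, 2L, max)
  n_top <- colSums(counts == rep(top, each = 4L) & counts > 0L)
  winner <- max.col(t(counts), ties.method = "first")
  seq_out <- ifelse(top == 0L | n_top > 1L, "N", DNA_BASES[winner])
  qual_out <- ifelse(seq_out == "N", 2L,
                     pmin(qsum[cbind(winner, seq_len(L))], 60))
  out <- data.frame(
    chrom = members$chrom[1], start = span_start, end = span_end,
    seq = paste0(seq_out, collapse = ""),
    qual = paste0(phred_to_char(qual_out), collapse = ""),
    family_size = size, umi = members$canonical_umi[1] %||% members$umi[1],
    orientation = members$orientation[1], stringsAsFactors = FALSE
  )
  attr(out, "clipped_reads") <- clipped
  out
}

#' UMI-aware deduplication of an aligned read set
#'
#' Groups reads into UMI families ([group_families()]), builds per-family
#' consensus reads ([build_consensus()]) and discards singleton families.
#' This is the error-correction stage the downstream variant caller
#' operates on.
#'
#' @inheritParams group_families
#' @param min_family_size Minimum read pairs per family (default 2).
#' @return List with `consensus` (consensus read data.frame, one row per
#'   retained family), `families` (all families incl. discarded singletons)
#'   and `qc` (named counters: input/retained reads, families, singletons
#'   discarded, mean family size, consensus reads).
#' @export
dedup_readset <- function(reads, max_mismatch = 1L, min_mapq = 20L,
                          min_family_size = 2L) {
  grouping <- group_families(reads, max_mismatch = max_mismatch, min_mapq = min_mapq)
  fams <- split(seq_len(nrow(grouping$members)), grouping$members$family)
  cons <- lapply(fams, function(rows) {
    build_consensus(grouping$members[rows, , drop = FALSE],
                    min_family_size = min_family_size)
  })
  cons <- cons[!vapply(cons, is.null, logical(1))]
  consensus <- if (length(cons)) do.call(rbind, cons) else data.frame(
    chrom = character(0), start = integer(0), end = integer(0),
    seq = character(0), qual = character(0), family_size = integer(0),
    umi = character(0), orientation = character(0), stringsAsFactors = FALSE)
  consensus <- consensus[order(consensus$chrom, consensus$start), , drop = FALSE]
  rownames(consensus) <- NULL
  n_fam <- nrow(grouping$families)
  qc <- c(grouping$counters,
          families = n_fam,
          singletons_discarded = sum(grouping$families$size < min_family_size),
          consensus_reads = nrow(consensus),
          mean_family_size = if (n_fam) mean(grouping$families$size) else NA_real_)
  list(consensus = consensus, families = grouping$families, qc = qc)
}
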