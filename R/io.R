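# File-format edges: SAM (via Rsamtools), BED (via rtracklayer), minimal
# VCF 4.2 output, and the TSV tables consumed by the filters.

#' Read target regions from a BED file
#'
#' @param path BED file (0-based half-open intervals).
#' @return data.frame of 1-based inclusive intervals (`chrom`, `start`,
#'   `end`, `name` when present).
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr),
                    end = GenomicRanges::end(gr), stringsAsFactors = FALSE)
  nm <- gr$name
  if (!is.null(nm)) out$name <- nm
  out
}

#' Write target regions to a BED file
#'
#' @param regions data.frame of 1-based inclusive intervals.
#' @param path Output BED path.
#' @export
write_bed <- function(regions, path) {
  regions <- validate_regions(regions)
  gr <- GenomicRanges::GRanges(
    regions$chrom, IRanges::IRanges(regions$start, regions$end),
    name = if ("name" %in% names(regions)) regions$name else
      paste0("target", seq_len(nrow(regions)))
  )
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

sam_header <- function(contig_lengths) {
  c("@HD\tVN:1.6\tSO:unknown",
    sprintf("@SQ\tSN:%s\tLN:%d", names(contig_lengths),
            as.integer(contig_lengths)))
}

contig_lengths_from <- function(chrom, end) {
  tapply(end, chrom, max) + 1000L
}

#' Write aligned reads or consensus reads as SAM
#'
#' Raw read pairs (data.frames with `qname`/`strand`/`first_in_pair`
#' columns) are written as paired records; consensus reads (with
#' `family_size`) as single-end records carrying the canonical UMI in the
#' `RX` tag, the family size in `cD:i` and the family orientation in
#' `cO:A`.
#'
#' @param x Read or consensus data.frame.
#' @param path Output SAM path.
#' @param contig_lengths Optional named vector of contig lengths for the
#'   header (derived from the data when omitted).
#' @return The path, invisibly.
#' @export
write_sam <- function(x, path, contig_lengths = NULL) {
  is_consensus <- "family_size" %in% names(x)
  if (is_consensus) {
    contig_lengths <- contig_lengths %||% contig_lengths_from(x$chrom, x$end)
    rec <- sprintf("cons%06d:%s\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s\tRX:Z:%s\tcD:i:%d\tcO:A:%s",
                   seq_len(nrow(x)), x$umi, x$chrom, x$start, nchar(x$seq),
                   x$seq, x$qual, x$umi, x$family_size, x$orientation)
  } else {
    stop_if_not_df_with(x, c("qname", "chrom", "pos", "mapq", "strand",
                             "first_in_pair", "mate_pos", "tlen", "seq",
                             "qual"), "reads")
    contig_lengths <- contig_lengths %||%
      contig_lengths_from(x$chrom, x$pos + nchar(x$seq))
    flag <- 1L + 2L +
      ifelse(x$strand == "-", 16L, 0L) + ifelse(x$strand == "-", 0L, 32L) +
      ifelse(x$first_in_pair, 64L, 128L)
    rec <- sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t=\t%d\t%d\t%s\t%s\tRX:Z:%s",
                   x$qname, flag, x$chrom, x$pos, x$mapq, nchar(x$seq),
                   x$mate_pos, x$tlen, x$seq, x$qual, x$umi)
  }
  writeLines(c(sam_header(contig_lengths), rec), path)
  invisible(path)
}

scan_sam <- function(path, tags) {
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(bam))
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "mrnm", "mpos",
             "isize", "seq", "qual"),
    tag = tags
  )
  Rsamtools::scanBam(bam, param = param)[[1]]
}

#' Read aligned reads from SAM/BAM
#'
#' @param path SAM (or BAM) file; UMIs are taken from the `RX` tag when
#'   present, otherwise from the terminal read-name token.
#' @param umi_len UMI length used for read-name extraction.
#' @return Aligned read data.frame (as produced by
#'   [simulate_umi_readset()]).
#' @export
read_sam <- function(path, umi_len = 8L) {
  b <- scan_sam(path, tags = c("RX"))
  flag <- b$flag
  umi <- b$tag$RX
  if (is.null(umi) || all(is.na(umi))) {
    umi <- extract_umi(b$qname, umi_len)$umi
  }
  data.frame(
    qname = b$qname, umi = umi, chrom = as.character(b$rname),
    pos = b$pos, mapq = b$mapq,
    strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
    first_in_pair = bitwAnd(flag, 64L) > 0L,
    mate_chrom = as.character(b$mrnm), mate_pos = b$mpos, tlen = b$isize,
    seq = as.character(b$seq), qual = as.character(b$qual),
    stringsAsFactors = FALSE
  )
}

#' Read consensus reads from SAM/BAM
#'
#' Counterpart of [write_sam()] for consensus read sets (tags `RX`, `cD`,
#' `cO`).
#' @param path SAM (or BAM) file.
#' @return Consensus read data.frame.
#' @export
read_consensus_sam <- function(path) {
  b <- scan_sam(path, tags = c("RX", "cD", "cO"))
  seqs <- as.character(b$seq)
  data.frame(
    chrom = as.character(b$rname), start = b$pos,
    end = b$pos + nchar(seqs) - 1L, seq = seqs, qual = as.character(b$qual),
    family_size = b$tag$cD, umi = b$tag$RX, orientation = b$tag$cO,
    stringsAsFactors = FALSE
  )
}

#' Write variant candidates as VCF 4.2
#'
#' One record per candidate; failed screening filters go to the FILTER
#' column, depth/alt/VAF/SNR/mean-read-position (and, when present,
#' double-strand support) to INFO.
#'
#' @param candidates A `variant_candidates` data.frame (screened, filtered
#'   and/or confirmed).
#' @param path Output VCF path.
#' @param sample Sample name recorded in the header.
#' @return The path, invisibly.
#' @export
write_vcf <- function(candidates, path, sample = "sample") {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=duplexplasma",
    sprintf("##sample=%s", sample),
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Consensus read depth\">",
    "##INFO=<ID=AC,Number=1,Type=Integer,Description=\"Alt consensus reads\">",
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Variant allele fraction\">",
    "##INFO=<ID=SNR,Number=1,Type=Float,Description=\"Signal-to-noise ratio\">",
    "##INFO=<ID=MRP,Number=1,Type=Float,Description=\"Mean variant position from nearer read end\">",
    "##INFO=<ID=DS,Number=0,Type=Flag,Description=\"Double-strand (duplex) support\">",
    "##INFO=<ID=DP2,Number=1,Type=Integer,Description=\"Duplex supporting pair count\">",
    "##FILTER=<ID=min_cov,Description=\"Coverage below threshold\">",
    "##FILTER=<ID=min_alt,Description=\"Too few alt consensus reads\">",
    "##FILTER=<ID=min_snr,Description=\"Signal-to-noise ratio below threshold\">",
    "##FILTER=<ID=min_mean_pos,Description=\"Variant too close to read ends\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  if (nrow(candidates)) {
    info <- sprintf("DP=%d;AC=%d;AF=%.6g;SNR=%.6g;MRP=%.6g",
                    candidates$depth, candidates$alt_count, candidates$vaf,
                    candidates$snr, candidates$mean_read_pos)
    if ("ds_pairs" %in% names(candidates)) {
      info <- paste0(info, sprintf(";DS;DP2=%d", candidates$ds_pairs))
    }
    filt <- ifelse(candidates$filter_status == "", "PASS",
                   candidates$filter_status)
    rec <- sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\t%s", candidates$chrom,
                   candidates$pos, candidates$ref, candidates$alt, filt, info)
  } else {
    rec <- character(0)
  }
  writeLines(c(hdr, rec), path)
  invisible(path)
}

read_checked_tsv <- function(path, required, what) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stop_if_not_df_with(df, required, what)
  df
}

#' Read a variant set (panel-of-normals member or patient call set)
#' @param path TSV with columns `chrom`, `pos`, `ref`, `alt` (extra columns
#'   such as `vaf` are kept).
#' @return data.frame.
#' @export
read_variant_set <- function(path) {
  read_checked_tsv(path, c("chrom", "pos", "ref", "alt"), basename(path))
}

#' Read a variant-impact annotation table
#'
#' @param path TSV with columns `chrom`, `pos`, `ref`, `alt`, `impact`
#'   (labels such as HIGH/MODERATE/LOW/MODIFIER). Rows with a non-numeric
#'   position or empty impact are rejected with their line numbers.
#' @return data.frame.
#' @export
read_impact_table <- function(path) {
  df <- read_checked_tsv(path, c("chrom", "pos", "ref", "alt", "impact"),
                         basename(path))
  bad <- which(is.na(suppressWarnings(as.integer(df$pos))) |
                 is.na(df$impact) | df$impact == "")
  if (length(bad)) {
    stop("malformed annotation row(s) in ", basename(path), " at line(s) ",
         paste(bad + 1L, collapse = ", "))
  }
  df$pos <- as.integer(df$pos)
  df
}

#' Read matched-normal per-site counts
#' @param path TSV with columns `chrom`, `pos`, `alt_reads`, `coverage`
#'   (mpileup-style tally of the buffy coat).
#' @return data.frame.
#' @export
read_normal_counts <- function(path) {
  read_checked_tsv(path, c("chrom", "pos", "alt_reads", "coverage"),
                   basename(path))
}

#' Read a per-target coverage table
#' @param path TSV with columns `gene`, `target`, `length`, `mean_cov`.
#' @return data.frame.
#' @export
read_coverage_table <- function(path) {
  read_checked_tsv(path, c("gene", "target", "length", "mean_cov"),
                   basename(path))
}

#' Write a data.frame as TSV
#' @param df data.frame.
#' @param path Output path.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
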