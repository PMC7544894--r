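# Shared fixtures and independent oracles, built in code.

# One aligned read row (unpaired unless mate fields are given).
make_read <- function(qname, umi, chrom = "chr1", pos = 100L, mapq = 60L,
                      strand = "+", first_in_pair = TRUE,
                      mate_chrom = NA_character_, mate_pos = NA_integer_,
                      tlen = 0L, seq = strrep("A", 50L), qual = NULL) {
  data.frame(qname = qname, umi = umi, chrom = chrom, pos = as.integer(pos),
             mapq = as.integer(mapq), strand = strand,
             first_in_pair = first_in_pair, mate_chrom = mate_chrom,
             mate_pos = as.integer(mate_pos), tlen = as.integer(tlen),
             seq = seq, qual = qual %||% strrep("I", nchar(seq)),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A proper read pair sharing fragment coordinates.
make_pair <- function(qname, umi, chrom = "chr1", frag_start = 100L,
                      frag_len = 160L, orientation = "F", read_len = 80L,
                      mapq = 60L, seq1 = NULL, seq2 = NULL) {
  frag_end <- frag_start + frag_len - 1L
  eff <- min(read_len, frag_len)
  p1 <- frag_start
  p2 <- frag_end - eff + 1L
  rbind(
    make_read(qname, umi, chrom, p1, mapq, "+", orientation == "F",
              chrom, p2, frag_len, seq1 %||% strrep("A", eff)),
    make_read(qname, umi, chrom, p2, mapq, "-", orientation == "R",
              chrom, p1, -frag_len, seq2 %||% strrep("A", eff))
  )
}

# One consensus read row.
make_cons <- function(chrom = "chr1", start = 100L, seq = strrep("A", 100L),
                      umi = "ACGTACGT", orientation = "F", family_size = 3L,
                      qual = NULL) {
  data.frame(chrom = chrom, start = as.integer(start),
             end = as.integer(start + nchar(seq) - 1L), seq = seq,
             qual = qual %||% strrep(rawToChar(as.raw(60L + 33L)), nchar(seq)),
             family_size = as.integer(family_size), umi = umi,
             orientation = orientation, stringsAsFactors = FALSE)
}

# Reference object for hand-built fixtures: a single contig string.
make_reference <- function(seq, chrom = "chr1", offset = 1L) {
  stats::setNames(list(list(offset = as.integer(offset), seq = seq)), chrom)
}

# --- independent oracles -----------------------------------------------------

oracle_hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# Brute-force adjacency partition: explicit directed edge matrix + repeated
# transitive expansion from the highest-count unassigned node.
oracle_adjacency_partition <- function(umis, counts, mm = 1L) {
  n <- length(umis)
  edge <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && oracle_hamming(umis[i], umis[j]) <= mm &&
          counts[i] >= 2L * counts[j] - 1L) {
        edge[i, j] <- TRUE
      }
    }
  }
  unassigned <- rep(TRUE, n)
  groups <- list()
  while (any(unassigned)) {
    cand <- which(unassigned)
    seed <- cand[order(-counts[cand], umis[cand])][1]
    members <- seed
    repeat {
      reach <- which(unassigned & !(seq_len(n) %in% members) &
                       apply(edge[members, , drop = FALSE], 2L, any))
      if (!length(reach)) break
      members <- c(members, reach)
    }
    unassigned[members] <- FALSE
    groups[[length(groups) + 1L]] <- sort(umis[members])
  }
  groups
}

# canonical form of a partition for set comparison
partition_sets <- function(groups) {
  s <- lapply(unname(groups), function(g) sort(unname(g)))
  s[order(vapply(s, `[`, character(1), 1L))]
}

# cohort concordance fixture rows
concord_row <- function(n, primary_alt, met_alt, primary_cov = 200L,
                        met_cov = 200L) {
  data.frame(vaf = stats::runif(n, 0.005, 0.2),
             primary_cov = primary_cov, primary_alt = primary_alt,
             met_cov = met_cov, met_alt = met_alt, stringsAsFactors = FALSE)
}

# Brute-force duplex check: enumerate all supporter pairs.
oracle_duplex <- function(supporters, mode = "endpoints") {
  n <- nrow(supporters)
  if (n < 2L) return(FALSE)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      same <- if (mode == "endpoints") {
        supporters$frag_start[i] == supporters$frag_start[j] &&
          supporters$frag_end[i] == supporters$frag_end[j]
      } else {
        supporters$frag_start[i] == supporters$frag_start[j]
      }
      if (same && supporters$orientation[i] != supporters$orientation[j] &&
          supporters$umi[i] != supporters$umi[j]) {
        return(TRUE)
      }
    }
  }
  FALSE
}

char_to_phred_test <- function(s) utf8ToInt(s) - 33L

random_umi_test <- function() {
  paste0(sample(c("A", "C", "G", "T"), 8, TRUE), collapse = "")
}

# small flat region table
region1 <- function(pos = 1000L, chrom = "chr1") {
  data.frame(chrom = chrom, start = as.integer(pos), end = as.integer(pos),
             stringsAsFactors = FALSE)
}
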