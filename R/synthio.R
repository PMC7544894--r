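# Synthetic fixture generation: UMI-tagged panel reads, consensus read sets,
# spiked variants, per-target coverage tables and fragment-length mixtures,
# all seeded and accompanied by ground-truth ledgers.

#' Specify a variant to spike into simulated reads
#'
#' @param chrom Contig name.
#' @param pos 1-based position.
#' @param ref,alt Single reference / alternate bases (must differ).
#' @param vaf Variant allele fraction in `[0, 1]`: the probability that a
#'   simulated molecule covering `pos` carries the alternate allele.
#' @param duplex If `TRUE`, each alternate molecule is emitted as two read
#'   families with identical fragment coordinates, opposite orientation and
#'   distinct UMIs -- the configuration required by double-strand
#'   confirmation. If `FALSE`, the spike emulates a single-strand artifact:
#'   all alternate families share one orientation and can never be
#'   duplex-confirmed.
#' @return A one-row data.frame; rows from several calls can be `rbind`-ed
#'   into a spike table.
#' @seealso [simulate_umi_readset()], [simulate_consensus_readset()]
#' @export
spike_spec <- function(chrom, pos, ref, alt, vaf, duplex = FALSE) {
  out <- data.frame(
    chrom = as.character(chrom), pos = as.integer(pos),
    ref = as.character(ref), alt = as.character(alt),
    vaf = as.numeric(vaf), duplex = as.logical(duplex),
    stringsAsFactors = FALSE
  )
  validate_spikes(out)
}

validate_spikes <- function(spikes) {
  if (is.null(spikes) || nrow(spikes) == 0L) return(spikes)
  stop_if_not_df_with(spikes, c("chrom", "pos", "ref", "alt", "vaf", "duplex"), "spikes")
  if (any(spikes$vaf < 0 | spikes$vaf > 1)) stop("spike vaf must lie in [0, 1]")
  if (!all(spikes$ref %in% DNA_BASES) || !all(spikes$alt %in% DNA_BASES)) {
    stop("spike ref/alt must be single bases in {A,C,G,T}")
  }
  if (any(spikes$ref == spikes$alt)) stop("spike ref and alt must differ")
  site <- paste(spikes$chrom, spikes$pos)
  if (anyDuplicated(site)) {
    stop("conflicting spikes at the same site: ", site[duplicated(site)][1])
  }
  spikes
}

#' Specify a fragment-length mixture
#'
#' Truncated Gaussian mixture over cfDNA fragment lengths. The default is a
#' mono/di-nucleosomal mixture (85% at 167 +/- 10 bp, 15% at 320 +/- 25 bp,
#' truncated to 50-500 bp), the canonical shape of healthy plasma cfDNA.
#'
#' @param weights Component weights (normalized to sum to 1; must be > 0).
#' @param means,sds Component means and standard deviations in bp. Standard
#'   deviations are floored at 1 bp.
#' @param min_len,max_len Truncation bounds in bp.
#' @return An object of class `fragment_mixture_spec`.
#' @export
fragment_mixture_spec <- function(weights = c(0.85, 0.15),
                                  means = c(167, 320),
                                  sds = c(10, 25),
                                  min_len = 50L, max_len = 500L) {
  if (length(weights) != length(means) || length(means) != length(sds)) {
    stop("weights, means and sds must have equal length")
  }
  if (any(weights <= 0)) stop("mixture weights must be positive")
  if (min_len >= max_len) stop("min_len must be smaller than max_len")
  structure(
    list(weights = weights / sum(weights), means = as.numeric(means),
         sds = pmax(as.numeric(sds), 1), min_len = as.integer(min_len),
         max_len = as.integer(max_len)),
    class = "fragment_mixture_spec"
  )
}

#' @export
print.fragment_mixture_spec <- function(x, ...) {
  cat("Fragment-length mixture (", length(x$weights), " components, ",
      x$min_len, "-", x$max_len, " bp):\n", sep = "")
  for (i in seq_along(x$weights)) {
    cat(sprintf("  %.2f x Normal(%g, %g)\n", x$weights[i], x$means[i], x$sds[i]))
  }
  invisible(x)
}

# CDF of the truncated, rounded mixture at integer length l (P(length <= l)).
# Exported for use as an analytic oracle against sampled data.
#' Mixture CDF of a fragment-length specification
#'
#' Probability that a simulated fragment length is `<= l`, accounting for
#' truncation to `[min_len, max_len]`. Useful as an analytic reference when
#' checking empirical short-fragment fractions or bin masses.
#' @param spec A [fragment_mixture_spec()].
#' @param l Length threshold(s) in bp.
#' @return Numeric vector of probabilities.
#' @export
fragment_mixture_cdf <- function(spec, l) {
  stopifnot(inherits(spec, "fragment_mixture_spec"))
  # lengths are rounded to integers then truncated; use the continuous CDF
  # at l + 0.5 (rounding boundary), renormalized to the truncation interval
  cdf <- function(q) {
    sapply(q, function(qi) sum(spec$weights * stats::pnorm(qi, spec$means, spec$sds)))
  }
  lo <- cdf(spec$min_len - 0.5)
  hi <- cdf(spec$max_len + 0.5)
  pmin(pmax((cdf(l + 0.5) - lo) / (hi - lo), 0), 1)
}

#' Simulate cfDNA fragment lengths
#'
#' Draws integer fragment lengths from a truncated Gaussian mixture by
#' component sampling with rejection outside the truncation bounds.
#'
#' @param spec A [fragment_mixture_spec()].
#' @param n Number of lengths (`>= 0`).
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used.
#' @return Integer vector of `n` lengths in `[min_len, max_len]`.
#' @export
simulate_fragment_lengths <- function(spec, n, seed = NULL) {
  stopifnot(inherits(spec, "fragment_mixture_spec"), n >= 0)
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n)
  if (n == 0L) return(integer(0))
  out <- integer(n)
  todo <- seq_len(n)
  while (length(todo)) {
    comp <- sample.int(length(spec$weights), length(todo), replace = TRUE,
                       prob = spec$weights)
    draw <- as.integer(round(stats::rnorm(length(todo), spec$means[comp], spec$sds[comp])))
    ok <- draw >= spec$min_len & draw <= spec$max_len
    out[todo[ok]] <- draw[ok]
    todo <- todo[!ok]
  }
  out
}

#' Specify a coverage simulation for CNV fixtures
#'
#' @param targets data.frame with columns `gene`, `target`, `length`
#'   (target length in bp).
#' @param baseline_mean Expected mean coverage per target (> 0).
#' @param dispersion Negative-binomial overdispersion `d` with
#'   `var = mu + d * mu^2`; `d = 0` yields deterministic coverage equal to
#'   the expectation.
#' @param amplified Named numeric vector mapping gene -> fold-change (> 0)
#'   applied to the case sample only.
#' @param seed Integer seed.
#' @return An object of class `coverage_sim_spec`.
#' @export
coverage_sim_spec <- function(targets, baseline_mean = 500, dispersion = 0.02,
                              amplified = NULL, seed = 1L) {
  stop_if_not_df_with(targets, c("gene", "target", "length"), "targets")
  if (nrow(targets) == 0L) stop("target list must be nonempty")
  if (anyDuplicated(targets$target)) stop("target ids must be unique")
  if (baseline_mean <= 0) stop("baseline_mean must be > 0")
  if (dispersion < 0) stop("dispersion must be >= 0")
  amplified <- amplified %||% numeric(0)
  if (length(amplified) && (is.null(names(amplified)) || any(amplified <= 0))) {
    stop("amplified must be a named vector of positive fold-changes")
  }
  structure(
    list(targets = targets, baseline_mean = baseline_mean,
         dispersion = dispersion, amplified = amplified,
         seed = as.integer(seed)),
    class = "coverage_sim_spec"
  )
}

#' Simulate per-target coverage tables for CNV calling
#'
#' Generates one case coverage table and `n_controls` control tables. Every
#' sample draws per-target coverage from a negative-binomial with a shared
#' baseline expectation (modulated by target length); genes in
#' `spec$amplified` have their case expectation multiplied by the
#' fold-change.
#'
#' @param spec A [coverage_sim_spec()].
#' @param n_controls Number of control samples (`>= 1`).
#' @return List with `case` (coverage data.frame: gene, target, length,
#'   mean_cov), `controls` (list of coverage data.frames) and `truth`
#'   (the amplified fold-changes used).
#' @export
simulate_coverage_tables <- function(spec, n_controls) {
  stopifnot(inherits(spec, "coverage_sim_spec"), n_controls >= 1)
  set.seed(spec$seed)
  tg <- spec$targets
  # expectation scales weakly with target length around its mean
  mu0 <- spec$baseline_mean * tg$length / mean(tg$length)
  draw <- function(mu) {
    if (spec$dispersion == 0) return(mu)
    stats::rnbinom(length(mu), size = 1 / spec$dispersion, mu = mu)
  }
  fold <- rep(1, nrow(tg))
  hit <- tg$gene %in% names(spec$amplified)
  fold[hit] <- spec$amplified[tg$gene[hit]]
  mk <- function(mu, id) {
    data.frame(gene = tg$gene, target = tg$target, length = tg$length,
               mean_cov = draw(mu), sample = id, stringsAsFactors = FALSE)
  }
  list(
    case = mk(mu0 * fold, "case"),
    controls = lapply(seq_len(n_controls), function(i) mk(mu0, paste0("control", i))),
    truth = list(amplified = spec$amplified, baseline_mean = spec$baseline_mean)
  )
}

# ---- reference sequence handling -------------------------------------------

# Build random reference sequences covering `regions` (plus padding), with
# spike reference bases forced. Returns a named list: chrom -> list(offset, seq).
build_reference <- function(regions, spikes, pad) {
  ref <- list()
  for (ch in unique(regions$chrom)) {
    r <- regions[regions$chrom == ch, , drop = FALSE]
    offset <- max(1L, min(r$start) - as.integer(pad))
    len <- max(r$end) + as.integer(pad) - offset + 1L
    s <- random_sequence(len)
    if (!is.null(spikes) && nrow(spikes)) {
      sp <- spikes[spikes$chrom == ch, , drop = FALSE]
      if (nrow(sp)) {
        off <- sp$pos - offset + 1L
        if (any(off < 1L | off > len)) stop("spike position outside reference span")
        # many positions within one string: go through a character array
        bases <- strsplit(s, "", fixed = TRUE)[[1]]
        bases[off] <- sp$ref
        s <- paste0(bases, collapse = "")
      }
    }
    ref[[ch]] <- list(offset = offset, seq = s)
  }
  ref
}

#' Look up reference bases
#'
#' @param reference Reference object as returned in the `$reference` slot of
#'   the simulators (named list of `list(offset, seq)` per contig).
#' @param chrom Contig name (scalar).
#' @param pos Integer positions.
#' @return Character vector of bases.
#' @export
ref_base <- function(reference, chrom, pos) {
  r <- reference[[chrom]]
  if (is.null(r)) stop("contig not present in reference: ", chrom)
  off <- pos - r$offset + 1L
  if (any(off < 1L | off > nchar(r$seq))) stop("position outside reference span on ", chrom)
  substring(r$seq, off, off)
}

# ---- molecule layer --------------------------------------------------------

validate_regions <- function(regions) {
  stop_if_not_df_with(regions, c("chrom", "start", "end"), "regions")
  if (any(regions$end < regions$start)) stop("region end < start")
  regions
}

# Draw `depth` molecules per region, assign spikes, expand duplex alt
# molecules into two opposite-orientation families. Uses the caller's RNG
# stream. Returns a data.frame of families (one consensus-read-to-be each).
simulate_molecules <- function(regions, depth, spikes, fragment_mixture, umi_len = 8L) {
  cols <- c("molecule", "chrom", "frag_start", "frag_end", "orientation", "umi")
  empty <- data.frame(molecule = integer(0), chrom = character(0),
                      frag_start = integer(0), frag_end = integer(0),
                      orientation = character(0), umi = character(0),
                      stringsAsFactors = FALSE)
  empty$alt_spike <- integer(0)
  if (depth == 0L || nrow(regions) == 0L) return(empty)

  pieces <- vector("list", nrow(regions))
  for (i in seq_len(nrow(regions))) {
    rg <- regions[i, ]
    n <- as.integer(depth)
    fraglen <- simulate_fragment_lengths(fragment_mixture, n)
    lo <- rg$start - fraglen + 1L
    frag_start <- lo + as.integer(floor(stats::runif(n) * (rg$end - lo + 1L)))
    pieces[[i]] <- data.frame(
      chrom = rg$chrom, frag_start = frag_start,
      frag_end = frag_start + fraglen - 1L,
      orientation = sample(c("F", "R"), n, replace = TRUE),
      umi = random_umis(n, umi_len), stringsAsFactors = FALSE
    )
  }
  mols <- do.call(rbind, pieces)
  mols <- cbind(molecule = seq_len(nrow(mols)), mols)
  mols$alt_spike <- NA_integer_   # index into the spike table, NA = wild type

  if (!is.null(spikes) && nrow(spikes)) {
    for (s in seq_len(nrow(spikes))) {
      cover <- which(mols$chrom == spikes$chrom[s] &
                     mols$frag_start <= spikes$pos[s] &
                     mols$frag_end >= spikes$pos[s] &
                     is.na(mols$alt_spike))
      if (!length(cover)) next
      take <- cover[stats::runif(length(cover)) < spikes$vaf[s]]
      mols$alt_spike[take] <- s
      # non-duplex spikes emulate single-strand artifacts: all alt families
      # share one orientation, so they can never gain double-strand support
      if (!spikes$duplex[s]) mols$orientation[take] <- "F"
    }
    # duplex spikes: mirror each alt molecule as a second family on the
    # opposite strand with a fresh UMI, same fragment coordinates
    dup <- which(!is.na(mols$alt_spike) & spikes$duplex[mols$alt_spike])
    if (length(dup)) {
      mirror <- mols[dup, , drop = FALSE]
      mirror$orientation <- ifelse(mirror$orientation == "F", "R", "F")
      mirror$umi <- random_umis(nrow(mirror), umi_len)
      mols <- rbind(mols, mirror)
    }
  }
  rownames(mols) <- NULL
  mols[c(cols, "alt_spike")]
}

# Inject per-base substitution errors into sequences (caller's RNG stream).
# Returns the mutated vector; the expected number of errors is
# error_rate * total bases.
inject_errors <- function(seqs, error_rate) {
  if (error_rate <= 0 || !length(seqs)) return(seqs)
  lens <- nchar(seqs)
  total <- sum(lens)
  n_err <- stats::rbinom(1L, total, error_rate)
  if (n_err == 0L) return(seqs)
  idx <- sample.int(length(seqs), n_err, replace = TRUE, prob = lens)
  off <- 1L + as.integer(floor(stats::runif(n_err) * lens[idx]))
  cur <- substr(seqs[idx], off, off)
  newb <- other_base(cur)
  # apply sequentially so repeated hits on one read are all kept
  for (k in seq_len(n_err)) {
    substr(seqs[idx[k]], off[k], off[k]) <- newb[k]
  }
  seqs
}

spike_truth <- function(spikes, mols) {
  if (is.null(spikes) || !nrow(spikes)) {
    return(data.frame(chrom = character(0), pos = integer(0), ref = character(0),
                      alt = character(0), vaf = numeric(0), duplex = logical(0),
                      n_alt_families = integer(0), stringsAsFactors = FALSE))
  }
  spikes$n_alt_families <-
    vapply(seq_len(nrow(spikes)), function(s) sum(mols$alt_spike %in% s), integer(1))
  spikes
}

# ---- consensus-level simulator ---------------------------------------------

#' Simulate an error-corrected (consensus) read set
#'
#' Generates UMI-family consensus reads directly: one read per simulated
#' molecule family, spanning the whole cfDNA fragment. Spiked variants are
#' assigned per molecule at the requested VAF; `duplex = TRUE` spikes emit
#' each alternate molecule as two families with identical fragment
#' coordinates, opposite orientation and distinct UMIs. Substitution errors
#' are applied at the family level (e.g. first-cycle PCR errors that survive
#' consensus), independently per family -- so errors are never coordinated
#' across strands.
#'
#' @param regions data.frame of 1-based inclusive target intervals
#'   (`chrom`, `start`, `end`). Every simulated fragment covers at least one
#'   base of its region; width-1 regions give exact per-site consensus depth.
#' @param depth Number of molecules simulated per region.
#' @param spikes Optional spike table built from [spike_spec()] rows.
#' @param error_rate Per-base family-level substitution error rate.
#' @param seed Optional integer seed.
#' @param fragment_mixture Fragment-length distribution
#'   ([fragment_mixture_spec()]).
#' @param base_qual Constant consensus base quality (capped consensus scores
#'   are near-constant in practice; default 60).
#' @param family_sizes Function `n -> integer vector` of family sizes
#'   (all `>= 2`); default `2 + Poisson(1)`.
#' @param umi_len UMI length in bases.
#' @return List with `consensus` (consensus read data.frame: chrom, start,
#'   end, seq, qual, family_size, umi, orientation), `truth` (molecule and
#'   spike ledgers) and `reference`.
#' @export
simulate_consensus_readset <- function(regions, depth, spikes = NULL,
                                       error_rate = 0, seed = NULL,
                                       fragment_mixture = fragment_mixture_spec(),
                                       base_qual = 60L,
                                       family_sizes = function(n) 2L + stats::rpois(n, 1),
                                       umi_len = 8L) {
  regions <- validate_regions(regions)
  spikes <- validate_spikes(spikes)
  stopifnot(depth >= 0, error_rate >= 0, error_rate < 1)
  if (!is.null(seed)) set.seed(seed)

  reference <- build_reference(regions, spikes, pad = fragment_mixture$max_len)
  mols <- simulate_molecules(regions, depth, spikes, fragment_mixture, umi_len)

  n <- nrow(mols)
  seqs <- character(n)
  for (ch in unique(mols$chrom)) {
    i <- mols$chrom == ch
    r <- reference[[ch]]
    seqs[i] <- substring(r$seq, mols$frag_start[i] - r$offset + 1L,
                         mols$frag_end[i] - r$offset + 1L)
  }
  # spike alternate alleles
  alt <- which(!is.na(mols$alt_spike))
  if (length(alt)) {
    s <- mols$alt_spike[alt]
    off <- spikes$pos[s] - mols$frag_start[alt] + 1L
    seqs[alt] <- substitute_base(seqs[alt], off, spikes$alt[s])
  }
  seqs <- inject_errors(seqs, error_rate)

  consensus <- data.frame(
    chrom = mols$chrom, start = mols$frag_start, end = mols$frag_end,
    seq = seqs, qual = strrep(phred_to_char(base_qual), nchar(seqs)),
    family_size = if (n) as.integer(family_sizes(n)) else integer(0),
    umi = mols$umi, orientation = mols$orientation,
    stringsAsFactors = FALSE
  )
  if (any(consensus$family_size < 2L)) stop("family_sizes must return values >= 2")
  list(consensus = consensus,
       truth = list(molecules = mols, spikes = spike_truth(spikes, mols)),
       reference = reference)
}

# ---- raw read-level simulator ----------------------------------------------

#' Simulate a raw UMI-tagged aligned read set
#'
#' Emulates a targeted-capture cfDNA library: molecules are drawn per target
#' region with nucleosomal fragment lengths, each molecule is amplified into
#' one or more paired-end read copies sharing a UMI (embedded in the read
#' name after the last `:`) and fragment coordinates, and per-base
#' sequencing errors are applied independently per read.
#'
#' @inheritParams simulate_consensus_readset
#' @param reads_per_molecule Either a positive integer (constant copies per
#'   molecule) or a function `n -> integer vector`; default zero-truncated
#'   Poisson with mean 3.
#' @param error_rate Per-base, per-read substitution error rate.
#' @param umi_error_rate Per-base substitution error rate applied to the UMI
#'   of each read pair.
#' @param read_len Read length in bp (paired 2 x `read_len`).
#' @return List with `reads` (aligned read data.frame; one row per mate),
#'   `truth` (molecule + spike ledgers, read-pair counts) and `reference`.
#' @export
simulate_umi_readset <- function(regions, depth, spikes = NULL,
                                 reads_per_molecule = NULL, umi_len = 8L,
                                 error_rate = 0, umi_error_rate = 0,
                                 seed = NULL, read_len = 150L,
                                 fragment_mixture = fragment_mixture_spec()) {
  regions <- validate_regions(regions)
  spikes <- validate_spikes(spikes)
  stopifnot(depth >= 0, error_rate >= 0, error_rate < 1)
  if (!is.null(seed)) set.seed(seed)
  draw_k <- if (is.null(reads_per_molecule)) {
    function(n) as.integer(rztpois(n, 3))
  } else if (is.function(reads_per_molecule)) {
    function(n) as.integer(reads_per_molecule(n))
  } else {
    k0 <- as.integer(reads_per_molecule)
    if (k0 < 1L) stop("reads_per_molecule must be >= 1")
    function(n) rep(k0, n)
  }

  reference <- build_reference(regions, spikes, pad = fragment_mixture$max_len + read_len)
  mols <- simulate_molecules(regions, depth, spikes, fragment_mixture, umi_len)
  mols$n_read_pairs <- if (nrow(mols)) draw_k(nrow(mols)) else integer(0)
  if (any(mols$n_read_pairs < 1L)) stop("reads_per_molecule draws must be >= 1")

  empty_reads <- data.frame(
    qname = character(0), umi = character(0), chrom = character(0),
    pos = integer(0), mapq = integer(0), strand = character(0),
    first_in_pair = logical(0), mate_chrom = character(0),
    mate_pos = integer(0), tlen = integer(0), seq = character(0),
    qual = character(0), stringsAsFactors = FALSE
  )
  if (!nrow(mols)) {
    return(list(reads = empty_reads,
                truth = list(molecules = mols, spikes = spike_truth(spikes, mols)),
                reference = reference))
  }

  # one row per read pair
  pr <- mols[rep(seq_len(nrow(mols)), mols$n_read_pairs), , drop = FALSE]
  pr$rep <- unlist(lapply(mols$n_read_pairs, seq_len), use.names = FALSE)
  fraglen <- pr$frag_end - pr$frag_start + 1L
  eff_len <- pmin(as.integer(read_len), fraglen)

  umi_obs <- inject_errors(pr$umi, umi_error_rate)
  qname <- paste0("m", pr$molecule, "p", pr$rep, ":", umi_obs)

  read_seq <- function(start) {
    out <- character(nrow(pr))
    for (ch in unique(pr$chrom)) {
      i <- pr$chrom == ch
      r <- reference[[ch]]
      out[i] <- substring(r$seq, start[i] - r$offset + 1L,
                          start[i] - r$offset + eff_len[i])
    }
    out
  }
  mate1_pos <- pr$frag_start
  mate2_pos <- pr$frag_end - eff_len + 1L
  seq1 <- read_seq(mate1_pos)
  seq2 <- read_seq(mate2_pos)

  # spike alternate alleles on reads covering the site
  alt <- !is.na(pr$alt_spike)
  if (any(alt)) {
    s <- pr$alt_spike[alt]
    p <- spikes$pos[s]
    off1 <- p - mate1_pos[alt] + 1L
    in1 <- off1 >= 1L & off1 <= eff_len[alt]
    seq1[alt][in1] <- substitute_base(seq1[alt][in1], off1[in1], spikes$alt[s][in1])
    off2 <- p - mate2_pos[alt] + 1L
    in2 <- off2 >= 1L & off2 <= eff_len[alt]
    seq2[alt][in2] <- substitute_base(seq2[alt][in2], off2[in2], spikes$alt[s][in2])
  }
  seq1 <- inject_errors(seq1, error_rate)
  seq2 <- inject_errors(seq2, error_rate)
  quals <- strrep(phred_to_char(40L), eff_len)

  mk_mate <- function(pos, strand, seq, first) {
    data.frame(
      qname = qname, umi = umi_obs, chrom = pr$chrom, pos = pos,
      mapq = 60L, strand = strand, first_in_pair = first,
      mate_chrom = pr$chrom,
      mate_pos = if (strand == "+") mate2_pos else mate1_pos,
      tlen = if (strand == "+") fraglen else -fraglen,
      seq = seq, qual = quals, stringsAsFactors = FALSE
    )
  }
  reads <- rbind(
    mk_mate(mate1_pos, "+", seq1, pr$orientation == "F"),
    mk_mate(mate2_pos, "-", seq2, pr$orientation == "R")
  )
  reads <- reads[order(reads$chrom, reads$pos, reads$qname), , drop = FALSE]
  rownames(reads) <- NULL

  list(reads = reads,
       truth = list(molecules = mols, spikes = spike_truth(spikes, mols),
                    n_read_pairs = sum(mols$n_read_pairs)),
       reference = reference)
}
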