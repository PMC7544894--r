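# Pileup construction and the step-1 screening filters.

ref100 <- function() make_reference(strrep("A", 3000L))

test_that("pileup counts alleles, qualities and read positions", {
  rg <- data.frame(chrom = "chr1", start = 1000L, end = 1002L)

  # no reads: zero depth at every position
  none <- make_cons()[0, ]
  pu <- build_pileup(none, rg, ref100())
  expect_true(all(pu$depth == 0L))
  expect_identical(nrow(pu), 3L)

  # ten identical reads with one alt base at 1001
  alt_seq <- paste0(strrep("A", 50L), "T", strrep("A", 49L))
  cons <- do.call(rbind, lapply(1:10, function(i) {
    make_cons(start = 951L, seq = alt_seq, umi = random_umi_test())
  }))
  pu <- build_pileup(cons, rg, ref100())
  col <- pu[pu$pos == 1001L & pu$allele == "T", ]
  expect_identical(col$depth, 10L)
  expect_identical(col$count, 10L)
  expect_identical(col$hq, 10L)
  # 1001 sits 51 bases from the left end, 50 from the right: nearer end = 50
  expect_equal(col$mean_read_pos, 50)

  expect_error(build_pileup(cons, data.frame(chrom = "chrX", start = 1L, end = 2L),
                            ref100()), "chrX")
})

test_that("pileup alt counts track simulated VAF within binomial noise", {
  sim <- simulate_consensus_readset(region1(), depth = 500,
                                    spikes = spike_spec("chr1", 1000, "A", "T", 0.1),
                                    seed = 9)
  # the reference base at the spike site was forced to the spike ref
  expect_identical(ref_base(sim$reference, "chr1", 1000L), "A")
  pu <- build_pileup(sim$consensus, region1(), sim$reference)
  alt <- pu[pu$allele == "T", ]
  expect_identical(alt$count, sim$truth$spikes$n_alt_families)
  expect_lt(abs(alt$count - 50), 3 * sqrt(500 * 0.1 * 0.9))
  expect_identical(sum(pu$count), pu$depth[1])
})

test_that("screening applies the four filter predicates", {
  mk_col <- function(depth, count, hq, lq, mrp) {
    structure(data.frame(chrom = "chr1", pos = 1L, ref = "A", depth = depth,
                         allele = "T", count = count, hq = hq, lq = lq,
                         mean_bq = 35, mean_read_pos = mrp, fwd = count,
                         rev = 0L, stringsAsFactors = FALSE),
              class = c("pileup", "data.frame"))
  }
  # two alt reads fail the 3-read rule
  expect_false(screen(mk_col(500L, 2L, 2L, 0L, 40))$pass)
  expect_match(screen(mk_col(500L, 2L, 2L, 0L, 40))$filter_status, "min_alt")
  # coverage 99 fails the 100x rule even with many alt reads
  expect_match(screen(mk_col(99L, 10L, 10L, 0L, 40))$filter_status, "min_cov")
  # SNR 10 passes default (>= 4) but fails stringent (>= 20)
  snr10 <- mk_col(500L, 11L, 10L, 1L, 40)
  expect_true(screen(snr10, screen_params("default"))$pass)
  expect_match(screen(snr10, screen_params("stringent"))$filter_status, "min_snr")
  expect_equal(screen(snr10)$snr, 10)
  # mean read position must be strictly greater than the threshold
  expect_match(screen(mk_col(500L, 10L, 10L, 0L, 10))$filter_status, "min_mean_pos")
  expect_true(screen(mk_col(500L, 10L, 10L, 0L, 10.5),
                     screen_params("default"))$pass)
})

test_that("screen matches a brute-force predicate evaluation and conserves VAF", {
  sim <- simulate_consensus_readset(
    data.frame(chrom = "chr1", start = seq(1000L, 4000L, 500L), end = seq(1000L, 4000L, 500L)),
    depth = 150, error_rate = 0.002, seed = 12,
    spikes = spike_spec("chr1", 1500, "A", "G", 0.08)
  )
  rg <- data.frame(chrom = "chr1", start = seq(1000L, 4000L, 500L),
                   end = seq(1000L, 4000L, 500L))
  pu <- build_pileup(sim$consensus, rg, sim$reference)
  for (mode in c("default", "stringent")) {
    p <- screen_params(mode)
    got <- screen(pu, p)
    # independent re-evaluation of the predicates per allele
    want <- pu[pu$allele != pu$ref & pu$allele != "N" & pu$count > 0, ]
    want_pass <- want$depth >= p$min_cov & want$count >= p$min_alt &
      (want$hq / pmax(want$lq, 0.5)) >= p$min_snr &
      want$mean_read_pos > p$min_mean_pos
    expect_identical(got$pass, unname(want_pass))
    expect_equal(got$vaf * got$depth, as.numeric(got$alt_count))
  }
  # stringent pass-set is a subset of the default pass-set
  d <- passing_variants(screen(pu, screen_params("default")))
  s <- passing_variants(screen(pu, screen_params("stringent")))
  key <- function(x) paste(x$chrom, x$pos, x$alt)
  expect_true(all(key(s) %in% key(d)))
})

cand_fixture <- function() {
  screen(structure(
    data.frame(chrom = "chr1", pos = 1:4, ref = "A", depth = 500L,
               allele = c("T", "G", "C", "T"), count = 10L, hq = 10L, lq = 0L,
               mean_bq = 35, mean_read_pos = 40, fwd = 5L, rev = 5L,
               stringsAsFactors = FALSE),
    class = c("pileup", "data.frame")))
}

test_that("panel-of-normals removes variants recurring in >= 2 healthy samples", {
  cand <- cand_fixture()
  healthy <- list(
    data.frame(chrom = "chr1", pos = c(1L, 2L), ref = "A", alt = c("T", "G")),
    data.frame(chrom = "chr1", pos = 2L, ref = "A", alt = "G"),
    data.frame(chrom = "chr1", pos = 9L, ref = "A", alt = "T")
  )
  kept <- filter_panel_of_normals(cand, healthy)
  # pos 1 seen in one healthy sample: kept; pos 2 in two: removed
  expect_setequal(kept$pos, c(1L, 3L, 4L))
})

test_that("impact filter keeps MODERATE/HIGH and drops unannotated", {
  cand <- cand_fixture()
  ann <- data.frame(chrom = "chr1", pos = 1:3, ref = "A",
                    alt = c("T", "G", "C"),
                    impact = c("HIGH", "LOW", "MODIFIER"),
                    stringsAsFactors = FALSE)
  expect_warning(kept <- filter_impact(cand, ann), "without impact")
  expect_identical(kept$pos, 1L)
  ann$impact[2] <- "MODERATE"
  expect_setequal(suppressWarnings(filter_impact(cand, ann))$pos, c(1L, 2L))
  expect_setequal(filter_impact(cand, ann, missing = "keep")$pos, c(1L, 2L, 4L))
})

test_that("matched-normal filter enforces zero alt and 100x normal coverage", {
  cand <- cand_fixture()
  nc <- data.frame(chrom = "chr1", pos = 1:3,
                   alt_reads = c(0L, 1L, 0L), coverage = c(150L, 500L, 99L))
  kept <- filter_matched_normal(cand, nc)
  # pos 2 has normal alt support, pos 3 thin normal coverage, pos 4 no data
  expect_identical(kept$pos, 1L)
})

test_that("cohort filters commute", {
  cand <- cand_fixture()
  healthy <- list(data.frame(chrom = "chr1", pos = 2L, ref = "A", alt = "G"),
                  data.frame(chrom = "chr1", pos = 2L, ref = "A", alt = "G"))
  ann <- data.frame(chrom = "chr1", pos = 1:4, ref = "A",
                    alt = c("T", "G", "C", "T"),
                    impact = c("HIGH", "HIGH", "MODERATE", "LOW"))
  nc <- data.frame(chrom = "chr1", pos = 1:4, alt_reads = 0L,
                   coverage = c(500L, 500L, 80L, 500L))
  perms <- list(c(1, 2, 3), c(3, 2, 1), c(2, 3, 1))
  filters <- list(
    function(x) filter_panel_of_normals(x, healthy),
    function(x) filter_impact(x, ann),
    function(x) filter_matched_normal(x, nc)
  )
  got <- lapply(perms, function(p) {
    out <- cand
    for (i in p) out <- filters[[i]](out)
    sort(out$pos)
  })
  expect_identical(got[[1]], got[[2]])
  expect_identical(got[[1]], got[[3]])
  expect_identical(got[[1]], 1L)
})
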