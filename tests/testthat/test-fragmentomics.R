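# Fragment-length extraction, profiles, pooling, correlation and the
# short-fragment fraction.

test_that("length extraction applies the pair-level filters once per pair", {
  reads <- rbind(
    make_pair("ok", "AAAAAAAA", frag_start = 100L, frag_len = 167L),
    make_pair("lowq", "CCCCCCCC", frag_start = 300L, frag_len = 180L, mapq = 5L),
    make_pair("inter", "GGGGGGGG", frag_start = 700L, frag_len = 150L)
  )
  reads$mate_chrom[reads$qname == "inter"] <- "chr2"
  s <- extract_fragment_lengths(reads, min_mapq = 10L, id = "t")
  expect_identical(s$lengths, 167L)
  expect_identical(unname(s$n_excluded["low_mapq"]), 1L)
  expect_identical(unname(s$n_excluded["interchrom"]), 1L)

  # one mate below the threshold disqualifies the pair
  mixed <- make_pair("m", "AAAAAAAA", frag_start = 100L, frag_len = 167L)
  mixed$mapq <- c(60L, 5L)
  expect_identical(length(extract_fragment_lengths(mixed)$lengths), 0L)

  # TLEN 0 rows never yield a length
  flat <- make_read("z", "AAAAAAAA", tlen = 0L)
  s0 <- extract_fragment_lengths(flat)
  expect_identical(length(s0$lengths), 0L)
  expect_identical(unname(s0$n_excluded["no_tlen"]), 1L)

  # empty input
  expect_identical(extract_fragment_lengths(make_read("x", "AAAAAAAA")[0, ])$n_pairs_total, 0L)

  # region restriction
  rg <- data.frame(chrom = "chr1", start = 90L, end = 120L)
  far <- rbind(make_pair("near", "AAAAAAAA", frag_start = 100L, frag_len = 167L),
               make_pair("far", "CCCCCCCC", frag_start = 5000L, frag_len = 167L))
  sr <- extract_fragment_lengths(far, regions = rg)
  expect_identical(length(sr$lengths), 1L)
  expect_identical(unname(sr$n_excluded["off_target"]), 1L)
})

test_that("profiles are normalized with out-of-range mass accounting", {
  mono <- fragment_sample(rep(167L, 40L))
  p <- build_profile(mono)
  expect_equal(sum(p$density), 1)
  expect_identical(sum(p$density > 0), 1L)
  # the 167 bin is [165, 170)
  expect_identical(which(p$density > 0), which(p$bin_edges == 165L))

  empty <- build_profile(fragment_sample(integer(0)))
  expect_true(all(empty$density == 0))
  expect_identical(empty$n_pairs, 0L)

  # exact conservation: density + out-of-range mass = 1
  set.seed(41)
  s <- fragment_sample(sample(c(30:60, 400:520), 500, TRUE))
  p <- build_profile(s)
  expect_equal(sum(p$density) + p$out_of_range, 1, tolerance = 1e-12)

  # external denominator: unprofiled pairs appear as out-of-range mass
  s2 <- fragment_sample(rep(167L, 30L), n_pairs_total = 60L)
  p2 <- build_profile(s2)
  expect_equal(sum(p2$density), 0.5)
  expect_equal(p2$out_of_range, 0.5)
})

test_that("bin masses match the analytic mixture CDF", {
  mix <- fragment_mixture_spec()
  n <- 50000L
  s <- fragment_sample(simulate_fragment_lengths(mix, n, seed = 42))
  p <- build_profile(s)
  # mass below 250 bp
  below <- sum(p$density[p$bin_edges[-length(p$bin_edges)] < 250])
  want <- fragment_mixture_cdf(mix, 249L)
  expect_lt(abs(below - want), 3 * sqrt(want * (1 - want) / n))
  # profile is bimodal: distinct mono- and di-nucleosomal peaks
  dens <- p$density
  mono_peak <- which.max(dens)
  expect_true(abs(p$bin_edges[mono_peak] - 167) <= 10)
  di <- which(p$bin_edges[-length(p$bin_edges)] >= 280 &
              p$bin_edges[-length(p$bin_edges)] <= 360)
  expect_gt(max(dens[di]), 0.005)
})

test_that("pooling is read-weighted concatenation", {
  mixA <- fragment_mixture_spec()
  mixB <- fragment_mixture_spec(c(0.7, 0.3), c(150, 320), c(12, 25))
  a <- fragment_sample(simulate_fragment_lengths(mixA, 9000, seed = 1), "a")
  b <- fragment_sample(simulate_fragment_lengths(mixB, 1000, seed = 2), "b")

  one <- pool_reference(list(a))
  expect_identical(one$density, build_profile(a)$density)
  twin <- pool_reference(list(a, a))
  expect_equal(twin$density, build_profile(a)$density)

  pool <- pool_reference(list(a, b))
  direct <- build_profile(fragment_sample(c(a$lengths, b$lengths)))
  expect_identical(pool$density, direct$density)
  # 9:1 weighted combination of the per-sample profiles, exactly
  expect_equal(pool$density,
               0.9 * build_profile(a)$density + 0.1 * build_profile(b)$density,
               tolerance = 1e-12)
})

test_that("profile correlation behaves as a Pearson correlation on bins", {
  mix <- fragment_mixture_spec()
  p <- build_profile(fragment_sample(simulate_fragment_lengths(mix, 50000, seed = 3)))
  q <- build_profile(fragment_sample(simulate_fragment_lengths(mix, 50000, seed = 4)))
  expect_equal(profile_correlation(p, p), 1)
  expect_gt(profile_correlation(p, q), 0.99)
  expect_equal(profile_correlation(p, q), profile_correlation(q, p))

  # affine invariance on the density vector
  p2 <- p
  p2$density <- 2 * p$density + 0.001
  expect_equal(profile_correlation(p, p2), 1)

  # mismatched bins and zero variance are rejected
  wide <- build_profile(fragment_sample(rep(167L, 5L)), bin_width = 10L)
  expect_error(profile_correlation(p, wide), "mismatched")
  flat <- p
  flat$density <- rep(0.5, length(p$density))
  expect_warning(r <- profile_correlation(p, flat), "zero-variance")
  expect_true(is.na(r))
})

test_that("deviation score is zero at the reference and grows with the shift", {
  mix <- fragment_mixture_spec()
  ref <- build_profile(fragment_sample(simulate_fragment_lengths(mix, 40000, seed = 5)))
  expect_equal(deviation_score(ref, ref), 0)

  # perfectly anti-correlated profiles reach the upper bound 2
  mk3 <- function(d) structure(
    list(bin_edges = c(0L, 5L, 10L, 15L), density = d, out_of_range = 0,
         range = c(0L, 15L), bin_width = 5L, n_pairs = 10L, id = "x"),
    class = "fragment_profile")
  expect_equal(deviation_score(mk3(c(1, 0, 1) / 2), mk3(c(0, 1, 0))), 2)

  # graded shift towards shorter fragments: monotone deviation
  shifts <- c(167, 160, 150, 140)
  dev <- vapply(seq_along(shifts), function(i) {
    m <- fragment_mixture_spec(c(0.85, 0.15), c(shifts[i], 320), c(10, 25))
    p <- build_profile(fragment_sample(simulate_fragment_lengths(m, 30000, seed = 10 + i)))
    deviation_score(p, ref)
  }, numeric(1))
  expect_true(all(diff(dev) > 0))
})

test_that("short-fragment fraction matches the truncated-CDF oracle", {
  expect_equal(short_fraction(fragment_sample(rep(167L, 10L))), 0)
  expect_equal(short_fraction(fragment_sample(rep(100L, 10L))), 1)
  expect_warning(sf <- short_fraction(fragment_sample(integer(0))), "empty")
  expect_true(is.na(sf))

  mix <- fragment_mixture_spec(c(0.6, 0.4), c(155, 320), c(15, 25))
  n <- 40000L
  s <- fragment_sample(simulate_fragment_lengths(mix, n, seed = 6))
  want <- fragment_mixture_cdf(mix, 149L)
  expect_lt(abs(short_fraction(s) - want), 3 * sqrt(want * (1 - want) / n))
})

test_that("healthy profiles separate from tumour-like shifted profiles", {
  healthy <- fragment_mixture_spec()
  tumour <- fragment_mixture_spec(c(0.45, 0.40, 0.15), c(145, 167, 320),
                                  c(15, 10, 25))
  hp <- lapply(1:5, function(i) {
    build_profile(fragment_sample(simulate_fragment_lengths(healthy, 20000, seed = i)))
  })
  tp <- lapply(1:3, function(i) {
    build_profile(fragment_sample(simulate_fragment_lengths(tumour, 20000, seed = 100 + i)))
  })
  hh <- utils::combn(5, 2, function(ij) profile_correlation(hp[[ij[1]]], hp[[ij[2]]]))
  ht <- outer(1:5, 1:3, Vectorize(function(i, j) profile_correlation(hp[[i]], tp[[j]])))
  expect_gt(min(hh), max(ht))
  expect_gt(min(hh), 0.95)
})
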