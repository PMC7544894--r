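# Log-ratio construction, Gaussian-mixture null estimation, thresholds,
# gene calls and HER2 classification metrics.

toy_targets <- function(n_per = 8L, genes = c("ERBB2", "G1", "G2", "G3")) {
  data.frame(gene = rep(genes, each = n_per),
             target = paste0("t", seq_len(n_per * length(genes))),
             length = 120L, stringsAsFactors = FALSE)
}

test_that("log ratios are zero on identity and follow log2 arithmetic", {
  tab <- toy_targets()
  base <- data.frame(tab, mean_cov = 400, stringsAsFactors = FALSE)
  lr <- compute_log_ratios(base, list(base, base))
  expect_equal(lr$log2_ratio, rep(0, nrow(tab)))

  # noise-free 4x on one gene of a wide panel: closed-form oracle for the
  # fraction-normalized ratio (slightly below 2 because the amplification
  # inflates the case library size)
  wide <- toy_targets(8L, c("ERBB2", paste0("G", 1:12)))
  base <- data.frame(wide, mean_cov = 400, stringsAsFactors = FALSE)
  case <- base
  amp <- case$gene == "ERBB2"
  case$mean_cov[amp] <- 1600
  lr <- compute_log_ratios(case, list(base), pseudo = 0)
  t_case <- sum(case$mean_cov)
  want_amp <- log2((1600 / t_case) / (400 / sum(base$mean_cov)))
  expect_equal(lr$log2_ratio[amp], rep(want_amp, sum(amp)))
  expect_lt(abs(want_amp - 2), 0.35)

  # zero case coverage stays finite through the pseudo-count
  case$mean_cov[1] <- 0
  lr0 <- compute_log_ratios(case, list(base))
  expect_true(all(is.finite(lr0$log2_ratio)))
  expect_lt(lr0$log2_ratio[1], -4)

  bad <- base
  bad$target[1] <- "other"
  expect_error(compute_log_ratios(case, list(bad)), "differ")
})

test_that("EM recovers well-separated components with monotone log-likelihood", {
  set.seed(101)
  x <- c(rnorm(700, 0, 0.1), rnorm(300, 5, 0.1))
  f <- fit_gmm(x, 2, seed = 1)
  expect_true(f$converged)
  expect_lt(abs(f$means[1] - 0), 0.05)
  expect_lt(abs(f$means[2] - 5), 0.05)
  expect_equal(sum(f$weights), 1)
  expect_true(all(diff(f$trace) >= -1e-8))
  expect_equal(f$aic, 2 * (3 * 2 - 1) - 2 * f$loglik)

  # nesting: a 3-component fit cannot do worse than the 2-component fit
  f3 <- fit_gmm(x, 3, seed = 1)
  expect_gte(f3$loglik, f$loglik - 1e-6)

  # order invariance: shuffled input converges to the same optimum
  fs <- fit_gmm(sample(x), 2, seed = 1)
  expect_equal(fs$means, f$means, tolerance = 1e-3)
  expect_equal(fs$weights, f$weights, tolerance = 1e-3)

  # degenerate data is flagged, tiny samples are rejected
  expect_false(fit_gmm(rep(1, 50), 2, seed = 1)$converged)
  expect_error(fit_gmm(rnorm(15), 2), "at least 20")
})

test_that("EM agrees with an independent mixture fitter", {
  suppressMessages(library(mclust))  # Mclust needs its namespace attached
  set.seed(102)
  x <- c(rnorm(400, 0, 0.2), rnorm(100, 1.5, 0.25))
  f <- fit_gmm(x, 2, seed = 1)
  m <- Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(f$loglik, m$loglik, tolerance = 1e-4)
  expect_equal(sort(f$means), sort(as.numeric(m$parameters$mean)),
               tolerance = 0.02)
})

test_that("AIC selection prefers the parsimonious null and recovers its mean", {
  mk_fit <- function(aic, k = 2L, converged = TRUE) {
    structure(list(k = k, weights = rep(1 / k, k), means = seq_len(k),
                   sds = rep(0.1, k), loglik = -aic / 2,
                   aic = aic, converged = converged, n_iter = 5L),
              class = "gaussian_mixture_fit")
  }
  expect_identical(select_null_model(mk_fit(100, 2L), mk_fit(120, 3L))$aic, 100)
  expect_identical(select_null_model(mk_fit(120, 2L), mk_fit(100, 3L))$aic, 100)
  expect_identical(select_null_model(mk_fit(100, 2L), mk_fit(100, 3L))$k, 2L)
  expect_identical(select_null_model(mk_fit(100, 2L, FALSE), mk_fit(300, 3L))$k, 3L)
  expect_error(select_null_model(mk_fit(1, 2L, FALSE), mk_fit(1, 3L, FALSE)),
               "converged")

  # replicated two-component data: the fitted null mean is recovered and
  # AIC prefers the bimodal model in a clear majority of replicates
  n_rep <- 60L
  sel2 <- logical(n_rep); null_ok <- logical(n_rep)
  set.seed(103)
  for (i in seq_len(n_rep)) {
    w <- runif(1, 0.7, 0.95)
    n0 <- round(250 * w)
    x <- c(rnorm(n0, 0, 0.2), rnorm(250 - n0, 1.5, 0.25))
    best <- select_null_model(fit_gmm(x, 2, seed = i), fit_gmm(x, 3, seed = i))
    sel2[i] <- best$k == 2L
    null_ok[i] <- abs(best$means[which.max(best$weights)]) < 0.05
  }
  expect_gte(mean(null_ok), 0.9)
  expect_gte(mean(sel2), 0.7)
})

test_that("thresholds come from the largest-weight component at mean +/- z sd", {
  fit <- structure(list(k = 2L, weights = c(0.7, 0.3), means = c(0, 2),
                        sds = c(0.2, 0.5), loglik = -1, aic = 12,
                        converged = TRUE, n_iter = 3L),
                   class = "gaussian_mixture_fit")
  th <- derive_thresholds(fit, z = 1.96)
  expect_identical(th$null_component, 1L)
  expect_equal(th$gain_cut, 0.392)
  expect_equal(th$loss_cut, -0.392)
  th0 <- derive_thresholds(fit, z = 0)
  expect_identical(th0$gain_cut, th0$loss_cut)
  # largest weight wins regardless of means
  fit$weights <- c(0.3, 0.7)
  expect_identical(derive_thresholds(fit)$null_component, 2L)
})

test_that("scale equivariance: shifting all ratios shifts fit and thresholds", {
  set.seed(104)
  x <- c(rnorm(300, 0, 0.2), rnorm(60, 1.6, 0.2))
  f <- fit_gmm(x, 2, seed = 7)
  fc <- fit_gmm(x + 0.75, 2, seed = 7)
  expect_equal(fc$means, f$means + 0.75, tolerance = 1e-6)
  expect_equal(fc$weights, f$weights, tolerance = 1e-6)
  expect_equal(derive_thresholds(fc)$gain_cut,
               derive_thresholds(f)$gain_cut + 0.75, tolerance = 1e-6)
})

test_that("gene calls and HER2 classification follow the thresholds", {
  th <- structure(list(null_component = 1L, null_mean = 0, null_sd = 0.15,
                       gain_cut = 0.294, loss_cut = -0.294, z = 1.96),
                  class = "cnv_thresholds")
  lr <- structure(data.frame(
    gene = c(rep("ERBB2", 4), rep("G1", 4), rep("G2", 2)),
    target = paste0("t", 1:10),
    log2_ratio = c(rep(1.8, 4), rep(0.01, 4), rep(-2, 2)),
    stringsAsFactors = FALSE), class = c("log_ratio_set", "data.frame"))
  calls <- call_gene_cnv(lr, th)
  expect_identical(calls$state[calls$gene == "ERBB2"], "amplified")
  expect_identical(calls$state[calls$gene == "G1"], "neutral")
  expect_identical(calls$state[calls$gene == "G2"], "no_call")  # 2 targets
  expect_identical(classify_her2(calls), "HER2+")

  lr$log2_ratio[1:4] <- 0
  calls <- call_gene_cnv(lr, th)
  expect_identical(classify_her2(calls), "HER2-")
  expect_error(classify_her2(calls[calls$gene != "ERBB2", ]), "absent")

  # all-zero ratios: everything neutral
  lr$log2_ratio <- 0
  expect_true(all(call_gene_cnv(lr, th, min_targets = 2L)$state == "neutral"))
})

test_that("end-to-end CNV calling detects a simulated ERBB2 amplification", {
  tab <- toy_targets(10L, c("ERBB2", paste0("G", 1:12)))
  cov <- simulate_coverage_tables(
    coverage_sim_spec(tab, baseline_mean = 500, dispersion = 0.02,
                      amplified = c(ERBB2 = 4), seed = 19), 8)
  lr <- compute_log_ratios(cov$case, cov$controls)
  best <- select_null_model(fit_gmm(lr$log2_ratio, 2, seed = 1),
                            fit_gmm(lr$log2_ratio, 3, seed = 1))
  calls <- call_gene_cnv(lr, derive_thresholds(best))
  expect_identical(calls$state[calls$gene == "ERBB2"], "amplified")
  expect_identical(classify_her2(calls), "HER2+")
  expect_true(all(calls$state[calls$gene != "ERBB2"] == "neutral"))
})

test_that("classification metrics match the confusion arithmetic", {
  expect_equal(classification_metrics(12, 3, 18, 2),
               c(precision = 80.0, sensitivity = 85.7, specificity = 85.7))
  expect_equal(unname(classification_metrics(10, 0, 10, 0)), c(100, 100, 100))
  m <- classification_metrics(0, 0, 5, 5)
  expect_true(is.na(m["precision"]))

  # oracle: recompute from labelled prediction lists
  set.seed(105)
  for (i in 1:20) {
    tp <- sample(0:40, 1); fp <- sample(0:40, 1)
    tn <- sample(0:40, 1); fn <- sample(0:40, 1)
    truth <- c(rep(TRUE, tp + fn), rep(FALSE, fp + tn))
    pred <- c(rep(TRUE, tp), rep(FALSE, fn), rep(TRUE, fp), rep(FALSE, tn))
    want <- c(
      precision = if (sum(pred) == 0) NA_real_ else
        round(100 * sum(pred & truth) / sum(pred), 1),
      sensitivity = if (sum(truth) == 0) NA_real_ else
        round(100 * sum(pred & truth) / sum(truth), 1),
      specificity = if (sum(!truth) == 0) NA_real_ else
        round(100 * sum(!pred & !truth) / sum(!truth), 1)
    )
    expect_equal(classification_metrics(tp, fp, tn, fn), want)
  }
})
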