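# Targeted-panel CNV calling by null-distribution estimation: per-target
# log2 coverage ratios, bimodal-vs-trimodal Gaussian mixture fits selected
# by AIC, gain/loss thresholds from the null component, gene-level calls
# and HER2 classification.

#' Per-target log2 coverage ratios against a control baseline
#'
#' Coverages are normalized to per-sample fractions of total on-target
#' coverage; each target's case fraction is compared with the median
#' control fraction. A depth-scaled pseudo-count keeps ratios finite at
#' zero coverage.
#'
#' @param case Coverage data.frame (`gene`, `target`, `length`, `mean_cov`).
#' @param controls List of control coverage data.frames sharing the target
#'   list.
#' @param pseudo Pseudo-count in coverage units (default 0.5), scaled by
#'   each sample's total coverage before entering the ratio.
#' @return data.frame of class `log_ratio_set` (`gene`, `target`,
#'   `log2_ratio`).
#' @export
compute_log_ratios <- function(case, controls, pseudo = 0.5) {
  stop_if_not_df_with(case, c("gene", "target", "mean_cov"), "case")
  if (!length(controls)) stop("at least one control sample is required")
  for (ct in controls) {
    stop_if_not_df_with(ct, c("gene", "target", "mean_cov"), "control")
    miss <- c(setdiff(case$target, ct$target), setdiff(ct$target, case$target))
    if (length(miss)) {
      stop("case/control target lists differ: ",
           paste(utils::head(miss, 5), collapse = ", "))
    }
  }
  case_total <- sum(case$mean_cov)
  if (case_total <= 0) stop("case sample has zero total coverage")
  case_frac <- case$mean_cov / case_total
  ctrl_frac <- vapply(controls, function(ct) {
    ct$mean_cov[match(case$target, ct$target)] / sum(ct$mean_cov)
  }, numeric(nrow(case)))
  ctrl_frac <- if (is.matrix(ctrl_frac)) apply(ctrl_frac, 1L, stats::median) else ctrl_frac
  p_case <- pseudo / case_total
  p_ctrl <- pseudo / stats::median(vapply(controls, function(ct) sum(ct$mean_cov), numeric(1)))
  out <- data.frame(gene = case$gene, target = case$target,
                    log2_ratio = log2((case_frac + p_case) / (ctrl_frac + p_ctrl)),
                    stringsAsFactors = FALSE)
  class(out) <- c("log_ratio_set", "data.frame")
  out
}

# k-means++ seeding: first centre uniform, later centres with probability
# proportional to squared distance from the nearest chosen centre.
kmeanspp_centers <- function(x, k) {
  centers <- numeric(k)
  centers[1] <- x[sample.int(length(x), 1L)]
  if (k > 1L) {
    d2 <- (x - centers[1])^2
    for (j in 2:k) {
      centers[j] <- if (all(d2 == 0)) x[sample.int(length(x), 1L)] else
        x[sample.int(length(x), 1L, prob = d2)]
      d2 <- pmin(d2, (x - centers[j])^2)
    }
  }
  centers
}

# component-wise log densities, n x k
gmm_log_comp <- function(x, w, mu, sd) {
  vapply(seq_along(w), function(j) {
    log(w[j]) + stats::dnorm(x, mu[j], sd[j], log = TRUE)
  }, numeric(length(x)))
}

gmm_loglik <- function(x, w, mu, sd) {
  comp <- matrix(gmm_log_comp(x, w, mu, sd), nrow = length(x))
  m <- do.call(pmax, as.data.frame(comp))
  sum(m + log(rowSums(exp(comp - m))))
}

em_once <- function(x, k, max_iter, tol, var_floor) {
  mu <- kmeanspp_centers(x, k)
  sd <- rep(max(stats::sd(x), sqrt(var_floor)), k)
  w <- rep(1 / k, k)
  ll_old <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    # E step (log-space responsibilities)
    lp <- matrix(gmm_log_comp(x, w, mu, sd), nrow = length(x))
    m <- do.call(pmax, as.data.frame(lp))
    lse <- m + log(rowSums(exp(lp - m)))
    ll <- sum(lse)
    r <- exp(lp - lse)
    # M step
    nk <- pmax(colSums(r), 1e-8)
    w <- nk / sum(nk)
    mu <- colSums(r * x) / nk
    sd <- sqrt(pmax(colSums(r * (x - rep(mu, each = length(x)))^2) / nk, var_floor))
    trace <- c(trace, ll)
    if (is.finite(ll_old) && ll - ll_old < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  list(w = w, mu = mu, sd = sd, loglik = ll, n_iter = it,
       converged = converged, trace = trace)
}

#' Fit a k-component Gaussian mixture by EM
#'
#' Expectation-maximization with k-means++ seeding, multiple restarts
#' (best log-likelihood kept), a variance floor, and convergence when the
#' log-likelihood improves by less than `tol`. Components are reported in
#' increasing order of mean. `aic = 2 * (3k - 1) - 2 * loglik`.
#'
#' @param values Numeric observations (at least `10 * k`).
#' @param k Component count (2 or 3 for the CNV null model).
#' @param seed Integer seed for the restart initializations.
#' @param max_iter,tol EM iteration cap and convergence tolerance.
#' @param n_restarts Number of k-means++ restarts (default 5).
#' @param var_floor Variance floor (default 1e-4).
#' @return Object of class `gaussian_mixture_fit`: `k`, `weights`, `means`,
#'   `sds`, `loglik`, `aic`, `converged`, `n_iter` and the per-iteration
#'   log-likelihood `trace` of the winning restart.
#' @export
fit_gmm <- function(values, k, seed = 1L, max_iter = 500L, tol = 1e-6,
                    n_restarts = 5L, var_floor = 1e-4) {
  x <- as.numeric(values)
  if (anyNA(x) || any(!is.finite(x))) stop("values must be finite")
  if (length(x) < 10L * k) stop("need at least ", 10L * k, " values for k = ", k)
  set.seed(seed)
  if (stats::var(x) == 0) {
    # degenerate: every observation identical -> variance-floored point fit
    w <- rep(1 / k, k)
    mu <- rep(x[1], k)
    sd <- rep(sqrt(var_floor), k)
    fit <- list(w = w, mu = mu, sd = sd, loglik = gmm_loglik(x, w, mu, sd),
                n_iter = 0L, converged = FALSE, trace = numeric(0))
  } else {
    fits <- lapply(seq_len(n_restarts), function(r) {
      em_once(x, k, max_iter, tol, var_floor)
    })
    fit <- fits[[which.max(vapply(fits, `[[`, numeric(1), "loglik"))]]
  }
  ord <- order(fit$mu)
  structure(
    list(k = as.integer(k), weights = fit$w[ord], means = fit$mu[ord],
         sds = fit$sd[ord], loglik = fit$loglik,
         aic = 2 * (3 * k - 1) - 2 * fit$loglik,
         converged = fit$converged, n_iter = fit$n_iter, trace = fit$trace,
         n = length(x)),
    class = "gaussian_mixture_fit"
  )
}

#' @export
print.gaussian_mixture_fit <- function(x, ...) {
  cat(sprintf("Gaussian mixture fit: k = %d, loglik = %.3f, AIC = %.3f (%s, %d iter)\n",
              x$k, x$loglik, x$aic,
              if (x$converged) "converged" else "not converged", x$n_iter))
  for (j in seq_len(x$k)) {
    cat(sprintf("  component %d: weight %.3f, mean %.4f, sd %.4f\n",
                j, x$weights[j], x$means[j], x$sds[j]))
  }
  invisible(x)
}

#' Choose the null model between bimodal and trimodal fits
#'
#' Returns the fit with the lower AIC; ties go to the 2-component model
#' (parsimony). If only one fit converged, it wins regardless of AIC.
#'
#' @param fit2,fit3 [fit_gmm()] results with `k = 2` and `k = 3`.
#' @return The chosen `gaussian_mixture_fit`.
#' @export
select_null_model <- function(fit2, fit3) {
  stopifnot(inherits(fit2, "gaussian_mixture_fit"),
            inherits(fit3, "gaussian_mixture_fit"))
  if (!fit2$converged && !fit3$converged) {
    stop("neither mixture fit converged; provide more data or restarts")
  }
  if (!fit3$converged) return(fit2)
  if (!fit2$converged) return(fit3)
  if (fit3$aic < fit2$aic) fit3 else fit2
}

#' Derive CNV gain/loss thresholds from the fitted null component
#'
#' The null component is the largest-weight component (targeted panels are
#' mostly copy-neutral); cutoffs sit at its mean +/- `z` standard
#' deviations.
#'
#' @param fit A converged [fit_gmm()] result (typically via
#'   [select_null_model()]).
#' @param z Quantile multiplier (default 1.96).
#' @return Object of class `cnv_thresholds`: `null_component`,
#'   `null_mean`, `null_sd`, `gain_cut`, `loss_cut`, `z`.
#' @export
derive_thresholds <- function(fit, z = 1.96) {
  stopifnot(inherits(fit, "gaussian_mixture_fit"))
  j <- which.max(fit$weights)
  structure(
    list(null_component = j, null_mean = fit$means[j], null_sd = fit$sds[j],
         gain_cut = fit$means[j] + z * fit$sds[j],
         loss_cut = fit$means[j] - z * fit$sds[j], z = z),
    class = "cnv_thresholds"
  )
}

#' @export
print.cnv_thresholds <- function(x, ...) {
  cat(sprintf("CNV thresholds: null component %d (mean %.4f, sd %.4f); gain > %.4f, loss < %.4f (z = %g)\n",
              x$null_component, x$null_mean, x$null_sd, x$gain_cut, x$loss_cut, x$z))
  invisible(x)
}

#' Gene-level CNV calls
#'
#' Summarizes each gene by the median of its target log2 ratios and calls
#' `amplified` above the gain cutoff, `deleted` below the loss cutoff,
#' `neutral` in between; genes with fewer than `min_targets` targets are
#' reported as `no_call`.
#'
#' @param ratios A [compute_log_ratios()] result.
#' @param thresholds A [derive_thresholds()] result.
#' @param min_targets Minimum targets per gene for a call (default 3).
#' @return data.frame (`gene`, `log2_ratio`, `n_targets`, `state`).
#' @export
call_gene_cnv <- function(ratios, thresholds, min_targets = 3L) {
  stopifnot(inherits(thresholds, "cnv_thresholds"))
  genes <- unique(ratios$gene)
  med <- vapply(genes, function(g) stats::median(ratios$log2_ratio[ratios$gene == g]),
                numeric(1))
  n <- vapply(genes, function(g) sum(ratios$gene == g), integer(1))
  state <- ifelse(n < min_targets, "no_call",
           ifelse(med > thresholds$gain_cut, "amplified",
           ifelse(med < thresholds$loss_cut, "deleted", "neutral")))
  data.frame(gene = genes, log2_ratio = med, n_targets = n, state = state,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' HER2 classification from gene CNV calls
#'
#' @param calls A [call_gene_cnv()] result containing an `ERBB2` row.
#' @param gene Oncogene defining the subtype (default `"ERBB2"`).
#' @return `"HER2+"` if the gene is amplified, `"HER2-"` otherwise,
#'   `"no_call"` when the gene had too few targets.
#' @export
classify_her2 <- function(calls, gene = "ERBB2") {
  i <- which(calls$gene == gene)
  if (!length(i)) stop(gene, " is absent from the CNV calls; cannot classify")
  switch(calls$state[i[1]],
         amplified = "HER2+",
         no_call = "no_call",
         "HER2-")
}

#' Classification metrics from a confusion matrix
#'
#' Precision (positive predictive value), sensitivity (true positive rate)
#' and specificity (true negative rate), as percentages rounded to one
#' decimal. Metrics with a zero denominator are returned as `NA`.
#'
#' @param tp,fp,tn,fn Nonnegative confusion counts.
#' @return Named numeric vector `c(precision, sensitivity, specificity)` in
#'   percent.
#' @examples
#' classification_metrics(tp = 12, fp = 3, tn = 18, fn = 2)
#' @export
classification_metrics <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0)) stop("confusion counts must be nonnegative")
  pct <- function(num, den) if (den == 0) NA_real_ else round(100 * num / den, 1)
  c(precision = pct(tp, tp + fp),
    sensitivity = pct(tp, tp + fn),
    specificity = pct(tn, tn + fp))
}
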