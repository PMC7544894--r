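# Cohort-level computations: plasma/tissue concordance categorization,
# error-reduction ratio, median VAF, and self-implemented Wilcoxon
# rank-sum and Pearson correlation (with exact small-sample enumeration).

#' Classify plasma/tissue concordance of variants
#'
#' Each plasma variant is assessed in the primary and metastatic tissue:
#' a tissue is `uncallable` when its coverage is not above `min_tissue_cov`
#' reads, `present` when it shows at least `min_tissue_alt` alt reads, and
#' `absent` otherwise. Variants with either tissue uncallable are excluded
#' from the category fractions.
#'
#' @param variants data.frame with one row per plasma variant: `vaf`,
#'   `primary_cov`, `primary_alt`, `met_cov`, `met_alt` (plus any
#'   identifying columns, carried through).
#' @param min_tissue_cov Coverage strictly required in both tissues for the
#'   variant to be callable (default 50, i.e. "more than 50 reads").
#' @param min_tissue_alt Alt reads defining tissue presence (default 3).
#' @return List with `records` (input plus `primary_status`, `met_status`,
#'   `category`) and `summary` (per-category counts and percentages of the
#'   callable set, rounded to one decimal).
#' @export
classify_concordance <- function(variants, min_tissue_cov = 50L,
                                 min_tissue_alt = 3L) {
  stop_if_not_df_with(variants, c("primary_cov", "primary_alt",
                                  "met_cov", "met_alt"), "variants")
  status <- function(cov, alt) {
    ifelse(cov <= min_tissue_cov, "uncallable",
           ifelse(alt >= min_tissue_alt, "present", "absent"))
  }
  rec <- variants
  rec$primary_status <- status(rec$primary_cov, rec$primary_alt)
  rec$met_status <- status(rec$met_cov, rec$met_alt)
  rec$category <- ifelse(
    rec$primary_status == "uncallable" | rec$met_status == "uncallable",
    "uncallable",
    ifelse(rec$primary_status == "present" & rec$met_status == "present", "all_three",
    ifelse(rec$met_status == "present", "met_only",
    ifelse(rec$primary_status == "present", "primary_only", "plasma_only"))))
  cats <- c("all_three", "met_only", "primary_only", "plasma_only")
  callable <- sum(rec$category != "uncallable")
  n <- vapply(cats, function(cc) sum(rec$category == cc), integer(1))
  summary <- data.frame(
    category = cats, n = n,
    percent = if (callable > 0L) round(100 * n / callable, 1) else NA_real_,
    stringsAsFactors = FALSE
  )
  list(records = rec, summary = summary, n_callable = callable,
       n_uncallable = nrow(rec) - callable)
}

#' Error-reduction ratio of the pipeline versus a baseline caller
#'
#' @param baseline_count Variant calls made by the baseline approach.
#' @param pipeline_count Variant calls made by the pipeline.
#' @return `round(baseline_count / pipeline_count)`; `Inf` when the
#'   pipeline makes no calls.
#' @examples
#' error_reduction_ratio(3971, 30)
#' @export
error_reduction_ratio <- function(baseline_count, pipeline_count) {
  if (pipeline_count < 0 || baseline_count < 0) stop("counts must be nonnegative")
  if (pipeline_count == 0) return(Inf)
  round(baseline_count / pipeline_count)
}

#' Median variant allele frequency
#'
#' @param vafs Numeric VAFs.
#' @return Median (mean of the middle pair for even counts); `NA` with a
#'   warning when empty.
#' @export
median_vaf <- function(vafs) {
  if (!length(vafs)) {
    warning("no variants; median VAF undefined")
    return(NA_real_)
  }
  stats::median(vafs)
}

# exact two-sided p for the rank-sum statistic by enumeration over all
# C(N, nx) assignments of the pooled (mid-)ranks to group x
wilcoxon_exact_p <- function(ranks, nx, W) {
  sums <- utils::combn(ranks, nx, FUN = sum)
  eps <- 1e-9
  p_le <- mean(sums <= W + eps)
  p_ge <- mean(sums >= W - eps)
  min(1, 2 * min(p_le, p_ge))
}

#' Wilcoxon rank-sum test (two-sided)
#'
#' Mid-ranks are used for ties; the statistic is the rank sum `W` of the
#' first group. For pooled sizes up to `exact_max` the two-sided p-value is
#' computed by exact enumeration of all rank assignments (doubled smaller
#' tail, capped at 1); larger samples use the normal approximation with tie
#' correction and continuity correction.
#'
#' @param x,y Numeric samples (each nonempty).
#' @param exact_max Largest pooled size for exact enumeration (default 12).
#' @return Object of class `group_comparison`: `statistic` (W), `p.value`,
#'   `method`, `n`.
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max = 12L) {
  stopifnot(length(x) >= 1L, length(y) >= 1L)
  nx <- length(x); ny <- length(y); N <- nx + ny
  pooled <- c(x, y)
  ranks <- rank(pooled)           # mid-ranks for ties
  W <- sum(ranks[seq_len(nx)])
  if (N <= exact_max) {
    p <- wilcoxon_exact_p(ranks, nx, W)
    method <- "exact enumeration"
  } else {
    mu <- nx * (N + 1) / 2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- nx * ny / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      # continuity correction toward the mean
      z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal approximation (tie + continuity corrected)"
  }
  structure(list(statistic = c(W = W), p.value = p, method = method,
                 n = c(nx = nx, ny = ny)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Wilcoxon rank-sum: W = %g, p = %.4g (%s; n = %d vs %d)\n",
              x$statistic, x$p.value, x$method, x$n[1], x$n[2]))
  invisible(x)
}

#' Pearson product-moment correlation
#'
#' `r` by the standard formula; the p-value comes from the t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` with `n - 2` degrees of freedom
#' (two-sided).
#'
#' @param x,y Numeric vectors of equal length (`>= 3`), each with nonzero
#'   variance.
#' @return List with `r`, `p.value`, `n`.
#' @export
pearson_r <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 3L) stop("need at least 3 paired observations")
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  dx <- x - mean(x); dy <- y - mean(y)
  sx <- sqrt(sum(dx^2)); sy <- sqrt(sum(dy^2))
  if (sx == 0 || sy == 0) {
    warning("zero variance; correlation undefined")
    return(list(r = NA_real_, p.value = NA_real_, n = n))
  }
  r <- sum(dx * dy) / (sx * sy)
  r <- max(-1, min(1, r))
  p <- if (abs(r) == 1) 0 else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(r = r, p.value = p, n = n)
}
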