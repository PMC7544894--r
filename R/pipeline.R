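# End-to-end orchestration: consensus -> screen -> filters -> duplex
# confirmation, with per-stage accounting, plus cohort-level report
# aggregation and YAML run configuration.

#' Validate a pipeline run configuration
#'
#' @param config Named list (e.g. from [read_config()]) with any of:
#'   `bam`, `bed`, `pon` (vector of healthy variant TSVs), `impact`,
#'   `normal`, `mode` (`"default"`/`"stringent"`), `coord_mode`, `seed`,
#'   and screening-threshold overrides.
#' @return The config with defaults filled in; errors name missing files.
#' @export
pipeline_config <- function(config = list()) {
  config$mode <- config$mode %||% "stringent"
  if (!config$mode %in% c("default", "stringent")) {
    stop("mode must be 'default' or 'stringent'")
  }
  config$coord_mode <- config$coord_mode %||% "endpoints"
  config$min_mapq <- config$min_mapq %||% 20L
  config$max_mismatch <- config$max_mismatch %||% 1L
  config$min_family_size <- config$min_family_size %||% 2L
  config$seed <- as.integer(config$seed %||% 1L)
  for (f in c("bam", "bed", "impact", "normal")) {
    if (!is.null(config[[f]]) && !file.exists(config[[f]])) {
      stop("configured ", f, " file does not exist: ", config[[f]])
    }
  }
  for (p in config$pon %||% character(0)) {
    if (!file.exists(p)) stop("configured panel-of-normals file does not exist: ", p)
  }
  config
}

#' Read a YAML run configuration
#' @param path YAML file.
#' @return Validated config list (see [pipeline_config()]).
#' @export
read_config <- function(path) {
  pipeline_config(yaml::read_yaml(path))
}

#' Process a sample: UMI-aware deduplication with QC
#'
#' Thin orchestration over [dedup_readset()]: accepts an aligned read
#' data.frame or a SAM/BAM path and returns consensus reads plus QC
#' counters. Deterministic for fixed input.
#'
#' @param reads Aligned read data.frame or path to SAM/BAM.
#' @inheritParams dedup_readset
#' @return List with `consensus`, `families`, `qc`.
#' @export
process_sample <- function(reads, max_mismatch = 1L, min_mapq = 20L,
                           min_family_size = 2L) {
  if (is.character(reads)) reads <- read_sam(reads)
  dedup_readset(reads, max_mismatch = max_mismatch, min_mapq = min_mapq,
                min_family_size = min_family_size)
}

#' Two-step variant calling with per-stage accounting
#'
#' Chains the screening step and the optional panel-of-normals, impact and
#' matched-normal filters, then double-strand confirmation. Stage counts
#' are monotone non-increasing.
#'
#' @param consensus Consensus read data.frame.
#' @param regions Target intervals.
#' @param reference Reference object (see [ref_base()]).
#' @param params A [screen_params()] preset (default the stringent preset
#'   used for patient plasma).
#' @param pon Optional list of healthy variant sets
#'   ([filter_panel_of_normals()]).
#' @param annotation Optional impact annotation ([filter_impact()]).
#' @param normal_counts Optional matched-normal counts
#'   ([filter_matched_normal()]).
#' @param coord_mode Duplex coordinate matching mode (see [confirm()]).
#' @return List with `final` (confirmed candidates), `screened` (all
#'   screening candidates with filter status) and `stage_counts`.
#' @export
call_variants <- function(consensus, regions, reference,
                          params = screen_params("stringent"),
                          pon = NULL, annotation = NULL, normal_counts = NULL,
                          coord_mode = c("endpoints", "start")) {
  coord_mode <- match.arg(coord_mode)
  pileup <- build_pileup(consensus, regions, reference, min_bq = params$min_bq)
  screened <- screen(pileup, params)
  cand <- passing_variants(screened)
  counts <- c(screened = nrow(cand))
  if (!is.null(pon)) {
    cand <- filter_panel_of_normals(cand, pon)
  }
  counts <- c(counts, panel_of_normals = nrow(cand))
  if (!is.null(annotation)) {
    cand <- filter_impact(cand, annotation)
  }
  counts <- c(counts, impact = nrow(cand))
  if (!is.null(normal_counts)) {
    cand <- filter_matched_normal(cand, normal_counts)
  }
  counts <- c(counts, matched_normal = nrow(cand))
  final <- confirm(cand, consensus, coord_mode = coord_mode)
  counts <- c(counts, confirmed = nrow(final))
  list(final = final, screened = screened, stage_counts = counts)
}

#' Consolidated cohort report
#'
#' Aggregates per-sample outputs (final variants, HER2 classification,
#' fragmentomics summaries) into cohort tables; missing components are
#' marked rather than dropped.
#'
#' @param samples Named list; each element a list with any of `variants`
#'   (final candidate data.frame), `her2` (classification string),
#'   `short_fraction`, `deviation_score`, `n_pairs`.
#' @return List of class `cohort_report`: `variants` (long table with a
#'   `sample` column), `per_sample` (one row per sample: variant count,
#'   median VAF, HER2 call, fragmentomics summaries) and `summary`.
#' @export
run_report <- function(samples) {
  if (is.null(names(samples)) && length(samples)) {
    names(samples) <- paste0("sample", seq_along(samples))
  }
  var_tabs <- list()
  rows <- lapply(names(samples), function(id) {
    s <- samples[[id]]
    v <- s$variants
    n_var <- if (is.null(v)) NA_integer_ else nrow(v)
    if (!is.null(v) && nrow(v)) {
      v$sample <- id
      var_tabs[[id]] <<- v
    }
    data.frame(
      sample = id, n_variants = n_var,
      median_vaf = if (!is.null(v) && nrow(v)) stats::median(v$vaf) else NA_real_,
      her2 = s$her2 %||% "missing",
      short_fraction = s$short_fraction %||% NA_real_,
      deviation_score = s$deviation_score %||% NA_real_,
      n_pairs = s$n_pairs %||% NA_integer_,
      stringsAsFactors = FALSE
    )
  })
  per_sample <- do.call(rbind, rows) %||% data.frame()
  variants <- if (length(var_tabs)) do.call(rbind, var_tabs) else NULL
  structure(
    list(variants = variants, per_sample = per_sample,
         summary = list(
           n_samples = length(samples),
           n_with_variants = sum(!is.na(per_sample$n_variants) &
                                   per_sample$n_variants > 0),
           n_variants_total = sum(per_sample$n_variants, na.rm = TRUE),
           median_vaf_pooled = if (!is.null(variants)) stats::median(variants$vaf)
                               else NA_real_,
           median_of_sample_medians =
             if (any(!is.na(per_sample$median_vaf)))
               stats::median(per_sample$median_vaf, na.rm = TRUE) else NA_real_
         )),
    class = "cohort_report"
  )
}

#' @export
print.cohort_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Cohort report: %d samples, %d with variants, %d variants total\n",
              s$n_samples, s$n_with_variants, s$n_variants_total))
  if (!is.na(s$median_vaf_pooled)) {
    cat(sprintf("  median VAF (pooled) %.4g; median of per-sample medians %.4g\n",
                s$median_vaf_pooled, s$median_of_sample_medians))
  }
  invisible(x)
}
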