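# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Phred+33 encoding of integer qualities (capped at 93, the printable range).
phred_to_char <- function(q) {
  q <- pmin(pmax(as.integer(q), 0L), 93L)
  intToUtf8(q + 33L, multiple = TRUE)
}

char_to_phred <- function(s) {
  if (length(s) == 1L) utf8ToInt(s) - 33L else utf8ToInt(paste0(s, collapse = "")) - 33L
}

# Zero-truncated Poisson sampler by inversion: u ~ U(P(X = 0), 1).
rztpois <- function(n, lambda) {
  stopifnot(lambda > 0)
  stats::qpois(stats::runif(n, stats::dpois(0, lambda), 1), lambda)
}

# n random UMIs over A/C/G/T, vectorized.
random_umis <- function(n, umi_len = 8L) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(DNA_BASES, n * umi_len, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

# Random reference sequence as a single string.
random_sequence <- function(len) {
  paste0(sample(DNA_BASES, len, replace = TRUE), collapse = "")
}

# Substitute, in x[i], the character at offset off[i] by base[i] (vectorized).
substitute_base <- function(x, off, base) {
  substr(x, off, off) <- base
  x
}

# For each current base, pick uniformly one of the three other bases.
other_base <- function(cur) {
  i <- match(cur, DNA_BASES)
  i[is.na(i)] <- sample.int(4L, sum(is.na(i)), replace = TRUE)  # N -> any base
  DNA_BASES[(i + sample.int(3L, length(cur), replace = TRUE) - 1L) %% 4L + 1L]
}

# Hamming distance between two equal-length strings.
hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) return(Inf)
  sum(utf8ToInt(a) != utf8ToInt(b))
}

variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

stop_if_not_df_with <- function(x, cols, what) {
  if (!is.data.frame(x)) stop(what, " must be a data.frame", call. = FALSE)
  miss <- setdiff(cols, names(x))
  if (length(miss)) {
    stop(what, " is missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  invisible(x)
}
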