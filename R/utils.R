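# Internal helpers shared across modules.

# Population (divide-by-n) standard deviation.
sd_pop <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}

# Column-wise z-score with population denominator; rows = genes.
zscore_rows <- function(mat) {
  mu <- rowMeans(mat)
  sg <- apply(mat, 1L, sd_pop)
  sweep(sweep(mat, 1L, mu, "-"), 1L, sg, "/")
}

# Harmonic mean of non-negative scores; 0 if any score is 0.
harmonic_mean <- function(x) {
  if (any(!is.finite(x)) || any(x < 0)) stop("scores must be finite and non-negative")
  if (any(x == 0)) return(0)
  length(x) / sum(1 / x)
}

# Jaccard index between two character sets.
jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
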