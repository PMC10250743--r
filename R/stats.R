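# Paired nonparametric statistics used throughout the pipeline.

# Cache of exact signed-rank distributions, keyed by the multiset of
# (doubled) ranks.  Bin-wise map comparisons hit the same rank pattern
# tens of thousands of times, so this matters.
.wsr_cache <- new.env(parent = emptyenv())

#' Paired Wilcoxon signed-rank test with exact enumeration
#'
#' Computes the paired Wilcoxon signed-rank statistic `W` (sum of the ranks
#' of the positive differences) and its p-value. Zero differences are
#' discarded before ranking (the classic Wilcoxon convention); ties among
#' the absolute differences receive midranks. For `m <= 25` effective pairs
#' the p-value is exact, obtained from the full distribution of `W` over all
#' `2^m` sign assignments of the observed (possibly tied) ranks; above that,
#' a normal approximation with tie-corrected variance and continuity
#' correction is used.
#'
#' If every difference is zero the test is degenerate and the function
#' returns `W = 0`, `p = 1` by convention.
#'
#' @param x,y Numeric vectors of equal length, one value per subject
#'   (`y` defaults to zeros, so `x` may be a vector of paired differences).
#' @param alternative `"two.sided"` (default), `"greater"` (x tends larger)
#'   or `"less"`.
#' @param exact_limit Largest number of non-zero differences for which the
#'   exact distribution is enumerated.
#' @return A list of class `"wsr_test"` with elements `W`, `p.value`,
#'   `n.effective` (pairs remaining after zero removal), `alternative` and
#'   `method` (`"exact"` or `"normal"`).
#' @examples
#' wilcoxon_signed_rank(c(1, 2, 3, 4, 5), rep(0, 5))  # W = 15, p = 0.0625
#' @export
wilcoxon_signed_rank <- function(x, y = NULL,
                                 alternative = c("two.sided", "greater", "less"),
                                 exact_limit = 25L) {
  alternative <- match.arg(alternative)
  if (is.null(y)) y <- numeric(length(x))
  if (length(x) != length(y)) {
    stop("pairing error: 'x' and 'y' must have equal length (",
         length(x), " vs ", length(y), ")")
  }
  if (anyNA(x) || anyNA(y)) stop("missing values in paired sample")
  d <- as.numeric(x) - as.numeric(y)
  d <- d[d != 0]
  m <- length(d)
  if (m == 0L) {
    out <- list(W = 0, p.value = 1, n.effective = 0L,
                alternative = alternative, method = "degenerate")
    class(out) <- "wsr_test"
    return(out)
  }
  if (m < 2L) {
    stop("insufficient data: fewer than 2 non-zero differences")
  }
  r <- rank(abs(d))               # midranks for ties
  W <- sum(r[d > 0])

  if (m <= exact_limit) {
    ir <- as.integer(round(2 * r))          # doubled ranks are integers
    dist <- .wsr_exact_distribution(ir)     # counts over W2 = 0..sum(ir)
    w2 <- as.integer(round(2 * W))
    total <- 2^m
    p_le <- sum(dist[seq_len(w2 + 1L)]) / total
    p_ge <- sum(dist[(w2 + 1L):length(dist)]) / total
    p <- switch(alternative,
                two.sided = min(1, 2 * min(p_le, p_ge)),
                greater   = p_ge,
                less      = p_le)
    method <- "exact"
  } else {
    mu <- m * (m + 1) / 4
    tie_tab <- table(r)
    sigma2 <- m * (m + 1) * (2 * m + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    sigma <- sqrt(sigma2)
    p <- switch(alternative,
                greater = stats::pnorm((W - mu - 0.5) / sigma, lower.tail = FALSE),
                less    = stats::pnorm((W - mu + 0.5) / sigma),
                two.sided = {
                  z <- (W - mu - sign(W - mu) * 0.5) / sigma
                  min(1, 2 * stats::pnorm(-abs(z)))
                })
    method <- "normal"
  }
  out <- list(W = W, p.value = p, n.effective = m,
              alternative = alternative, method = method)
  class(out) <- "wsr_test"
  out
}

# Exact distribution of twice the positive-rank sum over all sign
# assignments, by convolution over the doubled ranks (equivalent to full
# enumeration of the 2^m sign patterns, tie-aware). Returns counts indexed
# by W2 = 0..sum(ir); counts are exact in double precision for m <= 25.
.wsr_exact_distribution <- function(ir) {
  key <- paste(sort(ir), collapse = ",")
  hit <- .wsr_cache[[key]]
  if (!is.null(hit)) return(hit)
  total <- sum(ir)
  f <- numeric(total + 1L)
  f[1L] <- 1
  hi <- 0L
  for (r2 in ir) {
    idx <- (hi + r2):r2 + 1L          # descending target indices
    f[idx] <- f[idx] + f[idx - r2]
    hi <- hi + r2
  }
  .wsr_cache[[key]] <- f
  f
}

#' @export
print.wsr_test <- function(x, ...) {
  cat("Paired Wilcoxon signed-rank test (", x$method, ")\n", sep = "")
  cat("  W = ", format(x$W), ", p = ", format.pval(x$p.value, digits = 4),
      ", n(effective) = ", x$n.effective,
      ", alternative = ", x$alternative, "\n", sep = "")
  invisible(x)
}

#' Standard error of the mean
#'
#' Sample standard deviation (n-1 denominator) divided by sqrt(n); used for
#' the shaded uncertainty bands on averaged impedance curves.
#'
#' @param values Numeric vector, `n >= 2`.
#' @return Scalar SEM.
#' @export
sem <- function(values) {
  values <- as.numeric(values)
  if (anyNA(values)) stop("missing values")
  n <- length(values)
  if (n < 2L) stop("insufficient data: SEM requires at least 2 values")
  stats::sd(values) / sqrt(n)
}
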