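#' @include AllClasses.R
NULL

## Two-sample t-test (Welch or pooled) with explicit degenerate-case
## conventions. Both arms zero-variance: p = 1 if the means agree, p = 0
## otherwise. t.test() refuses constant data, so the convention is
## applied up front.
.t_p <- function(x, y, var_equal = FALSE) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2L || length(y) < 2L)
    stop("need >=2 finite replicates per arm")
  if (sd(x) == 0 && sd(y) == 0)
    return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
  t.test(x, y, var.equal = var_equal)$p.value
}

.welch_p <- function(x, y) .t_p(x, y, var_equal = FALSE)

## Wilcoxon rank-sum dispatch per the documented branch rule: exact
## enumeration when both groups have <= `exact_max` observations and there
## are no ties; otherwise normal approximation with continuity correction
## and mid-ranks.
.ranksum <- function(x, y, exact_max = 8L) {
  ties <- anyDuplicated(c(x, y)) > 0L
  use_exact <- !ties && length(x) <= exact_max && length(y) <= exact_max
  wt <- suppressWarnings(
    wilcox.test(x, y, exact = use_exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p.value = wt$p.value,
       exact = use_exact)
}

## Wilcoxon signed-rank on paired differences; zero differences dropped.
## Exact when <= `exact_max` non-zero differences with untied magnitudes.
.signedrank <- function(d, exact_max = 20L) {
  d <- d[is.finite(d)]
  d <- d[d != 0]
  if (!length(d)) return(list(statistic = NA_real_, p.value = 1, n = 0L,
                              exact = TRUE))
  ties <- anyDuplicated(abs(d)) > 0L
  use_exact <- !ties && length(d) <= exact_max
  wt <- suppressWarnings(wilcox.test(d, exact = use_exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p.value = wt$p.value,
       n = length(d), exact = use_exact)
}

## Spearman rank correlation with mid-rank ties; errors on constant input.
.spearman <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4L) stop("need >=4 paired finite observations")
  if (sd(x) == 0 || sd(y) == 0)
    stop("undefined correlation: constant input vector")
  cor(x, y, method = "spearman")
}

## Seed scoping: run `expr` under `seed` when given, without disturbing the
## caller's RNG stream.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

.check_count <- function(x, name, min = 0L) {
  if (length(x) != 1L || !is.finite(x) || x < min || x != floor(x))
    stop(sprintf("'%s' must be a single integer >= %d", name, min))
  as.integer(x)
}
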