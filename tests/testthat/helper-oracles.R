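suppressPackageStartupMessages(library(GenomicRanges))

# Independent oracles used to validate the package implementations.
# Everything here is written from first principles (definitions and
# enumeration), never by calling the code under test.

# Benjamini-Hochberg by the step-up definition: sort ascending, multiply
# p_(i) by m/i, take the cumulative minimum from the largest rank, cap at
# 1, return in input order.
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(ps)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Welch t-test from the textbook formulas: t statistic with
# Welch-Satterthwaite degrees of freedom, two-sided p from the t CDF.
welch_bruteforce <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- var(x); vy <- var(y)
  se2 <- vx / nx + vy / ny
  tstat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  2 * pt(-abs(tstat), df)
}

# Exact two-sided Wilcoxon rank-sum p by enumerating all labelings of the
# pooled sample (no ties assumed).
ranksum_enumerate <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled); nx <- length(x)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- combn(n, nx)
  us <- apply(combos, 2L, function(idx)
    sum(r[idx]) - nx * (nx + 1) / 2)
  mu <- nx * (n - nx) / 2
  # two-sided: as extreme or more, measured by distance from the mean U
  mean(abs(us - mu) >= abs(u_obs - mu))
}

# Exact two-sided Wilcoxon signed-rank p enumerating all 2^n sign
# assignments of the non-zero differences (no tied magnitudes assumed),
# counted via the generating function prod_r (1 + z^r) so that n = 20 is
# cheap.
signedrank_enumerate <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))          # 1..n when magnitudes are untied
  v_obs <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  m <- n * (n + 1) / 2
  cnt <- c(1, rep(0, m))     # cnt[v + 1] = #assignments with V = v
  for (rr in r) {
    shifted <- c(rep(0, rr), cnt[seq_len(m + 1 - rr)])
    cnt <- cnt + shifted
  }
  v <- 0:m
  sum(cnt[abs(v - mu) >= abs(v_obs - mu)]) / 2^n
}

# Pooled-variance (Student) two-sample t-test from the textbook formula.
pooled_bruteforce <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  2 * pt(-abs(tstat), nx + ny - 2)
}

# Brute-force disk median filter: per-pixel median over the in-bounds
# disk footprint, computed with plain loops.
median_bruteforce <- function(img, r) {
  ny <- nrow(img); nx <- ncol(img)
  ri <- floor(r)
  out <- matrix(0, ny, nx)
  for (i in seq_len(ny)) for (j in seq_len(nx)) {
    vals <- c()
    for (dy in -ri:ri) for (dx in -ri:ri) {
      if (dy^2 + dx^2 > r^2) next
      ii <- i + dy; jj <- j + dx
      if (ii >= 1 && ii <= ny && jj >= 1 && jj <= nx)
        vals <- c(vals, img[ii, jj])
    }
    out[i, j] <- median(vals)
  }
  out
}

# Brute-force grayscale opening with a ball structuring element
# (erosion then dilation, in-bounds offsets only).
ballopen_bruteforce <- function(img, r) {
  ny <- nrow(img); nx <- ncol(img)
  ri <- floor(r)
  offs <- list()
  for (dy in -ri:ri) for (dx in -ri:ri)
    if (dy^2 + dx^2 <= r^2)
      offs[[length(offs) + 1L]] <- c(dy, dx, sqrt(r^2 - dy^2 - dx^2) - r)
  pass <- function(src, f, sgn) {
    out <- matrix(0, ny, nx)
    for (i in seq_len(ny)) for (j in seq_len(nx)) {
      best <- if (sgn > 0) -Inf else Inf
      for (o in offs) {
        ii <- i + o[1L]; jj <- j + o[2L]
        if (ii >= 1 && ii <= ny && jj >= 1 && jj <= nx) {
          v <- src[ii, jj] + sgn * o[3L]
          best <- f(best, v)
        }
      }
      out[i, j] <- best
    }
    out
  }
  ero <- pass(img, min, -1)   # img - h
  pass(ero, max, +1)          # ero + h
}

# Shared small fixtures ----------------------------------------------------

make_tiny_plate <- function(values = NULL) {
  # one plate: 4 controls of each role in columns 2/23, 4 compound wells
  df <- data.frame(
    plate = "P1",
    row = c(1, 3, 5, 7, 2, 4, 6, 8, 1, 2, 3, 4),
    column = c(rep(2, 4), rep(23, 4), rep(5, 4)),
    role = c(rep("pos_ctrl", 4), rep("neg_ctrl", 4), rep("compound", 4)),
    compound = c(rep(NA, 8), "c1", "c1", "c2", "c2"),
    concentration_uM = 5, arm = "vehicle", replicate = 1,
    value = c(rep(100, 4), rep(1100, 4), 600, 600, 350, 350))
  if (!is.null(values)) df$value <- values
  PlateGrid(df)
}
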