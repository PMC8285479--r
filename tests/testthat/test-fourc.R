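test_that("noise-free simulation reproduces declared effects exactly", {
  eff <- data.frame(start = 2760000, end = 2800000, effect = 2)
  sim <- simulateFourC(fourcSimConfig(effect_regions = eff,
                                      dispersion = 0, seed = 1))
  sig <- contactSignal(sim$profile)
  cd <- signalInfo(sim$profile)
  c1 <- sig[, cd$condition == "vehicle", drop = FALSE]
  c2 <- sig[, cd$condition == "GC", drop = FALSE]
  inside <- sim$truth$effect == 2
  expect_true(any(inside) && any(!inside))
  expect_equal(unname(c2[!inside, ]), unname(c1[!inside, ]),
               tolerance = 1e-12)
  expect_equal(unname(c2[inside, ]), unname(2 * c1[inside, ]),
               tolerance = 1e-12)
  # all effects = 1 -> the two conditions are identical
  sim0 <- simulateFourC(fourcSimConfig(dispersion = 0, seed = 1))
  sg <- contactSignal(sim0$profile)
  expect_equal(sg[, 1:2], sg[, 3:4], ignore_attr = TRUE)
  # fixed-seed reproducibility
  simA <- simulateFourC(fourcSimConfig(seed = 5))
  simB <- simulateFourC(fourcSimConfig(seed = 5))
  expect_identical(contactSignal(simA$profile),
                   contactSignal(simB$profile))
})

test_that("fragment-to-region assignment uses inclusive midpoints", {
  sim <- simulateFourC(fourcSimConfig(seed = 2))
  fr <- fragmentRanges(sim$profile)
  full <- paste0("chr11: ", GenomicRanges::start(fr)[1], "-",
                 GenomicRanges::end(fr)[length(fr)])
  expect_equal(fragmentsInRegion(sim$profile, full),
               seq_along(fr))
  # region in a gap between two fragments -> empty-region error
  gap_start <- GenomicRanges::end(fr)[1] + 1
  gap_end <- GenomicRanges::start(fr)[2] - 1
  expect_error(fragmentsInRegion(
    sim$profile, sprintf("chr11: %d-%d", gap_start, gap_end)),
    "empty region")
  # fragment midpoint exactly at the region end is included
  mid3 <- floor((GenomicRanges::start(fr)[3] +
                   GenomicRanges::end(fr)[3]) / 2)
  idx <- fragmentsInRegion(sim$profile,
                           sprintf("chr11: %d-%d",
                                   GenomicRanges::start(fr)[1], mid3))
  expect_true(3 %in% idx)
  expect_false(4 %in% idx)
  expect_error(fragmentsInRegion(sim$profile, "chr7: 1-100"),
               "chromosome absent")
})

test_that("region comparison handles identical conditions and signs", {
  sim <- simulateFourC(fourcSimConfig(dispersion = 0, seed = 3))
  fr <- fragmentRanges(sim$profile)
  full <- paste0("chr11: ", GenomicRanges::start(fr)[1], "-",
                 GenomicRanges::end(fr)[length(fr)])
  r <- regionCompare(sim$profile, full)
  expect_equal(r$p.value, 1)
  expect_equal(r$median_diff, 0)
})

test_that("six uniform positive differences give the exact 2/2^6 p", {
  frags <- GRanges("chr1", IRanges(start = seq(1, 5001, by = 1000),
                                   width = 500))
  names(frags) <- paste0("f", 1:6)
  base <- c(10, 20, 30, 40, 50, 60)
  sig <- cbind(base, base, base * 1.5, base * 1.5)
  colnames(sig) <- c("v_r1", "v_r2", "t_r1", "t_r2")
  prof <- FourCProfile("vp", frags, sig, rep(c("v", "t"), each = 2),
                       rep(1:2, 2))
  r <- regionCompare(prof, "chr1: 1-6000")
  expect_equal(r$p.value, 0.03125)
  expect_equal(r$p.value, signedrank_enumerate(base * 0.5),
               tolerance = 1e-12)
})

test_that("the signed-rank p matches enumeration and is scale-invariant", {
  set.seed(20)
  frags <- GRanges("chr1", IRanges(start = seq(1, 9001, by = 1000),
                                   width = 500))
  for (i in 1:10) {
    base <- exp(rnorm(10, 3))
    fac <- exp(rnorm(10, 0, 0.5))
    sig <- cbind(base, base * fac)
    colnames(sig) <- c("a_r1", "b_r1")
    prof <- FourCProfile("vp", frags, sig, c("a", "b"), c(1L, 1L))
    r <- regionCompare(prof, "chr1: 1-10000")
    expect_equal(r$p.value, signedrank_enumerate(base * (fac - 1)),
                 tolerance = 1e-12)
    # common multiplicative rescaling of both conditions
    prof2 <- FourCProfile("vp", frags, sig * 7.3, c("a", "b"), c(1L, 1L))
    expect_equal(regionCompare(prof2, "chr1: 1-10000")$p.value,
                 r$p.value, tolerance = 1e-12)
  }
})

test_that("exact and approximate signed-rank branches agree at crossover", {
  set.seed(21)
  for (i in 1:8) {
    d <- rnorm(20)
    p_exact <- signedrank_enumerate(d)
    p_approx <- suppressWarnings(
      wilcox.test(d, exact = FALSE, correct = TRUE))$p.value
    expect_lt(abs(p_exact - p_approx), 0.01)
  }
})

test_that("an injected region effect is detected against dispersion", {
  eff <- data.frame(start = 2755000, end = 2805000, effect = 2)
  hits <- vapply(1:20, function(s) {
    sim <- simulateFourC(fourcSimConfig(n_fragments = 40,
                                        effect_regions = eff,
                                        dispersion = 0.1, seed = s))
    regionCompare(sim$profile, "chr11: 2755000-2805000")$p.value
  }, numeric(1))
  expect_true(mean(hits < 0.01) >= 0.95)
})

test_that("overlapping fragments are rejected at construction", {
  frags <- GRanges("chr1", IRanges(start = c(1, 50), end = c(100, 140)))
  sig <- matrix(1, 2, 2, dimnames = list(NULL, c("a_r1", "b_r1")))
  expect_error(FourCProfile("vp", frags, sig, c("a", "b"), c(1L, 1L)),
               "non-overlapping")
})
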