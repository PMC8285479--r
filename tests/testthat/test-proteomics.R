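make_lfq <- function(x, groups) {
  if (is.null(rownames(x)))
    rownames(x) <- sprintf("p%02d", seq_len(nrow(x)))
  LFQMatrix(x, groups)
}

test_that("valid-value filters apply the published rules", {
  x <- rbind(a = c(25, 26, NA, 25, 26, 27),   # 5/6 observed
             b = c(25, NA, NA, 25, 26, 27),   # 4/6; 1/3 in group 1
             c = c(25, 26, 27, 25, 26, 27),   # complete
             d = c(NA, NA, NA, 25, NA, NA))
  g <- rep(c("A", "B"), each = 3)
  lfq <- make_lfq(x, g)
  # 66% overall: a (83%), b (66.7%) and c pass, d does not
  f1 <- filterValid(lfq, "overall-fraction", min_fraction = 0.66)
  expect_equal(rownames(intensityMatrix(f1)), c("a", "b", "c"))
  # a row with 2/3 observed passes the 66% rule
  expect_true("a" %in% rownames(intensityMatrix(f1)))
  # >=2 valid values in both groups: drops b (1 in group A) and d
  f2 <- filterValid(lfq, "per-group-count", min_count = 2)
  expect_equal(rownames(intensityMatrix(f2)), c("a", "c"))
  # >=2 in at least one group keeps b
  f3 <- filterValid(lfq, "per-group-count", min_count = 2, scope = "any")
  expect_equal(rownames(intensityMatrix(f3)), c("a", "b", "c"))
  # complete matrix unchanged under any mode; filter idempotent
  full <- make_lfq(matrix(rnorm(12, 25), 2), g)
  expect_identical(intensityMatrix(filterValid(full, "overall-fraction")),
                   intensityMatrix(full))
  expect_identical(intensityMatrix(filterValid(f2, "per-group-count")),
                   intensityMatrix(f2))
  expect_warning(filterValid(make_lfq(x["d", , drop = FALSE], g),
                             "per-group-count"), "every protein")
})

test_that("downshifted-normal imputation matches its stated distribution", {
  # column engineered to mu = 25, sigma = 2 over the observed values
  obs <- 25 + 2 * scale(rnorm(200))[, 1]
  x <- matrix(c(obs, rep(NA, 10000)), ncol = 1)
  rownames(x) <- sprintf("p%05d", seq_len(nrow(x)))
  lfq <- LFQMatrix(x, "A")
  imp <- intensityMatrix(imputeDownshift(lfq, seed = 123))
  vals <- imp[201:10200, 1]
  expect_lt(abs(mean(vals) - (25 - 1.8 * 2)), 0.02)
  expect_lt(abs(sd(vals) - 0.3 * 2), 0.02)
})

test_that("imputation is deterministic and leaves observed values alone", {
  sim <- simulateLFQ(n_proteins = 60, missing_rate = 0.4, seed = 5)
  i1 <- imputeDownshift(sim$lfq, seed = 7)
  i2 <- imputeDownshift(sim$lfq, seed = 7)
  expect_identical(intensityMatrix(i1), intensityMatrix(i2))
  obs <- !missingMask(sim$lfq)
  expect_identical(intensityMatrix(i1)[obs],
                   intensityMatrix(sim$lfq)[obs])
  # complete input passes through untouched
  full <- simulateLFQ(n_proteins = 20, missing_rate = 0, seed = 2)$lfq
  expect_identical(intensityMatrix(imputeDownshift(full, seed = 1)),
                   intensityMatrix(full))
  # degenerate columns error
  bad <- LFQMatrix(matrix(c(5, 5, 5, 5, NA), ncol = 1,
                          dimnames = list(letters[1:5], NULL)), "A")
  expect_error(imputeDownshift(bad, seed = 1), "zero sd")
})

test_that("differential calls respect thresholds and on/off flags", {
  set.seed(10)
  g <- rep(c("veh", "trt"), each = 3)
  x <- rbind(null1 = rnorm(6, 25, 0.1),
             null2 = rnorm(6, 24, 0.5),
             null3 = rnorm(6, 27, 0.5),
             up1 = c(rnorm(3, 25, 0.1), rnorm(3, 27, 0.1)),
             onoff = c(NA, NA, NA, 26, 26.2, 25.8))
  lfq <- make_lfq(x, g)
  res <- differentialTest(imputeDownshift(lfq, seed = 3))
  expect_equal(res$call[res$protein == "null1"], "ns")
  expect_equal(res$call[res$protein == "up1"], "up")
  expect_equal(res$on_off[res$protein == "onoff"], "on")
  expect_true(is.na(res$p[res$protein == "onoff"]))
  # identical groups: everything ns
  y <- matrix(rnorm(60, 25, 0.2), 10, 6)
  y <- cbind(y[, 1:3], y[, 1:3])
  rownames(y) <- sprintf("q%02d", 1:10)
  expect_true(all(differentialTest(make_lfq(y, g))$call == "ns"))
})

test_that("injected shifts are recovered at the stated thresholds", {
  # caller power at shift 2, sd 0.3, 3 vs 3 on fully observed data
  hit <- logical(0)
  for (s in 1:15) {
    sim <- simulateLFQ(n_proteins = 60, n_diff = 6, diff_log2fc = 2,
                       noise_sd = 0.3, missing_rate = 0, seed = s)
    res <- differentialTest(sim$lfq)
    truth <- sim$truth
    idx <- res$protein %in% truth$protein[truth$log2_shift != 0]
    hit <- c(hit, res$call[idx] %in% c("up", "down"))
  }
  expect_gte(mean(hit), 0.95)
})

test_that("MNAR-censored differential proteins surface as on/off calls", {
  # under heavy intensity-dependent dropout, proteins fully observed in
  # one group and fully missing in the other bypass the t-test
  sim <- simulateLFQ(n_proteins = 300, n_diff = 30, diff_log2fc = 4,
                     noise_sd = 0.3, missing_rate = 0.4, seed = 8)
  m <- missingMask(sim$lfq)
  g <- sampleGroups(sim$lfq)
  full_onoff <- (rowSums(m[, g == levels(g)[1]]) == 3 &
                   rowSums(!m[, g == levels(g)[2]]) == 3) |
    (rowSums(!m[, g == levels(g)[1]]) == 3 &
       rowSums(m[, g == levels(g)[2]]) == 3)
  expect_gt(sum(full_onoff), 0)
  lfq <- imputeDownshift(sim$lfq, seed = 8)
  res <- differentialTest(lfq)
  expect_true(all(res$on_off[res$protein %in%
                               rownames(m)[full_onoff]] != ""))
})

test_that("enrichment presets reproduce the published rule boundaries", {
  # construct proteins with controlled difference and p
  fix <- function(diff, p) {
    # 3v3 with per-arm sd tuned to give the target Welch p
    ip <- c(-1, 0, 1); ct <- c(-1, 0, 1)
    f <- function(s) welch_bruteforce(diff + ip * s, ct * s) - p
    s <- uniroot(f, c(1e-4, 50))$root
    list(ip = matrix(diff + ip * s, 1), ct = matrix(ct * s, 1))
  }
  a <- fix(2.6, 10^(-2.5))   # enriched and significant under GR preset
  r <- enrichmentCall(a$ip, a$ct, preset = "GR")
  expect_true(r$interactor)
  b <- fix(2.6, 10^(-1.5))   # fails the -log p > 2 leg
  expect_false(enrichmentCall(b$ip, b$ct, preset = "GR")$interactor)
  cc <- fix(1.6, 10^(-1.4))  # passes the looser p57 preset
  expect_true(enrichmentCall(cc$ip, cc$ct, preset = "p57")$interactor)
  expect_false(enrichmentCall(cc$ip, cc$ct, preset = "GR")$interactor)
  expect_error(enrichmentCall(a$ip, NULL, preset = "GR"),
               "missing control")
  expect_error(enrichmentCall(a$ip, a$ct), "enrich_cut")
})

test_that("IgG correction subtracts the per-protein baseline", {
  set.seed(30)
  ip <- matrix(rnorm(30, 26), 10, 3,
               dimnames = list(sprintf("p%02d", 1:10), NULL))
  ct <- matrix(rnorm(30, 24), 10, 3, dimnames = dimnames(ip))
  igg <- matrix(rnorm(30, 20), 10, 3, dimnames = dimnames(ip))
  r0 <- enrichmentCall(ip, ct, enrich_cut = 1, logp_cut = 1)
  r1 <- enrichmentCall(ip, ct, enrich_cut = 1, logp_cut = 1,
                       igg_correct = igg)
  # subtracting a common per-protein baseline leaves the difference alone
  expect_equal(r1$log2_enrichment, r0$log2_enrichment, tolerance = 1e-12)
})
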