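test_that("rank correlation reproduces hand-computed values", {
  expect_equal(linkageCorrelation(1:5, c(10, 20, 30, 40, 50)), 1)
  expect_equal(linkageCorrelation(1:5, 5:1), -1)
  # 1 - 6*4 / (5*24) = 0.8
  expect_equal(linkageCorrelation(1:5, c(2, 1, 4, 3, 5)), 0.8)
  expect_error(linkageCorrelation(rep(1, 5), 1:5), "constant")
  # invariance under strictly monotone transforms
  set.seed(3)
  x <- rnorm(20); y <- rnorm(20)
  expect_equal(linkageCorrelation(exp(x), y^3 + y),
               linkageCorrelation(x, y))
})

test_that("the background quantile follows the mid-tie convention", {
  set.seed(8)
  expr <- rnorm(30)
  cand <- expr + rnorm(30, 0, 0.4)
  rho_c <- linkageCorrelation(cand, expr)
  # one background row identical to the candidate, the rest anti-linked
  bg <- rbind(twin = cand,
              matrix(-expr + rnorm(30 * 24, 0, 2), 24, 30))
  rownames(bg) <- c("twin", paste0("b", 1:24))
  r <- backgroundNull(rho_c, bg, expr)
  n <- length(r$background_rhos)
  expect_equal(r$empirical_quantile, (n - 1 + 0.5) / n)
  # candidate above every background rho -> quantile 1
  bg2 <- bg[-1, , drop = FALSE]
  expect_equal(backgroundNull(1, bg2, expr)$empirical_quantile, 1)
  # brute-force recount of the comparison set
  rhos <- r$background_rhos
  expect_equal(r$empirical_quantile,
               (sum(rhos < rho_c) + 0.5 * sum(rhos == rho_c)) / n)
})

test_that("constant background enhancers are dropped with a note", {
  expr <- rnorm(20)
  bg <- rbind(matrix(rnorm(20 * 21), 21, 20), flat = rep(2, 20))
  expect_message(r <- backgroundNull(0.5, bg, expr), "constant")
  expect_equal(length(r$background_rhos), 21)
})

test_that("an active linkage outranks the local background null", {
  sim <- simulateCohort(cohortSimConfig(n_samples = 200, seed = 31))
  res <- linkageAnalysis(sim$cohort, "candidate", "TARGET")
  expect_gte(res$empirical_quantile, 0.99)
  expect_gt(res$rho_candidate, 0.4)
})

test_that("neighbor specificity matches the primary estimator", {
  set.seed(12)
  acc <- rnorm(50); tgt <- acc + rnorm(50)
  nb <- rbind(TARGETCOPY = tgt, IND = rnorm(50), FLAT = rep(1, 50))
  expect_message(r <- neighborSpecificity(acc, nb), "constant")
  expect_equal(unname(r["TARGETCOPY"]), linkageCorrelation(acc, tgt))
  expect_false("FLAT" %in% names(r))
  # independent neighbors stay near zero on generator cohorts
  sim <- simulateCohort(cohortSimConfig(n_samples = 200, seed = 14))
  nr <- neighborSpecificity(accMatrix(sim$cohort)["candidate", ],
                            exprMatrix(sim$cohort)[
                              paste0("NEIGHBOR_", 1:4), ])
  expect_true(all(abs(nr) <= 0.2))
})

test_that("the conditioned curve starts at the unconditioned rho", {
  set.seed(4)
  acc <- rnorm(60); expr <- acc + rnorm(60); cond <- rnorm(60)
  cv <- conditionedCorrelationCurve(acc, expr, cond)
  expect_equal(cv$fraction[1], 0)
  expect_equal(cv$rho[1], linkageCorrelation(acc, expr))
  expect_equal(cv$n[1], 60)
  expect_true(all(diff(cv$n) < 0))
})

test_that("a receptor-gated linkage rises as low-receptor samples drop", {
  curves <- vapply(1:25, function(s) {
    sim <- simulateCohort(cohortSimConfig(n_samples = 150,
                                          gate = "top-half", seed = s))
    ex <- exprMatrix(sim$cohort); ac <- accMatrix(sim$cohort)
    cv <- conditionedCorrelationCurve(ac["candidate", ], ex["TARGET", ],
                                      ex["GR", ],
                                      fractions = seq(0, 0.5, 0.1))
    cv$rho
  }, numeric(6))
  avg <- rowMeans(curves)
  expect_true(all(diff(avg) > -0.02))   # nondecreasing up to noise
  expect_gt(avg[6] - avg[1], 0.1)
})

test_that("an ungated linkage yields a flat conditioned curve", {
  curves <- vapply(1:25, function(s) {
    sim <- simulateCohort(cohortSimConfig(n_samples = 150,
                                          gate = "none", seed = s))
    ex <- exprMatrix(sim$cohort); ac <- accMatrix(sim$cohort)
    cv <- conditionedCorrelationCurve(ac["candidate", ], ex["TARGET", ],
                                      ex["GR", ],
                                      fractions = seq(0, 0.5, 0.1))
    cv$rho
  }, numeric(6))
  avg <- rowMeans(curves)
  expect_true(all(abs(avg - avg[1]) <= 0.1))
})
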