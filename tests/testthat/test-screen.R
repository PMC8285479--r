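test_that("NPI anchors controls at 0 and 1 and is linear in between", {
  npi <- npiNormalize(make_tiny_plate())
  w <- as.data.frame(plateWells(npi))
  expect_lt(abs(mean(w$value[w$role == "pos_ctrl"])), 1e-12)
  expect_lt(abs(mean(w$value[w$role == "neg_ctrl"]) - 1), 1e-12)
  # mean_pos = 100, mean_neg = 1100, raw 600 -> 0.5
  expect_equal(w$value[w$role == "compound" & w$compound == "c1"],
               c(0.5, 0.5))
})

test_that("NPI is invariant to per-plate affine rescaling", {
  raw <- make_tiny_plate()
  a <- 3.7; b <- -250
  scaled <- PlateGrid(transform(as.data.frame(plateWells(raw)),
                                value = a * value + b))
  expect_equal(as.data.frame(plateWells(npiNormalize(raw)))$value,
               as.data.frame(plateWells(npiNormalize(scaled)))$value,
               tolerance = 1e-12)
})

test_that("NPI refuses degenerate or control-free plates", {
  df <- as.data.frame(plateWells(make_tiny_plate()))
  df$value[df$role %in% c("pos_ctrl", "neg_ctrl")] <- 7
  expect_error(npiNormalize(PlateGrid(df)), "degenerate")
})

test_that("differential viability follows the documented conventions", {
  # identical replicate-wise: zero differential, p = 1
  r <- differentialViability(c(0.4, 0.5, 0.6), c(0.4, 0.5, 0.6))
  expect_equal(r$differential, 0)
  expect_equal(r$p.value, 1)
  # both arms constant, unequal: p = 0 by the zero-variance convention
  r <- differentialViability(c(0.2, 0.2, 0.2), c(0.8, 0.8, 0.8))
  expect_equal(r$differential, -0.6)
  expect_equal(r$p.value, 0)
  # both arms constant, equal: p = 1
  expect_equal(differentialViability(c(1, 1), c(1, 1))$p.value, 1)
  expect_error(differentialViability(0.5, c(1, 1)), ">=2 replicates")
})

test_that("the t-test matches independent textbook implementations", {
  tr <- c(0.5, 0.6, 0.7); vh <- c(0.9, 1.0, 1.1)
  r <- differentialViability(tr, vh, var_equal = FALSE)
  expect_equal(r$differential, -0.4, tolerance = 1e-12)
  expect_equal(r$p.value, welch_bruteforce(tr, vh), tolerance = 1e-10)
  set.seed(42)
  for (i in 1:25) {
    x <- rnorm(sample(3:8, 1)); y <- rnorm(sample(3:8, 1), sd = 2)
    expect_equal(differentialViability(x, y, var_equal = FALSE)$p.value,
                 welch_bruteforce(x, y), tolerance = 1e-10)
    expect_equal(differentialViability(x, y)$p.value,
                 pooled_bruteforce(x, y), tolerance = 1e-10)
  }
})

test_that("BH adjustment equals the brute-force step-up definition", {
  expect_equal(adjustBH(0.04), 0.04)
  expect_equal(adjustBH(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(7)
  for (i in 1:200) {
    p <- runif(sample(1:40, 1))
    expect_equal(adjustBH(p), bh_bruteforce(p), tolerance = 1e-12)
  }
  expect_error(adjustBH(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("hit classification applies the published thresholds", {
  res <- data.frame(padj = c(0.01, 0.2, 0.01, 0.04, 0.01),
                    differential = c(-0.4, -0.9, 0.5, -0.25, -0.3))
  cls <- classifyHits(res)$hit_class
  expect_equal(cls, c("sensitized", "unchanged", "tolerant", "unchanged",
                      "unchanged"))  # diff exactly at -0.3 is not a hit
})

test_that("follow-up selection uses a strict cut at the 5 uM arm", {
  res <- data.frame(compound = c("a", "b", "c"),
                    concentration_uM = c(5, 5, 1),
                    mean_vehicle = c(0.69, 0.70, 0.5))
  expect_equal(selectFollowup(res), "a")
})

test_that("scoreScreen recovers an injected sensitization shift", {
  cfg <- plateSimConfig(n_compounds = 30, well_noise_sd = 5,
                        interaction_set = c(cmpd_0003 = -0.5,
                                            cmpd_0010 = -0.5),
                        seed = 11)
  sim <- simulatePlates(cfg)
  res <- classifyHits(scoreScreen(sim$plates))
  hits <- res$compound[res$hit_class == "sensitized" &
                         res$concentration_uM == 5]
  expect_true(all(c("cmpd_0003", "cmpd_0010") %in% hits))
  clean <- res$compound[res$hit_class != "unchanged"]
  expect_true(all(clean %in% c("cmpd_0003", "cmpd_0010")))
})
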