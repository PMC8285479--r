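test_that("rolling ball removes flat background entirely", {
  img <- matrix(500, 32, 32)
  r <- subtractBackground(img, pixel_size = 1, radius_um = 5)
  expect_true(all(r$corrected == 0))
  expect_equal(r$background, img)
})

test_that("rolling ball matches the brute-force opening on a fixture", {
  set.seed(40)
  img <- matrix(runif(64 * 64, 0, 100), 64, 64)
  # add a bright disk of diameter << ball radius
  for (i in 1:64) for (j in 1:64)
    if ((i - 20)^2 + (j - 44)^2 <= 9) img[i, j] <- img[i, j] + 500
  r <- subtractBackground(img, pixel_size = 1, radius_um = 12)
  oracle_bg <- ballopen_bruteforce(img, 12)
  expect_equal(r$background, oracle_bg, tolerance = 1e-12)
  expect_equal(r$corrected, pmax(img - oracle_bg, 0), tolerance = 1e-12)
})

test_that("small bright objects survive subtraction almost unchanged", {
  img <- matrix(100, 96, 96)
  disk <- function(ci, cj) {
    for (i in seq_len(96)) for (j in seq_len(96))
      if ((i - ci)^2 + (j - cj)^2 <= 16) img[i, j] <<- 100 + 1000
  }
  disk(30, 30); disk(70, 60)
  r <- subtractBackground(img, pixel_size = 1, radius_um = 40)
  peak <- max(r$corrected)
  expect_gt(peak, 1000 * 0.95)   # contrast preserved within 5%
  expect_lt(abs(r$corrected[30, 30] - r$corrected[70, 60]), 1000 * 0.05)
})

test_that("a linear ramp background does not bias per-nucleus means", {
  # identical scene rendered with and without the gradient (same seed,
  # same geometry): the gradient's leftover effect on each corrected
  # per-nucleus mean must stay within 5% of its amplitude
  A <- 2000
  with_bg <- simulateImage(imageSimConfig(n_nuclei = 12, noise_sd = 0,
                                          background_amplitude = A,
                                          seed = 6))
  no_bg <- simulateImage(imageSimConfig(n_nuclei = 12, noise_sd = 0,
                                        background_amplitude = 0,
                                        seed = 6))
  expect_identical(with_bg$labels, no_bg$labels)
  m <- function(s) {
    corr <- subtractBackground(s$nuclear, s$pixel_size)$corrected
    tapply(corr[s$labels > 0], s$labels[s$labels > 0], mean)
  }
  resid <- m(with_bg) - m(no_bg)
  expect_true(all(abs(resid) <= A * 0.05))
})

test_that("the disk median filter matches a brute-force median", {
  set.seed(41)
  img <- matrix(runif(32 * 32), 32, 32)
  r_px <- 2.5
  expect_equal(denoiseMedian(img, pixel_size = 1, radius_um = 2.5),
               median_bruteforce(img, r_px), tolerance = 1e-12)
  # constant image unchanged; single impulse removed
  flat <- matrix(3, 16, 16)
  expect_equal(denoiseMedian(flat, 1, 1.5), flat)
  imp <- flat; imp[8, 8] <- 1000
  expect_equal(denoiseMedian(imp, 1, 1.5), flat)
})

test_that("non-touching nuclei are counted and located accurately", {
  sim <- simulateImage(imageSimConfig(n_nuclei = 20,
                                      touching_fraction = 0, seed = 7))
  expect_equal(length(unique(sim$labels[sim$labels > 0])), 20)
  corr <- subtractBackground(sim$nuclear, sim$pixel_size)$corrected
  sm <- denoiseMedian(corr, sim$pixel_size)
  lab <- segmentNuclei(sm, sim$pixel_size)
  expect_equal(max(lab), 20)
  # centroids within 2 px of the ground truth
  cy <- tapply(row(lab)[lab > 0], lab[lab > 0], mean)
  cx <- tapply(col(lab)[lab > 0], lab[lab > 0], mean)
  d <- vapply(seq_len(20), function(k)
    min(sqrt((cx - sim$truth$x[k])^2 + (cy - sim$truth$y[k])^2)),
    numeric(1))
  expect_true(all(d <= 2))
})

test_that("watershed separates touching pairs; disabling it merges them", {
  sim <- simulateImage(imageSimConfig(n_nuclei = 2, touching_fraction = 1,
                                      noise_sd = 200,
                                      background_amplitude = 0, seed = 9))
  corr <- subtractBackground(sim$nuclear, sim$pixel_size)$corrected
  sm <- denoiseMedian(corr, sim$pixel_size)
  expect_equal(max(segmentNuclei(sm, sim$pixel_size)), 2)
  expect_equal(max(segmentNuclei(sm, sim$pixel_size,
                                 use_watershed = FALSE)), 1)
})

test_that("a noise-only image yields no nuclei", {
  found <- vapply(1:20, function(s) {
    sim <- simulateImage(imageSimConfig(n_nuclei = 0, size = c(128, 128),
                                        seed = s))
    max(segmentNuclei(denoiseMedian(
      subtractBackground(sim$nuclear, sim$pixel_size)$corrected,
      sim$pixel_size), sim$pixel_size))
  }, numeric(1))
  expect_true(mean(found == 0) >= 0.99)
  # and a truly blank configuration produces a blank image
  blank <- simulateImage(imageSimConfig(n_nuclei = 0, noise_sd = 0,
                                        background_amplitude = 0,
                                        seed = 1))
  expect_true(all(blank$nuclear == 0))
  expect_true(all(blank$labels == 0))
})

test_that("positivity calls are strict and control-calibrated", {
  lab <- matrix(0L, 10, 12)
  lab[2:3, 2:3] <- 1L; lab[5:6, 5:6] <- 2L; lab[8:9, 8:9] <- 3L
  marker <- matrix(0, 10, 12)
  marker[lab == 1L] <- 10; marker[lab == 2L] <- 20; marker[lab == 3L] <- 30
  r <- measureAndCall(lab, marker, pixel_size = 1, threshold = 5)
  expect_equal(sum(nucleusTable(r)$positive), 3)
  expect_equal(expressionIndex(r), 3 * 20)   # 3 positives, means 10/20/30
  # a mean exactly at the threshold is negative
  r2 <- measureAndCall(lab, marker, pixel_size = 1, threshold = 10)
  expect_false(nucleusTable(r2)$positive[1])
  expect_equal(sum(nucleusTable(r2)$positive), 2)
  # all below threshold: no positives, index 0
  r3 <- measureAndCall(lab, marker, pixel_size = 1, threshold = 100)
  expect_equal(sum(nucleusTable(r3)$positive), 0)
  expect_equal(expressionIndex(r3), 0)
  # doubling the marker doubles the index when the threshold scales too
  r4 <- measureAndCall(lab, marker * 2, pixel_size = 1, threshold = 10)
  expect_equal(expressionIndex(r4), 2 * expressionIndex(r))
  expect_error(measureAndCall(lab, marker, pixel_size = 1),
               "no control data")
})

test_that("control calibration separates a 50% positive population", {
  stats <- vapply(1:15, function(s) {
    ctrl <- simulateImage(imageSimConfig(n_nuclei = 30,
                                         marker_positive_fraction = 0,
                                         seed = 1000 + s))
    test <- simulateImage(imageSimConfig(n_nuclei = 40,
                                         marker_positive_fraction = 0.5,
                                         seed = 2000 + s))
    cm <- controlMeans(ctrl$labels, ctrl$marker)
    res <- measureAndCall(test$labels, test$marker, test$pixel_size,
                          controls = cm)
    called <- nucleusTable(res)$positive
    truth <- test$truth$positive
    c(recall = sum(called & truth) / sum(truth),
      precision = if (sum(called)) sum(called & truth) / sum(called)
      else 1)
  }, numeric(2))
  expect_gte(mean(stats["recall", ]), 0.95)
  expect_gte(mean(stats["precision", ]), 0.95)
})

test_that("the pipeline is equivariant to translation and rotation", {
  sim <- simulateImage(imageSimConfig(n_nuclei = 10, size = c(160, 160),
                                      background_amplitude = 0, seed = 12))
  run <- function(nuc, mk) {
    r <- ifQuantify(nuc, mk, sim$pixel_size, threshold = 2000)
    list(n = nrow(nucleusTable(r)), idx = expressionIndex(r))
  }
  base <- run(sim$nuclear, sim$marker)
  rot <- run(t(sim$nuclear)[ncol(sim$nuclear):1, ],
             t(sim$marker)[ncol(sim$marker):1, ])   # 90 degree rotation
  expect_equal(rot$n, base$n)
  expect_equal(rot$idx, base$idx, tolerance = 1e-9)
})

test_that("micron parameters give matching results across pixel sizes", {
  # the same physical scene sampled at 0.3 and (by 2x2 block averaging)
  # at 0.6 um/px must give the same counts and closely matching means
  block2 <- function(m) {
    ny <- nrow(m) %/% 2L; nx <- ncol(m) %/% 2L
    0.25 * (m[2 * seq_len(ny) - 1L, 2 * seq_len(nx) - 1L] +
            m[2 * seq_len(ny), 2 * seq_len(nx) - 1L] +
            m[2 * seq_len(ny) - 1L, 2 * seq_len(nx)] +
            m[2 * seq_len(ny), 2 * seq_len(nx)])
  }
  for (s in 1:3) {
    sim <- simulateImage(imageSimConfig(pixel_size = 0.3,
                                        size = c(320, 320),
                                        n_nuclei = 10, noise_sd = 500,
                                        marker_positive_fraction = 0.5,
                                        seed = s))
    hi <- ifQuantify(sim$nuclear, sim$marker, 0.3, threshold = 2000)
    lo <- ifQuantify(block2(sim$nuclear), block2(sim$marker), 0.6,
                     threshold = 2000)
    expect_equal(nrow(nucleusTable(lo)), nrow(nucleusTable(hi)))
    m_hi <- sort(nucleusTable(hi)$mean_intensity)
    m_lo <- sort(nucleusTable(lo)$mean_intensity)
    expect_true(all(abs(m_lo / m_hi - 1) <= 0.03))
  }
})
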